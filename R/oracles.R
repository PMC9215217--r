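#' Dense linear-programming solution of the transportation problem
#'
#' Solves the identical linear program as [solve_transport()] with a generic
#' dense two-phase tableau simplex (standard form `min c'x, Ax = b, x >= 0`,
#' Bland's rule). A completely independent code path from the network
#' simplex, intended as a verification oracle on small instances
#' (`m * n` up to a few hundred); used in the test suite.
#'
#' @inheritParams solve_transport
#' @return the optimal objective value (squared base-distance units).
#' @export
solve_transport_lp_oracle <- function(p, q, d = NULL, tol = 1e-9) {
  pv <- if (inherits(p, "probability_field")) p$probs else as.numeric(p)
  qv <- if (inherits(q, "probability_field")) q$probs else as.numeric(q)
  if (is.null(d)) d <- default_base_distance(p, q)
  m <- length(pv); n <- length(qv)
  if (abs(sum(pv) - 1) > tol || abs(sum(qv) - 1) > tol)
    stop_validation("unbalanced masses")
  pv <- pv / sum(pv); qv <- qv / sum(qv)
  cost <- as.vector(d^2)                      # column-major: k = i + (j-1)*m
  keep <- which(is.finite(cost))
  if (length(keep) == 0L) stop_infeasible("no feasible transport")
  nv <- length(keep)
  # equality constraints: m row sums + n col sums, last one redundant
  A <- matrix(0, m + n, nv)
  ri <- ((keep - 1L) %% m) + 1L
  cj <- ((keep - 1L) %/% m) + 1L
  A[cbind(ri, seq_len(nv))] <- 1
  A[cbind(m + cj, seq_len(nv))] <- 1
  A <- A[-(m + n), , drop = FALSE]
  b <- c(pv, qv)[-(m + n)]
  res <- dense_simplex(A, b, cost[keep])
  if (!res$feasible) stop_infeasible("no feasible transport under the given arc mask")
  res$objective
}

# Generic two-phase dense tableau simplex for min c'x, Ax = b (b >= 0),
# x >= 0. Entering variable by Bland's rule; tiny, for test oracles only.
dense_simplex <- function(A, b, cost, tol = 1e-10) {
  nr <- nrow(A); nv <- ncol(A)
  stopifnot(all(b >= -tol))
  b[b < 0] <- 0
  tab <- cbind(A, diag(nr), b)
  basis <- nv + seq_len(nr)
  run_phase <- function(tab, basis, cost_ext, eligible) {
    repeat {
      cb <- cost_ext[basis]
      z <- as.vector(cb %*% tab[, -ncol(tab), drop = FALSE])
      rc <- cost_ext - z
      cand <- which(eligible & rc < -tol)
      if (length(cand) == 0L) break
      ent <- cand[1L]                          # Bland
      col <- tab[, ent]
      rhs <- tab[, ncol(tab)]
      pos <- which(col > tol)
      if (length(pos) == 0L) stop("unbounded LP (cannot occur for transportation)")
      ratio <- rhs[pos] / col[pos]
      lv <- pos[which(ratio <= min(ratio) + tol)]
      lv <- lv[which.min(basis[lv])]           # Bland on the leaving side
      piv <- tab[lv, ent]
      tab[lv, ] <- tab[lv, ] / piv
      other <- setdiff(seq_len(nrow(tab)), lv)
      tab[other, ] <- tab[other, , drop = FALSE] -
        outer(tab[other, ent], tab[lv, ])
      basis[lv] <- ent
    }
    list(tab = tab, basis = basis)
  }
  # phase 1: drive artificials to zero
  c1 <- c(rep(0, nv), rep(1, nr))
  ph1 <- run_phase(tab, basis, c1, rep(TRUE, nv + nr))
  resid <- sum(c1[ph1$basis] * ph1$tab[, ncol(ph1$tab)])
  if (resid > 1e-9) return(list(feasible = FALSE))
  # phase 2: original costs, artificials barred from entering
  c2 <- c(cost, rep(0, nr))
  eligible <- c(rep(TRUE, nv), rep(FALSE, nr))
  ph2 <- run_phase(ph1$tab, ph1$basis, c2, eligible)
  x <- numeric(nv + nr)
  x[ph2$basis] <- ph2$tab[, ncol(ph2$tab)]
  list(feasible = TRUE, objective = sum(cost * x[seq_len(nv)]),
       x = x[seq_len(nv)])
}

#' Closed-form 1D 2-Wasserstein distance
#'
#' For discrete distributions on a line (depth profiles), W2 squared equals
#' the integral over `t in (0, 1)` of the squared difference of the two
#' quantile (inverse-CDF) functions. Exact and solver-free; the independent
#' check for [solve_transport()] with [depth_distance_matrix()] costs.
#'
#' @param p,q [probability_field] objects on depth axes, or bare probability
#'   vectors with `at_p`, `at_q` support positions.
#' @param at_p,at_q support positions (metres) when `p`, `q` are vectors.
#' @return W2 in metres (base-distance units of the supports).
#' @export
wasserstein_1d <- function(p, q, at_p = NULL, at_q = NULL) {
  if (inherits(p, "probability_field")) { at_p <- p$coords$depth; p <- p$probs }
  if (inherits(q, "probability_field")) { at_q <- q$coords$depth; q <- q$probs }
  stopifnot(length(p) == length(at_p), length(q) == length(at_q))
  op <- order(at_p); oq <- order(at_q)
  p <- p[op] / sum(p); zp <- at_p[op]
  q <- q[oq] / sum(q); zq <- at_q[oq]
  kp <- p > 0; kq <- q > 0
  p <- p[kp]; zp <- zp[kp]; q <- q[kq]; zq <- zq[kq]
  cp <- cumsum(p); cq <- cumsum(q)
  cp[length(cp)] <- 1; cq[length(cq)] <- 1
  t <- sort(unique(c(cp, cq)))
  w <- diff(c(0, t))
  eps <- 1e-13
  iP <- pmin(findInterval(t - eps, cp) + 1L, length(cp))
  iQ <- pmin(findInterval(t - eps, cq) + 1L, length(cq))
  sqrt(sum(w * (zp[iP] - zq[iQ])^2))
}
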