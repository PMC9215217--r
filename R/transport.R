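#' Solve the optimal transport problem between two probability fields
#'
#' Finds the transport plan f minimizing `sum_ij f_ij d_ij^2` subject to
#' `f >= 0`, row sums equal to P and column sums equal to Q -- the
#' transportation linear program whose square-rooted optimum is the
#' 2-Wasserstein ("ocean mover's") distance between the two normalized
#' fields. The problem is solved exactly with a transportation (network)
#' simplex started from a Vogel-style initial solution; the returned plan is
#' a basic optimal solution (the optimal objective is unique even when the
#' plan is not).
#'
#' Zero-probability cells are dropped from the support before solving (this
#' cannot change the optimum) and arc indices in the result refer to the
#' original supports. `+Inf` entries of `d` (see [mask_long_arcs()]) forbid
#' arcs; if no feasible plan remains an error of class
#' `omd_infeasible_error` is signalled.
#'
#' @param p,q [probability_field] objects, or bare probability vectors. Each
#'   must sum to 1 within `tol`; inputs are renormalized once before
#'   solving.
#' @param d base-distance matrix of *distances* (not squared), shape
#'   `length(p)` by `length(q)`; computed from the supports
#'   (great-circle km, or |depth difference| m) when omitted.
#' @param tol tolerance on |sum - 1| for each marginal.
#' @return an object of class `transport_plan` with elements
#'   \describe{
#'     \item{arcs}{data frame `i`, `j` (indices into the supports of `p`,
#'       `q`), `mass` (> 0), `dist` (base distance of the arc)}
#'     \item{objective}{optimal value, in squared base-distance units}
#'     \item{w2}{`sqrt(objective)`, in base-distance units}
#'     \item{source, target}{the input fields}
#'     \item{units}{`"km"` or `"m"` when known}
#'   }
#' @seealso [top_mass_arcs()], [transport_summary()], [wasserstein_1d()]
#' @export
solve_transport <- function(p, q, d = NULL, tol = 1e-9) {
  pf <- if (inherits(p, "probability_field")) p else NULL
  qf <- if (inherits(q, "probability_field")) q else NULL
  pv <- if (is.null(pf)) as.numeric(p) else pf$probs
  qv <- if (is.null(qf)) as.numeric(q) else qf$probs
  if (is.null(d)) {
    if (is.null(pf) || is.null(qf))
      stop_validation("d is required when p and q are bare vectors")
    d <- default_base_distance(pf, qf)
  }
  if (nrow(d) != length(pv) || ncol(d) != length(qv))
    stop_validation("d has shape ", nrow(d), "x", ncol(d),
                    " but |P| = ", length(pv), ", |Q| = ", length(qv))
  if (any(pv < 0) || any(qv < 0)) stop_validation("probabilities must be >= 0")
  sp <- sum(pv); sq <- sum(qv)
  if (abs(sp - 1) > tol || abs(sq - 1) > tol)
    stop_validation(sprintf("unbalanced masses: sum(P) = %.12g, sum(Q) = %.12g", sp, sq))
  if (abs(sp - 1) > 1e-12 || abs(sq - 1) > 1e-12)
    message(sprintf("renormalizing inputs (adjustments %.3g, %.3g)", sp - 1, sq - 1))
  pv <- pv / sp
  qv <- qv / sq

  ip <- which(pv > 0)
  iq <- which(qv > 0)
  dd <- d[ip, iq, drop = FALSE]
  if (any(dd < 0)) stop_validation("base distances must be >= 0")
  # quick infeasibility screen: a support cell with no finite arc at all
  if (any(!apply(is.finite(dd), 1, any)) || any(!apply(is.finite(dd), 2, any)))
    stop_infeasible("no feasible transport: some support cell has no allowed arc")

  res <- transport_simplex_cpp(pv[ip], qv[iq], dd^2)
  if (res$status == 2)
    stop_infeasible("no feasible transport under the given arc mask")
  if (res$status != 0)
    stop("transport simplex failed to converge (status ", res$status, ")")

  i <- ip[res$i]; j <- iq[res$j]
  arcs <- data.frame(i = i, j = j, mass = res$mass,
                     dist = d[cbind(i, j)])
  ord <- order(arcs$i, arcs$j)
  arcs <- arcs[ord, , drop = FALSE]
  rownames(arcs) <- NULL
  obj <- max(res$objective, 0)
  structure(list(arcs = arcs, objective = obj, w2 = sqrt(obj),
                 source = pf, target = qf,
                 units = attr(d, "units") %||% NA_character_),
            class = "transport_plan")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.transport_plan <- function(x, ...) {
  u <- if (is.na(x$units)) "" else paste0(" ", x$units)
  cat(sprintf("transport_plan: %d arcs, objective = %.6g%s^2, W2 = %.6g%s\n",
              nrow(x$arcs), x$objective, u, x$w2, u))
  invisible(x)
}

#' @export
summary.transport_plan <- function(object, fraction = 0.10, ...) {
  tm <- top_mass_arcs(object, fraction)
  moved <- object$arcs$mass[object$arcs$dist > 0]
  cat(sprintf("W2 = %.6g %s over %d arcs (%d carrying moved mass %.4g)\n",
              object$w2, ifelse(is.na(object$units), "", object$units),
              nrow(object$arcs), length(moved), sum(moved)))
  cat(sprintf("top %.0f%% of moved mass: %d arcs\n", 100 * fraction, nrow(tm$top)))
  invisible(object)
}

#' @export
as.data.frame.transport_plan <- function(x, ...) transport_summary(x)

#' Split a plan into its heaviest arcs and the rest
#'
#' Sorts the mass-moving arcs by mass (descending) and returns the smallest
#' prefix whose cumulative mass reaches `fraction` of the total moved mass --
#' the "top 10% of the masses" drawn opaque in transport-arrow maps -- plus
#' the remaining arcs. Stay-in-place arcs (zero base distance) carry no moved
#' mass and are excluded; a zero-cost plan yields two empty sets. Ties are
#' broken by (mass descending, i ascending, j ascending).
#'
#' @param plan a [solve_transport()] result.
#' @param fraction in (0, 1); default 0.10.
#' @return list with data frames `top` and `rest`.
#' @export
top_mass_arcs <- function(plan, fraction = 0.10) {
  stopifnot(inherits(plan, "transport_plan"))
  if (!(fraction > 0 && fraction < 1)) stop_validation("fraction must be in (0, 1)")
  a <- plan$arcs[plan$arcs$dist > 0, , drop = FALSE]
  if (nrow(a) == 0L)
    return(list(top = a, rest = a))
  a <- a[order(-a$mass, a$i, a$j), , drop = FALSE]
  cum <- cumsum(a$mass)
  k <- which(cum >= fraction * sum(a$mass) - 1e-15)[1]
  list(top = a[seq_len(k), , drop = FALSE],
       rest = a[-seq_len(k), , drop = FALSE])
}

#' Per-arc table of a transport plan
#'
#' One record per arc with the geographic (lon/lat) or depth endpoints, the
#' transported mass and the arc length; the data behind transport-arrow maps
#' and pooled depth-movement summaries.
#'
#' @param plan a [solve_transport()] result (needs field inputs for
#'   endpoint coordinates).
#' @param drop_zero_dist drop stay-in-place arcs; default TRUE, so a
#'   zero-cost plan yields an empty table.
#' @return data frame of arcs with endpoint coordinates.
#' @export
transport_summary <- function(plan, drop_zero_dist = TRUE) {
  stopifnot(inherits(plan, "transport_plan"))
  a <- plan$arcs
  if (drop_zero_dist) a <- a[a$dist > 0, , drop = FALSE]
  if (is.null(plan$source) || is.null(plan$target)) {
    rownames(a) <- NULL
    return(a)
  }
  src <- plan$source$coords[a$i, , drop = FALSE]
  tgt <- plan$target$coords[a$j, , drop = FALSE]
  names(src) <- paste0(names(src), "_i")
  names(tgt) <- paste0(names(tgt), "_j")
  out <- cbind(src, tgt, mass = a$mass, dist = a$dist)
  rownames(out) <- NULL
  out
}

#' Pool arc tables from several plans
#'
#' Aggregates transported mass over plans by (source, target) endpoint --
#' e.g. by (source depth, target depth) across many profile comparisons, to
#' expose a systematic displacement such as a depth-wise mismatch of the
#' chlorophyll maximum.
#'
#' @param plans list of [solve_transport()] results on like supports.
#' @return data frame of unique endpoint pairs with summed `mass`.
#' @export
pool_transport_summaries <- function(plans) {
  tabs <- lapply(plans, transport_summary)
  all <- do.call(rbind, tabs)
  if (nrow(all) == 0L) return(all)
  keycols <- setdiff(names(all), c("mass", "dist"))
  key <- do.call(paste, c(all[keycols], sep = "\r"))
  mass <- tapply(all$mass, key, sum)
  first <- all[!duplicated(key), c(keycols, "dist"), drop = FALSE]
  first$mass <- as.numeric(mass[do.call(paste, c(first[keycols], sep = "\r"))])
  first <- first[order(-first$mass), , drop = FALSE]
  rownames(first) <- NULL
  first
}

#' @export
plot.transport_plan <- function(x, fraction = 0.10, ...) {
  ts <- transport_summary(x)
  if (nrow(ts) == 0L) {
    plot.new()
    title(main = "zero-cost plan: nothing moved")
    return(invisible(x))
  }
  if (!is.null(x$source) && x$source$kind == "geo") {
    tm <- top_mass_arcs(x, fraction)
    plot(x$source$coords$lon, x$source$coords$lat, pch = ".",
         xlab = "lon", ylab = "lat", ...)
    with(ts, arrows(lon_i, lat_i, lon_j, lat_j, length = 0.05,
                    col = grDevices::adjustcolor("blue", 0.3)))
    if (nrow(tm$top))
      segments(x$source$coords$lon[tm$top$i], x$source$coords$lat[tm$top$i],
               x$target$coords$lon[tm$top$j], x$target$coords$lat[tm$top$j],
               col = "red", lwd = 2)
  } else {
    plot(ts$depth_i, ts$depth_j, cex = 50 * ts$mass,
         xlab = "source depth (m)", ylab = "target depth (m)", ...)
  }
  invisible(x)
}
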