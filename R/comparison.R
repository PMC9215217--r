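#' Root-mean-squared error between two probability fields
#'
#' The pixel-wise benchmark: `sqrt(mean((P_i - Q_i)^2))` over the `n` shared
#' valid cells. Unlike the Wasserstein distance, RMSE requires the two
#' distributions to live on the exact same cells.
#'
#' @param p,q [probability_field] objects on the identical support, or bare
#'   equal-length numeric vectors.
#' @return non-negative scalar (dimensionless: probabilities in, probability
#'   units out).
#' @export
rmse <- function(p, q) {
  pv <- if (inherits(p, "probability_field")) p$probs else as.numeric(p)
  qv <- if (inherits(q, "probability_field")) q$probs else as.numeric(q)
  if (inherits(p, "probability_field") && inherits(q, "probability_field") &&
      !same_support(p, q))
    stop_validation("fields are not on the same cells; reconcile them to a ",
                    "shared support before computing RMSE")
  if (length(pv) != length(qv))
    stop_validation("fields are not on the same cells; reconcile them to a ",
                    "shared support before computing RMSE")
  sqrt(mean((pv - qv)^2))
}

#' Pairwise distance matrix over a collection of fields
#'
#' Computes the `N(N-1)/2` unique pairwise distances between normalized
#' fields -- Wasserstein (via [solve_transport()]) or RMSE -- and mirrors
#' them into a symmetric matrix with a zero diagonal, e.g. the 24 x 24
#' matrix over 12 climatology months from two data sources.
#'
#' @param fields list of [probability_field] objects (or of
#'   [scalar_field()]/[depth_profile()] objects, which are normalized
#'   first).
#' @param metric `"wasserstein"` or `"rmse"`.
#' @param d optional base-distance matrix shared by all pairs (valid when
#'   all fields share one support); computed once from the first field's
#'   support when omitted and sharable.
#' @param labels row/column labels; defaults to `names(fields)`.
#' @return an `omd_distmat`: a symmetric labelled matrix.
#' @export
pairwise_distance_matrix <- function(fields,
                                     metric = c("wasserstein", "rmse"),
                                     d = NULL, labels = names(fields)) {
  metric <- match.arg(metric)
  if (length(fields) < 2L) stop_validation("need at least two fields")
  fields <- lapply(fields, normalize_field)
  N <- length(fields)
  if (is.null(labels)) labels <- as.character(seq_len(N))
  shared <- all(vapply(fields[-1], function(f) same_support(fields[[1]], f), logical(1)))
  if (metric == "rmse" && !shared)
    stop_validation("RMSE requires all fields on a shared support")
  if (metric == "wasserstein" && is.null(d) && shared)
    d <- default_base_distance(fields[[1]], fields[[1]])
  D <- matrix(0, N, N, dimnames = list(labels, labels))
  for (a in seq_len(N - 1L)) {
    for (b in seq.int(a + 1L, N)) {
      v <- tryCatch(
        if (metric == "rmse") rmse(fields[[a]], fields[[b]])
        else solve_transport(fields[[a]], fields[[b]], d = d)$w2,
        error = function(e) stop("pair (", labels[a], ", ", labels[b], "): ",
                                 conditionMessage(e), call. = FALSE))
      D[a, b] <- D[b, a] <- v
    }
  }
  structure(D, class = c("omd_distmat", "matrix", "array"), metric = metric)
}

#' @export
print.omd_distmat <- function(x, ...) {
  cat(sprintf("%d x %d %s distance matrix\n", nrow(x), ncol(x),
              attr(x, "metric") %||% ""))
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x))), drop = FALSE])
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Classical multidimensional scaling of a distance matrix
#'
#' Embeds the N objects in `dim` dimensions via the eigendecomposition of
#' the doubly centred matrix of squared distances (`-1/2 J D^2 J`):
#' coordinates are the leading eigenvectors scaled by the square roots of
#' their eigenvalues. Negative eigenvalues (which arise for non-Euclidean
#' Wasserstein matrices) are clamped to zero; if fewer than `dim`
#' eigenvalues are positive the missing coordinates are zero-padded with a
#' warning. Each axis is given a deterministic sign: the coordinate of
#' largest magnitude is made positive. For a distance matrix that is exactly
#' Euclidean-embeddable in `dim` dimensions the embedding reproduces all
#' pairwise distances (up to rigid motion).
#'
#' @param D symmetric distance matrix (an `omd_distmat` or plain matrix).
#' @param dim embedding dimension, default 2.
#' @return an `omd_mds` object: `points` (N x dim matrix, labelled),
#'   `eig` (all eigenvalues, descending), `eig_clamped` (negatives set to
#'   0), and `gof` (share of variance captured).
#' @export
classical_mds <- function(D, dim = 2) {
  D <- as.matrix(D)
  N <- nrow(D)
  if (N < dim + 1L) stop_validation("need at least dim + 1 objects")
  fit <- cmdscale(D, k = dim, eig = TRUE)
  pts <- fit$points
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 1L)
  if (ncol(pts) < dim) pts <- cbind(pts, matrix(0, N, dim - ncol(pts)))
  ev_all <- sort(fit$eig, decreasing = TRUE)
  npos <- sum(ev_all > max(ev_all[1], 0) * 1e-12)
  if (npos < dim) {
    warning(sprintf("only %d positive eigenvalue(s); padding %d zero coordinate(s)",
                    npos, dim - npos))
    pts[, seq.int(npos + 1L, dim)] <- 0
  }
  for (k in seq_len(ncol(pts))) {
    jmax <- which.max(abs(pts[, k]))
    if (pts[jmax, k] < 0) pts[, k] <- -pts[, k]
  }
  rownames(pts) <- rownames(D)
  colnames(pts) <- paste0("mds", seq_len(ncol(pts)))
  ev <- ev_all
  structure(list(points = pts, eig = ev, eig_clamped = pmax(ev, 0),
                 gof = fit$GOF),
            class = "omd_mds")
}

#' @export
print.omd_mds <- function(x, ...) {
  cat(sprintf("classical MDS embedding: %d points in %d dimensions (GOF %.3f)\n",
              nrow(x$points), ncol(x$points), x$gof[2]))
  print(head(x$points))
  if (nrow(x$points) > 6) cat("...\n")
  invisible(x)
}

#' @export
plot.omd_mds <- function(x, connect = TRUE, ...) {
  plot(x$points[, 1], x$points[, 2], xlab = "MDS 1", ylab = "MDS 2", ...)
  if (!is.null(rownames(x$points)))
    graphics::text(x$points[, 1], x$points[, 2], rownames(x$points),
                   pos = 3, cex = 0.7)
  if (connect && nrow(x$points) > 2)
    lines(x$points[, 1], x$points[, 2], lty = 3)
  invisible(x)
}
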