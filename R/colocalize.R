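#' Colocalization window
#'
#' The space-time vicinity used to average one dataset around each
#' observation of another: half-widths of 2 days and 5 metres by default,
#' with inclusive boundaries.
#'
#' @param time_halfwidth_days,depth_halfwidth_m positive half-widths.
#' @export
colocalization_window <- function(time_halfwidth_days = 2,
                                  depth_halfwidth_m = 5) {
  if (time_halfwidth_days <= 0 || depth_halfwidth_m <= 0)
    stop_validation("window half-widths must be > 0")
  structure(list(time_halfwidth_days = time_halfwidth_days,
                 depth_halfwidth_m = depth_halfwidth_m),
            class = "colocalization_window")
}

as_day_number <- function(x) {
  if (inherits(x, "Date")) as.numeric(x)
  else if (inherits(x, "POSIXt")) as.numeric(as.Date(x))
  else if (is.character(x)) as.numeric(as.Date(x))
  else as.numeric(x)
}

#' Colocalize gridded/model records to in-situ samples
#'
#' For each in-situ sample at (time t, depth z), the colocalized model value
#' is the unweighted arithmetic mean of the model values within the window
#' (|dt| <= 2 days and |dz| <= 5 m by default). Samples with no model record
#' in the window are dropped and reported in the `"dropped"` attribute.
#'
#' @param model_records data frame with columns `date` (Date, date string or
#'   numeric day), `depth` (m) and `value`.
#' @param samples in-situ samples, same columns; `NA` values are treated as
#'   missing and dropped.
#' @param window a [colocalization_window()].
#' @return data frame `date, depth, insitu, model` (one row per matched
#'   sample), with attribute `dropped` (the unmatched sample rows).
#' @export
colocalize <- function(model_records, samples,
                       window = colocalization_window()) {
  model_records <- as.data.frame(model_records)
  samples <- as.data.frame(samples)
  need <- c("date", "depth", "value")
  if (!all(need %in% names(model_records)) || !all(need %in% names(samples)))
    stop_validation("model_records and samples need columns date, depth, value")
  if (nrow(model_records) == 0L || nrow(samples) == 0L)
    stop_validation("model records and samples must be nonempty")
  samples <- samples[!is.na(samples$value), , drop = FALSE]
  mt <- as_day_number(model_records$date)
  mz <- model_records$depth
  mv <- model_records$value
  st <- as_day_number(samples$date)
  sz <- samples$depth
  out <- vector("list", nrow(samples))
  matched <- logical(nrow(samples))
  for (k in seq_len(nrow(samples))) {
    sel <- abs(mt - st[k]) <= window$time_halfwidth_days &
           abs(mz - sz[k]) <= window$depth_halfwidth_m & !is.na(mv)
    if (any(sel)) {
      matched[k] <- TRUE
      out[[k]] <- data.frame(date = samples$date[k], depth = sz[k],
                             insitu = samples$value[k],
                             model = mean(mv[sel]))
    }
  }
  if (!any(matched))
    stop_validation("no overlapping records: 0 of ", nrow(samples),
                    " attempted matches fell inside the window")
  res <- do.call(rbind, out[matched])
  rownames(res) <- NULL
  attr(res, "dropped") <- samples[!matched, , drop = FALSE]
  if (any(!matched))
    message(sum(!matched), " of ", nrow(samples),
            " samples had no model record in the window and were dropped")
  res
}

#' Build a normalized profile from irregular samples
#'
#' Assigns each sample to the nearest depth of the target axis (ties to the
#' shallower depth), averages samples falling in the same bin (concentration
#' is an intensive quantity), and normalizes the binned profile to sum to
#' one. Axis depths receiving no sample stay in the support with probability
#' zero.
#'
#' @param samples data frame with columns `depth` and `value` (a `date`
#'   column, if present, is ignored -- subset per date first).
#' @param axis a [depth_axis()].
#' @return a [probability_field] on `axis`.
#' @export
profile_from_samples <- function(samples, axis) {
  stopifnot(inherits(axis, "depth_axis"))
  samples <- as.data.frame(samples)
  samples <- samples[!is.na(samples$value), , drop = FALSE]
  if (nrow(samples) == 0L) stop_validation("all samples missing")
  if (any(samples$value < 0)) stop_validation("negative values are not allowed")
  z <- axis$depths
  bin <- vapply(samples$depth, function(d) which.min(abs(z - d)), integer(1))
  vals <- rep(0, length(z))
  means <- tapply(samples$value, bin, mean)
  vals[as.integer(names(means))] <- as.numeric(means)
  if (sum(vals) <= 0) stop_validation("zero total mass: no positive sample values")
  normalize_field(depth_profile(axis, vals))
}
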