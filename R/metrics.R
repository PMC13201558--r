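#' Regional statistics over equal axial thirds
#'
#' Partitions the axial extent `[0, extent]` into three equal intervals
#' (proximal = closest to the inlet, then middle and distal) and reports
#' mean, sample standard deviation, peak and count per segment. Intervals
#' are right-closed (a sample exactly on an interior boundary belongs to the
#' upstream segment); the origin belongs to the proximal segment.
#'
#' @param values Numeric samples.
#' @param positions Axial positions of the samples, mm (same origin as the
#'   extent).
#' @param extent Axial extent, mm.
#' @return A data frame with rows `proximal`, `middle`, `distal` and columns
#'   `segment`, `mean`, `sd`, `peak`, `n`. Empty segments carry `n = 0` and
#'   `NA` statistics.
#' @examples
#' segment_stats(1:9, positions = 1:9, extent = 9)$mean  # 2, 5, 8
#' @export
segment_stats <- function(values, positions, extent) {
  stopifnot(length(values) == length(positions), length(values) > 0, extent > 0)
  brk <- c(0, extent / 3, 2 * extent / 3, extent)
  seg <- cut(positions, breaks = brk, labels = c("proximal", "middle", "distal"),
             right = TRUE, include.lowest = TRUE)
  out <- lapply(levels(seg), function(s) {
    v <- values[seg == s & !is.na(seg)]
    if (length(v) == 0)
      data.frame(segment = s, mean = NA_real_, sd = NA_real_,
                 peak = NA_real_, n = 0L)
    else
      data.frame(segment = s, mean = mean(v),
                 sd = if (length(v) > 1) stats::sd(v) else 0,
                 peak = max(v), n = length(v))
  })
  do.call(rbind, out)
}

#' Mean absolute percentage error
#'
#' `100 * mean(|pred - ref| / |ref|)` over pairs whose reference magnitude
#' exceeds a floor; pairs below the floor are excluded (their count is
#' attached as attribute `n_excluded`). The default floor is 1% of the median
#' absolute reference value, guarding against division by near-zero
#' references.
#'
#' @param pred,ref Paired numeric vectors of equal length.
#' @param eps Exclusion floor on `|ref|`; `NULL` for the default.
#' @return MAPE in percent.
#' @examples
#' mape(c(1, 2, 3), c(2, 2, 2))  # 33.33
#' @export
mape <- function(pred, ref, eps = NULL) {
  stopifnot(length(pred) == length(ref), length(ref) > 0)
  if (is.null(eps)) eps <- 0.01 * stats::median(abs(ref))
  keep <- abs(ref) > eps
  if (!any(keep)) stop("all pairs excluded by the reference floor; MAPE undefined")
  out <- 100 * mean(abs(pred[keep] - ref[keep]) / abs(ref[keep]))
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties), returned as a
#' fraction with the percent form attached as attribute `percent`.
#'
#' @param pred,ref Paired numeric vectors, `n >= 3`.
#' @return Correlation in \[-1, 1\].
#' @examples
#' spearman_rho(1:5, c(1, 3, 2, 5, 4))  # 0.8
#' @export
spearman_rho <- function(pred, ref) {
  stopifnot(length(pred) == length(ref), length(pred) >= 3)
  rp <- rank(pred, ties.method = "average")
  rr <- rank(ref, ties.method = "average")
  if (stats::sd(rp) == 0 || stats::sd(rr) == 0)
    stop("zero-variance ranks: Spearman correlation undefined")
  rho <- stats::cor(rp, rr, method = "pearson")
  attr(rho, "percent") <- 100 * rho
  rho
}

#' Spatial variance of a wall shear stress map
#'
#' Sample variance (n - 1 denominator) of the WSS magnitudes over the wall
#' points in the analyzed extent.
#'
#' @param wss A `wss_map`/`reference_wss` (column `wss_pa`) or a numeric
#'   vector of magnitudes.
#' @return Variance in Pa^2.
#' @export
spatial_variance <- function(wss) {
  v <- if (is.data.frame(wss)) wss$wss_pa else wss
  if (length(v) < 2) stop("spatial variance needs at least 2 wall points")
  stats::var(v)
}

#' Welch group comparison of segment means
#'
#' Two-sided unequal-variance t-test between two groups of regional means
#' (e.g. malapposed vs well-apposed segments). A paired t-test is available.
#' Identical groups return `p = 1` with `t = 0`.
#'
#' @param a,b Numeric vectors of group values.
#' @param paired Use a paired test.
#' @return A list with `t`, `p_value`, `df`.
#' @export
group_test <- function(a, b, paired = FALSE) {
  if (length(a) == length(b) && all(a == b))
    return(list(t = 0, p_value = 1, df = NA_real_))
  ht <- stats::t.test(a, b, paired = paired, var.equal = FALSE)
  list(t = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter))
}

#' Compare an estimated map against a reference map
#'
#' Resamples the reference onto the predicted sample positions by
#' nearest-neighbor interpolation, then reports per-segment percent
#' differences of the means (`100 (mean_pred - mean_ref) / mean_ref`),
#' pointwise MAPE, Spearman correlation, spatial variances, peaks, and a
#' Welch test between the two sets of segment means. The comparison is
#' asymmetric: MAPE and percent differences normalize by the reference.
#'
#' @param pred_pos,pred Sample positions (mm) and values of the prediction.
#' @param ref_pos,ref Sample positions (mm) and values of the reference.
#' @param extent Axial extent for segmenting, mm (default: span of
#'   `pred_pos`).
#' @param offset Rigid axial shift applied to the reference positions before
#'   resampling, mm (see [align_offset()]).
#' @return An object of class `comparison_report` (a list with elements
#'   `segments`, `mape_pct`, `spearman`, `spearman_pct`,
#'   `spatial_variance_pred`, `spatial_variance_ref`, `peak_pred`,
#'   `peak_ref`, `p_value`).
#' @export
compare_maps <- function(pred_pos, pred, ref_pos, ref,
                         extent = max(pred_pos), offset = 0) {
  stopifnot(length(pred_pos) == length(pred), length(ref_pos) == length(ref))
  ref_pos <- ref_pos + offset
  if (max(ref_pos) < min(pred_pos) || min(ref_pos) > max(pred_pos))
    stop("no spatial overlap between prediction and reference")
  ref_rs <- .nearest_neighbor(ref_pos, ref, pred_pos)
  sp <- segment_stats(pred, pred_pos, extent)
  sr <- segment_stats(ref_rs, pred_pos, extent)
  segs <- data.frame(segment = sp$segment,
                     mean_pred = sp$mean, sd_pred = sp$sd, peak_pred = sp$peak,
                     mean_ref = sr$mean, sd_ref = sr$sd, peak_ref = sr$peak,
                     n = sp$n,
                     pct_diff = 100 * (sp$mean - sr$mean) / sr$mean)
  mp <- mape(pred, ref_rs)
  # a constant map (e.g. the analytic reference of a straight vessel) has
  # zero-variance ranks; report NA rather than abort
  rho <- tryCatch(spearman_rho(pred, ref_rs), error = function(e) NA_real_)
  structure(list(segments = segs,
                 mape_pct = as.numeric(mp),
                 mape_n_excluded = attr(mp, "n_excluded"),
                 spearman = as.numeric(rho),
                 spearman_pct = 100 * as.numeric(rho),
                 spatial_variance_pred = spatial_variance(pred),
                 spatial_variance_ref = spatial_variance(ref_rs),
                 peak_pred = max(pred), peak_ref = max(ref_rs),
                 p_value = group_test(sp$mean, sr$mean)$p_value),
            class = "comparison_report")
}

.nearest_neighbor <- function(pos, val, out_pos) {
  o <- order(pos)
  pos <- pos[o]; val <- val[o]
  mid <- pos[-length(pos)] + diff(pos) / 2
  idx <- findInterval(out_pos, mid) + 1L
  val[idx]
}

#' Exhaustive rigid axial offset search
#'
#' Finds the reference shift (within `+/- search` mm) minimizing the mean
#' squared nearest-neighbor mismatch against the prediction; a 1D stand-in
#' for point-cloud registration when maps are nominally aligned but offset by
#' a fraction of a millimetre.
#'
#' @param pred_pos,pred Prediction samples.
#' @param ref_pos,ref Reference samples.
#' @param search Half-width of the search window, mm.
#' @param step Search step, mm.
#' @return The best offset, mm.
#' @export
align_offset <- function(pred_pos, pred, ref_pos, ref, search = 0.5,
                         step = 0.05) {
  offs <- seq(-search, search, by = step)
  sse <- vapply(offs, function(o) {
    r <- .nearest_neighbor(ref_pos + o, ref, pred_pos)
    mean((pred - r)^2)
  }, numeric(1))
  offs[which.min(sse)]
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> MAPE %.2f%%, Spearman %.2f%%, p = %.4g\n",
              x$mape_pct, x$spearman_pct, x$p_value))
  print(x$segments, row.names = FALSE)
  invisible(x)
}

#' Write a comparison report to JSON (with a CSV twin of the segment table)
#'
#' @param report A `comparison_report`.
#' @param path JSON output path; the CSV twin replaces the extension.
#' @return The JSON path, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "comparison_report"))
  segs <- report$segments
  seg_list <- lapply(seq_len(nrow(segs)), function(i)
    list(mean = segs$mean_pred[i], sd = segs$sd_pred[i],
         peak = segs$peak_pred[i], mean_ref = segs$mean_ref[i],
         pct_diff = segs$pct_diff[i]))
  names(seg_list) <- segs$segment
  out <- list(segments = seg_list,
              mape_pct = report$mape_pct,
              spearman_pct = report$spearman_pct,
              spatial_variance_pred = report$spatial_variance_pred,
              spatial_variance_ref = report$spatial_variance_ref,
              peak_pred = report$peak_pred, peak_ref = report$peak_ref,
              p_value = report$p_value)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  utils::write.csv(segs, sub("\\.json$", ".csv", path), row.names = FALSE)
  invisible(path)
}
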