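#' Pearson correlation of log relative risks
#'
#' The two risk surfaces are compared on the log scale (the natural scale of
#' the linear predictor, and the scale of the comparison scatter plot); an
#' RR-scale option is provided for sensitivity.
#'
#' @param rr1,rr2 positive relative-risk vectors of equal length (>= 3).
#' @param log_scale correlate `log(rr)` (default) or raw RRs.
#' @return Pearson correlation in `[-1, 1]`.
#' @examples
#' pearson_log_rr(exp(c(0, 1, 2)), exp(c(1, 0, 2)))  # 0.5
#' @export
pearson_log_rr <- function(rr1, rr2, log_scale = TRUE) {
  if (length(rr1) != length(rr2)) stop("surfaces differ in length")
  if (length(rr1) < 3L) stop("need at least 3 areas")
  if (any(rr1 <= 0) || any(rr2 <= 0)) stop("relative risks must be positive")
  x <- if (log_scale) log(rr1) else rr1
  y <- if (log_scale) log(rr2) else rr2
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in a risk surface; correlation undefined")
  stats::cor(x, y)
}

#' Four-way high/low coincidence classification
#'
#' Each area is labelled high for an outcome when its relative risk strictly
#' exceeds the threshold (default 1, the map-average risk); ties count as
#' low. Areas are then classified `high_high`, `low_low` (matched) or
#' `high_low`, `low_high` (mismatched), and the matched/mismatched
#' percentages are reported.
#'
#' @param rr1,rr2 positive relative-risk vectors of equal length.
#' @param threshold high/low cutpoint on the RR scale.
#' @param area_ids optional labels.
#' @return Object of class `coincidence_result`: list with `areas` (data
#'   frame: `area_id`, `log_rr1`, `log_rr2`, `category`), `counts` (named
#'   table over the four categories), `matched_pct`, `mismatched_pct`,
#'   `threshold`, and `tie_rule = "ties classified low"`.
#' @examples
#' classify_coincidence(c(2, 0.5, 2, 0.5), c(2, 0.5, 0.5, 2))$matched_pct
#' @export
classify_coincidence <- function(rr1, rr2, threshold = 1,
                                 area_ids = NULL) {
  if (length(rr1) != length(rr2)) stop("surfaces differ in length")
  if (any(rr1 <= 0) || any(rr2 <= 0)) stop("relative risks must be positive")
  n <- length(rr1)
  if (is.null(area_ids)) area_ids <- as.character(seq_len(n))
  hi1 <- rr1 > threshold
  hi2 <- rr2 > threshold
  category <- ifelse(hi1, ifelse(hi2, "high_high", "high_low"),
                     ifelse(hi2, "low_high", "low_low"))
  counts <- table(factor(category, levels = c("high_high", "low_low",
                                              "high_low", "low_high")))
  matched <- 100 * sum(counts[c("high_high", "low_low")]) / n
  structure(list(
    areas = data.frame(area_id = area_ids, log_rr1 = log(rr1),
                       log_rr2 = log(rr2), category = category),
    counts = counts, matched_pct = matched,
    mismatched_pct = 100 - matched, threshold = threshold,
    tie_rule = "ties classified low"),
    class = "coincidence_result")
}

#' Compare two fitted relative-risk surfaces
#'
#' Aligns two [relative_risk()] surfaces by area id, then computes the
#' Pearson correlation of the posterior-mean log relative risks and the
#' four-way coincidence classification. This is the overlap summary of the
#' whole analysis: the correlation measures how similar the two risk maps
#' are, and the matched percentage says in how many areas both outcomes sit
#' on the same side of the average risk.
#'
#' @param surface1,surface2 `risk_surface` data frames sharing one area set.
#' @param threshold high/low cutpoint on the RR scale.
#' @return A `coincidence_result` (see [classify_coincidence()]) with the
#'   correlation in `$pearson_r` and scatter-ready records in `$areas`.
#' @export
compare_surfaces <- function(surface1, surface2, threshold = 1) {
  for (s in list(surface1, surface2))
    if (!all(c("area_id", "rr_mean") %in% names(s)))
      stop("surfaces need 'area_id' and 'rr_mean' columns")
  only1 <- setdiff(surface1$area_id, surface2$area_id)
  only2 <- setdiff(surface2$area_id, surface1$area_id)
  if (length(only1) || length(only2))
    stop("area sets differ; only in surface 1: ",
         paste(only1, collapse = ", "), "; only in surface 2: ",
         paste(only2, collapse = ", "))
  s2 <- surface2[match(surface1$area_id, surface2$area_id), ]
  res <- classify_coincidence(surface1$rr_mean, s2$rr_mean,
                              threshold = threshold,
                              area_ids = surface1$area_id)
  res$pearson_r <- pearson_log_rr(surface1$rr_mean, s2$rr_mean)
  res
}

#' @export
print.coincidence_result <- function(x, ...) {
  cat("Risk-surface coincidence analysis\n")
  if (!is.null(x$pearson_r))
    cat(sprintf("  Pearson r (log RR): %.3f\n", x$pearson_r))
  cat(sprintf("  matched: %.1f%%  mismatched: %.1f%%\n",
              x$matched_pct, x$mismatched_pct))
  print(x$counts)
  invisible(x)
}
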