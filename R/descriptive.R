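#' Per-group summary of a measurement matrix
#'
#' Exploratory statistics per group and measurement: sample size, mean,
#' and min-max range, the primitives behind per-element comparison tables.
#'
#' @param m An `osteo_matrix` from [select_matrix()].
#' @param unit Output unit, `"mm"` (default) or `"cm"`.
#' @return Tibble with columns `group_label`, `element`, `code`, `n`,
#'   `mean`, `min`, `max`; one row per (group, code) with n >= 1.
#' @export
group_summary <- function(m, unit = c("mm", "cm")) {
  unit <- match.arg(unit)
  stopifnot(inherits(m, "osteo_matrix"), nrow(m$x) >= 1)
  spec <- assign_groups(m$specimens)
  fac <- 1
  if (unit == "cm") fac <- 0.1
  long <- tibble::tibble(
    group_label = rep(spec$group_label, times = ncol(m$x)),
    code = rep(m$codes, each = nrow(m$x)),
    value = as.vector(m$x) * fac
  )
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$group_label, .data$code),
    n = dplyr::n(),
    mean = mean(.data$value),
    min = min(.data$value),
    max = max(.data$value),
    .groups = "drop"
  )
  out$element <- m$element
  out[, c("group_label", "element", "code", "n", "mean", "min", "max")]
}

#' Percent difference between two group means
#'
#' Asymmetric by design, with the second argument as the reference group:
#' `100 * (mean_a - mean_b) / mean_b`. A symmetric variant (mean of the
#' two as denominator) is available with `symmetric = TRUE`.
#'
#' @param mean_a,mean_b Group means; `mean_b` (the reference) must be
#'   positive.
#' @param symmetric Use the average of the two means as denominator.
#' @return Percent difference (positive when `mean_a > mean_b`).
#' @examples
#' percent_difference(110, 100) # 10
#' @export
percent_difference <- function(mean_a, mean_b, symmetric = FALSE) {
  if (any(mean_b <= 0)) stop("reference mean must be positive")
  denom <- if (symmetric) (mean_a + mean_b) / 2 else mean_b
  100 * (mean_a - mean_b) / denom
}

#' Overlap of two min-max ranges
#'
#' @param range_a,range_b Numeric length-2 vectors `c(lo, hi)` with
#'   `lo <= hi`.
#' @return The overlapping interval `c(lo, hi)` (possibly degenerate, a
#'   single shared point), or `NULL` when the ranges are disjoint.
#' @examples
#' overlap_range(c(66, 78), c(78, 92)) # touching: c(78, 78)
#' overlap_range(c(67, 83), c(87, 106)) # disjoint: NULL
#' @export
overlap_range <- function(range_a, range_b) {
  if (length(range_a) != 2L || length(range_b) != 2L ||
      any(is.na(c(range_a, range_b)))) {
    stop("ranges must be numeric length-2 vectors")
  }
  if (range_a[1] > range_a[2] || range_b[1] > range_b[2]) {
    stop("malformed interval: lo > hi")
  }
  lo <- max(range_a[1], range_b[1])
  hi <- min(range_a[2], range_b[2])
  if (lo > hi) NULL else c(lo, hi)
}

#' Five-number boxplot statistics with Tukey whiskers
#'
#' Backs the per-group isometric-size boxplots: median, quartiles, and
#' whiskers at the most extreme data points within 1.5 x IQR of the box.
#'
#' @param x Numeric vector.
#' @return Tibble with `ymin`, `lower`, `middle`, `upper`, `ymax`, and a
#'   list column `outliers`.
#' @export
boxplot_stats <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- x[x >= lo_fence & x <= hi_fence]
  tibble::tibble(
    ymin = min(inside), lower = q[1], middle = q[2], upper = q[3],
    ymax = max(inside),
    outliers = list(x[x < lo_fence | x > hi_fence])
  )
}

#' Write per-element summary tables as CSV
#'
#' @param summaries Tibble from [group_summary()] (possibly several
#'   elements bound together).
#' @param dir Output directory (created if needed).
#' @return Paths written, invisibly.
#' @export
write_summary_tables <- function(summaries, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (el in unique(summaries$element)) {
    p <- file.path(dir, paste0("summary_", el, ".csv"))
    readr::write_csv(summaries[summaries$element == el, ], p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
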