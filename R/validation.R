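#' Class values at point locations
#'
#' Looks up the quantile class of the cell containing each point
#' (half-open cell rule). Points outside the grid or outside the study
#' area (where the class map is `NA`) are excluded and counted, not
#' errors.
#'
#' @param class_map A [quantile_class_map()].
#' @param points Data frame (or 2-column matrix) with `x` and `y`.
#' @return List with `classes` (integer per point, `NA` for excluded
#'   points) and `n_excluded`.
#' @export
classes_at_points <- function(class_map, points) {
  if (is.matrix(points)) points <- data.frame(x = points[, 1L], y = points[, 2L])
  cls <- layer_values_at(class_map$classes, class_map$grid, points$x, points$y)
  cls <- as.integer(cls)
  list(classes = cls, n_excluded = sum(is.na(cls)))
}

#' Spearman rank correlation between class value and location count
#'
#' Correlates the class values (1..k) with the number of locations
#' falling in each class, using average ranks for tied counts. With zero
#' variance among counts the statistic is undefined and `NA` is returned.
#'
#' @param per_class_counts Integer vector: locations per class, ordered
#'   class 1..k.
#' @return Spearman's rho in \[-1, 1\], or `NA`.
#' @export
spearman_class_counts <- function(per_class_counts) {
  if (length(per_class_counts) < 2L) stop("need counts for at least 2 classes")
  if (length(unique(per_class_counts)) == 1L) return(NA_real_)
  suppressWarnings(
    cor(seq_along(per_class_counts), per_class_counts, method = "spearman")
  )
}

#' Validate a class map against point locations
#'
#' Overlays locations (e.g. verified outlier observations or GPS fixes)
#' on a predicted-use class map and computes the evaluation statistics:
#' Spearman rank correlation between class and per-class location counts,
#' mean class at the locations, and the percentage of locations in the
#' top class and in the top half of classes (classes 6-10 on a 10-class
#' map).
#'
#' @param class_map A [quantile_class_map()].
#' @param points Data frame with `x`, `y`.
#' @return Object of class `validation_summary`: `n_points`,
#'   `n_excluded`, `rho`, `mean_class`, `pct_top1`, `pct_top5`,
#'   `per_class_counts`.
#' @export
validation_summary <- function(class_map, points) {
  cp <- classes_at_points(class_map, points)
  cls <- cp$classes[!is.na(cp$classes)]
  if (!length(cls)) stop("all points fall outside the study area")
  k <- class_map$n_classes
  counts <- tabulate(cls, nbins = k)
  structure(list(
    n_points = length(cp$classes),
    n_excluded = cp$n_excluded,
    rho = spearman_class_counts(counts),
    mean_class = mean(cls),
    pct_top1 = 100 * mean(cls == k),
    pct_top5 = 100 * mean(cls > k / 2),
    per_class_counts = counts
  ), class = "validation_summary")
}

#' @export
print.validation_summary <- function(x, ...) {
  cat(sprintf(
    "<validation_summary> n = %d (%d excluded)\n  rho = %.3f, mean class = %.2f, top class %.1f%%, top half %.1f%%\n",
    x$n_points, x$n_excluded, x$rho, x$mean_class, x$pct_top1, x$pct_top5))
  invisible(x)
}
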