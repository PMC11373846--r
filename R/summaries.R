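#' Covariate availability by region
#'
#' Per region and covariate: the median, the 50% interquartile range
#' (0.25/0.75 quantiles) and the 95% range (0.025/0.975 quantiles), with
#' linear interpolation. Empty regions are omitted with a warning.
#'
#' @param landscape A [landscape()].
#' @param regions Character matrix of region labels (`NA` outside);
#'   defaults to `landscape$masks$region`.
#' @return Data frame with columns `region`, `covariate`, `q025`, `q25`,
#'   `median`, `q75`, `q975`.
#' @export
region_summary <- function(landscape, regions = landscape$masks$region) {
  if (is.null(regions)) stop("no region layer supplied")
  check_layer_dim(regions, landscape$grid, "regions")
  labs <- sort(unique(regions[!is.na(regions)]))
  rows <- list()
  for (rg in labs) {
    in_rg <- !is.na(regions) & regions == rg
    if (!any(in_rg)) {
      warning("region '", rg, "' is empty; omitted")
      next
    }
    for (nm in covariate_names()) {
      q <- quantile(landscape$covariates[[nm]][in_rg],
                    probs = c(0.025, 0.25, 0.5, 0.75, 0.975),
                    type = 7, names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        region = rg, covariate = nm,
        q025 = q[1L], q25 = q[2L], median = q[3L], q75 = q[4L], q975 = q[5L])
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Mean covariate values within each use class
#'
#' Arithmetic mean of every habitat covariate over the cells of each
#' quantile class; a positive relationship between class and covariate
#' indicates selection for higher values of that covariate. Classes
#' absent from the map are omitted.
#'
#' @param landscape A [landscape()].
#' @param class_map A [quantile_class_map()].
#' @return Data frame with columns `class`, `covariate`, `mean`.
#' @export
class_covariate_means <- function(landscape, class_map) {
  if (!same_grid(landscape$grid, class_map$grid))
    stop("class map is not aligned with the landscape")
  cls <- class_map$classes
  present <- sort(unique(cls[!is.na(cls)]))
  rows <- list()
  for (cl in present) {
    in_cl <- !is.na(cls) & cls == cl
    for (nm in covariate_names()) {
      rows[[length(rows) + 1L]] <- data.frame(
        class = cl, covariate = nm,
        mean = mean(landscape$covariates[[nm]][in_cl]))
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Land-ownership use by class
#'
#' Within each quantile class, the proportion of simulated use falling on
#' each land-ownership category. By default proportions are step-weighted
#' (steps on that ownership / total steps in the class), reflecting use;
#' `weight = "area"` gives the cell-area-weighted variant. Classes with
#' zero weight are flagged (`NA` proportions).
#'
#' @param step_raster A [step_count_raster()].
#' @param class_map A [quantile_class_map()] on the same grid.
#' @param ownership Character matrix of ownership labels.
#' @param weight `"steps"` (default) or `"area"`.
#' @return Data frame with columns `class`, `ownership`, `proportion`,
#'   `total_weight`.
#' @export
ownership_by_class <- function(step_raster, class_map, ownership,
                               weight = c("steps", "area")) {
  weight <- match.arg(weight)
  grid <- class_map$grid
  if (!same_grid(step_raster$grid, grid)) stop("grid mismatch")
  check_layer_dim(ownership, grid, "ownership")
  cls <- class_map$classes
  w <- if (weight == "steps") step_raster$counts else (step_raster$counts >= 0) * 1
  cats <- sort(unique(ownership[!is.na(ownership)]))
  rows <- list()
  for (cl in sort(unique(cls[!is.na(cls)]))) {
    in_cl <- !is.na(cls) & cls == cl
    tot <- sum(w[in_cl])
    for (ow in cats) {
      ww <- sum(w[in_cl & !is.na(ownership) & ownership == ow])
      rows[[length(rows) + 1L]] <- data.frame(
        class = cl, ownership = ow,
        proportion = if (tot > 0) ww / tot else NA_real_,
        total_weight = tot)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
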