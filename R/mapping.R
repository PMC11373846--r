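#' Step-count raster
#'
#' Per-cell counts of accumulated step endpoints, tagged with the
#' scenario/sex/sequence-window they summarize.
#'
#' @param counts Non-negative integer matrix aligned to `grid`.
#' @param grid A [grid_spec()].
#' @param tags Named list, e.g. `list(scenario=, sex=, window=)`.
#' @return Object of class `step_count_raster`.
#' @export
step_count_raster <- function(counts, grid, tags = list()) {
  check_layer_dim(counts, grid, "counts")
  if (any(counts < 0)) stop("counts must be non-negative")
  structure(list(grid = grid, counts = counts, tags = tags),
            class = "step_count_raster")
}

#' @export
print.step_count_raster <- function(x, ...) {
  tg <- paste(names(x$tags), unlist(x$tags), sep = "=", collapse = ", ")
  cat(sprintf("<step_count_raster> %s: %d steps over %d occupied cells\n",
              tg, sum(x$counts), sum(x$counts > 0)))
  invisible(x)
}

#' Accumulate trajectory endpoints into a step-count raster
#'
#' Every step endpoint increments its containing cell (half-open cell
#' rule). The start location itself deposits no count. Endpoints outside
#' the grid violate the simulator contract and raise an error.
#'
#' @param trajectories A `trajectory` or list of them.
#' @param grid A [grid_spec()].
#' @param tags Tags stored on the result.
#' @param steps Optional integer vector of step indices to accumulate
#'   (default: all steps).
#' @return A [step_count_raster()].
#' @export
accumulate_steps <- function(trajectories, grid, tags = list(), steps = NULL) {
  if (inherits(trajectories, "trajectory")) trajectories <- list(trajectories)
  nr <- grid$nrows
  total <- matrix(0L, nr, grid$ncols)
  ncell <- nr * grid$ncols
  for (tr in trajectories) {
    x <- tr$x; y <- tr$y
    if (!is.null(steps)) { x <- x[steps]; y <- y[steps] }
    rc <- xy_to_rowcol(grid, x, y)
    if (anyNA(rc[, 1L])) stop("trajectory endpoint outside the grid")
    cell <- (rc[, 2L] - 1L) * nr + rc[, 1L]
    total <- total + tabulate(cell, nbins = ncell)
  }
  step_count_raster(total, grid, tags)
}

#' Equal-area quantile class map
#'
#' Bins cell values inside the study area into `n_classes` quantile
#' classes of relative predicted use: class 1 = lowest, class
#' `n_classes` = highest. Breaks are the 0.1, 0.2, ..., 0.9 quantiles
#' (linear interpolation) of the in-mask values, and a cell's class is
#' 1 plus the number of breaks strictly below its value (ties to the lower
#' class). With all-distinct values each class covers an equal share of
#' the study area (within one cell); heavily tied values (e.g. many zero
#' counts from short runs) collapse into the lower classes.
#'
#' @param x A [step_count_raster()] or a numeric matrix.
#' @param study_mask Logical layer of the study area.
#' @param n_classes Number of classes (default 10).
#' @return Object of class `class_map` with fields `grid`, `classes`
#'   (integer matrix, `NA` outside the mask), `breaks` (the
#'   `n_classes - 1` break values) and `n_classes`.
#' @export
quantile_class_map <- function(x, study_mask, n_classes = 10) {
  if (inherits(x, "step_count_raster")) {
    grid <- x$grid; vals <- x$counts
  } else if (is.matrix(x)) {
    if (is.null(attr(x, "grid_spec")))
      stop("matrix input needs a 'grid_spec' attribute or use a step_count_raster")
    grid <- attr(x, "grid_spec"); vals <- x
  } else stop("x must be a step_count_raster or a matrix with a grid_spec attribute")
  check_layer_dim(study_mask, grid, "study_mask")
  if (!any(study_mask)) stop("study mask is empty")
  v <- as.numeric(vals[study_mask])
  if (any(!is.finite(v))) stop("non-finite values inside the study mask")
  breaks <- quantile(v, probs = seq_len(n_classes - 1) / n_classes,
                     type = 7, names = FALSE)
  cl <- rep(1L, length(v))
  for (b in breaks) cl <- cl + (v > b)
  classes <- matrix(NA_integer_, grid$nrows, grid$ncols)
  classes[study_mask] <- cl
  structure(list(grid = grid, classes = classes, breaks = breaks,
                 n_classes = as.integer(n_classes)),
            class = "class_map")
}

#' @export
print.class_map <- function(x, ...) {
  tab <- tabulate(x$classes[!is.na(x$classes)], nbins = x$n_classes)
  cat(sprintf("<class_map> %d classes over %d cells; cells per class: %s\n",
              x$n_classes, sum(tab), paste(tab, collapse = " ")))
  invisible(x)
}

#' Sequence maps: class maps per consecutive step window
#'
#' Partitions each trajectory's step indices into `n_windows` consecutive
#' equal windows (e.g. steps 1-5,000, 5,001-10,000, ... for 20,000 steps
#' and 4 windows), accumulates each window separately, and bins each
#' within the study area. Sequence maps depict how predicted use shifts
#' from the soonest to the most future period.
#'
#' @param trajectories A `trajectory` or list of them (equal lengths).
#' @param grid A [grid_spec()].
#' @param study_mask Logical study-area layer.
#' @param n_windows Number of windows (default 4); trajectory length must
#'   be divisible by it.
#' @param n_classes Classes per map (default 10).
#' @return List of length `n_windows`; each element has `counts`
#'   (a [step_count_raster()]) and `classes` (a [quantile_class_map()]).
#' @export
sequence_class_maps <- function(trajectories, grid, study_mask,
                                n_windows = 4, n_classes = 10) {
  if (inherits(trajectories, "trajectory")) trajectories <- list(trajectories)
  n_steps <- length(trajectories[[1L]]$x)
  if (n_steps %% n_windows != 0)
    stop("trajectory length must be divisible by n_windows")
  win_len <- n_steps %/% n_windows
  lapply(seq_len(n_windows), function(w) {
    idx <- ((w - 1L) * win_len + 1L):(w * win_len)
    counts <- accumulate_steps(trajectories, grid,
                               tags = list(window = w), steps = idx)
    list(counts = counts,
         classes = quantile_class_map(counts, study_mask, n_classes))
  })
}

#' Combine step-count rasters and rebin
#'
#' Cell-wise sum of count rasters on a shared grid (e.g. across sexes, or
#' across the recolonization and reintroduction scenarios for the combined
#' prediction), followed by fresh quantile binning of the sum.
#'
#' @param rasters List of [step_count_raster()] on one grid.
#' @param study_mask Logical study-area layer; if `NULL`, only the summed
#'   raster is returned.
#' @param n_classes Classes for the rebinned map.
#' @param tags Tags for the combined raster.
#' @return List with `counts` and (when `study_mask` is given) `classes`.
#' @export
combine_step_rasters <- function(rasters, study_mask = NULL, n_classes = 10,
                                 tags = list(window = "combined")) {
  stopifnot(length(rasters) >= 1)
  grid <- rasters[[1L]]$grid
  for (r in rasters) {
    if (!inherits(r, "step_count_raster")) stop("inputs must be step_count_raster")
    if (!same_grid(r$grid, grid)) stop("grid mismatch among rasters")
  }
  total <- Reduce(`+`, lapply(rasters, function(r) r$counts))
  out <- list(counts = step_count_raster(total, grid, tags))
  if (!is.null(study_mask))
    out$classes <- quantile_class_map(out$counts, study_mask, n_classes)
  out
}
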