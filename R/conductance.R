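#' Linear predictor of the selection model over a landscape
#'
#' Computes the dot product of an individual's selection coefficients with
#' the covariate vector of every simulation-area cell. Cells outside the
#' simulation area are `NA`.
#'
#' @param landscape A [landscape()].
#' @param model A [bear_model()].
#' @return Numeric matrix aligned to `landscape$grid`.
#' @export
linear_predictor <- function(landscape, model) {
  stopifnot(inherits(landscape, "bear_landscape"), inherits(model, "bear_model"))
  grid <- landscape$grid
  sim <- landscape$masks$simulation_area
  lp <- matrix(0, grid$nrows, grid$ncols)
  for (nm in covariate_names()) {
    cov <- landscape$covariates[[nm]]
    check_layer_dim(cov, grid, nm)
    b <- model$beta[[nm]]
    if (b != 0) lp <- lp + b * cov
  }
  if (any(!is.finite(lp[sim])))
    stop("non-finite covariate values inside simulation_area")
  lp[!sim] <- NA_real_
  lp
}

#' Conductance surface from a linear predictor
#'
#' Exponentiates the selection score (`w = exp(x'beta)`), winsorizes the
#' extremes at the 0.025 and 0.975 quantiles of the in-area values, and
#' min-max rescales to \[0, 1\]. Winsorizing (clamping to the quantile
#' values) rather than dropping trimmed cells keeps a movement weight on
#' every cell. If the clamped surface is constant, every cell is set to 1
#' (uniform movement).
#'
#' The linear predictor is shifted by its in-area maximum before
#' exponentiation; the shift cancels in the normalization, so the result is
#' invariant to adding any constant to the predictor while avoiding
#' floating-point overflow.
#'
#' @param lin_pred Numeric matrix from [linear_predictor()]; `NA` marks
#'   cells outside the simulation area.
#' @param grid The shared [grid_spec()].
#' @param owner Individual id the surface belongs to.
#' @param trim Lower/upper quantile bounds for winsorization.
#' @return An object of class `conductance_surface` with fields `grid`,
#'   `values` (in \[0, 1\] inside the simulation area, `NA` outside) and
#'   `owner`.
#' @export
conductance_surface <- function(lin_pred, grid, owner = "",
                                trim = c(0.025, 0.975)) {
  stopifnot(inherits(grid, "grid_spec"))
  check_layer_dim(lin_pred, grid, "lin_pred")
  in_mask <- is.finite(lin_pred)
  if (!any(in_mask)) stop("no finite cells: empty simulation area")
  w <- exp(lin_pred - max(lin_pred[in_mask]))
  q <- quantile(w[in_mask], probs = trim, type = 7, names = FALSE)
  vals <- pmin(pmax(w, q[1L]), q[2L])
  rng <- q[2L] - q[1L]
  if (rng == 0) {
    vals[in_mask] <- 1
  } else {
    vals <- (vals - q[1L]) / rng
  }
  vals[!in_mask] <- NA_real_
  structure(list(grid = grid, values = vals, owner = owner),
            class = "conductance_surface")
}

#' @export
print.conductance_surface <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("<conductance_surface> owner '%s': %d cells, range [%.3g, %.3g]\n",
              x$owner, length(v), min(v), max(v)))
  invisible(x)
}

#' Surface value at planar points
#'
#' Cell lookup with the half-open cell convention of [grid_spec()].
#' Points outside the grid or on cells outside the simulation area return
#' `NA` (a value-level signal, not an error).
#'
#' @param surface A `conductance_surface` (or any object with `grid` and
#'   `values` fields).
#' @param x,y Planar coordinates (vectorized).
#' @return Numeric vector, `NA` where undefined.
#' @export
value_at <- function(surface, x, y) {
  layer_values_at(surface$values, surface$grid, x, y)
}
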