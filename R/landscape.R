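#' Names of the seven habitat covariates
#'
#' The covariate stack a landscape must carry, in canonical order:
#' NDVI (food-abundance index, unitless in \[0, 1\]), terrain ruggedness
#' (unitless, >= 0), distance to forest edge (m), density of forest edge
#' (per unit area), density of riparian areas (per unit area), density of
#' buildings (per unit area), and distance to secure habitat (m).
#'
#' @return Character vector of length 7.
#' @export
covariate_names <- function() {
  c("ndvi", "ruggedness", "dist_forest_edge", "dens_forest_edge",
    "dens_riparian", "dens_buildings", "dist_secure")
}

#' Assemble a raster landscape
#'
#' Bundles the seven covariate layers and categorical/boolean masks on one
#' shared grid and validates their alignment and value ranges. The
#' `simulation_area` mask delimits where movement is permitted (covariates
#' must be finite there); the `study_area` mask, a subset of it, delimits
#' where habitat-use maps are binned.
#'
#' @param grid A [grid_spec()].
#' @param covariates Named list of numeric matrices covering
#'   [covariate_names()]. Values are used on the scale supplied; selection
#'   coefficients are assumed to be on the same scale (no internal
#'   standardization).
#' @param masks Named list of layers aligned to `grid`. Required: logical
#'   `simulation_area` and `study_area`. Optional: logical `start_recol`
#'   (recolonization start buffer), `start_zone` (reintroduction release
#'   zone), `exclusion` (e.g. city boundaries, removed from start-node
#'   placement); character `region` (subregion labels, `NA` elsewhere) and
#'   `ownership` (land-ownership categories).
#' @return An object of class `bear_landscape`.
#' @export
landscape <- function(grid, covariates, masks) {
  stopifnot(inherits(grid, "grid_spec"))
  missing_cov <- setdiff(covariate_names(), names(covariates))
  if (length(missing_cov))
    stop("missing covariate layers: ", paste(missing_cov, collapse = ", "))
  covariates <- covariates[covariate_names()]
  for (nm in covariate_names())
    check_layer_dim(covariates[[nm]], grid, nm)
  if (!all(c("simulation_area", "study_area") %in% names(masks)))
    stop("masks must include 'simulation_area' and 'study_area'")
  for (nm in names(masks))
    check_layer_dim(masks[[nm]], grid, paste0("mask '", nm, "'"))
  sim <- masks$simulation_area
  stu <- masks$study_area
  if (!is.logical(sim) || !is.logical(stu))
    stop("simulation_area and study_area masks must be logical")
  if (!any(sim)) stop("simulation_area mask is empty")
  if (any(stu & !sim)) stop("study_area must be contained in simulation_area")
  for (nm in covariate_names()) {
    v <- covariates[[nm]][sim]
    if (any(!is.finite(v)))
      stop("non-finite values of '", nm, "' inside simulation_area")
  }
  ndvi <- covariates$ndvi[sim]
  if (any(ndvi < 0 | ndvi > 1)) stop("ndvi must lie in [0, 1]")
  for (nm in c("dist_forest_edge", "dens_forest_edge", "dens_riparian",
               "dens_buildings", "dist_secure")) {
    if (any(covariates[[nm]][sim] < 0))
      stop("'", nm, "' must be non-negative")
  }
  structure(list(grid = grid, covariates = covariates, masks = masks),
            class = "bear_landscape")
}

#' @export
print.bear_landscape <- function(x, ...) {
  g <- x$grid
  cat(sprintf("<bear_landscape> %d x %d cells (%g m); %d covariates, %d masks\n",
              g$nrows, g$ncols, g$cell_size,
              length(x$covariates), length(x$masks)))
  cat(sprintf("  simulation area: %d cells; study area: %d cells\n",
              sum(x$masks$simulation_area), sum(x$masks$study_area)))
  invisible(x)
}

#' Construct one individual's movement model
#'
#' An individual's fitted step-selection model: a selection coefficient for
#' each habitat covariate (terms dropped from that individual's final model
#' are exactly 0) plus its movement kernel, a gamma distribution of step
#' lengths (meters) and a von Mises distribution of turn angles (radians,
#' mean 0).
#'
#' @param id Individual label.
#' @param sex `"F"` or `"M"`.
#' @param beta Numeric selection coefficients of length 7; if named, they
#'   are matched to [covariate_names()], otherwise taken in that order.
#' @param gamma_shape,gamma_scale Gamma step-length parameters (both > 0;
#'   mean step length is `shape * scale` meters).
#' @param vm_kappa von Mises turn-angle concentration (>= 0; 0 gives
#'   uniform turning, large values near-straight movement).
#' @return An object of class `bear_model`.
#' @export
bear_model <- function(id, sex, beta, gamma_shape, gamma_scale, vm_kappa) {
  sex <- match.arg(sex, c("F", "M"))
  if (length(beta) != 7L) stop("beta must have length 7")
  if (!is.null(names(beta))) {
    if (!setequal(names(beta), covariate_names()))
      stop("named beta must use covariate_names()")
    beta <- beta[covariate_names()]
  } else {
    names(beta) <- covariate_names()
  }
  if (any(!is.finite(beta))) stop("beta must be finite")
  if (!is.finite(gamma_shape) || gamma_shape <= 0) stop("gamma_shape must be > 0")
  if (!is.finite(gamma_scale) || gamma_scale <= 0) stop("gamma_scale must be > 0")
  if (!is.finite(vm_kappa) || vm_kappa < 0) stop("vm_kappa must be >= 0")
  structure(list(id = as.character(id), sex = sex, beta = beta,
                 gamma_shape = gamma_shape, gamma_scale = gamma_scale,
                 vm_kappa = vm_kappa),
            class = "bear_model")
}

#' @export
print.bear_model <- function(x, ...) {
  cat(sprintf("<bear_model> %s (%s): mean step %.0f m, kappa %.2f, %d active terms\n",
              x$id, x$sex, x$gamma_shape * x$gamma_scale, x$vm_kappa,
              sum(x$beta != 0)))
  invisible(x)
}

#' Read individual movement models from CSV
#'
#' Expected columns: `id`, `sex`, `beta_ndvi`, `beta_ruggedness`,
#' `beta_dist_forest_edge`, `beta_dens_forest_edge`, `beta_dens_riparian`,
#' `beta_dens_buildings`, `beta_dist_secure`, `gamma_shape`, `gamma_scale`,
#' `vm_kappa`.
#'
#' @param path CSV file path.
#' @return List of [bear_model()] objects.
#' @export
read_bear_models <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  beta_cols <- paste0("beta_", covariate_names())
  need <- c("id", "sex", beta_cols, "gamma_shape", "gamma_scale", "vm_kappa")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("bear model CSV lacks columns: ", paste(miss, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i) {
    beta <- as.numeric(df[i, beta_cols])
    names(beta) <- covariate_names()
    bear_model(df$id[i], df$sex[i], beta,
               df$gamma_shape[i], df$gamma_scale[i], df$vm_kappa[i])
  })
}

#' Write individual movement models to CSV
#'
#' Inverse of [read_bear_models()].
#'
#' @param models List of [bear_model()] objects.
#' @param path Output CSV path.
#' @export
write_bear_models <- function(models, path) {
  rows <- lapply(models, function(m) {
    beta <- as.list(m$beta)
    names(beta) <- paste0("beta_", covariate_names())
    c(list(id = m$id, sex = m$sex), beta,
      list(gamma_shape = m$gamma_shape, gamma_scale = m$gamma_scale,
           vm_kappa = m$vm_kappa))
  })
  df <- do.call(rbind, lapply(rows, as.data.frame))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
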