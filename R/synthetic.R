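# Gaussian random field by separable kernel smoothing of white noise,
# standardized to zero mean / unit sd. Reflect padding at the edges keeps
# variance roughly constant near the boundary.
smooth_field <- function(nrows, ncols, sigma_cells) {
  z <- matrix(rnorm(nrows * ncols), nrows, ncols)
  if (sigma_cells > 0) {
    h <- min(ceiling(3 * sigma_cells), nrows - 1L, ncols - 1L)
    k <- dnorm(seq(-h, h), sd = sigma_cells)
    k <- k / sum(k)
    conv_cols <- function(m) {
      n <- nrow(m)
      pad <- rbind(m[h:1, , drop = FALSE], m, m[n:(n - h + 1), , drop = FALSE])
      out <- apply(pad, 2L, function(col) stats::filter(col, k, sides = 2))
      out[(h + 1L):(h + n), , drop = FALSE]
    }
    z <- conv_cols(z)
    z <- t(conv_cols(t(z)))
  }
  (z - mean(z)) / sd(z)
}

#' Specification of a synthetic landscape
#'
#' Geometry and statistical structure of a generated test landscape: a
#' rectangular study area inset inside a buffered simulation area, a
#' recovery-zone rectangle ("BE") split into North/Central/South
#' subregions, a northern start buffer for recolonization with a small
#' exclusion block (emulating city boundaries), three ownership
#' categories, and spatially autocorrelated covariate fields at 300-m
#' resolution.
#'
#' @param nrows,ncols Grid dimensions (default 200 x 200, i.e. 60 x 60 km
#'   at 300 m).
#' @param cell_size Cell size in meters (default 300).
#' @param autocorr_range Autocorrelation range of the covariate fields in
#'   meters (Gaussian smoothing scale; default 3000).
#' @param study_margin Cells between the simulation-area edge and the
#'   study area (>= 1, so the simulation area strictly contains the study
#'   area).
#' @param buffer_width Depth in cells of the northern recolonization
#'   start buffer.
#' @param seed Integer seed; generation is a pure function of spec + seed.
#' @return Object of class `synth_landscape_spec`.
#' @export
synth_landscape_spec <- function(nrows = 200, ncols = 200, cell_size = 300,
                                 autocorr_range = 3000, study_margin = 15,
                                 buffer_width = 10, seed = 1) {
  if (study_margin < 1) stop("study_margin must be >= 1")
  if (nrows <= 2 * study_margin || ncols <= 2 * study_margin)
    stop("grid too small for the requested study_margin")
  structure(list(nrows = as.integer(nrows), ncols = as.integer(ncols),
                 cell_size = cell_size, autocorr_range = autocorr_range,
                 study_margin = as.integer(study_margin),
                 buffer_width = as.integer(buffer_width),
                 seed = as.integer(seed)),
            class = "synth_landscape_spec")
}

#' Generate a synthetic landscape
#'
#' Each covariate is a seeded Gaussian random field (white noise smoothed
#' to the requested autocorrelation range) transformed to its target
#' range: NDVI through a logistic squash into (0, 1), ruggedness through
#' an exponential (right-skewed, >= 0), distances and densities through
#' exponential quantile transforms (>= 0). Masks follow the geometry in
#' [synth_landscape_spec()]. Deterministic for a fixed spec and seed.
#'
#' @param spec A [synth_landscape_spec()].
#' @return A [landscape()] whose masks include `start_recol`,
#'   `start_zone`, `exclusion`, `region` and `ownership`.
#' @export
synth_landscape <- function(spec) {
  stopifnot(inherits(spec, "synth_landscape_spec"))
  set.seed(spec$seed)
  nr <- spec$nrows; nc <- spec$ncols
  sig <- spec$autocorr_range / spec$cell_size
  g <- grid_spec(nr, nc, spec$cell_size)

  fld <- function() smooth_field(nr, nc, sig)
  covs <- list(
    ndvi             = plogis(1.2 * fld()),
    ruggedness       = exp(0.6 * fld()),
    dist_forest_edge = qexp(pnorm(fld()), rate = 1 / 400),
    dens_forest_edge = qexp(pnorm(fld()), rate = 1 / 1.5),
    dens_riparian    = qexp(pnorm(fld()), rate = 1 / 0.8),
    dens_buildings   = qexp(pnorm(fld()), rate = 1 / 0.3),
    dist_secure      = qexp(pnorm(fld()), rate = 1 / 800)
  )

  row_i <- matrix(seq_len(nr), nr, nc)
  col_i <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  sim <- matrix(TRUE, nr, nc)
  m <- spec$study_margin
  study <- row_i > m & row_i <= nr - m & col_i > m & col_i <= nc - m

  # recovery zone: central block of the study area, split into thirds
  rz_r <- range(which(apply(study, 1L, any)))
  rz_c <- range(which(apply(study, 2L, any)))
  be_r0 <- rz_r[1L] + floor(0.15 * diff(rz_r))
  be_r1 <- rz_r[2L] - floor(0.15 * diff(rz_r))
  be_c0 <- rz_c[1L] + floor(0.2 * diff(rz_c))
  be_c1 <- rz_c[2L] - floor(0.2 * diff(rz_c))
  be <- study & row_i >= be_r0 & row_i <= be_r1 & col_i >= be_c0 & col_i <= be_c1
  third <- (be_r1 - be_r0 + 1L) / 3
  region <- matrix("other", nr, nc)
  region[be & row_i <  be_r0 + third] <- "BE_South"
  region[be & row_i >= be_r0 + third & row_i < be_r0 + 2 * third] <- "BE_Central"
  region[be & row_i >= be_r0 + 2 * third] <- "BE_North"

  # northern edge band of the simulation area; exclusion block inside it
  start_recol <- row_i > nr - spec$buffer_width
  excl <- start_recol & col_i > round(0.45 * nc) & col_i <= round(0.55 * nc)

  own_f <- fld()
  qo <- quantile(own_f, c(1 / 3, 2 / 3), names = FALSE)
  ownership <- matrix("public", nr, nc)
  ownership[own_f > qo[1L] & own_f <= qo[2L]] <- "private"
  ownership[own_f > qo[2L]] <- "tribal"

  masks <- list(simulation_area = sim, study_area = study,
                start_recol = start_recol, start_zone = be,
                exclusion = excl, region = region, ownership = ownership)
  for (nm in c("start_recol", "start_zone", "exclusion"))
    if (!any(masks[[nm]])) stop("mask '", nm, "' is empty for this geometry")
  landscape(g, covs, masks)
}

#' Specification of a synthetic individual population
#'
#' Defaults emulate the study population this package is patterned on:
#' 46 female and 19 male individual models with between-individual
#' variation in selection coefficients, a chance for any term to be
#' dropped (exactly zero, emulating per-individual model selection), and
#' sex-specific movement-kernel parameter ranges for 3-hour relocation
#' steps.
#'
#' @param n_females,n_males Number of individual models per sex.
#' @param beta_mean Named mean coefficient per covariate (covariate
#'   scale). Default signs follow the selection directions the simulation
#'   study reports: positive for NDVI, forest-edge density and riparian
#'   density; negative for ruggedness, building density and the two
#'   distances.
#' @param beta_sd Between-individual standard deviations (default 30% of
#'   `|beta_mean|`).
#' @param zero_prob Probability that a term is zeroed for an individual.
#' @param step_mean_range List with `F` and `M` ranges (m) of the mean
#'   step length; means are drawn uniformly within.
#' @param gamma_shape_range,kappa_range Uniform ranges for the gamma
#'   shape and von Mises concentration.
#' @param seed Integer seed.
#' @return Object of class `synth_population_spec`.
#' @export
synth_population_spec <- function(n_females = 46, n_males = 19,
                                  beta_mean = c(ndvi = 1.0, ruggedness = -0.4,
                                                dist_forest_edge = -8e-4,
                                                dens_forest_edge = 0.25,
                                                dens_riparian = 0.4,
                                                dens_buildings = -1.2,
                                                dist_secure = -6e-4),
                                  beta_sd = NULL, zero_prob = 0.2,
                                  step_mean_range = list(F = c(500, 1500),
                                                         M = c(800, 2000)),
                                  gamma_shape_range = c(0.8, 2),
                                  kappa_range = c(0.2, 1),
                                  seed = 1) {
  if (n_females < 0 || n_males < 0 || n_females + n_males < 1)
    stop("need at least one individual")
  beta_mean <- beta_mean[covariate_names()]
  if (anyNA(beta_mean)) stop("beta_mean must name all covariates")
  if (is.null(beta_sd)) beta_sd <- 0.3 * abs(beta_mean)
  beta_sd <- rep_len(beta_sd, 7L)
  if (any(beta_sd < 0)) stop("beta_sd must be >= 0")
  if (zero_prob < 0 || zero_prob > 1) stop("zero_prob must lie in [0, 1]")
  for (rg in c(step_mean_range, list(gamma_shape_range, kappa_range)))
    if (length(rg) != 2L || rg[1L] > rg[2L] || rg[1L] < 0)
      stop("parameter ranges must be non-negative and increasing")
  structure(list(n_females = as.integer(n_females),
                 n_males = as.integer(n_males),
                 beta_mean = beta_mean, beta_sd = setNames(beta_sd, covariate_names()),
                 zero_prob = zero_prob, step_mean_range = step_mean_range,
                 gamma_shape_range = gamma_shape_range,
                 kappa_range = kappa_range, seed = as.integer(seed)),
            class = "synth_population_spec")
}

#' Generate a synthetic population of individual models
#'
#' Per individual: coefficients drawn Normal(mean, sd) per covariate with
#' independent zeroing at `zero_prob`; a mean step length drawn uniformly
#' in the sex's range, a gamma shape drawn uniformly (scale = mean /
#' shape), and a von Mises concentration drawn uniformly. Deterministic
#' for a fixed spec and seed.
#'
#' @param spec A [synth_population_spec()].
#' @return List of [bear_model()] objects (females first).
#' @export
synth_bear_models <- function(spec) {
  stopifnot(inherits(spec, "synth_population_spec"))
  set.seed(spec$seed)
  make_one <- function(id, sex) {
    beta <- rnorm(7L, spec$beta_mean, spec$beta_sd)
    beta[runif(7L) < spec$zero_prob] <- 0
    names(beta) <- covariate_names()
    mean_step <- runif(1L, spec$step_mean_range[[sex]][1L],
                       spec$step_mean_range[[sex]][2L])
    shape <- runif(1L, spec$gamma_shape_range[1L], spec$gamma_shape_range[2L])
    kappa <- runif(1L, spec$kappa_range[1L], spec$kappa_range[2L])
    bear_model(id, sex, beta, gamma_shape = shape,
               gamma_scale = mean_step / shape, vm_kappa = kappa)
  }
  c(
    lapply(seq_len(spec$n_females),
           function(i) make_one(sprintf("F%02d", i), "F")),
    lapply(seq_len(spec$n_males),
           function(i) make_one(sprintf("M%02d", i), "M"))
  )
}

#' Synthetic prior-connectivity class map
#'
#' Bins a smoothed random field over the simulation area into quantile
#' classes — a synthetic stand-in for the prior connectivity classes used
#' to filter recolonization start nodes (labelled synthetic: it carries
#' no real geography).
#'
#' @param landscape A [landscape()].
#' @param autocorr_range Smoothing range in meters (default 6000).
#' @param n_classes Number of classes (default 10).
#' @param seed Integer seed.
#' @return A [quantile_class_map()] over the simulation area.
#' @export
synth_prior_class_map <- function(landscape, autocorr_range = 6000,
                                  n_classes = 10, seed = 1) {
  set.seed(seed)
  g <- landscape$grid
  f <- smooth_field(g$nrows, g$ncols, autocorr_range / g$cell_size)
  attr(f, "grid_spec") <- g
  quantile_class_map(f, landscape$masks$simulation_area, n_classes)
}

#' Synthetic validation points with class preference
#'
#' Samples study-area cells with probability proportional to
#' `class^gamma` and places one point uniformly within each chosen cell.
#' `gamma = 0` gives spatially uniform points; larger exponents emulate
#' locations concentrated in high-use habitat (as real animal locations
#' would be if the map is predictive).
#'
#' @param class_map A [quantile_class_map()].
#' @param n Number of points (>= 1).
#' @param gamma Preference exponent (>= 0).
#' @param seed Optional integer seed.
#' @return Data frame with columns `x`, `y`, `class`.
#' @export
synth_validation_points <- function(class_map, n, gamma = 1, seed = NULL) {
  if (n < 1) stop("n must be >= 1")
  if (gamma < 0) stop("gamma must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  g <- class_map$grid
  cells <- which(!is.na(class_map$classes))
  if (!length(cells)) stop("empty class map")
  cls <- as.numeric(class_map$classes[cells])
  pick <- cells[sample.int(length(cells), n, replace = TRUE,
                           prob = cls^gamma)]
  ctr <- cell_centers(g, pick)
  data.frame(x = ctr[, 1L] + runif(n, -0.5, 0.5) * g$cell_size,
             y = ctr[, 2L] + runif(n, -0.5, 0.5) * g$cell_size,
             class = class_map$classes[pick])
}
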