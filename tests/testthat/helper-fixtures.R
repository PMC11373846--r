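# Small in-code fixtures and independent oracles shared across tests.

# Landscape with constant covariate layers (overridable per layer, scalars
# or full matrices), full simulation area, study area defaulting to it.
const_landscape <- function(nrows = 10, ncols = 10, cell_size = 100,
                            values = list(), sim = NULL, study = NULL) {
  g <- grid_spec(nrows, ncols, cell_size)
  base <- list(ndvi = 0.5, ruggedness = 1, dist_forest_edge = 100,
               dens_forest_edge = 1, dens_riparian = 1, dens_buildings = 0.1,
               dist_secure = 200)
  base[names(values)] <- values
  covs <- lapply(base, function(v) if (is.matrix(v)) v else matrix(v, nrows, ncols))
  if (is.null(sim)) sim <- matrix(TRUE, nrows, ncols)
  if (is.null(study)) study <- sim
  landscape(g, covs, masks = list(simulation_area = sim, study_area = study))
}

# Landscape with random (iid) covariate layers, for dot-product oracles.
random_landscape <- function(nrows = 5, ncols = 5, cell_size = 100) {
  g <- grid_spec(nrows, ncols, cell_size)
  rmat <- function(gen) matrix(gen(nrows * ncols), nrows, ncols)
  covs <- list(ndvi = rmat(runif),
               ruggedness = rmat(function(n) rexp(n)),
               dist_forest_edge = rmat(function(n) rexp(n, 1 / 300)),
               dens_forest_edge = rmat(function(n) rexp(n)),
               dens_riparian = rmat(function(n) rexp(n)),
               dens_buildings = rmat(function(n) rexp(n, 4)),
               dist_secure = rmat(function(n) rexp(n, 1 / 500)))
  m <- matrix(TRUE, nrows, ncols)
  landscape(g, covs, masks = list(simulation_area = m, study_area = m))
}

random_bear <- function(id = "B1", sex = "F") {
  bear_model(id, sex, beta = rnorm(7, 0, 0.5),
             gamma_shape = runif(1, 0.8, 2), gamma_scale = runif(1, 200, 800),
             vm_kappa = runif(1, 0.2, 1))
}

# All-1 conductance surface (constant predictor degenerates to uniform).
uniform_surface <- function(nrows, ncols, cell_size = 300) {
  g <- grid_spec(nrows, ncols, cell_size)
  conductance_surface(matrix(0, nrows, ncols), g, owner = "unif")
}

# 10-class map with exactly equal class areas (all-distinct cell values).
balanced_class_map <- function(nrows = 50, ncols = 20, cell_size = 100) {
  g <- grid_spec(nrows, ncols, cell_size)
  vals <- matrix(seq_len(nrows * ncols), nrows, ncols)
  attr(vals, "grid_spec") <- g
  quantile_class_map(vals, matrix(TRUE, nrows, ncols))
}

# Independent oracle: Spearman as Pearson on average ranks.
oracle_spearman <- function(xs, ys) {
  rx <- rank(xs); ry <- rank(ys)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Independent oracle: Moran's I with rook (4-neighbour) weights.
oracle_morans_i <- function(m) {
  z <- m - mean(m)
  num <- sum(z[-nrow(m), ] * z[-1, ]) + sum(z[, -ncol(m)] * z[, -1])
  n_pairs <- (nrow(m) - 1) * ncol(m) + nrow(m) * (ncol(m) - 1)
  length(m) * num / (n_pairs * sum(z^2))
}
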