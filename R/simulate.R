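#' Configuration of a simulation scenario
#'
#' Defaults follow the study design this package implements: 11 candidate
#' steps per move, 20,000 steps per iteration, 100 iterations per female
#' model and 242 per male model (approximately equal per-sex totals when
#' the population holds 46 females and 19 males), and 4 sequence windows.
#'
#' @param scenario `"recolonization"` (start nodes filtered by a prior
#'   connectivity class map) or `"reintroduction"` (random starts inside a
#'   release zone).
#' @param n_candidates Candidate steps evaluated per move.
#' @param n_steps Steps per iteration; must be divisible by `n_windows`.
#' @param iterations_per_female,iterations_per_male Iterations run per
#'   individual model of each sex.
#' @param base_seed Integer seed; every iteration's RNG stream is derived
#'   deterministically from `(base_seed, bear id, iteration index)`, so
#'   results are independent of execution order.
#' @param boundary_retry_limit How many times a full candidate set is
#'   redrawn when no candidate lands on the mapped surface before the
#'   animal stalls in place for that step.
#' @param n_windows Number of consecutive equal sequence windows.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(scenario = c("recolonization", "reintroduction"),
                            n_candidates = 11, n_steps = 20000,
                            iterations_per_female = 100,
                            iterations_per_male = 242,
                            base_seed = 1, boundary_retry_limit = 100,
                            n_windows = 4) {
  scenario <- match.arg(scenario)
  counts <- c(n_candidates = n_candidates, n_steps = n_steps,
              iterations_per_female = iterations_per_female,
              iterations_per_male = iterations_per_male,
              boundary_retry_limit = boundary_retry_limit,
              n_windows = n_windows)
  if (any(counts < 1) || any(counts != floor(counts)))
    stop("all counts must be integers >= 1")
  if (n_steps %% n_windows != 0)
    stop("n_steps must be divisible by n_windows")
  structure(list(scenario = scenario,
                 n_candidates = as.integer(n_candidates),
                 n_steps = as.integer(n_steps),
                 iterations_per_female = as.integer(iterations_per_female),
                 iterations_per_male = as.integer(iterations_per_male),
                 base_seed = as.integer(base_seed),
                 boundary_retry_limit = as.integer(boundary_retry_limit),
                 n_windows = as.integer(n_windows)),
            class = "scenario_config")
}

#' Iteration bookkeeping for a planned run
#'
#' Tallies how many iterations a configuration implies per sex without
#' executing any movement.
#'
#' @param config A [scenario_config()].
#' @param models List of [bear_model()] objects.
#' @return Data frame with columns `sex`, `n_models`,
#'   `iterations_per_model`, `total_iterations`.
#' @export
plan_iterations <- function(config, models) {
  if (!length(models)) stop("no models supplied")
  sexes <- vapply(models, function(m) m$sex, character(1))
  per <- c(F = config$iterations_per_female, M = config$iterations_per_male)
  n_models <- c(F = sum(sexes == "F"), M = sum(sexes == "M"))
  data.frame(sex = c("F", "M"),
             n_models = as.integer(n_models),
             iterations_per_model = as.integer(per),
             total_iterations = as.integer(n_models * per),
             row.names = NULL)
}

# Deterministic per-iteration seed from (base_seed, bear id, iteration).
# Exact in double arithmetic (intermediates < 2^53); result < 2^31.
derive_seed <- function(base_seed, bear_id, iteration) {
  p <- 2147480009  # prime below 2^31
  h <- 0
  for (ch in utf8ToInt(as.character(bear_id))) h <- (h * 131 + ch) %% p
  as.integer((h * 31 + iteration * 2654435 + base_seed * 97) %% p)
}

#' Sample start nodes for the recolonization scenario
#'
#' Places uniform random points inside the start buffer (minus any
#' exclusion mask, e.g. city boundaries), thins them to a minimum pairwise
#' distance by rejection in insertion order, and retains points whose cell
#' falls in the top prior-connectivity classes.
#'
#' @param prior_class_map A [quantile_class_map()] of prior predicted use
#'   (stand-in for an earlier connectivity analysis), per sex.
#' @param start_buffer_mask Logical layer of the start buffer.
#' @param exclusion_mask Optional logical layer removed from placement.
#' @param n_random Points to place before thinning-based acceptance
#'   (default 25,000).
#' @param min_dist Minimum pairwise distance in meters (default 10).
#' @param min_class Lowest retained prior class; defaults to the top 3
#'   classes of the map (classes 8-10 on a 10-class map).
#' @param max_attempts Total candidate draws allowed before giving up.
#' @param sex Label attached to the returned set.
#' @return A `start_nodes` data frame with columns `x`, `y`.
#' @export
sample_recolonization_start_nodes <- function(prior_class_map,
                                              start_buffer_mask,
                                              exclusion_mask = NULL,
                                              n_random = 25000,
                                              min_dist = 10,
                                              min_class = NULL,
                                              max_attempts = 50 * n_random,
                                              sex = "both") {
  grid <- prior_class_map$grid
  check_layer_dim(start_buffer_mask, grid, "start_buffer_mask")
  elig <- start_buffer_mask
  if (!is.null(exclusion_mask)) {
    check_layer_dim(exclusion_mask, grid, "exclusion_mask")
    elig <- elig & !exclusion_mask
  }
  cells <- which(elig)
  if (!length(cells)) stop("no eligible area for start-node placement")
  if (is.null(min_class)) min_class <- prior_class_map$n_classes - 2L

  cs <- grid$cell_size
  xs <- numeric(n_random); ys <- numeric(n_random)
  bins <- new.env(hash = TRUE, parent = emptyenv())
  accepted <- 0L
  attempts <- 0L
  batch <- max(1024L, as.integer(n_random / 4L))
  while (accepted < n_random && attempts < max_attempts) {
    m <- min(batch, as.integer(max_attempts - attempts))
    attempts <- attempts + m
    idx <- cells[sample.int(length(cells), m, replace = TRUE)]
    ctr <- cell_centers(grid, idx)
    px <- ctr[, 1L] + runif(m, -0.5, 0.5) * cs
    py <- ctr[, 2L] + runif(m, -0.5, 0.5) * cs
    for (i in seq_len(m)) {
      bx <- floor(px[i] / min_dist); by <- floor(py[i] / min_dist)
      clash <- FALSE
      for (dx in -1:1) {
        for (dy in -1:1) {
          key <- paste0(bx + dx, ",", by + dy)
          pts <- bins[[key]]
          if (!is.null(pts) &&
              any((pts[, 1L] - px[i])^2 + (pts[, 2L] - py[i])^2 < min_dist^2)) {
            clash <- TRUE
            break
          }
        }
        if (clash) break
      }
      if (!clash) {
        accepted <- accepted + 1L
        xs[accepted] <- px[i]; ys[accepted] <- py[i]
        key <- paste0(bx, ",", by)
        bins[[key]] <- rbind(bins[[key]], c(px[i], py[i]))
        if (accepted == n_random) break
      }
    }
  }
  if (accepted < n_random)
    stop(sprintf("placed only %d of %d points at min_dist %g m",
                 accepted, n_random, min_dist))
  xs <- xs[seq_len(accepted)]; ys <- ys[seq_len(accepted)]
  cls <- layer_values_at(prior_class_map$classes, grid, xs, ys)
  keep <- !is.na(cls) & cls >= min_class
  structure(data.frame(x = xs[keep], y = ys[keep]),
            class = c("start_nodes", "data.frame"),
            scenario = "recolonization", sex = sex)
}

#' Draw one start location
#'
#' Recolonization draws uniformly among precomputed start nodes;
#' reintroduction draws a uniform random point within a release-zone mask.
#'
#' @param nodes_or_zone A `start_nodes` data frame, or a logical mask
#'   matrix (then `grid` is required).
#' @param grid [grid_spec()] of the mask, when a mask is given.
#' @return Numeric `c(x, y)`.
#' @export
draw_start <- function(nodes_or_zone, grid = NULL) {
  if (is.data.frame(nodes_or_zone)) {
    if (!nrow(nodes_or_zone)) stop("empty start-node set")
    i <- sample.int(nrow(nodes_or_zone), 1L)
    return(c(x = nodes_or_zone$x[i], y = nodes_or_zone$y[i]))
  }
  if (is.matrix(nodes_or_zone) && is.logical(nodes_or_zone)) {
    stopifnot(inherits(grid, "grid_spec"))
    cells <- which(nodes_or_zone)
    if (!length(cells)) stop("empty start-zone mask")
    cell <- cells[sample.int(length(cells), 1L)]
    ctr <- unname(cell_centers(grid, cell))
    return(c(x = ctr[1L, 1L] + runif(1, -0.5, 0.5) * grid$cell_size,
             y = ctr[1L, 2L] + runif(1, -0.5, 0.5) * grid$cell_size))
  }
  stop("nodes_or_zone must be a start_nodes data frame or a logical mask")
}

#' Propose candidate steps from the movement kernel
#'
#' Draws `k` candidate steps: lengths from the individual's gamma
#' distribution, turn angles from its von Mises distribution centered on
#' 0. Candidate bearings are the current bearing plus the turn, modulo
#' 2*pi.
#'
#' @param x,y Current location.
#' @param bearing Current heading in radians.
#' @param model A [bear_model()].
#' @param k Number of candidates (default 11).
#' @return Data frame with columns `x`, `y`, `bearing` (one row per
#'   candidate).
#' @export
propose_steps <- function(x, y, bearing, model, k = 11) {
  stopifnot(inherits(model, "bear_model"), k >= 1)
  len <- rgamma(k, shape = model$gamma_shape, scale = model$gamma_scale)
  trn <- rvonmises(k, model$vm_kappa)
  brg <- (bearing + trn) %% (2 * pi)
  data.frame(x = x + len * cos(brg), y = y + len * sin(brg), bearing = brg)
}

#' Choose among candidate steps by conductance weight
#'
#' Each candidate's weight is the conductance value at its endpoint;
#' endpoints off the grid or outside the simulation area weigh 0. The
#' chosen index is sampled with probability weight / sum(weights). When
#' every weight is 0 the index is `NA` — a "no valid step" signal the
#' caller handles (see [simulate_iteration()]).
#'
#' @param candidates Data frame from [propose_steps()].
#' @param surface A [conductance_surface()].
#' @return List with `index`, `x`, `y`, `bearing` (all `NA` on the
#'   zero-weight signal) and the `weights` used.
#' @export
select_step <- function(candidates, surface) {
  w <- value_at(surface, candidates$x, candidates$y)
  w[is.na(w)] <- 0
  tot <- sum(w)
  if (tot == 0)
    return(list(index = NA_integer_, x = NA_real_, y = NA_real_,
                bearing = NA_real_, weights = w))
  i <- sample.int(length(w), 1L, prob = w)
  list(index = i, x = candidates$x[i], y = candidates$y[i],
       bearing = candidates$bearing[i], weights = w)
}

#' Simulate one movement iteration
#'
#' A correlated random walk filtered through the individual's conductance
#' surface: from the current location and heading, `n_candidates` steps
#' are proposed, one is chosen with probability proportional to the
#' conductance at its endpoint, and the animal moves there. If no
#' candidate has positive weight the candidate set is redrawn up to
#' `boundary_retry_limit` times; if still none, the animal stalls — the
#' current location is recorded again as this step's endpoint. The initial
#' heading is uniform on `[0, 2*pi)`.
#'
#' @param start `c(x, y)` inside the simulation area.
#' @param model A [bear_model()].
#' @param surface The individual's [conductance_surface()].
#' @param config A [scenario_config()].
#' @param iteration Iteration index stored on the result.
#' @return An object of class `trajectory`: fields `bear_id`, `iteration`,
#'   `start`, `x`, `y`, `bearing` (length `n_steps`) and `stalled_steps`.
#' @export
simulate_iteration <- function(start, model, surface, config, iteration = NA_integer_) {
  g <- surface$grid
  vals <- surface$values
  if (is.na(layer_values_at(vals, g, start[1L], start[2L])))
    stop("start location outside the simulation area")
  n <- config$n_steps
  k <- config$n_candidates
  retry_max <- config$boundary_retry_limit
  shape <- model$gamma_shape; scl <- model$gamma_scale; kap <- model$vm_kappa
  ox <- g$origin_x; oy <- g$origin_y; cs <- g$cell_size
  nr <- g$nrows; nc <- g$ncols
  xs <- numeric(n); ys <- numeric(n); brgs <- numeric(n)
  cx <- start[[1L]]; cy <- start[[2L]]
  cb <- runif(1, 0, 2 * pi)
  stalled <- 0L
  # Kernel draws are independent of position, so one buffer of proposals
  # serves the whole iteration; retries past the buffer draw fresh sets.
  buf_len <- rgamma(n * k, shape = shape, scale = scl)
  buf_trn <- rvonmises(n * k, kap)
  for (s in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(retry_max)) {
      if (try == 1L) {
        j <- ((s - 1L) * k + 1L):(s * k)
        len <- buf_len[j]
        trn <- buf_trn[j]
      } else {
        len <- rgamma(k, shape = shape, scale = scl)
        trn <- rvonmises(k, kap)
      }
      nb <- (cb + trn) %% (2 * pi)
      nx <- cx + len * cos(nb)
      ny <- cy + len * sin(nb)
      col <- floor((nx - ox) / cs) + 1
      row <- floor((ny - oy) / cs) + 1
      ok <- col >= 1 & col <= nc & row >= 1 & row <= nr
      w <- numeric(k)
      if (any(ok)) {
        vv <- vals[cbind(row[ok], col[ok])]
        vv[is.na(vv)] <- 0
        w[ok] <- vv
      }
      cw <- cumsum(w)
      tot <- cw[k]
      if (tot > 0) {
        i <- sum(runif(1) * tot > cw) + 1L
        cx <- nx[i]; cy <- ny[i]; cb <- nb[i]
        placed <- TRUE
        break
      }
    }
    if (!placed) stalled <- stalled + 1L
    xs[s] <- cx; ys[s] <- cy; brgs[s] <- cb
  }
  structure(list(bear_id = model$id, iteration = iteration,
                 start = c(x = start[[1L]], y = start[[2L]]),
                 x = xs, y = ys, bearing = brgs, stalled_steps = stalled),
            class = "trajectory")
}

#' Run a full simulation scenario
#'
#' For each individual model the conductance surface is computed once;
#' iterations (100 per female, 242 per male by default) each run
#' [simulate_iteration()] under an RNG stream derived from
#' `(base_seed, bear id, iteration)`, and step endpoints are accumulated
#' into per-sex, per-sequence-window count rasters. Results are therefore
#' bit-reproducible and independent of execution order.
#'
#' @param config A [scenario_config()].
#' @param models List of [bear_model()] objects.
#' @param landscape A [landscape()].
#' @param start_nodes For the recolonization scenario: a `start_nodes`
#'   data frame, or a list with elements `F` and `M` for sex-specific
#'   node sets.
#' @param start_zone For the reintroduction scenario: logical release-zone
#'   mask (defaults to `landscape$masks$start_zone`).
#' @param verbose Print per-bear progress.
#' @return An object of class `scenario_result`: `per_sex[[sex]]$windows`
#'   (list of [step_count_raster()] per sequence window),
#'   `per_sex[[sex]]$total`, plus `plan` (from [plan_iterations()]) and
#'   `stalled_steps` per bear.
#' @export
run_scenario <- function(config, models, landscape,
                         start_nodes = NULL, start_zone = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(config, "scenario_config"),
            inherits(landscape, "bear_landscape"))
  if (!length(models)) stop("no models supplied")
  grid <- landscape$grid
  nr <- grid$nrows; nc <- grid$ncols
  ncell <- nr * nc
  nwin <- config$n_windows
  win_len <- config$n_steps %/% nwin
  sexes_present <- unique(vapply(models, function(m) m$sex, character(1)))

  if (config$scenario == "recolonization") {
    if (is.null(start_nodes)) stop("recolonization scenario needs start_nodes")
    get_start_input <- function(sex) {
      if (is.data.frame(start_nodes)) start_nodes
      else if (!is.null(start_nodes[[sex]])) start_nodes[[sex]]
      else stop("no start nodes for sex ", sex)
    }
  } else {
    if (is.null(start_zone)) start_zone <- landscape$masks$start_zone
    if (is.null(start_zone)) stop("reintroduction scenario needs a start_zone mask")
    check_layer_dim(start_zone, grid, "start_zone")
    get_start_input <- function(sex) start_zone
  }

  counts <- list()
  for (sx in sexes_present)
    counts[[sx]] <- lapply(seq_len(nwin), function(w) matrix(0L, nr, nc))
  stalled <- setNames(integer(length(models)),
                      vapply(models, function(m) m$id, character(1)))

  for (m_i in seq_along(models)) {
    model <- models[[m_i]]
    lp <- linear_predictor(landscape, model)
    surf <- conductance_surface(lp, grid, owner = model$id)
    n_iter <- if (model$sex == "F") config$iterations_per_female
              else config$iterations_per_male
    start_input <- get_start_input(model$sex)
    for (it in seq_len(n_iter)) {
      set.seed(derive_seed(config$base_seed, model$id, it))
      start <- if (is.data.frame(start_input)) draw_start(start_input)
               else draw_start(start_input, grid)
      traj <- simulate_iteration(start, model, surf, config, iteration = it)
      stalled[model$id] <- stalled[model$id] + traj$stalled_steps
      cell <- (floor((traj$x - grid$origin_x) / grid$cell_size)) * nr +
        floor((traj$y - grid$origin_y) / grid$cell_size) + 1
      for (w in seq_len(nwin)) {
        seg <- cell[((w - 1L) * win_len + 1L):(w * win_len)]
        counts[[model$sex]][[w]] <- counts[[model$sex]][[w]] +
          tabulate(seg, nbins = ncell)
      }
    }
    if (verbose)
      message(sprintf("bear %s (%s): %d iterations, %d stalled steps",
                      model$id, model$sex, n_iter, stalled[model$id]))
  }

  per_sex <- lapply(setNames(nm = sexes_present), function(sx) {
    wins <- lapply(seq_len(nwin), function(w) {
      step_count_raster(counts[[sx]][[w]], grid,
                        tags = list(scenario = config$scenario, sex = sx,
                                    window = w))
    })
    total <- step_count_raster(Reduce(`+`, counts[[sx]]), grid,
                               tags = list(scenario = config$scenario,
                                           sex = sx, window = "total"))
    list(windows = wins, total = total)
  })
  structure(list(scenario = config$scenario, config = config,
                 per_sex = per_sex,
                 plan = plan_iterations(config, models),
                 stalled_steps = stalled),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> %s: sexes %s, %d windows\n", x$scenario,
              paste(names(x$per_sex), collapse = "/"),
              x$config$n_windows))
  print(x$plan)
  invisible(x)
}
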