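# Reynolds flocking simulator on a toroidal 2-D arena.  Each boid carries a
# position and a heading angle; three steering rules (aggregation towards
# the flock centre, avoidance of the closest neighbour, alignment with
# neighbour headings) are weighted by scalar parameters a1, a2, a3.  The
# centre of mass of the flock is the candidate emergent feature, analysed
# through the Gaussian-estimator path of the criteria.

#' Flocking model parameters
#'
#' @param n_boids number of boids (>= 2; default 10).
#' @param a1 aggregation weight (fly towards the flock centre).
#' @param a2 avoidance weight (fly away from the closest neighbour).
#' @param a3 alignment weight (match neighbour headings).
#' @param speed distance travelled per time step (arena units).
#' @param timestep integration step (time units).
#' @param radius neighbourhood radius for alignment (default arena / 5).
#' @param arena side length of the square toroidal arena.
#' @param noise_sd standard deviation of the per-step heading noise
#'   (radians).
#' @return a `boids_params` list.
#' @export
boids_params <- function(n_boids = 10, a1 = 0.3, a2 = 1, a3 = 0.5,
                         speed = 0.1, timestep = 1, radius = NULL,
                         arena = 10, noise_sd = 0.2) {
  if (n_boids < 2) stop("`n_boids` must be >= 2")
  if (speed <= 0 || timestep <= 0 || arena <= 0)
    stop("speed, timestep and arena must be positive")
  if (is.null(radius)) radius <- arena / 5
  if (radius <= 0) stop("radius must be positive")
  if (a1 < 0 || a2 < 0 || a3 < 0) stop("steering weights must be non-negative")
  structure(list(n_boids = n_boids, a1 = a1, a2 = a2, a3 = a3, speed = speed,
                 timestep = timestep, radius = radius, arena = arena,
                 noise_sd = noise_sd),
            class = "boids_params")
}

# displacement from a to b on the torus (minimal image), vectorised over rows
torus_diff <- function(a, b, arena) {
  d <- b - a
  d - arena * round(d / arena)
}

unit_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm < 1e-12] <- 1
  m / nrm
}

#' One step of the flocking dynamics
#'
#' Per boid, the steering update is
#' `a1 * u(centre) + a2 * u(away from nearest neighbour) + a3 * u(mean
#' neighbour heading)`, where `u()` denotes a unit vector and the flock
#' centre / nearest neighbour are taken under the minimal-image convention
#' of the toroidal arena.  The new heading is the direction of the current
#' heading vector plus the steering sum (plus Gaussian heading noise), and
#' the position advances by `speed * timestep` along it.
#'
#' @param state list with `positions` (n x 2 matrix) and `headings`
#'   (n angles, radians).
#' @param params a [boids_params].
#' @return the updated state.
#' @export
boids_step <- function(state, params) {
  pos <- state$positions
  th <- state$headings
  n <- nrow(pos)
  hvec <- cbind(cos(th), sin(th))
  steer <- hvec
  # pairwise minimal-image displacements: dx[i, j] points from boid i to j
  dx <- outer(pos[, 1], pos[, 1], function(a, b) b - a)
  dy <- outer(pos[, 2], pos[, 2], function(a, b) b - a)
  dx <- dx - params$arena * round(dx / params$arena)
  dy <- dy - params$arena * round(dy / params$arena)
  d2 <- dx^2 + dy^2
  diag(d2) <- Inf
  if (params$a1 > 0) {
    centre <- cbind(rowSums(dx), rowSums(dy)) / (n - 1)
    steer <- steer + params$a1 * unit_rows(centre)
  }
  if (params$a2 > 0) {
    nn <- max.col(-d2, ties.method = "first")
    away <- -cbind(dx[cbind(seq_len(n), nn)], dy[cbind(seq_len(n), nn)])
    steer <- steer + params$a2 * unit_rows(away)
  }
  if (params$a3 > 0) {
    nb <- d2 <= params$radius^2
    align <- nb %*% hvec
    has <- rowSums(nb) > 0
    if (any(has))
      steer[has, ] <- steer[has, ] + params$a3 * unit_rows(align[has, , drop = FALSE])
  }
  new_th <- atan2(steer[, 2], steer[, 1])
  if (params$noise_sd > 0)
    new_th <- new_th + stats::rnorm(n, 0, params$noise_sd)
  new_th <- new_th %% (2 * pi)
  pos <- pos + params$speed * params$timestep * cbind(cos(new_th), sin(new_th))
  pos <- pos %% params$arena
  list(positions = pos, headings = new_th)
}

#' Centre of mass of the flock
#'
#' Arithmetic mean of the boid positions (raw coordinates).
#'
#' @param state a flock state as in [boids_step()].
#' @return length-2 numeric vector.
#' @export
center_of_mass <- function(state) {
  colMeans(state$positions)
}

#' Simulate a flock trajectory
#'
#' Runs the flocking dynamics from uniformly random initial positions and
#' headings and records, at every step, each boid's position and heading
#' together with the centre-of-mass feature.
#'
#' @param params a [boids_params].
#' @param steps number of recorded time steps.
#' @param seed integer RNG seed (required; trajectories are reproducible).
#' @param burn_in steps discarded before recording (default 100).
#' @return list with `system`: a continuous [sample_matrix]
#'   (1 x steps x 3 n) with per-boid columns `x_i`, `y_i`, `th_i`;
#'   `feature`: a continuous [sample_matrix] (1 x steps x 2) holding the
#'   centre of mass; and `parts`: the column grouping (one part of 3
#'   columns per boid) for [emergence()].
#' @export
simulate_boids <- function(params, steps = 4000, seed, burn_in = 100) {
  stopifnot(inherits(params, "boids_params"))
  if (missing(seed)) stop("`seed` is required")
  n <- params$n_boids
  out <- array(0, dim = c(1, steps, 3 * n))
  com <- array(0, dim = c(1, steps, 2))
  withr_seed(seed, {
    state <- list(positions = matrix(stats::runif(2 * n, 0, params$arena), n, 2),
                  headings = stats::runif(n, 0, 2 * pi))
    for (s in seq_len(burn_in)) state <- boids_step(state, params)
    for (s in seq_len(steps)) {
      state <- boids_step(state, params)
      out[1, s, ] <- c(t(cbind(state$positions, state$headings)))
      com[1, s, ] <- center_of_mass(state)
    }
  })
  vars <- as.vector(t(outer(seq_len(n), c("x", "y", "th"),
                            function(i, v) paste0(v, "_", i))))
  list(system = sample_matrix(out, "continuous", vars = vars),
       feature = sample_matrix(com, "continuous", vars = c("com_x", "com_y")),
       parts = lapply(seq_len(n), function(i) 3 * (i - 1) + 1:3),
       params = params)
}

#' Avoidance-parameter sweep of the flocking model
#'
#' For each avoidance weight `a2` in `a2_values` (with all other
#' parameters held fixed), simulates a flock, computes the emergence
#' criterion Psi of the centre of mass with the Gaussian estimator and
#' surrogate errors, and records Psi's two components
#' `I(V_t; V_t')` and `sum_i I(X_t^i; V_t')` separately.
#'
#' @param a2_values numeric vector of avoidance weights (>= 2 values).
#' @param params base [boids_params] (its `a2` is overridden).
#' @param steps trajectory length per setting.
#' @param seed integer seed; setting j uses `seed + j - 1` for the
#'   simulation and the surrogates.
#' @param n_surrogates surrogate count per setting.
#' @param tau criterion lag in subsampled steps.
#' @param stride subsampling stride (steps) applied before forming lagged
#'   pairs, to reduce autocorrelation.
#' @return a `boids_sweep`: data.frame with one row per `a2` value
#'   (psi, surrogate sd, components, verdicts), with the full
#'   [emergence()] reports in `attr(x, "reports")`.
#' @export
sweep_avoidance <- function(a2_values, params = boids_params(), steps = 4000,
                            seed = 1, n_surrogates = 20, tau = 1, stride = 5) {
  if (length(a2_values) < 2) stop("supply at least 2 avoidance values")
  reports <- vector("list", length(a2_values))
  rows <- vector("list", length(a2_values))
  for (j in seq_along(a2_values)) {
    pj <- params
    pj$a2 <- a2_values[j]
    sim <- simulate_boids(pj, steps = steps, seed = seed + j - 1)
    sys_sub <- subsample_sm(sim$system, stride)
    feat_sub <- subsample_sm(sim$feature, stride)
    rep <- emergence(sys_sub, feat_sub, k = 1, tau = tau,
                     estimator = "gaussian", parts = sim$parts,
                     n_surrogates = n_surrogates, seed = seed + j - 1)
    rep$provenance$a1 <- params$a1
    rep$provenance$a2 <- a2_values[j]
    rep$provenance$a3 <- params$a3
    rep$provenance$sim_seed <- seed + j - 1
    reports[[j]] <- rep
    rows[[j]] <- data.frame(
      a2 = a2_values[j], psi = rep$psi,
      psi_sd = if (is.null(rep$surrogate)) NA_real_ else rep$surrogate$sd[["psi"]],
      i_vv = rep$components[["i_vv"]], sum_xv = rep$components[["sum_xv"]],
      emergent = rep$verdicts$emergent)
  }
  out <- do.call(rbind, rows)
  attr(out, "reports") <- reports
  class(out) <- c("boids_sweep", "data.frame")
  out
}

subsample_sm <- function(x, stride) {
  if (stride <= 1) return(x)
  idx <- seq(1, n_time(x), by = stride)
  sample_matrix(x$values[, idx, , drop = FALSE], kind = x$kind,
                card = x$card, vars = x$vars)
}

#' @export
print.boids_sweep <- function(x, ...) {
  cat("Avoidance sweep (Psi of the flock centre of mass, Gaussian estimator)\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
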