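#' Step parameters of the single-particle walk
#'
#' A cargo particle on a microtubule steps -1, 0 or +1 lattice sites per
#' timestep (retrograde, pause, anterograde) with base probabilities
#' `p_minus`, `p_zero`, `p_plus`. The memory parameter `k` in `[0, 1]`
#' linearly interpolates between a memoryless walk (`k = 0`) and a walk
#' that always repeats its previous step (`k = 1`), producing sustained
#' unidirectional runs; the expected run length under a sustained step
#' grows as `1 / (1 - k)`.
#'
#' @param p_minus,p_zero,p_plus step probabilities (must sum to 1).
#' @param k run-length memory in `[0, 1]`.
#' @param step_length lattice step in um.
#' @param dt timestep in s.
#' @return A `walk_params` list.
#' @examples
#' walk_params(0.2, 0.35, 0.45)          # drift 0.25 um/s = 15 um/min
#' @export
walk_params <- function(p_minus, p_zero, p_plus, k = 0,
                        step_length = 1, dt = 1) {
  p <- c(p_minus, p_zero, p_plus)
  if (any(p < 0)) stop("step probabilities must be nonnegative")
  if (abs(sum(p) - 1) > 1e-12) stop("step probabilities must sum to 1")
  if (k < 0 || k > 1) stop("memory k must lie in [0, 1]")
  if (step_length <= 0 || dt <= 0) stop("step_length and dt must be positive")
  structure(
    list(p_minus = p_minus, p_zero = p_zero, p_plus = p_plus, k = k,
         step_length = step_length, dt = dt),
    class = "walk_params"
  )
}

#' Conditional step distribution of the history-dependent walk
#'
#' Row `v` (previous step -1, 0, +1) gives the distribution of the next
#' step: `p(v' | v) = (1 - k) p_base(v') + k [v' = v]`.
#'
#' @param params a [walk_params()].
#' @return A 3x3 row-stochastic matrix with dimnames `-1, 0, +1`.
#' @export
walk_transition_matrix <- function(params) {
  stopifnot(inherits(params, "walk_params"))
  base <- c(params$p_minus, params$p_zero, params$p_plus)
  m <- (1 - params$k) * matrix(base, 3, 3, byrow = TRUE) +
    params$k * diag(3)
  dimnames(m) <- list(prev = c("-1", "0", "+1"), step = c("-1", "0", "+1"))
  m
}

#' Simulate an ensemble of single-particle walks
#'
#' All particles start at lattice position 0 (the soma end of the neurite).
#' The first step of every particle is drawn from the memoryless base
#' distribution; later steps follow [walk_transition_matrix()]. With
#' `boundary = "reflecting"` (a neurite that begins at the soma) a step
#' below position 0 is suppressed: the particle stays at 0 and its run
#' memory is reset to a pause. `boundary = "free"` simulates an infinite
#' cable.
#'
#' @param params a [walk_params()].
#' @param n_particles,n_steps ensemble size and number of timesteps.
#' @param seed integer seed; the ensemble is reproducible given the seed.
#' @param boundary `"free"` or `"reflecting"`.
#' @return A `walk_ensemble`: list with `positions` (matrix, particles x
#'   (n_steps + 1) lattice positions), `times` (s), `params`, `seed`.
#' @export
simulate_walk <- function(params, n_particles, n_steps, seed,
                          boundary = c("free", "reflecting")) {
  stopifnot(inherits(params, "walk_params"))
  boundary <- match.arg(boundary)
  if (n_particles < 1 || n_steps < 1) {
    stop("n_particles and n_steps must be at least 1")
  }
  base <- c(params$p_minus, params$p_zero, params$p_plus)
  k <- params$k
  x <- matrix(0L, n_particles, n_steps + 1L)
  withr::with_seed(as.integer(seed), {
    v <- integer(n_particles)
    for (n in seq_len(n_steps)) {
      fresh <- sample(c(-1L, 0L, 1L), n_particles, replace = TRUE, prob = base)
      if (n == 1L || k == 0) {
        vn <- fresh
      } else {
        keep <- stats::runif(n_particles) < k
        vn <- ifelse(keep, v, fresh)
      }
      xn <- x[, n] + vn
      if (boundary == "reflecting") {
        hit <- xn < 0L
        xn[hit] <- 0L
        vn[hit] <- 0L
      }
      x[, n + 1L] <- xn
      v <- vn
    }
  })
  structure(
    list(positions = x, times = (0:n_steps) * params$dt,
         params = params, seed = as.integer(seed)),
    class = "walk_ensemble"
  )
}

#' @export
print.walk_ensemble <- function(x, ...) {
  cat(sprintf(
    "<walk_ensemble> %d particles x %d steps (k = %g, seed = %d)\n",
    nrow(x$positions), ncol(x$positions) - 1L, x$params$k, x$seed
  ))
  invisible(x)
}

#' Tidy a walk ensemble into a long tibble
#'
#' @param x a `walk_ensemble`.
#' @param ... unused.
#' @return Tibble with columns `particle`, `t_s`, `x_um`.
#' @export
tidy.walk_ensemble <- function(x, ...) {
  np <- nrow(x$positions)
  nt <- ncol(x$positions)
  tibble::tibble(
    particle = rep(seq_len(np), times = nt),
    t_s = rep(x$times, each = np),
    x_um = as.vector(x$positions) * x$params$step_length
  )
}

#' Closed-form mass-action rates of the memoryless walk
#'
#' Moment matching of the memoryless (`k = 0`) walk to the drift-diffusion
#' limit of the mass-action chain gives
#' `a = (2 p_plus - (p_plus - p_minus)^2) / 2` and
#' `b = (2 p_minus - (p_plus - p_minus)^2) / 2`, scaled to per-second rates
#' for the walk's lattice spacing and timestep.
#'
#' @param params a [walk_params()] with `k = 0`.
#' @return Named numeric `c(a = , b = )` in s^-1.
#' @examples
#' walk_analytic_rates(walk_params(0.2, 0.35, 0.45))  # a = 0.41875, b = 0.16875
#' @export
walk_analytic_rates <- function(params) {
  stopifnot(inherits(params, "walk_params"))
  if (params$k != 0) stop("closed-form rates require a memoryless walk (k = 0)")
  drift <- params$p_plus - params$p_minus
  b <- (2 * params$p_minus - drift^2) / 2
  if (b < 0) {
    stop("outside model validity: requires 2 p_minus >= (p_plus - p_minus)^2")
  }
  a <- (2 * params$p_plus - drift^2) / 2
  c(a = a / params$dt, b = b / params$dt)
}

#' Fit mass-action rates to a simulated ensemble
#'
#' Through-origin least-squares slopes of the ensemble mean position
#' (drift `= a - b`) and position variance (`= a + b`) against time, both
#' in lattice units per timestep, converted to per-second rates. The fit
#' quality is the R^2 of a Gaussian fit to the final concentration profile.
#'
#' @param ensemble a `walk_ensemble` from [simulate_walk()].
#' @return A `walk_fit` object; see [tidy.walk_fit()] and
#'   [glance.walk_fit()].
#' @export
fit_walk <- function(ensemble) {
  stopifnot(inherits(ensemble, "walk_ensemble"))
  x <- ensemble$positions
  if (ncol(x) < 3) stop("need at least 2 timepoints after t = 0")
  steps <- seq_len(ncol(x) - 1L)
  mu <- colMeans(x[, -1, drop = FALSE])
  vv <- apply(x[, -1, drop = FALSE], 2, stats::var)
  if (all(vv == 0)) stop("degenerate ensemble: zero variance at all times")
  drift <- sum(mu * steps) / sum(steps^2)
  var_rate <- sum(vv * steps) / sum(steps^2)
  dt <- ensemble$params$dt
  a <- (var_rate + drift) / (2 * dt)
  b <- (var_rate - drift) / (2 * dt)
  # Gaussian fit to the final concentration profile
  final <- x[, ncol(x)]
  tab <- table(final)
  pos <- as.numeric(names(tab))
  dens <- as.numeric(tab) / length(final)
  pred <- stats::dnorm(pos, mean = mean(final), sd = stats::sd(final))
  pred <- pred / sum(pred) * sum(dens)
  r2 <- 1 - sum((dens - pred)^2) / sum((dens - mean(dens))^2)
  structure(
    list(a = a, b = b, drift = drift / dt, var_rate = var_rate / dt,
         r_squared = r2, params = ensemble$params,
         n_particles = nrow(x), n_steps = ncol(x) - 1L),
    class = "walk_fit"
  )
}

#' @export
print.walk_fit <- function(x, ...) {
  cat(sprintf(
    "<walk_fit> a = %.4g, b = %.4g s^-1 (drift %.4g, variance rate %.4g per s; R^2 = %.3f)\n",
    x$a, x$b, x$drift, x$var_rate, x$r_squared
  ))
  invisible(x)
}

#' @rdname fit_walk
#' @param x a `walk_fit`.
#' @param ... unused.
#' @export
tidy.walk_fit <- function(x, ...) {
  tibble::tibble(
    term = c("a", "b"),
    estimate = c(x$a, x$b),
    unit = "1/s"
  )
}

#' @rdname fit_walk
#' @export
glance.walk_fit <- function(x, ...) {
  step <- x$params$step_length
  tibble::tibble(
    drift_um_s = x$drift * step,
    velocity_um_min = x$drift * step * 60,
    variance_rate_um2_s = x$var_rate * step^2,
    diffusion_um2_s = x$var_rate * step^2 / 2,
    r_squared = x$r_squared,
    n_particles = x$n_particles,
    n_steps = x$n_steps
  )
}

#' Occupancy noise of low-copy-number transport
#'
#' In the stochastic reading of the mass-action model the steady-state
#' occupancy of a compartment is binomial; with occupancy probability
#' `p_ss` and `n` independently transported particles the coefficient of
#' variation of the compartment content is `sqrt((1 - p_ss) / (n p_ss))`.
#'
#' @param p_ss steady-state occupancy probability in `(0, 1]`.
#' @param n number of transported particles (>= 1).
#' @return Dimensionless CV.
#' @export
occupancy_cv <- function(p_ss, n) {
  if (any(p_ss <= 0)) stop("occupancy probability must be positive")
  if (any(p_ss > 1)) stop("occupancy probability cannot exceed 1")
  if (any(n < 1)) stop("n must be at least 1")
  sqrt((1 - p_ss) / (n * p_ss))
}
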