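#' Mean percent error of a delivered distribution
#'
#' Both vectors are normalised to unit mass; the error is the mean, over
#' compartments with nonzero demand, of `|delivered - demand| / demand`,
#' in percent. Zero-demand compartments are excluded because a relative
#' error there is undefined (and hotspot-style figures report error at the
#' demanded sites).
#'
#' @param delivered nonnegative per-compartment masses (or a tibble with a
#'   `delivered` or `detached` column).
#' @param demand a [demand_profile()] or nonnegative vector.
#' @return Percent error (scalar).
#' @export
mean_percent_error <- function(delivered, demand) {
  x <- as_mass_vector(delivered)
  v <- demand_vector(demand)
  if (length(x) != length(v)) stop("length mismatch")
  if (any(x < 0)) stop("delivered mass must be nonnegative")
  if (sum(x) <= 0) stop("delivered mass must have positive total")
  x <- x / sum(x)
  nz <- v > 0
  100 * mean(abs(x[nz] - v[nz]) / v[nz])
}

as_mass_vector <- function(x) {
  if (is.data.frame(x)) {
    col <- intersect(c("delivered", "detached", "bound", "mass"), names(x))
    if (!length(col)) stop("no mass column found")
    x <- x[[col[1]]]
  }
  as.numeric(x)
}

#' L1 error from a demand profile
#'
#' `sum_i |state_i - demand_i * total|` where `total` is the total mass of
#' `state`; zero iff the state matches the demand-shaped target exactly.
#'
#' @param state per-compartment masses.
#' @param demand a [demand_profile()] or nonnegative vector.
#' @return Total absolute error (mass units).
#' @export
l1_error <- function(state, demand) {
  x <- as_mass_vector(state)
  v <- demand_vector(demand)
  if (length(x) != length(v)) stop("length mismatch")
  sum(abs(x - v * sum(x)))
}

#' Time to deliver a fraction of the cargo
#'
#' Earliest time at which the detached pool holds at least `q` of the total
#' mass, linearly interpolated between stored timepoints.
#'
#' @param trajectory a `cargo_trajectory`.
#' @param q fraction in (0, 1).
#' @return Time in seconds; `Inf` with a warning if not reached.
#' @export
time_to_fraction_delivered <- function(trajectory, q = 0.95) {
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  df <- tibble::as_tibble(trajectory) |>
    dplyr::group_by(.data$time_s) |>
    dplyr::summarise(frac = sum(.data$detached) /
                       sum(.data$detached + .data$bound), .groups = "drop")
  ix <- which(df$frac >= q)
  if (!length(ix)) {
    warning("fraction ", q, " not delivered within the trajectory horizon")
    return(Inf)
  }
  i <- ix[1]
  if (i == 1) return(df$time_s[1])
  t0 <- df$time_s[i - 1]; t1 <- df$time_s[i]
  f0 <- df$frac[i - 1]; f1 <- df$frac[i]
  t0 + (q - f0) / (f1 - f0) * (t1 - t0)
}

#' Excess cargo fraction at steady state
#'
#' The fraction of cargo still in transit (bound to microtubules) at the
#' steady state of a reversible system: `sum(u) / (sum(u) + sum(u*))`.
#' Irreversible systems deliver everything, so the excess is 0.
#'
#' @param system a [transport_system()], or the tibble from
#'   [steady_state()].
#' @return Dimensionless fraction in `[0, 1]`.
#' @export
excess_fraction <- function(system) {
  ss <- if (inherits(system, "transport_system")) {
    if (all(system$d == 0)) return(0)
    steady_state(system)
  } else system
  sum(ss$bound) / (sum(ss$bound) + sum(ss$detached))
}

#' Time to converge to the demand profile
#'
#' Earliest stored time at which the chosen pool's mean percent error from
#' demand falls below `tol` and remains below it for the rest of the
#' trajectory horizon.
#'
#' @param trajectory a `cargo_trajectory`.
#' @param demand a [demand_profile()] or vector.
#' @param tol tolerance in percent (default 10).
#' @param pool `"detached"` (default), `"bound"` or `"total"`.
#' @return Time in seconds; `Inf` with a warning if never reached.
#' @export
time_to_converge <- function(trajectory, demand, tol = 10,
                             pool = c("detached", "bound", "total")) {
  pool <- match.arg(pool)
  if (tol <= 0) stop("tol must be positive")
  df <- tibble::as_tibble(trajectory)
  df$value <- switch(pool,
    detached = df$detached, bound = df$bound,
    total = df$bound + df$detached
  )
  errs <- df |>
    dplyr::group_by(.data$time_s) |>
    dplyr::summarise(err = if (sum(.data$value) > 0) {
      mean_percent_error(.data$value, demand)
    } else Inf, .groups = "drop")
  below <- rev(cumprod(rev(errs$err < tol))) > 0
  if (!any(below)) {
    warning("error never settles below ", tol, "% within the horizon")
    return(Inf)
  }
  errs$time_s[which(below)[1]]
}

#' Sweep a strategy parameter and record the speed/precision tradeoff
#'
#' For each value of the swept parameter the strategy system is rebuilt and
#' three operating characteristics are recorded: the mean percent error of
#' the final delivered distribution (irreversible) or steady-state detached
#' pool (reversible); the delivery/convergence time (time to deliver the
#' fraction `q` for irreversible systems, time to reach `tol`% mean error
#' for reversible ones); and the excess (in-transit) fraction at steady
#' state. Fully deterministic.
#'
#' @param tree a [compartment_tree()].
#' @param demand a [demand_profile()].
#' @param strategy `"ddd"`, `"ddt"` or `"mix"`.
#' @param sweep name of the swept argument (`"c_max"`, `"d"` or `"beta"`).
#' @param values numeric sweep values (>= 1 value, reported sorted).
#' @param F mixing scalar for `strategy = "mix"`.
#' @param c_max,d fixed rates for parameters not being swept.
#' @param beta anterograde bias (cable only); swept or fixed.
#' @param normalization,D passed to the strategy constructors.
#' @param q delivered-fraction criterion for irreversible sweeps.
#' @param tol convergence tolerance (percent) for reversible sweeps.
#' @param horizon evolution horizon in seconds for convergence times.
#' @param n_times size of the logarithmic time grid.
#' @return A `tradeoff_curve` tibble: `param`, `value`, `error_pct`,
#'   `time_s`, `excess_frac`.
#' @export
tradeoff_sweep <- function(tree, demand, strategy = c("ddd", "ddt", "mix"),
                           sweep = c("c_max", "d", "beta"), values,
                           F = 0, c_max = 0, d = 0, beta = 0,
                           normalization = "physical", D = 10,
                           q = 0.95, tol = 10, horizon = 1e8, n_times = 64) {
  strategy <- match.arg(strategy)
  sweep <- match.arg(sweep)
  if (length(values) < 1) stop("need at least one sweep value")
  values <- sort(values)
  rows <- purrr::map(values, function(val) {
    cm <- if (sweep == "c_max") val else c_max
    dd <- if (sweep == "d") val else d
    bb <- if (sweep == "beta") val else beta
    sys <- switch(strategy,
      ddd = ddd_system(tree, demand, c_max = cm, d = dd,
                       normalization = normalization, D = D),
      ddt = ddt_system(tree, demand, c_max = cm, d = dd,
                       normalization = normalization, D = D),
      mix = mixed_system(tree, demand, F = F, c_max = cm, d = dd,
                         normalization = normalization, D = D)
    )
    if (bb > 0) sys <- apply_bias(sys, bb)
    if (all(sys$d == 0)) {
      deliv <- delivered_distribution(sys)
      err <- mean_percent_error(deliv, demand)
      traj <- evolve_transport(sys, log_times(1, horizon, n_times))
      tt <- suppressWarnings(time_to_fraction_delivered(traj, q))
      ex <- 0
    } else {
      ss <- steady_state(sys)
      err <- mean_percent_error(ss$detached, demand)
      traj <- evolve_transport(sys, log_times(1, horizon, n_times))
      tt <- suppressWarnings(time_to_converge(traj, demand, tol = tol))
      ex <- excess_fraction(ss)
    }
    tibble::tibble(param = sweep, value = val, error_pct = err,
                   time_s = tt, excess_frac = ex)
  })
  structure(dplyr::bind_rows(rows),
            class = c("tradeoff_curve", class(tibble::tibble())))
}

#' Overlay a tuned anterograde bias on a cable system
#'
#' Replaces the edge rates of an unbranched-cable system with the
#' [tuned_bias_rates()] profile, preserving each edge's rate sum (and so
#' the local diffusion coefficient).
#'
#' @param system a [transport_system()] on an unbranched cable with a
#'   uniform edge rate sum.
#' @param beta bias amplitude (s^-1).
#' @return The modified [transport_system()].
#' @export
apply_bias <- function(system, beta) {
  e <- system$edges
  if (!all(e$parent == seq_len(nrow(e)))) {
    stop("tuned bias requires an unbranched cable")
  }
  rsum <- unique(round(e$a + e$b, 12))
  if (length(rsum) != 1) stop("tuned bias requires a uniform edge rate sum")
  tb <- tuned_bias_rates(n_compartments(system$tree), beta, rate_sum = rsum)
  transport_system(system$tree, a = tb$a, b = tb$b,
                   c = system$c, d = system$d,
                   u0 = system$u0, ustar0 = system$ustar0)
}
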