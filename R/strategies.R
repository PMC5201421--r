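#' Demand profiles
#'
#' A demand profile is the target spatial distribution of delivered cargo:
#' a nonnegative per-compartment vector normalised to unit mass. The floor
#' `epsilon` (relative to the smallest nonzero demand) is substituted for
#' exact zeros by trafficking-based strategies, because a hard zero demand
#' closes the trafficking rates into that compartment entirely and creates
#' an infinitely strong transport bottleneck.
#'
#' @param demand nonnegative numeric vector (or a two-column data frame
#'   `id`, `demand`).
#' @param epsilon relative floor applied to zero-demand compartments by
#'   [ddt_system()] and interpolated strategies; expressed as a fraction
#'   of the smallest nonzero demand (default `1e-3`).
#' @return A `demand_profile` tibble with columns `id`, `demand`.
#' @export
demand_profile <- function(demand, epsilon = 1e-3) {
  if (is.data.frame(demand)) {
    stopifnot(all(c("id", "demand") %in% names(demand)))
    demand <- demand$demand[order(demand$id)]
  }
  if (any(demand < 0)) stop("demand must be nonnegative")
  if (sum(demand) <= 0) stop("demand must have positive total")
  if (epsilon < 0 || epsilon >= 1) stop("epsilon must lie in [0, 1)")
  d <- demand / sum(demand)
  structure(
    tibble::tibble(id = seq_along(d), demand = d),
    epsilon = epsilon,
    class = c("demand_profile", class(tibble::tibble()))
  )
}

demand_vector <- function(demand, n = NULL, floored = FALSE) {
  if (inherits(demand, "demand_profile")) {
    v <- demand$demand
    eps <- attr(demand, "epsilon")
  } else {
    v <- as.numeric(demand)
    if (any(v < 0) || sum(v) <= 0) stop("invalid demand vector")
    v <- v / sum(v)
    eps <- 1e-3
  }
  if (!is.null(n) && length(v) != n) {
    stop("demand has ", length(v), " entries but the tree has ", n,
         " compartments")
  }
  if (floored && any(v == 0)) {
    floor_val <- eps * min(v[v > 0])
    if (floor_val == 0) {
      stop("zero demand with epsilon = 0: trafficking rate would divide ",
           "by zero (bottleneck of infinite strength)")
    }
    v[v == 0] <- floor_val
    v <- v / sum(v)
  }
  v
}

# per-edge rate sums: "unit" fixes a + b = 1 per edge; "physical" fixes the
# local diffusion coefficient, a + b = 2 D / delta^2
edge_rate_sum <- function(tree, normalization = c("physical", "unit"),
                          D = 10) {
  normalization <- match.arg(normalization)
  edges <- tree_edges(tree)
  if (normalization == "unit") rep(1, nrow(edges)) else 2 * D / edges$delta^2
}

#' Demand-dependent trafficking (DDT)
#'
#' Local demand sets the trafficking rate ratio on every edge,
#' `b / a = demand_parent / demand_child`, with `a + b` fixed by the
#' normalisation; detachment is uniform and non-specific (`c = c_max`).
#' The trafficking-only steady state then matches the demand profile
#' exactly.
#'
#' @param tree a [compartment_tree()].
#' @param demand a [demand_profile()] or nonnegative vector.
#' @param c_max uniform detachment rate (s^-1).
#' @param d uniform reattachment rate (s^-1), 0 for irreversible delivery.
#' @param normalization `"physical"` (`a + b = 2 D / delta^2`, the default,
#'   with `D` in um^2/s) or `"unit"` (`a + b = 1`).
#' @param D diffusion coefficient for the physical normalisation (um^2/s).
#' @return A [transport_system()].
#' @export
ddt_system <- function(tree, demand, c_max = 0, d = 0,
                       normalization = c("physical", "unit"), D = 10) {
  v <- demand_vector(demand, n_compartments(tree), floored = TRUE)
  edges <- tree_edges(tree)
  rsum <- edge_rate_sum(tree, normalization, D)
  # b/a = v_parent / v_child and a + b = rsum
  ratio <- v[edges$parent] / v[edges$child]
  a <- rsum / (1 + ratio)
  b <- rsum - a
  transport_system(tree, a = a, b = b, c = c_max, d = d)
}

#' Demand-dependent detachment (DDD)
#'
#' Trafficking is spatially uniform (`a = b`) so cargo spreads everywhere;
#' detachment is proportional to local demand, `c_i = c_max *
#' demand_i / max(demand)`, so zero-demand compartments never capture
#' cargo.
#'
#' @inheritParams ddt_system
#' @return A [transport_system()].
#' @export
ddd_system <- function(tree, demand, c_max = 0, d = 0,
                       normalization = c("physical", "unit"), D = 10) {
  v <- demand_vector(demand, n_compartments(tree))
  rsum <- edge_rate_sum(tree, normalization, D)
  cvec <- if (max(v) > 0) c_max * v / max(v) else stop("all-zero demand")
  transport_system(tree, a = rsum / 2, b = rsum / 2, c = cvec, d = d)
}

#' Interpolated trafficking/detachment strategy
#'
#' Mixes DDT and DDD: the trafficking target along the microtubules is
#' `mix_i = F * demand_i + (1 - F) / N` and detachment is proportional to
#' `demand_i / mix_i`. `F = 1` reproduces [ddt_system()] exactly, `F = 0`
#' reproduces [ddd_system()].
#'
#' @inheritParams ddt_system
#' @param F mixing scalar in `[0, 1]`.
#' @return A [transport_system()].
#' @export
mixed_system <- function(tree, demand, F, c_max = 0, d = 0,
                         normalization = c("physical", "unit"), D = 10) {
  if (F < 0 || F > 1) stop("F must lie in [0, 1]")
  n <- n_compartments(tree)
  v <- demand_vector(demand, n, floored = (F == 1))
  mix <- F * v + (1 - F) / n
  if (any(mix == 0)) {
    # only possible at F = 1 with epsilon = 0; demand_vector already errors
    stop("degenerate mixture")
  }
  edges <- tree_edges(tree)
  rsum <- edge_rate_sum(tree, normalization, D)
  ratio <- mix[edges$parent] / mix[edges$child]
  a <- rsum / (1 + ratio)
  b <- rsum - a
  rel <- v / mix
  cvec <- if (max(rel) > 0) c_max * rel / max(rel) else stop("all-zero demand")
  transport_system(tree, a = a, b = b, c = cvec, d = d)
}

#' Linearly decreasing anterograde bias profile
#'
#' Upregulates anterograde trafficking near the soma on an unbranched
#' cable: with edge index `i = 1..N-1` from the soma and per-edge rate sum
#' `R` (so the diffusion coefficient is preserved),
#' `a_i = R/2 + beta (N - 1 - i) / (N - 2)` and `b_i = R - a_i`. The bias
#' is maximal at the soma (`a_1 = R/2 + beta`) and vanishes at the distal
#' end. Requires `beta < R/2` so no rate goes negative.
#'
#' @param n_compartments cable size N.
#' @param beta bias amplitude (s^-1), `0 <= beta < R/2`.
#' @param rate_sum per-edge `a + b` (s^-1); for a cable of spacing
#'   `delta` and diffusion coefficient `D`, `rate_sum = 2 D / delta^2`.
#' @return Tibble with `edge`, `a`, `b`.
#' @export
tuned_bias_rates <- function(n_compartments, beta, rate_sum = 1) {
  n <- n_compartments
  if (n < 3) stop("need at least 3 compartments")
  if (beta < 0 || beta >= rate_sum / 2) {
    stop("beta must satisfy 0 <= beta < (a + b)/2 = ", rate_sum / 2,
         " so that no retrograde rate becomes negative")
  }
  i <- seq_len(n - 1)
  a <- rate_sum / 2 + beta * (n - 1 - i) / (n - 2)
  tibble::tibble(edge = i, a = a, b = rate_sum - a)
}

#' Geometry-preserving trafficking rates
#'
#' Scales trafficking rates inversely with the squared midpoint spacing of
#' each edge, `a_e = b_e = D / delta_e^2`, so the local diffusion
#' coefficient `(a_e + b_e)/2 * delta_e^2` equals `D` everywhere and model
#' behaviour is invariant to the compartmentalisation.
#'
#' @param tree a [compartment_tree()].
#' @param D diffusion coefficient (um^2/s).
#' @return Tibble `parent`, `child`, `delta`, `a`, `b`.
#' @export
scale_rates_to_geometry <- function(tree, D) {
  if (D <= 0) stop("D must be positive")
  edges <- tree_edges(tree)
  if (any(edges$delta <= 0)) stop("zero-length edge")
  dplyr::mutate(edges, a = D / .data$delta^2, b = D / .data$delta^2)
}

#' Demand from a local biochemical signal
#'
#' Maps a per-compartment signal (e.g. cytosolic calcium) through a
#' monotone function `f` that models how the signal arrests local
#' trafficking; the implied demand is `1 / f(signal)`, normalised. A DDT
#' system built from this demand satisfies `b / a = f(signal_child) /
#' f(signal_parent)` on every edge.
#'
#' @param signal positive per-compartment signal values.
#' @param f monotone positive mapping; default a Hill function
#'   `s^h / (K^h + s^h)`.
#' @param K,hill Hill parameters used when `f` is not supplied.
#' @param epsilon passed to [demand_profile()].
#' @return A [demand_profile()].
#' @export
demand_from_signal <- function(signal, f = NULL, K = 1, hill = 1,
                               epsilon = 1e-3) {
  if (any(signal <= 0)) stop("signal must be positive")
  if (is.null(f)) f <- function(s) s^hill / (K^hill + s^hill)
  y <- f(signal)
  if (any(!is.finite(y)) || any(y <= 0)) {
    stop("mapping must be positive and finite on the signal")
  }
  o <- order(signal)
  ys <- y[o][!duplicated(signal[o])]
  if (length(ys) > 1 && !(all(diff(ys) >= 0) || all(diff(ys) <= 0))) {
    stop("mapping is not monotone on the supplied signal")
  }
  demand_profile(1 / y, epsilon = epsilon)
}
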