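#' Hotspot demand profiles
#'
#' Demand concentrated in `n_hotspots` compartments of equal weight
#' `1 / n_hotspots`, zero elsewhere. Even placement uses the centred grid
#' `round((j + 1/2) N / n)` for `j = 0..n-1`; random placement draws
#' distinct compartments uniformly under the given seed.
#'
#' @param n_compartments cable/tree size N.
#' @param n_hotspots number of hotspots (<= N).
#' @param placement `"evenly"` or `"random"`.
#' @param seed integer seed for random placement.
#' @param epsilon passed to [demand_profile()].
#' @return A [demand_profile()].
#' @examples
#' demand_hotspots(100, 6)  # six evenly spaced hotspots on a 100-cable
#' @export
demand_hotspots <- function(n_compartments, n_hotspots,
                            placement = c("evenly", "random"), seed = 1,
                            epsilon = 1e-3) {
  placement <- match.arg(placement)
  n <- n_compartments
  if (n_hotspots > n) stop("more hotspots than compartments")
  if (n_hotspots < 1) stop("need at least one hotspot")
  pos <- if (placement == "evenly") {
    round((seq_len(n_hotspots) - 0.5) * n / n_hotspots)
  } else {
    withr::with_seed(as.integer(seed), sort(sample.int(n, n_hotspots)))
  }
  pos <- pmin(pmax(pos, 1L), n)
  v <- numeric(n)
  v[pos] <- 1 / n_hotspots
  demand_profile(v, epsilon = epsilon)
}

#' Bottleneck demand profile
#'
#' Uniform demand with a contiguous low-demand region at `1 / ratio` of the
#' surrounding level (default an order of magnitude lower). Under DDT the
#' low-demand region throttles the trafficking rates into it and acts as a
#' transport bottleneck.
#'
#' @param n_compartments cable/tree size N.
#' @param low_region integer indices of the low-demand compartments.
#' @param ratio high/low demand ratio (> 0); `ratio = 1` is uniform.
#' @param epsilon passed to [demand_profile()].
#' @return A [demand_profile()].
#' @export
demand_bottleneck <- function(n_compartments,
                              low_region = middle_third(n_compartments),
                              ratio = 10, epsilon = 1e-3) {
  if (ratio <= 0) stop("ratio must be positive")
  if (length(low_region) == 0) stop("empty low-demand region")
  if (any(low_region < 1 | low_region > n_compartments)) {
    stop("low_region out of bounds")
  }
  v <- rep(1, n_compartments)
  v[low_region] <- 1 / ratio
  demand_profile(v, epsilon = epsilon)
}

#' @rdname demand_bottleneck
#' @export
middle_third <- function(n_compartments) {
  lo <- floor(n_compartments / 3) + 1L
  hi <- ceiling(2 * n_compartments / 3)
  seq.int(lo, hi)
}

#' Linear demand gradient
#'
#' Demand proportional to the compartment index counted from the soma,
#' emulating distance-dependent ion-channel expression gradients. The DDT
#' rates for this profile satisfy `b_i / a_i = i / (i + 1)`.
#'
#' @param n_compartments cable size N.
#' @param epsilon passed to [demand_profile()].
#' @return A [demand_profile()].
#' @export
demand_linear_gradient <- function(n_compartments, epsilon = 1e-3) {
  demand_profile(seq_len(n_compartments), epsilon = epsilon)
}

#' Three-compartment bottleneck fixture
#'
#' The minimal transport bottleneck: a three-compartment cable where
#' transport into the middle compartment runs at rate `epsilon` and
#' transport out of it at rate 1, with all cargo starting in compartment 1.
#' As `epsilon` shrinks the relaxation time `1 / |lambda_2|` grows without
#' bound.
#'
#' @param epsilon rate into the middle compartment (s^-1, > 0).
#' @return A [transport_system()].
#' @export
bottleneck_system <- function(epsilon) {
  if (epsilon <= 0) stop("epsilon must be positive")
  tree <- build_cable(3, 3)
  # edges 1->2 and 2->3: into the middle (a1, b2) slow; out of it fast
  transport_system(tree, a = c(epsilon, 1), b = c(1, epsilon))
}
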