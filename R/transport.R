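#' Mass-action transport system on a compartment tree
#'
#' Bundles a [compartment_tree()] with per-edge trafficking rates
#' (anterograde `a`, parent to child; retrograde `b`, child to parent),
#' per-compartment detachment (`c`) and reattachment (`d`) rates, and the
#' initial bound (`u0`) and detached (`ustar0`) cargo. All rates are in
#' s^-1; cargo is in arbitrary mass units. By default all cargo starts
#' bound in the root (somatic) compartment.
#'
#' @param tree a [compartment_tree()].
#' @param a,b per-edge rates, one per row of [tree_edges()] (recycled if
#'   scalar).
#' @param c,d per-compartment detachment/reattachment rates (recycled).
#' @param u0,ustar0 initial bound/detached cargo per compartment.
#' @return A `transport_system`.
#' @export
transport_system <- function(tree, a, b, c = 0, d = 0,
                             u0 = NULL, ustar0 = NULL) {
  stopifnot(inherits(tree, "compartment_tree"))
  edges <- tree_edges(tree)
  n <- n_compartments(tree)
  ne <- nrow(edges)
  a <- rep_len(a, ne); b <- rep_len(b, ne)
  c <- rep_len(c, n); d <- rep_len(d, n)
  if (any(!is.finite(c(a, b, c, d))) || any(c(a, b, c, d) < 0)) {
    stop("all rates must be finite and nonnegative")
  }
  if (is.null(u0)) {
    u0 <- numeric(n)
    u0[is.na(tree$parent)] <- 1
  }
  if (is.null(ustar0)) ustar0 <- numeric(n)
  u0 <- rep_len(u0, n); ustar0 <- rep_len(ustar0, n)
  if (any(u0 < 0) || any(ustar0 < 0)) stop("initial masses must be nonnegative")
  structure(
    list(tree = tree, edges = dplyr::mutate(edges, a = a, b = b),
         c = c, d = d, u0 = u0, ustar0 = ustar0),
    class = "transport_system"
  )
}

#' @export
print.transport_system <- function(x, ...) {
  cat(sprintf(
    "<transport_system> %d compartments; a in [%.3g, %.3g], b in [%.3g, %.3g] s^-1; detachment %s; reattachment %s\n",
    n_compartments(x$tree),
    min(x$edges$a), max(x$edges$a), min(x$edges$b), max(x$edges$b),
    if (all(x$c == 0)) "off" else sprintf("max %.3g s^-1", max(x$c)),
    if (all(x$d == 0)) "off" else sprintf("max %.3g s^-1", max(x$d))
  ))
  invisible(x)
}

#' Per-compartment rate table of a transport system
#' @param x a `transport_system`.
#' @param ... unused.
#' @return Tibble with `id`, `parent`, incoming `a`/`b` (NA at the root),
#'   `c`, `d`.
#' @export
tidy.transport_system <- function(x, ...) {
  tr <- x$tree
  m <- match(tr$id, x$edges$child)
  tibble::tibble(
    id = tr$id, parent = tr$parent,
    a = x$edges$a[m], b = x$edges$b[m],
    c = x$c, d = x$d
  )
}

# bound-block generator M (N x N): trafficking minus detachment outflow
bound_generator <- function(system, with_detachment = TRUE) {
  n <- n_compartments(system$tree)
  e <- system$edges
  i <- c(e$child, e$parent, e$parent, e$child)
  j <- c(e$parent, e$parent, e$child, e$child)
  v <- c(e$a, -e$a, e$b, -e$b)
  if (with_detachment) {
    i <- c(i, seq_len(n)); j <- c(j, seq_len(n)); v <- c(v, -system$c)
  }
  Matrix::sparseMatrix(i = i, j = j, x = v, dims = c(n, n))
}

#' Assemble the linear generator of a transport system
#'
#' Returns the sparse generator `A` of `d(state)/dt = A state`. With any
#' detachment the state is `(u, u*)` (bound block first, 2N x 2N); with all
#' detachment rates zero it is the N x N trafficking generator, which on an
#' unbranched cable is tridiagonal (a Hines matrix on trees). Every column
#' sums to zero: mass is conserved.
#'
#' @param system a [transport_system()].
#' @return A sparse `dgCMatrix`.
#' @export
transport_generator <- function(system) {
  n <- n_compartments(system$tree)
  if (all(system$c == 0) && all(system$d == 0)) {
    return(bound_generator(system, with_detachment = FALSE))
  }
  M <- bound_generator(system)
  A <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(2 * n, 2 * n))
  A[1:n, 1:n] <- M
  idx <- seq_len(n)
  A[cbind(n + idx, idx)] <- system$c
  A[cbind(idx, n + idx)] <- system$d
  A[cbind(n + idx, n + idx)] <- -system$d
  A
}

#' Logarithmically spaced time grid
#'
#' @param from,to positive endpoints in seconds.
#' @param n number of points (default 64).
#' @return Increasing numeric vector.
#' @export
log_times <- function(from, to, n = 64) {
  stopifnot(from > 0, to > from, n >= 2)
  exp(seq(log(from), log(to), length.out = n))
}

# propagate state through one interval with the matrix exponential
step_expm <- function(A, state, dt) {
  as.numeric(Matrix::expm(A * dt) %*% state)
}

#' Evolve a transport system exactly
#'
#' Exact solution of the linear mass-action system at the requested times,
#' computed with the matrix exponential (scaling and squaring) stepped
#' between consecutive timepoints. Irreversible systems (all reattachment
#' rates zero) use the block-triangular closed form: the bound pool evolves
#' under the bound-block generator and the detached pool accumulates its
#' integral, which avoids the defective full generator.
#'
#' @param system a [transport_system()].
#' @param times nonnegative, strictly increasing times (s); use
#'   [log_times()] for the customary logarithmic grids.
#' @param method `"expm"` (exact, default) or `"ode"` (stiff integrator via
#'   deSolve, for very large systems).
#' @return A `cargo_trajectory`: tidy tibble with columns `time_s`, `id`,
#'   `bound`, `detached`.
#' @export
evolve_transport <- function(system, times, method = c("expm", "ode")) {
  method <- match.arg(method)
  stopifnot(inherits(system, "transport_system"))
  if (any(times < 0) || is.unsorted(times, strictly = TRUE)) {
    stop("times must be nonnegative and strictly increasing")
  }
  n <- n_compartments(system$tree)
  irreversible <- all(system$d == 0)
  out <- matrix(0, length(times), 2 * n)
  if (method == "ode") {
    if (!requireNamespace("deSolve", quietly = TRUE)) {
      stop("method = \"ode\" needs the deSolve package")
    }
    A <- transport_generator(system)
    state0 <- if (nrow(A) == n) system$u0 else c(system$u0, system$ustar0)
    sol <- deSolve::lsoda(
      y = state0, times = c(0, times),
      func = function(t, y, p) list(as.numeric(A %*% y)),
      rtol = 1e-10, atol = 1e-12
    )
    sol <- sol[-1, -1, drop = FALSE]
    if (ncol(sol) == n) {
      out[, 1:n] <- sol
      out[, n + 1:n] <- matrix(system$ustar0, length(times), n, byrow = TRUE)
    } else {
      out[] <- sol
    }
  } else if (irreversible) {
    M <- bound_generator(system)
    u <- system$u0
    ustar <- system$ustar0
    tprev <- 0
    some_c <- any(system$c > 0)
    for (kk in seq_along(times)) {
      dt <- times[kk] - tprev
      if (dt > 0) {
        unew <- step_expm(M, u, dt)
        if (some_c) {
          # integral of c_i u_i over the interval: c * M^-1 (u(t) - u(t0))
          w <- Matrix::solve(M, unew - u)
          ustar <- ustar + system$c * as.numeric(w)
        }
        u <- unew
      }
      out[kk, ] <- c(u, ustar)
      tprev <- times[kk]
    }
  } else {
    A <- transport_generator(system)
    state <- c(system$u0, system$ustar0)
    tprev <- 0
    for (kk in seq_along(times)) {
      dt <- times[kk] - tprev
      if (dt > 0) state <- step_expm(A, state, dt)
      out[kk, ] <- state
      tprev <- times[kk]
    }
  }
  if (any(out < -1e-10 * max(sum(system$u0), sum(system$ustar0), 1))) {
    stop("evolution produced significantly negative mass; solver misconfigured")
  }
  out[out < 0] <- 0
  traj <- tibble::tibble(
    time_s = rep(times, 2 * n),
    id = rep(rep(seq_len(n), each = length(times)), 2),
    pool = rep(c("bound", "detached"), each = length(times) * n),
    mass = c(out[, 1:n], out[, n + 1:n])
  )
  traj <- tidyr::pivot_wider(traj, names_from = "pool", values_from = "mass")
  traj <- dplyr::arrange(traj, .data$time_s, .data$id)
  structure(traj, class = c("cargo_trajectory", class(tibble::tibble())),
            system = system)
}

#' Steady state of a transport system
#'
#' For a trafficking-only system the steady state is the one-dimensional
#' nullspace of the generator: every parent/child pair satisfies
#' `u_parent / u_child = b / a`, so the state is built exactly by the ratio
#' recursion from the root and normalised to the initial total mass. For a
#' reversible system (`d > 0` wherever `c > 0`) the detached pool adds
#' `ustar_i = (c_i / d_i) u_i` compartment-wise.
#'
#' @param system a [transport_system()].
#' @return Tibble with `id`, `bound`, `detached`.
#' @export
steady_state <- function(system) {
  stopifnot(inherits(system, "transport_system"))
  tr <- system$tree
  n <- n_compartments(tr)
  if (any(system$c > 0 & system$d == 0)) {
    stop("irreversible detachment has no finite bound steady state; ",
         "use delivered_distribution()")
  }
  e <- system$edges
  if (any(e$a <= 0) || any(e$b <= 0)) {
    bad <- which(e$a <= 0 | e$b <= 0)[1]
    stop("zero trafficking rate on edge ", e$parent[bad], " -> ",
         e$child[bad], ": flow is disconnected")
  }
  logu <- numeric(n)
  ord <- tree_order(tr)
  em <- match(tr$id, e$child)
  idx <- match(seq_len(n), tr$id)
  for (i in ord) {
    p <- tr$parent[i]
    if (!is.na(p)) {
      # u_child = u_parent * a / b (log scale: strong biases span many decades)
      logu[i] <- logu[idx[p]] + log(e$a[em[i]]) - log(e$b[em[i]])
    }
  }
  u <- exp(logu - max(logu))
  ratio <- ifelse(system$d > 0, system$c / system$d, 0)
  total <- sum(system$u0) + sum(system$ustar0)
  scale <- total / sum(u * (1 + ratio))
  tibble::tibble(id = tr$id, bound = u * scale, detached = u * scale * ratio)
}

#' Delivered (absorbed) cargo distribution of an irreversible system
#'
#' For a system with detachment but no reattachment, all bound cargo is
#' eventually absorbed into the detached pool; the closed form is
#' `delivered_i = ustar0_i + c_i [-M^{-1} u0]_i` with `M` the bound-block
#' generator (trafficking minus detachment outflow).
#'
#' @param system a [transport_system()] with all `d = 0` and some `c > 0`.
#' @return Tibble with `id`, `delivered`; sums to the initial total mass.
#' @export
delivered_distribution <- function(system) {
  stopifnot(inherits(system, "transport_system"))
  if (any(system$d > 0)) stop("delivered_distribution requires d = 0")
  if (all(system$c == 0)) {
    stop("no absorbing compartment: mass cannot be delivered")
  }
  M <- bound_generator(system)
  w <- tryCatch(
    as.numeric(Matrix::solve(M, -system$u0)),
    error = function(e) stop("no absorbing compartment reachable: ",
                             conditionMessage(e))
  )
  delivered <- system$ustar0 + system$c * w
  delivered[delivered < 0 & delivered > -1e-10 * sum(system$u0)] <- 0
  tibble::tibble(id = system$tree$id, delivered = delivered)
}

#' Relaxation timescale of a trafficking-only system
#'
#' The convergence time to steady state is governed by the nonzero
#' eigenvalue of smallest magnitude of the trafficking generator:
#' `tau = 1 / |lambda_2|`. All eigenvalues are checked to be nonpositive
#' (Gershgorin/stability).
#'
#' @param system a [transport_system()] (its trafficking part is used).
#' @return Timescale in seconds.
#' @export
convergence_timescale <- function(system) {
  stopifnot(inherits(system, "transport_system"))
  A <- bound_generator(system, with_detachment = FALSE)
  ev <- eigen(as.matrix(A), only.values = TRUE)$values
  re <- Re(ev)
  tol <- 1e-10 * max(abs(re), 1)
  if (any(re > tol)) stop("generator has a positive eigenvalue; unstable system")
  nz <- re[abs(re) > tol]
  if (length(nz) != length(re) - 1) {
    stop("trafficking graph is disconnected (repeated zero eigenvalue)")
  }
  1 / min(abs(nz))
}

#' Per-compartment first-passage delays
#'
#' The earliest trajectory time at which each compartment's cargo exceeds
#' a threshold.
#'
#' @param trajectory a `cargo_trajectory` from [evolve_transport()].
#' @param threshold mass threshold (> 0).
#' @param pool `"bound"`, `"detached"` or `"total"`.
#' @return Tibble with `id`, `delay_s` (`Inf` if never reached).
#' @export
compartment_delays <- function(trajectory, threshold,
                               pool = c("bound", "detached", "total")) {
  pool <- match.arg(pool)
  if (threshold <= 0) stop("threshold must be positive")
  df <- tibble::as_tibble(trajectory)
  df$value <- switch(pool,
    bound = df$bound, detached = df$detached,
    total = df$bound + df$detached
  )
  df |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(
      delay_s = if (any(.data$value >= threshold)) {
        min(.data$time_s[.data$value >= threshold])
      } else Inf,
      .groups = "drop"
    )
}
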