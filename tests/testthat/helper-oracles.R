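# Independent oracles and fixture builders used across the suite.

# Explicit small-step RK4 integration of du/dt = A u, independent of the
# package's matrix-exponential path.
rk4_evolve <- function(A, u0, times, dt_max = NULL) {
  A <- as.matrix(A)
  if (is.null(dt_max)) dt_max <- 0.02 / max(abs(diag(A)), 1e-12)
  state <- u0
  tprev <- 0
  out <- matrix(0, length(times), length(u0))
  f <- function(u) as.numeric(A %*% u)
  for (i in seq_along(times)) {
    span <- times[i] - tprev
    nstep <- max(1L, ceiling(span / dt_max))
    h <- span / nstep
    for (s in seq_len(nstep)) {
      k1 <- f(state)
      k2 <- f(state + h / 2 * k1)
      k3 <- f(state + h / 2 * k2)
      k4 <- f(state + h * k3)
      state <- state + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    out[i, ] <- state
    tprev <- times[i]
  }
  out
}

# random connected tree on n compartments (parents drawn among earlier ids)
random_tree <- function(n, seed) {
  withr::with_seed(seed, {
    parent <- c(NA_integer_, vapply(2:n, function(i) {
      sample.int(i - 1L, 1L)
    }, integer(1)))
    compartment_tree(data.frame(
      id = seq_len(n), parent = parent,
      length = stats::runif(n, 0.5, 2)
    ))
  })
}

random_system <- function(n, seed, c_max = 0, d_max = 0) {
  tree <- random_tree(n, seed)
  withr::with_seed(seed + 1000L, {
    ne <- n - 1L
    transport_system(
      tree,
      a = stats::runif(ne, 0.2, 2), b = stats::runif(ne, 0.2, 2),
      c = if (c_max > 0) stats::runif(n, 0.1, 1) * c_max else 0,
      d = if (d_max > 0) stats::runif(n, 0.1, 1) * d_max else 0,
      u0 = stats::runif(n)
    )
  })
}

# branched neuron fixture: basal subtree, apical trunk, two apical branches
branched_fixture <- function() {
  parent <- c(NA, 1, 2:20,  # basal 2..21
              1, 22:40,     # apical trunk 22..41
              41, 42:60,    # apical branch A 42..61
              41, 62:80)    # apical branch B 62..81
  compartment_tree(data.frame(id = 1:81, parent = parent, length = 1))
}

# synthetic SWC text: a stellate cell with n_dend straight dendrites of
# n_samp unit-length samples each (plus one soma sample)
synthetic_swc <- function(n_dend, n_samp, step = 1) {
  lines <- c("# synthetic stellate morphology", "1 1 0 0 0 2 -1")
  id <- 1L
  for (d in seq_len(n_dend)) {
    ang <- 2 * pi * d / n_dend
    parent <- 1L
    for (s in seq_len(n_samp)) {
      id <- id + 1L
      lines <- c(lines, sprintf("%d 3 %.6f %.6f 0 0.5 %d",
                                id, s * step * cos(ang), s * step * sin(ang),
                                parent))
      parent <- id
    }
  }
  lines
}

# synthetic SWC with nested binary branching (an elaborately branched cell)
synthetic_branched_swc <- function(depth, seg_samples, step = 2) {
  lines <- c("# synthetic branched morphology", "1 1 0 0 0 2 -1")
  id <- 1L
  env <- environment()
  grow <- function(parent, x, y, ang, level) {
    for (s in seq_len(seg_samples)) {
      assign("id", get("id", env) + 1L, env)
      x <- x + step * cos(ang); y <- y + step * sin(ang)
      assign("lines", c(get("lines", env),
                        sprintf("%d 3 %.6f %.6f 0 0.4 %d", get("id", env),
                                x, y, parent)), env)
      parent <- get("id", env)
    }
    if (level > 0) {
      grow(parent, x, y, ang + 0.5, level - 1)
      grow(parent, x, y, ang - 0.5, level - 1)
    }
  }
  grow(1L, 0, 0, pi / 2, depth)
  get("lines", env)
}

write_swc <- function(lines) {
  path <- withr::local_tempfile(fileext = ".swc",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

expect_valid_tree <- function(tree) {
  expect_s3_class(tree, "compartment_tree")
  expect_equal(sum(is.na(tree$parent)), 1L)
  expect_equal(sum(!is.na(tree$parent)), nrow(tree) - 1L)
  expect_true(all(tree$length > 0))
  # path distances nondecreasing from root to tips
  pd_parent <- tree$path_dist[tree$parent[!is.na(tree$parent)]]
  expect_true(all(tree$path_dist[!is.na(tree$parent)] >= pd_parent))
}
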