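#' Compartment trees
#'
#' A compartment tree is a tibble with one row per compartment and columns
#' `id` (integer, 1..N, soma/root first), `parent` (integer, `NA` for the
#' root), `length` (um, strictly positive), `path_dist` (um, path distance
#' from the root to the compartment midpoint-free distal node) and optional
#' 3D columns `x`, `y`, `z`, `radius` (um). Edges are always oriented
#' parent (closer to the soma) to child (closer to the periphery).
#'
#' @param compartments data frame with at least `id`, `parent`, `length`.
#' @return A `compartment_tree` tibble.
#' @export
compartment_tree <- function(compartments) {
  tr <- tibble::as_tibble(compartments)
  stopifnot(all(c("id", "parent", "length") %in% names(tr)))
  tr$id <- as.integer(tr$id)
  tr$parent <- as.integer(tr$parent)
  if (!"path_dist" %in% names(tr)) {
    tr$path_dist <- rep(NA_real_, nrow(tr))
  }
  tr <- structure(tr, class = c("compartment_tree", class(tibble::tibble())))
  tr$path_dist <- compute_path_dist(tr)
  validate_compartment_tree(tr)
  tr
}

compute_path_dist <- function(tree) {
  pd <- numeric(nrow(tree))
  ord <- tree_order(tree)
  idx <- match(seq_len(nrow(tree)), tree$id)
  for (i in ord) {
    p <- tree$parent[i]
    pd[i] <- if (is.na(p)) 0 else pd[idx[p]] + tree$length[i]
  }
  pd
}

#' @keywords internal
validate_compartment_tree <- function(tree) {
  n <- nrow(tree)
  if (n < 1) stop("tree has no compartments")
  if (anyDuplicated(tree$id)) stop("duplicate compartment ids")
  if (!identical(as.integer(tree$id), seq_len(n))) {
    stop("ids must be 1..N in row order")
  }
  roots <- which(is.na(tree$parent))
  if (length(roots) != 1) {
    stop("tree must have exactly one root, found ", length(roots))
  }
  if (any(!is.na(tree$parent) & !(tree$parent %in% tree$id))) {
    stop("parent id not present in tree")
  }
  if (any(tree$length <= 0)) stop("compartment lengths must be strictly positive")
  # connectivity and acyclicity: every compartment must reach the root
  idx <- match(seq_len(n), tree$id)
  for (i in seq_len(n)) {
    seen <- 0L
    j <- i
    while (!is.na(tree$parent[j])) {
      j <- idx[tree$parent[j]]
      seen <- seen + 1L
      if (seen > n) stop("cycle detected in tree")
    }
  }
  if (sum(!is.na(tree$parent)) != n - 1) stop("edge count must be N - 1")
  invisible(tree)
}

# depth-first order with parents before children (row indices)
tree_order <- function(tree) {
  n <- nrow(tree)
  idx <- match(seq_len(n), tree$id)
  kids <- split(seq_len(n), factor(tree$parent, levels = tree$id))
  root <- which(is.na(tree$parent))
  ord <- integer(0)
  stack <- root
  while (length(stack)) {
    i <- stack[[1]]
    stack <- stack[-1]
    ord <- c(ord, i)
    ch <- kids[[as.character(tree$id[i])]]
    if (length(ch)) stack <- c(ch, stack)
  }
  ord
}

#' Number of compartments in a tree
#' @param tree a [compartment_tree()].
#' @return Integer count.
#' @export
n_compartments <- function(tree) nrow(tree)

#' Edge table of a compartment tree
#'
#' One row per parent->child edge with the midpoint spacing `delta`
#' (um, the distance between the midpoints of the two compartments,
#' `(length_parent + length_child) / 2`).
#'
#' @param tree a [compartment_tree()].
#' @return A tibble with columns `parent`, `child`, `delta`.
#' @export
tree_edges <- function(tree) {
  child <- tree$id[!is.na(tree$parent)]
  parent <- tree$parent[!is.na(tree$parent)]
  lp <- tree$length[match(parent, tree$id)]
  lc <- tree$length[match(child, tree$id)]
  tibble::tibble(parent = parent, child = child, delta = (lp + lc) / 2)
}

#' @export
print.compartment_tree <- function(x, ...) {
  cat(sprintf(
    "<compartment_tree> %d compartments, %d edges, total cable %.6g um\n",
    nrow(x), sum(!is.na(x$parent)), sum(x$length)
  ))
  NextMethod()
}

#' Build an unbranched cable
#'
#' An unbranched chain of `n_compartments` equal compartments rooted at the
#' soma end (compartment 1).
#'
#' @param n_compartments number of compartments (>= 2).
#' @param total_length total cable length in um.
#' @return A [compartment_tree()].
#' @examples
#' build_cable(100, 800)  # the 800 um neurite, 8 um compartments
#' @export
build_cable <- function(n_compartments, total_length) {
  if (n_compartments < 2) stop("a cable needs at least 2 compartments")
  if (total_length <= 0) stop("total_length must be positive")
  n <- as.integer(n_compartments)
  compartment_tree(tibble::tibble(
    id = seq_len(n),
    parent = c(NA_integer_, seq_len(n - 1L)),
    length = rep(total_length / n, n)
  ))
}

#' Read a neuronal morphology from an SWC file
#'
#' Standard 7-column SWC (`id type x y z radius parent`). All soma samples
#' (type 1) are collapsed into a single root compartment placed at the soma
#' centroid; every other retained sample becomes one compartment whose
#' length is the Euclidean distance to its parent sample.
#'
#' @param path path to the SWC file.
#' @param types optional integer vector of SWC type codes to retain
#'   (besides the soma); default keeps everything.
#' @param soma_length length (um) assigned to the collapsed root
#'   compartment; defaults to the mean soma radius (or 1 um if radii are
#'   unusable).
#' @return A [compartment_tree()].
#' @export
read_swc <- function(path, types = NULL, soma_length = NULL) {
  if (!file.exists(path)) stop("SWC file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("SWC file is empty: ", path)
  fields <- strsplit(lines, "\\s+")
  if (any(lengths(fields) != 7)) {
    stop("malformed SWC line (expected 7 columns) in ", path)
  }
  m <- matrix(as.numeric(unlist(fields)), ncol = 7, byrow = TRUE)
  colnames(m) <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (anyNA(m)) stop("non-numeric field in SWC file ", path)
  swc <- tibble::as_tibble(m)
  if (anyDuplicated(swc$id)) stop("duplicate sample id in SWC file ", path)
  if (any(swc$radius <= 0)) {
    warning("non-positive radius in SWC file ", path)
  }
  # parents must be previously defined (or -1)
  seen <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(swc))) {
    p <- swc$parent[r]
    if (p != -1 && is.null(seen[[as.character(p)]])) {
      stop("SWC parent id ", p, " not previously defined (sample ",
           swc$id[r], ")")
    }
    seen[[as.character(swc$id[r])]] <- TRUE
  }
  soma <- swc[swc$type == 1, , drop = FALSE]
  rest <- swc[swc$type != 1, , drop = FALSE]
  if (!is.null(types)) rest <- rest[rest$type %in% types, , drop = FALSE]
  # drop samples whose ancestry was filtered out
  keep_ids <- c(soma$id, rest$id)
  repeat {
    ok <- rest$parent %in% keep_ids | rest$parent == -1
    if (all(ok)) break
    rest <- rest[ok, , drop = FALSE]
    keep_ids <- c(soma$id, rest$id)
  }
  if (nrow(soma) == 0) {
    # no soma samples: the first sample with parent -1 is the root
    root_rows <- which(rest$parent == -1)
    if (length(root_rows) != 1) {
      stop("SWC file has ", length(root_rows), " roots; expected one")
    }
  } else if (any(soma$parent != -1 & !(soma$parent %in% soma$id))) {
    stop("soma sample with non-soma parent in ", path)
  }
  if (nrow(soma) > 0) {
    cx <- mean(soma$x); cy <- mean(soma$y); cz <- mean(soma$z)
    cr <- mean(soma$radius)
    extra_roots <- rest$id[rest$parent == -1]
    if (length(extra_roots) > 0) {
      stop("multiple roots in SWC file: soma plus sample(s) ",
           paste(extra_roots, collapse = ", "))
    }
    if (is.null(soma_length)) soma_length <- if (cr > 0) cr else 1
    root <- tibble::tibble(
      id = 1L, parent = NA_integer_, length = soma_length,
      x = cx, y = cy, z = cz, radius = cr
    )
    new_id <- stats::setNames(seq_len(nrow(rest)) + 1L, rest$id)
    parent_of <- function(p) {
      if (p %in% soma$id) 1L else unname(new_id[as.character(p)])
    }
    comp <- tibble::tibble(
      id = unname(new_id[as.character(rest$id)]),
      parent = vapply(rest$parent, parent_of, integer(1)),
      x = rest$x, y = rest$y, z = rest$z, radius = rest$radius
    )
    px <- ifelse(comp$parent == 1L, cx, rest$x[match(comp$parent, comp$id)])
    py <- ifelse(comp$parent == 1L, cy, rest$y[match(comp$parent, comp$id)])
    pz <- ifelse(comp$parent == 1L, cz, rest$z[match(comp$parent, comp$id)])
    comp$length <- sqrt((comp$x - px)^2 + (comp$y - py)^2 + (comp$z - pz)^2)
    out <- dplyr::bind_rows(root, comp)
  } else {
    root_id <- rest$id[rest$parent == -1]
    ord <- order(rest$parent != -1)  # root first, original order otherwise
    rest <- rest[ord, , drop = FALSE]
    new_id <- stats::setNames(seq_len(nrow(rest)), rest$id)
    out <- tibble::tibble(
      id = unname(new_id[as.character(rest$id)]),
      parent = ifelse(rest$parent == -1, NA_integer_,
                      unname(new_id[as.character(rest$parent)])),
      x = rest$x, y = rest$y, z = rest$z, radius = rest$radius
    )
    px <- out$x[match(out$parent, out$id)]
    py <- out$y[match(out$parent, out$id)]
    pz <- out$z[match(out$parent, out$id)]
    out$length <- sqrt((out$x - px)^2 + (out$y - py)^2 + (out$z - pz)^2)
    out$length[is.na(out$parent)] <- if (mean(rest$radius) > 0) mean(rest$radius) else 1
  }
  zero <- !is.na(out$parent) & out$length <= 0
  if (any(zero)) {
    warning(sum(zero), " zero-length SWC segment(s) set to 1e-6 um")
    out$length[zero] <- 1e-6
  }
  compartment_tree(out)
}

#' Resample a tree to a target compartment spacing
#'
#' Each maximal unbranched section is re-divided into equal compartments of
#' approximately `target_spacing` um. Branch points are preserved and the
#' total length of every section is conserved exactly.
#'
#' @param tree a [compartment_tree()].
#' @param target_spacing desired compartment length in um.
#' @return A [compartment_tree()].
#' @export
resample_tree <- function(tree, target_spacing) {
  if (target_spacing <= 0) stop("target_spacing must be positive")
  n <- nrow(tree)
  idx <- match(seq_len(n), tree$id)
  n_children <- tabulate(tree$parent[!is.na(tree$parent)], nbins = n)
  root_row <- which(is.na(tree$parent))
  # section break at: root, branch points (>=2 children), and tips
  # walk sections from each section-start child
  is_break <- rep(FALSE, n)
  is_break[root_row] <- TRUE
  is_break[n_children >= 2] <- TRUE
  kids <- split(seq_len(n), factor(tree$parent, levels = tree$id))
  out_rows <- list()
  out_rows[[1]] <- tibble::tibble(id = 1L, parent = NA_integer_,
                                  length = tree$length[root_row])
  # map original row -> new id of its distal node (for attaching children)
  new_of <- integer(n)
  new_of[root_row] <- 1L
  next_id <- 2L
  # process sections in an order where the parent's section is done first
  ord <- tree_order(tree)
  for (i in ord) {
    if (is.na(tree$parent[i])) next
    pr <- idx[tree$parent[i]]
    if (!is_break[pr]) next  # not a section start
    # collect the section: follow single-child runs
    sec <- i
    j <- i
    while (!is_break[j] && length(kids[[as.character(tree$id[j])]]) == 1) {
      j <- kids[[as.character(tree$id[j])]]
      sec <- c(sec, j)
    }
    sec_len <- sum(tree$length[sec])
    m <- max(1L, as.integer(round(sec_len / target_spacing)))
    if (m == 1L && sec_len < target_spacing / 2) {
      warning("section shorter than target_spacing kept as one compartment")
    }
    ids <- seq.int(next_id, next_id + m - 1L)
    next_id <- next_id + m
    out_rows[[length(out_rows) + 1L]] <- tibble::tibble(
      id = ids,
      parent = c(new_of[pr], ids[-m]),
      length = rep(sec_len / m, m)
    )
    new_of[sec[length(sec)]] <- ids[m]
    is_break[sec[length(sec)]] <- TRUE  # ensure children attach here
  }
  compartment_tree(dplyr::bind_rows(out_rows))
}
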