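#' Morphology trees of cylindrical sections
#'
#' A `morph_tree` represents a branched neuronal morphology as a tree of
#' cylindrical sections, one section per SWC node. Each node stores the SWC
#' index, its parent, the SWC type (1 soma, 2 axon, 3 basal, 4 apical), the
#' xyz coordinate of its distal point (um), its radius (um) and its length
#' (um; the distance from the parent's coordinate). The root node is treated
#' as an iso-potential spherical soma of its radius (membrane area
#' `4*pi*R^2`); all other nodes are cylinders.
#'
#' Locations on the tree are `(node, x)` pairs with `x` in `[0, 1]` the
#' normalized arc position along the node's cylinder (0 proximal, 1 distal).
#' `(parent, x = 1)` and `(child, x = 0)` denote the same physical point and
#' are canonicalized to the parent representation.
#'
#' @name morph_tree
NULL

new_morph_tree <- function(nodes, soma_point = FALSE) {
  stopifnot(is.data.frame(nodes))
  req <- c("index", "parent", "type", "x", "y", "z", "radius", "length")
  stopifnot(all(req %in% names(nodes)))
  tree <- structure(
    list(nodes = nodes, phys = NULL, comp = NULL, soma_point = soma_point),
    class = "morph_tree"
  )
  tree <- .reindex_tree(tree)
  validate_morph_tree(tree)
  tree
}

# depth-first node order, id lookup, children lists
.reindex_tree <- function(tree) {
  nd <- tree$nodes
  root <- nd$index[is.na(nd$parent)]
  if (length(root) != 1L)
    stop("morphology must have exactly one root node", call. = FALSE)
  children <- split(nd$index, factor(nd$parent, levels = nd$index))
  order_ids <- integer(nrow(nd))
  stack <- root
  k <- 0L
  while (length(stack)) {
    id <- stack[[1L]]; stack <- stack[-1L]
    k <- k + 1L
    order_ids[k] <- id
    ch <- children[[as.character(id)]]
    if (length(ch)) stack <- c(sort(ch), stack)
  }
  if (k != nrow(nd)) stop("disconnected nodes in morphology", call. = FALSE)
  nd <- nd[match(order_ids, nd$index), , drop = FALSE]
  rownames(nd) <- NULL
  tree$nodes <- nd
  tree$root <- root
  tree$id2row <- stats::setNames(seq_len(nrow(nd)), nd$index)
  tree$children <- lapply(nd$index, function(id) {
    ch <- nd$index[!is.na(nd$parent) & nd$parent == id]
    sort(ch)
  })
  names(tree$children) <- nd$index
  # distance from soma of each node's distal point
  dd <- numeric(nrow(nd))
  for (i in seq_len(nrow(nd))) {
    p <- nd$parent[i]
    dd[i] <- nd$length[i] + if (is.na(p)) 0 else dd[tree$id2row[[as.character(p)]]]
  }
  tree$dist_distal <- stats::setNames(dd, nd$index)
  tree
}

validate_morph_tree <- function(tree) {
  nd <- tree$nodes
  if (sum(is.na(nd$parent)) != 1L)
    stop("morphology must have exactly one root node", call. = FALSE)
  if (anyDuplicated(nd$index))
    stop("duplicate node index in morphology", call. = FALSE)
  if (any(nd$radius <= 0))
    stop("non-positive radius in morphology", call. = FALSE)
  nonroot <- !is.na(nd$parent)
  if (any(nd$length[nonroot] <= 0))
    stop("zero-length non-root section after construction", call. = FALSE)
  bad <- nonroot & !(nd$parent %in% nd$index)
  if (any(bad))
    stop("parent id not present in morphology: ",
         paste(nd$parent[bad], collapse = ", "), call. = FALSE)
  invisible(tree)
}

#' @export
print.morph_tree <- function(x, ...) {
  nd <- x$nodes
  cat(sprintf("<morph_tree> %d nodes, root id %d, total length %.1f um\n",
              nrow(nd), x$root, sum(nd$length)))
  if (!is.null(x$phys)) cat("  physiology: set\n")
  if (!is.null(x$comp)) cat(sprintf("  computational tree: %d nodes\n",
                                    nrow(x$comp$tree$nodes)))
  invisible(x)
}

.node_row <- function(tree, id) {
  r <- tree$id2row[as.character(id)]
  if (any(is.na(r))) stop("invalid node index: ",
                          paste(id[is.na(r)], collapse = ", "), call. = FALSE)
  unname(r)
}

#' Read an SWC morphology file
#'
#' Parses the standard 7-column SWC dialect (index, type, x, y, z, radius,
#' parent; '#' comments; parent of the root is -1). Each SWC row becomes one
#' cylindrical section whose length is the Euclidean distance to the parent
#' coordinate; radii are taken verbatim (cylinders, not truncated cones).
#' Multi-point somas (e.g. the 3-point convention) are collapsed, with a
#' warning, to a single sphere of equivalent membrane area; zero-length
#' segments (duplicate coordinates) are merged into their parent with a
#' warning.
#'
#' @param path path to an SWC file.
#' @return a [morph_tree].
#' @export
read_swc <- function(path) {
  raw <- utils::read.table(path, comment.char = "#",
                           col.names = c("index", "type", "x", "y", "z",
                                         "radius", "parent"))
  if (anyDuplicated(raw$index))
    stop("duplicate index in SWC file", call. = FALSE)
  if (any(raw$radius <= 0))
    stop("non-positive radius in SWC file", call. = FALSE)
  root <- raw$index[raw$parent == -1]
  if (length(root) != 1L)
    stop("SWC file must contain exactly one root (parent = -1)", call. = FALSE)
  missing_par <- raw$parent != -1 & !(raw$parent %in% raw$index)
  if (any(missing_par))
    stop("SWC parent id does not exist: ",
         paste(unique(raw$parent[missing_par]), collapse = ", "), call. = FALSE)

  nd <- data.frame(index = raw$index, parent = ifelse(raw$parent == -1, NA,
                                                      raw$parent),
                   type = raw$type, x = raw$x, y = raw$y, z = raw$z,
                   radius = raw$radius)
  prow <- match(nd$parent, nd$index)
  nd$length <- ifelse(is.na(nd$parent), 0,
                      sqrt((nd$x - nd$x[prow])^2 + (nd$y - nd$y[prow])^2 +
                           (nd$z - nd$z[prow])^2))

  # collapse multi-point somas to one equivalent-area sphere
  soma_extra <- nd$index[nd$type == 1 & nd$index != root]
  if (length(soma_extra)) {
    warning("multi-point soma collapsed to a single equivalent-area sphere",
            call. = FALSE)
    keep <- nd[nd$type == 1, , drop = FALSE]
    area <- sum(2 * pi * keep$radius * keep$length)
    if (area <= 0) area <- 4 * pi * nd$radius[nd$index == root]^2
    r_eq <- sqrt(area / (4 * pi))
    reparent <- nd$parent %in% soma_extra & !(nd$index %in% soma_extra)
    nd$parent[reparent] <- root
    # lengths of reparented nodes: distance to the root coordinate
    rrow <- which(nd$index == root)
    idx <- which(reparent)
    nd$length[idx] <- sqrt((nd$x[idx] - nd$x[rrow])^2 +
                           (nd$y[idx] - nd$y[rrow])^2 +
                           (nd$z[idx] - nd$z[rrow])^2)
    nd <- nd[!(nd$index %in% soma_extra), , drop = FALSE]
    nd$radius[nd$index == root] <- r_eq
  }

  # merge zero-length non-root segments into their parent
  repeat {
    zl <- which(!is.na(nd$parent) & nd$length == 0)
    if (!length(zl)) break
    warning("zero-length SWC segment merged into parent", call. = FALSE)
    id <- nd$index[zl[1L]]
    par <- nd$parent[zl[1L]]
    nd$parent[!is.na(nd$parent) & nd$parent == id] <- par
    nd <- nd[nd$index != id, , drop = FALSE]
  }
  new_morph_tree(nd)
}

#' Write a morphology to an SWC file
#'
#' Inverse of [read_swc()]: `read_swc(write_swc(tree, path))` reproduces the
#' node set, topology, radii and coordinates.
#'
#' @param tree a [morph_tree].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(tree, path) {
  validate_morph_tree(tree)
  nd <- tree$nodes
  out <- data.frame(index = nd$index, type = nd$type,
                    x = nd$x, y = nd$y, z = nd$z, radius = nd$radius,
                    parent = ifelse(is.na(nd$parent), -1L, nd$parent))
  lines <- sprintf("%d %d %.9g %.9g %.9g %.9g %d", out$index, out$type,
                   out$x, out$y, out$z, out$radius, out$parent)
  writeLines(c("# SWC written by dendrocable", lines), path)
  invisible(path)
}

# ---- locations -------------------------------------------------------------

#' Normalize and canonicalize locations on a tree
#'
#' Accepts a data.frame with columns `node` and `x`, a single `(node, x)`
#' pair (numeric length-2 vector or list), or a list of such pairs. All
#' locations are canonicalized: `x = 0` on a non-root node becomes
#' `(parent, x = 1)`, and any location on the root becomes `(root, 0)`.
#'
#' @param tree a [morph_tree].
#' @param locs locations in any accepted form.
#' @return data.frame with columns `node` (integer) and `x` (double).
#' @export
as_locations <- function(tree, locs) {
  if (is.data.frame(locs)) {
    df <- data.frame(node = as.integer(locs$node), x = as.numeric(locs$x))
  } else if (is.numeric(locs) && length(locs) == 2L) {
    df <- data.frame(node = as.integer(locs[[1L]]), x = as.numeric(locs[[2L]]))
  } else if (is.list(locs) && !is.null(locs$node)) {
    df <- data.frame(node = as.integer(locs$node), x = as.numeric(locs$x))
  } else if (is.list(locs)) {
    df <- do.call(rbind, lapply(locs, function(l) {
      if (is.list(l) && !is.null(l$node))
        data.frame(node = as.integer(l$node), x = as.numeric(l$x))
      else data.frame(node = as.integer(l[[1L]]), x = as.numeric(l[[2L]]))
    }))
  } else stop("cannot interpret locations", call. = FALSE)
  if (any(df$x < 0 | df$x > 1)) stop("location x outside [0, 1]", call. = FALSE)
  .node_row(tree, df$node)  # validates indices
  canonical_loc(tree, df)
}

#' @rdname as_locations
#' @export
canonical_loc <- function(tree, locs) {
  df <- if (is.data.frame(locs)) locs else as_locations(tree, locs)
  for (i in seq_len(nrow(df))) {
    while (df$x[i] == 0 && df$node[i] != tree$root) {
      row <- .node_row(tree, df$node[i])
      df$node[i] <- tree$nodes$parent[row]
      df$x[i] <- 1
    }
    if (df$node[i] == tree$root) df$x[i] <- 0
  }
  df
}

#' Arc distance of locations from the soma
#'
#' @param tree a [morph_tree].
#' @param locs locations (see [as_locations()]).
#' @return numeric vector of distances, um.
#' @export
soma_distance <- function(tree, locs) {
  df <- as_locations(tree, locs)
  rows <- .node_row(tree, df$node)
  unname(tree$dist_distal[rows] - (1 - df$x) * tree$nodes$length[rows])
}

.root_path <- function(tree, id) {
  # node ids from root to id, inclusive
  path <- integer(0)
  cur <- id
  while (!is.na(cur)) {
    path <- c(cur, path)
    cur <- tree$nodes$parent[.node_row(tree, cur)]
  }
  path
}

#' Arc length of the tree path between two locations
#'
#' Symmetric, zero for identical locations.
#'
#' @param tree a [morph_tree].
#' @param loc_a,loc_b single locations.
#' @return path length, um.
#' @export
path_length <- function(tree, loc_a, loc_b) {
  a <- as_locations(tree, loc_a); b <- as_locations(tree, loc_b)
  stopifnot(nrow(a) == 1L, nrow(b) == 1L)
  da <- soma_distance(tree, a); db <- soma_distance(tree, b)
  pa <- .root_path(tree, a$node); pb <- .root_path(tree, b$node)
  ncom <- max(which(pa[seq_len(min(length(pa), length(pb)))] ==
                    pb[seq_len(min(length(pa), length(pb)))]))
  lca <- pa[ncom]
  if (lca == a$node || lca == b$node) {
    unname(abs(da - db))
  } else {
    dj <- tree$dist_distal[[as.character(lca)]]
    unname((da - dj) + (db - dj))
  }
}

#' Distribute locations at uniform arc-length spacing
#'
#' Places locations along every branch at arc-length multiples of `spacing`
#' measured from the soma surface; the soma point itself is excluded.
#' Locations falling exactly on a branch point use the parent node's
#' `x = 1` representation. Output order is depth-first and deterministic.
#'
#' @param tree a [morph_tree].
#' @param spacing arc-length spacing, um (> 0).
#' @param node_filter optional predicate taking a one-row node data.frame,
#'   or an integer vector of SWC types to keep.
#' @return data.frame of locations.
#' @export
distribute_locations_uniform <- function(tree, spacing, node_filter = NULL) {
  if (!is.numeric(spacing) || spacing <= 0)
    stop("spacing must be > 0", call. = FALSE)
  keep <- .filter_nodes(tree, node_filter)
  nd <- tree$nodes
  out <- list()
  for (i in seq_len(nrow(nd))) {     # depth-first row order
    if (!keep[i] || is.na(nd$parent[i])) next
    d1 <- tree$dist_distal[i]
    d0 <- d1 - nd$length[i]
    ms <- spacing * seq(floor(d0 / spacing) + 1L, floor(d1 / spacing))
    ms <- ms[ms > d0 & ms <= d1 & ms > 0]
    if (length(ms))
      out[[length(out) + 1L]] <- data.frame(node = nd$index[i],
                                            x = (ms - d0) / nd$length[i])
  }
  if (!length(out)) return(data.frame(node = integer(0), x = numeric(0)))
  do.call(rbind, out)
}

#' Distribute locations randomly, weighted by membrane area
#'
#' Samples `n` independent locations with probability density proportional
#' to membrane area per unit length (`2*pi*R`), i.e. uniform per unit area.
#'
#' @param tree a [morph_tree].
#' @param n number of locations (>= 0).
#' @param seed integer seed; the global RNG state is restored on exit.
#' @param node_filter see [distribute_locations_uniform()].
#' @return data.frame of locations.
#' @export
distribute_locations_random <- function(tree, n, seed = 1L,
                                        node_filter = NULL) {
  if (n < 0) stop("n must be >= 0", call. = FALSE)
  if (n == 0) return(data.frame(node = integer(0), x = numeric(0)))
  keep <- .filter_nodes(tree, node_filter)
  nd <- tree$nodes
  cand <- which(keep & !is.na(nd$parent))
  w <- 2 * pi * nd$radius[cand] * nd$length[cand]
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  rows <- sample(cand, n, replace = TRUE, prob = w)
  data.frame(node = nd$index[rows], x = stats::runif(n))
}

.filter_nodes <- function(tree, node_filter) {
  nd <- tree$nodes
  if (is.null(node_filter)) rep(TRUE, nrow(nd))
  else if (is.function(node_filter))
    vapply(seq_len(nrow(nd)),
           function(i) isTRUE(node_filter(nd[i, , drop = FALSE])), logical(1))
  else nd$type %in% node_filter
}

#' Minimal spanning subtree of a set of locations
#'
#' Returns the union of the tree paths between all given locations and the
#' root, as ordered (depth-first) segments `(node, x0, x1)` covering the
#' used portion of each node.
#'
#' @param tree a [morph_tree].
#' @param locs one or more locations.
#' @return data.frame with columns `node`, `x0`, `x1`.
#' @export
minimal_spanning_subtree <- function(tree, locs) {
  df <- as_locations(tree, locs)
  if (!nrow(df)) stop("need at least one location", call. = FALSE)
  xmax <- list()
  for (i in seq_len(nrow(df))) {
    path <- .root_path(tree, df$node[i])
    for (id in path) {
      key <- as.character(id)
      xm <- if (id == df$node[i]) df$x[i] else 1
      xmax[[key]] <- max(xmax[[key]] %||% 0, xm)
    }
  }
  ids <- tree$nodes$index[tree$nodes$index %in% as.integer(names(xmax))]
  data.frame(node = ids, x0 = 0,
             x1 = vapply(as.character(ids), function(k) xmax[[k]], numeric(1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Membrane surface area of the tree
#'
#' Sphere for the root soma (unless the tree is flagged as having a point
#' root), cylinder side areas elsewhere.
#'
#' @param tree a [morph_tree].
#' @return total area, um^2.
#' @export
membrane_area <- function(tree) {
  nd <- tree$nodes
  soma <- if (isTRUE(tree$soma_point)) 0 else 4 * pi * nd$radius[1L]^2
  soma + sum(2 * pi * nd$radius[-1L] * nd$length[-1L])
}
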