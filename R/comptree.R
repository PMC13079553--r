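#' Build the coarse-grained computational tree
#'
#' Merges maximal runs of non-branching nodes whose radius and every
#' physiological parameter agree within relative tolerance `rtol` into
#' single cylinders of summed length. Branch points and parameter
#' discontinuities are never merged across. The result is stored on the
#' tree together with bidirectional coordinate maps, so that user-facing
#' locations always reference the original tree; analytical engines use the
#' merged cylinders transparently. Any later physiology mutation discards
#' the computational tree.
#'
#' Must be called after model construction: it errors when physiology has
#' not been set.
#'
#' @param tree a [morph_tree] with physiology.
#' @param rtol relative tolerance for parameter comparisons.
#' @return the tree, with the computational tree attached (`tree$comp`).
#' @export
build_computational_tree <- function(tree, rtol = 1e-8) {
  if (is.null(tree$phys))
    stop("physiology has not been set; build the model first", call. = FALSE)
  nd <- tree$nodes
  pm <- .phys_matrix(tree)
  n <- nrow(nd)
  same <- function(i, j) {     # rows of nd/pm
    a <- pm[i, ]; b <- pm[j, ]
    both_na <- is.na(a) & is.na(b)
    a[both_na] <- 0; b[both_na] <- 0
    if (anyNA(a) || anyNA(b)) return(FALSE)
    all(abs(a - b) <= rtol * pmax(abs(a), abs(b), 1e-300))
  }
  # head of run: parent is root, parent branches, or params differ
  head_of_run <- logical(n)
  for (i in seq_len(n)) {
    p <- nd$parent[i]
    if (is.na(p)) { head_of_run[i] <- TRUE; next }
    prow <- .node_row(tree, p)
    head_of_run[i] <- is.na(nd$parent[prow]) ||
      length(tree$children[[prow]]) != 1L || !same(i, prow)
  }
  run_of <- integer(n)  # row of run head for each node
  for (i in seq_len(n)) {   # depth-first order: parent precedes child
    p <- nd$parent[i]
    run_of[i] <- if (head_of_run[i]) i else run_of[.node_row(tree, p)]
  }
  heads <- which(head_of_run)
  runs <- lapply(heads, function(h) which(run_of == h))
  comp_id <- vapply(runs, function(rws) nd$index[max(rws)], numeric(1))
  comp_of_row <- integer(n)
  for (k in seq_along(runs)) comp_of_row[runs[[k]]] <- k

  cn <- data.frame(
    index = as.integer(comp_id),
    parent = vapply(seq_along(runs), function(k) {
      h <- heads[k]
      p <- nd$parent[h]
      if (is.na(p)) NA_integer_
      else as.integer(comp_id[comp_of_row[.node_row(tree, p)]])
    }, integer(1)),
    type = nd$type[heads],
    x = nd$x[vapply(runs, max, numeric(1))],
    y = nd$y[vapply(runs, max, numeric(1))],
    z = nd$z[vapply(runs, max, numeric(1))],
    radius = nd$radius[heads],
    length = vapply(runs, function(rws) sum(nd$length[rws]), numeric(1)))
  ctree <- new_morph_tree(cn, soma_point = isTRUE(tree$soma_point))
  # physiology of the comp tree: take each run head's parameters
  ph <- tree$phys
  pick <- function(vec) stats::setNames(vec[as.character(nd$index[heads])],
                                        cn$index)
  cph <- list(cm = pick(ph$cm), ra = pick(ph$ra), gl = pick(ph$gl),
              el = pick(ph$el),
              channels = lapply(ph$channels, function(chs)
                list(channel = chs$channel, gmax = pick(chs$gmax),
                     e_rev = chs$e_rev)),
              pools = lapply(ph$pools, function(p)
                list(gamma = pick(p$gamma), tau = pick(p$tau),
                     cinf = pick(p$cinf))))
  ctree$phys <- cph

  # coordinate maps
  off <- numeric(n)   # arc offset of each original node's proximal end
  for (k in seq_along(runs)) {
    rws <- runs[[k]]  # in depth-first (proximal-to-distal) order
    off[rws] <- cumsum(c(0, nd$length[rws]))[seq_along(rws)]
  }
  o2c_tab <- data.frame(orig = nd$index, comp = comp_id[comp_of_row],
                        off = off, L = nd$length,
                        Lc = cn$length[comp_of_row])
  maps <- list(tree = ctree, table = o2c_tab)
  maps$orig2comp <- function(locs) {
    df <- as_locations(tree, locs)
    i <- match(df$node, o2c_tab$orig)
    xc <- ifelse(o2c_tab$Lc[i] > 0,
                 (o2c_tab$off[i] + df$x * o2c_tab$L[i]) / o2c_tab$Lc[i], 0)
    canonical_loc(ctree, data.frame(node = as.integer(o2c_tab$comp[i]),
                                    x = pmin(1, pmax(0, xc))))
  }
  maps$comp2orig <- function(locs) {
    df <- as_locations(ctree, locs)
    out <- df
    for (r in seq_len(nrow(df))) {
      rows <- which(o2c_tab$comp == df$node[r])
      s <- df$x[r] * o2c_tab$Lc[rows[1L]]
      hit <- rows[which(o2c_tab$off[rows] <= s + 1e-9 &
                        s <= o2c_tab$off[rows] + o2c_tab$L[rows] + 1e-9)][1L]
      out$node[r] <- o2c_tab$orig[hit]
      out$x[r] <- if (o2c_tab$L[hit] > 0)
        min(1, max(0, (s - o2c_tab$off[hit]) / o2c_tab$L[hit])) else 0
    }
    canonical_loc(tree, out)
  }
  tree$comp <- maps
  tree
}
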