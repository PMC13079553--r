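#' Attach and modify physiological parameters
#'
#' Physiology lives on the nodes of a [morph_tree]: membrane capacitance
#' `c_m` (uF/cm^2), axial resistivity `r_a` (Ohm*cm), leak conductance
#' `g_leak` (S/cm^2) and reversal `e_leak` (mV), plus per-channel maximal
#' conductance densities (S/cm^2) and per-ion concentration pools. Values
#' can be given as a single number (applied uniformly), a function of the
#' arc distance to the soma (um), or a named map `node index -> value`.
#' Any modification invalidates a previously built computational tree.
#'
#' @param tree a [morph_tree].
#' @param param one of `"c_m"`, `"r_a"`, `"g_leak"`, `"e_leak"`.
#' @param value constant, `function(distance_um)`, or named vector/list
#'   keyed by node index.
#' @param node_arg optional restriction: integer vector of node ids, an
#'   integer vector of SWC types wrapped in [swc_types()], or a predicate
#'   on a node row.
#' @return the modified tree.
#' @export
set_physiology <- function(tree, param, value, node_arg = NULL) {
  param <- match.arg(param, c("c_m", "r_a", "g_leak", "e_leak"))
  tree <- .ensure_phys(tree)
  res <- .resolve_values(tree, value, .select_nodes(tree, node_arg))
  if (param %in% c("c_m", "r_a") && any(res$vals <= 0))
    stop(param, " must be > 0", call. = FALSE)
  if (param == "g_leak" && any(res$vals < 0))
    stop("g_leak must be >= 0", call. = FALSE)
  slot <- c(c_m = "cm", r_a = "ra", g_leak = "gl", e_leak = "el")[[param]]
  tree$phys[[slot]][as.character(res$ids)] <- res$vals
  tree$comp <- NULL
  tree
}

#' @rdname set_physiology
#' @param channel an [ion_channel()].
#' @param g_max maximal conductance density (S/cm^2): constant, function of
#'   distance, or per-node map.
#' @param e_rev optional reversal override, mV.
#' @export
add_channel <- function(tree, channel, g_max, e_rev = NULL, node_arg = NULL) {
  stopifnot(inherits(channel, "ion_channel"))
  tree <- .ensure_phys(tree)
  res <- .resolve_values(tree, g_max, .select_nodes(tree, node_arg))
  if (any(res$vals < 0)) stop("g_max must be >= 0", call. = FALSE)
  nm <- channel$name
  if (is.null(tree$phys$channels[[nm]])) {
    g0 <- stats::setNames(rep(0, nrow(tree$nodes)), tree$nodes$index)
    tree$phys$channels[[nm]] <- list(channel = channel, gmax = g0,
                                     e_rev = e_rev %||% channel$e_rev)
  }
  if (!is.null(e_rev)) tree$phys$channels[[nm]]$e_rev <- e_rev
  tree$phys$channels[[nm]]$gmax[as.character(res$ids)] <- res$vals
  tree$comp <- NULL
  tree
}

#' @rdname set_physiology
#' @param ion ion name (e.g. `"ca"`).
#' @param gamma concentration change per unit inward current density,
#'   mM*um^2/(nA*ms); the pool obeys
#'   `d[ion]/dt = -gamma * i_ion - ([ion] - c_inf)/tau` with `i_ion` the net
#'   current density (nA/um^2, inward negative) of the channels carrying
#'   `ion`.
#' @param tau pool relaxation time, ms (> 0).
#' @param c_inf resting concentration, mM (>= 0).
#' @export
add_conc_pool <- function(tree, ion, gamma, tau, c_inf, node_arg = NULL) {
  tree <- .ensure_phys(tree)
  ids <- .select_nodes(tree, node_arg)
  rg <- .resolve_values(tree, gamma, ids)
  rt <- .resolve_values(tree, tau, ids)
  rc <- .resolve_values(tree, c_inf, ids)
  if (any(rt$vals <= 0)) stop("pool tau must be > 0", call. = FALSE)
  if (any(rc$vals < 0)) stop("c_inf must be >= 0", call. = FALSE)
  if (is.null(tree$phys$pools[[ion]])) {
    z <- stats::setNames(rep(NA_real_, nrow(tree$nodes)), tree$nodes$index)
    tree$phys$pools[[ion]] <- list(gamma = z, tau = z, cinf = z)
  }
  tree$phys$pools[[ion]]$gamma[as.character(rg$ids)] <- rg$vals
  tree$phys$pools[[ion]]$tau[as.character(rt$ids)] <- rt$vals
  tree$phys$pools[[ion]]$cinf[as.character(rc$ids)] <- rc$vals
  tree$comp <- NULL
  tree
}

#' Mark node selections by SWC type
#' @param ... SWC type codes (1 soma, 2 axon, 3 basal, 4 apical).
#' @return an object understood by the `node_arg` arguments.
#' @export
swc_types <- function(...) structure(c(...), class = "swc_types")

.ensure_phys <- function(tree) {
  if (is.null(tree$phys)) {
    ids <- as.character(tree$nodes$index)
    z <- function(v) stats::setNames(rep(v, length(ids)), ids)
    tree$phys <- list(cm = z(1), ra = z(100), gl = z(0), el = z(-70),
                      channels = list(), pools = list())
  }
  tree
}

.select_nodes <- function(tree, node_arg) {
  nd <- tree$nodes
  if (is.null(node_arg)) return(nd$index)
  if (inherits(node_arg, "swc_types")) return(nd$index[nd$type %in% node_arg])
  if (is.function(node_arg))
    return(nd$index[vapply(seq_len(nrow(nd)), function(i)
      isTRUE(node_arg(nd[i, , drop = FALSE])), logical(1))])
  if (!all(node_arg %in% nd$index))
    stop("unknown node index in selection", call. = FALSE)
  node_arg
}

# resolves a value spec over a node selection; for per-node maps only the
# listed nodes are touched
.value_per_node <- function(tree, value, ids) {
  res <- .resolve_values(tree, value, ids)
  res$vals
}

.resolve_values <- function(tree, value, ids) {
  if (is.function(value)) {
    d <- tree$dist_distal[.node_row(tree, ids)]
    list(ids = ids, vals = vapply(d, value, numeric(1)))
  } else if (!is.null(names(value))) {
    if (!all(names(value) %in% as.character(tree$nodes$index)))
      stop("unknown node index in value map", call. = FALSE)
    keep <- as.character(ids) %in% names(value)
    ids <- ids[keep]
    list(ids = ids, vals = unlist(value)[as.character(ids)])
  } else list(ids = ids, vals = rep(as.numeric(value), length(ids)))
}

#' Load a physiology configuration onto a tree
#'
#' The configuration is a list (or JSON file) with optional blocks:
#' `passive` (fields `c_m`, `r_a`, `g_leak`, `e_leak`), `channels` (list of
#' entries with `def` (a channel definition, see [parse_channel()]) or
#' `name` of an already supplied channel, `g_max`, optional `e_rev`,
#' optional `regions` = SWC type codes), and `pools` (entries with `ion`,
#' `gamma`, `tau`, `c_inf`, optional `regions`).
#'
#' @param tree a [morph_tree].
#' @param config named list or path to a JSON file.
#' @param channels optional named list of `ion_channel` objects referenced
#'   by name in the config.
#' @return the tree with physiology attached.
#' @export
apply_physiology_config <- function(tree, config, channels = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  pv <- config$passive
  if (!is.null(pv)) {
    for (p in intersect(names(pv), c("c_m", "r_a", "g_leak", "e_leak")))
      tree <- set_physiology(tree, p, pv[[p]])
  }
  for (chcfg in config$channels %||% list()) {
    ch <- if (!is.null(chcfg$def)) parse_channel(chcfg$def)
          else channels[[chcfg$name]]
    if (is.null(ch)) stop("channel '", chcfg$name, "' not supplied",
                          call. = FALSE)
    sel <- if (!is.null(chcfg$regions)) swc_types(unlist(chcfg$regions))
    tree <- add_channel(tree, ch, chcfg$g_max, e_rev = chcfg$e_rev,
                        node_arg = sel)
  }
  for (pcfg in config$pools %||% list()) {
    sel <- if (!is.null(pcfg$regions)) swc_types(unlist(pcfg$regions))
    tree <- add_conc_pool(tree, pcfg$ion, pcfg$gamma, pcfg$tau, pcfg$c_inf,
                          node_arg = sel)
  }
  tree
}

# per-node physiological parameter table used by comparisons and merging
.phys_matrix <- function(tree) {
  ph <- tree$phys
  if (is.null(ph)) stop("physiology has not been set", call. = FALSE)
  ids <- as.character(tree$nodes$index)
  m <- cbind(radius = tree$nodes$radius, cm = ph$cm[ids], ra = ph$ra[ids],
             gl = ph$gl[ids], el = ph$el[ids])
  for (nm in names(ph$channels))
    m <- cbind(m, ph$channels[[nm]]$gmax[ids])
  for (ion in names(ph$pools)) {
    p <- ph$pools[[ion]]
    m <- cbind(m, p$gamma[ids], p$tau[ids], p$cinf[ids])
  }
  m
}
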