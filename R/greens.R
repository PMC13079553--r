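#' Quasi-active linearization of a full model
#'
#' Linearizes every ion channel around a per-node expansion point and
#' returns a frequency-domain representation of the tree in which each node
#' carries a linearized membrane conductance density
#' \deqn{g_{lin}(\omega) = g_{leak} + \sum_c \bar g_c \lambda_c(\omega),}
#' with \eqn{\lambda_c} from [linearize()]. The result is the input to the
#' impedance and kernel computations. When the tree has a computational
#' tree attached, the merged cylinders are used (results are identical;
#' locations are always given in original-tree coordinates).
#'
#' @param tree a [morph_tree] with physiology.
#' @param v0 expansion potential: a single value (mV), a named per-node
#'   vector, or `NULL` to use the model's equilibrium (computed with
#'   [steady_state_tree()]).
#' @param with_conc logical; include the linearized coupling through ion
#'   concentration pools (channels whose gating reads a pooled ion acquire
#'   an extra admittance term filtered by the pool's relaxation).
#' @return an object of class `greens_tree`.
#' @export
make_quasi_active <- function(tree, v0 = NULL, with_conc = FALSE) {
  .make_linear_tree(tree, v0, with_conc = with_conc, passified = FALSE)
}

#' Passify a model: freeze channels into the leak
#'
#' Channels are replaced by the frequency-independent conductance
#' `g_max * o(y_inf(v0))`, folded into the leak; the result is a strictly
#' passive tree whose impedances are low-pass. This equals the
#' high-frequency (`omega -> Inf`) limit of the quasi-active linearization.
#'
#' @inheritParams make_quasi_active
#' @return a passive `greens_tree`.
#' @export
passify <- function(tree, v0 = NULL) {
  .make_linear_tree(tree, v0, with_conc = FALSE, passified = TRUE)
}

.expansion_profile <- function(tree, v0) {
  ids <- as.character(tree$nodes$index)
  if (is.null(v0)) {
    eq <- steady_state_tree(tree)
    list(v = eq$v[ids], conc = eq$conc)
  } else if (length(v0) == 1L && is.null(names(v0))) {
    conc <- lapply(tree$phys$pools, function(p) p$cinf)
    list(v = stats::setNames(rep(v0, length(ids)), ids), conc = conc)
  } else {
    conc <- lapply(tree$phys$pools, function(p) p$cinf)
    list(v = v0[ids], conc = conc)
  }
}

# core constructor: per-node static conductance + rational admittance terms.
# each term is w / prod_j (1 + i omega tau_j); g_lin(iw) evaluated by
# .eval_glin. 'only_channel': restrict to leak + that single channel
# (used by the reduction's per-channel fits).
.make_linear_tree <- function(tree, v0, with_conc = FALSE, passified = FALSE,
                              only_channel = NULL, drop_channels = FALSE) {
  if (is.null(tree$phys)) stop("physiology has not been set", call. = FALSE)
  use_comp <- !is.null(tree$comp)
  wt <- if (use_comp) tree$comp$tree else tree
  exp_prof <- .expansion_profile(tree, v0)
  # expansion values on the working tree
  map_ids <- if (use_comp) as.character(tree$comp$tree$nodes$index)
             else as.character(tree$nodes$index)
  vmap <- exp_prof$v
  if (use_comp) vmap <- vmap[map_ids]
  ph <- wt$phys
  nd <- wt$nodes
  ids <- as.character(nd$index)
  n <- nrow(nd)
  nodes <- vector("list", n)
  chnames <- names(ph$channels)
  if (drop_channels) chnames <- character(0)
  if (!is.null(only_channel)) {
    if (!only_channel %in% names(ph$channels))
      stop("unknown channel: ", only_channel, call. = FALSE)
    chnames <- only_channel
  }
  for (i in seq_len(n)) {
    id <- ids[i]
    vi <- vmap[[id]]
    conci <- lapply(exp_prof$conc, function(cc) cc[[id]])
    conci <- conci[!vapply(conci, is.na, logical(1))]
    g_static <- ph$gl[[id]] * .G_FACT
    terms <- list()
    chan_slope <- list()  # per ion: DC slope terms of carrying channels
    for (nm in chnames) {
      chs <- ph$channels[[nm]]
      g <- chs$gmax[[id]] * .G_FACT
      if (g == 0) next
      ch <- chs$channel
      ch$e_rev <- chs$e_rev
      ss <- steady_state(ch, vi, conci)
      g_static <- g_static + g * ss$p_open
      if (!passified) {
        env0 <- c(as.list(ss$y_inf), .gate_env(vi, conci))
        for (sv in ch$statevars) {
          dody <- eval(stats::D(ch$p_open, sv), env0)
          dyv <- eval(.dyinf(ch$gating[[sv]]), env0)
          w <- g * (vi - ch$e_rev) * dody * dyv
          if (w != 0)
            terms[[length(terms) + 1L]] <- list(w = w, taus = ss$tau[[sv]])
        }
      }
      if (ch$ion %in% names(ph$pools)) {
        # DC-and-dynamic slope of this channel's current wrt v, for the
        # concentration coupling below: g * lambda(omega) as terms
        sl <- list(list(w = g * ss$p_open, taus = numeric(0)))
        if (!passified) {
          env0 <- c(as.list(ss$y_inf), .gate_env(vi, conci))
          for (sv in ch$statevars) {
            dody <- eval(stats::D(ch$p_open, sv), env0)
            dyv <- eval(.dyinf(ch$gating[[sv]]), env0)
            w <- g * (vi - ch$e_rev) * dody * dyv
            if (w != 0) sl[[length(sl) + 1L]] <- list(w = w,
                                                     taus = ss$tau[[sv]])
          }
        }
        chan_slope[[ch$ion]] <- c(chan_slope[[ch$ion]] %||% list(), sl)
      }
    }
    if (with_conc && !passified && length(ph$pools)) {
      for (nm in chnames) {
        chs <- ph$channels[[nm]]
        g <- chs$gmax[[id]] * .G_FACT
        if (g == 0) next
        ch <- chs$channel
        ch$e_rev <- chs$e_rev
        deps <- intersect(ch$conc_deps, names(ph$pools))
        for (ion in deps) {
          pool <- ph$pools[[ion]]
          if (is.na(pool$tau[[id]])) next
          ss <- steady_state(ch, vi, conci)
          env0 <- c(as.list(ss$y_inf), .gate_env(vi, conci))
          slope <- chan_slope[[ion]] %||% list()
          for (sv in ch$statevars) {
            dody <- eval(stats::D(ch$p_open, sv), env0)
            dyc <- eval(.dyinf(ch$gating[[sv]], wrt = ion), env0)
            pref <- g * (vi - ch$e_rev) * dody * dyc *
              (-pool$gamma[[id]] * pool$tau[[id]])
            if (pref == 0) next
            # delta_ca = -gamma tau_c/(1+iw tau_c) * d i_ion/dv * delta_v
            for (s in slope) {
              terms[[length(terms) + 1L]] <-
                list(w = pref * s$w / .C_AREA_FACT,
                     taus = c(ss$tau[[sv]], pool$tau[[id]], s$taus))
            }
          }
        }
      }
    }
    nodes[[i]] <- list(g_static = g_static, terms = terms,
                       cm = ph$cm[[id]] * .C_FACT,
                       ra = ph$ra[[id]] * .RA_FACT,
                       R = nd$radius[i], L = nd$length[i])
  }
  names(nodes) <- ids
  gt <- structure(list(
    work = wt, nodes = nodes,
    soma_area = if (isTRUE(wt$soma_point)) 0 else 4 * pi * nd$radius[1L]^2,
    passive = passified ||
      all(vapply(nodes, function(nn) length(nn$terms) == 0L, logical(1))),
    use_comp = use_comp,
    src = tree,
    expansion = exp_prof
  ), class = "greens_tree")
  gt
}

# concentration coupling works on current *density*; areas cancel in the
# per-length admittance, so no extra factor is required
.C_AREA_FACT <- 1

#' @export
print.greens_tree <- function(x, ...) {
  cat(sprintf("<greens_tree> %d cylinders, %s membrane\n",
              nrow(x$work$nodes) - 1L,
              if (x$passive) "passive(ified)" else "quasi-active"))
  invisible(x)
}

# map user locations (original tree coords) to working-tree coords
.work_locs <- function(gt, locs) {
  if (gt$use_comp) gt$src$comp$orig2comp(locs)
  else as_locations(gt$work, locs)
}

# ---- frequency-domain core -------------------------------------------------

# evaluate g_lin (uS/um^2) of one node at complex iw (vector)
.eval_glin <- function(nn, iw) {
  g <- rep(nn$g_static + 0i, length(iw))
  for (tm in nn$terms) {
    den <- rep(1 + 0i, length(iw))
    for (tau in tm$taus) den <- den * (1 + iw * tau)
    g <- g + tm$w / den
  }
  g
}

.tanh_safe <- function(z) {
  out <- z
  big <- Re(z) > 20
  small <- Re(z) < -20
  mid <- !(big | small)
  out[big] <- 1 + 0i
  out[small] <- -1 + 0i
  out[mid] <- tanh(z[mid])
  out
}

# per-node cable coefficients at iw: gamma (1/um), zc (MOhm)
.cable_coeff <- function(gt, iw) {
  lapply(gt$nodes, function(nn) {
    if (nn$L == 0 && is.na(nn$ra)) return(NULL)
    y <- 2 * pi * nn$R * (.eval_glin(nn, iw) + iw * nn$cm)  # uS/um
    r <- nn$ra / (pi * nn$R^2)                              # MOhm/um
    list(gamma = sqrt(r * y), zc = sqrt(r / y))
  })
}

# admittance transform through a sub-cylinder of length del (looking through
# it at a load admittance YL on the far side)
.transform_Y <- function(YL, del, gamma, zc) {
  if (del == 0) return(YL)
  t <- .tanh_safe(gamma * del)
  (YL + t / zc) / (1 + YL * zc * t)
}

# all sweep quantities at iw (complex vector): per node, admittance looking
# distal from the distal end (Y_dist), input admittance of the node seen
# from its proximal end (Y_in), admittance looking proximal from the
# proximal end excluding the node itself (Y_out), and the root-point
# admittance.
.sweeps <- function(gt, iw) {
  nd <- gt$work$nodes
  n <- nrow(nd)
  cc <- .cable_coeff(gt, iw)
  nz <- length(iw)
  Y_dist <- Y_in <- Y_out <- vector("list", n)
  # leaf -> root (reverse depth-first row order)
  for (i in rev(seq_len(n))) {
    ch_rows <- .node_row(gt$work, gt$work$children[[i]])
    Yd <- rep(0 + 0i, nz)
    for (cr in ch_rows) Yd <- Yd + Y_in[[cr]]
    Y_dist[[i]] <- Yd
    if (i > 1L)
      Y_in[[i]] <- .transform_Y(Yd, nd$length[i], cc[[i]]$gamma, cc[[i]]$zc)
  }
  # soma lumped admittance
  soma <- gt$nodes[[1L]]
  Y_soma <- gt$soma_area * (.eval_glin(soma, iw) + iw * soma$cm)
  Y_root <- Y_soma + Y_dist[[1L]]
  # root -> leaf
  for (i in seq_len(n)) {
    ch_rows <- .node_row(gt$work, gt$work$children[[i]])
    if (!length(ch_rows)) next
    Y_thru <- if (i == 1L) Y_soma
      else .transform_Y(Y_out[[i]], nd$length[i], cc[[i]]$gamma, cc[[i]]$zc)
    for (cr in ch_rows) {
      Yo <- Y_thru
      for (sib in ch_rows) if (sib != cr) Yo <- Yo + Y_in[[sib]]
      Y_out[[cr]] <- Yo
    }
  }
  list(cc = cc, Y_dist = Y_dist, Y_in = Y_in, Y_out = Y_out,
       Y_root = Y_root, Y_soma = Y_soma)
}

.input_imp_at <- function(gt, sw, loc) {
  # loc: one row (node, x) in working-tree coordinates
  if (loc$node == gt$work$root) return(1 / sw$Y_root)
  i <- .node_row(gt$work, loc$node)
  L <- gt$work$nodes$length[i]
  cc <- sw$cc[[i]]
  Ya <- .transform_Y(sw$Y_out[[i]], loc$x * L, cc$gamma, cc$zc)
  Yb <- .transform_Y(sw$Y_dist[[i]], (1 - loc$x) * L, cc$gamma, cc$zc)
  1 / (Ya + Yb)
}

# voltage attenuation from loc1 to loc2 (product over path segments)
.attenuation <- function(gt, sw, loc1, loc2) {
  wtree <- gt$work
  n1 <- loc1$node; n2 <- loc2$node
  seg_att <- function(node, xa, xb) {
    i <- .node_row(wtree, node)
    L <- wtree$nodes$length[i]
    del <- abs(xb - xa) * L
    if (del == 0) return(1 + 0i)
    cc <- sw$cc[[i]]
    Yfar <- if (xb > xa)
      .transform_Y(sw$Y_dist[[i]], (1 - xb) * L, cc$gamma, cc$zc)
    else
      .transform_Y(sw$Y_out[[i]], xb * L, cc$gamma, cc$zc)
    g <- cc$gamma * del
    1 / (cosh(g) + cc$zc * Yfar * sinh(g))
  }
  if (n1 == n2)
    return(if (loc1$x == loc2$x) 1 + 0i else seg_att(n1, loc1$x, loc2$x))
  pa <- .root_path(wtree, n1); pb <- .root_path(wtree, n2)
  m <- min(length(pa), length(pb))
  ncom <- max(which(pa[seq_len(m)] == pb[seq_len(m)]))
  lca <- pa[ncom]
  A <- rep(1 + 0i, length(sw$Y_root))
  if (lca == n1) {
    # descend from loc1 through the chain to loc2
    down <- pb[(ncom + 1L):length(pb)]
    A <- A * seg_att(n1, loc1$x, 1)
    for (nd_id in down[-length(down)]) A <- A * seg_att(nd_id, 0, 1)
    A * seg_att(n2, 0, loc2$x)
  } else if (lca == n2) {
    up <- pa[length(pa):(ncom + 1L)]
    A <- A * seg_att(n1, loc1$x, 0)
    for (nd_id in up[-1L]) A <- A * seg_att(nd_id, 1, 0)
    A * seg_att(n2, 1, loc2$x)
  } else {
    up <- pa[length(pa):(ncom + 1L)]
    down <- pb[(ncom + 1L):length(pb)]
    A <- A * seg_att(n1, loc1$x, 0)
    for (nd_id in up[-1L]) A <- A * seg_att(nd_id, 1, 0)
    for (nd_id in down[-length(down)]) A <- A * seg_att(nd_id, 0, 1)
    A * seg_att(n2, 0, loc2$x)
  }
}

#' Input impedance at a location
#'
#' @param gt a `greens_tree` from [make_quasi_active()] or [passify()].
#' @param loc a single location (original-tree coordinates).
#' @param omega angular frequencies, rad/ms.
#' @return complex vector of impedances, MOhm.
#' @export
input_impedance <- function(gt, loc, omega) {
  lw <- .work_locs(gt, loc)
  if (nrow(lw) != 1L) stop("one location expected", call. = FALSE)
  sw <- .sweeps(gt, 1i * omega)
  .input_imp_at(gt, sw, lw[1L, ])
}

#' Transfer impedance between two locations
#'
#' `Z(xi1, xi2, omega)`: voltage at `loc2` per unit sinusoidal current at
#' `loc1`; by reciprocity symmetric in the two locations.
#'
#' @inheritParams input_impedance
#' @param loc1,loc2 single locations.
#' @return complex vector of impedances, MOhm.
#' @export
transfer_impedance <- function(gt, loc1, loc2, omega) {
  l1 <- .work_locs(gt, loc1); l2 <- .work_locs(gt, loc2)
  sw <- .sweeps(gt, 1i * omega)
  .input_imp_at(gt, sw, l1[1L, ]) * .attenuation(gt, sw, l1[1L, ], l2[1L, ])
}

#' Impedance matrix over a set of locations
#'
#' @inheritParams input_impedance
#' @param locs locations (>= 1).
#' @return an `impedance_result`: list with `locations`, `omega`, and `Z`,
#'   a complex array of dimension `(n_loc, n_loc, n_omega)`. At
#'   `omega = 0` the slice is the resistance matrix.
#' @export
impedance_matrix <- function(gt, locs, omega = 0) {
  lw <- .work_locs(gt, locs)
  if (!nrow(lw)) stop("need at least one location", call. = FALSE)
  sw <- .sweeps(gt, 1i * omega)
  nl <- nrow(lw); nw <- length(omega)
  Z <- array(0 + 0i, dim = c(nl, nl, nw))
  for (i in seq_len(nl)) {
    Zi <- .input_imp_at(gt, sw, lw[i, ])
    Z[i, i, ] <- Zi
    if (i < nl) for (j in seq((i + 1L), nl)) {
      Z[i, j, ] <- Z[j, i, ] <- Zi * .attenuation(gt, sw, lw[i, ], lw[j, ])
    }
  }
  structure(list(locations = as_locations(gt$src, locs), omega = omega,
                 Z = Z), class = "impedance_result")
}

#' Resistance matrix (impedance at omega = 0)
#' @inheritParams impedance_matrix
#' @return real matrix, MOhm.
#' @export
resistance_matrix_tree <- function(gt, locs) {
  Z <- impedance_matrix(gt, locs, 0)$Z
  matrix(Re(Z[, , 1L]), dim(Z)[1L], dim(Z)[2L])
}

# ---- time-domain kernels ---------------------------------------------------

# hybrid frequency grid for the cosine-transform inversion: dense linear
# part near 0 plus log-spaced tail; the linear spacing adapts to the
# largest requested time so that cos(w t) stays resolved where it matters
.kernel_omega_grid <- function(t_max, w_lin = 2, w_max = 3000,
                               n_log = 4000) {
  dw <- max(0.05 / max(t_max, 1), 2e-5)
  n_lin <- ceiling(w_lin / dw)
  c(seq(0, w_lin, length.out = n_lin + 1L)[-(n_lin + 1L)],
    exp(seq(log(w_lin), log(w_max), length.out = n_log)))
}

#' Time-domain response kernel by Fourier inversion
#'
#' Computes `k(t) = (2/pi) \int_0^Inf Re Z(i w) cos(w t) dw` on a hybrid
#' linear/log frequency grid by trapezoidal quadrature, with a first-order
#' tail correction. The kernel is the voltage response (mV) to a unit
#' charge impulse (nA*ms); its integral over t equals the DC resistance.
#' For quasi-active trees a stability check requires `Re Z >= 0` on the
#' whole grid; a violation (an unstable expansion point) is an error.
#'
#' @inheritParams transfer_impedance
#' @param t_grid times, ms (> 0).
#' @return a `time_kernel`: list with `times` (ms), `values` (mV/(nA*ms))
#'   and `dc` (MOhm).
#' @export
kernel_from_impedance <- function(gt, loc1, loc2, t_grid) {
  stopifnot(all(t_grid > 0))
  om <- .kernel_omega_grid(max(t_grid))
  Z <- transfer_impedance(gt, loc1, loc2, om)
  ReZ <- Re(Z)
  if (!gt$passive && any(ReZ < -1e-9 * max(abs(ReZ))))
    stop("unstable quasi-active linearization: Re Z < 0 on the grid ",
         "(expansion around v0 = ",
         signif(gt$expansion$v[[1L]], 4), " mV)", call. = FALSE)
  dw <- diff(om)
  nf <- length(om)
  dReZ <- c(diff(ReZ) / dw, 0)   # forward-difference slope, for the tail
  vals <- vapply(t_grid, function(t) {
    # integrate only while the grid resolves cos(w t); close with a
    # two-term integration-by-parts tail at the cutoff
    kcut <- nf
    unres <- which(dw * t > 0.3)
    if (length(unres)) kcut <- unres[1L]
    idx <- seq_len(kcut - 1L)
    integ <- sum((ReZ[idx + 1L] * cos(om[idx + 1L] * t) +
                  ReZ[idx] * cos(om[idx] * t)) / 2 * dw[idx])
    wc <- om[kcut]
    tail <- -ReZ[kcut] * sin(wc * t) / t - dReZ[kcut] * cos(wc * t) / t^2
    (2 / pi) * (integ + tail)
  }, numeric(1))
  structure(list(times = t_grid, values = vals, dc = Re(Z[1L])),
            class = "time_kernel")
}

#' @export
print.time_kernel <- function(x, ...) {
  cat(sprintf("<time_kernel> %d points, t in [%g, %g] ms, DC %g MOhm\n",
              length(x$times), min(x$times), max(x$times), x$dc))
  invisible(x)
}

#' @export
as.data.frame.time_kernel <- function(x, ...) {
  data.frame(t_ms = x$times, k = x$values)
}
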