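#' Reduced compartmental models by resistance-matrix fitting
#'
#' The reduction pipeline derives a few-compartment model that reproduces
#' the electrical behaviour of a full morphological model at user-chosen
#' locations. Its backbone is the observation that the inverse of the
#' resistance matrix evaluated at the compartment sites directly yields the
#' conductance parameters of the reduced model: the reduced conductance
#' matrix `G(theta)` (leak on the diagonal, `-g_c` on tree-adjacent
#' off-diagonals) is fitted by linear least squares on `|| Z G - I ||_F`.
#' Channel conductances are fitted jointly over multiple expansion points
#' (holding potentials, capped at 16 per channel), capacitances by matching
#' either the local membrane time constant or the slowest eigenmode,
#' concentration pools by rescaling the total ionic current, and leak
#' reversals by matching the equilibrium potentials.
#'
#' @name reducer
NULL

# ---- location bookkeeping --------------------------------------------------

#' Extend fit locations with the junctions between them
#'
#' Appends, after the user's locations (order preserved), every branch
#' point of the minimal spanning subtree that joins at least two covered
#' subtrees and is not already a fit location; the soma is appended when
#' absent.
#'
#' @param tree a [morph_tree].
#' @param locs locations.
#' @return data.frame of locations; the first `nrow(locs)` rows equal the
#'   input (canonicalized), in order.
#' @export
extend_locations <- function(tree, locs) {
  df <- as_locations(tree, locs)
  if (!nrow(df)) stop("need at least one location", call. = FALSE)
  mst <- minimal_spanning_subtree(tree, df)
  covered <- stats::setNames(mst$x1, mst$node)
  key <- function(d) paste(d$node, signif(d$x, 12))
  have <- key(df)
  out <- df
  for (i in seq_len(nrow(mst))) {
    id <- mst$node[i]
    if (covered[[as.character(id)]] < 1) next
    ch <- tree$children[[.node_row(tree, id)]]
    n_sub <- sum(ch %in% mst$node)
    if (id == tree$root || n_sub < 2L) next
    cand <- canonical_loc(tree, data.frame(node = id, x = 1))
    if (!key(cand) %in% key(out)) out <- rbind(out, cand)
  }
  soma <- data.frame(node = tree$root, x = 0)
  if (!key(soma) %in% key(out)) out <- rbind(out, soma)
  rownames(out) <- NULL
  out
}

# parent structure induced on a location set: parent = nearest location on
# the path to the soma (0 when none)
.loc_tree <- function(tree, locs) {
  df <- as_locations(tree, locs)
  n <- nrow(df)
  d <- soma_distance(tree, df)
  if (anyDuplicated(round(cbind(df$node, df$x * 1e12))))
    stop("locations coincident", call. = FALSE)
  paths <- lapply(df$node, function(id) .root_path(tree, id))
  parent <- integer(n)
  for (i in seq_len(n)) {
    anc <- vapply(seq_len(n), function(j) {
      if (j == i) return(FALSE)
      if (df$node[j] == df$node[i]) return(df$x[j] < df$x[i])
      df$node[j] %in% paths[[i]]
    }, logical(1))
    cand <- which(anc & d < d[i] + 1e-12)
    parent[i] <- if (!length(cand)) 0L else cand[which.max(d[cand])]
  }
  parent
}

# conductance matrix of a reduced model: diag membrane + tree couplings
.G_of <- function(g_mem, g_c, parent) {
  n <- length(g_mem)
  G <- diag(g_mem, n)
  for (i in seq_len(n)) if (parent[i] > 0L) {
    j <- parent[i]
    G[i, i] <- G[i, i] + g_c[i]
    G[j, j] <- G[j, j] + g_c[i]
    G[i, j] <- G[i, j] - g_c[i]
    G[j, i] <- G[j, i] - g_c[i]
  }
  G
}

# ---- resistance matrices of the full model under fit regimes ---------------

#' Resistance matrix of a model under a linearization regime
#'
#' The regimes used by the fitting pipeline: `"passified"` (all channels
#' frozen at the equilibrium, folded into the leak), `"leak"` (channels
#' stripped entirely), or a single channel quasi-actively linearized at a
#' holding potential on top of the bare leak
#' (`list(channel = name, vh = mV)`). Methods exist for full morphological
#' models (via the analytical impedance engine) and for compartmental
#' models (direct inversion of their conductance matrix), so that a known
#' compartment model can be posed as the "full" model in identity tests.
#'
#' @param model a [morph_tree] with physiology, or a `comp_tree_fit`.
#' @param locs fit locations (ignored for compartment models).
#' @param regime `"passified"`, `"leak"`, or `list(channel=, vh=)`.
#' @param v_eq optional equilibrium profile (named by node) reused across
#'   calls.
#' @return real matrix, MOhm.
#' @export
resistance_matrix <- function(model, locs, regime = "passified",
                              v_eq = NULL) {
  UseMethod("resistance_matrix")
}

#' @export
resistance_matrix.morph_tree <- function(model, locs, regime = "passified",
                                         v_eq = NULL) {
  gt <- if (identical(regime, "passified")) {
    .make_linear_tree(model, v_eq, passified = TRUE)
  } else if (identical(regime, "leak")) {
    .make_linear_tree(model, v_eq %||% -70, drop_channels = TRUE)
  } else {
    .make_linear_tree(model, regime$vh, only_channel = regime$channel)
  }
  resistance_matrix_tree(gt, locs)
}

#' @export
resistance_matrix.comp_tree_fit <- function(model, locs, regime = "passified",
                                            v_eq = NULL) {
  nd <- model$nodes
  n <- nrow(nd)
  g_mem <- nd$g_leak
  if (identical(regime, "passified")) {
    veq <- v_eq %||% rep(-70, n)
    for (nm in names(model$channels)) {
      chs <- model$channels[[nm]]
      for (i in seq_len(n)) {
        ss <- steady_state(chs$channel, veq[i], .pool_cinf(model, i))
        g_mem[i] <- g_mem[i] + chs$g[i] * ss$p_open
      }
    }
  } else if (!identical(regime, "leak")) {
    chs <- model$channels[[regime$channel]]
    for (i in seq_len(n)) {
      ch <- chs$channel; ch$e_rev <- chs$e_rev
      lam <- Re(linearize(ch, expansion_point(regime$vh,
                                              conc0 = .pool_cinf(model, i)),
                          0))
      g_mem[i] <- g_mem[i] + chs$g[i] * lam
    }
  }
  solve(.G_of(g_mem, nd$g_c, nd$parent))
}

.pool_cinf <- function(fit, i) {
  if (!length(fit$pools)) return(NULL)
  out <- lapply(fit$pools, function(p) p$cinf[i])
  out
}

# ---- individual fit stages -------------------------------------------------

#' Passive least-squares fit of leak and coupling conductances
#'
#' Minimizes `|| Z G(theta) - I ||_F^2` over the leak conductances and the
#' couplings of the nearest-neighbour tree induced by the locations; linear
#' least squares, closed form. With `nonneg = TRUE`, negative parameters
#' are clamped to zero and the rest refitted (a simple active-set pass);
#' otherwise negative values only trigger a warning, preserving exact
#' identity recovery.
#'
#' @param Z resistance matrix at the fit locations, MOhm.
#' @param parent parent index per location (from the induced tree).
#' @param nonneg constrain conductances to be nonnegative.
#' @return list with `g_mem` (uS), `g_c` (uS, per location, coupling to
#'   parent), `parent`, and the Frobenius `residual`.
#' @export
fit_passive_matrix <- function(Z, parent, nonneg = FALSE) {
  n <- nrow(Z)
  mats <- list()
  for (i in seq_len(n)) {
    M <- matrix(0, n, n); M[i, i] <- 1
    mats[[length(mats) + 1L]] <- M
  }
  edges <- which(parent > 0L)
  for (i in edges) {
    M <- matrix(0, n, n)
    j <- parent[i]
    M[i, i] <- M[j, j] <- 1
    M[i, j] <- M[j, i] <- -1
    mats[[length(mats) + 1L]] <- M
  }
  A <- vapply(mats, function(M) as.vector(Z %*% M), numeric(n * n))
  b <- as.vector(diag(n))
  theta <- .ls_solve(A, b, nonneg)
  g_mem <- theta[seq_len(n)]
  g_c <- rep(0, n)
  g_c[edges] <- theta[-seq_len(n)]
  if (!nonneg && any(theta < 0))
    warning("negative fitted conductance(s); consider nonneg = TRUE",
            call. = FALSE)
  G <- .G_of(g_mem, g_c, parent)
  list(g_mem = g_mem, g_c = g_c, parent = parent,
       residual = norm(Z %*% G - diag(n), "F"))
}

.ls_solve <- function(A, b, nonneg = FALSE) {
  theta <- qr.solve(A, b)
  if (!nonneg) return(theta)
  active <- rep(TRUE, length(theta))
  for (pass in seq_len(length(theta) + 1L)) {
    if (all(theta[active] >= -1e-14)) break
    active[active][theta[active] < 0] <- FALSE
    theta <- rep(0, ncol(A))
    if (any(active)) theta[active] <- qr.solve(A[, active, drop = FALSE], b)
  }
  pmax(theta, 0)
}

#' Joint channel-conductance fit over expansion points
#'
#' For each holding potential the full model is linearized with only the
#' channel of interest on top of the bare leak; the reduced counterpart is
#' `G_h = G_leak + diag(gbar_i lambda_c(0; v_h))`. All holdings enter one
#' linear least-squares problem for `gbar`.
#'
#' @param Zh list of resistance matrices, one per holding.
#' @param lam list of per-location `lambda_c(0; v_h)` vectors.
#' @param G0 leak-only reduced conductance matrix.
#' @param nonneg as in [fit_passive_matrix()].
#' @return list with `gbar` (uS) and `residual`.
#' @export
fit_channel_matrix <- function(Zh, lam, G0, nonneg = FALSE) {
  n <- nrow(G0)
  if (all(vapply(lam, function(l) max(abs(l)), numeric(1)) < 1e-12)) {
    warning("channel is unidentifiable (lambda ~ 0 at all holdings); ",
            "conductances set to 0", call. = FALSE)
    return(list(gbar = rep(0, n), residual = NA_real_))
  }
  A <- NULL; b <- NULL
  for (h in seq_along(Zh)) {
    Ah <- vapply(seq_len(n), function(i) {
      M <- matrix(0, n, n); M[i, i] <- lam[[h]][i]
      as.vector(Zh[[h]] %*% M)
    }, numeric(n * n))
    bh <- as.vector(diag(n) - Zh[[h]] %*% G0)
    A <- rbind(A, Ah); b <- c(b, bh)
  }
  gbar <- .ls_solve(A, b, nonneg)
  list(gbar = gbar, residual = sqrt(sum((A %*% gbar - b)^2)))
}

#' Default holding potentials for channel fits
#'
#' Evenly spaced potentials spanning -90..0 mV plus the equilibrium,
#' capped at 16.
#'
#' @param v_eq equilibrium potential, mV.
#' @param n_span number of evenly spaced holdings.
#' @return numeric vector of holding potentials (length <= 16).
#' @export
default_holdings <- function(v_eq = -70, n_span = 7) {
  h <- unique(c(seq(-90, 0, length.out = n_span), round(v_eq, 6)))
  h[seq_len(min(length(h), 16L))]
}

# ---- the full pipeline -----------------------------------------------------

#' Fit a reduced compartmental model
#'
#' Orchestrates the full reduction: location extension, equilibrium
#' computation, passive fit, per-channel fits over holding potentials,
#' capacitance fit, concentration-pool fit, and leak-reversal fit. The
#' first `n` locations of the returned `FitResult` equal the `n` input
#' locations, in order.
#'
#' @param tree a [morph_tree] with physiology.
#' @param locs fit locations.
#' @param holdings holding potentials for channel fits (default
#'   [default_holdings()]; at most 16 are used).
#' @param cap_strategy `"local_tau"` (capacitance from the local membrane
#'   time constant) or `"eigenmode"` (additionally rescaled so the slowest
#'   reduced eigenmode matches the full model's slowest time constant).
#' @param nonneg nonnegative constraint for the conductance fits.
#' @param dx_eq grid step for the equilibrium solve, um.
#' @return an object of class `fit_result`: list with `comp_tree` (a
#'   `comp_tree_fit`), `locations`, `residuals`, `v_eq`.
#' @export
fit_model <- function(tree, locs, holdings = NULL,
                      cap_strategy = c("local_tau", "eigenmode"),
                      nonneg = FALSE, dx_eq = 5) {
  cap_strategy <- match.arg(cap_strategy)
  stage <- "extend_locations"
  out <- tryCatch({
    locs_ext <- extend_locations(tree, locs)
    n <- nrow(locs_ext)
    parent <- .loc_tree(tree, locs_ext)

    stage <- "equilibrium"
    eqL <- steady_state_tree(tree, locs_ext, dx = dx_eq)
    eqN <- steady_state_tree(tree, dx = dx_eq)
    v_eq <- eqL$v

    stage <- "fit_passive"
    Zp <- resistance_matrix(tree, locs_ext, "passified", v_eq = eqN$v)
    pas <- fit_passive_matrix(Zp, parent, nonneg)

    stage <- "fit_channel"
    Z0 <- resistance_matrix(tree, locs_ext, "leak")
    p0 <- fit_passive_matrix(Z0, parent, nonneg)
    G0 <- .G_of(p0$g_mem, p0$g_c, parent)
    loc_ids <- as.character(locs_ext$node)
    hold <- holdings %||% default_holdings(v_eq[1L])
    hold <- hold[seq_len(min(length(hold), 16L))]
    channels <- list()
    ch_resid <- list()
    for (nm in names(tree$phys$channels)) {
      chs <- tree$phys$channels[[nm]]
      ch <- chs$channel; ch$e_rev <- chs$e_rev
      Zh <- lapply(hold, function(vh)
        resistance_matrix(tree, locs_ext, list(channel = nm, vh = vh)))
      lam <- lapply(hold, function(vh)
        vapply(loc_ids, function(id)
          Re(linearize(ch, expansion_point(vh, conc0 = .node_cinf(tree, id)),
                       0)), numeric(1)))
      cf <- fit_channel_matrix(Zh, lam, G0, nonneg)
      channels[[nm]] <- list(channel = chs$channel, g = cf$gbar,
                             e_rev = chs$e_rev)
      ch_resid[[nm]] <- cf$residual
    }

    stage <- "fit_capacitance"
    gt_pass <- .make_linear_tree(tree, eqN$v, passified = TRUE)
    wl <- .work_locs(gt_pass, locs_ext)
    tau_loc <- vapply(seq_len(n), function(i) {
      nn <- gt_pass$nodes[[as.character(wl$node[i])]]
      nn$cm / nn$g_static
    }, numeric(1))
    ca <- tau_loc * pas$g_mem
    if (cap_strategy == "eigenmode") {
      tau0_full <- find_time_scales(gt_pass, tau_min = 1)[1L]
      Gp <- .G_of(pas$g_mem, pas$g_c, parent)
      M <- diag(1 / sqrt(ca), n) %*% Gp %*% diag(1 / sqrt(ca), n)
      tau0_red <- 1 / min(eigen((M + t(M)) / 2, symmetric = TRUE,
                                only.values = TRUE)$values)
      ca <- ca * (tau0_full / tau0_red)
    }

    # final leak: passified membrane minus the frozen channel contribution
    g_leak <- pas$g_mem
    for (nm in names(channels)) {
      chs <- channels[[nm]]
      ch <- chs$channel; ch$e_rev <- chs$e_rev
      for (i in seq_len(n)) {
        cc <- lapply(eqL$conc, function(z) z[i])
        ss <- steady_state(ch, v_eq[i], cc)
        g_leak[i] <- g_leak[i] - chs$g[i] * ss$p_open
      }
    }

    fit <- structure(list(
      nodes = data.frame(comp = seq_len(n), loc_index = seq_len(n),
                         parent = parent, g_c = pas$g_c, ca = ca,
                         g_leak = g_leak, e_leak = rep(-70, n)),
      channels = channels, pools = list(), locations = locs_ext
    ), class = "comp_tree_fit")

    stage <- "fit_concentration"
    for (ion in names(tree$phys$pools))
      fit <- fit_concentration(tree, fit, ion)

    stage <- "fit_equilibrium_reversals"
    # iterate to self-consistency: the reduced pool's equilibrium
    # concentration feeds back into the reversal placement
    conc_cur <- eqL$conc
    for (it in 1:4) {
      fit <- fit_equilibrium_reversals(fit, v_eq, conc_cur)
      if (!length(fit$pools)) break
      eq_red <- steady_state_system(as_comp_system(fit))
      if (max(abs(eq_red$v - v_eq)) < 1e-9) break
      conc_cur <- eq_red$conc
    }

    structure(list(comp_tree = fit, locations = locs_ext,
                   residuals = list(passive = pas$residual,
                                    channels = ch_resid),
                   v_eq = v_eq, holdings = hold),
              class = "fit_result")
  }, error = function(e)
    stop("reduction failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE))
  out
}

.node_cinf <- function(tree, id) {
  if (!length(tree$phys$pools)) return(NULL)
  out <- lapply(tree$phys$pools, function(p) {
    v <- p$cinf[[id]]
    if (is.na(v)) 0 else v
  })
  out
}

#' Concentration-pool fit by ionic-current rescaling
#'
#' Pool time constants and resting concentrations are copied from the full
#' model at the fit locations; the current-to-concentration factor is
#' rescaled by the ratio of the full model's local carrying conductance
#' (per area, times the compartment's nominal surface) to the fitted total
#' carrying conductance, so that the concentration response to the fitted
#' ionic current matches the full model's local response. Exact for
#' iso-potential reductions.
#'
#' @param tree the full model.
#' @param fit a `comp_tree_fit` with channel fits done.
#' @param ion pooled ion name.
#' @return the fit with the pool attached.
#' @export
fit_concentration <- function(tree, fit, ion) {
  pool <- tree$phys$pools[[ion]]
  if (is.null(pool)) stop("no pool for ion '", ion, "'", call. = FALSE)
  locs <- fit$locations
  n <- nrow(locs)
  ids <- as.character(locs$node)
  carriers <- Filter(function(chs) chs$channel$ion == ion, fit$channels)
  if (!length(carriers))
    stop("no fitted channels carry ion '", ion, "'", call. = FALSE)
  g_fit <- Reduce(`+`, lapply(carriers, function(chs) chs$g))
  g_full_dens <- Reduce(`+`, lapply(names(carriers), function(nm)
    tree$phys$channels[[nm]]$gmax[ids] * .G_FACT))
  if (all(g_fit <= 0))
    stop("zero fitted conductance for ion '", ion, "'", call. = FALSE)
  gamma_p <- tau_p <- cinf_p <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.na(pool$tau[[ids[i]]]) || g_fit[i] <= 0) next
    gamma_p[i] <- pool$gamma[[ids[i]]] * g_full_dens[i] / g_fit[i]
    tau_p[i] <- pool$tau[[ids[i]]]
    cinf_p[i] <- pool$cinf[[ids[i]]]
  }
  fit$pools[[ion]] <- list(gamma = gamma_p, tau = tau_p, cinf = cinf_p)
  fit
}

#' Leak-reversal fit matching the equilibrium potentials
#'
#' Solves the compartment steady-state balance for `e_leak`:
#' `e_leak_i = v_i + (sum_c gbar_c o_c (v_i - e_c) +
#' sum_j g_c (v_i - v_j)) / g_leak_i`, with `v` the full model's
#' equilibrium at the fit locations; the reduced model's equilibrium then
#' equals `v` exactly.
#'
#' @param fit a `comp_tree_fit`.
#' @param v_eq equilibrium potentials at the fit locations, mV.
#' @param conc_eq named list of equilibrium concentrations at the fit
#'   locations.
#' @return the fit with `e_leak` set.
#' @export
fit_equilibrium_reversals <- function(fit, v_eq, conc_eq = list()) {
  nd <- fit$nodes
  n <- nrow(nd)
  if (any(nd$g_leak <= 0))
    stop("non-positive fitted leak; cannot place reversals", call. = FALSE)
  imem <- rep(0, n)
  for (nm in names(fit$channels)) {
    chs <- fit$channels[[nm]]
    for (i in seq_len(n)) {
      cc <- lapply(conc_eq, function(z) z[i])
      ss <- steady_state(chs$channel, v_eq[i], cc)
      imem[i] <- imem[i] + chs$g[i] * ss$p_open * (v_eq[i] - chs$e_rev)
    }
  }
  iax <- rep(0, n)
  for (i in seq_len(n)) if (nd$parent[i] > 0L) {
    j <- nd$parent[i]
    iax[i] <- iax[i] + nd$g_c[i] * (v_eq[i] - v_eq[j])
    iax[j] <- iax[j] + nd$g_c[i] * (v_eq[j] - v_eq[i])
  }
  fit$nodes$e_leak <- v_eq + (imem + iax) / nd$g_leak
  fit
}

#' @export
print.comp_tree_fit <- function(x, ...) {
  cat(sprintf("<comp_tree_fit> %d compartments, %d channel type(s), %d pool(s)\n",
              nrow(x$nodes), length(x$channels), length(x$pools)))
  invisible(x)
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %d compartments\n", nrow(x$comp_tree$nodes)))
  cat(sprintf("  passive residual ||ZG-I||_F = %.3g\n", x$residuals$passive))
  invisible(x)
}

#' Convert a fitted reduction to a simulatable system
#'
#' @param fit a `comp_tree_fit` or `fit_result`.
#' @return a `comp_system` for [integrate_system()] /
#'   [steady_state_system()].
#' @export
as_comp_system <- function(fit) {
  if (inherits(fit, "fit_result")) fit <- fit$comp_tree
  nd <- fit$nodes
  n <- nrow(nd)
  structure(list(
    n = n, parent = nd$parent, gc = nd$g_c,
    area = rep(NA_real_, n), ca = nd$ca, gl = nd$g_leak, el = nd$e_leak,
    channels = fit$channels,
    pools = fit$pools,
    locs = NULL, stimuli = list()
  ), class = "comp_system")
}

#' Kernel comparison between full and reduced model
#'
#' Computes the passive (passified) input and transfer response kernels of
#' the full model (Fourier inversion) and of the reduction (eigen
#' decomposition of the reduced system), for all `N (N + 1) / 2` location
#' pairs, together with a maximal-deviation summary per pair (relative to
#' that pair's kernel peak).
#'
#' @param tree the full model.
#' @param fit a `fit_result`.
#' @param t_grid times, ms.
#' @return data.frame with columns `i`, `j`, `t_ms`, `k_full`, `k_reduced`;
#'   the summary is in `attr(, "summary")`.
#' @export
plot_kernels <- function(tree, fit,
                         t_grid = exp(seq(log(0.5), log(80),
                                          length.out = 40))) {
  locs <- fit$locations
  n <- nrow(locs)
  ct <- fit$comp_tree
  eqN <- steady_state_tree(tree, dx = 5)
  gt <- .make_linear_tree(tree, eqN$v, passified = TRUE)
  # reduced passified membrane conductance
  g_mem <- ct$nodes$g_leak
  for (nm in names(ct$channels)) {
    chs <- ct$channels[[nm]]
    for (i in seq_len(n)) {
      cc <- lapply(ct$pools, function(p) p$cinf[i] %||% 0)
      names(cc) <- names(ct$pools)
      cc <- cc[!vapply(cc, is.na, logical(1))]
      ss <- steady_state(chs$channel, fit$v_eq[i], cc)
      g_mem[i] <- g_mem[i] + chs$g[i] * ss$p_open
    }
  }
  G <- .G_of(g_mem, ct$nodes$g_c, ct$nodes$parent)
  Cm <- ct$nodes$ca
  M <- diag(1 / sqrt(Cm), n) %*% G %*% diag(1 / sqrt(Cm), n)
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  U <- diag(1 / sqrt(Cm), n) %*% eg$vectors
  out <- list()
  summ <- list()
  for (i in seq_len(n)) for (j in i:n) {
    kf <- kernel_from_impedance(gt, locs[i, ], locs[j, ], t_grid)$values
    kr <- vapply(t_grid, function(t)
      sum(U[i, ] * U[j, ] * exp(-eg$values * t)), numeric(1))
    out[[length(out) + 1L]] <- data.frame(i = i, j = j, t_ms = t_grid,
                                          k_full = kf, k_reduced = kr)
    summ[[length(summ) + 1L]] <- data.frame(
      i = i, j = j, max_dev = max(abs(kf - kr)) / max(abs(kf)))
  }
  res <- do.call(rbind, out)
  attr(res, "summary") <- do.call(rbind, summ)
  res
}
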