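#' Compartmental systems by second-order finite differences
#'
#' [discretize_fd()] turns a full morphological model into a tree of
#' iso-potential compartments placed at cylinder-interior grid centers with
#' spacing at most `dx_max` (or at most `lambda_fraction` of the local DC
#' length constant). Axial coupling between adjacent centers is
#' `g = pi R^2 / (r_a dx)`, with the series combination of half-steps
#' across radius changes and junctions; the soma is lumped into a single
#' compartment. The resulting `comp_system` is what [integrate_system()]
#' simulates; reduced models from the fitting pipeline are converted with
#' [as_comp_system()].
#'
#' @param tree a [morph_tree] with physiology.
#' @param dx_max maximal grid spacing, um.
#' @param lambda_fraction optional: use per-cylinder spacing
#'   `lambda_fraction * lambda(0)` instead of `dx_max`.
#' @return an object of class `comp_system`.
#' @export
discretize_fd <- function(tree, dx_max = 10, lambda_fraction = NULL) {
  if (is.null(tree$phys)) stop("physiology has not been set", call. = FALSE)
  if (dx_max <= 0) stop("dx_max must be > 0", call. = FALSE)
  grid <- .fd_grid(tree, dx_max, lambda_fraction)
  ph <- tree$phys
  ids <- as.character(grid$node)
  sys <- list(
    n = nrow(grid),
    parent = grid$parent_comp,
    gc = unname(grid$gc),
    area = unname(grid$area),
    ca = unname(grid$area * ph$cm[ids] * .C_FACT),
    gl = unname(grid$area * ph$gl[ids] * .G_FACT),
    el = unname(ph$el[ids]),
    channels = lapply(ph$channels, function(chs) list(
      channel = chs$channel,
      g = unname(grid$area * chs$gmax[ids] * .G_FACT),
      e_rev = chs$e_rev)),
    pools = lapply(ph$pools, function(p) list(
      gamma = unname(ifelse(is.na(p$gamma[ids]) | grid$area == 0, NA,
                            p$gamma[ids] / pmax(grid$area, 1e-300))),
      tau = unname(p$tau[ids]), cinf = unname(p$cinf[ids]))),
    locs = data.frame(node = grid$node, x = grid$x),
    stimuli = list()
  )
  structure(sys, class = "comp_system")
}

# shared discretization geometry: compartments with parents and couplings
.fd_grid <- function(tree, dx_max, lambda_fraction = NULL) {
  nd <- tree$nodes
  ph <- tree$phys
  ids <- as.character(nd$index)
  ra <- ph$ra[ids] * .RA_FACT              # MOhm*um
  out <- list()
  # soma compartment (root)
  soma_area <- if (isTRUE(tree$soma_point)) 0 else 4 * pi * nd$radius[1L]^2
  out[[1L]] <- data.frame(node = nd$index[1L], x = 0, area = soma_area,
                          parent_comp = 0L, gc = 0,
                          half_r = 0, comp0 = 1L)
  last_comp_of_node <- integer(nrow(nd)); last_comp_of_node[1L] <- 1L
  ncomp <- 1L
  for (i in seq_len(nrow(nd))[-1L]) {
    L <- nd$length[i]; R <- nd$radius[i]
    dx <- dx_max
    if (!is.null(lambda_fraction)) {
      gl <- ph$gl[ids[i]] * .G_FACT
      # DC length constant of the cylinder, um
      lam <- sqrt((pi * R^2 / ra[i]) / (2 * pi * R * max(gl, 1e-12)))
      dx <- min(dx_max, lambda_fraction * lam)
    }
    nseg <- max(1L, ceiling(L / dx))
    dxl <- L / nseg
    r_half <- ra[i] * (dxl / 2) / (pi * R^2)   # MOhm per half step
    prow <- .node_row(tree, nd$parent[i])
    for (k in seq_len(nseg)) {
      ncomp <- ncomp + 1L
      if (k == 1L) {
        pc <- last_comp_of_node[prow]
        rser <- r_half + out[[pc]]$half_r
      } else {
        pc <- ncomp - 1L
        rser <- 2 * r_half
      }
      out[[ncomp]] <- data.frame(node = nd$index[i], x = (k - 0.5) / nseg,
                                 area = 2 * pi * R * dxl,
                                 parent_comp = pc, gc = 1 / rser,
                                 half_r = r_half, comp0 = ncomp)
    }
    last_comp_of_node[i] <- ncomp
    # explicit zero-area junction compartment at branch points, so that all
    # half-steps meet in a single potential (second-order at junctions)
    if (length(tree$children[[i]]) >= 2L) {
      ncomp <- ncomp + 1L
      out[[ncomp]] <- data.frame(node = nd$index[i], x = 1, area = 0,
                                 parent_comp = ncomp - 1L, gc = 1 / r_half,
                                 half_r = 0, comp0 = ncomp)
      last_comp_of_node[i] <- ncomp
    }
  }
  do.call(rbind, out)
}

#' @export
print.comp_system <- function(x, ...) {
  cat(sprintf("<comp_system> %d compartments, %d channel type(s), %d pool(s)\n",
              x$n, length(x$channels), length(x$pools)))
  invisible(x)
}

# axial conductance matrix (Laplacian, uS), sparse
.axial_matrix <- function(sys) {
  n <- sys$n
  i <- which(sys$parent > 0L)
  p <- sys$parent[i]
  g <- sys$gc[i]
  Matrix::sparseMatrix(
    i = c(i, p, i, p), j = c(p, i, i, p), x = c(-g, -g, g, g),
    dims = c(n, n))
}

# nearest compartment to each location (arc-length on the same node chain)
.nearest_comp <- function(sys, tree, locs) {
  df <- as_locations(tree, locs)
  d_loc <- soma_distance(tree, df)
  d_cmp <- soma_distance(tree, sys$locs)
  vapply(seq_len(nrow(df)), function(r) {
    cand <- which(sys$locs$node == df$node[r])
    if (df$node[r] == tree$root) return(1L)
    if (!length(cand)) {
      # location canonicalized to a parent x=1: child compartments also match
      cand <- seq_len(sys$n)
    }
    cand[which.min(abs(d_cmp[cand] - d_loc[r]))]
  }, integer(1))
}

#' Finite-difference impedance matrix (oracle for the analytic engine)
#'
#' Builds the compartmental system matrix
#' `G(omega) = G_axial + diag(area (g_lin(omega) + i omega c_m))` on a fine
#' grid and solves it for unit current injections, giving the discrete
#' impedance matrix at the compartments nearest the requested locations.
#' Converges to the continuous Green's function with order 2 in `dx`.
#'
#' @param gt a `greens_tree`.
#' @param locs locations.
#' @param dx grid spacing, um.
#' @param omega a single angular frequency, rad/ms.
#' @return complex (or real at `omega = 0`) matrix, MOhm.
#' @export
fd_impedance_matrix <- function(gt, locs, dx = 1, omega = 0) {
  wt <- gt$work
  grid <- .fd_grid(wt, dx)
  n <- nrow(grid)
  iw <- 1i * omega
  ids <- as.character(grid$node)
  gdens <- vapply(seq_len(n), function(k) .eval_glin(gt$nodes[[ids[k]]], iw),
                  complex(1))
  cdens <- vapply(ids, function(id) gt$nodes[[id]]$cm, numeric(1))
  gmem <- grid$area * (gdens + iw * cdens)
  i <- which(grid$parent_comp > 0L)
  p <- grid$parent_comp[i]
  g <- grid$gc[i]
  lw <- .work_locs(gt, locs)
  # linear interpolation weights between the two compartment centers that
  # bracket each location along its cable chain (second-order accurate;
  # clamped at sealed ends where the spatial gradient vanishes)
  W <- .loc_weights(wt, grid, lw)
  rows <- W$rows; wts <- W$w
  inj <- sort(unique(unlist(rows)))
  if (omega == 0) {
    Gax <- Matrix::sparseMatrix(i = c(i, p, i, p), j = c(p, i, i, p),
                                x = c(-g, -g, g, g), dims = c(n, n))
    A <- Gax + Matrix::Diagonal(n, Re(gmem))
    rhs <- matrix(0, n, length(inj))
    for (k in seq_along(inj)) rhs[inj[k], k] <- 1
    V <- as.matrix(Matrix::solve(A, rhs))
  } else {
    # complex case: dense solve (sparse complex is not supported)
    A <- matrix(0 + 0i, n, n)
    A[cbind(c(i, p), c(p, i))] <- -c(g, g)
    diagsum <- numeric(n)
    for (k in seq_along(i)) {
      diagsum[i[k]] <- diagsum[i[k]] + g[k]
      diagsum[p[k]] <- diagsum[p[k]] + g[k]
    }
    diag(A) <- diagsum + gmem
    rhs <- matrix(0 + 0i, n, length(inj))
    for (k in seq_along(inj)) rhs[inj[k], k] <- 1
    V <- solve(A, rhs)
  }
  colnames(V) <- inj
  m <- nrow(lw)
  Z <- if (omega == 0) matrix(0, m, m) else matrix(0 + 0i, m, m)
  for (a in seq_len(m)) for (b in seq_len(m)) {
    acc <- if (omega == 0) 0 else 0 + 0i
    if (a == b) {
      # interpolate along the (smooth) diagonal: the off-diagonal surface
      # has a derivative kink at the injection site
      for (u in seq_along(rows[[a]]))
        acc <- acc + wts[[a]][u] * V[rows[[a]][u], as.character(rows[[a]][u])]
    } else {
      for (u in seq_along(rows[[a]])) for (s in seq_along(rows[[b]]))
        acc <- acc + wts[[a]][u] * wts[[b]][s] *
          V[rows[[a]][u], as.character(rows[[b]][s])]
    }
    Z[a, b] <- acc
  }
  Z
}

# interpolation stencil: for each location, the compartment centers that
# bracket it along its cable chain (ancestor path plus single-child
# descendants) and the linear weights; clamped to the nearest center at
# chain ends
.loc_weights <- function(wt, grid, lw) {
  sys_like <- list(n = nrow(grid),
                   locs = data.frame(node = grid$node, x = grid$x))
  d_cmp <- soma_distance(wt, sys_like$locs)
  rows <- vector("list", nrow(lw))
  wts <- vector("list", nrow(lw))
  for (r in seq_len(nrow(lw))) {
    if (lw$node[r] == wt$root) {
      rows[[r]] <- 1L; wts[[r]] <- 1; next
    }
    chain <- .root_path(wt, lw$node[r])
    # extend through single-child descendants
    cur <- lw$node[r]
    repeat {
      ch <- wt$children[[.node_row(wt, cur)]]
      if (length(ch) != 1L) break
      cur <- ch
      chain <- c(chain, cur)
    }
    cand <- which(grid$node %in% chain)
    s <- soma_distance(wt, lw[r, , drop = FALSE])
    dd <- d_cmp[cand]
    o <- order(dd)
    cand <- cand[o]; dd <- dd[o]
    if (length(cand) < 2L) { rows[[r]] <- cand[1L]; wts[[r]] <- 1; next }
    hi <- which(dd >= s)[1L]
    if (is.na(hi)) hi <- length(dd)          # beyond last center: extrapolate
    hi <- max(hi, 2L)
    lo <- hi - 1L
    w_hi <- (s - dd[lo]) / (dd[hi] - dd[lo])
    rows[[r]] <- c(cand[lo], cand[hi])
    wts[[r]] <- c(1 - w_hi, w_hi)
  }
  list(rows = rows, w = wts)
}

# ---- membrane currents and steady state ------------------------------------

# total membrane current (nA) and its state, given v (mV) and conc (list)
.channel_states_inf <- function(sys, v, conc) {
  lapply(sys$channels, function(chs) {
    ch <- chs$channel
    env <- c(list(v = v), conc)
    ys <- lapply(ch$statevars, function(sv) {
      g <- ch$gating[[sv]]
      if (g$style == "ab") {
        a <- eval(g$alpha, env); b <- eval(g$beta, env)
        a / (a + b)
      } else eval(g$inf, env)
    })
    names(ys) <- ch$statevars
    ys
  })
}

.channel_current <- function(sys, v, states) {
  itot <- numeric(length(v))
  by_ion <- list()
  for (nm in names(sys$channels)) {
    chs <- sys$channels[[nm]]
    p <- eval(chs$channel$p_open, states[[nm]])
    icur <- chs$g * p * (v - chs$e_rev)
    itot <- itot + icur
    ion <- chs$channel$ion
    if (ion != "none")
      by_ion[[ion]] <- (by_ion[[ion]] %||% 0) + icur
  }
  list(total = itot, by_ion = by_ion)
}

#' Steady state (equilibrium) of a compartmental system
#'
#' Damped Newton iteration on the nonlinear DC system: channels at their
#' steady-state activation, concentration pools at the balance
#' `c = c_inf - gamma tau i_ion`. Converges to a residual below `tol` (in
#' mV, measured as the Newton update norm).
#'
#' @param sys a `comp_system`.
#' @param tol convergence tolerance, mV.
#' @param max_iter maximal Newton iterations.
#' @return list with `v` (mV per compartment) and `conc` (named list of mM
#'   vectors), plus the final `residual` (nA).
#' @export
steady_state_system <- function(sys, tol = 1e-10, max_iter = 200) {
  n <- sys$n
  Gax <- as.matrix(.axial_matrix(sys))
  v <- sys$el
  conc <- lapply(sys$pools, function(p) ifelse(is.na(p$cinf), 0, p$cinf))
  imem <- function(v, conc) {
    st <- .channel_states_inf(sys, v, conc)
    sys$gl * (v - sys$el) + .channel_current(sys, v, st)$total
  }
  resid_fun <- function(v, conc) drop(Gax %*% v) + imem(v, conc)
  for (outer in 1:8) {
    for (it in seq_len(max_iter)) {
      Fv <- resid_fun(v, conc)
      # numeric diagonal Jacobian of the membrane current
      dv <- 1e-4
      dmem <- (imem(v + dv, conc) - imem(v - dv, conc)) / (2 * dv)
      J <- Gax
      diag(J) <- diag(Gax) + dmem
      step <- tryCatch(solve(J, Fv), error = function(e) NULL)
      if (is.null(step)) stop("singular Jacobian in steady state",
                              call. = FALSE)
      lam <- 1
      repeat {
        vn <- v - lam * step
        if (max(abs(resid_fun(vn, conc))) <= max(abs(Fv)) || lam < 1e-4)
          break
        lam <- lam / 2
      }
      v <- vn
      if (max(abs(lam * step)) < tol) break
    }
    if (it == max_iter) stop("steady-state Newton did not converge",
                             call. = FALSE)
    # update pool concentrations from the ionic currents
    changed <- FALSE
    st <- .channel_states_inf(sys, v, conc)
    ic <- .channel_current(sys, v, st)
    for (ion in names(sys$pools)) {
      p <- sys$pools[[ion]]
      ii <- ic$by_ion[[ion]] %||% numeric(n)
      ok <- !is.na(p$tau) & !is.na(p$gamma)
      cn <- conc[[ion]]
      cn[ok] <- pmax(0, p$cinf[ok] - p$gamma[ok] * p$tau[ok] * ii[ok])
      if (max(abs(cn - conc[[ion]]), 0) > 1e-12) changed <- TRUE
      conc[[ion]] <- cn
    }
    if (!changed) break
  }
  list(v = v, conc = conc, residual = max(abs(resid_fun(v, conc))))
}

#' Equilibrium potential profile of a full model
#'
#' Discretizes the tree on a fine grid, solves the DC system, and reports
#' the equilibrium potential (and pool concentrations) per node of the
#' tree, or at requested locations.
#'
#' @param tree a [morph_tree] with physiology.
#' @param locs optional locations; when given, values at those locations
#'   are returned instead of the per-node profile.
#' @param dx discretization step, um.
#' @return list with `v` (named by node index, or per location) and `conc`.
#' @export
steady_state_tree <- function(tree, locs = NULL, dx = 10) {
  sys <- discretize_fd(tree, dx_max = dx)
  eq <- steady_state_system(sys)
  if (is.null(locs)) {
    ids <- tree$nodes$index
    rows <- .nearest_comp(sys, tree,
                          data.frame(node = ids,
                                     x = c(0, rep(1, length(ids) - 1L))))
    list(v = stats::setNames(eq$v[rows], ids),
         conc = lapply(eq$conc, function(cc) stats::setNames(cc[rows], ids)),
         residual = eq$residual)
  } else {
    rows <- .nearest_comp(sys, tree, locs)
    list(v = eq$v[rows],
         conc = lapply(eq$conc, function(cc) cc[rows]),
         residual = eq$residual)
  }
}

# ---- stimuli ---------------------------------------------------------------

#' Stimuli for compartmental simulations
#'
#' `stim_step()` and `stim_pulse()` inject current (nA) into a target
#' compartment between `onset` and `offset` (ms). `stim_synapse()` attaches
#' a conductance-based synapse with double-exponential kinetics
#' `g(t) = gmax N (exp(-t/tau_d) - exp(-t/tau_r))` per spike, normalized so
#' the peak equals `gmax`; receptor kinds set the defaults: AMPA
#' (tau_r 0.2, tau_d 3 ms, reversal 0 mV), GABA (tau_r 0.2, tau_d 10 ms,
#' reversal -80 mV) and NMDA (tau_r 2, tau_d 40 ms, reversal 0 mV with the
#' sigmoidal magnesium block `1/(1 + 0.3 [Mg] exp(-0.1 v))`, `[Mg]` = 1 mM).
#' Spike trains are given explicitly or generated as a Poisson train with
#' `rate` (1/ms) up to `t_max`, reproducibly from `seed`.
#'
#' @param target compartment index.
#' @param amp current amplitude, nA.
#' @param onset,offset stimulus window, ms.
#' @return a `stimulus` object for [add_stimulus()].
#' @export
stim_step <- function(target, amp, onset, offset = Inf) {
  structure(list(kind = "current", target = target, amp = amp,
                 onset = onset, offset = offset), class = "stimulus")
}

#' @rdname stim_step
#' @param width pulse width, ms.
#' @export
stim_pulse <- function(target, amp, onset, width = 0.1) {
  stim_step(target, amp, onset, onset + width)
}

#' @rdname stim_step
#' @param kind `"AMPA"`, `"NMDA"` or `"GABA"`.
#' @param gmax peak conductance, uS.
#' @param spike_times explicit presynaptic spike times, ms.
#' @param rate Poisson rate, spikes/ms (used when `spike_times` is NULL).
#' @param t_max end of the Poisson train, ms.
#' @param seed RNG seed for the Poisson train.
#' @param tau_r,tau_d rise/decay time constants, ms (defaults by kind).
#' @param e_rev synaptic reversal, mV (default by kind).
#' @export
stim_synapse <- function(target, kind = c("AMPA", "NMDA", "GABA"),
                         gmax = 1e-3, spike_times = NULL, rate = NULL,
                         t_max = NULL, seed = 1L,
                         tau_r = NULL, tau_d = NULL, e_rev = NULL) {
  kind <- match.arg(kind)
  defs <- switch(kind,
    AMPA = list(tau_r = 0.2, tau_d = 3, e_rev = 0),
    NMDA = list(tau_r = 2, tau_d = 40, e_rev = 0),
    GABA = list(tau_r = 0.2, tau_d = 10, e_rev = -80))
  tau_r <- tau_r %||% defs$tau_r
  tau_d <- tau_d %||% defs$tau_d
  e_rev <- e_rev %||% defs$e_rev
  if (is.null(spike_times)) {
    if (is.null(rate) || is.null(t_max))
      stop("supply spike_times, or rate and t_max", call. = FALSE)
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
    n_exp <- max(10, ceiling(rate * t_max * 3))
    st <- cumsum(stats::rexp(n_exp, rate))
    spike_times <- st[st <= t_max]
  }
  if (any(spike_times < 0)) stop("spike times must be >= 0", call. = FALSE)
  # peak normalization of the double exponential
  rr <- tau_r / tau_d
  N <- 1 / (rr^(tau_r / (tau_d - tau_r)) - rr^(tau_d / (tau_d - tau_r)))
  structure(list(kind = "synapse", receptor = kind, target = target,
                 gmax = gmax, tau_r = tau_r, tau_d = tau_d, e_rev = e_rev,
                 norm = N, spike_times = sort(spike_times)),
            class = "stimulus")
}

#' Attach a stimulus to a compartmental system
#' @param sys a `comp_system`.
#' @param stimulus a `stimulus` object.
#' @return the modified system.
#' @export
add_stimulus <- function(sys, stimulus) {
  if (!inherits(stimulus, "stimulus")) stop("unknown stimulus", call. = FALSE)
  if (stimulus$target < 1L || stimulus$target > sys$n)
    stop("stimulus target outside system", call. = FALSE)
  sys$stimuli <- c(sys$stimuli, list(stimulus))
  sys
}

# ---- time integration ------------------------------------------------------

#' Integrate a compartmental system
#'
#' Implicit integration: backward-Euler voltage step (direct solve of the
#' tree-structured linear system) with staggered gating: state variables
#' are advanced by exact exponential integration of the linear gating ODE
#' at frozen voltage, and pool concentrations by exact exponential
#' integration at frozen ionic current. Deterministic; records every
#' `dt` multiple.
#'
#' @param sys a `comp_system` (with stimuli attached).
#' @param t_end total simulated time, ms.
#' @param dt time step, ms.
#' @param record compartment indices to record (default: all).
#' @param v0 initial voltage: `"equilibrium"` (default; solved with
#'   [steady_state_system()]) or a numeric vector/scalar.
#' @return a `sim_traces` object: list with `t` (ms), `v` (matrix, time by
#'   recorded compartment, mV) and `conc` (named list of matrices, mM).
#' @export
integrate_system <- function(sys, t_end, dt = 0.025, record = NULL,
                             v0 = "equilibrium") {
  stopifnot(t_end > 0, dt > 0)
  n <- sys$n
  record <- record %||% seq_len(n)
  Gax <- as.matrix(.axial_matrix(sys))
  if (identical(v0, "equilibrium")) {
    eq <- steady_state_system(sys)
    v <- eq$v; conc <- eq$conc
  } else {
    v <- rep(v0, length.out = n)
    conc <- lapply(sys$pools, function(p) ifelse(is.na(p$cinf), 0, p$cinf))
  }
  states <- .channel_states_inf(sys, v, conc)
  # synapse state
  syns <- Filter(function(s) s$kind == "synapse", sys$stimuli)
  curs <- Filter(function(s) s$kind == "current", sys$stimuli)
  syn_a <- syn_b <- rep(0, length(syns))
  syn_decay_r <- vapply(syns, function(s) exp(-dt / s$tau_r), numeric(1))
  syn_decay_d <- vapply(syns, function(s) exp(-dt / s$tau_d), numeric(1))
  syn_ptr <- rep(1L, length(syns))

  nt <- floor(t_end / dt + 1e-9)
  tout <- seq(0, by = dt, length.out = nt + 1L)
  Vrec <- matrix(NA_real_, nt + 1L, length(record))
  Crec <- lapply(sys$pools, function(p) matrix(NA_real_, nt + 1L,
                                               length(record)))
  Vrec[1L, ] <- v[record]
  for (ion in names(sys$pools)) Crec[[ion]][1L, ] <- conc[[ion]][record]

  cdt <- sys$ca / dt
  base_diag <- diag(Gax) + cdt + sys$gl
  A <- Gax
  has_ch <- length(sys$channels) > 0L
  for (step in seq_len(nt)) {
    t_new <- step * dt
    # 1. gating update at frozen v (exact exponential step)
    if (has_ch) {
      env <- c(list(v = v), conc)
      for (nm in names(sys$channels)) {
        ch <- sys$channels[[nm]]$channel
        for (sv in ch$statevars) {
          g <- ch$gating[[sv]]
          if (g$style == "ab") {
            a <- eval(g$alpha, env); b <- eval(g$beta, env)
            yinf <- a / (a + b); ty <- 1 / (ch$q10 * (a + b))
          } else {
            yinf <- eval(g$inf, env); ty <- eval(g$tau, env) / ch$q10
          }
          yv <- states[[nm]][[sv]]
          states[[nm]][[sv]] <- yinf + (yv - yinf) * exp(-dt / ty)
        }
      }
    }
    # 2. synapse states: decay + spikes in (t_old, t_new]
    if (length(syns)) for (k in seq_along(syns)) {
      syn_a[k] <- syn_a[k] * syn_decay_r[k]
      syn_b[k] <- syn_b[k] * syn_decay_d[k]
      st <- syns[[k]]$spike_times
      while (syn_ptr[k] <= length(st) && st[syn_ptr[k]] <= t_new) {
        syn_a[k] <- syn_a[k] + 1
        syn_b[k] <- syn_b[k] + 1
        syn_ptr[k] <- syn_ptr[k] + 1L
      }
    }
    # 3. assemble and solve the backward-Euler voltage system
    gch <- rep(0, n); rch <- rep(0, n)
    if (has_ch) for (nm in names(sys$channels)) {
      chs <- sys$channels[[nm]]
      p <- eval(chs$channel$p_open, states[[nm]])
      gch <- gch + chs$g * p
      rch <- rch + chs$g * p * chs$e_rev
    }
    gsyn <- rep(0, n); rsyn <- rep(0, n)
    if (length(syns)) for (k in seq_along(syns)) {
      s <- syns[[k]]
      gk <- s$gmax * s$norm * (syn_b[k] - syn_a[k])
      if (s$receptor == "NMDA")
        gk <- gk / (1 + 0.3 * 1 * exp(-0.1 * v[s$target]))
      gsyn[s$target] <- gsyn[s$target] + gk
      rsyn[s$target] <- rsyn[s$target] + gk * s$e_rev
    }
    iinj <- rep(0, n)
    if (length(curs)) for (s in curs)
      if (t_new > s$onset && t_new <= s$offset)
        iinj[s$target] <- iinj[s$target] + s$amp
    diag(A) <- base_diag + gch + gsyn
    rhs <- cdt * v + sys$gl * sys$el + rch + rsyn + iinj
    v <- solve(A, rhs)
    if (any(!is.finite(v)) || max(abs(v)) > 1e3)
      stop("integration diverged at t = ", t_new, " ms", call. = FALSE)
    # 4. pool concentrations: exact exponential step at frozen current
    if (length(sys$pools)) {
      ic <- .channel_current(sys, v, states)
      for (ion in names(sys$pools)) {
        p <- sys$pools[[ion]]
        ii <- ic$by_ion[[ion]] %||% rep(0, n)
        ok <- !is.na(p$tau) & !is.na(p$gamma)
        css <- p$cinf[ok] - p$gamma[ok] * p$tau[ok] * ii[ok]
        conc[[ion]][ok] <- pmax(css + (conc[[ion]][ok] - css) *
                                  exp(-dt / p$tau[ok]), 0)
      }
    }
    Vrec[step + 1L, ] <- v[record]
    for (ion in names(sys$pools))
      Crec[[ion]][step + 1L, ] <- conc[[ion]][record]
  }
  structure(list(t = tout, v = Vrec, conc = Crec, record = record),
            class = "sim_traces")
}

#' @export
print.sim_traces <- function(x, ...) {
  cat(sprintf("<sim_traces> %d time points, %d compartment(s)\n",
              length(x$t), ncol(x$v)))
  invisible(x)
}

#' @export
as.data.frame.sim_traces <- function(x, ...) {
  df <- data.frame(t_ms = x$t)
  for (j in seq_len(ncol(x$v)))
    df[[paste0("v_", x$record[j])]] <- x$v[, j]
  for (ion in names(x$conc))
    for (j in seq_len(ncol(x$conc[[ion]])))
      df[[paste0(ion, "_", x$record[j])]] <- x$conc[[ion]][, j]
  df
}

#' Detect spikes as upward threshold crossings
#'
#' @param times uniform time grid, ms.
#' @param v voltage trace, mV.
#' @param threshold threshold, mV.
#' @param refractory lockout after each detection, ms.
#' @return numeric vector of spike times, ms.
#' @export
detect_spikes <- function(times, v, threshold = -20, refractory = 1) {
  up <- which(v[-1L] >= threshold & v[-length(v)] < threshold) + 1L
  if (!length(up)) return(numeric(0))
  st <- times[up]
  # enforce the lockout sequentially
  out <- numeric(0)
  last <- -Inf
  for (s in st) {
    if (s - last > refractory) { out <- c(out, s); last <- s }
  }
  out
}
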