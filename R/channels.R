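#' Hodgkin-Huxley style ion channels, defined symbolically
#'
#' A channel is specified by an open-probability expression `p_open` in its
#' state variables, and per state variable either rate functions
#' `alpha(v, ...)` / `beta(v, ...)` or the equivalent steady-state /
#' time-constant pair `inf(v, ...)` / `tau(v, ...)`. Expressions are R
#' expressions in `v` (mV), the state-variable names, and optionally ion
#' concentration names (mM) listed in `conc_deps`. The gating dynamics are
#' the standard first-order relaxation
#' `dy/dt = alpha(v) (1 - y) - beta(v) y`, i.e.
#' `dy/dt = (y_inf(v) - y) / tau_y(v)` with `y_inf = alpha/(alpha+beta)` and
#' `tau_y = 1/(alpha+beta)`. A temperature factor `q10` multiplies all rates
#' (divides all time constants); it leaves steady states untouched.
#'
#' @param name channel name.
#' @param p_open open probability: a string parsed as an R expression in the
#'   state-variable names.
#' @param gating named list, one entry per state variable, each a list with
#'   either elements `alpha` and `beta` or elements `inf` and `tau`
#'   (strings or expressions in `v` and any declared concentration).
#' @param ion ion carried: one of `"na"`, `"k"`, `"ca"`, `"none"`.
#' @param e_rev reversal potential, mV; when `NULL` a default is assigned by
#'   ion (na: 50, k: -85, ca: 50).
#' @param q10 rate scale factor (>= 0).
#' @param conc_deps character vector of ion names the gating expressions read.
#' @return an object of class `ion_channel`.
#' @export
ion_channel <- function(name, p_open, gating, ion = "none", e_rev = NULL,
                        q10 = 1, conc_deps = character(0)) {
  ion <- match.arg(ion, c("na", "k", "ca", "none"))
  if (is.null(e_rev)) {
    e_rev <- switch(ion, na = 50, k = -85.0, ca = 50.0,
                    stop("channel '", name,
                         "' carries no ion; e_rev is required", call. = FALSE))
  }
  po <- .parse1(p_open)
  svars <- names(gating)
  used <- all.vars(po)
  if (!all(used %in% svars))
    stop("p_open uses undeclared state variable(s): ",
         paste(setdiff(used, svars), collapse = ", "), call. = FALSE)
  if (!all(svars %in% used))
    stop("gating entries absent from p_open: ",
         paste(setdiff(svars, used), collapse = ", "), call. = FALSE)
  gating <- lapply(gating, function(g) {
    if (all(c("alpha", "beta") %in% names(g)))
      list(style = "ab", alpha = .parse1(g$alpha), beta = .parse1(g$beta))
    else if (all(c("inf", "tau") %in% names(g)))
      list(style = "inftau", inf = .parse1(g$inf), tau = .parse1(g$tau))
    else stop("gating entry must supply alpha/beta or inf/tau", call. = FALSE)
  })
  ch <- structure(list(name = name, p_open = po, gating = gating,
                       statevars = svars, ion = ion, e_rev = e_rev,
                       q10 = q10, conc_deps = conc_deps),
                  class = "ion_channel")
  .check_p_open_range(ch)
  ch
}

.parse1 <- function(e) {
  if (is.character(e)) str2lang(e)
  else if (is.expression(e)) e[[1L]]
  else e
}

.check_p_open_range <- function(ch, n = 64) {
  k <- length(ch$statevars)
  # deterministic quasi-random sample of the unit hypercube
  set <- outer(seq_len(n) - 0.5, sqrt(2 + seq_len(k) * 3)) %% 1
  for (i in seq_len(n)) {
    env <- as.list(set[i, ]); names(env) <- ch$statevars
    p <- eval(ch$p_open, env)
    if (!is.finite(p) || p < -1e-12 || p > 1 + 1e-12)
      stop("p_open of '", ch$name, "' leaves [0, 1] for state values in [0, 1]",
           call. = FALSE)
  }
  invisible(ch)
}

#' @export
print.ion_channel <- function(x, ...) {
  cat(sprintf("<ion_channel> %s (ion %s, e_rev %.1f mV, q10 %g)\n",
              x$name, x$ion, x$e_rev, x$q10))
  cat("  p_open =", deparse(x$p_open), "\n")
  for (sv in x$statevars) {
    g <- x$gating[[sv]]
    if (g$style == "ab")
      cat(sprintf("  %s: alpha = %s ; beta = %s\n", sv,
                  deparse(g$alpha), deparse(g$beta)))
    else
      cat(sprintf("  %s: inf = %s ; tau = %s\n", sv,
                  deparse(g$inf), deparse(g$tau)))
  }
  invisible(x)
}

#' Parse a channel definition from a declarative list or JSON file
#'
#' The structured form mirrors [ion_channel()]: fields `name`, `p_open`,
#' `gating` (named list with `alpha`/`beta` or `inf`/`tau` strings), and
#' optionally `ion`, `e_rev`, `q10`, `conc_deps`.
#'
#' @param definition a named list, or a path to a JSON file containing one.
#' @return an `ion_channel`.
#' @export
parse_channel <- function(definition) {
  if (is.character(definition) && length(definition) == 1L)
    definition <- jsonlite::read_json(definition, simplifyVector = TRUE)
  def <- definition
  ion_channel(name = def$name, p_open = def$p_open,
              gating = lapply(def$gating, as.list),
              ion = def$ion %||% "none",
              e_rev = def$e_rev,
              q10 = def$q10 %||% 1,
              conc_deps = def$conc_deps %||% character(0))
}

#' Serialize a channel definition to JSON
#' @param channel an `ion_channel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_channel <- function(channel, path) {
  g <- lapply(channel$gating, function(gg) {
    if (gg$style == "ab") list(alpha = deparse(gg$alpha),
                               beta = deparse(gg$beta))
    else list(inf = deparse(gg$inf), tau = deparse(gg$tau))
  })
  jsonlite::write_json(
    list(name = channel$name, p_open = deparse(channel$p_open), gating = g,
         ion = channel$ion, e_rev = channel$e_rev, q10 = channel$q10,
         conc_deps = channel$conc_deps),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.gate_env <- function(v, conc) {
  env <- c(list(v = v), as.list(conc %||% numeric(0)))
  env
}

#' Steady state of a channel
#'
#' Returns the steady-state value and time constant of every state variable
#' at membrane potential `v` (and concentrations `conc`), plus the open
#' probability evaluated at the steady state. For alpha/beta gating,
#' `y_inf = alpha/(alpha+beta)` (the `q10` factor cancels) and
#' `tau = 1/(q10 (alpha+beta))`; for inf/tau gating, `tau` is divided
#' by `q10`.
#'
#' @param channel an `ion_channel`.
#' @param v membrane potential, mV.
#' @param conc named list/vector of concentrations, mM (for channels with
#'   `conc_deps`).
#' @return list with elements `y_inf`, `tau` (named numeric) and `p_open`.
#' @export
steady_state <- function(channel, v, conc = NULL) {
  stopifnot(is.finite(v))
  miss <- setdiff(channel$conc_deps, names(conc))
  if (length(miss))
    stop("missing concentration(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  env <- .gate_env(v, conc)
  yinf <- tauy <- stats::setNames(numeric(length(channel$statevars)),
                                  channel$statevars)
  for (sv in channel$statevars) {
    g <- channel$gating[[sv]]
    if (g$style == "ab") {
      a <- eval(g$alpha, env); b <- eval(g$beta, env)
      if (a + b == 0) stop("singular rates (alpha + beta = 0) for '", sv,
                           "' at v = ", v, call. = FALSE)
      yinf[sv] <- a / (a + b)
      tauy[sv] <- 1 / (channel$q10 * (a + b))
    } else {
      yinf[sv] <- eval(g$inf, env)
      tauy[sv] <- eval(g$tau, env) / channel$q10
    }
  }
  p <- eval(channel$p_open, as.list(yinf))
  list(y_inf = yinf, tau = tauy, p_open = p)
}

#' Expansion point for quasi-active linearization
#'
#' @param v0 membrane potential, mV.
#' @param y0 optional named state-variable values in `[0, 1]`; defaults to
#'   the steady state at `v0`.
#' @param conc0 optional named concentrations, mM.
#' @return list of class `expansion_point`.
#' @export
expansion_point <- function(v0, y0 = NULL, conc0 = NULL) {
  if (!is.null(y0) && (any(y0 < 0) || any(y0 > 1)))
    stop("y0 values must lie in [0, 1]", call. = FALSE)
  structure(list(v0 = v0, y0 = y0, conc0 = conc0), class = "expansion_point")
}

# symbolic d y_inf / d v at v0 (and optionally d y_inf / d conc)
.dyinf <- function(g, wrt = "v") {
  if (g$style == "ab") {
    e <- call("/", g$alpha, call("(", call("+", g$alpha, g$beta)))
    stats::D(e, wrt)
  } else stats::D(g$inf, wrt)
}

#' Quasi-active linearization factor of a channel
#'
#' Linearizes the channel current around an expansion point and returns the
#' dimensionless complex factor `lambda(omega)` such that the linearized
#' membrane admittance density contributed by the channel is
#' `g_max * lambda(omega)`:
#' \deqn{\lambda(\omega) = o(y_0) + (v_0 - e_c) \sum_i
#'   \frac{\partial o/\partial y_i \; y_{i,\infty}'(v_0)}
#'        {1 + i \omega \tau_i(v_0)}.}
#' Derivatives are taken symbolically. At `omega = 0` this equals
#' `d/dv [o(y_inf(v)) (v - e_c)]` evaluated at `v0` divided by nothing —
#' i.e. the DC slope conductance per unit `g_max`; for `|omega| -> Inf` the
#' gating terms vanish and `lambda -> o(y0)` (frozen gating, the passified
#' limit).
#'
#' @param channel an `ion_channel`.
#' @param expansion an [expansion_point()] (or a plain voltage, mV).
#' @param omega angular frequencies, rad/ms (numeric vector; may be 0 or
#'   negative).
#' @return complex vector, same length as `omega`.
#' @export
linearize <- function(channel, expansion, omega) {
  if (is.numeric(expansion)) expansion <- expansion_point(expansion)
  v0 <- expansion$v0
  ss <- steady_state(channel, v0, expansion$conc0)
  y0 <- ss$y_inf
  if (!is.null(expansion$y0)) y0[names(expansion$y0)] <- expansion$y0
  if (any(ss$tau <= 0)) stop("non-positive gating time constant", call. = FALSE)
  env0 <- c(as.list(y0), .gate_env(v0, expansion$conc0))
  lam <- rep(eval(channel$p_open, env0) + 0i, length(omega))
  for (sv in channel$statevars) {
    dody <- eval(stats::D(channel$p_open, sv), env0)
    dyv <- eval(.dyinf(channel$gating[[sv]]), env0)
    lam <- lam + (v0 - channel$e_rev) * dody * dyv /
      (1 + 1i * omega * ss$tau[[sv]])
  }
  lam
}

# concentration sensitivity of the linearized channel: for each ion in
# conc_deps, the factor multiplying a concentration deviation delta[ion],
# per unit g_max, with the gating variable's own low-pass included.
.linearize_conc <- function(channel, expansion, omega, ion) {
  v0 <- expansion$v0
  ss <- steady_state(channel, v0, expansion$conc0)
  env0 <- c(as.list(ss$y_inf), .gate_env(v0, expansion$conc0))
  out <- rep(0 + 0i, length(omega))
  for (sv in channel$statevars) {
    dody <- eval(stats::D(channel$p_open, sv), env0)
    dyc <- eval(.dyinf(channel$gating[[sv]], wrt = ion), env0)
    out <- out + (v0 - channel$e_rev) * dody * dyc /
      (1 + 1i * omega * ss$tau[[sv]])
  }
  out
}
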