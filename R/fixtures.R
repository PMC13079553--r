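#' Synthetic model fixtures
#'
#' Deterministic generators for the morphologies and physiologies used in
#' examples and validation: a sealed cable without somatic load, a
#' ball-and-stick model, a symmetric Y-tree, a binary tree obeying Rall's
#' 3/2 power rule (equivalent to a single cylinder), and an active
#' soma + axon-initial-segment (AIS) layout with spiking Na/K channels,
#' Ca channels, a Ca pool and a Ca-activated K (SK-type) channel.
#'
#' The passive preset is `R_m` 20 kOhm*cm^2 (`g_leak` 5e-5 S/cm^2), `c_m`
#' 1 uF/cm^2, `r_a` 100 Ohm*cm, `e_leak` -70 mV.
#'
#' @name fixtures
NULL

.passive_preset <- list(c_m = 1, r_a = 100, g_leak = 5e-5, e_leak = -70)

.apply_passive <- function(tree, preset = .passive_preset) {
  tree <- set_physiology(tree, "c_m", preset$c_m)
  tree <- set_physiology(tree, "r_a", preset$r_a)
  tree <- set_physiology(tree, "g_leak", preset$g_leak)
  set_physiology(tree, "e_leak", preset$e_leak)
}

#' @rdname fixtures
#' @param L cable length, um.
#' @param R cable radius, um.
#' @param n_points number of SWC points along the cable.
#' @param passive logical; attach the passive preset.
#' @return a [morph_tree] (with physiology when `passive = TRUE`).
#' @export
make_cable <- function(L = 1000, R = 1, n_points = 10, passive = TRUE) {
  xs <- seq(0, L, length.out = n_points + 1L)
  nd <- data.frame(index = seq_len(n_points + 1L),
                   parent = c(NA, seq_len(n_points)),
                   type = c(1L, rep(3L, n_points)),
                   x = xs, y = 0, z = 0,
                   radius = c(R, rep(R, n_points)),
                   length = c(0, diff(xs)))
  tree <- new_morph_tree(nd, soma_point = TRUE)
  if (passive) tree <- .apply_passive(tree)
  tree
}

#' @rdname fixtures
#' @param soma_R soma radius, um.
#' @export
make_ball_and_stick <- function(L = 1000, R = 1, soma_R = 10, n_points = 21,
                                passive = TRUE) {
  # the stick emanates from the soma center (the soma is an iso-potential
  # sphere; arc lengths are measured from its center)
  xs <- seq(L / n_points, L, length.out = n_points)
  nd <- data.frame(index = seq_len(n_points + 1L),
                   parent = c(NA, seq_len(n_points)),
                   type = c(1L, rep(3L, n_points)),
                   x = c(0, xs), y = 0, z = 0,
                   radius = c(soma_R, rep(R, n_points)),
                   length = c(0, L / n_points, diff(xs)))
  tree <- new_morph_tree(nd, soma_point = FALSE)
  if (passive) tree <- .apply_passive(tree)
  tree
}

#' @rdname fixtures
#' @param stem,branch stem and branch lengths, um.
#' @param R_stem,R_branch radii, um.
#' @export
make_y_tree <- function(stem = 100, branch = 50, R_stem = 1, R_branch = 1,
                        soma_R = 5, passive = TRUE) {
  s <- 1 / sqrt(2)
  nd <- data.frame(
    index = 1:4,
    parent = c(NA, 1L, 2L, 2L),
    type = c(1L, 3L, 3L, 3L),
    x = c(0, stem, stem + branch * s, stem + branch * s),
    y = c(0, 0, branch * s, -branch * s),
    z = 0,
    radius = c(soma_R, R_stem, R_branch, R_branch),
    length = c(0, stem, branch, branch))
  tree <- new_morph_tree(nd, soma_point = FALSE)
  if (passive) tree <- .apply_passive(tree)
  tree
}

#' @rdname fixtures
#' @param depth number of bifurcation levels.
#' @param d_root root branch diameter, um.
#' @param L_root root branch length, um.
#' @details For the Rall tree, every bifurcation obeys
#'   `d_parent^(3/2) = sum d_child^(3/2)` with two equal children
#'   (`d_child = d_parent / 2^(2/3)`) and child lengths scaled by
#'   `sqrt(d_child/d_parent)` so that every level adds the same
#'   electrotonic length; the whole tree is then equivalent to a single
#'   sealed cylinder whose parameters are attached as the `eq_cyl`
#'   attribute (radius, physical length).
#' @export
make_rall_tree <- function(depth = 2, d_root = 2, L_root = 400,
                           passive = TRUE) {
  nodes <- list(data.frame(index = 1L, parent = NA_integer_, type = 1L,
                           x = 0, y = 0, z = 0, radius = d_root / 2,
                           length = 0))
  ctr <- 1L
  grow <- function(parent_id, pos, dir, diam, L, level) {
    ctr <<- ctr + 1L
    id <- ctr
    newpos <- pos + dir * L
    nodes[[length(nodes) + 1L]] <<- data.frame(
      index = id, parent = parent_id, type = 3L,
      x = newpos[1L], y = newpos[2L], z = newpos[3L],
      radius = diam / 2, length = L)
    if (level < depth) {
      th <- pi / 5 / (level + 1)
      rot <- function(a) {
        c(cos(a) * dir[1L] - sin(a) * dir[2L],
          sin(a) * dir[1L] + cos(a) * dir[2L], 0)
      }
      dch <- diam / 2^(2 / 3)
      Lch <- L * sqrt(dch / diam)
      grow(id, newpos, rot(th), dch, Lch, level + 1L)
      grow(id, newpos, rot(-th), dch, Lch, level + 1L)
    }
  }
  grow(1L, c(0, 0, 0), c(1, 0, 0), d_root, L_root, 0L)
  tree <- new_morph_tree(do.call(rbind, nodes), soma_point = TRUE)
  if (passive) tree <- .apply_passive(tree)
  # equivalent sealed cylinder: same radius as the root branch; each level
  # adds the electrotonic length of the root branch, so the equivalent
  # physical length at the root diameter is (depth + 1) * L_root
  attr(tree, "eq_cyl") <- list(R = d_root / 2, L = (depth + 1) * L_root)
  tree
}

# ---- active channel set ----------------------------------------------------

#' Generic active channel set for the soma+AIS fixture
#'
#' Sigmoid-kinetics Hodgkin-Huxley style channels: a transient Na channel
#' (`na_t`, m^3 h), a delayed-rectifier K channel (`kv`, n^4), high- and
#' low-voltage-activated Ca channels (`ca_hva` q^2, `ca_lva` s^2 u), and an
#' SK-type Ca-activated K channel (`sk`, gating by the local Ca
#' concentration with a Hill function). Parameterizations are generic,
#' chosen for robust spiking and adaptation, not tied to any published
#' cell model.
#'
#' @return named list of [ion_channel()] objects.
#' @export
preset_channels <- function() {
  list(
    na_t = ion_channel("na_t", "m**3*h", list(
      m = list(inf = "1/(1+exp(-(v+35)/7))", tau = "0.1"),
      h = list(inf = "1/(1+exp((v+48)/7))",
               tau = "0.5 + 4/(1+exp((v+50)/8))")), ion = "na"),
    kv = ion_channel("kv", "n**4", list(
      n = list(inf = "1/(1+exp(-(v+37)/10))",
               tau = "0.5 + 3/(1+exp((v+50)/10))")), ion = "k"),
    ca_hva = ion_channel("ca_hva", "q**2", list(
      q = list(inf = "1/(1+exp(-(v+25)/6))", tau = "1")), ion = "ca"),
    ca_lva = ion_channel("ca_lva", "s**2*u", list(
      s = list(inf = "1/(1+exp(-(v+50)/6))", tau = "2"),
      u = list(inf = "1/(1+exp((v+80)/6))", tau = "20")), ion = "ca"),
    sk = ion_channel("sk", "z", list(
      z = list(inf = "ca^2/(ca^2 + 0.00043^2)", tau = "1")),
      ion = "k", conc_deps = "ca")
  )
}

#' @rdname fixtures
#' @param ais_L,ais_R AIS cylinder length and radius, um.
#' @param with_ca_dynamics logical; `TRUE` attaches the Ca pool
#'   (`d[Ca]/dt = -gamma i_Ca - ([Ca] - c_inf)/tau`), `FALSE` clamps the
#'   concentration at `c_inf` (a pool with `gamma = 0`), the model
#'   "without concentration dynamics". The channel set is identical in
#'   both variants. The pool's `gamma` default corresponds to a ~0.1 um
#'   submembrane shell.
#' @param gbar named overrides of channel densities, S/cm^2 (and `gamma`
#'   for the pool factor).
#' @export
make_soma_ais <- function(soma_R = 10, ais_L = 50, ais_R = 1.5,
                          with_ca_dynamics = TRUE, gbar = list()) {
  nd <- data.frame(index = 1:3,
                   parent = c(NA, 1L, 2L),
                   type = c(1L, 2L, 2L),
                   x = c(0, ais_L / 2, ais_L),
                   y = 0, z = 0,
                   radius = c(soma_R, ais_R, ais_R),
                   length = c(0, ais_L / 2, ais_L / 2))
  tree <- new_morph_tree(nd, soma_point = FALSE)
  tree <- .apply_passive(tree)
  chans <- preset_channels()
  g <- function(nm, dflt) gbar[[nm]] %||% dflt
  tree <- add_channel(tree, chans$na_t, g("na_t", 0.05))
  tree <- add_channel(tree, chans$kv, g("kv", 0.01))
  tree <- add_channel(tree, chans$ca_hva, g("ca_hva", 2e-4))
  tree <- add_channel(tree, chans$ca_lva, g("ca_lva", 2e-4))
  tree <- add_channel(tree, chans$sk, g("sk", 5e-3))
  tree <- add_conc_pool(tree, "ca",
                        gamma = if (with_ca_dynamics) g("gamma", 10) else 0,
                        tau = 80, c_inf = 1e-4)
  tree
}

# ---- file-based fixture interface ------------------------------------------

#' Write a fixture as SWC + physiology configuration files
#'
#' Emits `model.swc` and `phys.json` (plus `channels.json` for active
#' presets) into `out_dir`; `read_swc()` + [apply_physiology_config()]
#' reproduce the in-memory fixture. For the Rall tree the equivalent
#' cylinder parameters are included in `phys.json` for use as an oracle.
#'
#' @param kind one of `"cable"`, `"ball-and-stick"`, `"y-tree"`,
#'   `"rall-tree"`, `"soma-ais"`.
#' @param out_dir output directory (created if missing).
#' @param ... passed to the matching `make_*` generator.
#' @return named list of written paths, invisibly.
#' @export
write_fixture <- function(kind, out_dir, ...) {
  kind <- match.arg(kind, c("cable", "ball-and-stick", "y-tree", "rall-tree",
                            "soma-ais"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tree <- switch(kind,
    "cable" = make_cable(...),
    "ball-and-stick" = make_ball_and_stick(...),
    "y-tree" = make_y_tree(...),
    "rall-tree" = make_rall_tree(...),
    "soma-ais" = make_soma_ais(...))
  swc <- file.path(out_dir, "model.swc")
  write_swc(tree, swc)
  cfg <- list(passive = .passive_preset, soma_point = isTRUE(tree$soma_point))
  if (!is.null(attr(tree, "eq_cyl"))) cfg$eq_cyl <- attr(tree, "eq_cyl")
  paths <- list(swc = swc, phys = file.path(out_dir, "phys.json"))
  if (kind == "soma-ais") {
    ph <- tree$phys
    cfg$channels <- lapply(names(ph$channels), function(nm) {
      list(name = nm, g_max = unname(ph$channels[[nm]]$gmax[1L]),
           e_rev = ph$channels[[nm]]$e_rev)
    })
    if (length(ph$pools)) {
      cfg$pools <- lapply(names(ph$pools), function(ion) {
        p <- ph$pools[[ion]]
        list(ion = ion, gamma = unname(p$gamma[1L]), tau = unname(p$tau[1L]),
             c_inf = unname(p$cinf[1L]))
      })
    }
    chfile <- file.path(out_dir, "channels.json")
    defs <- lapply(preset_channels()[names(ph$channels)], function(ch) {
      gg <- lapply(ch$gating, function(g) {
        if (g$style == "ab") list(alpha = deparse(g$alpha),
                                  beta = deparse(g$beta))
        else list(inf = deparse(g$inf), tau = deparse(g$tau))
      })
      list(name = ch$name, p_open = deparse(ch$p_open), gating = gg,
           ion = ch$ion, e_rev = ch$e_rev, q10 = ch$q10,
           conc_deps = ch$conc_deps)
    })
    jsonlite::write_json(defs, chfile, auto_unbox = TRUE, digits = NA)
    paths$channels <- chfile
  }
  jsonlite::write_json(cfg, paths$phys, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
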