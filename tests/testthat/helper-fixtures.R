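# shared helpers for the test suite; all inputs are generated in code

# closed-form constants of the standard passive cable used throughout:
# R = 1 um, R_m = 20 kOhm cm^2 (g = 5e-5 S/cm^2), r_a = 100 Ohm cm
cable_const <- function(R = 1) {
  g <- 5e-5 * 1e-2                 # uS/um^2
  ra <- 100 * 1e-2                 # MOhm um
  r <- ra / (pi * R^2)             # MOhm/um
  y <- 2 * pi * R * g              # uS/um
  list(lambda = 1 / sqrt(r * y), zc = sqrt(r / y), tau_m = 1e-5 / g, r = r)
}

write_swc_text <- function(lines) {
  f <- tempfile(fileext = ".swc")
  writeLines(lines, f)
  f
}

swc3 <- function() {
  write_swc_text(c("# three-point chain",
                   "1 1 0 0 0 5 -1",
                   "2 3 10 0 0 1 1",
                   "3 3 20 0 0 1 2"))
}

# generalized eigen-times of the finite-difference system (oracle for the
# separation-of-variables engine): G phi = (1/tau) C phi on a fine grid
fd_eigen_taus <- function(tree, dx = 2, k = 8) {
  gt <- passify(tree, v0 = -70)
  grid <- dendrocable:::.fd_grid(gt$work, dx)
  n <- nrow(grid)
  i <- which(grid$parent_comp > 0L)
  p <- grid$parent_comp[i]
  g <- grid$gc[i]
  G <- matrix(0, n, n)
  G[cbind(i, p)] <- G[cbind(i, p)] - g
  G[cbind(p, i)] <- G[cbind(p, i)] - g
  diag(G) <- -rowSums(G)
  ids <- as.character(grid$node)
  gdens <- vapply(ids, function(id) gt$nodes[[id]]$g_static, numeric(1))
  cdens <- vapply(ids, function(id) gt$nodes[[id]]$cm, numeric(1))
  area <- grid$area
  if (!isTRUE(gt$work$soma_point)) area[1L] <- gt$soma_area
  diag(G) <- diag(G) + area * gdens
  C <- area * cdens
  z <- which(C == 0)               # zero-area junction helper nodes
  if (length(z)) {                 # exact Schur elimination
    keep <- setdiff(seq_len(n), z)
    G <- G[keep, keep] - G[keep, z, drop = FALSE] %*%
      solve(G[z, z, drop = FALSE], G[z, keep, drop = FALSE])
    C <- C[keep]
  }
  M <- t(G / sqrt(C)) / sqrt(C)
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  sort(1 / ev[ev > 1e-12], decreasing = TRUE)[seq_len(k)]
}

# simulate a step response of a full tree at given recording locations
step_response <- function(tree, amp, t_end, record_locs, dx = 5,
                          dt = 0.025, onset = 5) {
  sys <- discretize_fd(tree, dx_max = dx)
  rows <- dendrocable:::.nearest_comp(sys, tree, record_locs)
  sys <- add_stimulus(sys, stim_step(1L, amp, onset = onset))
  integrate_system(sys, t_end, dt = dt, record = rows)
}
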