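test_that("sealed cable input and transfer impedances match closed forms", {
  cc <- cable_const()
  tr <- make_cable(L = 1000, R = 1, n_points = 10)   # L = lambda
  gt <- passify(tr, v0 = -70)
  z_in <- Re(input_impedance(gt, c(1, 0), 0))
  expect_equal(z_in, cc$zc / tanh(1000 / cc$lambda), tolerance = 1e-9)
  z_tr <- Re(transfer_impedance(gt, c(1, 0), c(11, 1), 0))
  expect_equal(z_tr, cc$zc / sinh(1000 / cc$lambda), tolerance = 1e-9)
  # numerically: ~417.9 and ~270.8 MOhm
  expect_equal(z_in, 417.9521, tolerance = 1e-4)
  expect_equal(z_tr, 270.8557, tolerance = 1e-4)
  # semi-infinite limit
  long <- passify(make_cable(L = 10 * cc$lambda, R = 1, n_points = 10), -70)
  expect_equal(Re(input_impedance(long, c(1, 0), 0)), cc$zc,
               tolerance = 1e-8)
})

test_that("transfer impedance is reciprocal and Hermitian", {
  rt <- make_rall_tree()
  gt <- passify(rt, -70)
  om <- c(0, 0.3, 2, 15)
  set.seed(11)
  ids <- rt$nodes$index[-1L]
  for (k in 1:6) {
    a <- c(sample(ids, 1), runif(1)); b <- c(sample(ids, 1), runif(1))
    zab <- transfer_impedance(gt, a, b, om)
    zba <- transfer_impedance(gt, b, a, om)
    expect_equal(zab, zba, tolerance = 1e-10)
    expect_equal(transfer_impedance(gt, a, b, -om), Conj(zab),
                 tolerance = 1e-12)
  }
  # coincident locations give the input impedance
  expect_equal(transfer_impedance(gt, c(2, 0.4), c(2, 0.4), om),
               input_impedance(gt, c(2, 0.4), om))
})

test_that("impedance matrices are symmetric and reduce to input impedance", {
  bs <- make_ball_and_stick()
  gt <- passify(bs, -70)
  res <- impedance_matrix(gt, data.frame(node = c(1, 6, 22),
                                         x = c(0, 0.5, 1)),
                          omega = c(0, 1, 10))
  for (k in 1:3)
    expect_equal(res$Z[, , k], t(res$Z[, , k]), tolerance = 1e-12)
  one <- impedance_matrix(gt, c(6, 0.5), 0)
  expect_equal(one$Z[1, 1, 1], input_impedance(gt, c(6, 0.5), 0))
})

test_that("Rall 3/2 tree equals its equivalent cylinder at the root", {
  rt <- make_rall_tree(depth = 2, d_root = 2, L_root = 400)
  eq <- attr(rt, "eq_cyl")
  cc <- cable_const(R = eq$R)
  gt <- passify(rt, -70)
  z <- Re(input_impedance(gt, c(1, 0), 0))
  expect_equal(z, cc$zc / tanh(eq$L / cc$lambda), tolerance = 1e-6)
})

test_that("quasi-active conductance composes leak and channel factors", {
  # passive-only tree: g_lin = g_leak at every frequency
  cb <- make_cable(n_points = 4)
  gq <- make_quasi_active(cb, -70)
  g0 <- dendrocable:::.eval_glin(gq$nodes[["3"]], 1i * c(0, 5))
  expect_equal(Re(g0), rep(5e-5 * 1e-2, 2))
  expect_equal(Im(g0), c(0, 0))
  # one channel with lambda(0) = 1.375 and gbar = 1 mS/cm^2, zero leak
  ch <- ion_channel("kx", "y",
                    list(y = list(inf = "1/(1+exp(-(v+50)/10))", tau = "5")),
                    ion = "k")
  cb2 <- set_physiology(cb, "g_leak", 0)
  cb2 <- add_channel(cb2, ch, 1e-3)
  gq2 <- make_quasi_active(cb2, v0 = -50)
  expect_equal(Re(dendrocable:::.eval_glin(gq2$nodes[["3"]], 0 + 0i)),
               1.375 * 1e-3 * 1e-2, tolerance = 1e-12)
  # Hermitian symmetry of the linearized conductance
  om <- c(0.2, 1, 30)
  expect_equal(dendrocable:::.eval_glin(gq2$nodes[["3"]], -1i * om),
               Conj(dendrocable:::.eval_glin(gq2$nodes[["3"]], 1i * om)),
               tolerance = 1e-14)
})

test_that("passification freezes gating at its steady state", {
  ch <- ion_channel("kx", "y",
                    list(y = list(inf = "1/(1+exp(-(v+50)/10))", tau = "5")),
                    ion = "k")
  cb <- add_channel(make_cable(n_points = 4), ch, 1e-3)
  gp <- passify(cb, v0 = -50)
  # o(y_inf(-50)) = 0.5 folded into the leak
  expect_equal(Re(dendrocable:::.eval_glin(gp$nodes[["3"]], 0 + 0i)),
               5e-7 + 0.5 * 1e-5, tolerance = 1e-12)
  # equals the high-frequency limit of the quasi-active conductance
  gq <- make_quasi_active(cb, v0 = -50)
  expect_equal(Re(dendrocable:::.eval_glin(gq$nodes[["3"]], 1i * 1e9)),
               Re(dendrocable:::.eval_glin(gp$nodes[["3"]], 0 + 0i)),
               tolerance = 1e-9)
  # passified impedance magnitude is low-pass (monotone non-increasing)
  om <- exp(seq(log(1e-3), log(100), length.out = 100))
  zp <- Mod(input_impedance(gp, c(3, 0.5), om))
  expect_true(all(diff(zp) <= 1e-9))
})

test_that("an h-type linearized channel can produce a band-pass impedance", {
  h <- ion_channel("h", "q",
                   list(q = list(inf = "1/(1+exp((v+80)/8))", tau = "50")),
                   ion = "none", e_rev = -43)
  cb <- add_channel(make_cable(L = 500, R = 1), h, 5e-4)
  gh <- make_quasi_active(cb, v0 = -70)
  om <- exp(seq(log(1e-3), log(10), length.out = 150))
  zz <- Mod(input_impedance(gh, c(6, 0.5), om))
  imax <- which.max(zz)
  expect_gt(imax, 1)
  expect_lt(imax, length(zz))
  expect_gt(max(zz) / zz[1L], 1.05)
})

test_that("analytic impedances equal the finite-difference matrix inverse", {
  fixtures <- list(
    list(tree = make_ball_and_stick(),
         locs = data.frame(node = c(1, 11, 22), x = c(0, 0.5, 1))),
    list(tree = make_y_tree(),
         locs = data.frame(node = c(1, 2, 3, 4), x = c(0, 0.5, 1, 1))),
    list(tree = make_rall_tree(),
         locs = data.frame(node = c(1, 2, 4), x = c(0, 1, 1))))
  for (fx in fixtures) {
    gt <- passify(fx$tree, -70)
    Za <- resistance_matrix_tree(gt, fx$locs)
    Zf <- fd_impedance_matrix(gt, fx$locs, dx = 1)
    expect_lt(max(abs(Za - Zf) / abs(Za)), 0.005)
  }
  # observed convergence order ~2 (Richardson on the ball-and-stick)
  gt <- passify(make_ball_and_stick(), -70)
  locs <- data.frame(node = c(1, 11, 22), x = c(0, 0.5, 1))
  Za <- resistance_matrix_tree(gt, locs)
  errs <- vapply(c(4, 2, 1), function(dx)
    max(abs(Za - fd_impedance_matrix(gt, locs, dx = dx)) / abs(Za)),
    numeric(1))
  orders <- log2(errs[-3] / errs[-1])
  expect_true(all(orders > 1.7 & orders < 2.3))
  # also at a nonzero frequency
  Z1 <- impedance_matrix(gt, locs, 2)$Z[, , 1L]
  Zf1 <- fd_impedance_matrix(gt, locs, dx = 1, omega = 2)
  expect_lt(max(abs(Z1 - Zf1) / abs(Z1)), 0.005)
})

test_that("passified and quasi-active impedances converge at high frequency", {
  tr <- make_soma_ais()
  gq <- make_quasi_active(tr)
  gp <- passify(tr)
  om_hi <- 2 * pi * c(1000, 2000, 5000) / 1000  # >= 1 kHz in rad/ms
  zq <- input_impedance(gq, c(1, 0), om_hi)
  zp <- input_impedance(gp, c(1, 0), om_hi)
  expect_lt(max(Mod(zq - zp) / Mod(zq)), 0.01)
  # with the concentration coupling included the DC values differ clearly,
  # while the high-frequency agreement is untouched
  gqc <- make_quasi_active(tr, with_conc = TRUE)
  expect_gt(abs(Re(input_impedance(gqc, c(1, 0), 0)) -
                Re(input_impedance(gp, c(1, 0), 0))) /
            Re(input_impedance(gqc, c(1, 0), 0)), 0.01)
  expect_lt(max(Mod(input_impedance(gqc, c(1, 0), om_hi) - zp) / Mod(zp)),
            0.01)
})

test_that("kernel inversion reproduces the RC closed form and the DC sum", {
  nd <- data.frame(index = 1L, parent = NA, type = 1L, x = 0, y = 0, z = 0,
                   radius = 10, length = 0)
  tr <- set_physiology(set_physiology(new_morph_tree(nd), "g_leak", 5e-5),
                       "e_leak", -70)
  gt <- passify(tr, -70)
  R <- Re(input_impedance(gt, c(1, 0), 0))
  tau <- 20
  tg <- seq(0.05, 120, by = 0.05)
  k <- kernel_from_impedance(gt, c(1, 0), c(1, 0), tg)
  expect_lt(max(abs(k$values - (R / tau) * exp(-tg / tau))) / (R / tau),
            1e-3)
  # DC identity: integral of the kernel equals Z(0), on a passive fixture
  bs <- passify(make_ball_and_stick(), -70)
  tg2 <- c(seq(0.005, 1, by = 0.005), seq(1.05, 250, by = 0.05))
  kb <- kernel_from_impedance(bs, c(1, 0), c(1, 0), tg2)
  integral <- sum(diff(tg2) * (kb$values[-1L] + kb$values[-length(tg2)]) / 2)
  integral <- integral + kb$values[1L] * tg2[1L]            # head
  tail_tau <- 20
  integral <- integral + kb$values[length(tg2)] * tail_tau  # exponential tail
  expect_lt(abs(integral - kb$dc) / kb$dc, 0.005)
})

test_that("quasi-active kernels match brief-pulse simulations", {
  tr <- make_soma_ais()
  gt <- make_quasi_active(tr, with_conc = TRUE)
  tg <- seq(0.1, 60, by = 0.05)
  k <- kernel_from_impedance(gt, c(1, 0), c(1, 0), tg)
  sys <- add_stimulus(discretize_fd(tr, dx_max = 5),
                      stim_pulse(1, 0.02, onset = 20, width = 0.1))
  trc <- integrate_system(sys, 90, 0.01)
  eqv <- trc$v[trc$t == 20, 1L]
  sel <- trc$t > 20.1
  vs <- trc$v[sel, 1L] - eqv
  ki <- approx(tg, k$values, trc$t[sel] - 20.05)$y * 0.02 * 0.1
  ok <- !is.na(ki)
  expect_lt(max(abs(vs[ok] - ki[ok])) / max(abs(ki[ok])), 0.02)
})

test_that("impedances are invariant to activating the computational tree", {
  bs <- make_ball_and_stick()
  bsc <- build_computational_tree(bs)
  locs <- data.frame(node = c(1, 7, 22), x = c(0, 0.25, 1))
  om <- c(0, 1, 10)
  z1 <- impedance_matrix(passify(bs, -70), locs, om)$Z
  z2 <- impedance_matrix(passify(bsc, -70), locs, om)$Z
  expect_equal(z1, z2, tolerance = 1e-10)
})

test_that("impedance results serialize to JSON and kernels to data frames", {
  gt <- passify(make_y_tree(), -70)
  res <- impedance_matrix(gt, data.frame(node = c(1, 3), x = c(0, 1)),
                          c(0, 2))
  f <- tempfile(fileext = ".json")
  write_impedance_json(res, f)
  back <- jsonlite::read_json(f, simplifyVector = FALSE)
  m <- do.call(rbind, lapply(back$Z_real[[1L]], unlist))
  expect_equal(m, Re(res$Z[, , 1]), tolerance = 1e-12,
               ignore_attr = TRUE)
  k <- kernel_from_impedance(gt, c(1, 0), c(1, 0), c(1, 2, 5))
  df <- as.data.frame(k)
  expect_named(df, c("t_ms", "k"))
  expect_equal(nrow(df), 3L)
})
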