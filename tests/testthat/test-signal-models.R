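pr_g <- grase_protocol()
pr_mc <- mcdespot_protocol()

test_that("EPG reduces to mono-exponential decay at 180 degrees", {
  for (t2 in c(20, 80, 500)) {
    e <- epg_cpmg_decay(t2, 1e9, grase_protocol(etl = 8), 180)
    expect_equal(e, exp(-(1:8) * 10 / t2), tolerance = 1e-12)
  }
  # lossless limit: all echoes = 1
  e <- epg_cpmg_decay(1e12, 1e12, grase_protocol(etl = 6), 180)
  expect_equal(e, rep(1, 6), tolerance = 1e-9)
  expect_error(epg_cpmg_decay(80, 1000, pr_g, 0), "refocusing")
  expect_error(epg_cpmg_decay(80, 1000, pr_g, 181), "refocusing")
})

test_that("EPG matches the isochromat Bloch oracle at imperfect refocusing", {
  for (beta in c(120, 90, 151.7)) {
    e <- epg_cpmg_decay(80, 1000, pr_g, beta)
    o <- iso_cpmg_oracle(80, 1000, 10, 32, beta)
    expect_lt(max(abs(e - o)), 1e-6)
  }
})

test_that("multicomponent decay is a linear combination of EPG decays", {
  w <- c(0.12, 0.88); t2s <- c(20, 80)
  d <- multicomponent_decay(w, t2s, 1000, pr_g, 180)
  expect_equal(d, 0.12 * exp(-(1:32) * 10 / 20) + 0.88 * exp(-(1:32) * 10 / 80),
               tolerance = 1e-12)
  expect_equal(multicomponent_decay(c(0, 1), t2s, 1000, pr_g, 140),
               epg_cpmg_decay(80, 1000, pr_g, 140), tolerance = 1e-14)
  expect_equal(multicomponent_decay(2 * w, t2s, 1000, pr_g, 140),
               2 * multicomponent_decay(w, t2s, 1000, pr_g, 140))
  expect_error(multicomponent_decay(c(1, 1), 20, 1000, pr_g), "length")
  expect_error(multicomponent_decay(c(-1, 2), t2s, 1000, pr_g), "non-negative")
})

test_that("SPGR closed form: limits, printed value, Ernst angle", {
  expect_equal(spgr_signal(2, 100, 90, 1e5), 2, tolerance = 1e-8)
  expect_equal(spgr_signal(1, 1000, 6, 6.5), 0.05681, tolerance = 1e-4)
  # Ernst angle maximizes the signal over a fine grid
  alphas <- seq(0.5, 60, by = 0.05)
  s <- spgr_signal(1, 1000, alphas, 6.5)
  ernst <- acos(exp(-6.5 / 1000)) * 180 / pi
  expect_lt(abs(alphas[which.max(s)] - ernst), 0.1)
  expect_error(spgr_signal(1, -5, 10, 10), "positive")
})

test_that("IR-SPGR: null point, inversion limit, recursion oracle", {
  pr <- mcdespot_protocol(ir_tr_total = 1e7)
  t1 <- 900
  pr_null <- mcdespot_protocol(ir_ti = t1 * log(2), ir_tr_total = 1e7)
  expect_lt(irspgr_signal(1, t1, pr_null), 1e-8)
  pr0 <- mcdespot_protocol(ir_ti = 1e-9, ir_tr_total = 1e7)
  expect_equal(irspgr_signal(1, t1, pr0), sin(5 * pi / 180), tolerance = 1e-6)
  # oracle: steady state of (invert, relax ti, saturating read, relax rest)
  prx <- mcdespot_protocol()         # ir_tr_total = 3000
  ti <- prx$ir_ti; TT <- prx$ir_tr_total
  mz <- 1
  for (i in 1:500) {
    mz_ti <- 1 + (-mz - 1) * exp(-ti / t1)       # after inversion + ti
    sig <- mz_ti
    mz <- 1 + (0 - 1) * exp(-(TT - ti) / t1)     # saturated readout, recover
  }
  expect_equal(irspgr_signal(1, t1, prx),
               abs(sin(5 * pi / 180) * sig), tolerance = 1e-6)
})

test_that("bSSFP: periodicity, closed form, recursion oracle, monotonicity", {
  s1 <- bssfp_signal(1, 1000, 80, 20, 5.8, 40, 0)
  s2 <- bssfp_signal(1, 1000, 80, 20, 5.8, 40 + 1000 / 5.8, 0)
  expect_equal(s1, s2, tolerance = 1e-10)

  # standard closed form at phase cycle 180, on resonance:
  # S = m0 sin(a) (1-E1) / (1 - (E1-E2) cos(a) - E1 E2) * E2^(1/2TR)
  a <- 25 * pi / 180; t1 <- 1000; t2 <- 80; tr <- 5.8
  e1 <- exp(-tr / t1); e2 <- exp(-tr / t2)
  closed <- sin(a) * (1 - e1) / (1 - (e1 - e2) * cos(a) - e1 * e2) *
    exp(-tr / 2 / t2)
  expect_equal(bssfp_signal(1, t1, t2, 25, tr, 0, 180), closed,
               tolerance = 1e-12)
  expect_equal(bssfp_signal(1.3, t1, t2, 25, tr, 17, 0, 1.1),
               bssfp_iter_oracle(1.3, t1, t2, 25, tr, 17, 0, 1.1),
               tolerance = 1e-10)
  # signal decreases as 1/t2 grows at fixed t1 (phase cycle 180, on resonance)
  t2s <- c(200, 100, 50, 25)
  ss <- vapply(t2s, function(t2) bssfp_signal(1, 300, t2, 30, 5.8, 0, 180), 0)
  expect_true(all(diff(ss) < 0))
  expect_error(bssfp_signal(1, 100, 200, 30, 5.8), "t2")
})

test_that("two-pool signals: reductions, exchange limit, recursion oracle", {
  # degenerate reduction to single pool
  p0 <- two_pool_params(m0 = 1, f_m = 0, t1_m = 400, t1_f = 1100,
                        t2_m = 20, t2_f = 80, k_mf = 0, delta_f0 = 10)
  s0 <- two_pool_signals(p0, pr_mc)
  expect_equal(unname(s0[1:7]),
               spgr_signal(1, 1100, pr_mc$spgr_alphas, pr_mc$spgr_tr),
               tolerance = 1e-10)
  for (c in 1:2) for (i in 1:7) {
    expect_equal(unname(s0[7 + (c - 1) * 7 + i]),
                 bssfp_signal(1, 1100, 80, pr_mc$bssfp_alphas[i],
                              pr_mc$bssfp_tr, 10,
                              pr_mc$bssfp_phase_cycles[c]),
                 tolerance = 1e-10)
  }

  # k -> infinity: population-weighted relaxation rates, single pool
  fm <- 0.15
  pk <- two_pool_params(f_m = fm, t1_m = 400, t1_f = 1100, t2_m = 20,
                        t2_f = 80, k_mf = 1e5)
  r1 <- fm / 400 + (1 - fm) / 1100
  r2 <- fm / 20 + (1 - fm) / 80
  sk <- two_pool_signals(pk, pr_mc)
  expect_equal(unname(sk[1:7]),
               spgr_signal(1, 1 / r1, pr_mc$spgr_alphas, pr_mc$spgr_tr),
               tolerance = 1e-3)
  expect_equal(unname(sk[8]),
               bssfp_signal(1, 1 / r1, 1 / r2, pr_mc$bssfp_alphas[1],
                            pr_mc$bssfp_tr, 0, 0), tolerance = 1e-3)

  # fixed-point recursion oracle at generic parameters
  pv <- two_pool_params(f_m = 0.15, t1_m = 400, t1_f = 1100, t2_m = 20,
                        t2_f = 90, k_mf = 9, delta_f0 = 12)
  s <- two_pool_signals(pv, pr_mc)
  for (ci in 1:2) for (i in c(1, 4, 7)) {
    o <- two_pool_bssfp_oracle(unclass(pv), pr_mc$bssfp_tr,
                               pr_mc$bssfp_alphas[i],
                               pr_mc$bssfp_phase_cycles[ci])
    expect_equal(unname(s[7 + (ci - 1) * 7 + i]), o, tolerance = 1e-8)
  }

  # fast scoring path agrees with the reference implementation
  sf <- qmyelin:::cpp_two_pool_signals_fast(unclass(pv), pr_mc$spgr_tr,
                                            pr_mc$spgr_alphas, pr_mc$bssfp_tr,
                                            pr_mc$bssfp_alphas,
                                            pr_mc$bssfp_phase_cycles)
  expect_equal(unname(s[1:21]), as.numeric(sf), tolerance = 1e-12)
  expect_error(two_pool_params(t2_m = 90, t2_f = 80), "t2_m")
})

test_that("MT pair and MTR ground truth", {
  mp <- mt_pair(100, 900, 0.4)
  expect_equal(mp$ms_img / mp$m0_img, 0.6)
  mp0 <- mt_pair(100, 900, 0)
  expect_equal(mp0$ms_img, mp0$m0_img)
  expect_equal(compute_mtr(mp$m0_img, mp$ms_img), 100 * 0.4, tolerance = 1e-12)
  expect_error(mt_pair(1, 900, 1.0), "mt_delta")
})

test_that("Rician noise model", {
  x <- array(runif(1000), c(10, 10, 10))
  expect_identical(add_rician_noise(x, Inf), x)
  set.seed(1)
  z <- add_rician_noise(rep(0, 1e6), 1, reference = 1)
  expect_equal(mean(z), sqrt(pi / 2), tolerance = 0.005)   # Rayleigh mean
  set.seed(7); a <- add_rician_noise(x, 50)
  set.seed(7); b <- add_rician_noise(x, 50)
  expect_identical(a, b)
  expect_error(add_rician_noise(x, -1), "snr")
})
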