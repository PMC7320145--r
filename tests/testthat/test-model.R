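test_that("build_scheme exposes the 7-species, 5-reaction network", {
  k <- donor_rate_constants("tight")
  sch <- build_scheme(k)
  expect_length(sch$species, 7)
  expect_length(sch$reactions, 5)
  expect_equal(dim(sch$stoich), c(7, 5))
  # every reaction conserves N-containing material
  n_content <- c(L = 0, G = 0, N = 1, GN = 1, LN = 1, LGN = 1, NADplus = 1)
  expect_equal(unname(n_content %*% sch$stoich), matrix(0, 1, 5))
})

test_that("trajectories conserve the L, G and N pools", {
  set.seed(5)
  for (i in 1:10) {
    k <- rate_constants(kon_gn = runif(1, 1, 200), koff_gn = runif(1, 1, 2000),
                        kon_ln = runif(1, 100, 3000),
                        koff_ln = runif(1, 100, 8000),
                        kon_cx = runif(1, 0, 500), koff_cx = runif(1, 10, 3e4),
                        k_transfer = runif(1, 0, 2e4),
                        kcat = runif(1, 100, 6000))
    init <- scheme_state(L = runif(1, 0.01, 1), G = runif(1, 10, 300),
                         N = runif(1, 1, 50), GN = runif(1, 0, 20))
    traj <- simulate_scheme(build_scheme(k), init, t_end = 0.2, n_out = 40)
    pools <- chankin:::pool_totals(traj)
    for (p in names(pools))
      expect_lt(max(abs(pools[[p]] - pools[[p]][1])) /
                  max(pools[[p]][1], 1e-12), 1e-7)
    expect_gt(min(as.matrix(traj[-1])), -1e-10)
  }
})

test_that("all-zero rate constants freeze the state", {
  k <- rate_constants(0, 0, 0, 0, 0, 0, 0, 0)
  init <- scheme_state(L = 0.1, G = 100, N = 20, GN = 10)
  traj <- simulate_scheme(build_scheme(k), init, 1)
  for (sp in c("L", "G", "N", "GN", "LN", "LGN", "NADplus"))
    expect_equal(traj[[sp]], rep(traj[[sp]][1], nrow(traj)))
})

test_that("binding-only equilibrium matches the joint closed-form solution", {
  # no turnover, no ternary complex: G+N and L+N equilibria only
  k <- rate_constants(kon_gn = 100, koff_gn = 80, kon_ln = 2000,
                      koff_ln = 8800, kon_cx = 0, koff_cx = 0,
                      k_transfer = 0, kcat = 0)
  init <- scheme_state(L = 5, G = 240, N = 40)
  traj <- simulate_scheme(build_scheme(k), init, t_end = 2, n_out = 50)
  nf_model <- traj$N[nrow(traj)]
  nf_closed <- free_ligand_multisite(c(240, 5), 40, c(0.8, 4.4))
  expect_equal(nf_model, nf_closed, tolerance = 1e-6)
  # equilibrium satisfies each Kd (detailed balance of the closed system)
  n <- nrow(traj)
  expect_equal(traj$G[n] * traj$N[n] / traj$GN[n], 0.8, tolerance = 1e-6)
  expect_equal(traj$L[n] * traj$N[n] / traj$LN[n], 4.4, tolerance = 1e-6)
})

test_that("equilibrium is path-independent in the initial N/GN split", {
  k <- rate_constants(kon_gn = 100, koff_gn = 80, kon_ln = 0, koff_ln = 0,
                      kon_cx = 0, koff_cx = 0, k_transfer = 0, kcat = 0)
  a <- simulate_scheme(build_scheme(k),
                       scheme_state(G = 200, N = 40, GN = 0), 2)
  b <- simulate_scheme(build_scheme(k),
                       scheme_state(G = 160, N = 0, GN = 40), 2)
  na <- nrow(a)
  expect_equal(a$N[na], b$N[na], tolerance = 1e-6)
  expect_equal(a$GN[na], b$GN[na], tolerance = 1e-6)
})

test_that("steady rate without channeling equals the free-diffusion prediction", {
  k0 <- donor_rate_constants("tight", channeling = FALSE)
  mm <- acceptor_mm_default()
  for (sites in c(100, 240)) {
    sr <- steady_rate(k0, 40, sites, 10)
    expect_equal(sr$specific_U_mg, calc_vcal(40, sites, 0.8, mm),
                 tolerance = 0.02)
  }
  expect_equal(steady_rate(k0, 0, 240, 10)$specific_U_mg, 0)
})

test_that("specific activity is invariant to tracer-level LDH amount", {
  k <- donor_rate_constants("tight")
  s1 <- steady_rate(k, 40, 240, 5)
  s2 <- steady_rate(k, 40, 240, 10)
  expect_equal(s2$v_uM_min / s1$v_uM_min, 2, tolerance = 0.02)
  expect_equal(s2$specific_U_mg, s1$specific_U_mg, tolerance = 0.02)
})

test_that("flux partition respects its limiting cases and conservation", {
  k <- donor_rate_constants("tight")
  sr <- steady_rate(k, 40, 240, 10)
  fp <- flux_partition(sr$trajectory)
  expect_equal(fp$channeled_product + fp$diffusive_product,
               sr$trajectory$NADplus[nrow(sr$trajectory)],
               tolerance = 1e-6)
  expect_true(fp$channeled_fraction > 0 && fp$channeled_fraction < 1)

  k0 <- donor_rate_constants("tight", channeling = FALSE)
  fp0 <- flux_partition(steady_rate(k0, 40, 240, 10)$trajectory)
  expect_equal(fp0$channeled_fraction, 0)

  kl <- rate_constants(kon_gn = 100, koff_gn = 80, kon_ln = 0,
                       koff_ln = 3900, kon_cx = 100, koff_cx = 2e4,
                       k_transfer = 2400, kcat = 4900)
  fp1 <- flux_partition(steady_rate(kl, 40, 240, 10)$trajectory)
  expect_equal(fp1$channeled_fraction, 1)

  empty <- simulate_scheme(build_scheme(k0), scheme_state(G = 100, N = 10),
                           0.01)
  expect_error(flux_partition(empty), "no product")
})

test_that("dead-end ternary complex forms but channels nothing", {
  k <- rate_constants(kon_gn = 100, koff_gn = 80, kon_ln = 2000,
                      koff_ln = 3900, kon_cx = 100, koff_cx = 2e4,
                      k_transfer = 0, kcat = 4900)
  sr <- steady_rate(k, 40, 240, 10)
  traj <- sr$trajectory
  expect_gt(max(traj$LGN), 0)
  expect_equal(max(traj$Pc), 0)
})

test_that("compensated off-rate sweep shows the off-rate-overlap trend", {
  k <- donor_rate_constants("tight")
  sw <- offrate_sweep(k, koff_gn_grid = c(80, 250, 820),
                      koff_cx_grid = 2e4, nadh_uM = 40,
                      gapdh_sites_uM = 240, ldh_nM = 10,
                      compensate_kd = TRUE)
  expect_true(all(diff(sw$channeled_fraction[, 1]) > 0))
  expect_true(all(diff(sw$ratio[, 1]) > 0))
})

test_that("an ever-shorter-lived complex loses its channeled flux", {
  k <- donor_rate_constants("tight")
  sw <- offrate_sweep(k, koff_gn_grid = 80,
                      koff_cx_grid = c(2e4, 2e5, 2e6),
                      nadh_uM = 40, gapdh_sites_uM = 240, ldh_nM = 10)
  expect_true(all(diff(sw$channeled_fraction[1, ]) < 0))
  expect_lt(sw$channeled_fraction[1, 3], 0.05)
})

test_that("single-point sweep agrees with a direct flux partition", {
  k <- donor_rate_constants("tight")
  sw <- offrate_sweep(k, koff_gn_grid = k[["koff_gn"]],
                      koff_cx_grid = k[["koff_cx"]],
                      nadh_uM = 40, gapdh_sites_uM = 240, ldh_nM = 10)
  fp <- flux_partition(steady_rate(k, 40, 240, 10)$trajectory)
  expect_equal(sw$channeled_fraction[1, 1], fp$channeled_fraction,
               tolerance = 1e-6)
})

test_that("weak-binding donor preset channels more than the tight one", {
  kt <- donor_rate_constants("tight")
  kw <- donor_rate_constants("weak")
  mm <- acceptor_mm_default()
  srt <- steady_rate(kt, 40, 240, 10)
  srw <- steady_rate(kw, 40, 240, 10)
  ft <- flux_partition(srt$trajectory)$channeled_fraction
  fw <- flux_partition(srw$trajectory)$channeled_fraction
  expect_gt(fw, ft)
  rt <- srt$specific_U_mg / calc_vcal(40, 240, 0.8, mm)
  rw <- srw$specific_U_mg / calc_vcal(40, 240, 8.2, mm)
  expect_gt(rw, rt)
  expect_gt(rt, 1)
})

test_that("channeling ratio rises as NADH falls at fixed donor", {
  k <- donor_rate_constants("tight")
  mm <- acceptor_mm_default()
  ratios <- vapply(c(40, 25, 10), function(n)
    steady_rate(k, n, 200, 10)$specific_U_mg / calc_vcal(n, 200, 0.8, mm),
    numeric(1))
  expect_true(all(diff(ratios) > 0))
})

test_that("channeled turnover never exceeds diffusive turnover", {
  set.seed(9)
  for (i in 1:10) {
    k <- calibrate_rate_constants(vmax = 140, km = 4.4,
                                  kd_gapdh = 10^runif(1, -1, 1),
                                  channeling = TRUE,
                                  kon_cx = runif(1, 50, 500),
                                  koff_cx = runif(1, 5e3, 5e4),
                                  transfer_enhancement = runif(1, 1, 100))
    ct <- channeled_turnover_comparison(k, 40, 240, 10)
    expect_lte(ct$channeled_turnover, ct$diffusive_turnover)
  }
  # instantaneous transfer removes the extra-step penalty
  kfast <- calibrate_rate_constants(140, 4.4, 0.8, channeling = TRUE,
                                    k_transfer = 1e8)
  ct <- channeled_turnover_comparison(kfast, 40, 240, 10)
  expect_gt(ct$ratio, 0.95)
  # no transfer, no channeled turnover
  kzero <- rate_constants(100, 80, 2000, 3900, 100, 2e4, 0, 4900)
  expect_equal(channeled_turnover_comparison(kzero, 40, 240, 10)$channeled_turnover, 0)
})

test_that("rate-constant calibration hits its macroscopic targets", {
  k <- calibrate_rate_constants(140, 4.4, 0.8)
  expect_equal(kd_gn(k), 0.8)
  expect_equal((k[["koff_ln"]] + k[["kcat"]]) / k[["kon_ln"]], 4.4)
  expect_equal(k[["kcat"]], 140 * 35)
  expect_error(calibrate_rate_constants(140, 4.4, 0.8, kon_ln = 500),
               "kon_ln")
  expect_error(rate_constants(-1, 1, 1, 1, 1, 1, 1, 1), ">= 0")
})
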