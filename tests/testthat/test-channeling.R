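test_that("calc_vcal reduces to the Michaelis-Menten limits", {
  mm <- acceptor_mm_default()
  # no donor, NADH at Km: half-saturation
  expect_equal(calc_vcal(4.4, 0, 0.8, mm), 70)
  expect_equal(calc_vcal(0, 240, 0.8, mm), 0)
  # buffered condition: free NADH from the oracle, then plain arithmetic
  nf <- oracle_free_ligand(240, 40, 0.8)
  expect_equal(calc_vcal(40, 240, 0.8, mm), oracle_mm(nf, 140, 4.4),
               tolerance = 1e-9)
  expect_equal(calc_vcal(40, 240, 0.8, mm), 4.89, tolerance = 1e-3)
})

test_that("calc_vcal decreases strictly with donor concentration", {
  mm <- acceptor_mm_default()
  v <- calc_vcal(40, seq(50, 400, length.out = 20), 0.8, mm)
  expect_true(all(diff(v) < 0))
})

test_that("delta-method Vcal error grows from zero with the kd error", {
  mm <- michaelis_params(140, 4.4, 20, 0.4)
  se0 <- calc_vcal_se(40, 240, 0.8, michaelis_params(140, 4.4), kd_err = 0)
  expect_equal(se0, 0)
  se <- calc_vcal_se(40, 240, 0.8, mm, kd_err = 0.06)
  expect_gt(se, 0)
})

test_that("channeling_ratio is the plain quotient with guarded domain", {
  expect_equal(channeling_ratio(5, 5), 1)
  expect_equal(channeling_ratio(1.85 * 3, 3), 1.85)
  expect_equal(channeling_ratio(0, 3), 0)
  expect_error(channeling_ratio(1, 0), "undefined")
})

test_that("fit_michaelis recovers parameters exactly from noiseless data", {
  for (p in list(c(140, 4.4), c(130, 7.8))) {
    conc <- c(1, 2, 4, 8, 16, 40, 100)
    fit <- fit_michaelis(conc, oracle_mm(conc, p[1], p[2]))
    expect_equal(unname(coef(fit)["vmax"]), p[1], tolerance = 1e-6)
    expect_equal(unname(coef(fit)["km"]), p[2], tolerance = 1e-6)
  }
  expect_error(fit_michaelis(c(1, 5, 20), c(10, 30, 60)), ">= 4")
})

test_that("channeled profile bookkeeping is exact", {
  k <- donor_rate_constants("tight")
  ds <- gen_buffering_dataset(k, "titrate_nadh_fixed_gapdh",
                              nadh_uM = c(10, 18, 26, 34, 40),
                              gapdh_sites_uM = 200, noise_sd = 0.02,
                              seed = 8)
  cp <- channeled_profile(ds)
  expect_equal(cp$table$v_channeled + cp$table$v_cal, cp$table$v_measured)
  expect_equal(residuals(cp) + fitted(cp), ds$v_measured_U_mg)
})

test_that("a dataset at exactly twice the prediction channels its own v_cal", {
  mm <- acceptor_mm_default()
  nadh <- c(10, 18, 26, 34, 40)
  vcal <- calc_vcal(nadh, 200, 0.8, mm)
  ds <- buffering_dataset("titrate_nadh_fixed_gapdh", nadh, 200, 10,
                          2 * vcal, 0.8, mm)
  cp <- channeled_profile(ds)
  expect_equal(cp$table$v_channeled, cp$table$v_cal, tolerance = 1e-12)
  expect_equal(cp$table$ratio, rep(2, 5))
})

test_that("channeling-off datasets are flagged as no-channeling nulls", {
  k0 <- donor_rate_constants("tight", channeling = FALSE)
  ds <- gen_buffering_dataset(k0, "titrate_gapdh_fixed_nadh",
                              gapdh_sites_uM = seq(100, 240, length.out = 4),
                              noise_sd = 0)
  cp <- channeled_profile(ds)
  expect_true(all(abs(cp$table$ratio - 1) < 0.05))
  expect_true(cp$no_channeling)
  expect_null(coef(cp))
})

test_that("apparent Km from noisy data stays within 15% of the noiseless pipeline", {
  k <- donor_rate_constants("tight")
  nadh <- c(5, 10, 15, 20, 28, 40)
  v_true <- buffering_true_rates(k, nadh, 200)
  ds0 <- gen_buffering_dataset(k, "titrate_nadh_fixed_gapdh", nadh_uM = nadh,
                               gapdh_sites_uM = 200, noise_sd = 0,
                               v_true = v_true)
  km0 <- coef(channeled_profile(ds0))[["km"]]
  ds <- gen_buffering_dataset(k, "titrate_nadh_fixed_gapdh", nadh_uM = nadh,
                              gapdh_sites_uM = 200, noise_sd = 0.02,
                              seed = 21, v_true = v_true)
  km <- coef(channeled_profile(ds))[["km"]]
  expect_lt(abs(km - km0) / km0, 0.15)
})

test_that("apparent Km for the complex substrate exceeds the free-NADH Km", {
  k <- donor_rate_constants("tight")
  ds0 <- gen_buffering_dataset(k, "titrate_nadh_fixed_gapdh",
                               nadh_uM = c(5, 10, 15, 20, 28, 40),
                               gapdh_sites_uM = 200, noise_sd = 0)
  cp <- channeled_profile(ds0)
  expect_gt(coef(cp)[["km"]], 4.4)
  # both substrate axes are available; the conventional axis changes the
  # numbers but not the ordering
  cp2 <- channeled_profile(ds0, substrate_axis = "total_nadh")
  expect_gt(coef(cp2)[["km"]], 4.4)
})

test_that("antibody saturation collapses the rate to the diffusion prediction", {
  mm <- acceptor_mm_default()
  vcal <- calc_vcal(40, 240, 0.8, mm)
  vchan <- 1.5 * vcal
  ab <- gen_antibody_series(vchan, vcal, alpha = 0, noise_sd = 0,
                            antibody_nM = c(0, 5, 20, 100, 400, 4000, 40000))
  rep <- diffusion_limit_check(ab$antibody_nM, ab$v_measured_U_mg,
                               40, 240, 0.8, mm)
  expect_true(rep$plateau_detected)
  expect_equal(rep$ratio, 1, tolerance = 0.02)
  expect_true(rep$pass)
})

test_that("missing plateau warns and an elevated plateau fails", {
  mm <- acceptor_mm_default()
  vcal <- calc_vcal(40, 240, 0.8, mm)
  expect_warning(
    diffusion_limit_check(c(0, 10), c(3 * vcal, 2 * vcal), 40, 240, 0.8, mm),
    "plateau")
  rep <- diffusion_limit_check(c(0, 500, 1000),
                               c(3 * vcal, 2 * vcal, 2 * vcal),
                               40, 240, 0.8, mm)
  expect_false(rep$pass)
  expect_true(rep$plateau_detected)
})
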