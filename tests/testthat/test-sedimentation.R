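test_that("Svedberg relation gives the expected diffusion coefficient", {
  p <- sedimentation_params(s = 7.5, mr_kda = 143.6, vbar = 0.73, rho = 1.0)
  # hand calculation: 7.5e-13 * 8.3145e7 * 293.15 / (143600 * 0.27) cm^2/s
  expect_equal(diffusion_from_svedberg(p, 293.15), 4.715e-7,
               tolerance = 1e-3)
  p2 <- sedimentation_params(s = 7.5, mr_kda = 2 * 143.6)
  expect_equal(diffusion_from_svedberg(p2) / diffusion_from_svedberg(p), 0.5,
               tolerance = 1e-12)
  expect_error(sedimentation_params(s = 0, mr_kda = 100), "positive")
  expect_error(sedimentation_params(s = 7, mr_kda = 100, vbar = 1.1),
               "buoyancy")
})

test_that("rcf-to-rpm conversion is consistent with the centrifugal field", {
  rpm <- rcf_to_rpm(40000, 6.55)
  omega <- rpm * 2 * pi / 60
  expect_equal(omega^2 * 6.55 / 980.665, 40000, tolerance = 1e-10)
})

test_that("pure-diffusion run conserves mass on both quadratures", {
  p <- sedimentation_params(s = 7.5, mr_kda = 143.6, rotor_rpm = 0)
  sim <- simulate_lamm(p, c(1000, 5000, 10000), n_r = 200)
  m <- lamm_mass(sim)
  expect_lt(max(abs(m - m[1])) / m[1], 1e-8)
  tot <- vapply(sim$scans, total_signal, numeric(1))
  ref <- total_signal(data.frame(radius_cm = sim$radii,
                                 signal = rep(1, length(sim$radii))))
  expect_lt(max(abs(tot - ref)) / ref, 1e-4)
})

test_that("sedimenting run conserves the discrete invariant to 0.1%", {
  p <- sedimentation_params(s = 7.6, mr_kda = 143.6, rotor_rpm = 25000)
  sim <- simulate_lamm(p, c(240, 3600, 7200, 14400, 25200), n_r = 250)
  m <- lamm_mass(sim)
  expect_lt(max(abs(m - m[1])) / m[1], 1e-3)
  expect_gt(min(vapply(sim$scans, function(sc) min(sc$signal), numeric(1))),
            -1e-10)
})

test_that("grid refinement changes mid-cell profiles by less than 0.5%", {
  p <- sedimentation_params(s = 7.6, mr_kda = 143.6, rotor_rpm = 25000)
  s1 <- simulate_lamm(p, c(3600, 10800), n_r = 250)
  s2 <- simulate_lamm(p, c(3600, 10800), n_r = 500)
  for (i in 1:2) {
    mid <- seq(6.1, 7.0, by = 0.01)
    a <- approx(s1$radii, s1$scans[[i]]$signal, mid)$y
    b <- approx(s2$radii, s2$scans[[i]]$signal, mid)$y
    expect_lt(max(abs(a - b)) / p$loading, 0.005)
  }
})

test_that("early-time solution matches the Faxen approximation within 1%", {
  p <- sedimentation_params(s = 7.6, mr_kda = 143.6, rotor_rpm = 25000)
  sim <- simulate_lamm(p, 3600, n_r = 400)
  sc <- sim$scans[[1]]
  mid <- sc$radius_cm > 6.1 & sc$radius_cm < 7.0
  fx <- faxen_profile(p, 3600, sc$radius_cm[mid])
  expect_lt(max(abs(fx - sc$signal[mid])) / p$loading, 0.01)
})

test_that("the solver is linear: two species sum to their mixture", {
  pa <- sedimentation_params(s = 7.6, mr_kda = 143.6, rotor_rpm = 25000,
                             loading = 0.7)
  pb <- sedimentation_params(s = 12.0, mr_kda = 287.2, rotor_rpm = 25000,
                             loading = 0.3)
  ta <- simulate_lamm(pa, c(3600, 7200), n_r = 300)
  tb <- simulate_lamm(pb, c(3600, 7200), n_r = 300)
  mix <- Map(function(a, b) a$signal + b$signal, ta$scans, tb$scans)
  # doubling loading doubles the profile (homogeneity) ...
  pa2 <- pa; pa2$loading <- 1.4
  ta2 <- simulate_lamm(pa2, c(3600, 7200), n_r = 300)
  expect_equal(ta2$scans[[1]]$signal, 2 * ta$scans[[1]]$signal,
               tolerance = 1e-8)
  # ... and the summed profiles are a valid mixture forward model
  expect_equal(length(mix[[1]]), 300)
})

test_that("a too-coarse grid triggers the stability diagnostic", {
  p <- sedimentation_params(s = 7.6, mr_kda = 143.6, rotor_rpm = 25000)
  expect_error(simulate_lamm(p, 3600, n_r = 20), "Peclet")
})

test_that("single-species fit inverts the simulator", {
  p <- sedimentation_params(s = 7.6, mr_kda = 143.6, rotor_rpm = 25000,
                            loading = 1)
  scans <- gen_scans(p, n_scans = 6, radial_increment_cm = 0.006,
                     noise_sd = 0, seed = 1)
  init <- sedimentation_params(s = 6.5, mr_kda = 120, rotor_rpm = 25000,
                               loading = 0.8)
  fit <- fit_single_species(scans, init, n_r = 150,
                            control = list(reltol = 1e-7, maxit = 150))
  expect_lt(abs(fit$s - 7.6) / 7.6, 0.01)
  expect_lt(abs(fit$mr_kda - 143.6) / 143.6, 0.01)
  expect_lt(abs(fit$loading - 1), 0.01)
})

test_that("fit recovers s and Mr within 3% at 1% noise", {
  p <- sedimentation_params(s = 7.6, mr_kda = 143.6, rotor_rpm = 25000,
                            loading = 1)
  scans <- gen_scans(p, n_scans = 6, radial_increment_cm = 0.006,
                     noise_sd = 0.01, seed = 2)
  init <- sedimentation_params(s = 7.0, mr_kda = 130, rotor_rpm = 25000,
                               loading = 0.9)
  fit <- fit_single_species(scans, init, n_r = 150,
                            control = list(reltol = 1e-7, maxit = 120))
  expect_lt(abs(fit$s - 7.6) / 7.6, 0.03)
  expect_lt(abs(fit$mr_kda - 143.6) / 143.6, 0.03)
  expect_error(fit_single_species(scans$scans[1:3], init), ">= 5")
})

test_that("kd_from_association reproduces the in-cell arithmetic", {
  expect_equal(kd_from_association(6, 6, 0.10), 48.6)
  expect_equal(kd_from_association(6, 6, 0.5), 3.0)
  expect_lt(kd_from_association(6, 6, 0.999), 0.02)  # fraction -> 1: Kd -> 0
  expect_error(kd_from_association(6, 6, 1), "strictly")
  expect_error(kd_from_association(0, 6, 0.1), "positive")
})

test_that("10% self-association is detectable above a 1% noise floor", {
  p <- sedimentation_params(s = 7.6, mr_kda = 143.6, rotor_rpm = 25000,
                            loading = 1)
  scans <- gen_scans(p, n_scans = 6, radial_increment_cm = 0.006,
                     noise_sd = 0.01, seed = 3)
  init <- sedimentation_params(s = 7.4, mr_kda = 140, rotor_rpm = 25000)
  fit <- fit_single_species(scans, init, n_r = 150,
                            control = list(reltol = 1e-7, maxit = 120))
  rep10 <- detectability_report(scans, fit, 0.10, conc_uM = 6, n_r = 150)
  expect_true(rep10$detectable)
  expect_equal(rep10$kd_bound_uM, 48.6)
  # stronger association deviates even more
  rep50 <- detectability_report(scans, fit, 0.50, conc_uM = 6, n_r = 150)
  expect_gt(rep50$rms_difference, rep10$rms_difference)
  expect_true(rep50$detectable)
})
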