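#' @name synthetic
#' @title Seeded synthetic-data generators
#' @description Generators for every input family the analysis consumes:
#' fluorescence titrations, enzyme-buffering rate tables, absorbance progress
#' curves, antibody competition series and sedimentation scans.  All
#' randomness is multiplicative Gaussian noise (relative standard deviation
#' `noise_sd`, default 0.02, the scale of routine assay precision) and every
#' generator is byte-reproducible under a fixed `seed`.
NULL

# wavelengths (nm) quoted per detection mode, metadata only
.mode_wavelengths <- list(
  protein_quench = c(excitation = 295, emission = 328),
  ligand_quench  = c(excitation = 328, emission = 457),
  fret           = c(excitation = 295, emission = 457),
  anisotropy     = c(excitation = 330, emission = 457))

# signal direction per mode: quenching readouts decrease, FRET/anisotropy rise
.mode_sign <- c(protein_quench = -1, ligand_quench = -1, fret = 1,
                anisotropy = 1)

#' Generate a fluorescence titration
#'
#' Signal model `baseline + dS * bound-site fraction` with the exact
#' depletion-corrected occupancy and multiplicative Gaussian noise; the
#' ligand grid is log-spaced around the true Kd.
#'
#' @param true_kd true dissociation constant (uM).
#' @param site_uM fixed site concentration (uM, default 1).
#' @param mode detection mode (quenching modes decrease, FRET/anisotropy
#'   increase).
#' @param n number of titration points (default 12).
#' @param span log-range of ligand concentrations as multiples of `true_kd`
#'   (default `c(1/16, 125)` so the isotherm is bracketed).
#' @param baseline,amplitude signal baseline and absolute amplitude.
#' @param noise_sd relative noise (default 0.02; 0 for noiseless).
#' @param seed RNG seed (default NULL leaves the RNG state alone).
#' @return list of class `fluorescence_titration`: `ligand_uM`, `signal`,
#'   `site_uM`, `mode`, `excitation_nm`, `emission_nm`, `true_kd`.
#' @export
gen_titration <- function(true_kd, site_uM = 1,
                          mode = c("protein_quench", "ligand_quench",
                                   "fret", "anisotropy"),
                          n = 12, span = c(1 / 16, 125),
                          baseline = 10, amplitude = 8,
                          noise_sd = 0.02, seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  L <- exp(seq(log(true_kd * span[1]), log(true_kd * span[2]),
               length.out = n))
  occ <- (L - free_ligand(site_uM, L, true_kd)) / site_uM
  sig <- baseline + .mode_sign[[mode]] * amplitude * occ
  if (noise_sd > 0) sig <- sig * (1 + stats::rnorm(n, 0, noise_sd))
  wl <- .mode_wavelengths[[mode]]
  structure(list(ligand_uM = L, signal = sig, site_uM = site_uM, mode = mode,
                 excitation_nm = wl[["excitation"]],
                 emission_nm = wl[["emission"]], true_kd = true_kd),
            class = "fluorescence_titration")
}

#' @export
print.fluorescence_titration <- function(x, ...) {
  cat(sprintf(
    "Fluorescence titration (%s, ex %g / em %g nm): %d points, sites %.3g uM\n",
    x$mode, x$excitation_nm, x$emission_nm, length(x$ligand_uM), x$site_uM))
  invisible(x)
}

#' Fit a generated titration (convenience wrapper)
#' @param titration a `fluorescence_titration`.
#' @return a [fit_binding_isotherm()] result.
#' @export
fit_titration <- function(titration) {
  stopifnot(inherits(titration, "fluorescence_titration"))
  fit_binding_isotherm(titration$ligand_uM, titration$signal,
                       titration$site_uM, titration$mode)
}

#' Noiseless buffering-assay rates from the kinetic model
#'
#' Computes the model-true specific activity ([steady_rate()]) for each point
#' of a design grid; used by [gen_buffering_dataset()] and reusable as a
#' cache when many noise replicates of the same grid are needed.
#'
#' @param constants a [rate_constants()] object.
#' @param nadh_uM,gapdh_sites_uM grids (recycled to common length).
#' @param ldh_nM acceptor concentration (nM tetramer).
#' @return numeric vector of specific activities (U/mg).
#' @export
buffering_true_rates <- function(constants, nadh_uM, gapdh_sites_uM,
                                 ldh_nM = 10) {
  n <- max(length(nadh_uM), length(gapdh_sites_uM))
  nadh_uM <- rep_len(nadh_uM, n); gapdh_sites_uM <- rep_len(gapdh_sites_uM, n)
  vapply(seq_len(n), function(i)
    steady_rate(constants, nadh_uM[i], gapdh_sites_uM[i],
                ldh_nM)$specific_U_mg, numeric(1))
}

#' Generate an enzyme-buffering dataset
#'
#' Measured rates are the transient-complex model's steady rates plus
#' multiplicative Gaussian noise.  Default grids follow the assay designs:
#' donor titration at fixed 40 uM NADH (sites 100-240 uM for a tight donor,
#' 240-480 uM for a weak one), or NADH titration 10-40 uM at fixed donor.
#'
#' @param constants a [rate_constants()] for the generating model.
#' @param design `"titrate_gapdh_fixed_nadh"` or
#'   `"titrate_nadh_fixed_gapdh"`.
#' @param nadh_uM,gapdh_sites_uM design grids; defaults depend on `design`.
#' @param ldh_nM acceptor concentration (nM, default 10).
#' @param acceptor_mm [michaelis_params()] handed to the analysis (defaults
#'   to the Vmax/Km implied by `constants`).
#' @param noise_sd relative noise (default 0.02).
#' @param seed RNG seed.
#' @param v_true optional precomputed noiseless rates
#'   ([buffering_true_rates()]) to reuse across noise replicates.
#' @return a [buffering_dataset()] carrying the analysis metadata
#'   (`kd_gapdh` from the constants, `acceptor_mm`).
#' @export
gen_buffering_dataset <- function(constants,
                                  design = c("titrate_gapdh_fixed_nadh",
                                             "titrate_nadh_fixed_gapdh"),
                                  nadh_uM = NULL, gapdh_sites_uM = NULL,
                                  ldh_nM = 10, acceptor_mm = NULL,
                                  noise_sd = 0.02, seed = NULL,
                                  v_true = NULL) {
  design <- match.arg(design)
  stopifnot(inherits(constants, "rate_constants"))
  if (!is.null(seed)) set.seed(seed)
  if (design == "titrate_gapdh_fixed_nadh") {
    if (is.null(nadh_uM)) nadh_uM <- 40
    if (is.null(gapdh_sites_uM))
      gapdh_sites_uM <- seq(100, 240, length.out = 6)
  } else {
    if (is.null(nadh_uM)) nadh_uM <- seq(10, 40, length.out = 6)
    if (is.null(gapdh_sites_uM)) gapdh_sites_uM <- 200
  }
  if (is.null(acceptor_mm)) {
    kcat <- constants[["kcat"]]
    km_bh <- (constants[["koff_ln"]] + kcat) / constants[["kon_ln"]]
    acceptor_mm <- michaelis_params(kcat / 35, km_bh)  # 35 kDa per LDH site
  }
  if (is.null(v_true))
    v_true <- buffering_true_rates(constants, nadh_uM, gapdh_sites_uM,
                                   ldh_nM)
  v <- if (noise_sd > 0)
    v_true * (1 + stats::rnorm(length(v_true), 0, noise_sd)) else v_true
  buffering_dataset(design = design, nadh_total_uM = nadh_uM,
                    gapdh_sites_uM = gapdh_sites_uM, ldh_nM = ldh_nM,
                    v_measured_U_mg = v, kd_gapdh = kd_gn(constants),
                    acceptor_mm = acceptor_mm)
}

#' Generate absorbance progress curves from the kinetic model
#'
#' Converts a model trajectory to a 340-nm absorbance trace (unreacted NADH,
#' bound or free, absorbing with molar absorptivity `epsilon`), optionally
#' adding a slow linear scattering drift that emulates gradual donor-enzyme
#' precipitation, plus multiplicative noise.
#'
#' @param constants a [rate_constants()].
#' @param nadh_uM,gapdh_sites_uM,ldh_nM assay condition.
#' @param t_end_min trace duration (min, default 1).
#' @param n points (default 60).
#' @param drift_abs_per_min linear scattering drift (absorbance/min,
#'   default 0).
#' @param noise_sd relative noise on absorbance (default 0.02).
#' @param epsilon molar absorptivity (M-1 cm-1, default 6220).
#' @param path_length_cm optical path (default 1).
#' @param seed RNG seed.
#' @return list: `curve` (a [progress_curve()], with drift and noise),
#'   `blank` (drift-only [progress_curve()]), `true_v0_uM_min` (model steady
#'   rate), `concentration_uM` (noiseless, drift-free).
#' @export
gen_progress_curves <- function(constants, nadh_uM = 40,
                                gapdh_sites_uM = 240, ldh_nM = 10,
                                t_end_min = 1, n = 60,
                                drift_abs_per_min = 0, noise_sd = 0.02,
                                epsilon = 6220, path_length_cm = 1,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sr <- steady_rate(constants, nadh_uM, gapdh_sites_uM, ldh_nM)
  kd <- kd_gn(constants)
  nf <- free_ligand(gapdh_sites_uM, nadh_uM, kd)
  init <- scheme_state(L = ldh_nM * 4 / 1000,
                       G = gapdh_sites_uM - (nadh_uM - nf),
                       N = nf, GN = nadh_uM - nf)
  traj <- simulate_scheme(build_scheme(constants), init, t_end_min,
                          n_out = n)
  nadh_left <- nadh_uM - traj$NADplus
  abs_clean <- nadh_left * 1e-6 * epsilon * path_length_cm
  abs_drift <- drift_abs_per_min * traj$time
  a <- abs_clean + abs_drift
  if (noise_sd > 0) a <- a * (1 + stats::rnorm(n, 0, noise_sd))
  list(curve = progress_curve(traj$time, a, path_length_cm, epsilon),
       blank = progress_curve(traj$time, abs_drift, path_length_cm, epsilon),
       true_v0_uM_min = sr$v_uM_min,
       concentration_uM = nadh_left)
}

#' Generate an antibody competition series
#'
#' Antibody occupancy follows a single-site binding curve; the channeled
#' contribution is scaled by `(1 - occupancy)` (bulky antibodies block the
#' protein-protein path) and the free-NADH contribution by
#' `(1 - alpha * occupancy)` with small `alpha` (mild steric inhibition).
#'
#' @param v_channeled_U_mg,v_diffusive_U_mg unperturbed path contributions
#'   (U/mg).
#' @param antibody_nM antibody grid (nM, default 0-1000).
#' @param kd_ab_nM antibody-LDH dissociation constant (nM, default 20).
#' @param alpha fractional inhibition of the free-NADH path at saturation
#'   (default 0.1).
#' @param noise_sd relative noise (default 0.02).
#' @param seed RNG seed.
#' @return data.frame `antibody_nM`, `v_measured_U_mg`, plus attribute
#'   `truth` with the noiseless series.
#' @export
gen_antibody_series <- function(v_channeled_U_mg, v_diffusive_U_mg,
                                antibody_nM = seq(0, 1000, length.out = 9),
                                kd_ab_nM = 20, alpha = 0.1,
                                noise_sd = 0.02, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  occ <- antibody_nM / (kd_ab_nM + antibody_nM)
  v_true <- v_channeled_U_mg * (1 - occ) +
    v_diffusive_U_mg * (1 - alpha * occ)
  v <- if (noise_sd > 0)
    v_true * (1 + stats::rnorm(length(v_true), 0, noise_sd)) else v_true
  structure(data.frame(antibody_nM = antibody_nM, v_measured_U_mg = v),
            truth = v_true)
}

#' Generate sedimentation-velocity scans
#'
#' [simulate_lamm()] profiles at the instrument's radial increment and scan
#' cadence, with additive Gaussian noise scaled to the loading signal.
#'
#' @param params a [sedimentation_params()].
#' @param scan_times_s scan times (default every 240 s for 7 h, thinned to
#'   `n_scans`).
#' @param n_scans number of scans kept (default 8, evenly spaced).
#' @param radial_increment_cm radial grid step (default 30 um = 0.003 cm).
#' @param noise_sd noise relative to the loading signal (default 0.01).
#' @param seed RNG seed.
#' @return a `lamm_scans` object whose scans carry the noise.
#' @export
gen_scans <- function(params, scan_times_s = NULL, n_scans = 8,
                      radial_increment_cm = 0.003, noise_sd = 0.01,
                      seed = NULL) {
  stopifnot(inherits(params, "sedimentation_params"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(scan_times_s)) {
    all_t <- seq(240, 7 * 3600, by = 240)
    scan_times_s <- all_t[unique(round(seq(1, length(all_t),
                                           length.out = n_scans)))]
  }
  n_r <- max(50L, round((params$bottom - params$meniscus) /
                          radial_increment_cm))
  sim <- simulate_lamm(params, scan_times_s, n_r = n_r)
  if (noise_sd > 0) {
    sim$scans <- lapply(sim$scans, function(sc) {
      sc$signal <- sc$signal +
        stats::rnorm(nrow(sc), 0, noise_sd * params$loading)
      sc
    })
  }
  sim
}
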