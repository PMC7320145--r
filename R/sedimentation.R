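R_GAS_CGS <- 8.314462618e7  # erg mol-1 K-1

#' Parameters of a single sedimenting species
#'
#' @param s sedimentation coefficient (Svedberg, 1e-13 s).
#' @param mr_kda molecular mass (kDa).
#' @param vbar partial specific volume (mL/g, default 0.73).
#' @param rho solvent density (g/mL, default 1.0).
#' @param eta_rel solvent viscosity relative to water (default 1.0); scales
#'   both sedimentation and diffusion.
#' @param rotor_rpm rotor speed (rpm).  Note that a relative centrifugal
#'   force in "x g" is not an rpm; convert explicitly with [rcf_to_rpm()].
#' @param meniscus,bottom cell radii (cm; defaults 5.9 and 7.2, a standard
#'   12-mm double-sector cell).
#' @param loading loading concentration (signal units, default 1).
#' @return object of class `sedimentation_params`.
#' @export
sedimentation_params <- function(s, mr_kda, vbar = 0.73, rho = 1.0,
                                 eta_rel = 1.0, rotor_rpm = 25000,
                                 meniscus = 5.9, bottom = 7.2, loading = 1) {
  if (s <= 0 || mr_kda <= 0) stop("sedimentation_params: s and mr must be positive",
                                  call. = FALSE)
  if (!(bottom > meniscus) || meniscus <= 0)
    stop("sedimentation_params: need bottom > meniscus > 0", call. = FALSE)
  buoy <- vbar * rho
  if (buoy <= 0 || buoy >= 1)
    stop("sedimentation_params: require 0 < vbar*rho < 1 (buoyancy)",
         call. = FALSE)
  structure(list(s = s, mr_kda = mr_kda, vbar = vbar, rho = rho,
                 eta_rel = eta_rel, rotor_rpm = rotor_rpm,
                 meniscus = meniscus, bottom = bottom, loading = loading),
            class = "sedimentation_params")
}

#' @export
print.sedimentation_params <- function(x, ...) {
  cat(sprintf(
    "Sedimentation: s = %.3g S, Mr = %.4g kDa, %g rpm, cell %.3g-%.3g cm, loading %.3g\n",
    x$s, x$mr_kda, x$rotor_rpm, x$meniscus, x$bottom, x$loading))
  invisible(x)
}

#' Convert a relative centrifugal force to rotor speed
#'
#' `rpm = (60 / 2 pi) * sqrt(g_rcf * 980.665 / radius_cm)`.
#'
#' @param rcf_g relative centrifugal force in multiples of g.
#' @param radius_cm reference radius (cm), typically mid-cell.
#' @return rotor speed in rpm.
#' @export
rcf_to_rpm <- function(rcf_g, radius_cm) {
  if (rcf_g <= 0 || radius_cm <= 0)
    stop("rcf_to_rpm: inputs must be positive", call. = FALSE)
  sqrt(rcf_g * 980.665 / radius_cm) * 60 / (2 * pi)
}

#' Diffusion coefficient from the Svedberg relation
#'
#' \deqn{D = \frac{s R T}{M_r (1 - \bar v \rho)}}
#'
#' @param params a [sedimentation_params()].
#' @param temperature_K absolute temperature (default 293.15 K).
#' @return diffusion coefficient (cm^2/s).
#' @examples
#' p <- sedimentation_params(s = 7.5, mr_kda = 143.6)
#' diffusion_from_svedberg(p)  # ~4.7e-7 cm^2/s
#' @export
diffusion_from_svedberg <- function(params, temperature_K = 293.15) {
  stopifnot(inherits(params, "sedimentation_params"))
  buoy <- 1 - params$vbar * params$rho
  if (buoy <= 0) stop("diffusion_from_svedberg: vbar*rho >= 1 (no buoyancy)",
                      call. = FALSE)
  params$s * 1e-13 * R_GAS_CGS * temperature_K /
    (params$mr_kda * 1000 * buoy)
}

#' Simulate sedimentation-velocity scans (Lamm equation)
#'
#' Claverie-type numerical solution of the Lamm equation
#' \deqn{\partial_t c = \frac{1}{r}\partial_r\left[ r D \partial_r c -
#'   s\omega^2 r^2 c\right]}
#' in a sector-shaped cell, by a conservative finite-volume discretisation
#' (central differences, zero-flux ends) integrated in time with a
#' stiff-capable banded solver.  Total signal \eqn{\int c\, r\, dr} is
#' conserved to machine precision by construction.
#'
#' @param params a [sedimentation_params()].
#' @param scan_times_s ascending scan times (s since speed-up).
#' @param n_r number of radial grid cells (default 300).
#' @param D diffusion coefficient (cm^2/s); default from
#'   [diffusion_from_svedberg()].
#' @param temperature_K temperature for the default D.
#' @return object of class `lamm_scans`: list with `scans` (a list of
#'   data.frames `time_s`, `radius_cm`, `signal`), `params`, `radii`, `D`.
#' @export
simulate_lamm <- function(params, scan_times_s, n_r = 300, D = NULL,
                          temperature_K = 293.15) {
  stopifnot(inherits(params, "sedimentation_params"))
  if (is.unsorted(scan_times_s, strictly = TRUE) || any(scan_times_s < 0))
    stop("simulate_lamm: scan times must be ascending and nonnegative",
         call. = FALSE)
  if (is.null(D)) D <- diffusion_from_svedberg(params, temperature_K)
  omega <- params$rotor_rpm * 2 * pi / 60
  s_eff <- params$s * 1e-13 / params$eta_rel
  D_eff <- D / params$eta_rel
  dr <- (params$bottom - params$meniscus) / n_r
  r_f <- params$meniscus + dr * (0:n_r)          # faces
  r_c <- params$meniscus + dr * (seq_len(n_r) - 0.5)  # cell centres

  # cell Peclet number: central differencing needs Pe <= 2 for a clean front
  if (D_eff > 0) {
    pe <- s_eff * omega^2 * max(r_f) * dr / D_eff
    if (pe > 2)
      stop("simulate_lamm: radial grid too coarse for this s/D ",
           "(cell Peclet ", signif(pe, 3), " > 2); increase n_r",
           call. = FALSE)
  }

  w_f <- s_eff * omega^2 * r_f                   # advection velocity at faces
  deriv <- function(t, c, p) {
    cf <- (c[-1] + c[-n_r]) / 2
    J <- w_f[2:n_r] * cf - D_eff * diff(c) / dr
    J <- c(0, J, 0)
    list(-(r_f[-1] * J[-1] - r_f[-(n_r + 1)] * J[-(n_r + 1)]) / (r_c * dr))
  }
  times <- unique(c(0, scan_times_s))
  sol <- deSolve::ode.1D(y = rep(params$loading, n_r), times = times,
                         func = deriv, parms = NULL, nspec = 1,
                         dimens = n_r, method = "lsoda",
                         rtol = 1e-8, atol = 1e-10)
  if (attr(sol, "istate")[1] < 0)
    stop("simulate_lamm: integrator failure", call. = FALSE)
  scans <- lapply(scan_times_s, function(tt) {
    row <- sol[match(tt, times), -1]
    data.frame(time_s = tt, radius_cm = r_c, signal = as.numeric(row))
  })
  structure(list(scans = scans, params = params, radii = r_c, D = D,
                 dr = dr),
            class = "lamm_scans")
}

#' @export
print.lamm_scans <- function(x, ...) {
  cat(sprintf("Lamm simulation: %d scans, %d radial points, s = %.3g S, D = %.3g cm2/s\n",
              length(x$scans), length(x$radii), x$params$s, x$D))
  invisible(x)
}

#' Total signal of a radial scan in a sector cell
#'
#' Sector-shaped cells dilute radially, so the conserved quantity is
#' \eqn{\int c\, r\, dr} (trapezoidal on the scan grid).
#'
#' @param scan data.frame with `radius_cm` and `signal`.
#' @return total signal (signal units times cm^2).
#' @export
total_signal <- function(scan) {
  r <- scan$radius_cm; c <- scan$signal
  sum(diff(r) * (c[-1] * r[-1] + c[-length(c)] * r[-length(r)]) / 2)
}

#' Conserved total mass of a Lamm simulation
#'
#' The finite-volume solver conserves the cell-centred sum
#' `sum(c_i r_i) dr` exactly (zero-flux ends, telescoping fluxes); this
#' helper evaluates it per scan.  [total_signal()] uses trapezoidal
#' quadrature, appropriate for instrument scans but not exactly the discrete
#' invariant once material piles up against the bottom.
#'
#' @param sim a `lamm_scans` object from [simulate_lamm()].
#' @return numeric vector of totals, one per scan.
#' @export
lamm_mass <- function(sim) {
  stopifnot(inherits(sim, "lamm_scans"))
  vapply(sim$scans, function(sc) sum(sc$signal * sim$radii) * sim$dr,
         numeric(1))
}

#' Early-time analytic approximation of the Lamm equation (Faxen)
#'
#' Boundary-free approximate solution used as an independent check of the
#' numerical solver: radial dilution plateau `c0 exp(-2 s w^2 t)` with an
#' error-function boundary centred at `r_m exp(s w^2 t)` of width
#' `2 sqrt(D t)`.  Valid while the boundary is far from both cell ends.
#'
#' @param params a [sedimentation_params()].
#' @param t_s time (s).
#' @param radii_cm radii at which to evaluate (cm).
#' @param D diffusion coefficient (cm^2/s; default Svedberg relation).
#' @param temperature_K temperature for the default D.
#' @return concentration profile (signal units).
#' @export
faxen_profile <- function(params, t_s, radii_cm, D = NULL,
                          temperature_K = 293.15) {
  stopifnot(inherits(params, "sedimentation_params"))
  if (is.null(D)) D <- diffusion_from_svedberg(params, temperature_K)
  omega <- params$rotor_rpm * 2 * pi / 60
  s_eff <- params$s * 1e-13 / params$eta_rel
  tau <- s_eff * omega^2 * t_s
  rb <- params$meniscus * exp(tau)
  erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
  params$loading * exp(-2 * tau) *
    0.5 * (1 + erf((radii_cm - rb) / (2 * sqrt(D / params$eta_rel * t_s))))
}

#' Fit a single sedimenting species to velocity scans
#'
#' Nonlinear least squares over (s, Mr, loading) with [simulate_lamm()] as
#' the forward model.  At fixed (s, Mr) the profile is linear in the loading
#' concentration, which is therefore solved by projection, leaving a
#' two-dimensional search over log(s), log(Mr).
#'
#' @param scans list of scan data.frames (`time_s`, `radius_cm`, `signal`),
#'   at least 5, or a `lamm_scans` object.
#' @param params_init a [sedimentation_params()] giving starting values and
#'   the fixed experiment geometry.
#' @param n_r radial grid cells for the forward model (default 300).
#' @param exclude_cm radial margins excluded from the fit at the meniscus
#'   and bottom, `c(meniscus, bottom)` in cm (default `c(0.05, 0.15)`):
#'   optical artefacts live at the meniscus and the steep back-of-cell
#'   accumulation layer dominates the residual while carrying no boundary
#'   information.
#' @param control passed to [stats::optim()] (Nelder-Mead).
#' @return object of class `lamm_fit`: `s`, `mr_kda`, `loading`, `ssr`,
#'   `rms`, `params` (fitted [sedimentation_params()]), `convergence`.
#' @export
fit_single_species <- function(scans, params_init, n_r = 300,
                               exclude_cm = c(0.05, 0.15),
                               control = list(reltol = 1e-8, maxit = 200)) {
  if (inherits(scans, "lamm_scans")) scans <- scans$scans
  if (length(scans) < 5)
    stop("fit_single_species: need >= 5 scans spanning boundary movement",
         call. = FALSE)
  stopifnot(inherits(params_init, "sedimentation_params"))
  lo <- params_init$meniscus + exclude_cm[1]
  hi <- params_init$bottom - exclude_cm[2]
  scans <- lapply(scans, function(sc)
    sc[sc$radius_cm >= lo & sc$radius_cm <= hi, , drop = FALSE])
  times <- vapply(scans, function(sc) sc$time_s[1], numeric(1))
  obs <- unlist(lapply(scans, `[[`, "signal"))

  forward <- function(s, mr) {
    p <- params_init; p$s <- s; p$mr_kda <- mr; p$loading <- 1
    sim <- simulate_lamm(p, times, n_r = n_r)
    unlist(lapply(seq_along(scans), function(i)
      stats::approx(sim$radii, sim$scans[[i]]$signal,
                    xout = scans[[i]]$radius_cm, rule = 2)$y))
  }
  objective <- function(par) {
    pred1 <- tryCatch(forward(exp(par[1]), exp(par[2])),
                      error = function(e) NULL)
    if (is.null(pred1)) return(1e12)
    load <- sum(obs * pred1) / sum(pred1^2)
    sum((obs - load * pred1)^2)
  }
  opt <- stats::optim(log(c(params_init$s, params_init$mr_kda)), objective,
                      method = "Nelder-Mead", control = control)
  if (!is.finite(opt$value) || opt$value >= 1e12)
    stop("fit_single_species: forward model failed over the search region",
         call. = FALSE)
  s_hat <- exp(opt$par[1]); mr_hat <- exp(opt$par[2])
  pred1 <- forward(s_hat, mr_hat)
  load_hat <- sum(obs * pred1) / sum(pred1^2)
  resid <- obs - load_hat * pred1
  p <- params_init; p$s <- s_hat; p$mr_kda <- mr_hat; p$loading <- load_hat
  structure(list(s = s_hat, mr_kda = mr_hat, loading = load_hat,
                 ssr = sum(resid^2), rms = sqrt(mean(resid^2)),
                 params = p, convergence = opt$convergence,
                 residuals = resid, times = times),
            class = "lamm_fit")
}

#' @export
print.lamm_fit <- function(x, ...) {
  cat(sprintf(
    "Single-species Lamm fit: s = %.4g S, Mr = %.5g kDa, loading %.4g (RMS %.3g)\n",
    x$s, x$mr_kda, x$loading, x$rms))
  invisible(x)
}

#' @export
coef.lamm_fit <- function(object, ...)
  c(s = object$s, mr_kda = object$mr_kda, loading = object$loading)

#' @export
residuals.lamm_fit <- function(object, ...) object$residuals

#' Dissociation constant implied by a fractional association
#'
#' For an equimolar A + B mixture in which a fraction of the limiting
#' component is complexed: `complex = fraction * min(a, b)`,
#' `Kd = (a - complex) (b - complex) / complex`.
#'
#' @param conc_a,conc_b total concentrations (uM), > 0.
#' @param associated_fraction fraction of the limiting component in the
#'   complex, strictly between 0 and 1.
#' @return dissociation constant (uM).
#' @examples
#' kd_from_association(6, 6, 0.10)  # 48.6
#' @export
kd_from_association <- function(conc_a, conc_b, associated_fraction) {
  if (conc_a <= 0 || conc_b <= 0)
    stop("kd_from_association: concentrations must be positive",
         call. = FALSE)
  if (associated_fraction <= 0 || associated_fraction >= 1)
    stop("kd_from_association: fraction must lie strictly in (0, 1)",
         call. = FALSE)
  cx <- associated_fraction * min(conc_a, conc_b)
  fa <- conc_a - cx; fb <- conc_b - cx
  if (fa < 0 || fb < 0)
    stop("kd_from_association: association exceeds available material",
         call. = FALSE)
  fa * fb / cx
}

#' Self-association detectability report
#'
#' Compares the best single-species description of a scan set with the
#' profiles expected if a given fraction of the material were self-associated
#' into a dimer (sedimenting with `s * 2^(2/3)` at twice the mass).  If the
#' association model deviates from the single-species fit by more than the
#' fit's own residual noise floor, an association of that magnitude would
#' have been detected — so a clean single-species fit bounds the interaction
#' Kd from below via [kd_from_association()].
#'
#' @param scans scan list (or `lamm_scans`) that was fitted.
#' @param fit a [fit_single_species()] result for those scans.
#' @param association_fraction hypothesised associated fraction (default
#'   0.10).
#' @param conc_uM per-component loading concentration (uM) used for the Kd
#'   bound (default 6).
#' @param n_r forward-model grid (default 300).
#' @param exclude_cm radial margins excluded from the comparison, as in
#'   [fit_single_species()].
#' @return list of class `detectability_report`: `rms_difference`
#'   (association model vs single-species fit), `noise_floor` (fit RMS),
#'   `detectable`, `kd_bound_uM`.
#' @export
detectability_report <- function(scans, fit, association_fraction = 0.10,
                                 conc_uM = 6, n_r = 300,
                                 exclude_cm = c(0.05, 0.15)) {
  if (inherits(scans, "lamm_scans")) scans <- scans$scans
  stopifnot(inherits(fit, "lamm_fit"))
  lo <- fit$params$meniscus + exclude_cm[1]
  hi <- fit$params$bottom - exclude_cm[2]
  scans <- lapply(scans, function(sc)
    sc[sc$radius_cm >= lo & sc$radius_cm <= hi, , drop = FALSE])
  times <- vapply(scans, function(sc) sc$time_s[1], numeric(1))

  sim_at <- function(p) {
    sim <- simulate_lamm(p, times, n_r = n_r)
    unlist(lapply(seq_along(scans), function(i)
      stats::approx(sim$radii, sim$scans[[i]]$signal,
                    xout = scans[[i]]$radius_cm, rule = 2)$y))
  }
  p1 <- fit$params
  single <- sim_at(p1)
  pm <- p1; pm$loading <- p1$loading * (1 - association_fraction)
  pd <- p1; pd$s <- p1$s * 2^(2 / 3); pd$mr_kda <- 2 * p1$mr_kda
  pd$loading <- p1$loading * association_fraction
  assoc <- sim_at(pm) + sim_at(pd)

  rms_diff <- sqrt(mean((assoc - single)^2))
  structure(list(rms_difference = rms_diff, noise_floor = fit$rms,
                 detectable = rms_diff > fit$rms,
                 association_fraction = association_fraction,
                 kd_bound_uM = kd_from_association(conc_uM, conc_uM,
                                                   association_fraction)),
            class = "detectability_report")
}

#' @export
print.detectability_report <- function(x, ...) {
  cat(sprintf(
    "Detectability: %0.0f%% association deviates RMS %.3g vs noise floor %.3g -> %s\n",
    100 * x$association_fraction, x$rms_difference, x$noise_floor,
    if (x$detectable) "detectable" else "not detectable"))
  cat(sprintf("  implied Kd bound: %.4g uM\n", x$kd_bound_uM))
  invisible(x)
}
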