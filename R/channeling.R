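#' Michaelis-Menten parameter pair
#'
#' @param vmax maximal specific activity (U/mg), > 0.
#' @param km Michaelis constant (uM), > 0.
#' @param vmax_err,km_err standard errors (same units; default `NA`).
#' @return object of class `michaelis_params`.
#' @export
michaelis_params <- function(vmax, km, vmax_err = NA_real_, km_err = NA_real_) {
  if (!is.finite(vmax) || !is.finite(km) || vmax <= 0 || km <= 0)
    stop("michaelis_params: vmax and km must be positive", call. = FALSE)
  structure(list(vmax = vmax, km = km, vmax_err = vmax_err, km_err = km_err),
            class = "michaelis_params")
}

#' @export
print.michaelis_params <- function(x, ...) {
  cat(sprintf("Michaelis-Menten: Vmax = %.4g +/- %.2g U/mg, Km = %.4g +/- %.2g uM\n",
              x$vmax, x$vmax_err, x$km, x$km_err))
  invisible(x)
}

#' Predicted free-diffusion LDH activity
#'
#' The expected acceptor activity if all delivery is by free diffusion:
#' \deqn{V_{cal} = \frac{V_{max} [NADH]_f}{K_m + [NADH]_f}}
#' with the free NADH concentration from the exact depletion-corrected
#' equilibrium ([free_ligand()]).
#'
#' @param nadh_total_uM total NADH (uM); vectorised.
#' @param gapdh_sites_uM donor site concentration (uM); vectorised.
#' @param kd_gapdh donor-NADH dissociation constant (uM).
#' @param mm a [michaelis_params()] for the acceptor with free NADH.
#' @return predicted specific activity (U/mg).
#' @examples
#' calc_vcal(40, 240, 0.8, michaelis_params(140, 4.4))  # ~4.9 U/mg
#' @export
calc_vcal <- function(nadh_total_uM, gapdh_sites_uM, kd_gapdh, mm) {
  stopifnot(inherits(mm, "michaelis_params"))
  nf <- ifelse(nadh_total_uM == 0, 0,
               free_ligand(gapdh_sites_uM, nadh_total_uM, kd_gapdh))
  mm$vmax * nf / (mm$km + nf)
}

#' First-order error propagation for the free-diffusion prediction
#'
#' Delta-method standard error of [calc_vcal()] from the uncertainties of the
#' donor Kd and the acceptor Vmax/Km, using numerical gradients.
#'
#' @inheritParams calc_vcal
#' @param kd_err standard error of `kd_gapdh` (uM).
#' @return standard error of the predicted activity (U/mg).
#' @export
calc_vcal_se <- function(nadh_total_uM, gapdh_sites_uM, kd_gapdh, mm,
                         kd_err = 0) {
  f <- function(kd, vmax, km)
    calc_vcal(nadh_total_uM, gapdh_sites_uM, kd,
              michaelis_params(vmax, km))
  h <- function(x) max(abs(x) * 1e-5, 1e-10)
  gk <- (f(kd_gapdh + h(kd_gapdh), mm$vmax, mm$km) -
         f(kd_gapdh - h(kd_gapdh), mm$vmax, mm$km)) / (2 * h(kd_gapdh))
  gv <- (f(kd_gapdh, mm$vmax + h(mm$vmax), mm$km) -
         f(kd_gapdh, mm$vmax - h(mm$vmax), mm$km)) / (2 * h(mm$vmax))
  gm <- (f(kd_gapdh, mm$vmax, mm$km + h(mm$km)) -
         f(kd_gapdh, mm$vmax, mm$km - h(mm$km))) / (2 * h(mm$km))
  verr <- if (is.finite(mm$vmax_err)) mm$vmax_err else 0
  merr <- if (is.finite(mm$km_err)) mm$km_err else 0
  sqrt((gk * kd_err)^2 + (gv * verr)^2 + (gm * merr)^2)
}

#' Channeling ratio
#'
#' Ratio of measured to calculated (free-diffusion) acceptor activity.
#' Values near 1 indicate delivery by diffusion alone; values above 1
#' indicate channeling.
#'
#' @param v_measured measured specific activity (U/mg).
#' @param v_cal predicted free-diffusion activity (U/mg), > 0.
#' @return dimensionless ratio (vectorised).
#' @export
channeling_ratio <- function(v_measured, v_cal) {
  if (any(v_cal <= 0))
    stop("channeling_ratio: undefined for v_cal <= 0", call. = FALSE)
  v_measured / v_cal
}

#' Assemble an enzyme-buffering dataset
#'
#' @param design `"titrate_gapdh_fixed_nadh"` (vary donor at fixed NADH) or
#'   `"titrate_nadh_fixed_gapdh"` (vary NADH at fixed donor).
#' @param nadh_total_uM,gapdh_sites_uM,ldh_nM,v_measured_U_mg per-point
#'   vectors (>= 4 points; the varied quantity must be strictly monotone).
#' @param kd_gapdh donor-NADH Kd (uM).
#' @param acceptor_mm a [michaelis_params()] for the acceptor with free NADH.
#' @param pyruvate_uM assay pyruvate (uM, metadata; default 630).
#' @return object of class `buffering_dataset` (a data.frame with
#'   attributes).
#' @export
buffering_dataset <- function(design = c("titrate_gapdh_fixed_nadh",
                                         "titrate_nadh_fixed_gapdh"),
                              nadh_total_uM, gapdh_sites_uM, ldh_nM,
                              v_measured_U_mg, kd_gapdh, acceptor_mm,
                              pyruvate_uM = 630) {
  design <- match.arg(design)
  stopifnot(inherits(acceptor_mm, "michaelis_params"))
  n <- length(v_measured_U_mg)
  df <- data.frame(nadh_total_uM = rep_len(nadh_total_uM, n),
                   gapdh_sites_uM = rep_len(gapdh_sites_uM, n),
                   ldh_nM = rep_len(ldh_nM, n),
                   v_measured_U_mg = v_measured_U_mg)
  if (n < 4) stop("buffering_dataset: need >= 4 points", call. = FALSE)
  if (any(df < 0)) stop("buffering_dataset: negative values", call. = FALSE)
  if (pyruvate_uM <= 0) stop("buffering_dataset: pyruvate must be positive",
                             call. = FALSE)
  varied <- if (design == "titrate_gapdh_fixed_nadh") df$gapdh_sites_uM
            else df$nadh_total_uM
  inc <- !is.unsorted(varied, strictly = TRUE)
  dec <- !is.unsorted(rev(varied), strictly = TRUE)
  if (!inc && !dec)
    stop("buffering_dataset: the varied quantity must be strictly monotone",
         call. = FALSE)
  if (kd_gapdh <= 0) stop("buffering_dataset: kd_gapdh must be positive",
                          call. = FALSE)
  structure(df, design = design, kd_gapdh = kd_gapdh,
            acceptor_mm = acceptor_mm, pyruvate_uM = pyruvate_uM,
            class = c("buffering_dataset", "data.frame"))
}

#' Fit Michaelis-Menten parameters to initial rates
#'
#' Nonlinear least squares `v = Vmax * c / (Km + c)` with standard errors,
#' initialised from the rate maximum and the half-maximal concentration.
#'
#' @param conc_uM substrate concentrations (uM), >= 4 points that bracket the
#'   Km.
#' @param rates_U_mg initial specific activities (U/mg).
#' @return object of class `mm_fit` containing a [michaelis_params()] and the
#'   fit (`fitted`, `residuals`, `data`).
#' @export
fit_michaelis <- function(conc_uM, rates_U_mg) {
  if (length(conc_uM) != length(rates_U_mg) || length(conc_uM) < 4)
    stop("fit_michaelis: need >= 4 matched (conc, rate) points",
         call. = FALSE)
  vmax0 <- max(rates_U_mg) * 1.2
  km0 <- stats::approx(rates_U_mg, conc_uM, xout = max(rates_U_mg) / 2,
                       ties = mean)$y
  if (!is.finite(km0) || km0 <= 0) km0 <- stats::median(conc_uM)
  dat <- data.frame(conc = conc_uM, v = rates_U_mg)
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ vmax * conc / (km + conc), data = dat,
                      start = list(vmax = vmax0, km = km0),
                      lower = c(1e-12, 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("fit_michaelis: nonlinear fit failed to converge (",
           conditionMessage(e), ")", call. = FALSE))
  cf <- stats::coef(fit); se <- summary(fit)$coefficients[, "Std. Error"]
  structure(list(params = michaelis_params(cf[["vmax"]], cf[["km"]],
                                           se[["vmax"]], se[["km"]]),
                 fitted = stats::fitted(fit),
                 residuals = stats::residuals(fit),
                 data = dat, nls = fit),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("Michaelis-Menten fit over", nrow(x$data), "points\n  ")
  print(x$params)
  invisible(x)
}

#' @export
coef.mm_fit <- function(object, ...)
  c(vmax = object$params$vmax, km = object$params$km)

#' @export
residuals.mm_fit <- function(object, ...) object$residuals

#' @export
predict.mm_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$data$conc else newdata$conc
  object$params$vmax * conc / (object$params$km + conc)
}

#' @export
summary.mm_fit <- function(object, ...) summary(object$nls, ...)

#' @export
plot.mm_fit <- function(x, ...) {
  graphics::plot(x$data$conc, x$data$v, xlab = "substrate (uM)",
                 ylab = "rate (U/mg)", ...)
  cc <- seq(0, max(x$data$conc), length.out = 200)
  graphics::lines(cc, x$params$vmax * cc / (x$params$km + cc))
  invisible(x)
}

#' Channeled-profile subtraction and apparent Michaelis-Menten constants
#'
#' The core of the enzyme-buffering analysis.  For every assay point the
#' free-diffusion prediction ([calc_vcal()]) and the channeling ratio are
#' computed; the channeled activity is the excess
#' `v_channeled = v_measured - v_cal` (retained even when negative, so the
#' no-channeling null is unbiased).  For NADH-titration designs the channeled
#' profile is then fitted by Michaelis-Menten kinetics against the
#' donor-NADH complex concentration (`nadh_total - free NADH`; set
#' `substrate_axis = "total_nadh"` to fit against total NADH instead, the
#' axis conventionally plotted), yielding apparent constants for the complex
#' as substrate.
#'
#' @param dataset a [buffering_dataset()].
#' @param substrate_axis `"complex"` (default) or `"total_nadh"`.
#' @return object of class `channeling_fit`: per-point `table` (v_cal, ratio,
#'   v_channeled, both substrate axes), `apparent_mm` (a `mm_fit`, or `NULL`
#'   with `no_channeling = TRUE` when every point is at or below the
#'   free-diffusion prediction), and the input metadata.
#' @export
channeled_profile <- function(dataset, substrate_axis = c("complex",
                                                          "total_nadh")) {
  stopifnot(inherits(dataset, "buffering_dataset"))
  substrate_axis <- match.arg(substrate_axis)
  kd <- attr(dataset, "kd_gapdh")
  mm <- attr(dataset, "acceptor_mm")
  design <- attr(dataset, "design")
  nf <- free_ligand(dataset$gapdh_sites_uM, dataset$nadh_total_uM, kd)
  vcal <- calc_vcal(dataset$nadh_total_uM, dataset$gapdh_sites_uM, kd, mm)
  tab <- data.frame(nadh_total_uM = dataset$nadh_total_uM,
                    gapdh_sites_uM = dataset$gapdh_sites_uM,
                    free_nadh_uM = nf,
                    complex_uM = dataset$nadh_total_uM - nf,
                    v_measured = dataset$v_measured_U_mg,
                    v_cal = vcal,
                    ratio = channeling_ratio(dataset$v_measured_U_mg, vcal),
                    v_channeled = dataset$v_measured_U_mg - vcal)
  no_chan <- all(tab$v_channeled <= 0)
  app <- NULL
  if (!no_chan && design == "titrate_nadh_fixed_gapdh") {
    xx <- if (substrate_axis == "complex") tab$complex_uM else tab$nadh_total_uM
    app <- tryCatch(fit_michaelis(xx, tab$v_channeled),
                    error = function(e) NULL)
  }
  structure(list(table = tab, apparent_mm = app, no_channeling = no_chan,
                 design = design, substrate_axis = substrate_axis,
                 kd_gapdh = kd, acceptor_mm = mm),
            class = "channeling_fit")
}

#' @export
print.channeling_fit <- function(x, ...) {
  cat("Enzyme-buffering channeling analysis (", x$design, ")\n", sep = "")
  cat(sprintf("  ratios %.3g - %.3g over %d points\n",
              min(x$table$ratio), max(x$table$ratio), nrow(x$table)))
  if (x$no_channeling)
    cat("  no channeling detected (all points at or below free-diffusion prediction)\n")
  else if (!is.null(x$apparent_mm)) {
    cat("  apparent constants for the donor-NADH complex as substrate:\n    ")
    print(x$apparent_mm$params)
  }
  invisible(x)
}

#' @export
summary.channeling_fit <- function(object, ...) {
  out <- list(table = object$table, no_channeling = object$no_channeling,
              apparent = if (!is.null(object$apparent_mm))
                object$apparent_mm$params else NULL,
              mean_ratio = mean(object$table$ratio),
              design = object$design)
  class(out) <- "summary.channeling_fit"
  out
}

#' @export
print.summary.channeling_fit <- function(x, ...) {
  cat("Channeling analysis (", x$design, "): mean ratio ",
      signif(x$mean_ratio, 4), "\n", sep = "")
  print(x$table, digits = 4)
  if (!is.null(x$apparent)) print(x$apparent)
  invisible(x)
}

#' @export
coef.channeling_fit <- function(object, ...) {
  if (is.null(object$apparent_mm)) return(NULL)
  coef(object$apparent_mm)
}

#' @export
fitted.channeling_fit <- function(object, ...) object$table$v_cal

#' @export
residuals.channeling_fit <- function(object, ...) object$table$v_channeled

#' @export
plot.channeling_fit <- function(x, ...) {
  tab <- x$table
  xx <- if (x$design == "titrate_gapdh_fixed_nadh") tab$gapdh_sites_uM
        else tab$nadh_total_uM
  xl <- if (x$design == "titrate_gapdh_fixed_nadh") "GAPDH sites (uM)"
        else "total NADH (uM)"
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(old))
  graphics::plot(xx, tab$ratio, xlab = xl, ylab = "measured / calculated",
                 pch = 19, ...)
  graphics::abline(h = 1, lty = 2)
  graphics::matplot(xx, cbind(tab$v_measured, tab$v_cal, tab$v_channeled),
                    type = "b", pch = c(19, 1, 2), lty = 1, xlab = xl,
                    ylab = "rate (U/mg)")
  graphics::legend("topleft", c("measured", "calculated", "channeled"),
                   pch = c(19, 1, 2), bty = "n")
  invisible(x)
}

#' Antibody competition diffusion-limit check
#'
#' In the antibody control, bulky anti-LDH antibodies block the
#' protein-protein (channeled) path while barely affecting free-NADH
#' turnover, so at saturating antibody the measured rate should fall to the
#' free-diffusion prediction.  This check detects the high-antibody plateau
#' and compares it with [calc_vcal()].
#'
#' @param antibody_nM ascending antibody concentrations (nM).
#' @param v_measured measured specific activities (U/mg), same length.
#' @param nadh_total_uM,gapdh_sites_uM,kd_gapdh,mm assay condition for the
#'   free-diffusion prediction.
#' @param tolerance relative tolerance for the pass flag (default 0.15).
#' @param plateau_tol maximal relative difference between the last two points
#'   for a plateau to be declared (default 0.10).
#' @return list of class `diffusion_limit_report`: `plateau`, `v_cal`,
#'   `ratio` (plateau / v_cal), `pass`, `plateau_detected`.
#' @export
diffusion_limit_check <- function(antibody_nM, v_measured, nadh_total_uM,
                                  gapdh_sites_uM, kd_gapdh, mm,
                                  tolerance = 0.15, plateau_tol = 0.10) {
  if (length(antibody_nM) != length(v_measured))
    stop("diffusion_limit_check: length mismatch", call. = FALSE)
  if (is.unsorted(antibody_nM, strictly = TRUE))
    stop("diffusion_limit_check: antibody concentrations must be ascending",
         call. = FALSE)
  vcal <- calc_vcal(nadh_total_uM, gapdh_sites_uM, kd_gapdh, mm)
  n <- length(v_measured)
  plateau_ok <- n >= 2 &&
    abs(v_measured[n] - v_measured[n - 1]) <=
      plateau_tol * abs(v_measured[n - 1])
  if (!plateau_ok) {
    warning("diffusion_limit_check: no plateau detected at high antibody; ",
            "extend the titration")
    plateau <- if (n >= 1) v_measured[n] else NA_real_
  } else plateau <- mean(v_measured[c(n - 1, n)])
  ratio <- plateau / vcal
  structure(list(plateau = plateau, v_cal = vcal, ratio = ratio,
                 pass = plateau_ok && abs(ratio - 1) <= tolerance,
                 plateau_detected = plateau_ok, tolerance = tolerance),
            class = "diffusion_limit_report")
}

#' @export
print.diffusion_limit_report <- function(x, ...) {
  cat(sprintf(
    "Diffusion-limit check: plateau %.4g U/mg vs Vcal %.4g (ratio %.3g) -> %s\n",
    x$plateau, x$v_cal, x$ratio,
    if (isTRUE(x$pass)) "PASS" else if (x$plateau_detected) "FAIL"
    else "no plateau"))
  invisible(x)
}
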