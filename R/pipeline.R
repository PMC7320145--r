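#' @name pipeline
#' @title CSV dialects and end-to-end analysis
#' @description Readers and writers for the plain-text formats the pipeline
#' exchanges, input validation, and the orchestrated workflow
#' ([run_full_analysis()]).  Column names carry their units (`*_uM`, `*_nM`,
#' `time_min`) to keep the unit conventions (uM, minutes, U/mg) explicit at
#' the file boundary.
NULL

#' Read / write a fluorescence titration CSV
#'
#' Columns: `mode`, `ligand_uM`, `signal`, `site_conc_uM`; one titration per
#' file, header required.
#'
#' @param path CSV path.
#' @return a `fluorescence_titration` (without wavelength metadata).
#' @export
read_titration_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("mode", "ligand_uM", "signal", "site_conc_uM")
  if (!all(req %in% names(df)))
    stop("read_titration_csv: missing columns: ",
         paste(setdiff(req, names(df)), collapse = ", "), call. = FALSE)
  structure(list(ligand_uM = df$ligand_uM, signal = df$signal,
                 site_uM = df$site_conc_uM[1], mode = df$mode[1],
                 excitation_nm = NA_real_, emission_nm = NA_real_,
                 true_kd = NA_real_),
            class = "fluorescence_titration")
}

#' @rdname read_titration_csv
#' @param titration a `fluorescence_titration`.
#' @export
write_titration_csv <- function(titration, path) {
  utils::write.csv(data.frame(mode = titration$mode,
                              ligand_uM = titration$ligand_uM,
                              signal = titration$signal,
                              site_conc_uM = titration$site_uM),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read / write a progress-curve CSV (`time_min`, `abs340`)
#' @param path CSV path.
#' @param ... passed to [progress_curve()] (path length, epsilon).
#' @return a [progress_curve()].
#' @export
read_progress_csv <- function(path, ...) {
  df <- utils::read.csv(path)
  if (!all(c("time_min", "abs340") %in% names(df)))
    stop("read_progress_csv: need columns time_min, abs340", call. = FALSE)
  progress_curve(df$time_min, df$abs340, ...)
}

#' @rdname read_progress_csv
#' @param curve a [progress_curve()].
#' @export
write_progress_csv <- function(curve, path) {
  utils::write.csv(data.frame(time_min = curve$time_min,
                              abs340 = curve$abs340),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read / write an enzyme-buffering dataset CSV
#'
#' Columns: `design`, `nadh_total_uM`, `gapdh_sites_uM`, `ldh_nM`,
#' `v_measured_U_mg`.  The donor Kd and acceptor Michaelis constants are
#' configuration, not data, and are supplied separately.
#'
#' @param path CSV path.
#' @param kd_gapdh donor-NADH Kd (uM).
#' @param acceptor_mm a [michaelis_params()].
#' @return a [buffering_dataset()].
#' @export
read_buffering_csv <- function(path, kd_gapdh, acceptor_mm) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("design", "nadh_total_uM", "gapdh_sites_uM", "ldh_nM",
           "v_measured_U_mg")
  if (!all(req %in% names(df)))
    stop("read_buffering_csv: missing columns: ",
         paste(setdiff(req, names(df)), collapse = ", "), call. = FALSE)
  buffering_dataset(design = df$design[1],
                    nadh_total_uM = df$nadh_total_uM,
                    gapdh_sites_uM = df$gapdh_sites_uM,
                    ldh_nM = df$ldh_nM,
                    v_measured_U_mg = df$v_measured_U_mg,
                    kd_gapdh = kd_gapdh, acceptor_mm = acceptor_mm)
}

#' @rdname read_buffering_csv
#' @param dataset a [buffering_dataset()].
#' @export
write_buffering_csv <- function(dataset, path) {
  utils::write.csv(data.frame(design = attr(dataset, "design"),
                              as.data.frame(dataset)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read / write sedimentation scans CSV (`time_s`, `radius_cm`, `abs280`)
#'
#' One block of rows per scan, identified by `time_s`.
#'
#' @param path CSV path.
#' @return list of scan data.frames (`time_s`, `radius_cm`, `signal`).
#' @export
read_scans_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "radius_cm", "abs280") %in% names(df)))
    stop("read_scans_csv: need columns time_s, radius_cm, abs280",
         call. = FALSE)
  lapply(split(df, df$time_s), function(b)
    data.frame(time_s = b$time_s, radius_cm = b$radius_cm,
               signal = b$abs280))
}

#' @rdname read_scans_csv
#' @param scans a scan list or `lamm_scans` object.
#' @export
write_scans_csv <- function(scans, path) {
  if (inherits(scans, "lamm_scans")) scans <- scans$scans
  df <- do.call(rbind, lapply(scans, function(sc)
    data.frame(time_s = sc$time_s, radius_cm = sc$radius_cm,
               abs280 = sc$signal)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Validate pipeline inputs
#'
#' Schema and unit-sanity checks on every referenced CSV: required columns
#' (header-driven, column order free), no negative concentrations, plausible
#' micromolar ranges.  Malformed files raise errors naming the file; soft
#' problems are returned as a diagnostics data.frame.
#'
#' @param config a run configuration (list or YAML path, see
#'   [run_full_analysis()]).
#' @return data.frame with columns `file`, `level`, `message` (zero rows when
#'   all inputs are clean).
#' @export
validate_inputs <- function(config) {
  config <- .load_config(config)
  diags <- list()
  note <- function(file, level, message)
    diags[[length(diags) + 1]] <<- data.frame(file = file, level = level,
                                              message = message)
  for (p in config$titration_csvs) {
    ti <- read_titration_csv(p)   # errors on schema problems
    if (any(ti$ligand_uM < 0)) note(p, "error", "negative ligand concentration")
    if (any(ti$ligand_uM > 1e5)) note(p, "warning",
                                      "ligand above 0.1 M; check units")
  }
  if (!is.null(config$buffering_csv)) {
    df <- utils::read.csv(config$buffering_csv)
    req <- c("design", "nadh_total_uM", "gapdh_sites_uM", "ldh_nM",
             "v_measured_U_mg")
    miss <- setdiff(req, names(df))
    if (length(miss))
      stop("validate_inputs: ", config$buffering_csv, " missing columns ",
           paste(miss, collapse = ", "), call. = FALSE)
    num <- df[setdiff(req, "design")]
    if (any(num < 0))
      note(config$buffering_csv, "error", "negative value in numeric column")
    if (any(df$nadh_total_uM > 1e4))
      note(config$buffering_csv, "warning", "NADH above 10 mM; check units")
  }
  for (p in config$progress_csvs) read_progress_csv(p)
  if (length(diags)) do.call(rbind, diags)
  else data.frame(file = character(), level = character(),
                  message = character())
}

.load_config <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or YAML path",
                             call. = FALSE)
  defaults <- list(titration_csvs = character(), progress_csvs = character(),
                   buffering_csv = NULL, blank_csv = NULL,
                   kd_uM = NULL, acceptor_vmax_U_mg = NULL,
                   acceptor_km_uM = NULL, out_dir = tempfile("chankin_run_"),
                   seed = 1L, diffusion_limit_tol = 0.15)
  config <- utils::modifyList(defaults, config)
  missing_files <- c(config$titration_csvs, config$progress_csvs,
                     config$buffering_csv, config$blank_csv)
  missing_files <- missing_files[!file.exists(missing_files)]
  if (length(missing_files))
    stop("config references missing files: ",
         paste(missing_files, collapse = ", "), call. = FALSE)
  config
}

#' Run the full enzyme-buffering analysis
#'
#' Orchestrates the pipeline: fit per-mode Kd values from titration CSVs
#' (or take a supplied `kd_uM`), extract initial rates from any progress
#' curves, run the channeling analysis on the buffering dataset, and write
#' per-stage CSVs plus a machine-readable JSON manifest.  Deterministic for
#' a fixed seed.
#'
#' @param config list or YAML path with entries: `titration_csvs` (character
#'   vector, optional if `kd_uM` given), `kd_uM` (optional donor Kd),
#'   `acceptor_vmax_U_mg` and `acceptor_km_uM` (required), `buffering_csv`
#'   (optional), `progress_csvs` and `blank_csv` (optional), `out_dir`,
#'   `seed`.
#' @return invisibly, a list with `kd` (aggregate), `kd_table`, `rates`,
#'   `channeling` (a `channeling_fit` or NULL), `manifest_path`, `out_dir`.
#' @export
run_full_analysis <- function(config) {
  config <- .load_config(config)
  set.seed(config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed,
                   defaults = list(diffusion_limit_tol =
                                     config$diffusion_limit_tol))

  # stage 1: donor Kd
  kd_table <- NULL; kd_used <- config$kd_uM
  if (length(config$titration_csvs)) {
    fits <- lapply(config$titration_csvs, function(p)
      tryCatch(fit_titration(read_titration_csv(p)),
               error = function(e)
                 stop("run_full_analysis [fit-kd stage] ", p, ": ",
                      conditionMessage(e), call. = FALSE)))
    kd_table <- data.frame(
      mode = vapply(fits, `[[`, character(1), "mode"),
      kd_uM = vapply(fits, `[[`, numeric(1), "kd"),
      stderr_uM = vapply(fits, `[[`, numeric(1), "stderr"))
    agg <- aggregate_kd(fits)
    kd_table <- rbind(kd_table,
                      data.frame(mode = "average", kd_uM = agg$mean,
                                 stderr_uM = agg$sd))
    utils::write.csv(kd_table, file.path(config$out_dir, "kd_table.csv"),
                     row.names = FALSE)
    if (is.null(kd_used)) kd_used <- agg$mean
  }
  if (is.null(kd_used))
    stop("run_full_analysis: no titrations and no kd_uM supplied",
         call. = FALSE)
  manifest$kd_uM <- kd_used

  # stage 2: initial rates from progress curves
  rates <- NULL
  if (length(config$progress_csvs)) {
    blank <- if (!is.null(config$blank_csv))
      read_progress_csv(config$blank_csv) else NULL
    rates <- do.call(rbind, lapply(config$progress_csvs, function(p) {
      cv <- read_progress_csv(p)
      if (!is.null(blank)) cv <- subtract_scatter_baseline(cv, blank)
      ir <- initial_rate(cv)
      data.frame(file = basename(p), v0_uM_min = ir$v0,
                 stderr = ir$stderr, method = ir$method)
    }))
    utils::write.csv(rates, file.path(config$out_dir, "rates.csv"),
                     row.names = FALSE)
  }

  # stage 3: channeling analysis
  chan <- NULL
  if (!is.null(config$buffering_csv)) {
    if (is.null(config$acceptor_vmax_U_mg) || is.null(config$acceptor_km_uM))
      stop("run_full_analysis: acceptor_vmax_U_mg and acceptor_km_uM are ",
           "required for the channeling stage", call. = FALSE)
    mm <- michaelis_params(config$acceptor_vmax_U_mg, config$acceptor_km_uM)
    ds <- read_buffering_csv(config$buffering_csv, kd_used, mm)
    chan <- channeled_profile(ds)
    utils::write.csv(chan$table,
                     file.path(config$out_dir, "channeling_table.csv"),
                     row.names = FALSE)
    if (!is.null(chan$apparent_mm)) {
      ap <- chan$apparent_mm$params
      utils::write.csv(data.frame(vmax_U_mg = ap$vmax, km_uM = ap$km,
                                  vmax_err = ap$vmax_err, km_err = ap$km_err),
                       file.path(config$out_dir, "apparent_mm.csv"),
                       row.names = FALSE)
    }
    manifest$channeling <- list(mean_ratio = mean(chan$table$ratio),
                                no_channeling = chan$no_channeling,
                                apparent_km_uM = if (!is.null(chan$apparent_mm))
                                  chan$apparent_mm$params$km else NA)
  }

  manifest$outputs <- setdiff(list.files(config$out_dir), "manifest.json")
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(kd = kd_used, kd_table = kd_table, rates = rates,
                 channeling = chan, manifest_path = manifest_path,
                 out_dir = config$out_dir))
}
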