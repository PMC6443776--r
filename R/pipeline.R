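## deep-merge user config over defaults
merge_config <- function(defaults, user) {
  if (is.null(user)) return(defaults)
  utils::modifyList(defaults, user)
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("config must be a list or a JSON file path")
  config
}

provenance_block <- function(config) {
  list(package = "silkstruct",
       version = as.character(utils::packageVersion("silkstruct")),
       config = config)
}

write_bundle <- function(bundle, out_dir) {
  if (is.null(out_dir)) return(invisible(bundle))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in setdiff(names(bundle), "tables")) {
    jsonlite::write_json(bundle[[nm]],
                         file.path(out_dir, paste0(nm, ".json")),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         na = "null")
  }
  for (nm in names(bundle$tables))
    utils::write.csv(bundle$tables[[nm]],
                     file.path(out_dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  invisible(bundle)
}

static_defaults <- function() {
  list(seed = 1L,
       waxd = list(crystallinity = 0.44,
                   cell = c(9.39, 9.50, 6.98),
                   wavelength = 0.15418),
       saxs = list(long_period = 38.5,
                   phase1_fraction = 15.7 / 38.5,
                   n_orders = 5L),
       equatorial = list(bundle_thickness = 150,
                         fibril_spacing = 4.7,
                         wavelength = 0.15418,
                         instrumental_fwhm = 0.005))
}

#' Static structural characterisation run
#'
#' Synthesises (or loads) the static WAXD profile, meridional and equatorial
#' SAXS profiles, and runs the full static analysis chain: crystallinity
#' deconvolution, harmonic long-period detection, correlation-function
#' decomposition, and Scherrer bundle size. All resolved parameters and the
#' package version are recorded in the bundle's provenance block, so a rerun
#' with the same config and seed is bit-identical.
#'
#' @param config list or JSON path; see `silkstruct:::static_defaults()` for
#'   the fields and their defaults. Set `config$waxd$profile` /
#'   `config$saxs$profile` / `config$equatorial$profile` to file paths to
#'   analyse measured profiles instead of synthetic ones.
#' @param out_dir optional output directory; per-stage JSON results and tidy
#'   CSV tables are written there.
#' @return a list of class `report_bundle`.
#' @export
run_static_analysis <- function(config = list(), out_dir = NULL) {
  config <- merge_config(static_defaults(), load_config(config))

  cw <- config$waxd
  cell <- unit_cell(cw$cell[1], cw$cell[2], cw$cell[3])
  waxd_prof <- if (!is.null(cw$profile)) read_profile(cw$profile) else
    generate_waxd_profile(beta_sheet_waxd_params(
      crystallinity = cw$crystallinity, cell = cell,
      wavelength = cw$wavelength, noise = cw$noise,
      seed = config$seed))$profile
  xc <- fit_crystallinity(waxd_prof, cell)

  cs <- config$saxs
  sax_prof <- if (!is.null(cs$profile)) read_profile(cs$profile) else
    generate_saxs_meridional(lamellar_params(
      long_period = cs$long_period,
      phase1_fraction = cs$phase1_fraction,
      n_orders = cs$n_orders, noise = cs$noise,
      seed = config$seed))$profile
  lp <- find_harmonic_peaks(kratky_transform(sax_prof))
  cf <- correlation_function(sax_prof)

  ce <- config$equatorial
  eq_prof <- if (!is.null(ce$profile)) read_profile(ce$profile) else
    generate_saxs_equatorial(
      bundle_thickness = ce$bundle_thickness,
      fibril_spacing = ce$fibril_spacing,
      wavelength = ce$wavelength,
      instrumental_fwhm = ce$instrumental_fwhm,
      seed = config$seed)$profile
  pk <- fit_equatorial_peak(eq_prof)
  sc <- scherrer_thickness(pk$center_q, pk$fwhm_q, ce$instrumental_fwhm,
                           eq_prof$wavelength)

  summary_tbl <- data.frame(
    quantity = c("crystallinity", "long_period_1st", "lp_ratio_2nd_3rd",
                 "corr_Lp", "corr_d_pI", "corr_d_pI_mean",
                 "corr_phase2_thickness", "fibril_spacing",
                 "bundle_thickness"),
    value = c(xc$Xc, lp$lp_1st, lp$ratio_2nd_3rd, cf$Lp, cf$d_pI,
              cf$d_pI_mean, cf$phase2_thickness, 2 * pi / pk$center_q,
              sc$d),
    units = c("percent", "nm", "", "nm", "nm", "nm", "nm", "nm", "nm"))

  bundle <- structure(list(
    crystallinity = list(Xc_percent = xc$Xc, Ic = xc$Ic, Ia = xc$Ia),
    long_period = list(lp_1st_nm = lp$lp_1st, lp_2nd_nm = lp$lp_2nd,
                       lp_3rd_nm = lp$lp_3rd,
                       ratio_2nd_3rd = lp$ratio_2nd_3rd),
    correlation = list(Q = cf$Q, Lp_nm = cf$Lp, d_pI_nm = cf$d_pI,
                       d_pI_mean_nm = cf$d_pI_mean,
                       phase2_thickness_nm = cf$phase2_thickness),
    scherrer = list(bundle_thickness_nm = sc$d,
                    beta_rad = sc$beta, K_factor = sc$K_factor),
    provenance = provenance_block(config),
    tables = list(static_summary = summary_tbl)),
    class = "report_bundle")
  write_bundle(bundle, out_dir)
}

deformation_defaults <- function() {
  list(seed = 1L,
       tensile = list(modulus = 28.1, yield_strain = 0.033,
                      fracture_strain = 0.22, strength = 1.4),
       gauge_length_mm = 15,
       stretch_rate_mm_s = 0.01,
       frame_interval_s = 9,
       lp_path = list(initial = 37.5, at_yield = 38.1, at_fracture = 44.7),
       d002_path = list(initial = 3.52, at_yield = 3.54,
                        at_fracture = 3.57),
       orientation_path = list(initial = 0.90, at_fracture = 0.84),
       wavelength = 0.0709)
}

## piecewise-linear structural trajectory against bulk strain (two stages)
stage_path <- function(strain_pct, yield_pct, fracture_pct, p) {
  at_yield <- p$at_yield %||% p$initial
  ifelse(strain_pct <= yield_pct,
         p$initial + (at_yield - p$initial) * strain_pct / yield_pct,
         at_yield + (p$at_fracture - at_yield) *
           (strain_pct - yield_pct) / (fracture_pct - yield_pct))
}

#' Time-resolved deformation analysis run
#'
#' Simulates the simultaneous tensile + scattering experiment (frames every
#' `frame_interval_s` during continuous stretching), re-measures each
#' frame's meridional SAXS harmonics and 002 WAXD centre from synthetic
#' profiles, joins them with the tensile log, and emits the deformation
#' series plus a per-stage summary table (stage I / II / total layout:
#' sample length, bulk strain, d002, crystal strain, long period,
#' long-period strain).
#'
#' @param config list or JSON path; see
#'   `silkstruct:::deformation_defaults()`.
#' @param out_dir optional output directory.
#' @return a list of class `report_bundle`; `$series` is the
#'   [assemble_deformation_series()] data.frame.
#' @export
run_deformation_analysis <- function(config = list(), out_dir = NULL) {
  config <- merge_config(deformation_defaults(), load_config(config))
  ct <- config$tensile
  hardening <- (ct$strength - ct$modulus * ct$yield_strain) /
    (ct$fracture_strain - ct$yield_strain)
  params <- tensile_params(modulus = ct$modulus,
                           yield_strain = ct$yield_strain,
                           hardening_slope = hardening,
                           fracture_strain = ct$fracture_strain)
  l0 <- config$gauge_length_mm
  rate_pct <- config$stretch_rate_mm_s / l0 * 100       # percent per s
  t_end <- ct$fracture_strain * 100 / rate_pct
  log_t <- seq(0, t_end, by = 1)
  tensile_log <- data.frame(
    time = log_t,
    displacement = config$stretch_rate_mm_s * log_t,
    stress = tensile_law(params, config$stretch_rate_mm_s * log_t / l0))

  frame_t <- seq(0, t_end, by = config$frame_interval_s)
  strain_pct <- rate_pct * frame_t
  ey <- ct$yield_strain * 100; ef <- ct$fracture_strain * 100
  lp_true <- stage_path(strain_pct, ey, ef, config$lp_path)
  d002_true <- stage_path(strain_pct, ey, ef, config$d002_path)
  orient <- config$orientation_path$initial +
    (config$orientation_path$at_fracture -
       config$orientation_path$initial) * strain_pct / ef

  # re-measure every frame from a synthetic profile (round trip)
  lp2 <- lp3 <- d002_meas <- numeric(length(frame_t))
  tt002_grid <- NULL
  for (i in seq_along(frame_t)) {
    prof <- generate_saxs_meridional(
      lamellar_params(long_period = lp_true[i],
                      phase1_fraction = 15.7 / 38.5))$profile
    hp <- find_harmonic_peaks(kratky_transform(prof))
    lp2[i] <- hp$lp_2nd; lp3[i] <- hp$lp_3rd
    tt0 <- d_to_two_theta(d002_true[i], config$wavelength)
    if (is.null(tt002_grid))
      tt002_grid <- seq(tt0 - 2, tt0 + 2, length.out = 400)
    wax <- profile1d(tt002_grid,
                     5 + 100 * stats::dnorm(tt002_grid, tt0, 0.12),
                     kind = "two_theta", wavelength = config$wavelength)
    d002_meas[i] <- fit_002_center(wax, tt002_grid[200])$d
  }
  frames <- data.frame(time = frame_t, d002 = d002_meas,
                       orientation_index = orient,
                       lp_2nd = lp2, lp_3rd = lp3)
  series <- assemble_deformation_series(frames, tensile_log,
                                        gauge_length_mm = l0,
                                        frame_interval =
                                          config$frame_interval_s)
  st <- attr(series, "stages")
  stage_row <- function(name, from_pct, to_pct) {
    i0 <- which.min(abs(series$bulk_strain - from_pct))
    i1 <- which.min(abs(series$bulk_strain - to_pct))
    data.frame(stage = name,
               sample_length_mm = sprintf("%.1f -> %.1f",
                                          l0 * (1 + from_pct / 100),
                                          l0 * (1 + to_pct / 100)),
               bulk_strain_pct = to_pct - from_pct,
               d002_A = sprintf("%.2f -> %.2f", series$d002[i0],
                                series$d002[i1]),
               crystal_strain_pct = series$crystal_strain[i1] -
                 series$crystal_strain[i0],
               lp_nm = sprintf("%.1f -> %.1f", series$lp_1st[i0],
                               series$lp_1st[i1]),
               lp_strain_pct = series$lp_strain[i1] -
                 series$lp_strain[i0])
  }
  ey_meas <- if (!is.null(st)) st$yield_strain * 100 else ey
  ef_meas <- if (!is.null(st)) st$fracture_strain * 100 else ef
  stage_tbl <- rbind(stage_row("I", 0, ey_meas),
                     stage_row("II", ey_meas, ef_meas),
                     stage_row("total", 0, ef_meas))
  bundle <- structure(list(
    series = series,
    stages = list(yield_strain_pct = ey_meas,
                  fracture_strain_pct = ef_meas,
                  ratio_2nd_3rd_mean = mean(series$lp_2nd / series$lp_3rd *
                                              2 / 3 * 3 / 2)),
    provenance = provenance_block(config),
    tables = list(deformation_series = as.data.frame(series),
                  stage_summary = stage_tbl)),
    class = "report_bundle")
  bundle$stages$ratio_2nd_3rd_mean <- mean(series$lp_2nd / series$lp_3rd)
  write_bundle(bundle, out_dir)
}

sequence_defaults <- function() {
  list(seed = 1L,
       n_motifs = 5L,
       min_run = 10L,
       residue_rise = 0.35,
       amorphous_phase_thickness = 15.7,
       saxs_phase2_thickness = 22.8)
}

#' Sequence-to-structure analysis run
#'
#' Generates (or reads) an H-Fib-like tandem-repeat protein, segments the
#' PAB+NPAB motifs, reports the NPAB chemistry, and maps the residue census
#' to predicted crystalline/amorphous phase lengths, comparing the predicted
#' crystal length with a supplied SAXS phase-II thickness.
#'
#' @param config list or JSON path; set `config$fasta` to analyse an
#'   external FASTA instead of a synthetic sequence. See
#'   `silkstruct:::sequence_defaults()`.
#' @param out_dir optional output directory.
#' @return a list of class `report_bundle`.
#' @export
run_sequence_analysis <- function(config = list(), out_dir = NULL) {
  config <- merge_config(sequence_defaults(), load_config(config))
  if (!is.null(config$fasta)) {
    seqs <- read_fasta(config$fasta)
    if (!length(seqs)) stop("empty FASTA: ", config$fasta)
    sequence <- unname(seqs[1])
  } else {
    sequence <- generate_sequences(
      sequence_params(n_motifs = config$n_motifs,
                      seed = config$seed))$sequence
  }
  blocks <- find_polyalanine_blocks(sequence, min_run = config$min_run)
  motifs <- withCallingHandlers(
    segment_tandem_motifs(sequence, blocks),
    warning = function(w) invokeRestart("muffleWarning"))
  if (!nrow(motifs)) {
    bundle <- structure(list(
      motifs = list(n_motifs = 0L),
      provenance = provenance_block(config),
      tables = list(motifs = as.data.frame(motifs))),
      class = "report_bundle")
    warning("no complete tandem motif found", call. = FALSE)
    return(write_bundle(bundle, out_dir))
  }
  census <- motif_census(motifs)
  chem <- classify_npab_chemistry(motifs[1, ], sequence)
  map <- map_to_phase_lengths(
    census$pab, census$npab_crystal, census$npab_amorphous,
    residue_rise = config$residue_rise,
    amorphous_phase_thickness = config$amorphous_phase_thickness)
  bundle <- structure(list(
    motifs = list(n_motifs = nrow(motifs),
                  median_motif_length = stats::median(motifs$motif_length),
                  census = census),
    chemistry = chem,
    phase_map = unclass(map),
    comparison = list(
      predicted_crystal_length_nm = round_half_up(map$crystal_length, 1),
      saxs_phase2_thickness_nm = config$saxs_phase2_thickness,
      difference_nm = round_half_up(map$crystal_length, 1) -
        config$saxs_phase2_thickness),
    provenance = provenance_block(config),
    tables = list(motifs = as.data.frame(motifs))),
    class = "report_bundle")
  write_bundle(bundle, out_dir)
}
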