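#' Synthetic heme-methyl probe set
#'
#' Three probes, one per heme, with synthetic truth shifts: reduced-state
#' shifts near 3 ppm, oxidized-state shifts 13-23 ppm, and protonation
#' offsets of 0.3-0.5 ppm between the protonated and deprotonated oxidized
#' forms. The probe identifiers follow the heme-methyl naming of the
#' experiments; the shift values themselves are synthetic stand-ins (the
#' measured shift tables are not deposited), chosen on the scale typical of
#' low-spin ferric heme methyls.
#'
#' @return A [methyl_probes] tibble with 3 rows.
#' @export
synthetic_probes <- function() {
  methyl_probes(
    probe_id = c("2-1CH3-I", "12-1CH3-III", "18-1CH3-IV"),
    heme = c("I", "III", "IV"),
    delta_red = c(3.2, 3.0, 3.4),
    delta_ox_prot = c(16.5, 22.1, 13.8),
    delta_ox_deprot = c(16.9, 22.6, 14.3)
  )
}

#' Specification for the synthetic-data generator
#'
#' Collects everything needed to simulate one study: the true thermodynamic
#' parameters, the probe truth shifts, the experimental design (pH values of
#' the stage-resolved NMR series; potential grid and pH values of the visible
#' titrations) and the noise model. Defaults reproduce the study design:
#' NMR at pH 6.0-9.0 in 0.5 steps for stages 1-3, visible titrations at pH 7
#' and 8 over -250 to +50 mV in 15 mV steps, Gaussian shift noise of
#' 0.005 ppm, and 3%-of-signal visible noise.
#'
#' @param params True [thermo_params].
#' @param probes True [methyl_probes]; default [synthetic_probes()].
#' @param nmr_ph pH values of the NMR series.
#' @param nmr_sigma_ppm Gaussian shift noise SD, ppm.
#' @param vis_potentials Potential grid of the visible titrations, mV.
#' @param vis_ph pH values of the visible titrations.
#' @param vis_rel_error Relative optical error of the visible points.
#' @param seed Integer seed; every generator call is deterministic given it.
#' @return A list of class `generator_spec`.
#' @export
generator_spec <- function(params, probes = synthetic_probes(),
                           nmr_ph = seq(6, 9, by = 0.5),
                           nmr_sigma_ppm = 0.005,
                           vis_potentials = seq(-250, 50, by = 15),
                           vis_ph = c(7, 8),
                           vis_rel_error = 0.03,
                           seed = 20241214) {
  stopifnot(inherits(params, "thermo_params"),
            nmr_sigma_ppm >= 0, vis_rel_error >= 0,
            length(nmr_ph) > 0, length(vis_potentials) > 0,
            length(vis_ph) > 0)
  structure(list(params = params, probes = probes, nmr_ph = nmr_ph,
                 nmr_sigma_ppm = nmr_sigma_ppm,
                 vis_potentials = vis_potentials, vis_ph = vis_ph,
                 vis_rel_error = vis_rel_error, seed = as.integer(seed)),
            class = "generator_spec")
}

#' Simulate a stage-resolved NMR shift dataset
#'
#' One record per (probe, stage 1-3, pH): the forward-model shift plus
#' independent Gaussian noise of SD `nmr_sigma_ppm`; the `sigma_ppm` column
#' carries that SD (the analogue of the linewidth-derived uncertainty).
#' Deterministic given `spec$seed`.
#'
#' @param spec A [generator_spec].
#' @return A tibble with columns `probe_id`, `heme`, `stage`, `pH`,
#'   `shift_ppm`, `sigma_ppm` (63 rows under the defaults).
#' @export
generate_nmr <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  grid <- tidyr::expand_grid(probe_id = spec$probes$probe_id,
                             stage = 1:3, pH = spec$nmr_ph)
  mu <- predicted_shift(spec$params, spec$probes, grid$probe_id,
                        grid$stage, grid$pH)
  noise <- withr::with_seed(spec$seed,
                            stats::rnorm(nrow(grid), 0, spec$nmr_sigma_ppm))
  tibble(
    probe_id = grid$probe_id,
    heme = spec$probes$heme[match(grid$probe_id, spec$probes$probe_id)],
    stage = grid$stage,
    pH = grid$pH,
    shift_ppm = mu + noise,
    sigma_ppm = pmax(spec$nmr_sigma_ppm, 1e-6)
  )
}

#' Simulate a visible redox-titration dataset
#'
#' One record per (potential, pH): the forward-model reduced fraction plus
#' Gaussian noise of SD `vis_rel_error * max(fraction, 0.05)`, clipped to
#' \[0, 1\]. The `sigma` column carries the same rule evaluated at the true
#' fraction. Deterministic given `spec$seed` (offset from the NMR stream so
#' the two datasets are independent).
#'
#' @param spec A [generator_spec].
#' @return A tibble with columns `pH`, `potential_mV`, `reduced_fraction`,
#'   `sigma` (42 rows under the defaults).
#' @export
generate_visible <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  grid <- tidyr::expand_grid(pH = spec$vis_ph,
                             potential_mV = spec$vis_potentials)
  mu <- predicted_reduced_fraction(spec$params, grid$potential_mV, grid$pH)
  sig <- visible_sigma(mu, rel_error = spec$vis_rel_error)
  noise <- withr::with_seed(spec$seed + 1L,
                            stats::rnorm(nrow(grid), 0, 1)) * sig
  tibble(
    pH = grid$pH,
    potential_mV = grid$potential_mV,
    reduced_fraction = pmin(pmax(mu + noise, 0), 1),
    sigma = pmax(sig, 1e-6)
  )
}

#' Write a complete synthetic fixture bundle to disk
#'
#' Generates, for one published parameter set, a directory containing
#' `params.json` (truth), `probes.json` (synthetic truth shifts), `nmr.csv`,
#' `vis.csv`, and `manifest.json` recording the seed and noise settings, so
#' parameter-recovery studies can be re-run from files alone.
#'
#' @param protein One of `"ppcA_Gu"`, `"ppcB_Gu"`, `"ppcA_Gs"`, `"ppcB_Gs"`.
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param nmr_sigma_ppm NMR shift noise SD, ppm.
#' @return The directory path, invisibly.
#' @export
make_fixture_bundle <- function(protein, dir, seed = 20241214,
                                nmr_sigma_ppm = 0.005) {
  params <- ppc_params(protein)
  spec <- generator_spec(params, seed = seed, nmr_sigma_ppm = nmr_sigma_ppm)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_thermo_params(params, file.path(dir, "params.json"))
  write_probes(spec$probes, file.path(dir, "probes.json"))
  readr::write_csv(generate_nmr(spec), file.path(dir, "nmr.csv"))
  readr::write_csv(generate_visible(spec), file.path(dir, "vis.csv"))
  manifest <- list(
    protein = protein, seed = spec$seed,
    nmr_sigma_ppm = spec$nmr_sigma_ppm, vis_rel_error = spec$vis_rel_error,
    nmr_ph = spec$nmr_ph, vis_ph = spec$vis_ph,
    vis_potentials = spec$vis_potentials,
    truth = list(g_ox = as.list(params$g_ox),
                 i_redox = as.list(params$i_redox),
                 g_H = params$g_h, i_bohr = as.list(params$i_bohr),
                 temperature_K = params$temperature)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read NMR and visible datasets from CSV
#'
#' `read_nmr_dataset()` expects columns `probe_id, heme, stage, pH,
#' shift_ppm, sigma_ppm`; `read_visible_dataset()` expects
#' `pH, potential_mV, reduced_fraction, sigma`.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_nmr_dataset <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("probe_id", "stage", "pH", "shift_ppm", "sigma_ppm")
  if (!all(need %in% names(d))) {
    abort(paste0("NMR dataset must have columns ",
                 paste(need, collapse = ", ")))
  }
  if (any(d$sigma_ppm <= 0)) abort("sigma_ppm must be positive")
  if (!all(d$stage %in% 1:3)) abort("NMR records must have stage in 1..3")
  d
}

#' @rdname read_nmr_dataset
#' @export
read_visible_dataset <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("pH", "potential_mV", "reduced_fraction", "sigma")
  if (!all(need %in% names(d))) {
    abort(paste0("visible dataset must have columns ",
                 paste(need, collapse = ", ")))
  }
  if (any(d$sigma <= 0)) abort("sigma must be positive")
  d
}
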