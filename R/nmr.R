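#' Heme-methyl probe definitions
#'
#' A probe is one heme methyl group whose chemical shift tracks the oxidation
#' of its heme: the shift is `delta_red` (ppm) while the heme is reduced and
#' `delta_ox_prot` / `delta_ox_deprot` while oxidized with the redox-Bohr
#' center protonated / deprotonated. The reduced-state shift is
#' protonation-independent, and shifts on reduced hemes are taken independent
#' of the oxidation of the other hemes (the methyls used point outward from
#' the heme core).
#'
#' @param probe_id Character vector of probe identifiers
#'   (e.g. `"2-1CH3-I"`).
#' @param heme Heme each probe reports on (`"I"`, `"III"`, `"IV"`).
#' @param delta_red Reduced-state shift, ppm.
#' @param delta_ox_prot Oxidized-state shift, protonated center, ppm.
#' @param delta_ox_deprot Oxidized-state shift, deprotonated center, ppm.
#' @return A tibble with one row per probe, class `methyl_probes`.
#' @export
methyl_probes <- function(probe_id, heme, delta_red,
                          delta_ox_prot, delta_ox_deprot) {
  heme <- vapply(heme, check_heme, character(1), USE.NAMES = FALSE)
  out <- tibble(probe_id = as.character(probe_id), heme = heme,
                delta_red = delta_red, delta_ox_prot = delta_ox_prot,
                delta_ox_deprot = delta_ox_deprot)
  if (anyDuplicated(out$probe_id) > 0) abort("duplicate probe_id")
  class(out) <- c("methyl_probes", class(out))
  out
}

#' Read and write probe definitions as JSON
#'
#' @param path File path. The JSON is an array of objects with fields `id`,
#'   `heme`, `delta_red`, and optional `delta_ox_prot`, `delta_ox_deprot`
#'   (used as fixed truth values or as initial guesses for the fit).
#' @return A [methyl_probes] tibble.
#' @export
read_probes <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  methyl_probes(
    probe_id = j$id, heme = j$heme, delta_red = j$delta_red,
    delta_ox_prot = j$delta_ox_prot %||% rep(NA_real_, length(j$id)),
    delta_ox_deprot = j$delta_ox_deprot %||% rep(NA_real_, length(j$id))
  )
}

#' @param probes A [methyl_probes] tibble.
#' @rdname read_probes
#' @export
write_probes <- function(probes, path) {
  j <- lapply(seq_len(nrow(probes)), function(i) {
    list(id = probes$probe_id[i], heme = probes$heme[i],
         delta_red = probes$delta_red[i],
         delta_ox_prot = probes$delta_ox_prot[i],
         delta_ox_deprot = probes$delta_ox_deprot[i])
  })
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Predicted heme-methyl chemical shift per oxidation stage and pH
#'
#' Forward model of the stage-resolved NMR observable. Intramolecular
#' electron exchange is fast on the chemical-shift time scale and
#' intermolecular exchange slow, so each oxidation stage yields one
#' population-averaged signal per probe: the Boltzmann average over the
#' stage-restricted ensemble of the microstate shift (`delta_red` when the
#' probe's heme is reduced; `delta_ox_prot` / `delta_ox_deprot` when
#' oxidized, by protonation of the redox-Bohr center). Stage 0 returns
#' `delta_red` for all pH.
#'
#' @param params A [thermo_params] object.
#' @param probes A [methyl_probes] tibble.
#' @param stage Oxidation stage per record, 0-3. Vectorized.
#' @param ph pH per record. Vectorized.
#' @param probe_id Probe identifier per record. `probe_id`, `stage` and `ph`
#'   are recycled to a common length for record-wise evaluation.
#' @return Numeric vector of shifts, ppm, one per record.
#' @examples
#' pr <- synthetic_probes()
#' predicted_shift(ppc_params("ppcA_Gu"), pr, probe_id = pr$probe_id[1],
#'                 stage = 1, ph = 7)
#' @export
predicted_shift <- function(params, probes, probe_id, stage, ph) {
  stopifnot(inherits(params, "thermo_params"))
  n <- max(length(probe_id), length(stage), length(ph))
  probe_id <- rep_len(as.character(probe_id), n)
  stage <- rep_len(stage, n)
  ph <- rep_len(ph, n)
  if (!all(stage %in% 0:3)) abort("stage must be in 0..3")
  pidx <- match(probe_id, probes$probe_id)
  if (anyNA(pidx)) {
    abort(paste0("unknown probe id(s): ",
                 paste(unique(probe_id[is.na(pidx)]), collapse = ", ")))
  }
  kt <- kT_meV(params$temperature)
  e <- state_energies(params)
  out <- numeric(n)
  # group records by (stage, ph) so the stage ensemble is computed once each
  grp <- paste(stage, ph)
  for (g in unique(grp)) {
    rows <- which(grp == g)
    s <- stage[rows[1]]; p <- ph[rows[1]]
    idx <- which(.microstates$stage == s)
    lw <- -e[idx] / kt + as.numeric(.microstates$deprotonated[idx]) *
      log(10) * p
    w <- exp(lw - max(lw)); w <- w / sum(w)
    for (r in rows) {
      pr <- pidx[r]
      hcol <- .ox_matrix[idx, probes$heme[pr]]
      dep <- .microstates$deprotonated[idx]
      shift_m <- ifelse(hcol == 1,
                        ifelse(dep, probes$delta_ox_deprot[pr],
                               probes$delta_ox_prot[pr]),
                        probes$delta_red[pr])
      out[r] <- sum(w * shift_m)
    }
  }
  out
}

#' Oxidation fraction from an observed chemical shift
#'
#' Linear normalization of an observed shift between the reduced- and
#' oxidized-state limits, `(observed - delta_red) / (delta_ox - delta_red)`,
#' clipped to \[0, 1\]. A plotting/diagnostic aid (the experimental
#' construction of per-stage oxidation fractions); never used inside the fit.
#'
#' @param observed Observed shift(s), ppm.
#' @param delta_red Reduced-state shift, ppm.
#' @param delta_ox Oxidized-state shift, ppm. Must differ from `delta_red`.
#' @return Fraction(s) in \[0, 1\].
#' @export
oxidation_fraction_from_shifts <- function(observed, delta_red, delta_ox) {
  if (any(delta_ox == delta_red)) {
    abort("degenerate shift span: delta_ox equals delta_red")
  }
  pmin(pmax((observed - delta_red) / (delta_ox - delta_red), 0), 1)
}
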