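#' Marginal heme oxidation fraction
#'
#' Probability that one heme is oxidized under the full 16-microstate
#' ensemble at given solution potential and pH.
#'
#' @param params A [thermo_params] object.
#' @param heme Heme label (`"I"`, `"III"`, `"IV"` or alias 1, 3, 4).
#' @param potential Solution potential, mV vs SHE. Vectorized.
#' @param ph Solution pH. Vectorized (recycled against `potential`).
#' @return Numeric vector of fractions in \[0, 1\].
#' @export
heme_oxidation_fraction <- function(params, heme, potential, ph) {
  stopifnot(inherits(params, "thermo_params"))
  heme <- check_heme(heme)
  fr <- fraction_matrix(params, potential, ph)
  unname(colSums(fr[.ox_matrix[, heme] == 1, , drop = FALSE]))
}

#' Heme oxidation curves and microstate fractions on a potential grid
#'
#' Evaluates the per-heme oxidation fractions, the total reduced fraction,
#' and the molar fraction of every microstate on a grid of solution
#' potentials at fixed pH.
#'
#' @inheritParams heme_oxidation_fraction
#' @param potentials Increasing grid of potentials, mV vs SHE. Default
#'   -300 to +150 mV in 1 mV steps.
#' @return A tibble with columns `potential_mV`, `pH`, `frac_ox_I`,
#'   `frac_ox_III`, `frac_ox_IV`, `frac_reduced_total`, and one column per
#'   microstate label.
#' @examples
#' oc <- oxidation_curves(ppc_params("ppcA_Gu"), ph = 7,
#'                        potentials = seq(-300, 150, by = 10))
#' @export
oxidation_curves <- function(params, ph = 7,
                             potentials = seq(-300, 150, by = 1)) {
  stopifnot(inherits(params, "thermo_params"), length(ph) == 1L)
  if (is.unsorted(potentials, strictly = TRUE)) {
    abort("`potentials` must be strictly increasing.")
  }
  fr <- fraction_matrix(params, potentials, ph)
  ox <- t(.ox_matrix) %*% fr   # 3 x n marginal oxidation fractions
  out <- tibble(
    potential_mV = potentials,
    pH = ph,
    frac_ox_I = ox["I", ],
    frac_ox_III = ox["III", ],
    frac_ox_IV = ox["IV", ],
    frac_reduced_total = 1 - colMeans(ox)
  )
  frt <- t(fr)
  colnames(frt) <- .microstates$label
  ms <- as_tibble(frt)
  dplyr::bind_cols(out, ms)
}

# log weights of the stage-restricted ensemble at fixed pH (the potential
# drops out: all members of a stage share n_ox)
stage_log_weights <- function(params, stage, ph) {
  idx <- which(.microstates$stage == stage)
  kt <- kT_meV(params$temperature)
  e <- state_energies(params)[idx]
  list(idx = idx, lw = -e / kt +
         as.numeric(.microstates$deprotonated[idx]) * log(10) * ph)
}

#' Stage-conditional heme oxidation fraction
#'
#' Probability that a heme is oxidized conditional on the protein being in a
#' given oxidation stage (the observable the stage-resolved NMR experiment
#' measures: intramolecular electron exchange is fast, so each stage yields a
#' single population-averaged signal set). Because all members of a stage
#' share the same number of oxidized hemes, this quantity is independent of
#' the solution potential and no potential argument exists.
#'
#' @inheritParams heme_oxidation_fraction
#' @param stage Oxidation stage, 0-3.
#' @return Fraction in \[0, 1\]. Stage 0 returns 0 and stage 3 returns 1 for
#'   every heme; across hemes the stage-n fractions sum to n.
#' @examples
#' stage_conditional_fraction(ppc_params("ppcA_Gu"), "III", stage = 1, ph = 7)
#' @export
stage_conditional_fraction <- function(params, heme, stage, ph) {
  stopifnot(inherits(params, "thermo_params"),
            length(stage) == 1L, stage %in% 0:3, length(ph) == 1L)
  heme <- check_heme(heme)
  sw <- stage_log_weights(params, stage, ph)
  w <- exp(sw$lw - max(sw$lw))
  sum(w[.ox_matrix[sw$idx, heme] == 1]) / sum(w)
}

#' Macroscopic stage pKa of the redox-Bohr center
#'
#' Apparent pKa of the redox-Bohr center averaged over the microstates of one
#' oxidation stage: the acid constants of the stage members are averaged with
#' Boltzmann weights of the protonated forms,
#' `pKa_n = -log10( sum w0 * 10^(-pKa_micro) / sum w0 )` with
#' `w0 = exp(-G(protonated)/kT)`. Equivalently, the unique pH at which the
#' protonated and deprotonated populations of the stage are equal.
#'
#' @inheritParams stage_conditional_fraction
#' @return pKa in pH units.
#' @examples
#' sapply(0:3, stage_pka, params = ppc_params("ppcA_Gu"))
#' @export
stage_pka <- function(params, stage) {
  stopifnot(inherits(params, "thermo_params"),
            length(stage) == 1L, stage %in% 0:3)
  kt <- kT_meV(params$temperature)
  idx <- which(.microstates$stage == stage & !.microstates$deprotonated)
  e <- state_energies(params)[idx]
  pka_m <- (params$g_h + drop(.ox_matrix[idx, , drop = FALSE] %*%
                                params$i_bohr[HEMES])) / (kt * log(10))
  # log-space weighted mean of Ka over the stage members
  lw <- -e / kt
  lw <- lw - max(lw)
  -log10(sum(exp(lw) * 10^(-pka_m)) / sum(exp(lw)))
}

#' Total redox-Bohr effect (delta pKa)
#'
#' Difference between the macroscopic pKa of the fully reduced protein
#' (stage 0) and the fully oxidized protein (stage 3). Closed form:
#' `-sum(i_bohr) / (kT ln 10)`, so negative redox-Bohr interactions give a
#' positive delta pKa. Gauges the protein's capacity for coupled
#' electron/proton (redox-Bohr) transfer.
#'
#' @param params A [thermo_params] object.
#' @return Delta pKa in pH units.
#' @examples
#' delta_pka(ppc_params("ppcA_Gu"))  # 3.08
#' @export
delta_pka <- function(params) {
  stopifnot(inherits(params, "thermo_params"))
  unname(-sum(params$i_bohr) / (kT_meV(params$temperature) * log(10)))
}

#' Stage pKa table for one or more proteins
#'
#' @param params A [thermo_params] object or a (possibly named) list of them.
#' @return A tibble with columns `protein`, `pKa_stage0` .. `pKa_stage3`,
#'   `delta_pKa` (full precision).
#' @export
pka_table <- function(params) {
  if (inherits(params, "thermo_params")) params <- list(params)
  purrr::imap_dfr(params, function(p, nm) {
    tibble(
      protein = p$protein %||% (if (is.character(nm)) nm else NA_character_),
      pKa_stage0 = stage_pka(p, 0), pKa_stage1 = stage_pka(p, 1),
      pKa_stage2 = stage_pka(p, 2), pKa_stage3 = stage_pka(p, 3),
      delta_pKa = delta_pka(p)
    )
  })
}

#' Apparent midpoint potential of a heme
#'
#' The solution potential at which the heme's marginal oxidation fraction is
#' 1/2 at the given pH, found by bisection to 0.01 mV on \[-1000, 1000\] mV.
#' The oxidation fraction is monotone in potential for these models, so the
#' root is unique.
#'
#' @inheritParams heme_oxidation_fraction
#' @return Potential in mV vs SHE.
#' @examples
#' midpoint_potential(ppc_params("ppcA_Gu"), "III", ph = 7)
#' @export
midpoint_potential <- function(params, heme, ph) {
  stopifnot(inherits(params, "thermo_params"), length(ph) == 1L)
  heme <- check_heme(heme)
  f <- function(e) heme_oxidation_fraction(params, heme, e, ph) - 0.5
  lo <- -1000; hi <- 1000
  if (f(lo) > 0 || f(hi) < 0) {
    abort("oxidation fraction does not bracket 1/2 on [-1000, 1000] mV")
  }
  while (hi - lo > 0.01) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Heme reduction potentials of the deprotonated protein
#'
#' Reduction potential of each heme in the fully reduced protein with the
#' redox-Bohr center deprotonated: the protonated-form potential plus the
#' heme's redox-Bohr interaction, `g_ox + i_bohr` per heme.
#'
#' @param params A [thermo_params] object.
#' @return Named numeric vector (mV vs SHE) over hemes I, III, IV.
#' @examples
#' deprotonated_potentials(ppc_params("ppcA_Gu"))["IV"]  # -143
#' @export
deprotonated_potentials <- function(params) {
  stopifnot(inherits(params, "thermo_params"))
  params$g_ox[HEMES] + params$i_bohr[HEMES]
}

#' Dominant-microstate route along the oxidation of the protein
#'
#' Sweeps the solution potential over a grid spanning full oxidation and
#' records the globally most-populated microstate at each point; returns the
#' deduplicated sequence of labels — the preferred electron (and proton)
#' transfer pathway. Ties are broken toward the lower-stage microstate.
#'
#' @inheritParams heme_oxidation_fraction
#' @param e_grid Increasing potential grid, mV vs SHE; must span full
#'   oxidation (total oxidized fraction below 1% at the first point and above
#'   99% at the last).
#' @return Character vector of microstate labels, e.g.
#'   `c("P0H", "P3H", "P134")`.
#' @examples
#' dominant_microstate_route(ppc_params("ppcA_Gu"), ph = 7)
#' @export
dominant_microstate_route <- function(params, ph = 7,
                                      e_grid = seq(-300, 150, by = 1)) {
  stopifnot(inherits(params, "thermo_params"), length(ph) == 1L)
  if (is.unsorted(e_grid, strictly = TRUE)) {
    abort("`e_grid` must be strictly increasing.")
  }
  fr <- fraction_matrix(params, e_grid, ph)
  tot_ox <- colMeans(t(.ox_matrix) %*% fr)
  if (tot_ox[1] >= 0.01 || tot_ox[length(tot_ox)] <= 0.99) {
    abort("`e_grid` does not span full oxidation (need < 1% oxidized at the first point and > 99% at the last)")
  }
  # which.max returns the first maximum; rows are stage-ordered, so ties
  # already resolve toward the lower-stage microstate
  top <- .microstates$label[apply(fr, 2, which.max)]
  rle(top)$values
}
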