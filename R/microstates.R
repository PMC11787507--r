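# Fixed enumeration of the 16 microstates: every subset of {I, III, IV}
# oxidized, crossed with the redox-Bohr center protonated/deprotonated.
# Built once at load; row order is stable (stage-major, protonated first).
build_microstate_table <- function() {
  grid <- expand.grid(I = c(FALSE, TRUE), III = c(FALSE, TRUE),
                      IV = c(FALSE, TRUE), deprotonated = c(FALSE, TRUE),
                      KEEP.OUT.ATTRS = FALSE)
  ox <- as.matrix(grid[, HEMES])
  stage <- rowSums(ox)
  label <- vapply(seq_len(nrow(grid)), function(i) {
    digits <- HEME_ALIAS[HEMES[ox[i, ]]]
    paste0("P", if (length(digits)) paste(digits, collapse = "") else "0",
           if (!grid$deprotonated[i]) "H" else "")
  }, character(1))
  ord <- order(stage, grid$deprotonated, label)
  tibble(
    label = label[ord],
    ox_I = ox[ord, "I"], ox_III = ox[ord, "III"], ox_IV = ox[ord, "IV"],
    stage = stage[ord],
    deprotonated = grid$deprotonated[ord]
  )
}

.microstates <- build_microstate_table()

# pair-indicator matrix: column k is 1 where both hemes of pair k oxidized
.pair_matrix <- local({
  m <- cbind(
    `I-III`  = .microstates$ox_I & .microstates$ox_III,
    `I-IV`   = .microstates$ox_I & .microstates$ox_IV,
    `III-IV` = .microstates$ox_III & .microstates$ox_IV
  )
  storage.mode(m) <- "double"
  m
})

.ox_matrix <- local({
  m <- as.matrix(.microstates[, c("ox_I", "ox_III", "ox_IV")])
  colnames(m) <- HEMES
  storage.mode(m) <- "double"
  m
})

#' The 16 microstates of a triheme protein with one redox-Bohr center
#'
#' @return A 16-row tibble with columns `label` (e.g. `"P0H"`, `"P3H"`,
#'   `"P134"`), logical oxidation flags `ox_I`, `ox_III`, `ox_IV`, the
#'   oxidation `stage` (number of oxidized hemes, 0-3), and `deprotonated`.
#'   The label is "P" + the numeric aliases of the oxidized hemes (0 if none)
#'   + "H" when the redox-Bohr center is protonated.
#' @examples
#' microstates()
#' @export
microstates <- function() .microstates

# ox_set argument -> logical length-3 vector in heme order; accepts
# character c("I","III"), numeric aliases c(1,3), or empty.
parse_ox_set <- function(ox_set) {
  if (length(ox_set) == 0) return(stats::setNames(rep(FALSE, 3), HEMES))
  if (is.numeric(ox_set)) {
    idx <- match(as.character(ox_set), HEME_ALIAS)
  } else {
    ox_set <- toupper(as.character(ox_set))
    idx <- match(ox_set, HEMES)
    if (anyNA(idx)) idx <- match(ox_set, HEME_ALIAS)
  }
  if (anyNA(idx) || anyDuplicated(idx) > 0) {
    abort(paste0("unknown heme label(s) in ox_set: ",
                 paste(ox_set, collapse = ", "),
                 " (hemes are I, III, IV / aliases 1, 3, 4)"))
  }
  out <- stats::setNames(rep(FALSE, 3), HEMES)
  out[idx] <- TRUE
  out
}

check_heme <- function(heme) {
  h <- if (is.numeric(heme)) HEMES[match(as.character(heme), HEME_ALIAS)] else
    HEMES[match(toupper(as.character(heme)), HEMES)]
  if (length(h) != 1L || is.na(h)) {
    abort(paste0("unknown heme label: ", heme, " (use I, III, IV or 1, 3, 4)"))
  }
  h
}

# energies of the 16 microstates, meV, in microstates() row order.
# G = sum g_ox(oxidized) + sum i_redox(oxidized pairs)
#     + deprotonated * (g_H + sum i_bohr(oxidized));
# the fully reduced protonated state is the zero of energy. The proton
# chemical potential is NOT included here (it enters the Boltzmann weight).
state_energies <- function(params) {
  drop(.ox_matrix %*% params$g_ox[HEMES] +
         .pair_matrix %*% params$i_redox[HEME_PAIRS] +
         .microstates$deprotonated *
           (params$g_h + drop(.ox_matrix %*% params$i_bohr[HEMES])))
}

#' Microstate free energy
#'
#' Free energy of one microstate relative to the fully reduced, protonated
#' protein, in meV: the sum of the oxidation energies of the oxidized hemes,
#' the redox interactions of oxidized pairs, and (if deprotonated) the
#' deprotonation energy plus the redox-Bohr interactions of the oxidized
#' hemes. The proton chemical potential is not included; it enters the
#' Boltzmann weight through the pH.
#'
#' @param params A [thermo_params] object.
#' @param ox_set Oxidized hemes, e.g. `c("I","III")`, `c(1,3)`, or
#'   `character(0)` for the fully reduced protein.
#' @param deprotonated Logical; is the redox-Bohr center deprotonated?
#' @return Energy in meV.
#' @examples
#' microstate_energy(ppc_params("ppcA_Gu"), "III")   # -82
#' @export
microstate_energy <- function(params, ox_set, deprotonated = FALSE) {
  stopifnot(inherits(params, "thermo_params"))
  ox <- parse_ox_set(ox_set)
  hemes <- HEMES[ox]
  e <- sum(params$g_ox[hemes])
  if (length(hemes) >= 2) {
    pairs <- utils::combn(hemes, 2)
    e <- e + sum(params$i_redox[paste(pairs[1, ], pairs[2, ], sep = "-")])
  }
  if (isTRUE(deprotonated)) e <- e + params$g_h + sum(params$i_bohr[hemes])
  unname(e)
}

# 16 x n matrix of log Boltzmann weights at conditions (potential, ph),
# both recycled to common length n. ln w = (n_ox*E - G)/kT + deprot*ln(10)*pH.
log_weight_matrix <- function(params, potential, ph) {
  n <- max(length(potential), length(ph))
  potential <- rep_len(potential, n)
  ph <- rep_len(ph, n)
  kt <- kT_meV(params$temperature)
  e <- state_energies(params)
  outer(.microstates$stage, potential) / kt - e / kt +
    outer(as.numeric(.microstates$deprotonated), ph) * log(10)
}

#' Log Boltzmann weight of a microstate
#'
#' Natural log of the population of a microstate relative to the fully
#' reduced, protonated reference state at given solution potential and pH:
#' `(n_ox * E - G) / kT + deprotonated * ln(10) * pH` with energies in meV and
#' the potential in mV vs SHE (1 mV per electron = 1 meV). The ratio
#' deprotonated/protonated at fixed oxidation pattern is
#' `10^(pH - microstate_pka)`; the oxidized/reduced ratio of a lone
#' non-interacting heme is `exp((E - g_ox)/kT)` (Nernst).
#'
#' @inheritParams microstate_energy
#' @param potential Solution potential, mV vs SHE. Vectorized (recycled
#'   against `ph`).
#' @param ph Solution pH. Vectorized.
#' @return Numeric vector of log relative populations.
#' @export
log_weight <- function(params, ox_set, deprotonated = FALSE,
                       potential, ph) {
  stopifnot(inherits(params, "thermo_params"))
  ox <- parse_ox_set(ox_set)
  kt <- kT_meV(params$temperature)
  e <- microstate_energy(params, HEMES[ox], deprotonated)
  n_ox <- sum(ox)
  n <- max(length(potential), length(ph))
  rep_len(potential, n) * n_ox / kt - e / kt +
    as.numeric(isTRUE(deprotonated)) * log(10) * rep_len(ph, n)
}

# 16 x n matrix of normalized molar fractions (columns sum to 1); log-sum-exp.
fraction_matrix <- function(params, potential, ph) {
  lw <- log_weight_matrix(params, potential, ph)
  mx <- apply(lw, 2, max)
  w <- exp(sweep(lw, 2, mx))
  sweep(w, 2, colSums(w), "/")
}

#' Equilibrium microstate populations
#'
#' Normalized molar fractions of all 16 microstates at one or more
#' (potential, pH) conditions, computed in log space (log-sum-exp) so the
#' result is overflow-free for |E| up to 1000 mV and pH 0-14.
#'
#' @inheritParams log_weight
#' @param params A [thermo_params] object.
#' @return A tibble with one row per microstate per condition: columns
#'   `potential_mV`, `pH`, `label`, `stage`, `deprotonated`, `fraction`.
#'   Fractions sum to 1 within each condition.
#' @examples
#' ens <- ensemble(ppc_params("ppcA_Gu"), potential = -100, ph = 7)
#' sum(ens$fraction)
#' @export
ensemble <- function(params, potential, ph) {
  stopifnot(inherits(params, "thermo_params"))
  n <- max(length(potential), length(ph))
  potential <- rep_len(potential, n)
  ph <- rep_len(ph, n)
  fr <- fraction_matrix(params, potential, ph)
  tibble(
    potential_mV = rep(potential, each = 16L),
    pH = rep(ph, each = 16L),
    label = rep(.microstates$label, n),
    stage = rep(.microstates$stage, n),
    deprotonated = rep(.microstates$deprotonated, n),
    fraction = as.vector(fr)
  )
}

#' Microstate pKa of the redox-Bohr center
#'
#' pKa of the redox-Bohr center for a fixed oxidation pattern:
#' `(g_H + sum of i_bohr over oxidized hemes) / (kT ln 10)`. At 288.15 K,
#' `kT ln 10` = 57.18 meV.
#'
#' @inheritParams microstate_energy
#' @return pKa in pH units.
#' @examples
#' microstate_pka(ppc_params("ppcA_Gu"), character(0))   # 9.15
#' microstate_pka(ppc_params("ppcA_Gu"), c("I","III","IV"))  # 6.07
#' @export
microstate_pka <- function(params, ox_set) {
  stopifnot(inherits(params, "thermo_params"))
  ox <- parse_ox_set(ox_set)
  unname((params$g_h + sum(params$i_bohr[HEMES[ox]])) /
           (kT_meV(params$temperature) * log(10)))
}
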