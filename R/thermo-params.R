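#' Thermodynamic parameter set for a triheme cytochrome
#'
#' Bundles the ten thermodynamic parameters of the interacting-centers model:
#' three heme oxidation energies, three heme-heme redox interaction energies,
#' the deprotonation energy of the redox-Bohr center, and three heme-proton
#' (redox-Bohr) interaction energies. All energies are in meV; with one
#' electron per heme, an oxidation energy in meV is numerically the heme's
#' reduction potential in mV vs SHE in the fully reduced, protonated protein.
#'
#' Hemes are named `I`, `III`, `IV` (no heme II), following the
#' cytochrome-c3-derived numbering; microstate labels use the numeric aliases
#' 1, 3, 4.
#'
#' @param g_ox Named numeric vector `c(I=, III=, IV=)` of heme oxidation
#'   energies, meV.
#' @param i_redox Named numeric vector `c("I-III"=, "I-IV"=, "III-IV"=)` of
#'   pairwise redox interaction energies, meV. Positive values mean oxidation
#'   of one heme raises the apparent potential requirement of the other.
#' @param g_h Deprotonation energy of the redox-Bohr center in the fully
#'   reduced protein, meV.
#' @param i_bohr Named numeric vector `c(I=, III=, IV=)` of redox-Bohr
#'   interaction energies, meV. Negative values mean deprotonation stabilizes
#'   the oxidized heme.
#' @param temperature Absolute temperature, K. Default 288.15 (15 degrees C,
#'   the experimental temperature).
#' @param protein Optional protein label carried through to outputs.
#' @return An object of class `thermo_params`.
#' @examples
#' p <- ppc_params("ppcA_Gu")
#' p$g_ox
#' @export
thermo_params <- function(g_ox, i_redox, g_h, i_bohr,
                          temperature = 288.15, protein = NULL) {
  g_ox <- check_named_numeric(g_ox, HEMES, "g_ox")
  i_redox <- check_named_numeric(normalize_pair_names(i_redox), HEME_PAIRS,
                                 "i_redox")
  i_bohr <- check_named_numeric(i_bohr, HEMES, "i_bohr")
  if (!is.numeric(g_h) || length(g_h) != 1L || !is.finite(g_h)) {
    abort("`g_h` must be a single finite number (meV).")
  }
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0) {
    abort("`temperature` must be a single positive number (K).")
  }
  structure(
    list(g_ox = g_ox, i_redox = i_redox, g_h = as.numeric(g_h),
         i_bohr = i_bohr, temperature = as.numeric(temperature),
         protein = protein),
    class = "thermo_params"
  )
}

check_named_numeric <- function(x, expected, what) {
  if (is.null(names(x)) || !setequal(names(x), expected) ||
      anyDuplicated(names(x)) > 0) {
    abort(paste0("`", what, "` must be named exactly {",
                 paste(expected, collapse = ", "), "}."))
  }
  x <- x[expected]
  if (!is.numeric(x) || !all(is.finite(x))) {
    abort(paste0("`", what, "` must be finite numeric."))
  }
  storage.mode(x) <- "double"
  x
}

# accept "III-I" etc. by sorting each pair into canonical heme order
normalize_pair_names <- function(x) {
  if (is.null(names(x))) return(x)
  nm <- vapply(strsplit(names(x), "-", fixed = TRUE), function(p) {
    p <- p[order(match(p, HEMES))]
    paste(p, collapse = "-")
  }, character(1))
  names(x) <- nm
  x
}

#' @export
print.thermo_params <- function(x, ...) {
  cat("<thermo_params>",
      if (!is.null(x$protein)) paste0(" ", x$protein), "\n", sep = "")
  cat(sprintf("  T = %.2f K (kT = %.3f meV)\n", x$temperature,
              kT_meV(x$temperature)))
  cat("  g_ox   (meV):", paste(sprintf("%s=%g", names(x$g_ox), x$g_ox),
                               collapse = "  "), "\n")
  cat("  i_redox(meV):", paste(sprintf("%s=%g", names(x$i_redox), x$i_redox),
                               collapse = "  "), "\n")
  cat("  g_H    (meV):", sprintf("%g", x$g_h), "\n")
  cat("  i_bohr (meV):", paste(sprintf("%s=%g", names(x$i_bohr), x$i_bohr),
                               collapse = "  "), "\n")
  invisible(x)
}

#' Published parameter sets for the PpcA/PpcB cytochromes
#'
#' Returns the transcribed thermodynamic parameter set for one of the four
#' characterized triheme cytochromes: PpcA and PpcB from *Geotalea
#' uraniireducens* (`ppcA_Gu`, `ppcB_Gu`) and from *Geobacter sulfurreducens*
#' (`ppcA_Gs`, `ppcB_Gs`).
#'
#' @param protein One of `"ppcA_Gu"`, `"ppcB_Gu"`, `"ppcA_Gs"`, `"ppcB_Gs"`.
#' @param temperature Absolute temperature, K.
#' @return A [thermo_params] object.
#' @export
ppc_params <- function(protein = c("ppcA_Gu", "ppcB_Gu", "ppcA_Gs", "ppcB_Gs"),
                       temperature = 288.15) {
  protein <- match.arg(protein)
  path <- system.file("extdata", paste0(protein, ".json"), package = "triheme",
                      mustWork = TRUE)
  p <- read_thermo_params(path)
  p$temperature <- temperature
  p
}

#' Read and write thermodynamic parameters as JSON
#'
#' The parameter file is JSON with keys `protein`, `temperature_K`,
#' `g_ox` (`I`, `III`, `IV`), `i_redox` (`I-III`, `I-IV`, `III-IV`), `g_H`,
#' and `i_bohr` (`I`, `III`, `IV`). Serialization round-trips exactly.
#'
#' @param path File path.
#' @return `read_thermo_params()` returns a [thermo_params] object;
#'   `write_thermo_params()` returns `path` invisibly.
#' @export
read_thermo_params <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (key in c("g_ox", "i_redox", "g_H", "i_bohr")) {
    if (is.null(j[[key]])) abort(paste0("parameter file lacks key `", key, "`"))
  }
  thermo_params(
    g_ox = unlist(j$g_ox), i_redox = unlist(j$i_redox),
    g_h = j$g_H, i_bohr = unlist(j$i_bohr),
    temperature = j$temperature_K %||% 288.15,
    protein = j$protein
  )
}

#' @param params A [thermo_params] object.
#' @rdname read_thermo_params
#' @export
write_thermo_params <- function(params, path) {
  stopifnot(inherits(params, "thermo_params"))
  j <- list(
    protein = params$protein %||% "unnamed",
    temperature_K = params$temperature,
    g_ox = as.list(params$g_ox),
    i_redox = as.list(params$i_redox),
    g_H = params$g_h,
    i_bohr = as.list(params$i_bohr)
  )
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
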