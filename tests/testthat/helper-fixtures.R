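# parameter sets used across tests, built in code

ppcA_Gu <- ppc_params("ppcA_Gu")
ppcB_Gu <- ppc_params("ppcB_Gu")
ppcA_Gs <- ppc_params("ppcA_Gs")
ppcB_Gs <- ppc_params("ppcB_Gs")
all_fixtures <- list(ppcA_Gu = ppcA_Gu, ppcB_Gu = ppcB_Gu,
                     ppcA_Gs = ppcA_Gs, ppcB_Gs = ppcB_Gs)

# no interactions at all: three independent Nernst centers + isolated acid
nernst_params <- function(g = c(I = -100, III = -50, IV = 0), g_h = 400) {
  thermo_params(
    g_ox = g,
    i_redox = c("I-III" = 0, "I-IV" = 0, "III-IV" = 0),
    g_h = g_h,
    i_bohr = c(I = 0, III = 0, IV = 0)
  )
}

# random but reproducible parameter sets for property-style tests
random_params <- function(seed) {
  withr::with_seed(seed, {
    thermo_params(
      g_ox = stats::setNames(round(runif(3, -200, 0), 1),
                             c("I", "III", "IV")),
      i_redox = stats::setNames(round(runif(3, -10, 50), 1),
                                c("I-III", "I-IV", "III-IV")),
      g_h = round(runif(1, 350, 600), 1),
      i_bohr = stats::setNames(round(runif(3, -90, 20), 1),
                               c("I", "III", "IV"))
    )
  })
}

# truth values of the ten thermodynamic parameters, in optimizer order
truth_vector <- function(params) {
  unname(c(params$g_ox, params$i_redox, params$g_h, params$i_bohr))
}
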