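test_that("the microstate enumeration is complete and canonically labelled", {
  ms <- microstates()
  expect_equal(nrow(ms), 16L)
  expect_equal(anyDuplicated(ms$label), 0L)
  expect_equal(as.vector(table(ms$stage)), c(2L, 6L, 6L, 2L))
  expect_setequal(ms$label[ms$stage == 0], c("P0H", "P0"))
  expect_true(all(c("P3H", "P14H", "P134", "P134H") %in% ms$label))
  expect_equal(ms$stage, rowSums(ms[, c("ox_I", "ox_III", "ox_IV")]))
})

test_that("microstate energies follow the additive interacting-centers rule", {
  expect_equal(microstate_energy(ppcA_Gu, "III"), -82)
  expect_equal(microstate_energy(ppcA_Gu, c("I", "III")), -113)
  expect_equal(microstate_energy(ppcA_Gu, character(0)), 0)
  # numeric aliases name the same states
  expect_equal(microstate_energy(ppcA_Gu, c(1, 3)),
               microstate_energy(ppcA_Gu, c("I", "III")))
  # deprotonated, fully oxidized: all ten parameters enter once
  expect_equal(
    microstate_energy(ppcA_Gu, c("I", "III", "IV"), deprotonated = TRUE),
    sum(ppcA_Gu$g_ox) + sum(ppcA_Gu$i_redox) + ppcA_Gu$g_h +
      sum(ppcA_Gu$i_bohr))
  expect_error(microstate_energy(ppcA_Gu, "II"), "unknown heme")
})

test_that("log weights obey the reference, Nernst and protonation contracts", {
  # fully reduced protonated reference has zero log weight anywhere
  expect_equal(log_weight(ppcA_Gu, character(0), FALSE,
                          potential = c(-300, 0, 250), ph = c(2, 7, 12)),
               c(0, 0, 0))
  # lone heme with no interactions at its midpoint: 50/50 with the reference
  np <- nernst_params()
  expect_equal(log_weight(np, "I", FALSE, potential = -100, ph = 7), 0)
  # direct substitution: oxidation of heme III of PpcA_Gu at E = g_ox
  expect_equal(log_weight(ppcA_Gu, "III", FALSE, potential = -82, ph = 7), 0)
  # protonation flip at fixed oxidation pattern: ratio 10^(pH - pKa)
  for (seed in 1:3) {
    p <- random_params(seed)
    for (ox in list(character(0), "I", c("III", "IV"), c("I", "III", "IV"))) {
      ph <- 7.3
      lr <- log_weight(p, ox, TRUE, potential = -40, ph = ph) -
        log_weight(p, ox, FALSE, potential = -40, ph = ph)
      expect_equal(lr, log(10) * (ph - microstate_pka(p, ox)))
    }
  }
})

test_that("populations obey detailed balance for single oxidation steps", {
  for (seed in 1:5) {
    p <- random_params(seed)
    kt <- kT_meV(p$temperature)
    e_cond <- -60; ph <- 7
    ens <- ensemble(p, e_cond, ph)
    fr <- stats::setNames(ens$fraction, ens$label)
    # P0H -> P3H (oxidize heme III) and P3H -> P34H (oxidize heme IV)
    dG1 <- microstate_energy(p, "III") - microstate_energy(p, character(0))
    expect_equal(log(fr[["P3H"]] / fr[["P0H"]]), (e_cond - dG1) / kt,
                 tolerance = 1e-10)
    dG2 <- microstate_energy(p, c("III", "IV")) - microstate_energy(p, "III")
    expect_equal(log(fr[["P34H"]] / fr[["P3H"]]), (e_cond - dG2) / kt,
                 tolerance = 1e-10)
    # protonation flip of the fully oxidized protein
    expect_equal(log10(fr[["P134"]] / fr[["P134H"]]),
                 ph - microstate_pka(p, c("I", "III", "IV")),
                 tolerance = 1e-10)
  }
})

test_that("ensemble fractions are normalized and saturate at the limits", {
  grid <- expand.grid(E = seq(-500, 500, by = 100), ph = 0:14)
  ens <- ensemble(ppcA_Gu, grid$E, grid$ph)
  sums <- tapply(ens$fraction, paste(ens$potential_mV, ens$pH), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_true(all(ens$fraction >= 0 & ens$fraction <= 1))

  low <- ensemble(ppcA_Gu, -500, 5)
  expect_gt(low$fraction[low$label == "P0H"], 0.99)
  # far above all midpoints at pH 7 (one unit above the oxidized pKa of
  # 6.07) the deprotonated fully oxidized state dominates: fraction
  # 10^0.93 / (1 + 10^0.93) = 0.895
  high <- ensemble(ppcA_Gu, 500, 7)
  expect_equal(which.max(high$fraction),
               which(high$label == "P134"), ignore_attr = TRUE)
  expect_gt(high$fraction[high$label == "P134"], 0.89)
  expect_gt(ensemble(ppcA_Gu, 500, 8)$fraction[high$label == "P134"], 0.98)
})

test_that("a uniform shift of energies and potential is a gauge of the model", {
  p <- ppcA_Gu
  shift <- 137.5
  p2 <- thermo_params(g_ox = p$g_ox + shift, i_redox = p$i_redox,
                      g_h = p$g_h, i_bohr = p$i_bohr,
                      temperature = p$temperature)
  e <- seq(-200, 100, by = 50)
  expect_equal(ensemble(p2, e + shift, 7)$fraction,
               ensemble(p, e, 7)$fraction, tolerance = 1e-12)
})

test_that("without interactions each heme titrates as an independent Nernst center", {
  p <- nernst_params(g_h = 1e6)  # proton never leaves
  e <- seq(-300, 200, by = 10)
  for (h in c("I", "III", "IV")) {
    expect_equal(heme_oxidation_fraction(p, h, e, 7),
                 1 / (1 + exp(-(e - p$g_ox[[h]]) / kT_meV(p$temperature))),
                 tolerance = 1e-10)
  }
})

test_that("relabelling hemes permutes all outputs consistently", {
  p <- random_params(11)
  # swap hemes I and IV everywhere
  perm <- c(I = "IV", III = "III", IV = "I")
  p2 <- thermo_params(
    g_ox = stats::setNames(p$g_ox[c("IV", "III", "I")], c("I", "III", "IV")),
    i_redox = c("I-III" = unname(p$i_redox["III-IV"]),
                "I-IV" = unname(p$i_redox["I-IV"]),
                "III-IV" = unname(p$i_redox["I-III"])),
    g_h = p$g_h,
    i_bohr = stats::setNames(p$i_bohr[c("IV", "III", "I")],
                             c("I", "III", "IV")))
  e <- seq(-250, 80, by = 30)
  for (h in c("I", "III", "IV")) {
    expect_equal(heme_oxidation_fraction(p2, h, e, 7.5),
                 heme_oxidation_fraction(p, perm[[h]], e, 7.5))
  }
  expect_equal(microstate_energy(p2, c("I", "III"), TRUE),
               microstate_energy(p, c("IV", "III"), TRUE))
  expect_equal(sapply(0:3, stage_pka, params = p2),
               sapply(0:3, stage_pka, params = p))
})

test_that("microstate pKa follows the redox-Bohr closed form", {
  expect_equal(microstate_pka(ppcA_Gu, character(0)), 9.15, tolerance = 1e-3)
  expect_equal(microstate_pka(ppcA_Gu, c("I", "III", "IV")), 6.07,
               tolerance = 1e-3)
  # no redox-Bohr coupling: identical pKa for all 8 oxidation patterns
  p <- nernst_params(g_h = 420)
  subsets <- list(character(0), "I", "III", "IV", c("I", "III"),
                  c("I", "IV"), c("III", "IV"), c("I", "III", "IV"))
  pkas <- vapply(subsets, microstate_pka, numeric(1), params = p)
  expect_equal(pkas, rep(420 / (kT_meV(288.15) * log(10)), 8))
})

test_that("parameter files round-trip bit-exactly through JSON", {
  p <- thermo_params(
    g_ox = c(I = -59.123456789, III = -82, IV = -66.000000001),
    i_redox = c("I-III" = 28, "I-IV" = 17.5, "III-IV" = 32),
    g_h = 523.987654321, i_bohr = c(I = -52, III = -47, IV = -77),
    temperature = 288.15, protein = "roundtrip")
  path <- withr::local_tempfile(fileext = ".json")
  write_thermo_params(p, path)
  q <- read_thermo_params(path)
  expect_identical(q$g_ox, p$g_ox)
  expect_identical(q$i_redox, p$i_redox)
  expect_identical(q$g_h, p$g_h)
  expect_identical(q$i_bohr, p$i_bohr)
  expect_identical(q$temperature, p$temperature)
  expect_identical(q$protein, p$protein)
})

test_that("invalid parameter sets are rejected", {
  expect_error(thermo_params(g_ox = c(I = 1, II = 2, IV = 3),
                             i_redox = c("I-III" = 0, "I-IV" = 0,
                                         "III-IV" = 0),
                             g_h = 1, i_bohr = c(I = 0, III = 0, IV = 0)),
               "g_ox")
  expect_error(thermo_params(g_ox = c(I = 1, III = 2, IV = 3),
                             i_redox = c("I-III" = 0, "I-IV" = 0,
                                         "III-IV" = 0),
                             g_h = 1, i_bohr = c(I = 0, III = 0, IV = 0),
                             temperature = -3),
               "temperature")
  # pair names are order-insensitive
  p <- thermo_params(g_ox = c(I = 1, III = 2, IV = 3),
                     i_redox = c("III-I" = 5, "IV-I" = 6, "IV-III" = 7),
                     g_h = 1, i_bohr = c(I = 0, III = 0, IV = 0))
  expect_equal(unname(p$i_redox), c(5, 6, 7))
})
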