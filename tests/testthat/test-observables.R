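test_that("heme oxidation fractions saturate and hit the Nernst midpoint", {
  expect_equal(heme_oxidation_fraction(ppcA_Gu, "III", -1e4, 7), 0,
               tolerance = 1e-10)
  expect_equal(heme_oxidation_fraction(ppcA_Gu, "III", 1e4, 7), 1,
               tolerance = 1e-10)
  np <- nernst_params(g_h = 1e6)
  for (h in c("I", "III", "IV")) {
    expect_equal(heme_oxidation_fraction(np, h, np$g_ox[[h]], 7), 0.5,
                 tolerance = 1e-12)
  }
  # at low potential the first oxidation of PpcA_Gu is led by heme III
  f <- sapply(c("I", "III", "IV"), heme_oxidation_fraction,
              params = ppcA_Gu, potential = -150, ph = 7)
  expect_gt(f[["III"]], f[["IV"]])
  expect_gt(f[["IV"]], f[["I"]])
})

test_that("stage-conditional fractions close each stage exactly", {
  for (p in all_fixtures) {
    for (stage in 0:3) {
      for (ph in c(6, 7, 8.5)) {
        tot <- sum(sapply(c("I", "III", "IV"), stage_conditional_fraction,
                          params = p, stage = stage, ph = ph))
        expect_equal(tot, stage, tolerance = 1e-14)
      }
    }
  }
  expect_equal(stage_conditional_fraction(ppcA_Gu, "I", 0, 7), 0)
  expect_equal(stage_conditional_fraction(ppcA_Gu, "I", 3, 7), 1)
  # stage-resolved NMR observable of PpcA_Gu: heme III carries half the
  # first oxidation step at pH 7
  expect_equal(stage_conditional_fraction(ppcA_Gu, "III", 1, 7), 0.505,
               tolerance = 1e-3)
})

test_that("marginal fractions decompose over stages", {
  for (p in list(ppcA_Gu, ppcB_Gs)) {
    for (e_cond in c(-150, -60, 20)) {
      ens <- ensemble(p, e_cond, 7.4)
      p_stage <- tapply(ens$fraction, ens$stage, sum)
      for (h in c("I", "III", "IV")) {
        recon <- sum(p_stage * sapply(0:3, stage_conditional_fraction,
                                      params = p, heme = h, ph = 7.4))
        expect_equal(heme_oxidation_fraction(p, h, e_cond, 7.4), recon,
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("stage pKa equals the population-balance root", {
  # oracle: the pH at which the protonated and deprotonated populations of
  # a stage are equal, found by bisection on the full ensemble
  oracle <- function(params, stage) {
    f <- function(ph) {
      ens <- ensemble(params, 0, ph)
      keep <- ens$stage == stage
      sum(ens$fraction[keep & !ens$deprotonated]) -
        sum(ens$fraction[keep & ens$deprotonated])
    }
    stats::uniroot(f, c(0, 14), tol = 1e-12)$root
  }
  for (p in all_fixtures) {
    for (stage in 0:3) {
      expect_equal(stage_pka(p, stage), oracle(p, stage), tolerance = 1e-9)
    }
  }
  # no redox-Bohr coupling: every stage returns g_H/(kT ln 10)
  np <- nernst_params(g_h = 450)
  expect_equal(sapply(0:3, stage_pka, params = np),
               rep(450 / (kT_meV() * log(10)), 4))
})

test_that("delta pKa matches its closed form and vanishes without coupling", {
  for (p in all_fixtures) {
    expect_equal(delta_pka(p), stage_pka(p, 0) - stage_pka(p, 3),
                 tolerance = 1e-12)
    expect_equal(delta_pka(p),
                 -sum(p$i_bohr) / (kT_meV(p$temperature) * log(10)))
  }
  expect_equal(delta_pka(nernst_params()), 0)
})

test_that("midpoint potentials reduce to g_ox without interactions and order III < IV < I for PpcA_Gu", {
  np <- nernst_params(g_h = 1e6)
  for (h in c("I", "III", "IV")) {
    expect_equal(midpoint_potential(np, h, 7), np$g_ox[[h]],
                 tolerance = 0.011)
  }
  m <- sapply(c("I", "III", "IV"), midpoint_potential,
              params = ppcA_Gu, ph = 7)
  expect_lt(m[["III"]], m[["IV"]])
  expect_lt(m[["IV"]], m[["I"]])
  # fully deprotonating limit with no heme-heme coupling: g_ox + i_bohr
  iso <- thermo_params(g_ox = c(I = -80, III = -40, IV = -120),
                       i_redox = c("I-III" = 0, "I-IV" = 0, "III-IV" = 0),
                       g_h = 100, i_bohr = c(I = -30, III = -50, IV = -10))
  for (h in c("I", "III", "IV")) {
    expect_equal(midpoint_potential(iso, h, 14),
                 iso$g_ox[[h]] + iso$i_bohr[[h]], tolerance = 0.02)
  }
})

test_that("deprotonated-form potentials add the redox-Bohr interaction per heme", {
  expect_equal(deprotonated_potentials(ppcA_Gu)[["IV"]], -143)
  expect_equal(deprotonated_potentials(ppcA_Gs)[["IV"]], -183)
  np <- nernst_params()
  expect_equal(deprotonated_potentials(np), np$g_ox)
})

test_that("dominant microstate routes match the functional mechanism", {
  expect_equal(dominant_microstate_route(ppcA_Gu, ph = 7),
               c("P0H", "P3H", "P134"))
  expect_equal(dominant_microstate_route(ppcB_Gu, ph = 7),
               c("P0H", "P3H", "P14H", "P134H"))
  # well-separated non-interacting hemes with the proton locked on:
  # the route climbs one heme at a time in potential order
  deg <- nernst_params(g = c(I = -200, III = -100, IV = 0), g_h = 1e6)
  expect_equal(dominant_microstate_route(deg, ph = 7,
                                         e_grid = seq(-400, 200, by = 1)),
               c("P0H", "P1H", "P13H", "P134H"))
  # identical non-interacting hemes: intermediates never dominate, and the
  # stage-0/stage-3 tie at the shared midpoint resolves to the lower stage
  same <- nernst_params(g = c(I = -80, III = -80, IV = -80), g_h = 1e6)
  expect_equal(dominant_microstate_route(same, ph = 7),
               c("P0H", "P134H"))
  expect_error(dominant_microstate_route(ppcA_Gu, ph = 7,
                                         e_grid = seq(-50, 20, by = 1)),
               "span")
})

test_that("oxidation curves are within bounds and nondecreasing on all fixtures", {
  e <- seq(-300, 150, by = 1)
  for (p in all_fixtures) {
    for (ph in c(6, 7, 8, 9)) {
      oc <- oxidation_curves(p, ph = ph, potentials = e)
      for (col in c("frac_ox_I", "frac_ox_III", "frac_ox_IV")) {
        expect_true(all(oc[[col]] >= 0 & oc[[col]] <= 1))
        expect_true(all(diff(oc[[col]]) >= -1e-12))
      }
      ms_cols <- as.matrix(oc[, microstates()$label])
      expect_true(all(abs(rowSums(ms_cols) - 1) < 1e-12))
    }
  }
  expect_error(oxidation_curves(ppcA_Gu, 7, potentials = c(0, -10)),
               "increasing")
})

test_that("PpcB_Gu heme III dominates both the first and the last oxidation step", {
  s1 <- sapply(c("I", "III", "IV"), stage_conditional_fraction,
               params = ppcB_Gu, stage = 1, ph = 7)
  expect_equal(names(which.max(s1)), "III")
  inc <- sapply(c("I", "III", "IV"), function(h) {
    stage_conditional_fraction(ppcB_Gu, h, 3, 7) -
      stage_conditional_fraction(ppcB_Gu, h, 2, 7)
  })
  expect_equal(names(which.max(inc)), "III")
})
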