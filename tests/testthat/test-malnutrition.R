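test_that("the scaling-parameter ratio behaves as a double ratio", {
  expect_equal(derive_psp(5, 5, 2, 2), 1)
  expect_equal(derive_psp(2.1, 4.25), 0.494, tolerance = 0.002)
  expect_equal(derive_psp(3, 4, 1.5, 2), (3 / 1.5) / (4 / 2))
  expect_error(derive_psp(-1, 2), "positive")
  expect_error(derive_psp(1, 0), "positive")
})

test_that("hematocrit factors back out of a reference of 47 at all levels", {
  t1 <- malnpbpk:::reference_study_table()
  t2 <- malnpbpk:::psp_fixture_table()
  for (lev in c("mild", "intermediate", "severe")) {
    reported <- t1$value[t1$measurement == "hematocrit" & t1$category == lev]
    expect_equal(derive_psp(reported, 47),
                 t2[[lev]][t2$compartment == "hematocrit"],
                 tolerance = 0.002)
  }
})

test_that("linear deficit interpolation reproduces the milder organ levels", {
  t2 <- malnpbpk:::psp_fixture_table()
  sev <- setNames(t2$severe, t2$compartment)
  for (cp in c("brain", "liver", "bone", "kidney", "heart", "gonads")) {
    expect_equal(interpolate_level(sev[[cp]], 89.5),
                 t2$mild[t2$compartment == cp], tolerance = 0.002)
    expect_equal(interpolate_level(sev[[cp]], 82.7),
                 t2$intermediate[t2$compartment == cp], tolerance = 0.002)
  }
  expect_equal(interpolate_level(0.7, 100), 1)
  expect_error(interpolate_level(0.7, 90, 100), "undefined")
})

test_that("skin factor follows the Du Bois weight exponent", {
  expect_equal(skin_psp(65.3, 73.0), 0.954, tolerance = 0.002)
  expect_equal(skin_psp(60.3, 73.0), 0.922, tolerance = 0.002)
  expect_equal(skin_psp(53.9, 73.0), 0.879, tolerance = 0.002)
  expect_equal(skin_psp(12.7, 12.7), 1)
  expect_error(skin_psp(-1, 2), "positive")
})

test_that("the built scaling table reproduces every derivable entry", {
  tab <- psps_cached()
  t2 <- malnpbpk:::psp_fixture_table()
  derivable <- c("plasma_proteins", "hematocrit", "skin", "bone", "brain",
                 "gonads", "intestines", "lung", "stomach", "heart",
                 "kidney", "liver", "pancreas", "spleen")
  for (lev in c("mild", "intermediate", "severe")) {
    f <- tab[[lev]]$factors
    for (cp in derivable) {
      expect_equal(unname(f[cp]), t2[[lev]][t2$compartment == cp],
                   tolerance = 0.002,
                   label = sprintf("%s/%s (%.4f)", lev, cp, f[cp]))
    }
    # blood pools carried from the fixture
    for (cp in c("blood_arterial", "blood_venous", "blood_portal")) {
      expect_equal(unname(f[cp]), t2[[lev]][t2$compartment == cp])
    }
  }
  expect_equal(unname(tab$severe$factors["spleen"]), 0.612)
  expect_equal(unname(tab$severe$factors["plasma_proteins"]), 0.494,
               tolerance = 0.002)
  expect_true(all(unlist(lapply(tab, function(s) s$factors)) > 0))
})

test_that("the severe set shrinks the reference man onto the study targets", {
  sev <- apply_psps(ref_man(), psps_cached()$severe)
  expect_equal(sev$bwt, 73.0 * 0.739, tolerance = 1e-6)
  expect_equal(round(sev$bwt, 1), 53.9)
  expect_equal(round(sev$bwt / (sev$ht / 100)^2, 1), 17.4)
  # the biometric table derives its ratio row from the printed body weight
  expect_equal(round(round(sev$bwt, 1) / (sev$ht / 100), 1), 30.6)
  expect_equal(sev$ht, 176) # height untouched
  # mild and intermediate land on the reported body-weight losses
  expect_equal(apply_psps(ref_man(), psps_cached()$mild)$bwt,
               73.0 * 0.895, tolerance = 1e-6)
  expect_equal(apply_psps(ref_man(), psps_cached()$intermediate)$bwt,
               73.0 * 0.827, tolerance = 1e-6)
})

test_that("scaling preserves mass closure and specific perfusion", {
  p <- small_pop(4)[[1]]
  sev <- apply_psps(p, psps_cached()$severe)
  expect_equal(sev$bwt, sum(sev$organ_masses), tolerance = 1e-12)
  expect_identical(sev$specific_perfusion, p$specific_perfusion)
  expect_identical(sev$age, p$age)
  expect_identical(sev$ontogeny, p$ontogeny)
  expect_equal(sev$gfr / p$gfr,
               unname(psps_cached()$severe$factors["kidney"]))
})

test_that("an all-ones set is the identity and composition is elementwise", {
  p <- ref_man()
  expect_equal(apply_psps(p, psp_identity())$organ_masses, p$organ_masses)
  # applying F then G equals applying the elementwise product
  tab <- psps_cached()
  fg <- tab$mild
  fg$factors <- tab$mild$factors * tab$severe$factors
  a <- apply_psps(apply_psps(p, tab$mild), tab$severe)
  b <- apply_psps(p, fg)
  expect_equal(a$organ_masses, b$organ_masses, tolerance = 1e-12)
  expect_equal(a$albumin, b$albumin, tolerance = 1e-12)
  expect_equal(a$hematocrit, b$hematocrit, tolerance = 1e-12)
})

test_that("a missing compartment factor is an error", {
  broken <- psps_cached()$severe
  broken$factors <- broken$factors[setdiff(names(broken$factors), "liver")]
  expect_error(apply_psps(ref_man(), broken), "liver")
})

test_that("severe scaling drops WHZ by a near-constant amount", {
  pop <- small_pop(40)
  sev <- lapply(pop, apply_psps, psps = psps_cached()$severe)
  delta <- vapply(sev, whz, numeric(1)) - vapply(pop, whz, numeric(1))
  expect_lt(sd(delta), 0.2 * abs(mean(delta)))
})

test_that("plasma-protein scaling raises the unbound fraction", {
  expect_equal(scale_fu(0.7, 1), 0.7)
  expect_equal(scale_fu(0.7, 0.494), 1 / (1 + (0.3 / 0.7) * 0.494))
  expect_gt(scale_fu(0.0029, 0.494), 0.0029)
  expect_error(scale_fu(0, 1), "fu_p")
})
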