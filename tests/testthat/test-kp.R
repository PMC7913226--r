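test_that("composition methods reduce to the water ratio in lipid/protein-free media", {
  d <- probe_drug(logP = 2, fu_p = 1)
  tis <- list(f_water = 0.7, f_lipid = 0, f_protein = 0, ph_iw = 7)
  pls <- list(f_water = 0.945, f_lipid = 0, f_protein = 0)
  expect_equal(kp_pksim_standard(d, tis, plasma = pls), 0.7 / 0.945)
  expect_equal(kp_schmitt(d, tis, plasma = pls), 0.7 / 0.945)
})

test_that("a neutral unbound drug sees a plasma-like tissue as plasma", {
  d <- probe_drug(logP = 1, fu_p = 1)
  pl <- tissue_composition("plasma")
  pl_as_tissue <- as.list(pl)
  pl_as_tissue$f_ew <- pl$f_water; pl_as_tissue$f_iw <- 0
  pl_as_tissue$ra_alb <- 1; pl_as_tissue$ph_iw <- 7.4
  expect_equal(kp_rodgers_rowland(d, pl_as_tissue), 1, tolerance = 0.1)
  expect_equal(kp_pksim_standard(d, pl), 1, tolerance = 1e-9)
})

test_that("the Rodgers-Rowland method matches a direct transcription", {
  # independent transcription of the weak-base/acid/neutral composition
  # equation, evaluated straight from the fixture rows
  d <- load_drug("pyrimethamine") # weak base, pKa 6.9
  mus <- tissue_composition("muscle")
  pl <- tissue_composition("plasma")
  P <- 10^d$logP; Pnp <- 0.3 * P + 0.7
  X <- 1 + 10^(6.9 - mus$ph_iw); Y <- 1 + 10^(6.9 - 7.4)
  kpu <- mus$f_ew + X / Y * mus$f_iw +
    (P * mus$f_nl + Pnp * mus$f_np) / Y +
    mus$ra_alb * (1 / d$fu_p - 1 - (P * pl$f_nl + Pnp * pl$f_np) / Y)
  expect_equal(kp_rodgers_rowland(d, "muscle"), kpu * d$fu_p,
               tolerance = 1e-9)

  sx <- load_drug("sulfadoxine") # acid, pKa 6.2
  liv <- tissue_composition("liver")
  Ps <- 10^sx$logP; Pnps <- 0.3 * Ps + 0.7
  Xs <- 1 + 10^(liv$ph_iw - 6.2); Ys <- 1 + 10^(7.4 - 6.2)
  kpus <- liv$f_ew + Xs / Ys * liv$f_iw +
    (Ps * liv$f_nl + Pnps * liv$f_np) / Ys +
    liv$ra_alb * (1 / sx$fu_p - 1 - (Ps * pl$f_nl + Pnps * pl$f_np) / Ys)
  expect_equal(kp_rodgers_rowland(sx, "liver"), kpus * sx$fu_p,
               tolerance = 1e-9)
})

test_that("adipose partitioning runs on the vegetable-oil scale", {
  d <- load_drug("pyrimethamine")
  kp_fat <- kp_rodgers_rowland(d, "fat")
  # octanol would predict far stronger adipose partitioning
  d_oct <- d; d_oct$logP <- d$logP # same drug, muscle comparison
  expect_lt(kp_fat, 10^d$logP * 0.853 * d$fu_p)
  expect_gt(kp_fat, 0)
})

test_that("lowering the unbound fraction lowers the partition coefficient", {
  d <- load_drug("pyrimethamine")
  expect_lt(kp_rodgers_rowland(d, "muscle", fu_p = d$fu_p / 2),
            kp_rodgers_rowland(d, "muscle"))
})

test_that("strong bases with extra ionizable groups are rejected", {
  zwit <- probe_drug(pka = list(list(value = 8.6, type = "base"),
                                list(value = 6.1, type = "acid")))
  expect_error(kp_rodgers_rowland(zwit, "muscle"),
               "multi-ionization")
})

test_that("charge attenuation makes the Schmitt method fall below the neutral method", {
  base <- probe_drug(logP = 2, fu_p = 0.5,
                     pka = list(list(value = 9.5, type = "base")))
  expect_lt(kp_schmitt(base, "fat"), kp_pksim_standard(base, "fat"))
  neut <- probe_drug(logP = 2, fu_p = 0.5)
  expect_equal(kp_schmitt(neut, "fat"), kp_pksim_standard(neut, "fat"))
})

test_that("blood:plasma ratio follows its defining algebra", {
  d <- load_drug("pyrimethamine")
  expect_equal(blood_plasma_ratio(d, 0), 1)
  kery <- kp_erythrocyte(d)
  for (h in c(0.2, 0.38, 0.47)) {
    expect_equal(blood_plasma_ratio(d, h), (1 - h) + h * kery)
  }
  # direct transcription of the erythrocyte partition for pyrimethamine
  pl <- tissue_composition("plasma")
  kprot <- (1 / d$fu_p - pl$f_water - 10^d$logP * pl$f_lipid) / pl$f_protein
  kery_oracle <- d$fu_p * (0.63 + 10^d$logP * 0 + kprot * 0.19)
  expect_equal(kery, kery_oracle, tolerance = 1e-9)
  expect_error(blood_plasma_ratio(d, 1.2))
})

test_that("partition sets cover every perfused compartment and repeat exactly", {
  for (nm in c("caffeine", "cefoxitin", "sulfadoxine")) {
    d <- load_drug(nm)
    k1 <- kp_all(d); k2 <- kp_all(d)
    expect_identical(k1, k2)
    expect_identical(names(k1), compartment_names(blood = FALSE))
    expect_true(all(k1 > 0))
  }
})
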