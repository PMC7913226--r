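test_that("reference man matches the canonical biometrics and closes mass", {
  p <- ref_man()
  expect_equal(p$bwt, 73.0, tolerance = 1e-6)
  expect_equal(p$ht, 176)
  expect_lt(abs(sum(p$organ_masses) - p$bwt) / p$bwt, 0.001)
  expect_true(all(p$organ_masses > 0))
  expect_gt(p$hematocrit, 0); expect_lt(p$hematocrit, 1)
  expect_equal(p$hematocrit, 0.47)
})

test_that("interpolated ages close mass and sit on the growth reference", {
  for (a in c(0.7, 2.5, 3.917, 7, 13, 22)) {
    for (s in c("male", "female")) {
      p <- reference_individual(a, s)
      expect_lt(abs(sum(p$organ_masses) - p$bwt) / p$bwt, 0.001)
    }
  }
  # a 4-year-old reference child is a median (WHZ ~ 0) child
  expect_lt(abs(whz(reference_individual(4, "male"))), 0.5)
  expect_lt(abs(whz(reference_individual(4, "female"))), 0.5)
})

test_that("ages outside the supported grid are rejected", {
  expect_error(reference_individual(0.1, "male"), "unsupported age")
  expect_error(reference_individual(95, "female"), "unsupported age")
})

test_that("ontogeny curves are monotone, bounded and adult-complete", {
  ages <- c(0.25, 0.5, 1, 2, 3, 5, 10, 18, 30)
  for (pw in ontogeny_pathways()) {
    f <- vapply(ages, function(a) ontogeny_factor(pw, a), numeric(1))
    expect_true(all(diff(f) >= -1e-12))
    expect_true(all(f > 0 & f <= 1))
    expect_equal(ontogeny_factor(pw, 30), 1)
  }
  expect_gte(ontogeny_factor("CYP3A4", 3), 0.9)
  expect_gte(ontogeny_factor("CYP1A2", 2), 0.9)
  expect_error(ontogeny_factor("CYP9Z9", 5), "unknown")
})

test_that("population generation is seed-deterministic", {
  a <- generate_population(population_spec(25, c(1, 5), seed = 42))
  b <- generate_population(population_spec(25, c(1, 5), seed = 42))
  expect_identical(a, b)
  c2 <- generate_population(population_spec(25, c(1, 5), seed = 43))
  expect_false(identical(a, c2))
})

test_that("zero-variability populations reproduce the reference grid", {
  pop <- generate_population(population_spec(
    10, c(2, 4), seed = 5, cv_organ = 0, sd_size = 0, sd_height = 0,
    cv_scalar = 0))
  for (p in pop) {
    ref <- reference_individual(p$age, p$sex)
    expect_equal(p$organ_masses, ref$organ_masses, tolerance = 1e-12)
    expect_equal(p$bwt, ref$bwt, tolerance = 1e-12)
    expect_equal(p$ht, ref$ht, tolerance = 1e-12)
  }
})

test_that("large populations average onto the reference body weight", {
  pop <- generate_population(population_spec(400, c(46 / 12, 48 / 12),
                                             seed = 2))
  mean_bwt <- mean(vapply(pop, `[[`, numeric(1), "bwt"))
  ref <- reference_individual(4, "male")$bwt
  expect_lt(abs(mean_bwt - ref) / ref, 0.10)
  for (p in pop[1:25]) {
    expect_lt(abs(sum(p$organ_masses) - p$bwt) / p$bwt, 0.001)
  }
})

test_that("outlier exclusion follows the SD rule and keeps order", {
  pop <- small_pop(60)
  kept <- exclude_outliers(pop, k = 1)
  expect_lt(length(kept), length(pop))
  ids <- vapply(kept, `[[`, integer(1), "id")
  expect_identical(ids, sort(ids)) # order retained
  expect_identical(exclude_outliers(pop, k = 1e9), pop)
  # identical biometrics: nothing removed
  clones <- rep(list(pop[[1]]), 5)
  expect_identical(exclude_outliers(clones, 1), clones)
  expect_error(exclude_outliers(pop[1], 1), "at least two")
})

test_that("cardiac output is positive and scales linearly with body size", {
  p <- ref_man()
  co <- cardiac_output(p)
  expect_gt(co, 0)
  q <- p
  q$organ_masses <- p$organ_masses * 1.7
  q$bwt <- sum(q$organ_masses)
  expect_equal(cardiac_output(q), 1.7 * co, tolerance = 1e-12)
  # the sum excludes the lung
  expect_equal(co, sum((p$specific_perfusion * p$organ_masses)[
    setdiff(compartment_names(), "lung")]))
})
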