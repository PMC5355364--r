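test_that("recipes convert between mass and molar scales correctly", {
  # equal masses of glycine and tryptophan: molar split follows inverse MW
  r <- diet_recipe("gw", c(G = 1, W = 1), unit = "g_per_L")
  prof <- recipe_to_profile(r)
  expect_equal(prof[["G"]], 204.23 / (204.23 + 75.07), tolerance = 1e-12)
  expect_equal(sum(prof), 1, tolerance = 1e-12)

  # molar input already on the simplex is returned unchanged
  molar <- diet_recipe("m", c(M = 0.25, K = 0.75), unit = "molar_proportion")
  prof <- recipe_to_profile(molar)
  expect_equal(prof[["M"]], 0.25)
  expect_equal(prof[["K"]], 0.75)

  # all mass on one amino acid
  one <- diet_recipe("one", c(M = 3), unit = "g_per_L")
  expect_equal(recipe_to_profile(one)[["M"]], 1)

  # missing molecular weight for a supplied amino acid is an error
  mw <- aa_molecular_weights()
  expect_error(recipe_to_profile(r, mw_table = mw[names(mw) != "W"]), "W")

  # a recipe must supply at least one essential amino acid
  expect_error(diet_recipe("bad", c(G = 1, A = 1), unit = "g_per_L"),
               "essential")
})

test_that("diet recipe TSVs round-trip", {
  rec <- diet_recipe("demo", c(M = 0.5, K = 1.25, R = 2, G = 0.1),
                     unit = "g_per_L", total_aa_mass = 10.7)
  path <- tempfile(fileext = ".tsv")
  write_diet_tsv(rec, path)
  back <- read_diet_tsv(path)
  expect_identical(back$name, "demo")
  expect_identical(back$unit, "g_per_L")
  expect_equal(back$total_aa_mass, 10.7)
  expect_equal(back$amounts, rec$amounts)
})

test_that("a perfectly matched diet scores one with a full tie", {
  exo <- uniform_profile()
  rep <- limiting_report(uniform_profile(), exo)
  expect_equal(rep$r, 1)
  expect_length(rep$limiting_set, 10L)
  expect_identical(rep$limiting_aa, "F")  # canonical-order tie break
  expect_true(all(abs(rep$scores - 1) < 1e-12))
})

test_that("zero supply and zero requirement behave as specified", {
  exo <- uniform_profile()
  rep <- limiting_report(aa_profile(uniform_amounts(R = 0)), exo)
  expect_equal(rep$r, 0)
  expect_identical(rep$limiting_aa, "R")

  bad_exome <- uniform_amounts(R = 0)
  expect_error(limiting_report(uniform_profile(), bad_exome), "R")
})

test_that("conditional pairs pool only when the dependent is deficient", {
  exo <- uniform_profile()

  # cysteine surplus: the pair constraint equals methionine's own score
  rep <- limiting_report(aa_profile(uniform_amounts(M = 0.6, C = 2)), exo)
  expect_equal(rep$pair_scores[["M+C"]], rep$scores[["M"]])
  expect_identical(rep$limiting_aa, "M")

  # cysteine deficit: pooled score, lying between the individual ratios
  amt <- uniform_amounts(M = 1, C = 0.2)
  rep <- limiting_report(aa_profile(amt), exo)
  s <- sum(amt)
  expect_equal(rep$pair_scores[["M+C"]], (20 * 1.2) / (2 * s),
               tolerance = 1e-12)
  expect_lt(rep$pair_scores[["M+C"]], rep$scores[["M"]])
  expect_gt(rep$pair_scores[["M+C"]], 20 * 0.2 / s)
  expect_identical(rep$limiting_aa, "M")  # precursor named, not C

  # continuity at the surplus/deficit boundary
  rep <- limiting_report(aa_profile(uniform_amounts(M = 0.7, C = 0.7)), exo)
  expect_equal(rep$pair_scores[["M+C"]], rep$scores[["M"]], tolerance = 1e-12)
})

test_that("the limiting score agrees with the Liebig feasibility oracle", {
  # toy 5-letter alphabet with a custom essential set and one pair
  toy_eaa <- eaa_config(essential = c("a", "b"),
                        conditional_pairs = list(c("b", "d")))
  set.seed(101)
  for (i in 1:60) {
    d <- stats::setNames(stats::rgamma(5, 1) + 1e-4, letters[1:5])
    p <- stats::setNames(stats::rgamma(5, 1) + 1e-4, letters[1:5])
    rep <- limiting_report(d, p, toy_eaa)
    expect_equal(rep$r, oracle_limiting_r(d, p, toy_eaa), tolerance = 1e-9)
  }

  # full alphabet, default fly/rodent configuration
  set.seed(102)
  for (i in 1:100) {
    d <- unclass(random_profile20())
    p <- unclass(random_profile20())
    rep <- limiting_report(d, p)
    expect_equal(rep$r, oracle_limiting_r(d, p), tolerance = 1e-9)
  }
})

test_that("limiting score invariants hold on random profiles", {
  set.seed(7)
  for (i in 1:40) {
    amt <- stats::setNames(stats::rgamma(20, 2) + 1e-4, aa_codes())
    p <- unclass(random_profile20())
    rep1 <- limiting_report(amt, p)

    # scale invariance of the renormalised score
    rep3 <- limiting_report(3 * amt, p)
    expect_equal(rep1$r, rep3$r, tolerance = 1e-12)
    expect_identical(rep1$limiting_set, rep3$limiting_set)

    # dropping the limiting constraint never lowers the minimum
    expect_gte(rep1$runner_up_score, rep1$r)

    # monotonicity on the amount scale: raising any one amino acid's
    # amount never lowers the supported output level r * total
    i_up <- sample(aa_codes(), 1)
    amt2 <- amt; amt2[i_up] <- amt2[i_up] * 1.5
    rep2 <- limiting_report(amt2, p)
    expect_gte(rep2$r * sum(amt2), rep1$r * sum(amt) - 1e-12)
  }
})

test_that("fold change is the ratio of limiting scores, diet2 over diet1", {
  exo <- uniform_profile()
  d1 <- aa_profile(uniform_amounts(R = 0.5))
  expect_equal(fold_change(d1, d1, exo), 1)

  # doubling the limiting amino acid at equal total mass doubles output
  # (mass balanced through a non-essential so other proportions are fixed)
  a1 <- uniform_amounts(R = 0.2, A = 1.8)
  a2 <- uniform_amounts(R = 0.4, A = 1.6)
  expect_equal(fold_change(aa_profile(a1), aa_profile(a2), exo), 2,
               tolerance = 1e-12)

  zero <- aa_profile(uniform_amounts(R = 0))
  expect_error(fold_change(zero, d1, exo), "zero output")
})

test_that("breakpoints locate where the next constraint binds", {
  exo <- uniform_profile()
  # limiting score exactly half the runner-up: breakpoint at 2x
  diet <- aa_profile(uniform_amounts(R = 0.5))
  bp <- breakpoint(diet, exo, aa = "R")
  expect_equal(bp$x_star, 2, tolerance = 1e-12)
  expect_identical(bp$next_limiting, "F")

  expect_error(breakpoint(diet, exo, aa = "M"), "limiting")
})

test_that("response curves match per-point recomputation of the report", {
  exo <- random_profile20()
  oracle_rel <- function(amt, aa, x, eaa = eaa_config()) {
    amt2 <- amt; amt2[aa] <- amt2[aa] * x
    (limiting_report(amt2, exo, eaa)$r * sum(amt2)) /
      (limiting_report(amt, exo, eaa)$r * sum(amt))
  }

  # ordinary case: unpaired limiting amino acid
  amt <- unclass(exo) * 1000  # matched amounts...
  amt["R"] <- amt["R"] * 0.4  # ...with arginine cut to make it limiting
  diet <- aa_profile(amt)
  rep <- limiting_report(diet, exo)
  expect_identical(rep$limiting_aa, "R")
  grid <- c(0.5, 1, 1.3, 1.8, 2.5, 4, 8)
  rc <- response_curve(diet, exo, aa = "R", fold_grid = grid)
  expect_equal(rc$predicted_relative_output,
               vapply(grid, function(x) oracle_rel(amt, "R", x), 0),
               tolerance = 1e-9)
  expect_equal(rc$predicted_relative_output,
               pmin(grid, rc$breakpoint_fold), tolerance = 1e-9)
  expect_true(all(diff(rc$predicted_relative_output) >= -1e-12))
  expect_equal(rc$predicted_relative_output[grid == 1], 1)

  # pair-precursor case: methionine limiting through the pooled (M,C)
  # constraint; the curve is affine beyond the pooling point but must
  # still match per-point recomputation exactly
  amt2 <- unclass(exo) * 1000
  amt2["M"] <- amt2["M"] * 0.3
  amt2["C"] <- amt2["C"] * 0.1
  diet2 <- aa_profile(amt2)
  rep2 <- limiting_report(diet2, exo)
  expect_identical(rep2$limiting_aa, "M")
  rc2 <- response_curve(diet2, exo, aa = "M", fold_grid = grid)
  expect_equal(rc2$predicted_relative_output,
               vapply(grid, function(x) oracle_rel(amt2, "M", x), 0),
               tolerance = 1e-9)
  bp2 <- breakpoint(diet2, exo, aa = "M")
  expect_equal(oracle_rel(amt2, "M", bp2$x_star) * rep2$r,
               bp2$r_next / (rep2$r) * rep2$r, tolerance = 1e-9)

  # an empirical ceiling caps the relative output
  rc3 <- response_curve(diet, exo, aa = "R", fold_grid = grid,
                        ceiling = 1.2 * rep$r)
  expect_true(all(rc3$predicted_relative_output <= 1.2 + 1e-12))
})
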