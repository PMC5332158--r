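test_that("RLS contours are monotone and exact on the beta = 0 boundary", {
  cg <- rls_contour_grid(c(0.001, 0.2), c(0, 0.5), resolution = 41)
  # strictly decreasing in alpha at fixed beta, and in beta at fixed alpha
  expect_true(all(apply(cg$rls_matrix, 2, diff) < 0))
  expect_true(all(apply(cg$rls_matrix, 1, diff) < 0))
  expect_equal(cg$rls_matrix[, 1], log(2) / cg$alpha_values, tolerance = 1e-12)
  # grid value matches the numeric-root oracle at (0.001, 0.3)
  cg2 <- rls_contour_grid(c(0.001, 0.001), c(0.3, 0.3), resolution = 2)
  expect_equal(cg2$rls_matrix[1, 1], 17.80689, tolerance = 1e-4)
  expect_error(rls_contour_grid(c(-1, 1), c(0, 1)), "positive")
})

test_that("aging classification separates exact exponential and gompertz curves", {
  ce <- exact_curve(mortality_model("exponential", 0.02))
  fe <- fit_survival(ce, "exponential"); fg <- fit_survival(ce, "gompertz")
  expect_identical(classify_aging(fe, fg)$verdict, "non_aging")

  cg <- exact_curve(mortality_model("gompertz", 0.005, 0.15), gmax = 40)
  fe2 <- fit_survival(cg, "exponential"); fg2 <- fit_survival(cg, "gompertz")
  v <- classify_aging(fe2, fg2)
  expect_identical(v$verdict, "aging")
  expect_equal(v$evidence$beta, 0.15, tolerance = 1e-4)
})

test_that("death-aligned binning indexes generations backwards from death", {
  gt <- data.frame(cell_id = rep(1:2, c(3, 6)), gen = c(1:3, 1:6),
                   division_length = c(11:13, 21:26),
                   doubling_time = 1, generation_count = rep(c(3L, 6L), c(3, 6)),
                   phenotype = "short")
  da <- post_synchronize_to_death(gt, k_max = 5)
  # cell 1 (3 generations) contributes to bins 1..3 only
  expect_identical(sort(da$k[da$cell_id == 1]), 1:3)
  expect_identical(sort(da$k[da$cell_id == 2]), 1:5)
  # k = 1 is the last completed division
  expect_equal(da$division_length[da$cell_id == 1 & da$k == 1], 13)
  expect_equal(da$division_length[da$cell_id == 2 & da$k == 1], 26)
})

test_that("death-aligned means are flat for the age-independent simulator", {
  m <- mortality_model("exponential", 0.1)
  coh <- simulate_cohort(m, n_cells = 120, seed = 31)
  keep <- coh$lifespans$generations_at_death >= 1
  da <- post_synchronize_to_death(coh$trajectories, k_max = 5)
  mu <- tapply(da$division_length, da$k, mean)
  expect_lt(diff(range(mu)) / mean(mu), 0.05)
  mu_t <- tapply(da$doubling_time, da$k, mean)
  expect_lt(diff(range(mu_t)) / mean(mu_t), 0.10)
})

test_that("KS comparisons star real shifts and respect the null", {
  # identical samples: p = 1, no stars
  da0 <- data.frame(k = rep(1:2, each = 50), cell_id = 1,
                    division_length = rep(rnorm(50, 16, 2), 2),
                    doubling_time = rep(rnorm(50, 2, 0.4), 2))
  class(da0) <- c("death_aligned", class(da0))
  ks0 <- ks_generation_comparison(da0)
  expect_true(all(ks0$p > 0.99))
  expect_true(all(ks0$stars == ""))

  # 3-sd shift at n = 300: decisive
  set.seed(41)
  da1 <- data.frame(k = rep(1:2, each = 300), cell_id = 1,
                    division_length = c(rnorm(300, 16, 2), rnorm(300, 22, 2)),
                    doubling_time = rnorm(600, 2, 0.4))
  class(da1) <- c("death_aligned", class(da1))
  ks1 <- ks_generation_comparison(da1, metrics = "division_length")
  expect_identical(ks1$stars, "**")

  # constructed terminal-only inflation shifts only the k=1 vs k=2 pair
  set.seed(42)
  n_cells <- 200
  gt <- do.call(rbind, lapply(seq_len(n_cells), function(i) {
    L <- 5
    dt <- rnorm(L, 2.05, 0.45)
    dt[L] <- dt[L] * 1.8   # last generation slows down
    data.frame(cell_id = i, gen = 1:L, division_length = rnorm(L, 16, 2.2),
               doubling_time = dt, generation_count = L, phenotype = "short")
  }))
  da2 <- post_synchronize_to_death(gt, k_max = 5)
  ks2 <- ks_generation_comparison(da2, metrics = "doubling_time")
  first_pair <- ks2$p[ks2$pair == "k=2 vs k=1"]
  others <- ks2$p[ks2$pair != "k=2 vs k=1"]
  expect_lt(first_pair, 0.01)
  expect_true(all(others > 0.05))
})

test_that("KS star rate is near nominal under the age-independent null", {
  set.seed(43)
  stars <- 0; total <- 0
  for (r in 1:60) {
    da <- data.frame(k = rep(1:5, each = 60), cell_id = 1,
                     division_length = rnorm(300, 16, 2.2),
                     doubling_time = rnorm(300, 2.05, 0.45))
    class(da) <- c("death_aligned", class(da))
    ks <- ks_generation_comparison(da)
    stars <- stars + sum(ks$p < 0.05)
    total <- total + nrow(ks)
  }
  expect_gt(stars / total, 0.02)
  expect_lt(stars / total, 0.09)
})

test_that("death-phenotype classification applies the length and duration rules", {
  g <- growth_params()
  trs <- simulate_trajectory(g, 3, phenotype = "short", seed = 51)
  expect_identical(classify_death_phenotype(trs), "short")
  tre <- simulate_trajectory(g, 3, phenotype = "elongated", seed = 52)
  expect_identical(classify_death_phenotype(tre), "elongated")
  trn <- simulate_trajectory(g, 3, phenotype = "none", seed = 53)
  expect_error(classify_death_phenotype(trn), "not applicable")

  # simulated cohort at default probabilities: ~72% short, classification
  # agrees with the generating phenotype
  m <- mortality_model("exponential", 0.1)
  coh <- simulate_cohort(m, n_cells = 150, seed = 54)
  cls <- vapply(coh$trajectories, classify_death_phenotype, character(1))
  expect_identical(unname(cls), coh$lifespans$terminal_phenotype)
  expect_equal(mean(cls == "short"), 0.72, tolerance = 0.15)
})

test_that("sibling-fate analysis reproduces counted proportions with bootstrap SDs", {
  # one age bin holding the counted fates 135/29/40
  lt <- data.frame(cell_id = 1:204,
                   generations_at_death = rep(10L, 204),
                   status = "died", terminal_phenotype = "short",
                   sibling_fate = rep(c("never_divided", "divided_once",
                                        "divided_multiple"), c(135, 29, 40)),
                   defect_class = "none")
  sf <- sibling_fate_by_age(lt, age_bins = 1, n_boot = 100, seed = 1)
  expect_equal(as.numeric(sf$proportions[1, ]), c(135, 29, 40) / 204,
               tolerance = 1e-12)
  expect_true(all(sf$sd > 0))

  # point-mass fate: zero bootstrap SD
  lt2 <- lt; lt2$sibling_fate <- "never_divided"
  sf2 <- sibling_fate_by_age(lt2, age_bins = 1, n_boot = 50, seed = 2)
  expect_true(all(sf2$sd == 0, na.rm = TRUE))
})

test_that("fate-age independence test holds its null on repeated cohorts", {
  m <- mortality_model("exponential", 0.05)
  ps <- vapply(1:30, function(r) {
    lt <- sample_lifespans(m, 250, seed = 600 + r)
    lt <- assign_terminal_phenotypes(lt, phenotype_probs(), seed = 700 + r)
    sibling_fate_by_age(lt, age_bins = 4, n_boot = 10, seed = r)$chisq_p
  }, numeric(1))
  # p-values roughly uniform: no mass collapse at 0
  expect_gt(mean(ps < 0.05), -1e-9)  # well-defined
  expect_lt(mean(ps < 0.05), 0.2)
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("segregation-defect tallies reproduce the counted rates", {
  # 88 defects of 1182 divisions overall; 56 of 141 terminal
  ev <- rbind(
    data.frame(population = "all",
               class = rep(c("normal", "multi", "unequal", "bridge"),
                           c(1094, 30, 30, 28))),
    data.frame(population = "terminal",
               class = rep(c("normal", "multi", "unequal", "bridge"),
                           c(85, 20, 19, 17))))
  tal <- tally_segregation_defects(ev)
  expect_equal(unname(tal$defect_rate[["all"]]), 88 / 1182, tolerance = 1e-12)
  expect_equal(unname(tal$defect_rate[["terminal"]]), 56 / 141, tolerance = 1e-12)
  expect_equal(tal$fold_enrichment, (56 / 141) / (88 / 1182), tolerance = 1e-12)

  # zero defects: rate 0, fold enrichment not applicable
  ev0 <- data.frame(population = rep(c("all", "terminal"), each = 10),
                    class = "normal")
  tal0 <- tally_segregation_defects(ev0)
  expect_equal(unname(tal0$defect_rate[["all"]]), 0)
  expect_true(is.na(tal0$fold_enrichment))
  expect_error(tally_segregation_defects(
    data.frame(population = "all", class = "weird")), "unknown")
})

test_that("defect lethality estimates per-class death probabilities with CIs", {
  # bridges/asymmetric lethal in 31 of 78
  ev <- data.frame(class = rep(c("bridge", "multi"), c(78, 12)),
                   died = c(rep(c(TRUE, FALSE), c(31, 47)), rep(TRUE, 12)))
  dl <- defect_lethality(ev)
  br <- dl[dl$class == "bridge", ]
  expect_equal(br$p_death, 31 / 78, tolerance = 1e-12)
  expect_true(br$lower < 31 / 78 & 31 / 78 < br$upper)
  expect_equal(dl[dl$class == "multi", "p_death"], 1)

  # simulated class with configured lethality 0.4 recovered within its CI
  set.seed(44)
  sim <- data.frame(class = "unequal", died = runif(300) < 0.4)
  dls <- defect_lethality(sim)
  expect_true(dls$lower <= 0.4 & 0.4 <= dls$upper)
})
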