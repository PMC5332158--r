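test_that("KM on complete data equals the empirical survivor fraction", {
  cu <- km_estimate(c(1, 2, 2, 3))
  expect_equal(cu$survival, c(1, 0.75, 0.25, 0))
  expect_equal(cu$at_risk, c(4L, 4L, 3L, 1L))
  # all cells die at g = k: step to zero
  cu2 <- km_estimate(rep(7L, 20))
  expect_equal(cu2$survival, c(rep(1, 7), 0))
  expect_error(km_estimate(data.frame(generations_at_death = integer(0),
                                      status = character(0))), "no died")
})

test_that("KM matches survival::survfit on complete data", {
  skip_if_not_installed("survival")
  set.seed(13)
  g <- sample(1:30, 200, replace = TRUE)
  cu <- km_estimate(g)
  sf <- survival::survfit(survival::Surv(g, rep(1, length(g))) ~ 1)
  s_at <- stats::stepfun(sf$time, c(1, sf$surv))(cu$generations)
  expect_equal(cu$survival, s_at, tolerance = 1e-12)
})

test_that("censoring-aware KM matches survival::survfit under censoring", {
  skip_if_not_installed("survival")
  set.seed(23)
  lt <- data.frame(cell_id = 1:150,
                   generations_at_death = sample(1:25, 150, replace = TRUE),
                   status = sample(c("died", "ejected"), 150, replace = TRUE,
                                   prob = c(0.8, 0.2)))
  cu <- km_estimate(lt, censor_lost = TRUE)
  sf <- survival::survfit(
    survival::Surv(lt$generations_at_death, lt$status == "died") ~ 1)
  s_at <- stats::stepfun(sf$time, c(1, sf$surv))(cu$generations)
  expect_equal(cu$survival, s_at, tolerance = 1e-12)
  # default excludes non-died rows entirely
  cu0 <- km_estimate(lt)
  expect_identical(cu0$n_total, sum(lt$status == "died"))
})

test_that("normality screen behaves on normal and skewed samples", {
  set.seed(24)
  ok <- screen_normality(rnorm(500))
  expect_true(ok$normal)
  bad <- screen_normality(rexp(500))
  expect_false(bad$normal)
  expect_error(screen_normality(1:5), "needs")
})

test_that("empirical KM curve converges to the generating model", {
  m <- mortality_model("exponential", 0.02)
  cu <- km_estimate(sample_lifespans(m, 10000, seed = 14))
  expect_lt(max(abs(cu$survival - survival_fn(m, cu$generations))), 0.02)
})

test_that("empirical hazard is flat for exponential and log-linear for gompertz", {
  expect_equal(empirical_hazard(km_estimate(c(1, 1, 1, 1)))$hazard, 1)

  mg <- mortality_model("gompertz", 0.005, 0.15)
  cu <- km_estimate(sample_lifespans(mg, 20000, seed = 15))
  hz <- empirical_hazard(cu)
  keep <- hz$hazard > 0 & cu$at_risk[match(hz$generations, cu$generations)] > 200
  fit <- lm(log(hz$hazard[keep]) ~ hz$generations[keep])
  expect_equal(unname(coef(fit)[2]), 0.15, tolerance = 0.15)
})

test_that("survival fits recover exact model curves to high precision", {
  cve <- exact_curve(mortality_model("exponential", 0.05))
  fe <- fit_survival(cve, "exponential")
  expect_equal(fe$coef[["alpha"]], 0.05, tolerance = 1e-7)
  expect_gt(fe$adjusted_r2, 1 - 1e-10)

  cvg <- exact_curve(mortality_model("gompertz", 0.005, 0.15))
  fg <- fit_survival(cvg, "gompertz")
  expect_equal(fg$coef[["alpha"]], 0.005, tolerance = 1e-5)
  expect_equal(fg$coef[["beta"]], 0.15, tolerance = 1e-5)

  # weighted and unweighted agree on noise-free curves
  fg2 <- fit_survival(cvg, "gompertz", weighting = "none")
  expect_equal(fg$coef, fg2$coef, tolerance = 1e-6)
})

test_that("fits on simulated wild-type cohorts recover the ~2% hazard", {
  m <- mortality_model("exponential", 0.02)
  cu <- km_estimate(sample_lifespans(m, 440, seed = 16))
  f <- fit_survival(cu, "exponential")
  expect_equal(f$coef[["alpha"]], 0.02, tolerance = 0.15)
  expect_equal(f$rls, log(2) / f$coef[["alpha"]], tolerance = 1e-12)
})

test_that("fitted hazard and RLS follow the closed forms", {
  cve <- exact_curve(mortality_model("exponential", 0.02))
  fe <- fit_survival(cve, "exponential")
  expect_equal(unique(hazard_from_fit(fe, 0:50)$hazard), fe$coef[["alpha"]])
  expect_equal(rls_from_fit(fe), 34.657, tolerance = 1e-3)

  cvg <- exact_curve(mortality_model("gompertz", 0.001, 0.3), gmax = 40)
  fg <- fit_survival(cvg, "gompertz")
  expect_equal(rls_from_fit(fg), 17.807, tolerance = 1e-2)
  expect_equal(survival_fn(fg$model, rls_from_fit(fg)), 0.5, tolerance = 1e-9)
})

test_that("model selection prefers the generating family and breaks ties simply", {
  ce <- exact_curve(mortality_model("exponential", 0.02))
  expect_identical(select_model(ce)$kind, "exponential")
  cg <- exact_curve(mortality_model("gompertz", 0.005, 0.2), gmax = 40)
  expect_identical(select_model(cg)$kind, "gompertz")
  expect_error(fit_survival(km_estimate(c(1, 1, 2)), "gompertz"),
               "under-determined|distinct")
})

test_that("bootstrap CIs are deterministic, widen with less data, and degenerate sanely", {
  # point mass -> zero-width CI
  bs <- bootstrap_cis(rep(5L, 60), "exponential", n_boot = 100, seed = 1)
  expect_equal(bs$ci["alpha", "lower"], bs$ci["alpha", "upper"])

  m <- mortality_model("exponential", 0.02)
  g1 <- sample_lifespans(m, 1000, seed = 17)$generations_at_death
  b1 <- bootstrap_cis(g1, "exponential", n_boot = 200, seed = 2)
  b1b <- bootstrap_cis(g1, "exponential", n_boot = 200, seed = 2)
  expect_identical(b1$replicates, b1b$replicates)
  g2 <- g1[1:100]
  b2 <- bootstrap_cis(g2, "exponential", n_boot = 200, seed = 3)
  expect_gt(diff(b2$ci["rls", ]), diff(b1$ci["rls", ]))
})

test_that("hazard normalization reports fold changes against a reference", {
  fe1 <- fit_survival(exact_curve(mortality_model("exponential", 0.02)), "exponential")
  fe2 <- fit_survival(exact_curve(mortality_model("exponential", 0.01)), "exponential")
  nh <- normalize_hazard(list(same = fe1, sir2OE_like = fe2), fe1)
  expect_equal(nh$fold_change, c(1, 0.5), tolerance = 1e-6)

  # simulated ~7-fold hazard pair (rqh1-delta-like vs wild type)
  m_wt <- mortality_model("exponential", 0.02)
  m_mut <- mortality_model("exponential", 0.14)
  f_wt <- fit_survival(km_estimate(sample_lifespans(m_wt, 2000, seed = 18)),
                       "exponential", n_boot = 100, seed = 4)
  f_mut <- fit_survival(km_estimate(sample_lifespans(m_mut, 2000, seed = 19)),
                        "exponential", n_boot = 100, seed = 5)
  nh2 <- normalize_hazard(list(mut = f_mut), f_wt)
  expect_equal(nh2$fold_change, 7, tolerance = 0.15 * 7)
  expect_true(nh2$lower < nh2$fold_change & nh2$fold_change < nh2$upper)
})

test_that("coefficient recovery: bootstrap CIs cover the truth across regimes", {
  grid <- expand.grid(alpha = c(0.005, 0.02, 0.08),
                      beta = c(0.05, 0.15, 0.3))
  cover_a <- 0; cover_b <- 0; total <- 0
  for (i in seq_len(nrow(grid))) {
    m <- mortality_model("gompertz", grid$alpha[i], grid$beta[i])
    for (r in 1:4) {
      lt <- sample_lifespans(m, 440, seed = 1000 * i + r)
      f <- tryCatch(fit_survival(km_estimate(lt), "gompertz", n_boot = 120,
                                 seed = r), error = function(e) NULL)
      if (is.null(f)) next
      total <- total + 1
      cover_a <- cover_a + (f$ci["alpha", "lower"] <= grid$alpha[i] &
                            grid$alpha[i] <= f$ci["alpha", "upper"])
      cover_b <- cover_b + (f$ci["beta", "lower"] <= grid$beta[i] &
                            grid$beta[i] <= f$ci["beta", "upper"])
    }
  }
  expect_gte(total, 30)
  expect_gte(cover_a / total, 0.9)
  expect_gte(cover_b / total, 0.9)
})
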