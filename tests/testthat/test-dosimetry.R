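test_that("time-activity fits recover exact curves and apply the form rule", {
  t4 <- c(1, 24, 48, 120)
  y <- 100 * exp(-0.05 * t4)
  fit <- fit_time_activity(t4, y, form = "mono")
  expect_equal(fit$coef, 100, tolerance = 1e-6)
  expect_equal(fit$rates, 0.05, tolerance = 1e-6)
  # with four points the default rule fits a biexponential whose total
  # amplitude and rates still reproduce the curve
  auto <- fit_time_activity(t4, y)
  expect_equal(auto$form, "bi")
  expect_equal(sum(auto$coef), 100, tolerance = 1e-4)
  expect_equal(auto$rates, c(0.05, 0.05), tolerance = 1e-3)
  # three points force a monoexponential even for biexponential data
  t3 <- c(1, 24, 120)
  yb <- 80 * exp(-0.2 * t3) + 20 * exp(-0.01 * t3)
  expect_equal(fit_time_activity(t3, yb)$form, "mono")
  expect_error(fit_time_activity(1, 5), "at least 2")
  expect_error(fit_time_activity(c(1, 2, 3), c(1, 2, 3), form = "bi"),
               "at least 4")
})

test_that("dominant biexponential rate survives noise", {
  # 10% noise, 5 points, dominant (fast) component
  t5 <- c(1, 6, 24, 72, 168)
  truth <- 80 * exp(-0.15 * t5) + 20 * exp(-0.01 * t5)
  set.seed(2024)
  ratios <- vapply(1:200, function(r) {
    y <- truth * rlnorm(5, 0, 0.10)
    f <- fit_time_activity(t5, y)
    f$rates[1] / 0.15
  }, 0)
  expect_lt(abs(median(ratios) - 1), 0.10)
})

test_that("cumulated activity has the exact closed form", {
  # pure physical decay with a 1 h half-life integrates to 1/ln2
  iso1 <- isotope_spec("X", 1)
  expect_equal(cumulated_activity(list(coef = 1, rates = 0), iso1),
               1 / log(2), tolerance = 1e-12)
  # linear in the amplitude
  f <- list(coef = c(30, 12), rates = c(0.2, 0.01))
  lu <- isotope_lu177()
  expect_equal(cumulated_activity(list(coef = 2 * f$coef, rates = f$rates),
                                  lu),
               2 * cumulated_activity(f, lu), tolerance = 1e-12)
  expect_error(cumulated_activity(list(coef = 1, rates = -1),
                                  isotope_spec("X", 1e9)), "positive")
})

test_that("closed-form integral agrees with numerical quadrature", {
  set.seed(314)
  lu <- isotope_lu177()
  for (i in 1:25) {
    f <- list(coef = runif(2, 1, 100), rates = c(runif(1, 0.05, 0.5),
                                                 runif(1, 1e-3, 0.02)))
    expect_equal(cumulated_activity(f, lu),
                 quad_cumulated(f$coef, f$rates, lu$lambda_phys),
                 tolerance = 1e-6)
  }
})

test_that("isotope translation is the algebraic substitution identity", {
  ind <- isotope_in111()
  lu <- isotope_lu177()
  # pure physical decay: ratio of integrals is the half-life ratio
  f0 <- list(coef = 5, rates = 0)
  expect_equal(translate_isotope(f0, ind, lu) /
                 cumulated_activity(f0, ind),
               lu$half_life_h / ind$half_life_h, tolerance = 1e-12)
  set.seed(99)
  for (i in 1:20) {
    f <- list(coef = runif(2, 1, 50), rates = runif(2, 1e-3, 0.5))
    expect_identical(translate_isotope(f, ind, lu),
                     cumulated_activity(f, lu))
    expect_identical(translate_isotope(f, ind, ind),
                     cumulated_activity(f, ind))
  }
})

simple_s <- function(organs, S = 0.02, ref = 1) {
  grid <- expand.grid(source = organs, target = organs,
                      stringsAsFactors = FALSE)
  grid$S_mGy_per_MBq_h <- ifelse(grid$source == grid$target, S, 0)
  grid$ref_mass_kg <- ref
  grid
}

test_that("absorbed doses follow the mass-scaled MIRD sum", {
  st <- simple_s(c("liver", "kidneys"))
  masses <- c(liver = 1, kidneys = 1)
  zero <- absorbed_dose(c(liver = 0, kidneys = 0), st, masses, 100)
  expect_equal(zero$dose_mGy, c(0, 0))
  one <- absorbed_dose(c(liver = 10, kidneys = 0), st, masses, 100)
  expect_equal(one$dose_mGy[one$organ == "liver"], 0.2)
  expect_equal(one$dose_mGy_per_MBq[one$organ == "liver"], 0.002)
  # halving the organ mass doubles the self-dose term
  half <- absorbed_dose(c(liver = 10, kidneys = 0), st,
                        c(liver = 0.5, kidneys = 1), 100)
  expect_equal(half$dose_mGy[half$organ == "liver"],
               2 * one$dose_mGy[one$organ == "liver"])
  # dose linear in administered activity; normalized dose invariant
  twice <- absorbed_dose(c(liver = 20, kidneys = 0), st, masses, 200)
  expect_equal(twice$dose_mGy[twice$organ == "liver"],
               2 * one$dose_mGy[one$organ == "liver"])
  expect_equal(twice$dose_mGy_per_MBq, one$dose_mGy_per_MBq)
  expect_error(absorbed_dose(c(spleen = 1), st, c(spleen = 1), 100),
               "spleen")
})

test_that("Spearman rho and exact p match brute-force enumeration", {
  expect_equal(spearman_exact(1:5, c(2, 4, 6, 7, 9))$rho, 1)
  expect_equal(spearman_exact(1:5, 5:1)$rho, -1)
  set.seed(61)
  x <- runif(5)
  y <- runif(5)
  got <- spearman_exact(x, y)
  ora <- brute_spearman(x, y)
  expect_equal(ora$n_perm, 120)
  expect_equal(got$rho, ora$rho, tolerance = 1e-12)
  expect_equal(got$p_value, ora$p, tolerance = 1e-12)
  # ties handled by mid-ranks, n = 6
  x2 <- c(1, 2, 2, 3, 4, 5)
  y2 <- c(2, 1, 4, 4, 5, 7)
  got2 <- spearman_exact(x2, y2)
  ora2 <- brute_spearman(x2, y2)
  expect_equal(got2$rho, ora2$rho, tolerance = 1e-12)
  expect_equal(got2$p_value, ora2$p, tolerance = 1e-12)
  expect_error(spearman_exact(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("session comparison uses matched organs and exact tests", {
  orgs <- c("lung", "liver", "kidneys", "spleen", "heart")
  r1 <- data.frame(organ = orgs, dose_mGy_per_MBq = c(0.1, 0.3, 0.9,
                                                      0.25, 0.15))
  s2vals <- c(0.13, 0.35, 0.99, 0.255, 0.17)  # distinct |differences|
  r2 <- data.frame(organ = rev(orgs), dose_mGy_per_MBq = rev(s2vals))
  cmp <- compare_sessions(r1, r2)
  expect_equal(cmp$spearman$rho, 1)
  expect_equal(cmp$spearman$method, "exact permutation")
  # Wilcoxon signed-rank agrees with enumeration over sign flips
  ora <- brute_signed_rank(r1$dose_mGy_per_MBq - s2vals)
  expect_equal(unname(cmp$wilcoxon$statistic), ora$V)
  expect_equal(cmp$wilcoxon$p.value, ora$p, tolerance = 1e-12)
  r3 <- r2
  r3$organ[1] <- "aorta"
  expect_error(compare_sessions(r1, r3), "mismatched")
})

test_that("cohort comparison needs at least two groups", {
  expect_error(compare_cohorts(1:6, rep("I", 6)), "at least 2")
  kt <- compare_cohorts(c(1, 2, 3, 7, 8, 9), rep(c("I", "II"), each = 3))
  expect_s3_class(kt, "htest")
  expect_equal(unname(kt$statistic),
               kruskal.test(list(c(1, 2, 3), c(7, 8, 9)))$statistic,
               ignore_attr = TRUE)
})
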