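test_that("cohort generation is a pure function of config and seed", {
  cc <- cohort_config(n_eyes = 306)
  a <- generate_cohort(cc, seed = 4)
  b <- generate_cohort(cc, seed = 4)
  expect_identical(a, b)
  expect_false(identical(a, generate_cohort(cc, seed = 5)))
  expect_equal(nrow(a), 306)
  expect_equal(length(unique(a$subject_id)), 153)
  expect_equal(unname(table(a$subject_id)["S0001"]), 2L)
})

test_that("generated eyes respect physiologic biometry invariants", {
  r <- generate_cohort(cohort_config(n_eyes = 306), seed = 8)
  expect_true(all(r$AL > 15 & r$AL < 35))
  expect_true(all(r$CCT > 0.3 & r$CCT < 0.8))
  expect_true(all(r$ACD > 1.5 & r$ACD < 5.5))
  expect_true(all(r$LT > 2.5 & r$LT < 6))
  expect_true(all(r$Km > 35 & r$Km < 52))
  expect_true(all(r$ACD + r$LT + r$CCT < r$AL))
  expect_true(all(r$C <= 0))
  expect_true(all(r$dS >= 0))
  expect_true(all(r$cyclo_S == r$S + r$dS))
  expect_true(all(r$S >= -7.5 & r$S <= 10.5))
  expect_equal(r$Km, (r$K1 + r$K2) / 2, tolerance = 1e-9)
})

test_that("cohort moments converge to the configured values", {
  cc <- cohort_config()
  stats <- sapply(1:10, function(s) {
    r <- generate_cohort(cc, seed = s)
    c(mS = mean(r$S), mdS = mean(r$dS), sS = sd(r$S), sdS = sd(r$dS),
      cor_age = cor(r$dS, r$age))
  })
  # grand means within 3 empirical standard errors of the targets
  expect_lt(abs(mean(stats["mS", ]) - (-1.53)),
            3 * sd(stats["mS", ]) / sqrt(10) + 0.02)
  expect_lt(abs(mean(stats["mdS", ]) - 0.34),
            3 * sd(stats["mdS", ]) / sqrt(10) + 0.01)
  expect_lt(abs(mean(stats["sS", ]) - 2.17), 0.15)
  expect_lt(abs(mean(stats["sdS", ]) - 0.53), 0.10)
  # shift negatively correlated with age in at least 9/10 seeds
  expect_gte(sum(stats["cor_age", ] < 0), 9)
})

test_that("fellow eyes are correlated and cycloplegic shift is lens-mediated", {
  r <- generate_cohort(cohort_config(n_eyes = 306), seed = 2)
  od <- seq(1, 305, by = 2); os <- seq(2, 306, by = 2)
  expect_gt(cor(r$S[od], r$S[os]), 0.5)
  expect_gt(cor(r$AL[od], r$AL[os]), 0.5)
  # thicker lenses and shallower chambers carry more accommodative tonus
  expect_gt(cor(r$LT, r$dS, method = "spearman"), 0.1)
  expect_lt(cor(r$ACD, r$dS, method = "spearman"), -0.1)
})

test_that("missingness injection is seeded, binomial and target-safe", {
  r <- generate_cohort(cohort_config(n_eyes = 306), seed = 6)
  expect_identical(inject_missingness(r, 0), r)
  m1 <- inject_missingness(r, 0.1, seed = 3)
  m2 <- inject_missingness(r, 0.1, seed = 3)
  expect_identical(m1, m2)
  bio <- c("IOP", "AL", "CCT", "ACD", "LT", "K1", "K2", "Km")
  n_cells <- length(bio) * nrow(r)
  n_blank <- sum(is.na(m1[, bio]))
  expect_lt(abs(n_blank - 0.1 * n_cells), 4 * sqrt(n_cells * 0.1 * 0.9))
  expect_false(anyNA(m1$cyclo_S))
  expect_false(anyNA(m1$eye_id))
  expect_error(inject_missingness(r, 1.2), "rate")
})

test_that("noiseless accommodation series lie exactly on the generating quadratics", {
  cfg <- accommodation_config(n_eyes = 4, acr_noise_sd = 0, pcr_noise_sd = 0)
  s <- generate_accommodation_series(cfg, seed = 1)
  f_acr <- fit_quadratic(s$delta_acr, s$stimulus, "anterior")
  expect_equal(unname(coef(f_acr)), c(0.01, -1.21, -0.02), tolerance = 1e-6)
  f_pcr <- fit_quadratic(s$delta_pcr, s$stimulus, "posterior")
  expect_equal(unname(coef(f_pcr)), c(-2.40, 9.30, -0.60), tolerance = 1e-6)
  # radius-referenced changes are zero at baseline and monotone in stimulus
  d <- delta_radii(s)
  expect_true(all(d$dACR[d$stimulus == 0] == 0))
  expect_true(all(d$dPCR[d$stimulus == 0] == 0))
  for (id in unique(s$eye_id)) {
    sub <- s[s$eye_id == id, ]
    expect_true(all(diff(sub$ACR) < 0))
    expect_true(all(diff(sub$PCR) < 0))
    expect_true(all(diff(sub$LT) > 0))
  }
})

test_that("accommodation series respect seeding and config validation", {
  cfg <- accommodation_config()
  expect_identical(generate_accommodation_series(cfg, seed = 2),
                   generate_accommodation_series(cfg, seed = 2))
  expect_equal(nrow(generate_accommodation_series(cfg, seed = 2)),
               16 * length(cfg$stimulus_levels))
  expect_error(accommodation_config(stimulus_levels = c(1, 2)), "baseline")
  expect_error(accommodation_config(stimulus_levels = c(0, 2, 1)), "increasing")
  expect_error(accommodation_config(acr_noise_sd = -1), "noise")
  # a stimulus beyond the quadratic's range has no real root
  expect_error(generate_accommodation_series(
    accommodation_config(stimulus_levels = c(0, 20)), seed = 1), "real root")
})

test_that("config validation rejects impossible cohorts", {
  expect_error(cohort_config(n_eyes = 305), "even")
  expect_error(cohort_config(missing_rate = 1), "missing_rate")
  expect_error(cohort_config(s_sd = -1), "positive")
  expect_error(cohort_config(dS_age_slope = 0.5), "slope")
})
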