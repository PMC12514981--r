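test_that("curvature changes are referenced to the relaxed baseline", {
  s <- data.frame(eye_id = "e1", stimulus = c(0, 2),
                  ACR = c(11.0, 9.5), PCR = c(6.0, 5.8))
  d <- delta_radii(s)
  expect_equal(d$dACR, c(0, 1.5))
  expect_equal(d$dPCR, c(0, 0.2))
  expect_error(delta_radii(s[2, ]), "baseline")
  expect_error(delta_radii(rbind(s, s[1, ])), "exactly one")
})

test_that("quadratic fits recover the printed curvature-accommodation relations", {
  dr <- seq(-5, 0, length.out = 7)
  acc <- 0.01 * dr^2 - 1.21 * dr - 0.02
  f <- fit_quadratic(dr, acc, "anterior")
  expect_equal(unname(coef(f)), c(0.01, -1.21, -0.02), tolerance = 1e-8)
  expect_equal(f$r2, 1, tolerance = 1e-10)
  expect_equal(slope_at_zero(f), 1.21, tolerance = 1e-8)
  expect_equal(mm_per_diopter_small_acc(f), 1 / 1.21, tolerance = 1e-8)
  dp <- seq(0, 0.95, length.out = 7)
  accp <- -2.40 * dp^2 + 9.30 * dp - 0.60
  g <- fit_quadratic(dp, accp, "posterior")
  expect_equal(unname(coef(g)), c(-2.40, 9.30, -0.60), tolerance = 1e-8)
  expect_equal(slope_at_zero(g), 9.30, tolerance = 1e-8)
  expect_equal(mm_per_diopter_small_acc(g), 1 / 9.30, tolerance = 1e-8)
  # anterior steepening buys far more accommodation per mm near rest
  expect_gt(slope_at_zero(g) / slope_at_zero(f), 5)
})

test_that("degenerate and noisy fits behave sensibly", {
  z <- fit_quadratic(rep(0, 5), rep(0, 5))
  expect_equal(unname(coef(z)), c(0, 0, 0))
  expect_true(is.na(z$r2))
  expect_equal(slope_at_zero(z), 0)
  expect_error(mm_per_diopter_small_acc(z), "zero slope")
  expect_error(fit_quadratic(c(0, 0, 1, 1), c(0, 0, 1, 2)), "3 distinct")
  set.seed(1)
  dr <- seq(-5, 0, length.out = 40)
  f <- fit_quadratic(dr, 0.01 * dr^2 - 1.21 * dr - 0.02 + rnorm(40, 0, 0.2))
  expect_lt(f$r2, 1)
  expect_equal(slope_at_zero(f), 1.21, tolerance = 0.15)
  expect_equal(predict(f, 0), f$c, tolerance = 1e-12)
  expect_output(print(f), "slope")
})

test_that("pooled fits on generated series recover the slope magnitudes", {
  cfg <- accommodation_config(acr_noise_sd = 0, pcr_noise_sd = 0)
  fits <- fit_accommodation(generate_accommodation_series(cfg, seed = 3))
  # radius-referenced axis flips the anterior sign; magnitudes survive
  expect_equal(slope_at_zero(fits$anterior), 1.21, tolerance = 1e-3)
  expect_equal(slope_at_zero(fits$posterior), 9.30, tolerance = 0.4)
  expect_gt(fits$posterior$b, 0)
})

test_that("thick-lens power from AS-OCT geometry matches the oracle", {
  expect_equal(lens_power_from_asoct(64, 64, 1e-9), 2, tolerance = 1e-6)
  expect_equal(lens_power_from_asoct(11.0, 6.0, 3.6), 16.32526406926407,
               tolerance = 1e-9)
  set.seed(2)
  acr <- runif(50, 8, 13); pcr <- runif(50, 5, 7); lt <- runif(50, 3, 4.5)
  expect_equal(lens_power_from_asoct(acr, pcr, lt),
               o_thick(o_ra(acr), o_ra(pcr), lt), tolerance = 1e-9)
  # steeper anterior surface at fixed posterior geometry -> more power
  grid <- seq(8, 13, length.out = 30)
  expect_true(all(diff(lens_power_from_asoct(grid, 6, 3.6)) < 0))
  expect_error(lens_power_from_asoct(-1, 6, 3.6), "positive")
})

test_that("principal-plane offset matches the closed form and its limits", {
  expect_equal(principal_plane_offset(11.00197268677597, 9.26, 3.6,
                                      6.911447084233261),
               -1.651315424804644, tolerance = 1e-9)
  set.seed(6)
  fa <- runif(40, 5, 20); fp <- runif(40, 5, 20)
  lt <- runif(40, 3, 4.5); rp <- runif(40, 5, 8)
  expect_equal(principal_plane_offset(fa, fp, lt, rp),
               o_op_prime(fa, fp, lt, rp), tolerance = 1e-9)
  # thin-lens degenerate limit: both sagitta and p' vanish
  expect_equal(principal_plane_offset(11, 9.26, 1e-9, 6.9), 0, tolerance = 1e-6)
  expect_error(principal_plane_offset(11, 9.26, 14, 6.9), "sagitta")
})

test_that("the offset is monotone in each surface power, opposite directions", {
  fa_grid <- seq(5, 20, length.out = 50)
  fp_grid <- seq(5, 20, length.out = 50)
  m <- op_prime_surface(fa_grid, fp_grid, LT = 3.6, rp = 6.9)
  expect_equal(dim(m), c(50, 50))
  expect_true(all(apply(m, 2, diff) < 0))  # decreasing in Fa down each column
  expect_true(all(apply(m, 1, diff) > 0))  # increasing in Fp along each row
  expect_equal(op_prime_surface(11, 9.26, 3.6, 6.9)[1, 1],
               principal_plane_offset(11, 9.26, 3.6, 6.9))
  # not symmetric under exchanging the surfaces of a thick lens
  expect_false(isTRUE(all.equal(m, t(m))))
  expect_error(op_prime_surface(numeric(0), fp_grid, 3.6, 6.9), "nonempty")
})
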