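test_that("corneal radius inverts the keratometric constant", {
  expect_equal(corneal_radius(45), 7.5)
  expect_equal(corneal_radius(33.75), 10.0)
  expect_equal(corneal_radius(43), 337.5 / 43, tolerance = 1e-12)
  expect_error(corneal_radius(0), "positive")
  expect_error(corneal_radius(-40), "positive")
})

test_that("corrected axial length matches the retinal-thickness correction", {
  expect_equal(corrected_axial_length(0), 0.65696)
  expect_equal(corrected_axial_length(23), 23 + 0.65696 - 0.02029 * 23)
  fp <- 0.65696 / 0.02029  # fixed point: correction vanishes
  expect_equal(corrected_axial_length(fp), fp, tolerance = 1e-12)
})

test_that("lens power formulas reproduce frozen fixture values", {
  r <- corneal_radius(43)
  expect_equal(iol_emmetropia(23.65, 3.60, r), 18.14688638376824, tolerance = 1e-10)
  expect_equal(iol_myopia(23.65, 3.60, r, SE = -3), 22.36493419122600, tolerance = 1e-10)
  expect_equal(contact_lens_power(-5), -5 / 1.06, tolerance = 1e-12)
  expect_equal(contact_lens_power(10), 10 / 0.88, tolerance = 1e-12)
  expect_equal(contact_lens_power(0), 0)
  expect_equal(contact_lens_power(-3), -2.895752895752896, tolerance = 1e-10)
  expect_equal(corrected_corneal_radius_cl(45, -5), 8.4375)
  expect_equal(corrected_corneal_radius_cl(43, 2), 7.5)
  expect_equal(iol_contact_lens(23.65, 3.60, 43, SE = -3),
               21.75784662959011, tolerance = 1e-10)
})

test_that("thick-lens inversion and radius relation match frozen values", {
  expect_equal(anterior_surface_power(20, 3.6), 11.00197268677597, tolerance = 1e-10)
  expect_equal(anterior_radius(64), 1.0)
  expect_equal(anterior_radius(8), 8.0)
  expect_equal(anterior_radius(11.00197268677597), 5.817138600691673,
               tolerance = 1e-9)
  # thin-lens limit: Fa -> F_total - F_p
  expect_equal(anterior_surface_power(20, 1e-9), 20 - 9.26, tolerance = 1e-6)
  expect_error(anterior_radius(0), "nonzero")
  expect_error(anterior_surface_power(20, 0), "positive")
})

test_that("every SRK/T operation matches the direct-arithmetic oracle on a grid", {
  g <- random_biometry(100, seed = 42)
  r <- corneal_radius(g$Km)
  expect_equal(r, o_r(g$Km), tolerance = 1e-9)
  expect_equal(corrected_axial_length(g$AL), o_lopt(g$AL), tolerance = 1e-9)
  expect_equal(iol_emmetropia(g$AL, g$ACD, r), o_iol_e(g$AL, g$ACD, r),
               tolerance = 1e-9)
  expect_equal(iol_myopia(g$AL, g$ACD, r, g$SE), o_iol_m(g$AL, g$ACD, r, g$SE),
               tolerance = 1e-9)
  expect_equal(contact_lens_power(g$SE), o_fc(g$SE), tolerance = 1e-9)
  expect_equal(corrected_corneal_radius_cl(g$Km, o_fc(g$SE)),
               o_rcl(g$Km, o_fc(g$SE)), tolerance = 1e-9)
  expect_equal(iol_contact_lens(g$AL, g$ACD, g$Km, g$SE),
               o_iol_cl(g$AL, g$ACD, g$Km, g$SE), tolerance = 1e-9)
})

test_that("ametropic and contact-lens formulations collapse to the emmetropic one at SE = 0", {
  g <- random_biometry(120, seed = 7)
  r <- corneal_radius(g$Km)
  e <- iol_emmetropia(g$AL, g$ACD, r)
  expect_equal(iol_myopia(g$AL, g$ACD, r, SE = rep(0, 120)), e, tolerance = 1e-12)
  expect_equal(iol_contact_lens(g$AL, g$ACD, g$Km, SE = rep(0, 120)), e,
               tolerance = 1e-12)
})

test_that("thick-lens recombination is the identity on total power", {
  set.seed(11)
  F_tot <- runif(200, 5, 40)
  LT <- runif(200, 2.5, 6)
  Fa <- anterior_surface_power(F_tot, LT)
  expect_equal(thick_lens_power(Fa, 9.26, LT), F_tot, tolerance = 1e-9)
})

test_that("emmetropic lens power decreases in AL and increases in corneal power", {
  r <- corneal_radius(43)
  expect_gt(iol_emmetropia(22, 3.6, r), iol_emmetropia(26, 3.6, r))
  als <- seq(21, 27, length.out = 30)
  expect_true(all(diff(iol_emmetropia(als, 3.6, r)) < 0))
  # steeper cornea (smaller r) leaves less power for the lens at fixed AL:
  rs <- seq(7.0, 8.4, length.out = 20)
  iols <- iol_emmetropia(rep(23.65, 20), 3.6, rs)
  expect_true(all(diff(iols) > 0))
  # ametropic variant: retained myopia demands more lens power
  expect_gt(iol_myopia(23.65, 3.6, r, -3), iol_myopia(23.65, 3.6, r, 3))
  expect_gt(iol_contact_lens(23.65, 3.6, 43, -3), iol_emmetropia(23.65, 3.6, r))
  expect_error(iol_emmetropia(3.0, 3.6, r), "degenerate")
})

test_that("vertex correction shrinks myopic and inflates hyperopic magnitudes", {
  se_neg <- -seq(0.25, 15, by = 0.25)
  expect_true(all(abs(contact_lens_power(se_neg)) < abs(se_neg)))
  se_pos <- seq(0.25, 79, by = 0.5)
  expect_true(all(abs(contact_lens_power(se_pos)) > abs(se_pos)))
})

test_that("power vectors satisfy the norm identity and axis conventions", {
  expect_equal(power_vectors(0, 37), list(J0 = 0, J45 = 0))
  pv <- power_vectors(-1, 90)
  expect_equal(pv$J0, -0.5, tolerance = 1e-12)
  expect_equal(pv$J45, 0, tolerance = 1e-12)
  pv <- power_vectors(-2, 45)
  expect_equal(pv$J0, 0, tolerance = 1e-12)
  expect_equal(pv$J45, 1.0, tolerance = 1e-12)
  set.seed(3)
  C <- -runif(100, 0, 4); ax <- runif(100, 0, 180 - 1e-9)
  pv <- power_vectors(C, ax)
  expect_equal(pv$J0^2 + pv$J45^2, (C / 2)^2, tolerance = 1e-12)
  expect_error(power_vectors(1, 90), "convention")
  expect_error(power_vectors(-1, 180), "axis")
})

test_that("spherical equivalent adds half the cylinder", {
  expect_equal(spherical_equivalent(-1, 0), -1)
  expect_equal(spherical_equivalent(-1, -1), -1.5)
  expect_equal(spherical_equivalent(2, -4), 0)
})

test_that("lens_derived_features chains the variant formulas consistently", {
  ld <- lens_derived_features(23.65, 3.60, 3.70, 43, SE = -3, variant = "cl")
  expect_equal(ld$iol, o_iol_cl(23.65, 3.60, 43, -3), tolerance = 1e-9)
  expect_equal(ld$Fa, o_fa(ld$iol, 3.70), tolerance = 1e-9)
  expect_equal(ld$ra, o_ra(ld$Fa), tolerance = 1e-9)
  expect_equal(ld$Fc, o_fc(-3), tolerance = 1e-12)
  ld_e <- lens_derived_features(23.65, 3.60, 3.70, 43, variant = "e")
  expect_true(is.na(ld_e$Fc) && is.na(ld_e$r_cl))
  expect_equal(ld_e$Fa, 9.109829950748634, tolerance = 1e-9)
  expect_equal(ld_e$ra, 7.025378118582835, tolerance = 1e-9)
})

test_that("optical constants validate their invariants", {
  expect_error(optical_constants(n_lens = 1.3), "exceed")
  expect_error(optical_constants(delta_n = -1), "positive")
  expect_output(print(optical_constants()), "lens index")
})
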