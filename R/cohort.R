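#' Configuration of the synthetic paediatric cohort generator
#'
#' Defaults reproduce the study population the analysis assumes: 306 eyes of
#' 153 children aged 4-15 years, non-cycloplegic sphere -1.53 +/- 2.17 D
#' (truncated to the observed range), a nonnegative cycloplegic sphere shift
#' of 0.34 +/- 0.53 D that decreases with age and is partly mediated by lens
#' geometry, and cylinder -0.87 +/- 0.75 D under the C <= 0 convention.
#'
#' The shift (accommodative tonus) model is multiplicative gamma:
#' `E[dS | age, LT, ACD] = dS_mean * (1 + dS_age_slope*(age_mid - age)) *
#' exp(gLT*(LT - E[LT|age]) - gACD*(ACD - E[ACD|age]) - s^2/2)`, with a
#' constant per-eye coefficient of variation solved in closed form so the
#' marginal mean and SD equal `dS_mean` and `dS_sd` exactly.
#'
#' @param n_eyes number of eyes (two per subject; must be even).
#' @param age_range years, uniform; shared within subject.
#' @param s_mean,s_sd non-cycloplegic sphere moments, D.
#' @param s_range truncation range for non-cycloplegic sphere, D.
#' @param s_age_slope change of mean sphere per year of age, D/yr.
#' @param dS_mean,dS_sd cycloplegic sphere shift moments, D.
#' @param dS_age_slope relative decrease of the mean shift per year, 1/yr
#'   (must keep the factor positive over `age_range`).
#' @param dS_lens_LT,dS_lens_ACD log-scale lens-mediation coefficients of
#'   the shift on lens thickness and anterior chamber depth, 1/mm.
#' @param c_mean,c_sd cylinder moments (of the C <= 0 truncated draw), D.
#' @param dC_mean,dC_sd cylinder shift under cycloplegia, D.
#' @param biometry_params named list of `mean`, `sd` and per-year `age_slope`
#'   for `AL`, `Km`, `ACD`, `LT`, `CCT`, `IOP`, plus `al_s_slope` (mm per D
#'   of sphere residual, axial myopia) and `lens_effectivity` (fraction of
#'   crystalline-lens power effective at the corneal plane in the reduced-eye
#'   consistency relation).
#' @param eye_corr within-subject (fellow-eye) Gaussian-copula correlation.
#' @param missing_rate fraction of biometry cells blanked by
#'   [inject_missingness()]; 0 disables.
#' @param seed default seed used when [generate_cohort()] is called without
#'   one.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_eyes = 306, age_range = c(4, 15),
                          s_mean = -1.53, s_sd = 2.17,
                          s_range = c(-7.50, 10.50), s_age_slope = -0.15,
                          dS_mean = 0.34, dS_sd = 0.53, dS_age_slope = 0.15,
                          dS_lens_LT = 2.2, dS_lens_ACD = 2.2,
                          c_mean = -0.87, c_sd = 0.75,
                          dC_mean = -0.03, dC_sd = 0.30,
                          biometry_params = NULL,
                          eye_corr = 0.8, missing_rate = 0, seed = 1L) {
  if (n_eyes %% 2 != 0) stop("n_eyes must be even (two eyes per subject)")
  if (any(c(s_sd, c_sd, dC_sd) <= 0) || dS_sd < 0)
    stop("all SDs must be positive")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  if (eye_corr < 0 || eye_corr > 1) stop("eye_corr must be in [0, 1]")
  mid <- mean(age_range)
  if (dS_age_slope * (age_range[2] - mid) >= 1)
    stop("dS_age_slope too steep: mean shift factor must stay positive")
  bp <- list(
    AL  = list(mean = 23.6, sd = 0.45, age_slope = 0.12),
    Km  = list(mean = 43.5, sd = 1.40, age_slope = 0.00),
    ACD = list(mean = 3.60, sd = 0.25, age_slope = 0.02),
    LT  = list(mean = 3.45, sd = 0.20, age_slope = -0.015),
    CCT = list(mean = 0.55, sd = 0.035, age_slope = 0.00),
    IOP = list(mean = 15.5, sd = 2.50, age_slope = 0.00),
    al_s_slope = -0.38, lens_effectivity = 0.62)
  if (!is.null(biometry_params)) bp[names(biometry_params)] <- biometry_params
  structure(list(n_eyes = n_eyes, age_range = age_range, s_mean = s_mean,
                 s_sd = s_sd, s_range = s_range, s_age_slope = s_age_slope,
                 dS_mean = dS_mean, dS_sd = dS_sd, dS_age_slope = dS_age_slope,
                 dS_lens_LT = dS_lens_LT, dS_lens_ACD = dS_lens_ACD,
                 c_mean = c_mean, c_sd = c_sd, dC_mean = dC_mean, dC_sd = dC_sd,
                 biometry_params = bp, eye_corr = eye_corr,
                 missing_rate = missing_rate, seed = seed),
            class = "cohort_config")
}

# Moments of a normal truncated above at `upper`.
.truncnorm_moments <- function(mu, sd, upper = 0) {
  a <- (upper - mu) / sd
  lambda <- stats::dnorm(a) / stats::pnorm(a)
  m <- mu - sd * lambda
  v <- sd^2 * (1 - a * lambda - lambda^2)
  c(mean = m, sd = sqrt(pmax(v, 0)))
}

# Solve pre-truncation (mu, sd) so the upper-truncated normal has the
# requested mean and sd. Used for the cylinder marginal.
.truncnorm_calibrate <- function(target_mean, target_sd, upper = 0) {
  obj <- function(p) {
    m <- .truncnorm_moments(p[1], exp(p[2]), upper)
    (m[1] - target_mean)^2 + (m[2] - target_sd)^2
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  c(mu = fit$par[1], sd = exp(fit$par[2]))
}

# Inverse-CDF draw from an upper-truncated normal given uniforms (copula-safe).
.qtruncnorm_upper <- function(u, mu, sd, upper = 0) {
  pa <- stats::pnorm((upper - mu) / sd)
  mu + sd * stats::qnorm(u * pa)
}

# Fellow-eye latent normals: one shared subject component, correlation rho.
.eye_latents <- function(n_subj, rho) {
  zs <- stats::rnorm(n_subj)
  z <- sqrt(rho) * rep(zs, each = 2) + sqrt(1 - rho) * stats::rnorm(2 * n_subj)
  z
}

#' Generate a synthetic per-eye cohort
#'
#' Draws a seeded cohort with the statistical structure described in
#' [cohort_config()]: uniform subject ages, age-trended correlated biometry
#' (fellow eyes share a Gaussian-copula component), a non-cycloplegic sphere
#' marginal with the configured moments, and a nonnegative accommodative
#' tonus `dS` (gamma, age-declining, lens-geometry-mediated) so that
#' `cyclo_S = S + dS`. A latent crystalline-lens power consistent with the
#' reduced-eye relation (corneal power plus effectivity-scaled lens power
#' focusing at the measured axial length up to the cycloplegic refraction)
#' is recorded in `lens_power_latent`. Biometry rows violating physiologic
#' bounds are rejection-resampled.
#'
#' @param config a [cohort_config()] object.
#' @param seed integer seed; defaults to `config$seed`.
#' @return a data.frame with one row per eye: identifiers (`subject_id`,
#'   `eye_id`, `eye`), `gender` (0/1), `age`, refraction (`S`, `C`, `axis`,
#'   `SE`, `J0`, `J45`), biometry (`IOP`, `AL`, `CCT`, `ACD`, `LT`, `K1`,
#'   `K2`, `Km`), the latent columns `dS` and `lens_power_latent`, and the
#'   targets `cyclo_S`, `cyclo_C`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(as.integer(seed))
  n_subj <- config$n_eyes / 2
  n <- config$n_eyes
  mid <- mean(config$age_range)
  var_age <- diff(config$age_range)^2 / 12
  bp <- config$biometry_params
  rho <- config$eye_corr

  age <- rep(stats::runif(n_subj, config$age_range[1], config$age_range[2]),
             each = 2)
  gender <- rep(stats::rbinom(n_subj, 1, 0.5), each = 2)

  # non-cycloplegic sphere: age trend + residual with matched marginal SD
  s_res_sd <- sqrt(max(config$s_sd^2 - config$s_age_slope^2 * var_age, 1e-8))
  z_s <- .eye_latents(n_subj, rho)
  S <- config$s_mean + config$s_age_slope * (age - mid) + s_res_sd * z_s
  for (i in seq_len(200)) {           # truncate to the observed range
    bad <- S < config$s_range[1] | S > config$s_range[2]
    if (!any(bad)) break
    S[bad] <- config$s_mean + config$s_age_slope * (age[bad] - mid) +
      s_res_sd * stats::rnorm(sum(bad))
  }
  s_resid <- S - (config$s_mean + config$s_age_slope * (age - mid))

  draw_bio <- function(nm, z, s_link = 0) {
    p <- bp[[nm]]
    p$mean + p$age_slope * (age - mid) + s_link * s_resid + p$sd * z
  }
  AL  <- draw_bio("AL", .eye_latents(n_subj, rho), bp$al_s_slope)
  Km  <- draw_bio("Km", .eye_latents(n_subj, rho))
  ACD <- draw_bio("ACD", .eye_latents(n_subj, rho))
  LT  <- draw_bio("LT", .eye_latents(n_subj, rho))
  CCT <- draw_bio("CCT", .eye_latents(n_subj, rho))
  IOP <- draw_bio("IOP", .eye_latents(n_subj, rho))
  for (i in seq_len(200)) {           # physiologic rejection resampling
    bad <- !(AL > 15 & AL < 35 & CCT > 0.3 & CCT < 0.8 & ACD > 1.5 &
             ACD < 5.5 & LT > 2.5 & LT < 6 & Km > 35 & Km < 52 &
             IOP > 8 & IOP < 30 & (ACD + LT + CCT) < AL)
    if (!any(bad)) break
    nb <- sum(bad)
    AL[bad]  <- bp$AL$mean + bp$AL$age_slope * (age[bad] - mid) +
      bp$al_s_slope * s_resid[bad] + bp$AL$sd * stats::rnorm(nb)
    Km[bad]  <- bp$Km$mean + bp$Km$age_slope * (age[bad] - mid) + bp$Km$sd * stats::rnorm(nb)
    ACD[bad] <- bp$ACD$mean + bp$ACD$age_slope * (age[bad] - mid) + bp$ACD$sd * stats::rnorm(nb)
    LT[bad]  <- bp$LT$mean + bp$LT$age_slope * (age[bad] - mid) + bp$LT$sd * stats::rnorm(nb)
    CCT[bad] <- bp$CCT$mean + bp$CCT$age_slope * (age[bad] - mid) + bp$CCT$sd * stats::rnorm(nb)
    IOP[bad] <- bp$IOP$mean + bp$IOP$age_slope * (age[bad] - mid) + bp$IOP$sd * stats::rnorm(nb)
  }

  # accommodative tonus dS >= 0: multiplicative gamma, marginal moments exact
  dS <- rep(0, n)
  if (config$dS_mean > 0) {
    m_age <- 1 + config$dS_age_slope * (mid - age)
    eta <- config$dS_lens_LT * (LT - (bp$LT$mean + bp$LT$age_slope * (age - mid))) -
      config$dS_lens_ACD * (ACD - (bp$ACD$mean + bp$ACD$age_slope * (age - mid)))
    s_eta2 <- config$dS_lens_LT^2 * bp$LT$sd^2 + config$dS_lens_ACD^2 * bp$ACD$sd^2
    mean_i <- config$dS_mean * m_age * exp(eta - s_eta2 / 2)
    Em2 <- 1 + config$dS_age_slope^2 * var_age
    cv2 <- (config$dS_sd^2 + config$dS_mean^2) /
      (config$dS_mean^2 * Em2 * exp(s_eta2)) - 1
    cv2 <- max(cv2, 0)
    u <- stats::pnorm(.eye_latents(n_subj, rho))
    if (cv2 > 0) {
      shape <- 1 / cv2
      dS <- stats::qgamma(u, shape = shape, scale = mean_i * cv2)
    } else dS <- mean_i
  }
  cyclo_S <- S + dS

  # cylinder: C <= 0 with matched truncated moments, copula-correlated eyes
  cal <- .truncnorm_calibrate(config$c_mean, config$c_sd, upper = 0)
  C <- .qtruncnorm_upper(stats::pnorm(.eye_latents(n_subj, rho)),
                         cal["mu"], cal["sd"])
  cyclo_C <- pmin(0, C + config$dC_mean +
                    config$dC_sd * .eye_latents(n_subj, rho))
  axis <- stats::runif(n, 0, 180)

  # keratometric astigmatism consistent with the refractive cylinder
  dK <- pmax(0.25, -0.9 * C + 0.25 * stats::rnorm(n))
  K1 <- Km - dK / 2
  K2 <- Km + dK / 2

  # latent lens power making the cycloplegic refraction optically consistent
  lens_power_latent <- (1000 * 1.336 / AL - Km - cyclo_S) / bp$lens_effectivity

  pv <- power_vectors(C, axis)
  subject_id <- sprintf("S%04d", rep(seq_len(n_subj), each = 2))
  eye <- rep(c("OD", "OS"), n_subj)
  out <- data.frame(subject_id = subject_id,
                    eye_id = paste0(subject_id, "_", eye), eye = eye,
                    gender = gender, age = age, S = S, C = C, axis = axis,
                    SE = spherical_equivalent(S, C), J0 = pv$J0, J45 = pv$J45,
                    IOP = IOP, AL = AL, CCT = CCT, ACD = ACD, LT = LT,
                    K1 = K1, K2 = K2, Km = Km, dS = dS,
                    lens_power_latent = lens_power_latent,
                    cyclo_S = cyclo_S, cyclo_C = cyclo_C,
                    stringsAsFactors = FALSE)
  if (config$missing_rate > 0)
    out <- inject_missingness(out, config$missing_rate, seed = seed + 10000L)
  out
}

#' Blank biometry cells at random
#'
#' Independently sets each non-key biometry cell (`IOP`, `AL`, `CCT`, `ACD`,
#' `LT`, `K1`, `K2`, `Km`) to `NA` with probability `rate`. Identifiers,
#' demographics, refraction and the training target are never blanked.
#'
#' @param records a per-eye data.frame (see [generate_cohort()]).
#' @param rate blanking probability in `[0, 1)`.
#' @param seed integer seed.
#' @return the records with missing cells injected.
#' @export
inject_missingness <- function(records, rate, seed = 1L) {
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  if (rate == 0) return(records)
  set.seed(as.integer(seed))
  cols <- intersect(c("IOP", "AL", "CCT", "ACD", "LT", "K1", "K2", "Km"),
                    names(records))
  for (cl in cols) {
    blank <- stats::runif(nrow(records)) < rate
    records[[cl]][blank] <- NA_real_
  }
  records
}

#' Configuration of the synthetic accommodation-series generator
#'
#' Emulates anterior-segment OCT measurements of anterior (ACR) and
#' posterior (PCR) lens-surface curvature radii under stepwise accommodation
#' stimuli in a small sample (default 16 eyes). Curvature changes follow the
#' configured generating quadratics (accommodation demand as a quadratic in
#' the radius change); each surface's quadratic keeps its own native sign
#' convention for the radius-change axis.
#'
#' @param n_eyes number of eyes (default 16, i.e. eight subjects).
#' @param stimulus_levels accommodation stimuli, D, increasing from 0.
#' @param quad_acr,quad_pcr generating quadratic coefficients `c(a, b, c)`
#'   of `AccD = a*x^2 + b*x + c` for the anterior/posterior surface.
#' @param acr_noise_sd,pcr_noise_sd measurement noise on the radius change,
#'   mm (defaults 0.15 and 0.05).
#' @param acr0_range,pcr0_range,lt0_range physiologic ranges for the
#'   unaccommodated ACR, PCR and lens thickness, mm.
#' @param lt_slope lens-thickness increase per diopter of stimulus, mm/D.
#' @param seed default seed.
#' @return an object of class `accommodation_config`.
#' @export
accommodation_config <- function(n_eyes = 16, stimulus_levels = 0:6,
                                 quad_acr = c(0.01, -1.21, -0.02),
                                 quad_pcr = c(-2.40, 9.30, -0.60),
                                 acr_noise_sd = 0.15, pcr_noise_sd = 0.05,
                                 acr0_range = c(10, 12),
                                 pcr0_range = c(5.5, 7),
                                 lt0_range = c(3.2, 3.8),
                                 lt_slope = 0.06, seed = 1L) {
  if (any(stimulus_levels < 0) || is.unsorted(stimulus_levels, strictly = TRUE))
    stop("stimulus_levels must be nonnegative and strictly increasing")
  if (stimulus_levels[1] != 0) stop("a zero-stimulus baseline is required")
  if (acr_noise_sd < 0 || pcr_noise_sd < 0) stop("noise SDs must be >= 0")
  structure(list(n_eyes = n_eyes, stimulus_levels = stimulus_levels,
                 quad_acr = quad_acr, quad_pcr = quad_pcr,
                 acr_noise_sd = acr_noise_sd, pcr_noise_sd = pcr_noise_sd,
                 acr0_range = acr0_range, pcr0_range = pcr0_range,
                 lt0_range = lt0_range, lt_slope = lt_slope, seed = seed),
            class = "accommodation_config")
}

# Root of a*x^2 + b*x + c = y continuous with the near-zero root at y = c(0).
.quad_root_near_zero <- function(coefs, y) {
  a <- coefs[1]; b <- coefs[2]; cc <- coefs[3]
  if (abs(a) < 1e-14) return((y - cc) / b)
  disc <- b^2 - 4 * a * (cc - y)
  if (any(disc < 0))
    stop("generating quadratic has no real root for a requested stimulus")
  r1 <- (-b + sqrt(disc)) / (2 * a)
  r2 <- (-b - sqrt(disc)) / (2 * a)
  ifelse(abs(r1) <= abs(r2), r1, r2)
}

#' Generate synthetic accommodation series
#'
#' For each eye and stimulus level, the surface's radius change is the real
#' root of the generating quadratic continuous with zero (`delta_acr`,
#' `delta_pcr`, in each quadratic's native axis convention) plus Gaussian
#' measurement noise; measured radii are re-referenced to the eye's
#' zero-stimulus measurement, so radius-derived changes ([delta_radii()])
#' are exactly zero at baseline. ACR decreases and PCR decreases in
#' magnitude as the stimulus increases (noise aside), and lens thickness
#' grows linearly with stimulus.
#'
#' @param config an [accommodation_config()] object.
#' @param seed integer seed; defaults to `config$seed`.
#' @return a data.frame with columns `eye_id`, `stimulus` (D), `ACR`, `PCR`,
#'   `LT` (mm) and the generator coordinates `delta_acr`, `delta_pcr` (mm).
#' @export
generate_accommodation_series <- function(config = accommodation_config(),
                                          seed = config$seed) {
  stopifnot(inherits(config, "accommodation_config"))
  set.seed(as.integer(seed))
  ns <- length(config$stimulus_levels)
  res <- vector("list", config$n_eyes)
  for (e in seq_len(config$n_eyes)) {
    acr0 <- stats::runif(1, config$acr0_range[1], config$acr0_range[2])
    pcr0 <- stats::runif(1, config$pcr0_range[1], config$pcr0_range[2])
    lt0 <- stats::runif(1, config$lt0_range[1], config$lt0_range[2])
    da <- .quad_root_near_zero(config$quad_acr, config$stimulus_levels) +
      stats::rnorm(ns, 0, config$acr_noise_sd)
    dp <- .quad_root_near_zero(config$quad_pcr, config$stimulus_levels) +
      stats::rnorm(ns, 0, config$pcr_noise_sd)
    # ACR's quadratic runs on a signed-change axis (negative = steepening),
    # PCR's on a magnitude-decrease axis; both radii shrink with stimulus.
    acr <- acr0 + (da - da[1])
    pcr <- pcr0 - (dp - dp[1])
    res[[e]] <- data.frame(eye_id = sprintf("A%03d", e),
                           stimulus = config$stimulus_levels,
                           ACR = acr, PCR = pcr,
                           LT = lt0 + config$lt_slope * config$stimulus_levels,
                           delta_acr = da, delta_pcr = dp,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}
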