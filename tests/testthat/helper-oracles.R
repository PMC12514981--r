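# Independent direct-arithmetic oracles, transcribed straight from the
# printed formulas. They deliberately share no code with the package.

o_r <- function(Km) 337.5 / Km

o_lopt <- function(AL) AL + 0.65696 - 0.02029 * AL

o_iol_e <- function(AL, ACD, r, na = 1.336, dn = 0.333) {
  lopt <- o_lopt(AL)
  1000 * na * (na * r - dn * lopt) / ((lopt - ACD) * (na * r - dn * ACD))
}

o_iol_m <- function(AL, ACD, r, SE, na = 1.336, dn = 0.333) {
  lopt <- o_lopt(AL)
  num <- na * r - dn * lopt - 0.001 * SE * (12 * (na * r - dn * lopt) + lopt * r)
  den <- na * r - dn * ACD - 0.001 * SE * (12 * (na * r - dn * lopt) + ACD * r)
  1000 * na * num / ((lopt - ACD) * den)
}

o_fc <- function(SE) SE / (1 - 0.012 * SE)

o_rcl <- function(Km, Fc) 337.5 / (Km + Fc)

o_iol_cl <- function(AL, ACD, Km, SE)
  o_iol_e(AL, ACD, o_rcl(Km, o_fc(SE)))

o_fa <- function(F_total, LT, Fp = 9.26, nl = 1.40)
  (F_total - Fp) / (1 - (LT / 1000 / nl) * Fp)

o_thick <- function(Fa, Fp, LT, nl = 1.40)
  Fa + Fp - (LT / 1000 / nl) * Fa * Fp

o_ra <- function(Fa, nl = 1.40, na = 1.336) 1000 * (nl - na) / Fa

o_op_prime <- function(Fa, Fp, LT, rp, na = 1.336, nl = 1.40) {
  F_tot <- o_thick(Fa, Fp, LT, nl)
  rp - sqrt(rp^2 - (LT / 2)^2) - (na / F_tot) * Fa * (LT / 1000 / nl) * 1000
}

# physiologic biometry grid for property tests
random_biometry <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(AL = runif(n, 21, 27), ACD = runif(n, 2.6, 4.4),
             LT = runif(n, 3.0, 4.2), Km = runif(n, 39, 47),
             CCT = runif(n, 0.45, 0.65), SE = runif(n, -8, 4))
}

# minimal raw record table with exact values for feature-building checks
toy_records <- function() {
  data.frame(subject_id = c("S1", "S1", "S2"), eye_id = c("S1_OD", "S1_OS", "S2_OD"),
             gender = c(0, 0, 1), age = c(8, 8, 12),
             S = c(-2.0, -1.5, 0.5), C = c(-1.0, 0.0, -0.5),
             axis = c(90, 0, 45), IOP = c(15, 16, 14),
             AL = c(24.0, 23.0, 23.65), CCT = c(0.55, 0.50, 0.54),
             ACD = c(3.45, 3.50, 3.60), LT = c(4.0, 3.60, 3.70),
             K1 = c(42.5, 43.0, 42.8), K2 = c(43.5, 43.0, 43.2),
             Km = c(43.0, 43.0, 43.0),
             cyclo_S = c(-1.6, -1.2, 0.7), stringsAsFactors = FALSE)
}

# small configs that keep model-fitting tests quick
tiny_gbt_grid <- function()
  expand.grid(eta = c(0.1, 0.3), max_depth = c(2, 3), subsample = 1.0,
              lambda = 1)

quick_config <- function(seed = 1, ...)
  experiment_config(gbt_grid = tiny_gbt_grid(), nrounds = 60, seed = seed, ...)
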