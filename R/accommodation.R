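#' Per-stimulus lens curvature changes referenced to the relaxed eye
#'
#' For each eye, subtracts the surface radii measured at every stimulus from
#' the eye's zero-stimulus (unaccommodated) measurement, so a positive
#' change means the surface steepened (its radius shrank). The change is
#' exactly zero at baseline by construction and is never computed from a
#' non-baseline reference.
#'
#' @param series a data.frame with columns `eye_id`, `stimulus` (D), `ACR`,
#'   `PCR` (mm); every eye must include a `stimulus == 0` row.
#' @return the series with added columns `dACR` and `dPCR` (mm, positive =
#'   steepening).
#' @export
delta_radii <- function(series) {
  need <- c("eye_id", "stimulus", "ACR", "PCR")
  if (!all(need %in% names(series)))
    stop("series needs columns: ", paste(need, collapse = ", "))
  out <- series
  out$dACR <- NA_real_
  out$dPCR <- NA_real_
  for (id in unique(series$eye_id)) {
    rows <- which(series$eye_id == id)
    base <- rows[series$stimulus[rows] == 0]
    if (length(base) != 1)
      stop("eye ", id, " must have exactly one zero-stimulus baseline")
    out$dACR[rows] <- series$ACR[base] - series$ACR[rows]
    out$dPCR[rows] <- series$PCR[base] - series$PCR[rows]
  }
  out
}

#' Quadratic accommodation-curvature fit
#'
#' Least-squares fit of accommodation demand as a quadratic in the surface
#' curvature change: `AccD = a*dr^2 + b*dr + c`.
#'
#' @param deltas surface radius changes, mm.
#' @param stimuli accommodation demands, D (same length).
#' @param surface label, `"anterior"` or `"posterior"`.
#' @return an object of class `accom_fit` with coefficients `a`, `b`, `c`
#'   (D/mm^2, D/mm, D), `r2` (NA when the response is degenerate), the fit
#'   residuals and the `lm` object.
#' @export
fit_quadratic <- function(deltas, stimuli, surface = c("anterior", "posterior")) {
  surface <- match.arg(surface)
  stopifnot(length(deltas) == length(stimuli))
  if (length(unique(deltas)) < 3) {
    if (stats::var(stimuli) == 0) {
      # no curvature excursion and constant demand: the flat polynomial,
      # with the goodness of fit flagged as degenerate
      return(structure(list(a = 0, b = 0, c = stimuli[1], r2 = NA_real_,
                            surface = surface,
                            residuals = rep(0, length(stimuli)),
                            n = length(deltas), lm = NULL),
                       class = "accom_fit"))
    }
    stop("need at least 3 distinct curvature changes for a quadratic fit")
  }
  fit <- stats::lm(stimuli ~ deltas + I(deltas^2))
  cf <- stats::coef(fit)
  sst <- sum((stimuli - mean(stimuli))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else NA_real_
  structure(list(a = unname(cf[3]), b = unname(cf[2]), c = unname(cf[1]),
                 r2 = r2, surface = surface, residuals = stats::residuals(fit),
                 n = length(deltas), lm = fit),
            class = "accom_fit")
}

#' @export
coef.accom_fit <- function(object, ...)
  c(a = object$a, b = object$b, c = object$c)

#' @method print accom_fit
#' @export
print.accom_fit <- function(x, ...) {
  cat(sprintf("Quadratic accommodation fit (%s lens surface, n = %d)\n",
              x$surface, x$n))
  cat(sprintf("  AccD = %.4f*dr^2 + %.4f*dr + %.4f   (r2 = %s)\n",
              x$a, x$b, x$c,
              if (is.na(x$r2)) "degenerate" else sprintf("%.3f", x$r2)))
  cat(sprintf("  |slope at dr = 0| = %.3f D/mm; %.4f mm/D at small accommodation\n",
              slope_at_zero(x), if (x$b != 0) 1 / abs(x$b) else NA_real_))
  invisible(x)
}

#' @export
predict.accom_fit <- function(object, newdata, ...) {
  dr <- if (missing(newdata)) stats::model.frame(object$lm)$deltas else newdata
  object$a * dr^2 + object$b * dr + object$c
}

#' @export
plot.accom_fit <- function(x, ...) {
  mf <- stats::model.frame(x$lm)
  dr <- mf$deltas; y <- mf$stimuli
  graphics::plot(dr, y, xlab = "Radius change (mm)",
                 ylab = "Accommodation (D)",
                 main = sprintf("%s surface quadratic fit", x$surface), ...)
  grid_x <- seq(min(dr), max(dr), length.out = 200)
  graphics::lines(grid_x, predict(x, grid_x))
  invisible(x)
}

#' Curvature-change slope at zero accommodation
#'
#' Magnitude of the derivative of the fitted quadratic at zero curvature
#' change, i.e. `|b|` in D/mm: how many diopters of accommodation one
#' millimetre of surface steepening buys near the relaxed state.
#'
#' @param fit an [fit_quadratic()] object.
#' @return `|b|`, D/mm.
#' @export
slope_at_zero <- function(fit) {
  stopifnot(inherits(fit, "accom_fit"))
  abs(fit$b)
}

#' Radius change per diopter at small accommodation
#'
#' The reciprocal of [slope_at_zero()]: millimetres of surface steepening
#' per diopter of accommodation in the small-accommodation limit.
#'
#' @param fit an [fit_quadratic()] object.
#' @return mm/D.
#' @export
mm_per_diopter_small_acc <- function(fit) {
  b <- slope_at_zero(fit)
  if (b == 0) stop("zero slope: mm-per-diopter undefined")
  1 / b
}

#' Total crystalline-lens power from AS-OCT geometry
#'
#' Surface powers from the refraction relation
#' `F = 1000*(n_lens - n_aqueous)/radius` (both radii as positive
#' magnitudes of a biconvex lens) combined by the Gullstrand thick-lens
#' equation.
#'
#' @param ACR,PCR anterior/posterior surface radii, mm (positive).
#' @param LT lens thickness, mm.
#' @param k an [optical_constants()] object.
#' @return total lens power, D.
#' @export
lens_power_from_asoct <- function(ACR, PCR, LT, k = optical_constants()) {
  if (any(ACR <= 0) || any(PCR <= 0) || any(LT <= 0))
    stop("ACR, PCR and LT must be positive")
  dn <- 1000 * (k$n_lens - k$n_aqueous)
  thick_lens_power(dn / ACR, dn / PCR, LT, k)
}

#' Image-principal-plane offset from the lens center
#'
#' Distance from the lens center to the image principal plane of the thick
#' crystalline lens. The principal plane sits at
#' `p' = -(n'/F) * Fa * (LT/1000/n_lens) * 1000` mm from the back vertex
#' (image-side index `n'` = aqueous/vitreous index, `F` the thick-lens
#' total power), and the back vertex sits one posterior sagitta
#' `rp - sqrt(rp^2 - (LT/2)^2)` behind the lens center, so
#' `OP' = sagitta + p'` (negative = toward the cornea).
#'
#' @param Fa,Fp anterior and posterior surface powers, D (positive for the
#'   crystalline lens).
#' @param LT lens thickness, mm.
#' @param rp posterior surface radius magnitude, mm; must be at least
#'   `LT/2` for the sagitta to be real.
#' @param k an [optical_constants()] object.
#' @return signed offset, mm.
#' @export
principal_plane_offset <- function(Fa, Fp, LT, rp, k = optical_constants()) {
  if (any(rp < LT / 2)) stop("imaginary sagitta: rp must be >= LT/2")
  F_tot <- thick_lens_power(Fa, Fp, LT, k)
  if (any(F_tot == 0)) stop("zero total lens power")
  p_prime <- -(k$n_aqueous / F_tot) * Fa * (LT / 1000 / k$n_lens) * 1000
  sag <- rp - sqrt(rp^2 - (LT / 2)^2)
  sag + p_prime
}

#' Principal-plane offset over a surface-power grid
#'
#' Evaluates [principal_plane_offset()] on the Cartesian product of
#' anterior and posterior surface-power grids (rows index `Fa_grid`,
#' columns `Fp_grid`), suitable for a heat map. The offset decreases along
#' each row (increasing anterior power pulls the principal plane toward the
#' cornea) and increases along each column.
#'
#' @param Fa_grid,Fp_grid surface powers, D.
#' @param LT lens thickness, mm.
#' @param rp posterior surface radius, mm.
#' @param k an [optical_constants()] object.
#' @return matrix of offsets, mm, `length(Fa_grid)` x `length(Fp_grid)`.
#' @export
op_prime_surface <- function(Fa_grid, Fp_grid, LT, rp, k = optical_constants()) {
  if (!length(Fa_grid) || !length(Fp_grid)) stop("grids must be nonempty")
  out <- outer(Fa_grid, Fp_grid,
               function(fa, fp) principal_plane_offset(fa, fp, LT, rp, k))
  dimnames(out) <- list(Fa = signif(Fa_grid, 6), Fp = signif(Fp_grid, 6))
  out
}

#' Fit both surface quadratics to an accommodation series
#'
#' Convenience wrapper: computes baseline-referenced curvature changes
#' ([delta_radii()]) across all eyes and fits one pooled quadratic per
#' surface. Note the changes are on the steepening-positive axis, so the
#' anterior fit's linear coefficient flips sign relative to a fit on the
#' generator's native (signed radius change) axis; its magnitude -- the
#' quantity of interest -- is unchanged.
#'
#' @param series see [delta_radii()].
#' @return list with `anterior` and `posterior` [fit_quadratic()] objects.
#' @export
fit_accommodation <- function(series) {
  d <- delta_radii(series)
  list(anterior = fit_quadratic(d$dACR, d$stimulus, "anterior"),
       posterior = fit_quadratic(d$dPCR, d$stimulus, "posterior"))
}
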