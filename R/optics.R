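#' Paraxial optical constants of the schematic eye
#'
#' Bundle of refractive indices and fixed surface powers used throughout the
#' lens-feature derivation. Defaults follow the Bennett-Rabbetts model eye:
#' aqueous/vitreous index 1.336, keratometric index difference 0.333,
#' crystalline-lens index 1.40, posterior lens surface power 9.26 D, and a
#' 12 mm spectacle vertex distance.
#'
#' @param n_aqueous refractive index of aqueous and vitreous (dimensionless).
#' @param delta_n keratometric index difference used by the SRK/T formula.
#' @param n_lens refractive index of the crystalline lens; must exceed
#'   `n_aqueous` so that surface radius and surface power share a sign.
#' @param F_posterior posterior lens surface power, D.
#' @param vertex_distance spectacle vertex distance, m.
#' @return an object of class `optical_constants` (a named list).
#' @examples
#' k <- optical_constants()
#' k$n_lens - k$n_aqueous  # 0.064: the index step at each lens surface
#' @export
optical_constants <- function(n_aqueous = 1.336, delta_n = 0.333,
                              n_lens = 1.40, F_posterior = 9.26,
                              vertex_distance = 0.012) {
  vals <- c(n_aqueous, delta_n, n_lens, F_posterior, vertex_distance)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all optical constants must be finite and strictly positive")
  if (n_lens <= n_aqueous)
    stop("n_lens must exceed n_aqueous")
  structure(list(n_aqueous = n_aqueous, delta_n = delta_n, n_lens = n_lens,
                 F_posterior = F_posterior, vertex_distance = vertex_distance),
            class = "optical_constants")
}

#' Mean corneal radius of curvature from keratometry
#'
#' Inverts the keratometric relation `Km = 337.5 / r`.
#'
#' @param Km mean keratometry, D; must be positive.
#' @return corneal radius, mm.
#' @examples
#' corneal_radius(45)  # 7.5 mm
#' @export
corneal_radius <- function(Km) {
  if (any(!is.finite(Km)) || any(Km <= 0))
    stop("Km must be positive and finite")
  337.5 / Km
}

#' SRK/T corrected (optical) axial length
#'
#' Retinal-thickness correction of the measured axial length:
#' `LOPT = AL + 0.65696 - 0.02029 * AL`.
#'
#' @param AL measured axial length, mm.
#' @return corrected axial length, mm.
#' @export
corrected_axial_length <- function(AL) {
  if (any(!is.finite(AL)) || any(AL < 0))
    stop("AL must be nonnegative and finite")
  AL + 0.65696 - 0.02029 * AL
}

#' SRK/T lens power for emmetropia
#'
#' The theoretical in-the-bag lens power that would render the measured eye
#' emmetropic, with the measured anterior chamber depth standing in for the
#' effective lens position:
#' \deqn{IOL_e = \frac{1000\, n_a (n_a r - \Delta n\, LOPT)}
#'                    {(LOPT - ACD)(n_a r - \Delta n\, ACD)}}
#' where all lengths are in mm and powers in D.
#'
#' @param AL axial length, mm.
#' @param ACD anterior chamber depth, mm.
#' @param r mean corneal radius, mm (see [corneal_radius()]).
#' @param k an [optical_constants()] object.
#' @return lens power, D.
#' @export
iol_emmetropia <- function(AL, ACD, r, k = optical_constants()) {
  lopt <- corrected_axial_length(AL)
  den1 <- lopt - ACD
  den2 <- k$n_aqueous * r - k$delta_n * ACD
  if (any(den1 <= 0) || any(abs(den2) < .Machine$double.eps))
    stop("degenerate geometry: LOPT must exceed ACD and n_a*r - dn*ACD must be nonzero")
  1000 * k$n_aqueous * (k$n_aqueous * r - k$delta_n * lopt) / (den1 * den2)
}

#' SRK/T lens power retaining the eye's refractive error
#'
#' Extends [iol_emmetropia()] with the eye's (non-cycloplegic) spherical
#' equivalent `SE`, so the computed lens power reproduces the measured
#' ametropia rather than emmetropia. The correction term
#' `0.001 * SE * (12 (n_a r - dn LOPT) + LOPT r)` enters the numerator, and
#' its analogue with ACD in place of LOPT enters the denominator. At
#' `SE = 0` this reduces exactly to [iol_emmetropia()].
#'
#' @inheritParams iol_emmetropia
#' @param SE spherical equivalent, D.
#' @return lens power, D.
#' @export
iol_myopia <- function(AL, ACD, r, SE, k = optical_constants()) {
  if (any(!is.finite(SE))) stop("SE must be finite")
  lopt <- corrected_axial_length(AL)
  na <- k$n_aqueous; dn <- k$delta_n
  corr <- 0.001 * SE * (12 * (na * r - dn * lopt) + lopt * r)
  corr_acd <- 0.001 * SE * (12 * (na * r - dn * lopt) + ACD * r)
  den1 <- lopt - ACD
  den2 <- na * r - dn * ACD - corr_acd
  if (any(den1 <= 0) || any(abs(den2) < .Machine$double.eps))
    stop("degenerate geometry in ametropic SRK/T denominator")
  1000 * na * (na * r - dn * lopt - corr) / (den1 * den2)
}

#' Spectacle-to-contact-lens power conversion
#'
#' Vertex correction of a spectacle-plane power to the corneal plane:
#' `Fc = SE / (1 - 0.012 * SE)` for a 12 mm vertex distance.
#'
#' @param SE spectacle-plane spherical equivalent, D.
#' @param k an [optical_constants()] object (supplies the vertex distance).
#' @return corneal-plane power, D.
#' @export
contact_lens_power <- function(SE, k = optical_constants()) {
  den <- 1 - k$vertex_distance * SE
  if (any(!is.finite(SE)) || any(abs(den) < 1e-12))
    stop("SE at the vertex singularity (1/vertex distance)")
  SE / den
}

#' Corneal radius corrected for a superimposed contact-lens power
#'
#' Adds the contact-lens power to the keratometric corneal power and converts
#' back to a radius: `r_cl = 337.5 / (Km + Fc)`.
#'
#' @param Km mean keratometry, D.
#' @param Fc contact-lens power, D (see [contact_lens_power()]).
#' @return corrected corneal radius, mm.
#' @export
corrected_corneal_radius_cl <- function(Km, Fc) {
  s <- Km + Fc
  if (any(!is.finite(s)) || any(s <= 0))
    stop("Km + Fc must be positive")
  337.5 / s
}

#' SRK/T lens power via the contact-lens corneal correction
#'
#' Third lens-power formulation: the non-cycloplegic spherical equivalent is
#' vertex-corrected to a contact-lens power ([contact_lens_power()]), folded
#' into the corneal radius ([corrected_corneal_radius_cl()]), and the
#' emmetropic SRK/T expression ([iol_emmetropia()]) is evaluated with that
#' corrected radius.
#'
#' @inheritParams iol_myopia
#' @param Km mean keratometry, D.
#' @return lens power, D.
#' @export
iol_contact_lens <- function(AL, ACD, Km, SE, k = optical_constants()) {
  Fc <- contact_lens_power(SE, k)
  r_cl <- corrected_corneal_radius_cl(Km, Fc)
  iol_emmetropia(AL, ACD, r_cl, k)
}

#' Anterior lens surface power from total lens power (thick-lens inversion)
#'
#' Solves the Gullstrand thick-lens equation
#' `F = Fa + Fp - (LT/1000/n_lens) * Fa * Fp` for the anterior surface power:
#' \deqn{F_a = \frac{F - F_p}{1 - (LT/1000/n_L) F_p}.}
#'
#' @param F_total total lens power, D.
#' @param LT lens thickness, mm.
#' @param k an [optical_constants()] object (`F_posterior`, `n_lens`).
#' @return anterior surface power, D.
#' @export
anterior_surface_power <- function(F_total, LT, k = optical_constants()) {
  if (any(LT <= 0)) stop("LT must be positive")
  t <- LT / 1000 / k$n_lens
  den <- 1 - t * k$F_posterior
  if (any(abs(den) < 1e-12)) stop("degenerate lens: singular thick-lens denominator")
  (F_total - k$F_posterior) / den
}

#' Thick-lens recombination of two surface powers
#'
#' Gullstrand's equation `F = Fa + Fp - (LT/1000/n_lens) * Fa * Fp`; the
#' algebraic inverse of [anterior_surface_power()].
#'
#' @param Fa,Fp anterior and posterior surface powers, D.
#' @param LT lens thickness, mm.
#' @param k an [optical_constants()] object.
#' @return total lens power, D.
#' @export
thick_lens_power <- function(Fa, Fp, LT, k = optical_constants()) {
  t <- LT / 1000 / k$n_lens
  Fa + Fp - t * Fa * Fp
}

#' Surface radius from surface power
#'
#' `ra = 1000 * (n_lens - n_aqueous) / Fa`; with the default indices the
#' numerator is 64, so a 64 D surface has a 1 mm radius.
#'
#' @param Fa surface power, D; must be nonzero.
#' @param k an [optical_constants()] object.
#' @return surface radius of curvature, mm.
#' @export
anterior_radius <- function(Fa, k = optical_constants()) {
  if (any(Fa == 0)) stop("Fa must be nonzero")
  1000 * (k$n_lens - k$n_aqueous) / Fa
}

#' Power-vector components of a cylinder
#'
#' Converts negative-cylinder notation to Cartesian power vectors:
#' `J0 = -(C/2) cos 2a`, `J45 = -(C/2) sin 2a` with the axis in degrees.
#' The components satisfy `J0^2 + J45^2 = (C/2)^2`.
#'
#' @param C cylinder, D; the negative-cylinder convention (`C <= 0`) is
#'   enforced.
#' @param axis cylinder axis, degrees in `[0, 180)`.
#' @return a list with numeric components `J0` and `J45` (D).
#' @export
power_vectors <- function(C, axis) {
  if (any(C > 0)) stop("cylinder must follow the C <= 0 convention")
  if (any(axis < 0) || any(axis >= 180))
    stop("axis must lie in [0, 180) degrees")
  a <- axis * pi / 180
  list(J0 = -C / 2 * cos(2 * a), J45 = -C / 2 * sin(2 * a))
}

#' Spherical equivalent
#'
#' `SE = S + C/2`.
#'
#' @param S sphere, D.
#' @param C cylinder, D.
#' @return spherical equivalent, D.
#' @export
spherical_equivalent <- function(S, C) S + C / 2

#' All lens-derived optical features for one formulation
#'
#' Chains the SRK/T lens power of the requested variant with the thick-lens
#' inversion and the radius relation, returning every derived quantity used
#' as a model feature.
#'
#' @param AL,ACD,LT axial length, anterior chamber depth, lens thickness, mm.
#' @param Km mean keratometry, D.
#' @param SE non-cycloplegic spherical equivalent, D (ignored by the
#'   emmetropic variant).
#' @param variant `"e"` (emmetropic), `"m"` (ametropic correction) or
#'   `"cl"` (contact-lens corneal correction).
#' @param k an [optical_constants()] object.
#' @return a list: `lopt`, `r`, `Fc`, `r_cl` (NA unless `variant = "cl"`),
#'   `iol`, `Fa`, `ra`, `variant`.
#' @export
lens_derived_features <- function(AL, ACD, LT, Km, SE = 0,
                                  variant = c("e", "m", "cl"),
                                  k = optical_constants()) {
  variant <- match.arg(variant)
  r <- corneal_radius(Km)
  Fc <- r_cl <- rep(NA_real_, length(AL))
  iol <- switch(variant,
    e  = iol_emmetropia(AL, ACD, r, k),
    m  = iol_myopia(AL, ACD, r, SE, k),
    cl = {
      Fc <- contact_lens_power(SE, k)
      r_cl <- corrected_corneal_radius_cl(Km, Fc)
      iol_emmetropia(AL, ACD, r_cl, k)
    })
  Fa <- anterior_surface_power(iol, LT, k)
  ra <- anterior_radius(Fa, k)
  list(lopt = corrected_axial_length(AL), r = r, Fc = Fc, r_cl = r_cl,
       iol = iol, Fa = Fa, ra = ra, variant = variant)
}

#' @method print optical_constants
#' @export
print.optical_constants <- function(x, ...) {
  cat("Paraxial optical constants\n")
  cat(sprintf("  n_aqueous (aqueous/vitreous index): %.3f\n", x$n_aqueous))
  cat(sprintf("  delta_n (keratometric index diff) : %.3f\n", x$delta_n))
  cat(sprintf("  n_lens (crystalline lens index)   : %.3f\n", x$n_lens))
  cat(sprintf("  F_posterior (posterior surface, D): %.2f\n", x$F_posterior))
  cat(sprintf("  vertex_distance (m)               : %.3f\n", x$vertex_distance))
  invisible(x)
}
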