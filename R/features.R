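#' Vitreous chamber depth from axial segment lengths
#'
#' The axial anatomy partitions the axial length into cornea, anterior
#' chamber, lens and vitreous: `VCD = AL - CCT - ACD - LT`.
#'
#' @param AL axial length, mm.
#' @param CCT central corneal thickness, mm.
#' @param ACD anterior chamber depth, mm.
#' @param LT lens thickness, mm.
#' @return vitreous chamber depth, mm (strictly positive).
#' @export
derive_vcd <- function(AL, CCT, ACD, LT) {
  vcd <- AL - CCT - ACD - LT
  if (any(!is.finite(vcd)) || any(vcd <= 0))
    stop("inconsistent biometry: AL must exceed CCT + ACD + LT")
  vcd
}

#' Feature column sets of the four prediction models
#'
#' The control model uses traditional ocular features only; each
#' experimental model augments it with anterior-segment lengths, the
#' variant's derived lens power and anterior-surface quantities, and the
#' associated axial ratios.
#'
#' @param group one of `"control"`, `"IOLe"`, `"IOLm"`, `"IOLcl"`.
#' @return character vector of feature column names.
#' @export
feature_columns <- function(group = c("control", "IOLe", "IOLm", "IOLcl")) {
  group <- match.arg(group)
  ctrl <- c("gender", "age", "S", "IOP", "AL", "CCT", "IOP_over_CCT",
            "AL_over_CCT", "K1", "K2", "Km", "r", "AL_over_CR", "VCD")
  if (group == "control") return(ctrl)
  c(ctrl, "ACD", "LT", "IOL", "Fa", "AL_over_ACD", "AL_over_LT",
    "AL_over_VCD", "ra", "LT_over_ra", "ACD_over_ra")
}

# rows where all the listed raw fields are present and physiologically usable
.complete_rows <- function(df, fields) {
  ok <- rep(TRUE, nrow(df))
  for (f in fields) ok <- ok & is.finite(df[[f]])
  ok
}

#' Assemble a per-eye feature table for one prediction model
#'
#' Builds the named feature columns of the requested model group from raw
#' per-eye records, deriving the lens-related quantities with the group's
#' SRK/T variant ([lens_derived_features()]). Rows whose derived values are
#' incomputable (missing inputs or degenerate geometry) keep `NA` in the
#' affected cells rather than being dropped; downstream imputation handles
#' them.
#'
#' @param records a data.frame of raw per-eye records with columns
#'   `subject_id`, `eye_id`, `gender` (0 = male, 1 = female), `age`, `S`,
#'   `C`, `axis`, `IOP`, `AL`, `CCT`, `ACD`, `LT`, `K1`, `K2`, `Km`, and
#'   optionally the training target `cyclo_S`.
#' @param group model group; see [feature_columns()].
#' @param k an [optical_constants()] object.
#' @param cct_unit unit of the `CCT` column, `"mm"` (default) or `"um"`;
#'   micrometre input is converted to mm.
#' @return a data.frame with `subject_id`, `eye_id`, the group's feature
#'   columns (in the order of [feature_columns()]), and `cyclo_S` when
#'   present in `records`.
#' @export
build_features <- function(records, group = c("control", "IOLe", "IOLm", "IOLcl"),
                           k = optical_constants(), cct_unit = c("mm", "um")) {
  group <- match.arg(group)
  cct_unit <- match.arg(cct_unit)
  raw <- c("gender", "age", "S", "C", "IOP", "AL", "CCT", "ACD", "LT",
           "K1", "K2", "Km")
  miss <- setdiff(c(raw, "subject_id", "eye_id"), names(records))
  if (length(miss))
    stop("records lack required columns: ", paste(miss, collapse = ", "))
  g <- records$gender
  if (!all(is.na(g) | g %in% c(0, 1)))
    stop("gender must be encoded 0 (male) / 1 (female)")
  n <- nrow(records)
  cct <- if (cct_unit == "um") records$CCT / 1000 else records$CCT

  out <- data.frame(subject_id = records$subject_id,
                    eye_id = records$eye_id,
                    gender = as.numeric(g), age = records$age,
                    S = records$S, IOP = records$IOP, AL = records$AL,
                    CCT = cct, stringsAsFactors = FALSE)
  out$IOP_over_CCT <- ifelse(cct > 0, records$IOP / cct, NA_real_)
  out$AL_over_CCT  <- ifelse(cct > 0, records$AL / cct, NA_real_)
  out$K1 <- records$K1; out$K2 <- records$K2; out$Km <- records$Km
  out$r <- ifelse(is.finite(records$Km) & records$Km > 0,
                  337.5 / records$Km, NA_real_)
  out$AL_over_CR <- records$AL / out$r

  vcd <- records$AL - cct - records$ACD - records$LT
  out$VCD <- ifelse(is.finite(vcd) & vcd > 0, vcd, NA_real_)

  if (group != "control") {
    variant <- c(IOLe = "e", IOLm = "m", IOLcl = "cl")[[group]]
    se <- spherical_equivalent(records$S, records$C)
    al_safe <- ifelse(is.finite(records$AL), records$AL, 0)
    ok <- .complete_rows(records, c("AL", "ACD", "LT", "Km")) &
      is.finite(se) & records$Km > 0 & records$LT > 0 &
      corrected_axial_length(pmax(al_safe, 0)) > records$ACD
    if (variant == "cl")
      ok <- ok & (records$Km + ifelse(is.finite(se),
                  se / (1 - k$vertex_distance * se), NA_real_)) > 0
    ok[is.na(ok)] <- FALSE
    iol <- Fa <- ra <- rep(NA_real_, n)
    if (any(ok)) {
      ld <- lens_derived_features(records$AL[ok], records$ACD[ok],
                                  records$LT[ok], records$Km[ok], se[ok],
                                  variant = variant, k = k)
      iol[ok] <- ld$iol; Fa[ok] <- ld$Fa; ra[ok] <- ld$ra
    }
    out$ACD <- records$ACD
    out$LT <- records$LT
    out$IOL <- iol
    out$Fa <- Fa
    out$AL_over_ACD <- ifelse(records$ACD > 0, records$AL / records$ACD, NA_real_)
    out$AL_over_LT  <- ifelse(records$LT > 0, records$AL / records$LT, NA_real_)
    out$AL_over_VCD <- records$AL / out$VCD
    out$ra <- ra
    out$LT_over_ra  <- ifelse(ra != 0, records$LT / ra, NA_real_)
    out$ACD_over_ra <- ifelse(ra != 0, records$ACD / ra, NA_real_)
  }

  cols <- c("subject_id", "eye_id", feature_columns(group))
  out <- out[, cols]
  if ("cyclo_S" %in% names(records)) out$cyclo_S <- records$cyclo_S
  attr(out, "group") <- group
  out
}
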