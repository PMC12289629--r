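# Spectrophotometric reference assay: chlorophyll content of an 80%
# acetone leaf extract from its absorbances at 645 and 663 nm
# (Beer-Lambert, A = K C L), converted to mg per g fresh leaf via the
# extract volume and leaf mass.

#' Arnon coefficient set for 645/663 nm, 80% acetone
#'
#' The linear map from the absorbance pair to pigment concentrations
#' (mg/L): `Ca = 12.7 A663 - 2.69 A645`, `Cb = 22.9 A645 - 4.68 A663`,
#' `Ct = 20.2 A645 + 8.02 A663` at 1 cm path length. These are the
#' canonical coefficients for this wavelength pair and solvent; they are
#' exposed here so a variant set (e.g. from a national standard method)
#' can be swapped in. Note the built-in identity
#' `Ct - (Ca + Cb) = 0.01 A645 - 0.01 A663`, a residue of rounding the
#' published coefficients.
#'
#' @return 3x2 numeric matrix, rows `cla`, `clb`, `tcl`, columns
#'   `a645`, `a663`.
#' @export
arnon_coefficients <- function() {
  matrix(c(-2.69, 12.7,
           22.9, -4.68,
           20.2, 8.02),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("cla", "clb", "tcl"), c("a645", "a663")))
}

#' Pigment concentrations from extract absorbances
#'
#' Applies the Arnon linear map to the 645/663 nm absorbance pair,
#' dividing by the cuvette path length (cm). Vectorized over records.
#' Negative concentrations (possible for absorbance pairs outside the
#' pigment model) are returned as-is with a warning, so the caller can
#' flag the assay.
#'
#' @param a645,a663 Absorbances (dimensionless, >= 0).
#' @param path_length Cuvette path length in cm (default 1).
#' @param coefficients Coefficient matrix, see [arnon_coefficients()].
#' @return Data frame with columns `cla`, `clb`, `tcl` (mg/L).
#' @export
#' @examples
#' arnon_concentrations(0.3, 0.8)
arnon_concentrations <- function(a645, a663, path_length = 1,
                                 coefficients = arnon_coefficients()) {
  if (any(path_length <= 0))
    lc_stop("path length must be > 0", "invalid_assay")
  if (anyNA(c(a645, a663)) || any(c(a645, a663) < 0))
    lc_stop("absorbances must be non-negative", "invalid_assay")
  conc <- cbind(a645, a663) %*% t(coefficients) / path_length
  out <- as.data.frame(conc)
  names(out) <- rownames(coefficients)
  if (any(conc < 0))
    warning("negative concentration: absorbance pair outside the pigment model")
  out
}

#' Convert solution concentration to content per leaf mass
#'
#' `mg/g = conc (mg/L) * volume (mL) / 1000 / mass (g)`. Intermediate
#' dilution steps of the extraction protocol collapse into the final
#' volumetric-flask volume, which is all that enters the mass balance.
#'
#' @param conc Concentration in mg/L (scalar, vector or data frame).
#' @param extract_volume Final extract volume in mL (default 5).
#' @param leaf_mass Fresh leaf mass in g (the protocol weighs
#'   0.02-0.04 g).
#' @return Content in mg per g fresh leaf, same shape as `conc`.
#' @export
#' @examples
#' content_per_mass(9.353, extract_volume = 5, leaf_mass = 0.03)
content_per_mass <- function(conc, extract_volume = 5, leaf_mass) {
  if (any(extract_volume <= 0) || any(leaf_mass <= 0))
    lc_stop("extract volume and leaf mass must be > 0", "invalid_assay")
  conc * (extract_volume / 1000) / leaf_mass
}

#' Reference contents from an assay table
#'
#' Turns a table of absorbance records into the reference-contents
#' table consumed by the calibration workflow. Required columns:
#' `sample_id, a645, a663, leaf_mass_g`; optional `extract_volume_ml`
#' (default 5) and `path_length_cm` (default 1).
#'
#' @param assay Data frame of absorbance records (or a path to a
#'   delimited file, read with [utils::read.csv()]).
#' @return Data frame `sample_id, cla_mg_g, clb_mg_g, tcl_mg_g`.
#' @export
assay_to_reference <- function(assay) {
  if (is.character(assay)) assay <- utils::read.csv(assay)
  need <- c("sample_id", "a645", "a663", "leaf_mass_g")
  if (!all(need %in% names(assay)))
    lc_stop(sprintf("assay table lacks column(s): %s",
                    paste(setdiff(need, names(assay)), collapse = ", ")),
            "schema")
  vol <- assay$extract_volume_ml %||% rep(5, nrow(assay))
  len <- assay$path_length_cm %||% rep(1, nrow(assay))
  conc <- arnon_concentrations(assay$a645, assay$a663, path_length = len)
  data.frame(sample_id = assay$sample_id,
             cla_mg_g = content_per_mass(conc$cla, vol, assay$leaf_mass_g),
             clb_mg_g = content_per_mass(conc$clb, vol, assay$leaf_mass_g),
             tcl_mg_g = content_per_mass(conc$tcl, vol, assay$leaf_mass_g))
}

#' Consistency check for a reference-contents table
#'
#' Total chlorophyll should equal the a + b sum up to the small residue
#' left by coefficient rounding in the Arnon map. Used to validate
#' reference tables (including summary tables of means) before
#' calibration.
#'
#' @param ref Data frame with columns `cla_mg_g, clb_mg_g, tcl_mg_g`.
#' @param tol Absolute tolerance in mg/g (default 0.005).
#' @return `TRUE` invisibly; errors on violation.
#' @export
check_reference_consistency <- function(ref, tol = 0.005) {
  need <- c("cla_mg_g", "clb_mg_g", "tcl_mg_g")
  if (!all(need %in% names(ref)))
    lc_stop("reference table needs cla_mg_g, clb_mg_g, tcl_mg_g", "schema")
  gap <- abs(ref$tcl_mg_g - (ref$cla_mg_g + ref$clb_mg_g))
  if (any(gap > tol))
    lc_stop(sprintf("total chlorophyll inconsistent with a + b (max gap %.4f mg/g)",
                    max(gap)), "invalid_reference")
  invisible(TRUE)
}
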