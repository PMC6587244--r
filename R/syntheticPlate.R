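## Synthetic colorimetric assay plates: a linear standard curve, sample
## wells whose product concentration follows from the planted specific
## activity, zero-activity negative controls and substrate-only blanks,
## all with additive Gaussian absorbance noise.

#' Generate a synthetic assay plate
#'
#' Well absorbance = `intercept + slope x product concentration +
#' N(0, noise_sd)`. Each enzyme's product concentration (umol/ml) is the
#' exact inverse of the specific-activity formula:
#' `conc = activity_u_per_mg x protein_mg x reaction_minutes /
#' reaction_volume_ml`, so [specificActivity()] recovers the planted
#' value exactly at zero noise. Negative-control and blank wells carry
#' zero product.
#'
#' @param enzymes data.frame with columns `enzyme`, `substrate`
#'   (`"CMC"`, `"pNPC"` or `"pNPG"`), `activity_u_per_mg`.
#' @param slope,intercept standard-curve parameters (absorbance per
#'   umol/ml, and absorbance); `slope` must be > 0.
#' @param noise_sd absorbance noise SD (>= 0).
#' @param seed integer seed.
#' @param replicates wells per enzyme/control/blank (>= 2).
#' @param reaction_minutes,reaction_volume_ml,protein_mg assay
#'   configuration used to convert activity to product concentration.
#' @param standard_concs standard-curve concentrations (umol/ml);
#'   default six points from 0 to 1.2x the largest sample concentration
#'   (or to 1 if all activities are zero).
#' @return data.frame: `well`, `role` (`standard`/`sample`/`control`/
#'   `blank`), `enzyme`, `substrate`, `replicate`, `conc`, `absorbance`;
#'   the assay configuration is attached as `attr(, "config")`.
#' @export
generateAssayPlate <- function(enzymes, slope, intercept = 0,
                               noise_sd = 0, seed = 1L, replicates = 3L,
                               reaction_minutes = 10,
                               reaction_volume_ml = 0.5,
                               protein_mg = 0.001,
                               standard_concs = NULL) {
  stopifnot(all(c("enzyme", "substrate", "activity_u_per_mg")
                %in% names(enzymes)))
  assertScalarNumeric(slope, "slope")
  if (slope <= 0) stop("'slope' must be > 0", call. = FALSE)
  assertScalarNumeric(noise_sd, "noise_sd", lower = 0)
  replicates <- assertCount(replicates, "replicates", min = 2L)

  conc <- enzymes$activity_u_per_mg * protein_mg * reaction_minutes /
    reaction_volume_ml
  if (is.null(standard_concs)) {
    top <- max(conc, 0)
    standard_concs <- seq(0, if (top > 0) 1.2 * top else 1, length.out = 6)
  }

  withSeed(seed, {
    rows <- list()
    add <- function(role, enzyme, substrate, cc, nrep) {
      a <- intercept + slope * cc + rnorm(nrep, 0, noise_sd)
      rows[[length(rows) + 1L]] <<- data.frame(
        role = role, enzyme = enzyme, substrate = substrate,
        replicate = seq_len(nrep), conc = cc, absorbance = a,
        stringsAsFactors = FALSE)
    }
    for (cc in standard_concs)
      add("standard", NA_character_, NA_character_, cc, 1L)
    for (i in seq_len(nrow(enzymes)))
      add("sample", enzymes$enzyme[i], enzymes$substrate[i], conc[i],
          replicates)
    for (s in unique(enzymes$substrate)) {
      add("control", NA_character_, s, 0, replicates)
      add("blank", NA_character_, s, 0, replicates)
    }
    out <- do.call(rbind, rows)
    out <- cbind(well = sprintf("W%03d", seq_len(nrow(out))), out)
    attr(out, "config") <- list(
      slope = slope, intercept = intercept, noise_sd = noise_sd,
      replicates = replicates, reaction_minutes = reaction_minutes,
      reaction_volume_ml = reaction_volume_ml, protein_mg = protein_mg)
    out
  })
}
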