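#' Percentile-bin distribution of a grain trait
#'
#' Seed-analyzer output format: contiguous, increasing bins with the
#' percentage of grains falling in each bin (summing to 100).
#'
#' @param lower,upper numeric bin bounds in trait units; bins must be
#'   contiguous (`upper[i] == lower[i + 1]`) and increasing.
#' @param pct per-bin percentage mass, nonnegative, summing to 100.
#' @param trait trait label.
#' @return data frame of class `bin_distribution` with columns `trait`,
#'   `bin_lower`, `bin_upper`, `pct`.
#' @export
bin_distribution <- function(lower, upper, pct, trait = "trait") {
  stopifnot(length(lower) == length(upper), length(pct) == length(lower))
  if (any(upper <= lower)) stopf("bins must have upper > lower")
  if (length(lower) > 1L && any(abs(lower[-1] - upper[-length(upper)]) > 1e-9)) {
    stopf("bins must be contiguous")
  }
  if (any(pct < 0)) stopf("bin percentages must be nonnegative")
  if (abs(sum(pct) - 100) > 1e-6) {
    stopf("bin percentages must sum to 100 (got %.8f)", sum(pct))
  }
  structure(
    data.frame(trait = trait, bin_lower = lower, bin_upper = upper, pct = pct,
               stringsAsFactors = FALSE),
    class = c("bin_distribution", "data.frame")
  )
}

#' Median of a binned trait distribution
#'
#' The trait value where the cumulative percentage first reaches 50, assuming
#' mass increases linearly within the crossing bin:
#' `lower + (50 - cumulative_below) / bin_pct * (upper - lower)`. A cumulative
#' total hitting exactly 50 at a bin boundary returns that boundary.
#'
#' @param distribution a [bin_distribution()].
#' @return interpolated median in trait units.
#' @export
bin_median <- function(distribution) {
  stopifnot(inherits(distribution, "bin_distribution"))
  cum <- cumsum(distribution$pct)
  i <- which(cum >= 50 - 1e-12)[1]
  below <- cum[i] - distribution$pct[i]
  if (distribution$pct[i] <= 0) {
    stopf("cumulative percentage crosses 50 in a zero-mass bin; cannot interpolate")
  }
  distribution$bin_lower[i] +
    (50 - below) / distribution$pct[i] *
      (distribution$bin_upper[i] - distribution$bin_lower[i])
}

#' Dry matter fraction from grain moisture
#'
#' `DM = (100 - moisture) / 100`.
#'
#' @param moisture grain moisture in percent, `0 <= moisture < 100`.
#' @return dry matter fraction in (0, 1].
#' @export
dry_matter <- function(moisture) {
  if (any(moisture < 0 | moisture >= 100)) {
    stopf("moisture must satisfy 0 <= moisture < 100")
  }
  (100 - moisture) / 100
}

#' Component mass per 1000 grains
#'
#' `Trait1000 = TGW * DM * C / 100`, in g per 1000 grains: combines thousand
#' grain weight with the dry-basis concentration of a grain component
#' (protein, fat or ash) to express its absolute per-grain amount.
#'
#' @param tgw thousand grain weight (g).
#' @param dm dry matter fraction from [dry_matter()].
#' @param concentration component concentration, % dry basis.
#' @param analyte optional label; names the result Prot1000/Fat1000/Ash1000.
#' @return named numeric, g per 1000 grains.
#' @export
per_grain_mass <- function(tgw, dm, concentration, analyte = NULL) {
  if (any(tgw < 0) || any(dm < 0) || any(concentration < 0)) {
    stopf("inputs must be nonnegative")
  }
  out <- tgw * dm * concentration / 100
  if (!is.null(analyte)) names(out) <- rep(mass_trait_label(analyte, "1000"), length(out))
  out
}

#' Component mass per plant
#'
#' `TraitP = GWP * DM * C / 100`, in g per plant, from grain weight per plant.
#'
#' @param gwp grain weight per plant (g).
#' @inheritParams per_grain_mass
#' @return named numeric, g per plant.
#' @export
per_plant_mass <- function(gwp, dm, concentration, analyte = NULL) {
  if (any(gwp < 0) || any(dm < 0) || any(concentration < 0)) {
    stopf("inputs must be nonnegative")
  }
  out <- gwp * dm * concentration / 100
  if (!is.null(analyte)) names(out) <- rep(mass_trait_label(analyte, "P"), length(out))
  out
}

mass_trait_label <- function(analyte, suffix) {
  stem <- c(protein = "Prot", fat = "Fat", ash = "Ash")[tolower(analyte)]
  if (is.na(stem)) stem <- analyte
  paste0(stem, suffix)
}
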