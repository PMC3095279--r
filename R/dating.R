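# Molecular-clock dating of duplication events: T = Ks / (2 * lambda), with
# lineage-specific synonymous substitution rates.

#' Default clock rates of synonymous substitution
#'
#' Rates (lambda, substitutions per synonymous site per year) for the four
#' species shipped as defaults: Arabidopsis 1.5e-8, Rice 6.5e-9, Poplar
#' 9.1e-9, Grape 6.5e-9.
#'
#' @return `data.frame` with columns `species`, `lambda`.
#' @export
clock_rates <- function() {
  data.frame(
    species = c("Arabidopsis", "Rice", "Poplar", "Grape"),
    lambda = c(1.5e-8, 6.5e-9, 9.1e-9, 6.5e-9),
    stringsAsFactors = FALSE
  )
}

#' Look up the synonymous clock rate for a species
#'
#' @param species Species tag.
#' @param rates Rate table (`species`, `lambda`); defaults to
#'   [clock_rates()].
#' @return The rate lambda (per year).
#' @export
species_rate <- function(species, rates = clock_rates()) {
  i <- match(species, rates$species)
  if (is.na(i))
    stop("no synonymous clock rate configured for species '", species,
         "'; supply one via the rate table")
  lam <- rates$lambda[i]
  if (!is.finite(lam) || lam <= 0) stop("lambda must be > 0")
  lam
}

#' Date a duplication event from its mean Ks
#'
#' Under a strict molecular clock, `T = Ks / (2 * lambda)` years, returned
#' in Ma (millions of years). The raw value is returned; use
#' [round_half_up()] with 2 digits for table-style reporting. A mean Ks
#' above the saturation cutoff 2.0 triggers a warning but is still dated.
#'
#' @param mean_ks Mean synonymous distance (substitutions per synonymous
#'   site), `>= 0`.
#' @param lambda Synonymous substitution rate per year, `> 0`.
#' @return Age in Ma (vectorized).
#' @examples
#' date_duplication(0.2120, 9.1e-9) # ~11.65 Ma
#' @export
date_duplication <- function(mean_ks, lambda) {
  if (any(mean_ks < 0)) stop("mean_ks must be >= 0")
  if (any(lambda <= 0)) stop("lambda must be > 0")
  if (any(mean_ks > 2.0))
    warning("mean Ks > 2.0 is beyond the saturation cutoff; ",
            "date is unreliable")
  mean_ks / (2 * lambda) / 1e6
}

#' Round half-up to a fixed number of decimals
#'
#' Reporting convention for dates (e.g. 11.645 -> 11.65 Ma), unlike R's
#' banker's rounding. Non-negative input assumed.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  f <- 10^digits
  floor(x * f + 0.5) / f
}

#' Date a table of duplicated gene pairs
#'
#' Applies `T = Ks/(2*lambda)` to rows of (mean Ks, species), producing a
#' duplicated-gene table with dates rounded half-up to 2 decimals.
#'
#' @param pairs `data.frame` with columns `gene1, gene2, mean_ks, species`.
#' @param rates Rate table, defaults to [clock_rates()].
#' @return Input with an added `date_ma` column.
#' @export
date_table <- function(pairs, rates = clock_rates()) {
  lam <- vapply(pairs$species, species_rate, numeric(1), rates = rates)
  pairs$date_ma <- round_half_up(date_duplication(pairs$mean_ks, lam), 2)
  pairs
}
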