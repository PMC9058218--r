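#' Acid-base speciation at a given pH
#'
#' Molar fractions of the successive deprotonation states of a polyprotic
#' acid at a given pH, from its macroscopic pKa values. With j protons
#' removed, the unnormalized population is 10^(j*pH - sum of the first j
#' pKa); fractions are the normalized populations. Exponents are
#' accumulated in log10 space and shifted by their maximum before
#' exponentiation, so long pKa lists cannot overflow.
#'
#' Microspecies (which hydroxyl deprotonates first) are not resolved; only
#' macrostates indexed by the number of protons removed.
#'
#' @param pKa Numeric vector of pKa values. Expected strictly increasing;
#'   a warning is emitted otherwise.
#' @param pH Working pH.
#' @return An object of class `"speciation_profile"`: a data frame with
#'   columns `protons_removed` and `fraction`, with the pH stored as an
#'   attribute.
#' @examples
#' species_fractions(pKa = 8.00, pH = 7.4)       # ~80% neutral, ~20% anion
#' species_fractions(pKa = c(4.0, 9.0), pH = 6.5)
#' @export
species_fractions <- function(pKa, pH) {
  if (length(pKa) == 0) stop("no dissociation constants")
  stopifnot(is.numeric(pKa), is.numeric(pH), length(pH) == 1)
  if (is.unsorted(pKa, strictly = TRUE))
    warning("pKa values are not strictly increasing")
  # log10 unnormalized population of state j (j = 0 .. length(pKa))
  expo <- c(0, cumsum(pH - pKa))
  w <- 10^(expo - max(expo))
  f <- w / sum(w)
  structure(
    data.frame(protons_removed = seq_along(f) - 1L, fraction = f),
    pH = pH, class = c("speciation_profile", "data.frame"))
}

#' @export
print.speciation_profile <- function(x, ...) {
  cat(sprintf("<speciation_profile> pH = %.2f\n", attr(x, "pH")))
  print(data.frame(protons_removed = x$protons_removed,
                   fraction = sprintf("%.4f", x$fraction)),
        row.names = FALSE)
  invisible(x)
}

#' Dominant acid-base forms
#'
#' Selects the protonation states whose molar fraction reaches a threshold;
#' these are the forms whose pathways enter the aqueous pipeline. The most
#' populated state is always included, so the result is never empty. The
#' default threshold of 5% sits between populations the source tables
#' retain (20%) and drop (2.5%).
#'
#' @param profile A [species_fractions()] result.
#' @param threshold Minimum molar fraction (default 0.05).
#' @return Integer vector of `protons_removed` values, in decreasing order
#'   of fraction.
#' @examples
#' dominant_forms(species_fractions(c(4.4, 9.0), pH = 7.4))
#' @export
dominant_forms <- function(profile, threshold = 0.05) {
  stopifnot(inherits(profile, "speciation_profile"),
            is.numeric(threshold), threshold <= 1)
  keep <- profile$fraction >= threshold
  keep[which.max(profile$fraction)] <- TRUE
  sel <- profile[keep, ]
  sel$protons_removed[order(sel$fraction, decreasing = TRUE)]
}
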