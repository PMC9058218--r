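#' Relaxed-scan energy profile
#'
#' Total energy along an approach coordinate (e.g. the HO...X distance as
#' the radical approaches the reactive site), relative to the separated
#' reactants. Profiles are stored in approach order (decreasing distance);
#' a profile supplied with increasing coordinates is reversed, which makes
#' the downstream classification independent of traversal direction.
#'
#' @param coordinate Approach distances in pm, strictly monotone, length
#'   >= 3.
#' @param energy Energies in kJ mol^-1, relative to the reactants.
#' @param spin_label Optional spin-state label (e.g. `"singlet"`).
#' @return A data frame of class `"scan_profile"` with columns
#'   `coordinate` and `energy`.
#' @export
scan_profile <- function(coordinate, energy, spin_label = NULL) {
  if (length(coordinate) < 3) stop("scan profile needs at least 3 points")
  if (length(coordinate) != length(energy))
    stop("coordinate and energy lengths differ")
  d <- diff(coordinate)
  if (!(all(d > 0) || all(d < 0)))
    stop("scan coordinate must be strictly monotone")
  if (all(d > 0)) {  # store in approach order
    coordinate <- rev(coordinate)
    energy <- rev(energy)
  }
  structure(data.frame(coordinate = coordinate, energy = energy),
            spin_label = spin_label,
            class = c("scan_profile", "data.frame"))
}

#' Classify a relaxed scan as barrierless or activated
#'
#' A profile is `BARRIERLESS` when the energy decreases continuously along
#' the approach — every forward step may rise by at most `noise_tol`, and
#' the global maximum does not exceed the starting point by more than
#' `noise_tol`. Such channels are diffusion-controlled and are assigned the
#' solvent's diffusion rate constant downstream. Otherwise the profile is
#' `ACTIVATED`, with the barrier height max(E) - E\[1\] attached as the
#' `"barrier"` attribute.
#'
#' The classification is invariant to adding a constant to all energies
#' and to the traversal direction of the coordinate.
#'
#' @param profile A [scan_profile()].
#' @param noise_tol Noise tolerance in kJ mol^-1 (default 0.5, a
#'   chemical-accuracy noise floor for scan grids).
#' @return `"BARRIERLESS"` or `"ACTIVATED"` (character), the latter with a
#'   `"barrier"` attribute in kJ mol^-1.
#' @export
classify_scan <- function(profile, noise_tol = 0.5) {
  stopifnot(inherits(profile, "scan_profile"))
  e <- profile$energy
  monotone <- all(diff(e) <= noise_tol)
  top_first <- max(e) <= e[1] + noise_tol
  if (monotone && top_first) return("BARRIERLESS")
  structure("ACTIVATED", barrier = max(e) - e[1])
}

#' Locate the spin-crossing point between two scan profiles
#'
#' Finds where two spin-state energy profiles become degenerate (the spin
#' crossing point of two-state reactivity): both profiles are linearly
#' interpolated onto the union grid of their overlapping coordinate range,
#' and each sign change of the energy difference is refined by linear
#' interpolation between the bracketing grid points. When several
#' crossings exist, the one at the largest approach distance — the first
#' met along the approach, where spin inversion can first occur — is
#' returned; all crossings are available in the `"all_crossings"`
#' attribute. The operation is symmetric in its two arguments.
#'
#' @param profile_low,profile_high Two [scan_profile()] objects on
#'   overlapping coordinate ranges.
#' @return A list with elements `coordinate` (pm) and `energy`
#'   (kJ mol^-1), or `NULL` when the profiles do not cross.
#' @export
find_spin_crossing <- function(profile_low, profile_high) {
  stopifnot(inherits(profile_low, "scan_profile"),
            inherits(profile_high, "scan_profile"))
  lo <- range(profile_low$coordinate)
  hi <- range(profile_high$coordinate)
  left <- max(lo[1], hi[1])
  right <- min(lo[2], hi[2])
  if (left >= right) stop("scan profiles have no overlapping coordinate range")
  grid <- sort(unique(c(profile_low$coordinate, profile_high$coordinate)))
  grid <- grid[grid >= left & grid <= right]
  eA <- stats::approx(profile_low$coordinate, profile_low$energy,
                      xout = grid)$y
  eB <- stats::approx(profile_high$coordinate, profile_high$energy,
                      xout = grid)$y
  d <- eA - eB
  s <- sign(d)
  crossings <- list()
  for (i in seq_len(length(grid) - 1)) {
    if (d[i] == 0) {
      crossings[[length(crossings) + 1]] <-
        c(coordinate = grid[i], energy = eA[i])
    } else if (s[i] * s[i + 1] < 0) {
      frac <- d[i] / (d[i] - d[i + 1])
      r <- grid[i] + frac * (grid[i + 1] - grid[i])
      e <- eA[i] + frac * (eA[i + 1] - eA[i])
      crossings[[length(crossings) + 1]] <- c(coordinate = r, energy = e)
    }
  }
  if (d[length(d)] == 0)
    crossings[[length(crossings) + 1]] <-
      c(coordinate = grid[length(grid)],
        energy = eA[length(grid)])
  if (length(crossings) == 0) return(NULL)
  tab <- do.call(rbind, crossings)
  tab <- unique(as.data.frame(tab))
  best <- tab[which.max(tab$coordinate), ]  # earliest along the approach
  structure(list(coordinate = best$coordinate, energy = best$energy),
            all_crossings = tab)
}
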