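#' Generate a synthetic mechanism network
#'
#' Draws a reproducible mechanism network with the structure of a
#' polyphenol/radical system: RAF channels at every ring position, HAT
#' channels at alternating (hydroxylated) positions, and one SET-PT and
#' one SPLET two-step mechanism. Reaction free energies are drawn from
#' per-mechanism normal distributions whose defaults caricature typical
#' phenolic scavengers — HAT strongly exergonic, RAF mildly exergonic,
#' and the first (electron-loss) step of SET-PT prohibitively endergonic
#' in non-polar solvent but borderline in water. Activation energies of
#' exergonic activated channels come from a truncated normal on
#' (0, `act_max`]; a configurable fraction of channels is barrierless
#' (diffusion-controlled); a fraction of activated channels carries Eckart
#' barrier parameters (imaginary frequency and reverse barrier).
#'
#' The defaults are loose caricatures of realistic ranges, documented as
#' such, not fits to any particular compound.
#'
#' @param seed Integer seed; the single pseudo-random source is seeded
#'   once per call and the seed is recorded in the `"seed"` attribute.
#' @param n_sites Number of ring positions (>= 1).
#' @param solvent_name `"benzene"` or `"water"`.
#' @param hat_mean,hat_sd HAT delta_rG distribution, kJ mol^-1.
#' @param raf_mean,raf_sd RAF delta_rG distribution, kJ mol^-1.
#' @param set1_mean,set1_sd SET first-step delta_rG distribution; defaults
#'   +300/100 in non-polar solvent and +50/80 in water.
#' @param act_mean,act_sd,act_max Truncated-normal parameters for
#'   activation energies, kJ mol^-1.
#' @param barrierless_frac Fraction of exergonic HAT/RAF channels that are
#'   barrierless.
#' @param eckart_frac Fraction of activated channels that carry Eckart
#'   tunneling parameters.
#' @param compound Compound name recorded in the network.
#' @return A [mechanism_network()] with a `"seed"` attribute.
#' @examples
#' net <- generate_network(seed = 1, n_sites = 6)
#' nrow(net$pathways)
#' @export
generate_network <- function(seed, n_sites = 6,
                             solvent_name = c("benzene", "water"),
                             hat_mean = -100, hat_sd = 30,
                             raf_mean = -30, raf_sd = 15,
                             set1_mean = NULL, set1_sd = NULL,
                             act_mean = 40, act_sd = 20, act_max = 80,
                             barrierless_frac = 0.2, eckart_frac = 0.5,
                             compound = sprintf("synthetic-%d", seed)) {
  stopifnot(n_sites >= 1, hat_sd > 0, raf_sd > 0, act_sd > 0, act_max > 0,
            barrierless_frac >= 0, barrierless_frac <= 1,
            eckart_frac >= 0, eckart_frac <= 1)
  solvent_name <- match.arg(solvent_name)
  aqueous <- solvent_name == "water"
  if (is.null(set1_mean)) set1_mean <- if (aqueous) 50 else 300
  if (is.null(set1_sd))  set1_sd  <- if (aqueous) 80 else 100
  set.seed(seed)

  rtrunc_act <- function(n) {
    out <- numeric(n)
    for (i in seq_len(n)) {
      repeat {
        x <- stats::rnorm(1, act_mean, act_sd)
        if (x > 0 && x <= act_max) break
      }
      out[i] <- x
    }
    out
  }

  form <- compound
  rows <- list()
  add_channel <- function(mech, site, dG) {
    p <- pathway(mech, site = site, form = form, delta_rG = dG)
    if (dG < 0) {
      if (stats::runif(1) < barrierless_frac) {
        p$barrierless <- TRUE
      } else {
        p$delta_G_act <- rtrunc_act(1)
        if (stats::runif(1) < eckart_frac) {
          p$imag_freq <- stats::runif(1, 800, 2000)
          p$reverse_barrier <- p$delta_G_act - dG
        }
      }
    }
    p
  }

  # ring template: RAF at every position, OH (HAT) at alternating positions
  for (i in seq_len(n_sites))
    rows[[length(rows) + 1]] <-
      add_channel("RAF", sprintf("%d-C", i), stats::rnorm(1, raf_mean, raf_sd))
  for (i in seq(1, n_sites, by = 2))
    rows[[length(rows) + 1]] <-
      add_channel("HAT", sprintf("%d-OH", i), stats::rnorm(1, hat_mean, hat_sd))

  lam <- function() stats::runif(1, 20, 120)
  et_row <- function(id, cid, comp, step, dG) {
    pathway("ET", site = "e", form = form, delta_rG = dG,
            vertical_energy = dG + lam(), composite = comp,
            composite_id = cid, step = step, id = id)
  }
  # one SET-PT: electron loss, then barrierless proton transfer
  rows[[length(rows) + 1]] <-
    pathway("SET", site = "e", form = form,
            delta_rG = stats::rnorm(1, set1_mean, set1_sd),
            vertical_energy = NA, composite = "SET_PT",
            composite_id = "setpt", step = 1L, id = "setpt.1")
  rows[[length(rows) + 1]] <-
    pathway("PT", site = "1-OH", form = form,
            delta_rG = stats::rnorm(1, -100, 40), barrierless = TRUE,
            composite = "SET_PT", composite_id = "setpt", step = 2L,
            id = "setpt.2")
  # one SPLET: barrierless proton loss, then electron transfer
  rows[[length(rows) + 1]] <-
    pathway("SPL", site = "1-OH", form = form,
            delta_rG = stats::rnorm(1, if (aqueous) -40 else 420,
                                    if (aqueous) 50 else 60),
            barrierless = TRUE, composite = "SPLET",
            composite_id = "splet", step = 1L, id = "splet.1")
  rows[[length(rows) + 1]] <-
    et_row("splet.2", "splet", "SPLET", 2L,
           stats::rnorm(1, -30, 40))
  # give the retained SET step a vertical energy too
  paths <- do.call(rbind, rows)
  is_set <- paths$mechanism == "SET"
  paths$vertical_energy[is_set] <- paths$delta_rG[is_set] + lam()

  net <- mechanism_network(
    compound = compound,
    forms = list(species_form(form, net_charge = 0L, protons_removed = 0L,
                              molar_fraction = 1)),
    solvent = solvent(solvent_name),
    pathways = paths)
  attr(net, "seed") <- seed
  net
}

#' Generate a synthetic relaxed-scan profile
#'
#' Emulates the three scan shapes the pipeline must classify:
#' * `"BARRIERLESS"`: a monotone Morse-like descent along the approach
#'   coordinate, plus optional Gaussian noise;
#' * `"ACTIVATED"`: an interior Gaussian barrier of height `bump_height`
#'   followed by a steep descent into the product well;
#' * `"CROSSING_PAIR"`: two spin-state profiles engineered to differ by a
#'   smooth function with exactly one sign change at a recorded
#'   ground-truth coordinate (returned as the `"ground_truth"` attribute).
#'
#' @param seed Integer seed.
#' @param kind `"BARRIERLESS"`, `"ACTIVATED"` or `"CROSSING_PAIR"`.
#' @param noise_sd Gaussian noise standard deviation in kJ mol^-1 (>= 0).
#' @param r_max,r_min,grid_step Approach-coordinate grid in pm (from
#'   `r_max` down to `r_min` in steps of `grid_step`).
#' @param well_depth Depth of the product well, kJ mol^-1.
#' @param bump_height,bump_pos,bump_width Barrier parameters for
#'   `"ACTIVATED"`, kJ mol^-1 / pm / pm.
#' @param ground_truth Engineered crossing coordinate in pm for
#'   `"CROSSING_PAIR"`.
#' @return A [scan_profile()] for the single-profile kinds, or a list with
#'   elements `low` and `high` (plus a `"ground_truth"` attribute) for
#'   `"CROSSING_PAIR"`.
#' @examples
#' classify_scan(generate_scan(1, "BARRIERLESS"))
#' @export
generate_scan <- function(seed,
                          kind = c("BARRIERLESS", "ACTIVATED",
                                   "CROSSING_PAIR"),
                          noise_sd = 0, r_max = 350, r_min = 150,
                          grid_step = 5, well_depth = 150,
                          bump_height = 20, bump_pos = 260,
                          bump_width = 15, ground_truth = 236.2) {
  kind <- match.arg(kind)
  stopifnot(noise_sd >= 0, r_max > r_min, grid_step > 0)
  set.seed(seed)
  r <- seq(r_max, r_min, by = -grid_step)
  n <- length(r)
  morse <- function(r) {
    a <- 0.015
    e <- well_depth * ((1 - exp(-a * (r - r_min)))^2 - 1)
    e - e[1]
  }
  noise <- function() stats::rnorm(n, 0, noise_sd)

  if (kind == "BARRIERLESS")
    return(scan_profile(r, morse(r) + noise()))

  if (kind == "ACTIVATED") {
    bump <- bump_height * exp(-(r - bump_pos)^2 / (2 * bump_width^2))
    # product well placed far enough below the barrier top that the
    # engineered barrier height stays within ~0.1% of bump_height
    well <- -well_depth /
      (1 + exp((r - (bump_pos - 5 * bump_width)) / 8))
    return(scan_profile(r, bump + well + noise()))
  }

  # CROSSING_PAIR: high = low + delta, delta has its single root at the
  # ground-truth coordinate (second root far outside the grid)
  e_low <- morse(r) + noise()
  slope <- 0.8
  delta <- slope * (r - ground_truth) *
    (1 + 1e-3 * (r - ground_truth))
  pair <- list(low = scan_profile(r, e_low, spin_label = "singlet"),
               high = scan_profile(r, e_low + delta,
                                   spin_label = "triplet"))
  attr(pair, "ground_truth") <- ground_truth
  pair
}
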