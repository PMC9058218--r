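#' Eyring (conventional TST) bimolecular rate constant
#'
#' k = sigma * kappa * (k_B T / h) * exp(-deltaG_act / RT), at the 1 M
#' standard state. The activation free energy is taken as already referred
#' to the 1 M standard state (as in the source tables that pair deltaG_act
#' with 1 M rate constants), so no additional concentration factor is
#' applied.
#'
#' @param delta_G_act Activation free energy in kJ mol^-1.
#' @param temperature Temperature in K.
#' @param degeneracy Reaction-path degeneracy sigma (>= 1).
#' @param kappa Tunneling transmission coefficient (>= 1; 1 = classical).
#' @return Rate constant in M^-1 s^-1.
#' @examples
#' eyring_rate(0)      # prefactor only: ~6.2124e12
#' eyring_rate(34.0)   # ~6.86e6
#' @export
eyring_rate <- function(delta_G_act, temperature = 298.15,
                        degeneracy = 1L, kappa = 1) {
  stopifnot(temperature > 0, degeneracy >= 1, kappa >= 1)
  if (any(delta_G_act < 0))
    warning("negative activation energy; rate computed anyway ",
            "(barrier recrossing not modeled)")
  degeneracy * kappa * .prefactor(temperature) *
    exp(-delta_G_act * 1000 / (.codata$R * temperature))
}

#' Asymmetric Eckart barrier
#'
#' Parameterization of the one-dimensional Eckart potential used for the
#' zero-curvature (ZCT-0) tunneling correction: forward and reverse barrier
#' heights and the magnitude of the transition-state imaginary frequency,
#' which sets the barrier curvature.
#'
#' @param V_f Forward barrier in kJ mol^-1 (> 0).
#' @param V_r Reverse barrier in kJ mol^-1 (> 0).
#' @param imag_freq Imaginary frequency magnitude in cm^-1 (> 0).
#' @return An object of class `"eckart_barrier"`.
#' @export
eckart_barrier <- function(V_f, V_r, imag_freq) {
  stopifnot(V_f > 0, V_r > 0, imag_freq > 0)
  structure(list(V_f = V_f, V_r = V_r, imag_freq = imag_freq),
            class = "eckart_barrier")
}

# log(cosh(x)), overflow-safe
.logcosh <- function(x) abs(x) + log1p(exp(-2 * abs(x))) - log(2)

# Transmission probability of the asymmetric Eckart barrier at energy E
# (J/mol, measured from the reactant asymptote). Evaluated in log space so
# the hyperbolic terms cannot overflow for thick/heavy barriers.
.eckart_P <- function(E, V1, V2, hnu) {
  alpha1 <- 2 * pi * V1 / hnu
  alpha2 <- 2 * pi * V2 / hnu
  cfac <- 1 / sqrt(alpha1) + 1 / sqrt(alpha2)
  a <- 2 * sqrt(alpha1 * E / V1) / cfac
  b <- 2 * sqrt(pmax((E / V1 - 1) * alpha1 + alpha2, 0)) / cfac
  darg <- alpha1 * alpha2 - pi^2 / 4
  if (darg < 0) {
    # thin-barrier regime: all arguments are small, direct arithmetic is safe
    D <- cos(2 * sqrt(-darg))
    p <- 1 - (cosh(a - b) + D) / (cosh(a + b) + D)
  } else {
    lD <- .logcosh(2 * sqrt(darg))
    lnum <- pmax(.logcosh(a - b), lD) +
      log1p(exp(-abs(.logcosh(a - b) - lD)))
    lden <- pmax(.logcosh(a + b), lD) +
      log1p(exp(-abs(.logcosh(a + b) - lD)))
    p <- -expm1(lnum - lden)
  }
  pmin(pmax(p, 0), 1)
}

#' Eckart (ZCT-0) tunneling transmission coefficient
#'
#' Thermally averaged transmission coefficient for zero-curvature tunneling
#' through an asymmetric Eckart barrier:
#' kappa = exp(V_f/RT) * integral of P(E) exp(-E/RT) dE / RT over
#' permissible energies, with P(E) the closed-form transmission probability
#' parameterized by (V_f, V_r, imag_freq). The quadrature is adaptive with
#' relative tolerance `rel_tol`, truncated 20 RT above the forward barrier
#' with an analytic bound on the remaining tail.
#'
#' kappa is >= 1 (within the quadrature tolerance), decreases with
#' temperature and increases with the imaginary frequency at fixed barrier
#' heights; it tends to 1 in the classical (imag_freq -> 0) and
#' high-temperature limits.
#'
#' @param barrier An [eckart_barrier()].
#' @param temperature Temperature in K.
#' @param rel_tol Relative tolerance of the adaptive quadrature.
#' @return Dimensionless transmission coefficient.
#' @examples
#' eckart_kappa(eckart_barrier(30, 30, 1500))  # ~10 at 298 K
#' eckart_kappa(eckart_barrier(30, 30, 1))     # ~1: classical limit
#' @export
eckart_kappa <- function(barrier, temperature = 298.15, rel_tol = 1e-6) {
  stopifnot(inherits(barrier, "eckart_barrier"), temperature > 0)
  V1 <- barrier$V_f * 1000
  V2 <- barrier$V_r * 1000
  RT <- .codata$R * temperature
  nu <- barrier$imag_freq * .codata$c_cm          # cm^-1 -> s^-1
  hnu <- .codata$h * nu * .codata$N_A             # J/mol
  E0 <- max(0, V1 - V2)
  Emax <- V1 + 20 * RT
  g <- function(E) .eckart_P(E, V1, V2, hnu) * exp((V1 - E) / RT) / RT
  # the integrand is a sharp unimodal peak (rising tunneling probability
  # times a falling Boltzmann factor); locating the mode and splitting
  # there keeps each quadrature piece monotone
  grid <- seq(E0, Emax, length.out = 401)
  i_max <- which.max(g(grid))
  lo <- grid[max(1, i_max - 1)]
  hi <- grid[min(length(grid), i_max + 1)]
  mode <- if (lo < hi)
    stats::optimize(g, c(lo, hi), maximum = TRUE, tol = 1e-3 * RT)$maximum
  else grid[i_max]
  breaks <- sort(unique(c(E0, mode, V1, Emax)))
  lims <- Map(c, breaks[-length(breaks)], breaks[-1])
  pieces <- lapply(lims, function(lim)
    stats::integrate(g, lim[1], lim[2], rel.tol = rel_tol,
                     subdivisions = 1000L, stop.on.error = FALSE))
  val <- sum(vapply(pieces, `[[`, 0, "value"))
  err <- sum(vapply(pieces, `[[`, 0, "abs.error"))
  if (!is.finite(val) || val <= 0 || err > 1e-4 * val)
    stop("Eckart quadrature failed to converge: ",
         paste(unique(vapply(pieces, `[[`, "", "message")), collapse = "; "),
         sprintf(" (V_f = %g, V_r = %g, imag_freq = %g cm^-1, T = %g K, est. error %g)",
                 barrier$V_f, barrier$V_r, barrier$imag_freq, temperature, err))
  tail <- .eckart_P(Emax, V1, V2, hnu) * exp((V1 - Emax) / RT)
  val + tail
}

#' Rate-table row for one pathway
#'
#' Kinetic dispatch for a single (screened, retained) pathway:
#' * a reference rate constant (`k_ref`), when present and
#'   `use_reference = TRUE`, is used verbatim (method `REFERENCE`);
#' * barrierless pathways are assigned the solvent diffusion-limited rate
#'   constant (method `DIFFUSION`);
#' * electron-transfer steps (SET/ET) are treated with Marcus theory and
#'   diffusion correction (method `MARCUS`, see [et_rate()]), deriving the
#'   reorganization energy from `vertical_energy` when available and
#'   falling back to a supplied activation energy otherwise;
#' * activated pathways (HAT/RAF and activated proton transfers) get an
#'   Eyring rate with an Eckart tunneling factor when the imaginary
#'   frequency and reverse barrier are known (method `TST_ECKART`), and
#'   kappa = 1 otherwise (method `TST_PLAIN`), so table comparisons never
#'   silently mix conventions.
#'
#' @param p A one-row pathway data frame (see [pathway()]).
#' @param solvent A [solvent()].
#' @param temperature Temperature in K (defaults to the solvent's).
#' @param use_reference Use `k_ref` when available (default `TRUE`).
#' @param clip Diffusion-correction rule for electron transfer, passed to
#'   [et_rate()].
#' @return One-row data frame with columns `pathway_id`, `reaction`,
#'   `mechanism`, `site`, `form`, `degeneracy`, `secondary`, `method`,
#'   `kappa`, `delta_G_act`, `k`.
#' @export
rate_for_pathway <- function(p, solvent, temperature = solvent$temperature,
                             use_reference = TRUE,
                             clip = c("collins-kimball", "min")) {
  stopifnot(is.data.frame(p), nrow(p) == 1)
  clip <- match.arg(clip)
  row <- data.frame(pathway_id = p$id, reaction = p$reaction,
                    mechanism = p$mechanism, site = p$site, form = p$form,
                    degeneracy = p$degeneracy, secondary = p$secondary,
                    method = NA_character_, kappa = NA_real_,
                    delta_G_act = p$delta_G_act, k = NA_real_,
                    stringsAsFactors = FALSE)
  if (use_reference && !is.na(p$k_ref)) {
    row$method <- "REFERENCE"
    row$k <- p$k_ref
    return(row)
  }
  if (isTRUE(p$barrierless)) {
    row$method <- "DIFFUSION"
    row$k <- diffusion_rate(solvent, temperature = temperature)
    return(row)
  }
  if (p$mechanism %in% c("SET", "ET")) {
    k_D <- diffusion_rate(solvent, temperature = temperature)
    if (!is.na(p$vertical_energy)) {
      lam <- reorganization_energy(p$vertical_energy, p$delta_rG)
      k <- et_rate(p$delta_rG, lam, k_D, temperature = temperature,
                   clip = clip)
      row$delta_G_act <- attr(k, "delta_G_act")
    } else if (!is.na(p$delta_G_act)) {
      k_act <- .prefactor(temperature) *
        exp(-p$delta_G_act * 1000 / (.codata$R * temperature))
      k <- .diffusion_clip(k_act, k_D, clip)
    } else {
      stop("electron-transfer pathway '", p$id,
           "' has neither vertical_energy nor delta_G_act")
    }
    row$method <- "MARCUS"
    row$k <- as.numeric(k)
    return(row)
  }
  if (is.na(p$delta_G_act))
    stop("activated pathway '", p$id, "' is missing delta_G_act")
  kap <- 1
  method <- "TST_PLAIN"
  if (!is.na(p$imag_freq) && !is.na(p$reverse_barrier)) {
    kap <- eckart_kappa(eckart_barrier(p$delta_G_act, p$reverse_barrier,
                                       p$imag_freq),
                        temperature = temperature)
    method <- "TST_ECKART"
  }
  row$method <- method
  row$kappa <- kap
  # per-site rate; degeneracy is applied at aggregation
  row$k <- eyring_rate(p$delta_G_act, temperature = temperature,
                       degeneracy = 1L, kappa = kap)
  row
}

#' Rate table for a screened network
#'
#' Builds the per-pathway rate-constant table for all retained pathways of
#' a network, dispatching each row through [rate_for_pathway()]. Rows
#' sharing a `reaction` identifier (intertwined composite mechanisms that
#' reuse one elementary step) are reported once.
#'
#' @param network A [mechanism_network()].
#' @param screened Result of [screen_pathways()]; computed from `network`
#'   when omitted.
#' @inheritParams rate_for_pathway
#' @return A data frame of class `"rate_table"`; all `k` are positive and
#'   carry a `method` provenance column (`REFERENCE`, `DIFFUSION`,
#'   `MARCUS`, `TST_ECKART`, `TST_PLAIN`).
#' @examples
#' net <- load_fixture("THB_benzene")
#' pathway_rates(net)
#' @export
pathway_rates <- function(network, screened = screen_pathways(network),
                          temperature = network$solvent$temperature,
                          use_reference = TRUE,
                          clip = c("collins-kimball", "min")) {
  clip <- match.arg(clip)
  ret <- screened$retained
  ret <- ret[!duplicated(ret$reaction), , drop = FALSE]
  rows <- lapply(seq_len(nrow(ret)), function(i)
    rate_for_pathway(ret[i, ], network$solvent, temperature = temperature,
                     use_reference = use_reference, clip = clip))
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pathway_id = character(), reaction = character(),
               mechanism = character(), site = character(),
               form = character(), degeneracy = integer(),
               secondary = logical(), method = character(),
               kappa = numeric(), delta_G_act = numeric(), k = numeric())
  class(out) <- c("rate_table", "data.frame")
  out
}

#' @export
print.rate_table <- function(x, ...) {
  cat(sprintf("<rate_table> %d reactions\n", nrow(x)))
  y <- as.data.frame(x)
  y$k <- sprintf("%.3g", y$k)
  y$kappa <- ifelse(is.na(y$kappa), ".", sprintf("%.3g", y$kappa))
  print(y[, c("pathway_id", "mechanism", "site", "form", "degeneracy",
              "method", "kappa", "k")], row.names = FALSE)
  invisible(x)
}

#' Temperature dependence of a pathway rate constant
#'
#' Evaluates the rate constant of a single activated pathway over a
#' temperature grid, recomputing the Eckart transmission coefficient at
#' each temperature when the barrier is parameterized. With kappa = 1 the
#' rate is strictly increasing in temperature; the tunneling factor itself
#' decreases with temperature.
#'
#' @param p A one-row pathway data frame (activated, i.e. with
#'   `delta_G_act`).
#' @param solvent A [solvent()].
#' @param temperatures Numeric vector of temperatures in K (non-empty).
#' @return Data frame with columns `temperature` and `k`.
#' @export
temperature_profile <- function(p, solvent, temperatures) {
  if (length(temperatures) == 0) stop("empty temperature grid")
  stopifnot(is.data.frame(p), nrow(p) == 1)
  if (is.na(p$delta_G_act) || isTRUE(p$barrierless))
    stop("temperature profiles require an activated pathway")
  k <- vapply(temperatures, function(Tk)
    rate_for_pathway(p, solvent, temperature = Tk,
                     use_reference = FALSE)$k, 0)
  data.frame(temperature = temperatures, k = k)
}
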