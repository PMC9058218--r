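# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive re-derivations (direct arithmetic, fine-grid brute
# force), kept separate from the package's implementations.

# Polyprotic speciation by direct evaluation of the unnormalized 10-powers.
oracle_species_fractions <- function(pKa, pH) {
  n <- length(pKa)
  u <- numeric(n + 1)
  for (j in 0:n)
    u[j + 1] <- 10^(j * pH) / prod(10^pKa[seq_len(j)])
  u / sum(u)
}

# Thermally averaged Eckart transmission coefficient by fine-grid
# trapezoidal integration of the direct (non-log-space) integrand.
oracle_eckart_kappa <- function(V_f, V_r, imag_freq, temperature = 298.15,
                                n_grid = 2e5) {
  cst <- physical_constants()
  V1 <- V_f * 1000
  V2 <- V_r * 1000
  RT <- cst$R * temperature
  hnu <- cst$h * imag_freq * cst$c_cm * cst$N_A
  a1 <- 2 * pi * V1 / hnu
  a2 <- 2 * pi * V2 / hnu
  cf <- 1 / sqrt(a1) + 1 / sqrt(a2)
  darg <- a1 * a2 - pi^2 / 4
  D <- if (darg >= 0) cosh(2 * sqrt(darg)) else cos(2 * sqrt(-darg))
  P <- function(E) {
    a <- 2 * sqrt(a1 * E / V1) / cf
    b <- 2 * sqrt(pmax((E / V1 - 1) * a1 + a2, 0)) / cf
    1 - (cosh(a - b) + D) / (cosh(a + b) + D)
  }
  E <- seq(max(0, V1 - V2), V1 + 25 * RT, length.out = n_grid)
  g <- P(E) * exp((V1 - E) / RT) / RT
  sum((g[-1] + g[-n_grid]) / 2) * diff(E)[1]
}

# Spin-crossing location by brute-force scan of the piecewise-linear
# difference on a 0.01 pm grid, reporting the crossing at the largest
# approach distance.
oracle_crossing <- function(profile_low, profile_high, step = 0.01) {
  left <- max(min(profile_low$coordinate), min(profile_high$coordinate))
  right <- min(max(profile_low$coordinate), max(profile_high$coordinate))
  grid <- seq(left, right, by = step)
  d <- stats::approx(profile_low$coordinate, profile_low$energy,
                     xout = grid)$y -
    stats::approx(profile_high$coordinate, profile_high$energy,
                  xout = grid)$y
  s <- sign(d)
  idx <- which(s[-1] * s[-length(s)] < 0 | d[-length(d)] == 0)
  if (length(idx) == 0) return(NULL)
  max(grid[idx])
}

# Small helper: a speciation profile built directly from given fractions.
make_profile <- function(fractions, pH = 7.4) {
  structure(
    data.frame(protons_removed = seq_along(fractions) - 1L,
               fraction = fractions),
    pH = pH, class = c("speciation_profile", "data.frame"))
}
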