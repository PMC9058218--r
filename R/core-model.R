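#' Solvent description
#'
#' A solvent carries the continuum and transport properties needed by the
#' kinetic machinery: dielectric constant, viscosity, temperature, pressure,
#' and (optionally) a fixed diffusion-limited rate constant to assign to
#' barrierless pathways. The presets `"water"` and `"benzene"` use
#' epsilon = 78.3553 and 2.2706 with handbook viscosities at 298.15 K
#' (8.91e-4 and 6.04e-4 Pa s); the water preset fixes the diffusion rate
#' constant at 1.91e9 M^-1 s^-1, the value assigned to barrierless
#' radical-scavenging steps in aqueous solution.
#'
#' @param name Solvent name. `"water"` and `"benzene"` fill in defaults;
#'   any other name requires `dielectric` and `viscosity`.
#' @param dielectric Relative permittivity (> 1).
#' @param viscosity Dynamic viscosity in Pa s (> 0).
#' @param temperature Temperature in K (default 298.15).
#' @param pressure Pressure in Pa (default 101325).
#' @param diffusion_k Optional diffusion-limited rate constant in M^-1 s^-1
#'   assigned to barrierless pathways. When `NULL`, it is computed on demand
#'   from the Smoluchowski equation with default encounter radii
#'   (see [diffusion_rate()]).
#' @return An object of class `"solvent"`.
#' @examples
#' solvent("water")
#' solvent("benzene", temperature = 310)
#' @export
solvent <- function(name, dielectric = NULL, viscosity = NULL,
                    temperature = 298.15, pressure = 101325,
                    diffusion_k = NULL) {
  presets <- list(
    water   = list(dielectric = 78.3553, viscosity = 8.91e-4, diffusion_k = 1.91e9),
    benzene = list(dielectric = 2.2706,  viscosity = 6.04e-4, diffusion_k = NULL)
  )
  if (name %in% names(presets)) {
    p <- presets[[name]]
    if (is.null(dielectric)) dielectric <- p$dielectric
    if (is.null(viscosity))  viscosity  <- p$viscosity
    if (is.null(diffusion_k)) diffusion_k <- p$diffusion_k
  }
  if (is.null(dielectric) || is.null(viscosity))
    stop("unknown solvent '", name, "': supply dielectric and viscosity")
  obj <- structure(
    list(name = name, dielectric = dielectric, viscosity = viscosity,
         temperature = temperature, pressure = pressure,
         diffusion_k = diffusion_k),
    class = "solvent")
  bad <- .solvent_diagnostics(obj)
  if (length(bad)) stop(paste(bad, collapse = "; "))
  obj
}

.solvent_diagnostics <- function(s) {
  d <- character()
  if (!is.numeric(s$dielectric) || s$dielectric <= 1)
    d <- c(d, "solvent: dielectric must be > 1")
  if (!is.numeric(s$viscosity) || s$viscosity <= 0)
    d <- c(d, "solvent: viscosity must be > 0")
  if (!is.numeric(s$temperature) || s$temperature <= 0)
    d <- c(d, "solvent: temperature must be > 0")
  d
}

#' @export
print.solvent <- function(x, ...) {
  cat(sprintf("<solvent> %s: eps = %.4f, eta = %.3g Pa s, T = %.2f K, P = %g Pa\n",
              x$name, x$dielectric, x$viscosity, x$temperature, x$pressure))
  if (!is.null(x$diffusion_k))
    cat(sprintf("  diffusion rate constant: %.3g M^-1 s^-1\n", x$diffusion_k))
  invisible(x)
}

#' Acid-base form of a scavenger
#'
#' One protonation state of the antioxidant (e.g. neutral molecule,
#' monoanion). Pathways reference the form that is their reactant; in
#' aqueous aggregation the overall rate constant weights each form by its
#' molar fraction at the working pH.
#'
#' @param name Form name (free text, e.g. `"THB-OH"`, `"THB-O-"`).
#' @param net_charge Integer net charge.
#' @param protons_removed Integer >= 0, protons removed relative to the
#'   neutral form.
#' @param molar_fraction Fraction in \[0, 1\], or `NA` if to be filled by
#'   speciation.
#' @return An object of class `"species_form"` (a named list).
#' @export
species_form <- function(name, net_charge = 0L, protons_removed = 0L,
                         molar_fraction = NA_real_) {
  structure(list(name = name, net_charge = as.integer(net_charge),
                 protons_removed = as.integer(protons_removed),
                 molar_fraction = as.numeric(molar_fraction)),
            class = "species_form")
}

.pathway_cols <- c("id", "mechanism", "composite", "composite_id", "step",
                   "site", "form", "reaction", "delta_rG", "delta_G_act",
                   "degeneracy", "barrierless", "imag_freq", "reverse_barrier",
                   "vertical_energy", "k_ref", "secondary")

.mechanisms <- c("HAT", "RAF", "SET", "PT", "SPL", "ET")

#' Elementary antioxidative pathway
#'
#' One elementary channel (or one step of a two-step SPLET / SET-PT
#' mechanism) with its thermochemistry and kinetic annotations. Energies are
#' in kJ mol^-1 throughout; equivalent sites sharing one transition state
#' are expressed through `degeneracy` rather than duplicated rows.
#'
#' @param mechanism One of `"HAT"`, `"RAF"`, `"SET"`, `"PT"`, `"SPL"`,
#'   `"ET"`.
#' @param site Site label, e.g. `"2-C"` or `"1-OH,3-OH,5-OH"`.
#' @param form Name of the reactant [species_form()].
#' @param delta_rG Reaction free energy in kJ mol^-1.
#' @param delta_G_act Activation free energy in kJ mol^-1 (`NA` for
#'   barrierless or electron-transfer steps).
#' @param degeneracy Reaction-path degeneracy sigma (integer >= 1).
#' @param barrierless Logical; `TRUE` for spontaneous (diffusion-controlled)
#'   channels.
#' @param imag_freq Imaginary frequency of the transition state in cm^-1
#'   (for Eckart tunneling; `NA` if unknown).
#' @param reverse_barrier Reverse barrier in kJ mol^-1 (Eckart; `NA` if
#'   unknown).
#' @param vertical_energy Vertical electron-transfer energy in kJ mol^-1,
#'   used to derive the Marcus reorganization energy; `NA` if unknown.
#' @param composite `"SPLET"` or `"SET_PT"` when the row is one step of a
#'   two-step mechanism, otherwise `NA`.
#' @param composite_id Identifier grouping the two steps of one composite
#'   mechanism.
#' @param step Step index (1 or 2) within a composite mechanism.
#' @param id Pathway identifier; autogenerated from mechanism/site/form when
#'   omitted.
#' @param reaction Identifier of the underlying elementary reaction. Two
#'   pathway rows may share a `reaction` when two composite mechanisms
#'   intertwine through the same step; rate tables count such a reaction
#'   once. Defaults to `id`.
#' @param k_ref Reference (literature) rate constant in M^-1 s^-1, used in
#'   place of a recomputed value when available.
#' @param secondary Logical; `TRUE` when the reactant is itself a downstream
#'   radical rather than the parent scavenger.
#' @return A one-row data frame with the standard pathway columns.
#' @examples
#' pathway("HAT", site = "1-OH,3-OH,5-OH", form = "THB-OH",
#'         delta_rG = -118.7, delta_G_act = 34.0, degeneracy = 3)
#' @export
pathway <- function(mechanism, site, form, delta_rG,
                    delta_G_act = NA_real_, degeneracy = 1L,
                    barrierless = FALSE, imag_freq = NA_real_,
                    reverse_barrier = NA_real_, vertical_energy = NA_real_,
                    composite = NA_character_, composite_id = NA_character_,
                    step = NA_integer_, id = NULL, reaction = NULL,
                    k_ref = NA_real_, secondary = FALSE) {
  mechanism <- match.arg(mechanism, .mechanisms)
  if (is.null(id)) {
    id <- tolower(paste(mechanism, gsub("[^0-9A-Za-z]+", "", site), form,
                        sep = "."))
  }
  if (is.null(reaction)) reaction <- id
  data.frame(id = id, mechanism = mechanism,
             composite = as.character(composite),
             composite_id = as.character(composite_id),
             step = as.integer(step), site = site, form = form,
             reaction = reaction, delta_rG = as.numeric(delta_rG),
             delta_G_act = as.numeric(delta_G_act),
             degeneracy = as.integer(degeneracy),
             barrierless = isTRUE(barrierless),
             imag_freq = as.numeric(imag_freq),
             reverse_barrier = as.numeric(reverse_barrier),
             vertical_energy = as.numeric(vertical_energy),
             k_ref = as.numeric(k_ref), secondary = isTRUE(secondary),
             stringsAsFactors = FALSE)[, .pathway_cols]
}

#' Mechanism network of a scavenger
#'
#' The unit the pipeline operates on: one scavenger, its acid-base forms,
#' the solvent, and all candidate antioxidative pathways. Aqueous networks
#' may carry a working pH and either pKa values (from which molar fractions
#' are computed) or pre-assigned molar fractions on the forms.
#'
#' @param compound Compound name.
#' @param forms List of [species_form()] objects.
#' @param solvent A [solvent()] object.
#' @param pathways A data frame of pathway rows (see [pathway()]), or a list
#'   of such one-row data frames which are row-bound.
#' @param pH Working pH (aqueous networks), or `NA`.
#' @param pKa Numeric vector of pKa values, or `NULL`.
#' @param reference_k_overall Overall rate constant of the reference
#'   antioxidant (Trolox) in the same solvent, M^-1 s^-1; used for the
#'   relative capacity r^T.
#' @param k_overall_ref Optional literature overall rate constant for this
#'   network (pinned reference total), M^-1 s^-1.
#' @return An object of class `"mechanism_network"`.
#' @seealso [validate_network()], [screen_pathways()], [run_pipeline()]
#' @export
mechanism_network <- function(compound, forms, solvent, pathways,
                              pH = NA_real_, pKa = NULL,
                              reference_k_overall = NA_real_,
                              k_overall_ref = NA_real_) {
  if (inherits(forms, "species_form")) forms <- list(forms)
  if (is.list(pathways) && !is.data.frame(pathways))
    pathways <- do.call(rbind, pathways)
  stopifnot(is.data.frame(pathways))
  missing_cols <- setdiff(.pathway_cols, names(pathways))
  if (length(missing_cols))
    stop("pathway table lacks columns: ", paste(missing_cols, collapse = ", "))
  structure(
    list(compound = compound, forms = forms, solvent = solvent,
         pH = as.numeric(pH), pKa = if (is.null(pKa)) NULL else as.numeric(pKa),
         pathways = pathways[, .pathway_cols],
         reference_k_overall = as.numeric(reference_k_overall),
         k_overall_ref = as.numeric(k_overall_ref)),
    class = "mechanism_network")
}

#' @export
print.mechanism_network <- function(x, ...) {
  cat(sprintf("<mechanism_network> %s in %s (eps = %.4f)\n",
              x$compound, x$solvent$name, x$solvent$dielectric))
  frk <- vapply(x$forms, function(f)
    sprintf("%s (q=%+d, f=%s)", f$name, f$net_charge,
            ifelse(is.na(f$molar_fraction), "?",
                   sprintf("%.3f", f$molar_fraction))), "")
  cat("  forms:", paste(frk, collapse = ", "), "\n")
  if (!is.na(x$pH)) cat(sprintf("  pH = %.2f\n", x$pH))
  if (!is.null(x$pKa)) cat("  pKa =", paste(x$pKa, collapse = ", "), "\n")
  tab <- table(x$pathways$mechanism)
  cat(sprintf("  %d pathway rows (%s)\n", nrow(x$pathways),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  if (!is.na(x$reference_k_overall))
    cat(sprintf("  reference k_overall (Trolox): %.3g M^-1 s^-1\n",
                x$reference_k_overall))
  invisible(x)
}

#' Validate a mechanism network
#'
#' Checks every structural invariant of the domain types and returns one
#' diagnostic message per violation; an empty character vector means the
#' network is consistent. Validation never throws and never modifies the
#' network.
#'
#' Checked invariants include: solvent dielectric > 1, viscosity > 0 and
#' temperature > 0; molar fractions within \[0, 1\] and summing to ~1 when
#' all are assigned; pathway degeneracy >= 1; barrierless pathways carrying
#' no activation energy; electron-transfer steps carrying no Eckart fields;
#' every pathway's reactant form being declared; composite steps coming in
#' complete 1/2 pairs; and the aqueous-mode pairing of pH with either pKa
#' values or pre-assigned molar fractions.
#'
#' @param network A [mechanism_network()].
#' @return Character vector of diagnostics (empty if valid).
#' @export
validate_network <- function(network) {
  d <- character()
  if (!inherits(network, "mechanism_network"))
    return("not a mechanism_network object")
  d <- c(d, .solvent_diagnostics(network$solvent))

  fr <- vapply(network$forms, function(f) f$molar_fraction, 0)
  nm <- vapply(network$forms, function(f) f$name, "")
  pr <- vapply(network$forms, function(f) f$protons_removed, 0L)
  if (anyDuplicated(nm)) d <- c(d, "forms: duplicate form names")
  bad <- !is.na(fr) & (fr < 0 | fr > 1)
  if (any(bad))
    d <- c(d, sprintf("form '%s': molar fraction %g outside [0, 1]",
                      nm[bad], fr[bad]))
  if (!anyNA(fr) && length(fr) && abs(sum(fr) - 1) > 0.05)
    d <- c(d, sprintf("forms: molar fractions sum to %.3f, not 1", sum(fr)))
  if (any(pr < 0)) d <- c(d, "forms: protons_removed must be >= 0")

  p <- network$pathways
  for (i in seq_len(nrow(p))) {
    r <- p[i, ]
    if (is.na(r$degeneracy) || r$degeneracy < 1)
      d <- c(d, sprintf("pathway '%s': degeneracy must be >= 1", r$id))
    if (isTRUE(r$barrierless) && !is.na(r$delta_G_act))
      d <- c(d, sprintf("pathway '%s': barrierless but has an activation energy",
                        r$id))
    if (r$mechanism %in% c("SET", "ET") &&
        (!is.na(r$imag_freq) || !is.na(r$reverse_barrier)))
      d <- c(d, sprintf("pathway '%s': electron transfer cannot carry Eckart fields",
                        r$id))
    if (!r$form %in% nm)
      d <- c(d, sprintf("pathway '%s': reactant form '%s' not among declared forms",
                        r$id, r$form))
    if (!is.na(r$composite) && (is.na(r$step) || !r$step %in% c(1L, 2L)))
      d <- c(d, sprintf("pathway '%s': composite step must be 1 or 2", r$id))
  }
  comp <- p[!is.na(p$composite), ]
  if (nrow(comp)) {
    for (cid in unique(comp$composite_id)) {
      steps <- sort(comp$step[comp$composite_id == cid])
      if (!identical(as.integer(steps), c(1L, 2L)))
        d <- c(d, sprintf("composite '%s': expected exactly steps 1 and 2", cid))
    }
  }

  aqueous_fracs_known <- length(fr) > 0 && !anyNA(fr)
  if (!is.na(network$pH) && is.null(network$pKa) && !aqueous_fracs_known)
    d <- c(d, "aqueous network: pH given but neither pKa values nor molar fractions")
  if (is.null(network$pKa) == FALSE && is.na(network$pH))
    d <- c(d, "network: pKa given without a working pH")
  d
}
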