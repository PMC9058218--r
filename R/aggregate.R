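#' Overall rate constant of a scavenger
#'
#' Sums the per-site rate constants of all radical-consuming reactions
#' (HAT, RAF, SET, ET — the steps that actually consume the free radical;
#' proton-transfer and proton-loss steps react with hydroxide and do not
#' enter the total):
#' k_overall = sum over forms of w_f * sum over pathways of sigma_i * k_i,
#' where sigma is the reaction-path degeneracy and w_f the form's molar
#' fraction when `weight_by_fraction` is `TRUE` (aqueous convention) and 1
#' otherwise (single-form non-polar convention).
#'
#' @param rates A [pathway_rates()] table.
#' @param network The corresponding [mechanism_network()] (source of molar
#'   fractions).
#' @param policy `"all_pathways"` (default) or `"primary_only"`, which
#'   excludes pathways tagged `secondary` (downstream-radical chemistry).
#' @param weight_by_fraction Weight each form by its molar fraction.
#'   Defaults to `TRUE` for aqueous networks (pH set) and `FALSE`
#'   otherwise.
#' @return Overall rate constant in M^-1 s^-1.
#' @examples
#' net <- load_fixture("THB_benzene")
#' overall_rate(pathway_rates(net), net)  # ~3.26e8
#' @export
overall_rate <- function(rates, network,
                         policy = c("all_pathways", "primary_only"),
                         weight_by_fraction = NULL) {
  policy <- match.arg(policy)
  if (is.null(weight_by_fraction))
    weight_by_fraction <- !is.na(network$pH)
  r <- rates[rates$mechanism %in% c("HAT", "RAF", "SET", "ET"), ,
             drop = FALSE]
  if (policy == "primary_only") r <- r[!r$secondary, , drop = FALSE]
  if (nrow(r) == 0) return(NA_real_)
  if (anyNA(r$k)) stop("missing rate constant for retained pathway(s): ",
                       paste(r$pathway_id[is.na(r$k)], collapse = ", "))
  w <- rep(1, nrow(r))
  if (weight_by_fraction) {
    fr <- stats::setNames(
      vapply(network$forms, function(f) f$molar_fraction, 0),
      vapply(network$forms, function(f) f$name, ""))
    w <- fr[r$form]
    if (anyNA(w)) stop("molar fraction missing for form(s): ",
                       paste(unique(r$form[is.na(w)]), collapse = ", "))
  }
  sum(w * r$degeneracy * r$k)
}

#' Branching ratios
#'
#' Share of the overall rate carried by each unique pathway, as a
#' percentage: Gamma_i = 100 * w_i * k_i / k_overall, reported per unique
#' site so that degenerate sites each get the per-site share (three
#' equivalent sites at 22.0% each, not 66% once). The degeneracy-weighted
#' shares sum to 100%.
#'
#' @param rates A [pathway_rates()] table (restricted to the rows that
#'   entered `k_overall`).
#' @param k_overall The overall rate constant the shares refer to (> 0).
#' @param weights Optional per-row form weights (molar fractions); default
#'   1 for all rows.
#' @return Data frame with columns `pathway_id`, `mechanism`, `site`,
#'   `form`, `degeneracy` and `gamma` (percent per site).
#' @examples
#' net <- load_fixture("THB_benzene")
#' rt <- pathway_rates(net)
#' branching_ratios(rt, overall_rate(rt, net))
#' @export
branching_ratios <- function(rates, k_overall, weights = NULL) {
  if (!is.numeric(k_overall) || is.na(k_overall) || k_overall <= 0)
    stop("k_overall must be positive")
  r <- rates[rates$mechanism %in% c("HAT", "RAF", "SET", "ET"), ,
             drop = FALSE]
  if (is.null(weights)) weights <- rep(1, nrow(r))
  data.frame(pathway_id = r$pathway_id, mechanism = r$mechanism,
             site = r$site, form = r$form, degeneracy = r$degeneracy,
             gamma = 100 * weights * r$k / k_overall,
             stringsAsFactors = FALSE)
}

#' Relative antioxidative capacity
#'
#' r^T = k_overall / k_overall(reference): the overall scavenging rate
#' constant of the antioxidant normalized by that of the reference
#' compound (Trolox) under matched conditions. r^T > 1 means the compound
#' out-scavenges Trolox.
#'
#' @param k_overall Overall rate constant of the antioxidant, M^-1 s^-1.
#' @param k_ref Overall rate constant of the reference, M^-1 s^-1 (> 0).
#' @return Dimensionless ratio.
#' @examples
#' relative_activity(7.76e9, 1.94e9)  # 4.00
#' @export
relative_activity <- function(k_overall, k_ref) {
  if (!is.numeric(k_ref) || is.na(k_ref) || k_ref <= 0)
    stop("reference rate constant must be positive")
  k_overall / k_ref
}

#' Assemble an activity report
#'
#' Runs aggregation over a computed rate table under both inclusion
#' policies and collects the overall rate constants, branching ratios and
#' Trolox-relative capacity into one object.
#'
#' @param network A [mechanism_network()].
#' @param rates A [pathway_rates()] table for the network.
#' @param screened The [screen_pathways()] result (for bookkeeping
#'   counts).
#' @param policy Policy whose branching ratios are reported.
#' @param weight_by_fraction See [overall_rate()].
#' @param ref_k Reference overall rate constant; defaults to the network's
#'   `reference_k_overall`.
#' @return An object of class `"activity_report"`.
#' @export
activity_report <- function(network, rates,
                            screened = screen_pathways(network),
                            policy = c("all_pathways", "primary_only"),
                            weight_by_fraction = NULL,
                            ref_k = network$reference_k_overall) {
  policy <- match.arg(policy)
  if (is.null(weight_by_fraction))
    weight_by_fraction <- !is.na(network$pH)
  k_all <- overall_rate(rates, network, "all_pathways", weight_by_fraction)
  k_pri <- overall_rate(rates, network, "primary_only", weight_by_fraction)
  k_sel <- if (policy == "all_pathways") k_all else k_pri

  status <- "ok"
  gamma <- NULL
  if (is.na(k_sel)) {
    status <- "no favourable pathways: all candidates rejected by the exergonicity gate"
  } else {
    r <- rates[rates$mechanism %in% c("HAT", "RAF", "SET", "ET"), ,
               drop = FALSE]
    if (policy == "primary_only") r <- r[!r$secondary, , drop = FALSE]
    w <- rep(1, nrow(r))
    if (weight_by_fraction) {
      fr <- stats::setNames(
        vapply(network$forms, function(f) f$molar_fraction, 0),
        vapply(network$forms, function(f) f$name, ""))
      w <- fr[r$form]
    }
    gamma <- branching_ratios(r, k_sel, weights = w)
  }
  r_T <- if (!is.na(ref_k) && !is.na(k_sel))
    relative_activity(k_sel, ref_k) else NA_real_
  r_T_ref <- if (!is.na(ref_k) && !is.na(network$k_overall_ref))
    relative_activity(network$k_overall_ref, ref_k) else NA_real_

  structure(
    list(compound = network$compound, solvent = network$solvent$name,
         policy = policy, weight_by_fraction = weight_by_fraction,
         n_pathways = nrow(network$pathways),
         n_retained = nrow(screened$retained),
         n_rejected = nrow(screened$rejected),
         k_overall = k_sel,
         k_overall_by_policy = c(all_pathways = k_all,
                                 primary_only = k_pri),
         k_overall_ref = network$k_overall_ref,
         gamma = gamma, r_T = r_T, r_T_ref = r_T_ref,
         reference_k = ref_k, status = status, rates = rates),
    class = "activity_report")
}

#' @export
print.activity_report <- function(x, ...) {
  cat(sprintf("<activity_report> %s in %s\n", x$compound, x$solvent))
  cat(sprintf("  pathways: %d candidates, %d retained, %d rejected\n",
              x$n_pathways, x$n_retained, x$n_rejected))
  if (x$status != "ok") {
    cat("  status:", x$status, "\n")
    return(invisible(x))
  }
  # table-style rounding: 3 significant digits for k, 1 decimal for shares
  cat(sprintf("  k_overall (%s%s): %.3g M^-1 s^-1\n", x$policy,
              if (x$weight_by_fraction) ", fraction-weighted" else "",
              x$k_overall))
  if (!is.na(x$k_overall_ref))
    cat(sprintf("  k_overall (literature reference): %.3g M^-1 s^-1\n",
                x$k_overall_ref))
  if (!is.na(x$r_T))
    cat(sprintf("  r^T vs reference: %.2f\n", x$r_T))
  if (!is.null(x$gamma)) {
    g <- x$gamma
    g$gamma <- sprintf("%.1f", g$gamma)
    cat("  branching ratios (% per site):\n")
    print(g[, c("mechanism", "site", "form", "degeneracy", "gamma")],
          row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.activity_report <- function(object, ...) {
  print(object)
  cat(sprintf("  k_overall by policy: all_pathways = %.3g, primary_only = %.3g\n",
              object$k_overall_by_policy[["all_pathways"]],
              object$k_overall_by_policy[["primary_only"]]))
  invisible(object)
}
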