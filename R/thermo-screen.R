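#' Exergonicity screening of antioxidative pathways
#'
#' Applies the thermodynamic gate that selects "favourable" pathways for
#' kinetic treatment: a single-step pathway is retained iff its reaction
#' free energy is strictly negative, and a two-step mechanism (SPLET or
#' SET-PT) is retained iff *both* steps are exergonic. The inequality is
#' strict with no tolerance band: a step with delta_rG = 0 (or +2.6
#' kJ mol^-1) is rejected.
#'
#' Pathways whose reactant is itself a downstream radical are screened
#' identically; they stay tagged `secondary` so aggregation can include or
#' exclude them by policy.
#'
#' @param network A [mechanism_network()] (or a bare pathway data frame).
#' @return An object of class `"screened_pathways"`: a list with elements
#'   `retained` (pathway data frame) and `rejected` (pathway data frame
#'   with an extra `reason` column naming the offending step). The two
#'   parts partition the input rows.
#' @examples
#' net <- load_fixture("THP_benzene")
#' screen_pathways(net)
#' @export
screen_pathways <- function(network) {
  p <- if (inherits(network, "mechanism_network")) network$pathways else network
  stopifnot(is.data.frame(p))
  if (anyNA(p$delta_rG)) {
    bad <- p$id[is.na(p$delta_rG)]
    stop("pathway(s) missing delta_rG: ", paste(bad, collapse = ", "))
  }

  reason <- rep(NA_character_, nrow(p))
  keep <- rep(NA, nrow(p))

  single <- is.na(p$composite)
  keep[single] <- p$delta_rG[single] < 0
  reason[single & !keep] <- sprintf("endergonic (delta_rG = %+.1f kJ/mol)",
                                    p$delta_rG[single & !keep])

  for (cid in unique(p$composite_id[!single])) {
    idx <- which(!single & p$composite_id == cid)
    bad_steps <- idx[p$delta_rG[idx] >= 0]
    if (length(bad_steps) == 0) {
      keep[idx] <- TRUE
    } else {
      keep[idx] <- FALSE
      lab <- paste(sprintf("step %d endergonic (delta_rG = %+.1f kJ/mol)",
                           p$step[bad_steps], p$delta_rG[bad_steps]),
                   collapse = "; ")
      reason[idx] <- lab
    }
  }

  rejected <- p[!keep, , drop = FALSE]
  rejected$reason <- reason[!keep]
  structure(list(retained = p[keep, , drop = FALSE], rejected = rejected),
            class = "screened_pathways")
}

#' @export
print.screened_pathways <- function(x, ...) {
  cat(sprintf("<screened_pathways> retained %d / rejected %d\n",
              nrow(x$retained), nrow(x$rejected)))
  if (nrow(x$retained)) {
    cat("retained:\n")
    print(x$retained[, c("id", "mechanism", "site", "form", "delta_rG")],
          row.names = FALSE)
  }
  if (nrow(x$rejected)) {
    cat("rejected:\n")
    print(x$rejected[, c("id", "mechanism", "site", "form", "delta_rG", "reason")],
          row.names = FALSE)
  }
  invisible(x)
}
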