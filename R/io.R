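.na_token <- "."

.fmt <- function(x) {
  if (is.na(x)) return(.na_token)
  if (is.logical(x)) return(if (x) "TRUE" else "FALSE")
  if (is.numeric(x)) return(sprintf("%.15g", x))
  as.character(x)
}

#' Parse a rate-constant or energy literal
#'
#' Accepts plain R numerics (`"3.65e7"`) as well as the typeset scientific
#' form used in published tables (`"3.65 × 10^7"`, `"3.65 x 10^7"`,
#' `"10^9"`), returning `NA` for the missing-value token `"."` or empty
#' strings.
#'
#' @param x Character vector.
#' @return Numeric vector.
#' @examples
#' parse_quantity(c("3.65 × 10^7", "1.91e9", "."))
#' @export
parse_quantity <- function(x) {
  vapply(as.character(x), function(s) {
    s <- trimws(s)
    if (s %in% c(.na_token, "", "NA")) return(NA_real_)
    # typeset forms: "3.65 × 10^7", "3.65 x 10^7^", "10^9"
    m <- regmatches(s, regexec(
      "^([+-]?[0-9]*\\.?[0-9]+)?\\s*[×x\\*]?\\s*10\\^\\(?([+-]?[0-9]+)\\)?\\^?$",
      s))[[1]]
    if (length(m) == 3) {
      mant <- if (m[2] == "") 1 else as.numeric(m[2])
      return(mant * 10^as.numeric(m[3]))
    }
    suppressWarnings(as.numeric(s))
  }, 0, USE.NAMES = FALSE)
}

#' Write a mechanism network to a structured text file
#'
#' Serializes a network to the package's plain-text schema: a `[meta]`
#' key-value section (compound, solvent properties, pH, pKa, reference
#' rate constants), a `[forms]` table and a `[pathways]` table, both
#' tab-separated with `"."` as the missing-value token. Reals are written
#' with 15 significant digits so a write/read round trip preserves them
#' to better than 12 significant digits.
#'
#' @param network A [mechanism_network()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_network()]
#' @export
write_network <- function(network, path) {
  s <- network$solvent
  meta <- c(
    compound = network$compound, solvent = s$name,
    dielectric = .fmt(s$dielectric), viscosity = .fmt(s$viscosity),
    temperature = .fmt(s$temperature), pressure = .fmt(s$pressure),
    diffusion_k = if (is.null(s$diffusion_k)) .na_token else .fmt(s$diffusion_k),
    pH = .fmt(network$pH),
    pKa = if (is.null(network$pKa)) .na_token else
      paste(vapply(network$pKa, .fmt, ""), collapse = ","),
    reference_k_overall = .fmt(network$reference_k_overall),
    k_overall_ref = .fmt(network$k_overall_ref),
    seed = if (is.null(attr(network, "seed"))) .na_token else
      .fmt(attr(network, "seed")))
  lines <- c("# radscav mechanism network v1", "[meta]",
             sprintf("%s = %s", names(meta), meta), "", "[forms]",
             paste(c("name", "net_charge", "protons_removed",
                     "molar_fraction"), collapse = "\t"))
  for (f in network$forms)
    lines <- c(lines, paste(c(f$name, .fmt(f$net_charge),
                              .fmt(f$protons_removed),
                              .fmt(f$molar_fraction)), collapse = "\t"))
  lines <- c(lines, "", "[pathways]",
             paste(.pathway_cols, collapse = "\t"))
  p <- network$pathways
  for (i in seq_len(nrow(p)))
    lines <- c(lines, paste(vapply(.pathway_cols, function(cn)
      .fmt(p[i, cn]), ""), collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

.read_table_block <- function(lines) {
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(lines) < 2) {
    tab <- as.data.frame(matrix(character(), 0, length(header)))
    names(tab) <- header
    return(tab)
  }
  cells <- lapply(lines[-1], function(l) strsplit(l, "\t", fixed = TRUE)[[1]])
  tab <- as.data.frame(do.call(rbind, cells), stringsAsFactors = FALSE)
  names(tab) <- header
  tab
}

#' Read a mechanism network from a structured text file
#'
#' Counterpart of [write_network()]; also accepts the typeset scientific
#' notation of published tables in any numeric field (see
#' [parse_quantity()]).
#'
#' @param path File in the network schema.
#' @return A [mechanism_network()].
#' @export
read_network <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  sec <- cumsum(grepl("^\\[", lines))
  names(sec) <- sub("^\\[(.*)\\]$", "\\1", lines)
  blocks <- split(lines, sec)
  get_block <- function(name) {
    for (b in blocks) {
      if (identical(b[1], paste0("[", name, "]")))
        return(b[-1][nzchar(trimws(b[-1]))])
    }
    stop("network file lacks a [", name, "] section: ", path)
  }

  kv <- get_block("meta")
  keys <- trimws(sub("=.*$", "", kv))
  vals <- trimws(sub("^[^=]*=", "", kv))
  meta <- stats::setNames(vals, keys)
  num <- function(key) parse_quantity(meta[[key]])

  diffusion_k <- num("diffusion_k")
  sol <- solvent(meta[["solvent"]],
                 dielectric = num("dielectric"),
                 viscosity = num("viscosity"),
                 temperature = num("temperature"),
                 pressure = num("pressure"),
                 diffusion_k = if (is.na(diffusion_k)) NULL else diffusion_k)

  ft <- .read_table_block(get_block("forms"))
  forms <- lapply(seq_len(nrow(ft)), function(i)
    species_form(ft$name[i], parse_quantity(ft$net_charge[i]),
                 parse_quantity(ft$protons_removed[i]),
                 parse_quantity(ft$molar_fraction[i])))

  pt <- .read_table_block(get_block("pathways"))
  chr_cols <- c("id", "mechanism", "composite", "composite_id", "site",
                "form", "reaction")
  log_cols <- c("barrierless", "secondary")
  p <- pt
  for (cn in setdiff(.pathway_cols, c(chr_cols, log_cols)))
    p[[cn]] <- parse_quantity(pt[[cn]])
  for (cn in log_cols) p[[cn]] <- pt[[cn]] == "TRUE"
  for (cn in chr_cols)
    p[[cn]] <- ifelse(pt[[cn]] == .na_token, NA_character_, pt[[cn]])
  p$step <- as.integer(p$step)
  p$degeneracy <- as.integer(p$degeneracy)

  pKa_raw <- meta[["pKa"]]
  pKa <- if (identical(pKa_raw, .na_token)) NULL else
    parse_quantity(strsplit(pKa_raw, ",")[[1]])
  net <- mechanism_network(
    compound = meta[["compound"]], forms = forms, solvent = sol,
    pathways = p[, .pathway_cols], pH = num("pH"), pKa = pKa,
    reference_k_overall = num("reference_k_overall"),
    k_overall_ref = num("k_overall_ref"))
  if (!identical(meta[["seed"]], .na_token))
    attr(net, "seed") <- as.integer(num("seed"))
  net
}

#' Read a pathway table from CSV
#'
#' Columnar form of the pathway table with headers `mechanism`, `site`,
#' `form`, `delta_rG_kJmol`, `delta_G_act_kJmol`, `degeneracy`,
#' `barrierless`, `imag_freq_cm1` (extra standard pathway columns are
#' passed through when present).
#'
#' @param path CSV file path.
#' @return Pathway data frame with the standard columns.
#' @export
read_pathways_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("mechanism", "site", "form", "delta_rG_kJmol")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("pathway CSV lacks columns: ", paste(missing, collapse = ", "))
  opt <- function(col, default) {
    if (col %in% names(tab)) tab[[col]] else rep(default, nrow(tab))
  }
  rows <- lapply(seq_len(nrow(tab)), function(i)
    pathway(tab$mechanism[i], site = tab$site[i], form = tab$form[i],
            delta_rG = parse_quantity(tab$delta_rG_kJmol[i]),
            delta_G_act = parse_quantity(opt("delta_G_act_kJmol", NA)[i]),
            degeneracy = opt("degeneracy", 1L)[i],
            barrierless = isTRUE(as.logical(opt("barrierless", FALSE)[i])),
            imag_freq = parse_quantity(opt("imag_freq_cm1", NA)[i]),
            k_ref = parse_quantity(opt("k_ref", NA)[i]),
            secondary = isTRUE(as.logical(opt("secondary", FALSE)[i]))))
  do.call(rbind, rows)
}

#' Read a relaxed-scan profile from CSV
#'
#' Two-column CSV with headers `distance_pm` and `energy_kJmol`, plus an
#' optional `spin_label` column (constant within a file).
#'
#' @param path CSV file path.
#' @return A [scan_profile()].
#' @export
read_scan_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("distance_pm", "energy_kJmol") %in% names(tab)))
    stop("scan CSV needs columns distance_pm and energy_kJmol")
  scan_profile(tab$distance_pm, tab$energy_kJmol,
               spin_label = if ("spin_label" %in% names(tab))
                 tab$spin_label[1] else NULL)
}

.fixture_names <- c("THB_benzene", "THP_benzene", "THB_water", "THP_water",
                    "trolox_refs")

#' Bundled literature fixtures
#'
#' Mechanism networks for phloroglucinol (1,3,5-trihydroxybenzene, THB-OH)
#' and 2,4,6-trihydroxypyridine (THP-OH) scavenging the hydroxyl radical
#' in benzene and in water at pH 7.4, with published reaction free
#' energies, activation energies and rate constants encoded as reference
#' data (`k_ref` on the pathway rows; pinned overall rate constants where
#' the published total is not recomputable from the per-pathway values).
#' `"trolox_refs"` returns the Trolox reference overall rate constants
#' (benzene: 1.31e8, water: 1.94e9 M^-1 s^-1).
#'
#' @param name One of `"THB_benzene"`, `"THP_benzene"`, `"THB_water"`,
#'   `"THP_water"`, `"trolox_refs"`.
#' @return A [mechanism_network()], or a named numeric vector for
#'   `"trolox_refs"`.
#' @examples
#' load_fixture("THB_benzene")
#' load_fixture("trolox_refs")
#' @export
load_fixture <- function(name) {
  if (!name %in% .fixture_names)
    stop("unknown fixture '", name, "'; valid fixtures: ",
         paste(.fixture_names, collapse = ", "))
  if (name == "trolox_refs")
    return(c(benzene = 1.31e8, water = 1.94e9))
  path <- system.file("extdata", paste0(tolower(name), ".net"),
                      package = "radscav", mustWork = TRUE)
  read_network(path)
}

#' Run the full screening/kinetics/aggregation pipeline
#'
#' Executes screen -> rate -> aggregate on a network (or a network file)
#' and returns an [activity_report()] with a run manifest attached as the
#' `"manifest"` attribute. The manifest records package and R versions,
#' input provenance, all options, the generator seed when the network
#' carries one, and per-stage counts — enough to reproduce the run
#' exactly. With `out_dir` set, the report (TSV + JSON, with rate
#' constants rounded to 3 significant digits and branching ratios to one
#' decimal as in published tables) and the manifest (JSON) are written
#' there.
#'
#' @param x A [mechanism_network()] or the path of a network file.
#' @param policy Aggregation policy reported (both totals are always
#'   computed); see [overall_rate()].
#' @param weight_by_fraction See [overall_rate()].
#' @param use_reference Use bundled reference rate constants where
#'   available; see [rate_for_pathway()].
#' @param ref_k Reference (Trolox) overall rate constant; defaults to the
#'   network's own field.
#' @param out_dir Optional output directory.
#' @return An [activity_report()] with a `"manifest"` attribute.
#' @examples
#' run_pipeline(load_fixture("THB_benzene"))
#' @export
run_pipeline <- function(x, policy = c("all_pathways", "primary_only"),
                         weight_by_fraction = NULL, use_reference = TRUE,
                         ref_k = NULL, out_dir = NULL) {
  policy <- match.arg(policy)
  input <- if (is.character(x)) x else "<in-memory network>"
  network <- if (is.character(x)) read_network(x) else x
  stopifnot(inherits(network, "mechanism_network"))
  diags <- validate_network(network)
  if (length(diags))
    stop("invalid network:\n  ", paste(diags, collapse = "\n  "))

  screened <- screen_pathways(network)
  rates <- pathway_rates(network, screened, use_reference = use_reference)
  report <- activity_report(network, rates, screened, policy = policy,
                            weight_by_fraction = weight_by_fraction,
                            ref_k = if (is.null(ref_k))
                              network$reference_k_overall else ref_k)

  manifest <- list(
    package = "radscav",
    package_version = as.character(utils::packageVersion("radscav")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC"),
    input = input, compound = network$compound,
    solvent = network$solvent$name,
    seed = attr(network, "seed"),
    options = list(policy = policy,
                   weight_by_fraction = report$weight_by_fraction,
                   use_reference = use_reference),
    counts = list(pathways = report$n_pathways,
                  retained = report$n_retained,
                  rejected = report$n_rejected,
                  rated = nrow(rates)))
  attr(report, "manifest") <- manifest

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report(report, out_dir)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
  }
  report
}

#' Write an activity report to disk
#'
#' Emits `report.json` and `rates.tsv` (and `branching.tsv` when
#' available) in `dir`, with rate constants rounded to 3 significant
#' digits and branching ratios to one decimal, matching the formatting of
#' published kinetics tables.
#'
#' @param report An [activity_report()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rates <- as.data.frame(report$rates)
  rates$k <- signif(rates$k, 3)
  rates$kappa <- signif(rates$kappa, 3)
  utils::write.table(rates[, c("pathway_id", "mechanism", "site", "form",
                               "degeneracy", "method", "kappa", "k")],
                     file.path(dir, "rates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(report$gamma)) {
    g <- report$gamma
    g$gamma <- round(g$gamma, 1)
    utils::write.table(g, file.path(dir, "branching.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  out <- list(compound = report$compound, solvent = report$solvent,
              policy = report$policy,
              weight_by_fraction = report$weight_by_fraction,
              k_overall = signif(report$k_overall, 3),
              k_overall_by_policy = lapply(
                as.list(report$k_overall_by_policy), signif, 3),
              k_overall_ref = signif(report$k_overall_ref, 3),
              r_T = round(report$r_T, 2),
              r_T_ref = round(report$r_T_ref, 2),
              status = report$status)
  jsonlite::write_json(out, file.path(dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       na = "null")
  invisible(dir)
}
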