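# Declarative biopsy-selection pathways over (PI-RADS score, PSAD band),
# with first-match rule semantics and a mandatory default decision.

#' Construct a biopsy pathway definition
#'
#' A pathway is an ordered list of rules over the 5 x 4 grid of PI-RADS
#' score and PSAD band. Each rule names a subset of PI-RADS scores, a subset
#' of bands and a decision; the first rule matching a patient's
#' (PI-RADS, band) cell wins, and `default_decision` covers every cell no
#' rule matches, so every pathway is total.
#'
#' @param name Unique pathway name.
#' @param rules List of rules, each a list with elements `pirads` (integer
#'   subset of 1..5), `bands` (subset of [psad_band_levels], or `"all"`) and
#'   `decision` (`"biopsy"` or `"no_biopsy"`).
#' @param default_decision Decision for unmatched cells.
#' @param description Optional free-text description.
#' @return An object of class `biopsy_pathway`.
#' @examples
#' # Biopsy PI-RADS 4-5 always, PI-RADS 3 only at PSAD >= 0.20:
#' new_pathway("custom",
#'   rules = list(
#'     list(pirads = 4:5, bands = "all", decision = "biopsy"),
#'     list(pirads = 3, bands = "very_high", decision = "biopsy")),
#'   default_decision = "no_biopsy")
#' @export
new_pathway <- function(name, rules = list(), default_decision,
                        description = NULL) {
  if (!rlang::is_string(name) || !nzchar(name)) {
    rlang::abort("`name` must be a non-empty string.",
                 class = "psadpathways_config_error")
  }
  default_decision <- check_decision(default_decision, "default_decision")
  rules <- lapply(seq_along(rules), function(i) {
    r <- rules[[i]]
    where <- sprintf("rules[[%d]]", i)
    if (!is.list(r) || !all(c("pirads", "bands", "decision") %in% names(r))) {
      rlang::abort(sprintf("%s must have `pirads`, `bands` and `decision`.", where),
                   class = "psadpathways_config_error")
    }
    pr <- as.integer(r$pirads)
    if (length(pr) == 0 || anyNA(pr) || !all(pr %in% 1:5)) {
      rlang::abort(sprintf("%s$pirads: values must be PI-RADS scores in 1..5.", where),
                   class = "psadpathways_config_error")
    }
    bands <- r$bands
    if (identical(bands, "all")) bands <- psad_band_levels
    if (!all(bands %in% psad_band_levels)) {
      rlang::abort(sprintf("%s$bands: unknown band name '%s'.", where,
                           setdiff(bands, psad_band_levels)[1]),
                   class = "psadpathways_config_error")
    }
    list(pirads = sort(unique(pr)), bands = unique(bands),
         decision = check_decision(r$decision, paste0(where, "$decision")))
  })
  structure(list(name = name, rules = rules,
                 default_decision = default_decision,
                 description = description),
            class = "biopsy_pathway")
}

check_decision <- function(x, what) {
  if (!rlang::is_string(x) || !(x %in% c("biopsy", "no_biopsy"))) {
    rlang::abort(sprintf("%s must be \"biopsy\" or \"no_biopsy\".", what),
                 class = "psadpathways_config_error")
  }
  x
}

#' @export
print.biopsy_pathway <- function(x, ...) {
  cat(sprintf("<biopsy_pathway> %s\n", x$name))
  if (!is.null(x$description)) cat(" ", x$description, "\n")
  for (r in x$rules) {
    cat(sprintf("  PI-RADS {%s} x bands {%s} -> %s\n",
                paste(r$pirads, collapse = ","),
                paste(r$bands, collapse = ","), r$decision))
  }
  cat(sprintf("  otherwise -> %s\n", x$default_decision))
  invisible(x)
}

#' Decision grid of a pathway
#'
#' Expands a pathway into its full 5 x 4 decision matrix (rows: PI-RADS
#' 1..5; columns: PSAD bands), applying first-match semantics and the
#' default. Useful for inspection and as the vectorised evaluation backend.
#'
#' @param pathway A `biopsy_pathway`.
#' @return A 5 x 4 character matrix of `"biopsy"` / `"no_biopsy"`.
#' @export
pathway_grid <- function(pathway) {
  stopifnot(inherits(pathway, "biopsy_pathway"))
  grid <- matrix(NA_character_, nrow = 5, ncol = 4,
                 dimnames = list(pirads = 1:5, band = psad_band_levels))
  for (r in pathway$rules) {
    cells <- as.matrix(expand.grid(r$pirads, match(r$bands, psad_band_levels)))
    unset <- is.na(grid[cells])
    grid[cells[unset, , drop = FALSE]] <- r$decision
  }
  grid[is.na(grid)] <- pathway$default_decision
  grid
}

#' The four built-in diagnostic pathways
#'
#' * `biopsy_all`: biopsy every man with suspected cancer, irrespective of
#'   MRI findings or PSAD (the comparator arm).
#' * `mri_focused`: biopsy iff PI-RADS >= 3; PSAD not considered.
#' * `risk_low` (risk-based, low threshold): biopsy PI-RADS 1-2 only at
#'   PSAD >= 0.20, PI-RADS 3 at PSAD >= 0.10, PI-RADS 4-5 always.
#' * `risk_high` (risk-based, high threshold): biopsy PI-RADS 3 only at
#'   PSAD >= 0.20, PI-RADS 4-5 always, PI-RADS 1-2 never.
#'
#' @return Named list of four `biopsy_pathway` objects, in the order above.
#' @export
builtin_pathways <- function() {
  list(
    biopsy_all = new_pathway(
      "biopsy_all", rules = list(), default_decision = "biopsy",
      description = "Biopsy all men irrespective of MRI findings or PSAD"),
    mri_focused = new_pathway(
      "mri_focused",
      rules = list(list(pirads = 3:5, bands = "all", decision = "biopsy")),
      default_decision = "no_biopsy",
      description = "MRI-focused: biopsy iff PI-RADS >= 3"),
    risk_low = new_pathway(
      "risk_low",
      rules = list(
        list(pirads = 1:2, bands = "very_high", decision = "biopsy"),
        list(pirads = 3, bands = c("intermediate", "high", "very_high"),
             decision = "biopsy"),
        list(pirads = 4:5, bands = "all", decision = "biopsy")),
      default_decision = "no_biopsy",
      description = "Risk-based, low threshold: PI-RADS 1-2 at PSAD >= 0.20, PI-RADS 3 at PSAD >= 0.10, PI-RADS 4-5 always"),
    risk_high = new_pathway(
      "risk_high",
      rules = list(
        list(pirads = 3, bands = "very_high", decision = "biopsy"),
        list(pirads = 4:5, bands = "all", decision = "biopsy")),
      default_decision = "no_biopsy",
      description = "Risk-based, high threshold: PI-RADS 3 at PSAD >= 0.20, PI-RADS 4-5 always"))
}

#' Biopsy decision for a single patient
#'
#' @param pathway A `biopsy_pathway`.
#' @param pirads PI-RADS score (1..5).
#' @param psad PSAD in ng/mL^2.
#' @return `"biopsy"` or `"no_biopsy"`.
#' @export
decide_biopsy <- function(pathway, pirads, psad) {
  stopifnot(length(pirads) == 1, length(psad) == 1)
  band <- as.character(assign_psad_band(psad))
  if (!(pirads %in% 1:5)) {
    rlang::abort("`pirads` must be in 1..5.", class = "psadpathways_validation_error")
  }
  pathway_grid(pathway)[pirads, band]
}

#' Apply a pathway to a cohort
#'
#' Evaluates the pathway's rules for every patient. A pure, deterministic
#' function of the pathway and the cohort.
#'
#' @param pathway A `biopsy_pathway`.
#' @param cohort A validated cohort tibble (validated here if not already).
#' @return A tibble (`patient_id`, `decision`) with one row per patient,
#'   cohort order preserved; `decision` is `"biopsy"`/`"no_biopsy"`, plus a
#'   `pathway` attribute carrying the name.
#' @export
apply_pathway <- function(pathway, cohort) {
  stopifnot(inherits(pathway, "biopsy_pathway"))
  cohort <- validate_cohort(cohort)
  grid <- pathway_grid(pathway)
  band <- as.integer(assign_psad_band(cohort$psad))
  decisions <- grid[cbind(cohort$pirads, band)]
  out <- tibble::tibble(patient_id = cohort$patient_id, decision = decisions)
  attr(out, "pathway") <- pathway$name
  out
}

#' Parse a pathway definition from YAML or JSON text
#'
#' The document has keys `name`, `default` (or `default_decision`) and
#' `rules`, each rule with `pirads`, `bands` (band names or `all`) and
#' `decision`. YAML is a superset of JSON here, so both parse with the same
#' reader. Round-trips with [format_pathway_config()].
#'
#' @param text A YAML or JSON document as a single string.
#' @return A validated `biopsy_pathway`.
#' @examples
#' parse_pathway_config("
#' name: pr45_only
#' default: no_biopsy
#' rules:
#'   - pirads: [4, 5]
#'     bands: all
#'     decision: biopsy
#' ")
#' @export
parse_pathway_config <- function(text) {
  doc <- tryCatch(yaml::yaml.load(text),
                  error = function(e) {
                    rlang::abort(paste0("Malformed pathway config: ",
                                        conditionMessage(e)),
                                 class = "psadpathways_config_error")
                  })
  if (!is.list(doc)) {
    rlang::abort("Pathway config must be a mapping.",
                 class = "psadpathways_config_error")
  }
  if (is.null(doc$name)) {
    rlang::abort("Pathway config: missing key `name`.",
                 class = "psadpathways_config_error")
  }
  default <- doc$default %||% doc$default_decision
  if (is.null(default)) {
    rlang::abort("Pathway config: missing key `default` (decision for uncovered cells).",
                 class = "psadpathways_config_error")
  }
  new_pathway(doc$name, rules = doc$rules %||% list(),
              default_decision = default, description = doc$description)
}

#' Serialise a pathway definition to YAML
#'
#' @param pathway A `biopsy_pathway`.
#' @return A YAML string; `parse_pathway_config()` of it reproduces the
#'   definition.
#' @export
format_pathway_config <- function(pathway) {
  stopifnot(inherits(pathway, "biopsy_pathway"))
  doc <- list(name = pathway$name,
              default = pathway$default_decision,
              rules = lapply(pathway$rules, function(r) {
                list(pirads = r$pirads, bands = r$bands, decision = r$decision)
              }))
  if (!is.null(pathway$description)) doc$description <- pathway$description
  yaml::as.yaml(doc)
}
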