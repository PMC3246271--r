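# Clone-level mutation records and population-collapsed events.
#
# A record is one (mutation, clone) observation; clones from the same
# population share part of their history, so identical records across
# clones of one population are the same mutational event seen more than
# once.  Rate inference and spectrum tests work on events or on per-clone
# counts, never on raw record rows.

mutation_table_columns <- c(
  "population", "clone", "generation", "position", "ref", "alt"
)

#' Read a clone-level mutation table
#'
#' Reads a tab-separated table of base substitutions with one row per
#' (mutation, clone) observation.  Required columns: `population`,
#' `clone`, `generation`, `position`, `ref`, `alt`; optional: `gene`,
#' `coding_class`.  Lines starting with `#` are comments.  All rows are
#' validated; offending rows are reported together by row number.
#'
#' @param path Path to the TSV file.
#' @param genome Optional [annotated_genome]; when given, each record's
#'   `ref` is checked against the genome sequence and `coding_class` is
#'   filled in by [classify_change()] where missing.
#' @return A tibble of validated records.
#' @seealso [ltee_mutations()] for the packaged example table.
#' @export
read_mutation_table <- function(path, genome = NULL) {
  if (!file.exists(path)) {
    abort(paste0("cannot read mutation table: no such file: ", path))
  }
  tbl <- readr::read_tsv(
    path, comment = "#", show_col_types = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  missing <- setdiff(mutation_table_columns, names(tbl))
  if (length(missing) > 0L) {
    abort(paste0(
      "mutation table lacks required column(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  tbl$generation <- suppressWarnings(as.numeric(tbl$generation))
  tbl$position <- suppressWarnings(as.integer(tbl$position))
  validate_mutation_records(tbl, genome = genome)
}

#' @rdname read_mutation_table
#' @param records A records tibble (as returned by `read_mutation_table()`).
#' @export
validate_mutation_records <- function(records, genome = NULL) {
  records <- as_tibble(records)
  problems <- character(0)
  flag <- function(bad, what) {
    if (any(bad, na.rm = TRUE)) {
      rows <- which(bad | is.na(bad))
      problems <<- c(problems, paste0(
        what, " (row", if (length(rows) > 1L) "s" else "", " ",
        paste(head(rows, 10L), collapse = ", "),
        if (length(rows) > 10L) ", ..." else "", ")"
      ))
    }
  }
  flag(!toupper(records$ref) %in% dna_bases, "invalid ref base")
  flag(!toupper(records$alt) %in% dna_bases, "invalid alt base")
  flag(toupper(records$ref) == toupper(records$alt), "ref equals alt")
  flag(is.na(records$generation) | records$generation <= 0,
       "non-positive generation")
  flag(is.na(records$position) | records$position < 1L, "invalid position")
  if (length(problems) > 0L) {
    abort(paste0(
      "invalid mutation record(s):\n  - ",
      paste(problems, collapse = "\n  - ")
    ))
  }
  records$ref <- toupper(records$ref)
  records$alt <- toupper(records$alt)
  if (!is.null(genome)) {
    seq_vec <- split_sequence(genome)
    bad_ref <- seq_vec[records$position] != records$ref
    if (any(bad_ref)) {
      abort(paste0(
        "record ref base disagrees with the genome at row(s) ",
        paste(head(which(bad_ref), 10L), collapse = ", ")
      ))
    }
    if (is.null(records$coding_class)) {
      records$coding_class <- NA_character_
    }
    todo <- is.na(records$coding_class)
    if (any(todo)) {
      records$coding_class[todo] <- classify_change(
        genome, records$position[todo], records$alt[todo]
      )
    }
  }
  records
}

#' @rdname read_mutation_table
#' @export
write_mutation_table <- function(records, path) {
  readr::write_tsv(records, path)
  invisible(records)
}

#' Packaged long-term evolution experiment fixtures
#'
#' `ltee_mutations()` returns the 52 clone-level synonymous substitution
#' records observed across 19 *E. coli* clones sampled from eight
#' nonmutator populations of a 40,000-generation evolution experiment
#' (positions on the ancestral REL606 chromosome).  `ltee_clones()`
#' returns the manifest of all 19 sequenced clones with their sampling
#' generations -- including clones that carry no synonymous mutation,
#' whose Poisson zeros still inform the rate estimate.
#'
#' @return A tibble of mutation records, or of (population, clone,
#'   generation) rows.
#' @examples
#' nrow(ltee_mutations())            # 52 clone-level records
#' nrow(collapse_events(ltee_mutations()))  # 35 independent events
#' @export
ltee_mutations <- function() {
  read_mutation_table(
    system.file("extdata", "ltee_synonymous_mutations.tsv",
                package = "synrate", mustWork = TRUE)
  )
}

#' @rdname ltee_mutations
#' @export
ltee_clones <- function() {
  read_clone_manifest(
    system.file("extdata", "ltee_clones.tsv",
                package = "synrate", mustWork = TRUE)
  )
}

#' @rdname read_mutation_table
#' @export
read_clone_manifest <- function(path) {
  tbl <- readr::read_tsv(
    path, comment = "#", show_col_types = FALSE,
    col_types = readr::cols(
      population = readr::col_character(),
      clone = readr::col_character(),
      generation = readr::col_double()
    )
  )
  if (any(tbl$generation <= 0)) {
    abort("clone manifest generations must be positive.")
  }
  if (anyDuplicated(tbl[c("population", "clone")]) > 0L) {
    abort("duplicated (population, clone) in manifest.")
  }
  tbl
}

#' @rdname read_mutation_table
#' @export
read_callable_sites <- function(path) {
  readr::read_tsv(
    path, comment = "#", show_col_types = FALSE,
    col_types = readr::cols(
      clone = readr::col_character(),
      type = readr::col_character(),
      sites = readr::col_double()
    )
  )
}

#' Collapse clone-level records into independent mutational events
#'
#' Clones sampled from one population share part of their lineage, so the
#' same mutation can appear in several clones without being independent.
#' Records identical in (population, position, ref, alt) are collapsed
#' into one event carrying the set of clones that bear it.  The same
#' position mutated in different populations remains distinct events, as
#' do different alternate bases at one position.
#'
#' @param records A validated records tibble.
#' @return A tibble with one row per event: `population`, `position`,
#'   `gene` (if present), `ref`, `alt`, `carriers` (list-column of
#'   tibbles with `clone` and `generation`) and `n_carriers`, sorted by
#'   population then position.
#' @export
collapse_events <- function(records) {
  records <- as_tibble(records)
  has_gene <- "gene" %in% names(records)
  grouped <- dplyr::group_by(
    records, .data$population, .data$position, .data$ref, .data$alt
  )
  out <- dplyr::summarise(
    grouped,
    gene = if (has_gene) .data$gene[1] else NA_character_,
    carriers = list(dplyr::pick("clone", "generation")),
    n_carriers = dplyr::n(),
    .groups = "drop"
  )
  out <- out[order(out$population, out$position), ]
  out[, c("population", "position", "gene", "ref", "alt",
          "carriers", "n_carriers")]
}

#' Observed counts of the six substitution types
#'
#' Tallies events by strand-collapsed type and splits them into
#' transitions and transversions.
#'
#' @param events An event tibble from [collapse_events()] (or any tibble
#'   with `ref` and `alt` columns, e.g. raw records).
#' @return A tibble with columns `type`, `count` and `transition`;
#'   attributes `transitions`, `transversions` and `n_events` carry the
#'   totals.
#' @examples
#' sc <- spectrum_counts(collapse_events(ltee_mutations()))
#' attr(sc, "transitions")    # 19
#' attr(sc, "transversions")  # 16
#' @export
spectrum_counts <- function(events) {
  if (nrow(events) == 0L) {
    abort("no events: spectrum undefined.")
  }
  type <- classify_type(events$ref, events$alt)
  counts <- table(factor(type, levels = mutation_types()))
  out <- tibble(
    type = mutation_types(),
    count = as.integer(counts[mutation_types()]),
    transition = is_transition(mutation_types())
  )
  structure(
    out,
    transitions = sum(out$count[out$transition]),
    transversions = sum(out$count[!out$transition]),
    n_events = nrow(events)
  )
}

#' Assemble per-clone observations for rate inference
#'
#' Builds the long table the Poisson model consumes: one row per (clone,
#' substitution type) holding the clone's elapsed generations `t`, its
#' observed synonymous count `m` of that type, and the number of
#' synonymous sites at risk `s` in that clone.  Sites come from a
#' per-clone callable-sites table when available (accounting for
#' deletions, low coverage and repeats in that clone) and otherwise fall
#' back to the ancestral genome-wide opportunities.  Clones listed in the
#' manifest but carrying no mutation contribute all-zero counts --
#' informative Poisson zeros.
#'
#' @param records Validated mutation records; rows whose `coding_class`
#'   is present and not `"synonymous"` are dropped.
#' @param clones Clone manifest tibble (`population`, `clone`,
#'   `generation`) covering every clone in `records`.
#' @param opportunity A `site_opportunity_table` used as the fallback
#'   source of per-type sites.
#' @param callable Optional tibble (`clone`, `type`, `sites`) of per-clone
#'   callable synonymous opportunities.
#' @return A tibble with columns `population`, `clone`, `t`, `type`, `m`,
#'   `s` (six rows per clone).
#' @export
build_clone_observations <- function(records, clones, opportunity = NULL,
                                     callable = NULL) {
  if (is.null(opportunity) && is.null(callable)) {
    abort("supply `opportunity` (ancestral fallback) and/or `callable` sites.")
  }
  records <- as_tibble(records)
  if ("coding_class" %in% names(records)) {
    records <- records[is.na(records$coding_class) |
                         records$coding_class == "synonymous", ]
  }
  key <- function(p, c) paste(p, c, sep = "\r")
  rec_keys <- unique(key(records$population, records$clone))
  man_keys <- key(clones$population, clones$clone)
  stray <- setdiff(rec_keys, man_keys)
  if (length(stray) > 0L) {
    abort(paste0(
      "clone(s) in records but absent from the manifest: ",
      paste(gsub("\r", "/", head(stray, 5L)), collapse = ", ")
    ))
  }

  counts <- dplyr::count(
    dplyr::mutate(records, type = classify_type(.data$ref, .data$alt)),
    .data$population, .data$clone, .data$type, name = "m"
  )
  grid <- tidyr::crossing(
    clones[, c("population", "clone", "generation")],
    type = mutation_types()
  )
  obs <- dplyr::left_join(
    grid, counts, by = c("population", "clone", "type")
  )
  obs$m <- ifelse(is.na(obs$m), 0L, obs$m)

  if (!is.null(callable)) {
    missing_clone <- setdiff(clones$clone, unique(callable$clone))
    if (length(missing_clone) > 0L && is.null(opportunity)) {
      abort(paste0(
        "clone(s) missing from callable-sites table with no fallback: ",
        paste(head(missing_clone, 5L), collapse = ", ")
      ))
    }
    obs <- dplyr::left_join(obs, callable, by = c("clone", "type"))
  } else {
    obs$sites <- NA_real_
  }
  if (!is.null(opportunity)) {
    fallback <- setNames(opportunity$opportunities, opportunity$type)
    obs$sites <- ifelse(is.na(obs$sites), fallback[obs$type], obs$sites)
  }
  if (anyNA(obs$sites)) {
    abort("some (clone, type) pairs have no site count from either source.")
  }

  out <- tibble(
    population = obs$population,
    clone = obs$clone,
    t = obs$generation,
    type = factor(obs$type, levels = mutation_types()),
    m = as.integer(obs$m),
    s = as.numeric(obs$sites)
  )
  out[order(out$population, out$clone, out$type), ]
}
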