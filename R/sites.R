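# Synonymous target-site counting.
#
# Every coding position admits three single-base changes.  Whether each
# change is synonymous is decided by translating the affected codon under
# the bacterial/archaeal genetic code (NCBI table 11), strand-aware, in
# every CDS containing the position.  A change is synonymous only if it is
# synonymous in all containing CDSs; a change that creates a stop codon in
# any CDS is nonsense.  Changes destroying a stop are nonsynonymous
# (stop-loss), never synonymous.

the_cache <- new.env(parent = emptyenv())

# 576-row lookup: codon x codon position x alternate base -> classification
codon_change_lookup <- function() {
  if (!is.null(the_cache$codon_lookup)) {
    return(the_cache$codon_lookup)
  }
  code <- Biostrings::getGeneticCode("11")
  codons <- names(code)
  tab <- expand.grid(
    codon = codons, pos = 1:3, alt = dna_bases,
    stringsAsFactors = FALSE
  )
  tab$ref <- substr(tab$codon, tab$pos, tab$pos)
  tab <- tab[tab$ref != tab$alt, ]
  new_codon <- tab$codon
  substr(new_codon, tab$pos, tab$pos) <- tab$alt
  ref_aa <- unname(code[tab$codon])
  alt_aa <- unname(code[new_codon])
  tab$class <- ifelse(
    alt_aa == ref_aa, "synonymous",
    ifelse(alt_aa == "*", "nonsense", "nonsynonymous")
  )
  tab$key <- paste0(tab$codon, tab$pos, tab$alt)
  lookup <- setNames(tab$class, tab$key)
  the_cache$codon_lookup <- lookup
  lookup
}

# Enumerate every (coding position, alternate base) pair with its
# classification aggregated over all containing CDSs.  Columns: pos
# (genome coordinate), ref, alt (genome strand), class.  The backbone of
# synonymous_opportunities(), count_sites_ng() and the simulator.
coding_change_table <- function(genome) {
  if (nrow(genome$features) == 0L) {
    abort("genome has no CDS features; cannot enumerate coding changes.")
  }
  len <- genome_length(genome)
  seq_vec <- split_sequence(genome)
  lookup <- codon_change_lookup()

  alt_map <- list(
    A = c("C", "G", "T"), C = c("A", "G", "T"),
    G = c("A", "C", "T"), T = c("A", "C", "G")
  )

  per_feature <- purrr::pmap(
    genome$features[, c("start", "end", "strand")],
    function(start, end, strand) {
      gpos <- wrap_positions(seq.int(start, end), len)
      if (strand == "-") gpos <- rev(gpos)
      base_g <- seq_vec[gpos]                  # genome-strand base
      base_r <- if (strand == "-") complement_base(base_g) else base_g
      n <- length(gpos)
      bm <- matrix(base_r, nrow = 3L)
      codons <- rep(paste0(bm[1L, ], bm[2L, ], bm[3L, ]), each = 3L)
      codon_pos <- rep.int(1:3, n %/% 3L)
      # three reading-frame alternates per position
      alt_r <- unlist(alt_map[base_r], use.names = FALSE)
      idx <- rep(seq_len(n), each = 3L)
      cls <- unname(lookup[paste0(codons[idx], codon_pos[idx], alt_r)])
      alt_g <- if (strand == "-") complement_base(alt_r) else alt_r
      tibble(
        pos = gpos[idx],
        ref = base_g[idx],
        alt = alt_g,
        class = cls
      )
    }
  )
  all_changes <- dplyr::bind_rows(per_feature)

  # fast path: no position covered by more than one CDS
  span_total <- nrow(all_changes) / 3L
  if (length(unique(all_changes$pos)) == span_total) {
    return(all_changes[order(all_changes$pos, all_changes$alt), ])
  }

  # collapse overlapping CDSs: synonymous only if synonymous everywhere;
  # nonsense if nonsense anywhere
  agg <- dplyr::summarise(
    dplyr::group_by(all_changes, .data$pos, .data$ref, .data$alt),
    n_cds = dplyr::n(),
    n_syn = sum(.data$class == "synonymous"),
    n_non = sum(.data$class == "nonsense"),
    .groups = "drop"
  )
  agg$class <- ifelse(
    agg$n_syn == agg$n_cds, "synonymous",
    ifelse(agg$n_non > 0L, "nonsense", "nonsynonymous")
  )
  agg[order(agg$pos, agg$alt), c("pos", "ref", "alt", "class")]
}

coding_change_table_cached <- function(genome) {
  # recovery experiments re-enumerate the same simulated genome many
  # times; memoise on the genome's content
  key <- paste0(
    genome$id, "|", genome_length(genome), "|", nrow(genome$features), "|",
    sum(as.numeric(genome$features$start) + as.numeric(genome$features$end))
  )
  hit <- the_cache$change_tables[[key]]
  if (!is.null(hit)) return(hit)
  val <- coding_change_table(genome)
  if (is.null(the_cache$change_tables)) the_cache$change_tables <- list()
  if (length(the_cache$change_tables) > 8L) the_cache$change_tables <- list()
  the_cache$change_tables[[key]] <- val
  val
}

#' Simple synonymous target sites: one third of the coding length
#'
#' The coarse approximation used for cross-study comparisons: every
#' protein-coding base admits three changes, roughly one of which is
#' synonymous, so the effective number of synonymous target sites is the
#' protein-coding length divided by three.  Positions covered by more
#' than one CDS are counted once.
#'
#' @param genome An [annotated_genome].
#' @return A single number, coding length / 3.
#' @seealso [synonymous_opportunities()] for the per-type enumeration.
#' @export
simple_synonymous_sites <- function(genome) {
  coding_genome_length(genome) / 3
}

# number of distinct genome positions covered by a CDS
coding_genome_length <- function(genome) {
  if (nrow(genome$features) == 0L) {
    abort("genome has no CDS features; coding length undefined.")
  }
  len <- genome_length(genome)
  pos <- unlist(purrr::map2(
    genome$features$start, genome$features$end,
    function(s, e) wrap_positions(seq.int(s, e), len)
  ))
  length(unique(pos))
}

#' Classify a base change at a genome position
#'
#' Translates every CDS containing the position (strand-aware, bacterial
#' code) with and without the change.  The change is `"synonymous"` only
#' if the encoded amino acid is unchanged in all containing CDSs,
#' `"nonsense"` if it creates a stop codon in any CDS, `"noncoding"` if
#' the position lies outside all CDSs, and `"nonsynonymous"` otherwise.
#'
#' @param genome An [annotated_genome].
#' @param position 1-based genome coordinate(s).
#' @param alt Alternate base(s), each different from the reference base at
#'   its position.
#' @return Character vector of classifications.
#' @examples
#' toy <- annotated_genome(
#'   "ATGAAATAA",
#'   tibble::tibble(gene = "toy", start = 1, end = 9, strand = "+")
#' )
#' classify_change(toy, 6, "G")  # AAA -> AAG, Lys -> Lys: synonymous
#' classify_change(toy, 4, "G")  # AAA -> GAA, Lys -> Glu: nonsynonymous
#' @export
classify_change <- function(genome, position, alt) {
  position <- as.integer(position)
  alt <- toupper(alt)
  n <- max(length(position), length(alt))
  position <- rep_len(position, n)
  alt <- rep_len(alt, n)
  if (any(!alt %in% dna_bases)) {
    abort("`alt` must be a base in {A, C, G, T}.")
  }
  len <- genome_length(genome)
  if (any(position < 1L | position > len)) {
    abort("`position` out of range [1, genome length].")
  }
  seq_vec <- split_sequence(genome)
  if (any(seq_vec[position] == alt)) {
    abort("`alt` equals the reference base at that position; not a substitution.")
  }
  lookup <- codon_change_lookup()
  feats <- genome$features

  vapply(seq_len(n), function(i) {
    p <- position[i]
    # containing features (feature coordinates may wrap past len)
    hit <- which(
      (feats$start <= p & feats$end >= p) |
        (feats$end > len & (p + len) >= feats$start & (p + len) <= feats$end)
    )
    if (length(hit) == 0L) {
      return("noncoding")
    }
    classes <- vapply(hit, function(j) {
      s <- feats$start[j]
      e <- feats$end[j]
      pp <- if (p < s) p + len else p
      offset <- if (feats$strand[j] == "+") pp - s else e - pp
      cpos <- (offset %% 3L) + 1L
      codon_start <- offset - (cpos - 1L)
      idx <- codon_start + 0:2
      gidx <- if (feats$strand[j] == "+") s + idx else e - idx
      bases <- seq_vec[wrap_positions(gidx, len)]
      if (feats$strand[j] == "-") bases <- complement_base(bases)
      codon <- paste(bases, collapse = "")
      a <- if (feats$strand[j] == "-") complement_base(alt[i]) else alt[i]
      unname(lookup[paste0(codon, cpos, a)])
    }, character(1))
    if (all(classes == "synonymous")) {
      "synonymous"
    } else if (any(classes == "nonsense")) {
      "nonsense"
    } else {
      "nonsynonymous"
    }
  }, character(1))
}

#' Per-type synonymous mutational opportunities
#'
#' Enumerates, for every coding position and each of its three possible
#' base changes, whether the change is synonymous, and tallies the
#' synonymous opportunities by strand-collapsed substitution type.  This
#' is the composition-aware counterpart of [simple_synonymous_sites()]:
#' it carries, per type, the number of site-change combinations at which
#' a mutation of that type would be synonymous (the "sites at risk" for
#' synonymous substitutions of that type).
#'
#' @param genome An [annotated_genome] with at least one CDS feature.
#' @return A tibble of class `site_opportunity_table` with columns `type`,
#'   `opportunities` and `weight` (the genome-wide frequency of the type's
#'   ancestral base pair), and attributes `coding_length`, `s_simple`,
#'   `n_at`, `n_gc`, `f_at`, `f_gc`, `genome_id`.
#' @export
synonymous_opportunities <- function(genome) {
  changes <- coding_change_table_cached(genome)
  syn <- changes[changes$class == "synonymous", , drop = FALSE]
  type <- classify_type(syn$ref, syn$alt)
  counts <- table(factor(type, levels = mutation_types()))

  seq_vec <- split_sequence(genome)
  n_at <- sum(seq_vec %in% c("A", "T"))
  n_gc <- sum(seq_vec %in% c("G", "C"))
  f_at <- n_at / (n_at + n_gc)
  f_gc <- n_gc / (n_at + n_gc)

  coding_length <- length(unique(changes$pos))
  out <- tibble(
    type = mutation_types(),
    opportunities = as.numeric(counts[mutation_types()]),
    weight = ifelse(type_origin(mutation_types()) == "AT", f_at, f_gc)
  )
  new_site_opportunity_table(
    out,
    coding_length = coding_length,
    s_simple = coding_length / 3,
    n_at = n_at, n_gc = n_gc, f_at = f_at, f_gc = f_gc,
    genome_id = genome$id
  )
}

new_site_opportunity_table <- function(tbl, coding_length, s_simple,
                                       n_at, n_gc, f_at, f_gc, genome_id) {
  structure(
    tbl,
    coding_length = coding_length,
    s_simple = s_simple,
    n_at = n_at, n_gc = n_gc, f_at = f_at, f_gc = f_gc,
    genome_id = genome_id,
    class = c("site_opportunity_table", class(tibble()))
  )
}

#' @export
print.site_opportunity_table <- function(x, ...) {
  cat(sprintf(
    "# Synonymous site opportunities for %s (coding length %s bp, S_simple = %s, f_AT = %.4f)\n",
    attr(x, "genome_id"), format(attr(x, "coding_length"), big.mark = ","),
    format(attr(x, "s_simple"), big.mark = ","), attr(x, "f_at")
  ))
  NextMethod()
}

#' @rdname synonymous_opportunities
#' @param table A `site_opportunity_table`.
#' @return For `site_composition()`, a named list with `n_at`, `n_gc`,
#'   `f_at`, `f_gc`, `coding_length`, `s_simple`.
#' @export
site_composition <- function(table) {
  list(
    n_at = attr(table, "n_at"), n_gc = attr(table, "n_gc"),
    f_at = attr(table, "f_at"), f_gc = attr(table, "f_gc"),
    coding_length = attr(table, "coding_length"),
    s_simple = attr(table, "s_simple")
  )
}

#' Expected mutational spectrum under uniform per-opportunity rates
#'
#' If every synonymous opportunity were equally likely to mutate, the
#' expected share of observed synonymous changes of each type would be
#' its share of opportunities.  This is the spectrum plotted as the
#' "expected" bars against observed counts.
#'
#' @param table A `site_opportunity_table` from
#'   [synonymous_opportunities()].
#' @return A tibble with columns `type` and `expected` (probabilities
#'   summing to 1).
#' @export
expected_spectrum <- function(table) {
  s <- sum(table$opportunities)
  if (!isTRUE(s > 0)) {
    abort("opportunity table is all zero; expected spectrum undefined.")
  }
  tibble(type = table$type, expected = table$opportunities / s)
}

#' Serialize a site opportunity table as TSV + JSON sidecar
#'
#' Writes the per-type opportunity counts as a two-column TSV and the
#' scalar metadata (composition, coding length, simple site count) as a
#' JSON sidecar next to it.
#'
#' @param table A `site_opportunity_table`.
#' @param path Output TSV path; the sidecar is written to
#'   `paste0(path, ".json")`.
#' @return `table`, invisibly.
#' @export
write_opportunity_table <- function(table, path) {
  readr::write_tsv(
    tibble(type = table$type, opportunities = table$opportunities),
    path
  )
  meta <- site_composition(table)
  meta$genome_id <- attr(table, "genome_id")
  writeLines(to_json(meta), paste0(path, ".json"))
  invisible(table)
}

#' @rdname write_opportunity_table
#' @export
read_opportunity_table <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    type = readr::col_character(), opportunities = readr::col_double()
  ))
  if (!setequal(tbl$type, mutation_types())) {
    abort("opportunity TSV must contain exactly the six substitution types.")
  }
  tbl <- tbl[match(mutation_types(), tbl$type), ]
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    abort(paste0("missing JSON sidecar: ", sidecar))
  }
  meta <- parse_json_scalars(readLines(sidecar, warn = FALSE))
  tbl$weight <- ifelse(type_origin(tbl$type) == "AT", meta$f_at, meta$f_gc)
  new_site_opportunity_table(
    tbl,
    coding_length = meta$coding_length, s_simple = meta$s_simple,
    n_at = meta$n_at, n_gc = meta$n_gc,
    f_at = meta$f_at, f_gc = meta$f_gc,
    genome_id = as.character(meta$genome_id)
  )
}

# tiny flat-object JSON helpers (scalars only; avoids a hard jsonlite
# dependency for one sidecar)
to_json <- function(x) {
  vals <- vapply(x, function(v) {
    if (is.character(v)) paste0('"', v, '"') else format(v, digits = 15)
  }, character(1))
  paste0("{", paste0('"', names(x), '": ', vals, collapse = ", "), "}")
}

parse_json_scalars <- function(line) {
  line <- paste(line, collapse = "")
  body <- gsub("^\\s*\\{|\\}\\s*$", "", line)
  parts <- strsplit(body, ",(?=\\s*\")", perl = TRUE)[[1]]
  out <- list()
  for (p in parts) {
    kv <- strsplit(p, ":", fixed = TRUE)[[1]]
    key <- gsub('^\\s*"|"\\s*$', "", kv[1])
    val <- trimws(paste(kv[-1], collapse = ":"))
    out[[key]] <- if (grepl('^"', val)) gsub('^"|"$', "", val) else as.numeric(val)
  }
  out
}
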