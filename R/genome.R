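#' Build an annotated genome from a sequence and CDS coordinates
#'
#' The central sequence container: a single (optionally circular) DNA
#' sequence together with the protein-coding features used for synonymous
#' site counting.  Features whose span is not divisible by three or is
#' shorter than two codons cannot be translated in a single frame and are
#' dropped with a warning; the dropped count is kept on the object.
#'
#' @param sequence A single DNA string over `{A, C, G, T}` (character or
#'   [Biostrings::DNAString]).  Ambiguity codes are rejected.
#' @param features A data frame with columns `gene`, `start`, `end`,
#'   `strand` (`"+"` or `"-"`); coordinates are 1-based inclusive.  For a
#'   circular genome a feature may run past the sequence end (`end >
#'   length`), meaning it wraps through the origin.
#' @param id Genome identifier.
#' @param circular Is the molecule circular?
#' @return An object of class `annotated_genome`: a list with elements
#'   `id`, `sequence` (a `DNAString`), `circular`, `features` (tibble) and
#'   `n_skipped_features`.
#' @examples
#' toy <- annotated_genome(
#'   "ATGAAATAA",
#'   tibble::tibble(gene = "toy", start = 1, end = 9, strand = "+")
#' )
#' toy
#' @export
annotated_genome <- function(sequence, features, id = "genome",
                             circular = TRUE) {
  seq_chr <- toupper(as.character(sequence))
  if (length(seq_chr) != 1L || nchar(seq_chr) == 0L) {
    abort("`sequence` must be a single non-empty DNA string.")
  }
  if (grepl("[^ACGT]", seq_chr)) {
    abort("`sequence` contains characters outside {A, C, G, T}; ambiguity codes are not supported.")
  }
  len <- nchar(seq_chr)

  features <- as_tibble(features)
  required <- c("gene", "start", "end", "strand")
  missing <- setdiff(required, names(features))
  if (length(missing) > 0L) {
    abort(paste0("`features` lacks column(s): ", paste(missing, collapse = ", ")))
  }
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  if (nrow(features) > 0L) {
    if (any(!features$strand %in% c("+", "-"))) {
      abort("feature `strand` must be \"+\" or \"-\".")
    }
    if (any(features$start < 1L) || any(features$end < features$start)) {
      abort("feature coordinates must satisfy 1 <= start <= end.")
    }
    max_end <- if (circular) 2L * len else len
    if (any(features$end > max_end)) {
      abort("feature extends past the sequence end (wrapping is only allowed on a circular genome).")
    }
    span <- features$end - features$start + 1L
    bad <- span %% 3L != 0L | span < 6L
    if (any(bad)) {
      warn(paste0(
        sum(bad), " feature(s) skipped: span not divisible by 3 or shorter ",
        "than two codons (", paste(head(features$gene[bad], 5L), collapse = ", "),
        if (sum(bad) > 5L) ", ..." else "", ")"
      ))
      features <- features[!bad, , drop = FALSE]
    }
    n_skipped <- sum(bad)
  } else {
    n_skipped <- 0L
  }

  structure(
    list(
      id = id,
      sequence = Biostrings::DNAString(seq_chr),
      circular = isTRUE(circular),
      features = features,
      n_skipped_features = n_skipped
    ),
    class = "annotated_genome"
  )
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf(
    "<annotated_genome> %s: %s bp (%s), %d CDS feature(s)%s\n",
    x$id, format(genome_length(x), big.mark = ","),
    if (x$circular) "circular" else "linear",
    nrow(x$features),
    if (x$n_skipped_features > 0)
      sprintf(", %d skipped at load", x$n_skipped_features) else ""
  ))
  invisible(x)
}

#' @rdname annotated_genome
#' @param genome An `annotated_genome`.
#' @export
genome_length <- function(genome) {
  length(genome$sequence)
}

# 1-based positions wrapped onto the circle
wrap_positions <- function(pos, len) {
  ((pos - 1L) %% len) + 1L
}

# character vector of bases at 1-based (possibly wrapping) positions
genome_bases <- function(genome, pos) {
  pos <- wrap_positions(as.integer(pos), genome_length(genome))
  strsplit(as.character(genome$sequence), "", fixed = TRUE)[[1]][pos]
}

# bases at positions, using a pre-split sequence vector (hot path)
split_sequence <- function(genome) {
  strsplit(as.character(genome$sequence), "", fixed = TRUE)[[1]]
}

#' Read an annotated genome from GenBank or GFF3 + FASTA
#'
#' Two on-disk layouts are supported: a single-record GenBank flat file
#' (CDS features and ORIGIN sequence), or a GFF3 annotation paired with a
#' FASTA sequence.  Only unspliced CDS features are used; GenBank
#' `join(...)` locations (spliced or origin-spanning compound features)
#' are skipped with a warning, as are CDS whose span is not a multiple of
#' three.
#'
#' @param path Path to the GenBank file, or to the GFF3 file when `fasta`
#'   is given.
#' @param fasta Optional path to a FASTA file holding the sequence; when
#'   supplied, `path` is parsed as GFF3.
#' @param circular Is the molecule circular?  For GenBank input the LOCUS
#'   line topology is used unless overridden.
#' @return An [annotated_genome].
#' @export
read_genome <- function(path, fasta = NULL, circular = NULL) {
  if (!file.exists(path)) {
    abort(paste0("cannot read genome: no such file: ", path))
  }
  if (is.null(fasta)) {
    read_genome_genbank(path, circular = circular)
  } else {
    if (!file.exists(fasta)) {
      abort(paste0("cannot read genome: no such file: ", fasta))
    }
    read_genome_gff3(path, fasta, circular = circular %||% TRUE)
  }
}

read_genome_gff3 <- function(gff_path, fasta_path, circular = TRUE) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("reading GFF3 requires the rtracklayer package.")
  }
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) != 1L) {
    abort("expected a single-sequence FASTA file.")
  }
  gr <- rtracklayer::import(gff_path, format = "gff3")
  gr <- gr[gr$type == "CDS"]
  if (length(gr) == 0L) {
    abort("no CDS features found in GFF3 file.")
  }
  gene <- as.character(gr$gene %||% rep(NA_character_, length(gr)))
  if (all(is.na(gene)) && !is.null(gr$locus_tag)) {
    gene <- as.character(gr$locus_tag)
  }
  if (!is.null(gr$ID)) gene <- ifelse(is.na(gene), as.character(gr$ID), gene)
  gene[is.na(gene)] <- paste0("cds_", seq_len(length(gr)))[is.na(gene)]
  feats <- tibble(
    gene = gene,
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr))
  )
  feats$strand[!feats$strand %in% c("+", "-")] <- "+"
  g <- annotated_genome(
    as.character(seqs[[1]]), feats,
    id = names(seqs)[1], circular = circular
  )
  if (nrow(g$features) == 0L) {
    abort("no usable CDS features after skipping untranslatable spans.")
  }
  g
}

# Minimal single-record GenBank flat-file parser: LOCUS topology, CDS
# locations ("123..456", "complement(123..456)"), /gene or /locus_tag
# qualifiers, ORIGIN sequence.  join() locations are skipped (spliced CDS
# are out of scope).
read_genome_genbank <- function(path, circular = NULL) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (is.null(circular)) {
    circular <- length(locus) > 0L && grepl("circular", locus[1], ignore.case = TRUE)
  }
  id <- grep("^(ACCESSION|LOCUS)", lines, value = TRUE)
  id <- if (length(id) > 0L) strsplit(trimws(id[length(id)]), "\\s+")[[1]][2] else "genome"

  feat_start <- grep("^FEATURES", lines)
  origin_start <- grep("^ORIGIN", lines)
  if (length(feat_start) == 0L || length(origin_start) == 0L) {
    abort("not a parseable GenBank flat file: FEATURES or ORIGIN section missing.")
  }
  feat_lines <- lines[(feat_start[1] + 1L):(origin_start[1] - 1L)]

  # a new feature starts with a key in columns 6-20
  is_key <- grepl("^ {5}\\S", feat_lines)
  key <- ifelse(is_key, trimws(substr(feat_lines, 6, 20)), NA_character_)
  grp <- cumsum(is_key)
  keep <- grp > 0L
  feats <- split(feat_lines[keep], grp[keep])
  keys <- key[is_key]

  cds <- list()
  n_join <- 0L
  for (i in seq_along(feats)) {
    if (keys[i] != "CDS") next
    block <- feats[[i]]
    # location may continue over lines until the first qualifier
    qual_at <- grep("^\\s{21}/", block)
    loc_end <- if (length(qual_at) > 0L) qual_at[1] - 1L else length(block)
    loc <- gsub("\\s", "", paste(
      c(sub("^ {5}CDS\\s*", "", block[1]),
        if (loc_end >= 2L) trimws(block[2:loc_end]) else character(0)),
      collapse = ""
    ))
    if (grepl("join|order", loc)) {
      n_join <- n_join + 1L
      next
    }
    strand <- if (grepl("^complement\\(", loc)) "-" else "+"
    loc <- gsub("^complement\\(|\\)$", "", loc)
    loc <- gsub("[<>]", "", loc)
    m <- regmatches(loc, regexec("^(\\d+)\\.\\.(\\d+)$", loc))[[1]]
    if (length(m) != 3L) next
    quals <- block[grepl("^\\s{21}/(gene|locus_tag)=", block)]
    gene <- if (length(quals) > 0L) {
      sub('^\\s*/(gene|locus_tag)="?([^"]*)"?\\s*$', "\\2", quals[1])
    } else {
      NA_character_
    }
    cds[[length(cds) + 1L]] <- tibble(
      gene = gene, start = as.integer(m[2]), end = as.integer(m[3]),
      strand = strand
    )
  }
  if (n_join > 0L) {
    warn(paste0(n_join, " compound (join/order) CDS location(s) skipped."))
  }
  if (length(cds) == 0L) {
    abort("no usable CDS features found in GenBank file.")
  }
  feats_tbl <- dplyr::bind_rows(cds)
  feats_tbl$gene[is.na(feats_tbl$gene)] <-
    paste0("cds_", which(is.na(feats_tbl$gene)))

  seq_lines <- lines[(origin_start[1] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  seq_chr <- toupper(gsub("[0-9 ]", "", paste(seq_lines, collapse = "")))

  g <- annotated_genome(seq_chr, feats_tbl, id = id, circular = circular)
  if (nrow(g$features) == 0L) {
    abort("no usable CDS features after skipping untranslatable spans.")
  }
  g
}

#' Write an annotated genome as FASTA + GFF3
#'
#' Companion writer for [read_genome()]'s GFF3 + FASTA layout, used mainly
#' to persist simulated genomes.
#'
#' @param genome An [annotated_genome].
#' @param fasta,gff Output paths.
#' @return `genome`, invisibly.
#' @export
write_genome <- function(genome, fasta, gff) {
  seqs <- Biostrings::DNAStringSet(genome$sequence)
  names(seqs) <- genome$id
  Biostrings::writeXStringSet(seqs, fasta)
  f <- genome$features
  gff_lines <- c(
    "##gff-version 3",
    sprintf(
      "%s\tsynrate\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;gene=%s",
      genome$id, f$start, f$end, f$strand, f$gene, f$gene
    )
  )
  writeLines(gff_lines, gff)
  invisible(genome)
}
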