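# Independent brute-force oracle for site classification: mutate the
# genome string, re-extract every containing CDS, translate it whole with
# Biostrings (start codons as ordinary codons), and compare proteins.
# Shares no code with the package's codon-lookup path.

oracle_translate <- function(x) {
  as.character(Biostrings::translate(
    x, genetic.code = Biostrings::getGeneticCode("11"),
    no.init.codon = TRUE
  ))
}

oracle_cds_string <- function(seq_vec, start, end, strand, len) {
  pos <- ((seq.int(start, end) - 1L) %% len) + 1L
  cds <- paste(seq_vec[pos], collapse = "")
  if (strand == "-") {
    cds <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(cds)
    ))
  }
  cds
}

oracle_compare_proteins <- function(p_ref, p_alt) {
  if (p_ref == p_alt) {
    return("synonymous")
  }
  ref_aa <- strsplit(p_ref, "")[[1]]
  alt_aa <- strsplit(p_alt, "")[[1]]
  changed <- which(ref_aa != alt_aa)
  if (any(alt_aa[changed] == "*")) "nonsense" else "nonsynonymous"
}

oracle_classify <- function(genome, position, alt) {
  seq_vec <- strsplit(as.character(genome$sequence), "")[[1]]
  len <- length(seq_vec)
  feats <- genome$features
  hit <- which(
    (feats$start <= position & feats$end >= position) |
      (feats$end > len & (position + len) >= feats$start &
         (position + len) <= feats$end)
  )
  if (length(hit) == 0L) {
    return("noncoding")
  }
  mut_vec <- seq_vec
  mut_vec[position] <- alt
  classes <- vapply(hit, function(j) {
    ref_cds <- oracle_cds_string(seq_vec, feats$start[j], feats$end[j],
                                 feats$strand[j], len)
    alt_cds <- oracle_cds_string(mut_vec, feats$start[j], feats$end[j],
                                 feats$strand[j], len)
    oracle_compare_proteins(
      oracle_translate(Biostrings::DNAString(ref_cds)),
      oracle_translate(Biostrings::DNAString(alt_cds))
    )
  }, character(1))
  if (all(classes == "synonymous")) {
    "synonymous"
  } else if (any(classes == "nonsense")) {
    "nonsense"
  } else {
    "nonsynonymous"
  }
}

# all (position, alt) coding changes with oracle classification; batched:
# every mutated CDS copy is translated in one DNAStringSet call
oracle_enumerate <- function(genome) {
  seq_vec <- strsplit(as.character(genome$sequence), "")[[1]]
  len <- length(seq_vec)
  feats <- genome$features
  bases <- c("A", "C", "G", "T")

  per_feature <- lapply(seq_len(nrow(feats)), function(j) {
    gpos <- ((seq.int(feats$start[j], feats$end[j]) - 1L) %% len) + 1L
    cds_plus <- seq_vec[gpos]          # plus-strand spelling of the CDS
    n <- length(gpos)
    # every (offset in CDS, alt on plus strand)
    offset <- rep(seq_len(n), each = 3L)
    ref <- cds_plus[offset]
    alt <- unlist(lapply(cds_plus, function(b) setdiff(bases, b)),
                  use.names = FALSE)
    mutated <- rep(paste(cds_plus, collapse = ""), length(offset))
    substr(mutated, offset, offset) <- alt
    to_translate <- Biostrings::DNAStringSet(
      c(paste(cds_plus, collapse = ""), mutated)
    )
    if (feats$strand[j] == "-") {
      to_translate <- Biostrings::reverseComplement(to_translate)
    }
    prots <- as.character(Biostrings::translate(
      to_translate, genetic.code = Biostrings::getGeneticCode("11"),
      no.init.codon = TRUE
    ))
    data.frame(
      pos = gpos[offset], ref = ref, alt = alt,
      class = vapply(prots[-1], oracle_compare_proteins,
                     p_ref = prots[1], character(1), USE.NAMES = FALSE),
      stringsAsFactors = FALSE
    )
  })
  all <- do.call(rbind, per_feature)
  # aggregate across overlapping CDSs: synonymous everywhere, else
  # nonsense anywhere, else nonsynonymous
  key <- paste(all$pos, all$alt)
  agg <- tapply(all$class, key, function(cl) {
    if (all(cl == "synonymous")) "synonymous"
    else if (any(cl == "nonsense")) "nonsense"
    else "nonsynonymous"
  })
  first <- !duplicated(key)
  out <- all[first, c("pos", "ref", "alt")]
  out$class <- as.vector(agg[key[first]])
  out <- out[order(out$pos, out$alt), ]
  rownames(out) <- NULL
  out
}

oracle_opportunities <- function(genome) {
  enum <- oracle_enumerate(genome)
  syn <- enum[enum$class == "synonymous", ]
  type <- classify_type(syn$ref, syn$alt)
  counts <- table(factor(type, levels = mutation_types()))
  stats::setNames(as.numeric(counts[mutation_types()]), mutation_types())
}

# independent exhaustive-summation two-tailed binomial p-value
oracle_two_tailed_binom <- function(x, n, p0) {
  probs <- vapply(0:n, function(k) stats::dbinom(k, n, p0), numeric(1))
  target <- probs[x + 1]
  min(1, sum(probs[probs <= target * (1 + 1e-7)]))
}
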