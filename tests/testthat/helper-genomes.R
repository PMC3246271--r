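# In-code fixtures: the 9-bp single-gene toy and small simulated genomes.

toy_genome <- function() {
  annotated_genome(
    "ATGAAATAA",
    tibble::tibble(gene = "toy", start = 1, end = 9, strand = "+"),
    id = "toy", circular = FALSE
  )
}

# write the toy as GFF3 + FASTA in a temp dir; returns the two paths
toy_genome_files <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  fasta <- file.path(dir, "toy.fasta")
  gff <- file.path(dir, "toy.gff3")
  writeLines(c(">toy", "ATGAAATAA"), fasta)
  writeLines(c(
    "##gff-version 3",
    "toy\ttest\tCDS\t1\t9\t.\t+\t0\tID=toy;gene=toy"
  ), gff)
  list(gff = gff, fasta = fasta)
}

small_sim_genome <- function(len = 6000, gc = 0.5, coding = 0.8, seed = 11) {
  simulate_genome(sim_config(
    genome_length = len, gc = gc, coding_fraction = coding, seed = seed
  ))
}

# tiny GenBank flat file with two CDS (one on the minus strand)
toy_genbank_file <- function(path = withr::local_tempfile(fileext = ".gb",
                                                          .local_envir = parent.frame())) {
  # 60 bp; gene A at 1..9 (+), gene B at 13..21 (complement)
  seqs <- paste0(
    "atgaaataa", "cgt", "ttacatcat", "acgtacgtacgtacgtacgtacgtacgt",
    "acgtacgtacg"
  )
  stopifnot(nchar(seqs) == 60)
  lines <- c(
    "LOCUS       TOYREC                 60 bp    DNA     circular BCT 01-JAN-2000",
    "DEFINITION  toy record.",
    "ACCESSION   TOYREC",
    "FEATURES             Location/Qualifiers",
    "     source          1..60",
    "     CDS             1..9",
    '                     /gene="toyA"',
    "     CDS             complement(13..21)",
    '                     /locus_tag="toyB"',
    "ORIGIN",
    paste0("        1 ", paste(substring(seqs, seq(1, 60, 10),
                                         pmin(seq(10, 69, 10), 60)),
                               collapse = " ")),
    "//"
  )
  writeLines(lines, path)
  path
}
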