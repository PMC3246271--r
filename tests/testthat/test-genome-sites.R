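test_that("toy genome loads from GFF3 + FASTA with one 9-bp gene", {
  paths <- toy_genome_files()
  g <- read_genome(paths$gff, fasta = paths$fasta)
  expect_s3_class(g, "annotated_genome")
  expect_equal(nrow(g$features), 1L)
  expect_equal(genome_length(g), 9L)
  expect_equal(simple_synonymous_sites(g), 3)
})

test_that("GenBank flat files parse: sequence, strands, locus_tag fallback", {
  path <- toy_genbank_file()
  g <- read_genome(path)
  expect_equal(genome_length(g), 60L)
  expect_true(g$circular)
  expect_equal(nrow(g$features), 2L)
  expect_setequal(g$features$gene, c("toyA", "toyB"))
  expect_equal(g$features$strand[g$features$gene == "toyB"], "-")
  # minus-strand gene reads ATG ATG TAA
  gene_b <- substr(as.character(g$sequence), 13, 21)
  expect_equal(
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(gene_b))),
    "ATGATGTAA"
  )
})

test_that("sequences with ambiguity codes are rejected at load", {
  expect_error(
    annotated_genome("ATGNNNTAA",
                     tibble::tibble(gene = "g", start = 1, end = 9,
                                    strand = "+")),
    "A, C, G, T"
  )
})

test_that("untranslatable CDS spans are skipped with a warning and counted", {
  expect_warning(
    g <- annotated_genome(
      strrep("ACGT", 10),
      tibble::tibble(gene = c("ok", "bad10"), start = c(1, 11),
                     end = c(9, 20), strand = "+")
    ),
    "skipped"
  )
  expect_equal(nrow(g$features), 1L)
  expect_equal(g$n_skipped_features, 1L)

  # a file whose only CDS is untranslatable is a content error
  dir <- withr::local_tempdir()
  fasta <- file.path(dir, "g.fasta")
  gff <- file.path(dir, "g.gff3")
  writeLines(c(">g", strrep("ACGT", 10)), fasta)
  writeLines(c("##gff-version 3",
               "g\tt\tCDS\t1\t10\t.\t+\t0\tID=x;gene=x"), gff)
  suppressWarnings(expect_error(read_genome(gff, fasta = fasta),
                                "no usable CDS"))
})

test_that("classify_change matches the codon table on the toy gene", {
  toy <- toy_genome()
  expect_equal(classify_change(toy, 6, "G"), "synonymous")    # AAA -> AAG
  expect_equal(classify_change(toy, 4, "G"), "nonsynonymous") # AAA -> GAA
  expect_error(classify_change(toy, 1, "A"), "reference")
  expect_error(classify_change(toy, 6, "N"), "base")
})

test_that("positions outside every CDS classify as noncoding", {
  g <- annotated_genome(
    "ATGAAATAACCC",
    tibble::tibble(gene = "g", start = 1, end = 9, strand = "+"),
    circular = FALSE
  )
  expect_equal(classify_change(g, 11, "T"), "noncoding")
})

test_that("classify_change agrees with the translation oracle everywhere", {
  for (g in list(toy_genome(),
                 small_sim_genome(len = 3000, coding = 0.7, seed = 4))) {
    enum <- oracle_enumerate(g)
    idx <- seq_len(nrow(enum))
    if (length(idx) > 600) idx <- sort(sample(idx, 600))
    got <- classify_change(g, enum$pos[idx], enum$alt[idx])
    expect_identical(got, enum$class[idx])
  }
})

test_that("synonymous opportunities equal brute-force enumeration exactly", {
  toy <- toy_genome()
  opp <- synonymous_opportunities(toy)
  expect_equal(
    stats::setNames(opp$opportunities, opp$type),
    oracle_opportunities(toy)
  )

  g <- small_sim_genome(len = 4000, gc = 0.55, coding = 0.8, seed = 9)
  opp_g <- synonymous_opportunities(g)
  expect_equal(
    stats::setNames(opp_g$opportunities, opp_g$type),
    oracle_opportunities(g)
  )
})

test_that("GGG codon third position offers the three GC-origin changes", {
  # interior GGG codon: ATG GGG AAA TAA; third position of GGG is 4-fold
  g <- annotated_genome(
    "ATGGGGAAATAA",
    tibble::tibble(gene = "g", start = 1, end = 12, strand = "+"),
    circular = FALSE
  )
  expect_equal(classify_change(g, 6, "A"), "synonymous")
  expect_equal(classify_change(g, 6, "C"), "synonymous")
  expect_equal(classify_change(g, 6, "T"), "synonymous")
  opp <- synonymous_opportunities(g)
  expect_equal(
    stats::setNames(opp$opportunities, opp$type),
    oracle_opportunities(g)
  )
})

test_that("opportunity totals are conserved and bounded", {
  g <- small_sim_genome(len = 4000, seed = 2)
  opp <- synonymous_opportunities(g)
  comp <- site_composition(opp)
  enum <- oracle_enumerate(g)
  expect_equal(sum(opp$opportunities), sum(enum$class == "synonymous"))
  expect_lte(sum(opp$opportunities), 3 * comp$coding_length)
  expect_equal(comp$f_at + comp$f_gc, 1, tolerance = 1e-12)
})

test_that("opportunity tables are strand-symmetric and deterministic", {
  g <- small_sim_genome(len = 4000, gc = 0.6, seed = 6)
  opp1 <- synonymous_opportunities(g)
  len <- genome_length(g)
  rc <- annotated_genome(
    as.character(Biostrings::reverseComplement(g$sequence)),
    tibble::tibble(
      gene = g$features$gene,
      start = len - g$features$end + 1L,
      end = len - g$features$start + 1L,
      strand = ifelse(g$features$strand == "+", "-", "+")
    ),
    id = "rc", circular = g$circular
  )
  opp2 <- synonymous_opportunities(rc)
  expect_equal(opp1$opportunities, opp2$opportunities)
  expect_equal(site_composition(opp1)$f_at, site_composition(opp2)$f_at)

  opp3 <- synonymous_opportunities(g)
  expect_identical(opp1$opportunities, opp3$opportunities)
})

test_that("overlapping CDS count coding bp once and classify conservatively", {
  # two overlapping plus-strand genes sharing bases 7..12
  g <- annotated_genome(
    paste0("ATGAAACCCTAA", "ATGCCCAAATAA"),
    tibble::tibble(gene = c("g1", "g2"), start = c(1, 7), end = c(12, 18),
                   strand = "+"),
    circular = FALSE
  )
  opp <- synonymous_opportunities(g)
  expect_equal(site_composition(opp)$coding_length, 18L)
  enum <- oracle_enumerate(g)
  expect_equal(
    stats::setNames(opp$opportunities, opp$type),
    oracle_opportunities(g)
  )
  got <- classify_change(g, enum$pos, enum$alt)
  expect_identical(got, enum$class)
})

test_that("expected spectrum normalizes opportunities and sums to one", {
  g <- small_sim_genome(len = 3000, seed = 13)
  opp <- synonymous_opportunities(g)
  es <- expected_spectrum(opp)
  expect_equal(sum(es$expected), 1, tolerance = 1e-12)
  expect_true(all(es$expected >= 0))
  expect_equal(es$expected, opp$opportunities / sum(opp$opportunities))

  uni <- opp
  uni$opportunities <- rep(10, 6)
  expect_equal(expected_spectrum(uni)$expected, rep(1 / 6, 6))
})

test_that("opportunity tables round-trip through TSV + JSON sidecar", {
  g <- small_sim_genome(len = 3000, seed = 5)
  opp <- synonymous_opportunities(g)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_opportunity_table(opp, path)
  back <- read_opportunity_table(path)
  expect_equal(back$opportunities, opp$opportunities)
  expect_equal(site_composition(back), site_composition(opp))
})

test_that("a genome without CDS features refuses site operations", {
  cfg <- sim_config(coding_fraction = 0, seed = 3)
  g <- simulate_genome(cfg)
  expect_equal(nrow(g$features), 0L)
  expect_error(simple_synonymous_sites(g), "no CDS")
  expect_error(synonymous_opportunities(g), "no CDS")
})
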