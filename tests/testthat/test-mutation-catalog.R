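test_that("the packaged mutation table holds 52 records collapsing to 35 events", {
  recs <- ltee_mutations()
  expect_equal(nrow(recs), 52L)
  ev <- collapse_events(recs)
  expect_equal(nrow(ev), 35L)
  expect_equal(sum(ev$n_carriers), 52L)
  # events carried by several clones never straddle populations
  expect_true(all(vapply(
    seq_len(nrow(ev)),
    function(i) length(unique(ev$carriers[[i]]$clone)) == ev$n_carriers[i],
    logical(1)
  )))
})

test_that("per-type tallies of the packaged events match the hand count", {
  ev <- collapse_events(ltee_mutations())
  sc <- spectrum_counts(ev)
  expect_equal(
    stats::setNames(sc$count, sc$type),
    c("AT>GC" = 1L, "AT>CG" = 6L, "AT>TA" = 4L,
      "GC>AT" = 18L, "GC>TA" = 6L, "GC>CG" = 0L)
  )
  expect_equal(attr(sc, "transitions"), 19L)
  expect_equal(attr(sc, "transversions"), 16L)
  expect_equal(sum(sc$count), nrow(ev))
})

test_that("strand collapse of base changes is total, 2-to-1, and involutive", {
  bases <- c("A", "C", "G", "T")
  pairs <- expand.grid(ref = bases, alt = bases, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  types <- classify_type(pairs$ref, pairs$alt)
  expect_false(anyNA(types))
  expect_equal(unname(table(factor(types, levels = mutation_types()))),
               rep(2L, 6), ignore_attr = TRUE)
  # complementing both bases never changes the category
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  expect_identical(types,
                   classify_type(comp[pairs$ref], comp[pairs$alt]))
  expect_identical(is_transition(c("AT>GC", "GC>AT", "AT>CG", "GC>CG")),
                   c(TRUE, TRUE, FALSE, FALSE))
})

test_that("mutation tables round-trip and malformed rows are reported", {
  recs <- ltee_mutations()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_mutation_table(recs, path)
  back <- read_mutation_table(path)
  expect_equal(as.data.frame(back), as.data.frame(recs))

  # empty file with header -> empty table
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("population\tclone\tgeneration\tposition\tref\talt", empty)
  expect_equal(nrow(read_mutation_table(empty)), 0L)

  # missing column is a format error
  bad_cols <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("population\tclone\tgeneration", "a\tb\t1"), bad_cols)
  expect_error(read_mutation_table(bad_cols), "required column")

  # ref == alt names the offending row
  bad_row <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "population\tclone\tgeneration\tposition\tref\talt",
    "p\tc1\t1000\t5\tA\tG",
    "p\tc1\t1000\t9\tC\tC"
  ), bad_row)
  expect_error(read_mutation_table(bad_row), "ref equals alt.*row.* 2")
})

test_that("collapse keeps distinct alternates and distinct populations apart", {
  recs <- tibble::tibble(
    population = c("p1", "p1", "p1", "p2"),
    clone = c("c1", "c2", "c1", "c1"),
    generation = 1000,
    position = c(10L, 10L, 10L, 10L),
    ref = "C", alt = c("T", "T", "A", "T"),
    coding_class = "synonymous"
  )
  ev <- collapse_events(recs)
  expect_equal(nrow(ev), 3L)           # C>T in p1, C>A in p1, C>T in p2
  expect_equal(ev$n_carriers[ev$population == "p1" & ev$alt == "T"], 2L)

  one <- collapse_events(recs[1, ])
  expect_equal(nrow(one), 1L)
  expect_equal(one$n_carriers, 1L)
})

test_that("records never number fewer than events, with equality iff all private", {
  recs <- ltee_mutations()
  ev <- collapse_events(recs)
  expect_gte(nrow(recs), nrow(ev))
  private <- recs[!duplicated(recs[c("population", "position", "alt")]), ]
  expect_equal(nrow(collapse_events(private)), nrow(private))
})

test_that("clone observations carry counts, exposures, and Poisson zeros", {
  recs <- ltee_mutations()
  clones <- ltee_clones()
  opp <- synonymous_opportunities(small_sim_genome(len = 3000, seed = 1))
  obs <- build_clone_observations(recs, clones, opportunity = opp)
  expect_equal(nrow(obs), 19L * 6L)
  expect_equal(sum(obs$m), 52L)
  # Ara-1 clones and Ara+2 40K-B carry nothing
  ara1 <- obs[obs$population == "Ara-1", ]
  expect_equal(nrow(ara1), 3L * 6L)
  expect_true(all(ara1$m == 0L))
  expect_true(all(ara1$t == 20000))
  expect_true(all(obs$m[obs$population == "Ara+2" &
                          obs$clone == "40K-B"] == 0L))
  # fallback sites are the ancestral per-type opportunities
  expect_equal(
    unique(obs$s[obs$type == "GC>AT"]),
    opp$opportunities[opp$type == "GC>AT"]
  )
})

test_that("per-clone callable tables override the ancestral fallback", {
  recs <- ltee_mutations()
  clones <- ltee_clones()
  opp <- synonymous_opportunities(small_sim_genome(len = 3000, seed = 1))
  callable <- tidyr::crossing(
    clone = unique(clones$clone), type = mutation_types()
  )
  lut <- stats::setNames(opp$opportunities, opp$type)
  callable$sites <- 0.5 * lut[callable$type]
  obs_half <- build_clone_observations(recs, clones, opportunity = opp,
                                       callable = callable)
  obs_full <- build_clone_observations(recs, clones, opportunity = opp)
  expect_equal(obs_half$s, 0.5 * obs_full$s)

  # a clone absent from the manifest is a content error
  expect_error(
    build_clone_observations(recs, clones[clones$population != "Ara+5", ],
                             opportunity = opp),
    "absent from the manifest"
  )
})
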