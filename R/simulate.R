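# Forward simulation of mutation-accumulation experiments.
#
# The generator mirrors the design it is meant to test: replicate
# populations propagated independently, several clones sampled per
# population, and a star-like within-population genealogy -- every clone
# shares a common lineage prefix (a fraction `shared_fraction` of its
# generations) and then accumulates private mutations.  Mutations of each
# of the six types arrive as a Poisson process on every branch and land
# uniformly over the genomic sites carrying the type's ancestral base
# pair; each landed change is then classified against the annotation.
# All mutations are neutral: selection is deliberately absent, matching
# the estimator's core assumption that synonymous changes accumulate
# clock-like.

#' Configuration for a simulated mutation-accumulation experiment
#'
#' Defaults describe a coding-dense bacterial chromosome sampled the way
#' the packaged long-term experiment was: eight replicate populations,
#' two clones each after 40,000 generations, with 60% of each clone's
#' history spent on its population's shared lineage (chosen to match the
#' packaged mutation table, where 15 of 35 events are carried by more
#' than one clone).
#'
#' @param genome_length Genome size in bp (at least 3 kb so codon
#'   statistics are meaningful).
#' @param gc Target GC fraction of the genome.
#' @param coding_fraction Fraction of the genome covered by CDS.
#' @param n_populations Number of replicate populations.
#' @param clones_per_population Clones sampled per population.
#' @param generations Generations elapsed per clone (scalar, or vector of
#'   length `clones_per_population`).
#' @param shared_fraction Fraction of each clone's generations spent on
#'   the population's common lineage, in `[0, 1]`.
#' @param mu Named per-type mutation rates (per ancestral base pair per
#'   generation); `NULL` means "calibrate with [ltee_like_rates()] when a
#'   genome is available".
#' @param seed Random seed (drives genome construction and, by default,
#'   mutation placement).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 30000, gc = 0.5,
                       coding_fraction = 0.85, n_populations = 8,
                       clones_per_population = 2, generations = 40000,
                       shared_fraction = 0.6, mu = NULL, seed = 1) {
  stopifnot(
    genome_length >= 3000,
    gc >= 0, gc <= 1,
    coding_fraction >= 0, coding_fraction <= 1,
    n_populations >= 1, clones_per_population >= 1,
    all(generations > 0),
    shared_fraction >= 0, shared_fraction <= 1
  )
  if (!is.null(mu)) {
    mu <- mu[mutation_types()]
    if (anyNA(mu) || any(mu < 0)) {
      abort("`mu` must be a non-negative vector named by the six types.")
    }
  }
  structure(
    list(
      genome_length = as.integer(genome_length), gc = gc,
      coding_fraction = coding_fraction,
      n_populations = as.integer(n_populations),
      clones_per_population = as.integer(clones_per_population),
      generations = rep_len(generations, clones_per_population),
      shared_fraction = shared_fraction,
      mu = mu, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# base-sampling probability g such that interior codons conditioned on
# not being a stop have mean GC content `target`
interior_gc_prob <- function(target) {
  cond_gc <- function(g) {
    a <- (1 - g) / 2
    c2 <- g / 2
    p_taa <- a^3
    p_tag <- a^2 * c2
    p_tga <- a^2 * c2
    p_stop <- p_taa + p_tag + p_tga
    (3 * g - (p_tag + p_tga)) / (3 * (1 - p_stop)) - target
  }
  if (target <= 0) return(0)
  if (target >= 1) return(1)
  uniroot(cond_gc, c(1e-6, 1 - 1e-6), tol = 1e-12)$root
}

sample_bases <- function(n, gc) {
  sample(dna_bases, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

#' Simulate an annotated coding-dense genome
#'
#' Draws a random circular genome at the configured GC content and tiles
#' it with non-overlapping CDS features on random strands until the
#' coding fraction is met.  Genes are built as start codon + interior
#' codons (stop-free, with the base distribution adjusted so the realized
#' GC still hits the target) + stop codon.  Deterministic given
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @return An [annotated_genome].
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  len <- config$genome_length
  gc <- config$gc
  seq_vec <- sample_bases(len, gc)

  feats <- list()
  if (config$coding_fraction > 0) {
    g_int <- interior_gc_prob(gc)
    stops <- c("TAA", "TAG", "TGA")
    stop_prob <- c((1 - gc)^2 / 4 * (1 - gc) / 2,
                   (1 - gc)^2 / 4 * gc / 2,
                   (1 - gc)^2 / 4 * gc / 2)
    if (sum(stop_prob) == 0) stop_prob <- c(1, 1, 1)
    pos <- 1L
    while (TRUE) {
      n_cod <- sample(100:400, 1)
      gene_len <- 3L * (n_cod + 2L)
      if (pos + gene_len - 1L > len) break
      # interior codons, resampling any that form a stop
      ncods <- n_cod
      bases <- sample_bases(3L * ncods, g_int)
      cod_mat <- matrix(bases, nrow = 3L)
      repeat {
        cods <- paste0(cod_mat[1, ], cod_mat[2, ], cod_mat[3, ])
        bad <- cods %in% stops
        if (!any(bad)) break
        cod_mat[, bad] <- matrix(sample_bases(3L * sum(bad), g_int),
                                 nrow = 3L)
      }
      gene_seq <- c("A", "T", "G", as.vector(cod_mat),
                    strsplit(sample(stops, 1, prob = stop_prob), "")[[1]])
      strand <- sample(c("+", "-"), 1)
      if (strand == "-") {
        gene_seq <- rev(chartr("ACGT", "TGCA", gene_seq))
      }
      idx <- pos:(pos + gene_len - 1L)
      seq_vec[idx] <- gene_seq
      feats[[length(feats) + 1L]] <- tibble(
        gene = sprintf("gene%04d", length(feats) + 1L),
        start = pos, end = pos + gene_len - 1L, strand = strand
      )
      mean_gap <- gene_len * (1 - config$coding_fraction) /
        max(config$coding_fraction, 1e-9)
      gap <- as.integer(round(runif(1, 0.5, 1.5) * mean_gap))
      pos <- pos + gene_len + gap
    }
    if (length(feats) == 0L) {
      abort("coding fraction infeasible: no gene fits in the genome.")
    }
  }
  features <- if (length(feats) > 0L) {
    dplyr::bind_rows(feats)
  } else {
    tibble(gene = character(), start = integer(), end = integer(),
           strand = character())
  }
  annotated_genome(
    paste(seq_vec, collapse = ""), features,
    id = sprintf("sim_seed%d", config$seed), circular = TRUE
  )
}

#' Per-type rates shaped like the observed long-term spectrum
#'
#' Builds a named per-type rate vector whose relative sizes follow the
#' event spectrum of the packaged mutation table (18:1:6:4:6 with a small
#' positive floor for the unobserved GC>CG class) and whose overall scale
#' is calibrated so one simulated dataset under `config` expects about
#' `target_events` synonymous mutational events -- the yield of the study
#' the generator emulates.
#'
#' @param genome An [annotated_genome] (its per-type opportunities set
#'   the scale).
#' @param config A [sim_config()].
#' @param target_events Expected number of synonymous events per dataset.
#' @param relative Named relative per-type rates.
#' @return Named per-type rate vector (per ancestral base pair per
#'   generation).
#' @export
ltee_like_rates <- function(genome, config, target_events = 35,
                            relative = c(
                              "AT>GC" = 1, "AT>CG" = 6, "AT>TA" = 4,
                              "GC>AT" = 18, "GC>TA" = 6, "GC>CG" = 0.5
                            )) {
  relative <- relative[mutation_types()]
  if (anyNA(relative)) {
    abort("`relative` must be named by the six mutation types.")
  }
  opp <- synonymous_opportunities(genome)
  s_c <- setNames(opp$opportunities, opp$type)
  t_cl <- config$generations
  shared <- config$shared_fraction * min(t_cl)
  branch_total <- config$n_populations * (shared + sum(t_cl - shared))
  expected_per_unit <- sum(relative * s_c) * branch_total
  if (expected_per_unit <= 0) {
    abort("no synonymous opportunities: cannot calibrate rates.")
  }
  k <- target_events / expected_per_unit
  setNames(k * relative, names(relative))
}

alt_for_type <- function(ref, type) {
  origin <- substr(type, 1, 2)
  altpair <- substr(type, 4, 5)
  ifelse(ref == substr(origin, 1, 1),
         substr(altpair, 1, 1), substr(altpair, 2, 2))
}

#' Simulate mutation accumulation over a clone genealogy
#'
#' For each population, lays out one shared branch (`shared_fraction` of
#' the shortest clone's generations) and one private branch per clone,
#' draws per-type mutation counts on every branch as Poisson with mean
#' `mu[type] * branch length * (number of genomic sites carrying the
#' type's ancestral pair)`, places them uniformly over those sites
#' (resampling collisions within a population: infinite-sites
#' convention), classifies each placed change against the annotation, and
#' expands shared-branch mutations to every clone of the population.
#'
#' @param genome An [annotated_genome].
#' @param config A [sim_config()]; a `NULL` `config$mu` is filled by
#'   [ltee_like_rates()].
#' @param seed Seed for mutation placement (defaults to `config$seed`).
#' @return A list of class `sim_result` with `records` (clone-level
#'   mutation tibble, all coding classes), `clones` (manifest),
#'   `truth` (list: `mu`, `combined_rate`, `mutations` per-branch tibble,
#'   `n_resampled`, `seed`) and `genome_id`.
#' @export
simulate_mutations <- function(genome, config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  mu <- config$mu %||% ltee_like_rates(genome, config)
  mu <- mu[mutation_types()]

  seq_vec <- split_sequence(genome)
  idx_origin <- list(
    AT = which(seq_vec %in% c("A", "T")),
    GC = which(seq_vec %in% c("G", "C"))
  )
  n_origin <- vapply(idx_origin, length, integer(1))
  changes <- if (nrow(genome$features) > 0L) {
    coding_change_table_cached(genome)
  } else {
    tibble(pos = integer(), ref = character(), alt = character(),
           class = character())
  }
  comp <- list(
    f_at = n_origin[["AT"]] / sum(n_origin),
    f_gc = n_origin[["GC"]] / sum(n_origin)
  )

  t_cl <- config$generations
  shared_len <- config$shared_fraction * min(t_cl)
  clone_names <- sprintf("clone%02d", seq_len(config$clones_per_population))
  pops <- sprintf("pop%02d", seq_len(config$n_populations))

  n_resampled <- 0L
  all_branch_mut <- list()
  records <- list()

  for (p in pops) {
    used <- integer(0)
    branches <- c(
      list(list(name = "shared", len = shared_len, clones = clone_names)),
      purrr::map(seq_along(clone_names), function(i) {
        list(name = clone_names[i], len = t_cl[i] - shared_len,
             clones = clone_names[i])
      })
    )
    for (br in branches) {
      if (br$len <= 0) next
      for (ty in mutation_types()) {
        origin <- type_origin(ty)
        n_mut <- rpois(1, mu[[ty]] * br$len * n_origin[[origin]])
        if (n_mut == 0L) next
        if (n_mut > n_origin[[origin]]) {
          abort("mutation rate too high: more mutations than sites.")
        }
        posn <- sample(idx_origin[[origin]], n_mut)
        # infinite-sites: resample collisions within the population
        while (any(posn %in% used) || anyDuplicated(posn) > 0L) {
          clash <- posn %in% used | duplicated(posn)
          n_resampled <- n_resampled + sum(clash)
          posn[clash] <- sample(idx_origin[[origin]], sum(clash))
        }
        used <- c(used, posn)
        ref <- seq_vec[posn]
        alt <- alt_for_type(ref, ty)
        all_branch_mut[[length(all_branch_mut) + 1L]] <- tibble(
          population = p, branch = br$name, position = posn,
          ref = ref, alt = alt, type = ty
        )
      }
    }
  }

  branch_mut <- if (length(all_branch_mut) > 0L) {
    dplyr::bind_rows(all_branch_mut)
  } else {
    tibble(population = character(), branch = character(),
           position = integer(), ref = character(), alt = character(),
           type = character())
  }

  # classify against the annotation and attach gene names
  branch_mut <- dplyr::left_join(
    branch_mut, changes, by = c("position" = "pos", "ref", "alt")
  )
  branch_mut$class[is.na(branch_mut$class)] <- "noncoding"
  branch_mut$gene <- feature_at(genome, branch_mut$position)

  if (sum(vapply(all_branch_mut, nrow, integer(1))) > 0L) {
    total_mut <- nrow(branch_mut)
    if (n_resampled > 0.01 * total_mut) {
      warn(sprintf(
        "infinite-sites resampling touched %d of %d mutations (> 1%%); rates may be too high for this genome",
        n_resampled, total_mut
      ))
    }
  }

  # expand to clone-level records
  clones_tbl <- tidyr::crossing(
    population = pops,
    tibble(clone = clone_names, generation = t_cl)
  )
  expand_one <- function(row_pop, row_branch) {
    if (row_branch == "shared") clone_names else row_branch
  }
  rec <- branch_mut
  rec$carriers <- purrr::map2(rec$population, rec$branch, expand_one)
  rec <- tidyr::unnest(
    dplyr::mutate(rec, clone = .data$carriers), "clone"
  )
  gen_lookup <- setNames(t_cl, clone_names)
  records <- tibble(
    population = rec$population,
    clone = rec$clone,
    generation = unname(gen_lookup[rec$clone]),
    position = rec$position,
    gene = rec$gene,
    ref = rec$ref,
    alt = rec$alt,
    coding_class = rec$class
  )
  records <- records[order(records$population, records$clone,
                           records$position), ]

  structure(
    list(
      records = records,
      clones = clones_tbl,
      truth = list(
        mu = mu,
        combined_rate = combine_rates(mu, comp),
        composition = comp,
        mutations = branch_mut[, c("population", "branch", "position",
                                   "ref", "alt", "type", "class")],
        n_resampled = n_resampled,
        seed = seed
      ),
      genome_id = genome$id
    ),
    class = "sim_result"
  )
}

# gene name of the feature containing each position (NA if noncoding)
feature_at <- function(genome, position) {
  if (length(position) == 0L) return(character(0))
  feats <- genome$features
  len <- genome_length(genome)
  vapply(position, function(p) {
    hit <- which(
      (feats$start <= p & feats$end >= p) |
        (feats$end > len & (p + len) >= feats$start & (p + len) <= feats$end)
    )
    if (length(hit) == 0L) NA_character_ else feats$gene[hit[1]]
  }, character(1))
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(
    "<sim_result> %d mutation event(s) -> %d clone-level record(s) on %s (seed %d)\n",
    nrow(x$truth$mutations), nrow(x$records), x$genome_id, x$truth$seed
  ))
  invisible(x)
}

#' Parameter-recovery experiment for the blocked estimator
#'
#' The package's end-to-end validation harness: simulate one genome under
#' `config`, then repeatedly (i) simulate mutation accumulation, (ii)
#' build clone observations from the synonymous records, (iii) fit the
#' blocked Poisson maximum-likelihood model, and (iv) jackknife the
#' combined rate over populations.  Reports per-replicate estimates and
#' interval limits together with bias, RMSE and interval coverage of the
#' true combined rate.
#'
#' @param config A [sim_config()].
#' @param replicates Number of simulated datasets (at least 2).
#' @param seed Seed for the replicate stream (the genome itself uses
#'   `config$seed`).
#' @param level Confidence level for the jackknife intervals.
#' @return An object of class `recovery_report`: `replicates` tibble
#'   (`estimate`, `lower`, `upper`, `covered`, `n_syn_records`,
#'   `n_events`), `truth` (true combined rate), `summary` list (mean
#'   estimate, bias, relative bias, RMSE, coverage), plus the config.
#' @export
recovery_experiment <- function(config, replicates, seed = 1,
                                level = 0.95) {
  stopifnot(inherits(config, "sim_config"), replicates >= 2)
  genome <- simulate_genome(config)
  opp <- synonymous_opportunities(genome)
  mu <- config$mu %||% ltee_like_rates(genome, config)
  cfg <- config
  cfg$mu <- mu

  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, replicates)

  rows <- purrr::map(seq_len(replicates), function(i) {
    sim <- simulate_mutations(genome, cfg, seed = rep_seeds[i])
    obs <- build_clone_observations(
      sim$records, sim$clones, opportunity = opp
    )
    fit <- fit_blocked_ml(obs, composition = opp)
    jk <- jackknife_ci(
      function(o) fit_blocked_ml(o, composition = opp)$combined_rate,
      obs, level = level
    )
    truth <- sim$truth$combined_rate
    tibble(
      replicate = i,
      estimate = fit$combined_rate,
      lower = jk$lower, upper = jk$upper,
      covered = jk$lower <= truth & truth <= jk$upper,
      n_syn_records = sum(obs$m),
      n_events = nrow(sim$truth$mutations)
    )
  })
  reps <- dplyr::bind_rows(rows)
  truth <- combine_rates(mu, opp)
  err <- reps$estimate - truth
  structure(
    list(
      replicates = reps,
      truth = truth,
      mu = mu,
      summary = list(
        mean_estimate = mean(reps$estimate),
        bias = mean(err),
        relative_bias = mean(err) / truth,
        rmse = sqrt(mean(err^2)),
        coverage = mean(reps$covered),
        level = level,
        n_replicates = replicates
      ),
      config = cfg,
      genome_id = genome$id
    ),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0(
      "<recovery_report> %d replicate(s) on %s\n",
      "true combined rate %.4g; mean estimate %.4g ",
      "(relative bias %+.2f%%, RMSE %.3g)\n",
      "jackknife %g%% CI coverage: %.3f\n"
    ),
    s$n_replicates, x$genome_id, x$truth, s$mean_estimate,
    100 * s$relative_bias, s$rmse, 100 * s$level, s$coverage
  ))
  invisible(x)
}
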