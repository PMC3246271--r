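# Base-substitution rate estimation.
#
# Two estimators are exposed.  The simple cross-study estimator divides
# the observed synonymous count by (cumulative generations x effective
# synonymous sites) and gets an exact binomial CI.  The blocked Poisson
# maximum-likelihood estimator models per-type synonymous counts in each
# clone as Poisson with mean mu_c * t * s, averages log-likelihoods over
# clones within each population block to undo pseudo-replication from
# shared ancestry, combines per-type rates by ancestral base-pair
# composition, and attaches Tukey jackknife confidence limits from
# delete-one-population re-estimates.

#' Simple per-site mutation rate with exact binomial confidence limits
#'
#' The cross-study estimator: the number of observed synonymous mutations
#' divided by the product of cumulative generations and the effective
#' number of synonymous target sites.  Treating each site-generation as
#' an independent Bernoulli trial gives exact (Clopper-Pearson) binomial
#' confidence limits on the per-trial probability.
#'
#' @param m Observed synonymous mutation count (non-negative integer).
#' @param generations Cumulative generations summed over the clones.
#' @param sites Effective synonymous target sites (e.g.
#'   [simple_synonymous_sites()]).
#' @param level Confidence level for the binomial interval.
#' @return An object of class `rate_estimate` with fields `rate`,
#'   `lower`, `upper`, `level`, `m`, `generations`, `sites`, `method`.
#' @examples
#' est <- point_estimate_simple(25, 300000, 941000)
#' signif(est$rate * 1e11, 2)  # 8.9, in units of 1e-11 per bp per generation
#' @export
point_estimate_simple <- function(m, generations, sites, level = 0.95) {
  if (!isTRUE(generations > 0) || !isTRUE(sites > 0)) {
    abort("`generations` and `sites` must both be positive.")
  }
  if (!isTRUE(m >= 0) || m != round(m)) {
    abort("`m` must be a non-negative integer count.")
  }
  trials <- generations * sites
  ci <- binomial_rate_ci(m, trials, level = level)
  structure(
    list(
      rate = m / trials,
      lower = ci[["lower"]], upper = ci[["upper"]], level = level,
      m = m, generations = generations, sites = sites,
      method = "simple"
    ),
    class = "rate_estimate"
  )
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf(
    "<rate_estimate: %s> %.3g per bp per generation [%.2g-%.2g, %g%% %s]\n",
    x$method, x$rate, x$lower, x$upper, 100 * x$level,
    if (x$method == "simple") "binomial" else "jackknife"
  ))
  invisible(x)
}

#' Exact binomial (Clopper-Pearson) limits on a per-trial rate
#'
#' Two-sided exact confidence limits on the success probability of a
#' binomial with `m` successes in `trials` trials.  The lower limit is
#' exactly 0 when `m = 0`.  `trials` may be a (large, non-integer)
#' effective trial count such as generations x sites.
#'
#' @param m Success count.
#' @param trials Number of trials (`trials >= m`).
#' @param level Confidence level.
#' @return Named numeric vector `c(lower = , upper = )`.
#' @export
binomial_rate_ci <- function(m, trials, level = 0.95) {
  if (!isTRUE(level > 0 && level < 1)) {
    abort("`level` must be in (0, 1).")
  }
  if (m < 0 || m > trials) {
    abort("need 0 <= m <= trials.")
  }
  a <- 1 - level
  lower <- if (m == 0) 0 else qbeta(a / 2, m, trials - m + 1)
  upper <- if (m >= trials) 1 else qbeta(1 - a / 2, m + 1, trials - m)
  c(lower = lower, upper = upper)
}

#' @rdname binomial_rate_ci
#' @description `poisson_rate_ci()` gives the exact Poisson (chi-square
#'   form) limits on a rate from a count over an exposure; the binomial
#'   limits converge to these as `trials` grows.
#' @param exposure Exposure (trials) over which `m` events were counted.
#' @export
poisson_rate_ci <- function(m, exposure, level = 0.95) {
  if (!isTRUE(exposure > 0)) abort("`exposure` must be positive.")
  a <- 1 - level
  lower <- if (m == 0) 0 else qchisq(a / 2, 2 * m) / 2 / exposure
  upper <- qchisq(1 - a / 2, 2 * m + 2) / 2 / exposure
  c(lower = lower, upper = upper)
}

#' Block-averaged Poisson log-likelihood for per-type rates
#'
#' The log-likelihood of per-type rates `mu` given per-clone observations.
#' Each clone's per-type synonymous count is Poisson with mean
#' `mu[type] * t * s`; clone log-likelihoods are *averaged* within each
#' population block (clones of one population pseudo-replicate their
#' shared history) and the block averages are summed.
#'
#' With `lgamma(m + 1)` as the factorial term and the convention
#' `0 * log(0) = 0`; a zero rate facing a nonzero count gives `-Inf`.
#'
#' @param observations Long tibble from [build_clone_observations()]:
#'   columns `population`, `clone`, `t`, `type`, `m`, `s`.
#' @param mu Named numeric vector of per-type rates (names from
#'   [mutation_types()]), per ancestral base pair per generation.
#' @return The blocked log-likelihood (a single number, possibly `-Inf`).
#' @export
blocked_loglik <- function(observations, mu) {
  mu <- mu[as.character(observations$type)]
  if (anyNA(mu)) {
    abort("`mu` must be named by the six mutation types.")
  }
  if (any(mu < 0)) abort("rates must be non-negative.")
  lambda <- mu * observations$t * observations$s
  ll <- ifelse(
    observations$m == 0,
    -lambda,
    observations$m * log(lambda) - lambda - lgamma(observations$m + 1)
  )
  # m > 0 with lambda = 0 -> log(0) = -Inf, as intended
  per_clone <- dplyr::summarise(
    dplyr::group_by(
      tibble(population = observations$population,
             clone = observations$clone, ll = ll),
      .data$population, .data$clone
    ),
    ll = sum(.data$ll), .groups = "drop_last"
  )
  sum(dplyr::summarise(per_clone, ll = mean(.data$ll))$ll)
}

#' Blocked maximum-likelihood estimate of the six substitution rates
#'
#' Maximizes [blocked_loglik()] over the six per-type rates.  The blocked
#' likelihood separates by type, so the maximum has the closed form
#' weighted-count over weighted-exposure, with each clone weighted by
#' 1 / (clones in its population):
#' \deqn{\hat\mu_c = \frac{\sum_p n_p^{-1} \sum_g m_{g,c}}
#'                        {\sum_p n_p^{-1} \sum_g t_g s_{g,c}}.}
#' Types never observed get rate 0, reported with a one-sided 95% upper
#' bound from the profile likelihood.
#'
#' @inheritParams blocked_loglik
#' @param composition Optional `site_opportunity_table` (or list with
#'   `f_at`, `f_gc`) used to combine per-type rates into an overall
#'   per-base-pair rate; see [combine_rates()].
#' @param genome_size Optional genome size (bp) for the per-genome rate.
#' @return An object of class `blocked_ml_fit`: per-type tibble (`type`,
#'   `m_total`, `weighted_m`, `weighted_exposure`, `rate`,
#'   `upper_bound_0`), the block count, log-likelihood at the optimum,
#'   and -- when `composition` is given -- `combined_rate` (and
#'   `genomic_rate` with `genome_size`).
#' @export
fit_blocked_ml <- function(observations, composition = NULL,
                           genome_size = NULL) {
  if (nrow(observations) == 0L) {
    abort("no observations: nothing to fit.")
  }
  obs <- as_tibble(observations)
  obs$type <- factor(as.character(obs$type), levels = mutation_types())
  n_by_pop <- dplyr::summarise(
    dplyr::group_by(obs, .data$population),
    n_p = dplyr::n_distinct(.data$clone), .groups = "drop"
  )
  obs <- dplyr::left_join(obs, n_by_pop, by = "population")
  per_type <- dplyr::summarise(
    dplyr::group_by(obs, .data$type),
    m_total = sum(.data$m),
    weighted_m = sum(.data$m / .data$n_p),
    weighted_exposure = sum(.data$t * .data$s / .data$n_p),
    .groups = "drop"
  )
  if (any(per_type$weighted_exposure <= 0 & per_type$weighted_m > 0)) {
    abort("a type has observed mutations but zero exposure.")
  }
  per_type$rate <- ifelse(
    per_type$weighted_m == 0, 0,
    per_type$weighted_m / per_type$weighted_exposure
  )
  # one-sided 95% upper bound for unobserved types: the profile
  # likelihood for a type with zero weighted counts is exp(-mu * E)
  per_type$upper_bound_0 <- ifelse(
    per_type$weighted_m == 0 & per_type$weighted_exposure > 0,
    -log(0.05) / per_type$weighted_exposure,
    NA_real_
  )

  mu <- setNames(per_type$rate, as.character(per_type$type))
  fit <- structure(
    list(
      per_type = per_type,
      mu = mu,
      n_blocks = nrow(n_by_pop),
      n_clones = sum(n_by_pop$n_p),
      loglik = blocked_loglik(obs[, setdiff(names(obs), "n_p")], mu)
    ),
    class = "blocked_ml_fit"
  )
  if (!is.null(composition)) {
    fit$combined_rate <- combine_rates(mu, composition)
    if (!is.null(genome_size)) {
      fit$genomic_rate <- genomic_rate(fit$combined_rate, genome_size)
    }
  }
  fit
}

#' @export
print.blocked_ml_fit <- function(x, ...) {
  cat(sprintf(
    "<blocked_ml_fit> %d population block(s), %d clone(s); log-likelihood %.4f\n",
    x$n_blocks, x$n_clones, x$loglik
  ))
  print(as_tibble(x$per_type[, c("type", "m_total", "rate")]))
  if (!is.null(x$combined_rate)) {
    cat(sprintf("combined rate: %.4g per bp per generation\n",
                x$combined_rate))
  }
  if (!is.null(x$genomic_rate)) {
    cat(sprintf("genomic rate:  %.4g per genome per generation\n",
                x$genomic_rate))
  }
  invisible(x)
}

#' Combine per-type rates into an overall per-base-pair rate
#'
#' Weights each type's rate by the genome-wide frequency of its ancestral
#' base pair: the three rates away from A:T are summed and weighted by
#' the A:T frequency, likewise for G:C,
#' \deqn{\mu = f_{AT}(\mu_{AT>GC}+\mu_{AT>CG}+\mu_{AT>TA})
#'           + f_{GC}(\mu_{GC>AT}+\mu_{GC>TA}+\mu_{GC>CG}).}
#'
#' @param mu Named per-type rate vector.
#' @param composition A `site_opportunity_table`, or any list with
#'   elements `f_at` and `f_gc` summing to 1.
#' @return The combined per-base-pair rate.
#' @export
combine_rates <- function(mu, composition) {
  comp <- if (inherits(composition, "site_opportunity_table")) {
    site_composition(composition)
  } else {
    composition
  }
  if (abs(comp$f_at + comp$f_gc - 1) > 1e-9) {
    abort("composition frequencies f_at + f_gc must sum to 1.")
  }
  mu <- mu[mutation_types()]
  if (anyNA(mu)) abort("`mu` must be named by the six mutation types.")
  at <- sum(mu[type_origin(mutation_types()) == "AT"])
  gc <- sum(mu[type_origin(mutation_types()) == "GC"])
  unname(comp$f_at * at + comp$f_gc * gc)
}

#' @rdname combine_rates
#' @description `genomic_rate()` scales a per-base-pair rate to a whole
#'   genome: the expected number of new base substitutions per genome per
#'   generation.
#' @param rate Per-base-pair per-generation rate.
#' @param genome_size Genome size in bp.
#' @export
genomic_rate <- function(rate, genome_size) {
  if (rate < 0 || genome_size <= 0) {
    abort("`rate` must be >= 0 and `genome_size` > 0.")
  }
  rate * genome_size
}

#' Tukey jackknife confidence limits by deleting whole populations
#'
#' Re-estimates a statistic on delete-one datasets that each drop all
#' clones of one population, forms pseudo-values
#' \eqn{\hat\theta_i = n\hat\theta - (n-1)\hat\theta_{(-i)}}, and builds a
#' t-interval from their mean and standard error with `n - 1` degrees of
#' freedom.  The lower limit is truncated at 0 (rates are non-negative).
#'
#' @param estimator A function taking an observations tibble and
#'   returning a single number.
#' @param observations Long observations tibble with a `population`
#'   column; each distinct population is one deletion block.
#' @param level Confidence level.
#' @return An object of class `jackknife_result`: `estimate` (full-data),
#'   `point` (pseudo-value mean), `se`, `df`, `lower`, `upper`, `level`,
#'   `pseudo_values`, `leave_one_out`, `blocks`.
#' @export
jackknife_ci <- function(estimator, observations, level = 0.95) {
  blocks <- unique(observations$population)
  n <- length(blocks)
  if (n < 2L) {
    abort("jackknife needs at least two population blocks.")
  }
  theta_hat <- estimator(observations)
  theta_loo <- vapply(blocks, function(b) {
    estimator(observations[observations$population != b, , drop = FALSE])
  }, numeric(1))
  pseudo <- n * theta_hat - (n - 1) * theta_loo
  point <- mean(pseudo)
  se <- sd(pseudo) / sqrt(n)
  a <- 1 - level
  half <- qt(1 - a / 2, df = n - 1) * se
  structure(
    list(
      estimate = theta_hat,
      point = point,
      se = se,
      df = n - 1,
      lower = max(0, point - half),
      upper = point + half,
      level = level,
      pseudo_values = setNames(pseudo, blocks),
      leave_one_out = setNames(theta_loo, blocks),
      blocks = blocks
    ),
    class = "jackknife_result"
  )
}

#' @export
print.jackknife_result <- function(x, ...) {
  cat(sprintf(
    "<jackknife_result> estimate %.4g (pseudo-value mean %.4g), %g%% CI [%.4g, %.4g], %d blocks\n",
    x$estimate, x$point, 100 * x$level, x$lower, x$upper, length(x$blocks)
  ))
  invisible(x)
}

#' One-call rate estimation from records to jackknifed combined rate
#'
#' Convenience pipeline: build per-clone observations, fit the blocked
#' Poisson maximum-likelihood model, combine per-type rates by ancestral
#' composition, and jackknife the combined rate over populations.
#'
#' @inheritParams build_clone_observations
#' @param genome_size Optional genome size for the per-genome rate.
#' @param level Confidence level for the jackknife interval.
#' @return A list with elements `fit` (the [fit_blocked_ml()] object),
#'   `jackknife` (the [jackknife_ci()] object for the combined rate) and
#'   `observations`.
#' @export
estimate_rate_ml <- function(records, clones, opportunity, callable = NULL,
                             genome_size = NULL, level = 0.95) {
  obs <- build_clone_observations(
    records, clones, opportunity = opportunity, callable = callable
  )
  fit <- fit_blocked_ml(obs, composition = opportunity,
                        genome_size = genome_size)
  jk <- jackknife_ci(
    function(o) fit_blocked_ml(o, composition = opportunity)$combined_rate,
    obs, level = level
  )
  list(fit = fit, jackknife = jk, observations = obs)
}
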