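# Composition-corrected mutational spectrum statistics.
#
# Raw counts of the six substitution types are confounded by how many
# genomic sites could have produced each type as a synonymous change.
# All ratios here therefore normalize counts by per-type synonymous
# opportunities before comparison, and the binomial nulls are the
# opportunity-implied probabilities under uniform per-opportunity rates.

counts_by_type <- function(counts) {
  if (is_tibble(counts) || is.data.frame(counts)) {
    if (!all(c("type", "count") %in% names(counts))) {
      abort("count table needs columns `type` and `count`.")
    }
    v <- setNames(as.numeric(counts$count), as.character(counts$type))
  } else {
    v <- counts
  }
  v <- v[mutation_types()]
  if (anyNA(v)) abort("counts must cover the six mutation types.")
  v
}

opportunities_by_type <- function(opportunities) {
  if (inherits(opportunities, "site_opportunity_table") ||
      is.data.frame(opportunities)) {
    v <- setNames(as.numeric(opportunities$opportunities),
                  as.character(opportunities$type))
  } else {
    v <- opportunities
  }
  v <- v[mutation_types()]
  if (anyNA(v)) abort("opportunities must cover the six mutation types.")
  v
}

#' Composition-corrected transition:transversion ratio
#'
#' Normalizes observed per-type counts by per-type synonymous
#' opportunities, then compares the summed transition rate against the
#' summed transversion rate.  The ratio is reported in the `1:x`
#' convention: the returned value is
#' \eqn{x = (\sum_{tv} c/S) / (\sum_{ts} c/S)}, so `x = 2` means
#' transitions and transversions occur at equal per-opportunity rates
#' (there are two transversion categories for every transition category
#' at each site).
#'
#' @param counts Observed per-type counts ([spectrum_counts()] tibble or
#'   named vector).
#' @param opportunities Per-type synonymous opportunities
#'   ([synonymous_opportunities()] table or named vector).
#' @return The transversion side `x` of the `1:x` corrected ratio.
#' @export
corrected_ts_tv <- function(counts, opportunities) {
  cnt <- counts_by_type(counts)
  opp <- opportunities_by_type(opportunities)
  ts <- is_transition(mutation_types())
  if (sum(opp[ts]) <= 0 || sum(opp[!ts]) <= 0) {
    abort("transition and transversion opportunity sums must be positive.")
  }
  rate_ts <- sum(cnt[ts] / opp[ts])
  rate_tv <- sum(cnt[!ts] / opp[!ts])
  if (rate_ts == 0) {
    abort("no transitions observed; the 1:x ratio is undefined.")
  }
  unname(rate_tv / rate_ts)
}

#' Composition-corrected fold bias between two substitution types
#'
#' The per-opportunity rate of `type_a` divided by that of `type_b`:
#' \eqn{(c_a/S_a) / (c_b/S_b)}.  The default contrast, GC>AT versus
#' AT>GC, measures the mutational pressure toward higher AT content.
#'
#' @inheritParams corrected_ts_tv
#' @param type_a,type_b Substitution type labels (see [mutation_types()]).
#' @return The fold bias (possibly `Inf` when `type_b` has zero counts).
#' @export
fold_bias <- function(counts, opportunities, type_a = "GC>AT",
                      type_b = "AT>GC") {
  if (!type_a %in% mutation_types() || !type_b %in% mutation_types()) {
    abort("`type_a` and `type_b` must be substitution type labels.")
  }
  cnt <- counts_by_type(counts)
  opp <- opportunities_by_type(opportunities)
  if (opp[[type_a]] <= 0 || opp[[type_b]] <= 0) {
    abort("both types need positive opportunity counts.")
  }
  unname((cnt[[type_a]] / opp[[type_a]]) / (cnt[[type_b]] / opp[[type_b]]))
}

#' Exact two-tailed binomial test (minimum-likelihood rule)
#'
#' The two-tailed p-value is the total probability of all outcomes `k` in
#' `0:total` whose point probability under the null does not exceed that
#' of the observed outcome (ties included, with a tiny relative tolerance
#' for floating-point equality).  At the distribution's mode the p-value
#' is 1.
#'
#' @param successes Observed success count.
#' @param total Number of trials.
#' @param null_probability Null success probability, in (0, 1).
#' @return The exact two-tailed p-value.
#' @examples
#' two_tailed_binomial_test(0, 10, 0.5)  # 2/1024
#' @export
two_tailed_binomial_test <- function(successes, total, null_probability) {
  if (!isTRUE(total >= 0) || total != round(total) ||
      !isTRUE(successes >= 0) || successes != round(successes) ||
      successes > total) {
    abort("need integer counts with 0 <= successes <= total.")
  }
  if (!isTRUE(null_probability > 0 && null_probability < 1)) {
    abort("`null_probability` must be strictly inside (0, 1).")
  }
  probs <- dbinom(0:total, total, null_probability)
  p_obs <- probs[successes + 1]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Full mutational-spectrum report
#'
#' Assembles observed per-type counts, opportunity-implied expected
#' proportions, per-opportunity rates, the corrected
#' transition:transversion ratio and GC>AT fold bias, and two exact
#' binomial tests: (i) transitions among all events against the
#' opportunity-implied null share of transitions (the share expected if
#' all six types had a uniform per-opportunity rate), and (ii) GC>AT
#' events among the two transition categories against their
#' opportunity-implied two-type null.
#'
#' @param events Event tibble from [collapse_events()] (or records).
#' @param opportunities A `site_opportunity_table`.
#' @return An object of class `spectrum_report`; see [tidy()] and
#'   [glance()] methods, and [autoplot()] for the expected-vs-observed
#'   bar chart.
#' @export
spectrum_report <- function(events, opportunities) {
  cnt_tbl <- spectrum_counts(events)
  cnt <- counts_by_type(cnt_tbl)
  opp <- opportunities_by_type(opportunities)
  expected <- expected_spectrum(opportunities)
  n <- sum(cnt)

  ts <- is_transition(mutation_types())
  p_ts_null <- sum(opp[ts]) / sum(opp)
  ts_count <- sum(cnt[ts])
  ts_test <- two_tailed_binomial_test(ts_count, n, p_ts_null)

  p_gc_null <- opp[["GC>AT"]] / (opp[["GC>AT"]] + opp[["AT>GC"]])
  n_transitions_pair <- cnt[["GC>AT"]] + cnt[["AT>GC"]]
  gc_test <- if (n_transitions_pair > 0) {
    two_tailed_binomial_test(cnt[["GC>AT"]], n_transitions_pair, p_gc_null)
  } else {
    NA_real_
  }

  structure(
    list(
      counts = tibble(
        type = mutation_types(),
        observed = unname(cnt),
        opportunities = unname(opp),
        rate = unname(cnt / opp),
        observed_prop = unname(cnt) / n,
        expected_prop = expected$expected
      ),
      n_events = n,
      ts_tv = list(
        ratio = corrected_ts_tv(cnt, opp),
        transitions = ts_count,
        transversions = n - ts_count,
        null_probability = unname(p_ts_null),
        p_value = ts_test
      ),
      gc_at_bias = list(
        fold = fold_bias(cnt, opp),
        null_probability = unname(p_gc_null),
        n = unname(n_transitions_pair),
        p_value = gc_test
      )
    ),
    class = "spectrum_report"
  )
}

#' @export
print.spectrum_report <- function(x, ...) {
  cat(sprintf("<spectrum_report> %d events\n", x$n_events))
  print(x$counts)
  cat(sprintf(
    "corrected ts:tv = 1:%.3g (null p_ts = %.3f, two-tailed exact P = %.3g)\n",
    x$ts_tv$ratio, x$ts_tv$null_probability, x$ts_tv$p_value
  ))
  cat(sprintf(
    "GC>AT vs AT>GC fold bias = %.3g (two-tailed exact P = %.3g)\n",
    x$gc_at_bias$fold, x$gc_at_bias$p_value
  ))
  invisible(x)
}
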