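# broom-style tidiers: tidy() gives the per-component table, glance()
# the one-row model summary.

#' @rdname point_estimate_simple
#' @param x A `rate_estimate`.
#' @param ... Unused.
#' @method tidy rate_estimate
#' @export
tidy.rate_estimate <- function(x, ...) {
  tibble(
    method = x$method,
    rate = x$rate, lower = x$lower, upper = x$upper,
    conf_level = x$level,
    m = x$m, generations = x$generations, sites = x$sites
  )
}

#' @rdname point_estimate_simple
#' @method glance rate_estimate
#' @export
glance.rate_estimate <- function(x, ...) {
  tidy.rate_estimate(x)
}

#' @rdname fit_blocked_ml
#' @param x A `blocked_ml_fit`.
#' @param ... Unused.
#' @method tidy blocked_ml_fit
#' @export
tidy.blocked_ml_fit <- function(x, ...) {
  out <- as_tibble(x$per_type)
  out$type <- as.character(out$type)
  out
}

#' @rdname fit_blocked_ml
#' @method glance blocked_ml_fit
#' @export
glance.blocked_ml_fit <- function(x, ...) {
  tibble(
    combined_rate = x$combined_rate %||% NA_real_,
    genomic_rate = x$genomic_rate %||% NA_real_,
    loglik = x$loglik,
    n_blocks = x$n_blocks,
    n_clones = x$n_clones
  )
}

#' @rdname jackknife_ci
#' @param x A `jackknife_result`.
#' @param ... Unused.
#' @method tidy jackknife_result
#' @export
tidy.jackknife_result <- function(x, ...) {
  tibble(
    block = x$blocks,
    leave_one_out = unname(x$leave_one_out),
    pseudo_value = unname(x$pseudo_values)
  )
}

#' @rdname jackknife_ci
#' @method glance jackknife_result
#' @export
glance.jackknife_result <- function(x, ...) {
  tibble(
    estimate = x$estimate, point = x$point, se = x$se, df = x$df,
    lower = x$lower, upper = x$upper, conf_level = x$level
  )
}

#' @rdname spectrum_report
#' @param x A `spectrum_report`.
#' @param ... Unused.
#' @method tidy spectrum_report
#' @export
tidy.spectrum_report <- function(x, ...) {
  x$counts
}

#' @rdname spectrum_report
#' @method glance spectrum_report
#' @export
glance.spectrum_report <- function(x, ...) {
  tibble(
    n_events = x$n_events,
    transitions = x$ts_tv$transitions,
    transversions = x$ts_tv$transversions,
    ts_tv_ratio = x$ts_tv$ratio,
    ts_tv_p = x$ts_tv$p_value,
    gc_at_fold = x$gc_at_bias$fold,
    gc_at_p = x$gc_at_bias$p_value
  )
}

#' @rdname recovery_experiment
#' @param x A `recovery_report`.
#' @param ... Unused.
#' @method tidy recovery_report
#' @export
tidy.recovery_report <- function(x, ...) {
  x$replicates
}

#' @rdname recovery_experiment
#' @method glance recovery_report
#' @export
glance.recovery_report <- function(x, ...) {
  s <- x$summary
  tibble(
    truth = x$truth,
    mean_estimate = s$mean_estimate,
    bias = s$bias,
    relative_bias = s$relative_bias,
    rmse = s$rmse,
    coverage = s$coverage,
    conf_level = s$level,
    n_replicates = s$n_replicates
  )
}
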