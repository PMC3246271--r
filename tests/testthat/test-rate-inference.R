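test_that("the simple estimator is m over generations times sites", {
  est <- point_estimate_simple(25, 300000, 941000)
  expect_equal(est$rate, 25 / (300000 * 941000))
  expect_equal(point_estimate_simple(0, 5000, 1e6)$rate, 0)
  expect_error(point_estimate_simple(2, 0, 1e6), "positive")
  expect_error(point_estimate_simple(2.5, 100, 1e6), "integer")
})

test_that("exact binomial limits behave at the boundaries", {
  ci <- binomial_rate_ci(0, 1e9)
  expect_identical(ci[["lower"]], 0)
  expect_gt(ci[["upper"]], 0)
  expect_error(binomial_rate_ci(5, 4), "m <= trials")
  # interval nests the point estimate
  est <- point_estimate_simple(7, 1e4, 1e5)
  expect_lte(est$lower, est$rate)
  expect_gte(est$upper, est$rate)
})

test_that("binomial limits converge to the exact Poisson limits", {
  for (m in c(1, 5, 25)) {
    b <- binomial_rate_ci(m, 1e11)
    p <- poisson_rate_ci(m, 1e11)
    expect_equal(b[["lower"]], p[["lower"]], tolerance = 1e-4)
    expect_equal(b[["upper"]], p[["upper"]], tolerance = 1e-4)
  }
})

test_that("a single-clone likelihood peaks at m/(t*s)", {
  obs <- tibble::tibble(
    population = "p1", clone = "c1", t = 1000,
    type = mutation_types(), m = c(3L, 0L, 0L, 0L, 0L, 0L), s = 2000
  )
  mle <- 3 / (1000 * 2000)
  base_mu <- stats::setNames(rep(mle, 6), mutation_types())
  ll_at <- function(r) {
    mu <- base_mu
    mu["AT>GC"] <- r
    blocked_loglik(obs, mu)
  }
  grid <- mle * seq(0.2, 3, length.out = 40)
  expect_equal(grid[which.max(vapply(grid, ll_at, numeric(1)))],
               mle, tolerance = 0.05)
  expect_true(all(vapply(grid[grid != mle], ll_at, numeric(1)) <= ll_at(mle)))
})

test_that("zero rate with observed mutations gives -Inf, not an error", {
  obs <- tibble::tibble(
    population = "p1", clone = "c1", t = 1000,
    type = mutation_types(), m = c(1L, rep(0L, 5)), s = 1000
  )
  mu <- stats::setNames(c(0, rep(1e-9, 5)), mutation_types())
  expect_identical(blocked_loglik(obs, mu), -Inf)
})

test_that("block averaging makes duplicated clones a no-op", {
  obs <- random_observations(21)
  mu <- stats::setNames(rep(2e-9, 6), mutation_types())
  dup <- dplyr::bind_rows(
    obs, dplyr::mutate(obs, clone = paste0(clone, "_copy"))
  )
  expect_equal(blocked_loglik(dup, mu), blocked_loglik(obs, mu))
  fit1 <- fit_blocked_ml(obs)
  fit2 <- fit_blocked_ml(dup)
  expect_equal(fit1$mu, fit2$mu, tolerance = 1e-12)
})

test_that("numeric optimization of the blocked likelihood matches the closed form", {
  for (seed in c(101, 202, 303, 404, 505)) {
    obs <- random_observations(seed)
    fit <- fit_blocked_ml(obs)
    for (ty in mutation_types()) {
      if (fit$mu[[ty]] <= 0) next
      f <- function(log_mu) {
        mu <- fit$mu
        mu[ty] <- exp(log_mu)
        blocked_loglik(obs, mu)
      }
      opt <- stats::optimize(f, interval = log(fit$mu[[ty]]) + c(-4, 4),
                             maximum = TRUE, tol = 1e-10)
      expect_equal(exp(opt$maximum), fit$mu[[ty]], tolerance = 1e-6)
    }
  }
})

test_that("rate estimates are equivariant under rescaling sites or time", {
  obs <- random_observations(77)
  fit <- fit_blocked_ml(obs)
  fit_s <- fit_blocked_ml(dplyr::mutate(obs, s = s * 4))
  expect_equal(fit_s$mu, fit$mu / 4, tolerance = 1e-12)
  fit_t <- fit_blocked_ml(dplyr::mutate(obs, t = t * 2.5))
  expect_equal(fit_t$mu, fit$mu / 2.5, tolerance = 1e-12)
})

test_that("with one clone per population the blocked fit pools like the simple estimator", {
  set.seed(9)
  n_pops <- 6
  obs <- dplyr::bind_rows(lapply(seq_len(n_pops), function(p) {
    tibble::tibble(
      population = paste0("p", p), clone = "c1", t = 20000,
      type = mutation_types(), s = 1500,
      m = stats::rpois(6, 3)
    )
  }))
  comp <- list(f_at = 0.5, f_gc = 0.5)
  fit <- fit_blocked_ml(obs, composition = comp)
  # with uniform per-type sites s0, uniform t and symmetric composition,
  # the combined rate collapses to the pooled simple estimate with
  # effective sites 2 * s0 (each pair class carries three type-specific
  # targets, weighted by f = 1/2)
  pooled <- point_estimate_simple(sum(obs$m), n_pops * 20000, 2 * 1500)
  expect_equal(fit$combined_rate, pooled$rate, tolerance = 1e-9)
  expect_equal(fit$combined_rate, sum(fit$mu) / 2, tolerance = 1e-12)
})

test_that("rate combination weights type sums by ancestral composition", {
  mu <- stats::setNames(rep(2e-10, 6), mutation_types())
  for (f_at in c(0.2, 0.5, 0.8)) {
    expect_equal(
      combine_rates(mu, list(f_at = f_at, f_gc = 1 - f_at)),
      3 * 2e-10
    )
  }
  mu2 <- stats::setNames(c(1, 2, 3, 4, 5, 6) * 1e-10, mutation_types())
  expect_equal(combine_rates(mu2, list(f_at = 1, f_gc = 0)),
               (1 + 2 + 3) * 1e-10)
  set.seed(3)
  r <- stats::setNames(stats::runif(6), mutation_types())
  f <- stats::runif(1)
  expect_equal(
    combine_rates(r, list(f_at = f, f_gc = 1 - f)),
    f * sum(r[c("AT>GC", "AT>CG", "AT>TA")]) +
      (1 - f) * sum(r[c("GC>AT", "GC>TA", "GC>CG")])
  )
})

test_that("genomic rate scales the per-bp rate by genome size", {
  expect_equal(genomic_rate(1e-10, 1e6), 1e-4)
  expect_equal(genomic_rate(0, 4.6e6), 0)
  expect_error(genomic_rate(1e-10, 0), "genome_size")
})

test_that("identical blocks give a zero-width jackknife interval", {
  one <- tibble::tibble(
    population = "p", clone = "c1", t = 1000,
    type = mutation_types(), m = c(2L, 1L, 0L, 5L, 1L, 0L), s = 3000
  )
  obs <- dplyr::bind_rows(lapply(1:4, function(p) {
    dplyr::mutate(one, population = paste0("p", p))
  }))
  comp <- list(f_at = 0.5, f_gc = 0.5)
  est <- function(o) fit_blocked_ml(o, composition = comp)$combined_rate
  jk <- jackknife_ci(est, obs)
  expect_equal(jk$se, 0)
  expect_equal(jk$lower, jk$estimate, tolerance = 1e-12)
  expect_equal(jk$upper, jk$estimate, tolerance = 1e-12)
  expect_equal(mean(jk$pseudo_values), jk$point)
})

test_that("delete-one estimates follow the closed form when a block drops out", {
  obs <- random_observations(55)
  comp <- list(f_at = 0.45, f_gc = 0.55)
  est <- function(o) fit_blocked_ml(o, composition = comp)$combined_rate
  jk <- jackknife_ci(est, obs)
  # recompute one leave-one-out estimate by hand from the closed form
  drop_block <- jk$blocks[1]
  kept <- obs[obs$population != drop_block, ]
  closed_form <- function(o) {
    n_p <- tapply(o$clone, o$population,
                  function(x) length(unique(x)))
    w <- 1 / n_p[o$population]
    mu <- vapply(mutation_types(), function(ty) {
      i <- o$type == ty
      num <- sum(w[i] * o$m[i])
      if (num == 0) 0 else num / sum(w[i] * o$t[i] * o$s[i])
    }, numeric(1))
    combine_rates(mu, comp)
  }
  expect_equal(jk$leave_one_out[[drop_block]], closed_form(kept),
               tolerance = 1e-12)
  n <- length(jk$blocks)
  expect_equal(
    unname(jk$pseudo_values[drop_block]),
    n * jk$estimate - (n - 1) * closed_form(kept),
    tolerance = 1e-12
  )
  expect_error(jackknife_ci(est, obs[obs$population == "p1", ]),
               "at least two")
})

test_that("types with zero counts get rate zero and a profile upper bound", {
  obs <- random_observations(31)
  obs$m[obs$type == "GC>CG"] <- 0L
  fit <- fit_blocked_ml(obs)
  expect_equal(fit$mu[["GC>CG"]], 0)
  per <- tidy(fit)
  ub <- per$upper_bound_0[per$type == "GC>CG"]
  expect_gt(ub, 0)
  # the bound is where the profile likelihood drops to 5%
  exposure <- per$weighted_exposure[per$type == "GC>CG"]
  expect_equal(exp(-ub * exposure), 0.05, tolerance = 1e-10)
})

test_that("tidiers return the advertised one-row and per-type shapes", {
  obs <- random_observations(61)
  comp <- list(f_at = 0.5, f_gc = 0.5)
  fit <- fit_blocked_ml(obs, composition = comp)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 6L)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$combined_rate, fit$combined_rate)
  est <- point_estimate_simple(5, 10700, 930000)
  expect_equal(tidy(est)$rate, est$rate)
  jk <- jackknife_ci(function(o) fit_blocked_ml(o)$mu[["GC>AT"]], obs)
  expect_equal(nrow(tidy(jk)), length(jk$blocks))
  expect_equal(glance(jk)$se, jk$se)
})
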