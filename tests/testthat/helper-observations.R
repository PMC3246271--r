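# random blocked observation sets for property checks
random_observations <- function(seed, min_mean = 0) {
  set.seed(seed)
  n_pops <- sample(3:6, 1)
  obs <- dplyr::bind_rows(lapply(seq_len(n_pops), function(p) {
    n_cl <- sample(1:3, 1)
    dplyr::bind_rows(lapply(seq_len(n_cl), function(cl) {
      tibble::tibble(
        population = paste0("p", p),
        clone = paste0("c", cl),
        t = sample(c(10000, 20000, 40000), 1),
        type = mutation_types(),
        s = stats::runif(6, 500, 5000)
      )
    }))
  }))
  mu_true <- stats::runif(6, 1e-10, 5e-9)
  obs$m <- stats::rpois(nrow(obs),
                        pmax(min_mean, mu_true * obs$t * obs$s))
  obs
}
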