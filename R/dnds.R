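# Per-clone dN/dS screening.
#
# Unweighted counting estimator with fractional site counts: each coding
# position contributes to the synonymous site total the fraction of its
# three possible changes that are synonymous, and the remainder to the
# nonsynonymous total.  No multiple-hit correction is applied -- per-clone
# substitution counts in accumulation experiments are far below one per
# gene, so corrected and uncorrected estimators coincide to within
# rounding.

#' Fractional synonymous and nonsynonymous site counts
#'
#' Counts sites the unweighted (equal-pathway) way: a coding position
#' where `k` of its three possible changes are synonymous contributes
#' `k/3` synonymous sites and `1 - k/3` nonsynonymous sites.  Totals sum
#' to the coding length.
#'
#' @param genome An [annotated_genome] with CDS features.
#' @return Named numeric vector `c(n_sites = , s_sites = )`.
#' @export
count_sites_ng <- function(genome) {
  changes <- coding_change_table_cached(genome)
  s_sites <- sum(changes$class == "synonymous") / 3
  coding_length <- length(unique(changes$pos))
  c(n_sites = coding_length - s_sites, s_sites = s_sites)
}

#' Per-clone dN/dS
#'
#' The ratio of nonsynonymous changes per nonsynonymous site to
#' synonymous changes per synonymous site for a single clone's
#' substitutions.  Nonsense changes count as nonsynonymous (they alter
#' the protein); noncoding records are ignored.  When the clone has no
#' synonymous changes, dS is 0 and the ratio is undefined (`NA`, flagged)
#' rather than infinite.
#'
#' @param records Mutation records from one clone, with `coding_class`
#'   present or a `genome` to compute it.
#' @param genome An [annotated_genome] (used for site counts and, when
#'   needed, classification).
#' @return A one-row tibble of class `dnds_result`: `clone`, `n_obs`,
#'   `s_obs`, `n_sites`, `s_sites`, `dn`, `ds`, `dnds`, `undefined`.
#' @export
dnds <- function(records, genome) {
  records <- as_tibble(records)
  if (nrow(records) > 0L && length(unique(records$clone)) > 1L) {
    abort("`records` spans multiple clones; use dnds_by_clone().")
  }
  if (!"coding_class" %in% names(records) ||
      anyNA(records$coding_class)) {
    records$coding_class <- classify_change(
      genome, records$position, records$alt
    )
  }
  sites <- count_sites_ng(genome)
  n_obs <- sum(records$coding_class %in% c("nonsynonymous", "nonsense"))
  s_obs <- sum(records$coding_class == "synonymous")
  dn <- n_obs / sites[["n_sites"]]
  ds <- s_obs / sites[["s_sites"]]
  out <- tibble(
    clone = if (nrow(records) > 0L) records$clone[1] else NA_character_,
    n_obs = n_obs, s_obs = s_obs,
    n_sites = sites[["n_sites"]], s_sites = sites[["s_sites"]],
    dn = dn, ds = ds,
    dnds = if (ds > 0) dn / ds else NA_real_,
    undefined = ds == 0
  )
  class(out) <- c("dnds_result", class(out))
  out
}

#' @rdname dnds
#' @description `dnds_by_clone()` maps [dnds()] over every clone present
#'   in a multi-clone record table.
#' @export
dnds_by_clone <- function(records, genome) {
  records <- as_tibble(records)
  out <- dplyr::bind_rows(lapply(
    split(records, paste(records$population %||% "", records$clone)),
    function(r) {
      res <- dnds(r, genome)
      if ("population" %in% names(r)) {
        res <- dplyr::bind_cols(tibble(population = r$population[1]), res)
      }
      res
    }
  ))
  out[order(out$clone), , drop = FALSE]
}
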