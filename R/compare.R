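#' Within-site permutation test of partner versus neighbour dyads
#'
#' Tests whether a dyad-level metric differs between partner and neighbour
#' dyads. The statistic is the weighted mean difference
#' (partner - neighbour), with weights typically the time each dyad was
#' simultaneously tracked. The null distribution permutes relationship
#' labels among dyads *within each site*, which respects site-level
#' structure while breaking the partner/neighbour assignment. The p-value
#' uses the add-one correction `(1 + #{|null| >= |obs|}) / (n_perm + 1)`.
#'
#' @param records Data frame with columns `relationship`
#'   (`"partner"`/`"neighbour"`), `site`, `weight`, and the metric column.
#' @param metric Name of the metric column (e.g. `"bc"`, `"ratio"`,
#'   `"median_separation"`).
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed (required).
#' @return List of class `permutation_test` with `statistic`, `p_value`,
#'   `n_perm`, `metric`, `seed`.
#' @export
permutation_test <- function(records, metric, n_perm = 999, seed) {
  check_columns(records, c("relationship", "site", "weight", metric),
                "records")
  check_number(n_perm, "n_perm", positive = TRUE)
  seed <- check_seed(seed)

  keep <- is.finite(records[[metric]]) & is.finite(records$weight)
  records <- records[keep, , drop = FALSE]
  rel <- records$relationship
  if (length(unique(rel)) < 2L)
    stop("need both partner and neighbour dyads", call. = FALSE)
  if (any(records$weight < 0))
    stop("weights must be non-negative", call. = FALSE)

  stat_fun <- function(labels) {
    p <- labels == "partner"
    weighted.mean(records[[metric]][p], records$weight[p]) -
      weighted.mean(records[[metric]][!p], records$weight[!p])
  }
  obs <- stat_fun(rel)

  site_idx <- split(seq_len(nrow(records)), records$site)
  null <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      perm <- rel
      for (idx in site_idx)
        if (length(idx) > 1L) perm[idx] <- rel[sample(idx)]
      stat_fun(perm)
    }, numeric(1))
  })
  null <- null[is.finite(null)]

  structure(list(
    statistic = obs,
    p_value = (1 + sum(abs(null) >= abs(obs))) / (length(null) + 1),
    n_perm = length(null),
    metric = metric,
    seed = seed
  ), class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf(
    "Within-site permutation test of `%s`:\n  partner - neighbour (weighted) = %.4g, p = %.4g (%d permutations)\n",
    x$metric, x$statistic, x$p_value, x$n_perm))
  invisible(x)
}
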