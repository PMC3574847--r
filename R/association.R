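# Randomization tests for symbiont-lineage / host-background association and
# per-haplotype exact binomial infection tests.

.randomization_result <- function(observed, null_stats, n_rand, seed,
                                  statistic, add_one) {
  p <- if (add_one) {
    (1 + sum(null_stats >= observed)) / (1 + n_rand)
  } else {
    sum(null_stats >= observed) / n_rand
  }
  structure(list(observed_stat = observed, null_stats = null_stats,
                 p_value = p, n_rand = n_rand, seed = seed,
                 statistic = statistic, add_one = add_one),
            class = "randomization_test")
}

#' @export
print.randomization_test <- function(x, ...) {
  cat(sprintf("Randomization test (%s)\n  observed = %.4g, p = %.4g (%d randomizations, seed %d)\n",
              x$statistic, x$observed_stat, x$p_value, x$n_rand, x$seed))
  invisible(x)
}

.check_meta_cols <- function(meta, cols) {
  miss <- setdiff(cols, names(meta))
  if (length(miss) > 0L)
    hc_input_error(sprintf("host metadata lacks column(s): %s",
                           paste(miss, collapse = ", ")))
}

#' Randomization test: symbiont lineage 2 vs southern host haplogroup
#'
#' Tests whether the second symbiont lineage ("Group 2") co-occurs with the
#' southern host mtDNA haplogroup more often than expected. The observed
#' statistic is the number of individuals carrying Group 2 and a southern
#' haplogroup; the null is built by shuffling the Group 2 indicator across
#' individuals (total count preserved); the one-sided p-value is the
#' proportion of randomized datasets whose statistic is at least the
#' observed one (`add_one = TRUE` switches to the add-one convention, under
#' which p = 0 is impossible).
#'
#' @param meta host metadata with columns `mtdna_haplogroup`
#'   (`"North"`/`"South"`) and logical `wgff_group2`.
#' @param n_rand number of randomized datasets (default 100).
#' @param seed integer seed (global RNG state preserved).
#' @param add_one use the add-one p-value convention (default off).
#' @param statistic `"count"` (default) or `"proportion"` of Group 2
#'   carriers that are southern; the two are monotone-equivalent at fixed
#'   margins.
#' @return A `randomization_test` object.
#' @export
test_group2_south <- function(meta, n_rand = 100L, seed = 1L, add_one = FALSE,
                              statistic = c("count", "proportion")) {
  statistic <- match.arg(statistic)
  .check_meta_cols(meta, c("mtdna_haplogroup", "wgff_group2"))
  g2 <- as.logical(meta$wgff_group2)
  south <- meta$mtdna_haplogroup == "South"
  if (anyNA(g2) || anyNA(south)) hc_input_error("NA in group2/haplogroup columns")
  k <- sum(g2)
  if (k == 0L) hc_no_test_error("no Group 2 carriers: test not defined")
  stat <- function(ind) {
    x <- sum(south & ind)
    if (statistic == "count") x else x / k
  }
  obs <- stat(g2)
  nulls <- withr::with_seed(seed, {
    vapply(seq_len(n_rand), function(i) stat(sample(g2)), 0)
  })
  .randomization_result(obs, nulls, n_rand, seed,
                        sprintf("Group2 & South (%s)", statistic), add_one)
}

#' Randomization test: infection status vs mixed-region host haplotypes
#'
#' Tests whether infected individuals carry host mtDNA haplotypes from the
#' contact region between the northern and southern haplogroups more often
#' than expected. The observed statistic is the proportion of infected
#' individuals whose haplotype is a mixed-region haplotype; the null
#' shuffles infection status across individuals (prevalence preserved).
#'
#' @param meta host metadata with logical columns `infected` and
#'   `mixed_region`.
#' @inheritParams test_group2_south
#' @return A `randomization_test` object.
#' @export
test_infection_mixedregion <- function(meta, n_rand = 100L, seed = 1L,
                                       add_one = FALSE) {
  .check_meta_cols(meta, c("infected", "mixed_region"))
  inf <- as.logical(meta$infected)
  mix <- as.logical(meta$mixed_region)
  if (anyNA(inf) || anyNA(mix)) hc_input_error("NA in infected/mixed_region columns")
  if (sum(inf) == 0L) hc_no_test_error("no infected individuals: test not defined")
  stat <- function(ind) mean(mix[ind])
  obs <- stat(inf)
  nulls <- withr::with_seed(seed, {
    vapply(seq_len(n_rand), function(i) stat(sample(inf)), 0)
  })
  .randomization_result(obs, nulls, n_rand, seed,
                        "proportion infected with mixed-region haplotype",
                        add_one)
}

#' One-sided exact binomial infection test
#'
#' For a host haplotype carried by `n_total` individuals of which
#' `k_infected` are infected, the probability of at least `k_infected`
#' infected under a fair split:
#' \eqn{P(X \ge k) = \sum_{j=k}^{n} \binom{n}{j} 0.5^n}.
#'
#' @param k_infected number of infected carriers (vectorised).
#' @param n_total total carriers.
#' @return Exact tail probabilities.
#' @examples
#' binomial_infection_test(5, 5) # 0.03125
#' @export
binomial_infection_test <- function(k_infected, n_total) {
  if (any(n_total < 1L) || any(k_infected < 0L) || any(k_infected > n_total))
    hc_input_error("need 0 <= k_infected <= n_total and n_total >= 1")
  pbinom(k_infected - 1L, n_total, 0.5, lower.tail = FALSE)
}

#' Per-haplotype infection table with binomial tests
#'
#' Mirrors the standard figure layout: for every host mtDNA haplotype, the
#' number of infected and uninfected carriers and the one-sided exact
#' binomial p-value for an excess of infected individuals. No
#' multiple-testing correction is applied by default; `bonferroni = TRUE`
#' adds a corrected column.
#'
#' @param meta host metadata with columns `mtdna_haplotype` and `infected`.
#' @param bonferroni add a Bonferroni-corrected p-value column.
#' @return A data frame `mtdna_haplotype`, `n_infected`, `n_uninfected`,
#'   `p` (and `p_adj`).
#' @export
infection_test_table <- function(meta, bonferroni = FALSE) {
  .check_meta_cols(meta, c("mtdna_haplotype", "infected"))
  sp <- split(as.logical(meta$infected), meta$mtdna_haplotype)
  out <- data.frame(
    mtdna_haplotype = names(sp),
    n_infected = vapply(sp, sum, 0L),
    n_uninfected = vapply(sp, function(x) sum(!x), 0L),
    stringsAsFactors = FALSE)
  out$p <- binomial_infection_test(out$n_infected,
                                   out$n_infected + out$n_uninfected)
  if (bonferroni) out$p_adj <- pmin(1, out$p * nrow(out))
  rownames(out) <- NULL
  out
}

#' Write a randomization-test result as TSV
#' @param result a `randomization_test`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_randomization <- function(result, path) {
  df <- data.frame(statistic = result$statistic,
                   observed = result$observed_stat, p = result$p_value,
                   n_rand = result$n_rand, seed = result$seed)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
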