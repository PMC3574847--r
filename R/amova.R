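# One-level AMOVA on a matrix of pairwise nucleotide differences
# (Excoffier-style: sums of squared distances partitioned within/among
# groups, variance components from their expectations, Phi_ST tested by
# permuting sequence-to-group labels).

.amova_components <- function(dsq, groups) {
  N <- length(groups)
  lv <- unique(groups)
  G <- length(lv)
  ssd_total <- sum(dsq[upper.tri(dsq)]) / N
  ssd_within <- 0
  ng <- integer(G)
  for (g in seq_len(G)) {
    idx <- which(groups == lv[g])
    ng[g] <- length(idx)
    sub <- dsq[idx, idx, drop = FALSE]
    ssd_within <- ssd_within + sum(sub[upper.tri(sub)]) / ng[g]
  }
  ssd_among <- ssd_total - ssd_within
  sigma_within <- ssd_within / (N - G)
  n_prime <- (N - sum(ng^2) / N) / (G - 1)
  sigma_among <- (ssd_among / (G - 1) - sigma_within) / n_prime
  tot <- sigma_among + sigma_within
  phi <- if (tot == 0) NaN else sigma_among / tot
  list(ssd_total = ssd_total, ssd_within = ssd_within, ssd_among = ssd_among,
       sigma_among = sigma_among, sigma_within = sigma_within, phi_st = phi,
       n_groups = G, n = N)
}

.check_amova_input <- function(dist, groups) {
  if (!is.matrix(dist) || nrow(dist) != ncol(dist))
    hc_input_error("dist must be a square matrix")
  if (length(groups) != nrow(dist))
    hc_input_error("groups must have one label per sequence")
  groups <- as.character(groups)
  tab <- table(groups)
  if (length(tab) < 2L)
    hc_analysis_error("AMOVA needs at least two groups")
  small <- names(tab)[tab < 2L]
  if (length(small) > 0L)
    hc_analysis_error(sprintf("group(s) with fewer than 2 sequences: %s",
                              paste(small, collapse = ", ")))
  groups
}

#' One-level AMOVA variance components
#'
#' Partitions the variation in a matrix of pairwise sequence distances into
#' among-group and within-group variance components using squared
#' distances. Negative among-group components are permitted (the percentage
#' of variation among groups is then negative and the within-group
#' percentage exceeds 100); the two percentages always sum to exactly 100.
#' Degenerate all-zero-distance input is reported as 0/100 with a warning.
#'
#' @param dist symmetric matrix of pairwise nucleotide differences (e.g.
#'   [pairwise_distance_matrix()] of the expanded sequences).
#' @param groups group label per sequence (row of `dist`); every group
#'   needs >= 2 sequences.
#' @return An `amova_result` list: `sigma2_among`, `sigma2_within`,
#'   `pct_among`, `pct_within`, `phi_st`, sums of squares and sizes.
#' @export
amova_one_level <- function(dist, groups) {
  groups <- .check_amova_input(dist, groups)
  cmp <- .amova_components(dist^2, groups)
  tot <- cmp$sigma_among + cmp$sigma_within
  if (tot == 0) {
    warning("no molecular variance in the data; reporting 0/100 by convention")
    pct_among <- 0
    pct_within <- 100
    phi <- 0
  } else {
    pct_among <- 100 * cmp$sigma_among / tot
    pct_within <- 100 - pct_among
    phi <- cmp$phi_st
  }
  structure(list(sigma2_among = cmp$sigma_among,
                 sigma2_within = cmp$sigma_within,
                 pct_among = pct_among, pct_within = pct_within,
                 phi_st = phi, ssd_total = cmp$ssd_total,
                 ssd_within = cmp$ssd_within, ssd_among = cmp$ssd_among,
                 n = cmp$n, n_groups = cmp$n_groups),
            class = "amova_result")
}

#' Permutation p-value for the AMOVA Phi statistic
#'
#' Sequence-to-group labels are permuted (group sizes fixed), Phi_ST is
#' recomputed for each permutation, and
#' \eqn{p = (1 + \#\{\Phi_{perm} \ge \Phi_{obs}\}) / (1 + n_{perm})}.
#'
#' @inheritParams amova_one_level
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed (global RNG state preserved).
#' @return The p-value.
#' @export
amova_permutation_p <- function(dist, groups, n_perm = 10000L, seed = 1L) {
  groups <- .check_amova_input(dist, groups)
  if (n_perm < 99L) hc_parameter_error("n_perm must be >= 99")
  dsq <- dist^2
  obs <- .amova_components(dsq, groups)$phi_st
  if (is.nan(obs)) {
    warning("no molecular variance; permutation p-value reported as 1")
    return(1)
  }
  phis <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i)
      .amova_components(dsq, sample(groups))$phi_st, 0)
  })
  (1 + sum(phis >= obs, na.rm = TRUE)) / (1 + n_perm)
}

#' One-level AMOVA with permutation test
#'
#' Convenience wrapper combining [amova_one_level()] and
#' [amova_permutation_p()].
#'
#' @inheritParams amova_permutation_p
#' @return An `amova_result` with `p_value`, `n_perm` and `seed` added.
#' @export
amova <- function(dist, groups, n_perm = 10000L, seed = 1L) {
  res <- amova_one_level(dist, groups)
  res$p_value <- amova_permutation_p(dist, groups, n_perm = n_perm, seed = seed)
  res$n_perm <- n_perm
  res$seed <- seed
  res
}

#' @export
print.amova_result <- function(x, ...) {
  cat("One-level AMOVA\n")
  cat(sprintf("  variance components: among = %.4f, within = %.4f\n",
              x$sigma2_among, x$sigma2_within))
  cat(sprintf("  percentage of variation: among = %.2f, within = %.2f\n",
              x$pct_among, x$pct_within))
  cat(sprintf("  Phi_ST = %.4f", x$phi_st))
  if (!is.null(x$p_value))
    cat(sprintf(", p = %.4g (%d permutations)", x$p_value, x$n_perm))
  cat("\n")
  invisible(x)
}

#' Write AMOVA results as TSV
#'
#' @param results named list of `amova_result` objects (names label the
#'   comparisons/datasets).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_amova <- function(results, path) {
  rows <- lapply(names(results), function(nm) {
    x <- results[[nm]]
    data.frame(comparison = nm, sigma2_among = x$sigma2_among,
               sigma2_within = x$sigma2_within, pct_among = x$pct_among,
               pct_within = x$pct_within, phi_st = x$phi_st,
               p = if (is.null(x$p_value)) NA_real_ else x$p_value,
               n_perm = if (is.null(x$n_perm)) NA_integer_ else x$n_perm,
               seed = if (is.null(x$seed)) NA_integer_ else x$seed,
               stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
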