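# Site-exclusion rule for diversity statistics: "complete deletion" —
# every column containing '-' or 'N' in the analysed set of sequences is
# dropped before computing pi, S and k. Pairwise deletion is available as
# an option for pi/k via `deletion = "pairwise"`.

complete_deletion <- function(m) {
  keep <- apply(m, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  m[, keep, drop = FALSE]
}

#' Haplotype diversity (Nei's unbiased estimator)
#'
#' \eqn{H_d = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)} with
#' \eqn{p_i = count_i / n}: the probability that two sequences sampled
#' without replacement are different haplotypes.
#'
#' @param counts integer vector of haplotype multiplicities (a
#'   `haplotype_table` is also accepted).
#' @return `Hd` in `[0, 1]`.
#' @examples
#' haplotype_diversity(c(3, 3)) # 0.6
#' @export
haplotype_diversity <- function(counts) {
  if (inherits(counts, "haplotype_table")) counts <- counts$count
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) hc_undefined_error("haplotype diversity undefined for n < 2")
  p <- counts / n
  n * (1 - sum(p^2)) / (n - 1)
}

# weighted average pairwise differences and per-site diversity in one pass
.pairwise_stats <- function(aln, weights, deletion) {
  stopifnot(inherits(aln, "haplo_alignment"))
  if (is.null(weights)) weights <- rep(1L, length(aln$ids))
  if (length(weights) != length(aln$ids))
    hc_input_error("weights must match the number of sequences")
  n <- sum(weights)
  if (n < 2) hc_undefined_error("statistic undefined for n < 2")
  m <- seq_matrix(aln)
  if (deletion == "complete") {
    m <- complete_deletion(m)
    L_eff <- ncol(m)
    if (L_eff == 0L) hc_undefined_error("all sites excluded by complete deletion")
  } else {
    L_eff <- ncol(m)
  }
  tot <- 0
  nh <- nrow(m)
  if (nh > 1L) {
    for (i in seq_len(nh - 1L)) {
      for (j in (i + 1L):nh) {
        if (deletion == "complete") {
          d <- sum(m[i, ] != m[j, ])
        } else {
          ok <- m[i, ] %in% c("A", "C", "G", "T") & m[j, ] %in% c("A", "C", "G", "T")
          d <- sum(m[i, ok] != m[j, ok])
        }
        tot <- tot + weights[i] * weights[j] * d
      }
    }
  }
  k <- tot / (n * (n - 1) / 2)
  list(k = k, L_eff = L_eff)
}

#' Average number of pairwise nucleotide differences (k)
#'
#' Unordered pairs over the expanded sequence multiset; multiplicities are
#' expanded exactly, never sampled.
#'
#' @param aln a [alignment()] of distinct sequences (or any sequences).
#' @param weights multiplicity of each sequence (default 1 each).
#' @param deletion `"complete"` (drop every column with `-`/`N`; the
#'   default) or `"pairwise"`.
#' @return k (differences per pair, unnormalised by length).
#' @export
avg_pairwise_differences <- function(aln, weights = NULL,
                                     deletion = c("complete", "pairwise")) {
  .pairwise_stats(aln, weights, match.arg(deletion))$k
}

#' Nucleotide diversity per site (pi)
#'
#' \eqn{\pi = k / L_{eff}} where `k` is [avg_pairwise_differences()] and
#' \eqn{L_{eff}} the number of analysed sites after the deletion rule.
#'
#' @inheritParams avg_pairwise_differences
#' @return pi (per-site, >= 0).
#' @export
nucleotide_diversity <- function(aln, weights = NULL,
                                 deletion = c("complete", "pairwise")) {
  s <- .pairwise_stats(aln, weights, match.arg(deletion))
  s$k / s$L_eff
}

#' Number of segregating sites (S)
#'
#' Analysed columns (after complete deletion) with two or more character
#' states.
#'
#' @param aln a [alignment()] object.
#' @return Integer count.
#' @export
segregating_sites <- function(aln) {
  stopifnot(inherits(aln, "haplo_alignment"))
  if (length(aln$ids) < 2L) hc_undefined_error("S undefined for n < 2")
  m <- complete_deletion(seq_matrix(aln))
  if (ncol(m) == 0L) return(0L)
  sum(apply(m, 2, function(col) length(unique(col)) >= 2L))
}

#' Diversity summaries per group
#'
#' Computes, for every group and for the pooled dataset, the number of
#' sequences and haplotypes, haplotype diversity, nucleotide diversity,
#' segregating sites and average pairwise differences. The sequence unit is
#' one haplotype occurrence per carrier individual (`unit = "carrier"`,
#' matching how clone-library tables report "sequences"), or the raw clone
#' multiplicities (`unit = "clone"`, whole-dataset row only).
#'
#' Groups with fewer than 2 sequences are reported with `NA` statistics.
#'
#' @param ht a `haplotype_table`.
#' @param grouping named character vector mapping `individual_id` to a group
#'   label, or `NULL` for the whole-dataset summary only.
#' @param unit see above.
#' @return A data frame with one row per group plus a `"(all)"` row:
#'   columns `group`, `n_sequences`, `n_haplotypes`, `Hd`, `pi`, `S`, `k`.
#' @export
summarize_groups <- function(ht, grouping = NULL, unit = c("carrier", "clone")) {
  unit <- match.arg(unit)
  ex <- expand_haplotypes(ht, unit = if (unit == "carrier") "carrier" else "clone")
  one <- function(label, haps, wts) {
    n <- sum(wts)
    if (n < 2) {
      return(data.frame(group = label, n_sequences = n,
                        n_haplotypes = length(haps), Hd = NA_real_,
                        pi = NA_real_, S = NA_integer_, k = NA_real_,
                        stringsAsFactors = FALSE))
    }
    sub <- ht[match(haps, ht$haplotype_id), ]
    aln <- alignment(sub$haplotype_id, sub$sequence)
    st <- .pairwise_stats(aln, wts, "complete")
    S <- if (length(haps) < 2L) 0L else segregating_sites(aln)
    data.frame(group = label, n_sequences = n, n_haplotypes = length(haps),
               Hd = haplotype_diversity(wts), pi = st$k / st$L_eff,
               S = S, k = st$k, stringsAsFactors = FALSE)
  }
  weights_of <- function(rows) {
    tab <- table(rows$haplotype_id)
    list(haps = names(tab), wts = as.integer(tab))
  }
  out <- list()
  if (!is.null(grouping)) {
    if (unit != "carrier")
      hc_input_error("per-group summaries require unit = 'carrier'")
    missing <- setdiff(unique(ex$individual_id), names(grouping))
    if (length(missing) > 0L)
      hc_input_error(sprintf("grouping does not cover carriers: %s",
                             paste(missing, collapse = ", ")))
    ex$group <- unname(grouping[ex$individual_id])
    for (g in sort(unique(ex$group))) {
      w <- weights_of(ex[ex$group == g, ])
      out[[length(out) + 1L]] <- one(g, w$haps, w$wts)
    }
  }
  w <- weights_of(ex)
  out[[length(out) + 1L]] <- one("(all)", w$haps, w$wts)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a diversity summary as TSV
#'
#' Haplotype diversity is printed to 3 decimals and nucleotide diversity to
#' 5, matching the conventional report precision; the unrounded values stay
#' in the returned data frame.
#'
#' @param summary output of [summarize_groups()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_diversity <- function(summary, path) {
  out <- summary
  out$Hd <- sprintf("%.3f", out$Hd)
  out$pi <- sprintf("%.5f", out$pi)
  out$k <- sprintf("%.4f", out$k)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
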