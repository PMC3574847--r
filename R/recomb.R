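#' Polymorphic site indices of an alignment
#'
#' Columns with at least two distinct plain bases (gaps and `N` ignored),
#' in ascending order. These columns are the substrate of the recombination
#' statistic.
#'
#' @param aln a [alignment()] object.
#' @return Integer vector of 1-based column indices.
#' @export
polymorphic_sites <- function(aln) {
  stopifnot(inherits(aln, "haplo_alignment"))
  if (length(aln$ids) < 2L) hc_input_error("need >= 2 sequences")
  m <- seq_matrix(aln)
  which(apply(m, 2, function(col) {
    b <- col[col %in% c("A", "C", "G", "T")]
    length(unique(b)) >= 2L
  }))
}

#' Maximal mismatch-free run between two restricted sequences
#'
#' Given two sequences restricted to the polymorphic sites of their
#' alignment, returns the longest run of consecutive sites at which the pair
#' agrees — the "inner fragment" score. Runs are broken by any mismatch
#' (and by gap/N positions); ties are broken by the smallest start.
#'
#' @param a,b equal-length character vectors (or strings) of the restricted
#'   sequences.
#' @return A list with `score` (run length), and `start`/`end`
#'   (1-based, half-open, in polymorphic-site coordinates; `NA` when the
#'   score is 0).
#' @export
max_inner_fragment <- function(a, b) {
  if (length(a) == 1L) a <- strsplit(a, "")[[1]]
  if (length(b) == 1L) b <- strsplit(b, "")[[1]]
  if (length(a) == 0L || length(a) != length(b))
    hc_input_error("restricted sequences must be non-empty and equal length")
  m <- a == b & a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  r <- rle(m)
  if (!any(r$values)) return(list(score = 0L, start = NA_integer_, end = NA_integer_))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]  # which.max -> smallest start on ties
  list(score = as.integer(r$lengths[best]),
       start = as.integer(starts[best]), end = as.integer(ends[best] + 1L))
}

# max run per row of a logical matrix
.row_max_runs <- function(M) {
  apply(M, 1, function(x) {
    r <- rle(x)
    if (any(r$values)) max(r$lengths[r$values]) else 0L
  })
}

#' Permutation screen for recombinant haplotypes
#'
#' Detects sequences whose pairwise similarity is concentrated in a run of
#' consecutive polymorphic sites longer than expected by chance — the
#' signature of gene conversion or of PCR-mediated template switching. For
#' every haplotype pair the observed statistic is the maximal mismatch-free
#' run over the alignment's polymorphic sites; the null distribution is
#' built by jointly permuting the order of the polymorphic-site columns
#' across all sequences and recording the global (all-pairs) maximum run per
#' permutation. Per-pair p-values are
#' \eqn{(1 + \#\{null \ge obs\}) / (1 + n_{perm})}, Bonferroni-corrected over
#' tested pairs; in each flagged pair the lower-frequency member (ties:
#' lexicographically later sequence) is marked as the putative recombinant.
#'
#' Fewer than 3 haplotypes or fewer than 2 polymorphic sites yield a
#' "no test" result with nothing flagged.
#'
#' @param ht a `haplotype_table` (counts are used for the flagging rule).
#' @param n_perm number of column permutations (>= 100).
#' @param seed integer seed (the global RNG state is preserved).
#' @param alpha family-wise significance level.
#' @return A `geneconv_result` list: `pairs` (per-pair scores, alignment
#'   spans as 0-based half-open columns, raw and corrected p-values,
#'   flagged member), `flagged` (haplotype ids), `tested`, `n_poly`,
#'   `n_perm`, `seed`, `alpha`.
#' @export
geneconv_test <- function(ht, n_perm = 10000L, seed = 1L, alpha = 0.05) {
  stopifnot(inherits(ht, "haplotype_table"))
  if (n_perm < 100L) hc_parameter_error("n_perm must be >= 100")
  no_test <- function(n_poly) {
    structure(list(pairs = NULL, flagged = character(0), tested = FALSE,
                   n_poly = n_poly, n_perm = n_perm, seed = seed,
                   alpha = alpha), class = "geneconv_result")
  }
  if (nrow(ht) < 3L) return(no_test(NA_integer_))
  # canonical internal order: lexicographic by sequence, so results are
  # invariant to input order for a fixed seed
  ord <- lex_order(ht$sequence)
  seqs <- ht$sequence[ord]
  ids <- ht$haplotype_id[ord]
  counts <- ht$count[ord]

  aln <- alignment(ids, seqs)
  ps <- polymorphic_sites(aln)
  S <- length(ps)
  if (S < 2L) return(no_test(S))
  m <- seq_matrix(aln)[, ps, drop = FALSE]
  okb <- m %in% c("A", "C", "G", "T")
  dim(okb) <- dim(m)

  prs <- combn(length(ids), 2L)
  P <- ncol(prs)
  M <- matrix(FALSE, P, S)
  for (k in seq_len(P)) {
    i <- prs[1, k]; j <- prs[2, k]
    M[k, ] <- m[i, ] == m[j, ] & okb[i, ] & okb[j, ]
  }

  obs <- integer(P)
  span <- matrix(NA_integer_, P, 2)
  for (k in seq_len(P)) {
    f <- max_inner_fragment(m[prs[1, k], ], m[prs[2, k], ])
    obs[k] <- f$score
    if (f$score > 0L)
      span[k, ] <- c(ps[f$start] - 1L, ps[f$end - 1L])  # 0-based half-open
  }

  null_max <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(S)
      max(.row_max_runs(M[, idx, drop = FALSE]))
    }, 0L)
  })

  p_raw <- vapply(obs, function(o) (1 + sum(null_max >= o)) / (1 + n_perm), 0)
  p_adj <- pmin(1, p_raw * P)
  sig <- p_adj < alpha

  flag_member <- function(k) {
    i <- prs[1, k]; j <- prs[2, k]
    if (counts[i] != counts[j]) {
      if (counts[i] < counts[j]) i else j
    } else {
      # tie: lexicographically later sequence
      if (seqs[i] > seqs[j]) i else j
    }
  }
  flagged_idx <- if (any(sig)) vapply(which(sig), flag_member, 0L) else integer(0)

  pairs <- data.frame(
    id_a = ids[prs[1, ]], id_b = ids[prs[2, ]], score = obs,
    span_start = span[, 1], span_end = span[, 2],
    p = p_raw, p_adj = p_adj,
    flagged_id = NA_character_, stringsAsFactors = FALSE)
  pairs$flagged_id[sig] <- ids[flagged_idx]

  structure(list(pairs = pairs, flagged = sort(unique(ids[flagged_idx])),
                 tested = TRUE, n_poly = S, n_perm = n_perm, seed = seed,
                 alpha = alpha),
            class = "geneconv_result")
}

#' @export
print.geneconv_result <- function(x, ...) {
  if (!x$tested) {
    cat("<geneconv_result> no test (too few haplotypes or polymorphic sites)\n")
  } else {
    cat(sprintf(
      "<geneconv_result> %d pairs over %d polymorphic sites, %d permutations; flagged: %s\n",
      nrow(x$pairs), x$n_poly, x$n_perm,
      if (length(x$flagged)) paste(x$flagged, collapse = ", ") else "none"))
  }
  invisible(x)
}

#' Remove flagged recombinants from a haplotype table
#'
#' @param ht a `haplotype_table`.
#' @param result a [geneconv_test()] result (or a character vector of
#'   haplotype ids).
#' @return The table without the flagged haplotypes.
#' @export
remove_recombinants <- function(ht, result) {
  flagged <- if (inherits(result, "geneconv_result")) result$flagged else result
  out <- ht[!ht$haplotype_id %in% flagged, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "L") <- attr(ht, "L")
  class(out) <- class(ht)
  out
}

#' Write a recombination-screen report as TSV
#' @param result a `geneconv_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_geneconv_report <- function(result, path) {
  tab <- if (result$tested) result$pairs else
    data.frame(id_a = character(0), id_b = character(0), score = integer(0),
               span_start = integer(0), span_end = integer(0), p = numeric(0),
               p_adj = numeric(0), flagged_id = character(0))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
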