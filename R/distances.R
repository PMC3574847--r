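# Pairwise Hamming distances with the shared gap/N exclusion rule:
# a column contributes to d(a, b) only when both sequences carry a plain
# base (A/C/G/T) there. Indels and ambiguities are treated as alignment
# artifacts, not substitutions.

#' Hamming distance between two aligned sequences
#'
#' Columns where either sequence has `-` or `N` are excluded.
#'
#' @param a,b equal-length DNA strings (or character vectors of single
#'   characters).
#' @return Integer count of differing columns.
#' @export
hamming <- function(a, b) {
  if (length(a) == 1L) a <- strsplit(a, "")[[1]]
  if (length(b) == 1L) b <- strsplit(b, "")[[1]]
  if (length(a) != length(b)) hc_alignment_error("sequences of unequal length")
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  sum(a[ok] != b[ok])
}

#' Pairwise distance matrix of nucleotide differences
#'
#' The substrate for network construction and AMOVA: a symmetric matrix of
#' Hamming distances under the gap/N exclusion rule.
#'
#' @param seqs character vector of equal-length sequences, a
#'   [alignment()] object, or a `haplotype_table`.
#' @return Symmetric integer matrix with zero diagonal, dimnames taken from
#'   record/haplotype ids when available.
#' @export
pairwise_distance_matrix <- function(seqs) {
  if (inherits(seqs, "haplotype_table")) {
    ids <- seqs$haplotype_id
    seqs <- seqs$sequence
  } else if (inherits(seqs, "haplo_alignment")) {
    ids <- seqs$ids
    seqs <- seqs$seqs
  } else {
    ids <- names(seqs)
    seqs <- as.character(seqs)
  }
  n <- length(seqs)
  if (n == 0L) hc_input_error("no sequences")
  if (length(unique(nchar(seqs))) != 1L)
    hc_alignment_error("sequences of unequal length")
  m <- do.call(rbind, strsplit(seqs, ""))
  ok <- m == "A" | m == "C" | m == "G" | m == "T"
  D <- matrix(0L, n, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        v <- ok[i, ] & ok[j, ]
        d <- sum(m[i, v] != m[j, v])
        D[i, j] <- D[j, i] <- d
      }
    }
  }
  dimnames(D) <- list(ids, ids)
  D
}
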