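# Fixtures are generated in code; seeds are always explicit.

BASES <- c("A", "C", "G", "T")

rand_seq <- function(L) paste(sample(BASES, L, replace = TRUE), collapse = "")

mutate_seq <- function(seq, positions) {
  ch <- strsplit(seq, "")[[1]]
  for (p in positions) ch[p] <- sample(setdiff(BASES, ch[p]), 1L)
  paste(ch, collapse = "")
}

# random alignment of n sequences derived from one ancestor (star tree)
star_alignment <- function(seed, n = 6, L = 120, subs = 3:6) {
  withr::with_seed(seed, {
    base <- rand_seq(L)
    seqs <- vapply(seq_len(n), function(i)
      mutate_seq(base, sample.int(L, sample(subs, 1L))), "")
    alignment(paste0("s", seq_len(n)), seqs)
  })
}

star_haplotypes <- function(seed, n = 6, L = 120, subs = 3:6) {
  aln <- star_alignment(seed, n, L, subs)
  collapse_haplotypes(clone_records(paste0("I", seq_along(aln$ids)), aln$seqs))
}

# two parents (count 2 each) and a spliced child singleton; parents differ
# at n_sites positions, the child takes the first half from parent 1 and
# the second half from parent 2
recomb_trio <- function(seed, n_sites = 20, L = 120) {
  withr::with_seed(seed, {
    p1 <- rand_seq(L)
    pos <- sort(sample.int(L, n_sites))
    p2 <- mutate_seq(p1, pos)
    half <- pos[(n_sites / 2 + 1):n_sites]
    child <- strsplit(p1, "")[[1]]
    child[half] <- strsplit(p2, "")[[1]][half]
    child <- paste(child, collapse = "")
    cl <- clone_records(
      individual_id = c("I1", "I1", "I2", "I2", "I3"),
      sequence = c(p1, p1, p2, p2, child))
    ht <- collapse_haplotypes(cl)
    attr(ht, "child_id") <- ht$haplotype_id[match(child, ht$sequence)]
    ht
  })
}

# independent complete-deletion pairwise-difference oracle (brute force over
# the expanded multiset)
oracle_k <- function(seqs, weights) {
  m <- do.call(rbind, strsplit(seqs, ""))
  keep <- apply(m, 2, function(col) all(col %in% BASES))
  m <- m[, keep, drop = FALSE]
  expanded <- m[rep(seq_along(weights), weights), , drop = FALSE]
  n <- nrow(expanded)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    tot <- tot + sum(expanded[i, ] != expanded[j, ])
  list(k = tot / (n * (n - 1) / 2), L_eff = ncol(m))
}
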