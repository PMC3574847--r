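#' Probability that a j-step connection is non-homoplastic
#'
#' The statistical-parsimony criterion connects two haplotypes differing at
#' `j` sites only when those differences can be trusted to represent `j`
#' single substitution events. Modelling substitutions as falling uniformly
#' and independently over the `L` alignment sites, the probability that `j`
#' events strike `j` distinct sites (no superimposed change, so the
#' parsimonious interpretation holds) is
#' \eqn{P_j = \prod_{i=1}^{j-1} (1 - i/L)}.
#'
#' @param j number of mutational steps (vectorised).
#' @param L alignment length in bp.
#' @return Probabilities in `(0, 1]`.
#' @export
parsimony_probability <- function(j, L) {
  vapply(j, function(jj) {
    if (jj <= 1) return(1)
    if (jj > L) return(0)
    prod(1 - seq_len(jj - 1L) / L)
  }, 0)
}

#' Statistical-parsimony connection limit
#'
#' Largest number of mutational steps `j` whose probability of a
#' non-homoplastic connection ([parsimony_probability()]) still reaches the
#' confidence level; pairs further apart than the limit are left
#' unconnected. The limit is monotone non-decreasing in `L`.
#'
#' @param L alignment length in bp.
#' @param confidence probability-of-parsimony threshold, default 0.95.
#' @param max_steps optional cap on the returned limit.
#' @return Integer number of steps (>= 1).
#' @export
connection_limit <- function(L, confidence = 0.95, max_steps = NULL) {
  if (L < 1L) hc_parameter_error("L must be >= 1")
  if (confidence <= 0 || confidence >= 1)
    hc_parameter_error("confidence must be in (0, 1)")
  j <- 1L
  P <- 1
  cap <- if (is.null(max_steps)) L else min(L, max_steps)
  while (j < cap) {
    P_next <- P * (1 - j / L)
    if (P_next < confidence) break
    P <- P_next
    j <- j + 1L
  }
  j
}

# minimal union-find
.uf_new <- function(n) seq_len(n)
.uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}
.uf_union <- function(parent, i, j) {
  ri <- .uf_find(parent, i); rj <- .uf_find(parent, j)
  if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  parent
}
.uf_components <- function(parent) {
  vapply(seq_along(parent), function(i) .uf_find(parent, i), 0L)
}

#' Build statistical-parsimony haplotype networks
#'
#' Greedy agglomeration in ascending distance order: haplotype pairs at 1
#' mutational step are connected first, then 2, and so on up to the
#' connection limit; each edge at `d` steps implies `d - 1` inferred
#' intermediate haplotypes. Pairs beyond the limit stay unconnected, so the
#' result may consist of several disjoint networks (components), returned
#' sorted by total haplotype frequency. Within a distance class the
#' higher-frequency pair is processed first (then lexicographic ids);
#' alternative equal-length connections (loops) are retained in the edge
#' set rather than broken.
#'
#' @param ht a `haplotype_table`.
#' @param limit connection limit in steps; default
#'   `connection_limit(L, confidence)`.
#' @param confidence used only when `limit` is `NULL`.
#' @return A `haplo_network` list: `nodes` (id, count, component), `edges`
#'   (from, to, steps, intermediates), `components` (list of id vectors,
#'   ordered by total frequency), `limit`.
#' @export
build_networks <- function(ht, limit = NULL, confidence = 0.95) {
  stopifnot(inherits(ht, "haplotype_table"))
  if (nrow(ht) == 0L) hc_input_error("empty haplotype table")
  L <- nchar(ht$sequence[1])
  if (is.null(limit)) limit <- connection_limit(L, confidence)
  D <- pairwise_distance_matrix(ht)
  n <- nrow(ht)
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  d <- D[pairs]
  keep <- d <= limit
  pairs <- pairs[keep, , drop = FALSE]
  d <- d[keep]
  pairfreq <- ht$count[pairs[, 1]] + ht$count[pairs[, 2]]
  ord <- lex_order(d, -pairfreq, ht$haplotype_id[pairs[, 1]],
                   ht$haplotype_id[pairs[, 2]])
  parent <- .uf_new(n)
  for (k in ord) parent <- .uf_union(parent, pairs[k, 1], pairs[k, 2])
  comp_raw <- .uf_components(parent)

  # rank components by total frequency (desc), then size, then smallest id
  comp_ids <- unique(comp_raw)
  tot <- vapply(comp_ids, function(c) sum(ht$count[comp_raw == c]), 0)
  siz <- vapply(comp_ids, function(c) sum(comp_raw == c), 0L)
  first_id <- vapply(comp_ids, function(c) min(ht$haplotype_id[comp_raw == c]), "")
  rank <- lex_order(-tot, -siz, first_id)
  comp_rank <- match(comp_raw, comp_ids[rank])

  edges <- data.frame(
    from = ht$haplotype_id[pairs[ord, 1]], to = ht$haplotype_id[pairs[ord, 2]],
    steps = d[ord], intermediates = pmax(0L, d[ord] - 1L),
    stringsAsFactors = FALSE)
  nodes <- data.frame(haplotype_id = ht$haplotype_id, count = ht$count,
                      component = comp_rank, stringsAsFactors = FALSE)
  components <- lapply(seq_along(comp_ids), function(r)
    ht$haplotype_id[comp_rank == r])
  structure(list(nodes = nodes, edges = edges, components = components,
                 limit = limit), class = "haplo_network")
}

#' @export
print.haplo_network <- function(x, ...) {
  cat(sprintf("<haplo_network> %d haplotypes, %d edges, %d network(s), connection limit %d steps\n",
              nrow(x$nodes), nrow(x$edges), length(x$components), x$limit))
  invisible(x)
}

#' Assign network group and subgroup labels
#'
#' Each disjoint network is one group, labelled `Group1`, `Group2`, ... in
#' order of total haplotype frequency. Within a group, subgroups are the
#' components that remain after removing edges longer than
#' `subgroup_threshold` steps, labelled `1a`, `1b`, ... by descending
#' frequency; a group that does not split gets no subgroup label.
#'
#' @param network a [build_networks()] result.
#' @param subgroup_threshold maximal steps kept inside a subgroup
#'   (default 5).
#' @return A data frame `haplotype_id`, `group`, `subgroup`.
#' @export
assign_groups <- function(network, subgroup_threshold = 5L) {
  stopifnot(inherits(network, "haplo_network"))
  nodes <- network$nodes
  out <- data.frame(haplotype_id = nodes$haplotype_id,
                    group = paste0("Group", nodes$component),
                    subgroup = NA_character_, stringsAsFactors = FALSE)
  short <- network$edges[network$edges$steps <= subgroup_threshold, , drop = FALSE]
  for (g in sort(unique(nodes$component))) {
    ids <- nodes$haplotype_id[nodes$component == g]
    n <- length(ids)
    parent <- .uf_new(n)
    e <- short[short$from %in% ids & short$to %in% ids, , drop = FALSE]
    for (k in seq_len(nrow(e)))
      parent <- .uf_union(parent, match(e$from[k], ids), match(e$to[k], ids))
    sub_raw <- .uf_components(parent)
    sub_ids <- unique(sub_raw)
    if (length(sub_ids) <= 1L) next
    cnt <- nodes$count[match(ids, nodes$haplotype_id)]
    tot <- vapply(sub_ids, function(s) sum(cnt[sub_raw == s]), 0)
    first_id <- vapply(sub_ids, function(s) min(ids[sub_raw == s]), "")
    rank <- match(sub_raw, sub_ids[lex_order(-tot, first_id)])
    out$subgroup[match(ids, out$haplotype_id)] <- paste0(g, letters[rank])
  }
  out
}

#' Write a network edge list as TSV
#'
#' @param network a `haplo_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  write.table(network$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
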