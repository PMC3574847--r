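test_that("the connection limit matches a directly evaluated probability series", {
  # independent evaluation: cumulative product of no-collision probabilities
  direct_limit <- function(L, conf) {
    P <- cumprod(c(1, 1 - seq_len(L - 1) / L))  # P[j] for j = 1..L steps
    max(which(P >= conf))
  }
  expect_equal(connection_limit(600), direct_limit(600, 0.95))
  expect_equal(connection_limit(1200), direct_limit(1200, 0.95))
  expect_equal(connection_limit(600, 0.99), direct_limit(600, 0.99))
  # near-certain confidence connects single steps only
  expect_lte(connection_limit(600, 1 - 1e-12), 1)
  # monotone non-decreasing in L
  lims <- vapply(c(100, 300, 600, 1200, 2400), connection_limit, 0L)
  expect_true(all(diff(lims) >= 0))
  expect_gte(connection_limit(1200), connection_limit(600))
})

test_that("simple networks connect as designed", {
  withr::with_seed(41, {
    s <- rand_seq(100)
    ht <- collapse_haplotypes(clone_records(c("I1", "I2"),
                                            c(s, mutate_seq(s, 7L))))
    net <- build_networks(ht, limit = 5)
    expect_length(net$components, 1)
    expect_equal(nrow(net$edges), 1)
    expect_equal(net$edges$steps, 1L)
    expect_equal(net$edges$intermediates, 0L)
    # two clusters separated far beyond the limit split into two networks
    far <- mutate_seq(s, 30:70)
    ht2 <- collapse_haplotypes(clone_records(
      paste0("I", 1:4), c(s, mutate_seq(s, 7L), far, mutate_seq(far, 2L))))
    net2 <- build_networks(ht2, limit = 5)
    expect_length(net2$components, 2)
  })
})

test_that("components equal the brute-force threshold-graph oracle", {
  for (s in 1:8) {
    ht <- star_haplotypes(50 + s, n = 15, L = 150, subs = 2:14)
    limit <- 6L
    net <- build_networks(ht, limit = limit)
    D <- pairwise_distance_matrix(ht)
    g <- igraph::graph_from_adjacency_matrix(D <= limit, mode = "undirected",
                                             diag = FALSE)
    oracle <- igraph::components(g)$membership
    mine <- net$nodes$component
    # same partition: identical co-membership structure
    expect_equal(unname(outer(mine, mine, "==")),
                 unname(outer(as.vector(oracle), as.vector(oracle), "==")))
  }
})

test_that("component count is non-increasing in the connection limit", {
  ht <- star_haplotypes(77, n = 12, L = 120, subs = 2:12)
  counts <- vapply(1:12, function(l)
    length(build_networks(ht, limit = l)$components), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("within-network path lengths respect the parsimony lower bound", {
  ht <- star_haplotypes(78, n = 10, L = 150, subs = 2:8)
  net <- build_networks(ht, limit = 10)
  D <- pairwise_distance_matrix(ht)
  g <- igraph::graph_from_data_frame(net$edges[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = net$nodes$haplotype_id)
  sp <- igraph::distances(g, weights = net$edges$steps)
  finite <- is.finite(sp)
  expect_true(all(sp[finite] >= D[rownames(sp), colnames(sp)][finite] - 1e-9))
})

test_that("groups and subgroups are labelled by frequency and are order-invariant", {
  withr::with_seed(55, {
    root <- rand_seq(300)
    centr <- lapply(c(1, 2, 3), function(i) mutate_seq(root, (i * 4):(i * 4 + 2)))
    far <- mutate_seq(root, 101:160)
    seqs <- c(centr[[1]], mutate_seq(centr[[1]], 200L),
              centr[[2]], centr[[3]], far, mutate_seq(far, 250L))
    counts <- c(6, 2, 4, 3, 2, 1)
    cl <- clone_records(paste0("I", rep(seq_along(seqs), counts)),
                        rep(seqs, counts))
    ht <- collapse_haplotypes(cl)
    net <- build_networks(ht, limit = 10)
    lab <- assign_groups(net, subgroup_threshold = 3)
    byseq <- setNames(lab$group, ht$sequence)
    # the high-frequency cluster is Group1, the far pair Group2
    expect_equal(unname(byseq[centr[[1]]]), "Group1")
    expect_equal(unname(byseq[far]), "Group2")
    subs <- setNames(lab$subgroup, ht$sequence)
    expect_equal(unname(subs[centr[[1]]]), "1a")  # heaviest subgroup
    expect_equal(unname(subs[mutate_seq(centr[[1]], 200L)]), "1a")
    expect_setequal(unname(subs[c(centr[[2]], centr[[3]])]), c("1b", "1c"))
    # a single unsplit component gets no subgroup labels
    one <- build_networks(collapse_haplotypes(
      clone_records(c("I1", "I2"), c(root, mutate_seq(root, 1L)))), limit = 5)
    lab1 <- assign_groups(one, subgroup_threshold = 5)
    expect_true(all(is.na(lab1$subgroup)))
    # label assignment invariant under input order
    perm <- sample.int(nrow(ht))
    ht2 <- ht[perm, ]
    attr(ht2, "L") <- attr(ht, "L")
    class(ht2) <- class(ht)
    lab2 <- assign_groups(build_networks(ht2, limit = 10),
                          subgroup_threshold = 3)
    m1 <- lab[order(lab$haplotype_id), c("group", "subgroup")]
    m2 <- lab2[order(lab2$haplotype_id), c("group", "subgroup")]
    expect_equal(m1$group, m2$group)
    expect_equal(m1$subgroup, m2$subgroup)
  })
})
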