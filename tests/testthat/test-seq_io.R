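test_that("alignment construction validates lengths, ids and alphabet", {
  aln <- alignment(c("a", "b", "c"), c("ACGTACGTAC", "ACGTACGTAA", "ACGTACGTNN"))
  expect_equal(aln$L, 10)
  expect_length(aln$ids, 3)
  expect_error(alignment(c("a", "b"), c("ACGTACGTAC", "ACGTACGTA")),
               class = "hc_alignment_error")
  expect_error(alignment(c("a", "a"), c("ACGT", "ACGA")),
               class = "hc_input_error")
  expect_error(alignment("a", "ACRT"), class = "hc_input_error")
  expect_error(alignment("a", ""), class = "hc_alignment_error")
})

test_that("FASTA round trip is lossless and lowercase input is uppercased", {
  aln <- withr::with_seed(11, {
    alignment(sprintf("JN|JN%d|r%d|c%02d", rep(1:5, each = 4),
                      rep(1:2, 10), 1:20),
              replicate(20, rand_seq(60)))
  })
  f1 <- withr::local_tempfile(fileext = ".fasta")
  write_alignment(aln, f1)
  back <- read_alignment(f1)
  expect_equal(back$ids, aln$ids)
  expect_equal(back$seqs, aln$seqs)
  # lowercase file reads to the same haplotypes as the uppercase one
  f2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(paste0(">", aln$ids, "\n", tolower(aln$seqs)), f2)
  low <- read_alignment(f2)
  expect_equal(low$seqs, aln$seqs)
})

test_that("clone labels parse under the configurable scheme", {
  aln <- alignment(c("JN|JN6|r1|c03", "BK|BK2|r2|c01"),
                   c("ACGTAC", "ACGTAA"))
  cl <- parse_clone_labels(aln)
  expect_equal(cl$site_code, c("JN", "BK"))
  expect_equal(cl$individual_id, c("JN6", "BK2"))
  expect_equal(cl$pcr_replicate, c(1L, 2L))
  bad <- alignment("JN|JN6|c03", "ACGTAC")
  expect_error(parse_clone_labels(bad), "JN\\|JN6\\|c03",
               class = "hc_input_error")
  nonum <- alignment("JN|JN6|rx|c03", "ACGTAC")
  expect_error(parse_clone_labels(nonum), class = "hc_input_error")
  # alternative field order
  alt <- parse_clone_labels(
    alignment("JN6_1_c03_JN", "ACGTAC"),
    label_scheme("_", c("individual", "replicate", "clone", "site")))
  expect_equal(alt$site_code, "JN")
  expect_equal(alt$pcr_replicate, 1L)
})

test_that("clone labels survive a write/read round trip at study scale", {
  study <- simulate_study(seed = 3)
  f <- withr::local_tempfile(fileext = ".fasta")
  write_clone_fasta(study$clones, f)
  back <- parse_clone_labels(read_alignment(f))
  expect_equal(length(unique(back$individual_id)), 47)
  expect_equal(length(unique(back$site_code)), 10)
  expect_equal(back$sequence, study$clones$sequence)
  expect_equal(back$individual_id, study$clones$individual_id)
  expect_equal(back$pcr_replicate, study$clones$pcr_replicate)
})

test_that("identical clones collapse to a single haplotype with full count", {
  cl <- clone_records(rep("JN6", 8), rep("ACGTACGTAC", 8))
  ht <- collapse_haplotypes(cl)
  expect_equal(nrow(ht), 1)
  expect_equal(ht$count, 8)
  expect_equal(ht$carriers[[1]], "JN6")
})

test_that("collapsing counts an arbitrary multiset exactly and conserves clones", {
  withr::with_seed(42, {
    templates <- replicate(7, rand_seq(40))
    draws <- sample(templates, 50, replace = TRUE)
    cl <- clone_records(paste0("I", sample(1:9, 50, replace = TRUE)), draws)
    ht <- collapse_haplotypes(cl)
    truth <- table(draws)
    expect_equal(sum(ht$count), 50)
    expect_equal(ht$count, as.integer(truth[ht$sequence]))
    # deterministic ordering: count desc then sequence
    expect_true(all(diff(ht$count) <= 0))
    # three pairwise-distinct sequences give three singletons
    ht3 <- collapse_haplotypes(clone_records(paste0("I", 1:3),
                                             templates[1:3]))
    expect_equal(ht3$count, rep(1L, 3))
  })
  expect_error(collapse_haplotypes(clone_records(character(0), character(0))),
               class = "hc_input_error")
})

test_that("collapsing is idempotent on a haplotype table's expansion", {
  ht <- star_haplotypes(5, n = 10, L = 60)
  ex <- expand_haplotypes(ht, unit = "clone")
  back <- collapse_haplotypes(clone_records(ex$haplotype_id, ex$sequence))
  expect_equal(back$sequence, ht$sequence)
  expect_equal(back$count, ht$count)
})

test_that("MLST identity check flags discordant clones and builds consensus", {
  lens <- c(gatB = 400L, coxA = 420L, fbpA = 400L, ftsZ = 415L)
  loci <- withr::with_seed(8, {
    lapply(lens, function(L) {
      s <- rand_seq(L)
      clone_records(rep("JN6", 8), rep(s, 8))
    })
  })
  chk <- mlst_identity_check(loci)
  expect_true(all(chk$report$identical))
  expect_equal(nrow(chk$consensus), 1)
  expect_equal(chk$consensus$length, sum(lens))  # 1635 bp
  # one clone differing at a single bp flags that (individual, locus)
  loci$coxA$sequence[3] <- mutate_seq(loci$coxA$sequence[3], 5L)
  chk2 <- mlst_identity_check(loci)
  bad <- chk2$report[!chk2$report$identical, ]
  expect_equal(bad$locus, "coxA")
  expect_equal(bad$individual_id, "JN6")
  expect_equal(bad$n_haplotypes, 2)
  expect_equal(nrow(chk2$consensus), 0)
})
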