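test_that("expected errors per clone is rate x length x cycles", {
  expect_equal(expected_errors(error_model(rate = 0, cycles = 35, length = 600)), 0)
  expect_equal(expected_errors(error_model(rate = 1e-4, cycles = 35, length = 600)), 2.1)
  expect_equal(expected_errors(error_model(rate = 7e-4, cycles = 70, length = 600)), 29.4)
  expect_error(error_model(rate = -1), class = "hc_parameter_error")
  expect_error(error_model(rate = 1), class = "hc_parameter_error")
})

test_that("artifact probability matches the Poisson closed form", {
  m0 <- error_model(rate = 0, cycles = 35, length = 600)
  expect_equal(artifact_probability(1, m0, n_clones = 5), 0)
  m1 <- error_model(rate = 0.1 / 600 / 35, cycles = 35, length = 600) # lambda 0.1
  expect_equal(artifact_probability(1, m1), 1 - exp(-0.1), tolerance = 1e-10)
  expect_error(artifact_probability(0, m1), class = "hc_logic_error")
})

test_that("artifact probability agrees with a Monte-Carlo Poisson oracle", {
  m <- error_model(rate = 0.1 / 600 / 35, cycles = 35, length = 600) # lambda 0.1
  p_pkg <- artifact_probability(3, m, n_clones = 20)
  expect_lt(p_pkg, 0.01)
  draws <- withr::with_seed(99, rpois(1e6, 0.1))
  p_one_mc <- mean(draws >= 3)
  p_mc <- 1 - (1 - p_one_mc)^20
  se <- 20 * sqrt(p_one_mc * (1 - p_one_mc) / 1e6)  # delta-method scale
  expect_lt(abs(p_pkg - p_mc), 4 * se)
})

test_that("replicate verification marks haplotypes seen in two independent PCRs", {
  cl <- data.frame(
    clone_id = paste0("c", 1:5),
    individual_id = c("JN6", "JN6", "JN6", "JN8", "JN8"),
    site_code = "JN",
    pcr_replicate = c(1L, 2L, 1L, 1L, 1L),
    sequence = c("AAAA", "AAAA", "CCCC", "CCCC", "GGGG"),
    stringsAsFactors = FALSE)
  rc <- reconditioning_consistency(cl)
  expect_true(rc$verified[rc$sequence == "AAAA"])   # replicates 1 and 2 of JN6
  expect_false(rc$verified[rc$sequence == "CCCC"])  # replicate 1 only, per fly
  expect_false(rc$verified[rc$sequence == "GGGG"])
  # invariant under clone input order
  perm <- withr::with_seed(1, sample.int(nrow(cl)))
  rc2 <- reconditioning_consistency(cl[perm, ])
  expect_equal(rc2$verified[order(rc2$sequence)],
               rc$verified[order(rc$sequence)])
})

test_that("an error-plausible singleton is removed, a distant one is kept in complete only", {
  withr::with_seed(21, {
    A <- rand_seq(100)
    B <- mutate_seq(A, 1L)                       # d = 1 from A
    C <- mutate_seq(A, sample(10:100, 12))       # d = 12 from A
    cl <- clone_records(c("I1", "I1", "I1", "I1", "I1", "I2"),
                        c(A, A, A, A, B, C))
    # lambda = 2.1: single-step slips are plausible, 12-step ones are not
    m <- error_model(rate = 1e-4, cycles = 35, length = 100 * 6)
    res <- build_datasets(cl, m, alpha = 0.05)
    expect_equal(res$artifacts$sequence, B)
    expect_setequal(res$complete$sequence, c(A, C))
    expect_equal(res$conservative$sequence, A)
    dec <- res$decisions
    expect_equal(dec$rule[dec$count == 4], "multiplicity")
    expect_true("artifact" %in% dec$rule)
    expect_true(all(res$conservative$count >= 2))
  })
})

test_that("with a zero error rate no singleton is ever flagged", {
  withr::with_seed(33, {
    A <- rand_seq(80)
    singles <- vapply(1:4, function(i) mutate_seq(A, i), "")
    cl <- clone_records(rep(c("I1", "I2"), c(3, 4)),
                        c(A, A, A, singles))
    res <- build_datasets(cl, error_model(rate = 0, length = 80), alpha = 0.05)
    expect_equal(nrow(res$artifacts), 0)
    expect_equal(nrow(res$complete), 5)
  })
})

test_that("the artifact set is nested as alpha loosens", {
  study <- simulate_study(sim_params(rate_e = 1e-5), seed = 9)
  m <- error_model(rate = 1e-5, cycles = 70, length = 600)
  alphas <- c(0.001, 0.01, 0.05, 0.2, 0.5)
  arts <- lapply(alphas, function(a)
    build_datasets(study$clones, m, alpha = a)$artifacts$sequence)
  for (i in seq_along(alphas)[-1]) {
    expect_true(all(arts[[i]] %in% arts[[i - 1]]))
  }
})

test_that("conservative is a subset of complete and clones are conserved", {
  for (s in 1:3) {
    study <- simulate_study(seed = 100 + s)
    m <- error_model(rate = study$params$rate_e, cycles = study$params$cycles,
                     length = study$params$L)
    res <- build_datasets(study$clones, m)
    expect_true(all(res$conservative$sequence %in% res$complete$sequence))
    expect_true(all(res$conservative$count >= 2))
    expect_equal(sum(res$complete$count) + sum(res$artifacts$count),
                 nrow(study$clones))
    expect_length(intersect(res$complete$sequence, res$artifacts$sequence), 0)
  }
})
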