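test_that("strain simulation is deterministic with exact designed distances", {
  s1 <- simulate_strains(sim_params(), seed = 5)
  s2 <- simulate_strains(sim_params(), seed = 5)
  expect_identical(s1$sequence, s2$sequence)
  expect_equal(nrow(s1), 11 + 4 + 3 + 3)
  expect_equal(anyDuplicated(s1$sequence), 0L)
  D <- pairwise_distance_matrix(setNames(s1$sequence, s1$strain_id))
  cross <- D[s1$lineage == "1", s1$lineage == "2"]
  expect_true(all(cross >= 40))  # lineage split dominates every within offset
  within1a <- D[s1$subgroup == "1a", s1$subgroup == "1a"]
  expect_true(all(within1a <= 4))  # leaves sit 1-2 steps from their centroid
  # minimal two-strain design: exactly D_between apart
  tiny <- simulate_strains(sim_params(strains_per_subgroup = 1L,
                                      centroid_offset = 0L,
                                      centroid_weights = 10,
                                      n_group2_strains = 1L,
                                      group2_weights = 3),
                           seed = 2)
  expect_equal(nrow(tiny), 2)
  expect_equal(hamming(tiny$sequence[1], tiny$sequence[2]), 40L)
})

test_that("an over-committed substitution budget is rejected", {
  expect_error(sim_params(D_between = 580), class = "hc_parameter_error")
  expect_error(sim_params(rate_e = 1.5), class = "hc_parameter_error")
  expect_error(sim_params(recombinant_rate = -0.1),
               class = "hc_parameter_error")
})

test_that("with no error and no recombination every clone equals its template", {
  p <- sim_params(rate_e = 0, recombinant_rate = 0)
  st <- simulate_study(p, seed = 6)
  ev <- st$truth$events
  expect_true(all(!ev$recombinant))
  expect_true(all(ev$n_errors == 0))
  tmpl <- setNames(st$strains$sequence, st$strains$strain_id)
  expect_equal(st$clones$sequence, unname(tmpl[ev$template_id]))
})

test_that("the error-free clone fraction matches the compounded per-site model", {
  p <- sim_params(rate_e = 1e-6)  # per-site error 7e-5, P(clean) ~ 0.959
  st <- simulate_study(p, seed = 8)
  p_site <- 1 - (1 - p$rate_e)^p$cycles
  p_clean <- (1 - p_site)^p$L
  frac <- mean(st$truth$events$n_errors == 0)
  n <- nrow(st$truth$events)
  expect_lt(abs(frac - p_clean), 3 * sqrt(p_clean * (1 - p_clean) / n))
  # recorded error positions reconstruct each clone from its template
  ev <- st$truth$events
  bad <- ev[ev$n_errors > 0 & !ev$recombinant, ]
  tmpl <- setNames(st$strains$sequence, st$strains$strain_id)
  for (i in seq_len(min(5, nrow(bad)))) {
    pos <- as.integer(strsplit(bad$error_pos[i], ",")[[1]])
    clone <- st$clones$sequence[st$clones$clone_id == bad$clone_id[i]]
    expect_equal(hamming(clone, tmpl[[bad$template_id[i]]]), length(pos))
  }
})

test_that("recombinant clones splice their parents at the recorded breakpoint", {
  p <- sim_params(rate_e = 0, recombinant_rate = 0.5, superinfection_rate = 1,
                  theta = 0)
  st <- simulate_study(p, seed = 10)
  ev <- st$truth$events
  rec <- ev[ev$recombinant, ]
  expect_gt(nrow(rec), 10)
  tmpl <- setNames(st$strains$sequence, st$strains$strain_id)
  for (i in seq_len(min(8, nrow(rec)))) {
    clone <- st$clones$sequence[st$clones$clone_id == rec$clone_id[i]]
    bp <- rec$breakpoint[i]
    a <- tmpl[[rec$parent_a[i]]]
    b <- tmpl[[rec$parent_b[i]]]
    expect_equal(substr(clone, 1, bp), substr(a, 1, bp))
    expect_equal(substr(clone, bp + 1, p$L), substr(b, bp + 1, p$L))
  }
})

test_that("host metadata honours the scenario sizes and coupling limits", {
  meta <- simulate_host_metadata(sim_params(), seed = 3)
  expect_equal(nrow(meta), 47)
  expect_equal(length(unique(meta$site_code)), 10)
  expect_true(all(table(meta$site_code) >= 2 & table(meta$site_code) <= 8))
  expect_true(all(meta$infected))
  scr <- simulate_host_metadata(sim_params(), seed = 3, n_screened = 366)
  expect_equal(nrow(scr), 366)
  # haplotype determines haplogroup consistently
  expect_true(all(tapply(meta$mtdna_haplogroup, meta$mtdna_haplotype,
                         function(x) length(unique(x)) == 1)))
  # extreme coupling confines lineage 2 to the southern haplogroup
  strong <- do.call(rbind, lapply(1:30, function(s)
    simulate_host_metadata(sim_params(theta = 50), seed = s)))
  expect_true(all(strong$mtdna_haplogroup[strong$wgff_group2] == "South"))
})

test_that("at theta = 0 the lineage-2/South odds ratio is near 1", {
  tab <- matrix(0, 2, 2)
  for (s in 1:300) {
    meta <- simulate_host_metadata(sim_params(theta = 0), seed = 4000 + s)
    tab <- tab + table(factor(meta$wgff_group2, c(FALSE, TRUE)),
                       factor(meta$mtdna_haplogroup == "South",
                              c(FALSE, TRUE)))
  }
  log_or <- log(tab[1, 1] * tab[2, 2] / (tab[1, 2] * tab[2, 1]))
  expect_lt(abs(log_or), 0.2)
})

test_that("two lineages and three subgroups are recovered end to end", {
  comp2 <- 0
  sub3 <- 0
  for (s in 1:20) {
    st <- simulate_study(seed = 600 + s)
    f <- build_datasets(st$clones,
                        error_model(rate = st$params$rate_e,
                                    cycles = st$params$cycles,
                                    length = st$params$L))
    net <- build_networks(f$conservative)
    lab <- assign_groups(net)
    comp2 <- comp2 + (length(net$components) == 2)
    in1 <- lab$subgroup[lab$group == "Group1"]
    sub3 <- sub3 + (length(unique(in1[!is.na(in1)])) == 3)
  }
  expect_gte(comp2, 17)
  expect_gte(sub3, 17)
})
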