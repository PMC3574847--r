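#' Pipeline configuration
#'
#' Bundles inputs, model parameters, test settings and the master seed for
#' an end-to-end run. With `simulate = TRUE` (default when no FASTA is
#' given) the input clone library and host metadata are generated by
#' [simulate_study()] under `params`.
#'
#' Every stochastic stage derives its own seed from the master seed by a
#' fixed rule (`seed * 100 + stage index`; stages are numbered in run
#' order), so any single stage can be reproduced in isolation from the
#' logged per-stage seed.
#'
#' @param outdir output directory (created on run).
#' @param clones_fasta path to an aligned clone FASTA, or `NULL` to
#'   simulate.
#' @param host_meta_tsv path to a host-metadata TSV, or `NULL` to simulate.
#' @param screening_meta_tsv optional path to a screening-survey metadata
#'   TSV for the infection/mixed-region test; simulated (`n_screened`) when
#'   simulating inputs.
#' @param params [sim_params()] used when simulating.
#' @param scheme [label_scheme()] for parsing clone ids.
#' @param model [error_model()] for the artifact filter; `NULL` derives the
#'   length from the input and uses the model defaults.
#' @param alpha_artifact,alpha_recomb significance levels for the artifact
#'   filter and recombination screen.
#' @param recomb_n_perm,amova_n_perm permutation counts.
#' @param assoc_n_rand randomized datasets for the association tests.
#' @param confidence probability-of-parsimony confidence for the network
#'   connection limit.
#' @param subgroup_threshold steps above which edges are cut when labelling
#'   subgroups.
#' @param n_screened screening-survey size when simulating.
#' @param skip_recomb bypass the recombination screen.
#' @param seed master seed.
#' @param verbose emit per-stage progress messages.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(outdir,
                            clones_fasta = NULL,
                            host_meta_tsv = NULL,
                            screening_meta_tsv = NULL,
                            params = sim_params(),
                            scheme = label_scheme(),
                            model = NULL,
                            alpha_artifact = 0.05,
                            alpha_recomb = 0.05,
                            recomb_n_perm = 1000L,
                            amova_n_perm = 1000L,
                            assoc_n_rand = 100L,
                            confidence = 0.95,
                            subgroup_threshold = 5L,
                            n_screened = 366L,
                            skip_recomb = FALSE,
                            seed = 1L,
                            verbose = TRUE) {
  structure(list(
    outdir = outdir, clones_fasta = clones_fasta,
    host_meta_tsv = host_meta_tsv, screening_meta_tsv = screening_meta_tsv,
    simulate = is.null(clones_fasta), params = params, scheme = scheme,
    model = model, alpha_artifact = alpha_artifact,
    alpha_recomb = alpha_recomb, recomb_n_perm = as.integer(recomb_n_perm),
    amova_n_perm = as.integer(amova_n_perm),
    assoc_n_rand = as.integer(assoc_n_rand), confidence = confidence,
    subgroup_threshold = as.integer(subgroup_threshold),
    n_screened = as.integer(n_screened), skip_recomb = isTRUE(skip_recomb),
    seed = as.integer(seed), verbose = isTRUE(verbose)),
    class = "pipeline_config")
}

PIPELINE_STAGES <- c("input", "validate", "filter", "recomb", "network",
                     "diversity", "amova", "association", "outputs")

stage_seed <- function(config, stage) {
  config$seed * 100L + match(stage, PIPELINE_STAGES)
}

#' Validate pipeline inputs
#'
#' Checks alignment integrity, clone-label parsing and metadata coverage.
#' Problems are reported, never silently corrected.
#'
#' @param clones parsed clone records.
#' @param meta host metadata.
#' @return A data frame of checks (`check`, `ok`, `detail`) with attribute
#'   `ok` (all checks passed).
#' @export
validate_inputs <- function(clones, meta) {
  checks <- list()
  add <- function(check, ok, detail = "") {
    checks[[length(checks) + 1L]] <<- data.frame(
      check = check, ok = ok, detail = detail, stringsAsFactors = FALSE)
  }
  add("clone sequences equal length",
      length(unique(nchar(clones$sequence))) == 1L,
      paste(sort(unique(nchar(clones$sequence))), collapse = ","))
  missing <- setdiff(unique(clones$individual_id), meta$individual_id)
  add("every sequenced fly present in metadata", length(missing) == 0L,
      paste(missing, collapse = ","))
  dup <- unique(meta$individual_id[duplicated(meta$individual_id)])
  add("metadata individuals unique", length(dup) == 0L,
      paste(dup, collapse = ","))
  need <- c("individual_id", "mtdna_haplogroup", "mtdna_haplotype")
  miss_cols <- setdiff(need, names(meta))
  add("metadata columns present", length(miss_cols) == 0L,
      paste(miss_cols, collapse = ","))
  if (length(miss_cols) == 0L) {
    bad <- !meta$mtdna_haplogroup %in% c("North", "South")
    add("haplogroup labels are North/South", !any(bad),
        paste(unique(meta$mtdna_haplogroup[bad]), collapse = ","))
  }
  out <- do.call(rbind, checks)
  attr(out, "ok") <- all(out$ok)
  out
}

#' Run the full clone-library analysis pipeline
#'
#' Stage order: input (read or simulate), validation, artifact filter
#' (complete/conservative datasets), recombination screen, parsimony
#' networks with group/subgroup labels, diversity summaries (by site, by
#' network group, by host haplogroup), one-level AMOVA of the symbiont
#' sequences against host mtDNA haplogroups (complete and conservative),
#' and the association tests. All tables are written to
#' `config$outdir` as TSV/FASTA together with a YAML config snapshot and a
#' manifest of md5 checksums; identical seeds give identical checksums.
#'
#' @param config a [pipeline_config()].
#' @param dry_run list the stages without computing or writing anything.
#' @return The run manifest (data frame `file`, `md5`) with the full
#'   results list attached as attribute `results`; for `dry_run`, the
#'   stage names.
#' @export
run_pipeline <- function(config, dry_run = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (dry_run) return(PIPELINE_STAGES)
  say <- function(...) if (config$verbose) message(sprintf(...))
  stage <- "input"
  res <- list()
  tryCatch({
    # -- input ---------------------------------------------------------
    if (config$simulate) {
      study <- simulate_study(config$params, stage_seed(config, "input"))
      clones <- study$clones
      meta <- study$meta
      screening <- simulate_host_metadata(config$params,
                                          stage_seed(config, "input") + 50L,
                                          n_screened = config$n_screened)
      res$truth <- study$truth
      say("input: simulated %d clones from %d flies", nrow(clones), nrow(meta))
    } else {
      aln <- read_alignment(config$clones_fasta)
      clones <- parse_clone_labels(aln, config$scheme)
      meta <- read_host_meta(config$host_meta_tsv)
      screening <- if (!is.null(config$screening_meta_tsv))
        read_host_meta(config$screening_meta_tsv) else NULL
      say("input: read %d clones from %d flies", nrow(clones),
          length(unique(clones$individual_id)))
    }
    # -- validate ------------------------------------------------------
    stage <- "validate"
    report <- validate_inputs(clones, meta)
    res$validation <- report
    if (!attr(report, "ok"))
      hc_input_error(paste("input validation failed:",
                           paste(report$check[!report$ok], collapse = "; ")))
    # -- artifact filter ----------------------------------------------
    stage <- "filter"
    model <- if (is.null(config$model))
      error_model(length = nchar(clones$sequence[1])) else config$model
    filt <- build_datasets(clones, model, alpha = config$alpha_artifact)
    res$filter <- filt
    say("filter: %d clones -> %d complete / %d conservative / %d artifact haplotypes",
        nrow(clones), nrow(filt$complete), nrow(filt$conservative),
        nrow(filt$artifacts))
    complete <- filt$complete
    conservative <- filt$conservative
    # -- recombination screen -----------------------------------------
    stage <- "recomb"
    if (!config$skip_recomb) {
      gc <- geneconv_test(complete, n_perm = config$recomb_n_perm,
                          seed = stage_seed(config, "recomb"),
                          alpha = config$alpha_recomb)
      res$recomb <- gc
      complete <- remove_recombinants(complete, gc)
      conservative <- remove_recombinants(conservative, gc)
      say("recomb: flagged %d haplotype(s)", length(gc$flagged))
    } else say("recomb: skipped")
    res$complete <- complete
    res$conservative <- conservative
    # -- networks ------------------------------------------------------
    stage <- "network"
    datasets <- list(complete = complete, conservative = conservative)
    res$network <- lapply(datasets, function(ht) {
      net <- build_networks(ht, confidence = config$confidence)
      labels <- assign_groups(net, config$subgroup_threshold)
      list(network = net, labels = labels)
    })
    say("network: %d component(s) [complete], %d [conservative], limit %d steps",
        length(res$network$complete$network$components),
        length(res$network$conservative$network$components),
        res$network$complete$network$limit)
    # -- diversity -----------------------------------------------------
    stage <- "diversity"
    hap_groups <- setNames(meta$mtdna_haplogroup, meta$individual_id)
    site_groups <- setNames(meta$site_code, meta$individual_id)
    res$diversity <- lapply(names(datasets), function(nm) {
      ht <- datasets[[nm]]
      labels <- res$network[[nm]]$labels
      carriers <- expand_haplotypes(ht, unit = "carrier")
      carriers$group <- labels$group[match(carriers$haplotype_id,
                                           labels$haplotype_id)]
      carriers$subgroup <- labels$subgroup[match(carriers$haplotype_id,
                                                 labels$haplotype_id)]
      netgrp <- summarize_network_groups(ht, labels)
      list(by_site = summarize_groups(ht, site_groups),
           by_haplogroup = summarize_groups(ht, hap_groups),
           by_network_group = netgrp)
    })
    names(res$diversity) <- names(datasets)
    # -- AMOVA ---------------------------------------------------------
    stage <- "amova"
    res$amova <- lapply(names(datasets), function(nm) {
      ht <- datasets[[nm]]
      ex <- expand_haplotypes(ht, unit = "carrier")
      groups <- hap_groups[ex$individual_id]
      D <- pairwise_distance_matrix(setNames(ex$sequence, NULL))
      tryCatch(
        amova(D, groups, n_perm = config$amova_n_perm,
              seed = stage_seed(config, "amova")),
        haploclone_error = function(e) e)
    })
    names(res$amova) <- names(datasets)
    # -- association ---------------------------------------------------
    stage <- "association"
    labels <- res$network$complete$labels
    g2_haps <- labels$haplotype_id[labels$group == "Group2"]
    carrier_g2 <- unique(unlist(
      res$complete$carriers[res$complete$haplotype_id %in% g2_haps]))
    meta$wgff_group2_observed <- meta$individual_id %in% carrier_g2
    assoc_meta <- meta
    assoc_meta$wgff_group2 <- assoc_meta$wgff_group2_observed
    res$assoc_group2_south <- tryCatch(
      test_group2_south(assoc_meta, n_rand = config$assoc_n_rand,
                        seed = stage_seed(config, "association")),
      haploclone_error = function(e) e)
    res$assoc_mixed <- if (!is.null(screening)) {
      test_infection_mixedregion(screening, n_rand = config$assoc_n_rand,
                                 seed = stage_seed(config, "association") + 1L)
    } else NULL
    res$infection_table <- if (!is.null(screening))
      infection_test_table(screening) else NULL
    # -- outputs -------------------------------------------------------
    stage <- "outputs"
    manifest <- write_pipeline_outputs(res, clones, meta, screening, config)
    say("outputs: %d files written to %s", nrow(manifest), config$outdir)
    attr(manifest, "results") <- res
    invisible(manifest)
  }, haploclone_error = function(e) {
    hc_pipeline_error(sprintf("pipeline failed at stage '%s': %s", stage,
                              conditionMessage(e)))
  })
}

# Table-2-style rows: diversity per network group, subgroup and overall,
# using per-carrier haplotype occurrences as the sequence unit.
summarize_network_groups <- function(ht, labels) {
  ex <- expand_haplotypes(ht, unit = "carrier")
  lab <- labels[match(ex$haplotype_id, labels$haplotype_id), ]
  rows <- list()
  one <- function(label, sel) {
    sub <- ex[sel, , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    tab <- table(sub$haplotype_id)
    haps <- names(tab)
    wts <- as.integer(tab)
    idx <- match(haps, ht$haplotype_id)
    if (sum(wts) < 2) {
      return(data.frame(group = label, n_sequences = sum(wts),
                        n_haplotypes = length(haps), Hd = NA_real_,
                        pi = NA_real_, S = NA_integer_, k = NA_real_,
                        stringsAsFactors = FALSE))
    }
    aln <- alignment(haps, ht$sequence[idx])
    st <- .pairwise_stats(aln, wts, "complete")
    S <- if (length(haps) < 2L) 0L else segregating_sites(aln)
    data.frame(group = label, n_sequences = sum(wts),
               n_haplotypes = length(haps), Hd = haplotype_diversity(wts),
               pi = st$k / st$L_eff, S = S, k = st$k,
               stringsAsFactors = FALSE)
  }
  rows[["all"]] <- one("Entire dataset", rep(TRUE, nrow(ex)))
  for (g in sort(unique(lab$group))) {
    rows[[g]] <- one(g, lab$group == g)
    subs <- sort(unique(lab$subgroup[lab$group == g & !is.na(lab$subgroup)]))
    for (s in subs)
      rows[[paste0("sub", s)]] <- one(paste0("Subgroup ", s),
                                      !is.na(lab$subgroup) & lab$subgroup == s)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

write_pipeline_outputs <- function(res, clones, meta, screening, config) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(config$outdir, ...)
  files <- character(0)
  put <- function(path) files <<- c(files, path)

  put(write_clone_fasta(clones, fp("clones.fasta")))
  put(write_host_meta(meta, fp("hosts.tsv")))
  if (!is.null(screening)) put(write_host_meta(screening, fp("screening.tsv")))
  put(write_haplotype_fasta(res$filter$complete, fp("complete.fasta")))
  put(write_haplotype_fasta(res$filter$conservative, fp("conservative.fasta")))
  if (nrow(res$filter$artifacts) > 0L)
    put(write_haplotype_fasta(res$filter$artifacts, fp("artifacts.fasta")))
  put(write_filter_log(res$filter, fp("filter_decisions.tsv")))
  if (!is.null(res$recomb))
    put(write_geneconv_report(res$recomb, fp("recombination.tsv")))
  for (nm in names(res$network)) {
    put(write_network(res$network[[nm]]$network, fp(paste0("network_", nm, ".tsv"))))
    ht <- res[[nm]]
    merged <- ht
    merged$group <- res$network[[nm]]$labels$group
    merged$subgroup <- res$network[[nm]]$labels$subgroup
    class(merged) <- class(ht)
    put(write_haplotypes(merged, fp(paste0("haplotypes_", nm, ".tsv"))))
    put(write_diversity(res$diversity[[nm]]$by_site,
                        fp(paste0("diversity_by_site_", nm, ".tsv"))))
    put(write_diversity(res$diversity[[nm]]$by_network_group,
                        fp(paste0("diversity_by_group_", nm, ".tsv"))))
    put(write_diversity(res$diversity[[nm]]$by_haplogroup,
                        fp(paste0("diversity_by_haplogroup_", nm, ".tsv"))))
  }
  amova_ok <- Filter(function(x) inherits(x, "amova_result"), res$amova)
  if (length(amova_ok) > 0L) put(write_amova(amova_ok, fp("amova.tsv")))
  if (inherits(res$assoc_group2_south, "randomization_test"))
    put(write_randomization(res$assoc_group2_south, fp("assoc_group2_south.tsv")))
  if (inherits(res$assoc_mixed, "randomization_test"))
    put(write_randomization(res$assoc_mixed, fp("assoc_infection_mixed.tsv")))
  if (!is.null(res$infection_table)) {
    write.table(res$infection_table, fp("infection_binomial.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    put(fp("infection_binomial.tsv"))
  }
  # provenance snapshot
  # run-location fields are excluded so that identical seeds yield
  # identical snapshot checksums wherever the run is placed
  snap <- unclass(config)[setdiff(names(config),
                                  c("params", "scheme", "model", "outdir"))]
  snap$params <- unclass(config$params)
  snap$params$site_sizes <- as.list(config$params$site_sizes)
  snap$scheme <- unclass(config$scheme)
  if (!is.null(config$model)) snap$model <- unclass(config$model)
  yaml::write_yaml(snap, fp("config.yaml"))
  put(fp("config.yaml"))

  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[lex_order(manifest$file), ]
  rownames(manifest) <- NULL
  write.table(manifest, fp("manifest.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  manifest
}
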