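#' Parameters for the synthetic clone-library generator
#'
#' The generator emulates the sampling structure of a two-lineage
#' endosymbiont survey: 10 collection sites with 2–8 sequenced flies each
#' (47 in total), 2–20 sequenced clones per fly, two divergent symbiont
#' lineages (lineage 1 structured into three subgroups, lineage 2 rare and
#' carried only by superinfected flies), polymerase error on each clone,
#' occasional within-host recombinant clones in superinfected flies, and
#' host mtDNA haplotypes structured into northern/southern haplogroups with
#' a mixed contact region.
#'
#' Strain sequences are built from a random ancestor by substitutions at
#' globally distinct positions, so all designed pairwise distances are
#' exact: the two lineage roots differ at `D_between` sites, lineage-1
#' subgroup centroids differ from the lineage-1 root at `centroid_offset`
#' sites each (pairwise `2 * centroid_offset`), and every leaf strain
#' differs from its centroid at `leaf_range[1]`–`leaf_range[2]` sites.
#'
#' @param L amplicon length in bp.
#' @param site_sizes named integer vector: flies sequenced per site.
#' @param clones_range inclusive range of clones per fly.
#' @param n_replicates number of PCR replicates clones are spread over.
#' @param D_between substitutions separating the two lineage roots.
#' @param centroid_offset substitutions from the lineage-1 root to each
#'   subgroup centroid.
#' @param leaf_range substitutions from a centroid to each leaf strain.
#' @param strains_per_subgroup strains per lineage-1 subgroup (centroid
#'   included).
#' @param n_group2_strains strains in lineage 2 (root included).
#' @param centroid_weights,leaf_weight,group2_weights sampling weights used
#'   when assigning strains to flies (centroids are the common strains).
#' @param rate_e polymerase error rate per bp per cycle. Clones acquire
#'   per-site errors with probability `1 - (1 - rate_e)^cycles`; the
#'   default is chosen so that roughly 1% of clones carry an error, the
#'   regime consistent with the within-fly clone concordance the analysis
#'   assumes (see the methods vignette).
#' @param cycles total effective PCR cycles (two consecutive 35-cycle
#'   amplifications).
#' @param recombinant_rate per-clone probability, in superinfected flies,
#'   of a template-switch chimera between the two resident strains.
#' @param superinfection_rate baseline probability (at `theta = 0`) that a
#'   fly carries lineage 2 in addition to lineage 1.
#' @param theta log-odds coupling of lineage-2 presence to the southern
#'   host haplogroup, centred so that `exp(theta)` is the Group2/South odds
#'   ratio and `theta -> Inf` confines lineage 2 to southern flies.
#' @param p_south probability a host mtDNA haplotype pool entry (and hence
#'   roughly each fly) belongs to the southern haplogroup.
#' @param n_mtdna_haplotypes size of the host mtDNA haplotype pool.
#' @param p_mixed probability a pool haplotype is a contact-region
#'   ("mixed") haplotype.
#' @param p_infected baseline infection prevalence in the screening
#'   scenario.
#' @param infection_coupling log-odds coupling of infection status to
#'   mixed-region haplotypes in the screening scenario.
#' @return A validated `sim_params` list.
#' @export
sim_params <- function(L = 600L,
                       site_sizes = c(BK = 2L, BN = 5L, BU = 3L, BV = 5L,
                                      JN = 8L, KK = 3L, MS = 6L, MF = 5L,
                                      OS = 4L, GF = 6L),
                       clones_range = c(2L, 20L),
                       n_replicates = 2L,
                       D_between = 40L,
                       centroid_offset = 3L,
                       leaf_range = c(1L, 2L),
                       strains_per_subgroup = c(11L, 4L, 3L),
                       n_group2_strains = 3L,
                       centroid_weights = c(10, 6, 4),
                       leaf_weight = 1,
                       group2_weights = c(3, 1, 1),
                       rate_e = 2.5e-7,
                       cycles = 70L,
                       recombinant_rate = 0.02,
                       superinfection_rate = 0.15,
                       theta = 0,
                       p_south = 0.5,
                       n_mtdna_haplotypes = 26L,
                       p_mixed = 0.4,
                       p_infected = 0.3,
                       infection_coupling = 0) {
  p <- list(L = as.integer(L), site_sizes = site_sizes,
            clones_range = as.integer(clones_range),
            n_replicates = as.integer(n_replicates),
            D_between = as.integer(D_between),
            centroid_offset = as.integer(centroid_offset),
            leaf_range = as.integer(leaf_range),
            strains_per_subgroup = as.integer(strains_per_subgroup),
            n_group2_strains = as.integer(n_group2_strains),
            centroid_weights = centroid_weights, leaf_weight = leaf_weight,
            group2_weights = group2_weights,
            rate_e = rate_e, cycles = as.integer(cycles),
            recombinant_rate = recombinant_rate,
            superinfection_rate = superinfection_rate, theta = theta,
            p_south = p_south,
            n_mtdna_haplotypes = as.integer(n_mtdna_haplotypes),
            p_mixed = p_mixed, p_infected = p_infected,
            infection_coupling = infection_coupling)
  probs <- c(p$recombinant_rate, p$superinfection_rate, p$p_south, p$p_mixed,
             p$p_infected)
  if (any(probs < 0 | probs > 1))
    hc_parameter_error("all probabilities must be in [0, 1]")
  if (p$rate_e < 0 || p$rate_e >= 1)
    hc_parameter_error("rate_e must satisfy 0 <= rate_e < 1")
  if (any(p$site_sizes < 1L)) hc_parameter_error("site sizes must be >= 1")
  if (p$clones_range[1] < 1L || p$clones_range[1] > p$clones_range[2])
    hc_parameter_error("invalid clones_range")
  if (length(p$strains_per_subgroup) != length(p$centroid_weights))
    hc_parameter_error("strains_per_subgroup and centroid_weights must align")
  # substitution budget: every designed substitution uses a distinct site
  budget <- p$D_between +
    length(p$strains_per_subgroup) * p$centroid_offset +
    sum(pmax(0L, p$strains_per_subgroup - 1L)) * p$leaf_range[2] +
    max(0L, p$n_group2_strains - 1L) * p$leaf_range[2]
  if (budget > p$L)
    hc_parameter_error(sprintf(
      "designed divergence (%d substitutions) exceeds amplicon length %d",
      budget, p$L))
  structure(p, class = "sim_params")
}

.mutate_at <- function(seq_chars, positions) {
  bases <- c("A", "C", "G", "T")
  for (pos in positions) {
    seq_chars[pos] <- sample(setdiff(bases, seq_chars[pos]), 1L)
  }
  seq_chars
}

#' Simulate true strain sequences
#'
#' Builds the two-lineage strain set described in [sim_params()]: a random
#' ancestral sequence, a second lineage root `D_between` substitutions
#' away, three lineage-1 subgroup centroids, and leaf strains around every
#' centroid. All substitutions fall at globally distinct positions, so the
#' designed distances hold exactly and all strains are pairwise distinct.
#'
#' @param params a [sim_params()] object.
#' @param seed integer seed.
#' @return A `strain_set` data frame: `strain_id`, `lineage`, `subgroup`,
#'   `weight`, `sequence`. The attribute `positions` records every
#'   substitution position used per strain.
#' @export
simulate_strains <- function(params = sim_params(), seed = 1L) {
  stopifnot(inherits(params, "sim_params"))
  withr::with_seed(seed, {
    L <- params$L
    bases <- c("A", "C", "G", "T")
    root <- sample(bases, L, replace = TRUE)
    pool <- sample.int(L)
    ptr <- 0L
    take <- function(n) {
      out <- pool[ptr + seq_len(n)]
      ptr <<- ptr + n
      out
    }
    rows <- list()
    pos_log <- list()
    add <- function(id, lineage, subgroup, weight, chars, positions) {
      rows[[length(rows) + 1L]] <<- data.frame(
        strain_id = id, lineage = lineage, subgroup = subgroup,
        weight = weight, sequence = paste(chars, collapse = ""),
        stringsAsFactors = FALSE)
      pos_log[[id]] <<- sort(positions)
    }
    n_sub <- length(params$strains_per_subgroup)
    sub_names <- paste0("1", letters[seq_len(n_sub)])
    centroids <- list()
    for (s in seq_len(n_sub)) {
      pos <- take(params$centroid_offset)
      centroids[[s]] <- .mutate_at(root, pos)
      add(sprintf("G%s.01", sub_names[s]), "1", sub_names[s],
          params$centroid_weights[s], centroids[[s]], pos)
      for (leaf in seq_len(params$strains_per_subgroup[s] - 1L)) {
        nl <- sample(seq(params$leaf_range[1], params$leaf_range[2]), 1L)
        lp <- take(nl)
        add(sprintf("G%s.%02d", sub_names[s], leaf + 1L), "1", sub_names[s],
            params$leaf_weight, .mutate_at(centroids[[s]], lp), c(pos, lp))
      }
    }
    pos2 <- take(params$D_between)
    root2 <- .mutate_at(root, pos2)
    add("G2.01", "2", "2", params$group2_weights[1], root2, pos2)
    for (leaf in seq_len(params$n_group2_strains - 1L)) {
      nl <- sample(seq(params$leaf_range[1], params$leaf_range[2]), 1L)
      lp <- take(nl)
      w <- params$group2_weights[min(leaf + 1L, length(params$group2_weights))]
      add(sprintf("G2.%02d", leaf + 1L), "2", "2", w,
          .mutate_at(root2, lp), c(pos2, lp))
    }
    strains <- do.call(rbind, rows)
    rownames(strains) <- NULL
    attr(strains, "positions") <- pos_log
    attr(strains, "params") <- params
    class(strains) <- c("strain_set", "data.frame")
    strains
  })
}

.haplotype_pool <- function(params) {
  n <- params$n_mtdna_haplotypes
  n_south <- round(n * params$p_south)
  data.frame(
    mtdna_haplotype = as.character(seq_len(n)),
    mtdna_haplogroup = rep(c("North", "South"), c(n - n_south, n_south)),
    mixed_region = as.logical(rbinom(n, 1L, params$p_mixed)),
    stringsAsFactors = FALSE)
}

#' Simulate host metadata
#'
#' Two scenarios share one host mtDNA haplotype pool (each pool haplotype
#' has a fixed haplogroup and contact-region flag):
#'
#' * the clone panel (default): one row per sequenced fly, site structure
#'   from `params$site_sizes`, all flies infected, lineage-2 presence drawn
#'   with the centred log-odds coupling `theta` to the southern haplogroup;
#' * the screening survey (`n_screened` set, e.g. 366): one row per
#'   screened fly with infection status coupled to mixed-region haplotypes
#'   by `infection_coupling`.
#'
#' @param params a [sim_params()] object.
#' @param seed integer seed.
#' @param n_screened if not `NULL`, emit the screening scenario with this
#'   many individuals.
#' @return A `host_meta` data frame; the `truth` attribute records the
#'   haplotype pool and coupling parameters.
#' @export
simulate_host_metadata <- function(params = sim_params(), seed = 1L,
                                   n_screened = NULL) {
  stopifnot(inherits(params, "sim_params"))
  withr::with_seed(seed, {
    pool <- .haplotype_pool(params)
    draw_hap <- function(south) {
      sub <- pool[pool$mtdna_haplogroup == (if (south) "South" else "North"), ]
      sub[sample.int(nrow(sub), 1L), ]
    }
    if (!is.null(n_screened)) {
      south <- as.logical(rbinom(n_screened, 1L, params$p_south))
      hp <- do.call(rbind, lapply(south, draw_hap))
      p_inf <- plogis(qlogis(params$p_infected) +
                        params$infection_coupling * (hp$mixed_region - 0.5))
      meta <- data.frame(
        individual_id = sprintf("F%04d", seq_len(n_screened)),
        site_code = NA_character_,
        mtdna_haplotype = hp$mtdna_haplotype,
        mtdna_haplogroup = hp$mtdna_haplogroup,
        mixed_region = hp$mixed_region,
        infected = as.logical(rbinom(n_screened, 1L, p_inf)),
        stringsAsFactors = FALSE)
    } else {
      sites <- rep(names(params$site_sizes), params$site_sizes)
      ids <- unlist(lapply(names(params$site_sizes), function(s)
        paste0(s, seq_len(params$site_sizes[[s]]))))
      n <- length(ids)
      coords <- data.frame(site_code = names(params$site_sizes),
                           latitude = round(runif(length(params$site_sizes),
                                                  -0.5, 3.5), 2),
                           longitude = round(runif(length(params$site_sizes),
                                                   30.0, 34.5), 2))
      south <- as.logical(rbinom(n, 1L, params$p_south))
      hp <- do.call(rbind, lapply(south, draw_hap))
      p_g2 <- plogis(qlogis(params$superinfection_rate) +
                       params$theta * ((hp$mtdna_haplogroup == "South") - 0.5))
      meta <- data.frame(
        individual_id = ids, site_code = sites,
        latitude = coords$latitude[match(sites, coords$site_code)],
        longitude = coords$longitude[match(sites, coords$site_code)],
        mtdna_haplotype = hp$mtdna_haplotype,
        mtdna_haplogroup = hp$mtdna_haplogroup,
        mixed_region = hp$mixed_region,
        infected = TRUE,
        wgff_group1 = TRUE,
        wgff_group2 = as.logical(rbinom(n, 1L, p_g2)),
        stringsAsFactors = FALSE)
    }
    rownames(meta) <- NULL
    attr(meta, "truth") <- list(pool = pool, theta = params$theta,
                                infection_coupling = params$infection_coupling)
    class(meta) <- c("host_meta", "data.frame")
    meta
  })
}

#' Simulate a clone library with ground truth
#'
#' Every fly receives one lineage-1 strain (sampled by strain weight) and,
#' if superinfected, one lineage-2 strain; each of its 2–20 clones picks a
#' template uniformly among the resident strains, may be replaced by a
#' spliced recombinant of the two templates (superinfected flies only,
#' uniform breakpoint), and then acquires independent per-site polymerase
#' errors with probability `1 - (1 - rate_e)^cycles` per site. Clones are
#' spread round-robin over the PCR replicates.
#'
#' @param strains a [simulate_strains()] result.
#' @param meta a clone-panel [simulate_host_metadata()] result.
#' @param params a [sim_params()] object.
#' @param seed integer seed.
#' @return A `clone_library` list: `clones` (clone-record data frame) and
#'   `truth` with `events` (per clone: template, parents and breakpoint for
#'   recombinants, error positions) and `strain_counts` (realized
#'   non-recombinant clone count per strain, with lineage/subgroup labels).
#' @export
simulate_clone_library <- function(strains, meta, params = sim_params(),
                                   seed = 1L) {
  stopifnot(inherits(strains, "strain_set"), inherits(meta, "host_meta"))
  withr::with_seed(seed, {
    L <- params$L
    p_site <- 1 - (1 - params$rate_e)^params$cycles
    bases <- c("A", "C", "G", "T")
    chars <- strsplit(setNames(strains$sequence, strains$strain_id), "")
    g1 <- strains[strains$lineage == "1", ]
    g2 <- strains[strains$lineage == "2", ]
    clone_rows <- list()
    event_rows <- list()
    for (f in seq_len(nrow(meta))) {
      fly <- meta$individual_id[f]
      site <- meta$site_code[f]
      resident <- g1$strain_id[sample.int(nrow(g1), 1L, prob = g1$weight)]
      if (isTRUE(meta$wgff_group2[f]))
        resident <- c(resident,
                      g2$strain_id[sample.int(nrow(g2), 1L, prob = g2$weight)])
      k <- sample(seq(params$clones_range[1], params$clones_range[2]), 1L)
      for (j in seq_len(k)) {
        template <- resident[sample.int(length(resident), 1L)]
        parent_a <- NA_character_; parent_b <- NA_character_
        breakpoint <- NA_integer_
        recombinant <- length(resident) == 2L &&
          runif(1) < params$recombinant_rate
        if (recombinant) {
          pr <- sample(resident)  # random parent order
          parent_a <- pr[1]; parent_b <- pr[2]
          breakpoint <- sample.int(L - 1L, 1L)
          sq <- c(chars[[parent_a]][seq_len(breakpoint)],
                  chars[[parent_b]][(breakpoint + 1L):L])
          template <- NA_character_
        } else {
          sq <- chars[[template]]
        }
        n_err <- rbinom(1L, L, p_site)
        err_pos <- integer(0)
        if (n_err > 0L) {
          err_pos <- sort(sample.int(L, n_err))
          sq <- .mutate_at(sq, err_pos)
        }
        rep_id <- ((j - 1L) %% params$n_replicates) + 1L
        cid <- sprintf("%s|%s|r%d|c%02d", site, fly, rep_id, j)
        clone_rows[[length(clone_rows) + 1L]] <- data.frame(
          clone_id = cid, site_code = site, individual_id = fly,
          pcr_replicate = rep_id, clone = sprintf("c%02d", j),
          sequence = paste(sq, collapse = ""), stringsAsFactors = FALSE)
        event_rows[[length(event_rows) + 1L]] <- data.frame(
          clone_id = cid, individual_id = fly, template_id = template,
          recombinant = recombinant, parent_a = parent_a,
          parent_b = parent_b, breakpoint = breakpoint, n_errors = n_err,
          error_pos = paste(err_pos, collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
    clones <- do.call(rbind, clone_rows)
    events <- do.call(rbind, event_rows)
    counts <- table(factor(events$template_id[!events$recombinant],
                           levels = strains$strain_id))
    strain_counts <- data.frame(
      strain_id = strains$strain_id, lineage = strains$lineage,
      subgroup = strains$subgroup, n_clones = as.integer(counts),
      stringsAsFactors = FALSE)
    structure(list(clones = clones,
                   truth = list(events = events,
                                strain_counts = strain_counts)),
              class = "clone_library")
  })
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper: strains (seed), clone-panel host metadata
#' (seed + 1) and clone library (seed + 2).
#'
#' @param params a [sim_params()] object.
#' @param seed integer base seed.
#' @return A `synthetic_study` list: `strains`, `meta`, `clones`, `truth`,
#'   `params`, `seed`.
#' @export
simulate_study <- function(params = sim_params(), seed = 1L) {
  strains <- simulate_strains(params, seed)
  meta <- simulate_host_metadata(params, seed + 1L)
  lib <- simulate_clone_library(strains, meta, params, seed + 2L)
  structure(list(strains = strains, meta = meta, clones = lib$clones,
                 truth = lib$truth, params = params, seed = seed),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d strains, %d flies, %d clones (seed %d)\n",
              nrow(x$strains), nrow(x$meta), nrow(x$clones), x$seed))
  invisible(x)
}

#' Write clone records as FASTA
#' @param clones clone-record data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clone_fasta <- function(clones, path) {
  write_alignment(alignment(clones$clone_id, clones$sequence), path)
}

#' Write host metadata as TSV
#' @param meta a `host_meta` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_host_meta <- function(meta, path) {
  write.table(as.data.frame(meta), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read host metadata from TSV
#' @param path input path.
#' @return A `host_meta` data frame.
#' @export
read_host_meta <- function(path) {
  if (!file.exists(path)) hc_input_error(sprintf("file not found: %s", path))
  meta <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                     colClasses = c(mtdna_haplotype = "character"))
  class(meta) <- c("host_meta", "data.frame")
  meta
}

#' Write ground truth as JSON
#' @param truth the `truth` element of a `clone_library`/`synthetic_study`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
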