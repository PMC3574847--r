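#' Polymerase error model for cloned amplicons
#'
#' Describes error accumulation during PCR amplification of a cloned
#' amplicon: a per-base-pair per-cycle substitution rate, the total number
#' of effective cycles (summed over consecutive PCRs — errors can arise in
#' either round), and the amplicon length. The model mean
#' \eqn{\lambda = rate \times L \times cycles} is the expected number of
#' polymerase-induced substitutions carried by one sequenced clone.
#'
#' @param rate errors per base pair per cycle (dimensionless, `0 <= rate < 1`).
#' @param cycles total effective PCR cycles (default 70 = two consecutive
#'   35-cycle amplifications).
#' @param length amplicon length in bp.
#' @return An `error_model` object.
#' @examples
#' expected_errors(error_model(rate = 1e-4, cycles = 35, length = 600)) # 2.1
#' @export
error_model <- function(rate = 4e-4, cycles = 70L, length = 600L) {
  if (!is.numeric(rate) || rate < 0 || rate >= 1)
    hc_parameter_error("rate must satisfy 0 <= rate < 1")
  if (cycles < 1L) hc_parameter_error("cycles must be >= 1")
  if (length < 1L) hc_parameter_error("length must be >= 1")
  structure(list(rate = rate, cycles = as.integer(cycles),
                 length = as.integer(length)), class = "error_model")
}

#' @export
print.error_model <- function(x, ...) {
  cat(sprintf("<error_model> rate %.3g /bp/cycle, %d cycles, %d bp (lambda = %.4g errors/clone)\n",
              x$rate, x$cycles, x$length, expected_errors(x)))
  invisible(x)
}

#' Expected polymerase errors per clone
#'
#' @param model an [error_model()].
#' @return \eqn{\lambda = rate \times length \times cycles} (errors per clone).
#' @export
expected_errors <- function(model) {
  stopifnot(inherits(model, "error_model"))
  model$rate * model$length * model$cycles
}

#' Probability that PCR error explains a candidate haplotype
#'
#' A candidate singleton haplotype at Hamming distance `d` (gap/N columns
#' excluded) from its nearest retained neighbour is explainable as a PCR
#' artifact if polymerase error can plausibly generate `d` or more
#' substitutions in at least one of the clones sequenced from the same
#' template pool. Per-clone error counts are modelled as Poisson with mean
#' [expected_errors()]: the per-clone tail is
#' \eqn{p_1 = 1 - \sum_{k<d} e^{-\lambda}\lambda^k/k!} and the pool-level
#' probability is \eqn{1 - (1 - p_1)^{n}}.
#'
#' @param d Hamming distance(s) to the nearest retained haplotype (>= 1).
#' @param model an [error_model()].
#' @param n_clones number of clones in the pool the candidate arose from.
#' @return Probability in `[0, 1]` (vectorised over `d`).
#' @export
artifact_probability <- function(d, model, n_clones = 1L) {
  stopifnot(inherits(model, "error_model"))
  if (any(d < 1L))
    hc_logic_error("d = 0: candidate identical to a retained haplotype (should have been collapsed)")
  if (n_clones < 1L) hc_parameter_error("n_clones must be >= 1")
  lambda <- expected_errors(model)
  p_one <- ppois(d - 1L, lambda, lower.tail = FALSE)
  1 - (1 - p_one)^n_clones
}

#' Replicate consistency of clone haplotypes
#'
#' Re-amplifying the same template in independent PCRs verifies strain
#' haplotypes: a haplotype observed in two or more PCR replicates of the
#' same individual cannot be a single-reaction artifact and is exempt from
#' artifact removal.
#'
#' @param clones a clone-record data frame with a `pcr_replicate` column.
#' @return A data frame keyed by `sequence` with the per-individual
#'   replicate sets (list-column `replicates`, aligned with list-column
#'   `individuals`) and a logical `verified` flag.
#' @export
reconditioning_consistency <- function(clones) {
  if (!"pcr_replicate" %in% names(clones))
    hc_input_error("clone records lack a pcr_replicate column")
  idx <- split(seq_len(nrow(clones)), clones$sequence)
  res <- lapply(idx, function(i) {
    reps <- split(clones$pcr_replicate[i], clones$individual_id[i])
    reps <- lapply(reps, function(r) sort(unique(r)))
    list(individuals = names(reps), replicates = unname(reps),
         verified = any(lengths(reps) >= 2L))
  })
  out <- data.frame(sequence = names(idx), stringsAsFactors = FALSE)
  out$individuals <- lapply(res, `[[`, "individuals")
  out$replicates <- lapply(res, `[[`, "replicates")
  out$verified <- vapply(res, `[[`, TRUE, "verified")
  rownames(out) <- NULL
  out
}

#' Build the complete and conservative haplotype datasets
#'
#' Classifies collapsed clone haplotypes as genuine variants or PCR/cloning
#' artifacts:
#'
#' 1. haplotypes found in multiple copies (count >= 2) or verified in two
#'    independent PCR replicates of one individual are retained
#'    unconditionally ("common" sequences);
#' 2. each remaining singleton is tested against the retained pool: it is
#'    flagged as an artifact when [artifact_probability()] at its distance to
#'    the nearest retained haplotype is at least `alpha`, i.e. when PCR error
#'    plausibly explains it; otherwise it is retained in the complete dataset
#'    only;
#' 3. the conservative dataset is the retained haplotypes with count >= 2.
#'
#' Singletons are always judged against the unconditionally retained pool
#' (not against other retained singletons), which makes the artifact set
#' nested in `alpha`. The clone pool size used in the probability is the
#' number of clones sequenced from the singleton's carrier individual.
#'
#' @param clones a clone-record data frame.
#' @param model an [error_model()]; the default derives the amplicon length
#'   from the clones.
#' @param alpha significance level in (0, 1): singletons whose artifact
#'   probability reaches `alpha` are removed.
#' @return A `filter_result` list with `complete`, `conservative` and
#'   `artifacts` haplotype tables plus a per-haplotype `decisions` log
#'   (rule fired, nearest retained neighbour, distance, lambda, probability).
#' @export
build_datasets <- function(clones, model = NULL, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) hc_parameter_error("alpha must be in (0, 1)")
  ht <- collapse_haplotypes(clones)
  if (is.null(model)) model <- error_model(length = nchar(ht$sequence[1]))
  verified <- reconditioning_consistency(clones)
  ht$verified <- verified$verified[match(ht$sequence, verified$sequence)]
  retained0 <- ht$count >= 2L | ht$verified

  clones_per_ind <- table(clones$individual_id)
  lambda <- expected_errors(model)

  dec <- data.frame(
    haplotype_id = ht$haplotype_id, count = ht$count, verified = ht$verified,
    rule = NA_character_, neighbor = NA_character_, d = NA_integer_,
    lambda = lambda, probability = NA_real_, stringsAsFactors = FALSE)
  dec$rule[ht$count >= 2L] <- "multiplicity"
  dec$rule[ht$verified & ht$count < 2L] <- "replicate-verified"

  singles <- which(!retained0)
  keep_single <- logical(0)
  if (length(singles) > 0L) {
    if (!any(retained0)) {
      warning("no haplotype retained unconditionally; singletons kept without artifact testing")
      keep_single <- rep(TRUE, length(singles))
      dec$rule[singles] <- "retained-singleton"
    } else {
      pool <- ht[retained0, ]
      pmat <- pairwise_distance_matrix(c(
        setNames(ht$sequence[singles], ht$haplotype_id[singles]),
        setNames(pool$sequence, pool$haplotype_id)))
      ns <- length(singles)
      keep_single <- logical(ns)
      for (k in seq_len(ns)) {
        dists <- pmat[k, ns + seq_len(nrow(pool))]
        # nearest retained neighbour: min distance, then largest count,
        # then lexicographic sequence
        ord <- lex_order(dists, -pool$count, pool$sequence)
        nb <- ord[1]
        d <- dists[nb]
        ind <- ht$carriers[[singles[k]]][1]
        n_pool <- as.integer(clones_per_ind[[ind]])
        p <- if (d == 0L) 1.0 else artifact_probability(d, model, n_pool)
        keep_single[k] <- p < alpha
        dec$neighbor[singles[k]] <- pool$haplotype_id[nb]
        dec$d[singles[k]] <- d
        dec$probability[singles[k]] <- p
        dec$rule[singles[k]] <- if (keep_single[k]) "retained-singleton" else "artifact"
      }
    }
  }

  keep <- retained0
  keep[singles] <- keep_single
  if (!any(keep)) hc_pipeline_error("dataset empty after filtering")

  subset_ht <- function(ht, i) {
    out <- ht[i, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "L") <- attr(ht, "L")
    class(out) <- class(ht)
    out
  }
  res <- list(
    complete = subset_ht(ht, keep),
    conservative = subset_ht(ht, keep & ht$count >= 2L),
    artifacts = subset_ht(ht, !keep),
    decisions = dec, model = model, alpha = alpha)
  class(res) <- "filter_result"
  res
}

#' @export
print.filter_result <- function(x, ...) {
  cat(sprintf(
    "<filter_result> complete: %d haplotypes (%d clones), conservative: %d, artifacts: %d; alpha = %g, lambda = %.4g\n",
    nrow(x$complete), sum(x$complete$count), nrow(x$conservative),
    nrow(x$artifacts), x$alpha, expected_errors(x$model)))
  invisible(x)
}

#' Write the artifact-filter decision log as TSV
#' @param result a `filter_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_filter_log <- function(result, path) {
  write.table(result$decisions, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
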