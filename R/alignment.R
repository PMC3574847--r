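ALN_ALPHABET <- c("A", "C", "G", "T", "-", "N")

#' Construct a validated alignment
#'
#' An alignment is the substrate of every downstream statistic: a set of
#' equal-length, uppercase DNA sequences over the alphabet `A,C,G,T,-,N`
#' with unique record labels. Characters are stored verbatim; gap and `N`
#' handling is decided by the downstream statistics, not here.
#'
#' @param ids character vector of unique record labels.
#' @param seqs character vector of DNA strings (one per record); lowercase
#'   input is uppercased.
#' @return An object of class `haplo_alignment`: a list with elements
#'   `ids`, `seqs` and `L` (alignment length in bp).
#' @examples
#' aln <- alignment(c("a", "b"), c("ACGT", "ACGA"))
#' aln$L
#' @export
alignment <- function(ids, seqs) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs))
    hc_input_error("ids and seqs must have equal length")
  if (length(seqs) == 0L) hc_input_error("alignment has no records")
  if (anyDuplicated(ids))
    hc_input_error(sprintf("duplicate record ids: %s",
                           paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  L <- nchar(seqs)
  if (length(unique(L)) != 1L)
    hc_alignment_error(sprintf(
      "ragged alignment: lengths %s", paste(sort(unique(L)), collapse = ", ")))
  if (L[1] == 0L) hc_alignment_error("alignment length is zero")
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad))
    hc_input_error(sprintf(
      "records with characters outside {A,C,G,T,-,N}: %s",
      paste(ids[bad], collapse = ", ")))
  structure(list(ids = ids, seqs = seqs, L = L[1]), class = "haplo_alignment")
}

#' @export
print.haplo_alignment <- function(x, ...) {
  cat(sprintf("<haplo_alignment> %d sequences x %d bp\n", length(x$ids), x$L))
  invisible(x)
}

#' Read an aligned multi-FASTA file
#'
#' Records are uppercased on read and validated (equal lengths, unique ids,
#' alphabet restricted to `A,C,G,T,-,N`).
#'
#' @param path path to a FASTA file.
#' @param format only `"fasta"` is supported.
#' @return A [alignment()] object.
#' @export
read_alignment <- function(path, format = "fasta") {
  format <- match.arg(format, "fasta")
  if (!file.exists(path)) hc_input_error(sprintf("file not found: %s", path))
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0L) hc_input_error(sprintf("no FASTA records in %s", path))
  seqs <- vapply(as.character(dna), function(s) paste(s, collapse = ""), "")
  alignment(names(dna), seqs)
}

#' Write an alignment to FASTA
#'
#' @param aln a [alignment()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "haplo_alignment"))
  dna <- ape::as.DNAbin(lapply(strsplit(aln$seqs, ""), tolower))
  names(dna) <- aln$ids
  ape::write.FASTA(dna, path)
  invisible(path)
}

# alignment as a character matrix (rows = records)
seq_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$seqs, ""))
  rownames(m) <- aln$ids
  m
}

#' Describe a clone-label scheme
#'
#' Clone record ids encode collection site, individual fly, PCR replicate and
#' clone, joined by a delimiter. The field order is configurable because
#' clone naming conventions vary between labs; the default is
#' `site|individual|replicate|clone` (e.g. `"JN|JN6|r1|c03"`).
#'
#' @param delim field delimiter (single string, used literally).
#' @param fields permutation of `c("site","individual","replicate","clone")`.
#' @return A `label_scheme` object.
#' @export
label_scheme <- function(delim = "|",
                         fields = c("site", "individual", "replicate", "clone")) {
  if (!setequal(fields, c("site", "individual", "replicate", "clone")))
    hc_input_error("fields must be a permutation of site/individual/replicate/clone")
  structure(list(delim = delim, fields = fields), class = "label_scheme")
}

#' Parse clone labels into clone records
#'
#' Splits each alignment record id under a [label_scheme()] into one clone
#' record per row: clone id, individual, collection site and PCR replicate,
#' carrying the sequence along.
#'
#' @param aln a [alignment()] object of cloned amplicon sequences.
#' @param scheme a [label_scheme()].
#' @return A data frame of clone records with columns `clone_id`,
#'   `site_code`, `individual_id`, `pcr_replicate` (integer), `clone` and
#'   `sequence`.
#' @export
parse_clone_labels <- function(aln, scheme = label_scheme()) {
  stopifnot(inherits(aln, "haplo_alignment"), inherits(scheme, "label_scheme"))
  parts <- strsplit(aln$ids, scheme$delim, fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != length(scheme$fields)))
    hc_input_error(sprintf(
      "unparseable clone label(s): %s (expected %d '%s'-delimited fields)",
      paste(aln$ids[nf != length(scheme$fields)], collapse = ", "),
      length(scheme$fields), scheme$delim))
  mat <- do.call(rbind, parts)
  colnames(mat) <- scheme$fields
  rep_raw <- mat[, "replicate"]
  rep_num <- suppressWarnings(as.integer(gsub("[^0-9]", "", rep_raw)))
  bad <- is.na(rep_num) | rep_num < 1L
  if (any(bad))
    hc_input_error(sprintf("non-numeric or invalid PCR replicate in id(s): %s",
                           paste(aln$ids[bad], collapse = ", ")))
  clones <- data.frame(
    clone_id = aln$ids,
    site_code = mat[, "site"],
    individual_id = mat[, "individual"],
    pcr_replicate = rep_num,
    clone = mat[, "clone"],
    sequence = aln$seqs,
    stringsAsFactors = FALSE
  )
  key <- paste(clones$individual_id, clones$pcr_replicate, clones$clone)
  if (anyDuplicated(key))
    hc_input_error("duplicate (individual, replicate, clone) combinations")
  clones
}

#' Build clone records directly
#'
#' Convenience constructor used by the simulator and by callers that do not
#' come through FASTA labels.
#'
#' @param individual_id,sequence required character vectors (recycled to a
#'   common length with the optional fields).
#' @param clone_id,site_code,pcr_replicate optional; defaults are generated.
#' @return A clone-record data frame as from [parse_clone_labels()].
#' @export
clone_records <- function(individual_id, sequence, clone_id = NULL,
                          site_code = NULL, pcr_replicate = 1L) {
  n <- max(length(individual_id), length(sequence))
  individual_id <- rep_len(as.character(individual_id), n)
  sequence <- toupper(rep_len(as.character(sequence), n))
  if (is.null(site_code)) site_code <- sub("[0-9]+$", "", individual_id)
  if (is.null(clone_id))
    clone_id <- sprintf("%s|%s|r%d|c%02d", rep_len(site_code, n), individual_id,
                        rep_len(as.integer(pcr_replicate), n), seq_len(n))
  data.frame(
    clone_id = clone_id,
    site_code = rep_len(as.character(site_code), n),
    individual_id = individual_id,
    pcr_replicate = rep_len(as.integer(pcr_replicate), n),
    clone = sprintf("c%02d", seq_len(n)),
    sequence = sequence,
    stringsAsFactors = FALSE
  )
}

#' Collapse clone records to a haplotype table
#'
#' Haplotype identity is exact string match including gaps and `N`; ambiguity
#' resolution is deferred to the artifact filter. Haplotype ids are assigned
#' deterministically by decreasing multiplicity, ties broken by lexicographic
#' sequence order.
#'
#' @param clones a clone-record data frame (needs columns `individual_id`,
#'   `sequence`; `site_code` is used when present).
#' @return A `haplotype_table` data frame with columns `haplotype_id`,
#'   `sequence`, `count`, and list-columns `carriers` (individual ids) and
#'   `sites` (site codes). The attribute `L` stores the alignment length.
#' @examples
#' cl <- clone_records(rep("JN6", 8), rep("ACGTACGT", 8))
#' collapse_haplotypes(cl)
#' @export
collapse_haplotypes <- function(clones) {
  if (is.null(clones) || nrow(clones) == 0L)
    hc_input_error("no clone records to collapse")
  L <- nchar(clones$sequence)
  if (length(unique(L)) != 1L)
    hc_alignment_error("clone sequences have unequal lengths")
  idx <- split(seq_len(nrow(clones)), clones$sequence)
  seqs <- names(idx)
  count <- lengths(idx)
  carriers <- lapply(idx, function(i) sort(unique(clones$individual_id[i])))
  sites <- if ("site_code" %in% names(clones))
    lapply(idx, function(i) sort(unique(clones$site_code[i])))
  else lapply(idx, function(i) character(0))
  ord <- lex_order(-count, seqs)
  width <- max(2L, nchar(length(seqs)))
  ht <- data.frame(
    haplotype_id = sprintf("H%0*d", width, seq_along(seqs)),
    sequence = seqs[ord],
    count = as.integer(count[ord]),
    stringsAsFactors = FALSE
  )
  ht$carriers <- unname(carriers[ord])
  ht$sites <- unname(sites[ord])
  rownames(ht) <- NULL
  attr(ht, "L") <- L[1]
  class(ht) <- c("haplotype_table", "data.frame")
  ht
}

#' Expand a haplotype table back to individual sequences
#'
#' @param ht a `haplotype_table`.
#' @param unit `"clone"` repeats each haplotype `count` times; `"carrier"`
#'   emits one sequence per (haplotype, carrier individual) pair — the unit
#'   used for group-level diversity and AMOVA summaries.
#' @return A data frame with columns `haplotype_id`, `sequence` and, for
#'   `unit = "carrier"`, `individual_id`.
#' @export
expand_haplotypes <- function(ht, unit = c("clone", "carrier")) {
  unit <- match.arg(unit)
  if (unit == "clone") {
    i <- rep(seq_len(nrow(ht)), ht$count)
    data.frame(haplotype_id = ht$haplotype_id[i], sequence = ht$sequence[i],
               stringsAsFactors = FALSE)
  } else {
    n <- lengths(ht$carriers)
    i <- rep(seq_len(nrow(ht)), n)
    data.frame(haplotype_id = ht$haplotype_id[i], sequence = ht$sequence[i],
               individual_id = unlist(ht$carriers), stringsAsFactors = FALSE)
  }
}

as_alignment <- function(ht) alignment(ht$haplotype_id, ht$sequence)

#' MLST clone-identity check
#'
#' For strain typing loci, all clones of one individual at one locus are
#' expected to be identical; any (individual, locus) group with more than
#' one distinct sequence is flagged. Individuals whose clones are identical
#' at every locus get a concatenation-ready consensus (loci concatenated in
#' the order given).
#'
#' @param per_locus_clones named list mapping locus name to a clone-record
#'   data frame.
#' @return A list with `report` (per individual and locus: clone and
#'   haplotype counts plus an `identical` flag) and `consensus` (per clean
#'   individual: the concatenated consensus sequence and its length).
#' @export
mlst_identity_check <- function(per_locus_clones) {
  stopifnot(is.list(per_locus_clones), length(names(per_locus_clones)) > 0)
  rows <- list()
  cons <- list()  # locus -> individual -> consensus sequence
  for (locus in names(per_locus_clones)) {
    cl <- per_locus_clones[[locus]]
    if (is.null(cl) || nrow(cl) == 0L) {
      warning(sprintf("locus %s has no clones; skipped", locus))
      next
    }
    by_ind <- split(cl$sequence, cl$individual_id)
    for (ind in names(by_ind)) {
      u <- unique(by_ind[[ind]])
      rows[[length(rows) + 1L]] <- data.frame(
        locus = locus, individual_id = ind,
        n_clones = length(by_ind[[ind]]), n_haplotypes = length(u),
        identical = length(u) == 1L, stringsAsFactors = FALSE)
      if (length(u) == 1L) cons[[locus]][[ind]] <- u
    }
  }
  report <- do.call(rbind, rows)
  loci <- names(per_locus_clones)
  inds <- sort(unique(report$individual_id))
  keep <- vapply(inds, function(ind) {
    all(vapply(loci, function(lc) !is.null(cons[[lc]][[ind]]), TRUE))
  }, TRUE)
  consensus <- data.frame(
    individual_id = inds[keep],
    sequence = vapply(inds[keep], function(ind)
      paste(vapply(loci, function(lc) cons[[lc]][[ind]], ""), collapse = ""), ""),
    stringsAsFactors = FALSE
  )
  consensus$length <- nchar(consensus$sequence)
  rownames(consensus) <- NULL
  list(report = report, consensus = consensus)
}

#' Write a haplotype table as TSV
#'
#' Columns are emitted in a fixed order; carrier and site sets are
#' comma-joined.
#'
#' @param ht a `haplotype_table` (extra plain columns such as group labels
#'   are carried through).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_haplotypes <- function(ht, path) {
  out <- as.data.frame(ht[setdiff(names(ht), c("carriers", "sites"))])
  out$carriers <- vapply(ht$carriers, paste, "", collapse = ",")
  out$sites <- vapply(ht$sites, paste, "", collapse = ",")
  lead <- intersect(c("haplotype_id", "count", "carriers", "sites"), names(out))
  out <- out[, c(lead, setdiff(names(out), c(lead, "sequence")), "sequence")]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a haplotype table as FASTA
#' @param ht a `haplotype_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_haplotype_fasta <- function(ht, path) {
  write_alignment(as_alignment(ht), path)
}
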