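#' Simple indel coding of alignment gaps
#'
#' Recodes each distinct contiguous gap run, identified by its exact
#' (start, end) span, as one binary presence/absence character: `1` if the
#' sequence has exactly that maximal gap run, `0` if it has nucleotides across
#' the span, and missing (`NA`) if a different, longer run strictly subsumes
#' the span (the state of the shorter event cannot be observed). Coordinates
#' are reported 1-based inclusive; half-open 0-based coordinates are used
#' internally.
#'
#' @param alignment a `yew_alignment`.
#' @return an object of class `indel_matrix`: list with `events`
#'   (data.frame `start`, `end`, 1-based inclusive, ordered by start then end)
#'   and `states` (matrix, sequences x events, values 1/0/NA).
#' @export
code_indels_simple <- function(alignment) {
  seqs <- alignment$seq
  n <- length(seqs)
  runs <- lapply(seqs, gap_runs)
  all_runs <- unique(do.call(rbind, c(list(matrix(integer(0), ncol = 2)), runs)))
  if (nrow(all_runs) == 0L) {
    out <- list(events = data.frame(start = integer(0), end = integer(0)),
                states = matrix(integer(0), nrow = n, ncol = 0,
                                dimnames = list(names(seqs), NULL)))
    class(out) <- "indel_matrix"
    return(out)
  }
  ord <- order(all_runs[, 1L], all_runs[, 2L])
  all_runs <- all_runs[ord, , drop = FALSE]
  m <- nrow(all_runs)
  states <- matrix(0L, nrow = n, ncol = m,
                   dimnames = list(names(seqs), NULL))
  for (i in seq_len(n)) {
    ri <- runs[[i]]
    for (k in seq_len(m)) {
      s <- all_runs[k, 1L]; e <- all_runs[k, 2L]
      if (nrow(ri) == 0L) next
      exact <- any(ri[, 1L] == s & ri[, 2L] == e)
      if (exact) {
        states[i, k] <- 1L
      } else if (any(ri[, 1L] <= s & ri[, 2L] >= e &
                     (ri[, 2L] - ri[, 1L]) > (e - s))) {
        states[i, k] <- NA_integer_
      }
    }
  }
  out <- list(events = data.frame(start = all_runs[, 1L] + 1L,
                                  end = all_runs[, 2L]),
              states = states)
  class(out) <- "indel_matrix"
  out
}

# Maximal gap runs of one sequence as a matrix of 0-based half-open
# (start, end) spans.
gap_runs <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  is_gap <- ch == "-"
  if (!any(is_gap)) return(matrix(integer(0), ncol = 2))
  r <- rle(is_gap)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  cbind(starts[r$values], ends[r$values])
}

#' Collapse aligned sequences into haplotypes
#'
#' Groups identical sequences into haplotypes and tallies counts per
#' population and per taxon. Haplotype identity can include indel-coded
#' characters (each distinct gap event contributing one character, see
#' [code_indels_simple()]): with `use_indel_chars = TRUE` the substitution key
#' is taken over gap-free columns and the indel character states are appended,
#' so sequences differing only by a gap event remain distinct. With
#' `use_indel_chars = FALSE`, gaps are either a fifth character state
#' (`gap_as_missing = FALSE`) or treated as missing data by complete deletion
#' of gapped columns (`gap_as_missing = TRUE`).
#'
#' Haplotype ids are assigned by first appearance in record order and
#' prefixed by `prefix` (e.g. `cp1`, `cp2`, ...), so numbering is reproducible
#' without sorting ambiguity.
#'
#' @param alignment a `yew_alignment`.
#' @param map a `sample_map` covering every individual in the alignment.
#' @param use_indel_chars append simple-indel-coding characters to the
#'   haplotype definition (default `TRUE`).
#' @param gap_as_missing only used when `use_indel_chars = FALSE`; see above.
#' @param prefix haplotype id prefix; default `"hap"`.
#' @return an object of class `haplotype_table`: list with
#'   `haplotypes` (data.frame `haplotype_id`, `sequence`),
#'   `counts` (haplotype x population matrix),
#'   `taxon_counts` (haplotype x taxon matrix),
#'   `assignment` (per-record data.frame with `record_id`, `individual`,
#'   `population`, `taxon`, `haplotype_id`),
#'   `indels` (the `indel_matrix` used, or NULL) and `ploidy_mode`.
#' @export
collapse_haplotypes <- function(alignment, map, use_indel_chars = TRUE,
                                gap_as_missing = !use_indel_chars,
                                prefix = "hap") {
  check_alignment_map(alignment, map)
  seqs <- alignment$seq
  n <- length(seqs)
  if (n == 0L) stop("empty alignment")
  chmat <- do.call(rbind, strsplit(unname(seqs), "", fixed = TRUE))
  indels <- NULL
  if (use_indel_chars) {
    indels <- code_indels_simple(alignment)
    gap_cols <- which(apply(chmat == "-", 2L, any))
    sub_key <- if (length(gap_cols) > 0L)
      apply(chmat[, -gap_cols, drop = FALSE], 1L, paste0, collapse = "")
    else apply(chmat, 1L, paste0, collapse = "")
    ind_key <- apply(indels$states, 1L, function(r)
      paste0(ifelse(is.na(r), "?", r), collapse = ""))
    key <- paste(sub_key, ind_key, sep = "|")
  } else if (gap_as_missing) {
    gap_cols <- which(apply(chmat == "-", 2L, any))
    keep <- if (length(gap_cols) > 0L) chmat[, -gap_cols, drop = FALSE] else chmat
    key <- apply(keep, 1L, paste0, collapse = "")
  } else {
    key <- unname(seqs)
  }
  first <- !duplicated(key)
  hap_keys <- key[first]
  hap_id <- paste0(prefix, seq_along(hap_keys))
  id_of <- stats::setNames(hap_id, hap_keys)
  rec_hap <- unname(id_of[key])

  ids <- names(seqs)
  inds <- individual_stems(ids)
  mrow <- match(inds, map$sample_id)
  assignment <- data.frame(record_id = ids,
                           individual = inds,
                           population = map$population[mrow],
                           taxon = map$taxon[mrow],
                           haplotype_id = rec_hap,
                           stringsAsFactors = FALSE)
  pops <- unique(map$population[mrow])
  taxa <- unique(map$taxon[mrow])
  counts <- table(factor(rec_hap, levels = hap_id),
                  factor(assignment$population, levels = pops))
  taxon_counts <- table(factor(rec_hap, levels = hap_id),
                        factor(assignment$taxon, levels = taxa))
  out <- list(haplotypes = data.frame(haplotype_id = hap_id,
                                      sequence = unname(seqs[first]),
                                      stringsAsFactors = FALSE),
              counts = unclass(as.matrix(counts)),
              taxon_counts = unclass(as.matrix(taxon_counts)),
              assignment = assignment,
              indels = if (use_indel_chars)
                list(events = indels$events,
                     states = indels$states[first, , drop = FALSE]) else NULL,
              ploidy_mode = alignment$ploidy_mode)
  class(out) <- "haplotype_table"
  out
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat("<haplotype_table> ", nrow(x$haplotypes), " haplotypes, ",
      sum(x$counts), " sequences, ", ncol(x$counts), " populations\n", sep = "")
  invisible(x)
}

#' Export a haplotype table
#'
#' Writes the haplotype x population count matrix as TSV and, optionally,
#' the haplotype sequences as FASTA.
#'
#' @param haptable a `haplotype_table`.
#' @param counts_path TSV output path for the count matrix.
#' @param fasta_path optional FASTA output path for haplotype sequences.
#' @return `counts_path`, invisibly.
#' @export
write_haplotype_table <- function(haptable, counts_path, fasta_path = NULL) {
  df <- data.frame(haplotype_id = haptable$haplotypes$haplotype_id,
                   haptable$counts, check.names = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(fasta_path)) {
    aln <- new_alignment(stats::setNames(haptable$haplotypes$sequence,
                                         haptable$haplotypes$haplotype_id))
    write_alignment(aln, fasta_path)
  }
  invisible(counts_path)
}
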