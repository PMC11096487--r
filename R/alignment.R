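#' Construct an alignment object
#'
#' An alignment is a set of equal-length sequences over the alphabet
#' `A,C,G,T,-,N`, either haploid (one record per sample, e.g. concatenated
#' chloroplast markers) or phased diploid (two records per individual with
#' `_h1`/`_h2` suffixes, e.g. ITS haplotype pairs).
#'
#' @param sequences named character vector of sequence strings; names are
#'   record identifiers and must be unique.
#' @param ploidy_mode `"haploid"` or `"diploid_phased"`.
#' @return An object of class `yew_alignment`: a list with elements
#'   `seq` (named character vector, upper case), `length` (alignment length)
#'   and `ploidy_mode`.
#' @export
new_alignment <- function(sequences, ploidy_mode = c("haploid", "diploid_phased")) {
  ploidy_mode <- match.arg(ploidy_mode)
  if (length(sequences) == 0L) {
    obj <- list(seq = character(0), length = 0L, ploidy_mode = ploidy_mode)
    class(obj) <- "yew_alignment"
    return(obj)
  }
  ids <- names(sequences)
  if (is.null(ids) || any(ids == "" | is.na(ids)))
    stop("every sequence must be named with a record id")
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("duplicate record id(s): ", paste(unique(dup), collapse = ", "))
  sequences <- toupper(sequences)
  lens <- nchar(sequences)
  if (any(lens == 0L))
    stop("empty sequence for record ", ids[which(lens == 0L)[1L]])
  if (length(unique(lens)) != 1L) {
    bad <- ids[lens != lens[1L]][1L]
    stop("length mismatch: record '", bad, "' has ", lens[ids == bad][1L],
         " bp, expected ", lens[1L])
  }
  bad_chars <- gsub("[ACGTN-]", "", sequences)
  if (any(nchar(bad_chars) > 0L)) {
    i <- which(nchar(bad_chars) > 0L)[1L]
    stop("record '", ids[i], "' contains unsupported character(s) '",
         bad_chars[i], "'; IUPAC ambiguity codes other than N are not accepted")
  }
  if (ploidy_mode == "diploid_phased") {
    if (!all(grepl("_h[12]$", ids)))
      stop("diploid_phased records must carry the '_h1'/'_h2' phase suffix")
    stems <- individual_stems(ids)
    tab <- table(stems)
    if (any(tab != 2L))
      stop("individual(s) without exactly two phased records: ",
           paste(names(tab)[tab != 2L], collapse = ", "))
  }
  obj <- list(seq = sequences, length = unname(lens[1L]), ploidy_mode = ploidy_mode)
  class(obj) <- "yew_alignment"
  obj
}

#' @export
print.yew_alignment <- function(x, ...) {
  cat("<yew_alignment> ", length(x$seq), " records x ", x$length, " bp (",
      x$ploidy_mode, ")\n", sep = "")
  invisible(x)
}

# Individual stem of a record id: the id itself for haploid records,
# the id minus the phase suffix for phased diploid records.
individual_stems <- function(ids) sub("_h[12]$", "", ids)

#' Individuals represented in an alignment
#'
#' @param alignment a [new_alignment()] object.
#' @return character vector of individual stems, one per individual, in
#'   first-occurrence order.
#' @export
alignment_individuals <- function(alignment) {
  unique(individual_stems(names(alignment$seq)))
}

#' Read a FASTA alignment
#'
#' Sequences must be pre-aligned (equal lengths) over `A,C,G,T,-,N`.
#' Unequal lengths, duplicate identifiers or ambiguity codes other than `N`
#' are hard errors naming the offending record.
#'
#' @param path path to a FASTA file.
#' @inheritParams new_alignment
#' @return a `yew_alignment`.
#' @export
read_alignment <- function(path, ploidy_mode = c("haploid", "diploid_phased")) {
  if (!file.exists(path)) stop("file not found: ", path)
  recs <- seqinr::read.fasta(path, seqtype = "DNA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  seqs <- vapply(recs, function(r) as.character(r)[1L], character(1))
  names(seqs) <- vapply(recs, function(r) attr(r, "name"), character(1))
  new_alignment(seqs, ploidy_mode = match.arg(ploidy_mode))
}

#' Write an alignment to FASTA
#'
#' @param alignment a `yew_alignment`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(alignment, path) {
  seqinr::write.fasta(as.list(unname(alignment$seq)),
                      names = names(alignment$seq),
                      file.out = path, nbchar = 80)
  invisible(path)
}

#' Read a sample map
#'
#' A tab-separated table with header
#' `sample_id  population  taxon  ploidy` mapping each individual to its
#' sampling site (population code) and taxon. `ploidy` is 1 for haploid
#' (chloroplast) samples and 2 for phased diploid (ITS) samples.
#'
#' @param path path to a TSV file.
#' @return a `data.frame` with class `c("sample_map", "data.frame")`.
#' @export
read_sample_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  as_sample_map(df)
}

#' Validate a data frame as a sample map
#'
#' @param df data.frame with columns `sample_id`, `population`, `taxon`,
#'   `ploidy`.
#' @return the validated map, classed `sample_map`.
#' @export
as_sample_map <- function(df) {
  need <- c("sample_id", "population", "taxon", "ploidy")
  if (!all(need %in% names(df)))
    stop("sample map must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id(s) in sample map: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if (!all(df$ploidy %in% c(1L, 2L)))
    stop("ploidy must be 1 or 2")
  df <- df[, need]
  class(df) <- c("sample_map", "data.frame")
  df
}

#' Write a sample map to TSV
#'
#' @param map a `sample_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_map <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Check that every alignment individual appears exactly once in the map.
check_alignment_map <- function(alignment, map) {
  inds <- alignment_individuals(alignment)
  missing <- setdiff(inds, map$sample_id)
  if (length(missing) > 0L)
    stop("individual(s) absent from sample map: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  invisible(TRUE)
}

#' Concatenate haploid marker alignments by individual
#'
#' Joins several single-marker alignments (e.g. the four chloroplast
#' intergenic spacers) into one concatenated alignment per individual, in the
#' supplied marker order. All markers must be haploid and cover exactly the
#' same individuals; a missing individual in any marker is a hard error (no
#' partial concatenation). Marker boundary offsets are recorded in the
#' `"boundaries"` attribute as 1-based inclusive start/end coordinates.
#'
#' @param alignments list of haploid `yew_alignment` objects, optionally
#'   named by marker.
#' @param map optional `sample_map` used to validate individual coverage.
#' @return a haploid `yew_alignment` of length `sum(marker lengths)`.
#' @export
concatenate_markers <- function(alignments, map = NULL) {
  if (length(alignments) == 0L) stop("no alignments supplied")
  for (a in alignments) {
    if (!inherits(a, "yew_alignment")) stop("alignments must be yew_alignment objects")
    if (a$ploidy_mode != "haploid") stop("all markers must be haploid")
  }
  ids <- names(alignments[[1L]]$seq)
  for (k in seq_along(alignments)) {
    idk <- names(alignments[[k]]$seq)
    miss <- setdiff(ids, idk)
    extra <- setdiff(idk, ids)
    if (length(miss) > 0L || length(extra) > 0L)
      stop("marker ", k, " does not cover the same individuals (missing: ",
           paste(utils::head(c(miss, extra), 5L), collapse = ", "), ")")
  }
  lens <- vapply(alignments, function(a) a$length, integer(1))
  cat_seq <- vapply(ids, function(id) {
    paste0(vapply(alignments, function(a) a$seq[[id]], character(1)),
           collapse = "")
  }, character(1))
  names(cat_seq) <- ids
  out <- new_alignment(cat_seq, "haploid")
  ends <- cumsum(lens)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  nm <- names(alignments)
  if (is.null(nm)) nm <- paste0("marker", seq_along(alignments))
  attr(out, "boundaries") <- data.frame(marker = nm, start = starts, end = ends)
  if (!is.null(map)) check_alignment_map(out, map)
  out
}
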