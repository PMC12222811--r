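#' Count distinct alignment locations of multireads on each replicon
#'
#' Builds one row of the match matrix per read: the number of distinct
#' candidate alignment locations on each replicon. K-mer hit positions
#' are projected (strand-aware) to implied read-start positions,
#' clustered with a merge window of one read length, and a cluster
#' supported by at least a fraction `tau_loc` of the read's hitting
#' k-mers counts as one location. Two locations are therefore distinct
#' only when their implied starts differ by at least the read length.
#' The counts are invariant to reverse-complementing the read.
#'
#' @param index a [build_index()] object.
#' @param reads multiread records: a tibble with `id` and `sequence`
#'   columns, or a character vector of sequences.
#' @param tau_loc minimum support fraction per location; default 0.5.
#' @return Integer matrix, one row per read (rownames = read ids) and
#'   one column per replicon (colnames = replicon ids).
#' @export
locate_matches <- function(index, reads, tau_loc = 0.5) {
  stopifnot(inherits(index, "kmer_index"))
  reads <- as_read_tbl(reads)
  M <- cpp_locate(index$ptr, reads$sequence, tau_loc)
  dimnames(M) <- list(reads$id, index$replicon_ids)
  M
}

#' Promote unique-location multireads and assemble the match matrix
#'
#' A multiread whose located matches sum to exactly one genomic location
#' is in fact unambiguous: it is promoted into the uniread counts of its
#' replicon. A read whose row sums to zero (location matching found
#' nothing) is reclassified unmapped. The remaining rows -- the true
#' multireads -- form the match matrix consumed by [pira_estimate()].
#' Read totals are conserved:
#' `sum(R) + nrow(M) + n_unmapped` is unchanged by promotion.
#'
#' @param summary an [classify_reads()] `assignment_summary`.
#' @param rows integer matrix from [locate_matches()], one row per
#'   multiread in `summary$multireads` (same order).
#' @return The updated `assignment_summary`, with an added element `M`
#'   (the match matrix of true multireads) and `multireads` restricted to
#'   the matrix rows.
#' @export
promote_unique <- function(summary, rows) {
  stopifnot(inherits(summary, "assignment_summary"))
  if (is.null(rows) || nrow(rows) == 0) {
    summary$M <- matrix(0L, 0, length(summary$R),
                        dimnames = list(NULL, names(summary$R)))
    return(summary)
  }
  stopifnot(nrow(rows) == nrow(summary$multireads))
  total <- rowSums(rows)
  promote <- total == 1L
  none <- total == 0L
  keep <- !promote & !none
  if (any(promote)) {
    rep_idx <- max.col(rows[promote, , drop = FALSE], ties.method = "first")
    summary$R <- summary$R +
      setNames(tabulate(rep_idx, nbins = length(summary$R)), names(summary$R))
  }
  summary$n_unmapped <- summary$n_unmapped + sum(none)
  summary$M <- rows[keep, , drop = FALSE]
  summary$multireads <- summary$multireads[keep, , drop = FALSE]
  summary
}

#' Write a match matrix as TSV for inspection
#'
#' @param M matrix from [locate_matches()] / [promote_unique()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_match_matrix <- function(M, path) {
  df <- data.frame(read_id = rownames(M), M, check.names = FALSE,
                   row.names = NULL)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
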