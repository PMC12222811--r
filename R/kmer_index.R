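#' Build a colored k-mer index over a genome
#'
#' Indexes every canonical k-mer (lexicographic minimum of the k-mer and
#' its reverse complement) of every replicon, recording the set of
#' replicons carrying it (its colors) and all occurrence positions.
#' K-mers containing `N` or any other ambiguity code are never indexed.
#'
#' The index is an in-memory structure (an external pointer); it is cheap
#' to rebuild and is not serializable across sessions.
#'
#' @param genome a [genome_ref()] object.
#' @param k odd k-mer size in `[11, 31]`; default 31, the standard choice
#'   for bacterial-scale pseudoalignment. The upper bound comes from
#'   packing canonical k-mers into 64-bit words.
#' @return An object of class `kmer_index`.
#' @export
build_index <- function(genome, k = 31) {
  stopifnot(inherits(genome, "genome_ref"))
  k <- as.integer(k)
  if (k %% 2L == 0L || k < 11L || k > 31L)
    stop("k must be odd and in [11, 31]")
  short <- genome$replicons$length < k
  if (any(short))
    stop("replicon shorter than k: ", genome$replicons$id[short][1])
  ptr <- cpp_index_build(unname(genome$sequences), k)
  structure(
    list(
      ptr = ptr,
      k = k,
      replicon_ids = genome$replicons$id,
      replicon_lengths = genome$replicons$length,
      roles = genome$replicons$role
    ),
    class = "kmer_index"
  )
}

#' @export
print.kmer_index <- function(x, ...) {
  s <- index_stats(x)
  cat("<kmer_index> k=", x$k, ", ", length(x$replicon_ids),
      " replicon(s), ", format(s$n_kmers, big.mark = ","),
      " distinct k-mers\n", sep = "")
  invisible(x)
}

#' Summary statistics of a k-mer index
#'
#' @param index a [build_index()] object.
#' @return List with `k`, `n_replicons`, `n_kmers` (distinct canonical
#'   k-mers) and `n_positions` (total indexed occurrences).
#' @export
index_stats <- function(index) {
  stopifnot(inherits(index, "kmer_index"))
  cpp_index_stats(index$ptr)
}

#' Color sets of query k-mers
#'
#' Mainly an inspection/testing aid: returns, for each query k-mer
#' string, the indices of the replicons carrying it.
#'
#' @param index a [build_index()] object.
#' @param kmers character vector of k-mer strings of length `k`.
#' @return List of integer vectors of replicon indices (empty when the
#'   k-mer is absent, has the wrong length, or contains `N`).
#' @export
kmer_colors <- function(index, kmers) {
  stopifnot(inherits(index, "kmer_index"))
  cpp_kmer_colors(index$ptr, as.character(kmers))
}

#' Pseudoalign reads to replicon sets
#'
#' Each read is assigned the set of replicons compatible with its k-mer
#' content: the intersection of the color sets of its k-mers that hit the
#' index. When the intersection is empty (as for chimeric junction
#' artifacts), the rule falls back to the union of colors supported by at
#' least a fraction `tau` of the hit k-mers. Reads with no hit at all --
#' including reads shorter than `k` -- are unmapped; this is how
#' erroneous reads drop out of the analysis. The classification is
#' strand-symmetric because k-mers are canonicalized.
#'
#' @param index a [build_index()] object.
#' @param reads a tibble with columns `id` and `sequence` (as from
#'   [load_reads()] or [simulate_reads()]), or a character vector of
#'   sequences.
#' @param tau fallback support fraction in (0, 1]; default 0.8.
#' @return A tibble with columns `read_id`, `status` (`"unmapped"`,
#'   `"uniread"` or `"multiread"`) and `replicons` (list column of
#'   integer replicon indices; empty for unmapped reads).
#' @export
pseudoalign_reads <- function(index, reads, tau = 0.8) {
  stopifnot(inherits(index, "kmer_index"))
  reads <- as_read_tbl(reads)
  res <- cpp_pseudoalign(index$ptr, reads$sequence, tau)
  sets <- res$sets
  uni <- res$status == 1L
  sets[uni] <- as.list(res$uni_rep[uni])
  sets[res$status == 0L] <- list(integer(0))
  tibble::tibble(
    read_id = reads$id,
    status = c("unmapped", "uniread", "multiread")[res$status + 1L],
    replicons = sets
  )
}

#' @rdname pseudoalign_reads
#' @param read a single read (one-row tibble or one sequence).
#' @export
pseudoalign_read <- function(index, read, tau = 0.8) {
  pseudoalign_reads(index, read, tau = tau)[1, ]
}

#' Classify a read set into unireads, multireads and unmapped reads
#'
#' Accumulates the per-replicon uniread counts `R` that seed the direct
#' copy-number estimate, retains the multiread records for location
#' matching, and counts unmapped reads. The counts always conserve the
#' input: `sum(R) + nrow(multireads) + n_unmapped == n_total`.
#'
#' @inheritParams pseudoalign_reads
#' @return An object of class `assignment_summary`: list with `R` (named
#'   integer vector of uniread counts per replicon), `multireads` (tibble
#'   of retained read records with a `replicons` list column),
#'   `n_unmapped` and `n_total`.
#' @export
classify_reads <- function(index, reads, tau = 0.8) {
  stopifnot(inherits(index, "kmer_index"))
  reads <- as_read_tbl(reads)
  n <- length(index$replicon_ids)
  if (nrow(reads) == 0) {
    return(structure(
      list(R = setNames(integer(n), index$replicon_ids),
           multireads = tibble::tibble(id = character(),
                                       sequence = character(),
                                       replicons = list()),
           n_unmapped = 0L, n_total = 0L),
      class = "assignment_summary"
    ))
  }
  res <- cpp_pseudoalign(index$ptr, reads$sequence, tau)
  R <- tabulate(res$uni_rep[res$status == 1L], nbins = n)
  multi <- res$status == 2L
  structure(
    list(
      R = setNames(as.integer(R), index$replicon_ids),
      multireads = tibble::tibble(id = reads$id[multi],
                                  sequence = reads$sequence[multi],
                                  replicons = res$sets[multi]),
      n_unmapped = sum(res$status == 0L),
      n_total = nrow(reads)
    ),
    class = "assignment_summary"
  )
}

#' @export
print.assignment_summary <- function(x, ...) {
  cat("<assignment_summary> ", x$n_total, " reads: ", sum(x$R),
      " unireads, ", nrow(x$multireads), " multireads, ", x$n_unmapped,
      " unmapped\n", sep = "")
  invisible(x)
}

as_read_tbl <- function(reads) {
  if (is.character(reads))
    return(tibble::tibble(id = paste0("read_", seq_along(reads)),
                          sequence = unname(reads)))
  stopifnot(is.data.frame(reads), all(c("id", "sequence") %in% names(reads)))
  reads
}
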