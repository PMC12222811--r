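#' Estimate plasmid copy numbers for one genome
#'
#' The full estimation pipeline: build the colored k-mer index, classify
#' reads into unireads/multireads/unmapped, locate multiread matches and
#' promote unique-location multireads, compute the direct coverage-ratio
#' estimate, refine it with the probabilistic iterative read assignment
#' EM ([pira_estimate()]), and flag plasmids supported by fewer than
#' `min_mapped_reads` mapped reads.
#'
#' @param genome a [genome_ref()] (already past [apply_genome_filters()]
#'   if genome-level filtering is wanted).
#' @param reads read tibble ([load_reads()] or [simulate_reads()]) or a
#'   character vector of sequences.
#' @param genome_id label copied into the output table.
#' @param k k-mer size ([build_index()]).
#' @param tau pseudoalignment fallback support fraction
#'   ([pseudoalign_reads()]).
#' @param tau_loc location support fraction ([locate_matches()]).
#' @param tol,max_iter EM convergence controls ([pira_estimate()]).
#' @param min_mapped_reads mapped-read threshold ([filter_estimates()]);
#'   applied after the EM, counting unireads, promoted reads and the
#'   rounded expected multiread allocation.
#' @return A tibble with one row per replicon: `genome_id`,
#'   `replicon_id`, `role`, `length_bp`, `uniread_count`
#'   (including promoted multireads), `multiread_alloc` (expected EM
#'   allocation), `mapped_reads`, `pcn_direct`, `pcn_pira`, `converged`,
#'   `iterations`, `kept` (mapped-read filter). The filter report and
#'   the unmapped-read count are attached as attributes `filter_report`
#'   and `n_unmapped`.
#' @export
estimate_pcn <- function(genome, reads, genome_id = "genome", k = 31,
                         tau = 0.8, tau_loc = 0.5, tol = 1e-6,
                         max_iter = 1000, min_mapped_reads = 10000) {
  stopifnot(inherits(genome, "genome_ref"))
  idx <- build_index(genome, k = k)
  summ <- classify_reads(idx, reads, tau = tau)
  if (nrow(summ$multireads) > 0) {
    rows <- locate_matches(idx, summ$multireads, tau_loc = tau_loc)
    summ <- promote_unique(summ, rows)
  } else {
    summ$M <- matrix(0L, 0, length(summ$R),
                     dimnames = list(NULL, names(summ$R)))
  }
  lengths <- genome$replicons$length
  pcn_direct <- direct_pcn(summ$R, lengths)
  fit <- pira_estimate(pcn_direct, summ$M, summ$R, lengths,
                       tol = tol, max_iter = max_iter)
  mapped <- summ$R + round(fit$multiread_alloc)
  filt <- filter_estimates(fit$pcn, mapped, genome$replicons$role,
                           min_reads = min_mapped_reads)
  out <- tibble::tibble(
    genome_id = genome_id,
    replicon_id = genome$replicons$id,
    role = genome$replicons$role,
    length_bp = lengths,
    uniread_count = as.integer(summ$R),
    multiread_alloc = unname(fit$multiread_alloc),
    mapped_reads = as.numeric(mapped),
    pcn_direct = as.numeric(pcn_direct),
    pcn_pira = as.numeric(fit$pcn),
    converged = fit$converged,
    iterations = fit$iterations,
    kept = filt$kept
  )
  attr(out, "filter_report") <- filt$report
  attr(out, "n_unmapped") <- summ$n_unmapped
  out
}
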