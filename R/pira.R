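#' Direct copy-number estimate from uniread coverage
#'
#' The coverage of replicon `j` is its uniread count divided by its
#' length; copy number is coverage relative to the reference (longest)
#' chromosome, which sits at index 1 and is pinned at copy number 1:
#' \deqn{\pi_j = (R_j / L_j) / (R_1 / L_1).}
#' Read length cancels in the ratio and is deliberately absent. The
#' ratio is computed as `(R_j * L_1) / (R_1 * L_j)` so that exactly
#' proportional integer counts give exact answers.
#'
#' @param R integer vector of uniread counts per replicon, reference
#'   first.
#' @param lengths integer vector of replicon lengths in bp, same order.
#' @return Numeric copy-number vector with `values[1] == 1`.
#' @export
direct_pcn <- function(R, lengths) {
  stopifnot(length(R) == length(lengths), all(lengths > 0), all(R >= 0))
  if (R[1] == 0) stop("no chromosomal coverage")
  pcn <- (as.numeric(R) * lengths[1]) / (as.numeric(R[1]) * lengths)
  names(pcn) <- names(R)
  pcn
}

#' Probabilistic iterative read assignment (EM) for copy numbers
#'
#' Allocates true multireads across replicons and re-estimates copy
#' numbers until convergence. Writing `M` for the match matrix (distinct
#' alignment locations of multiread `j` on replicon `k`) and `pi` for the
#' current copy-number vector, each iteration performs
#'
#' * E-step: responsibilities
#'   \eqn{L_{jk} = M_{jk}\pi_k / \sum_{k'} M_{jk'}\pi_{k'}}
#'   (equivalently: weight the columns of `M` by `pi` and normalize each
#'   row to sum to one -- the probabilistic read assignment step);
#' * M-step: \eqn{\pi_k \propto (R_k + \sum_j L_{jk}) / L_k},
#'   renormalized so the reference chromosome keeps copy number 1.
#'
#' This is an EM algorithm for the multinomial read-origin model in
#' which a read is drawn from a genomic location of replicon `k` with
#' probability proportional to \eqn{\pi_k}; the observed-data
#' log-likelihood ([log_likelihood()]) is therefore non-decreasing along
#' the iteration. Convergence is declared when the L1 norm of the change
#' in `pi` falls below `tol`.
#'
#' @param pi0 initial copy-number vector, typically [direct_pcn()] on the
#'   unireads (including promoted multireads).
#' @param M match matrix of true multireads ([promote_unique()]); may
#'   have zero rows, in which case `pi0` is returned unchanged after zero
#'   iterations. Rows must not be all zero.
#' @param R uniread counts per replicon (including promoted reads).
#' @param lengths replicon lengths in bp.
#' @param tol L1 convergence tolerance on the change in `pi`
#'   (default `1e-6`).
#' @param max_iter iteration ceiling (default 1000); hitting it returns
#'   `converged = FALSE` with a warning, never silently.
#' @return A list with `pcn` (converged copy-number vector), `converged`,
#'   `iterations`, `trace` (tibble with `iteration`, `delta`, `loglik`),
#'   `pi_history` (iterations x n matrix of snapshots),
#'   `multiread_alloc` (expected multireads allocated per replicon; sums
#'   to `nrow(M)`) and `responsibilities` (the final `L` matrix).
#' @export
pira_estimate <- function(pi0, M, R, lengths, tol = 1e-6, max_iter = 1000) {
  n <- length(lengths)
  stopifnot(length(pi0) == n, length(R) == n, all(lengths > 0))
  nm <- names(R)
  if (is.null(M) || nrow(M) == 0) {
    return(list(
      pcn = setNames(as.numeric(pi0), nm), converged = TRUE, iterations = 0L,
      trace = tibble::tibble(iteration = integer(), delta = numeric(),
                             loglik = numeric()),
      pi_history = matrix(numeric(), 0, n, dimnames = list(NULL, nm)),
      multiread_alloc = setNames(numeric(n), nm),
      responsibilities = matrix(numeric(), 0, n, dimnames = list(NULL, nm))
    ))
  }
  M <- as.matrix(M)
  stopifnot(ncol(M) == n, all(M >= 0))
  if (any(rowSums(M) == 0)) stop("match matrix has all-zero rows")
  pi <- as.numeric(pi0)
  it <- 0L
  converged <- FALSE
  delta <- loglik <- numeric(0)
  hist <- list()
  L <- NULL
  RD <- numeric(n)
  repeat {
    it <- it + 1L
    W <- sweep(M, 2L, pi, `*`)
    L <- W / rowSums(W)
    RD <- colSums(L)
    num <- (R + RD) / lengths
    pi_new <- num / num[1]
    d <- sum(abs(pi_new - pi))
    pi <- pi_new
    delta[it] <- d
    loglik[it] <- log_likelihood(pi, R, M, lengths)
    hist[[it]] <- pi
    if (d < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  if (!converged)
    warning("PIRA did not converge in ", max_iter,
            " iterations (last L1 step ", format(delta[it]), ")")
  list(
    pcn = setNames(pi, nm), converged = converged, iterations = it,
    trace = tibble::tibble(iteration = seq_len(it), delta = delta,
                           loglik = loglik),
    pi_history = matrix(unlist(hist), nrow = it, byrow = TRUE,
                        dimnames = list(NULL, nm)),
    multiread_alloc = setNames(RD, nm),
    responsibilities = L
  )
}

#' Observed-data log-likelihood of a copy-number vector
#'
#' Under multinomial sampling of reads from genomic locations, a read
#' lands in replicon `k` with probability
#' \eqn{\pi_k L_k / \sum_{k'} \pi_{k'} L_{k'}} (the fraction of cellular
#' DNA contributed by that replicon), and a multiread with `M_jk`
#' candidate locations contributes
#' \eqn{\log(\sum_k M_{jk}\pi_k) - \log(\sum_k \pi_k L_k)}. The constant
#' multinomial coefficient is omitted; it affects no comparison. This is
#' the objective that [pira_estimate()] ascends.
#'
#' @inheritParams pira_estimate
#' @param pi copy-number vector.
#' @return The log-likelihood (up to an additive constant); `-Inf` when
#'   some replicon with zero mass has a nonzero count.
#' @export
log_likelihood <- function(pi, R, M = NULL, lengths) {
  S <- sum(pi * lengths)
  mass <- pi * lengths / S
  if (any(R > 0 & mass == 0)) return(-Inf)
  ll <- sum(R[R > 0] * log(mass[R > 0]))
  if (!is.null(M) && nrow(M) > 0) {
    row_mass <- as.numeric(as.matrix(M) %*% pi) / S
    if (any(row_mass == 0)) return(-Inf)
    ll <- ll + sum(log(row_mass))
  }
  ll
}

#' Drop poorly covered plasmid estimates
#'
#' Plasmid copy-number estimates supported by fewer than `min_reads`
#' mapped reads (unireads plus promoted reads plus the rounded expected
#' multiread allocation) are unreliable and removed; the rule is a strict
#' less-than, so a plasmid with exactly `min_reads` reads is kept.
#' Chromosomes are never dropped.
#'
#' @param pcn copy-number vector (reference first).
#' @param mapped_reads per-replicon mapped-read totals, same order.
#' @param roles character vector of `"chromosome"`/`"plasmid"`.
#' @param min_reads threshold (default 10000).
#' @return List with `kept` (logical vector), `pcn` (the retained
#'   estimates) and `report` (tibble `replicon_id`, `mapped_reads`,
#'   `reason` for each removal).
#' @export
filter_estimates <- function(pcn, mapped_reads, roles, min_reads = 10000) {
  stopifnot(length(pcn) == length(mapped_reads),
            length(pcn) == length(roles))
  drop <- roles == "plasmid" & mapped_reads < min_reads
  ids <- if (!is.null(names(pcn))) names(pcn) else as.character(seq_along(pcn))
  list(
    kept = !drop,
    pcn = pcn[!drop],
    report = tibble::tibble(
      replicon_id = ids[drop],
      mapped_reads = mapped_reads[drop],
      reason = rep("fewer_mapped_reads_than_threshold", sum(drop))
    )
  )
}
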