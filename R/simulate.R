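#' Configuration for the multi-replicon read simulator
#'
#' Describes a synthetic genome -- one chromosome plus plasmids at known
#' copy numbers, optionally carrying mobile elements shared verbatim
#' across replicons -- and a short-read sample drawn from it with read
#' abundance proportional to DNA mass (copy number x length).
#'
#' @param chromosome_length chromosome length in bp (default 200000, a
#'   scaled-down bacterial chromosome).
#' @param plasmids data frame with columns `length` (bp) and `true_pcn`
#'   (positive real copies per chromosome; values below 1 model cells
#'   with more chromosome than plasmid copies).
#' @param shared_elements optional data frame with columns `length`
#'   (bp), `carriers` (list column of replicon indices: 1 = chromosome,
#'   2 = first plasmid, ...) and `copies_per_carrier` (integer). Each
#'   element is one random sequence written verbatim, at non-overlapping
#'   uniform positions, into every carrier -- a transposon that has
#'   jumped between replicons.
#' @param read_length read length in bp (default 150).
#' @param total_reads number of reads to sample; default gives 30x mean
#'   chromosome depth.
#' @param substitution_rate i.i.d. per-base substitution error rate in
#'   `[0, 1)` (default 0; indels are not modeled).
#' @param seed integer seed; the same config always yields byte-identical
#'   output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(chromosome_length = 200000,
                       plasmids = data.frame(length = 20000, true_pcn = 3),
                       shared_elements = NULL,
                       read_length = 150,
                       total_reads = NULL,
                       substitution_rate = 0,
                       seed = 1) {
  stopifnot(chromosome_length >= 1, nrow(plasmids) >= 0,
            all(plasmids$length >= 1), all(plasmids$true_pcn > 0),
            read_length >= 1, substitution_rate >= 0, substitution_rate < 1)
  lens <- c(chromosome_length, plasmids$length)
  if (read_length > min(lens))
    stop("read_length exceeds the shortest replicon")
  if (!is.null(shared_elements)) {
    stopifnot(all(c("length", "carriers", "copies_per_carrier") %in%
                    names(shared_elements)))
    for (i in seq_len(nrow(shared_elements))) {
      carriers <- shared_elements$carriers[[i]]
      stopifnot(all(carriers >= 1), all(carriers <= length(lens)),
                all(shared_elements$length[i] < lens[carriers]))
    }
  }
  if (is.null(total_reads))
    total_reads <- ceiling(30 * chromosome_length / read_length)
  structure(
    list(chromosome_length = chromosome_length, plasmids = plasmids,
         shared_elements = shared_elements, read_length = read_length,
         total_reads = as.integer(total_reads),
         substitution_rate = substitution_rate, seed = as.integer(seed)),
    class = "sim_config"
  )
}

random_sequence <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a multi-replicon genome with shared elements
#'
#' Backbones are i.i.d.-uniform random sequences; each shared element is
#' one random sequence written verbatim into every carrier at
#' non-overlapping uniform positions (`copies_per_carrier` times). At
#' k = 31 the probability of a chance shared k-mer between backbones is
#' negligible, so the planted elements are the only source of
#' multireads. Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return List with `genome` (a [genome_ref()]; the chromosome is the
#'   longest replicon and the reference) and `truth` (list with
#'   `mass_fraction` -- per-replicon DNA mass fractions in genome order
#'   -- `true_pcn`, and `elements`, a tibble of planted coordinates
#'   `element`, `replicon`, `start`, `end`, 1-based inclusive).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  local_seed(config$seed)
  n_pl <- nrow(config$plasmids)
  lens <- c(config$chromosome_length, config$plasmids$length)
  ids <- c("chromosome",
           if (n_pl > 0) sprintf("plasmid_%02d", seq_len(n_pl)))
  roles <- c("chromosome", rep("plasmid", n_pl))
  seqs <- vapply(lens, random_sequence, character(1))
  placed <- lapply(seq_along(lens), function(i) matrix(numeric(), 0, 2))
  coords <- list()
  se <- config$shared_elements
  for (e in seq_len(NROW(se))) {
    elen <- se$length[e]
    eseq <- random_sequence(elen)
    for (r in se$carriers[[e]]) {
      for (cp in seq_len(se$copies_per_carrier[e])) {
        ok <- FALSE
        for (try in 1:1000) {
          start <- sample.int(lens[r] - elen + 1L, 1L)
          end <- start + elen - 1L
          iv <- placed[[r]]
          if (nrow(iv) == 0 || all(end < iv[, 1] | start > iv[, 2])) {
            ok <- TRUE
            break
          }
        }
        if (!ok)
          stop("could not place element ", e, " on replicon ", r,
               " without overlap")
        placed[[r]] <- rbind(placed[[r]], c(start, end))
        substr(seqs[r], start, end) <- eseq
        coords[[length(coords) + 1L]] <-
          tibble::tibble(element = e, replicon = ids[r],
                         start = start, end = end)
      }
    }
  }
  genome <- genome_ref(ids, seqs, roles)
  ord <- match(genome$replicons$id, ids)
  true_pcn <- c(1, config$plasmids$true_pcn)[ord]
  mass <- true_pcn * genome$replicons$length
  truth <- list(
    true_pcn = setNames(true_pcn, genome$replicons$id),
    mass_fraction = setNames(mass / sum(mass), genome$replicons$id),
    elements = if (length(coords)) dplyr::bind_rows(coords)
               else tibble::tibble(element = integer(), replicon = character(),
                                   start = integer(), end = integer())
  )
  list(genome = genome, truth = truth)
}

#' Sample reads from a simulated genome
#'
#' Each read's source replicon is drawn with probability proportional to
#' `true_pcn x length` (its DNA mass fraction -- the quantity the
#' copy-number estimators invert), its start uniform over valid
#' positions, its strand uniform, and substitutions i.i.d. at
#' `substitution_rate`. With `proportional = "exact"` the per-replicon
#' read counts are fixed at the largest-remainder rounding of
#' `total_reads x mass_fraction` instead of being multinomial, giving
#' machine-exact coverage ratios for worked examples.
#'
#' @param genome,truth output of [simulate_genome()].
#' @param config the same [sim_config()].
#' @param proportional `"multinomial"` (default) or `"exact"`.
#' @return A tibble of reads with truth labels: `id`, `sequence`, `mate`
#'   (always `"single"`), `true_replicon`, `true_start` (1-based),
#'   `true_strand` (`"+"`/`"-"`).
#' @export
simulate_reads <- function(genome, truth, config,
                           proportional = c("multinomial", "exact")) {
  stopifnot(inherits(config, "sim_config"), inherits(genome, "genome_ref"))
  proportional <- match.arg(proportional)
  local_seed(config$seed + 1L)
  n <- nrow(genome$replicons)
  rl <- config$read_length
  total <- config$total_reads
  mass <- truth$mass_fraction
  if (proportional == "exact") {
    counts <- floor(total * mass)
    rem <- total - sum(counts)
    if (rem > 0) {
      extra <- order(total * mass - counts, decreasing = TRUE)[seq_len(rem)]
      counts[extra] <- counts[extra] + 1L
    }
    src <- rep.int(seq_len(n), counts)
  } else {
    src <- sample.int(n, total, replace = TRUE, prob = mass)
    counts <- tabulate(src, nbins = n)
  }
  seqs <- character(total)
  starts <- integer(total)
  strand <- ifelse(runif(total) < 0.5, "+", "-")
  # minus-strand reads are substrings of the reverse-complemented
  # replicon: one revcomp per replicon instead of one per read
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(genome$sequences)))
  for (r in seq_len(n)) {
    idx <- which(src == r)
    if (!length(idx)) next
    L <- genome$replicons$length[r]
    s <- sample.int(L - rl + 1L, length(idx), replace = TRUE)
    starts[idx] <- s
    fwd <- strand[idx] == "+"
    seqs[idx[fwd]] <- substring(genome$sequences[r], s[fwd],
                                s[fwd] + rl - 1L)
    if (any(!fwd)) {
      rs <- L - (s[!fwd] + rl - 1L) + 1L
      seqs[idx[!fwd]] <- substring(rc[r], rs, rs + rl - 1L)
    }
  }
  if (config$substitution_rate > 0) {
    nsub <- rbinom(total, rl, config$substitution_rate)
    for (i in which(nsub > 0)) {
      pos <- sample.int(rl, nsub[i])
      ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
      for (p in pos)
        ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
      seqs[i] <- paste(ch, collapse = "")
    }
  }
  tibble::tibble(
    id = sprintf("read_%07d", seq_len(total)),
    sequence = seqs,
    mate = "single",
    true_replicon = genome$replicons$id[src],
    true_start = starts,
    true_strand = strand
  )
}

#' Write simulated reads to FASTQ
#'
#' Qualities are constant (`I`, Q40): the simulator's error model is in
#' the sequence, not the quality string.
#'
#' @param reads tibble from [simulate_reads()].
#' @param path output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  qual <- vapply(nchar(reads$sequence),
                 function(n) strrep("I", n), character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$id, "\n", reads$sequence, "\n+\n", qual), con)
  invisible(path)
}
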