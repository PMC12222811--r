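# Independent oracles used across the suite. None of these call the
# package's own estimation path.

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Damped fixed-point solver for the multiread allocation equations,
# run from several starts (which must agree) to tight tolerance.
oracle_fixed_point <- function(M, R, lengths, alpha = 0.5, tol = 1e-13,
                               max_iter = 500000) {
  n <- length(lengths)
  step <- function(pi) {
    W <- sweep(M, 2, pi, `*`)
    L <- W / rowSums(W)
    num <- (R + colSums(L)) / lengths
    num / num[1]
  }
  solve_from <- function(pi) {
    for (i in seq_len(max_iter)) {
      nxt <- (1 - alpha) * pi + alpha * step(pi)
      if (sum(abs(nxt - pi)) < tol) return(nxt)
      pi <- nxt
    }
    stop("oracle failed to converge")
  }
  sols <- lapply(list(rep(1, n),
                      c(1, rep(0.05, n - 1)),
                      c(1, rep(20, n - 1))),
                 solve_from)
  stopifnot(sum(abs(sols[[2]] - sols[[1]])) < 1e-8,
            sum(abs(sols[[3]] - sols[[1]])) < 1e-8)
  sols[[1]]
}

# Random small PIRA instance: n replicons, m true multireads.
random_instance <- function(n, m) {
  lengths <- sort(sample(2000:200000, n), decreasing = TRUE)
  R <- c(sample(200:2000, 1), sample(0:500, n - 1, replace = TRUE))
  M <- matrix(stats::rpois(m * n, 0.8), m, n)
  bad <- rowSums(M) < 2
  while (any(bad)) {
    M[bad, ] <- matrix(stats::rpois(sum(bad) * n, 0.8), sum(bad), n)
    bad <- rowSums(M) < 2
  }
  list(M = M, R = R, lengths = lengths)
}

# Exact substring-scan read classifier (both strands, all replicons).
naive_classify <- function(genome, read) {
  rc <- revcomp(read)
  hit <- vapply(genome$sequences, function(s) {
    grepl(read, s, fixed = TRUE) || grepl(rc, s, fixed = TRUE)
  }, logical(1))
  reps <- which(hit)
  status <- if (length(reps) == 0) "unmapped"
            else if (length(reps) == 1) "uniread" else "multiread"
  list(status = status, replicons = unname(reps))
}

# Exact 1-D two-cluster K-means by sorted-split enumeration.
kmeans1d_exact <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  sse <- function(v) if (length(v) < 2) 0 else sum((v - mean(v))^2)
  best_s <- 1L
  best <- Inf
  for (s in 1:(n - 1)) {
    cur <- sse(xs[1:s]) + sse(xs[(s + 1):n])
    if (cur < best) { best <- cur; best_s <- s }
  }
  list(sse = best, threshold = xs[best_s],
       assignment = ifelse(x <= xs[best_s], "small", "large"))
}

# Build a genome by planting a given element into random backbones at
# fixed positions (1-based starts); copies per replicon are given as a list of start positions.
planted_genome <- function(backbone_lengths, roles, element, starts_list) {
  seqs <- vapply(backbone_lengths, rand_dna, character(1))
  for (r in seq_along(seqs)) {
    for (s in starts_list[[r]]) {
      substr(seqs[r], s, s + nchar(element) - 1) <- element
    }
  }
  genome_ref(paste0("rep", seq_along(seqs)), seqs, roles)
}
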