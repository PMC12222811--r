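test_that("index enumerates exactly the N-free k-mer windows", {
  set.seed(11)
  s <- rand_dna(10000)
  # punch a few Ns into the sequence
  npos <- sort(sample(100:9900, 5))
  for (p in npos) substr(s, p, p) <- "N"
  g <- genome_ref("chr", s, "chromosome")
  idx <- build_index(g, k = 31)
  st <- index_stats(idx)
  # brute-force count of windows containing no N
  wins <- vapply(1:(10000 - 31 + 1), function(i) {
    !grepl("N", substr(s, i, i + 30), fixed = TRUE)
  }, logical(1))
  expect_equal(st$n_positions, sum(wins))
  expect_equal(st$k, 31)

  # tiny single-replicon case: L - k + 1 occurrences, all color {1}
  g2 <- genome_ref("chr", rand_dna(14), "chromosome")
  idx2 <- build_index(g2, k = 11)
  expect_equal(index_stats(idx2)$n_positions, 4)
  kms <- substring(g2$sequences[[1]], 1:4, 11:14)
  expect_true(all(vapply(kmer_colors(idx2, kms),
                         identical, logical(1), 1L)))
})

test_that("k and replicon length preconditions are enforced", {
  set.seed(12)
  g <- genome_ref(c("chr", "tiny plasmid"), c(rand_dna(100), rand_dna(20)),
                  c("chromosome", "plasmid"))
  expect_error(build_index(g, k = 30), "odd")
  expect_error(build_index(g, k = 9), "odd|\\[11, 31\\]")
  expect_error(build_index(g, k = 31), "tiny")
})

test_that("k-mers inside a shared element carry both colors", {
  cfg <- sim_config(chromosome_length = 20000,
                    plasmids = data.frame(length = 5000, true_pcn = 2),
                    shared_elements = data.frame(
                      length = 2000, carriers = I(list(c(1, 2))),
                      copies_per_carrier = 1L),
                    total_reads = 10, seed = 21)
  sim <- simulate_genome(cfg)
  idx <- build_index(sim$genome, k = 31)
  el <- sim$truth$elements[sim$truth$elements$replicon == "chromosome", ]
  inside <- substring(sim$genome$sequences[["chromosome"]],
                      el$start + c(0, 500, 1000),
                      el$start + c(0, 500, 1000) + 30)
  for (cols in kmer_colors(idx, inside)) expect_equal(cols, c(1L, 2L))
  # a flank k-mer is single-colored
  flank <- substr(sim$genome$sequences[["chromosome"]],
                  el$end + 10, el$end + 40)
  expect_equal(kmer_colors(idx, flank)[[1]], 1L)
})

test_that("classification matches an exact substring-scan oracle", {
  set.seed(13)
  cfg <- sim_config(chromosome_length = 20000,
                    plasmids = data.frame(length = 5000, true_pcn = 2),
                    shared_elements = data.frame(
                      length = 1000, carriers = I(list(c(1, 2))),
                      copies_per_carrier = 1L),
                    total_reads = 300, read_length = 150, seed = 22)
  sim <- simulate_genome(cfg)
  idx <- build_index(sim$genome, k = 31)
  reads <- simulate_reads(sim$genome, sim$truth, cfg)
  asn <- pseudoalign_reads(idx, reads)
  for (i in sample(nrow(reads), 60)) {
    oracle <- naive_classify(sim$genome, reads$sequence[i])
    expect_equal(asn$status[i], oracle$status)
    expect_equal(sort(asn$replicons[[i]]), oracle$replicons)
  }
})

test_that("a junction-straddling read resolves to its carrier by intersection", {
  cfg <- sim_config(chromosome_length = 20000,
                    plasmids = data.frame(length = 5000, true_pcn = 2),
                    shared_elements = data.frame(
                      length = 2000, carriers = I(list(c(1, 2))),
                      copies_per_carrier = 1L),
                    total_reads = 10, seed = 23)
  sim <- simulate_genome(cfg)
  idx <- build_index(sim$genome, k = 31)
  el <- sim$truth$elements[sim$truth$elements$replicon == "plasmid_01", ]
  # read half on the unique plasmid flank, half inside the shared element
  read <- substr(sim$genome$sequences[["plasmid_01"]],
                 el$start - 75, el$start + 74)
  a <- pseudoalign_read(idx, read)
  expect_equal(a$status, "uniread")
  expect_equal(a$replicons[[1]], 2L)
  # read fully inside the element is a multiread
  mid <- substr(sim$genome$sequences[["plasmid_01"]],
                el$start + 500, el$start + 649)
  b <- pseudoalign_read(idx, mid)
  expect_equal(b$status, "multiread")
  expect_equal(b$replicons[[1]], c(1L, 2L))
})

test_that("assignments are invariant to reverse-complementing the reads", {
  set.seed(14)
  cfg <- sim_config(chromosome_length = 15000,
                    plasmids = data.frame(length = 4000, true_pcn = 3),
                    shared_elements = data.frame(
                      length = 1000, carriers = I(list(c(1, 2))),
                      copies_per_carrier = 1L),
                    total_reads = 400, seed = 24)
  sim <- simulate_genome(cfg)
  idx <- build_index(sim$genome, k = 31)
  reads <- simulate_reads(sim$genome, sim$truth, cfg)
  a <- pseudoalign_reads(idx, reads)
  flipped <- reads
  flipped$sequence <- revcomp(reads$sequence)
  b <- pseudoalign_reads(idx, flipped)
  expect_equal(a$status, b$status)
  expect_equal(a$replicons, b$replicons)
})

test_that("classify_reads conserves counts and handles empty input", {
  set.seed(15)
  cfg <- sim_config(chromosome_length = 15000,
                    plasmids = data.frame(length = 4000, true_pcn = 3),
                    shared_elements = data.frame(
                      length = 1000, carriers = I(list(c(1, 2))),
                      copies_per_carrier = 1L),
                    total_reads = 500, substitution_rate = 0.05, seed = 25)
  sim <- simulate_genome(cfg)
  idx <- build_index(sim$genome, k = 31)
  reads <- simulate_reads(sim$genome, sim$truth, cfg)
  s <- classify_reads(idx, reads)
  expect_equal(sum(s$R) + nrow(s$multireads) + s$n_unmapped, s$n_total)
  expect_equal(s$n_total, 500L)

  e <- classify_reads(idx, reads[0, ])
  expect_equal(sum(e$R), 0L)
  expect_equal(e$n_total, 0L)

  # a read shorter than k is unmapped
  short <- pseudoalign_read(idx, substr(reads$sequence[1], 1, 20))
  expect_equal(short$status, "unmapped")
})

test_that("erroneous reads drop out by failing to pseudoalign", {
  set.seed(16)
  base <- sim_config(chromosome_length = 20000,
                     plasmids = data.frame(length = 5000, true_pcn = 2),
                     total_reads = 3000, seed = 26)
  sim <- simulate_genome(base)
  idx <- build_index(sim$genome, k = 31)
  frac_unmapped <- function(rate) {
    cfg <- sim_config(chromosome_length = 20000,
                      plasmids = data.frame(length = 5000, true_pcn = 2),
                      total_reads = 3000, substitution_rate = rate,
                      seed = 26)
    s <- classify_reads(idx, simulate_reads(sim$genome, sim$truth, cfg))
    s$n_unmapped / s$n_total
  }
  expect_equal(frac_unmapped(0), 0)
  # at 10% error most k-mers are destroyed and mapping collapses, though
  # reads keeping one clean k-mer run still align
  expect_gt(frac_unmapped(0.10), 0.4)
  # at 25% error a clean 31-mer run is vanishingly rare
  expect_gte(frac_unmapped(0.25), 0.99)
})
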