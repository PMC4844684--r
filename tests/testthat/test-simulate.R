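test_that("simulations are reproducible under a fixed seed", {
  a <- simulate_null_genomes(n_genomes = 3, n_codons = 2000, seed = 4)
  b <- simulate_null_genomes(n_genomes = 3, n_codons = 2000, seed = 4)
  expect_identical(a, b)
  g1 <- generate_synthetic_genome(
    synthetic_truth(codons_per_gene = 100, n_operons = 4, io_len = 500),
    seed = 6)
  g2 <- generate_synthetic_genome(
    synthetic_truth(codons_per_gene = 100, n_operons = 4, io_len = 500),
    seed = 6)
  expect_identical(g1$genome$sequence, g2$genome$sequence)
})

test_that("null-simulation skews match the exact enumeration at GC = 0.5", {
  set.seed(21)
  n <- 2e5
  idx <- skewsel:::sample_codon_idx(n, rep(0.25, 4))
  counts <- tabulate(idx, 64)
  m <- skewsel:::.class_letter_counts(counts)
  exact <- enumerate_null_skews(0.5)
  for (cls in c("ns", "4s")) {
    at_obs <- (m[cls, "A"] - m[cls, "T"]) / (m[cls, "A"] + m[cls, "T"])
    gc_obs <- (m[cls, "G"] - m[cls, "C"]) / (m[cls, "G"] + m[cls, "C"])
    ex <- exact[exact$site_class == cls, ]
    n_at <- m[cls, "A"] + m[cls, "T"]
    n_gc <- m[cls, "G"] + m[cls, "C"]
    se_at <- 2 * sqrt(((1 + ex$at) / 2) * ((1 - ex$at) / 2) / n_at)
    se_gc <- 2 * sqrt(((1 + ex$gc) / 2) * ((1 - ex$gc) / 2) / n_gc)
    expect_lt(abs(at_obs - ex$at), 3 * se_at)
    expect_lt(abs(gc_obs - ex$gc), 3 * se_gc)
  }
})

test_that("stop-codon rejection preserves the conditional codon distribution", {
  set.seed(22)
  n <- 1e6
  p <- c(0.35, 0.15, 0.15, 0.35)  # AT-rich: highest stop-codon rate
  idx <- skewsel:::sample_codon_idx(n, p)
  counts <- tabulate(idx, 64)
  prob <- apply(skewsel:::CODON_LETTERS(), 1, function(r) {
    prod(p[match(r, c("A", "C", "G", "T"))])
  })
  prob[skewsel:::STOP_IDX()] <- 0
  prob <- prob / sum(prob)
  chi2 <- sum((counts - n * prob)[prob > 0]^2 / (n * prob)[prob > 0])
  expect_gt(pchisq(chi2, df = sum(prob > 0) - 1, lower.tail = FALSE), 0.001)
  expect_equal(sum(counts[skewsel:::STOP_IDX()]), 0)
})

test_that("degenerate frequency vectors are rejected", {
  expect_error(simulate_tradeoff_grid(gc_values = 0.5, skew_values = 1.5,
                                      n_codons = 10, seed = 1),
               "degenerate")
})

test_that("the cost trade-off runs in the right direction", {
  grid <- simulate_tradeoff_grid(gc_values = c(0.3, 0.5, 0.7),
                                 skew_values = c(-0.5, 0, 0.5),
                                 n_codons = 2e4, seed = 23)
  # amino-acid cost decreases with GC at zero skew
  at0 <- grid[grid$at_skew == 0, ]
  expect_true(all(diff(at0$mean_aa_cost[order(at0$gc)]) < 0))
  # and decreases with skew at fixed GC, while nucleotide cost increases
  for (g in unique(grid$gc)) {
    sub <- grid[grid$gc == g, ]
    sub <- sub[order(sub$at_skew), ]
    expect_true(all(diff(sub$mean_aa_cost) < 0))
    expect_true(all(diff(sub$mean_nt_cost) > 0))
  }
  # single-skew modes hold the other pair at zero
  at_only <- simulate_tradeoff_grid(gc_values = 0.5, skew_values = c(-0.4, 0.4),
                                    n_codons = 5000, mode = "AT-only", seed = 2)
  expect_true(all(at_only$gc_skew == 0))
  expect_true(all(at_only$at_skew != 0))
})

test_that("synthetic genomes contain no internal stops and round-trip through files", {
  tr <- synthetic_truth(codons_per_gene = 120, n_operons = 4, io_len = 500)
  sim <- generate_synthetic_genome(tr, genome_id = "rt1", seed = 31)
  counts <- count_sites(sim$genome, extract_interoperonic(sim$genome))
  expect_true(all(counts$a + counts$t + counts$g + counts$c > 0 |
                    counts$site_class == "3s"))

  dir <- withr::local_tempdir()
  write_synthetic_genome(sim, dir)
  g2 <- read_genome(file.path(dir, "rt1.fasta"),
                    gff = file.path(dir, "rt1.gff"),
                    operons = file.path(dir, "rt1_operons.tsv"),
                    origins = file.path(dir, "rt1_origin.tsv"))
  g2 <- rotate_to_origin(g2)
  expect_equal(g2$sequence, sim$genome$sequence)
  counts2 <- count_sites(g2, extract_interoperonic(g2))
  expect_equal(counts2$a, counts$a)
  expect_equal(counts2$c, counts$c)
})

test_that("a null ground truth yields unskewed site classes", {
  tr <- synthetic_truth(mu_io = 0, s_rna = 0, s_aa = 0, f = 0.35,
                        codons_per_gene = 2000, n_operons = 8, io_len = 1000)
  sim <- generate_synthetic_genome(tr, seed = 33)
  sk <- observed_skews(count_sites(sim$genome, extract_interoperonic(sim$genome)))
  est <- sk[sk$site_class %in% c("io", "4s", "ns"), ]
  se <- 1 / sqrt(est$denom)
  expect_true(all(abs(est$skew) < 4 * se))
})

test_that("estimates tighten with site count (consistency of the generator)", {
  sizes <- c(500, 5000)
  err <- vapply(seq_along(sizes), function(i) {
    tr <- synthetic_truth(codons_per_gene = sizes[i], n_operons = 8,
                          io_len = 1000)
    sim <- generate_synthetic_genome(tr, seed = 40 + i)
    sk <- observed_skews(count_sites(sim$genome,
                                     extract_interoperonic(sim$genome)))
    four <- sk[sk$site_class == "4s" & sk$pair == "AT", ]
    mu4 <- invert_mu(four$skew[four$strand == "leading"],
                     four$skew[four$strand == "lagging"])
    abs(mu4 - 1.5 * 0.05)
  }, numeric(1))
  expect_lt(err[2], err[1] + 0.02)
  expect_lt(err[2], 0.03)
})

test_that("f values beyond the generator's attainable range are refused", {
  expect_error(synthetic_truth(f = 0.6), "inconsistent structural")
  expect_error(synthetic_truth(f = c(AT = 0.3, GC = 0.55)), "inconsistent")
})
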