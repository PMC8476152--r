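test_that("Balding-Nichols frequencies have the stated mean and variance", {
  p <- simulate_reference_frequencies(rep(0.3, 10000), fst = 0.012,
                                      n_pops = 1L, seed = 1)[, 1]
  # Beta(mean 0.3, var fst * p * (1 - p))
  se_mean <- sqrt(0.012 * 0.3 * 0.7 / 10000)
  expect_lt(abs(mean(p) - 0.3), 4 * se_mean)
  expect_lt(abs(var(p) / (0.012 * 0.3 * 0.7) - 1), 0.1)
})

test_that("Balding-Nichols collapses to the ancestral frequency as fst -> 0", {
  p_anc <- c(0.1, 0.3, 0.5, 0.9)
  p <- simulate_reference_frequencies(p_anc, fst = 1e-8, n_pops = 3L,
                                      seed = 2)
  expect_true(all(abs(p - p_anc) < 1e-3))
})

test_that("Balding-Nichols rejects out-of-range inputs", {
  expect_error(simulate_reference_frequencies(c(0.2, 1.0), 0.01, 2),
               "strictly in")
  expect_error(simulate_reference_frequencies(0.5, 0, 2), "fst")
  expect_error(simulate_reference_frequencies(0.5, 1, 2), "fst")
  expect_error(simulate_reference_frequencies(c(0.5, NA), 0.01, 2))
})

test_that("two Balding-Nichols populations have Hudson FST near the divergence parameter", {
  p_anc <- with_seed <- NULL
  set.seed(11)
  p_anc <- runif(20000, 0.05, 0.95)
  fr <- simulate_reference_frequencies(p_anc, fst = 0.012, n_pops = 2L,
                                       seed = 11)
  g1 <- simulate_genotypes(fr[, 1], 150, seed = 12)
  g2 <- simulate_genotypes(fr[, 2], 150, seed = 13)
  est <- hudson_fst(colMeans(g1) / 2, colMeans(g2) / 2, n1 = 300, n2 = 300)
  expect_lt(abs(est - 0.012), 0.002)
})

test_that("tracts tile each chromosome exactly with half-open segments", {
  len <- c(chr1 = 120, chr2 = 80)
  tr <- simulate_tracts(10, c(A = 0.6, B = 0.4), len, 40, seed = 3)
  expect_true(all(tr$end_cM > tr$start_cM))
  per_hc <- tr[, .(tot = sum(end_cM - start_cM), first = min(start_cM),
                   last = max(end_cM)),
               by = .(sample, haplotype, chrom)]
  expect_equal(per_hc$tot, unname(len[per_hc$chrom]))
  expect_equal(per_hc$first, rep(0, nrow(per_hc)))
  # no overlaps: sorted starts match previous ends
  data.table::setorder(tr, sample, haplotype, chrom, start_cM)
  gaps <- tr[, .(ok = all(abs(head(end_cM, -1) - tail(start_cM, -1)) <
                            1e-12)),
             by = .(sample, haplotype, chrom)]
  expect_true(all(gaps$ok))
})

test_that("degenerate proportions give one single-ancestry tract per chromosome", {
  tr <- simulate_tracts(5, c(A = 1, B = 0), c(chr1 = 100), 10, seed = 4)
  expect_true(all(tr$ancestry == "A"))
})

test_that("mean tract length approaches 100/g cM", {
  tr <- simulate_tracts(10, c(A = 0.5, B = 0.5), c(chr1 = 100), 2000,
                        seed = 5)
  # interior segments are Exponential(g per Morgan); chromosome-edge
  # censoring shortens the mean slightly, so compare loosely
  expect_lt(abs(mean(tr$end_cM - tr$start_cM) - 10) / 10, 0.15)
})

test_that("breakpoint counts per haplotype are Poisson(g * L)", {
  g <- 10; L <- 100
  tr <- simulate_tracts(g, c(A = 0.5, B = 0.5), c(chr1 = L), 2000, seed = 6)
  nbp <- tr[, .N - 1L, by = .(sample, haplotype)]$V1
  lambda <- g * L / 100
  breaks <- c(-0.5, seq(2.5, 18.5), Inf)
  probs <- diff(ppois(breaks, lambda))
  obs <- table(cut(nbp, breaks))
  gof <- suppressWarnings(chisq.test(as.vector(obs), p = probs))
  expect_gt(gof$p.value, 0.01)
})

test_that("realized ancestry fractions converge to alpha", {
  alpha <- c(A = 0.9, B = 0.1)
  tr <- simulate_tracts(8, alpha, c(chr1 = 200, chr2 = 150), 500, seed = 7)
  tr[, len := end_cM - start_cM]
  fr <- sum(tr[ancestry == "B", len]) / sum(tr$len)
  # binomial SE on the number of independent segments
  n_seg <- nrow(tr)
  expect_lt(abs(fr - 0.1), 3 * sqrt(0.1 * 0.9 / n_seg) * 3)
})

test_that("haplogroup assignment follows founder proportions and sex", {
  freqs <- diag_freqs()
  sex <- rep(c("male", "female"), 50)
  hg <- assign_haplogroups(c(Chinese = 1, Malay = 0, Indian = 0),
                           c(Chinese = 0, Malay = 1, Indian = 0),
                           freqs, sex, seed = 8)
  mt <- hg$haplogroups[system == "MT"]
  expect_equal(nrow(mt), 100L)
  expect_true(all(mt$haplogroup == "M_CHN"))
  yy <- hg$haplogroups[system == "Y"]
  expect_equal(nrow(yy), 50L)
  expect_true(all(yy$haplogroup == "Y_MLY"))

  # all-female cohort: no Y records
  hg_f <- assign_haplogroups(c(Chinese = 0.5, Malay = 0.5, Indian = 0),
                             c(Chinese = 1, Malay = 0, Indian = 0),
                             freqs, rep("female", 30), seed = 9)
  expect_equal(nrow(hg_f$haplogroups[system == "Y"]), 0L)
})

test_that("realized maternal lineage fractions match the founder proportions", {
  freqs <- diag_freqs()
  props <- c(Chinese = 0.87, Malay = 0.12, Indian = 0.01)
  hg <- assign_haplogroups(props, c(Chinese = 1, Malay = 0, Indian = 0),
                           freqs, rep("female", 10000), seed = 10)
  frac <- mean(hg$founders$maternal_ancestry == "Malay")
  expect_lt(abs(frac - 0.12), 3 * sqrt(0.12 * 0.88 / 10000))
})

test_that("sex-linked inheritance arithmetic is exact", {
  expect_equal(expected_x_autosome_fractions(0.12, 0.05),
               c(autosomal = 0.085, X = 0.29 / 3))
  expect_equal(unname(expected_x_autosome_fractions(0.3, 0.3)),
               c(0.3, 0.3))
  expect_equal(unname(expected_x_autosome_fractions(0, 0)), c(0, 0))
  expect_error(expected_x_autosome_fractions(-0.1, 0.5), "\\[0, 1\\]")
})

test_that("seeded cohort simulation is bit-reproducible", {
  cfg <- sim_config(n_samples = 20L, n_snps = 50L, seed = 99L,
                    chrom_lengths = default_chrom_lengths(
                      n_chrom = 2L, total_cM = 300, include_x = TRUE))
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$tracts, b$tracts)
  expect_identical(a$haplogroups, b$haplogroups)
  expect_identical(a$haplotypes$geno, b$haplotypes$geno)
})

test_that("cohort invariants hold: tract coverage, MT for all, Y iff male", {
  cfg <- sim_config(n_samples = 30L, seed = 5L,
                    chrom_lengths = default_chrom_lengths(
                      n_chrom = 3L, total_cM = 400, include_x = TRUE))
  ch <- simulate_cohort(cfg)
  mt <- ch$haplogroups[system == "MT"]
  expect_setequal(mt$sample, names(ch$sample_sex))
  yy <- ch$haplogroups[system == "Y"]
  expect_setequal(yy$sample,
                  names(ch$sample_sex)[ch$sample_sex == "male"])
  # males carry one X haplotype, females two
  x_haps <- unique(ch$tracts[chrom == "X", .(sample, haplotype)])
  nx <- x_haps[, .N, by = sample]
  expect_equal(nx$N,
               unname(ifelse(ch$sample_sex[nx$sample] == "male", 1L, 2L)))
})

test_that("X-chromosome ancestry exceeds autosomal under female-biased admixture", {
  cfg <- sim_config(n_samples = 115L, g = 10, seed = 21L)
  exp_fr <- expected_x_autosome_fractions(0.12, 0.05)
  diffs <- vapply(1:8, function(i) {
    cfg$seed <- 21L + i
    ch <- simulate_cohort(cfg)
    fa <- global_fractions(ch$tracts, "autosomes")
    fx <- global_fractions(ch$tracts, "X")
    mean(fx$frac_Malay, na.rm = TRUE) - mean(fa$frac_Malay, na.rm = TRUE)
  }, numeric(1))
  # direction: X Malay fraction above autosomal in nearly all replicates
  expect_gte(sum(diffs > 0), 7L)
  expect_lt(abs(mean(diffs) - (exp_fr["X"] - exp_fr["autosomal"])), 0.02)
})
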