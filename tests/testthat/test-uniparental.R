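test_that("haplogroup frequency estimation matches count arithmetic", {
  hg <- data.table::data.table(
    sample = sprintf("s%03d", 1:299),
    population = "Chinese",
    system = "Y",
    haplogroup = rep(c("O1", "O2", "C"), c(95, 194, 10)))
  ft <- haplogroup_frequencies(hg, "Y")
  expect_equal(ft$freq["O1", "Chinese"], 95 / 299)
  expect_equal(sum(ft$freq[, "Chinese"]), 1)
  expect_equal(unname(ft$n["Chinese"]), 299)
  # all one haplogroup
  hg2 <- hg[haplogroup == "O1"]
  expect_equal(haplogroup_frequencies(hg2, "Y")$freq["O1", "Chinese"], 1)
  # Laplace pseudocount: counts (0, 10) with 2 haplogroups -> (1/12, 11/12)
  hg3 <- data.table::data.table(sample = sprintf("s%d", 1:10),
                                population = "P", system = "MT",
                                haplogroup = "B")
  hg3b <- rbind(hg3, data.table::data.table(sample = "x", population = "Q",
                                            system = "MT",
                                            haplogroup = "D"))
  ft3 <- haplogroup_frequencies(hg3b, "MT", pseudocount = 1)
  expect_equal(unname(ft3$freq[, "P"]),
               unname(c(B = 11 / 12, D = 1 / 12)[rownames(ft3$freq)]))
  expect_error(haplogroup_frequencies(hg3, "Y"), "empty population")
})

test_that("Bayes posterior reproduces the ancestry-informative haplogroup example", {
  # haplogroup E: common in Malays, rare in Chinese, absent in Indians
  f <- rbind(E = c(Chinese = 0.005, Malay = 0.13, Indian = 0),
             other = c(Chinese = 0.995, Malay = 0.87, Indian = 1))
  post <- posterior_per_haplogroup(f, autosomal_prior())
  expect_equal(unname(post["E", ]), c(0.3896918, 0.6103082, 0),
               tolerance = 1e-6)
  expect_equal(rowSums(post), c(E = 1, other = 1))
})

test_that("posterior degenerates with the prior and flattens to it", {
  f <- diag_freqs()$MT$freq
  post <- posterior_per_haplogroup(f, c(Chinese = 1, Malay = 0, Indian = 0))
  expect_equal(unname(post["M_CHN", ]), c(1, 0, 0))
  # uninformative likelihood: posterior equals prior for every haplogroup
  u <- matrix(1 / 3, 3, 3, dimnames = list(c("a", "b", "c"),
                                           c("Chinese", "Malay", "Indian")))
  prior <- autosomal_prior()
  post_u <- posterior_per_haplogroup(u, prior)
  for (h in rownames(u)) expect_equal(post_u[h, ], prior)
})

test_that("zero-evidence haplogroups are flagged undefined, not zeroed", {
  f <- rbind(A = c(X = 0.5, Y = 0.5), ghost = c(X = 0, Y = 0),
             B = c(X = 0.5, Y = 0.5))
  post <- posterior_per_haplogroup(f, c(X = 0.6, Y = 0.4))
  expect_equal(attr(post, "undefined"), "ghost")
  expect_true(all(is.na(post["ghost", ])))
  expect_warning(
    est <- estimate_contribution(c("A", "ghost", "B"), post),
    NA)  # ghost is in the table, so no "absent" warning...
  expect_equal(est$n_used, 2L)
  expect_equal(est$n_excluded, 1L)
})

test_that("contribution is the sample mean of posteriors", {
  post <- rbind(h1 = c(A = 0.39, B = 0.61, C = 0),
                h2 = c(A = 1, B = 0, C = 0))
  est <- estimate_contribution(c("h1", "h2"), post)
  expect_equal(est$rho, c(A = 0.695, B = 0.305, C = 0))
  expect_equal(sum(est$rho), 1)
  est_all <- estimate_contribution(rep("h2", 5), post)
  expect_equal(est_all$rho, c(A = 1, B = 0, C = 0))
})

test_that("with uninformative tables the contribution equals the prior exactly", {
  u <- matrix(1 / 3, 3, 3, dimnames = list(c("a", "b", "c"),
                                           c("Chinese", "Malay", "Indian")))
  prior <- autosomal_prior()
  post <- posterior_per_haplogroup(u, prior)
  est <- estimate_contribution(c("a", "b", "c", "a"), post)
  expect_equal(est$rho, prior)
})

test_that("contribution interpolates monotonically from evidence to prior", {
  sharp <- diag_freqs()$MT$freq
  u <- matrix(1 / 3, 3, 3, dimnames = dimnames(sharp))
  prior <- autosomal_prior()
  obs <- c(rep("M_CHN", 60), rep("M_MLY", 35), rep("M_IND", 5))
  rho_m <- vapply(seq(0, 1, by = 0.25), function(t) {
    f <- (1 - t) * sharp + t * u
    estimate_contribution(obs, posterior_per_haplogroup(f, prior))$rho["Malay"]
  }, numeric(1))
  # t = 0: realized lineage fraction; t = 1: prior; monotone in between
  expect_equal(unname(rho_m[1]), 0.35)
  expect_equal(unname(rho_m[5]), unname(prior["Malay"]))
  expect_true(all(diff(rho_m) < 0))
})

test_that("diagnostic haplogroups recover realized founder fractions independent of the prior", {
  freqs <- diag_freqs()
  hg <- assign_haplogroups(c(Chinese = 0.7, Malay = 0.25, Indian = 0.05),
                           c(Chinese = 1, Malay = 0, Indian = 0),
                           freqs, rep("female", 300), seed = 61)
  mt <- hg$haplogroups[system == "MT"]
  realized <- prop.table(table(hg$founders$maternal_ancestry))
  for (prior in list(autosomal_prior(),
                     c(Chinese = 1, Malay = 1, Indian = 1) / 3)) {
    est <- estimate_contribution(
      mt$haplogroup, posterior_per_haplogroup(freqs$MT, prior))
    expect_equal(unname(est$rho["Malay"]), unname(realized["Malay"]),
                 tolerance = 1e-12)
  }
})

test_that("resampling intervals and p-values match closed forms", {
  # degenerate posteriors: CI [1, 1], p for the carried ancestry < 1/R
  post1 <- matrix(rep(c(1, 0, 0), 10), 10, byrow = TRUE,
                  dimnames = list(NULL, c("A", "B", "C")))
  rs <- resample_contribution(post1, R = 500, seed = 1)
  expect_equal(unname(rs$ci[, "A"]), c(1, 1))
  expect_equal(unname(rs$p["A"]), 0)
  expect_equal(unname(rs$p_label["A"]), "<0.002")
  expect_equal(unname(rs$p["B"]), 1)

  # single sample, posterior (0.5, 0.5, 0): p_B = P(never drawing B) = 0.5
  post2 <- matrix(c(0.5, 0.5, 0), 1, dimnames = list(NULL, c("A", "B", "C")))
  rs2 <- resample_contribution(post2, R = 2000, seed = 2)
  expect_lt(abs(rs2$p["B"] - 0.5), 3 * sqrt(0.25 / 2000))

  # 100 samples each (0.9, 0.1, 0): p_B = 0.9^100 ~ 2.7e-5, below 1/R
  post3 <- matrix(rep(c(0.9, 0.1, 0), 100), 100, byrow = TRUE,
                  dimnames = list(NULL, c("A", "B", "C")))
  rs3 <- resample_contribution(post3, R = 1000, seed = 3)
  expect_equal(unname(rs3$p["B"]), 0)
  expect_equal(unname(rs3$p_label["B"]), "<0.001")
})

test_that("resampling is deterministic given (inputs, R, seed)", {
  post <- matrix(runif(30), 10, 3)
  post <- post / rowSums(post)
  colnames(post) <- c("A", "B", "C")
  r1 <- resample_contribution(post, R = 200, seed = 7)
  r2 <- resample_contribution(post, R = 200, seed = 7)
  expect_identical(r1$realizations, r2$realizations)
  expect_error(resample_contribution(rbind(post, NA), R = 10), "undefined")
})

test_that("resampling CIs cover the estimator's expectation across replicate cohorts", {
  freqs <- default_haplogroup_freqs()
  props <- c(Chinese = 0.87, Malay = 0.12, Indian = 0.01)
  prior <- autosomal_prior()
  ests <- lapply(1:40, function(i) {
    hg <- assign_haplogroups(props, c(Chinese = 1, Malay = 0, Indian = 0),
                             freqs, rep("female", 150), seed = 2000 + i)
    mt <- hg$haplogroups[system == "MT"]
    estimate_uniparental(mt$haplogroup, freqs$MT, prior, R = 300, seed = i)
  })
  target <- mean(vapply(ests, function(e) e$rho[["Malay"]], numeric(1)))
  covered <- vapply(ests, function(e)
    e$ci["lower", "Malay"] <= target && target <= e$ci["upper", "Malay"],
    logical(1))
  expect_gte(mean(covered), 0.9)
})

test_that("founder sex ratios reproduce the published arithmetic", {
  r <- founder_sex_ratio(c(Chinese = 0.87, Malay = 0.12),
                         c(Chinese = 0.95, Malay = 0.05))
  expect_equal(round(unname(r), 2), c(0.92, 2.40))
  expect_equal(unname(founder_sex_ratio(c(A = 0.3), c(A = 0.3))), 1)
  expect_true(is.na(founder_sex_ratio(c(A = 0.3), c(A = 0))))
})

test_that("haplogroup composition test handles 2x2 and larger tables", {
  t22 <- matrix(c(93, 23, 9, 31), 2, byrow = TRUE)
  res <- haplogroup_composition_test(t22)
  expect_s3_class(res, "htest")
  big <- matrix(c(20, 5, 3, 18, 7, 2, 1, 30, 2), 3)
  r1 <- haplogroup_composition_test(big, B = 2000, seed = 5)
  r2 <- haplogroup_composition_test(big, B = 2000, seed = 5)
  expect_equal(r1$p.value, r2$p.value)
})
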