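#' Ancestry-specific haplogroup frequency table
#'
#' A matrix of conditional haplogroup frequencies P(H | A): rows are
#' haplogroup labels, columns are ancestry labels, each column summing to 1.
#'
#' @param x numeric matrix with haplogroup rownames and ancestry colnames.
#' @param n optional named per-ancestry sample sizes.
#' @return object of class `frequency_table`.
#' @export
frequency_table <- function(x, n = NULL) {
  stopifnot(is.matrix(x), is.numeric(x), !is.null(rownames(x)),
            !is.null(colnames(x)))
  if (any(x < 0)) stop("haplogroup frequencies must be non-negative")
  cs <- colSums(x)
  if (any(abs(cs - 1) > 1e-9))
    stop("frequency columns must sum to 1 (within 1e-9)")
  structure(list(freq = x, n = n), class = "frequency_table")
}

#' @export
print.frequency_table <- function(x, ...) {
  cat(sprintf("Haplogroup frequency table: %d haplogroups x %d ancestries\n",
              nrow(x$freq), ncol(x$freq)))
  print(round(x$freq, 4))
  invisible(x)
}

as_frequency_matrix <- function(x) {
  if (inherits(x, "frequency_table")) x$freq else x
}

#' Estimate haplogroup frequencies P(H | A) from reference samples
#'
#' Counts haplogroups per reference population and converts counts to
#' frequencies, optionally with a Laplace pseudocount:
#' `P(H | A) = (count + pseudocount) / (n_A + pseudocount * n_haplogroups)`.
#'
#' @param haplogroups data.frame/data.table with columns `sample`,
#'   `population`, `system`, `haplogroup`.
#' @param system `"MT"` or `"Y"`.
#' @param populations optional subset/order of populations to use.
#' @param pseudocount non-negative Laplace pseudocount (default 0).
#' @return a [frequency_table()] with per-population sample sizes in `$n`.
#' @export
haplogroup_frequencies <- function(haplogroups, system = c("MT", "Y"),
                                   populations = NULL, pseudocount = 0) {
  system <- match.arg(system)
  dt <- as.data.table(haplogroups)
  stopifnot(all(c("sample", "population", "haplogroup") %in% names(dt)))
  if ("system" %in% names(dt)) {
    sel_system <- dt[["system"]] == system
    dt <- dt[sel_system]
  }
  if (nrow(dt) == 0L) stop("empty population set: no ", system, " records")
  if (is.null(populations)) populations <- sort(unique(dt$population))
  dt <- dt[dt[["population"]] %in% populations]
  haps <- sort(unique(dt$haplogroup))
  counts <- matrix(0, length(haps), length(populations),
                   dimnames = list(haps, populations))
  tab <- dt[, .N, by = .(population, haplogroup)]
  counts[cbind(match(tab$haplogroup, haps),
               match(tab$population, populations))] <- tab$N
  n <- colSums(counts)
  if (any(n == 0))
    stop("empty population(s) for system ", system, ": ",
         paste(populations[n == 0], collapse = ", "))
  freq <- sweep(counts + pseudocount, 2, n + pseudocount * length(haps), "/")
  frequency_table(freq, n = n)
}

#' Posterior ancestry probabilities per haplogroup (Bayes' theorem)
#'
#' For each haplogroup H, `P(A | H) = P(H | A) P(A) / sum_A P(H | A) P(A)`.
#' Haplogroups with zero total evidence (absent from every reference
#' population) get an all-`NA` row and are flagged as undefined rather than
#' silently zeroed.
#'
#' @param freqs a [frequency_table()] (or plain P(H|A) matrix).
#' @param prior named prior vector P(A) over the same ancestries, summing
#'   to 1 (typically autosomal global ancestry fractions).
#' @return matrix P(A | H) with haplogroup rows summing to 1; attribute
#'   `"undefined"` lists haplogroups without evidence.
#' @export
posterior_per_haplogroup <- function(freqs, prior) {
  f <- as_frequency_matrix(freqs)
  check_proportions(prior, "prior")
  if (is.null(names(prior))) names(prior) <- colnames(f)
  if (!all(names(prior) %in% colnames(f)))
    stop("prior names must match frequency-table ancestries")
  f <- f[, names(prior), drop = FALSE]
  num <- sweep(f, 2, prior, "*")
  tot <- rowSums(num)
  post <- num / tot
  undefined <- rownames(f)[tot == 0]
  post[tot == 0, ] <- NA_real_
  attr(post, "undefined") <- undefined
  post
}

#' Mean posterior ancestry contribution over a set of samples
#'
#' The contribution of ancestry A is the average of `P(A | H_i)` over
#' samples i; samples whose haplogroup has an undefined posterior are
#' excluded and counted.
#'
#' @param sample_haplogroups character vector of observed haplogroups (one
#'   per sample).
#' @param posterior matrix from [posterior_per_haplogroup()].
#' @return list with `rho` (named contribution vector summing to 1),
#'   `n_used`, `n_excluded`, and `excluded_haplogroups`.
#' @export
estimate_contribution <- function(sample_haplogroups, posterior) {
  idx <- match(sample_haplogroups, rownames(posterior))
  unknown <- is.na(idx)
  if (any(unknown))
    warning(sum(unknown), " sample(s) carry haplogroups absent from the ",
            "reference table and were excluded")
  rows <- posterior[idx[!unknown], , drop = FALSE]
  defined <- complete.cases(rows)
  rows <- rows[defined, , drop = FALSE]
  if (nrow(rows) == 0L) stop("no samples with a defined posterior")
  rho <- colMeans(rows)
  list(rho = rho, n_used = nrow(rows),
       n_excluded = length(sample_haplogroups) - nrow(rows),
       excluded_haplogroups =
         unique(sample_haplogroups[unknown |
                                     !sample_haplogroups %in%
                                       rownames(posterior)[
                                         complete.cases(posterior)]]))
}

#' Resampling confidence intervals and p-values for ancestry contributions
#'
#' For each of `R` realizations, every sample's founder ancestry is drawn
#' from the categorical distribution with probabilities `P(A | H_i)`; the
#' realization-level contribution is the resulting ancestry proportion. The
#' 95% CI of each contribution is the 2.5/97.5 percentile across
#' realizations, and the p-value for "ancestry A contributed nothing" is the
#' fraction of realizations in which A was never drawn (reported as
#' `"<1/R"` when that fraction is zero).
#'
#' @param sample_posteriors numeric matrix, one row per sample, columns the
#'   ancestries, rows summing to 1 (no undefined rows).
#' @param R number of realizations (default 1000).
#' @param seed optional integer seed.
#' @param level confidence level (default 0.95).
#' @return list with `ci` (2 x ancestries matrix), `p`, `p_label`,
#'   `realizations` (R x ancestries proportions), `R`, `seed`.
#' @export
resample_contribution <- function(sample_posteriors, R = 1000L, seed = NULL,
                                  level = 0.95) {
  stopifnot(is.matrix(sample_posteriors), R >= 2L)
  if (anyNA(sample_posteriors))
    stop("undefined posterior rows must be excluded before resampling")
  n <- nrow(sample_posteriors)
  k <- ncol(sample_posteriors)
  with_seed(seed, {
    # inverse-CDF draw: one uniform per (sample, realization)
    cum <- t(apply(sample_posteriors, 1L, cumsum))
    draws <- matrix(runif(n * R), n, R)
    anc <- matrix(0L, n, R)
    for (j in seq_len(k)) anc <- anc + (draws > cum[, j])
    anc <- anc + 1L  # 1-based ancestry index
    real <- matrix(0, R, k, dimnames = list(NULL,
                                            colnames(sample_posteriors)))
    for (j in seq_len(k)) real[, j] <- colSums(anc == j) / n
    a <- (1 - level) / 2
    ci <- apply(real, 2L, quantile, probs = c(a, 1 - a), names = FALSE)
    rownames(ci) <- c("lower", "upper")
    p <- colMeans(real == 0)
    p_label <- ifelse(p == 0, sprintf("<%g", 1 / R), format(p, digits = 3))
    list(ci = ci, p = p, p_label = p_label, realizations = real,
         R = as.integer(R), seed = seed)
  })
}

#' Bayes haplogroup estimate of maternal or paternal ancestry contributions
#'
#' Convenience pipeline: posterior per haplogroup from reference frequencies
#' and an autosomal prior, mean contribution over study samples, and
#' categorical-resampling confidence intervals and p-values.
#'
#' @param sample_haplogroups observed haplogroups of the study samples (one
#'   per sample; MT for the maternal line or Y for the paternal line).
#' @param freqs reference [frequency_table()] P(H | A).
#' @param prior named prior P(A) (autosomal global ancestry fractions over
#'   the ancestries in the reference table, renormalized).
#' @param R resampling realizations.
#' @param seed optional integer seed.
#' @return object of class `contribution_estimate`: `rho`, `ci`, `p`,
#'   `p_label`, `n_used`, `n_excluded`, `R`, `seed`.
#' @export
estimate_uniparental <- function(sample_haplogroups, freqs, prior,
                                 R = 1000L, seed = NULL) {
  post <- posterior_per_haplogroup(freqs, prior)
  est <- estimate_contribution(sample_haplogroups, post)
  idx <- match(sample_haplogroups, rownames(post))
  rows <- post[idx[!is.na(idx)], , drop = FALSE]
  rows <- rows[complete.cases(rows), , drop = FALSE]
  rs <- resample_contribution(rows, R = R, seed = seed)
  structure(list(rho = est$rho, ci = rs$ci, p = rs$p, p_label = rs$p_label,
                 n_used = est$n_used, n_excluded = est$n_excluded,
                 R = rs$R, seed = seed),
            class = "contribution_estimate")
}

#' @export
print.contribution_estimate <- function(x, ...) {
  cat(sprintf("Ancestry contributions (n = %d used, %d excluded, R = %d)\n",
              x$n_used, x$n_excluded, x$R))
  for (a in names(x$rho))
    cat(sprintf("  %-8s rho = %5.1f%%  95%% CI [%5.1f, %5.1f]  P %s\n",
                a, 100 * x$rho[a], 100 * x$ci["lower", a],
                100 * x$ci["upper", a], x$p_label[a]))
  invisible(x)
}

#' Female-to-male founder contribution ratio per ancestry
#'
#' Assuming equal numbers of male and female founders, the female:male
#' contribution ratio of an ancestry is the ratio of its maternal (MT-based)
#' to paternal (Y-based) contribution estimate.
#'
#' @param maternal,paternal named contribution vectors over the same
#'   ancestries.
#' @return named ratio vector; `NA` where the paternal entry is zero.
#' @examples
#' founder_sex_ratio(c(Chinese = 0.87, Malay = 0.12),
#'                   c(Chinese = 0.95, Malay = 0.05))
#' @export
founder_sex_ratio <- function(maternal, paternal) {
  stopifnot(length(maternal) == length(paternal))
  if (!is.null(names(maternal)) && !is.null(names(paternal)))
    paternal <- paternal[names(maternal)]
  out <- ifelse(paternal > 0, maternal / paternal, NA_real_)
  names(out) <- names(maternal)
  out
}

#' Test equality of haplogroup compositions between two groups
#'
#' Fisher's exact test on a haplogroup x group contingency table, with a
#' Monte-Carlo p-value (fixed seed) for tables larger than 2 x 2.
#'
#' @param counts contingency matrix (haplogroups x groups).
#' @param B Monte-Carlo replicates when the table exceeds 2 x 2.
#' @param seed integer seed for the Monte-Carlo p-value.
#' @return `htest` object from [stats::fisher.test()].
#' @export
haplogroup_composition_test <- function(counts, B = 1e5, seed = 1L) {
  stopifnot(is.matrix(counts))
  if (nrow(counts) <= 2L && ncol(counts) <= 2L)
    return(fisher.test(counts))
  with_seed(seed, fisher.test(counts, simulate.p.value = TRUE, B = B))
}
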