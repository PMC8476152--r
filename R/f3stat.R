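#' Three-population admixture statistic f3(target; A, B)
#'
#' Per SNP the statistic is `(c - a)(c - b)` for target frequency `c` and
#' source frequencies `a`, `b`; the estimate is the mean over SNPs. A
#' significantly negative value indicates the target is admixed between
#' populations related to the two sources. When haploid allele counts for
#' the target are supplied, the finite-sample bias of using the sample
#' frequency is removed by subtracting the unbiased within-target term
#' `c (1 - c) / (n_C - 1)` per SNP (the corrected estimator).
#'
#' @param target_freqs,a_freqs,b_freqs aligned allele-frequency vectors in
#'   `[0, 1]`.
#' @param target_counts optional haploid sample counts for the target (a
#'   scalar or per-SNP vector); enables the corrected estimator.
#' @return list with `per_snp` terms, `estimate` (their mean), `n_snps`,
#'   and `mode` (`"corrected"` or `"uncorrected"`).
#' @examples
#' f3_stat(c(0.5, 0.5, 0.5), c(0.2, 0.5, 0.9), c(0.8, 0.5, 0.1))$estimate
#' @export
f3_stat <- function(target_freqs, a_freqs, b_freqs, target_counts = NULL) {
  n <- length(target_freqs)
  if (length(a_freqs) != n || length(b_freqs) != n)
    stop("frequency vectors must have equal length")
  ok <- is.finite(target_freqs) & is.finite(a_freqs) & is.finite(b_freqs)
  if (!any(ok)) stop("no usable SNPs")
  c_ <- target_freqs[ok]; a <- a_freqs[ok]; b <- b_freqs[ok]
  if (any(c(c_, a, b) < 0 | c(c_, a, b) > 1))
    stop("allele frequencies must lie in [0, 1]")
  terms <- (c_ - a) * (c_ - b)
  mode <- "uncorrected"
  if (!is.null(target_counts)) {
    nc <- rep_len(target_counts, n)[ok]
    if (any(nc < 2)) stop("target haploid counts must be >= 2")
    terms <- terms - c_ * (1 - c_) / (nc - 1)
    mode <- "corrected"
  }
  list(per_snp = terms, estimate = mean(terms), n_snps = length(terms),
       mode = mode)
}

#' Block-jackknife standard error and Z-score for a mean over SNPs
#'
#' SNPs (in genomic order) are cut into `n_blocks` contiguous blocks of
#' near-equal count, any remainder spread one-per-block over the leading
#' blocks. Delete-one-block estimates feed the weighted block jackknife
#' (Busing et al. 1999), which reduces to the classical delete-one jackknife
#' for equal block sizes. The Z-score is `estimate / SE`, `NA` when the SE
#' is zero.
#'
#' @param per_snp_terms numeric vector of per-SNP statistic terms, in
#'   genomic order.
#' @param n_blocks number of contiguous blocks (default 727).
#' @return object of class `f3_result`: `estimate` (jackknife bias-corrected
#'   mean), `se`, `z`, `n_snps`, `n_blocks`, `block_sizes`.
#' @export
block_jackknife <- function(per_snp_terms, n_blocks = 727L) {
  n <- length(per_snp_terms)
  if (n_blocks < 2L) stop("n_blocks must be >= 2")
  if (n_blocks > n) stop("n_blocks exceeds the number of SNPs")
  base <- n %/% n_blocks
  rem <- n %% n_blocks
  sizes <- rep(base, n_blocks) + c(rep(1L, rem), rep(0L, n_blocks - rem))
  block <- rep(seq_len(n_blocks), times = sizes)
  tot <- sum(per_snp_terms)
  bsum <- as.vector(tapply(per_snp_terms, block, sum))
  theta_hat <- tot / n
  theta_minus <- (tot - bsum) / (n - sizes)
  h <- n / sizes
  g <- n_blocks
  theta_jack <- g * theta_hat - sum((1 - sizes / n) * theta_minus)
  tau <- h * theta_hat - (h - 1) * theta_minus
  se2 <- sum((tau - theta_jack)^2 / (h - 1)) / g
  se <- sqrt(max(se2, 0))
  z <- if (se > 0) theta_jack / se else NA_real_
  structure(list(estimate = theta_jack, se = se, z = z, n_snps = n,
                 n_blocks = as.integer(n_blocks), block_sizes = sizes),
            class = "f3_result")
}

#' @export
print.f3_result <- function(x, ...) {
  cat(sprintf("f3 = %.6g  SE = %.6g  Z = %s  (%d SNPs, %d blocks)\n",
              x$estimate, x$se,
              if (is.na(x$z)) "undefined" else sprintf("%.3f", x$z),
              x$n_snps, x$n_blocks))
  invisible(x)
}

#' f3 admixture test with block-jackknife inference
#'
#' @inheritParams f3_stat
#' @inheritParams block_jackknife
#' @return an `f3_result` (see [block_jackknife()]) with the estimator
#'   `mode` attached.
#' @export
f3_test <- function(target_freqs, a_freqs, b_freqs, target_counts = NULL,
                    n_blocks = 727L) {
  f3 <- f3_stat(target_freqs, a_freqs, b_freqs, target_counts)
  out <- block_jackknife(f3$per_snp, n_blocks = n_blocks)
  out$mode <- f3$mode
  out
}

#' Hudson FST between two populations (ratio of averages)
#'
#' Per SNP, the numerator is `(p1 - p2)^2` minus the within-population
#' sampling terms `p(1-p)/(n-1)`, and the denominator is
#' `p1 (1 - p2) + p2 (1 - p1)`; the estimate is the ratio of the SNP-wise
#' sums (the block-robust "ratio of averages" form).
#'
#' @param p1,p2 sample allele-frequency vectors.
#' @param n1,n2 haploid sample sizes (scalars or per-SNP vectors); when
#'   `NULL` the sampling correction is omitted (population frequencies).
#' @return scalar FST estimate.
#' @export
hudson_fst <- function(p1, p2, n1 = NULL, n2 = NULL) {
  stopifnot(length(p1) == length(p2))
  num <- (p1 - p2)^2
  if (!is.null(n1)) num <- num - p1 * (1 - p1) / (rep_len(n1, length(p1)) - 1)
  if (!is.null(n2)) num <- num - p2 * (1 - p2) / (rep_len(n2, length(p2)) - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}
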