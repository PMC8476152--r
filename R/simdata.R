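#' Simulate diverged reference allele frequencies (Balding-Nichols model)
#'
#' Each reference population's allele frequency at a SNP is drawn from a Beta
#' distribution with mean equal to the ancestral frequency `p_anc` and
#' variance `fst * p_anc * (1 - p_anc)`, i.e. the Balding-Nichols model of
#' population divergence parameterized by FST. Two populations simulated this
#' way have expected pairwise Hudson FST equal to `fst`.
#'
#' @param p_anc numeric vector of ancestral allele frequencies, all in (0, 1).
#' @param fst divergence parameter in (0, 1).
#' @param n_pops number of populations to draw.
#' @param seed optional integer seed (substream-safe; see [substream_seed()]).
#' @return numeric matrix of dimension `length(p_anc) x n_pops`; values are
#'   clipped to `[1e-6, 1 - 1e-6]` to avoid degenerate downstream draws.
#' @examples
#' p <- simulate_reference_frequencies(runif(100, 0.05, 0.95), fst = 0.012,
#'                                     n_pops = 2, seed = 1)
#' @export
simulate_reference_frequencies <- function(p_anc, fst, n_pops, seed = NULL) {
  stopifnot(is.numeric(p_anc), length(p_anc) >= 1L, all(is.finite(p_anc)),
            is.numeric(fst), length(fst) == 1L, is.finite(fst),
            n_pops >= 1L)
  if (any(p_anc <= 0 | p_anc >= 1))
    stop("ancestral frequencies must lie strictly in (0, 1)")
  if (fst <= 0 || fst >= 1) stop("fst must lie strictly in (0, 1)")
  shape_tot <- (1 - fst) / fst
  with_seed(seed, {
    m <- length(p_anc)
    out <- matrix(NA_real_, m, n_pops)
    for (k in seq_len(n_pops)) {
      out[, k] <- rbeta(m, shape1 = p_anc * shape_tot,
                        shape2 = (1 - p_anc) * shape_tot)
    }
    pmin(pmax(out, 1e-6), 1 - 1e-6)
  })
}

#' Default autosomal (and X) genetic map for simulations
#'
#' Chromosome lengths proportional to the human sex-averaged genetic map,
#' rescaled so the autosomes total `total_cM`. The default total of 3,500 cM
#' (35 Morgans) is configurable because tract-length normalization depends on
#' the map total.
#'
#' @param n_chrom number of autosomes (prefix of the human proportions).
#' @param total_cM autosomal total in cM after rescaling; `NULL` keeps the
#'   raw human-map values.
#' @param include_x append an X chromosome (scaled with the same factor).
#' @return named numeric vector of chromosome lengths in cM.
#' @export
default_chrom_lengths <- function(n_chrom = 22L, total_cM = 3500,
                                  include_x = FALSE) {
  human <- c(286.3, 268.8, 223.4, 214.6, 204.1, 192.0, 187.2, 168.0, 166.4,
             181.1, 158.2, 174.7, 125.7, 120.8, 141.9, 134.0, 128.5, 117.9,
             107.9, 108.3, 62.8, 74.1)
  x_len <- 180.8
  stopifnot(n_chrom >= 1L, n_chrom <= 22L)
  auto <- human[seq_len(n_chrom)]
  scale <- if (is.null(total_cM)) 1 else total_cM / sum(auto)
  out <- auto * scale
  names(out) <- paste0("chr", seq_len(n_chrom))
  if (include_x) out <- c(out, X = x_len * scale)
  out
}

#' Simulate local-ancestry tracts under a Markov/Poisson recombination model
#'
#' Per haplotype and chromosome, ancestry switch points are laid down as a
#' Poisson process at rate `g` per Morgan (`g` generations since admixture)
#' and the ancestry of each resulting segment is drawn independently from
#' `alpha`. Segments are half-open `[start_cM, end_cM)` and tile each
#' chromosome exactly. This is the tract process whose ancestry-indicator
#' autocovariance decays as `exp(-g * d)` with genetic distance `d` in
#' Morgans, making it internally consistent with [fit_decay()].
#'
#' @param g generations since admixture (positive real).
#' @param alpha named ancestry proportion vector summing to 1.
#' @param chrom_lengths named vector of chromosome lengths in cM.
#' @param n_haplotypes number of haplotypes to simulate.
#' @param seed optional integer seed.
#' @param samples,haplotypes optional per-haplotype sample labels and 0-based
#'   haplotype indices; by default haplotypes are paired into samples
#'   `S0001, S0002, ...` with haplotype indices 0 and 1.
#' @return a `data.table` with columns `sample`, `haplotype`, `chrom`,
#'   `start_cM`, `end_cM`, `ancestry` (a tract set).
#' @export
simulate_tracts <- function(g, alpha, chrom_lengths, n_haplotypes,
                            seed = NULL, samples = NULL, haplotypes = NULL) {
  stopifnot(is.numeric(g), length(g) == 1L, is.finite(g))
  if (g <= 0) stop("g must be positive")
  if (length(chrom_lengths) == 0L) stop("chrom_lengths must be non-empty")
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0))
    stop("chromosome lengths must be positive")
  check_proportions(alpha, "alpha")
  if (is.null(names(alpha))) names(alpha) <- paste0("Anc", seq_along(alpha))
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  if (is.null(samples)) samples <- sprintf("S%04d", (seq_len(n_haplotypes) + 1L) %/% 2L)
  if (is.null(haplotypes)) haplotypes <- (seq_len(n_haplotypes) + 1L) %% 2L
  stopifnot(length(samples) == n_haplotypes, length(haplotypes) == n_haplotypes)

  n_chr <- length(chrom_lengths)
  with_seed(seed, {
    # one group per haplotype x chromosome; Poisson number of breakpoints
    grp_hap <- rep(seq_len(n_haplotypes), each = n_chr)
    grp_chr <- rep(seq_len(n_chr), times = n_haplotypes)
    len <- chrom_lengths[grp_chr]
    nbp <- rpois(length(len), g * len / 100)
    # breakpoint positions, uniform on each chromosome
    bp_grp <- rep(seq_along(nbp), nbp)
    bp_pos <- runif(sum(nbp)) * len[bp_grp]
    dt <- data.table(grp = bp_grp, pos = bp_pos)
    setorder(dt, grp, pos)
    # segment boundaries: 0, sorted breakpoints, chromosome length
    nseg <- nbp + 1L
    seg_grp <- rep(seq_along(nseg), nseg)
    starts <- numeric(sum(nseg))
    ends <- numeric(sum(nseg))
    first <- cumsum(nseg) - nseg + 1L
    last <- cumsum(nseg)
    starts[first] <- 0
    if (nrow(dt)) {
      idx_not_first <- setdiff(seq_len(sum(nseg)), first)
      starts[idx_not_first] <- dt$pos
      idx_not_last <- setdiff(seq_len(sum(nseg)), last)
      ends[idx_not_last] <- dt$pos
    }
    ends[last] <- len
    anc_idx <- sample.int(length(alpha), sum(nseg), replace = TRUE,
                          prob = alpha)
    out <- data.table(
      sample = samples[grp_hap[seg_grp]],
      haplotype = as.integer(haplotypes[grp_hap[seg_grp]]),
      chrom = names(chrom_lengths)[grp_chr[seg_grp]],
      start_cM = starts,
      end_cM = ends,
      ancestry = names(alpha)[anc_idx]
    )
    out[]
  })
}

#' Expected autosomal and X-chromosome ancestry fractions under sex bias
#'
#' Under sex-biased admixture in which an ancestry contributes a fraction
#' `f_m` through females and `f_p` through males, autosomes inherit
#' `(f_m + f_p) / 2` of that ancestry while the X chromosome (two thirds of
#' which resides in females each generation) inherits `(2 f_m + f_p) / 3`.
#'
#' @param f_m maternal (female founder) contribution, in `[0, 1]`.
#' @param f_p paternal (male founder) contribution, in `[0, 1]`.
#' @return named numeric vector `c(autosomal = ..., X = ...)`.
#' @examples
#' expected_x_autosome_fractions(0.12, 0.05)
#' @export
expected_x_autosome_fractions <- function(f_m, f_p) {
  stopifnot(is.numeric(f_m), is.numeric(f_p),
            length(f_m) == 1L, length(f_p) == 1L)
  if (!is.finite(f_m) || !is.finite(f_p) || f_m < 0 || f_m > 1 ||
      f_p < 0 || f_p > 1)
    stop("f_m and f_p must lie in [0, 1]")
  c(autosomal = (f_m + f_p) / 2, X = (2 * f_m + f_p) / 3)
}

#' Default ancestry-specific MT and Y haplogroup frequency tables
#'
#' Plausible haplogroup spectra for the three Asian reference ancestries
#' (Chinese, Malay, Indian), built around the ancestry-informative markers of
#' the system: mitochondrial haplogroup E is common in Malays and nearly
#' absent in Chinese, haplogroup D the reverse; Y haplogroups O1 and O2 have
#' strongly different O1:O2 odds between Chinese and Malays and are nearly
#' absent in Indians. With `diagnostic = TRUE` each ancestry instead emits a
#' private haplogroup (disjoint supports), which makes the Bayes estimator
#' recover realized founder-lineage fractions exactly.
#'
#' @param diagnostic logical; use fully ancestry-diagnostic tables.
#' @return list with elements `MT` and `Y`, each a [frequency_table()].
#' @export
default_haplogroup_freqs <- function(diagnostic = FALSE) {
  anc <- c("Chinese", "Malay", "Indian")
  if (diagnostic) {
    mt <- diag(3)
    rownames(mt) <- c("M_CHN", "M_MLY", "M_IND")
    colnames(mt) <- anc
    y <- diag(3)
    rownames(y) <- c("Y_CHN", "Y_MLY", "Y_IND")
    colnames(y) <- anc
    return(list(MT = frequency_table(mt), Y = frequency_table(y)))
  }
  mt <- rbind(
    B = c(0.200, 0.250, 0.020),
    D = c(0.160, 0.020, 0.010),
    E = c(0.005, 0.130, 0.000),
    F = c(0.180, 0.170, 0.030),
    M = c(0.300, 0.270, 0.600),
    R = c(0.155, 0.160, 0.340)
  )
  colnames(mt) <- anc
  y <- rbind(
    O1  = c(0.290, 0.616, 0.010),
    O2  = c(0.590, 0.152, 0.010),
    O3  = c(0.080, 0.120, 0.020),
    C   = c(0.030, 0.100, 0.020),
    R1a = c(0.005, 0.007, 0.450),
    H   = c(0.005, 0.005, 0.490)
  )
  colnames(y) <- anc
  list(MT = frequency_table(mt), Y = frequency_table(y))
}

#' Assign founder lineages and uniparental haplogroups to a cohort
#'
#' Per sample, the maternal founder ancestry is drawn from `maternal_props`
#' and an MT haplogroup from that ancestry's MT frequency column; males
#' additionally draw a paternal founder ancestry from `paternal_props` and a
#' Y haplogroup from that ancestry's Y column. Founder lineages are recorded
#' as simulation truth.
#'
#' @param maternal_props,paternal_props named founder ancestry proportion
#'   vectors, each summing to 1.
#' @param haplogroup_freqs list with `MT` and `Y` [frequency_table()]s whose
#'   ancestry columns cover the names of the proportion vectors.
#' @param sample_sex character vector of `"male"` / `"female"` labels; names
#'   (if any) are used as sample ids.
#' @param seed optional integer seed.
#' @return list with `haplogroups` (data.table: `sample`, `sex`, `system`,
#'   `haplogroup`) and `founders` (data.table: `sample`, `maternal_ancestry`,
#'   `paternal_ancestry`; paternal is `NA` for females).
#' @export
assign_haplogroups <- function(maternal_props, paternal_props,
                               haplogroup_freqs, sample_sex, seed = NULL) {
  check_proportions(maternal_props, "maternal_props")
  check_proportions(paternal_props, "paternal_props")
  stopifnot(all(sample_sex %in% c("male", "female")))
  ids <- names(sample_sex)
  if (is.null(ids)) ids <- sprintf("S%04d", seq_along(sample_sex))
  mt <- as_frequency_matrix(haplogroup_freqs$MT)
  yt <- as_frequency_matrix(haplogroup_freqs$Y)
  for (a in names(maternal_props))
    if (!a %in% colnames(mt)) stop("no MT haplogroup table for ancestry ", a)
  for (a in names(paternal_props))
    if (!a %in% colnames(yt)) stop("no Y haplogroup table for ancestry ", a)

  with_seed(seed, {
    n <- length(sample_sex)
    mat_anc <- names(maternal_props)[
      sample.int(length(maternal_props), n, replace = TRUE,
                 prob = maternal_props)]
    mt_hap <- vapply(mat_anc, function(a) {
      rownames(mt)[sample.int(nrow(mt), 1L, prob = mt[, a])]
    }, character(1L))
    males <- sample_sex == "male"
    pat_anc <- rep(NA_character_, n)
    y_hap <- rep(NA_character_, n)
    if (any(males)) {
      pat_anc[males] <- names(paternal_props)[
        sample.int(length(paternal_props), sum(males), replace = TRUE,
                   prob = paternal_props)]
      y_hap[males] <- vapply(pat_anc[males], function(a) {
        rownames(yt)[sample.int(nrow(yt), 1L, prob = yt[, a])]
      }, character(1L))
    }
    haps <- rbind(
      data.table(sample = ids, sex = unname(sample_sex), system = "MT",
                 haplogroup = unname(mt_hap)),
      data.table(sample = ids[males], sex = "male", system = "Y",
                 haplogroup = unname(y_hap[males]))
    )
    founders <- data.table(sample = ids,
                           maternal_ancestry = unname(mat_anc),
                           paternal_ancestry = unname(pat_anc))
    list(haplogroups = haps[], founders = founders[])
  })
}

#' Simulation configuration for a synthetic admixed cohort
#'
#' Bundles and validates all parameters of the synthetic-cohort generator.
#' Defaults describe the study conditions the package targets: two-way
#' Chinese-Malay admixture with a small Indian founder component, FST 0.012
#' between the major source populations, admixture 6.55 generations before
#' present (190 years at 29 years per generation), and sex-biased founder
#' proportions (maternal Chinese/Malay/Indian 0.87/0.12/0.01, paternal
#' 0.95/0.05/0).
#'
#' @param n_pops number of reference populations for genotype simulation.
#' @param fst Balding-Nichols divergence parameter, in (0, 1).
#' @param n_snps number of SNPs to simulate (0 skips genotypes).
#' @param chrom_lengths named chromosome lengths in cM (autosomes; an entry
#'   named `"X"` is treated as the X chromosome).
#' @param g generations since admixture.
#' @param alpha autosomal ancestry proportions; defaults to the mean of the
#'   maternal and paternal founder proportions.
#' @param maternal_props,paternal_props founder ancestry proportions through
#'   the female and male line.
#' @param haplogroup_freqs list of MT and Y [frequency_table()]s.
#' @param n_samples cohort size.
#' @param sex_ratio fraction of males.
#' @param seed global integer seed; stages draw from named substreams.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_pops = 3L,
                       fst = 0.012,
                       n_snps = 0L,
                       chrom_lengths = default_chrom_lengths(total_cM = 3500,
                                                             include_x = TRUE),
                       g = 6.55,
                       maternal_props = c(Chinese = 0.87, Malay = 0.12,
                                          Indian = 0.01),
                       paternal_props = c(Chinese = 0.95, Malay = 0.05,
                                          Indian = 0.00),
                       alpha = (maternal_props + paternal_props) / 2,
                       haplogroup_freqs = default_haplogroup_freqs(),
                       n_samples = 115L,
                       sex_ratio = 0.35,
                       seed = 1L) {
  check_proportions(alpha, "alpha")
  check_proportions(maternal_props, "maternal_props")
  check_proportions(paternal_props, "paternal_props")
  if (fst <= 0 || fst >= 1) stop("fst must lie strictly in (0, 1)")
  if (g <= 0) stop("g must be positive")
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  if (sex_ratio < 0 || sex_ratio > 1) stop("sex_ratio must lie in [0, 1]")
  stopifnot(n_samples >= 1L, n_pops >= 1L, n_snps >= 0L)
  structure(list(
    n_pops = as.integer(n_pops), fst = fst, n_snps = as.integer(n_snps),
    chrom_lengths = chrom_lengths,
    map_length = sum(chrom_lengths[names(chrom_lengths) != "X"]) / 100,
    g = g, alpha = alpha,
    maternal_props = maternal_props, paternal_props = paternal_props,
    haplogroup_freqs = haplogroup_freqs,
    n_samples = as.integer(n_samples), sex_ratio = sex_ratio,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic-cohort configuration\n")
  cat(sprintf("  samples: %d (sex ratio %.2f male), seed %d\n",
              x$n_samples, x$sex_ratio, x$seed))
  cat(sprintf("  admixture: g = %.3g generations; alpha = %s\n", x$g,
              paste(sprintf("%s %.3g", names(x$alpha), x$alpha),
                    collapse = ", ")))
  cat(sprintf("  map: %d chromosomes, %.1f cM autosomal total\n",
              length(x$chrom_lengths), 100 * x$map_length))
  cat(sprintf("  genotypes: %d SNPs, %d populations at FST %.4g\n",
              x$n_snps, x$n_pops, x$fst))
  invisible(x)
}

#' Simulate a full synthetic admixed cohort
#'
#' Generates, from one [sim_config()]: per-sample sex; maternal/paternal
#' founder lineages with MT/Y haplogroups; autosomal local-ancestry tracts
#' (two haplotypes per sample, segment ancestries from `alpha`); X-chromosome
#' tracts (two haplotypes for females, one for males) with ancestry
#' proportions `(2 * maternal + paternal) / 3`; and, when `n_snps > 0`,
#' phased haplotype genotypes whose alleles are drawn from Balding-Nichols
#' population frequencies according to the local ancestry at each SNP.
#'
#' All randomness derives from `config$seed` through named substreams, so
#' repeated calls are bit-reproducible.
#'
#' @param config a [sim_config()].
#' @return object of class `simulated_cohort`: list with `tracts`,
#'   `haplogroups`, `founders`, `sample_sex`, `haplotypes` (or `NULL`),
#'   `pop_freqs`, and the `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ids <- sprintf("P%04d", seq_len(config$n_samples))
  n_male <- round(config$n_samples * config$sex_ratio)
  sex <- with_seed(substream_seed(config$seed, "sex"), {
    s <- rep("female", config$n_samples)
    s[sample.int(config$n_samples, n_male)] <- "male"
    s
  })
  names(sex) <- ids

  hg <- assign_haplogroups(config$maternal_props, config$paternal_props,
                           config$haplogroup_freqs, sex,
                           seed = substream_seed(config$seed, "haplogroups"))

  auto_len <- config$chrom_lengths[names(config$chrom_lengths) != "X"]
  tracts <- simulate_tracts(
    config$g, config$alpha, auto_len, 2L * config$n_samples,
    seed = substream_seed(config$seed, "tracts"),
    samples = rep(ids, each = 2L),
    haplotypes = rep(0:1, config$n_samples))

  if ("X" %in% names(config$chrom_lengths)) {
    alpha_x <- (2 * config$maternal_props + config$paternal_props) / 3
    n_x_hap <- ifelse(sex == "male", 1L, 2L)
    x_samples <- rep(ids, n_x_hap)
    x_hapidx <- unlist(lapply(n_x_hap, function(k) seq_len(k) - 1L))
    x_tracts <- simulate_tracts(
      config$g, alpha_x, config$chrom_lengths["X"], length(x_samples),
      seed = substream_seed(config$seed, "tracts_x"),
      samples = x_samples, haplotypes = x_hapidx)
    tracts <- rbind(tracts, x_tracts)
  }

  haplotypes <- NULL
  pop_freqs <- NULL
  if (config$n_snps > 0L) {
    seed_f <- substream_seed(config$seed, "frequencies")
    seed_g <- substream_seed(config$seed, "genotypes")
    p_anc <- with_seed(seed_f, runif(config$n_snps, 0.05, 0.95))
    pop_freqs <- simulate_reference_frequencies(
      p_anc, config$fst, config$n_pops, seed = seed_f + 1L)
    colnames(pop_freqs) <- names(config$alpha)[seq_len(config$n_pops)]
    haplotypes <- simulate_admixed_haplotypes(
      tracts, pop_freqs, auto_len, seed = seed_g)
  }

  structure(list(tracts = tracts, haplogroups = hg$haplogroups,
                 founders = hg$founders, sample_sex = sex,
                 haplotypes = haplotypes, pop_freqs = pop_freqs,
                 config = config),
            class = "simulated_cohort")
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf("Simulated cohort: %d samples (%d male), %d tract records\n",
              x$config$n_samples, sum(x$sample_sex == "male"),
              nrow(x$tracts)))
  if (!is.null(x$haplotypes))
    cat(sprintf("  haplotypes: %d SNPs x %d haplotypes\n",
                nrow(x$haplotypes$geno), ncol(x$haplotypes$geno)))
  invisible(x)
}

#' Draw phased haplotype alleles conditional on local-ancestry tracts
#'
#' SNPs are placed uniformly along the autosomes (1 cM per Mb map) and each
#' haplotype's allele at a SNP is Bernoulli with the allele frequency of the
#' population matching the tract ancestry covering that position. Ancestries
#' without a frequency column fall back to the first column.
#'
#' @param tracts tract table (autosomal rows are used).
#' @param pop_freqs SNP x population frequency matrix with ancestry colnames.
#' @param chrom_lengths named autosomal lengths in cM.
#' @param seed optional integer seed.
#' @return a `haplotype_matrix`: list with `geno` (0/1 matrix, SNPs x
#'   haplotypes), `variants` (data.table: `chrom`, `pos_bp`, `cM`, `id`,
#'   `ref`, `alt`), `samples`, `haplotype` index vector.
#' @export
simulate_admixed_haplotypes <- function(tracts, pop_freqs, chrom_lengths,
                                        seed = NULL) {
  n_snps <- nrow(pop_freqs)
  stopifnot(n_snps >= 1L)
  with_seed(seed, {
    # SNP placement proportional to genetic length
    chr_idx <- sample.int(length(chrom_lengths), n_snps, replace = TRUE,
                          prob = chrom_lengths)
    cm <- runif(n_snps) * chrom_lengths[chr_idx]
    ord <- order(chr_idx, cm)
    chr_idx <- chr_idx[ord]; cm <- cm[ord]
    variants <- data.table(
      chrom = names(chrom_lengths)[chr_idx],
      pos_bp = as.integer(round(cm * 1e6) + 1),
      cM = cm,
      id = sprintf("snp%06d", seq_len(n_snps)),
      ref = "A", alt = "G")

    tr <- as.data.table(tracts)[chrom %in% names(chrom_lengths)]
    setorder(tr, sample, haplotype, chrom, start_cM)
    key <- unique(tr[, .(sample, haplotype)])
    n_hap <- nrow(key)
    geno <- matrix(0L, n_snps, n_hap)
    anc_names <- colnames(pop_freqs)
    for (h in seq_len(n_hap)) {
      th <- tr[key[h], on = c("sample", "haplotype")]
      anc_at <- character(n_snps)
      for (cn in unique(th$chrom)) {
        rows <- which(variants$chrom == cn)
        tc <- th[chrom == cn]
        seg <- findInterval(variants$cM[rows], tc$start_cM)
        anc_at[rows] <- tc$ancestry[pmax(seg, 1L)]
      }
      col <- match(anc_at, anc_names)
      col[is.na(col)] <- 1L
      pvec <- pop_freqs[cbind(seq_len(n_snps), col)]
      geno[, h] <- rbinom(n_snps, 1L, pvec)
    }
    structure(list(geno = geno, variants = variants,
                   samples = key$sample, haplotype = key$haplotype),
              class = "haplotype_matrix")
  })
}

#' Draw diploid genotype dosages from population allele frequencies
#'
#' @param freqs numeric vector of allele frequencies (one population).
#' @param n number of diploid individuals.
#' @param seed optional integer seed.
#' @return integer matrix `n x length(freqs)` of dosages in 0..2.
#' @export
simulate_genotypes <- function(freqs, n, seed = NULL) {
  with_seed(seed, {
    m <- length(freqs)
    matrix(rbinom(n * m, 2L, rep(freqs, each = n)), nrow = n)
  })
}

check_proportions <- function(p, what) {
  if (!is.numeric(p) || length(p) < 1L || any(!is.finite(p)) || any(p < 0))
    stop(what, " must be a non-negative numeric vector")
  if (abs(sum(p) - 1) > 1e-12)
    stop(what, " must sum to 1 (within 1e-12); got ", format(sum(p)))
  invisible(TRUE)
}
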