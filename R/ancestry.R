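#' Mask low-confidence local-ancestry windows
#'
#' Windows (tract records) carrying a posterior probability vector are
#' relabelled with the argmax ancestry when the maximum posterior exceeds
#' `threshold`, and set to `"Unknown"` otherwise. Ties in the argmax are
#' broken by the fixed order of the posterior columns.
#'
#' @param tracts tract table with posterior columns named `p_<ancestry>`.
#' @param threshold posterior needed to accept a call (default 0.9; windows
#'   with max posterior `<= threshold` become Unknown).
#' @return the tract table with an updated `ancestry` column.
#' @export
mask_low_posterior <- function(tracts, threshold = 0.9) {
  dt <- as.data.table(tracts)
  pcols <- grep("^p_", names(dt), value = TRUE)
  if (length(pcols) == 0L) stop("no posterior columns (p_<ancestry>) found")
  post <- as.matrix(dt[, pcols, with = FALSE])
  bad <- abs(rowSums(post) - 1) > 1e-6
  if (any(bad))
    stop(sum(bad), " window(s) have posterior vectors not summing to 1")
  anc_names <- sub("^p_", "", pcols)
  best <- max.col(post, ties.method = "first")
  lab <- anc_names[best]
  lab[post[cbind(seq_len(nrow(post)), best)] <= threshold] <- "Unknown"
  dt[, ancestry := lab]
  dt[]
}

#' Length-weighted global ancestry fractions from local-ancestry tracts
#'
#' Per sample, the fraction of each ancestry is the total genetic length
#' (cM) of its tracts over both haplotypes divided by the total length of
#' all tracts of known ancestry; `"Unknown"` tracts are excluded from the
#' denominator. Samples with zero known-ancestry length get `NA` fractions
#' and are flagged, not silently zeroed.
#'
#' @param tracts tract table (`sample`, `haplotype`, `chrom`, `start_cM`,
#'   `end_cM`, `ancestry`).
#' @param chrom_set `"autosomes"` (every chromosome except `"X"`), `"X"`, or
#'   a character vector of chromosome names.
#' @param ancestries optional ancestry label order for the output columns;
#'   defaults to the sorted labels present.
#' @return data.table: one row per sample with a `frac_<ancestry>` column
#'   per ancestry, `unknown_cM`, `known_cM`.
#' @export
global_fractions <- function(tracts, chrom_set = "autosomes",
                             ancestries = NULL) {
  dt <- as.data.table(tracts)
  stopifnot(all(c("sample", "chrom", "start_cM", "end_cM", "ancestry")
                %in% names(dt)))
  if (any(dt$end_cM <= dt$start_cM)) stop("tracts must have end_cM > start_cM")
  keep <- if (identical(chrom_set, "autosomes")) {
    dt$chrom != "X"
  } else if (identical(chrom_set, "X")) {
    dt$chrom == "X"
  } else dt$chrom %in% chrom_set
  dt <- dt[keep]
  if (nrow(dt) == 0L) stop("no tracts on the requested chromosome set")
  dt[, length_cM := end_cM - start_cM]
  if (is.null(ancestries))
    ancestries <- setdiff(sort(unique(dt$ancestry)), "Unknown")
  tot <- dt[, .(total_cM = sum(length_cM),
                unknown_cM = sum(length_cM[ancestry == "Unknown"])),
            by = sample]
  known <- dt[ancestry != "Unknown",
              .(len = sum(length_cM)), by = .(sample, ancestry)]
  out <- tot[, .(sample, unknown_cM, known_cM = total_cM - unknown_cM)]
  for (a in ancestries) {
    la <- known[ancestry == a][out, on = "sample"]
    v <- ifelse(out$known_cM > 0, ifelse(is.na(la$len), 0, la$len) /
                  out$known_cM, NA_real_)
    out[, (paste0("frac_", a)) := v]
  }
  if (any(out$known_cM == 0))
    warning(sum(out$known_cM == 0),
            " sample(s) have zero known-ancestry length; fractions are NA")
  setorder(out, sample)
  out[]
}

#' Compare ancestry fractions (or any per-sample quantity) between groups
#'
#' The group comparisons used for Table-1-style summaries: Welch's t-test,
#' paired Welch (paired t-test on matched samples), Spearman rank
#' correlation, or Fisher's exact test on a composition table. Per-group
#' means carry t-based 95% confidence intervals.
#'
#' @param x,y numeric vectors (per-sample values for the two groups), or a
#'   contingency matrix in `x` for `mode = "fisher_composition"`.
#' @param mode one of `"welch"`, `"paired_welch"`, `"spearman"`,
#'   `"fisher_composition"`.
#' @param ids_x,ids_y optional sample ids used to align pairs in paired
#'   mode (mismatched ids are an error).
#' @param conf_level confidence level for group-mean CIs.
#' @return list with `statistic`, `p_value`, `estimate`, and (for the
#'   two-sample modes) `group_means` with per-group CI.
#' @export
compare_groups <- function(x, y = NULL,
                           mode = c("welch", "paired_welch", "spearman",
                                    "fisher_composition"),
                           ids_x = NULL, ids_y = NULL, conf_level = 0.95) {
  mode <- match.arg(mode)
  if (mode == "fisher_composition") {
    ht <- haplogroup_composition_test(x)
    return(list(statistic = unname(ht$estimate), p_value = ht$p.value,
                estimate = unname(ht$estimate), test = ht))
  }
  stopifnot(is.numeric(x), is.numeric(y), length(x) > 0, length(y) > 0)
  if (mode == "paired_welch") {
    if (!is.null(ids_x) || !is.null(ids_y)) {
      if (is.null(ids_x) || is.null(ids_y))
        stop("both ids_x and ids_y are required to align pairs")
      if (!setequal(ids_x, ids_y))
        stop("paired mode requires matched sample ids")
      y <- y[match(ids_x, ids_y)]
    } else if (length(x) != length(y)) {
      stop("paired mode requires equal-length (matched) vectors")
    }
    ht <- t.test(x, y, paired = TRUE, conf.level = conf_level)
  } else if (mode == "welch") {
    ht <- t.test(x, y, conf.level = conf_level)
  } else {
    ht <- suppressWarnings(cor.test(x, y, method = "spearman"))
  }
  mean_ci <- function(v) {
    m <- mean(v); s <- sd(v) / sqrt(length(v))
    q <- qt(1 - (1 - conf_level) / 2, df = length(v) - 1)
    c(mean = m, lower = m - q * s, upper = m + q * s)
  }
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       estimate = unname(ht$estimate),
       group_means = rbind(x = mean_ci(x), y = mean_ci(y)),
       test = ht)
}
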