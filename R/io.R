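#' Write a minimal phased VCF from a haplotype matrix
#'
#' Emits a VCFv4.2 file with CHROM, POS, ID, REF, ALT and phased GT fields.
#' Samples with two haplotypes are written as `a|b`; samples with a single
#' haplotype (male X) are written as homozygous diploid `a|a`, matching the
#' convention of coding male X genotypes as homozygotes.
#'
#' @param hapmat a `haplotype_matrix` (see [simulate_admixed_haplotypes()]).
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf_minimal <- function(hapmat, path) {
  v <- hapmat$variants
  ids <- unique(hapmat$samples)
  gt_cols <- vapply(ids, function(s) {
    cols <- which(hapmat$samples == s)
    if (length(cols) == 1L) {
      a <- hapmat$geno[, cols]
      paste0(a, "|", a)
    } else {
      paste0(hapmat$geno[, cols[1]], "|", hapmat$geno[, cols[2]])
    }
  }, character(nrow(v)))
  header <- c("##fileformat=VCFv4.2",
              "##source=straitsadmix",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", ids), collapse = "\t"))
  body <- paste(v$chrom, v$pos_bp, v$id, v$ref, v$alt, ".", "PASS", ".",
                "GT", apply(gt_cols, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a minimal phased VCF into a haplotype matrix
#'
#' Reads a VCF through `vcfR` and keeps bi-allelic SNP records with phased
#' genotypes. Multi-allelic records and indels are skipped with counts
#' recorded in the `skipped` attribute. Haploid GT fields (male X calls) are
#' expanded to two identical alleles (homozygous-diploid convention);
#' unphased diploid genotypes are an error when `require_phased` is `TRUE`.
#'
#' @param path VCF path.
#' @param require_phased error on `/`-separated genotypes (default `TRUE`).
#' @return a `haplotype_matrix` with attribute `skipped` (named counts of
#'   multi-allelic and indel records).
#' @export
read_vcf_minimal <- function(path, require_phased = TRUE) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(fix)  # single-record VCF
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  multi <- grepl(",", alt, fixed = TRUE)
  indel <- !multi & (nchar(ref) > 1L | nchar(alt) > 1L)
  keep <- !multi & !indel
  skipped <- c(multiallelic = sum(multi), indel = sum(indel))
  if (!any(keep)) stop("no usable bi-allelic SNP records")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  if (require_phased && any(grepl("/", gt, fixed = TRUE)))
    stop("unphased genotypes present but phased haplotypes required")
  ids <- colnames(gt)
  hap_list <- list()
  samples <- character(0)
  hapidx <- integer(0)
  for (s in ids) {
    parts <- data.table::tstrsplit(gt[, s], "|", fixed = TRUE)
    if (length(parts) == 1L) parts <- c(parts, parts)  # haploid -> homozygous
    for (j in 1:2) {
      hap_list[[length(hap_list) + 1L]] <- as.integer(parts[[j]])
      samples <- c(samples, s)
      hapidx <- c(hapidx, j - 1L)
    }
  }
  geno <- do.call(cbind, hap_list)
  variants <- data.table(chrom = fix[, "CHROM"],
                         pos_bp = as.integer(fix[, "POS"]),
                         id = fix[, "ID"], ref = fix[, "REF"],
                         alt = fix[, "ALT"])
  out <- structure(list(geno = geno, variants = variants, samples = samples,
                        haplotype = hapidx),
                   class = "haplotype_matrix")
  attr(out, "skipped") <- skipped
  out
}

#' Collapse a haplotype matrix to diploid dosages
#'
#' @param hapmat a `haplotype_matrix`.
#' @return integer matrix, samples x variants (rownames are sample ids).
#' @export
haplotypes_to_dosage <- function(hapmat) {
  ids <- unique(hapmat$samples)
  out <- vapply(ids, function(s) {
    cols <- which(hapmat$samples == s)
    if (length(cols) == 1L) 2L * hapmat$geno[, cols]
    else hapmat$geno[, cols[1]] + hapmat$geno[, cols[2]]
  }, integer(nrow(hapmat$geno)))
  t(out)
}

#' Write / read tract tables (RFMix-style TSV)
#'
#' Tab-separated with header: `sample`, `haplotype` (0/1), `chrom`,
#' `start_cM`, `end_cM`, `ancestry`, plus any posterior columns
#' (`p_<ancestry>`) and a `posterior` column when present. Round-trip
#' stable.
#'
#' @param tracts tract table.
#' @param path TSV path.
#' @return `path` invisibly; `read_tracts()` returns a `data.table`.
#' @export
write_tracts <- function(tracts, path) {
  fwrite(as.data.table(tracts), path, sep = "\t")
  invisible(path)
}

#' @rdname write_tracts
#' @export
read_tracts <- function(path) {
  dt <- fread(path, sep = "\t")
  need <- c("sample", "haplotype", "chrom", "start_cM", "end_cM")
  if (!all(need %in% names(dt)))
    stop("tract TSV must contain columns: ", paste(need, collapse = ", "))
  dt
}

#' Write / read per-sample haplogroup tables (TSV)
#'
#' Columns: `sample`, `sex`, `system` (MT/Y), `haplogroup`, and optionally
#' `population`.
#'
#' @param haplogroups haplogroup table.
#' @param path TSV path.
#' @return `path` invisibly; `read_haplogroups()` returns a `data.table`.
#' @export
write_haplogroups <- function(haplogroups, path) {
  fwrite(as.data.table(haplogroups), path, sep = "\t")
  invisible(path)
}

#' @rdname write_haplogroups
#' @export
read_haplogroups <- function(path) {
  dt <- fread(path, sep = "\t")
  need <- c("sample", "system", "haplogroup")
  if (!all(need %in% names(dt)))
    stop("haplogroup TSV must contain columns: ",
         paste(need, collapse = ", "))
  dt
}

#' Thin variants by physical distance after a MAF filter
#'
#' Applies a minor-allele-frequency filter, then greedily keeps, per
#' chromosome left to right, the first passing variant and every passing
#' variant at least `min_gap_bp` beyond the last kept one.
#'
#' @param chrom chromosome per variant.
#' @param pos_bp 1-based physical position per variant (sorted within
#'   chromosome; unsorted input is an error).
#' @param maf optional minor allele frequency per variant.
#' @param min_gap_bp minimum spacing in bp (default 2000).
#' @param maf_min MAF threshold (default 0.05); applied only when `maf` is
#'   given.
#' @return integer indices (into the input) of kept variants.
#' @export
thin_variants <- function(chrom, pos_bp, maf = NULL, min_gap_bp = 2000L,
                          maf_min = 0.05) {
  n <- length(pos_bp)
  stopifnot(length(chrom) == n)
  for (cn in unique(chrom)) {
    p <- pos_bp[chrom == cn]
    if (is.unsorted(p)) stop("positions must be sorted within chromosome ", cn)
  }
  idx <- seq_len(n)
  if (!is.null(maf)) idx <- idx[maf >= maf_min]
  if (length(idx) == 0L) {
    warning("no variants pass the MAF filter")
    return(integer(0))
  }
  kept <- integer(0)
  for (cn in unique(chrom[idx])) {
    ii <- idx[chrom[idx] == cn]
    last <- -Inf
    for (i in ii) {
      if (pos_bp[i] >= last + min_gap_bp) {
        kept <- c(kept, i)
        last <- pos_bp[i]
      }
    }
  }
  kept
}

#' Write a simulation-truth sidecar (JSON)
#'
#' Records every simulation parameter of a [sim_config()] so a synthetic
#' data set can be re-generated or audited.
#'
#' @param config a `sim_config`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_sidecar <- function(config, path) {
  x <- unclass(config)
  for (nm in c("alpha", "maternal_props", "paternal_props",
               "chrom_lengths"))
    x[[nm]] <- as.list(x[[nm]])  # keep names in the JSON object
  x$haplogroup_freqs <- lapply(x$haplogroup_freqs, function(ft) {
    m <- as_frequency_matrix(ft)
    list(haplogroups = rownames(m), ancestries = colnames(m),
         freq = unname(m))
  })
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
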