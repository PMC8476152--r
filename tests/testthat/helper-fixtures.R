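# Small in-code fixtures shared across test files.

# Evaluate `expr` under a fixed seed without disturbing the session RNG.
with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  expr
}

# A hand-written tract table: one sample, two haplotypes, one chromosome of
# 110 cM; haplotype 0 is 70 cM Chinese + 30 cM Malay + 10 cM Unknown.
toy_tracts <- function() {
  data.table::data.table(
    sample = "S1",
    haplotype = c(0L, 0L, 0L, 1L, 1L, 1L),
    chrom = "chr1",
    start_cM = c(0, 70, 100, 0, 50, 60),
    end_cM = c(70, 100, 110, 50, 60, 110),
    ancestry = c("Chinese", "Malay", "Unknown",
                 "Chinese", "Malay", "Unknown")
  )
}

# Windowed tracts carrying posterior vectors over four ancestries.
toy_posterior_tracts <- function() {
  data.table::data.table(
    sample = "S1", haplotype = 0L, chrom = "chr1",
    start_cM = c(0, 10, 20, 30),
    end_cM = c(10, 20, 30, 40),
    ancestry = NA_character_,
    p_Chinese = c(0.95, 0.60, 0.25, 0.05),
    p_Malay = c(0.03, 0.30, 0.25, 0.91),
    p_Indian = c(0.01, 0.05, 0.25, 0.03),
    p_European = c(0.01, 0.05, 0.25, 0.01)
  )
}

# Three-ancestry diagnostic haplogroup tables (disjoint supports).
diag_freqs <- function() default_haplogroup_freqs(diagnostic = TRUE)

# Table-1-style autosomal prior over Chinese/Malay/Indian, renormalized.
autosomal_prior <- function() {
  p <- c(Chinese = 0.933, Malay = 0.0562, Indian = 0.0092)
  p / sum(p)
}
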