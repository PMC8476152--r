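#' Pipeline configuration
#'
#' Validated stage parameters for [run_pipeline()]. Unknown keys are
#' rejected so that typos cannot silently fall back to defaults.
#'
#' @param seed global integer seed (drives every stage substream).
#' @param sim a [sim_config()] describing the synthetic cohort; its `seed`
#'   is overridden by `seed`.
#' @param n_ref reference individuals per population for the PCA and f3
#'   stages.
#' @param k_pcs number of principal components.
#' @param n_sd outlier threshold in SDs.
#' @param mask_threshold posterior masking threshold for tract input.
#' @param f3_blocks block count for the jackknife.
#' @param uniparental_R resampling realizations.
#' @param date_ancestry ancestry whose decay curve is dated.
#' @param date_grid coancestry grid `c(min, max, step)` in cM.
#' @param date_model `"one_date"` or `"two_date"`.
#' @param generation_time years per generation.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, sim = sim_config(),
                            n_ref = 60L, k_pcs = 3L, n_sd = 3,
                            mask_threshold = 0.9, f3_blocks = 40L,
                            uniparental_R = 1000L,
                            date_ancestry = "Malay",
                            date_grid = c(1, 50, 0.1),
                            date_model = "one_date",
                            generation_time = 29) {
  stopifnot(inherits(sim, "sim_config"))
  sim$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), sim = sim,
                 n_ref = as.integer(n_ref), k_pcs = as.integer(k_pcs),
                 n_sd = n_sd, mask_threshold = mask_threshold,
                 f3_blocks = as.integer(f3_blocks),
                 uniparental_R = as.integer(uniparental_R),
                 date_ancestry = date_ancestry, date_grid = date_grid,
                 date_model = date_model,
                 generation_time = generation_time),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys must be arguments of [pipeline_config()]; keys under `sim`
#' must be arguments of [sim_config()]. Unknown keys are rejected before any
#' computation.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- setdiff(names(formals(pipeline_config)), "sim")
  bad <- setdiff(names(raw), c(allowed, "sim"))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  sim_args <- raw$sim %||% list()
  bad_sim <- setdiff(names(sim_args), names(formals(sim_config)))
  if (length(bad_sim))
    stop("unknown sim config key(s): ", paste(bad_sim, collapse = ", "))
  if (!is.null(sim_args$alpha)) sim_args$alpha <- unlist(sim_args$alpha)
  for (nm in c("maternal_props", "paternal_props", "chrom_lengths"))
    if (!is.null(sim_args[[nm]])) sim_args[[nm]] <- unlist(sim_args[[nm]])
  raw$sim <- do.call(sim_config, sim_args)
  do.call(pipeline_config, raw)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Executes simulate, pca, fractions, f3, uniparental and date stages on a
#' synthetic cohort, writing per-stage TSV/JSON outputs plus a manifest
#' (seeds, parameters, stage outputs) and a resolved copy of the
#' configuration next to the outputs. Reruns with the same configuration are
#' byte-identical. A stage failure aborts with the stage name; outputs of
#' completed stages remain on disk.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @return manifest list, invisibly.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "straitsadmix",
                   version = as.character(utils::packageVersion("straitsadmix")),
                   seed = config$seed, outputs = list())
  fmt <- function(x) signif(x, 6)

  cohort <- run_stage("simulate", {
    sim <- config$sim
    if (sim$n_snps <= 0L) stop("pipeline requires n_snps > 0")
    simulate_cohort(sim)
  })
  write_tracts(cohort$tracts, file.path(outdir, "tracts.tsv"))
  write_haplogroups(cohort$haplogroups, file.path(outdir, "haplogroups.tsv"))
  write_truth_sidecar(config$sim, file.path(outdir, "truth.json"))
  manifest$outputs$simulate <- c("tracts.tsv", "haplogroups.tsv", "truth.json")

  pca_out <- run_stage("pca", {
    anc <- names(config$sim$alpha)[seq_len(config$sim$n_pops)]
    refs <- lapply(seq_along(anc), function(i)
      simulate_genotypes(cohort$pop_freqs[, i], config$n_ref,
                         seed = substream_seed(config$seed,
                                               paste0("refpanel_", i))))
    ref <- do.call(rbind, refs)
    rownames(ref) <- sprintf("%s_%03d", rep(anc, each = config$n_ref),
                             seq_len(config$n_ref))
    pca <- reference_pca(ref, k = config$k_pcs)
    study <- haplotypes_to_dosage(cohort$haplotypes)
    proj <- project_samples(pca$space, study)
    outl <- iterative_outlier_removal(proj, n_sd = config$n_sd,
                                      k = config$k_pcs)
    coords <- rbind(cbind(pca$coords,
                          group = rep(anc, each = config$n_ref),
                          kept = TRUE),
                    cbind(proj, group = "study",
                          kept = proj$sample %in% outl$kept))
    list(pca = pca, proj = proj, outliers = outl, coords = coords,
         ref_freqs = vapply(refs, function(g) colMeans(g) / 2,
                            numeric(config$sim$n_snps)))
  })
  cdt <- as.data.table(pca_out$coords)
  pccols <- grep("^PC", names(cdt), value = TRUE)
  cdt[, (pccols) := lapply(.SD, fmt), .SDcols = pccols]
  fwrite(cdt, file.path(outdir, "pca_coords.tsv"), sep = "\t")
  manifest$outputs$pca <- "pca_coords.tsv"

  fracs <- run_stage("fractions", {
    anc <- names(config$sim$alpha)
    auto <- global_fractions(cohort$tracts, "autosomes", ancestries = anc)
    xx <- global_fractions(cohort$tracts, "X", ancestries = anc)
    list(autosomes = auto, X = xx)
  })
  for (nm in c("autosomes", "X")) {
    ft <- copy(fracs[[nm]])
    numcols <- setdiff(names(ft), "sample")
    ft[, (numcols) := lapply(.SD, fmt), .SDcols = numcols]
    fwrite(ft, file.path(outdir, sprintf("fractions_%s.tsv", nm)),
           sep = "\t")
  }
  manifest$outputs$fractions <- c("fractions_autosomes.tsv",
                                  "fractions_X.tsv")

  f3_out <- run_stage("f3", {
    target <- colMeans(haplotypes_to_dosage(cohort$haplotypes)) / 2
    f3_test(target, pca_out$ref_freqs[, 1], pca_out$ref_freqs[, 2],
            target_counts = 2L * config$sim$n_samples,
            n_blocks = config$f3_blocks)
  })
  f3dt <- data.table(f3 = fmt(f3_out$estimate), se = fmt(f3_out$se),
                     z = fmt(f3_out$z), n_snps = f3_out$n_snps,
                     n_blocks = f3_out$n_blocks, mode = f3_out$mode)
  fwrite(f3dt, file.path(outdir, "f3.tsv"), sep = "\t")
  manifest$outputs$f3 <- "f3.tsv"

  uni <- run_stage("uniparental", {
    anc3 <- names(config$sim$maternal_props)
    fcols <- paste0("frac_", anc3)
    prior <- colMeans(as.matrix(fracs$autosomes[, fcols, with = FALSE]),
                      na.rm = TRUE)
    names(prior) <- anc3
    prior <- prior / sum(prior)
    mt_obs <- cohort$haplogroups[cohort$haplogroups$system == "MT"]
    y_obs <- cohort$haplogroups[cohort$haplogroups$system == "Y"]
    list(MT = estimate_uniparental(
           mt_obs$haplogroup, config$sim$haplogroup_freqs$MT, prior,
           R = config$uniparental_R,
           seed = substream_seed(config$seed, "resample_mt")),
         Y = estimate_uniparental(
           y_obs$haplogroup, config$sim$haplogroup_freqs$Y, prior,
           R = config$uniparental_R,
           seed = substream_seed(config$seed, "resample_y")),
         prior = prior)
  })
  unidt <- rbindlist(lapply(c("MT", "Y"), function(sys) {
    e <- uni[[sys]]
    data.table(system = sys, ancestry = names(e$rho), rho = fmt(e$rho),
               ci_lo = fmt(e$ci["lower", ]), ci_hi = fmt(e$ci["upper", ]),
               p = e$p, p_label = e$p_label, n = e$n_used, R = e$R)
  }))
  fwrite(unidt, file.path(outdir, "uniparental.tsv"), sep = "\t")
  manifest$outputs$uniparental <- "uniparental.tsv"

  date_out <- run_stage("date", {
    curve <- coancestry_curve(cohort$tracts, config$date_ancestry,
                              grid = config$date_grid)
    fit <- fit_decay(curve, config$date_model, config$generation_time)
    list(curve = curve, fit = fit)
  })
  cvdt <- data.table(bin_cM = date_out$curve$bins,
                     value = fmt(date_out$curve$value),
                     weight = fmt(date_out$curve$weight))
  fwrite(cvdt, file.path(outdir, "coancestry_curve.tsv"), sep = "\t")
  fitj <- list(model = date_out$fit$model,
               intercept = fmt(date_out$fit$intercept),
               amplitude = fmt(date_out$fit$amplitude),
               lambda = fmt(date_out$fit$lambda),
               dates_years = fmt(date_out$fit$dates_years),
               generation_time = date_out$fit$generation_time,
               no_signal = date_out$fit$no_signal)
  jsonlite::write_json(fitj, file.path(outdir, "decay_fit.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$outputs$date <- c("coancestry_curve.tsv", "decay_fit.json")

  cfg <- unclass(config)
  cfg$sim <- NULL
  yaml::write_yaml(cfg, file.path(outdir, "config_resolved.yaml"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
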