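#' Coancestry-decay curve: ancestry autocovariance versus genetic distance
#'
#' For an ancestry A, the curve value at genetic distance `d` is the
#' covariance of the ancestry indicator at two positions `d` cM apart on the
#' same haplotype: `mean[I_A(x) I_A(x + d)] - mean[I_A]^2`, pooled over all
#' haplotypes and positions, with cross-chromosome pairs excluded. Under a
#' Markov tract process with admixture `g` generations ago and proportion
#' `alpha`, the curve equals `alpha (1 - alpha) exp(-g d)` with `d` in
#' Morgans, which is the signal [fit_decay()] dates.
#'
#' The position average is evaluated in closed form (the continuous limit of
#' dense anchor sampling): per haplotype-chromosome, the lag-`d`
#' cross-product integral equals the total overlap length between the
#' ancestry-A tract set and its `d`-shifted copy, which this function
#' accumulates exactly at every bin center through a piecewise-linear kink
#' decomposition of the tract-pair overlap functions.
#'
#' @param tracts tract table (`sample`, `haplotype`, `chrom`, `start_cM`,
#'   `end_cM`, `ancestry`).
#' @param ancestry ancestry label whose indicator is analyzed (the minor
#'   ancestry for admixture dating).
#' @param grid numeric `c(min, max, step)` in cM; the default `c(1, 50,
#'   0.1)` targets recent admixture, while `c(1, 10, 0.01)` resolves ancient
#'   events whose decay completes within 10 cM.
#' @param chrom_set chromosomes to use (default `"autosomes"`, i.e.
#'   everything except `"X"`).
#' @return object of class `coancestry_curve`: `bins` (cM centers), `value`,
#'   `weight` (per-bin position measure in cM), the per-sample components
#'   used by [bootstrap_dates()], and the marginal ancestry fraction.
#' @export
coancestry_curve <- function(tracts, ancestry, grid = c(1, 50, 0.1),
                             chrom_set = "autosomes") {
  stopifnot(length(grid) == 3L, grid[1] > 0, grid[2] > grid[1], grid[3] > 0)
  anc <- ancestry
  tr <- as.data.table(tracts)
  keep <- if (identical(chrom_set, "autosomes")) tr$chrom != "X"
          else tr$chrom %in% chrom_set
  tr <- tr[keep]
  if (nrow(tr) == 0L) stop("no tracts on the requested chromosome set")
  bins <- seq(grid[1], grid[2], by = grid[3])
  chrom_len <- tr[, .(len = max(end_cM)), by = chrom]
  if (min(chrom_len$len) < grid[2])
    warning("grid maximum exceeds the shortest chromosome; ",
            "long-distance bins lose those chromosomes")

  samples <- sort(unique(tr$sample))
  ns <- length(samples)
  # per-sample position measure at each lag: sum over haplotype-chromosomes
  # of max(0, L_chrom - d)
  hc <- unique(tr[, .(sample, haplotype, chrom)])
  hc <- chrom_len[hc, on = "chrom"]
  wmat <- matrix(0, length(bins), ns, dimnames = list(NULL, samples))
  for (i in seq_len(nrow(hc))) {
    j <- match(hc$sample[i], samples)
    wmat[, j] <- wmat[, j] + pmax(0, hc$len[i] - bins)
  }
  tr[, length_cM := end_cM - start_cM]
  tot <- tr[, .(t_s = sum(length_cM)), by = sample]
  a_tab <- tr[tr$ancestry == anc, .(a_s = sum(length_cM)), by = sample]
  t_s <- setNames(numeric(ns), samples)
  t_s[tot$sample] <- tot$t_s
  a_s <- setNames(numeric(ns), samples)
  a_s[a_tab$sample] <- a_tab$a_s

  num <- matrix(0, length(bins), ns, dimnames = list(NULL, samples))
  ta <- tr[tr$ancestry == anc]
  if (nrow(ta) == 0L) {
    warning("ancestry '", anc, "' absent from tracts; curve is all zero")
  } else {
    ta[, grp := .GRP, by = .(sample, haplotype, chrom)]
    pairs <- ta[ta, on = "grp", allow.cartesian = TRUE]
    # ordered tract pairs (i, j) within a haplotype-chromosome; the overlap
    # between tract i and the d-shifted tract j is a trapezoid in d whose
    # four kinks (second-derivative impulses) are accumulated below
    s_i <- pairs$start_cM; e_i <- pairs$end_cM
    s_j <- pairs$i.start_cM; e_j <- pairs$i.end_cM
    # a shifted tract j strictly left of i (support ends at or before lag 0)
    # or starting beyond the grid maximum contributes exactly zero
    live <- (e_j > s_i) & (s_j - e_i < grid[2])
    samp <- pairs$sample[live]
    rm(pairs)
    s_i <- s_i[live]; e_i <- e_i[live]; s_j <- s_j[live]; e_j <- e_j[live]
    Lmin <- pmin(e_i - s_i, e_j - s_j)
    p <- c(s_j - e_i, s_j - e_i + Lmin, e_j - s_i - Lmin, e_j - s_i)
    w <- rep(c(1, -1, -1, 1), each = length(s_i))
    ks <- data.table(sample = rep(samp, 4L), p = p, w = w)
    rm(p, w, s_i, e_i, s_j, e_j, Lmin, samp)
    ks <- ks[ks$p < grid[2]]  # kinks at p >= d contribute 0 to F(d)
    setorder(ks, sample, p)
    ks[, `:=`(cw = cumsum(w), cwp = cumsum(w * p)), by = sample]
    fdt <- ks[, {
      idx <- findInterval(bins, p)
      list(bin = seq_along(bins),
           f = ifelse(idx > 0, bins * cw[pmax(idx, 1L)] -
                        cwp[pmax(idx, 1L)], 0))
    }, by = sample]
    num[cbind(fdt$bin, match(fdt$sample, samples))] <- fdt$f
  }
  value <- rowSums(num) / rowSums(wmat) - (sum(a_s) / sum(t_s))^2
  structure(list(bins = bins, value = value, weight = rowSums(wmat),
                 num = num, wmat = wmat, a_s = a_s, t_s = t_s,
                 samples = samples, ancestry = anc, grid = grid),
            class = "coancestry_curve")
}

#' @export
print.coancestry_curve <- function(x, ...) {
  cat(sprintf(
    "Coancestry curve for ancestry '%s': %d bins on [%g, %g] cM (step %g)\n",
    x$ancestry, length(x$bins), x$grid[1], x$grid[2], x$grid[3]))
  cat(sprintf("  %d samples; marginal fraction %.4f; value range [%.3g, %.3g]\n",
              length(x$samples), sum(x$a_s) / sum(x$t_s),
              min(x$value), max(x$value)))
  invisible(x)
}

# Rebuild a curve's value vector from a (resampled) set of sample indices.
curve_resample <- function(curve, idx) {
  num <- rowSums(curve$num[, idx, drop = FALSE])
  wt <- rowSums(curve$wmat[, idx, drop = FALSE])
  m <- sum(curve$a_s[idx]) / sum(curve$t_s[idx])
  list(value = num / wt - m^2, weight = wt)
}

# Weighted least squares of y on exponentials exp(-lambda * d) with an
# intercept; returns coefficients and weighted SSE.
exp_ls <- function(d, y, w, lambdas) {
  X <- cbind(1, vapply(lambdas, function(l) exp(-l * d), numeric(length(d))))
  sw <- sqrt(w / mean(w))
  fit <- tryCatch(lm.fit(X * sw, y * sw), error = function(e) NULL)
  if (is.null(fit) || anyNA(fit$coefficients))
    return(list(coef = rep(NA_real_, ncol(X)), sse = Inf))
  list(coef = unname(fit$coefficients), sse = sum(fit$residuals^2))
}

#' Fit an exponential decay model to a coancestry curve
#'
#' Weighted nonlinear least squares of `a + b exp(-lambda d)` (`one_date`)
#' or `a + b1 exp(-lambda1 d) + b2 exp(-lambda2 d)` (`two_date`) with `d` in
#' Morgans, weighting bins by their position measure. The decay rate
#' `lambda` is the number of generations since admixture; dates in years are
#' `lambda * generation_time`. Rates are profiled out on a multi-start log
#' grid (amplitudes and intercept solved linearly at each candidate), which
#' makes the fit deterministic. For `two_date` the faster rate must exceed
#' twice the slower one (identifiability guard); rates are reported with
#' `lambda1 < lambda2`.
#'
#' A curve with no decaying component (fitted amplitude not positive, or an
#' exponential term explaining < 1% of the weighted variance around the
#' intercept) is flagged `no_signal`.
#'
#' @param curve a [coancestry_curve()], or a list/data.frame with `bins`
#'   (cM), `value`, and optionally `weight`.
#' @param model `"one_date"` or `"two_date"`.
#' @param generation_time years per generation (default 29).
#' @return object of class `decay_fit`: `model`, `intercept`, `amplitude`,
#'   `lambda` (generations), `dates_years`, `generation_time`, `sse`,
#'   `no_signal`.
#' @export
fit_decay <- function(curve, model = c("one_date", "two_date"),
                      generation_time = 29) {
  model <- match.arg(model)
  d <- curve$bins / 100
  y <- curve$value
  w <- curve$weight %||% rep(1, length(y))
  ok <- is.finite(y) & is.finite(d) & w > 0
  d <- d[ok]; y <- y[ok]; w <- w[ok]
  if (length(y) < 10L) stop("need at least 10 usable bins")

  sse0 <- exp_ls(d, y, w, numeric(0))$sse  # intercept-only
  lgrid <- exp(seq(log(0.2), log(2000), length.out = 60))
  if (model == "one_date") {
    sses <- vapply(lgrid, function(l) exp_ls(d, y, w, l)$sse, numeric(1))
    i <- which.min(sses)
    lo <- lgrid[max(i - 1L, 1L)]; hi <- lgrid[min(i + 1L, length(lgrid))]
    opt <- optimize(function(ll) exp_ls(d, y, w, exp(ll))$sse,
                    lower = log(lo), upper = log(hi), tol = 1e-10)
    lambda <- exp(opt$minimum)
    fit <- exp_ls(d, y, w, lambda)
    amp <- fit$coef[2]
    out <- list(model = model, intercept = fit$coef[1], amplitude = amp,
                lambda = lambda, sse = fit$sse)
  } else {
    obj <- function(ll) {
      l <- exp(ll)
      if (l[2] / l[1] <= 2) return(Inf)  # identifiability guard
      exp_ls(d, y, w, l)$sse
    }
    starts <- list(c(2, 20), c(5, 50), c(2, 100), c(10, 100), c(5, 300),
                   c(20, 200))
    best <- NULL
    for (s in starts) {
      o <- tryCatch(optim(log(s), obj, method = "Nelder-Mead",
                          control = list(reltol = 1e-12, maxit = 2000)),
                    error = function(e) NULL)
      if (!is.null(o) && is.finite(o$value) &&
          (is.null(best) || o$value < best$value)) best <- o
    }
    if (is.null(best)) stop("two-date fit failed to converge from any start")
    lambda <- sort(exp(best$par))
    fit <- exp_ls(d, y, w, lambda)
    amp <- fit$coef[2:3]
    out <- list(model = model, intercept = fit$coef[1], amplitude = amp,
                lambda = lambda, sse = fit$sse)
  }
  # no detectable decay: non-positive amplitude, or amplitude within the
  # residual noise (3 sigma), or the exponential term explaining almost
  # none of the variance around a flat curve
  resid_sd <- sqrt(out$sse / max(length(y) - length(out$lambda) - 1, 1))
  out$no_signal <- !all(is.finite(out$amplitude)) ||
    max(out$amplitude) <= 0 || max(out$amplitude) < 3 * resid_sd ||
    (sse0 - out$sse) <= 0
  out$dates_years <- out$lambda * generation_time
  out$generation_time <- generation_time
  structure(out, class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("Exponential decay fit (%s, %g years/generation)\n",
              x$model, x$generation_time))
  for (i in seq_along(x$lambda))
    cat(sprintf("  lambda%d = %.3f generations -> %.0f years (amplitude %.3g)\n",
                i, x$lambda[i], x$dates_years[i], x$amplitude[i]))
  cat(sprintf("  intercept %.3g, weighted SSE %.4g%s\n", x$intercept, x$sse,
              if (x$no_signal) "  [no admixture signal]" else ""))
  invisible(x)
}

#' Bootstrap confidence intervals for admixture dates
#'
#' Resamples individuals with replacement, rebuilds the coancestry curve
#' from the stored per-sample components, refits the decay model, and takes
#' the 2.5/97.5 percentiles of the resulting dates.
#'
#' @param tracts tract table, or a precomputed [coancestry_curve()] passed
#'   via `curve`.
#' @param ancestry ancestry label (ignored when `curve` is given).
#' @param model,generation_time passed to [fit_decay()].
#' @param grid curve grid (ignored when `curve` is given).
#' @param B number of bootstrap replicates (default 100).
#' @param seed optional integer seed.
#' @param curve optional precomputed curve.
#' @return list with `estimate` (the full-data `decay_fit`), `ci` (matrix,
#'   one row per date), `dates` (B x n_dates matrix), `n_failed`, `B`,
#'   `seed`.
#' @export
bootstrap_dates <- function(tracts, ancestry, model = "one_date",
                            grid = c(1, 50, 0.1), B = 100L, seed = NULL,
                            generation_time = 29, curve = NULL) {
  if (is.null(curve)) curve <- coancestry_curve(tracts, ancestry, grid)
  if (B < 1L) stop("B must be >= 1")
  if (length(curve$samples) < 10L) stop("need at least 10 samples")
  est <- fit_decay(curve, model, generation_time)
  nd <- length(est$dates_years)
  ns <- length(curve$samples)
  with_seed(seed, {
    dates <- matrix(NA_real_, B, nd)
    for (b in seq_len(B)) {
      idx <- sample.int(ns, ns, replace = TRUE)
      rs <- curve_resample(curve, idx)
      fit_b <- tryCatch(
        fit_decay(list(bins = curve$bins, value = rs$value,
                       weight = rs$weight), model, generation_time),
        error = function(e) NULL)
      if (!is.null(fit_b)) dates[b, ] <- fit_b$dates_years
    }
    n_failed <- sum(!complete.cases(dates))
    if (n_failed > 0.2 * B)
      stop(n_failed, " of ", B, " bootstrap replicates failed to fit")
    ci <- t(apply(dates, 2, quantile, probs = c(0.025, 0.975),
                  na.rm = TRUE))
    dimnames(ci) <- list(paste0("date", seq_len(nd)),
                         c("lower", "upper"))
    list(estimate = est, ci = ci, dates = dates, n_failed = n_failed,
         B = as.integer(B), seed = seed)
  })
}

# Re-tile tracts into fixed windows of `window_cM` and permute the window
# ancestry labels within each haplotype. Window-level permutation destroys
# ancestry continuity beyond the window scale (the decay signal) while
# preserving each haplotype's marginal ancestry composition; permuting whole
# segments would not, because segment persistence itself carries the decay.
permute_windows <- function(tr, window_cM) {
  win <- tr[, {
    n_win <- max(1L, ceiling((end_cM - start_cM) / window_cM))
    edges <- seq(start_cM, end_cM, length.out = n_win + 1L)
    list(start_cM = edges[-length(edges)], end_cM = edges[-1],
         ancestry = rep(ancestry, n_win))
  }, by = .(sample, haplotype, chrom, segment = seq_len(nrow(tr)))]
  win[, segment := NULL]
  win[, ancestry := sample(ancestry), by = .(sample, haplotype)]
  win[]
}

#' Permutation test of the null hypothesis of no admixture
#'
#' Null replicates re-tile each haplotype into windows the size of the
#' grid's minimum distance and permute the window ancestry labels within the
#' haplotype, preserving its marginal ancestry fraction while destroying
#' ancestry continuity at the distances the curve measures. Observed data
#' and every null replicate are scored identically by the total fitted
#' exponential amplitude, and the empirical p-value is the fraction of null
#' replicates whose amplitude reaches the observed one.
#'
#' @inheritParams bootstrap_dates
#' @param window_cM permutation window size; defaults to the grid minimum.
#' @return list with `p_value`, `p_label` (`"<1/B"` style when 0),
#'   `observed` amplitude, `null_amplitudes`, `B`, `seed`.
#' @export
null_test <- function(tracts, ancestry, model = "one_date",
                      grid = c(1, 50, 0.1), B = 100L, seed = NULL,
                      generation_time = 29, window_cM = grid[1]) {
  if (B < 1L) stop("B must be >= 1")
  tr <- as.data.table(tracts)
  curve <- coancestry_curve(tr, ancestry, grid)
  if (length(curve$samples) < 10L) stop("need at least 10 samples")
  fit <- fit_decay(curve, model, generation_time)
  obs <- sum(fit$amplitude)
  with_seed(seed, {
    null_amp <- numeric(B)
    for (b in seq_len(B)) {
      perm <- permute_windows(tr, window_cM)
      cv <- coancestry_curve(perm, curve$ancestry, grid)
      nf <- fit_decay(cv, model, generation_time)
      null_amp[b] <- sum(nf$amplitude)
    }
    p <- mean(null_amp >= obs)
    list(p_value = p,
         p_label = if (p == 0) sprintf("<%g", 1 / B) else format(p, digits = 3),
         observed = obs, null_amplitudes = null_amp, B = as.integer(B),
         seed = seed)
  })
}
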