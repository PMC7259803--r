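## Gaussian-mixture machinery shared by the denoiser and the ploidy fitter.
##
## Model: K Gaussian components with a shared variance, optionally plus one
## Uniform(0,1) noise component. Means may be clamped (the fixed-mean ploidy
## models) or free. All computations in log space via log-sum-exp.

.em_gmm <- function(x, means, fix_means = FALSE, with_uniform = FALSE,
                    weights = NULL, sigma2 = NULL, max_iter = 500L,
                    tol = 1e-6, var_floor = 1e-4) {
  n <- length(x)
  k <- length(means)
  ncomp <- k + as.integer(with_uniform)
  if (is.null(weights)) weights <- rep(1 / ncomp, ncomp)
  if (is.null(sigma2)) sigma2 <- max(stats::var(x), var_floor)
  ll_trace <- numeric(max_iter)
  ll_old <- -Inf
  converged <- FALSE
  gidx <- seq_len(k)
  iter <- 0L
  d2 <- (x - rep(means, each = n))^2            # n x k, column-major
  dim(d2) <- c(n, k)
  repeat {
    iter <- iter + 1L
    logd <- -d2 / (2 * sigma2) +
      rep(log(weights[gidx]) - 0.5 * log(2 * pi * sigma2), each = n)
    dim(logd) <- c(n, k)
    if (with_uniform)
      logd <- cbind(logd, log(weights[ncomp]))  # dunif(x, 0, 1) = 1 on (0,1)
    mx <- do.call(pmax, lapply(seq_len(ncomp), function(j) logd[, j]))
    lse <- mx + log(rowSums(exp(logd - mx)))
    ll <- sum(lse)
    ll_trace[iter] <- ll
    resp <- exp(logd - lse)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
    ll_old <- ll
    nk <- colSums(resp)
    weights <- pmax(nk / n, 1e-12)
    weights <- weights / sum(weights)
    if (!fix_means) {
      means <- colSums(resp[, gidx, drop = FALSE] * x) / pmax(nk[gidx], 1e-12)
      d2 <- (x - rep(means, each = n))^2
      dim(d2) <- c(n, k)
    }
    ssq <- sum(resp[, gidx, drop = FALSE] * d2)
    sigma2 <- max(ssq / max(sum(nk[gidx]), 1e-12), var_floor)
  }
  list(loglik = ll_trace[iter], ll_trace = ll_trace[seq_len(iter)],
       means = means, weights = weights, sigma2 = sigma2, resp = resp,
       converged = converged, n_iter = iter)
}

## run short EMs from each init, then polish the best to convergence
.em_best <- function(x, inits, short_iter = 10L, ...) {
  args <- list(...)
  short_args <- args[setdiff(names(args), c("max_iter", "tol"))]
  best <- NULL
  for (m0 in inits) {
    fit <- do.call(.em_gmm, c(list(x = x, means = m0,
                                   max_iter = short_iter, tol = 0),
                              short_args))
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  polish_args <- args[setdiff(names(args), c("weights", "sigma2"))]
  do.call(.em_gmm, c(list(x = x, means = best$means,
                          weights = best$weights, sigma2 = best$sigma2),
                     polish_args))
}

## kmeans++-style spread initial means
.kpp_means <- function(x, k) {
  m <- numeric(k)
  m[1L] <- x[sample.int(length(x), 1L)]
  d2 <- (x - m[1L])^2
  for (j in 2:k) {
    if (sum(d2) == 0) m[j] <- x[sample.int(length(x), 1L)]
    else m[j] <- x[sample.int(length(x), 1L, prob = d2)]
    d2 <- pmin(d2, (x - m[j])^2)
  }
  sort(m)
}

#' Extract biallelic base frequencies from allele counts
#'
#' Keeps sites with total depth at least \code{min_depth}, at least
#' \code{min_minor_count} reads for each of the two alleles (so invariant
#' sites are excluded), and third-allele contamination
#' \code{countOther/depth} at most \code{max_other_frac}. Each kept site
#' contributes the frequencies of \emph{both} alleles (\eqn{f} and
#' \eqn{1-f}), so the resulting multiset is symmetric about 0.5 — the
#' representation used for all downstream band statistics and mixture fits.
#'
#' @param counts Site allele-count data frame (see
#'   \code{\link{read_counts_tsv}}); may hold several individuals.
#' @param min_depth Minimum total read depth per site.
#' @param min_minor_count Minimum reads supporting each allele.
#' @param max_other_frac Maximum fraction of third-allele reads.
#' @return Data frame of class \code{base_freq_set} with columns
#'   \code{individual}, \code{locus}, \code{site}, \code{freq}, \code{depth},
#'   \code{signal_posterior} (NA until denoised); two mirrored rows per kept
#'   site. Zero kept sites is flagged with a warning, not an error.
#' @export
extract_biallelic_frequencies <- function(counts, min_depth = 10L,
                                          min_minor_count = 3L,
                                          max_other_frac = 0.05) {
  depth <- counts$countA + counts$countB + counts$countOther
  keep <- depth >= min_depth &
    counts$countA >= min_minor_count &
    counts$countB >= min_minor_count &
    counts$countOther / pmax(depth, 1L) <= max_other_frac
  kept <- counts[keep, , drop = FALSE]
  if (nrow(kept) == 0L) {
    warning("no sites pass the biallelic filters")
    out <- data.frame(individual = character(0), locus = character(0),
                      site = integer(0), freq = numeric(0),
                      depth = integer(0), signal_posterior = numeric(0))
    class(out) <- c("base_freq_set", "data.frame")
    return(out)
  }
  d2 <- kept$countA + kept$countB
  f <- kept$countB / d2
  out <- data.frame(
    individual = rep(kept$individual, 2L),
    locus = rep(kept$locus, 2L),
    site = rep(kept$site, 2L),
    freq = c(f, 1 - f),
    depth = rep(d2, 2L),
    signal_posterior = NA_real_,
    stringsAsFactors = FALSE)
  class(out) <- c("base_freq_set", "data.frame")
  out
}

#' Denoise a base-frequency set
#'
#' Fits, by EM, a four-component mixture — one Uniform(0,1) noise component
#' plus three Gaussians with free means, free weights and a shared variance —
#' to the frequency entries, and assigns each entry a signal posterior
#' \eqn{1 - P(\mathrm{noise} \mid f)}. Posteriors of the two mirrored entries
#' of a site are averaged so that mirrored pairs are kept or dropped
#' together, preserving the symmetry of the set. Entries with signal
#' posterior at least 0.5 form the denoised set.
#'
#' @param freqs A \code{base_freq_set} for a single individual.
#' @param max_iter,tol EM stopping rule (absolute log-likelihood change).
#' @param var_floor Lower bound on the shared Gaussian variance.
#' @param n_restarts Random restarts in addition to the canonical
#'   \{0.25, 0.5, 0.75\} initialisation.
#' @return The denoised \code{base_freq_set}, with
#'   \code{signal_posterior} filled in; attributes \code{fit} (the winning EM
#'   fit), \code{noise_weight}, and \code{converged} (FALSE flags that the
#'   best run hit \code{max_iter}; best-so-far parameters are returned).
#' @export
denoise_frequencies <- function(freqs, max_iter = 500L, tol = 1e-6,
                                var_floor = 1e-4, n_restarts = 3L) {
  stopifnot(inherits(freqs, "base_freq_set"))
  x <- freqs$freq
  if (length(x) < 100L)
    stop("need at least 100 frequency entries to denoise")
  inits <- c(list(c(0.25, 0.5, 0.75)),
             lapply(seq_len(n_restarts), function(i) .kpp_means(x, 3L)))
  best <- .em_best(x, inits, fix_means = FALSE, with_uniform = TRUE,
                   weights = c(0.3, 0.3, 0.3, 0.1), max_iter = max_iter,
                   tol = tol, var_floor = var_floor)
  if (!best$converged)
    warning("denoising EM did not converge; returning best-so-far fit")
  post_signal <- 1 - best$resp[, 4L]
  key <- paste(freqs$individual, freqs$locus, freqs$site)
  post_site <- tapply(post_signal, key, mean)
  freqs$signal_posterior <- as.numeric(post_site[key])
  out <- freqs[freqs$signal_posterior >= 0.5, , drop = FALSE]
  if (nrow(out) == 0L)
    warning("denoising removed all entries")
  class(out) <- c("base_freq_set", "data.frame")
  attr(out, "fit") <- best
  attr(out, "noise_weight") <- best$weights[4L]
  attr(out, "converged") <- best$converged
  out
}

#' Assign ploidy by fixed-vs-free Gaussian mixture likelihood ratio
#'
#' For each candidate ploidy the expected allele-frequency peaks at biallelic
#' sites are clamped — diploid \{1/2\}, triploid \{1/3, 2/3\}, tetraploid
#' \{1/4, 1/2, 3/4\} — and a mixture with free weights and a shared free
#' variance is maximised by EM. A free three-component mixture (means also
#' free) is maximised as the saturated reference. All models additionally
#' carry a Uniform(0,1) noise component with free weight, so sequencing-error
#' outliers are absorbed symmetrically rather than biasing the model
#' comparison. The ploidy whose fixed
#' model loses the least log-likelihood against the free model
#' (\code{delta[p] = ll_free - ll_fixed[p]}, always nonnegative up to
#' numerical tolerance since each fixed model is nested in the free one) is
#' reported, ties broken toward the lower ploidy.
#'
#' Because the diploid peak set \{1/2\} is a subset of the tetraploid one
#' (and the free weights can silence the extra components), the fixed models
#' are partially nested in each other and true diploids produce near-ties
#' between \code{delta[2]} and \code{delta[4]}. Ties are therefore resolved
#' by parsimony with a tolerance: the lowest ploidy whose delta lies within
#' \code{tie_tol} log-likelihood units of the minimum is reported.
#'
#' @param freqs A (denoised) \code{base_freq_set} for one individual.
#' @param min_sites Minimum number of usable frequency entries.
#' @param n_restarts Random restarts for the free model (the free fit is also
#'   started from each fixed-model solution, which guarantees nesting).
#' @param tie_tol Log-likelihood tolerance of the parsimony tie-break
#'   (default 10: decisive evidence, a likelihood ratio of e^10, is required before
#'   invoking a higher-ploidy model nesting the lower one).
#' @param max_iter,tol,var_floor EM controls.
#' @return An object of class \code{ploidy_fit}: \code{ll_free},
#'   \code{ll_fixed} (named by ploidy), \code{delta}, \code{best_ploidy},
#'   \code{n_sites_used}, and the per-model fits.
#' @export
fit_ploidy <- function(freqs, min_sites = 200L, n_restarts = 10L,
                       tie_tol = 10, max_iter = 500L, tol = 1e-6,
                       var_floor = 1e-4) {
  stopifnot(inherits(freqs, "base_freq_set"))
  x <- freqs$freq
  if (length(x) < min_sites)
    stop(sprintf("insufficient sites: %d usable entries < min_sites = %d",
                 length(x), min_sites))
  fixed_means <- list(`2` = 0.5, `3` = c(1 / 3, 2 / 3),
                      `4` = c(0.25, 0.5, 0.75))
  ## every model carries a Uniform(0,1) noise component with free weight, so
  ## residual error-driven outliers load on the noise term in fixed and free
  ## models alike instead of distorting the likelihood-ratio deltas
  fixed_fits <- lapply(fixed_means, function(m)
    .em_gmm(x, means = m, fix_means = TRUE, with_uniform = TRUE,
            weights = c(rep(0.9 / length(m), length(m)), 0.1),
            max_iter = max_iter, tol = tol, var_floor = var_floor))
  ll_fixed <- vapply(fixed_fits, `[[`, 0, "loglik")

  ## free model: random kmeans++ restarts plus warm starts at each fixed
  ## solution (padded to 3 means), so ll_free >= max(ll_fixed) by EM ascent
  inits <- lapply(seq_len(n_restarts), function(i) .kpp_means(x, 3L))
  for (p in names(fixed_fits)) {
    fm <- fixed_means[[p]]
    inits <- c(inits, list(sort(c(fm, rep(0.5, 3L - length(fm))))))
  }
  free_best <- .em_best(x, inits, fix_means = FALSE, with_uniform = TRUE,
                        max_iter = max_iter, tol = tol,
                        var_floor = var_floor)
  ## guard nesting numerically: also continue EM from the best fixed-model
  ## optimum (extra components entering with negligible weight), so the free
  ## likelihood can only ascend above max(ll_fixed)
  ff <- fixed_fits[[which.max(ll_fixed)]]
  kf <- length(ff$means)
  wm <- c(ff$means, rep(0.5, 3L - kf))
  ww <- c(ff$weights[seq_len(kf)] * (1 - 1e-9),
          rep(1e-9 / max(3L - kf, 1L), 3L - kf),
          ff$weights[kf + 1L])
  wfit <- .em_gmm(x, means = wm, weights = ww / sum(ww),
                  sigma2 = ff$sigma2, fix_means = FALSE, with_uniform = TRUE,
                  max_iter = max_iter, tol = tol, var_floor = var_floor)
  if (wfit$loglik > free_best$loglik) free_best <- wfit
  delta <- free_best$loglik - ll_fixed
  ## parsimony tie-break: a lower-ploidy fixed model whose delta is within
  ## tie_tol log-units of the minimum wins (the diploid peak set is nested
  ## in the tetraploid one, so near-ties are expected for true diploids)
  ok <- delta <= min(delta) + tie_tol
  best <- as.integer(names(delta)[which(ok)[1L]])
  structure(list(ll_free = free_best$loglik,
                 ll_fixed = ll_fixed, delta = delta,
                 best_ploidy = best, n_sites_used = length(x),
                 tie_tol = tie_tol,
                 free_fit = free_best, fixed_fits = fixed_fits),
            class = "ploidy_fit")
}

#' @export
print.ploidy_fit <- function(x, ...) {
  cat(sprintf("<ploidy_fit> best ploidy %d (n = %d entries)\n",
              x$best_ploidy, x$n_sites_used))
  cat(sprintf("  delta(ll_free - ll_fixed): 2n %.3f | 3n %.3f | 4n %.3f\n",
              x$delta[["2"]], x$delta[["3"]], x$delta[["4"]]))
  invisible(x)
}

#' Seeded recovery experiment for the mixture ploidy caller
#'
#' Simulates individuals of known ploidy (diploid, triploid, tetrasomic
#' tetraploid), runs the extraction and fixed-vs-free mixture pipeline on
#' each, and tabulates estimated against true ploidy.
#'
#' @param n_per_ploidy Individuals per ploidy level.
#' @param seed Base seed.
#' @param n_sites Sites per individual.
#' @param mean_depth,error_rate Sequencing model.
#' @return Data frame with columns \code{true_ploidy}, \code{est_ploidy}.
#' @export
ploidy_recovery_experiment <- function(n_per_ploidy = 100L, seed = 1L,
                                       n_sites = 5000L, mean_depth = 50,
                                       error_rate = 0.005) {
  grid <- expand.grid(rep = seq_len(n_per_ploidy), ploidy = c(2L, 3L, 4L))
  est <- integer(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    pl <- grid$ploidy[r]
    cfg <- sim_config(seed = seed + 1000L * pl + grid$rep[r],
                      n_sites = n_sites, mean_depth = mean_depth,
                      error_rate = error_rate, ploidy = pl,
                      inheritance_mode = if (pl == 4L) "tetrasomic"
                      else "none")
    rc <- simulate_read_counts(simulate_genotypes(cfg), cfg)
    fr <- extract_biallelic_frequencies(rc)
    est[r] <- fit_ploidy(fr)$best_ploidy
  }
  data.frame(true_ploidy = grid$ploidy, est_ploidy = est)
}

#' Plot an allele-frequency histogram for one individual
#'
#' Standard diagnostic view of a base-frequency set: the histogram of both
#' allele frequencies, symmetric about 0.5, with the expected peak
#' positions of a chosen ploidy marked. Disomic tetraploids show a central
#' excess relative to the rare bands.
#'
#' @param freqs A \code{base_freq_set}.
#' @param ploidy Optional ploidy whose expected peaks are marked.
#' @param breaks Histogram breaks (passed to \code{\link[graphics]{hist}}).
#' @param ... Further arguments to \code{hist}.
#' @return Invisibly, the histogram object.
#' @export
plot_frequency_histogram <- function(freqs, ploidy = NULL, breaks = 50,
                                     ...) {
  stopifnot(inherits(freqs, "base_freq_set"))
  h <- graphics::hist(freqs$freq, breaks = breaks, xlim = c(0, 1),
                      main = if (nrow(freqs)) freqs$individual[1L] else "",
                      xlab = "allele frequency", col = "grey80",
                      border = "grey40", ...)
  if (!is.null(ploidy))
    graphics::abline(v = seq_len(ploidy - 1L) / ploidy, lty = 2,
                     col = "steelblue")
  invisible(h)
}

#' Informative sequence fraction of an individual
#'
#' Non-gap fraction of the individual's rows across the given locus
#' alignments (all haplotype rows concatenated).
#'
#' @param alignments List of \code{\link{locus_alignment}} objects.
#' @param individual Individual id.
#' @return Fraction in \code{[0, 1]}.
#' @export
informative_fraction <- function(alignments, individual) {
  tot <- 0L; inf <- 0L
  for (aln in alignments) {
    rows <- aln$meta$individual == individual
    if (!any(rows)) next
    s <- aln$seqs[rows, , drop = FALSE]
    tot <- tot + length(s)
    inf <- inf + sum(s != "-")
  }
  if (tot == 0L) stop("individual not present in any alignment")
  inf / tot
}

#' Sample QC: missing-data and ploidy-concordance filters
#'
#' Applies the study's two sample filters in order: an individual fails on
#' missing data when its informative fraction is below \code{threshold}
#' (the threshold itself passes: "at least 0.2" is inclusive), and otherwise
#' fails when the mixture-estimated ploidy does not match the expected
#' ploidy.
#'
#' @param informative_fraction Non-gap fraction for the individual (see
#'   \code{\link{informative_fraction}}).
#' @param expected_ploidy Expected ploidy (e.g. from cytology).
#' @param fit A \code{\link{fit_ploidy}} result.
#' @param threshold Minimum informative fraction.
#' @param individual_id Id stamped on the report.
#' @return One-row data frame: \code{individual}, \code{informative_fraction},
#'   \code{expected_ploidy}, \code{estimated_ploidy}, \code{status} in
#'   \{pass, fail_missing_data, fail_ploidy_mismatch\}.
#' @export
qc_sample <- function(informative_fraction, expected_ploidy, fit,
                      threshold = 0.2, individual_id = NA_character_) {
  status <- if (informative_fraction < threshold) "fail_missing_data"
  else if (fit$best_ploidy != expected_ploidy) "fail_ploidy_mismatch"
  else "pass"
  data.frame(individual = individual_id,
             informative_fraction = informative_fraction,
             expected_ploidy = as.integer(expected_ploidy),
             estimated_ploidy = fit$best_ploidy,
             status = status, stringsAsFactors = FALSE)
}
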