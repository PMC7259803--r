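#' Combine two diploid individuals into an in-silico tetraploid
#'
#' Sums per-site read counts of two diploids over their shared (locus, site)
#' coordinates, emulating the merge of their read sets. Combining two
#' conspecific diploids models an autotetraploid (tetrasomic inheritance);
#' combining diploids of different species models an allotetraploid, whose
#' fixed inter-species differences become balanced intermediate-frequency
#' (AABB-type) sites. Sites present in only one source are dropped. If both
#' tables carry \code{alleleA}/\code{alleleB} identity columns, counts are
#' matched by allele (swapped labels are reconciled; irreconcilable sites are
#' dropped and tallied).
#'
#' @param a,b Single-individual site allele-count data frames.
#' @return A combined count data frame (class \code{combined_tetraploid});
#'   attributes \code{source_ids}, \code{mode}
#'   (\code{"within_species"}/\code{"between_species"}) and
#'   \code{n_conflict_dropped}.
#' @export
combine_diploids <- function(a, b) {
  if (length(unique(a$individual)) != 1L || length(unique(b$individual)) != 1L)
    stop("combine_diploids expects single-individual count tables")
  has_alleles <- all(c("alleleA", "alleleB") %in% names(a)) &&
    all(c("alleleA", "alleleB") %in% names(b))
  if (!has_alleles && nrow(a) == nrow(b) &&
      all(a$locus == b$locus) && all(a$site == b$site)) {
    ## fast path: identical site grids (the common case for one locus set)
    out <- data.frame(
      individual = paste0(a$individual[1L], "+", b$individual[1L]),
      species = paste0(a$species[1L], "+", b$species[1L]),
      locus = a$locus, site = a$site,
      countA = a$countA + b$countA, countB = a$countB + b$countB,
      countOther = a$countOther + b$countOther, stringsAsFactors = FALSE)
    mode <- if (a$species[1L] == b$species[1L]) "within_species"
    else "between_species"
    return(structure(out, source_ids = c(a$individual[1L], b$individual[1L]),
                     mode = mode, n_conflict_dropped = 0L,
                     class = c("combined_tetraploid", "data.frame")))
  }
  m <- merge(a, b, by = c("locus", "site"), suffixes = c(".a", ".b"))
  n_conflict <- 0L
  if (has_alleles && nrow(m)) {
    same <- m$alleleA.a == m$alleleA.b & m$alleleB.a == m$alleleB.b
    swapped <- m$alleleA.a == m$alleleB.b & m$alleleB.a == m$alleleA.b
    conflict <- !(same | swapped)
    n_conflict <- sum(conflict)
    tmp <- m$countA.b[swapped]
    m$countA.b[swapped] <- m$countB.b[swapped]
    m$countB.b[swapped] <- tmp
    m <- m[!conflict, , drop = FALSE]
  }
  out <- data.frame(
    individual = paste0(a$individual[1L], "+", b$individual[1L]),
    species = paste0(a$species[1L], "+", b$species[1L]),
    locus = m$locus, site = m$site,
    countA = m$countA.a + m$countA.b,
    countB = m$countB.a + m$countB.b,
    countOther = m$countOther.a + m$countOther.b,
    stringsAsFactors = FALSE)
  out <- out[order(out$locus, out$site), , drop = FALSE]
  rownames(out) <- NULL
  mode <- if (a$species[1L] == b$species[1L]) "within_species"
  else "between_species"
  structure(out, source_ids = c(a$individual[1L], b$individual[1L]),
            mode = mode, n_conflict_dropped = n_conflict,
            class = c("combined_tetraploid", "data.frame"))
}

#' Build auto- and allotetraploid expectation sets from diploids
#'
#' All unordered within-species diploid pairs model autotetraploids
#' (tetrasomic expectation); all unordered between-species pairs model
#' allotetraploids (disomic expectation). The allo set can be restricted to a
#' named species pair.
#'
#' @param diploids Site allele-count data frame holding several diploid
#'   individuals (column \code{individual} distinguishes them).
#' @param species_pair Optional character vector of two species; restricts
#'   the allo set to pairs drawn one from each.
#' @param pairs \code{"all"} uses every unordered pair; \code{"disjoint"}
#'   uses each diploid in at most one auto and one allo pair, giving
#'   statistically independent model individuals — the design to use when
#'   the model groups enter rank tests, since all-pairs sets are heavily
#'   pseudo-replicated (each diploid appears in many pairs and their ratios
#'   are correlated).
#' @return List with elements \code{auto} and \code{allo}, each a list of
#'   \code{\link{combine_diploids}} results.
#' @export
build_expectation_sets <- function(diploids, species_pair = NULL,
                                   pairs = c("all", "disjoint")) {
  pairs <- match.arg(pairs)
  by_ind <- split(diploids, diploids$individual)
  ids <- names(by_ind)
  if (length(ids) < 2L) stop("need at least 2 diploid individuals")
  sp <- vapply(by_ind, function(d) d$species[1L], "")
  if (length(unique(sp)) < 2L)
    stop("need diploids from at least 2 species")
  single <- names(table(sp))[table(sp) < 2L]
  if (length(single))
    warning("species with <2 individuals contribute no auto pairs: ",
            paste(single, collapse = ", "))
  auto <- list(); allo <- list()
  if (pairs == "all") {
    for (i in seq_len(length(ids) - 1L)) {
      for (j in (i + 1L):length(ids)) {
        within <- sp[i] == sp[j]
        if (!within && !is.null(species_pair) &&
            !setequal(c(sp[i], sp[j]), species_pair)) next
        cmb <- combine_diploids(by_ind[[i]], by_ind[[j]])
        if (within) auto[[length(auto) + 1L]] <- cmb
        else allo[[length(allo) + 1L]] <- cmb
      }
    }
  } else {
    ## disjoint: consecutive within-species pairs for auto, then a parallel
    ## between-species matching for allo; every diploid used at most once
    ## per model set
    sp_use <- unique(sp)
    if (!is.null(species_pair)) sp_use <- intersect(sp_use, species_pair)
    for (s in sp_use) {
      members <- ids[sp[ids] == s]
      np <- length(members) %/% 2L
      for (k in seq_len(np))
        auto[[length(auto) + 1L]] <-
          combine_diploids(by_ind[[members[2L * k - 1L]]],
                           by_ind[[members[2L * k]]])
    }
    if (length(sp_use) >= 2L) {
      for (si in seq_len(length(sp_use) - 1L)) {
        for (sj in (si + 1L):length(sp_use)) {
          mi <- ids[sp[ids] == sp_use[si]]
          mj <- ids[sp[ids] == sp_use[sj]]
          for (k in seq_len(min(length(mi), length(mj))))
            allo[[length(allo) + 1L]] <-
              combine_diploids(by_ind[[mi[k]]], by_ind[[mj[k]]])
        }
      }
    }
  }
  list(auto = auto, allo = allo)
}

#' Intermediate/rare allele-frequency ratio
#'
#' The inheritance-mode diagnostic: the count of frequency entries in the
#' intermediate band (closed interval, default \code{[0.40, 0.60]}) divided
#' by the count in the rare band (default \code{(0, 0.30)}). On the
#' symmetric both-allele representation each intermediate site contributes
#' two entries while the rare band deliberately counts only the low side —
#' entries below 0.30, not their mirrors above 0.70 — a monotone transform of
#' the folded ratio that leaves rank tests unchanged. Disomic (allo-)
#' tetraploids are expected to show elevated ratios through their excess of
#' balanced AABB-type sites.
#'
#' @param freqs A \code{base_freq_set} for one individual (or combined
#'   tetraploid model).
#' @param int_band Closed intermediate band.
#' @param rare_max Open upper bound of the rare band.
#' @param group Label: \code{"observed_4n"}, \code{"model_auto"} or
#'   \code{"model_allo"}.
#' @return One-row data frame: \code{individual}, \code{n_intermediate},
#'   \code{n_rare}, \code{ratio} (NA when \code{n_rare} is 0),
#'   \code{defined}, \code{group}.
#' @export
intermediate_rare_ratio <- function(freqs, int_band = c(0.40, 0.60),
                                    rare_max = 0.30, group = NA_character_) {
  f <- freqs$freq
  n_int <- sum(f >= int_band[1L] & f <= int_band[2L])
  n_rare <- sum(f > 0 & f < rare_max)
  defined <- n_rare > 0L
  data.frame(individual = if (nrow(freqs)) freqs$individual[1L]
             else NA_character_,
             n_intermediate = n_int, n_rare = n_rare,
             ratio = if (defined) n_int / n_rare else NA_real_,
             defined = defined, group = group, stringsAsFactors = FALSE)
}

#' Wilcoxon rank-sum comparison of two ratio groups
#'
#' Two-sided Wilcoxon rank-sum test on the defined ratio values of two
#' groups: exact enumeration when both groups have at most 10 values and no
#' ties, otherwise the normal approximation with tie and continuity
#' correction. Undefined ratios (rare-band count zero) are excluded with a
#' logged count.
#'
#' @param a,b Data frames of \code{\link{intermediate_rare_ratio}} rows.
#' @return List: \code{statistic} (rank-sum W), \code{p_value},
#'   \code{n_a}, \code{n_b}, \code{n_undefined_excluded}, \code{exact}.
#' @export
compare_groups <- function(a, b) {
  ra <- a$ratio[a$defined]; rb <- b$ratio[b$defined]
  n_excl <- sum(!a$defined) + sum(!b$defined)
  if (length(ra) < 3L || length(rb) < 3L)
    stop("need at least 3 defined ratios per group")
  exact <- length(ra) <= 10L && length(rb) <= 10L &&
    !anyDuplicated(c(ra, rb))
  wt <- suppressWarnings(stats::wilcox.test(ra, rb, exact = exact,
                                            correct = TRUE,
                                            alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_a = length(ra), n_b = length(rb),
       n_undefined_excluded = n_excl, exact = exact)
}

#' Classify the inheritance mode of a tetraploid group
#'
#' Compares the observed tetraploids' intermediate/rare ratios against the
#' autotetraploid (tetrasomic) and allotetraploid (disomic) model sets with
#' two-sided Wilcoxon rank-sum tests, Benjamini-Hochberg adjusted across the
#' declared family (observed-vs-auto, observed-vs-allo, auto-vs-allo).
#' Decision rule: \code{tetrasomic} when the observed group differs
#' significantly from the allo models (observed lower) but not from the auto
#' models; \code{disomic} when the mirror holds (significantly above the auto
#' models, not distinguishable from the allo models); \code{mixed} otherwise
#' (both significant, or neither).
#'
#' @param observed,auto_model,allo_model Data frames of ratio rows (one per
#'   individual / model pair).
#' @param alpha Significance level applied to adjusted p-values.
#' @param species Label carried into the call.
#' @return List of class \code{inheritance_call}: \code{species},
#'   \code{label}, \code{p_vs_auto}, \code{p_vs_allo}, \code{p_auto_vs_allo}
#'   (BH-adjusted), raw p-values, group sizes and medians.
#' @export
classify_inheritance <- function(observed, auto_model, allo_model,
                                 alpha = 0.05, species = NA_character_) {
  if (!nrow(observed) || !nrow(auto_model) || !nrow(allo_model))
    stop("all three ratio groups must be nonempty")
  t_oa <- compare_groups(observed, auto_model)
  t_ol <- compare_groups(observed, allo_model)
  t_al <- compare_groups(auto_model, allo_model)
  raw <- c(vs_auto = t_oa$p_value, vs_allo = t_ol$p_value,
           auto_vs_allo = t_al$p_value)
  adj <- stats::p.adjust(raw, method = "BH")
  med <- function(d) stats::median(d$ratio[d$defined])
  m_obs <- med(observed); m_auto <- med(auto_model); m_allo <- med(allo_model)
  sig_auto <- adj[["vs_auto"]] < alpha
  sig_allo <- adj[["vs_allo"]] < alpha
  ## tetrasomic: significantly below the allo models and not above the auto
  ## models (being significantly BELOW auto still argues for tetrasomy, so
  ## only a significant difference on the auto side with the observed group
  ## lying between the two model sets blocks the call); disomic mirrors
  ## this. "mixed" = observed sits between the model sets with both sides
  ## significant, or neither side is significant.
  label <- if (sig_allo && m_obs < m_allo && (!sig_auto || m_obs <= m_auto))
    "tetrasomic"
  else if (sig_auto && m_obs > m_auto && (!sig_allo || m_obs >= m_allo))
    "disomic"
  else "mixed"
  structure(list(species = species, label = label,
                 p_vs_auto = adj[["vs_auto"]], p_vs_allo = adj[["vs_allo"]],
                 p_auto_vs_allo = adj[["auto_vs_allo"]], p_raw = raw,
                 alpha = alpha,
                 n_observed = sum(observed$defined),
                 n_auto = sum(auto_model$defined),
                 n_allo = sum(allo_model$defined),
                 median_observed = m_obs, median_auto = m_auto,
                 median_allo = m_allo),
            class = "inheritance_call")
}

#' Seeded recovery experiment for the inheritance-mode classifier
#'
#' Runs the full classification pipeline on synthetic data with known truth,
#' once per replicate: a two-species diploid population
#' (\code{\link{simulate_diploid_species_pair}}) supplies disjoint-pair
#' auto- and allotetraploid expectation sets; independent observed
#' tetraploids are simulated as tetrasomic (one panmictic pool) and disomic
#' (two subgenomes, fixed-difference fraction \code{fixed_diff_prob})
#' genotypes; both observed groups are classified against the model sets;
#' and a null comparison (two disjoint halves of the tetrasomic observed
#' group) records the false-positive behaviour of the rank-sum test.
#'
#' Diploids are sequenced at half the tetraploid depth so that summed
#' (in-silico tetraploid) counts match the observed tetraploids' depth, and
#' observed tetraploids are simulated over raw site counts chosen so that
#' about \code{n_sites} biallelic sites survive extraction — keeping the
#' error-driven rare-band leakage of homozygous sites identical between
#' observed and model groups.
#'
#' @param n_replicates Number of seeded replicates.
#' @param seed Base seed; replicate r uses \code{seed + 1000 * r} offsets.
#' @param n_tetraploids Observed tetraploids per truth group.
#' @param n_diploids Diploids per species.
#' @param n_sites Target biallelic sites per observed tetraploid.
#' @param diploid_sites Sites simulated per diploid.
#' @param mean_depth,error_rate Tetraploid sequencing model (diploids use
#'   \code{mean_depth / 2}).
#' @param fixed_diff_prob Inter-subgenome / inter-species divergence.
#' @param alpha Significance level of the classifier.
#' @return Data frame with one row per replicate: \code{label_tetrasomic}
#'   and \code{label_disomic} (classifier output for each truth group) and
#'   \code{p_null} (rank-sum p of the null split).
#' @export
inheritance_mode_recovery <- function(n_replicates = 100L, seed = 1L,
                                      n_tetraploids = 8L, n_diploids = 8L,
                                      n_sites = 5000L,
                                      diploid_sites = 50000L,
                                      mean_depth = 50, error_rate = 0.005,
                                      fixed_diff_prob = 0.05, alpha = 0.05) {
  ## raw site counts giving ~n_sites biallelic sites after extraction, from
  ## the Beta(0.2, 0.2) prior's probability that a tetraploid site is
  ## heterozygous (P ~ 0.26 tetrasomic; + fixed differences when disomic)
  p_bi <- 0.26
  raw_tet <- ceiling(n_sites / p_bi)
  raw_dis <- ceiling(n_sites / (fixed_diff_prob + (1 - fixed_diff_prob) * p_bi))
  ratio_of <- function(cnt, grp)
    intermediate_rare_ratio(extract_biallelic_frequencies(cnt), group = grp)
  out <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    base <- seed + 1000L * r
    dip <- simulate_diploid_species_pair(
      n_diploids, diploid_sites, fixed_diff_prob,
      mean_depth = mean_depth / 2, error_rate = error_rate, seed = base)
    es <- build_expectation_sets(dip, pairs = "disjoint")
    auto <- do.call(rbind, lapply(es$auto, ratio_of, grp = "model_auto"))
    allo <- do.call(rbind, lapply(es$allo, ratio_of, grp = "model_allo"))
    obs <- function(mode, off, nraw)
      do.call(rbind, lapply(seq_len(n_tetraploids), function(i) {
        cfg <- sim_config(seed = base + off + i, n_sites = nraw, ploidy = 4,
                          mean_depth = mean_depth, error_rate = error_rate,
                          inheritance_mode = mode,
                          fixed_diff_prob =
                            if (mode == "disomic") fixed_diff_prob else 0)
        ratio_of(simulate_read_counts(simulate_genotypes(cfg), cfg),
                 paste0("observed_", mode))
      }))
    ot <- obs("tetrasomic", 200L, raw_tet)
    od <- obs("disomic", 400L, raw_dis)
    half <- seq_len(n_tetraploids %/% 2L)
    out[[r]] <- data.frame(
      label_tetrasomic = classify_inheritance(ot, auto, allo,
                                              alpha = alpha)$label,
      label_disomic = classify_inheritance(od, auto, allo,
                                           alpha = alpha)$label,
      p_null = compare_groups(ot[half, ], ot[-half, ])$p_value,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' @export
print.inheritance_call <- function(x, ...) {
  cat(sprintf("<inheritance_call> %s: %s\n",
              ifelse(is.na(x$species), "(unnamed)", x$species), x$label))
  cat(sprintf("  adj. p vs auto %.4g | vs allo %.4g (alpha = %g)\n",
              x$p_vs_auto, x$p_vs_allo, x$alpha))
  cat(sprintf("  median ratio observed %.3g | auto %.3g | allo %.3g\n",
              x$median_observed, x$median_auto, x$median_allo))
  invisible(x)
}
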