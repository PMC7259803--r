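#' Site filters for a locus alignment
#'
#' Applies the study's site filters: sites containing any gap or ambiguous
#' base are handled by the gap policy (complete deletion drops them; pairwise
#' deletion keeps them for the pair-based statistics), sites with more than
#' two observed nucleotide alleles are dropped, and the locus as a whole is
#' rejected unless strictly more than \code{min_sites} sites survive.
#'
#' @param aln A \code{\link{locus_alignment}}.
#' @param min_sites Locus passes only with more than this many kept sites
#'   (strict inequality).
#' @param gap_policy \code{"complete"} (default; any gap/N drops the site) or
#'   \code{"pairwise"} (gap sites kept; downstream statistics must handle
#'   missing bases pairwise).
#' @return List of class \code{site_filter_result}: \code{kept_sites}
#'   (indices), \code{n_invariant}, \code{n_biallelic},
#'   \code{n_dropped_multiallelic}, \code{n_dropped_gap}, \code{pass},
#'   and \code{aln} (the filtered alignment).
#' @export
filter_locus <- function(aln, min_sites = 100L,
                         gap_policy = c("complete", "pairwise")) {
  gap_policy <- match.arg(gap_policy)
  stopifnot(inherits(aln, "locus_alignment"))
  if (ncol(aln$seqs) == 0L || nrow(aln$seqs) == 0L) stop("empty alignment")
  s <- aln$seqs
  is_gap <- s == "-" | s == "n"
  gap_site <- colSums(is_gap) > 0L
  nalleles <- apply(s, 2L, function(col) length(unique(col[!(col %in% c("-", "n"))])))
  multi <- nalleles > 2L
  if (gap_policy == "complete") {
    drop_gap <- gap_site
    drop_multi <- !gap_site & multi
  } else {
    drop_gap <- rep(FALSE, ncol(s))
    drop_multi <- multi
  }
  keep <- !(drop_gap | drop_multi)
  kept_idx <- which(keep)
  n_bi <- sum(nalleles[keep] == 2L)
  n_inv <- sum(keep) - n_bi
  faln <- locus_alignment(s[, keep, drop = FALSE], aln$meta,
                          locus_id = aln$locus_id)
  structure(list(kept_sites = kept_idx, n_invariant = n_inv,
                 n_biallelic = n_bi,
                 n_dropped_multiallelic = sum(drop_multi),
                 n_dropped_gap = sum(drop_gap),
                 pass = length(kept_idx) > min_sites, aln = faln),
            class = "site_filter_result")
}

## sum of pairwise differences over all haplotype pairs (complete data)
.pair_diff_sum <- function(s) {
  n <- nrow(s)
  tot <- 0
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      tot <- tot + sum(s[i, ] != s[j, ])
  tot
}

.tajima_constants <- function(n) {
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Within-species diversity statistics for one locus
#'
#' Computes, on the filtered sites of the species' haplotypes: segregating
#' sites \eqn{S}; per-site nucleotide diversity \eqn{\pi} (mean pairwise
#' difference over all haplotype pairs, divided by kept length); per-site
#' Watterson's \eqn{\theta_W = S / (a_1 L)}; and Tajima's D,
#' \deqn{D = \frac{\Pi - S/a_1}{\sqrt{e_1 S + e_2 S (S - 1)}}}
#' with \eqn{\Pi} the mean pairwise difference per locus and the standard
#' constants in the sample size. Tetraploids contribute their four phased
#' haplotypes as four rows; all statistics are haplotype-based.
#'
#' @param aln A \code{\link{locus_alignment}}.
#' @param species Species label; rows of other species are ignored.
#' @param min_sites Passed to \code{\link{filter_locus}}.
#' @return One-row data frame of class \code{locus_stats}: \code{locus},
#'   \code{species}, \code{n_haplotypes}, \code{L} (kept sites), \code{S},
#'   \code{pi}, \code{theta_w}, \code{tajimas_d} (NA when S = 0),
#'   \code{pass_filter}.
#' @export
diversity_stats <- function(aln, species, min_sites = 100L) {
  rows <- aln$meta$species == species
  if (sum(rows) < 2L) stop("need >= 2 haplotypes of the species")
  sub <- locus_alignment(aln$seqs[rows, , drop = FALSE],
                         aln$meta[rows, , drop = FALSE],
                         locus_id = aln$locus_id)
  fr <- filter_locus(sub, min_sites = min_sites)
  s <- fr$aln$seqs
  n <- nrow(s); L <- ncol(s)
  S <- fr$n_biallelic
  pi_total <- if (L > 0L) .pair_diff_sum(s) / choose(n, 2L) else 0
  k <- .tajima_constants(n)
  theta_w <- if (L > 0L) S / (k$a1 * L) else NA_real_
  D <- NA_real_
  if (S > 0L) {
    denom <- sqrt(k$e1 * S + k$e2 * S * (S - 1))
    D <- (pi_total - S / k$a1) / denom
  }
  out <- data.frame(locus = aln$locus_id, species = species,
                    n_haplotypes = n, L = L, S = S,
                    pi = if (L > 0L) pi_total / L else NA_real_,
                    theta_w = theta_w, tajimas_d = D,
                    pass_filter = fr$pass, stringsAsFactors = FALSE)
  class(out) <- c("locus_stats", "data.frame")
  out
}

#' Between-species differentiation for one locus (Hudson's Fst, dxy)
#'
#' Hudson-type estimator \eqn{F_{st} = 1 - H_w / H_b}: \eqn{H_w} is the mean
#' pairwise difference within species (average of the two species' means) and
#' \eqn{H_b} the mean pairwise difference between them, on the jointly
#' filtered sites. \eqn{d_{xy}} is \eqn{H_b} per kept site. \eqn{F_{st}} is
#' undefined (NA) when \eqn{H_b = 0}.
#'
#' @param aln A \code{\link{locus_alignment}} holding both species.
#' @param spA,spB Species labels.
#' @param min_sites Passed to \code{\link{filter_locus}}.
#' @return One-row data frame: \code{locus}, \code{speciesA}, \code{speciesB},
#'   \code{fst}, \code{dxy}, \code{hw}, \code{hb}, \code{L},
#'   \code{pass_filter}.
#' @export
pairwise_fst <- function(aln, spA, spB, min_sites = 100L) {
  ra <- aln$meta$species == spA
  rb <- aln$meta$species == spB
  if (sum(ra) < 2L || sum(rb) < 2L)
    stop("both species need >= 2 haplotypes at the locus")
  rows <- ra | rb
  sub <- locus_alignment(aln$seqs[rows, , drop = FALSE],
                         aln$meta[rows, , drop = FALSE],
                         locus_id = aln$locus_id)
  fr <- filter_locus(sub, min_sites = min_sites)
  s <- fr$aln$seqs
  ia <- which(fr$aln$meta$species == spA)
  ib <- which(fr$aln$meta$species == spB)
  L <- ncol(s)
  mean_pd <- function(idx) {
    if (length(idx) < 2L) return(NA_real_)
    .pair_diff_sum(s[idx, , drop = FALSE]) / choose(length(idx), 2L)
  }
  hw <- (mean_pd(ia) + mean_pd(ib)) / 2
  hb <- 0
  for (i in ia) for (j in ib) hb <- hb + sum(s[i, ] != s[j, ])
  hb <- hb / (length(ia) * length(ib))
  fst <- if (hb > 0) 1 - hw / hb else NA_real_
  data.frame(locus = aln$locus_id, speciesA = spA, speciesB = spB,
             fst = fst, dxy = if (L > 0L) hb / L else NA_real_,
             hw = hw, hb = hb, L = L, pass_filter = fr$pass,
             stringsAsFactors = FALSE)
}

#' Aggregate per-locus Fst (or dxy) into a species matrix
#'
#' Collects per-locus pairwise values into a symmetric species-by-species
#' matrix, aggregating across loci by the median for Fst (undefined loci
#' excluded) and by the mean for dxy.
#'
#' @param per_locus Data frame of \code{\link{pairwise_fst}} rows.
#' @param value Column to aggregate: \code{"fst"} (median) or \code{"dxy"}
#'   (mean).
#' @return Symmetric numeric matrix with zero diagonal, species as dimnames.
#' @export
aggregate_fst <- function(per_locus, value = c("fst", "dxy")) {
  value <- match.arg(value)
  aggfun <- if (value == "fst") stats::median else mean
  sp <- sort(unique(c(per_locus$speciesA, per_locus$speciesB)))
  m <- matrix(0, length(sp), length(sp), dimnames = list(sp, sp))
  for (i in seq_len(length(sp) - 1L)) {
    for (j in (i + 1L):length(sp)) {
      sel <- (per_locus$speciesA == sp[i] & per_locus$speciesB == sp[j]) |
        (per_locus$speciesA == sp[j] & per_locus$speciesB == sp[i])
      v <- per_locus[[value]][sel]
      v <- v[!is.na(v)]
      m[i, j] <- m[j, i] <- if (length(v)) aggfun(v) else NA_real_
    }
  }
  m
}

#' Hierarchical clustering of a species distance matrix
#'
#' Average-linkage (UPGMA) agglomerative clustering of a symmetric species
#' matrix, e.g. median pairwise Fst or mean between-species diversity.
#'
#' @param matrix Symmetric matrix, zero diagonal.
#' @param method Linkage passed to \code{\link[stats]{hclust}}.
#' @return An \code{hclust} dendrogram.
#' @export
cluster_species <- function(matrix, method = "average") {
  if (!isSymmetric(unname(matrix), tol = 1e-12))
    stop("matrix must be symmetric")
  stats::hclust(stats::as.dist(matrix), method = method)
}
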