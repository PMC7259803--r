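## Bipartition (split) machinery. A split is stored as a canonical string
## key: the sorted tip labels of the side NOT containing the alphabetically
## smallest leaf, comma-joined. Only non-trivial splits (both sides >= 2
## leaves) are kept; trees are treated as unrooted throughout.

.tree_splits <- function(tree) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  if (ntip < 4L) return(character(0))
  desc <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- i
  eo <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(eo$edge))) {
    p <- eo$edge[e, 1L]; ch <- eo$edge[e, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  ref <- sort(tree$tip.label)[1L]
  keys <- character(0)
  internal_children <- unique(eo$edge[eo$edge[, 2L] > ntip, 2L])
  for (v in internal_children) {
    tips <- tree$tip.label[desc[[v]]]
    if (length(tips) < 2L || length(tips) > ntip - 2L) next
    side <- if (ref %in% tips) setdiff(tree$tip.label, tips) else tips
    keys <- c(keys, paste(sort(side), collapse = ","))
  }
  unique(keys)
}

.split_key <- function(side, all_labels) {
  ref <- sort(all_labels)[1L]
  if (ref %in% side) side <- setdiff(all_labels, side)
  paste(sort(side), collapse = ",")
}

#' Robinson-Foulds distance between two trees
#'
#' The number of non-trivial bipartitions present in exactly one of the two
#' unrooted trees (unnormalized symmetric difference); the normalized variant
#' divides by \eqn{2(n-3)}, the maximum for two binary trees.
#'
#' @param t1,t2 \code{phylo} trees on the same leaf set.
#' @param normalized Return distance divided by \eqn{2(n-3)}?
#' @return Numeric distance.
#' @export
rf_distance <- function(t1, t2, normalized = FALSE) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    d <- c(setdiff(t1$tip.label, t2$tip.label),
           setdiff(t2$tip.label, t1$tip.label))
    stop("trees have different leaf sets; symmetric difference: ",
         paste(d, collapse = ", "))
  }
  s1 <- .tree_splits(t1); s2 <- .tree_splits(t2)
  d <- length(setdiff(s1, s2)) + length(setdiff(s2, s1))
  if (normalized) {
    n <- length(t1$tip.label)
    if (n > 3L) d <- d / (2 * (n - 3L))
  }
  d
}

#' Pairwise Robinson-Foulds distance matrix
#'
#' @param trees A \code{multiPhylo} list (or \code{tree_set}) on one leaf
#'   set.
#' @param normalized Passed to \code{\link{rf_distance}}.
#' @return Symmetric matrix of RF distances, zero diagonal.
#' @export
rf_matrix <- function(trees, normalized = FALSE) {
  if (inherits(trees, "tree_set")) trees <- trees$trees
  n <- length(trees)
  labs <- lapply(trees, function(t) sort(t$tip.label))
  if (length(unique(labs)) != 1L)
    stop("all trees must share one leaf set")
  splits <- lapply(trees, .tree_splits)
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- length(setdiff(splits[[i]], splits[[j]])) +
        length(setdiff(splits[[j]], splits[[i]]))
      m[i, j] <- m[j, i] <- d
    }
  }
  if (normalized) {
    ntip <- length(labs[[1L]])
    if (ntip > 3L) m <- m / (2 * (ntip - 3L))
  }
  m
}

#' Classical (Torgerson) MDS embedding of a distance matrix
#'
#' Double-centers \eqn{-\tfrac12 D^2} and takes the top eigenpairs;
#' coordinates are eigenvectors scaled by the square root of their (positive)
#' eigenvalues. Axes whose eigenvalue is not positive are dropped with a
#' warning. Sign convention: each axis is flipped so its first nonzero
#' coordinate is positive, making embeddings reproducible.
#'
#' @param D Symmetric non-negative distance matrix.
#' @param dims Target dimensionality (2 or 3 typical).
#' @return List: \code{coords} (n x dims', dims' <= dims), \code{eig}
#'   (all eigenvalues).
#' @export
mds_embed <- function(D, dims = 2L) {
  D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("D must be symmetric")
  if (any(D < 0)) stop("D must be non-negative")
  if (all(D == 0)) {
    return(list(coords = matrix(0, nrow(D), dims), eig = rep(0, nrow(D))))
  }
  fit <- stats::cmdscale(stats::as.dist(D), k = dims, eig = TRUE)
  co <- fit$points
  if (is.null(dim(co))) co <- matrix(co, ncol = 1L)
  if (ncol(co) < dims)
    warning(sprintf("only %d positive eigenvalue axes available (asked %d)",
                    ncol(co), dims))
  for (j in seq_len(ncol(co))) {
    nz <- which(abs(co[, j]) > 1e-12)
    if (length(nz) && co[nz[1L], j] < 0) co[, j] <- -co[, j]
  }
  list(coords = co, eig = fit$eig)
}

#' PAM clustering with gap-statistic model selection
#'
#' Embeds a tree (or any) distance matrix by classical MDS, runs partitioning
#' around medoids for each \eqn{k = 1..k_{max}}, and selects \eqn{k^*} by the
#' gap statistic against \code{B} uniform reference datasets drawn over the
#' bounding box of the coordinates: the smallest \eqn{k} with
#' \eqn{Gap(k) \ge Gap(k+1) - s_{k+1}}.
#'
#' Tree sets contain many exact topological duplicates, which collapse to
#' zero-width point masses in the embedding; left in place they make the gap
#' curve increase all the way to \code{k_max} (splitting a tight satellite
#' group off a zero-width core always pays). Model selection is therefore
#' run on the distinct points only (\code{collapse_duplicates}, default on),
#' with every item then assigned its representative's cluster. The
#' within-cluster dispersion uses squared distances, as in the original gap
#' formulation.
#'
#' @param x Either a symmetric distance matrix (embedded by
#'   \code{\link{mds_embed}} first) or an n x d coordinate matrix.
#' @param k_max Largest cluster count tried.
#' @param B Reference datasets for the gap statistic.
#' @param seed Integer seed (reference draws).
#' @param dims MDS dimensionality when \code{x} is a distance matrix
#'   (default 3: the third axis captures the local neighbourhood structure
#'   around each common topology, stabilising the gap curve).
#' @param collapse_duplicates Run PAM and the gap statistic on distinct
#'   coordinates only (recommended for tree distances).
#' @return List: \code{k_star}, \code{assignment} (all n items),
#'   \code{gap_curve} (data frame with \code{k}, \code{gap}, \code{se}),
#'   \code{coords}, \code{n_distinct}.
#' @export
pam_gap <- function(x, k_max = 10L, B = 50L, seed = 1L, dims = 3L,
                    collapse_duplicates = TRUE) {
  x <- as.matrix(x)
  is_dist <- nrow(x) == ncol(x) && isSymmetric(unname(x), tol = 1e-8) &&
    all(abs(diag(x)) < 1e-12)
  n <- nrow(x)
  if (n < k_max + 1L) stop("need at least k_max + 1 items")
  if (is_dist) {
    ## deduplicate BEFORE embedding: items at distance zero from each other
    ## are one point; leaving them in would weight the MDS geometry by
    ## multiplicity
    key <- apply(round(x, 8L), 1L, paste, collapse = "|")
    rep_idx <- if (collapse_duplicates) which(!duplicated(key))
    else seq_len(n)
    uco <- mds_embed(x[rep_idx, rep_idx, drop = FALSE], dims = dims)$coords
    coords <- NULL
  } else {
    coords <- x
    key <- apply(round(coords, 8L), 1L, paste, collapse = "|")
    rep_idx <- if (collapse_duplicates) which(!duplicated(key))
    else seq_len(n)
    uco <- coords[rep_idx, , drop = FALSE]
  }
  if (is.null(coords)) coords <- uco[match(key, key[rep_idx]), , drop = FALSE]
  if (nrow(uco) < 2L || all(stats::dist(uco) < 1e-12)) {
    return(list(k_star = 1L, assignment = rep(1L, n),
                gap_curve = NULL, coords = coords,
                n_distinct = nrow(uco)))
  }
  kmax_eff <- min(k_max, nrow(uco) - 1L)
  set.seed(seed)
  cg <- cluster::clusGap(uco,
                         FUNcluster = function(xx, k)
                           list(cluster = cluster::pam(xx, k,
                                                       cluster.only = TRUE)),
                         K.max = kmax_eff, B = B, spaceH0 = "original",
                         d.power = 2, verbose = FALSE)
  tab <- cg$Tab
  k_star <- cluster::maxSE(tab[, "gap"], tab[, "SE.sim"],
                           method = "Tibs2001SEmax")
  uassign <- if (k_star == 1L) rep(1L, nrow(uco))
  else cluster::pam(uco, k_star, cluster.only = TRUE)
  assignment <- uassign[match(key, key[rep_idx])]
  list(k_star = as.integer(k_star), assignment = assignment,
       gap_curve = data.frame(k = seq_len(kmax_eff), gap = tab[, "gap"],
                              se = tab[, "SE.sim"]),
       coords = coords, n_distinct = nrow(uco))
}

#' Gene concordance factors along a species tree
#'
#' For each internal branch of the species tree, the gene concordance factor
#' is the percentage of decisive gene trees whose topology contains the
#' branch's bipartition (restricted to the gene tree's leaves). A gene tree
#' is decisive for a branch when it carries at least one leaf from each of
#' the subtrees adjacent to that branch (the four groups around an internal
#' branch of a binary tree), so that it could in principle resolve it.
#'
#' @param species_tree \code{phylo}; leaf labels are species.
#' @param gene_trees \code{multiPhylo}/\code{tree_set}; leaf sets must be
#'   subsets of the species-tree leaves.
#' @return Data frame with one row per internal species-tree branch:
#'   \code{branch} (canonical split key), \code{gcf} (percent),
#'   \code{n_concordant}, \code{n_decisive}.
#' @export
gene_concordance <- function(species_tree, gene_trees) {
  if (inherits(gene_trees, "tree_set")) gene_trees <- gene_trees$trees
  st <- ape::unroot(species_tree)
  labs <- st$tip.label
  for (gt in gene_trees)
    if (!all(gt$tip.label %in% labs))
      stop("gene-tree leaves must be a subset of species-tree leaves")
  ntip <- length(labs)
  nnode <- st$Nnode
  ## adjacency over the unrooted tree
  adj <- vector("list", ntip + nnode)
  for (e in seq_len(nrow(st$edge))) {
    a <- st$edge[e, 1L]; b <- st$edge[e, 2L]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  comp_tips <- function(start, blocked) {
    ## tips reachable from `start` without crossing node `blocked`
    seen <- c(start); stack <- start
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (w in adj[[v]]) {
        if (w == blocked || w %in% seen) next
        seen <- c(seen, w); stack <- c(stack, w)
      }
    }
    labs[seen[seen <= ntip]]
  }
  gsplits <- lapply(gene_trees, .tree_splits)
  gleaves <- lapply(gene_trees, `[[`, "tip.label")
  internal_edges <- which(st$edge[, 2L] > ntip)
  out <- data.frame(branch = character(0), gcf = numeric(0),
                    n_concordant = integer(0), n_decisive = integer(0),
                    stringsAsFactors = FALSE)
  for (e in internal_edges) {
    u <- st$edge[e, 1L]; v <- st$edge[e, 2L]
    sideA <- comp_tips(v, u)             # tips on the child side
    if (length(sideA) < 2L || length(sideA) > ntip - 2L) next
    groups <- c(lapply(setdiff(adj[[v]], u), comp_tips, blocked = v),
                lapply(setdiff(adj[[u]], v), comp_tips, blocked = u))
    n_dec <- 0L; n_con <- 0L
    for (g in seq_along(gene_trees)) {
      gl <- gleaves[[g]]
      if (!all(vapply(groups, function(gr) any(gr %in% gl), TRUE))) next
      n_dec <- n_dec + 1L
      restA <- intersect(sideA, gl)
      key <- .split_key(restA, gl)
      if (key %in% gsplits[[g]]) n_con <- n_con + 1L
    }
    out <- rbind(out, data.frame(
      branch = .split_key(sideA, labs),
      gcf = if (n_dec > 0L) 100 * n_con / n_dec else NA_real_,
      n_concordant = n_con, n_decisive = n_dec, stringsAsFactors = FALSE))
  }
  out
}

#' Neighbor-joining tree from a locus alignment (JC69 distances)
#'
#' Desk-scale tree builder: Jukes-Cantor distances
#' \eqn{d = -\tfrac34 \ln(1 - \tfrac43 p)} with complete-deletion overlap,
#' then neighbor joining. Saturated pairs (\eqn{p \ge 3/4}) get the distance
#' cap with a warning.
#'
#' @param aln A \code{\link{locus_alignment}} with at least 3 sequences.
#' @param tip_labels Optional labels for the tips (default: row names, i.e.
#'   \code{individual|hN}).
#' @param cap Distance assigned to saturated pairs.
#' @return An unrooted \code{phylo}.
#' @export
build_tree <- function(aln, tip_labels = NULL, cap = 5) {
  stopifnot(inherits(aln, "locus_alignment"))
  if (nrow(aln$seqs) < 3L) stop("need at least 3 sequences")
  dna <- ape::as.DNAbin(aln$seqs)
  d <- ape::dist.dna(dna, model = "JC69", pairwise.deletion = FALSE)
  if (any(is.na(d) | !is.finite(d))) {
    warning("saturated or non-overlapping pairs set to distance cap")
    d[is.na(d) | !is.finite(d)] <- cap
  }
  tr <- ape::nj(d)
  if (!is.null(tip_labels)) {
    idx <- match(tr$tip.label, rownames(aln$seqs))
    tr$tip.label <- tip_labels[idx]
  }
  ape::unroot(tr)
}

#' Within-locus genealogy consistency test
#'
#' Distinguishes rapid speciation (loci disagree with each other, but
#' resamplings within a locus agree) from incomplete lineage sorting or gene
#' flow (disagreement already within loci). Per locus,
#' \code{n_replicates} random one-individual-per-species subsamples are
#' drawn, a neighbor-joining tree is built from each (one random haplotype
#' per chosen individual, tips renamed to species), and the within-locus
#' score is the mean pairwise RF distance among the replicate trees. Each
#' locus is summarised by its majority-rule (50\%) consensus tree, and the
#' between-locus score is the mean pairwise RF among those consensus trees.
#'
#' @param loci List of \code{\link{locus_alignment}}s; each species should
#'   have at least 2 individuals at each locus (loci with missing species are
#'   skipped with a message).
#' @param n_replicates Subsamples per locus.
#' @param seed Integer seed.
#' @param threshold RF score threshold of the verdict: verdict is
#'   \code{"rapid_speciation_like"} iff the median within-locus score is
#'   \code{<= threshold} while the between-locus score exceeds it.
#' @return List of class \code{consistency_report}: \code{per_locus} (data
#'   frame \code{locus}, \code{within_rf}), \code{between_rf},
#'   \code{verdict}, \code{n_skipped}, \code{consensus_trees}.
#' @export
within_locus_consistency <- function(loci, n_replicates = 6L, seed = 1L,
                                     threshold = 0) {
  set.seed(seed)
  species <- sort(unique(unlist(lapply(loci, function(a) a$meta$species))))
  if (length(species) < 4L)
    stop("need at least 4 species for informative topologies")
  per_locus <- data.frame(locus = character(0), within_rf = numeric(0),
                          stringsAsFactors = FALSE)
  cons <- list()
  n_skipped <- 0L
  for (aln in loci) {
    have <- vapply(species, function(sp) {
      ids <- unique(aln$meta$individual[aln$meta$species == sp])
      length(ids) >= 2L
    }, TRUE)
    if (!all(have)) {
      n_skipped <- n_skipped + 1L
      message("skipping locus ", aln$locus_id, ": species missing: ",
              paste(species[!have], collapse = ", "))
      next
    }
    reps <- vector("list", n_replicates)
    for (r in seq_len(n_replicates)) {
      rows <- integer(0)
      for (sp in species) {
        ids <- unique(aln$meta$individual[aln$meta$species == sp])
        id <- sample(ids, 1L)
        cand <- which(aln$meta$individual == id)
        rows <- c(rows, cand[sample.int(length(cand), 1L)])
      }
      sub <- locus_alignment(aln$seqs[rows, , drop = FALSE],
                             aln$meta[rows, , drop = FALSE],
                             locus_id = aln$locus_id)
      reps[[r]] <- build_tree(sub, tip_labels = sub$meta$species)
    }
    within <- rf_matrix(structure(reps, class = "multiPhylo"))
    per_locus <- rbind(per_locus, data.frame(
      locus = aln$locus_id,
      within_rf = mean(within[upper.tri(within)]),
      stringsAsFactors = FALSE))
    cons[[length(cons) + 1L]] <- ape::consensus(reps, p = 0.5)
  }
  if (!nrow(per_locus)) stop("no usable loci")
  between <- if (length(cons) > 1L) {
    bm <- rf_matrix(structure(cons, class = "multiPhylo"))
    mean(bm[upper.tri(bm)])
  } else NA_real_
  verdict <- if (!is.na(between) &&
                 stats::median(per_locus$within_rf) <= threshold &&
                 between > threshold) "rapid_speciation_like"
  else "ils_or_geneflow_like"
  structure(list(per_locus = per_locus, between_rf = between,
                 verdict = verdict, n_skipped = n_skipped,
                 consensus_trees = cons),
            class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf("<consistency_report> %d loci (%d skipped)\n",
              nrow(x$per_locus), x$n_skipped))
  cat(sprintf("  median within-locus RF %.3g | between-locus RF %.3g\n",
              stats::median(x$per_locus$within_rf), x$between_rf))
  cat("  verdict:", x$verdict, "\n")
  invisible(x)
}
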