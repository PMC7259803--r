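#' Simulation configuration for read-count generators
#'
#' Bundles the free parameters of the genotype and read-count simulators:
#' sequencing depth, error rate, ploidy and the inheritance-mode structure of
#' tetraploid genomes. A disomic tetraploid is modelled as two diploid
#' subgenomes; with probability \code{fixed_diff_prob} a site carries a fixed
#' inter-subgenome difference, which forces a balanced (AABB-type) dosage of
#' exactly 2 and is the mechanism behind the excess of intermediate-frequency
#' alleles expected in allotetraploids.
#'
#' @param seed Integer seed; every generator call is deterministic given it.
#' @param n_sites Number of candidate sites to simulate.
#' @param mean_depth Poisson rate of per-site read depth (reads/site); must be
#'   positive. Depth is truncated to at least one read.
#' @param error_rate Per-read base-miscall probability in \code{[0, 0.5)}.
#'   Errors flip a read between the two alleles (symmetric biallelic flip).
#' @param ploidy One of 2, 3, 4.
#' @param inheritance_mode \code{"none"} (single panmictic pool, the default),
#'   \code{"tetrasomic"} (synonym for \code{"none"} at ploidy 4), or
#'   \code{"disomic"} (two subgenomes; ploidy 4 only).
#' @param fixed_diff_prob Probability that a site is a fixed inter-subgenome
#'   difference; only meaningful for disomic tetraploids.
#' @param maf_alpha Shape of the symmetric Beta(\code{maf_alpha},
#'   \code{maf_alpha}) allele-frequency prior. The default 0.2 concentrates
#'   mass near 0 and 1, mimicking a neutral-spectrum excess of rare variants.
#'
#' @return An object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(seed = 1L, n_sites = 5000L, mean_depth = 50,
                       error_rate = 0.005, ploidy = 2L,
                       inheritance_mode = c("none", "tetrasomic", "disomic"),
                       fixed_diff_prob = 0, maf_alpha = 0.2) {
  inheritance_mode <- match.arg(inheritance_mode)
  if (!ploidy %in% c(2L, 3L, 4L))
    stop("ploidy must be 2, 3 or 4")
  if (mean_depth <= 0) stop("mean_depth must be positive")
  if (error_rate < 0 || error_rate >= 0.5)
    stop("error_rate must be in [0, 0.5)")
  if (fixed_diff_prob < 0 || fixed_diff_prob > 1)
    stop("fixed_diff_prob must be in [0, 1]")
  if (inheritance_mode == "disomic" && ploidy != 4L)
    stop("disomic inheritance requires ploidy 4")
  if (inheritance_mode == "tetrasomic" && ploidy != 4L)
    stop("tetrasomic inheritance requires ploidy 4")
  if (maf_alpha <= 0) stop("maf_alpha must be positive")
  structure(list(seed = as.integer(seed), n_sites = as.integer(n_sites),
                 mean_depth = mean_depth, error_rate = error_rate,
                 ploidy = as.integer(ploidy),
                 inheritance_mode = inheritance_mode,
                 fixed_diff_prob = fixed_diff_prob, maf_alpha = maf_alpha),
            class = "sim_config")
}

#' Simulate per-site alternate-allele dosages
#'
#' Draws a population allele frequency \eqn{q} per site from the
#' Beta(\code{maf_alpha}, \code{maf_alpha}) prior and a genotype dosage
#' \eqn{k}:
#' \itemize{
#'   \item diploid/triploid or tetrasomic tetraploid: \eqn{k \sim
#'     Binomial(ploidy, q)} — one panmictic pool of homologues;
#'   \item disomic tetraploid: \eqn{k = Binomial(2, q_1) + Binomial(2, q_2)},
#'     and with probability \code{fixed_diff_prob} the site is a fixed
#'     inter-subgenome difference (\eqn{q_1 = 0, q_2 = 1}), giving dosage
#'     exactly 2.
#' }
#'
#' @param cfg A \code{\link{sim_config}}.
#' @param biallelic_only If TRUE, sites whose realized dosage is invariant
#'   (0 or ploidy) are redrawn until heterozygous, so all \code{n_sites}
#'   sites are biallelic within the individual — the conditional
#'   distribution given heterozygosity. Used to simulate a target number of
#'   biallelic sites directly.
#' @return A list of class \code{genotype_vector} with integer \code{dosages},
#'   \code{site_truth} (\code{"invariant"} or \code{"biallelic"} within the
#'   individual), \code{fixed_diff} logical, and the \code{cfg}.
#' @export
simulate_genotypes <- function(cfg, biallelic_only = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_sites
  p <- cfg$ploidy
  draw <- function(m) {
    q <- stats::rbeta(m, cfg$maf_alpha, cfg$maf_alpha)
    if (cfg$inheritance_mode == "disomic") {
      fixed <- stats::runif(m) < cfg$fixed_diff_prob
      dos <- stats::rbinom(m, 2L, q) + stats::rbinom(m, 2L, q)
      dos[fixed] <- 2L
    } else {
      fixed <- rep(FALSE, m)
      dos <- stats::rbinom(m, p, q)
    }
    list(dos = dos, fixed = fixed)
  }
  d <- draw(n)
  dos <- d$dos; fixed <- d$fixed
  if (biallelic_only) {
    redo <- which(dos == 0L | dos == p)
    while (length(redo)) {
      d <- draw(length(redo))
      dos[redo] <- d$dos; fixed[redo] <- d$fixed
      redo <- redo[dos[redo] == 0L | dos[redo] == p]
    }
  }
  truth <- ifelse(dos > 0L & dos < p, "biallelic", "invariant")
  structure(list(dosages = dos, site_truth = truth, fixed_diff = fixed,
                 cfg = cfg),
            class = "genotype_vector")
}

#' Simulate read counts at simulated genotypes
#'
#' Per site, read depth is Poisson(\code{mean_depth}) truncated to at least
#' one read, and the alternate-read count is Binomial(depth, \eqn{f}) with
#' \eqn{f = (k/p)(1 - \epsilon) + (1 - k/p)\epsilon}: each read samples a
#' homologue uniformly and is flipped to the other allele with probability
#' \eqn{\epsilon}.
#'
#' @param gt A \code{genotype_vector} from \code{\link{simulate_genotypes}}.
#' @param cfg The \code{\link{sim_config}} used (depth/error parameters).
#' @param individual_id,species,locus Labels stamped on the output rows.
#' @return A site allele-count table: data frame with columns
#'   \code{individual}, \code{species}, \code{locus}, \code{site} (0-based),
#'   \code{countA} (reference-allele reads), \code{countB} (alternate reads),
#'   \code{countOther}.
#' @export
simulate_read_counts <- function(gt, cfg = gt$cfg, individual_id = "ind1",
                                 species = "sp1", locus = "L1") {
  stopifnot(inherits(gt, "genotype_vector"))
  n <- length(gt$dosages)
  if (any(gt$dosages < 0L | gt$dosages > cfg$ploidy))
    stop("dosages inconsistent with cfg ploidy")
  set.seed(cfg$seed + 1L)
  depth <- stats::rpois(n, cfg$mean_depth)
  while (any(depth == 0L))          # truncate to >= 1 read per site
    depth[depth == 0L] <- stats::rpois(sum(depth == 0L), cfg$mean_depth)
  f <- (gt$dosages / cfg$ploidy) * (1 - cfg$error_rate) +
    (1 - gt$dosages / cfg$ploidy) * cfg$error_rate
  b <- stats::rbinom(n, depth, f)
  data.frame(individual = individual_id, species = species, locus = locus,
             site = seq_len(n) - 1L, countA = depth - b, countB = b,
             countOther = 0L, stringsAsFactors = FALSE)
}

#' Simulate read counts for diploid individuals of two sister species
#'
#' Builds the substrate of the in-silico tetraploid construction: per site,
#' with probability \code{fixed_diff_prob} the species carry a fixed
#' difference (allele frequencies 0 and 1, orientation random), otherwise
#' they share a common frequency drawn from the
#' Beta(\code{maf_alpha}, \code{maf_alpha}) prior. Each individual's dosage
#' is Binomial(2, frequency of its species) and read counts follow
#' \code{\link{simulate_read_counts}}'s depth/error model. Combining two
#' conspecific individuals therefore emulates a tetrasomic autotetraploid,
#' while combining across species adds balanced intermediate-frequency
#' (AABB-type) sites at the fixed differences — the disomic allotetraploid
#' expectation.
#'
#' @param n_per_species Diploid individuals per species.
#' @param n_sites Sites per individual.
#' @param fixed_diff_prob Fraction of sites fixed between the species.
#' @param mean_depth,error_rate,maf_alpha As in \code{\link{sim_config}}.
#' @param seed Integer seed.
#' @param species Labels of the two species.
#' @return One site allele-count data frame holding all individuals
#'   (\code{individual} = \code{spX_dN}).
#' @export
simulate_diploid_species_pair <- function(n_per_species = 8L,
                                          n_sites = 5000L,
                                          fixed_diff_prob = 0.05,
                                          mean_depth = 50, error_rate = 0.005,
                                          maf_alpha = 0.2, seed = 1L,
                                          species = c("spA", "spB")) {
  set.seed(seed)
  n <- as.integer(n_sites)
  fixed <- stats::runif(n) < fixed_diff_prob
  q_shared <- stats::rbeta(n, maf_alpha, maf_alpha)
  orient <- stats::runif(n) < 0.5
  q1 <- ifelse(fixed, ifelse(orient, 0, 1), q_shared)
  q2 <- ifelse(fixed, ifelse(orient, 1, 0), q_shared)
  out <- vector("list", 2L * n_per_species)
  idx <- 0L
  for (s in 1:2) {
    qs <- if (s == 1L) q1 else q2
    for (i in seq_len(n_per_species)) {
      dos <- stats::rbinom(n, 2L, qs)
      depth <- stats::rpois(n, mean_depth)
      while (any(depth == 0L))
        depth[depth == 0L] <- stats::rpois(sum(depth == 0L), mean_depth)
      f <- (dos / 2) * (1 - error_rate) + (1 - dos / 2) * error_rate
      b <- stats::rbinom(n, depth, f)
      idx <- idx + 1L
      out[[idx]] <- data.frame(
        individual = sprintf("%s_d%d", species[s], i),
        species = species[s], locus = "L1", site = seq_len(n) - 1L,
        countA = depth - b, countB = b, countOther = 0L,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

## ---- coalescent alignment simulator -------------------------------------

#' Simulate a neutral coalescent locus alignment
#'
#' Standard single-population coalescent (Hudson's algorithm): with \eqn{j}
#' lineages the waiting time to the next coalescence is exponential with rate
#' \eqn{\binom{j}{2}} (in units of \eqn{2N} generations). Under exponential
#' growth at rate \code{growth} the population was smaller in the past, so the
#' coalescence hazard at time \eqn{t} is inflated by \eqn{e^{growth\, t}} and
#' waiting times are obtained by inverting the cumulative hazard. Mutations
#' follow the infinite-sites model: the total number is Poisson with mean
#' \eqn{\theta T_{total}/2}, each placed uniformly on the genealogy's total
#' branch length and assigned its own alignment column.
#'
#' @param n_haplotypes Sample size (>= 2).
#' @param theta Population mutation rate \eqn{\theta = 4N\mu} per locus.
#' @param growth Exponential growth rate (0 = constant size).
#' @param locus_length Alignment length in sites; must be at least the
#'   realized number of segregating sites (error otherwise).
#' @param seed Integer seed.
#' @param individuals Optional row metadata recycled across haplotypes; by
#'   default haplotypes are assigned in pairs to diploid individuals.
#' @param species Species label for all rows.
#' @return A \code{\link{locus_alignment}}; attribute \code{genealogy} holds
#'   the true tree (class \code{phylo}) and \code{n_mutations} the realized
#'   segregating-site count.
#' @export
simulate_coalescent_alignment <- function(n_haplotypes, theta, growth = 0,
                                          locus_length = 1000L, seed = 1L,
                                          species = "sp1",
                                          locus_id = "L1") {
  if (n_haplotypes < 2L) stop("n_haplotypes must be >= 2")
  if (theta < 0) stop("theta must be >= 0")
  set.seed(seed)
  n <- as.integer(n_haplotypes)

  ## genealogy: node times and topology by random pair merging
  active <- as.list(seq_len(n))          # tip sets of active lineages
  blen <- numeric(0)                     # per-branch lengths
  bset <- list()                         # per-branch descendant tip sets
  born <- rep(0, n)                      # time each active lineage started
  t_now <- 0
  merges <- matrix(0L, nrow = n - 1L, ncol = 2L)
  mtimes <- numeric(n - 1L)
  lin_id <- seq_len(n)                   # ids: tips 1..n, internals n+1..
  next_id <- n + 1L
  id_of <- seq_len(n)
  while (length(active) > 1L) {
    j <- length(active)
    rate <- j * (j - 1) / 2
    e <- stats::rexp(1L)
    if (growth == 0) {
      w <- e / rate
    } else {
      ## hazard rate * exp(growth * t); invert cumulative hazard from t_now
      w <- log(exp(growth * t_now) + growth * e / rate) / growth - t_now
    }
    t_now <- t_now + w
    pick <- sample.int(j, 2L)
    a <- min(pick); b <- max(pick)
    for (idx in c(a, b)) {
      blen <- c(blen, t_now - born[idx])
      bset <- c(bset, list(active[[idx]]))
    }
    merges[n - j + 1L, ] <- c(id_of[a], id_of[b])
    mtimes[n - j + 1L] <- t_now
    active[[a]] <- c(active[[a]], active[[b]])
    id_of[a] <- next_id
    next_id <- next_id + 1L
    born[a] <- t_now
    active <- active[-b]
    id_of <- id_of[-b]
    born <- born[-b]
  }

  t_total <- sum(blen)
  n_mut <- if (theta > 0) stats::rpois(1L, theta * t_total / 2) else 0L
  if (n_mut > locus_length)
    stop(sprintf(
      "locus_length (%d) smaller than realized segregating sites (%d)",
      locus_length, n_mut))

  seqs <- matrix("a", nrow = n, ncol = locus_length)
  if (n_mut > 0L) {
    branch <- sample.int(length(blen), n_mut, replace = TRUE, prob = blen)
    cols <- sample.int(locus_length, n_mut)   # infinite sites: distinct cols
    for (m in seq_len(n_mut)) {
      carriers <- bset[[branch[m]]]
      seqs[carriers, cols[m]] <- "g"
    }
  }

  ## genealogy as ape phylo via newick assembly
  lbl <- paste0("h", seq_len(n))
  nwk <- as.list(lbl)
  tdone <- rep(0, n)
  node_nwk <- vector("list", 2L * n - 1L)
  node_t <- c(rep(0, n), rep(NA_real_, n - 1L))
  for (i in seq_len(n)) node_nwk[[i]] <- lbl[i]
  for (m in seq_len(n - 1L)) {
    c1 <- merges[m, 1L]; c2 <- merges[m, 2L]
    tm <- mtimes[m]
    node_nwk[[n + m]] <- sprintf("(%s:%f,%s:%f)", node_nwk[[c1]],
                                 tm - node_t[c1], node_nwk[[c2]],
                                 tm - node_t[c2])
    node_t[n + m] <- tm
  }
  gen <- ape::read.tree(text = paste0(node_nwk[[2L * n - 1L]], ";"))

  meta <- data.frame(
    individual = paste0("ind", ceiling(seq_len(n) / 2)),
    haplotype = ((seq_len(n) - 1L) %% 2L) + 1L,
    species = species, ploidy = 2L, stringsAsFactors = FALSE)
  aln <- locus_alignment(seqs, meta, locus_id = locus_id)
  attr(aln, "genealogy") <- gen
  attr(aln, "n_mutations") <- n_mut
  aln
}

#' Simulate an alignment on a fixed tree under Jukes-Cantor
#'
#' Finite-sites companion to the infinite-sites coalescent generator, used to
#' build fixtures for distance-based tree estimation: sequences evolve down
#' \code{tree} (branch lengths in expected substitutions per site) under the
#' JC69 model.
#'
#' @param tree An \code{ape} \code{phylo} with branch lengths.
#' @param locus_length Number of sites.
#' @param seed Integer seed.
#' @param meta Optional row metadata (defaults: each tip is one haplotype of
#'   its own diploid individual, species = tip label).
#' @return A \code{\link{locus_alignment}} with rows in tip-label order.
#' @export
simulate_jc_alignment <- function(tree, locus_length = 500L, seed = 1L,
                                  meta = NULL, locus_id = "L1") {
  stopifnot(inherits(tree, "phylo"))
  set.seed(seed)
  bases <- c("a", "c", "g", "t")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  root <- ntip + 1L
  seqs <- matrix(NA_character_, nrow = ntip + nnode, ncol = locus_length)
  seqs[root, ] <- sample(bases, locus_length, replace = TRUE)
  ## preorder traversal
  eo <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(eo$edge))) {
    par <- eo$edge[e, 1L]; chd <- eo$edge[e, 2L]
    bl <- eo$edge.length[e]
    p_change <- 0.75 * (1 - exp(-4 * bl / 3))
    x <- seqs[par, ]
    hit <- stats::runif(locus_length) < p_change
    if (any(hit)) {
      for (i in which(hit)) x[i] <- sample(setdiff(bases, x[i]), 1L)
    }
    seqs[chd, ] <- x
  }
  tipseq <- seqs[seq_len(ntip), , drop = FALSE]
  if (is.null(meta)) {
    meta <- data.frame(individual = tree$tip.label, haplotype = 1L,
                       species = tree$tip.label, ploidy = 2L,
                       stringsAsFactors = FALSE)
  }
  locus_alignment(tipseq, meta, locus_id = locus_id)
}

#' Simulate a set of gene trees from a topology mixture
#'
#' Each tree is drawn from \code{base_topologies} with the given weights and
#' perturbed by one random nearest-neighbour interchange with probability
#' \code{nni_prob}. Emulates gene-tree sets whose distribution in tree space
#' is clustered around a few underlying histories.
#'
#' @param base_topologies List of \code{phylo} trees sharing one leaf set.
#' @param weights Mixture weights, summing to 1.
#' @param nni_prob Probability that a sampled tree receives one random NNI.
#' @param n_trees Number of trees to draw.
#' @param seed Integer seed.
#' @return A list of class \code{tree_set}: \code{trees} (class
#'   \code{multiPhylo}), \code{truth} (base-topology index per tree),
#'   \code{perturbed} (logical).
#' @export
simulate_gene_trees <- function(base_topologies, weights = NULL,
                                nni_prob = 0, n_trees = 100L, seed = 1L) {
  if (is.null(weights))
    weights <- rep(1 / length(base_topologies), length(base_topologies))
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  tips <- lapply(base_topologies, function(t) sort(t$tip.label))
  if (length(unique(tips)) != 1L)
    stop("base topologies must share one leaf set")
  set.seed(seed)
  idx <- sample.int(length(base_topologies), n_trees, replace = TRUE,
                    prob = weights)
  pert <- stats::runif(n_trees) < nni_prob
  trees <- vector("list", n_trees)
  for (i in seq_len(n_trees)) {
    tr <- base_topologies[[idx[i]]]
    if (pert[i]) tr <- phangorn::rNNI(tr, moves = 1L)
    trees[[i]] <- tr
  }
  class(trees) <- "multiPhylo"
  structure(list(trees = trees, truth = idx, perturbed = pert),
            class = "tree_set")
}

#' Simulate a pair of suitability rasters with known suitable areas
#'
#' Builds "current" and "past" presence-probability rasters on the same grid:
#' exactly \code{current_suitable_cells} (resp. \code{past_suitable_cells})
#' cells get probabilities in \code{[0.8, 1)} and the remainder in
#' \code{[0, 0.8)}, so the thresholded areas at the 0.8 cutoff are exact by
#' construction.
#'
#' @param nrow,ncol Grid dimensions.
#' @param current_suitable_cells,past_suitable_cells Planted suitable-cell
#'   counts.
#' @param seed Integer seed.
#' @param xll,yll,cellsize Georeferencing of the lower-left corner and cell
#'   size (degrees).
#' @return List with elements \code{current} and \code{past}, each a
#'   \code{\link{suit_raster}}.
#' @export
simulate_raster_pair <- function(nrow, ncol, current_suitable_cells,
                                 past_suitable_cells, seed = 1L,
                                 xll = 110, yll = -40, cellsize = 0.5) {
  ncell <- nrow * ncol
  if (current_suitable_cells > ncell || past_suitable_cells > ncell)
    stop("suitable cell counts must not exceed nrow * ncol")
  set.seed(seed)
  make <- function(k) {
    v <- 0.8 * stats::runif(ncell)
    if (k > 0) {
      pick <- sample.int(ncell, k)
      v[pick] <- 0.8 + 0.2 * stats::runif(k)
    }
    suit_raster(matrix(v, nrow = nrow, ncol = ncol), xll = xll, yll = yll,
                cellsize = cellsize)
  }
  list(current = make(current_suitable_cells), past = make(past_suitable_cells))
}
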