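test_that("RF distance matches definitions on small trees", {
  t1 <- ape::read.tree(text = "((a,b),(c,d));")
  t2 <- ape::read.tree(text = "((a,c),(b,d));")
  expect_equal(rf_distance(t1, t1), 0)
  expect_equal(rf_distance(t1, t2), 2)   # the two distinct 4-leaf topologies
  expect_equal(rf_distance(t1, t2, normalized = TRUE), 1)
  t3 <- ape::read.tree(text = "((a,b),(c,e));")
  expect_error(rf_distance(t1, t3), "symmetric difference")
})

test_that("RF equals independent oracles on random 8-leaf trees", {
  set.seed(8)
  trees <- lapply(1:30, function(i) ape::rtree(8, rooted = FALSE))
  class(trees) <- "multiPhylo"
  m <- rf_matrix(trees)
  # established independent implementation over all pairs
  mp <- as.matrix(phangorn::RF.dist(trees))
  expect_true(all(m == mp))
  # exhaustive subset-enumeration oracle on a few pairs
  for (k in 1:5) {
    i <- sample(30, 1); j <- sample(30, 1)
    expect_equal(m[i, j], oracle_rf(trees[[i]], trees[[j]]))
  }
})

test_that("RF is a metric on sampled triples", {
  set.seed(9)
  trees <- lapply(1:12, function(i) ape::rtree(7, rooted = FALSE))
  class(trees) <- "multiPhylo"
  m <- rf_matrix(trees)
  expect_true(all(m == t(m)))
  expect_true(all(diag(m) == 0))
  for (r in 1:30) {
    ijk <- sample(12, 3)
    expect_lte(m[ijk[1], ijk[3]], m[ijk[1], ijk[2]] + m[ijk[2], ijk[3]])
  }
})

test_that("classical MDS reproduces Euclidean configurations", {
  set.seed(10)
  pts <- matrix(rnorm(24), ncol = 2)
  D <- as.matrix(dist(pts))
  emb <- mds_embed(D, dims = 2)
  expect_equal(as.matrix(dist(emb$coords)), D, tolerance = 1e-8,
               ignore_attr = TRUE)
  # collinear points embed exactly in 1-D
  pts1 <- cbind(c(0, 1, 3, 7))
  D1 <- as.matrix(dist(pts1))
  emb1 <- suppressWarnings(mds_embed(D1, dims = 1))
  expect_equal(as.matrix(dist(emb1$coords)), D1, tolerance = 1e-8,
               ignore_attr = TRUE)
  # deterministic sign convention
  e2 <- mds_embed(D, dims = 2)
  expect_identical(emb$coords, e2$coords)
})

test_that("PAM + gap statistic recovers planted cluster structure", {
  set.seed(11)
  blobs <- rbind(matrix(rnorm(60, 0, 0.2), ncol = 2),
                 matrix(rnorm(60, 5, 0.2), ncol = 2))
  res <- pam_gap(blobs, k_max = 6, B = 25, seed = 2)
  expect_equal(res$k_star, 2L)
  expect_equal(length(unique(res$assignment[1:30])), 1L)
  expect_equal(length(unique(res$assignment[31:60])), 1L)
  # degenerate all-identical input
  res1 <- pam_gap(matrix(1, 20, 2), k_max = 5, B = 10, seed = 1)
  expect_equal(res1$k_star, 1L)
  # single blob: k = 1
  one <- matrix(rnorm(80), ncol = 2)
  res2 <- pam_gap(one, k_max = 6, B = 25, seed = 3)
  expect_equal(res2$k_star, 1L)
})

test_that("two-topology gene-tree sets embed as two clusters", {
  t1 <- ape::read.tree(text = "((a,b),(c,d),(e,(f,(g,h))));")
  t2 <- ape::read.tree(text = "((a,h),(g,b),(c,(f,(e,d))));")
  ts <- simulate_gene_trees(list(t1, t2), weights = c(0.5, 0.5),
                            nni_prob = 0.2, n_trees = 80, seed = 13)
  D <- rf_matrix(ts)
  res <- pam_gap(D, k_max = 6, B = 25, seed = 4)
  expect_equal(res$k_star, 2L)
  # cluster assignment recovers the generating topology labels
  tab <- table(res$assignment, ts$truth)
  expect_gte(sum(apply(tab, 1, max)) / sum(tab), 0.95)
})

test_that("gene concordance factors count decisive bipartitions", {
  sp <- ape::read.tree(text = "((a,b),(c,d),(e,(f,(g,h))));")
  same <- simulate_gene_trees(list(sp), nni_prob = 0, n_trees = 20, seed = 1)
  gcf <- gene_concordance(sp, same)
  expect_equal(nrow(gcf), 5L)            # 8-leaf unrooted binary: n-3 splits
  expect_true(all(gcf$gcf == 100))
  expect_true(all(gcf$n_decisive == 20L))
  # 50/50 mixture of one-NNI neighbours: affected branch 50, others 100
  # (the NNI moves b out of the (a,b) cherry, replacing the a,b split by
  # a,c,d; all other splits are shared)
  alt <- ape::read.tree(text = "((a,(c,d)),b,(e,(f,(g,h))));")
  expect_equal(rf_distance(sp, alt), 2)
  mix <- c(rep(list(sp), 10), rep(list(alt), 10))
  class(mix) <- "multiPhylo"
  gcf2 <- gene_concordance(sp, mix)
  affected <- gcf2$branch == "c,d,e,f,g,h"  # canonical key of the a,b split
  expect_equal(sum(affected), 1L)
  expect_equal(gcf2$gcf[affected], 50)
  expect_true(all(gcf2$gcf[!affected] == 100))
  # oracle equivalence: direct bipartition counting on random mixtures
  ts <- simulate_gene_trees(list(sp, alt), weights = c(0.7, 0.3),
                            nni_prob = 0.3, n_trees = 60, seed = 21)
  gcf3 <- gene_concordance(sp, ts)
  for (r in seq_len(nrow(gcf3))) {
    side <- strsplit(gcf3$branch[r], ",")[[1]]
    hits <- vapply(ts$trees, function(gt) oracle_is_split(gt, side), TRUE)
    expect_equal(gcf3$n_concordant[r], sum(hits))
    expect_equal(gcf3$n_decisive[r], 60L)   # full leaf sets are decisive
  }
})

test_that("NJ/JC69 builder recovers generating topologies", {
  # additive JC case
  tr <- ape::read.tree(text = "((a:0.05,b:0.05):0.05,(c:0.05,d:0.05):0.05);")
  aln <- simulate_jc_alignment(tr, locus_length = 2000, seed = 31)
  built <- build_tree(aln, tip_labels = aln$meta$individual)
  expect_equal(rf_distance(built, ape::unroot(tr)), 0)
  # identical sequences: star tree with ~zero branch lengths
  seqs <- matrix("a", 4, 50)
  meta <- data.frame(individual = paste0("i", 1:4), haplotype = 1L,
                     species = paste0("s", 1:4), ploidy = 2L)
  star <- build_tree(locus_alignment(seqs, meta))
  expect_equal(sum(star$edge.length), 0)
  # 6-leaf recovery across seeded replicates
  set.seed(32)
  base <- ape::rtree(6, rooted = FALSE)
  base$edge.length <- pmax(base$edge.length * 0.1, 0.02)
  hit <- 0L
  for (i in 1:20) {
    a <- simulate_jc_alignment(base, locus_length = 500, seed = 600 + i)
    b <- build_tree(a, tip_labels = a$meta$individual)
    hit <- hit + (rf_distance(b, base) == 0)
  }
  expect_gte(hit / 20, 0.95)
})

# build a multi-individual locus alignment evolving on a species topology;
# individuals within a species are identical copies unless swapped later
make_species_locus <- function(sp_tree, n_ind = 2, locus_length = 400,
                               seed = 1, locus_id = "L1") {
  a <- simulate_jc_alignment(sp_tree, locus_length = locus_length,
                             seed = seed, locus_id = locus_id)
  idx <- rep(seq_len(nrow(a$seqs)), each = n_ind)
  seqs <- a$seqs[idx, , drop = FALSE]
  sp <- a$meta$species[idx]
  meta <- data.frame(individual = paste0(sp, "_i", rep(seq_len(n_ind),
                                                       nrow(a$seqs))),
                     haplotype = 1L, species = sp, ploidy = 2L,
                     stringsAsFactors = FALSE)
  locus_alignment(seqs, meta, locus_id = locus_id)
}

test_that("consistency test separates rapid speciation from discordance", {
  sp1 <- ape::read.tree(text = "((A:1,B:1):1,((C:1,D:1):1,E:2):1);")
  sp2 <- ape::read.tree(text = "((A:1,D:1):1,((C:1,B:1):1,E:2):1);")
  sp1$edge.length <- sp1$edge.length * 0.05
  sp2$edge.length <- sp2$edge.length * 0.05
  # no intraspecific variation, loci from two different histories
  loci <- c(lapply(1:4, function(i)
    make_species_locus(sp1, seed = 100 + i, locus_id = paste0("A", i))),
    lapply(1:4, function(i)
      make_species_locus(sp2, seed = 200 + i, locus_id = paste0("B", i))))
  rep1 <- within_locus_consistency(loci, n_replicates = 5, seed = 3)
  expect_true(all(rep1$per_locus$within_rf == 0))
  expect_gt(rep1$between_rf, 0)
  expect_equal(rep1$verdict, "rapid_speciation_like")
  # planted discordant histories within species: swap one individual's
  # sequence between species B and D so subsamples disagree
  loci2 <- lapply(1:6, function(i) {
    a <- make_species_locus(sp1, seed = 300 + i, locus_id = paste0("C", i))
    rb <- which(a$meta$individual == "B_i2")
    rd <- which(a$meta$individual == "D_i2")
    tmp <- a$seqs[rb, ]; a$seqs[rb, ] <- a$seqs[rd, ]; a$seqs[rd, ] <- tmp
    a
  })
  rep2 <- within_locus_consistency(loci2, n_replicates = 6, seed = 4)
  expect_gt(stats::median(rep2$per_locus$within_rf), 0)
  expect_equal(rep2$verdict, "ils_or_geneflow_like")
  # locus with a missing species is skipped with a message
  drop_e <- loci[[1]]
  keep <- drop_e$meta$species != "E"
  loci3 <- c(list(locus_alignment(drop_e$seqs[keep, , drop = FALSE],
                                  drop_e$meta[keep, , drop = FALSE],
                                  locus_id = "noE")), loci[2:5])
  expect_message(rep3 <- within_locus_consistency(loci3, n_replicates = 3,
                                                  seed = 5), "skipping")
  expect_equal(rep3$n_skipped, 1L)
})
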