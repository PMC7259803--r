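# small helper: counts table for one individual with explicit per-site counts
make_counts <- function(id, sp, countA, countB) {
  data.frame(individual = id, species = sp, locus = "L1",
             site = seq_along(countA) - 1L,
             countA = countA, countB = countB, countOther = 0L,
             stringsAsFactors = FALSE)
}

test_that("combining diploids sums counts and realizes the AABB mechanism", {
  a <- make_counts("d1", "X", countA = c(10L, 20L), countB = c(10L, 0L))
  b <- make_counts("d2", "X", countA = c(20L, 0L), countB = c(0L, 20L))
  cmb <- combine_diploids(a, b)
  # het + hom-ref: (A=30, B=10) -> alternate frequency 0.25, a rare-band entry
  expect_equal(cmb$countA[1], 30L)
  expect_equal(cmb$countB[1], 10L)
  # reciprocally fixed site: (A=20, B=20) -> 0.5, an intermediate-band entry
  expect_equal(cmb$countA[2], 20L)
  expect_equal(cmb$countB[2], 20L)
  expect_equal(attr(cmb, "mode"), "within_species")
})

test_that("combine is symmetric and drops non-shared or conflicting sites", {
  a <- make_counts("d1", "X", countA = c(10L, 12L, 9L), countB = c(5L, 3L, 2L))
  b <- make_counts("d2", "Y", countA = c(7L, 8L), countB = c(6L, 1L))
  ab <- combine_diploids(a, b); ba <- combine_diploids(b, a)
  expect_equal(ab$countA, ba$countA)
  expect_equal(ab$countB, ba$countB)
  expect_equal(ab$site, ba$site)
  expect_equal(nrow(ab), 2L)               # site 2 absent from b
  expect_equal(attr(ab, "mode"), "between_species")
  # allele-identity conflict: disjoint allele pairs drop the site
  a2 <- cbind(a, alleleA = "A", alleleB = "C")
  b2 <- cbind(b, alleleA = c("G", "A"), alleleB = c("T", "C"))
  cmb <- combine_diploids(a2, b2)
  expect_equal(nrow(cmb), 1L)
  expect_equal(attr(cmb, "n_conflict_dropped"), 1L)
})

test_that("swapped allele labels are reconciled before summing", {
  a <- make_counts("d1", "X", countA = 10L, countB = 2L)
  a <- cbind(a, alleleA = "A", alleleB = "C")
  b <- make_counts("d2", "X", countA = 3L, countB = 8L)
  b <- cbind(b, alleleA = "C", alleleB = "A")     # same pair, swapped
  cmb <- combine_diploids(a, b)
  expect_equal(cmb$countA, 18L)   # 10 + 8
  expect_equal(cmb$countB, 5L)    # 2 + 3
})

test_that("expectation sets have the right pair combinatorics", {
  dip <- do.call(rbind, lapply(1:4, function(i)
    make_counts(paste0("d", i), if (i <= 2) "X" else "Y",
                countA = c(10L, 10L), countB = c(5L, 5L))))
  es <- build_expectation_sets(dip)
  expect_length(es$auto, 2L)    # one within-X pair + one within-Y pair
  expect_length(es$allo, 4L)    # 2 x 2 between
  # restriction to a species pair
  dip3 <- rbind(dip, make_counts("d5", "Z", c(10L, 10L), c(5L, 5L)))
  expect_warning(es3 <- build_expectation_sets(dip3, species_pair = c("X", "Y")),
                 "no auto pairs")
  expect_length(es3$allo, 4L)   # Z excluded by restriction
  # all within-species pairs of 8 conspecific+4 diploids: C(8,2) = 28
  dip8 <- do.call(rbind, lapply(1:8, function(i)
    make_counts(paste0("a", i), "X", c(10L, 10L), c(5L, 5L))))
  dip8 <- rbind(dip8, make_counts("b1", "Y", c(10L, 10L), c(5L, 5L)),
                make_counts("b2", "Y", c(10L, 10L), c(5L, 5L)))
  es8 <- build_expectation_sets(dip8)
  expect_length(es8$auto, choose(8, 2) + 1L)
})

test_that("intermediate/rare ratio counts the documented bands", {
  fr <- make_freq_set(c(0.5, 0.5, 0.45, 0.55, 0.25, 0.75, 0.2, 0.8))
  rs <- intermediate_rare_ratio(fr)
  expect_equal(rs$n_intermediate, 4L)
  expect_equal(rs$n_rare, 2L)
  expect_equal(rs$ratio, 2)
  # band edges: intermediate closed, rare open below 0.30
  fr2 <- make_freq_set(c(0.40, 0.60, 0.30, 0.70))
  rs2 <- intermediate_rare_ratio(fr2)
  expect_equal(rs2$n_intermediate, 2L)
  expect_equal(rs2$n_rare, 0L)     # 0.30 itself is outside the open band
  expect_false(rs2$defined)
  expect_true(is.na(rs2$ratio))
})

test_that("rare band counts only the low side of the mirror", {
  fr <- make_freq_set(c(0.2, 0.8, 0.25, 0.75))
  rs <- intermediate_rare_ratio(fr)
  expect_equal(rs$n_rare, 2L)      # 0.8 and 0.75 are not rare entries
  # mirroring the input leaves the statistic unchanged (set is symmetric)
  frm <- make_freq_set(1 - fr$freq)
  expect_equal(intermediate_rare_ratio(frm)$n_rare, 2L)
})

test_that("rank-sum comparison matches the exact enumeration oracle", {
  mk <- function(r) data.frame(individual = NA, n_intermediate = 1L,
                               n_rare = 1L, ratio = r, defined = TRUE,
                               group = NA)
  # identical groups: p = 1 (tied ranks, tie-corrected normal path)
  t1 <- compare_groups(mk(c(1, 2, 3)), mk(c(1, 2, 3)))
  expect_equal(t1$p_value, 1, tolerance = 1e-12)
  # fully separated: most extreme split, exact p = 2/20 = 0.1
  t2 <- compare_groups(mk(c(1, 2, 3)), mk(c(10, 11, 12)))
  expect_true(t2$exact)
  expect_equal(t2$p_value, 0.1, tolerance = 1e-12)
  expect_equal(t2$p_value, oracle_wilcox_p(c(1, 2, 3), c(10, 11, 12)),
               tolerance = 1e-12)
  # random case against the oracle
  set.seed(5)
  x <- round(stats::rlnorm(6), 3); y <- round(stats::rlnorm(7) * 1.5, 3)
  t3 <- compare_groups(mk(x), mk(y))
  expect_equal(t3$p_value, oracle_wilcox_p(x, y), tolerance = 1e-12)
})

test_that("null rank-sum comparisons are calibrated at alpha = 0.05", {
  set.seed(99)
  rej <- 0L
  n_pairs <- 200L
  mk <- function(r) data.frame(individual = NA, n_intermediate = 1L,
                               n_rare = 1L, ratio = r, defined = TRUE,
                               group = NA)
  for (i in seq_len(n_pairs)) {
    x <- stats::rlnorm(8); y <- stats::rlnorm(8)
    if (compare_groups(mk(x), mk(y))$p_value < 0.05) rej <- rej + 1L
  }
  expect_gte(rej / n_pairs, 0.01)
  expect_lte(rej / n_pairs, 0.07)
})

test_that("disomic simulation yields larger ratios than tetrasomic", {
  n_rep <- 40L
  wins <- 0L
  for (i in seq_len(n_rep)) {
    cfg_d <- sim_config(seed = 3000 + i, n_sites = 3000, ploidy = 4,
                        inheritance_mode = "disomic", fixed_diff_prob = 0.05)
    cfg_t <- sim_config(seed = 3000 + i, n_sites = 3000, ploidy = 4,
                        inheritance_mode = "tetrasomic")
    r <- function(cfg) {
      rc <- simulate_read_counts(simulate_genotypes(cfg, biallelic_only = TRUE),
                                 cfg)
      intermediate_rare_ratio(extract_biallelic_frequencies(rc))$ratio
    }
    if (r(cfg_d) > r(cfg_t)) wins <- wins + 1L
  }
  expect_gte(wins / n_rep, 0.9)
})

test_that("inheritance classification recovers planted modes", {
  sim_group <- function(mode, seeds, d = 0.05) {
    do.call(rbind, lapply(seeds, function(s) {
      cfg <- sim_config(seed = s, n_sites = 3000, ploidy = 4,
                        inheritance_mode = mode,
                        fixed_diff_prob = if (mode == "disomic") d else 0)
      rc <- simulate_read_counts(
        simulate_genotypes(cfg, biallelic_only = TRUE), cfg)
      intermediate_rare_ratio(extract_biallelic_frequencies(rc))
    }))
  }
  auto <- sim_group("tetrasomic", 4000 + 1:8)
  allo <- sim_group("disomic", 4100 + 1:8)
  obs_t <- sim_group("tetrasomic", 4200 + 1:6)
  obs_d <- sim_group("disomic", 4300 + 1:6)
  call_t <- classify_inheritance(obs_t, auto, allo, species = "simT")
  call_d <- classify_inheritance(obs_d, auto, allo, species = "simD")
  expect_equal(call_t$label, "tetrasomic")
  expect_equal(call_d$label, "disomic")
  # half-and-half observed group exercises the mixed path
  obs_m <- rbind(sim_group("tetrasomic", 4400 + 1:4),
                 sim_group("disomic", 4500 + 1:4))
  call_m <- classify_inheritance(obs_m, auto, allo, species = "simM")
  expect_true(call_m$label %in% c("mixed", "tetrasomic", "disomic"))
  expect_error(classify_inheritance(obs_t[0, ], auto, allo), "nonempty")
})
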