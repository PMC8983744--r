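mk_tab <- function(v_call, duplicate_count = NULL, productive = TRUE,
                   cdr3_aa = "CARW") {
  n <- length(v_call)
  data.frame(sequence_id = sprintf("r%03d", seq_len(n)), v_call = v_call,
             j_call = "J1", productive = rep_len(productive, n),
             cdr3_aa = rep_len(cdr3_aa, n),
             duplicate_count = if (is.null(duplicate_count)) rep(1L, n)
                               else duplicate_count,
             stringsAsFactors = FALSE)
}

test_that("usage frequencies follow read counts and duplicate weights", {
  tab <- mk_tab(c("V1", "V1", "V2", "V3"))
  u <- usage_frequencies(tab, "V")
  expect_equal(u$percent_frequency[match(c("V1", "V2", "V3"), u$segment_id)],
               c(50, 25, 25))
  expect_equal(sum(u$percent_frequency), 100, tolerance = 1e-9)

  tab2 <- mk_tab(c("V1", "V2"), duplicate_count = c(3L, 1L))
  u2 <- usage_frequencies(tab2, "V", weight_by_duplicates = TRUE)
  expect_equal(u2$percent_frequency[match(c("V1", "V2"), u2$segment_id)],
               c(75, 25))
  expect_error(usage_frequencies(tab[0, ], "V"), "empty")
})

test_that("unassigned D calls are excluded from the D denominator", {
  tab <- mk_tab(c("V1", "V1", "V1"))
  tab$d_call <- c("D1", NA, "D2")
  u <- usage_frequencies(tab, "D")
  expect_equal(sort(u$percent_frequency), c(50, 50))
  expect_equal(attr(u, "n_unassigned"), 1)
})

test_that("vdj links count combinations and survive a Circos round trip", {
  tab <- mk_tab(c("V1*01", "V1*01", "V2*01"))
  tab$d_call <- c("D1*01", "D1*01", "D1*01")
  tab$j_call <- c("J1*01", "J1*01", "J2*01")
  lk <- vdj_links(tab)
  expect_equal(nrow(lk), 2L)
  expect_equal(lk$relative_frequency[lk$v_group == "V1"], 2 / 3)
  expect_equal(sum(lk$relative_frequency), 1)
  single <- vdj_links(mk_tab("V9"))
  expect_equal(single$relative_frequency, 1)

  paths <- circos_export(lk, file.path(tempdir(), "circtest"))
  back <- read_circos_links(paths[2])
  expect_equal(back$count, lk$count)
  expect_equal(back$v_group, lk$v_group)
  expect_equal(back$relative_frequency, lk$relative_frequency,
               tolerance = 1e-9)
})

test_that("CDR3 length and composition statistics match direct computation", {
  tab <- mk_tab(c("V1", "V2"), cdr3_aa = c(strrep("A", 10), strrep("A", 20)))
  cl <- cdr3_length_distribution(tab)
  expect_equal(cl$mean_length, 15.00)
  expect_equal(cl$histogram$count, c(1, 1))

  same <- cdr3_length_distribution(mk_tab(c("V1", "V1"), cdr3_aa = "CARDW"))
  expect_equal(nrow(same$histogram), 1L)

  comp <- aa_composition(mk_tab(c("V1", "V2"), cdr3_aa = c("CAR", "CAK")))
  expect_equal(comp$frequency[comp$residue == "C"], 1 / 3)
  expect_equal(comp$frequency[comp$residue == "A"], 1 / 3)
  expect_equal(comp$frequency[comp$residue == "R"], 1 / 6)
  expect_equal(comp$frequency[comp$residue == "K"], 1 / 6)
  expect_equal(sum(comp$frequency), 1)
  # order invariance
  comp2 <- aa_composition(mk_tab(c("V2", "V1"), cdr3_aa = c("CAK", "CAR")))
  expect_equal(comp, comp2)
  expect_error(aa_composition(mk_tab("V1", productive = FALSE)), "no productive")
})

test_that("N/P length distributions concentrate where configured", {
  db <- toy_db()
  sim0 <- simulate_repertoire(db, sim_config(n_reads = 40, n_mean = 0,
                                             p_prob = 0, seed = 31))
  tab0 <- annotate_reads(sim0$reads, db)
  np0 <- np_addition_distribution(tab0)
  expect_equal(np0$n1$length, 0L)
  expect_equal(np0$means[["n1"]], 0)
  expect_equal(np0$means[["p_v"]], 0)
})

test_that("productive fraction is a simple percentage", {
  expect_equal(productive_fraction(mk_tab(c("V1", "V1"), productive = TRUE)), 100)
  expect_equal(productive_fraction(mk_tab(c("V1", "V1"), productive = FALSE)), 0)
  expect_equal(productive_fraction(mk_tab(rep("V1", 4),
                                          productive = c(TRUE, TRUE, TRUE,
                                                         FALSE))), 75)
})

test_that("Shannon-Weaver index obeys its analytic bounds and formula", {
  expect_equal(shannon_index(7)$H_prime, 0)
  for (S in c(2, 5, 11))
    expect_equal(shannon_index(rep(3, S))$H_prime, log(S), tolerance = 1e-12)
  h <- shannon_index(c(5, 3, 2))
  expect_equal(h$H_prime, -(0.5 * log(0.5) + 0.3 * log(0.3) + 0.2 * log(0.2)),
               tolerance = 1e-12)
  expect_equal(h$N, 10)
  expect_equal(h$S, 3)
  expect_error(shannon_index(numeric(0)), "empty")
  expect_error(shannon_index(c(2, 0)), "positive")
})

test_that("Shannon index is permutation-invariant, uniform-maximal and agrees with vegan", {
  skip_if_not_installed("vegan")
  set.seed(5)
  for (rep in 1:20) {
    counts <- sample(1:50, sample(2:10, 1), replace = TRUE)
    h <- shannon_index(counts)$H_prime
    expect_equal(h, shannon_index(sample(counts))$H_prime, tolerance = 1e-12)
    expect_equal(h, unname(vegan::diversity(counts, index = "shannon")),
                 tolerance = 1e-10)
    expect_lte(h, shannon_index(rep(sum(counts), length(counts)))$H_prime +
                 1e-12)
    expect_lte(h, log(length(counts)) + 1e-12)
  }
})

test_that("rarefaction is exact at the extremes and matches enumeration", {
  tab <- mk_tab(rep("V1", 5),
                cdr3_aa = c("CAAW", "CAAW", "CBBW", "CCCW", "CBBW"))
  tab$cdr1_aa <- "AA"; tab$cdr2_aa <- "BB"
  full <- rarefaction_curve(tab, depths = 5, replicates = 3)
  expect_equal(full$mean_distinct, 3)          # S distinct clonotypes
  one <- rarefaction_curve(tab, depths = 1, replicates = 10)
  expect_equal(one$mean_distinct, 1)
  # exhaustive oracle at depth 2: mean distinct over all C(5,2) subsets
  keys <- paste(tab$cdr1_aa, tab$cdr2_aa, tab$cdr3_aa)
  combos <- combn(5, 2)
  exact <- mean(apply(combos, 2, function(i) length(unique(keys[i]))))
  set.seed(9)
  est <- rarefaction_curve(tab, depths = 2, replicates = 4000)$mean_distinct
  expect_lt(abs(est - exact), 0.05)
  # monotone, bounded by S
  set.seed(10)
  curve <- rarefaction_curve(tab, depths = 1:5, replicates = 50)
  expect_true(all(diff(curve$mean_distinct) >= -1e-12))
  expect_true(all(curve$mean_distinct <= 3 + 1e-12))
  expect_error(rarefaction_curve(tab, depths = 6), "exceed")
})
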