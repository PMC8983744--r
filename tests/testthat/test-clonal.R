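mk_reads <- function(n, v = "IGHV1*01", d = "IGHD1*01", j = "IGHJ1*01",
                     cdr1 = "GFTF", cdr2 = "ISGG", cdr3 = "CARDW",
                     dup = 1L, locus = "IGH") {
  data.frame(sequence_id = sprintf("r%04d", seq_len(n)),
             locus = locus, v_call = rep_len(v, n), d_call = rep_len(d, n),
             j_call = rep_len(j, n), cdr1_aa = rep_len(cdr1, n),
             cdr2_aa = rep_len(cdr2, n), cdr3_aa = rep_len(cdr3, n),
             duplicate_count = rep_len(dup, n), stringsAsFactors = FALSE)
}

test_that("clonotype grouping keys on the joined CDR1-2-3 sequence", {
  tab <- rbind(mk_reads(2), mk_reads(1, cdr3 = "CARDF"))
  tab$sequence_id <- sprintf("r%04d", 1:3)
  ct <- group_clonotypes(tab)
  expect_equal(nrow(ct), 2L)
  expect_equal(ct$copy_count, c(2, 1))
  # copies conserved
  expect_equal(sum(ct$copy_count), sum(tab$duplicate_count))
})

test_that("clonotype copy conservation holds on simulated repertoires", {
  db <- toy_db()
  sim <- simulate_repertoire(db, sim_config(n_reads = 100, shm_rate = 0.01,
                                            n_lineages = 8, seed = 44))
  tab <- annotate_reads(sim$reads, db)
  tab$cdr1_aa[is.na(tab$cdr1_aa)] <- ""
  tab$cdr2_aa[is.na(tab$cdr2_aa)] <- ""
  tab$cdr3_aa[is.na(tab$cdr3_aa)] <- ""
  ct <- group_clonotypes(tab)
  expect_equal(sum(ct$copy_count), sum(tab$duplicate_count))
  # partition: every read in exactly one clonotype
  ids <- unlist(strsplit(ct$read_ids, ","))
  expect_setequal(ids, tab$sequence_id)
  expect_equal(length(ids), nrow(tab))
})

test_that("lineage grouping partitions reads and names by rank", {
  tab <- rbind(mk_reads(2, v = "IGHV1*01"), mk_reads(1, v = "IGHV2*01"))
  tab$sequence_id <- sprintf("r%04d", 1:3)
  lin <- group_lineages(tab)
  expect_equal(lin$name, c("CLH001", "CLH002"))
  expect_equal(lin$copy_count, c(2, 1))
  ids <- unlist(strsplit(lin$read_ids, ","))
  expect_setequal(ids, tab$sequence_id)
  expect_equal(length(ids), nrow(tab))
  # light chain naming
  link <- group_lineages(mk_reads(2, locus = "IGK", d = NA))
  expect_equal(link$name, "CLL001")
})

test_that("allele-level grouping separates what gene-level merges", {
  tab <- rbind(mk_reads(1, v = "IGHV1-2*01"), mk_reads(1, v = "IGHV1-2*02"))
  tab$sequence_id <- c("a", "b")
  expect_equal(nrow(group_lineages(tab, level = "gene")), 1L)
  expect_equal(nrow(group_lineages(tab, level = "allele")), 2L)
})

test_that("top_lineages is deterministic under ties", {
  tab <- rbind(mk_reads(1, v = "IGHV2*01"), mk_reads(1, v = "IGHV1*01"),
               mk_reads(2, v = "IGHV3*01"))
  tab$sequence_id <- sprintf("r%04d", 1:4)
  lin <- group_lineages(tab)
  expect_equal(nrow(top_lineages(lin, 2)), 2L)
  expect_equal(nrow(top_lineages(lin, 10)), 3L)
  # equal copies: key order decides
  expect_equal(lin$lineage_key[2:3],
               sort(lin$lineage_key[2:3]))
})

test_that("lineage fold change normalizes depth and flags pseudocounts", {
  pre <- data.frame(lineage_key = c("A", "B"), name = c("CLH001", "CLH002"),
                    copy_count = c(10, 5), stringsAsFactors = FALSE)
  post <- data.frame(lineage_key = c("A", "B", "C"),
                     name = c("CLH001", "CLH002", "CLH003"),
                     copy_count = c(100, 5, 7), stringsAsFactors = FALSE)
  # equal depths scale out: fold = (100/112) / (10/15) per 10k -> compute
  fc <- lineage_fold_change(pre, post)
  expect_equal(fc$fold_change[fc$lineage_key == "A"],
               (100 / 112 * 1e4) / (10 / 15 * 1e4))
  expect_true(fc$pseudocount_used[fc$lineage_key == "C"])
  expect_false(any(fc$pseudocount_used[fc$lineage_key %in% c("A", "B")]))

  # unequal depths: 5 of 5k pre vs 20 of 10k post -> fold 2.0
  pre2 <- data.frame(lineage_key = c("A", "other"), name = c("x", "y"),
                     copy_count = c(5, 4995), stringsAsFactors = FALSE)
  post2 <- data.frame(lineage_key = c("A", "other"), name = c("x", "y"),
                      copy_count = c(20, 9980), stringsAsFactors = FALSE)
  fc2 <- lineage_fold_change(pre2, post2)
  expect_equal(fc2$fold_change[fc2$lineage_key == "A"], 2.0)
  # equal copies and depths -> 1.0
  fc3 <- lineage_fold_change(pre, pre)
  expect_equal(fc3$fold_change, c(1, 1))
})

test_that("the per-position mutation rate is mutated reads over covering reads", {
  db <- toy_db()
  v <- "IGHV1-2*01"
  n <- 10L
  tab <- data.frame(
    sequence_id = sprintf("r%02d", 1:n), locus = "IGH",
    v_call = v, j_call = "IGHJ4*01",
    v_germline_start = 0L, v_germline_end = 300L,
    v_mutations = c(rep("123A>C", 3), rep("", 7)),
    v_mutation_count = c(rep(1L, 3), rep(0L, 7)),
    sequence = strrep("A", 360), stringsAsFactors = FALSE)
  raw <- shm_position_profile(tab, db)
  expect_equal(raw$rate[raw$position == 123], 30)
  expect_equal(raw$n_covered[raw$position == 123], 10L)
  expect_true(all(raw$rate[raw$position != 123] == 0))
})

test_that("profile normalization fills all 100 indices with region labels", {
  db <- toy_db()
  tab <- data.frame(
    sequence_id = c("a", "b"), locus = "IGH", v_call = "IGHV1-2*01",
    j_call = "IGHJ4*01", v_germline_start = 0L, v_germline_end = 300L,
    v_mutations = c("80A>C", ""), v_mutation_count = c(1L, 0L),
    sequence = c(strrep("A", 99), strrep("A", 101)),
    stringsAsFactors = FALSE)
  raw <- shm_position_profile(tab, db)
  expect_equal(attr(raw, "mean_length"), 100)
  prof <- normalize_profile(raw, db)
  expect_s3_class(prof, "mutation_profile")
  expect_equal(nrow(prof), 100L)
  expect_equal(prof$index, 1:100)
  expect_false(any(is.na(prof$rate)))
  expect_true(all(prof$rate >= 0 & prof$rate <= 100))
  expect_setequal(unique(prof$region[1:74]), c("FR1"))
  expect_true("CDR1" %in% prof$region)
  # no-mutation lineage gives the all-zero profile
  tab0 <- tab; tab0$v_mutations <- ""; tab0$v_mutation_count <- 0L
  prof0 <- normalize_profile(shm_position_profile(tab0, db), db)
  expect_true(all(prof0$rate == 0))
})

test_that("profile aggregation averages rates, optionally copy-weighted", {
  mk_prof <- function(r) structure(
    data.frame(index = 1:100, rate = rep(r, 100), region = "FR1"),
    class = c("mutation_profile", "data.frame"))
  agg <- aggregate_profiles(list(mk_prof(10), mk_prof(30)))
  expect_equal(unique(agg$rate), 20)
  wagg <- aggregate_profiles(list(mk_prof(10), mk_prof(30)),
                             weights = c(3, 1))
  expect_equal(unique(wagg$rate), 15)
  expect_error(aggregate_profiles(list(mk_prof(1)), weights = c(1, 2)))
})

test_that("mutation burden counts reads at or above the threshold", {
  tab <- data.frame(v_mutation_count = rep(0L, 10))
  expect_equal(shm_burden(tab), 0)
  tab$v_mutation_count <- c(rep(3L, 4), rep(1L, 6))
  expect_equal(shm_burden(tab), 40)
  # binomial tail oracle on simulated counts
  set.seed(77)
  counts <- rbinom(4000, 300, 0.01)
  tab2 <- data.frame(v_mutation_count = counts)
  expected <- 100 * (1 - pbinom(1, 300, 0.01))
  se <- 100 * sqrt(expected / 100 * (1 - expected / 100) / 4000)
  expect_lt(abs(shm_burden(tab2) - expected), 3 * se)
})

test_that("NJ trees handle degenerate sizes and cap copy overlays", {
  one <- nj_tree(c(x = "CARW"))
  expect_equal(length(one$tree$tip.label), 1L)
  two <- nj_tree(c(x = "CARW", y = "CTRW"))
  expect_equal(sum(two$tree$edge.length), 0.25)  # edit 1 / max length 4
  capped <- nj_tree(c(x = "CARW", y = "CTRW", z = "CCCW"),
                    copy_counts = c(120L, 10L, 1L))
  expect_equal(capped$overlay$overlay, c(50L, 10L, 1L))
  expect_equal(capped$overlay$capped, c(TRUE, FALSE, FALSE))
})
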