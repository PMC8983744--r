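test_that("unmutated simulated reads recover truth calls and junctions", {
  db <- toy_db()
  sim <- simulate_repertoire(db, sim_config(n_reads = 60, seed = 4))
  tab <- annotate_reads(sim$reads, db)
  expect_equal(nrow(tab), 60L)
  m <- match(tab$sequence_id, sim$truth$read_id)
  tr <- sim$truth[m, ]
  expect_identical(tab$v_call, tr$v_call)
  expect_identical(tab$j_call, tr$j_call)
  expect_identical(tab$d_call, tr$d_call)
  expect_identical(tab$n1, tr$n1_seq)
  expect_identical(tab$n2, tr$n2_seq)
  expect_identical(tab$v_trim, tr$v_trim)
  expect_identical(tab$j_trim, tr$j_trim)
  expect_identical(tab$p_v_length, tr$p_v_length)
  expect_identical(tab$p_j_length, tr$p_j_length)
})

test_that("IGK reads annotate without a D segment", {
  db <- toy_db()
  sim <- simulate_repertoire(db, sim_config(n_reads = 30, locus = "IGK",
                                            seed = 14))
  tab <- annotate_reads(sim$reads, db, locus = "IGK")
  m <- match(tab$sequence_id, sim$truth$read_id)
  expect_identical(tab$v_call, sim$truth$v_call[m])
  expect_identical(tab$j_call, sim$truth$j_call[m])
  expect_true(all(is.na(tab$d_call)))
  expect_identical(tab$n1, sim$truth$n1_seq[m])
})

test_that("identical germline V sequences tie-break lexicographically", {
  g <- write_mini_germline(function(s) {
    s$sequence[2] <- s$sequence[1]          # V2*01 duplicates V1*01
    s$functionality[2] <- "functional"
    s
  })
  db <- load_germline(g$fasta, g$metadata)
  read <- paste0(germline_sequence(db, "V1*01"), "ACCTT",
                 germline_sequence(db, "J1*01"))
  tab <- annotate_reads(c(r1 = read), db, min_v_length = 50L)
  expect_identical(tab$v_call, "V1*01")
  expect_true(tab$v_tie)
})

test_that("reads unrelated to the reference are excluded and counted", {
  db <- toy_db()
  set.seed(2)
  junk <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                collapse = "")
  good <- simulate_repertoire(db, sim_config(n_reads = 1, seed = 6))$reads
  tab <- annotate_reads(c(junk = junk, good), db)
  expect_equal(nrow(tab), 1L)
  qc <- attr(tab, "qc")
  expect_equal(qc$n_input, 2L)
  expect_equal(qc$n_unannotatable, 1L)
  expect_identical(qc$unannotatable_ids, "junk")
})

test_that("hand-constructed junctions decompose as built", {
  db <- toy_db()
  vseq <- germline_sequence(db, "IGHV1-2*01")       # ends ...GCGAGA
  dseq <- germline_sequence(db, "IGHD1-26*01")
  jseq <- germline_sequence(db, "IGHJ4*01")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  # choose N bases that cannot be read as P or as a germline extension
  last_v <- substr(vseq, nchar(vseq), nchar(vseq))
  n1_base <- setdiff(c("A", "C", "G", "T"),
                     c(comp[[last_v]], comp[[substr(dseq, 1, 1)]]))[1]
  n1 <- strrep(n1_base, 3)
  n2_base <- setdiff(c("A", "C", "G", "T"),
                     c(comp[[substr(dseq, nchar(dseq), nchar(dseq))]],
                       comp[[substr(jseq, 1, 1)]]))[1]
  n2 <- strrep(n2_base, 3)
  read <- paste0(vseq, n1, dseq, n2, jseq)
  tab <- annotate_reads(c(r = read), db)
  expect_identical(tab$n1, n1)
  expect_identical(tab$n2, n2)
  expect_equal(tab$v_trim + tab$j_trim + tab$d_trim_5 + tab$d_trim_3, 0L)
  expect_equal(tab$p_v_length + tab$p_j_length, 0L)

  # planted P: untrimmed V followed by the reverse complement of its last
  # two bases (ends ...GA -> P = "TC")
  p2 <- paste0(comp[[substr(vseq, nchar(vseq), nchar(vseq))]],
               comp[[substr(vseq, nchar(vseq) - 1, nchar(vseq) - 1)]])
  n1b_pool <- setdiff(c("A", "C", "G", "T"),
                      c(comp[[substr(vseq, nchar(vseq) - 2, nchar(vseq) - 2)]],
                        comp[[substr(dseq, 1, 1)]]))
  n1b <- strrep(n1b_pool[1], 4)
  read2 <- paste0(vseq, p2, n1b, dseq, n2, jseq)
  tab2 <- annotate_reads(c(r = read2), db)
  expect_equal(tab2$p_v_length, 2L)
  expect_identical(tab2$n1, n1b)
})

test_that("CDR3 anchors delimit the junction and flag degeneracies", {
  db <- toy_db()
  sim <- simulate_repertoire(db, sim_config(n_reads = 120, seed = 16))
  tab <- annotate_reads(sim$reads, db)
  res <- tab[!tab$cdr3_unresolved, ]
  expect_gt(nrow(res), 50)
  # CDR3 starts at the Cys104 codon and excludes the J Phe/Trp
  in_frame <- res[res$vj_in_frame, ]
  expect_true(all(substr(in_frame$cdr3_aa, 1, 1) == "C"))
  last_aa <- substr(in_frame$junction_aa, nchar(in_frame$junction_aa),
                    nchar(in_frame$junction_aa))
  expect_true(all(last_aa %in% c("F", "W")))
  expect_identical(in_frame$junction_aa,
                   paste0(in_frame$cdr3_aa, last_aa))
  # out-of-frame junction: CDR3 nt present, aa empty, never productive
  off <- res[!res$vj_in_frame, ]
  expect_gt(nrow(off), 0)
  expect_true(all(off$cdr3_aa == ""))
  expect_true(!any(off$productive))

  # mutate a V anchor codon to a stop: flagged unresolved, kept
  r <- res$sequence[1]
  va <- 291  # anchor offset of every toy V; V is 5' complete on the read
  substr(r, va + 1, va + 3) <- "TGA"
  tab3 <- annotate_reads(c(mut = r), db)
  expect_equal(nrow(tab3), 1L)
  expect_true(tab3$cdr3_unresolved)
  expect_false(tab3$productive)
})

test_that("V mutation positions match the simulator ground truth", {
  db <- toy_db()
  sim <- simulate_repertoire(db, sim_config(n_reads = 40, shm_rate = 0.02,
                                            seed = 19))
  tab <- annotate_reads(sim$reads, db)
  m <- match(tab$sequence_id, sim$truth$read_id)
  checked <- 0L
  for (i in seq_len(nrow(tab))) {
    if (tab$v_call[i] != sim$truth$v_call[m[i]]) next
    if (tab$v_start[i] != 0L || tab$v_germline_start[i] != 0L) next
    truth_pos <- as.integer(strsplit(sim$truth$mutation_positions[m[i]],
                                     ",")[[1]])
    expected <- truth_pos[truth_pos < tab$v_germline_end[i]]
    got <- vdjrep:::.parse_v_mutations(tab$v_mutations[i])
    expect_identical(got, as.integer(expected))
    checked <- checked + 1L
  }
  expect_gt(checked, 30)
})

test_that("productivity is invariant under synonymous substitutions", {
  db <- toy_db()
  sim <- simulate_repertoire(db, sim_config(n_reads = 100, seed = 23))
  tab <- annotate_reads(sim$reads, db)
  prod <- tab[tab$productive, ]
  expect_gt(nrow(prod), 3)
  gc <- Biostrings::GENETIC_CODE
  for (i in seq_len(min(5, nrow(prod)))) {
    r <- prod$sequence[i]
    # pick an FR1 codon (frame 0, V complete at 5') and swap it for a
    # synonymous codon
    swapped <- FALSE
    for (cs in seq(1, 60, by = 3)) {
      cod <- substr(r, cs, cs + 2)
      syn <- setdiff(names(gc)[gc == gc[[cod]]], cod)
      if (!length(syn)) next
      substr(r, cs, cs + 2) <- syn[1]
      swapped <- TRUE
      break
    }
    expect_true(swapped)
    tab2 <- annotate_reads(c(syn = r), db)
    expect_true(tab2$productive)
  }
})
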