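test_that("packaged motif table encodes the published T6 and I1a definitions", {
  tb <- default_motif_table()
  t6 <- motif_positions(tb, "T6")
  expect_equal(nrow(t6), 12L)
  expect_equal(t6$position,
               c(106L, 169L, 2536L, 7931L, 9682L, 11899L, 12923L, 13310L,
                 13374L, 14063L, 16109L, 16255L))
  i1a <- motif_positions(tb, "I1a")
  expect_equal(nrow(i1a), 5L)
  expect_equal(i1a$position, c(1495L, 3051L, 8646L, 12622L, 14027L))
  expect_equal(unique(i1a$parent), "I1")
  # clade divergence motif carries 233 variants
  expect_equal(sum(tb$level == "clade" & !is.na(tb$position)), 233L)
  # all eight major haplogroups plus T5 present
  expect_setequal(motif_labels(tb, "haplogroup"),
                  c("T1", "T2", "T3", "T4", "T5", "T6", "I1", "I2"))
  # no diagnostic position is shared between motifs
  pos <- tb$position[!is.na(tb$position)]
  expect_equal(anyDuplicated(pos), 0L)
})

test_that("motif table validation rejects malformed definitions", {
  base <- as.data.frame(mini_motif_table())
  orphan <- rbind(base, data.frame(level = "subhaplogroup", label = "Q1a",
                                   parent = "Q1", position = 17L,
                                   ref = "A", alt = "G"))
  expect_error(motif_table(orphan), "parent")
  dup <- rbind(base, base[base$label == "T6", ][1L, ])
  expect_error(motif_table(dup), "duplicate position")
  bad_allele <- base
  bad_allele$alt[1L] <- "A"  # equals ref
  expect_error(motif_table(bad_allele), "must differ")
  out_of_frame <- base
  out_of_frame$position[1L] <- 10000L
  expect_error(motif_table(out_of_frame, ref_length = 400L),
               "outside reference frame")
})

test_that("motif table TSV round-trips through the reader", {
  tb <- mini_motif_table()
  p <- tempfile(fileext = ".tsv")
  write_motif_table(tb, p)
  back <- load_motif_table(p, reference_id = "mini-ref", ref_length = 400L)
  expect_equal(as.data.frame(back), as.data.frame(tb))
})

test_that("every label round-trips: apply motif then classify recovers it", {
  for (tb in list(mini_motif_table(), default_motif_table())) {
    cfg <- if (attr(tb, "reference_id") == "mini-ref") {
      mini_config(seed = 2)
    } else synthetic_config(seed = 2)
    ref <- make_reference(cfg, tb)
    # the reference itself is the taurine backbone (T3), score 1
    cl_ref <- call_haplogroup(ref, ref, tb)
    expect_equal(cl_ref$clade, "T")
    expect_equal(cl_ref$haplogroup, "T3")
    expect_equal(cl_ref$score, 1)
    for (hg in setdiff(motif_labels(tb, "haplogroup"), c("T3", "I1"))) {
      s <- apply_motif(ref, tb, hg)
      cl <- call_haplogroup(s, ref, tb)
      expect_equal(cl$haplogroup, hg)
      expect_equal(cl$score, 1)
    }
    # sub-haplogroup: full motif present on top of the parent
    s <- apply_motif(ref, tb, "I1a")
    cl <- call_haplogroup(s, ref, tb)
    expect_equal(cl$clade, "I")
    expect_equal(cl$haplogroup, "I1")
    expect_equal(cl$subhaplogroup, "I1a")
  }
})

test_that("classification is stable under a few private mutations", {
  tb <- mini_motif_table()
  cfg <- mini_config(seed = 3)
  ref <- make_reference(cfg, tb)
  diag_pos <- tb$position[!is.na(tb$position)]
  free <- setdiff(seq_len(400L), diag_pos)
  for (seed in 1:10) {
    set.seed(seed)
    hg <- sample(c("T1", "T2", "T4", "T6", "I2"), 1L)
    s <- apply_motif(ref, tb, hg)
    pos <- sample(free, 2L)
    for (p in pos) s[p] <- setdiff(c("A", "C", "G", "T"), s[p])[1L]
    expect_equal(call_haplogroup(s, ref, tb)$haplogroup, hg)
  }
})

test_that("gaps and Ns at diagnostic positions are unassessed, not mismatches", {
  tb <- mini_motif_table()
  ref <- make_reference(mini_config(seed = 4), tb)
  s <- apply_motif(ref, tb, "T6")
  t6_pos <- motif_positions(tb, "T6")$position
  s[t6_pos[1L]] <- "N"
  cl <- call_haplogroup(s, ref, tb)
  expect_equal(cl$haplogroup, "T6")
  expect_equal(cl$total, length(t6_pos) - 1L)
  expect_true(t6_pos[1L] %in% cl$unassessed_positions)
  # sequence shorter than the largest motif position errors
  expect_error(call_haplogroup(s[1:100], ref, tb), "shorter")
})

test_that("novel matrilines are flagged and their private variants listed", {
  tb <- mini_motif_table()
  cfg <- mini_config(seed = 5)
  ref <- make_reference(cfg, tb)
  diag_pos <- tb$position[!is.na(tb$position)]

  # taurine sequence carrying 12 unknown mutations (the T6 situation:
  # backbone match plus many unexplained derived variants)
  set.seed(99)
  planted <- sort(sample(setdiff(seq_len(400L), diag_pos), 12L))
  s <- ref
  for (p in planted) s[p] <- setdiff(c("A", "C", "G", "T"), s[p])[1L]
  cl <- call_haplogroup(s, ref, tb)
  expect_equal(cl$clade, "T")
  expect_equal(cl$haplogroup, "T-novel")
  expect_equal(cl$private_positions, planted)

  # indicine sequence failing every in-clade motif above threshold
  s2 <- apply_motif(ref, tb, "I2")
  i2_pos <- motif_positions(tb, "I2")$position
  s2[i2_pos[1:2]] <- ref[i2_pos[1:2]]  # 1/3 motif match < 0.8
  for (p in planted) s2[p] <- setdiff(c("A", "C", "G", "T"), s2[p])[1L]
  cl2 <- call_haplogroup(s2, ref, tb)
  expect_equal(cl2$clade, "I")
  expect_equal(cl2$haplogroup, "I-novel")

  # cohort report: all-known cohort is empty; novel sequences listed
  co <- generate_cohort(mini_config(seed = 5), tb)
  calls <- classify_cohort(co$alignment, tb)
  expect_equal(nrow(detect_novel(calls)), 0L)

  mat <- rbind(co$alignment$seq, `NV001` = s)
  aln2 <- mito_alignment(mat, ref_seq = paste(ref, collapse = ""))
  calls2 <- classify_cohort(aln2, tb)
  nov <- detect_novel(calls2)
  expect_equal(nov$sample_id, "NV001")
  expect_equal(nov$n_private, 12L)
  expect_equal(nov$positions, paste(planted, collapse = ";"))
})

test_that("removing T6 from the table turns T6 carriers into T-novel", {
  tb <- mini_motif_table()
  ref <- make_reference(mini_config(seed = 7), tb)
  s <- apply_motif(ref, tb, "T6")
  tb_no_t6 <- motif_table(as.data.frame(tb)[tb$label != "T6", ],
                          reference_id = "mini-ref", ref_length = 400L)
  # the mini T6 motif has 4 variants, so scale the novelty cutoff down
  cl <- call_haplogroup(s, ref, tb_no_t6, novel_min_private = 4L)
  expect_equal(cl$haplogroup, "T-novel")
  expect_equal(cl$private_positions, motif_positions(tb, "T6")$position)
})

test_that("frequency table reproduces printed-percentage arithmetic", {
  counts <- c(I1 = 54L)
  fr <- haplogroup_frequencies(c(I1 = 54L, T3 = 75L))
  expect_equal(fr$pct[fr$label == "I1" & fr$level == "haplogroup"], 41.86)

  fr0 <- haplogroup_frequencies(c(X1 = 0L, X2 = 4L))
  expect_equal(fr0$pct[fr0$label == "X2"], 100)
  expect_false("X1" %in% fr0$label)  # zero-count labels don't occur

  # counts sum to n; percentages sum to 100 within rounding slack
  co <- generate_cohort(mini_config(seed = 8, rate = 1), mini_motif_table())
  calls <- classify_cohort(co$alignment, mini_motif_table())
  fr2 <- haplogroup_frequencies(calls)
  hg <- fr2[fr2$level == "haplogroup" & fr2$breed == "all", ]
  expect_equal(sum(hg$count), nrow(calls))
  expect_lt(abs(sum(hg$pct) - 100), 0.01 * nrow(hg) + 1e-9)
})
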