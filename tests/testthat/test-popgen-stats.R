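test_that("haplotype collapsing groups identical sequences and labels by frequency", {
  aln <- mito_alignment(c(s1 = "AAA", s2 = "AAA", s3 = "AAT", s4 = "ATT"))
  h <- collapse_haplotypes(aln, build_site_index(aln))
  expect_equal(nrow(h$seqs), 3L)
  expect_equal(unname(h$counts), c(2L, 1L, 1L))
  expect_equal(names(h$counts), c("H1", "H2", "H3"))
  expect_setequal(h$members$H1, c("s1", "s2"))
  # H2/H3 tie broken by first occurrence
  expect_equal(h$members$H2, "s3")

  aln4 <- mito_alignment(setNames(rep("ACGT", 4), paste0("x", 1:4)))
  h4 <- collapse_haplotypes(aln4, build_site_index(aln4))
  expect_equal(nrow(h4$seqs), 1L)
  expect_equal(unname(h4$counts), 4L)
})

test_that("variable-site classification matches the tally oracle", {
  # hand examples: singleton vs parsimony informative
  aln <- mito_alignment(c(a = "AA", b = "AA", c = "AA", d = "TA"))
  vs <- classify_variable_sites(aln, build_site_index(aln))
  expect_equal(vs$S, 1L)
  expect_equal(vs$singletons, 1L)

  aln2 <- mito_alignment(c(a = "A", b = "A", c = "T", d = "T"))
  vs2 <- classify_variable_sites(aln2, build_site_index(aln2))
  expect_equal(vs2$parsimony_informative, 1L)

  # multiallelic column with one singleton allele and two common alleles
  # counts as informative (column-level split keeps S additive)
  aln3 <- mito_alignment(c(a = "A", b = "A", c = "T", d = "T", e = "G"))
  vs3 <- classify_variable_sites(aln3, build_site_index(aln3))
  expect_equal(vs3$S, 1L)
  expect_equal(vs3$parsimony_informative, 1L)
  expect_equal(vs3$singletons, 0L)

  for (seed in 1:5) {
    aln4 <- rand_aln(20, 200, seed = seed)
    idx <- build_site_index(aln4)
    vs4 <- classify_variable_sites(aln4, idx)
    oracle <- brute_force_sites(aln4$seq[, idx$usable, drop = FALSE])
    expect_equal(vs4$S, oracle$S)
    expect_equal(vs4$singletons, oracle$singletons)
    expect_equal(vs4$parsimony_informative, oracle$parsimony_informative)
    expect_equal(vs4$S, vs4$singletons + vs4$parsimony_informative)
  }
})

test_that("Nei haplotype diversity and its SD match direct evaluation", {
  expect_equal(haplotype_diversity(c(4L))$Hd, 0)
  expect_equal(haplotype_diversity(c(1L, 1L, 1L, 1L))$Hd, 1)
  hd <- haplotype_diversity(c(2L, 1L, 1L))
  expect_equal(hd$Hd, 5 / 6, tolerance = 1e-12)
  expect_equal(hd$Hd_sd, brute_force_hd_sd(c(2, 1, 1)), tolerance = 1e-12)
  expect_equal(hd$Hd_sd, 0.2224392, tolerance = 1e-6)
  expect_error(haplotype_diversity(c(1L)), "n >= 2")
})

test_that("pairwise differences match the brute-force pair loop", {
  aln <- mito_alignment(c(a = "AAAAAAAAAA", b = "AAAAAAAAAT"))
  pw <- pairwise_differences(aln, build_site_index(aln))
  expect_equal(pw$k, 1)
  expect_equal(pw$Pi, 0.1)

  same <- mito_alignment(setNames(rep("ACGTACGT", 5), paste0("s", 1:5)))
  pw0 <- pairwise_differences(same, build_site_index(same))
  expect_equal(pw0$k, 0)
  expect_equal(pw0$Pi, 0)

  for (seed in 1:5) {
    aln2 <- rand_aln(15, 300, seed = 100 + seed)
    idx <- build_site_index(aln2)
    pw2 <- pairwise_differences(aln2, idx)
    k_oracle <- brute_force_k(aln2$seq[, idx$usable, drop = FALSE])
    expect_equal(pw2$k, k_oracle, tolerance = 1e-12)
    expect_equal(pw2$Pi, pw2$k / pw2$L_used)
    # haplotype-weighted route agrees
    h <- collapse_haplotypes(aln2, idx)
    expect_equal(unname(weighted_k(h)), pw2$k, tolerance = 1e-12)
    expect_equal(pairwise_differences(h)$k, pw2$k, tolerance = 1e-12)
  }
})

test_that("Hd and k are invariant under sample permutation", {
  aln <- rand_aln(12, 150, seed = 42)
  idx <- build_site_index(aln)
  st <- diversity_stats(aln, idx)
  perm <- sample(seq_len(nrow(aln$seq)))
  aln_p <- mito_alignment(aln$seq[perm, , drop = FALSE],
                          breed_map = aln$breed_map[perm])
  st_p <- diversity_stats(aln_p, build_site_index(aln_p))
  expect_equal(st_p$Hd, st$Hd)
  expect_equal(st_p$k, st$k)
  expect_equal(st_p$S, st$S)
  expect_equal(st_p$H, st$H)
})

test_that("diversity scan localizes concentrated variation", {
  set.seed(5)
  n <- 12; L <- 400
  mat <- matrix("A", n, L)
  # all variation confined to columns 100-150
  for (j in 100:150) mat[sample.int(n, n %/% 2), j] <- "G"
  rownames(mat) <- paste0("s", seq_len(n))
  aln <- mito_alignment(mat)
  idx <- build_site_index(aln)
  prof <- diversity_scan(aln, idx, window_size = 50L, step = 10L)
  pk <- scan_peak(prof)
  expect_true(pk$start_np <= 150 && pk$end_np >= 100)
  expect_error(diversity_scan(aln, idx, 50L, 10L, from = 0L), "outside")
  expect_error(diversity_scan(aln, idx, 50L, 10L, to = 1000L), "outside")
})

test_that("windows without usable sites are undefined, not zero", {
  mat <- matrix(sample(c("A", "G"), 6 * 60, replace = TRUE), 6, 60)
  mat[, 21:40] <- "-"  # a gap block -> no usable sites there
  rownames(mat) <- paste0("s", 1:6)
  aln <- mito_alignment(mat)
  idx <- build_site_index(aln)
  prof <- diversity_scan(aln, idx, window_size = 20L, step = 20L)
  mid <- prof[prof$start_np == 21L, ]
  expect_equal(mid$n_usable, 0L)
  expect_true(is.na(mid$Pi))
})

test_that("window Pi stays near global Pi for uniform alignments", {
  aln <- rand_aln(20, 500, seed = 77)
  idx <- build_site_index(aln)
  global <- pairwise_differences(aln, idx)$Pi
  prof <- diversity_scan(aln, idx, window_size = 100L, step = 50L)
  expect_true(all(abs(prof$Pi - global) < 5 * global))
})

test_that("per-breed report pools correctly and flags tiny breeds", {
  aln <- rand_aln(10, 120, seed = 9)
  bm <- setNames(rep(c("A-breed", "B-breed"), each = 5), rownames(aln$seq))
  aln <- mito_alignment(aln$seq, breed_map = bm)
  rep1 <- breed_diversity_report(aln)
  expect_setequal(rep1$Breed, c("A-breed", "B-breed", "Total"))
  tot <- rep1[rep1$Breed == "Total", ]
  expect_equal(tot$n, 10L)
  # pooling never decreases S or H
  expect_true(tot$S >= max(rep1$S[rep1$Breed != "Total"]))
  expect_true(tot$H >= max(rep1$H[rep1$Breed != "Total"]))

  # a breed with n < 2 gets NA statistics
  bm2 <- bm; bm2[1L] <- "Lone"
  aln2 <- mito_alignment(aln$seq, breed_map = bm2)
  rep2 <- breed_diversity_report(aln2)
  expect_true(is.na(rep2$Hd[rep2$Breed == "Lone"]))
})
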