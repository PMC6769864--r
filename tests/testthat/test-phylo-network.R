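test_that("hamming distances match brute-force pair comparison", {
  aln <- mito_alignment(c(h1 = "AAA", h2 = "AAT"))
  h <- collapse_haplotypes(aln, build_site_index(aln))
  d <- hamming_distances(h)
  expect_equal(unname(d["H1", "H2"]), 1)
  expect_equal(unname(diag(d)), c(0, 0))

  aln2 <- rand_aln(10, 120, seed = 21)
  idx <- build_site_index(aln2)
  h2 <- collapse_haplotypes(aln2, idx)
  d2 <- hamming_distances(h2)
  for (i in seq_len(nrow(h2$seqs))) {
    for (j in seq_len(nrow(h2$seqs))) {
      expect_equal(d2[i, j], sum(h2$seqs[i, ] != h2$seqs[j, ]))
    }
  }
  expect_equal(hamming_distances(h2, per_site = TRUE), d2 / ncol(h2$seqs),
               ignore_attr = TRUE)
})

test_that("NJ recovers additive trees exactly", {
  # 4 taxa from tree ((A,B),(C,D)) with internal edge 2
  d <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                       c("A", "B", "C", "D")))
  el <- c(A = 1, B = 2, C = 3, D = 4)
  for (x in c("A", "B")) for (y in c("C", "D")) {
    d[x, y] <- d[y, x] <- el[x] + 2 + el[y]
  }
  d["A", "B"] <- d["B", "A"] <- 3
  d["C", "D"] <- d["D", "C"] <- 7
  tr <- nj_tree(d)
  expect_equal(as.matrix(ape::cophenetic.phylo(tr))[rownames(d), rownames(d)],
               d)
  # the AB|CD split is present
  parts <- ape::prop.part(tr)
  expect_true(any(vapply(parts, function(p)
    setequal(tr$tip.label[p], c("A", "B")) ||
      setequal(tr$tip.label[p], c("C", "D")), logical(1L))))

  # 4-8 taxa random additive matrices round-trip through NJ
  for (k in 4:8) {
    set.seed(k)
    src <- ape::rtree(k)
    dk <- ape::cophenetic.phylo(src)
    trk <- nj_tree(dk)
    expect_equal(as.matrix(ape::cophenetic.phylo(trk))[rownames(dk),
                                                       colnames(dk)],
                 dk, tolerance = 1e-8)
  }
})

test_that("3-taxon NJ solves the closed-form branch lengths", {
  d <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  bl <- setNames(tr$edge.length[match(seq_along(tr$tip.label),
                                      tr$edge[, 2L])], tr$tip.label)
  expect_equal(unname(bl[c("A", "B", "C")]), c(1, 2, 4))
  expect_error(nj_tree(d[1:2, 1:2]), ">= 3")
})

test_that("rooting on the outgroup places it on a pendant edge", {
  aln <- rand_aln(8, 100, seed = 31)
  h <- collapse_haplotypes(aln, build_site_index(aln))
  d <- hamming_distances(h)
  out <- rownames(h$seqs)[1L]
  tr <- nj_tree(d, outgroup = out)
  expect_true(ape::is.rooted(tr))
  expect_error(nj_tree(d, outgroup = "nope"), "not a leaf")
})

test_that("bootstrap gives full support to an overwhelming split and is seeded", {
  set.seed(1)
  L <- 60
  base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  cl2 <- base
  cl2[1:50] <- unname(c(A = "G", C = "T", G = "A", T = "C")[base[1:50]])
  m <- rbind(base, base, cl2, cl2)
  flip <- c(A = "G", C = "T", G = "A", T = "C")
  m[2, 55] <- unname(flip[m[2, 55]])
  m[4, 57] <- unname(flip[m[4, 57]])
  rownames(m) <- paste0("h", 1:4)
  bs <- bootstrap_supports(m, n_reps = 100L, seed = 5L)
  # the single internal edge separating the two clusters
  expect_true(any(bs$supports == 100))
  bs2 <- bootstrap_supports(m, n_reps = 100L, seed = 5L)
  expect_identical(bs$supports, bs2$supports)
  bs3 <- bootstrap_supports(m, n_reps = 100L, seed = 6L)
  expect_equal(length(bs3$supports), length(bs$supports))

  flat <- matrix("A", 3, 10, dimnames = list(paste0("h", 1:3), NULL))
  expect_warning(b0 <- bootstrap_supports(flat, n_reps = 10L, seed = 1L),
                 "no variable sites")
  expect_true(all(b0$supports == 0))
})

test_that("median joining leaves observed intermediates as path nodes", {
  aln <- mito_alignment(c(a = "AAAA", b = "AATA", c = "AATT"))
  h <- collapse_haplotypes(aln, build_site_index(aln))
  net <- median_joining(h)
  expect_equal(sum(net$nodes$is_median), 0L)
  expect_equal(nrow(net$edges), 2L)
  expect_equal(sort(net$edges$n_mutations), c(1, 1))
})

test_that("median joining infers the unobserved Steiner point", {
  aln <- mito_alignment(c(a = "TAAA", b = "ATAA", c = "AATA", d = "AAAT"))
  h <- collapse_haplotypes(aln, build_site_index(aln))
  net <- median_joining(h)
  expect_equal(sum(net$nodes$is_median), 1L)
  mv <- net$nodes$label[net$nodes$is_median]
  expect_equal(unname(paste(net$seqs[mv, ], collapse = "")), "AAAA")
  deg <- table(c(net$edges$from, net$edges$to))
  expect_equal(unname(deg[mv]), 4L)
  expect_true(all(net$edges$n_mutations == 1))
  # haplotype frequencies sum to n; medians contribute 0
  expect_equal(sum(net$nodes$frequency), h$n)
})

test_that("the network at epsilon 0 contains a minimum spanning tree", {
  aln <- rand_aln(12, 80, seed = 55)
  h <- collapse_haplotypes(aln, build_site_index(aln))
  net <- median_joining(h)
  labs <- net$nodes$label
  # connectivity over all nodes
  reach <- labs[1L]
  repeat {
    nxt <- unique(c(reach,
                    net$edges$to[net$edges$from %in% reach],
                    net$edges$from[net$edges$to %in% reach]))
    if (length(nxt) == length(reach)) break
    reach <- nxt
  }
  expect_setequal(reach, labs)
  # the final node set's MST weight is attained within the network
  d <- mitohap:::hamming_matrix_rows(net$seqs)
  mst_w <- sum(mitohap:::mst_edges(d)[, 3L])
  # greedy Kruskal restricted to network edges
  ed <- net$edges[order(net$edges$n_mutations), ]
  comp <- setNames(seq_along(labs), labs)
  w <- 0
  for (e in seq_len(nrow(ed))) {
    ci <- comp[ed$from[e]]; cj <- comp[ed$to[e]]
    if (ci != cj) {
      w <- w + ed$n_mutations[e]
      comp[comp == cj] <- ci
    }
  }
  expect_equal(w, mst_w)
})

test_that("raising epsilon only adds feasible links", {
  aln <- rand_aln(10, 60, seed = 66)
  h <- collapse_haplotypes(aln, build_site_index(aln))
  d <- hamming_distances(h)
  a0 <- mitohap:::msn_adjacency(d, 0)
  a1 <- mitohap:::msn_adjacency(d, 1)
  a2 <- mitohap:::msn_adjacency(d, 3)
  expect_true(all(a1[a0]))
  expect_true(all(a2[a1]))
})

test_that("planted clade separation is recovered as the network gap", {
  co <- generate_cohort(mini_config(seed = 12), mini_motif_table())
  aln <- co$alignment
  idx <- build_site_index(aln)
  h <- collapse_haplotypes(aln, idx)
  net <- median_joining(h)
  truth <- co$truth
  t_samples <- truth$sample_id[truth$haplogroup %in% c("T1", "T2", "T3",
                                                       "T4", "T6")]
  hap_of <- function(ids) {
    unique(names(Filter(function(m) any(m %in% ids), h$members)))
  }
  t_h <- hap_of(t_samples)
  i_h <- hap_of(setdiff(truth$sample_id, t_samples))
  m_planted <- sum(mini_motif_table()$level == "clade" &
                     !is.na(mini_motif_table()$position))
  # closest cross-cluster pair: pure backbone T3 vs pure I1 = clade motif
  expect_equal(unname(network_separation(net, t_h, i_h)), m_planted)
})
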