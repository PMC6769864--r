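# Shared fixtures and independent oracles for the test suite.

# A scaled-down motif table (reference frame 400 np) so cohort-level tests
# stay fast. Structure mirrors the packaged default: clade I divergence
# motif (20 positions), taurine haplogroups with T3 as backbone, indicine
# I1 backbone + I2, sub-haplogroup I1a under I1.
mini_motif_table <- function(ref_length = 400L) {
  row <- function(level, label, parent, pos) {
    data.frame(level = level, label = label, parent = parent,
               position = pos, ref = "A", alt = "G",
               stringsAsFactors = FALSE)
  }
  df <- rbind(
    row("clade", "I", NA, seq(10L, 390L, by = 20L)),
    row("haplogroup", "T1", "T", c(15L, 55L, 95L, 135L)),
    row("haplogroup", "T2", "T", c(25L, 65L, 105L)),
    row("haplogroup", "T4", "T", c(35L, 75L)),
    row("haplogroup", "T6", "T", c(45L, 85L, 125L, 165L)),
    row("haplogroup", "I2", "I", c(155L, 195L, 235L)),
    row("subhaplogroup", "I1a", "I1", c(205L, 245L)),
    data.frame(level = "haplogroup", label = c("T3", "I1"),
               parent = c("T", "I"), position = NA_integer_,
               ref = NA_character_, alt = NA_character_,
               stringsAsFactors = FALSE))
  motif_table(df, reference_id = "mini-ref", ref_length = ref_length)
}

mini_config <- function(seed = 1L, rate = 0, ...) {
  synthetic_config(
    seed = seed, ref_length = 400L,
    haplogroup_counts = c(T1 = 5L, T2 = 3L, T3 = 6L, T4 = 2L, T6 = 2L,
                          I1 = 8L, I2 = 3L),
    haplotype_counts = NULL,
    subclade_counts = c(I1a = 4L), subclade_templates = c(I1a = 2L),
    private_mutation_rate = rate,
    hotspot = c(300L, 380L), hotspot_multiplier = 15,
    id_prefix = "MS", ...)
}

# Random alignment over A/C/G/T (optionally with gaps/Ns at given columns).
rand_aln <- function(n, L, seed, gap_cols = integer(0), n_cols = integer(0),
                     breed = "testbreed") {
  set.seed(seed)
  mat <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE,
                       prob = c(0.4, 0.25, 0.2, 0.15)), n, L)
  # resample some columns to low diversity so singletons/informative mix
  for (j in seq_len(L)) {
    if (runif(1) < 0.6) mat[, j] <- mat[1L, j]
  }
  if (length(gap_cols)) mat[sample.int(n, 1L), gap_cols] <- "-"
  if (length(n_cols)) mat[sample.int(n, 1L), n_cols] <- "N"
  rownames(mat) <- sprintf("s%02d", seq_len(n))
  mito_alignment(mat, breed_map = setNames(rep(breed, n), rownames(mat)))
}

# --- independent oracles -------------------------------------------------

# O(n^2 L) double loop over sample pairs.
brute_force_k <- function(mat) {
  n <- nrow(mat)
  tot <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      tot <- tot + sum(mat[i, ] != mat[j, ])
    }
  }
  tot / (n * (n - 1) / 2)
}

# Per-column tally classification of variable sites.
brute_force_sites <- function(mat) {
  S <- 0L; singles <- 0L; inform <- 0L
  for (j in seq_len(ncol(mat))) {
    tab <- table(mat[, j])
    if (length(tab) >= 2L) {
      S <- S + 1L
      if (sum(tab >= 2L) >= 2L) inform <- inform + 1L else
        singles <- singles + 1L
    }
  }
  list(S = S, singletons = singles, parsimony_informative = inform)
}

# Nei (1987) gene-diversity sampling variance, written out term by term.
brute_force_hd_sd <- function(counts) {
  n <- sum(counts)
  p <- counts / n
  a <- sum(p^2)
  b <- sum(p^3)
  v <- (2 / (n * (n - 1))) * (2 * (n - 2) * (b - a^2) + a - a^2)
  sqrt(v)
}

# Haplotype-weighted k: average differences using distinct haplotypes and
# their multiplicities (equivalence oracle for the column-tally route).
weighted_k <- function(h) {
  labs <- rownames(h$seqs)
  tot <- 0
  for (i in seq_along(labs)) {
    for (j in seq_along(labs)) {
      if (j <= i) next
      d <- sum(h$seqs[i, ] != h$seqs[j, ])
      tot <- tot + d * h$counts[labs[i]] * h$counts[labs[j]]
    }
  }
  tot / (h$n * (h$n - 1) / 2)
}
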