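# Seeded synthetic mitogenome cohorts with known haplogroup structure.
#
# Each cohort is built on a pseudo-random reference backbone (standing in
# for the bovine reference frame). A sample's sequence is the reference
# plus its haplogroup's full diagnostic motif (clade + haplogroup +
# optional sub-haplogroup), plus the private mutations of its haplotype
# template. Templates model shared within-haplogroup substructure: the
# cohort's distinct haplotypes are the templates, each carrying an
# independent Poisson number of private substitutions drawn with
# control-region hotspot weighting and a 10:1 transition:transversion
# ratio. Ground truth (labels, templates, private positions, hotspot) is
# recorded for every sample.

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the published cohort structure: 129 animals in the
#' seven observed haplogroups (T1:19, T2:5, T3:37, T4:7, T6:2, I1:54,
#' I2:5) collapsing to 47 haplotype templates (T6 a single haplotype),
#' 18 I1a animals in 6 templates forming a star-like sub-cluster, a
#' 16,338 bp reference frame, and a hypervariable hotspot at np
#' 15909-16315 with a 20x mutation-rate multiplier.
#'
#' @param seed integer RNG seed; fixed seed gives byte-identical cohorts.
#' @param ref_length reference frame length.
#' @param haplogroup_counts named integer vector, samples per haplogroup.
#' @param haplotype_counts named integer vector, distinct haplotype
#'   templates per haplogroup (NULL = one template per sample); entries
#'   must not exceed the sample counts.
#' @param subclade_counts named integer vector, samples carrying each
#'   sub-haplogroup motif (drawn from the parent haplogroup's samples).
#' @param subclade_templates named integer vector, templates among those
#'   samples.
#' @param private_mutation_rate Poisson mean of private substitutions per
#'   haplotype template.
#' @param hotspot np interval `c(start, end)` with elevated mutation rate.
#' @param hotspot_multiplier rate multiplier inside the hotspot.
#' @param ts_tv_ratio transition:transversion ratio for private mutations.
#' @param breed breed label recorded for every sample.
#' @param id_prefix sample id prefix.
#' @param allow_motif_collisions let private mutations hit diagnostic
#'   positions (default FALSE, keeping classification ground truth exact).
#' @param indel_columns number of gap columns (0-2) to insert inside the
#'   hotspot, emulating small alignment length variation.
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             ref_length = 16338L,
                             haplogroup_counts = c(T1 = 19L, T2 = 5L,
                                                   T3 = 37L, T4 = 7L,
                                                   T6 = 2L, I1 = 54L,
                                                   I2 = 5L),
                             haplotype_counts = c(T1 = 7L, T2 = 2L,
                                                  T3 = 12L, T4 = 3L,
                                                  T6 = 1L, I1 = 19L,
                                                  I2 = 3L),
                             subclade_counts = c(I1a = 18L),
                             subclade_templates = c(I1a = 6L),
                             private_mutation_rate = 3,
                             hotspot = c(15909L, 16315L),
                             hotspot_multiplier = 20,
                             ts_tv_ratio = 10,
                             breed = "Yunling",
                             id_prefix = "YL",
                             allow_motif_collisions = FALSE,
                             indel_columns = 0L) {
  stopifnot(all(haplogroup_counts >= 0L), private_mutation_rate >= 0,
            hotspot[1L] >= 1L, hotspot[2L] <= ref_length,
            hotspot[1L] <= hotspot[2L], hotspot_multiplier >= 1,
            indel_columns %in% 0:2)
  if (!is.null(haplotype_counts)) {
    common <- intersect(names(haplotype_counts), names(haplogroup_counts))
    if (any(haplotype_counts[common] > haplogroup_counts[common])) {
      stop("more haplotype templates than samples in a haplogroup")
    }
  }
  structure(
    list(seed = as.integer(seed), ref_length = as.integer(ref_length),
         haplogroup_counts = haplogroup_counts,
         haplotype_counts = haplotype_counts,
         subclade_counts = subclade_counts,
         subclade_templates = subclade_templates,
         private_mutation_rate = private_mutation_rate,
         hotspot = as.integer(hotspot),
         hotspot_multiplier = hotspot_multiplier,
         ts_tv_ratio = ts_tv_ratio, breed = breed, id_prefix = id_prefix,
         allow_motif_collisions = allow_motif_collisions,
         indel_columns = as.integer(indel_columns)),
    class = "synthetic_config")
}

#' Generate the synthetic reference backbone
#'
#' A deterministic pseudo-random A/C/G/T sequence of `ref_length`, with
#' every diagnostic position of `table` forced to the table's reference
#' allele so that the backbone is consistent with the motif definitions
#' regardless of seed.
#'
#' @param cfg a [synthetic_config()].
#' @param table a [motif_table()].
#' @return character vector (one element per np position).
#' @export
make_reference <- function(cfg, table = default_motif_table(cfg$ref_length)) {
  max_pos <- max(table$position, na.rm = TRUE)
  if (cfg$ref_length < max_pos) {
    stop("ref_length ", cfg$ref_length,
         " is shorter than the largest motif position ", max_pos)
  }
  ref <- with_local_seed(cfg$seed, {
    sample(c("A", "C", "G", "T"), cfg$ref_length, replace = TRUE)
  })
  var <- table[!is.na(table$position), , drop = FALSE]
  ref[var$position] <- var$ref
  ref
}

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv())) {
            rm(".Random.seed", envir = globalenv())
          })
  set.seed(as.integer(seed))
  expr
}

mutate_base <- function(base, ts_tv_ratio) {
  p_ts <- ts_tv_ratio / (ts_tv_ratio + 1)
  vapply(base, function(b) {
    ts <- TRANSITION[[b]]
    if (runif(1L) < p_ts) return(ts)
    sample(setdiff(c("A", "C", "G", "T"), c(b, ts)), 1L)
  }, character(1L), USE.NAMES = FALSE)
}

# Random composition of n into k positive parts (stars and bars on a
# shuffled sample), giving skewed realistic haplotype frequencies.
random_composition <- function(n, k) {
  if (k == 1L) return(n)
  cuts <- sort(sample.int(n - 1L, k - 1L))
  diff(c(0L, cuts, n))
}

#' Generate a synthetic mitogenome cohort
#'
#' @param cfg a [synthetic_config()].
#' @param table a [motif_table()]; every haplogroup in
#'   `cfg$haplogroup_counts` must be defined in it.
#' @return list with `alignment` (a [mito_alignment()] carrying the
#'   reference row and breed map) and `truth` (data.frame `sample_id`,
#'   `haplogroup`, `subhaplogroup`, `template`, `n_private`,
#'   `private_positions`; attributes `hotspot`, `ref`,
#'   `n_haplotype_classes` = number of distinct generated templates).
#' @export
generate_cohort <- function(cfg, table = default_motif_table(cfg$ref_length)) {
  unknown <- setdiff(names(cfg$haplogroup_counts),
                     motif_labels(table, "haplogroup"))
  if (length(unknown)) {
    stop("haplogroup label(s) absent from motif table: ",
         paste(unknown, collapse = ", "))
  }
  ref <- make_reference(cfg, table)
  L <- cfg$ref_length
  known_pos <- table$position[!is.na(table$position)]
  weights <- rep(1, L)
  weights[cfg$hotspot[1L]:cfg$hotspot[2L]] <- cfg$hotspot_multiplier
  if (!cfg$allow_motif_collisions) weights[known_pos] <- 0

  # generation units: (haplogroup, sub-haplogroup) classes
  units <- list()
  for (hg in names(cfg$haplogroup_counts)) {
    n_hg <- cfg$haplogroup_counts[[hg]]
    if (n_hg == 0L) next
    t_hg <- if (is.null(cfg$haplotype_counts)) n_hg else
      cfg$haplotype_counts[[hg]]
    if (is.null(t_hg) || is.na(t_hg)) t_hg <- n_hg
    subs <- names(cfg$subclade_counts)[
      vapply(names(cfg$subclade_counts), function(sb)
        identical(motif_parent(table, sb), hg), logical(1L))]
    n_sub <- if (length(subs)) sum(cfg$subclade_counts[subs]) else 0L
    if (n_sub > n_hg) stop("sub-haplogroup samples exceed parent count")
    for (sb in subs) {
      t_sb <- cfg$subclade_templates[[sb]]
      if (is.null(t_sb) || is.na(t_sb)) t_sb <- cfg$subclade_counts[[sb]]
      units[[paste0(hg, "/", sb)]] <-
        list(hg = hg, sub = sb, n = cfg$subclade_counts[[sb]],
             templates = min(t_sb, cfg$subclade_counts[[sb]]))
    }
    t_rem <- max(1L, t_hg - sum(vapply(units, function(u)
      if (u$hg == hg && !is.na(u$sub)) u$templates else 0L, numeric(1L))))
    if (n_hg - n_sub > 0L) {
      units[[hg]] <- list(hg = hg, sub = NA_character_, n = n_hg - n_sub,
                          templates = min(t_rem, n_hg - n_sub))
    }
  }

  out <- with_local_seed(cfg$seed + 1L, {
    seqs <- list(); truth <- list(); tmpl_total <- 0L
    for (uname in names(units)) {
      u <- units[[uname]]
      base <- apply_motif(ref, table,
                          if (is.na(u$sub)) u$hg else u$sub,
                          with_ancestors = TRUE)
      sizes <- random_composition(u$n, u$templates)
      tmpl_keys <- character(0)
      for (t in seq_len(u$templates)) {
        for (attempt in seq_len(50L)) {
          n_mut <- rpois(1L, cfg$private_mutation_rate)
          pos <- if (n_mut > 0L) {
            sample.int(L, n_mut, prob = weights)
          } else integer(0)
          key <- paste(sort(pos), collapse = ";")
          if (!key %in% tmpl_keys || cfg$private_mutation_rate == 0) break
        }
        tmpl_keys <- c(tmpl_keys, key)
        tseq <- base
        if (length(pos)) tseq[pos] <- mutate_base(tseq[pos], cfg$ts_tv_ratio)
        tmpl_total <- tmpl_total + 1L
        seqs[[length(seqs) + 1L]] <- list(
          seq = tseq, n = sizes[t], hg = u$hg, sub = u$sub,
          template = sprintf("tmpl%03d", tmpl_total),
          private = sort(pos))
      }
    }
    list(seqs = seqs, n_templates = tmpl_total)
  })

  rows <- list(); truth_rows <- list(); i <- 0L
  for (tp in out$seqs) {
    for (rep in seq_len(tp$n)) {
      i <- i + 1L
      id <- sprintf("%s%03d", cfg$id_prefix, i)
      rows[[id]] <- tp$seq
      truth_rows[[id]] <- data.frame(
        sample_id = id, haplogroup = tp$hg, subhaplogroup = tp$sub,
        template = tp$template, n_private = length(tp$private),
        private_positions = paste(tp$private, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  mat <- do.call(rbind, rows)
  rownames(mat) <- names(rows)
  ref_row <- ref
  if (cfg$indel_columns > 0L) {
    ins_at <- with_local_seed(cfg$seed + 2L, {
      sort(sample(cfg$hotspot[1L]:cfg$hotspot[2L], cfg$indel_columns))
    })
    for (ofs in seq_along(ins_at)) {
      at <- ins_at[ofs] + ofs - 1L
      gap_col <- matrix("-", nrow(mat), 1L)
      keep_seq <- with_local_seed(cfg$seed + 3L + ofs,
                                  sample.int(nrow(mat), 1L))
      gap_col[keep_seq, 1L] <- "A"
      mat <- cbind(mat[, seq_len(at - 1L), drop = FALSE], gap_col,
                   mat[, at:ncol(mat), drop = FALSE])
      ref_row <- c(ref_row[seq_len(at - 1L)], "-",
                   ref_row[at:length(ref_row)])
    }
  }
  aln <- mito_alignment(mat,
                        breed_map = setNames(rep(cfg$breed, nrow(mat)),
                                             rownames(mat)),
                        ref_id = attr(table, "reference_id"),
                        ref_seq = paste(ref_row, collapse = ""))
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  attr(truth, "hotspot") <- cfg$hotspot
  attr(truth, "ref") <- ref
  attr(truth, "n_haplotype_classes") <- if (cfg$private_mutation_rate == 0) {
    length(unique(paste(truth$haplogroup, truth$subhaplogroup)))
  } else {
    out$n_templates
  }
  list(alignment = aln, truth = truth)
}

#' Write a synthetic cohort as plain-text fixture files
#'
#' Emits `alignment.fasta`, `breeds.tsv`, `truth.tsv` and
#' `reference.fasta` into `out_dir`; the files round-trip through
#' [read_alignment()].
#'
#' @param cohort a [generate_cohort()] result.
#' @param out_dir output directory (created if missing).
#' @return named character vector of the written paths.
#' @export
write_fixture <- function(cohort, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output dir: ", out_dir)
  aln <- cohort$alignment
  seqs <- apply(aln$seq, 1L, paste, collapse = "")
  paths <- c(
    fasta = file.path(out_dir, "alignment.fasta"),
    breeds = file.path(out_dir, "breeds.tsv"),
    truth = file.path(out_dir, "truth.tsv"),
    reference = file.path(out_dir, "reference.fasta"))
  write_fasta(seqs, paths[["fasta"]])
  write.table(data.frame(sample_id = names(aln$breed_map),
                         breed = unname(aln$breed_map)),
              paths[["breeds"]], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write_tsv(cohort$truth, paths[["truth"]])
  write_fasta(setNames(paste(if (!is.null(aln$ref_row)) aln$ref_row else
    attr(cohort$truth, "ref"), collapse = ""), aln$ref_id),
    paths[["reference"]])
  paths
}
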