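# Diagnostic-motif tables for cattle mtDNA haplogroups.
#
# A motif table defines, relative to a reference backbone, the derived
# alleles whose joint presence diagnoses a clade (taurine T vs indicine I),
# a haplogroup (T1..T6, I1, I2) or a sub-haplogroup (I1a, T1a). Positions
# are 1-based np coordinates in the reference frame. The reference backbone
# is itself a T3 sequence, so T3 carries no derived diagnostic variants and
# acts as the taurine backbone; symmetrically I1 is the indicine backbone
# (diagnosed by the clade-divergence motif alone).

TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

# Deterministic allele assignment used by the packaged synthetic table and
# by the synthetic reference generator: the reference base at a diagnostic
# position is a fixed function of the position, the derived allele its
# transition (bovine mtDNA diagnostic sites are predominantly transitions).
ref_base_at <- function(position) {
  c("A", "C", "G", "T")[(position %% 4L) + 1L]
}

# T6: the novel taurine haplogroup's 12 diagnostic positions; I1a: the five
# positions separating the indicine sub-haplogroup I1a from I1.
T6_POSITIONS <- c(106L, 169L, 2536L, 7931L, 9682L, 11899L, 12923L, 13310L,
                  13374L, 14063L, 16109L, 16255L)
I1A_POSITIONS <- c(1495L, 3051L, 8646L, 12622L, 14027L)

# Synthetic stand-in positions for motifs whose published definitions are
# not reproduced here: all haplogroup-level positions except T6's, and the
# clade-divergence set. Chosen so that no two high-frequency diagnostic
# positions fall within one default scan window.
SYNTH_HG_POSITIONS <- list(
  T1 = c(500L, 2000L, 3500L, 5000L, 6500L, 8300L, 10000L, 11000L),
  T2 = c(800L, 2300L, 3800L, 5300L, 6800L, 11400L, 13700L),
  T4 = c(1100L, 4200L, 5700L, 7250L, 9000L, 14600L),
  T5 = c(4600L, 6100L, 7600L, 10500L, 12200L, 15300L),
  T1a = c(3200L, 6950L, 9300L, 15000L),
  I2 = c(1250L, 2850L, 4400L, 5900L, 7400L, 8900L, 10250L, 11600L,
         13050L, 14350L)
)

# Clade divergence motif: 233 positions separating the indicine (I) matriline
# from the taurine reference backbone (the number matches the mutation count
# separating the two clusters in the published haplotype network). Taken
# from an arithmetic grid, skipping any position already used by a
# haplogroup or sub-haplogroup motif.
clade_positions <- function(n = 233L, ref_length = 16338L) {
  taken <- c(T6_POSITIONS, I1A_POSITIONS, unlist(SYNTH_HG_POSITIONS))
  cand <- setdiff(seq.int(40L, ref_length, by = 69L), taken)
  if (length(cand) < n) stop("reference too short for clade motif")
  cand[seq_len(n)]
}

motif_row <- function(level, label, parent, positions) {
  ref <- ref_base_at(positions)
  data.frame(level = level, label = label, parent = parent,
             position = positions, ref = ref,
             alt = unname(TRANSITION[ref]), stringsAsFactors = FALSE)
}

#' The packaged default motif table
#'
#' Encodes the cattle haplogroup scheme used throughout the package:
#' taurine clade T with haplogroups T1, T2, T3 (backbone), T4, T5 and the
#' novel T6 (12 diagnostic positions), indicine clade I with I1 (backbone)
#' and I2, sub-haplogroups I1a (5 positions, parent I1) and T1a (parent
#' T1, from cited literature). Only the T6 and I1a positions are published
#' coordinates; the clade-divergence set (233 positions) and the remaining
#' haplogroup motifs are synthetic stand-ins with deterministically
#' assigned alleles (derived allele = transition of the reference base),
#' suitable for the synthetic reference frame. Real-data use against
#' V00654 requires regenerating ref/alt alleles from that sequence.
#'
#' @param ref_length length of the reference frame.
#' @return a `motif_table` (see [load_motif_table()]).
#' @export
default_motif_table <- function(ref_length = 16338L) {
  rows <- rbind(
    motif_row("clade", "I", NA_character_, clade_positions(233L, ref_length)),
    motif_row("haplogroup", "T1", "T", SYNTH_HG_POSITIONS$T1),
    motif_row("haplogroup", "T2", "T", SYNTH_HG_POSITIONS$T2),
    motif_row("haplogroup", "T4", "T", SYNTH_HG_POSITIONS$T4),
    motif_row("haplogroup", "T5", "T", SYNTH_HG_POSITIONS$T5),
    motif_row("haplogroup", "T6", "T", T6_POSITIONS),
    motif_row("haplogroup", "I2", "I", SYNTH_HG_POSITIONS$I2),
    motif_row("subhaplogroup", "I1a", "I1", I1A_POSITIONS),
    motif_row("subhaplogroup", "T1a", "T1", SYNTH_HG_POSITIONS$T1a)
  )
  backbone <- data.frame(
    level = "haplogroup", label = c("T3", "I1"), parent = c("T", "I"),
    position = NA_integer_, ref = NA_character_, alt = NA_character_,
    stringsAsFactors = FALSE)
  motif_table(rbind(rows, backbone), reference_id = "synthetic-ref",
              ref_length = ref_length)
}

#' Construct and validate a motif table
#'
#' @param df data.frame with columns `level` (clade / haplogroup /
#'   subhaplogroup), `label`, `parent`, `position`, `ref`, `alt`. A
#'   haplogroup row with `NA` position declares a backbone haplogroup
#'   (no derived diagnostic variants of its own).
#' @param reference_id identifier of the reference frame the positions
#'   refer to.
#' @param ref_length length of that reference.
#' @return object of class `motif_table`: the validated data.frame plus
#'   attributes, with accessors [motif_positions()] and [motif_labels()].
#' @export
motif_table <- function(df, reference_id = "synthetic-ref",
                        ref_length = max(df$position, na.rm = TRUE)) {
  need <- c("level", "label", "parent", "position", "ref", "alt")
  if (!all(need %in% names(df))) {
    stop("motif table needs columns: ", paste(need, collapse = ", "))
  }
  df$position <- as.integer(df$position)
  lev_ok <- df$level %in% c("clade", "haplogroup", "subhaplogroup")
  if (!all(lev_ok)) stop("unknown motif level: ", df$level[!lev_ok][1L])
  var <- df[!is.na(df$position), , drop = FALSE]
  if (any(var$position < 1L | var$position > ref_length)) {
    stop("motif position outside reference frame [1, ", ref_length, "]")
  }
  if (any(!var$ref %in% c("A", "C", "G", "T")) ||
      any(!var$alt %in% c("A", "C", "G", "T"))) {
    stop("motif alleles must be A/C/G/T")
  }
  if (any(var$ref == var$alt)) stop("motif ref and alt alleles must differ")
  dup <- duplicated(var[c("label", "position")])
  if (any(dup)) {
    stop("duplicate position within motif '", var$label[dup][1L], "'")
  }
  hg <- unique(df[df$level == "haplogroup", c("label", "parent")])
  if (anyDuplicated(hg$label)) stop("haplogroup assigned to multiple clades")
  sub <- unique(df[df$level == "subhaplogroup", c("label", "parent")])
  orphan <- setdiff(sub$parent, hg$label)
  if (length(orphan)) {
    stop("sub-haplogroup parent(s) not defined as haplogroup: ",
         paste(orphan, collapse = ", "))
  }
  clades <- unique(c(df$label[df$level == "clade"], hg$parent))
  structure(df, class = c("motif_table", "data.frame"),
            reference_id = reference_id, ref_length = ref_length,
            clades = clades)
}

#' @export
print.motif_table <- function(x, ...) {
  cat("motif_table (frame:", paste0(attr(x, "reference_id"), "):"),
      sum(x$level == "clade" & !is.na(x$position)), "clade variants;",
      "haplogroups:", paste(motif_labels(x, "haplogroup"), collapse = ", "),
      "\n")
  invisible(x)
}

#' Labels defined at a motif level
#' @param table a `motif_table`.
#' @param level `"clade"`, `"haplogroup"` or `"subhaplogroup"`.
#' @return character vector of labels.
#' @export
motif_labels <- function(table, level = "haplogroup") {
  sort(unique(table$label[table$level == level]))
}

#' Diagnostic variants of one label
#' @param table a `motif_table`.
#' @param label clade / haplogroup / sub-haplogroup label.
#' @return data.frame of the label's variants (0 rows for a backbone).
#' @export
motif_positions <- function(table, label) {
  out <- table[table$label == label & !is.na(table$position), , drop = FALSE]
  out[order(out$position), , drop = FALSE]
}

# Parent haplogroup of a sub-haplogroup / parent clade of a haplogroup;
# NA for a clade or an unknown label.
motif_parent <- function(table, label) {
  p <- unique(table$parent[table$label == label])
  p <- p[!is.na(p)]
  if (length(p)) p[1L] else NA_character_
}

#' Read a motif table from TSV
#'
#' Expects the six columns documented in [motif_table()]; `NA` (or empty)
#' position rows declare backbone haplogroups.
#'
#' @param path TSV path.
#' @inheritParams motif_table
#' @return a `motif_table`.
#' @export
load_motif_table <- function(path, reference_id = "synthetic-ref",
                             ref_length = NULL) {
  if (!file.exists(path)) stop("motif table file not found: ", path)
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (is.null(ref_length)) ref_length <- max(df$position, na.rm = TRUE)
  motif_table(df, reference_id = reference_id, ref_length = ref_length)
}

#' Write a motif table to TSV
#' @param table a `motif_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_motif_table <- function(table, path) {
  write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Apply a label's diagnostic motif to a sequence
#'
#' Substitutes the derived (alt) alleles of `label` — plus, for a
#' haplogroup or sub-haplogroup, the derived alleles of its ancestors
#' (clade motif; parent haplogroup motif for a sub-haplogroup) — into a
#' reference-frame sequence. Used by the synthetic generator and by
#' round-trip tests.
#'
#' @param seq character vector (one element per position) or single string.
#' @param table a `motif_table`.
#' @param label the label whose motif to apply.
#' @param with_ancestors substitute ancestral (clade, parent) motifs too.
#' @return character vector of the mutated sequence.
#' @export
apply_motif <- function(seq, table, label, with_ancestors = TRUE) {
  s <- if (length(seq) == 1L && nchar(seq[1L]) > 1L) {
    strsplit(seq, "", fixed = TRUE)[[1L]]
  } else seq
  chain <- label
  if (with_ancestors) {
    repeat {
      p <- motif_parent(table, chain[1L])
      if (is.na(p) || p %in% chain) break
      chain <- c(p, chain)
      if (!p %in% table$label) break  # clade absent from table (backbone)
    }
  }
  for (lab in chain) {
    v <- motif_positions(table, lab)
    if (nrow(v)) s[v$position] <- v$alt
  }
  s
}
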