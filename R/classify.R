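# Motif-based haplogroup classification.
#
# Assignment is hierarchical: (1) the clade is decided by comparing, over
# the clade-divergence positions, the fraction of derived (indicine)
# alleles against the fraction of reference (taurine) alleles; (2) within
# the clade, every haplogroup motif is scored as the fraction of its
# assessable diagnostic positions carrying the derived allele, the clade
# backbone (T3 / I1) being scored as the fraction of reference alleles
# over the union of the other in-clade motifs' positions; (3) a
# sub-haplogroup label is added when its full motif is present. N or gap
# at a diagnostic position makes that position unassessable (dropped from
# numerator and denominator).

score_positions <- function(s, positions, want) {
  obs <- s[positions]
  assessable <- obs %in% c("A", "C", "G", "T")
  matched <- sum(obs[assessable] == want[assessable])
  list(matched = matched, total = sum(assessable),
       score = if (sum(assessable)) matched / sum(assessable) else NA_real_,
       mismatched = positions[assessable & obs != want],
       unassessed = positions[!assessable])
}

#' Classify one mitogenome by diagnostic motifs
#'
#' @param seq sequence to classify (single string or per-position
#'   character vector) in the reference coordinate frame.
#' @param ref_seq the reference backbone in the same frame.
#' @param table a [motif_table()].
#' @param threshold minimum fraction of assessable diagnostic alleles that
#'   must match for a haplogroup label to be accepted (default 0.8).
#' @param novel_min_private minimum number of derived variants outside all
#'   known diagnostic positions for a backbone-matching sequence to be
#'   flagged `"<clade>-novel"` instead (default 10; the T6 discovery
#'   carried 12 such variants).
#' @return list of class `haplogroup_call`: `sample_id`, `clade`,
#'   `haplogroup` (possibly `"T-novel"`/`"I-novel"`), `subhaplogroup`
#'   (NA if none), `score`, `clade_score`, `matched`, `total`,
#'   `mismatched_positions`, `unassessed_positions`, `private_positions`
#'   (derived variants outside all known motifs), `tie` (TRUE when the
#'   deciding score was tied and broken by rule).
#' @export
call_haplogroup <- function(seq, ref_seq, table, threshold = 0.8,
                            novel_min_private = 10L) {
  s <- if (length(seq) == 1L && nchar(seq[1L]) > 1L) {
    strsplit(seq, "", fixed = TRUE)[[1L]]
  } else as.character(seq)
  r <- if (length(ref_seq) == 1L && nchar(ref_seq[1L]) > 1L) {
    strsplit(ref_seq, "", fixed = TRUE)[[1L]]
  } else as.character(ref_seq)
  max_pos <- max(table$position, na.rm = TRUE)
  if (length(s) < max_pos) {
    stop("sequence length ", length(s),
         " is shorter than the largest motif position ", max_pos)
  }
  s <- toupper(s); r <- toupper(r)

  # ---- clade ----
  clade_var <- table[table$level == "clade" & !is.na(table$position), ,
                     drop = FALSE]
  clades <- attr(table, "clades")
  clade_scores <- setNames(numeric(0), character(0))
  for (cl in sort(clades)) {
    v <- clade_var[clade_var$label == cl, , drop = FALSE]
    if (nrow(v)) {
      sc <- score_positions(s, v$position, v$alt)$score
    } else {
      # backbone clade: reference alleles over the other clades' positions
      sc <- score_positions(s, clade_var$position, clade_var$ref)$score
    }
    clade_scores[cl] <- sc
  }
  best_cl <- names(clade_scores)[order(-clade_scores, names(clade_scores))][1L]
  cl_max <- suppressWarnings(max(clade_scores, na.rm = TRUE))
  clade_tie <- is.finite(cl_max) &&
    sum(clade_scores == cl_max, na.rm = TRUE) > 1L

  # ---- haplogroup within clade ----
  hgs <- unique(table$label[table$level == "haplogroup" &
                              table$parent == best_cl])
  if (!length(hgs)) stop("no haplogroups defined for clade ", best_cl)
  union_pos <- sort(unique(table$position[
    table$level == "haplogroup" & table$parent == best_cl &
      !is.na(table$position)]))
  hg_res <- list()
  for (hg in hgs) {
    v <- motif_positions(table, hg)
    if (nrow(v)) {
      hg_res[[hg]] <- score_positions(s, v$position, v$alt)
      hg_res[[hg]]$backbone <- FALSE
    } else {
      hg_res[[hg]] <- score_positions(s, union_pos, r[union_pos])
      hg_res[[hg]]$backbone <- TRUE
    }
  }
  scores <- vapply(hg_res, function(x) x$score, numeric(1L))
  totals <- vapply(hg_res, function(x) x$total, numeric(1L))
  ord <- order(-scores, -totals, names(scores))
  best_hg <- names(scores)[ord][1L]
  top <- which(scores == scores[best_hg])
  hg_tie <- length(top) > 1L && length(unique(totals[top])) == 1L

  # derived variants not explained by any known diagnostic position
  known_pos <- table$position[!is.na(table$position)]
  derived <- which(s != r & s %in% c("A", "C", "G", "T") &
                     r %in% c("A", "C", "G", "T"))
  private <- setdiff(derived, known_pos)

  best <- hg_res[[best_hg]]
  if (is.na(best$score) || best$score < threshold) {
    label <- paste0(best_cl, "-novel")
  } else if (best$backbone && length(private) >= novel_min_private) {
    label <- paste0(best_cl, "-novel")
  } else {
    label <- best_hg
  }

  # ---- sub-haplogroup: full motif required ----
  sub_label <- NA_character_
  if (!endsWith(label, "-novel")) {
    subs <- unique(table$label[table$level == "subhaplogroup" &
                                 table$parent == label])
    for (sb in subs) {
      v <- motif_positions(table, sb)
      res <- score_positions(s, v$position, v$alt)
      if (res$total > 0L && res$matched == res$total) {
        sub_label <- sb
        break
      }
    }
  }

  structure(
    list(sample_id = NA_character_, clade = best_cl,
         haplogroup = label, subhaplogroup = sub_label,
         score = unname(best$score),
         clade_score = unname(clade_scores[best_cl]),
         matched = unname(best$matched), total = unname(best$total),
         mismatched_positions = best$mismatched,
         unassessed_positions = best$unassessed,
         private_positions = private,
         tie = clade_tie || hg_tie),
    class = "haplogroup_call")
}

#' @export
print.haplogroup_call <- function(x, ...) {
  cat(sprintf("haplogroup_call: clade %s, %s%s (score %.3f, %d/%d)\n",
              x$clade, x$haplogroup,
              if (!is.na(x$subhaplogroup)) paste0("/", x$subhaplogroup) else "",
              x$score, x$matched, x$total))
  invisible(x)
}

#' Classify every sample of an alignment
#'
#' Maps alignment columns to np coordinates through the site index's
#' reference projection before motif matching, then calls
#' [call_haplogroup()] per sample.
#'
#' @param aln a [mito_alignment()] (its `ref_row` is the backbone; a
#'   `ref_seq` argument overrides it).
#' @param table a [motif_table()].
#' @param ref_seq optional explicit reference sequence.
#' @inheritParams call_haplogroup
#' @return data.frame with one row per sample: `sample_id`, `breed`,
#'   `clade`, `haplogroup`, `subhaplogroup`, `score`, `matched`, `total`,
#'   `mismatches` and `private` (semicolon-joined np positions), plus the
#'   per-sample call objects in `attr(, "calls")`.
#' @export
classify_cohort <- function(aln, table, ref_seq = NULL, threshold = 0.8,
                            novel_min_private = 10L) {
  if (is.null(ref_seq)) ref_seq <- aln$ref_row
  if (is.null(ref_seq)) {
    stop("no reference sequence: supply ref_seq or build the alignment ",
         "with one")
  }
  if (length(ref_seq) == 1L && nchar(ref_seq[1L]) > 1L) {
    ref_seq <- strsplit(ref_seq, "", fixed = TRUE)[[1L]]
  }
  # project onto np coordinates: columns inserted relative to the
  # reference carry no np and are excluded from motif matching
  mat <- aln$seq
  if (any(ref_seq == "-")) {
    keep <- which(ref_seq != "-")
    mat <- mat[, keep, drop = FALSE]
    ref_seq <- ref_seq[keep]
  }
  calls <- lapply(rownames(mat), function(id) {
    cl <- call_haplogroup(mat[id, ], ref_seq, table,
                          threshold = threshold,
                          novel_min_private = novel_min_private)
    cl$sample_id <- id
    cl
  })
  df <- data.frame(
    sample_id = vapply(calls, `[[`, character(1L), "sample_id"),
    breed = unname(aln$breed_map[rownames(aln$seq)]),
    clade = vapply(calls, `[[`, character(1L), "clade"),
    haplogroup = vapply(calls, `[[`, character(1L), "haplogroup"),
    subhaplogroup = vapply(calls, `[[`, character(1L), "subhaplogroup"),
    score = vapply(calls, `[[`, numeric(1L), "score"),
    matched = vapply(calls, function(x) as.integer(x$matched), integer(1L)),
    total = vapply(calls, function(x) as.integer(x$total), integer(1L)),
    mismatches = vapply(calls, function(x)
      paste(x$mismatched_positions, collapse = ";"), character(1L)),
    private = vapply(calls, function(x)
      paste(x$private_positions, collapse = ";"), character(1L)),
    stringsAsFactors = FALSE)
  attr(df, "calls") <- calls
  df
}

# Round half away from zero to `digits` decimals (printed-table convention).
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Haplogroup frequency table
#'
#' Counts and percentages per haplogroup label, per breed and overall,
#' with clade-level aggregates. Percentages are 100 * count / n rounded
#' half-up to 2 decimals, the convention of printed frequency reports.
#'
#' @param calls a [classify_cohort()] data.frame, or a named vector of
#'   haplogroup counts (then `breed_map` is ignored and clades are taken
#'   from the label's first character).
#' @param breed_map optional named character vector (sample id -> breed);
#'   defaults to the `breed` column of `calls`.
#' @return data.frame with columns `breed` (`"all"` for the pooled rows),
#'   `level` (`"haplogroup"` or `"clade"`), `label`, `count`, `n`, `pct`.
#' @export
haplogroup_frequencies <- function(calls, breed_map = NULL) {
  if (!is.data.frame(calls)) {
    counts <- calls
    calls <- data.frame(
      sample_id = paste0("s", seq_len(sum(counts))),
      breed = "all",
      clade = rep(substr(names(counts), 1L, 1L), counts),
      haplogroup = rep(names(counts), counts),
      stringsAsFactors = FALSE)
  }
  if (!is.null(breed_map)) calls$breed <- breed_map[calls$sample_id]
  one_group <- function(sub, breed) {
    n <- nrow(sub)
    hg <- table(sub$haplogroup)
    cl <- table(sub$clade)
    rbind(
      data.frame(breed = breed, level = "haplogroup",
                 label = names(hg), count = as.integer(hg), n = n,
                 pct = round_half_up(100 * as.integer(hg) / n),
                 stringsAsFactors = FALSE),
      data.frame(breed = breed, level = "clade",
                 label = names(cl), count = as.integer(cl), n = n,
                 pct = round_half_up(100 * as.integer(cl) / n),
                 stringsAsFactors = FALSE))
  }
  out <- one_group(calls, "all")
  breeds <- setdiff(unique(calls$breed), "all")
  if (length(breeds) > 1L) {
    for (b in breeds) {
      out <- rbind(out, one_group(calls[calls$breed == b, , drop = FALSE], b))
    }
  }
  rownames(out) <- NULL
  out
}

#' Report sequences flagged as novel matrilines
#'
#' For every `"<clade>-novel"` call, lists the np positions where the
#' sequence differs from the reference, excluding positions explained by
#' known diagnostic motifs — the same style as a published novel-motif
#' list (e.g. the 12 mutations defining T6).
#'
#' @param calls a [classify_cohort()] result.
#' @return data.frame `sample_id`, `clade`, `n_private`, `positions`
#'   (semicolon-joined np list); zero rows when no sequence is novel.
#' @export
detect_novel <- function(calls) {
  novel <- calls[endsWith(calls$haplogroup, "-novel"), , drop = FALSE]
  data.frame(sample_id = novel$sample_id, clade = novel$clade,
             n_private = ifelse(novel$private == "", 0L,
                                lengths(strsplit(novel$private, ";"))),
             positions = novel$private,
             stringsAsFactors = FALSE, row.names = NULL)
}
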