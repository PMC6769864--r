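# Per-column pairwise mismatch machinery.
#
# At a column with base counts n_b over v valid (non-gap, non-N) samples,
# the number of mismatching unordered pairs is C(v,2) - sum_b C(v_b,2);
# dividing by C(v,2) gives the column's mean pairwise difference. Under
# complete deletion v = n at every usable column, so summing the fractions
# over columns equals the brute-force double loop's k exactly; under
# pairwise deletion columns are normalized by their own valid pair count.
# O(nL) instead of O(n^2 L).
column_mismatch_frac <- function(mat) {
  bases <- c("A", "C", "G", "T")
  cb <- vapply(bases, function(b) colSums(mat == b), numeric(ncol(mat)))
  if (is.null(dim(cb))) cb <- matrix(cb, nrow = 1L)
  valid <- rowSums(cb)
  same <- rowSums(cb * (cb - 1) / 2)
  pairs <- valid * (valid - 1) / 2
  ifelse(pairs > 0, (pairs - same) / pairs, NA_real_)
}

#' Classify variable sites
#'
#' A usable column is variable iff at least two distinct bases occur;
#' parsimony informative iff at least two distinct bases each occur in at
#' least two samples; singleton otherwise. The classification is at column
#' level, so S = singletons + parsimony informative.
#'
#' @param aln a [mito_alignment()].
#' @param idx a [build_site_index()] result.
#' @return list with `S`, `singletons`, `parsimony_informative`, and
#'   `variable_columns` (alignment column indices of the variable sites).
#' @export
classify_variable_sites <- function(aln, idx) {
  if (nrow(aln$seq) < 2L) stop("need at least 2 sequences")
  mat <- aln$seq[, idx$usable, drop = FALSE]
  counts <- sapply(c("A", "C", "G", "T"),
                   function(b) colSums(mat == b))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L)
  n_alleles <- rowSums(counts > 0L)
  n_common <- rowSums(counts >= 2L)
  variable <- n_alleles >= 2L
  informative <- variable & n_common >= 2L
  list(S = sum(variable),
       singletons = sum(variable & !informative),
       parsimony_informative = sum(informative),
       variable_columns = idx$usable[variable])
}

#' Nei haplotype (gene) diversity
#'
#' Hd = n(1 - sum p_i^2)/(n - 1) with Nei's (1987) sampling variance
#' V(Hd) = (2/(n(n-1))) * (2(n-2)(sum p_i^3 - (sum p_i^2)^2)
#' + sum p_i^2 - (sum p_i^2)^2); the reported SD is sqrt(V).
#'
#' @param h a [collapse_haplotypes()] result, or a vector of haplotype
#'   counts.
#' @return list with `Hd` and `Hd_sd`.
#' @export
haplotype_diversity <- function(h) {
  counts <- if (inherits(h, "haplotype_set")) h$counts else h
  n <- sum(counts)
  if (n < 2L) stop("haplotype diversity requires n >= 2")
  p <- counts / n
  s2 <- sum(p^2)
  s3 <- sum(p^3)
  hd <- n * (1 - s2) / (n - 1)
  v <- 2 / (n * (n - 1)) *
    (2 * (n - 2) * (s3 - s2^2) + s2 - s2^2)
  list(Hd = hd, Hd_sd = sqrt(max(v, 0)))
}

#' Average pairwise differences and nucleotide diversity
#'
#' k is the mean number of differing usable sites over all C(n,2) sample
#' pairs; Pi = k / L where L is the number of analyzed (usable) sites.
#' The SD of Pi is Nei's (1987) eq. 10.7 variance (stochastic + sampling):
#' V(pi) = (n+1)/(3(n-1)L) * pi + 2(n^2+n+3)/(9n(n-1)) * pi^2.
#'
#' @param aln a [mito_alignment()] (or a `haplotype_set`, in which case
#'   pairs are weighted by haplotype counts).
#' @param idx site index (ignored when `aln` is a `haplotype_set`).
#' @return list with `k`, `Pi`, `Pi_sd`, `L_used`.
#' @export
pairwise_differences <- function(aln, idx = NULL) {
  if (inherits(aln, "haplotype_set")) {
    mat <- aln$seqs
    n <- aln$n
    # weighted pairs: expand column mismatches over haplotype counts
    cts <- aln$counts
    tot_pairs <- n * (n - 1) / 2
    diffs <- 0
    hn <- nrow(mat)
    if (hn > 1L) {
      for (i in seq_len(hn - 1L)) {
        for (j in seq.int(i + 1L, hn)) {
          d <- sum(mat[i, ] != mat[j, ])
          diffs <- diffs + d * cts[i] * cts[j]
        }
      }
    }
    k <- unname(diffs / tot_pairs)
    L <- ncol(mat)
  } else {
    if (is.null(idx)) stop("a site_index is required for an alignment")
    mat <- aln$seq[, idx$usable, drop = FALSE]
    n <- nrow(mat)
    if (n < 2L) stop("pairwise differences require n >= 2")
    k <- sum(column_mismatch_frac(mat), na.rm = TRUE)
    L <- ncol(mat)
  }
  pi <- k / L
  v <- (n + 1) / (3 * (n - 1) * L) * pi +
    2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi^2
  list(k = k, Pi = pi, Pi_sd = sqrt(max(v, 0)), L_used = L)
}

#' Full diversity statistic bundle for one population
#'
#' Computes the per-population row of the genetic-structure table:
#' number of variable sites S (split into singletons and
#' parsimony-informative sites), number of haplotypes H, haplotype
#' diversity Hd with SD, average pairwise differences k, and nucleotide
#' diversity Pi with SD.
#'
#' @inheritParams classify_variable_sites
#' @return list of class `diversity_stats`.
#' @export
diversity_stats <- function(aln, idx) {
  h <- collapse_haplotypes(aln, idx)
  vs <- classify_variable_sites(aln, idx)
  hd <- haplotype_diversity(h)
  pw <- pairwise_differences(aln, idx)
  structure(
    list(S = vs$S, singletons = vs$singletons,
         parsimony_informative = vs$parsimony_informative,
         H = nrow(h$seqs), Hd = hd$Hd, Hd_sd = hd$Hd_sd,
         k = pw$k, Pi = pw$Pi, Pi_sd = pw$Pi_sd, L_used = pw$L_used),
    class = "diversity_stats")
}

#' @export
print.diversity_stats <- function(x, ...) {
  cat(sprintf(
    "S=%d (singletons %d, informative %d)  H=%d  k=%.3f\nHd=%.3f +/- %.3f  Pi=%.5f +/- %.5f  (L=%d sites)\n",
    x$S, x$singletons, x$parsimony_informative, x$H, x$k,
    x$Hd, x$Hd_sd, x$Pi, x$Pi_sd, x$L_used))
  invisible(x)
}

#' Sliding-window nucleotide diversity scan
#'
#' Computes Pi in windows of `window_size` reference (np) positions moved
#' by `step`, restricted to usable sites; windows containing no usable
#' site get `Pi = NA` (undefined, not zero). Used to localize
#' hypervariable regions such as the D-loop.
#'
#' @inheritParams classify_variable_sites
#' @param window_size window width in np positions.
#' @param step window offset in np positions.
#' @param from,to np range to scan (defaults to the full reference range).
#' @return data.frame of class `diversity_profile` with columns
#'   `start_np`, `end_np`, `n_usable`, `Pi`.
#' @export
diversity_scan <- function(aln, idx, window_size = 200L, step = 25L,
                           from = NULL, to = NULL) {
  stopifnot(window_size >= 1L, step >= 1L)
  np_max <- max(idx$np, na.rm = TRUE)
  if (is.null(from)) from <- 1L
  if (is.null(to)) to <- np_max
  if (from < 1L || to > np_max || from > to) {
    stop("scan range [", from, ", ", to, "] outside reference range [1, ",
         np_max, "]")
  }
  mat <- aln$seq[, idx$usable, drop = FALSE]
  mm <- column_mismatch_frac(mat)
  np <- idx$np[idx$usable]
  starts <- seq.int(from, max(from, to - window_size + 1L), by = step)
  ends <- pmin(starts + window_size - 1L, to)
  res <- data.frame(start_np = starts, end_np = ends,
                    n_usable = NA_integer_, Pi = NA_real_)
  for (w in seq_along(starts)) {
    inw <- np >= starts[w] & np <= ends[w]
    nu <- sum(inw)
    res$n_usable[w] <- nu
    if (nu > 0L) res$Pi[w] <- sum(mm[inw], na.rm = TRUE) / nu
  }
  attr(res, "window_size") <- window_size
  attr(res, "step") <- step
  class(res) <- c("diversity_profile", "data.frame")
  res
}

#' Peak window of a diversity profile
#' @param profile a [diversity_scan()] result.
#' @return the row (data.frame) with the highest Pi (first on ties).
#' @export
scan_peak <- function(profile) {
  ok <- which(!is.na(profile$Pi))
  if (!length(ok)) stop("no window with usable sites")
  profile[ok[which.max(profile$Pi[ok])], , drop = FALSE]
}

#' Per-breed diversity and haplogroup report
#'
#' One row per breed plus a pooled `Total` row (statistics recomputed on
#' the pooled alignment, not summed). Haplogroup columns are call counts
#' from [classify_cohort()]; breeds with fewer than 2 samples get `NA`
#' statistics.
#'
#' @param aln a [mito_alignment()] carrying a breed map.
#' @param calls optional data.frame of haplogroup calls (columns
#'   `sample_id`, `haplogroup`); omit to skip haplogroup columns.
#' @param policy site policy passed to [build_site_index()].
#' @return data.frame with columns Breed, n, one column per haplogroup
#'   label, then S, H, k, Hd, Hd_sd, Pi, Pi_sd.
#' @export
breed_diversity_report <- function(aln, calls = NULL, policy = "complete") {
  breeds <- unique(aln$breed_map[rownames(aln$seq)])
  groups <- c(as.list(setNames(breeds, breeds)), list(Total = breeds))
  if (length(breeds) == 1L) groups$Total <- NULL
  hg_labels <- if (!is.null(calls)) sort(unique(calls$haplogroup)) else NULL
  rows <- lapply(names(groups), function(gname) {
    keep <- rownames(aln$seq)[aln$breed_map[rownames(aln$seq)] %in%
                                groups[[gname]]]
    row <- list(Breed = gname, n = length(keep))
    if (!is.null(hg_labels)) {
      sub <- calls[calls$sample_id %in% keep, , drop = FALSE]
      for (hg in hg_labels) row[[hg]] <- sum(sub$haplogroup == hg)
    }
    if (length(keep) >= 2L) {
      sub_aln <- mito_alignment(aln$seq[keep, , drop = FALSE],
                                breed_map = aln$breed_map[keep],
                                ref_id = aln$ref_id)
      sub_aln$ref_row <- aln$ref_row
      st <- diversity_stats(sub_aln, build_site_index(sub_aln, policy))
      row <- c(row, st[c("S", "H", "k", "Hd", "Hd_sd", "Pi", "Pi_sd")])
    } else {
      row <- c(row, list(S = NA, H = NA, k = NA, Hd = NA, Hd_sd = NA,
                         Pi = NA, Pi_sd = NA))
    }
    as.data.frame(row, check.names = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a diversity report or profile as TSV
#' @param x data.frame to write.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
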