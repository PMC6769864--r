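#' Collapse samples into haplotypes
#'
#' Two samples share a haplotype iff they are identical at every usable
#' site. Labels "H1", "H2", ... are assigned by descending count, ties by
#' first occurrence in the alignment.
#'
#' @param aln a [mito_alignment()].
#' @param idx a [build_site_index()] result for `aln`.
#' @return an object of class `haplotype_set`: `seqs` (character matrix of
#'   distinct haplotypes over usable sites, rownames = labels), `counts`
#'   (named integer), `members` (named list of sample ids), `n` (total
#'   samples), `usable` (the site index columns used).
#' @export
collapse_haplotypes <- function(aln, idx) {
  sub <- aln$seq[, idx$usable, drop = FALSE]
  keys <- apply(sub, 1L, paste, collapse = "")
  first <- !duplicated(keys)
  uniq <- keys[first]
  grp <- match(keys, uniq)
  counts <- tabulate(grp, nbins = length(uniq))
  ord <- order(-counts, seq_along(uniq))
  labels <- character(length(uniq))
  labels[ord] <- paste0("H", seq_along(uniq))
  members <- split(rownames(sub), labels[grp])
  hmat <- sub[first, , drop = FALSE]
  rownames(hmat) <- labels
  hmat <- hmat[order(as.integer(sub("^H", "", rownames(hmat)))), ,
               drop = FALSE]
  counts <- setNames(counts[ord], paste0("H", seq_along(uniq)))
  members <- members[rownames(hmat)]
  structure(
    list(seqs = hmat, counts = counts, members = members,
         n = nrow(sub), usable = idx$usable,
         np = idx$np[idx$usable]),
    class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("haplotype_set:", nrow(x$seqs), "haplotypes over", ncol(x$seqs),
      "usable sites;", x$n, "samples\n")
  invisible(x)
}

#' Write one representative sequence per haplotype to FASTA
#'
#' Representatives are the full aligned sequence of the first member of
#' each haplotype; headers carry the haplotype label and count.
#'
#' @param h a `haplotype_set`.
#' @param aln the alignment it came from.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_haplotypes_fasta <- function(h, aln, path) {
  reps <- vapply(h$members, `[[`, character(1L), 1L)
  seqs <- apply(aln$seq[reps, , drop = FALSE], 1L, paste, collapse = "")
  names(seqs) <- sprintf("%s n=%d rep=%s", names(h$members),
                         h$counts[names(h$members)], reps)
  write_fasta(seqs, path)
}
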