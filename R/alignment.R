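#' @importFrom stats rpois runif setNames
#' @importFrom utils read.table write.table head tail
NULL

ALPHABET <- c("A", "C", "G", "T", "N", "-")

#' Construct a reference-frame mitogenome alignment
#'
#' A `mito_alignment` holds one row per animal over a common reference
#' coordinate frame ("np" positions, 1-based, as used for the bovine
#' reference V00654). All downstream statistics, motif matching and network
#' construction operate on this container.
#'
#' @param seqs named character vector of aligned sequences (one string per
#'   sample), or a character matrix with one row per sample and one aligned
#'   column per position.
#' @param breed_map named character vector mapping sample id to breed label;
#'   samples absent from the map are labelled `"unknown"`.
#' @param ref_id identifier of the reference coordinate frame.
#' @param ref_seq optional reference sequence in the same frame; when it
#'   contains gap columns these columns carry no np coordinate and are
#'   excluded from motif matching.
#' @return an object of class `mito_alignment` with elements `seq`
#'   (character matrix, rownames = sample ids), `aligned_length`, `ref_id`,
#'   `ref_row`, `breed_map`.
#' @export
mito_alignment <- function(seqs, breed_map = NULL, ref_id = "synthetic-ref",
                           ref_seq = NULL) {
  if (is.matrix(seqs)) {
    mat <- toupper(seqs)
    ids <- rownames(mat)
  } else {
    ids <- names(seqs)
    if (is.null(ids)) stop("sequences must be named by sample id")
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L) {
      bad <- names(seqs)[lens != lens[1L]]
      stop("alignment error: unequal sequence lengths for: ",
           paste(bad, collapse = ", "))
    }
    mat <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
    rownames(mat) <- ids
  }
  if (is.null(ids) || anyNA(ids) || any(ids == "")) {
    stop("every sequence must carry a sample id")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sample id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  mat[mat == "U"] <- "T"
  bad <- which(!(mat %in% ALPHABET))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(mat)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(mat)) + 1L
    stop(sprintf(
      "illegal character '%s' in sample '%s' at column %d (allowed: %s)",
      mat[bad[1L]], ids[i], j, paste(ALPHABET, collapse = "")))
  }
  if (!is.null(ref_seq)) {
    ref_row <- strsplit(toupper(ref_seq), "", fixed = TRUE)[[1L]]
    ref_row[ref_row == "U"] <- "T"
    if (length(ref_row) != ncol(mat)) {
      stop("reference sequence length (", length(ref_row),
           ") does not match aligned length (", ncol(mat), ")")
    }
  } else {
    ref_row <- NULL
  }
  bm <- setNames(rep("unknown", length(ids)), ids)
  if (!is.null(breed_map)) {
    extra <- setdiff(names(breed_map), ids)
    if (length(extra)) {
      stop("breed map refers to unknown sample id(s): ",
           paste(extra, collapse = ", "))
    }
    bm[names(breed_map)] <- unname(breed_map)
  }
  structure(
    list(seq = mat, aligned_length = ncol(mat), ref_id = ref_id,
         ref_row = ref_row, breed_map = bm),
    class = "mito_alignment")
}

#' @export
print.mito_alignment <- function(x, ...) {
  cat("mito_alignment:", nrow(x$seq), "samples x", x$aligned_length,
      "columns (frame:", paste0(x$ref_id, ")"), "\n")
  tb <- table(x$breed_map)
  cat("breeds:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  invisible(x)
}

#' Number of samples in an alignment
#' @param aln a `mito_alignment`.
#' @return integer sample count.
#' @export
n_samples <- function(aln) nrow(aln$seq)

#' Read an aligned mitogenome FASTA and breed map
#'
#' Reads a multi-FASTA of pre-aligned mitogenomes (all records in a common
#' reference frame, equal lengths) and an optional two-column TSV
#' (`sample_id<TAB>breed`, header optional) into a validated
#' [mito_alignment()]. Characters are uppercased and U is mapped to T.
#'
#' @param fasta_file path to the aligned multi-FASTA (>= 2 records).
#' @param breed_file optional path to the breed TSV.
#' @inheritParams mito_alignment
#' @return a `mito_alignment`.
#' @export
read_alignment <- function(fasta_file, breed_file = NULL,
                           ref_id = "synthetic-ref", ref_seq = NULL) {
  if (!file.exists(fasta_file)) stop("FASTA file not found: ", fasta_file)
  ss <- Biostrings::readBStringSet(fasta_file)
  if (length(ss) < 2L) stop("need at least 2 FASTA records, got ", length(ss))
  seqs <- setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  bm <- if (!is.null(breed_file)) read_breed_map(breed_file) else NULL
  if (!is.null(bm)) bm <- bm[names(bm) %in% names(seqs)]
  mito_alignment(seqs, breed_map = bm, ref_id = ref_id, ref_seq = ref_seq)
}

#' Read a breed map TSV
#'
#' @param path two-column TSV (sample_id, breed); a header line is detected
#'   and skipped when its first field is `sample_id`.
#' @return named character vector (sample id -> breed).
#' @export
read_breed_map <- function(path) {
  if (!file.exists(path)) stop("breed map file not found: ", path)
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE, col.names = c("sample_id", "breed"),
                   colClasses = "character")
  if (nrow(df) && identical(tolower(df$sample_id[1L]), "sample_id")) {
    df <- df[-1L, , drop = FALSE]
  }
  setNames(df$breed, df$sample_id)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Build the analyzed-site index for an alignment
#'
#' Implements the site-filtering convention for all diversity statistics.
#' Under the default complete-deletion policy any column containing a gap or
#' an N in any sample is excluded; under pairwise deletion only columns that
#' are gap/N in every sample are excluded (per-column sample exclusion is
#' then handled by the statistics). Columns absent from the reference row
#' (reference gap) carry no np coordinate and are always excluded.
#'
#' @param aln a `mito_alignment`.
#' @param policy `"complete"` (default) or `"pairwise"`.
#' @return an object of class `site_index`: `usable` (increasing column
#'   indices), `excluded` (data.frame of column + reason code), `np`
#'   (1-based reference coordinate of every column; NA for inserted
#'   columns), `policy`.
#' @export
build_site_index <- function(aln, policy = c("complete", "pairwise")) {
  policy <- match.arg(policy)
  mat <- aln$seq
  L <- ncol(mat)
  if (!is.null(aln$ref_row)) {
    ref_gap <- aln$ref_row == "-"
    np <- ifelse(ref_gap, NA_integer_, cumsum(!ref_gap))
  } else {
    ref_gap <- rep(FALSE, L)
    np <- seq_len(L)
  }
  has_gap <- colSums(mat == "-") > 0L
  has_n <- colSums(mat == "N") > 0L
  if (policy == "complete") {
    drop <- has_gap | has_n | ref_gap
  } else {
    all_missing <- colSums(mat == "-" | mat == "N") == nrow(mat)
    drop <- all_missing | ref_gap
  }
  reason <- rep(NA_character_, L)
  reason[has_n & !has_gap] <- "ambiguous"
  reason[has_gap] <- "gap"
  reason[ref_gap] <- "not_in_reference"
  usable <- which(!drop)
  if (!length(usable)) stop("zero usable sites under policy '", policy, "'")
  structure(
    list(usable = usable,
         excluded = data.frame(column = which(drop),
                               reason = reason[drop],
                               stringsAsFactors = FALSE),
         np = as.integer(np), policy = policy),
    class = "site_index")
}

#' @export
print.site_index <- function(x, ...) {
  cat("site_index:", length(x$usable), "usable sites,",
      nrow(x$excluded), "excluded (policy:", paste0(x$policy, ")"), "\n")
  invisible(x)
}

# Map np (reference) positions to alignment columns; NA when not present.
np_to_column <- function(idx, np_positions) {
  match(np_positions, idx$np)
}
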