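# Neighbor-joining tree over haplotypes, with column-resampling bootstrap.

#' Pairwise Hamming distances between haplotypes
#'
#' @param h a [collapse_haplotypes()] result, or a character matrix of
#'   aligned haplotype sequences (rownames = labels).
#' @param per_site divide raw differences by the number of compared sites.
#' @return a symmetric `matrix` with zero diagonal (class `dist` friendly
#'   via [stats::as.dist()]); metadata attribute `units` is
#'   `"differences"` or `"per_site"`.
#' @export
hamming_distances <- function(h, per_site = FALSE) {
  mat <- if (inherits(h, "haplotype_set")) h$seqs else h
  if (nrow(mat) < 2L) stop("need >= 2 haplotypes")
  labs <- rownames(mat)
  nh <- nrow(mat)
  d <- matrix(0, nh, nh, dimnames = list(labs, labs))
  for (i in seq_len(nh - 1L)) {
    for (j in seq.int(i + 1L, nh)) {
      dij <- sum(mat[i, ] != mat[j, ])
      d[i, j] <- d[j, i] <- dij
    }
  }
  if (per_site) d <- d / ncol(mat)
  attr(d, "units") <- if (per_site) "per_site" else "differences"
  d
}

#' Neighbor-joining tree
#'
#' Standard NJ agglomeration (Saitou & Nei Q-criterion, via
#' [ape::nj()]); optionally rooted on the pendant edge of a named
#' outgroup.
#'
#' @param d symmetric distance matrix (labels as dimnames) or `dist`.
#' @param outgroup optional leaf label to root on.
#' @return an [ape::phylo] tree (unrooted unless `outgroup` is given).
#' @export
nj_tree <- function(d, outgroup = NULL) {
  dm <- as.matrix(d)
  if (nrow(dm) < 3L) stop("neighbor-joining requires >= 3 labels")
  tr <- ape::nj(stats::as.dist(dm))
  if (!is.null(outgroup)) {
    if (!outgroup %in% tr$tip.label) {
      stop("outgroup '", outgroup, "' is not a leaf label")
    }
    tr <- ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
  }
  tr
}

#' Bootstrap supports for an NJ tree
#'
#' Resamples usable alignment columns with replacement, rebuilds the NJ
#' tree per replicate, and reports for each internal edge of the original
#' tree the percentage of replicates containing the same bipartition.
#'
#' @param h a `haplotype_set` (or character matrix) whose columns are the
#'   analyzed sites.
#' @param n_reps number of bootstrap replicates.
#' @param seed RNG seed (an integer) for reproducible resampling.
#' @param outgroup optional outgroup passed to [nj_tree()].
#' @return list: `tree` (the original NJ tree with `node.label` set to
#'   rounded support percentages), `supports` (numeric per internal
#'   node), `n_reps`.
#' @export
bootstrap_supports <- function(h, n_reps = 1000L, seed = 1L,
                               outgroup = NULL) {
  stopifnot(n_reps >= 1L)
  mat <- if (inherits(h, "haplotype_set")) h$seqs else h
  base_d <- hamming_distances(mat)
  tree <- nj_tree(base_d, outgroup = outgroup)
  n_var <- sum(apply(mat, 2L, function(col) length(unique(col))) > 1L)
  if (n_var == 0L) {
    warning("no variable sites: bootstrap supports undefined, reported as 0")
    supports <- rep(0, tree$Nnode)
  } else {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed))
    # resampling all L columns, but only variable columns can change a
    # Hamming distance: precompute per-pair difference indicators over
    # the variable columns, then each replicate's distance matrix is one
    # matrix-vector product with the sampled column multiplicities
    nh <- nrow(mat)
    labs <- rownames(mat)
    vcols <- which(apply(mat, 2L, function(col) length(unique(col)) > 1L))
    pairs <- which(upper.tri(matrix(0, nh, nh)), arr.ind = TRUE)
    M <- matrix(0L, nrow(pairs), length(vcols))
    for (p in seq_len(nrow(pairs))) {
      M[p, ] <- as.integer(mat[pairs[p, 1L], vcols] !=
                             mat[pairs[p, 2L], vcols])
    }
    reps <- vector("list", n_reps)
    for (b in seq_len(n_reps)) {
      cols <- sample.int(ncol(mat), replace = TRUE)
      w <- tabulate(match(cols, vcols, nomatch = 0L),
                    nbins = length(vcols))
      dv <- as.numeric(M %*% w)
      db <- matrix(0, nh, nh, dimnames = list(labs, labs))
      db[pairs] <- dv
      db <- db + t(db)
      reps[[b]] <- nj_tree(db, outgroup = outgroup)
    }
    counts <- ape::prop.clades(tree, reps, rooted = !is.null(outgroup))
    counts[is.na(counts)] <- 0L
    supports <- 100 * counts / n_reps
  }
  tree$node.label <- as.character(round(supports))
  list(tree = tree, supports = supports, n_reps = n_reps)
}

#' Write a tree as Newick
#'
#' Support values (if present) are written as internal node labels.
#'
#' @param tree an `ape::phylo`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
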