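# Median-joining haplotype network (Bandelt, Forster & Roehl 1999).
#
# Nodes are haplotype sequences over the variable usable sites plus
# inferred unobserved intermediates ("median vectors"). The construction
# iterates: (1) build the epsilon-relaxed minimum spanning network over
# the current node set -- an edge (u,v) is feasible iff
# d(u,v) <= bottleneck(u,v) + epsilon, where bottleneck(u,v) is the
# minimax edge weight over paths between u and v (epsilon = 0 yields the
# union of all minimum spanning trees); (2) for every connected triple
# propose the column-wise majority consensus as a median vector (ties
# resolved toward the first node in label order); (3) prune median
# vectors whose network degree falls below 3. All characters carry equal
# weight.

# Prim MST over a dense symmetric matrix; returns edge list (i, j, w).
mst_edges <- function(d) {
  n <- nrow(d)
  if (n == 1L) return(matrix(numeric(0), 0L, 3L))
  in_tree <- c(TRUE, rep(FALSE, n - 1L))
  best_w <- d[1L, ]
  best_from <- rep(1L, n)
  edges <- matrix(0, n - 1L, 3L)
  for (e in seq_len(n - 1L)) {
    cand <- which(!in_tree)
    v <- cand[which.min(best_w[cand])]
    edges[e, ] <- c(best_from[v], v, best_w[v])
    in_tree[v] <- TRUE
    upd <- !in_tree & d[v, ] < best_w
    best_from[upd] <- v
    best_w[upd] <- d[v, upd]
  }
  edges
}

# Minimax (bottleneck) path weights between all node pairs, computed on
# the MST (the bottleneck distance of any pair equals its minimax path
# weight in any minimum spanning tree).
bottleneck_matrix <- function(d) {
  n <- nrow(d)
  adj <- vector("list", n)
  em <- mst_edges(d)
  for (e in seq_len(nrow(em))) {
    i <- em[e, 1L]; j <- em[e, 2L]; w <- em[e, 3L]
    adj[[i]] <- rbind(adj[[i]], c(j, w))
    adj[[j]] <- rbind(adj[[j]], c(i, w))
  }
  bn <- matrix(0, n, n)
  for (s in seq_len(n)) {
    # DFS from s tracking the max edge on the path
    stack <- list(c(s, 0))
    seen <- rep(FALSE, n)
    seen[s] <- TRUE
    while (length(stack)) {
      top <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      v <- top[1L]; mx <- top[2L]
      bn[s, v] <- mx
      for (r in seq_len(NROW(adj[[v]]))) {
        if (NROW(adj[[v]]) == 0L) break
        u <- adj[[v]][r, 1L]; w <- adj[[v]][r, 2L]
        if (!seen[u]) {
          seen[u] <- TRUE
          stack[[length(stack) + 1L]] <- c(u, max(mx, w))
        }
      }
    }
  }
  bn
}

# Epsilon-relaxed minimum spanning network: logical adjacency matrix.
msn_adjacency <- function(d, epsilon = 0) {
  bn <- bottleneck_matrix(d)
  adj <- d <= bn + epsilon
  diag(adj) <- FALSE
  adj
}

majority_median <- function(u, v, w) {
  m <- u
  disagree <- !(u == v & v == w)
  for (i in which(disagree)) {
    cnt <- table(c(u[i], v[i], w[i]))
    top <- names(cnt)[cnt == max(cnt)]
    # majority if one exists, else the first node's state (label order)
    m[i] <- if (length(top) == 1L) top else u[i]
  }
  m
}

#' Median-joining haplotype network
#'
#' @param h a [collapse_haplotypes()] result.
#' @param epsilon relaxation parameter (>= 0); 0 gives the union of
#'   minimum spanning trees plus median vectors.
#' @param max_iter safety cap on median-addition rounds.
#' @return object of class `haplo_network`: `nodes` (data.frame `label`,
#'   `frequency`, `is_median`), `edges` (data.frame `from`, `to`,
#'   `n_mutations`, `positions` with semicolon-joined np coordinates),
#'   `epsilon`, and `seqs` (node sequences over the variable sites).
#' @export
median_joining <- function(h, epsilon = 0, max_iter = 20L) {
  stopifnot(inherits(h, "haplotype_set"), epsilon >= 0)
  if (nrow(h$seqs) < 2L) stop("need >= 2 haplotypes")
  # restrict to variable columns (constant columns carry no signal);
  # majority medians never leave the observed per-column alphabet
  variable <- apply(h$seqs, 2L, function(col) length(unique(col)) > 1L)
  mat <- h$seqs[, variable, drop = FALSE]
  np <- h$np[variable]
  n_hap <- nrow(mat)
  labels <- rownames(h$seqs)
  med_id <- 0L
  for (iter in seq_len(max_iter)) {
    d <- hamming_matrix_rows(mat)
    adj <- msn_adjacency(d, epsilon)
    # candidate triples: centre node connected to two neighbours
    new_meds <- character(0)
    new_rows <- list()
    keys <- apply(mat, 1L, paste, collapse = "")
    for (v in seq_len(nrow(mat))) {
      nb <- which(adj[v, ])
      if (length(nb) < 2L) next
      prs <- utils::combn(nb, 2L)
      for (cix in seq_len(ncol(prs))) {
        a <- prs[1L, cix]; b <- prs[2L, cix]
        trio <- sort(c(a, v, b))
        m <- majority_median(mat[trio[1L], ], mat[trio[2L], ],
                             mat[trio[3L], ])
        key <- paste(m, collapse = "")
        if (!key %in% keys && !key %in% new_meds) {
          new_meds <- c(new_meds, key)
          new_rows[[length(new_rows) + 1L]] <- m
        }
      }
    }
    if (!length(new_rows)) break
    add <- do.call(rbind, new_rows)
    rownames(add) <- paste0("mv", med_id + seq_len(nrow(add)))
    med_id <- med_id + nrow(add)
    mat <- rbind(mat, add)
    # prune: drop median vectors with degree < 3 in the recomputed network
    repeat {
      d <- hamming_matrix_rows(mat)
      adj <- msn_adjacency(d, epsilon)
      deg <- rowSums(adj)
      is_med <- seq_len(nrow(mat)) > n_hap
      drop <- which(is_med & deg < 3L)
      if (!length(drop)) break
      mat <- mat[-drop, , drop = FALSE]
    }
    if (nrow(mat) > 6L * n_hap) break  # safety valve
  }
  d <- hamming_matrix_rows(mat)
  adj <- msn_adjacency(d, epsilon)
  node_labels <- rownames(mat)
  is_med <- !node_labels %in% labels
  freq <- ifelse(is_med, 0L, as.integer(h$counts[node_labels]))
  eidx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  edges <- data.frame(
    from = node_labels[eidx[, 1L]], to = node_labels[eidx[, 2L]],
    n_mutations = d[eidx], stringsAsFactors = FALSE)
  edges$positions <- vapply(seq_len(nrow(edges)), function(e) {
    i <- eidx[e, 1L]; j <- eidx[e, 2L]
    paste(np[mat[i, ] != mat[j, ]], collapse = ";")
  }, character(1L))
  structure(
    list(nodes = data.frame(label = node_labels, frequency = freq,
                            is_median = is_med, stringsAsFactors = FALSE),
         edges = edges, epsilon = epsilon, seqs = mat, np = np),
    class = "haplo_network")
}

hamming_matrix_rows <- function(mat) {
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  if (n < 2L) return(d)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      d[i, j] <- d[j, i] <- sum(mat[i, ] != mat[j, ])
    }
  }
  d
}

#' @export
print.haplo_network <- function(x, ...) {
  cat("haplo_network:", sum(!x$nodes$is_median), "haplotypes +",
      sum(x$nodes$is_median), "median vectors;", nrow(x$edges),
      "edges (epsilon =", paste0(x$epsilon, ")"), "\n")
  invisible(x)
}

#' Shortest mutational path length between two node sets
#'
#' Dijkstra over the network with edge weights = mutation counts; used
#' e.g. to measure the separation between the taurine and indicine
#' clusters.
#'
#' @param net a [median_joining()] network.
#' @param from,to character vectors of node labels.
#' @return minimum total mutations over paths from any `from` node to any
#'   `to` node.
#' @export
network_separation <- function(net, from, to) {
  labs <- net$nodes$label
  n <- length(labs)
  w <- matrix(Inf, n, n, dimnames = list(labs, labs))
  for (e in seq_len(nrow(net$edges))) {
    i <- net$edges$from[e]; j <- net$edges$to[e]
    w[i, j] <- w[j, i] <- net$edges$n_mutations[e]
  }
  dist <- rep(Inf, n); names(dist) <- labs
  dist[from] <- 0
  done <- rep(FALSE, n)
  for (it in seq_len(n)) {
    u <- which(!done & dist == min(dist[!done]))[1L]
    if (!is.finite(dist[u])) break
    done[u] <- TRUE
    upd <- dist[u] + w[u, ] < dist
    dist[upd] <- dist[u] + w[u, upd]
  }
  min(dist[to])
}

#' Write network node and edge tables
#'
#' @param net a `haplo_network`.
#' @param nodes_path,edges_path output TSV paths.
#' @return invisibly, the two paths.
#' @export
write_network <- function(net, nodes_path, edges_path) {
  write_tsv(net$nodes, nodes_path)
  write_tsv(net$edges, edges_path)
  invisible(c(nodes_path, edges_path))
}
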