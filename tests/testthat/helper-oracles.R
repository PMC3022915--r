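# Independent oracles used by the tests: exhaustive unrooted-topology
# enumeration with least-squares branch fitting (for checking
# neighbour joining), additive-matrix construction, and a minimal
# linear-gap pairwise aligner.

# All unrooted binary topologies on tips 1..n (n <= 7 is practical).
# Each topology is an edge matrix; tips are positive, internal nodes
# negative.
enumerate_topologies <- function(n) {
  stopifnot(n >= 3L)
  trees <- list(list(edges = rbind(c(-1L, 1L), c(-1L, 2L), c(-1L, 3L)),
                     next_int = -2L))
  if (n == 3L) return(trees)
  for (k in 4:n) {
    out <- vector("list", 0L)
    for (tr in trees) for (e in seq_len(nrow(tr$edges))) {
      ed <- tr$edges
      m <- tr$next_int
      b <- ed[e, 2L]
      ed[e, 2L] <- m
      ed <- rbind(ed, c(m, b), c(m, k))
      out[[length(out) + 1L]] <- list(edges = ed, next_int = m - 1L)
    }
    trees <- out
  }
  trees
}

# Tips on the far side (child side) of edge row r, found by removing
# the edge and flooding from its second endpoint.
edge_far_tips <- function(edges, r, n) {
  keep <- edges[-r, , drop = FALSE]
  target <- edges[r, 2L]
  seen <- target
  repeat {
    hit <- keep[, 1L] %in% seen | keep[, 2L] %in% seen
    nxt <- unique(c(keep[hit, 1L], keep[hit, 2L]))
    nxt <- union(seen, nxt)
    if (length(nxt) == length(seen)) break
    seen <- nxt
  }
  sort(seen[seen > 0L])
}

# Canonical set of non-trivial splits of a topology, as "a,b|" keys.
topo_splits <- function(edges, n, labels = as.character(seq_len(n))) {
  keys <- character(0)
  for (r in seq_len(nrow(edges))) {
    side <- edge_far_tips(edges, r, n)
    if (length(side) < 2L || length(side) > n - 2L) next
    anchor <- sort(labels)[1L]
    s <- labels[side]
    if (anchor %in% s) s <- setdiff(labels, s)
    keys <- c(keys, paste(sort(s), collapse = "|"))
  }
  sort(unique(keys))
}

# Least-squares fit of branch lengths for a fixed topology; returns RSS.
ls_rss <- function(edges, n, dm) {
  far_sets <- lapply(seq_len(nrow(edges)), function(r)
    edge_far_tips(edges, r, n))
  pairs <- t(utils::combn(n, 2L))
  X <- matrix(0, nrow(pairs), nrow(edges))
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1L]; j <- pairs[p, 2L]
    for (r in seq_len(nrow(edges)))
      if ((i %in% far_sets[[r]]) != (j %in% far_sets[[r]])) X[p, r] <- 1
  }
  d <- dm[pairs]
  fit <- stats::lm.fit(X, d)
  sum(fit$residuals^2)
}

# Brute-force least-squares topology: the split set of the topology
# minimising RSS over all unrooted binary topologies.
ls_best_splits <- function(dm) {
  n <- nrow(dm)
  topos <- enumerate_topologies(n)
  rss <- vapply(topos, function(tr) ls_rss(tr$edges, n, dm), numeric(1L))
  best <- topos[[which.min(rss)]]
  topo_splits(best$edges, n, labels = rownames(dm))
}

# Additive distance matrix from a topology with given branch lengths.
additive_matrix <- function(edges, n, lengths,
                            labels = paste0("t", seq_len(n))) {
  dm <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    d <- 0
    for (r in seq_len(nrow(edges))) {
      far <- edge_far_tips(edges, r, n)
      if ((i %in% far) != (j %in% far)) d <- d + lengths[r]
    }
    dm[i, j] <- d; dm[j, i] <- d
  }
  dm
}

# Splits of an ape phylo by label (wrapper over the package helper).
phylo_splits <- function(phy) sort(unname(tree_splits(phy)))

# Minimal linear-gap global aligner (scores: match 1, mismatch 0,
# gap -1), used only as an independent check on tiny examples.
naive_align_score <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  S <- matrix(0, n + 1L, m + 1L)
  S[, 1L] <- gap * (0:n); S[1L, ] <- gap * (0:m)
  for (i in seq_len(n)) for (j in seq_len(m))
    S[i + 1L, j + 1L] <- max(S[i, j] + if (A[i] == B[j]) match else mismatch,
                             S[i, j + 1L] + gap, S[i + 1L, j] + gap)
  S[n + 1L, m + 1L]
}
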