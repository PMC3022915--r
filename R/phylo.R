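# Distance-based phylogeny: p-distances, neighbour-joining with
# deterministic tie-breaking, bootstrap bipartition supports, and
# outgroup rooting. Trees are `ape` "phylo" objects throughout.

#' Pairwise distance matrix from an alignment
#'
#' p-distance = mismatches / compared sites, with gapped sites deleted
#' pairwise; the Poisson correction -ln(1 - p) is available for amino
#' acid data.
#'
#' @param msa alignment (matrix or named gapped strings)
#' @param model `"p"` or `"poisson"`
#' @return symmetric numeric matrix with zero diagonal
#' @export
distance_matrix <- function(msa, model = c("p", "poisson")) {
  model <- match.arg(model)
  m <- if (is.matrix(msa)) unclass(msa)
       else do.call(rbind, strsplit(unname(msa), ""))
  if (is.null(rownames(m)) && !is.matrix(msa)) rownames(m) <- names(msa)
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    ok <- m[i, ] != "-" & m[j, ] != "-"
    if (!any(ok))
      stop("no comparable (ungapped) sites between ", rownames(m)[i],
           " and ", rownames(m)[j])
    p <- mean(m[i, ok] != m[j, ok])
    d <- if (model == "p") p else {
      if (p >= 1) stop("Poisson correction undefined at p >= 1 (",
                       rownames(m)[i], " vs ", rownames(m)[j], ")")
      -log(1 - p)
    }
    D[i, j] <- d; D[j, i] <- d
  }
  D
}

#' Neighbour-joining tree
#'
#' Saitou-Nei agglomeration on a distance matrix: at each step the pair
#' minimising the Q criterion is joined; exact ties are broken
#' deterministically by the lexicographically smallest pair of cluster
#' labels (a cluster is labelled by its smallest member leaf). Negative
#' branch-length estimates are clamped to zero with the deficit moved to
#' the sister branch, so all edge lengths are non-negative.
#'
#' @param dm symmetric distance matrix with dimnames (>= 3 taxa)
#' @return unrooted `phylo` object
#' @export
neighbor_joining <- function(dm) {
  dm <- as.matrix(dm)
  labels <- rownames(dm)
  n <- nrow(dm)
  if (n < 3L) stop("neighbour joining needs at least 3 taxa")
  if (is.null(labels)) stop("distance matrix must carry labels")
  fmt <- function(x) sprintf("%.10g", max(x, 0))

  newick <- labels          # subtree string per active cluster
  rep_lab <- labels         # smallest member label, for tie-breaking
  D <- dm
  while (length(newick) > 3L) {
    k <- nrow(D)
    r <- rowSums(D)
    Q <- (k - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pair_key <- apply(cand, 1L, function(ij) {
      p <- sort(c(rep_lab[ij[1]], rep_lab[ij[2]]))
      paste(p, collapse = "\r")
    })
    sel <- cand[order(pair_key)[1L], ]
    i <- sel[1L]; j <- sel[2L]
    vi <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (k - 2))
    vj <- D[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    node <- paste0("(", newick[i], ":", fmt(vi), ",",
                   newick[j], ":", fmt(vj), ")")
    dnew <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(k), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    newick <- c(newick[keep], node)
    rep_lab <- c(rep_lab[keep], min(rep_lab[c(i, j)]))
    D <- D2
  }
  if (length(newick) == 3L) {
    va <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
    vb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
    vc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
    txt <- paste0("(", newick[1], ":", fmt(va), ",",
                  newick[2], ":", fmt(vb), ",",
                  newick[3], ":", fmt(vc), ");")
  }
  ape::read.tree(text = txt)
}

# Canonical key of the bipartition under the edge above `tips` (a set of
# tip labels): the side not containing the alphabetically first label,
# sorted and joined. NA for trivial splits.
#' @keywords internal
split_key <- function(tips, all_labels) {
  if (length(tips) < 2L || length(tips) > length(all_labels) - 2L)
    return(NA_character_)
  anchor <- sort(all_labels)[1L]
  side <- if (anchor %in% tips) setdiff(all_labels, tips) else tips
  paste(sort(side), collapse = "|")
}

#' Non-trivial bipartitions of a tree
#'
#' @param phy a `phylo` object
#' @return character vector of canonical split keys, named by the
#'   internal node number whose subtending edge induces the split
#' @export
tree_splits <- function(phy) {
  pp <- ape::prop.part(phy)
  labs <- attr(pp, "labels")
  ntip <- length(phy$tip.label)
  keys <- vapply(seq_along(pp),
                 function(i) split_key(labs[pp[[i]]], labs), character(1L))
  names(keys) <- as.character(ntip + seq_along(pp))
  keys[!is.na(keys)]
}

#' Bootstrap supports for a neighbour-joining tree
#'
#' Alignment columns are resampled with replacement `n_reps` times; each
#' replicate yields an NJ tree, and the support of each internal edge of
#' the reference tree (NJ on the full alignment) is the percentage of
#' replicates whose tree contains the same bipartition. Replicate r
#' draws from a deterministic substream derived from (seed, r), so
#' results are reproducible and independent of evaluation order.
#'
#' @param msa alignment (matrix or named gapped strings)
#' @param n_reps number of bootstrap replicates
#' @param seed integer RNG seed
#' @param model distance model, see [distance_matrix()]
#' @return `phylo` with `node.label` holding supports in [0, 100]
#'   (empty at the basal node)
#' @export
bootstrap_support <- function(msa, n_reps = 1000L, seed = 1L,
                              model = c("p", "poisson")) {
  model <- match.arg(model)
  stopifnot(n_reps >= 1L)
  m <- if (is.matrix(msa)) unclass(msa)
       else do.call(rbind, strsplit(unname(msa), ""))
  if (!is.matrix(msa)) rownames(m) <- names(msa)
  ref <- neighbor_joining(distance_matrix(m, model = model))
  ref_splits <- tree_splits(ref)
  counts <- stats::setNames(numeric(length(ref_splits)), ref_splits)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(rep_seeds[r])
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    rep_splits <- tryCatch(
      tree_splits(neighbor_joining(distance_matrix(m[, cols, drop = FALSE],
                                                   model = model))),
      error = function(e) character(0))
    hit <- ref_splits %in% rep_splits
    counts[hit] <- counts[hit] + 1
  }
  support <- 100 * counts / n_reps
  nnode <- ref$Nnode
  ntip <- length(ref$tip.label)
  node_lab <- character(nnode)
  idx <- as.integer(names(ref_splits)) - ntip
  node_lab[idx] <- sprintf("%g", support[ref_splits])
  ref$node.label <- node_lab
  attr(ref, "bootstrap") <- stats::setNames(as.numeric(support),
                                            names(support))
  ref
}

#' Root a tree on an outgroup
#'
#' The root is placed on the outgroup's pendant edge; internal-edge
#' supports travel with their edges.
#'
#' @param tree a `phylo` (optionally with node labels from
#'   [bootstrap_support()])
#' @param label outgroup tip label
#' @return rooted `phylo`
#' @export
root_with_outgroup <- function(tree, label) {
  if (!label %in% tree$tip.label)
    stop("unknown outgroup label: ", label)
  ape::root(tree, outgroup = label, resolve.root = TRUE, edgelabel = TRUE)
}

#' Write / read Newick
#' @param tree a `phylo`
#' @param path file path
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)
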