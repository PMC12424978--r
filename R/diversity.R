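# Beta-diversity metrics, tree construction, and ordination.

.check_pair <- function(x, y) {
  stopifnot(length(x) == length(y), all(x >= 0), all(y >= 0))
  if (sum(x) == 0 && sum(y) == 0)
    stop("both count vectors are all-zero")
}

#' Bray-Curtis dissimilarity
#'
#' `sum(|x - y|) / sum(x + y)`; abundance-aware, non-phylogenetic.
#'
#' @param x,y non-negative count vectors of equal length (not both all-zero).
#' @return dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(x, y) {
  .check_pair(x, y)
  sum(abs(x - y)) / sum(x + y)
}

#' Jaccard distance
#'
#' One minus the ratio of shared to combined feature supports;
#' presence/absence only.
#'
#' @inheritParams bray_curtis
#' @return distance in `[0, 1]`.
#' @export
jaccard <- function(x, y) {
  .check_pair(x, y)
  a <- x > 0; b <- y > 0
  1 - sum(a & b) / sum(a | b)
}

# per-edge descendant-tip count sums for each column of `counts`
# (tips x samples); returns edges x samples matrix aligned to tree$edge rows
.edge_sums <- function(tree, counts) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  S <- ncol(counts)
  node_tot <- matrix(0, ntip + nnode, S)
  node_tot[seq_len(ntip), ] <- counts[tree$tip.label, , drop = FALSE]
  tr <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(tr$edge))) {
    p <- tr$edge[k, 1]; ch <- tr$edge[k, 2]
    node_tot[p, ] <- node_tot[p, ] + node_tot[ch, ]
  }
  es <- node_tot[tree$edge[, 2], , drop = FALSE]
  es
}

#' UniFrac distance between two samples
#'
#' Unweighted: fraction of the tree's branch length (restricted to branches
#' with descendants in either sample) leading to tips present in exactly one
#' sample. Weighted (classic, non-normalized): branch lengths weighted by the
#' absolute difference in the relative abundance descending through each
#' branch; `normalized = TRUE` divides by the abundance-weighted total branch
#' length, scaling into `[0, 1]`.
#'
#' @param tree rooted `phylo` with branch lengths; tips must cover the
#'   features present in `x` or `y`.
#' @param x,y named non-negative count vectors (names = tip labels).
#' @param weighted logical.
#' @param normalized for the weighted variant only.
#' @return UniFrac distance.
#' @export
unifrac <- function(tree, x, y, weighted = FALSE, normalized = FALSE) {
  feats <- union(names(x)[x > 0], names(y)[y > 0])
  miss <- setdiff(feats, tree$tip.label)
  if (length(miss))
    stop("feature(s) missing from tree: ", paste(miss, collapse = ", "))
  cnt <- matrix(0, length(tree$tip.label), 2,
                dimnames = list(tree$tip.label, c("x", "y")))
  cnt[names(x), 1] <- x
  cnt[names(y), 2] <- y
  es <- .edge_sums(tree, cnt)
  el <- tree$edge.length
  if (!weighted) {
    ax <- es[, 1] > 0; ay <- es[, 2] > 0
    den <- sum(el[ax | ay])
    if (den == 0) return(0)
    sum(el[xor(ax, ay)]) / den
  } else {
    px <- es[, 1] / sum(cnt[, 1])
    py <- es[, 2] / sum(cnt[, 2])
    d <- sum(el * abs(px - py))
    if (normalized) {
      den <- sum(el * (px + py))
      if (den == 0) return(0)
      d / den
    } else d
  }
}

#' Pairwise beta diversity over all samples of a feature table
#'
#' @param table a [feature_table()] or counts matrix (features x samples).
#' @param metric one of `"bray_curtis"`, `"jaccard"`,
#'   `"unweighted_unifrac"`, `"weighted_unifrac"`.
#' @param tree rooted `phylo` over the feature ids (required for the UniFrac
#'   metrics).
#' @param normalized passed to [unifrac()] for the weighted variant.
#' @return a `dist` object labeled with the sample ids.
#' @export
beta_diversity <- function(table,
                           metric = c("bray_curtis", "jaccard",
                                      "unweighted_unifrac",
                                      "weighted_unifrac"),
                           tree = NULL, normalized = FALSE) {
  metric <- match.arg(metric)
  m <- if (inherits(table, "feature_table")) table$counts else table
  S <- ncol(m)
  samples <- colnames(m)
  if (metric %in% c("unweighted_unifrac", "weighted_unifrac")) {
    if (is.null(tree)) stop("UniFrac metrics require a tree")
    miss <- setdiff(rownames(m)[rowSums(m) > 0], tree$tip.label)
    if (length(miss))
      stop("feature(s) missing from tree: ", paste(miss, collapse = ", "))
    cnt <- matrix(0, length(tree$tip.label), S,
                  dimnames = list(tree$tip.label, samples))
    common <- intersect(rownames(m), tree$tip.label)
    cnt[common, ] <- m[common, , drop = FALSE]
    es <- .edge_sums(tree, cnt)
    el <- tree$edge.length
    D <- matrix(0, S, S, dimnames = list(samples, samples))
    if (metric == "unweighted_unifrac") {
      pres <- es > 0
      for (i in seq_len(S - 1)) for (j in (i + 1):S) {
        den <- sum(el[pres[, i] | pres[, j]])
        D[i, j] <- D[j, i] <-
          if (den == 0) 0 else sum(el[xor(pres[, i], pres[, j])]) / den
      }
    } else {
      P <- sweep(es, 2L, colSums(cnt), "/")
      for (i in seq_len(S - 1)) for (j in (i + 1):S) {
        d <- sum(el * abs(P[, i] - P[, j]))
        if (normalized) {
          den <- sum(el * (P[, i] + P[, j]))
          d <- if (den == 0) 0 else d / den
        }
        D[i, j] <- D[j, i] <- d
      }
    }
  } else {
    fun <- if (metric == "bray_curtis") bray_curtis else jaccard
    D <- matrix(0, S, S, dimnames = list(samples, samples))
    for (i in seq_len(S - 1)) for (j in (i + 1):S)
      D[i, j] <- D[j, i] <- fun(m[, i], m[, j])
  }
  stats::as.dist(D)
}

#' Neighbor-joining tree over feature sequences
#'
#' Computes pairwise p-distances (per-site for equal-length sequences, from a
#' global alignment otherwise), runs neighbor joining, clamps negative branch
#' lengths to zero, and midpoint-roots the result. Input sequences are sorted
#' by feature id first, making the output invariant to input order.
#'
#' @param sequences named character vector (>= 2 distinct feature ids).
#' @return a rooted `phylo` object whose tips are the feature ids.
#' @export
build_tree <- function(sequences) {
  stopifnot(!is.null(names(sequences)), length(sequences) >= 2L)
  if (anyDuplicated(names(sequences))) stop("duplicate feature ids")
  sequences <- sequences[order(names(sequences))]
  n <- length(sequences)
  D <- matrix(0, n, n, dimnames = list(names(sequences), names(sequences)))
  lens <- nchar(sequences)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- sequences[[i]]; b <- sequences[[j]]
    if (lens[i] == lens[j]) {
      p <- .hamming(a, b) / lens[i]
    } else {
      aln <- Biostrings::pairwiseAlignment(a, b, type = "global")
      L <- nchar(as.character(Biostrings::alignedPattern(aln)))
      p <- (L - Biostrings::nmatch(aln)) / L
    }
    D[i, j] <- D[j, i] <- p
  }
  tr <- if (n == 2L) {
    ape::read.tree(text = sprintf("(%s:%f,%s:%f);", names(sequences)[1],
                                  D[1, 2] / 2, names(sequences)[2],
                                  D[1, 2] / 2))
  } else {
    t0 <- ape::nj(stats::as.dist(D))
    t0$edge.length[t0$edge.length < 0] <- 0
    phangorn::midpoint(t0)
  }
  ape::ladderize(tr)
}

#' Principal coordinates analysis
#'
#' Gower double-centering of `-0.5 * D^2` followed by eigendecomposition;
#' coordinates are returned for positive eigenvalues only (sorted
#' descending), negative eigenvalues are reported but their axes dropped.
#'
#' @param d a `dist` or symmetric distance matrix with zero diagonal.
#' @return list: `points` (samples x axes), `eigenvalues` (all, descending),
#'   `negative` (count of negative eigenvalues).
#' @export
pcoa <- function(d) {
  D <- as.matrix(d)
  if (!isSymmetric(unname(D), tol = 1e-8))
    stop("distance matrix must be symmetric")
  if (any(diag(D) != 0)) stop("distance matrix must have a zero diagonal")
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  ee <- eigen((B + t(B)) / 2, symmetric = TRUE)
  tol <- max(abs(ee$values), .Machine$double.eps) * 1e-9
  pos <- which(ee$values > tol)
  pts <- ee$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(ee$values[pos]), length(pos))
  rownames(pts) <- rownames(D)
  if (length(pos)) colnames(pts) <- paste0("Axis", seq_along(pos))
  list(points = pts, eigenvalues = ee$values,
       negative = sum(ee$values < -tol))
}
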