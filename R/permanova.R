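# Single-factor adonis-style PERMANOVA on a distance matrix.

# F statistic pieces for a label vector over a squared-distance matrix
.perm_ss <- function(d2, labels) {
  N <- nrow(d2)
  ss_total <- sum(d2[upper.tri(d2)]) / N
  ss_within <- 0
  for (g in unique(labels)) {
    idx <- which(labels == g)
    if (length(idx) > 1L)
      ss_within <- ss_within +
        sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
  }
  c(total = ss_total, within = ss_within, between = ss_total - ss_within)
}

.perm_F <- function(ss, a, N) {
  num <- ss[["between"]] / (a - 1)
  den <- ss[["within"]] / (N - a)
  if (den == 0) {
    if (num == 0) NaN else Inf
  } else num / den
}

# enumerate all distinct assignments of labels to N positions (multiset
# permutations); returns a matrix with one assignment per column
.enumerate_assignments <- function(labels) {
  rec <- function(remaining) {
    if (length(remaining) == 1L) return(list(remaining))
    out <- list()
    for (u in unique(remaining)) {
      i <- match(u, remaining)
      for (tail in rec(remaining[-i]))
        out[[length(out) + 1L]] <- c(u, tail)
    }
    out
  }
  do.call(cbind, rec(sort(as.character(labels))))
}

#' PERMANOVA (adonis-style) for one grouping factor
#'
#' Partitions the sum of squared distances between and within groups,
#' reporting a pseudo-F, the fraction of variance explained (R squared), and
#' a permutation p-value. When the number of distinct label assignments is at
#' most `exhaustive_limit` the permutation distribution is enumerated exactly
#' (p = proportion of assignments, the observed one included, with F at least
#' the observed F); otherwise `n_permutations` random relabelings are drawn
#' and p = (1 + #\{F* >= F\}) / (1 + n_permutations).
#'
#' @param d `dist` or symmetric distance matrix.
#' @param groups factor/character of group labels (>= 2 groups).
#' @param n_permutations number of random permutations.
#' @param seed RNG seed for the permutations.
#' @param exhaustive force (`TRUE`) or forbid (`FALSE`) exact enumeration;
#'   `NULL` decides by `exhaustive_limit`.
#' @param exhaustive_limit maximum number of distinct assignments enumerated.
#' @return object of class `permanova_result`: `pseudo_F`, `r_squared`,
#'   `p_value`, `n_permutations` (or number of enumerated assignments),
#'   `method`, `seed`, plus the sums of squares.
#' @export
permanova <- function(d, groups, n_permutations = 999L, seed = 1L,
                      exhaustive = NULL, exhaustive_limit = 10000L) {
  D <- as.matrix(d)
  N <- nrow(D)
  groups <- as.character(groups)
  stopifnot(length(groups) == N, n_permutations >= 1L)
  a <- length(unique(groups))
  if (a < 2L) stop("need at least two groups")
  d2 <- D^2
  ss <- .perm_ss(d2, groups)
  if (ss[["total"]] == 0) {
    # all samples identical: no structure by convention
    return(structure(list(pseudo_F = NaN, r_squared = 0, p_value = 1,
                          n_permutations = 0L, method = "degenerate",
                          seed = seed, ss = ss),
                     class = "permanova_result"))
  }
  f_obs <- .perm_F(ss, a, N)
  sizes <- table(groups)
  n_assign <- exp(lgamma(N + 1) - sum(lgamma(sizes + 1)))
  use_exh <- if (is.null(exhaustive)) n_assign <= exhaustive_limit
             else exhaustive
  if (use_exh) {
    A <- .enumerate_assignments(groups)
    fs <- apply(A, 2L, function(lb) .perm_F(.perm_ss(d2, lb), a, N))
    p <- mean(fs >= f_obs - 1e-12)
    nperm <- ncol(A)
    method <- "exhaustive"
  } else {
    counts <- with_seed(seed, {
      ge <- 0L
      # batched: per group, SS contribution via indicator matrix products
      labs <- unique(groups)
      L <- replicate(n_permutations, sample(groups))
      ssw <- numeric(n_permutations)
      for (g in labs) {
        Z <- matrix(as.numeric(L == g), nrow = N)
        ng <- sum(groups == g)
        ssw <- ssw + colSums(Z * (d2 %*% Z)) / (2 * ng)
      }
      fs <- ((ss[["total"]] - ssw) / (a - 1)) / (ssw / (N - a))
      fs[ssw == 0] <- Inf
      sum(fs >= f_obs - 1e-12)
    })
    p <- (1 + counts) / (1 + n_permutations)
    nperm <- n_permutations
    method <- "sampled"
  }
  structure(list(pseudo_F = f_obs,
                 r_squared = unname(ss[["between"]] / ss[["total"]]),
                 p_value = p, n_permutations = nperm, method = method,
                 seed = seed, ss = ss),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA (%s): pseudo-F = %.4g, R2 = %.4g, p = %.4g (%d permutations)\n",
              x$method, x$pseudo_F, x$r_squared, x$p_value,
              x$n_permutations))
  invisible(x)
}

#' PERMANOVA across several beta-diversity metrics
#'
#' Convenience wrapper running [beta_diversity()] + [permanova()] for each
#' metric, mirroring the metric-by-comparison layout of amplicon-design
#' benchmark tables.
#'
#' @param table a [feature_table()].
#' @param groups group labels, one per sample.
#' @param metrics metric names (see [beta_diversity()]).
#' @param tree rooted `phylo` for the UniFrac metrics.
#' @param ... passed to [permanova()].
#' @return data.frame: `metric`, `pseudo_F`, `r_squared`, `p_value`.
#' @export
permanova_table <- function(table, groups,
                            metrics = c("weighted_unifrac",
                                        "unweighted_unifrac",
                                        "bray_curtis", "jaccard"),
                            tree = NULL, ...) {
  rows <- lapply(metrics, function(mt) {
    d <- beta_diversity(table, mt, tree = tree)
    r <- permanova(d, groups, ...)
    data.frame(metric = mt, pseudo_F = r$pseudo_F,
               r_squared = r$r_squared, p_value = r$p_value)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
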