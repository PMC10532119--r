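# Strain-by-strain interaction matrices, their complete-linkage clustering,
# and bootstrap/subset Jaccard cluster stability.

#' Build the symmetric strain-by-strain interaction matrix
#'
#' Fills a square matrix of interaction indices for one growth parameter
#' from the per-pair records. The matrix is symmetric with a zero diagonal
#' (a strain "with itself" is the monoculture reference, index 0 by
#' construction). Every unordered pair must be present exactly once.
#'
#' @param records Tibble from [analyze_interactions()].
#' @param parameter One of `"auc"`, `"r"`, `"max_od"`, `"latency"`.
#' @return Numeric matrix with strain row/column names; attribute
#'   `significant` is the logical mask of records with outcome != "A", and
#'   `species` the species label per strain (when present in the records).
#' @export
build_interaction_matrix <- function(records, parameter) {
  parameter <- match.arg(parameter, c("auc", "r", "max_od", "latency"))
  rec <- records[records$parameter == parameter, ]
  strains <- sort(unique(c(rec$strain_1, rec$strain_2)))
  n <- length(strains)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  k <- key(rec$strain_1, rec$strain_2)
  if (anyDuplicated(k)) {
    dupes <- unique(k[duplicated(k)])
    conflicting <- vapply(dupes, function(d) {
      length(unique(rec$index[k == d])) > 1
    }, logical(1))
    if (any(conflicting)) {
      stop("conflicting duplicate entries for pair(s): ",
           paste(dupes[conflicting], collapse = ", "))
    }
    rec <- rec[!duplicated(k), ]
    k <- key(rec$strain_1, rec$strain_2)
  }
  expected <- combn(strains, 2)
  expected_keys <- key(expected[1, ], expected[2, ])
  missing <- setdiff(expected_keys, k)
  if (length(missing)) {
    stop("missing pair(s) for parameter ", parameter, ": ",
         paste(missing, collapse = ", "))
  }
  m <- matrix(0, n, n, dimnames = list(strains, strains))
  sig <- matrix(FALSE, n, n, dimnames = list(strains, strains))
  for (i in seq_len(nrow(rec))) {
    a <- rec$strain_1[i]
    b <- rec$strain_2[i]
    m[a, b] <- m[b, a] <- rec$index[i]
    sig[a, b] <- sig[b, a] <- rec$outcome[i] != "A"
  }
  attr(m, "significant") <- sig
  attr(m, "parameter") <- parameter
  if (all(c("species_1", "species_2") %in% names(rec))) {
    sp <- setNames(c(rec$species_1, rec$species_2),
                   c(rec$strain_1, rec$strain_2))
    attr(m, "species") <- sp[strains]
  }
  m
}

#' Cluster the interaction matrix
#'
#' Rows of the (symmetric) matrix are the strains' interaction profiles.
#' Agglomerative clustering with Euclidean distance and complete linkage,
#' cut at `k` clusters. Cluster labels are re-numbered deterministically in
#' order of first appearance along the lexicographic strain order, so the
#' partition does not depend on input row order.
#'
#' @param m Matrix from [build_interaction_matrix()] (or any numeric matrix
#'   with row names).
#' @param k Number of clusters, `2 <= k <= nrow(m)`.
#' @param exclude_self Drop the diagonal entry from each row's feature
#'   vector (default `FALSE`: the diagonal zero is kept).
#' @return List of class `"matrix_clustering"`: `assignments` (named
#'   integer), `tree` (an [stats::hclust] object), `k`.
#' @export
cluster_matrix <- function(m, k, exclude_self = FALSE) {
  n <- nrow(m)
  if (!is.numeric(k) || length(k) != 1 || k < 2 || k > n) {
    stop("`k` must be between 2 and the number of strains (", n, ")")
  }
  ord <- order(rownames(m))
  feat <- m[ord, ord, drop = FALSE]
  if (exclude_self) {
    diag(feat) <- NA
    d <- dist(t(apply(feat, 1, function(x) x[!is.na(x)])))
  } else {
    d <- dist(feat)
  }
  tree <- hclust(d, method = "complete")
  ct <- cutree(tree, k = k)
  # renumber by first appearance in lexicographic strain order
  relabel <- setNames(seq_len(k), unique(ct))
  assignments <- setNames(as.integer(relabel[as.character(ct)]), names(ct))
  structure(list(assignments = assignments, tree = tree, k = as.integer(k)),
            class = "matrix_clustering")
}

#' Bootstrap / subset Jaccard cluster stability
#'
#' Scores the stability of each cluster of the original partition by
#' resampling strains, re-clustering the resample at the same `k`, and
#' recording the best Jaccard similarity between the original cluster and
#' any cluster of the resampled solution (both restricted to the resampled
#' strains). `"bootstrap"` resamples `n` rows with replacement; `"subset"`
#' draws `floor(subset_frac * n)` rows without replacement. Each original
#' cluster's stability is the mean over the iterations in which it is
#' assessable (at least one of its members resampled, and enough distinct
#' rows to cut `k` clusters). Mean Jaccard below 0.5 is conventionally read
#' as a dissolved (unstable) cluster.
#'
#' @param m Matrix from [build_interaction_matrix()].
#' @param k Number of clusters.
#' @param B Number of resampling iterations (>= 1).
#' @param method `"subset"` or `"bootstrap"`.
#' @param seed Integer seed; the output is deterministic given the seed.
#' @param subset_frac Fraction of strains drawn by the subset method.
#' @param exclude_self Passed to [cluster_matrix()].
#' @return List of class `"cluster_stability"`: `k`, `assignments`,
#'   `jaccard` (per-cluster mean), `dissolved` (`jaccard < 0.5`), `method`,
#'   `B`, `n_assessed`.
#' @export
bootstrap_stability <- function(m, k, B = 1000,
                                method = c("subset", "bootstrap"),
                                seed = 1L, subset_frac = 0.5,
                                exclude_self = FALSE) {
  method <- match.arg(method)
  if (!is.numeric(B) || B < 1) {
    stop("`B` must be >= 1")
  }
  base <- cluster_matrix(m, k, exclude_self)
  n <- nrow(m)
  strains <- rownames(m)
  orig <- lapply(seq_len(k), function(g) strains[base$assignments == g])

  jsum <- numeric(k)
  jn <- integer(k)
  set.seed(seed)
  for (b in seq_len(B)) {
    idx <- if (method == "bootstrap") {
      sample.int(n, n, replace = TRUE)
    } else {
      sample.int(n, max(2L, floor(subset_frac * n)))
    }
    uid <- sort(unique(idx))
    if (length(uid) <= k) {
      next
    }
    sub <- m[uid, , drop = FALSE]
    ct <- cutree(hclust(dist(sub), method = "complete"), k = k)
    resampled <- strains[uid]
    new_clusters <- split(resampled, ct)
    for (g in seq_len(k)) {
      a <- intersect(orig[[g]], resampled)
      if (!length(a)) {
        next
      }
      jmax <- max(vapply(new_clusters, function(d) {
        length(intersect(a, d)) / length(union(a, d))
      }, numeric(1)))
      jsum[g] <- jsum[g] + jmax
      jn[g] <- jn[g] + 1L
    }
  }
  jaccard <- ifelse(jn > 0, jsum / jn, NA_real_)
  structure(
    list(k = as.integer(k), assignments = base$assignments,
         jaccard = jaccard, dissolved = jaccard < 0.5,
         method = method, B = as.integer(B), n_assessed = jn,
         subset_frac = if (method == "subset") subset_frac else NA_real_),
    class = "cluster_stability"
  )
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items; 1 for
#' identical partitions (up to label renaming), ~0 for independent ones.
#'
#' @param a,b Cluster label vectors of equal length.
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- sum(tab)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) {
    return(1)
  }
  (sum_ij - expected) / (maximum - expected)
}

#' Export a merge tree in Newick form
#'
#' @param clustering A `"matrix_clustering"` object.
#' @return Single Newick string (nested-parenthesis tree text).
#' @export
tree_newick <- function(clustering) {
  stopifnot(inherits(clustering, "matrix_clustering"))
  phy <- ape::as.phylo(clustering$tree)
  ape::write.tree(phy)
}
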