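# Embedding-evaluation suite: displacement distributions, conserved-KNN
# proportion, K-means + adjusted Rand index, Calinski-Harabasz index.

#' Per-protein embedding displacement
#'
#' Euclidean distance, in the original embedding space (no reduction),
#' between each protein's embedding before and after a transformation (e.g.
#' contrastive pretraining).
#'
#' @param before,after `n x D` matrices with matched rows.
#' @return Numeric vector of `n` distances.
#' @export
displacement_distribution <- function(before, after) {
  before <- as.matrix(before); after <- as.matrix(after)
  if (!all(dim(before) == dim(after)))
    stop("displacement_distribution: shape mismatch")
  sqrt(rowSums((after - before)^2))
}

#' Proportion of conserved K-nearest neighbours
#'
#' For each point, the overlap between its `K` nearest neighbours (Euclidean,
#' self excluded, ties broken by index order) before and after a
#' transformation, averaged over points.
#'
#' @param before,after `n x D` embedding matrices with matched rows.
#' @param K Neighbour count, `1 <= K <= n - 1`.
#' @return A `knn_conservation`: list with `K` and `proportion`.
#' @export
knn_conservation <- function(before, after, K) {
  before <- as.matrix(before); after <- as.matrix(after)
  n <- nrow(before)
  stopifnot(nrow(after) == n)
  if (K < 1L || K >= n) stop("knn_conservation: need 1 <= K <= n - 1")
  nn_sets <- function(M) {
    D <- as.matrix(stats::dist(M))
    lapply(seq_len(n), function(i) {
      ord <- order(D[i, -i])            # stable: ties fall back to index order
      idx <- seq_len(n)[-i]
      idx[ord][seq_len(K)]
    })
  }
  nb <- nn_sets(before); na_ <- nn_sets(after)
  prop <- mean(vapply(seq_len(n),
                      function(i) length(intersect(nb[[i]], na_[[i]])) / K,
                      numeric(1)))
  structure(list(K = as.integer(K), proportion = prop),
            class = "knn_conservation")
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions, from the closed-form
#' permutation-model formula over the contingency table.
#'
#' @param a,b Cluster assignment vectors of equal length.
#' @return Scalar; 1 iff the partitions are identical up to relabeling.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)       # both partitions trivial
  (sum_ij - expected) / (maxi - expected)
}

#' Calinski-Harabasz index
#'
#' `[trace(B)/(k - 1)] / [trace(W)/(n - k)]` with `B`, `W` the between- and
#' within-cluster scatter matrices about the label centroids.
#'
#' @param embeddings `n x D` matrix.
#' @param labels Ground-truth cluster labels (>= 2 distinct).
#' @return Positive scalar.
#' @export
calinski_harabasz <- function(embeddings, labels) {
  X <- as.matrix(embeddings)
  labels <- as.factor(labels)
  k <- nlevels(labels); n <- nrow(X)
  if (k < 2L) stop("calinski_harabasz: need at least 2 labels")
  gm <- colMeans(X)
  trB <- 0; trW <- 0
  for (lv in levels(labels)) {
    Xi <- X[labels == lv, , drop = FALSE]
    ci <- colMeans(Xi)
    trB <- trB + nrow(Xi) * sum((ci - gm)^2)
    trW <- trW + sum(sweep(Xi, 2, ci)^2)
  }
  if (trW == 0) stop("calinski_harabasz: zero within-cluster dispersion")
  (trB / (k - 1)) / (trW / (n - k))
}

#' K-means clustering evaluation against ground-truth labels
#'
#' Runs seeded K-means (10 restarts) with `k` equal to the number of
#' distinct labels, optionally after a seeded 2-D reduction (principal
#' components; the reference protocol used t-SNE for visualization, but the
#' reduction here must be deterministic and dependency-free, and ARI on the
#' raw embeddings is reported alongside). Returns ARI of the K-means
#' assignment against the labels plus the Calinski-Harabasz index of the
#' labels on the same representation.
#'
#' @param embeddings `n x D` matrix.
#' @param labels Ground-truth labels (length `n`).
#' @param n_clusters Number of clusters; defaults to the number of distinct
#'   labels.
#' @param reduce_2d Reduce to 2 principal components before clustering.
#' @param seed Seed for K-means restarts.
#' @param nstart K-means restarts.
#' @return A `cluster_eval_report`: list with `ari`, `chi`, `n_clusters`,
#'   `reduction`.
#' @export
cluster_ari <- function(embeddings, labels, n_clusters = NULL,
                        reduce_2d = FALSE, seed = 1L, nstart = 10L) {
  X <- as.matrix(embeddings)
  labels <- as.factor(labels)
  k <- n_clusters %||% nlevels(labels)
  if (nrow(X) < k) stop("cluster_ari: fewer points than clusters")
  if (reduce_2d) {
    pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
    X <- pc$x[, seq_len(min(2L, ncol(pc$x))), drop = FALSE]
  }
  km <- with_seed(seed, stats::kmeans(X, centers = k, nstart = nstart,
                                      iter.max = 50L))
  structure(list(ari = adjusted_rand_index(km$cluster, labels),
                 chi = calinski_harabasz(X, labels),
                 n_clusters = as.integer(k),
                 reduction = if (reduce_2d) "2d" else "none"),
            class = "cluster_eval_report")
}

#' @export
print.cluster_eval_report <- function(x, ...) {
  cat(sprintf("<cluster_eval_report> ARI %.3f, CHI %.2f (k = %d, %s)\n",
              x$ari, x$chi, x$n_clusters, x$reduction))
  invisible(x)
}
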