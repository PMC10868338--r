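#' Batch-mixing entropy of an embedding
#'
#' For each cell, the Shannon entropy of the batch proportions among its
#' `k_neighbors` Euclidean-nearest neighbours (self excluded), normalized by
#' `log(#batches)` and averaged over cells. 1 means batches are fully
#' interleaved locally; 0 means every neighbourhood is single-batch. Defined
#' as 0 when only one batch is present.
#'
#' @param latent cells x k embedding matrix.
#' @param batch per-cell batch labels.
#' @param k_neighbors neighbourhood size (default 30).
#' @return a number in `[0, 1]`.
#' @export
batch_mixing_entropy <- function(latent, batch, k_neighbors = 30) {
  latent <- as.matrix(latent)
  batch <- as.factor(batch)
  n <- nrow(latent)
  nb <- nlevels(batch)
  if (nb < 2) return(0)
  k <- min(k_neighbors, n - 1)
  D <- euclidean_cross_dist(latent, latent)
  diag(D) <- Inf
  ent <- vapply(seq_len(n), function(i) {
    nn <- order(D[i, ])[seq_len(k)]
    p <- tabulate(batch[nn], nbins = nb) / k
    p <- p[p > 0]
    -sum(p * log(p))
  }, numeric(1))
  mean(ent) / log(nb)
}

#' Clustering agreement with planted labels
#'
#' Seeded k-means on the embedding followed by the adjusted Rand index
#' against the true labels (1 = identical partition up to relabelling,
#' ~0 = chance).
#'
#' @param latent cells x k embedding matrix.
#' @param true_labels per-cell ground-truth labels.
#' @param n_clusters number of k-means clusters (typically the true type
#'   count).
#' @param seed seed for the k-means initialization (default 0).
#' @return adjusted Rand index in `[-1, 1]`.
#' @export
clustering_ari <- function(latent, true_labels, n_clusters, seed = 0) {
  latent <- as.matrix(latent)
  km <- withr::with_seed(
    seed,
    stats::kmeans(latent, centers = n_clusters, nstart = 10, iter.max = 50)
  )
  adjusted_rand_index(km$cluster, true_labels)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same cells;
#' symmetric and invariant to relabelling.
#'
#' @param a,b label vectors of equal length.
#' @return ARI in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(a, b) {
  mclust::adjustedRandIndex(a, b)
}

#' k-nearest-neighbour classification accuracy
#'
#' Leave-one-out (when `train` and `test` coincide) or train/test kNN majority
#' vote; used to probe how much batch signal an embedding retains (a domain
#' classifier near chance accuracy means a batch-invariant latent space).
#'
#' @param train_latent,train_labels training embedding and labels.
#' @param test_latent,test_labels test embedding and labels.
#' @param k_neighbors vote size (default 15).
#' @return classification accuracy in `[0, 1]`.
#' @export
knn_accuracy <- function(train_latent, train_labels,
                         test_latent, test_labels, k_neighbors = 15) {
  pred <- transfer_labels(train_latent, train_labels, test_latent,
                          k_neighbors = k_neighbors)
  mean(pred$predicted == as.character(test_labels))
}
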