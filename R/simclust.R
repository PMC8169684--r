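# Pairwise similarity, agglomerative clustering, validation indices.

#' Tanimoto similarity between two binary key vectors
#'
#' |A intersect B| / |A union B|. Undefined (error) when both vectors are
#' all-zero.
#'
#' @param a,b Binary vectors of equal length.
#' @return Similarity in [0, 1].
#' @export
#' @examples
#' tanimoto(c(1, 1, 1, 0), c(0, 1, 1, 1))  # 0.5
tanimoto <- function(a, b) {
  if (length(a) != length(b)) validation_error("vectors differ in length")
  a <- as.logical(a); b <- as.logical(b)
  un <- sum(a | b)
  if (un == 0) validation_error("Tanimoto undefined for two empty bit sets")
  sum(a & b) / un
}

#' Pairwise Jaccard (1 - Tanimoto) distance matrix
#'
#' @param fp A `fingerprint_matrix` (or binary matrix) with row ids.
#' @return Object of class `distance_matrix`: symmetric matrix with zero
#'   diagonal, attribute `metric = "jaccard"`.
#' @export
jaccard_distance_matrix <- function(fp) {
  m <- unclass(as.matrix(fp))
  storage.mode(m) <- "numeric"
  rs <- rowSums(m)
  if (any(rs == 0)) validation_error("all-zero fingerprint row(s)")
  inter <- tcrossprod(m)
  un <- outer(rs, rs, "+") - inter
  d <- 1 - inter / un
  diag(d) <- 0
  structure(d, class = c("distance_matrix", class(d)), metric = "jaccard")
}

#' Pairwise Euclidean distance matrix on scaled descriptors
#'
#' @param x Numeric matrix (rows = compounds, already scaled).
#' @return `distance_matrix` with attribute `metric = "euclidean"`.
#' @export
euclidean_distance_matrix <- function(x) {
  d <- as.matrix(stats::dist(as.matrix(x)))
  structure(d, class = c("distance_matrix", class(d)), metric = "euclidean")
}

#' Minimum Jaccard distance from each query to a training set
#'
#' The structural applicability-domain distance: min over training compounds
#' of 1 - Tanimoto.
#'
#' @param query A `fingerprint_matrix` (or binary matrix) of queries.
#' @param training A `fingerprint_matrix` of training compounds, same keys.
#' @return Numeric vector in [0, 1], one value per query row.
#' @export
min_jaccard_distance <- function(query, training) {
  q <- unclass(as.matrix(query)); tr <- unclass(as.matrix(training))
  if (nrow(tr) == 0) validation_error("empty training set")
  if (ncol(q) != ncol(tr)) validation_error("key dimension mismatch")
  storage.mode(q) <- "numeric"; storage.mode(tr) <- "numeric"
  inter <- q %*% t(tr)
  un <- outer(rowSums(q), rowSums(tr), "+") - inter
  d <- 1 - inter / un
  d[un == 0] <- NA  # both-empty pairs are undefined
  apply(d, 1, min, na.rm = TRUE)
}

#' Minimum Euclidean distance from each query to a training matrix
#'
#' Queries must be scaled with the training scaling statistics before calling.
#'
#' @param query Numeric matrix (or vector for one query).
#' @param training Numeric matrix with matching columns.
#' @return Numeric vector of minimum distances, one per query row.
#' @export
min_euclidean_distance <- function(query, training) {
  q <- if (is.null(dim(query))) matrix(query, nrow = 1) else as.matrix(query)
  tr <- as.matrix(training)
  if (nrow(tr) == 0) validation_error("empty training set")
  if (ncol(q) != ncol(tr)) validation_error("descriptor dimension mismatch")
  cross <- q %*% t(tr)
  d2 <- outer(rowSums(q^2), rowSums(tr^2), "+") - 2 * cross
  sqrt(pmax(apply(d2, 1, min), 0))
}

#' Hierarchical clustering with Ward's minimum-variance criterion
#'
#' Variance-minimizing agglomeration on the given dissimilarities using the
#' squared-distance ("ward.D2") update, cut into `k` clusters.
#'
#' @param dist A `distance_matrix` (or symmetric matrix / `dist`).
#' @param k Number of clusters, 1 <= k <= n.
#' @return Integer label vector named by compound id.
#' @export
hierarchical_clusters <- function(dist, k) {
  d <- stats::as.dist(as.matrix(dist))
  n <- attr(d, "Size")
  if (k < 1 || k > n) validation_error("k out of range")
  hc <- stats::hclust(d, method = "ward.D2")
  stats::cutree(hc, k = k)
}

#' Internal cluster-validation indices
#'
#' Dunn: minimum between-cluster separation / maximum cluster diameter.
#' Dunn2: minimum average between-cluster dissimilarity / maximum average
#' within-cluster dissimilarity. Average silhouette width compares each
#' point's mean within-cluster distance with its mean distance to the nearest
#' other cluster (singleton-cluster members get silhouette 0).
#'
#' @param dist A `distance_matrix` (or symmetric matrix).
#' @param labels Cluster labels, one per row of `dist`.
#' @return Named list: `dunn`, `dunn2`, `avg_silhouette`.
#' @export
cluster_validation <- function(dist, labels) {
  d <- as.matrix(dist)
  labels <- as.vector(labels)
  if (length(labels) != nrow(d)) validation_error("label length mismatch")
  cl <- unique(labels)
  if (length(cl) < 2) validation_error("need at least 2 clusters")

  min_sep <- Inf; max_diam <- 0
  min_avg_between <- Inf; max_avg_within <- 0
  for (i in seq_along(cl)) {
    ai <- labels == cl[i]
    di <- d[ai, ai, drop = FALSE]
    if (sum(ai) > 1) {
      max_diam <- max(max_diam, max(di))
      max_avg_within <- max(max_avg_within,
                            mean(di[upper.tri(di)]))
    }
    for (j in seq_along(cl)) {
      if (j <= i) next
      aj <- labels == cl[j]
      dij <- d[ai, aj, drop = FALSE]
      min_sep <- min(min_sep, min(dij))
      min_avg_between <- min(min_avg_between, mean(dij))
    }
  }
  sil <- cluster::silhouette(as.integer(factor(labels)), dmatrix = d)
  avg_sil <- if (is.matrix(sil)) mean(sil[, "sil_width"]) else NA_real_
  list(
    dunn = if (max_diam > 0) min_sep / max_diam else Inf,
    dunn2 = if (max_avg_within > 0) min_avg_between / max_avg_within else Inf,
    avg_silhouette = avg_sil
  )
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement; invariant to label renaming,
#' 1 for identical partitions, ~0 for independent ones.
#'
#' @param labels_a,labels_b Label vectors of equal length.
#' @return ARI (<= 1).
#' @export
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("x", "x", "y", "y"))  # 1
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    validation_error("partitions differ in length")
  }
  tab <- table(labels_a, labels_b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(labels_a))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}
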