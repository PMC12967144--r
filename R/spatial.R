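## Chromosomal and organelle spatial statistics: COM distances, distance
## matrices, proximity networks, K-means/silhouette and GMM clustering,
## within-cluster nearest-neighbour distances. Distances are Euclidean on
## physical (nm) coordinates; matrices report nm, displacements and
## nearest-neighbour distances report um.

#' Straight-line distance between two centres of mass
#'
#' @param p1,p2 Numeric length-3 `(x, y, z)` in nm.
#' @return Distance in nm.
#' @export
com_distance <- function(p1, p2) {
  if (any(!is.finite(p1)) || any(!is.finite(p2)))
    stop("points must be finite", call. = FALSE)
  sqrt(sum((as.numeric(p2) - as.numeric(p1))^2))
}

#' Displacement of an object from the cell centre
#'
#' COM-to-COM straight-line distance, reported in micrometres. Both COMs must
#' come from the same coordinate frame (same volume).
#'
#' @param object_com,cell_com Numeric length-3 `(x, y, z)` nm.
#' @param frame Optional pair of frame identifiers; if both are supplied and
#'   differ, an error is raised.
#' @return Displacement in um.
#' @export
displacement_from_center <- function(object_com, cell_com, frame = NULL) {
  if (!is.null(frame) && length(frame) == 2 && !identical(frame[[1]], frame[[2]]))
    stop("COMs come from different coordinate frames", call. = FALSE)
  nm_to_um(com_distance(object_com, cell_com))
}

#' Pairwise COM distance matrix
#'
#' @param coms Matrix or data frame with columns `(x, y, z)` in nm, one row
#'   per object; >= 2 objects.
#' @param object_ids Optional ids used as dimnames.
#' @return Symmetric matrix (nm) with zero diagonal, class `dist_matrix`.
#' @export
distance_matrix <- function(coms, object_ids = NULL) {
  coms <- as.matrix(coms)
  if (nrow(coms) < 2) stop("need at least 2 objects", call. = FALSE)
  m <- as.matrix(stats::dist(coms))
  ids <- if (!is.null(object_ids)) as.character(object_ids) else
    rownames(coms)
  if (!is.null(ids)) dimnames(m) <- list(ids, ids)
  class(m) <- c("dist_matrix", class(m))
  m
}

#' Rank chromosomes by volume against distance from the cell centre
#'
#' Chromosomes are numbered by descending volume (rank 1 = largest) and
#' listed with their COM distance from the cell centre, the Fig-style
#' "volume rank vs radial position" table.
#'
#' @param chromosomes Data frame with `object_id`, `volume_um3` and COM
#'   columns `com_x_nm`, `com_y_nm`, `com_z_nm`.
#' @param cell_com Numeric `(x, y, z)` nm.
#' @return Data frame: `rank`, `object_id`, `volume_um3`,
#'   `distance_from_center_nm`, sorted by rank.
#' @export
radial_ranking <- function(chromosomes, cell_com) {
  ch <- as.data.frame(chromosomes)
  dist_nm <- sqrt((ch$com_x_nm - cell_com[1])^2 +
                    (ch$com_y_nm - cell_com[2])^2 +
                    (ch$com_z_nm - cell_com[3])^2)
  ord <- order(-ch$volume_um3, ch$object_id)
  data.frame(rank = seq_len(nrow(ch)),
             object_id = ch$object_id[ord],
             volume_um3 = ch$volume_um3[ord],
             distance_from_center_nm = dist_nm[ord])
}

#' Proximity network from a distance matrix
#'
#' Default rule is mutual k-nearest-neighbours (k = 3): an edge joins i and j
#' only when each is among the other's k nearest neighbours, so every degree
#' is at most k and edge sets grow monotonically in k. Neighbour ties break
#' by (distance, id) order. An absolute distance threshold rule is also
#' available.
#'
#' @param dm Matrix from [distance_matrix()].
#' @param rule `"mutual_knn"` or `"threshold"`.
#' @param k Neighbour count for the mutual-kNN rule; must satisfy `k < n`.
#' @param threshold Distance cutoff (nm) for the threshold rule.
#' @return An `igraph` undirected graph; the rule is stored in the graph
#'   attribute `rule`.
#' @export
build_network <- function(dm, rule = c("mutual_knn", "threshold"), k = 3,
                          threshold = NULL) {
  rule <- match.arg(rule)
  m <- as.matrix(dm)
  n <- nrow(m)
  ids <- rownames(m)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  adj <- matrix(FALSE, n, n)
  if (rule == "mutual_knn") {
    if (k >= n) stop("k must be smaller than the number of objects", call. = FALSE)
    nn <- lapply(seq_len(n), function(i) {
      ord <- order(m[i, -i], seq_len(n)[-i])
      (seq_len(n)[-i])[ord][seq_len(k)]
    })
    for (i in seq_len(n)) for (j in nn[[i]])
      if (i %in% nn[[j]]) adj[i, j] <- adj[j, i] <- TRUE
    descr <- sprintf("mutual_knn(k=%d)", k)
  } else {
    if (is.null(threshold)) stop("threshold rule needs a threshold", call. = FALSE)
    adj <- m <= threshold
    diag(adj) <- FALSE
    descr <- sprintf("threshold(%g nm)", threshold)
  }
  dimnames(adj) <- list(ids, ids)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  g <- igraph::set_graph_attr(g, "rule", descr)
  g
}

#' K-means clustering with silhouette-selected K
#'
#' For each candidate k the points are clustered with `stats::kmeans`
#' (>= 10 restarts from the given seed) and scored by the mean silhouette
#' width (`cluster::silhouette` on Euclidean distances); the k maximising the
#' mean silhouette wins (ties to the smaller k). Deterministic for a fixed
#' seed.
#'
#' @param points Matrix `(x, y, z)` (or any dimension) in nm, n >= 3 rows.
#' @param k_range Candidate cluster counts, subset of `2:(n-1)`; default
#'   `2:min(10, n - 1)`.
#' @param seed Integer RNG seed (required for reproducibility).
#' @param nstart Restarts per k.
#' @return List of class `cluster_result`: `k`, `labels`, `centers`,
#'   `silhouette` (named vector over k_range), `nn_within_um`.
#' @export
kmeans_silhouette <- function(points, k_range = NULL, seed = 1729,
                              nstart = 25) {
  pts <- as.matrix(points)
  n <- nrow(pts)
  if (n < 3) stop("need at least 3 points", call. = FALSE)
  if (all(apply(pts, 2, function(v) diff(range(v)) == 0)))
    stop("degenerate configuration: all points identical", call. = FALSE)
  if (is.null(k_range)) k_range <- 2:min(10, n - 1)
  if (any(k_range < 2) || any(k_range > n - 1))
    stop("k_range must lie within [2, n-1]", call. = FALSE)
  D <- stats::dist(pts)
  sil <- numeric(length(k_range)); names(sil) <- k_range
  fits <- vector("list", length(k_range))
  set.seed(seed)
  for (i in seq_along(k_range)) {
    fits[[i]] <- stats::kmeans(pts, centers = k_range[i], nstart = nstart,
                               iter.max = 100)
    sw <- cluster::silhouette(fits[[i]]$cluster, D)
    sil[i] <- mean(sw[, "sil_width"])
  }
  best <- which.max(sil)    # first maximum -> smaller k on ties
  fit <- fits[[best]]
  structure(list(
    k = k_range[best],
    labels = fit$cluster,
    centers = fit$centers,
    silhouette = sil,
    nn_within_um = nn_within_clusters(pts, fit$cluster)
  ), class = "cluster_result")
}

#' Gaussian-mixture clustering with BIC-selected component count
#'
#' Fits full-covariance (VVV) Gaussian mixtures for 1..`max_components` with
#' `mclust` and keeps the component count with the best BIC. When sex labels
#' are given, the members of the cluster containing the X and Y chromosomes
#' are reported.
#'
#' @param points Matrix of coordinates (nm), n >= max_components rows.
#' @param max_components Largest component count to consider.
#' @param seed Integer RNG seed.
#' @param sex_ids Optional vector of row indices (or names matching rownames)
#'   of the sex chromosomes.
#' @return List of class `cluster_result`: `k`, `labels`, `centers`, `bic`
#'   (vector over component counts), `nn_within_um`, and `sex_cluster_members`
#'   when `sex_ids` is given.
#' @importFrom mclust Mclust mclustBIC
#' @export
gmm_cluster <- function(points, max_components = 5, seed = 1729,
                        sex_ids = NULL) {
  pts <- as.matrix(points)
  n <- nrow(pts)
  if (max_components < 1 || n < max_components)
    stop("need n >= max_components >= 1", call. = FALSE)
  set.seed(seed)
  fit <- mclust::Mclust(pts, G = 1:max_components, modelNames = "VVV",
                        verbose = FALSE)
  if (is.null(fit)) stop("mixture fit failed for all component counts",
                         call. = FALSE)
  bad <- apply(fit$BIC, 1, function(r) all(is.na(r)))
  if (any(bad))
    warning("singular fit skipped for G = ",
            paste(rownames(fit$BIC)[bad], collapse = ", "))
  res <- list(
    k = fit$G,
    labels = fit$classification,
    centers = t(fit$parameters$mean),
    bic = fit$BIC[, 1],
    nn_within_um = nn_within_clusters(pts, fit$classification)
  )
  if (!is.null(sex_ids)) {
    ridx <- if (is.character(sex_ids) && !is.null(rownames(pts)))
      match(sex_ids, rownames(pts)) else as.integer(sex_ids)
    cl <- unique(res$labels[ridx])
    members <- which(res$labels %in% cl)
    res$sex_cluster_members <- if (!is.null(rownames(pts)))
      rownames(pts)[members] else members
  }
  structure(res, class = "cluster_result")
}

#' Nearest-neighbour distance within each cluster
#'
#' For every object, the minimum distance to another object sharing its
#' cluster label, in micrometres. Members of singleton clusters get `NA`
#' (flagged undefined).
#'
#' @param points Matrix of coordinates in nm.
#' @param labels Cluster labels, one per row.
#' @return Numeric vector (um), `NA` for singleton clusters.
#' @export
nn_within_clusters <- function(points, labels) {
  pts <- as.matrix(points)
  n <- nrow(pts)
  stopifnot(length(labels) == n)
  m <- as.matrix(stats::dist(pts))
  diag(m) <- Inf
  out <- rep(NA_real_, n)
  for (lb in unique(labels)) {
    idx <- which(labels == lb)
    if (length(idx) < 2) next
    sub <- m[idx, idx, drop = FALSE]
    out[idx] <- apply(sub, 1, min)
  }
  nm_to_um(out)
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> k = %d, n = %d\n", x$k, length(x$labels)))
  invisible(x)
}
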