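#' kNN-density mode-seeking (X-shift style) clustering
#'
#' Unsupervised clustering of per-cell marker intensities in the spirit of
#' X-shift: estimate each cell's local density as the inverse mean distance
#' to its K nearest neighbours, link every cell to the densest of its
#' neighbours that is denser than itself, and take the trees rooted at
#' density modes as basins. Basins whose centroids lie within a few pooled
#' within-basin standard deviations of each other are merged (see
#' [xshift_cluster()]). Everything is deterministic given the input order and
#' K (ties broken toward the lowest index); the kNN search is exact
#' (blocked brute force).
#'
#' @name clustering
NULL

#' Prepare a feature matrix from a cell table
#'
#' Drops excluded markers, applies `arcsinh(x / cofactor)` and per-marker
#' z-scoring. Zero-variance markers are dropped with a warning.
#'
#' @param table cell table with marker columns.
#' @param markers marker columns to use (default: attribute `markers`).
#' @param exclude markers to exclude from clustering.
#' @param cofactor arcsinh cofactor (> 0; 5 is the cytometry convention).
#' @return numeric matrix of transformed features (finite values only).
#' @export
prepare_features <- function(table, markers = attr(table, "markers"),
                             exclude = character(0), cofactor = 5) {
  stopifnot(nrow(table) > 0, cofactor > 0)
  if (is.null(markers)) stop("no marker columns identified")
  bad <- setdiff(exclude, markers)
  if (length(bad)) stop("excluded markers not in table: ",
                        paste(bad, collapse = ", "))
  use <- setdiff(markers, exclude)
  X <- asinh(as.matrix(table[, use, drop = FALSE]) / cofactor)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance marker(s): ",
            paste(use[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  scale(X)
}

#' kNN density estimate
#'
#' Density of each point is the inverse of the mean Euclidean distance to its
#' K nearest neighbours (exact, all-pairs).
#'
#' @param features numeric matrix (rows = cells).
#' @param K neighbourhood size (2 <= K < n).
#' @return list with `density` (numeric vector), `nn_index` and `nn_dist`
#'   (n x K matrices).
#' @export
knn_density <- function(features, K) {
  n <- nrow(features)
  if (K >= n) stop("K must be smaller than the number of cells")
  stopifnot(K >= 2)
  nn <- knn_brute(features, K)
  md <- rowMeans(nn$dist)
  list(density = 1 / pmax(md, .Machine$double.eps),
       nn_index = nn$index, nn_dist = nn$dist)
}

#' X-shift style clustering
#'
#' @param features numeric matrix from [prepare_features()] (or any numeric
#'   feature matrix).
#' @param K number of nearest neighbours for the density estimate.
#' @param merge_sd basin-merge threshold in pooled within-basin standard
#'   deviation units. After mode seeking, basins whose centroids are closer
#'   than `merge_sd` pooled sds are agglomerated (closest pair first);
#'   genuinely distinct cell populations sit several within-population sds
#'   apart, while extra modes raised by density-estimator noise inside one
#'   population are much closer. Default 3.5.
#' @return a `cluster_result`: list with `labels` (dense integers
#'   1..n_clusters), `n_clusters`, `modes` (row index of each cluster's
#'   density peak), `density` (unsmoothed kNN density), `K`, and `profiles`
#'   (per-cluster mean feature vector).
#' @details The procedure is: (1) exact kNN density (inverse mean distance
#'   to the K nearest neighbours); (2) one round of neighbourhood averaging
#'   of the density, which suppresses spurious single-point modes without
#'   moving genuine peaks; (3) every point links to the densest of its K
#'   neighbours that is denser than itself (ties toward the lowest index);
#'   points with no denser neighbour are modes and the resulting forest
#'   defines basins; (4) basins are merged agglomeratively while the closest
#'   pair of basin centroids lies within `merge_sd` pooled within-basin sds.
#'   Deterministic given the input order and K.
#' @export
xshift_cluster <- function(features, K, merge_sd = 3.5) {
  n <- nrow(features)
  d <- ncol(features)
  kd <- knn_density(features, K)
  dens0 <- kd$density
  # neighbourhood-smoothed density for the mode-seeking topology
  dens <- (dens0 + rowSums(matrix(dens0[kd$nn_index], n))) / (K + 1)
  parent <- integer(n)
  for (i in seq_len(n)) {
    nb <- kd$nn_index[i, ]
    cand <- nb[dens[nb] > dens[i]]
    if (length(cand)) parent[i] <- cand[order(-dens[cand], cand)[1]]
  }
  root <- integer(n)
  find_root <- function(i) {
    path <- integer(0)
    while (parent[i] != 0L && root[i] == 0L) {
      path <- c(path, i)
      i <- parent[i]
    }
    r <- if (root[i] != 0L) root[i] else i
    root[c(path, i)] <<- r
    r
  }
  for (i in seq_len(n)) if (root[i] == 0L) find_root(i)
  modes <- sort(unique(root))
  members <- split(seq_len(n), match(root, modes))
  mode_of <- modes
  cent <- t(vapply(members, function(p)
    colMeans(features[p, , drop = FALSE]), numeric(d)))
  ssq <- vapply(seq_along(members), function(k) {
    p <- members[[k]]
    sum(rowSums((features[p, , drop = FALSE] -
                 matrix(cent[k, ], length(p), d, byrow = TRUE))^2))
  }, numeric(1))
  repeat {
    m <- length(members)
    if (m < 2) break
    nsz <- lengths(members)
    sig2 <- ssq / (nsz * d)
    best <- Inf; bi <- 0L; bj <- 0L
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      pooled <- sqrt((nsz[i] * sig2[i] + nsz[j] * sig2[j]) / (nsz[i] + nsz[j]))
      md <- sqrt(sum((cent[i, ] - cent[j, ])^2)) / max(pooled, 1e-12)
      if (md < best) { best <- md; bi <- i; bj <- j }
    }
    if (best >= merge_sd) break
    pts <- sort(c(members[[bi]], members[[bj]]))
    members[[bi]] <- pts
    mode_of[bi] <- if (dens0[mode_of[bi]] >= dens0[mode_of[bj]])
      mode_of[bi] else mode_of[bj]
    cent[bi, ] <- colMeans(features[pts, , drop = FALSE])
    ssq[bi] <- sum(rowSums((features[pts, , drop = FALSE] -
                            matrix(cent[bi, ], length(pts), d, byrow = TRUE))^2))
    members[[bj]] <- NULL
    mode_of <- mode_of[-bj]
    cent <- cent[-bj, , drop = FALSE]
    ssq <- ssq[-bj]
  }
  # dense labels ordered by each cluster's first member for determinism
  ord <- order(vapply(members, min, numeric(1)))
  labels <- integer(n)
  for (k in seq_along(ord)) labels[members[[ord[k]]]] <- k
  profiles <- rowsum(features, labels) / as.numeric(table(labels))
  structure(list(labels = labels, n_clusters = length(members),
                 modes = mode_of[ord], density = dens0, K = K,
                 profiles = profiles), class = "cluster_result")
}

#' Choose K by the elbow of the cluster-count curve
#'
#' Runs [xshift_cluster()] for each K in the sweep, records the cluster
#' count, and returns the K at the interior point of maximum positive second
#' difference of cluster count versus K (the elbow). If the curve has no
#' elbow (e.g. constant), the smallest K is returned with a warning.
#'
#' @param features feature matrix.
#' @param K_sweep ascending integer vector of at least 3 candidate K values.
#' @return chosen K, with the full curve in attribute `curve`
#'   (data.frame K, n_clusters).
#' @export
select_elbow <- function(features, K_sweep) {
  if (length(K_sweep) < 3) stop("K sweep must contain at least 3 values")
  if (is.unsorted(K_sweep, strictly = TRUE))
    stop("K sweep must be sorted ascending")
  counts <- vapply(K_sweep, function(K)
    xshift_cluster(features, K)$n_clusters, integer(1))
  curve <- data.frame(K = K_sweep, n_clusters = counts)
  d2 <- diff(counts, differences = 2)  # at interior points 2..(m-1)
  if (all(d2 <= 0) && all(diff(counts) == 0)) {
    warning("cluster count is flat across the sweep; returning smallest K")
    K <- K_sweep[1]
  } else {
    K <- K_sweep[which.max(d2) + 1L]
  }
  attr(K, "curve") <- curve
  K
}

#' Per-cluster marker profiles
#'
#' Mean raw and transformed intensity per marker for each cluster (all
#' markers, including any excluded from clustering, for reporting), ordered
#' by cluster size descending.
#'
#' @param result a `cluster_result`.
#' @param table the cell table that was clustered (same row order).
#' @param markers marker columns (default attribute).
#' @param cofactor arcsinh cofactor for the transformed profile.
#' @return data.frame: cluster, size, then `<marker>` (raw mean) and
#'   `<marker>_t` (transformed mean) columns.
#' @export
profile_clusters <- function(result, table, markers = attr(table, "markers"),
                             cofactor = 5) {
  stopifnot(length(result$labels) == nrow(table))
  lb <- result$labels
  sizes <- as.numeric(table(lb))
  stopifnot(all(sizes > 0), sum(sizes) == nrow(table))
  raw <- as.matrix(table[, markers, drop = FALSE])
  pr <- rowsum(raw, lb) / sizes
  tr <- rowsum(asinh(raw / cofactor), lb) / sizes
  colnames(tr) <- paste0(colnames(tr), "_t")
  out <- data.frame(cluster = sort(unique(lb)), size = sizes, pr, tr,
                    check.names = FALSE)
  out[order(-out$size), , drop = FALSE]
}

#' Adjusted Rand Index between two partitions
#'
#' Chance-corrected agreement, used to validate clustering against planted
#' truth. Thin wrapper over [mclust::adjustedRandIndex()].
#'
#' @param a,b integer label vectors of equal length.
#' @export
adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
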