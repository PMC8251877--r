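# Independent brute-force oracles used to validate the package's
# implementations on small inputs. These deliberately avoid the code paths
# they check.

# circular integer shift: out[y, x] = im[y - dy, x - dx]
int_shift <- function(im, dy, dx) {
  nr <- nrow(im); nc <- ncol(im)
  im[(seq_len(nr) - 1 - dy) %% nr + 1, (seq_len(nc) - 1 - dx) %% nc + 1]
}

# exhaustive integer-shift normalized cross-correlation over +-rad px
oracle_best_shift <- function(ref, mov, rad = 10) {
  best <- c(0, 0); bv <- -Inf
  r <- ref - mean(ref); m <- mov - mean(mov)
  for (dy in -rad:rad) for (dx in -rad:rad) {
    v <- sum(int_shift(r, dy, dx) * m)
    if (v > bv) { bv <- v; best <- c(dy, dx) }
  }
  best
}

# all-pairs kNN density: inverse mean distance to K nearest neighbours
oracle_knn_density <- function(X, K) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  diag(D) <- Inf
  vapply(seq_len(n), function(i) 1 / mean(sort(D[i, ])[seq_len(K)]),
         numeric(1))
}

# Spearman rho from explicit average ranks
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# canonical form of a partition for order-free comparison
partition_signature <- function(labels) {
  unname(split(seq_along(labels), labels)[order(vapply(
    split(seq_along(labels), labels), min, numeric(1)))])
}
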