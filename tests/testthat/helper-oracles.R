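# Independent oracles and small utilities shared across tests.

# Brute-force type-7 quantile: sort and linearly interpolate by hand.
brute_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  vapply(p, function(pp) {
    h <- (n - 1) * pp + 1
    lo <- floor(h)
    hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }, numeric(1))
}

# Best-permutation agreement between two labelings with the same k.
label_agreement <- function(truth, found, k = 3) {
  perms <- gtools_permutations(k)
  best <- 0
  for (i in seq_len(nrow(perms))) {
    best <- max(best, mean(perms[i, found] == truth))
  }
  best
}

# all permutations of 1..k (tiny k only)
gtools_permutations <- function(k) {
  if (k == 1) return(matrix(1))
  sub <- gtools_permutations(k - 1)
  out <- NULL
  for (i in seq_len(k)) {
    rest <- c(seq_len(k))[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# Exhaustive minimum within-SS partition of points into k groups
# (feasible for n <= 9, k = 3). Returns a canonical partition signature.
best_kmeans_partition <- function(xy, k = 3) {
  n <- nrow(xy)
  stopifnot(n <= 9)
  best_ss <- Inf
  best_sig <- NULL
  grids <- expand.grid(rep(list(seq_len(k)), n))
  for (i in seq_len(nrow(grids))) {
    g <- as.integer(grids[i, ])
    if (length(unique(g)) < k) next
    ss <- 0
    for (j in seq_len(k)) {
      pts <- xy[g == j, , drop = FALSE]
      ss <- ss + sum(scale(pts, scale = FALSE)^2)
    }
    if (ss < best_ss - 1e-12) {
      best_ss <- ss
      best_sig <- partition_signature(g)
    }
  }
  best_sig
}

partition_signature <- function(labels) {
  # canonical string independent of label names
  groups <- split(seq_along(labels), labels)
  paste(sort(vapply(groups, function(g) paste(g, collapse = ","), "")),
        collapse = "|")
}
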