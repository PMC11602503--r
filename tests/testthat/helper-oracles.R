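# Independent oracles used across the suite. These deliberately use naive
# loops / enumeration so they share no code with the implementation.

# all permutations of 1..n (n <= 6 is plenty here)
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L))
    for (pos in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
  out
}

# mapped clustering accuracy by exhaustive search over one-to-one mappings
# of predicted clusters onto true classes
exhaustive_accuracy <- function(truth, pred) {
  tl <- sort(unique(truth)); pl <- sort(unique(pred))
  k <- max(length(tl), length(pl))
  best <- 0
  for (perm in all_perms(k)) {
    hits <- 0
    for (i in seq_along(truth)) {
      j <- match(pred[i], pl)
      mapped <- perm[j]
      if (mapped <= length(tl) && tl[mapped] == truth[i]) hits <- hits + 1
    }
    best <- max(best, hits)
  }
  best / length(truth)
}

# plain row-wise MLP sharing the GCN's weights: affine + LeakyReLU per
# hidden layer, linear final layer
mlp_oracle <- function(X, W_list, slope) {
  H <- X
  for (l in seq_along(W_list)) {
    H <- H %*% W_list[[l]]
    if (l < length(W_list)) H <- ifelse(H > 0, H, slope * H)
  }
  H
}

# multi-layer GCN without any injection: act(A H W) per hidden layer
plain_gcn_oracle <- function(A, X, W_list, slope) {
  H <- X
  for (l in seq_along(W_list)) {
    H <- A %*% H %*% W_list[[l]]
    if (l < length(W_list)) H <- ifelse(H > 0, H, slope * H)
  }
  H
}

# random row-stochastic matrix
random_stochastic <- function(n, c) {
  M <- matrix(stats::runif(n * c, 0.05, 1), n, c)
  M / rowSums(M)
}
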