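## Multi-view fusion: adaptive weighting of GCN logits and
## error-reconstruction fusion of SAE latents.

row_softmax <- function(M) {
  M <- M - apply(M, 1L, max)             # shift invariance, overflow safety
  E <- exp(M)
  E / rowSums(E)
}

#' Initialize the adaptive fusion weight matrix
#'
#' `W_fusion` is (V*c) x c, initialized as V vertically stacked identity
#' blocks scaled by 1/V, so at initialization the fused logits are the
#' unweighted average of the per-view logits.
#'
#' @param n_views number of views V.
#' @param n_clusters number of clusters c.
#' @return numeric (V*c) x c matrix.
#' @export
init_fusion_weights <- function(n_views, n_clusters) {
  do.call(rbind, replicate(n_views, diag(n_clusters) / n_views,
                           simplify = FALSE))
}

#' Adaptive weighting fusion of per-view GCN outputs
#'
#' Concatenates the per-view logit matrices column-wise into an N x (V*c)
#' matrix, applies the learned linear map `W_fusion`, and row-softmaxes the
#' result into the probability matrix G whose entry g_ij is the probability
#' that sample i belongs to cluster j.
#'
#' @param per_view_logits list of N x c matrices, one per view.
#' @param W_fusion (V*c) x c weight matrix (see [init_fusion_weights()]).
#' @return row-stochastic N x c matrix G.
#' @export
adaptive_fusion <- function(per_view_logits, W_fusion) {
  stopifnot(length(per_view_logits) >= 1)
  d <- dim(per_view_logits[[1]])
  for (Lv in per_view_logits)
    if (!identical(dim(Lv), d))
      stop("all views must share N and c in adaptive_fusion", call. = FALSE)
  Gc <- do.call(cbind, per_view_logits)
  if (nrow(W_fusion) != ncol(Gc) || ncol(W_fusion) != d[2])
    stop("W_fusion must be (V*c) x c", call. = FALSE)
  row_softmax(Gc %*% W_fusion)
}

#' Error-reconstruction fusion loss
#'
#' `sum_v ||Z_fused - Z_v||_F^2` between the learnable consensus latent
#' matrix and the per-view SAE latents. Minimizing this alone drives
#' `Z_fused` to the elementwise mean of the views' latents; jointly with
#' the clustering losses it becomes a cluster-aware consensus.
#'
#' @param Z_fused N x d consensus matrix (a free learnable parameter).
#' @param per_view_latents list of N x d latent matrices.
#' @return nonnegative scalar.
#' @export
fusion_reconstruction_loss <- function(Z_fused, per_view_latents) {
  total <- 0
  for (Z in per_view_latents) {
    if (!identical(dim(Z), dim(Z_fused)))
      stop("Z_fused and per-view latents must share their shape",
           call. = FALSE)
    total <- total + sum((Z_fused - Z)^2)
  }
  total
}
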