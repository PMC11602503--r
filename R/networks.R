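## Per-view stacked autoencoder and graph-convolution branches, full batch.
## Parameters are plain R matrices; gradients live in train.R.

leaky_relu <- function(x, slope) x * (slope + (1 - slope) * (x > 0))
leaky_relu_grad <- function(pre, slope) slope + (1 - slope) * (pre > 0)

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -lim, lim), nin, nout)
}

#' Initialize a stacked autoencoder for one view
#'
#' Encoder layer widths are `c(m, encoder_dims)`; the decoder mirrors the
#' encoder. The final encoder width is the shared latent dimension d
#' (default configuration ends in 100). Weights are Glorot-uniform from the
#' current RNG stream, so seed before calling for reproducibility.
#'
#' @param m input feature count of the view.
#' @param encoder_dims hidden widths ending in the latent dimension.
#' @return `SaeState` list with `enc` and `dec` layer lists (`W`, `b`) and
#'   the dimension chain.
#' @export
init_sae <- function(m, encoder_dims = c(512L, 256L, 100L)) {
  dims <- c(m, as.integer(encoder_dims))
  L <- length(dims) - 1L
  enc <- lapply(seq_len(L), function(l)
    list(W = glorot(dims[l], dims[l + 1L]), b = numeric(dims[l + 1L])))
  rdims <- rev(dims)
  dec <- lapply(seq_len(L), function(l)
    list(W = glorot(rdims[l], rdims[l + 1L]), b = numeric(rdims[l + 1L])))
  structure(list(enc = enc, dec = dec, dims = dims), class = "SaeState")
}

#' Stacked-autoencoder forward pass
#'
#' Every encoder and decoder layer applies an affine map followed by
#' LeakyReLU. Returns all intermediate encoder representations, which the
#' GCN branch consumes through the joint-representation injection.
#'
#' @param X numeric N x m matrix (no missing values).
#' @param sae an [init_sae()] state.
#' @param slope LeakyReLU negative slope (default 0.01).
#' @return list with `latents` (encoder outputs Z^(1..L); `latents[[L]]` is
#'   the latent code), `xhat` (reconstruction, N x m) and `cache` for the
#'   backward pass.
#' @export
sae_forward <- function(X, sae, slope = 0.01) {
  if (ncol(X) != sae$dims[1])
    stop("input width ", ncol(X), " does not match first-layer weights (",
         sae$dims[1], ")", call. = FALSE)
  L <- length(sae$enc)
  latents <- vector("list", L); pre_e <- vector("list", L)
  A <- X
  for (l in seq_len(L)) {
    U <- sweep(A %*% sae$enc[[l]]$W, 2L, sae$enc[[l]]$b, "+")
    pre_e[[l]] <- U
    A <- leaky_relu(U, slope)
    latents[[l]] <- A
  }
  dec_in <- vector("list", L); pre_d <- vector("list", L)
  D <- latents[[L]]
  for (l in seq_len(L)) {
    dec_in[[l]] <- D
    U <- sweep(D %*% sae$dec[[l]]$W, 2L, sae$dec[[l]]$b, "+")
    pre_d[[l]] <- U
    D <- leaky_relu(U, slope)
  }
  list(latents = latents, xhat = D,
       cache = list(X = X, pre_e = pre_e, pre_d = pre_d, dec_in = dec_in,
                    slope = slope))
}

#' Summed reconstruction loss over views
#'
#' `(1 / 2N) * sum_v ||Xhat_v - X_v||_F^2` with N the shared sample count.
#'
#' @param views_X list of original matrices X_v.
#' @param xhats list of reconstructions, matching shapes.
#' @return nonnegative scalar.
#' @export
reconstruction_loss <- function(views_X, xhats) {
  stopifnot(length(views_X) == length(xhats))
  N <- nrow(views_X[[1]])
  total <- 0
  for (v in seq_along(views_X)) {
    if (!identical(dim(views_X[[v]]), dim(xhats[[v]])))
      stop("shape mismatch between X and Xhat in view ", v, call. = FALSE)
    total <- total + sum((xhats[[v]] - views_X[[v]])^2)
  }
  total / (2 * N)
}

#' Joint representation of GCN and SAE layers
#'
#' `H = (1 - epsilon) * G_prev + epsilon * Z_prev`. Feeding the SAE's
#' layer-wise features back into the graph convolution counters GCN
#' over-smoothing; `epsilon` balances the two sources (default 0.5).
#'
#' @param G_prev GCN representation of the previous layer.
#' @param Z_prev SAE representation of the same width.
#' @param epsilon balance parameter in \[0, 1\].
#' @return matrix of the shared shape.
#' @export
joint_representation <- function(G_prev, Z_prev, epsilon = 0.5) {
  if (!identical(dim(G_prev), dim(Z_prev)))
    stop("G_prev and Z_prev must have identical shape", call. = FALSE)
  (1 - epsilon) * G_prev + epsilon * Z_prev
}

#' Initialize a GCN branch for one view
#'
#' One graph-convolution layer per encoder layer (matching widths, so the
#' injection is well defined) plus a final classification layer of width
#' `n_clusters` that emits logits.
#'
#' @param m input feature count of the view.
#' @param encoder_dims the SAE's hidden widths (see [init_sae()]).
#' @param n_clusters number of clusters c.
#' @param epsilon injection balance parameter (default 0.5).
#' @return `GcnState` list with weight list `W` (length L + 1) and `epsilon`.
#' @export
init_gcn <- function(m, encoder_dims = c(512L, 256L, 100L), n_clusters,
                     epsilon = 0.5) {
  dims <- c(m, as.integer(encoder_dims), as.integer(n_clusters))
  W <- lapply(seq_len(length(dims) - 1L), function(l)
    glorot(dims[l], dims[l + 1L]))
  structure(list(W = W, dims = dims, epsilon = epsilon), class = "GcnState")
}

#' GCN forward pass with joint-representation injection
#'
#' First layer: `G^(1) = act(A_norm X W^(1))`. Each subsequent hidden layer
#' takes `H = (1 - eps) G + eps Z` (the SAE's matching encoder output) and
#' applies `act(A_norm H W)`. The final layer is linear of width c and
#' returns logits; the row softmax is applied later, in the fusion head.
#'
#' @param A_norm normalized adjacency (see [normalize_adjacency()]).
#' @param X the view's N x m matrix.
#' @param latents encoder outputs from [sae_forward()]; pass `NULL` to run
#'   a plain GCN without injection (equivalent to `epsilon = 0`).
#' @param gcn an [init_gcn()] state.
#' @param slope LeakyReLU negative slope.
#' @return list with `logits` (N x c) and `cache` for the backward pass.
#' @export
gcn_forward <- function(A_norm, X, latents, gcn, slope = 0.01) {
  nlayer <- length(gcn$W)
  if (!is.null(latents) && length(latents) != nlayer - 1L)
    stop("latent stack length ", length(latents),
         " does not match GCN hidden layer count ", nlayer - 1L, call. = FALSE)
  eps <- if (is.null(latents)) 0 else gcn$epsilon
  G <- vector("list", nlayer - 1L)
  pre <- vector("list", nlayer)
  Hs <- vector("list", nlayer)           # input of each layer (after A_norm)
  H <- X
  for (l in seq_len(nlayer)) {
    if (l > 1L) {
      H <- if (is.null(latents)) G[[l - 1L]]
           else joint_representation(G[[l - 1L]], latents[[l - 1L]], eps)
    }
    AH <- A_norm %*% H
    Hs[[l]] <- AH
    U <- AH %*% gcn$W[[l]]
    pre[[l]] <- U
    if (l < nlayer) G[[l]] <- leaky_relu(U, slope)
  }
  list(logits = pre[[nlayer]],
       cache = list(G = G, pre = pre, AH = Hs, slope = slope, eps = eps))
}
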