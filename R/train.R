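## End-to-end training: SAE pretraining, K-means center initialization,
## joint optimization of all parameters under the dual self-supervised
## objective. Gradients are hand-derived reverse-mode (full batch); the
## optimizer is Adam. Parameters live in one flat named list of matrices
## so the optimizer and the finite-difference checks can treat them
## uniformly.

#' Training configuration
#'
#' Defaults follow the published experimental settings of the method
#' (Adam, learning rate 1e-4, weight decay 1e-15, 500 epochs, latent
#' dimension 100 via `encoder_dims`, epsilon 0.5); quantities the source
#' leaves open (pretraining schedule, loss weights, P-update cadence) have
#' documented package defaults.
#'
#' @param n_clusters number of clusters c (>= 2). Required.
#' @param learning_rate Adam learning rate for joint training.
#' @param pretrain_learning_rate Adam learning rate for the
#'   reconstruction-only SAE pretraining phase.
#' @param weight_decay L2 coefficient added to every gradient.
#' @param epochs joint-training epochs.
#' @param pretrain_epochs reconstruction-only epochs before joint training.
#' @param p_update_interval epochs between refreshes of the target
#'   distribution P (P is constant within an interval).
#' @param seed integer seed controlling every random draw.
#' @param encoder_dims SAE hidden widths ending in the latent dimension.
#' @param epsilon joint-representation balance parameter.
#' @param leaky_slope LeakyReLU negative slope.
#' @param dof Student-t degrees of freedom of the soft assignment.
#' @param ablation_mode `"full"` (both branches, dual self-supervision),
#'   `"sae_only"` (no GCN; labels from the Student-t assignment Q), or
#'   `"gcn_only"` (no SAE; single self-supervision with P built from G).
#' @param verbose print a loss line every `verbose` epochs (0 = silent).
#' @return a `TrainConfig` list.
#' @export
train_config <- function(n_clusters,
                         learning_rate = 1e-4,
                         pretrain_learning_rate = 1e-3,
                         weight_decay = 1e-15,
                         epochs = 500L,
                         pretrain_epochs = 200L,
                         p_update_interval = 1L,
                         seed = 1L,
                         encoder_dims = c(512L, 256L, 100L),
                         epsilon = 0.5,
                         leaky_slope = 0.01,
                         dof = 1,
                         ablation_mode = c("full", "sae_only", "gcn_only"),
                         verbose = 0L) {
  ablation_mode <- match.arg(ablation_mode)
  stopifnot(n_clusters >= 2, epochs >= 1, pretrain_epochs >= 0,
            p_update_interval >= 1, learning_rate > 0, dof > 0,
            epsilon >= 0, epsilon <= 1, length(encoder_dims) >= 1)
  structure(list(n_clusters = as.integer(n_clusters),
                 learning_rate = learning_rate,
                 pretrain_learning_rate = pretrain_learning_rate,
                 weight_decay = weight_decay,
                 epochs = as.integer(epochs),
                 pretrain_epochs = as.integer(pretrain_epochs),
                 p_update_interval = as.integer(p_update_interval),
                 seed = as.integer(seed),
                 encoder_dims = as.integer(encoder_dims),
                 epsilon = epsilon, leaky_slope = leaky_slope, dof = dof,
                 ablation_mode = ablation_mode,
                 verbose = as.integer(verbose)),
            class = "TrainConfig")
}

## ---- flat parameter plumbing -------------------------------------------

.sae_from_flat <- function(params, v, L, dims) {
  enc <- lapply(seq_len(L), function(l)
    list(W = params[[sprintf("sae%d_enc%d_W", v, l)]],
         b = params[[sprintf("sae%d_enc%d_b", v, l)]]))
  dec <- lapply(seq_len(L), function(l)
    list(W = params[[sprintf("sae%d_dec%d_W", v, l)]],
         b = params[[sprintf("sae%d_dec%d_b", v, l)]]))
  list(enc = enc, dec = dec, dims = dims)
}

.gcn_from_flat <- function(params, v, nlayer, epsilon) {
  list(W = lapply(seq_len(nlayer), function(l)
         params[[sprintf("gcn%d_W%d", v, l)]]),
       epsilon = epsilon)
}

# SAE and GCN weights are drawn from independent seed-derived streams so
# that every ablation mode sees the identical branch initialization
# (common random numbers: mode comparisons are not confounded by init).
.init_params <- function(arch, seed) {
  p <- list()
  if (arch$mode != "gcn_only") {
    set.seed(seed)
    for (v in seq_len(arch$V)) {
      sae <- init_sae(arch$m[v], arch$encoder_dims)
      for (l in seq_len(arch$L)) {
        p[[sprintf("sae%d_enc%d_W", v, l)]] <- sae$enc[[l]]$W
        p[[sprintf("sae%d_enc%d_b", v, l)]] <- sae$enc[[l]]$b
        p[[sprintf("sae%d_dec%d_W", v, l)]] <- sae$dec[[l]]$W
        p[[sprintf("sae%d_dec%d_b", v, l)]] <- sae$dec[[l]]$b
      }
    }
  }
  if (arch$mode != "sae_only") {
    set.seed(seed + 1000003L)
    for (v in seq_len(arch$V)) {
      gcn <- init_gcn(arch$m[v], arch$encoder_dims, arch$c, arch$epsilon)
      for (l in seq_along(gcn$W))
        p[[sprintf("gcn%d_W%d", v, l)]] <- gcn$W[[l]]
    }
    p$W_fusion <- init_fusion_weights(arch$V, arch$c)
  }
  p
}

## ---- Adam ---------------------------------------------------------------
## Parameters are packed into one numeric vector inside the training loops
## so the moment updates are single vectorized expressions.

.flat_skeleton <- function(params) {
  lens <- vapply(params, length, 0L)
  list(names = names(params), dims = lapply(params, dim),
       lens = lens, ends = cumsum(lens))
}

.flatten <- function(params) unlist(params, use.names = FALSE)

.unflatten <- function(vec, sk) {
  out <- vector("list", length(sk$names))
  names(out) <- sk$names
  start <- 1L
  for (i in seq_along(out)) {
    x <- vec[start:sk$ends[i]]
    if (!is.null(sk$dims[[i]])) dim(x) <- sk$dims[[i]]
    out[[i]] <- x
    start <- sk$ends[i] + 1L
  }
  out
}

.adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

.adam_step <- function(theta, g, st, lr, wd,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  .adam_update_inplace(theta, g, st$m, st$v, lr, wd, beta1, beta2, eps, st$t)
  list(theta = theta, state = st)
}

## ---- forward / backward -------------------------------------------------

# Representations and soft assignments for the current parameters.
# data: list(X = list of N x m_v, A = list of N x N normalized adjacencies)
.smmsn_repr <- function(params, arch, data) {
  V <- arch$V; L <- arch$L
  fw <- list(sae = vector("list", V), gcn = vector("list", V),
             logits = vector("list", V))
  for (v in seq_len(V)) {
    if (arch$mode != "gcn_only")
      fw$sae[[v]] <- sae_forward(
        data$X[[v]],
        .sae_from_flat(params, v, L, c(arch$m[v], arch$encoder_dims)),
        slope = arch$slope)
    if (arch$mode != "sae_only") {
      latents <- if (arch$mode == "full") fw$sae[[v]]$latents else NULL
      g <- gcn_forward(data$A[[v]], data$X[[v]], latents,
                       .gcn_from_flat(params, v, L + 1L, arch$epsilon),
                       slope = arch$slope)
      fw$gcn[[v]] <- g
      fw$logits[[v]] <- g$logits
    }
  }
  if (arch$mode != "sae_only") {
    fw$Gc <- do.call(cbind, fw$logits)
    fw$G <- row_softmax(fw$Gc %*% params$W_fusion)
  }
  if (arch$mode != "gcn_only" && !is.null(params$Z_fused)) {
    fw$D2 <- sq_dist(params$Z_fused, params$mu)
    S <- (1 + fw$D2 / arch$dof)^(-(arch$dof + 1) / 2)
    fw$Q <- S / rowSums(S)
  }
  fw
}

.kl_safe <- function(P, R) {
  pos <- P > 0
  sum(P[pos] * log(P[pos] / pmax(R[pos], 1e-300)))
}

.smmsn_losses <- function(params, arch, data, fw, P, w) {
  N <- nrow(data$X[[1]])
  L_res <- if (arch$mode != "gcn_only")
    reconstruction_loss(data$X, lapply(fw$sae, `[[`, "xhat")) else 0
  L_fus <- if (arch$mode != "gcn_only")
    fusion_reconstruction_loss(params$Z_fused,
                               lapply(fw$sae, function(s) s$latents[[arch$L]]))
    else 0
  L_clu <- if (arch$mode != "gcn_only") .kl_safe(P, fw$Q) else 0
  L_gcn <- if (arch$mode != "sae_only") .kl_safe(P, fw$G) else 0
  parts <- list(L_res = L_res, L_fus = L_fus, L_clu = L_clu, L_gcn = L_gcn)
  parts$total <- total_loss(parts, w)
  parts
}

.zeros_like <- function(params) lapply(params, function(x) x * 0)

.smmsn_backward <- function(params, arch, data, fw, P, w) {
  V <- arch$V; L <- arch$L; N <- nrow(data$X[[1]])
  slope <- arch$slope
  gr <- .zeros_like(params)
  dLogits <- vector("list", V)

  if (arch$mode != "sae_only") {
    dMf <- w$lambda3 * (fw$G - P)            # KL through row softmax
    gr$W_fusion <- crossprod(fw$Gc, dMf)
    dGc <- dMf %*% t(params$W_fusion)
    cc <- arch$c
    for (v in seq_len(V))
      dLogits[[v]] <- dGc[, ((v - 1L) * cc + 1L):(v * cc), drop = FALSE]
  }

  if (arch$mode != "gcn_only") {
    # Student-t clustering KL (targets P are constants)
    Wt <- (P - fw$Q) / (arch$dof + fw$D2)
    coef <- w$lambda2 * (arch$dof + 1)
    gr$Z_fused <- coef * (rowSums(Wt) * params$Z_fused - Wt %*% params$mu)
    gr$mu <- -coef * (crossprod(Wt, params$Z_fused) -
                        colSums(Wt) * params$mu)
    # fusion-consensus loss
    Zsum <- Reduce(`+`, lapply(fw$sae, function(s) s$latents[[L]]))
    gr$Z_fused <- gr$Z_fused + w$lambda1 * 2 * (V * params$Z_fused - Zsum)
  }

  for (v in seq_len(V)) {
    dZacc <- NULL
    if (arch$mode != "gcn_only")
      dZacc <- lapply(fw$sae[[v]]$latents, function(z) z * 0)

    if (arch$mode != "sae_only") {
      gc <- fw$gcn[[v]]$cache
      eps <- gc$eps
      nlayer <- L + 1L
      dU <- dLogits[[v]]                     # final layer is linear
      gr[[sprintf("gcn%d_W%d", v, nlayer)]] <-
        crossprod(gc$AH[[nlayer]], dU)
      dH <- data$A[[v]] %*% (dU %*% t(params[[sprintf("gcn%d_W%d", v, nlayer)]]))
      dG <- (1 - eps) * dH
      if (!is.null(dZacc)) dZacc[[L]] <- dZacc[[L]] + eps * dH
      for (l in rev(seq_len(L))) {
        dU <- dG * leaky_relu_grad(gc$pre[[l]], slope)
        gr[[sprintf("gcn%d_W%d", v, l)]] <- crossprod(gc$AH[[l]], dU)
        if (l > 1L) {
          dH <- data$A[[v]] %*% (dU %*% t(params[[sprintf("gcn%d_W%d", v, l)]]))
          dG <- (1 - eps) * dH
          if (!is.null(dZacc)) dZacc[[l - 1L]] <- dZacc[[l - 1L]] + eps * dH
        }
      }
    }

    if (arch$mode != "gcn_only") {
      sc <- fw$sae[[v]]$cache
      # latent receives the fusion-consensus pull toward Z_fused
      dZacc[[L]] <- dZacc[[L]] +
        w$lambda1 * 2 * (fw$sae[[v]]$latents[[L]] - params$Z_fused)
      # decoder chain
      dD <- (fw$sae[[v]]$xhat - data$X[[v]]) / N
      for (k in rev(seq_len(L))) {
        dU <- dD * leaky_relu_grad(sc$pre_d[[k]], slope)
        gr[[sprintf("sae%d_dec%d_W", v, k)]] <- crossprod(sc$dec_in[[k]], dU)
        gr[[sprintf("sae%d_dec%d_b", v, k)]] <- colSums(dU)
        dD <- dU %*% t(params[[sprintf("sae%d_dec%d_W", v, k)]])
      }
      dZacc[[L]] <- dZacc[[L]] + dD
      # encoder chain
      dZ <- dZacc[[L]]
      for (l in rev(seq_len(L))) {
        dU <- dZ * leaky_relu_grad(sc$pre_e[[l]], slope)
        below <- if (l == 1L) data$X[[v]] else fw$sae[[v]]$latents[[l - 1L]]
        gr[[sprintf("sae%d_enc%d_W", v, l)]] <- crossprod(below, dU)
        gr[[sprintf("sae%d_enc%d_b", v, l)]] <- colSums(dU)
        if (l > 1L)
          dZ <- dU %*% t(params[[sprintf("sae%d_enc%d_W", v, l)]]) +
            dZacc[[l - 1L]]
      }
    }
  }
  gr
}

# reconstruction-only gradients for SAE pretraining
.pretrain_backward <- function(params, arch, data, fw) {
  w0 <- list(lambda1 = 0, lambda2 = 0, lambda3 = 0)
  mode_save <- arch$mode
  arch$mode <- "sae_only"
  gr <- .zeros_like(params[grep("^sae", names(params), value = TRUE)])
  N <- nrow(data$X[[1]]); L <- arch$L; slope <- arch$slope
  for (v in seq_len(arch$V)) {
    sc <- fw$sae[[v]]$cache
    dD <- (fw$sae[[v]]$xhat - data$X[[v]]) / N
    for (k in rev(seq_len(L))) {
      dU <- dD * leaky_relu_grad(sc$pre_d[[k]], slope)
      gr[[sprintf("sae%d_dec%d_W", v, k)]] <- crossprod(sc$dec_in[[k]], dU)
      gr[[sprintf("sae%d_dec%d_b", v, k)]] <- colSums(dU)
      dD <- dU %*% t(params[[sprintf("sae%d_dec%d_W", v, k)]])
    }
    dZ <- dD
    for (l in rev(seq_len(L))) {
      dU <- dZ * leaky_relu_grad(sc$pre_e[[l]], slope)
      below <- if (l == 1L) data$X[[v]] else fw$sae[[v]]$latents[[l - 1L]]
      gr[[sprintf("sae%d_enc%d_W", v, l)]] <- crossprod(below, dU)
      gr[[sprintf("sae%d_enc%d_b", v, l)]] <- colSums(dU)
      if (l > 1L)
        dZ <- dU %*% t(params[[sprintf("sae%d_enc%d_W", v, l)]])
    }
  }
  arch$mode <- mode_save
  gr
}

.row_dev <- function(M) if (is.null(M)) NA_real_ else max(abs(rowSums(M) - 1))

## ---- main entry ---------------------------------------------------------

#' Train the full multi-omics clustering model
#'
#' Runs the complete procedure: (1) reconstruction-only pretraining of the
#' per-view stacked autoencoders; (2) initialization of the consensus
#' latent `Z_fused` (elementwise mean of the per-view latents) and of the
#' cluster centers (K-means on `Z_fused`); (3) joint full-batch Adam
#' training of every parameter under the combined objective, with the
#' target distribution P refreshed (and detached) every
#' `p_update_interval` epochs; (4) hard labels from the final fused
#' probability matrix. Fully deterministic for a fixed config and seed.
#'
#' In `"sae_only"` mode the GCN branch and adaptive fusion are disabled and
#' labels come from the Student-t assignment Q; in `"gcn_only"` mode the
#' SAE branch is disabled, the GCN runs without injection, and P is built
#' from G itself (single self-supervision).
#'
#' @param views list of preprocessed [omics_view()]s with identical ordered
#'   samples (see [preprocess_omics()]).
#' @param graphs matching list of `SimilarityGraph`s.
#' @param cfg a [train_config()].
#' @param w a [loss_weights()].
#' @param truth optional named integer vector of ground-truth labels; when
#'   supplied, mapped clustering accuracy is computed.
#' @return a `ClusteringResult`: list with `labels` (named, 0-based),
#'   `loss_trace` (per-epoch data frame incl. row-sum deviations of Q, P,
#'   G), `pretrain_trace`, `acc` (or `NULL`), `config`, `weights`, and
#'   `model` (flat parameter list plus architecture, for checkpointing).
#' @export
train_smmsn <- function(views, graphs, cfg, w = loss_weights(), truth = NULL) {
  stopifnot(inherits(cfg, "TrainConfig"))
  mode <- cfg$ablation_mode
  if (mode == "gcn_only" && w$lambda2 > 0)
    stop("gcn_only ablation has no Student-t branch: lambda2 must be 0",
         call. = FALSE)
  V <- length(views)
  stopifnot(V >= 1, length(graphs) == V)
  samples <- views[[1]]$samples
  for (v in views)
    if (!identical(v$samples, samples))
      stop("views must share an identical ordered sample set", call. = FALSE)
  N <- length(samples)
  if (N < cfg$n_clusters) stop("fewer samples than clusters", call. = FALSE)

  data <- list(X = lapply(views, function(v) unname(v$X)),
               A = lapply(graphs, function(g) unname(g$A_norm)))
  arch <- list(V = V, L = length(cfg$encoder_dims),
               m = vapply(data$X, ncol, 0L),
               c = cfg$n_clusters, d = cfg$encoder_dims[length(cfg$encoder_dims)],
               encoder_dims = cfg$encoder_dims, epsilon = cfg$epsilon,
               slope = cfg$leaky_slope, dof = cfg$dof, mode = mode)

  params <- .init_params(arch, cfg$seed)

  # (1) reconstruction-only SAE pretraining
  pretrain_trace <- numeric(0)
  if (mode != "gcn_only" && cfg$pretrain_epochs > 0) {
    sae_names <- grep("^sae", names(params), value = TRUE)
    sk <- .flat_skeleton(params[sae_names])
    theta <- .flatten(params[sae_names])
    st <- .adam_init(length(theta))
    for (e in seq_len(cfg$pretrain_epochs)) {
      fw <- .smmsn_repr(params, modifyList(arch, list(mode = "sae_only")), data)
      pretrain_trace[e] <- reconstruction_loss(data$X,
                                               lapply(fw$sae, `[[`, "xhat"))
      gr <- .pretrain_backward(params, arch, data, fw)
      up <- .adam_step(theta, .flatten(gr), st,
                       cfg$pretrain_learning_rate, cfg$weight_decay)
      theta <- up$theta
      st <- up$state
      params[sae_names] <- .unflatten(theta, sk)
    }
  }

  # (2) consensus latent and cluster centers
  head <- NULL
  if (mode != "gcn_only") {
    fw <- .smmsn_repr(params, modifyList(arch, list(mode = "sae_only")), data)
    lat <- lapply(fw$sae, function(s) s$latents[[arch$L]])
    params$Z_fused <- Reduce(`+`, lat) / V
    head <- init_centers(params$Z_fused, arch$c, seed = cfg$seed,
                         dof = cfg$dof)
    params$mu <- head$centers
  }

  # (3) joint training
  trace <- vector("list", cfg$epochs)
  sk <- .flat_skeleton(params)
  theta <- .flatten(params)
  st <- .adam_init(length(theta))
  P <- NULL
  for (e in seq_len(cfg$epochs)) {
    fw <- .smmsn_repr(params, arch, data)
    if (is.null(P) || (e - 1L) %% cfg$p_update_interval == 0L) {
      P <- if (mode == "gcn_only") target_distribution(fw$G)
           else target_distribution(fw$Q)
    }
    parts <- .smmsn_losses(params, arch, data, fw, P, w)
    trace[[e]] <- data.frame(epoch = e, L_res = parts$L_res,
                             L_fus = parts$L_fus, L_clu = parts$L_clu,
                             L_gcn = parts$L_gcn, total = parts$total,
                             q_rowdev = .row_dev(fw$Q),
                             p_rowdev = .row_dev(P),
                             g_rowdev = .row_dev(fw$G))
    if (cfg$verbose > 0 && e %% cfg$verbose == 0)
      message(sprintf("epoch %4d  total %.5f  (res %.4f fus %.4f clu %.4f gcn %.4f)",
                      e, parts$total, parts$L_res, parts$L_fus,
                      parts$L_clu, parts$L_gcn))
    gr <- .smmsn_backward(params, arch, data, fw, P, w)
    up <- .adam_step(theta, .flatten(gr), st, cfg$learning_rate,
                     cfg$weight_decay)
    theta <- up$theta
    st <- up$state
    params <- .unflatten(theta, sk)
  }

  # (4) labels from the final representations
  fw <- .smmsn_repr(params, arch, data)
  G_final <- if (mode == "sae_only") fw$Q else fw$G
  rownames(G_final) <- samples
  labels <- assign_labels(G_final)

  acc <- NULL
  if (!is.null(truth)) {
    truth <- truth[samples]
    acc <- clustering_accuracy(truth, labels)
  }

  structure(list(labels = labels,
                 probabilities = G_final,
                 acc = acc,
                 loss_trace = do.call(rbind, trace),
                 pretrain_trace = pretrain_trace,
                 config = cfg, weights = w,
                 model = list(params = params, arch = arch,
                              samples = samples)),
            class = "ClusteringResult")
}

#' @export
print.ClusteringResult <- function(x, ...) {
  cat(sprintf("ClusteringResult: %d samples, %d clusters (%s mode)\n",
              length(x$labels), x$config$n_clusters,
              x$config$ablation_mode))
  cat("cluster sizes:", paste(table(x$labels), collapse = " / "), "\n")
  if (!is.null(x$acc)) cat(sprintf("mapped ACC: %.4f\n", x$acc))
  invisible(x)
}

#' Save / load a trained model checkpoint
#'
#' Serializes the flat parameter list, architecture and sample IDs.
#'
#' @param result a `ClusteringResult` from [train_smmsn()].
#' @param path checkpoint file path.
#' @export
save_checkpoint <- function(result, path) {
  saveRDS(result$model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
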