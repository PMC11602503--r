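## Dual self-supervised objective: Student-t soft assignments, sharpened
## target distribution, KL losses, cluster-center initialization.

#' Student-t soft cluster assignment
#'
#' `q_ij = (1 + ||z_i - mu_j||^2 / dof)^(-(dof+1)/2)`, row-normalized: the
#' probability that sample i belongs to center j under a Student-t kernel
#' (the standard deep-embedded-clustering similarity, dof = 1 by default).
#'
#' @param Z N x d latent matrix.
#' @param centers c x d matrix of cluster centers, c >= 2.
#' @param dof degrees of freedom of the kernel (positive).
#' @return row-stochastic N x c matrix Q.
#' @export
soft_assignment <- function(Z, centers, dof = 1) {
  if (nrow(centers) < 2L)
    stop("soft assignment needs at least 2 cluster centers", call. = FALSE)
  stopifnot(ncol(Z) == ncol(centers), dof > 0)
  D2 <- sq_dist(Z, centers)
  S <- (1 + D2 / dof)^(-(dof + 1) / 2)
  S / rowSums(S)
}

# pairwise squared Euclidean distances between rows of A (n x d) and B (c x d)
sq_dist <- function(A, B) {
  D2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  pmax(D2, 0)
}

#' Sharpened target distribution
#'
#' `p_ij = (q_ij^2 / f_j) / sum_j' (q_ij'^2 / f_j')` with soft cluster
#' frequencies `f_j = sum_i q_ij`. Squaring raises the confidence of
#' assignments while the frequency normalization prevents large clusters
#' from absorbing everything; P is the self-supervision target.
#'
#' @param Q row-stochastic N x c matrix of soft assignments.
#' @return row-stochastic N x c matrix P.
#' @export
target_distribution <- function(Q) {
  f <- colSums(Q)
  if (any(f == 0))
    stop("empty soft cluster: column(s) ", paste(which(f == 0), collapse = ", "),
         " of Q sum to zero", call. = FALSE)
  W <- sweep(Q^2, 2L, f, "/")
  W / rowSums(W)
}

#' Kullback-Leibler divergence between row-stochastic matrices
#'
#' `sum_ij p_ij log(p_ij / r_ij)`, with `0 * log(0 / r) = 0`. Nonnegative,
#' and zero iff the matrices are equal.
#'
#' @param P,R row-stochastic matrices of identical shape.
#' @return nonnegative scalar.
#' @export
kl_divergence <- function(P, R) {
  if (!identical(dim(P), dim(R)))
    stop("P and R must have identical shape", call. = FALSE)
  pos <- P > 0
  if (any(R[pos] == 0))
    stop("infinite divergence: r_ij = 0 where p_ij > 0", call. = FALSE)
  sum(P[pos] * log(P[pos] / R[pos]))
}

#' Combined training objective
#'
#' `L = L_res + lambda1 * L_fus + lambda2 * L_clu + lambda3 * L_gcn`:
#' reconstruction, fusion-consensus, Student-t clustering KL, and GCN
#' classification KL parts balanced by the loss weights.
#'
#' @param parts named list or vector with elements `L_res`, `L_fus`,
#'   `L_clu`, `L_gcn`.
#' @param w a [loss_weights()].
#' @return scalar total loss.
#' @export
total_loss <- function(parts, w = loss_weights()) {
  parts <- unlist(parts)
  needed <- c("L_res", "L_fus", "L_clu", "L_gcn")
  bad <- needed[!is.finite(parts[needed])]
  if (length(bad))
    stop("non-finite loss part(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  unname(parts["L_res"] + w$lambda1 * parts["L_fus"] +
           w$lambda2 * parts["L_clu"] + w$lambda3 * parts["L_gcn"])
}

#' Loss-balancing weights
#'
#' The source method leaves the three balance hyperparameters unspecified;
#' the defaults (1, 0.1, 0.01) follow common deep-clustering practice of
#' keeping reconstruction dominant and the KL terms as gentle guides, and
#' should be revisited per dataset.
#'
#' @param lambda1 weight of the fusion-consensus loss.
#' @param lambda2 weight of the Student-t clustering KL.
#' @param lambda3 weight of the GCN classification KL.
#' @return a `LossWeights` list.
#' @export
loss_weights <- function(lambda1 = 1.0, lambda2 = 0.1, lambda3 = 0.01) {
  stopifnot(lambda1 >= 0, lambda2 >= 0, lambda3 >= 0)
  if (lambda1 == 0 && lambda2 == 0 && lambda3 == 0)
    stop("at least one loss weight must be positive", call. = FALSE)
  structure(list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3),
            class = "LossWeights")
}

#' Initialize cluster centers by K-means on the fused latent
#'
#' @param Z N x d latent matrix.
#' @param c number of clusters (2 <= c <= N).
#' @param seed RNG seed; identical seeds give identical centers.
#' @param dof Student-t degrees of freedom stored in the head.
#' @return a `ClusterHead` list with `centers` (c x d) and `dof`.
#' @export
init_centers <- function(Z, c, seed = 1L, dof = 1) {
  if (nrow(Z) < c)
    stop("need at least as many samples as clusters", call. = FALSE)
  set.seed(seed)
  km <- stats::kmeans(Z, centers = c, nstart = 20L, iter.max = 100L)
  structure(list(centers = unname(km$centers), dof = dof),
            class = "ClusterHead")
}

#' Hard labels from a probability matrix
#'
#' `y_i = argmax_j g_ij`, ties broken toward the lowest column index.
#' Labels are 0-based cluster ids (0 .. c-1), the usual deep-clustering
#' convention, so they can be compared directly with generator labels.
#'
#' @param G row-stochastic N x c matrix (rows sum to 1).
#' @return integer vector of length N, named by G's row names if present.
#' @export
assign_labels <- function(G) {
  labs <- max.col(G, ties.method = "first") - 1L
  names(labs) <- rownames(G)
  labs
}
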