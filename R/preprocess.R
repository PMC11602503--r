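#' Preprocessing configuration
#'
#' Controls the missingness filters, feature standardization and
#' patient-similarity KNN graph construction.
#'
#' @param patient_missing_threshold drop a sample when its fraction of
#'   missing entries in a view strictly exceeds this (default 0.20).
#' @param feature_missing_threshold drop a feature when its missing fraction
#'   over the remaining samples strictly exceeds this (default 0.20).
#' @param k_neighbors K for the KNN graph (default 40; clamped to N-1).
#' @param sigma_mode heat-kernel bandwidth: `"median_sq_dist"` (median of
#'   pairwise squared Euclidean distances, the default) or `"fixed"`.
#' @param sigma_value bandwidth used when `sigma_mode = "fixed"`.
#' @return a `PreprocessConfig` list.
#' @export
preprocess_config <- function(patient_missing_threshold = 0.20,
                              feature_missing_threshold = 0.20,
                              k_neighbors = 40L,
                              sigma_mode = c("median_sq_dist", "fixed"),
                              sigma_value = NULL) {
  sigma_mode <- match.arg(sigma_mode)
  stopifnot(patient_missing_threshold > 0, patient_missing_threshold < 1,
            feature_missing_threshold > 0, feature_missing_threshold < 1,
            k_neighbors >= 1)
  if (sigma_mode == "fixed") {
    if (is.null(sigma_value) || sigma_value <= 0)
      stop("sigma_value must be a positive real when sigma_mode = 'fixed'",
           call. = FALSE)
  }
  structure(list(patient_missing_threshold = patient_missing_threshold,
                 feature_missing_threshold = feature_missing_threshold,
                 k_neighbors = as.integer(k_neighbors),
                 sigma_mode = sigma_mode,
                 sigma_value = sigma_value),
            class = "PreprocessConfig")
}

#' Filter missing entries from a view
#'
#' Samples whose missing fraction strictly exceeds the patient threshold are
#' removed first; then features whose missing fraction over the remaining
#' samples strictly exceeds the feature threshold. Residual missing entries
#' are imputed with the feature's mean over observed values. Idempotent.
#'
#' @param view an [omics_view()], possibly containing `NA` entries.
#' @param cfg a [preprocess_config()].
#' @return filtered [omics_view()] with attributes `dropped_samples` and
#'   `dropped_features` listing removed IDs.
#' @export
filter_missing <- function(view, cfg = preprocess_config()) {
  X <- view$X
  miss <- is.na(X)
  keep_s <- rowMeans(miss) <= cfg$patient_missing_threshold
  if (!any(keep_s))
    stop("all samples removed by missingness filter in view '", view$name, "'",
         call. = FALSE)
  X <- X[keep_s, , drop = FALSE]
  miss <- miss[keep_s, , drop = FALSE]
  keep_f <- colMeans(miss) <= cfg$feature_missing_threshold
  if (!any(keep_f))
    stop("all features removed by missingness filter in view '", view$name, "'",
         call. = FALSE)
  X <- X[, keep_f, drop = FALSE]
  # residual gaps: per-feature mean over observed values
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2]]
  }
  out <- omics_view(X, name = view$name)
  attr(out, "dropped_samples") <- view$samples[!keep_s]
  attr(out, "dropped_features") <- view$features[!keep_f]
  out
}

#' Standardize features of a view
#'
#' Centers every feature to mean zero and scales it to unit spread, using
#' the population standard deviation (divisor N). The normalization formula
#' is printed in the source method with Var(f) in the denominator; unit-
#' spread scaling is the standard reading and is what is implemented here
#' (dividing by the variance would leave features on incomparable scales).
#' Zero-variance features cannot be scaled and are dropped with a warning.
#'
#' @param view an [omics_view()] with no missing values.
#' @return standardized [omics_view()]; attribute `dropped_features` lists
#'   any constant features removed.
#' @export
normalize_features <- function(view) {
  X <- view$X
  if (anyNA(X))
    stop("normalize_features requires a view without missing values",
         call. = FALSE)
  n <- nrow(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  pop_sd <- sqrt(colSums(Xc^2) / n)
  keep <- pop_sd > 0
  if (!all(keep)) {
    warning(sum(!keep), " zero-variance feature(s) dropped in view '",
            view$name, "'", call. = FALSE)
    Xc <- Xc[, keep, drop = FALSE]
    pop_sd <- pop_sd[keep]
  }
  if (ncol(Xc) == 0L)
    stop("no features left after dropping constant columns in view '",
         view$name, "'", call. = FALSE)
  out <- omics_view(sweep(Xc, 2L, pop_sd, "/"), name = view$name)
  attr(out, "dropped_features") <- view$features[!keep]
  out
}

#' Heat-kernel patient similarity
#'
#' Pairwise similarity S\[i,j\] = exp(-||x_i - x_j||^2 / sigma) between
#' sample profiles of one view. With the default `sigma_mode =
#' "median_sq_dist"` the bandwidth is the median of the off-diagonal
#' pairwise squared Euclidean distances.
#'
#' @param view a standardized [omics_view()].
#' @param cfg a [preprocess_config()].
#' @return symmetric N x N similarity matrix with unit diagonal and entries
#'   in (0, 1]; the resolved bandwidth is attached as attribute `sigma`.
#' @export
heat_kernel_similarity <- function(view, cfg = preprocess_config()) {
  X <- view$X
  if (anyNA(X)) stop("view contains missing values", call. = FALSE)
  D2 <- as.matrix(stats::dist(X))^2
  sigma <- switch(cfg$sigma_mode,
    median_sq_dist = stats::median(D2[upper.tri(D2)]),
    fixed = cfg$sigma_value)
  if (!is.finite(sigma) || sigma <= 0)
    stop("heat-kernel bandwidth must be positive (got ", sigma, ")",
         call. = FALSE)
  S <- exp(-D2 / sigma)
  diag(S) <- 1
  dimnames(S) <- list(view$samples, view$samples)
  attr(S, "sigma") <- sigma
  S
}

#' Build a KNN patient-similarity graph
#'
#' Each sample selects its K most similar other samples (self excluded) as
#' directed neighbors; the binary adjacency is then symmetrized by union
#' (an edge is kept if either endpoint selected the other). Self-loops are
#' added only inside the normalized operator, via A + I.
#'
#' @param S symmetric similarity matrix with unit diagonal (see
#'   [heat_kernel_similarity()]).
#' @param cfg a [preprocess_config()]; `k_neighbors` is clamped to N-1 with
#'   a warning when it is too large.
#' @return a `SimilarityGraph`: list with the similarity `S`, binary
#'   symmetric adjacency `A` (zero diagonal), normalized operator `A_norm`
#'   = D^-1/2 (A + I) D^-1/2, and the `k` actually used.
#' @export
build_knn_graph <- function(S, cfg = preprocess_config()) {
  n <- nrow(S)
  if (n < 2L) stop("need at least 2 samples to build a KNN graph", call. = FALSE)
  k <- cfg$k_neighbors
  if (k >= n) {
    warning("k_neighbors = ", k, " >= N = ", n, "; clamped to N-1 = ", n - 1L,
            call. = FALSE)
    k <- n - 1L
  }
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- S[i, ]
    s[i] <- -Inf                         # self excluded
    nb <- order(s, decreasing = TRUE)[seq_len(k)]
    A[i, nb] <- 1
  }
  A <- pmax(A, t(A))                     # union symmetrization
  dimnames(A) <- dimnames(S)
  structure(list(S = S, A = A, A_norm = normalize_adjacency(A), k = k),
            class = "SimilarityGraph")
}

#' @export
print.SimilarityGraph <- function(x, ...) {
  cat(sprintf("SimilarityGraph: %d nodes, %d undirected edges, k = %d\n",
              nrow(x$A), sum(x$A) / 2, x$k))
  invisible(x)
}

#' Symmetric normalization of a graph adjacency
#'
#' Returns D^-1/2 (A + I) D^-1/2 where D is the degree matrix of A + I, the
#' standard graph-convolution operator; the added identity keeps every
#' node's self-connection so isolated nodes map to themselves.
#'
#' @param A binary symmetric adjacency with zero diagonal.
#' @return symmetric nonnegative matrix of the same dimension.
#' @export
normalize_adjacency <- function(A) {
  if (nrow(A) != ncol(A) || any(A != t(A)))
    stop("A must be a symmetric square matrix", call. = FALSE)
  Ahat <- A + diag(nrow(A))
  dinv <- 1 / sqrt(rowSums(Ahat))
  out <- Ahat * outer(dinv, dinv)
  dimnames(out) <- dimnames(A)
  out
}

#' Preprocess a multi-view omics dataset
#'
#' Full per-view pipeline: missingness filters, alignment to the common
#' sample set (ordered as in the first view), feature standardization, and
#' heat-kernel KNN graph construction.
#'
#' @param views list of [omics_view()] objects (raw, may contain `NA`).
#' @param cfg a [preprocess_config()].
#' @return list with `views` (clean, aligned `OmicsView`s), `graphs`
#'   (matching `SimilarityGraph`s), `samples` (common ordered IDs) and
#'   `report` (per-view dropped IDs, final sizes, resolved bandwidths).
#' @export
preprocess_omics <- function(views, cfg = preprocess_config()) {
  stopifnot(length(views) >= 1)
  if (is.null(names(views)) || any(names(views) == ""))
    names(views) <- vapply(views, function(v) v$name, character(1))
  filtered <- lapply(views, filter_missing, cfg = cfg)
  common <- Reduce(intersect, lapply(filtered, function(v) v$samples))
  if (length(common) < 2L)
    stop("fewer than 2 samples shared by all views after filtering",
         call. = FALSE)
  aligned <- lapply(filtered, function(v)
    omics_view(v$X[common, , drop = FALSE], name = v$name))
  normed <- lapply(aligned, normalize_features)
  sims <- lapply(normed, heat_kernel_similarity, cfg = cfg)
  graphs <- lapply(sims, build_knn_graph, cfg = cfg)
  report <- list(
    n_samples = length(common),
    views = lapply(seq_along(views), function(i) list(
      name = views[[i]]$name,
      n_features = ncol(normed[[i]]$X),
      dropped_samples = as.character(attr(filtered[[i]], "dropped_samples")),
      dropped_features = as.character(c(attr(filtered[[i]], "dropped_features"),
                                        attr(normed[[i]], "dropped_features"))),
      sigma = attr(sims[[i]], "sigma"),
      k = graphs[[i]]$k))
  )
  names(report$views) <- names(views)
  list(views = normed, graphs = graphs, samples = common, report = report)
}

#' Write a preprocessing report as JSON
#'
#' @param report the `report` element of [preprocess_omics()] output.
#' @param path output path.
#' @export
write_preprocess_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
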