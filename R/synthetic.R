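#' Specification of a synthetic multi-omics dataset
#'
#' The generator draws cluster labels from mixing proportions, places one
#' center per cluster in a shared latent space (pairwise center distance
#' scaled by `separation`, within-cluster spread fixed at 1), and maps each
#' sample's latent point into every view through a view-specific random
#' linear map plus Gaussian noise. All views therefore observe the same
#' cluster geometry, which is the structural assumption of the model.
#'
#' @param n_samples number of samples N.
#' @param n_clusters number of clusters c.
#' @param n_views number of omics views V.
#' @param dims integer vector of length V: features per view.
#' @param separation mean pairwise distance between latent cluster centers,
#'   in units of the within-cluster standard deviation; 0 means no cluster
#'   structure at all.
#' @param noise_sd standard deviation of the additive per-view noise.
#' @param missing_rate fraction of entries blanked to `NA` per view.
#' @param seed RNG seed; the output is bitwise reproducible.
#' @param mixing cluster proportions (default balanced); must sum to 1.
#' @return a `SyntheticSpec` list.
#' @export
synthetic_spec <- function(n_samples, n_clusters, n_views, dims,
                           separation = 5, noise_sd = 1, missing_rate = 0,
                           seed = 1L, mixing = NULL) {
  if (is.null(mixing)) mixing <- rep(1 / n_clusters, n_clusters)
  stopifnot(length(dims) == n_views,
            length(mixing) == n_clusters,
            abs(sum(mixing) - 1) < 1e-8,
            separation >= 0, noise_sd > 0,
            missing_rate >= 0, missing_rate < 1)
  if (n_clusters > n_samples)
    stop("n_clusters must not exceed n_samples", call. = FALSE)
  structure(list(n_samples = as.integer(n_samples),
                 n_clusters = as.integer(n_clusters),
                 n_views = as.integer(n_views),
                 dims = as.integer(dims),
                 separation = separation, noise_sd = noise_sd,
                 missing_rate = missing_rate, seed = as.integer(seed),
                 mixing = mixing),
            class = "SyntheticSpec")
}

#' Generate a synthetic multi-omics dataset with known cluster structure
#'
#' @param spec a [synthetic_spec()].
#' @return list with `views` (list of [omics_view()] with aligned sample
#'   IDs) and `labels` (named integer vector, clusters `0..c-1`).
#' @export
generate_multiomics <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  set.seed(spec$seed)
  N <- spec$n_samples; c <- spec$n_clusters; V <- spec$n_views
  # exact counts from the mixing proportions (balanced => equal blocks)
  counts <- diff(round(cumsum(c(0, spec$mixing)) * N))
  counts[c] <- counts[c] + (N - sum(counts))   # rounding remainder
  labels <- rep.int(seq_len(c) - 1L, counts)
  samples <- sprintf("S%04d", seq_len(N))
  names(labels) <- samples

  q <- c + 2L                                   # latent space dimension
  centers <- matrix(rnorm(c * q), c, q)
  centers <- sweep(centers, 2L, colMeans(centers))
  if (c > 1L) {
    pd <- stats::dist(centers)
    scale <- if (mean(pd) > 0) spec$separation / mean(pd) else 0
    centers <- centers * scale
  } else centers[] <- 0
  latent <- centers[labels + 1L, , drop = FALSE] +
    matrix(rnorm(N * q), N, q)

  views <- vector("list", V)
  for (v in seq_len(V)) {
    m <- spec$dims[v]
    map <- matrix(rnorm(q * m, sd = 1 / sqrt(q)), q, m)
    X <- latent %*% map + matrix(rnorm(N * m, sd = spec$noise_sd), N, m)
    if (spec$missing_rate > 0) {
      blank <- runif(length(X)) < spec$missing_rate
      X[blank] <- NA_real_
    }
    dimnames(X) <- list(samples, sprintf("V%d_F%04d", v, seq_len(m)))
    views[[v]] <- omics_view(X, name = sprintf("view%d", v))
  }
  names(views) <- vapply(views, function(v) v$name, character(1))
  list(views = views, labels = labels)
}

#' Named catalog of benchmark synthetic fixtures
#'
#' Three standing datasets used throughout the test-suite and examples:
#' \describe{
#'   \item{easy3}{N = 150, V = 2, c = 3, well separated - any reasonable
#'     method should recover the partition essentially perfectly.}
#'   \item{noisy4}{N = 200, V = 3, c = 4, moderate separation and strong
#'     noise - hard enough that naive clustering is clearly below 1.}
#'   \item{null2}{N = 120, V = 2, c = 2, zero separation - no structure,
#'     so any method should sit at chance level.}
#' }
#'
#' @param seed seed stored in each spec (override per draw as needed).
#' @return named list of [synthetic_spec()] objects.
#' @export
fixture_catalog <- function(seed = 1L) {
  list(
    easy3 = synthetic_spec(n_samples = 150, n_clusters = 3, n_views = 2,
                           dims = c(60L, 40L), separation = 8, noise_sd = 1,
                           seed = seed),
    noisy4 = synthetic_spec(n_samples = 200, n_clusters = 4, n_views = 3,
                            dims = c(80L, 60L, 40L), separation = 3,
                            noise_sd = 2, seed = seed),
    null2 = synthetic_spec(n_samples = 120, n_clusters = 2, n_views = 2,
                           dims = c(50L, 30L), separation = 0, noise_sd = 1,
                           seed = seed)
  )
}

#' Write a synthetic dataset to disk
#'
#' One TSV per view (in the exact format [read_omics_view()] reads) plus a
#' `labels.tsv` ground-truth table.
#'
#' @param data output of [generate_multiomics()].
#' @param dir output directory (created if absent).
#' @return the directory path, invisibly.
#' @export
write_multiomics <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (v in data$views)
    write_omics_view(v, file.path(dir, paste0(v$name, ".tsv")))
  write_labels(data$labels, file.path(dir, "labels.tsv"))
  invisible(dir)
}
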