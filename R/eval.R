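#' Mapped clustering accuracy
#'
#' `ACC = (1/n) max_map sum_i 1[t_i = map(y_i)]`, the fraction of samples
#' whose predicted cluster matches the true class after the optimal
#' one-to-one relabeling of clusters to classes. The optimum is found by
#' maximum-weight bipartite matching (Hungarian/Kuhn-Munkres) on the
#' truth x prediction contingency table; when the numbers of clusters and
#' classes differ the table is implicitly padded with zero-count rows or
#' columns (unmatched clusters contribute nothing).
#'
#' @param truth,pred equal-length label vectors (any label coding); at most
#'   64 distinct values each.
#' @return accuracy in \[0, 1\].
#' @export
clustering_accuracy <- function(truth, pred) {
  if (length(truth) != length(pred))
    stop("truth and pred must have equal length", call. = FALSE)
  n <- length(truth)
  if (n < 1L) stop("empty label vectors", call. = FALSE)
  tf <- factor(truth); pf <- factor(pred)
  r <- nlevels(tf); c <- nlevels(pf)
  if (r > 64L || c > 64L)
    stop("more than 64 distinct labels", call. = FALSE)
  tab <- table(tf, pf)
  idx <- which(tab > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(0)
  # bipartite graph: truth classes 1..r, predicted clusters r+1..r+c
  edges <- rbind(idx[, 1L], r + idx[, 2L])
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, r), rep(TRUE, c)),
    edges = as.vector(edges))
  m <- igraph::max_bipartite_match(g, weights = tab[idx])
  m$matching_weight / n
}

# entropy-normalized mutual information (diagnostic companion to ACC)
.nmi <- function(truth, pred) {
  tab <- table(truth, pred)
  n <- sum(tab)
  pj <- rowSums(tab) / n; pk <- colSums(tab) / n
  pij <- tab / n
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pj, pk)[nz]))
  ht <- -sum(pj[pj > 0] * log(pj[pj > 0]))
  hp <- -sum(pk[pk > 0] * log(pk[pk > 0]))
  if (ht == 0 || hp == 0) return(as.numeric(ht == hp))
  mi / sqrt(ht * hp)
}

#' Evaluate a clustering result against ground truth
#'
#' Aligns predicted and true labels by sample ID and reports mapped
#' clustering accuracy (the headline metric) together with the adjusted
#' Rand index and normalized mutual information as diagnostics, plus an
#' echo of the resolved configuration.
#'
#' @param result a `ClusteringResult` from [train_smmsn()], or a named
#'   integer label vector.
#' @param truth named integer vector of true labels.
#' @return a `metrics` list: `acc`, `ari`, `nmi`, `n`, `config_echo`.
#' @export
evaluate_run <- function(result, truth) {
  pred <- if (inherits(result, "ClusteringResult")) result$labels else result
  if (is.null(names(pred)) || is.null(names(truth)))
    stop("labels must be named by sample ID", call. = FALSE)
  missing_ids <- setdiff(names(pred), names(truth))
  extra_ids <- setdiff(names(truth), names(pred))
  if (length(missing_ids) || length(extra_ids))
    stop("unmatched sample IDs; in pred only: ",
         paste(utils::head(missing_ids, 5), collapse = ", "),
         "; in truth only: ",
         paste(utils::head(extra_ids, 5), collapse = ", "), call. = FALSE)
  truth <- truth[names(pred)]
  out <- list(acc = clustering_accuracy(truth, pred),
              ari = mclust::adjustedRandIndex(truth, pred),
              nmi = .nmi(truth, pred),
              n = length(pred))
  if (inherits(result, "ClusteringResult"))
    out$config_echo <- list(n_clusters = result$config$n_clusters,
                            seed = result$config$seed,
                            ablation_mode = result$config$ablation_mode)
  out
}

#' Write a metrics report as JSON
#'
#' @param metrics output of [evaluate_run()] (or any list of scalars).
#' @param path output path.
#' @export
write_metrics <- function(metrics, path) {
  jsonlite::write_json(metrics, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
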