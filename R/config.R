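#' Read a structured run configuration from YAML
#'
#' Sections: `data` (`views`: named map of file paths; optional `truth`
#' path), `preprocess` (arguments of [preprocess_config()]), `networks`
#' (`encoder_dims`, `epsilon`, `leaky_slope`), `loss_weights` (`lambda1`,
#' `lambda2`, `lambda3`) and `train` (remaining [train_config()]
#' arguments, including the required `n_clusters`). Omitted fields take
#' the package defaults.
#'
#' @param path YAML file path.
#' @return list with `data`, `preprocess` ([preprocess_config()]),
#'   `train` ([train_config()]) and `weights` ([loss_weights()]).
#' @export
read_smmsn_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$train$n_clusters))
    stop("config must set train.n_clusters", call. = FALSE)
  pre <- do.call(preprocess_config, as.list(y$preprocess))
  w <- do.call(loss_weights, as.list(y$loss_weights))
  tr_args <- c(as.list(y$train), as.list(y$networks))
  if (!is.null(tr_args$encoder_dims))
    tr_args$encoder_dims <- as.integer(unlist(tr_args$encoder_dims))
  tr <- do.call(train_config, tr_args)
  list(data = y$data, preprocess = pre, train = tr, weights = w)
}

#' Run the full pipeline from a resolved configuration
#'
#' Reads the view matrices, preprocesses them, trains the model and writes
#' the standard outputs into `out_dir`: `labels.tsv`, `metrics.json` (when
#' ground truth is available), `loss_trace.csv`, `preprocess_report.json`
#' and `checkpoint.rds`.
#'
#' @param config output of [read_smmsn_config()], or an equivalent list.
#' @param out_dir output directory (created if absent).
#' @return the `ClusteringResult`, invisibly.
#' @export
smmsn_run <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  views <- lapply(names(config$data$views), function(nm)
    read_omics_view(config$data$views[[nm]], name = nm))
  pre <- preprocess_omics(views, config$preprocess)
  truth <- NULL
  if (!is.null(config$data$truth)) {
    truth <- read_labels(config$data$truth)
    truth <- truth[pre$samples]
  }
  res <- train_smmsn(pre$views, pre$graphs, config$train, config$weights,
                     truth = truth)
  write_labels(res$labels, file.path(out_dir, "labels.tsv"))
  utils::write.table(res$loss_trace, file.path(out_dir, "loss_trace.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  write_preprocess_report(pre$report,
                          file.path(out_dir, "preprocess_report.json"))
  save_checkpoint(res, file.path(out_dir, "checkpoint.rds"))
  if (!is.null(truth))
    write_metrics(evaluate_run(res, truth), file.path(out_dir, "metrics.json"))
  invisible(res)
}
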