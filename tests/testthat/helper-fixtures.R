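# Shared builders for the end-to-end benchmark runs. The benchmark network
# uses a shallower encoder (256 -> 100) than the package default so a full
# 200 + 500 epoch fit stays fast on one core; the latent width stays at
# the standard 100.

bench_config <- function(n_clusters, seed, mode = "full", ...) {
  train_config(n_clusters = n_clusters, seed = seed,
               encoder_dims = c(256L, 100L), ablation_mode = mode, ...)
}

run_catalog_fixture <- function(name, seed, mode = "full", ...) {
  spec <- fixture_catalog(seed = seed)[[name]]
  dat <- generate_multiomics(spec)
  pre <- preprocess_omics(dat$views)
  w <- if (mode == "gcn_only") loss_weights(lambda2 = 0) else loss_weights()
  cfg <- bench_config(spec$n_clusters, seed, mode, ...)
  train_smmsn(pre$views, pre$graphs, cfg, w, truth = dat$labels)
}

# small random multi-view problem for unit-level training tests
tiny_problem <- function(seed = 7L, N = 24L, V = 2L, c = 3L) {
  spec <- synthetic_spec(n_samples = N, n_clusters = c, n_views = V,
                         dims = rep(10L, V), separation = 6, noise_sd = 1,
                         seed = seed)
  dat <- generate_multiomics(spec)
  pre <- preprocess_omics(dat$views, preprocess_config(k_neighbors = 5))
  list(pre = pre, labels = dat$labels, c = c)
}
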