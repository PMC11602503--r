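# independent brute-force reimplementation of the missingness filters:
# scan every row, then every remaining column, against the strict thresholds
filter_oracle <- function(X, thr_s = 0.2, thr_f = 0.2) {
  keep_s <- rownames(X)[sapply(seq_len(nrow(X)), function(i)
    mean(is.na(X[i, ])) <= thr_s)]
  X2 <- X[keep_s, , drop = FALSE]
  keep_f <- colnames(X2)[sapply(seq_len(ncol(X2)), function(j)
    mean(is.na(X2[, j])) <= thr_f)]
  X2 <- X2[, keep_f, drop = FALSE]
  for (j in seq_len(ncol(X2))) {
    nas <- is.na(X2[, j])
    if (any(nas)) X2[nas, j] <- mean(X2[!nas, j])
  }
  X2
}

named_mat <- function(X) {
  dimnames(X) <- list(sprintf("s%02d", seq_len(nrow(X))),
                      sprintf("f%02d", seq_len(ncol(X))))
  X
}

test_that("missingness filters drop samples first, then features, strictly above 20%", {
  set.seed(11)
  # one sample with 3/10 missing (30%) in a 10x10 view
  X <- named_mat(matrix(rnorm(100), 10, 10))
  X[3, c(1, 5, 9)] <- NA
  out <- filter_missing(omics_view(X))
  expect_equal(attr(out, "dropped_samples"), "s03")
  expect_equal(out$samples, rownames(X)[-3])
  expect_equal(ncol(out$X), 10L)

  # a view without gaps is returned unchanged
  Y <- named_mat(matrix(rnorm(30), 5, 6))
  expect_equal(filter_missing(omics_view(Y))$X, Y, ignore_attr = TRUE)

  # the 5x4 configuration: one feature missing in 2/5 samples; with only 4
  # features those two samples are themselves over the 20% sample threshold,
  # so the oracle decides what survives
  Z <- named_mat(matrix(rnorm(20), 5, 4))
  Z[c(2, 4), 3] <- NA
  out <- filter_missing(omics_view(Z))
  expect_equal(out$X, filter_oracle(Z), ignore_attr = TRUE)
  expect_equal(attr(out, "dropped_samples"), c("s02", "s04"))
  expect_equal(length(attr(out, "dropped_features")), 0L)

  # wide variant where the intended feature-drop path actually fires:
  # 2/5 samples miss the same feature (40% > 20%) while each sample sits
  # at 1/10 = 10% missing
  W <- named_mat(matrix(rnorm(50), 5, 10))
  W[c(1, 5), 7] <- NA
  out <- filter_missing(omics_view(W))
  expect_equal(attr(out, "dropped_features"), "f07")
  expect_equal(out$X, filter_oracle(W), ignore_attr = TRUE)
})

test_that("missingness filtering matches the brute-force oracle and is idempotent", {
  set.seed(42)
  for (rep in 1:20) {
    X <- named_mat(matrix(rnorm(12 * 8), 12, 8))
    X[stats::runif(length(X)) < 0.15] <- NA
    out <- filter_missing(omics_view(X))
    expect_equal(out$X, filter_oracle(X), ignore_attr = TRUE)
    twice <- filter_missing(out)
    expect_identical(twice$X, out$X)
  }
  all_na <- named_mat(matrix(NA_real_, 3, 3))
  expect_error(filter_missing(omics_view(all_na, "bad")), "bad")
})

test_that("feature standardization centers and scales by the population sd", {
  X <- named_mat(cbind(c(1, 2, 3), c(10, 20, 60)))
  out <- normalize_features(omics_view(X))
  # column (1,2,3): population sd sqrt(2/3)
  expect_equal(out$X[, 1], c(-1.2247449, 0, 1.2247449),
               tolerance = 1e-6, ignore_attr = TRUE)
  # scalar recomputation for the second column
  f <- X[, 2]
  expect_equal(out$X[, 2], (f - mean(f)) / sqrt(mean((f - mean(f))^2)),
               ignore_attr = TRUE)
  # idempotence
  again <- normalize_features(out)
  expect_equal(again$X, out$X, tolerance = 1e-12)
  # constant column dropped with a warning, not an error
  Y <- named_mat(cbind(c(5, 5, 5), c(1, 4, 2)))
  expect_warning(out <- normalize_features(omics_view(Y)), "zero-variance")
  expect_equal(out$features, "f02")
})

test_that("standardized columns have mean 0 and unit spread to 1e-9", {
  set.seed(5)
  X <- named_mat(matrix(rnorm(40 * 12, mean = 3, sd = 7), 40, 12))
  out <- normalize_features(omics_view(X))
  expect_lt(max(abs(colMeans(out$X))), 1e-9)
  pop_sd <- sqrt(colMeans(sweep(out$X, 2, colMeans(out$X))^2))
  expect_lt(max(abs(pop_sd - 1)), 1e-9)
})

test_that("heat-kernel similarity follows exp(-d2/sigma)", {
  # two identical rows => similarity exactly 1
  X <- named_mat(rbind(c(1, 2), c(1, 2), c(4, 6)))
  S <- heat_kernel_similarity(omics_view(X),
                              preprocess_config(sigma_mode = "fixed",
                                                sigma_value = 2))
  expect_equal(S[1, 2], 1)
  # squared distance equal to sigma => e^-1
  d2_13 <- sum((X[1, ] - X[3, ])^2)
  S2 <- heat_kernel_similarity(omics_view(X),
                               preprocess_config(sigma_mode = "fixed",
                                                 sigma_value = d2_13))
  expect_equal(S2[1, 3], exp(-1), tolerance = 1e-12)
  # scalar recomputation of every entry
  for (i in 1:3) for (j in 1:3)
    expect_equal(S2[i, j],
                 if (i == j) 1 else exp(-sum((X[i, ] - X[j, ])^2) / d2_13),
                 tolerance = 1e-12)
  # huge bandwidth => everything tends to 1
  S3 <- heat_kernel_similarity(omics_view(X),
                               preprocess_config(sigma_mode = "fixed",
                                                 sigma_value = 1e12))
  expect_true(all(S3 > 0.999999))
  expect_error(preprocess_config(sigma_mode = "fixed", sigma_value = -1),
               "positive")
})

test_that("similarity entries live in (0,1] and decrease with distance", {
  set.seed(9)
  X <- named_mat(matrix(rnorm(20 * 4), 20, 4))
  v <- normalize_features(omics_view(X))
  S <- heat_kernel_similarity(v)
  expect_true(all(S > 0 & S <= 1))
  expect_equal(S, t(S))
  D2 <- as.matrix(dist(v$X))^2
  ut <- upper.tri(S)
  ord <- order(D2[ut])
  expect_true(all(diff(S[ut][ord]) <= 1e-12))
})

test_that("KNN graph picks top-K neighbours and symmetrizes by union", {
  # 1-D points {0, 1, 3}, K = 1: directed edges 0->1, 1->0, 3->1;
  # union gives exactly {0-1, 1-3} (verified by exhaustive distance ranking)
  X <- named_mat(matrix(c(0, 1, 3), ncol = 1))
  S <- heat_kernel_similarity(omics_view(X),
                              preprocess_config(sigma_mode = "fixed",
                                                sigma_value = 1))
  g <- build_knn_graph(S, preprocess_config(k_neighbors = 1))
  expected_A <- matrix(c(0, 1, 0,
                         1, 0, 1,
                         0, 1, 0), 3, 3, byrow = TRUE)
  expect_equal(unname(g$A), expected_A)
  # K = N-1 yields the complete graph without self-loops
  g2 <- build_knn_graph(S, preprocess_config(k_neighbors = 2))
  expect_equal(unname(g2$A), 1 - diag(3))
  # K >= N clamps with a warning
  expect_warning(g3 <- build_knn_graph(S, preprocess_config(k_neighbors = 7)),
                 "clamped")
  expect_equal(g3$k, 2L)
  expect_error(build_knn_graph(S[1, 1, drop = FALSE]), "at least 2")
})

test_that("adjacency and its normalization are exactly symmetric", {
  set.seed(21)
  for (rep in 1:10) {
    X <- named_mat(matrix(rnorm(15 * 3), 15, 3))
    S <- heat_kernel_similarity(normalize_features(omics_view(X)))
    g <- build_knn_graph(S, preprocess_config(k_neighbors = 4))
    expect_identical(g$A, t(g$A))
    expect_identical(g$A_norm, t(g$A_norm))
    expect_true(all(diag(g$A) == 0))
    expect_true(all(rowSums(g$A) >= 4))   # every row selected 4 neighbours
  }
})

test_that("normalized operator equals D^-1/2 (A+I) D^-1/2", {
  # isolated node: self-loop only
  expect_equal(normalize_adjacency(matrix(0, 1, 1)), matrix(1, 1, 1))
  # two mutually connected nodes: D = diag(2,2), all entries 1/2
  A2 <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(normalize_adjacency(A2), matrix(0.5, 2, 2))
  # hand computation on a path graph 1-2-3
  A3 <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3)
  Ahat <- A3 + diag(3)
  D <- diag(1 / sqrt(rowSums(Ahat)))
  expect_equal(normalize_adjacency(A3), D %*% Ahat %*% D)
  expect_error(normalize_adjacency(matrix(c(0, 1, 0, 0), 2, 2)), "symmetric")
})

test_that("well-separated blobs never connect across blobs when K is small", {
  set.seed(33)
  centers <- rbind(c(0, 0), c(50, 0), c(0, 50))
  X <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(rnorm(20 * 2, sd = 0.5), 20, 2), 2, centers[k, ], "+")))
  X <- named_mat(X)
  blob <- rep(1:3, each = 20)
  S <- heat_kernel_similarity(omics_view(X))
  g <- build_knn_graph(S, preprocess_config(k_neighbors = 10))
  cross <- outer(blob, blob, "!=")
  expect_true(all(g$A[cross] == 0))
})

test_that("the full preprocessing pipeline aligns views and reports drops", {
  set.seed(3)
  spec <- synthetic_spec(n_samples = 30, n_clusters = 2, n_views = 2,
                         dims = c(12L, 9L), separation = 4, noise_sd = 1,
                         missing_rate = 0.05, seed = 3)
  dat <- generate_multiomics(spec)
  pre <- preprocess_omics(dat$views, preprocess_config(k_neighbors = 5))
  expect_identical(pre$views[[1]]$samples, pre$views[[2]]$samples)
  expect_false(anyNA(pre$views[[1]]$X))
  expect_equal(pre$report$n_samples, length(pre$samples))
  expect_true(all(vapply(pre$report$views, function(v) v$sigma > 0, TRUE)))
  tmp <- tempfile(fileext = ".json")
  write_preprocess_report(pre$report, tmp)
  expect_true(jsonlite::validate(paste(readLines(tmp), collapse = "")))
})
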