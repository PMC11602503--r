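# independent scalar reimplementations of the soft assignment and the
# target distribution, used as oracles
soft_assignment_oracle <- function(Z, mu, dof) {
  Q <- matrix(0, nrow(Z), nrow(mu))
  for (i in seq_len(nrow(Z))) {
    for (j in seq_len(nrow(mu))) {
      d2 <- sum((Z[i, ] - mu[j, ])^2)
      Q[i, j] <- (1 + d2 / dof)^(-(dof + 1) / 2)
    }
    Q[i, ] <- Q[i, ] / sum(Q[i, ])
  }
  Q
}

target_oracle <- function(Q) {
  f <- colSums(Q)
  P <- matrix(0, nrow(Q), ncol(Q))
  for (i in seq_len(nrow(Q))) {
    for (j in seq_len(ncol(Q))) P[i, j] <- Q[i, j]^2 / f[j]
    P[i, ] <- P[i, ] / sum(P[i, ])
  }
  P
}

test_that("Student-t assignment matches hand evaluation", {
  # equidistant from both centers: exactly (0.5, 0.5)
  Z <- matrix(c(0, 0), 1, 2)
  mu <- rbind(c(1, 0), c(-1, 0))
  expect_equal(soft_assignment(Z, mu), matrix(0.5, 1, 2))
  # z at mu1 with ||z - mu2||^2 = 1, dof 1: unnormalized (1, 0.5) -> (2/3, 1/3)
  Z2 <- matrix(c(0, 0), 1, 2)
  mu2 <- rbind(c(0, 0), c(1, 0))
  expect_equal(soft_assignment(Z2, mu2), matrix(c(2 / 3, 1 / 3), 1, 2))
  expect_error(soft_assignment(Z2, mu2[1, , drop = FALSE]), "at least 2")
})

test_that("assignments are row-stochastic and match the scalar oracle", {
  set.seed(7)
  for (rep in 1:100) {
    n <- sample(2:10, 1); d <- sample(1:5, 1); c <- sample(2:5, 1)
    Z <- matrix(rnorm(n * d), n, d)
    mu <- matrix(rnorm(c * d), c, d)
    dof <- sample(c(0.5, 1, 2), 1)
    Q <- soft_assignment(Z, mu, dof)
    expect_lt(max(abs(rowSums(Q) - 1)), 1e-9)
    expect_equal(Q, soft_assignment_oracle(Z, mu, dof), tolerance = 1e-12)
  }
})

test_that("target distribution sharpens Q exactly as the formula says", {
  # N = 1: P equals Q (q^2/f_j = q when f_j = q_j)
  Q1 <- matrix(c(0.3, 0.7), 1, 2)
  expect_equal(target_distribution(Q1), Q1)
  # uniform rows stay uniform
  Qu <- matrix(1 / 3, 4, 3)
  expect_equal(target_distribution(Qu), Qu)
  # worked example: f = (1.4, 0.6), first row ~ (0.9720, 0.0280)
  Q <- rbind(c(0.9, 0.1), c(0.5, 0.5))
  P <- target_distribution(Q)
  expect_equal(P, target_oracle(Q), tolerance = 1e-12)
  expect_equal(P[1, ], c(0.9720, 0.0280), tolerance = 1e-4)
  set.seed(8)
  for (rep in 1:30) {
    Qr <- random_stochastic(sample(2:8, 1), sample(2:5, 1))
    expect_equal(target_distribution(Qr), target_oracle(Qr),
                 tolerance = 1e-12)
  }
  expect_error(target_distribution(cbind(c(0.5, 0.5), 0)), "empty soft cluster")
})

test_that("KL divergence is the usual sum p log(p/r)", {
  P <- random_stochastic(4, 3)
  expect_equal(kl_divergence(P, P), 0)
  expect_equal(kl_divergence(matrix(c(1, 0), 1), matrix(c(0.5, 0.5), 1)),
               log(2))
  # zero p entries contribute nothing
  P0 <- matrix(c(0.5, 0.5, 0, 0.2, 0.3, 0.5), 2, 3, byrow = TRUE)
  R <- random_stochastic(2, 3)
  manual <- sum(ifelse(P0 > 0, P0 * log(P0 / R), 0))
  expect_equal(kl_divergence(P0, R), manual)
  expect_error(kl_divergence(matrix(c(1, 0), 1), matrix(c(0, 1), 1)),
               "infinite")
  set.seed(9)
  for (rep in 1:100) {
    A <- random_stochastic(5, 4); B <- random_stochastic(5, 4)
    expect_gte(kl_divergence(A, B), 0)
  }
})

test_that("the total loss combines the parts linearly in the weights", {
  parts <- list(L_res = 1, L_fus = 2, L_clu = 3, L_gcn = 4)
  expect_equal(total_loss(parts, loss_weights(1, 1, 1)), 10)
  expect_equal(total_loss(parts, loss_weights(1e-9, 1e-9, 1e-9)), 1,
               tolerance = 1e-6)
  # finite-difference linearity in each lambda
  for (k in 1:3) {
    lam <- c(0.4, 0.3, 0.2)
    up <- lam; up[k] <- up[k] + 0.5
    d <- total_loss(parts, do.call(loss_weights, as.list(up))) -
      total_loss(parts, do.call(loss_weights, as.list(lam)))
    expect_equal(d, 0.5 * parts[[k + 1]], tolerance = 1e-12)
  }
  expect_error(total_loss(list(L_res = NaN, L_fus = 0, L_clu = 0, L_gcn = 0),
                          loss_weights()), "L_res")
  expect_error(loss_weights(0, 0, 0), "positive")
})

test_that("K-means center initialization is deterministic and recovers blobs", {
  # exact point masses are recovered exactly
  Z <- rbind(matrix(1, 5, 2), matrix(-1, 5, 2))
  head <- init_centers(Z, 2, seed = 3)
  expect_equal(head$centers[order(head$centers[, 1]), ],
               rbind(c(-1, -1), c(1, 1)))
  # identical seeds give identical centers
  set.seed(10)
  Z2 <- matrix(rnorm(60), 30, 2)
  expect_identical(init_centers(Z2, 3, seed = 5)$centers,
                   init_centers(Z2, 3, seed = 5)$centers)
  # well-separated blobs: centers within 0.1 of the blob means
  set.seed(11)
  blob_means <- rbind(c(0, 0), c(10, 0), c(0, 10))
  Z3 <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(rnorm(100, sd = 0.3), 50, 2), 2, blob_means[k, ], "+")))
  ctr <- init_centers(Z3, 3, seed = 1)$centers
  ctr <- ctr[order(ctr[, 1] + 0.01 * ctr[, 2]), ]
  truth <- blob_means[order(blob_means[, 1] + 0.01 * blob_means[, 2]), ]
  expect_lt(max(abs(ctr - truth)), 0.1)
  expect_error(init_centers(Z[1:2, ], 3), "at least as many samples")
})

test_that("hard labels are the row argmax with lowest-index tie-break", {
  expect_equal(assign_labels(matrix(c(0.1, 0.7, 0.2), 1, 3)), 1L,
               ignore_attr = TRUE)
  expect_equal(assign_labels(matrix(c(0.5, 0.5), 1, 2)), 0L,
               ignore_attr = TRUE)
  set.seed(12)
  G <- random_stochastic(20, 4)
  scale <- runif(20, 0.5, 2)
  expect_identical(assign_labels(G), assign_labels(G * scale))
  rownames(G) <- sprintf("s%02d", 1:20)
  expect_named(assign_labels(G))
})
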