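# small random model + data for gradient-level checks, per ablation mode
make_grad_case <- function(mode, seed) {
  set.seed(seed)
  N <- 7L; V <- 2L; m <- c(5L, 4L); cc <- 3L
  arch <- list(V = V, L = 2L, m = m, c = cc, d = 3L,
               encoder_dims = c(4L, 3L), epsilon = 0.5, slope = 0.01,
               dof = 1, mode = mode)
  data <- list(X = lapply(m, function(mm) matrix(rnorm(N * mm), N, mm)),
               A = lapply(1:V, function(v) {
                 A <- matrix(0, N, N)
                 for (i in 1:N) A[i, sample(setdiff(1:N, i), 2)] <- 1
                 normalize_adjacency(pmax(A, t(A)))
               }))
  params <- smmsn:::.init_params(arch, seed)
  if (mode != "gcn_only") {
    params$Z_fused <- matrix(rnorm(N * 3), N, 3)
    params$mu <- matrix(rnorm(cc * 3), cc, 3)
  }
  w <- if (mode == "gcn_only") loss_weights(0.7, 0, 0.3)
       else loss_weights(0.7, 0.4, 0.3)
  fw <- smmsn:::.smmsn_repr(params, arch, data)
  P <- if (mode == "gcn_only") target_distribution(fw$G)
       else target_distribution(fw$Q)
  list(params = params, arch = arch, data = data, P = P, w = w)
}

grad_case_loss <- function(cs, params) {
  fw <- smmsn:::.smmsn_repr(params, cs$arch, cs$data)
  smmsn:::.smmsn_losses(params, cs$arch, cs$data, fw, cs$P, cs$w)$total
}
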