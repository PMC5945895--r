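test_that("time warp is the affine map with its stated fixed point", {
  expect_equal(time_warp(72, t0 = 70, alpha = 1, tau = 0), 72)
  expect_equal(time_warp(71, t0 = 70, alpha = 3, tau = 1), 70) # t = t0 + tau
  expect_equal(time_warp(72, t0 = 70, alpha = 2, tau = 1), 72) # 2(72-70-1)+70
  # strictly increasing in t
  t <- seq(50, 90, by = 0.5)
  w <- time_warp(t, 70, alpha = 0.3, tau = -4)
  expect_true(all(diff(w) > 0))
  expect_error(time_warp(70, 70, alpha = 0, tau = 0), "positive")
})

test_that("orthobasis columns are orthonormal and orthogonal to the velocity", {
  B <- build_orthobasis(c(1, 0, 0))
  expect_equal(dim(B), c(3L, 2L))
  # spans the (e2, e3) plane
  expect_equal(abs(B[1, ]), c(0, 0))
  expect_equal(crossprod(B), diag(2), tolerance = 1e-12)

  set.seed(2)
  for (K in c(5, 49)) {
    v <- rnorm(K)
    B <- build_orthobasis(v)
    expect_equal(crossprod(B), diag(K - 1), tolerance = 1e-10)
    expect_lt(max(abs(t(B) %*% v)), 1e-10 * sqrt(sum(v^2)))
    # projector comparison against a Gram-Schmidt oracle
    M <- diag(K) - tcrossprod(v) / sum(v^2)
    gs <- qr.Q(qr(M))[, seq_len(K - 1)] # orthonormal basis of range(M)
    expect_equal(tcrossprod(B), tcrossprod(gs), tolerance = 1e-8)
  }
  expect_error(build_orthobasis(rep(0, 4)), "nonzero")
})

test_that("mixing matrix and space shifts satisfy the identifiability constraint", {
  set.seed(4)
  K <- 10
  v <- rnorm(K)
  B <- build_orthobasis(v)

  expect_equal(mixing_matrix(rep(0, (K - 1) * 2), B),
               matrix(0, K, 2))
  e1 <- c(1, rep(0, K - 2))
  expect_equal(mixing_matrix(e1, B), B[, 1, drop = FALSE])

  beta <- rnorm((K - 1) * 3)
  A <- mixing_matrix(beta, B)
  expect_lt(max(abs(t(A) %*% v)), 1e-8)
  expect_error(mixing_matrix(rnorm(5), B), "multiple")

  expect_equal(space_shift(A, c(0, 0, 0)), rep(0, K))
  expect_equal(space_shift(A[, 1, drop = FALSE], 2), 2 * A[, 1])
  s <- rnorm(3)
  brute <- vapply(seq_len(K), function(k) sum(A[k, ] * s), numeric(1))
  expect_equal(space_shift(A, s), brute)
  expect_error(space_shift(A, 1:2), "length")
})

test_that("predictions follow the straight-line forward model", {
  ts <- tiny_sim()
  p <- ts$params
  g <- ts$graph
  fl <- netcourse:::param_fields(p, g)

  # zero random effects at t0: the position field
  expect_equal(drop(predict_course(p, g, p$t0)), fl$p_nodes)
  # population trajectory is linear in t
  y1 <- drop(predict_course(p, g, p$t0 + 1))
  y3 <- drop(predict_course(p, g, p$t0 + 3))
  y2 <- drop(predict_course(p, g, p$t0 + 2))
  expect_equal((y1 + y3) / 2, y2, tolerance = 1e-12)
  expect_equal(y1 - fl$p_nodes, fl$v_nodes, tolerance = 1e-12)

  # affine reparametrization: alpha = 2 at t0 + 1 equals alpha = 1 at t0 + 2
  ya <- predict_course(p, g, p$t0 + 1, xi = log(2))
  yb <- predict_course(p, g, p$t0 + 2, xi = 0)
  expect_equal(ya, yb, tolerance = 1e-12)
})

test_that("the warped-trajectory and node-wise forms of the model agree", {
  # gamma_k(w_k / gamma_dot_k(t0) + psi_i(t)) with gamma_k(t) =
  # v_k (t - t0) + p_k must equal p_k + w_k + v_k alpha (t - tau - t0)
  set.seed(9)
  ts <- tiny_sim(n_sources = 2L)
  p <- ts$params
  g <- ts$graph
  fl <- netcourse:::param_fields(p, g)
  for (r in 1:20) {
    xi <- rnorm(1, 0, 0.3); tau <- rnorm(1, 0, 3); s <- rnorm(2)
    t <- runif(1, 60, 80)
    w <- space_shift(fl$A, s)
    psi <- time_warp(t, p$t0, exp(xi), tau)
    gamma_form <- fl$v_nodes * (w / fl$v_nodes + psi - p$t0) + fl$p_nodes
    node_form <- drop(predict_course(p, g, t, xi = xi, tau = tau, s = s))
    expect_equal(gamma_form, node_form, tolerance = 1e-9)
  }
})

test_that("log-likelihood matches brute-force Gaussian sums", {
  ts <- tiny_sim(n_subjects = 4, sigma2 = 0.04, seed = 8)
  ll <- course_log_lik(ts$sim$data, ts$params, ts$graph, ts$sim$ind)

  # brute force: per-scalar normal density
  dm <- netcourse:::data_matrices(ts$sim$data)
  brute <- 0
  for (r in seq_len(nrow(dm$Y))) {
    i <- dm$subj[r]
    pred <- drop(predict_course(
      ts$params, ts$graph, dm$t[r],
      xi = ts$sim$ind$xi[i], tau = ts$sim$ind$tau[i],
      s = as.numeric(ts$sim$ind[i, c("s_1")])
    ))
    brute <- brute + sum(dnorm(dm$Y[r, ], pred, sqrt(ts$params$sigma2),
                               log = TRUE))
  }
  expect_equal(ll$log_lik, brute, tolerance = 1e-8)

  # residuals vanish on noiseless data
  ts0 <- tiny_sim(n_subjects = 3, sigma2 = 1e-30, seed = 8)
  ll0 <- course_log_lik(ts0$sim$data, ts0$params, ts0$graph, ts0$sim$ind)
  expect_lt(max(abs(ll0$residuals)), 1e-9)

  # single observation with residual sigma: logL = -1/2 (1 + log(2 pi s2))
  g1 <- path_graph(2)
  g1$control <- 1:2
  p1 <- course_params(t0 = 0, p_ctrl = c(0, 0), v_ctrl = c(0, 0),
                      beta = numeric(0), n_sources = 0,
                      sigma_tau2 = 1, sigma_xi2 = 1, sigma2 = 0.25,
                      bandwidth = 1)
  d1 <- tibble::tibble(subject_id = "a", age = 0,
                       node_1 = 0.5, node_2 = 0)
  ll1 <- course_log_lik(d1, p1, g1)
  expect_equal(ll1$log_lik,
               -0.5 * (1 + log(2 * pi * 0.25)) - 0.5 * log(2 * pi * 0.25))

  # doubling sigma with zero residuals lowers logL by N log 2
  d0 <- tibble::tibble(subject_id = "a", age = 0, node_1 = 0, node_2 = 0)
  lla <- course_log_lik(d0, p1, g1)$log_lik
  p2 <- p1; p2$sigma2 <- 4 * p1$sigma2
  llb <- course_log_lik(d0, p2, g1)$log_lik
  expect_equal(lla - llb, 2 * log(2), tolerance = 1e-12)
})

test_that("realigning event ages onto the common timeline shrinks their spread", {
  # diagnosis pinned at a fixed disease stage: warped ages are constant
  ts <- tiny_sim(n_subjects = 40, sigma2 = 1e-8, seed = 21)
  sim <- simulate_course(ts$params, ts$graph, 40, diag_stage_offset = 3,
                         seed = 22)
  out <- reparametrize_age(sim$ind, sim$ind$t_diag, ts$params$t0)
  expect_equal(out$warped_age, rep(ts$params$t0 + 3, 40), tolerance = 1e-9)
  expect_lt(sd(out$warped_age), sd(out$age))
  # data-frame interface
  ages_df <- tibble::tibble(subject_id = sim$ind$subject_id,
                            t_diag = sim$ind$t_diag)
  out2 <- reparametrize_age(sim$ind, ages_df, ts$params$t0)
  expect_equal(sort(out2$warped_age), sort(out$warped_age))
})

test_that("datasets are validated and duplicate visits rejected", {
  d <- tibble::tibble(subject_id = c("a", "a"), age = c(70, 70),
                      node_1 = c(1, 2))
  expect_error(as_course_data(d), "Duplicate")
  d2 <- tibble::tibble(subject_id = "a", age = 70, node_1 = NA_real_)
  expect_error(as_course_data(d2), "Missing")
  d3 <- tibble::tibble(subject_id = c("b", "a"), age = c(1, 2), node_1 = 0)
  expect_equal(as_course_data(d3)$subject_id, c("a", "b"))
})
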