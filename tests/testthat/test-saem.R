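test_that("step-size schedule follows the stochastic-approximation rule", {
  ctl <- saem_control(n_iter = 100, n_burn_in = 20, step_exponent = 0.65)
  rho <- netcourse:::step_sizes(ctl)
  expect_true(all(rho[1:20] == 1))
  expect_equal(rho[36], 16^-0.65, tolerance = 1e-12) # k - burn = 16
  expect_equal(rho[21], 1)
  g <- saem_control(n_iter = 50, n_burn_in = 10, schedule = "geometric",
                    geometric_rate = 0.9)
  expect_equal(netcourse:::step_sizes(g)[13], 0.9^3)
  expect_error(saem_control(n_iter = 10, n_burn_in = 10), "n_burn_in")
  expect_error(saem_control(step_exponent = 0.4), "step_exponent")
})

test_that("sufficient-statistic averaging is an exponential-moving update", {
  S <- list(a = c(0, 0), b = 3)
  Sz <- list(a = c(2, 4), b = 1)
  expect_equal(netcourse:::update_sufficient_statistics(S, Sz, 1), Sz)
  half <- netcourse:::update_sufficient_statistics(S, Sz, 0.5)
  expect_equal(half$a, c(1, 2))
  expect_equal(half$b, 2)
  # fixed point under a constant state
  cur <- S
  for (k in 1:200) {
    cur <- netcourse:::update_sufficient_statistics(cur, Sz, k^-0.65)
  }
  expect_equal(cur$a, Sz$a, tolerance = 1e-3)
  expect_error(netcourse:::update_sufficient_statistics(S, Sz, 0), "rho")
  expect_error(netcourse:::update_sufficient_statistics(S, Sz, 1.5), "rho")
})

test_that("maximization step recovers closed-form variance updates", {
  # onsets (t0 - 1, t0 + 1) around t0 = 70: time-shift variance 1
  S <- list(
    tau1 = c(69, 71), tau2 = c(69^2, 71^2),
    xi1 = c(0, 0), xi2 = c(0.02, 0.04),
    p1 = c(2, 4), p2 = c(4, 16), v1 = c(0.1, 0.3), v2 = c(0.01, 0.09),
    b1 = numeric(0), b2 = numeric(0),
    ssr = 10
  )
  up <- netcourse:::m_step(S, n_total = 1000)
  expect_equal(up$t0, 70)
  expect_equal(up$sigma_tau2, 1.0)
  expect_equal(up$sigma_xi2, 0.03)
  expect_equal(up$sigma2, 0.01) # residual SS 10 over 1000 scalars
  expect_equal(up$p_bar, 3)
  expect_equal(up$sigma_p2, 1.0)
  expect_equal(up$v_bar, 0.2)

  # degenerate statistics are floored
  S$xi2 <- c(0, 0)
  up2 <- netcourse:::m_step(S, 1000)
  expect_equal(up2$sigma_xi2, 1e-12)
  expect_true(attr(up2, "floored"))
})

test_that("the M-step maximizes the complete-data log-likelihood", {
  # numeric-optimizer oracle on a small instance: K = 4, few subjects
  set.seed(31)
  graph <- make_grid_graph(2)
  graph$control <- 1:4
  params <- course_params(
    t0 = 70, p_ctrl = c(3.0, 3.1, 3.2, 3.3), v_ctrl = rep(0.05, 4),
    beta = rep(0.05, 3), n_sources = 1L,
    sigma_tau2 = 9, sigma_xi2 = 0.05, sigma2 = 0.01, bandwidth = 1
  )
  sim <- simulate_course(params, graph, 4, visit_range = c(3L, 5L),
                         seed = 13)
  ts <- list(graph = graph, params = params, sim = sim)
  dm <- netcourse:::data_matrices(ts$sim$data)
  E <- netcourse:::field_evaluator(ts$graph, ts$params$bandwidth)
  I <- 4
  z <- list(
    xi = rnorm(I, 0, 0.2), tau = rnorm(I, 0, 2),
    S = matrix(rnorm(I), 1, I),
    p_ctrl = ts$params$p_ctrl + rnorm(4, 0, 0.1),
    v_ctrl = ts$params$v_ctrl + rnorm(4, 0, 0.01),
    beta = rnorm(3, 0, 0.1)
  )
  z$onset <- ts$params$t0 + z$tau

  # sufficient statistics of this single state (rho = 1)
  WT <- t(netcourse:::mixing_matrix(
    z$beta, build_orthobasis(as.numeric(E %*% z$v_ctrl))
  ) %*% z$S)
  ssr <- sum(netcourse:::ssr_components(
    dm, as.numeric(E %*% z$p_ctrl), as.numeric(E %*% z$v_ctrl), WT,
    exp(z$xi), z$onset, 0
  )$ssr)
  S <- list(
    xi1 = z$xi, xi2 = z$xi^2, tau1 = z$onset, tau2 = z$onset^2,
    s1 = z$S, p1 = z$p_ctrl, p2 = z$p_ctrl^2,
    v1 = z$v_ctrl, v2 = z$v_ctrl^2, b1 = z$beta, b2 = z$beta^2, ssr = ssr
  )
  up <- netcourse:::m_step(S, length(dm$t) * dm$K)

  # oracle: maximize the complete-data log-likelihood over
  # (t0, log sigma_tau2, log sigma_xi2, log sigma2) numerically
  obj <- function(par) {
    params <- ts$params
    params$t0 <- par[1]
    params$sigma_tau2 <- exp(par[2])
    params$sigma_xi2 <- exp(par[3])
    params$sigma2 <- exp(par[4])
    params$p_bar <- up$p_bar; params$sigma_p2 <- up$sigma_p2
    params$v_bar <- up$v_bar; params$sigma_v2 <- up$sigma_v2
    params$beta_bar <- up$beta_bar; params$sigma_beta2 <- up$sigma_beta2
    zz <- list(xi = z$xi, tau = z$onset - par[1], S = z$S,
               p_ctrl = z$p_ctrl, v_ctrl = z$v_ctrl, beta = z$beta)
    -netcourse:::complete_log_lik(dm, E, params, zz)
  }
  o <- optim(c(up$t0, log(up$sigma_tau2), log(up$sigma_xi2), log(up$sigma2)),
             obj, method = "Nelder-Mead",
             control = list(maxit = 5000, reltol = 1e-14))
  expect_equal(up$t0, o$par[1], tolerance = 1e-4)
  expect_equal(log(up$sigma_tau2), o$par[2], tolerance = 1e-4)
  expect_equal(log(up$sigma_xi2), o$par[3], tolerance = 1e-4)
  expect_equal(log(up$sigma2), o$par[4], tolerance = 1e-4)
})

test_that("initialization recovers exact fields from noiseless linear data", {
  g <- make_grid_graph(3)
  K <- 9
  params <- course_params(
    t0 = 70, p_ctrl = rep(2.5, length(g$control)),
    v_ctrl = rep(0.04, length(g$control)),
    beta = numeric(0), n_sources = 0,
    sigma_tau2 = 1, sigma_xi2 = 1, sigma2 = 1, bandwidth = 2
  )
  fl <- netcourse:::param_fields(params, g)
  ages <- list(c(70, 72, 74), c(68, 71), c(73, 75, 77, 79))
  rows <- purrr::imap(ages, function(a, i) {
    pred <- t(vapply(a, function(t) fl$p_nodes + fl$v_nodes * (t - 70),
                     numeric(K)))
    colnames(pred) <- paste0("node_", 1:K)
    dplyr::bind_cols(tibble::tibble(subject_id = paste0("s", i), age = a),
                     tibble::as_tibble(pred))
  })
  data <- dplyr::bind_rows(rows)
  th0 <- init_course(data, g, bandwidth = 2, n_sources = 0)
  # velocities: per-subject OLS slopes on exactly linear data are exact
  expect_equal(th0$v_ctrl, fl$v_nodes[g$control], tolerance = 1e-10)
  expect_equal(th0$t0, mean(data$age))
  # positions: mean observed value at each control node
  dmx <- netcourse:::data_matrices(data)
  expect_equal(th0$p_ctrl, colMeans(dmx$Y[, g$control]))
  # config overrides take precedence (simulation-study protocol)
  th1 <- init_course(data, g, bandwidth = 2, n_sources = 0,
                     init = list(p = 2, v = 0.01, t0 = 75,
                                 sigma_tau2 = 1e-3, sigma_xi2 = 1e-7))
  expect_equal(th1$p_ctrl, rep(2, length(g$control)))
  expect_equal(th1$v_ctrl, rep(0.01, length(g$control)))
  expect_equal(th1$t0, 75)
  expect_equal(th1$sigma_tau2, 1e-3)
  expect_equal(th1$sigma_xi2, 1e-7)
})

test_that("single-visit-only datasets fall back to zero slopes with a warning", {
  g <- make_grid_graph(2)
  data <- tibble::tibble(
    subject_id = c("a", "b"), age = c(70, 71),
    node_1 = c(1, 2), node_2 = c(1, 2), node_3 = c(1, 2), node_4 = c(1, 2)
  )
  g$control <- 1:4
  expect_warning(th0 <- init_course(data, g, bandwidth = 1, n_sources = 0),
                 "two visits")
  expect_equal(th0$v_ctrl, rep(0, 4))
})

test_that("Metropolis sampling matches a grid-integration posterior on a toy", {
  # one node, one subject, theta frozen; only the onset latent moves
  # (the log-acceleration prior is pinned); the chain mean must match
  # numeric integration of the posterior
  g <- path_graph(1)
  g$dist <- matrix(0, 1, 1)
  g$control <- 1L
  params <- course_params(
    t0 = 70, p_ctrl = 2, v_ctrl = 0.5, beta = numeric(0), n_sources = 0,
    sigma_tau2 = 4, sigma_xi2 = 1e-12, sigma2 = 0.25, bandwidth = 1
  )
  data <- tibble::tibble(subject_id = "a", age = c(69, 71, 73),
                         node_1 = c(1.2, 2.6, 3.4))
  ps <- posterior_sample_ind(data, params, g, n_iter = 24000,
                             n_burn_in = 4000, seed = 77)
  # oracle: 1-D quadrature over the onset (xi ~ 0 enforced by its prior)
  loglik <- function(onset) {
    vapply(onset, function(o) {
      sum(dnorm(data$node_1, 2 + 0.5 * (data$age - o), 0.5, log = TRUE)) +
        dnorm(o, 70, 2, log = TRUE)
    }, numeric(1))
  }
  os <- seq(50, 90, length.out = 4001)
  w <- exp(loglik(os) - max(loglik(os)))
  post_mean_onset <- sum(os * w) / sum(w)
  post_mean_tau <- post_mean_onset - 70
  expect_lt(abs(ps$mean$tau - post_mean_tau), 0.1)
})

test_that("same-seed fits are bit-identical and diverge with the seed", {
  ts <- tiny_sim(n_subjects = 6, sigma2 = 1e-4, seed = 15)
  ctl <- saem_control(n_iter = 60, n_burn_in = 20, seed = 5)
  f1 <- suppressWarnings(fit_course(ts$sim$data, ts$graph, bandwidth = 2,
                                    n_sources = 1, control = ctl))
  f2 <- suppressWarnings(fit_course(ts$sim$data, ts$graph, bandwidth = 2,
                                    n_sources = 1, control = ctl))
  expect_identical(f1$traces, f2$traces)
  expect_identical(f1$ind, f2$ind)
  f3 <- suppressWarnings(fit_course(
    ts$sim$data, ts$graph, bandwidth = 2, n_sources = 1,
    control = saem_control(n_iter = 60, n_burn_in = 20, seed = 6)
  ))
  expect_false(identical(f1$traces, f3$traces))
})

test_that("a fit started at the truth with vanishing noise stays at the truth", {
  ts <- tiny_sim(n_subjects = 10, n_sources = 0L, sigma2 = 1e-16,
                 sigma_tau2 = 1e-8, sigma_xi2 = 1e-8, seed = 23)
  p <- ts$params
  init <- list(p = p$p_ctrl, v = p$v_ctrl, t0 = p$t0,
               sigma_tau2 = p$sigma_tau2, sigma_xi2 = p$sigma_xi2)
  fit <- suppressWarnings(fit_course(
    ts$sim$data, ts$graph, bandwidth = p$bandwidth, n_sources = 0,
    control = saem_control(n_iter = 120, n_burn_in = 40, seed = 9),
    init = init
  ))
  # the population fields cannot drift away from the generating values:
  # every proposal that moves them is rejected at sigma -> 0
  expect_equal(fit$params$p_ctrl, p$p_ctrl, tolerance = 0.02)
  expect_equal(fit$params$t0, p$t0, tolerance = 0.5)
})
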