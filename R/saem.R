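#' MCMC-SAEM run configuration
#'
#' @param n_iter Total iterations.
#' @param n_burn_in Burn-in iterations (step size 1, proposal adaptation
#'   on); default 40% of `n_iter`.
#' @param step_exponent Exponent `a` of the post-burn-in step sizes
#'   `rho_k = (k - n_burn_in)^(-a)`; `a` in (0.5, 1] guarantees
#'   `sum rho = Inf`, `sum rho^2 < Inf`.
#' @param schedule `"polynomial"` (default) or `"geometric"`
#'   (`rho_k = geometric_rate^(k - n_burn_in)`).
#' @param geometric_rate Rate of the geometric schedule.
#' @param target_accept Target Metropolis acceptance rate during proposal
#'   adaptation.
#' @param adapt_gain Gain of the multiplicative Robbins-Monro scale
#'   adaptation (burn-in only; scales are frozen afterwards).
#' @param proposal Named list of initial random-walk proposal standard
#'   deviations per block (`xi`, `tau`, `s`, `p`, `v`, `beta`).
#' @param seed Optional integer seed; given the seed, a fit is bit
#'   reproducible.
#' @param verbose Emit a progress line every `log_every` iterations.
#' @param log_every Logging period, iterations.
#' @return A list of class `saem_control`.
#' @export
saem_control <- function(n_iter = 10000, n_burn_in = NULL,
                         step_exponent = 0.65,
                         schedule = c("polynomial", "geometric"),
                         geometric_rate = 0.98,
                         target_accept = 0.3, adapt_gain = 0.1,
                         proposal = list(), seed = NULL,
                         verbose = FALSE, log_every = 1000) {
  n_burn_in <- n_burn_in %||% max(1L, round(0.4 * n_iter))
  if (n_burn_in <= 0 || n_burn_in >= n_iter) {
    abort("`n_burn_in` must be in (0, n_iter).")
  }
  if (step_exponent <= 0.5 || step_exponent > 1) {
    abort("`step_exponent` must be in (0.5, 1].")
  }
  prop <- utils::modifyList(
    list(xi = 0.1, tau = 1.0, s = 0.2, p = 0.1, v = 0.01, beta = 0.05),
    proposal
  )
  structure(
    list(
      n_iter = as.integer(n_iter), n_burn_in = as.integer(n_burn_in),
      step_exponent = step_exponent, schedule = match.arg(schedule),
      geometric_rate = geometric_rate, target_accept = target_accept,
      adapt_gain = adapt_gain, proposal = prop, seed = seed,
      verbose = verbose, log_every = log_every
    ),
    class = "saem_control"
  )
}

step_sizes <- function(control) {
  k <- seq_len(control$n_iter)
  post <- pmax(k - control$n_burn_in, 0L)
  if (control$schedule == "polynomial") {
    ifelse(post == 0L, 1, post^(-control$step_exponent))
  } else {
    ifelse(post == 0L, 1, control$geometric_rate^post)
  }
}

#' Initialize model parameters from the raw data
#'
#' Data-driven starting point of the MCMC-SAEM: `t0` is the mean visit age;
#' the position at each control node is the mean observed value there; the
#' velocity at each control node is the mean over subjects of the
#' per-subject least-squares slope (subjects with a single visit contribute
#' no slope; if no subject has two visits, slopes fall back to 0 with a
#' warning); random effects and mixing coefficients start at zero, so every
#' initial individual trajectory equals the mean trajectory; the noise
#' variance is the mean squared residual of that initial model. Any entry
#' can be overridden through `init` (e.g. the deliberately uninformed
#' starting values of the simulation-study protocol).
#'
#' @param data A longitudinal dataset (see [as_course_data()]).
#' @param graph A `netcourse_graph` with control nodes.
#' @param bandwidth Kernel bandwidth of the fields.
#' @param n_sources Number of space-shift sources.
#' @param init Named list of overrides: `t0`, `p`, `v` (scalar or
#'   per-control-node vector), `beta`, `sigma_tau2`, `sigma_xi2`, `sigma2`,
#'   `sigma_p2`, `sigma_v2`, `sigma_beta2`.
#' @return A `course_params` starting value.
#' @export
init_course <- function(data, graph, bandwidth, n_sources = 2L,
                        init = list()) {
  data <- as_course_data(data)
  dm <- data_matrices(data)
  if (dm$K != n_nodes(graph)) abort("Dataset width does not match the graph.")
  ctrl <- graph$control
  if (length(ctrl) == 0L) abort("Graph has no control nodes.")
  Nc <- length(ctrl)
  K <- dm$K

  t0 <- mean(dm$t)
  p_ctrl <- colMeans(dm$Y[, ctrl, drop = FALSE])

  # per-subject OLS slope at each control node, averaged over subjects
  I <- length(dm$subjects)
  slopes <- matrix(NA_real_, I, Nc)
  for (i in seq_len(I)) {
    sel <- dm$subj == i
    if (sum(sel) >= 2L) {
      tt <- dm$t[sel] - mean(dm$t[sel])
      yy <- dm$Y[sel, ctrl, drop = FALSE]
      slopes[i, ] <- colSums(tt * yy) / sum(tt^2)
    }
  }
  if (all(is.na(slopes))) {
    warn("No subject has two visits; initial velocities fall back to 0.")
    v_ctrl <- rep(0, Nc)
  } else {
    v_ctrl <- colMeans(slopes, na.rm = TRUE)
  }

  expand_ctrl <- function(x, n) if (length(x) == 1L) rep(x, n) else x
  if (!is.null(init$p)) p_ctrl <- expand_ctrl(init$p, Nc)
  if (!is.null(init$v)) v_ctrl <- expand_ctrl(init$v, Nc)
  if (!is.null(init$t0)) t0 <- init$t0
  beta <- init$beta %||% rep(0, (K - 1) * n_sources)

  # noise from the residuals of the initial (zero-random-effect) model
  E <- field_evaluator(graph, bandwidth)
  p_nodes <- as.numeric(E %*% p_ctrl)
  v_nodes <- as.numeric(E %*% v_ctrl)
  R0 <- dm$Y - matrix(p_nodes, nrow(dm$Y), K, byrow = TRUE) -
    outer(dm$t - t0, v_nodes)
  sigma2 <- init$sigma2 %||% max(mean(R0^2), 1e-12)

  course_params(
    t0 = t0, p_ctrl = p_ctrl, v_ctrl = v_ctrl, beta = beta,
    n_sources = n_sources,
    sigma_tau2 = init$sigma_tau2 %||% 1.0,
    sigma_xi2 = init$sigma_xi2 %||% 0.01,
    sigma2 = sigma2, bandwidth = bandwidth,
    sigma_p2 = init$sigma_p2 %||% max(var(p_ctrl), 0.25),
    sigma_v2 = init$sigma_v2 %||% max(var(v_ctrl), 1e-3),
    sigma_beta2 = init$sigma_beta2 %||% 0.25
  )
}

# ---- internal numerics ----------------------------------------------------

# per-subject sum of squared residuals (and optionally the residual matrix)
ssr_components <- function(dm, p_nodes, v_nodes, WT, alpha, tau, t0,
                           want_R = FALSE) {
  n <- length(dm$t)
  dtv <- alpha[dm$subj] * (dm$t - tau[dm$subj] - t0)
  R <- dm$Y - matrix(p_nodes, n, dm$K, byrow = TRUE) -
    WT[dm$subj, , drop = FALSE] - outer(dtv, v_nodes)
  rs <- rowSums(R * R)
  ssr <- as.numeric(rowsum(rs, dm$subj, reorder = TRUE))
  if (want_R) list(ssr = ssr, R = R) else list(ssr = ssr)
}

# One Metropolis-within-Gibbs sweep over the individual-level blocks
# (all xi | all onset | all s), vectorized across subjects, which are
# conditionally independent given the population latents. `st` carries
# xi, onset (tau' = t0 + tau, the subject's onset age, whose Gaussian
# prior is centered at t0 -- in this parametrization t0 enters the model
# only through that prior), S (Ns x I), WT (I x K) and the per-subject
# ssr cache.
mh_sweep_ind <- function(dm, p_nodes, v_nodes, A, st, th, scales,
                         blocks = c("xi", "tau", "s")) {
  I <- length(st$xi)
  acc <- c(xi = NA_real_, tau = NA_real_, s = NA_real_)

  # xi block
  if ("xi" %in% blocks) {
    cand <- st$xi + scales[["xi"]] * rnorm(I)
    cc <- ssr_components(dm, p_nodes, v_nodes, st$WT, exp(cand), st$onset, 0)
    logr <- -0.5 * (cc$ssr - st$ssr) / th$sigma2 -
      (cand^2 - st$xi^2) / (2 * th$sigma_xi2)
    take <- log(runif(I)) < logr
    st$xi[take] <- cand[take]
    st$ssr[take] <- cc$ssr[take]
    acc[["xi"]] <- mean(take)
  }

  # onset (time-shift) block
  alpha <- exp(st$xi)
  if ("tau" %in% blocks) {
    cand <- st$onset + scales[["tau"]] * rnorm(I)
    cc <- ssr_components(dm, p_nodes, v_nodes, st$WT, alpha, cand, 0)
    logr <- -0.5 * (cc$ssr - st$ssr) / th$sigma2 -
      ((cand - th$t0)^2 - (st$onset - th$t0)^2) / (2 * th$sigma_tau2)
    take <- log(runif(I)) < logr
    st$onset[take] <- cand[take]
    st$ssr[take] <- cc$ssr[take]
    acc[["tau"]] <- mean(take)
  }

  # sources block (Laplace(0, 1/2) prior: log-density -2|s| per component)
  if ("s" %in% blocks && nrow(st$S) > 0) {
    cand <- st$S + scales[["s"]] * matrix(rnorm(length(st$S)), nrow(st$S))
    WTc <- t(A %*% cand)
    cc <- ssr_components(dm, p_nodes, v_nodes, WTc, alpha, st$onset, 0)
    logr <- -0.5 * (cc$ssr - st$ssr) / th$sigma2 -
      2 * (colSums(abs(cand)) - colSums(abs(st$S)))
    take <- log(runif(I)) < logr
    st$S[, take] <- cand[, take]
    st$WT[take, ] <- WTc[take, ]
    st$ssr[take] <- cc$ssr[take]
    acc[["s"]] <- mean(take)
  }
  list(state = st, accept = acc)
}

# Closed-form maximization step from the stochastically approximated
# sufficient statistics. In the internal onset parametrization
# (tau' = t0 + tau), t0 enters the complete-data likelihood only as the
# prior mean of the onset latents, so its exact update is the mean of
# their accumulated first moments; sigma_tau2 is the matching second
# central moment, and sigma2 is the mean accumulated squared residual.
m_step <- function(S, n_total, floor_var = 1e-12, update_hyper_var = TRUE) {
  floored <- FALSE
  fl <- function(x) {
    if (x < floor_var) { floored <<- TRUE; floor_var } else x
  }
  t0 <- mean(S$tau1)
  p_bar <- mean(S$p1)
  v_bar <- mean(S$v1)
  out <- list(
    t0 = t0, sigma2 = fl(S$ssr / n_total),
    sigma_tau2 = fl(mean(S$tau2) - 2 * t0 * mean(S$tau1) + t0^2),
    sigma_xi2 = fl(mean(S$xi2)),
    p_bar = p_bar, v_bar = v_bar, beta_bar = S$b1
  )
  # the hyper-variances of the population latents are frozen during
  # burn-in (the latents start as point masses, so their early across-node
  # dispersion is zero and an immediate update would pin them at the
  # start values); they join the SA updates in the sampling phase
  if (update_hyper_var) {
    out$sigma_p2 <- fl(mean(S$p2) - p_bar^2)
    out$sigma_v2 <- fl(mean(S$v2) - v_bar^2)
    out$sigma_beta2 <- if (length(S$b1)) fl(mean(S$b2 - S$b1^2)) else 1
  }
  attr(out, "floored") <- floored
  out
}

# stochastic approximation S <- S + rho (S(z) - S), elementwise over the
# statistic list
update_sufficient_statistics <- function(S, Sz, rho) {
  if (rho <= 0 || rho > 1) abort("`rho` must be in (0, 1].")
  purrr::map2(S, Sz, function(a, b) a + rho * (b - a))
}

# complete-data log-likelihood log p(y, z | theta), constants included
# (theta's variance parameters appear in the normalizers, so the M-step can
# be checked against a numeric maximizer of this function).
complete_log_lik <- function(dm, E, params, z) {
  p_nodes <- as.numeric(E %*% z$p_ctrl)
  v_nodes <- as.numeric(E %*% z$v_ctrl)
  K <- dm$K
  A <- if (params$n_sources > 0) {
    mixing_matrix(z$beta, build_orthobasis(v_nodes))
  } else {
    matrix(0, K, 0)
  }
  WT <- if (params$n_sources > 0) t(A %*% z$S) else
    matrix(0, length(z$xi), K)
  cc <- ssr_components(dm, p_nodes, v_nodes, WT, exp(z$xi), z$tau, params$t0)
  n <- length(dm$t) * K
  ll <- -0.5 * (sum(cc$ssr) / params$sigma2 + n * log(2 * pi * params$sigma2))
  ll <- ll + sum(dnorm(z$xi, 0, sqrt(params$sigma_xi2), log = TRUE))
  ll <- ll + sum(dnorm(z$tau, 0, sqrt(params$sigma_tau2), log = TRUE))
  ll <- ll + sum(dnorm(z$p_ctrl, params$p_bar, sqrt(params$sigma_p2), log = TRUE))
  ll <- ll + sum(dnorm(z$v_ctrl, params$v_bar, sqrt(params$sigma_v2), log = TRUE))
  if (length(z$beta)) {
    ll <- ll + sum(dnorm(z$beta, params$beta_bar, sqrt(params$sigma_beta2),
                         log = TRUE))
  }
  if (nrow(z$S) > 0) ll <- ll + sum(dlaplace_log(z$S, scale = 0.5))
  ll
}

# ---- main fit -------------------------------------------------------------

#' Fit a disease-course model with MCMC-SAEM
#'
#' Maximum-likelihood estimation of the spatiotemporal progression model by
#' stochastic approximation EM with Metropolis-within-Gibbs simulation of
#' the latent variables. Each iteration (i) updates the latent blocks
#' (all `xi`, all `tau`, all sources, then the control-node positions,
#' control-node velocities, and mixing coefficients as joint random-walk
#' blocks), (ii) folds the sufficient statistics into their
#' Robbins-Monro average, and (iii) maximizes the parameters in closed
#' form. Proposal scales adapt multiplicatively toward `target_accept`
#' during burn-in and are frozen afterwards. Population latents are
#' reported as their stochastic-approximation averages.
#'
#' @param data A longitudinal dataset (wide; see [as_course_data()]).
#' @param graph A `netcourse_graph` with control nodes selected.
#' @param bandwidth Kernel bandwidth of the position/velocity fields.
#' @param n_sources Number of space-shift sources (N_s >= 0).
#' @param control A [saem_control()].
#' @param init Initial-value overrides, passed to [init_course()].
#' @return An object of class `course_fit`: `params` (fitted
#'   [course_params()], fields at the SA-averaged control values), `ind`
#'   (tibble of individual-parameter estimates), `traces` (long tibble of
#'   per-iteration parameter values), `accept` (per-block acceptance-rate
#'   summaries and history), `stats` (final sufficient statistics),
#'   `control`, and `log_lik` (final observed-data Gaussian term at the
#'   current latents).
#' @seealso [personalize()], [simulate_course()], [tidy.course_fit()]
#' @export
fit_course <- function(data, graph, bandwidth, n_sources = 2L,
                       control = saem_control(), init = list()) {
  stopifnot(inherits(control, "saem_control"))
  if (!is.null(control$seed)) set.seed(control$seed)
  data <- as_course_data(data)
  dm <- data_matrices(data)
  I <- length(dm$subjects)
  K <- dm$K
  n_total <- length(dm$t) * K
  th0 <- init_course(data, graph, bandwidth, n_sources, init)
  Nc <- length(graph$control)
  Ns <- as.integer(n_sources)
  E <- field_evaluator(graph, bandwidth)

  # latent state (z) and derived caches; individual time shifts are
  # carried as onset ages tau' = t0 + tau (zero random effects at start)
  xi <- numeric(I)
  onset <- rep(th0$t0, I)
  Smat <- matrix(0, Ns, I)
  p_ctrl <- th0$p_ctrl; v_ctrl <- th0$v_ctrl
  beta <- th0$beta
  p_nodes <- as.numeric(E %*% p_ctrl)
  v_nodes <- as.numeric(E %*% v_ctrl)
  B <- if (Ns > 0) build_orthobasis(v_nodes) else NULL
  A <- if (Ns > 0) mixing_matrix(beta, B) else matrix(0, K, 0)
  WT <- matrix(0, I, K)
  th <- th0
  ssr_i <- ssr_components(dm, p_nodes, v_nodes, WT, exp(xi), onset, 0)$ssr

  # burn-in ceilings for the random-effect variances (see the heating
  # phase note in the loop below)
  mean_age_i <- as.numeric(rowsum(dm$t, dm$subj, reorder = TRUE)) /
    tabulate(dm$subj, I)
  cap_tau2 <- 2 * stats::var(mean_age_i) + 1
  cap_xi2 <- 2

  # sufficient-statistic accumulators
  S <- list(
    xi1 = xi, xi2 = xi^2, tau1 = onset, tau2 = onset^2, s1 = Smat,
    p1 = p_ctrl, p2 = p_ctrl^2, v1 = v_ctrl, v2 = v_ctrl^2,
    b1 = beta, b2 = beta^2, ssr = sum(ssr_i)
  )

  scales <- unlist(control$proposal)[c("xi", "tau", "s", "p", "v", "beta")]
  rho <- step_sizes(control)
  n_iter <- control$n_iter
  burn <- control$n_burn_in

  scalar_names <- c("t0", "sigma2", "sigma_tau2", "sigma_xi2",
                    "p_bar", "v_bar", "sigma_p2", "sigma_v2", "sigma_beta2",
                    "log_lik")
  tr_scalar <- matrix(NA_real_, n_iter, length(scalar_names),
                      dimnames = list(NULL, scalar_names))
  tr_p <- matrix(NA_real_, n_iter, Nc)
  tr_v <- matrix(NA_real_, n_iter, Nc)
  acc_hist <- matrix(NA_real_, n_iter, 4,
                     dimnames = list(NULL, c("xi", "s", "v", "ridge")))
  floor_warned <- FALSE

  n_vis <- length(dm$t)
  nobs_i <- tabulate(dm$subj, I)
  EtE <- crossprod(E)

  for (k in seq_len(n_iter)) {
    thk <- list(t0 = th$t0, sigma2 = th$sigma2,
                sigma_xi2 = th$sigma_xi2, sigma_tau2 = th$sigma_tau2)

    # --- simulation: Metropolis blocks for the nonlinear latents
    # (log-accelerations and sources; velocities below)
    sw <- mh_sweep_ind(dm, p_nodes, v_nodes, A,
                       list(xi = xi, onset = onset, S = Smat, WT = WT,
                            ssr = ssr_i),
                       thk, scales, blocks = c("xi", "s"))
    xi <- sw$state$xi
    Smat <- sw$state$S; WT <- sw$state$WT; ssr_i <- sw$state$ssr
    alpha <- exp(xi)
    acc_hist[k, c("xi", "s")] <- sw$accept[c("xi", "s")]

    # residual cache for the exact conditional draws below
    cc <- ssr_components(dm, p_nodes, v_nodes, WT, alpha, onset, 0,
                         want_R = TRUE)
    R <- cc$R; ssr_i <- cc$ssr

    # --- simulation: Gibbs draw of the onsets (the model is linear in
    # each onset, so its full conditional is Gaussian)
    sum_v2 <- sum(v_nodes^2)
    Sb2_i <- nobs_i * alpha^2 * sum_v2
    SRb_i <- alpha * as.numeric(rowsum(as.numeric(R %*% v_nodes), dm$subj,
                                       reorder = TRUE))
    prec <- Sb2_i / th$sigma2 + 1 / th$sigma_tau2
    mu <- (onset * Sb2_i / th$sigma2 - SRb_i / th$sigma2 +
             th$t0 / th$sigma_tau2) / prec
    onset_new <- rnorm(I, mu, 1 / sqrt(prec))
    dlt <- onset_new - onset
    ssr_i <- ssr_i + 2 * dlt * SRb_i + dlt^2 * Sb2_i
    R <- R + outer((alpha * dlt)[dm$subj], v_nodes)
    onset <- onset_new

    # --- simulation: Gibbs draw of the control-node positions (the
    # field is linear in them through the interpolation operator E)
    Ctot <- colSums(R) + n_vis * p_nodes
    Mp <- n_vis * EtE / th$sigma2 + diag(1 / th$sigma_p2, Nc)
    rhs <- as.numeric(crossprod(E, Ctot)) / th$sigma2 + th$p_bar / th$sigma_p2
    Up <- chol(Mp)
    p_new <- backsolve(Up, backsolve(Up, rhs, transpose = TRUE)) +
      backsolve(Up, rnorm(Nc))
    pn_new <- as.numeric(E %*% p_new)
    dfield <- pn_new - p_nodes
    ssr_i <- ssr_i - 2 * as.numeric(rowsum(as.numeric(R %*% dfield), dm$subj,
                                           reorder = TRUE)) +
      nobs_i * sum(dfield^2)
    R <- R - matrix(dfield, n_vis, K, byrow = TRUE)
    p_ctrl <- p_new; p_nodes <- pn_new

    # --- simulation: Metropolis on the control-node velocities; every
    # move rebuilds the orthobasis, mixing matrix and space shifts,
    # which all depend on the velocity field. During burn-in the walk is
    # joint (single-site moves would let the field slip to its
    # conditional optimum near zero before the onsets carry timing
    # information, deadlocking the fit); in the sampling phase it is
    # component-wise for better mixing.
    if (k <= burn) {
      cand <- v_ctrl + scales[["v"]] * rnorm(Nc)
      vn_c <- as.numeric(E %*% cand)
      B_c <- if (Ns > 0) build_orthobasis(vn_c) else NULL
      A_c <- if (Ns > 0) mixing_matrix(beta, B_c) else A
      WT_c <- if (Ns > 0) t(A_c %*% Smat) else WT
      cc <- ssr_components(dm, p_nodes, vn_c, WT_c, alpha, onset, 0)
      logr <- -0.5 * (sum(cc$ssr) - sum(ssr_i)) / th$sigma2 -
        (sum((cand - th$v_bar)^2) - sum((v_ctrl - th$v_bar)^2)) /
          (2 * th$sigma_v2)
      if (acc_hist[k, "v"] <- (log(runif(1)) < logr)) {
        v_ctrl <- cand; v_nodes <- vn_c; B <- B_c; A <- A_c; WT <- WT_c
        ssr_i <- cc$ssr
      }
    } else {
      acc_v <- 0
      steps <- scales[["v"]] * rnorm(Nc)
      for (j in seq_len(Nc)) {
        cand <- v_ctrl
        cand[j] <- cand[j] + steps[j]
        vn_c <- v_nodes + steps[j] * E[, j]
        B_c <- if (Ns > 0) build_orthobasis(vn_c) else NULL
        A_c <- if (Ns > 0) mixing_matrix(beta, B_c) else A
        WT_c <- if (Ns > 0) t(A_c %*% Smat) else WT
        cc <- ssr_components(dm, p_nodes, vn_c, WT_c, alpha, onset, 0)
        logr <- -0.5 * (sum(cc$ssr) - sum(ssr_i)) / th$sigma2 -
          ((cand[j] - th$v_bar)^2 - (v_ctrl[j] - th$v_bar)^2) /
            (2 * th$sigma_v2)
        if (log(runif(1)) < logr) {
          v_ctrl <- cand; v_nodes <- vn_c; B <- B_c; A <- A_c; WT <- WT_c
          ssr_i <- cc$ssr
          acc_v <- acc_v + 1
        }
      }
      acc_hist[k, "v"] <- acc_v / Nc
    }

    # --- simulation: Gibbs draw of the mixing coefficients. Because
    # the orthobasis columns are orthonormal, the full conditional of
    # the coefficient matrix factorizes over basis coordinates into
    # independent N_s-dimensional Gaussians sharing one precision
    # matrix.
    if (Ns > 0) {
      cc <- ssr_components(dm, p_nodes, v_nodes, WT, alpha, onset, 0,
                           want_R = TRUE)
      R <- cc$R
      Rt <- R + WT[dm$subj, , drop = FALSE]
      RB <- Rt %*% B
      G <- matrix(0, Ns, K - 1)
      for (m in seq_len(Ns)) {
        G[m, ] <- colSums(RB * Smat[m, dm$subj])
      }
      Msub <- Smat %*% (t(Smat) * nobs_i)
      Mb <- Msub / th$sigma2 + diag(1 / th$sigma_beta2, Ns)
      bb_mat <- matrix(th$beta_bar, K - 1, Ns)
      rhs <- G / th$sigma2 + t(bb_mat) / th$sigma_beta2
      Ub <- chol(Mb)
      mean_mat <- backsolve(Ub, backsolve(Ub, rhs, transpose = TRUE))
      draw <- mean_mat + backsolve(Ub, matrix(rnorm(Ns * (K - 1)), Ns))
      beta_mat <- t(draw)
      beta <- as.numeric(beta_mat)
      A <- B %*% beta_mat
      WT <- t(A %*% Smat)
      R <- Rt - WT[dm$subj, , drop = FALSE]
      ssr_i <- as.numeric(rowsum(rowSums(R * R), dm$subj, reorder = TRUE))
    }

    # --- gauge move along the reference-point ridge: for any c,
    # onset_i -> onset_i + c / alpha_i with p(x) -> p(x) + c v(x) leaves
    # every prediction unchanged (the reference point slides along the
    # population line), so a Metropolis move along this exact invariance
    # is accepted on the prior ratio alone and lets the onset prior pull
    # the chain to the variance-minimizing gauge. Run only in the
    # sampling phase, when the velocity field is informative.
    if (k > burn) {
      cprop <- 0.5 * rnorm(1)
      onset_c <- onset + cprop / alpha
      pctrl_c <- p_ctrl + cprop * v_ctrl
      logr <- -(sum((onset_c - th$t0)^2) - sum((onset - th$t0)^2)) /
        (2 * th$sigma_tau2) -
        (sum((pctrl_c - th$p_bar)^2) - sum((p_ctrl - th$p_bar)^2)) /
          (2 * th$sigma_p2)
      if (acc_hist[k, "ridge"] <- (log(runif(1)) < logr)) {
        onset <- onset_c
        p_ctrl <- pctrl_c
        p_nodes <- p_nodes + cprop * v_nodes
      }
    }

    # --- recentre the log-accelerations (exact reparametrization)
    # v(x) -> v(x) e^delta, xi_i -> xi_i - delta leaves every prediction
    # unchanged (the orthobasis depends only on the direction of the
    # velocity field), and removes the scale ridge between the velocity
    # field and the acceleration factors
    delta <- mean(xi)
    if (delta != 0) {
      xi <- xi - delta
      alpha <- exp(xi)
      sc <- exp(delta)
      v_ctrl <- v_ctrl * sc
      v_nodes <- v_nodes * sc
    }
    # --- sufficient statistics of the current state
    Sz <- list(
      xi1 = xi, xi2 = xi^2, tau1 = onset, tau2 = onset^2, s1 = Smat,
      p1 = p_ctrl, p2 = p_ctrl^2, v1 = v_ctrl, v2 = v_ctrl^2,
      b1 = beta, b2 = beta^2, ssr = sum(ssr_i)
    )
    S <- update_sufficient_statistics(S, Sz, rho[k])

    # --- maximization (closed form)
    up <- m_step(S, n_total, update_hyper_var = k > burn)
    if (k <= burn) {
      # heating phase: the random-effect variances may only grow during
      # burn-in (the chain starts as a point mass at the initial values,
      # so its early dispersion underestimates every variance; an
      # unconstrained update would collapse the priors onto the start
      # state before the data can spread the latents)
      up$sigma_tau2 <- max(up$sigma_tau2, th$sigma_tau2)
      up$sigma_xi2 <- max(up$sigma_xi2, th$sigma_xi2)
    }
    # data-scale ceilings, active throughout: the onset spread cannot
    # meaningfully exceed the spread of the subjects' mean visit ages;
    # without a ceiling an unidentified transient of the chain can
    # diffuse without bound, with the prior inflating behind it
    up$sigma_tau2 <- min(up$sigma_tau2, max(cap_tau2, th0$sigma_tau2))
    up$sigma_xi2 <- min(up$sigma_xi2, max(cap_xi2, th0$sigma_xi2))
    # rate-limit the reference time: t0 may track the onset mean by at
    # most 0.05 y per iteration, so the onset prior tethers the latent
    # cloud (otherwise neutral moves along the reparametrization ridge
    # let the whole cloud random-walk, with t0 chasing it)
    up$t0 <- th$t0 + max(min(up$t0 - th$t0, 0.05), -0.05)
    if (attr(up, "floored") && k > burn && !floor_warned) {
      warn("A variance update hit the 1e-12 floor.")
      floor_warned <- TRUE
    }
    th[names(up)] <- up
    if (!all(is.finite(unlist(up)))) {
      abort("MCMC-SAEM diverged: non-finite parameter update.",
            class = "netcourse_divergence",
            trace_scalar = tr_scalar[seq_len(k - 1), , drop = FALSE])
    }

    # --- proposal adaptation (burn-in only; Metropolis blocks)
    if (k <= burn) {
      mh <- c("xi", "s", "v")
      adj <- exp(control$adapt_gain *
                   (acc_hist[k, mh] - control$target_accept))
      adj[is.na(adj)] <- 1
      scales[mh] <- pmin(pmax(scales[mh] * adj, 1e-8), 1e3)
    }

    ll <- -0.5 * (sum(ssr_i) / th$sigma2 + n_total * log(2 * pi * th$sigma2))
    tr_scalar[k, ] <- c(th$t0, th$sigma2, th$sigma_tau2, th$sigma_xi2,
                        th$p_bar, th$v_bar, th$sigma_p2, th$sigma_v2,
                        th$sigma_beta2, ll)
    tr_p[k, ] <- p_ctrl
    tr_v[k, ] <- v_ctrl

    if (control$verbose && k %% control$log_every == 0) {
      message(sprintf(
        "iter %6d | logL %.4g | sigma %.4g | accept %s",
        k, ll, sqrt(th$sigma2),
        paste(sprintf("%s %.2f", colnames(acc_hist), acc_hist[k, ]),
              collapse = " ")
      ))
    }
  }

  params_hat <- course_params(
    t0 = th$t0, p_ctrl = S$p1, v_ctrl = S$v1, beta = S$b1,
    n_sources = Ns, sigma_tau2 = th$sigma_tau2, sigma_xi2 = th$sigma_xi2,
    sigma2 = th$sigma2, bandwidth = bandwidth,
    p_bar = th$p_bar, v_bar = th$v_bar, beta_bar = th$beta_bar,
    sigma_p2 = th$sigma_p2, sigma_v2 = th$sigma_v2,
    sigma_beta2 = th$sigma_beta2
  )
  ind <- tibble::tibble(subject_id = dm$subjects, xi = S$xi1,
                        tau = S$tau1 - th$t0)
  if (Ns > 0) for (j in seq_len(Ns)) ind[[paste0("s_", j)]] <- S$s1[j, ]

  traces <- dplyr::bind_rows(
    tidyr::pivot_longer(
      dplyr::mutate(tibble::as_tibble(tr_scalar), iter = seq_len(n_iter)),
      -"iter", names_to = "parameter", values_to = "value"
    ),
    tidyr::pivot_longer(
      dplyr::mutate(
        tibble::as_tibble(tr_p, .name_repair = ~ paste0("p_ctrl_", seq_len(Nc))),
        iter = seq_len(n_iter)
      ),
      -"iter", names_to = "parameter", values_to = "value"
    ),
    tidyr::pivot_longer(
      dplyr::mutate(
        tibble::as_tibble(tr_v, .name_repair = ~ paste0("v_ctrl_", seq_len(Nc))),
        iter = seq_len(n_iter)
      ),
      -"iter", names_to = "parameter", values_to = "value"
    )
  )
  adapted_win <- seq(max(1L, burn - floor(burn / 2) + 1L), burn)
  accept <- tibble::tibble(
    block = colnames(acc_hist),
    rate_adapted = colMeans(acc_hist[adapted_win, , drop = FALSE]),
    rate_sampling = colMeans(acc_hist[(burn + 1):n_iter, , drop = FALSE])
  )

  structure(
    list(
      params = params_hat, ind = ind, traces = traces, accept = accept,
      accept_history = acc_hist, stats = S, control = control,
      graph = graph, subjects = dm$subjects, n_obs = length(dm$t),
      proposal_scales = scales,
      log_lik = unname(tr_scalar[n_iter, "log_lik"])
    ),
    class = "course_fit"
  )
}

#' @export
print.course_fit <- function(x, ...) {
  cat("<course_fit> ", length(x$subjects), " subjects, ", x$n_obs,
      " visits, ", n_nodes(x$graph), " nodes\n", sep = "")
  print(x$params)
  invisible(x)
}

#' Posterior sampling of individual parameters with frozen theta
#'
#' Runs the Metropolis-within-Gibbs individual blocks with the population
#' parameters held fixed; used by `personalize(mode = "mean")` and for
#' sampler diagnostics.
#'
#' @param data Dataset of the subjects to sample.
#' @param params Fitted/fixed `course_params`.
#' @param graph Model graph.
#' @param n_iter,n_burn_in Chain length and burn-in (adaptation during
#'   burn-in).
#' @param scales Initial proposal standard deviations (`xi`, `tau`, `s`).
#' @param target_accept,adapt_gain Adaptation settings.
#' @param seed Optional seed.
#' @return List with `mean` (tibble of posterior-mean individual
#'   parameters), `chains` (list of matrices, post-burn-in), `accept`.
#' @export
posterior_sample_ind <- function(data, params, graph, n_iter = 2000,
                                 n_burn_in = floor(n_iter / 2),
                                 scales = c(xi = 0.1, tau = 1.0, s = 0.2),
                                 target_accept = 0.3, adapt_gain = 0.1,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data <- as_course_data(data)
  dm <- data_matrices(data)
  fl <- param_fields(params, graph)
  I <- length(dm$subjects)
  Ns <- params$n_sources
  st <- list(
    xi = numeric(I), onset = rep(params$t0, I), S = matrix(0, Ns, I),
    WT = matrix(0, I, dm$K)
  )
  st$ssr <- ssr_components(dm, fl$p_nodes, fl$v_nodes, st$WT, exp(st$xi),
                           st$onset, 0)$ssr
  th <- list(t0 = params$t0, sigma2 = params$sigma2,
             sigma_xi2 = params$sigma_xi2, sigma_tau2 = params$sigma_tau2)
  keep <- n_iter - n_burn_in
  ch_xi <- matrix(NA_real_, keep, I)
  ch_tau <- matrix(NA_real_, keep, I)
  ch_s <- array(NA_real_, c(keep, max(Ns, 1), I))
  acc_sum <- c(xi = 0, tau = 0, s = 0)
  for (k in seq_len(n_iter)) {
    sw <- mh_sweep_ind(dm, fl$p_nodes, fl$v_nodes, fl$A, st, th, scales)
    st <- sw$state
    if (k <= n_burn_in) {
      adj <- exp(adapt_gain * (sw$accept - target_accept))
      adj[is.na(adj)] <- 1
      scales <- pmin(pmax(scales * adj, 1e-8), 1e3)
    } else {
      j <- k - n_burn_in
      ch_xi[j, ] <- st$xi
      ch_tau[j, ] <- st$onset - params$t0
      if (Ns > 0) ch_s[j, , ] <- st$S
      acc_sum <- acc_sum + ifelse(is.na(sw$accept), 0, sw$accept)
    }
  }
  mean_tbl <- tibble::tibble(
    subject_id = dm$subjects, xi = colMeans(ch_xi), tau = colMeans(ch_tau)
  )
  if (Ns > 0) {
    for (j in seq_len(Ns)) mean_tbl[[paste0("s_", j)]] <- colMeans(ch_s[, j, ])
  }
  list(
    mean = mean_tbl,
    chains = list(xi = ch_xi, tau = ch_tau, s = if (Ns > 0) ch_s),
    accept = acc_sum / keep
  )
}
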