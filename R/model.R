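#' Individual time-warp
#'
#' Maps a subject's chronological age onto the common disease timeline:
#' `psi(t) = alpha (t - t0 - tau) + t0`, where `alpha = exp(xi)` is the
#' subject's acceleration factor and `t0 + tau` the subject-specific onset
#' reference. The map is affine and strictly increasing in `t`.
#'
#' @param t Age(s), years.
#' @param t0 Population reference time, years.
#' @param alpha Acceleration factor (> 0).
#' @param tau Time shift, years.
#' @return Warped age(s), years.
#' @examples
#' time_warp(72, t0 = 70, alpha = 2, tau = 1) # 72
#' @export
time_warp <- function(t, t0, alpha, tau) {
  if (any(alpha <= 0)) abort("`alpha` must be positive.")
  alpha * (t - t0 - tau) + t0
}

#' Orthonormal basis of the hyperplane orthogonal to a vector
#'
#' Builds a deterministic K x (K-1) matrix with orthonormal columns, each
#' orthogonal to `v`, via a single Householder reflection mapping `v/|v|`
#' onto the first coordinate axis. Used to parameterize space shifts
#' orthogonal to the population velocity direction (the identifiability
#' constraint of the model).
#'
#' @param v Nonzero numeric vector of length K.
#' @return K x (K-1) matrix `B` with `t(B) %*% B = I` and `t(B) %*% v = 0`.
#' @export
build_orthobasis <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv == 0) abort("`v` must be nonzero.")
  K <- length(v)
  u <- v / nv
  s <- if (u[1] >= 0) 1 else -1
  w <- u
  w[1] <- w[1] + s
  # H = I - 2 w w' / (w'w) is orthogonal, H e1 = -s u, so columns 2..K of H
  # are an orthonormal basis of the hyperplane orthogonal to u
  H <- diag(K) - 2 * tcrossprod(w) / sum(w^2)
  H[, -1, drop = FALSE]
}

#' Mixing matrix from free coefficients
#'
#' Assembles the K x N_s mixing matrix `A` whose columns live in the
#' hyperplane orthogonal to the population velocity direction:
#' column `j` is `B %*% beta[(j-1)(K-1) + 1:(K-1)]` for the orthobasis `B`.
#'
#' @param beta Numeric vector of length `(K-1) * n_sources`.
#' @param orthobasis K x (K-1) matrix from [build_orthobasis()].
#' @return K x N_s matrix. With `n_sources = 0`, a K x 0 matrix.
#' @export
mixing_matrix <- function(beta, orthobasis) {
  K1 <- ncol(orthobasis)
  if (length(beta) %% K1 != 0) {
    abort("`beta` length must be a multiple of K - 1.")
  }
  ns <- length(beta) / K1
  orthobasis %*% matrix(beta, nrow = K1, ncol = ns)
}

#' Space shift of one subject
#'
#' `w_i = A s_i`: the subject's deviation from the population trajectory in
#' measurement space, orthogonal to the population velocity direction.
#'
#' @param A K x N_s mixing matrix.
#' @param sources Numeric vector of length N_s.
#' @return Numeric vector of length K.
#' @export
space_shift <- function(A, sources) {
  if (length(sources) != ncol(A)) abort("`sources` length must match ncol(A).")
  as.numeric(A %*% sources)
}

# ---- population / individual parameter containers -------------------------

#' Population parameters of a disease-course model
#'
#' Bundles the fixed effects and population-level latent variables:
#' reference time `t0`, position and velocity values at the control nodes
#' (interpolated elsewhere by the Gaussian kernel), mixing coefficients of
#' the space-shift directions, random-effect variances, observation-noise
#' variance, and the hyper-parameters of the exponential-family priors.
#'
#' @param t0 Reference time (years).
#' @param p_ctrl,v_ctrl Position / velocity values at the control nodes.
#' @param beta Mixing coefficients, length `(K-1) * n_sources`.
#' @param n_sources Number of independent space-shift sources (>= 0).
#' @param sigma_tau2,sigma_xi2 Variances of the time-shift and
#'   log-acceleration random effects.
#' @param sigma2 Observation-noise variance.
#' @param bandwidth Kernel bandwidth used for the fields.
#' @param p_bar,v_bar,beta_bar,sigma_p2,sigma_v2,sigma_beta2 Prior
#'   hyper-parameters of the population latents (`beta_bar` has the length
#'   of `beta`).
#' @return An object of class `course_params`.
#' @export
course_params <- function(t0, p_ctrl, v_ctrl, beta, n_sources,
                          sigma_tau2, sigma_xi2, sigma2, bandwidth,
                          p_bar = mean(p_ctrl), v_bar = mean(v_ctrl),
                          beta_bar = rep(0, length(beta)),
                          sigma_p2 = max(var(p_ctrl), 0.25),
                          sigma_v2 = max(var(v_ctrl), 1e-3),
                          sigma_beta2 = 0.25) {
  stopifnot(
    sigma_tau2 > 0, sigma_xi2 > 0, sigma2 > 0, bandwidth > 0, n_sources >= 0
  )
  structure(
    list(
      t0 = t0, p_ctrl = as.numeric(p_ctrl), v_ctrl = as.numeric(v_ctrl),
      beta = as.numeric(beta), n_sources = as.integer(n_sources),
      sigma_tau2 = sigma_tau2, sigma_xi2 = sigma_xi2, sigma2 = sigma2,
      bandwidth = bandwidth, p_bar = p_bar, v_bar = v_bar,
      beta_bar = as.numeric(beta_bar), sigma_p2 = sigma_p2,
      sigma_v2 = sigma_v2, sigma_beta2 = sigma_beta2
    ),
    class = "course_params"
  )
}

#' @export
print.course_params <- function(x, ...) {
  cat("<course_params> t0 =", format(x$t0, digits = 4),
      "| sigma_tau2 =", format(x$sigma_tau2, digits = 4),
      "| sigma_xi2 =", format(x$sigma_xi2, digits = 4),
      "| sigma2 =", format(x$sigma2, digits = 4),
      "|", length(x$p_ctrl), "control nodes,", x$n_sources, "sources\n")
  invisible(x)
}

# node-level fields + mixing matrix derived from params on a graph
param_fields <- function(params, graph) {
  E <- field_evaluator(graph, params$bandwidth)
  p_nodes <- as.numeric(E %*% params$p_ctrl)
  v_nodes <- as.numeric(E %*% params$v_ctrl)
  if (params$n_sources > 0) {
    B <- build_orthobasis(v_nodes)
    A <- mixing_matrix(params$beta, B)
  } else {
    B <- NULL
    A <- matrix(0, length(p_nodes), 0)
  }
  list(p_nodes = p_nodes, v_nodes = v_nodes, B = B, A = A, E = E)
}

# ---- longitudinal datasets ------------------------------------------------

node_cols <- function(data) {
  nc <- grep("^node_\\d+$", names(data), value = TRUE)
  if (length(nc) == 0L) abort("No `node_<k>` measurement columns found.")
  nc[order(as.integer(sub("node_", "", nc)))]
}

#' Validate a longitudinal network dataset
#'
#' A dataset is a wide data frame with one row per subject-visit: columns
#' `subject_id`, `age`, and `node_1` .. `node_K` measurement columns
#' (additional covariate columns such as `t_diag` are carried along).
#' Within each subject, ages must be strictly increasing and distinct.
#'
#' @param data A data frame.
#' @return The validated data as a tibble, sorted by subject and age.
#' @export
as_course_data <- function(data) {
  data <- tibble::as_tibble(data)
  stopifnot(all(c("subject_id", "age") %in% names(data)))
  nc <- node_cols(data)
  if (anyNA(data[nc])) abort("Missing node measurements are not supported.")
  data <- dplyr::arrange(data, .data$subject_id, .data$age)
  dup <- dplyr::count(data, .data$subject_id, .data$age) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0(
      "Duplicate (subject_id, age) rows: ",
      paste(utils::head(paste0(dup$subject_id, "@", dup$age), 5),
            collapse = ", ")
    ))
  }
  data
}

# internal matrix view: Y (n_obs x K), subj (integer index), t (ages)
data_matrices <- function(data) {
  nc <- node_cols(data)
  subjects <- unique(data$subject_id)
  list(
    Y = unname(as.matrix(data[nc])),
    subj = match(data$subject_id, subjects),
    t = as.numeric(data$age),
    subjects = subjects,
    K = length(nc)
  )
}

# ---- forward model --------------------------------------------------------

#' Noiseless model prediction for one subject
#'
#' Evaluates the individual trajectory at given ages:
#' `eta_k(t) = p(x_k) + w_k + v(x_k) alpha (t - tau - t0)` where
#' `w = A s` is the subject's space shift. With all random effects zero this
#' is the population trajectory `p + v (t - t0)`, linear in `t`.
#'
#' @param params A `course_params`.
#' @param graph The `netcourse_graph` the model lives on.
#' @param ages Numeric vector of ages at which to predict.
#' @param xi,tau Individual log-acceleration and time shift (defaults 0).
#' @param s Individual sources (length `n_sources`; default all 0).
#' @param fields Optional precomputed [param_fields()] result (internal
#'   fast path).
#' @return A `length(ages)` x K matrix of predictions.
#' @export
predict_course <- function(params, graph, ages, xi = 0, tau = 0,
                           s = rep(0, params$n_sources), fields = NULL) {
  fl <- fields %||% param_fields(params, graph)
  w <- if (params$n_sources > 0) space_shift(fl$A, s) else 0 * fl$p_nodes
  dt <- exp(xi) * (ages - tau - params$t0)
  t(vapply(dt, function(d) fl$p_nodes + w + fl$v_nodes * d,
           numeric(length(fl$p_nodes))))
}

#' Residuals and Gaussian log-likelihood of a dataset
#'
#' Computes per-observation residuals `y - eta` under the model and the iid
#' Gaussian log-likelihood
#' `-(1/2) sum[(y - eta)^2 / sigma^2 + log(2 pi sigma^2)]`.
#'
#' @param data A dataset (see [as_course_data()]).
#' @param params A `course_params`.
#' @param graph The model graph.
#' @param ind A data frame of individual parameters with columns
#'   `subject_id`, `xi`, `tau` and `s_1` .. `s_Ns` (missing subjects get
#'   zero random effects).
#' @return A list with `log_lik` (scalar), `residuals` (n_obs x K matrix,
#'   rows aligned with the sorted data), and `data` (the sorted data).
#' @export
course_log_lik <- function(data, params, graph, ind = NULL) {
  data <- as_course_data(data)
  dm <- data_matrices(data)
  fl <- param_fields(params, graph)
  iv <- ind_vectors(ind, dm$subjects, params$n_sources)
  R <- residual_matrix(dm, fl, params$t0, iv$xi, iv$tau, iv$S)
  n <- length(R)
  ll <- -0.5 * (sum(R^2) / params$sigma2 + n * log(2 * pi * params$sigma2))
  list(log_lik = ll, residuals = R, data = data)
}

# ind tibble -> aligned vectors/matrix in `subjects` order
ind_vectors <- function(ind, subjects, n_sources) {
  I <- length(subjects)
  xi <- numeric(I); tau <- numeric(I)
  S <- matrix(0, nrow = max(n_sources, 0), ncol = I)
  if (!is.null(ind)) {
    idx <- match(subjects, ind$subject_id)
    ok <- !is.na(idx)
    xi[ok] <- ind$xi[idx[ok]]
    tau[ok] <- ind$tau[idx[ok]]
    if (n_sources > 0) {
      scols <- paste0("s_", seq_len(n_sources))
      if (!all(scols %in% names(ind))) {
        abort("`ind` must have columns s_1 .. s_Ns.")
      }
      S[, ok] <- t(as.matrix(ind[idx[ok], scols, drop = FALSE]))
    }
  }
  list(xi = xi, tau = tau, S = S)
}

# vectorized residuals over all observations; W is K x I (space shifts)
residual_matrix <- function(dm, fl, t0, xi, tau, S) {
  W <- if (nrow(S) > 0) fl$A %*% S else matrix(0, dm$K, length(xi))
  alpha <- exp(xi)
  dtv <- alpha[dm$subj] * (dm$t - tau[dm$subj] - t0)
  pred <- matrix(fl$p_nodes, nrow(dm$Y), dm$K, byrow = TRUE) +
    t(W)[dm$subj, , drop = FALSE] + outer(dtv, fl$v_nodes)
  dm$Y - pred
}

#' Realign ages onto the common disease timeline
#'
#' Applies each subject's time-warp to a per-subject age (typically the age
#' at diagnosis), returning the distribution of warped ages. On data where
#' the clinical event happens at a fixed disease stage, the warped ages
#' concentrate: their spread is smaller than that of the raw ages.
#'
#' @param ind Data frame with `subject_id`, `xi`, `tau`.
#' @param ages Data frame with `subject_id` and an age column, or a numeric
#'   vector aligned with `ind`.
#' @param t0 Population reference time.
#' @param age_col Name of the age column when `ages` is a data frame.
#' @return A tibble (`subject_id`, `age`, `warped_age`).
#' @export
reparametrize_age <- function(ind, ages, t0, age_col = "t_diag") {
  if (is.data.frame(ages)) {
    df <- dplyr::inner_join(
      dplyr::select(ind, "subject_id", "xi", "tau"),
      dplyr::select(ages, "subject_id", dplyr::all_of(age_col)),
      by = "subject_id"
    )
    a <- df[[age_col]]
  } else {
    df <- ind
    a <- ages
  }
  tibble::tibble(
    subject_id = df$subject_id, age = a,
    warped_age = time_warp(a, t0, exp(df$xi), df$tau)
  )
}
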