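#' Integrated VAC (IVAC) slow-mode identification
#'
#' Fits the integrated variational approach for conformational dynamics: the
#' time-lagged correlation matrices of the (mean-centered) features are
#' summed over a range of lag times,
#' \deqn{C_{int} = \sum_{\tau = lag\_min}^{lag\_max} \tfrac12\,(C(\tau) + C(\tau)^T),}
#' and the generalized symmetric eigenproblem
#' \eqn{C_{int} v = \lambda C(0) v} is solved.  The eigenvectors (time-lagged
#' independent components, tICs) are linear combinations of the input
#' features that decorrelate slowly; summing over a lag range makes the
#' result robust to the choice of any single lag.  Each correlation matrix is
#' symmetrized before summing so the spectrum is real on finite equilibrium
#' samples, and time-lagged pairs never straddle a trajectory boundary.
#'
#' When `C(0)` is ill-conditioned (condition number above `cond_max`) a tiny
#' ridge `eps * I` with `eps = 1e-10 * trace(C(0)) / d` is added; on
#' well-conditioned data this leaves the result unchanged to machine
#' precision.
#'
#' @param features a `feature_matrix` (from [pairwise_ca_distances()]) or a
#'   list of them; trajectory boundaries are respected.
#' @param lag_min,lag_max lag range, in frames (`1 <= lag_min <= lag_max`);
#'   every trajectory must be longer than `lag_max`.
#' @param stride lag-schedule stride: correlation matrices are accumulated at
#'   lags `seq(lag_min, lag_max, by = stride)`.  Default 1 (every lag).
#' @param cond_max condition-number threshold that triggers regularization.
#' @return An object of class `"tic_model"`: `lag_min`, `lag_max`, `stride`,
#'   `mean`, `eigenvalues` (integrated, descending), `eigenvectors`
#'   (`d x d`, columns normalized so that `v' C(0) v = 1`), `n_frames_used`,
#'   `labels`.
#' @export
fit_ivac <- function(features, lag_min, lag_max, stride = 1L, cond_max = 1e12) {
  fm <- combine_features(features)
  if (!is_count(lag_min) || !is_count(lag_max) || lag_min > lag_max)
    stop2("need integer lags with 1 <= lag_min <= lag_max")
  short <- which(fm$boundaries <= lag_max)
  if (length(short) > 0L)
    stop2("trajectory ", short[1L], " has ", fm$boundaries[short[1L]],
          " frames; every trajectory must be longer than lag_max = ", lag_max)

  X <- fm$values
  d <- ncol(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  N <- nrow(Xc)
  C0 <- crossprod(Xc) / N

  # regularize if ill-conditioned (or outright singular)
  ev0 <- eigen(C0, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev0) <= 0 || max(ev0) / max(min(ev0), .Machine$double.xmin) > cond_max) {
    eps <- 1e-10 * sum(diag(C0)) / d
    if (eps <= 0)
      stop2("C(0) is singular and has zero trace; features are constant. ",
            "Remove constant columns or add regularization.")
    C0 <- C0 + diag(eps, d)
    ev0 <- eigen(C0, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev0) <= 0 || max(ev0) / min(ev0) > 1 / .Machine$double.eps)
      stop2("C(0) remains singular after ridge regularization; ",
            "features are linearly dependent. Reduce the feature set ",
            "or increase the regularization.")
  }

  rows <- split_by_boundaries(fm$boundaries)
  lags <- seq.int(lag_min, lag_max, by = stride)
  Cint <- matrix(0, d, d)
  for (tau in lags) {
    Ct <- matrix(0, d, d)
    npairs <- 0L
    for (r in rows) {
      n <- length(r)
      if (n <= tau) next
      A <- Xc[r[1:(n - tau)], , drop = FALSE]
      B <- Xc[r[(1 + tau):n], , drop = FALSE]
      Ct <- Ct + crossprod(A, B)
      npairs <- npairs + (n - tau)
    }
    Ct <- Ct / npairs
    Cint <- Cint + (Ct + t(Ct)) / 2
  }

  # generalized symmetric eigenproblem via Cholesky whitening
  U <- chol(C0)
  Ui <- backsolve(U, diag(d))
  M <- t(Ui) %*% Cint %*% Ui
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  V <- Ui %*% e$vectors

  structure(list(lag_min = lag_min, lag_max = lag_max, stride = stride,
                 mean = mu, eigenvalues = e$values, eigenvectors = V,
                 n_frames_used = N, labels = fm$labels),
            class = "tic_model")
}

#' @export
print.tic_model <- function(x, ...) {
  cat("tic_model: lags", x$lag_min, "-", x$lag_max, "(stride", x$stride, "),",
      length(x$eigenvalues), "components,", x$n_frames_used, "frames\n")
  cat("leading integrated eigenvalues:",
      paste(signif(utils::head(x$eigenvalues, 5L), 4L), collapse = ", "), "\n")
  invisible(x)
}

#' Project features onto the leading tICs
#'
#' Column `i` of the result is `(x - mean) . v_i`.
#'
#' @param model a `"tic_model"` from [fit_ivac()].
#' @param features a `feature_matrix`, list of them, or a plain numeric
#'   matrix with matching feature dimension.
#' @param n_components number of tICs to keep.
#' @return Numeric matrix, frames x `n_components`; when the input carries
#'   trajectory boundaries they are attached as attribute `"boundaries"`.
#' @export
project_tics <- function(model, features, n_components) {
  if (!inherits(model, "tic_model")) stop2("model must be a tic_model")
  boundaries <- NULL
  if (is.matrix(features) && is.numeric(features)) {
    X <- features
  } else {
    fm <- combine_features(features)
    X <- fm$values
    boundaries <- fm$boundaries
  }
  d <- length(model$mean)
  if (ncol(X) != d)
    stop2("feature dimension ", ncol(X), " does not match model dimension ", d)
  if (!is_count(n_components) || n_components > d)
    stop2("n_components must be an integer in 1..", d)
  Y <- sweep(X, 2L, model$mean) %*% model$eigenvectors[, seq_len(n_components),
                                                       drop = FALSE]
  colnames(Y) <- paste0("tIC", seq_len(n_components))
  if (!is.null(boundaries)) attr(Y, "boundaries") <- boundaries
  Y
}

#' Select seed frames from poorly sampled regions of tIC space
#'
#' Estimates the sampling density of every frame in (at most the first three
#' dimensions of) the projected space with a Gaussian kernel density
#' estimate, and greedily returns the `n_seeds` lowest-density frames subject
#' to the constraint that selected frames are at least `bandwidth` apart.
#' Ties in density are broken by the lower frame index, so the selection is
#' deterministic; `seed` only matters when the density is evaluated against a
#' random subsample (frame counts above `max_eval`).
#'
#' @param projected frames x c matrix (tIC coordinates).
#' @param n_seeds number of frames to return.
#' @param bandwidth kernel bandwidth and minimum separation, in tIC units;
#'   default is the Scott rule on the dimensions used.
#' @param seed RNG seed for the density-reference subsample.
#' @param max_eval maximum number of reference points for the density sum.
#' @return Integer frame indices, in selection order.
#' @export
select_seeds <- function(projected, n_seeds = 14L, bandwidth = NULL, seed = 1L,
                         max_eval = 20000L) {
  X <- as.matrix(projected)
  n <- nrow(X)
  if (!is_count(n_seeds) || n_seeds > n)
    stop2("n_seeds must be an integer in 1..", n)
  X <- X[, seq_len(min(3L, ncol(X))), drop = FALSE]
  c_dim <- ncol(X)
  if (is.null(bandwidth)) {
    h <- apply(X, 2L, stats::sd) * n^(-1 / (c_dim + 4))
    h[h == 0] <- 1
    bandwidth <- exp(mean(log(h)))  # geometric mean as the common scale
  }
  if (bandwidth <= 0) stop2("bandwidth must be positive")

  ref <- seq_len(n)
  if (n > max_eval) {
    set.seed(as.integer(seed))
    ref <- sort(sample.int(n, max_eval))
  }
  R <- X[ref, , drop = FALSE]
  dens <- numeric(n)
  block <- 2000L
  for (s in seq(1L, n, by = block)) {
    e <- min(s + block - 1L, n)
    D2 <- outer(rowSums(X[s:e, , drop = FALSE]^2), rowSums(R^2), `+`) -
      2 * X[s:e, , drop = FALSE] %*% t(R)
    dens[s:e] <- rowSums(exp(-D2 / (2 * bandwidth^2)))
  }

  ord <- order(dens, seq_len(n))
  chosen <- integer(0)
  for (i in ord) {
    if (length(chosen) == n_seeds) break
    if (length(chosen) == 0L ||
        all(row_norms(X[chosen, , drop = FALSE] -
                      matrix(X[i, ], length(chosen), c_dim, byrow = TRUE)) >=
            bandwidth))
      chosen <- c(chosen, i)
  }
  if (length(chosen) < n_seeds)
    stop2("only ", length(chosen), " frames satisfy the ", bandwidth,
          " separation constraint; requested ", n_seeds)
  chosen
}

#' Locate the spectral gap in an eigenvalue sequence
#'
#' Returns the index `g` maximizing the drop `lambda_g - lambda_{g+1}` over
#' the nontrivial spectrum; the analysis pipeline then retains the first `g`
#' components.  The first occurrence wins on ties.
#'
#' @param eigenvalues numeric vector, descending, length >= 3.
#' @return Integer index of the gap.
#' @examples
#' spectral_gap(c(0.9, 0.8, 0.2, 0.1))  # 2
#' @export
spectral_gap <- function(eigenvalues) {
  if (length(eigenvalues) < 3L) stop2("need at least 3 eigenvalues")
  drops <- -diff(eigenvalues)
  if (diff(range(eigenvalues)) < 1e-12)
    stop2("no gap: the spectrum is constant")
  which.max(drops)
}

#' Principal angles between the leading tIC subspaces of two models
#'
#' Used to check robustness of the slow-mode identification to the lag-time
#' range: the leading subspaces of models fitted with different ranges on the
#' same data should nearly coincide.  Because tIC coefficient vectors are
#' normalized under the covariance metric (`v' C(0) v = 1`) and feature
#' variances can differ by orders of magnitude, the angles are computed in
#' the `C(0)` inner product of the supplied data, not the Euclidean one.
#'
#' @param model1,model2 `"tic_model"` objects fitted on the same features.
#' @param features the data whose instantaneous covariance defines the
#'   metric (typically the common training data).
#' @param n_components subspace dimension to compare.
#' @return Principal angles in degrees, ascending.
#' @export
subspace_angles <- function(model1, model2, features, n_components) {
  fm <- combine_features(features)
  Xc <- sweep(fm$values, 2L, colMeans(fm$values))
  C0 <- crossprod(Xc) / nrow(Xc)
  V1 <- model1$eigenvectors[, seq_len(n_components), drop = FALSE]
  V2 <- model2$eigenvectors[, seq_len(n_components), drop = FALSE]
  # orthonormalize each basis under the C0 metric, then take principal angles
  U <- chol(C0)
  Q1 <- qr.Q(qr(U %*% V1))
  Q2 <- qr.Q(qr(U %*% V2))
  s <- svd(crossprod(Q1, Q2))$d
  sort(deg(acos(pmin(pmax(abs(s), -1), 1))))
}

#' One round of the adaptive sample-expand loop
#'
#' Mirrors the iterative sampling strategy: fit IVAC on the cumulative data,
#' project, pick seed frames from poorly sampled regions, and (in place of
#' running new MD) generate fresh synthetic trajectories whose hidden chains
#' start from the hidden state underlying each selected frame.
#'
#' @param spec a [hidden_state_spec()] used to generate continuation data.
#' @param features cumulative `feature_matrix` (or list).
#' @param ground_truth ground truth of the cumulative data (for the hidden
#'   state of each seed frame).
#' @param residue_selection selection used for featurization of the new data.
#' @param lag_min,lag_max,n_components IVAC settings.
#' @param n_seeds,n_frames seeds to select / frames per new trajectory.
#' @param seed RNG seed.
#' @return List with `model`, `seed_frames`, and `new` (the freshly generated
#'   `generate_ensemble()` result whose chains start at the seed states).
#' @export
expand_sampling <- function(spec, features, ground_truth, residue_selection,
                            lag_min, lag_max, n_components = 3L,
                            n_seeds = 14L, n_frames = 1000L, seed = 1L) {
  model <- fit_ivac(features, lag_min, lag_max)
  Y <- project_tics(model, features, n_components)
  picks <- select_seeds(Y, n_seeds = n_seeds, seed = seed)
  all_states <- unlist(ground_truth$state_sequence)
  start_states <- all_states[picks]
  new <- generate_ensemble_from_states(spec, start_states, n_frames,
                                       seed = seed + 1L)
  list(model = model, seed_frames = picks, new = new)
}

# Like generate_ensemble() but with fixed initial hidden states.
generate_ensemble_from_states <- function(spec, start_states, n_frames, seed) {
  set.seed(as.integer(seed))
  P <- spec$transition_matrix
  cum <- t(apply(P, 1L, cumsum))
  n_states <- spec$n_states
  n_atoms <- spec$topology$n_atoms
  tpl <- array(NA_real_, c(n_states, n_atoms, 3L))
  for (s in seq_len(n_states)) tpl[s, , ] <- spec$templates[[s]]
  coords <- vector("list", length(start_states))
  seqs <- vector("list", length(start_states))
  for (t in seq_along(start_states)) {
    states <- integer(n_frames)
    states[1L] <- start_states[t]
    if (n_frames > 1L) {
      u <- stats::runif(n_frames - 1L)
      for (f in 2L:n_frames)
        states[f] <- min(findInterval(u[f - 1L], cum[states[f - 1L], ],
                                      left.open = TRUE) + 1L, n_states)
    }
    a <- tpl[states, , , drop = FALSE]
    if (spec$noise_sigma > 0)
      a <- a + stats::rnorm(length(a), 0, spec$noise_sigma)
    coords[[t]] <- a
    seqs[[t]] <- states
  }
  list(ensemble = traj_ensemble(spec$topology, coords, spec$frame_interval),
       ground_truth = list(state_sequence = seqs,
                           true_populations = stationary_distribution(P),
                           true_timescales = chain_timescales(P),
                           true_hb_pattern = attr(spec, "hb_pattern")))
}
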