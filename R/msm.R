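#' Microstate clustering by seeded k-means
#'
#' Clusters projected tIC coordinates into `k` microstates: k-means++
#' initialization (seeded, hence deterministic) followed by standard Lloyd
#' iterations via [stats::kmeans()].  Every frame is then (re)assigned to its
#' nearest final center so the assignment invariant holds exactly.
#'
#' @param projected frames x g matrix (e.g. from [project_tics()]); an
#'   attached `"boundaries"` attribute (frames per trajectory) is carried
#'   into the result for the transition counting downstream.
#' @param k number of microstates (`k <=` frames).
#' @param seed RNG seed for the k-means++ initialization.
#' @param max_iter Lloyd iteration cap.
#' @return `"microstate_model"`: `centers` (k x g), `assignments` (per-frame
#'   1-based microstate index), `k`, `seed`, `boundaries`, `inertia`.
#' @export
kmeans_cluster <- function(projected, k = 1000L, seed = 1L, max_iter = 100L) {
  X <- as.matrix(projected)
  n <- nrow(X)
  if (!is_count(k) || k > n) stop2("k must be an integer in 1..", n, " (frames)")
  set.seed(as.integer(seed))

  # k-means++ seeding
  centers <- matrix(NA_real_, k, ncol(X))
  i <- sample.int(n, 1L)
  centers[1L, ] <- X[i, ]
  d2 <- rowSums(sweep(X, 2L, centers[1L, ])^2)
  if (k > 1L) for (j in 2L:k) {
    if (all(d2 <= 0)) i <- sample.int(n, 1L)
    else i <- sample.int(n, 1L, prob = d2)
    centers[j, ] <- X[i, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2L, centers[j, ])^2))
  }

  km <- suppressWarnings(stats::kmeans(X, centers = centers,
                                       iter.max = max_iter,
                                       algorithm = "Lloyd"))
  centers <- km$centers
  assign <- nearest_center(X, centers)
  inertia <- sum(rowSums((X - centers[assign, , drop = FALSE])^2))
  structure(list(centers = centers, assignments = assign, k = k,
                 seed = seed, boundaries = attr(projected, "boundaries"),
                 inertia = inertia),
            class = "microstate_model")
}

nearest_center <- function(X, centers) {
  cn <- rowSums(centers^2)
  block <- 50000L
  out <- integer(nrow(X))
  for (s in seq(1L, nrow(X), by = block)) {
    e <- min(s + block - 1L, nrow(X))
    G <- X[s:e, , drop = FALSE] %*% t(centers)
    out[s:e] <- max.col(sweep(G, 2L, cn / 2), ties.method = "first")
  }
  out
}

#' @export
print.microstate_model <- function(x, ...) {
  cat("microstate_model:", x$k, "microstates,", length(x$assignments),
      "frames, inertia", signif(x$inertia, 5L), "\n")
  invisible(x)
}

# Resolve assignments + per-trajectory boundaries from the accepted inputs.
resolve_assignments <- function(assignments) {
  if (inherits(assignments, "microstate_model")) {
    b <- assignments$boundaries %||% length(assignments$assignments)
    return(list(a = assignments$assignments, boundaries = b))
  }
  if (is.list(assignments))
    return(list(a = unlist(assignments),
                boundaries = vapply(assignments, length, integer(1))))
  b <- attr(assignments, "boundaries") %||% length(assignments)
  list(a = as.integer(assignments), boundaries = b)
}

#' Estimate a Markov state model from microstate assignments
#'
#' Transition counts are collected with a sliding window at the given lag
#' within each trajectory (pairs never straddle trajectory boundaries).  The
#' default `symmetrized` estimator row-normalizes `(C + C')/2`, which
#' guarantees detailed balance and a real spectrum (the assumption behind the
#' metastable coarse-graining); `naive` row-normalizes the raw counts.  The
#' model is restricted to the largest strongly connected set of the count
#' graph (largest by frame count); dropped microstates are recorded.
#'
#' @param assignments a `"microstate_model"`, a list of per-trajectory
#'   integer vectors, or an integer vector with a `"boundaries"` attribute.
#' @param lag lag time in frames.
#' @param mode `"symmetrized"` (default) or `"naive"`.
#' @return `"markov_model"`: `lag`, `count_matrix` (raw counts on the
#'   connected set), `transition_matrix`, `stationary`, `eigenvalues`
#'   (descending), `right_vectors`, `connected_set` (original microstate
#'   ids), `dropped`, `mode`, `n_states`.
#' @export
estimate_msm <- function(assignments, lag, mode = c("symmetrized", "naive")) {
  mode <- match.arg(mode)
  ra <- resolve_assignments(assignments)
  if (!is_count(lag)) stop2("lag must be a positive integer (frames)")
  if (all(ra$boundaries <= lag))
    stop2("lag = ", lag, " is not shorter than any trajectory (lengths: ",
          paste(ra$boundaries, collapse = ", "), ")")
  k <- max(ra$a)
  C <- matrix(0, k, k)
  for (r in split_by_boundaries(ra$boundaries)) {
    n <- length(r)
    if (n <= lag) next
    from <- ra$a[r[1:(n - lag)]]
    to <- ra$a[r[(1 + lag):n]]
    tab <- table(factor(from, levels = 1:k), factor(to, levels = 1:k))
    C <- C + unclass(tab)
  }
  dimnames(C) <- NULL

  # largest strongly connected set (by frames) of the count graph
  g <- igraph::graph_from_adjacency_matrix(C > 0, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  occupied <- tabulate(ra$a, nbins = k)
  comp_frames <- vapply(seq_len(comp$no),
                        function(i) sum(occupied[comp$membership == i]),
                        numeric(1))
  keep <- which(comp$membership == which.max(comp_frames))
  keep <- keep[rowSums(C[keep, keep, drop = FALSE]) > 0]
  if (length(keep) == 0L) stop2("empty connected set at lag ", lag)
  dropped <- setdiff(which(occupied > 0), keep)
  Ck <- C[keep, keep, drop = FALSE]

  if (mode == "symmetrized") {
    Cs <- (Ck + t(Ck)) / 2
    T_ <- Cs / rowSums(Cs)
    pi_ <- rowSums(Cs) / sum(Cs)
    # similarity transform to a symmetric matrix => real spectrum
    s <- sqrt(pi_)
    S <- T_ * outer(s, 1 / s)
    S <- (S + t(S)) / 2
    e <- eigen(S, symmetric = TRUE)
    lam <- e$values
    R <- e$vectors / s   # right eigenvectors of T
  } else {
    T_ <- Ck / rowSums(Ck)
    e <- eigen(T_)
    ord <- order(Re(e$values), decreasing = TRUE)
    lam <- e$values[ord]
    R <- e$vectors[, ord, drop = FALSE]
    pi_ <- stationary_distribution(T_)
  }

  structure(list(lag = lag, count_matrix = Ck, transition_matrix = T_,
                 stationary = pi_, eigenvalues = lam, right_vectors = R,
                 connected_set = keep, dropped = dropped, mode = mode,
                 n_states = length(keep)),
            class = "markov_model")
}

#' @export
print.markov_model <- function(x, ...) {
  cat("markov_model:", x$n_states, "states, lag", x$lag, "frames,",
      x$mode, "estimator")
  if (length(x$dropped) > 0L)
    cat(",", length(x$dropped), "states outside the connected set")
  cat("\n")
  invisible(x)
}

#' Implied relaxation timescales
#'
#' `t_i = -lag / log |lambda_{i+1}|` for the leading nontrivial eigenvalues,
#' in frame units, descending.  Eigenvalues at (or numerically above) one
#' give `Inf`; non-positive eigenvalues have no defined timescale and are
#' reported as `NA`.
#'
#' @param model a `"markov_model"`.
#' @param n number of timescales.
#' @return Numeric vector of length `n`.
#' @export
implied_timescales <- function(model, n = 5L) {
  lam <- model$eigenvalues
  if (length(lam) < n + 1L)
    stop2("model has only ", length(lam), " eigenvalues; need n + 1 = ", n + 1L)
  lam <- lam[-1L][seq_len(n)]
  lam_re <- Re(lam)
  ts <- rep(NA_real_, n)
  pos <- !is.na(lam_re) & lam_re > 0 & abs(Im(lam)) < 1e-10
  ts[pos & lam_re >= 1 - 1e-12] <- Inf
  use <- pos & lam_re < 1 - 1e-12
  ts[use] <- -model$lag / log(lam_re[use])
  ts
}

#' Chapman-Kolmogorov test
#'
#' Validates Markovity: for each factor `f`, the set-to-set transition
#' probabilities predicted by propagating the model, `T(lag)^f`, are compared
#' with those of a model re-estimated at lag `f * lag`.  Set-to-set
#' probabilities are stationary-weighted:
#' `p_AB = sum_{i in A} (pi_i / pi_A) [T]_{i, j in B}`.  At `f = 1` both
#' sides coincide and the deviation is exactly zero.
#'
#' Standard errors use effective (non-overlapping-window) counts
#' `n_A / (f * lag)` because sliding-window transition pairs are serially
#' correlated.
#'
#' @param assignments as in [estimate_msm()].
#' @param macro_sets list of integer vectors of microstate indices (states as
#'   labeled in `assignments`).
#' @param lag base lag in frames.
#' @param factors integer factors (`>= 1`) at which to test.
#' @param mode estimator mode, as in [estimate_msm()].
#' @return Data frame with columns `factor`, `from_set`, `to_set`,
#'   `p_model`, `p_estimated`, `deviation`, `se`.
#' @export
ck_test <- function(assignments, macro_sets, lag, factors = 2:5,
                    mode = "symmetrized") {
  if (any(factors < 1L)) stop2("factors must be >= 1")
  base <- estimate_msm(assignments, lag, mode = mode)
  ra <- resolve_assignments(assignments)

  set_prob <- function(model, Tpow, sets) {
    # map original microstate ids to the model's connected-set rows
    pos <- match(seq_len(max(unlist(sets))), model$connected_set)
    out <- matrix(NA_real_, length(sets), length(sets))
    for (a in seq_along(sets)) {
      ia <- pos[sets[[a]]]; ia <- ia[!is.na(ia)]
      if (length(ia) == 0L) next
      w <- model$stationary[ia]; w <- w / sum(w)
      row <- as.numeric(w %*% Tpow[ia, , drop = FALSE])
      for (b in seq_along(sets)) {
        ib <- pos[sets[[b]]]; ib <- ib[!is.na(ib)]
        out[a, b] <- sum(row[ib])
      }
    }
    out
  }

  res <- NULL
  for (f in sort(unique(as.integer(factors)))) {
    if (all(ra$boundaries <= f * lag))
      stop2("insufficient data: no trajectory is longer than ", f, " * lag = ",
            f * lag, " frames")
    Tpow <- matpow(base$transition_matrix, f)
    p_model <- set_prob(base, Tpow, macro_sets)
    re <- estimate_msm(assignments, f * lag, mode = mode)
    p_est <- set_prob(re, re$transition_matrix, macro_sets)

    # effective start counts per set at the long lag
    npairs <- sum(pmax(ra$boundaries - f * lag, 0L))
    occ <- tabulate(ra$a, nbins = max(ra$a)) / length(ra$a)
    for (a in seq_along(macro_sets)) {
      n_a <- npairs * sum(occ[macro_sets[[a]]])
      n_eff <- max(n_a / (f * lag), 1)
      for (b in seq_along(macro_sets)) {
        p <- p_est[a, b]
        res <- rbind(res, data.frame(
          factor = f, from_set = a, to_set = b,
          p_model = p_model[a, b], p_estimated = p,
          deviation = abs(p_model[a, b] - p),
          se = sqrt(max(p * (1 - p), 1e-12) / n_eff)))
      }
    }
  }
  res
}

matpow <- function(M, p) {
  R <- diag(nrow(M))
  while (p > 0) {
    if (p %% 2 == 1) R <- R %*% M
    M <- M %*% M
    p <- p %/% 2
  }
  R
}

#' Per-frame equilibrium weights
#'
#' Reweights frames so that weighted statistics are equilibrium expectations:
#' a frame assigned to microstate `s` gets weight `pi_s / n_s` where `n_s` is
#' the number of frames in `s`.  Frames in microstates outside the model's
#' connected set get weight 0 (their count is reported via a message).
#' Weights sum to one.
#'
#' @param model a `"markov_model"`.
#' @param assignments as in [estimate_msm()] (same state labeling as used to
#'   build the model).
#' @return Numeric per-frame weight vector.
#' @export
frame_weights <- function(model, assignments) {
  ra <- resolve_assignments(assignments)
  a <- ra$a
  k <- max(a)
  counts <- tabulate(a, nbins = k)
  w_state <- numeric(k)
  pos <- match(seq_len(k), model$connected_set)
  in_set <- !is.na(pos)
  w_state[in_set] <- model$stationary[pos[in_set]] / counts[in_set]
  out <- w_state[a]
  n_dropped <- sum(!in_set[a])
  if (n_dropped > 0L)
    message(n_dropped, " frame(s) in microstates outside the connected set ",
            "received zero weight")
  out / sum(out)
}
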