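#' Perron cluster analysis (PCCA) of a Markov state model
#'
#' Groups microstates into `m` metastable macro-clusters from the `m` leading
#' right eigenvectors of the transition matrix, using the robust
#' simplex-vertex construction: the eigenvector rows lie (approximately) in a
#' simplex whose vertices correspond to the metastable sets; `m` rows
#' spanning that simplex are located by successive orthogonal
#' farthest-point search, and the fuzzy memberships are the barycentric
#' coordinates of every row (clipped at zero and row-renormalized).  On an
#' uncoupled block chain this degenerates to exact 0/1 indicators.  Crisp
#' labels are the argmax memberships.
#'
#' Macro-clusters are relabeled `0 .. m-1` in order of decreasing stationary
#' population (ties broken by ascending original label).
#'
#' @param model a `"markov_model"`; must have a real spectrum (use the
#'   symmetrized estimator).
#' @param m number of macro-clusters (`m <=` number of eigenvalues).
#' @param im_tol tolerance on imaginary parts of the leading spectrum.
#' @return `"macro_clustering"`: `m`, `membership` (k x m, rows sum to 1,
#'   columns in population order), `crisp_labels` (per-microstate, 0-based,
#'   population order), `populations` (descending, sums to 1),
#'   `connected_set` (microstate ids the labels refer to), `micro_pi`.
#' @export
pcca <- function(model, m, im_tol = 1e-8) {
  if (!inherits(model, "markov_model")) stop2("model must be a markov_model")
  k <- model$n_states
  if (!is_count(m, min = 2L) || m > k)
    stop2("m must be an integer in 2..", k)
  lam <- model$eigenvalues[seq_len(m)]
  if (any(abs(Im(lam)) > im_tol))
    stop2("complex eigenvalues in the leading spectrum; ",
          "re-estimate the model with mode = \"symmetrized\"")
  X <- Re(model$right_vectors[, seq_len(m), drop = FALSE])
  X[, 1L] <- 1  # the Perron eigenvector is constant; fix its scale exactly

  # simplex-vertex search (successive orthogonal farthest point)
  ind <- integer(m)
  ortho <- X
  ind[1L] <- which.max(row_norms(ortho))
  ortho <- sweep(ortho, 2L, ortho[ind[1L], ])
  for (j in seq_len(m - 1L)) {
    v <- ortho[ind[j], ]
    nv <- sqrt(sum(v^2))
    if (nv > 0) {
      v <- v / nv
      ortho <- ortho - (ortho %*% v) %*% t(v)
    }
    ind[j + 1L] <- which.max(row_norms(ortho))
  }

  A <- solve(X[ind, , drop = FALSE])
  chi <- X %*% A
  chi[chi < 0] <- 0
  chi <- chi / rowSums(chi)

  crisp <- max.col(chi, ties.method = "first")
  pops <- vapply(seq_len(m), function(j) sum(model$stationary[crisp == j]),
                 numeric(1))
  ord <- order(-pops, seq_len(m))  # descending population, ties by label
  relabel <- match(seq_len(m), ord)

  structure(list(m = m,
                 membership = chi[, ord, drop = FALSE],
                 crisp_labels = relabel[crisp] - 1L,
                 populations = pops[ord],
                 connected_set = model$connected_set,
                 micro_pi = model$stationary),
            class = "macro_clustering")
}

#' @export
print.macro_clustering <- function(x, ...) {
  cat("macro_clustering:", x$m, "clusters over", length(x$crisp_labels),
      "microstates\npopulations:",
      paste(signif(x$populations, 3L), collapse = ", "), "\n")
  invisible(x)
}

#' Macro-cluster populations
#'
#' Population of macro-cluster `A` is the sum of the stationary probabilities
#' of its microstates (crisp assignment); clusters are reported in descending
#' population order, matching the clustering's `0 .. m-1` labels.
#'
#' @param clustering a `"macro_clustering"`.
#' @param pi optional stationary vector over the clustering's microstates
#'   (defaults to the one stored at construction).
#' @return Named numeric vector (`"0"`, `"1"`, ...), sums to 1.
#' @export
macro_populations <- function(clustering, pi = NULL) {
  pi <- pi %||% clustering$micro_pi
  if (length(pi) != length(clustering$crisp_labels))
    stop2("pi has length ", length(pi), "; clustering covers ",
          length(clustering$crisp_labels), " microstates")
  pops <- vapply(0:(clustering$m - 1L),
                 function(j) sum(pi[clustering$crisp_labels == j]), numeric(1))
  names(pops) <- as.character(0:(clustering$m - 1L))
  pops
}

#' Equilibrium fluxes between macro-clusters
#'
#' The stationary probability mass flowing from macro-cluster `A` to `B` per
#' lag step: `F_AB = sum_{i in A, j in B} pi_i T_ij` (crisp labels, diagonal
#' zero).  For a reversible model the flux matrix is symmetric.  Also
#' reported: each flux as a fraction of the maximum flux, and the highlight
#' set of edges carrying at least 25 percent of the maximum.
#'
#' @param clustering a `"macro_clustering"`.
#' @param model the `"markov_model"` it was built from.
#' @param highlight_frac highlight threshold as a fraction of the maximum
#'   flux (default 0.25).
#' @return `"macro_flux"`: `flux` (m x m, per lag step), `normalized`,
#'   `highlighted` (logical), `lag` (frames).  `as.data.frame()` gives the
#'   edge list (source, target, flux, normalized, highlighted).
#' @export
macro_fluxes <- function(clustering, model, highlight_frac = 0.25) {
  if (model$n_states != length(clustering$crisp_labels))
    stop2("clustering and model cover different microstate sets")
  m <- clustering$m
  lab <- clustering$crisp_labels
  piT <- clustering$micro_pi * model$transition_matrix
  F_ <- matrix(0, m, m, dimnames = list(0:(m - 1L), 0:(m - 1L)))
  for (a in seq_len(m)) for (b in seq_len(m)) {
    if (a == b) next
    F_[a, b] <- sum(piT[lab == a - 1L, lab == b - 1L])
  }
  fmax <- max(F_)
  normalized <- if (fmax > 0) F_ / fmax else F_
  structure(list(flux = F_, normalized = normalized,
                 highlighted = normalized >= highlight_frac & F_ > 0,
                 lag = model$lag),
            class = "macro_flux")
}

#' @export
print.macro_flux <- function(x, ...) {
  cat("macro_flux:", nrow(x$flux), "clusters, max flux",
      signif(max(x$flux), 4L), "per", x$lag, "-frame lag step\n")
  invisible(x)
}

#' @export
as.data.frame.macro_flux <- function(x, ...) {
  m <- nrow(x$flux)
  idx <- which(upper.tri(x$flux) | lower.tri(x$flux), arr.ind = TRUE)
  data.frame(source = idx[, 1L] - 1L, target = idx[, 2L] - 1L,
             flux = x$flux[idx], normalized = x$normalized[idx],
             highlighted = x$highlighted[idx])
}

#' Map per-frame microstate assignments to macro-cluster labels
#'
#' Frames whose microstate fell outside the model's connected set get `NA`.
#'
#' @param clustering a `"macro_clustering"`.
#' @param assignments as in [estimate_msm()].
#' @return Integer vector of 0-based macro labels per frame (`NA` outside the
#'   connected set).
#' @export
frame_macro_labels <- function(clustering, assignments) {
  ra <- resolve_assignments(assignments)
  pos <- match(ra$a, clustering$connected_set)
  out <- rep(NA_integer_, length(ra$a))
  ok <- !is.na(pos)
  out[ok] <- clustering$crisp_labels[pos[ok]]
  out
}
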