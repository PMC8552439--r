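#' Hidden-state specification for the synthetic trajectory generator
#'
#' Defines a hidden discrete-state Markov chain together with one coordinate
#' template per state.  Frames are emitted as the template of the current
#' hidden state plus isotropic Gaussian noise, so the slow kinetics, the
#' metastable populations and the per-site hydrogen-bond patterns of the
#' generated ensemble are all known exactly in advance.
#'
#' @param transition_matrix `n_states x n_states` row-stochastic matrix of
#'   per-frame-step transition probabilities.
#' @param topology shared [topology()] of all templates (includes the
#'   water-oxygen pseudo-atoms; there is no explicit solvent dynamics).
#' @param templates list of `n_atoms x 3` coordinate matrices (nm), one per
#'   hidden state.
#' @param noise_sigma standard deviation of the iid Gaussian coordinate noise
#'   (nm); must be `>= 0`.
#' @param frame_interval time per frame step (ps).
#' @return An object of class `"hidden_state_spec"`.
#' @seealso [toy_chain_spec()] for a ready-made specification,
#'   [generate_ensemble()] to sample from one.
#' @export
hidden_state_spec <- function(transition_matrix, topology, templates,
                              noise_sigma = 0.02, frame_interval = 10) {
  check_stochastic(transition_matrix)
  n_states <- nrow(transition_matrix)
  if (!inherits(topology, "topology")) stop2("topology must be a topology object")
  if (length(templates) != n_states)
    stop2("need one template per state: got ", length(templates),
          " templates for ", n_states, " states")
  for (s in seq_len(n_states)) {
    tpl <- templates[[s]]
    if (!is.matrix(tpl) || ncol(tpl) != 3L || nrow(tpl) != topology$n_atoms)
      stop2("template for state ", s, " does not match the shared topology (",
            topology$n_atoms, " atoms x 3)")
  }
  if (!is.numeric(noise_sigma) || noise_sigma < 0)
    stop2("noise_sigma must be >= 0")
  structure(list(n_states = n_states, transition_matrix = transition_matrix,
                 topology = topology, templates = templates,
                 noise_sigma = noise_sigma, frame_interval = frame_interval),
            class = "hidden_state_spec")
}

#' Stationary distribution of a row-stochastic matrix
#'
#' Left eigenvector for eigenvalue 1, normalized to sum to one.  The chain
#' must be irreducible (one strongly connected communication class); for a
#' reducible chain the error message names the disconnected blocks.
#'
#' @param transition_matrix row-stochastic square matrix.
#' @return Probability vector of length `nrow(transition_matrix)`.
#' @examples
#' stationary_distribution(matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE))
#' @export
stationary_distribution <- function(transition_matrix) {
  check_stochastic(transition_matrix, tol = 1e-10)
  g <- igraph::graph_from_adjacency_matrix(transition_matrix > 0, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  if (comp$no > 1L) {
    blocks <- split(seq_len(nrow(transition_matrix)), comp$membership)
    stop2("chain is reducible; disconnected blocks: ",
          paste(vapply(blocks, function(b) paste0("{", paste(b, collapse = ","), "}"),
                       ""), collapse = " "))
  }
  e <- eigen(t(transition_matrix))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  if (any(v < -1e-10)) stop2("failed to find a nonnegative stationary vector")
  pmax(v, 0) / sum(pmax(v, 0))
}

# Relaxation timescales of a transition matrix, in frame-step units:
# -1/log|lambda_i| for the nontrivial eigenvalues, sorted descending.
chain_timescales <- function(transition_matrix) {
  lam <- eigen(transition_matrix, only.values = TRUE)$values
  lam <- sort(Mod(lam), decreasing = TRUE)[-1L]
  ts <- ifelse(lam >= 1, Inf, ifelse(lam <= 0, NA_real_, -1 / log(lam)))
  sort(ts, decreasing = TRUE, na.last = TRUE)
}

#' Generate a synthetic trajectory ensemble with known ground truth
#'
#' Simulates `n_traj` independent realizations of the hidden chain, each of
#' `n_frames` frames, starting from the stationary distribution (so empirical
#' occupancies are unbiased estimates of the true populations), and emits
#' coordinates as state template plus iid Gaussian noise.  Identical seeds
#' give bit-identical output.
#'
#' @param spec a [hidden_state_spec()].
#' @param n_traj number of trajectories.
#' @param n_frames frames per trajectory (`>= 2`).
#' @param seed integer RNG seed.
#' @param initial initial-state distribution; `NULL` (default) draws from the
#'   stationary distribution (requires an irreducible chain), otherwise a
#'   probability vector over states (allows reducible, e.g. absorbing,
#'   chains).
#' @return List with `ensemble` (a [traj_ensemble()]) and `ground_truth`, a
#'   list holding `state_sequence` (per-trajectory integer vectors, 1-based),
#'   `true_populations`, `true_timescales` (frame units, descending) and
#'   `true_hb_pattern` (when the spec carries one, see [toy_chain_spec()]).
#' @export
generate_ensemble <- function(spec, n_traj, n_frames, seed, initial = NULL) {
  if (!inherits(spec, "hidden_state_spec")) stop2("spec must be a hidden_state_spec")
  if (!is_count(n_traj)) stop2("n_traj must be a positive integer")
  if (!is_count(n_frames, min = 2L)) stop2("n_frames must be an integer >= 2")
  set.seed(as.integer(seed))
  P <- spec$transition_matrix
  n_states <- spec$n_states
  if (is.null(initial)) {
    pops <- stationary_distribution(P)
    start <- pops
  } else {
    if (length(initial) != n_states || any(initial < 0) ||
        abs(sum(initial) - 1) > 1e-8)
      stop2("initial must be a probability vector over the ", n_states, " states")
    start <- initial
    pops <- tryCatch(stationary_distribution(P), error = function(e) NULL)
  }
  cum <- t(apply(P, 1L, cumsum))
  n_atoms <- spec$topology$n_atoms

  # templates stacked for fast frame lookup
  tpl <- array(NA_real_, c(n_states, n_atoms, 3L))
  for (s in seq_len(n_states)) tpl[s, , ] <- spec$templates[[s]]

  coords <- vector("list", n_traj)
  seqs <- vector("list", n_traj)
  for (t in seq_len(n_traj)) {
    states <- integer(n_frames)
    states[1L] <- sample.int(n_states, 1L, prob = start)
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

  list(
    ensemble = traj_ensemble(spec$topology, coords, spec$frame_interval),
    ground_truth = list(
      state_sequence = seqs,
      true_populations = pops,
      true_timescales = chain_timescales(P),
      true_hb_pattern = attr(spec, "hb_pattern")
    )
  )
}

#' Toy-chain hidden-state specification
#'
#' Builds a complete [hidden_state_spec()] for a toy polypeptide of `n_res`
#' residues in chain `A`, each carrying backbone N, H, CA, C, O atoms plus
#' two side-chain oxygens (`OG`, `OD`; protein hydrogen-bond acceptors) and
#' two water-oxygen pseudo-atoms per residue.  The backbone lies along x
#' with 0.8 nm residue spacing, far enough apart that no hydrogen bond forms
#' by accident under any of the supported geometric criteria (donor-acceptor
#' distance up to 0.6 nm, donor-vertex angle up to 90 degrees).
#'
#' Per state and per site, the count matrices `hb_p` and `hb_w` (values 0, 1
#' or 2) place that many acceptors at ideal bonding geometry (about 0.28-0.31
#' nm from the amide N, nearly collinear with the N--H) and the rest far
#' away, so the expected hydrogen-bond counts of every site in every state
#' are exactly the requested pattern.  States additionally displace the
#' C-terminal half of the chain rigidly by `state_shift * (s - 1)` nm along a
#' state-specific direction, so the hidden state is visible in the pairwise
#' C-alpha distances and the slow modes of the chain are recoverable
#' downstream.
#'
#' @param transition_matrix row-stochastic matrix; its size sets the number of
#'   hidden states.
#' @param n_res residues in the toy chain.
#' @param hb_p,hb_w `n_states x n_res` matrices with values in `{0, 1, 2}`:
#'   expected protein/water hydrogen-bond count of each site in each state.
#'   Default: no bonds.
#' @param state_shift base magnitude (nm) of the per-state rigid displacement
#'   of the chain's C-terminal half.
#' @param noise_sigma,frame_interval passed to [hidden_state_spec()].
#' @return A [hidden_state_spec()]; the ground-truth hydrogen-bond pattern is
#'   attached and propagated by [generate_ensemble()].
#' @export
toy_chain_spec <- function(transition_matrix, n_res = 6L,
                           hb_p = NULL, hb_w = NULL,
                           state_shift = 0.4, noise_sigma = 0.01,
                           frame_interval = 10) {
  check_stochastic(transition_matrix)
  n_states <- nrow(transition_matrix)
  hb_p <- hb_p %||% matrix(0L, n_states, n_res)
  hb_w <- hb_w %||% matrix(0L, n_states, n_res)
  stopifnot(all(dim(hb_p) == c(n_states, n_res)),
            all(dim(hb_w) == c(n_states, n_res)),
            all(hb_p %in% 0:2), all(hb_w %in% 0:2))

  spacing <- 0.8
  res_atoms <- c("N", "H", "CA", "C", "O", "OG", "OD")
  na_res <- length(res_atoms)
  atoms <- data.frame(
    chain = c(rep("A", n_res * na_res), rep("W", 2L * n_res)),
    resno = c(rep(seq_len(n_res), each = na_res), seq_len(2L * n_res)),
    resname = c(rep("GLY", n_res * na_res), rep("HOH", 2L * n_res)),
    name = c(rep(res_atoms, times = n_res), rep("O", 2L * n_res)),
    elem = c(rep(c("N", "H", "C", "C", "O", "O", "O"), times = n_res),
             rep("O", 2L * n_res)),
    stringsAsFactors = FALSE)
  top <- topology(atoms)

  base <- matrix(NA_real_, top$n_atoms, 3L)
  for (r in seq_len(n_res)) {
    x <- spacing * (r - 1L)
    o <- (r - 1L) * na_res
    base[o + 1L, ] <- c(x, 0, 0)          # N
    base[o + 2L, ] <- c(x, 0.10, 0)       # H, amide hydrogen along +y
    base[o + 3L, ] <- c(x + 0.15, 0, 0)   # CA
    base[o + 4L, ] <- c(x + 0.30, 0, 0)   # C
    base[o + 5L, ] <- c(x + 0.30, -0.45, 0) # O, points away from the N-H
  }

  tail_res <- seq.int(ceiling(n_res / 2) + 1L, n_res)
  nprot <- n_res * na_res
  templates <- vector("list", n_states)
  for (s in seq_len(n_states)) {
    tpl <- base
    for (r in seq_len(n_res)) {
      x <- spacing * (r - 1L)
      o <- (r - 1L) * na_res
      tpl[o + 6L, ] <- if (hb_p[s, r] >= 1) c(x, 0.28, 0) else c(x, -0.60, 0.60)
      tpl[o + 7L, ] <- if (hb_p[s, r] >= 2) c(x, 0.275, -0.06) else c(x, -0.60, -0.60)
      w1 <- nprot + 2L * (r - 1L) + 1L
      w2 <- w1 + 1L
      tpl[w1, ] <- if (hb_w[s, r] >= 1) c(x, 0.30, 0.05) else c(x, 0.90, -0.50)
      tpl[w2, ] <- if (hb_w[s, r] >= 2) c(x, 0.295, 0.10) else c(x, 0.90, 0.50)
    }
    if (s > 1L && length(tail_res) > 0L) {
      # distinct magnitude AND direction per state, with an axial (x)
      # component on alternating states: the displacement then enters the
      # inter-block distances both linearly and quadratically, so the state
      # centroids span n_states - 1 dimensions of feature space instead of
      # collapsing onto a single |shift| coordinate
      theta <- pi * (s - 1L) / n_states
      u <- c(0.5 * ((s - 1L) %% 2L), sin(theta), cos(theta))
      u <- u / sqrt(sum(u^2))
      shift <- state_shift * (s - 1L) * u
      for (r in tail_res) {
        o <- (r - 1L) * na_res
        rows <- c(o + seq_len(na_res), nprot + 2L * (r - 1L) + 1:2)
        tpl[rows, ] <- sweep(tpl[rows, , drop = FALSE], 2L, shift, `+`)
      }
    }
    templates[[s]] <- tpl
  }

  spec <- hidden_state_spec(transition_matrix, top, templates,
                            noise_sigma = noise_sigma,
                            frame_interval = frame_interval)
  attr(spec, "hb_pattern") <- list(hb_p = hb_p, hb_w = hb_w)
  spec
}

#' Write the ground truth of a synthetic ensemble as CSV
#'
#' @param ground_truth the `ground_truth` element of [generate_ensemble()].
#' @param dir output directory.
#' @return Invisibly, the paths written.
#' @export
write_ground_truth <- function(ground_truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seq_path <- file.path(dir, "state_sequence.csv")
  df <- do.call(rbind, lapply(seq_along(ground_truth$state_sequence), function(t) {
    s <- ground_truth$state_sequence[[t]]
    data.frame(traj = t, frame = seq_along(s), state = s)
  }))
  utils::write.csv(df, seq_path, row.names = FALSE)
  pop_path <- file.path(dir, "populations.csv")
  utils::write.csv(data.frame(state = seq_along(ground_truth$true_populations),
                              population = ground_truth$true_populations,
                              stringsAsFactors = FALSE),
                   pop_path, row.names = FALSE)
  invisible(c(seq_path, pop_path))
}
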