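# Shared fixture builders and independent oracles.  Everything here is
# deliberately simple, brute-force code so the tests check the package
# implementation against an independent computation path.

# -- Markov chain simulation (independent of generate_ensemble) ---------------
sim_chain <- function(P, n, seed, start = NULL) {
  set.seed(seed)
  k <- nrow(P)
  pi0 <- start %||% stationary_distribution(P)
  s <- integer(n)
  s[1] <- sample.int(k, 1, prob = pi0)
  for (t in 2:n) s[t] <- sample.int(k, 1, prob = P[s[t - 1], ])
  s
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# -- random rigid transform ---------------------------------------------------
random_rotation <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

apply_rigid <- function(ensemble, R, shift) {
  ensemble$coords <- lapply(ensemble$coords, function(a) {
    out <- a
    for (f in seq_len(dim(a)[1])) {
      out[f, , ] <- matrix(a[f, , ], ncol = 3) %*% t(R) +
        matrix(shift, dim(a)[2], 3, byrow = TRUE)
    }
    out
  })
  ensemble
}

# -- a small random ensemble with protein + water atoms for hbond oracles -----
random_hbond_ensemble <- function(n_res = 10, n_wat = 20, n_frames = 10,
                                  seed = 1, box = 2) {
  set.seed(seed)
  res_atoms <- c("N", "H", "CA", "C", "O", "OG")
  atoms <- data.frame(
    chain = c(rep("A", n_res * length(res_atoms)), rep("W", n_wat)),
    resno = c(rep(seq_len(n_res), each = length(res_atoms)), seq_len(n_wat)),
    resname = c(rep("ALA", n_res * length(res_atoms)), rep("HOH", n_wat)),
    name = c(rep(res_atoms, times = n_res), rep("O", n_wat)),
    elem = c(rep(c("N", "H", "C", "C", "O", "O"), times = n_res),
             rep("O", n_wat)))
  top <- topology(atoms)
  coords <- array(runif(n_frames * top$n_atoms * 3, 0, box),
                  c(n_frames, top$n_atoms, 3))
  # keep each H 0.1 nm from its N so the donor geometry is sane
  for (s in seq_len(nrow(top$amide_sites))) {
    ni <- top$amide_sites$n_idx[s]; hi <- top$amide_sites$h_idx[s]
    for (f in seq_len(n_frames)) {
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      coords[f, hi, ] <- coords[f, ni, ] + 0.1 * u
    }
  }
  traj_ensemble(top, list(coords), 10)
}

# Brute-force all-pairs hydrogen-bond oracle (its own geometry code).
brute_hbond_oracle <- function(ensemble, dist_cut, ang_cut,
                               include_self = TRUE) {
  top <- ensemble$topology
  am <- top$amide_sites
  a <- ensemble$coords[[1]]
  nf <- dim(a)[1]
  hb_p <- matrix(0L, nf, nrow(am))
  hb_w <- matrix(0L, nf, nrow(am))
  ang_between <- function(u, v) {
    cosv <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
    acos(max(min(cosv, 1), -1)) * 180 / pi
  }
  for (f in seq_len(nf)) {
    xyz <- matrix(a[f, , ], ncol = 3)
    for (s in seq_len(nrow(am))) {
      np <- xyz[am$n_idx[s], ]; hp <- xyz[am$h_idx[s], ]
      for (j in seq_len(top$n_atoms)) {
        at <- top$atoms[j, ]
        if (j == am$n_idx[s] || j == am$h_idx[s]) next
        is_acc_p <- !at$is_water && at$elem %in% c("O", "N")
        if (is_acc_p && !include_self &&
            at$chain == am$chain[s] && at$resno == am$resno[s]) is_acc_p <- FALSE
        is_acc_w <- at$is_water && at$elem == "O"
        if (!is_acc_p && !is_acc_w) next
        d <- sqrt(sum((xyz[j, ] - np)^2))
        if (d > dist_cut) next
        if (ang_between(hp - np, xyz[j, ] - np) > ang_cut) next
        if (is_acc_p) hb_p[f, s] <- hb_p[f, s] + 1L
        else hb_w[f, s] <- hb_w[f, s] + 1L
      }
    }
  }
  list(hb_p = hb_p, hb_w = hb_w)
}

# -- minimal single-site ensemble from explicit acceptor positions ------------
# One residue A1 (N at origin, H at (0, 0.1, 0)), optional protein acceptor
# atoms (element O, residue A2 unless self = TRUE) and water oxygens at the
# given positions.
single_site_ensemble <- function(protein_acc = NULL, water_acc = NULL,
                                 self_acc = NULL) {
  rows <- data.frame(chain = c("A", "A", "A"), resno = c(1, 1, 1),
                     resname = "GLY", name = c("N", "H", "CA"),
                     elem = c("N", "H", "C"))
  pos <- rbind(c(0, 0, 0), c(0, 0.1, 0), c(0.15, 0, 0))
  add <- function(rows, pos, p, chain, resno, resname, name) {
    list(rows = rbind(rows, data.frame(chain = chain, resno = resno,
                                       resname = resname, name = name,
                                       elem = "O")),
         pos = rbind(pos, p))
  }
  if (!is.null(self_acc)) for (i in seq_len(nrow(self_acc))) {
    r <- add(rows, pos, self_acc[i, ], "A", 1, "GLY", paste0("OG", i))
    rows <- r$rows; pos <- r$pos
  }
  if (!is.null(protein_acc)) for (i in seq_len(nrow(protein_acc))) {
    r <- add(rows, pos, protein_acc[i, ], "A", 2, "GLY", paste0("OX", i))
    rows <- r$rows; pos <- r$pos
  }
  if (!is.null(water_acc)) for (i in seq_len(nrow(water_acc))) {
    r <- add(rows, pos, water_acc[i, ], "W", i, "HOH", "O")
    rows <- r$rows; pos <- r$pos
  }
  top <- topology(rows)
  coords <- array(NA_real_, c(1, nrow(pos), 3))
  coords[1, , ] <- pos
  traj_ensemble(top, list(coords), 10)
}

# -- geometric alpha-helix fixture -------------------------------------------
# Parametric helix whose i -> i+4 carbonyl-amide geometry satisfies tight
# hydrogen-bond criteria exactly; used by the helix_content tests.
make_helix_ensemble <- function(n_res, chain = "A") {
  rise <- 0.15; radius <- 0.23; turn <- 100 * pi / 180
  ca <- t(vapply(seq_len(n_res), function(i)
    c(radius * cos(turn * i), radius * sin(turn * i), rise * i), numeric(3)))
  res_atoms <- c("N", "H", "CA", "C", "O")
  atoms <- data.frame(chain = chain,
                      resno = rep(seq_len(n_res), each = length(res_atoms)),
                      resname = "ALA",
                      name = rep(res_atoms, times = n_res),
                      elem = rep(c("N", "H", "C", "C", "O"), times = n_res))
  top <- topology(atoms)
  pos <- matrix(NA_real_, top$n_atoms, 3)
  o_pos <- matrix(NA_real_, n_res, 3)
  for (i in seq_len(n_res)) {
    u <- if (i + 4 <= n_res) ca[i + 4, ] - ca[i, ] else ca[i, ] - ca[i - 4, ]
    u <- u / sqrt(sum(u^2))
    o_pos[i, ] <- ca[i, ] + 0.45 * u
  }
  for (i in seq_len(n_res)) {
    o <- (i - 1) * length(res_atoms)
    pos[o + 1, ] <- ca[i, ]                         # N on the CA trace
    h_dir <- if (i > 4) {
      v <- o_pos[i - 4, ] - ca[i, ]; v / sqrt(sum(v^2))
    } else c(0, 0, -1)
    pos[o + 2, ] <- ca[i, ] + 0.1 * h_dir           # H toward O_{i-4}
    pos[o + 3, ] <- ca[i, ] + c(0.05, 0.05, 0)      # CA marker
    pos[o + 4, ] <- ca[i, ] + c(-0.05, 0.05, 0)     # C marker
    pos[o + 5, ] <- o_pos[i, ]                      # carbonyl O
  }
  coords <- array(NA_real_, c(1, top$n_atoms, 3))
  coords[1, , ] <- pos
  traj_ensemble(top, list(coords), 10)
}

# Construct the 4th atom of a dihedral quadruple at a prescribed angle.
place_dihedral <- function(p1, p2, p3, length, bond_angle_deg, dihedral_deg) {
  b1 <- p2 - p1; b2 <- p3 - p2
  b2n <- b2 / sqrt(sum(b2^2))
  n <- cross3_test(b1, b2); n <- n / sqrt(sum(n^2))
  m <- cross3_test(n, b2n)
  ang <- bond_angle_deg * pi / 180; dih <- dihedral_deg * pi / 180
  d <- c(-length * cos(ang), length * sin(ang) * cos(dih),
         length * sin(ang) * sin(dih))
  p3 + d[1] * b2n + d[2] * m + d[3] * n
}

cross3_test <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# Build a markov_model object directly from a known transition matrix, the
# same way the symmetrized estimator does (for PCCA tests on exact chains).
model_from_T <- function(T_, lag = 1L) {
  pi_ <- stationary_distribution(T_)
  s <- sqrt(pi_)
  S <- T_ * outer(s, 1 / s)
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  structure(list(lag = lag, count_matrix = T_ * pi_,
                 transition_matrix = T_, stationary = pi_,
                 eigenvalues = e$values, right_vectors = e$vectors / s,
                 connected_set = seq_len(nrow(T_)), dropped = integer(0),
                 mode = "symmetrized", n_states = nrow(T_)),
            class = "markov_model")
}
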