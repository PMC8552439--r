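#' Backbone dihedral angle
#'
#' IUPAC-convention phi (`C_{i-1}, N_i, CA_i, C_i`) or psi
#' (`N_i, CA_i, C_i, N_{i+1}`), in degrees in (-180, 180].
#'
#' @param ensemble a [traj_ensemble()].
#' @param chain,resno residue address.
#' @param which `"phi"` or `"psi"`.
#' @param traj trajectory index.
#' @param frames frame indices (default: all frames of the trajectory).
#' @return Numeric vector of angles, one per frame.
#' @export
backbone_dihedral <- function(ensemble, chain, resno, which = c("phi", "psi"),
                              traj = 1L, frames = NULL) {
  which <- match.arg(which)
  top <- ensemble$topology
  flank <- if (which == "phi") {
    list(c(chain, resno - 1L, "C"), c(chain, resno, "N"),
         c(chain, resno, "CA"), c(chain, resno, "C"))
  } else {
    list(c(chain, resno, "N"), c(chain, resno, "CA"),
         c(chain, resno, "C"), c(chain, resno + 1L, "N"))
  }
  idx <- tryCatch(
    vapply(flank, function(a) atom_index(top, a[1L], as.integer(a[2L]), a[3L]),
           integer(1)),
    error = function(e)
      stop2("cannot compute ", which, " of ", site_label(chain, resno),
            ": chain-terminal residue lacks a flanking atom (", conditionMessage(e), ")"))
  a <- ensemble$coords[[traj]]
  frames <- frames %||% seq_len(dim(a)[1L])
  vapply(frames, function(f) {
    dihedral_angle(a[f, idx[1L], ], a[f, idx[2L], ], a[f, idx[3L], ],
                   a[f, idx[4L], ])
  }, numeric(1))
}

# Signed dihedral of four points, degrees in (-180, 180].
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * b2) / sqrt(sum(b2^2))
  ang <- deg(atan2(y, x))
  if (ang <= -180) ang + 360 else ang
}

cross3 <- function(u, v) {
  c(u[2L] * v[3L] - u[3L] * v[2L],
    u[3L] * v[1L] - u[1L] * v[3L],
    u[1L] * v[2L] - u[2L] * v[1L])
}

#' Reference plane through three anchor C-alpha atoms
#'
#' Defines the plane containing the C-alpha atoms of three anchor residues
#' (for insulin's "A-plane": A9, A13, A20) and a reference atom that fixes
#' the sign convention: per frame the plane normal is oriented so that the
#' reference atom has a positive signed distance.
#'
#' @param anchors data frame (`chain`, `resno`) or character labels of
#'   exactly three residues.
#' @param reference_atom list/vector `(chain, resno, name)` of the sign
#'   reference atom.
#' @return `"a_plane"` object for [plane_side()].
#' @export
a_plane <- function(anchors, reference_atom) {
  sel <- parse_selection(anchors)
  if (nrow(sel) != 3L) stop2("a plane needs exactly three anchor residues")
  structure(list(anchors = sel,
                 reference_atom = list(chain = as.character(reference_atom[[1L]]),
                                       resno = as.integer(reference_atom[[2L]]),
                                       name = as.character(reference_atom[[3L]]))),
            class = "a_plane")
}

#' Signed distance of an atom from a reference plane
#'
#' Positive on the side of the plane's reference atom.  Anchors must be
#' non-collinear (triangle area above 1e-6 nm^2).
#'
#' @param ensemble a [traj_ensemble()].
#' @param plane an [a_plane()].
#' @param atom list/vector `(chain, resno, name)` of the query atom.
#' @param traj,frames trajectory / frame selection.
#' @return Numeric vector of signed distances (nm), one per frame.
#' @export
plane_side <- function(ensemble, plane, atom, traj = 1L, frames = NULL) {
  top <- ensemble$topology
  ai <- ca_indices(top, plane$anchors$chain, plane$anchors$resno)
  qi <- atom_index(top, as.character(atom[[1L]]), as.integer(atom[[2L]]),
                   as.character(atom[[3L]]))
  ref <- plane$reference_atom
  ri <- atom_index(top, ref$chain, ref$resno, ref$name)
  a <- ensemble$coords[[traj]]
  frames <- frames %||% seq_len(dim(a)[1L])
  vapply(frames, function(f) {
    p1 <- a[f, ai[1L], ]; p2 <- a[f, ai[2L], ]; p3 <- a[f, ai[3L], ]
    n <- cross3(p2 - p1, p3 - p1)
    area <- sqrt(sum(n^2)) / 2
    if (area <= 1e-6)
      stop2("plane anchors are collinear (area ", format(area), " nm^2)")
    n <- n / sqrt(sum(n^2))
    if (sum((a[f, ri, ] - p1) * n) < 0) n <- -n
    sum((a[f, qi, ] - p1) * n)
  }, numeric(1))
}

#' Helical fraction of a residue range
#'
#' Residue `i` counts as helical when its backbone carbonyl O accepts a
#' hydrogen bond from the N--H of residue `i + 4` under the given geometric
#' criteria (the alpha-helical `i -> i+4` pattern).  The fraction is taken
#' over the testable residues of the range, i.e. those whose `i + 4` partner
#' is still inside it, so breaking one such bond lowers the value by exactly
#' one over that count.
#'
#' @param ensemble a [traj_ensemble()].
#' @param chain chain id.
#' @param res_range integer range of residue numbers (length >= 5).
#' @param criteria an [hbond_criteria()] used for the bond geometry.
#' @param traj,frames trajectory / frame selection.
#' @return Numeric vector in `[0, 1]`, one value per frame.
#' @export
helix_content <- function(ensemble, chain, res_range,
                          criteria = hbond_criteria(0.35, 40),
                          traj = 1L, frames = NULL) {
  res_range <- sort(as.integer(res_range))
  res_range <- seq.int(res_range[1L], res_range[length(res_range)])
  if (length(res_range) < 5L) stop2("res_range must span at least 5 residues")
  top <- ensemble$topology
  donors_res <- res_range[res_range + 4L <= max(res_range)] + 4L
  o_idx <- vapply(donors_res - 4L,
                  function(r) atom_index(top, chain, r, "O"), integer(1))
  n_idx <- vapply(donors_res, function(r) atom_index(top, chain, r, "N"),
                  integer(1))
  h_sites <- top$amide_sites[match(site_label(chain, donors_res),
                                   top$amide_sites$site), ]
  if (any(is.na(h_sites$h_idx)))
    stop2("residue ", site_label(chain, donors_res[is.na(h_sites$h_idx)][1L]),
          " has no amide N-H")
  a <- ensemble$coords[[traj]]
  frames <- frames %||% seq_len(dim(a)[1L])
  n_test <- length(donors_res)
  vapply(frames, function(f) {
    xyz <- matrix(a[f, , ], ncol = 3L)
    helical <- vapply(seq_len(n_test), function(j) {
      n_pos <- xyz[n_idx[j], ]; h_pos <- xyz[h_sites$h_idx[j], ]
      count_for(xyz, n_pos, h_pos, o_idx[j], criteria) > 0L
    }, logical(1))
    sum(helical) / n_test
  }, numeric(1))
}

# TRUE per frame when donor site's N-H donates to the backbone O of the
# acceptor residue.
has_hbond <- function(ensemble, donor, acceptor, criteria, traj, frames) {
  top <- ensemble$topology
  s <- top$amide_sites[top$amide_sites$site ==
                         site_label(donor[[1L]], as.integer(donor[[2L]])), ]
  if (nrow(s) != 1L)
    stop2("donor site ", site_label(donor[[1L]], donor[[2L]]), " not found")
  o_idx <- atom_index(top, as.character(acceptor[[1L]]),
                      as.integer(acceptor[[2L]]), "O")
  a <- ensemble$coords[[traj]]
  vapply(frames, function(f) {
    xyz <- matrix(a[f, , ], ncol = 3L)
    count_for(xyz, xyz[s$n_idx, ], xyz[s$h_idx, ], o_idx, criteria) > 0L
  }, logical(1))
}

# Minimum distance between two atom index sets in one frame.
min_set_distance <- function(xyz, idx1, idx2) {
  P <- xyz[idx1, , drop = FALSE]; Q <- xyz[idx2, , drop = FALSE]
  D2 <- outer(rowSums(P^2), rowSums(Q^2), `+`) - 2 * P %*% t(Q)
  sqrt(max(min(D2), 0))
}

select_atoms <- function(top, chain, from, to, atoms = "heavy") {
  a <- top$atoms
  in_sel <- !a$is_water & a$chain == chain & a$resno >= from & a$resno <= to
  if (identical(atoms, "heavy")) in_sel <- in_sel & a$elem != "H"
  else if (identical(atoms, "CA")) in_sel <- in_sel & a$name == "CA"
  which(in_sel)
}

#' Classify per-frame elements of conformational disorder
#'
#' Evaluates a configurable set of geometric rules frame by frame and
#' returns one logical flag per rule.  Rules are data, not code; each is a
#' list with a `name`, a `type` and type-specific parameters:
#'
#' * `helix_melt`: `chain`, `from`, `to`, `max_fraction` -- flag when
#'   [helix_content()] over the range is below `max_fraction`.
#' * `helix_extension`: `chain`, `from`, `to`, `min_fraction` -- flag when
#'   the helical fraction reaches `min_fraction`.
#' * `min_distance`: `sel1`, `sel2` (each `list(chain, from, to, atoms)`
#'   with `atoms` `"heavy"` or `"CA"`), and either `threshold` (flag when
#'   the minimum inter-set distance exceeds it) or `range = c(lo, hi)` (flag
#'   when it falls in `(lo, hi]`; disjoint ranges give mutually exclusive
#'   flags, e.g. partial vs. total detachment).
#' * `plane_crossing`: `plane` (an [a_plane()]), `atom` -- flag when the
#'   atom's signed distance is negative (it crossed to the non-reference
#'   side).
#' * `hbond_swap`: `new_donor`, `new_acceptor`, `old_donor`, `old_acceptor`
#'   (each `(chain, resno)`), `criteria` optional -- flag when the new
#'   N-H...O=C bond is present and the old one absent (e.g. the beta-turn
#'   shift where the B23-B20 bond is replaced by B22-B19).
#' * `dihedral_range`: `chain`, `resno`, `which`, `range = c(lo, hi)` --
#'   flag when the backbone dihedral falls in `[lo, hi]`.
#'
#' @param ensemble a [traj_ensemble()].
#' @param rules list of rule definitions as above.
#' @param traj,frames trajectory / frame selection.
#' @param criteria default [hbond_criteria()] for the hydrogen-bond based
#'   rules.
#' @return Logical matrix, frames x rules, columns named by rule name.
#' @seealso [default_disorder_rules()] for the insulin defaults.
#' @export
classify_elements <- function(ensemble, rules, traj = 1L, frames = NULL,
                              criteria = hbond_criteria(0.35, 40)) {
  a <- ensemble$coords[[traj]]
  frames <- frames %||% seq_len(dim(a)[1L])
  top <- ensemble$topology
  out <- matrix(NA, length(frames), length(rules))
  colnames(out) <- vapply(rules, function(r) r$name, "")
  for (ri in seq_along(rules)) {
    r <- rules[[ri]]
    out[, ri] <- switch(
      r$type,
      helix_melt = helix_content(ensemble, r$chain, c(r$from, r$to),
                                 criteria = r$criteria %||% criteria,
                                 traj = traj, frames = frames) < r$max_fraction,
      helix_extension = helix_content(ensemble, r$chain, c(r$from, r$to),
                                      criteria = r$criteria %||% criteria,
                                      traj = traj, frames = frames) >= r$min_fraction,
      min_distance = {
        i1 <- select_atoms(top, r$sel1$chain, r$sel1$from, r$sel1$to,
                           r$sel1$atoms %||% "heavy")
        i2 <- select_atoms(top, r$sel2$chain, r$sel2$from, r$sel2$to,
                           r$sel2$atoms %||% "heavy")
        if (length(i1) == 0L || length(i2) == 0L)
          stop2("rule ", r$name, " references absent residues")
        d <- vapply(frames, function(f)
          min_set_distance(matrix(a[f, , ], ncol = 3L), i1, i2), numeric(1))
        if (!is.null(r$range)) d > r$range[1L] & d <= r$range[2L]
        else d > r$threshold
      },
      plane_crossing = plane_side(ensemble, r$plane, r$atom, traj = traj,
                                  frames = frames) < 0,
      hbond_swap = {
        crit <- r$criteria %||% criteria
        has_hbond(ensemble, r$new_donor, r$new_acceptor, crit, traj, frames) &
          !has_hbond(ensemble, r$old_donor, r$old_acceptor, crit, traj, frames)
      },
      dihedral_range = {
        phi <- backbone_dihedral(ensemble, r$chain, r$resno,
                                 which = r$which %||% "phi",
                                 traj = traj, frames = frames)
        phi >= r$range[1L] & phi <= r$range[2L]
      },
      stop2("unknown rule type: ", r$type)
    )
  }
  out
}

#' Default disorder rules for the insulin monomer
#'
#' A configurable stand-in rule set for the classical elements of insulin
#' disorder: AN-helix melting (helical fraction of A2--A8 below 0.5), partial
#' and total B-chain N-terminus detachment (minimum heavy-atom distance
#' between B1--B7 and A6--A11 in (0.5, 1.0] nm, respectively above 1.0 nm --
#' the two flags are mutually exclusive by construction), B-chain C-terminus
#' detachment (minimum B24--B30 to core distance above the threshold),
#' B9--B14 B-helix melting, B19--B23 helix extension, the beta-turn shift
#' (B22 H--O=C B19 bond replacing B23 H--O=C B20), and B20--B30 A-plane
#' crossing (B21 C-alpha on the far side of the A9/A13/A20 plane).  All
#' thresholds are plain list entries and are meant to be edited.
#'
#' @param bnd_partial,bnd_total,bcd_threshold distance thresholds in nm.
#' @return List of rule definitions for [classify_elements()].
#' @export
default_disorder_rules <- function(bnd_partial = c(0.5, 1.0),
                                   bnd_total = c(1.0, Inf),
                                   bcd_threshold = 0.8) {
  list(
    list(name = "AN_melt", type = "helix_melt", chain = "A",
         from = 2L, to = 8L, max_fraction = 0.5),
    list(name = "BND_partial", type = "min_distance",
         sel1 = list(chain = "B", from = 1L, to = 7L),
         sel2 = list(chain = "A", from = 6L, to = 11L),
         range = bnd_partial),
    list(name = "BND_total", type = "min_distance",
         sel1 = list(chain = "B", from = 1L, to = 7L),
         sel2 = list(chain = "A", from = 6L, to = 11L),
         range = bnd_total),
    list(name = "BCD", type = "min_distance",
         sel1 = list(chain = "B", from = 24L, to = 30L, atoms = "CA"),
         sel2 = list(chain = "B", from = 9L, to = 19L, atoms = "CA"),
         threshold = bcd_threshold),
    list(name = "B_helix_melt", type = "helix_melt", chain = "B",
         from = 9L, to = 14L, max_fraction = 0.5),
    list(name = "B19_B23_extension", type = "helix_extension", chain = "B",
         from = 19L, to = 23L, min_fraction = 0.5),
    list(name = "beta_turn_shift", type = "hbond_swap",
         new_donor = c("B", 22L), new_acceptor = c("B", 19L),
         old_donor = c("B", 23L), old_acceptor = c("B", 20L)),
    list(name = "APC", type = "plane_crossing",
         plane = a_plane(c("A9", "A13", "A20"), c("B", 15L, "CA")),
         atom = c("B", 21L, "CA"))
  )
}

#' Physically weighted disorder percentages per cluster
#'
#' For each element and macro-cluster, the equilibrium-weighted percentage of
#' structures carrying the element:
#' `100 * sum(w[flag & cluster]) / sum(w[cluster])`.  The ensemble column
#' uses all frames.  Percentages of at least 80 are banded `"green"`, 20--80
#' `"orange"`, below 20 `"white"`; an empty (zero-weight) cluster reports
#' `NA`.  When `headline` names a subset of elements, the fraction of the
#' total weight carrying at least one of them is attached as attribute
#' `"headline_fraction"`.
#'
#' @param flags logical frames x elements matrix ([classify_elements()]).
#' @param weights per-frame equilibrium weights (must sum to 1; see
#'   [frame_weights()]).
#' @param cluster_labels per-frame 0-based macro labels (`NA` allowed).
#' @param headline optional character vector of headline element names.
#' @return Data frame: `element`, one column per cluster id, `ensemble`, and
#'   matching `band_*` columns via attribute `"bands"`.
#' @export
element_percentages <- function(flags, weights, cluster_labels,
                                headline = NULL) {
  flags <- as.matrix(flags)
  nf <- nrow(flags)
  if (length(weights) != nf || length(cluster_labels) != nf)
    stop2("flags, weights and cluster_labels must cover the same frames")
  if (abs(sum(weights) - 1) > 1e-8)
    stop2("weights must sum to 1")
  clusters <- sort(unique(cluster_labels[!is.na(cluster_labels)]))
  pct <- matrix(NA_real_, ncol(flags), length(clusters) + 1L,
                dimnames = list(colnames(flags),
                                c(as.character(clusters), "ensemble")))
  for (ci in seq_along(clusters)) {
    in_c <- !is.na(cluster_labels) & cluster_labels == clusters[ci]
    wc <- sum(weights[in_c])
    if (wc > 0)
      pct[, ci] <- 100 * colSums(weights[in_c] * flags[in_c, , drop = FALSE]) / wc
  }
  pct[, length(clusters) + 1L] <- 100 * colSums(weights * flags)
  band <- ifelse(is.na(pct), NA_character_,
                 ifelse(pct >= 80, "green", ifelse(pct >= 20, "orange", "white")))
  out <- data.frame(element = rownames(pct), pct, check.names = FALSE,
                    row.names = NULL)
  attr(out, "bands") <- band
  if (!is.null(headline)) {
    h <- flags[, headline, drop = FALSE]
    attr(out, "headline_fraction") <- sum(weights[rowSums(h) > 0])
  }
  out
}
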