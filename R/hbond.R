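#' Geometric hydrogen-bond criteria
#'
#' A bond between a backbone amide donor (N--H) and an acceptor atom `A` is
#' counted when the donor-acceptor distance is at most `distance_cutoff` and
#' the hydrogen-donor-acceptor angle is at most `angle_cutoff`.  Comparisons
#' are inclusive, so behaviour at the cutoffs is deterministic.
#'
#' With the default `angle_vertex = "donor"`, the angle is measured at the
#' donor nitrogen between the N-to-H and N-to-acceptor directions (the
#' deviation of the acceptor from the amide-hydrogen direction); loose
#' cutoffs up to 90 degrees are meaningful under this convention.  The
#' `"hydrogen"` alternative measures the deviation from linearity of the
#' N--H...A arrangement at the hydrogen, `180 - angle(N, H, A)`, so that
#' "counted when at most the cutoff" holds under both conventions.
#'
#' @param distance_cutoff donor-acceptor (N to A) distance cutoff in nm.
#' @param angle_cutoff angle cutoff in degrees, in (0, 180].
#' @param include_self_residue count acceptors in the donor's own residue
#'   (its backbone and side-chain O/N, never its own N or H)?  Default TRUE.
#' @param angle_vertex `"donor"` (default) or `"hydrogen"`.
#' @return An object of class `"hbond_criteria"`.
#' @export
hbond_criteria <- function(distance_cutoff = 0.5, angle_cutoff = 70,
                           include_self_residue = TRUE,
                           angle_vertex = c("donor", "hydrogen")) {
  if (!is.numeric(distance_cutoff) || distance_cutoff <= 0)
    stop2("distance_cutoff must be > 0 (nm)")
  if (!is.numeric(angle_cutoff) || angle_cutoff <= 0 || angle_cutoff > 180)
    stop2("angle_cutoff must be in (0, 180] degrees")
  structure(list(distance_cutoff = distance_cutoff,
                 angle_cutoff = angle_cutoff,
                 include_self_residue = isTRUE(include_self_residue),
                 angle_vertex = match.arg(angle_vertex)),
            class = "hbond_criteria")
}

# Angle (degrees) for donor N, hydrogen H, acceptor rows A (matrix).
hbond_angles <- function(n_pos, h_pos, A, vertex) {
  if (vertex == "donor") {
    u <- h_pos - n_pos
    V <- sweep(A, 2L, n_pos)
  } else {
    u <- n_pos - h_pos
    V <- sweep(A, 2L, h_pos)
    # deviation from linearity: angle between H->A and the extension of N->H
    u <- -u
  }
  nu <- sqrt(sum(u^2))
  nV <- row_norms(V)
  cosang <- (V %*% u) / (nV * nu)
  cosang <- pmin(pmax(cosang, -1), 1)
  deg(acos(cosang))
}

#' Count per-site amide hydrogen bonds to protein and to water
#'
#' For every frame and every backbone amide site, counts the hydrogen bonds
#' the site's N--H donates to protein acceptor atoms (all protein O and N
#' atoms except the donor's own backbone N and its hydrogen; `HB_p`) and to
#' water oxygens (`HB_w`) under the given geometric criteria.  Multiple
#' simultaneous acceptors each count.
#'
#' Candidate acceptors are found with a cell list of cell size equal to the
#' distance cutoff (`method = "cell"`, the default); output is identical, by
#' contract and by test, to the brute-force all-pairs search
#' (`method = "brute"`).
#'
#' @param ensemble a [traj_ensemble()] whose topology declares amide sites,
#'   protein acceptors and water oxygens.
#' @param criteria an [hbond_criteria()].
#' @param sites optional character vector of site labels to restrict to.
#' @param method `"cell"` or `"brute"`.
#' @return `"hbond_counts"`: `hb_p` and `hb_w` (total frames x sites integer
#'   matrices, site labels as column names), `sites`, `criteria`,
#'   `boundaries`.
#' @export
count_hbonds <- function(ensemble, criteria = hbond_criteria(),
                         sites = NULL, method = c("cell", "brute")) {
  method <- match.arg(method)
  top <- ensemble$topology
  am <- top$amide_sites
  if (nrow(am) == 0L) stop2("topology declares no amide sites")
  if (!is.null(sites)) {
    missing <- setdiff(sites, am$site)
    if (length(missing) > 0L)
      stop2("unknown site(s): ", paste(missing, collapse = ", "))
    am <- am[match(sites, am$site), , drop = FALSE]
  }
  # every site must have its hydrogen (guaranteed by topology(); re-checked
  # here because subsetted topologies can be constructed by hand)
  if (any(is.na(am$h_idx)))
    stop2("site ", am$site[which(is.na(am$h_idx))[1L]], " has no attached H")

  atoms <- top$atoms
  prot_acc <- top$acceptor_idx
  wat_acc <- top$water_o_idx
  ns <- nrow(am)
  nf <- n_frames(ensemble)
  hb_p <- matrix(0L, sum(nf), ns, dimnames = list(NULL, am$site))
  hb_w <- matrix(0L, sum(nf), ns, dimnames = list(NULL, am$site))

  # per-site protein acceptor sets (exclude own N and H; optionally the
  # whole own residue)
  acc_sets <- vector("list", ns)
  for (s in seq_len(ns)) {
    acc <- setdiff(prot_acc, c(am$n_idx[s], am$h_idx[s]))
    if (!criteria$include_self_residue) {
      own <- which(!atoms$is_water &
                     atoms$chain == am$chain[s] & atoms$resno == am$resno[s])
      acc <- setdiff(acc, own)
    }
    acc_sets[[s]] <- acc
  }

  off <- 0L
  for (t in seq_along(ensemble$coords)) {
    a <- ensemble$coords[[t]]
    for (f in seq_len(nf[t])) {
      xyz <- matrix(a[f, , ], ncol = 3L)
      cl <- if (method == "cell")
        build_cell_list(xyz, c(acc_sets, list(wat_acc)),
                        criteria$distance_cutoff) else NULL
      for (s in seq_len(ns)) {
        n_pos <- xyz[am$n_idx[s], ]
        h_pos <- xyz[am$h_idx[s], ]
        cand_p <- if (is.null(cl)) acc_sets[[s]]
                  else cell_neighbors(cl, n_pos, acc_sets[[s]])
        cand_w <- if (is.null(cl)) wat_acc
                  else cell_neighbors(cl, n_pos, wat_acc)
        hb_p[off + f, s] <- count_for(xyz, n_pos, h_pos, cand_p, criteria)
        hb_w[off + f, s] <- count_for(xyz, n_pos, h_pos, cand_w, criteria)
      }
    }
    off <- off + nf[t]
  }
  structure(list(hb_p = hb_p, hb_w = hb_w, sites = am$site,
                 criteria = criteria, boundaries = nf),
            class = "hbond_counts")
}

count_for <- function(xyz, n_pos, h_pos, acc_idx, criteria) {
  if (length(acc_idx) == 0L) return(0L)
  A <- xyz[acc_idx, , drop = FALSE]
  d <- row_norms(sweep(A, 2L, n_pos))
  ok <- d <= criteria$distance_cutoff
  if (!any(ok)) return(0L)
  ang <- hbond_angles(n_pos, h_pos, A[ok, , drop = FALSE],
                      criteria$angle_vertex)
  sum(ang <= criteria$angle_cutoff)
}

#' @export
print.hbond_counts <- function(x, ...) {
  cat("hbond_counts:", nrow(x$hb_p), "frames x", length(x$sites), "sites",
      sprintf("(dist <= %g nm, angle <= %g deg)\n",
              x$criteria$distance_cutoff, x$criteria$angle_cutoff))
  invisible(x)
}

#' @export
as.data.frame.hbond_counts <- function(x, ...) {
  nf <- nrow(x$hb_p)
  data.frame(frame = rep(seq_len(nf), times = length(x$sites)),
             site = rep(x$sites, each = nf),
             hb_p = as.vector(x$hb_p), hb_w = as.vector(x$hb_w))
}

# --- cell list ---------------------------------------------------------------
# Bins the union of candidate acceptor atoms into cubic cells with edge equal
# to the distance cutoff; a donor's candidates then live in the 27 cells
# around its own.  Output is identical to brute force because every atom
# within the cutoff of the donor necessarily lies in one of those cells.

build_cell_list <- function(xyz, idx_sets, cell) {
  idx <- sort(unique(unlist(idx_sets)))
  if (length(idx) == 0L)
    return(list(cell = cell, origin = c(0, 0, 0), bins = list(), dims = c(1L, 1L, 1L)))
  P <- xyz[idx, , drop = FALSE]
  origin <- apply(P, 2L, min)
  key <- floor(sweep(P, 2L, origin) / cell)
  dims <- apply(key, 2L, max) + 1L
  flat <- key[, 1L] + dims[1L] * (key[, 2L] + dims[2L] * key[, 3L]) + 1
  bins <- split(idx, flat)
  list(cell = cell, origin = origin, bins = bins, dims = dims)
}

cell_neighbors <- function(cl, pos, restrict) {
  if (length(cl$bins) == 0L) return(integer(0))
  k0 <- floor((pos - cl$origin) / cl$cell)
  out <- integer(0)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    k <- k0 + c(dx, dy, dz)
    if (any(k < 0) || any(k >= cl$dims)) next
    flat <- as.character(k[1L] + cl$dims[1L] * (k[2L] + cl$dims[2L] * k[3L]) + 1)
    b <- cl$bins[[flat]]
    if (!is.null(b)) out <- c(out, b)
  }
  intersect(out, restrict)
}
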