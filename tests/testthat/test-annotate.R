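# small 2-residue backbone with a hand-placed dihedral quadruple
make_dihedral_ensemble <- function(dihedral_deg) {
  p1 <- c(0, 0, 0)        # C of residue 1
  p2 <- c(0.133, 0, 0)    # N of residue 2
  p3 <- p2 + c(0.145 * cos(1.2), 0.145 * sin(1.2), 0)  # CA of residue 2
  p4 <- place_dihedral(p1, p2, p3, 0.152, 110, dihedral_deg)  # C of residue 2
  atoms <- data.frame(chain = "A", resno = c(1, 1, 2, 2, 2, 2),
                      resname = "GLY",
                      name = c("CA", "C", "N", "H", "CA", "C"),
                      elem = c("C", "C", "N", "H", "C", "C"))
  top <- topology(atoms)
  pos <- rbind(c(-0.1, -0.1, 0), p1, p2, p2 + c(0, 0, 0.1), p3, p4)
  coords <- array(NA_real_, c(1, 6, 3))
  coords[1, , ] <- pos
  traj_ensemble(top, list(coords), 10)
}

test_that("backbone dihedrals match their construction angle and conventions", {
  for (target in c(180, 80, -70, 23.5, -179)) {
    ens <- make_dihedral_ensemble(target)
    phi <- backbone_dihedral(ens, "A", 2, "phi")
    expect_equal(phi, target, tolerance = 1e-6)
  }
  # mirror image negates the dihedral (chirality)
  ens <- make_dihedral_ensemble(65)
  mirrored <- ens
  mirrored$coords[[1]][1, , 3] <- -mirrored$coords[[1]][1, , 3]
  expect_equal(backbone_dihedral(mirrored, "A", 2, "phi"), -65, tolerance = 1e-6)
  # terminal residue without a flank errors
  expect_error(backbone_dihedral(ens, "A", 1, "phi"), "flank")
})

test_that("random dihedral quadruples match the reference torsion implementation", {
  set.seed(15)
  for (i in 1:50) {
    p <- matrix(rnorm(12), 4, 3)
    oracle <- bio3d::torsion.xyz(as.numeric(t(p)))  # independent IUPAC torsion
    got <- msmhdx:::dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ])
    d <- abs(got - oracle) %% 360
    expect_lt(min(d, 360 - d), 1e-9)
  }
})

test_that("plane side distances are signed, symmetric, and detect collinearity", {
  atoms <- data.frame(chain = c("A", "A", "A", "B", "B"),
                      resno = c(9, 13, 20, 15, 21), resname = "GLY",
                      name = "CA", elem = "C")
  top <- topology(atoms)
  # anchors: unit triangle in z = 0; reference B15 above; query B21
  mk <- function(q) {
    pos <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0.2, 0.2, 1), q)
    coords <- array(NA_real_, c(1, 5, 3)); coords[1, , ] <- pos
    traj_ensemble(top, list(coords), 10)
  }
  pl <- a_plane(c("A9", "A13", "A20"), c("B", 15, "CA"))
  # in-plane atom: zero
  expect_equal(plane_side(mk(c(0.3, 0.3, 0)), pl, c("B", 21, "CA")), 0,
               tolerance = 1e-12)
  # reflection negates
  expect_equal(plane_side(mk(c(0.3, 0.3, 0.4)), pl, c("B", 21, "CA")),
               -plane_side(mk(c(0.3, 0.3, -0.4)), pl, c("B", 21, "CA")),
               tolerance = 1e-12)
  # known tetrahedron: distance is the analytic point-plane distance
  expect_equal(plane_side(mk(c(0.7, 0.1, -2.5)), pl, c("B", 21, "CA")), -2.5,
               tolerance = 1e-12)
  # collinear anchors error
  degenerate <- mk(c(0, 0, 1))
  degenerate$coords[[1]][1, 3, ] <- c(2, 0, 0)  # A20 on the A9-A13 line
  expect_error(plane_side(degenerate, pl, c("B", 21, "CA")), "collinear")
})

test_that("helix content is 1 on an ideal helix, 0 when extended, and drops by 1/range", {
  helix <- make_helix_ensemble(12)
  expect_equal(helix_content(helix, "A", 1:12), 1.0)
  # breaking the middle i -> i+4 bond: displace one carbonyl O far away
  broken <- helix
  top <- helix$topology
  o_idx <- msmhdx:::atom_index(top, "A", 4, "O")
  broken$coords[[1]][1, o_idx, ] <- broken$coords[[1]][1, o_idx, ] + c(0, 0, 5)
  expect_equal(helix_content(broken, "A", 1:12), 7 / 8)  # 8 testable residues

  # fully extended toy chain has no helical hydrogen bonds at all
  spec <- toy_chain_spec(matrix(1, 1, 1), n_res = 6, noise_sigma = 0)
  g <- generate_ensemble(spec, 1, 2, seed = 1)
  expect_equal(helix_content(g$ensemble, "A", 1:6), c(0, 0))
  expect_error(helix_content(g$ensemble, "A", 1:4), "5 residues")
})

test_that("rule-based classification flags the designed geometries", {
  P <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE)
  spec <- toy_chain_spec(P, n_res = 6, noise_sigma = 0, state_shift = 0.4)
  g <- generate_ensemble(spec, 1, 300, seed = 9)
  states <- g$ground_truth$state_sequence[[1]]
  # state 2 displaces the C-terminal half: detachment-style min-distance rule
  rules <- list(list(name = "tail_detached", type = "min_distance",
                     sel1 = list(chain = "A", from = 1, to = 3),
                     sel2 = list(chain = "A", from = 4, to = 6),
                     threshold = 0.57))
  flags <- classify_elements(g$ensemble, rules)
  expect_identical(unname(flags[, "tail_detached"]), states == 2L)

  # banded variant: partial vs total are mutually exclusive by construction
  rules2 <- list(
    list(name = "partial", type = "min_distance",
         sel1 = list(chain = "A", from = 1, to = 3),
         sel2 = list(chain = "A", from = 4, to = 6), range = c(0.57, 0.70)),
    list(name = "total", type = "min_distance",
         sel1 = list(chain = "A", from = 1, to = 3),
         sel2 = list(chain = "A", from = 4, to = 6), range = c(0.70, Inf)))
  flags2 <- classify_elements(g$ensemble, rules2)
  expect_true(all(!(flags2[, "partial"] & flags2[, "total"])))
  expect_identical(unname(flags2[, "partial"] | flags2[, "total"]),
                   states == 2L)

  expect_error(classify_elements(g$ensemble, list(
    list(name = "bad", type = "min_distance",
         sel1 = list(chain = "Q", from = 1, to = 2),
         sel2 = list(chain = "A", from = 1, to = 2), threshold = 1))),
    "absent")
})

test_that("the beta-turn-shift rule detects the swapped hydrogen bond", {
  # chain B, residues 19..23; donor H of B22 aimed at O of B19 (shifted
  # geometry) or donor H of B23 aimed at O of B20 (native geometry)
  res_atoms <- c("N", "H", "CA", "C", "O")
  atoms <- data.frame(chain = "B", resno = rep(19:23, each = 5),
                      resname = "GLY", name = rep(res_atoms, 5),
                      elem = rep(c("N", "H", "C", "C", "O"), 5))
  top <- topology(atoms)
  base <- function() {
    pos <- matrix(0, 25, 3)
    for (i in 0:4) {
      x <- 0.8 * i
      pos[i * 5 + 1, ] <- c(x, 0, 0)        # N
      pos[i * 5 + 2, ] <- c(x, 0.1, 0)      # H
      pos[i * 5 + 3, ] <- c(x + 0.15, 0, 0)
      pos[i * 5 + 4, ] <- c(x + 0.3, 0, 0)
      pos[i * 5 + 5, ] <- c(x + 0.3, -0.45, 0)  # O
    }
    pos
  }
  bond <- function(pos, donor_res, acceptor_res) {
    # move the acceptor O to ideal geometry above the donor's N-H
    d <- (donor_res - 19) * 5; a <- (acceptor_res - 19) * 5
    pos[a + 5, ] <- pos[d + 1, ] + c(0, 0.3, 0)
    pos
  }
  mk <- function(pos) {
    coords <- array(NA_real_, c(1, 25, 3)); coords[1, , ] <- pos
    traj_ensemble(top, list(coords), 10)
  }
  rule <- list(list(name = "beta_turn_shift", type = "hbond_swap",
                    new_donor = c("B", 22), new_acceptor = c("B", 19),
                    old_donor = c("B", 23), old_acceptor = c("B", 20)))
  native <- mk(bond(base(), 23, 20))       # B23 -> B20 present
  shifted <- mk(bond(base(), 22, 19))      # B22 -> B19 present, B23 -> B20 gone
  both <- mk(bond(bond(base(), 23, 20), 22, 19))
  expect_false(classify_elements(native, rule)[1, 1])
  expect_true(classify_elements(shifted, rule)[1, 1])
  expect_false(classify_elements(both, rule)[1, 1])  # old bond still intact
})

test_that("a dihedral window rule distinguishes the two turn geometries", {
  near80 <- make_dihedral_ensemble(80)
  nearm70 <- make_dihedral_ensemble(-70)
  rule <- list(list(name = "turn_flip", type = "dihedral_range",
                    chain = "A", resno = 2, which = "phi",
                    range = c(-110, -30)))
  expect_false(classify_elements(near80, rule)[1, 1])
  expect_true(classify_elements(nearm70, rule)[1, 1])
})

test_that("the default insulin rule set is well-formed", {
  rules <- default_disorder_rules()
  expect_true(all(vapply(rules, function(r) is.character(r$name), TRUE)))
  expect_setequal(
    vapply(rules, `[[`, "", "name"),
    c("AN_melt", "BND_partial", "BND_total", "BCD", "B_helix_melt",
      "B19_B23_extension", "beta_turn_shift", "APC"))
  # the partial/total bands are disjoint
  p <- rules[[2]]$range; t <- rules[[3]]$range
  expect_lte(p[2], t[1])
})

test_that("weighted element percentages aggregate and band correctly", {
  # all flags true => 100 percent everywhere
  flags <- matrix(TRUE, 4, 2, dimnames = list(NULL, c("e1", "e2")))
  w <- rep(0.25, 4)
  labs <- c(0L, 0L, 1L, 1L)
  pct <- element_percentages(flags, w, labs)
  expect_true(all(pct[, c("0", "1", "ensemble")] == 100))

  # two equal-weight frames, one flagged => 50 percent, orange band
  flags2 <- matrix(c(TRUE, FALSE), 2, 1, dimnames = list(NULL, "e"))
  pct2 <- element_percentages(flags2, c(0.5, 0.5), c(0L, 0L))
  expect_equal(pct2[1, "0"], 50)
  expect_identical(attr(pct2, "bands")[1, "0"], "orange")

  # banding edges: >= 80 green, 20-80 orange, < 20 white
  flags3 <- matrix(c(rep(TRUE, 9), FALSE,
                     rep(TRUE, 5), rep(FALSE, 5),
                     TRUE, rep(FALSE, 9)), 10, 3,
                   dimnames = list(NULL, c("hi", "mid", "lo")))
  pct3 <- element_percentages(flags3, rep(0.1, 10), rep(0L, 10))
  expect_identical(unname(attr(pct3, "bands")[, "0"]),
                   c("green", "orange", "white"))

  # ensemble column equals the population-weighted combination of clusters
  set.seed(20)
  flags4 <- matrix(runif(300) < 0.4, 100, 3,
                   dimnames = list(NULL, c("a", "b", "c")))
  w4 <- runif(100); w4 <- w4 / sum(w4)
  labs4 <- sample(0:2, 100, replace = TRUE)
  pct4 <- element_percentages(flags4, w4, labs4, headline = c("a", "b"))
  popw <- vapply(0:2, function(j) sum(w4[labs4 == j]), numeric(1))
  for (el in 1:3) {
    combo <- sum(popw * as.numeric(pct4[el, as.character(0:2)])) / sum(popw)
    expect_equal(pct4[el, "ensemble"], combo, tolerance = 1e-10)
  }
  expect_equal(attr(pct4, "headline_fraction"),
               sum(w4[flags4[, "a"] | flags4[, "b"]]))
  expect_true(all(as.matrix(pct4[, -1]) >= 0 & as.matrix(pct4[, -1]) <= 100))
})

test_that("designed state-linked elements give (100, 0) and the state population", {
  P <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE)
  spec <- toy_chain_spec(P, n_res = 6, noise_sigma = 0)
  g <- generate_ensemble(spec, 2, 3000, seed = 57)
  states <- unlist(g$ground_truth$state_sequence)
  rules <- list(list(name = "tail_detached", type = "min_distance",
                     sel1 = list(chain = "A", from = 1, to = 3),
                     sel2 = list(chain = "A", from = 4, to = 6),
                     threshold = 0.57))
  flags <- rbind(classify_elements(g$ensemble, rules, traj = 1),
                 classify_elements(g$ensemble, rules, traj = 2))
  w <- rep(1 / length(states), length(states))
  pct <- element_percentages(flags, w, states - 1L)
  expect_equal(pct[1, "0"], 0)
  expect_equal(pct[1, "1"], 100)
  # ensemble percentage = occupancy of state 2 (uniform weights)
  expect_equal(pct[1, "ensemble"] / 100, mean(states == 2), tolerance = 1e-10)
  expect_lt(abs(pct[1, "ensemble"] / 100 - g$ground_truth$true_populations[2]),
            0.02)
})
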