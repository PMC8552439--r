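hb_grid <- expand.grid(hb_p = 0:10, hb_w = 0:10)

test_that("bound-difference takes only the values -1, 0, 1 on the full grid", {
  spec <- pf_model_spec("bound_difference")
  f <- pf_structure(hb_grid$hb_p, hb_grid$hb_w, spec)
  expect_true(all(f %in% c(-1, 0, 1)))
  expect_equal(max(f), 1)
  expect_equal(min(f), -1)
})

test_that("ratio stays finite (max guard) when a structure has no water bonds", {
  spec <- pf_model_spec("ratio")
  f <- pf_structure(0:10, rep(0L, 11), spec)
  expect_true(all(is.finite(f)))
  expect_equal(f, 0:10)  # denominator guard pins it at HB_p / 1
})

test_that("all four models are monotone in both counts on the full grid", {
  for (name in c("park", "ratio", "difference", "bound_difference")) {
    spec <- pf_model_spec(name)
    f <- matrix(pf_structure(hb_grid$hb_p, hb_grid$hb_w, spec), 11, 11)
    # rows: hb_p = 0..10; cols: hb_w = 0..10
    expect_true(all(apply(f, 2, diff) >= 0), info = name)  # nondecr. in HB_p
    expect_true(all(apply(f, 1, diff) <= 0), info = name)  # nonincr. in HB_w
  }
})

test_that("the park base parameter sets the dynamic range", {
  expect_equal(pf_structure(2, 0, pf_model_spec("park")), 500)
  expect_equal(pf_structure(0, 3, pf_model_spec("park")), 1 / 500)
  expect_equal(pf_structure(1, 1, pf_model_spec("park")), 1)
  expect_equal(pf_structure(1, 0, pf_model_spec("park", b = 1e4)), 1e4)
  expect_error(pf_model_spec("park", b = 0), "b")
  expect_error(pf_model_spec("gibberish"), "arg")
  expect_error(pf_structure(-1, 0, pf_model_spec("park")), ">= 0")
})

make_counts <- function(hb_p, hb_w, sites = paste0("A", seq_len(ncol(hb_p)))) {
  structure(list(hb_p = hb_p, hb_w = hb_w, sites = sites,
                 criteria = hbond_criteria(), boundaries = nrow(hb_p)),
            class = "hbond_counts")
}

test_that("a single repeated frame gives exactly its per-structure value", {
  counts <- make_counts(matrix(2L, 5, 1), matrix(0L, 5, 1))
  expect_message(
    pt <- pf_cluster(counts, rep(0L, 5), weights = rep(0.2, 5),
                     spec = pf_model_spec("park"), n_sample = 100, seed = 2),
    "replacement")
  expect_equal(unname(pt$pf[1, 1]), 500)
})

test_that("two equal-weight frames average to the midpoint within binomial error", {
  # f values 0 and 1 under difference model: (1,0) and (0,0) with hb_p 1/0
  counts <- make_counts(matrix(c(1L, 0L), 2, 1), matrix(0L, 2, 1))
  n <- 4000
  suppressMessages(
    pt <- pf_cluster(counts, c(0L, 0L), weights = c(0.5, 0.5),
                     spec = pf_model_spec("difference"), n_sample = n, seed = 5))
  se <- sqrt(0.25 / n)
  expect_lt(abs(pt$pf[1, 1] - 0.5), 3 * se)
})

test_that("cluster sampling is weight-proportional and deterministic by seed", {
  counts <- make_counts(matrix(c(1L, 0L), 2, 1), matrix(0L, 2, 1))
  suppressMessages({
    p1 <- pf_cluster(counts, c(0L, 0L), weights = c(0.9, 0.1),
                     spec = pf_model_spec("difference"), n_sample = 4000, seed = 3)
    p2 <- pf_cluster(counts, c(0L, 0L), weights = c(0.9, 0.1),
                     spec = pf_model_spec("difference"), n_sample = 4000, seed = 3)
  })
  expect_identical(p1$pf, p2$pf)
  se <- sqrt(0.9 * 0.1 / 4000)
  expect_lt(abs(p1$pf[1, 1] - 0.9), 3 * se)
  expect_error(suppressMessages(
    pf_cluster(counts, c(0L, 0L), spec = pf_model_spec("park"),
               n_sample = 10, seed = 1)), NA)
  expect_error(suppressMessages(
    pf_cluster(counts, c(1L, 1L), spec = pf_model_spec("park"),
               n_sample = 10, seed = 1)), NA)
})

test_that("ensemble PF is the renormalized population-weighted cluster average", {
  pt <- structure(list(pf = matrix(c(10, 0), 1, dimnames = list("A1", c("0", "1"))),
                       sites = "A1", clusters = c(0L, 1L),
                       spec = pf_model_spec("park"),
                       criteria = hbond_criteria(), n_sample = 10),
                  class = "pf_table")
  pops <- c(`0` = 0.4, `1` = 0.1)
  pf <- pf_ensemble(pt, pops, included_clusters = c(0L, 1L))
  expect_equal(unname(pf["A1"]), (0.4 * 10 + 0.1 * 0) / 0.5)  # = 8
  # one included cluster reduces to that cluster's value
  expect_equal(unname(pf_ensemble(pt, pops, included_clusters = 0L)["A1"]), 10)
  # exact weighted-combination identity
  w <- attr(pf, "weights")
  expect_equal(unname(pf["A1"]), sum(w * pt$pf[1, ]), tolerance = 1e-10)
})

test_that("the default inclusion takes the five most populated clusters", {
  pf_mat <- matrix(seq(70, 10, by = -10), 1,
                   dimnames = list("A1", as.character(0:6)))
  pt <- structure(list(pf = pf_mat, sites = "A1", clusters = 0:6,
                       spec = pf_model_spec("park"),
                       criteria = hbond_criteria(), n_sample = 10),
                  class = "pf_table")
  pops <- setNames(c(0.3, 0.2, 0.15, 0.12, 0.08, 0.09, 0.06), 0:6)
  pf <- pf_ensemble(pt, pops)
  expect_setequal(attr(pf, "included_clusters"), c(0L, 1L, 2L, 3L, 5L))
})

test_that("experimental comparison reproduces the covariance formula", {
  set.seed(11)
  x <- rnorm(10); y <- 0.5 * x + rnorm(10, 0, 0.5)
  pf_i <- setNames(x, paste0("A", 1:10))
  tab <- data.frame(site = paste0("A", 1:10), pf = y)
  cmp <- compare_experimental(pf_i, tab)
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(cmp$r, r_direct, tolerance = 1e-12)
  expect_equal(cmp$n_shared, 10)

  # identity and negation limits
  expect_equal(compare_experimental(pf_i, data.frame(site = names(pf_i),
                                                     pf = x))$r, 1)
  expect_equal(compare_experimental(pf_i, data.frame(site = names(pf_i),
                                                     pf = -x))$r, -1)

  # unmatched sites are reported; too few shared sites error
  tab2 <- data.frame(site = c("A1", "A2", "A3", "B9"), pf = 1:4)
  cmp2 <- compare_experimental(pf_i, tab2)
  expect_identical(cmp2$unmatched_experimental, "B9")
  expect_length(cmp2$unmatched_computed, 7)
  expect_error(compare_experimental(pf_i[1:2],
                                    data.frame(site = c("A1", "A2"), pf = 1:2)),
               "3")
})

test_that("variable-site detection matches hand arithmetic under both presets", {
  pf_mat <- rbind(A1 = c(100, 0, 0, 0, 0),   # var 2000 >= 10 * mean 20
                  A2 = c(10, 10.5, 10, 10.5, 10),  # cv ~ 0.026
                  A3 = c(5, 5, 5, 5, 5),     # constant: never flagged
                  A4 = c(0, 0, 0, 0, 0))     # zero mean: skipped
  pt <- structure(list(pf = pf_mat, sites = rownames(pf_mat), clusters = 0:4,
                       spec = pf_model_spec("park"),
                       criteria = hbond_criteria(), n_sample = 10),
                  class = "pf_table")
  expect_message(vr <- variable_sites(pt, "variance_ratio"), "A4")
  expect_identical(as.character(vr), "A1")
  cv <- suppressMessages(variable_sites(pt, "cv"))
  expect_false("A2" %in% cv)   # cv ~ 2.6% < 10%
  expect_false("A3" %in% cv)
  expect_true("A1" %in% cv)
  st <- attr(vr, "stats")
  expect_equal(st$mean[1], 20)
  expect_equal(st$variance[1], stats::var(c(100, 0, 0, 0, 0)))
})

test_that("EX2 kinetics: limits, round trip and regime warning", {
  kin <- exchange_kinetics(k_op = 1, k_cl = 1, k_int = 0.001)
  expect_equal(kin$pf, 1)
  expect_equal(ex2_observed_rate(kin), kin$k_int)  # PF = 1: unprotected limit

  kin2 <- exchange_kinetics(k_op = 1e-6, k_cl = 10, k_int = 0.01)
  expect_lt(ex2_observed_rate(kin2), 1e-8)  # PF -> inf: k_obs -> 0

  # algebraic round trip
  kin3 <- exchange_kinetics(k_op = 0.02, k_cl = 7, k_int = 0.03)
  expect_equal(pf_from_rates(ex2_observed_rate(kin3), kin3$k_int), kin3$pf,
               tolerance = 1e-12)

  # outside EX2: warning raised and attached
  kin4 <- exchange_kinetics(k_op = 1, k_cl = 1, k_int = 1)
  expect_false(kin4$ex2_valid)
  expect_warning(r <- ex2_observed_rate(kin4), "EX2")
  expect_false(is.null(attr(r, "warning")))
})

test_that("rank order of site PFs is consistent across models and criteria", {
  P <- matrix(c(0.95, 0.05, 0.1, 0.9), 2, byrow = TRUE)
  hb_p <- rbind(c(2, 1, 0, 0), c(2, 0, 0, 0))
  hb_w <- rbind(c(0, 0, 1, 2), c(0, 1, 2, 2))
  spec <- toy_chain_spec(P, n_res = 4, hb_p = hb_p, hb_w = hb_w)
  g <- generate_ensemble(spec, 2, 1500, seed = 51)
  labels <- as.integer(unlist(g$ground_truth$state_sequence) == 2)
  pops <- setNames(g$ground_truth$true_populations, 0:1)
  ranks <- list()
  for (crit in list(hbond_criteria(0.35, 40), hbond_criteria(0.5, 70),
                    hbond_criteria(0.6, 90))) {
    cc <- count_hbonds(g$ensemble, crit)
    for (model in c("park", "ratio", "difference", "bound_difference")) {
      suppressMessages(
        pt <- pf_cluster(cc, labels, spec = pf_model_spec(model),
                         n_sample = 800, seed = 6))
      pf <- pf_ensemble(pt, pops, included_clusters = 0:1)
      ranks[[length(ranks) + 1]] <- rank(pf)
    }
  }
  # positive rank correlation between every pair of settings
  for (i in seq_along(ranks)) for (j in seq_along(ranks))
    expect_gt(stats::cor(ranks[[i]], ranks[[j]], method = "spearman"), 0)
})

test_that("binary protected/exposed classification matches the design", {
  P <- matrix(c(0.95, 0.05, 0.1, 0.9), 2, byrow = TRUE)
  # designed: sites 1,2 protected in every state; sites 3,4 exposed
  hb_p <- rbind(c(2, 1, 0, 0), c(2, 1, 0, 0))
  hb_w <- rbind(c(0, 0, 1, 2), c(0, 0, 2, 2))
  spec <- toy_chain_spec(P, n_res = 4, hb_p = hb_p, hb_w = hb_w)
  g <- generate_ensemble(spec, 2, 1200, seed = 53)
  labels <- as.integer(unlist(g$ground_truth$state_sequence) == 2)
  pops <- setNames(g$ground_truth$true_populations, 0:1)
  cc <- count_hbonds(g$ensemble, hbond_criteria(0.5, 70))
  for (model in c("park", "ratio", "difference", "bound_difference")) {
    suppressMessages(
      pt <- pf_cluster(cc, labels, spec = pf_model_spec(model),
                       n_sample = 800, seed = 8))
    pf <- pf_ensemble(pt, pops, included_clusters = 0:1)
    above <- pf > stats::median(pf)
    expect_identical(unname(above), c(TRUE, TRUE, FALSE, FALSE), info = model)
  }
})
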