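#' Protection-factor model specification
#'
#' Four per-structure models turn a site's hydrogen-bond counts (`HB_p` to
#' protein acceptors, `HB_w` to water oxygens) into a protection score
#' `f_i`.  All encode the same idea -- an amide is more protected the more
#' hydrogen bonds it forms with the protein and the fewer with water -- with
#' increasing amounts of structure:
#'
#' * `park`: `f = b ^ NH`, with `NH = min(HB_p, 1) - min(HB_w, 1)` and base
#'   parameter `b` (historically 1e4--1e6; default 500, which keeps the
#'   largest ensemble values near the largest experimentally observed ones).
#' * `ratio`: `f = HB_p / max(HB_w, 1)`; the max guard keeps the value
#'   finite for structures with `HB_w = 0`.
#' * `difference`: `f = HB_p - HB_w`.
#' * `bound_difference`: `f = NH` itself, so `f` can only take the values
#'   1, 0 or -1.
#'
#' Every model is non-decreasing in `HB_p` and non-increasing in `HB_w`.
#'
#' @param model one of `"park"`, `"ratio"`, `"difference"`,
#'   `"bound_difference"`.
#' @param b base parameter for the `park` model (`> 0`).
#' @return `"pf_model_spec"` object.
#' @export
pf_model_spec <- function(model = c("park", "ratio", "difference",
                                    "bound_difference"), b = 500) {
  model <- match.arg(model)
  if (!is.numeric(b) || length(b) != 1L || b <= 0) stop2("b must be > 0")
  structure(list(model = model, b = b), class = "pf_model_spec")
}

#' Per-structure protection score
#'
#' Applies the selected model elementwise; inputs may be vectors or matrices
#' of equal shape (nonnegative integers).
#'
#' @param hb_p,hb_w hydrogen-bond counts to protein acceptors / to water.
#' @param spec a [pf_model_spec()].
#' @return Numeric object of the same shape as the inputs.
#' @examples
#' pf_structure(2, 0, pf_model_spec("park"))       # 500
#' pf_structure(0:3, c(1, 0, 2, 0), pf_model_spec("ratio"))
#' @export
pf_structure <- function(hb_p, hb_w, spec) {
  if (!inherits(spec, "pf_model_spec")) stop2("spec must be a pf_model_spec")
  if (any(hb_p < 0) || any(hb_w < 0)) stop2("hydrogen-bond counts must be >= 0")
  if (!identical(dim(hb_p), dim(hb_w)) || length(hb_p) != length(hb_w))
    stop2("hb_p and hb_w must have the same shape")
  nh <- pmin(hb_p, 1) - pmin(hb_w, 1)
  switch(spec$model,
         park = spec$b^nh,
         ratio = hb_p / pmax(hb_w, 1),
         difference = hb_p - hb_w,
         bound_difference = nh)
}

#' Per-cluster mean protection factors
#'
#' For each macro-cluster `j`, draws `n_sample` frames from the cluster with
#' probability proportional to the frames' equilibrium weights (with
#' replacement when the cluster holds fewer than `n_sample` frames; a
#' message reports this) and averages the per-structure scores:
#' `PF_ij = mean over sampled frames of f_i`.
#'
#' @param counts an `"hbond_counts"` object.
#' @param cluster_labels per-frame 0-based macro labels (e.g. from
#'   [frame_macro_labels()]); `NA` frames are ignored.
#' @param weights per-frame equilibrium weights ([frame_weights()]); `NULL`
#'   for uniform sampling.
#' @param spec a [pf_model_spec()].
#' @param n_sample structures sampled per cluster (default 4000).
#' @param seed RNG seed; the sampling is deterministic given it.
#' @return `"pf_table"`: `pf` (sites x clusters matrix `PF_ij`), `sites`,
#'   `clusters` (0-based ids), `spec`, `criteria`, `n_sample`.
#' @export
pf_cluster <- function(counts, cluster_labels, weights = NULL, spec,
                       n_sample = 4000L, seed = 1L) {
  if (!inherits(counts, "hbond_counts")) stop2("counts must be hbond_counts")
  if (!is_count(n_sample)) stop2("n_sample must be a positive integer")
  nf <- nrow(counts$hb_p)
  if (length(cluster_labels) != nf)
    stop2("cluster_labels length ", length(cluster_labels),
          " does not match ", nf, " frames of counts")
  weights <- weights %||% rep(1 / nf, nf)
  f_all <- pf_structure(counts$hb_p, counts$hb_w, spec)

  clusters <- sort(unique(cluster_labels[!is.na(cluster_labels)]))
  set.seed(as.integer(seed))
  pf <- matrix(NA_real_, length(counts$sites), length(clusters),
               dimnames = list(counts$sites, as.character(clusters)))
  for (ci in seq_along(clusters)) {
    j <- clusters[ci]
    in_j <- which(!is.na(cluster_labels) & cluster_labels == j)
    if (length(in_j) == 0L) stop2("cluster ", j, " is empty")
    w <- weights[in_j]
    if (sum(w) <= 0) w <- rep(1, length(in_j))
    replace <- length(in_j) < n_sample
    if (replace)
      message("cluster ", j, ": ", length(in_j), " frames < n_sample = ",
              n_sample, "; sampling with replacement")
    take <- sample(in_j, n_sample, replace = replace, prob = w)
    pf[, ci] <- colMeans(f_all[take, , drop = FALSE])
  }
  structure(list(pf = pf, sites = counts$sites, clusters = clusters,
                 spec = spec, criteria = counts$criteria,
                 n_sample = n_sample),
            class = "pf_table")
}

#' @export
print.pf_table <- function(x, ...) {
  cat("pf_table:", length(x$sites), "sites x", length(x$clusters),
      "clusters,", x$spec$model, "model, n_sample", x$n_sample, "\n")
  invisible(x)
}

#' @export
as.data.frame.pf_table <- function(x, ...) {
  data.frame(site = rep(x$sites, times = length(x$clusters)),
             cluster = rep(x$clusters, each = length(x$sites)),
             pf = as.vector(x$pf))
}

#' Ensemble protection factors
#'
#' The per-site ensemble value is the population-weighted average of the
#' per-cluster means over the included clusters (their populations
#' renormalized to sum to one).  By default the five most populated clusters
#' are included.
#'
#' @param pf_table a `"pf_table"` from [pf_cluster()].
#' @param populations named macro-cluster populations
#'   ([macro_populations()]); names are 0-based cluster ids.
#' @param included_clusters integer ids of clusters to include; default the
#'   (up to) five most populated.
#' @return Named numeric vector `PF_i` per site, with attributes `weights`
#'   (the renormalized cluster weights) and `included_clusters`.
#' @export
pf_ensemble <- function(pf_table, populations, included_clusters = NULL) {
  if (!inherits(pf_table, "pf_table")) stop2("pf_table must be a pf_table")
  ids <- as.integer(names(populations))
  if (is.null(included_clusters))
    included_clusters <- ids[order(-populations)][seq_len(min(5L, length(ids)))]
  pops <- populations[match(included_clusters, ids)]
  if (any(is.na(pops)) || any(pops <= 0))
    stop2("included clusters must have positive populations")
  have <- match(as.character(included_clusters), colnames(pf_table$pf))
  if (any(is.na(have)))
    stop2("pf_table lacks cluster(s): ",
          paste(included_clusters[is.na(have)], collapse = ", "))
  w <- as.numeric(pops) / sum(pops)
  out <- as.numeric(pf_table$pf[, have, drop = FALSE] %*% w)
  names(out) <- pf_table$sites
  attr(out, "weights") <- stats::setNames(w, included_clusters)
  attr(out, "included_clusters") <- included_clusters
  out
}

#' Compare computed and experimental protection factors
#'
#' Matches sites by exact label (chain letter + residue number; no fuzzy
#' matching, a silent mismatch being worse than an error) and reports the
#' Pearson correlation over the shared sites together with per-site
#' residuals; sites present in only one table are listed as unmatched.
#'
#' @param pf_i named per-site ensemble values ([pf_ensemble()]).
#' @param experimental data frame with columns `site` and `pf`.
#' @return List: `r` (Pearson), `n_shared`, `residuals` (data frame `site`,
#'   `computed`, `experimental`, `residual`), `unmatched_computed`,
#'   `unmatched_experimental`.
#' @export
compare_experimental <- function(pf_i, experimental) {
  if (!all(c("site", "pf") %in% names(experimental)))
    stop2("experimental table needs columns site and pf")
  shared <- intersect(names(pf_i), experimental$site)
  if (length(shared) < 3L)
    stop2("only ", length(shared), " shared site(s) after label matching; ",
          "need at least 3")
  exp_pf <- experimental$pf[match(shared, experimental$site)]
  comp <- as.numeric(pf_i[shared])
  list(r = stats::cor(comp, exp_pf),
       n_shared = length(shared),
       residuals = data.frame(site = shared, computed = comp,
                              experimental = exp_pf,
                              residual = comp - exp_pf),
       unmatched_computed = setdiff(names(pf_i), shared),
       unmatched_experimental = setdiff(experimental$site, shared))
}

#' Sites whose protection varies strongly across clusters
#'
#' Two presets, computed over the per-cluster means `PF_ij` of each site:
#' `variance_ratio` flags sites whose variance is at least `threshold`
#' (default 10) times their mean; `cv` flags sites whose coefficient of
#' variation is at least `threshold` (default 0.10).  Sites with zero mean
#' are skipped under `variance_ratio` (a message reports them).
#'
#' @param pf_table a `"pf_table"` (needs at least 2 clusters).
#' @param criterion `"variance_ratio"` or `"cv"`.
#' @param threshold override of the preset threshold.
#' @return Character vector of flagged site labels; attribute `"stats"`
#'   holds the per-site mean, variance and cv.
#' @export
variable_sites <- function(pf_table, criterion = c("variance_ratio", "cv"),
                           threshold = NULL) {
  criterion <- match.arg(criterion)
  if (ncol(pf_table$pf) < 2L) stop2("need at least 2 clusters")
  threshold <- threshold %||% switch(criterion, variance_ratio = 10, cv = 0.10)
  mu <- rowMeans(pf_table$pf)
  v <- apply(pf_table$pf, 1L, stats::var)
  cv <- ifelse(mu != 0, sqrt(v) / abs(mu), NA_real_)
  st <- data.frame(site = pf_table$sites, mean = mu, variance = v, cv = cv)
  if (criterion == "variance_ratio") {
    zero <- mu == 0
    if (any(zero))
      message("skipping zero-mean site(s) under variance_ratio: ",
              paste(pf_table$sites[zero], collapse = ", "))
    flagged <- pf_table$sites[!zero & v >= threshold * mu]
  } else {
    flagged <- pf_table$sites[!is.na(cv) & cv >= threshold]
  }
  attr(flagged, "stats") <- st
  flagged
}

#' Hydrogen-exchange kinetics in the two-state opening model
#'
#' Exchange happens from the transiently open state of a site:
#' closed <-> open (rates `k_op`, `k_cl`), followed by intrinsic exchange at
#' `k_int`.  The protection factor is `PF = k_cl / k_op`.  In the EX2 regime
#' (`k_cl >> k_int`; validity flagged when `k_cl / k_int >=
#' ex2_ratio_threshold`) the observed rate is the intrinsic rate attenuated
#' by the protection factor, `k_obs = k_int / PF`.
#'
#' @param k_op,k_cl,k_int opening, closing and intrinsic rates (`> 0`, any
#'   common time unit).
#' @param ex2_ratio_threshold minimum `k_cl / k_int` for the EX2 flag.
#' @return `"exchange_kinetics"`: the rates, `pf`, `ex2_valid`.
#' @export
exchange_kinetics <- function(k_op, k_cl, k_int, ex2_ratio_threshold = 100) {
  if (any(c(k_op, k_cl, k_int) <= 0)) stop2("all rates must be > 0")
  structure(list(k_op = k_op, k_cl = k_cl, k_int = k_int,
                 pf = k_cl / k_op,
                 ex2_valid = (k_cl / k_int) >= ex2_ratio_threshold),
            class = "exchange_kinetics")
}

#' Observed exchange rate in the EX2 limit
#'
#' `k_obs = k_int / PF`.  If the kinetics object is outside the EX2 regime a
#' warning is raised and attached to the result.
#'
#' @param kin an [exchange_kinetics()] object.
#' @return Observed rate (same unit as the inputs), possibly with a
#'   `"warning"` attribute.
#' @export
ex2_observed_rate <- function(kin) {
  if (!inherits(kin, "exchange_kinetics")) stop2("kin must be exchange_kinetics")
  out <- kin$k_int / kin$pf
  if (!kin$ex2_valid) {
    msg <- paste0("EX2 approximation questionable: k_cl / k_int = ",
                  signif(kin$k_cl / kin$k_int, 3L))
    warning(msg, call. = FALSE)
    attr(out, "warning") <- msg
  }
  out
}

#' Protection factor from observed and intrinsic rates
#'
#' Inverse of [ex2_observed_rate()]: `PF = k_int / k_obs`.
#'
#' @param k_obs,k_int observed and intrinsic exchange rates (`> 0`).
#' @return Protection factor.
#' @export
pf_from_rates <- function(k_obs, k_int) {
  if (any(c(k_obs, k_int) <= 0)) stop2("rates must be > 0")
  k_int / k_obs
}
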