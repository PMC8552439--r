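# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

#' @noRd
is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == as.integer(x)
}

# Row-stochastic check; tolerance matches the container invariant.
check_stochastic <- function(P, tol = 1e-12, what = "transition matrix") {
  if (!is.matrix(P) || nrow(P) != ncol(P))
    stop2(what, " must be a square matrix")
  if (any(P < 0))
    stop2(what, " has negative entries")
  rs <- rowSums(P)
  if (any(abs(rs - 1) > tol))
    stop2(what, " is not row-stochastic: row sums deviate by up to ",
          format(max(abs(rs - 1))))
  invisible(P)
}

# Site labels are chain letter + residue number, e.g. "A1", "B22".
site_label <- function(chain, resno) paste0(chain, resno)

# Euclidean norms of the rows of a matrix.
row_norms <- function(x) sqrt(rowSums(x * x))

# Split a stacked per-frame vector/matrix into per-trajectory pieces.
split_by_boundaries <- function(n_per_traj) {
  ends <- cumsum(n_per_traj)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  Map(function(s, e) s:e, starts, ends)
}

# Degrees <-> radians
deg <- function(rad) rad * 180 / pi
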