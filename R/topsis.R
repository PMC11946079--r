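# TOPSIS with virtual positive/negative ideal solutions.

#' Normalize a decision matrix for TOPSIS
#'
#' Cost columns are inverted by the min-max complement (so every column is
#' benefit-oriented), then each column is vector-normalized:
#' `z = x / sqrt(sum(x^2))`. Min-max scaling to `[0, 1]` is available as an
#' alternative.
#'
#' @param X Raw decision matrix, alternatives x indicators.
#' @param direction Per-indicator `"benefit"`/`"cost"` vector.
#' @param norm `"vector"` (default, the TOPSIS standard) or `"minmax"`.
#' @return Normalized matrix with all columns benefit-oriented.
#' @export
topsis_normalize <- function(X, direction = rep("benefit", ncol(X)),
                             norm = c("vector", "minmax")) {
  norm <- match.arg(norm)
  X <- adjust_directions(as.matrix(X), direction)
  check_number(X, "X")
  if (norm == "vector") {
    nrm <- sqrt(colSums(X^2))
    bad <- which(nrm == 0)
    if (length(bad))
      stop("zero-norm column(s): ",
           paste(colnames(X)[bad] %||% bad, collapse = ", "), call. = FALSE)
    sweep(X, 2L, nrm, "/")
  } else {
    apply(X, 2L, function(v) {
      r <- max(v) - min(v)
      if (r == 0) rep(0.5, length(v)) else (v - min(v)) / r
    })
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Real and virtual ideal solutions of a normalized decision matrix
#'
#' The positive/negative ideal solutions `Z+`/`Z-` are the column-wise
#' maxima/minima. The virtual ideals extrapolate beyond them:
#' `V+ = 2 Z+ - Z-` and `V- = 2 Z- - Z+`, sharpening discrimination among
#' alternatives close to the real ideals. `V-` may have negative coordinates;
#' distances are unaffected and no clipping is applied.
#'
#' @param Z Normalized, benefit-oriented matrix (n >= 2 alternatives).
#' @return List with vectors `z_plus`, `z_minus`, `v_plus`, `v_minus`.
#' @export
ideal_solutions <- function(Z) {
  Z <- as.matrix(Z)
  if (nrow(Z) < 2L) stop("at least 2 alternatives required", call. = FALSE)
  zp <- apply(Z, 2L, max)
  zm <- apply(Z, 2L, min)
  list(z_plus = zp, z_minus = zm,
       v_plus = 2 * zp - zm, v_minus = 2 * zm - zp)
}

#' Weighted Euclidean distance to a reference point
#'
#' `d = sqrt(sum_j w_j (ref_j - z_j)^2)`; zero iff the row equals the
#' reference wherever the weight is positive.
#'
#' @param row Alternative vector.
#' @param ref Reference vector (same length).
#' @param w Non-negative weight vector (same length).
#' @return Non-negative scalar distance.
#' @export
weighted_distance <- function(row, ref, w) {
  if (length(row) != length(ref) || length(row) != length(w))
    stop("row, ref and w must have equal length", call. = FALSE)
  check_number(w, "w", nonneg = TRUE)
  sqrt(sum(w * (ref - row)^2))
}

#' Blend real- and virtual-ideal distances
#'
#' `S+ = alpha * D+ + beta * F+` and `S- = alpha * D- + beta * F-`, where
#' `D` are distances to the real ideal solutions and `F` to the virtual
#' ones. `alpha = 1, beta = 0` recovers classical TOPSIS.
#'
#' @param d_plus,d_minus Distances to `Z+` and `Z-`.
#' @param f_plus,f_minus Distances to `V+` and `V-`.
#' @param alpha,beta Non-negative blend constants, defaults 0.9 and 0.1.
#' @return List with vectors `s_plus`, `s_minus`.
#' @export
combined_distances <- function(d_plus, d_minus, f_plus, f_minus,
                               alpha = 0.9, beta = 0.1) {
  check_number(alpha, "alpha", nonneg = TRUE)
  check_number(beta, "beta", nonneg = TRUE)
  if (alpha + beta <= 0) stop("alpha + beta must be > 0", call. = FALSE)
  list(s_plus = alpha * d_plus + beta * f_plus,
       s_minus = alpha * d_minus + beta * f_minus)
}

#' Closeness coefficient
#'
#' `C = S- / (S+ + S-)` in `[0, 1]`; values closer to 1 indicate better
#' overall performance.
#'
#' @param s_plus,s_minus Combined distances from [combined_distances()].
#' @return Closeness vector.
#' @export
closeness <- function(s_plus, s_minus) {
  check_number(s_plus, "s_plus", nonneg = TRUE)
  check_number(s_minus, "s_minus", nonneg = TRUE)
  tot <- s_plus + s_minus
  if (any(tot == 0))
    stop("S+ + S- = 0 for some alternative (degenerate identical matrix)",
         call. = FALSE)
  s_minus / tot
}

#' Rank alternatives by TOPSIS with virtual ideal solutions
#'
#' Full chain: direction adjustment + normalization, real and virtual ideal
#' solutions, weighted distances, blended comprehensive distances
#' (`alpha`, `beta`), closeness coefficients and ranking. Ties in closeness
#' are broken deterministically by row order (alternative id order).
#'
#' @param X Raw decision matrix, alternatives x indicators (row names used
#'   as alternative ids).
#' @param weights Indicator weights (non-negative, summing to 1); typically
#'   the exponential-form entropy weights. Default: equal weights.
#' @param direction Per-indicator `"benefit"`/`"cost"` vector.
#' @param alpha,beta Blend constants for real vs virtual ideal distances
#'   (defaults 0.9, 0.1; `alpha = 1, beta = 0` is classical TOPSIS).
#' @param norm Normalization passed to [topsis_normalize()].
#' @return Object of class `wf_topsis`: data frame with one row per
#'   alternative (`d_plus`, `d_minus`, `f_plus`, `f_minus`, `s_plus`,
#'   `s_minus`, `closeness`, `rank`), ordered as the input, with the
#'   normalized matrix, ideals and parameters as attributes.
#' @examples
#' X <- matrix(runif(36, 1, 10), 9, 4,
#'             dimnames = list(paste0("T", 1:9), letters[1:4]))
#' tp <- topsis(X)
#' tp[order(tp$rank), ]
#' @export
topsis <- function(X, weights = NULL,
                   direction = rep("benefit", ncol(X)),
                   alpha = 0.9, beta = 0.1, norm = c("vector", "minmax")) {
  X <- as.matrix(X)
  m <- ncol(X)
  if (is.null(weights)) weights <- rep(1 / m, m)
  if (length(weights) != m)
    stop("one weight per indicator required", call. = FALSE)
  check_number(weights, "weights", nonneg = TRUE)
  if (abs(sum(weights) - 1) > 1e-8)
    stop("weights must sum to 1", call. = FALSE)
  Z <- topsis_normalize(X, direction, norm)
  ideals <- ideal_solutions(Z)
  dp <- apply(Z, 1L, weighted_distance, ref = ideals$z_plus, w = weights)
  dm <- apply(Z, 1L, weighted_distance, ref = ideals$z_minus, w = weights)
  fp <- apply(Z, 1L, weighted_distance, ref = ideals$v_plus, w = weights)
  fm <- apply(Z, 1L, weighted_distance, ref = ideals$v_minus, w = weights)
  s <- combined_distances(dp, dm, fp, fm, alpha, beta)
  C <- closeness(s$s_plus, s$s_minus)
  ord <- order(-C, seq_along(C))       # descending closeness, ties by id order
  rk <- integer(length(C)); rk[ord] <- seq_along(C)
  ids <- rownames(X) %||% paste0("A", seq_len(nrow(X)))
  res <- data.frame(id = ids, d_plus = dp, d_minus = dm,
                    f_plus = fp, f_minus = fm,
                    s_plus = s$s_plus, s_minus = s$s_minus,
                    closeness = C, rank = rk,
                    row.names = ids, stringsAsFactors = FALSE)
  attr(res, "normalized") <- Z
  attr(res, "ideals") <- ideals
  attr(res, "params") <- list(alpha = alpha, beta = beta,
                              weights = weights, norm = match.arg(norm))
  class(res) <- c("wf_topsis", "data.frame")
  res
}

#' Alternatives in ranked order
#'
#' @param result A `wf_topsis` result from [topsis()].
#' @return Character vector of alternative ids, best first.
#' @export
rank_alternatives <- function(result) {
  if (!inherits(result, "wf_topsis"))
    stop("result must come from topsis()", call. = FALSE)
  result$id[order(result$rank)]
}
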