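# Entropy weight method: classical and exponential-form ("improved") weights.

#' Direction-adjust cost indicators
#'
#' Converts cost columns (lower is better) to benefit orientation by the
#' min-max complement `x' = max(x) - x + min(x)`, which preserves
#' non-negativity and the column's value range.
#'
#' @param X Numeric matrix, alternatives x indicators.
#' @param direction Character vector per indicator, `"benefit"` or `"cost"`.
#' @return Matrix with all columns benefit-oriented.
#' @export
adjust_directions <- function(X, direction) {
  X <- as.matrix(X)
  if (length(direction) != ncol(X))
    stop("one direction per indicator required", call. = FALSE)
  if (!all(direction %in% c("benefit", "cost")))
    stop("direction entries must be 'benefit' or 'cost'", call. = FALSE)
  for (j in which(direction == "cost"))
    X[, j] <- max(X[, j]) - X[, j] + min(X[, j])
  X
}

#' Proportional (share) normalization of an indicator matrix
#'
#' `y_ij = x_ij / sum_i(x_ij)`: each indicator column is scaled to sum to 1.
#' Cost indicators must be direction-adjusted beforehand
#' (see [adjust_directions()]).
#'
#' @param X Numeric matrix, alternatives x indicators (finite, no missing).
#' @return Matrix of the same shape with unit column sums.
#' @export
normalize_proportional <- function(X) {
  X <- as.matrix(X)
  check_number(X, "X")
  cs <- colSums(X)
  bad <- which(cs == 0)
  if (length(bad)) {
    nm <- colnames(X)[bad]
    if (is.null(nm)) nm <- bad
    stop("zero column sum for indicator(s): ", paste(nm, collapse = ", "),
         call. = FALSE)
  }
  sweep(X, 2L, cs, "/")
}

#' Non-negative shift of a normalized matrix
#'
#' Adds a small constant (default 0.01) to every entry so that no zero values
#' enter the composite-score stage. The shift is affine; the matrix is not
#' renormalized.
#'
#' @param Y Normalized matrix.
#' @param delta Positive shift, default 0.01.
#' @return Shifted matrix `Z = Y + delta`.
#' @export
nonneg_shift <- function(Y, delta = 0.01) {
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta) || delta <= 0)
    stop("delta must be a single positive number", call. = FALSE)
  as.matrix(Y) + delta
}

#' Information entropy of each indicator
#'
#' `E_i = -(1/ln n) * sum_j y_ij ln y_ij` over the n alternatives, with the
#' convention `0 * ln 0 = 0`. For a column summing to 1 the entropy lies in
#' `[0, 1]`: 1 for a uniform column (no discriminating information), 0 for a
#' one-hot column.
#'
#' @param Y Normalized matrix (columns sum to 1, entries in `[0, 1]`).
#' @return Named numeric vector of entropies, one per indicator.
#' @export
entropy <- function(Y) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  if (n < 2L) stop("entropy needs at least 2 alternatives (ln n = 0)", call. = FALSE)
  check_number(Y, "Y", nonneg = TRUE)
  plogp <- Y * log(Y)
  plogp[Y == 0] <- 0
  -colSums(plogp) / log(n)
}

#' Classical entropy weights
#'
#' `H_i = (1 - E_i) / sum(1 - E_i)`: indicators with lower entropy (more
#' dispersed values) receive larger weights.
#'
#' @param E Entropy vector from [entropy()].
#' @return Weights summing to 1.
#' @export
classical_weights <- function(E) {
  check_number(E, "E", nonneg = TRUE)
  d <- sum(1 - E)
  if (d <= 0)
    stop("all entropies are 1: classical weights undefined", call. = FALSE)
  (1 - E) / d
}

#' Exponential-form entropy weights with a dispersion coefficient
#'
#' A variant of the entropy weight method in which the linear `1 - E` kernel
#' is replaced by the exponential difference
#' `exp(k * (sum(E) - E_x + 1)) - exp(k * E_x)`, normalized over indicators.
#' The slope coefficient `k` tunes how strongly entropy differences spread
#' the weights: for entropies in `[0, 1]` the weights are non-negative, sum
#' to 1, are non-increasing in the indicator's entropy, and for small entropy
#' spreads are less dispersed than the classical weights.
#'
#' @param E Entropy vector (values in `[0, 1]`).
#' @param k_coef Positive slope coefficient, default 1.
#' @return Weights summing to 1.
#' @examples
#' improved_weights(c(0.8, 0.9))         # approx (0.554, 0.446)
#' classical_weights(c(0.8, 0.9))        # (2/3, 1/3): more dispersed
#' @export
improved_weights <- function(E, k_coef = 1) {
  check_number(E, "E", nonneg = TRUE)
  if (!is.numeric(k_coef) || length(k_coef) != 1L || !is.finite(k_coef) || k_coef <= 0)
    stop("k_coef must be a single positive number", call. = FALSE)
  if (length(E) < 2L) stop("at least 2 indicators required", call. = FALSE)
  S <- sum(E)
  num <- exp(k_coef * (S - E + 1)) - exp(k_coef * E)
  d <- sum(num)
  if (!is.finite(d) || d <= 0)
    stop("degenerate weight denominator (check entropies are in [0, 1])",
         call. = FALSE)
  num / d
}

#' Composite scores from a shifted matrix and indicator weights
#'
#' Weighted sum `S_j = sum_i H_i * z_ji` per alternative (row); higher is
#' better once cost indicators have been direction-adjusted.
#'
#' @param Z Shifted normalized matrix, alternatives x indicators.
#' @param H Weight vector summing to 1, one weight per indicator.
#' @return Named numeric vector of scores, one per alternative.
#' @export
composite_scores <- function(Z, H) {
  Z <- as.matrix(Z)
  if (length(H) != ncol(Z))
    stop(sprintf("weight length (%d) must equal indicator count (%d)",
                 length(H), ncol(Z)), call. = FALSE)
  check_number(H, "H", nonneg = TRUE)
  drop(Z %*% H)
}

#' Entropy-weight analysis of an indicator matrix
#'
#' Runs the full chain: direction adjustment of cost indicators, proportional
#' normalization, non-negative shift, per-indicator entropies, classical and
#' exponential-form weights, and composite scores (using the selected
#' weighting).
#'
#' @param X Raw indicator matrix, alternatives x indicators (named).
#' @param direction Per-indicator `"benefit"`/`"cost"` vector.
#' @param k_coef Dispersion coefficient of the exponential-form weights.
#' @param delta Non-negative shift applied before scoring, default 0.01.
#' @param method Weighting used for the composite scores: `"improved"`
#'   (exponential form, default) or `"classical"`.
#' @param entropy_on_shifted If `TRUE`, compute entropies from the shifted
#'   matrix (renormalized) instead of the plain normalized matrix. Default
#'   `FALSE`: the shift feeds only the composite-score stage.
#' @return Object of class `wf_entropy`: list with `normalized`, `shifted`,
#'   `entropy`, `weights_classical`, `weights_improved`, `weights` (the
#'   selected set), `scores`, and the parameters used.
#' @examples
#' X <- matrix(runif(27, 1, 10), 9, 3,
#'             dimnames = list(paste0("T", 1:9), c("a", "b", "c")))
#' ew <- entropy_weights(X, direction = c("benefit", "benefit", "cost"))
#' ew$weights
#' @export
entropy_weights <- function(X, direction = rep("benefit", ncol(X)),
                            k_coef = 1, delta = 0.01,
                            method = c("improved", "classical"),
                            entropy_on_shifted = FALSE) {
  method <- match.arg(method)
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("at least 2 alternatives required", call. = FALSE)
  Xb <- adjust_directions(X, direction)
  if (any(Xb < 0))
    stop("negative values after direction adjustment; shift raw data first",
         call. = FALSE)
  Y <- normalize_proportional(Xb)
  Z <- nonneg_shift(Y, delta)
  E <- if (entropy_on_shifted) entropy(normalize_proportional(Z)) else entropy(Y)
  E <- pmin(pmax(E, 0), 1)  # clamp tiny fp excursions at the boundaries
  Hc <- classical_weights(E)
  Hx <- improved_weights(E, k_coef)
  H <- if (method == "improved") Hx else Hc
  structure(list(
    normalized = Y, shifted = Z, entropy = E,
    weights_classical = Hc, weights_improved = Hx, weights = H,
    scores = composite_scores(Z, H),
    method = method, k_coef = k_coef, delta = delta,
    direction = direction), class = "wf_entropy")
}

#' @export
print.wf_entropy <- function(x, ...) {
  cat("Entropy weighting (", x$method, ", k = ", x$k_coef, ")\n", sep = "")
  print(round(rbind(entropy = x$entropy,
                    classical = x$weights_classical,
                    improved = x$weights_improved), 4))
  cat("Composite scores:\n")
  print(round(sort(x$scores, decreasing = TRUE), 4))
  invisible(x)
}
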