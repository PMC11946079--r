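# Evaluation model, indicator screening, and the end-to-end pipeline.

#' Indicator matrix container
#'
#' Couples a treatments x indicators value matrix with per-indicator
#' direction (`"benefit"`/`"cost"`) and category (`"yield"`, `"quality"`,
#' `"efficiency"`) metadata.
#'
#' @param values Numeric matrix with row names (alternatives) and column
#'   names (indicators); finite, no missing cells, >= 2 rows.
#' @param direction,category Character vectors, one entry per indicator.
#' @return Object of class `wf_imatrix`: list with `values`, `direction`,
#'   `category` (the latter two named by indicator).
#' @export
indicator_matrix <- function(values, direction, category) {
  values <- as.matrix(values)
  if (nrow(values) < 2L || ncol(values) < 1L)
    stop("need >= 2 alternatives and >= 1 indicator", call. = FALSE)
  check_number(values, "values")
  if (is.null(colnames(values)))
    stop("values must have indicator column names", call. = FALSE)
  if (length(direction) != ncol(values) || length(category) != ncol(values))
    stop("direction and category must have one entry per indicator",
         call. = FALSE)
  if (!all(direction %in% c("benefit", "cost")))
    stop("direction entries must be 'benefit' or 'cost'", call. = FALSE)
  structure(list(values = values,
                 direction = setNames(direction, colnames(values)),
                 category = setNames(category, colnames(values))),
            class = "wf_imatrix")
}

#' @export
print.wf_imatrix <- function(x, ...) {
  cat("Indicator matrix:", nrow(x$values), "alternatives x",
      ncol(x$values), "indicators\n")
  print(data.frame(indicator = colnames(x$values),
                   category = unname(x$category),
                   direction = unname(x$direction)), row.names = FALSE)
  invisible(x)
}

#' Hierarchical evaluation model of the trial
#'
#' The three-dimension indicator system: yield (C11); quality — hardness Hd
#' (C21), vitamin C VC (C22), soluble protein SP (C23), lycopene LC (C24),
#' titratable acidity TA (C25), soluble sugars SS (C26), nitrate NA (C27),
#' soluble solids SSC (C28), moisture MC (C29); efficiency — WUE (C31) and
#' PFP (C32). Hd, TA and NA are cost indicators. The fruit shape index (FSI)
#' can be carried as an additional quality indicator so that
#' stability-based screening ([screen_indicators()]) can act on it.
#'
#' @param include_fsi Carry the fruit shape index as a candidate quality
#'   indicator (default `FALSE`).
#' @return Data frame with columns `indicator`, `code`, `category`,
#'   `direction`, `included`.
#' @export
evaluation_model <- function(include_fsi = FALSE) {
  m <- data.frame(
    indicator = c("yield", "Hd", "VC", "SP", "LC", "TA", "SS", "NA", "SSC",
                  "MC", "WUE", "PFP"),
    code = c("C11", paste0("C2", 1:9), "C31", "C32"),
    category = c("yield", rep("quality", 9), rep("efficiency", 2)),
    direction = c("benefit", "cost", "benefit", "benefit", "benefit", "cost",
                  "benefit", "cost", "benefit", "benefit", "benefit",
                  "benefit"),
    included = TRUE, stringsAsFactors = FALSE)
  if (include_fsi)
    m <- rbind(m, data.frame(indicator = "FSI", code = "C2X",
                             category = "quality", direction = "benefit",
                             included = TRUE))
  m
}

#' Spearman rank-correlation matrix of an indicator panel
#'
#' Pairwise Spearman correlations (average-rank tie handling) between
#' indicator columns; constant indicators, whose rank correlation is
#' undefined, are excluded and reported in the `"excluded"` attribute.
#'
#' @param X Numeric matrix (alternatives x indicators) or a `wf_imatrix`.
#' @return Symmetric correlation matrix with unit diagonal; attribute
#'   `excluded` names any constant indicators dropped.
#' @export
spearman_matrix <- function(X) {
  if (inherits(X, "wf_imatrix")) X <- X$values
  X <- as.matrix(X)
  if (nrow(X) < 3L) stop("need at least 3 alternatives", call. = FALSE)
  check_number(X, "X")
  const <- apply(X, 2L, function(v) diff(range(v)) == 0)
  excluded <- colnames(X)[const]
  if (all(const)) stop("all indicators are constant", call. = FALSE)
  rho <- cor(X[, !const, drop = FALSE], method = "spearman")
  attr(rho, "excluded") <- excluded
  rho
}

#' Count significant Spearman correlations
#'
#' Tests every indicator pair with [stats::cor.test()] (exact null
#' distribution for untied ranks at this sample size; t approximation under
#' ties) and counts p-values below `level`. Advisory output for indicator
#' screening.
#'
#' @param X Numeric matrix or `wf_imatrix`.
#' @param level Significance level, default 0.05.
#' @return List with `n_significant` and the `p` matrix.
#' @export
spearman_significance <- function(X, level = 0.05) {
  if (inherits(X, "wf_imatrix")) X <- X$values
  X <- as.matrix(X)
  m <- ncol(X)
  p <- matrix(NA_real_, m, m, dimnames = list(colnames(X), colnames(X)))
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    if (diff(range(X[, i])) == 0 || diff(range(X[, j])) == 0) next
    p[i, j] <- p[j, i] <- suppressWarnings(
      cor.test(X[, i], X[, j], method = "spearman")$p.value)
  }
  list(n_significant = sum(p[upper.tri(p)] < level, na.rm = TRUE), p = p)
}

#' Screen indicators out of the evaluation model
#'
#' Removes user-flagged unstable indicators (e.g. a fruit shape index that
#' varies with cultivar and environment rather than treatment). Exclusion is
#' advisory and configuration-driven; removing the last indicator of a
#' category is refused.
#'
#' @param model Evaluation model data frame from [evaluation_model()].
#' @param unstable Character vector of indicator names to drop.
#' @return The model with flagged indicators marked `included = FALSE`.
#' @export
screen_indicators <- function(model, unstable = character()) {
  if (!all(c("indicator", "category", "included") %in% names(model)))
    stop("not an evaluation model data frame", call. = FALSE)
  unknown <- setdiff(unstable, model$indicator)
  if (length(unknown))
    stop("unknown indicator(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  model$included[model$indicator %in% unstable] <- FALSE
  left <- table(model$category[model$included])
  gone <- setdiff(unique(model$category), names(left))
  if (length(gone))
    stop("screening would empty category: ", paste(gone, collapse = ", "),
         call. = FALSE)
  model
}

#' Run the full multi-objective evaluation
#'
#' Executes the whole chain on a synthetic trial (or tidy records):
#' replicate aggregation, indicator screening, per-category and global
#' entropy weighting with composite scores, TOPSIS ranking with virtual
#' ideal solutions, Spearman screening correlations, and water/fertilizer
#' input reductions of the top-ranked treatment relative to each
#' full-irrigation treatment. Deterministic given the trial and settings.
#'
#' @param trial A `wf_trial` from [generate_trial()], or a tidy records data
#'   frame with columns `year, treatment, replicate, indicator, value` (WUE
#'   and PFP rows already present or added via [add_efficiency()]).
#' @param k_coef,delta Entropy-weighting parameters (see
#'   [entropy_weights()]).
#' @param alpha,beta Virtual-ideal blend constants (see [topsis()]).
#' @param weighting `"improved"` or `"classical"` entropy weights.
#' @param mode `"both"` (default), `"category"` (per-dimension composite
#'   scores only) or `"global"` (single 12-indicator TOPSIS only).
#' @param unstable Indicators to screen out, passed to
#'   [screen_indicators()].
#' @param treatments Treatment input table for the reduction section.
#' @return Object of class `wf_report`: list with the aggregated
#'   `indicator_matrix`, screened `model`, `weights` (per category and
#'   global), `category_scores`, `topsis` table, `ranking`, `correlations`,
#'   `n_significant`, `reductions`, and a `settings` echo.
#' @examples
#' rep <- run_evaluation(generate_trial(trial_config(seed = 7)))
#' rep$ranking
#' @export
run_evaluation <- function(trial, k_coef = 1, delta = 0.01,
                           alpha = 0.9, beta = 0.1,
                           weighting = c("improved", "classical"),
                           mode = c("both", "category", "global"),
                           unstable = character(),
                           treatments = load_treatments()) {
  weighting <- match.arg(weighting)
  mode <- match.arg(mode)
  im <- if (inherits(trial, "wf_trial")) aggregate_replicates(trial)
        else aggregate_replicates(trial,
               meta = list(direction = setNames(evaluation_model()$direction,
                                                evaluation_model()$indicator),
                           category = setNames(evaluation_model()$category,
                                               evaluation_model()$indicator)))
  model <- evaluation_model(include_fsi = "FSI" %in% colnames(im$values))
  model <- model[model$indicator %in% colnames(im$values), , drop = FALSE]
  model <- screen_indicators(model, unstable)
  keep <- model$indicator[model$included]
  X <- im$values[, keep, drop = FALSE]
  dir_ <- unname(im$direction[keep])
  cat_ <- unname(im$category[keep])

  weights_by_cat <- list(); cat_scores <- list()
  if (mode %in% c("both", "category")) {
    for (cg in unique(cat_)) {
      cols <- which(cat_ == cg)
      if (length(cols) >= 2L) {
        ew <- entropy_weights(X[, cols, drop = FALSE], dir_[cols],
                              k_coef = k_coef, delta = delta,
                              method = weighting)
        weights_by_cat[[cg]] <- ew$weights
        cat_scores[[cg]] <- ew$scores
      } else {
        # single-indicator category: weight 1, score = shifted share
        y <- normalize_proportional(
          adjust_directions(X[, cols, drop = FALSE], dir_[cols]))
        weights_by_cat[[cg]] <- setNames(1, keep[cols])
        cat_scores[[cg]] <- drop(nonneg_shift(y, delta))
      }
    }
  }

  global <- NULL; tp <- NULL; ranking <- NULL
  if (mode %in% c("both", "global")) {
    global <- entropy_weights(X, dir_, k_coef = k_coef, delta = delta,
                              method = weighting)
    tp <- topsis(X, weights = global$weights, direction = dir_,
                 alpha = alpha, beta = beta)
    ranking <- rank_alternatives(tp)
  }

  rho <- spearman_matrix(X)
  nsig <- spearman_significance(X)$n_significant

  reductions <- NULL
  if (!is.null(ranking)) {
    top <- ranking[1]
    fi_ids <- rownames(l9_design())[l9_design()[, "IA"] == 3L]
    fi_ids <- intersect(fi_ids, unique(treatments$id))
    reductions <- lapply(setNames(fi_ids, fi_ids), function(b)
      input_reduction(top, b, treatments))
  }

  structure(list(
    indicator_matrix = im, model = model,
    weights = list(by_category = weights_by_cat,
                   global = if (is.null(global)) NULL else global$weights),
    entropy = if (is.null(global)) NULL else global$entropy,
    category_scores = cat_scores,
    topsis = tp, ranking = ranking,
    correlations = rho, n_significant = nsig,
    reductions = reductions,
    settings = list(k_coef = k_coef, delta = delta, alpha = alpha,
                    beta = beta, weighting = weighting, mode = mode,
                    unstable = unstable,
                    seed = if (inherits(trial, "wf_trial"))
                      trial$config$seed else NA_integer_)),
    class = "wf_report")
}

#' @export
print.wf_report <- function(x, ...) {
  s <- x$settings
  cat("Water-fertilizer evaluation report (mode =", s$mode,
      ", weighting =", s$weighting, ")\n")
  if (!is.null(x$ranking)) {
    cat("TOPSIS ranking (alpha =", s$alpha, ", beta =", s$beta, "):\n  ",
        paste(x$ranking, collapse = " > "), "\n")
    cat("Top treatment closeness:",
        round(max(x$topsis$closeness), 4), "\n")
  }
  for (cg in names(x$category_scores)) {
    sc <- x$category_scores[[cg]]
    cat(sprintf("Best by %s score: %s (%.4f)\n", cg,
                names(which.max(sc)), max(sc)))
  }
  if (!is.null(x$reductions) && length(x$reductions)) {
    top <- x$ranking[1]
    for (b in names(x$reductions)) {
      r <- x$reductions[[b]]
      cat(sprintf("%s vs %s: water reduction %s%%, fertilizer reduction %.1f%%\n",
                  top, b, paste(sprintf("%.1f", r$water_pct), collapse = "/"),
                  r$fert_pct))
    }
  }
  cat("Significant Spearman correlations:", x$n_significant, "\n")
  invisible(x)
}
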