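# Orthogonal design, treatment fixture, irrigation requirement, range analysis.

#' Factor names of the water-fertilizer design
#'
#' Four factors at three levels each: irrigation amount (IA, as a fraction of
#' crop evapotranspiration ET_c) and the fertilizer rate applied at the
#' seedling (FI), flowering/fruit-setting (FII) and peak-fruit (FIII) stages.
#'
#' @return Character vector of the four factor names.
#' @export
design_factors <- function() c("IA", "FI", "FII", "FIII")

#' Physical values of the three levels of each factor
#'
#' Irrigation levels are ET_c fractions (0.50 = severe deficit DIS, 0.75 =
#' mild deficit DIM, 1.00 = full irrigation FI); fertilizer levels are
#' per-stage rates in kg/ha.
#'
#' @return Named list with `irrigation_fraction` and `fertilizer_kg_ha`,
#'   each a length-3 increasing numeric vector.
#' @export
design_levels <- function() {
  list(irrigation_fraction = c(0.50, 0.75, 1.00),
       fertilizer_kg_ha    = c(562.5, 750, 937.5))
}

#' Build the L9(3^4) orthogonal array of the trial
#'
#' Returns the 9-run, 4-factor, 3-level orthogonal array underlying
#' treatments T1-T9, reconstructed from the treatment factor-level codes
#' (e.g. T5 = DIM, FI 750, FII 937.5, FIII 562.5). Every level appears
#' exactly three times in each column and every ordered pair of levels
#' appears exactly once in each pair of columns.
#'
#' @return A 9 x 4 integer matrix of level indices in `{1, 2, 3}`, with row
#'   names `T1`..`T9` and column names from [design_factors()].
#' @examples
#' d <- l9_design()
#' validate_design(d)
#' @export
l9_design <- function() {
  m <- matrix(c(
    1L, 1L, 1L, 1L,
    1L, 2L, 2L, 2L,
    1L, 3L, 3L, 3L,
    2L, 1L, 2L, 3L,
    2L, 2L, 3L, 1L,
    2L, 3L, 1L, 2L,
    3L, 1L, 3L, 2L,
    3L, 2L, 1L, 3L,
    3L, 3L, 2L, 1L),
    nrow = 9, byrow = TRUE,
    dimnames = list(paste0("T", 1:9), design_factors()))
  m
}

#' Validate an orthogonal design matrix
#'
#' Checks column balance (each level index 1..3 appears exactly three times
#' per column) and pairwise orthogonality (all nine ordered level pairs occur
#' exactly once for every pair of columns).
#'
#' @param design Integer matrix of level indices, 9 rows x 4 columns.
#' @return `design`, invisibly, if valid; otherwise an error.
#' @export
validate_design <- function(design) {
  if (!is.matrix(design) || nrow(design) != 9L || ncol(design) != 4L)
    stop("design must be a 9 x 4 matrix of level indices", call. = FALSE)
  if (!all(design %in% 1:3))
    stop("design cells must be level indices in {1, 2, 3}", call. = FALSE)
  for (j in seq_len(ncol(design))) {
    if (!all(tabulate(design[, j], 3L) == 3L))
      stop(sprintf("column %d is not balanced: each level must occur 3 times", j),
           call. = FALSE)
  }
  for (a in 1:3) for (b in (a + 1):4) {
    pairs <- paste(design[, a], design[, b])
    if (anyDuplicated(pairs))
      stop(sprintf("columns %d and %d are not orthogonal", a, b), call. = FALSE)
  }
  invisible(design)
}

#' Load a treatment table of irrigation volumes and stage fertilizer rates
#'
#' Reads a CSV with columns `id, year, irrigation_m3_ha, fert1_kg_ha,
#' fert2_kg_ha, fert3_kg_ha` (one row per treatment x year) and validates it:
#' all cells numeric, no duplicated (id, year), positive irrigation volumes.
#' The packaged fixture (the default) holds the trial's applied amounts:
#' per-year seasonal irrigation volume in m3/ha and the three per-stage
#' fertilizer rates in kg/ha for treatments T1-T9.
#'
#' @param path CSV file path; default is the packaged treatment table.
#' @return A data frame with the input columns plus `fert_total_kg_ha`,
#'   ordered by treatment then year.
#' @examples
#' tr <- load_treatments()
#' subset(tr, id == "T5")
#' @export
load_treatments <- function(path = system.file("extdata", "table1_treatments.csv",
                                               package = "wfeval", mustWork = TRUE)) {
  if (!file.exists(path)) stop("treatment table not found: ", path, call. = FALSE)
  tab <- tryCatch(read.csv(path, stringsAsFactors = FALSE, colClasses = "character"),
                  error = function(e) stop("cannot parse treatment table: ",
                                           conditionMessage(e), call. = FALSE))
  needed <- c("id", "year", "irrigation_m3_ha",
              "fert1_kg_ha", "fert2_kg_ha", "fert3_kg_ha")
  if (nrow(tab) == 0L)
    stop("treatment table is empty", call. = FALSE)
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols))
    stop("treatment table missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (any(!nzchar(tab$id)))
    stop("missing treatment id in row(s) ",
         paste(which(!nzchar(tab$id)), collapse = ", "), call. = FALSE)
  num_cols <- setdiff(needed, "id")
  for (cn in num_cols) {
    v <- suppressWarnings(as.numeric(tab[[cn]]))
    if (anyNA(v))
      stop(sprintf("non-numeric value in column '%s', row(s) %s", cn,
                   paste(which(is.na(v)), collapse = ", ")), call. = FALSE)
    tab[[cn]] <- v
  }
  key <- paste(tab$id, tab$year)
  if (anyDuplicated(key))
    stop("duplicate (id, year) row(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  if (any(tab$irrigation_m3_ha <= 0))
    stop("irrigation volumes must be positive", call. = FALSE)
  tab$fert_total_kg_ha <- tab$fert1_kg_ha + tab$fert2_kg_ha + tab$fert3_kg_ha
  tab[order(tab$id, tab$year), , drop = FALSE]
}

#' Stage pan coefficients
#'
#' Default pan coefficients (K_cp) converting cumulative pan evaporation into
#' crop water demand for the three growth stages: 0.6 (seedling), 1.3
#' (flowering/fruit-setting), 1.1 (peak fruit).
#'
#' @return Named numeric vector of length 3.
#' @export
stage_pan_coefficients <- function() {
  c(seedling = 0.6, flowering = 1.3, peak_fruit = 1.1)
}

#' Irrigation requirement from pan evaporation
#'
#' Computes the irrigation amount `I = Ep * Kcp * A`, where `Ep` is cumulative
#' evaporation (mm) from a standard evaporation pan, `Kcp` the pan
#' coefficient, and `A` the irrigated area (m2). With 1 mm of water over
#' 1 m2 equal to 1 litre, the result is in litres.
#'
#' @param Ep Cumulative pan evaporation, mm (>= 0).
#' @param A Irrigated area, m2 (> 0).
#' @param Kcp Pan coefficient (> 0); if `NULL`, taken from `stage`.
#' @param stage Growth stage used to pick a default `Kcp`
#'   (see [stage_pan_coefficients()]); ignored when `Kcp` is given.
#' @return Irrigation amount in litres.
#' @examples
#' irrigation_requirement(Ep = 100, A = 10, stage = "flowering")  # 1300 L
#' @export
irrigation_requirement <- function(Ep, A, Kcp = NULL,
                                   stage = c("seedling", "flowering", "peak_fruit")) {
  check_number(Ep, "Ep", nonneg = TRUE)
  check_number(A, "A", positive = TRUE)
  if (is.null(Kcp)) {
    stage <- match.arg(stage)
    Kcp <- stage_pan_coefficients()[[stage]]
  }
  check_number(Kcp, "Kcp", positive = TRUE)
  Ep * Kcp * A
}

#' Range analysis of an orthogonal-trial response
#'
#' Taguchi-style range analysis: for each factor, the mean response over the
#' three runs at each level (k-bar), the range `R = max(k-bar) - min(k-bar)`
#' ranking factor influence, and the optimal level (largest level mean for a
#' benefit response, smallest for a cost response).
#'
#' @param responses Numeric vector of 9 per-run responses (replicates already
#'   averaged), in design row order.
#' @param design Level-index matrix from [l9_design()] (validated).
#' @param direction `"benefit"` (higher is better) or `"cost"`.
#' @return An object of class `wf_range`: list with `level_means` (factors x
#'   levels matrix), `range` (named vector), `factor_order` (factor names by
#'   descending range, ties kept in column order), `optimal_level` (named
#'   integer vector) and `direction`.
#' @examples
#' d <- l9_design()
#' ra <- range_analysis(rnorm(9, 100, 10), d)
#' ra$factor_order
#' @export
range_analysis <- function(responses, design = l9_design(),
                           direction = c("benefit", "cost")) {
  direction <- match.arg(direction)
  validate_design(design)
  if (length(responses) != nrow(design))
    stop(sprintf("need exactly %d responses (one per run), got %d",
                 nrow(design), length(responses)), call. = FALSE)
  check_number(responses, "responses")
  nf <- ncol(design)
  km <- matrix(NA_real_, nf, 3L,
               dimnames = list(colnames(design), paste0("level", 1:3)))
  for (j in seq_len(nf)) for (l in 1:3)
    km[j, l] <- mean(responses[design[, j] == l])
  rng <- apply(km, 1L, max) - apply(km, 1L, min)
  opt <- apply(km, 1L, if (direction == "benefit") which.max else which.min)
  structure(list(
    level_means = km,
    range = rng,
    factor_order = colnames(design)[order(-rng)],  # order() is stable on ties
    optimal_level = opt,
    direction = direction), class = "wf_range")
}

#' @export
print.wf_range <- function(x, ...) {
  cat("Range analysis (", x$direction, " response)\n", sep = "")
  print(round(cbind(x$level_means, R = x$range), 4))
  cat("Factor influence: ", paste(x$factor_order, collapse = " > "), "\n")
  cat("Optimal levels:   ",
      paste(names(x$optimal_level), x$optimal_level, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Water and fertilizer input reduction of one treatment versus a baseline
#'
#' Percent reduction `100 * (baseline - candidate) / baseline` of the seasonal
#' irrigation volume (per year) and of the total fertilizer rate, for two
#' treatments in a treatment table.
#'
#' @param candidate,baseline Treatment ids (e.g. `"T5"`, `"T7"`).
#' @param treatments Treatment table from [load_treatments()].
#' @return List with `water_pct` (named by year) and `fert_pct` (scalar).
#'   Positive values mean the candidate uses less input than the baseline.
#' @examples
#' input_reduction("T5", "T7")$water_pct  # 25% in both years
#' @export
input_reduction <- function(candidate, baseline, treatments = load_treatments()) {
  pick <- function(id) {
    rows <- treatments[treatments$id == id, , drop = FALSE]
    if (nrow(rows) == 0L) stop("unknown treatment id: ", id, call. = FALSE)
    rows
  }
  cand <- pick(candidate)
  base <- pick(baseline)
  years <- sort(intersect(cand$year, base$year))
  if (length(years) == 0L)
    stop("candidate and baseline share no years", call. = FALSE)
  water <- vapply(years, function(y) {
    b <- base$irrigation_m3_ha[base$year == y]
    a <- cand$irrigation_m3_ha[cand$year == y]
    if (b == 0) stop("zero baseline irrigation volume in ", y, call. = FALSE)
    100 * (b - a) / b
  }, numeric(1))
  names(water) <- years
  bf <- base$fert_total_kg_ha[1]
  if (bf == 0) stop("zero baseline fertilizer total", call. = FALSE)
  fert <- 100 * (bf - cand$fert_total_kg_ha[1]) / bf
  list(water_pct = water, fert_pct = fert)
}
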