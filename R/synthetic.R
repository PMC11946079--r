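# Synthetic orthogonal fertigation trials with known ground truth.

#' Default indicator panel of the synthetic generator
#'
#' Ten directly simulated indicators — fruit yield plus nine quality traits
#' (Hd hardness, VC vitamin C, SP soluble protein, LC lycopene, TA titratable
#' acidity, SS soluble sugars, NA nitrate, SSC soluble solids, MC moisture) —
#' with baseline magnitudes and additive factor effects chosen to mirror a
#' greenhouse tomato fertigation trial: irrigation amount is the dominant
#' factor for every indicator, severe deficit depresses yield and most
#' quality traits while raising hardness, acidity and nitrate. WUE and PFP
#' are not simulated; they are derived downstream from yield and the applied
#' inputs ([add_efficiency()]), so the efficiency identities hold exactly on
#' generated data.
#'
#' Each element is a list with `baseline` (indicator units), `unit`,
#' `direction` (`"benefit"`/`"cost"`), `category`, `cv` (noise coefficient of
#' variation), `year_offset` (additive offset per year) and `effects`
#' (4 factors x 3 levels additive matrix, indicator units).
#'
#' @param cv Noise coefficient of variation applied to every indicator
#'   (default 0.05, a typical plot-to-plot CV for managed greenhouse trials).
#' @return Named list of indicator specifications.
#' @export
default_indicator_panel <- function(cv = 0.05) {
  eff <- function(ia, f1, f2, f3, baseline) {
    m <- rbind(IA = ia, FI = f1, FII = f2, FIII = f3) * baseline
    colnames(m) <- paste0("level", 1:3)
    m
  }
  spec <- function(baseline, unit, direction, category, ia, f1, f2, f3) {
    list(baseline = baseline, unit = unit, direction = direction,
         category = category, cv = cv,
         year_offset = c(0.01, -0.01) * baseline,
         effects = eff(ia, f1, f2, f3, baseline))
  }
  list(
    yield = spec(60000, "kg/ha", "benefit", "yield",
                 ia = c(-0.20, -0.07, 0), f1 = c(0, -0.01, -0.04),
                 f2 = c(-0.08, -0.03, 0), f3 = c(-0.04, 0, -0.02)),
    Hd = spec(6.0, "N", "cost", "quality",
              ia = c(0.10, 0.03, 0), f1 = c(0.010, 0.005, 0),
              f2 = c(0, 0.008, 0.015), f3 = c(0.006, 0, 0.003)),
    VC = spec(25, "mg/100g", "benefit", "quality",
              ia = c(-0.30, -0.05, 0), f1 = c(-0.030, -0.015, 0),
              f2 = c(-0.04, 0, -0.02), f3 = c(-0.06, 0, -0.03)),
    SP = spec(2.0, "mg/g", "benefit", "quality",
              ia = c(-0.40, -0.05, 0), f1 = c(0, -0.02, -0.04),
              f2 = c(-0.06, -0.02, 0), f3 = c(-0.05, 0, -0.02)),
    LC = spec(8.0, "mg/100g", "benefit", "quality",
              ia = c(-0.35, 0, -0.08), f1 = c(-0.03, 0, -0.01),
              f2 = c(-0.05, -0.02, 0), f3 = c(-0.04, 0, -0.02)),
    TA = spec(0.45, "%", "cost", "quality",
              ia = c(0.35, 0.02, 0), f1 = c(0.02, 0.01, 0),
              f2 = c(0, 0.01, 0.02), f3 = c(0, 0.008, 0.015)),
    SS = spec(4.5, "%", "benefit", "quality",
              ia = c(-0.28, -0.10, 0), f1 = c(0, -0.03, -0.06),
              f2 = c(-0.08, -0.03, 0), f3 = c(-0.05, 0, -0.02)),
    "NA" = spec(120, "mg/kg", "cost", "quality",
                ia = c(0.70, 0.10, 0), f1 = c(0, 0.03, 0.06),
                f2 = c(0, 0.01, 0.02), f3 = c(0, 0.01, 0.02)),
    SSC = spec(5.5, "%", "benefit", "quality",
               ia = c(-0.12, 0, -0.045), f1 = c(0, -0.01, -0.02),
               f2 = c(-0.03, 0, -0.01), f3 = c(-0.03, 0, -0.015)),
    MC = spec(94.0, "%", "benefit", "quality",
              ia = c(-0.020, -0.008, 0), f1 = c(-0.004, -0.002, 0),
              f2 = c(0, -0.002, -0.003), f3 = c(-0.003, 0, -0.001))
  )
}

#' Configuration for a synthetic orthogonal fertigation trial
#'
#' Bundles the design, the treatment input table, the indicator panel and the
#' sampling parameters for [generate_trial()]. Defaults emulate the study
#' conditions: two years, nine treatments on the L9(3^4) array, three
#' replicate plots, twelve evaluation indicators (ten simulated + WUE/PFP
#' derived), multiplicative Gaussian plot noise with CV 0.05.
#'
#' @param seed Integer seed for the pseudo-random stream.
#' @param years Number of years (default 2; must be covered by `treatments`).
#' @param replicates Replicate plots per treatment and year (default 3).
#' @param cv Noise coefficient of variation applied to all indicators
#'   (overrides the panel's per-indicator values when not `NULL`).
#' @param indicators Indicator panel, see [default_indicator_panel()].
#' @param design Orthogonal design matrix, see [l9_design()].
#' @param treatments Treatment input table, see [load_treatments()].
#' @param start_year First trial year (default 2023).
#' @return Object of class `wf_trial_config`.
#' @export
trial_config <- function(seed = 1L, years = 2L, replicates = 3L, cv = NULL,
                         indicators = default_indicator_panel(),
                         design = l9_design(),
                         treatments = load_treatments(),
                         start_year = 2023L) {
  validate_design(design)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer", call. = FALSE)
  if (years < 1L) stop("years must be >= 1", call. = FALSE)
  if (replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  if (!is.null(cv)) {
    check_number(cv, "cv", nonneg = TRUE)
    indicators <- lapply(indicators, function(s) { s$cv <- cv; s })
  }
  for (nm in names(indicators)) {
    s <- indicators[[nm]]
    if (!is.numeric(s$baseline) || s$baseline <= 0)
      stop("baseline must be > 0 for indicator ", nm, call. = FALSE)
    if (s$cv < 0) stop("cv must be >= 0 for indicator ", nm, call. = FALSE)
    if (!is.matrix(s$effects) || !all(dim(s$effects) == c(4L, 3L)) ||
        any(!is.finite(s$effects)))
      stop("effects must be a finite 4 x 3 matrix for indicator ", nm,
           call. = FALSE)
    if (!s$direction %in% c("benefit", "cost"))
      stop("direction must be benefit/cost for indicator ", nm, call. = FALSE)
  }
  yrs <- start_year + seq_len(years) - 1L
  if (!all(yrs %in% treatments$year))
    stop("treatment table does not cover year(s): ",
         paste(setdiff(yrs, treatments$year), collapse = ", "), call. = FALSE)
  structure(list(seed = as.integer(seed), years = as.integer(years),
                 replicates = as.integer(replicates),
                 indicators = indicators, design = design,
                 treatments = treatments, start_year = as.integer(start_year),
                 dominant = NULL),
            class = "wf_trial_config")
}

#' Configured optimal level per factor for each indicator
#'
#' Ground truth of a configuration: for each simulated indicator, the level
#' of each factor that the additive effects make optimal (argmax of the
#' effect row for a benefit indicator, argmin for a cost indicator; ties go
#' to the lowest level).
#'
#' @param config A `wf_trial_config`.
#' @return Integer matrix, indicators x factors.
#' @export
configured_optima <- function(config) {
  stopifnot(inherits(config, "wf_trial_config"))
  t(vapply(config$indicators, function(s) {
    f <- if (s$direction == "benefit") which.max else which.min
    apply(s$effects, 1L, f)
  }, integer(4L)))
}

#' Generate a synthetic two-year orthogonal fertigation trial
#'
#' Simulates tidy plot records `value = (baseline + sum of factor effects +
#' year offset) * (1 + cv * e)`, `e ~ N(0, 1)`, for every year x treatment x
#' replicate x indicator cell, then derives WUE and PFP per record from the
#' generated yield and the treatment input table. Values driven non-positive
#' by noise are resampled so strictly positive indicators stay positive.
#' Equal seeds give identical datasets.
#'
#' @param config A `wf_trial_config` from [trial_config()].
#' @return Object of class `wf_trial`: list with `records` (tidy data frame
#'   `year, treatment, replicate, indicator, value`), `truth` (list with
#'   `optimal_levels` from [configured_optima()] and `dominant`), and
#'   `config`.
#' @examples
#' trial <- generate_trial(trial_config(seed = 42))
#' nrow(trial$records)  # 2 years x 9 treatments x 3 reps x 12 indicators
#' @export
generate_trial <- function(config) {
  stopifnot(inherits(config, "wf_trial_config"))
  set.seed(config$seed)
  yrs <- config$start_year + seq_len(config$years) - 1L
  trt <- rownames(config$design)
  out <- vector("list", length(config$indicators))
  for (i in seq_along(config$indicators)) {
    nm <- names(config$indicators)[i]
    s <- config$indicators[[i]]
    yo <- rep_len(s$year_offset, config$years)
    eff_sum <- vapply(seq_along(trt), function(t)
      sum(s$effects[cbind(1:4, config$design[t, ])]), numeric(1))
    rows <- vector("list", config$years * length(trt))
    k <- 0L
    for (y in seq_along(yrs)) for (t in seq_along(trt)) {
      mu <- s$baseline + eff_sum[t] + yo[y]
      v <- mu * (1 + s$cv * rnorm(config$replicates))
      while (any(v <= 0))
        v[v <= 0] <- mu * (1 + s$cv * rnorm(sum(v <= 0)))
      k <- k + 1L
      rows[[k]] <- data.frame(year = yrs[y], treatment = trt[t],
                              replicate = seq_len(config$replicates),
                              indicator = nm, value = v,
                              stringsAsFactors = FALSE)
    }
    out[[i]] <- do.call(rbind, rows)
  }
  records <- do.call(rbind, out)
  records <- add_efficiency(records, config$treatments)
  rownames(records) <- NULL
  structure(list(records = records,
                 truth = list(optimal_levels = configured_optima(config),
                              dominant = config$dominant),
                 config = config),
            class = "wf_trial")
}

#' @export
print.wf_trial <- function(x, ...) {
  cat("Synthetic fertigation trial:", x$config$years, "year(s) x",
      nrow(x$config$design), "treatments x", x$config$replicates,
      "replicates,", length(unique(x$records$indicator)), "indicators (",
      nrow(x$records), "records), seed", x$config$seed, "\n")
  invisible(x)
}

#' Aggregate replicate records into a treatment x indicator matrix
#'
#' Averages over replicates within each (year, treatment, indicator), then
#' over years — the two-year-average convention. Errors if any cell is
#' missing.
#'
#' @param trial A `wf_trial`, or a tidy records data frame.
#' @param meta Optional list giving `direction` and `category` per indicator;
#'   inferred from the trial config (plus WUE/PFP as benefit/efficiency) when
#'   `trial` is a `wf_trial`.
#' @return Object of class `wf_imatrix` (see [indicator_matrix()]) with a
#'   9 x m value matrix in design row order.
#' @export
aggregate_replicates <- function(trial, meta = NULL) {
  if (inherits(trial, "wf_trial")) {
    cfg <- trial$config
    records <- trial$records
    dir <- c(vapply(cfg$indicators, `[[`, "", "direction"),
             WUE = "benefit", PFP = "benefit")
    cat_ <- c(vapply(cfg$indicators, `[[`, "", "category"),
              WUE = "efficiency", PFP = "efficiency")
    meta <- list(direction = dir, category = cat_)
    trts <- rownames(cfg$design)
  } else {
    records <- trial
    trts <- sort(unique(records$treatment))
  }
  inds <- unique(records$indicator)
  # completeness: every (year, treatment, indicator) cell must be present
  cells <- unique(records[c("year", "treatment", "indicator")])
  full <- expand.grid(year = unique(records$year), treatment = trts,
                      indicator = inds, stringsAsFactors = FALSE)
  have <- paste(cells$year, cells$treatment, cells$indicator)
  want <- paste(full$year, full$treatment, full$indicator)
  if (!all(want %in% have)) {
    miss <- full[!(want %in% have), ][1, ]
    stop(sprintf("missing records for treatment %s, indicator %s (%s)",
                 miss$treatment, miss$indicator, miss$year), call. = FALSE)
  }
  per_year <- aggregate(value ~ year + treatment + indicator, records, mean)
  overall <- aggregate(value ~ treatment + indicator, per_year, mean)
  vals <- matrix(NA_real_, length(trts), length(inds),
                 dimnames = list(trts, inds))
  vals[cbind(overall$treatment, overall$indicator)] <- overall$value
  indicator_matrix(vals,
                   direction = if (is.null(meta)) rep("benefit", length(inds))
                               else unname(meta$direction[inds]),
                   category = if (is.null(meta)) rep("quality", length(inds))
                              else unname(meta$category[inds]))
}

#' Reconfigure a trial so one treatment dominates
#'
#' Rewrites the panel's factor effects so that the target treatment is
#' strictly best on every benefit-adjusted indicator: each factor
#' contributes `margin * baseline` in the favourable direction at the
#' target's level and nothing elsewhere. Because two rows of an L9 array
#' share at most one level, every rival loses at least three such margins on
#' every indicator. The yield effect of the target's irrigation level is
#' boosted much harder (`irrigation_yield_boost * baseline`) so that the
#' derived ratios WUE = Y/IA and PFP = Y/F also favour the target despite
#' its mid-range water and fertilizer inputs.
#'
#' @param config A `wf_trial_config` to rewrite.
#' @param target Treatment id to make dominant (default `"T5"`).
#' @param margin Per-factor effect margin as a fraction of baseline
#'   (default 0.2).
#' @param irrigation_yield_boost Extra yield effect of the target's
#'   irrigation level, as a fraction of baseline (default 1.0).
#' @return The modified `wf_trial_config`, with `dominant` set.
#' @export
make_dominant_scenario <- function(config, target = "T5", margin = 0.2,
                                   irrigation_yield_boost = 1.0) {
  stopifnot(inherits(config, "wf_trial_config"))
  if (!target %in% rownames(config$design))
    stop("unknown target treatment: ", target, call. = FALSE)
  lv <- config$design[target, ]
  for (nm in names(config$indicators)) {
    s <- config$indicators[[nm]]
    sgn <- if (s$direction == "benefit") 1 else -1
    e <- matrix(0, 4L, 3L, dimnames = dimnames(s$effects))
    e[cbind(1:4, lv)] <- sgn * margin * s$baseline
    if (nm == "yield") e[1L, lv[1L]] <- irrigation_yield_boost * s$baseline
    config$indicators[[nm]]$effects <- e
  }
  config$dominant <- target
  config
}

#' Write / read a trial scenario as YAML
#'
#' Serializes the sampling parameters and the indicator panel (baselines,
#' directions, categories, CVs, year offsets and effect matrices) so a
#' scenario can be stored and re-generated elsewhere. The design and
#' treatment table are not serialized; the packaged defaults are used on
#' read.
#'
#' @param config A `wf_trial_config`.
#' @param path YAML file path.
#' @return `write_scenario`: `path`, invisibly. `read_scenario`: a
#'   `wf_trial_config`.
#' @export
write_scenario <- function(config, path) {
  stopifnot(inherits(config, "wf_trial_config"))
  ind <- lapply(config$indicators, function(s)
    list(baseline = s$baseline, unit = s$unit, direction = s$direction,
         category = s$category, cv = s$cv,
         year_offset = as.numeric(s$year_offset),
         effects = lapply(seq_len(4), function(i) as.numeric(s$effects[i, ]))))
  yaml::write_yaml(list(seed = config$seed, years = config$years,
                        replicates = config$replicates,
                        start_year = config$start_year,
                        dominant = config$dominant,
                        indicators = ind), path, precision = 15)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  sc <- yaml::read_yaml(path)
  ind <- lapply(sc$indicators, function(s) {
    eff <- do.call(rbind, s$effects)
    dimnames(eff) <- list(design_factors(), paste0("level", 1:3))
    list(baseline = s$baseline, unit = s$unit, direction = s$direction,
         category = s$category, cv = s$cv, year_offset = s$year_offset,
         effects = eff)
  })
  names(ind) <- names(sc$indicators)
  cfg <- trial_config(seed = sc$seed, years = sc$years,
                      replicates = sc$replicates, indicators = ind,
                      start_year = sc$start_year)
  cfg$dominant <- sc$dominant
  cfg
}
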