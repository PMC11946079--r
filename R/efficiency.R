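# Water use efficiency and partial factor productivity.

#' Water use efficiency
#'
#' `WUE = Y / IA` in kg/m3: fruit yield per unit of irrigation water applied.
#'
#' @param Y Fruit yield, kg/ha (>= 0).
#' @param IA Seasonal irrigation amount, m3/ha (> 0).
#' @return WUE in kg/m3 (vectorized).
#' @examples
#' wue(90000, 2287.5)
#' @export
wue <- function(Y, IA) {
  check_number(Y, "Y", nonneg = TRUE)
  check_number(IA, "IA", positive = TRUE)
  Y / IA
}

#' Partial factor productivity of fertilizer
#'
#' `PFP = Y / F` in kg/kg: fruit yield obtained per kilogram of fertilizer
#' applied. `F` is the per-season total across the three stage applications.
#'
#' @param Y Fruit yield, kg/ha (>= 0).
#' @param F_ Total fertilizer rate, kg/ha (> 0).
#' @return PFP in kg/kg (vectorized).
#' @examples
#' pfp(90000, 2250)
#' @export
pfp <- function(Y, F_) {
  check_number(Y, "Y", nonneg = TRUE)
  check_number(F_, "F", positive = TRUE)
  Y / F_
}

#' Append water/fertilizer efficiency records to a tidy trial table
#'
#' For every (year, treatment, replicate) yield record, computes WUE from the
#' treatment's per-year irrigation volume and PFP from its total fertilizer
#' rate, and appends them as `WUE` and `PFP` indicator rows. Replicate-level
#' values are computed first; per-treatment means follow from the usual
#' aggregation ([aggregate_replicates()]).
#'
#' @param records Tidy data frame with columns
#'   `year, treatment, replicate, indicator, value` containing a `yield`
#'   indicator (kg/ha).
#' @param treatments Treatment table from [load_treatments()].
#' @return `records` with `WUE` and `PFP` rows appended.
#' @export
add_efficiency <- function(records, treatments = load_treatments()) {
  needed <- c("year", "treatment", "replicate", "indicator", "value")
  if (!all(needed %in% names(records)))
    stop("records must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  yl <- records[records$indicator == "yield", , drop = FALSE]
  if (nrow(yl) == 0L) stop("no 'yield' indicator in records", call. = FALSE)
  key <- paste(treatments$id, treatments$year)
  ia <- setNames(treatments$irrigation_m3_ha, key)
  ft <- setNames(treatments$fert_total_kg_ha, key)
  k <- paste(yl$treatment, yl$year)
  if (anyNA(ia[k]))
    stop("treatment table lacks rows for: ",
         paste(unique(k[is.na(ia[k])]), collapse = ", "), call. = FALSE)
  w <- yl; w$indicator <- "WUE"; w$value <- wue(yl$value, unname(ia[k]))
  p <- yl; p$indicator <- "PFP"; p$value <- pfp(yl$value, unname(ft[k]))
  rbind(records, w, p)
}
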