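test_that("L9 array is balanced, orthogonal and matches the treatment codes", {
  d <- l9_design()
  expect_silent(validate_design(d))
  for (j in 1:4) expect_equal(unname(tabulate(d[, j], 3)), c(3, 3, 3))
  for (a in 1:3) for (b in (a + 1):4)
    expect_setequal(paste(d[, a], d[, b]),
                    paste(rep(1:3, each = 3), rep(1:3, 3)))
  # T5 = mild deficit irrigation with stage rates 750 / 937.5 / 562.5
  lv <- design_levels()
  expect_identical(unname(d["T5", ]), c(2L, 2L, 3L, 1L))
  expect_equal(lv$irrigation_fraction[d["T5", "IA"]], 0.75)
  expect_equal(lv$fertilizer_kg_ha[d["T5", c("FI", "FII", "FIII")]],
               c(750, 937.5, 562.5))
  # T1 sits at level 1 everywhere
  expect_identical(unname(d["T1", ]), rep(1L, 4))
})

test_that("validate_design rejects unbalanced and non-orthogonal arrays", {
  d <- l9_design()
  d[1, 1] <- 2L
  expect_error(validate_design(d), "balanced")
  d2 <- l9_design()
  d2[, 2] <- d2[, 1]  # duplicated column: balanced but not orthogonal
  expect_error(validate_design(d2), "orthogonal")
})

test_that("packaged treatment table reproduces the applied amounts", {
  tr <- load_treatments()
  expect_equal(nrow(tr), 18)
  expect_equal(tr$irrigation_m3_ha[tr$id == "T7" & tr$year == 2023], 3050)
  expect_equal(tr$fert_total_kg_ha[tr$id == "T5"][1], 2250)
  expect_equal(tr$fert_total_kg_ha[tr$id == "T3"][1], 2812.5)
  # stage rates only ever take the three design levels
  expect_true(all(unlist(tr[c("fert1_kg_ha", "fert2_kg_ha", "fert3_kg_ha")])
                  %in% c(562.5, 750, 937.5)))
  # deficit fractions realized in the applied volumes, both years
  for (y in c(2023, 2024)) {
    v <- function(id) tr$irrigation_m3_ha[tr$id == id & tr$year == y]
    expect_equal(v("T5") / v("T7"), 0.75)
    expect_equal(v("T1") / v("T7"), 0.50)
  }
})

test_that("treatment loader flags malformed tables by row", {
  hdr <- "id,year,irrigation_m3_ha,fert1_kg_ha,fert2_kg_ha,fert3_kg_ha"
  expect_error(load_treatments(write_treatment_csv(hdr)), "empty")
  expect_error(
    load_treatments(write_treatment_csv(c(hdr, "T1,2023,abc,562.5,562.5,562.5"))),
    "non-numeric.*irrigation_m3_ha")
  expect_error(
    load_treatments(write_treatment_csv(
      c(hdr, "T1,2023,1525,562.5,562.5,562.5", "T1,2023,1525,562.5,562.5,562.5"))),
    "duplicate.*T1 2023")
  expect_error(
    load_treatments(write_treatment_csv(c(hdr, ",2023,1525,562.5,562.5,562.5"))),
    "missing treatment id")
  expect_error(load_treatments(write_treatment_csv("id,year\nT1,2023")),
               "missing columns")
})

test_that("irrigation requirement follows I = Ep x Kcp x A in litres", {
  expect_equal(irrigation_requirement(Ep = 100, A = 10, Kcp = 1.3), 1300)
  expect_equal(irrigation_requirement(Ep = 0, A = 5, Kcp = 0.6), 0)
  # stage defaults: 0.6 / 1.3 / 1.1
  expect_equal(irrigation_requirement(10, 1, stage = "seedling"), 6)
  expect_equal(irrigation_requirement(10, 1, stage = "flowering"), 13)
  expect_equal(irrigation_requirement(10, 1, stage = "peak_fruit"), 11)
  expect_error(irrigation_requirement(-1, 1, Kcp = 1), ">= 0")
  expect_error(irrigation_requirement(1, 0, Kcp = 1), "> 0")
})

test_that("range analysis isolates the factor that generated the response", {
  d <- l9_design()
  # response equal to factor 1's level index: only factor 1 has spread
  ra <- range_analysis(as.numeric(d[, 1]), d)
  expect_equal(unname(ra$level_means["IA", ]), c(1, 2, 3))
  expect_equal(unname(ra$range), c(2, 0, 0, 0))
  expect_equal(ra$factor_order[1], "IA")
  expect_equal(unname(ra$optimal_level[["IA"]]), 3)
  ra_cost <- range_analysis(as.numeric(d[, 1]), d, direction = "cost")
  expect_equal(unname(ra_cost$optimal_level[["IA"]]), 1)
  # constant response: all ranges 0, order stable in column order
  rc <- range_analysis(rep(5, 9), d)
  expect_equal(unname(rc$range), rep(0, 4))
  expect_equal(rc$factor_order, design_factors())
  expect_error(range_analysis(1:8, d), "exactly 9")
})

test_that("level means obey the balance identity and match the oracle", {
  d <- l9_design()
  set.seed(101)
  for (i in 1:25) {
    resp <- runif(9, 0, 100)
    ra <- range_analysis(resp, d)
    orc <- oracle_range(d, resp)
    expect_equal(unname(ra$level_means), orc$level_means)
    expect_equal(unname(ra$range), orc$range)
    expect_equal(unname(ra$optimal_level), orc$optimal)
    # mean of the three level means recovers the grand mean, every factor
    expect_equal(unname(rowMeans(ra$level_means)), rep(mean(resp), 4))
  }
})

test_that("input reductions reproduce the design arithmetic and scale-invariance", {
  red <- input_reduction("T5", "T7")
  expect_equal(unname(red$water_pct), c(25, 25))
  expect_equal(red$fert_pct, 0)  # both total 2250 kg/ha
  expect_equal(input_reduction("T5", "T3")$fert_pct, 20)
  same <- input_reduction("T7", "T7")
  expect_equal(unname(same$water_pct), c(0, 0))
  expect_equal(same$fert_pct, 0)
  # scaling all inputs leaves percentages unchanged
  tr <- load_treatments()
  tr2 <- tr
  for (cn in c("irrigation_m3_ha", "fert1_kg_ha", "fert2_kg_ha",
               "fert3_kg_ha", "fert_total_kg_ha"))
    tr2[[cn]] <- tr2[[cn]] * 3.7
  expect_equal(input_reduction("T5", "T7", tr2),
               input_reduction("T5", "T7", tr))
  # swap changes sign of the absolute difference but not magnitude per year
  fwd <- input_reduction("T1", "T7")
  bwd <- input_reduction("T7", "T1")
  expect_true(all(fwd$water_pct > 0) && all(bwd$water_pct < 0))
  expect_error(input_reduction("T5", "nope"), "unknown treatment")
})
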