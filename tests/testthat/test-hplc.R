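test_that("retention libraries enforce discriminable spacing", {
  lib <- default_retention_library()
  expect_equal(lib$entries$rt_min, c(8.2, 15.4, 22.9))
  expect_error(retention_library(data.frame(analyte = c("a", "b"),
                                            rt_min = c(1.0, 1.4))),
               "tolerance")
  expect_error(retention_library(data.frame(analyte = c("a", "a"),
                                            rt_min = c(1, 10))),
               "duplicate")
})

test_that("peaks annotate to the nearest in-tolerance analyte", {
  pk <- as_peak_table(data.frame(sample_id = "s1",
                                 rt_min = c(8.2, 15.4, 22.9, 30.0),
                                 area = c(10, 20, 900, 5),
                                 analyte = NA_character_))
  ann <- annotate_peaks(pk, default_retention_library())
  expect_equal(ann$analyte, c("AMP", "ADP", "ATP", NA))

  empty <- as_peak_table(data.frame(sample_id = character(),
                                    rt_min = numeric(), area = numeric(),
                                    analyte = character()))
  expect_equal(nrow(annotate_peaks(empty, default_retention_library())), 0L)
})

test_that("duplicate matches keep the nearest peak and warn", {
  pk <- as_peak_table(data.frame(sample_id = "s1",
                                 rt_min = c(22.9, 23.1),
                                 area = c(900, 50),
                                 analyte = NA_character_))
  expect_warning(ann <- annotate_peaks(pk, default_retention_library()),
                 "nearest")
  expect_equal(ann$analyte, c("ATP", NA))
})

test_that("consumed ATP follows the adenosine-pool area ratio", {
  mk <- function(areas) {
    as_peak_table(data.frame(sample_id = "s1",
                             rt_min = c(22.9, 15.4, 8.2)[seq_along(areas)],
                             area = areas,
                             analyte = c("ATP", "ADP", "AMP")[seq_along(areas)]))
  }
  expect_equal(unname(hplc_consumed_atp(mk(c(100, 0, 0)))), 0)
  expect_equal(unname(hplc_consumed_atp(mk(c(50, 25, 25)))), 50)
  expect_equal(unname(hplc_consumed_atp(mk(c(0, 100)))), 100)
  expect_error(hplc_consumed_atp(mk(c(0, 0, 0))), "zero total area")
})

test_that("product formation follows the substrate/product area ratio", {
  mk <- function(sub, prod) {
    as_peak_table(data.frame(sample_id = "s1", rt_min = c(27, 28),
                             area = c(sub, prod),
                             analyte = c("dCyd", "dCyd-MP")))
  }
  expect_equal(unname(hplc_product(mk(20, 80), "dCyd", "dCyd-MP")), 80)
  expect_equal(unname(hplc_product(mk(50, 0), "dCyd", "dCyd-MP")), 0)
  expect_equal(unname(hplc_product(mk(13.5, 86.5), "dCyd", "dCyd-MP")), 86.5)
  expect_error(hplc_product(mk(0, 0), "dCyd", "dCyd-MP"), "zero area")
})

test_that("area-ratio quantities are invariant under common rescaling", {
  set.seed(404)
  for (i in 1:25) {
    areas <- runif(5, 1, 100)
    mk <- function(s) as_peak_table(data.frame(
      sample_id = "s1", rt_min = c(22.9, 15.4, 8.2, 27, 28),
      area = areas * s,
      analyte = c("ATP", "ADP", "AMP", "Sub", "Sub-MP")))
    k <- runif(1, 0.01, 50)
    expect_equal(hplc_consumed_atp(mk(1)), hplc_consumed_atp(mk(k)),
                 tolerance = 1e-12)
    expect_equal(hplc_product(mk(1), "Sub", "Sub-MP"),
                 hplc_product(mk(k), "Sub", "Sub-MP"), tolerance = 1e-12)
  }
})

test_that("method comparison pairs groups and summarises deviations", {
  lum <- data.frame(enzyme = "E", substrate = c("S1", "S2", "S3"),
                    donor = "ATP", consumed_pct = c(50, 10, 20),
                    product_pct = c(60, 12, 24))
  hp <- data.frame(enzyme = "E", substrate = c("S1", "S2", "S4"),
                   donor = "ATP", consumed_hplc_pct = c(44, 10, 1),
                   product_hplc_pct = c(52.5, 12, 1))
  cmp <- compare_methods(lum, hp)
  expect_equal(nrow(cmp$pairs), 2L)
  expect_equal(cmp$pairs$abs_deviation,
               c(7.5, 0))
  expect_equal(unname(cmp$summary),
               c(0, 7.5, 3.75))
  expect_setequal(cmp$unpaired, c("E:S3:ATP", "E:S4:ATP"))

  ident <- compare_methods(lum, data.frame(
    enzyme = "E", substrate = c("S1", "S2", "S3"), donor = "ATP",
    consumed_hplc_pct = c(50, 10, 20), product_hplc_pct = c(60, 12, 24)))
  expect_equal(unname(ident$summary), c(0, 0, 0))

  expect_error(compare_methods(lum, hp[0, ]), "no shared")
})

test_that("method-comparison deviation is symmetric in its inputs", {
  lum <- data.frame(enzyme = "E", substrate = c("S1", "S2"), donor = "ATP",
                    consumed_pct = c(50, 10), product_pct = c(60, 12))
  hp <- data.frame(enzyme = "E", substrate = c("S1", "S2"), donor = "ATP",
                   consumed_hplc_pct = c(44, 11),
                   product_hplc_pct = c(52.5, 13))
  a <- compare_methods(lum, hp)
  b <- compare_methods(hp, lum)
  expect_equal(a$pairs$abs_deviation, b$pairs$abs_deviation)
})
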