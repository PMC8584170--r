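test_that("consumed donor evaluates the background-corrected formula", {
  expect_equal(consumed_donor(R = 60000, N = 60000), 0)
  expect_equal(consumed_donor(R = 0, N = 60000), 100)
  expect_equal(consumed_donor(R = 45000, N = 60000, S = 500, B = 1000),
               100 - 100 * 46500 / 60500)
  # R above N clamps at zero; the raw value is negative
  expect_equal(consumed_donor(R = 65000, N = 60000), 0)
  expect_lt(consumed_donor(R = 65000, N = 60000, clamp = FALSE), 0)
  expect_error(consumed_donor(R = 1, N = 0, S = 0), "N \\+ S")
})

test_that("product formation scales by the stoichiometric ratio and clamps", {
  expect_equal(product_formation(50), 60)
  expect_equal(product_formation(90), 100)   # 108 clamped
  expect_equal(product_formation(0), 0)
  expect_error(product_formation(10, ratio = 0), "positive")
})

test_that("stoichiometric ratio of the standard conditions rounds to 1.2", {
  expect_equal(stoichiometric_ratio(400, 333), 1.2)
  expect_equal(stoichiometric_ratio(0.4 * 1000, 0.33 * 1000), 1.2)
  expect_equal(stoichiometric_ratio(400, 333, sig_figs = Inf), 400 / 333)
})

test_that("consumed donor matches an independent arithmetic oracle", {
  # independently coded oracle: literal transcription of the formula
  oracle <- function(R, B, S, N) {
    v <- 100 - (100 * (R + B + S) / (N + S))
    min(100, max(0, v))
  }
  set.seed(101)
  for (i in 1:1000) {
    R <- runif(1, 0, 7e4); B <- runif(1, 0, 5e3)
    S <- runif(1, 0, 2e3); N <- runif(1, 1, 7e4)
    expect_equal(consumed_donor(R, N = N, S = S, B = B), oracle(R, B, S, N),
                 tolerance = 1e-12)
  }
})

test_that("consumed donor is strictly decreasing in R before clamping", {
  R <- seq(0, 7e4, length.out = 50)
  v <- consumed_donor(R, N = 6e4, S = 500, B = 100, clamp = FALSE)
  expect_true(all(diff(v) < 0))
  p <- product_formation(seq(0, 100, 5), clamp = FALSE)
  expect_true(all(diff(p) >= 0))
})

test_that("quantify_plate applies the control scheme per group", {
  lay <- read_plate_layout(write_tmp_csv(demo_layout_lines()), "p1")
  rdg <- read_reader_export(write_tmp_csv(demo_reading_lines()), "p1")
  ann <- join_layout(rdg, lay)
  res <- quantify_plate(ann)
  expect_equal(nrow(res), 1L)
  # hand computation: R=20200, N=46100, S=2.5, basal=45050, B=1050
  expect_equal(res$R_mean_rlu, 20200)
  expect_equal(res$N_rlu, 46100)
  expect_equal(res$B_rlu, 1050)
  consumed <- 100 - 100 * (20200 + 1050 + 2.5) / (46100 + 2.5)
  expect_equal(res$consumed_pct, consumed, tolerance = 1e-12)
  expect_equal(res$product_pct, min(100, consumed * 1.2), tolerance = 1e-12)
  expect_equal(res$n_replicates, 2L)
})

test_that("missing controls error or degrade as declared", {
  lay_lines <- demo_layout_lines()
  no_neg <- lay_lines[!grepl("negative_control", lay_lines)]
  rd <- demo_reading_lines()[!grepl("^E2|^F2", demo_reading_lines())]
  ann <- join_layout(read_reader_export(write_tmp_csv(rd), "p1"),
                     read_plate_layout(write_tmp_csv(no_neg), "p1"))
  expect_error(quantify_plate(ann), "negative control")

  no_basal <- lay_lines[!grepl("basal_control", lay_lines)]
  rd2 <- demo_reading_lines()[!grepl("^A3|^B3", demo_reading_lines())]
  ann2 <- join_layout(read_reader_export(write_tmp_csv(rd2), "p1"),
                      read_plate_layout(write_tmp_csv(no_basal), "p1"))
  expect_warning(res <- quantify_plate(ann2), "basal")
  expect_equal(res$B_rlu, 0)
})

test_that("low positive conversions are flagged, zero is not", {
  mk <- function(rlu_rx) {
    ann <- data.frame(
      plate_id = "p", well = c("A1", "A2", "B1", "B2", "C1", "C2"),
      role = c("reaction", "reaction", "negative_control",
               "negative_control", "substrate_control", "substrate_control"),
      enzyme = c("E", "E", NA, NA, "E", "E"),
      substrate = "S", donor = c("ATP", "ATP", "ATP", "ATP", NA, NA),
      donor_conc_uM = 400, replicate = c(1, 2, 1, 2, 1, 2),
      rlu = c(rlu_rx, rlu_rx, 60000, 60000, 0, 0),
      stringsAsFactors = FALSE)
    ann$substrate[3:4] <- "S"
    class(ann) <- c("annotated_plate", "data.frame")
    suppressWarnings(quantify_plate(ann))  # no basal control on purpose
  }
  low <- mk(56500)   # consumed ~5.8% -> product ~7%
  expect_true(low$product_pct > 0 && low$product_pct < 10)
  expect_true(low$flag_verify)
  zero <- mk(60000)  # R equals N: no conversion, not a "low positive"
  expect_equal(zero$product_pct, 0)
  expect_false(zero$flag_verify)
  high <- mk(20000)
  expect_false(high$flag_verify)
})

test_that("quantification is deterministic and idempotent on fixed input", {
  lay <- read_plate_layout(write_tmp_csv(demo_layout_lines()), "p1")
  rdg <- read_reader_export(write_tmp_csv(demo_reading_lines()), "p1")
  ann <- join_layout(rdg, lay)
  expect_identical(quantify_plate(ann), quantify_plate(ann))
})

test_that("spectrum matrix pivots, averages duplicates and carries flags", {
  res <- data.frame(
    plate_id = "p", enzyme = rep(c("E1", "E2"), each = 2),
    substrate = c("S1", "S2", "S1", "S1"), donor = "ATP",
    R_mean_rlu = 0, N_rlu = 1, S_rlu = 0, B_rlu = 0,
    consumed_pct = 0, product_pct = c(80, 7, 40, 44), sd_pct = 0,
    n_replicates = 3L, flag_verify = c(FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  class(res) <- c("nk_quant", "data.frame")
  expect_warning(m <- build_spectrum(res), "more than once")
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(m["E2", "S1"], 42)
  expect_equal(m["E1", "S1"], 80)
  expect_true(is.na(m["E2", "S2"]))
  expect_true(attr(m, "flags")["E1", "S2"])

  empty <- quantify_plate(data.frame(plate_id = character(),
                                     role = character(), rlu = numeric()))
  expect_equal(dim(build_spectrum(empty)), c(0L, 0L))
})
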