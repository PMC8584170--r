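test_that("default donor models reproduce the observed 500 uM signal ladder", {
  m <- default_donor_models()
  sig500 <- function(d) {
    m$slope[m$donor == d] * 500 + m$intercept[m$donor == d]
  }
  expect_equal(sig500("ATP"), 57892)
  expect_equal(sig500("dATP"), 1128)
  expect_equal(sig500("GTP"), 504)
  expect_equal(sig500("UTP"), 220)
  expect_equal(sig500("CTP"), 161)
  expect_true(all(vapply(c("dGTP", "dCTP", "TTP"), sig500, 0) < 30))
  # zero concentration gives the (zero) intercept
  expect_equal(m$slope * 0 + m$intercept, rep(0, nrow(m)))
})

test_that("closed-form mass balance: full conversion leaves 67 uM residual donor", {
  cfg <- noiseless_config()
  q <- expected_quantities(cfg, conversion = 1)
  expect_equal(q$c_res_uM, 400 - 333)
  expect_equal(q$conv_frac, 333 / 400)
})

test_that("no-activity plates reproduce the negative-control signal exactly", {
  cfg <- noiseless_config()
  sim <- simulate_plate(cfg, demo_screen())
  ann <- join_layout(sim$readings, sim$layout)
  rx <- ann[ann$role == "reaction", ]
  neg <- ann[ann$role == "negative_control", ]
  expect_equal(unique(rx$rlu), unique(neg$rlu))
  expect_equal(sim$truth$product_lum_pct, rep(0, 3))
})

test_that("simulation is bit-identical under a fixed seed", {
  cfg <- sim_config(seed = 7,
                    true_conversion = data.frame(enzyme = "HsdCK",
                                                 substrate = "dCyd",
                                                 conversion = 0.5))
  a <- simulate_plate(cfg, demo_screen())
  b <- simulate_plate(cfg, demo_screen())
  expect_identical(a, b)
  pa <- simulate_peak_table(cfg, a$truth)
  pb <- simulate_peak_table(cfg, b$truth)
  expect_identical(pa, pb)
})

test_that("over-capacity screens fail with the well demand", {
  cfg <- sim_config(seed = 1)
  big <- data.frame(enzyme = "E", substrate = paste0("S", 1:40),
                    donor = "ATP")
  expect_error(simulate_plate(cfg, big), "wells")
})

test_that("simulated standards cover the configured series per donor", {
  cfg <- noiseless_config()
  sim <- simulate_plate(cfg, demo_screen(1))
  std <- sim$layout[sim$layout$role == "standard", ]
  expect_setequal(unique(std$donor_conc_uM), c(0, 50, 100, 200, 300, 400, 500))
  expect_equal(nrow(std), 7 * cfg$n_standard_replicates)
})

test_that("simulated chromatograms conserve mass before noise", {
  tc <- data.frame(enzyme = "HsdCK", substrate = c("dCyd", "Thd"),
                   conversion = c(0.6, 0.25))
  cfg <- sim_config(seed = 3, noise_cv = 0, true_conversion = tc)
  sim <- simulate_plate(cfg, demo_screen(2))
  pk <- simulate_peak_table(cfg, sim$truth, area_scale = 1000)
  for (sid in unique(pk$peaks$sample_id)) {
    s <- pk$peaks[pk$peaks$sample_id == sid, ]
    aden <- s$area[s$analyte %in% c("ATP", "ADP", "AMP")]
    expect_equal(sum(aden), 1000)
    pool <- s$area[!s$analyte %in% c("ATP", "ADP", "AMP")]
    expect_equal(sum(pool), 1000)
  }
})

test_that("degradation routes ~1% of the adenosine pool to AMP", {
  cfg <- sim_config(seed = 2, noise_cv = 0, basal_consumption = 0,
                    atp_degradation = 0.01)
  sim <- simulate_plate(cfg, demo_screen(1))  # zero conversion
  pk <- simulate_peak_table(cfg, sim$truth)
  s <- pk$peaks[pk$peaks$sample_id == pk$samples$sample_id[1], ]
  aden <- s[s$analyte %in% c("ATP", "ADP", "AMP"), ]
  amp_frac <- aden$area[aden$analyte == "AMP"] / sum(aden$area)
  expect_equal(amp_frac, 0.01)
})

test_that("estimator consistency: noiseless plates quantify to the closed form", {
  tc <- data.frame(enzyme = "HsdCK",
                   substrate = c("dCyd", "Thd", "Urd"),
                   conversion = c(0.8, 0.3, 0))
  cfg <- sim_config(seed = 5, noise_cv = 0, true_conversion = tc)
  sim <- simulate_plate(cfg, demo_screen())
  ann <- join_layout(sim$readings, sim$layout)
  res <- quantify_plate(ann, ratio = cfg$donor_conc / cfg$substrate_conc)
  m <- match(paste(res$enzyme, res$substrate),
             paste(sim$truth$enzyme, sim$truth$substrate))
  expect_equal(res$consumed_pct, sim$truth$consumed_lum_pct[m],
               tolerance = 1e-9)
  expect_equal(res$product_pct, sim$truth$product_lum_pct[m],
               tolerance = 1e-9)

  pk <- simulate_peak_table(cfg, sim$truth)
  h <- quantify_hplc(pk$peaks, pk$samples)
  mh <- match(paste(h$enzyme, h$substrate),
              paste(sim$truth$enzyme, sim$truth$substrate))
  expect_equal(h$consumed_hplc_pct, sim$truth$consumed_hplc_pct[mh],
               tolerance = 1e-9)
  expect_equal(h$product_hplc_pct, sim$truth$product_hplc_pct[mh],
               tolerance = 1e-9)
})

test_that("multi-plate screens cover every group exactly once", {
  cfg <- sim_config(seed = 11)
  screen <- expand.grid(enzyme = c("E1", "E2"),
                        substrate = paste0("S", 1:10),
                        donor = "ATP", stringsAsFactors = FALSE)
  sim <- simulate_screen(cfg, screen)
  expect_gt(length(sim$plates), 1L)
  expect_equal(nrow(sim$truth), nrow(screen))
  key <- paste(sim$truth$enzyme, sim$truth$substrate)
  expect_equal(anyDuplicated(key), 0L)
})
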