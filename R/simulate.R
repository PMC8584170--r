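#' Default phosphate-donor luminescence response models
#'
#' Linear RLU = slope * concentration + intercept models for the eight
#' (deoxy)NTPs the Ultra-Glo luciferase was probed with. Slopes are chosen
#' so the noiseless 500 uM signal reproduces the observed ladder:
#' ATP 57 892 >> dATP 1128 > GTP 504 > UTP 220 > CTP 161 > dGTP/dCTP/TTP
#' (grouped below the 30 RLU acceptance floor, emitted at 20 RLU).
#' Intercepts are zero.
#'
#' @return data frame with columns `donor`, `slope` (RLU per uM),
#'   `intercept` (RLU).
#' @examples
#' m <- default_donor_models()
#' m$slope[m$donor == "ATP"] * 500   # 57892
#' @export
default_donor_models <- function() {
  ref <- c(ATP = 57892, dATP = 1128, GTP = 504, UTP = 220, CTP = 161,
           dGTP = 20, dCTP = 20, TTP = 20)
  data.frame(donor = names(ref), slope = unname(ref) / 500,
             intercept = 0, stringsAsFactors = FALSE)
}

#' Simulation configuration for synthetic screening plates
#'
#' Bundles the assay conditions the simulator emulates: the linear
#' donor-response models, per-pair true conversion fractions, plate-reader
#' noise, basal (substrate-independent) donor consumption by the enzyme,
#' non-enzymatic ATP degradation to AMP, and the reaction concentrations.
#' Defaults mirror the assay conditions: 400 uM donor, 333 uM nucleoside,
#' standards in duplicate, samples in triplicate, ~1% ATP degradation.
#'
#' @param seed integer RNG seed; all simulator randomness flows from it.
#' @param noise_cv coefficient of variation of the multiplicative
#'   plate-reader noise (default 0.03).
#' @param n_replicates reaction replicates per group (default 3).
#' @param n_standard_replicates replicates per standard level (default 2).
#' @param n_control_replicates replicates per control type per group
#'   (default 3, matching the triplicate luciferase measurement applied
#'   to every well).
#' @param donor_models data frame `donor`, `slope`, `intercept`
#'   (default [default_donor_models()]).
#' @param true_conversion data frame `enzyme`, `substrate`, `conversion`
#'   giving the true fraction of substrate phosphorylated; pairs absent
#'   from the table convert 0.
#' @param basal_consumption fraction of donor consumed by enzyme without
#'   substrate (default 0.02).
#' @param atp_degradation fraction of donor non-enzymatically degraded to
#'   AMP (default 0.01).
#' @param donor_conc donor concentration in reactions, uM (default 400).
#' @param substrate_conc substrate concentration, uM (default 333).
#' @param standard_levels standard-series concentrations, uM.
#' @param substrate_autolum RLU emitted by substrate controls on top of the
#'   model intercept (default 0; switch on to exercise the interference
#'   detector).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed,
                       noise_cv = 0.03,
                       n_replicates = 3L,
                       n_standard_replicates = 2L,
                       n_control_replicates = 3L,
                       donor_models = default_donor_models(),
                       true_conversion = NULL,
                       basal_consumption = 0.02,
                       atp_degradation = 0.01,
                       donor_conc = 400,
                       substrate_conc = 333,
                       standard_levels = c(0, 50, 100, 200, 300, 400, 500),
                       substrate_autolum = 0) {
  stopifnot(length(seed) == 1L, is.finite(seed),
            noise_cv >= 0,
            n_replicates >= 1L, n_standard_replicates >= 1L,
            n_control_replicates >= 1L,
            basal_consumption >= 0, basal_consumption <= 1,
            atp_degradation >= 0, atp_degradation <= 1,
            donor_conc > 0, substrate_conc > 0,
            substrate_autolum >= 0)
  stopifnot(all(c("donor", "slope", "intercept") %in% names(donor_models)),
            all(donor_models$slope >= 0), all(donor_models$intercept >= 0))
  if (!is.null(true_conversion)) {
    stopifnot(all(c("enzyme", "substrate", "conversion") %in%
                    names(true_conversion)),
              all(true_conversion$conversion >= 0),
              all(true_conversion$conversion <= 1))
  }
  structure(list(seed = as.integer(seed), noise_cv = noise_cv,
                 n_replicates = as.integer(n_replicates),
                 n_standard_replicates = as.integer(n_standard_replicates),
                 n_control_replicates = as.integer(n_control_replicates),
                 donor_models = donor_models,
                 true_conversion = true_conversion,
                 basal_consumption = basal_consumption,
                 atp_degradation = atp_degradation,
                 donor_conc = donor_conc, substrate_conc = substrate_conc,
                 standard_levels = sort(unique(standard_levels)),
                 substrate_autolum = substrate_autolum),
            class = "sim_config")
}

donor_model <- function(config, donor) {
  i <- match(donor, config$donor_models$donor)
  if (anyNA(i)) {
    stop("no donor-response model for: ",
         paste(unique(donor[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  config$donor_models[i, , drop = FALSE]
}

model_rlu <- function(config, donor, conc) {
  m <- donor_model(config, donor)
  m$slope * conc + m$intercept
}

lookup_conversion <- function(config, enzyme, substrate) {
  tc <- config$true_conversion
  if (is.null(tc)) return(rep(0, length(enzyme)))
  i <- match(paste(enzyme, substrate, sep = "\r"),
             paste(tc$enzyme, tc$substrate, sep = "\r"))
  ifelse(is.na(i), 0, tc$conversion[i])
}

# multiplicative reader noise, floored at zero RLU
with_noise <- function(rlu, cv) {
  if (cv == 0) return(rlu)
  pmax(0, rlu * (1 + stats::rnorm(length(rlu), 0, cv)))
}

# well addresses in column-major plate order: A1..H1, A2..H2, ...
plate_wells_column_major <- function() {
  paste0(rep(LETTERS[1:8], times = 12), rep(1:12, each = 8))
}

#' Closed-form expectations for a simulated reaction group
#'
#' Mass balance of the simulated kinase reaction. The fraction of donor
#' consumed by the kinase is `min(1, conversion * substrate_conc /
#' donor_conc)`; basal consumption and non-enzymatic degradation are added
#' on top and the residual donor concentration is floored at zero. The
#' luminescence estimator (background-corrected, Eq.-style) recovers
#' `100 * conv_frac / (1 - degradation)` percent consumed donor, while the
#' HPLC estimator on the adenosine pool recovers
#' `100 * (conv_frac + basal + degradation)`.
#'
#' @param config a `sim_config`.
#' @param conversion true substrate conversion fraction(s) in `[0,1]`.
#' @param ratio donor:substrate multiplier used for the expected
#'   luminescence product; defaults to the exact concentration ratio.
#' @return data frame of per-group expectations: `conv_frac` (fraction of
#'   donor consumed by the kinase), `c_res_uM` (residual donor),
#'   `consumed_lum_pct`, `product_lum_pct`, `consumed_hplc_pct`,
#'   `product_hplc_pct`.
#' @export
expected_quantities <- function(config, conversion,
                                ratio = config$donor_conc / config$substrate_conc) {
  conv_frac <- pmin(1, conversion * config$substrate_conc / config$donor_conc)
  lost <- conv_frac + config$basal_consumption + config$atp_degradation
  c_res <- pmax(0, config$donor_conc * (1 - lost))
  consumed_lum <- pmin(100, pmax(0, 100 * conv_frac /
                                   (1 - config$atp_degradation)))
  product_lum <- pmin(100, pmax(0, consumed_lum * ratio))
  consumed_hplc <- pmin(100, 100 * pmin(1, lost))
  product_hplc <- 100 * conversion
  data.frame(conv_frac = conv_frac, c_res_uM = c_res,
             consumed_lum_pct = consumed_lum, product_lum_pct = product_lum,
             consumed_hplc_pct = consumed_hplc,
             product_hplc_pct = product_hplc)
}

#' Simulate a 96-well screening plate
#'
#' Generates a plate layout, a matching luminescence reading and a
#' ground-truth table for a screen of (enzyme, substrate, donor) triples.
#' The plate carries, in column-major order: a duplicate standard series
#' for every donor used, then per reaction group its reaction replicates,
#' negative controls (no enzyme), substrate controls (no donor) and basal
#' controls (no substrate), adjacent to the group.
#'
#' Signals (before multiplicative noise): reactions emit the donor model at
#' the residual donor concentration from the closed-form mass balance;
#' negative controls at `donor_conc * (1 - atp_degradation)`; basal
#' controls at `donor_conc * (1 - basal_consumption - atp_degradation)`;
#' substrate controls emit intercept-level signal (plus any configured
#' autoluminescence). Output is deterministic under the config seed.
#'
#' @param config a [sim_config()].
#' @param screen data frame with columns `enzyme`, `substrate`, `donor`;
#'   one row per reaction group. May be empty (standards-only plate), in
#'   which case a standard series for `standards_for` is still emitted.
#' @param plate_id plate identifier.
#' @param standards_for donors to lay a standard series for; defaults to
#'   the donors in `screen`, or `"ATP"` for an empty screen.
#' @return list with elements `layout` (`plate_layout`), `readings`
#'   (`plate_reading`) and `truth` (data frame: group, true conversion and
#'   the closed-form expected quantities of [expected_quantities()]).
#' @export
simulate_plate <- function(config, screen, plate_id = "sim-plate",
                           standards_for = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (missing(screen) || is.null(screen)) {
    screen <- data.frame(enzyme = character(), substrate = character(),
                         donor = character(), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("enzyme", "substrate", "donor") %in% names(screen)))
  if (is.null(standards_for)) {
    standards_for <- if (nrow(screen)) unique(screen$donor) else "ATP"
  }
  donor_model(config, standards_for)  # validate models exist

  n_std <- length(standards_for) * length(config$standard_levels) *
    config$n_standard_replicates
  per_group <- config$n_replicates + 3L * config$n_control_replicates
  demand <- n_std + nrow(screen) * per_group
  if (demand > 96L) {
    stop("screen needs ", demand, " wells but a plate has 96 ",
         "(", n_std, " standards + ", nrow(screen), " groups x ",
         per_group, ")", call. = FALSE)
  }

  rows <- list()
  add <- function(role, enzyme, substrate, donor, donor_conc, replicate,
                  rlu_true) {
    rows[[length(rows) + 1L]] <<- data.frame(
      role = role, enzyme = enzyme, substrate = substrate, donor = donor,
      donor_conc_uM = donor_conc, replicate = replicate, rlu_true = rlu_true,
      stringsAsFactors = FALSE)
  }

  for (d in standards_for) {
    for (lev in config$standard_levels) {
      add("standard", NA, NA, d, lev,
          seq_len(config$n_standard_replicates),
          rep(model_rlu(config, d, lev), config$n_standard_replicates))
    }
  }

  truth <- NULL
  if (nrow(screen)) {
    conv <- lookup_conversion(config, screen$enzyme, screen$substrate)
    exp_q <- expected_quantities(config, conv)
    truth <- cbind(plate_id = plate_id, screen,
                   true_conversion = conv, exp_q,
                   stringsAsFactors = FALSE)
    nc <- config$n_control_replicates
    for (g in seq_len(nrow(screen))) {
      e <- screen$enzyme[g]; s <- screen$substrate[g]; d <- screen$donor[g]
      m <- donor_model(config, d)
      add("reaction", e, s, d, config$donor_conc,
          seq_len(config$n_replicates),
          rep(m$slope * exp_q$c_res_uM[g] + m$intercept, config$n_replicates))
      add("negative_control", NA, s, d, config$donor_conc, seq_len(nc),
          rep(model_rlu(config, d,
                        config$donor_conc * (1 - config$atp_degradation)), nc))
      add("substrate_control", e, s, NA, NA, seq_len(nc),
          rep(m$intercept + config$substrate_autolum, nc))
      add("basal_control", e, NA, d, config$donor_conc, seq_len(nc),
          rep(model_rlu(config, d, config$donor_conc *
                          (1 - config$basal_consumption -
                             config$atp_degradation)), nc))
    }
  }

  tab <- do.call(rbind, rows)
  tab$well <- plate_wells_column_major()[seq_len(nrow(tab))]
  layout <- as_plate_layout(tab[, c("well", "role", "enzyme", "substrate",
                                    "donor", "donor_conc_uM", "replicate")],
                            plate_id = plate_id)
  set.seed(config$seed)
  readings <- as_plate_reading(
    data.frame(well = tab$well,
               rlu = with_noise(tab$rlu_true, config$noise_cv),
               stringsAsFactors = FALSE),
    plate_id)
  list(layout = layout, readings = readings, truth = truth)
}

#' Simulate HPLC peak tables matched to a simulated plate
#'
#' For each reaction group in a ground-truth table, emits one chromatogram
#' sample: the adenosine pool (ATP at 22.9 min, ADP at 15.4 min, AMP at
#' 8.2 min) with areas proportional to molar fractions — kinase- and
#' basal-consumed donor routed to ADP (single phosphate transfer),
#' degradation to AMP — and a substrate/product pair with areas
#' proportional to unconverted substrate and formed NMP. The same
#' multiplicative noise CV as the plate reader is applied per peak.
#' Sample ids are `enzyme:substrate:donor`.
#'
#' @param config a [sim_config()].
#' @param truth ground-truth table from [simulate_plate()].
#' @param area_scale total area assigned to each pool before noise
#'   (arbitrary units; ratios are what matter).
#' @return list with `peaks` (a `peak_table`, analyte-labelled), `samples`
#'   (data frame mapping `sample_id` to enzyme/substrate/donor) and
#'   `library` (the retention-time library covering all emitted analytes).
#' @export
simulate_peak_table <- function(config, truth, area_scale = 1000) {
  stopifnot(inherits(config, "sim_config"), is.data.frame(truth))
  lib <- synthetic_retention_library(unique(truth$substrate))
  rt_of <- function(a) lib$entries$rt_min[match(a, lib$entries$analyte)]

  set.seed(config$seed + 1L)
  out <- vector("list", nrow(truth))
  for (g in seq_len(nrow(truth))) {
    sid <- paste(truth$enzyme[g], truth$substrate[g], truth$donor[g],
                 sep = ":")
    atp_frac <- pmax(0, 1 - truth$conv_frac[g] - config$basal_consumption -
                       config$atp_degradation)
    adp_frac <- truth$conv_frac[g] + config$basal_consumption
    amp_frac <- config$atp_degradation
    sub <- truth$substrate[g]
    nmp <- paste0(sub, "-MP")
    conv <- truth$true_conversion[g]
    df <- data.frame(
      sample_id = sid,
      rt_min = c(rt_of("ATP"), rt_of("ADP"), rt_of("AMP"),
                 rt_of(sub), rt_of(nmp)),
      area = with_noise(area_scale * c(atp_frac, adp_frac, amp_frac,
                                       1 - conv, conv), config$noise_cv),
      analyte = c("ATP", "ADP", "AMP", sub, nmp),
      stringsAsFactors = FALSE)
    out[[g]] <- df
  }
  samples <- data.frame(
    sample_id = paste(truth$enzyme, truth$substrate, truth$donor, sep = ":"),
    enzyme = truth$enzyme, substrate = truth$substrate, donor = truth$donor,
    stringsAsFactors = FALSE)
  list(peaks = as_peak_table(do.call(rbind, out)), samples = samples,
       library = lib)
}

#' Synthetic retention-time library for simulated chromatograms
#'
#' The adenosine nucleotides keep their observed retention times (AMP 8.2,
#' ADP 15.4, ATP 22.9 min); nucleoside substrates and their monophosphate
#' products (`<substrate>-MP`) get invented, well-separated times beyond
#' 25 min. Spacing is 1 min, comfortably beyond twice the default 0.3 min
#' matching tolerance.
#'
#' @param substrates character vector of substrate names.
#' @return a [retention_library()].
#' @export
synthetic_retention_library <- function(substrates = character()) {
  substrates <- sort(unique(substrates))
  entries <- data.frame(analyte = c("AMP", "ADP", "ATP"),
                        rt_min = c(8.2, 15.4, 22.9),
                        stringsAsFactors = FALSE)
  if (length(substrates)) {
    i <- seq_along(substrates)
    entries <- rbind(entries,
                     data.frame(analyte = substrates, rt_min = 25 + 2 * i,
                                stringsAsFactors = FALSE),
                     data.frame(analyte = paste0(substrates, "-MP"),
                                rt_min = 26 + 2 * i,
                                stringsAsFactors = FALSE))
  }
  retention_library(entries)
}

#' Simulate a multi-plate screen
#'
#' Splits a screen over as many plates as needed (each with its own
#' standard series and per-group controls) and concatenates the results.
#' Plate seeds are derived deterministically from the config seed.
#'
#' @param config a [sim_config()].
#' @param screen data frame `enzyme`, `substrate`, `donor`.
#' @param plate_prefix prefix for plate ids (`<prefix>-1`, ...).
#' @return list of per-plate `simulate_plate()` results, plus a combined
#'   `truth` table as attribute-free data frame element `truth`.
#' @export
simulate_screen <- function(config, screen, plate_prefix = "sim-plate") {
  stopifnot(inherits(config, "sim_config"), nrow(screen) >= 1L)
  per_group <- config$n_replicates + 3L * config$n_control_replicates
  # standards are per plate, for the donors present on that plate; assume
  # the worst case (all screen donors) when sizing
  n_std <- length(unique(screen$donor)) * length(config$standard_levels) *
    config$n_standard_replicates
  cap <- max(1L, (96L - n_std) %/% per_group)
  if (96L - n_std < per_group) {
    stop("standard series leaves no room for reaction groups", call. = FALSE)
  }
  idx <- split(seq_len(nrow(screen)), ceiling(seq_len(nrow(screen)) / cap))
  plates <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    cfg_k <- config
    cfg_k$seed <- config$seed + k - 1L
    plates[[k]] <- simulate_plate(cfg_k, screen[idx[[k]], , drop = FALSE],
                                  plate_id = paste0(plate_prefix, "-", k))
  }
  truth <- do.call(rbind, lapply(plates, `[[`, "truth"))
  rownames(truth) <- NULL
  list(plates = plates, truth = truth)
}
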