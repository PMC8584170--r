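#' Run the whole screening pipeline end-to-end
#'
#' Calibrate -> QC -> quantify -> (optional) HPLC -> method comparison ->
#' spectrum matrix, reading plate files from disk and writing all result
#' tables plus a plain-text summary report. Output CSVs are written with a
#' fixed column order and no row names, so two runs on identical inputs
#' produce byte-identical files.
#'
#' @param layout path(s) to plate-layout CSV(s).
#' @param readings path(s) to reader-export CSV(s), parallel to `layout`.
#' @param out_dir output directory (created if missing).
#' @param peaks optional path to an HPLC peak-table CSV.
#' @param samples optional path to a sample-map CSV (`sample_id`,
#'   `enzyme`, `substrate`, `donor`) for the peak table; required when
#'   `peaks` is given and the table lacks analyte labels tied to groups.
#' @param rt_library optional `retention_library`; defaults to the
#'   adenosine-nucleotide library. Peaks already carrying analyte labels
#'   are used as-is.
#' @param ratio donor:substrate molar ratio (default 1.2).
#' @param verify_threshold low-conversion verification threshold in
#'   percent (default 10).
#' @param z_prime_min minimum acceptable per-plate Z' (default 0.5, the
#'   usual screening-window convention).
#' @return (invisibly) a `screen_report` list: `curves`, `qc`, `results`,
#'   `spectrum`, `hplc`, `comparison`, `pass` (logical: all plates meet
#'   the Z' minimum), `out_dir`.
#' @export
run_screen <- function(layout, readings, out_dir,
                       peaks = NULL, samples = NULL, rt_library = NULL,
                       ratio = 1.2, verify_threshold = 10,
                       z_prime_min = 0.5) {
  for (p in c(layout, readings, peaks, samples)) {
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  }
  stopifnot(length(layout) == length(readings))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  annotated <- do.call(rbind, lapply(seq_along(layout), function(i) {
    lay <- read_plate_layout(layout[i])
    rdg <- read_reader_export(readings[i],
                              plate_id = attr(lay, "plate_id"))
    join_layout(rdg, lay)
  }))
  class(annotated) <- c("annotated_plate", "data.frame")

  curves <- calibrate_plate(annotated)
  curve_df <- do.call(rbind, lapply(curves, function(cv) {
    data.frame(donor = cv$donor, slope = cv$slope, intercept = cv$intercept,
               r_squared = cv$r_squared, range_min = cv$range[["min"]],
               range_max = cv$range[["max"]], n_points = cv$n_points,
               stringsAsFactors = FALSE)
  }))
  rownames(curve_df) <- NULL
  utils::write.csv(curve_df, file.path(out_dir, "curves.csv"),
                   row.names = FALSE)

  qc <- plate_qc(annotated)
  utils::write.csv(qc, file.path(out_dir, "qc.csv"), row.names = FALSE)

  results <- quantify_plate(annotated, ratio = ratio,
                            verify_threshold = verify_threshold)
  utils::write.csv(as.data.frame(results),
                   file.path(out_dir, "results.csv"), row.names = FALSE)

  spectrum <- build_spectrum(results)
  spec_df <- data.frame(enzyme = rownames(spectrum),
                        unclass(spectrum)[, , drop = FALSE],
                        check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(spec_df, file.path(out_dir, "spectrum.csv"),
                   row.names = FALSE)

  hplc <- comparison <- NULL
  if (!is.null(peaks)) {
    if (is.null(samples)) {
      stop("HPLC peaks given without a sample map", call. = FALSE)
    }
    tab <- read_peak_table(peaks)
    if (anyNA(tab$analyte)) {
      if (is.null(rt_library)) rt_library <- default_retention_library()
      tab <- annotate_peaks(tab, rt_library)
    }
    smp <- utils::read.csv(samples, stringsAsFactors = FALSE)
    hplc <- quantify_hplc(tab, smp)
    utils::write.csv(hplc, file.path(out_dir, "hplc_results.csv"),
                     row.names = FALSE)
    comparison <- compare_methods(results, hplc)
    utils::write.csv(comparison$pairs,
                     file.path(out_dir, "comparison.csv"),
                     row.names = FALSE)
  }

  pass <- all(qc$z_prime >= z_prime_min)
  report <- file.path(out_dir, "summary.txt")
  lines <- c(
    "nucleoside kinase screening summary",
    "",
    sprintf("plates: %d; reaction groups: %d", nrow(qc), nrow(results)),
    sprintf("Z' per plate (minimum %.2f): %s", z_prime_min,
            paste(sprintf("%s=%.3f", qc$plate_id, qc$z_prime),
                  collapse = ", ")),
    sprintf("plate QC %s", if (pass) "PASS" else "FAIL"),
    sprintf("standard curves: %s",
            paste(sprintf("%s r2=%.4f", curve_df$donor,
                          curve_df$r_squared), collapse = ", ")),
    sprintf("groups flagged for verification (<%g%% product): %d",
            verify_threshold, sum(results$flag_verify)))
  if (sum(results$flag_verify)) {
    f <- results[results$flag_verify, ]
    lines <- c(lines, paste0("  ", f$enzyme, " x ", f$substrate, " x ",
                             f$donor, ": ", sprintf("%.1f%%", f$product_pct)))
  }
  if (!is.null(comparison)) {
    lines <- c(lines,
               sprintf("luminescence vs HPLC |deviation| [pp]: min %.2f, mean %.2f, max %.2f",
                       comparison$summary[["min"]],
                       comparison$summary[["mean"]],
                       comparison$summary[["max"]]))
  }
  writeLines(lines, report)

  invisible(structure(list(curves = curves, qc = qc, results = results,
                           spectrum = spectrum, hplc = hplc,
                           comparison = comparison, pass = pass,
                           out_dir = out_dir),
                      class = "screen_report"))
}

#' @export
print.screen_report <- function(x, ...) {
  cat("Screening run in '", x$out_dir, "': ",
      nrow(x$results), " groups on ", nrow(x$qc), " plate(s); QC ",
      if (x$pass) "PASS" else "FAIL", "\n", sep = "")
  invisible(x)
}

#' Write a simulated screen to disk as pipeline input files
#'
#' Convenience bridge from the simulator to [run_screen()]: writes
#' `layout-<k>.csv` / `readings-<k>.csv` per plate, plus `peaks.csv`,
#' `samples.csv` and `truth.csv`.
#'
#' @param config a [sim_config()].
#' @param screen data frame `enzyme`, `substrate`, `donor`.
#' @param dir output directory.
#' @return list of file paths (`layout`, `readings`, `peaks`, `samples`,
#'   `truth`) plus the combined `truth` table.
#' @export
write_simulated_screen <- function(config, screen, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sim <- simulate_screen(config, screen)
  lay_paths <- rdg_paths <- character(length(sim$plates))
  for (k in seq_along(sim$plates)) {
    lay_paths[k] <- file.path(dir, sprintf("layout-%d.csv", k))
    rdg_paths[k] <- file.path(dir, sprintf("readings-%d.csv", k))
    write_plate_layout(sim$plates[[k]]$layout, lay_paths[k])
    utils::write.csv(as.data.frame(sim$plates[[k]]$readings),
                     rdg_paths[k], row.names = FALSE)
  }
  pk <- simulate_peak_table(config, sim$truth)
  peaks_path <- file.path(dir, "peaks.csv")
  samples_path <- file.path(dir, "samples.csv")
  truth_path <- file.path(dir, "truth.csv")
  utils::write.csv(as.data.frame(pk$peaks), peaks_path, row.names = FALSE)
  utils::write.csv(pk$samples, samples_path, row.names = FALSE)
  utils::write.csv(sim$truth, truth_path, row.names = FALSE)
  list(layout = lay_paths, readings = rdg_paths, peaks = peaks_path,
       samples = samples_path, truth_path = truth_path, truth = sim$truth)
}
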