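#' Z'-factor plate-quality statistic
#'
#' `Z' = 1 - (3 * SD_negative + 3 * SD_substrate) /
#' (Average_negative - Average_substrate)`, computed from the plate's
#' negative controls (full donor signal) and substrate controls (signal
#' floor, no donor). Standard deviations are sample SDs (n - 1). A value
#' of 1 is a perfect assay window; values near or below 0 mark an
#' unusable plate.
#'
#' @param negatives RLU values of the negative controls (>= 2).
#' @param substrates RLU values of the substrate controls (>= 2).
#' @param plate_id plate identifier carried into the result.
#' @return a `plate_qc` list: `plate_id`, `avg_negative`, `sd_negative`,
#'   `avg_substrate`, `sd_substrate`, `z_prime`.
#' @examples
#' z_prime(c(59000, 60000, 61000), c(9500, 10000, 10500))
#' @export
z_prime <- function(negatives, substrates, plate_id = "plate") {
  if (length(negatives) < 2L || length(substrates) < 2L) {
    stop("need >= 2 values in each control group", call. = FALSE)
  }
  avg_n <- mean(negatives); avg_s <- mean(substrates)
  if (avg_n == avg_s) {
    stop("negative and substrate control means coincide; ",
         "Z' separation undefined", call. = FALSE)
  }
  sd_n <- stats::sd(negatives); sd_s <- stats::sd(substrates)
  structure(list(plate_id = plate_id,
                 avg_negative = avg_n, sd_negative = sd_n,
                 avg_substrate = avg_s, sd_substrate = sd_s,
                 z_prime = 1 - (3 * sd_n + 3 * sd_s) / (avg_n - avg_s)),
            class = "plate_qc")
}

#' @export
print.plate_qc <- function(x, ...) {
  cat("Plate '", x$plate_id, "': Z' = ", format(x$z_prime, digits = 4),
      "\n  negative controls:  mean ", format(x$avg_negative, digits = 6),
      " RLU, sd ", format(x$sd_negative, digits = 4),
      "\n  substrate controls: mean ", format(x$avg_substrate, digits = 6),
      " RLU, sd ", format(x$sd_substrate, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Per-plate Z' from annotated wells
#'
#' Pools each plate's negative-control and substrate-control wells and
#' computes [z_prime()] per plate.
#'
#' @param annotated an `annotated_plate` (possibly several plates
#'   row-bound).
#' @return data frame, one row per plate: `plate_id`, `avg_negative`,
#'   `sd_negative`, `avg_substrate`, `sd_substrate`, `z_prime`.
#' @export
plate_qc <- function(annotated) {
  stopifnot(is.data.frame(annotated))
  out <- lapply(split(annotated, annotated$plate_id), function(p) {
    q <- z_prime(p$rlu[p$role == "negative_control"],
                 p$rlu[p$role == "substrate_control"],
                 plate_id = p$plate_id[1L])
    as.data.frame(unclass(q), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Autoluminescence / luciferase-inhibition interference check
#'
#' Compares the luminescence of donor plus candidate compound against the
#' donor alone. A compound interferes when the relative shift of the mean
#' exceeds `shift_threshold`, or when a Welch two-sample comparison
#' rejects equality at `alpha` *and* the shift still exceeds 5% (both
#' branches guard against flagging trivially small but statistically
#' detectable shifts).
#'
#' @param with_compound RLU replicates of donor + compound (>= 2).
#' @param without RLU replicates of donor alone (>= 2).
#' @param compound compound name.
#' @param shift_threshold relative-shift threshold (default 0.10).
#' @param alpha significance level of the Welch branch (default 0.05).
#' @return data frame: `compound`, `mean_with`, `mean_without`,
#'   `relative_shift`, `p_value`, `interferes`.
#' @export
interference_check <- function(with_compound, without, compound = "compound",
                               shift_threshold = 0.10, alpha = 0.05) {
  if (length(with_compound) < 2L || length(without) < 2L) {
    stop("need >= 2 replicates in each group", call. = FALSE)
  }
  m_w <- mean(with_compound); m_o <- mean(without)
  if (m_o <= 0) stop("reference mean must be positive", call. = FALSE)
  shift <- (m_w - m_o) / m_o
  p <- if (stats::sd(with_compound) == 0 && stats::sd(without) == 0) {
    if (m_w == m_o) 1 else 0
  } else {
    stats::t.test(with_compound, without)$p.value
  }
  data.frame(compound = compound, mean_with = m_w, mean_without = m_o,
             relative_shift = shift, p_value = p,
             interferes = abs(shift) > shift_threshold ||
               (p < alpha && abs(shift) > 0.05),
             stringsAsFactors = FALSE)
}

#' AMP interference titration check
#'
#' Checks mixed ATP/AMP standards (e.g. 0.4 mM ATP, 0.3/0.1, 0.2/0.2,
#' 0.1/0.3, 0 ATP/0.4 AMP) against the signal an ATP standard curve
#' predicts for each level's ATP content. Levels whose mean RLU deviates
#' from the prediction by more than the shift threshold are flagged as
#' AMP-affected. If no curve is supplied, it is fitted from the AMP-free
#' levels of the series (>= 3 distinct ATP concentrations required).
#'
#' @param series data frame with columns `amp_uM`, `atp_uM`, `rlu`
#'   (replicate rows per level).
#' @param curve optional `standard_curve` for ATP.
#' @param shift_threshold relative deviation threshold (default 0.10).
#' @return data frame, one row per (atp_uM, amp_uM) level: means,
#'   `predicted_rlu`, `relative_shift`, `flagged`.
#' @export
amp_titration_check <- function(series, curve = NULL,
                                shift_threshold = 0.10) {
  stopifnot(is.data.frame(series))
  if (!nrow(series)) stop("empty titration series", call. = FALSE)
  stopifnot(all(c("amp_uM", "atp_uM", "rlu") %in% names(series)))
  if (is.null(curve)) {
    free <- series[series$amp_uM == 0, , drop = FALSE]
    if (length(unique(free$atp_uM)) < 3L) {
      stop("no reference curve and not enough AMP-free levels to fit one",
           call. = FALSE)
    }
    curve <- fit_standard_curve(free$atp_uM, free$rlu, donor = "ATP")
  }
  key <- paste(series$atp_uM, series$amp_uM, sep = "\r")
  lv <- !duplicated(key)
  out <- data.frame(atp_uM = series$atp_uM[lv], amp_uM = series$amp_uM[lv])
  out$mean_rlu <- as.numeric(tapply(series$rlu, key, mean)[key[lv]])
  out$predicted_rlu <- predict(curve, newconc = out$atp_uM)
  out$relative_shift <- ifelse(out$predicted_rlu > 0,
                               (out$mean_rlu - out$predicted_rlu) /
                                 out$predicted_rlu, NA_real_)
  out$flagged <- !is.na(out$relative_shift) &
    abs(out$relative_shift) > shift_threshold
  rownames(out) <- NULL
  out
}
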