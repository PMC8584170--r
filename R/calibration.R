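#' Fit a linear standard curve for a phosphate donor
#'
#' Ordinary least-squares fit of RLU against donor concentration over all
#' replicate points (not replicate means), with a freely estimated
#' intercept. The coefficient of determination is computed on the same
#' points, so it reflects replicate scatter as well as lack of fit.
#'
#' @param conc concentrations in uM, one per measured point (replicates
#'   repeat their concentration).
#' @param rlu luminescence signals (RLU), same length as `conc`.
#' @param donor donor name the curve belongs to.
#' @return a `standard_curve` object: components `donor`, `slope` (RLU per
#'   uM), `intercept` (RLU), `r_squared`, `range` (min/max calibrated uM),
#'   `n_points`, and the underlying `lm` fit.
#' @seealso [invert_curve()], [rank_donor_acceptance()]
#' @examples
#' sc <- fit_standard_curve(c(0, 100, 200, 500), c(0, 1000, 2000, 5000), "ATP")
#' coef(sc)
#' predict(sc, newconc = 250)
#' @export
fit_standard_curve <- function(conc, rlu, donor = "ATP") {
  conc <- as.numeric(conc); rlu <- as.numeric(rlu)
  stopifnot(length(conc) == length(rlu))
  if (anyNA(conc) || anyNA(rlu)) stop("NA in standard points", call. = FALSE)
  if (length(unique(conc)) < 3L) {
    stop("need >= 3 distinct concentrations to fit a standard curve",
         call. = FALSE)
  }
  if (stats::var(conc) == 0) {
    stop("zero concentration variance", call. = FALSE)
  }
  fit <- stats::lm(rlu ~ conc, data = data.frame(conc = conc, rlu = rlu))
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((rlu - mean(rlu))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  structure(list(donor = donor,
                 slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2,
                 range = c(min = min(conc), max = max(conc)),
                 n_points = length(conc),
                 fit = fit),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, digits = 4, ...) {
  cat("Standard curve for ", x$donor, "\n", sep = "")
  cat("  RLU = ", format(x$slope, digits = digits), " * conc[uM] + ",
      format(x$intercept, digits = digits), "\n", sep = "")
  cat("  r-squared = ", format(x$r_squared, digits = digits),
      "  (n = ", x$n_points, ", range ", x$range[["min"]], "-",
      x$range[["max"]], " uM)\n", sep = "")
  invisible(x)
}

#' @export
coef.standard_curve <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
residuals.standard_curve <- function(object, ...) {
  stats::residuals(object$fit)
}

#' @export
summary.standard_curve <- function(object, ...) {
  s <- summary(object$fit)
  out <- list(curve = object, lm_summary = s)
  class(out) <- "summary.standard_curve"
  out
}

#' @export
print.summary.standard_curve <- function(x, ...) {
  print(x$curve)
  cat("\nUnderlying least-squares fit:\n")
  print(stats::coef(x$lm_summary))
  invisible(x)
}

#' Predict RLU from concentration on a standard curve
#'
#' @param object a `standard_curve`.
#' @param newconc concentrations in uM.
#' @param ... unused.
#' @return predicted RLU values.
#' @export
predict.standard_curve <- function(object, newconc, ...) {
  if (missing(newconc)) return(stats::fitted(object$fit))
  object$slope * as.numeric(newconc) + object$intercept
}

#' @export
plot.standard_curve <- function(x, ...) {
  d <- x$fit$model
  graphics::plot(d$conc, d$rlu, xlab = "concentration [uM]",
                 ylab = "signal [RLU]",
                 main = paste0(x$donor, " standard curve (r2 = ",
                               format(x$r_squared, digits = 4), ")"), ...)
  graphics::abline(x$intercept, x$slope, col = "steelblue")
  invisible(x)
}

#' Invert a standard curve: RLU to concentration
#'
#' Returns `(rlu - intercept) / slope`, clipped to `[0, range_max]` of the
#' calibrated range; clipped values are flagged as extrapolated.
#'
#' @param curve a `standard_curve` with positive slope.
#' @param rlu luminescence values to invert.
#' @return data frame with `conc_uM` and logical `extrapolated`.
#' @export
invert_curve <- function(curve, rlu) {
  stopifnot(inherits(curve, "standard_curve"))
  if (curve$slope <= 0) stop("cannot invert a non-positive slope",
                             call. = FALSE)
  raw <- (as.numeric(rlu) - curve$intercept) / curve$slope
  hi <- curve$range[["max"]]
  conc <- pmin(hi, pmax(0, raw))
  data.frame(conc_uM = conc, extrapolated = raw < 0 | raw > hi)
}

#' Rank phosphate-donor acceptance by the luciferase
#'
#' Orders donors by their signal at the reference concentration and
#' expresses each as a fraction of the ATP signal. Donors whose signal
#' exceeds the acceptance floor are marked accepted; signals at or below
#' the floor group as non-substrates. Ties sort alphabetically.
#'
#' @param signals named numeric vector of RLU at the reference
#'   concentration (typically 500 uM), names are donors; must include the
#'   reference.
#' @param reference reference donor (default `"ATP"`).
#' @param floor acceptance floor in RLU (default 30, mirroring the
#'   grouping of dGTP/dCTP/TTP below 30 RLU as non-substrates).
#' @return data frame sorted by descending signal: `donor`,
#'   `signal_at_ref`, `relative_signal`, `accepted`.
#' @export
rank_donor_acceptance <- function(signals, reference = "ATP", floor = 30) {
  stopifnot(is.numeric(signals), !is.null(names(signals)))
  if (!reference %in% names(signals)) {
    stop("reference donor '", reference, "' missing from signals",
         call. = FALSE)
  }
  if (any(signals < 0)) stop("negative signal", call. = FALSE)
  ord <- order(-signals, names(signals))
  out <- data.frame(donor = names(signals)[ord],
                    signal_at_ref = unname(signals[ord]),
                    relative_signal = unname(signals[ord]) /
                      unname(signals[[reference]]),
                    accepted = unname(signals[ord]) > floor,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Fit standard curves for every donor on a plate
#'
#' Pulls the `standard` wells out of an annotated plate and fits one
#' [fit_standard_curve()] per donor.
#'
#' @param annotated an `annotated_plate` from [join_layout()].
#' @return named list of `standard_curve` objects, one per donor.
#' @export
calibrate_plate <- function(annotated) {
  std <- annotated[annotated$role == "standard", , drop = FALSE]
  if (!nrow(std)) stop("plate carries no standard wells", call. = FALSE)
  donors <- unique(std$donor)
  out <- lapply(donors, function(d) {
    s <- std[std$donor == d, , drop = FALSE]
    fit_standard_curve(s$donor_conc_uM, s$rlu, donor = d)
  })
  names(out) <- donors
  out
}
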