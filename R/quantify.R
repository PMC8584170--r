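clamp_pct <- function(x) pmin(100, pmax(0, x))

#' Consumed phosphate donor from luminescence
#'
#' Background-corrected percent of the phosphate donor consumed in the
#' kinase reaction:
#' `100 - 100 * (R + B + S) / (N + S)`, where `R` is the mean reaction
#' signal, `N` the mean negative control (no enzyme), `S` the substrate
#' control (no donor) and `B = max(0, N - basal)` the basal-activity
#' correction (enzyme without substrate). The result is clamped to
#' 0--100%.
#'
#' @param R reaction signal, RLU (scalar or vector).
#' @param N mean negative-control signal, RLU.
#' @param S mean substrate-control signal, RLU (default 0).
#' @param B basal-activity correction, RLU (default 0).
#' @param clamp clamp to `[0, 100]` (default `TRUE`).
#' @return consumed donor in percent.
#' @examples
#' consumed_donor(R = 45000, N = 60000, S = 500, B = 1000)  # 23.14 %
#' @export
consumed_donor <- function(R, N, S = 0, B = 0, clamp = TRUE) {
  if (any(N + S <= 0)) {
    stop("uninterpretable plate: N + S must be positive", call. = FALSE)
  }
  raw <- 100 - 100 * (R + B + S) / (N + S)
  if (clamp) clamp_pct(raw) else raw
}

#' Product formation from consumed donor
#'
#' Converts percent consumed donor into percent nucleoside monophosphate
#' formed by multiplying with the donor:substrate molar ratio (1.2 for the
#' standard 0.4 mM donor / 0.33 mM substrate conditions), clamped to
#' 0--100%.
#'
#' @param consumed_pct consumed donor in percent.
#' @param ratio donor:substrate molar ratio (default 1.2).
#' @param clamp clamp to `[0, 100]` (default `TRUE`).
#' @return product formation in percent.
#' @export
product_formation <- function(consumed_pct, ratio = 1.2, clamp = TRUE) {
  if (ratio <= 0) stop("ratio must be positive", call. = FALSE)
  raw <- consumed_pct * ratio
  if (clamp) clamp_pct(raw) else raw
}

#' Donor:substrate stoichiometric ratio
#'
#' The reaction's molar ratio of phosphate donor to nucleoside substrate,
#' rounded to two significant figures: 400 uM donor over 333 uM substrate
#' (0.4 / 0.33 mM) gives 1.2, the standard product-formation multiplier.
#'
#' @param donor_uM donor concentration.
#' @param substrate_uM substrate concentration.
#' @param sig_figs significant figures to round to; `Inf` for the exact
#'   ratio.
#' @return the ratio.
#' @export
stoichiometric_ratio <- function(donor_uM, substrate_uM, sig_figs = 2) {
  stopifnot(donor_uM > 0, substrate_uM > 0)
  r <- donor_uM / substrate_uM
  if (is.finite(sig_figs)) signif(r, sig_figs) else r
}

# Assemble the control set for one reaction group from same-plate controls.
# Negative controls match on (substrate, donor), falling back to donor;
# substrate controls on (enzyme, substrate), falling back to substrate;
# basal controls on (enzyme, donor), falling back to enzyme.
control_set <- function(plate, enzyme, substrate, donor) {
  pick <- function(role, primary, fallback) {
    w <- plate$role == role & primary
    if (!any(w)) w <- plate$role == role & fallback
    plate$rlu[w]
  }
  neg <- pick("negative_control",
              plate$substrate %in% substrate & plate$donor %in% donor,
              plate$donor %in% donor)
  sub <- pick("substrate_control",
              plate$enzyme %in% enzyme & plate$substrate %in% substrate,
              plate$substrate %in% substrate)
  bas <- pick("basal_control",
              plate$enzyme %in% enzyme & plate$donor %in% donor,
              plate$enzyme %in% enzyme)
  N <- if (length(neg)) mean(neg) else NA_real_
  S <- if (length(sub)) mean(sub) else 0
  basal <- if (length(bas)) mean(bas) else NA_real_
  B <- if (is.na(basal)) 0 else max(0, N - basal)
  list(N = N, S = S, basal = basal, B = B,
       n_negative = length(neg), n_substrate = length(sub),
       n_basal = length(bas))
}

#' Quantify every reaction group on a plate
#'
#' Groups reaction wells by enzyme x substrate x donor, builds the control
#' set from same-plate controls, and applies the consumed-donor and
#' product-formation equations. The group estimate uses the mean replicate
#' signal; the replicate spread is the standard deviation of per-replicate
#' product percentages (each replicate pushed through both equations, then
#' clamped). Groups with product formation strictly between zero and the
#' verification threshold are flagged for orthogonal verification (HPLC or
#' higher enzyme load) — low apparent conversions are where the
#' ATP-depletion readout is most error-prone.
#'
#' A missing negative or substrate control for a group is a hard error; a
#' missing basal control downgrades to a warning with `B = 0`.
#'
#' @param annotated an `annotated_plate` from [join_layout()] (or several
#'   row-bound together; grouping includes `plate_id`).
#' @param ratio donor:substrate molar ratio passed to
#'   [product_formation()] (default 1.2).
#' @param verify_threshold flagging threshold in percent product
#'   (default 10).
#' @return an `nk_quant` data frame: `plate_id`, `enzyme`, `substrate`,
#'   `donor`, `R_mean_rlu`, `N_rlu`, `S_rlu`, `B_rlu`, `consumed_pct`,
#'   `product_pct`, `sd_pct`, `n_replicates`, `flag_verify`.
#' @export
quantify_plate <- function(annotated, ratio = 1.2, verify_threshold = 10) {
  stopifnot(is.data.frame(annotated),
            all(c("plate_id", "role", "rlu") %in% names(annotated)))
  rx <- annotated[annotated$role == "reaction", , drop = FALSE]
  if (!nrow(rx)) {
    out <- data.frame(plate_id = character(), enzyme = character(),
                      substrate = character(), donor = character(),
                      R_mean_rlu = numeric(), N_rlu = numeric(),
                      S_rlu = numeric(), B_rlu = numeric(),
                      consumed_pct = numeric(), product_pct = numeric(),
                      sd_pct = numeric(), n_replicates = integer(),
                      flag_verify = logical(), stringsAsFactors = FALSE)
    class(out) <- c("nk_quant", "data.frame")
    return(out)
  }
  key <- paste(rx$plate_id, rx$enzyme, rx$substrate, rx$donor, sep = "\r")
  groups <- split(seq_len(nrow(rx)), key)
  res <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    g <- rx[groups[[i]], , drop = FALSE]
    plate <- annotated[annotated$plate_id == g$plate_id[1L], , drop = FALSE]
    cs <- control_set(plate, g$enzyme[1L], g$substrate[1L], g$donor[1L])
    label <- paste0(g$enzyme[1L], " x ", g$substrate[1L], " x ",
                    g$donor[1L], " on plate ", g$plate_id[1L])
    if (is.na(cs$N)) {
      stop("no negative control for group ", label, call. = FALSE)
    }
    if (cs$n_substrate == 0L) {
      stop("no substrate control for group ", label, call. = FALSE)
    }
    if (is.na(cs$basal)) {
      warning("no basal control for group ", label, "; B set to 0",
              call. = FALSE)
    }
    R <- mean(g$rlu)
    consumed <- consumed_donor(R, N = cs$N, S = cs$S, B = cs$B)
    product <- product_formation(consumed, ratio = ratio)
    per_rep <- clamp_pct(product_formation(
      consumed_donor(g$rlu, N = cs$N, S = cs$S, B = cs$B, clamp = FALSE),
      ratio = ratio, clamp = FALSE))
    res[[i]] <- data.frame(
      plate_id = g$plate_id[1L], enzyme = g$enzyme[1L],
      substrate = g$substrate[1L], donor = g$donor[1L],
      R_mean_rlu = R, N_rlu = cs$N, S_rlu = cs$S, B_rlu = cs$B,
      consumed_pct = consumed, product_pct = product,
      sd_pct = if (nrow(g) > 1L) stats::sd(per_rep) else NA_real_,
      n_replicates = nrow(g),
      flag_verify = product > 0 & product < verify_threshold,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out <- out[order(out$plate_id, out$enzyme, out$substrate, out$donor), ]
  rownames(out) <- NULL
  class(out) <- c("nk_quant", "data.frame")
  out
}

#' @export
print.nk_quant <- function(x, digits = 3, ...) {
  cat("Kinase screening results: ", nrow(x), " reaction group(s), ",
      sum(x$flag_verify), " flagged for verification\n", sep = "")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, digits)
  print(df)
  invisible(x)
}

#' @export
summary.nk_quant <- function(object, ...) {
  cat("Reaction groups:", nrow(object), "\n")
  cat("Enzymes:   ", paste(unique(object$enzyme), collapse = ", "), "\n")
  cat("Substrates:", length(unique(object$substrate)), "\n")
  cat("Product formation [%]:\n")
  print(summary(object$product_pct))
  cat("Flagged (< threshold, > 0):", sum(object$flag_verify), "\n")
  invisible(object)
}

#' Assemble the enzyme x substrate spectrum matrix
#'
#' Pivots quantification results into a matrix of product-formation
#' percentages over the union of enzymes (rows) and substrates (columns).
#' Cells never screened are `NA`; an (enzyme, substrate) pair screened
#' more than once (e.g. with different donors or on several plates) is
#' averaged with a warning. Verification flags are carried as a parallel
#' logical matrix (`TRUE` if any contributing result was flagged).
#'
#' @param results an `nk_quant` (rows from one or more plates).
#' @return a `spectrum_matrix`: numeric matrix with a `flags` attribute.
#' @export
build_spectrum <- function(results) {
  stopifnot(is.data.frame(results))
  enzymes <- unique(results$enzyme)
  substrates <- unique(results$substrate)
  m <- matrix(NA_real_, length(enzymes), length(substrates),
              dimnames = list(enzymes, substrates))
  fl <- matrix(FALSE, length(enzymes), length(substrates),
               dimnames = list(enzymes, substrates))
  if (nrow(results)) {
    key <- paste(results$enzyme, results$substrate, sep = "\r")
    if (anyDuplicated(key)) {
      dup <- unique(key[duplicated(key)])
      warning("averaging ", length(dup),
              " enzyme-substrate pair(s) screened more than once",
              call. = FALSE)
    }
    agg <- tapply(results$product_pct, key, mean)
    flg <- tapply(results$flag_verify, key, any)
    for (k in names(agg)) {
      es <- strsplit(k, "\r", fixed = TRUE)[[1L]]
      m[es[1L], es[2L]] <- agg[[k]]
      fl[es[1L], es[2L]] <- flg[[k]]
    }
  }
  structure(m, flags = fl, class = c("spectrum_matrix", class(m)))
}

#' @export
print.spectrum_matrix <- function(x, digits = 1, ...) {
  cat("Substrate spectrum: ", nrow(x), " enzyme(s) x ", ncol(x),
      " substrate(s); product formation [%]\n", sep = "")
  y <- unclass(x)
  attr(y, "flags") <- NULL
  print(round(y, digits))
  invisible(x)
}

#' @export
plot.spectrum_matrix <- function(x, ...) {
  y <- t(unclass(x))[, rev(seq_len(nrow(x))), drop = FALSE]
  attr(y, "flags") <- NULL
  graphics::image(seq_len(nrow(y)), seq_len(ncol(y)), y,
                  zlim = c(0, 100), axes = FALSE,
                  xlab = "substrate", ylab = "enzyme",
                  main = "Product formation [%]",
                  col = grDevices::hcl.colors(25, "YlOrRd", rev = TRUE), ...)
  graphics::axis(1, seq_len(nrow(y)), rownames(y), las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_len(ncol(y)), colnames(y), las = 1, cex.axis = 0.7)
  graphics::box()
  invisible(x)
}
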