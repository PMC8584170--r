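#' Retention-time library for peak annotation
#'
#' Maps analytes to their expected chromatographic retention times.
#' Expected times within one library must be distinct beyond twice the
#' matching tolerance, otherwise nearest-time assignment would be
#' ambiguous by construction.
#'
#' @param entries data frame with columns `analyte`, `rt_min`.
#' @param tolerance matching tolerance in minutes (default 0.3).
#' @return a `retention_library`.
#' @examples
#' retention_library(data.frame(analyte = c("AMP", "ADP", "ATP"),
#'                              rt_min = c(8.2, 15.4, 22.9)))
#' @export
retention_library <- function(entries, tolerance = 0.3) {
  stopifnot(is.data.frame(entries),
            all(c("analyte", "rt_min") %in% names(entries)),
            tolerance > 0)
  entries$analyte <- as.character(entries$analyte)
  entries$rt_min <- as.numeric(entries$rt_min)
  if (anyDuplicated(entries$analyte)) {
    stop("duplicate analyte in retention library", call. = FALSE)
  }
  rt <- sort(entries$rt_min)
  if (length(rt) > 1L && any(diff(rt) <= 2 * tolerance)) {
    stop("retention times closer than 2 x tolerance; method cannot ",
         "discriminate them", call. = FALSE)
  }
  structure(list(entries = entries[, c("analyte", "rt_min")],
                 tolerance = tolerance),
            class = "retention_library")
}

#' Default adenosine-nucleotide retention library
#'
#' AMP 8.2 min, ADP 15.4 min, ATP 22.9 min — the typical elution times of
#' the adenosine pool on the ion-pair C18 method.
#'
#' @param tolerance matching tolerance in minutes (default 0.3).
#' @return a [retention_library()].
#' @export
default_retention_library <- function(tolerance = 0.3) {
  retention_library(data.frame(analyte = c("AMP", "ADP", "ATP"),
                               rt_min = c(8.2, 15.4, 22.9),
                               stringsAsFactors = FALSE), tolerance)
}

#' Annotate chromatogram peaks by retention time
#'
#' Labels each peak with the library analyte whose expected time is
#' nearest and within tolerance; peaks matching nothing stay unlabelled.
#' If several peaks of one sample match the same analyte, the nearest
#' keeps the label and the others are unlabelled with a warning (an
#' analyte elutes once per run). Two library entries equidistant from one
#' peak is a method-ambiguity error (precluded by the library spacing
#' invariant, but checked defensively).
#'
#' @param table a `peak_table`.
#' @param library a [retention_library()].
#' @return the `peak_table` with the `analyte` column filled in.
#' @export
annotate_peaks <- function(table, library) {
  stopifnot(inherits(table, "peak_table"),
            inherits(library, "retention_library"))
  if (!nrow(library$entries)) stop("empty retention library", call. = FALSE)
  tab <- as.data.frame(table)
  tab$analyte <- rep(NA_character_, nrow(tab))
  lib <- library$entries
  for (i in seq_len(nrow(tab))) {
    d <- abs(lib$rt_min - tab$rt_min[i])
    j <- which(d == min(d))
    if (length(j) > 1L) {
      stop("peak at ", tab$rt_min[i], " min equidistant from analytes ",
           paste(lib$analyte[j], collapse = " and "), call. = FALSE)
    }
    if (d[j] <= library$tolerance) tab$analyte[i] <- lib$analyte[j]
  }
  # uniqueness within a sample: nearest peak wins, the rest unlabelled
  for (sid in unique(tab$sample_id)) {
    s <- which(tab$sample_id == sid & !is.na(tab$analyte))
    for (a in unique(tab$analyte[s])) {
      k <- s[tab$analyte[s] == a]
      if (length(k) > 1L) {
        exp_rt <- lib$rt_min[lib$analyte == a]
        keep <- k[which.min(abs(tab$rt_min[k] - exp_rt))]
        drop <- setdiff(k, keep)
        tab$analyte[drop] <- NA_character_
        warning("sample ", sid, ": ", length(drop) + 1L,
                " peaks matched ", a, "; keeping the nearest",
                call. = FALSE)
      }
    }
  }
  as_peak_table(tab)
}

sample_area <- function(tab, sid, analyte) {
  a <- tab$area[tab$sample_id == sid & !is.na(tab$analyte) &
                  tab$analyte == analyte]
  if (length(a)) sum(a) else 0
}

#' Consumed ATP from HPLC peak areas
#'
#' `(1 - A_ATP / A_total) * 100`, where `A_total` is the summed area of
#' the adenosine pool (ATP + ADP + AMP). Absent ADP/AMP peaks count as
#' zero area (low-conversion samples may show no detectable ADP).
#'
#' @param table an analyte-labelled `peak_table`.
#' @param sample_id sample(s) to quantify; default all samples in the
#'   table.
#' @return named numeric vector of percent consumed ATP per sample.
#' @export
hplc_consumed_atp <- function(table, sample_id = unique(table$sample_id)) {
  stopifnot(inherits(table, "peak_table"))
  tab <- as.data.frame(table)
  out <- vapply(sample_id, function(sid) {
    atp <- sample_area(tab, sid, "ATP")
    total <- atp + sample_area(tab, sid, "ADP") + sample_area(tab, sid, "AMP")
    if (total <= 0) {
      stop("sample ", sid, ": adenosine pool has zero total area",
           call. = FALSE)
    }
    (1 - atp / total) * 100
  }, 0)
  names(out) <- sample_id
  out
}

#' Product formation from HPLC peak areas
#'
#' `100 * P_products / (A_substrate + P_products)`: the formed nucleoside
#' monophosphate(s) as a percent of the substrate + product pool.
#'
#' @param table an analyte-labelled `peak_table`.
#' @param substrate substrate analyte name.
#' @param products character vector of product analyte name(s).
#' @param sample_id sample(s) to quantify; default all samples.
#' @return named numeric vector of percent product per sample.
#' @export
hplc_product <- function(table, substrate, products,
                         sample_id = unique(table$sample_id)) {
  stopifnot(inherits(table, "peak_table"), length(products) >= 1L)
  tab <- as.data.frame(table)
  out <- vapply(sample_id, function(sid) {
    p <- sum(vapply(products, function(a) sample_area(tab, sid, a), 0))
    s <- sample_area(tab, sid, substrate)
    if (p + s <= 0) {
      stop("sample ", sid, ": substrate + product pool has zero area",
           call. = FALSE)
    }
    100 * p / (s + p)
  }, 0)
  names(out) <- sample_id
  out
}

#' Quantify a whole peak table against its sample map
#'
#' Runs [hplc_consumed_atp()] and [hplc_product()] for every sample; the
#' product analyte for each substrate defaults to `<substrate>-MP` unless
#' a `products` mapping is given.
#'
#' @param table an analyte-labelled `peak_table`.
#' @param samples data frame mapping `sample_id` to `enzyme`,
#'   `substrate`, `donor`.
#' @param products optional named list: substrate -> character vector of
#'   product analytes.
#' @return data frame: `enzyme`, `substrate`, `donor`,
#'   `consumed_hplc_pct`, `product_hplc_pct`.
#' @export
quantify_hplc <- function(table, samples, products = NULL) {
  stopifnot(all(c("sample_id", "enzyme", "substrate", "donor") %in%
                  names(samples)))
  consumed <- hplc_consumed_atp(table, samples$sample_id)
  product <- vapply(seq_len(nrow(samples)), function(i) {
    sub <- samples$substrate[i]
    prods <- if (!is.null(products) && !is.null(products[[sub]])) {
      products[[sub]]
    } else {
      paste0(sub, "-MP")
    }
    hplc_product(table, sub, prods, samples$sample_id[i])
  }, 0)
  data.frame(enzyme = samples$enzyme, substrate = samples$substrate,
             donor = samples$donor,
             consumed_hplc_pct = unname(consumed),
             product_hplc_pct = unname(product),
             stringsAsFactors = FALSE)
}

#' Compare luminescence and HPLC quantification
#'
#' Joins the two methods' results on (enzyme, substrate, donor) and
#' reports per-group absolute deviations in percentage points plus
#' summary statistics. Groups present in only one method are listed
#' unpaired and excluded from the summary.
#'
#' @param lum an `nk_quant` from [quantify_plate()].
#' @param hplc data frame from [quantify_hplc()] (columns `enzyme`,
#'   `substrate`, `donor`, `consumed_hplc_pct`, `product_hplc_pct`).
#' @return a `method_comparison` list: `pairs` (per-group table with
#'   `abs_deviation`), `summary` (min/max/mean deviation in product
#'   percentage points), `unpaired` (group keys seen in one method only).
#' @export
compare_methods <- function(lum, hplc) {
  stopifnot(is.data.frame(lum), is.data.frame(hplc))
  col_of <- function(df, candidates) {
    hit <- intersect(candidates, names(df))
    if (!length(hit)) {
      stop("no product/consumed column among: ",
           paste(candidates, collapse = ", "), call. = FALSE)
    }
    df[[hit[1L]]]
  }
  lum_prod <- col_of(lum, c("product_pct", "product_lum_pct",
                            "product_hplc_pct"))
  lum_cons <- col_of(lum, c("consumed_pct", "consumed_lum_pct",
                            "consumed_hplc_pct"))
  hplc_prod <- col_of(hplc, c("product_hplc_pct", "product_pct",
                              "product_lum_pct"))
  hplc_cons <- col_of(hplc, c("consumed_hplc_pct", "consumed_pct",
                              "consumed_lum_pct"))
  kl <- paste(lum$enzyme, lum$substrate, lum$donor, sep = "\r")
  kh <- paste(hplc$enzyme, hplc$substrate, hplc$donor, sep = "\r")
  shared <- intersect(kl, kh)
  if (!length(shared)) {
    stop("no shared (enzyme, substrate, donor) groups between methods",
         call. = FALSE)
  }
  il <- match(shared, kl); ih <- match(shared, kh)
  pairs <- data.frame(
    enzyme = lum$enzyme[il], substrate = lum$substrate[il],
    donor = lum$donor[il],
    product_lum_pct = lum_prod[il],
    product_hplc_pct = hplc_prod[ih],
    consumed_lum_pct = lum_cons[il],
    consumed_hplc_pct = hplc_cons[ih],
    stringsAsFactors = FALSE)
  pairs$abs_deviation <- abs(pairs$product_lum_pct - pairs$product_hplc_pct)
  unpaired <- c(setdiff(kl, kh), setdiff(kh, kl))
  structure(list(
    pairs = pairs,
    summary = c(min = min(pairs$abs_deviation),
                max = max(pairs$abs_deviation),
                mean = mean(pairs$abs_deviation)),
    unpaired = gsub("\r", ":", unpaired, fixed = TRUE)),
    class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, digits = 3, ...) {
  cat("Luminescence vs HPLC: ", nrow(x$pairs), " paired group(s)\n",
      "  |product deviation| [pp]: min ",
      format(x$summary[["min"]], digits = digits), ", mean ",
      format(x$summary[["mean"]], digits = digits), ", max ",
      format(x$summary[["max"]], digits = digits), "\n", sep = "")
  if (length(x$unpaired)) {
    cat("  unpaired:", paste(x$unpaired, collapse = ", "), "\n")
  }
  df <- x$pairs
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, digits)
  print(df)
  invisible(x)
}
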