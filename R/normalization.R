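#' Remove measurements with DAPI intensity in the lowest percentile
#'
#' Images whose total DAPI staining intensity falls at or below the
#' empirical first percentile of all intensities in the screen are treated
#' as unreliable (sparse or failed wells) and removed before normalization.
#'
#' @param records Per-image measurement tibble (see
#'   [read_well_measurements()]).
#' @param percentile Lower-tail fraction, default `0.01`.
#' @return A list with tibbles `kept` and `removed`;
#'   `nrow(kept) + nrow(removed) == nrow(records)` always.
#' @details The cutoff is the empirical quantile (type 7, linear
#'   interpolation) and removal uses `intensity <= cutoff`. When all
#'   intensities are identical (zero spread) nothing is removed: the filter
#'   targets a lower tail that does not exist in that case.
#' @export
filter_low_dapi <- function(records, percentile = 0.01) {
  if (nrow(records) < 2) {
    rlang::abort("need at least 2 records to estimate an intensity percentile",
                 class = "mitoscreen_validation_error")
  }
  stopifnot_scalar_number(percentile, "percentile", min = 0)
  x <- records$dapi_intensity
  if (stats::mad(x) == 0 && length(unique(x)) == 1L) {
    removed <- records[0, , drop = FALSE]
    kept <- records
  } else {
    cutoff <- stats::quantile(x, probs = percentile, names = FALSE, type = 7)
    removed <- records[x <= cutoff, , drop = FALSE]
    kept <- records[x > cutoff, , drop = FALSE]
  }
  list(kept = tibble::as_tibble(kept), removed = tibble::as_tibble(removed))
}

#' Remove measurements with more mitotic cells than nuclei
#'
#' A pH3-positive count exceeding the total DAPI nucleus count is physically
#' impossible and indicates a segmentation failure; such images are removed.
#' The rule is a strict inequality: `ph3_count == dapi_count` is kept.
#'
#' @inheritParams filter_low_dapi
#' @return A list with tibbles `kept` and `removed`.
#' @export
filter_inconsistent <- function(records) {
  bad <- records$ph3_count > records$dapi_count
  list(
    kept = tibble::as_tibble(records[!bad, , drop = FALSE]),
    removed = tibble::as_tibble(records[bad, , drop = FALSE])
  )
}

#' Plate-median normalization of one measurement channel
#'
#' Each measurement is divided by the median of its plate and rescaled by
#' the overall median across all plates, so that after normalization every
#' plate's median equals the pre-normalization overall median. This removes
#' multiplicative plate effects (seeding density, staining efficiency).
#'
#' @param values Numeric vector of positive channel measurements.
#' @param plate_ids Plate identifier per measurement.
#' @return Numeric vector of normalized values. Plates whose median is zero
#'   cannot be rescaled; their values are returned as `NA` with a warning.
#' @export
normalize_channel <- function(values, plate_ids) {
  if (length(values) != length(plate_ids)) {
    rlang::abort("`values` and `plate_ids` must have equal length",
                 class = "mitoscreen_validation_error")
  }
  overall <- stats::median(values, na.rm = TRUE)
  plate_med <- tapply(values, plate_ids, stats::median, na.rm = TRUE)
  zero <- names(plate_med)[!is.na(plate_med) & plate_med == 0]
  if (length(zero) > 0) {
    rlang::warn(sprintf("plate(s) with zero channel median excluded: %s",
                        paste(zero, collapse = ", ")))
  }
  denom <- as.numeric(plate_med[as.character(plate_ids)])
  denom[denom == 0] <- NA_real_
  values / denom * overall
}

#' Mitotic index of an image
#'
#' The mitotic index (MI) is the fraction of cells in mitosis: the ratio of
#' phospho-histone H3 positive cells to DAPI-stained nuclei. Images with
#' zero pH3-positive cells receive a pseudocount on the numerator so the
#' index stays positive and `log2(MI)` is defined.
#'
#' @param dapi_count Nuclei per image (possibly normalized; must be > 0 for
#'   a defined MI — zero-nucleus images yield `NA`).
#' @param ph3_count pH3-positive cells per image (possibly normalized).
#' @param pseudocount Added to the numerator only when `ph3_count == 0`;
#'   default `0.5`.
#' @return Numeric vector of mitotic indices; `NA` where `dapi_count <= 0`.
#' @export
compute_mi <- function(dapi_count, ph3_count, pseudocount = 0.5) {
  stopifnot_scalar_number(pseudocount, "pseudocount", min = 0)
  num <- ph3_count + pseudocount * (ph3_count == 0)
  mi <- num / dapi_count
  mi[!is.finite(dapi_count) | dapi_count <= 0] <- NA_real_
  mi
}

#' Summarize per-image mitotic indices to one value per gene
#'
#' @param mi Per-image MI values for one gene (all surviving images across
#'   its duplexes).
#' @param method `"median"` (default, robust to single bad duplexes or
#'   images) or `"mean"`.
#' @return A list with `mi` (the summary, `NA` if no finite value survives)
#'   and `n_images_used`.
#' @export
summarize_gene <- function(mi, method = c("median", "mean")) {
  method <- match.arg(method)
  mi <- mi[is.finite(mi)]
  if (length(mi) == 0) {
    return(list(mi = NA_real_, n_images_used = 0L))
  }
  s <- if (method == "median") stats::median(mi) else mean(mi)
  list(mi = s, n_images_used = length(mi))
}

#' Robust z-scores from median and MAD
#'
#' `z = (x - median(x)) / MAD(x)` with
#' `MAD(x) = constant * median(|x - median(x)|)`. The default constant
#' 1.4826 makes the MAD a consistent estimator of the standard deviation
#' under normality.
#'
#' @param x Numeric vector (at least 3 finite values).
#' @param constant MAD scale constant; default `1.4826`, set `1` for the
#'   unscaled MAD.
#' @return Numeric vector of z-scores.
#' @export
robust_zscore <- function(x, constant = 1.4826) {
  if (sum(is.finite(x)) < 3) {
    rlang::abort("need >= 3 finite values for a robust z-score",
                 class = "mitoscreen_validation_error")
  }
  med <- stats::median(x, na.rm = TRUE)
  s <- stats::mad(x, constant = constant, na.rm = TRUE)
  if (s == 0) {
    rlang::abort(
      "MAD is zero: the screen is degenerate (all values identical?); inspect the input",
      class = "mitoscreen_degenerate_error"
    )
  }
  (x - med) / s
}

#' Normalize a mitotic-index screen
#'
#' Runs the full two-channel preprocessing in fixed order: (1) drop images
#' in the lowest percentile of DAPI intensity, (2) drop images with more
#' pH3-positive cells than nuclei, (3) plate-median normalization of each
#' channel, (4) per-image mitotic index, (5) per-gene summarization across
#' duplexes and images, (6) `log2`, (7) robust z-scores across the screen.
#'
#' @param records Per-image measurements joined to their layout (see
#'   [read_well_measurements()]), or a raw measurement table if `layout` is
#'   given.
#' @param layout Optional plate layout; required when `records` lacks
#'   `gene_symbol`/`role` columns.
#' @param percentile Lower DAPI-intensity percentile to remove (default 0.01).
#' @param pseudocount Numerator pseudocount for zero-pH3 images (default 0.5).
#' @param summary Per-gene summary statistic: `"median"` (default) or
#'   `"mean"`.
#' @param mad_constant MAD scale constant for z-scores (default 1.4826).
#' @param zscore_scope `"screen"` (default) computes z-scores across the
#'   whole screen after normalization; `"plate"` computes them within each
#'   gene's (modal) plate.
#' @param granularity `"gene"` (default) summarizes over a gene's three
#'   duplexes together; `"duplex"` returns one row per duplex (the
#'   `gene_symbol` column then holds `gene:duplex` identities in
#'   `duplex_id`).
#'
#' @return A tibble of class `"mi_screen"`, one row per gene (or duplex):
#'   `gene_symbol`, `mi`, `log2_mi`, `zscore`, `n_images_used`, `flags`.
#'   Attributes: `"records"` (surviving per-image table with normalized
#'   counts and per-image MI, controls included, for control-based QC),
#'   `"filter_counts"`, and the parameters used.
#' @export
normalize_screen <- function(records, layout = NULL,
                             percentile = 0.01, pseudocount = 0.5,
                             summary = c("median", "mean"),
                             mad_constant = 1.4826,
                             zscore_scope = c("screen", "plate"),
                             granularity = c("gene", "duplex")) {
  summary <- match.arg(summary)
  zscore_scope <- match.arg(zscore_scope)
  granularity <- match.arg(granularity)

  if (!all(c("gene_symbol", "role") %in% names(records))) {
    if (is.null(layout)) {
      rlang::abort("`records` has no layout columns; supply `layout`",
                   class = "mitoscreen_validation_error")
    }
    records <- validate_well_measurements(records, layout)
  }

  f1 <- filter_low_dapi(records, percentile = percentile)
  f2 <- filter_inconsistent(f1$kept)
  surv <- f2$kept
  if (nrow(surv) == 0) {
    rlang::abort("no measurements survive the QC filters",
                 class = "mitoscreen_validation_error")
  }
  surv$flag_low_dapi <- FALSE
  surv$flag_inconsistent <- FALSE

  surv$dapi_norm <- normalize_channel(surv$dapi_count, surv$plate_id)
  surv$ph3_norm <- normalize_channel(surv$ph3_count, surv$plate_id)
  surv$mi <- compute_mi(surv$dapi_norm, surv$ph3_norm, pseudocount = pseudocount)

  samples <- surv[surv$role == "sample" & surv$gene_symbol != "", , drop = FALSE]
  key <- if (granularity == "gene") samples$gene_symbol else
    paste(samples$gene_symbol, samples$duplex_id, sep = ":")

  per_gene <- samples |>
    dplyr::mutate(.key = key) |>
    dplyr::group_by(.data$.key, .data$gene_symbol) |>
    dplyr::summarise(
      n_images_used = sum(is.finite(.data$mi)),
      mi = summarize_gene(.data$mi, method = summary)$mi,
      .groups = "drop"
    ) |>
    dplyr::relocate("mi", .after = "gene_symbol")
  if (granularity == "duplex") {
    per_gene$duplex_id <- sub("^[^:]*:", "", per_gene$.key)
  }
  per_gene$.key <- NULL
  per_gene$log2_mi <- log2(per_gene$mi)

  ok <- is.finite(per_gene$log2_mi)
  per_gene$zscore <- NA_real_
  if (zscore_scope == "screen") {
    per_gene$zscore[ok] <- robust_zscore(per_gene$log2_mi[ok], constant = mad_constant)
  } else {
    plate_of <- samples |>
      dplyr::count(.data$gene_symbol, .data$plate_id) |>
      dplyr::slice_max(.data$n, n = 1, by = "gene_symbol", with_ties = FALSE)
    per_gene <- dplyr::left_join(per_gene, plate_of[c("gene_symbol", "plate_id")],
                                 by = "gene_symbol")
    for (p in unique(per_gene$plate_id)) {
      idx <- ok & per_gene$plate_id == p
      if (sum(idx) >= 3) {
        per_gene$zscore[idx] <- robust_zscore(per_gene$log2_mi[idx],
                                              constant = mad_constant)
      }
    }
  }
  per_gene <- dplyr::arrange(per_gene, .data$gene_symbol)

  out <- tibble::new_tibble(
    per_gene,
    class = "mi_screen",
    records = surv,
    filter_counts = c(low_dapi = nrow(f1$removed), inconsistent = nrow(f2$removed)),
    params = list(percentile = percentile, pseudocount = pseudocount,
                  summary = summary, mad_constant = mad_constant,
                  zscore_scope = zscore_scope, granularity = granularity)
  )
  out
}
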