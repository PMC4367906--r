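#' Call screen hits by the median +/- k*MAD rule
#'
#' A gene is a primary hit when its summarized `log2` mitotic index lies
#' strictly above or strictly below the screen median by more than `k`
#' median absolute deviations. Hits above the upper threshold form the
#' high-MI group (knockdown arrests cells in mitosis); hits below the lower
#' threshold form the low-MI group (knockdown blocks the cycle before
#' mitosis). Values exactly on a threshold are non-hits.
#'
#' @param screen An `mi_screen` tibble from [normalize_screen()], or any
#'   data frame with columns `gene_symbol` and `log2_mi` (a `zscore` column
#'   is carried through or recomputed).
#' @param k MAD multiplier, default `2`.
#' @param mad_constant MAD scale constant, default `1.4826`.
#' @return A tibble of class `"hit_table"` with columns `gene_symbol`,
#'   `log2_mi`, `zscore`, `call` (`"hit"`/`"non_hit"`), `group`
#'   (`"low"`/`"high"`/`"none"`) and `distance_in_mads` (signed deviation
#'   from the median in MAD units). Attributes record the `median`, `mad`,
#'   `k` and the two thresholds.
#' @export
call_hits <- function(screen, k = 2, mad_constant = 1.4826) {
  assert_columns(screen, c("gene_symbol", "log2_mi"), "normalized screen")
  stopifnot_scalar_number(k, "k", min = 0)
  df <- tibble::as_tibble(screen)[, intersect(
    c("gene_symbol", "mi", "log2_mi", "zscore"), names(screen)
  )]
  ok <- is.finite(df$log2_mi)
  if (sum(ok) < 10) {
    rlang::abort("need >= 10 genes with finite log2 MI to call hits",
                 class = "mitoscreen_validation_error")
  }
  x <- df$log2_mi[ok]
  med <- stats::median(x)
  s <- stats::mad(x, constant = mad_constant)
  if (s == 0) {
    rlang::abort("MAD of log2 MI is zero: degenerate screen, hits are undefined",
                 class = "mitoscreen_degenerate_error")
  }
  df$distance_in_mads <- (df$log2_mi - med) / s
  if (!"zscore" %in% names(df)) df$zscore <- df$distance_in_mads
  is_hit <- ok & abs(df$log2_mi - med) > k * s
  df$call <- ifelse(is_hit, "hit", "non_hit")
  df$group <- "none"
  df$group[is_hit & df$log2_mi < med] <- "low"
  df$group[is_hit & df$log2_mi > med] <- "high"
  df <- df[order(df$gene_symbol), ]
  tibble::new_tibble(
    df, class = "hit_table",
    median = med, mad = s, k = k,
    thresholds = c(lower = med - k * s, upper = med + k * s)
  )
}

#' Split a hit table into the low- and high-MI gene lists
#'
#' @param hits A `"hit_table"` from [call_hits()].
#' @return A list with character vectors `low` and `high`, each sorted
#'   alphabetically.
#' @export
classify_groups <- function(hits) {
  assert_columns(hits, c("gene_symbol", "call", "group"), "hit table")
  list(
    low = sort(hits$gene_symbol[hits$group == "low"]),
    high = sort(hits$gene_symbol[hits$group == "high"])
  )
}

#' Per-duplex hit calling
#'
#' Alternative selection mode: call the median +/- k*MAD rule on per-duplex
#' `log2` MI values and declare a gene a hit when at least `min_duplexes` of
#' its duplexes pass on the same side. Off the main path; the default
#' pipeline summarizes to gene level before selection.
#'
#' @param duplex_screen An `mi_screen` computed with
#'   `normalize_screen(..., granularity = "duplex")` (columns `gene_symbol`,
#'   `duplex_id`, `log2_mi`).
#' @inheritParams call_hits
#' @param min_duplexes Minimum concordant duplexes per gene, default `2`.
#' @return A tibble with per-gene `call`, `group` and the number of
#'   concordant duplexes `n_duplexes_passing`.
#' @export
call_hits_per_duplex <- function(duplex_screen, k = 2, mad_constant = 1.4826,
                                 min_duplexes = 2) {
  assert_columns(duplex_screen, c("gene_symbol", "duplex_id", "log2_mi"),
                 "per-duplex screen")
  per_duplex <- call_hits(
    dplyr::mutate(duplex_screen,
                  gene_symbol = paste(.data$gene_symbol, .data$duplex_id, sep = ":")),
    k = k, mad_constant = mad_constant
  )
  per_duplex$gene_symbol <- sub(":[^:]*$", "", per_duplex$gene_symbol)
  per_duplex |>
    dplyr::group_by(.data$gene_symbol) |>
    dplyr::summarise(
      n_low = sum(.data$group == "low"),
      n_high = sum(.data$group == "high"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      group = dplyr::case_when(
        .data$n_low >= min_duplexes & .data$n_low >= .data$n_high ~ "low",
        .data$n_high >= min_duplexes ~ "high",
        .default = "none"
      ),
      call = ifelse(.data$group == "none", "non_hit", "hit"),
      n_duplexes_passing = pmax(.data$n_low, .data$n_high)
    ) |>
    dplyr::select("gene_symbol", "call", "group", "n_duplexes_passing") |>
    dplyr::arrange(.data$gene_symbol)
}

#' Control-based plate quality control
#'
#' Summarizes the positive (Plk1-like) and negative (untreated and
#' lipofectant-only) control wells of every plate on the screen z-score
#' scale and flags plates where the two control populations fail to
#' separate. Plates are flagged, never dropped.
#'
#' @param screen An `mi_screen` from [normalize_screen()] (its per-image
#'   record attribute carries the control wells).
#' @param min_separation Minimum required `|median z(positive) - median
#'   z(negative)|`, in robust z units; default `3`.
#' @return A tibble of class `"qc_report"`: one row per plate with
#'   `pos_median_z`, `neg_median_z`, `separation` and logical `pass`.
#' @export
qc_controls <- function(screen, min_separation = 3) {
  records <- attr(screen, "records")
  if (is.null(records)) {
    rlang::abort("`screen` carries no per-image records; run normalize_screen() first",
                 class = "mitoscreen_validation_error")
  }
  params <- attr(screen, "params")
  ok <- is.finite(screen$log2_mi)
  med <- stats::median(screen$log2_mi[ok])
  s <- stats::mad(screen$log2_mi[ok], constant = params$mad_constant %||% 1.4826)

  is_pos <- records$role == "positive_control"
  is_neg <- records$role %in% c("negative_control_untreated", "negative_control_lipo")
  plates <- sort(unique(records$plate_id))
  missing_pos <- plates[!plates %in% unique(records$plate_id[is_pos])]
  missing_neg <- plates[!plates %in% unique(records$plate_id[is_neg])]
  if (length(missing_pos) > 0 || length(missing_neg) > 0) {
    rlang::abort(
      sprintf("plate(s) missing control wells: %s",
              paste(unique(c(missing_pos, missing_neg)), collapse = ", ")),
      class = "mitoscreen_qc_error"
    )
  }

  ctl <- records[is_pos | is_neg, , drop = FALSE]
  ctl$z <- (log2(ctl$mi) - med) / s
  report <- ctl |>
    dplyr::group_by(.data$plate_id) |>
    dplyr::summarise(
      pos_median_z = stats::median(.data$z[.data$role == "positive_control"], na.rm = TRUE),
      neg_median_z = stats::median(.data$z[.data$role != "positive_control"], na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      separation = abs(.data$pos_median_z - .data$neg_median_z),
      pass = .data$separation >= min_separation
    )
  tibble::new_tibble(report, class = "qc_report", min_separation = min_separation)
}
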