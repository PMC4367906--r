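#' Read a plate layout table
#'
#' A plate layout maps wells to siRNA duplexes: one row per well with the
#' plate identifier, the well identifier (e.g. `"A01"`), the targeted gene
#' symbol (empty for control/empty wells), the duplex identifier and the
#' well role.
#'
#' @param path Path to a comma-delimited, UTF-8, headered CSV with columns
#'   `plate_id`, `well_id`, `gene_symbol`, `duplex_id`, `role`.
#'
#' @details Roles must be one of `sample`, `positive_control`,
#'   `negative_control_untreated`, `negative_control_lipo`, `empty`.
#'   Gene symbols are matched case-insensitively and stored uppercase.
#'   A duplicated (plate, well) pair or a sample well without a gene symbol
#'   is an integrity error.
#'
#' @return A tibble, one row per well.
#' @export
read_plate_layout <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  validate_plate_layout(df)
}

#' Validate an in-memory plate layout
#'
#' @param layout A data frame with the columns documented in
#'   [read_plate_layout()].
#' @return The validated layout as a tibble (gene symbols uppercased).
#' @export
validate_plate_layout <- function(layout) {
  assert_columns(layout, c("plate_id", "well_id", "gene_symbol", "duplex_id", "role"),
                 "plate layout")
  layout <- tibble::as_tibble(layout)
  layout$gene_symbol <- as_gene_symbol(layout$gene_symbol)
  layout$gene_symbol[is.na(layout$gene_symbol)] <- ""

  bad_role <- setdiff(unique(layout$role), LAYOUT_ROLES)
  if (length(bad_role) > 0) {
    rlang::abort(sprintf("unknown well role(s): %s", paste(bad_role, collapse = ", ")),
                 class = "mitoscreen_schema_error")
  }
  dup <- duplicated(layout[c("plate_id", "well_id")])
  if (any(dup)) {
    offenders <- unique(paste(layout$plate_id[dup], layout$well_id[dup], sep = ","))
    rlang::abort(
      sprintf("duplicated (plate, well) pairs: %s", paste(offenders, collapse = "; ")),
      class = "mitoscreen_integrity_error"
    )
  }
  no_gene <- layout$role == "sample" & layout$gene_symbol == ""
  if (any(no_gene)) {
    rlang::abort(
      sprintf("%d sample well(s) lack a gene_symbol (first: %s %s)",
              sum(no_gene), layout$plate_id[no_gene][1], layout$well_id[no_gene][1]),
      class = "mitoscreen_integrity_error"
    )
  }
  layout
}

#' Read per-image well measurements
#'
#' Each row is one image of one well: total nuclei (`dapi_count`), summed or
#' mean DAPI staining intensity (`dapi_intensity`, arbitrary units) and the
#' number of phospho-histone H3 positive cells (`ph3_count`).
#'
#' @param path CSV with columns `plate_id`, `well_id`, `image_index`,
#'   `dapi_count`, `dapi_intensity`, `ph3_count`.
#' @param layout A plate layout (see [read_plate_layout()]). Records that do
#'   not join to a layout well are *reported*, not silently dropped: they are
#'   returned in the `"rejects"` attribute (see [rejected_records()]) with a
#'   warning.
#'
#' @return A tibble of accepted records joined to their layout row
#'   (`gene_symbol`, `duplex_id`, `role` carried along).
#' @export
read_well_measurements <- function(path, layout) {
  df <- readr::read_csv(
    path,
    col_types = readr::cols(
      plate_id = readr::col_character(),
      well_id = readr::col_character(),
      image_index = readr::col_integer(),
      dapi_count = readr::col_integer(),
      dapi_intensity = readr::col_double(),
      ph3_count = readr::col_integer()
    ),
    progress = FALSE
  )
  validate_well_measurements(df, layout)
}

#' Validate in-memory well measurements against a layout
#'
#' @inheritParams read_well_measurements
#' @param records Data frame of per-image measurements.
#' @return Accepted records as a tibble with a `"rejects"` attribute.
#' @export
validate_well_measurements <- function(records, layout) {
  assert_columns(records, c("plate_id", "well_id", "image_index",
                            "dapi_count", "dapi_intensity", "ph3_count"),
                 "measurement table")
  layout <- validate_plate_layout(layout)
  records <- tibble::as_tibble(records)

  for (col in c("dapi_count", "ph3_count")) {
    v <- records[[col]]
    if (any(!is.finite(v) | v < 0 | v != floor(v))) {
      rlang::abort(sprintf("`%s` must contain nonnegative integers", col),
                   class = "mitoscreen_validation_error")
    }
  }
  if (any(!is.finite(records$dapi_intensity) | records$dapi_intensity < 0)) {
    rlang::abort("`dapi_intensity` must be nonnegative and finite",
                 class = "mitoscreen_validation_error")
  }
  if (any(records$image_index < 1)) {
    rlang::abort("`image_index` must be >= 1", class = "mitoscreen_validation_error")
  }

  joined <- dplyr::left_join(
    records,
    layout[c("plate_id", "well_id", "gene_symbol", "duplex_id", "role")],
    by = c("plate_id", "well_id")
  )
  unmatched <- is.na(joined$role)
  rejects <- joined[unmatched, names(records)]
  accepted <- joined[!unmatched, , drop = FALSE]
  if (nrow(rejects) > 0) {
    rlang::warn(sprintf(
      "%d measurement record(s) do not match any layout well; see rejected_records()",
      nrow(rejects)
    ))
  }
  attr(accepted, "rejects") <- rejects
  accepted
}

#' Rejected rows from the last read/validate step
#'
#' @param x A table returned by [read_well_measurements()] or
#'   [validate_well_measurements()].
#' @return A tibble of rejected input rows (possibly empty).
#' @export
rejected_records <- function(x) {
  attr(x, "rejects") %||% tibble::tibble()
}

#' Read a typed protein-interaction table
#'
#' Interaction tables carry one edge per row with a relation class taken
#' from a four-class vocabulary: `interacting` (1), `interacting_phospho`
#' (2, interacting protein that is also a phosphoprotein), `substrate` (3)
#' and `substrate_phospho` (4, substrate that is also an interacting
#' phosphoprotein).
#'
#' @param path Tab- or comma-delimited file (delimiter sniffed from the
#'   header line) with columns `source`, `target`, `relation`.
#' @param allow_self_loops Keep rows with `source == target`? Default
#'   `FALSE`: self-loops are an integrity error.
#' @return A tibble with columns `source`, `target`, `relation` (factor over
#'   the four classes) and `relation_class` (integer 1-4).
#' @export
read_interaction_table <- function(path, allow_self_loops = FALSE) {
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- readr::read_delim(path, delim = delim,
                          col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
  validate_interaction_table(df, allow_self_loops = allow_self_loops)
}

#' Validate an in-memory interaction table
#'
#' @inheritParams read_interaction_table
#' @param interactions Data frame with columns `source`, `target`, `relation`.
#' @return A validated tibble (symbols uppercased, `relation_class` added).
#' @export
validate_interaction_table <- function(interactions, allow_self_loops = FALSE) {
  assert_columns(interactions, c("source", "target", "relation"), "interaction table")
  interactions <- tibble::as_tibble(interactions)
  interactions$source <- as_gene_symbol(interactions$source)
  interactions$target <- as_gene_symbol(interactions$target)

  unknown <- setdiff(unique(interactions$relation), names(RELATION_LEVELS))
  if (length(unknown) > 0) {
    rlang::abort(
      sprintf("unknown relation label(s): %s (expected one of: %s)",
              paste(unknown, collapse = ", "),
              paste(names(RELATION_LEVELS), collapse = ", ")),
      class = "mitoscreen_vocabulary_error"
    )
  }
  self <- interactions$source == interactions$target
  if (any(self) && !allow_self_loops) {
    rlang::abort(
      sprintf("%d self-loop(s) (e.g. %s); pass allow_self_loops = TRUE to keep them",
              sum(self), interactions$source[self][1]),
      class = "mitoscreen_integrity_error"
    )
  }
  interactions$relation_class <- unname(RELATION_LEVELS[interactions$relation])
  interactions
}

#' Read a flat gene-to-term annotation table
#'
#' A flat (pre-propagated) annotation table: one row per (gene, term) pair
#' with the term name and ontology namespace. No DAG semantics are applied.
#'
#' @param path Tab- or comma-delimited file with columns `gene_symbol`,
#'   `term_id`, `term_name`, `namespace`.
#' @return A validated tibble.
#' @export
read_annotation_table <- function(path) {
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- readr::read_delim(path, delim = delim,
                          col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
  validate_annotation_table(df)
}

#' Validate an in-memory annotation table
#'
#' @param annotations Data frame with columns `gene_symbol`, `term_id`,
#'   `term_name`, `namespace`.
#' @return A validated tibble with uppercased gene symbols.
#' @export
validate_annotation_table <- function(annotations) {
  assert_columns(annotations, c("gene_symbol", "term_id", "term_name", "namespace"),
                 "annotation table")
  annotations <- tibble::as_tibble(annotations)
  annotations$gene_symbol <- as_gene_symbol(annotations$gene_symbol)
  dup <- duplicated(annotations[c("gene_symbol", "term_id")])
  if (any(dup)) {
    rlang::abort(sprintf("%d duplicated (gene, term) pair(s)", sum(dup)),
                 class = "mitoscreen_integrity_error")
  }
  if (any(is.na(annotations$namespace) | annotations$namespace == "")) {
    rlang::abort("every annotation row needs a namespace tag",
                 class = "mitoscreen_schema_error")
  }
  annotations
}

#' Write screen tables to disk
#'
#' Thin CSV/TSV writers matching the corresponding readers, so that a write
#' followed by a read round-trips field-identically.
#'
#' @param x The table to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plate_layout <- function(x, path) {
  readr::write_csv(x[c("plate_id", "well_id", "gene_symbol", "duplex_id", "role")], path)
  invisible(path)
}

#' @rdname write_plate_layout
#' @export
write_well_measurements <- function(x, path) {
  readr::write_csv(x[c("plate_id", "well_id", "image_index",
                       "dapi_count", "dapi_intensity", "ph3_count")], path)
  invisible(path)
}

#' @rdname write_plate_layout
#' @export
write_interaction_table <- function(x, path) {
  readr::write_tsv(x[c("source", "target", "relation")], path)
  invisible(path)
}

#' @rdname write_plate_layout
#' @export
write_annotation_table <- function(x, path) {
  readr::write_tsv(x[c("gene_symbol", "term_id", "term_name", "namespace")], path)
  invisible(path)
}

#' Read and write hit tables
#'
#' @param hits A hit table as produced by [call_hits()].
#' @param path CSV path.
#' @return For the writer, `path` invisibly; for the reader, a tibble.
#' @export
write_hit_table <- function(hits, path) {
  cols <- intersect(
    c("gene_symbol", "mi", "log2_mi", "zscore", "call", "group", "distance_in_mads"),
    names(hits)
  )
  readr::write_csv(hits[cols], path)
  invisible(path)
}

#' @rdname write_hit_table
#' @export
read_hit_table <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    gene_symbol = readr::col_character(),
    call = readr::col_character(),
    group = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  assert_columns(df, c("gene_symbol", "log2_mi", "zscore", "call", "group"), "hit table")
  df
}
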