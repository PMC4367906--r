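test_that("plate layouts read, validate roles, and reject duplicate wells", {
  sim <- tiny_screen()
  path <- withr::local_tempfile(fileext = ".csv")
  write_plate_layout(sim$layout, path)
  layout <- read_plate_layout(path)
  expect_equal(nrow(layout), nrow(sim$layout))
  expect_equal(sum(layout$role != "sample"), 2 * 3)  # 3 controls on each of 2 plates

  ## every gene appears in exactly 3 sample wells
  per_gene <- table(layout$gene_symbol[layout$role == "sample"])
  expect_true(all(per_gene == 3))

  dup <- rbind(layout, layout[1, ])
  expect_error(validate_plate_layout(dup), class = "mitoscreen_integrity_error")

  bad <- layout
  bad$gene_symbol[bad$role == "sample"][1] <- ""
  expect_error(validate_plate_layout(bad), class = "mitoscreen_integrity_error")

  expect_error(
    validate_plate_layout(layout[, setdiff(names(layout), "role")]),
    "role", class = "mitoscreen_schema_error"
  )
})

test_that("measurements join to the layout and unjoinable rows are reported", {
  sim <- tiny_screen()
  path <- withr::local_tempfile(fileext = ".csv")
  write_well_measurements(sim$measurements, path)
  rec <- read_well_measurements(path, sim$layout)
  expect_equal(nrow(rec), nrow(sim$layout) * 4)  # 4 images per well
  expect_equal(nrow(rejected_records(rec)), 0)

  ## an unknown well lands in the rejects report, not in the output
  extra <- sim$measurements[1, ]
  extra$well_id <- "Z99"
  expect_warning(
    rec2 <- validate_well_measurements(rbind(sim$measurements, extra), sim$layout),
    "rejected_records"
  )
  expect_equal(nrow(rec2), nrow(sim$measurements))
  expect_equal(nrow(rejected_records(rec2)), 1)
  expect_equal(rejected_records(rec2)$well_id, "Z99")
  ## conservation: accepted + rejected = input
  expect_equal(nrow(rec2) + nrow(rejected_records(rec2)), nrow(sim$measurements) + 1)

  neg <- sim$measurements
  neg$ph3_count[5] <- -1L
  expect_error(validate_well_measurements(neg, sim$layout),
               class = "mitoscreen_validation_error")
})

test_that("interaction tables parse both delimiters and police the vocabulary", {
  tab <- tibble::tibble(
    source = c("FER", "plk1", "A", "B", "C", "D", "E", "F", "G", "H"),
    target = c("EGFR", "BUB1", "X", "X", "X", "Y", "Y", "Z", "Z", "Q"),
    relation = rep(c("interacting", "interacting_phospho", "substrate",
                     "substrate_phospho", "interacting"), 2)
  )
  tsv <- withr::local_tempfile(fileext = ".tsv")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_interaction_table(tab, tsv)
  readr::write_csv(tab, csv)
  for (p in c(tsv, csv)) {
    got <- read_interaction_table(p)
    expect_equal(nrow(got), 10)
    expect_equal(got$relation_class[1], 1L)
    ## case-insensitive symbols stored uppercase
    expect_true("PLK1" %in% got$source)
    ## passthrough of a named record
    expect_true(any(got$source == "FER" & got$target == "EGFR" &
                      got$relation == "interacting"))
  }

  bad <- tab
  bad$relation[3] <- "binds"
  expect_error(validate_interaction_table(bad), "binds",
               class = "mitoscreen_vocabulary_error")

  loop <- tab
  loop$target[1] <- "FER"
  expect_error(validate_interaction_table(loop), class = "mitoscreen_integrity_error")
  expect_equal(nrow(validate_interaction_table(loop, allow_self_loops = TRUE)), 10)
})

test_that("annotation tables require a namespace and unique (gene, term) pairs", {
  ann <- tibble::tibble(
    gene_symbol = c("A", "B", "A"),
    term_id = c("T1", "T1", "T2"),
    term_name = c("term one", "term one", "term two"),
    namespace = "biological_process"
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_annotation_table(ann, path)
  expect_equal(nrow(read_annotation_table(path)), 3)

  expect_error(validate_annotation_table(rbind(ann, ann[1, ])),
               class = "mitoscreen_integrity_error")
  noname <- ann
  noname$namespace[2] <- ""
  expect_error(validate_annotation_table(noname), class = "mitoscreen_schema_error")
})

test_that("write then read round-trips every table field-identically", {
  sim <- tiny_screen()
  d <- withr::local_tempdir()

  write_plate_layout(sim$layout, file.path(d, "layout.csv"))
  back <- read_plate_layout(file.path(d, "layout.csv"))
  expect_equal(as.data.frame(back), as.data.frame(sim$layout))

  write_well_measurements(sim$measurements, file.path(d, "m.csv"))
  got <- read_well_measurements(file.path(d, "m.csv"), sim$layout)
  got <- got[names(sim$measurements)]
  attr(got, "rejects") <- NULL
  expect_equal(as.data.frame(got), as.data.frame(sim$measurements))

  gi <- generate_interactome(interactome_config(n_proteins = 50), seed = 1)
  write_interaction_table(gi$interactions, file.path(d, "i.tsv"))
  got_i <- read_interaction_table(file.path(d, "i.tsv"))
  expect_equal(as.data.frame(got_i[c("source", "target", "relation")]),
               as.data.frame(gi$interactions))

  scr <- normalize_screen(sim$measurements, sim$layout)
  hits <- call_hits(scr)
  write_hit_table(hits, file.path(d, "h.csv"))
  got_h <- read_hit_table(file.path(d, "h.csv"))
  expect_equal(got_h$gene_symbol, hits$gene_symbol)
  expect_equal(got_h$group, hits$group)
  expect_equal(got_h$log2_mi, hits$log2_mi, tolerance = 1e-12)
})
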