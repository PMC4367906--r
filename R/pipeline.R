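#' Configuration for an end-to-end synthetic run
#'
#' @param screen A [screen_config()] for the simulated screen.
#' @param interactome An [interactome_config()] for the simulated
#'   interactome.
#' @param stages Character vector of stages to run, in fixed order
#'   `simulate`, `normalize`, `hits`, `qc`, `enrich`, `network`; stages are
#'   linearly dependent, so each listed stage requires its predecessors.
#' @param k MAD multiplier for hit calling.
#' @param percentile,pseudocount,summary,mad_constant Passed to
#'   [normalize_screen()].
#' @param map_fraction Fraction of hit kinases mapped onto interactome
#'   backbone proteins (the remainder emulates hits not documented in the
#'   interaction database), default 0.75.
#' @param n_random_terms Uninformative annotation terms for the enrichment
#'   stage.
#' @param outdir Optional directory: when given, layout, measurements,
#'   normalized screen, hit table, enrichment and per-group graph files are
#'   written there.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(screen = screen_config(),
                            interactome = interactome_config(),
                            stages = c("simulate", "normalize", "hits",
                                       "qc", "enrich", "network"),
                            k = 2, percentile = 0.01, pseudocount = 0.5,
                            summary = "median", mad_constant = 1.4826,
                            map_fraction = 0.75, n_random_terms = 20,
                            outdir = NULL) {
  order <- c("simulate", "normalize", "hits", "qc", "enrich", "network")
  bad <- setdiff(stages, order)
  if (length(bad) > 0) {
    rlang::abort(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")),
                 class = "mitoscreen_config_error")
  }
  structure(
    list(screen = screen, interactome = interactome,
         stages = order[order %in% stages], k = k,
         percentile = percentile, pseudocount = pseudocount,
         summary = summary, mad_constant = mad_constant,
         map_fraction = map_fraction, n_random_terms = n_random_terms,
         outdir = outdir),
    class = "pipeline_config"
  )
}

report_row <- function(stage, metric, value) {
  tibble::tibble(stage = stage, metric = metric, value = value)
}

#' Run the screen-analysis pipeline end to end on synthetic data
#'
#' Executes the stages in fixed order: simulate a screen, normalize it,
#' call hits by the median +/- k*MAD rule, run control QC, compare term
#' annotation of the low and high groups (one informative term is planted
#' on the true high-MI genes, emulating a cell-division annotation), and
#' build and summarize the typed interaction network of each hit group.
#'
#' @param config A [pipeline_config()].
#' @param seed Integer seed; every stochastic stage derives its seed from
#'   it, so runs are fully reproducible.
#' @return A list of class `"pipeline_run"`: `report` (tibble of stage,
#'   metric, value), plus the stage outputs `truth`, `screen`, `hits`,
#'   `groups`, `qc`, `enrichment`, `networks`, `topology`, `modules`
#'   (entries present only for stages that ran).
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1) {
  stages <- config$stages
  out <- list(report = report_row(character(), character(), numeric()))
  class(out) <- "pipeline_run"
  if (length(stages) == 0) return(out)

  sim <- generate_screen(config$screen, seed = seed)
  out$truth <- sim$truth
  out$report <- dplyr::bind_rows(
    out$report,
    report_row("simulate", "n_layout_wells", nrow(sim$layout)),
    report_row("simulate", "n_measurements", nrow(sim$measurements))
  )
  if (!"normalize" %in% stages) return(finish_run(out, config))

  screen <- normalize_screen(
    sim$measurements, sim$layout,
    percentile = config$percentile, pseudocount = config$pseudocount,
    summary = config$summary, mad_constant = config$mad_constant
  )
  out$screen <- screen
  fc <- attr(screen, "filter_counts")
  out$report <- dplyr::bind_rows(
    out$report,
    report_row("normalize", "n_genes", nrow(screen)),
    report_row("normalize", "n_removed_low_dapi", unname(fc["low_dapi"])),
    report_row("normalize", "n_removed_inconsistent", unname(fc["inconsistent"]))
  )
  if (!"hits" %in% stages) return(finish_run(out, config))

  hits <- call_hits(screen, k = config$k, mad_constant = config$mad_constant)
  groups <- classify_groups(hits)
  out$hits <- hits
  out$groups <- groups
  out$report <- dplyr::bind_rows(
    out$report,
    report_row("hits", "n_hits", sum(hits$call == "hit")),
    report_row("hits", "n_low", length(groups$low)),
    report_row("hits", "n_high", length(groups$high))
  )

  if ("qc" %in% stages) {
    qc <- qc_controls(screen)
    out$qc <- qc
    out$report <- dplyr::bind_rows(
      out$report,
      report_row("qc", "n_plates", nrow(qc)),
      report_row("qc", "n_plates_failing", sum(!qc$pass))
    )
  }

  if ("enrich" %in% stages) {
    universe <- out$truth$gene_symbol
    ann <- generate_annotations(
      universe,
      planted = list(list(
        term_id = "TERM_DIVISION", term_name = "cell division-like process",
        genes = out$truth$gene_symbol[out$truth$group == "high"],
        background_rate = 0.02
      )),
      n_random_terms = config$n_random_terms,
      seed = seed + 1000L
    )
    cmp <- compare_lists(groups$low, groups$high, ann$annotations)
    out$enrichment <- cmp
    top <- if (nrow(cmp) > 0) cmp$term_id[1] else NA_character_
    out$report <- dplyr::bind_rows(
      out$report,
      report_row("enrich", "n_terms_tested", nrow(cmp)),
      report_row("enrich", "n_terms_significant", sum(cmp$adjusted_p < 0.05))
    )
    out$top_term <- top
  }

  if ("network" %in% stages) {
    inter <- generate_interactome(config$interactome, seed = seed + 2000L)
    tab <- map_hits_to_interactome(inter$interactions, groups,
                                   fraction = config$map_fraction,
                                   seed = seed + 3000L)
    nets <- list(
      low = build_network(tab, groups$low),
      high = build_network(tab, groups$high)
    )
    out$networks <- nets
    out$topology <- dplyr::bind_rows(
      dplyr::mutate(degree_stats(nets$low)$summary, group = "low"),
      dplyr::mutate(degree_stats(nets$high)$summary, group = "high")
    ) |> dplyr::relocate("group")
    out$modules <- lapply(nets, shared_neighbor_modules)
    out$report <- dplyr::bind_rows(
      out$report,
      report_row("network", "low_nodes", igraph::vcount(nets$low)),
      report_row("network", "low_edges", igraph::ecount(nets$low)),
      report_row("network", "low_unmapped_hits", length(unmapped_hits(nets$low))),
      report_row("network", "high_nodes", igraph::vcount(nets$high)),
      report_row("network", "high_edges", igraph::ecount(nets$high)),
      report_row("network", "high_unmapped_hits", length(unmapped_hits(nets$high)))
    )
  }

  finish_run(out, config, sim = sim)
}

## rename a sampled subset of backbone proteins to hit-kinase symbols so a
## realistic fraction of hits is documented in the interaction table
map_hits_to_interactome <- function(interactions, groups, fraction, seed) {
  hits <- c(groups$low, groups$high)
  with_local_seed(seed, {
    n_map <- round(fraction * length(hits))
    mapped <- sample(hits, n_map)
    backbone <- sort(unique(c(interactions$source, interactions$target)))
    backbone <- grep("^PROT", backbone, value = TRUE)
    targets <- sample(backbone, length(mapped))
    rename <- stats::setNames(mapped, targets)
    src <- interactions$source
    tgt <- interactions$target
    hit_src <- src %in% names(rename)
    hit_tgt <- tgt %in% names(rename)
    interactions$source[hit_src] <- rename[src[hit_src]]
    interactions$target[hit_tgt] <- rename[tgt[hit_tgt]]
    interactions
  })
}

finish_run <- function(out, config, sim = NULL) {
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$outdir, f)
    if (!is.null(sim)) {
      write_plate_layout(sim$layout, p("layout.csv"))
      write_well_measurements(sim$measurements, p("measurements.csv"))
      readr::write_csv(sim$truth, p("truth.csv"))
    }
    if (!is.null(out$screen)) {
      readr::write_csv(tibble::as_tibble(out$screen), p("normalized.csv"))
    }
    if (!is.null(out$hits)) write_hit_table(out$hits, p("hits.csv"))
    if (!is.null(out$enrichment)) {
      readr::write_csv(tibble::as_tibble(out$enrichment), p("enrichment.csv"))
    }
    if (!is.null(out$networks)) {
      write_typed_graph(out$networks$low, edgelist = p("network_low.tsv"))
      write_typed_graph(out$networks$high, edgelist = p("network_high.tsv"))
      readr::write_csv(out$topology, p("topology.csv"))
    }
    readr::write_csv(out$report, p("run_report.csv"))
  }
  out
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<mitoscreen pipeline run>\n")
  print(x$report, n = Inf)
  invisible(x)
}
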