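#' Build a typed first-neighbor interaction network around hit kinases
#'
#' Keeps every interaction record with at least one endpoint in the hit
#' list, together with the partner proteins, as an undirected graph. Each
#' edge carries exactly one of the four relation classes (interacting = 1,
#' interacting phosphoprotein = 2, substrate = 3, substrate and interacting
#' phosphoprotein = 4); substrate directionality is retained as an edge
#' attribute for display but the graph is undirected for topology.
#'
#' Duplicate records for the same unordered pair are collapsed; when the
#' duplicates disagree on the relation class the most informative class
#' wins, with precedence 4 > 2 > 3 > 1 (the higher classes subsume the
#' information of the lower), and the conflict is reported.
#'
#' @param interactions Interaction table (see [read_interaction_table()]).
#' @param hit_kinases Character vector of hit gene symbols (nonempty).
#' @return An [igraph][igraph::igraph-package] graph of class
#'   `c("typed_graph", "igraph")` with vertex attribute `is_hit_kinase` and
#'   edge attributes `relation`, `relation_class`, `from_source`.
#'   Attributes: `"unmapped_hits"` (hit kinases absent from the interaction
#'   table), `"n_conflicts"` (relation-class conflicts resolved) and
#'   `"n_records_raw"` (matching records before de-duplication).
#' @export
build_network <- function(interactions, hit_kinases) {
  interactions <- validate_interaction_table(interactions, allow_self_loops = TRUE)
  hit_kinases <- unique(as_gene_symbol(hit_kinases))
  if (length(hit_kinases) == 0) {
    rlang::abort("`hit_kinases` must be nonempty", class = "mitoscreen_validation_error")
  }
  keep <- interactions$source %in% hit_kinases | interactions$target %in% hit_kinases
  edges <- interactions[keep, , drop = FALSE]
  mapped <- hit_kinases[hit_kinases %in% c(edges$source, edges$target)]
  unmapped <- setdiff(hit_kinases, mapped)

  if (nrow(edges) == 0) {
    rlang::warn("no interaction touches a hit kinase; returning an empty graph")
    g <- igraph::make_empty_graph(0, directed = FALSE)
    class(g) <- c("typed_graph", class(g))
    attr(g, "unmapped_hits") <- unmapped
    attr(g, "n_conflicts") <- 0L
    attr(g, "n_records_raw") <- 0L
    return(g)
  }

  ## canonical unordered pair; precedence 4 > 2 > 3 > 1 on conflicts
  precedence <- c(`1` = 1L, `3` = 2L, `2` = 3L, `4` = 4L)
  edges$a <- pmin(edges$source, edges$target)
  edges$b <- pmax(edges$source, edges$target)
  dedup <- edges |>
    dplyr::mutate(.prec = precedence[as.character(.data$relation_class)]) |>
    dplyr::arrange(.data$a, .data$b, dplyr::desc(.data$.prec)) |>
    dplyr::group_by(.data$a, .data$b) |>
    dplyr::summarise(
      n_records = dplyr::n(),
      n_classes = dplyr::n_distinct(.data$relation_class),
      relation = .data$relation[1],
      relation_class = .data$relation_class[1],
      from_source = .data$source[1],
      .groups = "drop"
    )
  n_conflicts <- sum(dedup$n_classes > 1)
  if (n_conflicts > 0) {
    rlang::inform(sprintf(
      "%d interaction pair(s) had conflicting relation classes; kept the most informative",
      n_conflicts
    ))
  }

  nodes <- sort(unique(c(dedup$a, dedup$b)))
  g <- igraph::graph_from_data_frame(
    dedup[c("a", "b", "relation", "relation_class", "from_source")],
    directed = FALSE,
    vertices = data.frame(name = nodes, is_hit_kinase = nodes %in% hit_kinases)
  )
  class(g) <- c("typed_graph", class(g))
  attr(g, "unmapped_hits") <- unmapped
  attr(g, "n_conflicts") <- n_conflicts
  attr(g, "n_records_raw") <- nrow(edges)
  g
}

#' Edge table of a typed graph
#'
#' @param graph A `typed_graph` from [build_network()].
#' @return A tibble with columns `source`, `target`, `relation`,
#'   `relation_class` (canonical order: `source < target`, sorted).
#' @export
as_edge_tibble <- function(graph) {
  if (igraph::ecount(graph) == 0) {
    return(tibble::tibble(source = character(), target = character(),
                          relation = character(), relation_class = integer()))
  }
  el <- igraph::as_data_frame(graph, what = "edges")
  tibble::tibble(
    source = pmin(el$from, el$to),
    target = pmax(el$from, el$to),
    relation = el$relation,
    relation_class = as.integer(el$relation_class)
  ) |>
    dplyr::arrange(.data$source, .data$target)
}

#' Hit kinases absent from the interaction table
#'
#' @param graph A `typed_graph`.
#' @return Character vector of unmapped hit kinases.
#' @export
unmapped_hits <- function(graph) attr(graph, "unmapped_hits") %||% character()

#' Degree histogram and topology summary of a network
#'
#' @param graph A `typed_graph` (or any undirected igraph graph).
#' @param fit_gamma Also fit a power-law exponent to the degree sequence?
#'   Default `TRUE`; skipped silently when the fit is impossible
#'   (degenerate degrees).
#' @param ... Passed to [fit_power_law()].
#' @return A list with `histogram` (tibble `degree`, `n_nodes`) and
#'   `summary` (one-row tibble: `n_nodes`, `n_edges`, `n_components`,
#'   `mean_degree`, `clustering_coefficient`, `power_law_gamma`,
#'   `gamma_fit_method`, `n_hit_kinases_included`).
#' @export
degree_stats <- function(graph, fit_gamma = TRUE, ...) {
  n <- igraph::vcount(graph)
  if (n == 0) {
    return(list(
      histogram = tibble::tibble(degree = integer(), n_nodes = integer()),
      summary = tibble::tibble(
        n_nodes = 0L, n_edges = 0L, n_components = 0L, mean_degree = 0,
        clustering_coefficient = 0, power_law_gamma = NA_real_,
        gamma_fit_method = NA_character_, n_hit_kinases_included = 0L
      )
    ))
  }
  deg <- igraph::degree(graph)
  hist <- tibble::as_tibble(as.data.frame(table(degree = deg),
                                          stringsAsFactors = FALSE))
  hist$degree <- as.integer(hist$degree)
  names(hist)[2] <- "n_nodes"

  gamma <- NA_real_
  method <- NA_character_
  if (fit_gamma && n >= 2) {
    fit <- tryCatch(fit_power_law(deg, ...), error = function(e) NULL)
    if (!is.null(fit)) {
      gamma <- fit$gamma
      method <- fit$method
    }
  }
  hit_attr <- igraph::vertex_attr(graph, "is_hit_kinase")
  list(
    histogram = hist,
    summary = tibble::tibble(
      n_nodes = n,
      n_edges = igraph::ecount(graph),
      n_components = igraph::count_components(graph),
      mean_degree = 2 * igraph::ecount(graph) / n,
      clustering_coefficient = igraph::transitivity(graph, type = "global"),
      power_law_gamma = gamma,
      gamma_fit_method = method,
      n_hit_kinases_included = if (is.null(hit_attr)) NA_integer_ else sum(hit_attr)
    )
  )
}

#' Fit a power-law exponent to a degree sequence
#'
#' Scale-free networks have degree distributions `P(k) ~ k^-gamma`. The
#' exponent is estimated by discrete maximum likelihood on the tail
#' `k >= xmin`; when `xmin` is not supplied it is chosen by the
#' Kolmogorov-Smirnov minimization of Clauset et al. Two closed-form
#' diagnostics are reported alongside: the continuous MLE approximation
#' `1 + n / sum(log(k / (xmin - 0.5)))` (accurate only for large `xmin`)
#' and the slope of the log-log regression of the degree histogram.
#'
#' @param degrees Integer vector of node degrees (zeros are dropped).
#' @param xmin Smallest degree included in the fit; `NULL` (default) scans
#'   for it.
#' @return A list: `gamma`, `xmin`, `n_tail`, `ks_stat`, `method`,
#'   `gamma_continuous_approx`, `loglog_slope`.
#' @export
fit_power_law <- function(degrees, xmin = NULL) {
  degrees <- degrees[is.finite(degrees) & degrees >= 1]
  if (length(degrees) < 10) {
    rlang::abort("need >= 10 nonzero degrees to fit a power law",
                 class = "mitoscreen_validation_error")
  }
  if (length(unique(degrees)) == 1L) {
    rlang::abort("all degrees are equal; a power-law exponent is undefined",
                 class = "mitoscreen_degenerate_error")
  }
  fit <- igraph::fit_power_law(degrees, xmin = xmin %||% NULL,
                               implementation = "plfit")
  used_xmin <- fit$xmin
  tail_deg <- degrees[degrees >= used_xmin]

  approx_gamma <- 1 + length(tail_deg) / sum(log(tail_deg / (used_xmin - 0.5)))

  tab <- table(degrees)
  kk <- as.numeric(names(tab))
  pk <- as.numeric(tab) / length(degrees)
  slope <- if (length(kk) >= 3) {
    unname(stats::coef(stats::lm(log(pk) ~ log(kk)))[2])
  } else NA_real_

  list(
    gamma = fit$alpha,
    xmin = used_xmin,
    n_tail = length(tail_deg),
    ks_stat = fit$KS.stat,
    method = if (is.null(xmin)) "discrete MLE, KS-selected xmin" else
      sprintf("discrete MLE, xmin = %g", xmin),
    gamma_continuous_approx = approx_gamma,
    loglog_slope = slope
  )
}

#' Extract the module around seed proteins
#'
#' The induced subgraph on all nodes within `radius` hops of any seed
#' (the union ego network); `radius = 0` gives the induced subgraph on the
#' seeds themselves.
#'
#' @param graph A `typed_graph`.
#' @param seeds Character vector of node names; all must be in the graph.
#' @param radius Hop radius, default 1.
#' @return The induced subgraph, still a `typed_graph`.
#' @export
extract_module <- function(graph, seeds, radius = 1) {
  seeds <- as_gene_symbol(seeds)
  missing <- setdiff(seeds, igraph::V(graph)$name)
  if (length(missing) > 0) {
    rlang::abort(sprintf("seed(s) not in graph: %s", paste(missing, collapse = ", ")),
                 class = "mitoscreen_validation_error")
  }
  hood <- igraph::ego(graph, order = radius, nodes = seeds)
  keep <- unique(unlist(lapply(hood, as.integer)))
  sub <- igraph::induced_subgraph(graph, keep)
  class(sub) <- unique(c("typed_graph", class(sub)))
  attr(sub, "unmapped_hits") <- character()
  sub
}

#' Rank hit-kinase pairs by shared neighbors
#'
#' Operationalizes visual module spotting: two hit kinases that connect to
#' the same set of partner proteins form a candidate functional module
#' (e.g. two cytosolic kinases both wired to several growth-factor
#' receptors). Pairs are ranked by the number of shared non-hit neighbors,
#' ties broken alphabetically.
#'
#' @param graph A `typed_graph` with >= 2 hit kinases.
#' @param min_shared Minimum shared neighbors to report, default 2.
#' @return A tibble: `kinase_a`, `kinase_b` (alphabetical within pair),
#'   `n_shared`, `shared_neighbors` (list column), best pair first.
#' @export
shared_neighbor_modules <- function(graph, min_shared = 2) {
  hit_names <- igraph::V(graph)$name[igraph::V(graph)$is_hit_kinase]
  empty <- tibble::tibble(kinase_a = character(), kinase_b = character(),
                          n_shared = integer(), shared_neighbors = list())
  if (length(hit_names) < 2) return(empty)
  nbrs <- lapply(hit_names, function(v) {
    nb <- igraph::neighbors(graph, v)$name
    setdiff(nb, hit_names)
  })
  names(nbrs) <- hit_names
  pairs <- utils::combn(sort(hit_names), 2)
  shared <- lapply(seq_len(ncol(pairs)), function(i) {
    sort(intersect(nbrs[[pairs[1, i]]], nbrs[[pairs[2, i]]]))
  })
  out <- tibble::tibble(
    kinase_a = pairs[1, ],
    kinase_b = pairs[2, ],
    n_shared = lengths(shared),
    shared_neighbors = shared
  ) |>
    dplyr::filter(.data$n_shared >= min_shared) |>
    dplyr::arrange(dplyr::desc(.data$n_shared), .data$kinase_a, .data$kinase_b)
  out
}

#' Export a typed graph
#'
#' @param graph A `typed_graph`.
#' @param graphml Optional GraphML output path.
#' @param edgelist Optional edge-list TSV output path (columns `source`,
#'   `target`, `relation`, `relation_class`).
#' @return Invisibly, a character vector of the paths written.
#' @export
write_typed_graph <- function(graph, graphml = NULL, edgelist = NULL) {
  written <- character()
  if (!is.null(graphml)) {
    g <- graph
    class(g) <- "igraph"
    igraph::write_graph(g, graphml, format = "graphml")
    written <- c(written, graphml)
  }
  if (!is.null(edgelist)) {
    readr::write_tsv(as_edge_tibble(graph), edgelist)
    written <- c(written, edgelist)
  }
  invisible(written)
}
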