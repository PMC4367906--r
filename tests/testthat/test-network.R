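abc_table <- function() {
  tibble::tibble(
    source = c("A", "B"),
    target = c("B", "C"),
    relation = c("interacting", "substrate")
  )
}

test_that("networks keep only first-neighbor edges of hit kinases", {
  g1 <- build_network(abc_table(), "A")
  expect_equal(sort(igraph::V(g1)$name), c("A", "B"))
  expect_equal(igraph::ecount(g1), 1)

  g2 <- build_network(abc_table(), c("A", "C"))
  expect_equal(sort(igraph::V(g2)$name), c("A", "B", "C"))
  expect_equal(igraph::ecount(g2), 2)
  expect_equal(sum(igraph::V(g2)$is_hit_kinase), 2)

  expect_warning(g0 <- build_network(abc_table(), "ZZZ"), "empty graph")
  expect_equal(igraph::vcount(g0), 0)
  expect_equal(unmapped_hits(g0), "ZZZ")
})

test_that("duplicate pairs collapse by informativeness precedence 4 > 2 > 3 > 1", {
  tab <- tibble::tibble(
    source = c("A", "B", "A", "A", "A"),
    target = c("B", "A", "B", "C", "C"),
    relation = c("interacting", "substrate", "interacting_phospho",
                 "substrate", "substrate_phospho")
  )
  g <- build_network(tab, "A")
  edges <- as_edge_tibble(g)
  expect_equal(nrow(edges), 2)
  expect_equal(edges$relation[edges$target == "B"], "interacting_phospho")  # 2 beats 3, 1
  expect_equal(edges$relation[edges$target == "C"], "substrate_phospho")    # 4 beats 3
  expect_equal(attr(g, "n_conflicts"), 2L)
  expect_equal(attr(g, "n_records_raw"), 5L)

  ## edge conservation over the 4 classes
  expect_equal(sum(table(edges$relation_class)), igraph::ecount(g))
})

test_that("network construction is independent of input row order", {
  gi <- generate_interactome(interactome_config(n_proteins = 300), seed = 5)
  hits <- c("FER", "CRKL", sprintf("PROT%05d", c(3, 10, 50, 120)))
  g_fwd <- build_network(gi$interactions, hits)
  set.seed(1)
  g_rev <- build_network(gi$interactions[sample(nrow(gi$interactions)), ], hits)
  expect_equal(as_edge_tibble(g_fwd), as_edge_tibble(g_rev))
  expect_equal(sort(igraph::V(g_fwd)$name), sort(igraph::V(g_rev)$name))
})

test_that("mapped plus unmapped hits account for the whole hit list", {
  gi <- generate_interactome(interactome_config(n_proteins = 300), seed = 6)
  hits <- c(sprintf("PROT%05d", c(1, 2, 3)), "GHOST1", "GHOST2")
  g <- build_network(gi$interactions, hits)
  s <- degree_stats(g, fit_gamma = FALSE)$summary
  expect_equal(s$n_hit_kinases_included + length(unmapped_hits(g)), length(hits))
  expect_equal(sort(unmapped_hits(g)), c("GHOST1", "GHOST2"))
})

test_that("degree statistics summarize stars and empty graphs correctly", {
  star <- igraph::make_star(10, mode = "undirected", center = 1)
  igraph::V(star)$name <- paste0("N", 1:10)
  igraph::V(star)$is_hit_kinase <- c(TRUE, rep(FALSE, 9))
  ds <- degree_stats(star, fit_gamma = FALSE)
  expect_equal(ds$summary$mean_degree, 1.8)
  expect_equal(ds$histogram$n_nodes[ds$histogram$degree == 1], 9)
  expect_equal(ds$histogram$n_nodes[ds$histogram$degree == 9], 1)
  expect_equal(ds$summary$n_hit_kinases_included, 1)

  e <- degree_stats(igraph::make_empty_graph(0, directed = FALSE))
  expect_equal(e$summary$n_nodes, 0)
  expect_equal(e$summary$n_edges, 0)
})

test_that("power-law fits recover known exponents", {
  ## degrees drawn from P(k) ~ k^-3
  kmax <- 10000
  p <- (1:kmax)^-3
  set.seed(31)
  d <- sample.int(kmax, 5000, replace = TRUE, prob = p / sum(p))
  fit <- fit_power_law(d)
  expect_gt(fit$gamma, 2.8)
  expect_lt(fit$gamma, 3.2)

  ## preferential-attachment graph: asymptotic exponent 3
  set.seed(32)
  g <- igraph::sample_pa(2000, m = 2, directed = FALSE)
  fit_pa <- fit_power_law(igraph::degree(g))
  expect_gt(fit_pa$gamma, 2.5)
  expect_lt(fit_pa$gamma, 3.5)

  expect_error(fit_power_law(rep(4, 50)), class = "mitoscreen_degenerate_error")
  expect_error(fit_power_law(1:5), class = "mitoscreen_validation_error")
})

test_that("generator graphs have heavy-tailed degree distributions", {
  gi <- generate_interactome(interactome_config(), seed = 41)
  g <- igraph::graph_from_data_frame(gi$interactions[1:2], directed = FALSE)
  deg <- igraph::degree(g)
  expect_gte(max(deg), 5 * median(deg))
})

test_that("module extraction is the union ego network of the seeds", {
  gi <- generate_interactome(interactome_config(n_proteins = 200), seed = 10)
  g <- build_network(gi$interactions, c("FER", "CRKL"))
  m <- extract_module(g, c("FER", "CRKL"), radius = 1)
  expect_equal(sort(igraph::V(m)$name),
               sort(c("FER", "CRKL", "EGFR", "ERBB2", "ERBB3")))

  m0 <- extract_module(g, c("FER", "CRKL"), radius = 0)
  expect_equal(sort(igraph::V(m0)$name), c("CRKL", "FER"))

  expect_error(extract_module(g, "ABSENT"), "ABSENT",
               class = "mitoscreen_validation_error")

  ## radius-1 module of all hit kinases is the whole built network
  gi2 <- generate_interactome(interactome_config(n_proteins = 300), seed = 11)
  hits <- c("FER", "CRKL", sprintf("PROT%05d", c(5, 9, 77)))
  g2 <- build_network(gi2$interactions, hits)
  full <- extract_module(g2, intersect(hits, igraph::V(g2)$name), radius = 1)
  expect_equal(igraph::vcount(full), igraph::vcount(g2))
  expect_equal(igraph::ecount(full), igraph::ecount(g2))
})

test_that("isolated seeds stay in the module as isolates", {
  tab <- abc_table()
  g <- build_network(tab, c("A", "C"))
  ## C connects only to B; a radius-0 module keeps C as an isolate
  m <- extract_module(g, c("A", "C"), radius = 0)
  expect_true("C" %in% igraph::V(m)$name)
  expect_equal(igraph::degree(m, "C"), c(C = 0))
})

test_that("shared-neighbor ranking recovers the planted receptor module", {
  gi <- generate_interactome(interactome_config(n_proteins = 500), seed = 13)
  hits <- c("FER", "CRKL", sprintf("PROT%05d", c(150, 200, 250, 300, 350, 400)))
  g <- build_network(gi$interactions, hits)
  mods <- shared_neighbor_modules(g, min_shared = 2)
  expect_equal(mods$kinase_a[1], "CRKL")
  expect_equal(mods$kinase_b[1], "FER")
  expect_equal(mods$n_shared[1], 3)
  expect_equal(sort(mods$shared_neighbors[[1]]), c("EGFR", "ERBB2", "ERBB3"))

  ## triangle: A-C, B-C with hits A, B shares exactly {C}
  tri <- tibble::tibble(source = c("A", "B"), target = c("C", "C"),
                        relation = "interacting")
  gt <- build_network(tri, c("A", "B"))
  m1 <- shared_neighbor_modules(gt, min_shared = 1)
  expect_equal(m1$shared_neighbors[[1]], "C")

  ## two hits whose only common contact is itself a hit share nothing
  g0 <- build_network(abc_table(), c("A", "B"))
  expect_equal(nrow(shared_neighbor_modules(g0, min_shared = 1)), 0)
})

test_that("typed graphs export to GraphML and edge-list TSV", {
  g <- build_network(abc_table(), c("A", "C"))
  d <- withr::local_tempdir()
  write_typed_graph(g, graphml = file.path(d, "g.graphml"),
                    edgelist = file.path(d, "g.tsv"))
  expect_true(file.exists(file.path(d, "g.graphml")))
  back <- readr::read_tsv(file.path(d, "g.tsv"), show_col_types = FALSE)
  expect_equal(nrow(back), 2)
  expect_true(grepl("graphml", readLines(file.path(d, "g.graphml"), n = 2)[2]))
})
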