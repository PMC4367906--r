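#' Configuration for the synthetic screen generator
#'
#' Defaults mirror the screened library and assay scale: 714 kinase genes
#' covered by 3 siRNA duplexes each, plated on 96-well plates with internal
#' controls, 4 images per well averaging 700 cells per image, and a baseline
#' mitotic index of 5% for cycling cells. Planted hits multiply the
#' baseline MI: 41 low-MI genes at x0.2 and 50 high-MI genes at x3.
#'
#' @param n_genes Number of screened genes.
#' @param duplexes_per_gene siRNA duplexes per gene.
#' @param images_per_well Images acquired per well.
#' @param wells_per_plate Plate format (96).
#' @param mean_cells_per_image Expected nuclei per image.
#' @param baseline_mi Mitotic index of unperturbed cycling cells.
#' @param plate_effect_sd SD of the log-normal multiplicative plate effect
#'   applied to cell counts (seeding/staining variation), default 0.1.
#' @param count_noise `"poisson"` (default) or `"negbin"`.
#' @param negbin_dispersion Dispersion (`size = 1/dispersion`) when
#'   `count_noise = "negbin"`.
#' @param n_low_hits,low_effect Number of planted low-MI hits and their MI
#'   multiplier (< 1).
#' @param n_high_hits,high_effect Number of planted high-MI hits and their
#'   MI multiplier (> 1).
#' @param positive_control_effect MI multiplier of the Plk1-like positive
#'   control (mitotic arrest), default 4.
#' @param intensity_gain Arbitrary-unit gain linking DAPI intensity to the
#'   nucleus count.
#' @param intensity_noise_sd Log-normal noise SD on DAPI intensity.
#' @return A list of class `"screen_config"`.
#' @export
screen_config <- function(n_genes = 714, duplexes_per_gene = 3,
                          images_per_well = 4, wells_per_plate = 96,
                          mean_cells_per_image = 700, baseline_mi = 0.05,
                          plate_effect_sd = 0.1,
                          count_noise = c("poisson", "negbin"),
                          negbin_dispersion = 0.1,
                          n_low_hits = 41, low_effect = 0.2,
                          n_high_hits = 50, high_effect = 3,
                          positive_control_effect = 4,
                          intensity_gain = 10, intensity_noise_sd = 0.05) {
  count_noise <- match.arg(count_noise)
  if (n_low_hits + n_high_hits > n_genes) {
    rlang::abort("planted hits exceed the number of genes",
                 class = "mitoscreen_config_error")
  }
  if (baseline_mi <= 0 || baseline_mi >= 1) {
    rlang::abort("`baseline_mi` must be in (0, 1)", class = "mitoscreen_config_error")
  }
  if (low_effect <= 0 || high_effect <= 0) {
    rlang::abort("effect multipliers must be positive",
                 class = "mitoscreen_config_error")
  }
  structure(
    list(n_genes = n_genes, duplexes_per_gene = duplexes_per_gene,
         images_per_well = images_per_well, wells_per_plate = wells_per_plate,
         mean_cells_per_image = mean_cells_per_image, baseline_mi = baseline_mi,
         plate_effect_sd = plate_effect_sd, count_noise = count_noise,
         negbin_dispersion = negbin_dispersion,
         n_low_hits = n_low_hits, low_effect = low_effect,
         n_high_hits = n_high_hits, high_effect = high_effect,
         positive_control_effect = positive_control_effect,
         intensity_gain = intensity_gain, intensity_noise_sd = intensity_noise_sd),
    class = "screen_config"
  )
}

well_ids_96 <- function(n) {
  ids <- as.vector(t(outer(LETTERS[1:8], sprintf("%02d", 1:12), paste0)))
  ids[seq_len(n)]
}

rcount <- function(n, mu, config) {
  if (config$count_noise == "poisson") {
    stats::rpois(n, mu)
  } else {
    stats::rnbinom(n, size = 1 / config$negbin_dispersion, mu = mu)
  }
}

#' Generate a synthetic mitotic-index screen with known ground truth
#'
#' Lays the gene-by-duplex library out on 96-well plates (3 control wells
#' per plate: a Plk1-like positive, an untreated and a lipofectant-only
#' negative), then draws per-image counts: `dapi_count` from the count-noise
#' model around `mean_cells_per_image` times a log-normal per-plate effect,
#' `ph3_count` around `dapi_count` times the well's true MI, and
#' `dapi_intensity` proportional to `dapi_count` with log-normal noise.
#'
#' @param config A [screen_config()].
#' @param seed Integer seed; the output is a pure function of
#'   `(config, seed)`.
#' @return A list: `layout` (plate layout tibble), `measurements`
#'   (per-image tibble), `truth` (per-gene tibble with `mi_multiplier`,
#'   `true_mi` and `group`), `plate_effects`.
#' @export
generate_screen <- function(config = screen_config(), seed = 1) {
  with_local_seed(seed, {
    genes <- sprintf("KIN%04d", seq_len(config$n_genes))
    low <- genes[seq_len(config$n_low_hits)]
    high <- genes[config$n_low_hits + seq_len(config$n_high_hits)]
    ## shuffle so planted hits are spread across plates
    genes_shuffled <- sample(genes)

    multiplier <- stats::setNames(rep(1, config$n_genes), genes)
    multiplier[low] <- config$low_effect
    multiplier[high] <- config$high_effect
    truth <- tibble::tibble(
      gene_symbol = genes,
      mi_multiplier = unname(multiplier[genes]),
      true_mi = config$baseline_mi * unname(multiplier[genes]),
      group = dplyr::case_when(
        genes %in% low ~ "low",
        genes %in% high ~ "high",
        .default = "none"
      )
    )

    n_controls <- 3L
    samples_per_plate <- config$wells_per_plate - n_controls
    sample_units <- tidyr::expand_grid(
      gene_symbol = genes_shuffled,
      duplex_id = sprintf("D%d", seq_len(config$duplexes_per_gene))
    )
    n_plates <- ceiling(nrow(sample_units) / samples_per_plate)

    layout <- vector("list", n_plates)
    for (p in seq_len(n_plates)) {
      rows <- sample_units[((p - 1) * samples_per_plate + 1):
                             min(p * samples_per_plate, nrow(sample_units)), ]
      n_wells <- nrow(rows) + n_controls
      layout[[p]] <- tibble::tibble(
        plate_id = sprintf("P%02d", p),
        well_id = well_ids_96(n_wells),
        gene_symbol = c("", "", "", rows$gene_symbol),
        duplex_id = c("CTRL_PLK1", "CTRL_UNTREATED", "CTRL_LIPO", rows$duplex_id),
        role = c("positive_control", "negative_control_untreated",
                 "negative_control_lipo", rep("sample", nrow(rows)))
      )
    }
    layout <- dplyr::bind_rows(layout)

    plate_effects <- stats::setNames(
      exp(stats::rnorm(n_plates, 0, config$plate_effect_sd)),
      sprintf("P%02d", seq_len(n_plates))
    )

    per_image <- layout[rep(seq_len(nrow(layout)), each = config$images_per_well), ]
    per_image$image_index <- rep(seq_len(config$images_per_well), nrow(layout))
    true_mi_of <- function(role, gene) {
      dplyr::case_when(
        role == "positive_control" ~ config$baseline_mi * config$positive_control_effect,
        role %in% c("negative_control_untreated", "negative_control_lipo") ~
          config$baseline_mi,
        .default = config$baseline_mi * unname(multiplier[gene])
      )
    }
    mi_true <- true_mi_of(per_image$role, per_image$gene_symbol)
    pe <- plate_effects[per_image$plate_id]
    dapi <- rcount(nrow(per_image), config$mean_cells_per_image * pe, config)
    ph3 <- rcount(nrow(per_image), pmax(dapi, 1) * mi_true, config)
    intensity <- dapi * config$intensity_gain *
      exp(stats::rnorm(nrow(per_image), 0, config$intensity_noise_sd))

    measurements <- tibble::tibble(
      plate_id = per_image$plate_id,
      well_id = per_image$well_id,
      image_index = per_image$image_index,
      dapi_count = as.integer(dapi),
      dapi_intensity = intensity,
      ph3_count = as.integer(ph3)
    )
    list(layout = layout, measurements = measurements, truth = truth,
         plate_effects = plate_effects)
  })
}

#' Generate a two-channel fluorescence image pair with planted objects
#'
#' Nuclei are Gaussian spots placed on a jittered grid (no overlap by
#' construction) over a smooth uneven illumination field; a random subset
#' of size `n_mitotic` is lit in the pH3 channel at the same centroids.
#'
#' @param n_nuclei,n_mitotic Planted object counts (`n_mitotic <= n_nuclei`).
#' @param shape Image dimensions in pixels, default `c(192, 192)`.
#' @param seed Integer seed.
#' @param spot_sigma Gaussian spot SD in pixels.
#' @param spot_amplitude Peak spot intensity above background.
#' @param illumination_amplitude Peak-to-trough amplitude of the smooth
#'   background field.
#' @return A list: `dapi`, `ph3` (matrices) and `truth` (tibble of planted
#'   centroids with a logical `mitotic` column).
#' @export
generate_image_pair <- function(n_nuclei, n_mitotic, shape = c(192, 192),
                                seed = 1, spot_sigma = 2.2,
                                spot_amplitude = 0.7,
                                illumination_amplitude = 0.12) {
  if (n_mitotic > n_nuclei) {
    rlang::abort("`n_mitotic` cannot exceed `n_nuclei`",
                 class = "mitoscreen_config_error")
  }
  cell <- 16L
  nx <- shape[1] %/% cell
  ny <- shape[2] %/% cell
  if (n_nuclei > nx * ny) {
    rlang::abort(sprintf(
      "cannot place %d non-overlapping nuclei on a %dx%d image (capacity %d)",
      n_nuclei, shape[1], shape[2], nx * ny
    ), class = "mitoscreen_placement_error")
  }
  with_local_seed(seed, {
    ## smooth illumination field: tilted plane plus a broad lobe
    xg <- seq_len(shape[1])
    yg <- seq_len(shape[2])
    field <- outer(xg / shape[1], yg / shape[2], function(u, v) {
      0.5 * u + 0.3 * v + 0.4 * sin(pi * u) * sin(pi * v)
    })
    field <- illumination_amplitude * field / max(field)
    dapi <- field
    ph3 <- 0.6 * field

    truth <- tibble::tibble(x = double(), y = double(), mitotic = logical())
    if (n_nuclei > 0) {
      cells <- sample.int(nx * ny, n_nuclei)
      cx <- ((cells - 1) %% nx) * cell + cell / 2 +
        stats::runif(n_nuclei, -3, 3)
      cy <- ((cells - 1) %/% nx) * cell + cell / 2 +
        stats::runif(n_nuclei, -3, 3)
      mitotic <- rep(FALSE, n_nuclei)
      mitotic[sample.int(n_nuclei, n_mitotic)] <- TRUE

      add_spot <- function(img, x0, y0, amp) {
        r <- ceiling(4 * spot_sigma)
        xs <- max(1, round(x0) - r):min(shape[1], round(x0) + r)
        ys <- max(1, round(y0) - r):min(shape[2], round(y0) + r)
        g <- outer(xs, ys, function(i, j) {
          amp * exp(-((i - x0)^2 + (j - y0)^2) / (2 * spot_sigma^2))
        })
        img[xs, ys] <- img[xs, ys] + g
        img
      }
      for (i in seq_len(n_nuclei)) {
        dapi <- add_spot(dapi, cx[i], cy[i], spot_amplitude)
        if (mitotic[i]) ph3 <- add_spot(ph3, cx[i], cy[i], spot_amplitude)
      }
      truth <- tibble::tibble(x = cx, y = cy, mitotic = mitotic)
    }
    list(dapi = dapi, ph3 = ph3, truth = truth)
  })
}

#' Configuration for the synthetic interactome generator
#'
#' @param n_proteins Backbone size (preferential attachment).
#' @param attachment_m Edges added per new node (>= 1).
#' @param relation_mix Probabilities of the four relation classes
#'   (`interacting`, `interacting_phospho`, `substrate`,
#'   `substrate_phospho`), summing to 1.
#' @param planted_modules List of modules, each a list with `seeds`
#'   (character) and `partners` (character): every seed is wired to every
#'   partner with an `interacting` edge. Planted proteins are named nodes
#'   appended to the backbone.
#' @return A list of class `"interactome_config"`.
#' @export
interactome_config <- function(n_proteins = 2000, attachment_m = 2,
                               relation_mix = c(interacting = 0.55,
                                                interacting_phospho = 0.20,
                                                substrate = 0.15,
                                                substrate_phospho = 0.10),
                               planted_modules = list(
                                 list(seeds = c("FER", "CRKL"),
                                      partners = c("EGFR", "ERBB2", "ERBB3"))
                               )) {
  if (attachment_m < 1) {
    rlang::abort("`attachment_m` must be >= 1", class = "mitoscreen_config_error")
  }
  if (length(relation_mix) != 4 || abs(sum(relation_mix) - 1) > 1e-9) {
    rlang::abort("`relation_mix` must be 4 probabilities summing to 1",
                 class = "mitoscreen_config_error")
  }
  planted_names <- unique(unlist(lapply(planted_modules,
                                        function(m) c(m$seeds, m$partners))))
  if (any(grepl("^PROT[0-9]+$", planted_names))) {
    idx <- as.integer(sub("^PROT", "", grep("^PROT[0-9]+$", planted_names, value = TRUE)))
    if (any(idx > n_proteins)) {
      rlang::abort("planted module references a backbone protein beyond n_proteins",
                   class = "mitoscreen_config_error")
    }
  }
  structure(
    list(n_proteins = n_proteins, attachment_m = attachment_m,
         relation_mix = relation_mix, planted_modules = planted_modules),
    class = "interactome_config"
  )
}

#' Generate a scale-free typed interactome with planted modules
#'
#' The backbone is an undirected preferential-attachment graph
#' (`n_proteins` nodes, `attachment_m` edges per new node), which has a
#' power-law degree distribution with asymptotic exponent 3. Each backbone
#' edge draws its relation class from `relation_mix`; planted modules are
#' appended as named proteins wired exactly as configured.
#'
#' @param config An [interactome_config()].
#' @param seed Integer seed.
#' @return A list: `interactions` (tibble `source`, `target`, `relation`)
#'   and `truth` (backbone edge count, planted module list).
#' @export
generate_interactome <- function(config = interactome_config(), seed = 1) {
  with_local_seed(seed, {
    g <- igraph::sample_pa(config$n_proteins, power = 1, m = config$attachment_m,
                           directed = FALSE)
    el <- igraph::as_edgelist(g, names = FALSE)
    backbone <- tibble::tibble(
      source = sprintf("PROT%05d", el[, 1]),
      target = sprintf("PROT%05d", el[, 2]),
      relation = sample(names(RELATION_LEVELS), nrow(el), replace = TRUE,
                        prob = config$relation_mix)
    )
    planted <- dplyr::bind_rows(lapply(config$planted_modules, function(m) {
      tidyr::expand_grid(source = as_gene_symbol(m$seeds),
                         target = as_gene_symbol(m$partners)) |>
        dplyr::mutate(relation = "interacting")
    }))
    interactions <- dplyr::bind_rows(backbone, planted)
    list(
      interactions = interactions,
      truth = list(n_backbone_edges = nrow(backbone),
                   planted_modules = config$planted_modules)
    )
  })
}

#' Generate a flat annotation table with planted enrichment signal
#'
#' Each planted term annotates its configured gene subset fully, plus
#' background genes at the given rate; additional random terms annotate
#' uniformly sampled genes and carry no signal.
#'
#' @param universe Character vector of gene symbols.
#' @param planted List of terms, each a list with `term_id`, `genes`
#'   (subset of `universe`) and `background_rate` in `[0, 1]`.
#' @param n_random_terms Number of uninformative terms, default 20.
#' @param random_term_size Size range of random terms, default `c(10, 50)`
#'   (capped at the universe size).
#' @param seed Integer seed.
#' @return A list: `annotations` (tibble) and `truth` (the planted list).
#' @export
generate_annotations <- function(universe, planted = list(),
                                 n_random_terms = 20,
                                 random_term_size = c(10, 50), seed = 1) {
  universe <- unique(as_gene_symbol(universe))
  for (p in planted) {
    if (!all(as_gene_symbol(p$genes) %in% universe)) {
      rlang::abort("planted term genes must be inside the universe",
                   class = "mitoscreen_config_error")
    }
  }
  with_local_seed(seed, {
    rows <- list()
    for (p in planted) {
      genes <- as_gene_symbol(p$genes)
      rate <- p$background_rate %||% 0
      bg_pool <- setdiff(universe, genes)
      bg <- bg_pool[stats::runif(length(bg_pool)) < rate]
      rows[[length(rows) + 1]] <- tibble::tibble(
        gene_symbol = c(genes, bg),
        term_id = p$term_id,
        term_name = p$term_name %||% p$term_id,
        namespace = p$namespace %||% "biological_process"
      )
    }
    lo <- min(random_term_size[1], length(universe))
    hi <- min(random_term_size[2], length(universe))
    for (i in seq_len(n_random_terms)) {
      size <- sample(seq(lo, hi), 1)
      rows[[length(rows) + 1]] <- tibble::tibble(
        gene_symbol = sample(universe, size),
        term_id = sprintf("RND%04d", i),
        term_name = sprintf("random term %d", i),
        namespace = "biological_process"
      )
    }
    annotations <- dplyr::bind_rows(rows)
    annotations <- annotations[!duplicated(annotations[c("gene_symbol", "term_id")]), ]
    list(annotations = tibble::as_tibble(annotations), truth = planted)
  })
}
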