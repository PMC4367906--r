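#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of
#' observing at least `k` annotated genes in a list of size `n` drawn
#' without replacement from a universe of `N` genes of which `K` carry the
#' annotation. Computed in log space via the cumulative distribution for
#' numerical stability at small p.
#'
#' @param k Observed annotated genes in the list.
#' @param n List size.
#' @param K Annotated genes in the universe.
#' @param N Universe size.
#' @return The tail probability, a number in (0, 1].
#' @export
hypergeom_tail <- function(k, n, K, N) {
  vals <- c(k = k, n = n, K = K, N = N)
  if (any(vals < 0) || any(vals != floor(vals))) {
    rlang::abort("k, n, K, N must be nonnegative integers",
                 class = "mitoscreen_validation_error")
  }
  if (k > n || n > N || k > K || K > N) {
    rlang::abort("inconsistent counts: need k <= n <= N and k <= K <= N",
                 class = "mitoscreen_validation_error")
  }
  if (k == 0) return(1)
  exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Term enrichment of a gene list by the hypergeometric test
#'
#' For every annotation term with at least `min_term_size` genes in the
#' universe, tests whether the list contains more annotated genes than
#' expected under sampling without replacement, and adjusts p-values with
#' Benjamini-Hochberg across the tested terms.
#'
#' @param genes Character vector of list genes (must all be in `universe`).
#' @param universe Character vector: the reference gene set. For hit groups
#'   from a focused screen the screened panel, not the genome, is the
#'   appropriate universe.
#' @param annotations Annotation table (see [read_annotation_table()]);
#'   rows for genes outside the universe are ignored.
#' @param min_term_size Minimum universe genes per tested term, default 3.
#' @return A tibble of class `"enrich_result"`, one row per tested term:
#'   `term_id`, `term_name`, `namespace`, `k`, `n`, `K`, `N`, `p_value`,
#'   `adjusted_p`, ordered by `p_value`.
#' @export
enrich_list <- function(genes, universe, annotations, min_term_size = 3) {
  genes <- unique(as_gene_symbol(genes))
  universe <- unique(as_gene_symbol(universe))
  outside <- setdiff(genes, universe)
  if (length(outside) > 0) {
    rlang::abort(sprintf("list gene(s) absent from the universe: %s",
                         paste(outside, collapse = ", ")),
                 class = "mitoscreen_validation_error")
  }
  annotations <- validate_annotation_table(annotations)
  ann <- annotations[annotations$gene_symbol %in% universe, , drop = FALSE]
  empty <- tibble::new_tibble(
    tibble::tibble(term_id = character(), term_name = character(),
                   namespace = character(), k = integer(), n = integer(),
                   K = integer(), N = integer(),
                   p_value = double(), adjusted_p = double()),
    class = "enrich_result"
  )
  if (nrow(ann) == 0) return(empty)

  n_universe <- length(universe)
  n_list <- length(genes)
  res <- ann |>
    dplyr::group_by(.data$term_id, .data$term_name, .data$namespace) |>
    dplyr::summarise(
      K = dplyr::n(),
      k = sum(.data$gene_symbol %in% genes),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$K >= min_term_size) |>
    dplyr::mutate(n = n_list, N = n_universe)
  if (nrow(res) == 0) return(empty)
  res$p_value <- purrr::pmap_dbl(res[c("k", "n", "K", "N")],
                                 function(k, n, K, N) hypergeom_tail(k, n, K, N))
  res$adjusted_p <- stats::p.adjust(res$p_value, method = "BH")
  res <- dplyr::arrange(res, .data$p_value, .data$term_id) |>
    dplyr::relocate("k", "n", "K", "N", .after = "namespace")
  tibble::new_tibble(res, class = "enrich_result",
                     n_list = n_list, n_universe = n_universe,
                     min_term_size = min_term_size)
}

#' Compare term annotation between two gene lists
#'
#' For every term, builds the 2x2 table of annotated/unannotated genes in
#' list A versus list B and applies a two-sided Fisher exact test; the
#' direction records which list carries the higher annotated fraction.
#' Used to contrast the low- and high-mitotic-index hit groups.
#'
#' @param list_a,list_b Disjoint character vectors of gene symbols.
#' @param annotations Annotation table.
#' @param min_term_size Minimum annotated genes (across both lists) per
#'   tested term, default 1.
#' @return A tibble of class `"enrich_result"`: per term `k_a`, `k_b`
#'   (annotated in each list), `n_a`, `n_b`, `p_value`, `adjusted_p` and
#'   `direction` (`"A"`, `"B"` or `"tie"`).
#' @export
compare_lists <- function(list_a, list_b, annotations, min_term_size = 1) {
  list_a <- unique(as_gene_symbol(list_a))
  list_b <- unique(as_gene_symbol(list_b))
  overlap <- intersect(list_a, list_b)
  if (length(overlap) > 0) {
    rlang::abort(sprintf("lists overlap: %s", paste(overlap, collapse = ", ")),
                 class = "mitoscreen_validation_error")
  }
  annotations <- validate_annotation_table(annotations)
  ann <- annotations[annotations$gene_symbol %in% c(list_a, list_b), , drop = FALSE]
  n_a <- length(list_a)
  n_b <- length(list_b)
  res <- ann |>
    dplyr::group_by(.data$term_id, .data$term_name, .data$namespace) |>
    dplyr::summarise(
      k_a = sum(.data$gene_symbol %in% list_a),
      k_b = sum(.data$gene_symbol %in% list_b),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$k_a + .data$k_b >= min_term_size) |>
    dplyr::mutate(n_a = n_a, n_b = n_b)
  if (nrow(res) == 0) {
    return(tibble::new_tibble(
      tibble::tibble(term_id = character(), term_name = character(),
                     namespace = character(), k_a = integer(), k_b = integer(),
                     n_a = integer(), n_b = integer(), p_value = double(),
                     adjusted_p = double(), direction = character()),
      class = "enrich_result"
    ))
  }
  res$p_value <- purrr::pmap_dbl(
    res[c("k_a", "k_b")],
    function(k_a, k_b) {
      tab <- matrix(c(k_a, n_a - k_a, k_b, n_b - k_b), nrow = 2)
      stats::fisher.test(tab, alternative = "two.sided")$p.value
    }
  )
  frac_a <- res$k_a / n_a
  frac_b <- res$k_b / n_b
  res$direction <- dplyr::case_when(
    frac_a > frac_b ~ "A",
    frac_b > frac_a ~ "B",
    .default = "tie"
  )
  res$adjusted_p <- stats::p.adjust(res$p_value, method = "BH")
  res <- dplyr::arrange(res, .data$p_value, .data$term_id) |>
    dplyr::relocate("adjusted_p", .after = "p_value")
  tibble::new_tibble(res, class = "enrich_result", n_list = n_a, n_list_b = n_b)
}
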