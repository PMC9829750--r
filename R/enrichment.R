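#' Annotate CpGs with functional categories and gene links
#'
#' Assigns every CpG the categories of all intervals it overlaps (promoter,
#' gene body, enhancer; CpG island, shore, shelf; transposon classes) plus
#' pathway membership through its gene links, and `open_sea` as the
#' complement of the island/shore/shelf tiling. Interval inputs are 0-based
#' half-open (BED); CpG positions are 1-based, converted at this boundary.
#' A CpG may carry several gene-linked categories at once; island-context
#' categories are mutually exclusive (island takes precedence over shore,
#' shore over shelf, where user-supplied intervals overlap).
#'
#' @param cpgs Tibble of CpGs (columns `cpg_id`, `chrom`, `pos`), e.g. one
#'   pair profile.
#' @param annotations A `methpair_annotations` object (see
#'   [simulate_annotations()]) or a list with tibbles `regions`, `islands`,
#'   `transposons`, `pathways` of the same shape.
#' @return A list of class `methpair_annotated`: `categories` (tibble
#'   `cpg_id`, `category`) and `gene_links` (tibble `cpg_id`, `gene`,
#'   `region`).
#' @export
annotate_cpgs <- function(cpgs, annotations) {
  need <- c("cpg_id", "chrom", "pos")
  if (!all(need %in% names(cpgs)))
    abort("`cpgs` must have columns cpg_id, chrom, pos.")
  cpgs <- as_tibble(cpgs[, need])

  hits_r <- interval_overlap(cpgs, annotations$regions)
  gene_links <- tibble(
    cpg_id = cpgs$cpg_id[hits_r$cpg_row],
    gene = annotations$regions$gene[hits_r$interval_row],
    region = annotations$regions$type[hits_r$interval_row]) |>
    dplyr::distinct()

  cat_region <- tibble(cpg_id = gene_links$cpg_id,
                       category = gene_links$region) |>
    dplyr::distinct()

  hits_i <- interval_overlap(cpgs, annotations$islands)
  island_hit <- tibble(
    cpg_id = cpgs$cpg_id[hits_i$cpg_row],
    context = annotations$islands$context[hits_i$interval_row]) |>
    dplyr::mutate(rank = match(.data$context, c("island", "shore", "shelf"))) |>
    dplyr::group_by(.data$cpg_id) |>
    dplyr::slice_min(.data$rank, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  cat_island <- dplyr::bind_rows(
    tibble(cpg_id = island_hit$cpg_id, category = island_hit$context),
    tibble(cpg_id = setdiff(cpgs$cpg_id, island_hit$cpg_id),
           category = "open_sea"))

  hits_t <- interval_overlap(cpgs, annotations$transposons)
  cat_tx <- tibble(
    cpg_id = cpgs$cpg_id[hits_t$cpg_row],
    category = annotations$transposons$class[hits_t$interval_row]) |>
    dplyr::distinct()

  cat_pw <- dplyr::inner_join(gene_links[, c("cpg_id", "gene")],
                              annotations$pathways, by = "gene",
                              relationship = "many-to-many") |>
    dplyr::transmute(cpg_id = .data$cpg_id, category = .data$pathway) |>
    dplyr::distinct()

  structure(
    list(categories = dplyr::bind_rows(cat_region, cat_island, cat_tx, cat_pw),
         gene_links = gene_links),
    class = "methpair_annotated")
}

#' One-sided Fisher enrichment of a category in altered CpGs
#'
#' Tests overrepresentation of CpGs called in the given direction among the
#' CpGs of a category, against the background of all measured CpGs of the
#' pair, with a one-sided (greater) Fisher exact test on the 2x2 table
#' (altered-in-category, altered-outside, unaltered-in-category,
#' unaltered-outside).
#'
#' @param calls State calls for one pair ([posterior_decode()] output).
#' @param annotated [annotate_cpgs()] output covering the pair's CpGs.
#' @param direction `"decreased"` or `"increased"`.
#' @param category Category name present in the annotation.
#' @return A one-row tibble: `direction`, `category`, counts `a`, `b`, `c`,
#'   `d` (2x2 in row order altered/unaltered x in/out), `p_value`.
#' @export
fisher_enrichment <- function(calls, annotated, direction, category) {
  direction <- match.arg(direction, c("decreased", "increased"))
  cats <- annotated$categories
  if (!category %in% cats$category)
    abort(sprintf("Category '%s' absent from the annotation.", category))
  if (nrow(calls) < 1) abort("No measured CpGs.")
  target_state <- if (direction == "decreased") "-" else "+"
  in_cat <- calls$cpg_id %in% cats$cpg_id[cats$category == category]
  altered <- calls$state == target_state
  a <- sum(altered & in_cat); b <- sum(altered & !in_cat)
  cc <- sum(!altered & in_cat); d <- sum(!altered & !in_cat)
  p <- fisher.test(matrix(c(a, cc, b, d), nrow = 2),
                   alternative = "greater")$p.value
  tibble(direction = direction, category = category,
         a = a, b = b, c = cc, d = d, p_value = p)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values, capped at 1 and monotone in the p-value ranks.
#' Input order is preserved.
#'
#' @param p Numeric p-values in (0, 1].
#' @return Adjusted q-values, same length and order as `p`.
#' @export
#' @examples
#' adjust_fdr(c(0.01, 0.02, 0.03))
adjust_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    abort("p-values must lie in (0, 1].")
  p.adjust(p, method = "BH")
}

#' Enrichment of all categories across all pairs and directions
#'
#' Runs [fisher_enrichment()] for every pair x direction x category and
#' adjusts for multiple testing within each pair-and-panel family (panels:
#' gene regions, island context, transposons, pathways), flagging
#' `q < alpha` as significant.
#'
#' @param calls_by_pair Named list of per-pair state-call tibbles, or one
#'   tibble with a `pair_id` column.
#' @param annotated [annotate_cpgs()] output (shared CpG universe), or a
#'   named list of per-pair annotations.
#' @param categories Character vector of categories to test; default all in
#'   the annotation.
#' @param directions Directions to test.
#' @param alpha Significance cutoff on the FDR-adjusted q-value.
#' @return A tibble of class `methpair_enrichment`: `pair_id`, `direction`,
#'   `category`, `panel`, counts, `p_value`, `q_value`, `significant`.
#' @export
enrichment_matrix <- function(calls_by_pair, annotated, categories = NULL,
                              directions = c("decreased", "increased"),
                              alpha = 0.05) {
  if (is.data.frame(calls_by_pair))
    calls_by_pair <- split(calls_by_pair, calls_by_pair$pair_id)
  per_pair_annot <- !inherits(annotated, "methpair_annotated")
  first_annot <- if (per_pair_annot) annotated[[1]] else annotated
  categories <- categories %||% unique(first_annot$categories$category)

  res <- purrr::imap_dfr(calls_by_pair, function(calls, pid) {
    ann <- if (per_pair_annot) annotated[[pid]] else annotated
    purrr::map_dfr(directions, function(dir) {
      purrr::map_dfr(categories, function(cat)
        fisher_enrichment(calls, ann, dir, cat))
    }) |>
      dplyr::mutate(pair_id = pid, .before = 1)
  })

  res$panel <- category_panel(res$category)
  res <- res |>
    dplyr::group_by(.data$pair_id, .data$panel) |>
    dplyr::mutate(q_value = adjust_fdr(.data$p_value)) |>
    dplyr::ungroup() |>
    dplyr::mutate(significant = .data$q_value < alpha)
  class(res) <- c("methpair_enrichment", class(res))
  res
}

category_panel <- function(category) {
  dplyr::case_when(
    category %in% c("promoter", "gene_body", "enhancer") ~ "gene_region",
    category %in% c("island", "shore", "shelf", "open_sea") ~ "island_context",
    category %in% c("LTR", "LINE", "DNA") ~ "transposon",
    TRUE ~ "pathway")
}

#' Plot an enrichment matrix
#'
#' Tile plot of pairs x categories, filled by -log10(q), with significant
#' cells marked by a cross, in the style of per-pair enrichment overviews.
#'
#' @param object A `methpair_enrichment` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.methpair_enrichment <- function(object, ...) {
  df <- as_tibble(object)
  df$mlq <- -log10(pmax(df$q_value, 1e-16))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pair_id, y = .data$category)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$mlq)) +
    ggplot2::geom_point(data = df[df$significant, ], shape = 4,
                        colour = "red", size = 2) +
    ggplot2::facet_grid(panel ~ direction, scales = "free_y",
                        space = "free_y") +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 name = "-log10(q)") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
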