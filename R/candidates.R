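#' Majority-vote consensus of a patient's pairs
#'
#' Collapses multiple metastases pairs of one patient to a single per-CpG
#' consensus state: `"-"` when strictly more pairs call decreased than
#' increased, `"+"` for the opposite, and `"="` otherwise - ties between
#' decreased and increased votes are considered unchanged, which excludes
#' non-decidable CpGs from the downstream ranking. CpGs missing from some
#' pairs are voted over the pairs in which they are present.
#'
#' @param calls State calls for one or more patients: a tibble with columns
#'   `patient_id`, `pair_id`, `cpg_id`, `state` (e.g. row-bound
#'   [posterior_decode()] outputs joined with pair metadata).
#' @return A tibble `patient_id`, `cpg_id`, `state` with one consensus row
#'   per (patient, CpG).
#' @export
#' @examples
#' calls <- tibble::tibble(patient_id = "P01",
#'                         pair_id = c("a", "b", "c"),
#'                         cpg_id = "cg1", state = c("-", "-", "+"))
#' patient_consensus(calls)  # "-"
patient_consensus <- function(calls) {
  need <- c("patient_id", "pair_id", "cpg_id", "state")
  if (!all(need %in% names(calls)))
    abort("`calls` needs columns patient_id, pair_id, cpg_id, state.")
  calls |>
    dplyr::group_by(.data$patient_id, .data$cpg_id) |>
    dplyr::summarise(n_dec = sum(.data$state == "-"),
                     n_inc = sum(.data$state == "+"), .groups = "drop") |>
    dplyr::mutate(state = dplyr::case_when(
      .data$n_dec > .data$n_inc ~ "-",
      .data$n_inc > .data$n_dec ~ "+",
      TRUE ~ "=")) |>
    dplyr::select("patient_id", "cpg_id", "state")
}

#' Rank CpGs by cross-patient alteration recurrence
#'
#' Counts, per CpG, the number of patients whose consensus state is
#' decreased and increased respectively; each patient contributes at most
#' one vote per direction.
#'
#' @param consensus [patient_consensus()] output across all patients.
#' @return A tibble `cpg_id`, `n_decreased`, `n_increased`, sorted by the
#'   larger of the two counts, descending.
#' @export
rank_cpgs <- function(consensus) {
  if (nrow(consensus) == 0) abort("Empty consensus table.")
  consensus |>
    dplyr::group_by(.data$cpg_id) |>
    dplyr::summarise(n_decreased = sum(.data$state == "-"),
                     n_increased = sum(.data$state == "+"),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(pmax(.data$n_decreased, .data$n_increased)),
                   .data$cpg_id)
}

#' Select candidate genes from the CpG ranking
#'
#' A gene enters the candidate set for a direction when at least one of its
#' linked CpGs (links restricted to promoter, enhancer and gene-body
#' regions) reaches the patient-count threshold in that direction - the
#' "altered in more than 50% of patients" rule at its reference setting of
#' `min_patients = 8` of 14. A CpG linked to several genes supports all of
#' them; CpGs without any gene link are skipped.
#'
#' @param rank [rank_cpgs()] output.
#' @param gene_links Tibble `cpg_id`, `gene`, `region` (e.g. from
#'   [annotate_cpgs()]).
#' @param min_patients Minimum number of supporting patients.
#' @return A tibble `gene`, `direction`, `n_patients` (maximum supporting
#'   count over the gene's CpGs), `n_cpgs`, `cpgs` (comma-separated),
#'   `regions`.
#' @export
select_candidate_genes <- function(rank, gene_links, min_patients) {
  gl <- gene_links[gene_links$region %in%
                     c("promoter", "enhancer", "gene_body"), ]
  long <- rank |>
    tidyr::pivot_longer(c("n_decreased", "n_increased"),
                        names_to = "direction", values_to = "n_patients") |>
    dplyr::mutate(direction = ifelse(.data$direction == "n_decreased",
                                     "decreased", "increased")) |>
    dplyr::filter(.data$n_patients >= min_patients) |>
    dplyr::inner_join(gl, by = "cpg_id", relationship = "many-to-many")
  if (nrow(long) == 0)
    return(tibble(gene = character(), direction = character(),
                  n_patients = integer(), n_cpgs = integer(),
                  cpgs = character(), regions = character()))
  long |>
    dplyr::group_by(.data$gene, .data$direction) |>
    dplyr::summarise(n_patients = max(.data$n_patients),
                     n_cpgs = dplyr::n_distinct(.data$cpg_id),
                     cpgs = paste(sort(unique(.data$cpg_id)), collapse = ","),
                     regions = paste(sort(unique(.data$region)),
                                     collapse = ","),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n_patients), .data$gene)
}

#' Intersect candidate genes with pathway gene sets
#'
#' @param candidates [select_candidate_genes()] output.
#' @param pathways Tibble `pathway`, `gene`.
#' @param which_pathways Pathway names to use; default all. Unknown names
#'   are an error.
#' @return A list: `genes` (candidate rows whose gene lies in the union of
#'   the requested pathways, with a `pathways` column) and `overlap` (tibble
#'   `pathway`, `n_overlap`, `percent` = 100 * overlap / candidate count).
#' @export
filter_pathway_genes <- function(candidates, pathways,
                                 which_pathways = NULL) {
  which_pathways <- which_pathways %||% unique(pathways$pathway)
  unknown <- setdiff(which_pathways, unique(pathways$pathway))
  if (length(unknown) > 0)
    abort(sprintf("Unknown pathway: %s.", paste(unknown, collapse = ", ")))
  pw <- pathways[pathways$pathway %in% which_pathways, ]
  cand_genes <- unique(candidates$gene)
  overlap <- pw |>
    dplyr::group_by(.data$pathway) |>
    dplyr::summarise(
      n_overlap = sum(unique(.data$gene) %in% cand_genes),
      .groups = "drop") |>
    dplyr::mutate(percent = if (length(cand_genes) == 0) 0
                  else 100 * .data$n_overlap / length(cand_genes))
  memb <- pw |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(pathways = paste(sort(unique(.data$pathway)),
                                      collapse = ","), .groups = "drop")
  genes <- dplyr::inner_join(candidates, memb, by = "gene")
  list(genes = genes, overlap = overlap)
}

#' Candidate-count curve over the patient threshold
#'
#' Number of candidate genes per direction as the minimum-patients threshold
#' increases; the curve is non-increasing by construction.
#'
#' @param rank,gene_links As in [select_candidate_genes()].
#' @param thresholds Integer thresholds to evaluate.
#' @return A tibble `min_patients`, `direction`, `n_genes` of class
#'   `methpair_candidate_curve`.
#' @export
candidate_curve <- function(rank, gene_links,
                            thresholds = seq_len(max(rank$n_decreased,
                                                     rank$n_increased))) {
  out <- purrr::map_dfr(thresholds, function(th) {
    cand <- select_candidate_genes(rank, gene_links, th)
    counts <- cand |>
      dplyr::group_by(.data$direction) |>
      dplyr::summarise(n_genes = dplyr::n_distinct(.data$gene),
                       .groups = "drop")
    tidyr::complete(counts,
                    direction = c("decreased", "increased"),
                    fill = list(n_genes = 0L)) |>
      dplyr::mutate(min_patients = th, .before = 1)
  })
  class(out) <- c("methpair_candidate_curve", class(out))
  out
}

#' @rdname candidate_curve
#' @param object A `methpair_candidate_curve`.
#' @param ... Unused.
#' @export
autoplot.methpair_candidate_curve <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$min_patients, y = .data$n_genes,
                               colour = .data$direction)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(decreased = "steelblue",
                                            increased = "firebrick")) +
    ggplot2::labs(x = "minimum number of supporting patients",
                  y = "candidate genes") +
    ggplot2::theme_minimal()
}
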