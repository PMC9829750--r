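#' Per-patient alteration burden and balance score
#'
#' Counts decreased and increased CpG calls per pair, averages the counts
#' over each patient's pairs, and derives the total burden
#' `n_diff = n_dec + n_inc` and the balance score
#' `s = (n_inc - n_dec) / (n_inc + n_dec)`, a dimensionless value in
#' \[-1, 1\]: negative when the intracranial metastasis lost methylation at
#' more CpGs than it gained. With no altered CpGs the score is undefined and
#' reported as `NA`, not 0.
#'
#' @param calls State calls with columns `patient_id`, `pair_id`, `state`.
#' @return A tibble `patient_id`, `n_pairs`, `n_dec`, `n_inc`, `n_diff`,
#'   `balance_score`.
#' @export
#' @examples
#' calls <- tibble::tibble(patient_id = "P01", pair_id = rep(c("a", "b"), c(3, 3)),
#'                         state = c("-", "-", "+", "-", "=", "="))
#' count_alterations(calls)
count_alterations <- function(calls) {
  need <- c("patient_id", "pair_id", "state")
  if (!all(need %in% names(calls)))
    abort("`calls` needs columns patient_id, pair_id, state.")
  per_pair <- calls |>
    dplyr::group_by(.data$patient_id, .data$pair_id) |>
    dplyr::summarise(dec = sum(.data$state == "-"),
                     inc = sum(.data$state == "+"), .groups = "drop")
  per_pair |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(n_pairs = dplyr::n(),
                     n_dec = mean(.data$dec), n_inc = mean(.data$inc),
                     .groups = "drop") |>
    dplyr::mutate(n_diff = .data$n_dec + .data$n_inc,
                  balance_score = ifelse(.data$n_diff == 0, NA_real_,
                                         (.data$n_inc - .data$n_dec) /
                                           .data$n_diff))
}

#' Join alteration burdens with clinical metadata
#'
#' Produces the tidy table behind burden-versus-clinical scatter plots
#' (months between metastases, treatment group, survival), plus descriptive
#' Spearman rank correlations of `n_diff` with the continuous covariates -
#' exploratory summaries only, no formal inference. Patients missing from
#' either table are dropped with a warning.
#'
#' @param summaries [count_alterations()] output.
#' @param clinical Clinical tibble (`patient_id`, `months_between`,
#'   `treatment`, `survival_months`, optionally `alive`).
#' @return A tibble of class `methpair_clinical` (one row per matched
#'   patient); Spearman correlations in `attr(, "spearman")` (tibble
#'   `covariate`, `rho`, `n`; `rho` is `NA` when undefined, e.g. constant
#'   input).
#' @export
clinical_scatter_tables <- function(summaries, clinical) {
  unmatched <- c(setdiff(summaries$patient_id, clinical$patient_id),
                 setdiff(clinical$patient_id, summaries$patient_id))
  if (length(unmatched) > 0)
    warn(sprintf("Dropping unmatched patient(s): %s.",
                 paste(unmatched, collapse = ", ")))
  j <- dplyr::inner_join(summaries, clinical, by = "patient_id")
  spearman_of <- function(y) {
    ok <- is.finite(j$n_diff) & is.finite(y)
    if (sum(ok) < 3 || sd(j$n_diff[ok]) == 0 || sd(y[ok]) == 0)
      return(c(rho = NA_real_, n = sum(ok)))
    c(rho = cor(j$n_diff[ok], y[ok], method = "spearman"), n = sum(ok))
  }
  sp <- purrr::map_dfr(
    c(months_between = "months_between", survival_months = "survival_months"),
    function(col) {
      v <- spearman_of(j[[col]])
      tibble(covariate = col, rho = v[["rho"]], n = as.integer(v[["n"]]))
    })
  structure(j, spearman = sp, class = c("methpair_clinical", class(j)))
}

#' Treatment-group consistency of top-ranking CpGs
#'
#' For every CpG whose cross-patient recurrence reaches `min_patients` in
#' some direction, reports the fraction of patients in each treatment group
#' whose consensus state equals that CpG's majority direction - the check
#' that the most discriminative CpGs alter homogeneously in treated and
#' untreated patients.
#'
#' @param rank [rank_cpgs()] output.
#' @param consensus [patient_consensus()] output.
#' @param clinical Clinical tibble with `patient_id`, `treatment`.
#' @param min_patients Recurrence threshold selecting the top CpGs.
#' @return A tibble `cpg_id`, `direction`, `n_patients_total`, `treatment`,
#'   `n_group`, `n_altered`, `proportion`. Treatment groups with no patients
#'   are omitted with a warning.
#' @export
treatment_consistency <- function(rank, consensus, clinical, min_patients) {
  groups <- clinical |>
    dplyr::count(.data$treatment, name = "n_group")
  empty <- setdiff(unique(clinical$treatment),
                   groups$treatment[groups$n_group > 0])
  if (length(empty) > 0)
    warn(sprintf("Empty treatment group(s) omitted: %s.",
                 paste(empty, collapse = ", ")))
  top <- rank |>
    dplyr::filter(pmax(.data$n_decreased, .data$n_increased) >= min_patients) |>
    dplyr::mutate(direction = ifelse(.data$n_decreased >= .data$n_increased,
                                     "decreased", "increased"),
                  n_patients_total = pmax(.data$n_decreased, .data$n_increased))
  if (nrow(top) == 0)
    return(tibble(cpg_id = character(), direction = character(),
                  n_patients_total = integer(), treatment = character(),
                  n_group = integer(), n_altered = integer(),
                  proportion = numeric()))
  cons <- dplyr::inner_join(consensus, clinical[, c("patient_id", "treatment")],
                            by = "patient_id")
  purrr::map_dfr(seq_len(nrow(top)), function(i) {
    target <- if (top$direction[i] == "decreased") "-" else "+"
    cc <- cons[cons$cpg_id == top$cpg_id[i], ]
    cc |>
      dplyr::group_by(.data$treatment) |>
      dplyr::summarise(n_group = dplyr::n(),
                       n_altered = sum(.data$state == target),
                       .groups = "drop") |>
      dplyr::mutate(proportion = .data$n_altered / .data$n_group,
                    cpg_id = top$cpg_id[i], direction = top$direction[i],
                    n_patients_total = top$n_patients_total[i]) |>
      dplyr::select("cpg_id", "direction", "n_patients_total", "treatment",
                    "n_group", "n_altered", "proportion")
  })
}

#' Per-gene expression log2-ratios of matched pairs
#'
#' `ratio = intra - extra` per gene per patient from normalized
#' log2-expression tables. Genes missing from either table are dropped (and
#' reported via a message). With several samples per patient and role,
#' `average_regions = TRUE` averages the per-region expression levels before
#' subtracting, which weighs every patient equally.
#'
#' @param expr Long expression tibble: `gene`, `patient_id`, `role`
#'   (`"intra"`/`"extra"`), `log2_expr` (normalized log2 expression).
#' @param average_regions Average multiple samples of the same patient and
#'   role before subtracting (otherwise an error if duplicates exist).
#' @return A tibble `gene`, `patient_id`, `ratio`.
#' @export
expression_log2_ratios <- function(expr, average_regions = TRUE) {
  need <- c("gene", "patient_id", "role", "log2_expr")
  if (!all(need %in% names(expr)))
    abort("`expr` needs columns gene, patient_id, role, log2_expr.")
  agg <- expr |>
    dplyr::group_by(.data$gene, .data$patient_id, .data$role) |>
    dplyr::summarise(log2_expr = if (average_regions)
      mean(.data$log2_expr)
      else {
        if (dplyr::n() > 1)
          abort("Multiple samples per patient/role; set `average_regions = TRUE`.")
        .data$log2_expr[1]
      }, .groups = "drop")
  wide <- tidyr::pivot_wider(agg, names_from = "role",
                             values_from = "log2_expr")
  if (!all(c("intra", "extra") %in% names(wide)))
    abort("`role` must contain both 'intra' and 'extra'.")
  dropped <- wide$gene[!complete.cases(wide[, c("intra", "extra")])]
  if (length(dropped) > 0)
    inform(sprintf("Dropping %d gene-patient rows missing one side.",
                   length(unique(dropped))))
  wide |>
    dplyr::filter(is.finite(.data$intra), is.finite(.data$extra)) |>
    dplyr::transmute(gene = .data$gene, patient_id = .data$patient_id,
                     ratio = .data$intra - .data$extra)
}

#' Test per-gene expression shifts against zero
#'
#' Two-sided one-sample t-test of the mean intra-minus-extra log2-ratio per
#' gene, BH-adjusted across genes; genes passing `q < alpha` are
#' additionally tested by a paired t-test on the per-patient intra vs extra
#' levels when those are supplied. Genes with zero ratio variance are
#' flagged and get no p-value.
#'
#' @param ratios [expression_log2_ratios()] output.
#' @param expr Optional long expression tibble (as in
#'   [expression_log2_ratios()]) enabling the paired follow-up test.
#' @param alpha FDR cutoff for the follow-up.
#' @return A tibble `gene`, `n`, `mean_shift`, `statistic`, `p_value`,
#'   `q_value`, `zero_variance`, `paired_p` (NA unless computed).
#' @export
test_expression_shift <- function(ratios, expr = NULL, alpha = 0.05) {
  res <- ratios |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(n = dplyr::n(), mean_shift = mean(.data$ratio),
                     sd_ratio = sd(.data$ratio), .groups = "drop")
  too_few <- res$gene[res$n < 2]
  if (length(too_few) > 0)
    abort(sprintf("Gene '%s' has fewer than 2 ratios.", too_few[1]))
  res$zero_variance <- res$sd_ratio == 0
  stat_p <- purrr::map_dfr(res$gene, function(g) {
    r <- ratios$ratio[ratios$gene == g]
    if (sd(r) == 0) {
      if (all(r == 0)) tibble(statistic = 0, p_value = 1)
      else tibble(statistic = NA_real_, p_value = NA_real_)
    } else {
      tt <- t.test(r)
      tibble(statistic = unname(tt$statistic), p_value = tt$p.value)
    }
  })
  res <- dplyr::bind_cols(res[, c("gene", "n", "mean_shift",
                                  "zero_variance")], stat_p)
  ok <- !is.na(res$p_value)
  res$q_value <- NA_real_
  res$q_value[ok] <- adjust_fdr(res$p_value[ok])
  res$paired_p <- NA_real_
  if (!is.null(expr)) {
    hits <- res$gene[!is.na(res$q_value) & res$q_value < alpha]
    for (g in hits) {
      agg <- expr[expr$gene == g, ] |>
        dplyr::group_by(.data$patient_id, .data$role) |>
        dplyr::summarise(v = mean(.data$log2_expr), .groups = "drop") |>
        tidyr::pivot_wider(names_from = "role", values_from = "v")
      if (all(c("intra", "extra") %in% names(agg)) && nrow(agg) >= 2 &&
          sd(agg$intra - agg$extra) > 0)
        res$paired_p[res$gene == g] <-
          t.test(agg$intra, agg$extra, paired = TRUE)$p.value
    }
  }
  res
}

#' Classify the methylation-expression relation of a gene
#'
#' The three canonical classes: (i) decreased gene-body methylation with
#' increased expression, (ii) decreased methylation with decreased
#' expression, (iii) increased methylation with decreased expression.
#' Increased methylation with increased expression falls outside the three
#' classes and is reported as `"other"`; a zero shift or unknown direction
#' is `"unclassified"`.
#'
#' @param meth_direction `"decreased"` or `"increased"` (vectorised).
#' @param mean_shift Mean expression log2-ratio (intra - extra).
#' @return Character vector over `c("i", "ii", "iii", "other",
#'   "unclassified")`.
#' @export
#' @examples
#' classify_meth_expr_relation("decreased", 0.8)   # "i"
#' classify_meth_expr_relation("increased", -0.4)  # "iii"
classify_meth_expr_relation <- function(meth_direction, mean_shift) {
  if (length(meth_direction) != length(mean_shift))
    abort("Inputs must have equal length.")
  dplyr::case_when(
    !meth_direction %in% c("decreased", "increased") | is.na(mean_shift) |
      mean_shift == 0 ~ "unclassified",
    meth_direction == "decreased" & mean_shift > 0 ~ "i",
    meth_direction == "decreased" & mean_shift < 0 ~ "ii",
    meth_direction == "increased" & mean_shift < 0 ~ "iii",
    TRUE ~ "other")
}

#' Plot alteration burden against clinical covariates
#'
#' Scatter of the per-patient number of differentially methylated CpGs
#' against months between metastases and survival, coloured by the balance
#' score (blue: net loss, red: net gain of methylation intracranially), with
#' the treatment group as the point shape.
#'
#' @param object A `methpair_clinical` table from [clinical_scatter_tables()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.methpair_clinical <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object),
                            c("months_between", "survival_months"),
                            names_to = "covariate", values_to = "months")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_diff, y = .data$months,
                                   colour = .data$balance_score,
                                   shape = .data$treatment)) +
    ggplot2::geom_point(size = 2, na.rm = TRUE) +
    ggplot2::facet_wrap(~covariate, scales = "free_y") +
    ggplot2::scale_colour_gradient2(low = "steelblue", mid = "grey70",
                                    high = "firebrick", limits = c(-1, 1),
                                    name = "balance score") +
    ggplot2::labs(x = "differentially methylated CpGs (per patient)",
                  y = "months") +
    ggplot2::theme_minimal()
}
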