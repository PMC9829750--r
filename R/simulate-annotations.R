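#' Simulate genomic annotations for a synthetic cohort
#'
#' Tiles genes along each chromosome (each gene body spanning a single CpG,
#' a short promoter upstream, and one single-CpG enhancer a state-run-length
#' downstream), places CpG islands with shore and shelf flanks (open sea is
#' the complement), scatters transposon intervals of the LTR, LINE and DNA
#' classes, and builds pathway gene sets. Gene units are deliberately sparse
#' in CpGs and widely separated (about 20 CpGs apart) so that, at the
#' default chain persistence, each gene contributes roughly one independent
#' methylation-state draw; the per-CpG Fisher enrichment test assumes
#' independent CpGs, and this geometry keeps that assumption approximately
#' valid on synthetic data.
#'
#' Two special pathways are always constructed. The truly enriched pathway
#' mixes genes whose body CpG shows decreased methylation (the dominant
#' direction) in the reference pair's truth with background genes, in the
#' proportion that makes the odds of a pathway-linked CpG being decreased
#' about `enrich_odds` times the background odds. The neutral pathway
#' samples genes uniformly, independent of the truth; remaining pathways are
#' uniform background sets.
#'
#' All intervals are 0-based half-open (BED convention); CpG positions are
#' 1-based, and the conversion happens at the annotation boundary.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param enrich_odds Odds favouring truly-altered genes when sampling the
#'   enriched pathway.
#' @param pathway_size Genes per pathway.
#' @param n_background_pathways Number of uniform background pathways.
#' @param reference_pair Pair id whose truth defines "altered" for the
#'   enriched pathway; defaults to the cohort's first pair.
#' @return An object of class `methpair_annotations`: tibbles `regions`
#'   (`chrom`, `start`, `end`, `gene`, `type` in promoter/gene_body/enhancer),
#'   `islands` (`chrom`, `start`, `end`, `context` in island/shore/shelf),
#'   `transposons` (`chrom`, `start`, `end`, `class` in LTR/LINE/DNA) and
#'   `pathways` (`pathway`, `gene`).
#' @export
simulate_annotations <- function(cohort, enrich_odds = 5, pathway_size = 60,
                                 n_background_pathways = 4,
                                 reference_pair = NULL) {
  stopifnot(inherits(cohort, "methpair_cohort"))
  if (nrow(cohort$coords) == 0) abort("Cohort has no CpGs.")
  config <- cohort$config
  coords <- cohort$coords
  reference_pair <- reference_pair %||% cohort$pair_meta$pair_id[1]

  with_seed(stream_seed(config$seed, "annotations"), {
    per_chr <- split(coords, chrom_order(coords$chrom), drop = TRUE)

    gene_counter <- 0L
    regions <- purrr::map_dfr(per_chr, function(cc) {
      n <- nrow(cc)
      starts_idx <- seq(5, n - 1, by = 20)
      purrr::map_dfr(starts_idx, function(s) {
        gene_counter <<- gene_counter + 1L
        g <- sprintf("GENE%04d", gene_counter)
        body_start0 <- cc$pos[s] - 51        # 0-based, 50 bp pad
        body_end0 <- cc$pos[s] + 50
        prom_start0 <- max(0, body_start0 - 400)
        enh_idx <- s + 10                     # about one state run away
        enh <- if (enh_idx <= n)
          tibble(chrom = cc$chrom[1], start = cc$pos[enh_idx] - 26,
                 end = cc$pos[enh_idx] + 25, gene = g, type = "enhancer")
        else NULL
        dplyr::bind_rows(
          tibble(chrom = cc$chrom[1], start = prom_start0, end = body_start0,
                 gene = g, type = "promoter"),
          tibble(chrom = cc$chrom[1], start = body_start0, end = body_end0,
                 gene = g, type = "gene_body"),
          enh)
      })
    })

    islands <- purrr::map_dfr(per_chr, function(cc) {
      n <- nrow(cc)
      isl_idx <- seq(12, n - 3, by = 50)
      purrr::map_dfr(isl_idx, function(s) {
        i_start <- cc$pos[s] - 26
        i_end <- cc$pos[s + 3] + 25
        tibble(chrom = cc$chrom[1],
               start = c(i_start, max(0, i_start - 1500), i_end,
                         max(0, i_start - 3000), i_end + 1500),
               end = c(i_end, i_start, i_end + 1500,
                       max(0, i_start - 1500), i_end + 3000),
               context = c("island", "shore", "shore", "shelf", "shelf"))
      })
    })
    islands <- islands[islands$end > islands$start, ]

    transposons <- purrr::map_dfr(per_chr, function(cc) {
      n <- nrow(cc)
      k <- max(1, n %/% 100)
      idx <- sort(sample(seq_len(n - 1), k))
      tibble(chrom = cc$chrom[1], start = cc$pos[idx] - 26,
             end = cc$pos[idx] + 25,
             class = sample(c("LTR", "LINE", "DNA"), k, replace = TRUE,
                            prob = c(0.4, 0.35, 0.25)))
    })

    genes <- unique(regions$gene)
    ref_truth <- cohort$truth[cohort$truth$pair_id == reference_pair, ]
    dec_cpg <- ref_truth$cpg_id[ref_truth$state == "-"]
    all_hits <- interval_overlap(coords, regions)
    links <- tibble(gene = regions$gene[all_hits$interval_row],
                    cpg_id = coords$cpg_id[all_hits$cpg_row])
    links <- dplyr::distinct(links)
    per_gene <- links |>
      dplyr::group_by(.data$gene) |>
      dplyr::summarise(n_cpg = dplyr::n(),
                       n_dec = sum(.data$cpg_id %in% dec_cpg),
                       .groups = "drop")
    body <- regions[regions$type == "gene_body", ]
    body_hits <- interval_overlap(coords, body)
    altered_genes <- unique(
      body$gene[body_hits$interval_row[
        coords$cpg_id[body_hits$cpg_row] %in% dec_cpg]])
    per_gene$altered <- per_gene$gene %in% altered_genes

    pathway_size <- min(pathway_size, length(genes))
    # mix altered and background genes so that pathway-linked CpGs reach
    # about enrich_odds times the background odds of being decreased
    f_bg <- sum(per_gene$n_dec) / sum(per_gene$n_cpg)
    odds_t <- enrich_odds * f_bg / (1 - f_bg)
    f_t <- odds_t / (1 + odds_t)
    f1 <- with(per_gene[per_gene$altered, ],
               if (sum(n_cpg) > 0) sum(n_dec) / sum(n_cpg) else NA_real_)
    f0 <- with(per_gene[!per_gene$altered, ],
               if (sum(n_cpg) > 0) sum(n_dec) / sum(n_cpg) else NA_real_)
    pool_a <- per_gene$gene[per_gene$altered]
    pool_b <- per_gene$gene[!per_gene$altered]
    m <- if (is.na(f1) || is.na(f0) || f1 <= f0) 0L
         else round(pathway_size * min(1, max(0, (f_t - f0) / (f1 - f0))))
    m <- min(m, length(pool_a))
    enriched <- c(sample(pool_a, m),
                  sample(pool_b, min(pathway_size - m, length(pool_b))))
    pw <- list(
      pw_true_enriched = enriched,
      pw_neutral = sample(genes, pathway_size))
    for (b in seq_len(n_background_pathways))
      pw[[sprintf("pw_background_%d", b)]] <- sample(genes, pathway_size)
    pathways <- purrr::imap_dfr(pw, function(gs, nm)
      tibble(pathway = nm, gene = gs))

    structure(
      list(regions = regions, islands = islands, transposons = transposons,
           pathways = pathways, reference_pair = reference_pair),
      class = "methpair_annotations")
  })
}

# Row indices of `coords` (1-based positions) falling inside 0-based
# half-open intervals `iv` on matching chromosomes.
interval_overlap <- function(coords, iv) {
  if (nrow(iv) == 0)
    return(tibble(cpg_row = integer(), interval_row = integer()))
  bad <- which(iv$end <= iv$start)
  if (length(bad) > 0)
    abort(sprintf("Malformed interval (end <= start) at line %d.", bad[1]))
  out <- purrr::map_dfr(unique(iv$chrom), function(ch) {
    ci <- which(coords$chrom == ch)
    ii <- which(iv$chrom == ch)
    if (length(ci) == 0 || length(ii) == 0)
      return(tibble(cpg_row = integer(), interval_row = integer()))
    # 1-based pos p overlaps [start, end) iff start < p <= end
    q <- IRanges::IRanges(start = coords$pos[ci], width = 1L)
    s <- IRanges::IRanges(start = iv$start[ii] + 1L, end = iv$end[ii])
    h <- IRanges::findOverlaps(q, s)
    tibble(cpg_row = ci[S4Vectors::queryHits(h)],
           interval_row = ii[S4Vectors::subjectHits(h)])
  })
  out
}

#' Simulate expression tables coupled to gene-body methylation
#'
#' Assigns each gene a coupling class - repressive (gene-body methylation
#' change and expression change have opposite signs, the canonical classes
#' (i) and (iii)) or co-directional (same sign, class (ii)) - and emits one
#' intracranial and one extracranial log2-expression sample per patient. The
#' intracranial value is shifted by `expr_effect` according to the gene's
#' per-patient consensus body-methylation direction (majority state over the
#' patient's pairs at the gene's body CpGs; ties and unchanged give no
#' shift), plus `N(0, expr_noise_sd)` noise.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param annotations Matching [simulate_annotations()] result.
#' @param prob_repressive Probability that a gene is repressive (defaults to
#'   10/13, the observed class balance).
#' @return A list with `expression` (tibble `gene`, `patient_id`, `role`,
#'   `sample_id`, `log2_expr`) and `truth` (tibble `gene`,
#'   `coupling_class`, `patient_id`, `meth_direction`, `category`, `shift`).
#'   `category` is `i`, `ii`, `iii`, `other` (increased methylation with
#'   co-directional coupling) or `none` (no methylation change).
#' @export
simulate_expression <- function(cohort, annotations,
                                prob_repressive = 10 / 13) {
  stopifnot(inherits(cohort, "methpair_cohort"),
            inherits(annotations, "methpair_annotations"))
  config <- cohort$config
  body <- annotations$regions[annotations$regions$type == "gene_body", ]
  genes <- unique(body$gene)
  if (length(genes) == 0) abort("No genes with body intervals to couple.")

  hits <- interval_overlap(cohort$coords, body)
  body_link <- tibble(cpg_id = cohort$coords$cpg_id[hits$cpg_row],
                      gene = body$gene[hits$interval_row])

  # per patient x gene: majority body-CpG state over the patient's pairs
  tr <- dplyr::inner_join(cohort$truth, body_link, by = "cpg_id",
                          relationship = "many-to-many")
  dirs <- tr |>
    dplyr::group_by(.data$patient_id, .data$gene) |>
    dplyr::summarise(n_dec = sum(.data$state == "-"),
                     n_inc = sum(.data$state == "+"), .groups = "drop") |>
    dplyr::mutate(meth_direction = dplyr::case_when(
      .data$n_dec > .data$n_inc & .data$n_dec > 0 ~ "decreased",
      .data$n_inc > .data$n_dec & .data$n_inc > 0 ~ "increased",
      TRUE ~ "unchanged"))

  with_seed(stream_seed(config$seed, "expression"), {
    coupling <- tibble(
      gene = genes,
      coupling_class = ifelse(runif(length(genes)) < prob_repressive,
                              "repressive", "codirectional"),
      base_expr = rnorm(length(genes), 7, 1.5))

    truth <- dirs |>
      dplyr::inner_join(coupling, by = "gene") |>
      dplyr::mutate(
        dir_num = dplyr::case_when(.data$meth_direction == "decreased" ~ -1,
                                   .data$meth_direction == "increased" ~ 1,
                                   TRUE ~ 0),
        shift = ifelse(.data$coupling_class == "repressive", -1, 1) *
          .data$dir_num * config$expr_effect,
        category = dplyr::case_when(
          .data$dir_num == 0 ~ "none",
          .data$coupling_class == "repressive" & .data$dir_num == -1 ~ "i",
          .data$coupling_class == "codirectional" & .data$dir_num == -1 ~ "ii",
          .data$coupling_class == "repressive" & .data$dir_num == 1 ~ "iii",
          TRUE ~ "other"))

    patients <- sprintf("P%02d", seq_len(config$n_patients))
    expression <- purrr::map_dfr(patients, function(p) {
      tshift <- truth[truth$patient_id == p, c("gene", "shift")]
      sh <- setNames(rep(0, length(genes)), genes)
      sh[tshift$gene] <- tshift$shift
      extra <- coupling$base_expr + rnorm(length(genes), 0, config$expr_noise_sd)
      intra <- coupling$base_expr + sh[coupling$gene] +
        rnorm(length(genes), 0, config$expr_noise_sd)
      dplyr::bind_rows(
        tibble(gene = coupling$gene, patient_id = p, role = "intra",
               sample_id = paste0(p, "_expr_intra"), log2_expr = intra),
        tibble(gene = coupling$gene, patient_id = p, role = "extra",
               sample_id = paste0(p, "_expr_extra"), log2_expr = extra))
    })

    list(expression = expression,
         truth = truth[, c("gene", "coupling_class", "patient_id",
                           "meth_direction", "category", "shift")])
  })
}

#' Simulate a clinical metadata table
#'
#' One row per patient: months between the surgical resections of the two
#' metastases (negative when the intracranial metastasis came first), a
#' treatment group, and survival months from the intracranial metastasis
#' (missing, with `alive = TRUE`, for a small fraction of patients).
#'
#' @param config A [sim_config()].
#' @return A tibble `patient_id`, `months_between`, `treatment`,
#'   `survival_months`, `alive`.
#' @export
simulate_clinical <- function(config) {
  stopifnot(inherits(config, "methpair_sim_config"))
  n <- config$n_patients
  with_seed(stream_seed(config$seed, "clinical"), {
    treatment <- sample(names(config$treatment_probs), n, replace = TRUE,
                        prob = config$treatment_probs)
    alive <- runif(n) < 0.08
    surv <- round(rlnorm(n, log(12), 0.6), 1)
    surv[alive] <- NA_real_
    tibble(patient_id = sprintf("P%02d", seq_len(n)),
           months_between = round(rnorm(n, 5, 4), 1),
           treatment = treatment,
           survival_months = surv,
           alive = alive)
  })
}
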