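test_that("cohort generation is deterministic under a fixed seed", {
  cfg <- tiny_config(seed = 99L)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$samples, b$samples)
  expect_identical(a$pairs, b$pairs)
  expect_identical(a$truth, b$truth)
  expect_identical(simulate_clinical(cfg), simulate_clinical(cfg))
  ann_a <- simulate_annotations(a)
  ann_b <- simulate_annotations(b)
  expect_identical(ann_a$pathways, ann_b$pathways)
  expect_identical(simulate_expression(a, ann_a)$expression,
                   simulate_expression(b, ann_b)$expression)
})

test_that("an absorbing unchanged chain emits only '=' with N(0, 0.5) noise", {
  cfg <- tiny_config(n_patients = 1, cpgs_per_chromosome = 5000,
                     n_chromosomes = 1,
                     start_probs = c(0, 1, 0), self_transition = 1,
                     label_noise = 0, seed = 5L)
  co <- simulate_cohort(cfg)
  expect_true(all(co$truth$state == "="))
  expect_lt(abs(mean(co$pairs$delta)), 3 * 0.5 / sqrt(5000))
  expect_lt(abs(sd(co$pairs$delta) - 0.5), 0.03)
})

test_that("realized truth fractions match the chain's stationary distribution", {
  # A = s*I + (1-s)*1 pi' makes start_probs the exact stationary law
  pi0 <- c(0.078, 0.888, 0.034)
  cfg <- tiny_config(n_patients = 1, n_chromosomes = 1,
                     cpgs_per_chromosome = 50000,
                     start_probs = pi0, seed = 21L)
  co <- simulate_cohort(cfg)
  frac <- c(mean(co$truth$state == "-"), mean(co$truth$state == "="),
            mean(co$truth$state == "+"))
  expect_true(all(abs(frac - pi0) < 0.01))
})

test_that("pair deltas equal the sample difference exactly and emissions match their state", {
  co <- simulate_cohort(tiny_config(cpgs_per_chromosome = 2000, seed = 3L))
  wide <- tidyr::pivot_wider(
    co$samples[, c("pair_id", "cpg_id", "role", "log2ratio")],
    names_from = "role", values_from = "log2ratio")
  j <- dplyr::inner_join(wide, co$pairs[, c("pair_id", "cpg_id", "delta")],
                         by = c("pair_id", "cpg_id"))
  expect_true(all(j$intra - j$extra == j$delta))

  # conditional emission means converge to the configured state means
  jt <- dplyr::inner_join(co$pairs, co$truth[, c("pair_id", "cpg_id", "state")],
                          by = c("pair_id", "cpg_id"))
  for (k in 1:3) {
    st <- c("-", "=", "+")[k]
    xs <- jt$delta[jt$state == st]
    expect_lt(abs(mean(xs) - c(-3, 0, 3)[k]),
              3 * c(0.3, 0.5, 0.3)[k] / sqrt(length(xs)))
  }
  # truth covers every emitted CpG exactly once per pair
  expect_identical(nrow(co$truth), nrow(co$pairs))
  expect_false(any(duplicated(co$truth[, c("pair_id", "cpg_id")])))
})

test_that("dominant patient effects make patient samples mutual nearest neighbours", {
  cfg <- tiny_config(n_patients = 14, pairs_per_patient = 1,
                     n_chromosomes = 1, cpgs_per_chromosome = 300,
                     patient_effect_sd = 3, tissue_effect_sd = 0.1,
                     seed = 42L)
  co <- simulate_cohort(cfg)
  m <- cohort_sample_matrix(co)
  d <- as.matrix(manhattan_distances(m))
  diag(d) <- Inf
  nn <- colnames(d)[apply(d, 1, which.min)]
  pid <- sub("_(intra|extra)\\d+$", "", rownames(d))
  nn_pid <- sub("_(intra|extra)\\d+$", "", nn)
  mutual <- vapply(seq_len(nrow(d)), function(i) {
    j <- which.min(d[i, ]); which.min(d[j, ]) == i && pid[i] == nn_pid[i]
  }, logical(1))
  per_patient <- tapply(mutual, pid, all)
  expect_gte(mean(per_patient), 0.95)
})

test_that("sim_config rejects invalid settings", {
  expect_error(tiny_config(start_probs = c(0.2, 0.2, 0.2)), "sum")
  expect_error(tiny_config(state_sds = c(0.3, -0.1, 0.3)), "positive")
  expect_error(tiny_config(cpgs_per_chromosome = 1), ">= 2")
  expect_error(tiny_config(self_transition = 1.2), "0, 1")
})

test_that("altered-fraction targets steer individual pairs", {
  aft <- tibble::tibble(frac_dec = c(0.25, 0.02), frac_inc = c(0.02, 0.2))
  cfg <- tiny_config(n_patients = 2, pairs_per_patient = 1,
                     n_chromosomes = 1, cpgs_per_chromosome = 20000,
                     altered_fraction_targets = aft, seed = 17L)
  co <- simulate_cohort(cfg)
  f <- co$truth |>
    dplyr::group_by(pair_id) |>
    dplyr::summarise(dec = mean(state == "-"), inc = mean(state == "+"))
  # chain autocorrelation inflates the binomial variance by (1+s)/(1-s) = 19
  tol <- 3 * sqrt(pmax(aft$frac_dec, aft$frac_inc) * 0.75 * 19 / 20000)
  expect_true(all(abs(f$dec - aft$frac_dec) < tol))
  expect_true(all(abs(f$inc - aft$frac_inc) < tol))
})

test_that("annotation geometry obeys the stated containment contracts", {
  co <- simulate_cohort(tiny_config(seed = 8L))
  ann <- simulate_annotations(co)
  annotated <- annotate_cpgs(co$coords, ann)

  # every CpG inside a gene-body interval carries the gene_body category
  body <- ann$regions[ann$regions$type == "gene_body", ]
  in_body <- purrr::map_lgl(seq_len(nrow(co$coords)), function(i) {
    any(body$chrom == co$coords$chrom[i] &
          body$start < co$coords$pos[i] & co$coords$pos[i] <= body$end)
  })
  body_cpgs <- annotated$categories$cpg_id[
    annotated$categories$category == "gene_body"]
  expect_setequal(co$coords$cpg_id[in_body], body_cpgs)

  # CpGs outside island/shore/shelf are open_sea, and contexts are exclusive
  ctx <- annotated$categories[annotated$categories$category %in%
                                c("island", "shore", "shelf", "open_sea"), ]
  expect_identical(sort(ctx$cpg_id), sort(co$coords$cpg_id))
  expect_false(any(duplicated(ctx$cpg_id)))

  expect_error(simulate_annotations(structure(list(coords = co$coords[0, ]),
                                              class = "methpair_cohort")),
               "no CpGs")
})

test_that("the constructed-enriched pathway beats the neutral one across seeds", {
  hits <- vapply(1:100, function(s) {
    cfg <- tiny_config(n_patients = 1, n_chromosomes = 1,
                       cpgs_per_chromosome = 5000, seed = 1000L + s)
    co <- simulate_cohort(cfg)
    ann <- simulate_annotations(co)
    annotated <- annotate_cpgs(co$coords, ann)
    calls <- co$truth[co$truth$pair_id == co$pair_meta$pair_id[1], ]
    p_enr <- fisher_enrichment(calls, annotated, "decreased",
                               "pw_true_enriched")$p_value
    p_neu <- fisher_enrichment(calls, annotated, "decreased",
                               "pw_neutral")$p_value
    p_enr < p_neu
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("expression coupling has the configured signs when noiseless", {
  cfg <- tiny_config(cpgs_per_chromosome = 2000, expr_noise_sd = 0,
                     expr_effect = 1, seed = 13L)
  co <- simulate_cohort(cfg)
  ann <- simulate_annotations(co)
  ex <- simulate_expression(co, ann)
  ratios <- expression_log2_ratios(ex$expression)
  j <- dplyr::inner_join(ratios, ex$truth, by = c("gene", "patient_id"))
  # class (i): decreased body methylation -> increased expression
  ci <- j[j$category == "i", ]
  expect_gt(nrow(ci), 0)
  expect_true(all(ci$ratio > 0))
  # class (iii): increased body methylation -> decreased expression
  ciii <- j[j$category == "iii", ]
  if (nrow(ciii) > 0) expect_true(all(ciii$ratio < 0))
  # class (ii): decreased methylation, co-directional -> decreased expression
  cii <- j[j$category == "ii", ]
  if (nrow(cii) > 0) expect_true(all(cii$ratio < 0))
  expect_true(all(j$ratio[j$category == "none"] == 0))
})

test_that("clinical tables have one row per patient and honour degenerate probabilities", {
  cfg <- tiny_config(n_patients = 14, pairs_per_patient = 1)
  cl <- simulate_clinical(cfg)
  expect_identical(nrow(cl), 14L)
  expect_identical(cl$patient_id, sprintf("P%02d", 1:14))

  cfg2 <- tiny_config(n_patients = 6, pairs_per_patient = 1,
                      treatment_probs = c(untreated = 1, im_treated = 0,
                                          im_em_treated = 0, unknown = 0))
  expect_true(all(simulate_clinical(cfg2)$treatment == "untreated"))
})
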