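test_that("alteration counts average over pairs and the balance score behaves", {
  calls <- tibble::tibble(
    patient_id = "P01",
    pair_id = rep(c("a", "b"), c(150, 270)),
    state = c(rep("-", 100), rep("+", 50),
              rep("-", 200), rep("+", 70)))
  s <- count_alterations(calls)
  expect_equal(s$n_dec, 150)
  expect_equal(s$n_inc, 60)
  expect_equal(s$n_diff, 210)
  expect_equal(s$balance_score, -3 / 7)

  only_dec <- tibble::tibble(patient_id = "P", pair_id = "a",
                             state = c("-", "-", "="))
  expect_equal(count_alterations(only_dec)$balance_score, -1)
  balanced <- tibble::tibble(patient_id = "P", pair_id = "a",
                             state = c("-", "+"))
  expect_equal(count_alterations(balanced)$balance_score, 0)
  none <- tibble::tibble(patient_id = "P", pair_id = "a", state = "=")
  expect_true(is.na(count_alterations(none)$balance_score))
  # antisymmetry under swapping the direction labels
  swapped <- dplyr::mutate(calls, state = chartr("-+", "+-", state))
  expect_equal(count_alterations(swapped)$balance_score, 3 / 7)
})

test_that("clinical joins keep matched patients and report Spearman descriptives", {
  summaries <- tibble::tibble(patient_id = c("P01", "P02", "P03", "P04"),
                              n_pairs = 1, n_dec = c(10, 20, 30, 40),
                              n_inc = 0, n_diff = c(10, 20, 30, 40),
                              balance_score = -1)
  clinical <- tibble::tibble(patient_id = c("P01", "P02", "P03", "P05"),
                             months_between = c(1, 5, 9, 2),
                             treatment = "untreated",
                             survival_months = c(12, NA, 30, 8),
                             alive = c(FALSE, TRUE, FALSE, FALSE))
  expect_warning(j <- clinical_scatter_tables(summaries, clinical),
                 "P04.*P05|P05.*P04")
  expect_identical(nrow(j), 3L)
  # the alive patient keeps a row with missing survival
  expect_true(is.na(j$survival_months[j$patient_id == "P02"]))
  sp <- attr(j, "spearman")
  expect_equal(sp$rho[sp$covariate == "months_between"], 1)

  # constant burden: correlation undefined, reported as NA
  const <- dplyr::mutate(summaries[1:3, ], n_diff = 5)
  expect_warning(j2 <- clinical_scatter_tables(const, clinical))
  expect_true(is.na(attr(j2, "spearman")$rho[1]))
})

test_that("treatment consistency reports per-group alteration proportions", {
  patients <- sprintf("P%02d", 1:6)
  clinical <- tibble::tibble(patient_id = patients,
                             treatment = rep(c("untreated", "im_treated"),
                                             each = 3))
  cons <- tidyr::expand_grid(patient_id = patients, cpg_id = c("cg1", "cg2")) |>
    dplyr::mutate(state = "=")
  cons$state[cons$cpg_id == "cg1"] <- "-"                  # all patients
  cons$state[cons$cpg_id == "cg2" &
               cons$patient_id %in% patients[4:6]] <- "-"  # treated only
  rank <- rank_cpgs(cons)
  tc <- treatment_consistency(rank, cons, clinical, min_patients = 3)
  t1 <- tc[tc$cpg_id == "cg1", ]
  expect_true(all(t1$proportion == 1))
  t2 <- tc[tc$cpg_id == "cg2", ]
  expect_equal(t2$proportion[t2$treatment == "untreated"], 0)
  expect_equal(t2$proportion[t2$treatment == "im_treated"], 1)
  # the threshold defines the top set exactly
  tc10 <- treatment_consistency(rank, cons, clinical, min_patients = 4)
  expect_identical(unique(tc10$cpg_id), "cg1")
})

test_that("expression ratios subtract, average regions and drop incomplete genes", {
  expr <- tibble::tibble(gene = "G1", patient_id = "P01",
                         role = c("intra", "extra"), log2_expr = c(5, 3))
  expect_equal(expression_log2_ratios(expr)$ratio, 2)

  same <- dplyr::mutate(expr, log2_expr = c(4, 4))
  expect_equal(expression_log2_ratios(same)$ratio, 0)

  multi <- tibble::tibble(gene = "G1", patient_id = "P01",
                          role = c("intra", "intra", "extra"),
                          log2_expr = c(4, 6, 1))
  expect_equal(expression_log2_ratios(multi)$ratio, 4)  # mean(4,6) - 1
  expect_error(expression_log2_ratios(multi, average_regions = FALSE),
               "Multiple samples")

  onesided <- tibble::tibble(gene = c("G1", "G1", "G2"),
                             patient_id = "P01",
                             role = c("intra", "extra", "intra"),
                             log2_expr = c(2, 1, 9))
  expect_message(r <- expression_log2_ratios(onesided), "missing one side")
  expect_identical(r$gene, "G1")
})

test_that("expression shift tests handle trivial, degenerate and null cases", {
  zeros <- tibble::tibble(gene = "G1", patient_id = sprintf("P%d", 1:4),
                          ratio = 0)
  res <- test_expression_shift(zeros)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  const <- tibble::tibble(gene = "G1", patient_id = sprintf("P%d", 1:4),
                          ratio = 1)
  res2 <- test_expression_shift(const)
  expect_true(res2$zero_variance)
  expect_true(is.na(res2$p_value))

  expect_error(test_expression_shift(
    tibble::tibble(gene = "G1", patient_id = "P1", ratio = 1)), "fewer than 2")

  # under the global null the q < 0.05 fraction respects FDR control
  set.seed(801)
  G <- 400
  null_ratios <- tidyr::expand_grid(gene = paste0("G", 1:G),
                                    patient_id = paste0("P", 1:8)) |>
    dplyr::mutate(ratio = rnorm(dplyr::n()))
  res3 <- test_expression_shift(null_ratios)
  frac <- mean(res3$q_value < 0.05, na.rm = TRUE)
  expect_lte(frac, 0.05 + 2 * sqrt(0.05 * 0.95 / G))
  # BH over genes is order-invariant
  perm <- null_ratios[sample(nrow(null_ratios)), ]
  res4 <- test_expression_shift(perm)
  expect_equal(res4$q_value[match(res3$gene, res4$gene)], res3$q_value)
})

test_that("synthetic coupled genes show the configured shift signs with power", {
  cfg <- tiny_config(n_patients = 8, pairs_per_patient = 1,
                     n_chromosomes = 1, cpgs_per_chromosome = 3000,
                     expr_effect = 1, expr_noise_sd = 0.3, seed = 91L)
  co <- simulate_cohort(cfg)
  ann <- simulate_annotations(co)
  ex <- simulate_expression(co, ann)
  ratios <- expression_log2_ratios(ex$expression)
  res <- test_expression_shift(ratios, expr = ex$expression)

  # per gene-patient instance, the observed ratio sign matches the class
  inst <- dplyr::inner_join(ratios, ex$truth, by = c("gene", "patient_id")) |>
    dplyr::filter(.data$category %in% c("i", "ii", "iii"))
  expect_gt(nrow(inst), 20)
  expected_sign <- ifelse(inst$category == "i", 1, -1)
  expect_gte(mean(sign(inst$ratio) == expected_sign), 0.9)
  # class (i) instances shift positively
  expect_gte(mean(inst$ratio[inst$category == "i"] > 0), 0.9)

  # paired follow-up only for FDR hits
  hit <- res$gene[!is.na(res$q_value) & res$q_value < 0.05]
  expect_true(all(is.na(res$paired_p[!res$gene %in% hit])))
  if (length(hit) > 0) expect_true(any(!is.na(res$paired_p)))
})

test_that("methylation-expression relation classes follow the three canonical patterns", {
  expect_identical(classify_meth_expr_relation("decreased", 0.8), "i")
  expect_identical(classify_meth_expr_relation("decreased", -0.5), "ii")
  expect_identical(classify_meth_expr_relation("increased", -0.4), "iii")
  expect_identical(classify_meth_expr_relation("increased", 0.4), "other")
  expect_identical(classify_meth_expr_relation("decreased", 0), "unclassified")
  expect_identical(classify_meth_expr_relation("unchanged", 1), "unclassified")
  expect_identical(
    classify_meth_expr_relation(c("decreased", "increased"), c(1, -1)),
    c("i", "iii"))
  expect_error(classify_meth_expr_relation(c("a", "b"), 1), "equal length")
})
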