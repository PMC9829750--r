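test_that("model initialisation reflects the configuration and rejects bad input", {
  p <- hmm_init(hmm_config())
  expect_equal(unname(p$means), c(-3, 0, 3))
  expect_equal(unname(p$sds), c(0.3, 0.5, 0.3))
  expect_equal(unname(p$start), c(0.1, 0.8, 0.1))
  expect_equal(unname(rowSums(p$trans)), rep(1, 3))
  expect_error(hmm_config(sds = c(0.3, -0.5, 0.3)), "positive")
  expect_error(hmm_config(start = c(0.5, 0.5, 0.5)), "sum")
})

test_that("forward-backward matches Bayes' rule on a single observation", {
  p <- hmm_init(hmm_config())
  fb <- forward_backward(p, 3.0)
  post <- p$start * dnorm(3.0, p$means, p$sds)
  post <- post / sum(post)
  expect_equal(unname(fb$gamma[1, ]), unname(post), tolerance = 1e-12)
  expect_gt(fb$gamma[1, "+"], 0.999)
  expect_equal(fb$loglik, log(sum(p$start * dnorm(3.0, p$means, p$sds))))
})

test_that("identical emission parameters leave posteriors at the chain marginals", {
  p <- hmm_init(hmm_config(means = c(0, 0, 0), sds = c(1, 1, 1),
                           scale_means = c(0, 0, 0), shape_sds = c(0, 0, 0)))
  fb <- forward_backward(p, c(0.3, -0.2, 1.5))
  # with rows of A equal to the start distribution, marginals stay constant
  for (t in 1:3) expect_equal(unname(fb$gamma[t, ]), c(0.1, 0.8, 0.1),
                              tolerance = 1e-12)
})

test_that("forward-backward equals exhaustive path enumeration", {
  set.seed(401)
  for (rep in 1:25) {
    n <- sample(1:8, 1)
    mu <- sort(runif(3, -4, 4))
    sd <- runif(3, 0.2, 2)
    start <- random_simplex()
    trans <- random_trans()
    x <- runif(n, -5, 5)
    p <- structure(list(means = mu, sds = sd, start = start, trans = trans),
                   class = "methpair_hmm_params")
    fb <- forward_backward(p, x)
    oracle <- enum_fb(x, mu, sd, start, trans)
    expect_equal(unname(fb$gamma), oracle$gamma, tolerance = 1e-10)
    expect_equal(fb$loglik, oracle$loglik, tolerance = 1e-10)
    expect_equal(unname(rowSums(fb$gamma)), rep(1, n), tolerance = 1e-8)
  }
  expect_error(forward_backward(hmm_init(), numeric(0)), "empty")
  expect_error(forward_backward(hmm_init(), c(1, NA, 2)), "index 2")
})

test_that("flat priors reduce MAP training to maximum-likelihood Baum-Welch", {
  set.seed(77)
  x <- c(rnorm(120, 0, 0.6), rnorm(40, -2.5, 0.4), rnorm(40, 2.5, 0.4))
  x <- sample(x)  # one 200-CpG toy sequence
  cfg <- hmm_config(means = c(-2, 0, 2), sds = c(0.5, 0.5, 0.5),
                    scale_means = c(0, 0, 0), shape_sds = c(0, 0, 0),
                    max_iter = 15, tol = 1e-300)
  fit <- fit_diffmeth_hmm(x, cfg)
  ref <- ml_bw_ref(list(x), c(-2, 0, 2), c(0.5, 0.5, 0.5), c(0.1, 0.8, 0.1),
                   matrix(rep(c(0.1, 0.8, 0.1), 3), 3, byrow = TRUE),
                   n_iter = 15)
  expect_equal(unname(fit$params$means), ref$mu, tolerance = 1e-8)
  expect_equal(unname(fit$params$sds), ref$sd, tolerance = 1e-8)
  expect_equal(unname(fit$params$start), ref$start, tolerance = 1e-8)
  expect_equal(unname(fit$params$trans), unname(ref$trans), tolerance = 1e-8)
})

test_that("huge prior scale pins the altered-state means", {
  set.seed(5)
  x <- rnorm(300, 0.5, 1.5)  # data that disagrees with the pinned means
  cfg <- hmm_config(scale_means = c(1e12, 1e3, 1e12), max_iter = 40)
  fit <- fit_diffmeth_hmm(x, cfg)
  expect_lt(abs(fit$params$means[["-"]] - (-3)), 1e-3)
  expect_lt(abs(fit$params$means[["+"]] - 3), 1e-3)
})

test_that("penalized log-likelihood is non-decreasing and training recovers parameters", {
  cfg <- tiny_config(n_patients = 4, pairs_per_patient = 1,
                     n_chromosomes = 2, cpgs_per_chromosome = 1500,
                     seed = 31L)
  co <- simulate_cohort(cfg)
  fit <- fit_diffmeth_hmm(co$pairs, hmm_config(max_iter = 120))
  pll <- fit$trace$penalized
  expect_true(all(diff(pll) >= -1e-8 * pmax(1, abs(pll[-length(pll)]))))
  expect_true(fit$converged)
  expect_lt(abs(fit$params$means[["="]]), 0.05)
  expect_true(all(abs(fit$params$sds / c(0.3, 0.5, 0.3) - 1) < 0.1))

  calls <- posterior_decode(fit, co$pairs[co$pairs$pair_id == "P01_pair1", ])
  truth <- co$truth[co$truth$pair_id == "P01_pair1", ]
  acc <- mean(calls$state[match(truth$cpg_id, calls$cpg_id)] == truth$state)
  expect_gte(acc, 0.95)
})

test_that("non-convergence is flagged, not thrown", {
  set.seed(9)
  fit <- fit_diffmeth_hmm(rnorm(200), hmm_config(max_iter = 2, tol = 1e-300))
  expect_false(fit$converged)
  expect_identical(fit$n_iter, 2L)
})

test_that("states are relabelled so the trained means are ordered", {
  set.seed(12)
  x <- c(rnorm(200, -2, 0.5), rnorm(200, 2, 0.5))
  # deliberately swapped initial means with no pinning priors
  cfg <- hmm_config(means = c(2, 0, -2), sds = c(0.5, 0.5, 0.5),
                    scale_means = c(0, 0, 0), shape_sds = c(0, 0, 0),
                    max_iter = 50)
  fit <- fit_diffmeth_hmm(sample(x), cfg)
  expect_true(all(diff(fit$params$means) > 0))
})

test_that("posterior decoding applies the conservative tie rule", {
  # symmetric parameters and a symmetric observation: '-' and '+' tie
  p <- structure(list(means = c(-1, 0, 1), sds = c(0.5, 0.5, 0.5),
                      start = c(0.45, 0.1, 0.45),
                      trans = matrix(rep(c(0.45, 0.1, 0.45), 3), 3,
                                     byrow = TRUE)),
                 class = "methpair_hmm_params")
  prof <- tibble::tibble(cpg_id = "cg1", chrom = "chr1", pos = 1L, delta = 0)
  expect_identical(posterior_decode(p, prof)$state, "=")

  # uninformative emissions with '='-dominated chain: everything unchanged
  p2 <- structure(list(means = c(0, 0, 0), sds = c(1, 1, 1),
                       start = c(0.1, 0.8, 0.1),
                       trans = matrix(rep(c(0.1, 0.8, 0.1), 3), 3,
                                      byrow = TRUE)),
                  class = "methpair_hmm_params")
  prof2 <- tibble::tibble(cpg_id = paste0("cg", 1:5), chrom = "chr1",
                          pos = 1:5 * 10L, delta = rnorm(5))
  expect_true(all(posterior_decode(p2, prof2)$state == "="))

  # a clear single observation decodes to '+'
  prof3 <- tibble::tibble(cpg_id = "cg1", chrom = "chr1", pos = 1L,
                          delta = 3.0)
  expect_identical(posterior_decode(hmm_init(), prof3)$state, "+")
})

test_that("conformity is a symmetric percentage of agreeing shared CpGs", {
  a <- tibble::tibble(cpg_id = paste0("cg", 1:4),
                      state = c("-", "=", "+", "="))
  expect_equal(conformity(a, a), 100)
  b <- dplyr::mutate(a, state = c("=", "-", "=", "+"))
  expect_equal(conformity(a, b), 0)
  c2 <- dplyr::mutate(a, state = c("-", "=", "=", "+"))
  expect_equal(conformity(a, c2), 50)
  expect_equal(conformity(c2, a), conformity(a, c2))
  # intersection only
  d <- tibble::tibble(cpg_id = c("cg1", "cg9"), state = c("-", "+"))
  expect_equal(conformity(a, d), 100)
  expect_error(conformity(a, tibble::tibble(cpg_id = "zz", state = "=")),
               "share no")
})

test_that("the rank-sum comparison reproduces exact enumeration", {
  res <- conformity_group_test(c(90, 89, 88), c(80, 81, 82))
  expect_equal(res$p_value, 0.05)
  expect_equal(res$p_value, wilcox_enum_p(c(90, 89, 88), c(80, 81, 82)))
  expect_equal(res$median_within, 89)
  expect_equal(res$median_between, 81)

  # swapped groups: complement up to the point mass at the observed statistic
  swap <- conformity_group_test(c(80, 81, 82), c(90, 89, 88))
  expect_equal(swap$p_value, wilcox_enum_p(c(80, 81, 82), c(90, 89, 88)))
  expect_gte(swap$p_value + res$p_value, 1)

  # identical multisets cannot show separation
  same <- suppressWarnings(conformity_group_test(c(1, 2, 3), c(1, 2, 3)))
  expect_gte(same$p_value, 0.5)
  expect_warning(conformity_group_test(c(5, 5), c(5, 5)), "tied")
})

test_that("trained models serialize and deserialize losslessly", {
  set.seed(2)
  fit <- fit_diffmeth_hmm(c(rnorm(150), rnorm(30, -3, 0.3)),
                          hmm_config(max_iter = 10))
  tmp <- withr::local_tempfile(fileext = ".json")
  write_hmm_model(fit, tmp)
  p <- read_hmm_model(tmp)
  expect_equal(p$means, fit$params$means)
  expect_equal(p$sds, fit$params$sds)
  expect_equal(p$start, fit$params$start)
  expect_equal(p$trans, fit$params$trans)
})

test_that("tidy and glance summarise a fit", {
  set.seed(3)
  fit <- fit_diffmeth_hmm(rnorm(100), hmm_config(max_iter = 5, tol = 1e-300))
  td <- tidy(fit)
  expect_identical(td$state, c("-", "=", "+"))
  expect_identical(nrow(glance(fit)), 1L)
  expect_false(glance(fit)$converged)
})
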