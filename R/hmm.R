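#' Configuration for the three-state differential-methylation HMM
#'
#' Bundles the initialisation and prior hyperparameters of the three-state
#' first-order hidden Markov model with Gaussian emissions used to classify
#' every CpG of a patient-matched difference profile as decreased (`"-"`),
#' unchanged (`"="`) or increased (`"+"`). The defaults are the reference
#' settings for EPIC-array log2-ratio difference profiles: emission means
#' -3/0/3, standard deviations 0.3/0.5/0.3, start probabilities 0.1/0.8/0.1,
#' and strong conjugate priors that pin the two altered states (scale
#' `kappa = 1e6`, shape `alpha = 5e5`) while leaving the unchanged state
#' nearly free (`kappa = 1e3`, `alpha = 10`).
#'
#' The prior on each state's emission parameters is Normal-Inverse-Gamma:
#' `mu_i | sigma_i^2 ~ N(m_i, sigma_i^2 / kappa_i)` and
#' `sigma_i^2 ~ InvGamma(alpha_i, beta_i)` with `beta_i = (alpha_i + 1) s_i^2`
#' so that the prior mode of `sigma_i^2` equals the initial `s_i^2`.
#' `kappa_i = 0` drops the mean prior for state i; `alpha_i = 0` (a flat,
#' improper variance prior) drops the variance prior, so with both at zero
#' training reduces to maximum-likelihood Baum-Welch.
#'
#' @param means Initial emission means for states `-`, `=`, `+` (log2-ratio
#'   units).
#' @param sds Initial emission standard deviations, all positive.
#' @param start Initial state probabilities, a 3-simplex.
#' @param scale_means Prior scale `kappa_i` on the state means, nonnegative;
#'   larger values pin the trained mean to its initial value.
#' @param shape_sds Prior shape `alpha_i` on the state variances, nonnegative;
#'   `0` means a flat variance prior.
#' @param trans_init Initial transition-matrix row, a 3-simplex applied to
#'   every row.
#' @param max_iter Maximum number of EM iterations.
#' @param tol Relative change of the penalized log-likelihood below which
#'   training stops.
#'
#' @return An object of class `methpair_hmm_config`.
#' @export
#' @examples
#' hmm_config()
hmm_config <- function(means = c(-3, 0, 3),
                       sds = c(0.3, 0.5, 0.3),
                       start = c(0.1, 0.8, 0.1),
                       scale_means = c(1e6, 1e3, 1e6),
                       shape_sds = c(5e5, 10, 5e5),
                       trans_init = c(0.1, 0.8, 0.1),
                       max_iter = 500L,
                       tol = 1e-4) {
  if (length(means) != 3 || any(!is.finite(means)))
    abort("`means` must be 3 finite values.")
  if (length(sds) != 3 || any(!is.finite(sds)) || any(sds <= 0))
    abort("`sds` must be 3 positive values.")
  assert_prob_simplex(start, "start")
  assert_prob_simplex(trans_init, "trans_init")
  if (length(scale_means) != 3 || any(scale_means < 0))
    abort("`scale_means` must be 3 nonnegative values.")
  if (length(shape_sds) != 3 || any(shape_sds < 0))
    abort("`shape_sds` must be 3 nonnegative values (0 = flat variance prior).")
  if (max_iter < 1) abort("`max_iter` must be at least 1.")
  if (tol <= 0) abort("`tol` must be positive.")
  structure(
    list(means = as.numeric(means), sds = as.numeric(sds),
         start = as.numeric(start),
         scale_means = as.numeric(scale_means),
         shape_sds = as.numeric(shape_sds),
         trans_init = as.numeric(trans_init),
         max_iter = as.integer(max_iter), tol = tol),
    class = "methpair_hmm_config"
  )
}

#' Initialise HMM parameters from a configuration
#'
#' @param config A [hmm_config()] object.
#' @return An object of class `methpair_hmm_params`: a list with elements
#'   `means`, `sds`, `start` and the 3x3 row-stochastic `trans` matrix, all
#'   indexed in the fixed state order `-`, `=`, `+`.
#' @export
#' @examples
#' hmm_init(hmm_config())
hmm_init <- function(config = hmm_config()) {
  stopifnot(inherits(config, "methpair_hmm_config"))
  trans <- matrix(rep(config$trans_init, each = 3), nrow = 3,
                  dimnames = list(.states, .states))
  structure(
    list(means = setNames(config$means, .states),
         sds = setNames(config$sds, .states),
         start = setNames(config$start, .states),
         trans = trans),
    class = "methpair_hmm_params"
  )
}

as_hmm_params <- function(object) {
  if (inherits(object, "methpair_hmm")) object$params
  else if (inherits(object, "methpair_hmm_params")) object
  else abort("Expected a `methpair_hmm` fit or `methpair_hmm_params` object.")
}

check_sequence <- function(x) {
  if (length(x) == 0) abort("Observation sequence is empty.")
  bad <- which(!is.finite(x))
  if (length(bad) > 0)
    abort(sprintf("Non-finite observation at index %d.", bad[1]))
  as.numeric(x)
}

#' Exact marginal state posteriors for one observation sequence
#'
#' Runs the scaled forward-backward recursions for a single chromosome-ordered
#' sequence of log2-ratio differences under fixed parameters.
#'
#' @param params A `methpair_hmm_params` object (or a `methpair_hmm` fit).
#' @param x Numeric vector of observations.
#' @return A list with `gamma` (length(x) x 3 matrix of per-position state
#'   posteriors, rows summing to 1), `xi_sum` (3x3 matrix of summed pairwise
#'   transition expectations) and `loglik`.
#' @export
#' @examples
#' fb <- forward_backward(hmm_init(), c(0.1, -3.2, -2.9, 0.4))
#' rowSums(fb$gamma)
forward_backward <- function(params, x) {
  params <- as_hmm_params(params)
  x <- check_sequence(x)
  fb <- .fb_one_cpp(x, params$means, params$sds, params$start, params$trans)
  dimnames(fb$gamma) <- list(NULL, .states)
  dimnames(fb$xi) <- list(.states, .states)
  list(gamma = fb$gamma, xi_sum = fb$xi, loglik = fb$loglik)
}

# Log prior density of the emission parameters under the Normal-Inverse-Gamma
# scheme; states with kappa = 0 / alpha = 0 contribute no mean / variance
# term. Constant in the data, so it only shifts the penalized log-likelihood.
log_prior_density <- function(params, config) {
  lp <- 0
  for (i in 1:3) {
    k <- config$scale_means[i]; a <- config$shape_sds[i]
    m <- config$means[i]; s2 <- config$sds[i]^2
    v <- params$sds[i]^2
    if (k > 0)
      lp <- lp + 0.5 * log(k / (2 * pi * v)) -
        k * (params$means[i] - m)^2 / (2 * v)
    if (a > 0) {
      b <- (a + 1) * s2
      lp <- lp + a * log(b) - lgamma(a) - (a + 1) * log(v) - b / v
    }
  }
  unname(lp)
}

pairs_to_sequences <- function(pairs) {
  if (is.numeric(pairs)) return(list(check_sequence(pairs)))
  if (is.list(pairs) && !is.data.frame(pairs))
    return(lapply(pairs, check_sequence))
  stopifnot(is.data.frame(pairs))
  need <- c("chrom", "pos", "delta")
  if (!all(need %in% names(pairs)))
    abort("Pair-profile data must have columns chrom, pos, delta.")
  df <- pairs
  if (!"pair_id" %in% names(df)) df$pair_id <- "pair"
  df <- dplyr::arrange(df, .data$pair_id, chrom_order(.data$chrom), .data$pos)
  sp <- split(df$delta, interaction(df$pair_id, df$chrom, drop = TRUE))
  lapply(unname(sp), check_sequence)
}

#' Train the three-state HMM by MAP (Bayesian) Baum-Welch
#'
#' Fits one shared parameter set jointly over all chromosome sequences of all
#' pair profiles, so that decoded states remain comparable across patients.
#' The E-step uses scaled forward-backward recursions; the M-step maximises
#' expected log-likelihood plus log prior density exactly (see
#' [hmm_config()] for the prior), so the penalized log-likelihood is
#' non-decreasing across iterations. Start and transition probabilities get
#' plain maximum-likelihood updates from expected counts; the start
#' distribution applies independently at the first CpG of every chromosome of
#' every pair. After training, states are relabelled if necessary so that the
#' means satisfy `mu(-) < mu(=) < mu(+)`.
#'
#' @param pairs A pair-profile tibble (columns `pair_id`, `chrom`, `pos`,
#'   `delta`; see [build_pair_profile()]), a numeric vector, or a list of
#'   numeric chromosome sequences.
#' @param config A [hmm_config()].
#' @return An object of class `methpair_hmm` with elements `params`
#'   (`methpair_hmm_params`), `trace` (tibble of per-iteration log-likelihood,
#'   penalized log-likelihood and parameter snapshots), `converged`,
#'   `n_iter`, `n_obs` and `config`. Non-convergence at `max_iter` is flagged
#'   in `converged`, not an error.
#' @export
#' @examples
#' x <- c(rnorm(50), rnorm(10, -3, 0.3), rnorm(50))
#' fit <- fit_diffmeth_hmm(x, hmm_config(max_iter = 25))
#' tidy(fit)
fit_diffmeth_hmm <- function(pairs, config = hmm_config()) {
  stopifnot(inherits(config, "methpair_hmm_config"))
  seqs <- pairs_to_sequences(pairs)
  if (length(seqs) < 1) abort("At least one sequence is required.")
  n_obs <- sum(lengths(seqs))
  if (n_obs < 10) abort("At least 10 observations are required for training.")

  params <- hmm_init(config)
  kappa <- config$scale_means
  alpha <- config$shape_sds
  beta <- ifelse(alpha > 0, (alpha + 1) * config$sds^2, 0)

  trace <- vector("list", config$max_iter)
  pll_prev <- -Inf
  converged <- FALSE
  iter <- 0L

  while (iter < config$max_iter) {
    iter <- iter + 1L
    st <- .fb_stats_cpp(seqs, params$means, params$sds, params$start,
                        params$trans)
    pll <- st$loglik + log_prior_density(params, config)
    trace[[iter]] <- c(iteration = iter, loglik = st$loglik, penalized = pll,
                       setNames(params$means, paste0("mu_", c("dec", "eq", "inc"))),
                       setNames(params$sds, paste0("sd_", c("dec", "eq", "inc"))))
    if (is.finite(pll_prev) &&
        abs(pll - pll_prev) <= config$tol * abs(pll_prev)) {
      converged <- TRUE
      break
    }
    pll_prev <- pll

    g <- st$gamma_sum
    bad <- g < 1e-8 & kappa == 0
    if (any(bad))
      abort(sprintf(
        "State '%s' received no posterior mass and has no prior support (kappa = 0); variance update degenerate.",
        .states[which(bad)[1]]))

    mu <- (kappa * config$means + st$gamma_x) / (kappa + g)
    S <- st$gamma_x2 - 2 * mu * st$gamma_x + mu^2 * g
    num <- S + ifelse(kappa > 0, kappa * (mu - config$means)^2, 0) + 2 * beta
    den <- g + (kappa > 0) + ifelse(alpha > 0, 2 * alpha + 2, 0)
    s2 <- pmax(num / den, 1e-6)

    start <- st$gamma_first / sum(st$gamma_first)
    trans <- st$xi_sum
    rs <- rowSums(trans)
    for (i in 1:3) {
      trans[i, ] <- if (rs[i] > 0) trans[i, ] / rs[i] else params$trans[i, ]
    }

    params$means <- setNames(mu, .states)
    params$sds <- setNames(sqrt(s2), .states)
    params$start <- setNames(start, .states)
    params$trans <- trans
    dimnames(params$trans) <- list(.states, .states)
  }

  # guard against label switching when priors are weak
  ord <- order(params$means)
  if (!identical(ord, 1:3)) {
    params$means <- setNames(params$means[ord], .states)
    params$sds <- setNames(params$sds[ord], .states)
    params$start <- setNames(params$start[ord], .states)
    params$trans <- params$trans[ord, ord]
    dimnames(params$trans) <- list(.states, .states)
  }

  structure(
    list(params = params,
         trace = as_tibble(do.call(rbind, trace[seq_len(iter)])),
         converged = converged, n_iter = iter, n_obs = n_obs,
         config = config),
    class = "methpair_hmm"
  )
}

#' @export
print.methpair_hmm <- function(x, ...) {
  cat("Three-state differential-methylation HMM\n")
  cat(sprintf("  %d observations, %d EM iterations, %s\n", x$n_obs, x$n_iter,
              if (x$converged) "converged" else "NOT converged (max_iter)"))
  cat("  means:", sprintf("%.3f", x$params$means), "\n")
  cat("  sds:  ", sprintf("%.3f", x$params$sds), "\n")
  invisible(x)
}

#' @describeIn fit_diffmeth_hmm One row per state with trained emission and
#'   start parameters.
#' @param x,object A `methpair_hmm` fit.
#' @param ... Unused.
#' @export
tidy.methpair_hmm <- function(x, ...) {
  tibble(state = .states,
         mean = unname(x$params$means),
         sd = unname(x$params$sds),
         start_prob = unname(x$params$start),
         self_transition = diag(x$params$trans))
}

#' @describeIn fit_diffmeth_hmm One-row model summary.
#' @export
glance.methpair_hmm <- function(x, ...) {
  tibble(n_obs = x$n_obs, n_iter = x$n_iter, converged = x$converged,
         loglik = x$trace$loglik[nrow(x$trace)],
         penalized_loglik = x$trace$penalized[nrow(x$trace)])
}

#' Posterior decoding of a pair profile
#'
#' Assigns each CpG the state with maximal marginal posterior, computed per
#' chromosome by forward-backward. An exact posterior tie is resolved to
#' `"="`: no alteration is claimed without a posterior majority.
#'
#' @param object A trained `methpair_hmm` fit or bare parameters.
#' @param profile A pair-profile tibble (columns `cpg_id`, `chrom`, `pos`,
#'   `delta`).
#' @return A tibble of state calls: the profile columns plus `state` and the
#'   posterior columns `gamma_dec`, `gamma_eq`, `gamma_inc`.
#' @export
#' @examples
#' prof <- tibble::tibble(cpg_id = c("cg1", "cg2"), chrom = "chr1",
#'                        pos = c(10L, 60L), delta = c(0.1, 3.1))
#' posterior_decode(hmm_init(), prof)
posterior_decode <- function(object, profile) {
  params <- as_hmm_params(object)
  need <- c("cpg_id", "chrom", "pos", "delta")
  if (!all(need %in% names(profile)))
    abort("`profile` must have columns cpg_id, chrom, pos, delta.")
  profile <- dplyr::arrange(profile, chrom_order(.data$chrom), .data$pos)
  parts <- split(profile, chrom_order(profile$chrom), drop = TRUE)
  out <- purrr::map(parts, function(p) {
    fb <- forward_backward(params, p$delta)
    g <- fb$gamma
    gmax <- apply(g, 1, max)
    tied <- (gmax - g) < 1e-12
    state <- .states[max.col(g, ties.method = "first")]
    state[rowSums(tied) > 1] <- "="
    p$state <- state
    p$gamma_dec <- g[, 1]; p$gamma_eq <- g[, 2]; p$gamma_inc <- g[, 3]
    p
  })
  dplyr::bind_rows(out)
}

#' Conformity of two sets of state calls
#'
#' Percentage of shared CpGs (intersection of the two call sets) on which the
#' decoded states agree. Symmetric in its arguments.
#'
#' @param calls_a,calls_b State-call tibbles from [posterior_decode()] (need
#'   columns `cpg_id`, `state`).
#' @return A single percentage in \[0, 100\].
#' @export
conformity <- function(calls_a, calls_b) {
  j <- dplyr::inner_join(
    dplyr::select(calls_a, "cpg_id", state_a = "state"),
    dplyr::select(calls_b, "cpg_id", state_b = "state"),
    by = "cpg_id")
  if (nrow(j) == 0) abort("The two call sets share no CpGs.")
  100 * mean(j$state_a == j$state_b)
}

#' Compare within-patient to between-patient conformity
#'
#' One-sided Wilcoxon rank-sum test that within-patient conformities exceed
#' between-patient conformities: exact when the combined sample size is at
#' most 10 and there are no ties, otherwise the normal approximation with tie
#' correction.
#'
#' @param within,between Numeric vectors of conformity percentages.
#' @return A one-row tibble with `median_within`, `median_between`,
#'   `statistic` (rank-sum W) and `p_value`.
#' @export
#' @examples
#' conformity_group_test(c(90, 89, 88), c(80, 81, 82))
conformity_group_test <- function(within, between) {
  if (length(within) == 0 || length(between) == 0)
    abort("Both groups must be non-empty.")
  all_vals <- c(within, between)
  if (length(unique(all_vals)) == 1) {
    warn("All conformities are tied across both groups; p = 1.")
    return(tibble(median_within = median(within),
                  median_between = median(between),
                  statistic = NA_real_, p_value = 1))
  }
  use_exact <- length(all_vals) <= 10 && !any(duplicated(all_vals))
  wt <- suppressWarnings(
    wilcox.test(within, between, alternative = "greater",
                exact = use_exact, correct = !use_exact))
  tibble(median_within = median(within), median_between = median(between),
         statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Serialize a trained HMM to JSON
#'
#' @param fit A `methpair_hmm` fit.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_hmm_model <- function(fit, path) {
  stopifnot(inherits(fit, "methpair_hmm"))
  obj <- list(
    means = unname(fit$params$means), sds = unname(fit$params$sds),
    start = unname(fit$params$start),
    trans = unname(apply(fit$params$trans, 1, function(r) unname(r),
                         simplify = FALSE)),
    converged = fit$converged, n_iter = fit$n_iter, n_obs = fit$n_obs,
    config = fit$config[c("means", "sds", "start", "scale_means",
                          "shape_sds", "trans_init", "max_iter", "tol")],
    final_loglik = fit$trace$loglik[nrow(fit$trace)])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read HMM parameters back from JSON
#'
#' @param path File written by [write_hmm_model()].
#' @return A `methpair_hmm_params` object.
#' @export
read_hmm_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tm <- obj$trans
  tm <- if (is.matrix(tm)) matrix(as.numeric(tm), nrow = 3)
        else matrix(as.numeric(unlist(tm)), nrow = 3, byrow = TRUE)
  dimnames(tm) <- list(.states, .states)
  structure(
    list(means = setNames(as.numeric(obj$means), .states),
         sds = setNames(as.numeric(obj$sds), .states),
         start = setNames(as.numeric(obj$start), .states),
         trans = tm),
    class = "methpair_hmm_params"
  )
}
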