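#' Configuration for a synthetic patient-matched methylome cohort
#'
#' Describes the generative model used to emulate a cohort of patient-matched
#' intracranial/extracranial methylome pairs: per-chromosome ordered CpGs; a
#' three-state first-order Markov chain over decreased/unchanged/increased
#' methylation with Gaussian emissions for the pair difference profile; a
#' shared per-patient baseline plus tissue noise at the sample level (so
#' hierarchical clustering groups samples by patient); and a base truth path
#' shared, up to label noise, by multiple pairs of the same patient.
#'
#' The default emission and start settings are the reference settings for
#' EPIC log2-ratio difference profiles (means -3/0/3, SDs 0.3/0.5/0.3, start
#' 0.1/0.8/0.1) and the default pair layout mirrors a 14-patient cohort with
#' 24 pairs. The transition matrix is built as
#' `A = s*I + (1-s)*1 pi'` with `s = self_transition` and `pi = start_probs`,
#' which makes `start_probs` the exact stationary distribution of the chain.
#'
#' @param n_patients Number of patients.
#' @param pairs_per_patient Integer vector (length 1 or `n_patients`) of
#'   metastases pairs per patient.
#' @param n_chromosomes,cpgs_per_chromosome Synthetic genome size
#'   (`cpgs_per_chromosome >= 2`).
#' @param state_means,state_sds Gaussian emission means/SDs for states
#'   `-`, `=`, `+` (log2-ratio units; SDs positive).
#' @param start_probs State distribution at each chromosome start; also the
#'   stationary distribution of the chain. Must sum to 1 within 1e-12.
#' @param self_transition Probability mass kept on the current state before
#'   redistributing `1 - self_transition` according to `start_probs`.
#' @param patient_effect_sd,tissue_effect_sd SDs of the per-patient baseline
#'   profile and of per-sample tissue noise (log2-ratio units). A large ratio
#'   `patient_effect_sd / tissue_effect_sd` yields patient-dominated
#'   clustering.
#' @param label_noise Fraction of CpGs at which a pair's truth path is
#'   resampled from `start_probs` independently of the patient's base path
#'   (emulates histologically distinct regions of one metastasis).
#' @param altered_fraction_targets Optional per-pair targets: a data frame
#'   with columns `frac_dec`, `frac_inc` and one row per pair. When given,
#'   each pair's chain uses its own stationary distribution
#'   `(frac_dec, 1 - frac_dec - frac_inc, frac_inc)` and truth paths are
#'   drawn per pair (no shared base path).
#' @param expr_effect,expr_noise_sd Expression coupling shift (log2 units)
#'   and additive Gaussian noise SD for [simulate_expression()].
#' @param treatment_probs Named probabilities over treatment groups
#'   `untreated`, `im_treated`, `im_em_treated`, `unknown`.
#' @param seed Integer master seed; expanded into per-stream sub-seeds so
#'   cohort, annotations, expression and clinical tables can be regenerated
#'   independently.
#'
#' @return An object of class `methpair_sim_config`.
#' @export
#' @examples
#' sim_config(n_patients = 2, pairs_per_patient = 1,
#'            cpgs_per_chromosome = 100)
sim_config <- function(n_patients = 14,
                       pairs_per_patient = c(1, 1, 2, 2, 3, 1, 1, 2, 2, 1, 1, 2, 1, 4),
                       n_chromosomes = 2,
                       cpgs_per_chromosome = 5000,
                       state_means = c(-3, 0, 3),
                       state_sds = c(0.3, 0.5, 0.3),
                       start_probs = c(0.1, 0.8, 0.1),
                       self_transition = 0.9,
                       patient_effect_sd = 2,
                       tissue_effect_sd = 0.25,
                       label_noise = 0.05,
                       altered_fraction_targets = NULL,
                       expr_effect = 1,
                       expr_noise_sd = 0.3,
                       treatment_probs = c(untreated = 8, im_treated = 2,
                                           im_em_treated = 3, unknown = 1) / 14,
                       seed = 1L) {
  if (n_patients < 1) abort("`n_patients` must be at least 1.")
  if (length(pairs_per_patient) == 1)
    pairs_per_patient <- rep(pairs_per_patient, n_patients)
  if (length(pairs_per_patient) != n_patients)
    abort("`pairs_per_patient` must have length 1 or `n_patients`.")
  if (any(pairs_per_patient < 1)) abort("Every patient needs >= 1 pair.")
  if (cpgs_per_chromosome < 2) abort("`cpgs_per_chromosome` must be >= 2.")
  if (n_chromosomes < 1) abort("`n_chromosomes` must be >= 1.")
  assert_prob_simplex(start_probs, "start_probs")
  if (length(state_sds) != 3 || any(state_sds <= 0))
    abort("`state_sds` must be 3 positive values.")
  if (length(state_means) != 3) abort("`state_means` must have length 3.")
  if (self_transition < 0 || self_transition > 1)
    abort("`self_transition` must be in [0, 1].")
  if (patient_effect_sd < 0 || tissue_effect_sd < 0)
    abort("Effect SDs must be nonnegative.")
  if (label_noise < 0 || label_noise > 1)
    abort("`label_noise` must be in [0, 1].")
  n_pairs <- sum(pairs_per_patient)
  if (!is.null(altered_fraction_targets)) {
    aft <- as_tibble(altered_fraction_targets)
    if (!all(c("frac_dec", "frac_inc") %in% names(aft)) ||
        nrow(aft) != n_pairs)
      abort("`altered_fraction_targets` needs columns frac_dec, frac_inc and one row per pair.")
    if (any(aft$frac_dec + aft$frac_inc >= 1) ||
        any(aft$frac_dec < 0) || any(aft$frac_inc < 0))
      abort("Altered fraction targets must be nonnegative and sum below 1.")
    altered_fraction_targets <- aft
  }
  if (abs(sum(treatment_probs) - 1) > 1e-8 || any(treatment_probs < 0))
    abort("`treatment_probs` must be nonnegative and sum to 1.")
  structure(
    list(n_patients = as.integer(n_patients),
         pairs_per_patient = as.integer(pairs_per_patient),
         n_chromosomes = as.integer(n_chromosomes),
         cpgs_per_chromosome = as.integer(cpgs_per_chromosome),
         state_means = as.numeric(state_means),
         state_sds = as.numeric(state_sds),
         start_probs = as.numeric(start_probs),
         self_transition = self_transition,
         patient_effect_sd = patient_effect_sd,
         tissue_effect_sd = tissue_effect_sd,
         label_noise = label_noise,
         altered_fraction_targets = altered_fraction_targets,
         expr_effect = expr_effect, expr_noise_sd = expr_noise_sd,
         treatment_probs = treatment_probs,
         seed = as.integer(seed)),
    class = "methpair_sim_config"
  )
}

# A = s*I + (1-s) * rep-row(pi): pi is exactly stationary.
stationary_transition <- function(self_transition, pi) {
  self_transition * diag(3) +
    (1 - self_transition) * matrix(pi, nrow = 3, ncol = 3, byrow = TRUE)
}

# Draw one state path of length n from the chain (integer states 1:3).
markov_path <- function(n, start, trans) {
  s <- integer(n)
  s[1] <- sample.int(3, 1, prob = start)
  if (n > 1) {
    u <- runif(n - 1)
    cums <- t(apply(trans, 1, cumsum))
    for (t in 2:n) {
      s[t] <- findInterval(u[t - 1], cums[s[t - 1], ]) + 1L
    }
  }
  s
}

#' Simulate a patient-matched methylome cohort with ground truth
#'
#' Draws, for every pair, a true state path from the configured Markov chain
#' (restarting from `start_probs` at every chromosome boundary) and the pair
#' difference value per CpG from the corresponding state's Gaussian. Pairs of
#' the same patient share a base truth path up to `label_noise`. Two
#' per-sample methylome tables are emitted per pair whose difference
#' reproduces the pair delta exactly: the extracranial sample is the
#' patient's baseline profile plus tissue noise, and the intracranial sample
#' is the extracranial sample plus the pair delta.
#'
#' @param config A [sim_config()].
#' @return An object of class `methpair_cohort`: a list with tibbles
#'   `samples` (per-sample CpG log2-ratios), `pairs` (pair difference
#'   profiles as produced by [build_pair_profile()]), `truth` (per pair and
#'   CpG the true state, plus `patient_effects`), and the `config`.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_patients = 2, pairs_per_patient = 1,
#'                                      cpgs_per_chromosome = 50))
#' head(cohort$pairs)
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "methpair_sim_config"))
  n_chr <- config$n_chromosomes
  n_cpg <- config$cpgs_per_chromosome

  coords <- with_seed(stream_seed(config$seed, "coords"), {
    purrr::map_dfr(seq_len(n_chr), function(ch) {
      gaps <- 2 + round(rexp(n_cpg, 1 / 1500))
      tibble(chrom = paste0("chr", ch), pos = cumsum(gaps) + 1000L)
    })
  })
  coords$cpg_id <- sprintf("cg%08d", seq_len(nrow(coords)))
  n_total <- nrow(coords)

  patients <- sprintf("P%02d", seq_len(config$n_patients))
  tissues <- c("lung", "lymph_node", "skin", "soft_tissue", "liver")

  per_pair_pi <- function(k) {
    if (is.null(config$altered_fraction_targets)) config$start_probs
    else {
      t <- config$altered_fraction_targets[k, ]
      c(t$frac_dec, 1 - t$frac_dec - t$frac_inc, t$frac_inc)
    }
  }

  truth_states <- with_seed(stream_seed(config$seed, "truth"), {
    pair_k <- 0L
    out <- list()
    for (p in seq_along(patients)) {
      npair <- config$pairs_per_patient[p]
      base <- NULL
      if (is.null(config$altered_fraction_targets)) {
        A <- stationary_transition(config$self_transition, config$start_probs)
        base <- unlist(lapply(seq_len(n_chr), function(ch)
          markov_path(n_cpg, config$start_probs, A)))
      }
      for (q in seq_len(npair)) {
        pair_k <- pair_k + 1L
        if (is.null(base)) {
          pi_k <- per_pair_pi(pair_k)
          A <- stationary_transition(config$self_transition, pi_k)
          st <- unlist(lapply(seq_len(n_chr), function(ch)
            markov_path(n_cpg, pi_k, A)))
        } else {
          st <- base
          if (config$label_noise > 0) {
            flip <- runif(n_total) < config$label_noise
            st[flip] <- sample.int(3, sum(flip), replace = TRUE,
                                   prob = config$start_probs)
          }
        }
        out[[pair_k]] <- st
      }
    }
    out
  })

  pair_meta <- with_seed(stream_seed(config$seed, "tissues"), {
    tibble(
      patient_id = rep(patients, config$pairs_per_patient),
      pair_index = unlist(lapply(config$pairs_per_patient, seq_len)),
      extracranial_tissue = rep(
        sample(tissues, config$n_patients, replace = TRUE,
               prob = c(6, 4, 2, 1, 1) / 14),
        config$pairs_per_patient))
  })
  pair_meta$pair_id <- sprintf("%s_pair%d", pair_meta$patient_id,
                               pair_meta$pair_index)

  deltas <- with_seed(stream_seed(config$seed, "emissions"), {
    lapply(truth_states, function(st)
      rnorm(n_total, mean = config$state_means[st], sd = config$state_sds[st]))
  })

  sample_parts <- with_seed(stream_seed(config$seed, "samples"), {
    baselines <- lapply(patients, function(p)
      rnorm(n_total, 0, config$patient_effect_sd))
    names(baselines) <- patients
    lapply(seq_len(nrow(pair_meta)), function(k) {
      pid <- pair_meta$patient_id[k]
      extra_val <- baselines[[pid]] + rnorm(n_total, 0, config$tissue_effect_sd)
      intra_val <- extra_val + deltas[[k]]
      list(extra = extra_val, intra = intra_val)
    })
  })
  # the profile delta is the literal sample difference (exact, to the bit);
  # it deviates from the drawn emission by at most one ulp
  deltas <- lapply(sample_parts, function(sp) sp$intra - sp$extra)

  pairs <- purrr::map_dfr(seq_len(nrow(pair_meta)), function(k) {
    tibble(pair_id = pair_meta$pair_id[k],
           patient_id = pair_meta$patient_id[k],
           extracranial_tissue = pair_meta$extracranial_tissue[k],
           cpg_id = coords$cpg_id, chrom = coords$chrom, pos = coords$pos,
           delta = deltas[[k]])
  })

  samples <- {
    purrr::map_dfr(seq_len(nrow(pair_meta)), function(k) {
      pid <- pair_meta$patient_id[k]
      extra_val <- sample_parts[[k]]$extra
      intra_val <- sample_parts[[k]]$intra
      dplyr::bind_rows(
        tibble(sample_id = sprintf("%s_intra%d", pid, pair_meta$pair_index[k]),
               patient_id = pid, tissue = "brain", role = "intra",
               pair_id = pair_meta$pair_id[k],
               cpg_id = coords$cpg_id, chrom = coords$chrom, pos = coords$pos,
               log2ratio = intra_val),
        tibble(sample_id = sprintf("%s_extra%d", pid, pair_meta$pair_index[k]),
               patient_id = pid, tissue = pair_meta$extracranial_tissue[k],
               role = "extra", pair_id = pair_meta$pair_id[k],
               cpg_id = coords$cpg_id, chrom = coords$chrom, pos = coords$pos,
               log2ratio = extra_val))
    })
  }

  truth <- purrr::map_dfr(seq_len(nrow(pair_meta)), function(k) {
    tibble(pair_id = pair_meta$pair_id[k],
           patient_id = pair_meta$patient_id[k],
           cpg_id = coords$cpg_id, chrom = coords$chrom, pos = coords$pos,
           state = .states[truth_states[[k]]])
  })

  structure(
    list(samples = samples, pairs = pairs,
         truth = truth, coords = coords, pair_meta = pair_meta,
         config = config),
    class = "methpair_cohort"
  )
}

#' @export
print.methpair_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic methylome cohort: %d patients, %d pairs, %d chromosomes x %d CpGs\n",
    x$config$n_patients, nrow(x$pair_meta), x$config$n_chromosomes,
    x$config$cpgs_per_chromosome))
  invisible(x)
}

#' CpG-by-sample matrix of a simulated cohort
#'
#' @param cohort A `methpair_cohort`.
#' @return A numeric matrix, rows = CpGs (genome order), columns = samples,
#'   suitable for [manhattan_distances()].
#' @export
cohort_sample_matrix <- function(cohort) {
  wide <- tidyr::pivot_wider(
    cohort$samples[, c("cpg_id", "sample_id", "log2ratio")],
    names_from = "sample_id", values_from = "log2ratio")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$cpg_id
  m[cohort$coords$cpg_id, , drop = FALSE]
}
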