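#' Autocorrelation of a pair difference profile
#'
#' Computes, per chromosome, the Pearson autocorrelation of the
#' chromosome-ordered delta sequence at positional (rank) lags 1..`max_lag`:
#' `rho(k) = cor(x[1..(n-k)], x[(1+k)..n])`. The aggregate curve is the
#' median over chromosomes. Strong positive `rho` at small lags is what
#' motivates segmenting these profiles with an HMM rather than calling CpGs
#' independently.
#'
#' @param profile A pair-profile tibble (columns `chrom`, `pos`, `delta`).
#' @param max_lag Largest positional lag; must be smaller than the shortest
#'   chromosome sequence.
#' @return A tibble of class `methpair_autocorr` with columns `lag` and
#'   `median_rho`; the per-chromosome curves are in
#'   `attr(, "per_chromosome")` (columns `chrom`, `lag`, `rho`).
#' @export
autocorr_curve <- function(profile, max_lag = 100) {
  if (max_lag < 1) abort("Lags start at 1; `max_lag` must be >= 1.")
  profile <- dplyr::arrange(profile, chrom_order(.data$chrom), .data$pos)
  seqs <- split(profile$delta, chrom_order(profile$chrom), drop = TRUE)
  per <- purrr::imap(seqs, function(x, nm) {
    tibble(chrom = nm, lag = seq_len(max_lag), rho = seq_rho(x, max_lag))
  })
  per <- dplyr::bind_rows(per)
  agg <- dplyr::summarise(dplyr::group_by(per, .data$lag),
                          median_rho = median(.data$rho), .groups = "drop")
  structure(agg, per_chromosome = per,
            class = c("methpair_autocorr", class(agg)))
}

# rho(k) for one chromosome sequence at lags 1..max_lag.
seq_rho <- function(x, max_lag) {
  n <- length(x)
  if (n <= max_lag)
    abort(sprintf(
      "Chromosome sequence of length %d is too short for max_lag %d.",
      n, max_lag))
  if (var(x) == 0)
    abort("Constant sequence: autocorrelation is undefined.")
  vapply(seq_len(max_lag), function(k) {
    a <- x[seq_len(n - k)]; b <- x[seq_len(n - k) + k]
    if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
    cor(a, b)
  }, numeric(1))
}

#' Permutation null band for autocorrelation curves
#'
#' Shuffles the delta values within each chromosome of each profile,
#' recomputes the aggregated median autocorrelation curve (median over
#' chromosomes within a pair, then over pairs), and returns per-lag quantiles
#' of the permuted curves. Destroying the genomic order this way removes the
#' local dependence, so the observed curve of a genuinely persistent profile
#' should sit above the upper band.
#'
#' @param profiles A single pair-profile tibble or a list of them (a tibble
#'   with a `pair_id` column is split on it).
#' @param max_lag Largest positional lag.
#' @param n_perm Number of permuted profile sets; 1000 gives stable
#'   0.5%/99.5% quantiles.
#' @param seed Integer seed; same seed, same bands.
#' @param probs Quantile levels of the null band.
#' @return A tibble of class `methpair_permband` with columns `lag`,
#'   `median_perm` and one `q*` column per level in `probs`; the observed
#'   aggregated curve is in `attr(, "observed")`.
#' @export
permutation_band <- function(profiles, max_lag = 100, n_perm = 1000,
                             seed = 1L,
                             probs = c(0.005, 0.25, 0.75, 0.995)) {
  if (n_perm < 1) abort("`n_perm` must be at least 1.")
  plist <- if (is.data.frame(profiles)) {
    if ("pair_id" %in% names(profiles))
      split(profiles, profiles$pair_id) else list(profiles)
  } else profiles
  plist <- lapply(plist, function(p)
    dplyr::arrange(p, chrom_order(.data$chrom), .data$pos))
  seq_sets <- lapply(plist, function(p)
    split(p$delta, chrom_order(p$chrom), drop = TRUE))

  agg_curve <- function(sets) {
    # median over chromosomes within a pair, then median over pairs
    per_pair <- vapply(sets, function(seqs) {
      rhos <- vapply(seqs, seq_rho, numeric(max_lag), max_lag = max_lag)
      apply(matrix(rhos, nrow = max_lag), 1, median)
    }, numeric(max_lag))
    apply(matrix(per_pair, nrow = max_lag), 1, median)
  }

  observed <- agg_curve(seq_sets)
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      shuffled <- lapply(seq_sets, function(seqs) lapply(seqs, sample))
      agg_curve(shuffled)
    }, numeric(max_lag))
  })
  perm <- matrix(perm, nrow = max_lag)
  qs <- t(apply(perm, 1, quantile, probs = probs))
  colnames(qs) <- paste0("q", sub("^0\\.", "", formatC(probs, format = "fg")))
  out <- dplyr::bind_cols(
    tibble(lag = seq_len(max_lag), median_perm = apply(perm, 1, median)),
    as_tibble(qs))
  structure(out,
            observed = tibble(lag = seq_len(max_lag), median_rho = observed),
            n_perm = n_perm, seed = seed,
            class = c("methpair_permband", class(out)))
}

#' Plot an autocorrelation curve against its permutation band
#'
#' @param object A `methpair_permband` from [permutation_band()].
#' @param ... Unused.
#' @return A ggplot: observed median autocorrelation per lag (line) over the
#'   permutation null quantile ribbons.
#' @export
autoplot.methpair_permband <- function(object, ...) {
  obs <- attr(object, "observed")
  band <- as_tibble(object)
  qcols <- grep("^q", names(band), value = TRUE)
  lo <- band[[qcols[1]]]; hi <- band[[qcols[length(qcols)]]]
  ggplot2::ggplot(band, ggplot2::aes(x = .data$lag)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = lo, ymax = hi),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$median_perm),
                       colour = "grey40", linetype = 2) +
    ggplot2::geom_line(data = obs,
                       ggplot2::aes(y = .data$median_rho), colour = "red") +
    ggplot2::labs(x = "positional lag (CpGs)",
                  y = "median autocorrelation",
                  title = "Observed vs permuted autocorrelation") +
    ggplot2::theme_minimal()
}
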