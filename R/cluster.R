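#' Manhattan distances between sample methylomes
#'
#' `d(a, b) = sum_f |a_f - b_f|` over the shared feature set, the metric of
#' choice for very high-dimensional methylome profiles.
#'
#' @param samples A numeric matrix (rows = features/CpGs, columns = samples)
#'   or a data frame of numeric sample columns. No missing values: callers
#'   drop incomplete features first.
#' @return A `dist` object over the samples.
#' @export
#' @examples
#' m <- cbind(a = c(0, 0), b = c(1, 2))
#' manhattan_distances(m)  # d(a, b) = 3
manhattan_distances <- function(samples) {
  m <- as.matrix(samples)
  if (!is.numeric(m)) abort("`samples` must be numeric.")
  if (ncol(m) < 2) abort("At least 2 samples are required.")
  if (anyNA(m))
    abort("Missing values in the feature matrix; drop incomplete features first.")
  dist(t(m), method = "manhattan")
}

#' Ward (ward.D2) hierarchical clustering
#'
#' Agglomerative variance-minimising clustering under the ward.D2 convention
#' (distances squared internally, merge heights reported on the original
#' scale).
#'
#' @param d A `dist` object, e.g. from [manhattan_distances()].
#' @return An `hclust` tree.
#' @export
ward_cluster <- function(d) {
  if (!inherits(d, "dist")) d <- as.dist(d)
  if (attr(d, "Size") < 2) abort("At least 2 samples are required.")
  hclust(d, method = "ward.D2")
}

# Leaf-label sets of the n-1 internal nodes of an hclust tree, each sorted;
# used as the identity of a cluster across bootstrap trees.
node_leaf_sets <- function(hc) {
  n <- length(hc$labels)
  sets <- vector("list", n - 1)
  for (k in seq_len(n - 1)) {
    members <- integer(0)
    for (child in hc$merge[k, ]) {
      members <- c(members, if (child < 0) -child else sets[[child]])
    }
    sets[[k]] <- sort(members)
  }
  lapply(sets, function(ix) sort(hc$labels[ix]))
}

#' Bootstrap support (BP and AU) for dendrogram nodes
#'
#' Multiscale bootstrap of the feature set: features are resampled with
#' replacement at relative sizes `r` in `scales`, the tree is rebuilt
#' (Manhattan distance + ward.D2 by default) and, for every internal node of
#' the original tree, `BP_r` is the fraction of bootstrap trees containing
#' that node's exact leaf set. The approximately unbiased support is
#' obtained from the multiscale model: a weighted least-squares fit of
#' `z(BP_r) = d*sqrt(r) + c/sqrt(r)` with `z = qnorm(1 - BP_r)`, giving
#' `AU = 100 * pnorm(c - d)` under the standard signed-distance/curvature
#' model. A node seen in every replicate at every scale has BP = AU = 100; a
#' node never seen at any scale has BP = 0 and missing AU. A degenerate BP
#' pattern that defeats the fit falls back to BP only (flagged by `au_ok`).
#'
#' @param samples Feature matrix (rows = features, columns = samples).
#' @param n_boot Bootstrap replicates per scale (>= 100; 10,000 is a
#'   common full-scale choice, 1000 a desk-scale default).
#' @param scales Relative resampling sizes; at least 3 values for AU.
#' @param seed Integer seed.
#' @param distance,linkage Passed through to the tree construction.
#' @return An object of class `methpair_boot`: list with the original
#'   `hclust` tree and a tibble `support` (`node`, `n_leaves`, `members`,
#'   `bp`, `au`, `au_ok`), BP/AU on the 0-100 scale.
#' @export
bootstrap_support <- function(samples, n_boot = 1000,
                              scales = seq(0.5, 1.4, by = 0.1), seed = 1L,
                              distance = manhattan_distances,
                              linkage = ward_cluster) {
  if (n_boot < 100) abort("`n_boot` must be at least 100 for BP values.")
  if (length(scales) < 3) abort("At least 3 scale factors are needed for AU.")
  m <- as.matrix(samples)
  if (anyNA(m)) abort("Missing values in the feature matrix.")
  nf <- nrow(m)
  hc <- linkage(distance(m))
  sets <- node_leaf_sets(hc)
  keys <- vapply(sets, paste, character(1), collapse = "\r")

  counts <- with_seed(seed, {
    vapply(scales, function(r) {
      size <- max(2L, round(r * nf))
      cnt <- numeric(length(keys))
      for (b in seq_len(n_boot)) {
        idx <- sample.int(nf, size, replace = TRUE)
        bt <- linkage(distance(m[idx, , drop = FALSE]))
        bkeys <- vapply(node_leaf_sets(bt), paste, character(1),
                        collapse = "\r")
        cnt <- cnt + (keys %in% bkeys)
      }
      cnt
    }, numeric(length(keys)))
  })
  counts <- matrix(counts, nrow = length(keys))
  bp_r <- counts / n_boot

  # BP at scale r = 1 (or the scale closest to 1)
  r1 <- which.min(abs(scales - 1))
  support <- purrr::map_dfr(seq_along(keys), function(k) {
    bp_k <- bp_r[k, ]
    au <- NA_real_; au_ok <- FALSE
    if (all(counts[k, ] == n_boot)) {
      au <- 100; au_ok <- TRUE
    } else if (all(counts[k, ] == 0)) {
      au <- NA_real_
    } else {
      # clamp counts away from 0/1 for finite z
      p <- pmin(pmax(counts[k, ], 0.5), n_boot - 0.5) / n_boot
      z <- qnorm(1 - p)
      wt <- n_boot * dnorm(z)^2 / (p * (1 - p))
      X <- cbind(sqrt(scales), 1 / sqrt(scales))
      fit <- tryCatch(stats::lm.wfit(X, z, wt), error = function(e) NULL)
      if (!is.null(fit) && all(is.finite(fit$coefficients))) {
        d_hat <- fit$coefficients[1]; c_hat <- fit$coefficients[2]
        au <- 100 * pnorm(c_hat - d_hat)
        au_ok <- TRUE
      }
    }
    tibble(node = k, n_leaves = length(sets[[k]]),
           members = paste(sets[[k]], collapse = ","),
           bp = 100 * bp_k[r1], au = au, au_ok = au_ok)
  })

  structure(list(hclust = hc, support = support, n_boot = n_boot,
                 scales = scales, seed = seed),
            class = "methpair_boot")
}

#' @export
print.methpair_boot <- function(x, ...) {
  cat(sprintf("Multiscale bootstrap of %d-leaf ward.D2 tree (%d reps x %d scales)\n",
              length(x$hclust$labels), x$n_boot, length(x$scales)))
  print(x$support, n = 10)
  invisible(x)
}

#' Export a supported dendrogram as Newick text
#'
#' Internal nodes are labelled `BP|AU` (rounded to integers; `NA` AU written
#' as `.`), leaves keep their sample labels.
#'
#' @param boot A [bootstrap_support()] result.
#' @param path Optional output file; when `NULL` the string is returned.
#' @return The Newick string, invisibly when written to `path`.
#' @export
newick_support <- function(boot, path = NULL) {
  hc <- boot$hclust
  sup <- boot$support
  lab <- function(k) {
    s <- sup[sup$node == k, ]
    sprintf("%.0f|%s", s$bp, ifelse(is.na(s$au), ".", sprintf("%.0f", s$au)))
  }
  build <- function(k) {
    ch <- vapply(hc$merge[k, ], function(child) {
      if (child < 0) hc$labels[-child] else build(child)
    }, character(1))
    sprintf("(%s,%s)%s:%g", ch[1], ch[2], lab(k), hc$height[k])
  }
  nwk <- paste0(build(nrow(hc$merge)), ";")
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}
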