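# Evaluation metrics for distributed source estimates: a two-sided ROC-AUC
# that scores near-field and far-field discrimination separately, a maxima
# detector with non-maximum suppression, localization-error / ghost / missed
# bookkeeping, squared-error measures, and nonparametric comparison tests.

#' Two-sided localization AUC
#'
#' ROC area for discriminating active from inactive vertices, computed twice
#' with different negative pools and averaged: `close` negatives are drawn
#' from the 20% of inactive vertices nearest to any active vertex (penalizes
#' blur around the source), `far` negatives from the 50% farthest (penalizes
#' spurious distant activity). Each pool is subsampled without replacement to
#' the number of positives and the ROC is integrated by the trapezoid rule.
#'
#' @param j_true numeric p-vector of true moments (vertices with nonzero
#'   moment are the positives).
#' @param j_hat numeric p-vector of estimated moments (absolute values are
#'   used as scores).
#' @param positions p x 3 matrix of vertex positions.
#' @param n_draws number of negative subsamples averaged (default 10).
#' @param seed optional integer for reproducible subsampling.
#' @return list with `auc` (mean of the two sides), `auc_close`, `auc_far`.
#' @export
auc_two_sided <- function(j_true, j_hat, positions, n_draws = 10, seed = NULL) {
  pos <- which(j_true != 0)
  neg <- which(j_true == 0)
  if (length(pos) == 0) stop("no active vertices in `j_true`")
  if (length(neg) == 0) stop("no inactive vertices in `j_true`")
  score <- abs(j_hat)
  d_neg <- apply(pairwise_dist(positions[neg, , drop = FALSE],
                               positions[pos, , drop = FALSE]), 1, min)
  ord <- neg[order(d_neg)]
  n_close <- max(1L, floor(0.2 * length(neg)))
  n_far <- max(1L, floor(0.5 * length(neg)))
  pool_close <- ord[seq_len(n_close)]
  pool_far <- ord[seq.int(length(neg) - n_far + 1L, length(neg))]
  one_side <- function(pool, s) {
    draws <- with_seed(s, {
      replicate(n_draws, {
        smp <- if (length(pool) <= length(pos)) pool else
          sample(pool, length(pos))
        roc_auc_trapezoid(score[pos], score[smp])
      })
    })
    mean(draws)
  }
  ac <- one_side(pool_close, if (is.null(seed)) NULL else derive_seed(seed, 1))
  af <- one_side(pool_far, if (is.null(seed)) NULL else derive_seed(seed, 2))
  list(auc = (ac + af) / 2, auc_close = ac, auc_far = af)
}

# Trapezoid-rule ROC area for positive vs negative score samples.
roc_auc_trapezoid <- function(s_pos, s_neg) {
  th <- sort(unique(c(s_pos, s_neg)), decreasing = TRUE)
  tpr <- c(0, vapply(th, function(t) mean(s_pos >= t), 0), 1)
  fpr <- c(0, vapply(th, function(t) mean(s_neg >= t), 0), 1)
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

#' Find local maxima of a source estimate on the mesh
#'
#' A vertex is a candidate when its (absolute) value strictly exceeds all mesh
#' neighbors. Candidates whose neighborhood mean falls below `rel_floor` of
#' the global maximum are discarded as noise peaks, and the survivors are
#' thinned by non-maximum suppression: descending by value, each kept maximum
#' removes all weaker candidates within `nms_radius`.
#'
#' @param j_hat numeric p-vector of estimated moments.
#' @param space the `source_space` the estimate lives on.
#' @param rel_floor noise floor as a fraction of the global maximum, applied
#'   to the mean over the candidate and its neighbors (default 0.2).
#' @param nms_radius suppression radius in mm (default 30).
#' @return integer vector of vertex indices, strongest first (possibly empty).
#' @export
find_maxima <- function(j_hat, space, rel_floor = 0.2, nms_radius = 30) {
  v <- abs(j_hat)
  top <- max(v)
  if (top == 0) return(integer(0))
  cand <- which(vapply(seq_along(v), function(i) {
    nb <- space$adjacency[[i]]
    length(nb) > 0 && all(v[i] > v[nb]) &&
      mean(v[c(i, nb)]) >= rel_floor * top
  }, logical(1)))
  if (length(cand) == 0) return(integer(0))
  cand <- cand[order(v[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in cand) {
    if (length(kept) == 0 ||
        all(sqrt(colSums((t(space$positions[kept, , drop = FALSE]) -
                          space$positions[i, ])^2)) >= nms_radius)) {
      kept <- c(kept, i)
    }
  }
  kept
}

#' Match estimated maxima to true cluster centers
#'
#' Each true center is matched to the nearest estimated maximum; matches
#' within `radius` mm are "found". Estimated maxima farther than `radius` from
#' every true center are ghost sources; true centers farther than `radius`
#' from every estimated maximum are missed.
#'
#' @param true_centers integer vector of true center vertex indices.
#' @param est_maxima integer vector of estimated maxima vertex indices.
#' @param space the shared `source_space`.
#' @param radius match radius in mm (default 30).
#' @return list with `n_found`, `n_ghost`, `n_missed`, `mle_all` (mean
#'   localization error over all true centers; each contributes its distance
#'   to the nearest estimated maximum), `mle_found` (mean over found centers
#'   only). Both are `NA` when `est_maxima` is empty; `mle_found` is `NA` when
#'   nothing is found.
#' @export
match_and_mle <- function(true_centers, est_maxima, space, radius = 30) {
  if (length(true_centers) == 0) stop("no true centers")
  if (length(est_maxima) == 0) {
    return(list(n_found = 0L, n_ghost = 0L, n_missed = length(true_centers),
                mle_all = NA_real_, mle_found = NA_real_))
  }
  D <- pairwise_dist(space$positions[true_centers, , drop = FALSE],
                     space$positions[est_maxima, , drop = FALSE])
  d_true <- apply(D, 1, min)   # per true center: nearest estimated maximum
  d_est <- apply(D, 2, min)    # per estimated maximum: nearest true center
  found <- d_true < radius
  list(n_found = sum(found),
       n_ghost = sum(d_est >= radius),
       n_missed = sum(!found),
       mle_all = mean(d_true),
       mle_found = if (any(found)) mean(d_true[found]) else NA_real_)
}

#' Mean squared error between source vectors
#' @param j_true,j_hat numeric p-vectors.
#' @return scalar MSE.
#' @export
mse <- function(j_true, j_hat) mean((j_true - j_hat)^2)

#' Normalized mean squared error
#'
#' MSE between the two vectors after each is scaled to unit maximum absolute
#' value, ignoring amplitude and comparing shapes only. A zero vector is left
#' unscaled.
#'
#' @param j_true,j_hat numeric p-vectors.
#' @return scalar nMSE.
#' @export
nmse <- function(j_true, j_hat) {
  u <- function(v) { m <- max(abs(v)); if (m > 0) v / m else v }
  mean((u(j_true) - u(j_hat))^2)
}

#' Paired permutation test for a difference in means
#'
#' Two-sided sign-flip permutation test on paired differences: the statistic
#' is `|mean(x - y)|` and the null distribution is generated by randomly
#' flipping the sign of each pair. The p-value uses the add-one estimator
#' `(1 + #{perm >= observed}) / (n_perm + 1)`.
#'
#' @param x,y paired numeric vectors (same length, NAs dropped pairwise).
#' @param n_perm number of permutations (default 10000).
#' @param seed optional integer seed.
#' @return list with `p_value`, `observed` (mean difference), `n_perm`, `n`.
#' @export
permutation_test <- function(x, y, n_perm = 10000, seed = NULL) {
  keep <- is.finite(x) & is.finite(y)
  d <- (x - y)[keep]
  n <- length(d)
  if (n < 2) stop("need at least 2 complete pairs")
  obs <- mean(d)
  exceed <- with_seed(seed, {
    signs <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), nrow = n)
    sum(abs(colMeans(signs * d)) >= abs(obs))
  })
  list(p_value = (1 + exceed) / (n_perm + 1), observed = obs,
       n_perm = n_perm, n = n)
}

#' Cohen's d effect size (pooled standard deviation)
#'
#' @param x,y numeric vectors (NAs dropped).
#' @return scalar d; `NaN` with a warning when the pooled SD is zero.
#' @export
cohens_d <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  nx <- length(x); ny <- length(y)
  sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
               (nx + ny - 2))
  if (sp == 0) {
    warning("zero pooled standard deviation; Cohen's d is undefined")
    return(NaN)
  }
  (mean(x) - mean(y)) / sp
}

#' Evaluate an inverse method on a simulated dataset
#'
#' Runs `invert` on every sample's peak-latency scalp vector, scores it
#' against the simulated truth (AUC, maxima matching, MSE/nMSE) and returns
#' per-sample records plus grouped summaries.
#'
#' @param dataset a dataset from [generate_dataset()].
#' @param model the `head_model` the estimates live on (its source space
#'   defines maxima adjacency and AUC geometry).
#' @param invert function mapping a q-vector of peak potentials to a p-vector
#'   of moment estimates.
#' @param method label stored with the results.
#' @param seed optional integer controlling AUC negative subsampling.
#' @return object of class `esi_eval`: `records` (one tibble row per sample:
#'   auc, auc_close, auc_far, mle_all, mle_found, n_found, n_ghost, n_missed,
#'   mse, nmse plus sample metadata), `by_extent`, `by_eccentricity`,
#'   `by_n_clusters` (grouped mean summaries), `method`.
#' @export
evaluate_method <- function(dataset, model, invert, method = "method",
                            seed = NULL) {
  space <- model$source_space
  n <- nrow(dataset$erp_peaks)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    j_hat <- abs(invert(dataset$erp_peaks[i, ]))
    j_true <- dataset$truth[i, ]
    a <- auc_two_sided(j_true, j_hat, space$positions,
                       seed = if (is.null(seed)) NULL else derive_seed(seed, i))
    centers <- as.integer(strsplit(dataset$meta$centers_gm[i], ",")[[1]])
    mx <- find_maxima(j_hat, space)
    mm <- match_and_mle(centers, mx, space)
    rows[[i]] <- tibble::tibble(
      sample = i, auc = a$auc, auc_close = a$auc_close, auc_far = a$auc_far,
      mle_all = mm$mle_all, mle_found = mm$mle_found,
      n_found = mm$n_found, n_ghost = mm$n_ghost, n_missed = mm$n_missed,
      mse = mse(j_true, j_hat), nmse = nmse(j_true, j_hat)
    )
  }
  records <- dplyr::bind_cols(dplyr::bind_rows(rows),
                              dataset$meta[setdiff(names(dataset$meta),
                                                   "sample")])
  grp <- function(var) {
    dplyr::summarise(
      dplyr::group_by(records, dplyr::across(dplyr::all_of(var))),
      dplyr::across(c("auc", "auc_close", "auc_far", "mle_all", "mle_found",
                      "n_ghost", "n_missed", "nmse"),
                    ~ mean(.x, na.rm = TRUE)),
      n = dplyr::n(), .groups = "drop")
  }
  records$extent <- records$total_extent
  records$eccentricity_bin <- cut(records$eccentricity, breaks = 3)
  structure(
    list(records = records, by_extent = grp("extent"),
         by_eccentricity = grp("eccentricity_bin"),
         by_n_clusters = grp("n_clusters"), method = method),
    class = "esi_eval"
  )
}

#' @export
print.esi_eval <- function(x, ...) {
  cat("<esi_eval>", x$method, "|", nrow(x$records), "samples\n")
  cat("  mean AUC:", round(100 * mean(x$records$auc), 2), "%",
      "(close", round(100 * mean(x$records$auc_close), 2),
      "/ far", round(100 * mean(x$records$auc_far), 2), ")\n")
  cat("  mean MLE (all):", round(mean(x$records$mle_all, na.rm = TRUE), 1),
      "mm | ghosts/sample:", round(mean(x$records$n_ghost), 2),
      "| missed/sample:", round(mean(x$records$n_missed), 2), "\n")
  invisible(x)
}

#' Tidy per-sample evaluation records
#' @param x an `esi_eval`.
#' @param ... unused.
#' @return the records tibble with a `method` column.
#' @export
tidy.esi_eval <- function(x, ...) {
  dplyr::mutate(x$records, method = x$method, .before = 1)
}

#' One-row evaluation summary
#' @param x an `esi_eval`.
#' @param ... unused.
#' @return a one-row tibble of mean metrics.
#' @export
glance.esi_eval <- function(x, ...) {
  r <- x$records
  tibble::tibble(
    method = x$method, n = nrow(r),
    auc = mean(r$auc), auc_close = mean(r$auc_close),
    auc_far = mean(r$auc_far),
    mle_all = mean(r$mle_all, na.rm = TRUE),
    mle_found = mean(r$mle_found, na.rm = TRUE),
    ghost_rate = mean(r$n_ghost), missed_rate = mean(r$n_missed),
    nmse = mean(r$nmse)
  )
}

#' Plot evaluation metrics against source extent
#' @param x an `esi_eval`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.esi_eval <- function(x, ...) {
  df <- x$by_extent
  ggplot2::ggplot(df, ggplot2::aes(x = .data$extent, y = .data$auc)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "total source extent (vertices)", y = "mean AUC",
                  title = x$method)
}
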