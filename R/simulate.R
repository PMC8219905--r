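# Simulation of ground-truth source activity and ERP-like scalp data:
# region-grown dipole clusters with Gaussian moment attenuation, a half-sine
# waveform, spatially correlated 1/f noise scaled to a target single-trial
# SNR, and trial averaging into an ERP.

#' Grow a dipole cluster from a seed vertex
#'
#' Region growing on the mesh adjacency: the support of a cluster of
#' neighborhood order `s` is every vertex within `s - 1` adjacency hops of the
#' seed (order 1 is the seed alone). Moments attenuate with Euclidean distance
#' `d` from the seed following a Gaussian profile
#' `moment(v) = seed_moment * exp(-d^2 / (2 sigma^2))` with
#' `sigma = radius / 2`, where `radius` is the largest distance within the
#' support; the seed keeps the full moment.
#'
#' @param space a `source_space`.
#' @param seed_vertex vertex index of the cluster seed.
#' @param order neighborhood order `s` (integer >= 1).
#' @param seed_moment dipole moment of the seed in nAm (default drawn range is
#'   5-10 in [sample_source_config()]).
#' @return object of class `source_activity`: `moments` (p-vector, nAm),
#'   `space_tag`, `clusters` (list of cluster specs).
#' @export
grow_cluster <- function(space, seed_vertex, order, seed_moment) {
  stopifnot(order >= 1, seed_vertex >= 1, seed_vertex <= n_dipoles(space))
  support <- bfs_neighborhood(space, seed_vertex, order - 1L)
  hemi_size <- sum(space$hemisphere == space$hemisphere[seed_vertex])
  if (length(support) >= hemi_size) {
    warning("cluster support spans a full hemisphere; clipped at hemisphere")
  }
  moments <- numeric(n_dipoles(space))
  if (length(support) == 1L) {
    moments[support] <- seed_moment
  } else {
    d <- sqrt(colSums((t(space$positions[support, , drop = FALSE]) -
                         space$positions[seed_vertex, ])^2))
    sigma <- max(d) / 2
    moments[support] <- seed_moment * exp(-d^2 / (2 * sigma^2))
  }
  structure(
    list(moments = moments, space_tag = "GM",
         clusters = list(list(seed_vertex = seed_vertex, order = as.integer(order),
                              seed_moment = seed_moment))),
    class = "source_activity"
  )
}

#' Draw a random multi-cluster source configuration
#'
#' Uniform draws of the number of clusters, seed vertices, neighborhood
#' orders and seed moments; overlapping clusters are summed so the forward
#' model stays linear.
#'
#' @param space a `source_space`.
#' @param n_clusters integer range `c(min, max)` (default 1-5).
#' @param orders integer range of neighborhood orders (default 2-5).
#' @param moment_range seed moment range in nAm (default 5-10).
#' @param seed RNG seed.
#' @return a `source_activity` with the drawn clusters recorded.
#' @export
sample_source_config <- function(space, n_clusters = c(1, 5), orders = c(2, 5),
                                 moment_range = c(5, 10), seed = NULL) {
  with_seed(seed, {
    k <- sample(seq(n_clusters[1], n_clusters[2]), 1)
    moments <- numeric(n_dipoles(space))
    clusters <- vector("list", k)
    for (i in seq_len(k)) {
      sv <- sample.int(n_dipoles(space), 1)
      s <- sample(seq(orders[1], orders[2]), 1)
      m <- stats::runif(1, moment_range[1], moment_range[2])
      cl <- grow_cluster(space, sv, s, m)
      moments <- moments + cl$moments
      clusters[[i]] <- cl$clusters[[1]]
    }
    structure(list(moments = moments, space_tag = "GM", clusters = clusters),
              class = "source_activity")
  })
}

#' Single-peak ERP waveform
#'
#' Half a period of a 5 Hz sinusoid (100 ms) centered in the epoch and
#' surrounded by zeros. The closed form used is
#' `w_k = sin(pi * (k + 0.5) / n) / max(...)` for the `n = fs / 10` samples of
#' the active window, so the waveform peaks at exactly 1 in the epoch center
#' (ties resolved to the earlier sample for the stored peak index).
#'
#' @param t epoch length in samples (default 100).
#' @param fs sampling frequency in Hz (default 100).
#' @return numeric vector of length `t` in `[0, 1]` with attribute
#'   `peak_index`.
#' @export
make_waveform <- function(t = 100, fs = 100) {
  n <- round(fs / 10)          # 100 ms half-period of a 5 Hz sine
  w <- sin(pi * (seq_len(n) - 0.5) / n)
  w <- w / max(w)
  out <- numeric(t)
  start <- floor((t - n) / 2)
  out[start + seq_len(n)] <- w
  attr(out, "peak_index") <- start + which.max(w)
  out
}

#' Project source activity to the electrodes
#'
#' The forward problem `M = K J` as an exact matrix product.
#' @param J a `source_activity`, p-vector or p x t matrix of moments (nAm).
#' @param model a `head_model` on the same source space.
#' @return q-vector or q x t matrix of potentials.
#' @export
project <- function(J, model) {
  j <- if (inherits(J, "source_activity")) J$moments else J
  if (is.null(dim(j))) as.vector(model$leadfield %*% j) else model$leadfield %*% j
}

#' Generate synthetic noise segments
#'
#' Emulates segments of resting EEG: independent 1/f spectral-profile sources
#' per channel are mixed through a smooth spatial matrix (Gaussian kernel over
#' electrode distances), low-pass filtered at 30 Hz with a 4th-order zero-phase
#' Butterworth filter (the 0.1 Hz high-pass corner is realized as per-segment
#' demeaning, which is all a 1 s epoch can resolve), baseline-corrected on the
#' first 100 ms and common-average referenced.
#'
#' @param montage a `montage` (defines channel count and spatial correlation).
#' @param t epoch length in samples (default 100).
#' @param fs sampling frequency (default 100 Hz).
#' @param n_segments number of segments (default 200).
#' @param seed RNG seed.
#' @param mixing_scale spatial kernel scale in mm (default 50).
#' @param lowpass low-pass corner in Hz (default 30).
#' @return list of q x t matrices.
#' @export
make_noise <- function(montage, t = 100, fs = 100, n_segments = 200,
                       seed = NULL, mixing_scale = 50, lowpass = 30) {
  q <- n_electrodes(montage)
  de <- pairwise_dist(montage$positions, montage$positions)
  A <- exp(-de^2 / (2 * mixing_scale^2))
  bf <- signal::butter(4, lowpass / (fs / 2), type = "low")
  freqs <- c(0, seq_len(t - 1)) * fs / t
  freqs <- pmin(freqs, fs - freqs)               # two-sided frequency axis
  amp <- 1 / sqrt(pmax(freqs, fs / t))           # 1/f power profile
  n_base <- round(0.1 * fs)
  with_seed(seed, {
    lapply(seq_len(n_segments), function(i) {
      lat <- matrix(stats::rnorm(q * t), q, t)
      lat <- t(apply(lat, 1, function(x) Re(stats::fft(stats::fft(x) * amp,
                                                       inverse = TRUE)) / t))
      seg <- A %*% lat
      seg <- seg - rowMeans(seg)
      seg <- t(apply(seg, 1, function(x) signal::filtfilt(bf, x)))
      seg <- seg - rowMeans(seg[, seq_len(n_base), drop = FALSE])
      car_ref(seg)
    })
  })
}

#' Scale noise to a target single-trial SNR
#'
#' SNR is defined at the signal peak sample as the ratio of global field
#' power (standard deviation across channels): `SNR = GFP(signal at peak) /
#' GFP(scaled noise at peak)`.
#'
#' @param signal q x t matrix (or q-vector) of noiseless potentials.
#' @param noise q x t matrix (or q-vector) of noise.
#' @param target_snr target ratio (default 1).
#' @param peak_index time index at which SNR is defined; defaults to the
#'   sample of maximal signal GFP.
#' @return the scaled noise, same shape as `noise`.
#' @export
scale_to_snr <- function(signal, noise, target_snr = 1, peak_index = NULL) {
  s <- if (is.null(dim(signal))) matrix(signal, ncol = 1) else signal
  n <- if (is.null(dim(noise))) matrix(noise, ncol = 1) else noise
  if (is.null(peak_index)) peak_index <- which.max(apply(s, 2, gfp))
  gs <- gfp(s[, peak_index])
  gn <- gfp(n[, peak_index])
  if (gs == 0) stop("all-zero signal at the peak sample")
  if (gn == 0) stop("all-zero noise at the peak sample")
  scaled <- noise * (gs / (gn * target_snr))
  scaled
}

#' Simulate a multi-trial ERP sample
#'
#' The spatial source pattern is modulated by the half-sine waveform,
#' projected through the leadfield, and `n_trials` trials are formed by adding
#' independently drawn noise segments scaled to `snr` at the ERP peak. Each
#' trial is then baseline-corrected (first 100 ms) and common-average
#' referenced; the ERP is the trial average. Averaging n SNR-1 trials yields a
#' theoretical ERP SNR of sqrt(n) (about 4.5 for 20 trials).
#'
#' @param J a `source_activity` on the model's source space.
#' @param model a `head_model`.
#' @param n_trials number of trials (default 20).
#' @param snr single-trial SNR at the peak (default 1).
#' @param noise_segments list of q x t noise matrices (from [make_noise()]);
#'   generated on the fly when NULL.
#' @param t,fs epoch length (samples) and sampling frequency (Hz).
#' @param seed RNG seed for segment selection (and noise generation if needed).
#' @return object of class `erp_sample`: `trials` (n x q x t array), `erp`
#'   (q x t), `peak_index`, `truth` (the `source_activity`),
#'   `snr_single_trial`, `signal` (noiseless q x t).
#' @export
make_erp_sample <- function(J, model, n_trials = 20, snr = 1,
                            noise_segments = NULL, t = 100, fs = 100,
                            seed = NULL) {
  if (is.null(noise_segments)) {
    noise_segments <- make_noise(model$montage, t = t, fs = fs,
                                 n_segments = max(20, n_trials),
                                 seed = derive_seed(seed, 1))
  }
  w <- make_waveform(t, fs)
  peak <- attr(w, "peak_index")
  m <- project(J, model)
  M <- outer(m, as.vector(w))
  q <- nrow(M)
  n_base <- round(0.1 * fs)
  trials <- array(0, dim = c(n_trials, q, t))
  erp <- matrix(0, q, t)
  with_seed(seed, {
    idx <- sample.int(length(noise_segments), n_trials, replace = TRUE)
    for (i in seq_len(n_trials)) {
      ns <- if (snr > 0) scale_to_snr(M, noise_segments[[idx[i]]], snr, peak) else
        noise_segments[[idx[i]]] * 0
      tr <- M + ns
      tr <- tr - rowMeans(tr[, seq_len(n_base), drop = FALSE])
      tr <- car_ref(tr)
      trials[i, , ] <- tr
      erp <- erp + tr
    }
  })
  erp <- erp / n_trials
  structure(
    list(trials = trials, erp = erp, peak_index = peak, truth = J,
         snr_single_trial = snr, signal = M),
    class = "erp_sample"
  )
}

preset_params <- function(preset) {
  switch(preset,
    train = list(n_clusters = c(1, 5), orders = c(2, 5), model = "GM"),
    eval_single = list(n_clusters = c(1, 1), orders = c(2, 7), model = "AGM"),
    eval_multi = list(n_clusters = c(1, 10), orders = c(2, 7), model = "AGM"),
    stop("unknown preset: ", preset)
  )
}

#' Generate a simulation dataset
#'
#' The `train` preset simulates on the GM; the `eval_single` / `eval_multi`
#' presets simulate on the AGM and transfer the ground truth to the GM source
#' space by k-nearest-neighbor interpolation with energy normalization, so
#' estimates computed on the GM can be scored against it. Only the scalp
#' vector at the waveform peak is retained as network input.
#'
#' @param model_gm GM `head_model`.
#' @param n_samples number of samples.
#' @param preset one of "train", "eval_single", "eval_multi".
#' @param model_agm AGM `head_model` (required for eval presets).
#' @param seed run seed; every sample derives its own seed from it.
#' @param n_trials,snr,t,fs trial structure (defaults 20 trials at SNR 1).
#' @param n_segments size of the shared noise-segment pool (default 200).
#' @param moment_range seed moment range in nAm.
#' @param knn neighbors for the AGM-to-GM source transfer (default 5).
#' @return object of class `esi_dataset`: `erp_peaks` (n x q), `truth`
#'   (n x p on the GM space), `meta` (tibble), `preset`, `space_tag` of the
#'   generating model, `peak_index`, `p`, `q`.
#' @export
generate_dataset <- function(model_gm, n_samples, preset = "train",
                             model_agm = NULL, seed = 1L, n_trials = 20,
                             snr = 1, t = 100, fs = 100, n_segments = 200,
                             moment_range = c(5, 10), knn = 5) {
  pp <- preset_params(preset)
  sim_model <- if (pp$model == "AGM") {
    if (is.null(model_agm)) stop("preset '", preset, "' requires model_agm")
    model_agm
  } else {
    model_gm
  }
  sim_space <- sim_model$source_space
  gm_space <- model_gm$source_space
  segs <- make_noise(sim_model$montage, t = t, fs = fs, n_segments = n_segments,
                     seed = derive_seed(seed, 101))
  map <- if (pp$model == "AGM") knn_map(sim_space, gm_space, k = knn) else NULL
  q <- n_electrodes(sim_model$montage)
  p <- n_dipoles(gm_space)
  erp_peaks <- matrix(0, n_samples, q)
  truth <- matrix(0, n_samples, p)
  meta <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    si <- derive_seed(seed, 1000 + i)
    J <- sample_source_config(sim_space, pp$n_clusters, pp$orders,
                              moment_range, seed = si)
    es <- make_erp_sample(J, sim_model, n_trials = n_trials, snr = snr,
                          noise_segments = segs, t = t, fs = fs,
                          seed = derive_seed(si, 7))
    erp_peaks[i, ] <- es$erp[, es$peak_index]
    truth[i, ] <- if (pp$model == "AGM") {
      map_sources(J$moments, sim_space, gm_space, k = knn, map = map)
    } else {
      J$moments
    }
    seeds <- vapply(J$clusters, function(cl) cl$seed_vertex, 1L)
    # cluster centers expressed on the GM space (nearest GM vertex to each
    # simulation-space seed; identity when simulating on the GM itself)
    centers_gm <- if (pp$model == "AGM") {
      vapply(seeds, function(sv) {
        which.min(colSums((t(gm_space$positions) -
                             sim_space$positions[sv, ])^2))
      }, 1L)
    } else {
      seeds
    }
    meta[[i]] <- tibble::tibble(
      sample = i,
      n_clusters = length(J$clusters),
      orders = paste(vapply(J$clusters, function(cl) cl$order, 1L),
                     collapse = ","),
      max_order = max(vapply(J$clusters, function(cl) cl$order, 1L)),
      seed_vertices = paste(seeds, collapse = ","),
      centers_gm = paste(centers_gm, collapse = ","),
      total_extent = sum(truth[i, ] != 0),
      eccentricity = sqrt(sum(sim_space$positions[seeds[1], ]^2)),
      provenance = pp$model,
      seed = si
    )
  }
  structure(
    list(erp_peaks = erp_peaks, truth = truth,
         meta = dplyr::bind_rows(meta), preset = preset,
         space_tag = pp$model, peak_index = attr(make_waveform(t, fs), "peak_index"),
         p = p, q = q),
    class = "esi_dataset"
  )
}

#' @export
print.esi_dataset <- function(x, ...) {
  cat(sprintf("<esi_dataset:%s> %d samples, %d channels -> %d dipoles (truth on GM)\n",
              x$preset, nrow(x$erp_peaks), x$q, x$p))
  invisible(x)
}

#' Save / load a simulation dataset container
#' @param dataset an `esi_dataset`.
#' @param path file path (conventionally `.rds`).
#' @export
save_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "esi_dataset"))
  saveRDS(dataset, path)
  invisible(path)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(path) {
  dataset <- readRDS(path)
  stopifnot(inherits(dataset, "esi_dataset"))
  dataset
}
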