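# End-to-end benchmark: build the GM and AGM head models, simulate training
# and evaluation data, train the network, evaluate it against the linear
# baselines, and return all reports plus a markdown summary.

#' Benchmark configuration
#'
#' @param gm_level,agm_level source-space subdivision levels of the inversion
#'   (GM) and simulation (AGM) models (defaults 3 and 4).
#' @param n_train number of training samples (default 5000).
#' @param n_eval_single,n_eval_multi evaluation set sizes (defaults 200, 100).
#' @param epochs training epochs (default 30, capped at 50).
#' @param seed run seed (training, initialization and all simulation seeds
#'   are derived from it).
#' @param lambda2 regularization fraction for both linear baselines.
#' @return list of class `bench_config`.
#' @export
bench_config <- function(gm_level = 3, agm_level = 4, n_train = 5000,
                         n_eval_single = 200, n_eval_multi = 100,
                         epochs = 30, seed = 1L, lambda2 = 1 / 9) {
  if (epochs > 50) stop("epochs capped at 50")
  structure(
    list(gm_level = gm_level, agm_level = agm_level, n_train = n_train,
         n_eval_single = n_eval_single, n_eval_multi = n_eval_multi,
         epochs = epochs, seed = as.integer(seed), lambda2 = lambda2),
    class = "bench_config"
  )
}

#' Run the full simulation-training-evaluation benchmark
#'
#' Builds a GM head model and a perturbed AGM counterpart, simulates a GM
#' training set and AGM evaluation sets, trains the convolutional network,
#' and evaluates the network, minimum norm and eLORETA on every evaluation
#' set. A hash-based leakage check verifies that no evaluation scalp vector
#' also occurs in the training set.
#'
#' @param config a [bench_config()].
#' @param verbose print progress (default TRUE).
#' @return object of class `esi_benchmark`: `config`, `net` (trained
#'   network), `evals` (nested list, set -> method -> `esi_eval`), `summary`
#'   (tibble, one row per set x method), `markdown` (character vector of
#'   report lines), `leakage_ok`.
#' @export
run_benchmark <- function(config = bench_config(), verbose = TRUE) {
  say <- function(...) if (verbose) message(...)
  t_start <- Sys.time()

  say("building head models (GM level ", config$gm_level, ", AGM level ",
      config$agm_level, ")")
  montage <- build_montage("standard31")
  gm_space <- build_source_space(config$gm_level)
  gm <- compute_leadfield(gm_space, montage)
  agm <- perturb_to_agm(gm, finer_level = config$agm_level,
                        seed = derive_seed(config$seed, 11))
  if (ncol(gm$leadfield) != n_dipoles(gm_space)) {
    stop("leadfield/source-space dipole count mismatch")
  }

  say("simulating ", config$n_train, " training samples on the GM")
  ds_train <- generate_dataset(gm, config$n_train, "train",
                               seed = derive_seed(config$seed, 21))
  say("simulating evaluation sets on the AGM")
  ds_single <- generate_dataset(gm, config$n_eval_single, "eval_single",
                                model_agm = agm,
                                seed = derive_seed(config$seed, 22))
  ds_multi <- generate_dataset(gm, config$n_eval_multi, "eval_multi",
                               model_agm = agm,
                               seed = derive_seed(config$seed, 23))

  # leakage check: no evaluation scalp vector may occur in the training set
  fp_train <- row_fingerprint(ds_train$erp_peaks)
  fp_eval <- c(row_fingerprint(ds_single$erp_peaks),
               row_fingerprint(ds_multi$erp_peaks))
  leakage_ok <- !any(fp_eval %in% fp_train)
  if (!leakage_ok) stop("evaluation sample found in the training set")

  say("training network (", config$epochs, " epochs)")
  net <- train_network(ds_train, gm,
                       train_config(epochs = config$epochs,
                                    seed = derive_seed(config$seed, 32)))

  mn <- minimum_norm(gm, lambda2 = config$lambda2)
  el <- eloreta(gm, lambda2 = config$lambda2)
  inverters <- list(
    cnn = function(m) {
      j <- predict(net, m)
      if (all(j == 0)) return(as.numeric(j))
      rescale_prediction(j, m, gm)$j_scaled
    },
    mne = function(m) apply_inverse(mn, m),
    eloreta = function(m) apply_inverse(el, m)
  )
  sets <- list(single = ds_single, multi = ds_multi)
  evals <- list()
  rows <- list()
  for (sn in names(sets)) {
    evals[[sn]] <- list()
    for (mn_name in names(inverters)) {
      say("evaluating ", mn_name, " on ", sn)
      ev <- evaluate_method(sets[[sn]], gm, inverters[[mn_name]],
                            method = mn_name,
                            seed = derive_seed(config$seed, 41))
      evals[[sn]][[mn_name]] <- ev
      g <- glance(ev)
      g$set <- sn
      rows[[paste(sn, mn_name)]] <- g
    }
  }
  summary_tbl <- dplyr::relocate(dplyr::bind_rows(rows), "set")

  md <- c(
    "# Benchmark report",
    "",
    sprintf("- GM level %d (p = %d), AGM level %d (p = %d), %d channels",
            config$gm_level, n_dipoles(gm_space), config$agm_level,
            n_dipoles(agm$source_space), n_electrodes(montage)),
    sprintf("- %d training samples, %d epochs; eval: %d single-source, %d multi-source",
            config$n_train, config$epochs, config$n_eval_single,
            config$n_eval_multi),
    sprintf("- train/eval leakage check: %s",
            if (leakage_ok) "passed" else "FAILED"),
    "",
    "| set | method | AUC | AUC close | AUC far | MLE (mm) | ghosts | missed |",
    "|---|---|---|---|---|---|---|---|",
    sprintf("| %s | %s | %.1f%% | %.1f%% | %.1f%% | %.1f | %.2f | %.2f |",
            summary_tbl$set, summary_tbl$method, 100 * summary_tbl$auc,
            100 * summary_tbl$auc_close, 100 * summary_tbl$auc_far,
            summary_tbl$mle_all, summary_tbl$ghost_rate,
            summary_tbl$missed_rate),
    "",
    sprintf("Elapsed: %.1f min",
            as.numeric(difftime(Sys.time(), t_start, units = "mins")))
  )

  structure(
    list(config = config, net = net, evals = evals, summary = summary_tbl,
         markdown = md, leakage_ok = leakage_ok),
    class = "esi_benchmark"
  )
}

#' @export
print.esi_benchmark <- function(x, ...) {
  cat(x$markdown, sep = "\n")
  invisible(x)
}
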