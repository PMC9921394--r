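#' Train a window classifier on a synthetic corpus
#'
#' Generates a training corpus, slices it into labeled windows under the
#' requested regime, splits 70:15:15, optionally z-scores with
#' training-split statistics, and trains the classifier with early
#' stopping. The four study variants map to `regime`/`normalize`:
#' C1 = nonoverlap/raw, C2 = nonoverlap/zscore, C3 = overlap/raw
#' (the variant selected for the deployed recognizer), C4 =
#' overlap/zscore.
#'
#' @param gen_cfg A [generator_config()].
#' @param n_protocols Number of training protocols to generate.
#' @param seed Integer seed controlling corpus, split and weights.
#' @param regime `"overlap"` (step 25) or `"nonoverlap"` (step 50).
#' @param normalize `"raw"` or `"zscore"`.
#' @param model_cfg A [model_config()]; its seed is overridden by `seed`.
#' @param verbose Print training progress.
#' @return A list: `model` (trained `cnn_model`), `test_accuracy`
#'   (window accuracy on the held-out split), `splits` sizes, `history`.
#' @export
train_classifier <- function(gen_cfg = generator_config(), n_protocols = 30L,
                             seed = 1L, regime = c("overlap", "nonoverlap"),
                             normalize = c("raw", "zscore"),
                             model_cfg = model_config(), verbose = FALSE) {
  regime <- match.arg(regime)
  normalize <- match.arg(normalize)
  corpus <- generate_dataset(gen_cfg, n_protocols, seed = seed)
  step <- if (regime == "overlap") 25L else 50L
  wds <- lapply(corpus, function(d) slice_windows(d$signal, d$protocol, step = step))
  ds <- combine_windows(wds)
  parts <- split_dataset(ds, seed = seed)
  if (normalize == "zscore") {
    st <- fit_normalizer(parts$train)
    parts <- lapply(parts, apply_normalizer, stats = st)
  }
  model_cfg$seed <- as.integer(seed)
  model <- build_model(model_cfg)
  model <- train_model(model, parts$train, parts$val, verbose = verbose)
  test_probs <- predict_batch(model, parts$test)
  list(model = model,
       test_accuracy = window_accuracy(test_probs, parts$test$labels),
       n_windows = vapply(parts, function(p) length(p$starts), integer(1)),
       history = model$history)
}

#' End-to-end benchmark on a synthetic corpus
#'
#' Reproduces the study's evaluation design on generated data: train the
#' classifier on one corpus, then on a disjoint evaluation corpus run
#' streaming inference, post-processing, segment extraction and
#' repetition counting, and score scenario recognition, per-sample
#' activity recall and repetition-count accuracy (exact, within 1,
#' within 2, miscount rate).
#'
#' @param gen_cfg A [generator_config()].
#' @param n_train,n_eval Training and evaluation corpus sizes
#'   (protocols).
#' @param seed Integer seed; the evaluation corpus uses a fixed offset of
#'   this seed so the two corpora are disjoint.
#' @param regime,normalize Classifier variant (see [train_classifier()]).
#' @param model_cfg A [model_config()].
#' @param ppb_cfg A [ppb_config()].
#' @param rcm_cfg An [rcm_config()].
#' @param verbose Print progress.
#' @return A list of class `eval_report`; see Details.
#' @details The report contains `window_accuracy` (held-out windows),
#'   `scenario_accuracy`, `activity_accuracy` (per-sample recall per
#'   class and total, pooled over the corpus), `repetitions` (per-segment
#'   table), `rep_exact`, `rep_within1`, `rep_within2` (each with
#'   per-activity and total fractions), `miscount`, `miscount_rate`,
#'   `n_protocols`, and the trained `model`.
#' @export
run_benchmark <- function(gen_cfg = generator_config(), n_train = 30L,
                          n_eval = 100L, seed = 1L,
                          regime = "overlap", normalize = "raw",
                          model_cfg = model_config(),
                          ppb_cfg = ppb_config(), rcm_cfg = rcm_config(),
                          verbose = FALSE) {
  trained <- train_classifier(gen_cfg, n_train, seed = seed, regime = regime,
                              normalize = normalize, model_cfg = model_cfg,
                              verbose = verbose)
  model <- trained$model
  eval_corpus <- generate_dataset(gen_cfg, n_eval, seed = seed + 500009L)

  scen_pred <- vector("list", n_eval)
  scen_truth <- vector("list", n_eval)
  correct <- numeric(4); total <- numeric(4)
  rep_rows <- vector("list", n_eval)

  for (i in seq_len(n_eval)) {
    d <- eval_corpus[[i]]
    rec <- recognize_activities(model, d$signal, ppb_cfg)
    scen_pred[[i]] <- rec$scenario
    scen_truth[[i]] <- protocol_scenario(d$protocol)
    tl <- sample_accuracy_tally(protocol_sample_labels(rec$segments),
                                protocol_sample_labels(d$protocol))
    correct <- correct + tl$correct
    total <- total + tl$total

    matched <- match_segments(rec$segments, d$protocol)
    pred <- integer(nrow(matched))
    for (j in seq_len(nrow(matched))) {
      if (matched$matched[j] &&
          matched$pred_end[j] - matched$pred_start[j] > 3L * rcm_cfg$order) {
        seg <- list(label = matched$label[j], start = matched$pred_start[j],
                    end = matched$pred_end[j])
        pred[j] <- count_repetitions(d$signal, seg, rcm_cfg)
      }
    }
    matched$predicted <- pred
    matched$protocol <- i
    rep_rows[[i]] <- matched
    if (verbose && i %% 10L == 0L) message("evaluated ", i, "/", n_eval)
  }

  reps <- do.call(rbind, rep_rows)
  class(reps) <- c("repetition_report", "data.frame")
  names(correct) <- names(total) <- activity_levels()
  structure(list(
    window_accuracy = trained$test_accuracy,
    scenario_accuracy = scenario_accuracy(scen_pred, scen_truth),
    activity_accuracy = list(
      per_activity = correct[total > 0] / total[total > 0],
      total = sum(correct) / sum(total)),
    repetitions = reps,
    rep_exact = repetition_accuracy(reps, 0),
    rep_within1 = repetition_accuracy(reps, 1),
    rep_within2 = repetition_accuracy(reps, 2),
    miscount = sum(abs(reps$predicted - reps$truth)),
    miscount_rate = sum(abs(reps$predicted - reps$truth)) / sum(reps$truth),
    n_protocols = n_eval, n_train = n_train,
    model = model), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  cat(sprintf("  window accuracy (held-out): %.3f\n", x$window_accuracy))
  cat(sprintf("  scenario accuracy:          %.3f  (%d protocols)\n",
              x$scenario_accuracy, x$n_protocols))
  cat(sprintf("  sample-level recall total:  %.3f\n", x$activity_accuracy$total))
  cat(sprintf("  repetitions: exact %.3f | within 1 %.3f | within 2 %.3f\n",
              x$rep_exact$total, x$rep_within1$total, x$rep_within2$total))
  cat(sprintf("  miscount %d / %d true reps (rate %.3f)\n",
              x$miscount, sum(x$repetitions$truth), x$miscount_rate))
  invisible(x)
}
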