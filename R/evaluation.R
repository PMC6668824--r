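#' Signal-detection d-prime for age classification
#'
#' Older adults are the signal class: hits are older adults classified old,
#' false alarms are younger adults classified old. Extreme proportions (0
#' or 1) are corrected before the normal-quantile transform, since
#' leave-one-out runs with modest samples can produce perfect rates.
#'
#' @param hits,misses,false_alarms,correct_rejections Non-negative counts;
#'   `hits + misses` is the number of older adults, `false_alarms +
#'   correct_rejections` the number of younger adults.
#' @param correction `"2N"` (default): a rate of 0 becomes `1/(2N)` and a
#'   rate of 1 becomes `1 - 1/(2N)`, with N the class size; `"loglinear"`:
#'   add 0.5 to each count and 1 to each class size; `"none"`: no
#'   correction (errors on extreme rates).
#' @return A list of class `dprime_result` with the counts, corrected
#'   `hit_rate` and `fa_rate`, and `dprime = qnorm(hit_rate) -
#'   qnorm(fa_rate)`.
#' @export
dprime <- function(hits, misses, false_alarms, correct_rejections,
                   correction = c("2N", "loglinear", "none")) {
  correction <- match.arg(correction)
  counts <- c(hits, misses, false_alarms, correct_rejections)
  if (any(counts < 0)) stop("counts must be non-negative")
  n_old <- hits + misses
  n_young <- false_alarms + correct_rejections
  if (n_old == 0 || n_young == 0) {
    stop("both classes must have at least one member")
  }
  rate <- function(x, n) {
    switch(correction,
           "2N" = {
             r <- x / n
             if (r == 0) r <- 1 / (2 * n)
             if (r == 1) r <- 1 - 1 / (2 * n)
             r
           },
           loglinear = (x + 0.5) / (n + 1),
           none = {
             r <- x / n
             if (r <= 0 || r >= 1) {
               stop("extreme rate with correction = 'none'")
             }
             r
           })
  }
  hr <- rate(hits, n_old)
  far <- rate(false_alarms, n_young)
  structure(list(hits = hits, misses = misses,
                 false_alarms = false_alarms,
                 correct_rejections = correct_rejections,
                 hit_rate = hr, fa_rate = far,
                 dprime = stats::qnorm(hr) - stats::qnorm(far),
                 correction = correction),
            class = "dprime_result")
}

#' @export
print.dprime_result <- function(x, ...) {
  cat(sprintf("d' = %.3f (HR %.3f, FAR %.3f; %d/%d old, %d/%d young)\n",
              x$dprime, x$hit_rate, x$fa_rate, x$hits, x$hits + x$misses,
              x$correct_rejections,
              x$false_alarms + x$correct_rejections))
  invisible(x)
}

#' Resubstitution accuracy of a trained network
#'
#' @param params Trained `network_params`.
#' @param features Feature matrix on the scale the network was trained on.
#' @param age_group Character vector of true labels (`"young"`/`"old"`).
#' @return Proportion of rows whose classification matches the true label.
#' @export
resubstitution_accuracy <- function(params, features, age_group) {
  pred <- nn_classify(params, features)
  if (length(pred) != length(age_group)) stop("shape mismatch")
  mean(pred == age_group)
}

# Deterministic 31-adic hash of a participant id, folded below 2^31 - 1.
# Fold seeds derive from it so LOOCV is invariant to cohort row order.
stable_id_hash <- function(id) {
  vapply(id, function(s) {
    h <- 0
    for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
    as.integer(h)
  }, integer(1L), USE.NAMES = FALSE)
}

#' Leave-one-out cross-validated classification
#'
#' For each participant in turn: the remaining n - 1 rows are restricted to
#' the requested feature subset and z-scored on themselves, a fresh network
#' is initialized with a fold-specific seed (base seed plus a stable hash
#' of the held-out participant's id, so results do not depend on row
#' order), trained, and used to classify the held-out row after
#' standardizing it with the training-fold statistics only. Fold
#' predictions aggregate to a signal-detection [dprime()].
#'
#' @param features Raw-scale `feature_matrix` with the 18 canonical
#'   columns.
#' @param age_group True labels, one per row.
#' @param config A [training_config()]; `config$seed` is the base seed.
#' @param subset `"all"`, `"item"` or `"associate"` (see
#'   [select_features()]).
#' @param hidden Hidden-unit count for each fold's network.
#' @param correction Extreme-rate correction passed to [dprime()].
#' @return A list of class `loocv_result`: per-individual `predictions`
#'   data frame (id, age_group, output, predicted, fold_seed), `dprime`
#'   (a `dprime_result`), `accuracy`, and the `subset` used.
#' @export
loocv <- function(features, age_group, config = training_config(),
                  subset = "all", hidden = 2L, correction = "2N") {
  if (!identical(attr(features, "scale"), "raw")) {
    stop("loocv standardizes within folds; supply the raw-scale matrix")
  }
  n <- nrow(features)
  if (n < 3L) stop("need at least 3 participants")
  if (length(age_group) != n) stop("one label per row required")
  sel <- unclass(select_features(features, subset))
  ids <- rownames(sel)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  fold_seeds <- (config$seed + stable_id_hash(ids)) %% 2147483647L
  output <- numeric(n)
  predicted <- character(n)
  for (i in seq_len(n)) {
    tr <- sel[-i, , drop = FALSE]
    if (length(unique(age_group[-i])) < 2L) {
      stop("training fold for id ", ids[i], " lost an entire class")
    }
    mu <- colMeans(tr)
    sd <- apply(tr, 2L, stats::sd)
    if (any(sd == 0)) {
      stop("constant column in training fold for id ", ids[i])
    }
    z_tr <- sweep(sweep(tr, 2L, mu, "-"), 2L, sd, "/")
    z_te <- (sel[i, ] - mu) / sd
    fold_cfg <- config
    fold_cfg$seed <- fold_seeds[i]
    fit <- nn_train(z_tr, encode_targets(age_group[-i]), fold_cfg,
                    hidden = hidden)
    output[i] <- nn_forward(fit$params, z_te)$output
    predicted[i] <- if (output[i] > 0) "old" else "young"
  }
  is_old <- age_group == "old"
  dp <- dprime(hits = sum(is_old & predicted == "old"),
               misses = sum(is_old & predicted == "young"),
               false_alarms = sum(!is_old & predicted == "old"),
               correct_rejections = sum(!is_old & predicted == "young"),
               correction = correction)
  structure(list(predictions = data.frame(id = ids, age_group = age_group,
                                          output = output,
                                          predicted = predicted,
                                          fold_seed = fold_seeds,
                                          stringsAsFactors = FALSE),
                 dprime = dp, accuracy = mean(predicted == age_group),
                 subset = subset),
            class = "loocv_result")
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf("LOOCV (%s features): accuracy %.3f, ", x$subset,
              x$accuracy))
  print(x$dprime)
  invisible(x)
}

#' Item-versus-associate feature ablation
#'
#' Runs [loocv()] twice, once on the 9 item-test columns and once on the 9
#' associate-test columns, under the same base seed so the fold-specific
#' initialization seeds are matched across the two runs (a paired
#' comparison), and reports both d-prime values and their difference.
#'
#' @inheritParams loocv
#' @return A list of class `ablation_result` with `item` and `associate`
#'   (`loocv_result`s), `dprime_item`, `dprime_assoc` and `difference`
#'   (associate minus item).
#' @export
ablation_compare <- function(features, age_group,
                             config = training_config(), hidden = 2L,
                             correction = "2N") {
  res_item <- loocv(features, age_group, config, subset = "item",
                    hidden = hidden, correction = correction)
  res_assoc <- loocv(features, age_group, config, subset = "associate",
                     hidden = hidden, correction = correction)
  structure(list(item = res_item, associate = res_assoc,
                 dprime_item = res_item$dprime$dprime,
                 dprime_assoc = res_assoc$dprime$dprime,
                 difference = res_assoc$dprime$dprime -
                   res_item$dprime$dprime),
            class = "ablation_result")
}

#' @export
print.ablation_result <- function(x, ...) {
  cat(sprintf("ablation: d' item %.3f, associate %.3f, difference %.3f\n",
              x$dprime_item, x$dprime_assoc, x$difference))
  invisible(x)
}
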