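# RBF-SVM classifiers and the leave-rats-out protocols.
#
# Model fitting is delegated to e1071 (libsvm); grid search, stratified
# inner cross-validation, tie-breaking and the one-vs-one vote aggregation
# are implemented here so the selection contract is explicit and testable.

#' Classifier configuration
#'
#' @param task One of `"sleep3"` (3-state scoring), `"pd2"` (binary
#'   sham/lesion) or `"integrated6"` (state x group).
#' @param features Character vector of feature column names.
#' @param C_grid,gamma_grid Positive penalty / kernel-width grids searched
#'   exhaustively (defaults: the log-2 lattices \eqn{2^0..2^7} and
#'   \eqn{2^{-7}..2^0}).
#' @param folds Inner stratified cross-validation folds for model selection.
#' @param tune_max Maximum number of epochs used during grid search; larger
#'   training sets are stratified-subsampled for tuning only (the final
#'   refit always uses every epoch).
#' @param seed Integer seed for fold assignment and subsampling.
#' @return Object of class `somno_model_config`.
#' @export
model_config <- function(task = c("sleep3", "pd2", "integrated6"),
                         features,
                         C_grid = 2^(0:7),
                         gamma_grid = 2^(-7:0),
                         folds = 5,
                         tune_max = 4000,
                         seed = 1) {
  task <- match.arg(task)
  if (length(features) < 1) stop("feature subset must be non-empty", call. = FALSE)
  if (length(C_grid) < 1 || any(C_grid <= 0) ||
      length(gamma_grid) < 1 || any(gamma_grid <= 0)) {
    stop("grids must be non-empty and positive", call. = FALSE)
  }
  structure(list(task = task, features = features,
                 C_grid = sort(C_grid), gamma_grid = sort(gamma_grid),
                 folds = folds, tune_max = tune_max, seed = seed),
            class = "somno_model_config")
}

# stratified fold assignment: within each class, shuffled indices are dealt
# round-robin so folds share the class balance
stratified_folds <- function(y, k, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (cl in levels(y)) {
      i <- which(y == cl)
      fold[i[sample.int(length(i))]] <- rep_len(seq_len(k), length(i))
    }
    fold
  })
}

# one-vs-one vote aggregation over libsvm pairwise decision values; vote
# ties are broken by the summed signed decision values in each class's favor
predict_svm <- function(fit, x, classes) {
  pr <- predict(fit, x, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  if (length(classes) == 2) {
    lab <- as.character(pr)
    # orient scores so larger = more like the second configured class
    cn <- colnames(dv)[1]
    first <- strsplit(cn, "/", fixed = TRUE)[[1]][1]
    score <- if (first == classes[1]) -dv[, 1] else dv[, 1]
    return(structure(factor(lab, levels = classes), score = unname(score)))
  }
  votes <- matrix(0L, nrow(dv), length(classes),
                  dimnames = list(NULL, classes))
  agg <- matrix(0, nrow(dv), length(classes), dimnames = list(NULL, classes))
  for (j in seq_len(ncol(dv))) {
    pair <- strsplit(colnames(dv)[j], "/", fixed = TRUE)[[1]]
    v <- dv[, j]
    winner <- ifelse(v > 0, pair[1], pair[2])
    votes[cbind(seq_along(v), match(winner, classes))] <-
      votes[cbind(seq_along(v), match(winner, classes))] + 1L
    agg[, pair[1]] <- agg[, pair[1]] + v
    agg[, pair[2]] <- agg[, pair[2]] - v
  }
  pick <- vapply(seq_len(nrow(votes)), function(i) {
    best <- which(votes[i, ] == max(votes[i, ]))
    if (length(best) > 1) best <- best[which.max(agg[i, best])]
    best
  }, integer(1))
  factor(classes[pick], levels = classes)
}

#' Train an RBF-kernel SVM with inner-CV grid search
#'
#' Exhaustive search over `C_grid` x `gamma_grid` by stratified k-fold
#' cross-validation on the training epochs, selecting the highest mean
#' validation accuracy (ties broken toward the smallest C, then the smallest
#' gamma); the winning pair is refit on all training epochs. Features are
#' used as supplied (the pipeline feeds 0--1 normalized columns), without
#' libsvm's internal rescaling.
#'
#' @param table A `somno_features` data frame (or any data frame containing
#'   `config$features`).
#' @param labels Per-epoch target labels (>= 2 classes present).
#' @param config A [model_config()].
#' @return Object of class `somno_model`: the fitted machine plus the
#'   selected `(C, gamma)`, feature list, class levels and tuning table.
#' @export
train_svm <- function(table, labels, config) {
  stopifnot(inherits(config, "somno_model_config"))
  miss <- setdiff(config$features, names(table))
  if (length(miss)) {
    stop("features missing from table: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (length(labels) != nrow(table)) {
    stop("feature/label length mismatch", call. = FALSE)
  }
  y <- droplevels(factor(labels))
  if (nlevels(y) < 2) stop("labels contain a single class", call. = FALSE)
  x <- as.matrix(table[, config$features, drop = FALSE])
  if (anyNA(x)) stop("missing feature values", call. = FALSE)

  tune_idx <- seq_len(nrow(x))
  if (nrow(x) > config$tune_max) {
    tune_idx <- with_seed(derive_seed(config$seed, 1L, 3L), {
      unlist(lapply(levels(y), function(cl) {
        i <- which(y == cl)
        sample(i, max(2L, round(length(i) * config$tune_max / nrow(x))))
      }))
    })
  }
  xt <- x[tune_idx, , drop = FALSE]
  yt <- droplevels(y[tune_idx])
  fold <- stratified_folds(yt, config$folds, derive_seed(config$seed, 2L, 3L))

  tuning <- expand.grid(C = config$C_grid, gamma = config$gamma_grid,
                        KEEP.OUT.ATTRS = FALSE)
  tuning$accuracy <- NA_real_
  best <- list(acc = -Inf, C = NA, gamma = NA)
  for (C in config$C_grid) {
    for (g in config$gamma_grid) {
      acc <- numeric(config$folds)
      for (f in seq_len(config$folds)) {
        tr <- fold != f
        fit <- e1071::svm(xt[tr, , drop = FALSE], droplevels(yt[tr]),
                          kernel = "radial", cost = C, gamma = g,
                          scale = FALSE)
        pr <- predict_svm(fit, xt[!tr, , drop = FALSE], levels(yt))
        acc[f] <- mean(as.character(pr) == as.character(yt[!tr]))
      }
      m <- mean(acc)
      tuning$accuracy[tuning$C == C & tuning$gamma == g] <- m
      if (m > best$acc) best <- list(acc = m, C = C, gamma = g)
    }
  }
  fit <- e1071::svm(x, y, kernel = "radial", cost = best$C,
                    gamma = best$gamma, scale = FALSE)
  structure(
    list(task = config$task, fit = fit, C = best$C, gamma = best$gamma,
         cv_accuracy = best$acc, features = config$features,
         levels = levels(y), tuning = tuning, config = config),
    class = "somno_model"
  )
}

#' @export
print.somno_model <- function(x, ...) {
  cat(sprintf("<somno_model> task %s: %d features, classes %s\n", x$task,
              length(x$features), paste(x$levels, collapse = "/")))
  cat(sprintf("  selected C = %g, gamma = %g (inner-CV accuracy %.3f)\n",
              x$C, x$gamma, x$cv_accuracy))
  invisible(x)
}

#' Predict epoch labels with a trained model
#'
#' @param object A `somno_model`.
#' @param table Data frame containing the model's feature columns.
#' @param ... Unused.
#' @return Factor of predicted labels, one per row; for binary tasks the
#'   decision scores (oriented toward the second class level) are attached
#'   as `attr(, "score")`.
#' @export
predict.somno_model <- function(object, table, ...) {
  miss <- setdiff(object$features, names(table))
  if (length(miss)) {
    stop("features missing from table: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  x <- as.matrix(table[, object$features, drop = FALSE])
  predict_svm(object$fit, x, object$levels)
}

# choose one held-out rat per group, deterministically from the seed
split_rats <- function(table, seed) {
  sham <- sort(unique(table$rat_id[table$group == "sham"]))
  lesion <- sort(unique(table$rat_id[table$group == "lesion"]))
  if (length(sham) < 2 || length(lesion) < 2) {
    stop("need at least 2 rats per group", call. = FALSE)
  }
  with_seed(seed, list(
    sham_train = NULL, lesion_train = NULL,
    sham_test = sample(sham, 1), lesion_test = sample(lesion, 1)
  )) -> sp
  sp$sham_train <- setdiff(sham, sp$sham_test)
  sp$lesion_train <- setdiff(lesion, sp$lesion_test)
  sp
}

ensure_normalized <- function(table) {
  if (!isTRUE(attr(table, "normalized"))) {
    table <- normalize_features(table)
  }
  table
}

sleep_feature_set <- function(site) {
  bands <- band_scheme()$band
  c(paste0("pow_", site, "_", bands), "emg_amp", paste0("cmc_", site, "_", bands))
}

#' Cross-group sleep--wake scoring protocol
#'
#' Trains one 3-state model on the sham training rats and one on the lesion
#' training rats (all but one randomly held-out rat per group), each on the
#' chosen site's 7 band powers, the EMG amplitude and the site's 7
#' coherence values, then evaluates both models on both held-out rats: four
#' confusion matrices.
#'
#' @param table A `somno_features` table for the whole cohort (normalized
#'   with [normalize_features()]; an unnormalized table is normalized with
#'   defaults first).
#' @param site `"occipital"` or `"frontal"`.
#' @param seed Integer seed (held-out rat choice, fold assignment).
#' @param ... Overrides passed to [model_config()] (for example `C_grid`).
#' @return Named list of four [evaluation_report()]s:
#'   `sham_train.sham_test`, `sham_train.lesion_test`,
#'   `lesion_train.sham_test`, `lesion_train.lesion_test`.
#' @export
run_sleep_protocol <- function(table, site = c("occipital", "frontal"),
                               seed = 1, ...) {
  site <- match.arg(site)
  table <- ensure_normalized(table)
  sp <- split_rats(table, derive_seed(seed, 1L, 4L))
  feats <- sleep_feature_set(site)
  cfg <- model_config("sleep3", feats, seed = derive_seed(seed, 2L, 4L), ...)
  out <- list()
  for (tg in c("sham", "lesion")) {
    train_rats <- sp[[paste0(tg, "_train")]]
    tr <- table[table$rat_id %in% train_rats, , drop = FALSE]
    model <- train_svm(tr, tr$state, cfg)
    for (eg in c("sham", "lesion")) {
      test_rat <- sp[[paste0(eg, "_test")]]
      te <- table[table$rat_id == test_rat, , drop = FALSE]
      pred <- predict(model, te)
      cm <- confusion_matrix(te$state, pred, vigilance_states())
      out[[paste0(tg, "_train.", eg, "_test")]] <- evaluation_report(
        cm, meta = list(label = sprintf("%s train -> %s test (%s)", tg, eg, site),
                        site = site, train_rats = train_rats,
                        test_rats = test_rat, C = model$C, gamma = model$gamma))
    }
  }
  out
}

#' Leave-one-pair-out parkinsonian diagnosis protocol
#'
#' Rats are paired by index after sorting ids (i-th sham with i-th lesion).
#' For each fold, a binary sham/lesion classifier is trained on the four
#' marker features over all epochs of the remaining pairs and tested on the
#' held-out pair. Per-fold accuracies and kappas are aggregated as
#' mean +/- SD, and the decision scores pooled over folds give the ROC/AUC.
#'
#' @inheritParams run_sleep_protocol
#' @param markers Feature columns of the binary classifier (default
#'   [pd_marker_features()]).
#' @return Object of class `somno_pd_result`: per-fold table, aggregate
#'   accuracy/kappa, pooled [evaluation_report()] with ROC and AUC.
#' @export
run_pd_protocol <- function(table, markers = pd_marker_features(),
                            seed = 1, ...) {
  table <- ensure_normalized(table)
  miss <- setdiff(markers, names(table))
  if (length(miss)) {
    stop("marker features missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  sham <- sort(unique(table$rat_id[table$group == "sham"]))
  lesion <- sort(unique(table$rat_id[table$group == "lesion"]))
  if (length(sham) != length(lesion) || length(sham) < 2) {
    stop("protocol requires equally many sham and lesion rats (>= 2 each)",
         call. = FALSE)
  }
  n_pairs <- length(sham)
  folds <- data.frame(pair = seq_len(n_pairs), accuracy = NA_real_,
                      kappa = NA_real_, C = NA_real_, gamma = NA_real_)
  scores <- truth <- vector("list", n_pairs)
  for (p in seq_len(n_pairs)) {
    test_rats <- c(sham[p], lesion[p])
    tr <- table[!(table$rat_id %in% test_rats), , drop = FALSE]
    te <- table[table$rat_id %in% test_rats, , drop = FALSE]
    cfg <- model_config("pd2", markers, seed = derive_seed(seed, p, 5L), ...)
    model <- train_svm(tr, tr$group, cfg)
    pred <- predict(model, te)
    cm <- confusion_matrix(te$group, pred, c("sham", "lesion"))
    folds$accuracy[p] <- sum(diag(cm)) / sum(cm)
    folds$kappa[p] <- cohens_kappa(cm)
    folds$C[p] <- model$C; folds$gamma[p] <- model$gamma
    sc <- attr(pred, "score")
    # orient pooled scores so larger = more lesion-like
    if (model$levels[2] != "lesion") sc <- -sc
    scores[[p]] <- sc
    truth[[p]] <- te$group
  }
  pooled_scores <- unlist(scores)
  pooled_truth <- unlist(truth)
  roc <- roc_auc(pooled_scores, pooled_truth, positive = "lesion")
  pooled_cm <- confusion_matrix(
    pooled_truth, ifelse(pooled_scores > 0, "lesion", "sham"),
    c("sham", "lesion"))
  structure(
    list(folds = folds,
         accuracy_mean = mean(folds$accuracy), accuracy_sd = sd(folds$accuracy),
         kappa_mean = mean(folds$kappa), kappa_sd = sd(folds$kappa),
         pooled = evaluation_report(pooled_cm,
                                    meta = list(label = "pooled leave-one-pair-out"),
                                    roc = roc),
         markers = markers),
    class = "somno_pd_result"
  )
}

#' @export
print.somno_pd_result <- function(x, ...) {
  cat(sprintf("<somno_pd_result> %d folds: accuracy %.3f +/- %.3f, kappa %.3f +/- %.3f, AUC %.3f\n",
              nrow(x$folds), x$accuracy_mean, x$accuracy_sd,
              x$kappa_mean, x$kappa_sd, x$pooled$roc$auc))
  invisible(x)
}

#' Integrated sleep-scoring and parkinsonian-recognition protocol
#'
#' A single 6-class model over (state x group) labels, trained on the sleep
#' features of the chosen site mode plus the EMG amplitude plus the four
#' marker features, using the training rats of both groups; tested on the
#' two held-out rats. Reports the 6-class confusion matrix and the two
#' marginals: 3-state scoring (group marginalized) and sham/lesion
#' recognition (state marginalized).
#'
#' @inheritParams run_sleep_protocol
#' @param site_mode `"frontal_only"` or `"occipital_frontal"`.
#' @return List of class `somno_integrated_result` with reports `six_class`,
#'   `state_marginal`, `pd_marginal`.
#' @export
run_integrated_protocol <- function(table,
                                    site_mode = c("frontal_only", "occipital_frontal"),
                                    seed = 1, ...) {
  site_mode <- match.arg(site_mode)
  table <- ensure_normalized(table)
  sp <- split_rats(table, derive_seed(seed, 1L, 4L))
  feats <- unique(c(
    if (site_mode == "occipital_frontal") sleep_feature_set("occipital"),
    sleep_feature_set("frontal"),
    pd_marker_features()
  ))
  lab6 <- function(df) paste(df$state, df$group, sep = "_")
  classes <- as.vector(outer(vigilance_states(), c("sham", "lesion"),
                             paste, sep = "_"))
  tr <- table[table$rat_id %in% c(sp$sham_train, sp$lesion_train), , drop = FALSE]
  te <- table[table$rat_id %in% c(sp$sham_test, sp$lesion_test), , drop = FALSE]
  cfg <- model_config("integrated6", feats, seed = derive_seed(seed, 2L, 4L), ...)
  model <- train_svm(tr, lab6(tr), cfg)
  pred6 <- as.character(predict(model, te))
  true6 <- lab6(te)
  meta <- list(label = sprintf("integrated (%s)", site_mode),
               site_mode = site_mode,
               train_rats = c(sp$sham_train, sp$lesion_train),
               test_rats = c(sp$sham_test, sp$lesion_test),
               C = model$C, gamma = model$gamma)
  part <- function(lab, i) vapply(strsplit(lab, "_", fixed = TRUE),
                                  `[`, "", i)
  structure(
    list(
      six_class = evaluation_report(
        confusion_matrix(true6, pred6, classes), meta = meta),
      state_marginal = evaluation_report(
        confusion_matrix(part(true6, 1), part(pred6, 1), vigilance_states()),
        meta = c(meta, marginal = "state")),
      pd_marginal = evaluation_report(
        confusion_matrix(part(true6, 2), part(pred6, 2), c("sham", "lesion")),
        meta = c(meta, marginal = "group"))
    ),
    class = "somno_integrated_result"
  )
}

#' @export
print.somno_integrated_result <- function(x, ...) {
  cat(sprintf("<somno_integrated_result> 6-class accuracy %.3f; state kappa %.3f; PD accuracy %.3f\n",
              x$six_class$metrics$accuracy, x$state_marginal$kappa,
              x$pd_marginal$metrics$accuracy))
  invisible(x)
}
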