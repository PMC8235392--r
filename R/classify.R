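#' Stratified train/test split
#'
#' Splits labeled samples 80/20 (by default) preserving class proportions
#' within one sample. With `groups` given (physical sample ids), all
#' measurements of one physical sample land on the same side, preventing
#' leakage of a sample's identity across the split; without it the split is
#' a literal row-level stratified split.
#'
#' @param labels Factor or character class labels.
#' @param train_fraction Fraction of each class assigned to training
#'   (default 0.8, strictly inside (0, 1)).
#' @param seed RNG seed for the split.
#' @param groups Optional grouping ids, same length as `labels`.
#' @return List with integer index vectors `train` and `test` (disjoint,
#'   covering all samples).
#' @export
stratified_split <- function(labels, train_fraction = 0.8, seed = 1L,
                             groups = NULL) {
  labels <- as.factor(labels)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be strictly between 0 and 1 ",
         "(both sides of the split must be non-empty)", call. = FALSE)
  }
  if (any(table(labels) < 2L)) {
    stop("every class needs at least 2 samples to split", call. = FALSE)
  }
  set.seed(seed)
  train <- integer(0)
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    if (is.null(groups)) {
      n_tr <- max(1L, min(length(idx) - 1L,
                          round(train_fraction * length(idx))))
      train <- c(train, sample(idx, n_tr))
    } else {
      g <- unique(groups[idx])
      n_tr <- max(1L, min(length(g) - 1L, round(train_fraction * length(g))))
      g_tr <- sample(g, n_tr)
      train <- c(train, idx[groups[idx] %in% g_tr])
    }
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

#' Extract classifier features from a cohort
#'
#' One row per thawing-range measurement (scheduled temperatures, next-day
#' excluded): the resistance or reactance values at the 36 grid
#' frequencies, ordered by ascending frequency -- the sequence axis the
#' LSTM walks along.
#'
#' @param cohort An `ft_cohort`.
#' @param channel `"X"` (reactance) or `"R"` (resistance).
#' @param temperatures Measurement schedule to include (default
#'   `seq(0, 4, 0.5)`).
#' @param tol Temperature matching tolerance, degrees C.
#' @return List with `x` (matrix, rows = spectra), `labels` (factor
#'   treatment), `groups` (sample ids), `temperature_C`.
#' @export
cohort_features <- function(cohort, channel = c("X", "R"),
                            temperatures = seq(0, 4, by = 0.5), tol = 0.25) {
  channel <- match.arg(channel)
  rows <- list(); labels <- character(); groups <- character()
  temps_out <- numeric()
  for (tC in temperatures) {
    for (s in select_at_temperature(cohort, tC, tol = tol)) {
      rows[[length(rows) + 1L]] <-
        if (channel == "R") s$resistance_ohm else s$reactance_ohm
      labels <- c(labels, s$treatment)
      groups <- c(groups, s$sample_id)
      temps_out <- c(temps_out, s$temperature_C)
    }
  }
  if (length(rows) == 0L) stop("no measurements matched the schedule",
                               call. = FALSE)
  ord <- order(groups, temps_out)
  list(x = do.call(rbind, rows)[ord, , drop = FALSE],
       labels = factor(labels[ord]), groups = groups[ord],
       temperature_C = temps_out[ord])
}

#' Train the LSTM thawing-method classifier
#'
#' Mini-batch Adam training with early stopping on the held-out loss.
#' Inputs are standardized per frequency point with training-set statistics
#' only; the standardization travels with the model. All randomness
#' (initialization, shuffling, dropout) derives from `config$seed`, so a
#' rerun with the same data and config reproduces the model exactly.
#'
#' @param x Feature matrix, samples x seq_len (e.g. from
#'   [cohort_features()]).
#' @param labels Factor with >= 2 represented classes.
#' @param config An [lstm_config()].
#' @param split List with `train`/`test` indices (e.g. from
#'   [stratified_split()]); by default an ungrouped stratified 80/20 split
#'   seeded from the config.
#' @return List with `model` (`lstm_model`, best-epoch weights) and
#'   `report` (per-epoch training/held-out loss and accuracy, split
#'   indices, best epoch, seed).
#' @export
train_classifier <- function(x, labels, config = lstm_config(),
                             split = NULL) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2L) stop("need at least 2 classes", call. = FALSE)
  if (is.null(split)) {
    split <- stratified_split(labels, 0.8, seed = config$seed)
  }
  x_tr <- x[split$train, , drop = FALSE]
  y_tr <- as.integer(labels[split$train])
  x_te <- x[split$test, , drop = FALSE]
  y_te <- as.integer(labels[split$test])
  set.seed(config$seed)
  model <- lstm_init(config, seq_len = ncol(x), n_classes = nlevels(labels))
  model$classes <- levels(labels)
  mu <- colMeans(x_tr)
  sd_tr <- apply(x_tr, 2L, stats::sd)
  sd_tr[sd_tr < 1e-12] <- 1
  model$norm <- list(mean = mu, sd = sd_tr)
  adam <- list(m = lapply(model$params, function(p) p * 0),
               v = lapply(model$params, function(p) p * 0),
               t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
  n_tr <- nrow(x_tr)
  report <- data.frame(epoch = integer(), train_loss = numeric(),
                       train_accuracy = numeric(), heldout_loss = numeric(),
                       heldout_accuracy = numeric())
  best <- list(loss = Inf, params = model$params, bn = model$bn_stats,
               epoch = 0L)
  wait <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    idx <- sample(n_tr)
    batch_losses <- numeric(); batch_n <- integer(); batch_correct <- integer()
    for (start in seq(1L, n_tr, by = config$batch_size)) {
      bi <- idx[start:min(start + config$batch_size - 1L, n_tr)]
      if (length(bi) < 2L) next  # batch statistics need >= 2 rows
      gr <- lstm_gradients(model, x_tr[bi, , drop = FALSE], y_tr[bi],
                           training = TRUE)
      if (!is.finite(gr$loss)) {
        stop("training diverged (non-finite loss) at epoch ", epoch,
             call. = FALSE)
      }
      # refresh running batch-norm statistics from this batch
      fw <- lstm_forward(model, x_tr[bi, , drop = FALSE], training = TRUE,
                         keep_cache = TRUE)
      model$bn_stats$mean <- fw$cache$bn_running$mean
      model$bn_stats$var <- fw$cache$bn_running$var
      adam$t <- adam$t + 1L
      for (nm in names(model$params)) {
        g <- gr$grads[[nm]]
        adam$m[[nm]] <- adam$beta1 * adam$m[[nm]] + (1 - adam$beta1) * g
        adam$v[[nm]] <- adam$beta2 * adam$v[[nm]] + (1 - adam$beta2) * g^2
        mhat <- adam$m[[nm]] / (1 - adam$beta1^adam$t)
        vhat <- adam$v[[nm]] / (1 - adam$beta2^adam$t)
        model$params[[nm]] <- model$params[[nm]] -
          config$learning_rate * mhat / (sqrt(vhat) + adam$eps)
      }
      pred <- max.col(fw$probs)
      batch_losses <- c(batch_losses, gr$loss)
      batch_n <- c(batch_n, length(bi))
      batch_correct <- c(batch_correct, sum(pred == y_tr[bi]))
    }
    ev_tr <- list(loss = stats::weighted.mean(batch_losses, batch_n),
                  accuracy = sum(batch_correct) / sum(batch_n))
    ev_te <- evaluate_classifier(model, x_te, y_te)
    report <- rbind(report, data.frame(
      epoch = epoch, train_loss = ev_tr$loss,
      train_accuracy = ev_tr$accuracy, heldout_loss = ev_te$loss,
      heldout_accuracy = ev_te$accuracy))
    if (ev_te$loss < best$loss - 1e-9) {
      best <- list(loss = ev_te$loss, params = model$params,
                   bn = model$bn_stats, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  model$params <- best$params
  model$bn_stats <- best$bn
  list(model = model,
       report = list(history = report, best_epoch = best$epoch,
                     seed = config$seed, split = split,
                     heldout_accuracy =
                       report$heldout_accuracy[best$epoch],
                     heldout_loss = report$heldout_loss[best$epoch]))
}

#' Evaluate the classifier on a labeled set
#'
#' Evaluation mode (dropout off, running batch-norm statistics): accuracy is
#' the fraction of argmax-correct predictions, loss the mean cross-entropy
#' (no ridge term).
#'
#' @param model A trained `lstm_model`.
#' @param x Feature matrix.
#' @param labels Integer labels (1-based) or factor matching
#'   `model$classes`.
#' @return List with `accuracy` and `loss`.
#' @export
evaluate_classifier <- function(model, x, labels) {
  if (nrow(x) == 0L) stop("test set must be non-empty", call. = FALSE)
  y <- if (is.numeric(labels)) as.integer(labels)
       else as.integer(factor(as.character(labels), levels = model$classes))
  fw <- lstm_forward(model, x, training = FALSE)
  list(accuracy = mean(max.col(fw$probs) == y),
       loss = -mean(log(pmax(fw$probs[cbind(seq_len(nrow(x)), y)],
                             1e-300))))
}

#' Class probabilities for new spectra
#'
#' @param model A trained `lstm_model`.
#' @param x Feature matrix (rows = spectra).
#' @return Matrix of class probabilities with `model$classes` as columns.
#' @export
predict_classifier <- function(model, x) {
  probs <- lstm_forward(model, x, training = FALSE)$probs
  colnames(probs) <- model$classes
  probs
}

#' Serialize / restore an LSTM model as JSON
#'
#' Single self-contained JSON document: weights, batch-norm running
#' statistics, input standardization, config and class labels, written at
#' full double precision so a reloaded model predicts identically.
#'
#' @param model A trained `lstm_model`.
#' @param path Output (input) JSON path.
#' @return `write_classifier_json`: `path` invisibly;
#'   `read_classifier_json`: the restored `lstm_model`.
#' @export
write_classifier_json <- function(model, path) {
  doc <- list(
    params = lapply(model$params, function(p) {
      if (is.matrix(p)) list(dim = dim(p), values = as.numeric(p))
      else list(dim = NULL, values = as.numeric(p))
    }),
    bn_stats = list(mean = list(dim = dim(model$bn_stats$mean),
                                values = as.numeric(model$bn_stats$mean)),
                    var = list(dim = dim(model$bn_stats$var),
                               values = as.numeric(model$bn_stats$var)),
                    momentum = model$bn_stats$momentum,
                    eps = model$bn_stats$eps),
    norm = model$norm,
    config = unclass(model$config),
    classes = model$classes,
    seq_len = model$seq_len)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_classifier_json
#' @export
read_classifier_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  unpack <- function(el) {
    if (!is.null(el$dim) && length(el$dim) == 2L) {
      matrix(el$values, el$dim[1L], el$dim[2L])
    } else {
      el$values
    }
  }
  cfg <- do.call(lstm_config, doc$config[setdiff(names(doc$config), NULL)])
  model <- structure(list(
    params = lapply(doc$params, unpack),
    bn_stats = list(mean = unpack(doc$bn_stats$mean),
                    var = unpack(doc$bn_stats$var),
                    momentum = doc$bn_stats$momentum,
                    eps = doc$bn_stats$eps),
    norm = list(mean = doc$norm$mean, sd = doc$norm$sd),
    config = cfg, classes = doc$classes,
    seq_len = as.integer(doc$seq_len)), class = "lstm_model")
  model
}

#' Train and evaluate one channel of the cohort classification experiment
#'
#' Convenience wrapper reproducing the discrimination protocol: extract the
#' 180-spectrum feature table (9 scheduled temperatures x 20 samples) for
#' one input channel, split 80/20 stratified by class, train, and report
#' held-out accuracy and loss.
#'
#' @param cohort An `ft_cohort`.
#' @param channel `"X"` or `"R"`.
#' @param config An [lstm_config()]; its `input_channel` is overridden by
#'   `channel`.
#' @param grouped Group-aware split keeping each physical sample on one
#'   side (default FALSE: literal row-level 80/20).
#' @return The [train_classifier()] result, plus `features` and `channel`.
#' @export
classify_cohort <- function(cohort, channel = c("X", "R"),
                            config = lstm_config(), grouped = FALSE) {
  channel <- match.arg(channel)
  config$input_channel <- channel
  feats <- cohort_features(cohort, channel = channel)
  split <- stratified_split(feats$labels, 0.8, seed = config$seed,
                            groups = if (grouped) feats$groups else NULL)
  res <- train_classifier(feats$x, feats$labels, config, split = split)
  res$channel <- channel
  res$features <- feats
  res
}
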