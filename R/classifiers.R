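#' Training configuration for the compartment classifiers
#'
#' Defaults: Adam with learning rate 1e-4,
#' categorical cross-entropy, early stopping on validation loss with
#' patience 25 and at most 1000 epochs, stratified 3-fold cross-validation
#' with 10 replicate trainings per fold (best kept by validation AUROC),
#' and class weighting `n_samples / (n_classes * n_c)` on the loss.
#'
#' @param learning_rate Adam learning rate.
#' @param patience Early-stopping patience in epochs; must be below
#'   `max_epochs`.
#' @param max_epochs Epoch cap.
#' @param folds Cross-validation folds (>= 2).
#' @param replicates_per_fold Replicate trainings per fold.
#' @param class_weighting Apply balanced class weights to the loss.
#' @param batch_size Mini-batch size.
#' @param dropout Dropout rate for the CNN dense head.
#' @param val_fraction Stratified fraction of each training fold carved out
#'   for early stopping / replicate selection.
#' @param seed Integer seed controlling folds, splits and initializations.
#' @return Object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, patience = 25,
                         max_epochs = 1000, folds = 3,
                         replicates_per_fold = 10, class_weighting = TRUE,
                         batch_size = 32, dropout = 0.3, val_fraction = 0.1,
                         seed = 1L) {
  stopifnot(folds >= 2, patience < max_epochs, replicates_per_fold >= 1)
  structure(list(learning_rate = learning_rate, patience = patience,
                 max_epochs = max_epochs, folds = folds,
                 replicates_per_fold = replicates_per_fold,
                 class_weighting = class_weighting, batch_size = batch_size,
                 dropout = dropout, val_fraction = val_fraction,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' One-vs-rest AUROC of a binary score
#'
#' Rank-based (Mann-Whitney) AUROC; ties count one half.
#' @param scores Numeric scores (higher = more positive).
#' @param positive Logical vector of positive membership.
#' @return AUROC in `[0, 1]`.
#' @export
binary_auroc <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  stopifnot(n1 > 0, n0 > 0)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Macro-averaged one-vs-rest AUROC
#'
#' Per class, the AUROC of that class's score against binary membership;
#' the macro value is the unweighted mean over classes present in the
#' labels. Classes in the score matrix but absent from the labels are
#' skipped with a warning.
#'
#' @param scores Matrix of per-class scores/probabilities, columns named
#'   by class.
#' @param labels Class labels (character or factor), one per row.
#' @return Macro one-vs-rest AUROC, with per-class values in attribute
#'   `per_class`.
#' @export
macro_ovr_auroc <- function(scores, labels) {
  labels <- as.character(labels)
  classes <- colnames(scores)
  per <- setNames(rep(NA_real_, length(classes)), classes)
  for (cl in classes) {
    if (!any(labels == cl)) {
      warning("class absent from labels, skipped: ", cl)
      next
    }
    per[cl] <- binary_auroc(scores[, cl], labels == cl)
  }
  out <- mean(per, na.rm = TRUE)
  attr(out, "per_class") <- per
  out
}

#' Univariate AUROC screening of features
#'
#' For each feature, fits a univariate logistic model per class
#' (one-vs-rest) on the full data, scores samples by the fitted
#' probability, and computes the macro one-vs-rest AUROC. Features with
#' AUROC strictly above 0.5 are retained. Because the logistic fit flips
#' anti-predictive features, a feature whose raw ranking yields AUROC 0.3
#' screens at 0.7.
#'
#' @param features Numeric matrix (samples x features) or `feature_matrix`.
#' @param labels Class labels, one per row.
#' @return Data frame `feature`, `auroc`, `retained`; retained names in
#'   attribute `retained`.
#' @export
screen_features <- function(features, labels) {
  x <- unclass(as.matrix(features))
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least 2 classes")
  auc <- vapply(seq_len(ncol(x)), function(j) {
    per <- vapply(classes, function(cl) {
      yy <- as.numeric(labels == cl)
      fit <- suppressWarnings(glm(yy ~ x[, j], family = binomial()))
      binary_auroc(fitted(fit), yy == 1)
    }, numeric(1))
    mean(per)
  }, numeric(1))
  res <- data.frame(feature = colnames(x) %||% as.character(seq_len(ncol(x))),
                    auroc = auc, retained = auc > 0.5)
  if (!any(res$retained)) stop("screening dropped every feature")
  attr(res, "retained") <- res$feature[res$retained]
  res
}

#' One-hot encode protein sequences
#'
#' @param records List of [protein_record()]s.
#' @param pad_length Common length; sequences longer than this error.
#'   Positions past a sequence's end are all-zero; `X` encodes as an
#'   all-zero row.
#' @return Array `(n, pad_length, 20)`, third dimension named by residue.
#' @export
one_hot_encode <- function(records, pad_length) {
  n <- length(records)
  out <- array(0, c(n, pad_length, 20),
               dimnames = list(record_ids(records), NULL, AA20))
  for (i in seq_len(n)) {
    chars <- seq_chars(records[[i]])
    if (length(chars) > pad_length) {
      stop("sequence longer than pad_length: ", records[[i]]$id)
    }
    for (t in seq_along(chars)) {
      if (chars[t] != "X") out[i, t, chars[t]] <- 1
    }
  }
  out
}

#' Stratified fold assignment
#'
#' Deals each class's shuffled members round-robin over folds, so each
#' fold's class counts are within one sample of proportionality.
#'
#' @param labels Class labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer fold id per sample.
#' @export
stratified_folds <- function(labels, k, seed = 1L) {
  labels <- as.character(labels)
  set.seed(derive_seed(seed, "folds"))
  fold <- integer(length(labels))
  offset <- 0L
  for (cl in sort(unique(labels))) {
    idx <- sample(which(labels == cl))
    fold[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    offset <- offset + length(idx)
  }
  fold
}

balanced_class_weights <- function(labels) {
  tab <- table(labels)
  w <- length(labels) / (length(tab) * tab)
  setNames(as.numeric(w[labels]), NULL)
}

## stratified early-stopping split: indices (relative to idx) held out
stratified_val_split <- function(labels, frac) {
  val <- integer(0)
  for (cl in unique(labels)) {
    members <- which(labels == cl)
    n_val <- max(1L, round(frac * length(members)))
    val <- c(val, sample(members, n_val))
  }
  sort(val)
}

## shared cross-validation driver for the three classifiers
train_classifier_cv <- function(x, labels, cfg, build_net, model_name) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  y_idx <- match(labels, classes)
  n <- length(labels)
  counts <- table(labels)
  if (any(counts < cfg$folds)) {
    stop("every class needs at least `folds` members")
  }
  w <- if (cfg$class_weighting) balanced_class_weights(labels) else rep(1, n)
  fold <- stratified_folds(labels, cfg$folds, seed = cfg$seed)
  per_fold <- NULL
  per_class <- matrix(NA_real_, cfg$folds, length(classes),
                      dimnames = list(NULL, classes))
  scores <- vector("list", cfg$folds)
  models <- vector("list", cfg$folds)
  for (f in seq_len(cfg$folds)) {
    tr <- which(fold != f); te <- which(fold == f)
    set.seed(derive_seed(cfg$seed, paste0(model_name, "-split-", f)))
    val_rel <- stratified_val_split(labels[tr], cfg$val_fraction)
    va <- tr[val_rel]; tr2 <- setdiff(tr, va)
    best <- NULL
    for (rep_i in seq_len(cfg$replicates_per_fold)) {
      set.seed(derive_seed(cfg$seed,
                           paste0(model_name, "-f", f, "-r", rep_i)))
      net <- build_net()
      res <- nn_train(net, take_rows(x, tr2), y_idx[tr2], w[tr2],
                      take_rows(x, va), y_idx[va], w[va],
                      lr = cfg$learning_rate, batch_size = cfg$batch_size,
                      max_epochs = cfg$max_epochs, patience = cfg$patience)
      val_probs <- nn_predict(res$net, take_rows(x, va))
      colnames(val_probs) <- classes
      val_auc <- suppressWarnings(macro_ovr_auroc(val_probs, labels[va]))
      if (is.null(best) || val_auc > best$val_auc) {
        best <- list(net = res$net, val_auc = val_auc, replicate = rep_i,
                     best_epoch = res$best_epoch,
                     epochs_run = res$epochs_run)
      }
    }
    test_probs <- nn_predict(best$net, take_rows(x, te))
    colnames(test_probs) <- classes
    macro <- suppressWarnings(macro_ovr_auroc(test_probs, labels[te]))
    per_class[f, ] <- attr(macro, "per_class")
    train_probs <- nn_predict(best$net, take_rows(x, tr))
    train_acc <- mean(classes[max.col(train_probs)] == labels[tr])
    per_fold <- rbind(per_fold, data.frame(
      fold = f, macro_auroc = as.numeric(macro), train_accuracy = train_acc,
      selected_replicate = best$replicate, val_auroc = best$val_auc,
      best_epoch = best$best_epoch, epochs_run = best$epochs_run))
    scores[[f]] <- data.frame(fold = f, id = te, label = labels[te],
                              test_probs, check.names = FALSE)
    models[[f]] <- best$net
  }
  structure(list(model = model_name, classes = classes,
                 per_fold = per_fold, per_class_auroc = per_class,
                 macro_auroc = mean(per_fold$macro_auroc),
                 scores = do.call(rbind, scores), fold_assignment = fold,
                 class_weights = if (cfg$class_weighting)
                   length(labels) / (length(classes) * counts) else NULL,
                 models = models, config = cfg),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report> %s: macro one-vs-rest AUROC %.3f over %d folds\n",
              x$model, x$macro_auroc, nrow(x$per_fold)))
  print(x$per_fold[, c("fold", "macro_auroc", "train_accuracy",
                       "selected_replicate", "best_epoch")], row.names = FALSE)
  invisible(x)
}

#' Feature-based MLP compartment classifier
#'
#' Two hidden layers of 128 and 64 units, each followed by batch
#' normalization and ReLU, softmax output; trained under stratified
#' cross-validation per the configuration. Features are expected screened
#' ([screen_features()]) and MinMax-normalized.
#'
#' @param features Numeric matrix (samples x features), no `NA`.
#' @param labels Class labels, one per row.
#' @param cfg A [train_config()].
#' @return A `classifier_report`.
#' @export
train_feature_mlp <- function(features, labels, cfg = train_config()) {
  x <- unclass(as.matrix(features))
  if (anyNA(x)) stop("NaN/NA in features")
  k <- length(unique(labels))
  build <- function() nn_new(list(
    nn_init_dense(ncol(x), 128), nn_init_batchnorm(128), list(type = "relu"),
    nn_init_dense(128, 64), nn_init_batchnorm(64), list(type = "relu"),
    nn_init_dense(64, k)))
  train_classifier_cv(x, labels, cfg, build, "feature_mlp")
}

#' Embedding-based MLP compartment classifier
#'
#' Same architecture and protocol as [train_feature_mlp()], applied to
#' fixed-length per-protein embedding vectors; no screening.
#'
#' @param embeddings Numeric matrix (proteins x embedding dims), rownames =
#'   protein ids.
#' @param labels Named or positional class labels; every labelled protein
#'   must have an embedding of the common dimension.
#' @param cfg A [train_config()].
#' @return A `classifier_report`.
#' @export
train_embedding_mlp <- function(embeddings, labels, cfg = train_config()) {
  x <- as.matrix(embeddings)
  if (!is.null(names(labels))) {
    miss <- setdiff(names(labels), rownames(x))
    if (length(miss)) stop("missing embedding for labelled protein(s): ",
                           paste(head(miss, 5), collapse = ", "))
    x <- x[names(labels), , drop = FALSE]
  }
  if (length(labels) != nrow(x)) stop("embedding/label dimension mismatch")
  if (anyNA(x)) stop("NaN/NA in embeddings")
  k <- length(unique(labels))
  build <- function() nn_new(list(
    nn_init_dense(ncol(x), 128), nn_init_batchnorm(128), list(type = "relu"),
    nn_init_dense(128, 64), nn_init_batchnorm(64), list(type = "relu"),
    nn_init_dense(64, k)))
  train_classifier_cv(x, as.character(labels), cfg, build, "embedding_mlp")
}

#' Sequence CNN compartment classifier
#'
#' Five convolutional blocks (128 same-padding filters, kernel 10, ReLU,
#' max pooling with pool size 2), global average pooling, a 64-unit dense
#' layer with dropout, and softmax classification, trained under the same
#' protocol as the MLPs.
#'
#' @param tensor One-hot array from [one_hot_encode()], `(n, L, 20)` with
#'   `L >= 32` so five poolings survive.
#' @param labels Class labels, one per sequence.
#' @param cfg A [train_config()].
#' @param n_filters,kernel,blocks Architecture knobs (defaults 128, 10, 5).
#' @return A `classifier_report`.
#' @export
train_seq_cnn <- function(tensor, labels, cfg = train_config(),
                          n_filters = 128, kernel = 10, blocks = 5) {
  stopifnot(length(dim(tensor)) == 3)
  if (dim(tensor)[2] < 2^blocks) {
    stop("pad_length must be at least 2^blocks")
  }
  k <- length(unique(labels))
  build <- function() {
    layers <- list()
    c_in <- dim(tensor)[3]
    for (b in seq_len(blocks)) {
      layers <- c(layers, list(nn_init_conv(c_in, n_filters, kernel),
                               list(type = "relu"),
                               list(type = "maxpool")))
      c_in <- n_filters
    }
    layers <- c(layers, list(list(type = "gap"),
                             nn_init_dense(n_filters, 64),
                             list(type = "relu"),
                             list(type = "dropout", rate = cfg$dropout),
                             nn_init_dense(64, k)))
    nn_new(layers)
  }
  train_classifier_cv(tensor, labels, cfg, build, "seq_cnn")
}
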