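## gradient of the model's class output wrt the input, inference mode
nn_input_gradient <- function(net, x, class_idx, output = "prob") {
  fw <- nn_forward(net, x, training = FALSE)
  logits <- fw$out
  n <- nrow(logits)
  if (output == "prob") {
    p <- softmax(logits)
    dlogits <- -p * p[, class_idx]
    dlogits[, class_idx] <- dlogits[, class_idx] + p[, class_idx]
  } else {
    dlogits <- matrix(0, n, ncol(logits))
    dlogits[, class_idx] <- 1
  }
  nn_backward(net, fw$caches, dlogits)$dx
}

model_output <- function(net, x, class_idx, output = "prob") {
  logits <- nn_forward(net, x, training = FALSE)$out
  if (output == "prob") softmax(logits)[, class_idx] else logits[, class_idx]
}

#' Integrated-gradients attribution for one input
#'
#' Attribution of the model's output for a target class to each input
#' feature, by averaging input gradients over `steps` interpolation points
#' on the straight path from the zero baseline to the input:
#' `attribution_i = x_i * mean_k dF/dx_i evaluated at (k/steps) * x`,
#' k = 1..steps (Riemann sum including the endpoint; trapezoidal available
#' as an option). For a linear model this is exact for any number of steps,
#' and in general the attributions sum approximately to
#' `F(x) - F(baseline)` (completeness).
#'
#' @param model A trained network (e.g. a fold model from
#'   [train_feature_mlp()], `report$models[[f]]`).
#' @param x Numeric feature vector (model input space).
#' @param target_class Integer index of the class output to attribute.
#' @param steps Interpolation steps (default 50; must be >= 1).
#' @param output `"prob"` (softmax probability, default) or `"logit"`.
#' @param rule `"riemann"` (default) or `"trapezoid"`.
#' @return Named numeric attribution per feature, with attributes `fx`
#'   (model output at `x`) and `f0` (at the baseline).
#' @export
integrated_gradients <- function(model, x, target_class, steps = 50,
                                 output = c("prob", "logit"),
                                 rule = c("riemann", "trapezoid")) {
  output <- match.arg(output); rule <- match.arg(rule)
  if (steps < 1) stop("steps must be >= 1")
  x <- as.numeric(x)
  alphas <- seq_len(steps) / steps
  pts <- outer(alphas, x)                     # steps x p
  grads <- nn_input_gradient(model, pts, target_class, output = output)
  mg <- if (rule == "riemann") {
    colMeans(grads)
  } else {
    g0 <- nn_input_gradient(model, matrix(0, 1, length(x)), target_class,
                            output = output)
    wts <- c(rep(1, steps - 1), 0.5)
    (0.5 * as.numeric(g0) + colSums(grads * wts)) / steps
  }
  attr_vec <- x * mg
  names(attr_vec) <- names(x)
  attr(attr_vec, "fx") <- model_output(model, matrix(x, 1), target_class,
                                       output)
  attr(attr_vec, "f0") <- model_output(model, matrix(0, 1, length(x)),
                                       target_class, output)
  attr_vec
}

#' Class-balanced integrated-gradients feature ranking
#'
#' Computes per-sample attributions toward each sample's true class
#' (optionally the predicted class), averages them per class with each
#' sample weighted by the inverse of its class size (so classes contribute
#' equally), and ranks features by mean attribution per class.
#'
#' @param model A trained network.
#' @param x Numeric matrix (samples x features) in the model's input space.
#' @param labels True class labels; must use the class order the model was
#'   trained with (`classes`).
#' @param classes Character vector giving the model's class order.
#' @param steps Interpolation steps (default 50).
#' @param top_k Features reported per class in the `top` slot (default 8).
#' @param toward `"true"` (default) or `"predicted"` class.
#' @param output Passed to [integrated_gradients()].
#' @return Object of class `attribution_report`: list with `mean_attribution`
#'   (classes x features), `ranking` (data.frame `class`, `feature`,
#'   `score`, `rank`), `top` (per-class top-k), `steps`, `baseline`.
#' @export
class_balanced_summary <- function(model, x, labels, classes = NULL,
                                   steps = 50, top_k = 8,
                                   toward = c("true", "predicted"),
                                   output = "prob") {
  toward <- match.arg(toward)
  x <- as.matrix(x)
  labels <- as.character(labels)
  if (is.null(classes)) classes <- sort(unique(labels))
  if (toward == "predicted") {
    pred <- nn_predict(model, x)
    labels <- classes[max.col(pred)]
  }
  p <- ncol(x)
  feat <- colnames(x) %||% paste0("f", seq_len(p))
  mean_attr <- matrix(NA_real_, length(classes), p,
                      dimnames = list(classes, feat))
  for (cl in classes) {
    idx <- which(labels == cl)
    if (!length(idx)) {
      warning("empty class skipped: ", cl)
      next
    }
    tc <- match(cl, classes)
    acc <- matrix(0, length(idx), p)
    for (i in seq_along(idx)) {
      acc[i, ] <- integrated_gradients(model, x[idx[i], ], tc, steps = steps,
                                       output = output)
    }
    mean_attr[cl, ] <- colMeans(acc)  # 1/n_c weight per sample
  }
  ranking <- do.call(rbind, lapply(classes, function(cl) {
    if (all(is.na(mean_attr[cl, ]))) return(NULL)
    ord <- order(mean_attr[cl, ], decreasing = TRUE)
    data.frame(class = cl, feature = feat[ord],
               score = unname(mean_attr[cl, ord]),
               rank = seq_len(p))
  }))
  top <- lapply(split(ranking, ranking$class),
                function(d) head(d$feature, top_k))
  structure(list(mean_attribution = mean_attr, ranking = ranking, top = top,
                 steps = steps, baseline = "zero vector"),
            class = "attribution_report")
}

#' @export
print.attribution_report <- function(x, ...) {
  cat(sprintf("<attribution_report> %d steps, zero baseline\n", x$steps))
  for (cl in names(x$top)) {
    cat(sprintf("  %s: %s\n", cl, paste(x$top[[cl]], collapse = ", ")))
  }
  invisible(x)
}
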