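#' Few-shot span classifiers
#'
#' Stage 2 of the pipeline maps an extracted span text into the feature's
#' closed vocabulary. Two classifiers are provided, both operating on the
#' embeddings of a small set of labelled example texts (typically 5-10 per
#' class):
#'
#' * **Prototype classifier** ([fit_prototype()]): scores each class by the
#'   maximum cosine similarity between the query embedding and that class's
#'   example embeddings (nearest labelled example; a centroid mode is also
#'   available), predicting the argmax class.
#' * **Contrastive few-shot classifier** ([fit_contrastive()]): first learns
#'   a linear refinement of the embedding space by gradient descent on a
#'   contrastive pair loss (same-class pairs pulled together, different-class
#'   pairs pushed below a margin), then fits a multinomial logistic head on
#'   the refined embeddings — the two-stage structure of few-shot
#'   sentence-embedding fine-tuning, realised at desk scale.
#'
#' Ties are broken by schema class order; `"not_present"` is never a
#' classifier target (it is assigned by routing, not classification).
#'
#' @name fewshot-classifiers
NULL

check_examples <- function(examples, feature = NULL) {
  stopifnot(is.data.frame(examples), all(c("text", "label") %in% names(examples)))
  if (!nrow(examples)) stop_ctx("no labelled examples supplied")
  examples$label <- normalize_label(examples$label)
  if (any(examples$label == NOT_PRESENT))
    stop_ctx("labelled examples may not use the reserved class 'not_present'")
  if (!is.null(feature)) {
    bad <- setdiff(unique(examples$label), feature$classes)
    if (length(bad))
      stop_ctx("example label '%s' not in vocabulary of feature '%s'",
               bad[1], feature$feature_id)
  }
  examples
}

example_classes <- function(examples, feature = NULL) {
  present <- unique(examples$label)
  if (!is.null(feature)) {
    cls <- setdiff(feature$classes, NOT_PRESENT)
    cls[cls %in% present]        # schema order restricted to observed classes
  } else present
}

softmax <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

#' Fit a prototype cosine-similarity classifier
#'
#' @param examples Data frame with columns `text`, `label` (one row per
#'   labelled example; every class to be predicted needs at least one).
#' @param embedder An embedding backend, e.g. [hashing_embedder()].
#' @param feature Optional [feature_schema()]; validates labels and fixes the
#'   tie-break class order.
#' @param mode `"max"` (nearest labelled example, default) or `"centroid"`.
#' @return An object of class `prototype_model`.
#' @export
fit_prototype <- function(examples, embedder, feature = NULL,
                          mode = c("max", "centroid")) {
  mode <- match.arg(mode)
  examples <- check_examples(examples, feature)
  classes <- example_classes(examples, feature)
  emb <- embedder$embed(examples$text)
  if (any(rowSums(emb^2) == 0))
    stop_ctx("example text embedded to the zero vector (empty text?)")
  structure(list(
    embeddings = emb,
    labels = examples$label,
    classes = classes,
    mode = mode,
    feature_id = if (!is.null(feature)) feature$feature_id else NA_character_,
    embedder = embedder
  ), class = "prototype_model")
}

#' @export
print.prototype_model <- function(x, ...) {
  cat(sprintf("<prototype_model> %d examples, %d classes (%s mode), embedder %s\n",
              nrow(x$embeddings), length(x$classes), x$mode, x$embedder$identity))
  invisible(x)
}

prototype_scores <- function(model, qvec) {
  sims <- as.numeric(model$embeddings %*% qvec)
  vapply(model$classes, function(cl) {
    s <- sims[model$labels == cl]
    if (model$mode == "max") max(s) else {
      centroid <- colMeans(model$embeddings[model$labels == cl, , drop = FALSE])
      nrm <- sqrt(sum(centroid^2))
      if (nrm > 0) sum(centroid * qvec) / nrm else 0
    }
  }, numeric(1))
}

#' Classify a span text with a prototype model
#'
#' @param model A [fit_prototype()] model.
#' @param text Non-empty span text.
#' @param temperature Softmax temperature for the reported confidence.
#' @return List with `label`, `confidence` (softmax probability of the
#'   winning class over per-class scores), and the per-class `scores`.
#' @export
classify_prototype <- function(model, text, temperature = 1) {
  stopifnot(inherits(model, "prototype_model"), temperature > 0)
  qvec <- as.numeric(model$embedder$embed(text))
  scores <- prototype_scores(model, qvec)
  probs <- softmax(scores / temperature)
  i <- which.max(scores)              # first class in schema order wins ties
  list(label = model$classes[i], confidence = unname(probs[i]),
       scores = scores)
}

#' @export
predict.prototype_model <- function(object, newdata, temperature = 1, ...) {
  res <- lapply(newdata, classify_prototype, model = object,
                temperature = temperature)
  data.frame(label = vapply(res, `[[`, "", "label"),
             confidence = vapply(res, `[[`, 0, "confidence"))
}

#' Sample contrastive training pairs
#'
#' For each labelled example, draws `R/2` positive pairs (a same-class
#' partner, outcome 1) and `R/2` negative pairs (a different-class partner,
#' outcome 0), uniformly with the given seed. A class with a single example
#' contributes only negative pairs (with a warning).
#'
#' @param examples Data frame with `text`, `label`; at least two classes.
#' @param R Pairs per example (split evenly between positive and negative).
#' @param seed Integer seed; the same seed reproduces the same pair list.
#' @return Data frame with columns `ia`, `ib` (example row indices), `y`.
#' @export
sample_pairs <- function(examples, R = 20L, seed = 1L) {
  examples <- check_examples(examples)
  if (length(unique(examples$label)) < 2L)
    stop_ctx("contrastive pairs need at least two classes")
  half <- max(1L, R %/% 2L)
  n <- nrow(examples)
  with_seed(seed, {
    ia <- ib <- integer(0); y <- integer(0)
    singleton_seen <- FALSE
    for (i in seq_len(n)) {
      same <- setdiff(which(examples$label == examples$label[i]), i)
      diff <- which(examples$label != examples$label[i])
      if (length(same)) {
        ia <- c(ia, rep(i, half)); ib <- c(ib, same[sample.int(length(same), half, replace = TRUE)])
        y <- c(y, rep(1L, half))
      } else singleton_seen <- TRUE
      ia <- c(ia, rep(i, half)); ib <- c(ib, diff[sample.int(length(diff), half, replace = TRUE)])
      y <- c(y, rep(0L, half))
    }
    if (singleton_seen)
      warning("class with a single example contributes only negative pairs",
              call. = FALSE)
    data.frame(ia = ia, ib = ib, y = y)
  })
}

#' Contrastive classifier configuration
#'
#' @param margin Cosine margin below which negative pairs stop being pushed.
#' @param pairs_per_example Pairs sampled per labelled example.
#' @param epochs Full-batch gradient-descent epochs for the refinement map.
#' @param learning_rate Step size for the refinement map.
#' @param lambda Ridge penalty of the multinomial logistic head.
#' @param seed Seed for pair sampling.
#' @export
contrastive_config <- function(margin = 0.25, pairs_per_example = 20L,
                               epochs = 10L, learning_rate = 0.01,
                               lambda = 1e-4, seed = 1L) {
  stopifnot(margin >= 0, margin < 1, epochs >= 0, learning_rate > 0, lambda >= 0)
  list(margin = margin, pairs_per_example = as.integer(pairs_per_example),
       epochs = as.integer(epochs), learning_rate = learning_rate,
       lambda = lambda, seed = as.integer(seed))
}

row_normalize <- function(m, eps = 1e-12) {
  m / pmax(sqrt(rowSums(m^2)), eps)
}

pair_loss <- function(s, y, margin) {
  ifelse(y == 1, (1 - s)^2, pmax(0, s - margin)^2)
}

# Ridge-penalised multinomial logistic regression fitted with L-BFGS-B from a
# deterministic zero initialisation (analytic gradient).
softmax_head_fit <- function(Z, y, classes, lambda = 1e-4, maxit = 300L) {
  n <- nrow(Z); d <- ncol(Z); K <- length(classes)
  Y <- outer(y, classes, `==`) * 1           # n x K indicator
  unpack <- function(par) list(W = matrix(par[seq_len(d * K)], d, K),
                               b = par[d * K + seq_len(K)])
  obj <- function(par) {
    p <- unpack(par)
    L <- Z %*% p$W + matrix(p$b, n, K, byrow = TRUE)
    L <- L - apply(L, 1, max)
    ll <- sum((L - log(rowSums(exp(L)))) * Y)
    -ll / n + lambda * sum(p$W^2) / 2
  }
  grad <- function(par) {
    p <- unpack(par)
    L <- Z %*% p$W + matrix(p$b, n, K, byrow = TRUE)
    L <- L - apply(L, 1, max)
    P <- exp(L) / rowSums(exp(L))
    D <- (P - Y) / n
    c(as.numeric(crossprod(Z, D)) + lambda * as.numeric(p$W), colSums(D))
  }
  fit <- stats::optim(numeric(d * K + K), obj, grad, method = "L-BFGS-B",
                      control = list(maxit = maxit))
  p <- unpack(fit$par)
  list(weights = p$W, bias = p$b, value = fit$value)
}

#' Fit the contrastive few-shot classifier
#'
#' Stage A learns a linear refinement map `W` (initialised at the identity)
#' by full-batch gradient descent on the contrastive pair loss
#' `y (1 - cos)^2 + (1 - y) max(0, cos - margin)^2` over sampled same- and
#' different-class pairs. Stage B fits a multinomial logistic head on the
#' re-normalised refined embeddings. Both stages are deterministic given the
#' configuration seed.
#'
#' @inheritParams fit_prototype
#' @param config A [contrastive_config()].
#' @return An object of class `contrastive_model` with the refinement map,
#'   the head, and the per-epoch mean pair loss (`loss_history`, starting at
#'   epoch 0).
#' @export
fit_contrastive <- function(examples, embedder, feature = NULL,
                            config = contrastive_config()) {
  examples <- check_examples(examples, feature)
  classes <- example_classes(examples, feature)
  if (length(classes) < 2L)
    stop_ctx("contrastive classifier needs at least two classes")
  E <- embedder$embed(examples$text)
  d <- ncol(E)
  W <- diag(d)
  loss_history <- numeric(0)
  if (config$epochs > 0L) {
    pairs <- sample_pairs(examples, R = config$pairs_per_example,
                          seed = config$seed)
    A <- E[pairs$ia, , drop = FALSE]
    B <- E[pairs$ib, , drop = FALSE]
    y <- pairs$y
    P <- nrow(A)
    for (epoch in seq_len(config$epochs + 1L)) {
      U <- A %*% t(W); V <- B %*% t(W)
      nu <- pmax(sqrt(rowSums(U^2)), 1e-12)
      nv <- pmax(sqrt(rowSums(V^2)), 1e-12)
      s <- rowSums(U * V) / (nu * nv)
      L <- mean(pair_loss(s, y, config$margin))
      if (!is.finite(L))
        stop_ctx("contrastive training diverged (non-finite pair loss at epoch %d)",
                 epoch - 1L)
      loss_history <- c(loss_history, L)
      if (epoch > config$epochs) break
      dLds <- ifelse(y == 1, -2 * (1 - s),
                     ifelse(s > config$margin, 2 * (s - config$margin), 0))
      Gu <- (dLds / (nu * nv)) * V - (dLds * s / nu^2) * U
      Gv <- (dLds / (nu * nv)) * U - (dLds * s / nv^2) * V
      GW <- (crossprod(Gu, A) + crossprod(Gv, B)) / P
      W <- W - config$learning_rate * GW
    }
  }
  Z <- row_normalize(E %*% t(W))
  head <- softmax_head_fit(Z, examples$label, classes, lambda = config$lambda)
  structure(list(
    W = W, head = head, classes = classes, config = config,
    loss_history = loss_history,
    feature_id = if (!is.null(feature)) feature$feature_id else NA_character_,
    embedder = embedder
  ), class = "contrastive_model")
}

#' @export
print.contrastive_model <- function(x, ...) {
  cat(sprintf("<contrastive_model> %d classes, %d refinement epochs, embedder %s\n",
              length(x$classes), x$config$epochs, x$embedder$identity))
  if (length(x$loss_history))
    cat(sprintf("  mean pair loss: %.4f -> %.4f\n",
                x$loss_history[1], x$loss_history[length(x$loss_history)]))
  invisible(x)
}

#' @export
coef.contrastive_model <- function(object, ...) {
  rbind(t(object$head$weights), bias = object$head$bias)
}

contrastive_probs <- function(model, texts) {
  E <- model$embedder$embed(texts)
  Z <- row_normalize(E %*% t(model$W))
  L <- Z %*% model$head$weights +
    matrix(model$head$bias, nrow(Z), length(model$classes), byrow = TRUE)
  t(apply(L, 1, softmax))
}

#' Classify a span text with the contrastive model
#'
#' @param model A [fit_contrastive()] model.
#' @param text Non-empty span text.
#' @return List with `label` (argmax head probability; ties go to the first
#'   class in schema order), `confidence` (that probability), and `probs`.
#' @export
classify_fewshot <- function(model, text) {
  stopifnot(inherits(model, "contrastive_model"))
  p <- contrastive_probs(model, text)[1, ]
  i <- which.max(p)
  list(label = model$classes[i], confidence = unname(p[i]),
       probs = stats::setNames(p, model$classes))
}

#' @export
predict.contrastive_model <- function(object, newdata, ...) {
  P <- contrastive_probs(object, newdata)
  i <- apply(P, 1, which.max)
  data.frame(label = object$classes[i],
             confidence = P[cbind(seq_len(nrow(P)), i)])
}

# Uniform interface used by the pipeline.
classify_span <- function(model, text, temperature = 1) {
  if (inherits(model, "prototype_model"))
    classify_prototype(model, text, temperature = temperature)
  else if (inherits(model, "contrastive_model"))
    classify_fewshot(model, text)
  else stop_ctx("unsupported classifier model of class '%s'", class(model)[1])
}
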