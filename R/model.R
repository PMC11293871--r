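#' Focal loss for multi-label classification
#'
#' The modulated binary cross-entropy
#' \deqn{-\sum_i [ y_i (1-p_i)^\gamma \log(p_i+\epsilon) +
#'                (1-y_i) p_i^\gamma \log(1-p_i+\epsilon) ]}
#' summed over all instance-class terms. The factors \eqn{(1-p)^\gamma}
#' and \eqn{p^\gamma} down-weight well-classified terms so that training
#' concentrates on hard examples, which matters under the heavy class
#' imbalance of the 13 relation types. With `gamma = 0` and `eps = 0`
#' the loss reduces exactly to summed binary cross-entropy.
#'
#' @param probs Numeric matrix (or vector) of predicted probabilities in
#'   (0, 1).
#' @param labels Binary matrix (or vector) of the same shape.
#' @param gamma Focusing parameter, default 0.5.
#' @param eps Additive guard inside the logarithms, default 1e-6.
#' @return Scalar loss (the sum over all terms, as defined above).
#' @export
#' @examples
#' focal_loss(0.5, 1)                 # one positive term at p = 0.5
#' focal_loss(matrix(0.9), matrix(1), gamma = 0, eps = 0)
focal_loss <- function(probs, labels, gamma = 0.5, eps = 1e-6) {
  if (length(probs) != length(labels)) abort("probs and labels must have the same shape")
  if (gamma < 0) abort("gamma must be >= 0")
  p <- as.numeric(probs); y <- as.numeric(labels)
  -sum(y * (1 - p)^gamma * log(p + eps) + (1 - y) * p^gamma * log(1 - p + eps))
}

# Gradient of the summed focal loss with respect to the logits z, where
# p = sigmoid(z). Requires p clamped away from 0 and 1 (so the
# (1-p)^(gamma-1) factors stay finite, including at gamma = 0).
focal_loss_grad_z <- function(p, y, gamma, eps) {
  dLdp <- ifelse(
    y == 1,
    gamma * (1 - p)^(gamma - 1) * log(p + eps) - (1 - p)^gamma / (p + eps),
    -gamma * p^(gamma - 1) * log(1 - p + eps) + p^gamma / (1 - p + eps)
  )
  dLdp * p * (1 - p)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

clamp_probs <- function(p, lo = 1e-7) pmin(pmax(p, lo), 1 - lo)

#' Fuse a context vector with sequence features
#'
#' `mode = "none"` returns the context matrix unchanged; `mode =
#' "concat"` appends the (L2-normalized) 576-dimensional sequence
#' descriptor of the instance's target protein, optionally passed
#' through a seeded random Gaussian projection to `proj_dim` columns.
#'
#' @param cls_mat n x d context matrix.
#' @param feat_mat n x 576 feature matrix aligned with `cls_mat` rows
#'   (ignored for `mode = "none"`).
#' @param mode `"none"` or `"concat"`.
#' @param projection Optional projection matrix (576 x proj_dim) as
#'   built by [feature_projection()].
#' @return Numeric matrix.
#' @export
fuse_features <- function(cls_mat, feat_mat = NULL, mode = c("none", "concat"), projection = NULL) {
  mode <- match.arg(mode)
  if (mode == "none") return(cls_mat)
  if (is.null(feat_mat)) abort("mode = 'concat' requires a feature matrix")
  if (nrow(feat_mat) != nrow(cls_mat)) abort("Feature matrix rows do not align with instances")
  if (!is.null(projection)) {
    if (nrow(projection) != ncol(feat_mat)) abort("Projection matrix does not match feature dimension")
    feat_mat <- feat_mat %*% projection
  }
  cbind(cls_mat, feat_mat)
}

#' Seeded random Gaussian projection for sequence features
#'
#' @param in_dim Input dimension (576 for the full descriptor vector).
#' @param out_dim Projected dimension.
#' @param seed Integer seed.
#' @return `in_dim` x `out_dim` matrix with entries
#'   `N(0, 1/in_dim)`.
#' @export
feature_projection <- function(in_dim, out_dim, seed) {
  withr_seed(seed, matrix(rnorm(in_dim * out_dim, sd = 1 / sqrt(in_dim)), nrow = in_dim))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Train a multi-label relation classifier
#'
#' Encodes each instance's `model_text` with the supplied encoder,
#' optionally concatenates L2-normalized protein sequence descriptors,
#' and fits a fully connected layer (13 sigmoid outputs, one per
#' relation type) by full-batch gradient descent on the focal loss
#' (binary cross-entropy selectable). All randomness -- weight
#' initialization and any seeded encoder state -- flows from the single
#' integer `seed`, so two runs with identical inputs and seed produce
#' identical states.
#'
#' @param instances A `dti_instances` tibble (uses `model_text` and the
#'   gold `label` column).
#' @param encoder A `dti_encoder`; default [hashed_encoder()].
#' @param seed Integer seed.
#' @param features Optional n x 576 matrix of sequence descriptors
#'   aligned with instances (L2-normalized rows; see [l2_normalize()]).
#' @param proj_dim Optional projection size for the feature block;
#'   `NULL` concatenates all 576 columns.
#' @param loss `"focal"` (default) or `"bce"` (focal with `gamma = 0`).
#' @param gamma,eps Focal loss parameters (defaults 0.5 and 1e-6).
#' @param epochs Number of full-batch gradient steps (default 1000).
#' @param learning_rate Step size (default 0.3 under Adam). The gradient
#'   is scaled by 1/n for step-size stability; [focal_loss()] itself
#'   reports the summed form.
#' @param optimizer `"adam"` (default; full-batch Adam with the usual
#'   moment decay rates 0.9/0.999) or `"sgd"` (plain gradient descent).
#' @param weight_decay L2 penalty on the head weights (bias excluded),
#'   default 3e-5. A small penalty concentrates logit mass on tokens
#'   that recur across many instances of a class (relation-indicating
#'   lexemes) instead of tokens that co-occur with a label only a few
#'   times, which is what makes the head generalize; large values cap
#'   the trigger weights below what the 0.5 decision threshold needs,
#'   so the default is deliberately small.
#' @return An object of class `dti_classifier`.
#' @export
train_relation_classifier <- function(instances, encoder = hashed_encoder(),
                                      seed = 1, features = NULL, proj_dim = NULL,
                                      loss = c("focal", "bce"), gamma = 0.5, eps = 1e-6,
                                      epochs = 1000, learning_rate = 0.3,
                                      optimizer = c("adam", "sgd"), weight_decay = 3e-5) {
  loss <- match.arg(loss)
  optimizer <- match.arg(optimizer)
  if (nrow(instances) == 0) abort("Cannot train on an empty instance list")
  if (loss == "bce") gamma <- 0
  Y <- label_matrix(instances)
  X <- encode_text(encoder, instances$model_text)
  projection <- NULL
  if (!is.null(features)) {
    if (!is.null(proj_dim)) {
      projection <- feature_projection(ncol(features), proj_dim, seed = seed + 1L)
    }
    X <- fuse_features(X, features, mode = "concat", projection = projection)
  }
  Xb <- cbind(1, X)
  d <- ncol(Xb)
  W <- withr_seed(seed, matrix(rnorm(d * 13, sd = 0.01), nrow = d,
                               dimnames = list(NULL, relation_types())))
  n <- nrow(Xb)
  final_loss <- NA_real_
  m1 <- matrix(0, nrow = d, ncol = 13)
  m2 <- matrix(0, nrow = d, ncol = 13)
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8
  for (ep in seq_len(epochs)) {
    P <- clamp_probs(sigmoid(Xb %*% W))
    G <- crossprod(Xb, focal_loss_grad_z(P, Y, gamma, eps)) / n
    if (weight_decay > 0) {
      pen <- weight_decay * W
      pen[1, ] <- 0 # no decay on the bias
      G <- G + pen
    }
    if (optimizer == "adam") {
      m1 <- b1 * m1 + (1 - b1) * G
      m2 <- b2 * m2 + (1 - b2) * G^2
      step <- (m1 / (1 - b1^ep)) / (sqrt(m2 / (1 - b2^ep)) + adam_eps)
      W <- W - learning_rate * step
    } else {
      W <- W - learning_rate * G
    }
    if (!all(is.finite(W))) {
      abort(sprintf(
        "Training diverged at epoch %d (non-finite weights; seed %d, lr %g) -- try a smaller learning rate or another seed",
        ep, seed, learning_rate
      ))
    }
  }
  P <- clamp_probs(sigmoid(Xb %*% W))
  final_loss <- focal_loss(P, Y, gamma = gamma, eps = eps)
  if (!is.finite(final_loss)) abort("Non-finite final loss after training")
  structure(list(
    encoder = encoder, W = W,
    uses_features = !is.null(features), projection = projection,
    config = list(loss = loss, gamma = gamma, eps = eps, epochs = epochs,
                  learning_rate = learning_rate, optimizer = optimizer,
                  weight_decay = weight_decay, seed = seed),
    n_train = n, final_loss = final_loss
  ), class = "dti_classifier")
}

#' Predict per-class probabilities
#'
#' @param state A `dti_classifier`.
#' @param instances A `dti_instances` tibble.
#' @param features Optional feature matrix (required iff the model was
#'   trained with one).
#' @return n x 13 matrix of probabilities in (0, 1), columns named by
#'   [relation_types()].
#' @export
predict_probs <- function(state, instances, features = NULL) {
  if (any(!nzchar(instances$model_text))) abort("Cannot predict on empty instance text")
  X <- encode_text(state$encoder, instances$model_text)
  if (state$uses_features) {
    if (is.null(features)) abort("This model was trained with sequence features; supply `features`")
    X <- fuse_features(X, features, mode = "concat", projection = state$projection)
  }
  P <- sigmoid(cbind(1, X) %*% state$W)
  rownames(P) <- instances$instance_id
  P
}

#' @export
print.dti_classifier <- function(x, ...) {
  cat(sprintf(
    "Relation classifier: encoder %s%s, loss %s (gamma %g), %d epochs, seed %d\n",
    x$encoder$name, if (x$uses_features) " + sequence features" else "",
    x$config$loss, x$config$gamma, x$config$epochs, x$config$seed
  ))
  cat(sprintf("Trained on %d instances; final %s loss %.4f\n", x$n_train, x$config$loss, x$final_loss))
  invisible(x)
}

#' @export
tidy.dti_classifier <- function(x, ...) {
  W <- x$W
  tibble(
    term = rep(c("(bias)", paste0("x", seq_len(nrow(W) - 1))), times = ncol(W)),
    rtype = rep(colnames(W), each = nrow(W)),
    estimate = as.numeric(W)
  )
}

#' @export
glance.dti_classifier <- function(x, ...) {
  tibble(
    encoder = x$encoder$name, loss = x$config$loss, gamma = x$config$gamma,
    epochs = x$config$epochs, seed = x$config$seed,
    n_train = x$n_train, final_loss = x$final_loss,
    uses_features = x$uses_features
  )
}
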