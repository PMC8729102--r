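# Single-hidden-layer backpropagation classifier with a choice of
# logistic-sigmoid or sine hidden activation (the two published network
# presets are backprop with 4 hidden units and a sine-activation net with
# 8). Full-batch gradient descent on the cross-entropy, deterministic
# given the seed.

#' Specification for the backprop classifier
#'
#' @param hidden_units Hidden layer width (>= 1).
#' @param activation `"sigmoid"` or `"sine"` hidden activation; sine
#'   applies an elementwise `sin` to the hidden pre-activations.
#' @param learning_rate Gradient-descent step size.
#' @param epochs Number of full-batch epochs.
#' @param seed Seed for the weight initialization.
#' @return A list of class `mlp_spec`.
#' @export
mlp_spec <- function(hidden_units = 4, activation = c("sigmoid", "sine"),
                     learning_rate = 0.5, epochs = 200, seed = 1) {
  activation <- match.arg(activation)
  if (hidden_units < 1) stop_domain("mlp_spec: hidden_units must be >= 1")
  structure(list(hidden_units = as.integer(hidden_units),
                 activation = activation,
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "mlp_spec")
}

#' Published network presets
#'
#' The two shipped configurations: plain backprop with 4 hidden units and
#' the sine-activation feed-forward net with 8.
#' @return An [mlp_spec()].
#' @export
mlp_preset_bp <- function() mlp_spec(hidden_units = 4, activation = "sigmoid")

#' @rdname mlp_preset_bp
#' @export
mlp_preset_sine <- function() mlp_spec(hidden_units = 8, activation = "sine")

#' Train the backprop classifier
#'
#' @param X Numeric matrix or data frame of features.
#' @param y Binary 0/1 outcome, both classes present.
#' @param spec An [mlp_spec()].
#' @return A fitted classifier of class `pcos_mlp` with a
#'   [predict.pcos_mlp()] method.
#' @export
train_mlp <- function(X, y, spec = mlp_spec()) {
  X <- as.matrix(X); storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop_domain("train_mlp: X rows must match y")
  if (length(unique(y)) < 2)
    stop_domain("train_mlp: y has a single class")
  if (!all(y %in% c(0, 1))) stop_domain("train_mlp: y must be 0/1")
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd); scl[scl == 0 | !is.finite(scl)] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  n <- nrow(Xs); p <- ncol(Xs); H <- spec$hidden_units
  with_seed(spec$seed, {
    W1 <- matrix(runif((p + 1) * H, -0.5, 0.5), p + 1, H)
    W2 <- runif(H + 1, -0.5, 0.5)
  })
  X1 <- cbind(1, Xs)
  sig <- function(a) 1 / (1 + exp(-a))
  for (ep in seq_len(spec$epochs)) {
    A1 <- X1 %*% W1
    if (spec$activation == "sine") { Z <- sin(A1); dZ <- cos(A1) }
    else { Z <- sig(A1); dZ <- Z * (1 - Z) }
    Z1 <- cbind(1, Z)
    phat <- sig(drop(Z1 %*% W2))
    err <- phat - y                      # d(cross-entropy)/d(logit)
    g2 <- drop(crossprod(Z1, err)) / n
    delta <- (err %o% W2[-1]) * dZ
    g1 <- crossprod(X1, delta) / n
    W2 <- W2 - spec$learning_rate * g2
    W1 <- W1 - spec$learning_rate * g1
  }
  structure(list(W1 = W1, W2 = W2, center = ctr, scale = scl,
                 spec = spec, features = colnames(X)),
            class = "pcos_mlp")
}

#' Predict method for the backprop classifier
#'
#' @param object A `pcos_mlp` fit.
#' @param newdata Feature matrix with the training columns.
#' @param type `"prob"` for class-1 probabilities, `"class"` for 0/1 at
#'   threshold 0.5.
#' @param ... Unused.
#' @return Numeric vector of probabilities or 0/1 labels.
#' @export
predict.pcos_mlp <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata); storage.mode(X) <- "double"
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  A1 <- cbind(1, Xs) %*% object$W1
  Z <- if (object$spec$activation == "sine") sin(A1) else 1 / (1 + exp(-A1))
  phat <- 1 / (1 + exp(-drop(cbind(1, Z) %*% object$W2)))
  if (type == "class") as.numeric(phat > 0.5) else phat
}

#' ROC area under the curve
#'
#' Probability that a random positive outscores a random negative, with
#' ties counted one half (the rank / Mann-Whitney formulation).
#'
#' @param scores Numeric classifier scores.
#' @param labels Binary 0/1 labels, both classes present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(scores) != length(labels))
    stop_domain("roc_auc: lengths differ")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop_domain("roc_auc: both classes required")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
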