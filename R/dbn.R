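#' Deep belief network model
#'
#' An ordered stack of RBM layers (depth = number of hidden layers) whose
#' adjacent dimensions chain, topped with a softmax classifier. The softmax
#' weights start at zero, which makes the untrained classifier predict a
#' uniform distribution -- a reproducible degenerate baseline.
#'
#' @param layers List of `rbm_params`, bottom first.
#' @param n_classes Number of output classes (2 for vegetation/other).
#' @return An object of class `dbn_model`.
#' @export
dbn_model <- function(layers, n_classes = 2L) {
  stopifnot(length(layers) >= 1L, n_classes >= 2L)
  for (k in seq_along(layers)) {
    stopifnot(inherits(layers[[k]], "rbm_params"))
    if (k > 1L && ncol(layers[[k]]$W) != nrow(layers[[k - 1L]]$W))
      stop("layer ", k, " visible size does not match layer ", k - 1L,
           " hidden size", call. = FALSE)
  }
  top_dim <- nrow(layers[[length(layers)]]$W)
  structure(list(layers = layers,
                 softmax_W = matrix(0, nrow = n_classes, ncol = top_dim),
                 softmax_b = numeric(n_classes),
                 feature_dim = ncol(layers[[1L]]$W),
                 n_classes = as.integer(n_classes)),
            class = "dbn_model")
}

#' @export
print.dbn_model <- function(x, ...) {
  dims <- c(x$feature_dim, vapply(x$layers, function(l) nrow(l$W), integer(1)))
  cat(sprintf("dbn_model: %s -> softmax(%d)\n",
              paste(dims, collapse = "-"), x$n_classes))
  invisible(x)
}

#' Greedy layer-wise unsupervised pretraining
#'
#' Trains the first RBM on the raw feature rows, then each subsequent RBM on
#' the previous layer's hidden activation probabilities, bottom-up. Labels
#' are never seen: the function accepts a feature matrix only. The softmax
#' output layer is zero-initialized.
#'
#' @param features `n x d` matrix of visible rows in `[0, 1]` (for a
#'   `pixel_dataset`, pass its `$features`).
#' @param hidden_sizes Integer vector of hidden unit counts, bottom first;
#'   its length is the network depth.
#' @param opts A [train_opts()] applied to every layer.
#' @return A `dbn_model`.
#' @export
pretrain <- function(features, hidden_sizes, opts = train_opts()) {
  features <- as.matrix(features)
  stopifnot(length(hidden_sizes) >= 1L)
  run <- function() {
    layers <- vector("list", length(hidden_sizes))
    input <- features
    for (k in seq_along(hidden_sizes)) {
      layers[[k]] <- train_rbm(input, hidden_sizes[k],
                               train_opts(opts$learning_rate, opts$batch_size,
                                          opts$epochs))
      input <- hidden_conditional(layers[[k]], input)
    }
    dbn_model(layers)
  }
  if (is.null(opts$seed)) run() else withr::with_seed(opts$seed, run())
}

#' Deterministic feedforward through the RBM stack
#'
#' Composes the hidden conditional probabilities of every layer (no
#' sampling), yielding the top-layer representation the softmax classifies.
#'
#' @param model A `dbn_model`.
#' @param features Feature matrix (rows) or single feature vector.
#' @return Matrix of top-layer activations in (0, 1).
#' @export
forward_features <- function(model, features) {
  a <- as_row_matrix(features, model$feature_dim, "features")
  for (layer in model$layers) a <- hidden_conditional(layer, a)
  a
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Forward pass keeping activations; loss and analytic gradients of the
# softmax cross-entropy SUMMED over the rows (per-sample stepping, matching
# the CD-1 convention) w.r.t. every layer's W and hidden bias c plus the
# softmax parameters. y is an integer vector in [0, n_classes).
dbn_loss_grads <- function(model, features, y) {
  X <- as_row_matrix(features, model$feature_dim, "features")
  n <- nrow(X)
  L <- length(model$layers)
  acts <- vector("list", L + 1L)
  acts[[1L]] <- X
  for (k in seq_len(L))
    acts[[k + 1L]] <- as_row_matrix(hidden_conditional(model$layers[[k]], acts[[k]]),
                                    nrow(model$layers[[k]]$W), "act")
  logits <- sweep(acts[[L + 1L]] %*% t(model$softmax_W), 2L,
                  model$softmax_b, "+")
  p <- softmax_rows(logits)
  idx <- cbind(seq_len(n), y + 1L)
  loss <- -sum(log(pmax(p[idx], 1e-300)))

  delta <- p
  delta[idx] <- delta[idx] - 1             # d loss / d logits
  g_softmax_W <- t(delta) %*% acts[[L + 1L]]
  g_softmax_b <- colSums(delta)
  back <- delta %*% model$softmax_W        # d loss / d top activation
  g_W <- vector("list", L)
  g_c <- vector("list", L)
  for (k in rev(seq_len(L))) {
    a <- acts[[k + 1L]]
    dz <- back * a * (1 - a)               # sigmoid derivative
    g_W[[k]] <- t(dz) %*% acts[[k]]
    g_c[[k]] <- colSums(dz)
    if (k > 1L) back <- dz %*% model$layers[[k]]$W
  }
  list(loss = loss, g_W = g_W, g_c = g_c,
       g_softmax_W = g_softmax_W, g_softmax_b = g_softmax_b, prob = p)
}

#' Fine-tuning options
#'
#' @inheritParams train_opts
#' @export
fine_tune_opts <- function(learning_rate = 0.01, batch_size = 100L,
                           epochs = 2L, seed = NULL) {
  train_opts(learning_rate, batch_size, epochs, seed)
}

#' Supervised top-down fine-tuning by backpropagation
#'
#' Minibatch gradient descent on the softmax cross-entropy through all
#' layers (sigmoid hidden activations). The learning rate applies per
#' sample: each batch step uses the summed (not averaged) per-sample
#' gradients, the same convention as the contrastive-divergence updates.
#' Every layer's weights and hidden biases are updated together with the
#' softmax parameters under one shared learning rate; RBM visible biases
#' play no role in the feedforward pass and are left untouched. Batches are
#' reshuffled each epoch. Aborts if the loss becomes non-finite.
#'
#' @param model A pretrained `dbn_model`.
#' @param data A `pixel_dataset` (features and labels).
#' @param opts A [fine_tune_opts()].
#' @return The fine-tuned `dbn_model`, with the per-epoch mean training loss
#'   attached as attribute `"loss_history"`.
#' @export
fine_tune <- function(model, data, opts = fine_tune_opts()) {
  stopifnot(inherits(model, "dbn_model"), inherits(data, "pixel_dataset"))
  if (any(data$labels < 0L) || any(data$labels >= model$n_classes))
    stop("labels out of range for the model's classes", call. = FALSE)
  run <- function() {
    n <- nrow(data$features)
    history <- numeric(opts$epochs)
    for (epoch in seq_len(opts$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = opts$batch_size)
      losses <- numeric(length(starts))
      for (i in seq_along(starts)) {
        idx <- ord[starts[i]:min(starts[i] + opts$batch_size - 1L, n)]
        g <- dbn_loss_grads(model, data$features[idx, , drop = FALSE],
                            data$labels[idx])
        if (!is.finite(g$loss))
          stop("fine-tuning diverged to non-finite loss at epoch ", epoch,
               ", batch ", i, "; lower the learning rate", call. = FALSE)
        losses[i] <- g$loss / length(idx)   # monitor mean per-sample loss
        lr <- opts$learning_rate
        for (k in seq_along(model$layers)) {
          model$layers[[k]]$W <- model$layers[[k]]$W - lr * g$g_W[[k]]
          model$layers[[k]]$c <- model$layers[[k]]$c - lr * g$g_c[[k]]
        }
        model$softmax_W <- model$softmax_W - lr * g$g_softmax_W
        model$softmax_b <- model$softmax_b - lr * g$g_softmax_b
      }
      history[epoch] <- mean(losses)
    }
    attr(model, "loss_history") <- history
    model
  }
  if (is.null(opts$seed)) run() else withr::with_seed(opts$seed, run())
}

#' Classify feature rows with a DBN
#'
#' Softmax over the top-layer representation; the predicted label is the
#' argmax, with ties broken toward the lower class index.
#'
#' @param object A `dbn_model`.
#' @param features Feature matrix (rows) or single feature vector.
#' @param ... Unused.
#' @return List with `labels` (integer vector in `[0, n_classes)`) and
#'   `prob` (`n x n_classes` matrix, rows summing to 1).
#' @export
predict.dbn_model <- function(object, features, ...) {
  top <- forward_features(object, features)
  logits <- sweep(top %*% t(object$softmax_W), 2L, object$softmax_b, "+")
  p <- softmax_rows(logits)
  labels <- max.col(p, ties.method = "first") - 1L
  list(labels = labels, prob = p)
}

#' Render a per-pixel classification map
#'
#' Predicts every pixel of a scene and paints vegetation red (255, 0, 0) and
#' everything else green (0, 255, 0), mirroring the conventional mine-cover
#' map rendering.
#'
#' @param model A trained `dbn_model`.
#' @param scene A `labeled_scene`.
#' @param palette 2 x 3 integer matrix of RGB rows: row 1 = non-vegetation,
#'   row 2 = vegetation.
#' @return `height x width x 3` integer array.
#' @export
classify_scene <- function(model, scene,
                           palette = rbind(other = c(0L, 255L, 0L),
                                           vegetation = c(255L, 0L, 0L))) {
  stopifnot(inherits(scene, "labeled_scene"))
  data <- extract_features(scene)
  labels <- predict(model, data$features)$labels
  h <- nrow(scene$mask); w <- ncol(scene$mask)
  lab_mat <- matrix(labels, nrow = h, ncol = w, byrow = TRUE)  # row-major order
  out <- array(0L, dim = c(h, w, 3L))
  for (ch in 1:3)
    out[, , ch] <- palette[lab_mat + 1L, ch]
  out
}

#' Joint probability of a small DBN state
#'
#' Evaluates the stacked generative joint
#' `P(v, h^1, ..., h^L) = (prod_k P(h^k | h^{k+1})) * P(h^{L-1}, h^L)`:
#' top-down factorized conditionals through the lower layers times the exact
#' joint of the top RBM (by enumeration, so the top layer must be small).
#' For a single-layer model this is the exact RBM joint.
#'
#' @param model A `dbn_model` whose top RBM has at most 20 total units.
#' @param v Binary visible vector.
#' @param h_list List of binary hidden vectors, bottom first, length = depth.
#' @return The joint probability of the state (a number in `[0, 1]`).
#' @export
dbn_joint <- function(model, v, h_list) {
  L <- length(model$layers)
  stopifnot(length(h_list) == L)
  states <- c(list(v), h_list)             # states[[k]] = layer k-1
  top <- model$layers[[L]]
  ex <- exact_distribution(top)
  pick <- function(states_mat, s) which(colSums(t(states_mat) != s) == 0L)
  p <- ex$prob[pick(ex$v_states, states[[L]]), pick(ex$h_states, states[[L + 1L]])]
  if (L >= 2L) {
    for (k in seq_len(L - 1L)) {
      # generative conditional of layer k-1 given layer k, through RBM k
      pv <- visible_conditional(model$layers[[k]], states[[k + 1L]])
      s <- states[[k]]
      p <- p * prod(pv^s * (1 - pv)^(1 - s))
    }
  }
  p
}
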