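#' Restricted Boltzmann machine parameters
#'
#' One layer's weights and biases. `W` is `n_hidden x n_visible`, `b` the
#' visible bias vector, `c` the hidden bias vector; the joint energy is
#' `E(v, h) = -b'v - c'h - h'Wv`.
#'
#' @param n_visible,n_hidden Unit counts.
#' @param init_sd Standard deviation of the Gaussian weight initialization
#'   (biases start at zero). The default `NULL` uses the fan-in scaled
#'   `1 / sqrt(n_visible)`, which keeps pre-activations of order one so
#'   stacked layers neither saturate nor wash the input out.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return An object of class `rbm_params` with elements `W`, `b`, `c`.
#' @export
rbm_params <- function(n_visible, n_hidden, init_sd = NULL, seed = NULL) {
  stopifnot(n_visible >= 1, n_hidden >= 1)
  if (is.null(init_sd)) init_sd <- 1 / sqrt(n_visible)
  draw <- function() matrix(stats::rnorm(n_hidden * n_visible, sd = init_sd),
                            nrow = n_hidden, ncol = n_visible)
  W <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  structure(list(W = W, b = numeric(n_visible), c = numeric(n_hidden)),
            class = "rbm_params")
}

#' @export
print.rbm_params <- function(x, ...) {
  cat(sprintf("rbm_params: %d visible, %d hidden\n", ncol(x$W), nrow(x$W)))
  invisible(x)
}

as_row_matrix <- function(x, width, what) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != width)
    stop(what, ": expected width ", width, ", got ", ncol(x), call. = FALSE)
  x
}

#' Conditional activation probabilities of an RBM
#'
#' `hidden_conditional` gives `P(h_j = 1 | v) = sigmoid(c_j + W_j. v)`;
#' `visible_conditional` the mirror `P(v_i = 1 | h) = sigmoid(b_i + W'._i h)`.
#' Both accept a single unit vector or a matrix with one configuration per
#' row, and return probabilities strictly inside (0, 1) (numerically stable
#' sigmoid via [stats::plogis()]).
#'
#' @param params An `rbm_params`.
#' @param v,h Unit configuration vector, or matrix of row configurations;
#'   visible units may be real-valued in `[0, 1]`.
#' @return Probability vector or matrix matching the input shape.
#' @export
hidden_conditional <- function(params, v) {
  vec <- is.null(dim(v))
  v <- as_row_matrix(v, ncol(params$W), "v")
  p <- stats::plogis(sweep(v %*% t(params$W), 2L, params$c, "+"))
  if (vec) drop(p) else p
}

#' @rdname hidden_conditional
#' @export
visible_conditional <- function(params, h) {
  vec <- is.null(dim(h))
  h <- as_row_matrix(h, nrow(params$W), "h")
  p <- stats::plogis(sweep(h %*% params$W, 2L, params$b, "+"))
  if (vec) drop(p) else p
}

#' Bernoulli sampling of unit states
#'
#' Independent draws `x_i ~ Bernoulli(p_i)`, reproducible under the current
#' RNG stream.
#'
#' @param p Probability vector or matrix.
#' @return 0/1 vector or matrix of the same shape.
#' @export
sample_units <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  out <- (stats::runif(length(p)) < p) * 1
  dim(out) <- dim(p)
  out
}

#' One contrastive-divergence (CD-1) parameter update
#'
#' A single Gibbs reconstruction step: hidden probabilities from the data,
#' sampled hidden states, sampled visible reconstruction, hidden
#' probabilities of the reconstruction; then
#' `W <- W + lr * (P(h1|v1)'v1 - P(h2|v2)'v2) / n`,
#' `b <- b + lr * mean(v1 - v2)`, `c <- c + lr * mean(P(h1|v1) - P(h2|v2))`,
#' the sufficient statistics averaged over the batch (the standard batched
#' form of the per-sample update rule). Hidden probabilities (not samples)
#' enter the statistics.
#'
#' @param params An `rbm_params`.
#' @param batch Matrix of visible rows with entries in `[0, 1]`.
#' @param lr Positive learning rate.
#' @return Updated `rbm_params`.
#' @export
cd1_update <- function(params, batch, lr) {
  batch <- as_row_matrix(batch, ncol(params$W), "batch")
  if (nrow(batch) < 1L) stop("batch must be nonempty", call. = FALSE)
  if (lr < 0) stop("learning rate must be nonnegative", call. = FALSE)
  n <- nrow(batch)
  ph1 <- hidden_conditional(params, batch)
  ph1 <- as_row_matrix(ph1, nrow(params$W), "ph1")
  h1 <- sample_units(ph1)
  pv2 <- as_row_matrix(visible_conditional(params, h1), ncol(params$W), "pv2")
  v2 <- sample_units(pv2)
  ph2 <- as_row_matrix(hidden_conditional(params, v2), nrow(params$W), "ph2")
  params$W <- params$W + lr * (t(ph1) %*% batch - t(ph2) %*% v2) / n
  params$b <- params$b + lr * colMeans(batch - v2)
  params$c <- params$c + lr * colMeans(ph1 - ph2)
  params
}

#' Training options for an RBM layer
#'
#' @param learning_rate Gradient step size.
#' @param batch_size Samples per CD-1 update.
#' @param epochs Full passes over the data ("number of iterations").
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @export
train_opts <- function(learning_rate = 0.01, batch_size = 100L,
                       epochs = 2L, seed = NULL) {
  stopifnot(learning_rate >= 0, batch_size >= 1, epochs >= 0)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = seed),
            class = "train_opts")
}

#' Train one RBM by minibatch CD-1
#'
#' Initializes weights from `Normal(0, 0.01)` with zero biases, reshuffles
#' the data every epoch, and applies [cd1_update()] per minibatch for
#' `opts$epochs` epochs.
#'
#' @param data Matrix of visible rows in `[0, 1]`.
#' @param n_hidden Hidden unit count.
#' @param opts A [train_opts()].
#' @return Trained `rbm_params`.
#' @export
train_rbm <- function(data, n_hidden, opts = train_opts()) {
  data <- as.matrix(data)
  if (nrow(data) < 1L) stop("training data must be nonempty", call. = FALSE)
  run <- function() {
    params <- rbm_params(ncol(data), n_hidden)
    n <- nrow(data)
    for (epoch in seq_len(opts$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = opts$batch_size)
      for (s in starts) {
        idx <- ord[s:min(s + opts$batch_size - 1L, n)]
        params <- cd1_update(params, data[idx, , drop = FALSE],
                             opts$learning_rate)
      }
    }
    params
  }
  if (is.null(opts$seed)) run() else withr::with_seed(opts$seed, run())
}

binary_states <- function(n) {
  # all 2^n binary vectors, one per row, lowest-order bit in column 1
  stopifnot(n >= 1)
  m <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  dimnames(m) <- NULL
  m
}

#' Exact joint distribution of a small RBM
#'
#' Enumerates every binary `(v, h)` state and normalizes
#' `exp(b'v + c'h + h'Wv)`. Tractable only for small models; used as the
#' test oracle for the conditional activations and the stacked joint.
#'
#' @param params An `rbm_params` with at most 20 total units.
#' @return List with `v_states` (`2^nv x nv`), `h_states` (`2^nh x nh`) and
#'   `prob`, a `2^nv x 2^nh` matrix summing to 1.
#' @export
exact_distribution <- function(params) {
  nv <- ncol(params$W); nh <- nrow(params$W)
  if (nv + nh > 20L) stop("model too large to enumerate", call. = FALSE)
  v_states <- binary_states(nv)
  h_states <- binary_states(nh)
  # log unnormalized mass for every (v, h) pair
  log_mass <- outer(drop(v_states %*% params$b), drop(h_states %*% params$c), "+") +
    v_states %*% t(params$W) %*% t(h_states)
  mass <- exp(log_mass - max(log_mass))
  list(v_states = v_states, h_states = h_states, prob = mass / sum(mass))
}

#' Mean-field reconstruction error of an RBM
#'
#' Mean over samples of `||v - P(v | h = P(h|v))||^2 / d`: the visible units
#' are reconstructed deterministically through the hidden probabilities.
#'
#' @param params An `rbm_params`.
#' @param data Matrix of visible rows.
#' @return Scalar mean squared error per unit.
#' @export
reconstruction_error <- function(params, data) {
  data <- as_row_matrix(as.matrix(data), ncol(params$W), "data")
  ph <- as_row_matrix(hidden_conditional(params, data), nrow(params$W), "ph")
  pv <- as_row_matrix(visible_conditional(params, ph), ncol(params$W), "pv")
  mean(rowSums((data - pv)^2) / ncol(data))
}
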