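# Independent oracles used across the suite. These re-derive quantities from
# first principles (enumeration, textbook formulas) and must stay independent
# of the implementation paths they check.

# Hand-coded hexcone RGB -> HSV (components as fractions of 1).
oracle_rgb_to_hsv <- function(r, g, b) {
  r <- r / 255; g <- g / 255; b <- b / 255
  mx <- max(r, g, b); mn <- min(r, g, b); d <- mx - mn
  v <- mx
  s <- if (mx == 0) 0 else d / mx
  h <- if (d == 0) 0
  else if (mx == r) ((g - b) / d) %% 6
  else if (mx == g) (b - r) / d + 2
  else (r - g) / d + 4
  c(h = h / 6, s = s, v = v)
}

# Textbook kappa: (p_o - p_e) / (1 - p_e) on a count matrix.
oracle_kappa <- function(cm) {
  N <- sum(cm)
  po <- sum(diag(cm)) / N
  pe <- sum((rowSums(cm) / N) * (colSums(cm) / N))
  (po - pe) / (1 - pe)
}

# P(h_j = 1 | v) for an RBM from its exact joint table, by marginalization.
oracle_hidden_conditional <- function(params, v) {
  ex <- exact_distribution(params)
  row <- which(apply(ex$v_states, 1L, function(s) all(s == v)))
  pv <- ex$prob[row, ]
  colSums(ex$h_states * pv) / sum(pv)
}

oracle_visible_conditional <- function(params, h) {
  ex <- exact_distribution(params)
  col <- which(apply(ex$h_states, 1L, function(s) all(s == h)))
  ph <- ex$prob[, col]
  colSums(ex$v_states * ph) / sum(ph)
}

# Exact log-likelihood gradient of an RBM w.r.t. W for a small dataset:
# E_data[p(h|v) v'] - E_model[p(h|v) v'], both terms from enumeration.
oracle_loglik_grad_W <- function(params, data) {
  ph_data <- hidden_conditional(params, data)
  pos <- t(ph_data) %*% data / nrow(data)
  ex <- exact_distribution(params)
  pv <- rowSums(ex$prob)                      # marginal P(v)
  ph_all <- hidden_conditional(params, ex$v_states)
  neg <- t(ph_all * pv) %*% ex$v_states
  pos - neg
}

random_params <- function(nv, nh, scale = 1) {
  p <- rbm_params(nv, nh, init_sd = 0.01)
  p$W <- matrix(stats::rnorm(nh * nv, sd = scale), nh, nv)
  p$b <- stats::rnorm(nv, sd = scale)
  p$c <- stats::rnorm(nh, sd = scale)
  p
}

# Small random DBN with nonzero softmax, for gradient and predict checks.
random_dbn <- function(dims, n_classes = 2L, scale = 0.5) {
  layers <- lapply(seq_len(length(dims) - 1L), function(k)
    random_params(dims[k], dims[k + 1L], scale = scale))
  m <- dbn_model(layers, n_classes = n_classes)
  top <- dims[length(dims)]
  m$softmax_W <- matrix(stats::rnorm(n_classes * top, sd = scale), n_classes, top)
  m$softmax_b <- stats::rnorm(n_classes, sd = scale)
  m
}

tiny_scene <- function(width = 64, height = 64, prevalence = 0.5,
                       noise_sd = 0, seed = 1)
  generate_scene(scene_config(width, height, target_prevalence = prevalence,
                              patch_scale = 8, noise_sd = noise_sd,
                              seed = seed))
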