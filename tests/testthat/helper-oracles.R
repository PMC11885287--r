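# Independent brute-force oracles used to check the package's DSP and
# neural primitives. These deliberately re-derive everything from first
# principles (direct summation, explicit loops) and never call the code
# paths they verify.

# Direct-summation DFT magnitude of one windowed frame.
oracle_dft_mag <- function(frame) {
  N <- length(frame)
  n_bins <- N %/% 2 + 1
  k <- 0:(n_bins - 1)
  n <- 0:(N - 1)
  re <- sapply(k, function(kk) sum(frame * cos(-2 * pi * kk * n / N)))
  im <- sapply(k, function(kk) sum(frame * sin(-2 * pi * kk * n / N)))
  sqrt(re^2 + im^2)
}

# Periodic Hann window (matches the documented analysis convention).
oracle_hann <- function(L) 0.5 * (1 - cos(2 * pi * (seq_len(L) - 1) / L))

# Centered frame extraction with mirror reflection, independent of the
# package's internals.
oracle_frame <- function(x, frame_length, hop, frame_index) {
  p <- frame_length %/% 2
  n <- length(x)
  refl <- function(i) {
    m <- (i - 1) %% (2 * (n - 1))
    ifelse(m < n, m + 1, 2 * n - 1 - m)
  }
  start <- (frame_index - 1) * hop - p + 1
  x[refl(start:(start + frame_length - 1))]
}

# Quadruple-loop 2D cross-correlation (valid region, stride 1, no pad).
oracle_conv <- function(x, W, b) {
  dx <- dim(x); dw <- dim(W)
  H <- dx[1] - dw[1] + 1; Wd <- dx[2] - dw[2] + 1
  out <- array(0, c(H, Wd, dw[4]))
  for (i in 1:H) for (j in 1:Wd) for (k in 1:dw[4]) {
    s <- b[k]
    for (m in 1:dw[1]) for (n in 1:dw[2]) for (ch in 1:dw[3]) {
      s <- s + W[m, n, ch, k] * x[i + m - 1, j + n - 1, ch]
    }
    out[i, j, k] <- s
  }
  out
}

# Explicit window-scan max pooling.
oracle_pool <- function(x, window, stride) {
  d <- dim(x)
  H <- (d[1] - window) %/% stride + 1
  Wd <- (d[2] - window) %/% stride + 1
  out <- array(0, c(H, Wd, d[3]))
  for (i in 1:H) for (j in 1:Wd) for (ch in 1:d[3]) {
    out[i, j, ch] <- max(x[((i - 1) * stride + 1):((i - 1) * stride + window),
                           ((j - 1) * stride + 1):((j - 1) * stride + window),
                           ch])
  }
  out
}

oracle_sigmoid <- function(x) 1 / (1 + exp(-x))

# One LSTM step evaluated literally from the gate equations.
oracle_lstm_step <- function(p, h_prev, C_prev, x_t) {
  z <- c(h_prev, x_t)
  f <- oracle_sigmoid(as.vector(p$W_f %*% z) + p$b_f)
  i <- oracle_sigmoid(as.vector(p$W_i %*% z) + p$b_i)
  Ct <- tanh(as.vector(p$W_C %*% z) + p$b_C)
  o <- oracle_sigmoid(as.vector(p$W_o %*% z) + p$b_o)
  C <- f * C_prev + i * Ct
  list(h = o * tanh(C), C = C)
}

# One GRU step evaluated literally.
oracle_gru_step <- function(p, h_prev, x_t) {
  z <- oracle_sigmoid(as.vector(p$W_z %*% x_t + p$U_z %*% h_prev))
  r <- oracle_sigmoid(as.vector(p$W_r %*% x_t + p$U_r %*% h_prev))
  h_tilde <- tanh(as.vector(p$W %*% x_t + r * as.vector(p$U %*% h_prev)))
  (1 - z) * h_prev + z * h_tilde
}

# Plain two-sum Pearson correlation.
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Two-pass mean / population std.
oracle_mean_std <- function(x) {
  m <- mean(x)
  c(mean = m, std = sqrt(sum((x - m)^2) / length(x)))
}

# Confusion-count metrics from explicit loops.
oracle_metrics <- function(pred, truth, classes) {
  K <- length(classes)
  cm <- matrix(0L, K, K)
  for (i in seq_along(pred)) {
    cm[match(truth[i], classes), match(pred[i], classes)] <-
      cm[match(truth[i], classes), match(pred[i], classes)] + 1L
  }
  prec <- rec <- f1 <- numeric(K)
  for (k in 1:K) {
    tp <- cm[k, k]
    prec[k] <- if (sum(cm[, k]) > 0) tp / sum(cm[, k]) else 0
    rec[k] <- if (sum(cm[k, ]) > 0) tp / sum(cm[k, ]) else 0
    f1[k] <- if (prec[k] + rec[k] > 0) 2 * prec[k] * rec[k] / (prec[k] + rec[k]) else 0
  }
  list(accuracy = sum(diag(cm)) / length(pred), confusion = cm,
       macro_precision = mean(prec), macro_recall = mean(rec),
       macro_f1 = mean(f1))
}

# Literal term-by-term evaluation of the cepstral cosine transform.
oracle_cepstrum <- function(X, n_keep) {
  N <- length(X)
  vapply(seq_len(n_keep), function(m) {
    s <- 0
    for (n in seq_len(N)) s <- s + X[n] * cos(m * (n - 0.5) * pi / N)
    s
  }, 0)
}
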