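# Independent reference implementations used as oracles.

# Brute-force 2-D convolution matching the package's weight layout:
# W[f, kr + k*kc + k^2*ch] applied to zero-padded input.
conv2d_brute <- function(X, W, b, k, stride, pad) {
  h <- dim(X)[1]; w <- dim(X)[2]; nc <- dim(X)[3]
  Xp <- array(0, dim = c(h + 2 * pad, w + 2 * pad, nc))
  Xp[pad + seq_len(h), pad + seq_len(w), ] <- X
  oh <- (h + 2 * pad - k) %/% stride + 1
  out <- array(NA_real_, dim = c(oh, oh, nrow(W)))
  for (f in seq_len(nrow(W))) {
    for (r in seq_len(oh)) for (cc in seq_len(oh)) {
      acc <- b[f]
      for (ch in seq_len(nc)) for (kc in seq_len(k)) for (kr in seq_len(k)) {
        acc <- acc + W[f, kr + k * (kc - 1) + k * k * (ch - 1)] *
          Xp[(r - 1) * stride + kr, (cc - 1) * stride + kc, ch]
      }
      out[r, cc, f] <- acc
    }
  }
  out
}

# Hand-evaluated LSTM cell (gate arithmetic written out).
lstm_cell_hand <- function(x, hprev, cprev, Wx, Wh, b) {
  H <- length(hprev)
  sig <- function(v) 1 / (1 + exp(-v))
  a <- as.numeric(Wx %*% x + Wh %*% hprev + b)
  i <- sig(a[seq_len(H)])
  f <- sig(a[H + seq_len(H)])
  g <- tanh(a[2 * H + seq_len(H)])
  o <- sig(a[3 * H + seq_len(H)])
  cnew <- f * cprev + i * g
  list(h = o * tanh(cnew), c = cnew)
}

# Naive two-pass cos/sin implementation of the phase-difference resultant.
cfs_naive <- function(phi_a, phi_b) {
  d <- phi_a - phi_b
  sqrt(mean(cos(d))^2 + mean(sin(d))^2)
}

# Random image sequence of the pipeline's geometry.
random_sequence <- function(T_ = 4, mesh = 32, seed = 1) {
  set.seed(seed)
  array(runif(mesh * mesh * 3 * T_), dim = c(mesh, mesh, 3, T_))
}

# Tiny classifier configuration for fast training tests.
tiny_cfg <- function(frames = 3) {
  cnn_lstm_config(mesh = 8, in_ch = 2, filters = c(2, 3), frames = frames,
                  hidden = 4, fc1 = 4, dropout = 0.5)
}

# Small separable sequence set for the tiny config: class 1 carries a bright
# top-left patch in every frame.
tiny_sequences <- function(n_per_class = 6, frames = 3, seed = 1) {
  set.seed(seed)
  mk <- function(cls) {
    x <- array(runif(8 * 8 * 2 * frames, 0, 0.3), dim = c(8, 8, 2, frames))
    if (cls == 1) x[1:3, 1:3, , ] <- x[1:3, 1:3, , ] + 0.7
    x
  }
  list(seqs = c(lapply(seq_len(n_per_class), function(i) mk(0)),
                lapply(seq_len(n_per_class), function(i) mk(1))),
       labels = rep(c("control", "dyslexic"), each = n_per_class))
}
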