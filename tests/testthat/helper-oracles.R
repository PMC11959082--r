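# Independent brute-force oracles. These deliberately re-derive every
# quantity from first principles (scalar loops, explicit kernels) and share
# no code with the package internals they check.

# neighbour offsets, n = 0..7 counterclockwise from east (row down = south)
oracle_offsets <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1),
                       c(0, -1), c(1, -1), c(1, 0), c(1, 1))

oracle_ltp <- function(window, tau) {
  centre <- window[2, 2]
  digits <- integer(8)
  upper <- 0L
  lower <- 0L
  ternary <- 0
  for (n in 0:7) {
    off <- oracle_offsets[[n + 1]]
    a <- window[2 + off[1], 2 + off[2]] - centre
    d <- if (a >= tau) 1L else if (a <= -tau) -1L else 0L
    digits[n + 1] <- d
    if (d == 1L) upper <- upper + 2L^n
    if (d == -1L) lower <- lower + 2L^n
    ternary <- ternary + d * 3^n
  }
  list(digits = digits, upper = upper, lower = lower, ternary = ternary)
}

# the eight Kirsch kernels written out explicitly, k[[n+1]] oriented toward
# neighbour n
oracle_kirsch <- list(
  rbind(c(-3, -3, 5), c(-3, 0, 5), c(-3, -3, 5)),   # E
  rbind(c(-3, 5, 5), c(-3, 0, 5), c(-3, -3, -3)),   # NE
  rbind(c(5, 5, 5), c(-3, 0, -3), c(-3, -3, -3)),   # N
  rbind(c(5, 5, -3), c(5, 0, -3), c(-3, -3, -3)),   # NW
  rbind(c(5, -3, -3), c(5, 0, -3), c(5, -3, -3)),   # W
  rbind(c(-3, -3, -3), c(5, 0, -3), c(5, 5, -3)),   # SW
  rbind(c(-3, -3, -3), c(-3, 0, -3), c(5, 5, 5)),   # S
  rbind(c(-3, -3, -3), c(-3, 0, 5), c(-3, 5, 5)))   # SE

oracle_loop <- function(window) {
  centre <- window[2, 2]
  h <- numeric(8)
  for (n in 0:7) h[n + 1] <- sum(oracle_kirsch[[n + 1]] * window)
  # rank of |h|: 0 = smallest ... 7 = largest, ties by neighbour index
  ord <- order(abs(h), seq_len(8))
  u <- integer(8)
  u[ord] <- 0:7
  code <- 0
  for (n in 0:7) {
    off <- oracle_offsets[[n + 1]]
    b <- (window[2 + off[1], 2 + off[2]] - centre) >= 0
    if (b) code <- code + 2^u[n + 1]
  }
  code
}

# gate-by-gate scalar LSTM oracle
oracle_lstm_step <- function(x, h_prev, c_prev, gates) {
  hs <- length(h_prev)
  z <- c(h_prev, x)
  gate <- function(w, b, act) {
    out <- numeric(hs)
    for (i in seq_len(hs)) {
      acc <- b[i]
      for (j in seq_along(z)) acc <- acc + w[i, j] * z[j]
      out[i] <- act(acc)
    }
    out
  }
  sig <- function(v) 1 / (1 + exp(-v))
  q <- gate(gates$Q$w, gates$Q$b, sig)
  i <- gate(gates$I$w, gates$I$b, sig)
  p <- gate(gates$P$w, gates$P$b, sig)
  xc <- gate(gates$X$w, gates$X$b, tanh)
  ct <- q * c_prev + i * xc
  list(h = p * tanh(ct), c = ct)
}

oracle_bilstm_score <- function(sequence, params) {
  tt <- nrow(sequence)
  hs <- length(params$forward$Q$b)
  h <- numeric(hs); cc <- numeric(hs)
  for (t in 1:tt) {
    st <- oracle_lstm_step(sequence[t, ], h, cc, params$forward)
    h <- st$h; cc <- st$c
  }
  h_fwd_last <- h
  h <- numeric(hs); cc <- numeric(hs)
  for (t in tt:1) {
    st <- oracle_lstm_step(sequence[t, ], h, cc, params$backward)
    h <- st$h; cc <- st$c
  }
  h_bwd_first <- h
  sum(params$w_out * c(h_fwd_last, h_bwd_first)) + params$b_out
}

# double-loop FCM oracles
oracle_fcm_objective <- function(w, centers, data, x) {
  acc <- 0
  for (i in seq_len(nrow(centers)))
    for (k in seq_len(nrow(data)))
      acc <- acc + w[k, i]^x * sum((data[k, ] - centers[i, ])^2)
  acc
}

oracle_memberships <- function(data, centers, x) {
  n <- nrow(data); cc <- nrow(centers)
  w <- matrix(0, n, cc)
  for (k in seq_len(n)) {
    dists <- sapply(seq_len(cc), function(i)
      sqrt(sum((data[k, ] - centers[i, ])^2)))
    for (i in seq_len(cc))
      w[k, i] <- 1 / sum((dists[i] / dists)^(2 / (x - 1)))
  }
  w
}

random_params <- function(config, seed) {
  set.seed(seed)
  v <- runif(chstm_param_count(config), -1, 1)
  nodulekit:::chstm_unflatten(v, config)
}
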