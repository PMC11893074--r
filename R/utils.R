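# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream (scene generation must be bit-reproducible per its own seed).
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

stop_invalid <- function(...) {
  stop(structure(class = c("ulmr_invalid_argument", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_degenerate <- function(...) {
  stop(structure(class = c("ulmr_degenerate_input", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# Centered moving-window sum with zero padding outside the image,
# window of (2*rh+1) x (2*rw+1), via an integral image. O(H*W).
box_sum <- function(M, rh, rw) {
  H <- nrow(M); W <- ncol(M)
  P <- matrix(0, H + 2 * rh, W + 2 * rw)
  P[(rh + 1):(rh + H), (rw + 1):(rw + W)] <- M
  S <- apply(apply(P, 2, cumsum), 1, cumsum)  # transposed integral image
  S <- t(S)
  S <- rbind(0, cbind(0, S))
  h <- 2 * rh + 1; w <- 2 * rw + 1
  # window for centered pixel (i, j) covers padded rows i..i+h-1, cols j..j+w-1
  S[(1 + h):(H + h), (1 + w):(W + w)] -
    S[(1 + h):(H + h), 1:W] -
    S[1:H, (1 + w):(W + w)] +
    S[1:H, 1:W]
}

# 1D Gaussian kernel, unit sum, odd length covering +-3.5 sigma.
gauss_kernel_1d <- function(sigma_px) {
  r <- max(1L, as.integer(ceiling(3.5 * sigma_px)))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma_px^2))
  k / sum(k)
}

# Separable convolution with zero padding (kernel must have unit sum for
# mass conservation away from boundaries).
sep_convolve <- function(M, k) {
  r <- (length(k) - 1L) / 2L
  H <- nrow(M); W <- ncol(M)
  P <- matrix(0, H + 2 * r, W)
  P[(r + 1):(r + H), ] <- M
  A <- matrix(0, H, W)
  for (i in seq_along(k)) A <- A + k[i] * P[i:(i + H - 1), , drop = FALSE]
  P2 <- matrix(0, H, W + 2 * r)
  P2[, (r + 1):(r + W)] <- A
  B <- matrix(0, H, W)
  for (i in seq_along(k)) B <- B + k[i] * P2[, i:(i + W - 1), drop = FALSE]
  B
}

# Disk-kernel convolution (unit-sum flat disk of radius r_px).
disk_convolve <- function(M, r_px) {
  r <- max(1L, as.integer(round(r_px)))
  x <- (-r):r
  d <- outer(x, x, function(a, b) sqrt(a^2 + b^2)) <= r_px + 1e-9
  k <- d / sum(d)
  H <- nrow(M); W <- ncol(M)
  P <- matrix(0, H + 2 * r, W + 2 * r)
  P[(r + 1):(r + H), (r + 1):(r + W)] <- M
  out <- matrix(0, H, W)
  for (i in seq_len(2 * r + 1))
    for (j in seq_len(2 * r + 1))
      if (k[i, j] > 0)
        out <- out + k[i, j] * P[i:(i + H - 1), j:(j + W - 1)]
  out
}

# FFT cross-correlation of image with kernel ("same" size, kernel centered):
# out(x) = sum_s I(x + s) K(s), s relative to the kernel center.
fft_crosscorr <- function(I, K, plan = NULL) {
  H <- nrow(I); W <- ncol(I)
  h <- nrow(K); w <- ncol(K)
  Hp <- stats::nextn(H + h - 1, c(2, 3, 5))
  Wp <- stats::nextn(W + w - 1, c(2, 3, 5))
  Ip <- matrix(0, Hp, Wp); Ip[1:H, 1:W] <- I
  if (is.null(plan)) {
    Kp <- matrix(0, Hp, Wp); Kp[1:h, 1:w] <- K
    FK <- Conj(stats::fft(Kp))
  } else FK <- plan
  R <- Re(stats::fft(stats::fft(Ip) * FK, inverse = TRUE)) / (Hp * Wp)
  rh <- (h - 1L) %/% 2L; rw <- (w - 1L) %/% 2L
  # R[u] = sum_t I[t + u] K[t] (circular, 0-based); the kernel-centered
  # correlation at image pixel (i, j) sits at u = (i - 1 - rh, j - 1 - rw)
  ridx <- (seq_len(H) - 1L - rh) %% Hp + 1L
  cidx <- (seq_len(W) - 1L - rw) %% Wp + 1L
  R[ridx, cidx]
}

# Precompute the conjugate kernel FFT for repeated fft_crosscorr calls.
fft_corr_plan <- function(dimI, K) {
  H <- dimI[1]; W <- dimI[2]
  h <- nrow(K); w <- ncol(K)
  Hp <- stats::nextn(H + h - 1, c(2, 3, 5))
  Wp <- stats::nextn(W + w - 1, c(2, 3, 5))
  Kp <- matrix(0, Hp, Wp); Kp[1:h, 1:w] <- K
  Conj(stats::fft(Kp))
}

ncc_global <- function(a, b) {
  va <- as.vector(a); vb <- as.vector(b)
  if (sd(va) == 0 || sd(vb) == 0) return(0)
  cor(va, vb)
}
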