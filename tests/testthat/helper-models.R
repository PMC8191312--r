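# Shared fixtures: small transition matrices and generators built in code.

# reversible transition matrix from a random symmetric count matrix;
# diagBoost controls metastability (larger -> slower mixing)
randReversibleT <- function(k, seed, diagBoost = 2) {
  set.seed(seed)
  S <- matrix(runif(k * k, 0.2, 1), k, k)
  S <- (S + t(S)) / 2
  diag(S) <- diag(S) + diagBoost
  S / rowSums(S)
}

T2 <- rbind(c(0.9, 0.1), c(0.2, 0.8))          # pi = (2/3, 1/3), lambda2 = 0.7

T4block <- rbind(c(0.90, 0.09, 0.01, 0.00),    # two weakly coupled blocks
                 c(0.09, 0.90, 0.00, 0.01),
                 c(0.01, 0.00, 0.90, 0.09),
                 c(0.00, 0.01, 0.09, 0.90))

# uniform birth-death chain on k states (reflecting interior, absorbing-free)
birthDeathT <- function(k, p = 0.5) {
  T <- matrix(0, k, k)
  for (i in seq_len(k)) {
    if (i == 1) { T[i, 1] <- 1 - p; T[i, 2] <- p }
    else if (i == k) { T[i, k] <- 1 - p; T[i, k - 1] <- p }
    else { T[i, i - 1] <- p / 2; T[i, i + 1] <- p / 2; T[i, i] <- 1 - p }
  }
  T
}

# brute-force committor by absorption power iteration
committorPower <- function(T, A, B, iters = 20000L) {
  k <- nrow(T)
  q <- numeric(k); q[B] <- 1
  I <- setdiff(seq_len(k), c(A, B))
  for (it in seq_len(iters)) {
    qn <- q
    qn[I] <- T[I, , drop = FALSE] %*% q
    if (max(abs(qn - q)) < 1e-14) { q <- qn; break }
    q <- qn
  }
  q
}

rotationMatrix3 <- function(axis, angleDeg) msmhelix:::.rotation_matrix(axis, angleDeg)

randomRotation <- function(seed) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(9), 3, 3))) * sample(c(-1, 1), 1)
}
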