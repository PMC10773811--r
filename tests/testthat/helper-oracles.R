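# Independent reference implementations used to cross-check the package.
# Written in plain loops so they share nothing with the library code paths.

# Channel attention evaluated sample by sample with dense arithmetic.
wa_reference <- function(x, W0, W1, b0, b1) {
  d <- dim(x)
  C <- d[1]; N <- d[4]
  att <- matrix(0, C, N)
  out <- array(0, d)
  for (n in seq_len(N)) {
    xavg <- numeric(C); xmax <- numeric(C)
    for (c in seq_len(C)) {
      v <- x[c, , , n]
      xavg[c] <- mean(v)
      xmax[c] <- max(v)
    }
    branch <- function(v) {
      h <- as.numeric(W0 %*% v + b0)
      h[h < 0] <- 0
      as.numeric(W1 %*% h + b1)
    }
    z <- branch(xavg) + branch(xmax)
    s <- 1 / (1 + exp(-z))
    att[, n] <- s
    for (c in seq_len(C)) out[c, , , n] <- x[c, , , n] * s[c]
  }
  list(attention = att, output = out)
}

# All-pairs AUC with half credit for ties.
pair_auc <- function(att, mask) {
  wins <- 0; total <- 0
  for (i in which(mask)) for (j in which(!mask)) {
    total <- total + 1
    if (att[i] > att[j]) wins <- wins + 1
    else if (att[i] == att[j]) wins <- wins + 0.5
  }
  wins / total
}
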