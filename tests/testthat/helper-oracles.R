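# Independent brute-force oracles used to validate the mRMR machinery.
# Deliberately written with naive loops, separate from the package code.

oracle_discretize <- function(v) {
  if (length(unique(v)) <= 2) return(v)
  mu <- mean(v)
  s <- sd(v)
  ifelse(v < mu - s, -1, ifelse(v > mu + s, 1, 0))
}

oracle_mi <- function(x, y) {
  n <- length(x)
  total <- 0
  for (a in unique(x)) {
    for (b in unique(y)) {
      pxy <- sum(x == a & y == b) / n
      if (pxy == 0) next
      px <- sum(x == a) / n
      py <- sum(y == b) / n
      total <- total + pxy * log2(pxy / (px * py))
    }
  }
  total
}

# Greedy mRMR (difference form) by exhaustive evaluation at every step.
oracle_mrmr_order <- function(X, y) {
  Xd <- apply(X, 2, oracle_discretize)
  m <- ncol(X)
  rel <- sapply(seq_len(m), function(j) oracle_mi(Xd[, j], y))
  sel <- integer(0)
  rem <- seq_len(m)
  while (length(rem)) {
    scores <- sapply(rem, function(j) {
      if (!length(sel)) return(rel[j])
      rel[j] - mean(sapply(sel, function(s) oracle_mi(Xd[, j], Xd[, s])))
    })
    pick <- rem[which.max(scores)]  # rem kept sorted: ties -> smaller index
    sel <- c(sel, pick)
    rem <- setdiff(rem, pick)
  }
  sel
}
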