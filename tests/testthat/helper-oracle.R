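# Independent brute-force oracles: plain linear-domain arithmetic with
# explicit loops, sharing no code with the package internals.

# H as a plain lookup closure over a table of (delta, prob)
oracleH <- function(deltas, probs, floor = 1e-10) {
  function(d) {
    d <- round(d)
    i <- match(d, deltas)
    ifelse(is.na(i), floor, probs[i])
  }
}

oracleGenotypeLik <- function(delta, H, l, eps = 0) {
  L0 <- 1; L1 <- 1; L2 <- 1
  for (d in delta) {
    L0 <- L0 * H(d - eps)
    L1 <- L1 * (H(d - eps) + H(d - l)) / 2
    L2 <- L2 * H(d - l)
  }
  c(L0, L1, L2)
}

oracleWeights <- function(L, f) {
  pri <- c((1 - f)^2, 2 * f * (1 - f), f^2)
  num <- numeric(3)
  for (g in 1:3) num[g] <- L[g] * pri[g]
  num / sum(num)
}

oracleLambda <- function(Llist, Wlist, pi0) {
  num <- 1 - pi0
  den <- pi0
  for (s in seq_along(Llist)) {
    num <- num * Llist[[s]][1]
    mix <- 0
    for (g in 1:3) mix <- mix + Wlist[[s]][g] * Llist[[s]][g]
    den <- den * mix
  }
  num / den
}

oracleUpdateF <- function(Wlist) {
  tot <- 0
  for (W in Wlist) tot <- tot + W[2] + 2 * W[3]
  tot / (2 * length(Wlist))
}

oracleShiftP <- function(d, H, l, eps, a1, a2) {
  a1 * H(d - l) / (H(d - eps) + H(d - l)) + a2
}

oracleUpdateL <- function(deltaList, Hlist, l, eps, Wlist) {
  num <- 0; den <- 0
  for (s in seq_along(deltaList)) {
    for (d in deltaList[[s]]) {
      P <- oracleShiftP(d, Hlist[[s]], l, eps, Wlist[[s]][2], Wlist[[s]][3])
      num <- num + d * P
      den <- den + P
    }
  }
  num / den
}

# exact HWE oracle for tiny n: enumerate every placement of the alternate
# alleles over the 2n ordered allele slots
oracleHweExact <- function(n00, n01, n11) {
  n <- n00 + n01 + n11
  nAlt <- 2 * n11 + n01
  if (nAlt == 0 || nAlt == 2 * n) return(1)
  slots <- 2 * n
  configs <- combn(slots, nAlt)
  hetCount <- integer(ncol(configs))
  for (k in seq_len(ncol(configs))) {
    alt <- logical(slots)
    alt[configs[, k]] <- TRUE
    g <- alt[seq(1, slots, by = 2)] + alt[seq(2, slots, by = 2)]
    hetCount[k] <- sum(g == 1)
  }
  tabs <- table(hetCount) / ncol(configs)
  pObs <- tabs[[as.character(n01)]]
  sum(tabs[tabs <= pObs + 1e-12])
}

# Mendelian-consistency oracle by explicit allele transmission
oracleMendelOk <- function(fa, mo, ch) {
  alleles <- function(g) switch(g + 1L, c(0L, 0L), c(0L, 1L), c(1L, 1L))
  for (a in alleles(fa)) for (b in alleles(mo))
    if (a + b == ch) return(TRUE)
  FALSE
}
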