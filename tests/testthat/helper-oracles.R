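# Independent oracles kept deliberately naive.

# Exhaustive-enumeration Mann-Whitney oracle: U statistic (pairs with
# a > b) and exact two-sided p over all assignments of the pooled
# ranks. Valid for untied samples with small n_a + n_b.
mwEnumerate <- function(a, b) {
  na <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  uOf <- function(ix) sum(r[ix]) - na * (na + 1) / 2
  uObs <- uOf(seq_len(na))
  mu <- na * length(b) / 2
  allU <- apply(utils::combn(length(pooled), na), 2, uOf)
  list(U = uObs,
       p = mean(abs(allU - mu) >= abs(uObs - mu) - 1e-12))
}

# closed-form pooled-variance two-sample t
tClosedForm <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * pt(-abs(t), na + nb - 2))
}

# closest distance from an ellipsoid centre to its surface along u
ellipsoidRayOracle <- function(semiaxes, u) {
  u <- u / sqrt(sum(u^2))
  1 / sqrt(sum((u / semiaxes)^2))
}
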