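# Independent oracles, written from first principles with explicit loops so
# they share no code path with the implementation they check.

# Brute-force standardize + signature score: per-gene reference mean and
# sample SD by summation, z-transform, then a loop-based mean over the
# present member genes.
oracle_scores <- function(expr, reference, members, ddof = 1) {
  genes <- rownames(expr)
  samples <- colnames(expr)
  z <- matrix(NA_real_, nrow(expr), ncol(expr), dimnames = dimnames(expr))
  kept <- character(0)
  for (g in genes) {
    vals <- expr[g, reference]
    m <- sum(vals) / length(vals)
    ss <- 0
    for (v in vals) ss <- ss + (v - m)^2
    s <- sqrt(ss / (length(vals) - ddof))
    if (s == 0) next
    kept <- c(kept, g)
    for (smp in samples) z[g, smp] <- (expr[g, smp] - m) / s
  }
  present <- members[members %in% kept]
  out <- stats::setNames(numeric(length(samples)), samples)
  for (smp in samples) {
    tot <- 0
    for (g in present) tot <- tot + z[g, smp]
    out[smp] <- tot / length(present)
  }
  out
}

# Exhaustive hypergeometric upper tail: probability that a uniformly drawn
# size-n hit subset of a size-N universe overlaps the first K elements in
# at least k_obs members, by enumeration of all C(N, n) subsets.
oracle_hyper_tail <- function(N, K, n, k_obs) {
  subs <- utils::combn(N, n)
  ge <- 0
  for (j in seq_len(ncol(subs)))
    if (sum(subs[, j] <= K) >= k_obs) ge <- ge + 1
  ge / ncol(subs)
}

# Textbook two-sided pooled-variance t-test.
oracle_student <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) /
    (n1 + n2 - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(statistic = t, p = 2 * stats::pt(-abs(t), n1 + n2 - 2))
}

# Textbook Welch t-test with Welch-Satterthwaite degrees of freedom.
oracle_welch <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  v1 <- stats::var(a) / n1; v2 <- stats::var(b) / n2
  t <- (mean(a) - mean(b)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(statistic = t, p = 2 * stats::pt(-abs(t), df))
}

# Exact two-sided Mann-Whitney p by full enumeration of the rank-sum null
# distribution (no ties assumed).
oracle_mann_whitney <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  subs <- utils::combn(n1 + n2, n1)
  w_null <- colSums(matrix(seq_len(n1 + n2)[subs], nrow = n1)) -
    n1 * (n1 + 1) / 2
  p_le <- mean(w_null <= w_obs)
  p_ge <- mean(w_null >= w_obs)
  list(statistic = w_obs, p = min(1, 2 * min(p_le, p_ge)))
}

# Small in-memory cohort used by several IO and stratification tests.
toy_cohort <- function() {
  expr <- matrix(c(1.5, 2.25, 3.5, 4.75,
                   2.0, 1.0, 0.5, 3.0,
                   5.0, 5.5, 6.0, 6.5),
                 nrow = 3, byrow = TRUE,
                 dimnames = list(c("GPC3", "MET", "AFP"),
                                 c("S1", "S2", "S3", "S4")))
  clinical <- data.frame(sample_id = c("S1", "S2", "S3", "S4"),
                         sample_type = c("HCC", "HCC", "HCC", "ST"),
                         os_time = c(24.5, 10, 36, 0),
                         os_event = c(1L, 0L, 1L, 0L),
                         stringsAsFactors = FALSE)
  mutations <- data.frame(sample_id = c("S1", "S2"),
                          gene = c("TP53", "TP53"),
                          variant_class = c("missense", "truncating"),
                          stringsAsFactors = FALSE)
  list(expr = expr, clinical = clinical, mutations = mutations)
}
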