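# shared fixture builders and independent oracles

make_table <- function(m) {
  score_table(m)
}

# brute-force confusion metrics from explicit label/prediction vectors
vectors_from_counts <- function(tp, tn, fp, fn) {
  list(labels = c(rep(1, tp), rep(0, tn), rep(0, fp), rep(1, fn)),
       preds  = c(rep(1, tp), rep(0, tn), rep(1, fp), rep(0, fn)))
}

brute_mcc <- function(tp, tn, fp, fn) {
  v <- vectors_from_counts(tp, tn, fp, fn)
  TP <- sum(v$labels == 1 & v$preds == 1)
  TN <- sum(v$labels == 0 & v$preds == 0)
  FP <- sum(v$labels == 0 & v$preds == 1)
  FN <- sum(v$labels == 1 & v$preds == 0)
  den <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  if (den == 0) return(0)
  (TP * TN - FP * FN) / sqrt(den)
}

brute_ba <- function(tp, tn, fp, fn) {
  v <- vectors_from_counts(tp, tn, fp, fn)
  sens <- mean(v$preds[v$labels == 1] == 1)
  spec <- mean(v$preds[v$labels == 0] == 0)
  (sens + spec) / 2
}

# all-pairs AUC oracle: P(active outranks inactive), ties = 1/2
brute_auc <- function(scores, labels, higher_active = TRUE) {
  s <- if (higher_active) scores else -scores
  a <- s[labels == 1]
  i <- s[labels == 0]
  tot <- 0
  for (x in a) for (y in i)
    tot <- tot + if (x > y) 1 else if (x == y) 0.5 else 0
  tot / (length(a) * length(i))
}

# naive double-loop calibration oracle
brute_calibrate <- function(q_scores, r_scores, r_act, S, p) {
  out <- numeric(length(q_scores))
  for (j in seq_along(q_scores)) {
    omega <- 0
    acc <- 0
    for (i in seq_along(r_scores)) {
      w <- S[j, i]^p
      omega <- omega + w
      acc <- acc + w * r_act[i] / r_scores[i]
    }
    out[j] <- if (omega == 0) q_scores[j] else q_scores[j] * acc / omega
  }
  out
}

# exhaustive bitmask subset counter (ensemble enumeration oracle)
brute_subset_count <- function(k, min_size, max_size) {
  n <- 0L
  for (mask in seq_len(2^k) - 1L) {
    sz <- sum(bitwAnd(mask, 2^(0:(k - 1))) > 0)
    if (sz >= min_size && sz <= max_size) n <- n + 1L
  }
  n
}
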