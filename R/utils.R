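#' @importFrom withr with_seed
NULL

# Area under the ROC curve via the rank (Mann-Whitney) identity.
# labels: logical/0-1 truth; scores: higher = more likely positive.
auroc <- function(labels, scores) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Derive a stream-specific 31-bit seed from a user seed, so independent
# generators consuming the same top-level seed do not share a stream.
derive_seed <- function(seed, stream) {
  as.integer(((as.numeric(seed) %% 2147483647) * 7919 + stream * 104729) %% 2147483647)
}
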