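# Independent oracles used to validate the analytical implementations.

# Brute-force KS running-sum: walk every position i of the ranked list,
# tracking the set's empirical CDF against the uniform line. Deviation above
# is evaluated after the step at i, deviation below just before it.
brute_force_es <- function(ranked_list, gene_set) {
  n <- length(ranked_list)
  t <- length(gene_set)
  hit <- ranked_list %in% gene_set
  cdf <- cumsum(hit) / t
  above <- max(cdf - seq_len(n) / n)
  below <- max(seq_len(n) / n - c(0, cdf[-n]))
  if (above >= below) above else -below
}

# The two one-sided running-sum deviations (top and bottom) separately.
brute_force_ab <- function(ranked_list, gene_set) {
  n <- length(ranked_list)
  t <- length(gene_set)
  cdf <- cumsum(ranked_list %in% gene_set) / t
  list(a = max(cdf - seq_len(n) / n),
       b = max(seq_len(n) / n - c(0, cdf[-n])))
}

# Direct hypergeometric upper-tail sum: P(overlap >= k) drawing n from a
# universe of N containing K marked genes.
hyper_tail_oracle <- function(k, K, n, N) {
  if (k <= 0) return(1)
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Build a signature_profile whose ranking places chosen genes at chosen
# positions: genes are "g1".."gn" ranked in index order (descending scores).
toy_signature <- function(n, up_positions = integer(0),
                          down_positions = integer(0), cap = 150) {
  genes <- sprintf("g%02d", seq_len(n))
  scores <- setNames(rev(seq_len(n)), genes)  # g01 highest
  sig <- build_signature(scores, cap = cap)
  sig$up_set <- genes[up_positions]
  sig$down_set <- genes[down_positions]
  sig
}
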