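# Independent brute-force oracles used against the implementation.

# all-pairs O(n^2) regulatory-network scan
brute_force_edges <- function(g) {
  out <- list()
  for (tf in g$genes) {
    if (tf$category != "tf") next
    for (target in g$genes) {
      if (motif_matches(tf$bind_motif, target$operator))
        out[[length(out) + 1L]] <- c(tf = tf$id, target = target$id)
    }
  }
  if (!length(out)) return(data.frame(tf = integer(), target = integer()))
  df <- as.data.frame(do.call(rbind, out))
  df[order(df$tf, df$target), ]
}

# exhaustive expectation of the intact-pair retention fraction when `k` of
# the `2p` genes of p ohnolog pairs are deleted uniformly at random
enumerate_retention <- function(p, k) {
  genes <- seq_len(2L * p)
  pair_of <- rep(seq_len(p), each = 2L)
  subsets <- utils::combn(genes, k, simplify = FALSE)
  vals <- vapply(subsets, function(del) {
    alive <- setdiff(genes, del)
    intact <- vapply(seq_len(p), function(q)
      all(which(pair_of == q) %in% alive), logical(1))
    in_pairs <- 2L * sum(intact)
    if (length(alive) == 0L) return(NA_real_)
    in_pairs / length(alive)
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}

# exact two-sided Mann-Whitney p-value by complete enumeration of group
# assignments (small n)
enumerate_rank_sum_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  m <- length(b)
  mid <- n * m / 2
  subsets <- utils::combn(length(pooled), n, simplify = FALSE)
  us <- vapply(subsets, function(idx)
    sum(r[idx]) - n * (n + 1) / 2, numeric(1))
  mean(abs(us - mid) >= abs(u_obs - mid) - 1e-12)
}
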