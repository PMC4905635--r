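# exhaustive enumeration of the permutation null for tiny instances
exhaustive_evalue <- function(a, b) {
  ra <- apply(a, 2, rank)
  rb <- apply(b, 2, rank)
  g <- nrow(a); k <- ncol(a)
  obs <- abs(rowMeans(log2(ra / rb)))
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  P <- perms(seq_len(g))
  idx <- expand.grid(rep(list(seq_along(P)), 2 * k))
  counts <- numeric(g)
  sumsq <- numeric(g)
  total <- nrow(idx)
  for (s in seq_len(total)) {
    la <- sapply(seq_len(k), function(r) log2(ra[P[[idx[s, r]]], r]))
    lb <- sapply(seq_len(k), function(r) log2(rb[P[[idx[s, k + r]]], r]))
    nullv <- abs(rowMeans(la - lb))
    cnt <- vapply(obs, function(o) sum(nullv >= o - 1e-12), numeric(1))
    counts <- counts + cnt
    sumsq <- sumsq + cnt^2
  }
  list(e = counts / total,
       sd = sqrt(pmax(sumsq / total - (counts / total)^2, 0)),
       total = total)
}
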