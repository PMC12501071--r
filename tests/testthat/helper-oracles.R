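# Independent oracles, written before the implementations they check.

# Sørensen index by explicit element counting (no set ops).
brute_sorensen <- function(a, b) {
  a <- a[!duplicated(a)]
  b <- b[!duplicated(b)]
  common <- 0
  for (x in a) for (y in b) if (identical(x, y)) common <- common + 1
  2 * common / (length(a) + length(b))
}

# ssGSEA running sum by literal position-by-position enumeration.
brute_ssgsea <- function(expr, gene_set, alpha = 0.25) {
  n <- length(expr)
  r <- rank(expr, ties.method = "average")
  ord <- order(-expr, names(expr))
  in_set <- names(expr) %in% gene_set
  m <- sum(in_set)
  if (m == n) return(0)
  denom <- sum(r[in_set]^alpha)
  p_in <- 0; p_out <- 0; s <- 0
  for (i in seq_len(n)) {
    g <- ord[i]
    if (in_set[g]) p_in <- p_in + r[g]^alpha / denom
    else p_out <- p_out + 1 / (n - m)
    s <- s + (p_in - p_out)
  }
  unname(s)
}

# Benjamini-Hochberg step-up applied by hand.
brute_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- p[ord] * n / seq_len(n)
  for (i in (n - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(n)
  out[ord] <- pmin(adj, 1)
  out
}

# Tumor-level consensus counting by brute force: for each gene, walk every
# tumor's modules and count tumors containing it at least once.
brute_consensus <- function(member_modules, recurrence_fraction = 0.5) {
  tumors <- unique(vapply(member_modules, `[[`, character(1), "source_tumor"))
  all_genes <- unique(unlist(lapply(member_modules, `[[`, "genes")))
  keep <- character()
  for (g in all_genes) {
    n_t <- 0
    for (t in tumors) {
      found <- FALSE
      for (m in member_modules)
        if (m$source_tumor == t && g %in% m$genes) found <- TRUE
      if (found) n_t <- n_t + 1
    }
    if (n_t / length(tumors) >= recurrence_fraction) keep <- c(keep, g)
  }
  sort(keep)
}
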