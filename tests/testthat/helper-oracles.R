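# Independent brute-force oracles used to cross-check the package's
# closed-form / vectorized implementations. Each is written from the
# defining formula, deliberately naive.

# upper-tail hypergeometric P(X >= k) by explicit binomial-coefficient sum
oracle_hyper_tail <- function(k, i, j, N) {
  if (k > min(i, j)) return(0)
  ks <- k:min(i, j)
  sum(choose(i, ks) * choose(N - i, j - ks)) / choose(N, j)
}

# TOM by literal double loop over the definition
oracle_tom <- function(a) {
  n <- nrow(a)
  k <- rowSums(a) - diag(a)
  out <- matrix(1, n, n)
  for (ii in seq_len(n)) for (jj in seq_len(n)) {
    if (ii == jj) next
    num <- sum(a[ii, -c(ii, jj)] * a[-c(ii, jj), jj]) + a[ii, jj]
    out[ii, jj] <- num / (min(k[ii], k[jj]) + 1 - a[ii, jj])
  }
  out
}

# ordinary pooled two-sample t with its two-sided p
oracle_pooled_t <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  sp2 <- ((n1 - 1) * var(x1) + (n2 - 1) * var(x2)) / (n1 + n2 - 2)
  t <- (mean(x2) - mean(x1)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * pt(-abs(t), df = n1 + n2 - 2))
}

# a small ranked_list built directly from named scores
make_ranked <- function(scores) {
  ord <- order(-scores, names(scores), method = "radix")
  out <- tibble::tibble(gene = names(scores)[ord], score = unname(scores[ord]))
  structure(out, n = nrow(out), n_pos = sum(out$score > 0),
            class = c("ranked_list", class(out)))
}

# random adjacency matrix: symmetric, [0,1], unit diagonal
random_adjacency <- function(n) {
  a <- matrix(runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  dimnames(a) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
  stressconcord:::new_gene_network(a, kind = "adjacency", beta = 1, signed = TRUE)
}

# hand-built enrichment_result for key-module pattern tests
fake_enrichment <- function(df, fdr = 0.05) {
  df$significant <- df$p_adj < fdr
  structure(tibble::as_tibble(df), background_size = 1000, fdr = fdr,
            class = c("enrichment_result", class(tibble::as_tibble(df))))
}

default_ring_experiments <- c(
  WT_VEH_up = "A", WT_CORT_up = "A", hMet_VEH_up = "A", hMet_CORT_up = "A",
  SH_RES_up = "B", SH_SUS_up = "B", EE_RES_up = "B", EE_SUS_up = "B")

# recovered label of the module holding the majority of a planted module
majority_label <- function(labels, truth, planted) {
  as.integer(names(sort(table(labels[names(truth)[truth == planted]]),
                        decreasing = TRUE))[1])
}
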