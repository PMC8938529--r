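test_that("Fisher enrichment p equals exhaustive hypergeometric tails", {
  bg <- sprintf("g%03d", 1:100)
  labels <- setNames(rep(0L, 100), bg)
  labels[1:10] <- 1L
  deg <- c(bg[1:5], bg[51:55])  # overlap 5 with the module
  res <- fisher_enrichment(labels, list(set1 = deg), bg)
  expect_equal(res$n_overlap, 5L)
  expect_equal(res$p, oracle_hyper_tail(5, 10, 10, 100), tolerance = 1e-12)
  # random instances over backgrounds up to 200
  set.seed(301)
  for (r in 1:20) {
    N <- sample(20:200, 1)
    bgx <- sprintf("x%03d", 1:N)
    nm <- sample(2:(N %/% 2), 1)
    nd <- sample(1:(N %/% 2), 1)
    lab <- setNames(rep(0L, N), bgx)
    lab[sample(N, nm)] <- 1L
    degx <- sample(bgx, nd)
    r1 <- fisher_enrichment(lab, list(s = degx), bgx)
    k <- length(intersect(names(lab)[lab == 1L], degx))
    expect_equal(r1$p, oracle_hyper_tail(k, nm, nd, N), tolerance = 1e-12)
  }
})

test_that("zero overlap is never significant and full overlap is extreme", {
  bg <- sprintf("g%03d", 1:60)
  labels <- setNames(rep(0L, 60), bg)
  labels[1:10] <- 1L
  res0 <- fisher_enrichment(labels, list(s = bg[11:20]), bg)
  expect_equal(res0$p, 1, tolerance = 1e-12)
  expect_false(res0$significant)
  # module identical to the DEG set: minimal possible p for the margins
  resx <- fisher_enrichment(labels, list(s = bg[1:10]), bg)
  expect_equal(resx$p, oracle_hyper_tail(10, 10, 10, 60), tolerance = 1e-12)
  expect_lt(resx$p, 1e-10)
})

test_that("DEG genes outside the background are dropped with a message", {
  bg <- sprintf("g%03d", 1:50)
  labels <- setNames(rep(c(1L, 0L), c(10, 40)), bg)
  expect_message(
    res <- fisher_enrichment(labels, list(s = c(bg[1:5], "zz1", "zz2")), bg),
    "2 DEG entries")
  expect_equal(res$n_set, 5L)
})

test_that("BH adjustment reproduces the hand step-up examples", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04), tolerance = 1e-12)
  expect_equal(bh_adjust(c(0.005, 0.011, 0.02, 0.04)),
               c(0.02, 0.022, 0.02 * 4 / 3, 0.04), tolerance = 1e-12)
  expect_equal(bh_adjust(0.03), 0.03)
  # order invariance: adjust, then restore order
  set.seed(302)
  p <- runif(50)
  perm <- sample(50)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]), tolerance = 1e-12)
  expect_error(bh_adjust(c(0.1, 1.2)), class = "sc_bad_input")
})

test_that("relevance score averages -log10 adjusted p across sets", {
  df <- tidyr::expand_grid(module = 1:2, set = paste0("s", 1:8))
  df$n_module <- 10L; df$n_set <- 10L; df$n_overlap <- 1L; df$odds_ratio <- 1
  df$p <- 0.5
  df$p_adj <- rep(c(0.1, 1), each = 8)
  enr <- fake_enrichment(df)
  rel <- relevance_score(enr)
  expect_equal(rel$relevance[rel$module == 1], 1, tolerance = 1e-12)
  expect_equal(rel$relevance[rel$module == 2], 0, tolerance = 1e-12)
})

test_that("key flags require significance in both experiments", {
  base <- tidyr::expand_grid(module = 1:3,
                             set = names(default_ring_experiments))
  base$n_module <- 20L; base$n_set <- 20L; base$n_overlap <- 2L
  base$odds_ratio <- 1; base$p <- 0.5; base$p_adj <- 0.5
  hit <- function(df, m, s) { df$p_adj[df$module == m & df$set == s] <- 0.01; df }
  # significant only in one CORT-experiment set: not key
  df <- hit(base, 1, "WT_CORT_up")
  # the published cyan-like pattern: CORT-up plus SH-SUS-up
  df <- hit(hit(df, 2, "hMet_CORT_up"), 2, "SH_SUS_up")
  # the published yellow-like pattern: hMet-VEH-up plus EE-SUS-up
  df <- hit(hit(df, 3, "hMet_VEH_up"), 3, "EE_SUS_up")
  keys <- key_modules(fake_enrichment(df), default_ring_experiments)
  expect_false(keys$key[keys$module == 1])
  expect_true(keys$key[keys$module == 2])
  expect_true(keys$key[keys$module == 3])
  expect_error(key_modules(fake_enrichment(df), c(WT_CORT_up = "A")),
               class = "sc_bad_input")
})

test_that("hub selection applies the mu + sigma rule with sample sd", {
  kmes <- c(1.0, 0.9, rep(0.5, 8))
  genes <- sprintf("h%02d", 1:10)
  kmat <- matrix(kmes, ncol = 1, dimnames = list(genes, "ME1"))
  labels <- setNames(rep(1L, 10), genes)
  hs <- select_hubs(kmat, labels, 1L)
  expect_equal(attr(hs, "threshold"), mean(kmes) + sd(kmes), tolerance = 1e-12)
  expect_identical(hs$gene[hs$is_hub], c("h01", "h02"))
  expect_identical(hs$gene, genes[order(-kmes, genes)])
  # same result when the kME rows arrive in arbitrary order
  set.seed(304)
  shuf <- sample(10)
  hs2 <- select_hubs(kmat[shuf, , drop = FALSE],
                     labels[shuf], 1L)
  expect_identical(hs2$gene, hs$gene)
  expect_identical(hs2$is_hub, hs$is_hub)
  expect_true(all(hs2$score[hs2$is_hub] > attr(hs2, "threshold")))
  expect_identical(order(-hs2$score), seq_len(nrow(hs2)))
  # all-equal kME: sigma = 0 and the strict inequality yields no hubs
  keq <- matrix(rep(0.7, 5), ncol = 1,
                dimnames = list(sprintf("e%d", 1:5), "ME1"))
  labeq <- setNames(rep(1L, 5), rownames(keq))
  expect_equal(sum(select_hubs(keq, labeq, 1L)$is_hub), 0L)
  # single-gene module: sd undefined
  k1 <- matrix(0.9, dimnames = list("solo", "ME1"))
  expect_error(select_hubs(k1, setNames(1L, "solo"), 1L),
               class = "sc_bad_input")
})

test_that("hub DEG flags and TOM edge export are attached", {
  set.seed(303)
  genes <- sprintf("h%02d", 1:6)
  kmat <- matrix(seq(0.9, 0.4, length.out = 6), ncol = 1,
                 dimnames = list(genes, "ME1"))
  labels <- setNames(rep(1L, 6), genes)
  a <- random_adjacency(6)
  rownames(a) <- colnames(a) <- genes
  tm <- tom(a)
  hs <- select_hubs(kmat, labels, 1L, degsets = list(s = c("h01", "h05")),
                    tom_mat = tm, edge_threshold = 0)
  expect_identical(hs$is_deg, hs$gene %in% c("h01", "h05"))
  edges <- attr(hs, "edges")
  expect_equal(nrow(edges), choose(6, 2))
  expect_true(all(edges$tom >= 0 & edges$tom <= 1))
  # kIN ranking variant runs and ranks by intramodular connectivity
  hk <- select_hubs(kmat, labels, 1L, tom_mat = tm, measure = "kin")
  kin <- rowSums(unclass(tm)) - diag(unclass(tm))
  expect_identical(hk$gene[1], names(which.max(kin)))
})
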