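# four-sample profiles with exactly known correlations
exact_cor_expr <- function() {
  x <- c(1, -1, 0, 0)
  z <- c(0, 0, 1, -1)
  rbind(g1 = x, g2 = x + sqrt(3) * z,  # cor(g1, g2) = 0.5 exactly
        g3 = 2 * x + 1,                # cor(g1, g3) = 1
        g4 = -x)                       # cor(g1, g4) = -1
}

test_that("adjacency implements the signed and unsigned maps", {
  e <- exact_cor_expr()
  a_s <- adjacency(e, beta = 6, signed = TRUE)
  a_u <- adjacency(e, beta = 6, signed = FALSE)
  expect_equal(a_s["g1", "g3"], 1)
  expect_equal(a_s["g1", "g4"], 0)
  expect_equal(a_u["g1", "g4"], 1)
  expect_equal(a_s["g1", "g2"], 0.75^6, tolerance = 1e-12)
  expect_equal(a_s["g1", "g2"], 0.1780, tolerance = 1e-3)
  expect_error(adjacency(rbind(e, g5 = rep(2, 4)), 6), "g5",
               class = "sc_zero_variance")
  expect_error(adjacency(e[, 1:3], 6), class = "sc_bad_input")
})

test_that("soft power selection honors target and fallback contracts", {
  set.seed(201)
  sim <- simulate_counts(sim_config(n_genes = 600, n_modules = 6,
                                    module_size = 50, seed = 201))
  e <- log_cpm(sim$A)
  fit <- pick_soft_power(e, powers = c(4, 6, 9, 12, 16))
  expect_true(fit$beta %in% c(4, 6, 9, 12, 16))
  expect_true(fit$reached_target)
  expect_gte(fit$fit$r2[fit$fit$power == fit$beta], 0.8)
  # unattainable target falls back to the argmax with a warning
  expect_warning(fb <- pick_soft_power(e, powers = c(1, 2), r2_target = 0.999),
                 "best fit")
  expect_false(fb$reached_target)
  expect_true(fb$beta %in% c(1, 2))
})

test_that("TOM reproduces the closed-form small cases", {
  # isolated pair: TOM12 = a
  for (a in c(0.2, 0.5, 0.9)) {
    net <- stressconcord:::new_gene_network(
      matrix(c(1, a, a, 1), 2, dimnames = list(c("x", "y"), c("x", "y"))),
      kind = "adjacency", beta = 1, signed = TRUE)
    expect_equal(tom(net)["x", "y"], a, tolerance = 1e-12)
  }
  # complete graph of ones
  ones <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  net1 <- stressconcord:::new_gene_network(ones, kind = "adjacency",
                                           beta = 1, signed = TRUE)
  expect_true(all(abs(tom(net1) - 1) < 1e-12))
})

test_that("TOM equals the double-loop oracle on random networks", {
  set.seed(202)
  for (n in c(6, 8, 10)) {
    a <- random_adjacency(n)
    expect_equal(unclass(tom(a)), oracle_tom(unclass(a)),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
  expect_error(tom(matrix(0.5, 3, 3)), class = "sc_bad_input")
})

test_that("consensus TOM is idempotent, bounded, and calibration-exact", {
  set.seed(203)
  tA <- tom(random_adjacency(8))
  expect_equal(unclass(consensus_tom(tA, tA)), unclass(tA),
               ignore_attr = TRUE, tolerance = 1e-12)
  tB <- tom(random_adjacency(8))
  cons <- consensus_tom(tA, tB)
  scale <- attr(cons, "calibration")
  off <- upper.tri(cons)
  expect_true(all(cons[off] <= pmin(unclass(tA), pmin(unclass(tB) * scale, 1))[off] + 1e-12))
  # tomB = 2 * tomA rescales back to tomA
  t2 <- unclass(tA) * 2
  diag(t2) <- 1
  tB2 <- stressconcord:::new_gene_network(t2, kind = "tom", beta = 1, signed = TRUE)
  cons2 <- consensus_tom(tA, tB2)
  expect_equal(cons2[off], unclass(tA)[off], tolerance = 1e-12)
  bad <- tB
  rownames(bad) <- colnames(bad) <- paste0("x", 1:8)
  expect_error(consensus_tom(tA, bad), class = "sc_gene_mismatch")
})

block_dissim <- function() {
  d <- matrix(0.9, 6, 6)
  d[1:3, 1:3] <- 0.1
  d[4:6, 4:6] <- 0.1
  diag(d) <- 0
  dimnames(d) <- list(letters[1:6], letters[1:6])
  d
}

test_that("branch cutting recovers planted blocks and filters small ones", {
  part <- cut_modules(block_dissim(), min_size = 3)
  expect_equal(sort(unique(part$membership$module)), c(1L, 2L))
  expect_equal(length(unique(part$membership$module[1:3])), 1L)
  expect_equal(length(unique(part$membership$module[4:6])), 1L)
  # min_size above the block size: everything is background
  part4 <- cut_modules(block_dissim(), min_size = 4)
  expect_true(all(part4$membership$module == 0L))
  # all-equal dissimilarity above the cut: all background
  flat <- matrix(0.9, 6, 6); diag(flat) <- 0
  dimnames(flat) <- list(letters[1:6], letters[1:6])
  pf <- cut_modules(flat, min_size = 2, cut_height = 0.5)
  expect_true(all(pf$membership$module == 0L))
  expect_error(cut_modules(block_dissim(), min_size = 1),
               class = "sc_bad_input")
})

test_that("eigengenes and kME satisfy their PCA contracts", {
  set.seed(204)
  base <- rnorm(10)
  e <- rbind(g1 = base, g2 = base, g3 = base,         # identical module
             g4 = rnorm(10), g5 = rnorm(10))
  labels <- setNames(c(1L, 1L, 1L, 2L, 2L), rownames(e))
  me <- eigengenes(e, labels)
  expect_equal(sum(me[, "ME1"]^2), 1, tolerance = 1e-12)  # unit norm
  km <- kme(e, me)
  expect_equal(unname(km[c("g1", "g2", "g3"), "ME1"]), rep(1, 3),
               tolerance = 1e-12)
  # a gene equal to the negated eigengene profile has kME -1
  e2 <- rbind(e, g6 = -me[, "ME1"])
  km2 <- kme(e2, me)
  expect_equal(unname(km2["g6", "ME1"]), -1, tolerance = 1e-12)
  # PC1 explains at least an average gene's share of variance
  sub <- t(scale(t(e[1:3, ] + matrix(rnorm(30, sd = 0.3), 3))))
  sv <- svd(sub)
  expect_gte(sv$d[1]^2 / sum(sv$d^2), 1 / 3)
  expect_error(eigengenes(e, setNames(c(1L, 2L, 2L, 0L, 0L), rownames(e))),
               class = "sc_bad_input")
})

test_that("eigengene merging rejoins artificially split modules", {
  sim <- simulate_counts(sim_config(n_genes = 400, n_modules = 4,
                                    module_size = 40, seed = 205))
  eA <- log_cpm(sim$A); eB <- log_cpm(sim$B)
  truth <- sim$truth$module_of_gene
  labels <- unname(truth)
  # split module 1 into two halves labelled 1 and 5
  idx <- which(labels == 1)
  labels[idx[1:20]] <- 5L
  part <- structure(list(
    membership = tibble::tibble(gene = names(truth), module = labels),
    dendrogram = NULL, cut_height = NA, min_size = 20),
    class = "module_partition")
  merged <- merge_close_modules(part, list(eA, eB), merge_height = 0.25)
  n_before <- length(setdiff(unique(labels), 0L))
  n_after <- length(setdiff(unique(merged$membership$module), 0L))
  expect_equal(n_after, n_before - 1L)
  lab2 <- setNames(merged$membership$module, merged$membership$gene)
  expect_equal(length(unique(lab2[names(truth)[truth == 1]])), 1L)
  # merge_height 0 leaves the partition unchanged
  same <- merge_close_modules(part, list(eA, eB), merge_height = 0)
  expect_identical(same$membership, part$membership)
})

test_that("module detection is invariant to gene-order permutation", {
  sim <- simulate_counts(sim_config(n_genes = 400, n_modules = 4,
                                    module_size = 40, seed = 206))
  eA <- log_cpm(sim$A); eB <- log_cpm(sim$B)
  p1 <- consensus_modules(eA, eB, beta = 12)
  set.seed(1); perm <- sample(nrow(eA))
  p2 <- consensus_modules(eA[perm, ], eB[perm, ], beta = 12)
  l1 <- setNames(p1$membership$module, p1$membership$gene)
  l2 <- setNames(p2$membership$module, p2$membership$gene)[names(l1)]
  tab <- table(l1, l2)
  # identical partition up to label names: one nonzero cell per row/col
  expect_true(all(rowSums(tab > 0) == 1))
  expect_true(all(colSums(tab > 0) == 1))
})
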