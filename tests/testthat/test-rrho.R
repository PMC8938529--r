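test_that("hypergeometric overlap p matches exhaustive enumeration", {
  expect_equal(hypergeom_overlap_p(3, 5, 5, 20), 1126 / 15504,
               tolerance = 1e-12)
  expect_equal(hypergeom_overlap_p(3, 5, 5, 20),
               oracle_hyper_tail(3, 5, 5, 20), tolerance = 1e-12)
  expect_equal(hypergeom_overlap_p(0, 5, 5, 20), 1)
  expect_equal(hypergeom_overlap_p(7, 7, 7, 7), 1)
  expect_error(hypergeom_overlap_p(6, 5, 5, 20), class = "sc_bad_input")
  expect_error(hypergeom_overlap_p(1, 25, 5, 20), class = "sc_bad_input")
})

test_that("every map cell equals brute-force set intersection at step 1", {
  set.seed(101)
  N <- 30
  genes <- sprintf("g%02d", 1:N)
  s1 <- setNames(rnorm(N), genes)
  s2 <- setNames(rnorm(N), genes)
  l1 <- make_ranked(s1); l2 <- make_ranked(s2)
  map <- rrho_map(l1, l2, step = 1)
  n1p <- attr(l1, "n_pos"); n2p <- attr(l2, "n_pos")
  regions1 <- list(U = l1$gene[seq_len(n1p)], D = rev(l1$gene)[seq_len(N - n1p)])
  regions2 <- list(U = l2$gene[seq_len(n2p)], D = rev(l2$gene)[seq_len(N - n2p)])
  for (quad in c("UU", "DD", "UD", "DU")) {
    q <- map$quadrants[[quad]]
    r1 <- regions1[[substr(quad, 1, 1)]]
    r2 <- regions2[[substr(quad, 2, 2)]]
    for (ii in seq_along(q$i)) for (jj in seq_along(q$j)) {
      top_i <- r1[seq_len(q$i[ii])]
      top_j <- r2[seq_len(q$j[jj])]
      k <- length(intersect(top_i, top_j))
      expect_identical(q$k[ii, jj], k)
      expect_equal(10^(-q$neg_log10_p[ii, jj]),
                   oracle_hyper_tail(k, q$i[ii], q$j[jj], N),
                   tolerance = 1e-12)
    }
  }
})

test_that("identical lists peak above randomly permuted ones", {
  set.seed(102)
  genes <- sprintf("g%03d", 1:200)
  sc <- setNames(rnorm(200), genes)
  l1 <- make_ranked(sc)
  self_peak <- max(rrho_map(l1, l1, step = 3)$quadrants$UU$neg_log10_p)
  for (r in 1:20) {
    perm <- make_ranked(setNames(sample(sc), genes))
    qq <- rrho_map(l1, perm, step = 3)$quadrants$UU
    expect_gte(self_peak, max(qq$neg_log10_p))
  }
})

test_that("a list with no positive scores leaves UU and UD empty but valid", {
  genes <- sprintf("g%02d", 1:20)
  l1 <- make_ranked(setNames(-seq(0.1, 2, length.out = 20), genes))
  l2 <- make_ranked(setNames(rnorm(20, sd = 2), genes))
  map <- rrho_map(l1, l2, step = 1)
  expect_true(map$quadrants$UU$empty)
  expect_true(map$quadrants$UD$empty)
  expect_false(map$quadrants$DD$empty)
  pk <- quadrant_peaks(map)
  expect_false(pk$present[pk$quadrant == "UU"])
  expect_true(pk$present[pk$quadrant == "DD"])
})

test_that("transposing the comparison swaps the discordant quadrants", {
  set.seed(103)
  genes <- sprintf("g%02d", 1:40)
  l1 <- make_ranked(setNames(rnorm(40), genes))
  l2 <- make_ranked(setNames(rnorm(40), genes))
  m12 <- rrho_map(l1, l2, step = 1)
  m21 <- rrho_map(l2, l1, step = 1)
  expect_equal(m12$quadrants$UU$neg_log10_p,
               t(m21$quadrants$UU$neg_log10_p))
  expect_equal(m12$quadrants$DD$neg_log10_p,
               t(m21$quadrants$DD$neg_log10_p))
  expect_equal(m12$quadrants$UD$neg_log10_p,
               t(m21$quadrants$DU$neg_log10_p))
})

test_that("nested top lists make full overlap the row minimum p", {
  # list2 shares list1's top-i exactly: overlap k = i has minimal p in row
  genes <- sprintf("g%02d", 1:30)
  sc1 <- setNames(seq(3, -3, length.out = 30), genes)
  sc2 <- sc1 + c(rep(0, 10), rnorm(20, sd = 0.1))
  l1 <- make_ranked(sc1); l2 <- make_ranked(sc2)
  map <- rrho_map(l1, l2, step = 1)
  q <- map$quadrants$UU
  i <- which(q$i == 10)
  expect_identical(q$k[i, which(q$j == 10)], 10L)
  expect_equal(max(q$neg_log10_p[i, ]), q$neg_log10_p[i, which(q$j == 10)])
})

test_that("mismatched backgrounds error with the set difference", {
  l1 <- make_ranked(c(a = 1, b = -1, c = 2))
  l2 <- make_ranked(c(a = 1, b = -1, d = 2))
  expect_error(rrho_map(l1, l2), "d", class = "sc_background_mismatch")
})

test_that("peak selection breaks ties toward the smallest thresholds", {
  # two cells tied at the maximum: take smallest i, then smallest j
  fake <- structure(list(
    quadrants = list(UU = list(
      i = c(2L, 4L), j = c(2L, 4L),
      k = matrix(c(2L, 2L, 2L, 2L), 2),
      neg_log10_p = matrix(c(3, 3, 1, 0.5), 2), empty = FALSE)),
    N = 8, step = 2, n1_pos = 4, n2_pos = 4,
    list1 = make_ranked(setNames(c(4:1, -(1:4)) / 10, letters[1:8])),
    list2 = make_ranked(setNames(c(4:1, -(1:4)) / 10, letters[1:8]))),
    class = "rrho_map")
  pk <- quadrant_peaks(fake)
  expect_equal(pk$i, 2L)
  expect_equal(pk$j, 2L)
})

test_that("peak gene sets contain only genes from the matching strata", {
  set.seed(104)
  genes <- sprintf("g%02d", 1:50)
  l1 <- make_ranked(setNames(rnorm(50), genes))
  l2 <- make_ranked(setNames(rnorm(50), genes))
  pk <- quadrant_peaks(rrho_map(l1, l2, step = 2))
  up1 <- l1$gene[l1$score > 0]; up2 <- l2$gene[l2$score > 0]
  uu <- pk$genes[[which(pk$quadrant == "UU")]]
  dd <- pk$genes[[which(pk$quadrant == "DD")]]
  expect_true(all(uu %in% intersect(up1, up2)))
  expect_true(all(dd %in% intersect(setdiff(genes, up1), setdiff(genes, up2))))
})

test_that("Venn decomposition matches hand enumeration", {
  out <- intersect_peak_sets(list(A = c("a", "b", "c"), B = c("b", "c", "d")))
  expect_equal(out$n[out$region == "A&B"], 2L)
  expect_identical(out$genes[[which(out$region == "A&B")]], c("b", "c"))
  # four identical sets collapse into the all-shared region
  s <- letters[1:5]
  out4 <- intersect_peak_sets(list(w = s, x = s, y = s, z = s))
  expect_equal(nrow(out4), 1L)
  expect_equal(out4$n, 5L)
  # constructed 3-set instance with known pairwise structure
  bg <- sprintf("g%02d", 1:30)
  A <- bg[1:10]; B <- bg[6:15]; C <- bg[c(1:3, 11:13, 16:19)]
  out3 <- intersect_peak_sets(list(A = A, B = B, C = C))
  count <- function(region) {
    n <- out3$n[out3$region == region]
    if (length(n)) n else 0L
  }
  expect_equal(count("A&B"), 5L)        # 6..10
  expect_equal(count("A&C"), 3L)        # 1,2,3
  expect_equal(count("B&C"), 3L)        # 11,12,13
  expect_equal(count("A&B&C"), 0L)
  expect_equal(count("A"), 2L)          # 4,5
  expect_equal(count("B"), 2L)          # 14,15
  expect_equal(count("C"), 4L)          # 16..19
  expect_equal(sum(out3$n), length(unique(c(A, B, C))))
})

test_that("UU peak genes recover strong planted concordance", {
  cfg <- sim_config(seed = 1, de_log2fc = 1.5)
  sim <- simulate_counts(cfg)
  meta <- sim$A$samples; metb <- sim$B$samples
  de_a <- moderated_t(log_cpm(sim$A),
                      meta$sample[meta$group == "WT_VEH"],
                      meta$sample[meta$group == "WT_CORT"], contrast = "A")
  de_b <- moderated_t(log_cpm(sim$B),
                      metb$sample[metb$group == "SH_RES"],
                      metb$sample[metb$group == "SH_SUS"], contrast = "B")
  map <- rrho_map(signed_rank_score(de_b), signed_rank_score(de_a))
  pk <- quadrant_peaks(map)
  uu <- pk$genes[[which(pk$quadrant == "UU")]]
  tr_b <- sim$truth$de_genes_per_contrast$SH_RES_vs_SH_SUS
  tr_a <- sim$truth$de_genes_per_contrast$WT_VEH_vs_WT_CORT
  planted <- intersect(tr_b$gene[tr_b$sign > 0], tr_a$gene[tr_a$sign > 0])
  jac <- length(intersect(uu, planted)) / length(union(uu, planted))
  expect_gte(jac, 0.5)
})
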