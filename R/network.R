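#' Soft-threshold co-expression adjacency
#'
#' Pearson-correlation adjacency raised to a soft power. Signed
#' networks map correlation to `((1 + cor)/2)^beta`, so perfectly
#' anti-correlated genes get adjacency 0; unsigned networks use
#' `|cor|^beta`.
#'
#' @param expr numeric matrix, genes x samples, >= 4 samples.
#' @param beta soft power >= 1.
#' @param signed signed network (default TRUE).
#' @return A `gene_network`: the gene x gene adjacency matrix with
#'   attributes `kind = "adjacency"`, `beta`, `signed`.
#' @export
adjacency <- function(expr, beta = 6, signed = TRUE) {
  stopifnot(is.matrix(expr), is.numeric(expr))
  if (ncol(expr) < 4) abort_sc("need at least 4 samples", "sc_bad_input")
  if (beta < 1) abort_sc("beta must be >= 1", "sc_bad_input")
  v <- apply(expr, 1, stats::var)
  if (any(v == 0)) {
    abort_sc(paste0("zero-variance gene(s): ",
                    paste(utils::head(rownames(expr)[v == 0], 5),
                          collapse = ", ")),
             "sc_zero_variance")
  }
  cc <- stats::cor(t(expr))
  a <- if (signed) ((1 + cc) / 2)^beta else abs(cc)^beta
  new_gene_network(a, kind = "adjacency", beta = beta, signed = signed)
}

new_gene_network <- function(m, kind, beta = NA_real_, signed = NA) {
  structure(m, kind = kind, beta = beta, signed = signed,
            class = c("gene_network", "matrix", "array"))
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("<gene_network> %s, %d genes, beta = %s, %s\n",
              attr(x, "kind"), nrow(x), format(attr(x, "beta")),
              if (isTRUE(attr(x, "signed"))) "signed" else "unsigned"))
  invisible(x)
}

#' Choose the soft power by the scale-free topology criterion
#'
#' For each candidate power, computes the connectivity distribution
#' (`k_i` = row sums of adjacency minus the self term), bins it, and
#' regresses log10 bin frequency on log10 mean bin connectivity. The
#' scale-free fit index is the regression R-squared, counted only when
#' the slope is negative. The smallest candidate reaching `r2_target`
#' is chosen; if none reaches it, the candidate with maximal fit is
#' returned with `reached_target = FALSE` and a warning.
#'
#' @param expr genes x samples matrix.
#' @param powers candidate powers (default 1:20).
#' @param r2_target scale-free fit target (default 0.8).
#' @param signed signed network (default TRUE).
#' @param n_bins connectivity histogram bins (default 10).
#' @return A `soft_power_fit`: list with `beta`, `reached_target`, and
#'   `fit`, a tibble (`power`, `r2`, `slope`, `mean_k`).
#' @export
pick_soft_power <- function(expr, powers = 1:20, r2_target = 0.8,
                            signed = TRUE, n_bins = 10) {
  if (!length(powers)) abort_sc("no candidate powers", "sc_bad_input")
  cc <- stats::cor(t(expr))
  base <- if (signed) (1 + cc) / 2 else abs(cc)
  fit <- purrr::map_dfr(powers, function(b) {
    a <- base^b
    k <- rowSums(a) - diag(a)
    sf <- scale_free_fit(k, n_bins)
    tibble::tibble(power = b, r2 = sf$r2, slope = sf$slope, mean_k = mean(k))
  })
  ok <- which(fit$r2 >= r2_target)
  if (length(ok)) {
    list(beta = fit$power[ok[1]], reached_target = TRUE, fit = fit) |>
      structure(class = "soft_power_fit")
  } else {
    warning("no candidate power reached the scale-free R2 target; ",
            "returning the best fit", call. = FALSE)
    structure(list(beta = fit$power[which.max(fit$r2)],
                   reached_target = FALSE, fit = fit),
              class = "soft_power_fit")
  }
}

scale_free_fit <- function(k, n_bins) {
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks, include.lowest = TRUE)
  freq <- tabulate(bin, nbins = n_bins)
  kmid <- tapply(k, bin, mean)
  occ <- which(freq > 0 & !is.na(kmid) & kmid > 0)
  if (length(occ) < 2) {
    abort_sc("fewer than 2 occupied connectivity bins", "sc_degenerate_fit")
  }
  lm_fit <- stats::lm(log10(freq[occ]) ~ log10(as.numeric(kmid[occ])))
  slope <- stats::coef(lm_fit)[2]
  r2 <- summary(lm_fit)$r.squared
  list(r2 = if (is.finite(slope) && slope < 0) r2 else 0, slope = unname(slope))
}

#' Topological overlap matrix
#'
#' Smooths an adjacency by shared-neighbor structure:
#' \deqn{TOM_{ij} = \frac{\sum_{u \ne i,j} a_{iu} a_{uj} + a_{ij}}
#'   {\min(k_i, k_j) + 1 - a_{ij}}, \qquad TOM_{ii} = 1,}
#' with connectivity \eqn{k_i = \sum_{j \ne i} a_{ij}}.
#'
#' @param net a `gene_network` of kind `"adjacency"` (symmetric, values
#'   in `[0, 1]`, unit diagonal).
#' @return A `gene_network` of kind `"tom"`.
#' @export
tom <- function(net) {
  if (!identical(attr(net, "kind"), "adjacency")) {
    abort_sc("tom() expects an adjacency network", "sc_bad_input")
  }
  a <- unclass(net)
  attributes(a)[c("kind", "beta", "signed")] <- NULL
  if (!isSymmetric(a, tol = 1e-10)) {
    abort_sc("adjacency must be symmetric", "sc_bad_input")
  }
  k <- rowSums(a) - diag(a)
  # sum_{u != i,j} a_iu a_uj = (A^2)_ij - a_ii a_ij - a_ij a_jj
  num <- a %*% a - outer(diag(a), rep(1, ncol(a))) * a -
    a * outer(rep(1, nrow(a)), diag(a)) + a
  den <- outer(k, k, pmin) + 1 - a
  t_mat <- num / den
  diag(t_mat) <- 1
  t_mat <- pmin(pmax((t_mat + t(t_mat)) / 2, 0), 1)
  dimnames(t_mat) <- dimnames(a)
  new_gene_network(t_mat, kind = "tom", beta = attr(net, "beta"),
                   signed = attr(net, "signed"))
}

#' Consensus topological overlap of two datasets
#'
#' Calibrates the second TOM so that its reference quantile (of
#' off-diagonal values) matches the first's, then takes the element-wise
#' minimum, clipped to `[0, 1]`. The minimum keeps only co-expression
#' supported in both experiments, which is what makes the resulting
#' modules consensus modules.
#'
#' @param tomA,tomB `gene_network` TOMs over identical gene sets.
#' @param calib_quantile quantile used for calibration (default 0.95).
#' @return A `gene_network` of kind `"tom"` with attribute
#'   `calibration` (the scale factor applied to `tomB`).
#' @export
consensus_tom <- function(tomA, tomB, calib_quantile = 0.95) {
  if (!identical(rownames(tomA), rownames(tomB))) {
    abort_sc("consensus requires identical gene sets in the same order",
             "sc_gene_mismatch")
  }
  a <- unclass(tomA); b <- unclass(tomB)
  ut <- upper.tri(a)
  qa <- stats::quantile(a[ut], calib_quantile, names = FALSE)
  qb <- stats::quantile(b[ut], calib_quantile, names = FALSE)
  scale <- if (qb > 0) qa / qb else 1
  b_cal <- pmin(pmax(b * scale, 0), 1)
  cons <- pmin(a, b_cal)
  diag(cons) <- 1
  out <- new_gene_network(cons, kind = "tom", beta = attr(tomA, "beta"),
                          signed = attr(tomA, "signed"))
  attr(out, "calibration") <- scale
  out
}

#' Cut a TOM dendrogram into modules
#'
#' Average-linkage hierarchical clustering of `1 - TOM`, followed by a
#' static branch cut at `cut_height`, one top-down refinement pass
#' (a retained branch is split when its two sub-branches each reach
#' `min_size` and their join height exceeds `0.9 * cut_height`), and a
#' size filter assigning branches smaller than `min_size` to the
#' background label 0. Module labels are ordered by decreasing size.
#'
#' @param dissim symmetric dissimilarity matrix with zero diagonal
#'   (typically `1 - TOM`).
#' @param min_size minimum module size, >= 2 (default 30).
#' @param cut_height static cut height; default spans 0.995 of the
#'   dendrogram height range above its minimum.
#' @return A `module_partition`: list with `membership` (tibble: `gene`,
#'   `module`), `dendrogram` (the hclust object), `cut_height`,
#'   `min_size`.
#' @export
cut_modules <- function(dissim, min_size = 30, cut_height = NULL) {
  if (inherits(dissim, "gene_network")) dissim <- unclass(dissim)
  stopifnot(is.matrix(dissim))
  if (min_size < 2) abort_sc("min_size must be >= 2", "sc_bad_input")
  if (!isSymmetric(unname(dissim), tol = 1e-10) || any(abs(diag(dissim)) > 1e-12)) {
    abort_sc("dissimilarity must be symmetric with zero diagonal",
             "sc_bad_input")
  }
  genes <- rownames(dissim) %||% sprintf("gene%d", seq_len(nrow(dissim)))
  hc <- stats::hclust(stats::as.dist(dissim), method = "average")
  h_rng <- range(hc$height)
  cut_height <- cut_height %||% (h_rng[1] + 0.995 * diff(h_rng))

  labels <- unname(stats::cutree(hc, h = cut_height))
  labels <- refine_branches(hc, labels, min_size, 0.9 * cut_height)

  sizes <- table(labels)
  keep <- names(sizes)[sizes >= min_size]
  labels[!labels %in% as.integer(keep)] <- 0L
  labels <- relabel_by_size(labels)

  structure(list(
    membership = tibble::tibble(gene = genes, module = labels),
    dendrogram = hc, cut_height = cut_height, min_size = min_size
  ), class = "module_partition")
}

# one top-down pass: split clusters whose root join is high and whose
# two children are both large enough
refine_branches <- function(hc, labels, min_size, split_height) {
  n <- length(labels)
  merge <- hc$merge
  # leaves under each internal node
  node_leaves <- vector("list", nrow(merge))
  for (m in seq_len(nrow(merge))) {
    node_leaves[[m]] <- unlist(lapply(merge[m, ], function(ch)
      if (ch < 0) -ch else node_leaves[[ch]]))
  }
  out <- labels
  next_label <- max(labels) + 1L
  for (cl in unique(labels)) {
    members <- which(labels == cl)
    if (length(members) < 2 * min_size) next
    inside <- vapply(node_leaves, function(lv) all(lv %in% members), logical(1))
    root <- which(inside & vapply(node_leaves, length, 1L) == length(members))
    if (!length(root)) next
    root <- root[which.max(hc$height[root])]
    if (hc$height[root] <= split_height) next
    kids <- merge[root, ]
    kid_sets <- lapply(kids, function(ch) if (ch < 0) -ch else node_leaves[[ch]])
    if (all(lengths(kid_sets) >= min_size)) {
      out[kid_sets[[2]]] <- next_label
      next_label <- next_label + 1L
    }
  }
  out
}

relabel_by_size <- function(labels) {
  mods <- setdiff(unique(labels), 0L)
  if (!length(mods)) return(labels)
  sizes <- vapply(mods, function(m) sum(labels == m), integer(1))
  ord <- mods[order(-sizes, mods)]
  new <- labels
  for (i in seq_along(ord)) new[labels == ord[i]] <- i
  new
}

#' @export
print.module_partition <- function(x, ...) {
  tab <- table(x$membership$module)
  k <- sum(names(tab) != "0")
  cat(sprintf("<module_partition> %d modules over %d genes (%d background)\n",
              k, nrow(x$membership),
              if ("0" %in% names(tab)) tab[["0"]] else 0L))
  invisible(x)
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' standardized (per-gene z-scored) expression submatrix, scaled to
#' unit norm over samples and sign-oriented to correlate positively
#' with the module's mean expression profile.
#'
#' @param expr genes x samples matrix.
#' @param partition a `module_partition` (background 0 is skipped) or a
#'   named integer vector of module labels.
#' @return A samples x modules numeric matrix, columns named `ME<k>`.
#' @export
eigengenes <- function(expr, partition) {
  labels <- partition_labels(partition, rownames(expr))
  mods <- sort(setdiff(unique(labels), 0L))
  if (!length(mods)) abort_sc("no modules in partition", "sc_bad_input")
  me <- vapply(mods, function(m) {
    sub <- expr[labels == m, , drop = FALSE]
    if (nrow(sub) < 2) {
      abort_sc(sprintf("module %d has fewer than 2 genes", m), "sc_bad_input")
    }
    z <- t(scale(t(sub)))
    sv <- svd(z, nu = 0, nv = 1)
    e <- sv$v[, 1]
    if (stats::cor(e, colMeans(z)) < 0) e <- -e
    e
  }, numeric(ncol(expr)))
  dimnames(me) <- list(colnames(expr), paste0("ME", mods))
  me
}

#' Module membership (kME)
#'
#' Pearson correlation of each gene's expression profile with each
#' module eigengene.
#'
#' @param expr genes x samples matrix.
#' @param me samples x modules eigengene matrix ([eigengenes()]).
#' @return A genes x modules matrix of correlations in `[-1, 1]`.
#' @export
kme <- function(expr, me) {
  stopifnot(ncol(expr) == nrow(me))
  stats::cor(t(expr), me)
}

partition_labels <- function(partition, genes) {
  if (inherits(partition, "module_partition")) {
    lab <- stats::setNames(partition$membership$module,
                           partition$membership$gene)
  } else if (!is.null(names(partition))) {
    lab <- partition
  } else {
    abort_sc("partition must be a module_partition or named labels",
             "sc_bad_input")
  }
  if (!is.null(genes)) {
    miss <- setdiff(genes, names(lab))
    if (length(miss)) abort_sc("genes missing from partition", "sc_bad_input")
    lab <- lab[genes]
  }
  stats::setNames(as.integer(lab), names(lab))
}

#' Merge modules with close eigengenes
#'
#' Repeatedly merges the pair of modules whose consensus eigengene
#' dissimilarity - the maximum over datasets of `1 - cor(ME_a, ME_b)` -
#' is smallest, while it is below `merge_height`, then relabels by
#' decreasing size. With two datasets this only merges modules whose
#' eigengenes agree in *both* experiments.
#'
#' @param partition a `module_partition`.
#' @param expr_list list of genes x samples matrices (one per dataset,
#'   same genes).
#' @param merge_height eigengene dissimilarity threshold (default
#'   0.25); 0 leaves the partition unchanged.
#' @return The merged `module_partition`.
#' @export
merge_close_modules <- function(partition, expr_list, merge_height = 0.25) {
  stopifnot(inherits(partition, "module_partition"))
  if (merge_height <= 0) return(partition)
  labels <- stats::setNames(partition$membership$module,
                            partition$membership$gene)
  repeat {
    mods <- sort(setdiff(unique(labels), 0L))
    if (length(mods) < 2) break
    diss <- matrix(Inf, length(mods), length(mods))
    for (expr in expr_list) {
      me <- eigengenes(expr, labels)
      d <- 1 - stats::cor(me)
      diss <- ifelse(is.finite(diss), pmax(diss, d), d)
    }
    diag(diss) <- Inf
    best <- which(diss == min(diss), arr.ind = TRUE)[1, ]
    if (diss[best[1], best[2]] >= merge_height) break
    a <- mods[min(best)]; b <- mods[max(best)]
    labels[labels == b] <- a
  }
  labels <- relabel_by_size(unname(labels))
  partition$membership$module <- labels
  partition
}

#' Consensus co-expression modules across two experiments
#'
#' One-call orchestration of the consensus network stage: per-dataset
#' soft-threshold adjacency and TOM, quantile-calibrated consensus TOM,
#' average-linkage clustering with branch cutting and size filtering,
#' eigengene merging, and per-dataset eigengenes and kME (plus their
#' mean, the consensus kME used for hub ranking). Genes with zero
#' variance in either dataset are removed first and reported via a
#' message.
#'
#' @param exprA,exprB genes x samples matrices over the same genes.
#' @param beta soft power, or `NULL` to choose by [pick_soft_power()]
#'   on dataset A.
#' @param signed signed network (default TRUE).
#' @param min_size,cut_height,merge_height see [cut_modules()] and
#'   [merge_close_modules()].
#' @param calib_quantile see [consensus_tom()].
#' @return A `module_partition` with added elements: `beta`,
#'   `consensus_tom`, `eigengenes` (list A/B), `kme` (list A/B/mean),
#'   `removed_genes`.
#' @export
consensus_modules <- function(exprA, exprB, beta = NULL, signed = TRUE,
                              min_size = 30, cut_height = NULL,
                              merge_height = 0.25, calib_quantile = 0.95) {
  stopifnot(identical(rownames(exprA), rownames(exprB)))
  vA <- apply(exprA, 1, stats::var)
  vB <- apply(exprB, 1, stats::var)
  drop <- vA == 0 | vB == 0
  if (any(drop)) {
    message(sum(drop), " zero-variance gene(s) removed before network construction")
    exprA <- exprA[!drop, , drop = FALSE]
    exprB <- exprB[!drop, , drop = FALSE]
  }
  if (is.null(beta)) beta <- pick_soft_power(exprA, signed = signed)$beta
  tomA <- tom(adjacency(exprA, beta, signed))
  tomB <- tom(adjacency(exprB, beta, signed))
  cons <- consensus_tom(tomA, tomB, calib_quantile)
  diss <- 1 - unclass(cons)
  diag(diss) <- 0
  part <- cut_modules(diss, min_size = min_size, cut_height = cut_height)
  part <- merge_close_modules(part, list(A = exprA, B = exprB), merge_height)
  meA <- eigengenes(exprA, part)
  meB <- eigengenes(exprB, part)
  kA <- kme(exprA, meA)
  kB <- kme(exprB, meB)
  part$beta <- beta
  part$consensus_tom <- cons
  part$eigengenes <- list(A = meA, B = meB)
  part$kme <- list(A = kA, B = kB, mean = (kA + kB) / 2)
  part$removed_genes <- rownames(exprA)[integer(0)]
  if (any(drop)) part$removed_genes <- names(drop)[drop]
  part
}
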