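#' Log counts-per-million transformation
#'
#' Converts raw counts to log2 counts per million with a prior count to
#' damp the variance of low counts:
#' `log2((count + prior) / (libsize + 2 * prior) * 1e6)`.
#' Library sizes are the column sums of `counts`.
#'
#' @param counts non-negative integer matrix, genes x samples (or a
#'   `count_matrix`).
#' @param prior_count positive pseudo-count (default 0.5).
#' @return A numeric matrix of the same shape.
#' @export
#' @examples
#' m <- matrix(c(0L, 100L, 50L, 10L), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' log_cpm(m)
log_cpm <- function(counts, prior_count = 0.5) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  check_count_matrix(counts)
  if (prior_count <= 0) abort_sc("prior_count must be positive", "sc_bad_input")
  lib <- colSums(counts)
  if (any(lib == 0)) {
    abort_sc(paste0("zero library size in sample(s): ",
                    paste(colnames(counts)[lib == 0], collapse = ", ")),
             "sc_zero_library")
  }
  log2(sweep(counts + prior_count, 2, lib + 2 * prior_count, "/") * 1e6)
}

#' Empirical-Bayes moderated two-group t-statistics
#'
#' Fits a two-group comparison per gene on a log-expression matrix with
#' variance moderation: gene-wise pooled variances \eqn{s_g^2} (residual
#' df \eqn{d_g = n_1 + n_2 - 2}) are shrunk towards a prior variance
#' \eqn{s_0^2} with prior df \eqn{d_0},
#' \deqn{\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},\qquad
#'   t_g = \frac{\Delta_g}{\tilde s_g \sqrt{1/n_1 + 1/n_2}},}
#' with two-sided p-values on \eqn{d_0 + d_g} df. The prior
#' \eqn{(d_0, s_0^2)} is estimated by method of moments on
#' \eqn{\log s_g^2}, using the moments of the log scaled-F
#' distribution: the observed variance of \eqn{\log s_g^2} in excess of
#' \eqn{\psi'(d_g/2)} determines \eqn{d_0} through
#' \eqn{\psi'(d_0/2)}, and the mean determines \eqn{s_0^2}. With
#' `d0 = 0` the ordinary pooled two-sample t is recovered; with
#' `d0 = Inf` every gene shares the variance \eqn{s_0^2}.
#'
#' The log2 fold change is `mean(group2) - mean(group1)`; `group1` is
#' the reference.
#'
#' @param logexpr numeric matrix, genes x samples (e.g. [log_cpm()]
#'   output).
#' @param group1,group2 column indices or names of the two groups, each
#'   of size >= 2.
#' @param weights optional positive precision-weight matrix of the same
#'   shape; group means and variances become weighted (off by default).
#' @param d0 optional override of the prior df (0, finite, or `Inf`);
#'   `NULL` (default) estimates it from the data.
#' @param contrast label stored with the result.
#' @return A `de_result`: list with `table` (tibble: `gene`, `log2_fc`,
#'   `t_mod`, `p`, `signed_score`, `constant`), `df_residual`, `d0`,
#'   `s0_2`, `contrast`. `signed_score = -log10(p) * sign(log2_fc)`.
#' @export
moderated_t <- function(logexpr, group1, group2, weights = NULL, d0 = NULL,
                        contrast = "group1_vs_group2") {
  stopifnot(is.matrix(logexpr), is.numeric(logexpr))
  i1 <- resolve_samples(logexpr, group1)
  i2 <- resolve_samples(logexpr, group2)
  n1 <- length(i1); n2 <- length(i2)
  if (n1 < 2 || n2 < 2) {
    abort_sc("each group needs at least 2 samples", "sc_small_group")
  }
  genes <- rownames(logexpr) %||% sprintf("gene%d", seq_len(nrow(logexpr)))

  if (is.null(weights)) {
    m1 <- rowMeans(logexpr[, i1, drop = FALSE])
    m2 <- rowMeans(logexpr[, i2, drop = FALSE])
    ss1 <- rowSums((logexpr[, i1, drop = FALSE] - m1)^2)
    ss2 <- rowSums((logexpr[, i2, drop = FALSE] - m2)^2)
    dg <- n1 + n2 - 2
    s2 <- (ss1 + ss2) / dg
    se_factor <- sqrt(1 / n1 + 1 / n2)
  } else {
    stopifnot(identical(dim(weights), dim(logexpr)), all(weights > 0))
    w1 <- weights[, i1, drop = FALSE]; w2 <- weights[, i2, drop = FALSE]
    m1 <- rowSums(w1 * logexpr[, i1, drop = FALSE]) / rowSums(w1)
    m2 <- rowSums(w2 * logexpr[, i2, drop = FALSE]) / rowSums(w2)
    ss1 <- rowSums(w1 * (logexpr[, i1, drop = FALSE] - m1)^2)
    ss2 <- rowSums(w2 * (logexpr[, i2, drop = FALSE] - m2)^2)
    dg <- n1 + n2 - 2
    s2 <- (ss1 + ss2) / dg
    se_factor <- sqrt(1 / rowSums(w1) + 1 / rowSums(w2))
  }

  lfc <- m2 - m1
  constant <- s2 <= 0 & lfc == 0

  prior <- if (is.null(d0)) {
    estimate_variance_prior(s2[!constant], dg)
  } else {
    list(d0 = d0, s0_2 = if (is.finite(d0) && d0 > 0)
      estimate_variance_prior(s2[!constant], dg)$s0_2
      else mean(s2[!constant]))
  }

  post_s2 <- if (is.infinite(prior$d0)) {
    rep(prior$s0_2, length(s2))
  } else if (prior$d0 == 0) {
    s2
  } else {
    (prior$d0 * prior$s0_2 + dg * s2) / (prior$d0 + dg)
  }
  df_total <- min(prior$d0 + dg, 1e6)

  t_mod <- lfc / (sqrt(post_s2) * se_factor)
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  t_mod[constant] <- 0
  p[constant] <- 1
  p[!is.finite(t_mod) & !constant] <- 0  # infinite t: zero variance, nonzero fc, d0 = 0
  p <- pmin(pmax(p, .Machine$double.xmin), 1)

  structure(list(
    table = tibble::tibble(
      gene = genes, log2_fc = unname(lfc), t_mod = unname(t_mod),
      p = unname(p), signed_score = unname(-log10(p) * sign(lfc)),
      constant = unname(constant)
    ),
    df_residual = dg, d0 = prior$d0, s0_2 = prior$s0_2,
    n1 = n1, n2 = n2, contrast = contrast
  ), class = "de_result")
}

resolve_samples <- function(m, idx) {
  if (is.character(idx)) {
    miss <- setdiff(idx, colnames(m))
    if (length(miss)) abort_sc(paste0("unknown samples: ",
                                      paste(miss, collapse = ", ")),
                               "sc_bad_input")
    match(idx, colnames(m))
  } else as.integer(idx)
}

# method-of-moments fit of the scaled-F prior on gene variances, on the
# log scale: log s2 ~ log s0_2 + log F(dg, d0)
estimate_variance_prior <- function(s2, dg) {
  s2 <- s2[is.finite(s2) & s2 > 0]
  if (length(s2) < 2) return(list(d0 = Inf, s0_2 = mean(s2)))
  z <- log(s2)
  e_mean <- digamma(dg / 2) - log(dg / 2)
  excess <- stats::var(z) - trigamma(dg / 2)
  if (excess <= 0) {
    d0 <- Inf
    s0_2 <- exp(mean(z) - e_mean)
  } else {
    d0 <- 2 * trigamma_inverse(excess)
    s0_2 <- exp(mean(z) - e_mean + digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s0_2 = s0_2)
}

# Newton iteration for trigamma^{-1}(x) on the log-d scale
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Call differentially expressed genes
#'
#' Applies the DEG rule: uncorrected `p < p_thresh` and natural-scale
#' fold change `> fc_thresh` in either direction (strict inequalities;
#' boundary genes are excluded).
#'
#' @param de a `de_result` from [moderated_t()].
#' @param p_thresh p-value cutoff in (0, 1); default 0.05.
#' @param fc_thresh fold-change cutoff > 1; default 1.3.
#' @return A `deg_set`: list with `contrast`, character vectors `up` and
#'   `down`, and the thresholds used.
#' @export
call_degs <- function(de, p_thresh = 0.05, fc_thresh = 1.3) {
  stopifnot(inherits(de, "de_result"))
  if (!is.numeric(p_thresh) || p_thresh <= 0 || p_thresh >= 1) {
    abort_sc("p_thresh must be in (0, 1)", "sc_bad_input")
  }
  if (!is.numeric(fc_thresh) || fc_thresh <= 1) {
    abort_sc("fc_thresh must exceed 1", "sc_bad_input")
  }
  tab <- de$table
  fc <- 2^tab$log2_fc
  up <- tab$gene[tab$p < p_thresh & fc > fc_thresh]
  down <- tab$gene[tab$p < p_thresh & fc < 1 / fc_thresh]
  structure(list(contrast = de$contrast, up = up, down = down,
                 p_thresh = p_thresh, fc_thresh = fc_thresh),
            class = "deg_set")
}

#' @export
print.deg_set <- function(x, ...) {
  cat(sprintf("<deg_set> %s: %d up, %d down (p < %g, FC > %g)\n",
              x$contrast, length(x$up), length(x$down),
              x$p_thresh, x$fc_thresh))
  invisible(x)
}

#' Signed-significance gene ranking
#'
#' Orders the transcriptome by `signed_score = -log10(p) * sign(log2FC)`
#' descending (most up-significant first, most down-significant last),
#' breaking ties lexicographically by gene id for determinism. Genes
#' with score exactly 0 are counted in the down stratum.
#'
#' @param de a `de_result`.
#' @return A `ranked_list`: tibble (`gene`, `score`) sorted, with
#'   attributes `n` (background size) and `n_pos` (strictly positive
#'   scores).
#' @export
signed_rank_score <- function(de) {
  stopifnot(inherits(de, "de_result"))
  tab <- de$table
  if (anyDuplicated(tab$gene)) {
    abort_sc("duplicate gene ids in DE result", "sc_bad_input")
  }
  ord <- order(-tab$signed_score, tab$gene, method = "radix")
  out <- tibble::tibble(gene = tab$gene[ord], score = tab$signed_score[ord])
  structure(out, n = nrow(out), n_pos = sum(out$score > 0),
            contrast = de$contrast,
            class = c("ranked_list", class(out)))
}
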