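#' Fisher enrichment of DEG sets in co-expression modules
#'
#' For every (module, DEG set) pair, tests over-representation of the
#' set inside the module with a one-sided Fisher exact test on the 2x2
#' table `[in-module & DEG, in-module & not; DEG & not-module, rest]`
#' over the network background, i.e. the upper hypergeometric tail
#' \eqn{P(X \ge k)}. P-values are BH-adjusted jointly across all
#' module-by-set tests (one family). DEG genes absent from the
#' background are dropped with a message.
#'
#' @param partition a `module_partition` or named integer label vector;
#'   label 0 is background and is not tested.
#' @param degsets named list of character gene vectors, typically the 8
#'   directional sets (one "up in group X" set per group).
#' @param background character vector of network genes.
#' @param fdr significance level on the adjusted p (default 0.05).
#' @return An `enrichment_result` tibble: `module`, `set`, `n_module`,
#'   `n_set`, `n_overlap`, `odds_ratio`, `p`, `p_adj`, `significant`;
#'   attribute `background_size`.
#' @export
fisher_enrichment <- function(partition, degsets, background, fdr = 0.05) {
  stopifnot(is.list(degsets), !is.null(names(degsets)))
  labels <- partition_labels(partition, NULL)
  if (inherits(partition, "module_partition")) {
    names(labels) <- partition$membership$gene
  }
  labels <- labels[names(labels) %in% background]
  N <- length(background)
  dropped <- sum(vapply(degsets, function(s) sum(!s %in% background), 1L))
  if (dropped > 0) {
    message(dropped, " DEG entries absent from the background were dropped")
  }
  degsets <- lapply(degsets, intersect, background)
  mods <- sort(setdiff(unique(labels), 0L))
  if (!length(mods)) abort_sc("no modules to test", "sc_bad_input")

  grid <- tidyr::expand_grid(module = mods, set = names(degsets))
  cells <- purrr::map2_dfr(grid$module, grid$set, function(m, s) {
    mod_genes <- names(labels)[labels == m]
    deg <- degsets[[s]]
    k <- length(intersect(mod_genes, deg))
    nm <- length(mod_genes); nd <- length(deg)
    p <- stats::phyper(k - 1, nd, N - nd, nm, lower.tail = FALSE)
    or <- (k * (N - nm - nd + k)) / ((nm - k) * (nd - k))
    tibble::tibble(n_module = nm, n_set = nd, n_overlap = k,
                   odds_ratio = or, p = p)
  })
  res <- dplyr::bind_cols(grid, cells)
  res$p_adj <- bh_adjust(res$p)
  res$significant <- res$p_adj < fdr
  structure(res, background_size = N, fdr = fdr,
            class = c("enrichment_result", class(res)))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH false-discovery-rate adjustment (monotone, capped at 1).
#' A validated wrapper around [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return The adjusted p-values, in the input order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
bh_adjust <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1)) {
    abort_sc("p-values must be finite and in [0, 1]", "sc_bad_input")
  }
  stats::p.adjust(p, method = "BH")
}

#' Differential-expression relevance score per module
#'
#' The mean over DEG sets of \eqn{-\log_{10}} of the (by default
#' BH-adjusted) enrichment p-value: the "average total enrichment" bar
#' of the circos display. Higher means the module's genes are, on
#' average across all group contrasts, more enriched in DEGs.
#'
#' @param result an `enrichment_result`.
#' @param use_adjusted use `p_adj` (default) or raw `p`.
#' @return A tibble: `module`, `relevance`, sorted by decreasing
#'   relevance.
#' @export
relevance_score <- function(result, use_adjusted = TRUE) {
  stopifnot(inherits(result, "enrichment_result"))
  col <- if (use_adjusted) "p_adj" else "p"
  result |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$module) |>
    dplyr::summarise(relevance = mean(-log10(.data[[col]])), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$relevance))
}

#' Cross-model key modules
#'
#' A module is *key* when it is significantly enriched (adjusted
#' p below the family FDR) in at least one DEG set from each of the two
#' experiments - the pattern that singles out modules whose DEG
#' enrichment spans both stress models.
#'
#' @param result an `enrichment_result`.
#' @param experiment_of_set named character vector mapping each DEG-set
#'   name to its experiment label (exactly two distinct labels).
#' @return A tibble: `module`, `n_sig_by_experiment` (list-column of
#'   named counts), `key`.
#' @export
key_modules <- function(result, experiment_of_set) {
  stopifnot(inherits(result, "enrichment_result"))
  sets <- unique(result$set)
  miss <- setdiff(sets, names(experiment_of_set))
  if (length(miss)) {
    abort_sc(paste0("no experiment label for set(s): ",
                    paste(miss, collapse = ", ")), "sc_bad_input")
  }
  exps <- unique(experiment_of_set[sets])
  if (length(exps) != 2) {
    abort_sc("experiment_of_set must define exactly two experiments",
             "sc_bad_input")
  }
  result |>
    tibble::as_tibble() |>
    dplyr::mutate(experiment = experiment_of_set[.data$set]) |>
    dplyr::group_by(.data$module) |>
    dplyr::summarise(
      n_sig_by_experiment = list(vapply(
        exps, function(e) sum(.data$significant[.data$experiment == e]),
        integer(1))),
      key = all(vapply(exps, function(e)
        any(.data$significant[.data$experiment == e]), logical(1))),
      .groups = "drop")
}

#' Hub genes of a module
#'
#' Ranks a module's members by decreasing consensus kME (or by
#' intramodular connectivity) and flags as hubs the members whose score
#' strictly exceeds the module mean plus one sample standard deviation
#' (the mu + sigma rule). DEG membership is flagged per hub so plots
#' can outline differentially expressed hubs, and intramodular edges
#' above a TOM threshold are exported for network rendering.
#'
#' @param kme_mat genes x modules kME matrix (consensus mean).
#' @param partition a `module_partition` or named labels.
#' @param module module label to analyse.
#' @param degsets optional named list of DEG sets; a gene is flagged if
#'   it appears in any.
#' @param tom_mat optional TOM for edge export.
#' @param edge_threshold minimal TOM for exported edges (default 0.1).
#' @param measure `"kme"` (default) or `"kin"` (intramodular
#'   connectivity: row sums of the module TOM; requires `tom_mat`).
#' @return A `hub_set` tibble: `gene`, `score`, `rank`, `is_hub`,
#'   `is_deg`; attributes `module`, `threshold`, `edges` (tibble
#'   `gene1`, `gene2`, `tom`).
#' @export
select_hubs <- function(kme_mat, partition, module, degsets = NULL,
                        tom_mat = NULL, edge_threshold = 0.1,
                        measure = c("kme", "kin")) {
  measure <- match.arg(measure)
  labels <- partition_labels(partition, NULL)
  if (inherits(partition, "module_partition")) {
    names(labels) <- partition$membership$gene
  }
  members <- names(labels)[labels == module]
  if (length(members) < 2) {
    abort_sc("hub selection needs a module of at least 2 genes (sd undefined)",
             "sc_bad_input")
  }
  score <- if (measure == "kme") {
    col <- paste0("ME", module)
    if (!col %in% colnames(kme_mat)) {
      abort_sc(paste0("kME matrix has no column ", col), "sc_bad_input")
    }
    kme_mat[members, col]
  } else {
    if (is.null(tom_mat)) abort_sc("measure 'kin' requires tom_mat",
                                   "sc_bad_input")
    sub <- unclass(tom_mat)[members, members]
    rowSums(sub) - diag(sub)
  }
  thr <- mean(score) + sample_sd(score)
  ord <- order(-score, members)
  genes_ord <- members[ord]
  score_ord <- unname(score[ord])
  out <- tibble::tibble(
    gene = genes_ord, score = score_ord,
    rank = seq_along(members),
    is_hub = score_ord > thr,
    is_deg = if (is.null(degsets)) NA else
      genes_ord %in% unique(unlist(degsets))
  )
  edges <- tibble::tibble(gene1 = character(0), gene2 = character(0),
                          tom = numeric(0))
  if (!is.null(tom_mat)) {
    sub <- unclass(tom_mat)[members, members]
    ut <- which(upper.tri(sub) & sub >= edge_threshold, arr.ind = TRUE)
    edges <- tibble::tibble(gene1 = members[ut[, 1]], gene2 = members[ut[, 2]],
                            tom = sub[ut])
  }
  structure(out, module = module, threshold = thr, measure = measure,
            edges = edges, class = c("hub_set", class(out)))
}
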