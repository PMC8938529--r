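#' Upper-tail hypergeometric overlap p-value
#'
#' Probability of observing at least `k` genes in common between a
#' fixed set of size `i` and an independently drawn set of size `j`
#' from a background of `N` genes: \eqn{P(X \ge k)},
#' \eqn{X \sim} Hypergeometric\eqn{(N, i, j)}.
#'
#' @param k observed overlap, `0 <= k <= min(i, j)`.
#' @param i,j set sizes, each `<= N`.
#' @param N background size.
#' @return The upper-tail p-value in (0, 1].
#' @export
#' @examples
#' hypergeom_overlap_p(3, 5, 5, 20)  # 1126/15504
hypergeom_overlap_p <- function(k, i, j, N) {
  if (any(k < 0) || any(k > pmin(i, j)) || any(i > N) || any(j > N)) {
    abort_sc("need 0 <= k <= min(i, j) <= N", "sc_bad_input")
  }
  stats::phyper(k - 1, i, N - i, j, lower.tail = FALSE)
}

#' Stratified rank-rank hypergeometric overlap map
#'
#' Computes the stratified RRHO between two signed ranked lists over one
#' background. The up-stratum of a list is its genes with strictly
#' positive signed score, taken from the top; the down-stratum is the
#' rest, taken from the bottom. Four quadrants are evaluated on a
#' threshold grid with step `step`:
#'
#' * `UU` - top-i of list 1 vs top-j of list 2 (co-up),
#' * `DD` - bottom-i vs bottom-j (co-down),
#' * `UD` - top-i of list 1 vs bottom-j of list 2,
#' * `DU` - bottom-i of list 1 vs top-j of list 2.
#'
#' Each grid cell stores \eqn{-\log_{10}} of the raw upper-tail
#' hypergeometric p-value of the overlap against the full background
#' `N`; an optional BH-corrected map (across all cells of all
#' quadrants) is attached when `correct = TRUE`.
#'
#' @param list1,list2 `ranked_list` objects ([signed_rank_score()])
#'   over identical backgrounds.
#' @param step grid step >= 1; default `ceiling(sqrt(N))`.
#' @param correct also compute a BH-adjusted map (default TRUE).
#' @return An `rrho_map`: list with `quadrants` (per quadrant: `i`, `j`
#'   threshold vectors, `k` overlap-count matrix, `neg_log10_p` matrix,
#'   optionally `neg_log10_p_adj`), `N`, `step`, `n1_pos`, `n2_pos`,
#'   and the two ranked lists.
#' @export
rrho_map <- function(list1, list2, step = NULL, correct = TRUE) {
  stopifnot(inherits(list1, "ranked_list"), inherits(list2, "ranked_list"))
  if (!setequal(list1$gene, list2$gene)) {
    d1 <- setdiff(list1$gene, list2$gene)
    d2 <- setdiff(list2$gene, list1$gene)
    abort_sc(paste0("ranked lists have different backgrounds; only in list1: ",
                    paste(utils::head(d1, 5), collapse = ","),
                    "; only in list2: ",
                    paste(utils::head(d2, 5), collapse = ",")),
             "sc_background_mismatch")
  }
  N <- nrow(list1)
  step <- step %||% ceiling(sqrt(N))
  if (step < 1) abort_sc("step must be >= 1", "sc_bad_input")

  # rank of each gene in each list, from the top (1 = most up-significant)
  r1 <- stats::setNames(seq_len(N), list1$gene)
  r2 <- stats::setNames(seq_len(N), list2$gene)[list1$gene]
  n1p <- attr(list1, "n_pos"); n2p <- attr(list2, "n_pos")

  top1 <- unname(r1); bot1 <- N - top1 + 1L
  top2 <- unname(r2); bot2 <- N - top2 + 1L

  quad_def <- list(
    UU = list(x = top1, y = top2, nx = n1p,     ny = n2p),
    DD = list(x = bot1, y = bot2, nx = N - n1p, ny = N - n2p),
    UD = list(x = top1, y = bot2, nx = n1p,     ny = N - n2p),
    DU = list(x = bot1, y = top2, nx = N - n1p, ny = n2p)
  )
  quadrants <- lapply(quad_def, function(q) {
    is <- threshold_seq(q$nx, step)
    js <- threshold_seq(q$ny, step)
    if (!length(is) || !length(js)) {
      return(list(i = is, j = js,
                  k = matrix(0L, length(is), length(js)),
                  neg_log10_p = matrix(numeric(0), length(is), length(js)),
                  empty = TRUE))
    }
    k <- dominance_counts(q$x, q$y, is, js)
    p <- matrix(stats::phyper(k - 1, rep(is, length(js)),
                              N - rep(is, length(js)),
                              rep(js, each = length(is)),
                              lower.tail = FALSE),
                length(is), length(js))
    list(i = is, j = js, k = k, neg_log10_p = -log10(p), empty = FALSE)
  })

  if (correct) {
    all_p <- unlist(lapply(quadrants, function(q)
      if (q$empty) numeric(0) else 10^(-q$neg_log10_p)))
    adj <- stats::p.adjust(all_p, method = "BH")
    pos <- 0L
    for (nm in names(quadrants)) {
      q <- quadrants[[nm]]
      if (q$empty) next
      n <- length(q$neg_log10_p)
      quadrants[[nm]]$neg_log10_p_adj <-
        matrix(-log10(adj[pos + seq_len(n)]), nrow(q$k), ncol(q$k))
      pos <- pos + n
    }
  }

  structure(list(quadrants = quadrants, N = N, step = as.integer(step),
                 n1_pos = n1p, n2_pos = n2p,
                 list1 = list1, list2 = list2),
            class = "rrho_map")
}

# thresholds step, 2*step, ..., always including the region boundary
threshold_seq <- function(n, step) {
  if (n < 1) return(integer(0))
  s <- seq.int(step, n, by = step)
  if (!length(s) || s[length(s)] != n) s <- c(s, n)
  as.integer(s)
}

# k(i, j) = #genes with x-rank <= i and y-rank <= j, on threshold grids
dominance_counts <- function(x, y, is, js) {
  xb <- findInterval(x, is + 0.5) + 1L  # first i-threshold covering x
  yb <- findInterval(y, js + 0.5) + 1L
  keep <- xb <= length(is) & yb <= length(js)
  k <- matrix(0L, length(is), length(js))
  if (any(keep)) {
    t0 <- table(factor(xb[keep], levels = seq_along(is)),
                factor(yb[keep], levels = seq_along(js)))
    k <- matrix(as.integer(t0), length(is), length(js))
  }
  if (nrow(k) > 1) for (r in 2:nrow(k)) k[r, ] <- k[r, ] + k[r - 1L, ]
  if (ncol(k) > 1) for (cc in 2:ncol(k)) k[, cc] <- k[, cc] + k[, cc - 1L]
  k
}

#' @export
print.rrho_map <- function(x, ...) {
  cat(sprintf("<rrho_map> N = %d, step = %d, up-strata %d/%d\n",
              x$N, x$step, x$n1_pos, x$n2_pos))
  pk <- quadrant_peaks(x)
  print(dplyr::select(pk, -"genes"))
  invisible(x)
}

#' Per-quadrant RRHO peaks and peak gene sets
#'
#' Returns, for each quadrant, the grid cell with the maximal
#' \eqn{-\log_{10}(p)} (ties resolved to the smallest `i`, then the
#' smallest `j`) and the overlapping genes at that cell. Empty quadrants
#' (no genes in a stratum) are flagged absent rather than erroring.
#'
#' @param map an `rrho_map`.
#' @param adjusted read peaks off the BH-corrected map if present
#'   (default FALSE: raw map, matching the published convention of
#'   reporting the max raw \eqn{-\log_{10} p}).
#' @return A tibble: `quadrant`, `present`, `i`, `j`, `neg_log10_p`,
#'   `n_overlap`, `genes` (list-column).
#' @export
quadrant_peaks <- function(map, adjusted = FALSE) {
  stopifnot(inherits(map, "rrho_map"))
  r1 <- stats::setNames(seq_len(map$N), map$list1$gene)
  r2 <- stats::setNames(seq_len(map$N), map$list2$gene)
  purrr::map_dfr(names(map$quadrants), function(nm) {
    q <- map$quadrants[[nm]]
    if (isTRUE(q$empty)) {
      return(tibble::tibble(quadrant = nm, present = FALSE,
                            i = NA_integer_, j = NA_integer_,
                            neg_log10_p = NA_real_, n_overlap = NA_integer_,
                            genes = list(character(0))))
    }
    vals <- if (adjusted && !is.null(q$neg_log10_p_adj)) q$neg_log10_p_adj
            else q$neg_log10_p
    best <- which(vals == max(vals), arr.ind = TRUE)
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    i <- q$i[best[1]]; j <- q$j[best[2]]
    genes <- peak_genes(map, nm, i, j, r1, r2)
    tibble::tibble(quadrant = nm, present = TRUE,
                   i = i, j = j,
                   neg_log10_p = vals[best[1], best[2]],
                   n_overlap = length(genes), genes = list(genes))
  })
}

peak_genes <- function(map, quadrant, i, j, r1, r2) {
  N <- map$N
  g <- map$list1$gene
  x <- switch(substr(quadrant, 1, 1), U = r1[g], D = N - r1[g] + 1L)
  y <- switch(substr(quadrant, 2, 2), U = r2[g], D = N - r2[g] + 1L)
  sort(g[x <= i & y <= j])
}

#' Venn decomposition of named gene sets
#'
#' Exact region cardinalities and member lists for every non-empty
#' membership pattern of the supplied sets (the regions of a Venn
#' diagram), e.g. to count genes shared across RRHO peak sets.
#'
#' @param sets named list of character vectors over one background.
#' @return A tibble: `region` (set names joined by `&`), `n_sets`,
#'   `n`, `genes` (list-column). Regions with zero members are kept
#'   only for the all-sets intersection.
#' @export
#' @examples
#' intersect_peak_sets(list(A = c("a", "b", "c"), B = c("b", "c", "d")))
intersect_peak_sets <- function(sets) {
  stopifnot(is.list(sets), !is.null(names(sets)), all(nzchar(names(sets))))
  genes <- unique(unlist(sets))
  member <- vapply(sets, function(s) genes %in% s, logical(length(genes)))
  if (length(genes) == 1) member <- matrix(member, nrow = 1,
                                           dimnames = list(NULL, names(sets)))
  pattern <- apply(member, 1, function(r) paste(names(sets)[r], collapse = "&"))
  out <- tibble::tibble(gene = genes, region = pattern) |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(n = dplyr::n(),
                     genes = list(sort(.data$gene)), .groups = "drop") |>
    dplyr::mutate(n_sets = lengths(strsplit(.data$region, "&", fixed = TRUE))) |>
    dplyr::arrange(dplyr::desc(.data$n_sets), .data$region) |>
    dplyr::select("region", "n_sets", "n", "genes")
  all_region <- paste(names(sets), collapse = "&")
  if (!all_region %in% out$region) {
    out <- dplyr::bind_rows(out,
      tibble::tibble(region = all_region, n_sets = length(sets),
                     n = 0L, genes = list(character(0))))
  }
  out
}

#' Assemble the full RRHO grid in display orientation
#'
#' Combines the four quadrant grids into one matrix oriented like the
#' published heatmaps: rows run from list 1's most down-significant gene
#' (top) to most up-significant (bottom), columns likewise for list 2,
#' so the upper-left block is co-down (`DD`) and the lower-right block
#' is co-up (`UU`).
#'
#' @param map an `rrho_map`.
#' @param adjusted use the BH-corrected values if present.
#' @return A numeric matrix of \eqn{-\log_{10}(p)} values.
#' @export
rrho_grid <- function(map, adjusted = FALSE) {
  stopifnot(inherits(map, "rrho_map"))
  val <- function(nm) {
    q <- map$quadrants[[nm]]
    if (isTRUE(q$empty)) return(matrix(numeric(0), length(q$i), length(q$j)))
    if (adjusted && !is.null(q$neg_log10_p_adj)) q$neg_log10_p_adj
    else q$neg_log10_p
  }
  # row direction: down-stratum thresholds reversed so the deepest
  # down-threshold sits in the top row; columns analogously
  dd <- val("DD"); du <- val("DU"); ud <- val("UD"); uu <- val("UU")
  top <- cbind(dd[rev(seq_len(nrow(dd))), rev(seq_len(ncol(dd))), drop = FALSE],
               du[rev(seq_len(nrow(du))), , drop = FALSE])
  bottom <- cbind(ud[, rev(seq_len(ncol(ud))), drop = FALSE], uu)
  rbind(top, bottom)
}
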