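#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a differential-expression result
#'
#' @param x a `de_result` from [moderated_t()].
#' @param ... unused.
#' @return The per-gene tibble (`gene`, `log2_fc`, `t_mod`, `p`,
#'   `signed_score`, `constant`).
#' @export
tidy.de_result <- function(x, ...) x$table

#' One-row summary of a differential-expression fit
#'
#' @param x a `de_result`.
#' @param ... unused.
#' @return A tibble: `contrast`, `n_genes`, `df_residual`, `d0`,
#'   `s0_2`, `n_p_lt_05`.
#' @export
glance.de_result <- function(x, ...) {
  tibble::tibble(contrast = x$contrast, n_genes = nrow(x$table),
                 df_residual = x$df_residual, d0 = x$d0, s0_2 = x$s0_2,
                 n_p_lt_05 = sum(x$table$p < 0.05))
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("<de_result> %s: %d genes, d0 = %.3g, s0^2 = %.3g, df = %d\n",
              x$contrast, nrow(x$table), x$d0, x$s0_2, x$df_residual))
  invisible(x)
}

#' Tidy an RRHO map into long format
#'
#' @param x an `rrho_map`.
#' @param ... unused.
#' @return A tibble: `quadrant`, `i`, `j`, `overlap`, `neg_log10_p`.
#' @export
tidy.rrho_map <- function(x, ...) {
  purrr::map_dfr(names(x$quadrants), function(nm) {
    q <- x$quadrants[[nm]]
    if (isTRUE(q$empty)) return(NULL)
    tibble::tibble(quadrant = nm,
                   i = rep(q$i, times = length(q$j)),
                   j = rep(q$j, each = length(q$i)),
                   overlap = as.vector(q$k),
                   neg_log10_p = as.vector(q$neg_log10_p))
  })
}

#' One-row-per-quadrant RRHO summary
#'
#' @param x an `rrho_map`.
#' @param ... unused.
#' @return [quadrant_peaks()] without the gene list-column.
#' @export
glance.rrho_map <- function(x, ...) {
  dplyr::select(quadrant_peaks(x), -"genes")
}

#' Tidy an enrichment result
#'
#' @param x an `enrichment_result`.
#' @param ... unused.
#' @return A plain tibble of the module-by-set tests.
#' @export
tidy.enrichment_result <- function(x, ...) {
  tibble::as_tibble(x)
}
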