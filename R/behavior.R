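#' Control-referenced directional z-score
#'
#' `z = ((x - mean_cont) / sd_cont) * direction`, where `direction` is
#' +1 or -1 chosen per variable so that a larger z always means more
#' emotionality (anxiety-/depression-like behavior).
#'
#' @param x measurement(s).
#' @param control_mean,control_sd control-group mean and sd
#'   (`control_sd > 0`).
#' @param direction +1 or -1.
#' @return The directional z-score(s).
#' @export
#' @examples
#' zscore_vs_control(14, 10, 2, -1)  # -2
zscore_vs_control <- function(x, control_mean, control_sd, direction = 1) {
  if (any(control_sd <= 0)) {
    abort_sc("control sd must be positive", "sc_degenerate_control")
  }
  if (!all(direction %in% c(-1, 1))) {
    abort_sc("direction must be +1 or -1", "sc_bad_input")
  }
  ((x - control_mean) / control_sd) * direction
}

# per-variable directional z table referenced to a control group
behavior_z <- function(table, control_group, var_info = NULL) {
  var_info <- var_info %||% attr(table, "var_info")
  if (is.null(var_info)) {
    abort_sc("supply var_info (variable, test, direction)", "sc_bad_input")
  }
  vars <- intersect(var_info$variable, names(table))
  if (!length(vars)) abort_sc("no scored variables found in table",
                              "sc_bad_input")
  ctrl <- table$group == control_group
  if (!any(ctrl)) abort_sc(paste0("control group not found: ", control_group),
                           "sc_bad_input")
  z <- table[c("animal", "group")]
  for (v in vars) {
    row <- var_info[var_info$variable == v, ]
    z[[v]] <- zscore_vs_control(table[[v]],
                                mean(table[[v]][ctrl]),
                                sample_sd(table[[v]][ctrl]),
                                row$direction)
  }
  attr(z, "var_info") <- var_info[var_info$variable %in% vars, ]
  z
}

#' Behavioral emotionality composite
#'
#' Z-normalizes every scored variable against the control group with
#' its emotionality direction, averages the directional z-scores within
#' each behavioral test, then averages across tests with equal weight.
#' A control animal sitting exactly at the control means scores 0.
#'
#' @param table behavioral tibble (columns `animal`, `group`, one
#'   column per variable), e.g. from [simulate_behavior()].
#' @param control_group label of the reference group.
#' @param var_info tibble with `variable`, `test`, `direction`;
#'   defaults to the table's `var_info` attribute.
#' @return A tibble: `animal`, `group`, `emotionality`.
#' @export
emotionality_score <- function(table, control_group, var_info = NULL) {
  z <- behavior_z(table, control_group, var_info)
  info <- attr(z, "var_info")
  per_test <- lapply(split(info$variable, info$test), function(vars) {
    rowMeans(as.matrix(z[vars]))
  })
  tibble::tibble(
    animal = z$animal, group = z$group,
    emotionality = rowMeans(do.call(cbind, per_test))
  )
}

#' Behavioral score (1 - z / a-bar)
#'
#' The per-animal behavioral score used to summarize each group against
#' its designated control: emotionality z-composites are computed for
#' the two groups of a comparison with the control group as reference,
#' all z values are normalized to the lowest z of the comparison cohort
#' by subtraction, a-bar is the mean normalized z of the control
#' animals, and each animal scores `1 - z_shifted / a_bar`. The animal
#' at the cohort minimum therefore scores exactly 1, an animal at the
#' control mean scores 0, and the score decreases strictly with
#' emotionality.
#'
#' @param table behavioral tibble.
#' @param group label of the comparison (non-reference) group.
#' @param control_group label of its control.
#' @param var_info see [emotionality_score()].
#' @return A tibble: `animal`, `group`, `z`, `z_shifted`, `score`.
#' @export
behavioral_score <- function(table, group, control_group, var_info = NULL) {
  cohort <- table[table$group %in% c(group, control_group), , drop = FALSE]
  attr(cohort, "var_info") <- var_info %||% attr(table, "var_info")
  emo <- emotionality_score(cohort, control_group)
  z_shifted <- emo$emotionality - min(emo$emotionality)
  a_bar <- mean(z_shifted[emo$group == control_group])
  if (a_bar == 0) {
    abort_sc("degenerate control spread: mean normalized control z is 0",
             "sc_degenerate_control")
  }
  tibble::tibble(animal = emo$animal, group = emo$group,
                 z = emo$emotionality, z_shifted = z_shifted,
                 score = 1 - z_shifted / a_bar)
}

#' Classify the social-interaction phenotype
#'
#' SI ratio strictly greater than 1 is resilient (`"RES"`); 1 or below
#' is susceptible (`"SUS"`).
#'
#' @param si_ratio non-negative SI ratio(s): time in the interaction
#'   zone with the aggressor present over absent.
#' @return Character vector of `"RES"` / `"SUS"`.
#' @export
#' @examples
#' classify_si(c(1.2, 0.8, 1))
classify_si <- function(si_ratio) {
  if (any(si_ratio < 0)) abort_sc("SI ratio must be >= 0", "sc_bad_input")
  ifelse(si_ratio > 1, "RES", "SUS")
}

#' Cohort proportions and housing-by-phenotype association
#'
#' Converts a phenotype x housing count table to percentages of the
#' grand total (full precision plus integer display rounding) and tests
#' the 2x2 association with a two-sided Fisher exact test.
#'
#' @param counts 2x2 numeric matrix (rows = phenotype, columns =
#'   housing) or a tibble with columns `phenotype`, `housing`, `n`.
#' @return A `cohort_proportions` tibble: `phenotype`, `housing`, `n`,
#'   `pct`, `pct_display`; attributes `fisher_p` and `total`.
#' @export
#' @examples
#' cohort_proportions(matrix(c(14, 59, 32, 49), 2,
#'                           dimnames = list(c("RES", "SUS"), c("SH", "EE"))))
cohort_proportions <- function(counts) {
  if (is.data.frame(counts)) {
    counts <- stats::xtabs(n ~ phenotype + housing, data = counts)
    counts <- as.matrix(unclass(counts))
  }
  if (!is.matrix(counts) || any(counts < 0) || any(counts != floor(counts))) {
    abort_sc("counts must be a matrix of non-negative integers",
             "sc_bad_input")
  }
  total <- sum(counts)
  p <- stats::fisher.test(counts)$p.value
  out <- tibble::as_tibble(as.table(counts), .name_repair = "minimal")
  names(out) <- c("phenotype", "housing", "n")
  out$pct <- 100 * out$n / total
  out$pct_display <- round(out$pct)
  structure(out, fisher_p = p, total = total,
            class = c("cohort_proportions", class(out)))
}

#' @export
print.cohort_proportions <- function(x, ...) {
  cat(sprintf("<cohort_proportions> n = %d, Fisher p = %.4g\n",
              attr(x, "total"), attr(x, "fisher_p")))
  NextMethod()
}
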