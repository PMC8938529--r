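#' Simulate the paired stress-model count matrices
#'
#' Draws two gene-by-sample negative-binomial count matrices that share
#' one set of planted co-expression modules, mimicking a consensus
#' design: every module gene keeps the same loading on its module's
#' latent factor in both experiments, while the factor realizations and
#' library sizes are experiment-specific. Concordant differential
#' expression is planted on the log2 scale *before* count sampling, in
#' the susceptibility module for CORT-treated and SH-susceptible groups
#' and in the resilience module for vehicle-treated hMet and
#' EE-susceptible groups, so the two experiments carry the concordance
#' pattern the downstream RRHO / consensus-network analysis looks for.
#'
#' The generative model for gene \eqn{g} in sample \eqn{j} is
#' \deqn{y_{gj} \sim NB(\mu_{gj}, 1/\phi), \quad
#'   \mu_{gj} = 2^{b_g + \lambda_g f_{j,m(g)} + \delta_{gj}} \cdot s_j}
#' with baseline \eqn{b_g}, loading \eqn{\lambda_g}, per-sample module
#' factor \eqn{f}, planted shift \eqn{\delta}, library-size scale
#' \eqn{s_j} and shared dispersion \eqn{\phi}.
#'
#' @param config a [sim_config()] object.
#' @return A list with elements `A` and `B` (each a `count_matrix`:
#'   `counts` integer matrix, `samples` tibble with
#'   sample/experiment/group/factor1/factor2) and `truth`
#'   (a `ground_truth`: `module_of_gene` named integer vector with 0 =
#'   background, and `de_genes_per_contrast`, a list of tibbles with
#'   columns `gene` and `sign`).
#' @export
#' @examples
#' sim <- simulate_counts(sim_config(n_genes = 300, n_modules = 3,
#'                                   module_size = 30, seed = 7))
#' dim(sim$A$counts)
#' table(sim$truth$module_of_gene)
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  genes <- sprintf("g%05d", seq_len(config$n_genes))

  module_of_gene <- integer(config$n_genes)
  idx <- seq_len(config$n_modules * config$module_size)
  module_of_gene[idx] <- rep(seq_len(config$n_modules), each = config$module_size)
  names(module_of_gene) <- genes

  baseline <- stats::rnorm(config$n_genes, config$baseline_log2_mean,
                           config$baseline_log2_sd)
  loading <- numeric(config$n_genes)
  loading[idx] <- stats::runif(length(idx),
                               config$module_loading_range[1],
                               config$module_loading_range[2])

  shift_of_group <- planted_shifts(config, module_of_gene)

  experiments <- list(A = "CORT", B = "CSDS")
  out <- lapply(names(experiments), function(exp_id) {
    grp <- config$groups[[exp_id]]
    n <- config$n_per_group
    group <- rep(grp, each = n)
    sample_id <- paste(exp_id, group, rep(seq_len(n), times = length(grp)),
                       sep = "_")
    ns <- length(sample_id)
    fac <- matrix(stats::rnorm(ns * config$n_modules), ns, config$n_modules)
    # center factors within each group: planted shifts stay the only
    # systematic group differences, so the serialized ground truth is exact
    for (g in grp) {
      rows <- group == g
      fac[rows, ] <- scale(fac[rows, , drop = FALSE], scale = FALSE)
    }
    libscale <- stats::rlnorm(ns, config$libsize_log_mean, config$libsize_log_sd)

    log2mu <- matrix(baseline, config$n_genes, ns)
    in_mod <- module_of_gene > 0
    log2mu[in_mod, ] <- log2mu[in_mod, ] +
      loading[in_mod] * t(fac[, module_of_gene[in_mod], drop = FALSE])
    for (s in seq_len(ns)) {
      log2mu[, s] <- log2mu[, s] + shift_of_group[, group[s]]
    }
    mu <- 2^log2mu * rep(libscale, each = config$n_genes)
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / config$nb_dispersion),
                     config$n_genes, ns,
                     dimnames = list(genes, sample_id))
    storage.mode(counts) <- "integer"
    fct <- do.call(rbind, strsplit(group, "_", fixed = TRUE))
    new_count_matrix(
      counts,
      tibble::tibble(sample = sample_id,
                     experiment = experiments[[exp_id]],
                     group = group,
                     factor1 = fct[, 1], factor2 = fct[, 2]),
      experiment = experiments[[exp_id]],
      libsize_scale = libscale
    )
  })
  names(out) <- names(experiments)

  truth <- structure(list(
    module_of_gene = module_of_gene,
    de_genes_per_contrast = planted_de_sets(config, module_of_gene),
    susceptibility_module = config$susceptibility_module_id,
    resilience_module = config$resilience_module_id
  ), class = "ground_truth")

  list(A = out$A, B = out$B, truth = truth)
}

# per-gene x per-group planted log2 shift matrix
planted_shifts <- function(config, module_of_gene) {
  groups <- unlist(config$groups, use.names = FALSE)
  shift <- matrix(0, length(module_of_gene), length(groups),
                  dimnames = list(names(module_of_gene), groups))
  planted <- c(susceptibility = config$susceptibility_module_id,
               resilience = config$resilience_module_id)
  for (eff in names(planted)) {
    g <- module_of_gene == planted[[eff]]
    shift[g, config$affected_groups[[eff]]] <- config$de_log2fc
  }
  shift
}

# ground-truth DE sets per contrast, with signs (+1 up in the non-reference group)
planted_de_sets <- function(config, module_of_gene) {
  shift <- planted_shifts(config, module_of_gene)
  contrasts <- c(sim_contrasts(config)$A, sim_contrasts(config)$B)
  lapply(contrasts, function(cc) {
    d <- shift[, cc[2]] - shift[, cc[1]]
    nz <- d != 0
    tibble::tibble(gene = names(module_of_gene)[nz], sign = unname(sign(d[nz])))
  })
}

new_count_matrix <- function(counts, samples, experiment, libsize_scale = NULL) {
  structure(list(counts = counts, samples = samples,
                 experiment = experiment, libsize_scale = libsize_scale),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %s: %d genes x %d samples (%s)\n",
              x$experiment, nrow(x$counts), ncol(x$counts),
              paste(unique(x$samples$group), collapse = ", ")))
  invisible(x)
}

#' Behavioral variable catalogue
#'
#' The variables scored by the two behavioral batteries, the test each
#' belongs to, control-group mean and sd used by the simulator, and the
#' direction sign that makes a larger directional z mean *more*
#' emotionality (anxiety-/depression-like behavior). Times are in
#' seconds, `pct_time_light` in percent, `si_ratio` dimensionless.
#'
#' @return A tibble with columns `variable`, `test`, `mean`, `sd`,
#'   `direction`.
#' @export
behavior_var_info <- function() {
  tibble::tribble(
    ~variable,           ~test,                ~mean, ~sd, ~direction,
    "pct_time_light",    "light_dark",          30,    8,  -1,
    "latency_to_light",  "light_dark",          60,   20,   1,
    "latency_to_dark",   "light_dark",          15,    6,  -1,
    "grooming_time",     "splash",              80,   20,  -1,
    "grooming_sessions", "splash",               7,    2,  -1,
    "grooming_latency",  "splash",              40,   15,   1,
    "si_zone_time",      "social_interaction",  75,   18,  -1,
    "si_ratio",          "social_interaction",  NA,   NA,  -1
  )
}

#' Simulate the behavioral cohorts
#'
#' Generates one behavioral table per experiment. Experiment A animals
#' (light-dark box and splash test) are drawn group-balanced; CORT
#' groups are shifted by `behavior_effect_size` control-sd units in the
#' emotionality-increasing direction of every variable. Experiment B
#' animals (social-interaction test) follow the configured cohort sizes;
#' susceptible groups are shifted likewise, and the SI ratio is drawn on
#' the matching side of 1 so that [classify_si()] reproduces the group
#' labels.
#'
#' @param config a [sim_config()] object.
#' @return A list of two tibbles `A` and `B` (columns: `animal`,
#'   `group`, `factor1`, `factor2`, then one column per behavioral
#'   variable), each carrying the relevant rows of
#'   [behavior_var_info()] as attribute `var_info`.
#' @export
simulate_behavior <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  info <- behavior_var_info()

  make_table <- function(groups, n_of_group, vars, shifted_groups, exp_id) {
    group <- rep(groups, times = n_of_group[groups])
    animal <- paste(exp_id, group, stats::ave(seq_along(group), group,
                                              FUN = seq_along), sep = "_")
    fct <- do.call(rbind, strsplit(group, "_", fixed = TRUE))
    tab <- tibble::tibble(animal = animal, group = group,
                          factor1 = fct[, 1], factor2 = fct[, 2])
    for (v in vars) {
      row <- info[info$variable == v, ]
      if (v == "si_ratio") {
        sus <- fct[, 2] == "SUS"
        val <- numeric(length(group))
        val[sus] <- pmin(pmax(stats::rnorm(sum(sus), 0.70, 0.12), 0.05), 0.99)
        val[!sus] <- pmax(stats::rnorm(sum(!sus), 1.40, 0.20), 1.01)
      } else {
        mu <- rep(row$mean, length(group))
        mu[group %in% shifted_groups] <- row$mean +
          config$behavior_effect_size * row$sd * row$direction
        val <- stats::rnorm(length(group), mu, row$sd)
      }
      tab[[v]] <- val
    }
    attr(tab, "var_info") <- info[info$variable %in% vars, ]
    tab
  }

  nA <- stats::setNames(rep(config$n_behavior_per_group, 4), config$groups$A)
  A <- make_table(config$groups$A, nA,
                  info$variable[info$test %in% c("light_dark", "splash")],
                  shifted_groups = c("WT_CORT", "hMet_CORT"), exp_id = "A")
  B <- make_table(config$groups$B, config$csds_cohort,
                  info$variable[info$test == "social_interaction"],
                  shifted_groups = c("SH_SUS", "EE_SUS"), exp_id = "B")
  list(A = A, B = B)
}
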