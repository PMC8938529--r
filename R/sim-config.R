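#' Configuration for the paired synthetic stress experiments
#'
#' Builds the configuration object consumed by [simulate_counts()] and
#' [simulate_behavior()]. The simulator emulates two bulk RNA-seq
#' experiments sharing one transcriptome: experiment A crosses BDNF
#' genotype (WT / hMet) with chronic oral corticosterone (VEH / CORT);
#' experiment B crosses housing (standard, SH / enriched, EE) with the
#' post-defeat phenotype (susceptible, SUS / resilient, RES). Gene
#' modules are planted as latent-factor blocks with loadings shared
#' across the two experiments, so a consensus co-expression analysis can
#' recover them, and concordant differential expression is planted in
#' two designated modules:
#'
#' * the *susceptibility* module is shifted up in `WT_CORT`, `hMet_CORT`
#'   and `SH_SUS` animals;
#' * the *resilience* module is shifted up in `hMet_VEH` and `EE_SUS`
#'   animals.
#'
#' @param n_genes total number of genes.
#' @param n_modules number of planted co-expression modules.
#' @param module_size genes per planted module; `n_modules * module_size`
#'   must not exceed `n_genes` (remaining genes are unstructured
#'   background).
#' @param n_per_group RNA-seq replicates per group (4 groups per
#'   experiment).
#' @param baseline_log2_mean,baseline_log2_sd mean and sd of the
#'   gene-wise baseline expression on the log2 scale.
#' @param nb_dispersion negative-binomial dispersion (1/size), shared by
#'   all genes.
#' @param libsize_log_mean,libsize_log_sd log-normal parameters of the
#'   per-sample library-size scale factor.
#' @param module_loading_range interval in (0, 1] from which gene
#'   loadings on their module's latent factor are drawn.
#' @param de_log2fc planted log2 fold change for affected module genes.
#' @param susceptibility_module_id,resilience_module_id integer labels
#'   (in `1:n_modules`) of the two planted effect modules.
#' @param affected_groups named list mapping `"susceptibility"` and
#'   `"resilience"` to the group labels that receive the `de_log2fc`
#'   shift in that module.
#' @param behavior_effect_size standardized group shift (in control-sd
#'   units) applied to behavioral variables of susceptible-like groups;
#'   0 gives a behavioral null.
#' @param n_behavior_per_group animals per group in experiment A's
#'   behavioral cohort.
#' @param csds_cohort named integer vector of CSDS cohort sizes
#'   (`SH_SUS`, `SH_RES`, `EE_SUS`, `EE_RES`); the default reproduces
#'   the published cohort proportions.
#' @param seed integer seed; identical configs with identical seeds
#'   reproduce byte-identical output.
#'
#' @return An object of class `sim_config` (a named list).
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 400, n_modules = 4, module_size = 40)
#' cfg$groups
sim_config <- function(n_genes = 2000,
                       n_modules = 10,
                       module_size = 50,
                       n_per_group = 6,
                       baseline_log2_mean = 5,
                       baseline_log2_sd = 1.5,
                       nb_dispersion = 0.2,
                       libsize_log_mean = 0,
                       libsize_log_sd = 0.3,
                       module_loading_range = c(0.45, 0.8),
                       de_log2fc = 0.6,
                       susceptibility_module_id = 1L,
                       resilience_module_id = 2L,
                       affected_groups = NULL,
                       behavior_effect_size = 1.2,
                       n_behavior_per_group = 10,
                       csds_cohort = c(SH_SUS = 59, SH_RES = 14,
                                       EE_SUS = 49, EE_RES = 32),
                       seed = 1L) {
  if (n_modules * module_size > n_genes) {
    abort_sc("module_size * n_modules exceeds n_genes", "sc_config_error")
  }
  if (!is.finite(de_log2fc)) {
    abort_sc("de_log2fc must be finite", "sc_config_error")
  }
  if (length(module_loading_range) != 2 ||
      module_loading_range[1] <= 0 || module_loading_range[2] > 1 ||
      diff(module_loading_range) < 0) {
    abort_sc("module_loading_range must be an interval within (0, 1]",
             "sc_config_error")
  }
  if (nb_dispersion <= 0) {
    abort_sc("nb_dispersion must be positive", "sc_config_error")
  }
  for (m in c(susceptibility_module_id, resilience_module_id)) {
    if (!m %in% seq_len(n_modules)) {
      abort_sc("planted effect modules must be in 1:n_modules",
               "sc_config_error")
    }
  }
  groups <- list(
    A = c("WT_VEH", "WT_CORT", "hMet_VEH", "hMet_CORT"),
    B = c("SH_SUS", "SH_RES", "EE_SUS", "EE_RES")
  )
  affected_groups <- affected_groups %||% list(
    susceptibility = c("WT_CORT", "hMet_CORT", "SH_SUS"),
    resilience     = c("hMet_VEH", "EE_SUS")
  )
  bad <- setdiff(unlist(affected_groups), unlist(groups))
  if (length(bad)) {
    abort_sc(paste0("affected_groups contains unknown group labels: ",
                    paste(bad, collapse = ", ")), "sc_config_error")
  }
  if (!setequal(names(csds_cohort), c("SH_SUS", "SH_RES", "EE_SUS", "EE_RES"))) {
    abort_sc("csds_cohort must name SH_SUS, SH_RES, EE_SUS, EE_RES",
             "sc_config_error")
  }
  structure(list(
    n_genes = as.integer(n_genes),
    n_modules = as.integer(n_modules),
    module_size = as.integer(module_size),
    n_per_group = as.integer(n_per_group),
    baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd,
    nb_dispersion = nb_dispersion,
    libsize_log_mean = libsize_log_mean,
    libsize_log_sd = libsize_log_sd,
    module_loading_range = module_loading_range,
    de_log2fc = de_log2fc,
    susceptibility_module_id = as.integer(susceptibility_module_id),
    resilience_module_id = as.integer(resilience_module_id),
    affected_groups = affected_groups,
    behavior_effect_size = behavior_effect_size,
    n_behavior_per_group = as.integer(n_behavior_per_group),
    csds_cohort = csds_cohort,
    groups = groups,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d genes, %d modules x %d genes, %d samples/group\n",
              x$n_genes, x$n_modules, x$module_size, x$n_per_group))
  cat(sprintf("  planted log2FC %.2f in modules %d (susceptibility) and %d (resilience)\n",
              x$de_log2fc, x$susceptibility_module_id, x$resilience_module_id))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}

# the four two-group contrasts (reference first; log2FC = second - first)
sim_contrasts <- function(config) {
  list(
    A = list(
      WT_VEH_vs_WT_CORT     = c("WT_VEH", "WT_CORT"),
      hMet_VEH_vs_hMet_CORT = c("hMet_VEH", "hMet_CORT")
    ),
    B = list(
      SH_RES_vs_SH_SUS = c("SH_RES", "SH_SUS"),
      EE_RES_vs_EE_SUS = c("EE_RES", "EE_SUS")
    )
  )
}
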