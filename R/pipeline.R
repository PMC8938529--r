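#' Configuration of a full concordance run
#'
#' Bundles the simulator configuration with every stage parameter so
#' that a single object reproduces a complete run. The configuration is
#' serialized verbatim (JSON) into the output directory of
#' [run_pipeline()].
#'
#' @param sim a [sim_config()].
#' @param p_thresh,fc_thresh DEG thresholds ([call_degs()]).
#' @param prior_count log-CPM pseudo-count.
#' @param rrho_step RRHO grid step (`NULL` = `ceiling(sqrt(N))`).
#' @param beta soft power (`NULL` = scale-free selection).
#' @param min_size,cut_height,merge_height module-cut parameters.
#' @param fdr enrichment FDR level.
#' @param stages which stages to run, in order; later stages require
#'   earlier ones (`"de"` requires `"simulate"`, everything else
#'   requires `"de"` except `"behavior"`).
#' @param out_dir optional output directory for artifacts.
#' @return A `run_config` list.
#' @export
run_config <- function(sim = sim_config(),
                       p_thresh = 0.05, fc_thresh = 1.3, prior_count = 0.5,
                       rrho_step = NULL, beta = NULL,
                       min_size = 30, cut_height = NULL, merge_height = 0.25,
                       fdr = 0.05,
                       stages = c("simulate", "de", "rrho", "network",
                                  "enrich", "hubs", "behavior"),
                       out_dir = NULL) {
  stopifnot(inherits(sim, "sim_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(sim = sim, p_thresh = p_thresh, fc_thresh = fc_thresh,
                 prior_count = prior_count, rrho_step = rrho_step,
                 beta = beta, min_size = min_size, cut_height = cut_height,
                 merge_height = merge_height, fdr = fdr,
                 stages = stages, out_dir = out_dir),
            class = "run_config")
}

#' Run the full cross-model concordance pipeline
#'
#' Orchestrates simulate -> differential expression (4 two-group
#' contrasts) -> stratified RRHO (each CSDS contrast against each CORT
#' contrast, 4 comparisons) -> consensus co-expression network ->
#' module enrichment, relevance and key-module flags -> hub selection
#' for key modules -> behavioral scoring, and returns a machine-
#' readable report. With `out_dir` set, per-stage artifacts (TSV/CSV/
#' JSON) and the verbatim config are written as well.
#'
#' @param config a [run_config()].
#' @return A `pipeline_report` list: `deg_counts`, `shared_degs`,
#'   `rrho_peaks`, `n_modules`, `key_modules`, `relevance`, `hubs`,
#'   `behavior`, `cohort`, plus `seed` and the intermediate objects in
#'   `objects` (dropped from the serialized report).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  stages <- config$stages
  report <- list(seed = config$sim$seed, stages = stages)
  objects <- list()
  out <- config$out_dir
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    cfg_json <- config
    cfg_json$sim <- unclass(config$sim)
    jsonlite::write_json(cfg_json, file.path(out, "config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
  }

  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      abort_sc(paste0("stage '", name, "' failed: ", conditionMessage(e)),
               "sc_stage_error")
    })
  }

  # --- simulate ------------------------------------------------------
  sim <- run_stage("simulate", function() simulate_counts(config$sim))
  objects$sim <- sim
  if (!is.null(out)) {
    write_counts_tsv(sim$A, file.path(out, "counts_A.tsv"))
    write_counts_tsv(sim$B, file.path(out, "counts_B.tsv"))
    readr::write_csv(dplyr::bind_rows(sim$A$samples, sim$B$samples),
                     file.path(out, "samples.csv"))
    write_ground_truth(sim$truth, file.path(out, "ground_truth.json"))
  }

  contrasts <- sim_contrasts(config$sim)

  # --- differential expression --------------------------------------
  if ("de" %in% stages) {
    de <- run_stage("de", function() {
      res <- list()
      for (exp_id in names(contrasts)) {
        lcpm <- log_cpm(sim[[exp_id]], config$prior_count)
        meta <- sim[[exp_id]]$samples
        for (nm in names(contrasts[[exp_id]])) {
          cc <- contrasts[[exp_id]][[nm]]
          res[[nm]] <- moderated_t(
            lcpm,
            meta$sample[meta$group == cc[1]],
            meta$sample[meta$group == cc[2]],
            contrast = nm)
        }
      }
      res
    })
    objects$de <- de
    degs <- lapply(de, call_degs, p_thresh = config$p_thresh,
                   fc_thresh = config$fc_thresh)
    objects$degs <- degs
    report$deg_counts <- lapply(degs, function(d)
      list(up = length(d$up), down = length(d$down)))
    # the 8 directional ring sets: up-genes of each group within its contrast
    ring_sets <- list()
    ring_experiment <- character(0)
    for (exp_id in names(contrasts)) {
      for (nm in names(contrasts[[exp_id]])) {
        cc <- contrasts[[exp_id]][[nm]]
        ring_sets[[paste0(cc[1], "_up")]] <- degs[[nm]]$down
        ring_sets[[paste0(cc[2], "_up")]] <- degs[[nm]]$up
        ring_experiment[paste0(cc[1], "_up")] <- exp_id
        ring_experiment[paste0(cc[2], "_up")] <- exp_id
      }
    }
    objects$ring_sets <- ring_sets
    objects$ring_experiment <- ring_experiment
    report$shared_degs <- list(
      concordant_up = length(Reduce(intersect, lapply(degs, `[[`, "up"))),
      concordant_down = length(Reduce(intersect, lapply(degs, `[[`, "down"))))
    if (!is.null(out)) {
      for (nm in names(de)) {
        readr::write_tsv(de[[nm]]$table,
                         file.path(out, paste0("de_", nm, ".tsv")))
      }
      write_gmt(ring_sets, file.path(out, "deg_ring_sets.gmt"))
    }
  }

  # --- RRHO ----------------------------------------------------------
  if ("rrho" %in% stages && "de" %in% stages) {
    rrho <- run_stage("rrho", function() {
      ranked <- lapply(objects$de, signed_rank_score)
      maps <- list()
      for (nb in names(contrasts$B)) {
        for (na in names(contrasts$A)) {
          maps[[paste(nb, "x", na)]] <-
            rrho_map(ranked[[nb]], ranked[[na]], step = config$rrho_step)
        }
      }
      maps
    })
    objects$rrho <- rrho
    report$rrho_peaks <- lapply(rrho, function(m) {
      pk <- quadrant_peaks(m)
      stats::setNames(lapply(seq_len(nrow(pk)), function(i)
        list(present = pk$present[i], i = pk$i[i], j = pk$j[i],
             neg_log10_p = pk$neg_log10_p[i], n_overlap = pk$n_overlap[i])),
        pk$quadrant)
    })
    if (!is.null(out)) {
      for (nm in names(rrho)) {
        utils::write.table(
          rrho_grid(rrho[[nm]]),
          file.path(out, paste0("rrho_", gsub(" ", "", nm), ".tsv")),
          sep = "\t", row.names = FALSE, col.names = FALSE)
      }
      jsonlite::write_json(report$rrho_peaks,
                           file.path(out, "rrho_peaks.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }

  # --- consensus network --------------------------------------------
  if ("network" %in% stages && "de" %in% stages) {
    part <- run_stage("network", function() {
      consensus_modules(log_cpm(sim$A, config$prior_count),
                        log_cpm(sim$B, config$prior_count),
                        beta = config$beta,
                        min_size = config$min_size,
                        cut_height = config$cut_height,
                        merge_height = config$merge_height)
    })
    objects$partition <- part
    report$n_modules <- length(setdiff(unique(part$membership$module), 0L))
    report$beta <- part$beta
    if (!is.null(out)) {
      readr::write_tsv(part$membership, file.path(out, "modules.tsv"))
      readr::write_tsv(tibble::as_tibble(part$kme$mean, rownames = "gene"),
                       file.path(out, "kme_mean.tsv"))
    }
  }

  # --- enrichment / relevance / key modules -------------------------
  if ("enrich" %in% stages && !is.null(objects$partition)) {
    enr <- run_stage("enrich", function() {
      fisher_enrichment(objects$partition, objects$ring_sets,
                        background = objects$partition$membership$gene,
                        fdr = config$fdr)
    })
    objects$enrichment <- enr
    rel <- relevance_score(enr)
    keys <- key_modules(enr, objects$ring_experiment)
    objects$relevance <- rel
    objects$keys <- keys
    report$relevance <- stats::setNames(rel$relevance,
                                        paste0("M", rel$module))
    report$key_modules <- keys$module[keys$key]
    if (!is.null(out)) {
      readr::write_tsv(tibble::as_tibble(enr), file.path(out, "enrichment.tsv"))
      readr::write_tsv(rel, file.path(out, "relevance.tsv"))
    }
  }

  # --- hubs ----------------------------------------------------------
  if ("hubs" %in% stages && !is.null(objects$enrichment)) {
    hubs <- run_stage("hubs", function() {
      lapply(stats::setNames(nm = report$key_modules), function(m) {
        select_hubs(objects$partition$kme$mean, objects$partition, m,
                    degsets = objects$ring_sets,
                    tom_mat = objects$partition$consensus_tom)
      })
    })
    objects$hubs <- hubs
    report$hubs <- lapply(hubs, function(h) h$gene[h$is_hub])
    if (!is.null(out)) {
      for (m in names(hubs)) {
        readr::write_tsv(tibble::as_tibble(hubs[[m]]),
                         file.path(out, paste0("hubs_M", m, ".tsv")))
        readr::write_tsv(attr(hubs[[m]], "edges"),
                         file.path(out, paste0("edges_M", m, ".tsv")))
      }
    }
  }

  # --- behavior ------------------------------------------------------
  if ("behavior" %in% stages) {
    beh <- run_stage("behavior", function() simulate_behavior(config$sim))
    objects$behavior <- beh
    emoA <- emotionality_score(beh$A, control_group = "WT_VEH")
    pheno <- classify_si(beh$B$si_ratio)
    cohort <- cohort_proportions(table(
      phenotype = factor(pheno, c("RES", "SUS")),
      housing = factor(beh$B$factor1, c("SH", "EE"))) |> unclass())
    objects$emotionality_A <- emoA
    objects$cohort <- cohort
    report$behavior <- list(
      emotionality_group_means = tapply(emoA$emotionality, emoA$group, mean) |>
        as.list(),
      phenotype_match = mean(pheno == beh$B$factor2))
    report$cohort <- list(
      pct = stats::setNames(as.list(cohort$pct_display),
                            paste(cohort$phenotype, cohort$housing, sep = "_")),
      fisher_p = attr(cohort, "fisher_p"))
    if (!is.null(out)) {
      readr::write_csv(beh$A, file.path(out, "behavior_A.csv"))
      readr::write_csv(beh$B, file.path(out, "behavior_B.csv"))
      readr::write_csv(emoA, file.path(out, "emotionality_A.csv"))
    }
  }

  report$objects <- objects
  if (!is.null(out)) {
    slim <- report[setdiff(names(report), "objects")]
    jsonlite::write_json(slim, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  structure(report, class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  if (!is.null(x$deg_counts)) {
    cat("  DEG counts:\n")
    for (nm in names(x$deg_counts)) {
      cat(sprintf("    %-24s up %4d  down %4d\n", nm,
                  x$deg_counts[[nm]]$up, x$deg_counts[[nm]]$down))
    }
  }
  if (!is.null(x$n_modules)) {
    cat(sprintf("  consensus modules: %d (beta = %s)\n",
                x$n_modules, format(x$beta)))
  }
  if (!is.null(x$key_modules)) {
    cat(sprintf("  key modules: %s\n",
                paste(x$key_modules, collapse = ", ")))
  }
  if (!is.null(x$cohort)) {
    cat(sprintf("  cohort: %s%%\n",
                paste(names(x$cohort$pct), unlist(x$cohort$pct),
                      sep = "=", collapse = "%, ")))
  }
  invisible(x)
}
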