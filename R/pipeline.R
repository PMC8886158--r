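# 32-bit FNV-1a hash of a character scalar, returned as 8 hex digits.
# Used to fingerprint pipeline configs in output headers.
.fnv1a32 <- function(txt) {
  bytes <- as.integer(charToRaw(txt))
  h <- 2166136261
  for (b in bytes) {
    # xor with a byte touches only the low 8 bits (h kept as a double)
    h <- h - (h %% 256) + bitwXor(h %% 256, b)
    # 32-bit modular multiply by the FNV prime 16777619 = 2^24 + 403
    lo <- h %% 65536; hi <- (h - lo) / 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  # format as 8 hex digits (h may exceed .Machine$integer.max)
  paste0(sprintf("%04x", (h - h %% 65536) / 65536), sprintf("%04x", h %% 65536))
}

#' Pipeline configuration
#'
#' Bundles every threshold of the analysis together with the simulation
#' config and the output directory. All thresholds default to the values
#' used throughout the package: lncRNA selection at |logFC| > 1 and
#' FDR < 0.05, pair prevalence within [0.20, 0.80], univariate screen at
#' p < 0.01, mRNA selection at |logFC| > 2 and FDR < 0.05, ROC horizons at
#' 2/3/4 years with the cutoff taken from the 3-year curve.
#'
#' @param seed master seed (propagated to the simulation and every seeded
#'   stage).
#' @param sim a \code{sim_config}; defaults to \code{sim_config(seed)}.
#' @param lfc_lncrna,fdr_lncrna specific-lncRNA selection thresholds.
#' @param prevalence_lower,prevalence_upper pair prevalence bounds.
#' @param screen_alpha univariate Cox Wald threshold.
#' @param lasso_folds,lasso_rule cross-validation folds and lambda rule.
#' @param lfc_mrna,fdr_mrna differential-mRNA thresholds.
#' @param consensus target-table consensus mode ("all" or "any").
#' @param horizons ROC horizons in days; \code{cutoff_horizon} picks the
#'   curve used for the risk cutoff.
#' @param cutoff_horizon horizon whose ROC defines the cutoff.
#' @param gsea_nperm GSEA permutations.
#' @param out_dir optional output directory; when non-NULL, stage artifacts
#'   are written there.
#' @return Object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(seed = 1,
                            sim = NULL,
                            lfc_lncrna = 1, fdr_lncrna = 0.05,
                            prevalence_lower = 0.20, prevalence_upper = 0.80,
                            screen_alpha = 0.01,
                            lasso_folds = 10, lasso_rule = "min",
                            lfc_mrna = 2, fdr_mrna = 0.05,
                            consensus = "all",
                            horizons = c(730, 1095, 1460),
                            cutoff_horizon = 1095,
                            gsea_nperm = 1000,
                            out_dir = NULL) {
  if (is.null(sim)) sim <- sim_config(seed = seed)
  stopifnot(lfc_lncrna >= 0, fdr_lncrna > 0, fdr_lncrna <= 1,
            prevalence_lower >= 0, prevalence_upper <= 1,
            prevalence_lower < prevalence_upper,
            screen_alpha > 0, screen_alpha <= 1,
            lfc_mrna >= 0, cutoff_horizon %in% horizons)
  structure(list(seed = as.integer(seed), sim = sim,
                 lfc_lncrna = lfc_lncrna, fdr_lncrna = fdr_lncrna,
                 prevalence_lower = prevalence_lower,
                 prevalence_upper = prevalence_upper,
                 screen_alpha = screen_alpha,
                 lasso_folds = lasso_folds, lasso_rule = lasso_rule,
                 lfc_mrna = lfc_mrna, fdr_mrna = fdr_mrna,
                 consensus = consensus,
                 horizons = horizons, cutoff_horizon = cutoff_horizon,
                 gsea_nperm = gsea_nperm, out_dir = out_dir),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param cfg a \code{pipeline_config}.
#' @export
config_hash <- function(cfg) {
  canon <- cfg
  canon$out_dir <- NULL
  .fnv1a32(as.character(jsonlite::toJSON(unclass(canon), auto_unbox = TRUE,
                                         digits = NA, force = TRUE)))
}

#' Run the full synthetic analysis pipeline
#'
#' Executes every stage in order: simulate the immune panel and tumor
#' cohort; quantile-normalize and (if batched) batch-adjust the panel;
#' select T-cell-specific lncRNAs; intersect with the cohort and build the
#' prevalence-filtered pair matrix; univariate Cox screen, Lasso-Cox
#' selection and multivariate fit; risk scores, time-dependent ROC curves
#' and the Youden cutoff; risk-group survival and clinical associations;
#' differential mRNAs, ceRNA network and enrichment; GSEA, infiltration,
#' gene correlates, four-group survival and drug-sensitivity comparisons.
#'
#' Any stage failure aborts with the stage name; completed artifacts are
#' kept in the returned (partial) structure attached to the error
#' condition. The returned summary carries the config hash and seed and is
#' byte-identical across reruns of the same config.
#'
#' @param cfg a \code{pipeline_config}.
#' @return List with \code{summary} (funnel counts and headline statistics)
#'   and \code{artifacts} (every intermediate object by stage name).
#' @export
run_full_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  art <- list()
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      cond <- simpleError(sprintf("pipeline stage '%s' failed: %s", name,
                                  conditionMessage(e)))
      cond$artifacts <- art
      stop(cond)
    })
    art[[name]] <<- res
    res
  }

  panel <- stage("panel", generate_immune_panel(cfg$sim))
  cohort <- stage("cohort", generate_tumor_cohort(cfg$sim))
  inter <- stage("interactions", generate_interaction_tables(cfg$sim))
  aux <- stage("auxiliary", generate_auxiliary_tables(cfg$sim, cohort))

  norm <- stage("normalize", {
    x <- quantile_normalize(panel$expr)
    if (nlevels(panel$batch) > 1) x <- batch_adjust(x, panel$batch) else x
  })
  # logFC orientation: first factor level is "A", so the T-cell group leads
  de_lnc <- stage("de_lncrna", {
    grp <- factor(ifelse(panel$celltype == "T_cell", "T_cell", "other"),
                  levels = c("T_cell", "other"))
    differential_expression(norm, grp)
  })
  specific <- stage("specific_lncrnas",
                    select_specific_lncrnas(de_lnc, cfg$lfc_lncrna,
                                            cfg$fdr_lncrna))

  tumor_expr <- cohort$expr[, cohort$sample_type == "tumor"]
  tumor_lnc <- tumor_expr[gene_biotype(tumor_expr) == "lncRNA", ]
  shared_lncs <- stage("cohort_lncrnas",
                suppressWarnings(intersect_with_cohort(specific, tumor_lnc)))

  # A null configuration (no specific lncRNAs, or nothing survives the
  # screen/Lasso) completes gracefully: the signature is flagged
  # non-prognostic and score-dependent stages are skipped.
  non_prognostic <- FALSE
  why <- ""
  pm_all <- pm <- NULL
  screen <- list(candidates = character())
  lasso <- list(selected = character(), lambda = NA_real_)
  if (length(shared_lncs) < 2L) {
    non_prognostic <- TRUE
    why <- "fewer than 2 specific lncRNAs present in the cohort"
  } else {
    pm_all <- stage("pairs", build_pair_matrix(tumor_lnc, shared_lncs))
    pm <- stage("pairs_filtered",
                prevalence_filter(pm_all, cfg$prevalence_lower,
                                  cfg$prevalence_upper))
    if (nrow(pm) < 1L) {
      non_prognostic <- TRUE
      why <- "no pair passed the prevalence filter"
    } else {
      screen <- stage("screen", univariate_cox_screen(pm, cohort$surv,
                                                      cfg$screen_alpha))
      if (length(screen$candidates) < 1L) {
        non_prognostic <- TRUE
        why <- "no pair passed the univariate screen"
      } else {
        lasso <- stage("lasso",
                       suppressWarnings(lasso_cox_select(
                         pm, screen$candidates, cohort$surv,
                         folds = cfg$lasso_folds, seed = cfg$seed,
                         rule = cfg$lasso_rule)))
        if (!length(lasso$selected)) {
          non_prognostic <- TRUE
          why <- "all Lasso coefficients shrunk to zero"
        }
      }
    }
  }

  if (non_prognostic) return(.finish_null_pipeline(cfg, art, specific, shared_lncs,
                                                   pm_all, pm, screen, why))
  sig <- stage("signature",
               multivariate_cox_fit(pm, lasso$selected, cohort$surv,
                                    seed = cfg$seed, folds = cfg$lasso_folds,
                                    lambda = lasso$lambda,
                                    horizon = cfg$cutoff_horizon))
  scores <- stage("scores", risk_score(sig$model, pm))
  rocs <- stage("roc", {
    hs <- cfg$horizons[cfg$horizons <= max(cohort$surv$time)]
    stats::setNames(lapply(hs, function(h)
      time_dependent_roc(scores, cohort$surv, h)), paste0("t", hs))
  })
  roc_cut <- rocs[[paste0("t", cfg$cutoff_horizon)]]
  if (is.null(roc_cut)) roc_cut <- rocs[[length(rocs)]]
  sig$model$cutoff <- stage("cutoff", select_cutoff(roc_cut))
  art$signature <- sig
  groups <- stage("groups", assign_risk_groups(scores, sig$model$cutoff))
  km <- stage("km", km_logrank(groups, cohort$surv))
  clin_uni <- stage("clinical_cox_uni",
                    clinical_cox(cohort$surv, scores, "univariate"))
  clin_multi <- stage("clinical_cox_multi",
                      clinical_cox(cohort$surv, scores, "multivariate"))
  assoc <- stage("associations",
                 group_association_tests(groups, cohort$surv, scores,
                                         mc_seed = cfg$seed))
  strat <- stage("stratified",
                 stratified_analysis(cohort$surv, groups, "stage", scores))

  de_m <- stage("de_mrna",
                de_mrna(cohort$expr, cohort$sample_type,
                        lfc = cfg$lfc_mrna, fdr_threshold = cfg$fdr_mrna))
  targ <- stage("targets",
                predict_targets(specific, inter$lnc_mirna,
                                inter$target_tables, cfg$consensus))
  hubs <- stage("hubs", hub_mrnas(targ$mrnas, de_m$genes))
  net <- stage("network",
               assemble_network(hubs, inter$lnc_mirna, inter$target_tables,
                                cfg$consensus))
  enr <- stage("enrichment", {
    universe <- rownames(cohort$expr)[gene_biotype(cohort$expr) == "mRNA"]
    terms <- c(aux$gene_sets,
               list(PLANTED_DE_BLOCK = cohort$truth$de_mrnas))
    if (length(hubs)) enrichment_test(hubs, terms, universe)
    else data.frame()
  })

  tumor_mrna <- tumor_expr[gene_biotype(tumor_expr) == "mRNA", ]
  gsea_res <- stage("gsea", {
    pheno <- factor(ifelse(groups == "low", "low", "high"),
                    levels = c("low", "high"))
    gsea(tumor_mrna, pheno, aux$gene_sets, n_perm = cfg$gsea_nperm,
         seed = cfg$seed)
  })
  inf_diff <- stage("infiltration_diff",
                    infiltration_diff(aux$infiltration, groups))
  inf_cor <- stage("infiltration_correlation",
                   infiltration_correlation(scores, aux$infiltration))
  panel_genes <- utils::head(cohort$truth$immune_program, 4)
  correl <- stage("gene_correlates",
                  gene_correlates(tumor_mrna, groups, panel_genes, scores))
  fourg <- stage("four_group",
                 four_group_survival(groups,
                                     unclass(tumor_mrna)[panel_genes[1], ],
                                     cohort$surv))
  drugs <- stage("drugs", drug_sensitivity_diff(aux$ic50, groups))

  summary <- list(
    config_hash = config_hash(cfg),
    seed = cfg$seed,
    non_prognostic = FALSE,
    reason = "",
    funnel = list(
      n_panel_lncrnas = nrow(panel$expr),
      n_specific_lncrnas = length(specific),
      n_cohort_lncrnas = length(shared_lncs),
      n_pairs_built = nrow(pm_all),
      n_pairs_prevalence = nrow(pm),
      n_screen_candidates = length(screen$candidates),
      n_lasso_selected = length(lasso$selected),
      n_signature_pairs = length(sig$model$pairs),
      n_de_mrnas = length(de_m$genes),
      n_predicted_mrnas = length(targ$mrnas),
      n_hub_mrnas = length(hubs)),
    model = list(cutoff = sig$model$cutoff,
                 lambda = lasso$lambda,
                 auc = lapply(rocs, `[[`, "auc"),
                 logrank_p = km$p),
    immune = list(gsea_nes = stats::setNames(gsea_res$nes, gsea_res$set),
                  gsea_fdr = stats::setNames(gsea_res$fdr_q, gsea_res$set),
                  drug_p = stats::setNames(drugs$p, drugs$drug)))
  out <- list(summary = summary, artifacts = art)
  if (!is.null(cfg$out_dir)) .write_pipeline_artifacts(cfg, out)
  out
}

# Wrap up a run whose signature is empty: the ceRNA branch (which depends
# only on the specific lncRNAs) still executes; score-dependent stages are
# skipped and the summary is flagged non-prognostic.
.finish_null_pipeline <- function(cfg, art, specific, shared_lncs, pm_all, pm,
                                  screen, why) {
  cohort <- art$cohort; inter <- art$interactions
  de_m <- tryCatch(de_mrna(cohort$expr, cohort$sample_type,
                           lfc = cfg$lfc_mrna, fdr_threshold = cfg$fdr_mrna),
                   error = function(e) list(table = data.frame(),
                                            genes = character()))
  art$de_mrna <- de_m
  targ <- predict_targets(specific, inter$lnc_mirna, inter$target_tables,
                          cfg$consensus)
  art$targets <- targ
  hubs <- hub_mrnas(targ$mrnas, de_m$genes)
  art$hubs <- hubs
  art$network <- suppressWarnings(
    assemble_network(hubs, inter$lnc_mirna, inter$target_tables,
                     cfg$consensus))
  summary <- list(
    config_hash = config_hash(cfg),
    seed = cfg$seed,
    non_prognostic = TRUE,
    reason = why,
    funnel = list(
      n_panel_lncrnas = nrow(art$panel$expr),
      n_specific_lncrnas = length(specific),
      n_cohort_lncrnas = length(shared_lncs),
      n_pairs_built = if (is.null(pm_all)) 0L else nrow(pm_all),
      n_pairs_prevalence = if (is.null(pm)) 0L else nrow(pm),
      n_screen_candidates = length(screen$candidates),
      n_lasso_selected = 0L,
      n_signature_pairs = 0L,
      n_de_mrnas = length(de_m$genes),
      n_predicted_mrnas = length(targ$mrnas),
      n_hub_mrnas = length(hubs)),
    model = list(cutoff = NA, lambda = NA, auc = list(), logrank_p = NA),
    immune = list())
  out <- list(summary = summary, artifacts = art)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

.write_pipeline_artifacts <- function(cfg, run) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- c(sprintf("# config_hash: %s", run$summary$config_hash),
           sprintf("# seed: %d", run$summary$seed))
  w <- function(name) file.path(cfg$out_dir, name)
  jsonlite::write_json(run$summary, w("summary.json"), auto_unbox = TRUE,
                       digits = NA)
  write_signature_json(run$artifacts$signature$model, w("signature.json"))
  write_pair_tsv(run$artifacts$pairs_filtered, w("pair_matrix.tsv"))
  for (nm in names(run$artifacts$roc))
    write_roc_tsv(run$artifacts$roc[[nm]], w(sprintf("roc_%s.tsv", nm)))
  km_path <- w("km_curves.tsv")
  writeLines(hdr, km_path)
  suppressWarnings(utils::write.table(run$artifacts$km$curves, km_path,
                                      sep = "\t", quote = FALSE,
                                      row.names = FALSE, append = TRUE))
  utils::write.table(run$artifacts$screen$fits, w("univariate_cox.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(run$artifacts$signature$fits, w("multivariate_cox.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_network_tsv(run$artifacts$network, w("cerna_edges.tsv"))
  write_network_sif(run$artifacts$network, w("cerna.sif"))
  if (nrow(run$artifacts$enrichment))
    utils::write.table(run$artifacts$enrichment, w("enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(run$artifacts$gsea, w("gsea.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(run$artifacts$drugs, w("drug_sensitivity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(cfg$out_dir)
}

#' Render a human-readable report from pipeline artifacts
#'
#' Writes the headline tables (funnel, KM curves, ROC points, network
#' statistics) as TSV plus simple KM / ROC / funnel plots in one PDF.
#' Sections whose artifact is missing are skipped with a notice. Rerunning
#' on the same artifacts reproduces the tables byte-for-byte.
#'
#' @param run result of [run_full_pipeline()].
#' @param dir output directory.
#' @param plots logical; also draw the PDF figures (default TRUE).
#' @return Invisibly, the directory; attribute \code{"sections"} lists the
#'   rendered/skipped sections.
#' @export
render_report <- function(run, dir, plots = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sections <- character()
  note <- function(s) sections <<- c(sections, s)
  a <- run$artifacts

  funnel <- data.frame(step = names(run$summary$funnel),
                       count = unlist(run$summary$funnel), row.names = NULL)
  utils::write.table(funnel, file.path(dir, "funnel.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  note("funnel")

  if (!is.null(a$km)) {
    utils::write.table(a$km$curves, file.path(dir, "km_curves.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    note("km")
  } else note("km: skipped (missing artifact)")

  if (!is.null(a$roc)) {
    for (nm in names(a$roc))
      write_roc_tsv(a$roc[[nm]], file.path(dir, sprintf("roc_%s.tsv", nm)))
    note("roc")
  } else note("roc: skipped (missing artifact)")

  if (!is.null(a$network)) {
    nstat <- data.frame(metric = c("n_lncRNA", "n_miRNA", "n_mRNA", "n_edges"),
                        value = c(sum(a$network$nodes$type == "lncRNA"),
                                  sum(a$network$nodes$type == "miRNA"),
                                  sum(a$network$nodes$type == "mRNA"),
                                  nrow(a$network$edges)))
    utils::write.table(nstat, file.path(dir, "network_stats.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    note("network")
  } else note("network: skipped (missing artifact)")

  if (plots) {
    grDevices::pdf(file.path(dir, "report.pdf"), width = 7, height = 5)
    on.exit(grDevices::dev.off())
    graphics::barplot(funnel$count, names.arg = funnel$step, las = 2,
                      cex.names = 0.6, main = "Selection funnel")
    if (!is.null(a$km)) {
      cur <- a$km$curves
      graphics::plot(NULL, xlim = range(cur$time), ylim = c(0, 1),
                     xlab = "time", ylab = "survival",
                     main = "Kaplan-Meier by risk group")
      for (g in unique(cur$group)) {
        cg <- cur[cur$group == g, ]
        graphics::lines(stats::stepfun(cg$time, c(1, cg$survival)),
                        do.points = FALSE)
      }
    }
    if (!is.null(a$roc)) {
      for (nm in names(a$roc)) {
        r <- a$roc[[nm]]
        graphics::plot(1 - r$spec, r$sens, type = "l", xlab = "1 - specificity",
                       ylab = "sensitivity",
                       main = sprintf("Time-dependent ROC %s (AUC %.3f)",
                                      nm, r$auc))
        graphics::abline(0, 1, lty = 3)
      }
    }
  }
  structure(invisible(dir), sections = sections)
}
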