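#' Simulation configuration
#'
#' Defines every knob of the synthetic study: the immune expression panel
#' with planted T-cell-specific lncRNAs, the tumor cohort whose Weibull
#' proportional-hazards survival is driven by planted lncRNA-pair
#' indicators, the interaction tables with planted lncRNA-miRNA-mRNA triads,
#' and the auxiliary gene-set / infiltration / IC50 tables.
#'
#' Expression is generated directly on the log2(x+1) scale (no count
#' model): the pair features downstream are rank-based within samples, so
#' only the ordering of values matters.
#'
#' @param seed integer master seed; all generators derive their streams
#'   from it.
#' @param n_immune_celltypes number of immune cell types in the panel
#'   (>= 2; the first is the T-cell type).
#' @param n_samples_per_type samples per cell type (>= 3).
#' @param n_lncrnas number of lncRNAs simulated (shared between panel and
#'   cohort).
#' @param n_specific number of planted T-cell-specific lncRNAs.
#' @param specific_logfc planted log2 fold change of specific lncRNAs in
#'   T cells (> 1 so they pass the default selection threshold).
#' @param n_patients tumor cohort size.
#' @param n_normals matched normal samples (for tumor-vs-normal mRNA DE).
#' @param planted_pairs data.frame with columns \code{lnc_a}, \code{lnc_b},
#'   \code{beta} and optionally \code{prevalence} (target indicator
#'   prevalence, default 0.5). May have zero rows (null cohort).
#' @param censoring_fraction fraction of patients censored, in [0, 1].
#' @param baseline_scale,baseline_shape Weibull baseline survival
#'   parameters (time unit: days).
#' @param noise_sd residual SD of expression values on the log2 scale.
#' @param n_mirnas,n_mrnas numbers of miRNAs / mRNAs.
#' @param n_de_mrnas number of mRNAs planted as tumor-vs-normal
#'   differential (log2 FC \code{de_logfc}).
#' @param de_logfc planted tumor-vs-normal mRNA log2 fold change.
#' @param n_planted_triads number of complete lncRNA-miRNA-mRNA chains
#'   whose mRNA is in every target table and differentially expressed.
#' @param immune_program_size number of mRNAs coupled negatively to the
#'   risk linear predictor (the planted "immune program" gene set).
#' @param immune_coupling log2 expression change per SD of the risk linear
#'   predictor for immune-program genes.
#' @param infiltration_cor planted correlation between infiltration scores
#'   and the risk linear predictor (negative by default).
#' @param n_infiltration_celltypes infiltration columns.
#' @param ic50_shift planted group IC50 shift in SD units (two planted
#'   drugs, opposite directions, plus null drugs).
#' @param n_null_drugs number of drugs with no planted shift.
#' @param n_batches,batch_sd optional additive batch structure of the
#'   immune panel (a single scalar offset per batch).
#' @param confound_covariates if TRUE, tumor stage contributes to the
#'   hazard (covariates are independent of the planted pairs either way).
#' @return Object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(seed = 1,
                       n_immune_celltypes = 4,
                       n_samples_per_type = 20,
                       n_lncrnas = 200,
                       n_specific = 75,
                       specific_logfc = 2,
                       n_patients = 300,
                       n_normals = 40,
                       planted_pairs = NULL,
                       censoring_fraction = 0.3,
                       baseline_scale = 2000,
                       baseline_shape = 1.2,
                       noise_sd = 1,
                       n_mirnas = 30,
                       n_mrnas = 500,
                       n_de_mrnas = 40,
                       de_logfc = 2.5,
                       n_planted_triads = 5,
                       immune_program_size = 30,
                       immune_coupling = 0.8,
                       infiltration_cor = -0.5,
                       n_infiltration_celltypes = 8,
                       ic50_shift = 1,
                       n_null_drugs = 2,
                       n_batches = 1,
                       batch_sd = 0,
                       confound_covariates = FALSE) {
  if (is.null(planted_pairs)) {
    ids <- .lnc_ids(n_lncrnas)
    planted_pairs <- data.frame(
      lnc_a = ids[c(1, 3, 5)], lnc_b = ids[c(2, 4, 6)],
      beta = c(0.8, -0.8, 0.6), prevalence = 0.5,
      stringsAsFactors = FALSE)
  }
  if (nrow(planted_pairs) && !"prevalence" %in% names(planted_pairs))
    planted_pairs$prevalence <- 0.5
  cfg <- list(seed = as.integer(seed),
              n_immune_celltypes = n_immune_celltypes,
              n_samples_per_type = n_samples_per_type,
              n_lncrnas = n_lncrnas, n_specific = n_specific,
              specific_logfc = specific_logfc,
              n_patients = n_patients, n_normals = n_normals,
              planted_pairs = planted_pairs,
              censoring_fraction = censoring_fraction,
              baseline_scale = baseline_scale,
              baseline_shape = baseline_shape,
              noise_sd = noise_sd,
              n_mirnas = n_mirnas, n_mrnas = n_mrnas,
              n_de_mrnas = n_de_mrnas, de_logfc = de_logfc,
              n_planted_triads = n_planted_triads,
              immune_program_size = immune_program_size,
              immune_coupling = immune_coupling,
              infiltration_cor = infiltration_cor,
              n_infiltration_celltypes = n_infiltration_celltypes,
              ic50_shift = ic50_shift, n_null_drugs = n_null_drugs,
              n_batches = n_batches, batch_sd = batch_sd,
              confound_covariates = confound_covariates)
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param cfg a list of configuration values.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_immune_celltypes >= 2, cfg$n_samples_per_type >= 3,
            cfg$n_lncrnas >= 2, cfg$n_specific >= 0,
            cfg$specific_logfc > 0, cfg$n_patients >= 2,
            cfg$censoring_fraction >= 0, cfg$censoring_fraction <= 1,
            cfg$baseline_scale > 0, cfg$baseline_shape > 0,
            cfg$noise_sd > 0, cfg$n_mirnas >= 1, cfg$n_mrnas >= 1,
            cfg$n_planted_triads >= 0)
  if (cfg$n_specific > cfg$n_lncrnas)
    stop("invalid config: n_specific exceeds n_lncrnas")
  ids <- .lnc_ids(cfg$n_lncrnas)
  pp <- cfg$planted_pairs
  if (nrow(pp)) {
    if (!all(c(pp$lnc_a, pp$lnc_b) %in% ids))
      stop("invalid config: planted pair ids not among generated lncRNA ids")
    if (!all(is.finite(pp$beta)))
      stop("invalid config: planted pair betas must be finite")
    if (any(pp$lnc_a == pp$lnc_b)) stop("invalid config: degenerate pair")
  }
  if (cfg$n_planted_triads > 0 &&
      cfg$n_planted_triads > min(cfg$n_specific, floor(cfg$n_mirnas / 2),
                                 cfg$n_de_mrnas, cfg$n_mrnas))
    stop("invalid config: n_planted_triads exceeds available ids")
  structure(cfg, class = "sim_config")
}

.lnc_ids  <- function(n) sprintf("LNC%04d", seq_len(n))
.mrna_ids <- function(n) sprintf("MRNA%04d", seq_len(n))
.mir_ids  <- function(n) sprintf("MIR%03d", seq_len(n))

#' @rdname sim_config
#' @param path YAML file path.
#' @export
read_sim_config <- function(path) {
  obj <- yaml::read_yaml(path)
  if (!is.null(obj$planted_pairs))
    obj$planted_pairs <- as.data.frame(lapply(obj$planted_pairs, unlist),
                                       stringsAsFactors = FALSE)
  do.call(sim_config, obj)
}

#' @rdname sim_config
#' @export
write_sim_config <- function(cfg, path) {
  obj <- unclass(cfg)
  obj$planted_pairs <- as.list(obj$planted_pairs)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Generate the multi-cell-type immune expression panel
#'
#' Log2-scale lncRNA expression for \code{n_immune_celltypes} cell types
#' (the first is the T-cell type), with the first \code{n_specific} lncRNAs
#' shifted up by \code{specific_logfc} in T-cell samples. Optional additive
#' batch offsets.
#'
#' @param cfg a \code{sim_config}.
#' @return List: \code{expr} (an \code{expr_matrix}, biotype lncRNA),
#'   \code{celltype} (factor, first level \code{"T_cell"}), \code{batch}
#'   (factor), \code{specific} (planted specific lncRNA ids).
#' @export
generate_immune_panel <- function(cfg) {
  cfg <- validate_sim_config(cfg)
  set.seed(cfg$seed)
  genes <- .lnc_ids(cfg$n_lncrnas)
  specific <- genes[seq_len(cfg$n_specific)]
  types <- c("T_cell", paste0("Other", seq_len(cfg$n_immune_celltypes - 1)))
  celltype <- factor(rep(types, each = cfg$n_samples_per_type), levels = types)
  n_samp <- length(celltype)
  samples <- sprintf("IMM%03d", seq_len(n_samp))
  mu <- stats::rnorm(cfg$n_lncrnas, mean = 6, sd = 1.5)
  x <- matrix(stats::rnorm(cfg$n_lncrnas * n_samp, sd = cfg$noise_sd),
              cfg$n_lncrnas, n_samp, dimnames = list(genes, samples)) + mu
  if (cfg$n_specific > 0)
    x[specific, celltype == "T_cell"] <-
      x[specific, celltype == "T_cell"] + cfg$specific_logfc
  batch <- factor(rep_len(paste0("batch", seq_len(cfg$n_batches)), n_samp))
  if (cfg$n_batches > 1 && cfg$batch_sd > 0) {
    off <- stats::rnorm(cfg$n_batches, sd = cfg$batch_sd)
    x <- x + rep(off[as.integer(batch)], each = cfg$n_lncrnas)
  }
  list(expr = expr_matrix(x, "lncRNA"), celltype = celltype, batch = batch,
       specific = specific)
}

#' Generate the tumor cohort: expression, survival, clinical covariates
#'
#' lncRNA and mRNA expression for tumor and matched normal samples, plus a
#' survival table for the tumor samples. The hazard follows a Weibull
#' proportional-hazards model \code{h(t) = h0(t) exp(sum_k beta_k z_k)}
#' where \code{z_k} is the 0/1 indicator of planted pair k computed from
#' the generated expression. Censoring times are independent exponential,
#' with the rate calibrated by root-finding so the expected censoring
#' fraction equals \code{censoring_fraction}.
#'
#' The prevalence of a planted pair (a, b) is tuned by the mean difference
#' of the two genes: with both genes having residual SD \code{noise_sd},
#' P(indicator = 1) = pnorm((mu_a - mu_b) / (noise_sd * sqrt(2))), so the
#' generator sets mu_a - mu_b = qnorm(prevalence) * noise_sd * sqrt(2).
#'
#' @param cfg a \code{sim_config}.
#' @return List: \code{expr} (\code{expr_matrix}, tumor + normal columns),
#'   \code{sample_type} (factor tumor/normal), \code{surv} (survival table
#'   for tumor samples), \code{truth} (planted pair keys, per-patient
#'   linear predictor, planted DE mRNA ids, immune-program mRNA ids).
#' @export
generate_tumor_cohort <- function(cfg) {
  cfg <- validate_sim_config(cfg)
  set.seed(cfg$seed + 1L)
  lnc <- .lnc_ids(cfg$n_lncrnas); mr <- .mrna_ids(cfg$n_mrnas)
  pats <- sprintf("PAT%04d", seq_len(cfg$n_patients))
  norms <- sprintf("NRM%04d", seq_len(cfg$n_normals))
  samples <- c(pats, norms)
  n_samp <- length(samples)

  mu_l <- stats::rnorm(cfg$n_lncrnas, 6, 1.5)
  names(mu_l) <- lnc
  pp <- cfg$planted_pairs
  if (nrow(pp)) {
    # prevalence control: mu_a - mu_b = qnorm(prev) * noise_sd * sqrt(2)
    delta <- stats::qnorm(pp$prevalence) * cfg$noise_sd * sqrt(2)
    mu_l[pp$lnc_b] <- mu_l[pp$lnc_a] - delta
  }
  xl <- matrix(stats::rnorm(cfg$n_lncrnas * n_samp, sd = cfg$noise_sd),
               cfg$n_lncrnas, n_samp, dimnames = list(lnc, samples)) + mu_l

  de_ids <- .mrna_ids(cfg$n_mrnas)[seq_len(min(cfg$n_de_mrnas, cfg$n_mrnas))]
  prog_ids <- setdiff(mr, de_ids)[seq_len(min(cfg$immune_program_size,
                                              cfg$n_mrnas - length(de_ids)))]
  mu_m <- stats::rnorm(cfg$n_mrnas, 7, 1.5)
  xm <- matrix(stats::rnorm(cfg$n_mrnas * n_samp, sd = cfg$noise_sd),
               cfg$n_mrnas, n_samp, dimnames = list(mr, samples)) + mu_m
  xm[de_ids, pats] <- xm[de_ids, pats] + cfg$de_logfc

  # planted pair indicators and risk linear predictor (tumor samples)
  z <- if (nrow(pp))
    sapply(seq_len(nrow(pp)), function(k)
      as.numeric(xl[pp$lnc_a[k], pats] > xl[pp$lnc_b[k], pats]))
  else matrix(0, cfg$n_patients, 0)
  lp <- if (ncol(z)) drop(z %*% pp$beta) else rep(0, cfg$n_patients)

  # clinical covariates (independent of the planted pairs)
  age <- pmin(pmax(round(stats::rnorm(cfg$n_patients, 61, 10)), 25), 90)
  sex <- sample(c("male", "female"), cfg$n_patients, TRUE, c(0.73, 0.27))
  grade <- sample(paste0("G", 1:4), cfg$n_patients, TRUE, c(0.1, 0.45, 0.35, 0.1))
  stage <- sample(paste0("stage", 1:4), cfg$n_patients, TRUE, c(0.1, 0.15, 0.25, 0.5))
  t_st <- sample(paste0("T", 1:4), cfg$n_patients, TRUE, c(0.15, 0.3, 0.3, 0.25))
  n_st <- sample(paste0("N", 0:3), cfg$n_patients, TRUE, c(0.45, 0.2, 0.3, 0.05))
  m_st <- sample(paste0("M", 0:1), cfg$n_patients, TRUE, c(0.97, 0.03))
  lp_total <- lp
  if (isTRUE(cfg$confound_covariates))
    lp_total <- lp_total + 0.3 * (as.numeric(gsub("stage", "", stage)) - 2.5)

  # immune program: coupled negatively to risk in tumor samples
  if (length(prog_ids) && stats::sd(lp_total) > 0) {
    zlp <- as.numeric(scale(lp_total))
    xm[prog_ids, pats] <- xm[prog_ids, pats] -
      cfg$immune_coupling * rep(zlp, each = length(prog_ids))
  }

  # Weibull PH survival: T = scale * (-log U / exp(lp))^(1/shape)
  u <- stats::runif(cfg$n_patients)
  tev <- cfg$baseline_scale * (-log(u) / exp(lp_total))^(1 / cfg$baseline_shape)
  if (any(!is.finite(tev)) || any(tev <= 0))
    stop("internal error: non-positive survival time generated")
  if (cfg$censoring_fraction <= 0) {
    time <- tev; event <- rep(1L, cfg$n_patients)
  } else if (cfg$censoring_fraction >= 1) {
    time <- tev / 2; event <- rep(0L, cfg$n_patients)
  } else {
    f <- function(rate) mean(1 - exp(-rate * tev)) - cfg$censoring_fraction
    rate <- stats::uniroot(f, c(1e-10, 1e3), extendInt = "upX")$root
    cens <- stats::rexp(cfg$n_patients, rate)
    time <- pmin(tev, cens); event <- as.integer(tev <= cens)
  }

  expr <- expr_matrix(rbind(xl, xm),
                      c(rep("lncRNA", cfg$n_lncrnas), rep("mRNA", cfg$n_mrnas)))
  surv <- data.frame(sample_id = pats, time = time, event = event,
                     age = age, sex = sex, grade = grade, stage = stage,
                     t_stage = t_st, n_stage = n_st, m_stage = m_st,
                     stringsAsFactors = FALSE)
  truth <- list(pair_keys = if (nrow(pp)) paste(pp$lnc_a, pp$lnc_b, sep = "|")
                            else character(),
                planted_pairs = pp,
                lp = stats::setNames(lp_total, pats),
                de_mrnas = de_ids, immune_program = prog_ids)
  list(expr = expr,
       sample_type = factor(rep(c("tumor", "normal"),
                                c(cfg$n_patients, cfg$n_normals)),
                            levels = c("tumor", "normal")),
       surv = validate_survival(surv), truth = truth)
}

#' Generate lncRNA-miRNA and miRNA-mRNA interaction tables
#'
#' Plants \code{n_planted_triads} complete lncRNA-miRNA-mRNA chains whose
#' mRNA appears in all three miRNA-target tables and is generated as
#' differentially expressed in the tumor cohort. Decoy edges are added that
#' each break at least one of those conditions: a non-specific lncRNA edge,
#' a target present in only two of the three tables, a non-differential
#' consensus target, and a miRNA unreachable from the specific lncRNAs.
#'
#' @param cfg a \code{sim_config}.
#' @return List: \code{lnc_mirna} (interaction table), \code{target_tables}
#'   (named list of three miRNA-mRNA tables), \code{truth} (planted lnc,
#'   miRNA, mRNA ids).
#' @export
generate_interaction_tables <- function(cfg) {
  cfg <- validate_sim_config(cfg)
  set.seed(cfg$seed + 2L)
  nt <- cfg$n_planted_triads
  lnc <- .lnc_ids(cfg$n_lncrnas); mir <- .mir_ids(cfg$n_mirnas)
  de_ids <- .mrna_ids(cfg$n_mrnas)[seq_len(min(cfg$n_de_mrnas, cfg$n_mrnas))]
  specific <- lnc[seq_len(max(cfg$n_specific, 1L))]

  p_lnc <- specific[seq_len(nt)]
  p_mir <- mir[seq_len(nt)]
  p_mrna <- de_ids[seq_len(nt)]

  lm <- data.frame(source_id = p_lnc, target_id = p_mir,
                   source_db = rep("mircode_synth", nt),
                   stringsAsFactors = FALSE)
  dbs <- c("mirdb_synth", "mirtarbase_synth", "targetscan_synth")
  tt <- lapply(dbs, function(db)
    data.frame(source_id = p_mir, target_id = p_mrna,
               source_db = rep(db, nt), stringsAsFactors = FALSE))
  names(tt) <- dbs

  # decoys, one batch per planted triad (4 decoy edges each)
  decoy_mir <- mir[rev(seq_len(cfg$n_mirnas))][seq_len(nt)]
  nonspec_lnc <- rev(lnc)[seq_len(nt)]
  nonde <- setdiff(.mrna_ids(cfg$n_mrnas), de_ids)
  for (i in seq_len(nt)) {
    # (a) lncRNA outside the specific list -> unreachable chain
    lm <- rbind(lm, data.frame(source_id = nonspec_lnc[i],
                               target_id = decoy_mir[i],
                               source_db = "mircode_synth"))
    # (b) target of a planted miRNA present in only 2 of 3 tables
    two_tab <- rev(nonde)[i]
    for (db in dbs[1:2])
      tt[[db]] <- rbind(tt[[db]], data.frame(source_id = p_mir[i],
                                             target_id = two_tab,
                                             source_db = db))
    # (c) consensus target that is not differentially expressed
    cons_nonde <- nonde[i]
    for (db in dbs)
      tt[[db]] <- rbind(tt[[db]], data.frame(source_id = p_mir[i],
                                             target_id = cons_nonde,
                                             source_db = db))
    # (d) decoy miRNA (no lncRNA among the specific list) hitting a DE mRNA
    de_extra <- de_ids[(nt + i - 1) %% length(de_ids) + 1]
    for (db in dbs)
      tt[[db]] <- rbind(tt[[db]], data.frame(source_id = decoy_mir[i],
                                             target_id = de_extra,
                                             source_db = db))
  }
  list(lnc_mirna = interaction_table(unique(lm), "lncRNA-miRNA"),
       target_tables = lapply(tt, function(d)
         interaction_table(unique(d), "miRNA-mRNA")),
       truth = list(lnc = p_lnc, mirna = p_mir, mrna = p_mrna))
}

#' Generate gene sets, infiltration scores and predicted IC50 tables
#'
#' Uses the cohort's true risk linear predictor as the planted axis: the
#' immune-program gene set is up-shifted in low-risk samples (by
#' construction in [generate_tumor_cohort()]); infiltration scores are
#' drawn with a planted correlation against the linear predictor; two drugs
#' receive opposite planted IC50 shifts along the risk axis and the
#' remaining drugs are null.
#'
#' @param cfg a \code{sim_config}.
#' @param cohort result of [generate_tumor_cohort()] under the same config.
#' @return List: \code{gene_sets} (named list, first element the planted
#'   immune program), \code{infiltration} (samples x cell types),
#'   \code{ic50} (samples x drugs), \code{truth} (planted drug names).
#' @export
generate_auxiliary_tables <- function(cfg, cohort) {
  cfg <- validate_sim_config(cfg)
  set.seed(cfg$seed + 3L)
  lp <- cohort$truth$lp
  pats <- names(lp)
  n <- length(lp)
  zlp <- if (stats::sd(lp) > 0) as.numeric(scale(lp)) else rep(0, n)

  sets <- list(IMMUNE_PROGRAM = cohort$truth$immune_program)
  mr <- rownames(cohort$expr)[gene_biotype(cohort$expr) == "mRNA"]
  for (k in 1:3)
    sets[[paste0("RANDOM_SET_", k)]] <-
      sort(sample(mr, length(cohort$truth$immune_program)))
  sets <- lapply(sets, function(s) structure(s, description = "synthetic"))

  r <- cfg$infiltration_cor
  cells <- sprintf("celltype_%02d", seq_len(cfg$n_infiltration_celltypes))
  inf <- sapply(cells, function(ct)
    r * zlp + sqrt(max(0, 1 - r^2)) * stats::rnorm(n))
  rownames(inf) <- pats

  drugs <- c("synthdrug_A", "synthdrug_B",
             sprintf("nulldrug_%d", seq_len(cfg$n_null_drugs)))
  ic50 <- sapply(drugs, function(dr) stats::rnorm(n))
  # drug A: higher IC50 with risk (low-risk more sensitive); drug B opposite
  ic50[, "synthdrug_A"] <- ic50[, "synthdrug_A"] + cfg$ic50_shift * zlp
  ic50[, "synthdrug_B"] <- ic50[, "synthdrug_B"] - cfg$ic50_shift * zlp
  rownames(ic50) <- pats

  list(gene_sets = sets, infiltration = inf, ic50 = ic50,
       truth = list(planted_drugs = c("synthdrug_A", "synthdrug_B"),
                    null_drugs = drugs[-(1:2)]))
}

#' Write a survival table as TSV
#' @param surv survival table.
#' @param path file path.
#' @export
write_survival_tsv <- function(surv, path) {
  utils::write.table(surv, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_survival_tsv
#' @export
read_survival_tsv <- function(path) {
  validate_survival(utils::read.delim(path, stringsAsFactors = FALSE))
}
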