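small_cfg <- function(...) {
  args <- list(n_lncrnas = 40, n_specific = 10, n_patients = 120,
               n_normals = 20, n_mrnas = 80, n_de_mrnas = 12,
               n_planted_triads = 3, n_mirnas = 10, immune_program_size = 10,
               planted_pairs = data.frame(lnc_a = c("LNC0001", "LNC0003"),
                                          lnc_b = c("LNC0002", "LNC0004"),
                                          beta = c(0.8, -0.8),
                                          prevalence = 0.5))
  do.call(sim_config, utils::modifyList(args, list(...)))
}

test_that("generators are bit-reproducible under a fixed seed", {
  cfg <- small_cfg(seed = 11)
  a <- generate_immune_panel(cfg); b <- generate_immune_panel(cfg)
  expect_identical(a, b)
  ca <- generate_tumor_cohort(cfg); cb <- generate_tumor_cohort(cfg)
  expect_identical(ca, cb)
  ia <- generate_interaction_tables(cfg)
  expect_identical(ia, generate_interaction_tables(cfg))
  expect_identical(generate_auxiliary_tables(cfg, ca),
                   generate_auxiliary_tables(cfg, ca))
  # a different seed changes the draw
  expect_false(identical(unclass(a$expr),
                         unclass(generate_immune_panel(small_cfg(seed = 12))$expr)))
})

test_that("panel logFC moments match the planted effect", {
  ok <- vapply(1:10, function(s) {
    cfg <- sim_config(seed = s, n_lncrnas = 50, n_specific = 10,
                      specific_logfc = 2, noise_sd = 0.1,
                      n_immune_celltypes = 4, n_samples_per_type = 20)
    p <- generate_immune_panel(cfg)
    x <- unclass(p$expr)
    lf <- rowMeans(x[p$specific, p$celltype == "T_cell", drop = FALSE]) -
      rowMeans(x[p$specific, p$celltype != "T_cell", drop = FALSE])
    mean(lf >= 1.8 & lf <= 2.2)
  }, numeric(1))
  expect_gte(mean(ok), 0.95)
})

test_that("a panel without planted genes yields no differential lncRNAs beyond the FDR bound", {
  cfg <- sim_config(seed = 5, n_lncrnas = 200, n_specific = 0,
                    n_planted_triads = 0)
  p <- generate_immune_panel(cfg)
  grp <- factor(ifelse(p$celltype == "T_cell", "T", "other"),
                levels = c("T", "other"))
  de <- differential_expression(quantile_normalize(p$expr), grp)
  sel <- select_specific_lncrnas(de)
  expect_lte(length(sel), ceiling(0.05 * 200))
})

test_that("the survival generator reproduces the planted hazard ratio and censoring", {
  cfg <- sim_config(seed = 21, n_lncrnas = 10, n_specific = 2,
                    n_patients = 2000, censoring_fraction = 0,
                    n_planted_triads = 1, n_mirnas = 4, n_de_mrnas = 2,
                    n_mrnas = 20, immune_program_size = 5,
                    planted_pairs = data.frame(lnc_a = "LNC0001",
                                               lnc_b = "LNC0002",
                                               beta = log(2),
                                               prevalence = 0.5))
  co <- generate_tumor_cohort(cfg)
  expect_true(all(co$surv$event == 1))
  z <- as.numeric(unclass(co$expr)["LNC0001", co$surv$sample_id] >
                  unclass(co$expr)["LNC0002", co$surv$sample_id])
  fit <- survival::coxph(survival::Surv(co$surv$time, co$surv$event) ~ z)
  expect_gt(exp(coef(fit)), 1.8)
  expect_lt(exp(coef(fit)), 2.2)
  # planted prevalence inside the filter window
  expect_gt(mean(z), 0.2); expect_lt(mean(z), 0.8)

  # empirical censoring fraction tracks the configured value
  for (cf in c(0.2, 0.5)) {
    cfg2 <- small_cfg(seed = 31, censoring_fraction = cf, n_patients = 400)
    co2 <- generate_tumor_cohort(cfg2)
    expect_lt(abs(mean(1 - co2$surv$event) - cf), 0.1)
  }
})

test_that("a cohort without planted pairs has exchangeable survival", {
  cfg <- small_cfg(seed = 41)
  cfg$planted_pairs <- cfg$planted_pairs[0, ]
  co <- generate_tumor_cohort(cfg)
  expect_equal(unname(co$truth$lp), rep(0, 120))
  set.seed(42)
  ps <- vapply(1:30, function(i) {
    g <- sample(rep(c("a", "b"), 60))
    km_logrank(g, co$surv)$p
  }, numeric(1))
  # random splits of a null cohort: no systematic signal
  expect_gt(mean(ps > 0.05), 0.8)
})

test_that("interaction tables plant recoverable triads with decoys that each break a rule", {
  cfg <- small_cfg(seed = 51)
  it <- generate_interaction_tables(cfg)
  co <- generate_tumor_cohort(cfg)
  specific <- sprintf("LNC%04d", 1:10)
  pred <- predict_targets(specific, it$lnc_mirna, it$target_tables, "all")
  hubs <- hub_mrnas(pred$mrnas, co$truth$de_mrnas)
  expect_identical(hubs, sort(it$truth$mrna))
  # decoy count: 4 decoy edge groups per planted triad
  n_decoy_edges <- nrow(it$lnc_mirna) - cfg$n_planted_triads +
    sum(vapply(it$target_tables, nrow, 1L)) - 3 * cfg$n_planted_triads
  expect_gte(n_decoy_edges, 20)

  # a consensus-breaking decoy is excluded under "all" but present under "any"
  any_pred <- predict_targets(specific, it$lnc_mirna, it$target_tables, "any")
  expect_gt(length(any_pred$mrnas), length(pred$mrnas))

  # zero triads produce an empty hub set
  cfg0 <- small_cfg(seed = 52)
  cfg0$n_planted_triads <- 0L
  it0 <- generate_interaction_tables(cfg0)
  pred0 <- predict_targets(specific, it0$lnc_mirna, it0$target_tables, "all")
  expect_length(hub_mrnas(pred0$mrnas, co$truth$de_mrnas), 0)
})

test_that("auxiliary tables carry the planted correlation and drug shifts", {
  cfg <- small_cfg(seed = 61, n_patients = 400)
  co <- generate_tumor_cohort(cfg)
  aux <- generate_auxiliary_tables(cfg, co)
  rho <- cor(co$truth$lp[rownames(aux$infiltration)], aux$infiltration[, 1],
             method = "spearman")
  expect_gt(rho, -0.65); expect_lt(rho, -0.35)
  groups <- factor(ifelse(co$truth$lp > stats::median(co$truth$lp),
                          "high", "low"), levels = c("low", "high"))
  res <- drug_sensitivity_diff(aux$ic50, groups)
  expect_lt(max(res$p[res$drug %in% aux$truth$planted_drugs]), 0.01)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_lncrnas = 10, n_specific = 20), "n_specific")
  expect_error(sim_config(planted_pairs = data.frame(
    lnc_a = "LNC9999", lnc_b = "LNC0001", beta = 1, prevalence = 0.5)),
    "planted pair ids")
  expect_error(sim_config(planted_pairs = data.frame(
    lnc_a = "LNC0001", lnc_b = "LNC0002", beta = Inf, prevalence = 0.5)),
    "finite")
})

test_that("simulation configs round-trip through YAML", {
  cfg <- small_cfg(seed = 71)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_equal(back$planted_pairs, cfg$planted_pairs)
  expect_identical(unclass(generate_immune_panel(back)$expr),
                   unclass(generate_immune_panel(cfg)$expr))
})
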