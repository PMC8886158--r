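test_that("univariate screen excludes constant pairs and recovers a known hazard ratio", {
  pm <- independent_pair_matrix(3, 60, seed = 1)
  ind <- unclass(pm)
  ind[2, ] <- 1L  # constant
  pmc <- pair_matrix(ind, pair_info(pm)$lnc_a, pair_info(pm)$lnc_b)
  surv <- sim_ph_surv(t(ind), c(0, 0, 0), seed = 1)
  res <- univariate_cox_screen(pmc, surv, alpha = 0.01)
  expect_true(any(res$excluded$reason == "zero variance"))
  expect_false(rownames(pmc)[2] %in% res$fits$pair)

  # Wald CI coverage of the true log-HR
  covered <- vapply(1:50, function(s) {
    pm <- independent_pair_matrix(1, 300, seed = s)
    surv <- sim_ph_surv(t(unclass(pm)), log(2), cens_frac = 0.3, seed = s + 1000)
    f <- univariate_cox_screen(pm, surv, alpha = 1)$fits
    f$lo95 <= 2 && 2 <= f$hi95
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})

test_that("lasso selection reduces to the unpenalized fit at lambda ~ 0 and to nothing at large lambda", {
  pm <- independent_pair_matrix(3, 300, seed = 5)
  z <- t(unclass(pm))
  surv <- sim_ph_surv(z, c(0.8, -0.5, 0.3), seed = 6)
  keys <- rownames(pm)

  expect_warning(big <- lasso_cox_select(pm, keys, surv, lambda = 1e5),
                 "shrunk to zero")
  expect_length(big$selected, 0)

  small <- lasso_cox_select(pm, keys, surv, lambda = 1e-6)
  oracle <- survival::coxph(survival::Surv(surv$time, surv$event) ~ z,
                            ties = "efron")
  expect_equal(unname(small$betas), unname(coef(oracle)), tolerance = 1e-3)
})

test_that("lasso keeps planted signal pairs among null decoys", {
  hits <- vapply(1:10, function(s) {
    pm <- independent_pair_matrix(33, 300, seed = s)
    z <- t(unclass(pm))
    beta <- c(0.9, -0.9, 0.7, rep(0, 30))
    surv <- sim_ph_surv(z, beta, cens_frac = 0.3, seed = s + 500)
    sel <- suppressWarnings(
      lasso_cox_select(pm, rownames(pm), surv, seed = s)$selected)
    mean(rownames(pm)[1:3] %in% sel)
  }, numeric(1))
  expect_gte(mean(hits >= 2 / 3), 0.8)
})

test_that("multivariate fit recovers planted coefficients and is deterministic", {
  pm <- independent_pair_matrix(2, 500, seed = 2)
  z <- t(unclass(pm))
  surv <- sim_ph_surv(z, c(0.8, -0.8), seed = 3)
  fit1 <- multivariate_cox_fit(pm, rownames(pm), surv)
  fit2 <- multivariate_cox_fit(pm, rownames(pm), surv)
  expect_identical(fit1$model$betas, fit2$model$betas)
  expect_lt(max(abs(fit1$model$betas - c(0.8, -0.8))), 0.3)
  expect_equal(fit1$fits$hr, exp(fit1$fits$beta), tolerance = 1e-12)

  # two groups with identical survival: coefficient near zero
  ind <- matrix(rep(c(0L, 1L), each = 250), 1, 500,
                dimnames = list(NULL, sprintf("P%04d", 1:500)))
  pm0 <- pair_matrix(ind, "a", "b")
  surv0 <- sim_ph_surv(matrix(0, 500, 1), 0, seed = 9)
  f0 <- multivariate_cox_fit(pm0, "a|b", surv0)
  expect_lt(abs(f0$model$betas), 0.25)
})

test_that("risk scores are the linear combination of indicators and betas", {
  pm <- independent_pair_matrix(2, 4, seed = 7)
  model <- structure(list(pairs = rownames(pm),
                          betas = setNames(c(0.5, -0.3), rownames(pm)),
                          cutoff = NA_real_, metadata = list()),
                     class = "signature_model")
  sc <- risk_score(model, pm)
  oracle <- drop(t(unclass(pm)) %*% c(0.5, -0.3))
  expect_equal(unname(sc), unname(oracle))

  model0 <- model; model0$betas[] <- 0
  expect_true(all(risk_score(model0, pm) == 0))

  model_bad <- model; model_bad$pairs <- c(model$pairs, "zz|ww")
  expect_error(risk_score(model_bad, pm), "zz\\|ww")
})

test_that("risk-group assignment is strict at the cutoff", {
  sc <- c(a = -1, b = 0.5, c = 0.5000001, d = 2)
  g <- assign_risk_groups(sc, 0.5)
  expect_equal(as.character(g), c("low", "low", "high", "high"))
  expect_equal(as.character(assign_risk_groups(sc, 10)), rep("low", 4))
  expect_error(assign_risk_groups(sc, NA), "finite")
  # oracle sweep
  set.seed(1)
  x <- rnorm(50); cut <- 0.2
  expect_equal(assign_risk_groups(x, cut) == "high", x > cut,
               ignore_attr = TRUE)
})

test_that("log-rank statistic matches a hand-computed observed-minus-expected table", {
  # 3 vs 3 patients, all events, alternating event times
  surv <- data.frame(sample_id = paste0("p", 1:6),
                     time = c(1, 3, 5, 2, 4, 6), event = 1)
  groups <- rep(c("A", "B"), each = 3)
  res <- km_logrank(groups, surv)
  # oracle: walk the pooled event times accumulating O, E, V for group A
  times <- c(1, 2, 3, 4, 5, 6); member <- c("A", "B", "A", "B", "A", "B")
  oA <- eA <- v <- 0
  for (i in seq_along(times)) {
    atrisk_A <- sum(surv$time[groups == "A"] >= times[i])
    atrisk <- sum(surv$time >= times[i])
    oA <- oA + (member[i] == "A")
    eA <- eA + atrisk_A / atrisk
    v <- v + atrisk_A * (atrisk - atrisk_A) / atrisk^2
  }
  expect_equal(res$chisq, (oA - eA)^2 / v, tolerance = 1e-12)
  expect_equal(res$obs_exp$observed, c(3, 3))
  expect_equal(res$obs_exp$expected[1], eA, tolerance = 1e-12)

  # identical survival in both groups: statistic 0, p 1
  dup <- data.frame(sample_id = paste0("q", 1:10),
                    time = rep(c(2, 4, 6, 8, 10), 2), event = 1)
  res0 <- km_logrank(rep(c("A", "B"), each = 5), dup)
  expect_equal(res0$chisq, 0, tolerance = 1e-12)
  expect_equal(res0$p, 1)
  # KM curves start at or below 1 and are non-increasing per group
  for (g in c("A", "B")) {
    sv <- res0$curves$survival[res0$curves$group == g]
    expect_true(all(diff(sv) <= 0) && all(sv <= 1))
  }
})

test_that("clinical Cox finds a true linear predictor and is consistent across modes", {
  set.seed(31)
  n <- 300
  score <- rnorm(n)
  surv <- sim_ph_surv(matrix(score), 1, cens_frac = 0.3, seed = 32)
  surv$age <- round(rnorm(n, 60, 10))
  surv$sex <- sample(c("male", "female"), n, TRUE)
  names(score) <- surv$sample_id
  multi <- clinical_cox(surv, score, "multivariate")
  row <- multi[multi$term == "risk_score", ]
  expect_gt(row$hr, 1)
  expect_lt(row$p, 0.05)

  uni <- clinical_cox(surv, scores = NULL, mode = "univariate",
                      covariates = "age")
  multi1 <- clinical_cox(surv, scores = NULL, mode = "multivariate",
                         covariates = "age")
  expect_equal(uni$beta, multi1$beta, tolerance = 1e-12)

  # null covariate: CI covers HR = 1 around the nominal rate
  covered <- vapply(1:60, function(s) {
    surv0 <- sim_ph_surv(matrix(0, 120, 1), 0, seed = s + 2000)
    surv0$age <- round(rnorm(120, 60, 10))
    f <- clinical_cox(surv0, NULL, "univariate", covariates = "age")
    f$lo95 <= 1 && 1 <= f$hi95
  }, logical(1))
  expect_gte(mean(covered), 0.85)
})

test_that("group association tests match textbook formulas", {
  # balanced 2x2: statistic 0, p 1
  surv <- data.frame(sample_id = paste0("p", 1:40), time = 1:40, event = 1,
                     sex = rep(c("male", "female"), 20))
  groups <- rep(c("low", "high"), each = 20)
  scores <- setNames(seq(0, 1, length.out = 40), surv$sample_id)
  res <- group_association_tests(groups, surv, scores, covariates = "sex")
  expect_equal(res$chisq$statistic, 0)
  expect_equal(res$chisq$p, 1)

  # chi-square equals sum (O-E)^2/E on random tables
  set.seed(77)
  for (rep in 1:5) {
    tab <- matrix(rpois(4, 30) + 5, 2)
    ct <- stats::chisq.test(tab, correct = FALSE)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(unname(ct$statistic), sum((tab - expected)^2 / expected))
  }

  # exact rank-sum: {1,2,3} vs {4,5,6} has one-sided p 1/20, two-sided 0.1
  p <- stats::wilcox.test(c(1, 2, 3), c(4, 5, 6))$p.value
  expect_equal(p, 0.1)
  surv2 <- data.frame(sample_id = paste0("q", 1:6), time = 1:6, event = 1,
                      grade = rep(c("G1", "G2"), each = 3))
  sc2 <- setNames(c(1, 2, 3, 4, 5, 6), surv2$sample_id)
  res2 <- suppressWarnings(
    group_association_tests(rep(c("low", "high"), 3), surv2, sc2,
                            covariates = "grade", mc_seed = 1))
  expect_equal(res2$score_strata$p, 0.1)
})

test_that("stratified analysis reduces to the unstratified one on a single stratum", {
  pm <- independent_pair_matrix(1, 80, seed = 41)
  surv <- sim_ph_surv(t(unclass(pm)), 1, cens_frac = 0.2, seed = 42)
  surv$age <- round(rnorm(80, 60, 8))
  surv$stratum <- "all"
  scores <- setNames(drop(unclass(pm)[1, ]), surv$sample_id)
  groups <- assign_risk_groups(scores, 0.5)
  res <- stratified_analysis(surv, groups, "stratum", scores)
  whole <- km_logrank(groups, surv)
  expect_equal(res$all$km$chisq, whole$chisq)
  expect_equal(res$all$km$p, whole$p)

  # a stratum below the minimum size is skipped with a reason
  surv$stratum[1:5] <- "tiny"
  res2 <- stratified_analysis(surv, groups, "stratum", scores, min_size = 20)
  expect_match(res2$tiny$skipped, "stratum size 5")
})
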