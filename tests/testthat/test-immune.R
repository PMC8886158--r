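test_that("infiltration differences detect planted shifts and respect nulls", {
  set.seed(101)
  n <- 60
  groups <- factor(rep(c("low", "high"), each = n / 2),
                   levels = c("low", "high"))
  smallest <- vapply(1:20, function(s) {
    set.seed(s)
    inf <- matrix(rnorm(n * 5), n, 5,
                  dimnames = list(sprintf("P%03d", 1:n), paste0("ct", 1:5)))
    inf[groups == "high", 3] <- inf[groups == "high", 3] + 1.5
    res <- infiltration_diff(inf, groups)
    res$cell_type[which.min(res$p)] == "ct3"
  }, logical(1))
  expect_gte(mean(smallest), 0.9)

  # identical distributions: p values large; constant column flagged
  inf0 <- matrix(rep(c(1, 2, 3), each = 20), 60, 2)
  colnames(inf0) <- c("a", "b"); inf0[, 2] <- 5
  res0 <- infiltration_diff(inf0, sample(groups))
  expect_equal(res0$p[res0$cell_type == "b"], 1)
  expect_match(res0$note[res0$cell_type == "b"], "constant")
})

test_that("rank-sum p agrees with exhaustive enumeration for tiny samples", {
  set.seed(7)
  a <- c(0.3, 1.2, 2.5, 0.9); b <- c(1.7, 3.1, 2.2, 4.0)
  # enumeration over all C(8,4) assignments of the pooled values
  pooled <- c(a, b)
  w_obs <- sum(rank(pooled)[1:4])
  splits <- utils::combn(8, 4)
  w_all <- apply(splits, 2, function(ix) sum(rank(pooled)[ix]))
  mu <- mean(w_all)
  p_exact <- mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
  inf <- cbind(ct = pooled)
  rownames(inf) <- sprintf("P%02d", 1:8)
  res <- infiltration_diff(inf, rep(c("low", "high"), each = 4))
  expect_equal(res$p, p_exact, tolerance = 1e-12)
})

test_that("risk-infiltration correlation is rank-based and signed correctly", {
  sc <- setNames(seq(0.1, 4, length.out = 40), sprintf("P%03d", 1:40))
  inf <- cbind(same = sc, flip = -sc^3)
  res <- infiltration_correlation(sc, inf)
  expect_equal(res$rho[res$cell_type == "same"], 1)
  expect_equal(res$rho[res$cell_type == "flip"], -1)
  # invariance under a strictly monotone transform
  res2 <- infiltration_correlation(exp(sc / 2), inf)
  expect_equal(res2$rho, res$rho)
})

test_that("gene correlates recover planted direction and closed-form Pearson", {
  set.seed(111)
  n <- 50
  x <- matrix(rnorm(6 * n), 6, n,
              dimnames = list(paste0("G", 1:6), sprintf("P%03d", 1:n)))
  groups <- factor(rep(c("low", "high"), each = n / 2),
                   levels = c("low", "high"))
  x["G1", groups == "low"] <- x["G1", groups == "low"] + 2
  x["G2", ] <- x["G1", ]  # exact copy
  sc <- setNames(rnorm(n), colnames(x))
  res <- gene_correlates(as_em(x), groups, c("G1", "G2", "G3", "ABSENT"), sc)
  expect_equal(res$skipped, "ABSENT")
  expect_equal(res$diff$direction[res$diff$gene == "G1"], "higher_in_low")
  pw <- res$pairwise
  expect_equal(pw$pearson_r[pw$gene_a == "G1" & pw$gene_b == "G2"], 1)

  # closed-form Pearson on 5-point vectors
  a <- c(1, 2, 4, 7, 11); b <- c(2, 1, 5, 6, 13)
  r_formula <- (sum(a * b) - 5 * mean(a) * mean(b)) /
    sqrt((sum(a^2) - 5 * mean(a)^2) * (sum(b^2) - 5 * mean(b)^2))
  expect_equal(cor(a, b), r_formula, tolerance = 1e-12)
})

test_that("four-group survival partitions the cohort and handles degenerate splits", {
  set.seed(121)
  n <- 80
  sc <- rnorm(n)
  surv <- sim_ph_surv(matrix(sc), 1, cens_frac = 0.2, seed = 122)
  names(sc) <- surv$sample_id
  groups <- assign_risk_groups(sc, 0)
  gene <- setNames(rnorm(n), names(sc))
  res <- four_group_survival(groups, gene, surv)
  expect_equal(sum(table(res$labels)), n)
  expect_equal(nlevels(res$labels), 4)
  expect_equal(res$km$df, 3)

  # gene identical to the score (cutoff at the median) degenerates to two
  # informative groups: the off-diagonal cells are empty
  groups2 <- assign_risk_groups(sc, unname(median(sc)))
  res2 <- four_group_survival(groups2, sc, surv)
  expect_equal(length(res2$empty), 2)
})

test_that("drug sensitivity comparison flags planted shifts with correct direction", {
  set.seed(131)
  n <- 100
  groups <- factor(rep(c("low", "high"), each = n / 2),
                   levels = c("low", "high"))
  ic50 <- matrix(rnorm(n * 3), n, 3,
                 dimnames = list(sprintf("P%03d", 1:n),
                                 c("drugA", "drugB", "null")))
  ic50[groups == "high", "drugA"] <- ic50[groups == "high", "drugA"] + 1
  ic50[groups == "high", "drugB"] <- ic50[groups == "high", "drugB"] - 1
  res <- drug_sensitivity_diff(ic50, groups)
  expect_lt(res$p[res$drug == "drugA"], 0.01)
  expect_equal(res$direction[res$drug == "drugA"], "more_sensitive_in_low")
  expect_equal(res$direction[res$drug == "drugB"], "more_sensitive_in_high")
  expect_gt(res$p[res$drug == "null"], 0.01)

  # swapping the groups flips the direction flags
  swapped <- drug_sensitivity_diff(ic50, factor(
    ifelse(groups == "low", "high", "low"), levels = c("low", "high")))
  expect_equal(swapped$p, res$p)
  a <- res$direction[res$direction != "none"]
  b <- swapped$direction[swapped$direction != "none"]
  expect_true(all(a != b))
})
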