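#' Validate a survival record table
#'
#' A survival table is a data.frame with columns \code{sample_id},
#' \code{time} (> 0), \code{event} (0/1) and optional clinical covariates
#' \code{age} (numeric), \code{sex}, \code{grade}, \code{stage},
#' \code{t_stage}, \code{n_stage}, \code{m_stage} (categorical, missing
#' allowed).
#'
#' @param surv data.frame.
#' @return The validated data.frame (invisibly re-ordered is never done).
#' @export
validate_survival <- function(surv) {
  need <- c("sample_id", "time", "event")
  if (!all(need %in% names(surv)))
    stop("survival table must contain columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(surv$sample_id)) stop("duplicate sample_id")
  if (any(!is.finite(surv$time)) || any(surv$time <= 0))
    stop("all survival times must be finite and > 0")
  if (!all(surv$event %in% c(0, 1))) stop("event must be 0/1")
  surv
}

.align_surv <- function(pm_samples, surv) {
  surv <- validate_survival(surv)
  if (!all(pm_samples %in% surv$sample_id))
    stop("samples missing from survival table")
  surv[match(pm_samples, surv$sample_id), , drop = FALSE]
}

#' Univariate Cox screen over pair features
#'
#' Fits one single-covariate Cox proportional-hazards model per pair
#' (Efron handling of tied event times) and retains pairs with Wald
#' p below \code{alpha}. Constant indicators and monotone-likelihood
#' (perfectly separating) pairs are excluded and reported with a reason.
#'
#' @param pm a \code{pair_matrix}.
#' @param surv survival table (see [validate_survival()]).
#' @param alpha Wald p-value threshold, default 0.01.
#' @return List: \code{candidates} (pair keys passing the screen),
#'   \code{fits} (data.frame pair, beta, hr, lo95, hi95, p),
#'   \code{excluded} (data.frame pair, reason).
#' @export
univariate_cox_screen <- function(pm, surv, alpha = 0.01) {
  surv <- .align_surv(colnames(pm), surv)
  if (sum(surv$event) < 2L) stop("need at least 2 events")
  y <- survival::Surv(surv$time, surv$event)
  keys <- rownames(pm)
  rows <- vector("list", length(keys))
  excl <- list()
  for (i in seq_along(keys)) {
    z <- unclass(pm)[i, ]
    if (length(unique(z)) < 2L) {
      excl[[length(excl) + 1L]] <- data.frame(pair = keys[i], reason = "zero variance")
      next
    }
    fit <- tryCatch(
      withCallingHandlers(
        survival::coxph(y ~ z, ties = "efron"),
        warning = function(w) {
          if (grepl("converged before|infinite", conditionMessage(w)))
            invokeRestart("muffleWarning") else invokeRestart("muffleWarning")
        }),
      error = function(e) NULL)
    if (is.null(fit)) {
      excl[[length(excl) + 1L]] <- data.frame(pair = keys[i], reason = "fit failure")
      next
    }
    s <- summary(fit)
    beta <- unname(stats::coef(fit))
    se <- s$coefficients[1, "se(coef)"]
    if (!is.finite(beta) || abs(beta) > 15 || !is.finite(se)) {
      excl[[length(excl) + 1L]] <- data.frame(pair = keys[i],
                                              reason = "monotone likelihood")
      next
    }
    rows[[i]] <- data.frame(pair = keys[i], beta = beta, hr = exp(beta),
                            lo95 = exp(beta - 1.96 * se),
                            hi95 = exp(beta + 1.96 * se),
                            p = s$coefficients[1, "Pr(>|z|)"])
  }
  fits <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(fits))
    fits <- data.frame(pair = character(), beta = numeric(), hr = numeric(),
                       lo95 = numeric(), hi95 = numeric(), p = numeric())
  rownames(fits) <- NULL
  list(candidates = fits$pair[fits$p < alpha],
       fits = fits,
       excluded = if (length(excl)) do.call(rbind, excl)
                  else data.frame(pair = character(), reason = character()))
}

#' Lasso-Cox selection of pair features
#'
#' L1-penalized Cox regression over the candidate pairs with the penalty
#' chosen by k-fold cross-validated partial-likelihood deviance. The pairs
#' with a nonzero coefficient at the chosen lambda are returned.
#'
#' @param pm a \code{pair_matrix} (will be subset to \code{candidates}).
#' @param candidates character vector of pair keys.
#' @param surv survival table.
#' @param folds number of CV folds (default 10).
#' @param seed integer seed controlling the fold assignment.
#' @param rule \code{"min"} (default, lambda at minimum CV deviance) or
#'   \code{"1se"}.
#' @param lambda optional fixed lambda overriding cross-validation.
#' @return List: \code{selected} pair keys, \code{betas} (penalized
#'   coefficients at the chosen lambda), \code{lambda}.
#' @export
lasso_cox_select <- function(pm, candidates, surv, folds = 10, seed = 1,
                             rule = c("min", "1se"), lambda = NULL) {
  rule <- match.arg(rule)
  surv <- .align_surv(colnames(pm), surv)
  if (length(candidates) < 2L)
    return(list(selected = candidates, betas = NULL, lambda = NA_real_))
  x <- t(unclass(pm)[candidates, , drop = FALSE])
  y <- survival::Surv(surv$time, surv$event)
  if (!is.null(lambda)) {
    fit <- glmnet::glmnet(x, y, family = "cox", lambda = lambda)
    b <- as.numeric(stats::coef(fit, s = lambda))
  } else {
    set.seed(seed)
    foldid <- sample(rep(seq_len(folds), length.out = nrow(x)))
    cv <- glmnet::cv.glmnet(x, y, family = "cox", foldid = foldid)
    lambda <- if (rule == "min") cv$lambda.min else cv$lambda.1se
    b <- as.numeric(stats::coef(cv, s = lambda))
  }
  sel <- candidates[b != 0]
  if (!length(sel)) warning("all coefficients shrunk to zero at chosen lambda")
  list(selected = sel, betas = stats::setNames(b[b != 0], sel), lambda = lambda)
}

#' Multivariate Cox fit of the final signature
#'
#' Joint Cox proportional-hazards fit (Efron ties) over the selected pairs;
#' the coefficients define the signature's risk score.
#'
#' @param pm a \code{pair_matrix}.
#' @param pairs character vector of pair keys (rows of \code{pm}).
#' @param surv survival table.
#' @param seed,folds,lambda,horizon metadata recorded in the model.
#' @return List: \code{model} (a \code{signature_model}: pairs, betas,
#'   cutoff (NA until [select_cutoff()]), metadata) and \code{fits}
#'   (per-pair beta, HR, CI95, Wald p).
#' @export
multivariate_cox_fit <- function(pm, pairs, surv, seed = NA, folds = NA,
                                 lambda = NA, horizon = NA) {
  if (!length(pairs)) stop("no pairs to fit")
  missing <- setdiff(pairs, rownames(pm))
  if (length(missing)) stop("pairs absent from pair matrix: ",
                            paste(missing, collapse = ", "))
  surv <- .align_surv(colnames(pm), surv)
  x <- t(unclass(pm)[pairs, , drop = FALSE])
  if (any(apply(x, 2L, function(v) length(unique(v))) < 2L))
    stop("constant pair indicator among selected pairs")
  df <- data.frame(x, check.names = FALSE)
  y <- survival::Surv(surv$time, surv$event)
  fit <- survival::coxph(y ~ ., data = df, ties = "efron")
  if (!is.null(fit$info) && isTRUE(fit$info$fail)) stop("Cox fit did not converge")
  s <- summary(fit)
  co <- s$coefficients
  fits <- data.frame(pair = pairs, beta = co[, "coef"],
                     hr = exp(co[, "coef"]),
                     lo95 = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
                     hi95 = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
                     p = co[, "Pr(>|z|)"], row.names = NULL)
  model <- structure(list(pairs = pairs,
                          betas = stats::setNames(co[, "coef"], pairs),
                          cutoff = NA_real_,
                          metadata = list(seed = seed, folds = folds,
                                          lambda = lambda, horizon = horizon,
                                          n = nrow(surv),
                                          n_events = sum(surv$event))),
                     class = "signature_model")
  list(model = model, fits = fits)
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf("signature_model: %d pairs, cutoff %s\n", length(x$pairs),
              ifelse(is.na(x$cutoff), "unset", format(x$cutoff))))
  for (i in seq_along(x$pairs))
    cat(sprintf("  %-30s beta = %+.4f\n", x$pairs[i], x$betas[i]))
  invisible(x)
}

#' Risk score of a signature on a pair matrix
#'
#' \code{score(s) = sum_k indicator_k(s) * beta_k}; a plain linear
#' combination with no intercept.
#'
#' @param model a \code{signature_model}.
#' @param pm a \code{pair_matrix} containing every model pair.
#' @return Named numeric vector of per-sample scores.
#' @export
risk_score <- function(model, pm) {
  missing <- setdiff(model$pairs, rownames(pm))
  if (length(missing))
    stop("pair(s) missing from pair matrix: ", paste(missing, collapse = ", "))
  drop(crossprod(unclass(pm)[model$pairs, , drop = FALSE], model$betas))[colnames(pm)]
}

#' Dichotomize risk scores at the model cutoff
#'
#' Scores strictly greater than the cutoff are labelled \code{"high"},
#' all others \code{"low"} (a score exactly equal to the cutoff is low
#' risk).
#'
#' @param scores numeric vector.
#' @param cutoff finite numeric cutoff.
#' @return Factor with levels \code{c("low", "high")}, named like
#'   \code{scores}.
#' @export
assign_risk_groups <- function(scores, cutoff) {
  if (!is.finite(cutoff)) stop("cutoff must be finite")
  factor(ifelse(scores > cutoff, "high", "low"), levels = c("low", "high"))
}

#' Serialize a signature model to JSON
#'
#' @param model a \code{signature_model}.
#' @param path file path.
#' @export
write_signature_json <- function(model, path) {
  obj <- list(pairs = model$pairs, betas = unname(model$betas),
              cutoff = model$cutoff, metadata = model$metadata)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_signature_json
#' @export
read_signature_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(pairs = obj$pairs,
                 betas = stats::setNames(as.numeric(obj$betas), obj$pairs),
                 cutoff = if (is.null(obj$cutoff)) NA_real_ else obj$cutoff,
                 metadata = obj$metadata),
            class = "signature_model")
}

#' Kaplan-Meier curves and log-rank test across groups
#'
#' @param groups factor of group labels, one per row of \code{surv}.
#' @param surv survival table.
#' @return List: \code{curves} (data.frame group, time, n_risk, n_event,
#'   survival), \code{chisq}, \code{df}, \code{p}, \code{obs_exp}
#'   (per-group observed and expected event counts).
#' @export
km_logrank <- function(groups, surv) {
  surv <- validate_survival(surv)
  groups <- as.factor(droplevels(as.factor(groups)))
  if (length(groups) != nrow(surv)) stop("one group label per sample required")
  if (nlevels(groups) < 2L) stop("need at least 2 non-empty groups")
  if (sum(surv$event) < 1L) stop("need at least 1 event")
  y <- survival::Surv(surv$time, surv$event)
  sf <- survival::survfit(y ~ groups)
  strata <- rep(names(sf$strata), sf$strata)
  curves <- data.frame(group = sub("^groups=", "", strata), time = sf$time,
                       n_risk = sf$n.risk, n_event = sf$n.event,
                       survival = sf$surv, row.names = NULL)
  sd <- survival::survdiff(y ~ groups)
  k <- length(sd$n)
  p <- stats::pchisq(sd$chisq, df = k - 1, lower.tail = FALSE)
  list(curves = curves, chisq = unname(sd$chisq), df = k - 1, p = p,
       obs_exp = data.frame(group = sub("^groups=", "", names(sd$n)),
                            n = as.numeric(sd$n), observed = sd$obs,
                            expected = sd$exp, row.names = NULL))
}

# Ordinal/numeric coding of clinical covariates: age numeric; sex binary
# (female = 1); grade/stage/t/n/m mapped to the integer in their label.
.code_clinical <- function(surv, covariates) {
  out <- list()
  for (cv in covariates) {
    if (!cv %in% names(surv)) next
    v <- surv[[cv]]
    out[[cv]] <- switch(cv,
      age = as.numeric(v),
      sex = as.numeric(tolower(as.character(v)) %in% c("female", "f", "1")),
      as.numeric(gsub("[^0-9]", "", as.character(v))))
  }
  as.data.frame(out)
}

#' Cox regression on clinical covariates and the risk score
#'
#' Univariate mode fits one Cox model per covariate; multivariate mode one
#' joint model. Covariate coding: age numeric, sex binary, staging variables
#' as ordinal integers; rows with missing values are dropped per fit and the
#' retained count reported. Collinear covariates (aliased in the joint fit)
#' are flagged.
#'
#' @param surv survival table with clinical columns.
#' @param scores optional named numeric risk-score vector (matched by
#'   \code{sample_id}).
#' @param mode \code{"univariate"} or \code{"multivariate"}.
#' @param covariates clinical columns to use.
#' @return data.frame: term, beta, hr, lo95, hi95, p, n, n_events, note.
#' @export
clinical_cox <- function(surv, scores = NULL,
                         mode = c("univariate", "multivariate"),
                         covariates = c("age", "sex", "grade", "stage")) {
  mode <- match.arg(mode)
  surv <- validate_survival(surv)
  x <- .code_clinical(surv, covariates)
  if (!is.null(scores)) {
    if (!is.null(names(scores))) scores <- scores[surv$sample_id]
    x$risk_score <- as.numeric(scores)
  }
  if (!ncol(x)) stop("no usable covariates")
  one_fit <- function(xx, terms) {
    cc <- stats::complete.cases(xx)
    xx <- xx[cc, , drop = FALSE]
    y <- survival::Surv(surv$time[cc], surv$event[cc])
    fit <- survival::coxph(y ~ ., data = xx, ties = "efron")
    co <- summary(fit)$coefficients
    aliased <- setdiff(terms, rownames(co))
    res <- data.frame(term = rownames(co), beta = co[, "coef"],
                      hr = exp(co[, "coef"]),
                      lo95 = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
                      hi95 = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
                      p = co[, "Pr(>|z|)"], n = sum(cc),
                      n_events = sum(surv$event[cc]), note = "",
                      row.names = NULL)
    if (length(aliased))
      res <- rbind(res, data.frame(term = aliased, beta = NA, hr = NA,
                                   lo95 = NA, hi95 = NA, p = NA, n = sum(cc),
                                   n_events = sum(surv$event[cc]),
                                   note = "collinear: aliased"))
    res
  }
  if (mode == "multivariate") return(one_fit(x, names(x)))
  do.call(rbind, lapply(names(x), function(nm) one_fit(x[, nm, drop = FALSE], nm)))
}

#' Association of risk groups with clinical strata
#'
#' Pearson chi-square test (without continuity correction) of each
#' categorical covariate against the risk group, switching to a Monte-Carlo
#' p-value (with recorded seed) when any expected cell count falls below 1;
#' plus two-sided Mann-Whitney tests of the risk score between every pair
#' of levels of each stratifying covariate.
#'
#' @param groups risk-group factor.
#' @param surv survival table with clinical columns.
#' @param scores named risk-score vector.
#' @param covariates categorical columns to test.
#' @param mc_seed seed used if a Monte-Carlo chi-square p is needed.
#' @return List: \code{chisq} (covariate, statistic, df, p, method) and
#'   \code{score_strata} (covariate, level_a, level_b, p).
#' @export
group_association_tests <- function(groups, surv, scores,
                                    covariates = c("sex", "grade", "stage",
                                                   "t_stage", "n_stage"),
                                    mc_seed = 1) {
  surv <- validate_survival(surv)
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2L) stop("need at least 2 groups")
  if (!is.null(names(scores))) scores <- scores[surv$sample_id]
  chisq_rows <- list(); strata_rows <- list()
  for (cv in intersect(covariates, names(surv))) {
    v <- as.factor(surv[[cv]])
    ok <- !is.na(v)
    tab <- table(v[ok], groups[ok])
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    if (nrow(tab) < 2L) next
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 1)) {
      set.seed(mc_seed)
      ct <- stats::chisq.test(tab, simulate.p.value = TRUE, B = 2000)
      method <- sprintf("monte-carlo (seed %d)", mc_seed)
      df <- NA_real_
    } else {
      ct <- stats::chisq.test(tab, correct = FALSE)
      method <- "pearson"
      df <- unname(ct$parameter)
    }
    chisq_rows[[cv]] <- data.frame(covariate = cv,
                                   statistic = unname(ct$statistic),
                                   df = df, p = ct$p.value, method = method)
    lev <- levels(droplevels(v[ok]))
    for (i in seq_along(lev)) for (j in seq_along(lev)) {
      if (i >= j) next
      a <- scores[ok][v[ok] == lev[i]]; b <- scores[ok][v[ok] == lev[j]]
      if (length(a) < 2L || length(b) < 2L) next
      p <- stats::wilcox.test(a, b)$p.value
      strata_rows[[paste(cv, i, j)]] <-
        data.frame(covariate = cv, level_a = lev[i], level_b = lev[j], p = p)
    }
  }
  list(chisq = if (length(chisq_rows)) do.call(rbind, c(chisq_rows, make.row.names = FALSE))
               else data.frame(),
       score_strata = if (length(strata_rows)) do.call(rbind, c(strata_rows, make.row.names = FALSE))
                      else data.frame())
}

#' Stratified survival analysis
#'
#' Repeats the two-group log-rank comparison and the multivariate clinical
#' Cox fit within each level of a stratifying covariate; strata below the
#' minimum size are skipped with a reason.
#'
#' @param surv survival table.
#' @param groups risk-group factor (aligned with \code{surv} rows).
#' @param stratum_var name of the stratifying column in \code{surv}.
#' @param scores named risk-score vector.
#' @param min_size minimum stratum size (default 20).
#' @return Named list per stratum: either \code{list(km =, cox =)} or
#'   \code{list(skipped = reason)}.
#' @export
stratified_analysis <- function(surv, groups, stratum_var, scores,
                                min_size = 20) {
  surv <- validate_survival(surv)
  v <- as.factor(surv[[stratum_var]])
  if (!is.null(names(scores))) scores <- scores[surv$sample_id]
  out <- list()
  for (lev in levels(v)) {
    idx <- which(!is.na(v) & v == lev)
    if (length(idx) < min_size) {
      out[[lev]] <- list(skipped = sprintf("stratum size %d < %d",
                                           length(idx), min_size))
      next
    }
    g <- droplevels(as.factor(groups[idx]))
    s <- surv[idx, , drop = FALSE]
    km <- if (nlevels(g) >= 2L && sum(s$event) >= 1L)
      km_logrank(g, s) else list(skipped = "degenerate groups or no events")
    cox <- tryCatch(clinical_cox(s, scores[idx], mode = "multivariate"),
                    error = function(e) list(skipped = conditionMessage(e)))
    out[[lev]] <- list(km = km, cox = cox, n = length(idx))
  }
  out
}
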