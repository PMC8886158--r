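# Shared fixture builders for the test suite. Everything is generated in
# code under fixed seeds; no data files.

# quick expr_matrix from a plain matrix, inventing gene/sample names
as_em <- function(x, biotype = "other") {
  if (is.null(rownames(x))) rownames(x) <- sprintf("g%02d", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- sprintf("s%02d", seq_len(ncol(x)))
  expr_matrix(x, biotype)
}

# exponential proportional-hazards survival data for a covariate matrix z:
# h(t) = exp(z %*% beta), optional uniform censoring tuned roughly to the
# requested fraction
sim_ph_surv <- function(z, beta, cens_frac = 0, seed = 1) {
  set.seed(seed)
  z <- as.matrix(z)
  n <- nrow(z)
  lp <- drop(z %*% beta)
  tev <- stats::rexp(n, rate = exp(lp))
  if (cens_frac > 0) {
    f <- function(r) mean(1 - exp(-r * tev)) - cens_frac
    rate <- stats::uniroot(f, c(1e-8, 1e4), extendInt = "upX")$root
    cens <- stats::rexp(n, rate)
    time <- pmin(tev, cens); event <- as.integer(tev <= cens)
  } else {
    time <- tev; event <- rep(1L, n)
  }
  data.frame(sample_id = sprintf("P%04d", seq_len(n)), time = time,
             event = event, stringsAsFactors = FALSE)
}

# pair matrix of k mutually independent pairs (disjoint gene pairs)
independent_pair_matrix <- function(k, n, seed = 1, prevalence = 0.5) {
  set.seed(seed)
  ind <- matrix(stats::rbinom(k * n, 1, prevalence), k, n,
                dimnames = list(NULL, sprintf("P%04d", seq_len(n))))
  pair_matrix(ind, sprintf("LA%04d", seq_len(k)), sprintf("LB%04d", seq_len(k)))
}

# brute-force double-loop oracle for the pair indicator transformation
pair_oracle <- function(x, genes) {
  genes <- sort(genes)
  out <- list(); a <- c(); b <- c()
  for (i in seq_along(genes)) for (j in seq_along(genes)) {
    if (i >= j) next
    row <- integer(ncol(x))
    for (s in seq_len(ncol(x)))
      row[s] <- if (x[genes[i], s] > x[genes[j], s]) 1L else 0L
    out[[length(out) + 1L]] <- row
    a <- c(a, genes[i]); b <- c(b, genes[j])
  }
  m <- do.call(rbind, out)
  rownames(m) <- paste(a, b, sep = "|")
  colnames(m) <- colnames(x)
  m
}

# naive running-sum GSEA enrichment score (position-by-position walk)
es_oracle <- function(metric, members, weight = 1) {
  o <- order(metric, decreasing = TRUE)
  g <- names(metric)[o]; r <- metric[o]
  nh <- sum(g %in% members); n <- length(g)
  nr <- 0
  for (i in seq_len(n)) if (g[i] %in% members) nr <- nr + abs(r[i])^weight
  run <- 0; best <- 0
  for (i in seq_len(n)) {
    if (g[i] %in% members) {
      run <- run + (if (nr > 0) unname(abs(r[i]))^weight / nr else 1 / nh)
    } else {
      run <- run - 1 / (n - nh)
    }
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}
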