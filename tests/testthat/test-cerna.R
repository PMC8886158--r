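itab <- function(src, tgt, db, kind) {
  interaction_table(data.frame(source_id = src, target_id = tgt,
                               source_db = db, stringsAsFactors = FALSE),
                    kind)
}

test_that("target prediction applies the consensus rule across databases", {
  lm <- itab(c("L1", "L1", "L2"), c("m1", "m2", "m3"), "dbA", "lncRNA-miRNA")
  t1 <- itab(c("m1", "m1", "m2"), c("R1", "R2", "R3"), "t1", "miRNA-mRNA")
  t2 <- itab(c("m1", "m1", "m2"), c("R1", "R2", "R3"), "t2", "miRNA-mRNA")
  t3 <- itab(c("m1", "m2"), c("R1", "R3"), "t3", "miRNA-mRNA")
  tables <- list(t1, t2, t3)

  res_all <- predict_targets(c("L1"), lm, tables, "all")
  expect_equal(res_all$mirnas, c("m1", "m2"))
  # R2 is in only 2 of 3 tables -> excluded under "all"
  expect_equal(res_all$mrnas, c("R1", "R3"))
  res_any <- predict_targets(c("L1"), lm, tables, "any")
  expect_equal(res_any$mrnas, c("R1", "R2", "R3"))
  expect_true(all(res_all$mrnas %in% res_any$mrnas))

  expect_equal(predict_targets(character(), lm, tables, "all")$mrnas,
               character())
  expect_error(predict_targets("L1", lm, tables, "most"))
})

test_that("hub intersection is symmetric and sorted", {
  expect_equal(hub_mrnas(c("X", "Y"), c("Y", "Z")), "Y")
  expect_equal(hub_mrnas(c("X", "Y"), c("Y", "Z")),
               hub_mrnas(c("Y", "Z"), c("X", "Y")))
  expect_equal(hub_mrnas(c("A"), c("B")), character())
  expect_equal(hub_mrnas(c("b", "a"), c("a", "b")), c("a", "b"))
})

test_that("network assembly back-propagates from hubs without orphans", {
  lm <- itab(c("L1", "L2"), c("m1", "m2"), "dbA", "lncRNA-miRNA")
  tts <- lapply(c("t1", "t2", "t3"), function(db)
    itab(c("m1", "m2"), c("R1", "R2"), db, "miRNA-mRNA"))
  net <- assemble_network("R1", lm, tts, "all")
  expect_equal(net$nodes$id, c("L1", "m1", "R1"))
  expect_equal(nrow(net$edges), 2)
  expect_equal(net$hubs, "R1")

  # hub with no consensus miRNA is dropped with a warning
  t_partial <- list(itab("m9", "R9", "t1", "miRNA-mRNA"),
                    itab("mX", "R9", "t2", "miRNA-mRNA"),
                    itab("mX", "R9", "t3", "miRNA-mRNA"))
  expect_warning(net2 <- assemble_network("R9", lm, t_partial, "all"),
                 "dropped")
  expect_equal(nrow(net2$nodes), 0)

  # every edge connects adjacent layers
  type_of <- setNames(net$nodes$type, net$nodes$id)
  for (k in seq_len(nrow(net$edges))) {
    pair <- sort(type_of[c(net$edges$source[k], net$edges$target[k])])
    expect_true(identical(unname(pair), c("lncRNA", "miRNA")) ||
                identical(unname(pair), c("mRNA", "miRNA")))
  }
})

test_that("network assembly equals a brute-force two-hop search and is monotone", {
  set.seed(55)
  for (rep in 1:10) {
    lncs <- paste0("L", 1:4); mirs <- paste0("m", 1:5); mrs <- paste0("R", 1:6)
    lm_df <- unique(data.frame(
      source_id = sample(lncs, 12, TRUE), target_id = sample(mirs, 12, TRUE),
      source_db = "dbA", stringsAsFactors = FALSE))
    tts <- lapply(c("t1", "t2", "t3"), function(db)
      unique(data.frame(source_id = sample(mirs, 15, TRUE),
                        target_id = sample(mrs, 15, TRUE),
                        source_db = db, stringsAsFactors = FALSE)))
    hubs <- sample(mrs, 3)
    net <- suppressWarnings(assemble_network(hubs, lm_df, tts, "all"))

    # oracle: consensus edge set, then explicit two-hop walk
    keyset <- Reduce(intersect, lapply(tts, function(d)
      paste(d$source_id, d$target_id)))
    keep_m <- character(); keep_h <- character(); keep_l <- character()
    for (m in mirs) for (h in hubs)
      if (paste(m, h) %in% keyset) {
        if (any(lm_df$target_id == m)) {
          keep_m <- union(keep_m, m); keep_h <- union(keep_h, h)
        }
      }
    for (l in lncs) for (m in keep_m)
      if (any(lm_df$source_id == l & lm_df$target_id == m))
        keep_l <- union(keep_l, l)
    expect_setequal(net$nodes$id[net$nodes$type == "miRNA"], keep_m)
    expect_setequal(net$hubs, sort(keep_h))
    expect_setequal(net$nodes$id[net$nodes$type == "lncRNA"], keep_l)

    # monotone: adding edges never removes nodes
    extra <- lapply(tts, function(d)
      unique(rbind(d, data.frame(source_id = "m1", target_id = "R1",
                                 source_db = d$source_db[1]))))
    lm_extra <- unique(rbind(lm_df, data.frame(source_id = "L1",
                                               target_id = "m1",
                                               source_db = "dbA")))
    net_big <- suppressWarnings(assemble_network(union(hubs, "R1"),
                                                 lm_extra, extra, "all"))
    expect_true(all(net$nodes$id %in% net_big$nodes$id))
  }
})

test_that("hypergeometric enrichment matches exact tail sums", {
  # full overlap in a 20-gene universe: p = 1 / C(20,5)
  uni <- paste0("g", 1:20)
  res <- enrichment_test(uni[1:5], list(term = uni[1:5]), uni)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$p, 1 / 15504, tolerance = 1e-12)

  # a term equal to the universe is uninformative
  res_u <- enrichment_test(uni[1:5], list(all = uni), uni)
  expect_equal(res_u$p, 1)

  # exact tail-sum oracle on random configurations
  set.seed(66)
  for (rep in 1:100) {
    N <- sample(10:40, 1); K <- sample(1:(N - 1), 1); n <- sample(1:(N - 1), 1)
    uni <- paste0("u", seq_len(N))
    term <- sample(uni, K); hits <- sample(uni, n)
    k <- length(intersect(term, hits))
    res <- enrichment_test(hits, list(t = term), uni)
    oracle <- sum(vapply(k:min(K, n), function(i)
      choose(K, i) * choose(N - K, n - i), 0)) / choose(N, n)
    expect_equal(res$p, oracle, tolerance = 1e-10)
  }
})

test_that("network files are written in standard formats", {
  lm <- itab("L1", "m1", "dbA", "lncRNA-miRNA")
  tts <- lapply(c("t1", "t2", "t3"), function(db)
    itab("m1", "R1", db, "miRNA-mRNA"))
  net <- assemble_network("R1", lm, tts, "all")
  sif <- withr::local_tempfile(fileext = ".sif")
  write_network_sif(net, sif)
  expect_equal(readLines(sif),
               c("L1\tlncRNA-miRNA\tm1", "m1\tmiRNA-mRNA\tR1"))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_network_tsv(net, tsv)
  expect_equal(nrow(utils::read.delim(tsv)), 2)
  skip_if_not_installed("igraph")
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(net, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(g), 3)
  expect_equal(igraph::gsize(g), 2)
})
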