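test_that("hypergeometric overlap p matches exhaustive enumeration", {
  # spec-sized worked case: N=10, K=4, n=5, k=3 -> 66/252
  expect_equal(overlap_pvalue(10, 4, 5, 3), 66 / 252, tolerance = 1e-12)
  expect_equal(enum_overlap_p(10, 4, 5, 3), 66 / 252, tolerance = 1e-12)
  # saturated: everything shared -> certain event
  expect_equal(overlap_pvalue(6, 6, 6, 6), 1)
  expect_equal(overlap_pvalue(8, 3, 5, 0), 1)
  # random spot checks against the enumeration oracle
  set.seed(42)
  for (i in 1:25) {
    N <- sample(2:11, 1)
    K <- sample(1:N, 1); n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(overlap_pvalue(N, K, n, k), enum_overlap_p(N, K, n, k),
                 tolerance = 1e-12,
                 label = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
  }
  expect_error(overlap_pvalue(10, 11, 5, 3), "N")
  expect_error(overlap_pvalue(10, 4, 5, 5), "exceeds")
})

test_that("shared-miRNA test counts sets within the universe", {
  db <- tiny_interactions()
  uni <- c("miR-1", "miR-2", "miR-3")
  res <- shared_mirna_test("L1", "G1", db, uni)
  expect_equal(res$shared, c("miR-1", "miR-2"))
  expect_equal(res[c("N", "K", "n", "k")], list(N = 3, K = 2, n = 2, k = 2))
  expect_equal(res$overlap_p, enum_overlap_p(3, 2, 2, 2), tolerance = 1e-12)
  # no shared miRNA -> not scored
  expect_null(shared_mirna_test("L1", "G2", db, uni))
  # target with no miRNA in the universe -> error (skipped upstream)
  expect_error(shared_mirna_test("L1", "G2", db, c("miR-1", "miR-2")),
               "no targeting miRNAs")
})

test_that("co-expression returns Pearson r with the t-based p-value", {
  set.seed(1)
  x <- rnorm(10)
  grp <- rep("tumor", 10)
  lnc <- logcpm_from(matrix(x, 1, 10, dimnames = list("L1", paste0("S", 1:10))),
                     "lncRNA", grp)
  up <- logcpm_from(matrix(2 * x + 1, 1, 10,
                           dimnames = list("G1", paste0("S", 1:10))),
                    "mRNA", grp)
  dn <- logcpm_from(matrix(-x, 1, 10,
                           dimnames = list("G1", paste0("S", 1:10))),
                    "mRNA", grp)
  expect_equal(coexpression("L1", "G1", lnc, up)$pcc_r, 1)
  expect_equal(coexpression("L1", "G1", lnc, dn)$pcc_r, -1)
  # p-value equals cor.test's t-distribution p
  set.seed(2)
  y <- rnorm(10)
  m2 <- logcpm_from(matrix(y, 1, 10, dimnames = list("G1", paste0("S", 1:10))),
                    "mRNA", grp)
  co <- coexpression("L1", "G1", lnc, m2)
  ref <- cor.test(x, y)
  expect_equal(co$pcc_r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(co$pcc_p, ref$p.value, tolerance = 1e-10)
  # zero variance is an error, not a silent NA
  cst <- logcpm_from(matrix(5, 1, 10, dimnames = list("G1", paste0("S", 1:10))),
                     "mRNA", grp)
  expect_error(coexpression("L1", "G1", lnc, cst), "zero variance")
})

test_that("correlation p-values are calibrated at the 5% level", {
  set.seed(33)
  n <- 100
  hits <- replicate(1000, {
    abs(cor(rnorm(n), rnorm(n)))
  })
  crit <- 0.197  # |r| threshold for p < 0.05 at n = 100
  expect_lt(abs(mean(hits > crit) - 0.05), 0.015)
})

test_that("regulation similarity matches its hand-computed cases", {
  # identical correlation profiles -> 1
  expect_equal(regsim_score(c(0.5, -0.2, 0.9), c(0.5, -0.2, 0.9)), 1)
  # M = 1, opposite signs of equal magnitude -> 0
  expect_equal(regsim_score(0.4, -0.4), 0)
  # M = 2, one opposite pair and one identical pair -> 1 - (1 + 0)/2 = 0.5
  expect_equal(regsim_score(c(0.4, 0.3), c(-0.4, 0.3)), 0.5)
  # 0/0 terms count as identical (0 contribution)
  expect_equal(regsim_score(c(0, 0.3), c(0, 0.3)), 1)
  # exponent "1" variant: plain mean of normalized differences
  expect_equal(regsim_score(c(0.4, 0.3), c(-0.4, 0.3), exponent = "1"), 0.5)
  expect_equal(regsim_score(c(0.2, 0.1), c(-0.4, 0.3), exponent = "1"),
               1 - mean(c(0.6 / 0.6, 0.2 / 0.4)))
})

test_that("regulation similarity is bounded and permutation-symmetric", {
  set.seed(9)
  for (i in 1:50) {
    M <- sample(1:6, 1)
    r1 <- runif(M, -1, 1); r2 <- runif(M, -1, 1)
    s <- regsim_score(r1, r2)
    expect_gte(s, 0); expect_lte(s, 1)
    perm <- sample(M)
    expect_equal(regsim_score(r1[perm], r2[perm]), s, tolerance = 1e-12)
  }
})

test_that("regulation similarity over matrices drops zero-variance miRNAs", {
  set.seed(4)
  n <- 12
  grp <- rep("tumor", n)
  sn <- paste0("S", 1:n)
  mirv <- rbind(rnorm(n), rep(3, n))
  dimnames(mirv) <- list(c("miR-1", "miR-2"), sn)
  mir <- logcpm_from(mirv, "miRNA", grp)
  lnc <- logcpm_from(matrix(rnorm(n), 1, n, dimnames = list("L1", sn)),
                     "lncRNA", grp)
  mrna <- logcpm_from(matrix(rnorm(n), 1, n, dimnames = list("G1", sn)),
                      "mRNA", grp)
  cfg <- run_config(correlation_sample_set = "tumor")
  expect_warning(
    rs <- regulation_similarity("L1", "G1", c("miR-1", "miR-2"),
                                mir, lnc, mrna, cfg),
    "zero variance")
  expect_equal(rs$M, 1)
  expect_equal(names(rs$corr_lnc), "miR-1")
  r1 <- cor(mirv[1, ], lnc$values[1, ])
  r2 <- cor(mirv[1, ], mrna$values[1, ])
  expect_equal(rs$regsim, regsim_score(r1, r2), tolerance = 1e-12)
})

test_that("network construction counts nodes, edges and hubs correctly", {
  # one pair with 3 shared miRNAs -> 5 nodes, 6 edges, each miRNA degree 2
  pairs <- data.frame(
    lncrna_id = "L1", mrna_id = "G1", M = 3L,
    shared_mirnas = "miR-1,miR-2,miR-3",
    overlap_p = 0.001, pcc_r = 0.9, pcc_p = 0.001, regsim = 0.8,
    pass_overlap = TRUE, pass_pcc = TRUE, passes = TRUE,
    stringsAsFactors = FALSE)
  net <- build_network(pairs, run_config())
  expect_equal(nrow(net$nodes), 5)
  expect_equal(nrow(net$edges), 6)
  mir_deg <- net$nodes$degree[grepl("^miR", net$nodes$id)]
  expect_equal(mir_deg, rep(2L, 3))
  expect_equal(sum(net$nodes$degree), 2 * nrow(net$edges))

  # star: 1 lncRNA x 9 mRNAs via one miRNA -> the miRNA is hub #1, degree 10
  star <- do.call(rbind, lapply(1:9, function(i) {
    p <- pairs; p$mrna_id <- paste0("G", i); p$shared_mirnas <- "miR-hub"; p
  }))
  net2 <- build_network(star, run_config())
  expect_equal(net2$hubs[1], "miR-hub")
  expect_equal(net2$nodes$degree[net2$nodes$id == "miR-hub"], 10L)

  # duplicated miRNA-lncRNA edge across two pairs stored once
  two <- rbind(pairs, within(pairs, mrna_id <- "G2"))
  two$shared_mirnas <- "miR-1"
  net3 <- build_network(two, run_config())
  expect_equal(sum(net3$edges$source == "miR-1" & net3$edges$target == "L1"), 1)
  expect_equal(nrow(net3$edges), 3)

  # bipartite by construction: every edge has a miRNA endpoint
  expect_true(all(net3$edges$source %in%
                    net3$nodes$id[net3$nodes$class == "miRNA"]))
  expect_error(build_network(pairs[0, ], run_config()), "no passing")
})

test_that("triplet extraction respects the hub restriction", {
  pairs <- data.frame(
    lncrna_id = c("L1", "L2"), mrna_id = c("G1", "G2"), M = c(2L, 1L),
    shared_mirnas = c("miR-1,miR-2", "miR-1"),
    overlap_p = 0.01, pcc_r = 0.8, pcc_p = 0.01, regsim = 0.9,
    pass_overlap = TRUE, pass_pcc = TRUE, passes = TRUE,
    stringsAsFactors = FALSE)
  net <- build_network(pairs, run_config(hub_k = 4))
  trip <- extract_triplets(net, pairs)
  expect_equal(nrow(trip), 3)
  # a triplet whose member misses the hub set is flagged out
  hub_only <- trip[trip$in_hub_subnet, ]
  expect_true(all(hub_only$lncrna_id %in% net$hubs &
                    hub_only$mirna_id %in% net$hubs &
                    hub_only$mrna_id %in% net$hubs))
  excluded <- trip[!trip$in_hub_subnet, ]
  expect_true(all(!(excluded$lncrna_id %in% net$hubs) |
                    !(excluded$mirna_id %in% net$hubs) |
                    !(excluded$mrna_id %in% net$hubs)))
  # no passing pair -> empty triplet table
  expect_equal(nrow(extract_triplets(net, pairs[0, ])), 0)
})

test_that("planted pairs pass all gates and decoys mostly fail", {
  co <- simulate_cohort(seed = 8)
  lc <- lapply(co[c("lncrna", "mrna", "mirna")], log_cpm)
  cfg <- run_config()
  de_mir <- de_genes(call_de(co$mirna, cfg))
  de_lnc <- de_genes(call_de(co$lncrna, cfg))
  de_mrna <- de_genes(call_de(co$mrna, cfg))
  db <- restrict_db(co$db, de_mir, c(de_lnc, de_mrna))
  pairs <- score_cerna_pairs(db, lc$lncrna, lc$mrna, lc$mirna, cfg)
  key <- paste(pairs$lncrna_id, pairs$mrna_id)
  tr <- co$truth$planted_triplets
  planted_key <- paste(tr$lncrna_id, tr$mrna_id)
  expect_true(all(planted_key %in% key))
  expect_true(all(pairs$passes[key %in% planted_key]))
  decoy <- pairs[!(key %in% planted_key), ]
  expect_gte(mean(!decoy$passes), 0.9)
  # filter chain is monotone
  expect_lte(sum(pairs$pass_pcc), sum(pairs$pass_overlap))
  expect_lte(sum(pairs$passes), sum(pairs$pass_pcc))
})
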