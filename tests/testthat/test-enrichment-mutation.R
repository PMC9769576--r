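test_that("variant classification follows the nonsynonymous rule", {
  maf <- maf_table(c("p1", "p2", "p2", "p3"),
                   c("TP53", "TP53", "TP53", "KRAS"),
                   c("Silent", "Missense", "Silent", "Frame_Shift_Del"))
  status <- classify_variants(maf, samples = c("p1", "p2", "p3", "p4"),
                              genes = c("TP53", "KRAS"))
  expect_false(status["p1", "TP53"])  # silent-only carrier is wild-type
  expect_true(status["p2", "TP53"])   # >=1 nonsynonymous record suffices
  expect_true(status["p3", "KRAS"])
  expect_false(any(status["p4", ]))   # record-free sample stays wild-type
  # empty MAF: all wild-type
  empty <- maf_table(character(0), character(0), character(0))
  st0 <- classify_variants(empty, samples = c("p1", "p2"), genes = "TP53")
  expect_false(any(st0))
  expect_error(classify_variants(
    maf_table("p1", "TP53", "Made_Up_Class")), "unknown variant")
})

test_that("classification is idempotent and order-independent", {
  set.seed(131)
  vocab <- unlist(variant_class_map())
  maf <- maf_table(sample(sprintf("p%02d", 1:10), 60, TRUE),
                   sample(c("TP53", "KRAS", "ARID1A"), 60, TRUE),
                   sample(vocab, 60, TRUE))
  s1 <- classify_variants(maf, samples = sprintf("p%02d", 1:10),
                          genes = c("TP53", "KRAS", "ARID1A"))
  shuffled <- maf[sample(nrow(maf)), ]
  class(shuffled) <- class(maf)
  s2 <- classify_variants(shuffled, samples = sprintf("p%02d", 1:10),
                          genes = c("TP53", "KRAS", "ARID1A"))
  expect_identical(s1, s2)
})

test_that("frequency comparison matches textbook z and chi-square formulas", {
  status <- matrix(FALSE, 200, 1, dimnames = list(sprintf("p%03d", 1:200), "G"))
  status[1:30, 1] <- TRUE          # 30/100 in group high
  status[101:110, 1] <- TRUE       # 10/100 in group low
  groups <- stats::setNames(rep(c("high", "low"), each = 100),
                            rownames(status))
  cmp <- compare_mutation_frequency(status, groups, higher = "high")
  p1 <- 0.3; p2 <- 0.1; pp <- 0.2
  z_hand <- (p1 - p2) / sqrt(pp * 0.8 * (1 / 100 + 1 / 100))
  expect_equal(cmp$z, z_hand, tolerance = 1e-10)
  expect_equal(cmp$p_z, stats::pnorm(z_hand, lower.tail = FALSE),
               tolerance = 1e-10)
  # Pearson chi-square (no continuity correction) equals z^2 on a 2x2
  expect_equal(cmp$p_chisq, stats::pchisq(z_hand^2, 1, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_true(cmp$significant)
})

test_that("equal proportions give z = 0 and degenerate genes p = 1", {
  status <- matrix(FALSE, 40, 2, dimnames = list(sprintf("p%02d", 1:40),
                                                 c("EQ", "NONE")))
  status[c(1:5, 21:25), "EQ"] <- TRUE
  groups <- stats::setNames(rep(c("high", "low"), each = 20), rownames(status))
  cmp <- compare_mutation_frequency(status, groups, higher = "high")
  eq <- cmp[cmp$gene == "EQ", ]
  expect_equal(eq$z, 0)
  expect_equal(eq$p_z, 0.5)
  none <- cmp[cmp$gene == "NONE", ]
  expect_true(none$degenerate)
  expect_equal(none$p_z, 1)
  expect_equal(none$p_chisq, 1)
})

test_that("generator truth is recovered by the frequency test", {
  prof <- list(high = c(DIFF = 0.5, SAME = 0.3),
               low = c(DIFF = 0.1, SAME = 0.3))
  cfg <- synthetic_config(seed = 132, n_genes = 10, n_samples = 10,
                          signature_size = 2, mutation_profile = prof)
  groups <- stats::setNames(rep(c("high", "low"), each = 500),
                            sprintf("S%04d", 1:1000))
  maf <- generate_maf(cfg, groups, silent_rate = 0)
  status <- classify_variants(maf, samples = names(groups),
                              genes = c("DIFF", "SAME"))
  cmp <- compare_mutation_frequency(status, groups, higher = "high")
  expect_lt(cmp$p_z[cmp$gene == "DIFF"], 0.01)
  expect_gt(cmp$p_z[cmp$gene == "SAME"], 0.01)
})

test_that("Fisher exact agrees with full enumeration on small tables", {
  cases <- list(c(0, 5, 7, 0), c(3, 2, 1, 4), c(10, 0, 0, 10), c(2, 2, 2, 2))
  for (tb in cases) {
    for (alt in c("two.sided", "greater", "less")) {
      expect_equal(fisher_exact_2x2(tb[1], tb[2], tb[3], tb[4], alt),
                   fisher_enum_oracle(tb[1], tb[2], tb[3], tb[4], alt),
                   tolerance = 1e-10)
    }
  }
  expect_equal(fisher_exact_2x2(0, 0, 0, 0), 1)
  # proportional rows: close to independence, p near 1
  expect_gt(fisher_exact_2x2(4, 8, 2, 4), 0.99)
  # symmetry under transposition and row/column swaps
  expect_equal(fisher_exact_2x2(3, 1, 2, 6), fisher_exact_2x2(3, 2, 1, 6))
  expect_equal(fisher_exact_2x2(3, 1, 2, 6), fisher_exact_2x2(6, 2, 1, 3))
})

test_that("co-occurrence scan finds planted pairs and skips rare genes", {
  prof <- list(all = c(GA = 0.25, GB = 0.25, GC = 0.25, RARE = 0.002))
  cfg <- synthetic_config(seed = 133, n_genes = 10, n_samples = 10,
                          signature_size = 2, mutation_profile = prof,
                          cooccurrence_pairs = list(list("GA", "GB", 5)))
  groups <- stats::setNames(rep("all", 500), sprintf("S%04d", 1:500))
  maf <- generate_maf(cfg, groups, silent_rate = 0)
  status <- classify_variants(maf, samples = names(groups),
                              genes = c("GA", "GB", "GC", "RARE"))
  expect_message(res <- cooccurrence_scan(status, min_mutated = 5),
                 "skipping")
  expect_false(any(res$gene_a == res$gene_b))
  expect_false("RARE" %in% c(res$gene_a, res$gene_b))
  planted <- res[res$gene_a == "GA" & res$gene_b == "GB", ]
  expect_equal(planted$direction, "co-occurring")
  expect_lt(planted$q, 0.05)
  expect_error(cooccurrence_scan(status[, "RARE", drop = FALSE]),
               "fewer than 2")
})

test_that("independent gene pairs rarely reach q < 0.05", {
  hits <- 0; total <- 0
  for (s in 1:20) {
    prof <- list(all = stats::setNames(rep(0.25, 6), paste0("N", 1:6)))
    cfg <- synthetic_config(seed = 200 + s, n_genes = 10, n_samples = 10,
                            signature_size = 2, mutation_profile = prof)
    groups <- stats::setNames(rep("all", 200), sprintf("S%04d", 1:200))
    maf <- generate_maf(cfg, groups, silent_rate = 0, seed = 200 + s)
    status <- classify_variants(maf, samples = names(groups),
                                genes = paste0("N", 1:6))
    res <- cooccurrence_scan(status, min_mutated = 5)
    hits <- hits + sum(res$q < 0.05)
    total <- total + nrow(res)
  }
  expect_lte(hits / total, 0.05)
})

test_that("hypergeometric ORA matches closed forms and enumeration", {
  universe <- sprintf("u%02d", 1:20)
  query <- universe[1:5]
  res <- hypergeom_ora(query, list(gene_signature("hit", universe[1:5])),
                       universe)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$p, ora_enum_oracle(5, 5, 20, 5), tolerance = 1e-12)
  # query = set = universe: overlap is certain
  res2 <- hypergeom_ora(universe, list(all = universe), universe)
  expect_equal(res2$p, 1)
  # zero overlap with a large set: p ~ 1
  res3 <- hypergeom_ora(universe[1:3],
                        list(gene_signature("other", universe[10:20])),
                        universe)
  expect_gt(res3$p, 0.9)
  # random instances against enumeration
  set.seed(134)
  for (i in 1:20) {
    u <- sprintf("g%02d", 1:12)
    st <- sample(u, sample(2:8, 1))
    q <- sample(u, sample(2:8, 1))
    k <- length(intersect(st, q))
    res4 <- hypergeom_ora(q, list(s = st), u)
    expect_equal(res4$p, ora_enum_oracle(k, length(st), 12, length(q)),
                 tolerance = 1e-12)
  }
  expect_warning(hypergeom_ora(c(universe[1], "OUTSIDER"),
                               list(s = universe[1:4]), universe),
                 "outside the universe")
  expect_error(suppressWarnings(
    hypergeom_ora("OUTSIDER", list(s = universe[1:4]), universe)),
    "empty")
})

test_that("BH adjustment matches the hand step-up computation", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(135)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_equal(q, bh_oracle(p), tolerance = 1e-12)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
})
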