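test_that("normalization applies CP10K+log2 to counts and is idempotent", {
  m <- matrix(c(10, 90, 0, 0), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  em <- expression_matrix(m, "raw_counts")
  norm <- normalize_matrix(em)
  expect_identical(expr_space(norm), "log_normalized")
  expect_equal(unname(norm["g1", "s1"]), log2(1 + 1000))
  expect_equal(unname(norm["g2", "s1"]), log2(1 + 9000))
  expect_equal(unname(norm[, "s2"]), c(0, 0))  # all-zero sample stays zero
  expect_identical(unclass(normalize_matrix(norm)), unclass(norm))
})

test_that("winsorization clamps gene tails", {
  em <- random_expr(20, 200, seed = 61)
  w <- normalize_matrix(em, winsorize = TRUE)
  for (g in rownames(em)) {
    q <- stats::quantile(unclass(em)[g, ], c(0.01, 0.99), names = FALSE)
    expect_gte(min(w[g, ]), q[1])
    expect_lte(max(w[g, ]), q[2])
  }
})

test_that("ssGSEA matches the step-by-step running-sum oracle", {
  x_top <- c(a = 5, b = 4, c = 3, d = 2, e = 1)
  x_bot <- c(a = 1, b = 2, c = 5, d = 4, e = 3)
  em <- expression_matrix(cbind(top = x_top, bottom = x_bot), "log_normalized")
  sc <- ssgsea_score(em, gene_signature("sig", c("a", "b")))$scores
  expect_equal(unname(sc["top"]), ssgsea_oracle(x_top, c("a", "b")),
               tolerance = 1e-12)
  expect_equal(unname(sc["bottom"]), ssgsea_oracle(x_bot, c("a", "b")),
               tolerance = 1e-12)
  # frozen oracle values: signature at the top of the list scores higher
  expect_equal(unname(sc["top"]), 2.513942856221443, tolerance = 1e-9)
  expect_equal(unname(sc["bottom"]), -2.456786383137055, tolerance = 1e-9)
  expect_gt(sc["top"], sc["bottom"])
})

test_that("ssGSEA is rank-invariant, deterministic, and errors on no overlap", {
  for (s in 1:25) {
    em <- random_expr(40, 3, seed = 600 + s)
    sig <- gene_signature("s", sample(rownames(em), 6))
    sc1 <- ssgsea_score(em, sig)$scores
    # strictly increasing transform per sample leaves ranks untouched
    em2 <- expression_matrix(exp(unclass(em)) * 3 + 1, "log_normalized")
    sc2 <- ssgsea_score(em2, sig)$scores
    expect_equal(sc1, sc2, tolerance = 1e-12)
    expect_identical(sc1, ssgsea_score(em, sig)$scores)
  }
  em <- random_expr(20, 2, seed = 700)
  expect_error(ssgsea_score(em, gene_signature("none", c("ZZZ1", "ZZZ2"))),
               "no genes in common")
  # identical expression vectors get identical scores
  m <- unclass(random_expr(30, 1, seed = 701))
  em3 <- expression_matrix(cbind(s1 = m[, 1], s2 = m[, 1]), "log_normalized")
  sc <- ssgsea_score(em3, gene_signature("s", rownames(m)[1:5]))$scores
  expect_equal(unname(sc["s1"]), unname(sc["s2"]))
})

test_that("absent signature genes are dropped with a message", {
  em <- random_expr(30, 4, seed = 71)
  sig <- gene_signature("s", c(rownames(em)[1:4], "NOT_THERE"))
  expect_message(sc <- ssgsea_score(em, sig), "dropped 1")
  expect_equal(sc$n_used, 4L)
})

test_that("expression bins are near-equal, deterministic, and validated", {
  em <- random_expr(100, 5, seed = 81)
  bins <- assign_bins(em, 50)
  expect_true(all(table(bins) == 2))
  expect_identical(sort(names(bins)), sort(rownames(em)))
  expect_true(all(assign_bins(em, 1) == 1))
  expect_error(assign_bins(em, 101), "exceeds")
  # constant matrix: lexicographic tie-break, rerun-stable
  cm <- expression_matrix(matrix(1, 10, 2,
                                 dimnames = list(letters[10:1], c("a", "b"))),
                          "log_normalized")
  b1 <- assign_bins(cm, 5); b2 <- assign_bins(cm, 5)
  expect_identical(b1, b2)
  expect_identical(b1[order(names(b1))], setNames(rep(1:5, each = 2),
                                                  sort(names(b1))))
  # bins follow mean expression
  mu <- rowMeans(unclass(em))
  expect_true(all(diff(bins[order(mu, rownames(em))]) >= 0))
})

test_that("matched background sets preserve size and per-bin frequency", {
  em <- random_expr(500, 6, seed = 91)
  sig <- gene_signature("s", sample(rownames(em), 40))
  bins <- assign_bins(em, 10)
  sets <- sample_matched_background(bins, sig, n_iterations = 200, seed = 7)
  nb <- table(factor(bins[sig$genes], levels = 1:10))
  for (st in sets) {
    expect_length(st, 40L)
    expect_length(unique(st), 40L)  # within-draw sampling w/o replacement
    expect_equal(as.vector(table(factor(bins[st], levels = 1:10))),
                 as.vector(nb))
  }
  # reproducible from seed
  expect_identical(sets,
                   sample_matched_background(bins, sig, 200, seed = 7))
})

test_that("signature occupying a whole bin forces that bin into every draw", {
  m <- matrix(seq_len(20), 20, 2,
              dimnames = list(sprintf("g%02d", 1:20), c("a", "b")))
  em <- expression_matrix(m * 1.0, "log_normalized")
  bins <- assign_bins(em, 4)
  whole_bin <- names(bins)[bins == 2]
  sets <- sample_matched_background(bins, gene_signature("s", whole_bin),
                                    n_iterations = 50, seed = 3)
  for (st in sets) expect_setequal(st, whole_bin)
})

test_that("background gene inclusion frequencies match the sampling law", {
  em <- random_expr(200, 4, seed = 92)
  bins <- assign_bins(em, 10)  # 20 genes per bin
  sig <- gene_signature("s", unlist(lapply(split(names(bins), bins),
                                           `[`, 1:2), use.names = FALSE))
  sets <- sample_matched_background(bins, sig, n_iterations = 1000, seed = 11)
  incl <- table(factor(unlist(sets), levels = names(bins))) / 1000
  # each gene is included with prob N_b/|bin| = 2/20; 99% binomial bounds
  p <- 2 / 20
  bound <- stats::qnorm(0.995) * sqrt(p * (1 - p) / 1000)
  expect_true(all(abs(incl - p) < bound + 0.01))
})

test_that("degenerate null of the signature itself reproduces its score", {
  em <- random_expr(60, 5, seed = 93)
  sig <- gene_signature("s", rownames(em)[1:8])
  own <- ssgsea_score(em, sig)$scores
  null <- background_scores(em, replicate(20, sig$genes, simplify = FALSE))
  expect_equal(unname(null$random_score), unname(own), tolerance = 1e-12)
  expect_true(all(null$null_sd < 1e-12))
})

test_that("quantile threshold follows the linear-interpolation definition", {
  expect_equal(crd_threshold(c(1, 2, 3, 4), 0.75), 3.25)
  expect_equal(crd_threshold(rep(7, 10), 0.75), 7)
  x <- c(2.2, 0.4, 9.1, 5.5, 3.3)
  expect_equal(crd_threshold(x, 0.5), stats::median(x))
  expect_error(crd_threshold(c(1, 2, 3, 4), 1.2), "between 0 and 1")
  expect_error(crd_threshold(c(1, 2, 3), 0.75), "at least 4")
})

test_that("categorization splits tertiles evenly and is rank-invariant", {
  sc <- stats::setNames(as.numeric(1:9), paste0("s", 1:9))
  lab <- categorize(sc, "tertile")
  expect_equal(as.vector(table(lab)[c("low", "medium", "high")]), c(3, 3, 3))
  lab2 <- categorize(exp(sc) * 2, "tertile")
  expect_identical(lab, lab2)
  thr <- categorize(sc, "threshold", threshold_value = 6.5)
  expect_equal(sum(thr == "abnormal"), 3)
  expect_error(categorize(sc, "threshold"), "threshold_value")
})

test_that("score gap between spiked and background grows with spike effect", {
  gap <- vapply(c(0.5, 1, 2), function(delta) {
    cfg <- synthetic_config(seed = 17, n_genes = 400, n_samples = 60,
                            signature_size = 25, spike_effect = delta)
    g <- generate_expression(cfg)
    sc <- ssgsea_score(g$expr, g$signature)$scores
    mean(sc[g$labels == "spiked"]) - mean(sc[g$labels == "background"])
  }, numeric(1))
  expect_gt(gap[1], 0)
  expect_true(all(diff(gap) > 0))
})

test_that("spiked samples are recovered in the high tertile", {
  cfg <- synthetic_config(seed = 19, n_genes = 1000, n_samples = 300,
                          signature_size = 50, spike_effect = 2)
  g <- generate_expression(cfg)
  sc <- ssgsea_score(g$expr, g$signature)$scores
  lab <- categorize(sc, "tertile")
  tab <- table(spiked = g$labels == "spiked", high = lab == "high")
  expect_lt(stats::fisher.test(tab)$p.value, 0.01)
})
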