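# Per-sample ssGSEA scoring of a gene signature, the expression-bin-matched
# random background, and quartile-based abnormality calling.
#
# The running-sum enrichment statistic depends only on within-sample ranks,
# so every score here is invariant under strictly increasing transforms of a
# sample's expression vector.

#' Normalize an expression matrix for signature scoring
#'
#' Raw counts are converted per sample to log2(1 + counts-per-10k); matrices
#' already in log space pass through unchanged. Optional winsorization clamps
#' each gene at its 1st/99th percentile across samples to damp outliers.
#'
#' @param expr An [expression_matrix()].
#' @param winsorize Clamp each gene at its 1st/99th percentile.
#' @param scale_factor Library-size scale factor (default 1e4).
#' @return An `ExpressionMatrix` with `space = "log_normalized"`.
#' @export
normalize_matrix <- function(expr, winsorize = FALSE, scale_factor = 1e4) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  m <- unclass(expr)
  if (expr_space(expr) == "raw_counts") {
    if (any(m < 0)) stop("raw counts must be non-negative")
    libsize <- colSums(m)
    scale <- ifelse(libsize > 0, scale_factor / libsize, 0)
    m <- log2(1 + sweep(m, 2, scale, `*`))
  }
  if (winsorize) {
    m <- t(apply(m, 1, function(x) {
      q <- stats::quantile(x, c(0.01, 0.99), names = FALSE)
      pmin(pmax(x, q[1]), q[2])
    }))
    dimnames(m) <- dimnames(expr)
  }
  expression_matrix(m, space = "log_normalized")
}

# Per-sample rank machinery shared by signature and background scoring.
# For each sample: w = rank(x, ties average)^alpha (top-expressed gene gets
# the largest weight) and m = G - pos + 1 where pos is the position in the
# descending walk (expression ties broken by gene symbol for determinism).
ssgsea_prepare <- function(expr, alpha) {
  m <- unclass(expr)
  G <- nrow(m)
  W <- apply(m, 2, function(x) rank(x, ties.method = "average")^alpha)
  POS <- apply(m, 2, function(x) {
    o <- order(-x, rownames(m))
    p <- integer(G); p[o] <- seq_len(G)
    G - p + 1  # contribution multiplier of each gene to the running-sum area
  })
  rownames(W) <- rownames(m); rownames(POS) <- rownames(m)
  list(W = W, M = POS, G = G, genes = rownames(m),
       samples = colnames(m), m_total = G * (G + 1) / 2)
}

# Score a list of gene sets on prepared rank data; returns sets x samples.
ssgsea_score_sets <- function(prep, sets) {
  idx <- lapply(sets, function(g) match(g, prep$genes))
  if (any(vapply(idx, anyNA, logical(1))))
    stop("internal: set gene absent from matrix")
  k <- lengths(idx)
  if (any(k >= prep$G)) stop("a gene set covers the whole matrix universe")
  n <- length(sets)
  ind <- Matrix::sparseMatrix(i = rep(seq_len(n), k), j = unlist(idx), x = 1,
                              dims = c(n, prep$G))
  wm_in <- as.matrix(ind %*% (prep$W * prep$M))  # sum_{g in S} w_g m_g
  w_in <- as.matrix(ind %*% prep$W)              # sum_{g in S} w_g
  m_in <- as.matrix(ind %*% prep$M)              # sum_{g in S} m_g
  wm_in / w_in - (prep$m_total - m_in) / (prep$G - k)
}

#' Single-sample GSEA enrichment score
#'
#' For each sample, all genes are ranked by expression (descending walk,
#' expression ties broken alphabetically; rank weights use average ranks).
#' Walking down the list, the running sum accumulates the normalized
#' rank-weight mass of signature genes seen (`P_in`) minus the normalized
#' count of non-signature genes seen (`P_out`); the score is the sum of
#' `P_in - P_out` over all list positions (area variant). Signature genes
#' absent from the matrix are dropped with a message; zero overlap is an
#' error.
#'
#' @param expr An [expression_matrix()] (log space recommended; see
#'   [normalize_matrix()]).
#' @param signature A [gene_signature()].
#' @param alpha Rank-weight exponent (default 0.25).
#' @param normalize Divide all scores by `max - min` over samples.
#' @return Object of class `EnrichmentResult`: list with `scores` (named
#'   per-sample numeric), `signature`, `alpha`, `normalized`, `n_used`
#'   (signature genes present).
#' @export
ssgsea_score <- function(expr, signature, alpha = 0.25, normalize = FALSE) {
  stopifnot(inherits(expr, "ExpressionMatrix"),
            inherits(signature, "GeneSignature"))
  present <- intersect(signature$genes, rownames(expr))
  dropped <- length(signature$genes) - length(present)
  if (length(present) == 0L)
    stop("signature '", signature$name,
         "' has no genes in common with the expression matrix")
  if (dropped > 0L)
    message(sprintf("ssgsea_score: dropped %d signature gene(s) absent from the matrix",
                    dropped))
  prep <- ssgsea_prepare(expr, alpha)
  sc <- drop(ssgsea_score_sets(prep, list(present)))
  names(sc) <- prep$samples
  if (normalize) {
    rng <- max(sc) - min(sc)
    if (rng > 0) sc <- sc / rng else warning("score range is zero; normalization skipped")
  }
  structure(list(scores = sc, signature = signature$name, alpha = alpha,
                 normalized = normalize, n_used = length(present)),
            class = "EnrichmentResult")
}

#' Assign genes to average-expression bins
#'
#' Genes are sorted by row mean (ties broken by gene symbol) and split into
#' `n_bins` groups of near-equal size (sizes differ by at most one; any
#' remainder goes to the lowest-expression bins). Bin 1 holds the
#' lowest-expressed genes.
#'
#' @param expr An [expression_matrix()].
#' @param n_bins Number of bins (default 50).
#' @return Named integer vector: gene -> bin index.
#' @export
assign_bins <- function(expr, n_bins = 50) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  G <- nrow(expr)
  if (n_bins < 1) stop("n_bins must be >= 1")
  if (n_bins > G) stop("n_bins (", n_bins, ") exceeds the number of genes (", G, ")")
  mu <- rowMeans(unclass(expr))
  ord <- order(mu, rownames(expr))
  base <- G %/% n_bins; rem <- G %% n_bins
  sizes <- rep(base, n_bins) + c(rep(1L, rem), rep(0L, n_bins - rem))
  bins <- integer(G)
  bins[ord] <- rep.int(seq_len(n_bins), sizes)
  names(bins) <- rownames(expr)
  bins
}

#' Sample expression-matched random gene sets
#'
#' For each bin, the signature's frequency `N_b` within that bin is computed;
#' each random set draws exactly `N_b` genes uniformly without replacement
#' from bin `b`, so every set matches the signature's expression-bin profile
#' and has the signature's total size `K`.
#'
#' @param bins Gene -> bin mapping from [assign_bins()].
#' @param signature A [gene_signature()]; all its genes must be binned.
#' @param n_iterations Number of random sets (default 1000).
#' @param seed Integer seed.
#' @return List of `n_iterations` character vectors of gene symbols.
#' @export
sample_matched_background <- function(bins, signature, n_iterations = 1000,
                                      seed = 1L) {
  stopifnot(inherits(signature, "GeneSignature"))
  missing <- setdiff(signature$genes, names(bins))
  if (length(missing))
    stop("signature gene(s) not in the binned universe: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  nb <- table(factor(bins[signature$genes], levels = sort(unique(bins))))
  members <- split(names(bins), bins)
  used <- names(nb)[nb > 0]
  for (b in used) {
    if (nb[[b]] > length(members[[b]]))
      stop("bin ", b, " holds ", length(members[[b]]),
           " genes but the signature needs ", nb[[b]])
  }
  with_seed(seed, {
    lapply(seq_len(n_iterations), function(i) {
      unlist(lapply(used, function(b) {
        pool <- members[[b]]
        pool[sample.int(length(pool), nb[[b]])]
      }), use.names = FALSE)
    })
  })
}

#' Score the random background sets
#'
#' Scores every matched random set on every sample with the same ssGSEA
#' statistic as the signature, yielding the empirical null distribution of
#' scores per sample and its mean, the "random score" background level.
#'
#' @param expr An [expression_matrix()].
#' @param random_sets List of gene sets from [sample_matched_background()].
#' @param alpha Rank-weight exponent.
#' @return Object of class `BackgroundNull`: list with `null_scores`
#'   (iterations x samples matrix), `random_score` (per-sample null mean),
#'   `null_sd` (per-sample null sd), `n_iterations`.
#' @export
background_scores <- function(expr, random_sets, alpha = 0.25) {
  stopifnot(inherits(expr, "ExpressionMatrix"), length(random_sets) >= 1)
  prep <- ssgsea_prepare(expr, alpha)
  ns <- ssgsea_score_sets(prep, random_sets)
  colnames(ns) <- prep$samples
  structure(list(null_scores = ns,
                 random_score = colMeans(ns),
                 null_sd = apply(ns, 2, stats::sd),
                 n_iterations = length(random_sets), alpha = alpha),
            class = "BackgroundNull")
}

#' Quantile threshold for abnormal CRD calling
#'
#' Returns the `q`-th empirical quantile (linear interpolation, type 7) of a
#' score vector; samples scoring above it are called abnormal. The published
#' analysis used the 75% quartile of its own cohort (-0.24 there); the
#' reusable rule is the quantile, not that data-dependent value.
#'
#' @param scores Numeric vector of at least 4 scores.
#' @param q Quantile in (0, 1); default 0.75.
#' @return The threshold value.
#' @export
crd_threshold <- function(scores, q = 0.75) {
  if (q <= 0 || q >= 1) stop("q must lie strictly between 0 and 1")
  if (length(scores) < 4) stop("need at least 4 scores for a quartile threshold")
  stats::quantile(scores, q, names = FALSE, type = 7)
}

#' Categorize samples by CRD score
#'
#' `tertile` splits scores into near-equal low/medium/high groups at the 1/3
#' and 2/3 empirical quantiles; `threshold` makes a binary abnormal/normal
#' call at a supplied threshold (scores above it are abnormal).
#'
#' @param scores Named numeric score vector.
#' @param method `"tertile"` or `"threshold"`.
#' @param threshold_value Required for `method = "threshold"`.
#' @return Named character vector of labels.
#' @export
categorize <- function(scores, method = c("tertile", "threshold"),
                       threshold_value = NULL) {
  method <- match.arg(method)
  if (!all(is.finite(scores))) stop("scores must be finite")
  if (method == "tertile") {
    qs <- stats::quantile(scores, c(1, 2) / 3, names = FALSE, type = 7)
    lab <- ifelse(scores > qs[2], "high", ifelse(scores > qs[1], "medium", "low"))
  } else {
    if (is.null(threshold_value))
      stop("method = 'threshold' requires threshold_value")
    lab <- ifelse(scores > threshold_value, "abnormal", "normal")
  }
  stats::setNames(lab, names(scores))
}

#' Full CRD scoring pipeline for one signature
#'
#' Normalizes the matrix, scores the signature per sample, builds the
#' expression-bin-matched null, and returns a per-sample table with score,
#' null mean/sd, empirical p-value and category call.
#'
#' @param expr An [expression_matrix()].
#' @param signature A [gene_signature()].
#' @param alpha Rank-weight exponent (default 0.25).
#' @param n_bins Expression bins for the null (default 50).
#' @param n_iterations Random sets (default 1000).
#' @param seed Integer seed for the background draws.
#' @param threshold_quantile Quantile for the abnormality threshold
#'   (default 0.75).
#' @return List with `table` (data.frame: sample, score, null_mean, null_sd,
#'   empirical_p, category), `threshold`, `null` (the `BackgroundNull`),
#'   `enrichment` (the `EnrichmentResult`).
#' @export
crd_score <- function(expr, signature, alpha = 0.25, n_bins = 50,
                      n_iterations = 1000, seed = 1L,
                      threshold_quantile = 0.75) {
  norm <- normalize_matrix(expr)
  present <- gene_signature(signature$name,
                            intersect(signature$genes, rownames(norm)))
  es <- ssgsea_score(norm, present, alpha = alpha)
  bins <- assign_bins(norm, n_bins = n_bins)
  sets <- sample_matched_background(bins, present, n_iterations = n_iterations,
                                    seed = seed)
  null <- background_scores(norm, sets, alpha = alpha)
  emp_p <- vapply(seq_along(es$scores), function(j)
    (1 + sum(null$null_scores[, j] >= es$scores[j])) / (null$n_iterations + 1),
    numeric(1))
  thr <- crd_threshold(es$scores, threshold_quantile)
  cat_lab <- categorize(es$scores, "threshold", threshold_value = thr)
  list(table = data.frame(sample = names(es$scores),
                          score = unname(es$scores),
                          null_mean = unname(null$random_score),
                          null_sd = unname(null$null_sd),
                          empirical_p = emp_p,
                          category = unname(cat_lab),
                          stringsAsFactors = FALSE),
       threshold = thr, null = null, enrichment = es)
}
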