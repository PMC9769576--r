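# Variant-class mapping, group-wise mutation-frequency tests, pairwise
# co-occurrence / mutual exclusivity, hypergeometric over-representation and
# BH adjustment.

#' The variant classification vocabulary
#'
#' Nonsynonymous classes confer mutated status; synonymous classes (silent,
#' intronic, UTR, intergenic) leave the protein unchanged and count as
#' wild-type.
#'
#' @return List with character vectors `nonsynonymous` and `synonymous`.
#' @export
variant_class_map <- function() {
  list(nonsynonymous = c("Missense", "Nonsense", "Frame_Shift_Ins",
                         "Frame_Shift_Del", "In_Frame_Ins", "In_Frame_Del",
                         "Splice_Site", "Translation_Start_Site", "Nonstop"),
       synonymous = c("Silent", "Intron", "3'UTR", "5'UTR", "Intergenic"))
}

#' Collapse a MAF table to per-sample per-gene mutation status
#'
#' A sample is mutated in a gene iff it carries at least one nonsynonymous
#' record for that gene; samples whose only records in a gene are synonymous
#' are wild-type there. Unknown classification strings are an error.
#'
#' @param maf A [maf_table()].
#' @param map Variant classification map ([variant_class_map()] by default).
#' @param samples Sample universe for the output rows (defaults to the
#'   samples present in the MAF; pass the full cohort so mutation-free
#'   samples appear as wild-type rows).
#' @param genes Gene universe for the output columns (defaults to genes in
#'   the MAF).
#' @return Logical matrix, samples x genes; `TRUE` = mutated.
#' @export
classify_variants <- function(maf, map = variant_class_map(),
                              samples = NULL, genes = NULL) {
  stopifnot(inherits(maf, "MAFTable"))
  vocab <- c(map$nonsynonymous, map$synonymous)
  unknown <- setdiff(unique(maf$variant_classification), vocab)
  if (length(unknown))
    stop("unknown variant classification(s): ",
         paste(unknown, collapse = ", "))
  if (is.null(samples)) samples <- unique(maf$sample)
  if (is.null(genes)) genes <- unique(maf$gene)
  status <- matrix(FALSE, length(samples), length(genes),
                   dimnames = list(samples, genes))
  hit <- maf$variant_classification %in% map$nonsynonymous &
    maf$sample %in% samples & maf$gene %in% genes
  if (any(hit))
    status[cbind(maf$sample[hit], maf$gene[hit])] <- TRUE
  status
}

#' Compare per-gene mutation frequencies between two groups
#'
#' For each gene, the mutated proportion in the `higher` group is tested
#' against the other group with a pooled-proportion one-sided z-test
#' (alternative: higher group more frequently mutated) and a two-sided
#' Pearson chi-square test without continuity correction. Degenerate genes
#' (both proportions 0 or both 1) get p = 1 and a flag. BH adjustment across
#' genes.
#'
#' @param status Logical samples x genes matrix from [classify_variants()].
#' @param groups Group label per sample (named by sample id or aligned with
#'   rows); exactly two levels.
#' @param higher Label of the group hypothesized to be more mutated
#'   (defaults to `"high"` when present, otherwise the first level).
#' @return Data.frame per gene: counts, proportions, `z`, `p_z` (one-sided),
#'   `p_chisq` (two-sided), `q_z`, `q_chisq`, `degenerate`, `significant`
#'   (p_z < 0.05).
#' @export
compare_mutation_frequency <- function(status, groups, higher = NULL) {
  if (!is.null(names(groups))) groups <- groups[rownames(status)]
  if (length(groups) != nrow(status))
    stop("groups must align with status rows")
  lev <- unique(groups)
  if (length(lev) != 2) stop("exactly two groups required; got: ",
                             paste(lev, collapse = ", "))
  if (is.null(higher)) higher <- if ("high" %in% lev) "high" else lev[1]
  if (!higher %in% lev) stop("'higher' must be one of the group labels")
  other <- setdiff(lev, higher)
  a_idx <- groups == higher; b_idx <- groups == other
  n1 <- sum(a_idx); n2 <- sum(b_idx)
  if (n1 == 0 || n2 == 0) stop("both groups must be non-empty")
  res <- lapply(colnames(status), function(g) {
    x1 <- sum(status[a_idx, g]); x2 <- sum(status[b_idx, g])
    p1 <- x1 / n1; p2 <- x2 / n2
    pp <- (x1 + x2) / (n1 + n2)
    degenerate <- pp == 0 || pp == 1
    if (degenerate) {
      z <- 0; pz <- 1; pc <- 1
    } else {
      z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
      pz <- stats::pnorm(z, lower.tail = FALSE)
      tab <- matrix(c(x1, n1 - x1, x2, n2 - x2), 2, 2)
      pc <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    }
    data.frame(gene = g, mutated_high = x1, n_high = n1, mutated_low = x2,
               n_low = n2, prop_high = p1, prop_low = p2, z = z, p_z = pz,
               p_chisq = pc, degenerate = degenerate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_z <- bh_adjust(out$p_z)
  out$q_chisq <- bh_adjust(out$p_chisq)
  out$significant <- out$p_z < 0.05
  out
}

#' Fisher exact test on a 2x2 table
#'
#' Exact p by hypergeometric probabilities of tables as or more extreme than
#' the observed one; the two-sided criterion is probability ordering (tables
#' with probability at most the observed one). All-zero tables give p = 1.
#'
#' @param a,b,c,d Non-negative integer cell counts (rows: first factor,
#'   columns: second).
#' @param alternative `"two.sided"`, `"greater"`, or `"less"`.
#' @return The p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d,
                             alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cells must be non-negative integers")
  if (sum(cells) == 0) return(1)
  stats::fisher.test(matrix(cells, 2, 2, byrow = TRUE),
                     alternative = alternative)$p.value
}

#' Pairwise mutation co-occurrence / mutual exclusivity scan
#'
#' For every pair of genes mutated in at least `min_mutated` samples, the
#' 2x2 table (both / first only / second only / neither) is tested with a
#' two-sided Fisher exact test; the direction is co-occurring when the
#' sample odds ratio exceeds 1 and exclusive when below 1. BH adjustment
#' across pairs.
#'
#' @param status Logical samples x genes matrix from [classify_variants()].
#' @param genes Optional subset of genes to scan.
#' @param min_mutated Minimum mutated-sample count per gene (default 5).
#' @return Data.frame per pair: `gene_a`, `gene_b`, `n_both`, `n_a_only`,
#'   `n_b_only`, `n_neither`, `odds_ratio`, `direction`, `p`, `q`.
#' @export
cooccurrence_scan <- function(status, genes = NULL, min_mutated = 5) {
  if (!is.null(genes)) status <- status[, intersect(genes, colnames(status)),
                                        drop = FALSE]
  counts <- colSums(status)
  skipped <- names(counts)[counts < min_mutated]
  if (length(skipped))
    message(sprintf("cooccurrence_scan: skipping %d gene(s) mutated in < %d samples",
                    length(skipped), min_mutated))
  eligible <- names(counts)[counts >= min_mutated]
  if (length(eligible) < 2)
    stop("fewer than 2 genes pass the min_mutated filter")
  pairs <- utils::combn(eligible, 2)
  res <- lapply(seq_len(ncol(pairs)), function(i) {
    ga <- pairs[1, i]; gb <- pairs[2, i]
    a <- sum(status[, ga] & status[, gb])
    b <- sum(status[, ga] & !status[, gb])
    c_ <- sum(!status[, ga] & status[, gb])
    d <- sum(!status[, ga] & !status[, gb])
    or <- (a * d) / (b * c_)
    dir <- if (is.nan(or) || or == 1) "none"
           else if (or > 1) "co-occurring" else "exclusive"
    data.frame(gene_a = ga, gene_b = gb, n_both = a, n_a_only = b,
               n_b_only = c_, n_neither = d, odds_ratio = or,
               direction = dir, p = fisher_exact_2x2(a, b, c_, d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_adjust(out$p)
  out
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test of the overlap between a query gene list
#' and each gene set, within a stated universe; BH adjustment across sets.
#' Query genes outside the universe are dropped with a warning.
#'
#' @param query Character vector of query genes.
#' @param sets List of [gene_signature()]s (or named list of character
#'   vectors).
#' @param universe Character vector: the gene universe.
#' @return Data.frame per set: `set`, `overlap`, `query_size`, `set_size`,
#'   `universe_size`, `p`, `q`.
#' @export
hypergeom_ora <- function(query, sets, universe) {
  universe <- unique(universe)
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(sprintf("dropping %d query gene(s) outside the universe", length(outside)))
    query <- intersect(query, universe)
  }
  if (!length(query)) stop("query is empty after universe filtering")
  res <- lapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    nm <- if (inherits(s, "GeneSignature")) s$name
          else if (!is.null(names(sets))) names(sets)[i] else paste0("set", i)
    gs <- if (inherits(s, "GeneSignature")) s$genes else s
    gs <- intersect(unique(gs), universe)
    k <- length(intersect(query, gs))
    p <- stats::phyper(k - 1, length(gs), length(universe) - length(gs),
                       length(query), lower.tail = FALSE)
    data.frame(set = nm, overlap = k, query_size = length(query),
               set_size = length(gs), universe_size = length(universe),
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_adjust(out$p)
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR q-values with monotonicity enforcement; order-preserving.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
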