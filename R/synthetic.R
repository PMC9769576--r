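# Ground-truth generators: log-normal (or NB) expression with a spiked
# signature in a "high-CRD" subset, proportional-hazards survival times, and
# grouped mutation tables with controllable co-occurrence.

#' Configuration for the synthetic-data generators
#'
#' Bundles every knob of the ground-truth test bed: expression dimensions and
#' the spiked signature, the proportional-hazards survival generator, and the
#' grouped mutation profile.
#'
#' @param seed Integer seed; every generator is a pure function of
#'   (config, seed).
#' @param n_genes,n_samples Matrix dimensions.
#' @param signature_size Number of signature (CRG-like) genes, `K`.
#' @param spike_fraction Fraction of samples that are "high-CRD" (spiked).
#' @param spike_effect Additive shift, log scale, applied to signature genes
#'   in spiked samples.
#' @param baseline_logmean Baseline log-mean; scalar (shared) or one value
#'   per gene.
#' @param baseline_logsd Log-scale standard deviation of expression noise.
#' @param gene_mean_sd Standard deviation of per-gene baseline log-mean
#'   offsets (genes differ in average expression, which is what the
#'   expression bins of the background null stratify on); 0 gives a flat
#'   gene profile.
#' @param family `"lognormal"` (default; scoring is rank-based so the
#'   marginal family is immaterial) or `"nb"` for negative-binomial counts.
#' @param nb_dispersion NB size parameter (only used for `family = "nb"`).
#' @param hazard_coefficients Named numeric vector: per-gene log-hazard
#'   coefficients used to build the survival linear predictor.
#' @param baseline_hazard Baseline exponential event rate, events/day.
#' @param censor_rate Target expected fraction of censored subjects.
#' @param mutation_profile Named list `list(high = c(GENE = p, ...),
#'   low = c(...))`: per-group per-gene mutation probabilities.
#' @param cooccurrence_pairs List of `list(gene_a, gene_b, odds)` entries
#'   tilting the joint mutation probability of a pair.
#' @return A validated list of class `SyntheticConfig`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_genes = 3000L,
                             n_samples = 300L,
                             signature_size = 50L,
                             spike_fraction = 0.25,
                             spike_effect = 2,
                             baseline_logmean = 0,
                             baseline_logsd = 1,
                             gene_mean_sd = 1,
                             family = c("lognormal", "nb"),
                             nb_dispersion = 2,
                             hazard_coefficients = NULL,
                             baseline_hazard = 1 / 1000,
                             censor_rate = 0.3,
                             mutation_profile = NULL,
                             cooccurrence_pairs = list()) {
  family <- match.arg(family)
  stopifnot(n_genes >= 2, n_samples >= 2)
  if (signature_size >= n_genes)
    stop("signature_size must be smaller than n_genes")
  if (spike_fraction <= 0 || spike_fraction >= 1)
    stop("spike_fraction must lie strictly between 0 and 1")
  if (baseline_hazard <= 0) stop("baseline_hazard must be > 0")
  if (censor_rate < 0 || censor_rate >= 1)
    stop("censor_rate must lie in [0, 1)")
  if (!length(baseline_logmean) %in% c(1L, n_genes))
    stop("baseline_logmean must be scalar or length n_genes")
  if (!is.null(mutation_profile)) {
    for (g in names(mutation_profile)) {
      p <- mutation_profile[[g]]
      if (any(p < 0 | p > 1)) stop("mutation probabilities must lie in [0,1]")
    }
  }
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 n_samples = as.integer(n_samples),
                 signature_size = as.integer(signature_size),
                 spike_fraction = spike_fraction, spike_effect = spike_effect,
                 baseline_logmean = baseline_logmean,
                 baseline_logsd = baseline_logsd, gene_mean_sd = gene_mean_sd,
                 family = family, nb_dispersion = nb_dispersion,
                 hazard_coefficients = hazard_coefficients,
                 baseline_hazard = baseline_hazard, censor_rate = censor_rate,
                 mutation_profile = mutation_profile,
                 cooccurrence_pairs = cooccurrence_pairs),
            class = "SyntheticConfig")
}

# run code with a private RNG stream so generators are pure in (config, seed)
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Generate a synthetic expression matrix with a spiked signature
#'
#' Genes get baseline log-means (optionally heterogeneous across genes);
#' log-expression is Gaussian noise around them. In the spiked ("high-CRD")
#' fraction of samples, signature genes are shifted upward by
#' `spike_effect` on the log scale. With `family = "nb"` the log-scale values
#' become NB means and counts are drawn instead.
#'
#' @param config A [synthetic_config()].
#' @return List with `expr` (an [expression_matrix()]), `signature` (a
#'   [gene_signature()] of the spiked genes), and `labels` (per-sample
#'   `"spiked"`/`"background"` ground truth, named by sample).
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  G <- config$n_genes; S <- config$n_samples; K <- config$signature_size
  genes <- sprintf("G%05d", seq_len(G))
  samples <- sprintf("S%04d", seq_len(S))
  with_seed(config$seed, {
    mu_g <- if (length(config$baseline_logmean) == G) config$baseline_logmean
            else rep(config$baseline_logmean, G)
    if (length(config$baseline_logmean) == 1L && config$gene_mean_sd > 0)
      mu_g <- mu_g + stats::rnorm(G, 0, config$gene_mean_sd)
    sig_idx <- sample.int(G, K)
    n_spike <- max(1L, round(config$spike_fraction * S))
    spike_idx <- sample.int(S, n_spike)
    logx <- matrix(stats::rnorm(G * S, mean = mu_g, sd = config$baseline_logsd),
                   nrow = G, ncol = S)
    logx[sig_idx, spike_idx] <- logx[sig_idx, spike_idx] + config$spike_effect
    if (config$family == "lognormal") {
      m <- logx
      space <- "log_normalized"
    } else {
      m <- matrix(stats::rnbinom(G * S, size = config$nb_dispersion,
                                 mu = exp(logx)),
                  nrow = G, ncol = S)
      storage.mode(m) <- "double"
      space <- "raw_counts"
    }
    rownames(m) <- genes; colnames(m) <- samples
    labels <- rep("background", S); labels[spike_idx] <- "spiked"
    names(labels) <- samples
    list(expr = expression_matrix(m, space = space),
         signature = gene_signature("synthetic_CRG", genes[sig_idx]),
         labels = labels)
  })
}

#' Generate survival times from a proportional-hazards model
#'
#' Event times are exponential with rate `lambda0 * exp(lp)` per sample.
#' Censoring is administrative-uniform on `[0, c]` with `c` solved
#' numerically so the expected censored fraction equals `censor_rate`.
#'
#' @param lp Named numeric vector of linear predictors (names = sample ids).
#' @param lambda0 Baseline hazard, events/day; must be > 0.
#' @param censor_rate Target expected censored fraction in `[0, 1)`.
#' @param seed Integer seed.
#' @return A [survival_table()].
#' @export
generate_survival <- function(lp, lambda0, censor_rate = 0, seed = 1L) {
  if (lambda0 <= 0) stop("lambda0 must be > 0")
  if (!all(is.finite(lp))) stop("linear predictors must be finite")
  if (censor_rate < 0 || censor_rate >= 1) stop("censor_rate must lie in [0, 1)")
  n <- length(lp)
  ids <- if (!is.null(names(lp))) names(lp) else sprintf("S%04d", seq_len(n))
  rates <- lambda0 * exp(lp)
  with_seed(seed, {
    t_event <- stats::rexp(n, rate = rates)
    if (censor_rate == 0) {
      return(survival_table(ids, t_event, rep(1, n)))
    }
    # P(censored_i) = P(C < T_i) = E[exp(-r_i C)] = (1 - exp(-r_i c))/(r_i c)
    cens_frac <- function(cc) mean((1 - exp(-rates * cc)) / (rates * cc))
    f <- function(logc) cens_frac(exp(logc)) - censor_rate
    cc <- exp(stats::uniroot(f, lower = log(1e-8 / lambda0),
                             upper = log(1e8 / lambda0))$root)
    t_cens <- stats::runif(n, 0, cc)
    survival_table(ids, pmin(t_event, t_cens), as.numeric(t_event <= t_cens))
  })
}

# Plackett-style joint mutation probability for a pair with fixed margins
# (pa, pb) and odds ratio omega: returns P(both mutated).
joint_prob_or <- function(pa, pb, omega) {
  if (omega == 1) return(pa * pb)
  s <- 1 + (pa + pb) * (omega - 1)
  p11 <- (s - sqrt(s^2 - 4 * omega * (omega - 1) * pa * pb)) / (2 * (omega - 1))
  min(max(p11, max(0, pa + pb - 1)), min(pa, pb))
}

# default sampling weights over nonsynonymous variant classes
nonsyn_class_weights <- c(Missense = 0.60, Nonsense = 0.10,
                          Frame_Shift_Del = 0.08, Frame_Shift_Ins = 0.06,
                          Splice_Site = 0.06, In_Frame_Del = 0.04,
                          In_Frame_Ins = 0.03, Translation_Start_Site = 0.02,
                          Nonstop = 0.01)

#' Generate a grouped synthetic mutation table
#'
#' Per sample, each profiled gene mutates independently with its group's
#' probability; pairs listed in `cooccurrence_pairs` are drawn jointly with
#' the requested odds ratio (Plackett construction, margins preserved).
#' Mutated records receive a nonsynonymous variant class; an optional
#' `silent_rate` sprinkles in Silent records that downstream classification
#' must treat as wild-type.
#'
#' @param config A [synthetic_config()] with a `mutation_profile`.
#' @param groups Named character vector: group label per sample; labels must
#'   match the names of `config$mutation_profile`.
#' @param silent_rate Per-sample per-gene probability of an extra Silent
#'   record.
#' @param seed Integer seed (defaults to the config seed).
#' @return A [maf_table()] (possibly with zero rows).
#' @export
generate_maf <- function(config, groups, silent_rate = 0.05,
                         seed = config$seed) {
  stopifnot(inherits(config, "SyntheticConfig"))
  prof <- config$mutation_profile
  if (is.null(prof)) stop("config has no mutation_profile")
  bad <- setdiff(unique(groups), names(prof))
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  ids <- if (!is.null(names(groups))) names(groups)
         else sprintf("S%04d", seq_along(groups))
  all_genes <- unique(unlist(lapply(prof, names)))
  pair_genes <- unlist(lapply(config$cooccurrence_pairs,
                              function(p) c(p[[1]], p[[2]])))
  with_seed(seed, {
    rec_s <- character(0); rec_g <- character(0); rec_v <- character(0)
    classes <- names(nonsyn_class_weights)
    for (i in seq_along(ids)) {
      p <- prof[[groups[[i]]]]
      status <- stats::setNames(logical(length(all_genes)), all_genes)
      # jointly drawn pairs first
      for (pr in config$cooccurrence_pairs) {
        ga <- pr[[1]]; gb <- pr[[2]]; omega <- pr[[3]]
        pa <- if (ga %in% names(p)) p[[ga]] else 0
        pb <- if (gb %in% names(p)) p[[gb]] else 0
        p11 <- joint_prob_or(pa, pb, omega)
        u <- stats::runif(1)
        if (u < p11) { status[ga] <- TRUE; status[gb] <- TRUE
        } else if (u < pa) { status[ga] <- TRUE
        } else if (u < pa + pb - p11) { status[gb] <- TRUE }
      }
      rest <- setdiff(intersect(names(p), all_genes), pair_genes)
      if (length(rest))
        status[rest] <- stats::runif(length(rest)) < p[rest]
      mut <- names(status)[status]
      if (length(mut)) {
        rec_s <- c(rec_s, rep(ids[i], length(mut)))
        rec_g <- c(rec_g, mut)
        rec_v <- c(rec_v, sample(classes, length(mut), replace = TRUE,
                                 prob = nonsyn_class_weights))
      }
      if (silent_rate > 0) {
        sil <- all_genes[stats::runif(length(all_genes)) < silent_rate]
        if (length(sil)) {
          rec_s <- c(rec_s, rep(ids[i], length(sil)))
          rec_g <- c(rec_g, sil)
          rec_v <- c(rec_v, rep("Silent", length(sil)))
        }
      }
    }
    maf_table(rec_s, rec_g, rec_v)
  })
}
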