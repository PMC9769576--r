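# End-to-end orchestration: simulate a ground-truth dataset to disk, and run
# the full analysis (score -> risk -> stratify -> survdiff -> mutcompare)
# from a JSON-style config, writing a manifest that reproduces the run.

#' Serialize a risk model to JSON
#' @param model A [risk_model()].
#' @param path Output path.
#' @export
write_risk_model <- function(model, path) {
  stopifnot(inherits(model, "RiskModel"))
  jsonlite::write_json(list(coefficients = as.list(model$coefficients),
                            provenance = model$provenance),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a risk model from JSON
#' @param path Path written by [write_risk_model()].
#' @return A [risk_model()].
#' @export
read_risk_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  risk_model(unlist(obj$coefficients),
             provenance = if (!is.null(obj$provenance)) obj$provenance else path)
}

default_mutation_profile <- function() {
  list(high = c(TP53 = 0.50, MYO18B = 0.30, ARID1A = 0.25, CTNNB1 = 0.25,
                VCAN = 0.20, KMT2C = 0.20),
       low = c(TP53 = 0.20, MYO18B = 0.10, ARID1A = 0.25, CTNNB1 = 0.25,
               VCAN = 0.20, KMT2C = 0.20))
}

#' Simulate a complete dataset to disk
#'
#' Generates expression with a spiked signature, proportional-hazards
#' survival driven by a gene-based risk model, and a grouped mutation table,
#' then writes them as plain-text fixtures (TSV/GMT/JSON) plus a ground-truth
#' JSON. The survival linear predictor is the (centered) risk score of the
#' written model, so the whole pipeline can be run and checked against known
#' truth.
#'
#' @param config A [synthetic_config()].
#' @param out_dir Output directory (created if needed).
#' @return Named list of written paths (invisibly also the in-memory data as
#'   attribute `"data"`).
#' @export
simulate_dataset <- function(config, out_dir) {
  stopifnot(inherits(config, "SyntheticConfig"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_expression(config)
  hc <- config$hazard_coefficients
  if (is.null(hc)) {
    gs <- gen$signature$genes
    bg <- setdiff(rownames(gen$expr), gs)
    hc <- stats::setNames(c(0.8, -0.8, 0.8), c(gs[1], gs[2], bg[1]))
  }
  model <- risk_model(hc, provenance = "synthetic ground-truth hazard model")
  lp <- risk_score(gen$expr, model)
  lp <- lp - mean(lp)
  surv <- generate_survival(lp, config$baseline_hazard, config$censor_rate,
                            seed = config$seed + 1L)
  prof <- if (is.null(config$mutation_profile)) default_mutation_profile()
          else config$mutation_profile
  cfg_mut <- config
  cfg_mut$mutation_profile <- prof
  groups <- stats::setNames(ifelse(gen$labels == "spiked", "high", "low"),
                            names(gen$labels))
  maf <- generate_maf(cfg_mut, groups, seed = config$seed + 2L)
  paths <- list(expr = file.path(out_dir, "expr.tsv"),
                gmt = file.path(out_dir, "signature.gmt"),
                survival = file.path(out_dir, "survival.tsv"),
                maf = file.path(out_dir, "maf.tsv"),
                model = file.path(out_dir, "model.json"),
                truth = file.path(out_dir, "truth.json"))
  write_expression(gen$expr, paths$expr)
  write_gmt(gen$signature, paths$gmt)
  write_survival(surv, paths$survival)
  write_maf(maf, paths$maf)
  write_risk_model(model, paths$model)
  jsonlite::write_json(list(labels = as.list(gen$labels),
                            groups = as.list(groups),
                            signature = gen$signature$genes,
                            hazard_coefficients = as.list(hc),
                            seed = config$seed),
                       paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  structure(paths, data = list(expr = gen$expr, signature = gen$signature,
                               labels = gen$labels, surv = surv, maf = maf,
                               model = model))
}

validate_pipeline_config <- function(config) {
  req <- c("expr", "gmt", "survival", "maf", "out_dir", "seed")
  missing <- setdiff(req, names(config))
  if (length(missing))
    stop("pipeline config is missing field(s): ", paste(missing, collapse = ", "))
  if (!is.numeric(config$seed))
    stop("pipeline config must carry an explicit integer seed")
  for (f in c("expr", "gmt", "survival", "maf")) {
    if (!file.exists(config[[f]]))
      stop("configured input does not exist: ", f, " = ", config[[f]])
  }
  defaults <- list(signature = NULL, model = "published", alpha = 0.25,
                   n_bins = 50, n_iterations = 1000, threshold_quantile = 0.75,
                   horizons = c(365, 1095, 1825), min_mutated = 5,
                   space = "log_normalized", impute_zero = FALSE)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  config
}

#' Run the full CRD analysis pipeline
#'
#' Stages, mirroring the analysis order of the method: signature scoring
#' with the bin-matched null and threshold call; risk scoring and median
#' stratification; survival comparison of the risk groups (KM, log-rank,
#' Cox on the continuous score, time-dependent AUC); mutation-frequency and
#' co-occurrence comparison between the abnormal/normal CRD groups. Writes
#' TSV/JSON outputs plus a manifest recording parameters, seeds, input
#' checksums and per-stage outputs. Deterministic given the config seed.
#'
#' @param config Named list, or path to a JSON file, with fields `expr`,
#'   `gmt`, `survival`, `maf`, `out_dir`, `seed` and optional parameters
#'   (`signature`, `model` = `"published"` or a model JSON path, `alpha`,
#'   `n_bins`, `n_iterations`, `threshold_quantile`, `horizons`,
#'   `min_mutated`, `space`, `impute_zero`).
#' @return The manifest, invisibly; written to `<out_dir>/manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  config <- validate_pipeline_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "score"
  manifest <- list(package = "liverCRD",
                   version = as.character(utils::packageVersion("liverCRD")),
                   parameters = config[setdiff(names(config),
                                               c("expr", "gmt", "survival", "maf"))],
                   inputs = lapply(config[c("expr", "gmt", "survival", "maf")],
                                   function(p) list(path = p,
                                                    md5 = unname(tools::md5sum(p)))),
                   stages = list())
  res <- tryCatch({
    expr <- read_expression(config$expr, space = config$space)
    sigs <- read_gmt(config$gmt)
    sig <- if (is.null(config$signature)) sigs[[1]] else sigs[[config$signature]]
    if (is.null(sig)) stop("signature '", config$signature, "' not found in GMT")
    scored <- crd_score(expr, sig, alpha = config$alpha,
                        n_bins = config$n_bins,
                        n_iterations = config$n_iterations,
                        seed = config$seed,
                        threshold_quantile = config$threshold_quantile)
    score_path <- file.path(out_dir, "crd_scores.tsv")
    utils::write.table(scored$table, score_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest$stages$score <- list(output = score_path,
                                  threshold = scored$threshold)

    stage <- "risk"
    model <- if (identical(config$model, "published")) published_livercrd_model()
             else read_risk_model(config$model)
    rs <- risk_score(expr, model, impute_zero = isTRUE(config$impute_zero))
    risk_groups <- stratify_by_median(rs)
    risk_path <- file.path(out_dir, "risk_scores.tsv")
    utils::write.table(data.frame(sample = names(rs), risk_score = unname(rs),
                                  group = unname(risk_groups)),
                       risk_path, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$risk <- list(output = risk_path,
                                 model = model$provenance,
                                 n_genes = length(model$genes))

    stage <- "survdiff"
    surv <- read_survival(config$survival)
    common <- intersect(surv$sample, names(rs))
    if (length(common) < 4) stop("too few samples shared between expression and survival")
    surv_c <- surv[match(common, surv$sample), ]
    lr <- logrank_test(surv_c, risk_groups[common])
    kms <- km_estimate(surv_c, risk_groups[common])
    medians <- vapply(kms, median_survival, numeric(1))
    cox <- cox_fit(surv_c, matrix(rs[common], ncol = 1,
                                  dimnames = list(common, "risk_score")))
    horizons <- config$horizons[config$horizons <= max(surv_c$time)]
    auc <- if (length(horizons))
      time_dependent_auc(rs[common], surv_c, horizons) else NULL
    for (g in names(kms)) {
      utils::write.table(as.data.frame(kms[[g]]),
                         file.path(out_dir, paste0("km_", g, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    sd_path <- file.path(out_dir, "survdiff.json")
    jsonlite::write_json(list(logrank = list(chisq = lr$statistic, df = lr$df,
                                             p = lr$p_value),
                              median_survival = as.list(medians),
                              cox = list(coef = unname(cox$coef),
                                         hr = unname(cox$hr),
                                         se = unname(cox$se),
                                         p = unname(cox$p)),
                              auc = if (is.null(auc)) NULL else
                                list(horizon = auc$horizon, auc = auc$auc)),
                         sd_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest$stages$survdiff <- list(output = sd_path,
                                     km = file.path(out_dir,
                                                    paste0("km_", names(kms), ".tsv")))

    stage <- "mutcompare"
    maf <- read_maf(config$maf)
    crd_groups <- stats::setNames(
      ifelse(scored$table$category == "abnormal", "high", "low"),
      scored$table$sample)
    status <- classify_variants(maf, samples = scored$table$sample)
    freq <- compare_mutation_frequency(status, crd_groups, higher = "high")
    freq_path <- file.path(out_dir, "mutation_frequency.tsv")
    utils::write.table(freq, freq_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    cooc <- cooccurrence_scan(status, min_mutated = config$min_mutated)
    cooc_path <- file.path(out_dir, "cooccurrence.tsv")
    utils::write.table(cooc, cooc_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest$stages$mutcompare <- list(frequency = freq_path,
                                       cooccurrence = cooc_path)
    manifest
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(res, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(res)
}
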