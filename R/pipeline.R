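# End-to-end orchestration: simulate -> preprocess -> table1 -> covselect
# -> dmp -> enrich -> exprcorr -> posthoc, from a single config, with a run
# manifest recording counts at every filter. All randomness derives from
# the single config seed. Logs go to messages (stderr); data go to TSV
# files under the output directory.

#' Pipeline run configuration
#'
#' Assembles the configuration for [run_pipeline()]. Defaults are the
#' synthetic study conditions of [cohort_config()]; expression cohorts
#' default to the two small independent-cohort sizes (n = 11 and n = 10)
#' with population methylation-expression correlation 0.5.
#'
#' @param out_dir output directory for stage TSVs.
#' @param seed master seed; all stage seeds derive from it.
#' @param planted_effects named numeric vector of per-transcript M-shifts
#'   passed to the cohort generator.
#' @param genes,window_bp candidate panel (see [candidate_panel()]).
#' @param alpha_nominal nominal per-probe threshold and binomial p0.
#' @param alpha_covariate covariate-inclusion threshold for the forward
#'   screen.
#' @param sided binomial sidedness (see [binomial_test()]).
#' @param pca_sd_threshold beta-SD probe filter for outlier PCA. The
#'   default (0.05) suits the desk-scale synthetic panel, whose probe
#'   variability is narrower than a genome-wide array's.
#' @param expr_rho,expr_n population correlation and sizes of the two
#'   synthetic expression cohorts.
#' @param noise_sd residual M-value SD of the generator.
#' @param target_transcript transcript carried into the expression and
#'   post-hoc stages. Default `"AJ877169"`.
#' @return list of class `run_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("hpameth_run_"),
                            seed = 1L,
                            planted_effects = numeric(0),
                            genes = c("CRH", "CRHBP", "CRHR1", "CRHR2",
                                      "FKBP5", "NR3C1"),
                            window_bp = 2000,
                            alpha_nominal = 0.05,
                            alpha_covariate = 0.10,
                            sided = "two-sided",
                            pca_sd_threshold = 0.05,
                            expr_rho = 0.5,
                            expr_n = c(11L, 10L),
                            noise_sd = 0.5,
                            target_transcript = "AJ877169") {
  assert_that(alpha_nominal > 0 && alpha_nominal < 1,
              "alpha_nominal must lie in (0, 1)")
  assert_that(alpha_covariate > 0 && alpha_covariate < 1,
              "alpha_covariate must lie in (0, 1)")
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 planted_effects = planted_effects, genes = genes,
                 window_bp = window_bp, alpha_nominal = alpha_nominal,
                 alpha_covariate = alpha_covariate, sided = sided,
                 pca_sd_threshold = pca_sd_threshold,
                 expr_rho = expr_rho, expr_n = expr_n,
                 noise_sd = noise_sd,
                 target_transcript = target_transcript),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; `planted_effects` is
#' a mapping of transcript id to M-shift.
#'
#' @param path YAML file path.
#' @return `run_config` list.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$planted_effects)) {
    raw$planted_effects <- unlist(raw$planted_effects)
  }
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes all stages in order, writes each stage's output as TSV under
#' `config$out_dir`, and returns a manifest with per-stage status and the
#' probe/sample counts at every filter. Any stage error aborts with the
#' stage name.
#'
#' @param config a `run_config` list from [pipeline_config()] or
#'   [read_pipeline_config()], or a path to a YAML config.
#' @return manifest list: `seed`, `stages` (named list with per-stage
#'   details), `counts`, `warnings`; written to `manifest.yaml` in the
#'   output directory.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  assert_that(inherits(config, "run_config"), "config must be a run_config")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed, stages = list(), counts = list(),
                   warnings = character(0))
  warn <- function(msg) manifest$warnings <<- c(manifest$warnings, msg)
  stage <- function(name, expr) {
    message(sprintf("[hpameth] stage %s", name))
    out <- tryCatch(expr, error = function(e) {
      stop_hpameth(sprintf("pipeline stage '%s' failed: %s", name,
                           conditionMessage(e)))
    })
    manifest$stages[[name]] <<- list(status = "completed")
    out
  }

  # 1. simulate
  cohort <- stage("simulate", {
    cc <- cohort_config(planted_effects = config$planted_effects,
                        noise_sd = config$noise_sd,
                        seed = config$seed)
    ch <- generate_cohort(cc)
    write_cohort(ch, config$out_dir)
    ch
  })
  manifest$counts$probes_in <- nrow(cohort$beta)
  manifest$counts$samples_in <- ncol(cohort$beta)

  # 2. preprocess: QC flags, sample exclusion, M transform
  pre <- stage("preprocess", {
    rep <- pca_outlier_flags(cohort$beta,
                             sd_threshold = config$pca_sd_threshold)
    keep <- names(rep$flagged)[!rep$flagged]
    if (any(rep$flagged)) {
      warn(sprintf("excluded %d sample(s) as PC1 outliers", sum(rep$flagged)))
    }
    qc <- data.frame(sample_id = names(rep$scores), pc1_score = rep$scores,
                     flagged = rep$flagged, row.names = NULL)
    write_tsv_table(qc, file.path(config$out_dir, "qc_outliers.tsv"))
    m <- beta_to_m(cohort$beta[, keep, drop = FALSE])
    write_matrix_tsv(m, file.path(config$out_dir, "m_values.tsv"))
    list(m = m, report = rep, keep = keep)
  })
  pheno <- cohort$pheno[cohort$pheno$sample_id %in% pre$keep, , drop = FALSE]
  manifest$counts$samples_after_qc <- length(pre$keep)
  manifest$counts$pc1_variance_pct <- unname(pre$report$pc1_variance_pct)

  # 3. table1
  stage("table1", {
    t1 <- cohort_table1(pheno, group = "dst_ns")
    write_tsv_table(t1, file.path(config$out_dir, "table1.tsv"))
    t1
  })

  # 4. covariate forward selection for the DST model
  covsel <- stage("covselect", {
    cands <- intersect(default_covariate_candidates(), colnames(pheno))
    sel <- forward_select(pheno$dst_ns,
                          pheno[, cands, drop = FALSE],
                          alpha = config$alpha_covariate)
    write_tsv_table(sel$trace, file.path(config$out_dir, "covselect_trace.tsv"))
    sel
  })
  manifest$counts$covariates_selected <- length(covsel$selected)

  # 5. candidate selection + differential methylation
  dmp <- stage("dmp", {
    panel <- candidate_panel(genes = config$genes,
                             window_bp = config$window_bp)
    cand <- select_candidate_probes(cohort$annotation, panel)
    m_cand <- pre$m[unique(cand$probe_id), , drop = FALSE]
    manifest$counts$candidates <- nrow(m_cand)
    fit <- run_dmp(m_cand, pheno = pheno, preset = "dst",
                   phenotype = NULL)
    write_tsv_table(fit, file.path(config$out_dir, "dmp.tsv"))
    list(fit = fit, annotation = cand)
  })
  manifest$counts$modelled <- attr(dmp$fit, "n_used")
  manifest$counts$dropped_for_missingness <- attr(dmp$fit, "n_dropped")
  manifest$counts$nominally_significant <-
    sum(dmp$fit$p < config$alpha_nominal)

  # 6. transcript enrichment
  enr <- stage("enrich", {
    e <- run_enrichment(dmp$fit, dmp$annotation,
                        alpha_nominal = config$alpha_nominal,
                        sided = config$sided)
    write_tsv_table(e, file.path(config$out_dir, "enrichment.tsv"))
    e
  })
  manifest$counts$flagged_transcripts <- enr$transcript[enr$significant]

  # 7. expression correlation in two synthetic cohorts
  stage("exprcorr", {
    tr <- config$target_transcript
    sub <- cohort$annotation[cohort$annotation$transcript == tr, ,
                             drop = FALSE]
    gene <- sub$gene[1]
    labels <- c("expr_cohort_n11", "expr_cohort_n10")[seq_along(config$expr_n)]
    res <- do.call(rbind, lapply(seq_along(config$expr_n), function(i) {
      ec <- generate_expression_cohort(config$expr_n[i], config$expr_rho,
                                       seed = config$seed + 1000L + i)
      meth <- matrix(ec$m, nrow = 1,
                     dimnames = list(sub$probe_id[1], names(ec$m)))
      expr <- matrix(ec$expr, nrow = 1,
                     dimnames = list(gene, names(ec$expr)))
      mapping <- data.frame(transcript = tr, gene = gene,
                            probe_id = sub$probe_id[1])
      correlate_cohort(meth, expr, mapping, cohort_label = labels[i])
    }))
    write_tsv_table(res, file.path(config$out_dir, "exprcorr.tsv"))
    res
  })

  # 8. post-hoc interaction models on the top probe
  stage("posthoc", {
    top <- dmp$fit$probe_id[which.min(dmp$fit$p)]
    cg <- pre$m[top, pheno$sample_id]
    lin <- interaction_linear(cg, pheno$dst_ns, pheno$hypersexuality)
    logi <- tryCatch(
      interaction_logistic(pheno$dst_ns, cg, pheno$hypersexuality),
      error = function(e) {
        warn(sprintf("posthoc logistic model: %s", conditionMessage(e)))
        NULL
      })
    rows <- data.frame(model = "linear", probe_id = top,
                       term = names(lin$coefficients),
                       coefficient = unname(lin$coefficients),
                       p = unname(lin$p), stringsAsFactors = FALSE)
    if (!is.null(logi)) {
      rows <- rbind(rows, data.frame(model = "logistic", probe_id = top,
                                     term = names(logi$coefficients),
                                     coefficient = unname(logi$coefficients),
                                     p = unname(logi$p),
                                     stringsAsFactors = FALSE))
    }
    write_tsv_table(rows, file.path(config$out_dir, "posthoc.tsv"))
    rows
  })

  manifest$n_stages_completed <- length(manifest$stages)
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  manifest
}
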