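# Tiny polynomial rolling hash of a string; fingerprints the parameter set
# in the run manifest without external digest dependencies.
param_hash <- function(s) {
  h <- 0
  for (b in as.integer(charToRaw(s))) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Pipeline configuration
#'
#' Declarative configuration for the end-to-end analysis: a simulation
#' config (or paths to pre-simulated inputs written by the package's own
#' writers), annotation coverages, stage toggles, thresholds, and jackknife
#' block counts.
#'
#' @param sim A [sim_config()] describing the synthetic cohort.
#' @param out_dir Output directory for result tables and the manifest.
#' @param n_traits Number of traits to simulate and scan.
#' @param effect_cor Shared-architecture effect correlation between traits.
#' @param annotation_coverage Named vector of SNP-coverage fractions for the
#'   planted/curated categories. Defaults to every category named in
#'   `sim$enrichment_factors` at 5% plus two random "functional-like"
#'   baseline categories (10% and 15%).
#' @param stages Character vector of stages to run, a subset of the canonical
#'   order: qc, gwas, ancestry, ldscore, h2_rg, sds, multitest, curation,
#'   loci.
#' @param qc_thresholds List: maf_min, hwe_p_min, info_min.
#' @param clump_thresholds List: p_max, r2_min.
#' @param coverage_min Minimum annotation SNP coverage (default 0.01).
#' @param alpha FDR level for the final summary.
#' @param ld_window LD window in bp for scores, expansion and clumping.
#' @param n_blocks_regression,n_blocks_sds Jackknife block counts for the
#'   regression fits (default 200) and the tSDS test (default 100).
#' @param ancestry_regress Whether to apply ancestry regression; default
#'   TRUE when the simulation is confounded.
#' @param n_pcs Ancestry PCs for the regression (default 20).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(1000, 5000, seed = 1L),
                            out_dir = tempfile("evoanno_run_"),
                            n_traits = 2,
                            effect_cor = 0.5,
                            annotation_coverage = NULL,
                            stages = c("qc", "gwas", "ancestry", "ldscore",
                                       "h2_rg", "sds", "multitest",
                                       "curation", "loci"),
                            qc_thresholds = list(maf_min = 0.001,
                                                 hwe_p_min = 1e-6,
                                                 info_min = 0.7),
                            clump_thresholds = list(p_max = 5e-8,
                                                    r2_min = 0.6),
                            coverage_min = 0.01,
                            alpha = 0.05,
                            ld_window = 1e5,
                            n_blocks_regression = 200,
                            n_blocks_sds = 100,
                            ancestry_regress = NULL,
                            n_pcs = 20) {
  validate_sim_config(sim)
  canonical <- c("qc", "gwas", "ancestry", "ldscore", "h2_rg", "sds",
                 "multitest", "curation", "loci")
  stopifnot(all(stages %in% canonical))
  if (is.null(annotation_coverage)) {
    planted <- names(sim$enrichment_factors)
    annotation_coverage <- c(
      stats::setNames(rep(0.05, length(planted)), planted),
      functional_A = 0.10, functional_B = 0.15)
  }
  if (is.null(ancestry_regress)) ancestry_regress <- sim$confound_strength > 0
  stopifnot(alpha > 0, alpha < 1, coverage_min >= 0, ld_window > 0)
  structure(list(
    sim = sim, out_dir = out_dir, n_traits = as.integer(n_traits),
    effect_cor = effect_cor, annotation_coverage = annotation_coverage,
    stages = canonical[canonical %in% stages],
    qc_thresholds = qc_thresholds, clump_thresholds = clump_thresholds,
    coverage_min = coverage_min, alpha = alpha, ld_window = ld_window,
    n_blocks_regression = n_blocks_regression, n_blocks_sds = n_blocks_sds,
    ancestry_regress = ancestry_regress, n_pcs = n_pcs
  ), class = "pipeline_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in canonical order — variant QC, per-trait GWAS,
#' ancestry regression (when enabled), partitioned LD scores, stratified
#' heritability and pairwise genetic-correlation fits, the tSDS selection
#' test, effective-trait FDR, annotation curation/coverage QC, and LD
#' clumping with annotation overlap — writing every stage's table to
#' `config$out_dir` together with a machine-readable manifest. All
#' randomness derives from `config$sim$seed`; identical configurations give
#' identical result tables.
#'
#' @param config A [pipeline_config()].
#' @return A report bundle (list) with the per-stage objects, the final
#'   enrichment summary (`summary`), and the manifest. Invisible file side
#'   effects under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list()
  stage_status <- stats::setNames(
    rep("skipped", 9),
    c("qc", "gwas", "ancestry", "ldscore", "h2_rg", "sds", "multitest",
      "curation", "loci"))
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  bundle <- list(config = config)

  # inputs (simulation)
  panel <- simulate_panel(config$sim)
  anns_raw <- synthetic_annotations(panel, config$annotation_coverage,
                                    seed = config$sim$seed + 3L)
  pheno <- simulate_phenotypes(panel, anns_raw, config$sim,
                               n_traits = config$n_traits,
                               effect_cor = config$effect_cor)
  sds_tab <- simulate_sds(panel, pheno$true_betas[, 1], config$sim)
  log$simulate <- sprintf("simulated %d x %d panel, %d traits",
                          n_individuals(panel), n_snps(panel), config$n_traits)

  # qc
  if ("qc" %in% config$stages) {
    panel_qc <- run_stage("qc", qc_variants(
      panel, config$qc_thresholds$maf_min, config$qc_thresholds$hwe_p_min,
      config$qc_thresholds$info_min))
    log$qc <- sprintf("QC: %d of %d SNPs retained", n_snps(panel_qc),
                      n_snps(panel))
    stage_status["qc"] <- "run"
  } else panel_qc <- panel
  bundle$panel <- panel_qc

  # curation: resolve annotations on the QC'd reference, apply coverage rule
  anns <- annotation_set(anns_raw$categories, panel_qc$snps)
  coverage <- do.call(rbind, lapply(colnames(anns$membership), function(nm) {
    cr <- snp_coverage(anns$categories[[nm]], panel_qc$snps,
                       config$coverage_min)
    data.frame(category = nm, n_snps_in = cr$n_snps_in,
               n_reference = cr$n_reference, fraction = cr$fraction,
               passes_threshold = cr$passes_threshold,
               stringsAsFactors = FALSE)
  }))
  if ("curation" %in% config$stages) {
    keep_cats <- coverage$category[coverage$passes_threshold]
    if (!length(keep_cats)) stop("no annotation passes the coverage rule",
                                 call. = FALSE)
    anns <- annotation_set(anns$categories[keep_cats], panel_qc$snps)
    write_tsv(coverage, file.path(config$out_dir, "annotation_coverage.tsv"))
    log$curation <- sprintf("curation: %d of %d categories pass >= %.0f%% coverage",
                            length(keep_cats), nrow(coverage),
                            100 * config$coverage_min)
    stage_status["curation"] <- "run"
  }
  bundle$annotations <- anns
  bundle$coverage <- coverage

  # gwas
  stats_list <- list()
  if ("gwas" %in% config$stages) {
    for (t in seq_len(config$n_traits)) {
      st <- run_stage("gwas", run_gwas(panel_qc, pheno$values[, t],
                                       pheno$covariates))
      stats_list[[pheno$trait_names[t]]] <- st
      write_tsv(st[, setdiff(names(st), "missing")],
                file.path(config$out_dir,
                          paste0("sumstats_", pheno$trait_names[t], ".tsv")))
    }
    log$gwas <- sprintf("GWAS: %d traits x %d SNPs", length(stats_list),
                        n_snps(panel_qc))
    stage_status["gwas"] <- "run"
  }

  # ancestry regression
  if ("ancestry" %in% config$stages && config$ancestry_regress &&
      length(stats_list)) {
    loadings <- panel_pc_loadings(panel_qc, config$n_pcs)
    pc_tests <- lapply(stats_list, pc_beta_jackknife, loadings = loadings,
                       n_blocks = config$n_blocks_regression)
    stats_list <- lapply(stats_list, ancestry_regress, loadings = loadings)
    bundle$pc_tests <- pc_tests
    log$ancestry <- sprintf("ancestry regression applied (%d PCs)",
                            ncol(loadings))
    stage_status["ancestry"] <- "run"
  }
  bundle$stats <- stats_list

  # LD scores
  if ("ldscore" %in% config$stages) {
    ldsc_tab <- run_stage("ldscore", compute_ld_scores(
      panel_qc, anns, window = config$ld_window))
    write_ld_scores(ldsc_tab, file.path(config$out_dir, "ldscores.tsv"))
    log$ldscore <- sprintf("LD scores: %d SNPs x %d categories",
                           nrow(ldsc_tab$scores), ncol(ldsc_tab$scores))
    stage_status["ldscore"] <- "run"
    bundle$ldscores <- ldsc_tab
  }

  # partitioned h2 + rg
  h2_list <- list(); rg_mat <- NULL
  if ("h2_rg" %in% config$stages && length(stats_list) &&
      !is.null(bundle$ldscores)) {
    for (nm in names(stats_list)) {
      fit <- run_stage("h2_rg", fit_partitioned_h2(
        stats_list[[nm]], ldsc_tab, n_blocks = config$n_blocks_regression))
      h2_list[[nm]] <- fit
      write_tsv(fit$categories,
                file.path(config$out_dir, paste0("h2_", nm, ".tsv")))
    }
    Tt <- length(stats_list)
    rg_mat <- diag(Tt)
    dimnames(rg_mat) <- list(names(stats_list), names(stats_list))
    if (Tt > 1) {
      for (i in 1:(Tt - 1)) for (j in (i + 1):Tt) {
        # an undefined rg (non-positive h2 at small scale) is recorded as 0,
        # the conservative choice for the effective-trait count downstream
        rr <- tryCatch(fit_rg(stats_list[[i]], stats_list[[j]], ldsc_tab,
                              n_blocks = config$n_blocks_regression),
                       error = function(e) NULL)
        rg_mat[i, j] <- rg_mat[j, i] <- if (is.null(rr)) 0 else rr$rg
      }
      write_tsv(cbind(trait = rownames(rg_mat), as.data.frame(rg_mat)),
                file.path(config$out_dir, "rg_matrix.tsv"))
    }
    log$h2_rg <- sprintf("partitioned h2 for %d traits; rg matrix %dx%d",
                         length(h2_list), Tt, Tt)
    stage_status["h2_rg"] <- "run"
  }
  bundle$h2 <- h2_list
  bundle$rg_matrix <- rg_mat

  # tSDS selection test
  sds_results <- NULL
  if ("sds" %in% config$stages && length(stats_list)) {
    rows <- lapply(names(stats_list), function(nm) {
      merged <- align_tsds(stats_list[[nm]], sds_tab)
      res <- run_stage("sds", tsds_test(merged, config$n_blocks_sds))
      data.frame(trait = nm, rho = res$rho, se_jack = res$se_jack,
                 z = res$z, p = res$p, n_snps = res$n_snps,
                 stringsAsFactors = FALSE)
    })
    sds_results <- do.call(rbind, rows)
    # conservative plain BH across traits for the selection arm
    sds_results <- cbind(sds_results,
                         q = bh_fdr(sds_results$p, alpha = config$alpha)$q)
    write_tsv(sds_results, file.path(config$out_dir, "sds_results.tsv"))
    log$sds <- sprintf("tSDS test on %d traits", nrow(sds_results))
    stage_status["sds"] <- "run"
  }
  bundle$sds <- sds_results

  # effective traits + FDR summary of enrichments
  summary_df <- NULL; veff <- NULL
  if ("multitest" %in% config$stages && length(h2_list)) {
    veff <- if (!is.null(rg_mat) && nrow(rg_mat) > 1)
      veff_li(repair_correlation(rg_mat)) else
      structure(list(eigenvalues = 1, veff_li = 1, m = 1),
                class = "veff_result")
    rows <- list()
    for (nm in names(h2_list)) {
      cc <- h2_list[[nm]]$categories
      cc <- cc[cc$category != "base", , drop = FALSE]
      rows[[nm]] <- data.frame(trait = nm, cc, stringsAsFactors = FALSE)
    }
    summary_df <- do.call(rbind, rows)
    rownames(summary_df) <- NULL
    # FDR within category across traits, with the effective trait count
    summary_df$q <- NA_real_
    for (cat in unique(summary_df$category)) {
      sel <- summary_df$category == cat & !is.na(summary_df$p_enrichment)
      if (any(sel))
        summary_df$q[sel] <- bh_fdr(summary_df$p_enrichment[sel],
                                    m_eff = veff$veff_li,
                                    alpha = config$alpha)$q
    }
    summary_df$significant <- !is.na(summary_df$q) &
      summary_df$q <= config$alpha
    summary_df$direction <- ifelse(summary_df$enrichment < 1, "depletion",
                                   "enrichment")
    write_tsv(summary_df, file.path(config$out_dir, "enrichment_summary.tsv"))
    log$multitest <- sprintf("VeffLi = %.2f of %d traits", veff$veff_li,
                             veff$m)
    stage_status["multitest"] <- "run"
  }
  bundle$veff <- veff
  bundle$summary <- summary_df

  # clumping + overlap
  if ("loci" %in% config$stages && length(stats_list)) {
    iv_cats <- Filter(Negate(is.null),
                      lapply(anns$categories, function(x) x$intervals))
    all_loci <- list()
    for (nm in names(stats_list)) {
      lo <- run_stage("loci", clump_loci(
        stats_list[[nm]], panel_qc,
        p_max = config$clump_thresholds$p_max,
        r2_min = config$clump_thresholds$r2_min,
        window = config$ld_window))
      all_loci[[nm]] <- lo
      write_tsv(lo[, setdiff(names(lo), "members")],
                file.path(config$out_dir, paste0("loci_", nm, ".tsv")))
      if (nrow(lo) && length(iv_cats)) {
        ov <- overlap_annotations(lo, iv_cats)
        write_tsv(ov$records,
                  file.path(config$out_dir, paste0("overlaps_", nm, ".tsv")))
      }
    }
    bundle$loci <- all_loci
    log$loci <- sprintf("clumping: %s loci per trait",
                        paste(vapply(all_loci, nrow, integer(1)),
                              collapse = "/"))
    stage_status["loci"] <- "run"
  }

  params_str <- paste(utils::capture.output(utils::str(
    config[setdiff(names(config), "out_dir")])), collapse = "\n")
  manifest <- list(
    package = "evoanno",
    version = as.character(utils::packageVersion("evoanno")),
    seed = config$sim$seed,
    parameter_hash = param_hash(params_str),
    stages = as.list(stage_status),
    log = log
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  bundle$manifest <- manifest
  class(bundle) <- "evoanno_report"
  bundle
}

#' @export
print.evoanno_report <- function(x, ...) {
  cat("evoanno pipeline report\n")
  for (nm in names(x$manifest$stages))
    cat(sprintf("  %-10s %s\n", nm, x$manifest$stages[[nm]]))
  if (!is.null(x$summary)) {
    sig <- x$summary[x$summary$significant, , drop = FALSE]
    cat(sprintf("  significant enrichments/depletions: %d\n", nrow(sig)))
    if (nrow(sig))
      print.data.frame(sig[, c("trait", "category", "enrichment",
                               "se_enrichment", "q", "direction")],
                       row.names = FALSE)
  }
  invisible(x)
}
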