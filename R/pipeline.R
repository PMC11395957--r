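#' Assemble a run configuration for the end-to-end study
#'
#' @param genotypes path to a VCF (`.vcf`) or dosage table.
#' @param phenotypes path to the phenotype TSV.
#' @param out_dir output directory.
#' @param seed root seed (mandatory; every random stage derives a named
#'   substream from it).
#' @param traits trait columns to analyse (default: all phenotype columns).
#' @param gff optional GFF3 annotation for candidate-gene mapping.
#' @param maf_min,hwe_alpha marker QC thresholds.
#' @param prune if TRUE, LD-prune (r^2 > `prune_r2max`) before GWAS; off by
#'   default since the dense scan is the primary analysis.
#' @param prune_r2max pruning threshold for the optional pre-GWAS prune.
#' @param prune_target marker count for the GLDBLUP subset / GFBLUP
#'   background pool.
#' @param genomewide,suggestive GWAS significance thresholds.
#' @param fdr_q FDR level for feature-marker selection.
#' @param flank candidate-region half-width in bp.
#' @param cv_k,cv_replicates cross-validation design.
#' @param methods prediction methods to compare.
#' @return list of class `RunConfig`.
#' @export
run_config <- function(genotypes, phenotypes, out_dir, seed,
                       traits = NULL, gff = NULL,
                       maf_min = 0.05, hwe_alpha = 1e-7,
                       prune = FALSE, prune_r2max = 0.9, prune_target = 2000,
                       genomewide = 5e-8, suggestive = 5e-6, fdr_q = 0.05,
                       flank = 20000, cv_k = 10, cv_replicates = 20,
                       methods = c("gblup", "gldblup", "gfblup")) {
  if (missing(seed)) stop("seed is mandatory")
  for (p in c(genotypes, phenotypes, gff))
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
  structure(as.list(environment()), class = "RunConfig")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full study pipeline
#'
#' QC -> (optional) LD pruning -> per-trait descriptive statistics, REML
#' variance components, mixed-model GWAS with significance classification
#' -> candidate-gene regions (when a GFF3 is supplied) -> three-method
#' cross-validated genomic prediction on identical fold plans. All tables
#' are written under `config$out_dir` with fixed names, together with a
#' machine-readable run manifest.
#'
#' @param config a [run_config()].
#' @return invisible list of in-memory results (per-trait GWAS, variance
#'   components, prediction reports, QC report, manifest).
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  od <- config$out_dir

  gm <- .stage("genotype_io", {
    if (grepl("\\.vcf$", config$genotypes)) read_vcf(config$genotypes)
    else read_dosage_table(config$genotypes)
  })
  pheno <- .stage("genotype_io", read_phenotypes(config$phenotypes))
  traits <- config$traits %||% setdiff(names(pheno), "sample_id")

  qc <- .stage("qc", apply_qc(gm, config$maf_min, config$hwe_alpha))
  gm <- qc$genotypes
  utils::write.table(qc$report$per_marker, file.path(od, "qc_markers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  if (isTRUE(config$prune)) {
    kept <- .stage("ld_prune", ld_prune(gm, r2_max = config$prune_r2max))
    gm <- subset_genotypes(gm, markers = kept)
    writeLines(kept, file.path(od, "pruned_marker_ids.txt"))
  }

  grm <- .stage("relationship", build_grm(gm))
  pcs <- compute_pcs(grm, k = min(10, nrow(grm$matrix)))
  utils::write.table(
    data.frame(sample_id = grm$sample_ids, pcs$vectors,
               check.names = FALSE),
    file.path(od, "pca.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  decay <- .stage("ld_tools", ld_decay(gm))
  utils::write.table(decay, file.path(od, "ld_decay.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  genes <- if (!is.null(config$gff)) .stage("gene_annotation", load_gff(config$gff)) else NULL

  summaries <- list(); var_tabs <- list(); gwas_res <- list()
  regions_res <- list(); pred_res <- list()
  for (tr in traits) {
    y <- align_phenotype(gm, pheno, tr)
    gm_tr <- subset_genotypes(gm, samples = names(y))
    grm_tr <- build_grm(gm_tr)
    summaries[[tr]] <- descriptive_stats(y)
    gw <- .stage("mlm_gwas", run_gwas(gm_tr, y, grm = grm_tr,
                                      genomewide = config$genomewide,
                                      suggestive = config$suggestive))
    gwas_res[[tr]] <- gw
    var_tabs[[tr]] <- variance_table(attr(gw, "null")$est, trait = tr)
    utils::write.table(as.data.frame(gw), file.path(od, paste0("gwas_", tr, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    hits <- gw[gw$class != "none", , drop = FALSE]
    reg <- build_regions(hits, flank = config$flank)
    if (!is.null(genes)) reg <- map_candidate_genes(reg, genes)
    regions_res[[tr]] <- reg
    utils::write.table(as.data.frame(reg),
                       file.path(od, paste0("candidate_regions_", tr, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    plan <- make_fold_plan(names(y), k = config$cv_k,
                           replicates = config$cv_replicates,
                           seed = substream_seed(config$seed, paste0("cv:", tr)))
    reps <- lapply(config$methods, function(m)
      .stage("genomic_prediction",
             crossvalidate(gm_tr, y, method = m, fold_plan = plan,
                           prune_target = min(config$prune_target, ncol(gm_tr$dosages)),
                           fdr_q = config$fdr_q)))
    names(reps) <- config$methods
    pred_res[[tr]] <- reps
    tab <- do.call(rbind, lapply(config$methods, function(m)
      cbind(trait = tr, method = m, reps[[m]]$summary)))
    utils::write.table(tab, file.path(od, paste0("prediction_", tr, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  st <- do.call(rbind, lapply(traits, function(tr)
    data.frame(trait = tr, n = summaries[[tr]]$n, mean = summaries[[tr]]$mean,
               sd = summaries[[tr]]$sd, cv_pct = summaries[[tr]]$cv,
               min = summaries[[tr]]$min, max = summaries[[tr]]$max)))
  utils::write.table(st, file.path(od, "trait_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  vt <- do.call(rbind, var_tabs)
  utils::write.table(vt, file.path(od, "variance_components.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  cfg_plain <- config
  class(cfg_plain) <- NULL
  cfg_file <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg_plain, cfg_file, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "sturgeonGP",
    package_version = as.character(utils::packageVersion("sturgeonGP")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config = cfg_plain,
    config_md5 = unname(tools::md5sum(cfg_file)),
    qc = list(n_input = qc$report$n_input_markers,
              removed_maf = qc$report$n_removed_maf,
              removed_hwe = qc$report$n_removed_hwe,
              retained = qc$report$n_retained),
    lambda = lapply(gwas_res, function(g) attr(g, "lambda")))
  jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(qc = qc$report, trait_summaries = summaries,
                 variance = vt, gwas = gwas_res, regions = regions_res,
                 prediction = pred_res, pca = pcs, ld_decay = decay,
                 manifest = manifest))
}

#' Export plotting-ready tables from a run directory
#'
#' Writes Manhattan and QQ tables for every GWAS result found in a
#' [run_study()] output directory; LD-decay and PCA tables are already part
#' of the run itself. No graphics are rendered.
#'
#' @param run_dir a directory produced by [run_study()].
#' @return invisible character vector of files written.
#' @export
export_plots_data <- function(run_dir) {
  files <- list.files(run_dir, pattern = "^gwas_.*\\.tsv$", full.names = TRUE)
  if (length(files) == 0) stop("no GWAS tables found in ", run_dir)
  written <- character()
  for (f in files) {
    tab <- utils::read.table(f, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    class(tab) <- c("GwasResult", class(tab))
    pd <- gwas_plot_data(tab)
    trait <- sub("^gwas_(.*)\\.tsv$", "\\1", basename(f))
    mf <- file.path(run_dir, paste0("manhattan_", trait, ".tsv"))
    qf <- file.path(run_dir, paste0("qq_", trait, ".tsv"))
    utils::write.table(pd$manhattan, mf, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(pd$qq, qf, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, mf, qf)
  }
  invisible(written)
}
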