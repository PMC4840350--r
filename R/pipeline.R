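#' Default pipeline configuration
#'
#' A configuration is a plain list (serialisable to YAML/JSON) with either
#' an `input` block (paths: `vcf` + `pheno`, or `ped` + `map`) or
#' `simulate = TRUE` (the built-in synthetic study design); exactly one of
#' the two drives the run.
#'
#' @param simulate use the synthetic default study design.
#' @param seed integer seed recorded in every output header.
#' @param n_cases,n_controls synthetic cohort sizes.
#' @param n_permutations epistasis permutation count (0 = nominal P only).
#' @param maf_min,hwe_min,callrate_min QC thresholds.
#' @param models genetic models for the single-marker scan.
#' @param adjust adjust logistic fits for sex and age.
#' @return A config list.
#' @export
default_pipeline_config <- function(simulate = TRUE, seed = 1L,
                                    n_cases = 2518L, n_controls = 7521L,
                                    n_permutations = 0L,
                                    maf_min = 0.05, hwe_min = 1e-4,
                                    callrate_min = 0.97,
                                    models = c("additive", "dominant", "recessive"),
                                    adjust = TRUE) {
  list(simulate = simulate, input = NULL, seed = as.integer(seed),
       n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
       n_permutations = as.integer(n_permutations),
       qc = list(maf_min = maf_min, hwe_min = hwe_min,
                 callrate_min = callrate_min),
       models = models, adjust = adjust)
}

.config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(deparse(config[order(names(config))]), collapse = ""), f)
  unname(tools::md5sum(f))
}

#' Write / read a pipeline report TSV
#'
#' Every report begins with `#` header lines naming the tool version, the
#' run seed and the configuration hash, followed by a TSV with a header
#' row.
#'
#' @param x data.frame to write.
#' @param path output path.
#' @param seed,config_hash,stage header metadata.
#' @return `write_report`: the path, invisibly. `read_report`: the
#'   data.frame (header comments skipped).
#' @export
write_report <- function(x, path, seed = NA, config_hash = "", stage = "") {
  hdr <- c(sprintf("# candigene %s", .pkg_version()),
           sprintf("# seed: %s", seed),
           sprintf("# config_hash: %s", config_hash),
           sprintf("# stage: %s", stage))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE)
}

#' Run the full association pipeline
#'
#' Stages, in order: load or simulate the cohort; per-SNP QC; single-marker
#' association; within-chromosome pairwise LD and block construction;
#' haplotype association per block; exhaustive cross-chromosome epistasis
#' (with permutation correction when `n_permutations > 0`). Each stage
#' writes its own TSV so stages can be re-run and inspected independently;
#' a run log records stage timings, QC in/out counts and the thresholds in
#' effect. Deterministic given `config$seed`.
#'
#' @param config a [default_pipeline_config()]-style list, or a path to a
#'   YAML/JSON file with the same fields.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the per-stage objects and `files` (the
#'   written report paths).
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)   # yaml reads JSON too
    base <- default_pipeline_config()
    config <- utils::modifyList(base, config)
  }
  has_input <- !is.null(config$input)
  if (isTRUE(config$simulate) == has_input)
    stop("config must set exactly one of `simulate = TRUE` or `input`")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- .config_hash(config)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat(sprintf("# candigene %s run log\n", .pkg_version()), file = log_path)
  logf("seed: %s; config_hash: %s", config$seed, hash)
  logf("qc thresholds: maf_min=%s hwe_min=%s callrate_min=%s",
       config$qc$maf_min, config$qc$hwe_min, config$qc$callrate_min)
  files <- character(0)
  emit <- function(x, name, stage) {
    p <- file.path(out_dir, name)
    write_report(x, p, seed = config$seed, config_hash = hash, stage = stage)
    files[[name]] <<- p
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    logf("stage %s: %.2f s", name, proc.time()[["elapsed"]] - t0)
    out
  }

  cohort <- stage("load", {
    if (has_input) {
      inp <- config$input
      if (!is.null(inp$vcf)) read_vcf(inp$vcf, inp$pheno)
      else read_plink_text(inp$ped, inp$map, inp$covar %||% NULL)
    } else {
      cfg <- default_study_config()
      cs <- cohort_spec(n_cases = config$n_cases,
                        n_controls = config$n_controls,
                        seed = config$seed)
      simulate_cohort(cs, cfg$regions, cfg$effects)
    }
  })
  logf("cohort: %d samples, %d SNPs", nrow(cohort$samples), nrow(cohort$snps))

  qc <- stage("qc", apply_qc(cohort, config$qc$maf_min, config$qc$hwe_min,
                             config$qc$callrate_min))
  emit(qc$summary, "qc.tsv", "qc")
  logf("qc: %d of %d SNPs pass", sum(qc$summary$pass), nrow(qc$summary))
  cohort <- qc$cohort

  assoc <- stage("assoc", single_marker_scan(cohort, config$models,
                                             adjust = config$adjust))
  emit(assoc, "assoc.tsv", "assoc")

  ld <- stage("ld", pairwise_ld(cohort, within_chromosome = TRUE))
  emit(ld, "ld_pairs.tsv", "ld")
  blocks <- stage("blocks", find_blocks(ld, cohort$snps))
  emit(blocks, "blocks.tsv", "blocks")
  logf("blocks: %d", nrow(blocks))

  haps <- stage("haplotypes", {
    if (nrow(blocks)) haplotype_scan(cohort, blocks, seed = config$seed)
    else data.frame(SNPS = character(0), HAPLOTYPE = character(0),
                    F_A = numeric(0), F_U = numeric(0),
                    CHISQ = numeric(0), P = numeric(0))
  })
  emit(haps, "haplotypes.tsv", "haplotypes")

  epi <- stage("epistasis", {
    pairs <- enumerate_cross_chrom_pairs(cohort$snps)
    if (nrow(pairs)) permutation_scan(cohort, pairs,
                                      n_perm = config$n_permutations,
                                      seed = config$seed,
                                      adjust = config$adjust)
    else list(results = data.frame(), null = list(min_p_values = numeric(0)))
  })
  if (nrow(epi$results)) {
    emit(epi$results, "epistasis.tsv", "epistasis")
    emit(data.frame(replicate = seq_along(epi$null$min_p_values),
                    min_p = epi$null$min_p_values),
         "epistasis_null.tsv", "epistasis")
  }
  logf("done")
  invisible(list(cohort = cohort, qc = qc$summary, assoc = assoc, ld = ld,
                 blocks = blocks, haplotypes = haps, epistasis = epi,
                 files = files))
}

#' Regional association table around a reference SNP
#'
#' Table form of a regional association plot: all scan results for SNPs
#' within `window/2` base pairs of the centre SNP on its chromosome,
#' sorted by position, with `-log10(P)` and the centre row flagged as the
#' reference.
#'
#' @param results a [single_marker_scan()] data.frame.
#' @param snps the cohort's SNP table (for chromosome/position).
#' @param center_snp reference SNP id (must be present).
#' @param window full window width in base pairs (default 1e6).
#' @param model which model's rows to tabulate (default "additive").
#' @return data.frame: `snp_id`, `chromosome`, `position`, `p_value`,
#'   `neg_log10_p`, `genotyped`, `is_reference`.
#' @export
regional_table <- function(results, snps, center_snp, window = 1e6,
                           model = "additive") {
  c_idx <- match(center_snp, snps$snp_id)
  if (is.na(c_idx)) stop("center SNP not in panel: ", center_snp)
  chrom <- snps$chromosome[c_idx]
  pos0 <- snps$position[c_idx]
  sel <- snps$chromosome == chrom & abs(snps$position - pos0) <= window / 2
  res <- results[results$model == model, , drop = FALSE]
  idx <- which(sel)
  out <- data.frame(
    snp_id = snps$snp_id[idx], chromosome = snps$chromosome[idx],
    position = snps$position[idx],
    p_value = res$p_value[match(snps$snp_id[idx], res$snp_id)],
    stringsAsFactors = FALSE)
  out$neg_log10_p <- -log10(out$p_value)
  out$genotyped <- TRUE
  out$is_reference <- out$snp_id == center_snp
  out[order(out$position), , drop = FALSE]
}
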