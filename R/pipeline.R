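# End-to-end pipeline: BLUPs -> founder probabilities -> marker filters ->
# IBD / haplotype blocks -> per-model scans -> permutation thresholds ->
# support intervals -> cross-model merge -> effect sizes.

#' Run the full QTL-mapping pipeline
#'
#' Stages are executed in order and all declared outputs are written to
#' `config$out_dir`. The run is deterministic for a fixed `config$seed`
#' (a rerun with an identical config reproduces the scan tables exactly).
#'
#' @param config a list with either file paths (see [load_dataset()]) or
#'   in-memory objects `map`, `founders`, `line_geno`, `pheno`, plus:
#'   `out_dir` (required), `models` (subset of `c("GWAS_SNP", "QTL_F",
#'   "QTL_H")`), `n_perm` (default 100), `alpha` (default 0.05),
#'   `r2_filter` (default 0.95), `error` (HMM, default 0.002), `gens`
#'   (HMM, default 7), `grid_step` (default 0.01), `seed` (default 1),
#'   `min_lines` (default 5), `prob_threshold` (default 0.8),
#'   `ibd` (optional precomputed `ibd_segments`)
#' @return invisible list with all intermediate objects (`blups`,
#'   `posterior`, `blocks`, `scans`, `thresholds`, `intervals`, `merged`)
#' @export
run_pipeline <- function(config) {
  out_dir <- config$out_dir %||% stop_invalid("config$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  models <- config$models %||% c("GWAS_SNP", "QTL_F", "QTL_H")
  n_perm <- config$n_perm %||% 100
  alpha <- config$alpha %||% 0.05
  r2f <- config$r2_filter %||% 0.95
  grid_step <- config$grid_step %||% 0.01

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_invalid("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  }

  dat <- if (!is.null(config$founders) && inherits(config$founders, "founder_set")) {
    list(map = config$map %||% config$founders$map,
         founders = config$founders, line_geno = config$line_geno,
         pheno = config$pheno, ibd = config$ibd)
  } else stage("load", load_dataset(config))
  map <- dat$map

  blups <- stage("blups", {
    if (is.null(dat$pheno)) NULL else calc_blups(dat$pheno)
  })

  posterior <- stage("founder_probabilities",
    infer_founder_probabilities(dat$line_geno, dat$founders, map,
                                error = config$error %||% 0.002,
                                gens = config$gens %||% 7))
  kept_f <- stage("filter_founder_markers",
                  filter_probability_markers(posterior, r2f))

  ibd <- dat$ibd %||% stage("ibd", detect_pairwise_ibd(dat$founders, map))
  blocks <- stage("blocks",
                  build_haplotype_blocks(ibd, map, founder_ids(dat$founders)))
  hap <- stage("haplotype_probabilities",
               haplotype_probabilities(posterior, blocks))
  kept_h <- stage("filter_haplotype_markers",
                  filter_haplotype_markers(hap, r2f))

  K_loco <- stage("kinship", {
    if (length(map_chromosomes(map)) >= 2) compute_grm_loco(dat$line_geno, map)
    else compute_grm(dat$line_geno)
  })

  y <- if (!is.null(blups)) {
    setNames(blups$blup, blups$line)[rownames(dat$line_geno)]
  } else stop_invalid("pipeline needs phenotypes")
  if (anyNA(y)) {
    keep <- !is.na(y)
    stop_invalid("phenotypes missing for ", sum(!keep), " genotyped line(s)")
  }

  sets <- list(
    GWAS_SNP = function() snp_markers(dat$line_geno, map),
    QTL_F = function() founder_markers(posterior, keep = kept_f),
    QTL_H = function() haplotype_markers(hap, keep = kept_h))
  scans <- list(); thresholds <- list(); intervals <- list()
  for (mdl in models) {
    ms <- sets[[mdl]]()
    sc <- stage(paste0("scan_", mdl),
                genome_scan(y, ms, K_loco, grid_step = grid_step))
    th <- stage(paste0("permute_", mdl),
                permutation_threshold(y, ms, K_loco, n_perm = n_perm,
                                      alpha = alpha, seed = seed,
                                      grid_step = grid_step))
    scans[[mdl]] <- sc
    thresholds[[mdl]] <- th$threshold
    write_scan(sc, file.path(out_dir, paste0("scan_", mdl, ".tsv")))
    if (max(sc$neglog10p, na.rm = TRUE) > th$threshold) {
      intervals[[mdl]] <- support_interval(sc, phenotype = "trait")
    }
  }
  merged <- if (length(intervals)) merge_qtl(do.call(rbind, intervals)) else NULL

  effects <- NULL
  if (!is.null(merged) && "QTL_F" %in% names(intervals)) {
    ms <- sets$QTL_F()
    pk <- match(intervals$QTL_F$peak_marker, ms$info$marker)
    effects <- stage("effects",
      estimate_effect_sizes(y, ms$full[[pk]],
                            K = K_loco[[ms$info$chrom[pk]]],
                            min_lines = config$min_lines %||% 5,
                            prob_threshold = config$prob_threshold %||% 0.8,
                            grid_step = grid_step))
    write.table(effects, file.path(out_dir, "effects_QTL_F.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  write_blocks_bed(blocks, file.path(out_dir, "haplotype_blocks.bed"))
  if (!is.null(merged))
    write.table(merged[, setdiff(names(merged), "members")],
                file.path(out_dir, "qtl_merged.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- c(sprintf("seed\t%s", seed),
            sprintf("n_perm\t%s", n_perm),
            sprintf("alpha\t%s", alpha),
            sprintf("models\t%s", paste(models, collapse = ",")),
            sprintf("threshold_%s\t%.4f", names(thresholds),
                    unlist(thresholds)))
  writeLines(meta, file.path(out_dir, "run_metadata.tsv"))

  invisible(list(blups = blups, posterior = posterior, kept_founder = kept_f,
                 ibd = ibd, blocks = blocks, kept_haplotype = kept_h,
                 scans = scans, thresholds = thresholds,
                 intervals = intervals, merged = merged, effects = effects))
}
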