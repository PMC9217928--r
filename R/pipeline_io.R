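# Readers, writers, configuration and end-to-end orchestration. The
# interchange dialect is headered CSV/TSV; counts are TSV with genes as rows
# and a leading gene_id column; dendrograms are Newick; the run report is
# JSON with numbers at 6 significant digits so regeneration is
# byte-checkable.

MORPH_COLS <- c("fetus_id", "dam_id", "group", "sex", "day", "weight_g", "twin")
EXAM_COLS <- c("fetus_id", "day", "AD", "AH", "TD", "TH", "CRL", "HL", "BPD")
META_COLS <- c("sample_id", "dam_id", "day", "group", "n_fetuses",
               "total_fetal_mass", "extreme")
CT_COLS <- c("sample_id", "gene", "ct", "role")

require_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s) %s", what, paste(miss, collapse = ", ")),
         call. = FALSE)
  df
}

#' Read a fetal morphometry CSV
#'
#' Expects header `fetus_id,dam_id,group,sex,day,weight_g,twin`. Duplicate
#' fetus ids, unknown group codes and non-positive weights are hard errors
#' reported with row numbers.
#'
#' @param path File path.
#' @return Validated data frame.
#' @export
read_morphometry_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_cols(df, MORPH_COLS, path)
  if (anyDuplicated(df$fetus_id))
    stop(sprintf("%s: duplicate fetus_id at row(s) %s", path,
                 paste(which(duplicated(df$fetus_id)), collapse = ", ")), call. = FALSE)
  bad <- which(!df$group %in% c("AI", "IVP"))
  if (length(bad))
    stop(sprintf("%s: unknown group code at row(s) %s", path,
                 paste(bad, collapse = ", ")), call. = FALSE)
  bad <- which(!is.finite(df$weight_g) | df$weight_g <= 0)
  if (length(bad))
    stop(sprintf("%s: non-positive weight at row(s) %s", path,
                 paste(bad, collapse = ", ")), call. = FALSE)
  df$twin <- as.logical(df$twin)
  df
}

#' Read a D55 ultrasound CSV
#'
#' Expects `fetus_id`, `day` and the seven measurement columns (cm).
#'
#' @param path File path.
#' @return Validated data frame.
#' @export
read_ultrasound_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_cols(df, EXAM_COLS, path)
  for (m in setdiff(EXAM_COLS, c("fetus_id", "day"))) {
    bad <- which(!is.finite(df[[m]]) | df[[m]] <= 0)
    if (length(bad))
      stop(sprintf("%s: non-positive %s at row(s) %s", path, m,
                   paste(bad, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Read a gene x sample counts TSV
#'
#' First column `gene_id`, remaining columns one per sample. Negative or
#' missing entries are errors naming the gene and sample.
#'
#' @param path File path.
#' @return Integer matrix with gene/sample dimnames.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "gene_id") stop(sprintf("%s: first column must be gene_id", path), call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  bad <- which(is.na(m) | m < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("%s: negative or missing count for gene %s, sample %s", path,
                 rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]), call. = FALSE)
  storage.mode(m) <- "integer"
  check_counts(m)
}

#' Read a sample metadata CSV
#'
#' Expects `sample_id,dam_id,day,group,n_fetuses,total_fetal_mass,extreme`.
#' `extreme = TRUE` on a non-`IVP-LOS` sample violates the design invariant
#' and is an error.
#'
#' @param path File path.
#' @return Validated data frame.
#' @export
read_sample_meta_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_cols(df, META_COLS, path)
  if (anyDuplicated(df$sample_id))
    stop(sprintf("%s: duplicate sample_id", path), call. = FALSE)
  df$extreme <- as.logical(df$extreme)
  bad <- which(df$extreme & df$group != "IVP-LOS")
  if (length(bad))
    stop(sprintf("%s: extreme=TRUE but group != IVP-LOS at row(s) %s", path,
                 paste(bad, collapse = ", ")), call. = FALSE)
  df
}

#' Read a qPCR CT CSV
#'
#' Expects `sample_id,gene,ct,role`.
#'
#' @param path File path.
#' @return Validated data frame.
#' @export
read_ct_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_cols(df, CT_COLS, path)
  bad <- which(!is.finite(df$ct) | df$ct <= 0)
  if (length(bad))
    stop(sprintf("%s: non-positive CT at row(s) %s", path,
                 paste(bad, collapse = ", ")), call. = FALSE)
  if (!all(df$role %in% c("target", "reference")))
    stop(sprintf("%s: role must be 'target' or 'reference'", path), call. = FALSE)
  df
}

#' Write a counts matrix as TSV (genes as rows)
#' @param counts Integer matrix genes x samples.
#' @param path Output path.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Validates the thresholds and options shared across stages.
#'
#' @param q Overgrowth percentile (default 0.97).
#' @param screen_threshold `"control-max"` or `"fixed"`.
#' @param fixed_threshold Product threshold when `"fixed"` (default 100).
#' @param alpha Differential-expression significance level (default 0.05).
#' @param cv_max Reference-gene CV ceiling (default 0.10).
#' @param cluster_log2 Log-transform normalized counts before clustering?
#' @param prior_df_a,prior_df_b Dispersion shrinkage weights per backend.
#' @param seed Seed recorded with every random stage.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(q = 0.97, screen_threshold = c("control-max", "fixed"),
                            fixed_threshold = 100, alpha = 0.05, cv_max = 0.10,
                            cluster_log2 = FALSE, prior_df_a = 10, prior_df_b = 0,
                            seed = 1L) {
  screen_threshold <- match.arg(screen_threshold)
  if (q <= 0 || q >= 1) bad_field("q", "must be in (0, 1)")
  if (alpha <= 0 || alpha >= 1) bad_field("alpha", "must be in (0, 1)")
  check_pos(fixed_threshold, "fixed_threshold")
  check_pos(cv_max, "cv_max")
  structure(list(q = q, screen_threshold = screen_threshold,
                 fixed_threshold = fixed_threshold, alpha = alpha,
                 cv_max = cv_max, cluster_log2 = isTRUE(cluster_log2),
                 prior_df_a = prior_df_a, prior_df_b = prior_df_b,
                 seed = check_count(seed, "seed")),
            class = "pipeline_config")
}

#' Run the full screening pipeline
#'
#' Stage order mirrors the analysis: LOS classification and prevalence,
#' sex-ratio test, fetometry screen and correlations, then (when a count
#' matrix is supplied) size factors, average-linkage clustering with Newick
#' export, dual-backend NB-LRT differential expression per contrast with
#' intersection consensus and reference-gene selection, and (when a CT
#' table is supplied) comparative-CT folds for the extreme samples against
#' the rest. Stages without inputs are skipped; a morphometry-only run is a
#' valid success.
#'
#' @param fetuses Fetus table (see [read_morphometry_csv()]).
#' @param exams Optional ultrasound table.
#' @param counts Optional counts matrix.
#' @param meta Optional sample metadata (required with `counts`).
#' @param ct_table Optional qPCR CT table; folds are computed for every
#'   `target`-role gene, extreme-dam samples vs all others.
#' @param config A [pipeline_config()].
#' @param contrasts Named list of `list(full =, reduced =)` formulas for the
#'   DE stage; default tests the extreme-dam signature per day.
#' @param out_dir Optional directory: writes labels CSV, screening CSV,
#'   size-factor CSV, DE TSVs, Newick file, and `report.json`.
#' @return A list report of class `pipeline_report`.
#' @export
run_pipeline <- function(fetuses, exams = NULL, counts = NULL, meta = NULL,
                         ct_table = NULL, config = pipeline_config(),
                         contrasts = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list(seed = config$seed)

  labels <- classify_los(fetuses, q = config$q)
  report$thresholds <- as.list(labels$thresholds)
  report$labels <- labels$labels
  report$prevalence <- los_prevalence(labels)
  sexes <- table(factor(fetuses$sex, levels = c("F", "M")), fetuses$group)
  report$sex_ratio <- lapply(colnames(sexes), function(g) {
    sr <- sex_ratio_test(sexes["F", g], sum(sexes[, g]))
    list(group = g, n_female = sr$n_female, n_total = sr$n_total, p_value = sr$p_value)
  })

  if (!is.null(exams) && nrow(exams)) {
    fr <- fetometry_report(exams, fetuses, labels,
                           threshold = config$screen_threshold,
                           fixed_threshold = config$fixed_threshold)
    report$fetometry <- list(threshold = fr$threshold,
                             n_flagged = sum(fr$table$flagged),
                             flagged = fr$table$fetus_id[fr$table$flagged],
                             correlations = fr$correlations)
    report$fetometry_table <- fr$table
  }

  if (!is.null(counts)) {
    if (is.null(meta)) stop("stage 'transcriptome': counts supplied without sample metadata", call. = FALSE)
    sf <- list(mor = size_factors_mor(counts), tmm = tmm_factors(counts),
               uq = upperquartile_factors(counts))
    report$size_factors <- lapply(sf, unclass)
    norm <- normalize_counts(counts, sf$mor, log2 = config$cluster_log2)
    hc <- hierarchical_cluster(norm)
    report$newick <- dendrogram_newick(hc)
    report$first_merge_pairs <- first_merge_pairs(hc)
    if (is.null(contrasts))
      contrasts <- list(extreme_vs_rest = list(full = ~extreme, reduced = ~1))
    report$de <- list()
    for (nm in names(contrasts)) {
      ca <- contrasts[[nm]]
      ta <- nb_lrt(counts, meta, ca$full, ca$reduced, s = sf$tmm,
                   backend = "A", prior_df = config$prior_df_a)
      tb <- nb_lrt(counts, meta, ca$full, ca$reduced, s = sf$mor,
                   backend = "B", prior_df = config$prior_df_b)
      cons <- consensus_genes(ta, tb, alpha = config$alpha)
      report$de[[nm]] <- list(table_a = ta, table_b = tb,
                              consensus = cons$consensus,
                              n_significant_a = length(cons$significant_a),
                              n_significant_b = length(cons$significant_b))
      if (nm == names(contrasts)[1]) {
        refs <- select_reference_genes(ta, tb, normalize_counts(counts, sf$mor),
                                       cv_max = config$cv_max)
        report$reference_genes <- as.character(refs)
      }
    }
  }

  if (!is.null(ct_table) && nrow(ct_table)) {
    if (is.null(meta)) stop("stage 'qpcr': CT table supplied without sample metadata", call. = FALSE)
    baseline <- meta$sample_id[!meta$extreme & meta$sample_id %in% ct_table$sample_id]
    targets <- unique(ct_table$gene[ct_table$role == "target"])
    report$qpcr <- lapply(targets, function(tg)
      ddct_fold(ct_table, tg, baseline = baseline))
    names(report$qpcr) <- targets
  }

  class(report) <- "pipeline_report"
  if (!is.null(out_dir)) write_pipeline_report(report, out_dir)
  report
}

# First-merge leaf pairs of a dendrogram: merges joining two singletons.
first_merge_pairs <- function(hc) {
  rows <- which(hc$merge[, 1] < 0 & hc$merge[, 2] < 0)
  lapply(rows, function(r) hc$labels[-hc$merge[r, ]])
}

#' Write a pipeline report to disk
#'
#' Emits `labels.csv`, `screening.csv`, `size_factors.csv`, one
#' `de_<contrast>_<backend>.tsv` per contrast, `dendrogram.newick`,
#' `qpcr_<target>.csv`, and `report.json` (numbers at 6 significant digits).
#'
#' @param report A `pipeline_report`.
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$labels, file.path(out_dir, "labels.csv"), row.names = FALSE)
  if (!is.null(report$fetometry_table))
    utils::write.csv(report$fetometry_table, file.path(out_dir, "screening.csv"), row.names = FALSE)
  if (!is.null(report$size_factors)) {
    sfd <- data.frame(sample_id = names(report$size_factors$mor),
                      median_of_ratios = unname(report$size_factors$mor),
                      tmm = unname(report$size_factors$tmm[names(report$size_factors$mor)]),
                      upper_quartile = unname(report$size_factors$uq[names(report$size_factors$mor)]))
    utils::write.csv(sfd, file.path(out_dir, "size_factors.csv"), row.names = FALSE)
  }
  if (!is.null(report$newick))
    writeLines(report$newick, file.path(out_dir, "dendrogram.newick"))
  for (nm in names(report$de)) {
    utils::write.table(report$de[[nm]]$table_a, file.path(out_dir, sprintf("de_%s_A.tsv", nm)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(report$de[[nm]]$table_b, file.path(out_dir, sprintf("de_%s_B.tsv", nm)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (tg in names(report$qpcr))
    utils::write.csv(report$qpcr[[tg]], file.path(out_dir, sprintf("qpcr_%s.csv", tg)),
                     row.names = FALSE)
  summary <- list(
    seed = report$seed,
    thresholds = lapply(report$thresholds, function(x) signif(x, 6)),
    prevalence = signif(report$prevalence, 6),
    sex_ratio = lapply(report$sex_ratio, function(sr) {
      sr$p_value <- signif(sr$p_value, 6); sr
    }),
    fetometry = if (!is.null(report$fetometry))
      list(threshold = signif(report$fetometry$threshold, 6),
           n_flagged = report$fetometry$n_flagged,
           flagged = report$fetometry$flagged),
    consensus = lapply(report$de, `[[`, "consensus"),
    reference_genes = report$reference_genes
  )
  jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(out_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("LOS screening pipeline report\n")
  cat(sprintf("  thresholds (g): %s\n",
              paste(sprintf("%s = %.2f", names(x$thresholds), unlist(x$thresholds)), collapse = ", ")))
  cat(sprintf("  LOS prevalence among IVP: %.1f%%\n", 100 * x$prevalence))
  for (sr in x$sex_ratio)
    cat(sprintf("  sex ratio %s: %d/%d female, p = %.4g\n", sr$group, sr$n_female,
                sr$n_total, sr$p_value))
  if (!is.null(x$fetometry))
    cat(sprintf("  fetometry: threshold %.2f, %d flagged (%s)\n", x$fetometry$threshold,
                x$fetometry$n_flagged, paste(x$fetometry$flagged, collapse = ", ")))
  for (nm in names(x$de))
    cat(sprintf("  DE %s: consensus %d gene(s)\n", nm, length(x$de[[nm]]$consensus)))
  if (!is.null(x$reference_genes))
    cat(sprintf("  reference genes: %s\n", paste(x$reference_genes, collapse = ", ")))
  invisible(x)
}
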