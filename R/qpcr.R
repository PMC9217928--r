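#' Geometric mean of reference-gene CT values
#'
#' The per-sample normalizer of the comparative-CT method: the geometric
#' mean of the endogenous reference genes' CT values (cycles).
#'
#' @param cts Positive numeric vector of CT values.
#' @return The geometric mean, cycles.
#' @export
geomean_ct <- function(cts) {
  if (!is.numeric(cts) || length(cts) == 0L || anyNA(cts) || any(cts <= 0))
    bad_field("cts", "must be positive CT values")
  geomean(cts)
}

#' Comparative-CT (delta-delta-CT) fold differences
#'
#' For each sample, `dCT = CT_target - geomean(reference CTs)`; the baseline
#' mean dCT is the arithmetic mean over `baseline` samples;
#' `ddCT = dCT - mean(baseline dCT)` and `fold = 2^(-ddCT)`. Centred on the
#' baseline-mean dCT, the geometric mean of the baseline folds is exactly 1
#' (the "average fold difference = 1" convention). Technical replicate CTs,
#' if present, are averaged arithmetically first (and this is recorded in
#' the result's `replicates_averaged` attribute).
#'
#' @param table Data frame with columns `sample_id`, `gene`, `ct`, `role`
#'   (`"target"`/`"reference"`).
#' @param target Target gene name.
#' @param baseline Character vector of baseline sample ids (the comparison
#'   group; e.g., all dams except those carrying the two largest overgrown
#'   fetuses).
#' @param test Optional character vector of test sample ids; defaults to all
#'   non-baseline samples in the table. Must be disjoint from `baseline`.
#' @param ref_mode `"ct"` (default): geometric mean of the reference CT
#'   values themselves (the literal protocol wording); `"linear"`: the CT
#'   equivalent of the geometric mean of linearized `2^(-CT)` quantities,
#'   which reduces to the arithmetic mean of the reference CTs. The two
#'   differ by at most a small fraction of a cycle for typical CT spreads;
#'   both are exposed because both phrasings circulate.
#' @return Data frame of class `qpcr_result` (`sample_id`, `gene`, `dct`,
#'   `ddct`, `fold`, `baseline`), with attributes `baseline_mean_dct` and
#'   `replicates_averaged`.
#' @export
ddct_fold <- function(table, target, baseline, test = NULL,
                      ref_mode = c("ct", "linear")) {
  ref_mode <- match.arg(ref_mode)
  req <- c("sample_id", "gene", "ct", "role")
  miss <- setdiff(req, names(table))
  if (length(miss)) bad_field("table", paste("missing columns:", paste(miss, collapse = ", ")))
  if (length(baseline) == 0L) bad_field("baseline", "must be non-empty")
  if (!is.null(test) && length(intersect(baseline, test)))
    bad_field("test", "must be disjoint from baseline")
  check_pos(table$ct, "ct")
  samples <- unique(table$sample_id)
  if (is.null(test)) test <- setdiff(samples, baseline)
  used <- union(baseline, test)
  ref_genes <- unique(table$gene[table$role == "reference"])
  if (length(ref_genes) == 0L) stop("no reference genes in table", call. = FALSE)
  reps <- FALSE
  dct <- vapply(used, function(s) {
    sub <- table[table$sample_id == s, ]
    tgt <- sub$ct[sub$gene == target & sub$role == "target"]
    if (length(tgt) == 0L)
      stop(sprintf("missing target CT for sample %s, gene %s", s, target), call. = FALSE)
    if (length(tgt) > 1L) reps <<- TRUE
    refs <- vapply(ref_genes, function(g) {
      ct <- sub$ct[sub$gene == g & sub$role == "reference"]
      if (length(ct) == 0L)
        stop(sprintf("missing reference CT for sample %s, gene %s", s, g), call. = FALSE)
      if (length(ct) > 1L) reps <<- TRUE
      mean(ct)
    }, numeric(1))
    norm <- if (ref_mode == "ct") geomean_ct(refs) else -log2(geomean(2^(-refs)))
    mean(tgt) - norm
  }, numeric(1))
  base_mean <- mean(dct[baseline])
  ddct <- dct - base_mean
  out <- data.frame(sample_id = used, gene = target, dct = unname(dct),
                    ddct = unname(ddct), fold = unname(2^(-ddct)),
                    baseline = used %in% baseline, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "baseline_mean_dct") <- base_mean
  attr(out, "replicates_averaged") <- reps
  class(out) <- c("qpcr_result", "data.frame")
  out
}
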