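# Count-matrix analytics for the maternal leukocyte transcriptomes: three
# size-factor methods, average-linkage clustering, and a negative-binomial
# GLM likelihood-ratio engine run in two configurations whose significant
# gene sets are intersected.

check_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    bad_field("counts", "must be a numeric matrix (genes x samples)")
  if (anyNA(counts) || any(counts < 0)) bad_field("counts", "entries must be non-negative")
  if (ncol(counts) < 2L) bad_field("counts", "need at least 2 samples")
  if (is.null(rownames(counts))) rownames(counts) <- sprintf("G%05d", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- sprintf("S%03d", seq_len(ncol(counts)))
  if (anyDuplicated(rownames(counts))) bad_field("counts", "duplicate gene ids")
  if (anyDuplicated(colnames(counts))) bad_field("counts", "duplicate sample ids")
  counts
}

new_size_factors <- function(factors, method) {
  check_pos(factors, "factors")
  structure(factors, method = method, class = "size_factors")
}

#' @export
print.size_factors <- function(x, ...) {
  cat(sprintf("Size factors (%s):\n", attr(x, "method")))
  print(round(unclass(x), 4))
  invisible(x)
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median across reference genes
#' (genes with positive counts in every sample) of the ratio of the sample's
#' count to the gene's geometric mean. Scaling one sample's counts by `c`
#' scales its factor by exactly `c`.
#'
#' @param counts Non-negative numeric matrix, genes x samples.
#' @return A named `size_factors` vector, method `"median-of-ratios"`.
#' @export
size_factors_mor <- function(counts) {
  counts <- check_counts(counts)
  allpos <- rowSums(counts > 0) == ncol(counts)
  if (!any(allpos)) stop("no reference genes for geometric means", call. = FALSE)
  lg <- log(counts[allpos, , drop = FALSE])
  gm <- rowMeans(lg)
  s <- apply(exp(lg - gm), 2, stats::median)
  new_size_factors(s, "median-of-ratios")
}

#' Trimmed mean of M-values (TMM) size factors
#'
#' Ratio-based normalization robust to composition effects: gene-wise log2
#' ratios of library proportions against a reference sample are doubly
#' trimmed (by log-ratio and by average log abundance), then combined by a
#' precision-weighted mean with inverse asymptotic binomial variances as
#' weights. The reference is the sample whose upper quartile of
#' library-scaled positive counts is closest to the mean upper quartile.
#' Factors are rescaled to geometric mean 1; they are depth-free, so the
#' effective library size is `colSums(counts) * factor`.
#'
#' @param counts Non-negative numeric matrix, genes x samples.
#' @param trim_m,trim_a Tail-trim fractions for M and A (defaults 0.30 and
#'   0.05, each tail).
#' @return A named `size_factors` vector, method `"TMM"`.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  counts <- check_counts(counts)
  lib <- colSums(counts)
  if (any(lib == 0)) stop("sample with zero total count", call. = FALSE)
  uq <- vapply(seq_len(ncol(counts)), function(j) {
    x <- counts[, j]
    stats::quantile(x[x > 0] / lib[j], 0.75, type = 7, names = FALSE)
  }, numeric(1))
  ref <- which.min(abs(uq - mean(uq)))
  f <- numeric(ncol(counts))
  yr <- counts[, ref]
  for (j in seq_len(ncol(counts))) {
    if (j == ref) { f[j] <- 0; next }
    yj <- counts[, j]
    keep <- yj > 0 & yr > 0
    if (!any(keep)) {
      warning(sprintf("sample %s shares no positive genes with the reference; factor set to 1",
                      colnames(counts)[j]))
      f[j] <- 0
      next
    }
    pj <- yj[keep] / lib[j]
    pr <- yr[keep] / lib[ref]
    M <- log2(pj / pr)
    A <- 0.5 * log2(pj * pr)
    v <- (lib[j] - yj[keep]) / (lib[j] * yj[keep]) +
         (lib[ref] - yr[keep]) / (lib[ref] * yr[keep])
    n <- length(M)
    loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
    rM <- rank(M, ties.method = "first")
    rA <- rank(A, ties.method = "first")
    keep2 <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (!any(keep2)) keep2 <- rep(TRUE, n)  # tiny panels: fall back to untrimmed
    f[j] <- sum(M[keep2] / v[keep2]) / sum(1 / v[keep2])
  }
  s <- 2^f
  s <- s / geomean(s)
  new_size_factors(stats::setNames(s, colnames(counts)), "TMM")
}

#' Upper-quartile size factors
#'
#' The between-lane depth adjustment: each sample's factor is its 75th
#' percentile (type 7) of positive counts divided by the geometric mean of
#' those percentiles, giving factors with geometric mean 1 that carry the
#' depth signal.
#'
#' @param counts Non-negative numeric matrix, genes x samples.
#' @param p Quantile used (default 0.75).
#' @return A named `size_factors` vector, method `"upper-quartile"`.
#' @export
upperquartile_factors <- function(counts, p = 0.75) {
  counts <- check_counts(counts)
  u <- vapply(seq_len(ncol(counts)), function(j) {
    x <- counts[, j]
    x <- x[x > 0]
    if (length(x) == 0L)
      stop(sprintf("sample %s has no positive counts", colnames(counts)[j]), call. = FALSE)
    stats::quantile(x, p, type = 7, names = FALSE)
  }, numeric(1))
  s <- u / geomean(u)
  new_size_factors(stats::setNames(s, colnames(counts)), "upper-quartile")
}

#' Scale a count matrix by size factors
#'
#' @param counts Genes x samples matrix.
#' @param s A `size_factors` vector covering every sample.
#' @param log2 If `TRUE`, return `log2(x + 1)` of the scaled values.
#' @return Numeric matrix of the same shape.
#' @export
normalize_counts <- function(counts, s, log2 = FALSE) {
  counts <- check_counts(counts)
  if (is.null(names(s)) || !all(colnames(counts) %in% names(s)))
    stop("size factors missing for sample(s): ",
         paste(setdiff(colnames(counts), names(s)), collapse = ", "), call. = FALSE)
  out <- sweep(counts, 2, unclass(s)[colnames(counts)], `/`)
  if (log2) out <- log2(out + 1)
  out
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Agglomerative clustering of sample columns under euclidean distance over
#' genes: at each step the pair of clusters with the smallest average
#' inter-cluster distance is merged, the merge height being that average.
#' Distance ties are broken by the lexicographically smallest pair of
#' smallest original column indices, so the dendrogram (and its Newick
#' serialization) is fully deterministic.
#'
#' @param mat Numeric matrix (genes x samples; columns are clustered), or a
#'   `dist` object.
#' @return An object of class `hclust` (method `"average"`), usable with
#'   [stats::cophenetic()], [dendrogram_newick()], etc.
#' @export
hierarchical_cluster <- function(mat) {
  if (inherits(mat, "dist")) {
    D <- as.matrix(mat)
  } else {
    if (!is.numeric(mat) || anyNA(mat) || any(!is.finite(mat)))
      bad_field("mat", "must be a finite numeric matrix")
    D <- as.matrix(stats::dist(t(mat), method = "euclidean"))
  }
  n <- nrow(D)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  labels <- rownames(D)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  active <- seq_len(n)
  members <- as.list(seq_len(n))      # original leaf indices per cluster
  node <- -seq_len(n)                 # hclust node codes
  sizes <- rep(1L, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  d <- D
  for (s in seq_len(n - 1L)) {
    best <- NULL
    for (ii in seq_along(active)) {
      for (jj in seq_along(active)) {
        if (jj <= ii) next
        a <- active[ii]; b <- active[jj]
        dv <- d[a, b]
        rep_ab <- sort(c(min(members[[a]]), min(members[[b]])))
        if (is.null(best) || dv < best$d ||
            (dv == best$d && (rep_ab[1] < best$rep[1] ||
                              (rep_ab[1] == best$rep[1] && rep_ab[2] < best$rep[2])))) {
          best <- list(i = a, j = b, d = dv, rep = rep_ab)
        }
      }
    }
    i <- best$i; j <- best$j
    # order the merge row by smallest original index for determinism
    if (min(members[[i]]) > min(members[[j]])) { tmp <- i; i <- j; j <- tmp }
    merge[s, ] <- c(node[i], node[j])
    height[s] <- best$d
    for (k in active) {
      if (k == i || k == j) next
      d[i, k] <- d[k, i] <- (sizes[i] * d[i, k] + sizes[j] * d[j, k]) / (sizes[i] + sizes[j])
    }
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    node[i] <- s
    active <- setdiff(active, j)
  }
  order <- integer(0)
  walk <- function(nd) {
    if (nd < 0) order <<- c(order, -nd)
    else { walk(merge[nd, 1]); walk(merge[nd, 2]) }
  }
  walk(n - 1L)
  structure(list(merge = merge, height = height, order = order,
                 labels = labels, method = "average",
                 dist.method = "euclidean", call = match.call()),
            class = "hclust")
}

#' Serialize a dendrogram to Newick
#'
#' Branch lengths are height differences between a node and its parent
#' (leaves sit at height 0), so cophenetic distances are preserved.
#'
#' @param hc An `hclust` object.
#' @param digits Significant digits for branch lengths.
#' @return A single Newick string terminated by `";"`.
#' @export
dendrogram_newick <- function(hc, digits = 6) {
  stopifnot(inherits(hc, "hclust"))
  fmt <- function(x) format(x, digits = digits, trim = TRUE, scientific = FALSE)
  rec <- function(nd, parent_h) {
    if (nd < 0) {
      sprintf("%s:%s", gsub("[,;:()\\s]", "_", hc$labels[-nd], perl = TRUE),
              fmt(parent_h))
    } else {
      h <- hc$height[nd]
      sprintf("(%s,%s):%s", rec(hc$merge[nd, 1], h), rec(hc$merge[nd, 2], h),
              fmt(parent_h - h))
    }
  }
  top <- length(hc$height)
  h <- hc$height[top]
  sprintf("(%s,%s);", rec(hc$merge[top, 1], h), rec(hc$merge[top, 2], h))
}

# ---- negative-binomial GLM engine ------------------------------------------

# IRLS fit of a NB log-linear model with fixed dispersion phi and offset.
nb_glm_fit <- function(y, X, offset, phi, max_iter = 50L, tol = 1e-8) {
  eta <- log(pmax(y, 0.5)) # init at saturated-ish values
  beta <- qr.coef(qr(X), eta - offset)
  beta[is.na(beta)] <- 0
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    eta <- pmin(pmax(drop(X %*% beta) + offset, -50), 50)
    mu <- pmax(exp(eta), 1e-10)
    w <- mu / (1 + phi * mu)
    z <- (eta - offset) + (y - mu) / mu
    fit <- stats::lm.wfit(X, z, w)
    b_new <- fit$coefficients
    b_new[is.na(b_new)] <- 0
    beta <- b_new
    eta <- pmin(pmax(drop(X %*% beta) + offset, -50), 50)
    mu <- pmax(exp(eta), 1e-10)
    ll <- nb_loglik(y, mu, phi)
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
  }
  w <- mu / (1 + phi * mu)
  list(beta = beta, mu = mu, loglik = nb_loglik(y, mu, phi), w = w)
}

nb_loglik <- function(y, mu, phi) {
  if (phi < 1e-10) sum(stats::dpois(y, mu, log = TRUE))
  else sum(stats::dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
}

# Cox-Reid adjusted profile log-likelihood of the dispersion for one gene.
nb_apl <- function(log_phi, y, X, offset) {
  phi <- exp(log_phi)
  fit <- nb_glm_fit(y, X, offset, phi)
  XtWX <- crossprod(X * sqrt(fit$w))
  ld <- determinant(XtWX, logarithm = TRUE)$modulus
  as.numeric(fit$loglik - 0.5 * ld)
}

#' Negative-binomial likelihood-ratio differential expression
#'
#' Fits, per gene, nested negative-binomial log-linear models
#' `log mu = X beta + log(effective library size)` by iteratively reweighted
#' least squares and compares them with a likelihood-ratio chi-square test.
#' Gene-wise dispersions are maximum Cox-Reid adjusted profile-likelihood
#' estimates, optionally shrunk toward the common all-gene estimate on the
#' log scale with a prior weight expressed in residual-df equivalents. Two
#' standard configurations are exposed: backend `"A"` (TMM effective library
#' sizes, shrunk dispersion, prior weight 10) and backend `"B"`
#' (median-of-ratios offsets, purely gene-wise dispersion). P-values are
#' Benjamini-Hochberg adjusted. All-zero genes are retained with `p = 1`
#' and flagged untestable so gene universes stay aligned across backends.
#'
#' @param counts Integer matrix, genes x samples.
#' @param meta Data frame of sample covariates; rows match columns of
#'   `counts` by `sample_id`.
#' @param full,reduced Model formulas over columns of `meta`; `reduced` must
#'   be nested in `full`.
#' @param s Optional `size_factors`; defaults to [tmm_factors()] for backend
#'   A and [size_factors_mor()] for backend B.
#' @param backend `"A"` or `"B"`.
#' @param prior_df Dispersion shrinkage weight (residual-df equivalents);
#'   default 10 for backend A, 0 for backend B.
#' @return Data frame of class `de_table`: `gene`, `baseMean`, `log2FC`,
#'   `lrt_stat`, `df`, `p`, `adj_p`, `dispersion`, `status`, `backend`.
#' @export
nb_lrt <- function(counts, meta, full, reduced, s = NULL,
                   backend = c("A", "B"), prior_df = NULL) {
  backend <- match.arg(backend)
  counts <- check_counts(counts)
  if (!is.null(meta$sample_id)) {
    if (!all(colnames(counts) %in% meta$sample_id))
      stop("metadata missing for sample(s): ",
           paste(setdiff(colnames(counts), meta$sample_id), collapse = ", "), call. = FALSE)
    meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
  } else if (nrow(meta) != ncol(counts)) {
    stop("meta must have one row per sample", call. = FALSE)
  }
  Xf <- stats::model.matrix(full, meta)
  Xr <- stats::model.matrix(reduced, meta)
  qf <- qr(Xf)
  if (qf$rank < ncol(Xf)) stop("full design is not of full rank (empty design cell?)", call. = FALSE)
  if (qr(cbind(Xr, Xf))$rank > qf$rank)
    stop("designs are not nested: reduced model is not a submodel of full", call. = FALSE)
  df_test <- ncol(Xf) - ncol(Xr)
  if (df_test < 1L) stop("designs are not nested: full model adds no coefficients", call. = FALSE)
  if (is.null(s)) s <- if (backend == "A") tmm_factors(counts) else size_factors_mor(counts)
  sv <- unclass(s)[colnames(counts)]
  offset <- switch(attr(s, "method"),
                   "TMM" = log(colSums(counts) * sv),
                   log(sv))
  offset <- offset - mean(offset)
  if (is.null(prior_df)) prior_df <- if (backend == "A") 10 else 0
  G <- nrow(counts)
  nzero <- rowSums(counts) == 0
  interval <- c(log(1e-6), log(20))
  disp_gene <- rep(NA_real_, G)
  for (g in which(!nzero)) {
    disp_gene[g] <- exp(stats::optimize(nb_apl, interval, maximum = TRUE,
                                        y = counts[g, ], X = Xf, offset = offset,
                                        tol = 0.01)$maximum)
  }
  if (prior_df > 0) {
    common <- exp(stats::optimize(function(lp) {
      sum(vapply(which(!nzero), function(g)
        nb_apl(lp, counts[g, ], Xf, offset), numeric(1)))
    }, interval, maximum = TRUE, tol = 0.01)$maximum)
    rdf <- ncol(counts) - ncol(Xf)
    disp <- exp((prior_df * log(common) + rdf * log(disp_gene)) / (prior_df + rdf))
  } else {
    disp <- disp_gene
  }
  dropped <- setdiff(colnames(Xf), colnames(Xr))
  rel <- exp(offset) / geomean(exp(offset))
  baseMean <- rowMeans(sweep(counts, 2, rel, `/`))
  lrt <- rep(0, G); pval <- rep(1, G); lfc <- rep(0, G)
  status <- ifelse(nzero, "untestable", "ok")
  for (g in which(!nzero)) {
    y <- counts[g, ]
    ff <- nb_glm_fit(y, Xf, offset, disp[g])
    fr <- nb_glm_fit(y, Xr, offset, disp[g])
    lrt[g] <- max(0, 2 * (ff$loglik - fr$loglik))
    pval[g] <- stats::pchisq(lrt[g], df_test, lower.tail = FALSE)
    if (length(dropped)) lfc[g] <- ff$beta[dropped[1]] / log(2)
  }
  out <- data.frame(gene = rownames(counts), baseMean = baseMean,
                    log2FC = lfc, lrt_stat = lrt, df = df_test, p = pval,
                    adj_p = bh_adjust(pval), dispersion = disp,
                    status = status, backend = backend,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("de_table", "data.frame")
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (same order), capped at 1.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    bad_field("p", "must be probabilities in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Dual-backend consensus of significant genes
#'
#' A gene is a consensus candidate when its adjusted p-value is at or below
#' `alpha` in both backend tables; intersecting the two significant sets is
#' the guard against method-specific false positives.
#'
#' @param table_a,table_b `de_table` objects over the same gene universe.
#' @param alpha Significance level (default 0.05).
#' @return List of class `consensus_result`: `alpha`, `significant_a`,
#'   `significant_b`, `consensus`.
#' @export
consensus_genes <- function(table_a, table_b, alpha = 0.05) {
  check_prob(alpha, "alpha")
  if (!setequal(table_a$gene, table_b$gene)) {
    diff <- union(setdiff(table_a$gene, table_b$gene), setdiff(table_b$gene, table_a$gene))
    stop("gene universes differ: ", paste(diff, collapse = ", "), call. = FALSE)
  }
  sa <- table_a$gene[table_a$adj_p <= alpha]
  sb <- table_b$gene[table_b$adj_p <= alpha]
  structure(list(alpha = alpha, significant_a = sa, significant_b = sb,
                 consensus = intersect(sa, sb)),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("Consensus at alpha = %g: backend A %d, backend B %d, intersection %d gene(s)\n",
              x$alpha, length(x$significant_a), length(x$significant_b), length(x$consensus)))
  if (length(x$consensus)) cat(" ", paste(x$consensus, collapse = ", "), "\n")
  invisible(x)
}

#' Select stable reference genes for qPCR normalization
#'
#' A gene qualifies as an endogenous reference when both backends call it
#' unambiguously null (backend A adjusted p at the top of the scale,
#' operationalized as `adj_p >= fdr_one`; backend B `adj_p > padj_min`) and
#' its normalized counts are stable across samples (coefficient of
#' variation `<= cv_max`).
#'
#' @param table_a,table_b `de_table` objects over the same genes.
#' @param normalized Normalized count matrix (genes x samples).
#' @param cv_max Maximum CV (default 0.10).
#' @param fdr_one Backend-A "FDR = 1" operationalization (default 0.99).
#' @param padj_min Backend-B lower bound (default 0.8, exclusive).
#' @return Character vector of selected genes; attribute `"criteria"` holds
#'   the per-gene screening table (with exclusion reasons).
#' @export
select_reference_genes <- function(table_a, table_b, normalized,
                                   cv_max = 0.10, fdr_one = 0.99, padj_min = 0.8) {
  genes <- intersect(intersect(table_a$gene, table_b$gene), rownames(normalized))
  if (length(genes) == 0L) stop("tables and matrix share no genes", call. = FALSE)
  m <- rowMeans(normalized[genes, , drop = FALSE])
  sdv <- apply(normalized[genes, , drop = FALSE], 1, stats::sd)
  cv <- ifelse(m > 0, sdv / m, NA_real_)
  pa <- table_a$adj_p[match(genes, table_a$gene)]
  pb <- table_b$adj_p[match(genes, table_b$gene)]
  pass <- !is.na(cv) & pa >= fdr_one & pb > padj_min & cv <= cv_max
  crit <- data.frame(gene = genes, adj_p_a = pa, adj_p_b = pb, mean = m,
                     cv = cv, selected = pass,
                     reason = ifelse(pass, "selected",
                                     ifelse(is.na(cv), "zero mean",
                                            ifelse(pa < fdr_one | pb <= padj_min,
                                                   "not null enough", "CV too high"))),
                     stringsAsFactors = FALSE)
  structure(genes[pass], criteria = crit)
}
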