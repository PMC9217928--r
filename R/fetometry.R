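#' Six-measurement D55 ultrasound product index
#'
#' The screening statistic is the product of six D55 ultrasonographic
#' measurements: abdominal diameter x abdominal height x crown-rump length x
#' head length x thoracic height x thoracic diameter (cm^6). Biparietal
#' diameter is excluded (it showed no association with collection weight).
#' The product scales as the sixth power of a uniform rescaling, which makes
#' it sensitive to overall size.
#'
#' @param exams Data frame with columns `AD`, `AH`, `CRL`, `HL`, `TH`, `TD`
#'   (cm) and optionally `fetus_id`; one row per fetus.
#' @return Numeric vector of products (cm^6), named by `fetus_id` when
#'   present.
#' @export
product_index <- function(exams) {
  req <- c("AD", "AH", "CRL", "HL", "TH", "TD")
  if (is.numeric(exams) && !is.null(names(exams))) exams <- as.data.frame(as.list(exams))
  miss <- setdiff(req, names(exams))
  if (length(miss))
    stop("missing measurement(s): ", paste(miss, collapse = ", "), call. = FALSE)
  for (m in req) {
    v <- exams[[m]]
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)) || any(v <= 0))
      stop(sprintf("measurement %s must be positive and finite", m), call. = FALSE)
  }
  p <- exams$AD * exams$AH * exams$CRL * exams$HL * exams$TH * exams$TD
  if (!is.null(exams$fetus_id)) names(p) <- exams$fetus_id
  p
}

#' Control-derived screening threshold
#'
#' The screening threshold is the maximum product index observed among
#' control (AI) fetuses; IVP fetuses whose product exceeds it are candidate
#' extreme overgrowth cases.
#'
#' @param products Named numeric of product-index values (names = fetus ids).
#' @param labels A `los_labels` object; fetuses labelled `Control-AI` define
#'   the threshold.
#' @return The threshold (cm^6).
#' @export
control_threshold <- function(products, labels) {
  stopifnot(inherits(labels, "los_labels"))
  ctrl <- labels$labels$fetus_id[labels$labels$label == "Control-AI"]
  p <- products[names(products) %in% ctrl]
  if (length(p) == 0L) stop("no control fetuses with an ultrasound exam", call. = FALSE)
  max(p)
}

#' Flag fetuses above a product-index threshold
#'
#' Flagging is strictly greater-than: fetuses on or below the threshold are
#' not flagged.
#'
#' @param products Named numeric of product-index values.
#' @param threshold Positive threshold (cm^6); either the control maximum
#'   from [control_threshold()] or the fixed 100 cm^6 convention.
#' @return Named logical vector of flags.
#' @export
screen_products <- function(products, threshold) {
  check_pos(threshold, "threshold")
  if (length(products) == 0L) return(stats::setNames(logical(0), character(0)))
  products > threshold
}

#' Pearson correlation with exact t-based p-value
#'
#' @param x,y Numeric vectors of equal length (>= 3) with non-zero variance.
#' @return List with `r`, `p` (two-sided, from the t distribution on `n - 2`
#'   df), and `n`.
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y)) bad_field("y", "must have the same length as x")
  if (length(x) < 3L) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Joint fetometry screening report
#'
#' Joins ultrasound product indices with collection weights and LOS labels,
#' derives the control-max (or fixed) threshold, flags fetuses, and reports
#' product-vs-weight correlations per conception group and per sex within
#' group (where at least 3 fetuses are available).
#'
#' @param exams Ultrasound exam data frame (see [product_index()]) with
#'   `fetus_id`.
#' @param fetuses Fetus table with `fetus_id`, `group`, `sex`, `weight_g`.
#' @param labels A `los_labels` object for the same fetuses.
#' @param threshold `"control-max"` (default) or `"fixed"`.
#' @param fixed_threshold Threshold used when `threshold = "fixed"`
#'   (default 100 cm^6, the dashed-line convention).
#' @return List of class `fetometry_report`: `table` (per-fetus product,
#'   threshold, flag), `threshold`, `correlations` (data frame), and
#'   `unmatched` (ids present in only one input).
#' @export
fetometry_report <- function(exams, fetuses, labels,
                             threshold = c("control-max", "fixed"),
                             fixed_threshold = 100) {
  threshold <- match.arg(threshold)
  stopifnot(inherits(labels, "los_labels"))
  if (nrow(exams) == 0L) {
    warning("no ultrasound exams supplied; empty report")
    return(structure(list(table = data.frame(), threshold = NA_real_,
                          correlations = data.frame(), unmatched = character(0)),
                     class = "fetometry_report"))
  }
  p <- product_index(exams)
  unmatched <- union(setdiff(names(p), fetuses$fetus_id),
                     setdiff(fetuses$fetus_id, names(p)))
  if (length(unmatched))
    warning("ids present in only one input: ", paste(unmatched, collapse = ", "))
  common <- intersect(names(p), fetuses$fetus_id)
  fe <- fetuses[match(common, fetuses$fetus_id), ]
  pv <- p[common]
  thr <- if (threshold == "control-max") control_threshold(pv, labels) else check_pos(fixed_threshold, "fixed_threshold")
  tab <- data.frame(fetus_id = common, group = fe$group, sex = fe$sex,
                    weight_g = fe$weight_g, product = unname(pv),
                    threshold = thr, flagged = unname(pv > thr),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$fetus_id), ]
  rownames(tab) <- NULL
  cors <- list()
  strata <- c(lapply(unique(fe$group), function(g) list(name = g, idx = fe$group == g)),
              unlist(lapply(unique(fe$group), function(g)
                lapply(unique(fe$sex), function(s)
                  list(name = paste0(g, ".", s), idx = fe$group == g & fe$sex == s))),
                recursive = FALSE))
  for (st in strata) {
    if (sum(st$idx) >= 3L && stats::sd(pv[st$idx]) > 0 && stats::sd(fe$weight_g[st$idx]) > 0) {
      cc <- correlate(pv[st$idx], fe$weight_g[st$idx])
      cors[[length(cors) + 1L]] <- data.frame(stratum = st$name, r = cc$r, p = cc$p,
                                              n = cc$n, stringsAsFactors = FALSE)
    }
  }
  correlations <- if (length(cors)) do.call(rbind, cors) else data.frame()
  structure(list(table = tab, threshold = thr, correlations = correlations,
                 unmatched = unmatched),
            class = "fetometry_report")
}

#' @export
print.fetometry_report <- function(x, ...) {
  cat(sprintf("Fetometry screen: %d fetuses, threshold %.2f cm^6, %d flagged\n",
              nrow(x$table), x$threshold, sum(x$table$flagged)))
  if (nrow(x$correlations)) {
    cat("Product-vs-weight correlations:\n")
    print(x$correlations, row.names = FALSE)
  }
  invisible(x)
}
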