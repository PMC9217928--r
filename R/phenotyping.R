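#' Sex-specific weight percentile (Hyndman-Fan type 7)
#'
#' Linear-interpolation sample percentile used to derive the overgrowth
#' threshold from control (AI) fetal weights. Follows the type-7 convention
#' (`h = (n - 1) q + 1` on the sorted values), the default of most
#' statistical software.
#'
#' @param values Numeric vector of observations (e.g., control weights, g).
#' @param q Probability in `[0, 1]`; the LOS threshold uses `q = 0.97`.
#' @return The interpolated percentile, a length-one numeric.
#' @examples
#' weight_percentile(1:8, 0.97)  # 7.79
#' @export
weight_percentile <- function(values, q) {
  if (length(values) == 0L) stop("no control fetuses of this sex", call. = FALSE)
  if (!is.numeric(values) || anyNA(values)) bad_field("values", "must be numeric without NA")
  check_prob(q, "q")
  unname(stats::quantile(values, probs = q, type = 7, names = FALSE))
}

#' Classify fetuses as LOS by the 97th-percentile rule
#'
#' A fetus conceived by in vitro production (IVP) is labelled `IVP-LOS` when
#' its weight is greater than or equal to the 97th percentile of the control
#' (AI) weights of the same sex and collection day; lighter IVP fetuses are
#' `IVP-Normal` and AI fetuses are always `Control-AI`. Thresholds are
#' computed per sex and never pooled across collection days.
#'
#' @param fetuses Data frame with columns `fetus_id`, `group` (`"AI"` or
#'   `"IVP"`), `sex` (`"M"`/`"F"`), `day`, `weight_g`. All rows must share one
#'   collection day.
#' @param thresholds Optional named numeric (`M`, `F`) of externally supplied
#'   thresholds in grams (e.g., the published study values); when `NULL` they
#'   are computed from the AI weights via [weight_percentile()].
#' @param q Percentile defining overgrowth (default 0.97).
#' @return An object of class `los_labels`: a list with `thresholds` (named
#'   numeric, grams) and `labels` (data frame `fetus_id`, `group`, `sex`,
#'   `weight_g`, `label`).
#' @export
classify_los <- function(fetuses, thresholds = NULL, q = 0.97) {
  req <- c("fetus_id", "group", "sex", "day", "weight_g")
  miss <- setdiff(req, names(fetuses))
  if (length(miss)) bad_field("fetuses", paste("missing columns:", paste(miss, collapse = ", ")))
  if (length(unique(fetuses$day)) > 1L)
    stop("fetuses span multiple collection days; classify each day separately", call. = FALSE)
  if (!all(fetuses$group %in% c("AI", "IVP"))) bad_field("group", "must be 'AI' or 'IVP'")
  check_pos(fetuses$weight_g, "weight_g")
  sexes <- sort(unique(fetuses$sex))
  if (is.null(thresholds)) {
    thresholds <- vapply(sexes, function(s) {
      w <- fetuses$weight_g[fetuses$group == "AI" & fetuses$sex == s]
      if (length(w) == 0L)
        stop(sprintf("no control fetuses of sex %s", s), call. = FALSE)
      weight_percentile(w, q)
    }, numeric(1))
  } else {
    if (is.null(names(thresholds)) || !all(sexes %in% names(thresholds)))
      bad_field("thresholds", "must be named with an entry per sex present")
    check_pos(thresholds, "thresholds")
    thresholds <- thresholds[sexes]
  }
  label <- ifelse(fetuses$group == "AI", "Control-AI",
                  ifelse(fetuses$weight_g >= thresholds[fetuses$sex], "IVP-LOS", "IVP-Normal"))
  out <- list(
    thresholds = thresholds,
    labels = data.frame(fetus_id = fetuses$fetus_id, group = fetuses$group,
                        sex = fetuses$sex, weight_g = fetuses$weight_g,
                        label = label, stringsAsFactors = FALSE)
  )
  class(out) <- "los_labels"
  out
}

#' @export
print.los_labels <- function(x, ...) {
  cat("LOS classification\n")
  cat("  thresholds (g):", paste(sprintf("%s = %.2f", names(x$thresholds), x$thresholds), collapse = ", "), "\n")
  tab <- table(x$labels$label)
  cat("  labels:", paste(sprintf("%s = %d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' LOS prevalence among IVP fetuses
#'
#' @param labels A `los_labels` object from [classify_los()].
#' @return Fraction of IVP fetuses labelled `IVP-LOS`, in `[0, 1]`.
#' @export
los_prevalence <- function(labels) {
  stopifnot(inherits(labels, "los_labels"))
  ivp <- labels$labels$group == "IVP"
  if (!any(ivp)) stop("no IVP fetuses; prevalence undefined", call. = FALSE)
  sum(labels$labels$label[ivp] == "IVP-LOS") / sum(ivp)
}

#' Exact one-sided binomial test for female deficiency
#'
#' Compares an observed female count to the expected 1:1 sex ratio with the
#' exact lower-tail binomial probability
#' `p = sum_{k<=n_female} C(n, k) (1/2)^n` (no normal approximation); the
#' one-sided deficiency direction asks whether females are under-represented.
#'
#' @param n_female Number of female fetuses observed.
#' @param n_total Total number of fetuses.
#' @return A list of class `sex_ratio_result` with `n_female`, `n_total`,
#'   `p_value`, `null_prob = 0.5`.
#' @examples
#' sex_ratio_test(4, 12)$p_value  # 794/4096
#' @export
sex_ratio_test <- function(n_female, n_total) {
  n_female <- check_count(n_female, "n_female")
  n_total <- check_count(n_total, "n_total", min = 1L)
  if (n_female > n_total) bad_field("n_female", "cannot exceed n_total")
  p <- stats::pbinom(n_female, n_total, 0.5)
  structure(list(n_female = n_female, n_total = n_total,
                 p_value = p, null_prob = 0.5),
            class = "sex_ratio_result")
}

#' @export
print.sex_ratio_result <- function(x, ...) {
  cat(sprintf("Exact binomial sex-ratio test: %d females of %d (p = %.4g, one-sided vs 1:1)\n",
              x$n_female, x$n_total, x$p_value))
  invisible(x)
}

#' Umbilicus-to-crown-rump-length ratio from calibrated image measurements
#'
#' Pixel lengths traced on a lateral photograph are converted to centimetres
#' using the gridded surface the fetus lies on (each square is 2.54 cm); the
#' calibration cancels in the ratio.
#'
#' @param square_side_px Side of one calibration square, pixels.
#' @param umbilicus_px Umbilicus base diameter, pixels.
#' @param crl_px Crown-rump length, pixels.
#' @param square_cm Physical side of a calibration square (default 2.54 cm).
#' @return List with `scale` (cm/pixel), `umbilicus_cm`, `crl_cm`, `ratio`.
#' @export
umbilicus_ratio <- function(square_side_px, umbilicus_px, crl_px, square_cm = 2.54) {
  check_pos(square_side_px, "square_side_px")
  check_pos(umbilicus_px, "umbilicus_px")
  check_pos(crl_px, "crl_px")
  check_pos(square_cm, "square_cm")
  scale <- square_cm / square_side_px
  u <- umbilicus_px * scale
  crl <- crl_px * scale
  list(scale = scale, umbilicus_cm = u, crl_cm = crl, ratio = u / crl)
}
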