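# Case-control association of haplogroups and mtSNPs: odds ratios with
# Woolf confidence intervals, Pearson chi-square with Fisher fallback, and
# the per-factor screen.

as_2x2 <- function(table) {
  if (is.matrix(table)) {
    stopifnot(all(dim(table) == c(2L, 2L)))
    c(a = table[1, 1], b = table[1, 2], c = table[2, 1], d = table[2, 2])
  } else {
    stopifnot(length(table) == 4L)
    structure(as.numeric(table), names = c("a", "b", "c", "d"))
  }
}

#' Odds ratio with Woolf 95% confidence interval
#'
#' OR = (a/b)/(c/d) for the table (a, b; c, d) of exposed/unexposed cases
#' over exposed/unexposed controls; CI = exp(ln OR +/- 1.96 sqrt(1/a +
#' 1/b + 1/c + 1/d)).  When any cell is zero the Haldane-Anscombe
#' correction (+0.5 to every cell) is applied and flagged.  Two zero
#' cells in the same margin leave the OR undefined and error.
#'
#' @param table 2x2 matrix or length-4 vector \code{c(a, b, c, d)}.
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble: \code{or}, \code{ci_low}, \code{ci_high},
#'   \code{corrected}.
#' @export
odds_ratio_ci <- function(table, conf_level = 0.95) {
  t0 <- as_2x2(table)
  if (any(t0 < 0)) stop("negative cell counts")
  if ((t0["a"] == 0 && t0["c"] == 0) || (t0["b"] == 0 && t0["d"] == 0) ||
      (t0["a"] == 0 && t0["b"] == 0) || (t0["c"] == 0 && t0["d"] == 0))
    stop("two zero cells in the same margin: odds ratio undefined")
  corrected <- any(t0 == 0)
  t1 <- if (corrected) t0 + 0.5 else t0
  or <- (t1["a"] / t1["b"]) / (t1["c"] / t1["d"])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(sum(1 / t1))
  tibble::tibble(or = unname(or),
                 ci_low = unname(exp(log(or) - z * se)),
                 ci_high = unname(exp(log(or) + z * se)),
                 corrected = corrected)
}

#' Pearson chi-square test with automatic Fisher fallback
#'
#' Pearson statistic without continuity correction (df = 1); when any
#' expected count falls below 5 the two-sided Fisher exact test is used
#' instead and the method recorded.  A zero margin is an error.
#'
#' @param table 2x2 matrix or length-4 vector \code{c(a, b, c, d)}.
#' @param method \code{"auto"} (default), or force \code{"chisq"} /
#'   \code{"fisher"}.
#' @return List with \code{statistic} (NA for Fisher), \code{p_value},
#'   \code{method}, \code{expected}.
#' @export
chi_square_test <- function(table, method = c("auto", "chisq", "fisher")) {
  method <- match.arg(method)
  t0 <- as_2x2(table)
  m <- matrix(t0, 2L, 2L, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("zero margin in contingency table")
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (method == "auto")
    method <- if (any(expected < 5) || any(t0 == 0)) "fisher" else "chisq"
  if (method == "fisher") {
    p <- stats::fisher.test(m)$p.value
    return(list(statistic = NA_real_, p_value = p, method = "fisher",
                expected = expected))
  }
  ct <- stats::chisq.test(m, correct = FALSE)
  list(statistic = unname(ct$statistic), p_value = ct$p.value,
       method = "chi-square", expected = expected)
}

#' Screen factors for case-control association
#'
#' Builds one 2x2 carrier table per factor (presence/absence of a
#' haplogroup label or variant label per individual), computes OR with
#' 95% CI and the chi-square/Fisher p-value, and sorts by p.  The default
#' significance threshold is 0.05 with no multiplicity correction; a
#' Benjamini-Hochberg column is provided alongside.  Factors carried by
#' nobody are skipped with a note.
#'
#' @param case_sets,control_sets Lists of per-individual character
#'   vectors (variant labels and/or haplogroup names).
#' @param factors Character vector of factor labels to screen.
#' @param alpha Significance threshold (default 0.05).
#' @return Tibble: \code{factor}, counts, \code{or}, \code{ci_low},
#'   \code{ci_high}, \code{corrected}, \code{p_value}, \code{method},
#'   \code{significant}, \code{p_bh}, plus a \code{"skipped"} attribute.
#' @export
screen_factors <- function(case_sets, control_sets, factors, alpha = 0.05) {
  rows <- list(); skipped <- character(0)
  n_case <- length(case_sets); n_control <- length(control_sets)
  for (f in factors) {
    a <- sum(vapply(case_sets, function(s) f %in% s, logical(1)))
    c_ <- sum(vapply(control_sets, function(s) f %in% s, logical(1)))
    if (a + c_ == 0L) { skipped <- c(skipped, f); next }
    tab <- c(a, n_case - a, c_, n_control - c_)
    orr <- odds_ratio_ci(tab)
    tst <- chi_square_test(tab)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      factor = f, case_carriers = a, case_total = n_case,
      control_carriers = c_, control_total = n_control,
      or = orr$or, ci_low = orr$ci_low, ci_high = orr$ci_high,
      corrected = orr$corrected, p_value = tst$p_value, method = tst$method)
  }
  if (!length(rows)) {
    res <- tibble::tibble(factor = character(0))
    attr(res, "skipped") <- skipped
    return(res)
  }
  res <- do.call(rbind, rows)
  res$significant <- res$p_value < alpha
  res$p_bh <- stats::p.adjust(res$p_value, method = "BH")
  res <- res[order(res$p_value), ]
  attr(res, "skipped") <- skipped
  res
}
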