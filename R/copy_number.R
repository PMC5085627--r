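# Relative mtDNA copy number from qPCR Ct tables (mtDNA target vs nuclear
# 18S reference) and the cohort-level comparison.

#' Read a qPCR Ct table
#'
#' CSV with columns \code{sample_id,tissue,target,ct1,ct2,ct3}
#' (\code{target} is \code{mt} or \code{nuclear}; fewer than 3 replicate
#' columns are allowed).  Replicate Ct values must lie in 10..40 cycles.
#'
#' @param path CSV path.
#' @return Tibble with per-record \code{mean_ct} and \code{sd_ct}.
#' @export
read_ct_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "tissue", "target") %in% names(df)))
  reps <- grep("^ct\\d+$", names(df), value = TRUE)
  if (!length(reps)) stop("no replicate Ct columns (ct1, ct2, ...)")
  m <- as.matrix(df[reps])
  if (any(m < 10 | m > 40, na.rm = TRUE))
    stop("replicate Ct outside 10..40 cycles")
  df$mean_ct <- rowMeans(m, na.rm = TRUE)
  df$sd_ct <- apply(m, 1L, stats::sd, na.rm = TRUE)
  tibble::as_tibble(df)
}

#' Relative mtDNA content of one sample
#'
#' Default is the ideal-efficiency delta-Ct model: content =
#' 2^(mean Ct_nuclear - mean Ct_mt).  With explicit amplification
#' efficiencies (e.g. from a standard curve, E = 10^(-1/slope)) the ratio
#' form E_nuc^Ct_nuc / E_mt^Ct_mt is used, which reduces to the default
#' at E = 2.  A replicate SD above 0.5 cycles triggers a warning.
#'
#' @param ct_mt,ct_nuc One-row Ct records for the same sample
#'   (mt target / nuclear reference).
#' @param efficiency Length-2 numeric \code{c(mt = , nuclear = )},
#'   default both 2.
#' @return One-row tibble with \code{sample_id}, \code{tissue},
#'   \code{relative_content}.
#' @export
relative_content <- function(ct_mt, ct_nuc, efficiency = c(mt = 2, nuclear = 2)) {
  if (ct_mt$sample_id != ct_nuc$sample_id)
    stop("mismatched sample ids: ", ct_mt$sample_id, " vs ", ct_nuc$sample_id)
  if (any(c(ct_mt$sd_ct, ct_nuc$sd_ct) > 0.5, na.rm = TRUE))
    warning("replicate SD > 0.5 cycles for sample ", ct_mt$sample_id)
  content <- efficiency[["nuclear"]]^ct_nuc$mean_ct / efficiency[["mt"]]^ct_mt$mean_ct
  tibble::tibble(sample_id = ct_mt$sample_id, tissue = ct_mt$tissue,
                 relative_content = content)
}

#' Tumor/normal copy-number fold change
#'
#' @param tumor,normal One-row results of \code{\link{relative_content}}
#'   for the same subject.
#' @return Fold-change ratio (tumor/normal); "increased" means ratio > 1.
#' @export
fold_change <- function(tumor, normal) {
  if (is.null(normal) || !nrow(normal) || !is.finite(normal$relative_content) ||
      normal$relative_content <= 0)
    stop("normal content absent or non-positive")
  tumor$relative_content / normal$relative_content
}

#' Two-sided Mann-Whitney U comparison of two groups
#'
#' Computes the U statistic from midranks.  When both groups have at most
#' \code{exact_max} observations and there are no ties, the exact null
#' distribution of U is used; otherwise the tie-corrected normal
#' approximation (no continuity correction).  A paired Wilcoxon
#' signed-rank alternative is available but is not the default (the
#' standard cohort comparison treats the groups as independent).
#'
#' @param x,y Numeric vectors (e.g. tumor and normal relative contents),
#'   each with at least 2 values.
#' @param paired Use the paired signed-rank test instead.
#' @param exact_max Group-size bound for the exact path (default 10).
#' @return List with \code{statistic} (U of group x), \code{p_value},
#'   \code{method}.
#' @export
cohort_compare <- function(x, y, paired = FALSE, exact_max = 10L) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 observations")
  if (paired) {
    wt <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = FALSE)
    return(list(statistic = unname(wt$statistic), p_value = wt$p.value,
                method = "wilcoxon-signed-rank"))
  }
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (!ties && n1 <= exact_max && n2 <= exact_max) {
    p <- 2 * min(stats::pwilcox(u, n1, n2),
                 stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE))
    return(list(statistic = u, p_value = min(1, p), method = "exact"))
  }
  n <- n1 + n2
  tt <- table(c(x, y))
  tie_term <- sum(tt^3 - tt) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  z <- (u - n1 * n2 / 2) / sqrt(sigma2)
  list(statistic = u, p_value = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal-approximation")
}
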