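# Rule-based pathogenicity classification: novelty lookup, candidate
# filters (population frequency, tissue specificity, conservation),
# per-program binarization and the >= 4-of-7 majority vote, and the final
# pathogenic set (all nonsense + all frameshift + voted non-synonymous
# candidates).

PREDICTOR_VOCAB <- list(
  polyphen2 = c("Probably", "Possibly", "Benign"),
  sift = c("NotTolerated", "Tolerated"),
  mutation_assessor = c("High", "Medium", "Low", "Neutral"),
  provean = c("Deleterious", "Neutral"),
  snp_and_go = c("Disease", "Neutral"),
  align_gvgd = c("C65", "C55", "C45", "C35", "C25", "C15", "C0")
)

PREDICTORS <- c(names(PREDICTOR_VOCAB), "panther_pdel")

#' Is a variant absent from the local catalog?
#'
#' Novelty is evaluated against a local catalog snapshot (TSV with a
#' \code{label} column); a variant is novel iff its canonical label is
#' absent.
#'
#' @param label Canonical variant label (or vector of labels).
#' @param catalog Catalog tibble from \code{\link{read_catalog}} (possibly
#'   zero rows).
#' @return Logical vector.
#' @export
is_novel <- function(label, catalog) {
  !label %in% catalog$label
}

#' Read a variant-catalog snapshot
#' @param path TSV with at least a \code{label} column.
#' @return Tibble.
#' @export
read_catalog <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"label" %in% names(df)) stop("catalog needs a 'label' column")
  tibble::as_tibble(df)
}

#' Candidate filters for potential pathogenicity
#'
#' A variant is a candidate when (1) it is carried by fewer than 1% of the
#' healthy control cohort (a frequency of exactly 1% or more marks a
#' polymorphism), (2) it is absent from the normal thyroid samples
#' (otherwise tissue-specific), and (3) the altered residue or nucleotide
#' is highly conserved (CI > 75%).  A missing CI fails criterion (3).
#'
#' @param context Tibble/list with \code{control_count},
#'   \code{control_total}, \code{normal_thyroid_count}, \code{ci_percent}.
#' @param ci_cutoff Conservation cutoff (default 75).
#' @param freq_cutoff Polymorphism frequency cutoff (default 0.01).
#' @return List with \code{candidate} flag and \code{reasons} character
#'   vector auditing every rule outcome.
#' @export
passes_candidate_filters <- function(context, ci_cutoff = 75,
                                     freq_cutoff = 0.01) {
  reasons <- character(0)
  freq <- context$control_count / context$control_total
  ok_freq <- is.finite(freq) && freq < freq_cutoff
  reasons <- c(reasons, if (ok_freq)
    sprintf("control frequency %.2f%% < %.0f%%", 100 * freq, 100 * freq_cutoff)
    else sprintf("polymorphism: control frequency %.2f%% >= %.0f%%",
                 100 * freq, 100 * freq_cutoff))
  ok_tissue <- context$normal_thyroid_count == 0L
  reasons <- c(reasons, if (ok_tissue) "absent in normal thyroid"
               else "tissue-specific: present in normal thyroid")
  if (is.null(context$ci_percent) || is.na(context$ci_percent)) {
    ok_ci <- FALSE
    reasons <- c(reasons, "CI unavailable")
  } else {
    ok_ci <- context$ci_percent > ci_cutoff
    reasons <- c(reasons, sprintf("CI %.2f%% %s %.0f%%", context$ci_percent,
                                  if (ok_ci) ">" else "<=", ci_cutoff))
  }
  list(candidate = ok_freq && ok_tissue && ok_ci, reasons = reasons)
}

#' Binarize one predictor output into a deleterious vote
#'
#' Deleterious iff: PolyPhen-2 Probably or Possibly damaging; SIFT not
#' tolerated; MutationAssessor High, Medium or Low functional impact;
#' Provean deleterious; SNP&GO disease; Align-GVGD class C65 (only the
#' highest class); PANTHER P(deleterious) > 0.5.  \code{NA} never votes.
#' Unknown vocabulary values are an error naming the offending token.
#'
#' @param program One of \code{polyphen2}, \code{sift},
#'   \code{mutation_assessor}, \code{provean}, \code{snp_and_go},
#'   \code{align_gvgd}, \code{panther_pdel}.
#' @param value The program's output (character, or numeric for PANTHER).
#' @return Logical: vote deleterious?
#' @export
binarize_predictor <- function(program, value) {
  program <- match.arg(program, PREDICTORS)
  if (is.null(value) || (length(value) == 1L && is.na(value))) return(FALSE)
  if (program == "panther_pdel") {
    value <- as.numeric(value)
    if (is.na(value)) return(FALSE)
    return(value > 0.5)
  }
  vocab <- PREDICTOR_VOCAB[[program]]
  hit <- match(tolower(value), tolower(vocab))
  if (is.na(hit))
    stop("unknown ", program, " value: '", value, "'")
  value <- vocab[hit]
  switch(program,
    polyphen2 = value %in% c("Probably", "Possibly"),
    sift = value == "NotTolerated",
    mutation_assessor = value %in% c("High", "Medium", "Low"),
    provean = value == "Deleterious",
    snp_and_go = value == "Disease",
    align_gvgd = value == "C65")
}

#' Seven-program majority vote
#'
#' Counts deleterious votes over all seven programs and flags the variant
#' pathogenic-by-vote when at least 4 vote deleterious -- a strict
#' majority of 7, with a fixed denominator even when some programs return
#' \code{NA}.
#'
#' @param profile One-row tibble/list with the seven predictor fields.
#' @param vote_threshold Votes needed for a pathogenic call (default 4).
#' @return List with \code{votes_deleterious} and \code{vote_pathogenic}.
#' @export
majority_vote <- function(profile, vote_threshold = 4L) {
  votes <- sum(vapply(PREDICTORS, function(p)
    binarize_predictor(p, profile[[p]]), logical(1)))
  list(votes_deleterious = votes, vote_pathogenic = votes >= vote_threshold)
}

#' Full pathogenicity classification
#'
#' Combines consequence category, candidate filters and the majority
#' vote: nonsense and frameshift coding mutations are pathogenic
#' unconditionally; non-synonymous substitutions are pathogenic iff they
#' pass the candidate filters and the vote; everything else is not
#' pathogenic.  A non-synonymous candidate with no predictor profile is
#' left undetermined.
#'
#' @param consequences Tibble with \code{label} and \code{category}
#'   (\code{nonsense}/\code{frameshift}/\code{non-synonymous}/...).
#' @param contexts Tibble keyed by \code{label} with the candidate-filter
#'   fields (\code{control_count}, \code{control_total},
#'   \code{normal_thyroid_count}, \code{ci_percent}); may be missing rows
#'   for truncating mutations.
#' @param profiles Tibble keyed by \code{label} with the seven predictor
#'   columns.
#' @param vote_threshold Votes needed (default 4 of 7).
#' @param ci_cutoff,freq_cutoff Candidate-filter thresholds.
#' @return Verdict tibble: \code{label}, \code{category},
#'   \code{candidate}, \code{votes_deleterious}, \code{vote_pathogenic},
#'   \code{final_pathogenic}, \code{reasons}.
#' @export
classify_pathogenic <- function(consequences, contexts = NULL,
                                profiles = NULL, vote_threshold = 4L,
                                ci_cutoff = 75, freq_cutoff = 0.01) {
  out <- lapply(seq_len(nrow(consequences)), function(i) {
    cq <- consequences[i, ]
    row <- tibble::tibble(label = cq$label, category = cq$category,
                          candidate = NA, votes_deleterious = NA_integer_,
                          vote_pathogenic = NA, final_pathogenic = FALSE,
                          reasons = "")
    if (cq$category %in% c("nonsense", "frameshift")) {
      row$final_pathogenic <- TRUE
      row$reasons <- "truncating mutation: pathogenic unconditionally"
      return(row)
    }
    if (cq$category != "non-synonymous") {
      row$reasons <- paste0("category ", cq$category, ": not eligible")
      return(row)
    }
    ctx <- if (!is.null(contexts)) contexts[contexts$label == cq$label, ] else NULL
    if (is.null(ctx) || nrow(ctx) == 0L) {
      row$candidate <- FALSE
      row$reasons <- "no candidate context supplied"
      return(row)
    }
    flt <- passes_candidate_filters(ctx[1L, ], ci_cutoff, freq_cutoff)
    row$candidate <- flt$candidate
    if (!flt$candidate) {
      row$reasons <- paste(flt$reasons, collapse = "; ")
      return(row)
    }
    prof <- if (!is.null(profiles)) profiles[profiles$label == cq$label, ] else NULL
    if (is.null(prof) || nrow(prof) == 0L) {
      row$final_pathogenic <- NA
      row$reasons <- "candidate but predictor profile missing: undetermined"
      return(row)
    }
    mv <- majority_vote(prof[1L, ], vote_threshold)
    row$votes_deleterious <- mv$votes_deleterious
    row$vote_pathogenic <- mv$vote_pathogenic
    row$final_pathogenic <- mv$vote_pathogenic
    row$reasons <- paste(c(flt$reasons,
                           sprintf("%d of 7 programs deleterious", mv$votes_deleterious)),
                         collapse = "; ")
    row
  })
  do.call(rbind, out)
}

#' Read a predictor-output table
#'
#' TSV mirroring the seven-program column layout
#' (\code{label polyphen2 sift mutation_assessor provean snp_and_go
#' align_gvgd panther_pdel}, extra columns kept).  Categorical values are
#' case-normalized on ingestion; empty strings and \code{"NA"} become
#' \code{NA}.
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_predictor_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  stopifnot("label" %in% names(df))
  for (p in names(PREDICTOR_VOCAB)) {
    if (!p %in% names(df)) next
    vocab <- PREDICTOR_VOCAB[[p]]
    idx <- match(tolower(df[[p]]), tolower(vocab))
    bad <- !is.na(df[[p]]) & is.na(idx)
    if (any(bad))
      stop("unknown ", p, " value: '", df[[p]][which(bad)[1L]], "'")
    df[[p]] <- vocab[idx]
  }
  if ("panther_pdel" %in% names(df))
    df$panther_pdel <- as.numeric(df$panther_pdel)
  tibble::as_tibble(df)
}
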