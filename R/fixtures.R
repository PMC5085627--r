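# Bundled example tables from a whole-mtDNA characterization of a
# papillary thyroid carcinoma cohort (66 tumor/normal pairs, 16 normal
# thyroid tissues, 376 blood controls).  Variant labels use this
# package's canonical notation.

#' Novel-variant example table
#'
#' The 33 cohort variants absent from the reference catalog: 7 RNA-region
#' and 26 protein-region entries, with conservation index (percent of 41
#' primates carrying the human wild-type symbol), carrier counts and
#' zygosity.
#'
#' @return Tibble, one row per variant.
#' @export
novel_variant_fixture <- function() {
  tibble::tribble(
    ~label, ~gene, ~region, ~change, ~ci_percent, ~n_case, ~n_control, ~zygosity,
    "A1629T", "tRNA-Val", "rna", "A-U pair abolished", 24.4, 1L, 0L, "homoplasmic",
    "A2274G", "16S-rRNA", "rna", NA, 100, 1L, 0L, "heteroplasmic",
    "3275-3276delCA", "tRNA-Leu(UUR)", "rna", NA, NA, 1L, 0L, "heteroplasmic",
    "T4272C", "tRNA-Ile", "rna", "A-U pair abolished", 100, 1L, 0L, "homoplasmic",
    "5835insT", "tRNA-Tyr", "rna", NA, NA, 1L, 0L, "homoplasmic",
    "G5881C", "tRNA-Tyr", "rna", "C-G pair abolished", 100, 1L, 0L, "homoplasmic",
    "C10040A", "tRNA-Gly", "rna", NA, 43.9, 1L, 0L, "homoplasmic",
    "4520-4521delAC", "ND2", "protein", NA, NA, 1L, 0L, "homoplasmic",
    "C4875T", "ND2", "protein", "Leu->Leu", 100, 1L, 0L, "homoplasmic",
    "G4969A", "ND2", "protein", "Trp->Ter", 100, 1L, 0L, "homoplasmic",
    "G4971A", "ND2", "protein", "Gly->Ser", 100, 1L, 0L, "homoplasmic",
    "G5977A", "COI", "protein", "Trp->Ter", 100, 1L, 0L, "heteroplasmic",
    "T6238C", "COI", "protein", "Leu->Pro", 100, 1L, 0L, "heteroplasmic",
    "T7104C", "COI", "protein", "Ser->Pro", 100, 1L, 0L, "heteroplasmic",
    "C7750A", "COII", "protein", "Ile->Met", 58.5, 1L, 0L, "homoplasmic",
    "G7928A", "COII", "protein", "Gly->Ter", 56.1, 1L, 0L, "homoplasmic",
    "G9253A", "COIII", "protein", "Trp->Ter", 100, 1L, 0L, "heteroplasmic",
    "G10521A", "ND4L", "protein", "Gly->Ter", 100, 1L, 0L, "homoplasmic",
    "C10622T", "ND4L", "protein", "Thr->Thr", 36.6, 1L, 0L, "homoplasmic",
    "11646insT", "ND4", "protein", NA, NA, 1L, 0L, "homoplasmic",
    "11673-11677:C5-4", "ND4", "protein", NA, NA, 1L, 0L, "heteroplasmic",
    "11673-11677:C5-6", "ND4", "protein", NA, NA, 1L, 0L, "homoplasmic",
    "T12794A", "ND5", "protein", "Leu->Ter", 100, 1L, 0L, "heteroplasmic",
    "12858insT", "ND5", "protein", NA, NA, 1L, 0L, "heteroplasmic",
    "C12943T", "ND5", "protein", "Leu->Phe", 24.4, 1L, 0L, "heteroplasmic",
    "13128-13132:C5-4", "ND5", "protein", NA, NA, 1L, 0L, "homoplasmic",
    "13170delA", "ND5", "protein", NA, NA, 1L, 0L, "homoplasmic",
    "C13621T", "ND5", "protein", "Leu->Phe", 51.2, 1L, 0L, "homoplasmic",
    "G13825A", "ND5", "protein", "Gly->Ter", 100, 1L, 0L, "homoplasmic",
    "C14310A", "ND6", "protein", "Gly->Trp", 70.7, 1L, 0L, "heteroplasmic",
    "14495-14502:AAAT2-1", "ND6", "protein", NA, NA, 1L, 0L, "homoplasmic",
    "C14774A", "Cytb", "protein", "Leu->Ile", 63.4, 1L, 0L, "heteroplasmic",
    "T15018A", "Cytb", "protein", "Phe->Tyr", 100, 1L, 0L, "heteroplasmic"
  )
}

#' Truncating-mutation example table
#'
#' The 18 protein-region truncating mutations of the cohort: 7 nonsense
#' substitutions and 11 frameshift indels, with catalog status.
#'
#' @return Tibble.
#' @export
truncating_mutation_fixture <- function() {
  tibble::tribble(
    ~label, ~gene, ~class, ~reported, ~zygosity,
    "G4969A", "ND2", "nonsense", FALSE, "homoplasmic",
    "G5977A", "COI", "nonsense", FALSE, "heteroplasmic",
    "G7928A", "COII", "nonsense", FALSE, "homoplasmic",
    "G9253A", "COIII", "nonsense", FALSE, "heteroplasmic",
    "G10521A", "ND4L", "nonsense", FALSE, "homoplasmic",
    "T12794A", "ND5", "nonsense", FALSE, "heteroplasmic",
    "G13825A", "ND5", "nonsense", FALSE, "homoplasmic",
    "4520-4521delAC", "ND2", "frameshift", FALSE, "homoplasmic",
    "10952insC", "ND4", "frameshift", TRUE, "homoplasmic",
    "11032-11038:A7-6", "ND4", "frameshift", TRUE, "mixed",
    "11646insT", "ND4", "frameshift", FALSE, "homoplasmic",
    "11673-11677:C5-4", "ND4", "frameshift", FALSE, "heteroplasmic",
    "11673-11677:C5-6", "ND4", "frameshift", FALSE, "homoplasmic",
    "12418-12425:A8-7", "ND5", "frameshift", TRUE, "heteroplasmic",
    "12858insT", "ND5", "frameshift", FALSE, "heteroplasmic",
    "13128-13132:C5-4", "ND5", "frameshift", FALSE, "homoplasmic",
    "13170delA", "ND5", "frameshift", FALSE, "homoplasmic",
    "14495-14502:AAAT2-1", "ND6", "frameshift", FALSE, "homoplasmic"
  )
}

#' Predictor-profile example table
#'
#' The candidate non-synonymous substitutions that passed the frequency
#' and conservation filters, with the outputs of the seven pathogenicity
#' predictors as published (\code{NA} where a program returned no call)
#' and the cohort/control carrier counts used by the candidate filters.
#'
#' @return Tibble, one row per candidate variant.
#' @export
predictor_profile_fixture <- function() {
  tibble::tribble(
    ~label, ~gene, ~aa_change, ~ci_percent, ~reported, ~n_case,
    ~n_thyroid, ~n_control, ~polyphen2, ~sift, ~mutation_assessor,
    ~provean, ~snp_and_go, ~align_gvgd, ~panther_pdel,
    "G3392A", "ND1", "Gly->Asp", 100, TRUE, 1L, 0L, 0L,
    "Probably", "NotTolerated", "High", "Deleterious", "Disease", "C65", NA,
    "T3644C", "ND1", "Val->Ala", 97.60, TRUE, 1L, 0L, 2L,
    "Benign", "NotTolerated", "Medium", "Deleterious", "Neutral", "C65", 0.29125,
    "T3679C", "ND1", "Ser->Pro", 100, TRUE, 1L, 0L, 0L,
    "Probably", "NotTolerated", "High", "Deleterious", "Disease", "C65", 0.74261,
    "G3745A", "ND1", "Ala->Thr", 92.70, TRUE, 1L, 0L, 0L,
    "Benign", "NotTolerated", "Low", "Neutral", "Neutral", "C55", 0.21113,
    "G4971A", "ND2", "Gly->Ser", 100, FALSE, 1L, 0L, 0L,
    "Probably", "NotTolerated", "Medium", "Deleterious", "Neutral", "C55", 0.36251,
    "T6238C", "COI", "Leu->Pro", 100, FALSE, 1L, 0L, 0L,
    "Probably", "NotTolerated", "High", "Deleterious", "Disease", "C65", 0.87509,
    "C6340T", "COI", "Thr->Ile", 82.90, TRUE, 1L, 0L, 0L,
    "Benign", "NotTolerated", "Medium", "Neutral", "Neutral", "C65", 0.21096,
    "T6681C", "COI", "Tyr->His", 85.40, TRUE, 1L, 0L, 0L,
    "Benign", "Tolerated", "Neutral", "Neutral", "Neutral", "C65", 0.32881,
    "T7104C", "COI", "Ser->Pro", 100, FALSE, 1L, 0L, 0L,
    "Possibly", "NotTolerated", "Neutral", "Neutral", "Disease", "C65", 0.5134,
    "T7329C", "COI", "Phe->Leu", 100, FALSE, 1L, 0L, 0L,
    "Benign", "Tolerated", "Low", "Neutral", "Neutral", "C15", 0.16379,
    "G8156A", "COII", "Val->Met", 75.61, FALSE, 1L, 0L, 0L,
    "Probably", "NotTolerated", "Medium", "Neutral", "Neutral", "C15", 0.53442,
    "G8989A", "ATP6", "Ala->Thr", 100, TRUE, 1L, 0L, 0L,
    "Probably", "NotTolerated", "Low", "Deleterious", "Neutral", "C55", 0.47286,
    "T9187C", "ATP6", "Tyr->His", 100, TRUE, 1L, 0L, 0L,
    "Probably", "NotTolerated", "High", "Deleterious", "Disease", "C65", NA,
    "A9355G", "COIII", "Asn->Ser", 82.90, TRUE, 1L, 0L, 0L,
    "Benign", "Tolerated", "Neutral", "Neutral", "Neutral", "C45", 0.14014,
    "G10573A", "ND4L", "Gly->Glu", 97.60, TRUE, 1L, 0L, 0L,
    "Probably", "NotTolerated", "High", "Deleterious", "Neutral", "C65", 0.40946,
    "A12850G", "ND5", "Ile->Val", 90.20, TRUE, 1L, 0L, 0L,
    "Possibly", "Tolerated", "Neutral", "Neutral", "Neutral", "C25", 0.50297,
    "A13535G", "ND5", "Asn->Ser", 87.80, TRUE, 1L, 0L, 0L,
    "Benign", "NotTolerated", "Low", "Deleterious", "Neutral", "C45", NA,
    "A13748G", "ND5", "Asn->Ser", 85.40, TRUE, 1L, 0L, 0L,
    "Benign", "Tolerated", "Neutral", "Neutral", "Neutral", "C45", 0.5082,
    "C14310A", "ND6", "Gly->Trp", 78.05, FALSE, 1L, 0L, 0L,
    "Probably", "NotTolerated", "Medium", "Deleterious", "Disease", "C65", 0.71527,
    "T14463C", "ND6", "Thr->Ala", 90.20, TRUE, 1L, 0L, 0L,
    "Benign", "Tolerated", "Neutral", "Deleterious", "Neutral", "C55", 0.15283,
    "T15018A", "Cytb", "Phe->Tyr", 100, FALSE, 1L, 0L, 0L,
    "Possibly", "NotTolerated", "High", "Deleterious", "Disease", "C15", 0.68543,
    "G15045A", "Cytb", "Arg->Gln", 100, TRUE, 1L, 0L, 0L,
    "Probably", "NotTolerated", "High", "Deleterious", "Disease", "C35", 0.59378,
    "T15090C", "Cytb", "Ile->Thr", 85.40, TRUE, 1L, 0L, 1L,
    "Possibly", "Tolerated", "Low", "Deleterious", "Neutral", "C65", 0.42865,
    "T15479C", "Cytb", "Phe->Leu", 80.50, TRUE, 1L, 0L, 0L,
    "Benign", "Tolerated", "Low", "Deleterious", "Neutral", "C15", 0.39962,
    "C15483T", "Cytb", "Ser->Leu", 80.50, TRUE, 1L, 0L, 0L,
    "Possibly", "Tolerated", "Low", "Deleterious", "Neutral", "C65", 0.45816
  )
}

#' Path of a bundled fixture file
#' @param file File name under \code{inst/extdata}.
#' @return Absolute path.
#' @export
mitovar_extdata <- function(file) {
  p <- system.file("extdata", file, package = "mitovar", mustWork = FALSE)
  if (!nzchar(p)) stop("no bundled file ", file)
  p
}
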