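#' Vertebrate mitochondrial codon table
#'
#' Returns the vertebrate mitochondrial genetic code (NCBI translation
#' table 2): \code{TGA} encodes Trp, \code{AGA}/\code{AGG} are stop codons
#' and \code{ATA} encodes Met.  The table is taken from
#' \code{Biostrings::getGeneticCode("2")} and validated on construction.
#'
#' @return A list with elements \code{code} (named character vector mapping
#'   all 64 codons to one-letter amino acids, stops as \code{"*"}) and
#'   \code{start_codons} (character vector).
#' @export
mito_codon_table <- function() {
  code <- Biostrings::getGeneticCode("2")
  stopifnot(
    length(code) == 64L,
    code[["TGA"]] == "W",
    code[["AGA"]] == "*",
    code[["AGG"]] == "*",
    code[["ATA"]] == "M"
  )
  list(code = code, start_codons = c("ATG", "ATA", "ATT"))
}

MT_LENGTH <- 16569L

#' Load a circular mitochondrial reference with gene annotations
#'
#' Reads a whole-mtDNA reference (FASTA) plus a gene-annotation table and
#' returns a validated circular reference object.  Coordinates are 1-based
#' inclusive throughout; only the control region may wrap the origin
#' (e.g. a D-loop annotated 16024..576).
#'
#' @param fasta_path Path to a single-record FASTA of length 16,569.
#' @param annotation_path Path to a TSV with header
#'   \code{name start end strand kind}; \code{strand} is \code{H} or
#'   \code{L}, \code{kind} one of \code{protein}, \code{tRNA}, \code{rRNA},
#'   \code{control-region}.
#' @return An object of class \code{mito_reference}: list with \code{seq}
#'   (character scalar), \code{name}, \code{circular = TRUE} and
#'   \code{features} (tibble sorted by start).
#' @export
load_reference <- function(fasta_path, annotation_path) {
  stopifnot(file.exists(fasta_path), file.exists(annotation_path))
  ss <- Biostrings::readDNAStringSet(fasta_path)
  if (length(ss) != 1L)
    stop("reference FASTA must contain exactly one record, found ", length(ss))
  seq <- as.character(ss[[1L]])
  if (nchar(seq) != MT_LENGTH)
    stop("reference has length ", nchar(seq), ", expected ", MT_LENGTH)
  if (!grepl("^[ACGTN]+$", seq))
    stop("reference alphabet must be A/C/G/T/N")
  feats <- read_annotation(annotation_path)
  ref <- structure(
    list(seq = seq, name = names(ss)[1L], circular = TRUE, features = feats),
    class = "mito_reference"
  )
  validate_features(ref)
  ref
}

read_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "start", "end", "strand", "kind")
  if (!all(need %in% names(df)))
    stop("annotation table must have columns: ", paste(need, collapse = " "))
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  tibble::as_tibble(df[order(df$start), need])
}

validate_features <- function(ref) {
  f <- ref$features
  if (!all(f$strand %in% c("H", "L")))
    stop("feature strand must be H or L")
  if (!all(f$kind %in% c("protein", "tRNA", "rRNA", "control-region")))
    stop("unknown feature kind: ",
         paste(setdiff(f$kind, c("protein", "tRNA", "rRNA", "control-region")),
               collapse = ", "))
  bad_coord <- f$start < 1L | f$start > MT_LENGTH | f$end < 1L | f$end > MT_LENGTH
  if (any(bad_coord))
    stop("feature coordinates outside 1..", MT_LENGTH, ": ",
         paste(f$name[bad_coord], collapse = ", "))
  wraps <- f$start > f$end
  if (any(wraps & f$kind != "control-region"))
    stop("only the control region may wrap the origin: ",
         paste(f$name[wraps & f$kind != "control-region"], collapse = ", "))
  invisible(ref)
}

#' @export
print.mito_reference <- function(x, ...) {
  cat("<mito_reference> ", x$name, " (", nchar(x$seq), " bp, circular)\n",
      sep = "")
  cat("  ", nrow(x$features), " annotated features\n", sep = "")
  invisible(x)
}

feature_length <- function(feature) {
  if (feature$start <= feature$end) feature$end - feature$start + 1L
  else (MT_LENGTH - feature$start + 1L) + feature$end
}

#' Features overlapping a reference position
#'
#' Circular-aware containment lookup: a wrapping feature (start > end)
#' contains positions \code{>= start} or \code{<= end}.
#'
#' @param reference A \code{mito_reference}.
#' @param position Integer position in 1..16,569.
#' @return Tibble of the features containing the position (possibly empty;
#'   overlapping genes such as ATP8/ATP6 both appear).
#' @export
feature_at <- function(reference, position) {
  position <- as.integer(position)
  if (is.na(position) || position < 1L || position > MT_LENGTH)
    stop("position must be in 1..", MT_LENGTH)
  f <- reference$features
  hit <- ifelse(f$start <= f$end,
                position >= f$start & position <= f$end,
                position >= f$start | position <= f$end)
  f[hit, , drop = FALSE]
}

#' Coding sequence of a protein feature
#'
#' Extracts the coding-orientation nucleotide sequence of a feature.
#' L-strand genes are reverse-complemented.  Protein genes whose genomic
#' interval is not a multiple of 3 (incomplete terminal stop codons
#' completed by polyadenylation) are padded with \code{A} to the next
#' codon boundary.
#'
#' @param reference A \code{mito_reference}.
#' @param feature One row of \code{reference$features} (or a list with
#'   \code{start}, \code{end}, \code{strand}).
#' @param pad Pad an incomplete final codon with A (default \code{TRUE}).
#' @return Character scalar.
#' @export
cds_sequence <- function(reference, feature, pad = TRUE) {
  s <- substr(reference$seq, feature$start, feature$end)
  if (feature$strand == "L")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  if (pad && nchar(s) %% 3L != 0L)
    s <- paste0(s, strrep("A", 3L - nchar(s) %% 3L))
  s
}

#' Codon containing a position of a protein gene
#'
#' Returns the coding-orientation codon overlapping a reference position,
#' together with the 1..3 offset of the position within that codon and the
#' codon number counted from the start codon.  For L-strand genes the
#' codon is the reverse complement of the genomic triplet, so mutating the
#' genomic base changes the complementary position of the codon.
#'
#' @param reference A \code{mito_reference}.
#' @param feature A protein feature row.
#' @param position Reference position inside the feature.
#' @return List with \code{codon}, \code{offset}, \code{codon_number}.
#' @export
codon_at <- function(reference, feature, position) {
  if (feature$kind != "protein")
    stop("codon_at requires a protein feature, got ", feature$kind)
  position <- as.integer(position)
  if (position < feature$start || position > feature$end)
    stop("position ", position, " outside feature ", feature$name)
  cds <- cds_sequence(reference, feature)
  cds_pos <- if (feature$strand == "H") position - feature$start + 1L
             else feature$end - position + 1L
  codon_number <- (cds_pos - 1L) %/% 3L + 1L
  offset <- (cds_pos - 1L) %% 3L + 1L
  codon <- substr(cds, 3L * codon_number - 2L, 3L * codon_number)
  list(codon = codon, offset = offset, codon_number = codon_number)
}

#' Translate under the vertebrate mitochondrial code
#'
#' Codon-by-codon translation that stops at the first stop codon and
#' returns the peptide preceding it.  Codons containing \code{N} translate
#' to the unknown residue \code{X} rather than being skipped.  A trailing
#' partial codon is ignored unless \code{pad = TRUE}.
#'
#' @param nucleotides Character scalar, length >= 3.
#' @param codon_table A codon table from \code{\link{mito_codon_table}}.
#' @param truncate Stop at the first stop codon (default \code{TRUE}).
#' @param pad Pad a trailing partial codon with A before translating.
#' @return Character scalar peptide (one-letter, no stop symbol when
#'   truncating; \code{"*"} retained when \code{truncate = FALSE}).
#' @export
translate_mt <- function(nucleotides, codon_table = mito_codon_table(),
                         truncate = TRUE, pad = FALSE) {
  if (nchar(nucleotides) < 3L)
    stop("need at least one full codon")
  s <- toupper(nucleotides)
  if (pad && nchar(s) %% 3L != 0L)
    s <- paste0(s, strrep("A", 3L - nchar(s) %% 3L))
  n_codon <- nchar(s) %/% 3L
  starts <- 3L * seq_len(n_codon) - 2L
  codons <- substring(s, starts, starts + 2L)
  aa <- unname(codon_table$code[codons])
  aa[is.na(aa)] <- "X"                       # codons containing N or gaps
  if (truncate) {
    stop_at <- which(aa == "*")
    if (length(stop_at)) aa <- aa[seq_len(stop_at[1L] - 1L)]
  }
  paste(aa, collapse = "")
}

#' Number of codons (terminal stop included) of a protein feature
#' @keywords internal
cds_codon_count <- function(feature) {
  as.integer(ceiling(feature_length(feature) / 3))
}
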