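# Pairwise alignment of whole-mtDNA sample sequences to the reference and
# variant extraction.
#
# Samples are accepted linearized at reference position 1 and must share
# >= 95% identity with the reference.  Alignment is global with affine gap
# penalties (match +1, mismatch -2, gap open 6, gap extend 0.5 -- chosen so
# a 4-nt repeat-unit deletion aligns as a single gap).  For speed the
# aligner anchors on exact shared 40-mers and runs the dynamic program
# only between anchors, which is exact for near-identical sequences.

default_alignment_params <- function() {
  list(match = 1, mismatch = -2, gap_open = 6, gap_extend = 0.5,
       kmer = 40L, window = 1500L)
}

pw_align <- function(ref, alt, params) {
  if (!nchar(ref) && !nchar(alt)) return(list(ref = "", alt = ""))
  if (!nchar(ref)) return(list(ref = strrep("-", nchar(alt)), alt = alt))
  if (!nchar(alt)) return(list(ref = ref, alt = strrep("-", nchar(ref))))
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = params$match, mismatch = params$mismatch, baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(alt), Biostrings::DNAString(ref),
    type = "global", substitutionMatrix = mat,
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  list(ref = as.character(Biostrings::alignedSubject(aln)),
       alt = as.character(Biostrings::alignedPattern(aln)))
}

align_core <- function(ref, alt, params) {
  if (ref == alt) return(list(ref = ref, alt = alt))
  nr <- nchar(ref); na <- nchar(alt)
  if (max(nr, na) <= params$window) return(pw_align(ref, alt, params))
  # anchor: an exact k-mer of alt that occurs exactly once in the
  # corresponding region of ref, searched outward from the middle
  k <- params$kmer
  mid <- na %/% 2L
  offs <- seq(60L, 720L, by = 60L)
  for (off in c(0L, as.integer(rbind(offs, -offs)))) {
    i <- mid + off
    if (i < 1L || i + k - 1L > na) next
    kmer <- substr(alt, i, i + k - 1L)
    lo <- max(1L, i - 800L); hi <- min(nr, i + k - 1L + 800L)
    hits <- gregexpr(kmer, substr(ref, lo, hi), fixed = TRUE)[[1L]]
    if (length(hits) == 1L && hits[1L] > 0L) {
      j <- lo + hits[1L] - 1L
      left <- align_core(substr(ref, 1L, j - 1L), substr(alt, 1L, i - 1L), params)
      right <- align_core(substr(ref, j + k, nr), substr(alt, i + k, na), params)
      return(list(ref = paste0(left$ref, kmer, right$ref),
                  alt = paste0(left$alt, kmer, right$alt)))
    }
  }
  if (max(nr, na) <= 8000L) return(pw_align(ref, alt, params))
  stop("could not anchor alignment; sequence too divergent from reference")
}

#' Align a sample mtDNA sequence to the reference
#'
#' Global alignment of one full-length sample allele against the circular
#' reference (both linearized at position 1).  Errors when the sequence
#' length is outside 16,569 +/- 600 nt or the aligned identity is below
#' 95% ("not an mtDNA sequence").
#'
#' @param sample_allele Character scalar (IUPAC codes must already be
#'   expanded; see \code{\link{expand_iupac}}).
#' @param reference A \code{mito_reference}.
#' @param params Alignment parameters (match/mismatch/gap penalties).
#' @return Object of class \code{mito_alignment}: gapped \code{ref}/\code{alt}
#'   strings plus identity.
#' @export
align_to_reference <- function(sample_allele, reference,
                               params = default_alignment_params()) {
  sample_allele <- toupper(sample_allele)
  n <- nchar(sample_allele)
  if (abs(n - MT_LENGTH) > 600L)
    stop("sample length ", n, " outside ", MT_LENGTH, " +/- 600")
  aln <- tryCatch(align_core(reference$seq, sample_allele, params),
                  error = function(e)
                    stop("not an mtDNA sequence (", conditionMessage(e), ")",
                         call. = FALSE))
  rc <- strsplit(aln$ref, "", fixed = TRUE)[[1L]]
  ac <- strsplit(aln$alt, "", fixed = TRUE)[[1L]]
  ident <- sum(rc == ac) / length(rc)
  if (ident < 0.95)
    stop("not an mtDNA sequence (identity ", sprintf("%.1f%%", 100 * ident), ")")
  structure(list(ref = aln$ref, alt = aln$alt, identity = ident,
                 params = params),
            class = "mito_alignment")
}

#' Extract normalized variants from an alignment
#'
#' Walks the alignment columns, merges adjacent gap columns into single
#' indel events, reports each mismatch column as a substitution, and
#' normalizes indels (3'-most shift within repeats, tract notation,
#' microsatellite flag).  Differences at the legacy placeholder position
#' 3107 and events involving N are never called.
#'
#' @param alignment A \code{mito_alignment}.
#' @param reference The \code{mito_reference} the alignment was made against.
#' @return Variant tibble (zero rows for identical sequences).
#' @export
extract_variants <- function(alignment, reference) {
  rc <- strsplit(alignment$ref, "", fixed = TRUE)[[1L]]
  ac <- strsplit(alignment$alt, "", fixed = TRUE)[[1L]]
  refc <- strsplit(reference$seq, "", fixed = TRUE)[[1L]]
  refpos <- cumsum(rc != "-")            # reference position per column
  diffcol <- which(rc != ac)
  out <- list()
  i <- 1L
  while (i <= length(diffcol)) {
    col <- diffcol[i]
    if (rc[col] == "-" || ac[col] == "-") {
      gap_in <- if (rc[col] == "-") "ref" else "alt"
      j <- i
      while (j < length(diffcol) && diffcol[j + 1L] == diffcol[j] + 1L &&
             ((gap_in == "ref" && rc[diffcol[j + 1L]] == "-") ||
              (gap_in == "alt" && ac[diffcol[j + 1L]] == "-")))
        j <- j + 1L
      cols <- diffcol[i:j]
      if (gap_in == "alt") {             # deletion from the sample
        seqs <- paste(rc[cols], collapse = "")
        pos <- refpos[cols[1L]]
        if (!grepl("N", seqs, fixed = TRUE))
          out[[length(out) + 1L]] <- normalize_indel(refc, pos, seqs, "deletion")
      } else {                           # insertion in the sample
        seqs <- paste(ac[cols], collapse = "")
        pos <- refpos[cols[1L]]          # ref base preceding the gap
        if (!grepl("N", seqs, fixed = TRUE))
          out[[length(out) + 1L]] <- normalize_indel(refc, pos, seqs, "insertion")
      }
      i <- j + 1L
    } else {                             # substitution column
      pos <- refpos[col]
      if (pos != 3107L && rc[col] != "N" && ac[col] != "N") {
        v <- variant_tibble(pos, pos, "substitution", rc[col], ac[col],
                            "", FALSE, NA, NA, NA_character_, NA, NA)
        v$label <- variant_label(v)
        out[[length(out) + 1L]] <- v
      }
      i <- i + 1L
    }
  }
  if (!length(out)) return(variant_tibble())
  res <- do.call(rbind, out)
  res[order(res$pos, res$label), ]
}

IUPAC_TWO <- list(R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                  W = c("A", "T"), K = c("G", "T"), M = c("A", "C"))

#' Expand IUPAC two-base ambiguity codes into two alleles
#'
#' A single sequence containing two-base ambiguity codes (R/Y/S/W/K/M) is
#' expanded into two full-length alleles; at each ambiguous site allele 1
#' takes the first base of the code and allele 2 the second.  Sequences
#' without ambiguity codes are returned unchanged (one allele).
#'
#' @param seq Character scalar.
#' @return Character vector of 1 or 2 alleles.
#' @export
expand_iupac <- function(seq) {
  seq <- toupper(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  amb <- which(ch %in% names(IUPAC_TWO))
  if (!length(amb)) return(seq)
  a1 <- ch; a2 <- ch
  for (i in amb) {
    a1[i] <- IUPAC_TWO[[ch[i]]][1L]
    a2[i] <- IUPAC_TWO[[ch[i]]][2L]
  }
  c(paste(a1, collapse = ""), paste(a2, collapse = ""))
}

#' Call variants and heteroplasmy for one sample
#'
#' Aligns each allele of a sample, takes the union of the per-allele
#' variant sets, and labels each call homoplasmic (present in every
#' allele) or heteroplasmic (present in exactly one of two alleles;
#' fraction fixed at 0.5, the binary dual-allele convention of
#' chromatogram-confirmed calls).
#'
#' @param sample List with \code{sample_id}, \code{tissue},
#'   \code{subject_id} and \code{alleles} (1 or 2 sequences; a single
#'   sequence with IUPAC codes is expanded first).
#' @param reference A \code{mito_reference}.
#' @return Call tibble: variant columns plus \code{sample_id},
#'   \code{tissue}, \code{subject_id}, \code{zygosity}, \code{origin}
#'   (initially \code{"undetermined"}) and \code{het_fraction}.
#' @export
detect_heteroplasmy <- function(sample, reference) {
  alleles <- sample$alleles
  if (length(alleles) == 1L) alleles <- expand_iupac(alleles)
  if (length(alleles) < 1L || length(alleles) > 2L)
    stop("sample must have 1 or 2 alleles")
  if (length(alleles) == 2L &&
      abs(nchar(alleles[1L]) - nchar(alleles[2L])) > 600L)
    stop("alleles of grossly different length")
  per_allele <- lapply(alleles, function(a)
    extract_variants(align_to_reference(a, reference), reference))
  labels <- lapply(per_allele, function(v) v$label)
  all_v <- do.call(rbind, per_allele)
  all_v <- all_v[!duplicated(all_v$label), , drop = FALSE]
  if (nrow(all_v) == 0L) {
    out <- all_v
    out$sample_id <- character(0); out$tissue <- character(0)
    out$subject_id <- character(0); out$zygosity <- character(0)
    out$origin <- character(0); out$het_fraction <- numeric(0)
    return(out)
  }
  n_with <- vapply(unname(all_v$label), function(l)
    sum(vapply(labels, function(x) l %in% x, logical(1))), integer(1),
    USE.NAMES = FALSE)
  all_v$sample_id <- sample$sample_id
  all_v$tissue <- sample$tissue
  all_v$subject_id <- sample$subject_id
  all_v$zygosity <- ifelse(n_with == length(alleles), "homoplasmic",
                           "heteroplasmic")
  all_v$origin <- "undetermined"
  all_v$het_fraction <- ifelse(all_v$zygosity == "heteroplasmic", 0.5, NA_real_)
  all_v
}

#' Classify tumor calls as somatic or germline against the paired normal
#'
#' A tumor variant is somatic when the paired normal tissue carries no
#' variant overlapping its position, germline when the same variant is
#' present in the normal, and undetermined otherwise (including when no
#' paired normal exists: pass \code{normal_calls = NULL}).  Zygosity is
#' ignored: a variant heteroplasmic in the tumor and absent in the normal
#' is somatic.
#'
#' @param tumor_calls,normal_calls Call tibbles from
#'   \code{\link{detect_heteroplasmy}} (same subject).
#' @return \code{tumor_calls} with \code{origin} filled in.
#' @export
classify_origin <- function(tumor_calls, normal_calls) {
  if (is.null(normal_calls)) {
    tumor_calls$origin <- "undetermined"
    return(tumor_calls)
  }
  if (nrow(tumor_calls) && nrow(normal_calls) &&
      !identical(unique(tumor_calls$subject_id), unique(normal_calls$subject_id)))
    stop("tumor and normal calls belong to different subjects")
  overlaps_normal <- function(p, e) {
    nrow(normal_calls) > 0L && any(normal_calls$pos <= e & normal_calls$end >= p)
  }
  origin <- character(nrow(tumor_calls))
  for (i in seq_len(nrow(tumor_calls))) {
    v <- tumor_calls[i, ]
    if (nrow(normal_calls) && v$label %in% normal_calls$label)
      origin[i] <- "germline"
    else if (!overlaps_normal(v$pos, v$end))
      origin[i] <- "somatic"
    else origin[i] <- "undetermined"
  }
  tumor_calls$origin <- origin
  tumor_calls
}

#' Read sample sequences from a cohort FASTA
#'
#' Record headers follow \code{subject|tissue|allele}; records sharing
#' subject and tissue are collected into one sample with up to two
#' alleles.
#'
#' @param path FASTA path.
#' @return List of sample lists (\code{sample_id}, \code{subject_id},
#'   \code{tissue}, \code{alleles}).
#' @export
read_sample_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(ss), "|", fixed = TRUE)
  key <- vapply(parts, function(p) paste(p[1:2], collapse = "|"), character(1))
  lapply(split(seq_along(ss), factor(key, levels = unique(key))), function(idx) {
    p <- parts[[idx[1L]]]
    list(sample_id = paste(p[1L], p[2L], sep = "."),
         subject_id = p[1L], tissue = p[2L],
         alleles = unname(as.character(ss[idx])))
  })
}
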