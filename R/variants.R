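# Variant representation, canonical labels and indel normalization.
#
# A variant is a row of a tibble with columns
#   pos, end  : 1-based rCRS-style coordinates.  For substitutions and
#               deletions [pos, end] is the affected interval; for
#               insertions pos == end is the reference base after which
#               the sequence is inserted (3'-most anchor).
#   kind      : substitution | insertion | deletion
#   ref, alt  : affected reference bases / inserted-replacement bases
#               ("" for the absent side of an indel)
#   label     : canonical string, see variant_label()
#   mtMSI     : indel falls in a microsatellite-instability window
#   tract_*   : repeat-tract interval/unit/copy counts, NA outside tracts

#' Default microsatellite-instability windows
#'
#' The three mtDNA repeat windows commonly scored for microsatellite
#' instability: the two control-region poly-C tracts (np 303-315 and
#' 16184-16193) and the CA repeat at np 514-523.
#'
#' @return Tibble with columns \code{name}, \code{start}, \code{end}.
#' @export
mtmsi_windows <- function() {
  tibble::tribble(
    ~name,        ~start,  ~end,
    "polyC-CSB2",   303L,   315L,
    "CA-repeat",    514L,   523L,
    "polyC-HVS1", 16184L, 16193L
  )
}

variant_tibble <- function(pos = integer(), end = integer(),
                           kind = character(), ref = character(),
                           alt = character(), label = character(),
                           mtMSI = logical(), tract_start = integer(),
                           tract_end = integer(), tract_unit = character(),
                           tract_n_ref = integer(), tract_n_alt = integer()) {
  tibble::tibble(pos = as.integer(pos), end = as.integer(end), kind = kind,
                 ref = ref, alt = alt, label = label, mtMSI = mtMSI,
                 tract_start = as.integer(tract_start),
                 tract_end = as.integer(tract_end),
                 tract_unit = tract_unit,
                 tract_n_ref = as.integer(tract_n_ref),
                 tract_n_alt = as.integer(tract_n_alt))
}

smallest_period <- function(x) {
  n <- nchar(x)
  for (p in seq_len(n)) {
    if (n %% p != 0L) next
    if (strrep(substr(x, 1L, p), n %/% p) == x) return(p)
  }
  n
}

# Count copies of `unit` tiling the reference around [from, to] and return
# the maximal tract interval, or NULL when fewer than `min_copies` copies.
repeat_tract <- function(refc, from, unit, min_copies = 2L) {
  u <- nchar(unit)
  start <- from
  while (start - u >= 1L &&
         paste(refc[(start - u):(start - 1L)], collapse = "") == unit)
    start <- start - u
  end <- from - 1L
  while (end + u <= length(refc) &&
         paste(refc[(end + 1L):(end + u)], collapse = "") == unit)
    end <- end + u
  n <- (end - start + 1L) %/% u
  if (n < min_copies) return(NULL)
  list(start = start, end = end, unit = unit, n = n)
}

in_mtmsi <- function(start, end, windows = mtmsi_windows()) {
  any(start <= windows$end & end >= windows$start)
}

#' Canonical label of a variant
#'
#' Substitutions are labelled \code{"G4969A"}.  Indels inside a repeat
#' tract of at least two unit copies are labelled with the tract interval
#' and copy-count change (\code{"11032-11038:A7-6"},
#' \code{"14495-14502:AAAT2-1"}), except inside the microsatellite
#' windows, where the conventional anchored form is used
#' (\code{"309insC"}, \code{"523delCA"}).  Non-tract indels are labelled
#' \code{"13170delA"} / \code{"4520-4521delAC"} / \code{"5835insT"}.
#'
#' @param v A one-row variant tibble (already normalized).
#' @return Character scalar.
#' @export
variant_label <- function(v) {
  if (v$kind == "substitution") return(paste0(v$ref, v$pos, v$alt))
  tract <- !is.na(v$tract_start)
  if (v$kind == "insertion") {
    if (tract && !v$mtMSI)
      return(sprintf("%d-%d:%s%d-%d", v$tract_start, v$tract_end,
                     v$tract_unit, v$tract_n_ref, v$tract_n_alt))
    return(sprintf("%dins%s", v$pos, v$alt))
  }
  # deletion
  if (tract && !v$mtMSI)
    return(sprintf("%d-%d:%s%d-%d", v$tract_start, v$tract_end,
                   v$tract_unit, v$tract_n_ref, v$tract_n_alt))
  if (v$mtMSI || v$pos == v$end) return(sprintf("%ddel%s", v$end, v$ref))
  sprintf("%d-%ddel%s", v$pos, v$end, v$ref)
}

#' Parse a canonical variant label
#'
#' Inverse of \code{\link{variant_label}} for the label forms the package
#' emits.  PhyloTree-style back-mutation labels (trailing \code{"!"}) are
#' rejected explicitly.
#'
#' @param label Character scalar.
#' @return A one-row variant tibble (tract fields filled for tract labels;
#'   \code{mtMSI} computed against the default windows).
#' @export
parse_variant_label <- function(label) {
  if (grepl("!", label, fixed = TRUE))
    stop("back-mutation labels (\"!\") are not supported: ", label)
  if (grepl("^[ACGTN](\\d+)[ACGTN]$", label)) {
    pos <- as.integer(gsub("^[ACGTN]|[ACGTN]$", "", label))
    return(variant_tibble(pos, pos, "substitution",
                          substr(label, 1L, 1L),
                          substr(label, nchar(label), nchar(label)),
                          label, FALSE, NA, NA, NA_character_, NA, NA))
  }
  m <- regmatches(label, regexec("^(\\d+)-(\\d+):([ACGT]+)(\\d+)-(\\d+)$", label))[[1]]
  if (length(m)) {
    ts <- as.integer(m[2]); te <- as.integer(m[3]); unit <- m[4]
    n0 <- as.integer(m[5]); n1 <- as.integer(m[6])
    u <- nchar(unit); d <- abs(n1 - n0) * u
    msi <- in_mtmsi(ts, te)
    if (n1 < n0) {
      pos <- te - d + 1L
      return(variant_tibble(pos, te, "deletion",
                            strrep(unit, n0 - n1), "", label, msi,
                            ts, te, unit, n0, n1))
    }
    return(variant_tibble(te, te, "insertion", "", strrep(unit, n1 - n0),
                          label, msi, ts, te, unit, n0, n1))
  }
  m <- regmatches(label, regexec("^(\\d+)ins([ACGTN]+)$", label))[[1]]
  if (length(m)) {
    pos <- as.integer(m[2])
    return(variant_tibble(pos, pos, "insertion", "", m[3], label,
                          in_mtmsi(pos, pos), NA, NA, NA_character_, NA, NA))
  }
  m <- regmatches(label, regexec("^(\\d+)(?:-(\\d+))?del([ACGTN]+)$", label))[[1]]
  if (length(m)) {
    # in the single-number form the number is the 3'-most deleted base
    end <- if (nzchar(m[3])) as.integer(m[3]) else as.integer(m[2])
    pos <- end - nchar(m[4]) + 1L
    return(variant_tibble(pos, end, "deletion", m[4], "", label,
                          in_mtmsi(pos, end), NA, NA, NA_character_, NA, NA))
  }
  stop("cannot parse variant label: ", label)
}

# Normalize a raw indel event against the full reference: 3'-shift within
# repeated sequence, attach tract metadata, flag mtMSI, build the label.
normalize_indel <- function(refc, pos, seqs, kind,
                            windows = mtmsi_windows()) {
  L <- nchar(seqs)
  if (kind == "deletion") {
    # deleting [pos, pos+L-1]; shift right while the base after the block
    # equals the first deleted base
    while (pos + L <= length(refc) && refc[pos + L] == refc[pos]) {
      pos <- pos + 1L
      seqs <- paste(refc[pos:(pos + L - 1L)], collapse = "")
    }
    unit <- substr(seqs, 1L, smallest_period(seqs))
    tract <- repeat_tract(refc, pos, unit)
    start <- pos; end <- pos + L - 1L
    msi <- in_mtmsi(if (is.null(tract)) start else tract$start,
                    if (is.null(tract)) end else tract$end, windows)
    v <- variant_tibble(start, end, "deletion", seqs, "", "", msi,
                        if (is.null(tract)) NA else tract$start,
                        if (is.null(tract)) NA else tract$end,
                        if (is.null(tract)) NA_character_ else unit,
                        if (is.null(tract)) NA else tract$n,
                        if (is.null(tract)) NA else tract$n - L %/% nchar(unit))
  } else {
    # insertion of seqs after refc[pos]; rotate right while next reference
    # base matches the head of the insertion
    while (pos + 1L <= length(refc) && refc[pos + 1L] == substr(seqs, 1L, 1L)) {
      seqs <- paste0(substr(seqs, 2L, L), substr(seqs, 1L, 1L))
      pos <- pos + 1L
    }
    unit <- substr(seqs, 1L, smallest_period(seqs))
    tract <- if (pos >= 1L) repeat_tract(refc, pos + 1L, unit) else NULL
    # tract must end at the anchor to represent a copy-count change
    if (!is.null(tract) && tract$end != pos) tract <- NULL
    msi <- in_mtmsi(if (is.null(tract)) pos else tract$start,
                    if (is.null(tract)) pos else tract$end, windows)
    v <- variant_tibble(pos, pos, "insertion", "", seqs, "", msi,
                        if (is.null(tract)) NA else tract$start,
                        if (is.null(tract)) NA else tract$end,
                        if (is.null(tract)) NA_character_ else unit,
                        if (is.null(tract)) NA else tract$n,
                        if (is.null(tract)) NA else tract$n + nchar(seqs) %/% nchar(unit))
  }
  v$label <- variant_label(v)
  v
}

#' Flag a variant as microsatellite-instability associated
#'
#' TRUE iff the variant is an indel whose (tract-expanded) interval
#' intersects one of the configured repeat windows.  Substitutions are
#' never flagged.
#'
#' @param variant One-row variant tibble.
#' @param windows Window table, see \code{\link{mtmsi_windows}}.
#' @return Logical scalar.
#' @export
flag_mtMSI <- function(variant, windows = mtmsi_windows()) {
  if (variant$kind == "substitution") return(FALSE)
  start <- if (!is.na(variant$tract_start)) variant$tract_start else variant$pos
  end <- if (!is.na(variant$tract_end)) variant$tract_end else variant$end
  in_mtmsi(start, end, windows)
}

#' Variation load of a gene or complex
#'
#' Percentage of altered nucleotides per unit: the number of distinct
#' reference positions touched by the supplied calls inside the unit,
#' divided by the unit length, times 100.  Units are single gene names or
#' the groupings \code{"Complex I"} (ND genes), \code{"Complex III"}
#' (Cytb), \code{"Complex IV"} (CO genes), \code{"Complex V"} (ATP genes),
#' \code{"rRNA"}, \code{"tRNA"} and \code{"D-loop"}.
#'
#' @param calls Variant (or call) tibble with \code{pos}/\code{end}.
#' @param features Feature tibble of the reference.
#' @param unit Unit name.
#' @return Tibble with \code{unit}, \code{altered_nucleotides},
#'   \code{unit_length}, \code{load}.
#' @export
variation_load <- function(calls, features, unit) {
  complexes <- list(
    "Complex I" = c("ND1", "ND2", "ND3", "ND4", "ND4L", "ND5", "ND6"),
    "Complex III" = "Cytb",
    "Complex IV" = c("COI", "COII", "COIII"),
    "Complex V" = c("ATP6", "ATP8")
  )
  if (unit %in% names(complexes)) {
    f <- features[features$name %in% complexes[[unit]], ]
  } else if (unit %in% c("rRNA", "tRNA")) {
    f <- features[features$kind == unit, ]
  } else if (unit == "D-loop") {
    f <- features[features$kind == "control-region", ]
  } else if (unit %in% features$name) {
    f <- features[features$name == unit, ]
  } else stop("unknown unit: ", unit)
  unit_len <- sum(vapply(seq_len(nrow(f)), function(i) feature_length(f[i, ]),
                         integer(1)))
  member <- function(p) {
    any(ifelse(f$start <= f$end, p >= f$start & p <= f$end,
               p >= f$start | p <= f$end))
  }
  pos <- unique(unlist(Map(seq.int, calls$pos, calls$end)))
  pos <- pos[vapply(as.integer(pos), member, logical(1))]
  tibble::tibble(unit = unit, altered_nucleotides = length(pos),
                 unit_length = unit_len,
                 load = length(pos) / unit_len * 100)
}
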