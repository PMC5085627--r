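# Consequence annotation: coding substitutions and indels, RNA stem
# disruption, and the primate conservation index.

AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", "*" = "Ter", X = "Xaa")

aa3 <- function(one) unname(AA3[one])

#' Transition or transversion
#' @param ref,alt Single reference/alternate bases.
#' @return \code{"transition"} (A<->G, C<->T) or \code{"transversion"}.
#' @export
ti_tv <- function(ref, alt) {
  if (paste0(ref, alt) %in% c("AG", "GA", "CT", "TC")) "transition"
  else "transversion"
}

consequence_tibble <- function(label, gene, category, aa_change = NA_character_,
                               product_length_ref = NA_integer_,
                               product_length_alt = NA_integer_,
                               ti_tv = NA_character_, note = NA_character_) {
  tibble::tibble(label = label, gene = gene, category = category,
                 aa_change = aa_change,
                 product_length_ref = as.integer(product_length_ref),
                 product_length_alt = as.integer(product_length_alt),
                 ti_tv = ti_tv, note = note)
}

protein_feature_at <- function(reference, position) {
  f <- feature_at(reference, position)
  f[f$kind == "protein", , drop = FALSE]
}

#' Annotate a coding substitution
#'
#' Recomputes the codon in coding orientation (L-strand genes as reverse
#' complement), compares reference and mutant amino acids under the
#' vertebrate mitochondrial code, and classifies the change as synonymous,
#' non-synonymous or nonsense.  Positions outside protein genes are
#' classified \code{rna} or \code{control-region} with no amino-acid
#' change.  For positions inside overlapping genes one row per gene is
#' returned.
#'
#' @param variant One-row substitution tibble.
#' @param reference A \code{mito_reference}.
#' @param codon_table Codon table (default vertebrate mitochondrial).
#' @return Consequence tibble.
#' @export
annotate_substitution <- function(variant, reference,
                                  codon_table = mito_codon_table()) {
  stopifnot(variant$kind == "substitution")
  pos <- variant$pos
  prot <- protein_feature_at(reference, pos)
  titv <- ti_tv(variant$ref, variant$alt)
  if (nrow(prot) == 0L) {
    f <- feature_at(reference, pos)
    cat_ <- if (nrow(f) && any(f$kind == "control-region")) "control-region"
            else "rna"
    gene <- if (nrow(f)) paste(f$name, collapse = ",") else NA_character_
    return(consequence_tibble(variant$label, gene, cat_, ti_tv = titv))
  }
  out <- lapply(seq_len(nrow(prot)), function(i) {
    f <- prot[i, ]
    ca <- codon_at(reference, f, pos)
    genomic_base <- if (f$strand == "H") variant$alt
                    else chartr("ACGT", "TGCA", variant$alt)
    mut_codon <- ca$codon
    substr(mut_codon, ca$offset, ca$offset) <- genomic_base
    aa_ref <- unname(codon_table$code[ca$codon])
    aa_alt <- unname(codon_table$code[mut_codon])
    category <- if (aa_alt == "*") "nonsense"
                else if (aa_ref == aa_alt) "synonymous"
                else "non-synonymous"
    n_ref <- cds_codon_count(f)
    n_alt <- if (category == "nonsense") ca$codon_number - 1L else NA_integer_
    consequence_tibble(variant$label, f$name, category,
                       paste0(aa3(aa_ref), "->", aa3(aa_alt)),
                       if (category == "nonsense") n_ref else NA_integer_,
                       n_alt, titv)
  })
  do.call(rbind, out)
}

# Rebuild the mutant coding sequence of a feature with one indel applied
# (genomic coordinates), in coding orientation.
mutant_cds <- function(reference, feature, variant) {
  s <- reference$seq
  if (variant$kind == "deletion") {
    g <- paste0(substr(s, feature$start, variant$pos - 1L),
                substr(s, variant$end + 1L, feature$end))
  } else {
    g <- paste0(substr(s, feature$start, variant$pos),
                variant$alt,
                substr(s, variant$pos + 1L, feature$end))
  }
  if (feature$strand == "L")
    g <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(g)))
  if (nchar(g) %% 3L != 0L) g <- paste0(g, strrep("A", 3L - nchar(g) %% 3L))
  g
}

#' Annotate a coding insertion or deletion
#'
#' Indels of length not divisible by 3 are frameshifts; in-frame indels
#' are classified \code{inframe-indel}.  The mutant coding sequence is
#' rebuilt with the indel applied and translated to the first stop codon,
#' giving the truncated product length (residues before the premature
#' stop; the reference product length counts all codons of the annotated
#' frame, terminal stop included).  An indel spanning a feature boundary
#' is annotated against every overlapped protein feature with a warning.
#'
#' @inheritParams annotate_substitution
#' @return Consequence tibble.
#' @export
annotate_indel <- function(variant, reference,
                           codon_table = mito_codon_table()) {
  stopifnot(variant$kind %in% c("insertion", "deletion"))
  prot <- protein_feature_at(reference, variant$pos)
  if (variant$kind == "deletion") {
    prot_end <- protein_feature_at(reference, variant$end)
    if (!identical(prot$name, prot_end$name))
      warning("indel ", variant$label, " spans a feature boundary")
    prot <- unique(rbind(prot, prot_end))
  }
  if (nrow(prot) == 0L) {
    f <- feature_at(reference, variant$pos)
    cat_ <- if (nrow(f) && any(f$kind == "control-region")) "control-region"
            else "rna"
    gene <- if (nrow(f)) paste(f$name, collapse = ",") else NA_character_
    return(consequence_tibble(variant$label, gene, cat_))
  }
  len <- if (variant$kind == "deletion") nchar(variant$ref) else nchar(variant$alt)
  frameshift <- len %% 3L != 0L
  out <- lapply(seq_len(nrow(prot)), function(i) {
    f <- prot[i, ]
    n_ref <- cds_codon_count(f)
    mut <- mutant_cds(reference, f, variant)
    pep <- translate_mt(mut, codon_table)
    n_alt <- nchar(pep)
    consequence_tibble(variant$label, f$name,
                       if (frameshift) "frameshift" else "inframe-indel",
                       product_length_ref = n_ref,
                       product_length_alt = n_alt)
  })
  do.call(rbind, out)
}

#' Read an RNA stem pairing map
#'
#' TSV with columns \code{gene pos1 pos2}, one stem base pair per row in
#' reference coordinates.  Each position may appear in at most one pair.
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_pairing_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "pos1", "pos2") %in% names(df)))
  pos <- c(df$pos1, df$pos2)
  if (anyDuplicated(pos))
    stop("a position appears in more than one stem pair")
  tibble::as_tibble(df)
}

WATSON_CRICK <- c(A = "T", T = "A", G = "C", C = "G")

#' Assess disruption of an RNA stem base pair
#'
#' If the variant position lies in a stem pair of the supplied pairing
#' map and the mutant base no longer Watson-Crick-pairs its partner, the
#' pair is reported disrupted with the conventional RNA notation
#' (e.g. \code{"A-U (down)"}).  Positions not listed in the map are loop
#' positions (not disrupted); a gene with no pairing map at all yields
#' \code{"undetermined"}.
#'
#' @param variant One-row substitution tibble in an RNA gene.
#' @param pairing_map Tibble from \code{\link{read_pairing_map}}.
#' @param reference A \code{mito_reference}.
#' @return Tibble with \code{label}, \code{gene}, \code{status}
#'   (\code{disrupted}/\code{intact}/\code{loop}/\code{undetermined}) and
#'   \code{description}.
#' @export
annotate_rna <- function(variant, pairing_map, reference) {
  f <- feature_at(reference, variant$pos)
  rna <- f[f$kind %in% c("tRNA", "rRNA"), , drop = FALSE]
  gene <- if (nrow(rna)) rna$name[1L] else NA_character_
  rna_base <- function(b) chartr("T", "U", b)
  if (is.na(gene) || !gene %in% pairing_map$gene)
    return(tibble::tibble(label = variant$label, gene = gene,
                          status = "undetermined", description = NA_character_))
  pm <- pairing_map[pairing_map$gene == gene, ]
  hit <- which(pm$pos1 == variant$pos | pm$pos2 == variant$pos)
  if (!length(hit))
    return(tibble::tibble(label = variant$label, gene = gene,
                          status = "loop", description = "loop position"))
  pr <- pm[hit[1L], ]
  partner_pos <- if (pr$pos1 == variant$pos) pr$pos2 else pr$pos1
  partner <- substr(reference$seq, partner_pos, partner_pos)
  ref_pair <- paste0(rna_base(variant$ref), "-", rna_base(partner))
  disrupted <- WATSON_CRICK[[variant$alt]] != partner
  tibble::tibble(
    label = variant$label, gene = gene,
    status = if (disrupted) "disrupted" else "intact",
    description = if (disrupted) paste0(ref_pair, " abolished") else ref_pair)
}

#' Conservation index of an alignment column
#'
#' Percentage of the 41 aligned primate sequences (human included)
#' carrying the human wild-type residue or nucleotide.  Gaps and any
#' non-wild-type symbol count against conservation.
#'
#' @param column Character vector of exactly 41 aligned symbols.
#' @param human_wildtype The human wild-type symbol.
#' @return Tibble with \code{wildtype_count} and \code{ci_percent}.
#' @export
conservation_index <- function(column, human_wildtype) {
  if (length(column) != 41L)
    stop("conservation column must have 41 symbols, got ", length(column))
  n <- sum(toupper(column) == toupper(human_wildtype))
  tibble::tibble(wildtype_count = n, ci_percent = n / 41 * 100)
}

#' Read a 41-row primate alignment FASTA
#'
#' Human first; all records must share one aligned length.
#'
#' @param path FASTA path.
#' @return Character matrix (41 rows x alignment columns).
#' @export
read_primate_alignment <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) != 41L)
    stop("primate alignment must have 41 records, found ", length(ss))
  w <- unique(Biostrings::width(ss))
  if (length(w) != 1L) stop("primate alignment rows differ in length")
  m <- do.call(rbind, strsplit(as.character(ss), "", fixed = TRUE))
  rownames(m) <- names(ss)
  m
}
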