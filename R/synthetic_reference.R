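# Deterministic synthetic stand-in for the human mtDNA reference.
#
# The sequence is NOT the rCRS: it is a synthetic 16,569-bp molecule that
# reuses the standard NC_012920 gene boundaries and reproduces, by
# construction, every sequence context this package's example tables refer
# to: reference bases and codons at the documented variant positions, the
# three microsatellite-instability repeat tracts, the coding-region
# homopolymer tracts, the (AAAT)2 repeat of ND6 whose one-unit deletion
# truncates the product from 175 to 58 residues, selected tRNA stem
# base-pairs, the legacy placeholder N at position 3107, and the reference
# alleles of the bundled haplogroup tree and mtSNP panel.  All protein
# genes start with ATG (genomic CAT for the L-strand ND6), end in a
# complete or polyadenylation-completed stop codon, and contain no internal
# stop in any overlapping reading frame.

mt_gene_table <- function() {
  tibble::tribble(
    ~name, ~start, ~end, ~strand, ~kind,
    "D-loop",         16024L,   576L, "H", "control-region",
    "tRNA-Phe",         577L,   647L, "H", "tRNA",
    "12S-rRNA",         648L,  1601L, "H", "rRNA",
    "tRNA-Val",        1602L,  1670L, "H", "tRNA",
    "16S-rRNA",        1671L,  3229L, "H", "rRNA",
    "tRNA-Leu(UUR)",   3230L,  3304L, "H", "tRNA",
    "ND1",             3307L,  4262L, "H", "protein",
    "tRNA-Ile",        4263L,  4331L, "H", "tRNA",
    "tRNA-Gln",        4329L,  4400L, "L", "tRNA",
    "tRNA-Met",        4402L,  4469L, "H", "tRNA",
    "ND2",             4470L,  5511L, "H", "protein",
    "tRNA-Trp",        5512L,  5579L, "H", "tRNA",
    "tRNA-Ala",        5587L,  5655L, "L", "tRNA",
    "tRNA-Asn",        5657L,  5729L, "L", "tRNA",
    "tRNA-Cys",        5761L,  5826L, "L", "tRNA",
    "tRNA-Tyr",        5826L,  5891L, "L", "tRNA",
    "COI",             5904L,  7445L, "H", "protein",
    "tRNA-Ser(UCN)",   7446L,  7514L, "L", "tRNA",
    "tRNA-Asp",        7518L,  7585L, "H", "tRNA",
    "COII",            7586L,  8269L, "H", "protein",
    "tRNA-Lys",        8295L,  8364L, "H", "tRNA",
    "ATP8",            8366L,  8572L, "H", "protein",
    "ATP6",            8527L,  9207L, "H", "protein",
    "COIII",           9207L,  9990L, "H", "protein",
    "tRNA-Gly",        9991L, 10058L, "H", "tRNA",
    "ND3",            10059L, 10404L, "H", "protein",
    "tRNA-Arg",       10405L, 10469L, "H", "tRNA",
    "ND4L",           10470L, 10766L, "H", "protein",
    "ND4",            10760L, 12137L, "H", "protein",
    "tRNA-His",       12138L, 12206L, "H", "tRNA",
    "tRNA-Ser(AGY)",  12207L, 12265L, "H", "tRNA",
    "tRNA-Leu(CUN)",  12266L, 12336L, "H", "tRNA",
    "ND5",            12337L, 14148L, "H", "protein",
    "ND6",            14149L, 14673L, "L", "protein",
    "tRNA-Glu",       14674L, 14742L, "L", "tRNA",
    "Cytb",           14747L, 15887L, "H", "protein",
    "tRNA-Thr",       15888L, 15953L, "H", "tRNA",
    "tRNA-Pro",       15956L, 16023L, "L", "tRNA"
  )
}

# Frozen base assignments (genomic H-strand), the contract the rest of the
# package's fixtures are written against.  Conflicting duplicate
# assignments abort.
synthetic_reference_constraints <- function() {
  fx <- character(0)
  put <- function(start, bases) {
    b <- strsplit(bases, "")[[1L]]
    p <- as.character(seq.int(start, start + length(b) - 1L))
    structure(b, names = p)
  }
  add <- function(...) fx <<- c(fx, ...)

  # protein gene start codons (ATG; ND6 is L-strand: genomic CAT)
  for (s in c(3307L, 4470L, 5904L, 7586L, 8366L, 8527L, 9207L, 10059L,
              10470L, 10760L, 12337L, 14747L))
    add(put(s, "ATG"))
  add(put(14671L, "CAT"))

  # terminal stop codons; partial T/TA codons are completed by A-padding
  add(put(4261L, "TA"), put(5511L, "T"), put(7443L, "TAA"),
      put(8267L, "TAA"), put(8570L, "TAA"), put(9205L, "TAA"),
      put(9990L, "T"), put(10404L, "T"), put(10764L, "TAA"),
      put(12137L, "T"), put(14146L, "TAA"), put(14149L, "TTA"),
      put(15887L, "T"))

  # frames flanking the overlapping gene pairs (ATP8/ATP6, ND4L/ND4)
  add(put(8525L, "CC"), put(8573L, "C"),
      put(10758L, "CC"), put(10763L, "C"), put(10767L, "T"))

  # reference codons at the documented coding substitution sites
  codons <- c(
    "3391" = "GGC",  "3643" = "GTA",  "3679" = "TCA",  "3745" = "GCC",
    "4518" = "CCA",  "4875" = "CTA",  "4968" = "TGG",  "4971" = "GGC",
    "5460" = "GGC",  "5976" = "TGG",  "6237" = "CTA",  "6339" = "ACC",
    "6678" = "TTT",  "6681" = "TAC",  "7104" = "TCA",  "7329" = "TTC",
    "7748" = "ATC",  "7928" = "GGA",  "8156" = "GTG",  "8989" = "GCC",
    "9121" = "GCG",  "9187" = "TAC",  "9252" = "TGG",  "9354" = "AAC",
    "10521" = "GGA", "10572" = "GGA", "10620" = "ACC", "12793" = "TTA",
    "12850" = "ATC", "12943" = "CTC", "13534" = "AAC", "13621" = "CTT",
    "13747" = "AAT", "13825" = "GGA", "14774" = "CTC", "15017" = "TTT",
    "15044" = "CGA", "15089" = "ATT", "15479" = "TTC", "15482" = "TCA"
  )
  for (p in names(codons)) add(put(as.integer(p), codons[[p]]))

  # ND6 (L-strand) contexts, written as genomic bases
  add(put(14308L, "CCC"),          # coding GGG, Gly codon hit by C14310A
      put(14461L, "TGT"),          # coding ACA, Thr codon hit by T14463C
      put(14587L, "AAG"),          # coding CTT, silent mtSNP A14587G
      put(14493L, "CT"),           # downstream frame: TAG stop after slip
      put(14495L, "AAATAAAT"),     # (AAAT)2, one-unit deletion -> 58 aa
      put(14503L, "G"))

  # microsatellite-instability tracts and their non-repeat flanks
  add(put(302L, "A"), put(303L, strrep("C", 7L)), put(310L, "T"),
      put(311L, strrep("C", 5L)), put(316L, "A"))
  add(put(513L, "T"), put(514L, strrep("CA", 5L)), put(524L, "T"))
  add(put(16183L, "A"), put(16184L, strrep("C", 10L)), put(16194L, "A"))

  # coding-region repeat tracts behind the documented indels
  add(put(11030L, "CC"), put(11032L, strrep("A", 7L)), put(11039L, "C"))
  add(put(11672L, "A"), put(11673L, strrep("C", 5L)), put(11678L, "G"))
  add(put(12417L, "C"), put(12418L, strrep("A", 8L)), put(12426L, "C"))
  add(put(13126L, "AT"), put(13128L, strrep("C", 5L)), put(13133L, "TA"))
  add(put(13168L, "CCA"), put(13171L, "G"))            # lone A at 13170
  add(put(10951L, "TCTG"))                             # lone C at 10952
  add(put(11646L, "TG"), put(12858L, "TG"), put(5835L, "TG"))
  add(put(4520L, "ACT"), put(3274L, "GCAG"))           # delAC / delCA sites

  # RNA-region variant sites and stem partners (pairs listed in the
  # bundled pairing map: 1629-1650, 4272-4310, 5845-5881)
  add(c("709" = "G", "1629" = "A", "1650" = "T", "2274" = "A",
        "3107" = "N", "4272" = "T", "4310" = "A", "5845" = "C",
        "5881" = "G", "10040" = "C"))

  # mtSNP panel reference alleles (D-loop members)
  add(c("16164" = "A", "16266" = "C", "16362" = "T"))

  # haplogroup-tree defining-variant reference alleles (all D-loop)
  add(c("73" = "A", "93" = "T", "103" = "C", "143" = "C", "152" = "A",
        "195" = "T", "204" = "A", "235" = "C", "247" = "A", "249" = "T",
        "16051" = "A", "16071" = "C", "16093" = "T", "16104" = "C",
        "16111" = "A", "16129" = "G", "16145" = "C", "16154" = "A",
        "16172" = "C", "16209" = "A", "16223" = "C", "16234" = "A",
        "16243" = "C", "16249" = "A", "16278" = "C", "16290" = "A",
        "16304" = "C", "16311" = "A", "16320" = "C"))

  pos <- as.integer(names(fx))
  dup <- duplicated(pos)
  if (any(dup)) {
    for (p in unique(pos[dup])) {
      v <- unique(fx[pos == p])
      if (length(v) > 1L)
        stop("conflicting frozen bases at position ", p, ": ",
             paste(v, collapse = "/"))
    }
    fx <- fx[!dup]
    pos <- pos[!dup]
  }
  structure(fx, names = as.character(pos))
}

STOP_CODONS_MT <- c("TAA", "TAG", "AGA", "AGG")

#' Deterministic synthetic mtDNA reference
#'
#' Builds the package's synthetic 16,569-bp reference (see the package
#' vignette): random background sequence under a fixed internal seed, the
#' frozen variant/tract/pairing contexts applied, and all protein reading
#' frames (including the ATP8/ATP6 and ND4L/ND4 overlaps) scrubbed of
#' internal stop codons.  The result is identical on every call.
#'
#' @return A \code{mito_reference} named \code{"synthetic-mtDNA"}.
#' @export
synthetic_reference <- function() {
  if (!is.null(.mitovar_cache$reference)) return(.mitovar_cache$reference)
  ref <- build_synthetic_reference()
  .mitovar_cache$reference <- ref
  ref
}

.mitovar_cache <- new.env(parent = emptyenv())

build_synthetic_reference <- function() {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(1659401L)
  s <- sample(c("A", "C", "G", "T"), MT_LENGTH, replace = TRUE)
  fx <- synthetic_reference_constraints()
  frozen_pos <- as.integer(names(fx))
  s[frozen_pos] <- unname(fx)
  frozen <- logical(MT_LENGTH)
  frozen[frozen_pos] <- TRUE

  feats <- mt_gene_table()
  prot <- feats[feats$kind == "protein", ]
  ct <- mito_codon_table()

  genomic_codon_pos <- function(f, k) {
    # genomic positions of coding codon k, in coding order
    if (f$strand == "H") f$start + 3L * (k - 1L) + 0:2
    else f$end - 3L * (k - 1L) - (0:2)
  }
  coding_codon <- function(f, k) {
    gp <- genomic_codon_pos(f, k)
    b <- ifelse(gp >= f$start & gp <= f$end, s[gp], "A")  # A-padding
    if (f$strand == "L") b <- chartr("ACGT", "TGCA", b)
    paste(b, collapse = "")
  }
  internal_stops <- function(f) {
    n <- cds_codon_count(f)
    ks <- seq_len(n - 1L)
    ks[vapply(ks, function(k) coding_codon(f, k) %in% STOP_CODONS_MT, logical(1))]
  }

  for (pass in 1:40) {
    changed <- FALSE
    for (i in seq_len(nrow(prot))) {
      f <- prot[i, ]
      for (k in internal_stops(f)) {
        gp <- genomic_codon_pos(f, k)
        gp <- gp[gp >= f$start & gp <= f$end]
        free <- gp[!frozen[gp]]
        if (!length(free))
          stop("frozen internal stop codon in ", f$name, " at codon ", k)
        fixed <- FALSE
        for (p in rev(free)) {            # prefer the third codon position
          for (b in c("C", "G", "T", "A")) {
            if (b == s[p]) next
            keep <- s[p]; s[p] <- b
            ok <- TRUE
            for (j in seq_len(nrow(prot))) {
              g <- prot[j, ]
              if (p < g$start || p > g$end) next
              kk <- if (g$strand == "H") (p - g$start) %/% 3L + 1L
                    else (g$end - p) %/% 3L + 1L
              if (kk < cds_codon_count(g) &&
                  coding_codon(g, kk) %in% STOP_CODONS_MT) { ok <- FALSE; break }
            }
            if (ok) { fixed <- TRUE; changed <- TRUE; break }
            s[p] <- keep
          }
          if (fixed) break
        }
        if (!fixed) stop("could not remove stop codon in ", f$name, " codon ", k)
      }
    }
    if (!changed) break
  }

  ref <- structure(
    list(seq = paste(s, collapse = ""), name = "synthetic-mtDNA",
         circular = TRUE, features = feats),
    class = "mito_reference"
  )
  validate_features(ref)
  ref
}

#' Write the synthetic reference fixtures to a directory
#'
#' Writes \code{synthetic_mtdna.fasta} and \code{mito_genes.tsv} (the gene
#' annotation) so they can be re-loaded through \code{\link{load_reference}}.
#'
#' @param dir Output directory (created if missing).
#' @return Invisibly, the two file paths.
#' @export
write_reference_fixtures <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ref <- synthetic_reference()
  fa <- file.path(dir, "synthetic_mtdna.fasta")
  ss <- Biostrings::DNAStringSet(ref$seq)
  names(ss) <- ref$name
  Biostrings::writeXStringSet(ss, fa, width = 70L)
  ann <- file.path(dir, "mito_genes.tsv")
  utils::write.table(ref$features, ann, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta = fa, annotation = ann))
}
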