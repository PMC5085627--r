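test_that("documented substitution consequences are reproduced", {
  ref <- test_ref()
  cases <- list(
    list(label = "T12794A", gene = "ND5", cat = "nonsense", aa = "Leu->Ter"),
    list(label = "C4875T", gene = "ND2", cat = "synonymous", aa = "Leu->Leu"),
    list(label = "T6238C", gene = "COI", cat = "non-synonymous", aa = "Leu->Pro"),
    list(label = "G4969A", gene = "ND2", cat = "nonsense", aa = "Trp->Ter"),
    list(label = "C14310A", gene = "ND6", cat = "non-synonymous", aa = "Gly->Trp"),
    list(label = "T14463C", gene = "ND6", cat = "non-synonymous", aa = "Thr->Ala"),
    list(label = "C7750A", gene = "COII", cat = "non-synonymous", aa = "Ile->Met"),
    list(label = "C10622T", gene = "ND4L", cat = "synonymous", aa = "Thr->Thr")
  )
  for (cs in cases) {
    res <- annotate_substitution(parse_variant_label(cs$label), ref)
    expect_equal(res$gene, cs$gene, label = cs$label)
    expect_equal(res$category, cs$cat, label = cs$label)
    expect_equal(res$aa_change, cs$aa, label = cs$label)
  }
  # transition/transversion bookkeeping
  expect_equal(annotate_substitution(parse_variant_label("G4969A"), ref)$ti_tv,
               "transition")
  expect_equal(annotate_substitution(parse_variant_label("T12794A"), ref)$ti_tv,
               "transversion")
  # non-coding positions never get an amino-acid change
  rna <- annotate_substitution(parse_variant_label("A2274G"), ref)
  expect_equal(rna$category, "rna")
  expect_true(is.na(rna$aa_change))
  dl <- annotate_substitution(parse_variant_label("A73G"), ref)
  expect_equal(dl$category, "control-region")
})

test_that("indels classify by frame and truncate the product", {
  ref <- test_ref()
  nd6 <- annotate_indel(parse_variant_label("14495-14502:AAAT2-1"), ref)
  expect_equal(nd6$category, "frameshift")
  expect_equal(nd6$product_length_ref, 175L)
  expect_equal(nd6$product_length_alt, 58L)
  ins <- annotate_indel(parse_variant_label("10952insC"), ref)
  expect_equal(ins$category, "frameshift")
  expect_equal(ins$gene, "ND4")
  # a 3-nt deletion keeps the frame
  v <- parse_variant_label(
    sprintf("3400-3402del%s", substr(ref$seq, 3400, 3402)))
  inframe <- annotate_indel(v, ref)
  expect_equal(inframe$category, "inframe-indel")
})

test_that("frameshift truncation agrees with an independent translation", {
  ref <- test_ref()
  code2 <- Biostrings::getGeneticCode("2")
  tm <- truncating_mutation_fixture()
  fs <- tm$label[tm$class == "frameshift"]
  for (lab in fs) {
    v <- parse_variant_label(lab)
    res <- annotate_indel(v, ref)
    f <- feature_by_name(ref, res$gene)
    # oracle: rebuild the mutant gene interval independently and translate
    # with Biostrings
    if (v$kind == "deletion") {
      g <- paste0(substr(ref$seq, f$start, v$pos - 1),
                  substr(ref$seq, v$end + 1, f$end))
    } else {
      g <- paste0(substr(ref$seq, f$start, v$pos), v$alt,
                  substr(ref$seq, v$pos + 1, f$end))
    }
    if (f$strand == "L")
      g <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(g)))
    g <- substr(g, 1, 3 * (nchar(g) %/% 3))
    pep <- as.character(Biostrings::translate(
      Biostrings::DNAString(g), genetic.code = code2,
      if.fuzzy.codon = "solve"))
    oracle_len <- if (grepl("*", pep, fixed = TRUE))
      regexpr("*", pep, fixed = TRUE)[[1]] - 1L else nchar(pep)
    expect_equal(res$product_length_alt, oracle_len, label = lab)
    expect_lte(res$product_length_alt, res$product_length_ref)
  }
})

test_that("substitution categories are strand-invariant", {
  # mutate matched codon positions of an H-strand and an L-strand gene and
  # verify category against a brute-force rebuild-and-translate oracle
  ref <- test_ref()
  ct <- mito_codon_table()
  set.seed(7)
  for (gene in c("ND5", "ND6")) {
    f <- feature_by_name(ref, gene)
    for (rep in 1:20) {
      p <- sample((f$start + 3):(f$end - 3), 1)
      base <- ref_base(ref, p)
      alt <- sample(other_bases(base), 1)
      v <- parse_variant_label(paste0(base, p, alt))
      res <- annotate_substitution(v, ref)
      res <- res[res$gene == gene, ]
      mut <- ref
      mut$seq <- mutate_seq(ref$seq, list(list(op = "sub", pos = p, base = alt)))
      pep_ref <- translate_mt(cds_sequence(ref, f), ct, truncate = FALSE)
      pep_alt <- translate_mt(cds_sequence(mut, f), ct, truncate = FALSE)
      k <- codon_at(ref, f, p)$codon_number
      aa_r <- substr(pep_ref, k, k); aa_a <- substr(pep_alt, k, k)
      expected <- if (aa_a == "*") "nonsense"
                  else if (aa_r == aa_a) "synonymous" else "non-synonymous"
      expect_equal(res$category, expected, label = paste(gene, p))
    }
  }
})

test_that("RNA stem disruption follows Watson-Crick pairing", {
  ref <- test_ref()
  pm <- read_pairing_map(mitovar_extdata("pairing_maps.tsv"))
  d1 <- annotate_rna(parse_variant_label("A1629T"), pm, ref)
  expect_equal(d1$status, "disrupted")
  expect_match(d1$description, "A-U")
  d2 <- annotate_rna(parse_variant_label("T4272C"), pm, ref)
  expect_equal(d2$status, "disrupted")
  # loop position of a mapped gene: not disrupted
  loop <- annotate_rna(parse_variant_label(
    paste0(ref_base(ref, 1610), 1610, "A")), pm, ref)
  expect_equal(loop$status, "loop")
  # gene with no pairing map: undetermined, not an error
  und <- annotate_rna(parse_variant_label("C10040A"), pm, ref)
  expect_equal(und$status, "undetermined")
  # a change that preserves pairing potential is intact
  pm2 <- tibble::tibble(gene = "tRNA-Val", pos1 = 1629L, pos2 = 1650L)
  ref2 <- ref
  ref2$seq <- mutate_seq(ref$seq, list(list(op = "sub", pos = 1650, base = "C")))
  intact <- annotate_rna(parse_variant_label("A1629G"), pm2, ref2)
  expect_equal(intact$status, "intact")
})

test_that("conservation index is the wild-type fraction of 41", {
  expect_equal(conservation_index(rep("L", 41), "L")$ci_percent, 100)
  r <- conservation_index(c(rep("L", 32), rep("P", 9)), "L")
  expect_equal(r$wildtype_count, 32L)
  expect_equal(round(r$ci_percent, 2), 78.05)
  r2 <- conservation_index(c(rep("A", 10), rep("-", 31)), "A")
  expect_equal(round(r2$ci_percent, 2), 24.39)
  expect_error(conservation_index(rep("A", 40), "A"), "41")
})
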