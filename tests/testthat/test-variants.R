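test_that("alignment of the reference to itself yields no variants", {
  ref <- test_ref()
  aln <- align_to_reference(ref$seq, ref)
  expect_equal(aln$identity, 1)
  expect_equal(nrow(extract_variants(aln, ref)), 0L)
})

test_that("single planted edits are recovered exactly", {
  ref <- test_ref()
  mut <- mutate_seq(ref$seq, list(list(op = "sub", pos = 4969, base = "A")))
  v <- extract_variants(align_to_reference(mut, ref), ref)
  expect_equal(v$label, "G4969A")
  expect_equal(v$kind, "substitution")
})

test_that("a repeat-unit deletion aligns as one gap (edit-distance oracle)", {
  ref <- test_ref()
  # delete one AAAT unit from the (AAAT)2 tract
  mut <- mutate_seq(ref$seq, list(list(op = "del", pos = 14495, len = 4)))
  aln <- align_to_reference(mut, ref)
  # oracle: brute-force edit distance on the 60-bp window around the edit
  w_ref <- substr(ref$seq, 14465, 14525)
  w_mut <- substr(mut, 14465, 14521)
  expect_equal(drop(utils::adist(w_ref, w_mut)), 4)
  v <- extract_variants(aln, ref)
  expect_equal(nrow(v), 1L)
  expect_equal(v$kind, "deletion")
  expect_equal(nchar(v$ref), 4L)
  expect_equal(v$label, "14495-14502:AAAT2-1")
})

test_that("indel normalization reproduces the conventional labels", {
  ref <- test_ref()
  refc <- strsplit(ref$seq, "")[[1]]
  cases <- list(
    # insert C anywhere in the 303-309 poly-C: label anchors at 309
    list(edit = list(op = "ins", pos = 304, seq = "C"), label = "309insC",
         msi = TRUE),
    list(edit = list(op = "del", pos = 11033, len = 1),
         label = "11032-11038:A7-6", msi = FALSE),
    list(edit = list(op = "ins", pos = 11675, seq = "C"),
         label = "11673-11677:C5-6", msi = FALSE),
    list(edit = list(op = "del", pos = 514, len = 2), label = "523delCA",
         msi = TRUE),
    list(edit = list(op = "ins", pos = 16190, seq = "C"), label = "16193insC",
         msi = TRUE),
    list(edit = list(op = "del", pos = 13170, len = 1), label = "13170delA",
         msi = FALSE),
    list(edit = list(op = "del", pos = 4520, len = 2),
         label = "4520-4521delAC", msi = FALSE),
    list(edit = list(op = "ins", pos = 5835, seq = "T"), label = "5835insT",
         msi = FALSE)
  )
  for (cs in cases) {
    mut <- mutate_seq(ref$seq, list(cs$edit))
    v <- extract_variants(align_to_reference(mut, ref), ref)
    expect_equal(v$label, cs$label)
    expect_equal(v$mtMSI, cs$msi, label = cs$label)
  }
})

test_that("normalized indel position is independent of the deleted copy", {
  ref <- test_ref()
  m1 <- mutate_seq(ref$seq, list(list(op = "del", pos = 14495, len = 4)))
  m2 <- mutate_seq(ref$seq, list(list(op = "del", pos = 14499, len = 4)))
  v1 <- extract_variants(align_to_reference(m1, ref), ref)
  v2 <- extract_variants(align_to_reference(m2, ref), ref)
  expect_identical(v1$label, v2$label)
  expect_identical(v1$pos, v2$pos)
})

test_that("divergent or mis-sized sequences are rejected", {
  ref <- test_ref()
  expect_error(align_to_reference(strrep("A", 10000), ref), "outside")
  set.seed(5)
  junk <- paste(sample(c("A", "C", "G", "T"), 16569, TRUE), collapse = "")
  expect_error(align_to_reference(junk, ref), "not an mtDNA sequence")
})

test_that("round-trip recovery of planted variant sets", {
  ref <- test_ref()
  set.seed(11)
  pool <- setdiff(seq(700L, 16000L, by = 1L),
                  as.integer(names(mitovar:::synthetic_reference_constraints())))
  for (rep in 1:30) {
    n <- sample(3:12, 1)
    pos <- sort(sample(pool, n))
    pos <- pos[c(TRUE, diff(pos) >= 10)]
    edits <- lapply(pos, function(p)
      list(op = "sub", pos = p,
           base = sample(other_bases(ref_base(ref, p)), 1)))
    planted <- vapply(edits, function(e)
      paste0(ref_base(ref, e$pos), e$pos, e$base), character(1))
    mut <- mutate_seq(ref$seq, edits)
    v <- extract_variants(align_to_reference(mut, ref), ref)
    expect_setequal(v$label, planted)
  }
})

test_that("position 3107 and N bases are never called", {
  ref <- test_ref()
  mut <- mutate_seq(ref$seq, list(list(op = "sub", pos = 3107, base = "A")))
  v <- extract_variants(align_to_reference(mut, ref), ref)
  expect_equal(nrow(v), 0L)
})

test_that("heteroplasmy follows the dual-allele subset rule", {
  ref <- test_ref()
  m1 <- mutate_seq(ref$seq, list(list(op = "sub", pos = 6238, base = "C")))
  sam <- list(sample_id = "s.t", subject_id = "s", tissue = "tumor",
              alleles = c(m1, ref$seq))
  calls <- detect_heteroplasmy(sam, ref)
  expect_equal(calls$label, "T6238C")
  expect_equal(calls$zygosity, "heteroplasmic")
  expect_equal(calls$het_fraction, 0.5)
  # both alleles carrying the variant -> homoplasmic
  m2 <- mutate_seq(ref$seq, list(list(op = "sub", pos = 4875, base = "T")))
  sam2 <- list(sample_id = "s.t", subject_id = "s", tissue = "tumor",
               alleles = c(m2, m2))
  calls2 <- detect_heteroplasmy(sam2, ref)
  expect_equal(calls2$zygosity, "homoplasmic")
  expect_true(is.na(calls2$het_fraction))
  # IUPAC code expansion
  m3 <- mutate_seq(ref$seq, list(list(op = "sub", pos = 6238, base = "Y")))
  sam3 <- list(sample_id = "s.t", subject_id = "s", tissue = "tumor",
               alleles = m3)
  calls3 <- detect_heteroplasmy(sam3, ref)
  expect_equal(calls3$label, "T6238C")
  expect_equal(calls3$zygosity, "heteroplasmic")
  # grossly different allele lengths
  expect_error(detect_heteroplasmy(
    list(sample_id = "x", subject_id = "x", tissue = "tumor",
         alleles = c(ref$seq, strrep("A", 10000))), ref), "length")
})

test_that("somatic/germline classification follows the pairing rules", {
  ref <- test_ref()
  tv <- parse_variant_label("T6238C")
  tv$sample_id <- "s.t"; tv$tissue <- "tumor"; tv$subject_id <- "s"
  tv$zygosity <- "heteroplasmic"; tv$origin <- "undetermined"
  tv$het_fraction <- 0.5
  gv <- tv; gv$tissue <- "normal"; gv$sample_id <- "s.n"
  none <- tv[0, ]
  expect_equal(classify_origin(tv, none)$origin, "somatic")
  expect_equal(classify_origin(tv, gv)$origin, "germline")
  expect_equal(classify_origin(tv, NULL)$origin, "undetermined")
  # no call may be both germline and somatic
  both <- classify_origin(rbind(tv, tv), gv)
  expect_true(all(both$origin == "germline"))
  wrong <- gv; wrong$subject_id <- "other"
  expect_error(classify_origin(tv, wrong), "subject")
})

test_that("mtMSI flag is interval-based and substitution-safe", {
  expect_true(flag_mtMSI(parse_variant_label("309insC")))
  expect_true(flag_mtMSI(parse_variant_label("523delCA")))
  expect_false(flag_mtMSI(parse_variant_label("14495-14502:AAAT2-1")))
  expect_false(flag_mtMSI(parse_variant_label("A3243G")))
})

test_that("variation load applies the altered-positions formula", {
  ref <- test_ref()
  nd1 <- feature_by_name(ref, "ND1")
  calls <- do.call(rbind, lapply(c(3310, 3400, 3500, 3600, 3700),
                                 function(p) {
    v <- parse_variant_label(paste0(ref_base(ref, p), p, "A"))
    v
  }))
  res <- variation_load(calls, ref$features, "ND1")
  expect_equal(res$unit_length, 956L)
  expect_equal(res$load, 5 / 956 * 100)
  # duplicate positions count once
  res2 <- variation_load(rbind(calls, calls[1, ]), ref$features, "ND1")
  expect_equal(res2$altered_nucleotides, 5L)
  # no variants -> zero
  expect_equal(variation_load(calls[0, ], ref$features, "ND1")$load, 0)
  # complexes and wrapped control region
  expect_equal(variation_load(calls, ref$features, "Complex I")$unit_length,
               sum(c(956, 1042, 346, 1378, 297, 1812, 525)))
  expect_equal(variation_load(calls, ref$features, "D-loop")$unit_length, 1122L)
  expect_error(variation_load(calls, ref$features, "nope"), "unknown unit")
})

test_that("variant labels parse back to their coordinates", {
  for (lab in c("A3243G", "309insC", "523delCA", "11032-11038:A7-6",
                "14495-14502:AAAT2-1", "13170delA", "4520-4521delAC",
                "5835insT", "11673-11677:C5-6")) {
    v <- parse_variant_label(lab)
    expect_equal(variant_label(v), lab)
  }
  expect_error(parse_variant_label("C10400T!"), "back-mutation")
})
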