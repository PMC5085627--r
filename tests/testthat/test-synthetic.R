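test_that("cohort generation is seed-deterministic, byte for byte", {
  cfg <- sim_config(seed = 2, n_pairs = 3, n_controls = 3,
                    n_normal_thyroid = 1)
  d1 <- tempfile(); d2 <- tempfile()
  generate_cohort(cfg, dir = d1)
  generate_cohort(cfg, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("somatic_rate 0 gives identical tumor and normal sequences", {
  cfg <- sim_config(seed = 6, n_pairs = 3, n_controls = 0,
                    n_normal_thyroid = 0, somatic_rate = 0,
                    mtmsi_stutter_prob = 0)
  out <- generate_cohort(cfg, dir = tempfile())
  samples <- read_sample_fasta(out$paths$cohort_fasta)
  by_subject <- split(samples, vapply(samples, `[[`, character(1), "subject_id"))
  for (s in by_subject) {
    tum <- s[[which(vapply(s, `[[`, character(1), "tissue") == "tumor")]]
    nor <- s[[which(vapply(s, `[[`, character(1), "tissue") == "normal")]]
    expect_identical(tum$alleles, nor$alleles)
  }
})

test_that("heteroplasmy_prob 1 makes every somatic call heteroplasmic", {
  ref <- test_ref()
  cfg <- sim_config(seed = 9, n_pairs = 4, n_controls = 0,
                    n_normal_thyroid = 0, somatic_rate = 2,
                    heteroplasmy_prob = 1, mtmsi_stutter_prob = 0)
  out <- generate_cohort(cfg, dir = tempfile())
  samples <- read_sample_fasta(out$paths$cohort_fasta)
  calls <- call_cohort(samples, ref)
  som <- calls[calls$origin == "somatic", ]
  expect_gt(nrow(som), 0)
  expect_true(all(som$zygosity == "heteroplasmic"))
})

test_that("generated files round-trip through the package readers", {
  cfg <- sim_config(seed = 12, n_pairs = 2, n_controls = 2,
                    n_normal_thyroid = 1)
  out <- generate_cohort(cfg, dir = tempfile())
  samples <- read_sample_fasta(out$paths$cohort_fasta)
  expect_equal(length(samples), 2 * 2 + 1)
  expect_true(all(vapply(samples, function(s)
    all(nchar(s$alleles) >= 16000), logical(1))))
  ct <- read_ct_table(out$paths$ct_csv)
  expect_equal(nrow(ct), 2 * 2 * 2)
  expect_true(all(is.finite(ct$mean_ct)))
  clin <- utils::read.delim(out$paths$clinical_tsv)
  expect_equal(nrow(clin), 4)
  truth <- jsonlite::fromJSON(out$paths$truth_json)
  expect_equal(truth$config$seed, 12)
})

test_that("primate alignment generation records exact per-site truth", {
  ref <- test_ref()
  full <- generate_primate_alignment(ref, conserved_fraction = 1, seed = 1)
  expect_true(all(full$truth$ci_percent == 100))
  g <- generate_primate_alignment(ref, conserved_fraction = 0.85, seed = 2)
  expect_equal(dim(g$matrix), c(41L, 16569L))
  set.seed(4)
  for (p in sample.int(16569L, 50L)) {
    ci <- conservation_index(g$matrix[, p], g$matrix[1, p])
    expect_equal(ci$wildtype_count, g$truth$wildtype_count[p])
    expect_equal(ci$ci_percent, g$truth$ci_percent[p])
  }
  # FASTA round trip
  fa <- tempfile(fileext = ".fasta")
  generate_primate_alignment(ref, conserved_fraction = 0.9, seed = 3,
                             path = fa)
  m <- read_primate_alignment(fa)
  expect_equal(dim(m), c(41L, 16569L))
})

test_that("predictor-table generation honors the miscall rate", {
  labs <- sprintf("V%02d", 1:20)
  truth <- rep(c(TRUE, FALSE), 10)
  perfect <- generate_predictor_table(labs, truth, miscall_rate = 0, seed = 1)
  votes <- vapply(seq_len(nrow(perfect)), function(i)
    majority_vote(perfect[i, ])$vote_pathogenic, logical(1))
  expect_identical(votes, truth)
  hopeless <- generate_predictor_table(labs, truth, miscall_rate = 1, seed = 1)
  votes2 <- vapply(seq_len(nrow(hopeless)), function(i)
    majority_vote(hopeless[i, ])$vote_pathogenic, logical(1))
  expect_identical(votes2, !truth)
  pub <- generate_predictor_table(published = TRUE)
  expect_equal(nrow(pub), 25L)
  expect_identical(pub, predictor_profile_fixture())
})

test_that("bundled fixture files agree with the in-code tables", {
  prof_file <- read_predictor_table(mitovar_extdata("predictor_profiles.tsv"))
  prof <- predictor_profile_fixture()
  expect_identical(prof_file$label, prof$label)
  for (p in c("polyphen2", "sift", "mutation_assessor", "provean",
              "snp_and_go", "align_gvgd"))
    expect_identical(prof_file[[p]], prof[[p]])
  expect_equal(prof_file$panther_pdel, prof$panther_pdel)
  tm <- utils::read.delim(mitovar_extdata("truncating_mutations.tsv"))
  expect_identical(tm$label, truncating_mutation_fixture()$label)
  nv <- utils::read.delim(mitovar_extdata("novel_variants.tsv"))
  expect_identical(nv$label, novel_variant_fixture()$label)
})
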