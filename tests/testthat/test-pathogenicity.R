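test_that("per-program binarization matches the documented rules", {
  expect_false(binarize_predictor("align_gvgd", "C55"))
  expect_true(binarize_predictor("align_gvgd", "C65"))
  expect_true(binarize_predictor("panther_pdel", 0.5134))
  expect_false(binarize_predictor("panther_pdel", 0.5))
  expect_true(binarize_predictor("mutation_assessor", "Low"))
  expect_false(binarize_predictor("mutation_assessor", "Neutral"))
  expect_true(binarize_predictor("polyphen2", "Possibly"))
  expect_false(binarize_predictor("polyphen2", "Benign"))
  expect_true(binarize_predictor("sift", "NotTolerated"))
  expect_true(binarize_predictor("provean", "Deleterious"))
  expect_true(binarize_predictor("snp_and_go", "Disease"))
  expect_false(binarize_predictor("sift", NA))
  expect_error(binarize_predictor("sift", "Damaging"), "Damaging")
})

test_that("vote counts over the bundled profiles match the frozen oracle", {
  prof <- predictor_profile_fixture()
  votes <- vapply(seq_len(nrow(prof)), function(i)
    majority_vote(prof[i, ])$votes_deleterious, integer(1))
  # hand-derived per-row counts under the documented binarization
  expect_equal(votes, c(6L, 4L, 7L, 2L, 4L, 7L, 3L, 1L, 5L, 1L, 4L, 4L, 6L,
                        0L, 5L, 2L, 3L, 1L, 7L, 1L, 6L, 6L, 4L, 2L, 4L))
  expect_equal(sum(votes >= 4), 15L)
  # all-NA profile: zero votes
  empty <- prof[1, ]
  for (p in c("polyphen2", "sift", "mutation_assessor", "provean",
              "snp_and_go", "align_gvgd"))
    empty[[p]] <- NA_character_
  empty$panther_pdel <- NA_real_
  expect_equal(majority_vote(empty)$votes_deleterious, 0L)
})

test_that("candidate filters apply the frequency/tissue/conservation rules", {
  ok <- passes_candidate_filters(list(control_count = 2, control_total = 376,
                                      normal_thyroid_count = 0,
                                      ci_percent = 97.6))
  expect_true(ok$candidate)
  low_ci <- passes_candidate_filters(list(control_count = 0, control_total = 376,
                                          normal_thyroid_count = 0,
                                          ci_percent = 58.5))
  expect_false(low_ci$candidate)
  poly <- passes_candidate_filters(list(control_count = 4, control_total = 376,
                                        normal_thyroid_count = 0,
                                        ci_percent = 100))
  expect_false(poly$candidate)
  # exactly 1% resolves to polymorphism
  exact <- passes_candidate_filters(list(control_count = 4, control_total = 400,
                                         normal_thyroid_count = 0,
                                         ci_percent = 100))
  expect_false(exact$candidate)
  tissue <- passes_candidate_filters(list(control_count = 0, control_total = 376,
                                          normal_thyroid_count = 1,
                                          ci_percent = 100))
  expect_false(tissue$candidate)
  no_ci <- passes_candidate_filters(list(control_count = 0, control_total = 376,
                                         normal_thyroid_count = 0,
                                         ci_percent = NA))
  expect_false(no_ci$candidate)
  expect_true(any(grepl("CI unavailable", no_ci$reasons)))
})

test_that("novelty is a pure catalog lookup", {
  catalog <- read_catalog(mitovar_extdata("variant_catalog.tsv"))
  expect_false(is_novel("10952insC", catalog))
  expect_true(is_novel("G4969A", catalog))
  empty <- catalog[0, ]
  expect_true(all(is_novel(c("G4969A", "10952insC"), empty)))
})

test_that("final classification combines category gate, filters and vote", {
  prof <- predictor_profile_fixture()
  cons <- tibble::tibble(label = prof$label, category = "non-synonymous")
  ctx <- tibble::tibble(label = prof$label, control_count = prof$n_control,
                        control_total = 376L,
                        normal_thyroid_count = prof$n_thyroid,
                        ci_percent = prof$ci_percent)
  v <- classify_pathogenic(cons, ctx, prof)
  expect_equal(sum(v$final_pathogenic), 15L)
  # a synonymous variant with a perfect profile is never pathogenic
  cons_syn <- tibble::tibble(label = prof$label[3], category = "synonymous")
  v_syn <- classify_pathogenic(cons_syn, ctx, prof)
  expect_false(v_syn$final_pathogenic)
  # truncating mutations bypass the vote
  cons_tr <- tibble::tibble(label = c("x", "y"),
                            category = c("nonsense", "frameshift"))
  v_tr <- classify_pathogenic(cons_tr)
  expect_true(all(v_tr$final_pathogenic))
  # candidate without a profile is undetermined
  cons_np <- tibble::tibble(label = "G3392A", category = "non-synonymous")
  v_np <- classify_pathogenic(cons_np, ctx, profiles = NULL)
  expect_true(is.na(v_np$final_pathogenic))
  expect_match(v_np$reasons, "profile missing")
})

test_that("verdicts are order-invariant and vote-monotone", {
  prof <- predictor_profile_fixture()
  cons <- tibble::tibble(label = prof$label, category = "non-synonymous")
  ctx <- tibble::tibble(label = prof$label, control_count = prof$n_control,
                        control_total = 376L,
                        normal_thyroid_count = prof$n_thyroid,
                        ci_percent = prof$ci_percent)
  v1 <- classify_pathogenic(cons, ctx, prof)
  set.seed(3)
  perm <- sample.int(nrow(prof))
  v2 <- classify_pathogenic(cons[perm, ], ctx[sample.int(nrow(ctx)), ],
                            prof[sample.int(nrow(prof)), ])
  expect_identical(v1[order(v1$label), ], v2[order(v2$label), ])
  # adding a deleterious vote never flips pathogenic -> not
  for (i in seq_len(nrow(prof))) {
    before <- majority_vote(prof[i, ])
    boosted <- prof[i, ]
    if (is.na(boosted$panther_pdel) || boosted$panther_pdel <= 0.5) {
      boosted$panther_pdel <- 0.9
    } else boosted$polyphen2 <- "Probably"
    after <- majority_vote(boosted)
    expect_gte(after$votes_deleterious, before$votes_deleterious)
    if (before$vote_pathogenic) expect_true(after$vote_pathogenic)
  }
  # lowering the control frequency never demotes a candidate
  for (i in seq_len(nrow(prof))) {
    base <- list(control_count = prof$n_control[i], control_total = 376,
                 normal_thyroid_count = prof$n_thyroid[i],
                 ci_percent = prof$ci_percent[i])
    lower <- base; lower$control_count <- 0
    if (passes_candidate_filters(base)$candidate)
      expect_true(passes_candidate_filters(lower)$candidate)
  }
})
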