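# Synthetic cohort generation with recorded ground truth.
#
# The generator emulates the study design the analysis assumes: paired
# tumor/adjacent-normal whole-mtDNA sequences for 66 subjects, 16 normal
# thyroid tissues and 376 blood controls; per-subject haplogroup
# backbones drawn on the bundled tree; Poisson-distributed somatic
# substitutions in tumors (heteroplasmic with a configurable
# probability); microsatellite stutter indels in the three repeat
# windows; log-normal tumor copy-number fold changes measured through
# noisy triplicate Ct values; and an optional planted case-control mtSNP
# enrichment at a requested odds ratio.

#' Simulation configuration
#'
#' Defaults are the emulated study conditions: 66 tumor/normal pairs, 16
#' normal thyroid tissues, 376 blood controls, ~0.8 somatic mutations per
#' tumor (52 somatic calls across 66 tumors), somatic mutations
#' heteroplasmic, stutter probability 0.3 per repeat window, mean log2
#' tumor/normal copy-number fold 2 (an average near four-fold) with SD 1,
#' and 0.15-cycle replicate Ct noise.
#'
#' @param seed Integer master seed; every output is a deterministic
#'   function of it.
#' @param n_pairs,n_controls,n_normal_thyroid Cohort sizes.
#' @param haplogroup_frequencies Named probabilities over tree leaves.
#' @param somatic_rate Mean somatic substitutions per tumor (Poisson).
#' @param heteroplasmy_prob Probability a somatic mutation is
#'   heteroplasmic.
#' @param mtmsi_stutter_prob Per-window stutter probability per tumor.
#' @param pathogenic_fraction Fraction of somatic substitutions drawn
#'   from stop-gain-capable codon positions.
#' @param log2_fold_mean,log2_fold_sd Tumor/normal log2 fold-change
#'   distribution.
#' @param ct_noise_sd Replicate Ct noise (cycles).
#' @param snp_panel mtSNP labels genotyped in everyone.
#' @param planted_association Optional list \code{(label, or,
#'   control_prob)} enriching one mtSNP in cases.
#' @return List of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L, n_pairs = 66L, n_controls = 376L,
                       n_normal_thyroid = 16L,
                       haplogroup_frequencies = c(
                         C = 0.11, D4 = 0.12, G = 0.11, Z = 0.11,
                         A4 = 0.12, B4a = 0.11, B4g = 0.05, F = 0.10,
                         R = 0.09, Y = 0.08),
                       somatic_rate = 0.8, heteroplasmy_prob = 1.0,
                       mtmsi_stutter_prob = 0.3,
                       pathogenic_fraction = 0.25,
                       log2_fold_mean = 2, log2_fold_sd = 1,
                       ct_noise_sd = 0.15,
                       snp_panel = c("G709A", "G5460A", "T6680C", "G9123A",
                                     "A14587G", "A16164G", "C16266T",
                                     "T16362C"),
                       planted_association = NULL) {
  stopifnot(somatic_rate >= 0, heteroplasmy_prob >= 0, heteroplasmy_prob <= 1,
            mtmsi_stutter_prob >= 0, mtmsi_stutter_prob <= 1,
            pathogenic_fraction >= 0, pathogenic_fraction <= 1,
            abs(sum(haplogroup_frequencies) - 1) < 1e-6)
  if (!is.null(planted_association)) {
    p0 <- planted_association$control_prob
    or <- planted_association$or
    p1 <- or * p0 / (1 - p0 + or * p0)
    if (!is.finite(p1) || p1 <= 0 || p1 >= 1)
      stop("infeasible planted odds ratio / control frequency combination")
    planted_association$case_prob <- p1
  }
  structure(list(
    seed = as.integer(seed), n_pairs = as.integer(n_pairs),
    n_controls = as.integer(n_controls),
    n_normal_thyroid = as.integer(n_normal_thyroid),
    haplogroup_frequencies = haplogroup_frequencies,
    somatic_rate = somatic_rate, heteroplasmy_prob = heteroplasmy_prob,
    mtmsi_stutter_prob = mtmsi_stutter_prob,
    pathogenic_fraction = pathogenic_fraction,
    log2_fold_mean = log2_fold_mean, log2_fold_sd = log2_fold_sd,
    ct_noise_sd = ct_noise_sd, snp_panel = snp_panel,
    planted_association = planted_association), class = "sim_config")
}

# Deterministic sub-stream: outputs drawn under sub-seeds so adding an
# output never perturbs existing ones.  Kept below 2^31.
sub_seed <- function(config, k) {
  as.integer((as.numeric(config$seed) * 1009L + k * 9973L) %% 2147483647L)
}

apply_variants_to_seq <- function(seq, variants) {
  if (!nrow(variants)) return(seq)
  v <- variants[order(-variants$pos), ]
  for (i in seq_len(nrow(v))) {
    if (v$kind[i] == "substitution") {
      substr(seq, v$pos[i], v$pos[i]) <- v$alt[i]
    } else if (v$kind[i] == "deletion") {
      seq <- paste0(substr(seq, 1L, v$pos[i] - 1L),
                    substr(seq, v$end[i] + 1L, nchar(seq)))
    } else {
      seq <- paste0(substr(seq, 1L, v$pos[i]), v$alt[i],
                    substr(seq, v$pos[i] + 1L, nchar(seq)))
    }
  }
  seq
}

# Positions where a single substitution creates a stop codon (stop-gain
# capable sites), with the required alternate base.
stop_gain_sites <- function(reference) {
  if (!is.null(.mitovar_cache$stop_gain)) return(.mitovar_cache$stop_gain)
  prot <- reference$features[reference$features$kind == "protein" &
                             reference$features$strand == "H", ]
  out <- list()
  for (i in seq_len(nrow(prot))) {
    f <- prot[i, ]
    cds <- cds_sequence(reference, f)
    n <- nchar(cds) %/% 3L
    for (k in seq_len(n - 1L)) {
      codon <- substr(cds, 3L * k - 2L, 3L * k)
      hit <- switch(codon,
        TGG = c(2L, "A"),     # -> TAG
        GGA = c(1L, "A"),     # -> AGA
        TTA = c(2L, "A"),     # -> TAA
        TCA = c(2L, "A"),     # Ser TCA -> TAA? no: TCA pos2 C->A = TAA
        NULL)
      if (is.null(hit)) next
      pos <- f$start + 3L * (k - 1L) + as.integer(hit[1L]) - 1L
      out[[length(out) + 1L]] <-
        tibble::tibble(pos = pos, ref = substr(reference$seq, pos, pos),
                       alt = hit[2L], gene = f$name)
    }
  }
  res <- do.call(rbind, out)
  .mitovar_cache$stop_gain <- res
  res
}

# Positions eligible for random somatic substitutions: outside every
# frozen fixture context, repeat window and tract, and outside local
# homopolymers.
somatic_site_pool <- function(reference) {
  if (!is.null(.mitovar_cache$somatic_pool)) return(.mitovar_cache$somatic_pool)
  banned <- unique(c(
    as.integer(names(synthetic_reference_constraints())),
    unlist(Map(seq.int, mtmsi_windows()$start - 2L, mtmsi_windows()$end + 2L)),
    3107L))
  refc <- strsplit(reference$seq, "", fixed = TRUE)[[1L]]
  pool <- setdiff(600L:16000L, banned)
  # drop sites inside homopolymers of length >= 3 (keeps truth unambiguous)
  keep <- vapply(pool, function(p) {
    w <- refc[max(1L, p - 2L):min(MT_LENGTH, p + 2L)]
    r <- rle(w)
    all(r$lengths < 3L)
  }, logical(1))
  res <- pool[keep]
  .mitovar_cache$somatic_pool <- res
  res
}

draw_somatic <- function(config, reference, n) {
  pool <- somatic_site_pool(reference)
  sg <- stop_gain_sites(reference)
  sg <- sg[sg$pos %in% pool, ]
  out <- list(); used <- integer(0)
  for (i in seq_len(n)) {
    for (try in 1:50) {
      if (stats::runif(1) < config$pathogenic_fraction && nrow(sg)) {
        j <- sample.int(nrow(sg), 1L)
        pos <- sg$pos[j]; ref <- sg$ref[j]; alt <- sg$alt[j]
      } else {
        pos <- sample(pool, 1L)
        ref <- substr(reference$seq, pos, pos)
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
      }
      if (!length(used) || min(abs(used - pos)) >= 10L) break
    }
    if (length(used) && min(abs(used - pos)) < 10L) next
    used <- c(used, pos)
    v <- variant_tibble(pos, pos, "substitution", ref, alt, "", FALSE,
                        NA, NA, NA_character_, NA, NA)
    v$label <- variant_label(v)
    out[[length(out) + 1L]] <- v
  }
  if (!length(out)) return(variant_tibble())
  do.call(rbind, out)
}

stutter_variant <- function(reference, window_idx, insertion) {
  refc <- strsplit(reference$seq, "", fixed = TRUE)[[1L]]
  anchor <- c(309L, 523L, 16193L)[window_idx]
  unit <- c("C", "CA", "C")[window_idx]
  if (insertion) normalize_indel(refc, anchor, unit, "insertion")
  else normalize_indel(refc, anchor - nchar(unit) + 1L,
                       paste(refc[(anchor - nchar(unit) + 1L):anchor],
                             collapse = ""), "deletion")
}

draw_haplogroups <- function(config, tree, n) {
  leaves <- names(config$haplogroup_frequencies)
  stopifnot(all(leaves %in% tree$node))
  sample(leaves, n, replace = TRUE, prob = config$haplogroup_frequencies)
}

snp_carriage <- function(config, n, base_probs, planted_prob = NULL) {
  panel <- config$snp_panel
  out <- vector("list", n)
  for (i in seq_len(n)) {
    carried <- panel[stats::runif(length(panel)) < base_probs]
    pa <- config$planted_association
    if (!is.null(pa) && !is.null(planted_prob)) {
      carried <- setdiff(carried, pa$label)
      if (stats::runif(1) < planted_prob) carried <- c(carried, pa$label)
    }
    out[[i]] <- carried
  }
  out
}

#' Generate a synthetic study cohort
#'
#' Writes a run directory containing \code{cohort.fasta} (tumor,
#' adjacent-normal and normal-thyroid records, headers
#' \code{subject|tissue|allele}), \code{controls.fasta} (blood controls),
#' \code{ct.csv} (triplicate Ct values per tissue), \code{clinical.tsv}
#' (per-individual group/haplogroup/mtSNP table) and \code{truth.json}
#' (planted ground truth), plus \code{manifest.json}.  Regenerating with
#' the same configuration yields byte-identical files.
#'
#' @param config A \code{\link{sim_config}}.
#' @param reference A \code{mito_reference} (default the synthetic one).
#' @param tree A \code{haplo_tree} (default the bundled mini tree).
#' @param dir Output directory.
#' @return Invisibly, a list with the truth tables and file paths.
#' @export
generate_cohort <- function(config, reference = synthetic_reference(),
                            tree = mini_haplo_tree(), dir) {
  stopifnot(inherits(config, "sim_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  # -- haplogroups and germline genotypes ------------------------------
  set.seed(sub_seed(config, 1L))
  hap_cases <- draw_haplogroups(config, tree, config$n_pairs)
  hap_thyroid <- draw_haplogroups(config, tree, config$n_normal_thyroid)
  hap_controls <- draw_haplogroups(config, tree, config$n_controls)
  base_probs <- stats::runif(length(config$snp_panel), 0.05, 0.35)
  names(base_probs) <- config$snp_panel
  pa <- config$planted_association
  snps_cases <- snp_carriage(config, config$n_pairs, base_probs,
                             if (!is.null(pa)) pa$case_prob)
  snps_controls <- snp_carriage(config, config$n_controls, base_probs,
                                if (!is.null(pa)) pa$control_prob)
  snps_thyroid <- snp_carriage(config, config$n_normal_thyroid, base_probs,
                               if (!is.null(pa)) pa$control_prob)

  germline_variants <- function(hap, snps) {
    labs <- unique(c(path_variants(tree, hap), snps))
    if (!length(labs)) return(variant_tibble())
    do.call(rbind, lapply(labs, parse_variant_label))
  }

  # -- somatic events --------------------------------------------------
  set.seed(sub_seed(config, 2L))
  truth_rows <- list()
  fasta_records <- list()
  add_record <- function(subject, tissue, allele_idx, seq) {
    fasta_records[[length(fasta_records) + 1L]] <<-
      list(name = paste(subject, tissue, allele_idx, sep = "|"), seq = seq)
  }
  add_truth <- function(subject, tissue, label, zygosity, origin) {
    truth_rows[[length(truth_rows) + 1L]] <<- tibble::tibble(
      subject_id = subject, tissue = tissue, label = label,
      zygosity = zygosity, origin = origin)
  }

  for (i in seq_len(config$n_pairs)) {
    subject <- sprintf("case%02d", i)
    germ <- germline_variants(hap_cases[i], snps_cases[[i]])
    germ_seq <- apply_variants_to_seq(reference$seq, germ)
    n_som <- stats::rpois(1L, config$somatic_rate)
    som <- draw_somatic(config, reference, n_som)
    if (nrow(som)) {
      # avoid germline collisions within 10 nt
      keep <- vapply(som$pos, function(p)
        !nrow(germ) || min(abs(germ$pos - p)) >= 10L, logical(1))
      som <- som[keep, , drop = FALSE]
    }
    som_het <- if (nrow(som))
      stats::runif(nrow(som)) < config$heteroplasmy_prob else logical(0)
    stutter <- list()
    for (w in 1:3) if (stats::runif(1) < config$mtmsi_stutter_prob)
      stutter[[length(stutter) + 1L]] <- stutter_variant(reference, w,
                                                         stats::runif(1) < 0.6)
    stutter <- if (length(stutter)) do.call(rbind, stutter) else variant_tibble()
    stut_het <- if (nrow(stutter))
      stats::runif(nrow(stutter)) < config$heteroplasmy_prob else logical(0)

    som_all <- rbind(som, stutter)
    het_all <- c(som_het, stut_het)
    homo_idx <- which(!het_all)
    tumor_a1 <- apply_variants_to_seq(
      germ_seq, som_all[homo_idx, , drop = FALSE])
    add_record(subject, "normal", 1L, germ_seq)
    if (any(het_all)) {
      tumor_a2 <- apply_variants_to_seq(germ_seq, som_all)
      add_record(subject, "tumor", 1L, tumor_a1)
      add_record(subject, "tumor", 2L, tumor_a2)
    } else {
      add_record(subject, "tumor", 1L, tumor_a1)
    }
    for (l in germ$label) {
      add_truth(subject, "tumor", l, "homoplasmic", "germline")
      add_truth(subject, "normal", l, "homoplasmic", "germline")
    }
    for (k in seq_len(nrow(som_all)))
      add_truth(subject, "tumor", som_all$label[k],
                if (het_all[k]) "heteroplasmic" else "homoplasmic", "somatic")
  }
  for (i in seq_len(config$n_normal_thyroid)) {
    subject <- sprintf("thy%02d", i)
    germ <- germline_variants(hap_thyroid[i], snps_thyroid[[i]])
    add_record(subject, "normal-thyroid", 1L,
               apply_variants_to_seq(reference$seq, germ))
    for (l in germ$label)
      add_truth(subject, "normal-thyroid", l, "homoplasmic", "germline")
  }
  control_records <- list()
  for (i in seq_len(config$n_controls)) {
    subject <- sprintf("ctrl%03d", i)
    germ <- germline_variants(hap_controls[i], snps_controls[[i]])
    control_records[[length(control_records) + 1L]] <-
      list(name = paste(subject, "blood-control", 1L, sep = "|"),
           seq = apply_variants_to_seq(reference$seq, germ))
    for (l in germ$label)
      add_truth(subject, "blood-control", l, "homoplasmic", "germline")
  }

  # -- copy number -----------------------------------------------------
  set.seed(sub_seed(config, 3L))
  cn <- sim_copy_number_draw(config)
  ct_rows <- list()
  for (i in seq_len(config$n_pairs)) {
    subject <- sprintf("case%02d", i)
    for (tis in c("tumor", "normal")) {
      content <- if (tis == "tumor") cn$content_tumor[i] else cn$content_normal[i]
      ct_nuc <- stats::rnorm(1L, 24, 0.3)
      ct_mt <- ct_nuc - log2(content)
      for (tgt in c("mt", "nuclear")) {
        base <- if (tgt == "mt") ct_mt else ct_nuc
        reps <- round(base + stats::rnorm(3L, 0, config$ct_noise_sd), 3L)
        ct_rows[[length(ct_rows) + 1L]] <- tibble::tibble(
          sample_id = paste(subject, tis, sep = "."), tissue = tis,
          target = tgt, ct1 = reps[1L], ct2 = reps[2L], ct3 = reps[3L])
      }
    }
  }
  ct <- do.call(rbind, ct_rows)

  # -- clinical table --------------------------------------------------
  set.seed(sub_seed(config, 4L))
  clin <- tibble::tibble(
    id = c(sprintf("case%02d", seq_len(config$n_pairs)),
           sprintf("ctrl%03d", seq_len(config$n_controls))),
    group = c(rep("case", config$n_pairs), rep("control", config$n_controls)),
    haplogroup = c(hap_cases, hap_controls),
    snp_list = vapply(c(snps_cases, snps_controls),
                      function(s) paste(sort(s), collapse = ","), character(1)),
    age_group = sample(c("young", "old"),
                       config$n_pairs + config$n_controls, TRUE),
    stage = c(sample(c("I-II", "III-IV"), config$n_pairs, TRUE),
              rep(NA_character_, config$n_controls)))

  truth <- do.call(rbind, truth_rows)
  truth_list <- list(
    config = unclass(config),
    haplogroups = list(cases = as.list(stats::setNames(hap_cases,
                         sprintf("case%02d", seq_len(config$n_pairs)))),
                       thyroid = as.list(stats::setNames(hap_thyroid,
                         sprintf("thy%02d", seq_len(config$n_normal_thyroid)))),
                       controls = as.list(stats::setNames(hap_controls,
                         sprintf("ctrl%03d", seq_len(config$n_controls))))),
    fold_change = as.list(stats::setNames(cn$true_fold,
                         sprintf("case%02d", seq_len(config$n_pairs)))),
    variants = truth)

  # -- writing ---------------------------------------------------------
  write_fasta <- function(records, path) {
    ss <- Biostrings::DNAStringSet(vapply(records, `[[`, character(1), "seq"))
    names(ss) <- vapply(records, `[[`, character(1), "name")
    Biostrings::writeXStringSet(ss, path, width = 70L)
  }
  paths <- list(
    cohort_fasta = file.path(dir, "cohort.fasta"),
    controls_fasta = file.path(dir, "controls.fasta"),
    ct_csv = file.path(dir, "ct.csv"),
    clinical_tsv = file.path(dir, "clinical.tsv"),
    truth_json = file.path(dir, "truth.json"),
    manifest_json = file.path(dir, "manifest.json"))
  write_fasta(fasta_records, paths$cohort_fasta)
  write_fasta(control_records, paths$controls_fasta)
  utils::write.csv(ct, paths$ct_csv, row.names = FALSE, quote = FALSE)
  utils::write.table(clin, paths$clinical_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(truth_list, paths$truth_json, auto_unbox = TRUE,
                       digits = NA)
  jsonlite::write_json(list(seed = config$seed,
                            files = lapply(paths, basename)),
                       paths$manifest_json, auto_unbox = TRUE)
  invisible(list(truth = truth_list, paths = paths))
}

# Per-subject true contents and fold changes (no side effects on files).
sim_copy_number_draw <- function(config) {
  n <- config$n_pairs
  content_normal <- 2^stats::rnorm(n, 6.6, 0.5)
  true_fold <- 2^stats::rnorm(n, config$log2_fold_mean, config$log2_fold_sd)
  tibble::tibble(content_normal = content_normal,
                 content_tumor = content_normal * true_fold,
                 true_fold = true_fold)
}

#' Simulate paired copy-number contents only
#'
#' Fast path for statistical experiments: draws the per-subject true
#' normal content and tumor fold change of \code{\link{generate_cohort}}
#' without writing sequences.
#'
#' @param config A \code{\link{sim_config}}.
#' @return Tibble with \code{content_normal}, \code{content_tumor},
#'   \code{true_fold}.
#' @export
sim_copy_number <- function(config) {
  set.seed(sub_seed(config, 3L))
  sim_copy_number_draw(config)
}

#' Simulate case/control genotype label sets only
#'
#' Fast path for association experiments: per-individual mtSNP carriage
#' sets (plus haplogroup names) under the same stream as
#' \code{\link{generate_cohort}}, without sequences.
#'
#' @param config A \code{\link{sim_config}}.
#' @param tree A \code{haplo_tree}.
#' @return List with \code{case_sets}, \code{control_sets},
#'   \code{hap_cases}, \code{hap_controls}.
#' @export
sim_genotypes <- function(config, tree = mini_haplo_tree()) {
  set.seed(sub_seed(config, 1L))
  hap_cases <- draw_haplogroups(config, tree, config$n_pairs)
  invisible(draw_haplogroups(config, tree, config$n_normal_thyroid))
  hap_controls <- draw_haplogroups(config, tree, config$n_controls)
  base_probs <- stats::runif(length(config$snp_panel), 0.05, 0.35)
  pa <- config$planted_association
  case_sets <- snp_carriage(config, config$n_pairs, base_probs,
                            if (!is.null(pa)) pa$case_prob)
  control_sets <- snp_carriage(config, config$n_controls, base_probs,
                               if (!is.null(pa)) pa$control_prob)
  list(case_sets = Map(c, case_sets, hap_cases),
       control_sets = Map(c, control_sets, hap_controls),
       hap_cases = hap_cases, hap_controls = hap_controls)
}

#' Generate a 41-primate alignment with known per-site conservation
#'
#' Row 1 is the human sequence (the reference); each non-human row keeps
#' the human base with probability \code{conserved_fraction} per site and
#' otherwise mutates to one of the other three bases.  The realized
#' wild-type count per site is returned as truth.
#'
#' @param reference A \code{mito_reference}.
#' @param conserved_fraction Per-site, per-species retention probability.
#' @param seed Integer seed.
#' @param path Optional FASTA output path.
#' @return List with \code{matrix} (41 x L characters), \code{truth}
#'   (tibble of \code{position}, \code{wildtype_count}, \code{ci_percent})
#'   and \code{path}.
#' @export
generate_primate_alignment <- function(reference, conserved_fraction = 0.9,
                                       seed = 1L, path = NULL) {
  stopifnot(conserved_fraction >= 0, conserved_fraction <= 1)
  set.seed(as.integer(seed))
  human <- strsplit(reference$seq, "", fixed = TRUE)[[1L]]
  L <- length(human)
  bases <- c("A", "C", "G", "T")
  m <- matrix("", nrow = 41L, ncol = L)
  m[1L, ] <- human
  for (r in 2:41) {
    keep <- stats::runif(L) < conserved_fraction
    row <- human
    idx <- which(!keep)
    if (length(idx)) {
      alt <- vapply(human[idx], function(b)
        sample(setdiff(bases, b), 1L), character(1))
      row[idx] <- alt
    }
    m[r, ] <- row
  }
  rownames(m) <- c("human", sprintf("primate%02d", 1:40))
  wt <- colSums(m == matrix(human, 41L, L, byrow = TRUE))
  truth <- tibble::tibble(position = seq_len(L), wildtype_count = wt,
                          ci_percent = wt / 41 * 100)
  if (!is.null(path)) {
    ss <- Biostrings::BStringSet(apply(m, 1L, paste, collapse = ""))
    Biostrings::writeXStringSet(ss, path, width = 70L)
  }
  list(matrix = m, truth = truth, path = path)
}

#' Generate predictor profiles for planted variants
#'
#' Planted-pathogenic variants receive a profile with at least 4
#' deleterious calls with probability \code{1 - miscall_rate} (and a
#' benign profile otherwise); other variants the reverse.  With
#' \code{published = TRUE} the packaged example predictor table is
#' returned verbatim.
#'
#' @param labels Character vector of variant labels.
#' @param pathogenic Logical vector: planted truth per label.
#' @param miscall_rate Probability of flipping a profile.
#' @param seed Integer seed.
#' @param published Return the bundled published-profile fixture instead.
#' @return Predictor tibble as read by \code{\link{read_predictor_table}}.
#' @export
generate_predictor_table <- function(labels = character(0),
                                     pathogenic = logical(0),
                                     miscall_rate = 0, seed = 1L,
                                     published = FALSE) {
  if (published) return(predictor_profile_fixture())
  stopifnot(length(labels) == length(pathogenic),
            miscall_rate >= 0, miscall_rate <= 1)
  set.seed(as.integer(seed))
  deleterious <- tibble::tibble(
    polyphen2 = "Probably", sift = "NotTolerated", mutation_assessor = "High",
    provean = "Deleterious", snp_and_go = "Disease", align_gvgd = "C65",
    panther_pdel = 0.9)
  benign <- tibble::tibble(
    polyphen2 = "Benign", sift = "Tolerated", mutation_assessor = "Neutral",
    provean = "Neutral", snp_and_go = "Neutral", align_gvgd = "C15",
    panther_pdel = 0.1)
  rows <- lapply(seq_along(labels), function(i) {
    want_del <- xor(pathogenic[i], stats::runif(1) < miscall_rate)
    prof <- if (want_del) deleterious else benign
    cbind(tibble::tibble(label = labels[i]), prof)
  })
  if (!length(rows)) {
    out <- cbind(tibble::tibble(label = character(0)), deleterious[0, ])
    return(tibble::as_tibble(out))
  }
  tibble::as_tibble(do.call(rbind, rows))
}
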