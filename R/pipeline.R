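# End-to-end orchestration: variant calling over a cohort, annotation,
# pathogenicity classification, haplogroups, copy number, association,
# and report tables.  The report layer only collates stage outputs; every
# number is computed by a stage.

#' Call variants across a cohort FASTA
#'
#' Runs \code{\link{detect_heteroplasmy}} on every sample and
#' \code{\link{classify_origin}} on tumor/normal pairs.
#'
#' @param samples List of samples from \code{\link{read_sample_fasta}}.
#' @param reference A \code{mito_reference}.
#' @return Call tibble with a \code{gene} column.
#' @export
call_cohort <- function(samples, reference) {
  calls <- lapply(samples, detect_heteroplasmy, reference = reference)
  names(calls) <- vapply(samples, `[[`, character(1), "sample_id")
  tissue_of <- vapply(samples, `[[`, character(1), "tissue")
  subject_of <- vapply(samples, `[[`, character(1), "subject_id")
  out <- list()
  for (i in seq_along(samples)) {
    cc <- calls[[i]]
    if (tissue_of[i] == "tumor") {
      j <- which(subject_of == subject_of[i] & tissue_of == "normal")
      cc <- classify_origin(cc, if (length(j)) calls[[j[1L]]] else NULL)
    } else if (tissue_of[i] %in% c("normal", "normal-thyroid", "blood-control")) {
      if (nrow(cc)) cc$origin <- "germline"
    }
    out[[i]] <- cc
  }
  res <- do.call(rbind, out)
  if (is.null(res) || !nrow(res)) return(res)
  res$gene <- vapply(res$pos, function(p) {
    f <- feature_at(reference, p)
    if (nrow(f)) paste(f$name, collapse = ",") else NA_character_
  }, character(1))
  res
}

#' Annotate consequences for a call table
#'
#' @param calls Call tibble (unique variants are annotated once).
#' @param reference A \code{mito_reference}.
#' @return Consequence tibble keyed by \code{label}.
#' @export
annotate_cohort <- function(calls, reference) {
  uniq <- calls[!duplicated(calls$label), , drop = FALSE]
  out <- lapply(seq_len(nrow(uniq)), function(i) {
    v <- uniq[i, ]
    if (v$kind == "substitution") annotate_substitution(v, reference)
    else annotate_indel(v, reference)
  })
  do.call(rbind, out)
}

#' Pipeline run configuration
#'
#' Bundles input paths and thresholds.  Thresholds default to the
#' standard screen: conservation cutoff CI > 75%, polymorphism cutoff
#' 1%, vote threshold 4 of 7, significance level 0.05.
#'
#' @param reference_fasta,annotation_tsv,catalog_tsv,tree_path Input paths
#'   (defaults: the bundled fixtures).
#' @param cohort_fasta,controls_fasta,ct_csv,clinical_tsv Cohort inputs
#'   (e.g. from \code{\link{generate_cohort}}).
#' @param predictor_tsv Optional predictor table path.
#' @param ci_cutoff,freq_cutoff,vote_threshold,alpha Thresholds.
#' @return List of class \code{run_config}.
#' @export
run_config <- function(reference_fasta = mitovar_extdata("synthetic_mtdna.fasta"),
                       annotation_tsv = mitovar_extdata("mito_genes.tsv"),
                       catalog_tsv = mitovar_extdata("variant_catalog.tsv"),
                       tree_path = mitovar_extdata("haplo_tree.tsv"),
                       cohort_fasta = NULL, controls_fasta = NULL,
                       ct_csv = NULL, clinical_tsv = NULL,
                       predictor_tsv = NULL,
                       ci_cutoff = 75, freq_cutoff = 0.01,
                       vote_threshold = 4L, alpha = 0.05) {
  structure(as.list(environment()), class = "run_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' The YAML keys mirror the arguments of \code{\link{run_config}};
#' missing keys keep their defaults.
#'
#' @param path YAML file path.
#' @return A \code{run_config}.
#' @export
run_config_from_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

#' Run the full characterization pipeline
#'
#' Calls variants over the cohort, annotates consequences, classifies
#' pathogenicity (novelty against the catalog; candidate contexts from
#' observed cohort/control counts; predictor profiles from
#' \code{predictor_tsv} when supplied), assigns haplogroups, computes
#' relative copy number and tumor/normal fold changes, screens
#' case-control factors, and writes report tables plus a JSON summary
#' into \code{out_dir}.
#'
#' @param config A \code{\link{run_config}}.
#' @param out_dir Output directory.
#' @return List of report tables and the summary list.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  reference <- stage("reference",
    load_reference(config$reference_fasta, config$annotation_tsv))
  catalog <- stage("catalog", read_catalog(config$catalog_tsv))
  tree <- stage("tree", load_tree(config$tree_path))

  samples <- stage("read-cohort", read_sample_fasta(config$cohort_fasta))
  calls <- stage("call", call_cohort(samples, reference))
  consequences <- stage("annotate", annotate_cohort(calls, reference))
  calls$novel <- is_novel(calls$label, catalog)

  control_calls <- NULL
  if (!is.null(config$controls_fasta)) {
    controls <- stage("read-controls", read_sample_fasta(config$controls_fasta))
    control_calls <- stage("call-controls", call_cohort(controls, reference))
  }

  # candidate contexts from observed counts
  tissue_of <- vapply(samples, `[[`, character(1), "tissue")
  n_thyroid <- sum(tissue_of == "normal-thyroid")
  n_controls <- if (is.null(control_calls)) 0L
                else length(unique(control_calls$sample_id))
  uniq_labels <- unique(calls$label)
  contexts <- tibble::tibble(
    label = uniq_labels,
    control_count = vapply(uniq_labels, function(l)
      if (is.null(control_calls)) 0L
      else length(unique(control_calls$sample_id[control_calls$label == l])),
      integer(1)),
    control_total = max(1L, n_controls),
    normal_thyroid_count = vapply(uniq_labels, function(l)
      length(unique(calls$sample_id[calls$label == l &
                                    calls$tissue == "normal-thyroid"])),
      integer(1)),
    ci_percent = NA_real_)

  profiles <- if (!is.null(config$predictor_tsv))
    read_predictor_table(config$predictor_tsv) else NULL
  verdicts <- stage("classify", classify_pathogenic(
    consequences, contexts, profiles,
    vote_threshold = config$vote_threshold,
    ci_cutoff = config$ci_cutoff, freq_cutoff = config$freq_cutoff))

  # haplogroups per subject (tumor or single-tissue sample variant sets)
  subj <- unique(tibble::tibble(
    subject_id = vapply(samples, `[[`, character(1), "subject_id"),
    tissue = tissue_of))
  hap <- do.call(rbind, lapply(unique(subj$subject_id), function(s) {
    labs <- calls$label[calls$subject_id == s]
    cbind(tibble::tibble(sample_id = s), assign_haplogroup(labs, tree))
  }))

  # copy number
  cn <- NULL
  if (!is.null(config$ct_csv)) {
    ct <- stage("ct", read_ct_table(config$ct_csv))
    ids <- unique(ct$sample_id)
    cn <- do.call(rbind, lapply(ids, function(id) {
      mt <- ct[ct$sample_id == id & ct$target == "mt", ]
      nc <- ct[ct$sample_id == id & ct$target == "nuclear", ]
      relative_content(mt[1L, ], nc[1L, ])
    }))
    cn$subject_id <- sub("\\.(tumor|normal)$", "", cn$sample_id)
    tum <- cn[cn$tissue == "tumor", ]
    nor <- cn[cn$tissue == "normal", ]
    shared <- intersect(tum$subject_id, nor$subject_id)
    fc <- vapply(shared, function(s)
      fold_change(tum[tum$subject_id == s, ], nor[nor$subject_id == s, ]),
      numeric(1))
    cn_summary <- list(
      n_pairs = length(shared),
      n_increased = sum(fc > 1),
      mean_of_ratios = mean(fc),
      ratio_of_means = mean(tum$relative_content[match(shared, tum$subject_id)]) /
        mean(nor$relative_content[match(shared, nor$subject_id)]),
      test = cohort_compare(tum$relative_content[match(shared, tum$subject_id)],
                            nor$relative_content[match(shared, nor$subject_id)]))
    cn <- list(contents = cn, fold_change =
                 tibble::tibble(subject_id = shared, fold = fc),
               summary = cn_summary)
  }

  # association screen (haplogroups + mtSNP labels from the clinical table)
  assoc <- NULL
  if (!is.null(config$clinical_tsv)) {
    clin <- utils::read.delim(config$clinical_tsv, stringsAsFactors = FALSE,
                              na.strings = c("NA", ""))
    sets <- lapply(seq_len(nrow(clin)), function(i) {
      snps <- if (is.na(clin$snp_list[i])) character(0)
              else strsplit(clin$snp_list[i], ",", fixed = TRUE)[[1L]]
      c(clin$haplogroup[i], snps)
    })
    case_sets <- sets[clin$group == "case"]
    control_sets <- sets[clin$group == "control"]
    factors <- unique(unlist(sets))
    assoc <- stage("associate",
                   screen_factors(case_sets, control_sets, factors,
                                  alpha = config$alpha))
  }

  summary <- list(
    n_samples = length(samples),
    n_calls = nrow(calls),
    n_sites = length(unique(calls$pos)),
    n_novel = sum(calls$novel[!duplicated(calls$label)]),
    n_heteroplasmic = sum(calls$zygosity == "heteroplasmic"),
    n_somatic = sum(calls$origin == "somatic"),
    n_pathogenic = sum(verdicts$final_pathogenic, na.rm = TRUE),
    increased_copy_number_fraction =
      if (is.null(cn)) NA else cn$summary$n_increased / cn$summary$n_pairs)

  tabs <- list(calls = calls, consequences = consequences,
               verdicts = verdicts, haplogroups = hap,
               copy_number = cn, association = assoc, summary = summary)
  utils::write.table(calls, file.path(out_dir, "variant_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(consequences, file.path(out_dir, "consequence_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(verdicts, file.path(out_dir, "pathogenicity_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(hap, file.path(out_dir, "haplogroup_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(assoc))
    utils::write.table(assoc, file.path(out_dir, "association_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(tabs)
}

#' Export a call table as VCF
#'
#' VCF 4.2 on contig \code{chrM} (length 16,569).  Indels are
#' left-aligned with an anchor base per the VCF convention; the INFO
#' field carries the package's 3'-anchored canonical label plus
#' zygosity, origin and the microsatellite flag.
#'
#' @param calls Call tibble (may be empty).
#' @param reference A \code{mito_reference}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
export_vcf <- function(calls, reference, path) {
  refc <- strsplit(reference$seq, "", fixed = TRUE)[[1L]]
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chrM,length=16569>",
    "##INFO=<ID=LABEL,Number=1,Type=String,Description=\"Canonical 3'-anchored variant label\">",
    "##INFO=<ID=ZYG,Number=1,Type=String,Description=\"Zygosity call\">",
    "##INFO=<ID=ORIGIN,Number=1,Type=String,Description=\"Somatic/germline origin\">",
    "##INFO=<ID=MTMSI,Number=0,Type=Flag,Description=\"Microsatellite-instability window indel\">",
    "##INFO=<ID=SAMPLE,Number=1,Type=String,Description=\"Sample identifier\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"))
  body <- character(0)
  for (i in seq_len(nrow(calls))) {
    v <- calls[i, ]
    if (v$kind == "substitution") {
      pos <- v$pos; ref <- v$ref; alt <- v$alt
    } else if (v$kind == "deletion") {
      p <- v$pos; L <- v$end - v$pos + 1L
      while (p > 1L && refc[p - 1L] == refc[p + L - 1L]) p <- p - 1L
      pos <- p - 1L
      ref <- paste(refc[(p - 1L):(p + L - 1L)], collapse = "")
      alt <- refc[p - 1L]
    } else {
      p <- v$pos; ins <- v$alt; L <- nchar(ins)
      while (p > 0L && p >= 1L &&
             substr(ins, L, L) == refc[p]) {
        ins <- paste0(refc[p], substr(ins, 1L, L - 1L))
        p <- p - 1L
      }
      pos <- max(p, 1L)
      ref <- refc[pos]
      alt <- paste0(refc[pos], ins)
    }
    info <- sprintf("LABEL=%s;ZYG=%s;ORIGIN=%s%s%s", v$label,
                    if ("zygosity" %in% names(v)) v$zygosity else ".",
                    if ("origin" %in% names(v)) v$origin else ".",
                    if (isTRUE(v$mtMSI)) ";MTMSI" else "",
                    if ("sample_id" %in% names(v))
                      paste0(";SAMPLE=", v$sample_id) else "")
    body <- c(body, paste("chrM", pos, ".", ref, alt, ".", "PASS", info,
                          sep = "\t"))
  }
  writeLines(c(header, body), path)
  invisible(path)
}
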