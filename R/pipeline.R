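#' Run the full genotyping and haplotyping pipeline
#'
#' Orchestrates the stages in order: merge indistinguishable genes for the
#' protocol, assign reads, detect undocumented allele candidates and apply
#' the filter battery, augment the reference with passing candidates,
#' re-assign against the individual-specific directories, genotype V and D
#' genes, call TRBD2 genotype groups, test for double chromosome deletions,
#' infer haplotypes for samples heterozygous at the anchor, and compute
#' genotype-stratified usage.
#'
#' @param samples named list of read tibbles (`sequence_id`, `sequence`),
#'   or a directory containing one AIRR TSV per sample.
#' @param germline a [germline_set()] with V, D and J records.
#' @param protocol a [protocol_spec()].
#' @param out_dir optional output directory; stage TSVs and a JSON run
#'   manifest are written there.
#' @param min_support,chimera_filter novel-allele filter settings.
#' @param anchor_gene haplotype anchor (`"TRBJ1-6"` or `"TRBD2"`).
#' @param lk_threshold haplotype confidence floor.
#' @param min_cutoff,alpha deletion-test settings.
#' @param epsilon_v V genotyping mis-assignment probability.
#' @return List with the per-stage results: `assignments`, `candidates`,
#'   `novel_alleles`, `genotypes_v`, `genotypes_d`, `d2_model`,
#'   `deletions`, `haplotypes`, `family_usage`, `manifest`.
#' @export
run_pipeline <- function(samples, germline, protocol, out_dir = NULL,
                         min_support = 0.05, chimera_filter = TRUE,
                         anchor_gene = "TRBJ1-6", lk_threshold = 2,
                         min_cutoff = 0.0005, alpha = 0.01,
                         epsilon_v = 0.01) {
  if (is.character(samples)) {
    files <- list.files(samples, pattern = "\\.tsv$", full.names = TRUE)
    if (length(files) == 0L) {
      stop_trbkit("no input samples found", "trbkit_no_input")
    }
    samples <- lapply(files, read_airr)
    names(samples) <- sub("\\.tsv$", "", basename(files))
  }
  if (length(samples) == 0L) {
    stop_trbkit("no input samples", "trbkit_no_input")
  }
  counts <- list()
  merged <- merge_indistinguishable(germline, protocol)

  assigned <- lapply(names(samples), function(sid) {
    assign_rearrangements(samples[[sid]], merged, protocol, sample_id = sid)
  })
  names(assigned) <- names(samples)
  counts$assigned <- vapply(assigned, nrow, integer(1))

  # undocumented allele stage: per-sample detection, population modality
  cand_list <- lapply(assigned, detect_novel_candidates,
                      set = merged, protocol = protocol)
  all_cand <- dplyr::bind_rows(cand_list, .id = "sample_id")
  pop_fracs <- NULL
  best_cand <- all_cand[0, , drop = FALSE]
  if (nrow(all_cand) > 0L) {
    pop_fracs <- lapply(split(all_cand, all_cand$name),
                        function(d) d$support_fraction)
    best_cand <- all_cand[order(all_cand$name, -all_cand$support_fraction), ]
    best_cand <- best_cand[!duplicated(best_cand$name), , drop = FALSE]
    best_cand <- apply_novel_filters(best_cand, merged, protocol,
                                     population_fractions = pop_fracs,
                                     min_support = min_support,
                                     chimera_filter = chimera_filter)
  }
  novel <- if ("pass" %in% names(best_cand)) {
    best_cand[best_cand$pass, , drop = FALSE]
  } else best_cand
  counts$novel_candidates <- nrow(best_cand)
  counts$novel_passing <- nrow(novel)

  augmented <- augment_reference(merged, novel)
  if (nrow(augmented) > nrow(merged)) {
    assigned <- lapply(names(samples), function(sid) {
      assign_rearrangements(samples[[sid]], augmented, protocol,
                            sample_id = sid)
    })
    names(assigned) <- names(samples)
  }

  genotypes_v <- dplyr::bind_rows(
    lapply(assigned, genotype_sample, segment = "V", epsilon = epsilon_v),
    .id = "sample_id")
  genotypes_d <- dplyr::bind_rows(
    lapply(assigned, genotype_sample, segment = "D"), .id = "sample_id")
  genotypes_j <- dplyr::bind_rows(
    lapply(assigned, genotype_sample, segment = "J"), .id = "sample_id")

  d2_fracs <- vapply(assigned, function(df) {
    suppressWarnings(trbd2_fraction(df))
  }, numeric(1))
  d2_model <- NULL
  if (sum(!is.na(d2_fracs)) >= 3L) {
    d2_model <- suppressWarnings(call_d2_groups(d2_fracs))
  }

  all_assigned <- dplyr::bind_rows(assigned)
  usage <- usage_table(all_assigned)
  deletions <- deletion_tests(usage, min_cutoff = min_cutoff, alpha = alpha)

  haplotypes <- list()
  for (sid in names(assigned)) {
    gj <- genotypes_j[genotypes_j$sample_id == sid &
                        genotypes_j$gene == anchor_gene, , drop = FALSE]
    het <- nrow(gj) == 1L && length(strsplit(gj$alleles, ";")[[1]]) == 2L
    if (!het) next
    anchor_alleles <- strsplit(gj$alleles, ";")[[1]]
    eps <- choose_epsilon(assigned[[sid]], anchor_gene)
    haplotypes[[sid]] <- tryCatch(
      infer_haplotype(assigned[[sid]], anchor_gene, anchor_alleles,
                      epsilon = eps, lk_threshold = lk_threshold),
      trbkit_error = function(e) NULL)
  }
  haplotypes <- dplyr::bind_rows(haplotypes)

  fam_usage <- dplyr::bind_rows(
    lapply(assigned, function(df) tibble::as_tibble(as.list(family_usage(df)))),
    .id = "sample_id")

  manifest <- list(
    package_version = as.character(utils::packageVersion("trbkit")),
    protocol = protocol$name,
    n_samples = length(samples),
    counts = counts)
  result <- list(assignments = assigned, candidates = best_cand,
                 novel_alleles = novel, genotypes_v = genotypes_v,
                 genotypes_d = genotypes_d, genotypes_j = genotypes_j,
                 d2_model = d2_model, deletions = deletions,
                 haplotypes = haplotypes, family_usage = fam_usage,
                 manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (sid in names(assigned)) {
      write_airr(assigned[[sid]], file.path(out_dir,
                                            paste0(sid, "_assigned.tsv")))
    }
    readr::write_tsv(genotypes_v, file.path(out_dir, "genotypes_v.tsv"))
    readr::write_tsv(genotypes_d, file.path(out_dir, "genotypes_d.tsv"))
    readr::write_tsv(deletions, file.path(out_dir, "deletions.tsv"))
    if (nrow(haplotypes) > 0L) {
      readr::write_tsv(haplotypes, file.path(out_dir, "haplotypes.tsv"))
    }
    if (!is.null(d2_model)) {
      readr::write_tsv(d2_model$samples, file.path(out_dir, "d2_groups.tsv"))
    }
    manifest$input_hashes <- NULL
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  result
}
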