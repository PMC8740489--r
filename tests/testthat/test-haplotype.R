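test_that("epsilon follows the dominant TRBD2 allele", {
  df02 <- tibble::tibble(d_call = c(rep("TRBD2*02", 80), rep("TRBD2*01", 20)))
  df01 <- tibble::tibble(d_call = c(rep("TRBD2*01", 80), rep("TRBD2*02", 20)))
  expect_equal(choose_epsilon(df02, "TRBD2"), 0.125)
  expect_equal(choose_epsilon(df01, "TRBD2"), 0.04)
  expect_equal(choose_epsilon(df01, "TRBJ1-6"), 0.01)
})

make_anchored_reads <- function(gene_counts, anchor_gene = "TRBJ1-6") {
  # gene_counts: tibble(v_name, n1, n2) -> reads with the anchor allele
  rows <- list()
  for (i in seq_len(nrow(gene_counts))) {
    gc <- gene_counts[i, ]
    rows[[i]] <- tibble::tibble(
      v_call = gc$v_name,
      j_call = c(rep(paste0(anchor_gene, "*01"), gc$n1),
                 rep(paste0(anchor_gene, "*02"), gc$n2)),
      d_call = NA_character_, sample_id = "s1")
  }
  dplyr::bind_rows(rows)
}

test_that("allele placement follows the binomial model with anchor flips", {
  df <- make_anchored_reads(tibble::tibble(
    v_name = c("TRBVA*01", "TRBVB*01", "TRBVB*02", "TRBVC*01"),
    n1 = c(30L, 25L, 1L, 2L),
    n2 = c(0L, 1L, 24L, 1L)))
  hp <- infer_haplotype(df, "TRBJ1-6", c("01", "02"), epsilon = 0.01)
  a <- hp[hp$gene == "TRBVA", ]
  # allele on chromosome 1 only; no evidence of the gene on chromosome 2
  expect_equal(a$chromosome_1, "01")
  expect_equal(a$chromosome_2, "Del")
  b <- hp[hp$gene == "TRBVB", ]
  expect_equal(b$chromosome_1, "01")
  expect_equal(b$chromosome_2, "02")
  # genes below the informative-read floor stay unknown
  expect_equal(hp$chromosome_1[hp$gene == "TRBVC"], "Unk")
  # balanced counts: present on both chromosomes
  both <- make_anchored_reads(tibble::tibble(v_name = "TRBVD*01",
                                             n1 = 25L, n2 = 25L))
  both <- dplyr::bind_rows(both, make_anchored_reads(tibble::tibble(
    v_name = "TRBVE*01", n1 = 10L, n2 = 12L)))
  hp2 <- infer_haplotype(both, "TRBJ1-6", c("01", "02"), epsilon = 0.01)
  expect_equal(hp2$chromosome_1[hp2$gene == "TRBVD"], "01")
  expect_equal(hp2$chromosome_2[hp2$gene == "TRBVD"], "01")
})

test_that("swapping anchor labels transposes the haplotype table", {
  df <- make_anchored_reads(tibble::tibble(
    v_name = c("TRBVA*01", "TRBVB*01", "TRBVB*02"),
    n1 = c(30L, 25L, 1L), n2 = c(1L, 2L, 28L)))
  hp <- infer_haplotype(df, "TRBJ1-6", c("01", "02"), epsilon = 0.01)
  hp_sw <- infer_haplotype(df, "TRBJ1-6", c("02", "01"), epsilon = 0.01)
  expect_equal(hp$chromosome_1, hp_sw$chromosome_2)
  expect_equal(hp$chromosome_2, hp_sw$chromosome_1)
  expect_equal(hp$n1, hp_sw$n2)
})

test_that("non-heterozygous anchors are refused", {
  df <- make_anchored_reads(tibble::tibble(v_name = "TRBVA*01",
                                           n1 = 20L, n2 = 0L))
  expect_error(infer_haplotype(df, "TRBJ1-6", c("01", "02")),
               class = "trbkit_not_heterozygous")
})

test_that("clean simulated haplotypes are recovered, with the cis deletion", {
  run <- sim_and_assign(seed = 77, n_individuals = 2, depth = 14000,
                        error_rate = 0,
                        force_het = c("TRBJ1-6", "TRBV7-2"))
  mg <- attr(run$merged, "merged_genes")
  label_of <- function(g) {
    for (grp in mg) if (g %in% grp) return(paste(sort(grp), collapse = "/"))
    g
  }
  for (sid in names(run$assigned)) {
    truth <- run$sim$truth[[sid]]
    j16 <- c(truth$haplotype[[1]][["TRBJ1-6"]],
             truth$haplotype[[2]][["TRBJ1-6"]])
    hp <- infer_haplotype(run$assigned[[sid]], "TRBJ1-6", c("01", "02"),
                          epsilon = 0.01)
    # chromosome k of the inference carries anchor allele 0k
    chr_for <- function(allele) which(j16 == allele)
    for (g in hp$gene) {
      for (k in 1:2) {
        want <- truth$haplotype[[chr_for(c("01", "02")[k])]]
        truth_gene <- names(want)[!is.na(want) &
                                    vapply(names(want), label_of,
                                           character(1)) == g]
        state <- hp[[paste0("chromosome_", k)]][hp$gene == g]
        n_here <- hp[[paste0("n", k)]][hp$gene == g]
        if (n_here < 10L || state == "Unk") next
        if (state == "Del") {
          expect_equal(length(truth_gene), 0L,
                       label = paste(sid, g, "chr", k, "Del"))
        } else {
          expect_setequal(strsplit(state, ";")[[1]],
                          unique(unname(want[truth_gene])))
        }
      }
    }
    # the TRBV7-2*02 chromosome shows the linked TRBV4-3 deletion
    tag_chr <- which(c(truth$haplotype[[1]][["TRBV7-2"]],
                       truth$haplotype[[2]][["TRBV7-2"]]) == "02")
    k <- which(c("01", "02") == j16[tag_chr])
    expect_equal(hp[[paste0("chromosome_", k)]][hp$gene == "TRBV4-3"], "Del",
                 label = paste(sid, "cis deletion on anchor chr", k))
  }
})
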