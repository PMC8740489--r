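# Fixture: reads carrying an engineered SNP against the toy reference.
make_snp_reads <- function(gene = "TRBV19", pos = 30L, n_carrier = 40L,
                           n_plain = 60L, seed = 1L) {
  set <- toy_germline_set()
  prot <- protocol_spec("full")
  merged <- merge_indistinguishable(set, prot)
  base <- merged$seq[merged$name == paste0(gene, "*01")]
  ref <- substr(base, pos, pos)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  snp_seq <- base
  substr(snp_seq, pos, pos) <- alt
  j <- merged[merged$segment == "J", ]
  d2 <- merged$seq[merged$name == "TRBD2*01"]
  withr::with_seed(seed, {
    mk <- function(vseq, n) {
      js <- sample(j$name, n, replace = TRUE)
      ins <- vapply(seq_len(n), function(i) {
        paste(sample(c("A", "C", "G", "T"), sample(0:4, 1), TRUE),
              collapse = "")
      }, character(1))
      paste0(vseq, ins, d2, merged$seq[match(js, merged$name)])
    }
    seqs <- c(mk(snp_seq, n_carrier), mk(base, n_plain))
  })
  list(merged = merged, prot = prot, seqs = seqs,
       name = paste0(gene, "*01_", ref, pos, alt), ref = ref, alt = alt)
}

test_that("recurrent SNP patterns become candidates with exact support", {
  fx <- make_snp_reads(n_carrier = 40L, n_plain = 60L)
  a <- assign_rearrangements(fx$seqs, fx$merged, fx$prot)
  cands <- detect_novel_candidates(a, fx$merged, fx$prot, gene = "TRBV19")
  expect_equal(nrow(cands), 1L)
  expect_equal(cands$name, fx$name)
  expect_equal(cands$support_fraction, 0.40)
  expect_equal(cands$snps[[1]]$pos, 30L)
  # no mismatches, no candidates
  clean <- make_snp_reads(n_carrier = 0L, n_plain = 50L)
  a2 <- assign_rearrangements(clean$seqs, clean$merged, clean$prot)
  expect_equal(nrow(detect_novel_candidates(a2, clean$merged, clean$prot,
                                            gene = "TRBV19")), 0L)
})

test_that("SNPs in the primer guard region are not counted", {
  # boundary starts at sequence start + 5 under the full protocol: a SNP
  # at position 5 sits inside the guard and must not yield a candidate
  fx <- make_snp_reads(pos = 5L, n_carrier = 40L, n_plain = 60L)
  a <- assign_rearrangements(fx$seqs, fx$merged, fx$prot)
  cands <- detect_novel_candidates(a, fx$merged, fx$prot, gene = "TRBV19")
  expect_false(fx$name %in% cands$name)
})

test_that("the filter battery flags support, diversity, stretch and modality", {
  fx <- make_snp_reads(n_carrier = 40L, n_plain = 60L)
  a <- assign_rearrangements(fx$seqs, fx$merged, fx$prot)
  cands <- detect_novel_candidates(a, fx$merged, fx$prot, gene = "TRBV19")
  flagged <- apply_novel_filters(cands, fx$merged, fx$prot)
  expect_true(flagged$pass)

  # support below 5% fails
  low <- cands
  low$support_fraction <- 0.04
  expect_false(apply_novel_filters(low, fx$merged, fx$prot)$pass_support)
  # single CDR3 length or single J gene fails diversity
  mono <- cands
  mono$cdr3_length_count <- 1L
  expect_false(apply_novel_filters(mono, fx$merged, fx$prot)$pass_diversity)
  monoj <- cands
  monoj$j_gene_count <- 1L
  expect_false(apply_novel_filters(monoj, fx$merged, fx$prot)$pass_diversity)
  # two SNPs within four adjacent positions fail the stretch rule
  stretch <- cands
  stretch$snps <- list(tibble::tibble(ref = c("A", "A"), pos = c(30L, 32L),
                                      alt = c("G", "C")))
  expect_false(apply_novel_filters(stretch, fx$merged,
                                   fx$prot)$pass_snp_stretch)
  wide <- cands
  wide$snps <- list(tibble::tibble(ref = c("A", "A"), pos = c(30L, 38L),
                                   alt = c("G", "C")))
  expect_true(apply_novel_filters(wide, fx$merged, fx$prot)$pass_snp_stretch)
  # uni-modal low-fraction population distribution fails modality
  pop_low <- stats::setNames(list(rep(0.06, 8)), cands$name)
  expect_false(apply_novel_filters(cands, fx$merged, fx$prot,
                                   population_fractions = pop_low)$pass_modality)
  pop_het <- stats::setNames(list(c(rep(0.06, 4), rep(0.5, 4))), cands$name)
  expect_true(apply_novel_filters(cands, fx$merged, fx$prot,
                                  population_fractions = pop_het)$pass_modality)
})

test_that("chimeric candidates are recognised by the exhaustive breakpoint scan", {
  set <- toy_germline_set()
  prot <- protocol_spec("full")
  merged <- merge_indistinguishable(set, prot)
  wins <- window_alleles(merged[merged$segment == "V", ], prot)
  bw <- c(start = 6L, end = 51L)
  ga <- wins[wins$name == "TRBV15*01", ]
  gb <- wins[wins$name == "TRBV18*01", ]
  k <- 20L
  chim <- paste0(substr(ga$window, bw["start"], k),
                 substr(gb$window, k + 1L, bw["end"]))
  expect_true(chimera_possible(chim, wins, bw, "TRBV15"))
  # a genuine mid-window SNP candidate cannot be stitched from two genes:
  # any prefix covering the SNP and any suffix covering it both fail
  cand <- substr(ga$window, bw["start"], bw["end"])
  mid <- 20L
  substr(cand, mid, mid) <- setdiff(c("A", "C", "G", "T"),
                                    substr(cand, mid, mid))[1]
  expect_false(chimera_possible(cand, wins, bw, "TRBV15"))
})

test_that("no candidate carries SNPs outside the boundary window", {
  run <- sim_and_assign(seed = 31, n_individuals = 3, depth = 800,
                        error_rate = 0.003)
  for (sid in names(run$assigned)) {
    cands <- detect_novel_candidates(run$assigned[[sid]], run$merged,
                                     run$protocol)
    for (s in cands$snps) {
      expect_true(all(s$pos >= 6L & s$pos <= 51L))
    }
  }
})

test_that("upstream consensus reports majority and split variants", {
  prot <- protocol_spec("full")
  ups <- rep("TATAAGGCTGG", 50)
  res <- upstream_consensus(ups, prot)
  expect_equal(res$consensus, "TATAAGGCTGG")
  expect_equal(res$depth, 50L)
  # 60/40 split at one position with threshold 0.3: two variants
  mix <- c(rep("TATAAGGCTGG", 60), rep("TATACGGCTGG", 40))
  res2 <- upstream_consensus(mix, prot, cluster_threshold = 0.3)
  expect_equal(nrow(res2), 2L)
  expect_setequal(res2$consensus, c("TATAAGGCTGG", "TATACGGCTGG"))
  expect_setequal(res2$depth, c(60L, 40L))
  expect_error(upstream_consensus(ups, toy_protocol("adaptive")),
               class = "trbkit_unsupported_protocol")
})

test_that("augmented references gain the novel allele and support re-assignment", {
  fx <- make_snp_reads(n_carrier = 40L, n_plain = 60L)
  a <- assign_rearrangements(fx$seqs, fx$merged, fx$prot)
  cands <- detect_novel_candidates(a, fx$merged, fx$prot, gene = "TRBV19")
  cands <- apply_novel_filters(cands, fx$merged, fx$prot)
  aug <- augment_reference(fx$merged, cands)
  expect_true(fx$name %in% aug$name)
  a2 <- assign_rearrangements(fx$seqs, aug, fx$prot)
  # carrier reads now assign to the novel allele with zero mismatches
  expect_equal(sum(a2$v_call == fx$name), 40L)
  expect_true(all(a2$v_mismatches[a2$v_call == fx$name] == 0L))
})
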