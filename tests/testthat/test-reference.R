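test_that("FASTA loading parses both header dialects and strips IMGT gaps", {
  fa <- system.file("extdata", "gapped_v_demo.fasta", package = "trbkit")
  set <- load_reference(fa, segment = "V")
  expect_equal(nrow(set), 3L)
  expect_equal(set$gene, c("TRBV91-1", "TRBV91-1", "TRBV91-2"))
  expect_equal(set$allele, c("01", "02", "01"))
  # gaps stripped: ungapped sequence, map skips gap positions
  expect_false(grepl(".", set$seq[1], fixed = TRUE))
  raw <- readLines(fa)
  expect_equal(regap(set$seq[1], set$gapped_map[[1]]), raw[2])
  expect_equal(regap(set$seq[2], set$gapped_map[[2]]), raw[4])
  # bare-header record has the identity map
  expect_equal(set$gapped_map[[3]], seq_len(nchar(set$seq[3])))
})

test_that("reference loading rejects duplicates and bad characters", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">TRBVX*01", "ACGT", ">TRBVX*01", "ACGG"), f)
  expect_error(load_reference(f), class = "trbkit_duplicate_allele")
  writeLines(c(">TRBVX*01", "ACGN"), f)
  expect_error(load_reference(f), "TRBVX", class = "trbkit_bad_sequence")
  writeLines(character(), f)
  expect_warning(set <- load_reference(f), "empty")
  expect_equal(nrow(set), 0L)
})

test_that("reference round-trips through write_reference", {
  set <- toy_germline_set()
  f <- withr::local_tempfile(fileext = ".fasta")
  write_reference(set, f)
  back <- load_reference(f)
  expect_equal(back$name, set$name)
  expect_equal(back$seq, set$seq)
})

test_that("protocol windows restrict V alleles as configured", {
  set <- toy_germline_set()
  full <- window_alleles(set[set$segment == "V", ], protocol_spec("full"))
  expect_equal(full$window, set$seq[set$segment == "V"])
  # partial protocol: suffix from the first position after the primer
  toy_len <- nchar(set$seq[set$segment == "V"][1])
  bio <- window_alleles(set[set$segment == "V", ], toy_protocol("biomed2"))
  expect_true(all(nchar(bio$window) == toy_len - 15L))
  expect_true(all(bio$window_start_imgt == 16L))
  one <- set[set$name == "TRBV9*01", ]
  expect_equal(bio$window[bio$name == "TRBV9*01"],
               substr(one$seq, 16L, toy_len))
  # primer config read back from YAML behaves identically
  yml <- system.file("extdata", "biomed2_demo.yaml", package = "trbkit")
  prot <- read_protocol(yml)
  expect_s3_class(prot, "protocol_spec")
  expect_equal(prot$per_gene_primer_end[["TRBV91-1"]], 8L)
})

test_that("genes without a primer raise MissingPrimer", {
  set <- toy_germline_set()
  prot <- toy_protocol("biomed2", missing_primer_gene = "TRBV12-3")
  expect_error(
    window_alleles(set[set$name == "TRBV12-3*01", ], prot),
    class = "trbkit_missing_primer")
})

test_that("pair distance matches the brute-force oracle on random pairs", {
  expect_equal(gene_pair_distance("ACGT", "ACGT"), 0L)
  expect_equal(gene_pair_distance("ACGT", "ACGA"), 1L)
  # suffix windows of unequal length align free at the padded beginning
  expect_equal(pad_align_cost("CGT", "ACGT"), 0L)
  withr::with_seed(404, {
    for (i in 1:60) {
      a <- paste(sample(c("A", "C", "G", "T"), sample(3:12, 1), TRUE),
                 collapse = "")
      b <- paste(sample(c("A", "C", "G", "T"), sample(3:12, 1), TRUE),
                 collapse = "")
      expect_equal(pad_align_cost(a, b), oracle_pad_cost(a, b))
      expect_equal(pad_align_cost(a, b), pad_align_cost(b, a))
    }
  })
  expect_error(gene_pair_distance(character(), "A"),
               class = "trbkit_empty_windows")
})

test_that("indistinguishable genes merge per protocol, transitively and monotonically", {
  set <- toy_germline_set()
  merged_of <- function(p) {
    m <- merge_indistinguishable(set, p)
    sort(vapply(attr(m, "merged_genes"), paste, character(1), collapse = "/"))
  }
  full <- merged_of(protocol_spec("full"))
  bio <- merged_of(toy_protocol("biomed2"))
  ada <- merged_of(toy_protocol("adaptive"))
  expect_equal(full, "TRBV6-2/TRBV6-3")
  expect_equal(bio, c("TRBV12-3/TRBV12-4", "TRBV6-2/TRBV6-3"))
  expect_equal(ada, c("TRBV12-3/TRBV12-4", "TRBV3-1/TRBV3-2",
                      "TRBV6-2/TRBV6-3"))
  # protocol monotone: shorter windows merge at least as much
  expect_true(all(full %in% bio))
  expect_true(all(bio %in% ada))
  # idempotent
  m1 <- merge_indistinguishable(set, toy_protocol("biomed2"))
  m2 <- merge_indistinguishable(m1, toy_protocol("biomed2"))
  expect_equal(m2$name, m1$name)
  # identical alleles of a merged pair collapse under a single name
  expect_true("TRBV6-2/TRBV6-3*01" %in% m1$name)
})

test_that("pattern groups partition alleles with identical windows", {
  set <- toy_germline_set()
  for (pname in c("full", "biomed2", "adaptive")) {
    prot <- toy_protocol(pname)
    merged <- merge_indistinguishable(set, prot)
    pats <- collapse_patterns(merged, prot)
    wins <- window_alleles(merged[merged$segment == "V", ], prot)
    # partition: every allele in exactly one group
    members <- unlist(pats$members)
    expect_setequal(members, wins$name)
    expect_false(anyDuplicated(members) > 0)
    for (i in seq_len(nrow(pats))) {
      w <- wins$window[match(pats$members[[i]], wins$name)]
      expect_true(all(w == pats$representative[i]))
    }
    # across groups of one gene, representatives differ
    for (g in unique(pats$gene)) {
      reps <- pats$representative[pats$gene == g]
      expect_false(anyDuplicated(reps) > 0)
    }
  }
})

test_that("pattern naming follows the protocol prefix convention", {
  set <- toy_germline_set()
  bio <- collapse_patterns(merge_indistinguishable(set, toy_protocol("biomed2")),
                           toy_protocol("biomed2"))
  expect_true(all(grepl("\\*bp[0-9][0-9]$", bio$pattern_name)))
  ada <- collapse_patterns(merge_indistinguishable(set, toy_protocol("adaptive")),
                           toy_protocol("adaptive"))
  expect_true(all(grepl("\\*ap[0-9][0-9]$", ada$pattern_name)))
  # dense numbering from 01 within each gene
  for (g in unique(bio$pattern_name)) expect_match(g, "\\*bp0[1-9]$")
  # full protocol: singleton groups keep the allele's own name
  full <- collapse_patterns(merge_indistinguishable(set, protocol_spec("full")),
                            protocol_spec("full"))
  singles <- lengths(full$members) == 1L
  expect_equal(full$pattern_name[singles],
               unlist(full$members[singles]))
  # representative comes from the longest full reference in the group
  m <- merge_indistinguishable(set, toy_protocol("biomed2"))
  pats <- collapse_patterns(m, toy_protocol("biomed2"))
  grp <- pats[pats$gene == "TRBV12-3/TRBV12-4" & lengths(pats$members) > 1, ]
  expect_gte(nrow(grp), 1L)
})
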