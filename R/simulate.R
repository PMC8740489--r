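# Ground-truthed synthetic repertoire generator. The bundled toy germline
# set echoes the real TRB locus structure (a V panel with indistinguishable
# gene pairs and allelic variants, the two short G-rich D genes with the
# single-SNP TRBD2 allele pair, and the two J families including biallelic
# TRBJ1-6) at reduced V length so simulations stay fast; the TRBD2 and
# TRBD1 sequences are the real 16 bp / 12 bp germline sequences.

.trbkit_env <- new.env(parent = emptyenv())

TOY_V_GENES <- c(
  "TRBV2", "TRBV3-1", "TRBV3-2", "TRBV4-1", "TRBV4-3", "TRBV5-1",
  "TRBV6-1", "TRBV6-2", "TRBV6-3", "TRBV7-2", "TRBV7-3", "TRBV9",
  "TRBV10-1", "TRBV11-1", "TRBV12-3", "TRBV12-4", "TRBV13", "TRBV15",
  "TRBV18", "TRBV19", "TRBV20-1", "TRBV24-1", "TRBV25-1", "TRBV27",
  "TRBV28", "TRBV29-1", "TRBV30")

# gene -> IMGT position of the allele-*02 SNP (all inside the full-length
# boundary window 6..60; ensures novel-style names such as 02 variants)
TOY_BIALLELIC <- c("TRBV7-2" = 45L, "TRBV24-1" = 40L, "TRBV20-1" = 38L,
                   "TRBV6-1" = 42L, "TRBV12-3" = 44L, "TRBV5-1" = 39L,
                   "TRBV9" = 41L, "TRBV28" = 47L)

TOY_V_LEN <- 60L
TOY_J_LEN <- 30L
TOY_CYS_POS <- 52L   # TGT codon anchoring the junction 5' end
TOY_PHE_POS <- 10L   # TTC codon anchoring the junction 3' end within J

random_coding_seq <- function(len) {
  repeat {
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
    if (!has_stop_codon(s)) return(s)
  }
}

apply_snp <- function(seq, pos, alt) {
  substr(seq, pos, pos) <- alt
  seq
}

# a substitution at `pos` that differs from the reference base and keeps
# the translation from `frame_start` stop-free
pick_alt <- function(seq, pos, frame_start = 1L) {
  ref <- substr(seq, pos, pos)
  for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
    mut <- apply_snp(seq, pos, alt)
    if (!has_stop_codon(substr(mut, frame_start, nchar(mut)))) return(alt)
  }
  stop("no stop-free substitution at position ", pos)
}

#' Bundled toy TRB germline set
#'
#' A deterministic synthetic reference (27 V genes of 60 nt, the real
#' TRBD1/TRBD2 sequences, 13 J genes of 30 nt) engineered to reproduce the
#' structural features the inference pipeline must cope with:
#' `TRBV6-2`/`TRBV6-3` are identical at full length; `TRBV12-3`/`TRBV12-4`
#' differ only 5' of the BIOMED-2 primers; `TRBV3-1`/`TRBV3-2` differ only
#' 5' of the Adaptive primers; eight V genes and `TRBJ1-6` are biallelic;
#' `TRBD2*01`/`TRBD2*02` differ by the single G/A SNP flanked by G runs.
#' Junction anchors (V Cys at position 52, J Phe at J position 10) are
#' recorded in `attr(set, "anchors")`.
#'
#' @return A [germline_set()] with V, D and J records.
#' @export
toy_germline_set <- function() {
  if (!is.null(.trbkit_env$toy_set)) return(.trbkit_env$toy_set)
  set <- withr::with_seed(20220107, {
    vseq <- character(0)
    for (g in TOY_V_GENES) {
      s <- random_coding_seq(TOY_V_LEN)
      substr(s, TOY_CYS_POS, TOY_CYS_POS + 2L) <- "TGT"
      while (has_stop_codon(s)) {
        s <- random_coding_seq(TOY_V_LEN)
        substr(s, TOY_CYS_POS, TOY_CYS_POS + 2L) <- "TGT"
      }
      vseq[g] <- s
    }
    # engineered indistinguishable pairs
    vseq["TRBV6-3"] <- vseq["TRBV6-2"]
    s <- vseq["TRBV12-3"]
    for (p in c(8L, 12L)) s <- apply_snp(s, p, pick_alt(s, p))
    vseq["TRBV12-4"] <- s
    s <- vseq["TRBV3-1"]
    for (p in c(20L, 30L)) s <- apply_snp(s, p, pick_alt(s, p))
    vseq["TRBV3-2"] <- s

    gene <- names(vseq); allele <- rep("01", length(vseq)); seqs <- unname(vseq)
    for (g in names(TOY_BIALLELIC)) {
      pos <- TOY_BIALLELIC[[g]]
      base <- vseq[[g]]
      gene <- c(gene, g); allele <- c(allele, "02")
      seqs <- c(seqs, apply_snp(base, pos, pick_alt(base, pos)))
    }
    v <- germline_set(gene, allele, seqs, segment = "V")

    d <- germline_set(c("TRBD1", "TRBD2", "TRBD2"), c("01", "01", "02"),
                      c("GGGACAGGGGGC",
                        "GGGACTAGCGGGGGGG",
                        "GGGACTAGCGGGAGGG"),
                      segment = "D")

    j_genes <- c(paste0("TRBJ1-", 1:6), paste0("TRBJ2-", 1:7))
    jseq <- character(0)
    for (g in j_genes) {
      s <- paste(sample(c("A", "C", "G", "T"), TOY_J_LEN, replace = TRUE),
                 collapse = "")
      substr(s, TOY_PHE_POS, TOY_PHE_POS + 2L) <- "TTC"
      # frame downstream of the junction (from position 13) must be clean
      while (has_stop_codon(substr(s, TOY_PHE_POS + 3L, TOY_J_LEN))) {
        s <- paste(sample(c("A", "C", "G", "T"), TOY_J_LEN, replace = TRUE),
                   collapse = "")
        substr(s, TOY_PHE_POS, TOY_PHE_POS + 2L) <- "TTC"
      }
      jseq[g] <- s
    }
    jg <- j_genes; ja <- rep("01", length(j_genes)); js <- unname(jseq)
    s16 <- jseq[["TRBJ1-6"]]
    jg <- c(jg, "TRBJ1-6"); ja <- c(ja, "02")
    js <- c(js, apply_snp(s16, 20L, pick_alt(s16, 20L, TOY_PHE_POS + 3L)))
    j <- germline_set(jg, ja, js, segment = "J")

    out <- dplyr::bind_rows(v, d, j)
    class(out) <- class(v)
    out
  })
  attr(set, "anchors") <- list(v_cys_imgt = TOY_CYS_POS,
                               j_phe_pos = TOY_PHE_POS)
  .trbkit_env$toy_set <- set
  set
}

#' Toy protocol specifications matching the bundled germline set
#'
#' The partial protocols put every V primer end at the same position
#' (BIOMED-2-style at IMGT 15, Adaptive-style at IMGT 35), mirroring the
#' FR2-anchored and J-proximal designs at toy scale. `missing_primer_gene`
#' removes one gene from the BIOMED-2 table to emulate designs without a
#' primer for every gene.
#'
#' @param name protocol name.
#' @param missing_primer_gene optional gene dropped from the primer table.
#' @return A [protocol_spec()].
#' @export
toy_protocol <- function(name = c("full", "biomed2", "adaptive"),
                         missing_primer_gene = NULL) {
  name <- match.arg(name)
  if (name == "full") return(protocol_spec("full"))
  pos <- if (name == "biomed2") 15L else 35L
  genes <- TOY_V_GENES
  if (!is.null(missing_primer_gene)) genes <- setdiff(genes, missing_primer_gene)
  protocol_spec(name, stats::setNames(rep(pos, length(genes)), genes),
                j_anchor_length = if (name == "adaptive") 87L else NULL)
}

#' Simulation configuration
#'
#' Defaults define a population with genotypes in Hardy-Weinberg
#' proportions, the TRBV4-3/TRBV3-2 deletion carried in cis with
#' TRBV7-2*02, TRBD2--TRBJ1-6 linkage disequilibrium, the
#' TRBD2-to-TRBJ2-only recombination constraint, geometric exonuclease
#' trimming, Poisson N-addition biased towards G, and uniform per-base
#' substitution error.
#'
#' @param seed mandatory integer seed; the same seed reproduces the same
#'   population byte for byte.
#' @param n_individuals,depth population size and reads drawn per sample
#'   (unique sequences may be fewer after deduplication).
#' @param germline reference set the reads are generated from (plant an
#'   undocumented allele by augmenting this set).
#' @param protocol sequencing protocol applied to the reads.
#' @param allele_freqs optional named list gene -> named allele frequency
#'   vector, overriding the defaults (biallelic genes 0.6/0.4, TRBD2 and
#'   TRBJ1-6 0.5/0.5).
#' @param deletion_linkage list describing genes deleted in cis with a tag
#'   allele, e.g. `list(tag_gene = "TRBV7-2", tag_allele = "02",
#'   deleted = c("TRBV4-3", "TRBV3-2"), prob = 1)`; `NULL` disables.
#' @param d2_j16_ld probability that a chromosome's TRBJ1-6 allele is the
#'   one linked to its TRBD2 allele (*01 with J1-6*02) rather than drawn
#'   independently.
#' @param d2_usage named probabilities that a read from a chromosome uses
#'   TRBD2 (vs TRBD1), per TRBD2 allele of the chromosome.
#' @param p_j1_given_d1 probability that a TRBD1 read recombines with a
#'   TRBJ1-family gene (TRBD2 reads always take TRBJ2).
#' @param v_trim_mean,d_trim_mean,j_trim_mean mean geometric trimming at
#'   the V 3', both D ends, and J 5'.
#' @param max_v_trim,max_j_trim trimming caps.
#' @param n_insert_mean mean Poisson N-addition length per junction side.
#' @param p_g probability that an inserted nucleotide is G (the remaining
#'   mass is spread evenly); the G bias drives the asymmetric TRBD2
#'   mis-assignment.
#' @param error_rate per-base substitution error probability.
#' @param force_het genes forced heterozygous in every individual (the
#'   second chromosome takes a different allele): convenient when a study
#'   design conditions on heterozygosity at an anchor gene. Applied after
#'   the TRBD2--TRBJ1-6 coupling and before the deletion linkage; leaves
#'   Hardy-Weinberg draws of other genes intact.
#' @return A `sim_config` list.
#' @export
simulate_config <- function(seed,
                            n_individuals = 10L, depth = 1000L,
                            germline = toy_germline_set(),
                            protocol = protocol_spec("full"),
                            allele_freqs = list(),
                            deletion_linkage = list(
                              tag_gene = "TRBV7-2", tag_allele = "02",
                              deleted = c("TRBV4-3", "TRBV3-2"), prob = 1),
                            d2_j16_ld = 0.9,
                            d2_usage = c("01" = 0.394, "02" = 0.531),
                            p_j1_given_d1 = 0.78,
                            v_trim_mean = 1.5, d_trim_mean = 2.5,
                            j_trim_mean = 1.5,
                            max_v_trim = 6L, max_j_trim = 6L,
                            n_insert_mean = 3, p_g = 0.5,
                            error_rate = 0.001,
                            force_het = character()) {
  if (missing(seed)) stop_trbkit("a seed is mandatory", "trbkit_no_seed")
  for (fr in allele_freqs) {
    if (any(fr < 0) || abs(sum(fr) - 1) > 1e-8) {
      stop_trbkit("allele frequencies must be non-negative and sum to 1",
                  "trbkit_bad_freq")
    }
  }
  structure(as.list(environment()), class = "sim_config")
}

default_allele_freqs <- function(germline, overrides) {
  freqs <- list()
  for (g in unique(germline$gene)) {
    alleles <- sort(germline$allele[germline$gene == g])
    freqs[[g]] <- switch(as.character(length(alleles)),
      "1" = stats::setNames(1, alleles),
      "2" = stats::setNames(c(0.6, 0.4), alleles),
      stats::setNames(rep(1 / length(alleles), length(alleles)), alleles))
    if (g %in% c("TRBD2", "TRBJ1-6")) {
      freqs[[g]] <- stats::setNames(c(0.5, 0.5), alleles)
    }
  }
  utils::modifyList(freqs, overrides)
}

rgeom_capped <- function(n, mean, cap) {
  pmin(stats::rgeom(n, 1 / (1 + mean)), pmax(cap, 0L))
}

random_inserts <- function(lens, p_g) {
  total <- sum(lens)
  if (total == 0L) return(rep("", length(lens)))
  probs <- c(A = (1 - p_g) / 3, C = (1 - p_g) / 3, G = p_g, T = (1 - p_g) / 3)
  chars <- sample(names(probs), total, replace = TRUE, prob = probs)
  out <- character(length(lens))
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  for (i in which(lens > 0L)) {
    out[i] <- paste(chars[starts[i]:ends[i]], collapse = "")
  }
  out
}

add_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  nerr <- stats::rbinom(length(seqs), nchar(seqs), rate)
  for (i in which(nerr > 0L)) {
    pos <- sample.int(nchar(seqs[i]), nerr[i])
    chars <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    for (p in pos) {
      chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
    }
    seqs[i] <- paste(chars, collapse = "")
  }
  seqs
}

#' Simulate a ground-truthed population of TRB repertoires
#'
#' Draws genotypes in Hardy-Weinberg proportions, builds two chromosomes
#' per individual honouring the configured deletion linkage and
#' TRBD2--TRBJ1-6 coupling, and emits reads by picking a chromosome
#' uniformly, a V/D/J combination honouring the TRBD2-to-TRBJ2 constraint,
#' trimming the segment ends, inserting G-biased N nucleotides, applying
#' substitution errors and truncating to the protocol window. Deterministic
#' under the config seed.
#'
#' @param config a [simulate_config()].
#' @return List with `samples` (named list of tibbles: `sequence_id`,
#'   `sequence`, `sample_id`; unique sequences), `truth` (per sample:
#'   `genotype`, `haplotype`, per-read records) and `config`.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  gl <- config$germline
  freqs <- default_allele_freqs(gl, config$allele_freqs)
  seq_of <- stats::setNames(gl$seq, gl$name)
  v_genes <- unique(gl$gene[gl$segment == "V"])
  j1_genes <- grep("^TRBJ1", unique(gl$gene), value = TRUE)
  j2_genes <- grep("^TRBJ2", unique(gl$gene), value = TRUE)
  d2_len <- nchar(seq_of[["TRBD2*01"]])
  d1_len <- nchar(seq_of[["TRBD1*01"]])
  prot <- config$protocol
  withr::with_seed(config$seed, {
    samples <- list(); truth <- list()
    for (ind in seq_len(config$n_individuals)) {
      sid <- sprintf("S%02d", ind)
      hap <- list()
      for (chr in 1:2) {
        h <- vapply(names(freqs), function(g) {
          sample(names(freqs[[g]]), 1L, prob = freqs[[g]])
        }, character(1))
        hap[[chr]] <- h
      }
      # TRBD2 -- TRBJ1-6 linkage: *01 rides with J1-6*02
      for (chr in 1:2) {
        if (stats::runif(1) < config$d2_j16_ld) {
          hap[[chr]][["TRBJ1-6"]] <-
            if (hap[[chr]][["TRBD2"]] == "01") "02" else "01"
        }
      }
      for (g in config$force_het) {
        if (hap[[1]][[g]] == hap[[2]][[g]]) {
          others <- setdiff(names(freqs[[g]]), hap[[1]][[g]])
          if (length(others)) hap[[2]][[g]] <- others[1]
        }
      }
      # deletion polymorphism in cis with the tag allele
      dl <- config$deletion_linkage
      if (!is.null(dl)) {
        for (chr in 1:2) {
          if (hap[[chr]][[dl$tag_gene]] == dl$tag_allele &&
              stats::runif(1) < dl$prob) {
            hap[[chr]][dl$deleted] <- NA_character_
          }
        }
      }
      K <- config$depth
      chrom <- sample(1:2, K, replace = TRUE)
      v_gene <- character(K)
      for (chr in 1:2) {
        pool <- v_genes[!is.na(hap[[chr]][v_genes])]
        idx <- which(chrom == chr)
        v_gene[idx] <- sample(pool, length(idx), replace = TRUE)
      }
      v_allele <- vapply(seq_len(K),
                         function(i) hap[[chrom[i]]][[v_gene[i]]], character(1))
      d2_allele <- vapply(chrom, function(c) hap[[c]][["TRBD2"]], character(1))
      use_d2 <- stats::runif(K) < config$d2_usage[d2_allele]
      d_gene <- ifelse(use_d2, "TRBD2", "TRBD1")
      d_allele <- ifelse(use_d2, d2_allele, "01")
      j_family <- ifelse(use_d2, 2L,
                         ifelse(stats::runif(K) < config$p_j1_given_d1, 1L, 2L))
      j_gene <- character(K)
      j_gene[j_family == 1L] <- sample(j1_genes, sum(j_family == 1L), TRUE)
      j_gene[j_family == 2L] <- sample(j2_genes, sum(j_family == 2L), TRUE)
      j_allele <- rep("01", K)
      j16 <- j_gene == "TRBJ1-6"
      j_allele[j16] <- vapply(chrom[j16], function(c) hap[[c]][["TRBJ1-6"]],
                              character(1))
      v_trim <- rgeom_capped(K, config$v_trim_mean, config$max_v_trim)
      d_len <- ifelse(d_gene == "TRBD2", d2_len, d1_len)
      d_trim5 <- rgeom_capped(K, config$d_trim_mean, d_len - 1L)
      d_trim3 <- rgeom_capped(K, config$d_trim_mean, d_len - 1L - d_trim5)
      j_trim <- rgeom_capped(K, config$j_trim_mean, config$max_j_trim)
      ins1 <- random_inserts(stats::rpois(K, config$n_insert_mean), config$p_g)
      ins2 <- random_inserts(stats::rpois(K, config$n_insert_mean), config$p_g)
      v_full <- seq_of[paste0(v_gene, "*", v_allele)]
      d_full <- seq_of[paste0(d_gene, "*", d_allele)]
      j_full <- seq_of[paste0(j_gene, "*", j_allele)]
      reads <- unname(paste0(
        substr(v_full, 1L, nchar(v_full) - v_trim), ins1,
        substr(d_full, d_trim5 + 1L, d_len - d_trim3), ins2,
        substr(j_full, j_trim + 1L, nchar(j_full))))
      reads <- add_errors(reads, config$error_rate)
      if (prot$name != "full") {
        pe_map <- vapply(stats::setNames(nm = v_genes),
                         function(g) primer_end_for(prot, g), integer(1))
        reads <- substr(reads, pe_map[v_gene] + 1L, nchar(reads))
      }
      keep <- !duplicated(reads)
      genotype <- lapply(stats::setNames(nm = names(freqs)), function(g) {
        sort(unique(stats::na.omit(c(hap[[1]][[g]], hap[[2]][[g]]))))
      })
      samples[[sid]] <- tibble::tibble(
        sequence_id = sprintf("%s_r%05d", sid, which(keep)),
        sequence = reads[keep],
        sample_id = sid)
      truth[[sid]] <- list(
        genotype = genotype,
        haplotype = hap,
        reads = tibble::tibble(
          sequence_id = sprintf("%s_r%05d", sid, which(keep)),
          chromosome = chrom[keep],
          v_gene = v_gene[keep], v_allele = v_allele[keep],
          d_gene = d_gene[keep], d_allele = d_allele[keep],
          j_gene = j_gene[keep], j_allele = j_allele[keep],
          v_trim = v_trim[keep], d_trim5 = d_trim5[keep],
          d_trim3 = d_trim3[keep], j_trim = j_trim[keep],
          n1 = nchar(ins1[keep]), n2 = nchar(ins2[keep])))
    }
    list(samples = samples, truth = truth, config = config)
  })
}

#' Simulate per-sample TRBD2*01 fractions for a population cohort
#'
#' Fraction-level generator for the tri-modal TRBD2 group analysis: each
#' individual's genotype is drawn in Hardy-Weinberg proportions; the true
#' TRBD2*01 usage is 1 (hom *01), 0 (hom *02) or a normally distributed
#' heterozygous usage; the observed fraction then passes through the
#' asymmetric mis-assignment channel (per-individual rates jittered around
#' the configured means) and binomial read sampling.
#'
#' @param n_individuals cohort size.
#' @param p_allele population frequency of TRBD2*01.
#' @param depth unambiguous TRBD2 reads per individual.
#' @param het_usage_mean,het_usage_sd heterozygous TRBD2*01 usage
#'   distribution (biased below 0.5, as observed in repertoires).
#' @param eps_01_to_02,eps_02_to_01 mean mis-assignment rates.
#' @param eps_sd per-individual jitter SDs of the two rates.
#' @param seed integer seed.
#' @return Tibble with `sample`, `genotype` (`hom01`/`het`/`hom02`) and
#'   `fraction`.
#' @export
simulate_d2_cohort <- function(n_individuals = 786L, p_allele = 0.494,
                               depth = 300L,
                               het_usage_mean = 0.393, het_usage_sd = 0.08,
                               eps_01_to_02 = 0.04, eps_02_to_01 = 0.125,
                               eps_sd = c(0.015, 0.025), seed = 1L) {
  withr::with_seed(seed, {
    n01 <- stats::rbinom(n_individuals, 2L, p_allele)
    genotype <- c("hom02", "het", "hom01")[n01 + 1L]
    u <- ifelse(n01 == 2L, 1, ifelse(n01 == 0L, 0,
      pmin(pmax(stats::rnorm(n_individuals, het_usage_mean, het_usage_sd),
                0.05), 0.95)))
    e12 <- pmax(stats::rnorm(n_individuals, eps_01_to_02, eps_sd[1]), 0.001)
    e21 <- pmax(stats::rnorm(n_individuals, eps_02_to_01, eps_sd[2]), 0.001)
    p_obs <- u * (1 - e12) + (1 - u) * e21
    fraction <- stats::rbinom(n_individuals, depth, p_obs) / depth
    tibble::tibble(sample = sprintf("I%04d", seq_len(n_individuals)),
                   genotype = genotype, fraction = fraction)
  })
}
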