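# Undocumented-allele discovery: candidate detection from recurrent
# mismatch patterns inside the boundary window, followed by the filter
# battery (support, rearrangement diversity, chimerism, SNP stretches,
# population modality).

# Boundary window of one reference, in IMGT numbering:
# start = max(primer_end, sequence_start) + 5, end = 316 (clipped to the
# reference length).
boundary_window <- function(window_start_imgt, seq_len, primer_end,
                            boundary_end = 316L) {
  start <- max(primer_end, window_start_imgt) + 5L
  end <- min(boundary_end, window_start_imgt + seq_len - 1L)
  if (start >= end) {
    stop_trbkit("degenerate boundary window", "trbkit_bad_window")
  }
  c(start = start, end = end)
}

#' Detect undocumented allele candidates for one gene
#'
#' Groups the gene's single-call reads by their exact mismatch-position
#' pattern against the called reference inside the boundary window
#' (primer end + 5 to IMGT position 316). Each recurrent pattern yields
#' one candidate named `base_allele` plus concatenated SNP tokens
#' (e.g. `TRBV6-3*01_G47A`); its support fraction is the fraction of the
#' gene's assignments exactly matching the candidate over the window.
#'
#' @param df assigned rearrangement tibble of one sample.
#' @param set the [germline_set()] used for assignment (genes merged).
#' @param protocol the [protocol_spec()].
#' @param gene gene (or merged/pattern gene label) to scan; default all.
#' @param min_reads,min_fraction candidate floor before filtering.
#' @param boundary_end 3' boundary position (IMGT numbering).
#' @return Tibble with one row per candidate: `gene`, `base_allele`,
#'   `name`, `snps` (list of `ref`/`pos`/`alt` tibbles), `support_count`,
#'   `support_fraction`, `cdr3_length_count`, `j_gene_count`, `gene_reads`.
#' @export
detect_novel_candidates <- function(df, set, protocol, gene = NULL,
                                    min_reads = 2L, min_fraction = 0.01,
                                    boundary_end = NULL) {
  boundary_end <- resolve_boundary_end(set, boundary_end)
  refs <- assignment_refs(set, protocol)
  vrefs <- refs[refs$segment == "V", , drop = FALSE]
  single <- df[n_calls(df$v_call) == 1L, , drop = FALSE]
  genes <- if (is.null(gene)) unique(call_gene(single$v_call)) else gene
  out <- list()
  for (g in genes) {
    gdf <- single[call_gene(single$v_call) == g, , drop = FALSE]
    n_gene <- nrow(gdf)
    if (n_gene == 0L) next
    for (ref_name in unique(gdf$v_call)) {
      ri <- match(ref_name, vrefs$name)
      if (is.na(ri)) next
      rdf <- gdf[gdf$v_call == ref_name, , drop = FALSE]
      ref_seq <- vrefs$seq[ri]
      ws <- vrefs$window_start_imgt[ri]
      pe <- primer_end_for(protocol, vrefs$gene[ri])
      bw <- boundary_window(ws, nchar(ref_seq), pe, boundary_end)
      rows <- seq.int(bw["start"] - ws + 1L, bw["end"] - ws + 1L)
      # reads must cover the whole window for an exact-match comparison
      covered <- rdf$v_sequence_end >= max(rows)
      rdf <- rdf[covered, , drop = FALSE]
      if (nrow(rdf) == 0L) next
      M <- seq_char_matrix(rdf$sequence, max(rows))
      ref_chars <- strsplit(ref_seq, "", fixed = TRUE)[[1]]
      mism <- M[rows, , drop = FALSE] != ref_chars[rows]
      pattern_key <- apply(mism, 2L, function(col) {
        paste(which(col), collapse = ",")
      })
      for (key in unique(pattern_key[pattern_key != ""])) {
        idx <- which(pattern_key == key)
        # exact support: identical alternative bases at every SNP position
        pos_rows <- as.integer(strsplit(key, ",")[[1]])
        alt_mat <- M[rows[pos_rows], idx, drop = FALSE]
        alt_key <- apply(alt_mat, 2L, paste, collapse = "")
        for (ak in unique(alt_key)) {
          if (grepl("[^ACGT]", ak)) next
          sup <- idx[alt_key == ak]
          if (length(sup) < min_reads) next
          if (length(sup) / n_gene < min_fraction) next
          alt <- strsplit(ak, "", fixed = TRUE)[[1]]
          imgt_pos <- ws + rows[pos_rows] - 1L
          snps <- tibble::tibble(ref = ref_chars[rows[pos_rows]],
                                 pos = imgt_pos, alt = alt)
          nm <- paste0(ref_name, "_",
                       paste0(snps$ref, snps$pos, snps$alt, collapse = "_"))
          jl <- rdf$junction_length[sup]
          jg <- call_gene(first_call(rdf$j_call[sup]))
          out[[length(out) + 1L]] <- tibble::tibble(
            gene = g, base_allele = ref_name, name = nm, snps = list(snps),
            support_count = length(sup),
            support_fraction = length(sup) / n_gene,
            cdr3_length_count = length(unique(jl[!is.na(jl)])),
            j_gene_count = length(unique(jg[!is.na(jg)])),
            gene_reads = n_gene)
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(gene = character(), base_allele = character(),
                          name = character(), snps = list(),
                          support_count = integer(),
                          support_fraction = numeric(),
                          cdr3_length_count = integer(),
                          j_gene_count = integer(), gene_reads = integer()))
  }
  dplyr::bind_rows(out)
}

# Candidate windowed sequence (reference window with the SNPs applied),
# restricted to the boundary range, in IMGT coordinates.
candidate_boundary_seq <- function(ref_seq, ws, snps, bw) {
  chars <- strsplit(ref_seq, "", fixed = TRUE)[[1]]
  chars[snps$pos - ws + 1L] <- snps$alt
  paste(chars[(bw["start"] - ws + 1L):(bw["end"] - ws + 1L)], collapse = "")
}

#' Could a candidate arise from chimerism between two genes?
#'
#' Brute force over all ordered pairs of alleles from different genes and
#' all breakpoints in the boundary window: the candidate fails if the
#' 5'-prefix of one allele concatenated with the 3'-suffix of an allele
#' from a different gene reproduces it exactly over the window. The
#' exhaustive enumeration is itself the defining check.
#'
#' @param cand_seq candidate boundary-window sequence.
#' @param window_tbl [window_alleles()] output for the reference set.
#' @param bw boundary window (`start`/`end`, IMGT numbering).
#' @param gene gene of the candidate (its own alleles are not chimera
#'   parents on both sides).
#' @return `TRUE` if some cross-gene prefix+suffix equals the candidate.
#' @export
chimera_possible <- function(cand_seq, window_tbl, bw, gene) {
  L <- nchar(cand_seq)
  # per-allele boundary substring, genes with a window covering the range
  segs <- list()
  for (i in seq_len(nrow(window_tbl))) {
    ws <- window_tbl$window_start_imgt[i]
    lo <- bw["start"] - ws + 1L
    hi <- bw["end"] - ws + 1L
    if (lo < 1L || hi > nchar(window_tbl$window[i])) next
    segs[[length(segs) + 1L]] <- list(
      gene = window_tbl$gene[i],
      seq = substr(window_tbl$window[i], lo, hi))
  }
  if (length(segs) < 2L) return(FALSE)
  for (a in segs) {
    for (b in segs) {
      if (a$gene == b$gene) next
      for (k in seq_len(L - 1L)) {
        if (substr(a$seq, 1L, k) == substr(cand_seq, 1L, k) &&
            substr(b$seq, k + 1L, L) == substr(cand_seq, k + 1L, L)) {
          return(TRUE)
        }
      }
    }
  }
  FALSE
}

# Histogram mode count on population usage fractions: bins of width
# `bin_width`, a mode is a local maximum bin with mass >= min_mass.
count_modes <- function(fractions, bin_width = 0.1, min_mass = 2L) {
  fractions <- fractions[!is.na(fractions) & fractions > 0]
  if (length(fractions) == 0L) return(0L)
  bins <- findInterval(fractions, seq(0, 1, by = bin_width),
                       rightmost.closed = TRUE)
  h <- tabulate(bins, nbins = ceiling(1 / bin_width))
  padded <- c(0L, h, 0L)
  modes <- 0L
  for (i in seq_along(h)) {
    if (h[i] >= min_mass && h[i] > padded[i] && h[i] >= padded[i + 2L]) {
      modes <- modes + 1L
    }
  }
  modes
}

#' Apply the undocumented-allele filter battery
#'
#' Flags each candidate on five rules: (a) support — exact match to at
#' least `min_support` of the gene's alignments; (b) diversity — at least
#' two distinct CDR3 lengths and two TRBJ genes among supporting reads;
#' (c) chimera — no cross-gene prefix+suffix concatenation reproduces the
#' candidate over the boundary window (optional, for noisy data sets);
#' (d) SNP stretch — at most one SNP within any four adjacent positions;
#' (e) modality — across the population the candidate's usage fractions
#' must reach 0.20 in some carrier or show a bi-/tri-modal histogram.
#'
#' @param candidates tibble from [detect_novel_candidates()].
#' @param set,protocol reference set and protocol used for assignment.
#' @param population_fractions optional named list: candidate name ->
#'   numeric vector of per-sample usage fractions (among the gene's
#'   assignments). `NULL` skips the modality rule (single-sample use).
#' @param min_support support-fraction floor.
#' @param chimera_filter apply rule (c)?
#' @param boundary_end 3' boundary position.
#' @param modality_min_fraction carrier fraction that passes rule (e)
#'   outright.
#' @return `candidates` with logical columns `pass_support`,
#'   `pass_diversity`, `pass_chimera`, `pass_snp_stretch`,
#'   `pass_modality`, `pass` (conjunction).
#' @export
apply_novel_filters <- function(candidates, set, protocol,
                                population_fractions = NULL,
                                min_support = 0.05, chimera_filter = TRUE,
                                boundary_end = NULL,
                                modality_min_fraction = 0.20) {
  n <- nrow(candidates)
  boundary_end <- resolve_boundary_end(set, boundary_end)
  pass_support <- candidates$support_fraction >= min_support
  pass_diversity <- candidates$cdr3_length_count >= 2L &
    candidates$j_gene_count >= 2L
  pass_snp <- vapply(candidates$snps, function(s) {
    pos <- sort(s$pos)
    length(pos) <= 1L || all(diff(pos) > 3L)
  }, logical(1))
  pass_chimera <- rep(TRUE, n)
  if (chimera_filter && n > 0L) {
    refs <- assignment_refs(set, protocol)
    vrefs <- refs[refs$segment == "V", , drop = FALSE]
    wins <- tibble::tibble(gene = vrefs$gene, window = vrefs$seq,
                           window_start_imgt = vrefs$window_start_imgt)
    for (i in seq_len(n)) {
      ri <- match(candidates$base_allele[i], vrefs$name)
      ws <- vrefs$window_start_imgt[ri]
      pe <- primer_end_for(protocol, vrefs$gene[ri])
      bw <- boundary_window(ws, nchar(vrefs$seq[ri]), pe, boundary_end)
      cand_seq <- candidate_boundary_seq(vrefs$seq[ri], ws,
                                         candidates$snps[[i]], bw)
      pass_chimera[i] <- !chimera_possible(cand_seq, wins, bw,
                                           candidates$gene[i])
    }
  }
  pass_modality <- rep(TRUE, n)
  if (!is.null(population_fractions)) {
    for (i in seq_len(n)) {
      f <- population_fractions[[candidates$name[i]]]
      if (is.null(f)) next
      pass_modality[i] <- max(f, 0) >= modality_min_fraction ||
        count_modes(f) >= 2L
    }
  }
  candidates$pass_support <- pass_support
  candidates$pass_diversity <- pass_diversity
  candidates$pass_chimera <- pass_chimera
  candidates$pass_snp_stretch <- pass_snp
  candidates$pass_modality <- pass_modality
  candidates$pass <- pass_support & pass_diversity & pass_chimera &
    pass_snp & pass_modality
  candidates
}

#' Add passing novel candidates to a germline set
#'
#' Builds individual-specific reference directories: each passing
#' candidate becomes a new allele of its base allele's gene, named with the
#' SNP suffix, so a re-assignment pass can use it.
#'
#' @param set a [germline_set()].
#' @param candidates filtered candidate tibble (rows with `pass == TRUE`
#'   are added; pass columns absent means all rows).
#' @return The augmented set.
#' @export
augment_reference <- function(set, candidates) {
  if ("pass" %in% names(candidates)) {
    candidates <- candidates[candidates$pass, , drop = FALSE]
  }
  candidates <- candidates[!duplicated(candidates$name), , drop = FALSE]
  for (i in seq_len(nrow(candidates))) {
    base <- candidates$base_allele[i]
    # base may be a pattern name; fall back to the first member allele
    bi <- match(base, set$name)
    if (is.na(bi)) next
    snps <- candidates$snps[[i]]
    chars <- strsplit(set$seq[bi], "", fixed = TRUE)[[1]]
    idx <- imgt_to_ungapped(set$gapped_map[[bi]], snps$pos)
    if (any(is.na(idx))) next
    chars[idx] <- snps$alt
    new_allele <- paste0(set$allele[bi], "_",
                         paste0(snps$ref, snps$pos, snps$alt, collapse = "_"))
    if (paste0(set$gene[bi], "*", new_allele) %in% set$name) next
    new_row <- set[bi, , drop = FALSE]
    new_row$allele <- new_allele
    new_row$name <- paste0(new_row$gene, "*", new_allele)
    new_row$seq <- paste(chars, collapse = "")
    attrs <- attributes(set)
    set <- dplyr::bind_rows(set, new_row)
    attr(set, "anchors") <- attrs$anchors
    attr(set, "merged_genes") <- attrs$merged_genes
    class(set) <- attrs$class
  }
  set
}

#' Upstream (5' UTR) consensus construction
#'
#' Position-wise majority consensus over reads upstream of the V region,
#' right-aligned at the V start. When a secondary variant at some position
#' exceeds `cluster_threshold`, the reads are split on that position and
#' two consensus variants are reported. Only meaningful for full-length
#' (5'RACE) data.
#'
#' @param upstream character vector of upstream sequences (all ending at
#'   the V start).
#' @param protocol a [protocol_spec()]; must be the full protocol.
#' @param min_depth minimal number of reads.
#' @param cluster_threshold secondary-variant fraction that triggers a
#'   split.
#' @return Tibble with `consensus` and `depth`.
#' @export
upstream_consensus <- function(upstream, protocol, min_depth = 2L,
                               cluster_threshold = 0.3) {
  if (protocol$name != "full") {
    stop_trbkit("upstream consensus requires full-length (5'RACE) data",
                "trbkit_unsupported_protocol")
  }
  upstream <- upstream[!is.na(upstream) & nchar(upstream) > 0L]
  if (length(upstream) < min_depth) {
    return(tibble::tibble(consensus = character(), depth = integer()))
  }
  width <- max(nchar(upstream))
  # right-align by left-padding with N
  padded <- vapply(upstream, function(s) {
    paste0(strrep("N", width - nchar(s)), s)
  }, character(1), USE.NAMES = FALSE)
  M <- matrix(unlist(strsplit(padded, "", fixed = TRUE), use.names = FALSE),
              nrow = width)
  split_pos <- 0L
  split_base <- ""
  for (i in seq_len(width)) {
    tab <- sort(table(M[i, M[i, ] != "N"]), decreasing = TRUE)
    if (length(tab) >= 2L && tab[2] / sum(tab) >= cluster_threshold) {
      split_pos <- i
      split_base <- names(tab)[1]
      break
    }
  }
  consensus_of <- function(cols) {
    cc <- vapply(seq_len(width), function(i) {
      col <- M[i, cols]
      col <- col[col != "N"]
      if (length(col) == 0L) return("")
      names(sort(table(col), decreasing = TRUE))[1]
    }, character(1))
    paste(cc, collapse = "")
  }
  if (split_pos == 0L) {
    return(tibble::tibble(consensus = consensus_of(seq_along(upstream)),
                          depth = length(upstream)))
  }
  major <- which(M[split_pos, ] == split_base)
  minor <- setdiff(which(M[split_pos, ] != "N"), major)
  dplyr::bind_rows(
    tibble::tibble(consensus = consensus_of(major), depth = length(major)),
    tibble::tibble(consensus = consensus_of(minor), depth = length(minor)))
}
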