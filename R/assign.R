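# Native V(D)J assigner.
#
# Scores each read against the protocol's assignment references (pattern
# representatives for V, whole alleles for D/J). V and J are scored by
# ungapped end-anchored comparison with a search over recombination trims:
# score = matched_length - 2 * mismatches, maximised over 3' V trims
# (respectively 5' J trims). All references achieving the maximal score are
# kept as a comma-joined multi-call; ties are never broken arbitrarily,
# because the "single assignment" genotyping filter downstream relies on
# them. D segments are assigned by the longest exact germline substring
# match inside the junction interval (no mismatches: D-mismatch reads are
# discarded by the genotyping filter anyway).

# Per-reference best end-trimmed comparison for a block of reads.
# M: char matrix (width x n). Returns score, matched length L and
# boundary-window mismatches for the best trim of this reference.
score_reference <- function(M, ref_chars, max_trim, win_rows) {
  m <- length(ref_chars)
  mism <- M[seq_len(m), , drop = FALSE] != ref_chars
  mm_full <- colSums(mism)
  win_rows <- win_rows[win_rows <= m]
  mm_win_full <- if (length(win_rows)) colSums(mism[win_rows, , drop = FALSE]) else 0L
  best_score <- rep(-Inf, ncol(M))
  best_L <- integer(ncol(M))
  best_mm_win <- integer(ncol(M))
  tail_mm <- 0L
  # k = 0 last so that ties prefer the least-trimmed alignment
  for (k in seq(max_trim, 0L)) {
    L <- m - k
    if (L < 1L) next
    if (k > 0L) {
      rows <- (L + 1L):m
      tail_mm <- colSums(mism[rows, , drop = FALSE])
      lost_win <- intersect(rows, win_rows)
      tail_win <- if (length(lost_win)) colSums(mism[lost_win, , drop = FALSE]) else 0L
    } else {
      tail_mm <- 0L
      tail_win <- 0L
    }
    mm_k <- mm_full - tail_mm
    sc <- L - 2L * mm_k
    upd <- sc >= best_score
    best_score[upd] <- sc[upd]
    best_L[upd] <- L
    best_mm_win[upd] <- (mm_win_full - tail_win)[upd]
  }
  list(score = best_score, L = best_L, mm_win = best_mm_win)
}

# Longest exact substring of each D allele found in each junction string.
d_longest_match <- function(junctions, d_refs, min_len) {
  n <- length(junctions)
  out <- matrix(0L, nrow = n, ncol = nrow(d_refs))
  colnames(out) <- d_refs$name
  for (di in seq_len(nrow(d_refs))) {
    dseq <- d_refs$seq[di]
    dlen <- nchar(dseq)
    unresolved <- which(!is.na(junctions) & nchar(junctions) >= min_len)
    if (length(unresolved) == 0L) next
    hi <- min(dlen, max(nchar(junctions[unresolved])))
    if (hi < min_len) next
    for (len in seq(hi, min_len)) {
      if (length(unresolved) == 0L) break
      subs <- unique(substring(dseq, 1:(dlen - len + 1L), len:dlen))
      hit <- rep(FALSE, length(unresolved))
      for (s in subs) {
        hit <- hit | grepl(s, junctions[unresolved], fixed = TRUE)
      }
      out[unresolved[hit], di] <- len
      unresolved <- unresolved[!hit]
    }
  }
  out
}

#' Assign V, D and J segments to reads
#'
#' Native stand-in for the aligner stage of the pipeline. Produces an AIRR
#' rearrangement tibble with multi-valued calls comma-joined, per-read V
#' mismatch counts inside the undocumented-allele boundary window, the
#' contiguous germline-matched D length, the junction and productivity.
#'
#' @param seqs character vector of read sequences (or a tibble with
#'   `sequence_id` and `sequence` columns).
#' @param set a [germline_set()] with V, D and J records (genes already
#'   merged for the protocol; see [merge_indistinguishable()]).
#' @param protocol a [protocol_spec()].
#' @param sample_id sample label stored on every row.
#' @param max_v_trim,max_j_trim maximal recombination trims searched at the
#'   V 3' / J 5' ends.
#' @param min_d_length minimal reportable exact D match (nt).
#' @param max_mismatch_rate reads whose best V or J alignment exceeds this
#'   mismatch rate are flagged unusable (`v_call`/`j_call` `NA`), not
#'   dropped.
#' @param boundary_end 3' end of the mismatch-counting boundary window, in
#'   IMGT numbering (the window runs from primer end + 5 to this position).
#' @return Tibble with columns `sequence_id`, `sequence`, `v_call`,
#'   `d_call`, `j_call`, `v_mismatches`, `d_matched_length`, `junction`,
#'   `junction_length`, `productive`, `v_sequence_end`, `j_sequence_start`,
#'   `sample_id`.
#' @export
assign_rearrangements <- function(seqs, set, protocol, sample_id = NA_character_,
                                  max_v_trim = 8L, max_j_trim = 8L,
                                  min_d_length = 5L, max_mismatch_rate = 0.2,
                                  boundary_end = NULL) {
  if (is.data.frame(seqs)) {
    ids <- seqs$sequence_id
    seqs <- seqs$sequence
  } else {
    ids <- paste0("read", seq_along(seqs))
  }
  refs <- assignment_refs(set, protocol)
  vrefs <- refs[refs$segment == "V", , drop = FALSE]
  drefs <- refs[refs$segment == "D", , drop = FALSE]
  jrefs <- refs[refs$segment == "J", , drop = FALSE]
  anchors <- attr(set, "anchors")
  boundary_end <- resolve_boundary_end(set, boundary_end)
  n <- length(seqs)
  rl <- nchar(seqs)

  # --- V: prefix comparison with 3' trim search -------------------------
  vmax <- max(nchar(vrefs$seq))
  M <- seq_char_matrix(seqs, vmax)
  nv <- nrow(vrefs)
  v_score <- matrix(-Inf, n, nv); v_L <- matrix(0L, n, nv); v_mmw <- matrix(0L, n, nv)
  for (i in seq_len(nv)) {
    ws <- vrefs$window_start_imgt[i]
    pe <- primer_end_for(protocol, vrefs$gene[i])
    row_lo <- max(pe, ws) + 5L - ws + 1L
    row_hi <- min(boundary_end, ws + nchar(vrefs$seq[i]) - 1L) - ws + 1L
    bw_rows <- if (row_hi >= row_lo) seq.int(row_lo, row_hi) else integer()
    sc <- score_reference(M, strsplit(vrefs$seq[i], "", fixed = TRUE)[[1]],
                          max_v_trim, bw_rows)
    v_score[, i] <- sc$score; v_L[, i] <- sc$L; v_mmw[, i] <- sc$mm_win
  }
  v_best <- apply(v_score, 1L, max)
  v_call <- character(n); v_mm <- integer(n); v_end <- integer(n)
  for (r in seq_len(n)) {
    hits <- which(v_score[r, ] == v_best[r])
    v_call[r] <- paste(vrefs$name[hits], collapse = ",")
    v_mm[r] <- v_mmw[r, hits[1L]]
    v_end[r] <- v_L[r, hits[1L]]
  }
  v_rate <- (v_end - v_best) / 2 / pmax(v_end, 1L)
  v_bad <- v_rate > max_mismatch_rate

  # --- J: suffix comparison via reversed sequences ----------------------
  rseqs <- reverse_string(seqs)
  jmax <- max(nchar(jrefs$seq))
  Mr <- seq_char_matrix(rseqs, jmax)
  nj <- nrow(jrefs)
  j_score <- matrix(-Inf, n, nj); j_L <- matrix(0L, n, nj)
  for (i in seq_len(nj)) {
    sc <- score_reference(Mr, rev(strsplit(jrefs$seq[i], "", fixed = TRUE)[[1]]),
                          max_j_trim, integer())
    j_score[, i] <- sc$score; j_L[, i] <- sc$L
  }
  j_best <- apply(j_score, 1L, max)
  j_call <- character(n); j_len <- integer(n)
  for (r in seq_len(n)) {
    hits <- which(j_score[r, ] == j_best[r])
    j_call[r] <- paste(jrefs$name[hits], collapse = ",")
    j_len[r] <- j_L[r, hits[1L]]
  }
  j_rate <- (j_len - j_best) / 2 / pmax(j_len, 1L)
  j_bad <- j_rate > max_mismatch_rate
  j_start <- rl - j_len + 1L

  # --- D: longest exact substring inside the junction interval ----------
  dj_region <- ifelse(j_start - 1L >= v_end + 1L,
                      substr(seqs, v_end + 1L, j_start - 1L), NA_character_)
  d_call <- rep(NA_character_, n)
  d_len <- rep(0L, n)
  if (nrow(drefs) > 0L) {
    dmat <- d_longest_match(dj_region, drefs, min_d_length)
    dmax <- apply(dmat, 1L, max)
    for (r in which(dmax >= min_d_length)) {
      hits <- which(dmat[r, ] == dmax[r])
      d_call[r] <- paste(drefs$name[hits], collapse = ",")
      d_len[r] <- dmax[r]
    }
  }

  # --- junction and productivity ----------------------------------------
  junction <- rep(NA_character_, n)
  if (!is.null(anchors)) {
    first_v <- match(first_call(v_call), vrefs$name)
    ws <- vrefs$window_start_imgt[first_v]
    cys_idx <- anchors$v_cys_imgt - ws + 1L
    first_j <- match(first_call(j_call), jrefs$name)
    j_trim <- nchar(jrefs$seq[first_j]) - j_len
    phe_idx <- j_start + anchors$j_phe_pos - 1L - j_trim
    ok <- !v_bad & !j_bad & !is.na(cys_idx) & cys_idx >= 1L &
      (cys_idx + 2L) <= v_end & j_trim < anchors$j_phe_pos &
      (phe_idx + 2L) <= rl & phe_idx > cys_idx
    junction[ok] <- substr(seqs[ok], cys_idx[ok], phe_idx[ok] + 2L)
  }
  junction_length <- ifelse(is.na(junction), NA_integer_, nchar(junction))
  productive <- classify_functionality(junction)

  v_call[v_bad] <- NA_character_
  j_call[j_bad] <- NA_character_
  tibble::tibble(
    sequence_id = ids, sequence = seqs,
    v_call = v_call, d_call = d_call, j_call = j_call,
    v_mismatches = v_mm, d_matched_length = d_len,
    junction = junction, junction_length = junction_length,
    productive = productive,
    v_sequence_end = v_end, j_sequence_start = j_start,
    sample_id = sample_id)
}

#' Productivity of a rearrangement from its junction
#'
#' A rearrangement is productive when its junction length is a multiple of
#' three (no frame shift between V and J) and the in-frame junction carries
#' no stop codon. An unlocatable junction gives `NA` (excluded from both
#' the functional and the non-functional stratum).
#'
#' @param junction junction nucleotide string(s), `NA` if not locatable.
#' @return Logical vector.
#' @export
classify_functionality <- function(junction) {
  vapply(junction, function(j) {
    if (is.na(j)) return(NA)
    if (nchar(j) %% 3L != 0L) return(FALSE)
    !has_stop_codon(j)
  }, logical(1), USE.NAMES = FALSE)
}
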