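#' Unit-cost alignment distance with a free padded beginning
#'
#' Global alignment cost between two windowed sequences with a penalty of
#' one per mismatch, insertion or deletion, except that leading gaps are
#' free on either sequence (a "padded beginning"). This is the distance
#' used to decide whether two genes are distinguishable within a protocol's
#' sequenced window: suffix windows of unequal length align at zero cost
#' when one is a suffix of the other.
#'
#' @param a,b nucleotide strings.
#' @return Non-negative integer cost.
#' @export
pad_align_cost <- function(a, b) {
  if (identical(a, b)) return(0L)
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(ca); m <- length(cb)
  prev <- integer(m + 1L)            # leading gaps in `a` are free
  for (i in seq_len(n)) {
    cur <- integer(m + 1L)
    cur[1L] <- 0L                    # leading gaps in `b` are free
    for (j in seq_len(m)) {
      cur[j + 1L] <- min(prev[j] + (ca[i] != cb[j]),
                         prev[j + 1L] + 1L,
                         cur[j] + 1L)
    }
    prev <- cur
  }
  as.integer(prev[m + 1L])
}

#' Minimum pairwise distance between two genes' windowed alleles
#'
#' @param windows_a,windows_b non-empty character vectors of windowed
#'   allele sequences of two genes.
#' @return The minimum [pad_align_cost()] over all allele pairs; symmetric.
#' @export
gene_pair_distance <- function(windows_a, windows_b) {
  if (length(windows_a) == 0L || length(windows_b) == 0L) {
    stop_trbkit("gene_pair_distance needs non-empty allele window lists",
                "trbkit_empty_windows")
  }
  best <- Inf
  for (a in windows_a) {
    for (b in windows_b) {
      d <- pad_align_cost(a, b)
      if (d < best) best <- d
      if (best == 0L) return(0L)
    }
  }
  as.integer(best)
}

#' Merge genes indistinguishable under a protocol
#'
#' Genes whose windowed alleles are at distance zero are unioned under a
#' slash-joined label (transitive closure, so A/B/C is well defined).
#' The merged groups are recorded in `attr(set, "merged_genes")`.
#'
#' @param set a [germline_set()] (V segment rows are merged; D/J untouched).
#' @param protocol a [protocol_spec()].
#' @return The set with merged gene labels and renamed alleles.
#' @export
merge_indistinguishable <- function(set, protocol) {
  vrows <- which(set$segment == "V")
  wins <- window_alleles(set[vrows, , drop = FALSE], protocol)
  genes <- unique(wins$gene)
  parent <- stats::setNames(genes, genes)
  find <- function(g) { while (parent[[g]] != g) g <- parent[[g]]; g }
  win_by_gene <- split(wins$window, wins$gene)
  if (length(genes) > 1L) {
    for (i in seq_len(length(genes) - 1L)) {
      for (j in (i + 1L):length(genes)) {
        if (gene_pair_distance(win_by_gene[[genes[i]]],
                               win_by_gene[[genes[j]]]) == 0L) {
          parent[[find(genes[j])]] <- find(genes[i])
        }
      }
    }
  }
  roots <- vapply(genes, find, character(1))
  groups <- split(genes, roots)
  merged <- Filter(function(g) length(g) > 1L, groups)
  label <- stats::setNames(
    vapply(groups, function(g) paste(sort(g), collapse = "/"), character(1))[roots],
    genes)
  set$source_gene <- set$gene
  set$gene[vrows] <- unname(label[set$gene[vrows]])
  set$name <- paste0(set$gene, "*", set$allele)
  if (anyDuplicated(set$name)) {
    # identical alleles of merged genes collapse to one row (longest full
    # reference kept); same-named alleles with different sequences stay
    # distinct, disambiguated by their source gene
    ord <- order(set$name, -nchar(set$seq))
    set <- set[ord, , drop = FALSE]
    set <- set[!duplicated(paste(set$name, set$seq)), , drop = FALSE]
    coll <- duplicated(set$name) | duplicated(set$name, fromLast = TRUE)
    fix <- coll & duplicated(set$name)
    if (any(fix)) {
      suffix <- sub("^TRB[VDJ]", "", set$source_gene[fix])
      set$allele[fix] <- paste0(set$allele[fix], "-", suffix)
      set$name <- paste0(set$gene, "*", set$allele)
    }
    set <- set[order(set$name), , drop = FALSE]
  }
  attr(set, "merged_genes") <- unname(lapply(merged, sort))
  set
}

#' Collapse alleles into partial allelic-variation pattern groups
#'
#' Within each (possibly merged) gene, alleles with identical windowed
#' sequences form one pattern group. Under the partial protocols groups are
#' named `gene*bp01`, `gene*bp02`, ... (BIOMED-2) or `gene*ap01`, ...
#' (Adaptive), densely numbered from 01 in order of their smallest member
#' allele. Under the full protocol each group keeps its allele's own name.
#' The representative sequence is the window of the member with the longest
#' full reference.
#'
#' @param set a [germline_set()], genes already merged for the protocol.
#' @param protocol a [protocol_spec()].
#' @return Tibble with `gene`, `pattern_name`, `members` (list of full
#'   allele names), `representative` and `window_start_imgt`.
#' @export
collapse_patterns <- function(set, protocol) {
  vrows <- set[set$segment == "V", , drop = FALSE]
  wins <- window_alleles(vrows, protocol)
  wins$full_len <- nchar(vrows$seq)
  prefix <- switch(protocol$name, full = NA, biomed2 = "bp", adaptive = "ap")
  out <- list()
  for (g in unique(wins$gene)) {
    gw <- wins[wins$gene == g, , drop = FALSE]
    gw <- gw[order(gw$allele), , drop = FALSE]
    groups <- split(seq_len(nrow(gw)), match(gw$window, unique(gw$window)))
    for (k in seq_along(groups)) {
      idx <- groups[[k]]
      rep_idx <- idx[which.max(gw$full_len[idx])]
      pattern_name <- if (protocol$name == "full") {
        if (length(idx) > 1L)
          paste0(g, "*", paste(gw$allele[idx], collapse = "/"))
        else gw$name[idx]
      } else {
        paste0(g, "*", prefix, formatC(k, width = 2, flag = "0"))
      }
      out[[length(out) + 1L]] <- tibble::tibble(
        gene = g,
        pattern_name = pattern_name,
        members = list(gw$name[idx]),
        representative = gw$window[rep_idx],
        window_start_imgt = gw$window_start_imgt[rep_idx])
    }
  }
  dplyr::bind_rows(out)
}

# References the assigner aligns against: pattern representatives for V
# (with merged/pattern names), whole alleles for D and J. J alleles with
# identical sequences are collapsed into a joint comma-free "/" name too.
assignment_refs <- function(set, protocol) {
  pats <- collapse_patterns(set, protocol)
  v <- tibble::tibble(name = pats$pattern_name, gene = pats$gene,
                      segment = "V", seq = pats$representative,
                      window_start_imgt = pats$window_start_imgt)
  dj <- set[set$segment != "V", , drop = FALSE]
  out <- v
  if (nrow(dj) > 0L) {
    dj2 <- tibble::tibble(name = dj$name, gene = dj$gene,
                          segment = dj$segment, seq = dj$seq,
                          window_start_imgt = 1L)
    out <- dplyr::bind_rows(v, dj2)
  }
  out
}
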