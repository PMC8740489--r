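# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @noRd
stop_trbkit <- function(msg, class) {
  stop(structure(
    class = c(class, "trbkit_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Character matrix of the first `width` positions of each sequence, one
# column per sequence; positions past the end of a sequence are padded with
# "N" so they always count as mismatches.
seq_char_matrix <- function(seqs, width) {
  n <- length(seqs)
  padded <- vapply(seqs, function(s) {
    if (nchar(s) >= width) substr(s, 1L, width)
    else paste0(s, strrep("N", width - nchar(s)))
  }, character(1), USE.NAMES = FALSE)
  matrix(unlist(strsplit(padded, "", fixed = TRUE), use.names = FALSE),
         nrow = width, ncol = n)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# TRUE if the in-frame translation of `seq` (frame 1) contains a stop codon.
has_stop_codon <- function(seq) {
  n <- nchar(seq)
  if (n < 3L) return(FALSE)
  starts <- seq.int(1L, n - 2L, by = 3L)
  any(substring(seq, starts, starts + 2L) %in% STOP_CODONS)
}

reverse_string <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Split comma-joined AIRR call strings into a list of character vectors.
split_calls <- function(x) strsplit(x, ",", fixed = TRUE)

n_calls <- function(x) {
  out <- lengths(split_calls(x))
  out[is.na(x) | x == ""] <- 0L
  out
}

first_call <- function(x) vapply(split_calls(x), `[`, character(1), 1L)

# gene component of a "gene*allele" name (merged gene labels may contain "/").
call_gene <- function(x) sub("\\*.*$", "", x)
call_allele <- function(x) sub("^.*\\*", "", x)

# 3' end of the novel-allele boundary window: explicit value, else the
# position just before the reference set's junction Cys anchor, else the
# standard IMGT position 316.
resolve_boundary_end <- function(set, boundary_end) {
  if (!is.null(boundary_end)) return(as.integer(boundary_end))
  anchors <- attr(set, "anchors")
  if (!is.null(anchors$v_cys_imgt)) return(as.integer(anchors$v_cys_imgt) - 1L)
  316L
}
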