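#' Sequencing-protocol specification
#'
#' Describes how much of each V gene a library design actually sequences.
#' `full` (5'RACE-style) covers whole V regions; `biomed2` and `adaptive`
#' are partial designs whose amplicons only cover the region 3' of a
#' per-gene primer. `per_gene_primer_end` gives, for each gene, the
#' IMGT-numbering position at which its primer ends; the protocol-restricted
#' view of an allele starts at the first position after the primer.
#'
#' @param name `"full"`, `"biomed2"` or `"adaptive"`.
#' @param per_gene_primer_end named integer vector, gene -> primer end
#'   position (1-based IMGT numbering). Must be empty for `full`.
#' @param j_anchor_length optional read length measured from the fixed J
#'   anchor (adaptive-style designs); informational.
#' @return A `protocol_spec` list.
#' @export
protocol_spec <- function(name = c("full", "biomed2", "adaptive"),
                          per_gene_primer_end = integer(),
                          j_anchor_length = NULL) {
  name <- match.arg(name)
  if (name == "full" && length(per_gene_primer_end) > 0L) {
    stop_trbkit("the full protocol takes no per-gene primer positions",
                "trbkit_bad_protocol")
  }
  if (name != "full" && length(per_gene_primer_end) > 0L &&
      is.null(names(per_gene_primer_end))) {
    stop_trbkit("per_gene_primer_end must be named by gene",
                "trbkit_bad_protocol")
  }
  structure(
    list(name = name,
         per_gene_primer_end = per_gene_primer_end,
         j_anchor_length = j_anchor_length,
         merged_gene_pairs = list()),
    class = "protocol_spec")
}

#' Read a protocol specification from YAML
#'
#' Expected keys: `name`, optional `per_gene_primer_end` (map gene ->
#' position) and `j_anchor_length`. Primer tables are data, not code, so
#' they ship as editable config files.
#'
#' @param file YAML path.
#' @return A [protocol_spec()].
#' @export
read_protocol <- function(file) {
  cfg <- yaml::read_yaml(file)
  pe <- unlist(cfg$per_gene_primer_end %||% list())
  protocol_spec(cfg$name,
                per_gene_primer_end = if (length(pe)) pe else integer(),
                j_anchor_length = cfg$j_anchor_length)
}

# Primer end for one (possibly merged "A/B") gene label, or a MissingPrimer
# error mirroring genes a partial protocol cannot amplify.
primer_end_for <- function(protocol, gene) {
  if (protocol$name == "full") return(0L)
  parts <- strsplit(gene, "/", fixed = TRUE)[[1]]
  hit <- protocol$per_gene_primer_end[parts]
  if (any(is.na(hit)) || length(hit) == 0L) {
    stop_trbkit(paste0("no ", protocol$name, " primer for gene ", gene),
                "trbkit_missing_primer")
  }
  as.integer(max(hit))
}

#' Protocol-restricted view of an allele
#'
#' Returns the subsequence a given protocol can actually observe: the full
#' sequence under `full`, and the suffix starting at the first position
#' after the gene's primer end under the partial protocols. Positions are
#' resolved through the allele's `gapped_map`, so primer ends are expressed
#' in IMGT numbering. Only V segments are windowed; D and J references are
#' returned whole.
#'
#' @param set a [germline_set()] (or one row of it).
#' @param protocol a [protocol_spec()].
#' @return Tibble with columns `name`, `gene`, `allele`, `window`
#'   (windowed sequence) and `window_start_imgt` (IMGT position of its
#'   first nucleotide).
#' @export
window_alleles <- function(set, protocol) {
  win <- character(nrow(set))
  ws <- integer(nrow(set))
  for (i in seq_len(nrow(set))) {
    if (set$segment[i] != "V" || protocol$name == "full") {
      keep <- seq_len(nchar(set$seq[i]))
    } else {
      n_end <- primer_end_for(protocol, set$gene[i])
      keep <- which(set$gapped_map[[i]] > n_end)
      if (length(keep) == 0L) {
        stop_trbkit(paste0("primer end ", n_end, " not inside allele ",
                           set$name[i]), "trbkit_bad_protocol")
      }
    }
    win[i] <- substr(set$seq[i], keep[1], keep[length(keep)])
    ws[i] <- set$gapped_map[[i]][keep[1]]
  }
  tibble::tibble(name = set$name, gene = set$gene, allele = set$allele,
                 window = win, window_start_imgt = ws)
}
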