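#' Germline reference sets
#'
#' A germline set is a tibble with one row per allele and columns `gene`,
#' `allele`, `name` (`gene*allele`), `segment` (V/D/J), `functionality`
#' (functional/ORF/pseudogene), `seq` (ungapped nucleotides) and
#' `gapped_map` (list column; integer vector mapping each ungapped position
#' to its 1-based IMGT-numbering position on the gapped alignment). Novel
#' allele names carry SNP suffixes such as `01_G47A`, i.e. reference base,
#' IMGT position, alternative base.
#'
#' @param gene,allele,seq,segment,functionality,gapped_map vectors (and a
#'   list of integer vectors for `gapped_map`) describing one allele each.
#'   `gapped_map` defaults to the identity map `1..nchar(seq)`.
#' @return A `germline_set` tibble.
#' @export
germline_set <- function(gene, allele, seq, segment = "V",
                         functionality = "functional", gapped_map = NULL) {
  seq <- toupper(seq)
  n <- length(gene)
  if (is.null(gapped_map)) {
    gapped_map <- lapply(nchar(seq), seq_len)
  }
  set <- tibble::tibble(
    gene = gene,
    allele = allele,
    name = paste0(gene, "*", allele),
    segment = rep_len(segment, n),
    functionality = rep_len(functionality, n),
    seq = seq,
    gapped_map = gapped_map
  )
  validate_germline_set(set)
  class(set) <- c("germline_set", class(tibble::tibble()))
  set
}

validate_germline_set <- function(set) {
  if (nrow(set) == 0L) return(invisible(set))
  bad <- grepl("[^ACGT]", set$seq) | nchar(set$seq) == 0L
  if (any(bad)) {
    stop_trbkit(
      paste0("non-ACGT or empty sequence in record(s): ",
             paste(set$name[bad], collapse = ", ")),
      "trbkit_bad_sequence")
  }
  if (anyDuplicated(set$name)) {
    dup <- unique(set$name[duplicated(set$name)])
    stop_trbkit(paste0("duplicate (gene, allele): ",
                       paste(dup, collapse = ", ")),
                "trbkit_duplicate_allele")
  }
  ok_map <- mapply(function(s, m) {
    length(m) == nchar(s) && !is.unsorted(m, strictly = TRUE)
  }, set$seq, set$gapped_map)
  if (!all(ok_map)) {
    stop_trbkit(paste0("gapped_map not strictly increasing for: ",
                       paste(set$name[!ok_map], collapse = ", ")),
                "trbkit_bad_map")
  }
  invisible(set)
}

#' Load a germline reference set from FASTA
#'
#' Accepts both the IMGT pipe-delimited header dialect
#' (`>X57616|TRBV6-2*01|Homo sapiens|F|V-REGION|...`) and bare headers
#' (`>TRBV6-2*01`). IMGT gap characters (`.`) are stripped into the
#' `gapped_map`: the stored sequence is ungapped and the map records the
#' 1-based gapped (IMGT-numbering) position of every nucleotide.
#'
#' @param fasta path to a FASTA file.
#' @param segment segment label recorded on every record (`"V"`, `"D"`, `"J"`).
#' @return A [germline_set()] indexed by gene/allele.
#' @export
load_reference <- function(fasta, segment = "V") {
  recs <- Biostrings::readBStringSet(fasta)
  if (length(recs) == 0L) {
    warning("empty FASTA stream: returning an empty germline set")
    return(germline_set(character(), character(), character(),
                        segment = character(), functionality = character(),
                        gapped_map = list()))
  }
  headers <- names(recs)
  seqs <- toupper(as.character(recs))
  parse_one <- function(h) {
    fields <- strsplit(h, "|", fixed = TRUE)[[1]]
    if (length(fields) >= 2L) {
      token <- trimws(fields[2])
      fun <- if (length(fields) >= 4L) trimws(fields[4]) else "F"
    } else {
      token <- trimws(strsplit(h, "[ \t]")[[1]][1])
      fun <- "F"
    }
    fun <- switch(sub("^\\((.*)\\)$", "\\1", fun),
                  "F" = "functional", "ORF" = "ORF", "P" = "pseudogene",
                  "functional")
    c(token = token, fun = fun)
  }
  parsed <- lapply(headers, parse_one)
  token <- vapply(parsed, `[[`, character(1), "token")
  functionality <- vapply(parsed, `[[`, character(1), "fun")
  if (any(!grepl("\\*", token))) {
    bad <- headers[!grepl("\\*", token)]
    stop_trbkit(paste0("header without gene*allele token: ",
                       paste(bad, collapse = "; ")),
                "trbkit_bad_header")
  }
  bad_char <- grepl("[^ACGT.]", seqs)
  if (any(bad_char)) {
    stop_trbkit(paste0("non-ACGT/non-gap character in record(s): ",
                       paste(token[bad_char], collapse = ", ")),
                "trbkit_bad_sequence")
  }
  chars <- strsplit(seqs, "", fixed = TRUE)
  gapped_map <- lapply(chars, function(cc) which(cc != "."))
  ungapped <- vapply(seqs, function(s) gsub(".", "", s, fixed = TRUE),
                     character(1), USE.NAMES = FALSE)
  germline_set(
    gene = call_gene(token),
    allele = call_allele(token),
    seq = ungapped,
    segment = segment,
    functionality = functionality,
    gapped_map = gapped_map
  )
}

#' Re-insert IMGT gaps into an ungapped allele sequence
#'
#' Inverse of the gap stripping performed by [load_reference()]: rebuilds
#' the gapped string by placing each nucleotide at its `gapped_map` position
#' and filling the remaining positions with `.`.
#'
#' @param seq ungapped sequence.
#' @param gapped_map integer vector of gapped positions, one per nucleotide.
#' @return The gapped sequence string.
#' @export
regap <- function(seq, gapped_map) {
  out <- rep(".", max(gapped_map))
  out[gapped_map] <- strsplit(seq, "", fixed = TRUE)[[1]]
  paste(out, collapse = "")
}

#' Write a germline set to FASTA (bare `>gene*allele` headers)
#'
#' @param set a [germline_set()].
#' @param file output path.
#' @export
write_reference <- function(set, file) {
  x <- Biostrings::BStringSet(set$seq)
  names(x) <- set$name
  Biostrings::writeXStringSet(x, file)
  invisible(file)
}

# IMGT position -> ungapped index for one allele (NA if gapped there).
imgt_to_ungapped <- function(gapped_map, pos) {
  match(pos, gapped_map)
}
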