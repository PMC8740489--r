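AIRR_REQUIRED <- c("sequence_id", "sequence")

#' Read an AIRR rearrangement TSV
#'
#' Minimal reader for the AIRR Rearrangement schema as used here:
#' tab-separated, header row, multi-valued calls comma-joined. Unknown
#' columns are preserved as character.
#'
#' @param file TSV path.
#' @return Tibble of rearrangements.
#' @export
read_airr <- function(file) {
  df <- readr::read_tsv(file, col_types = readr::cols(
    .default = readr::col_character()))
  missing <- setdiff(AIRR_REQUIRED, names(df))
  if (length(missing) > 0L) {
    stop_trbkit(paste0("missing mandatory AIRR column(s): ",
                       paste(missing, collapse = ", ")),
                "trbkit_bad_airr")
  }
  if (anyDuplicated(df$sequence_id)) {
    dup <- unique(df$sequence_id[duplicated(df$sequence_id)])
    stop_trbkit(paste0("duplicated sequence_id: ",
                       paste(utils::head(dup, 5), collapse = ", ")),
                "trbkit_duplicate_id")
  }
  for (col in intersect(c("v_mismatches", "j_mismatches", "d_matched_length",
                          "junction_length", "v_sequence_end",
                          "j_sequence_start"), names(df))) {
    df[[col]] <- as.integer(df[[col]])
  }
  if ("productive" %in% names(df)) {
    raw <- df$productive
    df$productive <- raw %in% c("T", "TRUE", "true")
    df$productive[is.na(raw) | raw == ""] <- NA
  }
  df
}

#' Write an AIRR rearrangement TSV
#'
#' @param df rearrangement tibble (as produced by [assign_rearrangements()]).
#' @param file output path.
#' @export
write_airr <- function(df, file) {
  out <- df
  if ("productive" %in% names(out)) {
    out$productive <- ifelse(is.na(out$productive), NA,
                             ifelse(out$productive, "T", "F"))
  }
  readr::write_tsv(out, file, na = "")
  invisible(file)
}
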