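#' Per-sample gene usage table
#'
#' Usage of a gene is the fraction of a sample's unique sequences mapped to
#' it. Multi-call reads are either split fractionally across their calls or
#' attributed to their first call.
#'
#' @param df combined rearrangement tibble with a `sample_id` column.
#' @param call_col which call to tabulate (`"v_call"`, `"d_call"`,
#'   `"j_call"`).
#' @param counting `"fractional"` (a read with k calls adds 1/k to each
#'   gene) or `"first"`.
#' @return Tibble with `sample_id`, `gene`, `count`, `total`, `usage`;
#'   usage sums to 1 per sample over counted genes.
#' @export
usage_table <- function(df, call_col = "v_call",
                        counting = c("fractional", "first")) {
  counting <- match.arg(counting)
  calls <- df[[call_col]]
  keep <- !is.na(calls) & calls != ""
  df <- df[keep, , drop = FALSE]
  calls <- split_calls(df[[call_col]])
  if (counting == "first") calls <- lapply(calls, `[`, 1L)
  k <- lengths(calls)
  long <- tibble::tibble(
    sample_id = rep(df$sample_id, k),
    gene = call_gene(unlist(calls, use.names = FALSE)),
    w = rep(1 / k, k))
  counts <- dplyr::summarise(dplyr::group_by(long, sample_id, gene),
                             count = sum(w), .groups = "drop")
  totals <- dplyr::summarise(dplyr::group_by(counts, sample_id),
                             total = sum(count), .groups = "drop")
  out <- dplyr::left_join(counts, totals, by = "sample_id")
  out$usage <- out$count / out$total
  out
}

#' Binomial test for double chromosome deletions
#'
#' For each gene, the reference rate P is the smallest per-sample usage of
#' that gene exceeding `min_cutoff` (samples at or below the cutoff are
#' themselves deletion candidates and are excluded from setting P). Every
#' (sample, gene) pair is then scored with the lower binomial tail
#' p = Pr[Binomial(N, P) <= X], where X is the sample's unique-read count
#' for the gene and N its total; a pair is declared deleted when its
#' Bonferroni-adjusted p-value (over all tested pairs) falls below `alpha`.
#' Deletions are statements about the expressed repertoire, not the genome.
#'
#' @param usage a [usage_table()] tibble (all samples of the population).
#' @param min_cutoff usage cutoff below which a sample is a deletion
#'   candidate for the gene.
#' @param alpha significance level after Bonferroni adjustment.
#' @return Tibble with `sample_id`, `gene`, `X`, `N`, `P`, `p_value`,
#'   `p_adjusted`, `deleted`, `testable`. Genes for which no sample
#'   exceeds the cutoff are reported untestable.
#' @export
deletion_tests <- function(usage, min_cutoff = 0.0005, alpha = 0.01) {
  samples <- unique(usage$sample_id)
  genes <- unique(usage$gene)
  # complete the sample x gene grid: absent combinations are zero counts
  grid <- merge(
    data.frame(sample_id = samples),
    data.frame(gene = genes))
  totals <- unique(usage[, c("sample_id", "total")])
  full <- dplyr::left_join(grid, usage[, c("sample_id", "gene", "count")],
                           by = c("sample_id", "gene"))
  full <- dplyr::left_join(full, totals, by = "sample_id")
  full$count[is.na(full$count)] <- 0
  full$usage <- full$count / full$total
  ref_p <- vapply(genes, function(g) {
    u <- full$usage[full$gene == g & full$usage > min_cutoff]
    if (length(u) == 0L) NA_real_ else min(u)
  }, numeric(1))
  full$P <- ref_p[match(full$gene, genes)]
  full$testable <- !is.na(full$P)
  full$X <- round(full$count)
  full$N <- round(full$total)
  full$p_value <- NA_real_
  t_idx <- which(full$testable)
  full$p_value[t_idx] <- stats::pbinom(full$X[t_idx], full$N[t_idx],
                                       full$P[t_idx])
  m <- length(t_idx)
  full$p_adjusted <- pmin(1, full$p_value * m)
  full$deleted <- !is.na(full$p_adjusted) & full$p_adjusted < alpha
  tibble::as_tibble(full[, c("sample_id", "gene", "X", "N", "P", "p_value",
                             "p_adjusted", "deleted", "testable")])
}
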