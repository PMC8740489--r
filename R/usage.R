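#' TRBJ family usage of one sample
#'
#' Summed usage of a J family's genes among J-assigned reads; the TRBJ1
#' and TRBJ2 fractions sum to one.
#'
#' @param df assigned rearrangement tibble of one sample.
#' @param counting multi-call handling, see [usage_table()].
#' @return Named numeric vector of family fractions (`TRBJ1`, `TRBJ2`).
#' @export
family_usage <- function(df, counting = "fractional") {
  if (!"sample_id" %in% names(df)) df$sample_id <- "sample"
  u <- usage_table(df, call_col = "j_call", counting = counting)
  fam <- sub("^(TRBJ[0-9]+).*$", "\\1", u$gene)
  tapply(u$usage, fam, sum)
}

#' Conditional TRBJ usage given the D gene
#'
#' P(J = j | D = d) over reads with a single D call matching `d_gene` and
#' a germline-matched D length above `min_d_length` nucleotides. For
#' TRBD2, which rearranges only with TRBJ2 genes, support is restricted to
#' the TRBJ2 family (reads whose J call contradicts the constraint are
#' assignment noise and are dropped).
#'
#' @param df assigned rearrangement tibble.
#' @param d_gene conditioning D gene.
#' @param min_d_length reads must have `d_matched_length` strictly greater
#'   than this.
#' @return Named numeric vector over J genes summing to 1 (with a warning
#'   and length 0 when no read qualifies).
#' @export
conditional_usage <- function(df, d_gene = "TRBD2", min_d_length = 7L) {
  keep <- n_calls(df$d_call) == 1L &
    call_gene(ifelse(is.na(df$d_call), "", df$d_call)) == d_gene &
    df$d_matched_length > min_d_length &
    n_calls(df$j_call) == 1L
  j <- call_gene(df$j_call[which(keep)])
  if (d_gene == "TRBD2") j <- j[grepl("^TRBJ2", j)]
  if (length(j) == 0L) {
    warning("no qualifying reads for P(J | ", d_gene, ")")
    return(stats::setNames(numeric(), character()))
  }
  tab <- table(j)
  stats::setNames(as.numeric(tab) / sum(tab), names(tab))
}

#' Compare gene usage between genotype groups
#'
#' Per-gene two-tailed Mann-Whitney (Wilcoxon rank-sum) tests between two
#' sample groups, Bonferroni-adjusted over the genes tested in the panel.
#'
#' @param usage a [usage_table()] tibble.
#' @param groups named character vector, sample -> group label; exactly
#'   two distinct labels with at least two samples each are compared.
#' @return Tibble with `gene`, `statistic`, `p_raw`,
#'   `p_adjusted` (`min(1, p_raw * n_genes)`), `significant`
#'   (`p_adjusted < 0.05`) and `stars` (`*`, `**`, `***` at
#'   0.05/0.01/0.001).
#' @export
compare_usage <- function(usage, groups) {
  labs <- unique(groups)
  if (length(labs) != 2L) {
    stop_trbkit("compare_usage needs exactly two groups", "trbkit_bad_groups")
  }
  if (any(table(groups) < 2L)) {
    stop_trbkit("each group needs at least two samples", "trbkit_bad_groups")
  }
  usage <- usage[usage$sample_id %in% names(groups), , drop = FALSE]
  genes <- sort(unique(usage$gene))
  rows <- list()
  for (g in genes) {
    gu <- usage[usage$gene == g, , drop = FALSE]
    # samples without the gene have usage zero
    vals <- stats::setNames(rep(0, length(groups)), names(groups))
    vals[gu$sample_id] <- gu$usage
    x <- vals[groups == labs[1]]
    y <- vals[groups == labs[2]]
    if (length(unique(c(x, y))) == 1L) {
      rows[[g]] <- tibble::tibble(gene = g, statistic = NA_real_, p_raw = 1)
      next
    }
    wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
    rows[[g]] <- tibble::tibble(gene = g, statistic = unname(wt$statistic),
                                p_raw = wt$p.value)
  }
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- pmin(1, out$p_raw * nrow(out))
  out$significant <- out$p_adjusted < 0.05
  out$stars <- ifelse(out$p_adjusted < 0.001, "***",
               ifelse(out$p_adjusted < 0.01, "**",
               ifelse(out$p_adjusted < 0.05, "*", "n.s.")))
  out
}
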