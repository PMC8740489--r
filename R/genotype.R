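#' Select reads that qualify for genotyping
#'
#' V genotyping uses reads with a single (only one best match) V call and
#' at most one mismatch inside the boundary window. D genotyping uses reads
#' with a single D call, no D mismatches (the exact-match D assigner never
#' reports mismatched D segments) and a germline-matched D length of at
#' least nine nucleotides. J genotyping uses reads with a single J call.
#'
#' @param df rearrangement tibble from [assign_rearrangements()].
#' @param segment `"V"`, `"D"` or `"J"`.
#' @param max_v_mismatches mismatch ceiling for V reads.
#' @param min_d_length minimal D germline length for D reads.
#' @return The qualifying subset of `df`.
#' @export
select_genotype_reads <- function(df, segment = c("V", "D", "J"),
                                  max_v_mismatches = 1L, min_d_length = 9L) {
  segment <- match.arg(segment)
  keep <- switch(segment,
    V = n_calls(df$v_call) == 1L & !is.na(df$v_mismatches) &
        df$v_mismatches <= max_v_mismatches,
    D = n_calls(df$d_call) == 1L & df$d_matched_length >= min_d_length,
    J = n_calls(df$j_call) == 1L)
  df[which(keep), , drop = FALSE]
}

# Log-likelihood of the counts under one genotype model (member subset).
# Members share the non-error mass equally; the mis-assignment mass epsilon
# is split over the observed non-member alleles (none observed: members
# simply share the whole mass 1/k).
genotype_model_loglik <- function(counts, members, epsilon) {
  k <- length(members)
  alleles <- names(counts)
  is_member <- alleles %in% members
  p <- numeric(length(counts))
  if (all(is_member)) {
    p[] <- 1 / k
  } else {
    p[is_member] <- (1 - epsilon) / k
    p[!is_member] <- epsilon / sum(!is_member)
  }
  if (any(counts > 0 & p == 0)) return(-Inf)
  sum(counts[counts > 0] * log(p[counts > 0]))
}

#' Bayesian genotype call for one gene
#'
#' Model space: every non-empty subset of the top-`max_alleles` observed
#' alleles (by count); alleles beyond the cap are pooled into the
#' mis-assignment mass. Under a model with k member alleles the expected
#' fractions are (1 - epsilon)/k per member with the epsilon mass shared by
#' the non-member alleles; the marginal likelihood is the multinomial
#' likelihood at those fractions, with a uniform prior over models. The
#' confidence `lk` is the base-10 log of the Bayes factor K between the
#' best and runner-up model.
#'
#' @param counts named numeric vector of unique-read counts per allele.
#' @param epsilon mis-assignment probability in `[0, 0.5)`.
#' @param max_alleles cap on genotype size (and on the modelled alleles).
#' @return List of class `genotype_call`: `alleles` (called set), `counts`,
#'   `total_reads`, `lk`, and the ranked `models` tibble.
#' @export
bayes_genotype <- function(counts, epsilon = 0.01, max_alleles = 4L) {
  counts <- counts[!is.na(counts)]
  if (length(counts) == 0L || sum(counts) == 0) {
    stop_trbkit("no reads to genotype", "trbkit_no_data")
  }
  if (epsilon < 0 || epsilon >= 0.5) {
    stop_trbkit("epsilon must be in [0, 0.5)", "trbkit_bad_epsilon")
  }
  counts <- sort(counts, decreasing = TRUE)
  top <- names(counts)[seq_len(min(max_alleles, length(counts)))]
  models <- list()
  for (k in seq_along(top)) {
    combs <- utils::combn(top, k, simplify = FALSE)
    models <- c(models, combs)
  }
  ll <- vapply(models, function(m) genotype_model_loglik(counts, m, epsilon),
               numeric(1))
  ord <- order(ll, decreasing = TRUE)
  lk <- if (length(ll) > 1L) (ll[ord[1L]] - ll[ord[2L]]) / log(10) else Inf
  best <- models[[ord[1L]]]
  structure(list(
    alleles = sort(best),
    counts = counts[names(counts) %in% best],
    total_reads = sum(counts),
    lk = lk,
    models = tibble::tibble(
      model = vapply(models[ord], paste, character(1), collapse = ";"),
      loglik = ll[ord])
  ), class = "genotype_call")
}

#' @export
print.genotype_call <- function(x, ...) {
  cat("Genotype:", paste(x$alleles, collapse = ";"),
      sprintf("(lk = %.2f, %d reads)\n", x$lk, x$total_reads))
  invisible(x)
}

#' Genotype every gene of one sample
#'
#' Applies the genotyping read filters, counts unique reads per allele and
#' calls [bayes_genotype()] gene by gene.
#'
#' @param df rearrangement tibble of one sample.
#' @param segment `"V"`, `"D"` or `"J"`.
#' @param epsilon mis-assignment probability passed to the model. The
#'   TRBD2-specific tri-modal treatment lives in [call_d2_groups()]; this
#'   generic model is appropriate for V and J genes.
#' @param min_reads genes with fewer qualifying reads are not called.
#' @return Tibble with `gene`, `alleles` (`;`-joined), `counts`
#'   (`;`-joined, same order), `total`, `lk`.
#' @export
genotype_sample <- function(df, segment = "V", epsilon = 0.01, min_reads = 5L) {
  sel <- select_genotype_reads(df, segment)
  call_col <- switch(segment, V = "v_call", D = "d_call", J = "j_call")
  calls <- sel[[call_col]]
  genes <- call_gene(calls)
  alleles <- call_allele(calls)
  out <- list()
  for (g in unique(genes)) {
    cnt <- table(alleles[genes == g])
    if (sum(cnt) < min_reads) next
    gc <- bayes_genotype(stats::setNames(as.numeric(cnt), names(cnt)),
                         epsilon = epsilon)
    out[[g]] <- tibble::tibble(
      gene = g,
      alleles = paste(gc$alleles, collapse = ";"),
      counts = paste(gc$counts[gc$alleles], collapse = ";"),
      total = gc$total_reads,
      lk = gc$lk)
  }
  if (length(out) == 0L) {
    return(tibble::tibble(gene = character(), alleles = character(),
                          counts = character(), total = numeric(),
                          lk = numeric()))
  }
  dplyr::arrange(dplyr::bind_rows(out), gene)
}
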