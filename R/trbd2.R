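#' Fraction of TRBD2*01 among unambiguous TRBD2 assignments
#'
#' @param df rearrangement tibble of one sample.
#' @param gene D gene of interest.
#' @return Fraction in `[0, 1]`, or `NA` (with a warning) when the sample
#'   has no unambiguously assigned reads of that gene.
#' @export
trbd2_fraction <- function(df, gene = "TRBD2") {
  single <- df$d_call[n_calls(df$d_call) == 1L]
  d2 <- single[call_gene(single) == gene]
  if (length(d2) == 0L) {
    warning("no unambiguous ", gene, " assignments; sample excluded")
    return(NA_real_)
  }
  mean(call_allele(d2) == "01")
}

#' Equilibrium point between two normal distributions
#'
#' The point x between the two means at which the two group-membership
#' tail probabilities are equal, i.e. the solution of
#' Phi((mu1 - x)/sigma1) = Phi((x - mu2)/sigma2); in closed form
#' x = (mu1*sigma2 + mu2*sigma1) / (sigma1 + sigma2). Used as the border
#' between adjacent genotype groups.
#'
#' @param mu1,sigma1 mean and SD of the lower group.
#' @param mu2,sigma2 mean and SD of the upper group.
#' @return The equilibrium point (the common mean when `mu1 == mu2`).
#' @export
equilibrium_point <- function(mu1, sigma1, mu2, sigma2) {
  if (any(c(sigma1, sigma2) <= 0)) {
    stop_trbkit("sigma must be positive", "trbkit_bad_sigma")
  }
  (mu1 * sigma2 + mu2 * sigma1) / (sigma1 + sigma2)
}

#' Tri-modal TRBD2 genotype-group calling
#'
#' Samples are first grouped by the coarse ranges of their TRBD2*01
#' fraction (0-0.2 homozygous *02, 0.2-0.8 heterozygous, 0.8-1 homozygous
#' *01); per-group means and SDs then define refined borders as the
#' equilibrium points between adjacent groups, and samples are re-assigned
#' by those borders. The homozygous group means double as mis-assignment
#' estimates: eps(01->02) = 1 - mu(hom01) and eps(02->01) = mu(hom02), from
#' which the heterozygous TRBD2*01 usage corrected for mis-assignment is
#' t = (mean_het - eps21) / (1 - eps12 - eps21).
#'
#' @param fractions named numeric vector, sample -> TRBD2*01 fraction.
#'   `NA` fractions are dropped.
#' @param coarse_cuts the initial group cut points.
#' @param iterate if `TRUE`, border computation and re-assignment are
#'   repeated until the grouping is stable (at most `max_iter` passes);
#'   the default single pass follows the original procedure.
#' @param max_iter iteration cap.
#' @return List of class `d2_group_model`: `samples` tibble (sample,
#'   fraction, group), `group_params` (group, n, mu, sigma), `borders`
#'   (x_low, x_high), `eps_01_to_02`, `eps_02_to_01`,
#'   `corrected_het_usage`.
#' @export
call_d2_groups <- function(fractions, coarse_cuts = c(0.2, 0.8),
                           iterate = FALSE, max_iter = 10L) {
  fractions <- fractions[!is.na(fractions)]
  if (length(fractions) < 3L) {
    stop_trbkit("need at least 3 samples with defined fractions",
                "trbkit_no_data")
  }
  group_of <- function(f, cuts) {
    ifelse(f < cuts[1], "hom02", ifelse(f <= cuts[2], "het", "hom01"))
  }
  grp <- group_of(fractions, coarse_cuts)
  borders <- coarse_cuts
  n_pass <- if (iterate) max_iter else 1L
  for (pass in seq_len(n_pass)) {
    params <- lapply(c("hom02", "het", "hom01"), function(g) {
      f <- fractions[grp == g]
      list(group = g, n = length(f),
           mu = if (length(f)) mean(f) else NA_real_,
           sigma = if (length(f) >= 2L) stats::sd(f) else NA_real_)
    })
    names(params) <- c("hom02", "het", "hom01")
    pairable <- function(a, b) {
      !is.na(params[[a]]$mu) && !is.na(params[[b]]$mu) &&
        !is.na(params[[a]]$sigma) && !is.na(params[[b]]$sigma) &&
        params[[a]]$sigma > 0 && params[[b]]$sigma > 0
    }
    new_borders <- borders
    if (pairable("hom02", "het")) {
      new_borders[1] <- equilibrium_point(params$hom02$mu, params$hom02$sigma,
                                          params$het$mu, params$het$sigma)
    } else {
      if (params$hom02$n == 0L || params$het$n == 0L) {
        warning("empty coarse group; low border falls back to ", coarse_cuts[1])
      }
      new_borders[1] <- coarse_cuts[1]
    }
    if (pairable("het", "hom01")) {
      new_borders[2] <- equilibrium_point(params$het$mu, params$het$sigma,
                                          params$hom01$mu, params$hom01$sigma)
    } else {
      if (params$hom01$n == 0L || params$het$n == 0L) {
        warning("empty coarse group; high border falls back to ", coarse_cuts[2])
      }
      new_borders[2] <- coarse_cuts[2]
    }
    borders <- new_borders
    new_grp <- group_of(fractions, borders)
    stable <- identical(new_grp, grp)
    grp <- new_grp
    if (stable) break
  }
  # final parameters under the final assignment
  params <- dplyr::bind_rows(lapply(c("hom02", "het", "hom01"), function(g) {
    f <- fractions[grp == g]
    tibble::tibble(group = g, n = length(f),
                   mu = if (length(f)) mean(f) else NA_real_,
                   sigma = if (length(f) >= 2L) stats::sd(f) else NA_real_)
  }))
  mu_of <- function(g) params$mu[params$group == g]
  eps12 <- 1 - mu_of("hom01")   # TRBD2*01 mis-assigned as *02
  eps21 <- mu_of("hom02")       # TRBD2*02 mis-assigned as *01
  t_corr <- (mu_of("het") - eps21) / (1 - eps12 - eps21)
  structure(list(
    samples = tibble::tibble(sample = names(fractions),
                             fraction = unname(fractions), group = grp),
    group_params = params,
    borders = c(x_low = borders[1], x_high = borders[2]),
    eps_01_to_02 = eps12,
    eps_02_to_01 = eps21,
    corrected_het_usage = t_corr
  ), class = "d2_group_model")
}

#' @export
print.d2_group_model <- function(x, ...) {
  cat("TRBD2 genotype groups:",
      sprintf("borders %.4f / %.4f\n", x$borders[1], x$borders[2]))
  print(x$group_params)
  cat(sprintf("eps(01->02) = %.4f, eps(02->01) = %.4f, corrected het usage = %.4f\n",
              x$eps_01_to_02, x$eps_02_to_01, x$corrected_het_usage))
  invisible(x)
}

#' Hardy-Weinberg frequencies and chi-square test
#'
#' @param counts numeric vector of genotype counts `(hom1, het, hom2)`.
#' @return List with observed genotype frequencies, allele frequencies
#'   `p`/`q`, expected counts under Hardy-Weinberg proportions, the
#'   1-df chi-square statistic and its p-value.
#' @export
hwe_test <- function(counts) {
  if (length(counts) != 3L || any(counts < 0) || sum(counts) == 0) {
    stop_trbkit("counts must be (hom1, het, hom2) with positive total",
                "trbkit_bad_counts")
  }
  n <- sum(counts)
  obs_freq <- counts / n
  p <- (2 * counts[1] + counts[2]) / (2 * n)
  q <- 1 - p
  expected <- c(p^2, 2 * p * q, q^2) * n
  chisq <- sum((counts - expected)^2 / expected)
  list(obs_freq = unname(obs_freq), p = unname(p), q = unname(q),
       expected = unname(expected), chisq = unname(chisq),
       p_value = unname(stats::pchisq(chisq, df = 1, lower.tail = FALSE)))
}
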