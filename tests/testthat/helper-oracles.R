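# Independent oracles and small fixture builders used across the suite.
# The oracles deliberately take different code paths from the package
# implementation they check.

# Free-leading-pad unit-cost alignment distance via base adist():
# a free padded beginning is equivalent to skipping a prefix of exactly
# one of the two sequences at no cost, then paying plain edit distance.
oracle_pad_cost <- function(a, b) {
  costs <- c(
    vapply(0:nchar(a), function(i) {
      utils::adist(substring(a, i + 1), b)[1, 1]
    }, numeric(1)),
    vapply(0:nchar(b), function(j) {
      utils::adist(a, substring(b, j + 1))[1, 1]
    }, numeric(1)))
  min(costs)
}

# Numeric root of the tail-probability equality defining the equilibrium
# point between two normal distributions.
oracle_equilibrium <- function(mu1, sigma1, mu2, sigma2) {
  if (mu1 == mu2) return(mu1)
  lo <- min(mu1, mu2) - 1e3 * max(sigma1, sigma2)
  hi <- max(mu1, mu2) + 1e3 * max(sigma1, sigma2)
  stats::uniroot(function(x) {
    stats::pnorm((mu1 - x) / sigma1) - stats::pnorm((x - mu2) / sigma2)
  }, c(lo, hi), tol = 1e-12)$root
}

# Exhaustive genotype-model enumeration via dmultinom, written
# independently of the package's likelihood code.
oracle_genotype <- function(counts, epsilon, max_alleles = 4L) {
  counts <- sort(counts, decreasing = TRUE)
  top <- names(counts)[seq_len(min(max_alleles, length(counts)))]
  models <- unlist(lapply(seq_along(top), function(k) {
    utils::combn(top, k, simplify = FALSE)
  }), recursive = FALSE)
  ll <- vapply(models, function(m) {
    k <- length(m)
    inside <- names(counts) %in% m
    if (all(inside)) {
      p <- rep(1 / k, length(counts))
    } else {
      p <- ifelse(inside, (1 - epsilon) / k, epsilon / sum(!inside))
    }
    if (any(counts > 0 & p == 0)) return(-Inf)
    stats::dmultinom(counts, prob = p / sum(p), log = TRUE)
  }, numeric(1))
  ord <- order(ll, decreasing = TRUE)
  # dmultinom includes the multinomial coefficient; it cancels in the ratio
  list(alleles = sort(models[[ord[1]]]),
       lk = (ll[ord[1]] - ll[ord[2]]) / log(10))
}

# Expected (merged-label) V genotypes from a simulation truth record.
expected_v_genotypes <- function(truth_sample, merged_groups) {
  label_of <- function(g) {
    for (grp in merged_groups) {
      if (g %in% grp) return(paste(sort(grp), collapse = "/"))
    }
    g
  }
  out <- list()
  for (g in names(truth_sample$genotype)) {
    if (!startsWith(g, "TRBV")) next
    lab <- label_of(g)
    out[[lab]] <- sort(unique(c(out[[lab]], truth_sample$genotype[[g]])))
  }
  out
}

# One assigned population: simulate under `config_args`, assign every
# sample against the merged toy reference, return assignments + truth.
sim_and_assign <- function(seed, n_individuals, depth, protocol = NULL, ...) {
  set <- toy_germline_set()
  protocol <- protocol %||% protocol_spec("full")
  merged <- merge_indistinguishable(set, protocol)
  cfg <- simulate_config(seed = seed, n_individuals = n_individuals,
                         depth = depth, protocol = protocol, ...)
  sim <- simulate_population(cfg)
  assigned <- lapply(names(sim$samples), function(sid) {
    assign_rearrangements(sim$samples[[sid]], merged, protocol,
                          sample_id = sid)
  })
  names(assigned) <- names(sim$samples)
  list(sim = sim, assigned = assigned, merged = merged, protocol = protocol)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
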