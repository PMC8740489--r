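test_that("TRBD2*01 fraction counts unambiguous assignments only", {
  df <- tibble::tibble(d_call = c(rep("TRBD2*01", 30), rep("TRBD2*02", 210),
                                  rep("TRBD2*01,TRBD2*02", 40),
                                  rep("TRBD1*01", 100)))
  expect_equal(trbd2_fraction(df), 30 / 240)
  expect_equal(trbd2_fraction(tibble::tibble(d_call = rep("TRBD2*01", 5))), 1)
  expect_warning(f <- trbd2_fraction(tibble::tibble(d_call = "TRBD1*01")),
                 "excluded")
  expect_true(is.na(f))
})

test_that("equilibrium point closed form solves the tail-probability equality", {
  expect_equal(equilibrium_point(0.2, 0.05, 0.6, 0.05), 0.4)  # equal SDs
  expect_equal(equilibrium_point(0.3, 0.02, 0.3, 0.07), 0.3)  # equal means
  expect_error(equilibrium_point(0.1, 0, 0.5, 0.1),
               class = "trbkit_bad_sigma")
  withr::with_seed(99, {
    for (i in 1:200) {
      mu1 <- stats::runif(1, 0, 0.4); mu2 <- stats::runif(1, 0.5, 1)
      s1 <- stats::runif(1, 0.005, 0.2); s2 <- stats::runif(1, 0.005, 0.2)
      x <- equilibrium_point(mu1, s1, mu2, s2)
      expect_equal(x, oracle_equilibrium(mu1, s1, mu2, s2), tolerance = 1e-9)
      # the defining property itself
      expect_equal(stats::pnorm((mu1 - x) / s1),
                   stats::pnorm((x - mu2) / s2), tolerance = 1e-12)
      expect_true(x > mu1 && x < mu2)
    }
  })
})

test_that("tri-modal group calling recovers generating labels and rates", {
  withr::with_seed(2022, {
    n <- 300
    lab <- sample(c("hom02", "het", "hom01"), n, replace = TRUE)
    f <- stats::setNames(ifelse(lab == "hom02", stats::rnorm(n, 0.12, 0.03),
                         ifelse(lab == "het", stats::rnorm(n, 0.45, 0.08),
                                stats::rnorm(n, 0.96, 0.02))),
                         paste0("s", seq_len(n)))
    f <- pmin(pmax(f, 0), 1)
    model <- call_d2_groups(f)
    expect_gte(mean(model$samples$group == lab), 0.99)
    # borders strictly between adjacent group means
    mu <- stats::setNames(model$group_params$mu, model$group_params$group)
    expect_true(mu[["hom02"]] < model$borders[["x_low"]])
    expect_true(model$borders[["x_low"]] < mu[["het"]])
    expect_true(mu[["het"]] < model$borders[["x_high"]])
    expect_true(model$borders[["x_high"]] < mu[["hom01"]])
    # mis-assignment estimates recover the generating means
    expect_lt(abs(model$eps_02_to_01 - 0.12), 0.03)
    expect_lt(abs(model$eps_01_to_02 - 0.04), 0.03)
    # corrected usage is the linear unmixing of the heterozygous mean
    t_by_hand <- (mu[["het"]] - model$eps_02_to_01) /
      (1 - model$eps_01_to_02 - model$eps_02_to_01)
    expect_equal(model$corrected_het_usage, unname(t_by_hand))
  })
})

test_that("a homozygous-*01 group mean of 0.96 gives a 4% mis-assignment", {
  f <- c(stats::setNames(c(0.95, 0.96, 0.97), paste0("a", 1:3)),
         stats::setNames(c(0.44, 0.45, 0.46), paste0("b", 1:3)),
         stats::setNames(c(0.11, 0.12, 0.13), paste0("c", 1:3)))
  model <- call_d2_groups(f)
  expect_equal(model$eps_01_to_02, 0.04, tolerance = 1e-12)
  expect_equal(model$eps_02_to_01, 0.12, tolerance = 1e-12)
  # corrected usage equals the raw mean when both rates are zero
  f0 <- c(stats::setNames(c(0, 0, 0), paste0("c", 1:3)),
          stats::setNames(c(0.39, 0.40, 0.41), paste0("b", 1:3)),
          stats::setNames(c(1, 1, 1), paste0("a", 1:3)))
  m0 <- call_d2_groups(f0)
  expect_equal(m0$corrected_het_usage, 0.40)
})

test_that("degenerate cohorts fall back to the coarse cut points", {
  f <- stats::setNames(stats::runif(6, 0.85, 0.99), paste0("s", 1:6))
  w <- testthat::capture_warnings(model <- call_d2_groups(f))
  expect_true(any(grepl("empty coarse group", w)))
  expect_true(all(model$samples$group == "hom01"))
  expect_equal(unname(model$borders), c(0.2, 0.8))
})

test_that("re-assignment by borders never moves a sample across two groups", {
  withr::with_seed(5, {
    for (rep in 1:5) {
      n <- 120
      f <- stats::setNames(c(stats::rnorm(n / 3, 0.12, 0.04),
                             stats::rnorm(n / 3, 0.45, 0.1),
                             stats::rnorm(n / 3, 0.95, 0.03)),
                           paste0("s", 1:n))
      f <- pmin(pmax(f, 0), 1)
      model <- call_d2_groups(f)
      coarse <- ifelse(f < 0.2, "hom02", ifelse(f <= 0.8, "het", "hom01"))
      moved2 <- (coarse == "hom02" & model$samples$group == "hom01") |
        (coarse == "hom01" & model$samples$group == "hom02")
      expect_false(any(moved2))
    }
  })
})

test_that("Hardy-Weinberg utilities reproduce the textbook arithmetic", {
  h <- hwe_test(c(192, 404, 190))
  expect_equal(round(h$obs_freq[2], 3), 0.514)
  expect_equal(h$p + h$q, 1)
  exact <- hwe_test(c(25, 50, 25))
  expect_equal(exact$chisq, 0)
  expect_equal(exact$p, 0.5)
  expect_error(hwe_test(c(0, 0, 0)), class = "trbkit_bad_counts")
  # heterozygosity 2p(1-p) is maximised at one half
  opt <- stats::optimize(function(p) 2 * p * (1 - p), c(0, 1), maximum = TRUE)
  expect_equal(opt$objective, 0.5, tolerance = 1e-6)
  expect_equal(opt$maximum, 0.5, tolerance = 1e-4)
})
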