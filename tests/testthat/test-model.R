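# Probabilistic kernels: single-base and dinucleotide observation
# probabilities, genotype prior, window log-likelihood.

test_that("single_base_prob matches hand-computed and enumerated values", {
  # no damage, no error: a C stays a C
  expect_equal(single_base_prob("C", 0, 0, 0.75, TRUE, 0, 0), 1.0)
  # linearity of the methylation mixture: 0.75*0.4 + 0.25*0.1
  expect_equal(single_base_prob("T", 0.4, 0.1, 0.75, TRUE, 0, 0), 0.325)
  # with sequencing and mapping error (value frozen from the enumeration
  # oracle: 0.05*0.25 + 0.95*(0.325*0.99 + 0.675*0.01/3))
  expect_equal(single_base_prob("T", 0.4, 0.1, 0.75, TRUE, 0.01, 0.05),
               0.3203, tolerance = 1e-12)
  expect_equal(oracle_single_base("T", 0.4, 0.1, 0.75, TRUE, 0.01, 0.05),
               0.3203, tolerance = 1e-12)
  expect_error(single_base_prob("T", 1.4, 0.1, 0.75, TRUE, 0, 0),
               "probability")
})

test_that("single_base_prob normalizes and agrees with the oracle", {
  set.seed(42)
  for (i in 1:25) {
    d1 <- runif(1); d0 <- runif(1); F <- runif(1)
    cpg <- sample(c(TRUE, FALSE), 1)
    eps <- runif(1, 0, 0.3); Q <- runif(1, 0, 0.5)
    p <- vapply(c("C", "T", "OTHER"), function(o)
      single_base_prob(o, d1, d0, F, cpg, eps, Q), numeric(1))
    expect_equal(sum(p), 1, tolerance = 1e-12)
    for (o in c("C", "T", "OTHER"))
      expect_equal(single_base_prob(o, d1, d0, F, cpg, eps, Q),
                   oracle_single_base(o, d1, d0, F, cpg, eps, Q),
                   tolerance = 1e-12)
  }
})

test_that("genotype prior follows the independent-allele-draw model", {
  p0 <- genotype_prior(0)
  expect_equal(unname(p0$probs),
               c(1, 0, 0, 0, 0, 0, 0))
  p <- genotype_prior(0.001)
  expect_equal(unname(p$probs[["CG/CG"]]), 0.997^2)
  expect_equal(unname(p$probs[["CG/TG"]]), 2 * 0.997 * 0.001)
  expect_equal(unname(p$probs[["CG/CA"]]), 2 * 0.997 * 0.001)
  expect_equal(unname(p$probs[["TG/CA"]]), 2 * 0.001^2)
  expect_equal(sum(p$probs), 1, tolerance = 1e-15)
  for (th in c(0, 0.001, 0.05, 0.25)) {
    pr <- genotype_prior(th)
    expect_equal(sum(pr$probs), 1, tolerance = 1e-12)
    expect_true(all(pr$probs >= 0))
    if (th < 0.25)
      expect_equal(names(which.max(pr$probs)), "CG/CG")
  }
  expect_error(genotype_prior(0.3), "theta")
  expect_error(genotype_prior(-0.1), "theta")
})

clean_obs <- function(base1, base2, strand = "+", eps1 = 0, eps2 = 0,
                      Q = 0, k1 = 0L, v1 = "5p", k2 = 0L, v2 = "5p") {
  data.frame(base1 = base1, base2 = base2, eps1 = eps1, eps2 = eps2,
             Q = Q, strand = strand, k1 = k1, v1 = v1, k2 = k2, v2 = v2,
             stringsAsFactors = FALSE)
}

flatD <- function(d0, d1, K = 5) {
  deamination_profile(
    rate_unmeth = matrix(d0, K, 2, dimnames = list(NULL, c("5p", "3p"))),
    rate_meth = matrix(d1, K, 2, dimnames = list(NULL, c("5p", "3p"))))
}

test_that("dinucleotide_obs_prob reproduces closed-form cases", {
  D0 <- flatD(0, 0)
  # clean reference read, no variation, no damage
  expect_equal(dinucleotide_obs_prob(clean_obs("C", "G"), "CG/CG", 0, D0), 1)
  # methylation mixture linearity: 0.5*0.4 + 0.5*0.1
  D <- flatD(0.1, 0.4)
  expect_equal(dinucleotide_obs_prob(clean_obs("T", "G"), "CG/CG", 0.5, D),
               0.25)
  # reverse-strand clean read is (G, C) in sequenced-strand space
  expect_equal(dinucleotide_obs_prob(clean_obs("G", "C", strand = "-"),
                                     "CG/CG", 0, D0), 1)
})

test_that("dinucleotide_obs_prob agrees with exhaustive enumeration", {
  set.seed(7)
  D <- random_profile()
  for (i in 1:40) {
    o <- random_pile_table(1, max_reads = 1)
    f <- runif(1)
    for (g in .ognames)
      expect_equal(dinucleotide_obs_prob(o, g, f, D),
                   oracle_dinuc(o, g, f, D), tolerance = 1e-12)
  }
})

test_that("dinucleotide probabilities normalize over the 16 base pairs", {
  set.seed(11)
  D <- random_profile()
  bases <- c("A", "C", "G", "T")
  for (strand in c("+", "-")) for (g in c("CG/CG", "CG/TG", "TG/CA", "OTHER")) {
    f <- runif(1); eps1 <- runif(1, 0, 0.2); eps2 <- runif(1, 0, 0.2)
    Q <- runif(1, 0, 0.5)
    tot <- 0
    for (b1 in bases) for (b2 in bases)
      tot <- tot + dinucleotide_obs_prob(
        clean_obs(b1, b2, strand = strand, eps1 = eps1, eps2 = eps2, Q = Q,
                  k1 = 1L, v1 = "5p", k2 = 2L, v2 = "3p"), g, f, D)
    expect_equal(tot, 1, tolerance = 1e-12)
  }
})

test_that("missing bases are marginalized", {
  set.seed(13)
  D <- random_profile()
  for (strand in c("+", "-")) {
    f <- runif(1)
    o_miss <- clean_obs("T", NA, strand = strand, eps1 = 0.05, eps2 = NA,
                        Q = 0.1, k2 = NA_integer_, v2 = NA_character_)
    tot <- sum(vapply(c("A", "C", "G", "T"), function(b2)
      dinucleotide_obs_prob(clean_obs("T", b2, strand = strand, eps1 = 0.05,
                                      eps2 = 0.07, Q = 0.1, k2 = 2L,
                                      v2 = "3p"), "CG/TG", f, D),
      numeric(1)))
    expect_equal(dinucleotide_obs_prob(o_miss, "CG/TG", f, D), tot,
                 tolerance = 1e-12)
  }
})

test_that("reverse-strand observations mirror forward ones", {
  # p(rev obs (b1, b2)) = p(fwd obs (b2, b1)) with terminal coordinates
  # swapped and the TG/CA alleles interchanged
  set.seed(17)
  D <- random_profile()
  swap_g <- c(`CG/CG` = "CG/CG", `CG/TG` = "CG/CA", `CG/CA` = "CG/TG",
              `TG/TG` = "CA/CA", `TG/CA` = "TG/CA", `CA/CA` = "TG/TG",
              OTHER = "OTHER")
  bases <- c("A", "C", "G", "T")
  for (i in 1:20) {
    b1 <- sample(bases, 1); b2 <- sample(bases, 1)
    e1 <- runif(1, 0, 0.2); e2 <- runif(1, 0, 0.2); Q <- runif(1, 0, 0.4)
    k1 <- sample(0:4, 1); k2 <- sample(0:4, 1)
    v1 <- sample(c("5p", "3p"), 1); v2 <- sample(c("5p", "3p"), 1)
    f <- runif(1); g <- sample(.ognames, 1)
    p_rev <- dinucleotide_obs_prob(
      clean_obs(b1, b2, "-", e1, e2, Q, k1, v1, k2, v2), g, f, D)
    p_fwd <- dinucleotide_obs_prob(
      clean_obs(b2, b1, "+", e2, e1, Q, k2, v2, k1, v1), swap_g[[g]], f, D)
    expect_equal(p_rev, p_fwd, tolerance = 1e-12)
  }
})

test_that("window log-likelihood: trivial cases and oracle equivalence", {
  D <- random_profile()
  empty <- data.frame(cpg_id = integer(), base1 = character(),
                      base2 = character(), eps1 = numeric(),
                      eps2 = numeric(), Q = numeric(), strand = character(),
                      k1 = integer(), v1 = character(), k2 = integer(),
                      v2 = character())
  expect_equal(window_log_likelihood(0.5, empty, D, genotype_prior(0.001)), 0)

  set.seed(23)
  # theta = 0: prior collapses onto CG/CG
  o <- random_pile_table(1, max_reads = 1)
  f <- 0.3
  expect_equal(window_log_likelihood(f, o, D, genotype_prior(0)),
               log(dinucleotide_obs_prob(o, "CG/CG", f, D)))
  # small windows vs raw-probability re-implementation
  for (i in 1:10) {
    piles <- random_pile_table(2, max_reads = 2)
    f <- runif(1)
    pr <- genotype_prior(runif(1, 0, 0.2))
    expect_equal(window_log_likelihood(f, piles, D, pr),
                 oracle_window_ll(f, piles, D, pr), tolerance = 1e-10)
  }
})

test_that("all-mismapped data makes the likelihood flat in f", {
  D <- flatD(0.1, 0.4)
  piles <- clean_obs(c("T", "C", "T"), "G", Q = 1)
  piles$cpg_id <- 1:3
  lls <- vapply(seq(0, 1, 0.1), function(f)
    window_log_likelihood(f, piles, D, genotype_prior(0.001)), numeric(1))
  expect_lt(diff(range(lls)), 1e-12)
})

test_that("likelihood argmax rises with the number of T-carrying reads", {
  D <- flatD(0.05, 0.5)
  grid <- seq(0, 1, 0.01)
  argmax <- vapply(0:6, function(nT) {
    piles <- clean_obs(c(rep("T", nT), rep("C", 6 - nT)), "G")
    piles$cpg_id <- 1L
    lls <- vapply(grid, function(f)
      window_log_likelihood(f, piles, D, genotype_prior(0.001)), numeric(1))
    grid[which.max(lls)]
  }, numeric(1))
  expect_true(all(diff(argmax) >= 0))
})
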