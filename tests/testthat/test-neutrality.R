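test_that("site frequency spectra fold and polarize correctly", {
  al <- AlignmentSample(c("AAA", "AAA", "AAT", "ATT"), outgroup = "AAA")
  sfs <- siteFrequencySpectrum(al)
  expect_equal(sfs$unfolded, c(1L, 1L, 0L))
  expect_equal(sfs$folded, c(1L, 1L))
  expect_equal(sfs$S, 2L)
  # monomorphic alignment: all-zero spectrum
  m <- siteFrequencySpectrum(AlignmentSample(rep("ACGT", 4)))
  expect_equal(sum(m$folded), 0L)
  # outgroup equal to the minor allele: derived count is n - minor count
  al2 <- AlignmentSample(c("A", "A", "A", "T"), outgroup = "T")
  expect_equal(siteFrequencySpectrum(al2)$unfolded, c(0L, 0L, 1L))
  # triallelic ingroup sites are excluded with a message
  expect_message(s3 <- siteFrequencySpectrum(
    AlignmentSample(c("A", "C", "G", "A"))), "triallelic")
  expect_equal(s3$S, 0L)
  # outgroup carrying a third state excludes the site from both spectra
  expect_message(s4 <- siteFrequencySpectrum(
    AlignmentSample(c("A", "A", "T", "T"), outgroup = "C")), "outgroup")
  expect_equal(s4$S, 0L)
  expect_equal(sum(s4$unfolded), 0L)
})

test_that("the hand-derived four-sequence example evaluates exactly", {
  al <- AlignmentSample(c("AAA", "AAA", "AAT", "ATT"), outgroup = "AAA")
  st <- neutralityStats(al)
  expect_equal(st$pi, 7 / 6)
  expect_equal(st$theta_w, 2 / (1 + 1 / 2 + 1 / 3))
  expect_equal(st$tajima_d, 0.5916, tolerance = 1e-4)
  expect_equal(st$theta_h, 5 / 6)
  expect_equal(st$fay_wu_h, 1 / 3)
  # closed form for Watterson's estimator
  k <- IGHGpop:::.sfs_constants(10)
  expect_equal(5 / k$a1, 1.7674, tolerance = 1e-4)
})

test_that("H = pi - theta_H and spectra agree on every random sample", {
  for (i in 1:50) {
    ra <- random_alignment(n = sample(4:10, 1), L = sample(10:30, 1),
                           seed = 1000 + i)
    al <- AlignmentSample(ra$seqs, outgroup = ra$outgroup)
    st <- suppressMessages(neutralityStats(al))
    sfs <- suppressMessages(siteFrequencySpectrum(al))
    # brute-force oracles: direct loops over pairs and sites
    expect_equal(st$pi, brute_pi(ra$seqs))
    expect_equal(st$S, brute_S(ra$seqs))
    expect_equal(sfs$unfolded, brute_unfolded(ra$seqs, ra$outgroup))
    expect_equal(st$fay_wu_h, st$pi - st$theta_h, tolerance = 1e-12)
    expect_equal(sum(sfs$folded), sum(sfs$unfolded))
    # statistics recomputed from first principles on the brute spectrum
    n <- st$n; S <- st$S
    a1 <- sum(1 / seq_len(n - 1))
    expect_equal(st$theta_w, S / a1)
    i_ <- seq_len(n - 1)
    th <- sum(2 * sfs$unfolded * i_^2) / (n * (n - 1))
    expect_equal(st$theta_h, th)
  }
})

test_that("outgroup-polarized statistics refuse to run without an outgroup", {
  al <- AlignmentSample(c("AAA", "AAA", "AAT", "ATT"))
  expect_error(fayWuH(al), "outgroup")
  expect_error(fuLiD(al), "outgroup")
  expect_error(fuLiF(al), "outgroup")
  st <- neutralityStats(al)
  expect_true(is.na(st$fay_wu_h) && is.na(st$fuli_d) && is.na(st$fuli_f))
  expect_false(is.na(st$fuli_dstar) || is.na(st$fuli_fstar))
})

test_that("a monomorphic sample yields undefined statistics and p = 1", {
  al <- AlignmentSample(rep("ACGTACGT", 5), outgroup = "ACGTACGT")
  null <- coalescentNull(5, S = 3, replicates = 100, seed = 1)
  st <- neutralityStats(al, null = null)
  expect_equal(st$S, 0L)
  expect_true(is.na(st$tajima_d))
  expect_true(all(st$p_values == 1))
})

test_that("coalescent simulation matches theory", {
  # theta mode: E[S] = theta * a1
  n <- 10; theta <- 2
  nu <- coalescentNull(n, theta = theta, replicates = 8000, seed = 3,
                       mode = "theta")
  a1 <- sum(1 / seq_len(n - 1))
  se <- sd(nu$S) / sqrt(length(nu$S))
  expect_lt(abs(mean(nu$S) - theta * a1), 3 * se)
  # fixed-S null: Tajima's D has its known near-zero mean
  nu2 <- coalescentNull(12, S = 6, replicates = 10000, seed = 4)
  expect_gt(mean(nu2$stats[, "tajima_d"], na.rm = TRUE), -0.2)
  expect_lt(mean(nu2$stats[, "tajima_d"], na.rm = TRUE), 0.1)
  expect_error(coalescentNull(1, S = 2), "n >= 2")
})

test_that("the neutrality report attaches lower-tail p-values", {
  cnt <- c("IGHG1*02" = 30, "IGHG1*03" = 10, "IGHG1*07" = 8)
  al <- simulateAlignment(acat, "IGHG1", cnt, cons_fa, divergence = 0.03,
                          seed = 5)
  rep_ <- neutralityReport(list(sim = al), replicates = 400, seed = 5)
  expect_equal(nrow(rep_), 6L)
  expect_true(all(rep_$p >= 0 & rep_$p <= 1, na.rm = TRUE))
  expect_true(all(rep_$significance %in% c("ns", "*", "**", "***")))
})
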