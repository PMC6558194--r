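test_that("allele frequencies come from direct counting, two per individual", {
  at <- data.frame(individual_id = paste0("i", 1:46), population = "P",
                   segment = "IGHG1", allele1 = "IGHG1*02",
                   allele2 = "IGHG1*07", ambiguity_class = "resolvable",
                   stringsAsFactors = FALSE)
  fr <- alleleFrequencies(at)
  expect_equal(sort(fr$count), c(46L, 46L))
  expect_equal(fr$frequency, c(0.5, 0.5))
  expect_equal(fr$two_n, c(92L, 92L))
  expect_error(alleleFrequencies(at[0, ]), "undefined")
  # deterministic reconstruction of the Guarani Kaiowa IGHG1 sample
  sim <- simulatePopulation(populationConfig("GKW", seed = 3), acat)
  fr2 <- alleleFrequencies(assignmentTable(typeIndividuals(
    sim$genotypes[sim$genotypes$segment == "IGHG1", ], acat)))
  expect_equal(fr2$count[fr2$allele == "IGHG1*02"], 48L)
  expect_equal(fr2$count[fr2$allele == "IGHG1*07"], 44L)
})

test_that("HWE exact test enumerates small tables correctly", {
  p <- hweExactTest(data.frame(allele1 = c("A", "a"), allele2 = c("A", "a"),
                               count = c(1, 1)))
  expect_equal(p$p, 1 / 3)
  expect_equal(p$method, "enumeration")
  # two double heterozygotes: the only alternative array is less probable
  p2 <- hweExactTest(data.frame(allele1 = "A", allele2 = "a", count = 2))
  expect_equal(p2$p, 1)
  # monomorphic sample
  pm <- hweExactTest(data.frame(allele1 = "A", allele2 = "A", count = 5))
  expect_equal(pm$p, 1)
  expect_true(pm$monomorphic)
})

test_that("Guo-Thompson Monte Carlo agrees with enumeration within 3 s.e.", {
  fixtures <- list(
    data.frame(allele1 = c("A", "A", "a"), allele2 = c("A", "a", "a"),
               count = c(6, 3, 5)),
    data.frame(allele1 = c("A", "A", "B", "B", "C", "A"),
               allele2 = c("A", "B", "B", "C", "C", "C"),
               count = c(4, 3, 2, 2, 1, 2)),
    data.frame(allele1 = c("A", "B", "C"), allele2 = c("B", "C", "A"),
               count = c(4, 4, 4)))
  for (f in fixtures) {
    pe <- hweExactTest(f, method = "enumeration")
    pm <- hweExactTest(f, method = "mc", steps = 4e4, burnin = 4e3, seed = 2)
    expect_lt(abs(pm$p - pe$p), 3 * pm$se)
  }
})

test_that("EM haplotype estimation handles degenerate and simulated data", {
  # all individuals homozygous at every locus: frequencies are the observed
  # combination frequencies and the log-likelihood is the multinomial maximum
  g <- rbind(
    data.frame(individual_id = paste0("i", 1:6), locus = "L1",
               allele1 = "a", allele2 = "a"),
    data.frame(individual_id = paste0("i", 1:6), locus = "L2",
               allele1 = "x", allele2 = "x"),
    data.frame(individual_id = paste0("i", 7:10), locus = "L1",
               allele1 = "b", allele2 = "b"),
    data.frame(individual_id = paste0("i", 7:10), locus = "L2",
               allele1 = "y", allele2 = "y"))
  em <- emHaplotypes(g, seed = 1)
  h <- em$haplotypes
  expect_equal(nrow(h), 2L)
  expect_equal(sort(h$frequency), c(0.4, 0.6))
  expect_equal(em$loglik, 12 * log(0.6) + 8 * log(0.4))
  # one double heterozygote: the symmetric stationary point
  g2 <- data.frame(individual_id = "i1", locus = c("L1", "L2"),
                   allele1 = c("a", "x"), allele2 = c("b", "y"))
  em2 <- emHaplotypes(g2, n_restarts = 0L)
  expect_equal(em2$haplotypes$frequency, rep(0.25, 4))
})

test_that("EM recovers simulated trio frequencies within TV 0.05", {
  # note (IGHG2*03, IGHG2*08) is avoided: its unphased genotype is also
  # explained by (IGHG2*12, IGHG2*13), so such records are flagged ambiguous
  truth <- data.frame(
    g3 = c("IGHG3*14", "IGHG3*14", "IGHG3*11", "IGHG3*19"),
    g1 = c("IGHG1*02", "IGHG1*07", "IGHG1*03", "IGHG1*02"),
    g2 = c("IGHG2*03", "IGHG2*03", "IGHG2*02", "IGHG2*09"),
    frequency = c(0.4, 0.3, 0.2, 0.1), stringsAsFactors = FALSE)
  sim <- simulatePopulation(list(label = "SIM", n = 200,
                                 haplotype_freq = truth, seed = 17), acat)
  at <- assignmentTable(typeIndividuals(sim$genotypes, acat))
  at <- at[at$ambiguity_class != "ambiguous_requires_phasing", ]
  ids <- Reduce(intersect, split(at$individual_id, at$segment))
  g <- do.call(rbind, lapply(c("IGHG3", "IGHG1", "IGHG2"), function(s) {
    y <- at[at$segment == s & at$individual_id %in% ids, ]
    data.frame(individual_id = y$individual_id, locus = s,
               allele1 = y$allele1, allele2 = y$allele2)
  }))
  em <- emHaplotypes(g, seed = 17)
  est <- setNames(em$haplotypes$frequency,
                  paste(em$haplotypes$IGHG3, em$haplotypes$IGHG1,
                        em$haplotypes$IGHG2))
  tf <- setNames(truth$frequency, paste(truth$g3, truth$g1, truth$g2))
  keys <- union(names(est), names(tf))
  tv <- sum(abs(ifelse(keys %in% names(est), est[keys], 0) -
                ifelse(keys %in% names(tf), tf[keys], 0))) / 2
  expect_lt(tv, 0.05)
  expect_true(em$converged)
})

test_that("linkage disequilibrium matches closed forms", {
  h <- rbind(c("A", "B"), c("a", "b"))
  ld <- ldPairwise(h, c(0.5, 0.5))
  expect_equal(ld$D_prime, 1)
  expect_equal(ld$r2, 1)
  # independent sites at equilibrium: D = 0
  h2 <- rbind(c("A", "B"), c("A", "b"), c("a", "B"), c("a", "b"))
  ld2 <- ldPairwise(h2, c(0.21, 0.49, 0.09, 0.21))  # product frequencies
  expect_equal(ld2$D, 0, tolerance = 1e-12)
  # monomorphic site skipped with a message
  h3 <- rbind(c("A", "B"), c("A", "b"))
  expect_message(out <- ldPairwise(h3, c(0.5, 0.5)), "not biallelic")
  expect_equal(nrow(out), 0L)
  # the G1m3 / G2m23 sites are in complete LD under the KIV Gm haplotypes
  kiv <- rbind(c("G", "A"), c("A", "G"), c("A", "G"), c("G", "A"))
  colnames(kiv) <- c("IGHG1_CH1_289", "IGHG2_CH2_150")
  ldk <- ldPairwise(kiv, c(0.02, 0.77, 0.20, 0.01))
  expect_equal(ldk$D_prime, 1)
  expect_gt(ldk$r2, 0.87)
})

test_that("two-locus EM resolves LD from unphased genotypes", {
  set.seed(8)
  n <- 80
  hap <- function() if (runif(1) < 0.6) c("A", "G") else c("C", "T")
  rows <- NULL
  for (i in 1:n) {
    h1 <- hap(); h2 <- hap()
    rows <- rbind(rows,
      data.frame(individual_id = paste0("i", i), exon = "CH1",
                 exonic_pos = c(1L, 2L),
                 base1 = pmin(c(h1[1], h1[2]), c(h2[1], h2[2])),
                 base2 = pmax(c(h1[1], h1[2]), c(h2[1], h2[2]))))
  }
  ld <- suppressMessages(ldFromGenotypes(rows, seed = 2))
  expect_equal(ld$D_prime, 1, tolerance = 0.02)
  expect_gt(ld$r2, 0.9)
})

test_that("pairwise FST equals an independent ANOVA-form oracle", {
  # independent route: one-way ANOVA F-ratio form on allele indicators
  oracle_theta <- function(n1, c1, n2, c2) {
    p1 <- c1 / n1; p2 <- c2 / n2; N <- n1 + n2; r <- 2
    pw <- (c1 + c2) / N
    ssa <- n1 * (p1 - pw)^2 + n2 * (p2 - pw)^2
    ssw <- n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)
    msa <- ssa / (r - 1); msw <- ssw / (N - r)
    nc <- (N - (n1^2 + n2^2) / N) / (r - 1)
    (msa - msw) / (msa + (nc - 1) * msw)
  }
  set.seed(4)
  for (rep in 1:25) {
    n1 <- sample(20:120, 1); n2 <- sample(20:120, 1)
    c1 <- sample(0:n1, 1); c2 <- sample(0:n2, 1)
    if ((c1 == 0 && c2 == 0) || (c1 == n1 && c2 == n2)) next
    counts <- data.frame(
      population = rep(c("P1", "P2"), each = 2), locus = "L1",
      allele = rep(c("A", "a"), 2), count = c(c1, n1 - c1, c2, n2 - c2))
    got <- pairwiseFst(counts)$pairs$fst
    expect_equal(got, oracle_theta(n1, c1, n2, c2), tolerance = 1e-12)
  }
})

test_that("FST behaves at the boundaries and the matrix is well-formed", {
  cnt <- data.frame(population = rep(c("P1", "P2", "P3"), each = 2),
                    locus = "L1", allele = rep(c("x", "y"), 3),
                    count = c(30, 70, 30, 70, 60, 40))
  out <- pairwiseFst(cnt)
  expect_true(isSymmetric(out$fst))
  expect_equal(diag(out$fst), setNames(rep(0, 3), c("P1", "P2", "P3")))
  # identical samples: the unbiased estimator is near zero (slightly
  # negative, reported as computed)
  expect_lte(out$fst["P1", "P2"], 0)
  expect_lt(abs(out$fst["P1", "P2"]), 0.02)
  # reciprocally fixed alleles with no within-population variance
  fix <- data.frame(population = rep(c("P1", "P2"), each = 2), locus = "L1",
                    allele = rep(c("x", "y"), 2), count = c(500, 0, 0, 500))
  expect_equal(pairwiseFst(fix)$pairs$fst, 1)
  expect_error(pairwiseFst(cnt[cnt$population == "P1", ]), "two populations")
})

test_that("exact differentiation test matches Fisher on 2x2 and flags extremes", {
  tb <- matrix(c(12, 5, 3, 14), 2, 2)
  et <- exactDifferentiationTest(tb, steps = 5e4, burnin = 5e3, seed = 2)
  expect_lt(abs(et$p - stats::fisher.test(tb)$p.value), 3 * et$se + 0.002)
  # a private fixed allele with large counts
  tb2 <- matrix(c(100, 0, 0, 100), 2, 2)
  expect_lt(exactDifferentiationTest(tb2, steps = 2e4, seed = 1)$p, 0.001)
  # degenerate one-population table
  expect_equal(exactDifferentiationTest(matrix(c(5, 5), 1, 2))$p, 1)
})

test_that("the differentiation test is calibrated when both samples share one urn", {
  set.seed(2000)
  B <- 500; rej <- 0
  for (b in seq_len(B)) {
    f <- c(0.4, 0.3, 0.2, 0.1)
    tab <- rbind(t(rmultinom(1, 60, f)), t(rmultinom(1, 60, f)))
    p <- exactDifferentiationTest(tab, steps = 6000, burnin = 600,
                                  seed = 20000 + b)$p
    if (p <= 0.05) rej <- rej + 1
  }
  expect_lt(abs(rej / B - 0.05), 1.96 * sqrt(0.05 * 0.95 / B) + 1e-9)
})

test_that("PCA of frequency profiles separates duplicated clusters", {
  m <- rbind(a = c(0.6, 0.4, 0), b = c(0.6, 0.4, 0),
             c = c(0, 0.4, 0.6), d = c(0, 0.4, 0.6))
  pc <- pcaPopulations(m)
  expect_equal(pc$explained[1], 1)
  expect_equal(pc$scores["a", 1], pc$scores["b", 1])
  expect_gt(abs(pc$scores["a", 1] - pc$scores["c", 1]), 0)
  expect_equal(sum(pc$explained), 1)
  m0 <- rbind(a = c(0.5, 0.5), b = c(0.5, 0.5))
  pc0 <- pcaPopulations(m0)
  expect_equal(unname(pc0$scores[1, ]), unname(pc0$scores[2, ]))
  expect_error(pcaPopulations(m[1, , drop = FALSE]), "two populations")
})

test_that("PCA of the packaged Gm table groups Amerindian populations", {
  g6 <- read.delim(ighgFixture("gm_haplotype_freq.tsv"), comment.char = "#")
  strs <- unique(g6$gm_string)
  pops <- unique(g6$population)
  m <- t(vapply(pops, function(p) {
    v <- setNames(rep(0, length(strs)), strs)
    x <- g6[g6$population == p, ]
    v[x$gm_string] <- x$frequency
    v
  }, setNames(numeric(length(strs)), strs)))
  pc <- pcaPopulations(m)
  sc <- pc$scores[, 1:2]
  amer <- c("GKW", "GND", "GRC", "KIV", "KRC")
  d <- as.matrix(dist(sc))
  within <- mean(d[amer, amer][upper.tri(d[amer, amer])])
  to_ctba <- mean(d[amer, "CTBA"])
  expect_lt(within, to_ctba)
})
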