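test_that("variant catalog loads with the documented site counts", {
  expect_equal(nSites(vcat), 49L)
  expect_equal(nNonSynonymous(vcat), 26L)
  expect_equal(nSites(vcat, "IGHG1"), 16L)
  expect_equal(nSites(vcat, "IGHG2"), 13L)
  expect_equal(nSites(vcat, "IGHG3"), 20L)
  # chromosome-14 coordinates strictly decrease along the coding strand
  s <- variantSites(vcat)
  for (seg in unique(s$segment)) {
    x <- s[s$segment == seg, ]
    x <- x[order(IGHGpop:::EXON_ORDER[x$exon], x$exonic_pos), ]
    expect_true(all(diff(x$chr14_pos) < 0))
  }
})

test_that("catalog parsing rejects malformed input and accepts the empty case", {
  hdr <- readLines(ighgFixture("ighg_variant_sites.tsv"), n = 2L)
  f <- tempfile(fileext = ".tsv")
  writeLines(hdr, f)
  expect_equal(nSites(loadVariantCatalog(f)), 0L)
  # row with too many fields names its line
  writeLines(c(hdr, paste(c(rep("x", 15)), collapse = "\t")), f)
  expect_error(loadVariantCatalog(f), "parse error.*line")
  # duplicated (segment, chr14_pos) is an integrity error
  body <- readLines(ighgFixture("ighg_variant_sites.tsv"))
  writeLines(c(body, body[3]), f)
  expect_error(loadVariantCatalog(f), "duplicate")
  expect_error(loadVariantCatalog(tempfile()), "no such file")
})

test_that("allele catalog loads the published allele sets", {
  a <- alleleTable(acat)
  expect_equal(nrow(a), 57L)
  expect_equal(sum(a$status == "baseline"), 29L)
  expect_equal(sum(a$status == "novel"), 28L)
  for (seg in c("IGHG1", "IGHG2", "IGHG3"))
    expect_true(sum(a$copies[a$segment == seg]) %% 2L == 0L)
  # every allele state resolves to a site column of its segment
  sc <- siteColumns(acat)
  for (i in seq_len(nrow(a))) {
    st <- a$variant_states[[i]]
    if (!length(st)) next
    k <- paste(a$segment[i], names(st), sep = ":")
    expect_true(all(k %in% paste(sc$segment, sc$exon, sc$exonic_pos, sep = ":")))
  }
})

test_that("pooled variant frequencies recompute from copy counts", {
  # the two sites whose printed frequency is exactly consistent with copies
  expect_equal(round(pooledVariantFrequency(acat, "IGHG1", "CH3", 47, "G"), 3),
               0.118)
  expect_equal(round(pooledVariantFrequency(acat, "IGHG1", "CH3", 51, "A"), 3),
               0.118)
  # alt and ref partitions sum to one at every catalog site
  s <- variantSites(vcat)
  for (i in seq_len(nrow(s))) {
    falt <- pooledVariantFrequency(acat, s$segment[i], s$exon[i],
                                   s$exonic_pos[i], s$alt[i])
    fref <- pooledVariantFrequency(acat, s$segment[i], s$exon[i],
                                   s$exonic_pos[i], s$ref[i])
    expect_equal(falt + fref, 1)
  }
  # a state carried by no allele has frequency 0; by all observed alleles, 1
  expect_equal(pooledVariantFrequency(acat, "IGHG1", "CH1", 68, "C"), 0)
  expect_equal(pooledVariantFrequency(acat, "IGHG1", "CH2", 212, "T"), 1)
  empty <- acat
  empty@alleles$copies <- 0L
  expect_error(pooledVariantFrequency(empty, "IGHG1", "CH3", 47, "G"),
               "undefined")
})

test_that("allele hamming distances match the published gene-conversion tracts", {
  h <- alleleHamming(acat, "IGHG2*03", "IGHG2*09")
  expect_equal(h$count, 3L)
  expect_equal(h$sites$exon, rep("CH1", 3))
  expect_equal(h$sites$exonic_pos, c(56L, 58L, 60L))
  h2 <- alleleHamming(acat, "IGHG1*02", "IGHG1*11")
  expect_equal(h2$count, 3L)
  expect_equal(h2$sites$exonic_pos, c(233L, 234L, 254L))
  expect_equal(alleleHamming(acat, "IGHG1*03", "IGHG1*03")$count, 0L)
  expect_error(alleleHamming(acat, "IGHG1*02", "IGHG2*03"), "segments")
  # hinge-size difference is reported separately, never in the count
  h3 <- alleleHamming(acat, "IGHG3*11", "IGHG3*12")
  expect_equal(h3$count, 0L)
  expect_equal(h3$hinge_diff, "H3")
})

test_that("allele hamming is a metric on every segment", {
  for (seg in c("IGHG1", "IGHG2", "IGHG3")) {
    nm <- alleleNames(acat, seg)
    k <- length(nm)
    D <- matrix(0, k, k, dimnames = list(nm, nm))
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      dij <- alleleHamming(acat, nm[i], nm[j])$count
      dji <- alleleHamming(acat, nm[j], nm[i])$count
      expect_equal(dij, dji)
      D[i, j] <- D[j, i] <- dij
    }
    for (i in 1:k) for (j in 1:k) for (l in 1:k)
      expect_lte(D[i, j], D[i, l] + D[l, j])
  }
})

test_that("allele sequences reconstruct with substitutions and hinge absence", {
  # no variant states: consensus unchanged
  s01 <- reconstructAlleleSequence(acat, "IGHG1*01", cons_fa)
  expect_equal(nchar(s01), 294 + 330 + 321)
  # IGHG1*08 differs from the consensus at exactly CH1:289 and CH2:212
  s08 <- reconstructAlleleSequence(acat, "IGHG1*08", cons_fa)
  d <- which(strsplit(s01, "")[[1]] != strsplit(s08, "")[[1]])
  expect_equal(d, c(289L, 294L + 212L))
  # IGHG3 hinge exons appear between CH1 and CH2 and absent ones are omitted
  s11 <- reconstructAlleleSequence(acat, "IGHG3*11", cons_fa)
  s12 <- reconstructAlleleSequence(acat, "IGHG3*12", cons_fa)
  expect_equal(nchar(s11) - nchar(s12), 45L)  # H3 block length
  expect_false("H3" %in% attr(s12, "exon_ranges")$exon)
  # a coordinate beyond the consensus is an error
  short <- Biostrings::DNAStringSet(setNames("ACGT", "IGHG1|CH1"))
  expect_error(reconstructAlleleSequence(acat, "IGHG1*08", short),
               "coordinate error")
})

test_that("catalog validity rejects genuinely conflicting observed definitions", {
  bad <- acat
  i <- which(bad@alleles$name == "IGHG1*09")
  bad@alleles$variant_states[[i]] <-
    bad@alleles$variant_states[[which(bad@alleles$name == "IGHG1*02")]]
  expect_error(suppressWarnings(methods::validObject(bad)),
               "share a definition")
})
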