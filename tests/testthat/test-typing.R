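test_that("sequence diffs are annotated against the site catalog", {
  cons <- list(CH1 = as.character(cons_fa[["IGHG1|CH1"]]))
  expect_equal(nrow(diffSequences(cons, cons, vcat, "IGHG1")), 0L)
  obs <- cons
  substr(obs$CH1, 289, 289) <- "G"
  d <- diffSequences(obs, cons, vcat, "IGHG1")
  expect_equal(d$rsid, "rs1071803")
  expect_false(d$new_site)
  substr(obs$CH1, 10, 10) <- if (substr(cons$CH1, 10, 10) == "A") "C" else "A"
  d2 <- diffSequences(obs, cons, vcat, "IGHG1")
  expect_true(d2$new_site[d2$exonic_pos == 10])
  obs$CH1 <- substr(obs$CH1, 1, 100)
  expect_error(diffSequences(obs, cons, vcat, "IGHG1"), "alignment error")
})

test_that("compatible-pair enumeration matches its examples and the oracle", {
  # het C/G at CH3:271 over a hom-T CH2:212, consensus elsewhere
  g <- full_record(acat, "IGHG1", "IGHG1*02", "IGHG1*07")
  p <- enumerateCompatiblePairs(g, acat, "IGHG1")
  expect_equal(nrow(p), 1L)
  expect_equal(c(p$allele1, p$allele2), c("IGHG1*02", "IGHG1*07"))
  # fully consensus except hom T at CH2:212
  g2 <- full_record(acat, "IGHG1", "IGHG1*02", "IGHG1*02")
  p2 <- enumerateCompatiblePairs(g2, acat, "IGHG1")
  expect_equal(c(p2$allele1, p2$allele2), c("IGHG1*02", "IGHG1*02"))
  # an alternative state carried by no catalog allele yields no pair
  g3 <- g2
  g3$base1[g3$exon == "CH3" & g3$exonic_pos == 271] <- "A"
  expect_equal(nrow(enumerateCompatiblePairs(g3, acat, "IGHG1")), 0L)
  # exhaustive agreement with the brute-force oracle
  set.seed(42)
  for (seg in c("IGHG1", "IGHG2", "IGHG3")) {
    nm <- alleleNames(acat, seg)
    pairs <- t(combn(nm, 2))
    pairs <- rbind(pairs, cbind(nm, nm))
    take <- if (seg == "IGHG1") seq_len(nrow(pairs))
            else sample(nrow(pairs), 30)
    for (r in take) {
      rec <- full_record(acat, seg, pairs[r, 1], pairs[r, 2])
      got <- enumerateCompatiblePairs(rec, acat, seg)
      want <- oracle_pairs(acat, seg, rec)
      expect_equal(nrow(got), nrow(want))
      expect_setequal(paste(got$allele1, got$allele2),
                      paste(want[, 1], want[, 2]))
    }
  }
})

test_that("allele assignment classifies phase certainty correctly", {
  # homozygote
  r <- assignAlleles(full_record(acat, "IGHG2", "IGHG2*03", "IGHG2*03"),
                     acat, "IGHG2")
  expect_equal(r$ambiguity_class, "homozygous")
  expect_equal(c(r$allele1, r$allele2), c("IGHG2*03", "IGHG2*03"))
  # one heterozygous position
  r1 <- assignAlleles(full_record(acat, "IGHG1", "IGHG1*02", "IGHG1*08"),
                      acat, "IGHG1")
  expect_equal(r1$ambiguity_class, "single_het_unambiguous")
  # several het sites but a unique catalog pair
  r2 <- assignAlleles(full_record(acat, "IGHG2", "IGHG2*03", "IGHG2*09"),
                      acat, "IGHG2")
  expect_equal(r2$ambiguity_class, "resolvable")
  expect_equal(c(r2$allele1, r2$allele2), c("IGHG2*03", "IGHG2*09"))
  # contradictory bases
  bad <- full_record(acat, "IGHG1", "IGHG1*02", "IGHG1*02")
  bad$base1[1] <- "Z"
  expect_error(assignAlleles(bad, acat, "IGHG1"), "data error")
})

test_that("novel alleles are constructed parsimoniously and phase ambiguity flagged", {
  # the historical discovery situation: *11's genotype against a catalog
  # without *11 -- three het sites, no known pair, many phase splits
  g <- full_record(acat, "IGHG1", "IGHG1*02", "IGHG1*11")
  r <- assignAlleles(g, baseline_cat, "IGHG1")
  expect_equal(r$ambiguity_class, "ambiguous_requires_phasing")
  expect_equal(r$allele1, "IGHG1*02")  # parsimony: one known + one novel
  expect_equal(length(r$novel_definitions), 1L)
  expect_setequal(names(r$novel_definitions[[1]]$variant_states),
                  c("CH2:212", "CH2:233", "CH2:234", "CH2:254"))
  # one het site against a novel background is unambiguous
  g2 <- full_record(acat, "IGHG1", "IGHG1*02", "IGHG1*08")
  r2 <- assignAlleles(g2, baseline_cat, "IGHG1")
  expect_equal(r2$ambiguity_class, "single_het_unambiguous")
  expect_equal(r2$allele1, "IGHG1*02")
  expect_equal(names(r2$novel_definitions[[1]]$variant_states),
               c("CH1:289", "CH2:212"))
  # novel homozygote
  g3 <- full_record(acat, "IGHG1", "IGHG1*08", "IGHG1*08")
  r3 <- assignAlleles(g3, baseline_cat, "IGHG1")
  expect_equal(r3$ambiguity_class, "homozygous")
})

test_that("novel detection recovers the published 28 definitions", {
  expect_equal(nrow(detectNovel(baseline_cat, baseline_cat)), 0L)
  nv <- detectNovel(acat, baseline_cat)
  expect_equal(nrow(nv), 28L)
  expect_equal(sum(nv$segment == "IGHG1"), 9L)
  expect_equal(sum(nv$segment == "IGHG2"), 9L)
  expect_equal(sum(nv$segment == "IGHG3"), 10L)
  expect_true(all(grepl("^IGHG[123]\\*novel-\\d+$", nv$provisional_name)))
  # deduplication: the same novel pattern in several individuals counts once
  g <- full_record(acat, "IGHG1", "IGHG1*02", "IGHG1*08")
  as_ <- lapply(1:5, function(i) assignAlleles(g, baseline_cat, "IGHG1",
                                               individual = paste0("i", i)))
  expect_equal(nrow(detectNovel(as_, baseline_cat)), 1L)
})

test_that("round-trip typing recovers simulated truth or flags ambiguity", {
  for (pop in c("GKW", "BrJAP")) {
    sim <- simulatePopulation(populationConfig(pop, seed = 5), acat)
    at <- assignmentTable(typeIndividuals(sim$genotypes, acat))
    m <- merge(at[at$ambiguity_class != "ambiguous_requires_phasing", ],
               sim$ledger$pairs, by = c("individual_id", "segment"))
    expect_true(all(m$allele1.x == m$allele1.y & m$allele2.x == m$allele2.y))
  }
})
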