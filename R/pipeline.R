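#' Run the full typing and population-genetics pipeline
#'
#' Orchestrates catalog loading, genotype acquisition (simulation configs or
#' a genotype TSV), allele typing, per-population frequency tables, HWE
#' tests, EM haplotype estimation with Gm allotype aggregation, linkage
#' disequilibrium, pairwise FST with exact differentiation tests, the
#' median-joining allele network, neutrality statistics on simulated
#' alignments, the codon-based selection test, and PCA of Gm haplotype
#' frequencies. Every stage is a pure function of (inputs, config); outputs
#' are TSV files plus a JSON manifest with seeds and file checksums, so a
#' rerun with the same config reproduces identical checksums.
#'
#' @param config list with elements `outdir`; either `populations` (list of
#'   [simulatePopulation()] configs) or `genotypes` (TSV path); `analyses`
#'   (character subset of freqs, hwe, gm, ld, fst, difftest, network,
#'   neutrality, dnds, pca; default all); `seed` (master seed); optional MC
#'   parameters `hwe_steps`, `hwe_burnin`, `diff_steps`, `boot_B`,
#'   `coal_replicates`.
#' @return invisible list of stage results (also written to `outdir`).
#' @export
runPipeline <- function(config) {
  if (is.null(config$outdir)) stop("config error: outdir required")
  known <- c("outdir", "populations", "genotypes", "analyses", "seed",
             "hwe_steps", "hwe_burnin", "diff_steps", "boot_B",
             "coal_replicates")
  extra <- setdiff(names(config), known)
  if (length(extra)) stop("config error: unknown keys ",
                          paste(extra, collapse = ", "))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  analyses <- if (is.null(config$analyses))
    c("freqs", "hwe", "gm", "ld", "fst", "difftest", "network",
      "neutrality", "dnds", "pca") else config$analyses
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  vcat <- loadVariantCatalog()
  acat <- suppressWarnings(loadAlleleCatalog())
  res <- list(seed = seed)
  tsv <- function(df, name) {
    path <- file.path(config$outdir, name)
    writeLines(paste0("# IGHGpop pipeline output: ", name), path)
    suppressWarnings(utils::write.table(df, path, sep = "\t", quote = FALSE,
                                        row.names = FALSE, append = TRUE))
    path
  }
  files <- character(0)
  # --- genotypes
  geno <- NULL; ledgers <- list()
  if (!is.null(config$populations)) {
    for (pc in config$populations) {
      if (is.null(pc$seed)) pc$seed <- seed
      sim <- simulatePopulation(pc, acat)
      geno <- rbind(geno, sim$genotypes)
      ledgers[[pc$label]] <- sim$ledger
    }
  } else if (!is.null(config$genotypes)) {
    geno <- readGenotypes(config$genotypes)
  } else stop("config error: populations or genotypes required")
  # --- typing
  assignments <- typeIndividuals(geno, acat)
  atab <- assignmentTable(assignments)
  files <- c(files, tsv(atab, "assignments.tsv"))
  res$assignments <- atab
  # --- frequencies
  if ("freqs" %in% analyses) {
    freqs <- alleleFrequencies(atab)
    files <- c(files, tsv(freqs, "allele_frequencies.tsv"))
    res$frequencies <- freqs
  }
  # --- HWE
  if ("hwe" %in% analyses) {
    hwe <- NULL
    for (pop in unique(atab$population)) for (seg in unique(atab$segment)) {
      x <- atab[atab$population == pop & atab$segment == seg &
                  atab$ambiguity_class != "ambiguous_requires_phasing", ]
      if (nrow(x) < 2L) next
      h <- hweExactTest(cbind(x$allele1, x$allele2),
                        steps = config$hwe_steps %||% 1e4,
                        burnin = config$hwe_burnin %||% 1e3, seed = seed)
      hwe <- rbind(hwe, data.frame(population = pop, segment = seg,
                                   p = h$p, method = h$method,
                                   stringsAsFactors = FALSE))
    }
    files <- c(files, tsv(hwe, "hwe.tsv"))
    res$hwe <- hwe
  }
  # --- EM haplotypes + Gm aggregation
  if ("gm" %in% analyses) {
    gm_all <- NULL; em_all <- list()
    for (pop in unique(atab$population)) {
      x <- atab[atab$population == pop &
                  atab$ambiguity_class != "ambiguous_requires_phasing", ]
      segs <- c("IGHG3", "IGHG1", "IGHG2")
      ids <- Reduce(intersect, lapply(segs, function(s)
        x$individual_id[x$segment == s]))
      if (length(ids) < 1L) next
      g <- do.call(rbind, lapply(segs, function(s) {
        y <- x[x$segment == s & x$individual_id %in% ids, ]
        data.frame(individual_id = y$individual_id, locus = s,
                   allele1 = y$allele1, allele2 = y$allele2,
                   stringsAsFactors = FALSE)
      }))
      em <- emHaplotypes(g, seed = seed)
      em_all[[pop]] <- em
      haps <- em$haplotypes
      names(haps)[seq_along(em$loci)] <- c("g3", "g1", "g2")
      gm <- gmFrequencies(haps, acat)
      gm$population <- pop
      gm_all <- rbind(gm_all, gm)
    }
    files <- c(files, tsv(gm_all, "gm_haplotype_frequencies.tsv"))
    res$gm <- gm_all; res$em <- em_all
  }
  # --- LD
  if ("ld" %in% analyses) {
    ld_all <- NULL
    for (pop in unique(geno$population)) for (seg in unique(geno$segment)) {
      g <- geno[geno$population == pop & geno$segment == seg &
                  geno$exonic_pos > 0, ]
      ld <- suppressMessages(ldFromGenotypes(g, seed = seed))
      if (nrow(ld)) { ld$population <- pop; ld$segment <- seg }
      ld_all <- rbind(ld_all, ld)
    }
    if (!is.null(ld_all) && nrow(ld_all))
      files <- c(files, tsv(ld_all, "ld.tsv"))
    res$ld <- ld_all
  }
  # --- FST + exact differentiation
  if (any(c("fst", "difftest") %in% analyses) &&
      length(unique(atab$population)) >= 2L) {
    freqs <- alleleFrequencies(atab)
    counts <- data.frame(population = freqs$population, locus = freqs$segment,
                         allele = freqs$allele, count = freqs$count,
                         stringsAsFactors = FALSE)
    if ("fst" %in% analyses) {
      fst <- pairwiseFst(counts)
      files <- c(files, tsv(fst$pairs, "fst.tsv"))
      res$fst <- fst
    }
    if ("difftest" %in% analyses) {
      dt <- NULL
      pops <- unique(counts$population)
      for (i in seq_along(pops)) for (j in seq_along(pops)) {
        if (j <= i) next
        tabs <- lapply(unique(counts$locus), function(loc) {
          x <- counts[counts$locus == loc &
                        counts$population %in% pops[c(i, j)], ]
          t(vapply(pops[c(i, j)], function(p) {
            v <- setNames(rep(0L, length(unique(x$allele))), unique(x$allele))
            y <- x[x$population == p, ]
            v[y$allele] <- y$count
            v
          }, setNames(integer(length(unique(x$allele))), unique(x$allele))))
        })
        ps <- vapply(tabs, function(tb)
          exactDifferentiationTest(tb, steps = config$diff_steps %||% 1e4,
                                   seed = seed)$p, 0)
        # Fisher combination over the three segments
        chi <- -2 * sum(log(pmax(ps, 1e-12)))
        p <- pchisq(chi, df = 2 * length(ps), lower.tail = FALSE)
        dt <- rbind(dt, data.frame(pop1 = pops[i], pop2 = pops[j], p = p,
                                   p_bonferroni = NA_real_,
                                   stringsAsFactors = FALSE))
      }
      dt$p_bonferroni <- p.adjust(dt$p, "bonferroni")
      files <- c(files, tsv(dt, "differentiation.tsv"))
      res$difftest <- dt
    }
  }
  # --- network
  if ("network" %in% analyses) {
    for (seg in unique(atab$segment)) {
      sm <- alleleStateMatrix(acat, seg, observed_only = TRUE)
      if (nrow(sm$states) >= 2L) {
        net <- medianJoining(sm$states, sm$freq, weights = sm$weights)
        f <- file.path(config$outdir, paste0("network_", seg, ".graphml"))
        writeNetwork(net, f)
        files <- c(files, f)
        res$network[[seg]] <- net
      }
    }
  }
  # --- neutrality on reconstructed alignments
  if ("neutrality" %in% analyses && "freqs" %in% analyses) {
    cons <- loadConsensus()
    samples <- list()
    freqs <- res$frequencies
    for (pop in unique(freqs$population)) for (seg in unique(freqs$segment)) {
      x <- freqs[freqs$population == pop & freqs$segment == seg, ]
      if (nrow(x) == 0L) next
      counts <- setNames(x$count, x$allele)
      samples[[paste(pop, seg, sep = "_")]] <-
        simulateAlignment(acat, seg, counts, cons, seed = seed)
    }
    rep_n <- config$coal_replicates %||% 1000L
    nr <- neutralityReport(samples, replicates = rep_n, seed = seed)
    files <- c(files, tsv(nr, "neutrality.tsv"))
    res$neutrality <- nr
  }
  # --- dN/dS
  if ("dnds" %in% analyses) {
    cons <- loadConsensus()
    dn <- NULL
    for (seg in SEGMENTS) {
      seqs <- codonAlignmentFromAlleles(acat, seg, cons)
      z <- codonZTest(seqs, "purifying", B = config$boot_B %||% 1000L,
                      seed = seed)
      dn <- rbind(dn, data.frame(segment = seg, dS = z$dS, dN = z$dN,
                                 Z = z$Z, p = z$p, stringsAsFactors = FALSE))
    }
    files <- c(files, tsv(dn, "dnds.tsv"))
    res$dnds <- dn
  }
  # --- PCA of Gm frequencies
  if ("pca" %in% analyses && !is.null(res$gm) &&
      length(unique(res$gm$population)) >= 2L) {
    gm <- res$gm
    strs <- unique(gm$gm_string)
    mat <- t(vapply(unique(gm$population), function(p) {
      v <- setNames(rep(0, length(strs)), strs)
      x <- gm[gm$population == p, ]
      v[x$gm_string] <- x$frequency
      v
    }, setNames(numeric(length(strs)), strs)))
    pca <- pcaPopulations(mat)
    files <- c(files, tsv(as.data.frame(pca$scores), "pca_scores.tsv"))
    res$pca <- pca
  }
  manifest <- list(
    package = "IGHGpop",
    version = as.character(utils::packageVersion("IGHGpop")),
    seed = seed, analyses = analyses,
    checksums = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
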