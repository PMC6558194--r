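#' Deterministic integer counts from printed frequencies
#'
#' Largest-remainder rounding of frequencies times the number of chromosomes;
#' counts sum exactly to `two_n`. Remainder ties are resolved by descending
#' frequency, then by name order, so the reconstruction is fully
#' deterministic.
#'
#' @param freq named numeric vector of frequencies.
#' @param two_n total chromosomes (even).
#' @return named integer vector summing to `two_n`.
#' @examples
#' reconstructCounts(c("IGHG1*02" = 0.522, "IGHG1*07" = 0.478), 92)
#' # 48 and 44
#' @export
reconstructCounts <- function(freq, two_n) {
  if (two_n %% 2 != 0) stop("two_n must be even")
  raw <- freq * two_n
  base <- floor(raw)
  rem <- raw - base
  short <- two_n - sum(base)
  if (short > 0) {
    ord <- order(-rem, -freq, names(freq))
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
  }
  out <- as.integer(base)
  names(out) <- names(freq)
  out
}

#' Simulate a diploid population from allele or haplotype frequencies
#'
#' Draws chromosomes according to the configured frequencies (deterministic
#' largest-remainder counts by default, matching a printed frequency table;
#' multinomial sampling optionally), pairs them into diploid individuals by
#' random permutation (Hardy-Weinberg proportions), and emits the unphased
#' per-site genotype table the typing module consumes, together with a
#' ledger of the true allele pairs and haplotypes for recovery testing.
#' Hinge-exon presence (IGHG3) is emitted as pseudo-sites (`exonic_pos` 0,
#' states P/A), mirroring the laboratory observability of hinge copy number
#' through amplicon length. Optional missingness masks each site call
#' independently.
#'
#' @param config list with elements:
#'   \describe{
#'     \item{label}{population label.}
#'     \item{n}{number of individuals (per segment; may be a named vector).}
#'     \item{allele_freq}{named list segment -> named frequency vector; or}
#'     \item{haplotype_freq}{data.frame g3, g1, g2, frequency for
#'       three-segment haplotypes.}
#'     \item{missingness}{per-call masking probability (default 0).}
#'     \item{seed}{integer seed.}
#'     \item{deterministic_counts}{largest-remainder counts (default TRUE).}
#'   }
#' @param catalog an [AlleleCatalog-class].
#' @return list with `genotypes` (data.frame), `ledger` (true pairs; and
#'   haplotypes when simulating trios).
#' @export
simulatePopulation <- function(config, catalog) {
  if (is.null(config$label) || is.null(config$n)) stop("config error: label/n")
  miss <- if (is.null(config$missingness)) 0 else config$missingness
  set.seed(if (is.null(config$seed)) 1L else config$seed)
  det <- !isFALSE(config$deterministic_counts)
  geno <- NULL; ledger <- list(label = config$label)
  if (!is.null(config$haplotype_freq)) {
    hf <- config$haplotype_freq
    for (seg_alleles in c(hf$g3, hf$g1, hf$g2))
      if (!seg_alleles %in% catalog@alleles$name)
        stop("config error: unknown allele ", seg_alleles)
    n <- config$n[1]
    key <- paste(hf$g3, hf$g1, hf$g2, sep = "|")
    cnt <- if (det) reconstructCounts(setNames(hf$frequency, key), 2L * n)
           else setNames(as.integer(rmultinom(1, 2L * n, hf$frequency)), key)
    pool <- rep(names(cnt), times = cnt)
    pool <- sample(pool)
    hap1 <- pool[seq(1, 2L * n, 2)]; hap2 <- pool[seq(2, 2L * n, 2)]
    split3 <- function(x, i) vapply(strsplit(x, "|", fixed = TRUE), `[`, "", i)
    ledger$haplotypes <- data.frame(individual_id = .ind_ids(config$label, n),
                                    hap1 = hap1, hap2 = hap2,
                                    stringsAsFactors = FALSE)
    per_seg <- list(IGHG3 = cbind(split3(hap1, 1), split3(hap2, 1)),
                    IGHG1 = cbind(split3(hap1, 2), split3(hap2, 2)),
                    IGHG2 = cbind(split3(hap1, 3), split3(hap2, 3)))
    for (seg in names(per_seg))
      geno <- rbind(geno, .emit_genotypes(per_seg[[seg]], seg, config$label,
                                          catalog, miss))
    ledger$pairs <- do.call(rbind, lapply(names(per_seg), function(seg)
      data.frame(individual_id = .ind_ids(config$label, n), segment = seg,
                 allele1 = pmin(per_seg[[seg]][, 1], per_seg[[seg]][, 2]),
                 allele2 = pmax(per_seg[[seg]][, 1], per_seg[[seg]][, 2]),
                 stringsAsFactors = FALSE)))
  } else if (!is.null(config$allele_freq)) {
    pairs_all <- NULL
    for (seg in names(config$allele_freq)) {
      f <- config$allele_freq[[seg]]
      if (!all(names(f) %in% catalog@alleles$name))
        stop("config error: unknown allele ",
             paste(setdiff(names(f), catalog@alleles$name), collapse = ","))
      if (abs(sum(f) - 1) > 1e-2)
        stop("config error: frequencies of ", seg, " sum to ", sum(f))
      n <- if (length(config$n) > 1L) config$n[[seg]] else config$n
      cnt <- if (det) reconstructCounts(f / sum(f), 2L * n)
             else setNames(as.integer(rmultinom(1, 2L * n, f)), names(f))
      pool <- sample(rep(names(cnt), times = cnt))
      mat <- cbind(pool[seq(1, 2L * n, 2)], pool[seq(2, 2L * n, 2)])
      geno <- rbind(geno, .emit_genotypes(mat, seg, config$label, catalog,
                                          miss))
      pairs_all <- rbind(pairs_all, data.frame(
        individual_id = .ind_ids(config$label, n), segment = seg,
        allele1 = pmin(mat[, 1], mat[, 2]), allele2 = pmax(mat[, 1], mat[, 2]),
        stringsAsFactors = FALSE))
    }
    ledger$pairs <- pairs_all
  } else stop("config error: need allele_freq or haplotype_freq")
  list(genotypes = geno, ledger = ledger)
}

.ind_ids <- function(label, n) sprintf("%s_%03d", label, seq_len(n))

.emit_genotypes <- function(pair_mat, segment, label, catalog, miss) {
  prof <- .allele_profiles(catalog, segment)
  keys <- colnames(prof)
  parts <- strsplit(keys, ":", fixed = TRUE)
  ex <- vapply(parts, `[`, "", 1L)
  pos <- as.integer(vapply(parts, `[`, "", 2L))
  n <- nrow(pair_mat)
  ids <- .ind_ids(label, n)
  out <- data.frame(
    individual_id = rep(ids, each = length(keys)),
    population = label, segment = segment,
    exon = rep(ex, n), exonic_pos = rep(pos, n),
    base1 = NA_character_, base2 = NA_character_, stringsAsFactors = FALSE)
  b1 <- prof[pair_mat[, 1], , drop = FALSE]
  b2 <- prof[pair_mat[, 2], , drop = FALSE]
  lo <- pmin(b1, b2); hi <- pmax(b1, b2)
  out$base1 <- as.vector(t(lo)); out$base2 <- as.vector(t(hi))
  if (miss > 0) {
    mask <- rbinom(nrow(out), 1, miss) == 1L
    out$base1[mask] <- NA_character_; out$base2[mask] <- NA_character_
  }
  out
}

#' Simulate an alignment of allele sequences with an outgroup
#'
#' Reconstructs allele coding sequences according to the supplied chromosome
#' counts and adds an outgroup: the consensus sequence with a
#' Poisson(divergence x length) number of extra substitutions placed at
#' positions outside the catalog's site columns, emulating an outgroup
#' lineage that is informative for polarization without disturbing the
#' ingroup's polymorphic sites.
#'
#' @param catalog an [AlleleCatalog-class].
#' @param segment segment name.
#' @param counts named integer vector allele -> number of haplotypes.
#' @param consensus per-exon consensus DNAStringSet ([loadConsensus()]).
#' @param divergence expected substitutions per site on the outgroup lineage
#'   (>= 0).
#' @param seed integer seed.
#' @param exons exons to include (default CH exons, keeping equal lengths
#'   across IGHG3 hinge variants).
#' @return an [AlignmentSample-class].
#' @export
simulateAlignment <- function(catalog, segment, counts, consensus,
                              divergence = 0.05, seed = 1L,
                              exons = c("CH1", "CH2", "CH3")) {
  if (divergence < 0) stop("config error: negative divergence")
  set.seed(seed)
  ch <- consensus[names(consensus) %in% paste0(segment, "|", exons)]
  seqs <- character(0)
  for (al in names(counts)) {
    if (counts[[al]] == 0L) next
    s <- as.character(reconstructAlleleSequence(catalog, al, ch))
    seqs <- c(seqs, setNames(rep(s, counts[[al]]),
                             paste0(al, "_", seq_len(counts[[al]]))))
  }
  cons_seq <- paste(vapply(as.list(ch), as.character, ""), collapse = "")
  chars <- strsplit(cons_seq, "")[[1]]
  # positions of catalog site columns within the concatenated CH exons
  taken <- integer(0); off <- 0L
  sc <- siteColumns(catalog, segment)
  ord <- names(ch)[order(EXON_ORDER[sub("^.*\\|", "", names(ch))])]
  for (id in ord) {
    exn <- sub("^.*\\|", "", id)
    taken <- c(taken, off + sc$exonic_pos[sc$exon == exn])
    off <- off + nchar(as.character(ch[[which(names(ch) == id)]]))
  }
  free <- setdiff(seq_along(chars), taken)
  nmut <- rpois(1L, divergence * length(chars))
  nmut <- min(nmut, length(free))
  if (nmut > 0) {
    at <- sample(free, nmut)
    for (p in at) chars[p] <- sample(setdiff(c("A", "C", "G", "T"),
                                             chars[p]), 1L)
  }
  AlignmentSample(Biostrings::DNAStringSet(seqs),
                  Biostrings::DNAStringSet(setNames(paste(chars, collapse = ""),
                                                    "outgroup_consensus")),
                  segment)
}

#' Population configurations from the packaged frequency tables
#'
#' Builds [simulatePopulation()] configurations from the packaged
#' per-population allele frequency table (one per population, per-segment
#' sample sizes as published) or from the packaged Gm-era haplotype table.
#'
#' @param population population label (GKW, GND, GRC, KIV, KRC, BrJAP, CTBA).
#' @param seed seed stored in the config.
#' @param freq_path,size_path fixture overrides.
#' @return a config list.
#' @export
populationConfig <- function(population, seed = 1L,
                             freq_path = ighgFixture("ighg_pop_allele_freq.tsv"),
                             size_path = ighgFixture("ighg_pop_sample_sizes.tsv")) {
  f <- utils::read.delim(freq_path, comment.char = "#",
                         stringsAsFactors = FALSE)
  s <- utils::read.delim(size_path, comment.char = "#",
                         stringsAsFactors = FALSE)
  f <- f[f$population == population, ]
  s <- s[s$population == population, ]
  if (nrow(f) == 0L) stop("unknown population: ", population)
  af <- lapply(split(f, f$segment), function(x)
    setNames(x$frequency, x$allele))
  list(label = population, n = setNames(s$n_individuals, s$segment),
       allele_freq = af, missingness = 0, seed = seed,
       deterministic_counts = TRUE)
}
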