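#' Pairwise linkage disequilibrium between variant sites
#'
#' Computes D, Lewontin's D' and r-squared for pairs of biallelic sites from
#' two-locus haplotype frequencies. Haplotypes can be given directly (phased
#' states with frequencies or counts) or resolved from unphased genotypes by
#' a two-locus EM ([ldFromGenotypes()]). Monomorphic sites are skipped with a
#' message.
#'
#' @param haps matrix or data.frame of haplotype states (rows: haplotypes,
#'   columns: sites, character states).
#' @param freq haplotype frequencies or counts (recycled to sum 1).
#' @param pairs optional 2-column matrix of site-name pairs; all pairs by
#'   default.
#' @return data.frame site1, site2, D, D_prime, r2.
#' @export
ldPairwise <- function(haps, freq = NULL, pairs = NULL) {
  haps <- as.matrix(haps)
  if (is.null(colnames(haps)))
    colnames(haps) <- paste0("site", seq_len(ncol(haps)))
  if (is.null(freq)) freq <- rep(1, nrow(haps))
  freq <- freq / sum(freq)
  sites <- colnames(haps)
  if (is.null(pairs)) {
    if (length(sites) < 2L) return(.ld_empty())
    pairs <- t(combn(sites, 2L))
  }
  out <- NULL
  for (r in seq_len(nrow(pairs))) {
    s1 <- pairs[r, 1]; s2 <- pairs[r, 2]
    st1 <- haps[, s1]; st2 <- haps[, s2]
    a1 <- sort(unique(st1)); a2 <- sort(unique(st2))
    if (length(a1) != 2L || length(a2) != 2L) {
      message("skipping ", s1, "/", s2, ": site not biallelic in sample")
      next
    }
    pA <- sum(freq[st1 == a1[1]]); pB <- sum(freq[st2 == a2[1]])
    pAB <- sum(freq[st1 == a1[1] & st2 == a2[1]])
    D <- pAB - pA * pB
    dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
            else min(pA * pB, (1 - pA) * (1 - pB))
    out <- rbind(out, data.frame(
      site1 = s1, site2 = s2, D = D,
      D_prime = if (dmax > 0) abs(D) / dmax else NA_real_,
      r2 = D^2 / (pA * (1 - pA) * pB * (1 - pB)),
      stringsAsFactors = FALSE))
  }
  if (is.null(out)) .ld_empty() else out
}

.ld_empty <- function() data.frame(site1 = character(0), site2 = character(0),
                                   D = numeric(0), D_prime = numeric(0),
                                   r2 = numeric(0))

#' @rdname ldPairwise
#' @param geno genotype data.frame (individual_id, exon, exonic_pos, base1,
#'   base2) for one population and segment; each site is treated as a locus
#'   and phased with the two-locus EM before computing LD.
#' @param seed seed passed to the EM restarts.
#' @export
ldFromGenotypes <- function(geno, pairs = NULL, seed = 1L) {
  geno$site <- paste(geno$exon, geno$exonic_pos, sep = ":")
  sites <- unique(geno$site)
  poly <- vapply(sites, function(s) {
    b <- c(geno$base1[geno$site == s], geno$base2[geno$site == s])
    length(unique(b[!is.na(b)])) == 2L
  }, NA)
  sites <- sites[poly]
  if (is.null(pairs)) {
    if (length(sites) < 2L) return(.ld_empty())
    pairs <- t(combn(sites, 2L))
  }
  out <- NULL
  for (r in seq_len(nrow(pairs))) {
    g2 <- geno[geno$site %in% pairs[r, ], ]
    g2 <- g2[!is.na(g2$base1) & !is.na(g2$base2), ]
    em <- emHaplotypes(data.frame(individual_id = g2$individual_id,
                                  locus = g2$site, allele1 = g2$base1,
                                  allele2 = g2$base2),
                       n_restarts = 2L, seed = seed)
    h <- em$haplotypes
    out <- rbind(out, ldPairwise(h[, em$loci, drop = FALSE], h$frequency))
  }
  if (is.null(out)) .ld_empty() else out
}

#' Pairwise FST between populations
#'
#' Weir-Cockerham-type variance-component estimator on allele (haplotype)
#' counts: for every allele of every locus the among-population and
#' within-population components are computed from the sample frequencies, and
#' a multi-locus estimate for a population pair is the ratio of summed
#' components over all alleles of all loci. Negative estimates are reported
#' as computed.
#'
#' @param counts data.frame population, locus, allele, count (gene copies).
#' @return list with `fst` (symmetric matrix, zero diagonal) and `pairs`
#'   (long data.frame).
#' @export
pairwiseFst <- function(counts) {
  pops <- unique(counts$population)
  if (length(pops) < 2L) stop("need at least two populations")
  M <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  pairs <- NULL
  for (i in seq_along(pops)) for (j in seq_along(pops)) {
    if (j <= i) next
    th <- .theta_pair(counts, pops[i], pops[j])
    M[i, j] <- M[j, i] <- th
    pairs <- rbind(pairs, data.frame(pop1 = pops[i], pop2 = pops[j],
                                     fst = th, stringsAsFactors = FALSE))
  }
  list(fst = M, pairs = pairs)
}

.theta_pair <- function(counts, p1, p2) {
  x <- counts[counts$population %in% c(p1, p2), ]
  num <- 0; den <- 0
  for (loc in unique(x$locus)) {
    xl <- x[x$locus == loc, ]
    n1 <- sum(xl$count[xl$population == p1])
    n2 <- sum(xl$count[xl$population == p2])
    if (n1 < 1L || n2 < 1L) next
    alleles <- unique(xl$allele)
    r <- 2; nbar <- (n1 + n2) / 2
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    for (al in alleles) {
      c1 <- sum(xl$count[xl$population == p1 & xl$allele == al])
      c2 <- sum(xl$count[xl$population == p2 & xl$allele == al])
      q1 <- c1 / n1; q2 <- c2 / n2
      pbar <- (n1 * q1 + n2 * q2) / (r * nbar)
      msp <- (n1 * (q1 - pbar)^2 + n2 * (q2 - pbar)^2) / (r - 1)
      msg <- (n1 * q1 * (1 - q1) + n2 * q2 * (1 - q2)) / (n1 - 1 + n2 - 1)
      a <- (msp - msg) / nc
      num <- num + a
      den <- den + a + msg
    }
  }
  if (den == 0) 0 else num / den
}

#' Exact test of population differentiation (Raymond-Rousset)
#'
#' Markov chain over population x allele contingency tables with fixed
#' margins: the chain proposes +1/-1 swaps on 2x2 subtables (Metropolis
#' acceptance by the hypergeometric probability ratio) and the p-value is the
#' proportion of visited tables whose conditional probability does not
#' exceed that of the observed table.
#'
#' @param tab matrix of allele counts, rows = populations, columns = alleles.
#' @param steps,burnin chain steps after dememorization, and dememorization.
#' @param seed integer seed.
#' @return list p, se, steps.
#' @export
exactDifferentiationTest <- function(tab, steps = 2e4, burnin = 2e3,
                                     seed = 1L) {
  tab <- as.matrix(tab)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  r <- nrow(tab); k <- ncol(tab)
  if (r < 2L || k < 2L)
    return(list(p = 1, se = NA_real_, steps = 0L))
  logp <- function(m) -sum(lgamma(m + 1))
  lp_obs <- logp(tab)
  set.seed(seed)
  cur <- tab; lp <- lp_obs
  ri <- matrix(sample.int(r, 2L * (steps + burnin), replace = TRUE), ncol = 2)
  ci <- matrix(sample.int(k, 2L * (steps + burnin), replace = TRUE), ncol = 2)
  us <- runif(steps + burnin)
  ind <- logical(steps)
  for (t in seq_len(steps + burnin)) {
    i1 <- ri[t, 1]; i2 <- ri[t, 2]; j1 <- ci[t, 1]; j2 <- ci[t, 2]
    if (i1 != i2 && j1 != j2 && cur[i1, j1] > 0L && cur[i2, j2] > 0L) {
      ratio <- (cur[i1, j1] * cur[i2, j2]) /
        ((cur[i1, j2] + 1) * (cur[i2, j1] + 1))
      if (us[t] < ratio) {
        cur[i1, j1] <- cur[i1, j1] - 1L; cur[i2, j2] <- cur[i2, j2] - 1L
        cur[i1, j2] <- cur[i1, j2] + 1L; cur[i2, j1] <- cur[i2, j1] + 1L
        lp <- logp(cur)
      }
    }
    if (t > burnin) ind[t - burnin] <- lp <= lp_obs + 1e-9
  }
  p <- mean(ind)
  nb <- 50L
  bs <- floor(steps / nb)
  bm <- vapply(seq_len(nb), function(b)
    mean(ind[((b - 1L) * bs + 1L):(b * bs)]), 0)
  list(p = p, se = stats::sd(bm) / sqrt(nb), steps = steps)
}

#' Principal component analysis of population frequency profiles
#'
#' Column-centered singular value decomposition of a populations x
#' haplotype-frequency matrix (covariance PCA): used to place study
#' populations among serologically characterized reference populations by
#' their Gm allotype haplotype frequencies.
#'
#' @param freq numeric matrix, rows = populations (rownames kept), columns
#'   aligned across populations with absent haplotypes as 0.
#' @return list scores, loadings, explained (fractions summing to 1).
#' @export
pcaPopulations <- function(freq) {
  freq <- as.matrix(freq)
  if (nrow(freq) < 2L) stop("need at least two populations")
  ctr <- scale(freq, center = TRUE, scale = FALSE)
  sv <- svd(ctr)
  d2 <- sv$d^2
  expl <- if (sum(d2) > 0) d2 / sum(d2) else rep(0, length(d2))
  scores <- sv$u %*% diag(sv$d, length(sv$d))
  rownames(scores) <- rownames(freq)
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  loadings <- sv$v
  rownames(loadings) <- colnames(freq)
  colnames(loadings) <- paste0("PC", seq_len(ncol(loadings)))
  list(scores = scores, loadings = loadings, explained = expl)
}
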