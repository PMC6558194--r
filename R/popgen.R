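#' Allele frequencies by direct counting
#'
#' Each typed individual contributes two chromosomes per segment. Individuals
#' with unresolved phase ambiguity or missing calls can be excluded.
#'
#' @param assignments assignment table ([assignmentTable()]) or list from
#'   [typeIndividuals()].
#' @param drop_ambiguous exclude `ambiguous_requires_phasing` records.
#' @return data.frame population, segment, allele, count, frequency, two_n.
#' @export
alleleFrequencies <- function(assignments, drop_ambiguous = TRUE) {
  tab <- if (is.data.frame(assignments)) assignments
         else assignmentTable(assignments)
  if (nrow(tab) == 0L) stop("undefined: no typed individuals")
  if (drop_ambiguous)
    tab <- tab[tab$ambiguity_class != "ambiguous_requires_phasing", , drop = FALSE]
  if (nrow(tab) == 0L) stop("undefined: no unambiguous individuals")
  out <- NULL
  for (pop in unique(tab$population)) for (seg in unique(tab$segment)) {
    x <- tab[tab$population == pop & tab$segment == seg, , drop = FALSE]
    if (nrow(x) == 0L) next
    cnt <- table(c(x$allele1, x$allele2))
    out <- rbind(out, data.frame(
      population = pop, segment = seg, allele = names(cnt),
      count = as.integer(cnt), frequency = as.integer(cnt) / (2 * nrow(x)),
      two_n = 2L * nrow(x), stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Exact test of Hardy-Weinberg equilibrium (Guo-Thompson)
#'
#' Tests the observed genotype array against the Levene conditional
#' distribution given the allele counts. When the number of possible genotype
#' arrays is small the p-value is computed by full enumeration (the sum of
#' the conditional probabilities of all arrays no more probable than the
#' observed one); otherwise it is estimated by the Guo-Thompson Monte Carlo
#' scheme -- a random-transposition chain over the pairing of the 2n gene
#' copies, whose stationary distribution on genotype arrays is exactly the
#' conditional distribution.
#'
#' @param genotypes data.frame with columns allele1, allele2, count, or a
#'   2-column matrix/data.frame of per-individual allele pairs.
#' @param method "auto", "enumeration" or "mc".
#' @param max_enum largest number of enumerated arrays before switching to
#'   Monte Carlo under "auto".
#' @param steps,burnin chain length after dememorization, and dememorization
#'   steps.
#' @param seed integer seed for the chain.
#' @return list p, se (NA under enumeration), method, n_arrays or n_samples,
#'   monomorphic flag.
#' @examples
#' hweExactTest(data.frame(allele1 = c("A","a"), allele2 = c("A","a"),
#'                         count = c(1, 1)))$p  # 1/3
#' @export
hweExactTest <- function(genotypes, method = c("auto", "enumeration", "mc"),
                         max_enum = 2e5, steps = 1e5, burnin = 1e4,
                         seed = 1L) {
  method <- match.arg(method)
  gt <- .genotype_counts(genotypes)
  alleles <- sort(unique(c(gt$a1, gt$a2)))
  k <- length(alleles)
  n <- sum(gt$count)
  if (n < 2L) stop("need at least 2 individuals")
  if (k < 2L)
    return(list(p = 1, se = NA_real_, method = "degenerate",
                monomorphic = TRUE))
  m <- setNames(numeric(k), alleles)   # allele counts
  for (i in seq_len(nrow(gt))) {
    m[gt$a1[i]] <- m[gt$a1[i]] + gt$count[i]
    m[gt$a2[i]] <- m[gt$a2[i]] + gt$count[i]
  }
  obs <- matrix(0, k, k, dimnames = list(alleles, alleles))
  for (i in seq_len(nrow(gt))) {
    a <- gt$a1[i]; b <- gt$a2[i]
    obs[a, b] <- obs[a, b] + gt$count[i]
    if (a != b) obs[b, a] <- obs[b, a] + gt$count[i]
  }
  logp_obs <- .levene_logp(obs, m, n)
  if (method != "mc") {
    arrays <- .enumerate_arrays(m, n, if (method == "auto") max_enum else Inf)
    if (!is.null(arrays)) {
      lps <- vapply(arrays, .levene_logp, 0, m = m, n = n)
      p <- sum(exp(lps[lps <= logp_obs + 1e-9]))
      return(list(p = min(p, 1), se = NA_real_, method = "enumeration",
                  n_arrays = length(arrays), monomorphic = FALSE))
    }
    if (method == "enumeration") stop("enumeration bound exceeded")
  }
  set.seed(seed)
  pool <- rep(seq_len(k), times = m)          # 2n gene copies
  pool <- sample(pool)
  cur <- .pairing_counts(pool, k)
  lp <- .levene_logp2(cur)
  lp_obs <- .levene_logp2(.upper_of(obs))
  total <- burnin + steps
  u <- sample.int(2L * n, total, replace = TRUE)
  v <- sample.int(2L * n, total, replace = TRUE)
  ind <- logical(steps)
  for (t in seq_len(total)) {
    i <- u[t]; j <- v[t]
    if (pool[i] != pool[j]) {
      # update the two affected genotype cells
      pi_ <- .pair_of(i); pj_ <- .pair_of(j)
      g1o <- sort(c(pool[pi_[1]], pool[pi_[2]]))
      g2o <- sort(c(pool[pj_[1]], pool[pj_[2]]))
      tmp <- pool[i]; pool[i] <- pool[j]; pool[j] <- tmp
      g1n <- sort(c(pool[pi_[1]], pool[pi_[2]]))
      g2n <- sort(c(pool[pj_[1]], pool[pj_[2]]))
      for (g in list(g1o, g2o)) cur[g[1], g[2]] <- cur[g[1], g[2]] - 1L
      for (g in list(g1n, g2n)) cur[g[1], g[2]] <- cur[g[1], g[2]] + 1L
      lp <- .levene_logp2(cur)
    }
    if (t > burnin) ind[t - burnin] <- lp <= lp_obs + 1e-9
  }
  p <- mean(ind)
  # batch-means standard error, accounting for chain autocorrelation
  nb <- 50L
  bs <- floor(steps / nb)
  bm <- vapply(seq_len(nb), function(b)
    mean(ind[((b - 1L) * bs + 1L):(b * bs)]), 0)
  list(p = p, se = stats::sd(bm) / sqrt(nb), method = "mc",
       n_samples = steps, monomorphic = FALSE)
}

.genotype_counts <- function(genotypes) {
  if (is.matrix(genotypes)) genotypes <- as.data.frame(genotypes)
  if (!"count" %in% names(genotypes)) {
    a1 <- pmin(genotypes[[1]], genotypes[[2]])
    a2 <- pmax(genotypes[[1]], genotypes[[2]])
    tab <- table(paste(a1, a2, sep = "\r"))
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    return(data.frame(a1 = vapply(parts, `[`, "", 1L),
                      a2 = vapply(parts, `[`, "", 2L),
                      count = as.integer(tab), stringsAsFactors = FALSE))
  }
  data.frame(a1 = pmin(genotypes$allele1, genotypes$allele2),
             a2 = pmax(genotypes$allele1, genotypes$allele2),
             count = genotypes$count, stringsAsFactors = FALSE)
}

# conditional probability of a genotype array given allele counts (Levene)
.levene_logp <- function(full, m, n) {
  up <- full; up[lower.tri(up)] <- 0
  h <- sum(up[upper.tri(up)])
  lgamma(n + 1) + h * log(2) + sum(lgamma(m + 1)) - lgamma(2 * n + 1) -
    sum(lgamma(up[upper.tri(up, diag = TRUE)] + 1))
}

# same up to a constant, from an upper-triangular count matrix
.levene_logp2 <- function(up) {
  h <- sum(up[upper.tri(up)])
  h * log(2) - sum(lgamma(up[upper.tri(up, diag = TRUE)] + 1))
}

.upper_of <- function(full) { up <- full; up[lower.tri(up)] <- 0; up }

.pair_of <- function(i) { base <- i - (i - 1L) %% 2L; c(base, base + 1L) }

.pairing_counts <- function(pool, k) {
  up <- matrix(0L, k, k)
  for (t in seq_len(length(pool) / 2L)) {
    g <- sort(c(pool[2L * t - 1L], pool[2L * t]))
    up[g[1], g[2]] <- up[g[1], g[2]] + 1L
  }
  up
}

# all genotype arrays compatible with allele counts m (k x k upper counts);
# returns NULL when more than max_n arrays exist
.enumerate_arrays <- function(m, n, max_n) {
  k <- length(m)
  cells <- which(upper.tri(matrix(0, k, k), diag = TRUE), arr.ind = TRUE)
  cells <- cells[order(cells[, 1], cells[, 2]), , drop = FALSE]
  out <- list()
  rec <- function(idx, rem, cur) {
    if (length(out) > max_n) return(FALSE)
    if (idx > nrow(cells)) {
      if (all(rem == 0)) {
        full <- cur + t(cur * upper.tri(cur))
        dimnames(full) <- list(names(m), names(m))
        out[[length(out) + 1L]] <<- full
      }
      return(TRUE)
    }
    i <- cells[idx, 1]; j <- cells[idx, 2]
    cap <- if (i == j) rem[i] %/% 2L else min(rem[i], rem[j])
    for (x in 0:cap) {
      rem2 <- rem
      if (i == j) rem2[i] <- rem2[i] - 2L * x
      else { rem2[i] <- rem2[i] - x; rem2[j] <- rem2[j] - x }
      cur[i, j] <- x
      if (!rec(idx + 1L, rem2, cur)) return(FALSE)
    }
    TRUE
  }
  ok <- rec(1L, as.integer(m), matrix(0L, k, k))
  if (!ok) return(NULL)
  out
}

#' EM estimation of multi-segment haplotype frequencies
#'
#' Estimates the frequencies of allele haplotypes (one allele per locus,
#' e.g. the IGHG3-IGHG1-IGHG2 trio) from unphased multilocus genotypes by
#' expectation-maximization, run from a uniform start plus random restarts;
#' the best run by log-likelihood is returned. The log-likelihood is
#' guaranteed non-decreasing across iterations and is checked at every step.
#'
#' @param genotypes data.frame with columns individual_id, locus, allele1,
#'   allele2 (one row per individual per locus).
#' @param n_restarts random restarts in addition to the uniform start.
#' @param max_iter,tol iteration cap and convergence threshold on the
#'   log-likelihood increase.
#' @param seed integer seed for the random restarts.
#' @return list with haplotypes (data.frame of per-locus alleles and
#'   frequency), loglik, n_iterations, converged, loci, phases (most probable
#'   phase per individual).
#' @export
emHaplotypes <- function(genotypes, n_restarts = 5L, max_iter = 500L,
                         tol = 1e-10, seed = 1L) {
  loci <- unique(genotypes$locus)
  ids <- unique(genotypes$individual_id)
  if (length(ids) < 1L) stop("need at least one individual")
  G <- lapply(ids, function(id) {
    g <- genotypes[genotypes$individual_id == id, ]
    g <- g[match(loci, g$locus), ]
    if (anyNA(g$allele1) || anyNA(g$allele2))
      stop("individual ", id, " lacks a genotype at some locus")
    cbind(g$allele1, g$allele2)
  })
  # all phase decompositions per individual: pairs of haplotype strings
  decomp <- lapply(G, function(g) {
    het <- which(g[, 1] != g[, 2])
    if (length(het) == 0L)
      return(list(cbind(paste(g[, 1], collapse = "|"),
                        paste(g[, 2], collapse = "|"))))
    fix <- het[1]  # orient first het locus to halve the enumeration
    rest <- het[-1]
    combos <- expand.grid(rep(list(c(TRUE, FALSE)), length(rest)))
    lapply(seq_len(max(1L, nrow(combos))), function(r) {
      h1 <- g[, 1]; h2 <- g[, 2]
      if (length(rest)) for (ii in seq_along(rest)) if (!combos[r, ii]) {
        l <- rest[ii]; tmp <- h1[l]; h1[l] <- h2[l]; h2[l] <- tmp
      }
      cbind(paste(h1, collapse = "|"), paste(h2, collapse = "|"))
    })
  })
  hap_names <- sort(unique(unlist(decomp)))
  H <- length(hap_names)
  run_em <- function(f0) {
    f <- f0; ll_old <- -Inf; it <- 0L; converged <- FALSE
    repeat {
      it <- it + 1L
      expect <- setNames(numeric(H), hap_names)
      ll <- 0
      for (d in decomp) {
        w <- vapply(d, function(pr) {
          p <- f[pr[1]] * f[pr[2]]
          if (pr[1] != pr[2]) 2 * p else p
        }, 0)
        tot <- sum(w)
        ll <- ll + log(tot)
        if (tot > 0) for (z in seq_along(d)) {
          pr <- d[[z]]; wz <- w[z] / tot
          expect[pr[1]] <- expect[pr[1]] + wz
          expect[pr[2]] <- expect[pr[2]] + wz
        }
      }
      if (ll < ll_old - 1e-8)
        stop("internal error: EM log-likelihood decreased")
      f <- expect / sum(expect)
      if (is.finite(ll_old) && ll - ll_old < tol) { converged <- TRUE; break }
      if (it >= max_iter) break
      ll_old <- ll
    }
    list(f = f, loglik = ll, iter = it, converged = converged)
  }
  set.seed(seed)
  starts <- c(list(rep(1 / H, H)),
              lapply(seq_len(n_restarts), function(i) {
                x <- rexp(H); x / sum(x)
              }))
  runs <- lapply(starts, function(s) run_em(setNames(s, hap_names)))
  best <- runs[[which.max(vapply(runs, `[[`, 0, "loglik"))]]
  f <- best$f
  phases <- lapply(seq_along(decomp), function(i) {
    d <- decomp[[i]]
    w <- vapply(d, function(pr) {
      p <- f[pr[1]] * f[pr[2]]; if (pr[1] != pr[2]) 2 * p else p
    }, 0)
    z <- which.max(w)
    list(individual_id = ids[i], hap1 = d[[z]][1], hap2 = d[[z]][2],
         posterior = if (sum(w) > 0) w[z] / sum(w) else NA_real_)
  })
  keep <- f > 1e-8
  parts <- strsplit(hap_names[keep], "|", fixed = TRUE)
  hdf <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(hdf) <- as.character(loci)
  hdf$frequency <- unname(f[keep])
  hdf <- hdf[order(-hdf$frequency), , drop = FALSE]
  rownames(hdf) <- NULL
  list(haplotypes = hdf, loglik = best$loglik, n_iterations = best$iter,
       converged = best$converged, loci = as.character(loci), phases = phases)
}
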