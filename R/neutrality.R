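#' Site frequency spectrum of an alignment sample
#'
#' Counts polymorphic sites by minor-allele count (folded spectrum) and, when
#' an outgroup is present, by derived-allele count (unfolded spectrum,
#' polarized by the outgroup state). Sites with a non-ACGT symbol in any
#' ingroup sequence are excluded listwise (complete deletion); triallelic
#' ingroup sites are excluded with a message; when an outgroup is used,
#' sites where it carries a gap or a third state are excluded as
#' unpolarizable, so the folded and unfolded spectra are computed on the
#' same set of sites.
#'
#' @param sample an [AlignmentSample-class].
#' @return list with `folded` (counts indexed 1..floor(n/2)), `unfolded`
#'   (1..n-1, NULL without outgroup), `S`, `n`, `used_sites`.
#' @export
siteFrequencySpectrum <- function(sample) {
  mat <- .alignment_matrix(sample)
  x <- mat$ingroup; og <- mat$outgroup
  n <- nrow(x)
  folded <- integer(max(1L, floor(n / 2)))
  unfolded <- if (!is.null(og)) integer(n - 1L) else NULL
  used <- 0L
  for (j in mat$usable) {
    col <- x[, j]
    tb <- table(col)
    if (length(tb) == 1L) { used <- used + 1L; next }
    if (length(tb) > 2L) { message("excluding triallelic site ", j); next }
    if (!is.null(og)) {
      anc <- og[j]
      if (!anc %in% names(tb)) {
        message("excluding site ", j, ": outgroup state not in ingroup")
        next
      }
      derived <- sum(col != anc)
      unfolded[derived] <- unfolded[derived] + 1L
    }
    minor <- min(tb)
    folded[minor] <- folded[minor] + 1L
    used <- used + 1L
  }
  list(folded = folded, unfolded = unfolded, S = sum(folded), n = n,
       used_sites = used)
}

.alignment_matrix <- function(sample) {
  seqs <- as.character(sample@sequences)
  x <- do.call(rbind, strsplit(seqs, ""))
  og <- if (length(sample@outgroup))
    strsplit(as.character(sample@outgroup[[1]]), "")[[1]] else NULL
  ok <- apply(x, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  if (!is.null(og)) ok <- ok & og %in% c("A", "C", "G", "T")
  list(ingroup = x, outgroup = og, usable = which(ok))
}

#' Summary statistics and neutrality tests for one alignment
#'
#' Computes the standard site-frequency-spectrum summaries and test
#' statistics for a sample of n haplotypes: number of segregating sites S,
#' mean pairwise differences (nucleotide diversity) pi, Watterson's theta,
#' Tajima's D, Fu and Li's D and F (requiring the outgroup to identify
#' mutations on external branches), their outgroup-free starred versions D*
#' and F*, and -- with an outgroup -- Fay and Wu's theta_H and unnormalized
#' H = pi - theta_H, which is sensitive to an excess of high-frequency
#' derived variants such as that left by hitchhiking. Requesting the
#' outgroup-polarized statistics without an outgroup is an error rather than
#' a silent fold.
#'
#' @param sample an [AlignmentSample-class] (n >= 4 for the variance-based
#'   tests).
#' @param null optional result of [coalescentNull()]; when supplied,
#'   lower-tail p-values are attached.
#' @return list with n, S, pi, theta_w, theta_h, tajima_d, fuli_d, fuli_f,
#'   fuli_dstar, fuli_fstar, fay_wu_h, and p_values (NULL unless `null`).
#' @export
neutralityStats <- function(sample, null = NULL) {
  sfs <- siteFrequencySpectrum(sample)
  n <- sfs$n
  if (n < 4L) stop("need at least 4 sequences")
  has_og <- !is.null(sfs$unfolded)
  S <- sfs$S
  out <- list(n = n, S = S)
  if (S == 0L) {
    out[c("pi", "theta_w", "theta_h")] <- list(0, 0, if (has_og) 0 else NA_real_)
    out[c("tajima_d", "fuli_d", "fuli_f", "fuli_dstar", "fuli_fstar",
          "fay_wu_h")] <- list(NA_real_, NA_real_, NA_real_, NA_real_,
                               NA_real_, if (has_og) 0 else NA_real_)
    out$p_values <- if (is.null(null)) NULL else
      setNames(rep(1, 6), c("tajima_d", "fuli_d", "fuli_f", "fuli_dstar",
                            "fuli_fstar", "fay_wu_h"))
    return(out)
  }
  folded <- sfs$folded; unfolded <- sfs$unfolded
  if (has_og) {
    i <- seq_len(n - 1)
    pi <- sum(unfolded * 2 * i * (n - i)) / (n * (n - 1))
    eta_e <- unfolded[1]
    theta_h <- sum(2 * unfolded * i^2) / (n * (n - 1))
  } else {
    i <- seq_along(folded)
    pi <- sum(folded * 2 * i * (n - i)) / (n * (n - 1))
    eta_s <- folded[1]
    theta_h <- NA_real_
  }
  k <- .sfs_constants(n)
  theta_w <- S / k$a1
  out$pi <- pi; out$theta_w <- theta_w; out$theta_h <- theta_h
  vd <- k$e1 * S + k$e2 * S * (S - 1)
  out$tajima_d <- if (vd > 0) (pi - theta_w) / sqrt(vd) else NA_real_
  eta_s_folded <- if (has_og) {
    # singletons regardless of polarity (counts of minor-allele-1 sites)
    f <- integer(max(1L, floor(n / 2)))
    mi <- pmin(seq_len(n - 1), n - seq_len(n - 1))
    for (d in seq_len(n - 1)) f[mi[d]] <- f[mi[d]] + unfolded[d]
    f[1]
  } else eta_s
  out$fuli_dstar <- (n / (n - 1) * S - k$a1 * eta_s_folded) /
    sqrt(k$uDs * S + k$vDs * S^2)
  out$fuli_fstar <- (pi - (n - 1) / n * eta_s_folded) /
    sqrt(k$uFs * S + k$vFs * S^2)
  if (has_og) {
    out$fuli_d <- (S - k$a1 * eta_e) / sqrt(k$uD * S + k$vD * S^2)
    out$fuli_f <- (pi - eta_e) / sqrt(k$uF * S + k$vF * S^2)
    out$fay_wu_h <- pi - theta_h
  } else {
    out$fuli_d <- out$fuli_f <- out$fay_wu_h <- NA_real_
  }
  if (!is.null(null)) out$p_values <- .null_pvalues(out, null)
  out
}

# coefficients of the SFS test statistics (Tajima 1989; Fu & Li 1993 with
# the Simonsen et al. 1995 corrected variance terms)
.sfs_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2); an1 <- a1 + 1 / n
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  cn <- if (n > 2) 2 * (n * a1 - 2 * (n - 1)) / ((n - 1) * (n - 2)) else 1
  vD <- 1 + a1^2 / (a2 + a1^2) * (cn - (n + 1) / (n - 1))
  uD <- a1 - 1 - vD
  vF <- (cn + 2 * (n^2 + n + 3) / (9 * n * (n - 1)) - 2 / (n - 1)) / (a1^2 + a2)
  uF <- (1 + (n + 1) / (3 * (n - 1)) -
           4 * (n + 2) / (n + 1)^2 * (an1 - 2 * n / (n + 1))) / a1 - vF
  dn <- cn + (n - 2) / (n - 1)^2 +
    2 / (n - 1) * (1.5 - (2 * an1 - 3) / (n - 2) - 1 / n)
  vDs <- ((n / (n - 1))^2 * a2 + a1^2 * dn -
            2 * n * a1 * (a1 + 1) / (n - 1)^2) / (a1^2 + a2)
  uDs <- n / (n - 1) * (a1 - n / (n - 1)) - vDs
  vFs <- ((2 * n^3 + 110 * n^2 - 255 * n + 153) / (9 * n^2 * (n - 1)) +
            2 * (n - 1) * a1 / n^2 - 8 * a2 / n) / (a1^2 + a2)
  uFs <- (n / (n - 1) + (n + 1) / (3 * (n - 1)) - 4 / (n * (n - 1)) +
            2 * (n + 1) / (n - 1)^2 * (an1 - 2 * n / (n + 1))) / a1 - vFs
  list(a1 = a1, a2 = a2, e1 = e1, e2 = e2, cn = cn, uD = uD, vD = vD,
       uF = uF, vF = vF, uDs = uDs, vDs = vDs, uFs = uFs, vFs = vFs)
}

#' Coalescent null distributions for the neutrality statistics
#'
#' Simulates standard neutral coalescent genealogies for n haplotypes and
#' places mutations on branches, either a fixed number S (matching the
#' common "given S" conditioning of the reported tests) or Poisson with rate
#' theta/2 per unit branch length ("theta" mode, used for calibration
#' checks). Each replicate yields the full set of statistics; p-values are
#' lower-tail proportions (the alternatives of interest are negative values).
#'
#' @param n sample size.
#' @param S fixed number of segregating sites ("fixed_s" mode).
#' @param theta population mutation rate ("theta" mode).
#' @param replicates number of genealogies.
#' @param seed integer seed.
#' @param mode "fixed_s" or "theta".
#' @return list with `stats` (replicates x statistic matrix), `S` (simulated
#'   S per replicate), n, mode.
#' @export
coalescentNull <- function(n, S = NULL, theta = NULL, replicates = 1000L,
                           seed = 1L, mode = c("fixed_s", "theta")) {
  mode <- match.arg(mode)
  if (n < 2L) stop("need n >= 2")
  if (mode == "fixed_s" && is.null(S)) stop("fixed_s mode needs S")
  if (mode == "theta" && is.null(theta)) stop("theta mode needs theta")
  set.seed(seed)
  nm <- c("pi", "theta_w", "theta_h", "tajima_d", "fuli_d", "fuli_f",
          "fuli_dstar", "fuli_fstar", "fay_wu_h")
  stats <- matrix(NA_real_, replicates, length(nm),
                  dimnames = list(NULL, nm))
  Ss <- integer(replicates)
  k <- .sfs_constants(n)
  for (r in seq_len(replicates)) {
    br <- .sim_genealogy_branches(n)       # branch sizes + lengths
    L <- sum(br$len)
    s <- if (mode == "fixed_s") S else rpois(1L, theta * L / 2)
    Ss[r] <- s
    unfolded <- integer(n - 1L)
    if (s > 0 && L > 0) {
      hit <- sample.int(length(br$len), s, replace = TRUE, prob = br$len)
      for (b in hit) unfolded[br$size[b]] <- unfolded[br$size[b]] + 1L
    }
    stats[r, ] <- .stats_from_unfolded(unfolded, n, k)
  }
  list(stats = stats, S = Ss, n = n, mode = mode)
}

# branches of one standard coalescent genealogy: subtree size and length
.sim_genealogy_branches <- function(n) {
  size <- rep(1L, n)
  len <- rep(0, n)
  active <- seq_len(n)
  sizes <- size
  out_size <- integer(0); out_len <- numeric(0)
  while (length(active) > 1L) {
    kk <- length(active)
    t <- rexp(1, rate = kk * (kk - 1) / 2)
    len[active] <- len[active] + t
    pick <- sample(active, 2L)
    out_size <- c(out_size, sizes[pick])
    out_len <- c(out_len, len[pick])
    new <- length(sizes) + 1L
    sizes <- c(sizes, sum(sizes[pick]))
    len <- c(len, 0)
    active <- c(setdiff(active, pick), new)
  }
  list(size = out_size, len = out_len)
}

.stats_from_unfolded <- function(unfolded, n, k) {
  S <- sum(unfolded)
  if (S == 0L)
    return(c(pi = 0, theta_w = 0, theta_h = 0, tajima_d = NA, fuli_d = NA,
             fuli_f = NA, fuli_dstar = NA, fuli_fstar = NA, fay_wu_h = 0))
  i <- seq_len(n - 1)
  pi <- sum(unfolded * 2 * i * (n - i)) / (n * (n - 1))
  theta_w <- S / k$a1
  theta_h <- sum(2 * unfolded * i^2) / (n * (n - 1))
  eta_e <- unfolded[1]
  mi <- pmin(i, n - i)
  eta_s <- sum(unfolded[mi == 1])
  vd <- k$e1 * S + k$e2 * S * (S - 1)
  c(pi = pi, theta_w = theta_w, theta_h = theta_h,
    tajima_d = if (vd > 0) (pi - theta_w) / sqrt(vd) else NA,
    fuli_d = (S - k$a1 * eta_e) / sqrt(k$uD * S + k$vD * S^2),
    fuli_f = (pi - eta_e) / sqrt(k$uF * S + k$vF * S^2),
    fuli_dstar = (n / (n - 1) * S - k$a1 * eta_s) /
      sqrt(k$uDs * S + k$vDs * S^2),
    fuli_fstar = (pi - (n - 1) / n * eta_s) / sqrt(k$uFs * S + k$vFs * S^2),
    fay_wu_h = pi - theta_h)
}

.null_pvalues <- function(obs, null) {
  nm <- c("tajima_d", "fuli_d", "fuli_f", "fuli_dstar", "fuli_fstar",
          "fay_wu_h")
  out <- setNames(rep(NA_real_, length(nm)), nm)
  for (s in nm) {
    v <- null$stats[, s]
    v <- v[is.finite(v)]
    if (!length(v) || !is.finite(obs[[s]])) next
    out[s] <- mean(v <= obs[[s]])
  }
  out
}

#' Outgroup-polarized statistics with an explicit precondition
#'
#' Fay and Wu's H and Fu and Li's D and F need an outgroup to label derived
#' states; these accessors raise an error when the sample has none rather
#' than silently folding the spectrum.
#'
#' @param sample an [AlignmentSample-class].
#' @export
fayWuH <- function(sample) .polarized_stat(sample, "fay_wu_h")

#' @rdname fayWuH
#' @export
fuLiD <- function(sample) .polarized_stat(sample, "fuli_d")

#' @rdname fayWuH
#' @export
fuLiF <- function(sample) .polarized_stat(sample, "fuli_f")

.polarized_stat <- function(sample, what) {
  if (length(sample@outgroup) == 0L)
    stop("precondition error: ", what, " requires an outgroup sequence")
  neutralityStats(sample)[[what]]
}

#' Read an alignment FASTA with a tagged outgroup record
#'
#' @param path FASTA file; the record whose ID contains `outgroup_token`
#'   (case-insensitive) becomes the outgroup.
#' @param segment segment label.
#' @param outgroup_token substring marking the outgroup record.
#' @return an [AlignmentSample-class].
#' @export
readAlignmentFasta <- function(path, segment = NA_character_,
                               outgroup_token = "outgroup") {
  x <- Biostrings::readDNAStringSet(path)
  og <- grepl(outgroup_token, names(x), ignore.case = TRUE)
  AlignmentSample(x[!og], if (any(og)) x[og][1] else NULL, segment)
}

#' Neutrality report for a set of alignments
#'
#' @param samples named list of [AlignmentSample-class] objects.
#' @param replicates,seed coalescent null settings.
#' @return data.frame mirroring a per-population statistics table (one row
#'   per sample and statistic, with value, p and a significance code).
#' @export
neutralityReport <- function(samples, replicates = 1000L, seed = 1L) {
  out <- NULL
  for (nm in names(samples)) {
    st <- neutralityStats(samples[[nm]])
    if (st$S > 0) {
      null <- coalescentNull(st$n, S = st$S, replicates = replicates,
                             seed = seed)
      st <- neutralityStats(samples[[nm]], null = null)
    }
    for (s in c("tajima_d", "fuli_d", "fuli_f", "fuli_dstar", "fuli_fstar",
                "fay_wu_h")) {
      p <- if (!is.null(st$p_values)) unname(st$p_values[s]) else NA_real_
      out <- rbind(out, data.frame(
        sample = nm, statistic = s, value = st[[s]], p = p,
        significance = if (!is.na(p) && p < 0.001) "***"
          else if (!is.na(p) && p < 0.01) "**"
          else if (!is.na(p) && p < 0.05) "*" else "ns",
        stringsAsFactors = FALSE))
    }
  }
  out
}
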