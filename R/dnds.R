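#' Nei-Gojobori synonymous and non-synonymous site counts of a codon
#'
#' Fractional site counts by enumeration of all nine single-base mutants:
#' the synonymous site count is the fraction of mutations (per position) that
#' preserve the encoded amino acid, summed over the three positions;
#' mutations to stop codons are never synonymous and are counted on the
#' non-synonymous side, so s + n = 3.
#'
#' @param codon 3-letter string, one of the 61 sense codons.
#' @return c(s = synonymous sites, n = non-synonymous sites).
#' @examples
#' ng86Sites("TTT")  # s = 1/3
#' ng86Sites("ATG")  # s = 0 (Met has no synonym)
#' @export
ng86Sites <- function(codon) {
  codon <- toupper(codon)
  aa <- .translate_codon(codon)
  if (aa == "*") stop("domain error: stop codon ", codon)
  syn <- 0
  for (pos in 1:3) for (b in setdiff(c("A", "C", "G", "T"),
                                     substr(codon, pos, pos))) {
    mut <- codon
    substr(mut, pos, pos) <- b
    if (.translate_codon(mut) == aa) syn <- syn + 1
  }
  c(s = syn / 3, n = 3 - syn / 3)
}

.translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) stop("not a codon: ", codon)
  aa
}

#' Pairwise Nei-Gojobori proportions and Jukes-Cantor distances
#'
#' Site counts are averaged over the two sequences; codons differing at more
#' than one position are resolved by averaging the synonymous/non-synonymous
#' step classification over all minimal mutational pathways, excluding
#' pathways that pass through a stop codon (all pathways are used if every
#' one is blocked). Proportions are corrected with the Jukes-Cantor formula
#' d = -(3/4) log(1 - 4p/3); p >= 3/4 leaves the distance undefined (NA,
#' flagged).
#'
#' @param s1,s2 nucleotide strings of equal length divisible by 3, shared
#'   reading frame.
#' @return list with Sd, Nd, S_sites, N_sites, pS, pN, dS, dN, undefined.
#' @export
ng86Pairwise <- function(s1, s2) {
  c1 <- .codons(s1); c2 <- .codons(s2)
  if (length(c1) != length(c2)) stop("sequences differ in length")
  Sd <- 0; Nd <- 0; Ss <- 0; Ns <- 0
  for (i in seq_along(c1)) {
    st1 <- ng86Sites(c1[i]); st2 <- ng86Sites(c2[i])
    Ss <- Ss + (st1["s"] + st2["s"]) / 2
    Ns <- Ns + (st1["n"] + st2["n"]) / 2
    if (c1[i] != c2[i]) {
      d <- .pathway_average(c1[i], c2[i])
      Sd <- Sd + d["s"]; Nd <- Nd + d["n"]
    }
  }
  Sd <- unname(Sd); Nd <- unname(Nd); Ss <- unname(Ss); Ns <- unname(Ns)
  pS <- if (Ss > 0) Sd / Ss else 0
  pN <- if (Ns > 0) Nd / Ns else 0
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(Sd = Sd, Nd = Nd, S_sites = Ss, N_sites = Ns, pS = pS, pN = pN,
       dS = jc(pS), dN = jc(pN),
       undefined = pS >= 0.75 || pN >= 0.75)
}

.codons <- function(s) {
  s <- toupper(as.character(s))
  if (nchar(s) %% 3 != 0) stop("length not divisible by 3")
  substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
}

# average (synonymous, non-synonymous) step counts over minimal pathways
.pathway_average <- function(a, b) {
  pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  paths <- if (length(pos) == 1L) list(pos) else
    .permutations(pos)
  score <- function(path, allow_stop) {
    cur <- a; s <- 0; n <- 0
    for (p in path) {
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      if (!allow_stop && .translate_codon(nxt) == "*") return(NULL)
      if (.translate_codon(cur) != "*" && .translate_codon(nxt) != "*" &&
          .translate_codon(cur) == .translate_codon(nxt)) s <- s + 1
      else n <- n + 1
      cur <- nxt
    }
    c(s = s, n = n)
  }
  res <- Filter(Negate(is.null), lapply(paths, score, allow_stop = FALSE))
  if (!length(res)) res <- lapply(paths, score, allow_stop = TRUE)
  Reduce(`+`, res) / length(res)
}

.ng86_cache <- new.env(parent = emptyenv())

.ng86_sites_cached <- function(codon) {
  v <- .ng86_cache[[codon]]
  if (is.null(v)) {
    v <- ng86Sites(codon)
    .ng86_cache[[codon]] <- v
  }
  v
}

.pathway_average_cached <- function(a, b) {
  key <- paste0(a, "|", b)
  v <- .ng86_cache[[key]]
  if (is.null(v)) {
    v <- .pathway_average(a, b)
    .ng86_cache[[key]] <- v
  }
  v
}

.permutations <- function(x) {
  if (length(x) == 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in .permutations(x[-i]))
      out[[length(out) + 1L]] <- c(x[i], rest)
  out
}

#' Codon-based Z-test of selection over an allele set
#'
#' Computes the overall average of the pairwise Nei-Gojobori dS and dN over
#' all sequence pairs and tests dN < dS (purifying) or dN > dS (positive)
#' with a one-tailed normal test; the variance of dS - dN is estimated by
#' bootstrap over codon columns.
#'
#' @param seqs named character vector of coding sequences (equal length,
#'   shared frame).
#' @param alternative "purifying" (dN < dS) or "positive" (dN > dS).
#' @param B bootstrap resamples.
#' @param seed integer seed for the bootstrap.
#' @param warn_stops warn and mask codon columns containing internal stop
#'   codons instead of failing.
#' @return list Z, p, dS, dN, se, n_pairs.
#' @export
codonZTest <- function(seqs, alternative = c("purifying", "positive"),
                       B = 1000L, seed = 1L, warn_stops = TRUE) {
  alternative <- match.arg(alternative)
  if (length(seqs) < 2L) stop("need at least two sequences")
  cod <- lapply(seqs, .codons)
  L <- length(cod[[1]])
  stopmask <- rep(FALSE, L)
  for (cs in cod) stopmask <- stopmask |
      vapply(cs, function(x) .translate_codon(x) == "*", NA)
  if (any(stopmask)) {
    if (!warn_stops) stop("internal stop codons present")
    warning(sum(stopmask), " codon columns with internal stops masked")
  }
  keep <- which(!stopmask)
  # per-pair per-codon-column contributions, so the bootstrap only resamples
  # and sums columns
  prs <- utils::combn(length(cod), 2L)
  np <- ncol(prs)
  sdM <- matrix(0, np, L); ndM <- matrix(0, np, L)
  ssM <- matrix(0, np, L); nsM <- matrix(0, np, L)
  for (q in seq_len(np)) {
    ci <- cod[[prs[1, q]]]; cj <- cod[[prs[2, q]]]
    for (col in keep) {
      s1 <- .ng86_sites_cached(ci[col]); s2 <- .ng86_sites_cached(cj[col])
      ssM[q, col] <- (s1[1] + s2[1]) / 2
      nsM[q, col] <- (s1[2] + s2[2]) / 2
      if (ci[col] != cj[col]) {
        d <- .pathway_average_cached(ci[col], cj[col])
        sdM[q, col] <- d[1]; ndM[q, col] <- d[2]
      }
    }
  }
  jc <- function(p) ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
  mean_d <- function(cols) {
    Ss <- rowSums(ssM[, cols, drop = FALSE])
    Ns <- rowSums(nsM[, cols, drop = FALSE])
    Sd <- rowSums(sdM[, cols, drop = FALSE])
    Nd <- rowSums(ndM[, cols, drop = FALSE])
    dS <- jc(ifelse(Ss > 0, Sd / Ss, 0))
    dN <- jc(ifelse(Ns > 0, Nd / Ns, 0))
    c(dS = mean(dS, na.rm = TRUE), dN = mean(dN, na.rm = TRUE))
  }
  obs <- mean_d(keep)
  if (!is.finite(obs["dS"]) || (obs["dS"] == 0 && obs["dN"] == 0))
    return(list(Z = 0, p = 1, dS = unname(obs["dS"]), dN = unname(obs["dN"]),
                se = NA_real_, n_pairs = choose(length(cod), 2)))
  set.seed(seed)
  boot <- vapply(seq_len(B), function(b) {
    cols <- sample(keep, length(keep), replace = TRUE)
    d <- mean_d(cols)
    d["dS"] - d["dN"]
  }, 0)
  se <- sd(boot, na.rm = TRUE)
  diff <- unname(obs["dS"] - obs["dN"])
  Z <- if (alternative == "purifying") diff / se else -diff / se
  list(Z = Z, p = 1 - pnorm(Z), dS = unname(obs["dS"]),
       dN = unname(obs["dN"]), se = se, n_pairs = choose(length(cod), 2))
}

#' Codon alignment of all alleles of one segment
#'
#' Reconstructs the coding sequence of every allele over the CH exons only
#' (hinge exons vary in copy number between IGHG3 alleles and would break
#' the shared frame) for the selection analysis.
#'
#' @param catalog an [AlleleCatalog-class].
#' @param segment segment name.
#' @param consensus per-exon consensus [Biostrings::DNAStringSet].
#' @param observed_only drop zero-copy alleles.
#' @return named character vector of coding sequences.
#' @export
codonAlignmentFromAlleles <- function(catalog, segment, consensus,
                                      observed_only = FALSE) {
  ch <- consensus[names(consensus) %in% paste0(segment, "|",
                                               c("CH1", "CH2", "CH3"))]
  a <- alleleTable(catalog, segment)
  if (observed_only) a <- a[a$copies > 0L, ]
  out <- vapply(a$name, function(nm)
    as.character(reconstructAlleleSequence(catalog, nm, ch)), "")
  names(out) <- a$name
  out
}
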