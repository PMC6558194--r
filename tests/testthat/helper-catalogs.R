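# shared fixtures and small independent oracles used across test files

vcat <- loadVariantCatalog()
acat <- suppressWarnings(loadAlleleCatalog())
baseline_cat <- local({
  b <- acat
  b@alleles <- b@alleles[b@alleles$status == "baseline", , drop = FALSE]
  suppressWarnings(methods::validObject(b))
  b
})
cons_fa <- loadConsensus()

# build the complete genotype record of an allele pair (all catalog columns)
full_record <- function(catalog, segment, n1, n2) {
  prof <- IGHGpop:::.allele_profiles(catalog, segment)
  keys <- colnames(prof)
  parts <- strsplit(keys, ":", fixed = TRUE)
  b1 <- prof[n1, ]; b2 <- prof[n2, ]
  data.frame(exon = vapply(parts, `[`, "", 1L),
             exonic_pos = as.integer(vapply(parts, `[`, "", 2L)),
             base1 = pmin(b1, b2), base2 = pmax(b1, b2),
             stringsAsFactors = FALSE)
}

# independent enumeration oracle: all allele pairs whose state union matches
# the record, written against the profile matrix directly
oracle_pairs <- function(catalog, segment, record) {
  prof <- IGHGpop:::.allele_profiles(catalog, segment)
  key <- paste(record$exon, record$exonic_pos, sep = ":")
  obs <- paste(record$base1, record$base2, sep = "/")
  names(obs) <- key
  nm <- rownames(prof)
  hits <- NULL
  for (i in seq_along(nm)) for (j in i:length(nm)) {
    ok <- TRUE
    for (k in key) {
      got <- paste(sort(c(prof[nm[i], k], prof[nm[j], k])), collapse = "/")
      if (got != obs[[k]]) { ok <- FALSE; break }
    }
    if (ok) hits <- rbind(hits, c(nm[i], nm[j]))
  }
  hits
}

# brute-force alignment summaries: direct double loops over pairs and sites
brute_pi <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, ""))
  n <- nrow(m); tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) tot <- tot + sum(m[i, ] != m[j, ])
  tot / choose(n, 2)
}
brute_S <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, ""))
  sum(apply(m, 2, function(col) length(unique(col)) > 1))
}
brute_unfolded <- function(seqs, outgroup) {
  m <- do.call(rbind, strsplit(seqs, ""))
  og <- strsplit(outgroup, "")[[1]]
  n <- nrow(m)
  sfs <- integer(n - 1)
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    if (length(unique(col)) != 2) next
    d <- sum(col != og[j])
    if (d >= 1 && d <= n - 1) sfs[d] <- sfs[d] + 1L
  }
  sfs
}

# random small ACGT alignment with a clean outgroup (binary sites only)
random_alignment <- function(n, L, seed) {
  set.seed(seed)
  anc <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  m <- matrix(rep(anc, each = n), n, L)
  n_mut <- sample(1:max(2, L %/% 3), 1)
  at <- sample(L, n_mut)
  for (p in at) {
    carriers <- sample(n, sample(n - 1, 1))
    m[carriers, p] <- sample(setdiff(c("A", "C", "G", "T"), anc[p]), 1)
  }
  list(seqs = apply(m, 1, paste, collapse = ""),
       outgroup = paste(anc, collapse = ""))
}
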