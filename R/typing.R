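#' Annotate differences between an observed sequence and the consensus
#'
#' Compares pre-aligned per-exon coding sequences against the per-exon
#' consensus and annotates every mismatch against the variant site catalog;
#' mismatches at positions absent from the catalog are flagged `new_site`.
#'
#' @param observed named character vector or DNAStringSet of per-exon
#'   sequences (names are exon labels).
#' @param consensus same shape, the consensus sequences.
#' @param catalog a [VariantCatalog-class].
#' @param segment segment label the exons belong to.
#' @return data.frame exon, exonic_pos, ref, obs, rsid, new_site.
#' @export
diffSequences <- function(observed, consensus, catalog, segment) {
  observed <- vapply(as.list(observed), as.character, "")
  consensus <- vapply(as.list(consensus), as.character, "")
  sites <- variantSites(catalog, segment)
  out <- NULL
  for (ex in names(observed)) {
    if (!ex %in% names(consensus)) stop("no consensus for exon ", ex)
    o <- strsplit(observed[[ex]], "")[[1]]
    k <- strsplit(consensus[[ex]], "")[[1]]
    if (length(o) != length(k))
      stop("alignment error: ", ex, " lengths differ (", length(o),
           " vs ", length(k), ")")
    pos <- which(o != k)
    for (p in pos) {
      hit <- sites$exon == ex & sites$exonic_pos == p & sites$alt == o[p]
      out <- rbind(out, data.frame(
        exon = ex, exonic_pos = p, ref = k[p], obs = o[p],
        rsid = if (any(hit)) sites$rsid[which(hit)[1]] else NA_character_,
        new_site = !any(hit), stringsAsFactors = FALSE))
    }
  }
  if (is.null(out))
    out <- data.frame(exon = character(0), exonic_pos = integer(0),
                      ref = character(0), obs = character(0),
                      rsid = character(0), new_site = logical(0))
  out
}

# state of every catalog allele at every site column of a segment
# (rows: alleles, cols: "EXON:POS" keys; hinge presence as pseudo-sites
#  "EXON:0" with states "P"/"A")
.allele_profiles <- function(catalog, segment) {
  a <- catalog@alleles[catalog@alleles$segment == segment, , drop = FALSE]
  s <- catalog@sites[catalog@sites$segment == segment, , drop = FALSE]
  keys <- paste(s$exon, s$exonic_pos, sep = ":")
  m <- matrix(rep(s$consensus, each = nrow(a)), nrow = nrow(a),
              dimnames = list(a$name, keys))
  for (i in seq_len(nrow(a))) {
    st <- a$variant_states[[i]]
    if (length(st)) m[i, names(st)] <- unname(st)
  }
  hinge_ex <- unique(s$exon[startsWith(s$exon, "H")])
  if (length(hinge_ex)) {
    hp <- matrix("P", nrow(a), length(hinge_ex),
                 dimnames = list(a$name, paste0(hinge_ex, ":0")))
    for (i in seq_len(nrow(a))) {
      hs <- .hinge_set(a$hinge_absent[i])
      if (length(hs)) hp[i, paste0(hs, ":0")] <- "A"
    }
    m <- cbind(m, hp)
  }
  m
}

.calls_from_df <- function(df) {
  key <- paste(df$exon, df$exonic_pos, sep = ":")
  ok <- !is.na(df$base1) & !is.na(df$base2)
  calls <- lapply(which(ok), function(i)
    sort(c(df$base1[i], df$base2[i])))
  names(calls) <- key[ok]
  list(calls = calls, missing = key[!ok])
}

#' All catalog allele pairs compatible with an unphased genotype
#'
#' Enumerates every unordered pair of catalog alleles whose combined states
#' reproduce the observed genotype exactly at every typed site; sites with
#' missing calls are excluded from the compatibility check.
#'
#' @param calls named list of sorted base pairs (names "EXON:POS"), or a
#'   genotype data.frame with columns exon, exonic_pos, base1, base2.
#' @param catalog an [AlleleCatalog-class].
#' @param segment segment label.
#' @param profiles precomputed allele state profiles for the segment
#'   (internal reuse across many records; computed when NULL).
#' @return data.frame allele1, allele2 (allele1 <= allele2); zero rows when
#'   no pair fits.
#' @export
enumerateCompatiblePairs <- function(calls, catalog, segment,
                                     profiles = NULL) {
  if (is.data.frame(calls)) calls <- .calls_from_df(calls)$calls
  prof <- if (is.null(profiles)) .allele_profiles(catalog, segment)
          else profiles
  keys <- intersect(names(calls), colnames(prof))
  foreign <- setdiff(names(calls), colnames(prof))
  # a call at a non-catalog site can only be explained by novel alleles
  if (length(foreign) > 0L)
    return(data.frame(allele1 = character(0), allele2 = character(0)))
  nm <- rownames(prof)
  n <- length(nm); K <- length(keys)
  lo <- vapply(calls[keys], `[`, "", 1L)
  hi <- vapply(calls[keys], `[`, "", 2L)
  sub <- prof[, keys, drop = FALSE]
  out1 <- character(0); out2 <- character(0)
  lo_m <- matrix(lo, n, K, byrow = TRUE)
  hi_m <- matrix(hi, n, K, byrow = TRUE)
  for (i in seq_len(n)) {
    ri <- matrix(sub[i, ], n, K, byrow = TRUE)
    hit <- which(rowSums(pmin(ri, sub) == lo_m & pmax(ri, sub) == hi_m) == K)
    hit <- hit[hit >= i]
    if (length(hit)) {
      out1 <- c(out1, rep(nm[i], length(hit))); out2 <- c(out2, nm[hit])
    }
  }
  data.frame(allele1 = out1, allele2 = out2, stringsAsFactors = FALSE)
}

#' Assign an allele pair to one individual
#'
#' Resolves an individual's unphased per-site genotype to a pair of catalog
#' alleles, or to provisional novel definitions when no catalog pair fits.
#' Phase certainty is classified as `homozygous` (no heterozygous site),
#' `single_het_unambiguous` (one heterozygous site, phase irrelevant),
#' `resolvable` (two or more heterozygous sites but a unique compatible
#' catalog pair) or `ambiguous_requires_phasing` (several consistent
#' decompositions; in the laboratory these were settled by molecular
#' cloning). When novel alleles must be invoked the decomposition minimizes
#' the number of novel alleles, then their total variant count, then breaks
#' ties lexicographically; an ambiguous record still reports that
#' representative pair but keeps the ambiguity flag.
#'
#' @param geno genotype data.frame for one individual and segment (columns
#'   exon, exonic_pos, base1, base2; NA bases mark missing calls).
#' @param catalog an [AlleleCatalog-class].
#' @param segment segment label.
#' @param individual,population optional labels carried through.
#' @param profiles precomputed allele state profiles (see
#'   [enumerateCompatiblePairs()]).
#' @return list with allele1, allele2, ambiguity_class, n_het_sites,
#'   novel_definitions (list), has_missing, candidates (data.frame of
#'   compatible catalog pairs).
#' @export
assignAlleles <- function(geno, catalog, segment,
                          individual = NA_character_,
                          population = NA_character_,
                          profiles = NULL) {
  if (is.null(profiles)) profiles <- .allele_profiles(catalog, segment)
  parsed <- .calls_from_df(geno)
  calls <- parsed$calls
  bases_ok <- vapply(calls, function(b) all(b %in% c("A","C","G","T","P")) ||
                       all(b %in% c("P","A")), NA)
  if (!all(bases_ok))
    stop("data error: invalid base calls at ",
         paste(names(calls)[!bases_ok], collapse = ","))
  het <- vapply(calls, function(b) b[1] != b[2], NA)
  n_het <- sum(het)
  pairs <- enumerateCompatiblePairs(calls, catalog, segment,
                                    profiles = profiles)
  res <- list(individual = individual, population = population,
              segment = segment, n_het_sites = n_het,
              has_missing = length(parsed$missing) > 0L,
              missing_sites = parsed$missing,
              novel_definitions = list(), candidates = pairs)
  if (nrow(pairs) == 1L) {
    res$allele1 <- pairs$allele1; res$allele2 <- pairs$allele2
    res$ambiguity_class <- if (n_het == 0L) "homozygous"
      else if (n_het == 1L) "single_het_unambiguous" else "resolvable"
    return(res)
  }
  if (nrow(pairs) > 1L) {
    ord <- order(pairs$allele1, pairs$allele2)
    res$allele1 <- pairs$allele1[ord[1]]; res$allele2 <- pairs$allele2[ord[1]]
    res$ambiguity_class <- "ambiguous_requires_phasing"
    return(res)
  }
  # no catalog pair: build decompositions with minimal novelty
  dec <- .novel_decompositions(calls, catalog, segment, profiles)
  best <- dec[[1]]
  res$allele1 <- best$name1; res$allele2 <- best$name2
  res$novel_definitions <- best$novel
  res$ambiguity_class <-
    if (n_het == 0L) "homozygous"
    else if (n_het == 1L) "single_het_unambiguous"
    else "ambiguous_requires_phasing"
  res
}

# decompositions of a genotype into two haplotypes, preferring catalog
# alleles; returns list ordered by (n novel, total novel variants, names)
.novel_decompositions <- function(calls, catalog, segment, profiles = NULL) {
  prof <- if (is.null(profiles)) .allele_profiles(catalog, segment)
          else profiles
  cons <- c(.consensus_lookup(catalog, segment),
            setNames(rep("P", sum(startsWith(colnames(prof), "H") &
                                    endsWith(colnames(prof), ":0"))),
                     grep("^H.*:0$", colnames(prof), value = TRUE)))
  keys <- names(calls)
  foreign <- setdiff(keys, names(cons))
  dec <- list()
  # one catalog allele + one (possibly novel) partner; impossible when the
  # record carries states at sites the catalog does not describe
  if (length(foreign) == 0L) for (nm in rownames(prof)) {
    if (!all(vapply(keys, function(k) prof[nm, k] %in% calls[[k]], NA))) next
    partner <- vapply(keys, function(k) {
      b <- calls[[k]]
      if (b[1] == b[2]) b[1] else setdiff(b, prof[nm, k])[1]
    }, "")
    pd <- .partner_definition(partner, cons, segment)
    dec[[length(dec) + 1L]] <- list(
      name1 = nm, name2 = pd$name, novel = list(pd$def),
      n_novel = 1L, n_var = length(pd$def$variant_states))
  }
  if (!length(dec)) {
    # two novel haplotypes: put all heterozygous alternative states on one
    partner1 <- vapply(keys, function(k) {
      b <- calls[[k]]
      if (b[1] == b[2]) b[1]
      else if (!is.na(cons[k]) && cons[k] %in% b) unname(cons[k])
      else sort(b)[1]
    }, "")
    partner2 <- vapply(keys, function(k) {
      b <- calls[[k]]
      if (b[1] == b[2]) b[1] else setdiff(b, partner1[[k]])[1]
    }, "")
    p1 <- .partner_definition(partner1, cons, segment, suffix = "a")
    p2 <- .partner_definition(partner2, cons, segment, suffix = "b")
    novel <- Filter(Negate(is.null), list(p1$def, p2$def))
    dec[[1L]] <- list(name1 = p1$name, name2 = p2$name, novel = novel,
                      n_novel = length(novel),
                      n_var = sum(vapply(novel, function(d)
                        length(d$variant_states), 0L)))
  }
  ord <- order(vapply(dec, `[[`, 0L, "n_novel"),
               vapply(dec, `[[`, 0L, "n_var"),
               vapply(dec, `[[`, "", "name1"),
               vapply(dec, `[[`, "", "name2"))
  dec[ord]
}

.partner_definition <- function(states, cons, segment, suffix = "") {
  keys <- names(states)
  dif <- keys[is.na(cons[keys]) | states[keys] != cons[keys]]
  hinge_abs <- sub(":0$", "", dif[endsWith(dif, ":0")])
  vs <- states[setdiff(dif, paste0(hinge_abs, ":0"))]
  name <- paste0(segment, "*novel", if (nzchar(suffix)) paste0("-", suffix))
  list(name = name,
       def = list(segment = segment, name = name,
                  variant_states = vs,
                  hinge_absent = paste(sort(hinge_abs), collapse = ";")))
}

#' Deduplicated novel allele definitions in a typed collection
#'
#' Compares observed allele definitions against a baseline catalog by their
#' variant-state and hinge-pattern signature; definitions absent from the
#' baseline are reported once each with provisional names `SEG*novel-k` in
#' discovery order. Individuals carrying a missing call or an ambiguous phase
#' are excluded from discovery.
#'
#' @param observed either an [AlleleCatalog-class] (only alleles with
#'   observed copies count as seen) or a list of assignment results from
#'   [assignAlleles()].
#' @param baseline the baseline [AlleleCatalog-class].
#' @param include_unobserved when `observed` is a catalog, also compare
#'   zero-copy definitions.
#' @return data.frame segment, provisional_name, variant_states, hinge_absent.
#' @export
detectNovel <- function(observed, baseline, include_unobserved = TRUE) {
  base_sig <- vapply(seq_len(nrow(baseline@alleles)), function(i)
    paste(baseline@alleles$segment[i],
          alleleSignature(baseline@alleles$variant_states[[i]],
                          baseline@alleles$hinge_absent[i])), "")
  defs <- list()
  if (methods::is(observed, "AlleleCatalog")) {
    a <- observed@alleles
    keep <- if (include_unobserved) seq_len(nrow(a)) else which(a$copies > 0L)
    for (i in keep)
      defs[[length(defs) + 1L]] <- list(segment = a$segment[i],
                                        variant_states = a$variant_states[[i]],
                                        hinge_absent = a$hinge_absent[i])
  } else {
    for (as_ in observed) {
      if (isTRUE(as_$has_missing)) next
      if (identical(as_$ambiguity_class, "ambiguous_requires_phasing")) next
      for (d in as_$novel_definitions)
        defs[[length(defs) + 1L]] <- list(segment = d$segment,
                                          variant_states = d$variant_states,
                                          hinge_absent = d$hinge_absent)
    }
  }
  out <- NULL; seen <- character(0); counter <- c(IGHG1 = 0L, IGHG2 = 0L, IGHG3 = 0L)
  for (d in defs) {
    ha <- if (is.null(d$hinge_absent) || is.na(d$hinge_absent)) "" else d$hinge_absent
    sig <- paste(d$segment, alleleSignature(d$variant_states, ha))
    if (sig %in% base_sig || sig %in% seen) next
    seen <- c(seen, sig)
    counter[d$segment] <- counter[d$segment] + 1L
    out <- rbind(out, data.frame(
      segment = d$segment,
      provisional_name = paste0(d$segment, "*novel-", counter[d$segment]),
      variant_states = paste(names(d$variant_states), d$variant_states,
                             sep = ":", collapse = ";"),
      hinge_absent = ha, stringsAsFactors = FALSE))
  }
  if (is.null(out))
    out <- data.frame(segment = character(0), provisional_name = character(0),
                      variant_states = character(0), hinge_absent = character(0))
  out
}

#' Type every individual in a genotype table
#'
#' @param geno genotype data.frame (individual_id, population, segment, exon,
#'   exonic_pos, base1, base2), e.g. from [readGenotypes()] or
#'   [simulatePopulation()].
#' @param catalog an [AlleleCatalog-class].
#' @return list of assignment results (one per individual x segment); see
#'   [assignAlleles()]. `assignmentTable()` flattens it.
#' @export
typeIndividuals <- function(geno, catalog) {
  out <- list()
  for (seg in unique(geno$segment)) {
    gs <- geno[geno$segment == seg, ]
    prof <- .allele_profiles(catalog, seg)
    for (id in unique(gs$individual_id)) {
      gi <- gs[gs$individual_id == id, ]
      out[[length(out) + 1L]] <-
        assignAlleles(gi, catalog, seg, individual = id,
                      population = gi$population[1], profiles = prof)
    }
  }
  out
}

#' @rdname typeIndividuals
#' @param assignments list produced by `typeIndividuals`.
#' @export
assignmentTable <- function(assignments) {
  do.call(rbind, lapply(assignments, function(a) data.frame(
    individual_id = a$individual, population = a$population,
    segment = a$segment, allele1 = a$allele1, allele2 = a$allele2,
    ambiguity_class = a$ambiguity_class, n_het_sites = a$n_het_sites,
    novel = length(a$novel_definitions) > 0L,
    has_missing = a$has_missing, stringsAsFactors = FALSE)))
}

#' Read / write genotype tables
#' @param path TSV path.
#' @export
readGenotypes <- function(path) {
  g <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  need <- c("individual_id", "population", "segment", "exon", "exonic_pos",
            "base1", "base2")
  if (!all(need %in% names(g)))
    stop("genotype table lacks columns: ",
         paste(setdiff(need, names(g)), collapse = ", "))
  g
}

#' @rdname readGenotypes
#' @param geno genotype data.frame.
#' @export
writeGenotypes <- function(geno, path) {
  writeLines("# IGHG genotype table, format v1", path)
  suppressWarnings(utils::write.table(geno, path, sep = "\t", quote = FALSE,
                                      row.names = FALSE, append = TRUE))
  invisible(path)
}
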