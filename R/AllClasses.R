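#' @import methods
#' @importFrom stats setNames rbinom runif rexp rpois rmultinom sd quantile prcomp p.adjust pnorm pchisq
#' @importFrom utils read.delim write.table combn head tail
#' @importFrom tools md5sum
NULL

SEGMENTS <- c("IGHG1", "IGHG2", "IGHG3")
EXON_ORDER <- c(CH1 = 1L, H = 2L, H1 = 2L, H2 = 3L, H3 = 4L, H4 = 5L,
                CH2 = 6L, CH3 = 7L)

#' Catalog of exonic variant sites of the IGHG gene segments
#'
#' Holds one row per polymorphic exonic position of IGHG1, IGHG2 or IGHG3,
#' with dual coordinates (1-based exonic position on the coding strand, and
#' the GRCh37 chromosome 14 position carried as annotation -- the gene is on
#' the minus strand, so chromosome coordinates decrease as exonic coordinates
#' increase), reference and alternative bases, amino-acid consequence,
#' serological allotype switch, Grantham distance of the replacement, and the
#' pooled alternative-allele frequency.
#'
#' @slot sites data.frame with columns segment, rsid, chr14_pos, exon,
#'   imgt_num, eu_num, exonic_pos, ref, alt, aa_ref, aa_alt, allotype_switch,
#'   grantham, pooled_freq.
#' @seealso [loadVariantCatalog()]
#' @export
setClass("VariantCatalog", representation(sites = "data.frame"))

setValidity("VariantCatalog", function(object) {
  s <- object@sites
  need <- c("segment", "rsid", "chr14_pos", "exon", "imgt_num", "eu_num",
            "exonic_pos", "ref", "alt", "aa_ref", "aa_alt",
            "allotype_switch", "grantham", "pooled_freq")
  if (!all(need %in% names(s)))
    return(paste("missing columns:", paste(setdiff(need, names(s)), collapse = ", ")))
  if (nrow(s) == 0L) return(TRUE)
  if (anyDuplicated(s[, c("segment", "chr14_pos")]))
    return("duplicated (segment, chr14_pos)")
  if (!all(s$ref %in% c("A", "C", "G", "T")) || !all(s$alt %in% c("A", "C", "G", "T")))
    return("ref/alt bases must be A/C/G/T")
  # synonymous sites carry no Grantham value, non-synonymous always do
  syn <- is.na(s$aa_alt) | s$aa_alt == ""
  gna <- is.na(s$grantham)
  if (!all(syn == gna))
    return("aa_alt and grantham must be jointly present or jointly absent")
  # minus-strand gene: chr14 position strictly decreases along the coding strand
  for (seg in unique(s$segment)) {
    x <- s[s$segment == seg, ]
    x <- x[order(EXON_ORDER[x$exon], x$exonic_pos), ]
    if (any(diff(x$chr14_pos) >= 0))
      return(paste0(seg, ": chr14_pos not strictly decreasing along coding order"))
  }
  TRUE
})

#' Catalog of named IGHG alleles
#'
#' Each allele is a set of departures from the per-exon consensus: a map from
#' (exon, exonic position) to an alternative base, plus -- for IGHG3 -- a
#' hinge-exon presence pattern (hinge copy number varies between alleles and
#' is part of allele identity, but a missing hinge exon is not a substitution
#' and is excluded from site-based statistics). Observed copy numbers are
#' chromosomes, so they sum to an even total per segment.
#'
#' @slot alleles data.frame with columns segment, name, status
#'   (baseline/novel), genbank, allotypes (comma string, "(..)" for none),
#'   hinge_absent (";"-joined absent hinge exons), variant_states (list column
#'   of named character vectors, names "EXON:POS"), copies.
#' @slot sites data.frame of the allele-table site columns: segment, exon,
#'   exonic_pos, imgt_num, eu_num, consensus, aa_annotation.
#' @seealso [loadAlleleCatalog()]
#' @export
setClass("AlleleCatalog", representation(alleles = "data.frame", sites = "data.frame"))

setValidity("AlleleCatalog", function(object) {
  a <- object@alleles
  s <- object@sites
  if (anyDuplicated(paste(a$segment, a$name))) return("duplicate allele names")
  if (any(a$copies < 0)) return("negative copy counts")
  key <- paste(s$segment, s$exon, s$exonic_pos, sep = ":")
  cons <- setNames(s$consensus, key)
  for (i in seq_len(nrow(a))) {
    st <- a$variant_states[[i]]
    if (length(st) == 0L) next
    k <- paste(a$segment[i], names(st), sep = ":")
    if (!all(k %in% key))
      return(paste0(a$name[i], ": state at unknown site ",
                    paste(names(st)[!k %in% key], collapse = ",")))
    if (any(cons[k] == st))
      return(paste0(a$name[i], ": variant state equals consensus"))
  }
  for (seg in unique(a$segment)) {
    if (sum(a$copies[a$segment == seg]) %% 2L != 0L)
      return(paste0(seg, ": copies do not sum to an even (diploid) total"))
    x <- a[a$segment == seg, ]
    sig <- vapply(seq_len(nrow(x)), function(i)
      alleleSignature(x$variant_states[[i]], x$hinge_absent[i]), "")
    for (grp in split(seq_len(nrow(x)), sig)) {
      if (length(grp) < 2L) next
      # the printed source tables contain one duplicated definition among
      # alleles distinguished only at sites not shown; tolerate a duplicate
      # group with a warning unless two of its members were both observed
      if (sum(x$copies[grp] > 0L) > 1L)
        return(paste0(seg, ": observed alleles share a definition: ",
                      paste(x$name[grp], collapse = ", ")))
      warning(seg, ": alleles with identical printed definitions: ",
              paste(x$name[grp], collapse = ", "), call. = FALSE)
    }
  }
  TRUE
})

alleleSignature <- function(states, hinge_absent) {
  if (length(states))
    states <- states[order(names(states))]
  paste(paste(names(states), states, sep = "=", collapse = ";"),
        hinge_absent, sep = "|")
}

#' Aligned sequence sample with optional outgroup
#'
#' A set of equal-length haplotype sequences from one gene segment, plus an
#' optional single outgroup sequence used to polarize ancestral vs derived
#' states for the unfolded site frequency spectrum.
#'
#' @slot sequences a [Biostrings::DNAStringSet] of ingroup haplotypes.
#' @slot outgroup a DNAStringSet of length 0 or 1.
#' @slot segment character label.
#' @export
setClass("AlignmentSample",
         representation(sequences = "DNAStringSet", outgroup = "DNAStringSet",
                        segment = "character"))

setValidity("AlignmentSample", function(object) {
  w <- Biostrings::width(object@sequences)
  if (length(unique(w)) > 1L) return("ingroup sequences differ in length")
  if (length(object@outgroup) > 1L) return("at most one outgroup sequence")
  if (length(object@outgroup) == 1L && length(w) &&
      Biostrings::width(object@outgroup) != w[1L])
    return("outgroup length differs from ingroup")
  TRUE
})

#' @describeIn AlignmentSample-class construct from character vectors.
#' @param sequences,outgroup,segment see slots.
#' @export
AlignmentSample <- function(sequences, outgroup = NULL, segment = NA_character_) {
  if (!methods::is(sequences, "DNAStringSet"))
    sequences <- Biostrings::DNAStringSet(sequences)
  og <- if (is.null(outgroup)) Biostrings::DNAStringSet() else {
    if (!methods::is(outgroup, "DNAStringSet"))
      outgroup <- Biostrings::DNAStringSet(outgroup)
    outgroup
  }
  methods::new("AlignmentSample", sequences = sequences, outgroup = og,
               segment = as.character(segment))
}

setMethod("show", "VariantCatalog", function(object) {
  s <- object@sites
  cat("VariantCatalog:", nrow(s), "sites,",
      sum(!is.na(s$aa_alt) & s$aa_alt != ""), "non-synonymous\n")
  for (seg in unique(s$segment))
    cat(" ", seg, ":", sum(s$segment == seg), "sites\n")
})

setMethod("show", "AlleleCatalog", function(object) {
  a <- object@alleles
  cat("AlleleCatalog:", nrow(a), "alleles (",
      sum(a$status == "baseline"), "baseline,",
      sum(a$status == "novel"), "novel ),",
      sum(a$copies), "observed chromosomes\n")
})

setMethod("show", "AlignmentSample", function(object) {
  cat("AlignmentSample [", object@segment, "]: n =",
      length(object@sequences), "haplotypes of width",
      if (length(object@sequences)) Biostrings::width(object@sequences)[1] else 0,
      if (length(object@outgroup)) "(+ outgroup)" else "(no outgroup)", "\n")
})

#' Accessors for catalog objects
#'
#' @param x a `VariantCatalog` or `AlleleCatalog`.
#' @param segment optional segment filter ("IGHG1", "IGHG2" or "IGHG3").
#' @return `variantSites` and `alleleTable` return data.frames;
#'   `nSites`/`nNonSynonymous`/`nAlleles` return integer counts;
#'   `alleleNames` a character vector; `siteColumns` the allele-table site
#'   definition data.frame (with consensus bases).
#' @name catalog-accessors
NULL

#' @rdname catalog-accessors
#' @export
variantSites <- function(x, segment = NULL) {
  s <- x@sites
  if (!is.null(segment)) s <- s[s$segment %in% segment, , drop = FALSE]
  s
}

#' @rdname catalog-accessors
#' @export
nSites <- function(x, segment = NULL) nrow(variantSites(x, segment))

#' @rdname catalog-accessors
#' @export
nNonSynonymous <- function(x, segment = NULL) {
  s <- variantSites(x, segment)
  sum(!is.na(s$aa_alt) & s$aa_alt != "")
}

#' @rdname catalog-accessors
#' @export
alleleTable <- function(x, segment = NULL) {
  a <- x@alleles
  if (!is.null(segment)) a <- a[a$segment %in% segment, , drop = FALSE]
  a
}

#' @rdname catalog-accessors
#' @export
alleleNames <- function(x, segment = NULL) alleleTable(x, segment)$name

#' @rdname catalog-accessors
#' @export
nAlleles <- function(x, segment = NULL) nrow(alleleTable(x, segment))

#' @rdname catalog-accessors
#' @export
siteColumns <- function(x, segment = NULL) {
  s <- x@sites
  if (!is.null(segment)) s <- s[s$segment %in% segment, , drop = FALSE]
  s
}
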