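#' Load the Gm marker state rules and Lefranc haplotype identifiers
#'
#' Each serological Gm marker is defined by a conjunction of required
#' nucleotide states at one or more sites of its segment (some markers, such
#' as G3m5, require the consensus state at two positions; a single-site rule
#' cannot express them). The Lefranc table maps canonical Gm haplotype
#' strings to the letter identifiers A-M used in the literature (only the
#' letters attested in the packaged frequency table are shipped).
#'
#' @param path TSV path; packaged defaults.
#' @return data.frames.
#' @export
loadMarkerRules <- function(path = ighgFixture("gm_marker_rules.tsv")) {
  r <- .read_catalog_tsv(path, c("marker_class", "marker", "segment",
                                 "required_states", "display_order"))
  r$display_order <- as.integer(r$display_order)
  r
}

#' @rdname loadMarkerRules
#' @export
loadLefrancIds <- function(path = ighgFixture("gm_lefranc_ids.tsv")) {
  .read_catalog_tsv(path, c("lefranc_id", "gm_string"))
}

#' Gm allotype markers carried by an allele
#'
#' For catalog alleles the allotype column of the catalog is returned; for
#' novel or provisional alleles the markers are derived from the marker state
#' rules applied to the allele's states (consensus assumed at unstated
#' sites). If a state combination matches no rule consistently the result
#' carries an `undetermined` attribute.
#'
#' @param catalog an [AlleleCatalog-class].
#' @param allele an allele name present in the catalog, or a list with
#'   `segment` and `variant_states` (as from novel detection).
#' @param rules marker rule table from [loadMarkerRules()].
#' @param derive force rule-based derivation even for catalog alleles.
#' @return character vector of marker tokens (empty when the segment carries
#'   no polymorphic marker, printed "(..)" in the catalog).
#' @examples
#' ac <- loadAlleleCatalog()
#' alleleAllotypes(ac, "IGHG1*07")  # "17" "1" "2"
#' @export
alleleAllotypes <- function(catalog, allele, rules = loadMarkerRules(),
                            derive = FALSE) {
  if (is.character(allele) && !derive) {
    a <- catalog@alleles
    i <- match(allele, a$name)
    if (is.na(i)) stop("allele not in catalog: ", allele)
    al <- a$allotypes[i]
    if (al %in% c("(..)", "(.)", "", NA)) return(character(0))
    return(strsplit(al, ",", fixed = TRUE)[[1]])
  }
  if (is.character(allele)) {
    a <- catalog@alleles
    i <- match(allele, a$name)
    if (is.na(i)) stop("allele not in catalog: ", allele)
    seg <- a$segment[i]; states <- a$variant_states[[i]]
  } else {
    seg <- allele$segment; states <- allele$variant_states
  }
  deriveAllotypes(seg, states, catalog, rules)
}

#' @rdname alleleAllotypes
#' @param segment,states segment label and named state vector ("EXON:POS").
#' @export
deriveAllotypes <- function(segment, states, catalog,
                            rules = loadMarkerRules()) {
  cons <- .consensus_lookup(catalog, segment)
  r <- rules[rules$segment == segment, , drop = FALSE]
  hit <- logical(nrow(r)); undetermined <- FALSE
  for (i in seq_len(nrow(r))) {
    req <- parseStateTokens(r$required_states[i])
    have <- ifelse(names(req) %in% names(states),
                   states[names(req)], cons[names(req)])
    if (anyNA(have)) { undetermined <- TRUE; next }
    hit[i] <- all(have == req)
  }
  out <- r$marker[hit][order(r$display_order[hit])]
  # a state at a marker-relevant site that neither any rule nor any catalog
  # allele carries is outside the serological correspondence
  known_states <- unlist(lapply(r$required_states, parseStateTokens))
  if (length(states)) {
    seg_states <- unlist(
      catalog@alleles$variant_states[catalog@alleles$segment == segment])
    rel <- intersect(names(states), names(known_states))
    for (k in rel) {
      alphabet <- c(known_states[names(known_states) == k],
                    seg_states[names(seg_states) == k], cons[[k]])
      if (!states[[k]] %in% alphabet) undetermined <- TRUE
    }
  }
  attr(out, "undetermined") <- undetermined
  out
}

#' Gm allotype haplotype of a three-segment allele haplotype
#'
#' Combines one allele per segment into the serological Gm haplotype string,
#' written in chromosomal order G3m;G1m;G2m (IGHG3-IGHG1-IGHG2), with "(.)"
#' for an empty marker list, and attaches the Lefranc letter identifier when
#' the string is listed.
#'
#' @param catalog an [AlleleCatalog-class].
#' @param g3,g1,g2 allele names for IGHG3, IGHG1 and IGHG2.
#' @param lefranc Lefranc table from [loadLefrancIds()].
#' @param rules marker rules, used for alleles whose catalog row has no
#'   allotype annotation.
#' @return list with g3m, g1m, g2m (character vectors), canonical_string and
#'   lefranc_id (NA when unlisted).
#' @examples
#' ac <- loadAlleleCatalog()
#' gmHaplotype(ac, "IGHG3*14", "IGHG1*02", "IGHG2*03")$canonical_string
#' # "21,26,27,28;17,1;(.)"
#' @export
gmHaplotype <- function(catalog, g3, g1, g2, lefranc = loadLefrancIds(),
                        rules = NULL) {
  mk <- function(name) {
    if (is.null(rules)) alleleAllotypes(catalog, name)
    else alleleAllotypes(catalog, name, rules = rules)
  }
  m3 <- mk(g3); m1 <- mk(g1); m2 <- mk(g2)
  str <- paste(vapply(list(m3, m1, m2), function(m)
    if (length(m)) paste(m, collapse = ",") else "(.)", ""), collapse = ";")
  id <- lefranc$lefranc_id[match(str, lefranc$gm_string)]
  list(g3m = m3, g1m = m1, g2m = m2, canonical_string = str,
       lefranc_id = if (length(id) && !is.na(id)) id else NA_character_)
}

#' Aggregate allele-haplotype frequencies into Gm haplotype frequencies
#'
#' Several allele haplotypes can encode the same serological Gm haplotype;
#' this is the many-to-one aggregation that produces a Gm frequency table
#' from estimated allele-haplotype frequencies. Total frequency is conserved.
#'
#' @param haps data.frame with columns g3, g1, g2 (allele names) and
#'   frequency.
#' @param catalog an [AlleleCatalog-class].
#' @param lefranc Lefranc table.
#' @param tol tolerance on the input frequencies summing to one.
#' @return data.frame lefranc_id, gm_string, frequency (descending).
#' @export
gmFrequencies <- function(haps, catalog, lefranc = loadLefrancIds(),
                          tol = 1e-6) {
  if (any(haps$frequency < 0)) stop("data error: negative frequency")
  if (abs(sum(haps$frequency) - 1) > tol)
    stop("frequencies sum to ", sum(haps$frequency), ", not 1")
  strs <- character(nrow(haps)); ids <- character(nrow(haps))
  for (i in seq_len(nrow(haps))) {
    g <- gmHaplotype(catalog, haps$g3[i], haps$g1[i], haps$g2[i], lefranc)
    strs[i] <- g$canonical_string; ids[i] <- g$lefranc_id
  }
  agg <- tapply(haps$frequency, strs, sum)
  out <- data.frame(gm_string = names(agg), frequency = as.numeric(agg),
                    stringsAsFactors = FALSE)
  out$lefranc_id <- lefranc$lefranc_id[match(out$gm_string, lefranc$gm_string)]
  out <- out[order(-out$frequency), c("lefranc_id", "gm_string", "frequency")]
  rownames(out) <- NULL
  out
}
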