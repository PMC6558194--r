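#' Load the variant site catalog
#'
#' Reads a tab-separated catalog of exonic variant sites (one row per
#' polymorphic position; see [VariantCatalog-class] for columns). The packaged
#' catalog transcribes the published site table verbatim, including the pooled
#' alternative-allele frequencies as printed.
#'
#' @param path TSV file; defaults to the packaged catalog.
#' @return a [VariantCatalog-class].
#' @export
loadVariantCatalog <- function(path = ighgFixture("ighg_variant_sites.tsv")) {
  if (!file.exists(path)) stop("no such file: ", path)
  s <- .read_catalog_tsv(path, c("segment", "rsid", "chr14_pos", "exon",
                                 "imgt_num", "eu_num", "exonic_pos", "ref",
                                 "alt", "aa_ref", "aa_alt", "allotype_switch",
                                 "grantham", "pooled_freq"))
  for (col in c("aa_ref", "aa_alt", "allotype_switch"))
    s[[col]][!is.na(s[[col]]) & s[[col]] == ""] <- NA_character_
  s$grantham <- suppressWarnings(as.integer(s$grantham))
  s$chr14_pos <- as.integer(s$chr14_pos)
  s$exonic_pos <- as.integer(s$exonic_pos)
  s$pooled_freq <- as.numeric(s$pooled_freq)
  if (anyDuplicated(s[, c("segment", "chr14_pos")])) {
    d <- s[duplicated(s[, c("segment", "chr14_pos")]), ]
    stop("integrity error: duplicate (segment, chr14_pos): ",
         paste(d$segment, d$chr14_pos, collapse = "; "))
  }
  methods::new("VariantCatalog", sites = s)
}

#' Load the allele catalog
#'
#' Reads the allele definition table (allele name, status, Gm allotypes,
#' hinge-exon presence, variant states as "EXON:POS:BASE" tokens, observed
#' chromosome copies) together with its site-column definitions, which carry
#' the per-column consensus base.
#'
#' @param path allele TSV; defaults to the packaged catalog.
#' @param sites_path site-column TSV; defaults to the packaged table.
#' @return an [AlleleCatalog-class].
#' @export
loadAlleleCatalog <- function(path = ighgFixture("ighg_alleles.tsv"),
                              sites_path = ighgFixture("ighg_allele_sites.tsv")) {
  a <- .read_catalog_tsv(path, c("segment", "name", "status", "genbank",
                                 "allotypes", "hinge_absent", "variant_states",
                                 "copies"))
  s <- .read_catalog_tsv(sites_path, c("segment", "exon", "exonic_pos",
                                       "imgt_num", "eu_num", "consensus",
                                       "aa_annotation"))
  s$exonic_pos <- as.integer(s$exonic_pos)
  a$copies <- as.integer(a$copies)
  a$variant_states <- lapply(a$variant_states, parseStateTokens)
  methods::new("AlleleCatalog", alleles = a, sites = s)
}

#' @rdname loadAlleleCatalog
#' @param tokens ";"-joined "EXON:POS:BASE" string (or empty / NA).
#' @return `parseStateTokens` returns a named character vector
#'   (names "EXON:POS").
#' @export
parseStateTokens <- function(tokens) {
  if (is.na(tokens) || !nzchar(tokens)) return(setNames(character(0), character(0)))
  parts <- strsplit(strsplit(tokens, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  bad <- lengths(parts) != 3L
  if (any(bad)) stop("malformed state token: ", tokens)
  setNames(vapply(parts, `[`, "", 3L),
           vapply(parts, function(p) paste(p[1], p[2], sep = ":"), ""))
}

.read_catalog_tsv <- function(path, need) {
  lines <- readLines(path)
  body <- grep("^#", lines, invert = TRUE)
  header <- strsplit(lines[body[1]], "\t", fixed = TRUE)[[1]]
  if (!all(need %in% header))
    stop("parse error in ", basename(path), ": header lacks ",
         paste(setdiff(need, header), collapse = ", "))
  rows <- body[-1]
  if (length(rows) == 0L) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(header)),
                                  header), stringsAsFactors = FALSE)
    return(out[need])
  }
  cells <- strsplit(lines[rows], "\t", fixed = TRUE)
  bad <- which(lengths(cells) > length(header))
  if (length(bad))
    stop("parse error in ", basename(path), " at line ", rows[bad[1]],
         ": expected ", length(header), " fields")
  out <- as.data.frame(do.call(rbind, lapply(cells, function(x) {
    length(x) <- length(header); x
  })), stringsAsFactors = FALSE)
  names(out) <- header
  out[need]
}

#' Path of a packaged data file
#' @param file file name under the package's extdata directory.
#' @export
ighgFixture <- function(file) {
  p <- system.file("extdata", file, package = "IGHGpop", mustWork = FALSE)
  if (!nzchar(p)) stop("packaged file not found: ", file)
  p
}

#' Nucleotide differences between two alleles of the same segment
#'
#' Counts positions at which the two alleles carry different states, treating
#' the consensus base as a state; used to argue descent and gene-conversion
#' relationships between alleles. Hinge-exon presence differences (IGHG3) are
#' reported separately and are not part of the count, since a missing hinge
#' exon is not a substitution.
#'
#' @param catalog an [AlleleCatalog-class].
#' @param name1,name2 allele names (same segment).
#' @return list with `count`, `sites` (data.frame exon/exonic_pos/state1/state2)
#'   and `hinge_diff` (character vector of hinge exons present in only one).
#' @examples
#' cat2 <- loadAlleleCatalog()
#' alleleHamming(cat2, "IGHG2*03", "IGHG2*09")$count  # 3
#' @export
alleleHamming <- function(catalog, name1, name2) {
  a <- catalog@alleles
  i <- match(name1, a$name); j <- match(name2, a$name)
  if (is.na(i) || is.na(j)) stop("unknown allele name")
  if (a$segment[i] != a$segment[j])
    stop("alleles belong to different segments: ", name1, " vs ", name2)
  s1 <- a$variant_states[[i]]; s2 <- a$variant_states[[j]]
  seg <- a$segment[i]
  keys <- union(names(s1), names(s2))
  cons <- .consensus_lookup(catalog, seg)
  st1 <- ifelse(keys %in% names(s1), s1[keys], cons[keys])
  st2 <- ifelse(keys %in% names(s2), s2[keys], cons[keys])
  diff <- which(st1 != st2)
  parts <- strsplit(keys[diff], ":", fixed = TRUE)
  sites <- data.frame(
    exon = vapply(parts, `[`, "", 1L),
    exonic_pos = as.integer(vapply(parts, `[`, "", 2L)),
    state1 = unname(st1[diff]), state2 = unname(st2[diff]),
    stringsAsFactors = FALSE)
  sites <- sites[order(EXON_ORDER[sites$exon], sites$exonic_pos), , drop = FALSE]
  h1 <- .hinge_set(a$hinge_absent[i]); h2 <- .hinge_set(a$hinge_absent[j])
  list(count = length(diff), sites = sites,
       hinge_diff = sort(union(setdiff(h1, h2), setdiff(h2, h1))))
}

.hinge_set <- function(x) if (is.na(x) || !nzchar(x)) character(0) else
  strsplit(x, ";", fixed = TRUE)[[1]]

.consensus_lookup <- function(catalog, segment) {
  s <- catalog@sites[catalog@sites$segment == segment, ]
  setNames(s$consensus, paste(s$exon, s$exonic_pos, sep = ":"))
}

#' Pooled alternative-allele frequency of a variant site
#'
#' The frequency of the alternative base over all observed chromosomes,
#' recomputed from allele copy counts: (copies of alleles carrying the
#' alternative state) / (total copies in the segment).
#'
#' @param catalog an [AlleleCatalog-class].
#' @param segment,exon,exonic_pos,alt site coordinates and alternative base.
#' @export
pooledVariantFrequency <- function(catalog, segment, exon, exonic_pos, alt) {
  a <- catalog@alleles[catalog@alleles$segment == segment, ]
  total <- sum(a$copies)
  if (total == 0L) stop("undefined: zero total copies in ", segment)
  key <- paste(exon, exonic_pos, sep = ":")
  cons <- .consensus_lookup(catalog, segment)[key]
  carry <- vapply(a$variant_states, function(st) {
    state <- if (key %in% names(st)) st[[key]] else cons
    isTRUE(state == alt)
  }, NA)
  sum(a$copies[carry]) / total
}

#' Reconstruct the full coding sequence of an allele
#'
#' Substitutes the allele's alternative bases into per-exon consensus
#' sequences and concatenates the exons in coding order, omitting hinge exons
#' the allele lacks. Used to emit FASTA for the dN/dS and neutrality analyses.
#'
#' @param catalog an [AlleleCatalog-class].
#' @param name allele name.
#' @param consensus a named [Biostrings::DNAStringSet], IDs "SEGMENT|EXON"
#'   (see [loadConsensus()]).
#' @param as_character return a plain string instead of a DNAString.
#' @return the coding sequence, with an `exon_ranges` attribute
#'   (data.frame exon/start/end) when `as_character = TRUE`.
#' @export
reconstructAlleleSequence <- function(catalog, name, consensus,
                                      as_character = TRUE) {
  a <- catalog@alleles
  i <- match(name, a$name)
  if (is.na(i)) stop("unknown allele: ", name)
  seg <- a$segment[i]
  ex_all <- unique(catalog@sites$exon[catalog@sites$segment == seg])
  ids <- names(consensus)
  have <- sub("\\|.*$", "", ids) == seg
  exons <- sub("^.*\\|", "", ids[have])
  ord <- exons[order(EXON_ORDER[exons])]
  skip <- .hinge_set(a$hinge_absent[i])
  states <- a$variant_states[[i]]
  pieces <- character(0); ranges <- NULL; off <- 0L
  for (ex in ord) {
    if (ex %in% skip) next
    seq <- as.character(consensus[[which(ids == paste0(seg, "|", ex))]])
    chars <- strsplit(seq, "")[[1]]
    mine <- states[startsWith(names(states), paste0(ex, ":"))]
    if (length(mine)) {
      pos <- as.integer(sub("^.*:", "", names(mine)))
      if (any(pos > length(chars)))
        stop("coordinate error: ", name, " ", ex, ":",
             pos[pos > length(chars)][1], " beyond consensus length ",
             length(chars))
      chars[pos] <- unname(mine)
    }
    pieces <- c(pieces, paste(chars, collapse = ""))
    ranges <- rbind(ranges, data.frame(exon = ex, start = off + 1L,
                                       end = off + length(chars)))
    off <- off + length(chars)
  }
  out <- paste(pieces, collapse = "")
  if (!as_character) return(Biostrings::DNAString(out))
  attr(out, "exon_ranges") <- ranges
  out
}

#' @rdname reconstructAlleleSequence
#' @param path FASTA of per-exon consensus sequences; the packaged default is
#'   a synthetic consensus (arbitrary fixed bases away from catalog columns,
#'   catalog consensus bases at them), sufficient for coordinate-faithful
#'   sequence work without any external download.
#' @export
loadConsensus <- function(path = ighgFixture("consensus_synthetic.fasta")) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub(" .*$", "", names(x))
  x
}
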