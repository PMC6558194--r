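#' Median-joining network of alleles
#'
#' Builds a median-joining network from allele state vectors: a minimum
#' spanning network at tolerance epsilon (all links that tie with a minimum
#' spanning tree connection, plus links within epsilon of it) iteratively
#' augmented with median vectors -- per-site majority consensus of connected
#' triplets, representing possible unsampled or ancestral sequences -- until
#' stable; median vectors that end with degree one or less are pruned.
#' Duplicate state vectors are merged first, with frequencies summed. Hinge
#' presence (IGHG3) can be supplied as one extra binary character with its
#' own weight; at weight 0 alleles differing only in hinge size collapse
#' into one node, reproducing the published grouping of IGHG3*11/IGHG3*12.
#'
#' @param states matrix of character states (rows = alleles, named; columns
#'   = sites).
#' @param freq frequencies or counts per allele (node size attribute).
#' @param epsilon non-negative integer tolerance on spanning-link selection.
#' @param weights per-column weights (default 1); weight-0 columns never
#'   contribute to distances but are carried for labels.
#' @param max_rounds safety cap on median-augmentation rounds.
#' @return list with `nodes` (data.frame name, median, frequency), `edges`
#'   (data.frame from, to, distance, sites label) and `epsilon`;
#'   `mjGraph()` converts the result to an igraph object.
#' @export
medianJoining <- function(states, freq = NULL, epsilon = 0L, weights = NULL,
                          max_rounds = 10L) {
  states <- as.matrix(states)
  if (is.null(rownames(states))) rownames(states) <- paste0("h", seq_len(nrow(states)))
  if (is.null(colnames(states))) colnames(states) <- paste0("s", seq_len(ncol(states)))
  if (is.null(freq)) freq <- rep(1, nrow(states))
  if (is.null(weights)) weights <- rep(1, ncol(states))
  if (nrow(states) < 2L) stop("need at least two alleles")
  # merge duplicates under the active (weight > 0) characters
  act <- weights > 0
  key <- apply(states[, act, drop = FALSE], 1, paste, collapse = "")
  grp <- split(seq_len(nrow(states)), key)[unique(key)]
  merged <- t(vapply(grp, function(ix) states[ix[1], ], states[1, ]))
  rownames(merged) <- vapply(grp, function(ix)
    paste(rownames(states)[ix], collapse = "/"), "")
  mfreq <- vapply(grp, function(ix) sum(freq[ix]), 0)
  obs_n <- nrow(merged)
  nodes <- merged
  is_median <- rep(FALSE, obs_n)
  nfreq <- mfreq
  dist_fn <- function(a, b) sum(weights[act] * (a[act] != b[act]))
  mcount <- 0L
  for (round in seq_len(max_rounds)) {
    E <- .msn_edges(nodes, dist_fn, epsilon)
    # candidate medians from triplets connected through the current network
    adj <- vector("list", nrow(nodes))
    for (r in seq_len(nrow(E))) {
      adj[[E$i[r]]] <- c(adj[[E$i[r]]], E$j[r])
      adj[[E$j[r]]] <- c(adj[[E$j[r]]], E$i[r])
    }
    new_m <- NULL
    for (v in seq_len(nrow(nodes))) {
      nb <- adj[[v]]
      if (length(nb) < 2L) next
      for (pr in utils::combn(nb, 2L, simplify = FALSE)) {
        trip <- nodes[c(v, pr), , drop = FALSE]
        med <- apply(trip, 2, function(col) {
          tb <- table(col)
          if (max(tb) >= 2L) names(tb)[which.max(tb)] else col[1]
        })
        if (!any(apply(nodes, 1, function(x) all(x[act] == med[act]))) &&
            (is.null(new_m) ||
             !any(apply(new_m, 1, function(x) all(x[act] == med[act])))))
          new_m <- rbind(new_m, med)
      }
    }
    if (is.null(new_m)) break
    rownames(new_m) <- paste0("mv", mcount + seq_len(nrow(new_m)))
    mcount <- mcount + nrow(new_m)
    nodes <- rbind(nodes, new_m)
    is_median <- c(is_median, rep(TRUE, nrow(new_m)))
    nfreq <- c(nfreq, rep(0, nrow(new_m)))
  }
  # prune medians of degree <= 1, re-spanning until stable
  repeat {
    E <- .msn_edges(nodes, dist_fn, epsilon)
    deg <- tabulate(c(E$i, E$j), nbins = nrow(nodes))
    drop <- which(is_median & deg <= 1L)
    if (!length(drop)) break
    keep <- setdiff(seq_len(nrow(nodes)), drop)
    nodes <- nodes[keep, , drop = FALSE]
    is_median <- is_median[keep]; nfreq <- nfreq[keep]
  }
  lab <- vapply(seq_len(nrow(E)), function(r) {
    a <- nodes[E$i[r], ]; b <- nodes[E$j[r], ]
    paste(colnames(nodes)[act & (a != b)], collapse = ";")
  }, "")
  list(nodes = data.frame(name = rownames(nodes), median = is_median,
                          frequency = nfreq, stringsAsFactors = FALSE),
       edges = data.frame(from = rownames(nodes)[E$i],
                          to = rownames(nodes)[E$j],
                          distance = E$d, sites = lab,
                          stringsAsFactors = FALSE),
       epsilon = epsilon)
}

# minimum spanning network: link (u,v) is kept iff d(u,v) <= delta(u,v) +
# epsilon, where delta is the Kruskal connection level (the largest step on
# the minimax path); at epsilon = 0 this includes every link of every MST
.msn_edges <- function(nodes, dist_fn, epsilon) {
  n <- nrow(nodes)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    D[i, j] <- D[j, i] <- dist_fn(nodes[i, ], nodes[j, ])
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  lv <- sort(unique(D[upper.tri(D)]))
  conn <- matrix(Inf, n, n)
  for (d in lv) {
    at <- which(upper.tri(D) & D == d, arr.ind = TRUE)
    # connection level is evaluated before merging anything at this level
    roots <- vapply(seq_len(n), function(x) find(x), 0L)
    for (r in seq_len(nrow(at))) {
      i <- at[r, 1]; j <- at[r, 2]
      if (roots[i] != roots[j]) conn[i, j] <- conn[j, i] <- d
    }
    for (r in seq_len(nrow(at))) {
      i <- find(at[r, 1]); j <- find(at[r, 2])
      if (i != j) parent[i] <- j
    }
    # components connected at this level: pairs joined later get level > d
    roots2 <- vapply(seq_len(n), function(x) find(x), 0L)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      if (!is.finite(conn[i, j]) && roots2[i] == roots2[j])
        conn[i, j] <- conn[j, i] <- d
  }
  keep <- which(upper.tri(D) & D <= conn + epsilon, arr.ind = TRUE)
  data.frame(i = keep[, 1], j = keep[, 2], d = D[keep])
}

#' @rdname medianJoining
#' @param net result of `medianJoining`.
#' @param pop_freq optional data.frame allele, population, frequency added as
#'   node attributes (per-population frequency columns).
#' @export
mjGraph <- function(net, pop_freq = NULL) {
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = net$nodes)
  if (!is.null(pop_freq)) {
    for (p in unique(pop_freq$population)) {
      v <- setNames(rep(0, nrow(net$nodes)), net$nodes$name)
      pf <- pop_freq[pop_freq$population == p, ]
      for (r in seq_len(nrow(pf))) {
        hit <- vapply(strsplit(net$nodes$name, "/", fixed = TRUE),
                      function(nm) pf$allele[r] %in% nm, NA)
        v[hit] <- v[hit] + pf$frequency[r]
      }
      g <- igraph::set_vertex_attr(g, paste0("freq_", p), value = unname(v))
    }
  }
  g
}

#' @rdname medianJoining
#' @param file output path; format from extension (".graphml" or ".dot").
#' @export
writeNetwork <- function(net, file, pop_freq = NULL) {
  g <- mjGraph(net, pop_freq)
  fmt <- if (grepl("\\.dot$", file)) "dot" else "graphml"
  igraph::write_graph(g, file, format = fmt)
  invisible(file)
}

#' State vectors of catalog alleles for network construction
#'
#' Builds the character matrix [medianJoining()] consumes from the allele
#' catalog of one segment: one column per allele-table site column, plus (for
#' IGHG3) one binary hinge-pattern character per variable hinge exon, given
#' weight `hinge_weight` (0 by default, so hinge size alone does not separate
#' nodes).
#'
#' @param catalog an [AlleleCatalog-class].
#' @param segment segment name.
#' @param observed_only drop zero-copy alleles.
#' @param hinge_weight weight of the hinge-presence characters.
#' @return list states, freq, weights.
#' @export
alleleStateMatrix <- function(catalog, segment, observed_only = FALSE,
                              hinge_weight = 0) {
  prof <- .allele_profiles(catalog, segment)
  a <- catalog@alleles[catalog@alleles$segment == segment, ]
  if (observed_only) {
    prof <- prof[a$copies > 0L, , drop = FALSE]
    a <- a[a$copies > 0L, , drop = FALSE]
  }
  hinge_cols <- grepl("^H.*:0$", colnames(prof))
  site_cols <- !hinge_cols & !grepl("^H", colnames(prof))
  hs_cols <- !hinge_cols & grepl("^H", colnames(prof))  # hinge substitutions
  w <- c(rep(1, sum(site_cols)), rep(1, sum(hs_cols)),
         rep(hinge_weight, sum(hinge_cols)))
  states <- cbind(prof[, site_cols, drop = FALSE],
                  prof[, hs_cols, drop = FALSE],
                  prof[, hinge_cols, drop = FALSE])
  list(states = states, freq = a$copies, weights = w)
}
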