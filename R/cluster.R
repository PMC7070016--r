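# Clustering of retained hits into communities (criterion 1 within one pair
# of young clades) and hit groups (criteria 1 + 2, complete linkage), each
# group representing one direct or indirect transfer between two clades.

# ---- identity evidence ----------------------------------------------------

#' Build a pairwise-identity lookup from identity tables and hits
#'
#' Collects the maximum recorded percent identity for every copy pair seen in
#' the within-clade identity table and (optionally) the hit table; alignments
#' shorter than `min_aln` are ignored.  Used by criterion 1, copy retrieval
#' and the explanatory-transfer procedure.
#'
#' @param identities identity table (`copy1`, `copy2`, `pid`, `aln_len`).
#' @param hits optional hit table contributing cross-clade identities.
#' @param min_aln minimum alignment length in bp (default 100).
#' @return an environment mapping "id1|id2" (ids sorted) to max pID.
#' @export
identity_lookup <- function(identities, hits = NULL, min_aln = 100) {
  k1 <- character(0); k2 <- character(0); pv <- numeric(0)
  if (nrow(identities) > 0L) {
    ok <- identities$aln_len >= min_aln
    k1 <- c(k1, identities$copy1[ok]); k2 <- c(k2, identities$copy2[ok])
    pv <- c(pv, identities$pid[ok])
  }
  if (!is.null(hits) && nrow(hits) > 0L) {
    ok <- hits$length >= min_aln
    k1 <- c(k1, hits$qseqid[ok]); k2 <- c(k2, hits$sseqid[ok])
    pv <- c(pv, hits$pident[ok])
  }
  env <- new.env(hash = TRUE, parent = emptyenv())
  if (length(k1) > 0L) {
    key <- paste0(pmin(k1, k2), "|", pmax(k1, k2))
    ord <- order(key, -pv)          # max pID per unordered pair
    first <- !duplicated(key[ord])
    keys <- key[ord][first]
    vals <- pv[ord][first]
    env$..keys <- keys
    env$..values <- vals
    # per-key entries for cheap scalar/small lookups
    list2env(as.list(stats::setNames(vals, keys)), envir = env)
  } else {
    env$..keys <- character(0)
    env$..values <- numeric(0)
  }
  env
}

# vectorized lookup; NA where no alignment is recorded; identical ids -> 100.
# Small queries go through the hashed environment; large ones through one
# match() against the key vector.
lookup_pid <- function(env, c1, c2) {
  key <- paste0(pmin(c1, c2), "|", pmax(c1, c2))
  if (length(key) > 200L) {
    out <- env$..values[match(key, env$..keys)]
  } else {
    out <- unlist(mget(key, envir = env, ifnotfound = NA_real_),
                  use.names = FALSE)
  }
  out[c1 == c2] <- 100
  out
}

# ---- preclustering --------------------------------------------------------

#' Single-linkage preclustering of hits sharing a TE copy
#'
#' Connects any two hits sharing a copy, takes connected components, and
#' keeps at most `max_hits` hits per component per species pair, favoring
#' hits covering the longest protein-coding regions (largest `n_codons`,
#' ties by score then hit id).
#'
#' @param hits retained hit table (needs `n_codons`).
#' @param max_hits cap per cluster per species pair (default 200).
#' @return `hits` subset with a `precluster` column.
#' @export
precluster <- function(hits, max_hits = 200) {
  if (nrow(hits) == 0L) {
    hits$precluster <- integer(0)
    return(hits)
  }
  ids <- unique(c(hits$qseqid, hits$sseqid))
  g <- igraph::graph_from_edgelist(
    cbind(match(hits$qseqid, ids), match(hits$sseqid, ids)),
    directed = FALSE)
  comp <- igraph::components(g)$membership
  hits$precluster <- comp[match(hits$qseqid, ids)]

  spkey <- ifelse(hits$qspecies < hits$sspecies,
                  paste(hits$qspecies, hits$sspecies),
                  paste(hits$sspecies, hits$qspecies))
  grp <- paste(hits$precluster, spkey)
  ord <- order(grp, -hits$n_codons, -hits$bitscore, hits$hit_id)
  rank <- stats::ave(seq_along(ord), grp[ord], FUN = seq_along)
  keep <- ord[rank <= max_hits]
  out <- hits[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- criterion 1 on hits --------------------------------------------------

#' Criterion 1 for a pair of hits between the same two clades
#'
#' Two hits can reflect the same transfer when, in at least one clade, the
#' within-clade identity between the two hits' copies in that clade exceeds
#' the between-clade identity, taken as `min(pID(h1), pID(h2))`.  Copies
#' without a recorded within-clade alignment contribute no link; a copy
#' shared by both hits counts as identity 100.
#'
#' @param a1,a2 copy ids of the two hits in the first clade; `b1`, `b2` in
#'   the second; `p1`, `p2` the hits' pIDs (all vectorized).
#' @param idt identity lookup from [identity_lookup()].
#' @return logical vector.
#' @export
criterion1_hits <- function(a1, a2, b1, b2, p1, p2, idt) {
  ref <- pmin(p1, p2)
  wa <- lookup_pid(idt, a1, a2)
  wb <- lookup_pid(idt, b1, b2)
  (!is.na(wa) & wa > ref) | (!is.na(wb) & wb > ref)
}

# ---- communities ----------------------------------------------------------

#' Delineate hit communities within each pair of young clades
#'
#' First clustering iteration: hits of one superfamily between the same two
#' clades younger than `young_clade_age` form a graph with criterion-1
#' passes as edges; communities are the modularity-maximizing partition of
#' that graph (greedy agglomerative, deterministic).  Singleton communities
#' are allowed.
#'
#' @param hits retained (preclustered) hit table.
#' @param idt identity lookup.
#' @param tree `species_tree`.
#' @param young_clade_age clade age threshold (default 40 My).
#' @return list with `hits` (gaining `community` ids) and `communities`
#'   (data frame of per-community summaries: sides, sizes, mean Ks/pID).
#' @export
build_communities <- function(hits, idt, tree, young_clade_age = 40) {
  if (nrow(hits) == 0L) {
    hits$community <- character(0)
    return(list(hits = hits, communities = community_summaries(hits, tree)))
  }
  part <- clades_younger_than(tree, young_clade_age)
  cl_q <- part$clade[hits$qspecies]
  cl_s <- part$clade[hits$sspecies]
  # orient each hit's clade pair deterministically
  cl_a <- pmin(cl_q, cl_s)
  cl_b <- pmax(cl_q, cl_s)
  hits$clade_a <- cl_a
  hits$clade_b <- cl_b
  hits$copy_a <- ifelse(cl_q <= cl_s, hits$qseqid, hits$sseqid)
  hits$copy_b <- ifelse(cl_q <= cl_s, hits$sseqid, hits$qseqid)

  block <- paste(hits$superfamily, cl_a, cl_b)
  hits$community <- NA_character_
  for (bl in unique(block)) {
    ii <- which(block == bl)
    n <- length(ii)
    memb <- if (n == 1L) 1L else {
      pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
      pass <- criterion1_hits(hits$copy_a[ii[pr[, 1L]]],
                              hits$copy_a[ii[pr[, 2L]]],
                              hits$copy_b[ii[pr[, 1L]]],
                              hits$copy_b[ii[pr[, 2L]]],
                              hits$pident[ii[pr[, 1L]]],
                              hits$pident[ii[pr[, 2L]]], idt)
      g <- igraph::make_empty_graph(n, directed = FALSE)
      if (any(pass))
        g <- igraph::add_edges(g, t(pr[pass, , drop = FALSE]))
      greedy_modularity_membership(g)
    }
    hits$community[ii] <- sprintf("%s/cm%02d", bl, memb)
  }
  list(hits = hits, communities = community_summaries(hits, tree))
}

# greedy agglomerative modularity partition, deterministic: cut the merge
# dendrogram at the level of maximal modularity, ties toward fewer
# communities (a clique is never split)
greedy_modularity_membership <- function(g) {
  n <- igraph::vcount(g)
  if (igraph::ecount(g) == 0L) return(seq_len(n))
  fg <- igraph::cluster_fast_greedy(g)
  tr <- fg$modularity            # modularity after each merge; level i has
  ks <- n - seq_along(tr) + 1L   # n - i + 1 communities
  ncomp <- igraph::components(g)$no
  okk <- ks >= ncomp
  tr <- tr[okk]; ks <- ks[okk]
  best <- which(tr >= max(tr) - 1e-12)
  best_k <- min(ks[best])        # ties toward fewer communities
  igraph::cut_at(fg, no = best_k)
}

community_summaries <- function(hits, tree) {
  if (nrow(hits) == 0L || is.null(hits$community))
    return(data.frame(community = character(0), superfamily = character(0),
                      clade_a = character(0), clade_b = character(0),
                      n_hits = integer(0), mean_ks = numeric(0),
                      mean_pid = numeric(0), stringsAsFactors = FALSE))
  sp <- split(seq_len(nrow(hits)), hits$community)
  data.frame(
    community = names(sp),
    superfamily = vapply(sp, function(i) hits$superfamily[i[1L]], ""),
    clade_a = vapply(sp, function(i) hits$clade_a[i[1L]], ""),
    clade_b = vapply(sp, function(i) hits$clade_b[i[1L]], ""),
    n_hits = lengths(sp),
    mean_ks = vapply(sp, function(i) mean(hits$ks[i]), 0),
    mean_pid = vapply(sp, function(i) mean(hits$pident[i]), 0),
    row.names = NULL, stringsAsFactors = FALSE)
}

# species sets of a community's two sides
community_sides <- function(hits, community) {
  ii <- which(hits$community == community)
  qa <- ifelse(hits$copy_a[ii] == hits$qseqid[ii],
               hits$qspecies[ii], hits$sspecies[ii])
  qb <- ifelse(hits$copy_a[ii] == hits$qseqid[ii],
               hits$sspecies[ii], hits$qspecies[ii])
  list(a = sort(unique(qa)), b = sort(unique(qb)),
       copies_a = sort(unique(hits$copy_a[ii])),
       copies_b = sort(unique(hits$copy_b[ii])))
}

# orientation of c2's sides relative to c1's: pair the sides so that the
# summed MRCA ages of the two side unions are smallest; NULL when either
# orientation mixes the sides (non-disjoint unions both ways)
side_orientation <- function(s1, s2, tree) {
  age_of <- function(sp) {
    sp <- unique(sp)
    if (length(sp) == 1L) return(0)
    tree$age[ape::getMRCA(tree$phylo, sp)]
  }
  ok_straight <- length(intersect(c(s1$a, s2$a), c(s1$b, s2$b))) == 0L
  ok_swapped  <- length(intersect(c(s1$a, s2$b), c(s1$b, s2$a))) == 0L
  if (!ok_straight && !ok_swapped) return(NULL)
  if (ok_straight && ok_swapped) {
    cost_s <- age_of(c(s1$a, s2$a)) + age_of(c(s1$b, s2$b))
    cost_w <- age_of(c(s1$a, s2$b)) + age_of(c(s1$b, s2$a))
    if (cost_w < cost_s) "swapped" else "straight"
  } else if (ok_straight) "straight" else "swapped"
}

# ---- criteria on community pairs -----------------------------------------

#' Criterion 1 for a pair of communities
#'
#' Passed when at least `frac` (default 5%) of all cross-community hit pairs
#' pass [criterion1_hits()], or — the fragmentation fallback — when the two
#' copy sets share no recorded nucleotide homology and less than 100 bp of
#' protein-anchored coding region, in which case they may be non-overlapping
#' parts of one fragmented TE.
#'
#' @param hits hit table with `community` assignments; @param c1,c2
#'   community ids; @param idt identity lookup; @param orientation
#'   `"straight"`/`"swapped"` pairing of the sides; @param frames per-copy
#'   frame annotations (for the protein-overlap fallback); @param frac pass
#'   fraction.
#' @return TRUE/FALSE.
#' @export
criterion1_communities <- function(hits, c1, c2, idt,
                                   orientation = "straight",
                                   frames = NULL, frac = 0.05) {
  i1 <- which(hits$community == c1)
  i2 <- which(hits$community == c2)
  pr <- expand.grid(i = i1, j = i2)
  a2 <- if (orientation == "straight") hits$copy_a[pr$j] else hits$copy_b[pr$j]
  b2 <- if (orientation == "straight") hits$copy_b[pr$j] else hits$copy_a[pr$j]
  pass <- criterion1_hits(hits$copy_a[pr$i], a2, hits$copy_b[pr$i], b2,
                          hits$pident[pr$i], hits$pident[pr$j], idt)
  if (mean(pass) >= frac) return(TRUE)

  # fragmentation fallback
  cs1 <- unique(c(hits$qseqid[i1], hits$sseqid[i1]))
  cs2 <- unique(c(hits$qseqid[i2], hits$sseqid[i2]))
  grid <- expand.grid(x = cs1, y = cs2, stringsAsFactors = FALSE)
  any_nt <- any(!is.na(lookup_pid(idt, grid$x, grid$y)) &
                  !(grid$x == grid$y))
  if (any(grid$x == grid$y)) any_nt <- TRUE  # shared copies are homology
  if (any_nt) return(FALSE)
  overlap <- protein_overlap_bp(frames, cs1, cs2)
  overlap < 100
}

# shared protein-anchored region (bp) between two copy sets, from frame
# segments carrying `prot_start` (codon offset on the anchor protein);
# segments without protein coordinates are compared on copy coordinates
protein_overlap_bp <- function(frames, cs1, cs2) {
  if (is.null(frames)) return(Inf)
  span <- function(ids) {
    segs <- do.call(rbind, lapply(ids, function(id) {
      fr <- frames[[id]]
      if (is.null(fr) || nrow(fr) == 0L) return(NULL)
      if (!is.null(fr$prot_start))
        data.frame(s = fr$prot_start * 3L,
                   e = fr$prot_start * 3L + (fr$end - fr$start))
      else data.frame(s = fr$start, e = fr$end)
    }))
    segs
  }
  s1 <- span(cs1); s2 <- span(cs2)
  if (is.null(s1) || is.null(s2)) return(0)
  tot <- 0
  for (i in seq_len(nrow(s1))) for (j in seq_len(nrow(s2)))
    tot <- max(tot, min(s1$e[i], s2$e[j]) - max(s1$s[i], s2$s[j]))
  max(tot, 0)
}

#' Criterion 2 for a pair of communities
#'
#' The average Ks of each community's hits must be compatible with a single
#' transfer predating every within-clade speciation the merged event would
#' straddle: on every side where the two communities involve different
#' species lineages, both communities' mean Ks must be at least the 0.5%
#' quantile of the core-gene Ks distribution of the sister-clade pair
#' spanning those lineages.  Sides with identical species sets pass
#' vacuously.
#'
#' @param hits,c1,c2,orientation as in [criterion1_communities()].
#' @param dist_for function(sp1, sp2) returning the `ks_distribution` of the
#'   sister-clade pair of two species.
#' @param tree `species_tree`; @param core_quantile quantile level.
#' @return TRUE/FALSE.
#' @export
criterion2_communities <- function(hits, c1, c2, orientation, dist_for,
                                   tree, core_quantile = 0.005) {
  s1 <- community_sides(hits, c1)
  s2 <- community_sides(hits, c2)
  if (orientation == "swapped") s2 <- list(a = s2$b, b = s2$a)
  m1 <- mean(hits$ks[hits$community == c1])
  m2 <- mean(hits$ks[hits$community == c2])
  sides <- list(list(s1$a, s2$a), list(s1$b, s2$b))
  for (sd in sides) {
    if (setequal(sd[[1L]], sd[[2L]])) next     # no straddled speciation
    # a lineage split the merged transfer must predate: one species from
    # each community's side, taken across the symmetric difference
    rep2 <- setdiff(sd[[2L]], sd[[1L]])[1L]
    rep1 <- sd[[1L]][1L]
    if (is.na(rep2)) {
      rep2 <- setdiff(sd[[1L]], sd[[2L]])[1L]
      rep1 <- sd[[2L]][1L]
    }
    if (is.na(rep2) || rep1 == rep2) next
    q <- dist_for(rep1, rep2)$quantile(core_quantile)
    if (!(m1 >= q && m2 >= q)) return(FALSE)
  }
  TRUE
}

# ---- hit groups -----------------------------------------------------------

#' Complete-linkage clustering of communities into hit groups
#'
#' Evaluates criteria 1 and 2 on every pair of same-superfamily communities
#' and agglomerates with complete linkage: a merge is allowed only when
#' every community pair across the two groups passes both criteria.  Merges
#' are attempted in order of decreasing mean hit identity (ties by community
#' id), so the partition is deterministic.
#'
#' @param com_hits list from [build_communities()] (`hits` + `communities`).
#' @param idt identity lookup; @param dist_for distribution getter (see
#'   [criterion2_communities()]); @param tree `species_tree`;
#' @param frames per-copy frame annotations; @param frac criterion-1 pass
#'   fraction; @param core_quantile criterion-2 quantile.
#' @return list with `groups` (data frame community -> group) and
#'   `pass` (the symmetric pass matrix used, community x community).
#' @export
hit_groups <- function(com_hits, idt, dist_for, tree, frames = NULL,
                       frac = 0.05, core_quantile = 0.005) {
  hits <- com_hits$hits
  com <- com_hits$communities
  n <- nrow(com)
  pass <- matrix(FALSE, n, n, dimnames = list(com$community, com$community))
  diag(pass) <- TRUE
  ori <- matrix(NA_character_, n, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (com$superfamily[i] != com$superfamily[j]) next
      s1 <- community_sides(hits, com$community[i])
      s2 <- community_sides(hits, com$community[j])
      o <- side_orientation(s1, s2, tree)
      if (is.null(o)) next
      ori[i, j] <- ori[j, i] <- o
      ok <- criterion1_communities(hits, com$community[i], com$community[j],
                                   idt, o, frames, frac) &&
        criterion2_communities(hits, com$community[i], com$community[j],
                               o, dist_for, tree, core_quantile)
      pass[i, j] <- pass[j, i] <- ok
    }
  }

  # agglomerative complete linkage, deterministic merge order
  grp <- seq_len(n)
  if (n > 1L) {
    pairs <- which(upper.tri(pass), arr.ind = TRUE)
    ordp <- pairs[order(-(com$mean_pid[pairs[, 1L]] +
                            com$mean_pid[pairs[, 2L]]),
                        pairs[, 1L], pairs[, 2L]), , drop = FALSE]
    repeat {
      merged <- FALSE
      for (r in seq_len(nrow(ordp))) {
        gi <- grp[ordp[r, 1L]]; gj <- grp[ordp[r, 2L]]
        if (gi == gj) next
        mi <- which(grp == gi); mj <- which(grp == gj)
        if (all(pass[mi, mj])) {
          grp[mj] <- gi
          merged <- TRUE
          break
        }
      }
      if (!merged) break
    }
  }
  com$group <- sprintf("g%03d", match(grp, sort(unique(grp))))
  list(groups = com, pass = pass, orientation = ori)
}
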