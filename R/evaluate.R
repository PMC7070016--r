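# Post-clustering evaluation of hit groups: retrieval and attribution of
# unclustered copies, minimum copy counts (anti-contamination) and rejection
# of Ks-truncated groups (anti-vertical-inheritance).

#' Assemble hit-group objects from a community grouping
#'
#' Collects, for every hit group, its member hits and copies per clade side
#' (orienting each community against the group's accumulated sides), the Ks
#' values of member hits, and the largest per-hit Ks selection threshold.
#'
#' @param hits hit table with `community` assignments and `theta`.
#' @param groups_df community-to-group table from [hit_groups()].
#' @param tree `species_tree`.
#' @return named list of `hit_group` objects (id, superfamily, communities,
#'   hit ids, `copies_a`/`copies_b`, `species_a`/`species_b`, `ks`, `pid`,
#'   `theta`).
#' @export
assemble_groups <- function(hits, groups_df, tree) {
  out <- list()
  for (gid in sort(unique(groups_df$group))) {
    coms <- sort(groups_df$community[groups_df$group == gid])
    sideA <- sideB <- character(0)
    copA <- copB <- character(0)
    hit_ids <- character(0)
    for (cm in coms) {
      s <- community_sides(hits, cm)
      o <- if (length(sideA) == 0L) "straight" else
        side_orientation(list(a = sideA, b = sideB), s, tree)
      if (is.null(o)) o <- "straight"  # degenerate; sides kept as-is
      if (o == "swapped") s <- list(a = s$b, b = s$a,
                                    copies_a = s$copies_b,
                                    copies_b = s$copies_a)
      sideA <- sort(unique(c(sideA, s$a)))
      sideB <- sort(unique(c(sideB, s$b)))
      copA <- sort(unique(c(copA, s$copies_a)))
      copB <- sort(unique(c(copB, s$copies_b)))
      hit_ids <- c(hit_ids, hits$hit_id[hits$community == cm])
    }
    ii <- match(hit_ids, hits$hit_id)
    out[[gid]] <- structure(list(
      id = gid,
      superfamily = hits$superfamily[ii[1L]],
      communities = coms,
      hit_ids = hit_ids,
      copies_a = copA, copies_b = copB,
      species_a = sideA, species_b = sideB,
      ks = hits$ks[ii], pid = hits$pident[ii],
      theta = max(hits$theta[ii])), class = "hit_group")
  }
  out
}

#' @export
print.hit_group <- function(x, ...) {
  cat(sprintf(
    "Hit group %s (%s): %d hits, %d communities, %d+%d copies, mean Ks %.3f\n",
    x$id, x$superfamily, length(x$hit_ids), length(x$communities),
    length(x$copies_a), length(x$copies_b), mean(x$ks)))
  invisible(x)
}

#' Retrieve unclustered copies and attribute them to the group's clades
#'
#' A candidate copy (same superfamily, from a species of the group, not a
#' member, with recorded alignments of at least 100 bp to member copies) is
#' attributed to clade A when its average identity to the group's clade-A
#' copies exceeds the group's average cross-clade identity (the mean pID of
#' its hits); strictly — ties are not attributed.  A copy qualifying for
#' both clades goes to the side with the higher average.
#'
#' @param g `hit_group`; @param copies copy table; @param idt identity
#'   lookup built with `min_aln = 100`.
#' @return `g` with `retrieved_a`, `retrieved_b` copy-id vectors added.
#' @export
retrieve_and_attribute <- function(g, copies, idt) {
  cross_mean <- mean(g$pid)
  member <- c(g$copies_a, g$copies_b)
  cand <- copies$copy_id[copies$superfamily == g$superfamily &
                           copies$species %in% c(g$species_a, g$species_b) &
                           !(copies$copy_id %in% member)]
  ra <- rb <- character(0)
  for (cp in cand) {
    mA <- lookup_pid(idt, rep(cp, length(g$copies_a)), g$copies_a)
    mB <- lookup_pid(idt, rep(cp, length(g$copies_b)), g$copies_b)
    mA <- if (all(is.na(mA))) NA_real_ else mean(mA, na.rm = TRUE)
    mB <- if (all(is.na(mB))) NA_real_ else mean(mB, na.rm = TRUE)
    okA <- !is.na(mA) && mA > cross_mean
    okB <- !is.na(mB) && mB > cross_mean
    if (okA && okB) {
      if (mA >= mB) ra <- c(ra, cp) else rb <- c(rb, cp)
    } else if (okA) ra <- c(ra, cp)
    else if (okB) rb <- c(rb, cp)
  }
  g$retrieved_a <- ra
  g$retrieved_b <- rb
  g
}

#' Minimum copy-count filter (anti-contamination)
#'
#' Keep iff each clade holds at least `min_incl` copies counting retrieved
#' ones and at least `min_excl` copies not counting them.
#'
#' @param g evaluated `hit_group` (after [retrieve_and_attribute()]).
#' @param min_incl,min_excl thresholds (defaults 5 and 2).
#' @return TRUE/FALSE.
#' @export
copy_count_filter <- function(g, min_incl = 5, min_excl = 2) {
  na <- length(g$copies_a); nb <- length(g$copies_b)
  ra <- length(g$retrieved_a); rb <- length(g$retrieved_b)
  (na + ra) >= min_incl && (nb + rb) >= min_incl &&
    na >= min_excl && nb >= min_excl
}

#' Ks histogram classes
#'
#' Class boundaries and counts as delineated by `hist()`: Sturges' class
#' count on "nice" rounded break points covering the range.
#'
#' @param ks_values numeric vector (non-empty).
#' @return list with `breaks` and `counts`.
#' @export
ks_histogram <- function(ks_values) {
  if (length(ks_values) == 0L)
    stop("cannot build Ks classes from an empty vector")
  h <- graphics::hist(ks_values, plot = FALSE)
  list(breaks = h$breaks, counts = h$counts)
}

#' Ks-truncation filter (anti-vertical-inheritance)
#'
#' A group whose hit Ks distribution looks right-truncated by the selection
#' threshold may be the slow tail of vertical divergence.  Keep iff the
#' modal Ks class holds at least `gap` more hits than the rightmost
#' non-empty class, and the maximum Ks is at most `theta - margin` (theta =
#' the Ks threshold used at hit selection).
#'
#' @param g `hit_group`; @param gap required mode-vs-rightmost excess
#'   (default 20); @param margin distance below theta (default 0.2).
#' @return TRUE/FALSE.
#' @export
truncation_filter <- function(g, gap = 20, margin = 0.2) {
  h <- ks_histogram(g$ks)
  nz <- which(h$counts > 0)
  modal <- max(h$counts)
  rightmost <- h$counts[nz[length(nz)]]
  modal >= rightmost + gap && max(g$ks) <= g$theta - margin
}

#' Evaluate all hit groups
#'
#' Runs retrieval, the copy-count filter and the truncation filter on each
#' group; both filters are pure predicates, so their order is immaterial.
#'
#' @param groups list of `hit_group`s; @param copies copy table;
#' @param idt identity lookup; @param config [htt_config()].
#' @return list with `groups` (augmented, surviving), `audit` (one row per
#'   input group: counts, modal/rightmost, max Ks, theta, decisions).
#' @export
evaluate_groups <- function(groups, copies, idt, config = htt_config()) {
  audit <- list()
  kept <- list()
  for (g in groups) {
    g <- retrieve_and_attribute(g, copies, idt)
    ok_count <- copy_count_filter(g, config$min_copies_incl,
                                  config$min_copies_excl)
    h <- ks_histogram(g$ks)
    nz <- which(h$counts > 0)
    ok_trunc <- truncation_filter(g, config$trunc_gap, config$trunc_margin)
    audit[[g$id]] <- data.frame(
      group = g$id, superfamily = g$superfamily,
      n_hits = length(g$hit_ids),
      copies_a = length(g$copies_a), copies_b = length(g$copies_b),
      retrieved_a = length(g$retrieved_a), retrieved_b = length(g$retrieved_b),
      modal = max(h$counts), rightmost = h$counts[nz[length(nz)]],
      max_ks = max(g$ks), theta = g$theta,
      pass_counts = ok_count, pass_truncation = ok_trunc,
      kept = ok_count && ok_trunc, stringsAsFactors = FALSE)
    if (ok_count && ok_trunc) kept[[g$id]] <- g
  }
  list(groups = kept,
       audit = if (length(audit) > 0L) do.call(rbind, c(audit, list(make.row.names = FALSE)))
       else data.frame())
}
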