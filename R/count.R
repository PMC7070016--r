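# Reduction of hit groups to a minimal set of independent HTT events by the
# reliability-ordered explanatory-transfer procedure.

#' Reliability score of a hit group
#'
#' For every member copy, the highest pID among the group's hits involving
#' it; these maxima are summed per clade and the lower of the two sums is
#' the score.  Groups with low scores are the most likely indirect
#' transfers and are processed first.
#'
#' @param g `hit_group`; @param hits hit table.
#' @return numeric score.
#' @export
reliability <- function(g, hits) {
  hh <- hits[match(g$hit_ids, hits$hit_id), ]
  best <- tapply(c(hh$pident, hh$pident), c(hh$copy_a, hh$copy_b), max)
  sum_a <- sum(best[g$copies_a], na.rm = TRUE)
  sum_b <- sum(best[g$copies_b], na.rm = TRUE)
  min(sum_a, sum_b)
}

# clade relation used by the explanatory-transfer conditions: C qualifies
# relative to A when the species sets are equal, nested, or encompassing
clade_compatible <- function(cladeC, cladeA) {
  all(cladeC %in% cladeA) || all(cladeA %in% cladeC)
}

#' Can one copy of a focal transfer be explained by a candidate transfer?
#'
#' Copy A (from clade A of the focal group) is explained by the candidate
#' group when (i) the candidate involves a clade C equal to, nested in, or
#' encompassing clade A, and (ii) copy A shows higher recorded similarity to
#' some clade-C copy of the candidate than it does to at least one clade-B
#' copy of the focal group it has a recorded similarity with.
#'
#' @param copy_a copy id; @param cladeA species set of the focal side
#'   holding the copy; @param focal_b_copies clade-B copies of the focal
#'   group; @param candidate `hit_group` (evaluated); @param idt identity
#'   lookup (hits + identity table).
#' @return TRUE/FALSE.
#' @export
copy_explained <- function(copy_a, cladeA, focal_b_copies, candidate, idt) {
  sides <- list(list(sp = candidate$species_a,
                     cp = c(candidate$copies_a, candidate$retrieved_a)),
                list(sp = candidate$species_b,
                     cp = c(candidate$copies_b, candidate$retrieved_b)))
  simB <- lookup_pid(idt, rep(copy_a, length(focal_b_copies)),
                     focal_b_copies)
  if (all(is.na(simB))) return(FALSE)
  weakest <- min(simB, na.rm = TRUE)
  for (sd in sides) {
    if (!clade_compatible(sd$sp, cladeA)) next
    cp <- setdiff(sd$cp, copy_a)
    if (length(cp) == 0L) next
    simC <- lookup_pid(idt, rep(copy_a, length(cp)), cp)
    if (any(!is.na(simC) & simC > weakest)) return(TRUE)
  }
  FALSE
}

#' Count independent HTT events among evaluated hit groups
#'
#' Processes groups in order of increasing [reliability()] (ties by group
#' id).  For each focal group, requirement 1 holds when every species of the
#' focal group has at least one copy explained (per [copy_explained()]) by
#' some group still in the explanatory pool, and at least two distinct pool
#' groups serve as explanatory transfers overall.  An explanatory group
#' whose removal would break requirement 1 is flagged "required" and can no
#' longer be explained itself.  A focal group complying with requirement 1
#' and not flagged required is "explained" and leaves the pool; all groups
#' never explained are the independent transfers.
#'
#' @param groups named list of evaluated `hit_group`s; @param hits hit
#'   table; @param idt identity lookup; @param species_of named character
#'   vector mapping copy ids to species.
#' @param decreasing process in order of decreasing reliability instead
#'   (used to probe the order sensitivity of the greedy procedure).
#' @return data frame per group: `group`, `reliability`, `independent`,
#'   `explained_by` (comma string), `required_for` (comma string),
#'   `rep_species_a`, `rep_species_b` (the [representative_pair()]).
#' @export
count_independent <- function(groups, hits, idt, species_of,
                              decreasing = FALSE) {
  ids <- names(groups)
  n <- length(ids)
  rel <- vapply(groups, reliability, 0, hits = hits)
  ord <- ids[order(rel[ids], ids)]
  if (decreasing) ord <- rev(ord)

  pool <- ids
  required <- character(0)
  required_for <- stats::setNames(rep("", n), ids)
  explained_by <- stats::setNames(rep("", n), ids)
  explained <- stats::setNames(rep(FALSE, n), ids)

  for (focal in ord) {
    g <- groups[[focal]]
    cand_ids <- setdiff(pool, focal)
    # explanatory groups usable per species of the focal transfer
    species <- list()
    sides <- list(list(sp = g$species_a, own = g$species_a,
                       cp = g$copies_a, other = g$copies_b),
                  list(sp = g$species_b, own = g$species_b,
                       cp = g$copies_b, other = g$copies_a))
    expl_of_species <- list()
    for (sd in sides) {
      spof <- unname(species_of[sd$cp])
      for (sp in sd$own) {
        cps <- sd$cp[spof == sp]
        found <- character(0)
        for (cand in cand_ids) {
          if (groups[[cand]]$superfamily != g$superfamily) next
          hit <- FALSE
          for (cp in cps) {
            if (copy_explained(cp, sd$own, sd$other, groups[[cand]], idt)) {
              hit <- TRUE; break
            }
          }
          if (hit) found <- c(found, cand)
        }
        expl_of_species[[sp]] <- found
      }
    }
    all_sp <- c(g$species_a, g$species_b)
    per_sp <- expl_of_species[all_sp]
    req1 <- all(lengths(per_sp) > 0L) &&
      length(unique(unlist(per_sp))) >= 2L
    if (!req1) next
    used <- sort(unique(unlist(per_sp)))
    # flag explanatory groups whose removal breaks requirement 1
    for (e in used) {
      wo <- lapply(per_sp, setdiff, e)
      broken <- any(lengths(wo) == 0L) || length(unique(unlist(wo))) < 2L
      if (broken) {
        required <- union(required, e)
        required_for[e] <- paste(c(
          setdiff(strsplit(required_for[e], ",")[[1L]], ""), focal),
          collapse = ",")
      }
    }
    if (focal %in% required) next
    explained[focal] <- TRUE
    explained_by[focal] <- paste(used, collapse = ",")
    pool <- setdiff(pool, focal)
  }

  reps <- t(vapply(ids, function(id)
    representative_pair(groups[[id]], hits), character(2L)))
  data.frame(group = ids,
             superfamily = vapply(groups, `[[`, "", "superfamily"),
             reliability = unname(rel[ids]),
             independent = !explained[ids],
             explained_by = unname(explained_by[ids]),
             required_for = unname(required_for[ids]),
             rep_species_a = reps[, 1L], rep_species_b = reps[, 2L],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Representative species pair of a transfer
#'
#' The species pair of the group's hit with the highest pID (ties broken by
#' hit id), used by the permutation analyses.
#'
#' @param g `hit_group`; @param hits hit table.
#' @return character vector of two species (clade-A species first).
#' @export
representative_pair <- function(g, hits) {
  hh <- hits[match(g$hit_ids, hits$hit_id), ]
  best <- hh[order(-hh$pident, hh$hit_id), ][1L, ]
  a_sp <- if (best$copy_a == best$qseqid) best$qspecies else best$sspecies
  b_sp <- if (best$copy_b == best$qseqid) best$qspecies else best$sspecies
  if (a_sp %in% g$species_a) c(a_sp, b_sp) else c(b_sp, a_sp)
}
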