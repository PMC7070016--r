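# Null distributions of transfer counts across clades by constrained species
# permutation, and the habitat permutation test.

#' Constrained species permutations of representative transfer pairs
#'
#' A permutation is a bijection on the species involved in the given
#' transfers, applied consistently to every pair (a species is replaced by
#' the same species everywhere), which preserves the per-species transfer
#' counts.  Permutations creating any pair of species that diverged less
#' than `min_age` My ago are illegal and redrawn until `n_perm` legal
#' permutations are collected.
#'
#' @param pairs two-column character matrix (or data frame) of
#'   representative species pairs, one row per transfer.
#' @param tree `species_tree`.
#' @param n_perm number of legal permutations (default 1000).
#' @param min_age legality threshold in My (default 120).
#' @param max_attempts attempt budget before erroring with advice to subset.
#' @return list with `perms` (list of named character vectors: original
#'   species -> permuted species) and `attempts`.
#' @export
permute_species <- function(pairs, tree, n_perm = 1000, min_age = 120,
                            max_attempts = 1e7) {
  pairs <- as.matrix(pairs)
  stopifnot(nrow(pairs) > 0L)
  sp <- sort(unique(as.vector(pairs)))
  i1 <- match(pairs[, 1L], sp)
  i2 <- match(pairs[, 2L], sp)
  div <- tree$div[sp, sp, drop = FALSE]
  perms <- vector("list", n_perm)
  got <- 0L
  attempts <- 0L
  while (got < n_perm) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("fewer than ", n_perm, " legal permutations found in ",
           max_attempts, " attempts; permute subsets of transfers instead")
    p <- sample.int(length(sp))
    if (all(div[cbind(p[i1], p[i2])] >= min_age)) {
      got <- got + 1L
      perms[[got]] <- stats::setNames(sp[p], sp)
    }
  }
  list(perms = perms, attempts = attempts, species = sp)
}

#' Clade-wise transfer counts against the permutation null
#'
#' A transfer counts for a clade when either of its representative species
#' belongs to it (once, not twice, when both do).  Each clade's observed
#' count is compared with its null distribution over the permuted pair
#' sets: verdict `"below_all"`/`"above_all"` when outside every permutation
#' (empirical p < 1/n_perm), `"within_95"` when inside the central 95%,
#' otherwise `"outside_95"`.
#'
#' @param pairs representative species pairs (matrix-like, one row per
#'   transfer).
#' @param clade_of named character vector: species -> clade label.
#' @param perms result of [permute_species()].
#' @return data frame per clade: observed, null mean, null 2.5/97.5%
#'   quantiles, verdict, ratio (observed / null mean).
#' @export
clade_count_test <- function(pairs, clade_of, perms) {
  pairs <- as.matrix(pairs)
  clades <- sort(unique(unname(clade_of)))
  count_by_clade <- function(p1, p2) {
    c1 <- clade_of[p1]; c2 <- clade_of[p2]
    vapply(clades, function(cl) sum(c1 == cl | c2 == cl), 0)
  }
  obs <- count_by_clade(pairs[, 1L], pairs[, 2L])
  null <- vapply(perms$perms, function(pm)
    count_by_clade(unname(pm[pairs[, 1L]]), unname(pm[pairs[, 2L]])),
    numeric(length(clades)))
  if (is.null(dim(null))) null <- matrix(null, nrow = 1L)
  data.frame(
    clade = clades,
    observed = obs,
    null_mean = rowMeans(null),
    null_q025 = apply(null, 1L, stats::quantile, 0.025),
    null_q975 = apply(null, 1L, stats::quantile, 0.975),
    verdict = vapply(seq_along(clades), function(i) {
      if (obs[i] < min(null[i, ])) "below_all"
      else if (obs[i] > max(null[i, ])) "above_all"
      else if (obs[i] >= stats::quantile(null[i, ], 0.025) &&
               obs[i] <= stats::quantile(null[i, ], 0.975)) "within_95"
      else "outside_95"
    }, ""),
    ratio = obs / rowMeans(null),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Pool small superfamilies and split large ones into permutation units
#'
#' Superfamilies with at least `min_per_family` transfers form their own
#' analysis units; smaller ones are pooled per TE class
#' (`"<class> (other)"`).  Units exceeding `max_for_perm` transfers are
#' split, after a seeded shuffle, into balanced contiguous subsets of at
#' most `max_for_perm`.
#'
#' @param transfers data frame with `superfamily`, `te_class` (one row per
#'   transfer).
#' @param min_per_family,max_for_perm unit bounds (defaults 20 and 120).
#' @return character vector of unit labels, one per transfer row.
#' @export
pool_and_subset <- function(transfers, min_per_family = 20,
                            max_for_perm = 120) {
  n_sf <- table(transfers$superfamily)
  unit <- ifelse(n_sf[transfers$superfamily] >= min_per_family,
                 transfers$superfamily,
                 paste0(transfers$te_class, " (other)"))
  out <- unit
  for (u in unique(unit)) {
    ii <- which(unit == u)
    if (length(ii) > max_for_perm) {
      k <- ceiling(length(ii) / max_for_perm)
      sz <- ceiling(length(ii) / k)
      shuffled <- sample(ii)
      chunk <- ceiling(seq_along(shuffled) / sz)
      out[shuffled] <- paste0(u, " [", chunk, "]")
    }
  }
  out
}

#' Habitat permutation test for fish-tetrapod transfers
#'
#' Permutes the habitat labels (aquatic/terrestrial, amphibious counted as
#' aquatic) of the tetrapod species involved in hit groups with ray-finned
#' fishes, and compares the observed number of groups joining an aquatic
#' tetrapod with a fish to the central 95% of the permuted counts.
#'
#' @param tetrapods character vector: the tetrapod species of each
#'   fish-tetrapod hit group (one entry per group).
#' @param habitat named character vector: tetrapod species -> `"aquatic"` or
#'   `"terrestrial"`.
#' @param n_perm number of permutations (default 1000).
#' @return list with `observed`, `null` (vector), `q025`, `q975`,
#'   `verdict` (`"within_95"` or `"outside_95"`).
#' @export
habitat_permutation <- function(tetrapods, habitat, n_perm = 1000) {
  sp <- sort(unique(tetrapods))
  lab <- habitat[sp]
  if (anyNA(lab))
    stop("missing habitat labels for: ",
         paste(sp[is.na(lab)], collapse = ", "))
  observed <- sum(habitat[tetrapods] == "aquatic")
  null <- vapply(seq_len(n_perm), function(i) {
    pl <- stats::setNames(sample(lab), sp)
    sum(pl[tetrapods] == "aquatic")
  }, 0)
  q <- stats::quantile(null, c(0.025, 0.975))
  list(observed = observed, null = null,
       q025 = unname(q[1L]), q975 = unname(q[2L]),
       verdict = if (observed >= q[1L] && observed <= q[2L])
         "within_95" else "outside_95")
}
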