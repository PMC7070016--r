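# Selection of TE-TE hits whose divergence is incompatible with vertical
# inheritance, against core-gene Ks null distributions per sister-clade pair.

#' Build the core-gene Ks distribution for one sister-clade pair
#'
#' Keeps cross-pair ortholog Ks values from alignments of at least 600 bp,
#' retaining only the longest alignment per gene (orthologs from different
#' species pairs count as different genes).  For clade pairs older than
#' 250 My, only one designated genome per subclade younger than 30 My is
#' used — the species with the most annotated genes — to curb redundancy.
#'
#' @param ortholog_ks data frame `gene`, `species_a`, `species_b`, `ks`,
#'   `aln_len`.
#' @param pair a `clade_pair` from [sister_clade_pair()].
#' @param tree the `species_tree`.
#' @param min_aln_bp minimum alignment length (default 600).
#' @param deep_pair_age,subclade_age the 250-My / 30-My subsampling rule.
#' @return object of class `ks_distribution`: list with `values`, `pair_id`,
#'   and `quantile(q)` accessor (empirical, linear interpolation).
#' @export
build_core_ks <- function(ortholog_ks, pair, tree,
                          min_aln_bp = 600, deep_pair_age = 250,
                          subclade_age = 30) {
  a <- normalize_species(ortholog_ks$species_a)
  b <- normalize_species(ortholog_ks$species_b)
  cross <- (a %in% pair$clade_a & b %in% pair$clade_b) |
    (a %in% pair$clade_b & b %in% pair$clade_a)
  rec <- ortholog_ks[cross & ortholog_ks$aln_len >= min_aln_bp &
                       !is.na(ortholog_ks$ks), , drop = FALSE]

  if (pair$mrca_age > deep_pair_age && nrow(rec) > 0L) {
    part <- clades_younger_than(tree, subclade_age)
    n_genes <- table(c(rec$species_a, rec$species_b))
    keep_sp <- vapply(part$members, function(m) {
      cnt <- n_genes[m]; cnt[is.na(cnt)] <- 0L
      m[order(-cnt, m)][1L]
    }, character(1L))
    rec <- rec[rec$species_a %in% keep_sp & rec$species_b %in% keep_sp, ,
               drop = FALSE]
  }

  # longest alignment per gene; gene identity includes the species pair
  if (nrow(rec) > 0L) {
    key <- paste(rec$gene, rec$species_a, rec$species_b)
    rec <- rec[order(key, -rec$aln_len), , drop = FALSE]
    rec <- rec[!duplicated(paste(rec$gene, rec$species_a, rec$species_b)), ,
               drop = FALSE]
  }
  if (nrow(rec) == 0L)
    stop("empty core-gene Ks distribution for clade pair at ",
         pair$mrca_age, " My; thresholds are undefined")
  values <- rec$ks
  structure(list(values = values,
                 pair_id = pair$node,
                 mrca_age = pair$mrca_age,
                 quantile = function(q)
                   unname(stats::quantile(values, q, type = 7))),
            class = "ks_distribution")
}

#' @export
print.ks_distribution <- function(x, ...) {
  cat(sprintf(
    "Core-gene Ks distribution (clade pair %s, %.0f My): n = %d, q0.5%% = %.4f\n",
    as.character(x$pair_id), x$mrca_age, length(x$values), x$quantile(0.005)))
  invisible(x)
}

#' Ks threshold of a core-gene distribution
#'
#' The smallest value between 0.5 and the 0.5% quantile of the core-gene Ks.
#' @param dist a `ks_distribution`.
#' @param ks_max absolute cap (default 0.5).
#' @param core_quantile quantile level (default 0.005).
#' @export
ks_threshold <- function(dist, ks_max = 0.5, core_quantile = 0.005) {
  min(ks_max, dist$quantile(core_quantile))
}

#' Basic hit retention rule
#'
#' TRUE iff the alignment is at least `min_len` bp, identity at least
#' `min_pid` percent, score at least `min_score`, and both copies belong to
#' the same superfamily.
#'
#' @param hits hit data frame (needs `pident`, `length`, `bitscore`, and
#'   either one `superfamily` column or `qsuperfamily`/`ssuperfamily`).
#' @param min_len,min_pid,min_score thresholds.
#' @return logical vector.
#' @export
retain_hit <- function(hits, min_len = 300, min_pid = 75, min_score = 200) {
  same_sf <- if (!is.null(hits$qsuperfamily))
    hits$qsuperfamily == hits$ssuperfamily else TRUE
  hits$length >= min_len & hits$pident >= min_pid &
    hits$bitscore >= min_score & same_sf
}

#' Remove hits between recently diverged species
#'
#' Hits whose species diverged strictly less than `min_age` My ago are
#' removed (a pair at exactly the boundary is kept).
#'
#' @param hits hit data frame with `qspecies`, `sspecies`.
#' @param tree `species_tree`.
#' @param min_age minimum divergence (default 120 My).
#' @return the surviving subset of `hits`.
#' @export
exclude_young_pairs <- function(hits, tree, min_age = 120) {
  if (nrow(hits) == 0L) return(hits)
  d <- divergence_my(tree, hits$qspecies, hits$sspecies)
  hits[d >= min_age, , drop = FALSE]
}

#' Global-identity prefilter against the core-gene Ks quantile
#'
#' Discards hits whose global divergence proxy `1 - pID/100` exceeds the
#' 0.5% quantile of the relevant core-gene Ks distribution; purely an
#' optimization, since any hit discarded here would also fail [ks_filter()].
#'
#' @param hits hit data frame; @param dist `ks_distribution`;
#' @param core_quantile quantile level.
#' @return logical keep vector.
#' @export
pid_prefilter <- function(hits, dist, core_quantile = 0.005) {
  (1 - hits$pident / 100) <= dist$quantile(core_quantile)
}

#' The Ks filter
#'
#' Keeps a hit iff `Ks + 2*Ks_sd` does not exceed the 0.5% quantile of the
#' core-gene Ks distribution, `Ks < 0.5`, and the estimate rests on at least
#' 100 codons.  NA rates (no projectable codons, or saturated estimates)
#' fail.
#'
#' @param hits hit data frame with `ks`, `ks_sd`, `n_codons`.
#' @param dist `ks_distribution` for the hits' sister-clade pair.
#' @param ks_max,core_quantile,min_codons thresholds.
#' @return logical keep vector.
#' @export
ks_filter <- function(hits, dist, ks_max = 0.5, core_quantile = 0.005,
                      min_codons = 100) {
  q <- dist$quantile(core_quantile)
  ok <- !is.na(hits$ks) & !is.na(hits$ks_sd) &
    (hits$ks + 2 * hits$ks_sd) <= q &
    hits$ks < ks_max & hits$n_codons >= min_codons
  ok
}

#' Run the full hit-selection stage
#'
#' Applies, in order: basic retention ([retain_hit()]), reciprocal-duplicate
#' removal, the young-pair exclusion, the identity prefilter, Ka/Ks
#' annotation ([batch_kaks()]) and the Ks filter.  Sister-clade core-gene
#' distributions are built once per MRCA node encountered.
#'
#' @param hits hit table; @param copies copy table; @param core_ks ortholog
#'   Ks records; @param tree `species_tree`; @param config [htt_config()].
#' @return list with `hits` (annotated, audit column `discarded_by`:
#'   NA = kept), `kept` (the surviving subset), `dists` (per-node
#'   `ks_distribution`s), `theta` (per-hit Ks threshold used).
#' @export
filter_hits <- function(hits, copies, core_ks, tree,
                        config = htt_config()) {
  n0 <- nrow(hits)
  discarded <- rep(NA_character_, n0)

  ok <- retain_hit(hits, config$min_aln_bp, config$min_pid, config$min_score)
  discarded[!ok] <- "basic"

  if (n0 > 0L) {
    key <- ifelse(hits$qseqid < hits$sseqid,
                  paste(hits$qseqid, hits$sseqid),
                  paste(hits$sseqid, hits$qseqid))
    ord <- order(key, -hits$bitscore)
    dup <- ord[duplicated(key[ord])]
    discarded[dup[is.na(discarded[dup])]] <- "reciprocal_duplicate"
  }

  live <- which(is.na(discarded))
  if (length(live) > 0L) {
    d <- divergence_my(tree, hits$qspecies[live], hits$sspecies[live])
    discarded[live[d < config$min_age]] <- "young_pair"
  }

  # sister-clade distribution per MRCA node
  live <- which(is.na(discarded))
  dists <- list()
  theta <- rep(NA_real_, n0)
  qv <- rep(NA_real_, n0)
  if (length(live) > 0L) {
    spkey <- paste(hits$qspecies[live], hits$sspecies[live])
    for (k in unique(spkey)) {
      ii <- live[spkey == k]
      pr <- sister_clade_pair(tree, hits$qspecies[ii[1L]],
                              hits$sspecies[ii[1L]])
      nk <- as.character(pr$node)
      if (is.null(dists[[nk]]))
        dists[[nk]] <- build_core_ks(core_ks, pr, tree,
                                     config$core_min_aln_bp,
                                     config$deep_pair_age,
                                     config$subclade_age)
      qv[ii] <- dists[[nk]]$quantile(config$core_quantile)
      theta[ii] <- min(config$ks_max, qv[ii][1L])
    }
    pre <- (1 - hits$pident[live] / 100) <= qv[live]
    discarded[live[!pre]] <- "pid_prefilter"
  }

  live <- which(is.na(discarded))
  if (length(live) > 0L) {
    ann <- batch_kaks(hits[live, , drop = FALSE], copies)
    hits$ka <- hits$ks <- hits$ks_sd <- rep(NA_real_, n0)
    hits$n_codons <- rep(NA_integer_, n0)
    hits$ka[live] <- ann$ka; hits$ks[live] <- ann$ks
    hits$ks_sd[live] <- ann$ks_sd; hits$n_codons[live] <- ann$n_codons
    bad <- is.na(hits$ks[live]) | is.na(hits$ks_sd[live]) |
      (hits$ks[live] + 2 * hits$ks_sd[live]) > qv[live] |
      hits$ks[live] >= config$ks_max |
      hits$n_codons[live] < config$min_codons
    discarded[live[bad]] <- "ks_filter"
  } else {
    hits$ka <- hits$ks <- hits$ks_sd <- rep(NA_real_, n0)
    hits$n_codons <- rep(NA_integer_, n0)
  }

  hits$discarded_by <- discarded
  hits$theta <- theta
  list(hits = hits, kept = hits[is.na(discarded), , drop = FALSE],
       dists = dists, theta = theta)
}
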