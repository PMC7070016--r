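# Selection-regime analysis: Ka/Ks distributions of horizontally transferred
# versus within-genome (transposition-only) TE pairs, tested against
# neutrality.

#' Within-genome TE pairs for transposition-only Ka/Ks
#'
#' Pairs of copies sharing a hit community and a genome, aligned over at
#' least `min_coding_bp` of protein-coding region; such pairs diverged by
#' transposition alone.  Ka/Ks is computed on each pair with [li93()] via
#' the same codon projection as for hits.
#'
#' @param hits clustered hit table (with `community`); @param copies copy
#'   table; @param identities identity table (provides the within-genome
#'   alignments); @param min_coding_bp minimum aligned coding length
#'   (default 300).
#' @return data frame: `copy1`, `copy2`, `species`, `superfamily`,
#'   `community`, `ka`, `ks`, `n_codons`.
#' @export
within_genome_pairs <- function(hits, copies, identities,
                                min_coding_bp = 300) {
  empty <- data.frame(copy1 = character(0), copy2 = character(0),
                      species = character(0), superfamily = character(0),
                      community = character(0), ka = numeric(0),
                      ks = numeric(0), n_codons = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(hits) == 0L || is.null(hits$community)) return(empty)
  com_of <- c(
    stats::setNames(hits$community, hits$qseqid),
    stats::setNames(hits$community, hits$sseqid))
  com_of <- com_of[!duplicated(names(com_of))]
  idt <- identities[identities$species1 == identities$species2 &
                      identities$aln_len >= min_coding_bp, , drop = FALSE]
  if (nrow(idt) == 0L) return(empty)
  c1 <- com_of[idt$copy1]; c2 <- com_of[idt$copy2]
  idt <- idt[!is.na(c1) & !is.na(c2) & c1 == c2, , drop = FALSE]
  if (nrow(idt) == 0L) return(empty)
  ph <- data.frame(qseqid = idt$copy1, sseqid = idt$copy2,
                   gapopen = 0L, qstart = NA_integer_, qend = NA_integer_,
                   sstart = NA_integer_, send = NA_integer_,
                   stringsAsFactors = FALSE)
  ann <- batch_kaks(ph, copies)
  data.frame(copy1 = idt$copy1, copy2 = idt$copy2,
             species = idt$species1, superfamily = idt$superfamily,
             community = unname(com_of[idt$copy1]),
             ka = ann$ka, ks = ann$ks, n_codons = ann$n_codons,
             stringsAsFactors = FALSE)
}

#' Paired Ka/Ks distributions per superfamily
#'
#' Builds, for each superfamily, the Ka/Ks values of horizontally
#' transferred pairs (the retained hits) and of within-genome pairs.
#' Ratios are used unchanged; pairs with `Ks = 0` carry no ratio and are
#' excluded with a logged count (infinite and 0/0 ratios alike).
#'
#' @param ht_hits retained hit table with `ka`, `ks`;
#' @param wg_pairs within-genome pair table from [within_genome_pairs()].
#' @return named list per superfamily: list(ht = numeric, wg = numeric,
#'   n_dropped_zero_ks = integer).
#' @export
kaks_by_superfamily <- function(ht_hits, wg_pairs) {
  ratio <- function(ka, ks) {
    ok <- !is.na(ka) & !is.na(ks) & ks > 0
    list(v = ka[ok] / ks[ok], dropped = sum(!is.na(ka) & !is.na(ks) & ks == 0))
  }
  sfs <- sort(unique(c(ht_hits$superfamily, wg_pairs$superfamily)))
  out <- list()
  for (sf in sfs) {
    h <- ratio(ht_hits$ka[ht_hits$superfamily == sf],
               ht_hits$ks[ht_hits$superfamily == sf])
    w <- ratio(wg_pairs$ka[wg_pairs$superfamily == sf],
               wg_pairs$ks[wg_pairs$superfamily == sf])
    if (length(h$v) == 0L && length(w$v) == 0L) next
    out[[sf]] <- list(ht = h$v, wg = w$v,
                      n_dropped_zero_ks = h$dropped + w$dropped)
  }
  out
}

#' One-sided location test of Ka/Ks ratios against neutrality
#'
#' One-sample Wilcoxon signed-rank test of the ratios against 1, one-sided
#' toward purifying selection (`"less"`); values exactly 1 are dropped per
#' the classical procedure.  The null is exact for 25 or fewer non-tied
#' values and a normal approximation with continuity correction above.
#'
#' @param values Ka/Ks ratios; @param side `"less"` (default) or
#'   `"greater"`.
#' @return p-value.
#' @export
test_vs_neutral <- function(values, side = "less") {
  v <- values[is.finite(values)]
  v <- v[v != 1]
  if (length(v) == 0L) {
    warning("all values equal 1; p = 1 by convention")
    return(1)
  }
  suppressWarnings(
    stats::wilcox.test(v, mu = 1, alternative = side,
                       exact = length(v) <= 25, correct = TRUE)$p.value)
}

#' Selection-regime summary table
#'
#' @param dists result of [kaks_by_superfamily()].
#' @return data frame: superfamily, context (`ht`/`wg`), n, median Ka/Ks,
#'   p-value vs neutrality (one-sided, less).
#' @export
selection_summary <- function(dists) {
  rows <- list()
  for (sf in names(dists)) for (ctx in c("ht", "wg")) {
    v <- dists[[sf]][[ctx]]
    if (length(v) == 0L) next
    rows[[paste(sf, ctx)]] <- data.frame(
      superfamily = sf, context = ctx, n = length(v),
      median_kaks = stats::median(v),
      p_less_1 = test_vs_neutral(v), stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(superfamily = character(0), context = character(0),
                      n = integer(0), median_kaks = numeric(0),
                      p_less_1 = numeric(0)))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
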