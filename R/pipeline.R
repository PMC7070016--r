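# End-to-end orchestration: one configuration record housing every
# threshold, one entry point running all stages, and S3 methods on the
# result.

#' Pipeline configuration
#'
#' Every tunable threshold of the detection procedure lives here, once, with
#' its published screening value as default; each stage reads it from
#' this record.
#'
#' @param young_clade_age clade age (My) under which HTT is not searched and
#'   species are collapsed for clustering (40).
#' @param min_age minimum species divergence (My) for a hit to be considered
#'   HTT at all (120); must be positive — with 0 the HTT-versus-vertical
#'   decision is undefined.
#' @param subclade_age,deep_pair_age core-gene subsampling rule: pairs older
#'   than `deep_pair_age` (250) use one genome per subclade younger than
#'   `subclade_age` (30).
#' @param min_aln_bp,min_pid,min_score basic hit retention (300 bp, 75%,
#'   200).
#' @param core_min_aln_bp minimum core-gene alignment (600 bp).
#' @param ks_max absolute Ks cap (0.5); @param core_quantile quantile of the
#'   core-gene Ks null (0.005); @param min_codons minimum codons per
#'   estimate (100).
#' @param max_hits_per_cluster precluster cap per species pair (200).
#' @param c1_frac criterion-1 community pass fraction (0.05).
#' @param min_copies_incl,min_copies_excl copy-count filter (5 and 2).
#' @param trunc_gap,trunc_margin truncation filter (20 hits, 0.2).
#' @param pool_min,perm_max permutation unit bounds (20 and 120 transfers).
#' @param n_perm permutations per unit (1000).
#' @param seed master seed for the permutation stage.
#' @return a `htt_config` list.
#' @export
htt_config <- function(young_clade_age = 40,
                       min_age = 120,
                       subclade_age = 30,
                       deep_pair_age = 250,
                       min_aln_bp = 300,
                       min_pid = 75,
                       min_score = 200,
                       core_min_aln_bp = 600,
                       ks_max = 0.5,
                       core_quantile = 0.005,
                       min_codons = 100,
                       max_hits_per_cluster = 200,
                       c1_frac = 0.05,
                       min_copies_incl = 5,
                       min_copies_excl = 2,
                       trunc_gap = 20,
                       trunc_margin = 0.2,
                       pool_min = 20,
                       perm_max = 120,
                       n_perm = 1000,
                       seed = 1L) {
  if (min_age <= 0)
    stop("min_age must be positive: with no divergence floor, horizontal ",
         "transfer cannot be told apart from vertical inheritance")
  cfg <- as.list(environment())
  class(cfg) <- "htt_config"
  cfg
}

#' Run the full HTT detection pipeline
#'
#' Stages: hit selection ([filter_hits()]), preclustering and community
#' delineation ([precluster()], [build_communities()]), hit-group assembly
#' ([hit_groups()]), group evaluation ([evaluate_groups()]), independent
#' event counting ([count_independent()]), clade permutation tests and the
#' selection-regime analysis.  Input is either a simulated dataset or the
#' same tables read from files.
#'
#' @param data an `htt_dataset` from [simulate_dataset()], or a list with
#'   elements `tree`, `hits`, `copies`, `core_ks`, `identities`.
#' @param config a [htt_config()].
#' @param permute run the permutation stage (needs >= 2 transfers and is
#'   skipped, with a note in the manifest, when impossible).
#' @param selection run the selection-regime (Ka/Ks distribution) stage.
#' @return object of class `htt_scan`.
#' @export
htt_scan <- function(data, config = htt_config(), permute = TRUE,
                     selection = TRUE) {
  stopifnot(!is.null(data$tree), !is.null(data$hits),
            !is.null(data$copies), !is.null(data$core_ks))
  tree <- data$tree
  t0 <- Sys.time()

  filt <- filter_hits(data$hits, data$copies, data$core_ks, tree, config)
  kept <- filt$kept

  idt <- identity_lookup(data$identities, kept, min_aln = 100)
  pre <- precluster(kept, config$max_hits_per_cluster)
  com <- build_communities(pre, idt, tree, config$young_clade_age)

  dist_cache <- filt$dists
  dist_for <- function(sp1, sp2) {
    pr <- sister_clade_pair(tree, sp1, sp2)
    nk <- as.character(pr$node)
    if (is.null(dist_cache[[nk]]))
      dist_cache[[nk]] <<- build_core_ks(data$core_ks, pr, tree,
                                         config$core_min_aln_bp,
                                         config$deep_pair_age,
                                         config$subclade_age)
    dist_cache[[nk]]
  }
  frames <- copy_frames(data$copies)
  hg <- hit_groups(com, idt, dist_for, tree, frames,
                   config$c1_frac, config$core_quantile)
  groups <- assemble_groups(com$hits, hg$groups, tree)

  ev <- evaluate_groups(groups, data$copies, idt, config)

  species_of <- stats::setNames(data$copies$species, data$copies$copy_id)
  counts <- if (length(ev$groups) > 0L)
    count_independent(ev$groups, com$hits, idt, species_of)
  else data.frame()
  transfers <- if (nrow(counts) > 0L)
    counts[counts$independent, , drop = FALSE] else counts

  perm_res <- NULL
  if (permute && nrow(transfers) >= 2L &&
      length(unique(c(transfers$rep_species_a,
                      transfers$rep_species_b))) >= 3L) {
    set.seed(config$seed)
    te_class_of <- stats::setNames(data$copies$te_class,
                                   data$copies$superfamily)
    transfers$te_class <- unname(te_class_of[transfers$superfamily])
    units <- pool_and_subset(transfers, config$pool_min, config$perm_max)
    part <- clades_younger_than(tree, config$young_clade_age)
    perm_res <- list()
    for (u in unique(units)) {
      tt <- transfers[units == u, , drop = FALSE]
      prs <- cbind(tt$rep_species_a, tt$rep_species_b)
      pm <- tryCatch(
        permute_species(prs, tree, config$n_perm, config$min_age),
        error = function(e) e)
      perm_res[[u]] <- if (inherits(pm, "error")) pm$message else
        clade_count_test(prs, part$clade, pm)
    }
  }

  if (selection) {
    wg <- within_genome_pairs(com$hits, data$copies, data$identities,
                              min_coding_bp = config$min_aln_bp)
    sel <- selection_summary(kaks_by_superfamily(kept, wg))
  } else {
    wg <- NULL
    sel <- data.frame()
  }

  manifest <- list(
    config = unclass(config),
    started = t0, finished = Sys.time(),
    n_hits_in = nrow(data$hits),
    n_hits_retained = nrow(kept),
    n_hits_clustered = nrow(pre),
    n_communities = nrow(com$communities),
    n_groups = length(groups),
    n_groups_evaluated = length(ev$groups),
    n_independent = if (nrow(counts) > 0L) sum(counts$independent) else 0L)

  structure(list(tree = tree, config = config,
                 hits = filt$hits, retained = kept,
                 communities = com$communities, clustered_hits = com$hits,
                 group_table = hg$groups, groups = ev$groups,
                 group_audit = ev$audit,
                 counts = counts, transfers = transfers,
                 permutation = perm_res,
                 within_genome = wg, selection = sel,
                 manifest = manifest),
            class = "htt_scan")
}

#' @export
print.htt_scan <- function(x, ...) {
  m <- x$manifest
  cat("Horizontal transposon transfer scan\n")
  cat(sprintf("  %d hits in -> %d retained by the Ks filters\n",
              m$n_hits_in, m$n_hits_retained))
  cat(sprintf("  %d communities -> %d hit groups -> %d after evaluation\n",
              m$n_communities, m$n_groups, m$n_groups_evaluated))
  cat(sprintf("  %d independent HTT events\n", m$n_independent))
  invisible(x)
}

#' @export
summary.htt_scan <- function(object, ...) {
  x <- object
  print(x)
  if (nrow(x$transfers) > 0L) {
    cat("\nIndependent transfers:\n")
    print(x$transfers[, c("group", "superfamily", "reliability",
                          "rep_species_a", "rep_species_b")],
          row.names = FALSE)
  }
  if (nrow(x$selection) > 0L) {
    cat("\nSelection regimes (median Ka/Ks, one-sided p vs 1):\n")
    print(x$selection, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' @export
plot.htt_scan <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  if (nrow(x$retained) > 0L) {
    graphics::hist(x$retained$ks, breaks = 20, col = "grey80",
                   main = "Retained hit Ks", xlab = "Ks")
  } else {
    graphics::plot.new(); graphics::title("No retained hits")
  }
  if (nrow(x$counts) > 0L) {
    tab <- table(x$counts$superfamily, x$counts$independent)
    graphics::barplot(t(tab), beside = TRUE, las = 2,
                      legend.text = c("explained", "independent"),
                      main = "Hit groups per superfamily")
  } else {
    graphics::plot.new(); graphics::title("No hit groups")
  }
  invisible(x)
}
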