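# Forward simulator of core-gene and TE evolution along a dated species tree,
# with planted horizontal transfers and ground-truth labels.  It emits every
# input the detection pipeline consumes: TE copies with coding frames, core
# ortholog Ks records per species pair, a TE-TE hit table in BLAST outfmt-6
# shape, within-clade identity tables, and a truth table.

#' Simulation configuration
#'
#' Defaults describe the screening conditions the simulator emulates: a neutral
#' synonymous clock of 3.1e-9 substitutions per site and year, TE
#' superfamilies of both classes with their own target Ka/Ks, transposition
#' bursts that amplify a family after it enters a lineage, and planted HTT
#' events at chosen times between chosen lineages.
#'
#' @param tree a `species_tree` (see [parse_timetree()]).
#' @param n_core_genes number of neutral single-copy orthologs to evolve.
#' @param core_gene_length ortholog length in bp (>= 600, multiple of 3).
#' @param mu_s synonymous substitution rate per site per year.
#' @param superfamilies data frame with columns `superfamily`, `te_class`
#'   (`"retrotransposon"` or `"DNA transposon"`), `omega` (target Ka/Ks of
#'   active copies), `n_families`, `coding_length` (codons per copy), and
#'   optionally `origin_species` / `origin_age`: the lineage (a tip label)
#'   and age (My) where the superfamily's families originate — `NA` means
#'   the tree root.  A family restricted to a recent origin on a donor
#'   lineage models the young, recently active families that mediate
#'   detectable transfers.  An optional `burst_rate` column overrides the
#'   global rate per superfamily (activity differs between superfamilies).
#' @param burst_rate baseline transposition-burst rate per family per lineage
#'   per My.
#' @param burst_lambda copies per burst are `1 + rpois(burst_lambda)`.
#' @param invasion_boost burst-rate multiplier during `invasion_window` My
#'   after a family enters a lineage (at its origin or through HTT).
#' @param invasion_window length of the elevated-activity window, My.
#' @param htt_events NULL or data frame with columns `donor`, `recipient`
#'   (tip labels naming the two lineages), `time_my` and `superfamily`.
#' @param deactivation_rate per-copy rate (per My) of switching to neutral
#'   evolution (omega -> 1), the simulator's handle on selection-regime
#'   change; 0 disables it.
#' @param young_clade_age clade age (My) used when emitting within-clade
#'   identity tables.
#' @param seed integer master seed; every stage derives its stream from it.
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(tree,
                       n_core_genes = 200L,
                       core_gene_length = 600L,
                       mu_s = 3.1e-9,
                       superfamilies = default_superfamilies(),
                       burst_rate = 0.02,
                       burst_lambda = 2,
                       invasion_boost = 30,
                       invasion_window = 20,
                       htt_events = NULL,
                       deactivation_rate = 0,
                       young_clade_age = 40,
                       seed = 1L) {
  stopifnot(inherits(tree, "species_tree"),
            mu_s > 0, core_gene_length >= 600L,
            core_gene_length %% 3L == 0L,
            all(superfamilies$omega >= 0))
  if (!is.null(htt_events) && nrow(htt_events) > 0L) {
    bad <- character(0)
    for (i in seq_len(nrow(htt_events))) {
      e <- htt_events[i, ]
      ok <- all(c(e$donor, e$recipient) %in% tree$tips) &&
        e$superfamily %in% superfamilies$superfamily &&
        e$time_my > 0 &&
        e$time_my < divergence_my(tree, e$donor, e$recipient)
      if (!ok)
        bad <- c(bad, sprintf(
          "event %d (%s -> %s at %g My, %s)",
          i, e$donor, e$recipient, e$time_my, e$superfamily))
    }
    if (length(bad) > 0L)
      stop("invalid htt_events (lineages must exist and be distinct at the ",
           "transfer time): ", paste(bad, collapse = "; "))
  }
  structure(list(tree = tree, n_core_genes = as.integer(n_core_genes),
                 core_gene_length = as.integer(core_gene_length),
                 mu_s = mu_s, superfamilies = superfamilies,
                 burst_rate = burst_rate, burst_lambda = burst_lambda,
                 invasion_boost = invasion_boost,
                 invasion_window = invasion_window,
                 htt_events = htt_events,
                 deactivation_rate = deactivation_rate,
                 young_clade_age = young_clade_age,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_superfamilies <- function() {
  data.frame(
    superfamily = c("Tc1_Mariner", "Rex_Babar"),
    te_class = c("DNA transposon", "retrotransposon"),
    omega = c(1.0, 0.4),
    n_families = c(1L, 1L),
    coding_length = c(220L, 220L),
    origin_species = c(NA_character_, NA_character_),
    origin_age = c(NA_real_, NA_real_),
    stringsAsFactors = FALSE
  )
}

# deterministic sub-seed derivation from the master seed (kept below 2^31)
derive_seed <- function(seed, stage) {
  (as.double(seed) * 48271 + stage * 16807) %% 2147483647
}

#' Evolve a codon sequence for a given time
#'
#' Per-site substitution process: proposals arrive at rate `mu_s` per
#' nucleotide site per year, the proposed base is uniform among the three
#' alternatives, proposals creating stop codons are rejected, and
#' non-synonymous proposals are accepted with probability `omega`.  A
#' proposal that would create a stop codon is rerouted to a uniformly chosen
#' valid nonsynonymous alternative of the same site (and then subjected to
#' the same `omega` acceptance); without the rerouting the realized Ka/Ks
#' would fall a few percent below its target, because the estimator's site
#' counts include the stop-bound directions that the simulation could never
#' realize.  Under Li's estimator this realizes an expected pairwise Ks
#' of `2*mu_s*t` for two lineages split `t` years ago and an expected Ka/Ks
#' of `omega`.
#'
#' @param parent_seq integer codon vector (see [nt_to_codons()]) or a
#'   nucleotide string; no stop codons allowed.
#' @param t_years elapsed time in years (>= 0).
#' @param mu_s,omega process parameters.
#' @return evolved sequence, same representation as the input.
#' @export
evolve_codon_sequence <- function(parent_seq, t_years, mu_s, omega) {
  chr <- is.character(parent_seq)
  cod <- if (chr) nt_to_codons(parent_seq)[[1L]] else parent_seq
  if (any(codon_aa(cod) == "*"))
    stop("stop codon in input sequence")
  stopifnot(t_years >= 0)
  out <- evolve_codons_(cod, t_years, mu_s, omega)
  if (chr) codons_to_nt(out) else out
}

# internal engine on integer codon vectors; vectorized rounds, one event per
# codon per round
evolve_codons_ <- function(cod, t_years, mu_s, omega) {
  L3 <- 3L * length(cod)
  if (L3 == 0L || t_years == 0) return(cod)
  n_ev <- stats::rpois(1L, L3 * mu_s * t_years)
  if (n_ev == 0L) return(cod)
  pos <- sample.int(L3, n_ev, replace = TRUE)
  ev_cod <- (pos - 1L) %/% 3L + 1L
  ev_off <- (pos - 1L) %% 3L + 1L
  while (length(ev_cod) > 0L) {
    first <- !duplicated(ev_cod)
    ci <- ev_cod[first]
    oi <- ev_off[first]
    cur <- cod[ci]
    b0 <- codon_base(cur, oi)
    nb <- (b0 - 1L + sample.int(3L, length(ci), replace = TRUE)) %% 4L + 1L
    new <- cur + (nb - b0) * 4L^(3L - oi)
    hit_stop <- codon_aa(new) == "*"
    if (any(hit_stop)) {
      w <- which(hit_stop)
      n_ok <- .STOP_ALT$n_ok[cbind(cur[w], oi[w])]
      pickable <- n_ok > 0L
      if (any(pickable)) {
        wp <- w[pickable]
        k <- 1L + as.integer(stats::runif(length(wp)) * n_ok[pickable])
        new[wp] <- .STOP_ALT$targets[cbind(cur[wp], oi[wp], k)]
      }
    }
    syn <- codon_aa(new) == codon_aa(cur)
    acc <- codon_aa(new) != "*" &
      (syn | stats::runif(length(ci)) < omega)
    cod[ci[acc]] <- new[acc]
    ev_cod <- ev_cod[!first]
    ev_off <- ev_off[!first]
  }
  cod
}

# random sense-codon sequence of n codons
random_codons <- function(n) {
  sense <- which(codon_aa(seq_len(64L)) != "*")
  sample(sense, n, replace = TRUE)
}

#' Simulate a complete synthetic dataset
#'
#' Core genes evolve neutrally (omega = 1); TE families descend vertically
#' through speciations, amplify by transposition bursts, and planted HTT
#' events copy an active donor-lineage TE into the recipient lineage at the
#' stated time, after which it diversifies there under the same process.
#' Reproducible: the same config (including seed) gives identical output.
#'
#' @param cfg a [sim_config()].
#' @return object of class `htt_dataset`: list with `tree`, `copies` (copy
#'   table with `seq_codons` list-column, `sequence`, `frames`), `core_ks`
#'   (gene, species_a, species_b, ks, aln_len), `hits` (outfmt-6 shaped),
#'   `identities` (within-clade pairwise identities), `truth`, `config`.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  tree <- cfg$tree

  set.seed(derive_seed(cfg$seed, 1))
  core_ks <- simulate_core_ks(cfg)

  set.seed(derive_seed(cfg$seed, 2))
  te <- simulate_te_copies(cfg)

  set.seed(derive_seed(cfg$seed, 3))
  hits <- emit_hit_table(te$copies)
  identities <- emit_identity_table(te$copies, tree, cfg$young_clade_age)

  structure(list(tree = tree, copies = te$copies, core_ks = core_ks,
                 hits = hits, identities = identities, truth = te$truth,
                 config = cfg),
            class = "htt_dataset")
}

#' @export
print.htt_dataset <- function(x, ...) {
  cat(sprintf(paste0(
    "Synthetic HTT dataset: %d species, %d TE copies, %d hits,\n",
    "  %d core-gene Ks records, %d planted transfers\n"),
    length(x$tree$tips), nrow(x$copies), nrow(x$hits),
    nrow(x$core_ks), if (is.null(x$truth)) 0L else nrow(x$truth)))
  invisible(x)
}

# ---- core genes -----------------------------------------------------------

simulate_core_ks <- function(cfg) {
  if (cfg$n_core_genes == 0L)
    return(data.frame(gene = character(0), species_a = character(0),
                      species_b = character(0), ks = numeric(0),
                      aln_len = integer(0), stringsAsFactors = FALSE))
  tree <- cfg$tree
  phy <- tree$phylo
  ntip <- length(tree$tips)
  n_genes <- cfg$n_core_genes
  Lg <- cfg$core_gene_length %/% 3L
  total <- n_genes * Lg

  root <- ntip + 1L
  states <- vector("list", max(phy$edge))
  states[[root]] <- random_codons(total)
  # preorder traversal
  ord <- order(-tree$age[phy$edge[, 1L]])
  for (ei in ord) {
    par <- phy$edge[ei, 1L]; chi <- phy$edge[ei, 2L]
    dt <- (tree$age[par] - tree$age[chi]) * 1e6
    states[[chi]] <- evolve_codons_(states[[par]], dt, cfg$mu_s, 1)
  }

  pairs <- utils::combn(ntip, 2L)
  npair <- ncol(pairs)
  gene_of <- rep(seq_len(n_genes), each = Lg)
  ks <- numeric(npair * n_genes)
  for (p in seq_len(npair)) {
    r <- li93_multi(states[[pairs[1L, p]]], states[[pairs[2L, p]]], gene_of)
    ks[((p - 1L) * n_genes + 1L):(p * n_genes)] <-
      r$ks[order(as.integer(r$group))]
  }
  data.frame(
    gene = rep(paste0("gene", seq_len(n_genes)), npair),
    species_a = rep(tree$tips[pairs[1L, ]], each = n_genes),
    species_b = rep(tree$tips[pairs[2L, ]], each = n_genes),
    ks = ks, aln_len = Lg * 3L, stringsAsFactors = FALSE)
}

# ---- TE copies ------------------------------------------------------------

# genome-family state: list(cod = L x n matrix, active, born, arrival, id)
new_te_state <- function(cod, age, id0) {
  list(cod = matrix(cod, ncol = 1L), active = TRUE, born = age,
       arrival = age, id = id0)
}

# evolve all copies of a state over dt_my (split by activity regime)
evolve_state <- function(st, dt_my, mu_s, omega) {
  if (dt_my <= 0 || ncol(st$cod) == 0L) return(st)
  t_yr <- dt_my * 1e6
  for (grp in list(which(st$active), which(!st$active))) {
    if (length(grp) == 0L) next
    om <- if (st$active[grp[1L]]) omega else 1
    v <- as.vector(st$cod[, grp])
    v <- evolve_codons_(v, t_yr, mu_s, om)
    st$cod[, grp] <- v
  }
  st
}

# simulate one family state down one edge, from age a0 to age a1
run_edge <- function(st, a0, a1, cfg, omega, counter_env) {
  if (ncol(st$cod) == 0L) return(st)
  # burst events, thinned against the invasion-boosted rate
  win_end <- st$arrival - cfg$invasion_window
  seg <- function(from, to, rate) {
    len <- from - to
    if (len <= 0 || rate <= 0) return(numeric(0))
    n <- stats::rpois(1L, rate * len)
    if (n == 0L) return(numeric(0))
    sort(stats::runif(n, to, from), decreasing = TRUE)
  }
  hi <- min(a0, st$arrival)
  boost_hi <- hi; boost_lo <- max(a1, win_end)
  ev_burst <- c(
    seg(boost_hi, max(boost_lo, a1), cfg$burst_rate * cfg$invasion_boost),
    seg(min(a0, win_end), a1, cfg$burst_rate)
  )
  ev <- data.frame(age = ev_burst,
                   type = rep("burst", length(ev_burst)))
  # deactivations
  if (cfg$deactivation_rate > 0) {
    p <- 1 - exp(-cfg$deactivation_rate * (a0 - a1))
    hitc <- which(st$active & stats::runif(ncol(st$cod)) < p)
    if (length(hitc) > 0L)
      ev <- rbind(ev, data.frame(age = stats::runif(length(hitc), a1, a0),
                                 type = paste0("deact", hitc)))
  }
  ev <- ev[order(-ev$age), , drop = FALSE]
  cur <- a0
  for (r in seq_len(nrow(ev))) {
    st <- evolve_state(st, cur - ev$age[r], cfg$mu_s, omega)
    cur <- ev$age[r]
    if (ev$type[r] == "burst") {
      act <- which(st$active)
      if (length(act) > 0L) {
        src <- if (length(act) == 1L) act else sample(act, 1L)
        k <- 1L + stats::rpois(1L, cfg$burst_lambda)
        ids <- counter_env$n + seq_len(k)
        counter_env$n <- counter_env$n + k
        st$cod <- cbind(st$cod, st$cod[, rep(src, k), drop = FALSE])
        st$active <- c(st$active, rep(TRUE, k))
        st$born <- c(st$born, rep(cur, k))
        st$id <- c(st$id, ids)
      }
    } else {
      ci <- as.integer(sub("deact", "", ev$type[r]))
      st$active[ci] <- FALSE
    }
  }
  evolve_state(st, cur - a1, cfg$mu_s, omega)
}

# path of node ids from root to a tip
root_path <- function(phy, tip) {
  parent <- integer(max(phy$edge))
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  path <- tip
  while (parent[path[1L]] != 0L) path <- c(parent[path[1L]], path)
  path
}

simulate_te_copies <- function(cfg) {
  tree <- cfg$tree
  phy <- tree$phylo
  ntip <- length(tree$tips)
  root <- ntip + 1L
  sf <- cfg$superfamilies
  htt <- cfg$htt_events
  copies_out <- list()
  truth_out <- list()

  kids_of <- split(phy$edge[, 2L], phy$edge[, 1L])

  collect_tips <- function(st, node, superfam, te_class, fam, event, acc) {
    sp <- tree$tips[node]
    n <- ncol(st$cod)
    if (n == 0L) return(acc)
    ids <- sprintf("%s|%s|%s|c%d", sp, superfam, fam, st$id)
    acc[[length(acc) + 1L]] <- list(
      df = data.frame(copy_id = ids, species = sp, superfamily = superfam,
                      te_class = te_class, family = fam,
                      active = st$active, born = st$born,
                      htt_event = if (is.null(event)) NA_character_ else event,
                      stringsAsFactors = FALSE),
      cods = lapply(seq_len(n), function(j) st$cod[, j]))
    acc
  }

  # recursive descent from a node (or mid-edge point) with a given state
  descend <- function(st, node, from_age, superfam, te_class, fam, omega,
                      event, counter_env, snap_wanted, acc) {
    # snap_wanted: data.frame(age, key) of donor snapshots to take on the
    # lineage ABOVE `node` handled by caller; here handle subtree below node
    if (node <= ntip) {
      st <- run_edge(st, from_age, 0, cfg_eff, omega, counter_env)
      acc$tips <- collect_tips(st, node, superfam, te_class, fam, event,
                               acc$tips)
      return(acc)
    }
    node_age <- tree$age[node]
    st <- run_edge(st, from_age, node_age, cfg_eff, omega, counter_env)
    for (k in kids_of[[as.character(node)]]) {
      acc <- descend(st, k, node_age, superfam, te_class, fam, omega,
                     event, counter_env, snap_wanted, acc)
    }
    acc
  }

  for (si in seq_len(nrow(sf))) {
    superfam <- sf$superfamily[si]
    te_class <- sf$te_class[si]
    omega <- sf$omega[si]
    org_sp <- if (!is.null(sf$origin_species)) sf$origin_species[si] else NA
    org_age <- if (!is.null(sf$origin_age)) sf$origin_age[si] else NA
    cfg_eff <- cfg
    if (!is.null(sf$burst_rate) && !is.na(sf$burst_rate[si]))
      cfg_eff$burst_rate <- sf$burst_rate[si]
    for (fi in seq_len(sf$n_families[si])) {
      fam <- sprintf("%s_f%d", superfam, fi)
      counter_env <- new.env(); counter_env$n <- 1L
      root_age <- max(tree$age)
      if (is.na(org_sp) || is.na(org_age)) {
        start_node <- root
        start_age <- root_age
      } else {
        opath <- root_path(phy, match(normalize_species(org_sp), tree$tips))
        start_node <- opath[tree$age[opath] < org_age][1L]
        start_age <- org_age
      }
      st0 <- new_te_state(random_codons(sf$coding_length[si]), start_age, 1L)

      # planted transfers of this superfamily, round-robin over its families
      ev_fam <- NULL
      if (!is.null(htt) && nrow(htt) > 0L) {
        ev_fam <- htt[htt$superfamily == superfam, , drop = FALSE]
        if (nrow(ev_fam) > 0L && sf$n_families[si] > 1L)
          ev_fam <- ev_fam[((seq_len(nrow(ev_fam)) - 1L) %%
                              sf$n_families[si]) + 1L == fi, , drop = FALSE]
      }

      # vertical pass, splitting edges at donor-snapshot times
      snapshots <- list()
      acc <- list(tips = list())
      walk <- function(st, node, from_age, acc) {
        if (!is.null(ev_fam) && nrow(ev_fam) > 0L) {
          for (e in seq_len(nrow(ev_fam))) {
            dpath <- root_path(phy, match(normalize_species(ev_fam$donor[e]),
                                          tree$tips))
            tau <- ev_fam$time_my[e]
            to_age <- if (node <= ntip) 0 else tree$age[node]
            on_lineage <- node %in% dpath
            if (on_lineage && tau < from_age && tau >= to_age &&
                is.null(snapshots[[paste0("e", e)]])) {
              st <- run_edge(st, from_age, tau, cfg_eff, omega, counter_env)
              from_age <- tau
              act <- which(st$active)
              src <- if (length(act) == 0L) 1L else
                if (length(act) == 1L) act else sample(act, 1L)
              snapshots[[paste0("e", e)]] <<- st$cod[, src]
            }
          }
        }
        if (node <= ntip) {
          st <- run_edge(st, from_age, 0, cfg_eff, omega, counter_env)
          acc$tips <- collect_tips(st, node, superfam, te_class, fam, NULL,
                                   acc$tips)
          return(acc)
        }
        node_age <- tree$age[node]
        st <- run_edge(st, from_age, node_age, cfg_eff, omega, counter_env)
        for (k in kids_of[[as.character(node)]])
          acc <- walk(st, k, node_age, acc)
        acc
      }
      acc <- walk(st0, start_node, start_age, acc)

      # second pass: inject each transfer into the recipient lineage
      if (!is.null(ev_fam) && nrow(ev_fam) > 0L) {
        for (e in seq_len(nrow(ev_fam))) {
          tau <- ev_fam$time_my[e]
          snap <- snapshots[[paste0("e", e)]]
          if (is.null(snap))
            stop("transfer ", rownames(ev_fam)[e], ": donor lineage '",
                 ev_fam$donor[e], "' carries no ", fam,
                 " copy at ", tau, " My")
          rtip <- match(normalize_species(ev_fam$recipient[e]), tree$tips)
          rpath <- root_path(phy, rtip)
          ages <- tree$age[rpath]
          # node at the lower end of the edge spanning tau
          below <- rpath[ages < tau][1L]
          ev_id <- sprintf("htt_%s", rownames(ev_fam)[e])
          counter2 <- new.env(); counter2$n <- 200000L + e * 10000L
          stx <- new_te_state(snap, tau, counter2$n)
          counter2$n <- counter2$n + 1L
          acc2 <- list(tips = list())
          acc2 <- descend(stx, below, tau, superfam, te_class, fam, omega,
                          ev_id, counter2, NULL, acc2)
          rec_ids <- unlist(lapply(acc2$tips, function(x) x$df$copy_id))
          acc$tips <- c(acc$tips, acc2$tips)
          truth_out[[length(truth_out) + 1L]] <- data.frame(
            event_id = ev_id,
            donor = normalize_species(ev_fam$donor[e]),
            recipient = normalize_species(ev_fam$recipient[e]),
            time_my = tau, superfamily = superfam, te_class = te_class,
            family = fam,
            recipient_copies = paste(rec_ids, collapse = ","),
            stringsAsFactors = FALSE)
        }
      }
      copies_out <- c(copies_out, acc$tips)
    }
  }

  df <- do.call(rbind, lapply(copies_out, `[[`, "df"))
  cods <- do.call(c, lapply(copies_out, `[[`, "cods"))
  df$seq_codons <- cods
  df$sequence <- vapply(cods, codons_to_nt, character(1L))
  L3 <- nchar(df$sequence)
  df$frames <- lapply(L3, function(l)
    data.frame(start = 0L, end = l, phase = 0L))
  rownames(df) <- NULL
  truth <- if (length(truth_out) > 0L) do.call(rbind, truth_out) else
    data.frame(event_id = character(0), donor = character(0),
               recipient = character(0), time_my = numeric(0),
               superfamily = character(0), te_class = character(0),
               family = character(0), recipient_copies = character(0))
  list(copies = df, truth = truth)
}

# ---- hit and identity emission -------------------------------------------

# nucleotide match counts between copies given as codon-index matrices
# (columns = copies); one 64x64 lookup per codon pair
match_counts <- function(A, B) {
  .codon_match_cpp(A, B, .NTMATCH64)
}

codmat <- function(cods) {
  # list of equal-length codon vectors -> L x n codon-index matrix
  matrix(unlist(cods), ncol = length(cods))
}

#' Emit the TE-TE hit table of a simulated copy set
#'
#' Mimics the reciprocal-search convention: for every query copy and every
#' other species, the best-scoring comparison is reported, in both
#' directions; the two directions of one copy pair are then deduplicated.
#' Copies within a family are gapless homologs, so an alignment is the
#' positional comparison over the full shared region: pID is the percentage
#' of matching positions and the score is `2*matches - 3*mismatches`.  Hits
#' shorter than `min_len`, weaker than `min_pid` or `min_score`, or crossing
#' superfamilies are absent.
#'
#' @param copies copy table from [simulate_dataset()].
#' @param min_len,min_pid,min_score retention thresholds (bp, %, score).
#' @return hit data frame in BLAST outfmt-6 column order plus `hit_id`,
#'   `qspecies`, `sspecies`, `superfamily`.
#' @export
emit_hit_table <- function(copies, min_len = 300, min_pid = 75,
                           min_score = 200) {
  rows <- list()
  for (fam in unique(copies$family)) {
    sub <- copies[copies$family == fam, ]
    ntm <- codmat(sub$seq_codons)
    L3 <- 3L * nrow(ntm)
    if (L3 < min_len) next
    spp <- unique(sub$species)
    if (length(spp) < 2L) next
    idx_sp <- split(seq_len(nrow(sub)), sub$species)
    emit_dir <- function(mm, ia, ib, spa, spb) {
      score <- 2 * mm - 3 * (L3 - mm)
      best <- max.col(score, ties.method = "first")
      sel <- cbind(seq_along(ia), best)
      list(qseqid = sub$copy_id[ia], sseqid = sub$copy_id[ib[best]],
           pident = mm[sel] / L3 * 100, length = rep(L3, length(ia)),
           mismatch = L3 - mm[sel], bitscore = score[sel],
           qspecies = rep(spa, length(ia)), sspecies = rep(spb, length(ia)),
           superfamily = rep(sub$superfamily[1L], length(ia)))
    }
    for (a in seq_len(length(spp) - 1L)) for (b in (a + 1L):length(spp)) {
      ia <- idx_sp[[spp[a]]]; ib <- idx_sp[[spp[b]]]
      mm <- match_counts(ntm[, ia, drop = FALSE], ntm[, ib, drop = FALSE])
      rows[[length(rows) + 1L]] <- emit_dir(mm, ia, ib, spp[a], spp[b])
      rows[[length(rows) + 1L]] <- emit_dir(t(mm), ib, ia, spp[b], spp[a])
    }
  }
  if (length(rows) == 0L) return(empty_hits())
  hits <- data.frame(
    qseqid = unlist(lapply(rows, `[[`, "qseqid")),
    sseqid = unlist(lapply(rows, `[[`, "sseqid")),
    pident = unlist(lapply(rows, `[[`, "pident")),
    length = unlist(lapply(rows, `[[`, "length")),
    mismatch = unlist(lapply(rows, `[[`, "mismatch")),
    gapopen = 0L, qstart = 1L,
    qend = unlist(lapply(rows, `[[`, "length")),
    sstart = 1L, send = unlist(lapply(rows, `[[`, "length")),
    evalue = 0,
    bitscore = unlist(lapply(rows, `[[`, "bitscore")),
    qspecies = unlist(lapply(rows, `[[`, "qspecies")),
    sspecies = unlist(lapply(rows, `[[`, "sspecies")),
    superfamily = unlist(lapply(rows, `[[`, "superfamily")),
    stringsAsFactors = FALSE)
  # dedup the two directions of one unordered copy pair, keep higher score
  key <- ifelse(hits$qseqid < hits$sseqid,
                paste(hits$qseqid, hits$sseqid),
                paste(hits$sseqid, hits$qseqid))
  hits <- hits[order(key, -hits$bitscore), ]
  hits <- hits[!duplicated(key[order(key, -hits$bitscore)]), ]
  hits <- hits[hits$length >= min_len & hits$pident >= min_pid &
                 hits$bitscore >= min_score, ]
  hits <- hits[order(hits$qseqid, hits$sseqid), ]
  rownames(hits) <- NULL
  hits$hit_id <- sprintf("h%06d", seq_len(nrow(hits)))
  hits
}

empty_hits <- function() {
  data.frame(qseqid = character(0), sseqid = character(0),
             pident = numeric(0), length = integer(0), mismatch = integer(0),
             gapopen = integer(0), qstart = integer(0), qend = integer(0),
             sstart = integer(0), send = integer(0), evalue = numeric(0),
             bitscore = numeric(0), qspecies = character(0),
             sspecies = character(0), superfamily = character(0),
             hit_id = character(0), stringsAsFactors = FALSE)
}

#' Within-clade pairwise identity table
#'
#' For every TE family and every clade younger than `young_clade_age`, the
#' pairwise percent identity between the clade's copies (including pairs
#' within one genome), from positional comparison of the gapless homologs;
#' alignments shorter than 100 bp are not reported.
#'
#' @param copies copy table; @param tree `species_tree`;
#' @param young_clade_age clade age threshold in My.
#' @return data frame `copy1`, `copy2`, `pid`, `aln_len`, `species1`,
#'   `species2`, `clade`, `superfamily`, `family` (one row per unordered
#'   pair).
#' @export
emit_identity_table <- function(copies, tree, young_clade_age = 40) {
  part <- clades_younger_than(tree, young_clade_age)
  rows <- list()
  for (fam in unique(copies$family)) {
    sub <- copies[copies$family == fam, ]
    L3 <- 3L * length(sub$seq_codons[[1L]])
    if (L3 < 100L) next
    cl <- part$clade[sub$species]
    for (cid in unique(cl)) {
      ii <- which(cl == cid)
      if (length(ii) < 2L) next
      ntm <- codmat(sub$seq_codons[ii])
      mm <- match_counts(ntm, ntm)
      pr <- which(upper.tri(mm), arr.ind = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        copy1 = sub$copy_id[ii[pr[, 1L]]],
        copy2 = sub$copy_id[ii[pr[, 2L]]],
        pid = mm[pr] / L3 * 100,
        aln_len = L3,
        species1 = sub$species[ii[pr[, 1L]]],
        species2 = sub$species[ii[pr[, 2L]]],
        clade = cid,
        superfamily = sub$superfamily[1L], family = fam,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(copy1 = character(0), copy2 = character(0),
                      pid = numeric(0), aln_len = integer(0),
                      species1 = character(0), species2 = character(0),
                      clade = character(0), superfamily = character(0),
                      family = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Standard demonstration arena with planted transfers
#'
#' Builds a [sim_config()] on [demo_timetree()] with `K` planted,
#' well-separated transfers: each uses its own superfamily whose single
#' family originates on the donor lineage 24 My ago (a recently active
#' family, the kind that mediates detectable transfer) and crosses between
#' a fish-like and a tetrapod-like clade 18 My ago — inside the detection
#' window set by the pipeline's thresholds (cross-clade Ks well below
#' 0.3, pID well above 75%).  A vertical background superfamily spanning
#' the whole tree is always included.  With `K = 0` the dataset is purely
#' vertical.
#'
#' @param K number of planted transfers (0..8).
#' @param seed master seed.
#' @param n_core_genes core orthologs to simulate (default 100).
#' @param ... further arguments passed to [sim_config()].
#' @return a `sim_config`.
#' @export
demo_sim_config <- function(K, seed, n_core_genes = 100L, ...) {
  stopifnot(K >= 0, K <= 8)
  tree <- demo_timetree()
  donors <- paste0("F", rep(1:4, 2), c(rep("a", 4), rep("b", 4)))
  recips <- paste0("T", rep(1:4, 2), c(rep("a", 4), rep("b", 4)))
  base <- data.frame(
    superfamily = "LINE1", te_class = "retrotransposon", omega = 0.4,
    n_families = 1L, coding_length = 600L,
    origin_species = NA_character_, origin_age = NA_real_,
    burst_rate = 0.008, stringsAsFactors = FALSE)
  if (K > 0) {
    sfs <- data.frame(
      superfamily = paste0("SF", seq_len(K)),
      te_class = rep(c("DNA transposon", "retrotransposon"),
                     length.out = K),
      omega = rep(c(1.0, 0.4), length.out = K),
      n_families = 1L, coding_length = 600L,
      origin_species = donors[seq_len(K)],
      origin_age = 24,
      burst_rate = 0.028, stringsAsFactors = FALSE)
    ev <- data.frame(donor = donors[seq_len(K)],
                     recipient = recips[seq_len(K)],
                     time_my = 18,
                     superfamily = paste0("SF", seq_len(K)),
                     stringsAsFactors = FALSE)
    sim_config(tree, n_core_genes = n_core_genes,
               superfamilies = rbind(sfs, base), htt_events = ev,
               seed = seed, ...)
  } else {
    sim_config(tree, n_core_genes = n_core_genes,
               superfamilies = base, seed = seed, ...)
  }
}
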