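# Random small instances of the explanatory-transfer counting problem, plus
# a literal, independently coded implementation of the procedure's semantics
# and an exhaustive minimal-explanation search.

# clades used by the instance generator: nested options on the "A" side
.inst_clades <- list(
  X  = c("x1", "x2"), X1 = "x1",
  Y  = c("y1", "y2"), Y1 = "y1",
  Z  = c("z1", "z2"), Z1 = "z1")

random_count_instance <- function(n_groups, seed) {
  set.seed(seed)
  groups <- list()
  hit_rows <- list()
  id_rows <- list()
  all_copies <- character(0)
  species_of <- character(0)
  hid <- 0L
  for (g in seq_len(n_groups)) {
    gid <- sprintf("g%03d", g)
    sideA <- .inst_clades[[sample(c("X", "X1"), 1L)]]
    sideB <- .inst_clades[[sample(c("Y", "Y1", "Z", "Z1"), 1L)]]
    mk_copies <- function(side, tag) {
      n <- sample.int(4L, 1L)
      sp <- sample(side, n, replace = TRUE)
      ids <- sprintf("%s.%s.%s%d", gid, sp, tag, seq_len(n))
      species_of[ids] <<- sp
      ids
    }
    ca <- mk_copies(sideA, "a")
    cb <- mk_copies(sideB, "b")
    all_copies <- c(all_copies, ca, cb)
    hit_ids <- character(0)
    for (i in seq_along(ca)) for (j in seq_along(cb)) {
      hid <- hid + 1L
      h <- sprintf("h%05d", hid)
      hit_ids <- c(hit_ids, h)
      hit_rows[[h]] <- data.frame(
        hit_id = h, pident = round(stats::runif(1, 80, 99), 2),
        length = 300L,
        copy_a = ca[i], copy_b = cb[j],
        qseqid = ca[i], sseqid = cb[j],
        qspecies = species_of[ca[i]], sspecies = species_of[cb[j]],
        superfamily = "SF", stringsAsFactors = FALSE)
    }
    hh <- do.call(rbind, hit_rows[hit_ids])
    groups[[gid]] <- structure(list(
      id = gid, superfamily = "SF", communities = gid,
      hit_ids = hit_ids,
      copies_a = sort(ca), copies_b = sort(cb),
      species_a = sort(unique(species_of[ca])),
      species_b = sort(unique(species_of[cb])),
      ks = stats::runif(length(hit_ids), 0.05, 0.2),
      pid = hh$pident, theta = 0.5,
      retrieved_a = character(0), retrieved_b = character(0)),
      class = "hit_group")
  }
  hits <- do.call(rbind, hit_rows)
  rownames(hits) <- NULL
  # cross-group similarity evidence: a random subset of copy pairs
  pairs <- utils::combn(all_copies, 2L)
  pick <- which(stats::runif(ncol(pairs)) < 0.4)
  identities <- data.frame(
    copy1 = pairs[1L, pick], copy2 = pairs[2L, pick],
    pid = round(stats::runif(length(pick), 70, 99), 2),
    aln_len = rep(300L, length(pick)),
    species1 = unname(species_of[pairs[1L, pick]]),
    species2 = unname(species_of[pairs[2L, pick]]),
    clade = rep(NA_character_, length(pick)),
    superfamily = rep("SF", length(pick)),
    family = rep("SF_f1", length(pick)),
    stringsAsFactors = FALSE)
  list(groups = groups, hits = hits, identities = identities,
       species_of = species_of,
       idt = identity_lookup(identities, hits, min_aln = 100))
}

# naive similarity scan over the raw evidence tables (no shared lookup code)
oracle_sim <- function(c1, c2, identities, hits) {
  if (c1 == c2) return(100)
  vals <- c(
    identities$pid[(identities$copy1 == c1 & identities$copy2 == c2) |
                     (identities$copy1 == c2 & identities$copy2 == c1)],
    hits$pident[(hits$qseqid == c1 & hits$sseqid == c2) |
                  (hits$qseqid == c2 & hits$sseqid == c1)])
  if (length(vals) == 0) NA_real_ else max(vals)
}

oracle_reliability <- function(g, hits) {
  score_side <- function(copies) {
    s <- 0
    for (cp in copies) {
      p <- hits$pident[hits$hit_id %in% g$hit_ids &
                         (hits$copy_a == cp | hits$copy_b == cp)]
      if (length(p) > 0) s <- s + max(p)
    }
    s
  }
  min(score_side(g$copies_a), score_side(g$copies_b))
}

# requirement 1 of one focal group against an explicit candidate pool
oracle_req1 <- function(focal, pool_ids, groups, identities, hits,
                        species_of) {
  per_species <- list()
  sides <- list(list(own_sp = focal$species_a, own_cp = focal$copies_a,
                     other_cp = focal$copies_b),
                list(own_sp = focal$species_b, own_cp = focal$copies_b,
                     other_cp = focal$copies_a))
  for (sd in sides) for (sp in sd$own_sp) {
    found <- character(0)
    for (cand_id in pool_ids) {
      cand <- groups[[cand_id]]
      if (cand$superfamily != focal$superfamily) next
      ok <- FALSE
      for (cp in sd$own_cp[species_of[sd$own_cp] == sp]) {
        simsB <- vapply(sd$other_cp, oracle_sim, 0, c1 = cp,
                        identities = identities, hits = hits)
        if (all(is.na(simsB))) next
        weakest <- min(simsB, na.rm = TRUE)
        for (cside in list(list(sp = cand$species_a, cp = cand$copies_a),
                           list(sp = cand$species_b, cp = cand$copies_b))) {
          own_clade <- if (cp %in% focal$copies_a) focal$species_a else
            focal$species_b
          nested <- all(cside$sp %in% own_clade) ||
            all(own_clade %in% cside$sp)
          if (!nested) next
          for (cc in setdiff(cside$cp, cp)) {
            s <- oracle_sim(cp, cc, identities, hits)
            if (!is.na(s) && s > weakest) { ok <- TRUE; break }
          }
          if (ok) break
        }
        if (ok) break
      }
      if (ok) found <- c(found, cand_id)
    }
    per_species[[sp]] <- found
  }
  req1 <- all(lengths(per_species) > 0) &&
    length(unique(unlist(per_species))) >= 2
  list(req1 = req1, per_species = per_species)
}

# literal sequential procedure: ascending reliability, required flags,
# explained groups leave the pool
oracle_count_independent <- function(inst, decreasing = FALSE) {
  groups <- inst$groups
  ids <- names(groups)
  rel <- vapply(groups, oracle_reliability, 0, hits = inst$hits)
  ord <- ids[order(rel[ids], ids)]
  if (decreasing) ord <- rev(ord)
  pool <- ids
  required <- character(0)
  explained <- character(0)
  for (focal_id in ord) {
    r <- oracle_req1(groups[[focal_id]], setdiff(pool, focal_id), groups,
                     inst$identities, inst$hits, inst$species_of)
    if (!r$req1) next
    used <- unique(unlist(r$per_species))
    for (e in used) {
      wo <- lapply(r$per_species, setdiff, e)
      if (any(lengths(wo) == 0) || length(unique(unlist(wo))) < 2)
        required <- union(required, e)
    }
    if (focal_id %in% required) next
    explained <- c(explained, focal_id)
    pool <- setdiff(pool, focal_id)
  }
  setdiff(ids, explained)  # the independent groups
}

# exhaustive minimum number of unexplained groups: a subset S is a valid
# explanation support when every group outside S meets requirement 1 using
# candidates drawn from S only
oracle_min_explanation <- function(inst) {
  ids <- names(inst$groups)
  n <- length(ids)
  best <- n
  for (mask in 0:(2^n - 1)) {
    S <- ids[as.logical(bitwAnd(mask, 2^(0:(n - 1))))]
    if (length(S) >= best) next
    valid <- TRUE
    for (g in setdiff(ids, S)) {
      r <- oracle_req1(inst$groups[[g]], S, inst$groups,
                       inst$identities, inst$hits, inst$species_of)
      if (!r$req1) { valid <- FALSE; break }
    }
    if (valid) best <- length(S)
  }
  best
}
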