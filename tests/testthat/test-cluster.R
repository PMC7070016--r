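test_that("preclustering connects hits sharing a copy and caps per pair", {
  h <- make_hits(copy_a = c("A.1", "A.1", "D.1"),
                 copy_b = c("B.1", "C.1", "E.1"))
  out <- precluster(h, max_hits = 200)
  expect_equal(length(unique(out$precluster)), 2L)
  expect_equal(out$precluster[1], out$precluster[2])
  # cap: 250 hits between one species pair in one cluster -> 200 kept,
  # favoring the longest coding regions
  h2 <- make_hits(copy_a = rep("A.1", 250),
                  copy_b = sprintf("B.%03d", 1:250),
                  n_codons = c(rep(150L, 100), rep(120L, 150)))
  out2 <- precluster(h2, max_hits = 200)
  expect_equal(nrow(out2), 200L)
  expect_equal(sum(out2$n_codons == 150L), 100L)
  # hits sharing no copies stay separate clusters
  h3 <- make_hits(copy_a = c("A.1", "A.2"), copy_b = c("B.1", "B.2"))
  expect_equal(length(unique(precluster(h3)$precluster)), 2L)
})

test_that("criterion 1 on hit pairs compares within- to between-clade identity", {
  idt <- identity_lookup(make_identities(
    c("A.1", "B.1"), c("A.2", "B.2"), c(95, 84)), min_aln = 100)
  # within-clade 95 beats both hits' pID 90
  expect_true(criterion1_hits("A.1", "A.2", "B.1", "B.2", 90, 90, idt))
  # neither side exceeds min(pID): 85-capped evidence fails at 90
  idt2 <- identity_lookup(make_identities(
    c("A.1", "B.1"), c("A.2", "B.2"), c(85, 84)), min_aln = 100)
  expect_false(criterion1_hits("A.1", "A.2", "B.1", "B.2", 90, 90, idt2))
  # a shared copy counts as identity 100
  expect_true(criterion1_hits("A.1", "A.1", "B.1", "B.2", 90, 90, idt2))
  # absent alignments contribute no link
  idt3 <- identity_lookup(make_identities("X.1", "X.2", 99), min_aln = 100)
  expect_false(criterion1_hits("A.1", "A.2", "B.1", "B.2", 90, 90, idt3))
})

test_that("community detection splits disconnected cliques, keeps cliques", {
  tr <- demo_timetree()
  # two independent bundles between the same clade pair: high within-bundle
  # identity, none across bundles
  ca <- sprintf("F1a.%d", 1:6); cb <- sprintf("T1a.%d", 1:6)
  h <- make_hits(copy_a = rep(ca, each = 1), copy_b = cb, pident = 90,
                 species_a = "F1a", species_b = "T1a")
  ids <- rbind(
    make_identities(rep(ca[1:3], times = 2), ca[c(2,3,1, 3,1,2)], 97),
    make_identities(rep(ca[4:6], times = 2), ca[c(5,6,4, 6,4,5)], 97),
    make_identities(rep(cb[1:3], times = 2), cb[c(2,3,1, 3,1,2)], 97),
    make_identities(rep(cb[4:6], times = 2), cb[c(5,6,4, 6,4,5)], 97))
  idt <- identity_lookup(ids, min_aln = 100)
  com <- build_communities(h, idt, tr, 40)
  expect_equal(nrow(com$communities), 2L)
  expect_equal(length(unique(com$hits$community[1:3])), 1L)
  expect_false(com$hits$community[1] == com$hits$community[4])
  # fully connected graph: one community
  pa <- utils::combn(ca, 2); pb <- utils::combn(cb, 2)
  ids_all <- rbind(make_identities(pa[1, ], pa[2, ], 97),
                   make_identities(pb[1, ], pb[2, ], 97))
  idt2 <- identity_lookup(ids_all, min_aln = 100)
  com2 <- build_communities(h, idt2, tr, 40)
  expect_equal(nrow(com2$communities), 1L)
})

test_that("criterion 1 on communities uses the 5% rule inclusively", {
  tr <- demo_timetree()
  ca <- sprintf("F1a.%d", 1:20); cb <- sprintf("T1a.%d", 1:20)
  h <- make_hits(copy_a = ca, copy_b = cb, pident = 90,
                 species_a = "F1a", species_b = "T1a")
  h$community <- rep(c("c1", "c2"), each = 10)
  # exactly 5 of 100 cross pairs pass: identity between A-copies of the
  # first five cross pairs
  ids <- make_identities(ca[1:5], ca[11:15], 95)
  idt <- identity_lookup(ids, min_aln = 100)
  expect_true(criterion1_communities(h, "c1", "c2", idt, "straight"))
  ids4 <- make_identities(ca[1:4], ca[11:14], 95)
  expect_false(criterion1_communities(h, "c1", "c2",
                                      identity_lookup(ids4, min_aln = 100),
                                      "straight"))
})

test_that("fragmentation fallback passes only disjoint no-homology fragments", {
  tr <- demo_timetree()
  h <- make_hits(copy_a = c("F1a.1", "F1a.2"), copy_b = c("T1a.1", "T1a.2"),
                 pident = 90, species_a = "F1a", species_b = "T1a")
  h$community <- c("c1", "c2")
  idt <- identity_lookup(make_identities("zz.1", "zz.2", 80), min_aln = 100)
  frames <- list(
    "F1a.1" = data.frame(start = 0L, end = 300L, phase = 0L, prot_start = 0L),
    "T1a.1" = data.frame(start = 0L, end = 300L, phase = 0L, prot_start = 0L),
    "F1a.2" = data.frame(start = 0L, end = 300L, phase = 0L, prot_start = 150L),
    "T1a.2" = data.frame(start = 0L, end = 300L, phase = 0L, prot_start = 150L))
  # 5' and 3' fragments of one protein: no overlap, no homology -> pass
  expect_true(criterion1_communities(h, "c1", "c2", idt, "straight",
                                     frames = frames))
  # same protein region on both sides: fallback refused
  frames2 <- frames
  frames2[["F1a.2"]]$prot_start <- 0L
  frames2[["T1a.2"]]$prot_start <- 0L
  expect_false(criterion1_communities(h, "c1", "c2", idt, "straight",
                                      frames = frames2))
  # nucleotide homology between the sets: fallback refused
  idt2 <- identity_lookup(make_identities("F1a.1", "F1a.2", 85),
                          min_aln = 100)
  expect_false(criterion1_communities(h, "c1", "c2", idt2, "straight",
                                      frames = frames))
})

test_that("criterion 2 admits one transfer only if it predates speciations", {
  tr <- demo_timetree()
  mkdist <- function(q) function(sp1, sp2)
    structure(list(values = 1, pair_id = 1, mrca_age = 1,
                   quantile = function(p) q), class = "ks_distribution")
  h <- rbind(make_hits("F1a.1", "T1a.1", pident = 90, ks = 0.05),
             make_hits("F1b.1", "T1a.2", pident = 90, ks = 0.05))
  h$community <- c("c1", "c2")
  h$hit_id <- c("h1", "h2")
  # communities involve different F-side species (F1a vs F1b): their mean
  # Ks (0.05) is BELOW the species quantile (0.08): cannot be one event
  expect_false(criterion2_communities(h, "c1", "c2", "straight",
                                      mkdist(0.08), tr))
  # transfer older than the speciation: passes
  h$ks <- 0.12
  expect_true(criterion2_communities(h, "c1", "c2", "straight",
                                     mkdist(0.08), tr))
  # identical species sets on both sides: vacuously compatible
  h2 <- rbind(make_hits("F1a.1", "T1a.1", pident = 90, ks = 0.01),
              make_hits("F1a.2", "T1a.2", pident = 90, ks = 0.01))
  h2$community <- c("c1", "c2"); h2$hit_id <- c("h1", "h2")
  expect_true(criterion2_communities(h2, "c1", "c2", "straight",
                                     mkdist(0.9), tr))
})

test_that("hit groups obey complete linkage and are deterministic", {
  ds <- simulate_dataset(demo_sim_config(3, seed = 31))
  res1 <- htt_scan(ds, htt_config(), permute = FALSE, selection = FALSE)
  res2 <- htt_scan(ds, htt_config(), permute = FALSE, selection = FALSE)
  expect_identical(res1$group_table$group, res2$group_table$group)
  expect_identical(res1$counts, res2$counts)
  # exhaustive audit: every within-group community pair passes both criteria
  gt <- res1$group_table
  idt <- identity_lookup(ds$identities, res1$retained, min_aln = 100)
  dist_for <- function(sp1, sp2) {
    pr <- sister_clade_pair(ds$tree, sp1, sp2)
    build_core_ks(ds$core_ks, pr, ds$tree)
  }
  frames <- httscan:::copy_frames(ds$copies)
  for (g in unique(gt$group)) {
    coms <- gt$community[gt$group == g]
    if (length(coms) < 2) next
    for (pair in utils::combn(coms, 2, simplify = FALSE)) {
      s1 <- httscan:::community_sides(res1$clustered_hits, pair[1])
      s2 <- httscan:::community_sides(res1$clustered_hits, pair[2])
      o <- httscan:::side_orientation(s1, s2, ds$tree)
      expect_false(is.null(o))
      expect_true(criterion1_communities(res1$clustered_hits, pair[1],
                                         pair[2], idt, o, frames))
      expect_true(criterion2_communities(res1$clustered_hits, pair[1],
                                         pair[2], o, dist_for, ds$tree))
    }
  }
  # distinct-superfamily communities never share a group
  expect_true(all(tapply(gt$superfamily, gt$group,
                         function(x) length(unique(x))) == 1L))
})
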