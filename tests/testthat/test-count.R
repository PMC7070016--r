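test_that("reliability is the lower clade sum of per-copy best pIDs", {
  h <- make_hits(copy_a = c("A.1", "A.1", "A.2"),
                 copy_b = c("B.1", "B.2", "B.1"),
                 pident = c(90, 85, 80))
  g <- make_group("g", h, c("A.1", "A.2"), c("B.1", "B.2"))
  # A.1 -> 90, A.2 -> 80 (sum 170); B.1 -> 90, B.2 -> 85 (sum 175)
  expect_equal(reliability(g, h), 170)
  o <- oracle_reliability(g, h)
  expect_equal(reliability(g, h), o)
  # adding a copy with its own hit can only increase the score
  h2 <- rbind(h, make_hits("A.3", "B.1", pident = 70))
  h2$hit_id <- sprintf("h%05d", 1:4)
  g2 <- make_group("g", h2, c("A.1", "A.2", "A.3"), c("B.1", "B.2"))
  expect_gte(reliability(g2, h2), reliability(g, h))
})

test_that("copy explanation needs a compatible clade and better similarity", {
  h <- make_hits(copy_a = c("A.1", "A.2"), copy_b = c("B.1", "B.2"),
                 pident = 90)
  cand <- make_group("gc", make_hits("A.7", "C.1", pident = 95),
                     "A.7", "C.1")
  # evidence: focal copy A.1 vs candidate's A-side copy A.7 at 95, focal
  # cross-clade similarity floor at 90
  idt <- identity_lookup(rbind(
    make_identities("A.1", "A.7", 95),
    make_identities("A.1", "B.1", 90),
    make_identities("A.1", "B.2", 92)), min_aln = 100)
  expect_true(copy_explained("A.1", c("A"), c("B.1", "B.2"), cand, idt))
  # candidate clade disjoint from the focal clade: never explains
  cand2 <- make_group("gd", make_hits("Z.7", "C.1", pident = 95),
                      "Z.7", "C.1")
  idt2 <- identity_lookup(rbind(
    make_identities("A.1", "Z.7", 99),
    make_identities("A.1", "B.1", 90)), min_aln = 100)
  expect_false(copy_explained("A.1", c("A"), c("B.1", "B.2"), cand2, idt2))
  # similarity below every focal cross-clade link: not explained
  idt3 <- identity_lookup(rbind(
    make_identities("A.1", "A.7", 89),
    make_identities("A.1", "B.1", 90),
    make_identities("A.1", "B.2", 92)), min_aln = 100)
  expect_false(copy_explained("A.1", c("A"), c("B.1", "B.2"), cand, idt3))
})

test_that("lone or mutually dependent groups stay independent", {
  inst <- random_count_instance(1, seed = 1)
  sp_of <- inst$species_of
  res <- count_independent(inst$groups, inst$hits, inst$idt, sp_of)
  expect_true(all(res$independent))
  # two groups: requirement 1 needs two distinct explanatory transfers, so
  # each can offer the other only one candidate -> both independent
  inst2 <- random_count_instance(2, seed = 7)
  res2 <- count_independent(inst2$groups, inst2$hits, inst2$idt,
                            inst2$species_of)
  expect_true(all(res2$independent))
})

test_that("the procedure matches the literal oracle on small instances", {
  for (seed in 1:40) {
    n <- sample(3:6, 1)
    inst <- random_count_instance(n, seed = seed + 1000)
    res <- count_independent(inst$groups, inst$hits, inst$idt,
                             inst$species_of)
    mine <- sort(res$group[res$independent])
    oracle <- sort(oracle_count_independent(inst))
    expect_identical(mine, oracle)
  }
})

test_that("greedy counts stay within one of the exhaustive minimum", {
  over <- 0
  for (seed in 1:25) {
    inst <- random_count_instance(sample(4:6, 1), seed = seed + 5000)
    res <- count_independent(inst$groups, inst$hits, inst$idt,
                             inst$species_of)
    greedy <- sum(res$independent)
    lower <- oracle_min_explanation(inst)
    expect_lte(greedy, lower + 1)
    if (greedy > lower) over <- over + 1
  }
})

test_that("representative pairs come from the highest-identity hit", {
  h <- make_hits(copy_a = c("A.1", "A.2", "A.3"),
                 copy_b = c("B.1", "B.2", "B.3"),
                 pident = c(91, 95, 88))
  g <- make_group("g", h, c("A.1", "A.2", "A.3"), c("B.1", "B.2", "B.3"))
  expect_equal(representative_pair(g, h), c("A", "B"))
  h$qspecies <- c("A1", "A2", "A3")
  h$sspecies <- c("B1", "B2", "B3")
  g$species_a <- c("A1", "A2", "A3"); g$species_b <- c("B1", "B2", "B3")
  expect_equal(representative_pair(g, h), c("A2", "B2"))
  # single-hit group: that hit's pair
  g1 <- make_group("g", h[1, ], "A.1", "B.1")
  g1$species_a <- "A1"; g1$species_b <- "B1"
  expect_equal(representative_pair(g1, h), c("A1", "B1"))
})
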