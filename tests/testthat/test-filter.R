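core_rec <- function(gene, a, b, ks, len) {
  data.frame(gene = gene, species_a = a, species_b = b, ks = ks,
             aln_len = len, stringsAsFactors = FALSE)
}

test_that("core Ks distributions keep the longest alignment per gene", {
  tr <- toy_tree()
  pr <- sister_clade_pair(tr, "A", "C")
  rec <- rbind(core_rec("g1", "A", "C", 0.8, 650),
               core_rec("g1", "A", "C", 0.6, 900),
               core_rec("g2", "B", "C", 0.7, 700))
  d <- build_core_ks(rec, pr, tr)
  expect_setequal(d$values, c(0.6, 0.7))
  # all alignments below 600 bp: empty distribution is an error
  rec2 <- core_rec("g1", "A", "C", 0.5, 599)
  expect_error(build_core_ks(rec2, pr, tr), "empty")
})

test_that("deep clade pairs are subsampled to one genome per young subclade", {
  tr <- parse_timetree("(((A:10,B:10):290,C:300):100,D:400);")
  pr <- sister_clade_pair(tr, "A", "D")   # 400 My > 250
  rec <- rbind(core_rec("g1", "A", "D", 1.2, 700),
               core_rec("g1", "B", "D", 1.3, 700),
               core_rec("g2", "A", "D", 1.1, 700),
               core_rec("g2", "B", "D", 1.4, 700),
               core_rec("g3", "B", "D", 1.0, 700))
  d <- build_core_ks(rec, pr, tr)
  # B has 3 annotated genes vs A's 2: B represents the A/B subclade
  expect_setequal(d$values, c(1.3, 1.4, 1.0))
})

test_that("the Ks threshold is the minimum of 0.5 and the 0.5% quantile", {
  mk <- function(v) structure(list(values = v, pair_id = 1, mrca_age = 100,
                                   quantile = function(q) unname(quantile(v, q))),
                              class = "ks_distribution")
  expect_equal(ks_threshold(mk(rep(0.8, 100))), 0.5)
  expect_equal(ks_threshold(mk(rep(0.3, 100))), 0.3)
  expect_equal(ks_threshold(mk(0.4)), 0.4)
})

test_that("basic retention enforces all four hit conditions", {
  h <- data.frame(pident = c(74.9, 80, 80, 80),
                  length = c(400, 299, 400, 400),
                  bitscore = c(250, 250, 250, 199),
                  qsuperfamily = "SF", ssuperfamily = c("SF","SF","SF","SF"))
  expect_equal(retain_hit(h), c(FALSE, FALSE, TRUE, FALSE))
  h2 <- data.frame(pident = 80, length = 400, bitscore = 200,
                   qsuperfamily = "SF", ssuperfamily = "OTHER")
  expect_false(retain_hit(h2))
  h3 <- data.frame(pident = 80, length = 400, bitscore = 200,
                   qsuperfamily = "SF", ssuperfamily = "SF")
  expect_true(retain_hit(h3))
})

test_that("the young-pair exclusion is strict below the boundary", {
  tr <- parse_timetree("((A:119,B:119):1,(C:120,D:120):0.0001);")
  h <- data.frame(qspecies = c("A", "C"), sspecies = c("B", "D"), x = 1:2)
  out <- exclude_young_pairs(h, tr, 120)
  expect_equal(out$qspecies, "C")   # diverged exactly 120: kept
})

test_that("identity prefilter and Ks filter apply the documented arithmetic", {
  mk <- function(q) structure(list(values = 1, pair_id = 1, mrca_age = 1,
                                   quantile = function(p) q),
                              class = "ks_distribution")
  h <- data.frame(pident = c(99, 90))
  expect_equal(pid_prefilter(h, mk(0.02)), c(TRUE, FALSE))
  hk <- data.frame(ks = c(0.10, 0.49, 0.5, 0.2),
                   ks_sd = c(0.02, 0, 0, 0),
                   n_codons = c(150L, 99L, 150L, 150L))
  expect_equal(ks_filter(hk, mk(0.13)),
               c(FALSE, FALSE, FALSE, FALSE))
  # 0.10 + 2*0.02 = 0.14 > 0.13 -> out; 99 codons -> out; Ks = 0.5 -> out
  expect_equal(ks_filter(hk, mk(0.6)), c(TRUE, FALSE, FALSE, TRUE))
  hna <- data.frame(ks = NA_real_, ks_sd = NA_real_, n_codons = 0L)
  expect_false(ks_filter(hna, mk(0.6)))
})

test_that("the prefilter never removes a hit the Ks filter would keep", {
  ds <- simulate_dataset(demo_sim_config(2, seed = 10))
  res <- filter_hits(ds$hits, ds$copies, ds$core_ks, ds$tree, htt_config())
  pre_removed <- res$hits[!is.na(res$hits$discarded_by) &
                            res$hits$discarded_by == "pid_prefilter", ]
  if (nrow(pre_removed) > 0) {
    ann <- batch_kaks(pre_removed, ds$copies)
    for (i in seq_len(nrow(ann))) {
      pr <- sister_clade_pair(ds$tree, ann$qspecies[i], ann$sspecies[i])
      d <- res$dists[[as.character(pr$node)]]
      keep <- !is.na(ann$ks[i]) &&
        (ann$ks[i] + 2 * ann$ks_sd[i]) <= d$quantile(0.005) &&
        ann$ks[i] < 0.5 && ann$n_codons[i] >= 100
      expect_false(keep)
    }
  }
  # and the surviving set equals what the Ks filter alone would keep
  expect_true(all(is.na(res$kept$discarded_by)))
})

test_that("filter audit assigns each discarded hit exactly one rule", {
  ds <- simulate_dataset(demo_sim_config(1, seed = 12))
  res <- filter_hits(ds$hits, ds$copies, ds$core_ks, ds$tree, htt_config())
  expect_equal(nrow(res$kept) + sum(!is.na(res$hits$discarded_by)),
               nrow(ds$hits))
  expect_true(all(res$hits$discarded_by[!is.na(res$hits$discarded_by)] %in%
                    c("basic", "reciprocal_duplicate", "young_pair",
                      "pid_prefilter", "ks_filter")))
  # every kept hit satisfies every rule
  k <- res$kept
  expect_true(all(k$pident >= 75 & k$length >= 300 & k$bitscore >= 200))
  expect_true(all(divergence_my(ds$tree, k$qspecies, k$sspecies) >= 120))
  expect_true(all(k$ks < 0.5 & k$n_codons >= 100))
})
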