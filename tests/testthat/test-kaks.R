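test_that("li93 matches hand-computed single-change cases", {
  # 100 glycine codons, one third-position transition: purely synonymous
  a <- nt_to_codons(paste(rep("GGA", 100), collapse = ""))[[1]]
  b <- a; b[50] <- nt_to_codons("GGG")[[1]]
  r <- li93(a, b)
  expect_equal(r$ka, 0)
  expect_equal(r$ks, 0.5 * log(1 / 0.98), tolerance = 1e-12)
  expect_equal(unname(r$L), c(200, 0, 100))
  # identical sequences
  r0 <- li93(a, a)
  expect_equal(c(r0$ka, r0$ks, r0$ks_sd), c(0, 0, 0))
})

test_that("li93 agrees with the brute-force degeneracy oracle", {
  set.seed(101)
  for (rep in 1:25) {
    cs <- random_codon_strings(60)
    cs2 <- mutate_codons(cs, rpois(1, 12))
    r <- li93(nt_to_codons(paste(cs, collapse = ""))[[1]],
              nt_to_codons(paste(cs2, collapse = ""))[[1]])
    o <- oracle_li93(cs, cs2)
    expect_equal(r$saturated, o$saturated)
    if (!o$saturated) {
      expect_equal(r$ks, o$ks, tolerance = 1e-10)
      expect_equal(r$ka, o$ka, tolerance = 1e-10)
      expect_equal(r$ks_sd, o$ks_sd, tolerance = 1e-5)
    }
  }
})

test_that("li93 is symmetric and rejects degenerate input", {
  set.seed(5)
  for (rep in 1:20) {
    cs <- random_codon_strings(50)
    cs2 <- mutate_codons(cs, 8)
    x <- nt_to_codons(paste(cs, collapse = ""))[[1]]
    y <- nt_to_codons(paste(cs2, collapse = ""))[[1]]
    r1 <- li93(x, y); r2 <- li93(y, x)
    expect_equal(r1$ks, r2$ks)
    expect_equal(r1$ka, r2$ka)
    expect_equal(r1$ks_sd, r2$ks_sd)
  }
  expect_error(li93(integer(0), integer(0)), "empty")
  expect_error(li93(nt_to_codons("TAA")[[1]], nt_to_codons("TAC")[[1]]),
               "stop codons")
})

test_that("saturated pairs are flagged rather than estimated", {
  set.seed(9)
  a <- nt_to_codons(paste(random_codon_strings(100), collapse = ""))[[1]]
  b <- nt_to_codons(paste(random_codon_strings(100), collapse = ""))[[1]]
  r <- li93(a, b)   # unrelated sequences: corrections overflow
  expect_true(r$saturated)
  expect_true(is.na(r$ks))
})

test_that("li93 stays close to the seqinr implementation", {
  skip_if_not_installed("seqinr")
  set.seed(42)
  dks <- dka <- numeric(0)
  for (rep in 1:30) {
    cs <- random_codon_strings(150)
    cs2 <- mutate_codons(cs, rpois(1, 20))
    r <- li93(nt_to_codons(paste(cs, collapse = ""))[[1]],
              nt_to_codons(paste(cs2, collapse = ""))[[1]])
    aln <- seqinr::as.alignment(2, c("a", "b"),
                                tolower(c(paste(cs, collapse = ""),
                                          paste(cs2, collapse = ""))))
    sq <- seqinr::kaks(aln)
    if (sq$ks >= 0 && sq$ks < 5) {
      dks <- c(dks, r$ks - as.numeric(sq$ks))
      dka <- c(dka, r$ka - as.numeric(sq$ka))
    }
  }
  # conventions differ in detail (site-class tables); agreement is close
  expect_lt(max(abs(dks)), 0.03)
  expect_lt(max(abs(dka)), 0.02)
})

test_that("codon projection respects frames, gaps and phase re-derivation", {
  set.seed(11)
  cs <- random_codon_strings(100)
  seq_a <- paste(cs, collapse = "")
  frames <- data.frame(start = 0L, end = 300L, phase = 0L)
  aln0 <- list(astart = 0L, bstart = 0L, a = seq_a, b = seq_a)
  cp <- codon_project(seq_a, seq_a, frames, frames, aln0)
  expect_equal(cp$n_codons, 100L)

  # 1-bp gap inside codon 50 of copy a: that codon is dropped and downstream
  # codons re-phase from copy b's own frame map
  ga <- paste0(substr(seq_a, 1, 148), "-", substr(seq_a, 150, 300))
  aln1 <- list(astart = 0L, bstart = 0L, a = ga, b = seq_a)
  seq_a_del <- paste0(substr(seq_a, 1, 148), substr(seq_a, 150, 300))
  frames_a <- data.frame(start = c(0L, 148L), end = c(148L, 299L),
                         phase = c(0L, 2L))
  cp1 <- codon_project(seq_a_del, seq_a, frames_a, frames, aln1)
  expect_equal(cp1$n_codons, 99L)

  # frames offset by one: no within-codon position ever agrees
  frames_off <- data.frame(start = 0L, end = 300L, phase = 1L)
  cp2 <- codon_project(seq_a, seq_a, frames_off, frames, aln0)
  expect_equal(cp2$n_codons, 0L)

  # non-coding region: empty result, not an error
  cp3 <- codon_project(seq_a, seq_a,
                       frames[0, ], frames, aln0)
  expect_equal(cp3$n_codons, 0L)
})

test_that("the gapless fast path equals the general projector", {
  set.seed(13)
  cs <- random_codon_strings(120)
  s1 <- paste(cs, collapse = "")
  s2 <- paste(mutate_codons(cs, 15), collapse = "")
  copies <- data.frame(copy_id = c("c1", "c2"), stringsAsFactors = FALSE)
  copies$sequence <- c(s1, s2)
  copies$frames <- list(data.frame(start = 0L, end = 360L, phase = 0L),
                        data.frame(start = 0L, end = 360L, phase = 0L))
  # offset alignment starting mid-codon: qstart 5 on c1, sstart 8 on c2
  hits <- data.frame(qseqid = "c1", sseqid = "c2", gapopen = 0L,
                     qstart = 5L, qend = 300L, sstart = 8L, send = 303L,
                     stringsAsFactors = FALSE)
  ann <- batch_kaks(hits, copies)
  aln <- list(astart = 4L, bstart = 7L,
              a = substr(s1, 5, 300), b = substr(s2, 8, 303))
  cp <- codon_project(s1, s2, copies$frames[[1]], copies$frames[[2]], aln)
  expect_equal(ann$n_codons, cp$n_codons)
  r <- li93(cp$codons_a, cp$codons_b)
  expect_equal(ann$ks, r$ks)
  expect_equal(ann$ka, r$ka)
})

test_that("batch annotation is element-wise, deterministic, and keyed", {
  ds <- simulate_dataset(demo_sim_config(1, seed = 2, n_core_genes = 0))
  hits <- head(ds$hits, 30)
  a1 <- batch_kaks(hits, ds$copies)
  a2 <- batch_kaks(hits, ds$copies)
  expect_identical(a1, a2)
  one <- batch_kaks(hits[7, , drop = FALSE], ds$copies)
  expect_equal(one$ks, a1$ks[7])
  bad <- hits; bad$qseqid[1] <- "missing_copy"
  expect_error(batch_kaks(bad, ds$copies), "absent")
})
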