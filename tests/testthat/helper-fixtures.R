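# Small constructors shared by the unit tests.

toy_tree <- function() parse_timetree("((A:10,B:10):30,C:40);")

# a minimal hit table with the columns the cluster/evaluate/count stages use
make_hits <- function(copy_a, copy_b, pident = 90,
                      ks = 0.1, theta = 0.5, n_codons = 200L,
                      species_a = sub("\\..*$", "", copy_a),
                      species_b = sub("\\..*$", "", copy_b),
                      superfamily = "SF", community = "cm1") {
  n <- length(copy_a)
  data.frame(
    hit_id = sprintf("h%05d", seq_len(n)),
    qseqid = copy_a, sseqid = copy_b,
    copy_a = copy_a, copy_b = copy_b,
    qspecies = species_a, sspecies = species_b,
    pident = rep_len(pident, n), length = 600L,
    mismatch = 0L, gapopen = 0L, qstart = 1L, qend = 600L,
    sstart = 1L, send = 600L, evalue = 0, bitscore = 1000,
    ks = rep_len(ks, n), ks_sd = 0.01, n_codons = rep_len(n_codons, n),
    theta = rep_len(theta, n),
    superfamily = superfamily, community = rep_len(community, n),
    stringsAsFactors = FALSE)
}

make_group <- function(id, hits, copies_a, copies_b,
                       retrieved_a = character(0),
                       retrieved_b = character(0), theta = 0.5) {
  structure(list(
    id = id, superfamily = hits$superfamily[1L],
    communities = unique(hits$community),
    hit_ids = hits$hit_id,
    copies_a = copies_a, copies_b = copies_b,
    species_a = sort(unique(sub("\\..*$", "", copies_a))),
    species_b = sort(unique(sub("\\..*$", "", copies_b))),
    ks = hits$ks, pid = hits$pident, theta = theta,
    retrieved_a = retrieved_a, retrieved_b = retrieved_b),
    class = "hit_group")
}

make_identities <- function(copy1, copy2, pid, aln_len = 300L) {
  data.frame(copy1 = copy1, copy2 = copy2, pid = pid,
             aln_len = rep_len(aln_len, length(copy1)),
             species1 = sub("\\..*$", "", copy1),
             species2 = sub("\\..*$", "", copy2),
             clade = NA_character_, superfamily = "SF", family = "SF_f1",
             stringsAsFactors = FALSE)
}

# random sense-codon strings for the Ka/Ks oracle comparisons
random_codon_strings <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sense <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))
  sense <- chartr("U", "T", sense)
  sample(sense, n, replace = TRUE)
}

# mutate codon strings with k random single-base changes, avoiding stops
mutate_codons <- function(codons, k) {
  for (i in seq_len(k)) {
    repeat {
      j <- sample(length(codons), 1L)
      pos <- sample(3L, 1L)
      b <- sample(setdiff(c("A", "C", "G", "T"),
                          substr(codons[j], pos, pos)), 1L)
      cand <- codons[j]
      substr(cand, pos, pos) <- b
      if (oracle_translate(cand) != "*") { codons[j] <- cand; break }
    }
  }
  codons
}
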