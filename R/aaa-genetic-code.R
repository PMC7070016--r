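# Codon machinery shared by the simulator and the Ka/Ks estimator.
#
# Codons are stored as integer indices 1..64 with bases ordered T, C, A, G
# (first base most significant), so index = 16*(b1-1) + 4*(b2-1) + b3.
# All lookup tables below are computed once at install time.

.BASES <- c("T", "C", "A", "G")

# Standard genetic code in TCAG nested order (TTT, TTC, TTA, TTG, TCT, ...).
.AA64 <- strsplit(
  "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
  ""
)[[1L]]

.CODON_STRINGS <- paste0(
  rep(.BASES, each = 16L),
  rep(rep(.BASES, each = 4L), 4L),
  rep(.BASES, 16L)
)
names(.AA64) <- .CODON_STRINGS
.STOP_CODONS <- which(.AA64 == "*")

# Base of codon `cod` at position `pos` (1..3), as integer 1..4.
codon_base <- function(cod, pos) {
  ((cod - 1L) %/% 4L^(3L - pos)) %% 4L + 1L
}

# Replace base at `pos` with integer base `b` (1..4).
codon_set_base <- function(cod, pos, b) {
  old <- codon_base(cod, pos)
  cod + (b - old) * 4L^(3L - pos)
}

# TRUE when the two integer bases differ by a transition (T<->C, A<->G).
is_transition <- function(b1, b2) {
  # purines are 3,4 (A,G); pyrimidines 1,2 (T,C)
  b1 != b2 & ((b1 <= 2L) == (b2 <= 2L))
}

# Degeneracy class (0, 2 or 4) of every codon x position, from the number of
# synonymous single-base changes: 0 synonymous -> nondegenerate, 3 -> fourfold,
# otherwise twofold (threefold-degenerate Ile sites counted as twofold, per
# Li's convention).  Changes creating stop codons count as nonsynonymous.
.DEG_CLASS <- local({
  m <- matrix(NA_integer_, nrow = 64L, ncol = 3L)
  for (cod in seq_len(64L)) {
    if (.AA64[cod] == "*") next
    for (pos in 1:3) {
      b0 <- codon_base(cod, pos)
      syn <- 0L
      for (b in seq_len(4L)[-b0]) {
        alt <- codon_set_base(cod, pos, b)
        if (.AA64[alt] != "*" && .AA64[alt] == .AA64[cod]) syn <- syn + 1L
      }
      m[cod, pos] <- if (syn == 0L) 0L else if (syn == 3L) 4L else 2L
    }
  }
  m
})

# Per-codon-pair contributions to Li's site and difference counts.
# Row index for pair (a, b): (a-1)*64 + b.  Columns are the classes 0/2/4.
# A site contributes 0.5 to each codon's own class; a differing position
# contributes 0.5 transitional or transversional weight to each class.
.PAIR_TABLES <- local({
  L  <- matrix(0, nrow = 64L * 64L, ncol = 3L)
  TS <- matrix(0, nrow = 64L * 64L, ncol = 3L)
  TV <- matrix(0, nrow = 64L * 64L, ncol = 3L)
  cls_col <- function(cl) match(cl, c(0L, 2L, 4L))
  for (a in seq_len(64L)) {
    if (.AA64[a] == "*") next
    for (b in seq_len(64L)) {
      if (.AA64[b] == "*") next
      row <- (a - 1L) * 64L + b
      for (pos in 1:3) {
        ca <- cls_col(.DEG_CLASS[a, pos])
        cb <- cls_col(.DEG_CLASS[b, pos])
        L[row, ca] <- L[row, ca] + 0.5
        L[row, cb] <- L[row, cb] + 0.5
        ba <- codon_base(a, pos)
        bb <- codon_base(b, pos)
        if (ba != bb) {
          if (is_transition(ba, bb)) {
            TS[row, ca] <- TS[row, ca] + 0.5
            TS[row, cb] <- TS[row, cb] + 0.5
          } else {
            TV[row, ca] <- TV[row, ca] + 0.5
            TV[row, cb] <- TV[row, cb] + 0.5
          }
        }
      }
    }
  }
  list(L = L, TS = TS, TV = TV, ALL = cbind(L, TS, TV))
})

#' Convert nucleotide strings to integer codon vectors
#'
#' @param x character vector of nucleotide sequences (A/C/G/T, case
#'   insensitive); each length must be a multiple of 3.
#' @return list of integer vectors with values in 1..64; positions containing
#'   ambiguous bases yield NA codons.
#' @export
nt_to_codons <- function(x) {
  lapply(x, function(s) {
    b <- match(strsplit(toupper(s), "")[[1L]], .BASES)
    n <- length(b)
    if (n %% 3L != 0L)
      stop("sequence length ", n, " is not a multiple of 3")
    dim(b) <- c(3L, n %/% 3L)
    (b[1L, ] - 1L) * 16L + (b[2L, ] - 1L) * 4L + b[3L, ]
  })
}

#' Convert integer codon vectors back to a nucleotide string
#' @param cod integer vector of codon indices (1..64)
#' @return single nucleotide string
#' @export
codons_to_nt <- function(cod) {
  paste(.CODON_STRINGS[cod], collapse = "")
}

# Amino acid letters for codon indices ('*' for stops).
codon_aa <- function(cod) .AA64[cod]

# 64x64 table (flattened) of identical nucleotide positions between codons
.NTMATCH64 <- local({
  m <- integer(64L * 64L)
  for (a in seq_len(64L)) for (b in seq_len(64L)) {
    cnt <- 0L
    for (pos in 1:3)
      if (codon_base(a, pos) == codon_base(b, pos)) cnt <- cnt + 1L
    m[(a - 1L) * 64L + b] <- cnt
  }
  m
})

# Per codon x position: number of single-base alternatives that create a
# stop, and that are valid (non-stop) nonsynonymous changes.  Used by the
# simulator to keep the realized Ka/Ks at its target: the nonsynonymous
# flux lost to stop rejection is redistributed onto the remaining
# nonsynonymous alternatives of the same site.
.STOP_ALT <- local({
  ns <- matrix(0L, 64L, 3L)
  ok <- matrix(0L, 64L, 3L)
  tg <- array(NA_integer_, c(64L, 3L, 3L))
  for (cod in seq_len(64L)) {
    if (.AA64[cod] == "*") next
    for (pos in 1:3) {
      b0 <- codon_base(cod, pos)
      for (b in seq_len(4L)[-b0]) {
        alt <- codon_set_base(cod, pos, b)
        if (.AA64[alt] == "*") ns[cod, pos] <- ns[cod, pos] + 1L
        else if (.AA64[alt] != .AA64[cod]) {
          ok[cod, pos] <- ok[cod, pos] + 1L
          tg[cod, pos, ok[cod, pos]] <- alt
        }
      }
    }
  }
  list(n_stop = ns, n_ok = ok, targets = tg)
})
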