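# Pairwise Ka/Ks by Li's (1993) degeneracy-class method, on codon alignments
# reconstructed from nucleotide alignments and protein-anchored reading frames.

#' Pairwise Ka and Ks by Li's (1993) method
#'
#' Estimates synonymous (Ks) and non-synonymous (Ka) divergence between two
#' aligned, gap-free codon sequences.  Each codon position is classified as
#' nondegenerate, twofold or fourfold degenerate from the standard genetic
#' code; the class of a site in a codon pair is the average of the two codons'
#' classes.  Transitional (P) and transversional (Q) difference proportions
#' per class are corrected with Kimura's two-parameter formulas
#' \eqn{A_i = \frac12\ln\frac{1}{1-2P_i-Q_i} - \frac14\ln\frac{1}{1-2Q_i}} and
#' \eqn{B_i = \frac12\ln\frac{1}{1-2Q_i}}, then combined as
#' \eqn{Ks = (L_2 A_2 + L_4 A_4)/(L_2+L_4) + B_4} and
#' \eqn{Ka = A_0 + (L_0 B_0 + L_2 B_2)/(L_0+L_2)}.
#' The standard deviation of Ks is obtained by the delta method from the
#' multinomial sampling variance of the \eqn{(P_i, Q_i)}.
#'
#' @param codons_a,codons_b integer codon vectors (see [nt_to_codons()]) of
#'   equal length, without stop codons or NA.
#' @return list of class `li93` with elements `ka`, `ks`, `ks_sd`,
#'   `n_codons`, `L` (site counts per class), `P`, `Q`, `A`, `B` (per-class
#'   statistics, classes 0/2/4), and `saturated` (TRUE when a logarithm
#'   argument was non-positive, in which case `ka`/`ks` are NA).
#' @export
li93 <- function(codons_a, codons_b) {
  n <- length(codons_a)
  if (length(codons_b) != n)
    stop("codon vectors differ in length")
  if (n == 0L)
    stop("cannot estimate Ka/Ks on an empty codon alignment")
  if (anyNA(codons_a) || anyNA(codons_b))
    stop("NA codons in input")
  if (any(codon_aa(codons_a) == "*") || any(codon_aa(codons_b) == "*"))
    stop("stop codons in input")

  rows <- (codons_a - 1L) * 64L + codons_b
  agg <- colSums(.PAIR_TABLES$ALL[rows, , drop = FALSE])
  L  <- agg[1:3]
  TS <- agg[4:6]
  TV <- agg[7:9]

  P <- ifelse(L > 0, TS / L, 0)
  Q <- ifelse(L > 0, TV / L, 0)

  arg_a <- 1 - 2 * P - Q   # argument of the transitional log
  arg_b <- 1 - 2 * Q       # argument of the transversional log
  saturated <- any(L > 0 & (arg_a <= 0 | arg_b <= 0))

  out <- list(
    ka = NA_real_, ks = NA_real_, ks_sd = NA_real_,
    n_codons = n,
    L = stats::setNames(L, c("L0", "L2", "L4")),
    P = P, Q = Q, A = rep(NA_real_, 3L), B = rep(NA_real_, 3L),
    saturated = saturated
  )
  class(out) <- "li93"
  if (saturated) return(out)

  a <- 1 / arg_a
  b <- 1 / arg_b
  A <- 0.5 * log(a) - 0.25 * log(b)
  B <- 0.5 * log(b)
  A[L == 0] <- 0
  B[L == 0] <- 0
  out$A <- A
  out$B <- B

  L0 <- L[1L]; L2 <- L[2L]; L4 <- L[3L]
  ks <- if (L2 + L4 > 0) (L2 * A[2L] + L4 * A[3L]) / (L2 + L4) + B[3L] else NA_real_
  ka <- if (L0 + L2 > 0) A[1L] + (L0 * B[1L] + L2 * B[2L]) / (L0 + L2) else NA_real_

  # Delta-method variance of Ks in (P2, Q2, P4, Q4); classes independent,
  # within a class Var(P) = P(1-P)/L, Var(Q) = Q(1-Q)/L, Cov(P,Q) = -PQ/L.
  w2 <- if (L2 + L4 > 0) L2 / (L2 + L4) else 0
  w4 <- if (L2 + L4 > 0) L4 / (L2 + L4) else 0
  # dA/dP = a, dA/dQ = (a - b)/2, dB/dQ = b
  g <- list(
    c(P = w2 * a[2L], Q = w2 * (a[2L] - b[2L]) / 2),            # class 2
    c(P = w4 * a[3L], Q = w4 * (a[3L] - b[3L]) / 2 + b[3L])     # class 4
  )
  vks <- 0
  for (k in 1:2) {
    i <- k + 1L
    if (L[i] == 0) next
    vP <- P[i] * (1 - P[i]) / L[i]
    vQ <- Q[i] * (1 - Q[i]) / L[i]
    cPQ <- -P[i] * Q[i] / L[i]
    gr <- g[[k]]
    vks <- vks + gr["P"]^2 * vP + gr["Q"]^2 * vQ + 2 * gr["P"] * gr["Q"] * cPQ
  }

  out$ks <- unname(ks)
  out$ka <- unname(ka)
  out$ks_sd <- sqrt(unname(vks))
  out
}

#' @export
print.li93 <- function(x, ...) {
  cat(sprintf("Li (1993) pairwise rates over %d codons\n", x$n_codons))
  if (x$saturated) {
    cat("  saturated (a correction logarithm was undefined); Ka/Ks are NA\n")
  } else {
    cat(sprintf("  Ka = %.5f   Ks = %.5f (sd %.5f)   Ka/Ks = %s\n",
                x$ka, x$ks, x$ks_sd,
                if (isTRUE(x$ks > 0)) sprintf("%.4f", x$ka / x$ks) else "NA"))
  }
  cat(sprintf("  sites: L0 = %.1f, L2 = %.1f, L4 = %.1f\n",
              x$L[1L], x$L[2L], x$L[3L]))
  invisible(x)
}

#' Reconstruct a codon-level pairwise alignment from a nucleotide alignment
#'
#' Projects an aligned pair of TE regions onto codons using each copy's own
#' protein-anchored frame annotation.  A codon (triplet of consecutive copy-a
#' coding positions with phases 0,1,2 in one frame segment) is retained only
#' when all three of its alignment columns pair a copy-a base with a copy-b
#' base, both bases fall inside annotated frame segments, the two copies'
#' within-codon phases agree at every column, the copy-b positions are
#' likewise three consecutive in-frame positions, neither triplet contains an
#' ambiguous base, and neither codon is a stop.  Phases are always re-derived
#' from the frame maps, so an interior indel never lets phase drift corrupt
#' downstream codons.
#'
#' @param seq_a,seq_b nucleotide sequences of the two copies (full copies,
#'   not the aligned region).
#' @param frames_a,frames_b data frames with columns `start`, `end` (0-based
#'   half-open copy coordinates) and `phase` (0..2, phase of the segment's
#'   first base within its codon); rows must not overlap.
#' @param aln list with `astart`, `bstart` (0-based offsets of the aligned
#'   region in each copy) and `a`, `b` (equal-length aligned strings, gaps as
#'   `-`).
#' @return list with integer codon vectors `codons_a`, `codons_b` and
#'   `n_codons`; `n_codons = 0` when no codon survives (not an error).
#' @export
codon_project <- function(seq_a, seq_b, frames_a, frames_b, aln) {
  ca <- strsplit(toupper(aln$a), "")[[1L]]
  cb <- strsplit(toupper(aln$b), "")[[1L]]
  if (length(ca) != length(cb))
    stop("aligned strings differ in length")
  ncol_ <- length(ca)
  # 0-based coordinate of each alignment column in each copy (NA at gaps)
  pos_a <- cumsum(ca != "-") - 1L + aln$astart
  pos_a[ca == "-"] <- NA_integer_
  pos_b <- cumsum(cb != "-") - 1L + aln$bstart
  pos_b[cb == "-"] <- NA_integer_

  phase_of <- function(pos, frames) {
    # phase (0..2) of each 0-based position under its frame segment; NA outside
    out <- rep(NA_integer_, length(pos))
    seg <- rep(NA_integer_, length(pos))
    for (i in seq_len(nrow(frames))) {
      inside <- !is.na(pos) & pos >= frames$start[i] & pos < frames$end[i]
      if (any(inside & !is.na(seg)))
        stop("overlapping frame segments in annotation")
      out[inside] <- (pos[inside] - frames$start[i] + frames$phase[i]) %% 3L
      seg[inside] <- i
    }
    list(phase = out, seg = seg)
  }
  fa <- phase_of(pos_a, frames_a)
  fb <- phase_of(pos_b, frames_b)

  good <- !is.na(pos_a) & !is.na(pos_b) &
    !is.na(fa$phase) & !is.na(fb$phase) &
    fa$phase == fb$phase &
    ca %in% .BASES & cb %in% .BASES

  # candidate codon starts: good columns with phase 0 followed by two good
  # columns of phases 1, 2 that are consecutive in BOTH copies and in the
  # same frame segment on each side
  keep_a <- integer(0)
  keep_b <- integer(0)
  i <- 1L
  while (i <= ncol_ - 2L) {
    if (good[i] && fa$phase[i] == 0L &&
        good[i + 1L] && good[i + 2L] &&
        fa$phase[i + 1L] == 1L && fa$phase[i + 2L] == 2L &&
        pos_a[i + 1L] == pos_a[i] + 1L && pos_a[i + 2L] == pos_a[i] + 2L &&
        pos_b[i + 1L] == pos_b[i] + 1L && pos_b[i + 2L] == pos_b[i] + 2L &&
        fa$seg[i] == fa$seg[i + 2L] && fb$seg[i] == fb$seg[i + 2L]) {
      keep_a <- c(keep_a, i)
      i <- i + 3L
    } else {
      i <- i + 1L
    }
  }
  if (length(keep_a) == 0L)
    return(list(codons_a = integer(0), codons_b = integer(0), n_codons = 0L))

  idx <- function(chars, at) {
    b <- match(chars[c(rbind(at, at + 1L, at + 2L))], .BASES)
    dim(b) <- c(3L, length(at))
    (b[1L, ] - 1L) * 16L + (b[2L, ] - 1L) * 4L + b[3L, ]
  }
  cod_a <- idx(ca, keep_a)
  cod_b <- idx(cb, keep_a)
  ok <- codon_aa(cod_a) != "*" & codon_aa(cod_b) != "*"
  list(codons_a = cod_a[ok], codons_b = cod_b[ok],
       n_codons = sum(ok))
}

#' Annotate a hit table with Ka, Ks, Ks_sd and codon counts
#'
#' Runs [codon_project()] then [li93()] on every hit.  Gapless hits
#' (`gapopen == 0`) are projected directly from their BLAST coordinates;
#' gapped hits are realigned globally with `Biostrings::pairwiseAlignment()`
#' on the hit regions first.  Hits with no projectable codons get
#' `n_codons = 0` and NA rates; saturated estimates get NA rates (both are
#' removed later by the Ks filter).
#'
#' @param hits hit data frame (BLAST outfmt-6 columns, plus `hit_id`).
#' @param copies copy table as produced by the simulator or
#'   [read_copy_table()]: columns `copy_id`, `sequence`, and a `frames`
#'   attribute or list-column describing coding segments.  A copy without
#'   frame annotation is treated as non-coding (0 codons).
#' @return `hits` with columns `ka`, `ks`, `ks_sd`, `n_codons` filled.
#' @export
batch_kaks <- function(hits, copies) {
  seqs <- copies$sequence
  names(seqs) <- copies$copy_id
  frames <- copy_frames(copies)
  missing <- setdiff(unique(c(hits$qseqid, hits$sseqid)), copies$copy_id)
  if (length(missing) > 0L)
    stop("hits reference copies absent from the copy table: ",
         paste(utils::head(missing, 5L), collapse = ", "))

  # integer base vectors cached per copy for the gapless fast path
  nt_cache <- lapply(seqs, function(s) match(strsplit(toupper(s), "")[[1L]], .BASES))

  n <- nrow(hits)
  h_q <- hits$qseqid; h_s <- hits$sseqid
  h_qs <- hits$qstart; h_qe <- hits$qend
  h_ss <- hits$sstart; h_se <- hits$send
  h_go <- hits$gapopen
  ka <- ks <- sd <- rep(NA_real_, n)
  ncod <- integer(n)
  for (i in seq_len(n)) {
    q <- h_q[i]; s <- h_s[i]
    qs <- h_qs[i]; qe <- h_qe[i]
    ss <- h_ss[i]; se <- h_se[i]
    if (is.na(qs)) {  # coordinate-free hit: full-length comparison
      qs <- 1L; qe <- nchar(seqs[[q]]); ss <- 1L; se <- nchar(seqs[[s]])
    }
    gapless <- is.na(h_go[i]) || h_go[i] == 0
    cp <- NULL
    if (gapless) {
      cp <- project_gapless_fast(nt_cache[[q]], nt_cache[[s]],
                                 frames[[q]], frames[[s]],
                                 qs, qe, ss, se)
    }
    if (is.null(cp)) {
      rq <- substr(seqs[[q]], qs, qe)
      rs <- substr(seqs[[s]], ss, se)
      if (!gapless) {
        pa <- Biostrings::pairwiseAlignment(rq, rs, type = "global")
        aln <- list(astart = qs - 1L, bstart = ss - 1L,
                    a = as.character(Biostrings::alignedPattern(pa)),
                    b = as.character(Biostrings::alignedSubject(pa)))
      } else {
        aln <- list(astart = qs - 1L, bstart = ss - 1L, a = rq, b = rs)
      }
      cp <- codon_project(seqs[[q]], seqs[[s]],
                          frames[[q]], frames[[s]], aln)
    }
    ncod[i] <- cp$n_codons
    if (cp$n_codons > 0L) {
      r <- li93(cp$codons_a, cp$codons_b)
      ka[i] <- r$ka; ks[i] <- r$ks; sd[i] <- r$ks_sd
    }
  }
  hits$ka <- ka
  hits$ks <- ks
  hits$ks_sd <- sd
  hits$n_codons <- ncod
  hits
}

# Vectorized projection for the common case: a gapless hit whose query and
# subject regions each fall inside a single frame segment.  Returns NULL when
# the case does not apply (caller falls back to codon_project).
project_gapless_fast <- function(ba, bb, frames_a, frames_b,
                                 qs, qe, ss, se) {
  if (se - ss != qe - qs) return(NULL)          # not a positional alignment
  fa <- frames_a[frames_a$start <= qs - 1L & frames_a$end >= qe, , drop = FALSE]
  fb <- frames_b[frames_b$start <= ss - 1L & frames_b$end >= se, , drop = FALSE]
  if (nrow(fa) != 1L || nrow(fb) != 1L) {
    # region not fully inside one segment on both sides: only trivially empty
    # annotations can be short-circuited
    if (nrow(frames_a) == 0L || nrow(frames_b) == 0L)
      return(list(codons_a = integer(0), codons_b = integer(0), n_codons = 0L))
    return(NULL)
  }
  pha <- (qs - 1L - fa$start + fa$phase) %% 3L
  phb <- (ss - 1L - fb$start + fb$phase) %% 3L
  if (pha != phb)
    return(list(codons_a = integer(0), codons_b = integer(0), n_codons = 0L))
  shift <- (3L - pha) %% 3L
  aq <- qs + shift; as_ <- ss + shift
  len <- ((qe - aq + 1L) %/% 3L) * 3L
  if (len < 3L)
    return(list(codons_a = integer(0), codons_b = integer(0), n_codons = 0L))
  va <- ba[aq:(aq + len - 1L)]
  vb <- bb[as_:(as_ + len - 1L)]
  dim(va) <- dim(vb) <- c(3L, len %/% 3L)
  cod_a <- (va[1L, ] - 1L) * 16L + (va[2L, ] - 1L) * 4L + va[3L, ]
  cod_b <- (vb[1L, ] - 1L) * 16L + (vb[2L, ] - 1L) * 4L + vb[3L, ]
  ok <- !is.na(cod_a) & !is.na(cod_b) &
    codon_aa(cod_a) != "*" & codon_aa(cod_b) != "*"
  list(codons_a = cod_a[ok], codons_b = cod_b[ok], n_codons = sum(ok))
}

# Per-copy frame annotations as a named list of data frames (start, end,
# phase), from either a `frames` list-column or a `frames` attribute
# (data frame with copy_id, start, end, phase).
copy_frames <- function(copies) {
  if (!is.null(copies$frames)) {
    out <- copies$frames
    names(out) <- copies$copy_id
    return(out)
  }
  ft <- attr(copies, "frames")
  out <- vector("list", nrow(copies))
  names(out) <- copies$copy_id
  empty <- data.frame(start = integer(0), end = integer(0), phase = integer(0))
  for (id in copies$copy_id) out[[id]] <- empty
  if (!is.null(ft)) {
    for (id in unique(ft$copy_id))
      out[[id]] <- ft[ft$copy_id == id, c("start", "end", "phase")]
  }
  out
}

# Vectorized Li93 over many independent alignments at once: `group` labels
# each codon pair with its alignment; returns per-group ks/ka/ks_sd.
# Shares the formulas of li93(); kept in step with it (oracle-tested there).
li93_multi <- function(codons_a, codons_b, group) {
  rows <- (codons_a - 1L) * 64L + codons_b
  agg <- rowsum(.PAIR_TABLES$ALL[rows, , drop = FALSE], group)
  L  <- agg[, 1:3, drop = FALSE]
  P  <- agg[, 4:6, drop = FALSE] / L
  Q  <- agg[, 7:9, drop = FALSE] / L
  P[L == 0] <- 0; Q[L == 0] <- 0
  arg_a <- 1 - 2 * P - Q
  arg_b <- 1 - 2 * Q
  sat <- rowSums(L > 0 & (arg_a <= 0 | arg_b <= 0)) > 0
  arg_a[arg_a <= 0] <- NA_real_      # saturated rows are masked below
  arg_b[arg_b <= 0] <- NA_real_
  a <- 1 / arg_a; b <- 1 / arg_b
  A <- 0.5 * log(a) - 0.25 * log(b)
  B <- 0.5 * log(b)
  A[L == 0] <- 0; B[L == 0] <- 0
  L0 <- L[, 1L]; L2 <- L[, 2L]; L4 <- L[, 3L]
  ks <- (L2 * A[, 2L] + L4 * A[, 3L]) / (L2 + L4) + B[, 3L]
  ka <- A[, 1L] + (L0 * B[, 1L] + L2 * B[, 2L]) / (L0 + L2)
  w2 <- L2 / (L2 + L4); w4 <- L4 / (L2 + L4)
  vks <- numeric(nrow(L))
  for (k in 2:3) {
    w <- if (k == 2L) w2 else w4
    gP <- w * a[, k]
    gQ <- w * (a[, k] - b[, k]) / 2 + if (k == 3L) b[, k] else 0
    ok <- L[, k] > 0
    vP <- P[, k] * (1 - P[, k]) / L[, k]
    vQ <- Q[, k] * (1 - Q[, k]) / L[, k]
    cPQ <- -P[, k] * Q[, k] / L[, k]
    add <- gP^2 * vP + gQ^2 * vQ + 2 * gP * gQ * cPQ
    vks[ok] <- vks[ok] + add[ok]
  }
  ks[sat] <- NA_real_; ka[sat] <- NA_real_; vks[sat] <- NA_real_
  data.frame(group = rownames(agg), ks = ks, ka = ka,
             ks_sd = sqrt(vks), saturated = sat,
             row.names = NULL, stringsAsFactors = FALSE)
}
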