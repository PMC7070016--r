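# Independent oracles, written as literal brute force against the published
# formulas; they share no code with the implementations they check.

# genetic code for the oracle, built from Biostrings (not the package table)
.oracle_code <- local({
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- chartr("U", "T", names(gc))
  gc
})

oracle_translate <- function(codon) unname(.oracle_code[codon])

# degeneracy class of one position of one codon, by explicit mutation
oracle_site_class_raw <- function(codon, pos) {
  from <- substr(codon, pos, pos)
  syn <- 0
  for (b in setdiff(c("A", "C", "G", "T"), from)) {
    mut <- codon
    substr(mut, pos, pos) <- b
    if (oracle_translate(mut) != "*" &&
        oracle_translate(mut) == oracle_translate(codon)) syn <- syn + 1
  }
  if (syn == 0) 0 else if (syn == 3) 4 else 2
}

# memoized over the oracle's own computation (62 sense codons x 3 positions)
.oracle_class_memo <- local({
  memo <- new.env(parent = emptyenv())
  function(codon, pos) {
    key <- paste0(codon, pos)
    v <- memo[[key]]
    if (is.null(v)) {
      v <- oracle_site_class_raw(codon, pos)
      memo[[key]] <- v
    }
    v
  }
})
oracle_site_class <- function(codon, pos) .oracle_class_memo(codon, pos)

oracle_is_transition <- function(b1, b2) {
  (b1 %in% c("A", "G") && b2 %in% c("A", "G")) ||
    (b1 %in% c("C", "T") && b2 %in% c("C", "T"))
}

# Li (1993) Ka/Ks by direct arithmetic on two codon-string vectors;
# numeric-gradient delta method for the Ks standard deviation
oracle_li93 <- function(codons1, codons2) {
  stopifnot(length(codons1) == length(codons2))
  L <- c(`0` = 0, `2` = 0, `4` = 0)
  ts <- c(`0` = 0, `2` = 0, `4` = 0)
  tv <- c(`0` = 0, `2` = 0, `4` = 0)
  for (i in seq_along(codons1)) {
    for (pos in 1:3) {
      c1 <- as.character(oracle_site_class(codons1[i], pos))
      c2 <- as.character(oracle_site_class(codons2[i], pos))
      L[c1] <- L[c1] + 0.5
      L[c2] <- L[c2] + 0.5
      b1 <- substr(codons1[i], pos, pos)
      b2 <- substr(codons2[i], pos, pos)
      if (b1 != b2) {
        w <- if (oracle_is_transition(b1, b2)) "ts" else "tv"
        if (w == "ts") { ts[c1] <- ts[c1] + 0.5; ts[c2] <- ts[c2] + 0.5 }
        else           { tv[c1] <- tv[c1] + 0.5; tv[c2] <- tv[c2] + 0.5 }
      }
    }
  }
  P <- ifelse(L > 0, ts / L, 0)
  Q <- ifelse(L > 0, tv / L, 0)
  kfun <- function(P, Q) {
    A <- 0.5 * log(1 / (1 - 2 * P - Q)) - 0.25 * log(1 / (1 - 2 * Q))
    B <- 0.5 * log(1 / (1 - 2 * Q))
    A[L == 0] <- 0; B[L == 0] <- 0
    ks <- (L["2"] * A["2"] + L["4"] * A["4"]) / (L["2"] + L["4"]) + B["4"]
    ka <- A["0"] + (L["0"] * B["0"] + L["2"] * B["2"]) / (L["0"] + L["2"])
    c(ks = unname(ks), ka = unname(ka))
  }
  base <- kfun(P, Q)
  if (any(L > 0 & (1 - 2 * P - Q <= 0 | 1 - 2 * Q <= 0)))
    return(list(ks = NA_real_, ka = NA_real_, ks_sd = NA_real_,
                saturated = TRUE))
  # numeric gradient of Ks in (P2,Q2,P4,Q4), multinomial covariances
  eps <- 1e-7
  grad <- numeric(4)
  park <- list(c("2", "P"), c("2", "Q"), c("4", "P"), c("4", "Q"))
  for (k in 1:4) {
    Pp <- P; Qp <- Q
    if (park[[k]][2] == "P") Pp[park[[k]][1]] <- Pp[park[[k]][1]] + eps
    else Qp[park[[k]][1]] <- Qp[park[[k]][1]] + eps
    grad[k] <- (kfun(Pp, Qp)["ks"] - base["ks"]) / eps
  }
  v <- 0
  for (cl in c("2", "4")) {
    if (L[cl] == 0) next
    iP <- if (cl == "2") 1 else 3
    vP <- P[cl] * (1 - P[cl]) / L[cl]
    vQ <- Q[cl] * (1 - Q[cl]) / L[cl]
    cv <- -P[cl] * Q[cl] / L[cl]
    v <- v + grad[iP]^2 * vP + grad[iP + 1]^2 * vQ +
      2 * grad[iP] * grad[iP + 1] * cv
  }
  list(ks = unname(base["ks"]), ka = unname(base["ka"]),
       ks_sd = unname(sqrt(v)), saturated = FALSE)
}

# histogram classes by direct application of Sturges' rule on pretty breaks
oracle_hist_classes <- function(x) {
  k <- ceiling(log2(length(x)) + 1)
  breaks <- pretty(range(x), n = k)
  counts <- integer(length(breaks) - 1)
  for (i in seq_along(counts)) {
    lo <- breaks[i]; hi <- breaks[i + 1]
    counts[i] <- if (i == 1) sum(x >= lo & x <= hi)
    else sum(x > lo & x <= hi)
  }
  list(breaks = breaks, counts = counts)
}

# exact one-sided signed-rank p-value by enumerating all sign patterns
oracle_signed_rank_p <- function(values, mu = 1) {
  d <- values - mu
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  total <- 0
  for (mask in 0:(2^n - 1)) {
    signs <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    w <- sum(r[signs])
    if (w <= w_obs) total <- total + 1
  }
  total / 2^n
}
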