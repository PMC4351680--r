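# Shared fixtures and independent oracle implementations.
# Oracles are deliberately written as plain transcriptions of the defining
# formulas (scalar loops, enumeration, grid search), separate from the
# package's vectorised code paths.

fixture_panel <- function() {
  read_breed_panel(system.file("extdata", "tables1_2.csv",
                               package = "adaptscan"))
}

fixture_climate <- function() {
  suppressWarnings(read_climate_table(
    system.file("extdata", "table8_climate.csv", package = "adaptscan")))
}

six_unlinked <- c("g.703_704del(2)A", "g.667_668insC", "g.666_667insC",
                  "g.601A>C", "g.522A>G", "g.516_517insG")

response_loci <- c("I-668" = "g.667_668insC", "I-667" = "g.666_667insC",
                   "G-660" = "g.660G>C", "A-601" = "g.601A>C",
                   "A-522" = "g.522A>G", "I-516" = "g.516_517insG")

retained_predictors <- c("LAT", "LON", "MINaT", "MThm", "ANT", "TW",
                         "TAR", "MxR", "MiR", "HrA")

fixture_responses <- function(panel = fixture_panel()) {
  af <- allele_freq(panel)[, response_loci]
  colnames(af) <- names(response_loci)
  af
}

# --- HWE oracle: direct factorial transcription of the conditional
#     distribution of heterozygote counts given allele counts
hwe_oracle <- function(n11, n12, n22) {
  n <- n11 + n12 + n22
  n1 <- 2 * n11 + n12
  if (n1 == 0 || n1 == 2 * n) return(1)
  hets <- seq(n1 %% 2, min(n1, 2 * n - n1), by = 2)
  pr <- sapply(hets, function(h) {
    a <- (n1 - h) / 2
    b <- n - a - h
    if (a < 0 || b < 0) return(0)
    exp(lfactorial(n) - lfactorial(a) - lfactorial(h) - lfactorial(b) +
          h * log(2) +
          lfactorial(n1) + lfactorial(2 * n - n1) - lfactorial(2 * n))
  })
  pr <- pr / sum(pr)
  obs <- pr[hets == n12]
  sum(pr[pr <= obs + 1e-12])
}

# --- Weir-Cockerham oracle: literal scalar transcription of the a/b/c
#     component formulas
wc_oracle <- function(counts) {
  counts <- matrix(counts, ncol = 3)
  r <- nrow(counts)
  n <- numeric(r); p <- numeric(r); h <- numeric(r)
  for (i in 1:r) {
    n[i] <- counts[i, 1] + counts[i, 2] + counts[i, 3]
    p[i] <- (2 * counts[i, 1] + counts[i, 2]) / (2 * n[i])
    h[i] <- counts[i, 2] / n[i]
  }
  nbar <- sum(n) / r
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- 0; hbar <- 0
  for (i in 1:r) { pbar <- pbar + n[i] * p[i]; hbar <- hbar + n[i] * h[i] }
  pbar <- pbar / (r * nbar); hbar <- hbar / (r * nbar)
  s2 <- 0
  for (i in 1:r) s2 <- s2 + n[i] * (p[i] - pbar)^2
  s2 <- s2 / ((r - 1) * nbar)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                        (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc, theta = a / (a + b + cc))
}

# --- LD oracle: 1-D grid search over the coupling fraction of double
#     heterozygotes, maximising the multinomial genotype likelihood
ld_grid_oracle <- function(g1, g2, grid = seq(0, 1, 1e-4)) {
  n <- length(g1)
  loglik <- function(f) {
    # f = c(f11, f12, f21, f22) haplotype freqs
    probs <- matrix(0, 3, 3)
    for (i in 0:2) for (j in 0:2) {
      pr <- 0
      # enumerate haplotype pairs compatible with genotype (i, j)
      haps <- expand.grid(a1 = 0:1, b1 = 0:1, a2 = 0:1, b2 = 0:1)
      for (k in seq_len(nrow(haps))) {
        hh <- haps[k, ]
        if (hh$a1 + hh$a2 == i && hh$b1 + hh$b2 == j) {
          idx1 <- 2 * (1 - hh$a1) + (1 - hh$b1) + 1
          idx2 <- 2 * (1 - hh$a2) + (1 - hh$b2) + 1
          pr <- pr + f[idx1] * f[idx2]
        }
      }
      probs[i + 1, j + 1] <- pr
    }
    ll <- 0
    for (k in seq_len(n)) {
      pk <- probs[g1[k] + 1, g2[k] + 1]
      ll <- ll + log(max(pk, 1e-300))
    }
    ll
  }
  tab <- table(factor(g1, 0:2), factor(g2, 0:2))
  dh <- tab["1", "1"]
  base <- c(2 * tab["2", "2"] + tab["2", "1"] + tab["1", "2"],
            2 * tab["2", "0"] + tab["2", "1"] + tab["1", "0"],
            2 * tab["0", "2"] + tab["0", "1"] + tab["1", "2"],
            2 * tab["0", "0"] + tab["0", "1"] + tab["1", "0"])
  best <- NULL; best_ll <- -Inf
  for (w in grid) {
    f <- (base + dh * c(w, 1 - w, 1 - w, w)) / (2 * n)
    ll <- loglik(f)
    if (ll > best_ll) { best_ll <- ll; best <- f }
  }
  best
}

# --- K2P closed form (independent of the T92 code path)
k2p_oracle <- function(P, Q) {
  -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))
}

# --- Tajima constants oracle: independent transcription
tajima_oracle <- function(n, S, pi) {
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# --- closed-form 2x2 likelihood-ratio statistic for binary x, binary y
g2x2_oracle <- function(y, x) {
  tab <- table(factor(y, 0:1), factor(x, sort(unique(x))))
  n <- sum(tab)
  g <- 0
  for (i in 1:2) for (j in 1:2) {
    e <- sum(tab[i, ]) * sum(tab[, j]) / n
    if (tab[i, j] > 0) g <- g + 2 * tab[i, j] * log(tab[i, j] / e)
  }
  g
}
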