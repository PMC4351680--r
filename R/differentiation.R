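#' Weir-Cockerham variance components for one biallelic locus
#'
#' Direct implementation of the 1984 method-of-moments estimator for
#' diploid data: `a` (among populations), `b` (among individuals within
#' populations) and `c` (within individuals), with theta = a / (a + b + c).
#' Observed heterozygote counts enter through `h_i`, so the estimator uses
#' the reconstructed genotype counts, not just allele frequencies.
#'
#' @param counts populations x 3 matrix of genotype counts
#'   `(n11, n12, n22)`; populations with zero individuals are dropped.
#' @return list `a`, `b`, `c`, `theta` (`theta` is `NA` when the locus is
#'   monomorphic across all populations).
#' @export
wc_components <- function(counts) {
  counts <- matrix(counts, ncol = 3)
  n_i <- rowSums(counts)
  counts <- counts[n_i > 0, , drop = FALSE]
  n_i <- n_i[n_i > 0]
  r <- length(n_i)
  if (r < 2) stop("need at least two populations with data")
  p_i <- (2 * counts[, 1] + counts[, 2]) / (2 * n_i)
  h_i <- counts[, 2] / n_i
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  if (pbar == 0 || pbar == 1)
    return(list(a = 0, b = 0, c = 0, theta = NA_real_))
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc, theta = a / (a + b + cc))
}

#' Multi-locus Weir-Cockerham FST for a breed panel
#'
#' Per-locus theta plus the global ratio-of-sums estimate
#' `sum(a) / sum(a + b + c)` over loci, together with the pooled expected
#' heterozygosity of each locus (the He that the outlier scan conditions
#' on).
#'
#' @param panel a `breed_panel`.
#' @param loci locus subset (default all).
#' @return list with `per_locus` data frame (`locus`, `He`, `fst`) and
#'   `global` (multilocus theta).
#' @export
fst_multilocus <- function(panel, loci = NULL) {
  loci <- if (is.null(loci)) panel$loci else match_loci(panel, loci)
  num <- den <- 0
  per <- lapply(loci, function(l) {
    cc <- matrix(panel$counts[, l, ], ncol = 3)
    w <- wc_components(cc)
    tot <- colSums(cc)
    he <- heterozygosity(tot)$He
    if (!is.na(w$theta)) {
      num <<- num + w$a
      den <<- den + w$a + w$b + w$c
    }
    data.frame(locus = l, He = he, fst = w$theta)
  })
  list(per_locus = do.call(rbind, per),
       global = if (den > 0) num / den else NA_real_)
}

#' Pairwise multi-locus FST matrix
#'
#' @param panel a `breed_panel`.
#' @param loci locus subset (default all).
#' @return symmetric breeds x breeds matrix of multilocus theta (ratio of
#'   summed components over loci); monomorphic pairs give 0.
#' @export
pairwise_fst <- function(panel, loci = NULL) {
  loci <- if (is.null(loci)) panel$loci else match_loci(panel, loci)
  nb <- length(panel$breeds)
  m <- matrix(0, nb, nb, dimnames = list(panel$breeds, panel$breeds))
  for (i in seq_len(nb - 1)) for (j in (i + 1):nb) {
    num <- den <- 0
    for (l in loci) {
      cc <- panel$counts[c(i, j), l, ]
      p <- (2 * cc[, 1] + cc[, 2]) / (2 * rowSums(cc))
      if (p[1] == p[2] && p[1] %in% c(0, 1)) next
      w <- wc_components(cc)
      if (is.na(w$theta)) next
      num <- num + w$a; den <- den + w$a + w$b + w$c
    }
    m[i, j] <- m[j, i] <- if (den > 0) num / den else 0
  }
  m
}

#' Reynolds distance matrix with optional permutation significance
#'
#' `D = -ln(1 - FST)` per breed pair, FST clipped to `[0, 1)` before the
#' transform (negative estimates print as distance 0).  Significance, when
#' requested, comes from permuting individuals (genotype rows, preserving
#' within-individual structure) between the two breeds and recomputing the
#' pairwise FST; `p = (1 + #{FST_perm >= FST_obs}) / (1 + n_perm)`.
#'
#' @param panel a `breed_panel`.
#' @param loci locus subset (default all).
#' @param n_perm permutations per pair (0 = skip significance; published
#'   analyses used 90,000).
#' @param alpha significance level recorded alongside the p-values.
#' @return list of class `reynolds_dist`: `D`, `fst`, `p` (or NULL),
#'   `alpha` and `summary` (mean/median/max/min over off-diagonal entries).
#' @export
reynolds_distance <- function(panel, loci = NULL, n_perm = 0, alpha = 0.05) {
  loci <- if (is.null(loci)) panel$loci else match_loci(panel, loci)
  fst <- pairwise_fst(panel, loci)
  fst_cl <- pmin(pmax(fst, 0), 1 - 1e-12)
  capped <- fst >= 1
  if (any(capped)) warning("FST = 1 for some pair; distance capped")
  D <- -log(1 - fst_cl)
  diag(D) <- 0
  p <- NULL
  if (n_perm > 0) {
    nb <- length(panel$breeds)
    p <- matrix(NA_real_, nb, nb, dimnames = dimnames(fst))
    for (i in seq_len(nb - 1)) for (j in (i + 1):nb) {
      obs <- fst[i, j]
      gi <- lapply(loci, function(l) rep(c(2L, 1L, 0L), panel$counts[i, l, ]))
      gj <- lapply(loci, function(l) rep(c(2L, 1L, 0L), panel$counts[j, l, ]))
      ni <- panel$n_animals[i]; nj <- panel$n_animals[j]
      ge <- length(loci)
      cnt <- 0L
      for (b in seq_len(n_perm)) {
        num <- den <- 0
        for (k in seq_len(ge)) {
          # genotypes (not alleles) are reassigned between the two samples;
          # loci are permuted independently because tabulated panels carry
          # no real multi-locus individuals to keep intact
          idx <- sample.int(ni + nj, ni)
          gg <- c(gi[[k]], gj[[k]])
          g1 <- gg[idx]; g2 <- gg[-idx]
          cc <- rbind(tabulate(3L - g1, 3L), tabulate(3L - g2, 3L))
          pp <- (2 * cc[, 1] + cc[, 2]) / (2 * rowSums(cc))
          if (pp[1] == pp[2] && pp[1] %in% c(0, 1)) next
          w <- wc_components(cc)
          if (is.na(w$theta)) next
          num <- num + w$a; den <- den + w$a + w$b + w$c
        }
        th <- if (den > 0) num / den else 0
        if (th >= obs) cnt <- cnt + 1L
      }
      p[i, j] <- p[j, i] <- (1 + cnt) / (1 + n_perm)
    }
  }
  off <- D[lower.tri(D)]
  structure(list(
    D = D, fst = fst, p = p, alpha = alpha,
    summary = c(mean = mean(off), median = stats::median(off),
                max = max(off), min = min(off))),
    class = "reynolds_dist")
}

#' @export
print.reynolds_dist <- function(x, ...) {
  cat("Reynolds distance matrix over", nrow(x$D), "populations\n")
  s <- x$summary
  cat(sprintf("off-diagonal: mean %.4f  median %.4f  max %.4f  min %.4f\n",
              s["mean"], s["median"], s["max"], s["min"]))
  if (!is.null(x$p))
    cat("pairs significant at", x$alpha, ":",
        sum(x$p[lower.tri(x$p)] < x$alpha), "/", sum(lower.tri(x$p)), "\n")
  invisible(x)
}

#' Write a square distance matrix in PHYLIP format
#' @param D symmetric numeric matrix with dimnames.
#' @param path output path.
#' @export
write_phylip <- function(D, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(format(nrow(D)), con)
  for (i in seq_len(nrow(D)))
    writeLines(paste(formatC(rownames(D)[i], width = -10),
                     paste(sprintf("%.6f", D[i, ]), collapse = " ")), con)
  invisible(path)
}

log_hyper_2x2 <- function(n11, r1, r2, c1) {
  # log conditional probability of a 2x2 table given margins
  n <- r1 + r2
  stats::dhyper(n11, c1, n - c1, r1, log = TRUE)
}

# single-locus Markov-chain estimate of the probability-ordering exact p
mc_exact_p <- function(a1, t1, t2, c1, mc_steps, dememorization) {
  lo <- max(0, c1 - t2); hi <- min(t1, c1)
  state <- a1
  lp_state <- log_hyper_2x2(state, t1, t2, c1)
  lp_obs <- lp_state
  total <- dememorization + mc_steps
  step <- sample(c(-1L, 1L), total, replace = TRUE)
  u <- stats::runif(total)
  hits <- 0L
  for (s in seq_len(total)) {
    cand <- state + step[s]
    if (cand >= lo && cand <= hi) {
      lp_new <- log_hyper_2x2(cand, t1, t2, c1)
      if (log(u[s]) < lp_new - lp_state) { state <- cand; lp_state <- lp_new }
    }
    if (s > dememorization && lp_state <= lp_obs + 1e-9) hits <- hits + 1L
  }
  (1 + hits) / (1 + mc_steps)
}

#' Exact test of population differentiation (Markov chain)
#'
#' Tests a random distribution of alleles between two populations across
#' loci (Raymond-Rousset style).  Each locus contributes a 2 x 2
#' populations x alleles contingency table.  Per locus the p-value is the
#' probability, over tables with the same margins, of a conditional
#' (hypergeometric) probability no larger than the observed one; for a
#' biallelic locus this equals the two-sided Fisher exact test and is
#' computed by enumeration (or, with `force_mc`, estimated by a Metropolis
#' chain of `mc_steps` samples after `dememorization` burn-in).  Across
#' loci the default global p combines the per-locus p-values by Fisher's
#' method; `combine = "chain"` instead runs one Metropolis chain over the
#' concatenated tables with the product-probability statistic, updating one
#' randomly chosen locus per step.
#'
#' @param counts1,counts2 loci x 3 genotype-count matrices (or vectors for
#'   one locus) for the two populations; alleles are counted from genotypes.
#' @param mc_steps Markov-chain samples (published setting 100,000).
#' @param dememorization burn-in steps (published setting 10,000).
#' @param combine multi-locus combination: `"fisher"` (default; Fisher's
#'   combined probability over the per-locus exact p-values, the
#'   population-genetics convention) or `"chain"` (one Metropolis chain
#'   over the concatenated tables with the product statistic).
#' @param force_mc estimate per-locus p-values by Markov chain even where
#'   enumeration is available (used to validate the chain against the
#'   closed form).
#' @return list with `p_global`, `p_locus` (per-locus two-sided p-values)
#'   and `n_polymorphic`.
#' @export
exact_differentiation_test <- function(counts1, counts2,
                                       mc_steps = 100000,
                                       dememorization = 10000,
                                       combine = c("fisher", "chain"),
                                       force_mc = FALSE) {
  combine <- match.arg(combine)
  counts1 <- matrix(counts1, ncol = 3)
  counts2 <- matrix(counts2, ncol = 3)
  stopifnot(nrow(counts1) == nrow(counts2))
  a1 <- 2 * counts1[, 1] + counts1[, 2]; t1 <- 2 * rowSums(counts1)
  a2 <- 2 * counts2[, 1] + counts2[, 2]; t2 <- 2 * rowSums(counts2)
  c1 <- a1 + a2                     # allele-1 margin
  poly <- c1 > 0 & c1 < t1 + t2
  p_locus <- rep(1, length(a1))
  for (k in which(poly)) {
    if (force_mc) {
      p_locus[k] <- mc_exact_p(a1[k], t1[k], t2[k], c1[k],
                               mc_steps, dememorization)
    } else {
      # exact two-sided Fisher by probability ordering
      lo <- max(0, c1[k] - t2[k]); hi <- min(t1[k], c1[k])
      lp <- log_hyper_2x2(lo:hi, t1[k], t2[k], c1[k])
      pr <- exp(lp - max(lp)); pr <- pr / sum(pr)
      obs <- a1[k] - lo + 1
      p_locus[k] <- min(1, sum(pr[pr <= pr[obs] * (1 + 1e-12)]))
    }
  }
  if (sum(poly) == 0)
    return(list(p_global = 1, p_locus = p_locus, n_polymorphic = 0L))
  if (sum(poly) == 1)
    return(list(p_global = p_locus[which(poly)], p_locus = p_locus,
                n_polymorphic = 1L))
  if (combine == "fisher") {
    stat <- -2 * sum(log(pmax(p_locus[poly], 1e-300)))
    return(list(
      p_global = stats::pchisq(stat, 2 * sum(poly), lower.tail = FALSE),
      p_locus = p_locus, n_polymorphic = sum(poly)))
  }

  # multi-locus chain on the concatenated tables
  ks <- which(poly)
  state <- a1[ks]
  lo <- pmax(0, c1[ks] - t2[ks]); hi <- pmin(t1[ks], c1[ks])
  lp_state <- vapply(seq_along(ks), function(i)
    log_hyper_2x2(state[i], t1[ks[i]], t2[ks[i]], c1[ks[i]]), 0)
  lp_obs <- sum(lp_state)
  total <- dememorization + mc_steps
  pick <- sample.int(length(ks), total, replace = TRUE)
  step <- sample(c(-1L, 1L), total, replace = TRUE)
  u <- stats::runif(total)
  hits <- 0L
  for (s in seq_len(total)) {
    i <- pick[s]
    cand <- state[i] + step[s]
    if (cand >= lo[i] && cand <= hi[i]) {
      lp_new <- log_hyper_2x2(cand, t1[ks[i]], t2[ks[i]], c1[ks[i]])
      if (log(u[s]) < lp_new - lp_state[i]) {
        state[i] <- cand; lp_state[i] <- lp_new
      }
    }
    if (s > dememorization && sum(lp_state) <= lp_obs + 1e-9)
      hits <- hits + 1L
  }
  list(p_global = (1 + hits) / (1 + mc_steps),
       p_locus = p_locus, n_polymorphic = length(ks))
}

#' Pairwise exact differentiation tests for a panel
#'
#' @param panel a `breed_panel`.
#' @param loci locus subset (default all).
#' @param mc_steps,dememorization chain settings per pair.
#' @param combine passed to [exact_differentiation_test()].
#' @return symmetric matrix of global p-values (diagonal NA).
#' @export
pairwise_exact_test <- function(panel, loci = NULL,
                                mc_steps = 100000, dememorization = 10000,
                                combine = "fisher") {
  loci <- if (is.null(loci)) panel$loci else match_loci(panel, loci)
  nb <- length(panel$breeds)
  p <- matrix(NA_real_, nb, nb, dimnames = list(panel$breeds, panel$breeds))
  for (i in seq_len(nb - 1)) for (j in (i + 1):nb) {
    r <- exact_differentiation_test(
      panel$counts[i, loci, , drop = TRUE],
      panel$counts[j, loci, , drop = TRUE],
      mc_steps = mc_steps, dememorization = dememorization,
      combine = combine)
    p[i, j] <- p[j, i] <- r$p_global
  }
  p
}

#' Histogram of significantly differentiated populations
#'
#' For each population, the number of other populations whose pairwise
#' differentiation p-value falls below `alpha`.
#'
#' @param pmat symmetric p-value matrix (diagonal ignored).
#' @param alpha significance level.
#' @return list with `counts` (named integer vector), `range` and `mean`.
#' @export
differentiation_histogram <- function(pmat, alpha = 0.05) {
  diag(pmat) <- NA
  counts <- apply(pmat, 1, function(r) sum(r < alpha, na.rm = TRUE))
  list(counts = counts, range = range(counts), mean = mean(counts))
}
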