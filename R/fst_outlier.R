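#' Simulate neutral loci under an island model
#'
#' The stationary allele-frequency distribution of an island model at
#' differentiation `F` is approximated by the Balding-Nichols beta: an
#' ancestral frequency `p0` is drawn uniformly on `(0.01, 0.99)`, each
#' population's frequency from `Beta(p0 (1-F)/F, (1-p0)(1-F)/F)`, and
#' genotypes from Hardy-Weinberg proportions at the population's sample
#' size.  Each simulated locus is summarised with the *same* estimators
#' applied to observed data: pooled expected heterozygosity and the
#' multi-population Weir-Cockerham theta.  Loci monomorphic in the total
#' sample are redrawn (up to 100 attempts each, then dropped).
#'
#' Randomness comes from R's global RNG; call `set.seed()` for
#' reproducibility.
#'
#' @param neutral_fst target differentiation, in (0, 1).
#' @param sample_sizes integer vector of per-population sample sizes
#'   (individuals).
#' @param n_loci number of loci to simulate.
#' @return data frame `He`, `fst`, one row per locus.
#' @export
simulate_null_fst <- function(neutral_fst, sample_sizes, n_loci) {
  stopifnot(neutral_fst > 0, neutral_fst < 1, all(sample_sizes > 0))
  r <- length(sample_sizes)
  draw <- function(m) {
    p0 <- stats::runif(m, 0.01, 0.99)
    shape_scale <- (1 - neutral_fst) / neutral_fst
    n11 <- n12 <- matrix(0L, m, r)
    for (k in seq_len(r)) {
      p <- stats::rbeta(m, p0 * shape_scale, (1 - p0) * shape_scale)
      ni <- sample_sizes[k]
      aa <- stats::rbinom(m, ni, p^2)
      het_p <- ifelse(p < 1, 2 * p * (1 - p) / (1 - p^2), 0)
      ab <- stats::rbinom(m, ni - aa, pmin(het_p, 1))
      n11[, k] <- aa; n12[, k] <- ab
    }
    list(n11 = n11, n12 = n12)
  }
  he <- fst <- rep(NA_real_, n_loci)
  filled <- 0L
  attempt <- 0L
  while (filled < n_loci && attempt < 100L) {
    attempt <- attempt + 1L
    m <- n_loci - filled
    d <- draw(m)
    st <- wc_theta_rows(d$n11, d$n12, sample_sizes)
    ok <- !is.na(st$theta)
    k <- sum(ok)
    if (k) {
      he[filled + seq_len(k)] <- st$He[ok]
      fst[filled + seq_len(k)] <- st$theta[ok]
      filled <- filled + k
    }
  }
  data.frame(He = he[seq_len(filled)], fst = fst[seq_len(filled)])
}

# vectorised Weir-Cockerham theta for many loci at once;
# n11/n12: loci x pops genotype-count matrices, n: pop sizes
wc_theta_rows <- function(n11, n12, n) {
  r <- length(n)
  nmat <- matrix(n, nrow(n11), r, byrow = TRUE)
  p_i <- (2 * n11 + n12) / (2 * nmat)
  h_i <- n12 / nmat
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- rowSums(nmat * p_i) / (r * nbar)
  s2 <- rowSums(nmat * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(nmat * h_i) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  theta <- a / (a + b + cc)
  theta[pbar == 0 | pbar == 1] <- NA_real_
  list(theta = theta, He = 2 * pbar * (1 - pbar))
}

#' Conditional lower-tail probability of an observed FST
#'
#' Among simulated loci whose expected heterozygosity lies within
#' `bandwidth` of the observed locus's He (band widened by half its width
#' until at least `min_neighbors` simulated loci qualify), the fraction
#' with simulated FST below the observed value; ties count half.
#'
#' @param he_obs,fst_obs observed locus summary.
#' @param sim data frame from [simulate_null_fst()].
#' @param bandwidth initial He half-width (default 0.05).
#' @param min_neighbors minimum simulated neighbours (default 200).
#' @return `p_lower` in `[0, 1]`; `NA` (with warning) when `he_obs` is 0.
#' @export
conditional_p <- function(he_obs, fst_obs, sim, bandwidth = 0.05,
                          min_neighbors = 200) {
  if (he_obs == 0) {
    warning("observed He = 0; conditional p undefined")
    return(NA_real_)
  }
  bw <- bandwidth
  repeat {
    nb <- abs(sim$He - he_obs) <= bw
    if (sum(nb) >= min_neighbors || bw > 1) break
    bw <- bw * 1.5
  }
  f <- sim$fst[nb]
  (sum(f < fst_obs) + 0.5 * sum(f == fst_obs)) / length(f)
}

#' Island-model FST-outlier scan with iterative neutral-FST refinement
#'
#' Three-stage procedure: (1) simulate the null (He, FST) cloud at the
#' multilocus FST of all loci and compute each locus's conditional
#' `P(sim FST < obs FST)`; (2) remove loci outside the central `ci`
#' confidence band and recompute the neutral FST from the remaining loci;
#' (3) rerun the simulation at the refined neutral FST and scan *all* loci.
#' Loci are classified `balancing` when `p_lower <= tails[1]`,
#' `directional` when `p_lower >= tails[2]`, otherwise `neutral`.  The
#' removal band and the reporting tails are independent settings.
#'
#' @param panel a `breed_panel`.
#' @param loci loci to scan (>= 3; default all).
#' @param ci confidence band used for removal before re-estimating the
#'   neutral FST (default 0.99).
#' @param n_sims simulated loci per stage (default 100,000).
#' @param tails reporting tail thresholds (default `c(0.025, 0.975)`).
#' @param bandwidth,min_neighbors passed to [conditional_p()].
#' @return object of class `fst_outlier_scan`: data frame `table` (locus,
#'   He, fst, p_lower, class), `neutral_fst` (refined), `neutral_fst_initial`,
#'   `removed` (loci trimmed at stage 2), `settings`, and `sim` (final
#'   simulated cloud).
#' @export
fst_outlier_scan <- function(panel, loci = NULL, ci = 0.99,
                             n_sims = 100000, tails = c(0.025, 0.975),
                             bandwidth = 0.05, min_neighbors = 200) {
  loci <- if (is.null(loci)) panel$loci else match_loci(panel, loci)
  if (length(loci) < 3) stop("need at least 3 loci")
  obs <- fst_multilocus(panel, loci)
  ok <- !is.na(obs$per_locus$fst)
  sizes <- panel$n_animals
  f0 <- obs$global
  sim1 <- simulate_null_fst(f0, sizes, n_sims)
  p1 <- vapply(which(ok), function(k)
    conditional_p(obs$per_locus$He[k], obs$per_locus$fst[k], sim1,
                  bandwidth, min_neighbors), 0)
  lo <- (1 - ci) / 2; hi <- 1 - lo
  inside <- p1 >= lo & p1 <= hi
  retained <- loci[ok][inside]
  if (length(retained) == 0) {
    warning("all loci outside the confidence band; neutral FST untrimmed")
    retained <- loci[ok]
  }
  f1 <- fst_multilocus(panel, retained)$global
  sim2 <- simulate_null_fst(f1, sizes, n_sims)
  p2 <- rep(NA_real_, length(loci))
  p2[ok] <- vapply(which(ok), function(k)
    conditional_p(obs$per_locus$He[k], obs$per_locus$fst[k], sim2,
                  bandwidth, min_neighbors), 0)
  cls <- rep("neutral", length(loci))
  cls[!ok] <- NA_character_
  cls[!is.na(p2) & p2 <= tails[1]] <- "balancing"
  cls[!is.na(p2) & p2 >= tails[2]] <- "directional"
  structure(list(
    table = data.frame(locus = loci, He = obs$per_locus$He,
                       fst = obs$per_locus$fst, p_lower = p2, class = cls),
    neutral_fst = f1, neutral_fst_initial = f0,
    removed = loci[ok][!inside],
    settings = list(ci = ci, n_sims = n_sims, tails = tails,
                    bandwidth = bandwidth, min_neighbors = min_neighbors,
                    sample_sizes = sizes),
    sim = sim2), class = "fst_outlier_scan")
}

#' @export
print.fst_outlier_scan <- function(x, ...) {
  cat("Island-model FST-outlier scan over", nrow(x$table), "loci\n")
  cat(sprintf("Neutral FST: initial %.6f, refined %.6f (removed: %s)\n",
              x$neutral_fst_initial, x$neutral_fst,
              if (length(x$removed)) paste(x$removed, collapse = ", ") else "none"))
  tb <- x$table
  tb$He <- round(tb$He, 3); tb$fst <- round(tb$fst, 3)
  tb$p_lower <- round(tb$p_lower, 4)
  print(tb, row.names = FALSE)
  invisible(x)
}

#' @export
summary.fst_outlier_scan <- function(object, ...) {
  with(object$table, table(factor(class, c("balancing", "neutral", "directional"))))
}

#' @export
plot.fst_outlier_scan <- function(x, ...) {
  plot(x$sim$He, x$sim$fst, pch = ".", col = "grey",
       xlab = "expected heterozygosity", ylab = "FST", ...)
  with(x$table, {
    graphics::points(He, fst, pch = 19,
                     col = ifelse(class == "neutral", "black", "red"))
    graphics::text(He, fst, locus, pos = 3, cex = 0.7)
  })
  invisible(x)
}
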