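#' Observed and expected heterozygosity from genotype counts
#'
#' `Ho` is the fraction of heterozygotes; `He = 2p(1-p)` with `p` the
#' allele-1 frequency from the counts.  The plain (uncorrected) form is the
#' default because published pooled values match it; the
#' `2n/(2n-1)` small-sample correction is available by flag.
#'
#' @param counts integer vector `(n11, n12, n22)` of genotype-class counts
#'   (class 1 homozygote, heterozygote, class 2 homozygote).
#' @param unbiased apply the `2n/(2n-1)` correction to He.
#' @return list with `Ho`, `He`, `p` (allele-1 frequency) and `n`.
#' @export
heterozygosity <- function(counts, unbiased = FALSE) {
  n <- sum(counts)
  if (n == 0) stop("no individuals: heterozygosity undefined")
  p <- (2 * counts[1] + counts[2]) / (2 * n)
  he <- 2 * p * (1 - p)
  if (unbiased) he <- he * 2 * n / (2 * n - 1)
  list(Ho = counts[2] / n, He = unname(he), p = unname(p), n = n)
}

#' Per-locus diversity summary for a panel
#'
#' In `pooled` mode the reconstructed counts are summed over breeds before
#' computing per-locus statistics ("all breeds joined"); otherwise a
#' per-breed table is returned.  The reported averages are plain means over
#' loci.
#'
#' @param panel a `breed_panel`.
#' @param pooled pool counts over breeds first (default TRUE).
#' @param unbiased passed to [heterozygosity()].
#' @return data frame with `locus`, `maf`, `minor_allele`, `Ho`, `He`,
#'   `hwe_p` (pooled mode adds attribute `averages`), or in per-breed mode
#'   the same columns plus `breed_id`.
#' @export
pooled_diversity <- function(panel, pooled = TRUE, unbiased = FALSE) {
  one <- function(cc) {
    h <- heterozygosity(cc, unbiased)
    maf <- min(h$p, 1 - h$p)
    data.frame(maf = maf,
               minor_allele = if (h$p <= 0.5) 1L else 2L,
               Ho = h$Ho, He = h$He,
               hwe_p = hwe_exact_test(cc[1], cc[2], cc[3]))
  }
  if (pooled) {
    out <- do.call(rbind, lapply(panel$loci, function(l)
      cbind(locus = l, one(colSums(matrix(panel$counts[, l, ], ncol = 3))))))
    rownames(out) <- NULL
    attr(out, "averages") <- c(Ho = mean(out$Ho), He = mean(out$He))
    out
  } else {
    out <- do.call(rbind, lapply(panel$breeds, function(b)
      do.call(rbind, lapply(panel$loci, function(l)
        cbind(breed_id = b, locus = l, one(panel$counts[b, l, ]))))))
    rownames(out) <- NULL
    out
  }
}

#' Hardy-Weinberg exact test (probability ordering)
#'
#' Conditional on the observed allele counts, all possible heterozygote
#' counts are enumerated and the two-sided p-value is the summed probability
#' of tables no more probable than the observed one (the standard
#' probability-ordering exact test for biallelic markers).
#'
#' @param n11,n12,n22 genotype-class counts.
#' @return exact p-value in `(0, 1]`; monomorphic samples return 1 by
#'   convention.
#' @export
hwe_exact_test <- function(n11, n12, n22) {
  stopifnot(n11 >= 0, n12 >= 0, n22 >= 0)
  n <- n11 + n12 + n22
  n1 <- 2 * n11 + n12            # allele-1 count
  if (n == 0 || n1 == 0 || n1 == 2 * n) return(1.0)
  nr <- min(n1, 2 * n - n1)      # rarer allele count
  hets <- seq(nr %% 2, nr, by = 2)
  # log conditional probability of each heterozygote count
  lp <- sapply(hets, function(h) {
    a <- (nr - h) / 2; b <- (2 * n - nr - h) / 2
    lgamma(n + 1) - lgamma(a + 1) - lgamma(h + 1) - lgamma(b + 1) +
      h * log(2) + lgamma(nr + 1) + lgamma(2 * n - nr + 1) - lgamma(2 * n + 1)
  })
  p <- exp(lp - max(lp)); p <- p / sum(p)
  obs <- which(hets == n12)
  min(1, sum(p[p <= p[obs] * (1 + 1e-12)]))
}

#' EM estimate of two-locus haplotype frequencies and LD r2
#'
#' Haplotype frequencies for two biallelic loci are estimated from unphased
#' genotypes by expectation-maximisation over the phase of double
#' heterozygotes, started from linkage equilibrium.  `r2 = D^2 /
#' (pA pa pB pb)` where `D` is the gametic disequilibrium of the estimated
#' haplotype frequencies.
#'
#' @param g1,g2 integer genotype vectors (0/1/2 copies of allele 1, NA
#'   allowed); individuals missing at either locus are dropped pairwise.
#' @param tol convergence threshold on the maximum haplotype-frequency
#'   change (default 1e-10).
#' @param max_iter iteration cap.
#' @return list with `r2`, `D`, `Dprime`, `hap_freq` (named 4-vector,
#'   order 11, 12, 21, 22 by allele at locus 1 then locus 2) and `n`.
#'   `r2` is `NA` if either locus is monomorphic in the retained sample.
#' @export
ld_r2 <- function(g1, g2, tol = 1e-10, max_iter = 1000) {
  keep <- !is.na(g1) & !is.na(g2)
  g1 <- g1[keep]; g2 <- g2[keep]
  n <- length(g1)
  if (n < 2) stop("need at least 2 individuals with complete genotypes")
  pA <- mean(g1) / 2; pB <- mean(g2) / 2
  if (pA %in% c(0, 1) || pB %in% c(0, 1))
    return(list(r2 = NA_real_, D = NA_real_, Dprime = NA_real_,
                hap_freq = rep(NA_real_, 4), n = n))
  tab <- table(factor(g1, 0:2), factor(g2, 0:2))   # rows locus1, cols locus2
  # known haplotype contributions; only the (1,1) double-het cell is ambiguous
  dh <- tab["1", "1"]
  base <- c(
    h11 = 2 * tab["2", "2"] + tab["2", "1"] + tab["1", "2"],
    h12 = 2 * tab["2", "0"] + tab["2", "1"] + tab["1", "0"],
    h21 = 2 * tab["0", "2"] + tab["0", "1"] + tab["1", "2"],
    h22 = 2 * tab["0", "0"] + tab["0", "1"] + tab["1", "0"])
  f <- c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))
  for (it in seq_len(max_iter)) {
    # E: split double heterozygotes between coupling (11/22) and repulsion
    cpl <- f[1] * f[4]; rpl <- f[2] * f[3]
    w <- if (cpl + rpl > 0) cpl / (cpl + rpl) else 0.5
    hap <- base + dh * c(w, 1 - w, 1 - w, w)
    fnew <- hap / (2 * n)
    if (max(abs(fnew - f)) < tol) { f <- fnew; break }
    f <- fnew
  }
  D <- f[1] - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  list(r2 = unname(D^2 / (pA * (1 - pA) * pB * (1 - pB))),
       D = unname(D),
       Dprime = unname(if (dmax > 0) abs(D) / dmax else NA_real_),
       hap_freq = stats::setNames(as.numeric(f), c("11", "12", "21", "22")),
       n = n)
}

#' Pairwise LD r2 matrix for a genotype matrix
#'
#' @param geno a `genotype_matrix`; optionally restricted to one breed.
#' @param breed compute within this breed only (default: whole sample).
#' @return symmetric loci x loci matrix of r2 (NA where undefined).
#' @export
ld_matrix <- function(geno, breed = NULL) {
  if (!is.null(breed)) geno <- geno[geno$breed_id %in% breed, ]
  loci <- attr(geno, "loci")
  k <- length(loci)
  m <- matrix(NA_real_, k, k, dimnames = list(loci, loci))
  diag(m) <- 1
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    m[i, j] <- m[j, i] <- ld_r2(geno[[loci[i]]], geno[[loci[j]]])$r2
  m
}

#' Single-linkage LD blocks
#'
#' Loci are grouped by single linkage: any chain of pairwise `r2 >=
#' threshold` joins loci into one block.  Output order follows locus
#' position in the input matrix; deterministic.
#'
#' @param r2mat symmetric r2 matrix (NA treated as below threshold).
#' @param threshold block-joining threshold.
#' @return list of character vectors of locus names.
#' @export
ld_blocks <- function(r2mat, threshold = 0.8) {
  loci <- rownames(r2mat)
  k <- length(loci)
  comp <- seq_len(k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    if (!is.na(r2mat[i, j]) && r2mat[i, j] >= threshold) {
      old <- comp[j]; comp[comp == old] <- comp[i]
    }
  unname(lapply(unique(comp), function(cid) loci[comp == cid]))
}
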