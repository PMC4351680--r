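#' Binary allele-presence coding
#'
#' The spatial-analysis coding: an allele scores 1 for an individual if the
#' individual carries at least one copy.  A heterozygote is positive for
#' both alleles; a missing genotype is missing for both.
#'
#' @param g integer genotype vector (0/1/2 copies of allele 1, NA allowed).
#' @return two-column integer matrix `y1`, `y2` (presence of allele 1 and
#'   allele 2).
#' @export
allele_presence <- function(g) {
  bad <- !(is.na(g) | g %in% 0:2)
  if (any(bad)) stop("genotype codes outside {0,1,2,NA}")
  cbind(y1 = as.integer(g >= 1), y2 = as.integer(g <= 1))
}

#' Univariate logistic environmental-association fit
#'
#' Maximum-likelihood logistic regression of allele presence on one
#' environmental variable, with the likelihood-ratio statistic `G` against
#' the intercept-only model and the Wald statistic `W = (slope / SE)^2`,
#' both referred to chi-square with 1 df.  Complete separation is flagged
#' when the slope on the standardised variable exceeds 15 in magnitude; the
#' Wald statistic is then unreliable (the likelihood-ratio G remains
#' valid).
#'
#' @param y binary presence vector.
#' @param x environmental value per individual (breed value broadcast to
#'   its animals).
#' @return one-row data frame: `intercept`, `slope` (per raw unit), `G`,
#'   `W`, `p_G`, `p_W`, `separation`, `skipped`, `reason`.
#' @export
fit_allele_logistic <- function(y, x) {
  keep <- !is.na(y) & !is.na(x)
  y <- y[keep]; x <- x[keep]
  empty <- data.frame(intercept = NA_real_, slope = NA_real_, G = NA_real_,
                      W = NA_real_, p_G = NA_real_, p_W = NA_real_,
                      separation = FALSE, skipped = TRUE,
                      reason = "monomorphic presence")
  if (length(unique(y)) < 2) return(empty)
  if (stats::sd(x) == 0) { empty$reason <- "constant variable"; return(empty) }
  fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial(),
                                     control = list(epsilon = 1e-8, maxit = 100)))
  sm <- suppressWarnings(summary(fit))
  slope <- stats::coef(fit)[2]
  g <- fit$null.deviance - fit$deviance
  w <- (slope / sm$coefficients[2, 2])^2
  sep <- abs(slope * stats::sd(x)) > 15
  data.frame(intercept = unname(stats::coef(fit)[1]), slope = unname(slope),
             G = g, W = unname(w),
             p_G = stats::pchisq(g, 1, lower.tail = FALSE),
             p_W = stats::pchisq(unname(w), 1, lower.tail = FALSE),
             separation = sep, skipped = FALSE, reason = "")
}

#' Spatial-analysis scan of alleles against environmental variables
#'
#' Runs every allele x variable logistic model on individual data (either a
#' genotype matrix, or a panel deterministically expanded to individuals;
#' animals within a breed share the breed's environmental value).  A model
#' is significant only when *both* the likelihood-ratio and Wald tests
#' reject at the Bonferroni threshold `ST = alpha_family / (2 L V)` over
#' the `2 L` alleles and `V` variables.
#'
#' @param geno a `genotype_matrix`, or a `breed_panel` (expanded with
#'   [expand_panel_genotypes()]).
#' @param climate a `climate_table` (rows matched to `breed_id`).
#' @param loci loci to scan (default: all in `geno`).
#' @param variables climate variables (default: the 14 numeric ones).
#' @param alpha_family family-wise level before Bonferroni (default 0.01).
#' @return object of class `sam_scan`: data frame `results` (one row per
#'   allele x variable), `significance` (alleles x variables 0/1 matrix),
#'   `ST`, `n_models`.
#' @export
sam_scan <- function(geno, climate, loci = NULL,
                     variables = c("LAT", "LON", "MINaT", "MAXaT", "MThm",
                                   "ANT", "TW", "TAR", "MxR", "MiR", "HrA",
                                   "HrMx", "HrMi", "THI"),
                     alpha_family = 0.01) {
  if (inherits(geno, "breed_panel"))
    geno <- expand_panel_genotypes(geno, loci)
  loci <- if (is.null(loci)) attr(geno, "loci") else
    intersect(attr(geno, "loci"), loci)
  env <- as.data.frame(climate)[match(geno$breed_id, climate$breed_id),
                                variables, drop = FALSE]
  n_models <- 2L * length(loci) * length(variables)
  st <- alpha_family / n_models
  rows <- list()
  for (l in loci) {
    pres <- allele_presence(geno[[l]])
    for (a in 1:2) for (v in variables) {
      r <- fit_allele_logistic(pres[, a], env[[v]])
      r <- cbind(data.frame(locus = l, allele = a, variable = v), r)
      rows[[length(rows) + 1L]] <- r
    }
  }
  res <- do.call(rbind, rows)
  res$significant <- !res$skipped & res$p_G <= st & res$p_W <= st
  sig <- matrix(0L, 2L * length(loci), length(variables),
                dimnames = list(
                  paste0(rep(loci, each = 2), ".a", 1:2), variables))
  for (k in seq_len(nrow(res)))
    sig[paste0(res$locus[k], ".a", res$allele[k]), res$variable[k]] <-
      as.integer(isTRUE(res$significant[k]))
  structure(list(results = res, significance = sig, ST = st,
                 n_models = n_models, alpha_family = alpha_family),
            class = "sam_scan")
}

#' @export
print.sam_scan <- function(x, ...) {
  cat("SAM scan:", x$n_models, "allele x variable models;",
      sprintf("Bonferroni threshold ST = %.4g", x$ST), "\n")
  ns <- sum(x$results$significant, na.rm = TRUE)
  cat("Models significant on both G and Wald tests:", ns, "\n")
  if (ns) {
    s <- x$results[which(x$results$significant), c("locus", "allele", "variable", "G", "W")]
    print(s, row.names = FALSE)
  }
  invisible(x)
}

#' Correlogram of a fitted allele-environment model
#'
#' Predicted presence probability over a grid spanning the observed
#' variable range, plus the difference between the curve's extremes (how
#' much the allele's presence probability changes across the gradient).
#'
#' @param intercept,slope logistic coefficients (raw-variable scale).
#' @param x_range observed range of the variable.
#' @param n_grid grid points (default 100).
#' @return list `grid`, `prob`, `extreme_difference`.
#' @export
sam_correlogram <- function(intercept, slope, x_range, n_grid = 100) {
  g <- seq(x_range[1], x_range[2], length.out = n_grid)
  p <- stats::plogis(intercept + slope * g)
  list(grid = g, prob = p,
       extreme_difference = abs(p[n_grid] - p[1]))
}
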