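#' Configuration for the synthetic-data generators
#'
#' Defaults are sized like the real study panel: 31 breeds of 27 animals,
#' 11 biallelic loci, island-model differentiation 0.07.  Selected loci
#' tie a breed's allele frequency to one climate variable through a
#' logistic cline; outlier loci override the island-model FST for that
#' locus.  A single top-level seed fans out to fixed per-stage substreams
#' so that redrawing one stage leaves the others unchanged.
#'
#' @param n_breeds number of populations.
#' @param n_animals animals per breed (scalar or vector).
#' @param n_neutral_loci neutral background loci.
#' @param selected data frame with columns `variable` (climate column),
#'   `slope` (logistic slope per SD of the variable), `baseline`
#'   (logit of the mid-gradient frequency); NULL for none.
#' @param outlier_fst numeric vector of per-locus FST overrides for
#'   additional outlier loci; NULL for none.
#' @param neutral_fst island-model differentiation of the background.
#' @param climate_mean,climate_sd named vectors over the 12 base climate
#'   variables (TW and THI are derived, never drawn).
#' @param climate_cor correlation matrix over the base variables (default
#'   identity); must be positive semi-definite.
#' @param seed top-level seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_breeds = 31, n_animals = 27, n_neutral_loci = 11,
                       selected = NULL, outlier_fst = NULL,
                       neutral_fst = 0.07,
                       climate_mean = c(LAT = 40, LON = 20, MINaT = 1,
                                        MAXaT = 24, MThm = 33, ANT = 13,
                                        TAR = 500, MxR = 70, MiR = 15,
                                        HrA = 66, HrMx = 80, HrMi = 52),
                       climate_sd = c(LAT = 8, LON = 25, MINaT = 9,
                                      MAXaT = 4, MThm = 5, ANT = 5,
                                      TAR = 170, MxR = 40, MiR = 12,
                                      HrA = 9, HrMx = 6, HrMi = 12),
                       climate_cor = NULL, seed = 1) {
  vars <- names(climate_mean)
  if (is.null(climate_cor)) {
    climate_cor <- diag(length(vars))
    dimnames(climate_cor) <- list(vars, vars)
  }
  ev <- eigen(climate_cor, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("climate correlation matrix is not positive semi-definite")
  if (!is.null(selected)) {
    stopifnot(all(c("variable", "slope", "baseline") %in% names(selected)),
              all(is.finite(selected$slope)))
  }
  if (!is.null(outlier_fst))
    stopifnot(all(outlier_fst > 0), all(outlier_fst < 1))
  stopifnot(neutral_fst > 0, neutral_fst < 1)
  if (length(n_animals) == 1) n_animals <- rep(n_animals, n_breeds)
  structure(list(
    n_breeds = n_breeds, n_animals = n_animals,
    n_neutral_loci = n_neutral_loci, selected = selected,
    outlier_fst = outlier_fst, neutral_fst = neutral_fst,
    climate_mean = climate_mean, climate_sd = climate_sd,
    climate_cor = climate_cor, seed = seed), class = "sim_config")
}

# deterministic per-stage substream seeding (keep below 2^31)
stage_seed <- function(config, stage) {
  (config$seed * 1000003L + stage * 7919L) %% 2147483629L
}

#' Simulate a breed-level climate table
#'
#' Base variables are drawn multivariate normal with the configured means,
#' SDs and correlation; rainfall and humidity are clipped to their valid
#' ranges; `TW = MAXaT - MINaT` and `THI` ([compute_thi()]) are derived;
#' `CTY` follows the total-annual-rainfall bands.
#'
#' @param config a [sim_config()].
#' @return a `climate_table` data frame.
#' @export
simulate_climate <- function(config) {
  set.seed(stage_seed(config, 1L))
  vars <- names(config$climate_mean)
  n <- config$n_breeds
  z <- matrix(stats::rnorm(n * length(vars)), n)
  cu <- chol(config$climate_cor + diag(1e-10, length(vars)))
  x <- z %*% cu
  x <- sweep(sweep(x, 2, config$climate_sd[vars], "*"), 2,
             config$climate_mean[vars], "+")
  colnames(x) <- vars
  x <- as.data.frame(x)
  x$TAR <- pmax(x$TAR, 5)
  x$MxR <- pmin(pmax(x$MxR, 1), x$TAR)
  x$MiR <- pmin(pmax(x$MiR, 0), x$MxR)
  for (v in c("HrA", "HrMx", "HrMi")) x[[v]] <- pmin(pmax(x[[v]], 5), 100)
  x$HrMx <- pmax(x$HrMx, x$HrA); x$HrMi <- pmin(x$HrMi, x$HrA)
  x$TW <- x$MAXaT - x$MINaT
  x$THI <- compute_thi(x$MAXaT, x$HrA / 100)
  x$CTY <- as.character(cut(x$TAR, c(-Inf, 250, 500, 1000, 2000, Inf),
                            labels = c("A", "SA", "SD", "D", "VD")))
  x <- cbind(breed_id = sprintf("B%02d", seq_len(n)),
             N = config$n_animals, x)
  rownames(x) <- x$breed_id
  structure(x, class = c("climate_table", "data.frame"))
}

#' Simulate a breed panel (and its individual genotypes)
#'
#' Neutral loci draw breed allele frequencies from the Balding-Nichols
#' beta around a uniform ancestral frequency at the configured island
#' differentiation; selected loci centre the beta on a logistic cline in
#' the configured climate variable (standardised across breeds); outlier
#' loci use their own FST override.  Individuals are drawn in
#' Hardy-Weinberg proportions within breeds, and the returned panel's
#' frequencies/counts come from the drawn genotypes, exactly as a real
#' panel would be tabulated.  Cline frequencies are clamped to
#' `[1/(2n), 1 - 1/(2n)]`.
#'
#' @param config a [sim_config()].
#' @param climate a climate table from [simulate_climate()] (or real data
#'   with matching `breed_id` rows).
#' @return list `panel` (a `breed_panel`), `genotypes`
#'   (a `genotype_matrix`), `locus_type` (named character: neutral /
#'   selected / outlier), `truth` (per-breed expected frequencies).
#' @export
simulate_breed_panel <- function(config, climate = simulate_climate(config)) {
  set.seed(stage_seed(config, 2L))
  nb <- config$n_breeds
  n_animals <- config$n_animals
  n_sel <- if (is.null(config$selected)) 0L else nrow(config$selected)
  n_out <- length(config$outlier_fst)
  loci <- c(if (n_sel) paste0("sel", seq_len(n_sel)),
            if (n_out) paste0("out", seq_len(n_out)),
            paste0("neu", seq_len(config$n_neutral_loci)))
  type <- c(rep("selected", n_sel), rep("outlier", n_out),
            rep("neutral", config$n_neutral_loci))
  names(type) <- loci
  bn_draw <- function(mu, fst) {
    s <- (1 - fst) / fst
    stats::rbeta(nb, mu * s, (1 - mu) * s)
  }
  truth <- matrix(NA_real_, nb, length(loci),
                  dimnames = list(climate$breed_id, loci))
  counts <- array(0L, c(nb, length(loci), 3),
                  dimnames = list(climate$breed_id, loci, NULL))
  for (k in seq_along(loci)) {
    if (type[k] == "selected") {
      sel <- config$selected[sum(type[seq_len(k)] == "selected"), ]
      v <- climate[[sel$variable]]
      zv <- (v - mean(v)) / stats::sd(v)
      mu <- stats::plogis(sel$baseline + sel$slope * zv)
      s <- (1 - config$neutral_fst) / config$neutral_fst
      p <- stats::rbeta(nb, mu * s, (1 - mu) * s)
    } else {
      fst <- if (type[k] == "outlier")
        config$outlier_fst[sum(type[seq_len(k)] == "outlier")] else
          config$neutral_fst
      p0 <- stats::runif(1, 0.1, 0.9)
      p <- bn_draw(p0, fst)
    }
    p <- pmin(pmax(p, 1 / (2 * n_animals)), 1 - 1 / (2 * n_animals))
    truth[, k] <- p
    for (i in seq_len(nb))
      counts[i, k, ] <- as.integer(stats::rmultinom(
        1, n_animals[i], c(p[i]^2, 2 * p[i] * (1 - p[i]), (1 - p[i])^2)))
  }
  freq <- do.call(rbind, lapply(seq_len(nb), function(i)
    do.call(rbind, lapply(seq_along(loci), function(k) {
      cc <- counts[i, k, ]; n <- sum(cc)
      data.frame(breed = climate$breed_id[i], breed_id = climate$breed_id[i],
                 n_chromosomes = 2L * n, locus = loci[k],
                 genotype11 = "11", genotype12 = "12", genotype22 = "22",
                 freq_g11 = cc[1] / n, freq_g12 = cc[2] / n,
                 freq_g22 = cc[3] / n,
                 allele1 = "A", allele2 = "B",
                 freq_a1 = (2 * cc[1] + cc[2]) / (2 * n),
                 freq_a2 = (2 * cc[3] + cc[2]) / (2 * n))
    }))))
  panel <- breed_panel(freq, tol = 1e-9)
  panel$counts[] <- counts     # exact drawn counts, no re-rounding
  geno <- expand_panel_genotypes(panel)
  list(panel = panel, genotypes = geno, locus_type = type, truth = truth)
}

#' Evolve an alignment down a tree under the T92 model
#'
#' The root sequence is drawn from the stationary composition implied by
#' the GC content `theta`; each site evolves independently along branches
#' under the T92 rate matrix (transition/transversion rate ratio `kappa`),
#' optionally with per-site gamma rate multipliers.
#'
#' @param tree an [ape::phylo] tree with branch lengths in expected
#'   substitutions per site.
#' @param width alignment width (sites).
#' @param theta equilibrium GC content in (0, 1).
#' @param gamma_shape per-site rate gamma shape, or NULL for equal rates.
#' @param kappa transition/transversion rate ratio (default 4).
#' @return a `species_alignment` with rows named by tip label.
#' @export
simulate_alignment_t92 <- function(tree, width, theta = 0.5,
                                   gamma_shape = NULL, kappa = 4) {
  if (any(!is.finite(tree$edge.length))) stop("non-finite branch length")
  bases <- c("A", "C", "G", "T")
  pi <- c(A = (1 - theta) / 2, C = theta / 2, G = theta / 2, T = (1 - theta) / 2)
  # T92 rate matrix (rows from, cols to), scaled to 1 expected sub/site
  R <- matrix(0, 4, 4, dimnames = list(bases, bases))
  for (i in bases) for (j in bases) if (i != j) {
    ts <- (i %in% c("A", "G") && j %in% c("A", "G")) ||
      (i %in% c("C", "T") && j %in% c("C", "T"))
    R[i, j] <- pi[j] * if (ts) kappa else 1
  }
  diag(R) <- -rowSums(R)
  scalev <- -sum(pi * diag(R))
  R <- R / scalev
  eg <- eigen(R)
  pmat <- function(t) {
    m <- Re(eg$vectors %*% diag(exp(eg$values * t)) %*% solve(eg$vectors))
    m[m < 0] <- 0
    m <- m / rowSums(m)
    dimnames(m) <- list(bases, bases)
    m
  }
  rates <- if (is.null(gamma_shape)) rep(1, width) else
    stats::rgamma(width, gamma_shape, gamma_shape)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[root]] <- sample(bases, width, replace = TRUE, prob = pi)
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    from <- ord$edge[e, 1]; to <- ord$edge[e, 2]
    bl <- ord$edge.length[e]
    parent <- seqs[[from]]
    if (bl == 0) { seqs[[to]] <- parent; next }
    child <- parent
    for (rt in unique(rates)) {
      idx <- which(rates == rt)
      if (rt == 0) next
      Pm <- pmat(bl * rt)
      pv <- parent[idx]
      child[idx] <- vapply(seq_along(idx), function(s)
        sample(bases, 1, prob = Pm[pv[s], ]), "")
    }
    seqs[[to]] <- child
  }
  m <- do.call(rbind, seqs[seq_len(ntip)])
  rownames(m) <- tree$tip.label
  structure(m, class = c("species_alignment", class(m)))
}

#' Neutral coalescent sample with infinite-sites mutation
#'
#' Standard Kingman coalescent for `n` haploid lineages; mutations fall on
#' branches at rate `theta / 2` per lineage per coalescent time unit, each
#' creating a new segregating site.  Returned as a two-state alignment
#' (ancestral `A`, derived `T`) so that [tajimas_d()] applies directly.
#'
#' @param n sample size (>= 2).
#' @param theta population mutation rate.
#' @return a `species_alignment` of `n` haplotypes (width = number of
#'   segregating sites; a monomorphic outcome yields width 1 of all `A`).
#' @export
coalescent_sample <- function(n, theta) {
  stopifnot(n >= 2, theta > 0)
  active <- as.list(seq_len(n))       # descendant tip sets
  t_branch <- list()                  # (tips, length) per branch segment
  k <- n
  while (k > 1) {
    t_coal <- stats::rexp(1, k * (k - 1) / 2)
    for (b in seq_along(active))
      t_branch[[length(t_branch) + 1L]] <- list(tips = active[[b]], len = t_coal)
    pair <- sample.int(k, 2)
    merged <- c(active[[pair[1]]], active[[pair[2]]])
    active <- c(active[-pair], list(merged))
    k <- k - 1
  }
  # aggregate branch lengths per distinct tip set
  sets <- vapply(t_branch, function(b) paste(sort(b$tips), collapse = ","), "")
  lens <- vapply(t_branch, `[[`, 0, "len")
  agg <- tapply(lens, sets, sum)
  total <- sum(lens)
  n_mut <- stats::rpois(1, theta / 2 * total)
  m <- matrix("A", n, max(1, n_mut))
  if (n_mut > 0) {
    on_set <- sample(names(agg), n_mut, replace = TRUE, prob = agg / total)
    for (s in seq_len(n_mut)) {
      tips <- as.integer(strsplit(on_set[s], ",")[[1]])
      m[tips, s] <- "T"
    }
  }
  rownames(m) <- paste0("hap", seq_len(n))
  structure(m, class = c("species_alignment", class(m)))
}
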