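#' Tamura 3-parameter distance between two aligned sequences
#'
#' The T92 model corrects divergence for transition/transversion bias and
#' GC content: with `P` and `Q` the transition and transversion proportions
#' over usable sites, `theta` the pooled GC content of the pair and
#' `h = 2 theta (1 - theta)`,
#' `d = -h log(1 - P/h - Q) - (1 - h)/2 log(1 - 2Q)`.
#' With gamma-distributed rate variation of shape `a` each logarithm
#' `log(x)` is replaced by `-a (x^(-1/a) - 1)` (the continuous-gamma
#' transform); at `theta = 0.5` the formulas reduce exactly to Kimura's
#' two-parameter distance.  Sites where either sequence is not a plain
#' `A/C/G/T` are excluded pairwise.
#'
#' @param s1,s2 character vectors of single bases (rows of a
#'   `species_alignment`) or single strings.
#' @param gamma_shape gamma shape parameter, or `NULL` for equal rates.
#' @return list `d`, `P`, `Q`, `theta`, `n_sites` (usable sites).
#'   Saturated pairs (log argument <= 0) return `d = Inf` with a warning.
#' @export
t92_distance <- function(s1, s2, gamma_shape = NULL) {
  if (length(s1) == 1) s1 <- strsplit(toupper(s1), "")[[1]]
  if (length(s2) == 1) s2 <- strsplit(toupper(s2), "")[[1]]
  if (length(s1) != length(s2)) stop("sequences differ in aligned length")
  bases <- c("A", "C", "G", "T")
  use <- s1 %in% bases & s2 %in% bases
  n <- sum(use)
  if (n == 0) stop("no usable site in the pair")
  a <- s1[use]; b <- s2[use]
  transition <- (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
  diffs <- a != b
  P <- sum(transition) / n
  Q <- sum(diffs & !transition) / n
  theta <- mean(c(a, b) %in% c("G", "C"))
  h <- 2 * theta * (1 - theta)
  x1 <- 1 - P / h - Q
  x2 <- 1 - 2 * Q
  if (P == 0 && Q == 0)
    return(list(d = 0, P = 0, Q = 0, theta = theta, n_sites = n))
  if (x1 <= 0 || x2 <= 0) {
    warning("saturated pair: distance infinite")
    return(list(d = Inf, P = P, Q = Q, theta = theta, n_sites = n))
  }
  tr <- if (is.null(gamma_shape)) log else
    function(x) -gamma_shape * (x^(-1 / gamma_shape) - 1)
  d <- -h * tr(x1) - (1 - h) / 2 * tr(x2)
  list(d = d, P = P, Q = Q, theta = theta, n_sites = n)
}

#' Between-species divergence matrix with bootstrap standard errors
#'
#' The distance between two species is the mean T92(+gamma) distance over
#' all cross-species sequence pairs (group mean; within-species variation
#' is not subtracted).  Standard errors come from resampling alignment
#' columns (`n_boot` site-bootstrap replicates).
#'
#' @param aln a `species_alignment` (rows are haplotypes).
#' @param groups factor/character of species labels, one per row of `aln`.
#' @param gamma_shape passed to [t92_distance()].
#' @param n_boot bootstrap replicates for SEs (0 = skip; default 1000).
#' @return list `d` (species x species mean distances), `se` (bootstrap
#'   SEs, NA diagonal), and `table` (combined layout: d below the
#'   diagonal, SE above).
#' @export
divergence_matrix <- function(aln, groups, gamma_shape = NULL,
                              n_boot = 1000) {
  groups <- as.character(groups)
  sp <- unique(groups)
  ns <- length(sp)
  dist_one <- function(m) {
    d <- matrix(0, ns, ns, dimnames = list(sp, sp))
    for (i in seq_len(ns - 1)) for (j in (i + 1):ns) {
      ri <- which(groups == sp[i]); rj <- which(groups == sp[j])
      vals <- outer(ri, rj, Vectorize(function(a, b)
        t92_distance(m[a, ], m[b, ], gamma_shape)$d))
      d[i, j] <- d[j, i] <- mean(vals)
    }
    d
  }
  d <- dist_one(unclass(aln))
  se <- matrix(NA_real_, ns, ns, dimnames = list(sp, sp))
  if (n_boot > 0) {
    L <- ncol(aln)
    boots <- array(NA_real_, c(ns, ns, n_boot))
    for (b in seq_len(n_boot)) {
      cols <- sample.int(L, L, replace = TRUE)
      boots[, , b] <- dist_one(unclass(aln)[, cols, drop = FALSE])
    }
    se <- apply(boots, c(1, 2), stats::sd)
    dimnames(se) <- list(sp, sp)
    diag(se) <- NA
  }
  tab <- d
  tab[upper.tri(tab)] <- se[upper.tri(se)]
  diag(tab) <- NA
  list(d = d, se = se, table = tab)
}

#' Tajima's neutrality test
#'
#' Contrasts mean pairwise diversity `pi` with Watterson's
#' segregating-sites estimator `S / a1`; under neutrality their difference,
#' standardised by Tajima's variance estimate, is near zero.  Negative
#' values indicate an excess of low-frequency polymorphism.  Sites with
#' anything other than two plain bases among the sequences are ignored;
#' only biallelic segregating sites enter `S` and `pi`.
#'
#' @param aln a `species_alignment` (or plain character matrix) of n >= 4
#'   haplotypes.
#' @return list `n`, `S`, `pi`, `theta_w`, `D`, and `band` (conventional
#'   significance band: `|D| < 2` "not significant (p > 0.05)").
#' @export
tajimas_d <- function(aln) {
  m <- unclass(aln)
  n <- nrow(m)
  if (n < 4) stop("need at least 4 sequences")
  bases <- c("A", "C", "G", "T")
  S <- 0L; pi_sum <- 0
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    col <- col[col %in% bases]
    if (length(col) < n) next          # pairwise-complete columns only
    tab <- table(col)
    if (length(tab) == 2) {
      S <- S + 1L
      k <- as.integer(tab[1])
      pi_sum <- pi_sum + k * (n - k) / choose(n, 2)
    }
  }
  if (S == 0) stop("no segregating site: Tajima's D undefined")
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  D <- (pi_sum - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  list(n = n, S = S, pi = pi_sum, theta_w = S / a1, D = D,
       band = if (abs(D) < 2) "not significant (p > 0.05)" else
         "outside the conventional (-2, 2) band")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration (via [ape::nj()]); negative branch lengths,
#' an artefact of the least-squares step, are set to zero and their
#' magnitude transferred to the adjacent branch (standard practice).
#'
#' @param d symmetric distance matrix (>= 3 taxa) or `dist`.
#' @return an [ape::phylo] tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("need at least 3 taxa")
  tr <- ape::nj(as.dist(d))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    # transfer the negative length to the sibling edge sharing the parent
    parent <- tr$edge[e, 1]
    sib <- setdiff(which(tr$edge[, 1] == parent), e)
    if (length(sib)) tr$edge.length[sib[1]] <-
        tr$edge.length[sib[1]] + tr$edge.length[e]
    tr$edge.length[e] <- 0
  }
  tr
}

#' Bootstrap support for an NJ tree from an alignment
#'
#' Resamples alignment columns, rebuilds the distance matrix and NJ tree
#' per replicate, and reports the percentage of replicates containing each
#' internal bipartition of the reference tree.
#'
#' @param aln `species_alignment`.
#' @param groups species labels per row (one representative distance
#'   matrix is built at the species level via [divergence_matrix()]).
#' @param n_boot replicates (default 1000; tree-support analyses often use
#'   5000).
#' @param gamma_shape passed to the distance.
#' @return list `tree` (reference NJ tree with `node.label` = support %),
#'   `support`.
#' @export
nj_bootstrap <- function(aln, groups, n_boot = 1000, gamma_shape = NULL) {
  ref_d <- divergence_matrix(aln, groups, gamma_shape, n_boot = 0)$d
  ref <- nj_tree(ref_d)
  trees <- vector("list", n_boot)
  L <- ncol(aln)
  for (b in seq_len(n_boot)) {
    cols <- sample.int(L, L, replace = TRUE)
    db <- divergence_matrix(
      structure(unclass(aln)[, cols, drop = FALSE], class = class(aln)),
      groups, gamma_shape, n_boot = 0)$d
    trees[[b]] <- nj_tree(db)
  }
  cnt <- ape::prop.clades(ref, trees, rooted = FALSE)
  cnt[is.na(cnt)] <- 0
  support <- 100 * cnt / n_boot
  ref$node.label <- round(support, 1)
  list(tree = ref, support = support)
}
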