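#' Breed genotype/allele-frequency panel
#'
#' A `breed_panel` holds, for a set of populations (breeds) and biallelic
#' loci, the published genotype-class and allele frequencies together with
#' integer genotype counts reconstructed from them.  All downstream
#' statistics in the package run on the reconstructed counts so that results
#' are exactly reproducible from the shipped tables.
#'
#' Published tables print frequencies rounded to two decimals, and real
#' tables contain the occasional corrupted cell.  The constructor therefore
#' validates every breed x locus cell and reconciles the two frequency
#' sources:
#'
#' * a genotype row whose three classes sum to 1 within `tol` is used
#'   directly (largest-remainder rounding to integer counts);
#' * a genotype row that is an exact *reversal* of the published allele
#'   frequency (implied allele-1 frequency matching `1 - published` within
#'   `tol`) is flipped, on the grounds that the published allele row and the
#'   genotype row disagree only in class order;
#' * a genotype row that fails the sum-to-1 check falls back to
#'   Hardy-Weinberg-imputed counts from the published allele frequencies;
#' * a published allele row that fails its own sum-to-1 check is replaced by
#'   the genotype-implied frequency.
#'
#' Every reconciliation is recorded in the `flags` component.
#'
#' @param freq a data frame in the long layout written by
#'   [write_breed_panel()]: columns `breed`, `breed_id`, `n_chromosomes`,
#'   `locus`, `genotype11/12/22` (class labels), `freq_g11/g12/g22`,
#'   `allele1`, `allele2`, `freq_a1`, `freq_a2`.
#' @param tol tolerance on frequency-class sums (published rounding).
#' @return an object of class `breed_panel`: a list with components
#'   `breeds`, `loci`, `n_animals` (named integer vector),
#'   `genotype_freq` and `allele_freq_published` (3-d arrays),
#'   `counts` (breeds x loci x 3 integer array of reconstructed genotype
#'   counts), `allele_labels` (loci x 2), `monomorphic` (logical matrix) and
#'   `flags` (data frame of per-cell reconciliation notes).
#' @seealso [read_breed_panel()], [reconstruct_genotype_counts()],
#'   [allele_freq()]
#' @export
breed_panel <- function(freq, tol = 0.02) {
  need <- c("breed_id", "n_chromosomes", "locus",
            "freq_g11", "freq_g12", "freq_g22", "freq_a1", "freq_a2")
  miss <- setdiff(need, names(freq))
  if (length(miss))
    stop("breed panel table lacks column(s): ", paste(miss, collapse = ", "))
  if (!"breed" %in% names(freq)) freq$breed <- freq$breed_id

  breeds <- unique(as.character(freq$breed_id))
  loci   <- unique(as.character(freq$locus))
  nb <- length(breeds); nl <- length(loci)

  n_chrom <- tapply(freq$n_chromosomes, freq$breed_id, function(x) x[1])[breeds]
  if (any(is.na(n_chrom)) || any(n_chrom <= 0) || any(n_chrom %% 2 != 0))
    stop("n_chromosomes must be positive even integers (2 x animals)")
  n_animals <- as.integer(n_chrom / 2)
  names(n_animals) <- breeds

  gf <- array(NA_real_, c(nb, nl, 3), dimnames = list(breeds, loci, NULL))
  af <- array(NA_real_, c(nb, nl, 2), dimnames = list(breeds, loci, NULL))
  counts <- array(NA_integer_, c(nb, nl, 3), dimnames = list(breeds, loci, NULL))
  alleles <- matrix(NA_character_, nl, 2, dimnames = list(loci, NULL))
  flags <- list()

  for (k in seq_len(nrow(freq))) {
    b <- as.character(freq$breed_id[k]); l <- as.character(freq$locus[k])
    g <- as.numeric(freq[k, c("freq_g11", "freq_g12", "freq_g22")])
    a <- as.numeric(freq[k, c("freq_a1", "freq_a2")])
    if (anyNA(g) || anyNA(a) || any(g < 0) || any(a < 0))
      stop(sprintf("invalid frequencies for breed %s, locus %s", b, l))
    n <- n_animals[b]
    gs <- sum(g); as_ <- sum(a)
    g_ok <- abs(gs - 1) <= tol
    a_ok <- abs(as_ - 1) <= tol
    if (!g_ok && !a_ok)
      stop(sprintf(
        "breed %s, locus %s: genotype sum %.2f and allele sum %.2f both outside 1 +- %.2f",
        b, l, gs, as_, tol))
    note <- NULL
    if (g_ok) {
      implied <- g[1] + g[2] / 2
      if (a_ok && abs(implied - a[1]) > tol) {
        if (abs((1 - implied) - a[1]) <= tol) {
          g <- rev(g)
          note <- "genotype classes reversed; flipped to match published alleles"
        } else {
          note <- sprintf(
            "genotype-implied allele frequency %.3f differs from published %.2f",
            implied, a[1])
        }
      }
      cc <- largest_remainder_counts(g, n)
    } else {
      p <- a[1] / as_
      cc <- largest_remainder_counts(c(p^2, 2 * p * (1 - p), (1 - p)^2), n)
      note <- sprintf("genotype row sums %.2f; counts Hardy-Weinberg-imputed", gs)
    }
    if (!a_ok) {
      implied <- g[1] + g[2] / 2
      a <- c(implied, 1 - implied)
      note <- c(note, sprintf(
        "published allele row sums %.2f; replaced by genotype-implied", as_))
    }
    gf[b, l, ] <- g
    af[b, l, ] <- a
    counts[b, l, ] <- cc
    if (all(c("allele1", "allele2") %in% names(freq)))
      alleles[l, ] <- c(as.character(freq$allele1[k]), as.character(freq$allele2[k]))
    if (!is.null(note))
      flags[[length(flags) + 1L]] <- data.frame(
        breed_id = b, locus = l, note = paste(note, collapse = "; "))
  }
  if (anyNA(counts))
    stop("missing breed x locus combinations in panel table")

  p1 <- (2 * counts[, , 1] + counts[, , 2]) / (2 * (counts[, , 1] + counts[, , 2] + counts[, , 3]))
  mono <- p1 == 0 | p1 == 1

  structure(list(
    breeds = breeds, loci = loci, n_animals = n_animals,
    genotype_freq = gf, allele_freq_published = af,
    counts = counts, allele_labels = alleles,
    monomorphic = matrix(mono, nb, nl, dimnames = list(breeds, loci)),
    flags = if (length(flags)) do.call(rbind, flags) else
      data.frame(breed_id = character(), locus = character(), note = character())
  ), class = "breed_panel")
}

#' Read a breed panel from CSV
#'
#' @param path CSV file with one row per breed x locus (see [breed_panel()]
#'   for the column layout).  The table shipped with the package
#'   (`system.file("extdata", "tables1_2.csv", package = "adaptscan")`)
#'   holds the 31-breed, 11-locus heat-shock-protein promoter panel.
#' @param tol frequency-sum tolerance passed to [breed_panel()].
#' @return a [breed_panel()] object.
#' @export
read_breed_panel <- function(path, tol = 0.02) {
  breed_panel(utils::read.csv(path, check.names = FALSE), tol = tol)
}

#' Write a breed panel back to the long CSV layout
#'
#' Frequencies are written at the stored (published) precision so that
#' `read_breed_panel(write_breed_panel(p))` round-trips.
#'
#' @param panel a `breed_panel`.
#' @param path output CSV path.
#' @export
write_breed_panel <- function(panel, path) {
  rows <- expand.grid(locus = panel$loci, breed_id = panel$breeds,
                      stringsAsFactors = FALSE)[, 2:1]
  bi <- match(rows$breed_id, panel$breeds)
  li <- match(rows$locus, panel$loci)
  out <- data.frame(
    breed = rows$breed_id, breed_id = rows$breed_id,
    n_chromosomes = 2L * panel$n_animals[rows$breed_id],
    locus = rows$locus,
    genotype11 = "11", genotype12 = "12", genotype22 = "22",
    freq_g11 = panel$genotype_freq[cbind(bi, li, 1L)],
    freq_g12 = panel$genotype_freq[cbind(bi, li, 2L)],
    freq_g22 = panel$genotype_freq[cbind(bi, li, 3L)],
    allele1 = panel$allele_labels[li, 1],
    allele2 = panel$allele_labels[li, 2],
    freq_a1 = panel$allele_freq_published[cbind(bi, li, 1L)],
    freq_a2 = panel$allele_freq_published[cbind(bi, li, 2L)],
    row.names = NULL)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(out)
}

#' Largest-remainder rounding of class frequencies to integer counts
#'
#' Each class is first rounded (`floor(x + 0.5)`, avoiding banker's
#' rounding); any deficit or excess relative to `n` is then distributed one
#' unit at a time to the classes with the largest (respectively smallest)
#' fractional remainders, ties broken by lower class index.  Deterministic.
#'
#' @param freq numeric vector of class frequencies (need not sum exactly
#'   to 1; published tables are rounded).
#' @param n target total count.
#' @param warn_limit emit a warning if any single class is adjusted by more
#'   than this many units (rounding inconsistency in the source).
#' @return integer vector summing exactly to `n`.
#' @export
largest_remainder_counts <- function(freq, n, warn_limit = 1L) {
  x <- freq * n
  cc <- floor(x + 0.5)
  rem <- x - floor(x)
  d <- n - sum(cc)
  adj <- integer(length(cc))
  ord_up <- order(-rem, seq_along(rem))
  ord_dn <- order(rem, seq_along(rem))
  i <- 1L
  while (d != 0) {
    if (d > 0) {
      j <- ord_up[(i - 1L) %% length(cc) + 1L]
      cc[j] <- cc[j] + 1; adj[j] <- adj[j] + 1L; d <- d - 1
    } else {
      j <- ord_dn[(i - 1L) %% length(cc) + 1L]
      if (cc[j] > 0) { cc[j] <- cc[j] - 1; adj[j] <- adj[j] + 1L; d <- d + 1 }
    }
    i <- i + 1L
  }
  if (any(adj > warn_limit))
    warning("largest-remainder adjustment exceeded ", warn_limit,
            " per class; source frequencies are internally inconsistent")
  as.integer(cc)
}

#' Reconstruct genotype counts for a panel
#'
#' Returns the panel with its `counts` component recomputed from the stored
#' genotype frequencies (the constructor already does this; the function
#' exists so reconstruction is callable on frequency-edited panels).
#'
#' @param panel a `breed_panel`.
#' @return the panel, counts recomputed.
#' @export
reconstruct_genotype_counts <- function(panel) {
  for (b in panel$breeds) for (l in panel$loci)
    panel$counts[b, l, ] <- largest_remainder_counts(
      panel$genotype_freq[b, l, ], panel$n_animals[b])
  panel
}

#' Allele-1 frequencies of a panel
#'
#' @param panel a `breed_panel`.
#' @param loci loci to extract (default all).
#' @param source `"counts"` (from reconstructed integer counts, the default
#'   used by all downstream statistics) or `"published"` (as printed).
#' @return breeds x loci matrix of allele-1 frequencies.
#' @export
allele_freq <- function(panel, loci = NULL,
                        source = c("counts", "published")) {
  source <- match.arg(source)
  loci <- if (is.null(loci)) panel$loci else match_loci(panel, loci)
  if (source == "published")
    return(panel$allele_freq_published[, loci, 1, drop = TRUE])
  cc <- panel$counts[, loci, , drop = FALSE]
  f <- (2 * cc[, , 1] + cc[, , 2]) / (2 * rowSums(cc, dims = 2))
  matrix(f, nrow = length(panel$breeds),
         dimnames = list(panel$breeds, loci))
}

match_loci <- function(panel, loci) {
  bad <- setdiff(loci, panel$loci)
  if (length(bad)) stop("unknown locus: ", paste(bad, collapse = ", "))
  loci
}

#' @export
print.breed_panel <- function(x, ...) {
  cat("Breed panel:", length(x$breeds), "breeds x", length(x$loci),
      "biallelic loci\n")
  cat("Animals per breed:", min(x$n_animals), "-", max(x$n_animals),
      "(total", sum(x$n_animals), ")\n")
  nmono <- sum(x$monomorphic)
  if (nmono) cat("Monomorphic breed x locus cells:", nmono, "\n")
  if (nrow(x$flags)) {
    cat("Reconciled cells:", nrow(x$flags), "\n")
    for (i in seq_len(min(5, nrow(x$flags))))
      cat("  ", x$flags$breed_id[i], x$flags$locus[i], "-", x$flags$note[i], "\n")
    if (nrow(x$flags) > 5) cat("  ...\n")
  }
  invisible(x)
}

#' Subset a breed panel by breeds and/or loci
#' @param x a `breed_panel`.
#' @param breeds,loci subsets to keep (default all).
#' @param ... unused.
#' @export
subset.breed_panel <- function(x, breeds = NULL, loci = NULL, ...) {
  breeds <- if (is.null(breeds)) x$breeds else intersect(x$breeds, breeds)
  loci <- if (is.null(loci)) x$loci else match_loci(x, loci)
  x$counts <- x$counts[breeds, loci, , drop = FALSE]
  x$genotype_freq <- x$genotype_freq[breeds, loci, , drop = FALSE]
  x$allele_freq_published <- x$allele_freq_published[breeds, loci, , drop = FALSE]
  x$monomorphic <- x$monomorphic[breeds, loci, drop = FALSE]
  x$allele_labels <- x$allele_labels[loci, , drop = FALSE]
  x$n_animals <- x$n_animals[breeds]
  x$breeds <- breeds; x$loci <- loci
  x$flags <- x$flags[x$flags$breed_id %in% breeds & x$flags$locus %in% loci, ]
  x
}
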