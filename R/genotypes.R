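#' Individual-level genotype matrices
#'
#' Genotypes are coded per locus as the number of copies of the designated
#' reference (allele-1) allele: 0, 1 or 2; `NA` marks a missing call.
#' Missing calls are excluded pairwise (per locus or locus pair), never
#' listwise.
#'
#' @param path CSV with header: columns `individual_id`, `breed_id`, then
#'   one column per locus holding codes in `{0, 1, 2}` or empty/NA.
#' @return a data frame of class `genotype_matrix`.
#' @export
read_genotype_matrix <- function(path) {
  x <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("individual_id", "breed_id") %in% names(x)))
    stop("genotype matrix needs individual_id and breed_id columns")
  loci <- setdiff(names(x), c("individual_id", "breed_id"))
  for (l in loci) {
    v <- x[[l]]
    if (!all(is.na(v) | v %in% 0:2))
      stop("unknown genotype code at locus ", l,
           " (expected 0/1/2/NA): ", paste(unique(v[!v %in% 0:2 & !is.na(v)]),
                                           collapse = ", "))
    x[[l]] <- as.integer(v)
  }
  structure(x, class = c("genotype_matrix", "data.frame"), loci = loci)
}

#' Read PED/MAP genotypes (two allele columns per locus)
#'
#' Minimal whitespace-delimited reader for the classic pedigree dialect:
#' MAP supplies locus names (column 2); PED rows are
#' `family id father mother sex phenotype` followed by two allele symbols
#' per locus, `0` meaning missing.  The first allele symbol observed per
#' locus (in file order, after sorting symbols) is allele 1.
#'
#' @param ped,map file paths.
#' @return a `genotype_matrix` (family id used as `breed_id`).
#' @export
read_ped <- function(ped, map) {
  mp <- utils::read.table(map, header = FALSE, stringsAsFactors = FALSE)
  loci <- as.character(mp[[2]])
  pd <- utils::read.table(ped, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(pd) != 6 + 2 * length(loci))
    stop("PED has ", ncol(pd), " columns; expected ", 6 + 2 * length(loci))
  out <- data.frame(individual_id = as.character(pd[[2]]),
                    breed_id = as.character(pd[[1]]),
                    stringsAsFactors = FALSE)
  for (j in seq_along(loci)) {
    a1 <- as.character(pd[[6 + 2 * j - 1]]); a2 <- as.character(pd[[6 + 2 * j]])
    miss <- a1 == "0" | a2 == "0"
    sym <- sort(unique(c(a1[!miss], a2[!miss])))
    if (length(sym) > 2) stop("locus ", loci[j], " has >2 alleles")
    ref <- sym[1]
    g <- (a1 == ref) + (a2 == ref)
    g[miss] <- NA_integer_
    out[[loci[j]]] <- as.integer(g)
  }
  structure(out, class = c("genotype_matrix", "data.frame"), loci = loci)
}

#' Deterministically expand panel counts into individual genotypes
#'
#' Within each breed the reconstructed genotype counts are written out as
#' that many individuals per genotype class (class order 2, 1, 0 copies of
#' allele 1).  Loci are expanded independently, which preserves per-locus
#' frequencies exactly; between-locus phase is arbitrary and the expansion
#' must not be used for linkage statistics.
#'
#' @param panel a `breed_panel`.
#' @param loci loci to include (default all).
#' @return a `genotype_matrix` with `sum(n_animals)` rows.
#' @export
expand_panel_genotypes <- function(panel, loci = NULL) {
  loci <- if (is.null(loci)) panel$loci else match_loci(panel, loci)
  ids <- unlist(lapply(panel$breeds, function(b)
    paste0(b, "_", seq_len(panel$n_animals[b]))))
  out <- data.frame(
    individual_id = ids,
    breed_id = rep(panel$breeds, panel$n_animals),
    stringsAsFactors = FALSE)
  for (l in loci)
    out[[l]] <- unlist(lapply(panel$breeds, function(b) {
      cc <- panel$counts[b, l, ]
      rep(c(2L, 1L, 0L), cc)
    }))
  structure(out, class = c("genotype_matrix", "data.frame"), loci = loci)
}

#' Per-breed allele-1 frequencies from a genotype matrix
#' @param geno a `genotype_matrix`.
#' @return breeds x loci matrix.
#' @export
genotype_allele_freq <- function(geno) {
  loci <- attr(geno, "loci")
  breeds <- unique(geno$breed_id)
  f <- sapply(loci, function(l)
    tapply(geno[[l]], geno$breed_id, function(v) mean(v, na.rm = TRUE) / 2)[breeds])
  matrix(f, nrow = length(breeds), dimnames = list(breeds, loci))
}

#' Read a multi-species promoter alignment from FASTA
#'
#' Wraps [ape::read.FASTA()] and validates that all records share one
#' aligned width.  Gaps (`-`) and ambiguous bases are retained; pairwise
#' statistics mask any site where either sequence is not a plain base.
#'
#' @param path FASTA file.
#' @return character matrix (rows = records, upper case), class
#'   `species_alignment`.
#' @export
read_alignment <- function(path) {
  dna <- ape::read.FASTA(path)
  lens <- lengths(dna)
  if (length(unique(lens)) != 1)
    stop("ragged alignment: record lengths ",
         paste(sort(unique(lens)), collapse = ", "))
  m <- toupper(do.call(rbind, lapply(as.character(dna), identity)))
  rownames(m) <- names(dna)
  structure(m, class = c("species_alignment", class(m)))
}

#' Build a species alignment from in-memory sequences
#' @param seqs named character vector of equal-length sequences.
#' @return `species_alignment` character matrix.
#' @export
species_alignment <- function(seqs) {
  n <- nchar(seqs)
  if (length(unique(n)) != 1) stop("ragged alignment")
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(m) <- names(seqs)
  structure(m, class = c("species_alignment", class(m)))
}

#' Write a species alignment to FASTA
#' @param aln `species_alignment`.
#' @param path output path.
#' @export
write_alignment <- function(aln, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_len(nrow(aln)))
    writeLines(c(paste0(">", rownames(aln)[i]),
                 paste(aln[i, ], collapse = "")), con)
  invisible(path)
}
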