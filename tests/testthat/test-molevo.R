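make_pair_theta_half <- function() {
  # 200 sites, 50 of each base; 10 transition and 6 transversion changes
  # arranged to preserve composition, so pooled GC is exactly 0.5
  s1 <- rep(c("A", "C", "G", "T"), each = 50)
  s2 <- s1
  s2[1:5] <- "G";   s2[101:105] <- "A"     # A<->G transitions
  s2[6:8] <- "T";   s2[151:153] <- "A"     # A<->T transversions
  list(s1 = s1, s2 = s2)
}

test_that("T92 reduces to Kimura's two-parameter form at GC = 0.5", {
  pr <- make_pair_theta_half()
  d <- t92_distance(pr$s1, pr$s2)
  expect_equal(d$theta, 0.5)
  expect_equal(d$P, 10 / 200)
  expect_equal(d$Q, 6 / 200)
  expect_equal(d$d, k2p_oracle(d$P, d$Q), tolerance = 1e-12)
  expect_equal(t92_distance(pr$s1, pr$s1)$d, 0)
})

test_that("gamma rate variation inflates the distance", {
  pr <- make_pair_theta_half()
  d0 <- t92_distance(pr$s1, pr$s2)$d
  for (a in c(0.5, 2, 5.6803)) {
    expect_gte(t92_distance(pr$s1, pr$s2, gamma_shape = a)$d, d0)
  }
  # smaller shape = more rate heterogeneity = larger correction
  d_small <- t92_distance(pr$s1, pr$s2, gamma_shape = 0.5)$d
  d_big <- t92_distance(pr$s1, pr$s2, gamma_shape = 50)$d
  expect_gt(d_small, d_big)
})

test_that("distances recover the generating divergence of simulated pairs", {
  set.seed(51)
  tr <- ape::read.tree(text = "(a:0.025,b:0.025);")
  aln <- simulate_alignment_t92(tr, 10000, theta = 0.5)
  est <- t92_distance(aln["a", ], aln["b", ])
  # site-bootstrap SE
  boots <- replicate(100, {
    cols <- sample.int(10000, replace = TRUE)
    t92_distance(aln["a", cols], aln["b", cols])$d
  })
  expect_lt(abs(est$d - 0.05), 3 * sd(boots))
})

test_that("divergence matrix: counting oracle, SE behaviour, layout", {
  pr <- make_pair_theta_half()
  aln <- structure(rbind(sp1 = pr$s1, sp2 = pr$s2),
                   class = c("species_alignment", "matrix", "array"))
  dv <- divergence_matrix(aln, c("sp1", "sp2"), n_boot = 100)
  expect_equal(dv$d["sp1", "sp2"], k2p_oracle(0.05, 0.03), tolerance = 1e-12)
  expect_gt(dv$se["sp1", "sp2"], 0)
  # identical haplotypes within and between species: d = 0, SE = 0
  aln0 <- structure(rbind(a = pr$s1, b = pr$s1),
                    class = c("species_alignment", "matrix", "array"))
  dv0 <- divergence_matrix(aln0, c("x", "y"), n_boot = 20)
  expect_equal(dv0$d["x", "y"], 0)
  expect_equal(dv0$se["x", "y"], 0)
  # longer alignments give smaller bootstrap SE at the same divergence
  set.seed(52)
  alnL <- structure(cbind(unclass(aln), unclass(aln), unclass(aln),
                          unclass(aln), unclass(aln), unclass(aln),
                          unclass(aln), unclass(aln), unclass(aln),
                          unclass(aln)),
                    class = class(aln))
  dvL <- divergence_matrix(alnL, c("sp1", "sp2"), n_boot = 100)
  expect_lt(dvL$se["sp1", "sp2"], dv$se["sp1", "sp2"])
  # combined table: distance below diagonal, SE above
  expect_equal(dv$table["sp2", "sp1"], dv$d["sp1", "sp2"])
  expect_equal(dv$table["sp1", "sp2"], dv$se["sp1", "sp2"])
})

test_that("Tajima's D matches the constants oracle and known signs", {
  # 4 sequences, 2 segregating sites, both singletons
  aln <- species_alignment(c(h1 = "AAAA", h2 = "ATAA", h3 = "AACA",
                             h4 = "AAAA"))
  td <- tajimas_d(aln)
  expect_identical(td$S, 2L)
  expect_equal(td$pi, 1.0)
  expect_equal(td$D, tajima_oracle(4, 2, 1.0), tolerance = 1e-12)
  expect_equal(td$D, -0.70988, tolerance = 1e-4)
  # every segregating site at frequency 1/2: positive D
  aln2 <- species_alignment(c(h1 = "TTAA", h2 = "TTAA", h3 = "AAAA",
                              h4 = "AAAA"))
  expect_gt(tajimas_d(aln2)$D, 0)
  expect_error(tajimas_d(species_alignment(
    c(h1 = "AAAA", h2 = "AAAA", h3 = "AAAA", h4 = "AAAA"))), "segregating")
})

test_that("Tajima's D is centred near zero under the neutral coalescent", {
  set.seed(53)
  d <- replicate(1000, {
    a <- coalescent_sample(20, 5)
    if (ncol(a) < 2 || length(unique(as.vector(a))) < 2) return(NA_real_)
    tajimas_d(a)$D
  })
  d <- d[!is.na(d)]
  expect_gt(length(d), 900)
  expect_lt(abs(mean(d)), 0.1)
  expect_gt(mean(d > -2 & d < 2), 0.9)
})

test_that("neighbor joining recovers additive trees exactly", {
  # 3 taxa: closed-form branch lengths
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- nj_tree(d3)
  bl <- setNames(t3$edge.length[match(seq_len(3), t3$edge[, 2])],
                 t3$tip.label)
  expect_equal(unname(bl["A"]), (3 + 4 - 5) / 2)
  expect_equal(unname(bl["B"]), (3 + 5 - 4) / 2)
  expect_equal(unname(bl["C"]), (4 + 5 - 3) / 2)
  # constructed additive 4-taxon matrix recovers the split and lengths
  tr4 <- ape::read.tree(text = "((A:1,B:2):1.5,(C:1,D:3):1);")
  nt <- nj_tree(ape::cophenetic.phylo(tr4))
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr4), nt)), 0)
  expect_equal(sum(nt$edge.length), sum(ape::unroot(tr4)$edge.length),
               tolerance = 1e-10)
  # property over random additive trees
  set.seed(54)
  for (k in 1:20) {
    tr <- ape::rtree(sample(4:8, 1))
    nt <- nj_tree(ape::cophenetic.phylo(tr))
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), nt)), 0)
  }
  # degenerate equidistant matrix still yields a valid tree
  de <- matrix(1, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(de) <- 0
  td <- nj_tree(de)
  expect_s3_class(td, "phylo")
  expect_true(all(td$edge.length >= 0))
})

test_that("bootstrap support is high for a well-separated split", {
  set.seed(55)
  tr <- ape::read.tree(text = "((a:0.02,b:0.02):0.15,(c:0.02,d:0.02):0.15);")
  aln <- simulate_alignment_t92(tr, 800, theta = 0.5)
  nb <- nj_bootstrap(aln, groups = rownames(aln), n_boot = 50)
  expect_s3_class(nb$tree, "phylo")
  expect_true(all(nb$support >= 0 & nb$support <= 100))
  expect_gt(max(nb$support), 90)
})
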