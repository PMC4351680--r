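test_that("generators are bit-reproducible under a fixed seed", {
  cfg <- sim_config(seed = 61, n_breeds = 8, n_animals = 12,
                    n_neutral_loci = 4)
  c1 <- simulate_climate(cfg); c2 <- simulate_climate(cfg)
  expect_identical(c1, c2)
  s1 <- simulate_breed_panel(cfg, c1); s2 <- simulate_breed_panel(cfg, c2)
  expect_identical(s1$panel$counts, s2$panel$counts)
  set.seed(62); a1 <- coalescent_sample(6, 3)
  set.seed(62); a2 <- coalescent_sample(6, 3)
  expect_identical(a1, a2)
})

test_that("climate generator honours the configured correlation structure", {
  cfg0 <- sim_config(seed = 63, n_breeds = 200)
  cl0 <- simulate_climate(cfg0)
  # identity correlation: base-variable pairs uncorrelated
  for (pair in list(c("LAT", "TAR"), c("LON", "HrA"), c("MINaT", "MxR")))
    expect_lt(abs(cor(cl0[[pair[1]]], cl0[[pair[2]]])), 0.2)
  # a thermal-width anticorrelation emerges from the configured bases
  vars <- names(cfg0$climate_mean)
  cc <- diag(length(vars)); dimnames(cc) <- list(vars, vars)
  cc["MINaT", "MAXaT"] <- cc["MAXaT", "MINaT"] <- 0.5
  cfg1 <- sim_config(seed = 64, n_breeds = 200, climate_cor = cc)
  cl1 <- simulate_climate(cfg1)
  expect_gt(cor(cl1$MINaT, cl1$MAXaT), 0.3)
  expect_lt(cor(cl1$MINaT, cl1$TW), -0.7)
  # derived columns and type bands
  expect_equal(cl1$TW, cl1$MAXaT - cl1$MINaT)
  expect_equal(cl1$THI, compute_thi(cl1$MAXaT, cl1$HrA / 100))
  expect_true(all(cl1$CTY[cl1$TAR <= 250] == "A"))
  expect_true(all(cl1$CTY[cl1$TAR > 500 & cl1$TAR <= 1000] == "SD"))
  # non-PSD correlation rejected at config time
  bad <- cc; bad["LAT", "LON"] <- bad["LON", "LAT"] <- 2
  expect_error(sim_config(climate_cor = bad), "positive semi-definite")
})

test_that("panel generator produces HWE genotypes at the intended frequencies", {
  cfg <- sim_config(seed = 65, n_breeds = 40, n_animals = 200,
                    n_neutral_loci = 6, neutral_fst = 0.05)
  sim <- simulate_breed_panel(cfg)
  af <- allele_freq(sim$panel)
  # drawn frequencies track the latent truth at n = 200 animals
  expect_lt(max(abs(af - sim$truth)), 0.1)
  # genotype counts consistent with HWE within breeds (pooled exact test)
  pv <- vapply(sim$panel$loci, function(l) {
    cc <- sim$panel$counts[5, l, ]
    hwe_exact_test(cc[1], cc[2], cc[3])
  }, 0)
  expect_gt(min(pv), 1e-4)
})

test_that("zero cline slope leaves selected loci indistinguishable from neutral", {
  flagged <- 0L
  for (k in 1:25) {
    cfg <- sim_config(n_breeds = 31, n_animals = 25, n_neutral_loci = 9,
                      selected = data.frame(variable = "MINaT", slope = 0,
                                            baseline = 0),
                      neutral_fst = 0.07, seed = 9500 + k)
    sim <- simulate_breed_panel(cfg)
    set.seed(9500 + k)
    tail <- 0.025 / 10
    sc <- fst_outlier_scan(sim$panel, n_sims = 3000,
                           tails = c(tail, 1 - tail))
    if (any(sc$table$class != "neutral", na.rm = TRUE)) flagged <- flagged + 1L
  }
  expect_gte(25L - flagged, 22L)
})

test_that("coalescent sample matches Watterson and pairwise expectations", {
  set.seed(66)
  a1 <- sum(1 / seq_len(9))
  S <- replicate(2000, sum(apply(coalescent_sample(10, 5), 2,
                                 function(col) length(unique(col)) > 1)))
  expect_lt(abs(mean(S) - 5 * a1), 0.05 * 5 * a1)
  pi2 <- replicate(2000, {
    a <- coalescent_sample(2, 5)
    sum(a[1, ] != a[2, ])
  })
  expect_lt(abs(mean(pi2) - 5), 0.05 * 5 + 0.15)
})

test_that("T92 alignment evolution: stationarity, zero branches, GC content", {
  set.seed(67)
  tr <- ape::read.tree(text = "(a:0,b:0.4);")
  aln <- simulate_alignment_t92(tr, 10000, theta = 0.5)
  root_gc <- mean(aln["a", ] %in% c("G", "C"))
  expect_lt(abs(root_gc - 0.5), 0.02)
  # zero-length branch copies the parent exactly; long branch diverges
  expect_gt(mean(aln["a", ] != aln["b", ]), 0.1)
  tr0 <- ape::read.tree(text = "(a:0,b:0);")
  aln0 <- simulate_alignment_t92(tr0, 500, theta = 0.3)
  expect_identical(aln0["a", ], aln0["b", ])
  # biased GC equilibrium is respected on a long branch
  set.seed(68)
  trL <- ape::read.tree(text = "(a:4,b:4);")
  alnL <- simulate_alignment_t92(trL, 8000, theta = 0.8)
  expect_lt(abs(mean(alnL["b", ] %in% c("G", "C")) - 0.8), 0.03)
  expect_error(simulate_alignment_t92(
    structure(list(edge = matrix(c(3L, 3L, 1L, 2L), 2),
                   edge.length = c(NA, 1), Nnode = 1L,
                   tip.label = c("a", "b")), class = "phylo"), 100),
    "non-finite")
})

test_that("end-to-end pipeline recovers exactly the planted signals", {
  ok <- 0L; false_pos <- 0L
  for (k in 1:20) {
    cfg <- sim_config(n_breeds = 31, n_animals = 27, n_neutral_loci = 8,
                      selected = data.frame(variable = "MINaT", slope = 1.3,
                                            baseline = -0.8),
                      outlier_fst = 0.35, neutral_fst = 0.07,
                      seed = 20000 + k)
    cli <- simulate_climate(cfg)
    sim <- simulate_breed_panel(cfg, cli)
    vars <- c("MINaT", "MAXaT", "TAR", "HrA")
    sc <- sam_scan(sim$genotypes, cli, variables = vars)
    q2 <- press_q2(climate_predictors(cli, vars),
                   allele_freq(sim$panel), 2)$Q2
    set.seed(20000 + k)
    tail <- 0.025 / 10
    out <- fst_outlier_scan(sim$panel, n_sims = 3000,
                            tails = c(tail, 1 - tail))
    # an association call needs both a significant SAM model and Q2 > 0.4
    sam_loci <- unique(sc$results$locus[which(sc$results$significant)])
    assoc <- intersect(sam_loci, names(q2)[q2 > 0.4])
    outliers <- out$table$locus[which(out$table$class == "directional")]
    driven_found <- "sel1" %in% assoc
    outlier_found <- "out1" %in% outliers
    neutral_hits <- length(grep("^neu", c(assoc, outliers), value = TRUE))
    false_pos <- false_pos + neutral_hits
    if (driven_found && outlier_found && neutral_hits == 0) ok <- ok + 1L
  }
  expect_gte(ok, 15L)
  expect_lte(false_pos, 1L)
})
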