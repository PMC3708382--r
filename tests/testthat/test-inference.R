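## shared strong-signal quartet fixture
quartet_chrono <- read_newick("((A:50,B:50):50,(C:50,D:50):50);", rooted = TRUE)
strong_aln <- simulate_alignment(quartet_chrono,
                                 site_rate_vector(rep(2e-3, 1000), "generating"),
                                 "K2P", seed = 101)
qset <- inference_settings("K2P", n_gamma_categories = 1,
                           bootstrap_reps = 15, seed = 5)

## the three quartet topologies on A,B,C,D
quartets <- lapply(c("((A,B),(C,D));", "((A,C),(B,D));", "((A,D),(B,C));"),
                   function(s) {
                     t <- read_newick(s)
                     t$edge.length <- rep(0.05, nrow(t$edge))
                     t
                   })

test_that("tree_log_likelihood equals exhaustive enumeration (with gamma)", {
  set.seed(33)
  phy <- random_topology(4, 12)
  phy$edge.length <- runif(nrow(phy$edge), 0.05, 0.5)
  mat <- matrix(sample(c("A", "C", "G", "T"), 4 * 8, TRUE), 4, 8,
                dimnames = list(phy$tip.label, NULL))
  aln <- pi_alignment(mat, "dna")
  model <- substitution_model("K2P", 2)
  s1 <- inference_settings("K2P", n_gamma_categories = 1)
  expect_equal(tree_log_likelihood(phy, aln, s1),
               oracle_tree_loglik(phy, aln, model), tolerance = 1e-10)
  s4 <- inference_settings("K2P", n_gamma_categories = 4)
  expect_equal(tree_log_likelihood(phy, aln, s4, gamma_shape = 0.6),
               oracle_tree_loglik(phy, aln, model, shape = 0.6, k = 4),
               tolerance = 1e-10)
  ## likelihood is invariant to rerooting (pulley principle)
  rer <- ape::root(phy, outgroup = phy$tip.label[1], resolve.root = TRUE)
  rer$edge.length[rer$edge.length == 0] <- 1e-12
  expect_equal(tree_log_likelihood(ape::unroot(rer), aln, s1),
               tree_log_likelihood(phy, aln, s1), tolerance = 1e-8)
})

test_that("two identical taxa at zero distance give log(1/4) per site", {
  tr <- read_newick("(A:0.0,B:0.0);")
  aln <- pi_alignment(rbind(A = "G", B = "G"), "dna")
  expect_equal(tree_log_likelihood(tr, aln, inference_settings("K2P", 1)),
               log(0.25), tolerance = 1e-12)
})

test_that("ml_tree recovers the generating quartet and beats its start", {
  fit <- ml_tree(strong_aln, qset)
  expect_identical(bipartitions(fit$tree), "C|D")
  ## exhaustive quartet check: generating topology has the best likelihood
  lls <- vapply(quartets, function(q)
    as.numeric(stats::logLik(pirank:::.refit_topology(q, fit$fit, qset))),
    numeric(1))
  expect_identical(which.max(lls), 1L)
  expect_gte(fit$logLik, max(lls) - 1e-3)
  ## permuting taxon order changes nothing topologically
  fit_p <- ml_tree(strong_aln[c(3, 1, 4, 2), ], qset)
  expect_identical(bipartitions(fit_p$tree), "C|D")
  expect_equal(fit_p$logLik, fit$logLik, tolerance = 1e-6)
})

test_that("ml_bootstrap: full support on strong signal, seeded reproducibility", {
  fit <- ml_tree(strong_aln, qset)
  bp <- ml_bootstrap(strong_aln, qset, fit)
  expect_identical(bp$ml_bp, 100)
  bp2 <- ml_bootstrap(strong_aln, qset, fit)
  expect_identical(bp, bp2)
  ## all-invariant alignment: arbitrary tree, supports still bounded
  flat <- pi_alignment(matrix("A", 4, 30,
                              dimnames = list(c("A", "B", "C", "D"), NULL)),
                       "dna")
  qf <- inference_settings("K2P", n_gamma_categories = 1,
                           bootstrap_reps = 5, seed = 2)
  bpf <- quiet(ml_bootstrap(flat, qf, quiet(ml_tree(flat, qf))))
  expect_true(all(bpf$ml_bp >= 0 & bpf$ml_bp <= 100))
})

test_that("alrt matches the exhaustive quartet oracle and is non-negative", {
  fit <- ml_tree(strong_aln, qset)
  a <- alrt_statistic(fit, qset)
  expect_identical(a$split, "C|D")
  expect_gte(a$alrt, 0)
  lls <- sort(vapply(quartets, function(q)
    as.numeric(stats::logLik(pirank:::.refit_topology(q, fit$fit, qset))),
    numeric(1)), decreasing = TRUE)
  expect_equal(a$alrt, 2 * (lls[1] - lls[2]), tolerance = 0.02)
  ## null case: no site supports the internal branch
  null_aln <- pi_alignment(
    rbind(A = rep(c("A", "C"), 20), B = rep(c("C", "A"), 20),
          C = rep(c("A", "C"), c(20, 20)), D = rep(c("C", "A"), c(20, 20))),
    "dna")
  nf <- quiet(ml_tree(null_aln, qset))
  expect_lt(quiet(alrt_statistic(nf, qset))$alrt[1], 0.5)
})

test_that("fitch_score equals brute-force minimum and is unrooted", {
  t1 <- read_newick("((A,B),(C,D));")
  aln1 <- pi_alignment(rbind(A = "A", B = "A", C = "T", D = "T"), "dna")
  expect_identical(fitch_score(t1, aln1), 1L)
  t2 <- read_newick("((A,C),(B,D));")
  expect_identical(fitch_score(t2, aln1), 2L)
  expect_identical(fitch_score(pi_alignment(matrix("G", 4, 7,
    dimnames = list(LETTERS[1:4], NULL)), "dna"), topology = t1), 0L)
  for (seed in 1:8) {
    phy <- random_topology(5, seed + 40)
    mat <- matrix(sample(c("A", "C", "G", "T", "-"), 5 * 4, TRUE,
                         prob = c(rep(0.23, 4), 0.08)), 5, 4,
                  dimnames = list(phy$tip.label, NULL))
    aln <- pi_alignment(mat, "dna")
    codes <- pirank:::alignment_codes(aln)
    expect_identical(fitch_score(phy, aln),
                     as.integer(oracle_fitch(phy, codes)))
    ## rerooting leaves the score unchanged
    rr <- ape::root(phy, outgroup = phy$tip.label[2], resolve.root = TRUE)
    expect_identical(fitch_score(rr, aln), fitch_score(phy, aln))
  }
})

test_that("mp_tree: exhaustive optimum, search contract, site additivity", {
  mp <- mp_tree(strong_aln, qset)
  expect_true(mp$exhaustive)
  expect_identical(bipartitions(mp$tree), "C|D")
  ## duplicate an informative site: score rises by its minimum steps
  col <- unclass(strong_aln)[, 1, drop = FALSE]
  aug <- pi_alignment(cbind(unclass(strong_aln), col), "dna")
  extra <- fitch_score(mp$tree, pi_alignment(col, "dna"))
  expect_identical(mp_tree(aug, qset)$score, mp$score + extra)
  ## heuristic path (> cutoff): never worse than the NJ topology
  ch <- generate_chronogram(10, 400, seed = 3)
  rv <- assign_site_rates(simulation_design(1e-3, gamma_alpha = 1,
                                            n_sites = 200, model_tag = "K2P"),
                          seed = 4)
  aln10 <- simulate_alignment(ch, rv, "K2P", seed = 5)
  st10 <- inference_settings("K2P", n_gamma_categories = 1,
                             bootstrap_reps = 5, seed = 6)
  mp10 <- mp_tree(aln10, st10)
  expect_false(mp10$exhaustive)
  nj_score <- fitch_score(pirank:::.nj_start(pirank:::as_phydat(aln10)), aln10)
  expect_lte(mp10$score, nj_score)
})

test_that("mp_bootstrap is strong on signal and reproducible", {
  mp <- mp_tree(strong_aln, qset)
  bp <- mp_bootstrap(strong_aln, qset, mp)
  expect_identical(bp$mp_bp, 100)
  expect_identical(bp, mp_bootstrap(strong_aln, qset, mp))
  ## agreement with ML-BP on the strong-signal gene
  ml <- ml_bootstrap(strong_aln, qset)
  expect_lte(max(abs(ml$ml_bp - bp$mp_bp)), 15)
})

test_that("decay_index matches the exhaustive quartet oracle", {
  mp <- mp_tree(strong_aln, qset)
  di <- decay_index(mp, strong_aln, qset)
  expect_true(di$exact)
  expect_gte(di$di, 0)
  sc <- sort(vapply(quartets, fitch_score, integer(1),
                    alignment = strong_aln))
  expect_identical(di$di, as.integer(sc[2] - sc[1]))
  ## unsupported branch has decay 0
  null_aln <- pi_alignment(
    rbind(A = rep("A", 10), B = rep("C", 10), C = rep("G", 10),
          D = rep("T", 10)), "dna")
  mp0 <- mp_tree(null_aln, qset)
  expect_identical(decay_index(mp0, null_aln, qset)$di, 0L)
})
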