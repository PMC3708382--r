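test_that("generate_chronogram is ultrametric, exact-depth, deterministic", {
  ch <- generate_chronogram(4, 100, seed = 1)
  d <- ape::node.depth.edgelength(ch)[1:4]
  expect_equal(d, rep(100, 4), tolerance = 1e-9)
  expect_identical(write_newick(generate_chronogram(9, 50, seed = 5)),
                   write_newick(generate_chronogram(9, 50, seed = 5)))
  differs <- vapply(1:10, function(s)
    !identical(bipartitions(generate_chronogram(9, 50, seed = s)),
               bipartitions(generate_chronogram(9, 50, seed = 99))),
    logical(1))
  expect_true(any(differs))
  expect_error(generate_chronogram(3, 100), ">= 4")
})

test_that("Yule waiting times follow the exponential growth law", {
  ## while k lineages exist the next split waits Exp(k): over many draws
  ## the mean inter-split time from k to k+1 lineages is 1/k
  n <- 8
  waits <- matrix(NA_real_, 500, n - 2)
  for (s in seq_len(500)) {
    ev <- attr(generate_chronogram(n, 1, seed = s), "event_times")
    waits[s, ] <- diff(ev)  # unscaled split times, k = 2 .. n-1
  }
  expected <- 1 / (2:(n - 1))
  expect_equal(colMeans(waits), expected, tolerance = 0.15)
})

test_that("fixed-counts site rates reproduce the stated design exactly", {
  des <- simulation_design(5e-4, gamma_alpha = 1, model_tag = "JTT")
  rv <- assign_site_rates(des, seed = 2)
  expect_length(rv$rates, 300)
  expect_identical(sum(rv$rates == 0), 60L)
  tab <- table(rv$rates[rv$rates > 0])
  expect_length(tab, 10)
  expect_true(all(tab == 24))
  ## category rates average the design mean over the variable sites
  expect_equal(mean(rv$rates[rv$rates > 0]), 5e-4, tolerance = 1e-12)
  ## same seed, same multiset and positions; different seed, same multiset
  rv2 <- assign_site_rates(des, seed = 2)
  expect_identical(rv$rates, rv2$rates)
  rv3 <- assign_site_rates(des, seed = 3)
  expect_equal(sort(rv$rates), sort(rv3$rates), tolerance = 1e-15)
  ## indivisible counts error
  expect_error(assign_site_rates(
    simulation_design(1e-4, gamma_alpha = 1, n_sites = 299)), "divisible")
})

test_that("no-heterogeneity and scaling conventions behave as documented", {
  des <- simulation_design(4e-4, gamma_alpha = NA, model_tag = "K2P")
  rv <- assign_site_rates(des, seed = 1)
  expect_setequal(unique(rv$rates), c(0, 4e-4))
  ## global scaling preserves the alignment-wide mean instead
  desg <- simulation_design(4e-4, gamma_alpha = NA, model_tag = "K2P",
                            rate_scaling = "global")
  rvg <- assign_site_rates(desg, seed = 1)
  expect_equal(mean(rvg$rates), 4e-4, tolerance = 1e-12)
})

test_that("simulate_alignment honours invariant sites and determinism", {
  ch <- generate_chronogram(6, 200, seed = 4)
  rates <- site_rate_vector(c(rep(0, 10), rep(2e-3, 20)), "generating")
  a1 <- simulate_alignment(ch, rates, "K2P", seed = 9)
  a2 <- simulate_alignment(ch, rates, "K2P", seed = 9)
  expect_identical(unclass(a1), unclass(a2))
  inv <- which(rates$rates == 0)
  expect_true(all(apply(unclass(a1)[, inv], 2,
                        function(x) length(unique(x)) == 1)))
  ## all-zero rates: entire alignment monomorphic
  a0 <- simulate_alignment(ch, site_rate_vector(rep(0, 5), "generating"),
                           "JTT", seed = 1)
  expect_true(all(apply(unclass(a0), 2, function(x) length(unique(x)) == 1)))
})

test_that("two-taxon K2P divergence matches the closed form", {
  ## path length 2 * 60 Myr at rate 2.5e-3 -> v = 0.3 expected subs
  ch <- read_newick("((A:60,B:60):60,(C:60,D:60):60);", rooted = TRUE)
  rate <- 2.5e-3
  n <- 10000
  aln <- simulate_alignment(ch, site_rate_vector(rep(rate, n), "generating"),
                            "K2P", seed = 10)
  x <- unclass(aln)
  pdiff <- mean(x["A", ] != x["B", ])
  expected <- k2p_p_diff(2 * 60 * rate, kappa = 2)
  ## binomial error: ~4 sigma margin
  expect_lt(abs(pdiff - expected), 4 * sqrt(expected * (1 - expected) / n))
})

test_that("JTT simulation is stationary at the model frequencies", {
  ch <- read_newick("((A:40,B:40):40,(C:40,D:40):40);", rooted = TRUE)
  n <- 12500  # 4 taxa x 12500 sites = 50000 residue draws
  aln <- simulate_alignment(ch, site_rate_vector(rep(5e-3, n), "generating"),
                            "JTT", seed = 11)
  freq <- table(factor(unclass(aln), levels = pirank:::AA_STATES)) / (4 * n)
  expect_lt(max(abs(as.numeric(freq) - pirank:::JTT_FREQS)), 0.01)
})

test_that("build_study emits the full grid with reproducible manifest", {
  grid <- standard_design_grid("K2P", n_replicates = 2, n_sites = 50)
  expect_length(grid, 50)
  ## two replicates per design on a small chronogram
  ch <- generate_chronogram(6, 300, seed = 1)
  study <- build_study(grid[1:4], ch, seed = 5)
  expect_length(study$genes, 8)
  expect_true(all(vapply(study$genes, function(g) ncol(g$alignment),
                         integer(1)) == 50))
  ## stored seeds regenerate identical alignments
  g <- study$genes[[3]]
  again <- simulate_alignment(ch, assign_site_rates(g$design, seed = g$seed),
                              g$design$model_tag, g$design$kappa,
                              seed = g$seed + 1)
  expect_identical(unclass(again), unclass(g$alignment))
  ## round trip through disk
  dir <- withr::local_tempdir()
  write_study(study, dir)
  man <- read.delim(file.path(dir, "manifest.tsv"))
  expect_identical(nrow(man), 8L)
  back <- read_alignment(file.path(dir, man$path[3]))
  expect_identical(unclass(back), unclass(g$alignment))
})

test_that("substitution counts scale linearly with site rate", {
  ## averaged over replicates, per-site parsimony steps on the true tree
  ## grow ~ linearly in lambda in the low-rate regime
  ch <- generate_chronogram(10, 300, seed = 6)
  rates <- rep(c(2e-4, 4e-4, 8e-4), each = 60)
  rv <- site_rate_vector(rates, "generating")
  aln <- simulate_alignment(ch, rv, "K2P", seed = 7)
  d <- pirank:::as_phydat(aln)
  per_pattern <- phangorn::fitch(ch, d, site = "pattern")
  steps <- per_pattern[attr(d, "index")]
  mean_steps <- tapply(steps, rates, mean)
  ratios <- mean_steps / as.numeric(names(mean_steps))
  expect_lt(max(ratios) / min(ratios), 1.35)
})
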