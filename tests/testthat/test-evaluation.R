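test_that("rf_distance satisfies the metric axioms and known cases", {
  t1 <- read_newick("((A,B),(C,D),E);")
  expect_identical(rf_distance(t1, t1), 0L)
  ## one NNI apart on 5 taxa (only the C|D split is destroyed): distance 2
  t2 <- read_newick("((A,B),(C,E),D);")
  expect_identical(rf_distance(t1, t2), 2L)
  expect_error(rf_distance(t1, read_newick("((A,B),(C,X),E);")), "leaf")
  set.seed(9)
  for (i in 1:12) {
    n <- sample(5:10, 1)
    ta <- random_topology(n, i); tb <- random_topology(n, i + 50)
    tc <- random_topology(n, i + 100)
    ## agreement with the independent phangorn implementation
    expect_identical(rf_distance(ta, tb),
                     as.integer(phangorn::RF.dist(ta, tb)))
    ## symmetry, identity, triangle inequality, parity, range
    expect_identical(rf_distance(ta, tb), rf_distance(tb, ta))
    expect_lte(rf_distance(ta, tc),
               rf_distance(ta, tb) + rf_distance(tb, tc))
    expect_identical(rf_distance(ta, tb) %% 2L, 0L)
    expect_lte(rf_distance(ta, tb), 2L * (n - 3L))
  }
})

test_that("pair_genes pairs best-with-worst, dropping an odd median", {
  mk <- function(n) data.frame(gene_id = sprintf("g%02d", 1:n),
                               dpi = rev(seq_len(n)), rank = 1:n)
  p50 <- pair_genes(mk(50))
  expect_identical(nrow(p50), 25L)
  expect_identical(p50$gene_hi[1], "g01"); expect_identical(p50$gene_lo[1], "g50")
  p4 <- pair_genes(mk(4))
  expect_identical(p4$gene_hi, c("g01", "g02"))
  expect_identical(p4$gene_lo, c("g04", "g03"))
  p5 <- pair_genes(mk(5))
  expect_identical(nrow(p5), 2L)
  expect_false("g03" %in% c(p5$gene_hi, p5$gene_lo))
})

test_that("ppp and epp implement the paired-performance arithmetic", {
  expect_equal(ppp(3, 1), 0.75)
  expect_equal(ppp(2, 2), 0.5)
  expect_equal(ppp(1, 0), 1)
  expect_error(ppp(0, 0), "zero")
  expect_error(ppp(1, 2), ">=")
  e <- epp(c(9, 8, 7, 6, 1), c(1, 2, 3, 4, 5))
  expect_equal(e$epp, 0.8)
  expect_identical(c(e$n_hi, e$n_lo), c(4L, 1L))
  ## all ties: undefined
  expect_true(is.na(epp(c(1, 1), c(1, 1))$epp))
  ## antisymmetry under gene swap
  set.seed(4)
  a <- sample(0:100, 12, TRUE); b <- sample(0:100, 12, TRUE)
  e1 <- epp(a, b); e2 <- epp(b, a)
  if (!is.na(e1$epp)) expect_equal(e2$epp, 1 - e1$epp)
  ## half-tie policy splits ties evenly
  eh <- epp(c(5, 5, 9), c(5, 5, 1), tie_policy = "half")
  expect_equal(eh$epp, 2 / 3)
  expect_error(epp(1:3, 1:4), "node set")
})

test_that("supports map onto the reference by bipartition identity", {
  ref <- read_newick("((A,B),(C,D),(E,F));")
  same <- data.frame(split = bipartitions(ref), x = c(10, 20, 30))
  m <- map_supports_to_reference(same, ref, "x")
  expect_equal(unname(m[same$split]), same$x)
  ## fully incompatible gene tree contributes nothing
  other <- read_newick("((A,C),(B,E),(D,F));")
  sup_other <- data.frame(split = bipartitions(other), x = c(9, 9, 9))
  expect_identical(unname(map_supports_to_reference(sup_other, ref, "x")),
                   c(0, 0, 0))
  ## partial overlap: exactly the shared splits carry support
  half <- read_newick("((A,B),(C,E),(D,F));")
  sup_half <- data.frame(split = bipartitions(half), x = c(5, 5, 5))
  mapped <- map_supports_to_reference(sup_half, ref, "x")
  shared <- intersect(bipartitions(half), bipartitions(ref))
  expect_true(all(mapped[shared] == 5))
  expect_true(all(mapped[setdiff(names(mapped), shared)] == 0))
})

test_that("plrs normalizations and the summation identity", {
  m <- rbind(g1 = c(10, 0, 4), g2 = c(0, 0, 4), g3 = c(5, 0, 2))
  p <- plrs(m)
  expect_equal(unname(p["g1"]), mean(c(10, 0, 4) / 3))
  expect_equal(plrs(matrix(0, 2, 4)), c(0, 0), ignore_attr = TRUE)
  ## single gene, single node: statistic / n_genes
  expect_equal(unname(plrs(matrix(10, 1, 1), n_genes = 5)), 2)
  ## sum over genes equals grand node-mean of the summed support
  expect_equal(sum(p), mean(colSums(m)) / nrow(m) * 1)
  pn <- plrs(m, normalization = "node_sum")
  expect_equal(unname(pn["g1"]), mean(c(10 / 15, 0, 4 / 10)))
})

test_that("cumulative paths conserve totals and bound all orderings", {
  set.seed(11)
  sup <- setNames(runif(9), sprintf("g%d", 1:9))
  ranking <- data.frame(gene_id = sample(names(sup)), rank = 1:9)
  cp <- cumulative_paths(sup, ranking)
  total <- sum(sup)
  expect_equal(cp$ideal[9], total)
  expect_equal(cp$worst[9], total)
  expect_equal(cp$average[9], total)
  expect_equal(cp$dpi_order[9], total)
  expect_true(all(cp$ideal >= cp$dpi_order - 1e-12))
  expect_true(all(cp$ideal >= cp$average - 1e-12))
  expect_true(all(cp$worst <= cp$dpi_order + 1e-12))
  ## perfectly predictive case: DPI order coincides with the ideal path
  ranking2 <- data.frame(gene_id = names(sort(sup, decreasing = TRUE)),
                         rank = 1:9)
  cp2 <- cumulative_paths(sup, ranking2)
  expect_equal(cp2$dpi_order, cp2$ideal)
})

test_that("pearson matches direct computation", {
  expect_equal(pearson(1:10, 2 * (1:10) + 1)$r, 1)
  expect_equal(pearson(1:10, -(1:10))$r, -1)
  p <- pearson(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(p$r, 0.6)
  ## p-value agrees with cor.test
  ct <- cor.test(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(p$p, unname(ct$p.value), tolerance = 1e-12)
  expect_error(pearson(rep(1, 5), 1:5), "constant")
})

test_that("evaluate_study runs the fixture end-to-end and is reproducible", {
  fx <- make_fixtures(seed = 2)
  st <- evaluation_settings(
    support = "ml_bp",
    inference = inference_settings("K2P", n_gamma_categories = 1,
                                   bootstrap_reps = 8, seed = 3),
    rates = rate_settings("K2P"), seed = 3)
  ev1 <- quiet(evaluate_study(fx$mini8, st))
  ev2 <- quiet(evaluate_study(fx$mini8, st))
  expect_identical(ev1$correlations, ev2$correlations)
  expect_identical(ev1$genes, ev2$genes)
  expect_identical(nrow(ev1$genes), 6L)
  expect_identical(sort(ev1$genes$rank), 1:6)
  expect_true(all(ev1$genes$rf %% 2 == 0))
  expect_true(all(ev1$genes$plrs >= 0))
  expect_identical(nrow(ev1$pairs), 3L)
  expect_true(all(ev1$pairs$ppp >= 0.5 & ev1$pairs$ppp <= 1, na.rm = TRUE))
  ## non-saturated fixture: DPI ranking should follow the generating
  ## mean-rate order (designs mini01..mini06 have increasing rates)
  expect_identical(ev1$ranking$gene_id, sprintf("mini%02d", 6:1))
})

test_that("identical genes tie stably and their pair drops from EPP", {
  fx <- make_fixtures(seed = 5)
  g <- fx$mini8$genes[1:2]
  g[[2]]$gene_id <- "mini00"  # same alignment under a different id
  g[[2]]$alignment <- g[[1]]$alignment
  study <- structure(list(chronogram = fx$mini8$chronogram, genes = g,
                          manifest = fx$mini8$manifest[1:2, ]),
                     class = "pi_study")
  st <- evaluation_settings(
    support = "ml_bp",
    inference = inference_settings("K2P", n_gamma_categories = 1,
                                   bootstrap_reps = 5, seed = 1),
    rates = rate_settings("K2P"), seed = 1)
  ev <- quiet(evaluate_study(study, st))
  ## equal DPI: tie broken by ascending gene id
  expect_identical(ev$ranking$gene_id, c("mini00", "mini01"))
  expect_equal(ev$ranking$dpi[1], ev$ranking$dpi[2], tolerance = 1e-12)
  ## the only pair is all-tied on supports, so EPP is undefined
  expect_true(is.na(ev$pairs$epp[1]))
})
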