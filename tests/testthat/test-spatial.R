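test_that("aggregation index hits its anchors and its exact permutation p", {
  # two adjacent clone pairs far apart: every nearest neighbour shares
  # its label -> Ac = 1
  d <- tibble::tibble(x = c(0, 0.1, 10, 10.1), y = 0,
                      lab = c("a", "a", "b", "b"))
  r <- aggregation_index(d, "lab", n_perm = 200, seed = 1)
  expect_equal(r$ac, 1)

  # exact p by enumerating all 4! label permutations: P_nn per labelling
  perms <- rbind(
    c(1,2,3,4), c(1,2,4,3), c(1,3,2,4), c(1,3,4,2), c(1,4,2,3), c(1,4,3,2),
    c(2,1,3,4), c(2,1,4,3), c(2,3,1,4), c(2,3,4,1), c(2,4,1,3), c(2,4,3,1),
    c(3,1,2,4), c(3,1,4,2), c(3,2,1,4), c(3,2,4,1), c(3,4,1,2), c(3,4,2,1),
    c(4,1,2,3), c(4,1,3,2), c(4,2,1,3), c(4,2,3,1), c(4,3,1,2), c(4,3,2,1))
  labs <- c("a", "a", "b", "b")
  nn <- c(2, 1, 4, 3)  # nearest neighbours by construction
  ac_exact <- apply(perms, 1, function(p) {
    l <- labs[p]
    p_nn <- mean(l[nn] == l)
    p_all <- 1 / 3  # 2 same-label pairs of 6
    (p_nn - p_all) / (1 - p_all)
  })
  exact_p <- mean(ac_exact >= 1)  # 8 of 24 labelings keep the pairs together
  big <- aggregation_index(d, "lab", n_perm = 5000, seed = 2)
  expect_lt(abs(big$p_value - exact_p), 3 * sqrt(exact_p * (1 - exact_p) / 5000) + 1e-3)

  # permuted labels centre the index near 0 under the null
  withr::with_seed(8, {
    d2 <- tibble::tibble(x = runif(40, 0, 50), y = runif(40, 0, 50),
                         lab = sample(c("a", "b"), 40, replace = TRUE))
  })
  r2 <- aggregation_index(d2, "lab", n_perm = 500, seed = 3)
  expect_lt(abs(mean(r2$null)), 0.05)

  # invariance to rotation/translation and label renaming
  th <- 0.7
  d3 <- d2
  d3$x <- cos(th) * d2$x - sin(th) * d2$y + 100
  d3$y <- sin(th) * d2$x + cos(th) * d2$y - 40
  d3$lab <- chartr("ab", "xy", d2$lab)
  r3 <- aggregation_index(d3, "lab", n_perm = 500, seed = 3)
  expect_equal(r3$ac, r2$ac, tolerance = 1e-9)
  expect_equal(r3$p_value, r2$p_value)

  expect_error(aggregation_index(tibble::tibble(x = 1:3, y = 1, lab = "a"), "lab"),
               "identical")
})

test_that("clonal subrange equals the brute-force pair maximum", {
  expect_equal(clonal_subrange(1, 1), 0)
  expect_equal(clonal_subrange(c(0, 3, 0), c(0, 0, 4)), 5)
  withr::with_seed(17, {
    for (k in 1:5) {
      n <- sample(3:12, 1)
      x <- runif(n, 0, 100); y <- runif(n, 0, 100)
      bf <- max(outer(seq_len(n), seq_len(n), function(i, j)
        sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)))
      expect_equal(clonal_subrange(x, y), bf)
    }
  })
})

test_that("Mantel r is exact on identical matrices and p matches full enumeration", {
  m <- as.matrix(dist(cbind(c(0, 1, 4, 9), c(0, 2, 1, 5))))
  r <- mantel_ibd(m, m, n_perm = 99, seed = 1)
  expect_equal(r$r, 1)

  g1 <- matrix(c(0, 1, 2, 3, 1, 0, 1, 2, 2, 1, 0, 1, 3, 2, 1, 0), 4)
  g2 <- as.matrix(dist(c(0, 2, 3, 7)))
  lt <- lower.tri(g1)
  r_obs <- cor(g1[lt], g2[lt])
  perms <- rbind(
    c(1,2,3,4), c(1,2,4,3), c(1,3,2,4), c(1,3,4,2), c(1,4,2,3), c(1,4,3,2),
    c(2,1,3,4), c(2,1,4,3), c(2,3,1,4), c(2,3,4,1), c(2,4,1,3), c(2,4,3,1),
    c(3,1,2,4), c(3,1,4,2), c(3,2,1,4), c(3,2,4,1), c(3,4,1,2), c(3,4,2,1),
    c(4,1,2,3), c(4,1,3,2), c(4,2,1,3), c(4,2,3,1), c(4,3,1,2), c(4,3,2,1))
  null_r <- apply(perms, 1, function(p) cor(g1[p, p][lt], g2[lt]))
  exact_p <- mean(null_r >= r_obs)
  mc <- mantel_ibd(g1, g2, n_perm = 4000, seed = 9)
  expect_equal(mc$r, r_obs)
  expect_lt(abs(mc$p_value - exact_p),
            3 * sqrt(exact_p * (1 - exact_p) / 4000) + 1e-3)

  # agreement with an independent implementation on a larger instance
  withr::with_seed(23, {
    xy <- cbind(runif(15), runif(15))
    gg <- as.matrix(dist(xy))
    gd <- as.matrix(dist(xy + matrix(rnorm(30, 0, 0.2), 15)))
  })
  ours <- mantel_ibd(gd, gg, n_perm = 999, seed = 4)
  veg <- vegan::mantel(gd, gg, permutations = 999)
  expect_equal(ours$r, unname(veg$statistic), tolerance = 1e-10)
})

test_that("Loiselle kinship matches its 1-locus closed form and centres near 0", {
  # one locus, two alleles, frequencies from the sample itself
  al <- matrix(c(1L, 1L, 1L, 2L, 2L), ncol = 1)
  gt <- toy_genotypes(al)
  n <- 5; p <- 3 / 5
  Fm <- loiselle_kinship(gt)
  # closed form: x centred indicators over both allele columns
  num_same_1 <- (1 - p)^2 + (0 - (1 - p)) * (0 - (1 - p))  # allele1 + allele2 cols
  denom <- p * (1 - p) + (1 - p) * p
  corr <- (p * (1 - p) + (1 - p) * p) / (n - 1) / denom
  f_same1 <- ((1 - p)^2 + (1 - p)^2) / denom + corr
  expect_equal(Fm[1, 2], f_same1)
  # sharing no alleles: negative
  expect_lt(Fm[1, 4], 0)
  # centring: all-pairs mean is ~0 up to the small-sample term
  off <- Fm[lower.tri(Fm)]
  expect_lt(abs(mean(off)), 0.15)

  withr::with_seed(12, {
    big <- toy_genotypes(matrix(sample(1:4, 50 * 5, replace = TRUE), 50, 5))
  })
  Fb <- loiselle_kinship(big)
  expect_equal(Fb, t(Fb))
  expect_lt(abs(mean(Fb[lower.tri(Fb)])), 0.02)
})

test_that("spatial autocorrelation detects simulated IBD and is null on random data", {
  # spatially random genotypes: class means ~ 0, Sp ~ 0
  withr::with_seed(5, {
    rnd <- toy_genotypes(matrix(sample(1:4, 60 * 6, replace = TRUE), 60, 6),
                         x = runif(60, 0, 200), y = runif(60, 0, 200))
  })
  r0 <- spatial_autocorrelation(rnd, n_classes = 6, min_dist = 20,
                                n_perm = 200, seed = 2)
  expect_lt(max(abs(r0$by_class$mean_fij)), 0.1)
  expect_lt(abs(r0$Sp), 0.05)

  # simulated local mating: positive kinship nearby, negative slope, Sp > 0
  sim <- simulate_multigenet_site(multigenet_config(seed = 19,
                                                    dispersal_scale = 5))
  a <- assign_mlgs(sim$gleba)
  sg <- p_sex_significance(a, n_sim = 200, seed = 2)
  cc <- clone_correct(a, sg)
  r1 <- spatial_autocorrelation(cc, n_classes = 8, min_dist = 5,
                                n_perm = 300, seed = 2)
  expect_gt(r1$F1, 0)
  expect_lt(r1$b, 0)
  expect_gt(r1$Sp, 0)

  # restricting the regression to short range on steep local structure
  # raises Sp relative to the full range
  r5 <- spatial_autocorrelation(cc, n_classes = 8, min_dist = 5,
                                n_perm = 50, seed = 2,
                                max_regression_dist = 5)
  expect_gt(r5$Sp, r1$Sp)
})

test_that("Sp is positive under local mating across replicate simulations", {
  hits <- vapply(1:20, function(k) {
    sim <- simulate_multigenet_site(multigenet_config(
      seed = 100 + k, dispersal_scale = 5, n_genets = 30,
      fruitbodies_per_year = c(30L, 30L)))
    a <- assign_mlgs(sim$gleba)
    cc <- clone_correct(a, p_sex_significance(a, n_sim = 100, seed = 1))
    r <- spatial_autocorrelation(cc, n_classes = 6, min_dist = 5,
                                 n_perm = 20, seed = 1)
    r$Sp > 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
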