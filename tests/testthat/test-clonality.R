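test_that("MLG assignment matches brute-force pairwise grouping", {
  # handcrafted: rows 1 and 3 identical -> 4 MLGs among 5 samples
  al <- matrix(c(1, 2, 1, 3, 1,
                 5, 5, 5, 5, 6,
                 9, 9, 9, 8, 9), 5, 3)
  gt <- toy_genotypes(al)
  a <- assign_mlgs(gt)
  expect_equal(dplyr::n_distinct(a$mlg_id), 4)
  expect_equal(a$mlg_id[1], a$mlg_id[3])

  # equal SSR profile, opposite mating type -> distinct MLGs
  gt2 <- toy_genotypes(matrix(c(1L, 1L), 2, 1), mat = c("MAT1-1", "MAT1-2"))
  expect_equal(dplyr::n_distinct(assign_mlgs(gt2)$mlg_id), 2)

  # all identical -> one MLG holding every ramet
  gt3 <- toy_genotypes(matrix(1L, 7, 2))
  a3 <- assign_mlgs(gt3)
  expect_equal(unique(a3$mlg_id), "MLG001")

  # property: random genotype tables up to 200 samples agree with the
  # O(N^2) brute force
  withr::with_seed(99, {
    for (rep in 1:5) {
      n <- sample(20:200, 1)
      al <- matrix(sample(1:3, n * 4, replace = TRUE), n, 4)
      gt <- toy_genotypes(al, mat = sample(mat_idiomorphs(), n, replace = TRUE))
      a <- assign_mlgs(gt)
      bf <- brute_force_mlgs(gt, ssr_loci(gt))
      expect_equal(as.integer(factor(a$mlg_id, levels = unique(a$mlg_id))), bf)
    }
  })
})

test_that("allele frequencies sum to one and respond to clone correction", {
  gt <- toy_genotypes(matrix(c(1L, 1L, 2L, 2L), 4, 1))
  f <- allele_frequencies(gt, clone_corrected = FALSE)
  expect_equal(f$freq, c(0.5, 0.5))

  mono <- toy_genotypes(matrix(1L, 3, 1))
  expect_equal(allele_frequencies(mono, clone_corrected = FALSE)$freq, 1)

  # 200-ramet dominant clone: raw vs clone-corrected by hand count
  al <- matrix(c(rep(1L, 200), 2L, 3L), ncol = 1)
  gt <- toy_genotypes(al)
  raw <- allele_frequencies(gt, clone_corrected = FALSE)
  cc <- allele_frequencies(gt, clone_corrected = TRUE)
  expect_equal(raw$freq[raw$allele == 1], 200 / 202)
  expect_equal(cc$freq[cc$allele == 1], 1 / 3)
  expect_equal(sum(cc$freq), 1)
})

test_that("p_gen is the product of allele frequencies", {
  f <- tibble::tibble(locus = c("L1", "L1", "L2", "L2", "L3"),
                      allele = c(1L, 2L, 1L, 2L, 1L),
                      count = 1, freq = c(0.3, 0.7, 0.2, 0.8, 1), n = 10)
  expect_equal(p_gen(c(L1 = 1, L2 = 1, L3 = 1), f), 0.06)
  half <- tibble::tibble(locus = rep(c("A", "B", "C"), each = 2),
                         allele = rep(1:2, 3), count = 1, freq = 0.5, n = 4)
  expect_equal(p_gen(c(A = 1, B = 2, C = 1), half), 0.125)
  mono <- tibble::tibble(locus = c("A", "B"), allele = 1L, count = 4,
                         freq = 1, n = 4)
  expect_equal(p_gen(c(A = 1, B = 1), mono), 1)
})

test_that("P_sex equals the exact binomial tail and is monotone", {
  expect_equal(p_sex(0.01, 2, 10), exact_binom_tail(2, 10, 0.01))
  expect_equal(p_sex(0.3, 4, 12), exact_binom_tail(4, 12, 0.3))
  expect_equal(p_sex(1, 5, 10), 1)
  expect_warning(p1 <- p_sex(0.2, 1, 10), "singleton")
  expect_equal(p1, 1)

  # non-increasing in n_copies, non-decreasing in p_gen
  for (pg in c(0.01, 0.1, 0.5)) {
    vals <- p_sex(pg, 2:10, 10)
    expect_true(all(diff(vals) <= 1e-12))
  }
  for (n in c(2, 5, 9)) {
    vals <- p_sex(seq(0.05, 0.95, by = 0.05), n, 10)
    expect_true(all(diff(vals) >= -1e-12))
  }
  # Parks-Werth variant: exact form on the reduced sample
  expect_equal(p_sex(0.1, 3, 8, method = "parks_werth"),
               exact_binom_tail(2, 7, 0.1))
})

test_that("Monte-Carlo P_sex significance separates true clones from chance repeats", {
  # dominant 200-ramet clone under low diversity -> significant
  withr::with_seed(21, {
    al <- cbind(c(rep(1L, 200), sample(1:4, 10, replace = TRUE)),
                c(rep(2L, 200), sample(1:4, 10, replace = TRUE)),
                c(rep(1L, 200), sample(1:4, 10, replace = TRUE)))
  })
  gt <- toy_genotypes(al)
  a <- assign_mlgs(gt)
  sg <- p_sex_significance(a, n_sim = 300, seed = 5)
  dom_row <- sg[sg$n_ramets == max(sg$n_ramets), ]
  expect_true(dom_row$significant)

  # a duplicated pair of the most common profile in a 1-locus 2-allele
  # system repeats by chance all the time -> non-significant
  gt2 <- toy_genotypes(matrix(c(1L, 1L, 1L, 1L, 2L, 2L, 1L, 2L), ncol = 1))
  a2 <- assign_mlgs(gt2)
  sg2 <- p_sex_significance(a2, n_sim = 500, seed = 5)
  common <- sg2[which.max(sg2$n_ramets), ]
  expect_false(common$significant)

  # determinism under a fixed seed
  sg2b <- p_sex_significance(a2, n_sim = 500, seed = 5)
  expect_identical(sg2$significant, sg2b$significant)
  expect_identical(sg2$p_sex, sg2b$p_sex)
})

test_that("clone correction collapses significant clones to centroids and keeps the rest", {
  al <- matrix(c(1L, 1L, 2L, 3L, 3L, 3L, 4L), ncol = 1)
  gt <- toy_genotypes(al, x = c(0, 2, 5, 1, 1, 1, 9), y = c(0, 0, 5, 1, 1, 1, 9))
  a <- assign_mlgs(gt)
  sig <- tibble::tibble(
    mlg_id = unique(a$mlg_id),
    significant = c(TRUE, NA, FALSE, NA))  # MLG of 1s significant, of 3s not
  cc <- clone_correct(a, sig)
  # significant pair (0,0)+(2,0) -> one representative at (1,0)
  rep1 <- cc[cc$mlg_id == a$mlg_id[1], ]
  expect_equal(nrow(rep1), 1)
  expect_equal(c(rep1$x, rep1$y), c(1, 0))
  # non-significant triplet retained ramet by ramet
  expect_equal(sum(cc$mlg_id == a$mlg_id[4]), 3)
  # singletons untouched; dataset of singletons -> identity
  singles <- toy_genotypes(matrix(1:5, ncol = 1))
  asing <- assign_mlgs(singles)
  ssig <- p_sex_significance(asing, n_sim = 50, seed = 1)
  expect_equal(nrow(clone_correct(asing, ssig)), 5)
})

test_that("richness, Simpson diversity and evenness match closed forms and brute force", {
  expect_equal(round(genotypic_richness(66, 34), 3), 0.508)
  expect_equal(genotypic_richness(20, 20), 1)
  expect_equal(genotypic_richness(10, 1), 0)

  expect_equal(simpson_diversity(c(5)), 0)
  expect_equal(simpson_diversity(rep(1, 6)), 1)
  expect_equal(simpson_diversity(c(3, 1)), 0.5)

  expect_equal(simpson_evenness(c(2, 2, 2)), 1)
  expect_equal(simpson_evenness(c(4, 4, 4, 4)), 1)
  expect_equal(simpson_evenness(rev(c(7, 1))), simpson_evenness(c(7, 1)))

  # brute force over every composition for N <= 8: the index lives in
  # [0, 1], the skewed composition attains the minimum, the even one the
  # maximum
  for (N in 4:8) {
    for (G in 2:(N - 1)) {
      vals <- vapply(compositions(N, G), simpson_evenness, numeric(1))
      expect_true(all(vals >= -1e-12 & vals <= 1 + 1e-12))
      skew <- simpson_evenness(c(rep(1, G - 1), N - G + 1))
      expect_equal(min(vals), skew)
    }
  }
})

test_that("unbiased gene diversity matches the n/(n-1) closed form", {
  gt <- toy_genotypes(cbind(c(1L, 1L, 2L, 2L), c(3L, 3L, 3L, 3L)))
  u <- unbiased_gene_diversity(allele_frequencies(gt, clone_corrected = FALSE))
  expect_equal(u$uHe[u$locus == "L1"], (4 / 3) * 0.5)  # two alleles at 0.5, n=4
  expect_equal(u$uHe[u$locus == "L2"], 0)              # monomorphic
  expect_equal(glance(u)$mean_uHe, mean(u$uHe))
})

test_that("diversity summary reproduces the dominant-clone site pattern", {
  sim <- simulate_fairy_ring(ring_sim_config(
    seed = 2, fruitbodies_per_year = c(52L, 51L, 51L, 51L)))  # 205 gleba
  a <- assign_mlgs(sim$gleba)
  sg <- p_sex_significance(a, n_sim = 200, seed = 3)
  ds <- diversity_summary(a, sg)
  expect_equal(ds$N, 205)
  expect_equal(ds$G, 2)
  expect_equal(round(ds$R, 3), 0.005)
  expect_lt(ds$D_star, 0.1)

  # paternal side: many singleton fathers -> high richness
  pat <- infer_paternal(sim$gleba, sim$spores)
  tl <- sim$truth$loci
  patrec <- pat[, c("fruitbody_id", tl, "mat")]
  names(patrec)[1] <- "sample_id"
  patrec$sample_id <- paste0(patrec$sample_id, "_p")
  patrec$site <- "RING"; patrec$year <- 2016L; patrec$role <- "ascospore"
  patrec$x <- NA_real_; patrec$y <- NA_real_; patrec$resolved <- TRUE
  ap <- assign_mlgs(patrec)
  dp <- diversity_summary(ap, p_sex_significance(ap, n_sim = 200, seed = 3))
  expect_gt(dp$R, 0.5)
  expect_gt(dp$R, 50 * ds$R)
})
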