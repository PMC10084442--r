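#' Configuration for a fairy-ring population simulation
#'
#' Defaults emulate a single-genet fairy-ring site: four annual fruitbody
#' cohorts (harvest sizes 109, 78, 28, 76), an annulus expanding 0.30 m
#' per year from an initial radius of 3.7 m with radial noise of 0.15 m,
#' a 14-locus SSR panel with 5 monomorphic loci and 1-8 alleles per
#' locus under a strongly skewed (low-diversity) frequency profile, one
#' dominant maternal genet carrying a fraction 0.976 of the gleba samples
#' (the remainder belongs to a second, minor maternal genet of opposite
#' mating type), and ephemeral paternal partners: each fruitbody's father
#' is a fresh recombinant spore offspring of the maternal genotype and
#' the site allele pool, unless it reuses a persistent father
#' (probability `paternal_persistence_prob`).
#'
#' @param seed Integer seed; every draw is deterministic under it.
#' @param years Calendar years of the harvests.
#' @param center Ring centre `c(x, y)` in metres.
#' @param initial_radius Ring radius in the first year (m).
#' @param growth_rate Radial outgrowth (m/yr, default 0.30).
#' @param annulus_sd Radial noise around the annulus (m, default 0.15).
#' @param fruitbodies_per_year Integer harvest sizes, one per year.
#' @param n_loci Number of SSR loci (default 14).
#' @param n_monomorphic Loci fixed for a single allele (default 5).
#' @param max_alleles Maximum alleles per polymorphic locus (default 8).
#' @param dominant_maternal_fraction Fraction of gleba samples formed by
#'   the dominant genet (default 0.976).
#' @param paternal_persistence_prob Probability a fruitbody reuses an
#'   existing father genotype (default 0.15).
#' @param hermaphrodite_rate Probability that a fruitbody of the dominant
#'   genet is fathered by the minor maternal genet, making it a
#'   hermaphrodite (default 0; single-genet rings rarely show them).
#' @param maternal_mat Idiomorph of the dominant maternal genet.
#' @param site Site label.
#' @return A list of class `ring_sim_config`.
#' @export
ring_sim_config <- function(seed = 1962, years = 2016:2019,
                            center = c(0, 0), initial_radius = 3.7,
                            growth_rate = 0.30, annulus_sd = 0.15,
                            fruitbodies_per_year = c(109L, 78L, 28L, 76L),
                            n_loci = 14, n_monomorphic = 5, max_alleles = 8,
                            dominant_maternal_fraction = 0.976,
                            paternal_persistence_prob = 0.15,
                            hermaphrodite_rate = 0,
                            maternal_mat = "MAT1-1", site = "RING") {
  stopifnot(growth_rate > 0, annulus_sd >= 0,
            length(fruitbodies_per_year) == length(years),
            all(fruitbodies_per_year >= 1),
            dominant_maternal_fraction >= 0, dominant_maternal_fraction <= 1,
            paternal_persistence_prob >= 0, paternal_persistence_prob <= 1,
            hermaphrodite_rate >= 0, hermaphrodite_rate <= 1,
            n_monomorphic <= n_loci, maternal_mat %in% mat_idiomorphs())
  structure(as.list(environment()), class = "ring_sim_config")
}

# Skewed low-diversity allele pool: one dominant allele per locus.
# Returns a list of frequency vectors named by 3-digit allele sizes.
sim_allele_pool <- function(n_loci, n_monomorphic, max_alleles) {
  lapply(seq_len(n_loci), function(l) {
    k <- if (l <= n_monomorphic) 1L else sample(2:max_alleles, 1)
    w <- exp(-1.4 * (seq_len(k) - 1))
    f <- w / sum(w)
    names(f) <- as.character(100 + l * 10 + seq_len(k) - 1)
    f
  })
}

draw_genotype <- function(pool) {
  vapply(pool, function(f) as.integer(sample(names(f), 1, prob = f)), integer(1))
}

opposite_mat <- function(mat) ifelse(mat == "MAT1-1", "MAT1-2", "MAT1-1")

# One meiotic recombinant of mother x allele pool: keeps the maternal
# allele with probability 1/2 per locus, otherwise draws from the pool.
recombinant_spore <- function(maternal, pool) {
  keep <- runif(length(pool)) < 0.5
  ifelse(keep, maternal, draw_genotype(pool))
}

#' Simulate a fairy-ring truffle population
#'
#' Generates georeferenced gleba genotypes and pooled ascospore-extract
#' profiles for a ring-forming single dominant genet (see
#' [ring_sim_config()]), together with a truth record holding every
#' parental assignment, so downstream inferences (MLG calling, paternal
#' inference, growth-rate estimation) can be scored exactly.
#'
#' @param cfg A [ring_sim_config()].
#' @return A list of class `clonering_sim`: `gleba` (genotype tibble),
#'   `spores` (spore-extract tibble), `truth` (list with `config`,
#'   `pool`, `maternal_genotypes`, `father` tibble of true paternal
#'   haplotypes and their genet ids per fruitbody).
#' @export
#' @examples
#' sim <- simulate_fairy_ring(ring_sim_config(seed = 42))
#' nrow(sim$gleba)
simulate_fairy_ring <- function(cfg) {
  stopifnot(inherits(cfg, "ring_sim_config"))
  with_seed(cfg$seed, {
    loci <- sprintf("ssr%02d", seq_len(cfg$n_loci))
    pool <- sim_allele_pool(cfg$n_loci, cfg$n_monomorphic, cfg$max_alleles)
    names(pool) <- loci

    # dominant genet carries the most common allele everywhere; the minor
    # maternal genet differs at every polymorphic locus and carries the
    # opposite idiomorph
    dom <- vapply(pool, function(f) as.integer(names(f)[which.max(f)]), integer(1))
    minor <- vapply(pool, function(f) {
      if (length(f) == 1) as.integer(names(f))
      else as.integer(sample(names(f)[-which.max(f)], 1))
    }, integer(1))
    mats <- c(cfg$maternal_mat, opposite_mat(cfg$maternal_mat))

    n_total <- sum(cfg$fruitbodies_per_year)
    year <- rep(cfg$years, cfg$fruitbodies_per_year)
    t_idx <- rep(seq_along(cfg$years) - 1, cfg$fruitbodies_per_year)
    theta <- runif(n_total, 0, 2 * pi)
    radius <- cfg$initial_radius + cfg$growth_rate * t_idx +
      rnorm(n_total, 0, cfg$annulus_sd)
    x <- cfg$center[1] + radius * cos(theta)
    y <- cfg$center[2] + radius * sin(theta)
    maternal_idx <- ifelse(runif(n_total) < cfg$dominant_maternal_fraction, 1L, 2L)

    fathers <- list()   # genotype cache per idiomorph, keyed by father id
    father_id <- character(n_total)
    father_geno <- matrix(NA_integer_, n_total, cfg$n_loci,
                          dimnames = list(NULL, loci))
    father_mat <- character(n_total)
    herm <- logical(n_total)
    for (i in seq_len(n_total)) {
      mom <- if (maternal_idx[i] == 1) dom else minor
      fmat <- opposite_mat(mats[maternal_idx[i]])
      if (maternal_idx[i] == 1 && runif(1) < cfg$hermaphrodite_rate) {
        father_id[i] <- "GENET2"
        father_geno[i, ] <- minor
        herm[i] <- TRUE
      } else {
        compatible <- names(fathers)[vapply(fathers, function(fd) fd$mat == fmat,
                                            logical(1))]
        if (length(compatible) && runif(1) < cfg$paternal_persistence_prob) {
          fid <- sample(compatible, 1)
          father_id[i] <- fid
          father_geno[i, ] <- fathers[[fid]]$geno
        } else {
          fid <- sprintf("FATHER%03d", length(fathers) + 1)
          g <- recombinant_spore(mom, pool)
          fathers[[fid]] <- list(geno = g, mat = fmat)
          father_id[i] <- fid
          father_geno[i, ] <- g
        }
      }
      father_mat[i] <- fmat
    }

    ids <- sprintf("%s_%d_%03d", cfg$site, year, stats::ave(seq_len(n_total),
                                                            year, FUN = seq_along))
    gleba <- tibble::tibble(
      sample_id = ids, site = cfg$site, year = as.integer(year),
      role = "gleba", x = x, y = y)
    for (j in seq_len(cfg$n_loci)) {
      gleba[[loci[j]]] <- ifelse(maternal_idx == 1L, dom[j], minor[j])
    }
    gleba$mat <- mats[maternal_idx]
    gleba$resolved <- TRUE

    spores <- tibble::tibble(fruitbody_id = ids)
    for (j in seq_len(cfg$n_loci)) {
      momal <- ifelse(maternal_idx == 1L, dom[j], minor[j])
      dadal <- father_geno[, j]
      spores[[loci[j]]] <- ifelse(momal == dadal, as.character(momal),
                                  paste(pmin(momal, dadal), pmax(momal, dadal),
                                        sep = "/"))
    }
    spores$mat11 <- TRUE   # pooled recombinant spores carry both idiomorphs
    spores$mat12 <- TRUE

    truth <- list(
      config = cfg, pool = pool, loci = loci,
      maternal_genotypes = rbind(GENET1 = dom, GENET2 = minor),
      maternal_mat = setNames(mats, c("GENET1", "GENET2")),
      maternal_id = paste0("GENET", maternal_idx),
      father = tibble::tibble(fruitbody_id = ids, father_id = father_id,
                              father_mat = father_mat,
                              hermaphrodite = herm) |>
        dplyr::bind_cols(tibble::as_tibble(father_geno)))
    structure(list(gleba = gleba, spores = spores, truth = truth),
              class = "clonering_sim")
  })
}

#' Configuration for a multi-genet site simulation
#'
#' Defaults emulate a natural multi-genet truffle ground: genets placed
#' by a clustered (Thomas) point process over the site extent, genotypes
#' propagated parent-to-offspring with kernel-scale dispersal so that
#' relatedness decays with distance (isolation by distance), mating
#' types assigned in spatial patches, and each fruitbody fathered either
#' by an ephemeral recombinant spore (annual turnover of males) or, with
#' probability `hermaphrodite_rate`, by a persistent genet of the
#' opposite mating type drawn under a distance-decaying mating kernel.
#'
#' @param seed Integer seed.
#' @param extent Side of the square site (m, default 100).
#' @param n_genets Number of persistent genets (default 40).
#' @param cluster_radius Thomas-process cluster radius (m, default 8).
#' @param dispersal_scale Parent-offspring genotype dispersal kernel
#'   scale (m, default 10): smaller values give stronger IBD.
#' @param mating_scale Distance-decay scale of the mating kernel (m,
#'   default 5); `Inf` gives panmixia.
#' @param patch_scale Spatial scale of mating-type patches (m, default
#'   25).
#' @param n_loci,n_monomorphic,max_alleles Panel profile as in
#'   [ring_sim_config()].
#' @param years Harvest years.
#' @param fruitbodies_per_year Harvest sizes.
#' @param hermaphrodite_rate Probability that a fruitbody's father is a
#'   persistent genet (default 0.1), the source of hermaphroditic MLGs.
#' @param resample_prob Per-locus probability that an offspring genet
#'   redraws its allele from the site pool instead of inheriting
#'   (default 0.25).
#' @param site Site label.
#' @return A list of class `multigenet_config`.
#' @export
multigenet_config <- function(seed = 1962, extent = 100, n_genets = 40,
                              cluster_radius = 8, dispersal_scale = 10,
                              mating_scale = 5, patch_scale = 25,
                              n_loci = 14, n_monomorphic = 1, max_alleles = 8,
                              years = c(2013L, 2019L),
                              fruitbodies_per_year = c(40L, 35L),
                              hermaphrodite_rate = 0.1,
                              resample_prob = 0.25, site = "SITE") {
  stopifnot(extent > 0, n_genets >= 4, cluster_radius > 0,
            dispersal_scale > 0, mating_scale > 0, patch_scale > 0,
            length(fruitbodies_per_year) == length(years),
            hermaphrodite_rate >= 0, hermaphrodite_rate <= 1)
  structure(as.list(environment()), class = "multigenet_config")
}

#' Simulate a multi-genet truffle site
#'
#' See [multigenet_config()] for the generative model. Emits gleba and
#' spore-extract tables in the same schema as [simulate_fairy_ring()]
#' and a truth record with genet positions, genotypes, mating types and
#' each fruitbody's true parents.
#'
#' @param cfg A [multigenet_config()].
#' @return A list of class `clonering_sim`: `gleba`, `spores`, `truth`.
#' @export
simulate_multigenet_site <- function(cfg) {
  stopifnot(inherits(cfg, "multigenet_config"))
  with_seed(cfg$seed, {
    loci <- sprintf("ssr%02d", seq_len(cfg$n_loci))
    pool <- sim_allele_pool(cfg$n_loci, cfg$n_monomorphic, cfg$max_alleles)
    names(pool) <- loci

    # Thomas process: cluster parents, genets scattered around them
    n_par <- max(2, round(cfg$n_genets / 5))
    px <- runif(n_par, 0, cfg$extent); py <- runif(n_par, 0, cfg$extent)
    parent <- sample.int(n_par, cfg$n_genets, replace = TRUE)
    gx <- pmin(pmax(px[parent] + rnorm(cfg$n_genets, 0, cfg$cluster_radius), 0),
               cfg$extent)
    gy <- pmin(pmax(py[parent] + rnorm(cfg$n_genets, 0, cfg$cluster_radius), 0),
               cfg$extent)

    # genotype propagation: each genet (after the founders) inherits from
    # a distance-weighted existing genet with per-locus resampling
    geno <- matrix(NA_integer_, cfg$n_genets, cfg$n_loci,
                   dimnames = list(NULL, loci))
    n_founders <- max(2, round(cfg$n_genets * 0.25))
    for (i in seq_len(cfg$n_genets)) {
      if (i <= n_founders) {
        geno[i, ] <- draw_genotype(pool)
      } else {
        d <- sqrt((gx[seq_len(i - 1)] - gx[i])^2 + (gy[seq_len(i - 1)] - gy[i])^2)
        par_i <- sample.int(i - 1, 1, prob = exp(-d / cfg$dispersal_scale))
        redraw <- runif(cfg$n_loci) < cfg$resample_prob
        geno[i, ] <- ifelse(redraw, draw_genotype(pool), geno[par_i, ])
      }
    }

    # mating types in patches: nearest of alternating-type patch seeds
    n_seeds <- max(2, round(cfg$extent / cfg$patch_scale))
    sx <- runif(n_seeds, 0, cfg$extent); sy <- runif(n_seeds, 0, cfg$extent)
    stype <- mat_idiomorphs()[rep_len(1:2, n_seeds)]
    nearest_seed <- vapply(seq_len(cfg$n_genets), function(i) {
      which.min((sx - gx[i])^2 + (sy - gy[i])^2)
    }, integer(1))
    gmat <- stype[nearest_seed]
    if (length(unique(gmat)) == 1) gmat[sample.int(cfg$n_genets, 1)] <- opposite_mat(gmat[1])

    n_total <- sum(cfg$fruitbodies_per_year)
    year <- rep(cfg$years, cfg$fruitbodies_per_year)
    mother <- sample.int(cfg$n_genets, n_total, replace = TRUE)
    fx <- gx[mother] + rnorm(n_total, 0, 1.5)
    fy <- gy[mother] + rnorm(n_total, 0, 1.5)

    father_geno <- matrix(NA_integer_, n_total, cfg$n_loci,
                          dimnames = list(NULL, loci))
    father_id <- character(n_total)
    for (i in seq_len(n_total)) {
      fmat <- opposite_mat(gmat[mother[i]])
      cand <- which(gmat == fmat)
      if (length(cand) && runif(1) < cfg$hermaphrodite_rate) {
        d <- sqrt((gx[cand] - fx[i])^2 + (gy[cand] - fy[i])^2)
        w <- if (is.finite(cfg$mating_scale)) exp(-d / cfg$mating_scale)
             else rep(1, length(cand))
        fid <- if (length(cand) == 1) cand else
          cand[sample.int(length(cand), 1, prob = w)]
        father_id[i] <- sprintf("GENET%03d", fid)
        father_geno[i, ] <- geno[fid, ]
      } else {
        father_id[i] <- sprintf("SPORE%03d", i)
        father_geno[i, ] <- recombinant_spore(geno[mother[i], ], pool)
      }
    }

    ids <- sprintf("%s_%d_%03d", cfg$site, year,
                   stats::ave(seq_len(n_total), year, FUN = seq_along))
    gleba <- tibble::tibble(sample_id = ids, site = cfg$site,
                            year = as.integer(year), role = "gleba",
                            x = fx, y = fy)
    for (j in seq_len(cfg$n_loci)) gleba[[loci[j]]] <- geno[mother, j]
    gleba$mat <- gmat[mother]
    gleba$resolved <- TRUE

    spores <- tibble::tibble(fruitbody_id = ids)
    for (j in seq_len(cfg$n_loci)) {
      momal <- geno[mother, j]
      dadal <- father_geno[, j]
      spores[[loci[j]]] <- ifelse(momal == dadal, as.character(momal),
                                  paste(pmin(momal, dadal), pmax(momal, dadal),
                                        sep = "/"))
    }
    spores$mat11 <- TRUE
    spores$mat12 <- TRUE

    truth <- list(
      config = cfg, pool = pool, loci = loci,
      genets = tibble::tibble(genet_id = sprintf("GENET%03d", seq_len(cfg$n_genets)),
                              x = gx, y = gy, mat = gmat) |>
        dplyr::bind_cols(tibble::as_tibble(geno)),
      mother_id = sprintf("GENET%03d", mother),
      father = tibble::tibble(fruitbody_id = ids, father_id = father_id) |>
        dplyr::bind_cols(tibble::as_tibble(father_geno)))
    structure(list(gleba = gleba, spores = spores, truth = truth),
              class = "clonering_sim")
  })
}

#' Simulate ECM root-tip records, soil samples and a qPCR plate
#'
#' Overlays a transect soil survey on a simulated fairy ring: soil cores
#' every `step` metres along radial transects. The true ITS copy field is
#' a Gaussian ridge on the current ring radius with decayed values inside
#' the ring (the mycelium dies back behind the front), optionally with an
#' interior patch of the opposite mating type. ECM root tips occur where
#' the field is high and always carry the dominant maternal genotype
#' (root tips host only maternal/hermaphroditic genets). Cq triplicates
#' are generated from a configured standard curve with replicate noise.
#'
#' @param sim A [simulate_fairy_ring()] result.
#' @param n_transects Number of radial transects (default 4).
#' @param length_m Transect length from the centre (default 6.6).
#' @param step Core spacing (m, default 0.3).
#' @param peak_copies Peak ITS copies per g soil on the ring (default
#'   5e7).
#' @param ridge_sd Radial width of the ridge (m, default 0.4).
#' @param interior_frac Interior plateau as a fraction of the peak
#'   (default 0.02).
#' @param mat2_patch Add an interior opposite-MAT patch of 5 positions on
#'   transect 3 (default `TRUE`).
#' @param curve_slope,curve_intercept True standard-curve parameters
#'   (defaults -3.3219 and 38, a 100%-efficiency assay).
#' @param cq_sd Replicate Cq noise (default 0.05 cycles).
#' @param ecm_threshold Field fraction of peak above which an ECM root
#'   tip is recovered (default 0.2).
#' @param seed Integer seed (default: the ring config's seed + 1).
#' @return A list: `soil` (tibble with transect, position, x, y, true
#'   copies per g, mat flags), `ecm` (genotype tibble), `plate` (long
#'   tibble of standards and unknown triplicate Cq), `truth` (curve
#'   parameters and scaling constants).
#' @export
simulate_ecm_and_soil <- function(sim, n_transects = 4, length_m = 6.6,
                                  step = 0.3, peak_copies = 5e7,
                                  ridge_sd = 0.4, interior_frac = 0.02,
                                  mat2_patch = TRUE,
                                  curve_slope = -3.3219, curve_intercept = 38,
                                  cq_sd = 0.05, ecm_threshold = 0.2,
                                  seed = NULL) {
  stopifnot(inherits(sim, "clonering_sim"))
  cfg <- sim$truth$config
  if (!inherits(cfg, "ring_sim_config")) {
    abort("simulate_ecm_and_soil expects a fairy-ring simulation.")
  }
  seed <- seed %||% (cfg$seed + 1)
  with_seed(seed, {
    ring_r <- cfg$initial_radius +
      cfg$growth_rate * (length(cfg$years) - 1)
    angles <- seq(0, 2 * pi, length.out = n_transects + 1)[seq_len(n_transects)]
    pos <- seq(step, length_m, by = step)
    grid <- tidyr::expand_grid(transect = seq_len(n_transects), position = pos)
    grid$x <- cfg$center[1] + grid$position * cos(angles[grid$transect])
    grid$y <- cfg$center[2] + grid$position * sin(angles[grid$transect])

    r <- grid$position
    field <- peak_copies * exp(-(r - ring_r)^2 / (2 * ridge_sd^2))
    inside <- r < ring_r - 2 * ridge_sd
    field[inside] <- pmax(field[inside], interior_frac * peak_copies *
                            exp(-(ring_r - r[inside]) / ring_r))
    grid$true_copies_per_g <- field
    grid$mat11 <- field > 1e-4 * peak_copies
    grid$mat12 <- FALSE
    if (mat2_patch && n_transects >= 3) {
      patch_idx <- which(grid$transect == 3 & inside)[seq_len(5)]
      patch_idx <- patch_idx[!is.na(patch_idx)]
      grid$true_copies_per_g[patch_idx] <- 0.1 * peak_copies
      grid$mat12[patch_idx] <- TRUE
      grid$mat11[patch_idx] <- FALSE
    }

    # ECM root tips where the maternal mycelium is abundant
    ecm_idx <- which(grid$true_copies_per_g > ecm_threshold * peak_copies &
                       !grid$mat12)
    dom <- sim$truth$maternal_genotypes["GENET1", ]
    ecm <- tibble::tibble(
      sample_id = sprintf("ECM_%03d", seq_along(ecm_idx)),
      site = cfg$site, year = max(cfg$years), role = "ecm",
      x = grid$x[ecm_idx], y = grid$y[ecm_idx])
    for (j in seq_along(sim$truth$loci)) ecm[[sim$truth$loci[j]]] <- dom[j]
    ecm$mat <- unname(sim$truth$maternal_mat["GENET1"])
    ecm$resolved <- TRUE

    # qPCR plate: plasmid standards + unknown triplicates
    # copies per reaction from the soil scaling constants (0.25 g soil,
    # 100 ul eluate, 5 ul template at 1:10)
    scale_per_g <- 10 * (100 / 5) / 0.25
    std <- tidyr::expand_grid(copies = 10^(2:7), rep = 1:3)
    std_cq <- curve_intercept + curve_slope * log10(std$copies) +
      rnorm(nrow(std), 0, cq_sd)
    unk <- tidyr::expand_grid(well = seq_len(nrow(grid)), rep = 1:3)
    unk_copies_rxn <- grid$true_copies_per_g[unk$well] / scale_per_g
    unk_cq <- ifelse(unk_copies_rxn > 1,
                     curve_intercept + curve_slope * log10(unk_copies_rxn) +
                       rnorm(nrow(unk), 0, cq_sd),
                     NA_real_)
    plate <- dplyr::bind_rows(
      tibble::tibble(sample = sprintf("STD_%d", log10(std$copies)),
                     role = "standard", copies = std$copies,
                     rep = std$rep, cq = std_cq),
      tibble::tibble(sample = sprintf("SOIL_%03d", unk$well),
                     role = "unknown", copies = NA_real_,
                     rep = unk$rep, cq = unk_cq))

    list(soil = grid, ecm = ecm, plate = plate,
         truth = list(curve_slope = curve_slope,
                      curve_intercept = curve_intercept,
                      scale_per_g = scale_per_g, ring_radius = ring_r))
  })
}
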