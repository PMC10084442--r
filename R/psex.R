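#' Per-locus allele frequencies
#'
#' Frequencies are computed over resolved records, by default after clone
#' correction in the cheap sense of one representative record per MLG
#' (repeated multilocus genotypes otherwise inflate the frequency of the
#' clone's alleles). A round-robin (leave-one-MLG-out) estimate is also
#' available for probability-of-identity calculations.
#'
#' @param data A genotype tibble; `mlg_id` is computed via [assign_mlgs()]
#'   if absent.
#' @param loci Optional SSR locus subset.
#' @param clone_corrected Use one representative per MLG (default `TRUE`).
#' @return A tibble with columns `locus`, `allele`, `count`, `freq`, `n`
#'   (genotypes contributing at that locus). Frequencies sum to 1 per
#'   locus.
#' @export
allele_frequencies <- function(data, loci = NULL, clone_corrected = TRUE) {
  loci <- ssr_loci(data, loci)
  if ("resolved" %in% names(data)) data <- data[data$resolved, , drop = FALSE]
  if (!nrow(data)) abort("No resolved records.")
  if (clone_corrected) {
    if (!"mlg_id" %in% names(data)) data <- assign_mlgs(data, loci)
    data <- data[!duplicated(data$mlg_id), , drop = FALSE]
  }
  data |>
    tidyr::pivot_longer(dplyr::all_of(loci), names_to = "locus", values_to = "allele") |>
    dplyr::filter(!is.na(.data$allele)) |>
    dplyr::count(.data$locus, .data$allele, name = "count") |>
    dplyr::group_by(.data$locus) |>
    dplyr::mutate(n = sum(.data$count), freq = .data$count / .data$n) |>
    dplyr::ungroup() |>
    dplyr::mutate(locus = factor(.data$locus, levels = loci)) |>
    dplyr::arrange(.data$locus, .data$allele) |>
    dplyr::mutate(locus = as.character(.data$locus))
}

#' Probability of a haploid multilocus genotype under random assortment
#'
#' `p_gen` is the product over loci of the population frequency of the
#' genotype's allele, i.e. the probability that one independent sexual
#' event produces exactly this multilocus genotype under linkage
#' equilibrium. An allele absent from the frequency table (possible under
#' round-robin estimation) is substituted by the smallest observed
#' frequency at any locus, with a warning.
#'
#' @param genotype Named list/one-row data frame of alleles, or a named
#'   vector; names are locus names.
#' @param freqs Frequency table from [allele_frequencies()].
#' @param loci Loci to include (default: all loci in `freqs`).
#' @return A single probability in (0, 1].
#' @export
#' @examples
#' f <- tibble::tibble(locus = c("L1", "L1", "L2"), allele = c(1L, 2L, 5L),
#'                     count = c(2, 2, 4), freq = c(0.5, 0.5, 1), n = 4)
#' p_gen(c(L1 = 1, L2 = 5), f)  # 0.5
p_gen <- function(genotype, freqs, loci = NULL) {
  if (is.data.frame(genotype)) genotype <- unlist(genotype[1, , drop = FALSE])
  loci <- loci %||% unique(freqs$locus)
  fmin <- min(freqs$freq)
  p <- 1
  for (l in loci) {
    fl <- freqs[freqs$locus == l, , drop = FALSE]
    hit <- fl$freq[match(as.integer(genotype[[l]]), fl$allele)]
    if (is.na(hit)) {
      warn(paste0("Allele at ", l, " has zero estimated frequency; ",
                  "substituting smallest observed frequency."))
      hit <- fmin
    }
    p <- p * hit
  }
  p
}

#' Probability that copies of an MLG arose from independent sexual events
#'
#' The tail probability of observing at least `n_copies` independent
#' occurrences of a genotype of probability `p_gen` among `N` sampled
#' genotypes. Small values indicate that the repeated MLG is a true clone.
#' The default is the plain binomial tail `P(X >= n_copies)`,
#' `X ~ Bin(N, p_gen)`; `method = "parks_werth"` conditions on the first
#' observation (`P(X >= n_copies - 1)` among the remaining `N - 1`).
#'
#' @param p_gen Genotype probability from [p_gen()] (vectorised).
#' @param n_copies Observed copies of the MLG (>= 2 for a meaningful
#'   test; singletons return 1 with a warning).
#' @param N Number of sampled genotypes.
#' @param method `"binomial"` (default) or `"parks_werth"`.
#' @return P_sex in (0, 1].
#' @export
#' @examples
#' p_sex(0.01, n_copies = 2, N = 10)
p_sex <- function(p_gen, n_copies, N, method = c("binomial", "parks_werth")) {
  method <- match.arg(method)
  stopifnot(all(n_copies <= N))
  if (any(n_copies < 2)) {
    warn("P_sex is undefined for singleton MLGs; returning 1.")
  }
  out <- switch(method,
    binomial = pbinom(n_copies - 1, N, p_gen, lower.tail = FALSE),
    parks_werth = pbinom(n_copies - 2, N - 1, p_gen, lower.tail = FALSE))
  out[n_copies < 2] <- 1
  out
}

#' Monte-Carlo clonality significance of repeated MLGs
#'
#' For every MLG observed in 2 or more samples, computes `p_gen` and
#' `P_sex`, then tests the observed `P_sex` against a simulated null: each
#' of `n_sim` replicate datasets draws `N` independent multilocus
#' genotypes locus-wise from the allele frequencies, and the `P_sex`
#' values of every repeated genotype in the replicates form the null
#' distribution. An observed MLG is a significant (true) clone when its
#' `P_sex` falls strictly below the `alpha`-quantile of that null
#' (ties resolve to non-significant). If the null is degenerate — no
#' repeated genotype ever arises in simulation, or no locus is
#' polymorphic — every repeated MLG is flagged accordingly (significant
#' when repeats are unsimulable, i.e. observed repetition is already more
#' extreme than anything the null produces; non-significant in the
#' monomorphic case where repetition is certain).
#'
#' @param data Output of [assign_mlgs()].
#' @param loci Optional SSR locus subset (the mating type is part of MLG
#'   identity but not of `p_gen`; set `include_mat = TRUE` to add it as a
#'   two-allele locus).
#' @param n_sim Number of simulated null datasets (default 1000).
#' @param alpha Significance level (default 0.05).
#' @param seed Integer seed for the Monte-Carlo draw (default 1962).
#' @param clone_corrected Frequency estimation mode, see
#'   [allele_frequencies()].
#' @param include_mat Include the mating-type locus in `p_gen` (default
#'   `FALSE`).
#' @param method P_sex tail convention, see [p_sex()].
#' @return A tibble with one row per MLG: `mlg_id`, `n_ramets`, `p_gen`,
#'   `p_sex`, `significant` (NA for singletons), plus the critical value
#'   as attribute `"critical"`.
#' @export
p_sex_significance <- function(data, loci = NULL, n_sim = 1000, alpha = 0.05,
                               seed = 1962, clone_corrected = TRUE,
                               include_mat = FALSE,
                               method = c("binomial", "parks_werth")) {
  method <- match.arg(method)
  loci <- ssr_loci(data, loci)
  if (!"mlg_id" %in% names(data)) data <- assign_mlgs(data, loci)
  N <- nrow(data)

  freqs <- allele_frequencies(data, loci, clone_corrected = clone_corrected)
  if (include_mat) {
    matf <- data[!duplicated(data$mlg_id), , drop = FALSE] |>
      dplyr::count(.data$mat, name = "count") |>
      dplyr::mutate(locus = "mat", allele = match(.data$mat, mat_idiomorphs()),
                    n = sum(.data$count), freq = .data$count / .data$n) |>
      dplyr::select("locus", "allele", "count", "freq", "n")
    freqs <- dplyr::bind_rows(freqs, matf)
    data$mat_allele <- match(data$mat, mat_idiomorphs())
    loci <- c(loci, "mat")
  }

  per_locus <- split(freqs, freqs$locus)[unique(freqs$locus)]
  polymorphic <- any(vapply(per_locus, nrow, integer(1)) > 1)

  # observed statistics per MLG
  obs <- data |>
    dplyr::group_by(.data$mlg_id) |>
    dplyr::summarise(n_ramets = dplyr::n(), .groups = "drop")
  reps <- data[!duplicated(data$mlg_id), , drop = FALSE]
  pg <- rep(1, nrow(reps))
  fmin <- min(freqs$freq)
  for (l in setdiff(loci, "mat")) {
    fl <- per_locus[[l]]
    f <- fl$freq[match(reps[[l]], fl$allele)]
    f[is.na(f)] <- fmin
    pg <- pg * f
  }
  if (include_mat) {
    fl <- per_locus[["mat"]]
    pg <- pg * fl$freq[match(reps$mat_allele, fl$allele)]
  }
  obs <- dplyr::left_join(obs, tibble::tibble(mlg_id = reps$mlg_id, p_gen = pg),
                          by = "mlg_id")
  obs$p_sex <- suppressWarnings(p_sex(obs$p_gen, obs$n_ramets, N, method))
  obs$p_sex[obs$n_ramets < 2] <- NA_real_

  # Monte-Carlo null of P_sex values among repeated simulated genotypes
  null_psex <- with_seed(seed, {
    sim_keys <- matrix("", nrow = n_sim * N, ncol = length(loci))
    sim_pg <- rep(1, n_sim * N)
    for (j in seq_along(loci)) {
      fl <- per_locus[[loci[j]]]
      idx <- sample.int(nrow(fl), n_sim * N, replace = TRUE, prob = fl$freq)
      sim_keys[, j] <- as.character(fl$allele[idx])
      sim_pg <- sim_pg * fl$freq[idx]
    }
    key <- do.call(paste, c(asplit(sim_keys, 2), sep = "|"))
    sim <- rep(seq_len(n_sim), each = N)
    tab <- tibble::tibble(sim = sim, key = key, p_gen = sim_pg) |>
      dplyr::count(.data$sim, .data$key, .data$p_gen, name = "copies") |>
      dplyr::filter(.data$copies >= 2)
    if (!nrow(tab)) numeric(0)
    else p_sex(tab$p_gen, tab$copies, N, method)
  })

  if (!polymorphic) {
    warn("No polymorphic loci: P_sex null degenerate; all repeated MLGs flagged significant.")
    obs$significant <- ifelse(obs$n_ramets >= 2, TRUE, NA)
    attr(obs, "critical") <- NA_real_
    return(obs)
  }
  if (!length(null_psex)) {
    warn("No repeated genotypes arose in the null; all repeats significant.")
    obs$significant <- ifelse(obs$n_ramets >= 2, TRUE, NA)
    attr(obs, "critical") <- 0
    return(obs)
  }
  crit <- unname(quantile(null_psex, alpha, type = 1))
  obs$significant <- ifelse(obs$n_ramets >= 2, obs$p_sex < crit, NA)
  attr(obs, "critical") <- crit
  obs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a local RNG seed without touching the global stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}
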