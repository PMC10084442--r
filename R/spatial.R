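#' Nearest-neighbour spatial aggregation index Ac
#'
#' Measures whether samples carrying the same label (an MLG, a mating
#' type, a genetic cluster) clump in space. With `P_nn` the proportion of
#' samples whose nearest neighbour carries the same label and `P_all` the
#' probability that two random distinct samples share a label,
#' `Ac = (P_nn - P_all)/(1 - P_all)`: 0 when nearest neighbours share
#' labels no more than random pairs do, 1 when every nearest neighbour
#' shares its label. (The index's original definition is verbal; this
#' closed form satisfies both of its anchor points and is the one
#' implemented throughout.) Significance comes from permuting labels over
#' the fixed positions, one-sided for aggregation, with add-one
#' smoothing.
#'
#' Nearest-neighbour ties (co-nearest points) are handled by averaging
#' the same-label indicator over all co-nearest neighbours, so the index
#' is invariant to coordinate rotation/translation and label renaming.
#'
#' @param data Tibble with `x`, `y` and the label column; rows without
#'   coordinates are dropped.
#' @param label Name of the label column (e.g. `"mat"`, `"mlg_id"`).
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Integer seed (default 1962).
#' @return A list of class `clonering_ac`: `ac`, `p_value`, `p_nn`,
#'   `p_all`, `n`, `n_perm`, `label`.
#' @export
aggregation_index <- function(data, label = "mat", n_perm = 1000, seed = 1962) {
  ok <- !is.na(data$x) & !is.na(data$y) & !is.na(data[[label]])
  data <- data[ok, , drop = FALSE]
  n <- nrow(data)
  if (n < 3) abort("Aggregation index needs at least 3 positioned samples.")
  lab <- as.character(data[[label]])
  if (length(unique(lab)) < 2) {
    abort("All labels identical: aggregation index undefined (P_all = 1).")
  }
  D <- as.matrix(dist(cbind(data$x, data$y)))
  diag(D) <- Inf
  nn <- lapply(seq_len(n), function(i) which(D[i, ] == min(D[i, ])))
  single <- all(lengths(nn) == 1L)
  nn_vec <- if (single) vapply(nn, identity, integer(1)) else NULL

  p_nn <- function(l) {
    if (single) mean(l[nn_vec] == l)
    else mean(vapply(seq_len(n), function(i) mean(l[nn[[i]]] == l[i]), numeric(1)))
  }
  cnt <- table(lab)
  p_all <- sum(cnt * (cnt - 1)) / (n * (n - 1))
  ac_of <- function(l) (p_nn(l) - p_all) / (1 - p_all)
  ac <- ac_of(lab)
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(k) ac_of(sample(lab)), numeric(1))
  })
  p <- (1 + sum(perm >= ac)) / (n_perm + 1)
  structure(list(ac = ac, p_value = p, p_nn = p_nn(lab), p_all = p_all,
                 n = n, n_perm = n_perm, label = label, null = perm),
            class = "clonering_ac")
}

#' @export
print.clonering_ac <- function(x, ...) {
  cat(sprintf("Spatial aggregation of %s: Ac = %.3f (p = %.3g, %d permutations, n = %d)\n",
              x$label, x$ac, x$p_value, x$n_perm, x$n))
  invisible(x)
}

#' @export
glance.clonering_ac <- function(x, ...) {
  tibble::tibble(ac = x$ac, p_value = x$p_value, p_nn = x$p_nn,
                 p_all = x$p_all, n = x$n, n_perm = x$n_perm)
}

#' Pairwise genetic distance between haploid genotypes
#'
#' Counts the loci at which two genotypes differ (a haploid mismatch
#' metric; also the squared distance used by the AMOVA).
#'
#' @param data Genotype tibble.
#' @param loci Optional SSR locus subset.
#' @return A symmetric `n x n` matrix with sample ids as dimnames.
#' @export
genetic_distance <- function(data, loci = NULL) {
  loci <- ssr_loci(data, loci)
  G <- as.matrix(data[, loci, drop = FALSE])
  n <- nrow(G)
  D <- matrix(0, n, n, dimnames = list(data$sample_id, data$sample_id))
  for (l in seq_along(loci)) {
    D <- D + outer(G[, l], G[, l], "!=")
  }
  D
}

#' Mantel test for isolation by distance
#'
#' Pearson correlation between the off-diagonal entries of a genetic and
#' a geographic distance matrix, with significance from simultaneous
#' row/column permutation of one matrix (one-sided for positive
#' association, add-one smoothing).
#'
#' @param gen,geo Square symmetric distance matrices in the same sample
#'   order (>= 4 samples).
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed (default 1962).
#' @return A list of class `clonering_mantel`: `r`, `p_value`, `n`,
#'   `n_perm`.
#' @export
mantel_ibd <- function(gen, geo, n_perm = 999, seed = 1962) {
  gen <- as.matrix(gen); geo <- as.matrix(geo)
  n <- nrow(gen)
  stopifnot(nrow(geo) == n, ncol(gen) == n, ncol(geo) == n)
  if (n < 4) abort("Mantel test needs at least 4 samples.")
  lt <- lower.tri(gen)
  if (sd(gen[lt]) == 0 || sd(geo[lt]) == 0) {
    abort("Zero-variance distance matrix: Mantel r undefined.")
  }
  r <- stats::cor(gen[lt], geo[lt])
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(k) {
      s <- sample.int(n)
      stats::cor(gen[s, s][lt], geo[lt])
    }, numeric(1))
  })
  p <- (1 + sum(perm >= r)) / (n_perm + 1)
  structure(list(r = r, p_value = p, n = n, n_perm = n_perm),
            class = "clonering_mantel")
}

#' @export
print.clonering_mantel <- function(x, ...) {
  cat(sprintf("Mantel IBD: r = %.3f (p = %.3g, %d permutations, n = %d)\n",
              x$r, x$p_value, x$n_perm, x$n))
  invisible(x)
}

#' @export
glance.clonering_mantel <- function(x, ...) {
  tibble::tibble(r = x$r, p_value = x$p_value, n = x$n, n_perm = x$n_perm)
}

#' Loiselle kinship coefficients for haploid genotypes
#'
#' Pairwise kinship `F_ij` with genotypes coded as 0/1 allele indicators:
#' the numerator sums, over loci and alleles, the cross-products
#' `(x_i - p)(x_j - p)` plus the small-sample term `p(1 - p)/(n - 1)`;
#' the denominator is the total `sum p(1 - p)`. Reference frequencies
#' default to the analysed sample itself (so the all-pairs average is
#' near 0 up to the small-sample term); the estimator is symmetric and
#' robust to rare alleles.
#'
#' @param data Genotype tibble (conventionally clone-corrected).
#' @param loci Optional SSR locus subset.
#' @param freqs Optional reference [allele_frequencies()] table; default
#'   computes plain frequencies from `data` itself.
#' @return A symmetric `n x n` kinship matrix (diagonal included but
#'   conventionally ignored).
#' @export
loiselle_kinship <- function(data, loci = NULL, freqs = NULL) {
  loci <- ssr_loci(data, loci)
  n <- nrow(data)
  if (is.null(freqs)) {
    freqs <- allele_frequencies(data, loci, clone_corrected = FALSE)
  }
  freqs <- freqs[freqs$freq < 1, , drop = FALSE]  # monomorphic: no information
  if (!nrow(freqs)) abort("No polymorphic loci: kinship undefined.")
  X <- matrix(0, n, length(freqs$allele))
  for (k in seq_len(nrow(freqs))) {
    X[, k] <- as.integer(data[[freqs$locus[k]]] == freqs$allele[k])
  }
  p <- freqs$freq
  Xc <- sweep(X, 2, p)
  correction <- sum(p * (1 - p) / (n - 1))
  denom <- sum(p * (1 - p))
  Fm <- (Xc %*% t(Xc) + correction) / denom
  dimnames(Fm) <- list(data$sample_id, data$sample_id)
  Fm
}

#' Kinship autocorrelation by distance class and the Sp statistic
#'
#' Bins pairwise Loiselle kinship into distance classes, tests each class
#' mean against the null of no spatial genetic structure by permuting
#' spatial locations among individuals (two-sided, add-one smoothing),
#' regresses pair-level kinship on ln(distance) and summarises the decay
#' as `Sp = -b / (1 - F1)`, where `b` is the regression slope and `F1`
#' the mean kinship of the first distance class. Pairs at distance 0 are
#' excluded from the log regression.
#'
#' @param data Positioned, clone-corrected genotype tibble.
#' @param loci Optional SSR locus subset.
#' @param n_classes Number of distance classes (default 13) when `edges`
#'   is not given; edges are set to `min_dist` plus equal-pair-count
#'   quantiles up to `max_dist`.
#' @param min_dist Upper edge of the first class in metres (default 5).
#' @param max_dist Largest distance analysed (default: max pair
#'   distance).
#' @param edges Explicit class upper edges (overrides the above).
#' @param n_perm Location permutations (default 10000).
#' @param seed Integer seed (default 1962).
#' @param max_regression_dist Restrict the ln-distance regression (and
#'   Sp) to pairs up to this distance, e.g. 5 to probe structure within
#'   the first metres; default uses all binned pairs.
#' @return A list of class `clonering_sgs`: `by_class` tibble (`edge_lo`,
#'   `edge_hi`, `n_pairs`, `mean_dist`, `mean_fij`, `p_value`), `b`
#'   (slope), `F1`, `Sp`, `n`, `n_perm`.
#' @export
spatial_autocorrelation <- function(data, loci = NULL, n_classes = 13,
                                    min_dist = 5, max_dist = NULL,
                                    edges = NULL, n_perm = 10000, seed = 1962,
                                    max_regression_dist = NULL) {
  ok <- !is.na(data$x) & !is.na(data$y)
  data <- data[ok, , drop = FALSE]
  n <- nrow(data)
  if (n < 4) abort("Autocorrelation needs at least 4 positioned genotypes.")
  Fm <- loiselle_kinship(data, loci)
  D <- as.matrix(dist(cbind(data$x, data$y)))
  lt <- which(lower.tri(D), arr.ind = TRUE)
  d <- D[lower.tri(D)]
  f <- Fm[lower.tri(Fm)]
  if (is.null(max_dist)) max_dist <- max(d)
  if (is.null(edges)) {
    inner <- d[d > min_dist & d <= max_dist]
    edges <- if (length(inner) && n_classes > 1) {
      c(min_dist, unname(quantile(inner, seq_len(n_classes - 1) / (n_classes - 1))))
    } else min_dist
    edges <- unique(edges)
  }
  edges <- sort(edges)
  cls <- cut(d, breaks = c(0, edges), labels = FALSE, right = TRUE)
  keep <- !is.na(cls)
  used <- sort(unique(cls[keep]))
  if (length(used) < length(edges)) warn("Empty distance class(es) dropped.")

  by_class <- tibble::tibble(
    class = used,
    edge_lo = c(0, edges)[used],
    edge_hi = edges[used],
    n_pairs = vapply(used, function(k) sum(cls == k, na.rm = TRUE), numeric(1)),
    mean_dist = vapply(used, function(k) mean(d[which(cls == k)]), numeric(1)),
    mean_fij = vapply(used, function(k) mean(f[which(cls == k)]), numeric(1)))

  # permute individuals among the fixed locations; recompute class means
  idx_by_class <- lapply(used, function(k) which(cls == k))
  perm_means <- with_seed(seed, {
    out <- matrix(NA_real_, n_perm, length(used))
    ii <- lt[, 1]; jj <- lt[, 2]
    for (bb in seq_len(n_perm)) {
      s <- sample.int(n)
      fp <- Fm[cbind(s[ii], s[jj])]
      out[bb, ] <- vapply(seq_along(used),
                          function(k) mean(fp[idx_by_class[[k]]]), numeric(1))
    }
    out
  })
  by_class$p_value <- vapply(seq_along(used), function(k) {
    obs <- by_class$mean_fij[k]
    null <- perm_means[, k]
    ctr <- mean(null)
    (1 + sum(abs(null - ctr) >= abs(obs - ctr))) / (n_perm + 1)
  }, numeric(1))

  reg_keep <- keep & d > 0
  if (!is.null(max_regression_dist)) reg_keep <- reg_keep & d <= max_regression_dist
  fit <- lm(f[reg_keep] ~ log(d[reg_keep]))
  b <- unname(coef(fit)[2])
  F1 <- by_class$mean_fij[1]
  structure(list(by_class = by_class, b = b, F1 = F1, Sp = -b / (1 - F1),
                 n = n, n_perm = n_perm),
            class = "clonering_sgs")
}

#' @export
print.clonering_sgs <- function(x, ...) {
  cat(sprintf("Spatial genetic structure: b = %.4g, F1 = %.4f, Sp = %.4f (n = %d)\n",
              x$b, x$F1, x$Sp, x$n))
  print(x$by_class, ...)
  invisible(x)
}

#' @export
tidy.clonering_sgs <- function(x, ...) x$by_class

#' @export
glance.clonering_sgs <- function(x, ...) {
  tibble::tibble(b = x$b, F1 = x$F1, Sp = x$Sp, n = x$n, n_perm = x$n_perm)
}
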