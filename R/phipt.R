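#' AMOVA-based PhiPT differentiation for haploid genotypes
#'
#' Partitions the sum of squared genetic distances (count of differing
#' loci between haploid genotypes) among and within groups, in the
#' analysis-of-molecular-variance framework. `PhiPT = Va / (Va + Vw)`
#' where `Va` is the among-group and `Vw` the within-group variance
#' component: 0 for identical group compositions, 1 for fully
#' differentiated groups. Negative `Va` estimates are truncated to 0 with
#' a warning (standard practice). Significance comes from permuting
#' genotypes across groups (one-sided, add-one smoothing). Conventionally
#' run on clone-corrected datasets; the mating-type locus is excluded by
#' default (pass it in `loci` to include it).
#'
#' @param data Genotype tibble with a grouping column.
#' @param group Name of the grouping column (default `"site"`).
#' @param loci Optional SSR locus subset.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed (default 1962).
#' @param pairwise Also compute the pairwise group matrix (default
#'   `TRUE`).
#' @return A list of class `clonering_phipt`: `phi_pt`, `p_value`,
#'   `va`, `vw`, `df`, `groups`, and (if requested) `pairwise_phi` /
#'   `pairwise_p` matrices.
#' @export
phi_pt <- function(data, group = "site", loci = NULL, n_perm = 999,
                   seed = 1962, pairwise = TRUE) {
  loci <- ssr_loci(data, loci)
  g <- as.character(data[[group]])
  cnt <- table(g)
  if (length(cnt) < 2) abort("PhiPT needs at least 2 groups.")
  if (any(cnt < 2)) {
    abort(paste0("Group(s) with fewer than 2 genotypes: ",
                 paste(names(cnt)[cnt < 2], collapse = ", ")))
  }
  D2 <- genetic_distance(data, loci)  # already a squared (mismatch-count) metric

  phi_of <- function(lab) {
    n <- length(lab)
    k <- length(unique(lab))
    ss_total <- sum(D2[lower.tri(D2)]) / n
    ss_within <- 0
    for (gr in unique(lab)) {
      idx <- which(lab == gr)
      sub <- D2[idx, idx, drop = FALSE]
      ss_within <- ss_within + sum(sub[lower.tri(sub)]) / length(idx)
    }
    ss_among <- ss_total - ss_within
    df_a <- k - 1
    df_w <- n - k
    ms_a <- ss_among / df_a
    ms_w <- ss_within / df_w
    sizes <- table(lab)
    n0 <- (n - sum(sizes^2) / n) / df_a
    va <- (ms_a - ms_w) / n0
    vw <- ms_w
    list(va = va, vw = vw, phi = if (va + vw <= 0) 0 else va / (va + vw))
  }

  obs <- phi_of(g)
  truncated <- obs$va < 0
  if (truncated) {
    warn("Negative among-group variance estimate truncated to 0.")
  }
  phi_obs <- if (truncated) 0 else obs$phi
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(k) max(0, phi_of(sample(g))$phi), numeric(1))
  })
  p <- (1 + sum(perm >= phi_obs)) / (n_perm + 1)

  res <- list(phi_pt = phi_obs, p_value = p,
              va = max(0, obs$va), vw = obs$vw,
              df = c(among = length(cnt) - 1, within = length(g) - length(cnt)),
              groups = names(cnt), n_perm = n_perm)
  if (pairwise && length(cnt) > 2) {
    grs <- names(cnt)
    m <- matrix(0, length(grs), length(grs), dimnames = list(grs, grs))
    pm <- m; diag(pm) <- NA
    for (a in seq_along(grs)[-1]) for (b in seq_len(a - 1)) {
      sub <- data[g %in% grs[c(a, b)], , drop = FALSE]
      r <- phi_pt(sub, group = group, loci = loci, n_perm = n_perm,
                  seed = seed + a * 131 + b, pairwise = FALSE)
      m[a, b] <- m[b, a] <- r$phi_pt
      pm[a, b] <- pm[b, a] <- r$p_value
    }
    res$pairwise_phi <- m
    res$pairwise_p <- pm
  } else if (pairwise) {
    grs <- names(cnt)
    m <- matrix(0, 2, 2, dimnames = list(grs, grs))
    m[1, 2] <- m[2, 1] <- phi_obs
    pm <- matrix(p, 2, 2, dimnames = list(grs, grs)); diag(pm) <- NA
    res$pairwise_phi <- m
    res$pairwise_p <- pm
  }
  class(res) <- "clonering_phipt"
  res
}

#' @export
print.clonering_phipt <- function(x, ...) {
  cat(sprintf("PhiPT = %.3f (p = %.3g; Va = %.3f, Vw = %.3f; groups: %s)\n",
              x$phi_pt, x$p_value, x$va, x$vw, paste(x$groups, collapse = ", ")))
  invisible(x)
}

#' @export
glance.clonering_phipt <- function(x, ...) {
  tibble::tibble(phi_pt = x$phi_pt, p_value = x$p_value, va = x$va,
                 vw = x$vw, n_groups = length(x$groups), n_perm = x$n_perm)
}

#' @export
tidy.clonering_phipt <- function(x, ...) {
  if (is.null(x$pairwise_phi)) {
    return(tibble::tibble(group1 = character(), group2 = character(),
                          phi_pt = numeric(), p_value = numeric()))
  }
  grs <- rownames(x$pairwise_phi)
  idx <- which(lower.tri(x$pairwise_phi), arr.ind = TRUE)
  tibble::tibble(group1 = grs[idx[, 2]], group2 = grs[idx[, 1]],
                 phi_pt = x$pairwise_phi[idx], p_value = x$pairwise_p[idx])
}
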