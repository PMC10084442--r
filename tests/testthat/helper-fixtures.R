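# Small in-code fixtures shared across test files.

# Hand-built genotype tibble: `alleles` is a matrix (samples x loci).
toy_genotypes <- function(alleles, mat = "MAT1-1", site = "A", year = 2019L,
                          role = "gleba", x = NULL, y = NULL) {
  n <- nrow(alleles)
  loci <- colnames(alleles)
  if (is.null(loci)) loci <- sprintf("L%d", seq_len(ncol(alleles)))
  out <- tibble::tibble(
    sample_id = sprintf("S%02d", seq_len(n)),
    site = rep_len(site, n), year = rep_len(year, n),
    role = rep_len(role, n),
    x = if (is.null(x)) runif(n, 0, 10) else x,
    y = if (is.null(y)) runif(n, 0, 10) else y)
  for (j in seq_along(loci)) out[[loci[j]]] <- as.integer(alleles[, j])
  out$mat <- rep_len(mat, n)
  out$resolved <- TRUE
  out
}

# Independent O(N^2) brute-force MLG grouping over SSR + MAT.
brute_force_mlgs <- function(data, loci) {
  n <- nrow(data)
  group <- integer(n)
  next_id <- 0L
  for (i in seq_len(n)) {
    hit <- 0L
    if (i > 1) {
      for (j in seq_len(i - 1)) {
        same <- data$mat[i] == data$mat[j]
        for (l in loci) same <- same && data[[l]][i] == data[[l]][j]
        if (same) { hit <- group[j]; break }
      }
    }
    group[i] <- if (hit) hit else (next_id <- next_id + 1L)
  }
  group
}

# Exact binomial tail by explicit summation.
exact_binom_tail <- function(n_copies, N, p) {
  sum(vapply(n_copies:N, function(k) choose(N, k) * p^k * (1 - p)^(N - k),
             numeric(1)))
}

# All compositions of N into G positive parts (unordered, as count vectors).
compositions <- function(N, G) {
  if (G == 1) return(list(N))
  out <- list()
  for (first in seq_len(N - G + 1)) {
    for (rest in compositions(N - first, G - 1)) {
      out[[length(out) + 1]] <- c(first, rest)
    }
  }
  out
}

# Independent minimal Genepop reader for haploid 3-digit exports.
read_genepop_minimal <- function(path) {
  lines <- readLines(path)
  pop_idx <- which(toupper(trimws(lines)) == "POP")
  loci <- trimws(lines[2:(pop_idx[1] - 1)])
  rows <- list()
  pop <- 0
  for (i in (pop_idx[1]):length(lines)) {
    ln <- trimws(lines[i])
    if (toupper(ln) == "POP") { pop <- pop + 1; next }
    parts <- strsplit(ln, ",")[[1]]
    id <- trimws(parts[1])
    alleles <- as.integer(strsplit(trimws(parts[2]), "\\s+")[[1]])
    rows[[length(rows) + 1]] <- c(list(id = id, pop = pop),
                                  setNames(as.list(alleles), loci))
  }
  dplyr::bind_rows(rows)
}
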