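# Independent oracles and small fixtures used across the suite. Each
# oracle deliberately re-derives its quantity by a different route than
# the package implementation (brute force, enumeration, closed form).

# Second transcription of the published population table, kept as raw
# text and parsed here with code independent of read_population_table().
# Column order: population, distance_km, then the nine markers in the
# order of table1_fixture().
table1_second_transcription <- function() {
  txt <- "San|0|0,75|0,75|1,00|0,83|1,00|0,83|0,83|1,00|1,00
Mbuti|2716|0,97|0,80|1,00|0,87|1,00|0,83|0,83|0,97|1,00
Bantu speakers|2920|0,93|0,73|1,00|0,65|0,95|0,83|0,95|0,93|0,87
Biaka|2934|0,92|0,87|1,00|0,79|1,00|1,00|1,00|0,97|1,00
Yoruba|3900|0,94|0,58|1,00|0,67|0,94|0,90|0,92|0,94|0,98
Mandenka|5574|0,90|0,83|1,00|0,50|0,89|0,85|0,88|0,85|1,00
Bedouin|6400|0,94|0,47|0,99|0,66|0,90|0,67|0,89|0,98|0,78
Mozabite|6470|0,88|0,67|0,91|0,63|0,92|0,68|0,92|0,97|0,90
Palestinian|6482|0,92|0,58|0,98|0,68|0,95|0,78|0,95|0,97|0,84
Druze|6696|0,89|0,79|0,99|0,68|0,72|0,68|0,72|0,98|0,96
Adygei|7840|0,82|0,65|0,97|0,62|0,88|0,82|0,88|1,00|0,94
Italians|8708|0,88|0,67|1,00|0,72|0,88|0,71|0,88|1,00|0,81
Sardinian|8886|0,91|0,55|0,96|0,80|0,74|0,59|0,75|1,00|0,84
Balochi|9099|0,89|0,58|0,97|0,70|0,85|0,74|0,85|1,00|0,89
Brahui|9285|0,86|0,52|0,98|0,52|0,88|0,86|0,88|0,98|0,98
French|9411|0,79|0,64|0,97|0,79|0,72|0,53|0,72|1,00|0,81
Sindhi|9783|0,84|0,58|0,93|0,72|0,80|0,68|0,80|1,00|0,88
Basque|9878|0,77|0,54|0,85|0,71|0,75|0,58|0,75|1,00|0,83
Kalash|9967|0,90|0,90|1,00|0,88|0,86|0,84|0,86|1,00|0,98
Orcadian|10513|0,66|0,66|0,97|0,78|0,63|0,44|0,63|1,00|0,81
Uyghur|10945|0,85|0,85|1,00|0,80|0,90|0,90|0,90|1,00|1,00
Tu|12147|0,70|1,00|1,00|1,00|0,75|0,75|0,75|1,00|1,00
Russians|12164|0,76|0,54|0,88|0,62|0,70|0,60|0,70|1,00|0,90
Mongolian|12551|0,55|1,00|1,00|1,00|0,56|0,60|0,60|1,00|1,00
Dai|12873|0,70|0,95|1,00|1,00|0,72|0,75|0,75|1,00|1,00
Lahu|12895|0,65|0,95|1,00|0,95|0,65|0,65|0,65|1,00|1,00
Yi|13022|0,70|0,95|1,00|0,90|0,65|0,65|0,65|1,00|1,00
Miao|13126|0,70|1,00|1,00|1,00|0,70|0,70|0,70|1,00|1,00
Daur|13380|0,78|0,89|0,89|0,89|0,72|0,72|0,72|1,00|1,00
Han|13400|0,89|1,00|1,00|1,00|0,89|0,89|0,89|1,00|1,00
Tujia|13654|0,85|1,00|1,00|1,00|0,85|0,85|0,85|1,00|1,00
Cambodians, Khmer|13803|0,91|0,95|1,00|0,91|0,77|0,77|0,77|1,00|1,00
Oroqen|13803|0,65|0,95|1,00|0,95|0,70|0,70|0,70|1,00|1,00
Hezhe|14141|0,67|1,00|1,00|1,00|0,81|0,83|0,83|1,00|1,00
Naxi|14147|0,83|0,89|1,00|0,89|0,83|0,83|0,83|1,00|1,00
She|14203|0,85|0,90|1,00|0,90|0,85|0,85|0,85|1,00|1,00
Japanese|15379|0,77|1,00|1,00|0,98|0,79|0,79|0,79|1,00|1,00
Papuan New Guinean|18323|1,00|0,79|1,00|1,00|1,00|0,82|1,00|1,00|1,00
Melanesian, Nasioi|19515|0,92|0,84|1,00|1,00|0,95|0,84|0,95|1,00|1,00
Pima, Mexico|21788|0,44|0,98|1,00|0,98|0,46|0,46|0,46|1,00|1,00
Maya, Yucatan|23603|0,48|0,90|0,98|0,94|0,52|0,50|0,52|1,00|0,98
Karitiana|28012|0,35|1,00|1,00|1,00|0,42|0,42|0,42|1,00|1,00
Surui|28336|0,33|1,00|1,00|1,00|0,38|0,38|0,38|1,00|1,00"
  rows <- strsplit(strsplit(txt, "\n")[[1]], "|", fixed = TRUE)
  vals <- t(vapply(rows, function(r)
    as.numeric(gsub(",", ".", r[-1], fixed = TRUE)), numeric(10)))
  list(population = vapply(rows, `[[`, character(1), 1L),
       values = vals)  # col 1 distance, cols 2..10 the nine markers
}

# naive motif scan: all 0-based start positions of `motif` in `s`
naive_motif_positions <- function(s, motif) {
  k <- nchar(motif)
  n <- nchar(s)
  if (n < k) return(integer(0))
  hits <- integer(0)
  for (i in seq_len(n - k + 1L))
    if (substr(s, i, i + k - 1L) == motif) hits <- c(hits, i - 1L)
  hits
}

# naive digestion: cut before every primary motif, report fragments and
# internal-secondary flags, independent of Biostrings
naive_digest <- function(s, primary = "GATC", secondary = "GTAC") {
  len <- nchar(s)
  cuts <- sort(unique(c(0L, naive_motif_positions(s, primary), len)))
  start <- cuts[-length(cuts)]
  end <- cuts[-1L]
  sec <- naive_motif_positions(s, secondary)
  has_sec <- vapply(seq_along(start), function(i)
    any(sec >= start[i] & sec + nchar(secondary) <= end[i]), logical(1))
  data.frame(start = start, end = end, has_secondary = has_sec)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# direct Gaussian GLS log-likelihood, no whitening tricks
gls_loglik_direct <- function(beta, sigma2, X, y, R) {
  n <- length(y)
  e <- y - X %*% beta
  Rinv <- solve(R)
  ld <- as.numeric(determinant(R, logarithm = TRUE)$modulus)
  -0.5 * (n * log(2 * pi * sigma2) + ld + drop(t(e) %*% Rinv %*% e) / sigma2)
}

# numeric ML oracle over (beta, log sigma2)
gls_optim_oracle <- function(X, y, R) {
  nll <- function(th) {
    k <- ncol(X)
    -gls_loglik_direct(th[seq_len(k)], exp(th[k + 1L]), X, y, R)
  }
  start <- c(qr.solve(X, y), log(stats::var(y)))
  o <- stats::optim(start, nll, method = "BFGS",
                    control = list(reltol = 1e-15, maxit = 10000))
  o <- stats::optim(o$par, nll, control = list(reltol = 1e-15, maxit = 50000))
  k <- ncol(X)
  list(beta = o$par[seq_len(k)], sigma2 = exp(o$par[k + 1L]),
       loglik = -o$value)
}

# independent two-locus genotype log-likelihood (explicit 9-cell loop)
two_locus_loglik_direct <- function(h, counts) {
  p <- matrix(0, 3, 3)
  p[1, 1] <- h[1]^2;          p[1, 2] <- 2 * h[1] * h[2];  p[1, 3] <- h[2]^2
  p[2, 1] <- 2 * h[1] * h[3]; p[2, 2] <- 2 * h[1] * h[4] + 2 * h[2] * h[3]
  p[2, 3] <- 2 * h[2] * h[4]
  p[3, 1] <- h[3]^2;          p[3, 2] <- 2 * h[3] * h[4];  p[3, 3] <- h[4]^2
  ll <- 0
  for (i in 1:3) for (j in 1:3)
    if (counts[i, j] > 0) ll <- ll + counts[i, j] * log(p[i, j])
  ll
}

# exhaustive grid maximization of the two-locus likelihood over the
# 3-simplex: coarse full scan at `coarse`, then exhaustive fine scan at
# `fine` in a box around the coarse optimum
grid_em_oracle <- function(counts, coarse = 0.01, fine = 0.002) {
  best_of_grid <- function(h1s, h2s, h3s) {
    g <- expand.grid(h1 = h1s, h2 = h2s, h3 = h3s)
    g <- g[g$h1 + g$h2 + g$h3 <= 1 + 1e-12, ]
    H <- rbind(g$h1, g$h2, g$h3, pmax(0, 1 - g$h1 - g$h2 - g$h3))
    # vectorized likelihood over grid columns
    h1 <- H[1, ]; h2 <- H[2, ]; h3 <- H[3, ]; h4 <- H[4, ]
    pg <- rbind(h1^2, 2 * h1 * h2, h2^2,
                2 * h1 * h3, 2 * (h1 * h4 + h2 * h3), 2 * h2 * h4,
                h3^2, 2 * h3 * h4, h4^2)
    cnt <- as.vector(t(counts))
    used <- cnt > 0
    ll <- colSums(log(pmax(pg[used, , drop = FALSE], 1e-300)) * cnt[used])
    i <- which.max(ll)
    list(h = H[, i], loglik = ll[i])
  }
  s <- seq(0, 1, by = coarse)
  c1 <- best_of_grid(s, s, s)
  box <- function(v) {
    lo <- max(0, v - 1.5 * coarse); hi <- min(1, v + 1.5 * coarse)
    seq(lo, hi, by = fine)
  }
  best_of_grid(box(c1$h[1]), box(c1$h[2]), box(c1$h[3]))
}

# all permutations of a vector (recursive, for small n)
all_permutations <- function(x) {
  n <- length(x)
  if (n == 1L) return(list(x))
  out <- list()
  for (i in seq_len(n))
    for (p in all_permutations(x[-i]))
      out[[length(out) + 1L]] <- c(x[i], p)
  out
}

# random valid population table for round-trip properties
random_population_table <- function(n_pops, n_markers, seed) {
  withr::with_seed(seed, {
    df <- data.frame(population = paste0("pop", seq_len(n_pops)),
                     distance_km = round(stats::runif(n_pops, 0, 30000), 1))
    for (m in seq_len(n_markers))
      df[[paste0("mk", m)]] <- round(stats::runif(n_pops), 3)
  })
  population_table(df)
}

# independent 3x3 genotype count tabulation (rows: Dup dose, cols: T dose)
genotype_counts_direct <- function(g) {
  counts <- matrix(0L, 3L, 3L)
  for (i in seq_len(nrow(g))) {
    dd <- sum(strsplit(g$cnv[i], "/")[[1]] == "Dup")
    td <- sum(strsplit(g$snp[i], "/")[[1]] == "T")
    counts[dd + 1L, td + 1L] <- counts[dd + 1L, td + 1L] + 1L
  }
  counts
}
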