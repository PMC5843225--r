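## Genotype-level support: Hardy-Weinberg chi-square, expected
## heterozygosity, two-locus EM haplotype frequencies, and linkage
## disequilibrium statistics. The two loci are the SIRPB1 copy-number
## variant (alleles Sin/Dup) and its tagging SNP (alleles C/T); the
## haplotype order is fixed as (Sin-C, Sin-T, Dup-C, Dup-T).

HAPLOTYPE_NAMES <- c("Sin-C", "Sin-T", "Dup-C", "Dup-T")

#' Hardy-Weinberg equilibrium chi-square test
#'
#' Pearson chi-square on one biallelic locus, 1 df, no continuity
#' correction (the convention of the usual haplotype-browser displays).
#' Expected counts are `n p^2, 2 n p (1-p), n (1-p)^2` with
#' `p = (2 n_AA + n_Aa) / 2n`. A monomorphic sample is returned as
#' `chi2 = 0` with a warning.
#'
#' @param n_AA,n_Aa,n_aa Observed genotype counts.
#' @return List of class `hwe_result`: `observed`, `expected`, `p_hat`,
#'   `chi2`, `p_value`.
#' @export
hwe_chi2 <- function(n_AA, n_Aa, n_aa) {
  obs <- c(AA = n_AA, Aa = n_Aa, aa = n_aa)
  stopifnot(all(obs >= 0))
  n <- sum(obs)
  if (n == 0) stop("no observations")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  if (p %in% c(0, 1)) {
    warning("monomorphic sample: HWE chi-square is 0 by convention")
    exp_counts <- c(AA = n * p^2, Aa = 2 * n * p * (1 - p), aa = n * (1 - p)^2)
    return(structure(list(observed = obs, expected = exp_counts, p_hat = p,
                          chi2 = 0, p_value = 1), class = "hwe_result"))
  }
  exp_counts <- c(AA = n * p^2, Aa = 2 * n * p * (1 - p), aa = n * (1 - p)^2)
  chi2 <- sum((obs - exp_counts)^2 / exp_counts)
  structure(list(observed = obs, expected = exp_counts, p_hat = p,
                 chi2 = chi2, p_value = stats::pchisq(chi2, 1, lower.tail = FALSE)),
            class = "hwe_result")
}

#' Expected heterozygosity of a biallelic locus
#' @param p Allele proportion in \[0, 1\].
#' @return `2 p (1 - p)`.
#' @export
expected_heterozygosity <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("proportions must lie in [0, 1]")
  2 * p * (1 - p)
}

# 3x3 genotype count matrix: rows = Dup-allele count (0,1,2),
# cols = T-allele count (0,1,2)
.genotype_counts <- function(g) {
  stopifnot(inherits(g, "genotype_table"))
  cnv_dose <- vapply(strsplit(g$cnv, "/", fixed = TRUE),
                     function(a) sum(a == "Dup"), integer(1))
  snp_dose <- vapply(strsplit(g$snp, "/", fixed = TRUE),
                     function(a) sum(a == "T"), integer(1))
  counts <- matrix(0L, 3L, 3L, dimnames = list(cnv = 0:2, snp = 0:2))
  for (i in seq_along(cnv_dose))
    counts[cnv_dose[i] + 1L, snp_dose[i] + 1L] <-
      counts[cnv_dose[i] + 1L, snp_dose[i] + 1L] + 1L
  counts
}

# observed-data log-likelihood of the 3x3 genotype counts at haplotype
# frequencies h = (Sin-C, Sin-T, Dup-C, Dup-T); vectorized over columns
# of a 4 x m matrix for the grid oracle in the tests
.two_locus_loglik <- function(h, counts) {
  h <- matrix(h, nrow = 4L)
  h1 <- h[1L, ]; h2 <- h[2L, ]; h3 <- h[3L, ]; h4 <- h[4L, ]
  pg <- rbind(  # genotype probabilities, row order (cnv,snp) dose pairs
    `00` = h1^2,            `01` = 2 * h1 * h2,          `02` = h2^2,
    `10` = 2 * h1 * h3,     `11` = 2 * (h1 * h4 + h2 * h3), `12` = 2 * h2 * h4,
    `20` = h3^2,            `21` = 2 * h3 * h4,          `22` = h4^2)
  cnt <- c(counts[1, 1], counts[1, 2], counts[1, 3],
           counts[2, 1], counts[2, 2], counts[2, 3],
           counts[3, 1], counts[3, 2], counts[3, 3])
  used <- cnt > 0
  colSums(log(pg[used, , drop = FALSE]) * cnt[used])
}

#' Two-locus haplotype frequencies by EM
#'
#' Maximum-likelihood haplotype frequencies for the CNV x SNP pair from
#' unphased genotypes. Only the double heterozygote (Sin/Dup, C/T) has
#' ambiguous phase; the E-step splits it between the (Sin-C, Dup-T) and
#' (Sin-T, Dup-C) resolutions in proportion to their current expected
#' gamete products. Initialization is linkage equilibrium of the
#' observed allele frequencies (single deterministic start); iteration
#' stops when `max |delta h| < tol` or after `max_iter` updates. The
#' observed-data log-likelihood is checked to be non-decreasing at every
#' update.
#'
#' @param g A `genotype_table`.
#' @param tol Convergence tolerance on haplotype frequencies (default
#'   1e-8).
#' @param max_iter Maximum EM updates (default 1000).
#' @return Object of class `haplotype_estimate`: `h` (named frequencies,
#'   order Sin-C, Sin-T, Dup-C, Dup-T), `loglik`, `loglik_trace`,
#'   `iterations`, `converged`, `counts` (3x3 genotype counts), `n`.
#' @export
em_haplotypes <- function(g, tol = 1e-8, max_iter = 1000L) {
  counts <- .genotype_counts(g)
  n <- sum(counts)
  if (n == 0L) stop("empty genotype table")
  # allele frequencies of Dup and T
  dose <- 0:2
  p_dup <- sum(rowSums(counts) * dose) / (2 * n)
  p_t <- sum(colSums(counts) * dose) / (2 * n)
  h <- c((1 - p_dup) * (1 - p_t), (1 - p_dup) * p_t,
         p_dup * (1 - p_t), p_dup * p_t)
  names(h) <- HAPLOTYPE_NAMES
  # haplotype contributions of the unambiguous cells (2 per subject)
  base <- c(
    2 * counts[1, 1] + counts[1, 2] + counts[2, 1],              # Sin-C
    2 * counts[1, 3] + counts[1, 2] + counts[2, 3],              # Sin-T
    2 * counts[3, 1] + counts[2, 1] + counts[3, 2],              # Dup-C
    2 * counts[3, 3] + counts[2, 3] + counts[3, 2])              # Dup-T
  ndh <- counts[2, 2]  # double heterozygotes
  trace <- .two_locus_loglik(h, counts)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    cis <- h[1] * h[4]; trans <- h[2] * h[3]
    q <- if (cis + trans > 0) cis / (cis + trans) else 0.5
    new_h <- (base + ndh * c(q, 1 - q, 1 - q, q)) / (2 * n)
    names(new_h) <- HAPLOTYPE_NAMES
    ll <- .two_locus_loglik(new_h, counts)
    if (ll < utils::tail(trace, 1) - 1e-9)
      stop("EM log-likelihood decreased; this should be impossible")
    trace <- c(trace, ll)
    delta <- max(abs(new_h - h))
    h <- new_h
    if (delta < tol) { converged <- TRUE; break }
  }
  structure(list(h = h, loglik = unname(utils::tail(trace, 1)),
                 loglik_trace = unname(trace), iterations = iter,
                 converged = converged, counts = counts, n = n),
            class = "haplotype_estimate")
}

#' @export
print.haplotype_estimate <- function(x, ...) {
  cat(sprintf("EM haplotype estimate (n = %d, %d iterations%s):\n", x$n,
              x$iterations, if (x$converged) "" else ", NOT converged"))
  print(round(x$h, 4))
  cat(sprintf("loglik = %.4f\n", x$loglik))
  invisible(x)
}

#' Linkage disequilibrium statistics from haplotype frequencies
#'
#' With `p_A` the Sin frequency and `p_B` the C frequency,
#' `D = h(Sin-C) - p_A p_B`; `D' = |D| / D_max` where `D_max` is
#' `min(p_A (1-p_B), (1-p_A) p_B)` for positive D and
#' `min(p_A p_B, (1-p_A)(1-p_B))` for negative D;
#' `r^2 = D^2 / (p_A (1-p_A) p_B (1-p_B))`.
#'
#' @param h A `haplotype_estimate`, or a numeric vector of 4 frequencies
#'   in the order (Sin-C, Sin-T, Dup-C, Dup-T).
#' @return List of class `ld_stats`: `D`, `Dprime`, `r2`, `p_A`, `p_B`.
#' @export
ld_stats <- function(h) {
  if (inherits(h, "haplotype_estimate")) h <- h$h
  stopifnot(length(h) == 4L, all(h >= 0), abs(sum(h) - 1) < 1e-6)
  p_A <- h[1] + h[2]  # Sin
  p_B <- h[1] + h[3]  # C
  if (p_A %in% c(0, 1) || p_B %in% c(0, 1))
    stop("LD undefined for a monomorphic locus")
  D <- h[1] - p_A * p_B
  d_max <- if (D >= 0) min(p_A * (1 - p_B), (1 - p_A) * p_B) else
    min(p_A * p_B, (1 - p_A) * (1 - p_B))
  structure(list(D = unname(D),
                 Dprime = unname(if (D == 0) 0 else abs(D) / d_max),
                 r2 = unname(D^2 / (p_A * (1 - p_A) * p_B * (1 - p_B))),
                 p_A = unname(p_A), p_B = unname(p_B)),
            class = "ld_stats")
}
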