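## Synthetic-data generators mirroring the statistical structure each
## analysis stage assumes: drift-correlated allele-frequency clines
## along a serial-founder chain, null marker columns for the inflation
## factor, two-locus genotype samples, 4C read counts under a
## distance-decay plus insulator-attenuation model, and noisy qPCR Ct
## replicates. Every generator is a pure function of (config, seed).

#' Simulate drift-correlated allele frequencies along a founder chain
#'
#' Populations sit on a serial-founder chain at given route positions
#' (km). On the arcsine scale the ancestral value
#' `x0 = asin(sqrt(p0))` accumulates independent Gaussian increments of
#' sd `drift_sd` at every colonization step, and a deterministic cline
#' `distance / beta_true` is added, so a Gaussian-ML regression of
#' distance on the transformed frequency has true slope `beta_true`.
#' Values are clipped to `[0, pi/2]` and back-transformed to
#' `p = sin(x)^2`. The implied squared genetic distance between
#' populations i and j is the drift variance accumulated on the path
#' between them, `|i - j| * drift_sd^2`. The true error structure of
#' the chain is the Brownian-sharing covariance kernel
#' `min(i, j)` (returned scaled by `1/n_pops` as `R_true`); note its
#' diagonal grows along the chain — the serial founder effect is
#' heteroskedastic, so the plain correlation matrix would discard part
#' of the structure. Pass `R_true` as the `R` of [gls_fit()] for an
#' exactly specified drift adjustment.
#'
#' Defaults state a Table-1-like world: 42 populations spanning 0 to
#' 28,000 km, African ancestral frequency 0.85, drift of 0.05 radians
#' per step, and a cline of 15,000 km per radian (the magnitude of the
#' published univariate slopes).
#'
#' @param n_pops Number of populations (>= 3).
#' @param distances Route positions in km, length `n_pops`.
#' @param beta_true True slope in km per radian; 0 means no cline (the
#'   null).
#' @param drift_sd Per-step drift sd on the arcsine scale (radians).
#' @param p0 Ancestral allele proportion.
#' @param n_markers Number of independent marker columns.
#' @param seed Integer seed (required).
#' @return List: `table` (a `population_table`), `D2` (implied
#'   `drift_distance_matrix`), `R_true` (true chain error covariance
#'   structure, up to scale), `truth` (list with the generating
#'   parameters).
#' @export
simulate_drift_frequencies <- function(n_pops = 42,
                                       distances = seq(0, 28000,
                                                       length.out = n_pops),
                                       beta_true = 15000, drift_sd = 0.05,
                                       p0 = 0.85, n_markers = 1, seed) {
  stopifnot(n_pops >= 3, length(distances) == n_pops, drift_sd >= 0,
            p0 >= 0, p0 <= 1)
  x0 <- arcsine_sqrt(p0)
  cline <- if (beta_true == 0) rep(0, n_pops) else distances / beta_true
  withr::with_seed(seed, {
    cols <- vapply(seq_len(n_markers), function(m) {
      drift <- cumsum(stats::rnorm(n_pops, 0, drift_sd))
      x <- x0 + drift + cline
      clipped <- sum(x < 0 | x > pi / 2)
      attr(x, "clipped") <- clipped
      sin(pmin(pi / 2, pmax(0, x)))^2
    }, numeric(n_pops))
  })
  colnames(cols) <- paste0("m", seq_len(n_markers))
  df <- data.frame(population = sprintf("pop%02d", seq_len(n_pops)),
                   distance_km = distances, check.names = FALSE)
  df <- cbind(df, as.data.frame(cols))
  idx <- seq_len(n_pops)
  D2 <- abs(outer(idx, idx, "-")) * drift_sd^2
  diag(D2) <- 0
  R_true <- outer(idx, idx, pmin) / n_pops
  dimnames(R_true) <- list(df$population, df$population)
  list(table = population_table(df),
       D2 = drift_distance_matrix(D2, df$population),
       R_true = R_true,
       truth = list(beta_true = beta_true, drift_sd = drift_sd, p0 = p0,
                    distances = distances))
}

#' Null marker columns for the inflation-factor correction
#'
#' Generates frequency columns carrying no distance effect, to stand in
#' for the random genome-wide SNPs used to calibrate the empirical
#' inflation factor. `method = "permute"` (default) permutes an
#' existing marker column across populations per draw — a valid null
#' under exchangeability with no nuisance parameters.
#' `method = "drift"` redraws chain-drift columns with `drift_sd` and
#' no cline.
#'
#' @param table A `population_table`.
#' @param n_markers Number of null columns (default 10000).
#' @param seed Integer seed (required).
#' @param method `"permute"` or `"drift"`.
#' @param drift_sd Per-step sd for `method = "drift"`.
#' @param p0 Ancestral proportion for `method = "drift"`.
#' @return Numeric matrix, `n_pops x n_markers`.
#' @export
simulate_null_markers <- function(table, n_markers = 10000, seed,
                                  method = c("permute", "drift"),
                                  drift_sd = 0.05, p0 = 0.85) {
  method <- match.arg(method)
  n <- nrow(table)
  stopifnot(n_markers >= 1)
  withr::with_seed(seed, {
    if (method == "permute") {
      mk <- markers(table)
      src <- sample(mk, n_markers, replace = TRUE)
      out <- vapply(src, function(m)
        sample(as.data.frame(table)[[m]]), numeric(n))
    } else {
      x0 <- arcsine_sqrt(p0)
      out <- vapply(seq_len(n_markers), function(j) {
        x <- x0 + cumsum(stats::rnorm(n, 0, drift_sd))
        sin(pmin(pi / 2, pmax(0, x)))^2
      }, numeric(n))
    }
  })
  colnames(out) <- paste0("null", seq_len(n_markers))
  out
}

#' Simulate unphased two-locus genotypes at given haplotype frequencies
#'
#' Subjects are unordered pairs of haplotypes drawn iid from the four
#' CNV x SNP haplotypes (Sin-C, Sin-T, Dup-C, Dup-T); phase is erased.
#'
#' @param h Haplotype frequencies, length 4, nonnegative, summing to 1
#'   (order Sin-C, Sin-T, Dup-C, Dup-T).
#' @param n_subjects Number of subjects (>= 1).
#' @param seed Integer seed (required).
#' @return A `genotype_table`.
#' @export
simulate_genotypes <- function(h, n_subjects, seed) {
  stopifnot(length(h) == 4L, all(h >= 0), n_subjects >= 1)
  if (abs(sum(h) - 1) > 1e-8) stop("haplotype frequencies must sum to 1")
  cnv_of <- c("Sin", "Sin", "Dup", "Dup")
  snp_of <- c("C", "T", "C", "T")
  withr::with_seed(seed, {
    hap1 <- sample.int(4L, n_subjects, replace = TRUE, prob = h)
    hap2 <- sample.int(4L, n_subjects, replace = TRUE, prob = h)
  })
  pair <- function(a, b, order) paste(c(a, b)[order(match(c(a, b), order))],
                                      collapse = "/")
  cnv <- vapply(seq_len(n_subjects), function(i)
    pair(cnv_of[hap1[i]], cnv_of[hap2[i]], CNV_ALLELES), character(1))
  snp <- vapply(seq_len(n_subjects), function(i)
    pair(snp_of[hap1[i]], snp_of[hap2[i]], SNP_ALLELES), character(1))
  genotype_table(data.frame(subject = sprintf("S%04d", seq_len(n_subjects)),
                            cnv = cnv, snp = snp))
}

#' Simulate a 4C experiment under distance decay with an insulator
#'
#' Builds a synthetic primary fragment map (realistic length mix,
#' including a share of blind and of sub-40 bp fragments so the filters
#' have work to do), then draws reads per sample: the expected weight of
#' a valid fragment end at coordinate `c` is proportional to
#' `(1 + |c - viewpoint|)^(-decay)`, multiplied by
#' `(1 - strength * dosage / 2)` for ends beyond the insulator (which
#' sits downstream of the viewpoint), and reads are a multinomial draw
#' over ends, placed uniformly within each end's half-fragment.
#'
#' @param n_fragments Number of primary fragments.
#' @param mean_fragment_bp Mean fragment length (default 200).
#' @param decay Decay exponent of contact weight with distance.
#' @param insulator_offset_bp Insulator position downstream of the
#'   viewpoint (default 25 kb).
#' @param insulator_strength Attenuation `s` in \[0, 1\].
#' @param reads_per_sample Reads drawn per sample.
#' @param dosages Dup-allele dosage (0/1/2) per sample.
#' @param blind_frac,short_frac Fractions of blind and short fragments.
#' @param seed Integer seed (required).
#' @return List: `fragments` (a `fragment_map`), `params` (a
#'   `fourc_params` with the viewpoint at the central fragment
#'   boundary), `reads` (list of integer position vectors, one per
#'   sample), `dosages`, `truth` (expected downstream fraction per
#'   sample from the noiseless weights).
#' @export
simulate_4c <- function(n_fragments = 2000, mean_fragment_bp = 200,
                        decay = 1, insulator_offset_bp = 25000,
                        insulator_strength = 0.5, reads_per_sample = 1e5,
                        dosages = c(0, 0, 1, 1, 2, 2),
                        blind_frac = 0.1, short_frac = 0.05, seed) {
  stopifnot(insulator_strength >= 0, insulator_strength <= 1,
            reads_per_sample > 0, all(dosages %in% 0:2))
  withr::with_seed(seed, {
    lens <- pmax(5L, stats::rpois(n_fragments, mean_fragment_bp))
    short_idx <- sample.int(n_fragments, round(short_frac * n_fragments))
    lens[short_idx] <- sample(5:39, length(short_idx), replace = TRUE)
    blind <- stats::runif(n_fragments) < blind_frac
    start <- cumsum(c(0L, lens[-n_fragments]))
    end <- start + lens
    seqlen <- end[n_fragments]
    fm <- fragment_map(data.frame(start = start, end = end, length_bp = lens,
                                  has_secondary = !blind),
                       seqname = "chrS", seqlen = seqlen)
    viewpoint <- fm$start[n_fragments %/% 2L]
    params <- fourc_params(viewpoint = viewpoint,
                           normalization_halfwidth_bp = seqlen)
    valid <- filter_fragments(fm, params)
    mid <- valid$start + valid$length_bp %/% 2L
    coord <- as.vector(rbind(valid$start, valid$end))
    half_lo <- as.vector(rbind(valid$start, mid))
    half_hi <- as.vector(rbind(mid, valid$end))
    insulator <- viewpoint + insulator_offset_bp
    base_w <- (1 + abs(coord - viewpoint))^(-decay)
    reads <- vector("list", length(dosages))
    truth <- numeric(length(dosages))
    for (s in seq_along(dosages)) {
      atten <- ifelse(coord > insulator,
                      1 - insulator_strength * dosages[s] / 2, 1)
      w <- base_w * atten
      truth[s] <- sum(w[coord > viewpoint]) /
        sum(w[coord != viewpoint])
      cnt <- stats::rmultinom(1L, reads_per_sample, w)[, 1L]
      pos <- unlist(lapply(which(cnt > 0), function(e)
        half_lo[e] + sample.int(max(1L, half_hi[e] - half_lo[e]), cnt[e],
                                replace = TRUE) - 1L))
      reads[[s]] <- as.integer(sort(pos))
    }
  })
  list(fragments = fm, params = params, reads = reads, dosages = dosages,
       truth = list(expected_downstream = truth, insulator = insulator,
                    strength = insulator_strength, decay = decay))
}

#' Simulate replicate qPCR Cts for an allelic contact assay
#'
#' `Ct_T = baseline + N(0, noise_sd)` per replicate;
#' `Ct_C = Ct_T + log2(true_ratio) + N(0, noise_sd)`, so the expected
#' measured ratio `2^(mean Ct_C - mean Ct_T)` is `true_ratio`.
#'
#' @param true_ratio True allelic template ratio (> 0).
#' @param noise_sd_cycles Replicate noise sd in cycles.
#' @param replicates Number of replicates per allele.
#' @param baseline Baseline Ct (default 25 cycles).
#' @param seed Integer seed (required).
#' @return List with numeric vectors `ct_c` and `ct_t`.
#' @export
simulate_ct <- function(true_ratio, noise_sd_cycles = 0.1, replicates = 3,
                        baseline = 25, seed) {
  stopifnot(true_ratio > 0, noise_sd_cycles >= 0, replicates >= 1)
  withr::with_seed(seed, {
    ct_t <- baseline + stats::rnorm(replicates, 0, noise_sd_cycles)
    ct_c <- ct_t + log2(true_ratio) + stats::rnorm(replicates, 0,
                                                   noise_sd_cycles)
  })
  list(ct_c = ct_c, ct_t = ct_t)
}
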