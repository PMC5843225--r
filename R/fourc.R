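## 4C-seq processing: in silico restriction digestion, fragment
## filtering, read-to-fragment-end assignment, running-mean smoothing,
## window normalization, and contact asymmetry around the viewpoint;
## plus the allele-specific 3C delta-Ct quantification and the rank
## tests used on both. Coordinates are 0-based half-open throughout.

#' Read the first sequence of a FASTA file
#' @param path FASTA file.
#' @return Uppercase character string of the first record.
#' @export
read_fasta_sequence <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("no sequences in ", path)
  toupper(as.character(ss[[1L]]))
}

#' In silico digestion into a primary-enzyme fragment map
#'
#' Cuts the sequence before every occurrence of the primary motif
#' (DpnII, `GATC`; blunt-cut convention: the fragment boundary sits at
#' the first base of the motif) and annotates each fragment with the
#' presence of an internal secondary-enzyme site (Csp6I, `GTAC`).
#' Fragments tile `[0, length)` without gaps or overlaps.
#'
#' @param sequence Character string over A/C/G/T/N (or a
#'   `Biostrings::DNAString`).
#' @param primary,secondary Non-degenerate recognition motifs.
#' @param seqname Sequence name carried into downstream BED-style output.
#' @return A `fragment_map`: data.frame with `start`, `end` (0-based
#'   half-open), `length_bp`, `has_secondary`; attributes `seqname`,
#'   `seqlen`.
#' @export
digest_fragments <- function(sequence, primary = "GATC", secondary = "GTAC",
                             seqname = "chrS") {
  if (!is.character(sequence)) sequence <- as.character(sequence)
  sequence <- toupper(sequence)
  len <- nchar(sequence)
  if (len == 0L) stop("empty sequence")
  dna <- Biostrings::DNAString(sequence)
  p_sites <- Biostrings::start(Biostrings::matchPattern(primary, dna)) - 1L
  s_sites <- Biostrings::start(Biostrings::matchPattern(secondary, dna)) - 1L
  bounds <- sort(unique(c(0L, p_sites, len)))
  start <- bounds[-length(bounds)]
  end <- bounds[-1L]
  s_end <- s_sites + nchar(secondary)
  has_secondary <- vapply(seq_along(start), function(i)
    any(s_sites >= start[i] & s_end <= end[i]), logical(1))
  fragment_map(data.frame(start = start, end = end,
                          length_bp = end - start,
                          has_secondary = has_secondary),
               seqname = seqname, seqlen = len)
}

#' Assemble a fragment map from cut-site positions
#'
#' Alternative to [digest_fragments()] when only the chromosome length
#' and enzyme-site coordinates are known (no sequence needed).
#'
#' @param seqlen Sequence length in bp.
#' @param primary_sites 0-based positions of primary-enzyme cut sites.
#' @param secondary_sites 0-based positions of secondary-enzyme sites
#'   (site width assumed 4 bp).
#' @param seqname Sequence name.
#' @return A `fragment_map`.
#' @export
fragment_map_from_sites <- function(seqlen, primary_sites, secondary_sites,
                                    seqname = "chrS") {
  bounds <- sort(unique(c(0L, as.integer(primary_sites), as.integer(seqlen))))
  start <- bounds[-length(bounds)]
  end <- bounds[-1L]
  s <- as.integer(secondary_sites); s_end <- s + 4L
  has_secondary <- vapply(seq_along(start), function(i)
    any(s >= start[i] & s_end <= end[i]), logical(1))
  fragment_map(data.frame(start = start, end = end, length_bp = end - start,
                          has_secondary = has_secondary),
               seqname = seqname, seqlen = as.integer(seqlen))
}

fragment_map <- function(df, seqname, seqlen) {
  stopifnot(all(df$end > df$start))
  structure(df, class = c("fragment_map", "data.frame"),
            seqname = seqname, seqlen = seqlen)
}

#' 4C processing parameters
#'
#' Defaults are the standard pipeline settings: fragments under 40 bp or
#' within 10 kb of the viewpoint are dropped, profiles are smoothed with
#' a 30-fragment running mean and normalized to the total signal within
#' +/- 2 Mb of the viewpoint.
#'
#' @param viewpoint 0-based coordinate of the viewpoint (bait).
#' @param min_fragment_bp Minimum fragment length retained (strict:
#'   `length >= min_fragment_bp`).
#' @param viewpoint_exclusion_bp Half-width of the exclusion zone.
#' @param smoothing_window_fragments Running-mean window, in fragment
#'   ends.
#' @param normalization_halfwidth_bp Half-width of the normalization
#'   window.
#' @return A `fourc_params` list.
#' @export
fourc_params <- function(viewpoint, min_fragment_bp = 40,
                         viewpoint_exclusion_bp = 10000,
                         smoothing_window_fragments = 30,
                         normalization_halfwidth_bp = 2e6) {
  stopifnot(viewpoint >= 0, min_fragment_bp > 0, viewpoint_exclusion_bp > 0,
            smoothing_window_fragments >= 1, normalization_halfwidth_bp > 0)
  structure(list(viewpoint = viewpoint, min_fragment_bp = min_fragment_bp,
                 viewpoint_exclusion_bp = viewpoint_exclusion_bp,
                 smoothing_window_fragments = smoothing_window_fragments,
                 normalization_halfwidth_bp = normalization_halfwidth_bp),
            class = "fourc_params")
}

#' Filter a fragment map to informative fragments
#'
#' Removes blind fragments (no internal secondary-enzyme site, i.e.
#' flanked by two sites of the same enzyme), fragments shorter than
#' `min_fragment_bp`, and fragments overlapping the closed interval
#' `[viewpoint - w, viewpoint + w]` with `w` the exclusion half-width.
#' Idempotent; may return an empty map with a warning.
#'
#' @param fm A `fragment_map`.
#' @param params A `fourc_params`.
#' @return The surviving subset, still a `fragment_map`, with a
#'   `filter_counts` attribute recording removals per rule.
#' @export
filter_fragments <- function(fm, params) {
  stopifnot(inherits(fm, "fragment_map"), inherits(params, "fourc_params"))
  vp <- params$viewpoint
  w <- params$viewpoint_exclusion_bp
  if (vp < 0 || vp >= attr(fm, "seqlen")) stop("viewpoint outside sequence")
  blind <- !fm$has_secondary
  short <- fm$length_bp < params$min_fragment_bp
  near_vp <- fm$start <= (vp + w) & fm$end > (vp - w)
  keep <- !(blind | short | near_vp)
  out <- fm[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) warning("no fragments survive filtering")
  attr(out, "seqname") <- attr(fm, "seqname")
  attr(out, "seqlen") <- attr(fm, "seqlen")
  attr(out, "filter_counts") <- c(blind = sum(blind), short = sum(short),
                                  near_viewpoint = sum(near_vp))
  class(out) <- class(fm)
  out
}

#' Import mapped read start positions from BED
#' @param path BED file of mapped reads.
#' @return Integer vector of 0-based read start positions.
#' @export
read_bed_starts <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  as.integer(GenomicRanges::start(gr)) - 1L
}

#' Write read start positions as BED
#' @param positions Integer vector of 0-based start positions.
#' @param path Output BED path.
#' @param seqname Sequence name.
#' @param read_length Read length in bp (default 1).
#' @return `path`, invisibly.
#' @export
write_reads_bed <- function(positions, path, seqname = "chrS",
                            read_length = 1L) {
  gr <- GenomicRanges::GRanges(seqname,
    IRanges::IRanges(start = as.integer(positions) + 1L,
                     width = read_length))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Convert mapped reads to per-fragment-end counts
#'
#' Each valid primary fragment contributes two ends; a read whose start
#' falls in the primary-site-proximal half of a fragment is counted on
#' that end (left half to the left end, right half to the right end,
#' split at the fragment midpoint). Reads falling outside the retained
#' fragments are discarded and counted.
#'
#' @param reads Integer vector of 0-based read start positions, or a BED
#'   path.
#' @param fm A (typically filtered) `fragment_map`.
#' @return A `contact_profile`: one row per fragment end, ordered by
#'   coordinate, with columns `fragment`, `side` (`L`/`R`), `coord` (the
#'   primary-site boundary of the end), `half_start`, `half_end`,
#'   `count`; attributes `assigned` and `discarded`.
#' @export
reads_to_profile <- function(reads, fm) {
  stopifnot(inherits(fm, "fragment_map"))
  if (is.character(reads)) reads <- read_bed_starts(reads)
  reads <- as.integer(reads)
  seqlen <- attr(fm, "seqlen")
  if (length(reads) && (min(reads) < 0L || max(reads) >= seqlen))
    stop("read position beyond sequence bounds")
  mid <- fm$start + fm$length_bp %/% 2L
  ends <- data.frame(
    fragment = rep(seq_len(nrow(fm)), each = 2L),
    side = rep(c("L", "R"), nrow(fm)),
    coord = as.vector(rbind(fm$start, fm$end)),
    half_start = as.vector(rbind(fm$start, mid)),
    half_end = as.vector(rbind(mid, fm$end)))
  ends <- ends[order(ends$coord, ends$fragment), , drop = FALSE]
  rownames(ends) <- NULL
  counts <- integer(nrow(ends))
  assigned <- 0L
  if (length(reads)) {
    idx <- findInterval(reads, fm$start)
    ok <- idx >= 1L & reads < fm$end[pmax(idx, 1L)]
    assigned <- sum(ok)
    r <- reads[ok]; fi <- idx[ok]
    is_right <- r >= mid[fi]
    end_key <- paste0(fi, ifelse(is_right, "R", "L"))
    tab <- table(end_key)
    pos <- match(names(tab), paste0(ends$fragment, ends$side))
    counts[pos] <- as.integer(tab)
  }
  ends$count <- counts
  structure(ends, class = c("contact_profile", "data.frame"),
            seqname = attr(fm, "seqname"), seqlen = seqlen,
            assigned = assigned, discarded = length(reads) - assigned)
}

#' Running-mean smoothing of a contact profile
#'
#' Centered running mean over the ordered fragment ends. For a window of
#' `w` ends, interior positions average over `ceiling((w-1)/2)` ends to
#' the left and `floor((w-1)/2)` to the right (a 30-end window is 15
#' left + self + 14 right). Near the edges the window shrinks
#' symmetrically to the available ends (no padding).
#'
#' @param profile A `contact_profile`.
#' @param window Window size in fragment ends (default 30).
#' @return The profile with a `smoothed` column added.
#' @export
smooth_profile <- function(profile, window = 30) {
  stopifnot(inherits(profile, "contact_profile"), window >= 1)
  x <- profile$count
  n <- length(x)
  l <- ceiling((window - 1) / 2)
  r <- window - 1 - l
  sm <- numeric(n)
  for (i in seq_len(n)) {
    if (i - l >= 1 && i + r <= n) {
      lo <- i - l; hi <- i + r
    } else {
      h <- min(i - 1, n - i)
      lo <- i - h; hi <- i + h
    }
    sm[i] <- mean(x[lo:hi])
  }
  profile$smoothed <- sm
  profile
}

#' Normalize a smoothed profile to the viewpoint window
#'
#' Divides every smoothed value by the total smoothed signal at ends
#' within `halfwidth` of the viewpoint, so in-window weights sum to 1.
#'
#' @param profile A smoothed `contact_profile`.
#' @param viewpoint Viewpoint coordinate.
#' @param halfwidth Window half-width in bp (default 2 Mb).
#' @return The profile with a `weight` column; attributes `viewpoint`
#'   and `halfwidth`.
#' @export
normalize_profile <- function(profile, viewpoint, halfwidth = 2e6) {
  stopifnot(inherits(profile, "contact_profile"))
  if (is.null(profile$smoothed)) stop("profile must be smoothed first")
  in_win <- abs(profile$coord - viewpoint) <= halfwidth
  total <- sum(profile$smoothed[in_win])
  if (total <= 0) stop("no signal within the normalization window")
  profile$weight <- profile$smoothed / total
  attr(profile, "viewpoint") <- viewpoint
  attr(profile, "halfwidth") <- halfwidth
  profile
}

#' Full 4C processing pipeline
#'
#' Filter the fragment map, assign reads to fragment ends, smooth, and
#' normalize, using one `fourc_params` object.
#'
#' @param fm A `fragment_map` (unfiltered).
#' @param reads Read start positions (or BED path).
#' @param params A `fourc_params`.
#' @return A normalized `contact_profile`.
#' @export
fourc_pipeline <- function(fm, reads, params) {
  valid <- filter_fragments(fm, params)
  p <- reads_to_profile(reads, valid)
  p <- smooth_profile(p, params$smoothing_window_fragments)
  normalize_profile(p, params$viewpoint, params$normalization_halfwidth_bp)
}

#' Export a profile track as bedGraph
#' @param profile A `contact_profile`.
#' @param path Output path.
#' @param value Which column to export: `count`, `smoothed` or `weight`.
#' @return `path`, invisibly.
#' @export
write_profile_bedgraph <- function(profile, path,
                                   value = c("weight", "smoothed", "count")) {
  value <- match.arg(value)
  if (is.null(profile[[value]])) stop("profile has no '", value, "' column")
  gr <- GenomicRanges::GRanges(attr(profile, "seqname"),
    IRanges::IRanges(start = profile$half_start + 1L, end = profile$half_end),
    score = profile[[value]])
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Upstream/downstream contact asymmetry around the viewpoint
#'
#' Fractions of the normalized in-window weight strictly upstream
#' (coordinate < viewpoint) and downstream (> viewpoint); the two
#' fractions sum to 1.
#'
#' @param profile A normalized `contact_profile`.
#' @param viewpoint Viewpoint coordinate (default: stored on the
#'   profile).
#' @param dosage Optional Dup-allele dosage (0/1/2) of the sample,
#'   carried along for [genotype_trend()].
#' @return List of class `asymmetry_result`: `fraction_upstream`,
#'   `fraction_downstream`, `dosage`.
#' @export
contact_asymmetry <- function(profile, viewpoint = attr(profile, "viewpoint"),
                              dosage = NA_real_) {
  stopifnot(inherits(profile, "contact_profile"))
  if (is.null(profile$weight)) stop("profile must be normalized first")
  if (is.null(viewpoint)) stop("viewpoint unknown")
  hw <- attr(profile, "halfwidth") %||% Inf
  in_win <- abs(profile$coord - viewpoint) <= hw
  up <- sum(profile$weight[in_win & profile$coord < viewpoint])
  down <- sum(profile$weight[in_win & profile$coord > viewpoint])
  if (up + down <= 0) stop("no in-window signal")
  structure(list(fraction_upstream = up / (up + down),
                 fraction_downstream = down / (up + down),
                 dosage = dosage),
            class = "asymmetry_result")
}

## --- rank statistics -------------------------------------------------------

# distinct permutations of a multiset (deterministic order)
.multiset_permutations <- function(x) {
  x <- sort(x)
  n <- length(x)
  out <- list()
  recurse <- function(prefix, rest) {
    if (length(rest) == 0L) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible(NULL))
    }
    for (v in unique(rest)) {
      i <- match(v, rest)
      recurse(c(prefix, v), rest[-i])
    }
  }
  recurse(numeric(0), x)
  out
}

.n_multiset_perms <- function(x) {
  tab <- table(x)
  exp(lgamma(length(x) + 1) - sum(lgamma(tab + 1)))
}

#' Spearman trend of contact asymmetry with CNV dosage
#'
#' Rank correlation (mid-rank ties) between the Dup-allele dosage and
#' the downstream contact fraction across samples. The p-value is an
#' exact permutation p (full enumeration of the distinct arrangements of
#' the dosage vector) for small samples, otherwise the t approximation.
#'
#' @param results List of `asymmetry_result`s with dosages, or a numeric
#'   vector of downstream fractions (then supply `dosages`).
#' @param dosages Dup dosages (0/1/2) when `results` is numeric.
#' @param exact_max_perms Enumerate exactly when the number of distinct
#'   dosage arrangements is at most this (default 1e5, which covers any
#'   design with n <= 10 and tied dosages; the canonical 2+2+2 design
#'   has 90).
#' @return List of class `trend_result`: `rho`, `p_value`, `method`,
#'   `n`.
#' @export
genotype_trend <- function(results, dosages = NULL, exact_max_perms = 1e5) {
  if (is.list(results) && !is.data.frame(results) &&
      all(vapply(results, inherits, logical(1), "asymmetry_result"))) {
    fractions <- vapply(results, `[[`, numeric(1), "fraction_downstream")
    dosages <- vapply(results, `[[`, numeric(1), "dosage")
  } else fractions <- as.numeric(results)
  n <- length(fractions)
  if (n < 3L) stop("need at least 3 samples")
  if (length(unique(dosages)) < 2L) stop("need at least 2 distinct dosages")
  if (stats::sd(fractions) == 0) stop("constant fractions: correlation undefined")
  rx <- rank(dosages); ry <- rank(fractions)
  rho <- stats::cor(rx, ry)
  if (n <= 10L && .n_multiset_perms(dosages) <= exact_max_perms) {
    perms <- .multiset_permutations(rx)
    rhos <- vapply(perms, function(p) stats::cor(p, ry), numeric(1))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1e-12, 1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
    method <- "t approximation"
  }
  structure(list(rho = rho, p_value = p, method = method, n = n),
            class = "trend_result")
}

#' Allelic contact ratio from qPCR Cts
#'
#' `delta Ct = mean(Ct of allele C) - mean(Ct of allele T)`; the allelic
#' template ratio is `2^(delta Ct)`. Equal Cts give a ratio of 1
#' (balanced contacts); the allele with the less efficient contact has
#' the higher Ct.
#'
#' @param ct_c,ct_t Replicate threshold cycles for alleles C and T.
#' @return List of class `allele_contact`: `delta_ct`, `ratio`,
#'   `n_replicates`.
#' @export
allele_ratio <- function(ct_c, ct_t) {
  if (length(ct_c) < 1L || length(ct_t) < 1L)
    stop("need at least one replicate per allele")
  stopifnot(all(ct_c > 0), all(ct_t > 0))
  dct <- mean(ct_c) - mean(ct_t)
  structure(list(delta_ct = dct, ratio = 2^dct,
                 n_replicates = c(C = length(ct_c), T = length(ct_t))),
            class = "allele_contact")
}

#' Allelic ratios for every sample/amplicon in a Ct table
#' @param records A `ct_records` data.frame.
#' @return Data.frame with one row per (sample, role): `delta_ct`,
#'   `ratio`.
#' @export
allele_ratios <- function(records) {
  stopifnot(inherits(records, "ct_records"))
  keys <- unique(records[, c("sample", "role")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- records[records$sample == keys$sample[i] &
                     records$role == keys$role[i], ]
    ar <- allele_ratio(sub$ct[sub$allele == "C"], sub$ct[sub$allele == "T"])
    data.frame(sample = keys$sample[i], role = keys$role[i],
               delta_ct = ar$delta_ct, ratio = ar$ratio)
  })
  do.call(rbind, out)
}

#' Mann-Whitney U test
#'
#' Two-sided comparison of two independent groups: exact enumeration
#' when the combined sample size is at most 12 and there are no ties,
#' otherwise the normal approximation with tie correction.
#'
#' @param group_a,group_b Numeric vectors.
#' @return List of class `mann_whitney`: `U` (for `group_a`),
#'   `p_value`, `method`.
#' @export
mann_whitney <- function(group_a, group_b) {
  if (length(group_a) == 0L || length(group_b) == 0L)
    stop("both groups must be nonempty")
  no_ties <- !anyDuplicated(c(group_a, group_b))
  use_exact <- (length(group_a) + length(group_b)) <= 12L && no_ties
  wt <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = use_exact,
                       correct = !use_exact))
  structure(list(U = unname(wt$statistic), p_value = wt$p.value,
                 method = if (use_exact) "exact" else
                   "normal approximation, tie-corrected"),
            class = "mann_whitney")
}
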