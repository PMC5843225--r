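test_that("digestion cuts before each primary site and flags blind fragments", {
  # no primary site: a single fragment spanning the sequence
  fm0 <- digest_fragments("AAAACCCCTTTT")
  expect_equal(nrow(fm0), 1L)
  expect_equal(c(fm0$start, fm0$end), c(0L, 12L))
  # 60-bp toy with GATC starting at 0-based 10 and 30
  s <- paste0(strrep("A", 10), "GATC", strrep("C", 16), "GATC",
              strrep("T", 26))
  fm <- digest_fragments(s)
  expect_equal(fm$start, c(0L, 10L, 30L))
  expect_equal(fm$end, c(10L, 30L, 60L))
  expect_equal(nchar(s), 60L)
  # GTAC annotation
  s2 <- paste0(strrep("A", 10), "GATC", "AAGTACAA", strrep("T", 10))
  fm2 <- digest_fragments(s2)
  expect_equal(fm2$has_secondary, c(FALSE, TRUE))
  expect_error(digest_fragments(""), "empty")
})

test_that("digestion equals a naive scan oracle and tiles the sequence", {
  withr::with_seed(31, {
    for (i in 1:50) {
      s <- random_dna(sample(50:400, 1))
      fm <- digest_fragments(s)
      oracle <- naive_digest(s)
      expect_equal(fm$start, oracle$start)
      expect_equal(fm$end, oracle$end)
      expect_equal(fm$has_secondary, oracle$has_secondary)
      # tiling: no gaps, no overlaps, lengths sum to sequence length
      expect_equal(fm$start[-1], fm$end[-nrow(fm)])
      expect_equal(sum(fm$length_bp), nchar(s))
    }
  })
})

test_that("fragment filtering enforces all three rules at their boundaries", {
  # hand-built map: viewpoint at 50000
  mk <- function(start, end, sec) data.frame(start = start, end = end,
                                             length_bp = end - start,
                                             has_secondary = sec)
  vp <- 50000L
  frags <- rbind(
    mk(0L, 39L, TRUE),            # 39 bp -> removed (short)
    mk(39L, 79L, TRUE),           # 40 bp -> retained
    mk(79L, 30000L, FALSE),       # blind -> removed
    mk(30000L, 40001L, TRUE),     # ends 9999 bp before vp -> removed
    mk(40001L, 60001L, TRUE),     # overlaps the viewpoint zone -> removed
    mk(60001L, 70000L, TRUE),     # starts 10001 bp after vp -> retained
    mk(70000L, 80000L, TRUE))
  fm <- structure(frags, class = c("fragment_map", "data.frame"),
                  seqname = "chrS", seqlen = 80000L)
  params <- fourc_params(viewpoint = vp)
  kept <- filter_fragments(fm, params)
  expect_equal(kept$start, c(39L, 60001L, 70000L))
  # every survivor satisfies all predicates (checked exhaustively)
  expect_true(all(kept$has_secondary))
  expect_true(all(kept$length_bp >= 40))
  expect_true(all(kept$end <= vp - 10000 | kept$start > vp + 10000))
  # idempotence
  again <- filter_fragments(kept, params)
  expect_equal(as.data.frame(again), as.data.frame(kept),
               ignore_attr = TRUE)
  # the 10,001-bp-away fragment on the left is retained too
  fm2 <- structure(mk(vp - 10000L - 5000L, vp - 10001L + 1L, TRUE),
                   class = c("fragment_map", "data.frame"),
                   seqname = "chrS", seqlen = 80000L)
  expect_equal(nrow(filter_fragments(fm2, params)), 1L)
})

test_that("reads map to the primary-site-proximal fragment end and conserve", {
  s <- paste0(strrep("A", 50), "GATC", strrep("C", 92), "GTAC",
              strrep("G", 50))  # fragments [0,50) and [50,200)
  fm <- digest_fragments(s)
  expect_equal(fm$end, c(50L, 200L))
  prof0 <- reads_to_profile(integer(0), fm)
  expect_true(all(prof0$count == 0))
  # one read at the second fragment's first base -> its left end
  prof1 <- reads_to_profile(50L, fm)
  expect_equal(prof1$count[prof1$fragment == 2 & prof1$side == "L"], 1L)
  expect_equal(sum(prof1$count), 1L)
  # right half -> right end
  prof2 <- reads_to_profile(c(130L, 199L), fm)
  expect_equal(prof2$count[prof2$fragment == 2 & prof2$side == "R"], 2L)
  expect_error(reads_to_profile(200L, fm), "beyond sequence bounds")
  # conservation against a filtered (gappy) map
  params <- fourc_params(viewpoint = 10L, viewpoint_exclusion_bp = 30L,
                         min_fragment_bp = 10L)
  kept <- filter_fragments(fm, params)  # drops fragment 1 (near viewpoint)
  withr::with_seed(5, reads <- sample(0:199, 300, replace = TRUE))
  prof <- reads_to_profile(reads, kept)
  expect_equal(sum(prof$count) + attr(prof, "discarded"), 300L)
  expect_equal(attr(prof, "assigned"), sum(prof$count))
})

test_that("running-mean smoothing has the stated window and edge behavior", {
  fm <- digest_fragments(paste(rep("GATCAACCGGTTGTACAACCGGTTAACCGGTTAACCGGTA",
                                   40), collapse = ""))
  prof <- reads_to_profile(integer(0), fm)
  n <- nrow(prof)
  # constant signal stays constant
  prof$count <- rep(3L, n)
  expect_equal(smooth_profile(prof, 30)$smoothed, rep(3, n))
  # window 1 is the identity
  withr::with_seed(8, prof$count <- rpois(n, 5))
  expect_equal(smooth_profile(prof, 1)$smoothed, as.numeric(prof$count))
  # interior unit impulse spreads to exactly 30 positions at 1/30
  prof$count <- integer(n)
  center <- n %/% 2
  prof$count[center] <- 1L
  sm <- smooth_profile(prof, 30)$smoothed
  expect_equal(sum(sm > 0), 30L)
  expect_equal(unique(sm[sm > 0]), 1 / 30, tolerance = 1e-12)
})

test_that("normalization fixes unit mass in the viewpoint window", {
  sim <- simulate_4c(n_fragments = 400, reads_per_sample = 5000,
                     dosages = 0, seed = 77)
  valid <- filter_fragments(sim$fragments, sim$params)
  prof <- smooth_profile(reads_to_profile(sim$reads[[1]], valid), 30)
  norm <- normalize_profile(prof, sim$params$viewpoint,
                            sim$params$normalization_halfwidth_bp)
  in_win <- abs(norm$coord - sim$params$viewpoint) <=
    sim$params$normalization_halfwidth_bp
  expect_equal(sum(norm$weight[in_win]), 1, tolerance = 1e-9)
  # doubling raw counts leaves weights unchanged
  prof2 <- prof
  prof2$count <- prof2$count * 2L
  prof2 <- smooth_profile(prof2, 30)
  norm2 <- normalize_profile(prof2, sim$params$viewpoint,
                             sim$params$normalization_halfwidth_bp)
  expect_equal(norm2$weight, norm$weight, tolerance = 1e-12)
  # zero in-window total errors
  prof0 <- prof
  prof0$count[] <- 0L
  prof0 <- smooth_profile(prof0, 30)
  expect_error(normalize_profile(prof0, sim$params$viewpoint), "no signal")
})

test_that("contact asymmetry reports upstream/downstream weight fractions", {
  # mirror-symmetric synthetic profile around a viewpoint
  mkprof <- function(coords, weights) {
    structure(data.frame(fragment = seq_along(coords), side = "L",
                         coord = coords, half_start = coords,
                         half_end = coords + 1, count = 1L,
                         smoothed = weights, weight = weights),
              class = c("contact_profile", "data.frame"),
              seqname = "chrS", seqlen = max(coords) + 10,
              viewpoint = 0, halfwidth = Inf)
  }
  sym <- mkprof(c(-30, -20, -10, 10, 20, 30), c(0.3, 0.1, 0.1, 0.1, 0.1, 0.3))
  a <- contact_asymmetry(sym)
  expect_equal(a$fraction_downstream, 0.5)
  expect_equal(a$fraction_upstream + a$fraction_downstream, 1)
  up_only <- mkprof(c(-30, -20, -10), c(0.5, 0.3, 0.2))
  expect_equal(contact_asymmetry(up_only)$fraction_downstream, 0)
})

test_that("dosage trend p-value matches full permutation enumeration", {
  dos <- c(0, 0, 1, 1, 2, 2)
  frac <- c(0.47, 0.46, 0.40, 0.39, 0.35, 0.34)  # strictly decreasing
  tr <- genotype_trend(frac, dos)
  expect_lt(tr$rho, 0)
  expect_equal(tr$method, "exact permutation")
  # oracle: all 720 permutations of the dosage vector
  perms <- all_permutations(rank(dos))
  ry <- rank(frac)
  rhos <- vapply(perms, function(p) stats::cor(p, ry), numeric(1))
  expect_equal(tr$p_value, mean(abs(rhos) >= abs(tr$rho) - 1e-12),
               tolerance = 1e-12)
  # dosage-independent shuffle: no signal
  withr::with_seed(12, frac_null <- sample(frac))
  trn <- genotype_trend(frac_null, dos)
  expect_gt(trn$p_value, 0.05)
  expect_error(genotype_trend(c(0.4, 0.6), c(0, 2)), "at least 3")
  expect_error(genotype_trend(c(0.4, 0.5, 0.6), c(1, 1, 1)), "distinct")
  expect_error(genotype_trend(rep(0.5, 4), c(0, 1, 1, 2)), "constant")
})

test_that("allelic Ct ratio is 2^(delta Ct)", {
  even <- allele_ratio(c(25, 25.2), c(25.1, 25.1))
  expect_equal(even$ratio, 2^(25.1 - 25.1), tolerance = 1e-12)
  expect_equal(allele_ratio(26, 25)$ratio, 2)
  expect_equal(allele_ratio(23, 25)$ratio, 0.25)
  expect_error(allele_ratio(numeric(0), 25), "at least one")
  rec <- ct_records(data.frame(
    sample = "d1", role = rep(c("control", "sensor"), each = 2),
    allele = rep(c("C", "T"), 2), ct = c(25, 25, 27, 25)))
  tab <- allele_ratios(rec)
  expect_equal(tab$ratio[tab$role == "control"], 1)
  expect_equal(tab$ratio[tab$role == "sensor"], 4)
})

test_that("Mann-Whitney U uses exact enumeration for small tie-free samples", {
  r <- mann_whitney(c(1, 2, 3), c(10, 11, 12))
  expect_equal(unname(r$U), 0)
  expect_equal(r$p_value, 2 / choose(6, 3), tolerance = 1e-12)  # 0.1
  expect_equal(r$method, "exact")
  same <- mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gte(same$p_value, 0.99)
  # invariance under a strictly monotone transform
  a <- c(0.2, 1.5, 3.1, 4.4); b <- c(0.9, 2.2, 5.0)
  expect_equal(mann_whitney(exp(a), exp(b))$p_value,
               mann_whitney(a, b)$p_value, tolerance = 1e-12)
  expect_error(mann_whitney(numeric(0), 1), "nonempty")
})

test_that("profiles and reads survive BED round trips", {
  path <- withr::local_tempfile(fileext = ".bed")
  pos <- c(10L, 25L, 25L, 400L)
  write_reads_bed(pos, path, seqname = "chrS")
  expect_equal(sort(read_bed_starts(path)), sort(pos))
  sim <- simulate_4c(n_fragments = 400, reads_per_sample = 2000, dosages = 0,
                     seed = 3)
  prof <- fourc_pipeline(sim$fragments, sim$reads[[1]], sim$params)
  bg <- withr::local_tempfile(fileext = ".bedGraph")
  write_profile_bedgraph(prof, bg, "weight")
  expect_gt(length(readLines(bg)), 10)
})
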