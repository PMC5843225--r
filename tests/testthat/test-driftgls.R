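test_that("arcsine-square-root transform maps [0,1] to [0, pi/2]", {
  expect_equal(arcsine_sqrt(0), 0)
  expect_equal(arcsine_sqrt(1), pi / 2)
  expect_equal(arcsine_sqrt(0.5), pi / 4)
  expect_error(arcsine_sqrt(1.01), "\\[0, 1\\]")
  # complement identity used for allele reorientation: affine flip
  p <- seq(0.05, 0.95, by = 0.1)
  expect_equal(arcsine_sqrt(1 - p), pi / 2 - arcsine_sqrt(p))
})

test_that("drift pseudo-correlation implements (max - D2)/max", {
  D2 <- matrix(c(0, 1, 4, 1, 0, 2, 4, 2, 0), 3)
  R <- drift_to_correlation(drift_distance_matrix(D2, letters[1:3]))
  expect_equal(unclass(R),
               matrix(c(1, 0.75, 0, 0.75, 1, 0.5, 0, 0.5, 1), 3,
                      dimnames = list(letters[1:3], letters[1:3])),
               ignore_attr = TRUE)
  expect_error(drift_to_correlation(drift_distance_matrix(matrix(0, 3, 3))),
               "degenerate")
  # properties on random distance matrices
  withr::with_seed(11, {
    for (i in 1:10) {
      n <- sample(3:8, 1)
      A <- matrix(runif(n * n, 0, 5), n)
      D <- A + t(A); diag(D) <- 0
      R <- drift_to_correlation(drift_distance_matrix(D))
      expect_equal(unclass(R), t(unclass(R)))
      expect_true(all(diag(R) == 1))
      expect_true(all(R >= -1e-12 & R <= 1 + 1e-12))
      if (attr(R, "ridge") == 0)
        expect_true(all(abs(unclass(R)[D == max(D)]) < 1e-12))
    }
  })
})

test_that("design matrices carry transformed mains and product interactions", {
  tab <- table1_fixture()
  d <- build_design(tab, "rs2209313")
  expect_equal(dim(d$X), c(43L, 2L))
  expect_equal(d$X[, 2], arcsine_sqrt(tab$rs2209313))
  # product column equals brute-force row-wise multiplication
  sp <- model_spec(c("rs2209313", "rs6074896"),
                   list(c("rs2209313", "rs6074896")))
  d2 <- build_design(tab, sp)
  brute <- vapply(seq_len(43), function(i)
    asin(sqrt(tab$rs2209313[i])) * asin(sqrt(tab$rs6074896[i])), numeric(1))
  expect_equal(unname(d2$X[, "rs2209313:rs6074896"]), brute)
  # a marker fixed at 1 yields a zero-variance column
  bad <- population_table(data.frame(population = letters[1:5],
                                     distance_km = 1:5 * 100,
                                     fixed = rep(1, 5),
                                     ok = seq(0.2, 0.6, by = 0.1)))
  expect_error(build_design(bad, "fixed"), "zero-variance.*fixed")
  # interaction with an all-ones marker collapses onto the main effect
  sp_coll <- model_spec("ok", list(c("ok", "fixed")))
  d3 <- build_design(bad, sp_coll)
  expect_equal(unname(d3$X[, "fixed:ok"]),
               unname(d3$X[, "ok"]) * asin(sqrt(1)))
  expect_error(gls_fit(d3$X, d3$y), "collinear")
})

test_that("identity-correlation ML fit reduces to closed-form OLS", {
  tab <- table1_fixture()
  for (m in c("rs2209313", "rs6074896")) {
    d <- build_design(tab, m)
    f <- gls_fit(d$X, d$y)
    ols <- solve(crossprod(d$X), crossprod(d$X, d$y))
    expect_equal(unname(f$coefficients), unname(drop(ols)), tolerance = 1e-8)
    lmf <- stats::lm(d$y ~ d$X[, 2])
    expect_equal(unname(f$coefficients), unname(coef(lmf)), tolerance = 1e-8)
    # ML sigma2 uses the n denominator
    expect_equal(f$sigma2, sum(resid(lmf)^2) / f$n, tolerance = 1e-10)
    expect_equal(f$aic, -2 * f$loglik + 2 * (f$k + 1))
  }
})

test_that("GLS with non-identity correlation matches a numeric ML oracle", {
  withr::with_seed(3, {
    X <- cbind(1, c(0.2, 0.5, 0.9, 1.3))
    y <- c(1000, 4000, 9000, 14000) + rnorm(4, 0, 500)
  })
  R <- outer(1:4, 1:4, function(i, j) pmin(i, j) / sqrt(i * j))
  f <- gls_fit(X, y, R)
  oracle <- gls_optim_oracle(X, y, R)
  expect_equal(unname(f$coefficients), oracle$beta, tolerance = 1e-6)
  expect_equal(f$sigma2, oracle$sigma2, tolerance = 1e-5)
  expect_equal(f$loglik, oracle$loglik, tolerance = 1e-8)
  # and the direct-likelihood formula agrees at the fitted point
  expect_equal(f$loglik,
               gls_loglik_direct(f$coefficients, f$sigma2, X, y, R),
               tolerance = 1e-10)
})

test_that("fitted (beta, sigma2) is a local likelihood maximum", {
  tab <- table1_fixture()
  d <- build_design(tab, "rs2209313")
  n <- length(d$y)
  R <- diag(n)
  f <- gls_fit(d$X, d$y)
  withr::with_seed(17, {
    for (i in 1:100) {
      db <- rnorm(2) * c(1000, 2000)
      ds <- rnorm(1, 0, 0.3)
      ll <- gls_loglik_direct(f$coefficients + db, f$sigma2 * exp(ds),
                              d$X, d$y, R)
      expect_lte(ll, f$loglik + 1e-9)
    }
  })
})

test_that("degenerate and ill-posed designs are rejected", {
  X <- cbind(1, 1:6)
  expect_error(gls_fit(X, rep(5000, 6)), "degenerate")
  expect_error(gls_fit(cbind(1, 1:6, 2 * (1:6)), c(1, 3, 2, 5, 4, 6)),
               "collinear")
  expect_error(gls_fit(cbind(1, 1:3), c(1, 2, 3) * 1.0,
                       R = matrix(1, 3, 3)), "positive definite")
})

test_that("model enumeration matches independent combinatorial counts", {
  expect_length(enumerate_models("A", 2), 1L)
  m2 <- enumerate_models(c("A", "B"), 2)
  expect_length(m2, 4L)
  expect_setequal(vapply(m2, format, character(1)),
                  c("A", "B", "A + B", "A + B + A:B"))
  # 4 markers, order 2: sum over main subsets s of C(4,s) * 2^C(s,2)
  count4 <- sum(vapply(1:4, function(s)
    choose(4, s) * 2^choose(s, 2), numeric(1)))
  expect_length(enumerate_models(c("A", "B", "C", "D"), 2), count4)
  # 3 markers, order 3
  count3 <- sum(vapply(1:3, function(s)
    choose(3, s) * 2^(choose(s, 2) + choose(s, 3)), numeric(1)))
  expect_length(enumerate_models(c("A", "B", "C"), 3), count3)
  # non-hierarchical: any non-empty subset of the term universe
  free2 <- enumerate_models(c("A", "B"), 2, require_mains = FALSE)
  expect_length(free2, 2^3 - 1)
  has_orphan <- any(vapply(free2, function(s)
    length(s$mains) == 0 && length(s$interactions) == 1, logical(1)))
  expect_true(has_orphan)
})

test_that("AIC selection breaks ties toward fewer parameters", {
  mk <- function(aic, k) structure(list(aic = aic, k = k, id = paste(aic, k)),
                                   class = "gls_fit")
  expect_error(select_best_aic(list()), "no fits")
  single <- mk(10, 2)
  expect_identical(select_best_aic(list(single)), single)
  a <- mk(10, 3); b <- mk(10, 2)
  expect_identical(select_best_aic(list(a, b)), b)
  # equal AIC and k: first in enumeration order wins
  c1 <- mk(10, 2); c2 <- mk(10, 2)
  expect_identical(select_best_aic(list(c1, c2)), c1)
})

test_that("inflation factor and p-value correction follow their definitions", {
  expect_equal(inflation_factor(c(0.2, 0.5, 0.9)), 0)
  expect_equal(inflation_factor(rep(0.01, 50)), 20)
  expect_error(inflation_factor(numeric(0)), "at least one")
  expect_error(inflation_factor(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_equal(correct_pvalues(c(0.1, 0.4), 1), c(0.1, 0.4))
  expect_equal(correct_pvalues(0.6, 2), 1)
  expect_equal(correct_pvalues(0.01, 2.5), 0.025)
})

test_that("univariate scan reproduces the published slope signs", {
  tab <- table1_fixture()
  four <- c("rs1535882", "rs2209313", "rs4814391", "rs6074896")
  slopes <- vapply(four, function(m)
    unname(fit_cline_model(tab, m,
                           complement = "rs1535882")$coefficients[2]),
    numeric(1))
  expect_equal(sign(slopes), c(rs1535882 = 1, rs2209313 = -1,
                               rs4814391 = 1, rs6074896 = 1))
})

test_that("a one-marker scan reduces to the single GLS fit", {
  tab <- table1_fixture()
  sc <- ooa_scan(tab, "rs2209313")
  f <- fit_cline_model(tab, "rs2209313")
  expect_equal(nrow(sc$models), 1L)
  expect_equal(sc$models$aic, f$aic)
  expect_equal(sc$coefficients$beta[2], unname(f$coefficients[2]))
  expect_true(is.na(sc$inflation))
})

test_that("AIC ranking is invariant under km-to-m rescaling of distances", {
  tab <- table1_fixture()
  specs <- enumerate_models(c("rs2209313", "rs6074896"), 2)
  fits_km <- lapply(specs, function(s) fit_cline_model(tab, s))
  df <- as.data.frame(tab)
  df$distance_km <- df$distance_km * 1000
  tab_m <- population_table(df)
  fits_m <- lapply(specs, function(s) fit_cline_model(tab_m, s))
  aic_km <- vapply(fits_km, `[[`, numeric(1), "aic")
  aic_m <- vapply(fits_m, `[[`, numeric(1), "aic")
  n <- nrow(tab)
  shift <- aic_m - aic_km
  expect_equal(shift, rep(2 * n * log(1000), length(shift)), tolerance = 1e-6)
  expect_equal(order(aic_km), order(aic_m))
})

test_that("the AIC search recovers a generating interaction term", {
  hits <- 0L
  for (r in 1:100) {
    withr::with_seed(200 + r, {
      n <- 42
      p1 <- runif(n, 0.3, 0.95); p2 <- runif(n, 0.3, 0.95)
      y <- 50000 * asin(sqrt(p1)) * asin(sqrt(p2)) + rnorm(n, 0, 2000)
    })
    tb <- population_table(data.frame(population = paste0("p", 1:n),
                                      distance_km = pmax(0, y),
                                      A = p1, B = p2))
    fits <- lapply(enumerate_models(c("A", "B"), 2),
                   function(sp) fit_cline_model(tb, sp))
    best <- select_best_aic(fits)
    if (length(best$spec$interactions) == 1L) hits <- hits + 1L
  }
  expect_gte(hits, 90L)
})

test_that("drift-adjusted scan with drift-process nulls keeps corrected type I near nominal", {
  # null world: shared-drift frequencies, no cline; the scan mirrors the
  # published final analysis (drift-adjusted fits + genomic-null factor)
  cnt <- 0L; tot <- 0L
  for (r in 1:30) {
    s <- simulate_drift_frequencies(n_pops = 42, beta_true = 0,
                                    drift_sd = 0.05, n_markers = 2,
                                    seed = 9000 + r)
    sc <- ooa_scan(s$table, c("m1", "m2"), R = s$R_true, max_order = 2,
                   null_generator = function(t, nn, seed)
                     simulate_null_markers(t, nn, seed, method = "drift"),
                   n_null = 200, seed = 100 + r)
    pc <- sc$coefficients$p_corrected[sc$coefficients$term != "(Intercept)"]
    cnt <- cnt + sum(pc < 0.05); tot <- tot + length(pc)
  }
  expect_lte(cnt / tot, 0.07)
})
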