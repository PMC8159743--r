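# Residual-regression causal inference, Holm-Bonferroni, AIC/BIC
# direction comparison.

# generative helpers ---------------------------------------------------------

# locus -> t2 -> t1 mediation chain (t2 upstream), plus sex/diet structure
sim_mediation <- function(n, a = 1, lambda = 0.7, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- draw_f2_locus(n)
  sex <- sample(c("F", "M"), n, TRUE)
  diet <- sample(c("american", "ketogenic"), n, TRUE)
  t2 <- a * (g - 1) + 0.5 * (sex == "M") + rnorm(n)
  t1 <- lambda * t2 + 0.3 * (diet == "ketogenic") + rnorm(n)
  list(pheno = make_pheno(n, sex = sex, diet = diet, t1 = t1, t2 = t2),
       geno = make_geno(matrix(g, ncol = 1), single_chrom_map(1, 10)))
}

# locus with direct, independent effects on both traits
sim_independent <- function(n, a1 = 0.8, a2 = 0.8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- draw_f2_locus(n)
  sex <- sample(c("F", "M"), n, TRUE)
  diet <- sample(c("american", "ketogenic"), n, TRUE)
  t1 <- a1 * (g - 1) + rnorm(n)
  t2 <- a2 * (g - 1) + rnorm(n)
  list(pheno = make_pheno(n, sex = sex, diet = diet, t1 = t1, t2 = t2),
       geno = make_geno(matrix(g, ncol = 1), single_chrom_map(1, 10)))
}

locus1 <- function(sim) sim$geno$map$marker[1]

# ----------------------------------------------------------------------------

test_that("residualization matches the closed-form oracle", {
  # hand-solvable 5-point regression (no covariate structure: single sex,
  # single diet collapse the design to target ~ adjuster)
  ph <- make_pheno(10, sex = rep("F", 10), diet = rep("american", 10),
                   t1 = c(1, 2, 3, 4, 6, 5, 7, 8, 9, 11),
                   t2 = c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9))
  r <- residualize(ph, "t1", "t2", include_interaction = FALSE)
  X <- cbind(1, ph$t2)
  beta <- solve(crossprod(X), crossprod(X, ph$t1))
  expect_equal(r, as.numeric(ph$t1 - X %*% beta), tolerance = 1e-12)
  expect_equal(mean(r), 0, tolerance = 1e-12)

  # target == adjuster -> zero residuals; orthogonal -> variance kept
  set.seed(81)
  n <- 500
  ph2 <- make_pheno(n, t1 = rnorm(n), t2 = rnorm(n))
  ph2$t3 <- ph2$t1
  expect_lt(max(abs(residualize(ph2, "t1", "t3"))), 1e-10)
  rv <- residualize(ph2, "t1", "t2")
  expect_equal(var(rv, na.rm = TRUE), var(ph2$t1), tolerance = 0.05)

  ph2$tc <- 1
  expect_error(residualize(ph2, "t1", "tc"), "constant")
})

test_that("Holm-Bonferroni reproduces the step-down procedure", {
  h <- holm_bonferroni(c(0.0046, 0.0252))
  expect_equal(h$threshold, c(0.025, 0.05))
  expect_true(all(h$reject))

  h2 <- holm_bonferroni(c(0.03, 0.04))
  expect_equal(h2$threshold, c(0.025, 0.05))
  expect_false(any(h2$reject))  # step-down stops at the first failure

  h3 <- holm_bonferroni(0.049)
  expect_true(h3$reject)

  expect_equal(nrow(holm_bonferroni(numeric())), 0)

  # flags come back in input order
  h4 <- holm_bonferroni(c(0.9, 0.001, 0.04))
  expect_equal(h4$rank, c(3L, 1L, 2L))
})

test_that("Holm rejections nest between Bonferroni and unadjusted", {
  set.seed(82)
  for (r in 1:50) {
    m <- sample(2:8, 1)
    p <- runif(m)^sample(1:3, 1)
    holm <- holm_bonferroni(p, 0.05)$reject
    bonf <- p <= 0.05 / m
    raw <- p <= 0.05
    expect_true(all(holm[bonf]))   # Holm rejects everything Bonferroni does
    expect_true(all(raw[holm]))    # and nothing the unadjusted test retains
  }
})

test_that("mediation chains and shared-locus pleiotropy are classified", {
  cls_med <- vapply(1:200, function(r) {
    sim <- sim_mediation(469, seed = 2000 + r)
    causal_network_inference(sim$pheno, sim$geno, "t1", "t2",
                             locus1(sim))$classification
  }, character(1))
  expect_gte(mean(cls_med == "T2_upstream"), 0.9)

  cls_ind <- vapply(1:200, function(r) {
    sim <- sim_independent(469, seed = 2300 + r)
    causal_network_inference(sim$pheno, sim$geno, "t1", "t2",
                             locus1(sim))$classification
  }, character(1))
  expect_gte(mean(cls_ind == "independent"), 0.8)
})

test_that("a null locus is classified undetermined at the nominal rate", {
  cls <- vapply(1:200, function(r) {
    sim <- sim_independent(300, a1 = 0, a2 = 0, seed = 2600 + r)
    causal_network_inference(sim$pheno, sim$geno, "t1", "t2",
                             locus1(sim))$classification
  }, character(1))
  # expected rate (1 - alpha)^2 = 0.9025; binomial 99.9% band at n = 200
  expect_gt(mean(cls == "undetermined"), 0.83)
})

test_that("swapping the traits swaps residual p-values and classification", {
  sim <- sim_mediation(469, seed = 83)
  a <- causal_network_inference(sim$pheno, sim$geno, "t1", "t2", locus1(sim))
  b <- causal_network_inference(sim$pheno, sim$geno, "t2", "t1", locus1(sim))
  expect_equal(a$p_r1, b$p_r2, tolerance = 1e-12)
  expect_equal(a$p_r2, b$p_r1, tolerance = 1e-12)
  swap <- c(T1_upstream = "T2_upstream", T2_upstream = "T1_upstream",
            independent = "independent", undetermined = "undetermined")
  expect_equal(unname(swap[a$classification]), b$classification)
})

test_that("joint AIC/BIC prefer the true causal direction under mediation", {
  pref <- vapply(1:200, function(r) {
    sim <- sim_mediation(469, seed = 2900 + r)
    ms <- compare_causal_models(sim$pheno, sim$geno, "t1", "t2",
                                locus1(sim), method = "joint")
    ms$model[ms$preferred_aic]
  }, character(1))
  expect_gte(mean(pref == "t2 -> t1"), 0.8)
})

test_that("single-regression AIC tracks the response with smaller residual scale", {
  # with equal noise scales the anti-causal regression has the higher R^2,
  # so the directed-regression comparison resolves by response scale; on
  # trait pairs with very different units (serum vs mass) the small-scale
  # response wins, which is why the joint factorization exists
  sim <- sim_mediation(469, seed = 85)
  ph <- sim$pheno
  ph$t2 <- ph$t2 * 50          # serum-like units for the upstream trait
  ms <- compare_causal_models(ph, sim$geno, "t1", "t2", locus1(sim))
  expect_equal(ms$model[ms$preferred_aic], "t2 -> t1")
  expect_equal(ms$model[ms$preferred_bic], "t2 -> t1")
})

test_that("symmetric traits give no systematic direction preference", {
  pref <- vapply(1:200, function(r) {
    set.seed(3200 + r)
    n <- 200
    g <- draw_f2_locus(n)
    z <- rnorm(n)
    ph <- make_pheno(n, t1 = z + rnorm(n), t2 = z + rnorm(n))
    geno <- make_geno(matrix(g, ncol = 1), single_chrom_map(1, 10))
    ms <- compare_causal_models(ph, geno, "t1", "t2", geno$map$marker[1],
                                standardize = TRUE)
    ms$model[ms$preferred_aic]
  }, character(1))
  expect_gt(mean(pref == "t2 -> t1"), 0.35)
  expect_lt(mean(pref == "t2 -> t1"), 0.65)
})

test_that("BIC - AIC equals k (ln n - 2) and scores match their formulas", {
  sim <- sim_mediation(300, seed = 84)
  ms <- compare_causal_models(sim$pheno, sim$geno, "t1", "t2", locus1(sim))
  expect_equal(ms$bic - ms$aic, ms$k * (log(ms$n) - 2), tolerance = 1e-10)
  expect_equal(ms$aic, ms$n * log(ms$rss / ms$n) + 2 * ms$k,
               tolerance = 1e-10)
})

test_that("direction recovery increases with the mediation strength", {
  rate <- vapply(c(0, 0.25, 0.5, 1.0), function(lam) {
    hits <- vapply(1:200, function(r) {
      sim <- sim_mediation(300, a = 1, lambda = lam,
                           seed = 3500 + r + round(1e4 * lam))
      causal_network_inference(sim$pheno, sim$geno, "t1", "t2",
                               locus1(sim))$classification == "T2_upstream"
    }, logical(1))
    mean(hits)
  }, numeric(1))
  # allow small Monte-Carlo wiggle while requiring the trend
  expect_true(all(diff(rate) > -0.05))
  expect_gt(rate[4], rate[1])
})
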