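# Scan statistics: marker regression vs brute-force oracles, permutation
# thresholds, support intervals, variance explained, interaction tests,
# conditioned scans, sex/diet ANOVA.

test_that("marker regression reproduces the hand-computed one-way ANOVA", {
  # 12-row toy: 4 per class, cell means 0/1/3 plus fixed residuals
  resid4 <- c(-0.3, 0.1, 0.25, -0.05)
  y <- c(0 + resid4, 1 + resid4, 3 + resid4)
  g <- rep(0:2, each = 4)
  # closed-form one-way ANOVA
  gm <- mean(y)
  ssb <- 4 * sum((tapply(y, g, mean) - gm)^2)
  ssw <- sum((y - rep(tapply(y, g, mean), each = 4))^2)
  f_oracle <- (ssb / 2) / (ssw / 9)
  p_oracle <- pf(f_oracle, 2, 9, lower.tail = FALSE)
  mr <- marker_regression(y, NULL, g)
  expect_equal(mr$f_stat, f_oracle, tolerance = 1e-12)
  expect_equal(mr$p, p_oracle, tolerance = 1e-12)
  expect_equal(mr$lod, -log10(p_oracle), tolerance = 1e-12)
})

test_that("marker regression matches the normal-equations oracle on toys", {
  set.seed(61)
  for (rep in 1:20) {
    n <- sample(30:80, 1)
    cov_df <- data.frame(sex = sample(c("F", "M"), n, TRUE),
                         diet = sample(c("american", "ketogenic"), n, TRUE))
    y <- rnorm(n)
    g <- draw_f2_locus(n)
    g[sample(n, 3)] <- NA
    X <- model.matrix(~ sex * diet, cov_df)
    orc <- oracle_partial_f(y, X, g)
    mr <- marker_regression(y, X[, -1], g)
    expect_equal(mr$f_stat, orc$f, tolerance = 1e-10)
    expect_equal(mr$lod, orc$lod, tolerance = 1e-10)
    expect_equal(c(mr$effect_het, mr$effect_fvb), orc$effects,
                 tolerance = 1e-10)
  }
})

test_that("compiled genome scan agrees with per-marker regression in R", {
  map <- single_chrom_map(12, 60)
  cfg <- cross_sim_config(map, n_f2 = 120,
                          traits = list(t1 = trait_spec(sex_effect = 1)),
                          qtls = list(qtl_spec(map$marker[6], "t1",
                                               additive = 0.8)),
                          missing_rate = 0.05)
  cr <- simulate_cross(cfg, seed = 62)
  sc <- genome_scan(cr$pheno, cr$geno, "t1")
  covm <- model.matrix(~ sex * diet, cr$pheno)[, -1]
  for (j in seq_len(nrow(map))) {
    mr <- marker_regression(cr$pheno$t1, covm, cr$geno$calls[, j])
    expect_equal(sc$lod[j], mr$lod, tolerance = 1e-9)
    expect_equal(sc$effect_fvb[j], mr$effect_fvb, tolerance = 1e-9)
    expect_equal(sc$f_stat[j], mr$f_stat, tolerance = 1e-9)
  }
})

test_that("an exact genotype-determined trait caps the LOD", {
  g <- rep(0:2, each = 30)
  mr <- marker_regression(as.numeric(g), NULL, g)
  expect_equal(mr$lod, 300)
  expect_equal(mr$effect_het, 1, tolerance = 1e-8)
  expect_equal(mr$effect_fvb, 2, tolerance = 1e-8)
})

test_that("null marker p-values are uniform", {
  set.seed(63)
  g <- draw_f2_locus(469)
  cov_df <- data.frame(sex = sample(c("F", "M"), 469, TRUE),
                       diet = sample(c("american", "ketogenic"), 469, TRUE))
  pvals <- vapply(1:500, function(i)
    marker_regression(rnorm(469), cov_df, g)$p, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("signed LOD is antisymmetric under allele relabeling", {
  set.seed(64)
  g <- draw_f2_locus(200)
  y <- 0.5 * g + rnorm(200)
  a <- marker_regression(y, NULL, g)
  b <- marker_regression(y, NULL, 2L - g)
  expect_equal(a$lod, b$lod, tolerance = 1e-10)
  expect_equal(a$signed_lod, -b$signed_lod, tolerance = 1e-10)
})

test_that("F-test and chi-square limits agree on large-n null data", {
  set.seed(65)
  g <- draw_f2_locus(5000)
  y <- rnorm(5000)
  mr <- marker_regression(y, NULL, g)
  lod_chisq <- -stats::pchisq(mr$f_stat * mr$df_num, mr$df_num,
                              lower.tail = FALSE, log.p = TRUE) / log(10)
  expect_lt(abs(mr$lod - lod_chisq), 0.02)
})

test_that("single genotype class is skipped with a flag", {
  mr <- marker_regression(rnorm(30), NULL, rep(1L, 30))
  expect_true(mr$skipped)
  expect_true(is.na(mr$lod))
})

test_that("support intervals follow the drop-and-flank convention", {
  map <- single_chrom_map(5, 40)
  sc <- data.frame(marker = map$marker, chrom = map$chrom,
                   pos_mb = map$pos_mb, pos_cm = map$pos_cm,
                   lod = c(1, 3, 5, 3, 1))
  class(sc) <- c("scan_result", "data.frame")
  si <- support_interval(sc, "1", drop = 1.5)
  expect_equal(si$top_marker, map$marker[3])
  expect_equal(si$left_marker, map$marker[2])
  expect_equal(si$right_marker, map$marker[4])

  # monotone profile peaking at the chromosome end
  sc$lod <- c(1, 2, 3, 4, 5)
  si2 <- support_interval(sc, "1", drop = 1.5)
  expect_equal(si2$top_marker, map$marker[5])
  expect_equal(si2$right_marker, map$marker[5])
  expect_equal(si2$left_marker, map$marker[3])  # 4 in-drop, plus flank
})

test_that("support intervals cover the simulated locus at nominal rate", {
  map <- single_chrom_map(51, 100)
  qtl_m <- map$marker[26]
  qtl_cm <- map$pos_cm[26]
  hits <- vapply(1:200, function(r) {
    cfg <- cross_sim_config(map, n_f2 = 469,
                            traits = list(t1 = trait_spec(noise_sd = 1)),
                            qtls = list(qtl_spec(qtl_m, "t1",
                                                 additive = 0.5)))
    cr <- simulate_cross(cfg, seed = 700 + r)
    sc <- genome_scan(cr$pheno, cr$geno, "t1", formula = ~1, min_n = 10)
    si <- support_interval(sc, "1", drop = 1.5)
    si$left_cm <= qtl_cm && qtl_cm <= si$right_cm
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("genome scan localizes a moderate QTL", {
  map <- build_map(90, c("1" = 100, "2" = 100, "3" = 100))
  qtl_m <- marker_near(map, "2", 0.5)
  qtl_cm <- map$pos_cm[map$marker == qtl_m]
  hits <- vapply(1:100, function(r) {
    cfg <- cross_sim_config(map, n_f2 = 469,
                            traits = list(t1 = trait_spec(noise_sd = 1)),
                            qtls = list(qtl_spec(qtl_m, "t1",
                                                 additive = 0.5)))
    cr <- simulate_cross(cfg, seed = 900 + r)
    sc <- genome_scan(cr$pheno, cr$geno, "t1", formula = ~1, min_n = 10)
    top <- sc[which.max(sc$lod), ]
    top$chrom == "2" && abs(top$pos_cm - qtl_cm) <= 10
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("permutation thresholds behave like single-test quantiles without multiplicity", {
  set.seed(66)
  n <- 2000
  ph <- make_pheno(n, t1 = rnorm(n))
  geno <- make_geno(matrix(draw_f2_locus(n), ncol = 1),
                    single_chrom_map(1, 10))
  thr <- permutation_thresholds(ph, geno, "t1", formula = ~1,
                                alphas = 0.05, n_perm = 400, seed = 1)
  expect_equal(unname(thr$thresholds), -log10(0.05), tolerance = 0.12)
})

test_that("permutation thresholds are location-invariant and deterministic", {
  map <- single_chrom_map(8, 60)
  cfg <- cross_sim_config(map, n_f2 = 150,
                          traits = list(t1 = trait_spec()))
  cr <- simulate_cross(cfg, seed = 67)
  t1 <- permutation_thresholds(cr$pheno, cr$geno, "t1", alphas = 0.05,
                               n_perm = 100, seed = 5)
  ph2 <- cr$pheno
  ph2$t1 <- ph2$t1 + 100
  t2 <- permutation_thresholds(ph2, cr$geno, "t1", alphas = 0.05,
                               n_perm = 100, seed = 5)
  expect_equal(t1$max_lod, t2$max_lod, tolerance = 1e-8)
  t3 <- permutation_thresholds(cr$pheno, cr$geno, "t1", alphas = 0.05,
                               n_perm = 100, seed = 5)
  expect_identical(t1$max_lod, t3$max_lod)
})

test_that("variance explained matches its construction", {
  set.seed(68)
  n <- 2000
  g <- draw_f2_locus(n)
  x <- g - 1
  # marker R^2 = var(beta x)/var(y) = 0.25 when beta^2*0.5 / (beta^2*0.5+s2)
  beta <- 1
  s2 <- beta^2 * 0.5 * 3          # leaves R^2 = 1/4
  y <- beta * x + rnorm(n, 0, sqrt(s2))
  ph <- make_pheno(n, t1 = y)
  geno <- make_geno(matrix(g, ncol = 1), single_chrom_map(1, 10))
  ve <- variance_explained(ph, geno, "t1", geno$map$marker[1], formula = ~1)
  expect_equal(ve, 25, tolerance = 3)

  y0 <- rnorm(n)
  ph0 <- make_pheno(n, t1 = y0)
  ve0 <- variance_explained(ph0, geno, "t1", geno$map$marker[1],
                            formula = ~1)
  expect_lt(ve0, 1)
})

test_that("stratified variance explained peaks in the driving cell", {
  map <- single_chrom_map(3, 20)
  cfg <- cross_sim_config(
    map, n_f2 = 2000,
    traits = list(t1 = trait_spec(noise_sd = 1)),
    qtls = list(qtl_spec(map$marker[2], "t1", additive = 0.7,
                         sex_modifier = 2, diet_modifier = 2)))
  cr <- simulate_cross(cfg, seed = 69)
  cells <- expand.grid(sex = c("F", "M"), diet = c("american", "ketogenic"),
                       stringsAsFactors = FALSE)
  ve <- vapply(seq_len(4), function(i)
    variance_explained(cr$pheno, cr$geno, "t1", map$marker[2],
                       stratum = as.list(cells[i, ])), numeric(1))
  mk <- which(cells$sex == "M" & cells$diet == "ketogenic")
  expect_true(all(ve[mk] > ve[-mk]))
})

test_that("two-locus interaction test is calibrated and covers the effect", {
  set.seed(71)
  # null calibration
  pnull <- vapply(1:200, function(r) {
    n <- 200
    ga <- draw_f2_locus(n); gb <- draw_f2_locus(n)
    ph <- make_pheno(n, t1 = rnorm(n) + 0.5 * (ga - 1) + 0.3 * (gb >= 1))
    geno <- make_geno(cbind(ga, gb), build_map(2, c("1" = 20, "2" = 20)))
    marker_interaction_test(ph, geno, "t1", geno$map$marker[1],
                            geno$map$marker[2])$p
  }, numeric(1))
  expect_gt(stats::ks.test(pnull, "punif")$p.value, 0.01)

  # +5 unit interaction in the (BB at a) x (FVB carrier at b) cell
  cover <- vapply(1:200, function(r) {
    n <- 300
    ga <- draw_f2_locus(n); gb <- draw_f2_locus(n)
    y <- rnorm(n, sd = 2) + 5 * (ga == 0 & gb >= 1)
    ph <- make_pheno(n, t1 = y)
    geno <- make_geno(cbind(ga, gb), build_map(2, c("1" = 20, "2" = 20)))
    it <- marker_interaction_test(ph, geno, "t1", geno$map$marker[1],
                                  geno$map$marker[2])
    it$ci[1] <= 5 && 5 <= it$ci[2]
  }, logical(1))
  expect_gte(mean(cover), 0.9)
})

test_that("interaction estimate ignores added main effects", {
  set.seed(72)
  n <- 400
  ga <- draw_f2_locus(n); gb <- draw_f2_locus(n)
  y <- rnorm(n) + 2 * (ga == 0 & gb >= 1)
  geno <- make_geno(cbind(ga, gb), build_map(2, c("1" = 20, "2" = 20)))
  ph1 <- make_pheno(n, t1 = y)
  ph2 <- make_pheno(n, t1 = y + 3 * (ga == 0) - 2 * (gb >= 1))
  e1 <- marker_interaction_test(ph1, geno, "t1", geno$map$marker[1],
                                geno$map$marker[2])$estimate
  e2 <- marker_interaction_test(ph2, geno, "t1", geno$map$marker[1],
                                geno$map$marker[2])$estimate
  expect_equal(e1, e2, tolerance = 1e-10)
})

test_that("conditioning detects mediation and ignores irrelevant traits", {
  map <- single_chrom_map(5, 40)
  shared <- vapply(1:100, function(r) {
    cfg <- cross_sim_config(
      map, n_f2 = 469,
      traits = list(t2 = trait_spec(noise_sd = 1),
                    t1 = trait_spec(noise_sd = 1)),
      qtls = list(qtl_spec(map$marker[3], "t2", additive = 1)),
      pleiotropy = pleiotropy_spec(map$marker[3], "t2", "t1", lambda = 0.7))
    cr <- simulate_cross(cfg, seed = 1100 + r)
    cs <- conditioned_scan(cr$pheno, cr$geno, "t1", "t2",
                           at_markers = map$marker[3])
    cs$delta$shared
  }, logical(1))
  expect_gte(mean(shared), 0.9)

  # conditioning on an independent noise trait: |delta| < 2 almost always
  null_shared <- vapply(1:100, function(r) {
    cfg <- cross_sim_config(
      map, n_f2 = 469,
      traits = list(t1 = trait_spec(noise_sd = 1),
                    tn = trait_spec(noise_sd = 1)),
      qtls = list(qtl_spec(map$marker[3], "t1", additive = 0.6)))
    cr <- simulate_cross(cfg, seed = 1300 + r)
    cs <- conditioned_scan(cr$pheno, cr$geno, "t1", "tn",
                           at_markers = map$marker[3])
    cs$delta$shared
  }, logical(1))
  expect_lte(mean(null_shared), 0.1)
})

test_that("an unrelated conditioning trait leaves the profile unchanged", {
  map <- single_chrom_map(5, 40)
  cfg <- cross_sim_config(
    map, n_f2 = 400,
    traits = list(t1 = trait_spec(noise_sd = 1),
                  tn = trait_spec(noise_sd = 1)),
    qtls = list(qtl_spec(map$marker[3], "t1", additive = 0.8)))
  cr <- simulate_cross(cfg, seed = 73)
  cs <- conditioned_scan(cr$pheno, cr$geno, "t1", "tn")
  expect_equal(cs$conditioned$lod, cs$unconditioned$lod, tolerance = 0.5)
  expect_error(conditioned_scan(cr$pheno, cr$geno, "t1", "t1"),
               "must differ")
})

test_that("sex/diet interaction ANOVA flags cell-specific QTL effects", {
  map <- single_chrom_map(3, 20)
  sig3 <- vapply(1:50, function(r) {
    cfg <- cross_sim_config(
      map, n_f2 = 469,
      traits = list(t1 = trait_spec(noise_sd = 1)),
      qtls = list(qtl_spec(map$marker[2], "t1", additive = 0.7,
                           sex_modifier = 3, diet_modifier = 3)))
    # strong multiplicative modifiers concentrate the effect in
    # ketogenic males (cell multipliers 1 / 3 / 3 / 9)
    cr <- simulate_cross(cfg, seed = 1500 + r)
    an <- sex_diet_marker_anova(cr$pheno, cr$geno, "t1", map$marker[2])
    an$p[an$term == "sex:diet:g"] < 0.05
  }, logical(1))
  expect_gte(mean(sig3), 0.8)

  # permuting sex labels destroys the marker x sex signal
  cfg <- cross_sim_config(
    map, n_f2 = 2000, traits = list(t1 = trait_spec(noise_sd = 1)),
    qtls = list(qtl_spec(map$marker[2], "t1", additive = 0.8,
                         sex_modifier = 4)))
  cr <- simulate_cross(cfg, seed = 74)
  an1 <- sex_diet_marker_anova(cr$pheno, cr$geno, "t1", map$marker[2])
  set.seed(75)
  ph2 <- cr$pheno
  ph2$sex <- sample(ph2$sex)
  an2 <- sex_diet_marker_anova(ph2, cr$geno, "t1", map$marker[2])
  expect_lt(an1$p[an1$term == "sex:g"], 1e-4)
  expect_gt(an2$p[an2$term == "sex:g"], 1e-4)
})
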