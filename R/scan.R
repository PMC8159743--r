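# Single-marker genome scans under the combined model, permutation
# thresholds, 1.5-LOD support intervals, variance explained, top-marker
# interaction tests, and conditioned scans with the shared-QTL rule.
#
# "LOD" throughout is -log10 of the marker-term p-value from the partial
# F-test (2 df for a fully segregating marker), not the classical
# likelihood-ratio LOD; the classical LOD is available as an extra column.

LOD_CAP_DEFAULT <- 300

as_scan_formula <- function(formula) {
  if (is.null(formula)) return(~1)
  if (is.character(formula)) formula <- as.formula(paste("~", formula))
  formula
}

scan_design <- function(pheno, trait, formula = ~ sex * diet,
                        condition_on = NULL) {
  if (!trait %in% names(pheno)) stop("trait not found: ", trait)
  fml <- as_scan_formula(formula)
  vars <- all.vars(fml)
  if (!is.null(condition_on)) {
    if (condition_on == trait)
      stop("conditioning trait must differ from the scanned trait")
    if (!condition_on %in% names(pheno))
      stop("conditioning trait not found: ", condition_on)
  }
  y <- pheno[[trait]]
  ok <- !is.na(y)
  for (v in vars) ok <- ok & !is.na(pheno[[v]])
  if (!is.null(condition_on)) ok <- ok & !is.na(pheno[[condition_on]])
  X <- model.matrix(fml, pheno[ok, , drop = FALSE])
  if (!is.null(condition_on)) {
    z <- pheno[[condition_on]][ok]
    if (abs(stats::cor(y[ok], z)) > 0.999)
      stop("conditioning trait is collinear with the scanned trait (|r| > 0.999)")
    X <- cbind(X, z)
    colnames(X)[ncol(X)] <- condition_on
  }
  if (qr(X)$rank < ncol(X)) stop("covariate design is rank deficient")
  list(y = y[ok], X = X, rows = which(ok))
}

#' Single-marker regression
#'
#' Fits the reduced (covariates only) and full (covariates + marker as a
#' categorical factor with B6/B6 reference) least-squares models on rows
#' complete for the trait, covariates and genotype, and reports the partial
#' F-test of the marker term. The LOD is -log10 of that p-value, capped at
#' `lod_cap` when p underflows.
#'
#' @param y numeric trait values.
#' @param covariates covariate data frame (expanded additively via
#'   `model.matrix(~ .)`), a numeric design matrix to which an intercept
#'   is prepended (use this for interaction designs), or `NULL` for an
#'   intercept-only reduced model.
#' @param genotype genotypes as FVB-allele counts (0/1/2) or BB/BF/FF
#'   labels; missing allowed.
#' @param lod_cap ceiling for the LOD when the p-value underflows.
#' @return list with `n`, `lod`, `signed_lod`, `effect_het`, `effect_fvb`,
#'   `f_stat`, `df_num`, `df_den`, `p`, `skipped` (single genotype class).
#' @export
marker_regression <- function(y, covariates = NULL, genotype,
                              lod_cap = LOD_CAP_DEFAULT) {
  if (is.character(genotype) || is.factor(genotype))
    genotype <- geno_codes(genotype)
  ok <- !is.na(y) & !is.na(genotype)
  if (!is.null(covariates)) ok <- ok & complete.cases(covariates)
  y <- y[ok]; g <- genotype[ok]
  X <- if (is.null(covariates)) {
    matrix(1, length(y), 1)
  } else if (is.matrix(covariates)) {
    cbind(`(Intercept)` = 1, covariates[ok, , drop = FALSE])
  } else {
    model.matrix(~ ., droplevels(as.data.frame(covariates)[ok, , drop = FALSE]))
  }
  if (qr(X)$rank < ncol(X)) stop("covariate design is rank deficient")
  classes <- sort(unique(g))
  if (length(classes) < 2)
    return(list(n = length(y), lod = NA_real_, signed_lod = NA_real_,
                effect_het = NA_real_, effect_fvb = NA_real_,
                f_stat = NA_real_, df_num = NA_real_, df_den = NA_real_,
                p = NA_real_, skipped = TRUE))
  D <- sapply(classes[-1], function(cl) as.numeric(g == cl))
  colnames(D) <- paste0("g", classes[-1])
  fit1 <- lm.fit(cbind(X, D), y)
  fit0 <- lm.fit(X, y)
  rss1 <- sum(fit1$residuals^2)
  rss0 <- sum(fit0$residuals^2)
  df_num <- ncol(D)
  df_den <- length(y) - ncol(X) - df_num
  f <- ((rss0 - rss1) / df_num) / (rss1 / df_den)
  logp <- pf(f, df_num, df_den, lower.tail = FALSE, log.p = TRUE)
  p <- exp(logp)
  lod <- min(-logp / log(10), lod_cap)
  eff_het <- if (classes[1] == 0 && 1 %in% classes)
    unname(fit1$coefficients["g1"]) else NA_real_
  eff_fvb <- if (classes[1] == 0 && 2 %in% classes)
    unname(fit1$coefficients["g2"]) else NA_real_
  list(n = length(y), lod = lod,
       signed_lod = lod * if (is.na(eff_fvb)) 1 else sign(eff_fvb),
       effect_het = eff_het, effect_fvb = eff_fvb, f_stat = f,
       df_num = df_num, df_den = df_den, p = p, skipped = FALSE)
}

#' Genome scan under the combined model
#'
#' Runs [marker_regression()] at every retained marker (via a compiled
#' scan kernel) for `trait` under the covariate formula (default the
#' combined model `~ sex * diet`). `signed_lod` carries the sign of the
#' FVB/FVB effect: positive values mean the FVB allele increases the
#' trait.
#'
#' @param pheno a `phenotype_table`.
#' @param geno a `genotype_matrix` aligned with `pheno` rows by id.
#' @param trait trait name.
#' @param formula covariate formula (one-sided formula or string such as
#'   `"sex*diet"`).
#' @param condition_on optional trait entered as an extra covariate
#'   (conditioned scan).
#' @param min_n minimum complete rows required (default 50).
#' @param lod_cap LOD ceiling for underflowing p-values.
#' @return a `scan_result` data frame: marker, chrom, pos_mb, pos_cm, n,
#'   lod, signed_lod, effect_het, effect_fvb, f_stat, df_num, df_den, p,
#'   lod_classical.
#' @export
genome_scan <- function(pheno, geno, trait, formula = ~ sex * diet,
                        condition_on = NULL, min_n = 50,
                        lod_cap = LOD_CAP_DEFAULT) {
  d <- scan_design(pheno, trait, formula, condition_on)
  if (length(d$y) < min_n)
    stop("only ", length(d$y), " complete rows (min_n = ", min_n, ")")
  G <- align_geno(geno, pheno$id[d$rows])
  eng <- .scan_engine(d$X, d$y, G)
  df_den <- eng[, "n"] - eng[, "df_num"] - ncol(d$X)
  ss <- eng[, "rss0"] - eng[, "rss1"]
  f <- (ss / eng[, "df_num"]) / (eng[, "rss1"] / df_den)
  logp <- pf(f, eng[, "df_num"], df_den, lower.tail = FALSE, log.p = TRUE)
  lod <- pmin(-logp / log(10), lod_cap)
  # classical likelihood LOD: (n/2) * log10(RSS0/RSS1)
  lod_cl <- (eng[, "n"] / 2) * log10(eng[, "rss0"] / eng[, "rss1"])
  sgn <- ifelse(is.na(eng[, "effect_fvb"]), 1, sign(eng[, "effect_fvb"]))
  out <- data.frame(
    marker = geno$map$marker, chrom = geno$map$chrom,
    pos_mb = geno$map$pos_mb, pos_cm = geno$map$pos_cm,
    n = eng[, "n"], lod = lod, signed_lod = lod * sgn,
    effect_het = eng[, "effect_het"], effect_fvb = eng[, "effect_fvb"],
    f_stat = f, df_num = eng[, "df_num"], df_den = df_den, p = exp(logp),
    lod_classical = lod_cl, stringsAsFactors = FALSE)
  attr(out, "model") <- list(trait = trait,
                             formula = deparse(as_scan_formula(formula)),
                             condition_on = condition_on)
  class(out) <- c("scan_result", "data.frame")
  out
}

align_geno <- function(geno, ids) {
  idx <- match(ids, rownames(geno$calls))
  if (anyNA(idx))
    stop("phenotype ids absent from genotype matrix: ",
         paste(utils::head(ids[is.na(idx)], 5), collapse = ", "))
  geno$calls[idx, , drop = FALSE]
}

#' Permutation-based genome-wide thresholds
#'
#' Estimates genome-wide significance thresholds for the scan statistic
#' (max over markers of the LOD) by shuffling genotype rows as a block
#' against intact (phenotype, covariate) pairs, preserving the
#' covariate-trait relationship under the null of no linkage. The
#' threshold for level `alpha` is the empirical (1 - alpha) quantile of
#' the permutation distribution of the genome-wide maximum.
#'
#' @inheritParams genome_scan
#' @param alphas genome-wide type I error rates.
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed for the permutations.
#' @return a `threshold_set`: list with `thresholds` (named by alpha),
#'   `n_perm`, `seed` and the permutation maxima `max_lod`.
#' @export
permutation_thresholds <- function(pheno, geno, trait, formula = ~ sex * diet,
                                   alphas = c(0.05, 0.01), n_perm = 1000,
                                   seed = NULL, condition_on = NULL) {
  stopifnot(n_perm >= 100, all(alphas > 0 & alphas < 1))
  if (any(alphas * n_perm < 5))
    warning("n_perm = ", n_perm, " is small for alpha = ",
            min(alphas), "; threshold will be unstable", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  d <- scan_design(pheno, trait, formula, condition_on)
  G <- align_geno(geno, pheno$id[d$rows])
  n <- length(d$y)
  perms <- vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))
  mx <- .perm_max_stat(d$X, d$y, G, perms)
  thr <- quantile(mx, 1 - alphas, names = FALSE)
  structure(list(thresholds = setNames(thr, alphas), n_perm = n_perm,
                 seed = seed, max_lod = mx),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat("Genome-wide LOD thresholds from", x$n_perm, "permutations:\n")
  for (a in names(x$thresholds))
    cat(sprintf("  alpha = %s: %.2f\n", a, x$thresholds[[a]]))
  invisible(x)
}

#' 1.5-LOD support interval
#'
#' Approximate 95% confidence region for a QTL location: starting from the
#' chromosome peak (leftmost marker on ties), the interval spans the
#' contiguous run of markers with LOD within `drop` of the peak, extended
#' by one flanking marker below the cut on each side where available.
#'
#' @param scan a `scan_result`.
#' @param chrom chromosome label.
#' @param drop LOD units to descend from the peak (default 1.5).
#' @return a `support_interval` data frame row: chrom, left/top/right
#'   marker names with Mb and cM positions, peak lod, drop.
#' @export
support_interval <- function(scan, chrom, drop = 1.5) {
  s <- scan[scan$chrom == chrom & !is.na(scan$lod), , drop = FALSE]
  if (nrow(s) == 0) stop("no scanned markers on chromosome ", chrom)
  s <- s[order(s$pos_cm), ]
  top <- which.max(s$lod)           # which.max takes the leftmost tie
  cut <- s$lod[top] - drop
  left <- top
  while (left > 1 && s$lod[left - 1] >= cut) left <- left - 1
  right <- top
  while (right < nrow(s) && s$lod[right + 1] >= cut) right <- right + 1
  if (left > 1) left <- left - 1    # flanking extension
  if (right < nrow(s)) right <- right + 1
  out <- data.frame(
    chrom = chrom,
    left_marker = s$marker[left], left_mb = s$pos_mb[left],
    left_cm = s$pos_cm[left],
    top_marker = s$marker[top], top_mb = s$pos_mb[top],
    top_cm = s$pos_cm[top],
    right_marker = s$marker[right], right_mb = s$pos_mb[right],
    right_cm = s$pos_cm[right],
    lod = s$lod[top], drop = drop, stringsAsFactors = FALSE)
  class(out) <- c("support_interval", "data.frame")
  out
}

#' Variance explained by a marker
#'
#' Percentage of the total sum of squares of the trait attributable to the
#' marker term: 100 x (SS_model(covariates + marker) - SS_model(covariates))
#' / SS_total. With a `stratum`, computed within that sex/diet cell with
#' the marker-only model.
#'
#' @inheritParams genome_scan
#' @param marker marker name.
#' @param stratum optional named list, e.g. `list(sex = "M",
#'   diet = "ketogenic")`.
#' @return percentage (scalar); `NA` if the total SS is zero.
#' @export
variance_explained <- function(pheno, geno, trait, marker,
                               formula = ~ sex * diet, stratum = NULL) {
  rows <- seq_len(nrow(pheno))
  if (!is.null(stratum)) {
    keep <- rep(TRUE, nrow(pheno))
    for (v in names(stratum)) keep <- keep & pheno[[v]] == stratum[[v]]
    rows <- which(keep)
    formula <- ~1
  }
  ph <- pheno[rows, , drop = FALSE]
  d <- scan_design(ph, trait, formula)
  g <- align_geno(geno, ph$id[d$rows])[, marker]
  ok <- !is.na(g)
  y <- d$y[ok]; X <- d$X[ok, , drop = FALSE]; g <- g[ok]
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(NA_real_)
  D <- sapply(sort(unique(g))[-1], function(cl) as.numeric(g == cl))
  rss0 <- sum(lm.fit(X, y)$residuals^2)
  rss1 <- sum(lm.fit(cbind(X, D), y)$residuals^2)
  100 * (rss0 - rss1) / sst
}

#' Two-locus interaction test
#'
#' Tests the interaction between two QTLs under a configurable genotype
#' grouping (default: locus-a B6/B6 homozygote vs rest crossed with
#' locus-b FVB carrier vs not), optionally within a sex/diet stratum.
#' Reports the interaction contrast with its Wald confidence interval and
#' the F-test p-value of the interaction term.
#'
#' @inheritParams variance_explained
#' @param marker_a,marker_b marker names.
#' @param group_a,group_b functions mapping FVB-allele counts to a logical
#'   grouping at each locus.
#' @param level confidence level for the Wald interval.
#' @return list with `estimate`, `ci` (length 2), `p`, `f_stat`, `n`.
#' @export
marker_interaction_test <- function(pheno, geno, trait, marker_a, marker_b,
                                    stratum = NULL,
                                    group_a = function(g) g == 0,
                                    group_b = function(g) g >= 1,
                                    level = 0.95) {
  rows <- seq_len(nrow(pheno))
  if (!is.null(stratum)) {
    keep <- rep(TRUE, nrow(pheno))
    for (v in names(stratum)) keep <- keep & pheno[[v]] == stratum[[v]]
    rows <- which(keep)
  }
  if (length(rows) == 0) stop("empty stratum")
  ph <- pheno[rows, , drop = FALSE]
  G <- align_geno(geno, ph$id)
  y <- ph[[trait]]
  a <- group_a(G[, marker_a])
  b <- group_b(G[, marker_b])
  ok <- !is.na(y) & !is.na(a) & !is.na(b)
  dat <- data.frame(y = y[ok], a = factor(a[ok], c(FALSE, TRUE)),
                    b = factor(b[ok], c(FALSE, TRUE)))
  if (any(table(dat$a, dat$b) == 0))
    return(list(estimate = NA_real_, ci = c(NA_real_, NA_real_),
                p = NA_real_, f_stat = NA_real_, n = nrow(dat),
                inestimable = TRUE))
  fit <- lm(y ~ a * b, data = dat)
  an <- anova(fit)
  est <- coef(fit)[["aTRUE:bTRUE"]]
  ci <- confint(fit, "aTRUE:bTRUE", level = level)
  list(estimate = est, ci = as.numeric(ci), p = an["a:b", "Pr(>F)"],
       f_stat = an["a:b", "F value"], n = nrow(dat), inestimable = FALSE)
}

#' Conditioned genome scan and the shared-QTL rule
#'
#' Rescans `trait` with `conditioning_trait` added as a covariate, on the
#' rows complete for both traits and the covariates (the unconditioned
#' scan is recomputed on the same rows for comparability). At each
#' requested marker (default: the unconditioned genome-wide peak),
#' delta LOD = unconditioned - conditioned; |delta LOD| >= `delta_threshold`
#' (default 2.0, a 5% type I error rate) calls the locus shared
#' (pleiotropic) between the traits.
#'
#' @inheritParams genome_scan
#' @param conditioning_trait trait entered as the extra covariate.
#' @param at_markers markers at which to evaluate delta LOD; default the
#'   top marker of the unconditioned scan.
#' @param delta_threshold LOD change declaring a shared QTL.
#' @return list with `unconditioned`, `conditioned` (both `scan_result`)
#'   and `delta`, a data frame (marker, lod_unconditioned,
#'   lod_conditioned, delta_lod, shared).
#' @export
conditioned_scan <- function(pheno, geno, trait, conditioning_trait,
                             formula = ~ sex * diet, at_markers = NULL,
                             delta_threshold = 2.0, min_n = 50) {
  # restrict both scans to rows complete for y, covariates and conditioner
  keep <- !is.na(pheno[[conditioning_trait]])
  ph <- pheno[keep, , drop = FALSE]
  un <- genome_scan(ph, geno, trait, formula, min_n = min_n)
  co <- genome_scan(ph, geno, trait, formula,
                    condition_on = conditioning_trait, min_n = min_n)
  if (is.null(at_markers))
    at_markers <- un$marker[which.max(un$lod)]
  i <- match(at_markers, un$marker)
  delta <- data.frame(
    marker = at_markers,
    lod_unconditioned = un$lod[i],
    lod_conditioned = co$lod[match(at_markers, co$marker)],
    stringsAsFactors = FALSE)
  delta$delta_lod <- delta$lod_unconditioned - delta$lod_conditioned
  delta$shared <- abs(delta$delta_lod) >= delta_threshold
  list(unconditioned = un, conditioned = co, delta = delta)
}

#' Sex/diet-by-marker interaction ANOVA
#'
#' Sequential-SS ANOVA of `y ~ sex * diet * marker` at one marker,
#' reporting the F and p of each genotype-involving interaction term
#' (marker x sex, marker x diet, marker x sex x diet).
#'
#' @inheritParams variance_explained
#' @return data frame with term, df, f_stat, p; terms that are
#'   inestimable because of empty cells carry `NA`.
#' @export
sex_diet_marker_anova <- function(pheno, geno, trait, marker) {
  g <- align_geno(geno, pheno$id)[, marker]
  dat <- data.frame(y = pheno[[trait]], sex = pheno$sex, diet = pheno$diet,
                    g = factor(geno_labels(g), c("BB", "BF", "FF")))
  dat <- dat[complete.cases(dat), ]
  dat$g <- droplevels(dat$g)
  fit <- lm(y ~ sex * diet * g, data = dat)
  an <- anova(fit)
  want <- c("sex:g", "diet:g", "sex:diet:g")
  out <- data.frame(term = want,
                    df = an[want, "Df"],
                    f_stat = an[want, "F value"],
                    p = an[want, "Pr(>F)"], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Plot a signed-LOD genome profile
#'
#' @param x a `scan_result`.
#' @param thresholds optional `threshold_set` drawn as horizontal lines.
#' @param ... passed to [plot()].
#' @export
plot.scan_result <- function(x, thresholds = NULL, ...) {
  chroms <- unique(x$chrom)
  offs <- c(0, cumsum(tapply(x$pos_cm, factor(x$chrom, chroms), max) + 10))
  xpos <- x$pos_cm + offs[match(x$chrom, chroms)]
  plot(xpos, x$signed_lod, type = "n", xaxt = "n",
       xlab = "chromosome", ylab = "signed LOD (-log10 p)", ...)
  for (i in seq_along(chroms)) {
    sel <- x$chrom == chroms[i]
    graphics::lines(xpos[sel], x$signed_lod[sel],
                    col = c("grey30", "steelblue")[1 + i %% 2])
  }
  graphics::axis(1, at = offs[-length(offs)] +
                   tapply(x$pos_cm, factor(x$chrom, chroms), max) / 2,
                 labels = chroms, tick = FALSE)
  if (!is.null(thresholds))
    graphics::abline(h = c(thresholds$thresholds, -thresholds$thresholds),
                     lty = 2, col = c("orange", "darkgreen"))
  graphics::abline(h = 0, col = "grey70")
  invisible(x)
}
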