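# Synthetic F2 intercross generator: genetic map, meiosis, phenotype
# architecture (sex/diet-modulated QTLs, epistasis, pleiotropy), and
# parental/F1 cohorts with zero within-cohort genetic variance.

#' Mouse-style linkage-group lengths
#'
#' Twenty linkage groups (19 autosome-like groups plus one labelled "X")
#' with lengths proportioned like the mouse genetic map and rescaled so the
#' genome totals `total_cm` centimorgans (default 1400 cM, the scale of a
#' dense mouse F2 panel).
#'
#' @param total_cm total genome length in centimorgans.
#' @return named numeric vector of per-chromosome lengths (cM).
#' @export
mouse_chrom_lengths <- function(total_cm = 1400) {
  len <- c(98.5, 103.9, 82.7, 88.6, 90.2, 79.0, 89.1, 76.2, 75.1, 77.9,
           88.0, 63.9, 67.3, 66.4, 59.0, 57.8, 61.2, 59.4, 56.2, 79.4)
  names(len) <- c(as.character(1:19), "X")
  len * total_cm / sum(len)
}

#' Build an evenly spaced genetic map
#'
#' Allocates `n_markers` across chromosomes proportionally to their genetic
#' length (largest-remainder rounding, at least one marker per chromosome)
#' and spaces markers evenly from 0 to the chromosome end. Physical
#' positions are derived from the genetic positions at a constant Mb/cM
#' ratio.
#'
#' @param n_markers total number of markers; must be at least the number of
#'   chromosomes.
#' @param chrom_lengths_cm named numeric vector of chromosome lengths (cM).
#' @param mb_per_cm physical-to-genetic scale (megabases per centimorgan).
#' @return a `genetic_map`: data frame with columns `marker`, `chrom`,
#'   `pos_mb`, `pos_cm`, sorted by (chrom, pos_cm).
#' @export
build_map <- function(n_markers, chrom_lengths_cm = mouse_chrom_lengths(),
                      mb_per_cm = 1.8) {
  stopifnot(all(chrom_lengths_cm > 0))
  nc <- length(chrom_lengths_cm)
  if (n_markers < nc)
    stop("n_markers (", n_markers, ") is smaller than the number of chromosomes (",
         nc, ")")
  share <- n_markers * chrom_lengths_cm / sum(chrom_lengths_cm)
  cnt <- floor(share)
  rem <- n_markers - sum(cnt)
  if (rem > 0) {
    up <- order(share - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[up] <- cnt[up] + 1
  }
  # guarantee every chromosome carries a marker
  while (any(cnt == 0)) {
    cnt[which.max(cnt)] <- max(cnt) - 1
    cnt[which(cnt == 0)[1]] <- 1
  }
  chroms <- names(chrom_lengths_cm)
  if (is.null(chroms)) chroms <- as.character(seq_len(nc))
  rows <- lapply(seq_len(nc), function(i) {
    m <- cnt[i]
    pos <- if (m == 1) chrom_lengths_cm[i] / 2 else
      seq(0, chrom_lengths_cm[i], length.out = m)
    data.frame(marker = sprintf("c%s_m%03d", chroms[i], seq_len(m)),
               chrom = chroms[i],
               pos_mb = pos * mb_per_cm,
               pos_cm = pos,
               stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, rows)
  rownames(map) <- NULL
  class(map) <- c("genetic_map", "data.frame")
  map
}

#' @export
print.genetic_map <- function(x, ...) {
  cat("Genetic map:", nrow(x), "markers on", length(unique(x$chrom)),
      "chromosomes,", round(sum(tapply(x$pos_cm, x$chrom, max))), "cM total\n")
  invisible(x)
}

new_genotype_matrix <- function(calls, map) {
  stopifnot(ncol(calls) == nrow(map))
  colnames(calls) <- map$marker
  structure(list(ids = rownames(calls), calls = calls, map = map),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("Genotype matrix:", nrow(x$calls), "individuals x", ncol(x$calls),
      "markers (", round(100 * mean(is.na(x$calls)), 2), "% missing )\n")
  invisible(x)
}

#' Genotype code helpers
#'
#' Genotypes are stored internally as FVB-allele counts: 0 = B6/B6,
#' 1 = B6/FVB, 2 = FVB/FVB, `NA` = missing. `geno_labels()` converts counts
#' to "BB"/"BF"/"FF" labels and `geno_codes()` converts labels (accepting
#' the BB/BF/FF, 0/1/2 and A/H/B dialects) back to counts.
#'
#' @param x integer codes (for `geno_labels`) or character labels (for
#'   `geno_codes`).
#' @return character labels, or integer FVB-allele counts.
#' @export
geno_labels <- function(x) c("BB", "BF", "FF")[x + 1L]

#' @rdname geno_labels
#' @export
geno_codes <- function(x) {
  lut <- c(BB = 0L, BF = 1L, FB = 1L, FF = 2L,
           "0" = 0L, "1" = 1L, "2" = 2L,
           A = 0L, H = 1L, B = 2L)
  x <- as.character(x)
  out <- lut[x]
  bad <- !is.na(x) & x != "" & x != "NA" & is.na(out)
  if (any(bad))
    stop("unknown genotype code(s): ", paste(unique(x[bad]), collapse = ", "))
  unname(out)
}

# Simulate gametes for one chromosome as a Haldane (no crossover
# interference) mosaic: recombination between adjacent markers is an
# independent Bernoulli event with probability given by the Haldane map
# function of the interval length, which is exactly the marker-level law of
# a Poisson crossover process on the cM scale.
sim_chrom_genotypes <- function(n, pos_cm) {
  m <- length(pos_cm)
  ng <- 2L * n
  start <- matrix(runif(ng) < 0.5, ng, 1)
  if (m == 1) {
    al <- start
  } else {
    r <- 0.5 * (1 - exp(-2 * diff(pos_cm) / 100))
    rec <- matrix(runif(ng * (m - 1)) < rep(r, each = ng), ng, m - 1)
    xo <- matrixcumsum(rec)
    al <- (cbind(0L, xo) + as.integer(start)) %% 2L
  }
  al[seq(1L, ng, 2L), , drop = FALSE] + al[seq(2L, ng, 2L), , drop = FALSE]
}

matrixcumsum <- function(x) {
  # row-wise cumulative sums without apply-transpose overhead
  out <- matrix(0L, nrow(x), ncol(x))
  acc <- integer(nrow(x))
  for (j in seq_len(ncol(x))) {
    acc <- acc + x[, j]
    out[, j] <- acc
  }
  out
}

#' Simulate F2 genotypes
#'
#' Each F2 individual is the union of two independent F1 gametes; each
#' gamete is a B6/FVB mosaic with crossovers following a no-interference
#' (Haldane) process on the centimorgan scale. Genotypes are FVB-allele
#' counts (0/1/2).
#'
#' @param map a `genetic_map` from [build_map()].
#' @param n number of F2 individuals.
#' @param seed optional RNG seed.
#' @return a `genotype_matrix` (ids x markers, values 0/1/2).
#' @export
simulate_f2 <- function(map, n, seed = NULL) {
  if (nrow(map) == 0) stop("empty genetic map")
  stopifnot(n > 0)
  if (!is.null(seed)) set.seed(seed)
  chroms <- unique(map$chrom)
  calls <- do.call(cbind, lapply(chroms, function(ch) {
    sim_chrom_genotypes(n, map$pos_cm[map$chrom == ch])
  }))
  storage.mode(calls) <- "integer"
  rownames(calls) <- sprintf("F2_%04d", seq_len(n))
  new_genotype_matrix(calls, map)
}

#' Mask genotype calls at random
#'
#' Sets a uniformly random fraction of calls to missing, emulating
#' quality-filtered array genotypes without modelling array chemistry.
#'
#' @param geno a `genotype_matrix`.
#' @param rate fraction of calls to set missing, in \[0, 1).
#' @param seed optional RNG seed.
#' @return the masked `genotype_matrix`.
#' @export
mask_missing <- function(geno, rate, seed = NULL) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(geno)
  if (!is.null(seed)) set.seed(seed)
  drop <- matrix(runif(length(geno$calls)) < rate, nrow(geno$calls))
  geno$calls[drop] <- NA_integer_
  geno
}

#' QTL, epistasis and pleiotropy specifications
#'
#' `qtl_spec()` describes one locus effect on one trait: `additive` is the
#' trait change per FVB allele copy, `dominance` the extra deviation of
#' heterozygotes, and `sex_modifier`/`diet_modifier` multiply the whole
#' locus effect in males and on the ketogenic diet respectively (1 = no
#' modulation). `epistasis_spec()` adds `effect` trait units when
#' `condition(g_a, g_b)` holds (genotypes as FVB-allele counts), optionally
#' restricted to a (sex, diet) stratum. `pleiotropy_spec()` feeds
#' `lambda` times the upstream trait value into the downstream trait,
#' creating a locus -> upstream -> downstream causal chain through any QTL
#' on the upstream trait at `locus`.
#'
#' @param marker,marker_a,marker_b marker names (must exist in the map).
#' @param trait trait name the effect applies to.
#' @param additive,dominance,effect effect sizes in trait units.
#' @param sex_modifier,diet_modifier finite multipliers.
#' @param condition predicate of two genotype-count vectors.
#' @param stratum optional list with elements `sex` and/or `diet`.
#' @param locus,upstream,downstream,lambda pleiotropy chain: marker name,
#'   upstream trait, downstream trait, mediation coefficient.
#' @return a specification list of class `qtl_spec`, `epistasis_spec` or
#'   `pleiotropy_spec`.
#' @export
qtl_spec <- function(marker, trait, additive, dominance = 0,
                     sex_modifier = 1, diet_modifier = 1) {
  stopifnot(is.finite(additive), is.finite(dominance),
            is.finite(sex_modifier), is.finite(diet_modifier))
  structure(list(marker = marker, trait = trait, additive = additive,
                 dominance = dominance, sex_modifier = sex_modifier,
                 diet_modifier = diet_modifier), class = "qtl_spec")
}

#' @rdname qtl_spec
#' @export
epistasis_spec <- function(marker_a, marker_b, trait, effect,
                           condition = function(ga, gb) ga == 0 & gb >= 1,
                           stratum = NULL) {
  stopifnot(marker_a != marker_b, is.finite(effect))
  structure(list(marker_a = marker_a, marker_b = marker_b, trait = trait,
                 effect = effect, condition = condition, stratum = stratum),
            class = "epistasis_spec")
}

#' @rdname qtl_spec
#' @export
pleiotropy_spec <- function(locus, upstream, downstream, lambda) {
  stopifnot(is.finite(lambda))
  structure(list(locus = locus, upstream = upstream, downstream = downstream,
                 lambda = lambda), class = "pleiotropy_spec")
}

#' Trait architecture for the cross simulator
#'
#' Per-trait generative parameters: `intercept` is the trait mean for
#' females on the American diet with all-B6 genotype background,
#' `sex_effect` the male deviation, `diet_effect` the ketogenic deviation,
#' `sexdiet_effect` the extra male-on-ketogenic deviation, and `noise_sd`
#' the environmental (residual) standard deviation. `polygenic_sd` is the
#' SD of an unmapped polygenic background value: it is drawn per
#' individual in segregating (F2) populations and is absent in the
#' genetically uniform parental/F1 cohorts, so it contributes to
#' broad-sense heritability without being attributable to any marker —
#' emulating the many small-effect loci a sparse QTL architecture leaves
#' unmodelled.
#'
#' @param intercept,sex_effect,diet_effect,sexdiet_effect trait units.
#' @param noise_sd positive residual SD in trait units.
#' @param polygenic_sd SD of the unmapped genetic background in
#'   segregating populations (default 0).
#' @return a `trait_spec` list.
#' @export
trait_spec <- function(intercept = 0, sex_effect = 0, diet_effect = 0,
                       sexdiet_effect = 0, noise_sd = 1, polygenic_sd = 0) {
  stopifnot(noise_sd > 0, polygenic_sd >= 0)
  structure(list(intercept = intercept, sex_effect = sex_effect,
                 diet_effect = diet_effect, sexdiet_effect = sexdiet_effect,
                 noise_sd = noise_sd, polygenic_sd = polygenic_sd),
            class = "trait_spec")
}

#' Full cross-simulation configuration
#'
#' Bundles the genetic map, cohort sizes, trait architectures, locus
#' effects and the missing-data rate into one validated object consumed by
#' [simulate_cross()], [simulate_phenotypes()] and
#' [simulate_line_cohorts()].
#'
#' @param map a `genetic_map`.
#' @param n_f2 number of F2 individuals.
#' @param n_per_line_cohort individuals per parental/F1 cohort.
#' @param traits named list of [trait_spec()]s.
#' @param qtls list of [qtl_spec()]s.
#' @param epistases list of [epistasis_spec()]s.
#' @param pleiotropy a [pleiotropy_spec()] or `NULL`.
#' @param missing_rate fraction of genotype calls masked to missing.
#' @return a `cross_sim_config` list.
#' @export
cross_sim_config <- function(map, n_f2 = 469, n_per_line_cohort = 20,
                             traits, qtls = list(), epistases = list(),
                             pleiotropy = NULL, missing_rate = 0) {
  stopifnot(n_f2 > 0, n_per_line_cohort > 0,
            missing_rate >= 0, missing_rate < 1,
            length(traits) > 0, !is.null(names(traits)))
  for (q in qtls)
    if (!q$marker %in% map$marker)
      stop("QTL marker not in map: ", q$marker)
  for (e in epistases)
    if (!all(c(e$marker_a, e$marker_b) %in% map$marker))
      stop("epistasis marker not in map: ", e$marker_a, "/", e$marker_b)
  for (q in qtls)
    if (!q$trait %in% names(traits)) stop("unknown trait in QTL spec: ", q$trait)
  if (!is.null(pleiotropy) &&
      !all(c(pleiotropy$upstream, pleiotropy$downstream) %in% names(traits)))
    stop("unknown trait name in pleiotropy spec")
  structure(list(map = map, n_f2 = n_f2,
                 n_per_line_cohort = n_per_line_cohort, traits = traits,
                 qtls = qtls, epistases = epistases, pleiotropy = pleiotropy,
                 missing_rate = missing_rate),
            class = "cross_sim_config")
}

#' Marker nearest a relative chromosome position
#'
#' @param map a `genetic_map`.
#' @param chrom chromosome label.
#' @param frac relative position along the chromosome in \[0, 1\].
#' @return the marker name.
#' @export
marker_near <- function(map, chrom, frac) {
  sub <- map[map$chrom == chrom, ]
  if (nrow(sub) == 0) stop("no markers on chromosome ", chrom)
  sub$marker[which.min(abs(sub$pos_cm - frac * max(sub$pos_cm)))]
}

# genetic value contributed by one QTL; missing genotypes contribute the
# population-mean effect (x = 0, heterozygote share 1/2)
qtl_value <- function(q, g, sex, diet) {
  x <- ifelse(is.na(g), 0, g - 1)
  h <- ifelse(is.na(g), 0.5, as.numeric(g == 1L))
  mod <- ifelse(sex == "M", q$sex_modifier, 1) *
    ifelse(diet == "ketogenic", q$diet_modifier, 1)
  mod * (q$additive * x + q$dominance * h)
}

simulate_traits <- function(config, calls, sex, diet, segregating = TRUE) {
  n <- length(sex)
  traits <- config$traits
  order_names <- names(traits)
  pl <- config$pleiotropy
  if (!is.null(pl)) {
    # upstream trait must be generated before its downstream target
    order_names <- c(pl$upstream, setdiff(order_names, pl$upstream))
  }
  out <- matrix(NA_real_, n, length(traits),
                dimnames = list(NULL, names(traits)))
  for (tn in order_names) {
    ts <- traits[[tn]]
    y <- ts$intercept +
      ts$sex_effect * (sex == "M") +
      ts$diet_effect * (diet == "ketogenic") +
      ts$sexdiet_effect * (sex == "M") * (diet == "ketogenic")
    for (q in config$qtls)
      if (q$trait == tn)
        y <- y + qtl_value(q, calls[, q$marker], sex, diet)
    for (e in config$epistases)
      if (e$trait == tn) {
        ga <- calls[, e$marker_a]; gb <- calls[, e$marker_b]
        hit <- !is.na(ga) & !is.na(gb) & e$condition(ga, gb)
        if (!is.null(e$stratum)) {
          if (!is.null(e$stratum$sex)) hit <- hit & sex == e$stratum$sex
          if (!is.null(e$stratum$diet)) hit <- hit & diet == e$stratum$diet
        }
        y <- y + e$effect * hit
      }
    if (!is.null(pl) && pl$downstream == tn)
      y <- y + pl$lambda * out[, pl$upstream]
    if (segregating && ts$polygenic_sd > 0)
      y <- y + rnorm(n, 0, ts$polygenic_sd)
    out[, tn] <- y + rnorm(n, 0, ts$noise_sd)
  }
  out
}

#' Simulate F2 phenotypes
#'
#' Assigns sex and diet by balanced Bernoulli(1/2) draws and generates each
#' trait as intercept + sex/diet/sex:diet effects + QTL effects (additive +
#' dominance, scaled by the locus sex/diet modifiers) + epistatic terms +
#' the pleiotropic contribution of the upstream trait + Gaussian noise.
#' Missing genotypes at a QTL contribute the population-mean effect.
#'
#' @param geno a `genotype_matrix` (unmasked or masked).
#' @param config a [cross_sim_config()].
#' @param seed optional RNG seed.
#' @return a `phenotype_table`: data frame with `id`, `generation`, `sex`,
#'   `diet` and one column per trait.
#' @export
simulate_phenotypes <- function(geno, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(geno$calls)
  sex <- ifelse(runif(n) < 0.5, "F", "M")
  diet <- ifelse(runif(n) < 0.5, "american", "ketogenic")
  tr <- simulate_traits(config, geno$calls, sex, diet)
  out <- data.frame(id = rownames(geno$calls), generation = "F2",
                    sex = sex, diet = diet, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(tr))
  class(out) <- c("phenotype_table", "data.frame")
  out
}

#' Simulate parental and F1 cohorts
#'
#' B6, FVB and F1 cohorts have zero within-cohort genetic variance: every
#' individual carries the homozygous-B6 (0), homozygous-FVB (2) or uniformly
#' heterozygous (1) genotype at all markers, so trait values are the cohort
#' genetic mean plus sex/diet effects plus environmental noise. The F1
#' cohort variance therefore estimates the environmental variance used by
#' [broad_sense_heritability()].
#'
#' @inheritParams simulate_phenotypes
#' @return a `phenotype_table` with generations B6, FVB and F1.
#' @export
simulate_line_cohorts <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_per_line_cohort
  M <- nrow(config$map)
  one <- function(gen, code) {
    calls <- matrix(code, n, M, dimnames = list(
      sprintf("%s_%03d", gen, seq_len(n)), config$map$marker))
    storage.mode(calls) <- "integer"
    sex <- ifelse(runif(n) < 0.5, "F", "M")
    diet <- ifelse(runif(n) < 0.5, "american", "ketogenic")
    tr <- simulate_traits(config, calls, sex, diet, segregating = FALSE)
    out <- data.frame(id = rownames(calls), generation = gen, sex = sex,
                      diet = diet, stringsAsFactors = FALSE)
    cbind(out, as.data.frame(tr))
  }
  out <- rbind(one("B6", 0L), one("FVB", 2L), one("F1", 1L))
  class(out) <- c("phenotype_table", "data.frame")
  out
}

#' Simulate a complete diet-response cross
#'
#' One-call generator: F2 genotypes from the configured map, masked at the
#' configured missing rate, F2 phenotypes under the configured trait
#' architecture, and parental/F1 cohorts.
#'
#' @param config a [cross_sim_config()].
#' @param seed RNG seed governing every random draw.
#' @return list with elements `map`, `geno`, `pheno` (F2) and `cohorts`.
#' @export
simulate_cross <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  geno <- simulate_f2(config$map, config$n_f2)
  pheno <- simulate_phenotypes(geno, config)
  geno <- mask_missing(geno, config$missing_rate)
  cohorts <- simulate_line_cohorts(config)
  list(map = config$map, geno = geno, pheno = pheno, cohorts = cohorts)
}

#' Study-scale default simulation configuration
#'
#' The default configuration mirrors the scale and inferred genetic
#' architecture of a B6xFVB diet-response intercross: 469 F2s on 1667
#' markers over 20 linkage groups totalling 1400 cM; fat mass gain (g)
#' with three QTLs (one shared with serum HDL via a pleiotropic chain, one
#' male/ketogenic-amplified, one dominant-acting), lean mass gain (g)
#' sharing the chromosome-5 locus, serum HDL (ng/mL) with one strong
#' additive locus; one epistatic locus pair acting in ketogenic males; 2%
#' missing genotype calls.
#'
#' @param n_f2 number of F2 individuals.
#' @param n_markers marker count.
#' @param missing_rate genotype missingness fraction.
#' @return a [cross_sim_config()].
#' @export
default_cross_config <- function(n_f2 = 469, n_markers = 1667,
                                 missing_rate = 0.02) {
  map <- build_map(n_markers)
  fmgq1 <- marker_near(map, "1", 0.90)
  hdlq1 <- marker_near(map, "1", 0.78)
  fmgq2 <- marker_near(map, "5", 0.55)
  fmgq3 <- marker_near(map, "7", 0.40)
  traits <- list(
    fat_mass_gain = trait_spec(intercept = 4.5, sex_effect = 3.7,
                               noise_sd = 2.0, polygenic_sd = 3.2),
    lean_mass_gain = trait_spec(intercept = 5.5, sex_effect = 3.5,
                                diet_effect = -0.5, sexdiet_effect = -1.3,
                                noise_sd = 1.4, polygenic_sd = 2.0),
    hdl = trait_spec(intercept = 157.6, sex_effect = 44, diet_effect = -8,
                     noise_sd = 40, polygenic_sd = 20))
  qtls <- list(
    qtl_spec(fmgq1, "fat_mass_gain", additive = 1.16, dominance = 0.28),
    qtl_spec(fmgq2, "fat_mass_gain", additive = -0.65, dominance = -0.20,
             sex_modifier = 2.0, diet_modifier = 2.0),
    qtl_spec(fmgq3, "fat_mass_gain", additive = -0.85, dominance = 1.08),
    qtl_spec(fmgq2, "lean_mass_gain", additive = -0.40, dominance = 0.02,
             sex_modifier = 1.8, diet_modifier = 1.8),
    qtl_spec(hdlq1, "hdl", additive = 24.0, dominance = 2.88))
  epi <- list(epistasis_spec(fmgq2, fmgq1, "fat_mass_gain", effect = 5,
                             condition = function(ga, gb) ga == 0 & gb >= 1,
                             stratum = list(sex = "M", diet = "ketogenic")))
  cross_sim_config(map, n_f2 = n_f2, n_per_line_cohort = 20, traits = traits,
                   qtls = qtls, epistases = epi,
                   pleiotropy = pleiotropy_spec(hdlq1, "hdl", "fat_mass_gain",
                                                lambda = 0.01),
                   missing_rate = missing_rate)
}
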