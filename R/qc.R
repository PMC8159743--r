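# Pre-analysis quality control: iterative sex-stratified outlier removal,
# marker filtering, and covariate-adjusted trait correlations.

trait_columns <- function(pheno, traits = NULL) {
  reserved <- c("id", "generation", "sex", "diet")
  if (is.null(traits)) {
    num <- vapply(pheno, is.numeric, logical(1))
    traits <- setdiff(names(pheno)[num], reserved)
  }
  missing <- setdiff(traits, names(pheno))
  if (length(missing)) stop("unknown trait(s): ", paste(missing, collapse = ", "))
  traits
}

#' Iterative outlier removal
#'
#' Within each group (by default each sex) and each trait, values more than
#' `k` sample standard deviations from the group mean are set to missing;
#' the group mean and SD are then recomputed and the rule reapplied until
#' no value qualifies. The boundary is strict (exactly `k` SD is
#' retained). Groups with fewer than 3 non-missing values are skipped with
#' a warning; a zero group SD removes nothing.
#'
#' @param pheno a `phenotype_table`.
#' @param k SD multiplier (default 3).
#' @param group_keys grouping columns (default `"sex"`).
#' @param traits trait columns to screen; default all numeric traits.
#' @return list with `pheno` (values masked to `NA`) and `report`, a data
#'   frame of removals (`trait`, `group`, `id`, `value`, `iteration`).
#' @export
remove_outliers_iterative <- function(pheno, k = 3, group_keys = "sex",
                                      traits = NULL) {
  stopifnot(k > 0)
  traits <- trait_columns(pheno, traits)
  grp <- interaction(pheno[group_keys], drop = TRUE, sep = ":")
  report <- list()
  for (tr in traits) {
    for (g in levels(grp)) {
      rows <- which(grp == g)
      if (sum(!is.na(pheno[[tr]][rows])) < 3) {
        warning("group ", g, " has fewer than 3 non-missing values for ",
                tr, "; skipped", call. = FALSE)
        next
      }
      iter <- 0L
      repeat {
        iter <- iter + 1L
        v <- pheno[[tr]][rows]
        m <- mean(v, na.rm = TRUE)
        s <- sd(v, na.rm = TRUE)
        if (!is.finite(s) || s == 0) break
        out <- which(!is.na(v) & abs(v - m) > k * s)
        if (length(out) == 0) break
        report[[length(report) + 1L]] <- data.frame(
          trait = tr, group = g, id = pheno$id[rows[out]],
          value = v[out], iteration = iter, stringsAsFactors = FALSE)
        pheno[[tr]][rows[out]] <- NA_real_
      }
    }
  }
  report <- if (length(report)) do.call(rbind, report) else
    data.frame(trait = character(), group = character(), id = character(),
               value = numeric(), iteration = integer(),
               stringsAsFactors = FALSE)
  rownames(report) <- NULL
  list(pheno = pheno, report = report)
}

#' Filter uninformative markers
#'
#' Drops markers with a single observed genotype class (monomorphic, the
#' non-segregating-marker rule) or with a missing-call fraction above
#' `max_missing`; the map is subset accordingly and marker order is
#' preserved.
#'
#' @param geno a `genotype_matrix`.
#' @param max_missing maximum tolerated missing fraction (default 0.1).
#' @return list with the filtered `geno` and a `report` data frame
#'   (`marker`, `reason` in \{"monomorphic", "excess-missing"\}).
#' @export
filter_markers <- function(geno, max_missing = 0.1) {
  calls <- geno$calls
  miss <- colMeans(is.na(calls))
  ncls <- apply(calls, 2, function(g) length(unique(g[!is.na(g)])))
  reason <- rep(NA_character_, ncol(calls))
  reason[ncls <= 1] <- "monomorphic"
  reason[miss > max_missing] <- "excess-missing"
  drop <- !is.na(reason)
  if (all(drop)) stop("all ", ncol(calls), " markers removed by filtering (",
                      sum(reason == "monomorphic", na.rm = TRUE),
                      " monomorphic, ",
                      sum(reason == "excess-missing", na.rm = TRUE),
                      " excess-missing)")
  report <- data.frame(marker = colnames(calls)[drop], reason = reason[drop],
                       stringsAsFactors = FALSE)
  geno$calls <- calls[, !drop, drop = FALSE]
  geno$map <- geno$map[geno$map$marker %in% colnames(geno$calls), ]
  rownames(geno$map) <- NULL
  list(geno = geno, report = report)
}

#' Covariate-adjusted trait correlations
#'
#' Residualizes each trait on sex + diet (+ their interaction) by least
#' squares and returns the matrix of pairwise Pearson correlations of the
#' residuals on pairwise-complete rows.
#'
#' @param pheno a `phenotype_table`.
#' @param traits traits to correlate; default all numeric traits.
#' @param include_interaction include the sex:diet term (default `TRUE`).
#' @return symmetric correlation matrix with unit diagonal; undefined
#'   entries (constant residuals) are `NA`.
#' @export
residual_correlations <- function(pheno, traits = NULL,
                                  include_interaction = TRUE) {
  traits <- trait_columns(pheno, traits)
  fml <- if (include_interaction) ~ sex * diet else ~ sex + diet
  res <- sapply(traits, function(tr) {
    ok <- complete.cases(pheno[[tr]], pheno$sex, pheno$diet)
    if (sum(ok) < 3) stop("fewer than 3 complete observations for ", tr)
    r <- rep(NA_real_, nrow(pheno))
    X <- model.matrix(fml, pheno[ok, ])
    r[ok] <- lm.fit(X, pheno[[tr]][ok])$residuals
    r
  })
  suppressWarnings(cr <- stats::cor(res, use = "pairwise.complete.obs"))
  diag(cr) <- 1
  cr
}
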