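# Observed-variable path analysis: per-equation least squares on
# standardized outcomes and predictors, significance-based pruning, and
# last-entry per-predictor variance shares, plus residual correlations for
# declared outcome pairs.

#' Path-model specification
#'
#' A recursive observed-variable path model: a list of regression
#' equations (outcome plus predictors drawn from `sex`, `diet`,
#' `sex:diet`, marker names and other traits) and optional residual
#' covariances between outcome pairs.
#'
#' @param equations list of `list(outcome = , predictors = )`.
#' @param residual_covariances list of character pairs of outcomes.
#' @return a `path_model_spec`.
#' @export
path_model_spec <- function(equations, residual_covariances = list()) {
  for (eq in equations) {
    stopifnot(is.character(eq$outcome), length(eq$outcome) == 1)
    if (eq$outcome %in% eq$predictors)
      stop("outcome ", eq$outcome, " predicts itself")
  }
  structure(list(equations = equations,
                 residual_covariances = residual_covariances),
            class = "path_model_spec")
}

# Resolve predictor columns: sex -> male indicator, diet -> ketogenic
# indicator, sex:diet -> their product, marker names -> additive
# (FVB-allele count) coding, anything else -> phenotype column.
resolve_variable <- function(name, pheno, G) {
  if (name == "sex") return(as.numeric(pheno$sex == "M"))
  if (name == "diet") return(as.numeric(pheno$diet == "ketogenic"))
  if (name %in% c("sex:diet", "sex*diet"))
    return(as.numeric(pheno$sex == "M") *
             as.numeric(pheno$diet == "ketogenic"))
  if (!is.null(G) && name %in% colnames(G)) return(as.numeric(G[, name]))
  if (name %in% names(pheno)) return(pheno[[name]])
  stop("unknown predictor: ", name)
}

fit_one_equation <- function(eq, pheno, G) {
  y <- resolve_variable(eq$outcome, pheno, G)
  Xr <- sapply(eq$predictors, resolve_variable, pheno = pheno, G = G)
  Xr <- matrix(Xr, ncol = length(eq$predictors),
               dimnames = list(NULL, eq$predictors))
  ok <- complete.cases(cbind(y, Xr))
  y <- y[ok]; Xr <- Xr[ok, , drop = FALSE]
  ys <- as.numeric(scale(y))
  Xs <- scale(Xr)
  if (any(attr(Xs, "scaled:scale") == 0))
    stop("constant predictor in equation for ", eq$outcome, ": ",
         paste(eq$predictors[attr(Xs, "scaled:scale") == 0], collapse = ", "))
  dat <- data.frame(.y = ys, Xs, check.names = FALSE)
  fml <- as.formula(paste(".y ~", paste(sprintf("`%s`", eq$predictors),
                                        collapse = " + ")))
  fit <- lm(fml, data = dat)
  if (anyNA(coef(fit)))
    stop("rank-deficient design in equation for ", eq$outcome,
         " (collinear: ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "), ")")
  sm <- summary(fit)$coefficients
  idx <- 2:(length(eq$predictors) + 1)
  shares <- variance_shares_fit(y, Xr)
  paths <- data.frame(
    outcome = eq$outcome, predictor = eq$predictors,
    coefficient = unname(sm[idx, "Estimate"]),
    t_stat = unname(sm[idx, "t value"]),
    p = unname(sm[idx, "Pr(>|t|)"]),
    pct_var = shares, stringsAsFactors = FALSE)
  list(paths = paths, n = length(ys),
       total_pct = 100 * summary(fit)$r.squared,
       ok = ok, res = resid(fit))
}

# last-entry variance shares on the raw (unstandardized) data; SS ratios
# are invariant to the standardization used for the path coefficients
variance_shares_fit <- function(y, X) {
  sst <- sum((y - mean(y))^2)
  Xf <- cbind(1, X)
  rss_full <- sum(lm.fit(Xf, y)$residuals^2)
  vapply(seq_len(ncol(X)), function(j) {
    rss_red <- sum(lm.fit(Xf[, -(j + 1), drop = FALSE], y)$residuals^2)
    100 * (rss_red - rss_full) / sst
  }, numeric(1))
}

#' Fit an observed-variable path model
#'
#' Each equation is fitted by least squares on z-scored outcome and
#' predictors (markers coded additively as FVB-allele counts before
#' standardization), so coefficients are standardized path coefficients;
#' per-path variance shares are last-entry shares from
#' [predictor_variance_shares()]. Residual correlations are computed for
#' each declared outcome pair on their common complete rows.
#'
#' @param spec a [path_model_spec()].
#' @param pheno a `phenotype_table`.
#' @param geno a `genotype_matrix` (may be `NULL` if no marker predictors).
#' @return a `path_fit`: list with `paths` (one row per path:
#'   standardized coefficient, t, p, percent variance), `outcomes` (per
#'   equation n and total percent variance explained), and
#'   `residual_correlations`.
#' @export
fit_path_model <- function(spec, pheno, geno = NULL) {
  G <- if (is.null(geno)) NULL else align_geno(geno, pheno$id)
  if (length(spec$equations) == 0)
    return(structure(list(paths = data.frame(), outcomes = data.frame(),
                          residual_correlations = data.frame()),
                     class = "path_fit"))
  fits <- lapply(spec$equations, fit_one_equation, pheno = pheno, G = G)
  paths <- do.call(rbind, lapply(fits, `[[`, "paths"))
  rownames(paths) <- NULL
  outcomes <- data.frame(
    outcome = vapply(spec$equations, `[[`, "", "outcome"),
    n = vapply(fits, `[[`, 0, "n"),
    total_pct_var = vapply(fits, `[[`, 0, "total_pct"),
    stringsAsFactors = FALSE)
  rc <- lapply(spec$residual_covariances, function(pr) {
    i <- match(pr[1], outcomes$outcome); j <- match(pr[2], outcomes$outcome)
    if (is.na(i) || is.na(j)) stop("residual covariance names unknown outcome")
    ri <- rep(NA_real_, nrow(pheno)); ri[fits[[i]]$ok] <- fits[[i]]$res
    rj <- rep(NA_real_, nrow(pheno)); rj[fits[[j]]$ok] <- fits[[j]]$res
    data.frame(outcome_a = pr[1], outcome_b = pr[2],
               r = stats::cor(ri, rj, use = "pairwise.complete.obs"),
               stringsAsFactors = FALSE)
  })
  rc <- if (length(rc)) do.call(rbind, rc) else
    data.frame(outcome_a = character(), outcome_b = character(),
               r = numeric())
  structure(list(paths = paths, outcomes = outcomes,
                 residual_correlations = rc),
            class = "path_fit")
}

#' @export
print.path_fit <- function(x, ...) {
  if (nrow(x$paths) == 0) { cat("Empty path model\n"); return(invisible(x)) }
  cat("Path model fit:\n")
  df <- x$paths
  df$coefficient <- sprintf("%.2f (%.2f%%)", df$coefficient, df$pct_var)
  print(df[c("outcome", "predictor", "coefficient", "t_stat", "p")],
        row.names = FALSE)
  for (i in seq_len(nrow(x$outcomes)))
    cat(sprintf("  %s: %.2f%% of variation explained (n = %d)\n",
                x$outcomes$outcome[i], x$outcomes$total_pct_var[i],
                x$outcomes$n[i]))
  if (nrow(x$residual_correlations))
    for (i in seq_len(nrow(x$residual_correlations)))
      cat(sprintf("  residual r(%s, %s) = %.3f\n",
                  x$residual_correlations$outcome_a[i],
                  x$residual_correlations$outcome_b[i],
                  x$residual_correlations$r[i]))
  invisible(x)
}

#' Prune non-significant paths
#'
#' Iteratively removes the least significant path with p > alpha (largest
#' p first; ties broken by declaration order) and refits, until every
#' retained path is significant. Equations whose predictors are all
#' removed are dropped.
#'
#' @inheritParams fit_path_model
#' @param alpha retention threshold on the per-path p-value.
#' @return list with the pruned `spec` and its `fit`.
#' @export
prune_paths <- function(spec, pheno, geno = NULL, alpha = 0.05) {
  repeat {
    if (length(spec$equations) == 0)
      return(list(spec = spec, fit = fit_path_model(spec, pheno, geno)))
    fit <- fit_path_model(spec, pheno, geno)
    bad <- which(fit$paths$p > alpha)
    if (length(bad) == 0) return(list(spec = spec, fit = fit))
    worst <- bad[which.max(fit$paths$p[bad])]  # first max in declaration order
    out_name <- fit$paths$outcome[worst]
    pred <- fit$paths$predictor[worst]
    for (i in seq_along(spec$equations)) {
      eq <- spec$equations[[i]]
      if (eq$outcome == out_name && pred %in% eq$predictors) {
        eq$predictors <- setdiff(eq$predictors, pred)
        spec$equations[[i]] <- eq
        break
      }
    }
    keep <- vapply(spec$equations, function(e) length(e$predictors) > 0,
                   logical(1))
    if (!all(keep))
      message("dropped equation(s) with no remaining predictors: ",
              paste(vapply(spec$equations[!keep], `[[`, "", "outcome"),
                    collapse = ", "))
    spec$equations <- spec$equations[keep]
    spec$residual_covariances <- Filter(function(pr) {
      all(pr %in% vapply(spec$equations, `[[`, "", "outcome"))
    }, spec$residual_covariances)
  }
}

#' Per-predictor variance shares
#'
#' For one equation, the share of each predictor is
#' 100 x (SS_model(all predictors) - SS_model(all minus this one)) /
#' SS_total(outcome) -- a last-entry (partial) share. Shares sum to the
#' total percent explained only when predictors are orthogonal.
#'
#' @inheritParams fit_path_model
#' @param outcome outcome name.
#' @param predictors character vector of predictors.
#' @return named numeric vector of percentages.
#' @export
predictor_variance_shares <- function(pheno, geno = NULL, outcome,
                                      predictors) {
  G <- if (is.null(geno)) NULL else align_geno(geno, pheno$id)
  y <- resolve_variable(outcome, pheno, G)
  X <- sapply(predictors, resolve_variable, pheno = pheno, G = G)
  X <- matrix(X, ncol = length(predictors),
              dimnames = list(NULL, predictors))
  ok <- complete.cases(cbind(y, X))
  setNames(variance_shares_fit(y[ok], X[ok, , drop = FALSE]), predictors)
}
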