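# Shared fixtures: small maps and crosses built in code at test time.

# one-chromosome map: `m` markers evenly spaced over `len` cM
single_chrom_map <- function(m = 51, len = 100) {
  build_map(m, chrom_lengths_cm = c("1" = len))
}

# minimal phenotype table wrapped around externally built columns
make_pheno <- function(n, sex = NULL, diet = NULL, ...) {
  if (is.null(sex)) sex <- rep(c("F", "M"), length.out = n)
  if (is.null(diet)) diet <- rep(c("american", "ketogenic"), each = 2,
                                 length.out = n)
  out <- data.frame(id = sprintf("F2_%04d", seq_len(n)), generation = "F2",
                    sex = sex, diet = diet, ..., stringsAsFactors = FALSE)
  class(out) <- c("phenotype_table", "data.frame")
  out
}

# genotype_matrix from a bare matrix of 0/1/2 codes
make_geno <- function(calls, map) {
  storage.mode(calls) <- "integer"
  rownames(calls) <- sprintf("F2_%04d", seq_len(nrow(calls)))
  colnames(calls) <- map$marker
  structure(list(ids = rownames(calls), calls = calls, map = map),
            class = "genotype_matrix")
}

# independent 1:2:1 genotypes at a single locus
draw_f2_locus <- function(n) sample(0:2, n, replace = TRUE,
                                    prob = c(0.25, 0.5, 0.25))

# brute-force partial-F oracle via explicit normal equations
oracle_partial_f <- function(y, X, g) {
  ok <- !is.na(y) & !is.na(g) & stats::complete.cases(X)
  y <- y[ok]; X <- X[ok, , drop = FALSE]; g <- g[ok]
  cls <- sort(unique(g))
  D <- sapply(cls[-1], function(cl) as.numeric(g == cl))
  rss <- function(A) {
    b <- solve(crossprod(A), crossprod(A, y))
    sum((y - A %*% b)^2)
  }
  rss0 <- rss(X); rss1 <- rss(cbind(X, D))
  df1 <- ncol(D); df2 <- length(y) - ncol(X) - df1
  f <- ((rss0 - rss1) / df1) / (rss1 / df2)
  b1 <- solve(crossprod(cbind(X, D)), crossprod(cbind(X, D), y))
  list(f = f, p = pf(f, df1, df2, lower.tail = FALSE),
       lod = -pf(f, df1, df2, lower.tail = FALSE, log.p = TRUE) / log(10),
       effects = as.numeric(utils::tail(b1, df1)))
}
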