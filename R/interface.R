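# File I/O for the cross (native CSV dialect and the R/qtl "csvs"
# rotated-cross dialect) and the end-to-end pipeline driver.
#
# CSV dialect: comma-separated, UTF-8, "." decimal, "NA" for missing.
# Marker order is always map order.

#' Write a cross to CSV files
#'
#' Writes `<prefix>_pheno.csv` (id, generation, sex, diet, traits),
#' `<prefix>_geno.csv` (id plus one BB/BF/FF column per marker, `NA` for
#' missing) and `<prefix>_map.csv` (marker, chrom, pos_mb, pos_cm).
#'
#' @param pheno a `phenotype_table`.
#' @param geno a `genotype_matrix`.
#' @param map a `genetic_map`.
#' @param prefix output path prefix.
#' @return invisibly, the three file paths.
#' @export
write_cross <- function(pheno, geno, map, prefix) {
  paths <- paste0(prefix, c("_pheno.csv", "_geno.csv", "_map.csv"))
  write.csv(pheno, paths[1], row.names = FALSE, quote = FALSE)
  gdf <- data.frame(id = rownames(geno$calls),
                    matrix(geno_labels(geno$calls), nrow(geno$calls),
                           dimnames = list(NULL, colnames(geno$calls))),
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(gdf, paths[2], row.names = FALSE, quote = FALSE)
  write.csv(as.data.frame(map), paths[3], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Read a cross from CSV files
#'
#' Reads and cross-validates the phenotype, genotype and map files written
#' by [write_cross()] (genotype codes BB/BF/FF, 0/1/2 and A/H/B are all
#' accepted). Duplicate ids, unknown genotype codes (reported with file,
#' row and column) and genotype markers absent from the map are distinct
#' errors; ids present in only one of the phenotype/genotype files are
#' reported in a warning.
#'
#' @param pheno_path,geno_path,map_path file paths.
#' @return list with `pheno`, `geno`, `map`.
#' @export
read_cross <- function(pheno_path, geno_path, map_path) {
  map <- read.csv(map_path, stringsAsFactors = FALSE,
                  colClasses = c(chrom = "character"))
  stopifnot(all(c("marker", "chrom", "pos_mb", "pos_cm") %in% names(map)))
  if (anyDuplicated(map$marker))
    stop("duplicate marker names in ", map_path)
  map <- map[order(factor(map$chrom, unique(map$chrom)), map$pos_cm), ]
  rownames(map) <- NULL
  class(map) <- c("genetic_map", "data.frame")

  pheno <- read.csv(pheno_path, stringsAsFactors = FALSE)
  if (anyDuplicated(pheno$id))
    stop("duplicate individual ids in ", pheno_path)
  class(pheno) <- c("phenotype_table", "data.frame")

  graw <- read.csv(geno_path, stringsAsFactors = FALSE,
                   colClasses = "character")
  if (names(graw)[1] != "id") stop("first genotype column must be 'id'")
  if (anyDuplicated(graw$id))
    stop("duplicate individual ids in ", geno_path)
  markers <- names(graw)[-1]
  extra <- setdiff(markers, map$marker)
  if (length(extra))
    stop("genotype marker(s) absent from map: ",
         paste(utils::head(extra, 5), collapse = ", "))
  calls <- matrix(NA_integer_, nrow(graw), length(markers),
                  dimnames = list(graw$id, markers))
  for (j in seq_along(markers)) {
    v <- graw[[j + 1]]
    codes <- tryCatch(geno_codes(v), error = function(e) e)
    if (inherits(codes, "error")) {
      bad <- which(!v %in% c("BB", "BF", "FB", "FF", "0", "1", "2",
                             "A", "H", "B", "", "NA") & !is.na(v))[1]
      stop("unknown genotype code '", v[bad], "' in ", geno_path,
           ", row ", bad, ", column ", markers[j])
    }
    calls[, j] <- codes
  }
  map_sub <- map[map$marker %in% markers, ]
  calls <- calls[, map_sub$marker, drop = FALSE]  # map order wins
  geno <- new_genotype_matrix(calls, map_sub)
  only_p <- setdiff(pheno$id, graw$id)
  only_g <- setdiff(graw$id, pheno$id)
  if (length(only_p) || length(only_g))
    warning(length(only_p), " id(s) only in phenotypes, ", length(only_g),
            " only in genotypes", call. = FALSE)
  list(pheno = pheno, geno = geno, map = map_sub)
}

#' Export/import the R/qtl "csvs" dialect
#'
#' `write_cross_rqtl()` writes the rotated two-file comma-separated format
#' used by R/qtl's `read.cross(format = "csvs")`: a genotype file whose
#' marker columns carry the chromosome and cM position in the second and
#' third rows and A/H/B genotype codes below, and a phenotype file sharing
#' the id column. `read_cross_rqtl()` reads that layout back into native
#' objects (Mb positions are reconstructed from cM at `mb_per_cm`).
#'
#' @inheritParams write_cross
#' @param genfile,phefile file paths of the genotype and phenotype csvs.
#' @param mb_per_cm Mb/cM scale used to reconstruct physical positions.
#' @return `write_cross_rqtl()` the two paths, invisibly;
#'   `read_cross_rqtl()` a list with `pheno`, `geno`, `map`.
#' @export
write_cross_rqtl <- function(pheno, geno, map, prefix) {
  genfile <- paste0(prefix, "_rqtl_gen.csv")
  phefile <- paste0(prefix, "_rqtl_phe.csv")
  lab <- matrix(c("A", "H", "B")[geno$calls + 1L], nrow(geno$calls))
  lab[is.na(lab)] <- "-"
  body <- cbind(rownames(geno$calls), lab)
  header <- c("id", map$marker)
  chrow <- c("", map$chrom)
  posrow <- c("", format(map$pos_cm, trim = TRUE, digits = 10))
  con <- file(genfile, "w")
  writeLines(paste(header, collapse = ","), con)
  writeLines(paste(chrow, collapse = ","), con)
  writeLines(paste(posrow, collapse = ","), con)
  utils::write.table(body, con, sep = ",", col.names = FALSE,
                     row.names = FALSE, quote = FALSE)
  close(con)
  write.csv(pheno, phefile, row.names = FALSE, quote = FALSE)
  invisible(c(genfile, phefile))
}

#' @rdname write_cross_rqtl
#' @export
read_cross_rqtl <- function(genfile, phefile, mb_per_cm = 1.8) {
  raw <- read.csv(genfile, header = FALSE, stringsAsFactors = FALSE,
                  colClasses = "character")
  markers <- as.character(raw[1, -1])
  map <- data.frame(marker = markers,
                    chrom = as.character(raw[2, -1]),
                    pos_cm = as.numeric(raw[3, -1]),
                    stringsAsFactors = FALSE)
  map$pos_mb <- map$pos_cm * mb_per_cm
  map <- map[c("marker", "chrom", "pos_mb", "pos_cm")]
  class(map) <- c("genetic_map", "data.frame")
  body <- raw[-(1:3), , drop = FALSE]
  lut <- c(A = 0L, H = 1L, B = 2L)
  calls <- matrix(NA_integer_, nrow(body), length(markers),
                  dimnames = list(body[[1]], markers))
  for (j in seq_along(markers)) {
    v <- body[[j + 1]]
    codes <- unname(lut[v])
    bad <- !v %in% c("A", "H", "B", "-", "", "NA")
    if (any(bad))
      stop("unknown genotype code '", v[which(bad)[1]], "' in ", genfile,
           ", row ", which(bad)[1], ", column ", markers[j])
    calls[, j] <- codes
  }
  pheno <- read.csv(phefile, stringsAsFactors = FALSE)
  class(pheno) <- c("phenotype_table", "data.frame")
  list(pheno = pheno, geno = new_genotype_matrix(calls, map), map = map)
}

#' Run the full analysis pipeline
#'
#' Chains qc (iterative outlier removal, marker filtering), genome scans,
#' permutation thresholds, support intervals and variance explained for
#' each requested trait, plus optional conditioned-scan/causal stages,
#' into one report. Outputs are written under `out_dir` as CSV/JSON; the
#' same config and seed reproduce the same report.
#'
#' @param pheno,geno phenotype table and genotype matrix (F2 rows).
#' @param traits traits to scan.
#' @param formula covariate formula for the scans.
#' @param n_perm permutations for the thresholds (0 disables thresholds).
#' @param alphas genome-wide significance levels.
#' @param seed RNG seed, recorded in the report.
#' @param sd_k outlier SD multiplier.
#' @param max_missing marker missingness cut-off.
#' @param drop LOD support-interval drop.
#' @param condition_pairs optional list of `c(trait, conditioning_trait)`
#'   pairs for conditioned scans.
#' @param causal optional list `list(t1 = , t2 = , locus = )` for
#'   causal-network inference (locus defaults to the top marker of the
#'   t1 scan).
#' @param out_dir output directory, or `NULL` to skip writing files.
#' @return an `analysis_report` list: `qtl_table` (per significant QTL:
#'   chrom, interval markers, lod, effects, percent variance),
#'   `thresholds`, `scans`, `conditioned`, `causal`, `provenance`.
#' @export
run_pipeline <- function(pheno, geno, traits, formula = ~ sex * diet,
                         n_perm = 1000, alphas = c(0.05, 0.01), seed = 1,
                         sd_k = 3, max_missing = 0.1, drop = 1.5,
                         condition_pairs = NULL, causal = NULL,
                         out_dir = NULL) {
  set.seed(seed)
  qc_out <- remove_outliers_iterative(pheno, k = sd_k, traits = traits)
  pheno <- qc_out$pheno
  mk <- filter_markers(geno, max_missing = max_missing)
  geno <- mk$geno
  scans <- list(); thresholds <- list(); qtl_rows <- list()
  for (tr in traits) {
    sc <- genome_scan(pheno, geno, tr, formula)
    scans[[tr]] <- sc
    thr <- NULL
    if (n_perm > 0) {
      thr <- permutation_thresholds(pheno, geno, tr, formula,
                                    alphas = alphas, n_perm = n_perm,
                                    seed = seed)
      thresholds[[tr]] <- thr
      sig_chroms <- unique(sc$chrom[!is.na(sc$lod) &
                                      sc$lod > min(thr$thresholds)])
      for (ch in sig_chroms) {
        si <- support_interval(sc, ch, drop = drop)
        topm <- si$top_marker
        row <- data.frame(
          trait = tr, chrom = ch,
          left_mb = si$left_mb, top_mb = si$top_mb, right_mb = si$right_mb,
          top_marker = topm, lod = si$lod,
          significance = if (si$lod > max(thr$thresholds)) "high" else
            "significant",
          effect_het = sc$effect_het[sc$marker == topm],
          effect_fvb = sc$effect_fvb[sc$marker == topm],
          pct_var = variance_explained(pheno, geno, tr, topm, formula),
          stringsAsFactors = FALSE)
        qtl_rows[[length(qtl_rows) + 1]] <- row
      }
    }
  }
  qtl_table <- if (length(qtl_rows)) do.call(rbind, qtl_rows) else
    data.frame()
  conditioned <- lapply(condition_pairs, function(pr) {
    cs <- conditioned_scan(pheno, geno, pr[1], pr[2], formula)
    cs$delta$trait <- pr[1]; cs$delta$conditioned_on <- pr[2]
    cs$delta
  })
  conditioned <- if (length(conditioned)) do.call(rbind, conditioned) else
    NULL
  causal_rep <- NULL
  if (!is.null(causal)) {
    locus <- causal$locus
    if (is.null(locus)) {
      sc <- scans[[causal$t1]]
      locus <- sc$marker[which.max(sc$lod)]
    }
    causal_rep <- causal_network_inference(pheno, geno, causal$t1,
                                           causal$t2, locus)
  }
  report <- list(qtl_table = qtl_table, thresholds = thresholds,
                 scans = scans, conditioned = conditioned,
                 causal = causal_rep, qc = qc_out$report,
                 markers_removed = mk$report,
                 provenance = list(seed = seed,
                                   formula = deparse(as_scan_formula(formula)),
                                   n_perm = n_perm,
                                   n_individuals = nrow(pheno),
                                   n_markers = ncol(geno$calls),
                                   package_version =
                                     as.character(utils::packageVersion("dietcross"))))
  class(report) <- "analysis_report"
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (nrow(qtl_table))
      write.csv(qtl_table, file.path(out_dir, "qtl_table.csv"),
                row.names = FALSE)
    for (tr in names(scans))
      write.csv(scans[[tr]], file.path(out_dir, paste0("scan_", tr, ".csv")),
                row.names = FALSE)
    if (!is.null(conditioned))
      write.csv(conditioned, file.path(out_dir, "conditioned_scans.csv"),
                row.names = FALSE)
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      prov <- report$provenance
      thr <- lapply(thresholds, function(t) as.list(t$thresholds))
      jsonlite::write_json(list(provenance = prov, thresholds = thr),
                           file.path(out_dir, "report.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Analysis report (seed", x$provenance$seed, "):",
      x$provenance$n_individuals, "individuals,",
      x$provenance$n_markers, "markers\n")
  if (nrow(x$qtl_table)) {
    cat("Significant QTLs:\n")
    print(x$qtl_table, row.names = FALSE)
  } else cat("No QTLs above threshold (or permutations disabled)\n")
  invisible(x)
}
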