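#' Load a genotype modality from a VCF file
#'
#' Reads biallelic genotypes from a VCF, counts alternate alleles per sample
#' to form the dosage matrix, and rescales the POS column to [0, 1].
#'
#' @param path path to an (uncompressed or gzipped) VCF file.
#' @param impute_missing if `TRUE`, missing genotypes are replaced by the
#'   marker mean dosage; otherwise missingness is an error.
#' @param modality_id label for the modality.
#' @return A [variant_function()].
#' @export
load_genotypes_vcf <- function(path, impute_missing = FALSE,
                               modality_id = "genotype") {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("package 'vcfR' is required to read VCF files")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0L) stop("no variant records in '", path, "'")
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi))
    stop("multi-allelic sites are not supported: ",
         paste(paste0(fix[multi, "CHROM"], ":", fix[multi, "POS"]),
               collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")
  alleles <- function(x) {
    a <- strsplit(x, "[/|]")
    vapply(a, function(ai) {
      if (any(ai == "." | is.na(ai))) NA_real_ else sum(ai == "1")
    }, numeric(1))
  }
  dosage <- t(apply(gt, 1L, alleles))  # markers x samples
  if (nrow(gt) == 1L) dosage <- matrix(dosage, nrow = 1L)
  dosage[is.na(gt)] <- NA_real_
  if (anyNA(dosage)) {
    if (!impute_missing)
      stop("missing genotypes present; rerun with impute_missing = TRUE ",
           "to mean-impute")
    for (j in seq_len(nrow(dosage))) {
      miss <- is.na(dosage[j, ])
      if (any(miss)) dosage[j, miss] <- mean(dosage[j, !miss])
    }
  }
  pos <- as.numeric(fix[, "POS"])
  ord <- order(pos)
  variant_function(t(dosage[ord, , drop = FALSE]), positions_bp = pos[ord],
                   modality_id = modality_id)
}

# Minimal biallelic VCF writer for simulated dosage matrices (0/1/2 coded as
# 0/0, 0/1, 1/1 on a synthetic contig).
write_genotypes_vcf <- function(ovf, path, contig = "sim1") {
  stopifnot(inherits(ovf, "variant_function"))
  g <- ovf$values
  if (!all(g %in% c(0, 1, 2)))
    stop("VCF export requires dosage values in {0, 1, 2}")
  pos <- ovf$positions_bp
  if (is.null(pos)) pos <- round(ovf$positions01 * 1e6) + 1
  n <- nrow(g); p <- ncol(g)
  gt_codes <- c("0/0", "0/1", "1/1")
  lines <- c("##fileformat=VCFv4.2",
             sprintf("##contig=<ID=%s>", contig),
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", sprintf("S%03d", seq_len(n))),
                   collapse = "\t"))
  body <- vapply(seq_len(p), function(j) {
    paste(c(contig, format(pos[j], scientific = FALSE),
            sprintf("var%d", j), "A", "T", ".", "PASS", ".", "GT",
            gt_codes[g[, j] + 1L]), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Export a simulated dataset to plain-text files
#'
#' Writes genotype modalities as VCF (GT field on a synthetic contig),
#' expression matrices and phenotypes as TSV, and the realized scenario
#' (specification plus coefficient draws) as a JSON sidecar.
#'
#' @param ds a [make_dataset()] result.
#' @param dir output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "sim_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (k in seq_along(ds$modalities)) {
    m <- ds$modalities[[k]]
    if (inherits(m, "variant_function")) {
      f <- file.path(dir, sprintf("modality%d_genotypes.vcf", k))
      write_genotypes_vcf(m, f, contig = sprintf("sim%d", k))
    } else {
      f <- file.path(dir, sprintf("modality%d_expression.tsv", k))
      utils::write.table(as.matrix(m), f, sep = "\t", row.names = FALSE,
                         col.names = sprintf("expr%d", seq_len(ncol(m))))
    }
    paths[sprintf("modality%d", k)] <- f
  }
  f <- file.path(dir, "phenotype.tsv")
  utils::write.table(ds$y, f, sep = "\t", row.names = FALSE,
                     col.names = sprintf("y%d", seq_len(ncol(ds$y))))
  paths["phenotype"] <- f
  f <- file.path(dir, "scenario.json")
  sidecar <- list(spec = unclass(ds$spec), seed = ds$seed, draws = ds$draws)
  writeLines(jsonlite::toJSON(sidecar, digits = NA, auto_unbox = TRUE,
                              null = "null"), f)
  paths["scenario"] <- f
  invisible(paths)
}
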