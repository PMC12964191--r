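#' Read a genotype matrix from VCF or PLINK dosage text
#'
#' Alt-allele dosages 0/1/2 are recoded to the symmetric -1/0/1 encoding
#' on read. Supported formats: VCF (plain or bgzipped, biallelic records,
#' GT field; parsed with \pkg{VariantAnnotation}), PLINK `.traw`
#' (variants as rows) and PLINK `.raw` (samples as rows). The dialect is
#' detected from the header when `format = "auto"`.
#'
#' Missing genotypes are rejected (the expected input is a complete
#' post-QC matrix); the error names the offending variant and sample.
#'
#' @param path File path.
#' @param format One of `"auto"`, `"vcf"`, `"traw"`, `"raw"`.
#' @return A [genotype_matrix].
#' @seealso [write_genotypes()]
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "traw", "raw")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- detect_genotype_format(path)
  }
  switch(format,
         vcf = read_genotypes_vcf(path),
         traw = read_genotypes_traw(path),
         raw = read_genotypes_raw(path))
}

detect_genotype_format <- function(path) {
  if (grepl("\\.vcf(\\.b?gz)?$", path)) return("vcf")
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  on.exit(close(con))
  first <- readLines(con, n = 1L)
  if (startsWith(first, "##fileformat=VCF")) return("vcf")
  fields <- strsplit(first, "\t|\\s+")[[1]]
  if (identical(fields[1:2], c("CHR", "SNP"))) return("traw")
  if (identical(fields[1:2], c("FID", "IID"))) return("raw")
  stop("cannot detect genotype format of ", path,
       " (expected VCF, PLINK .traw or PLINK .raw)")
}

read_table_fast <- function(path, ...) {
  if (requireNamespace("data.table", quietly = TRUE)) {
    as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                    showProgress = FALSE, ...))
  } else {
    utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  }
}

dosage_to_ternary <- function(dos, variant_ids, sample_ids) {
  # dos: n x L numeric alt-allele dosage matrix (variants in columns)
  if (anyNA(dos)) {
    idx <- which(is.na(dos), arr.ind = TRUE)[1L, ]
    stop("missing genotype at variant '", variant_ids[idx[2L]],
         "', sample '", sample_ids[idx[1L]], "'; complete matrix required")
  }
  if (!all(dos %in% c(0, 1, 2))) {
    idx <- which(!(dos %in% c(0, 1, 2)))[1L]
    stop("dosages must be 0, 1 or 2; found ", dos[idx])
  }
  matrix(as.integer(dos) - 1L, nrow = nrow(dos), ncol = ncol(dos))
}

read_genotypes_traw <- function(path) {
  tab <- read_table_fast(path)
  meta_cols <- c("CHR", "SNP", "(C)M", "POS", "COUNTED", "ALT")
  if (!all(meta_cols %in% names(tab))) {
    stop("not a PLINK .traw file (missing header columns): ", path)
  }
  sample_ids <- setdiff(names(tab), meta_cols)
  # sample columns may be FID_IID; keep as-is
  dos <- t(as.matrix(tab[, sample_ids, drop = FALSE]))
  values <- dosage_to_ternary(dos, tab$SNP, sample_ids)
  variants <- data.frame(chrom = as.character(tab$CHR), bp = as.integer(tab$POS),
                         id = as.character(tab$SNP), stringsAsFactors = FALSE)
  genotype_matrix(values, variants, sample_ids)
}

read_genotypes_raw <- function(path) {
  tab <- read_table_fast(path)
  meta_cols <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!all(meta_cols %in% names(tab))) {
    stop("not a PLINK .raw file (missing header columns): ", path)
  }
  snp_cols <- setdiff(names(tab), meta_cols)
  dos <- as.matrix(tab[, snp_cols, drop = FALSE])
  sample_ids <- as.character(tab$IID)
  # .raw headers carry the counted allele as a suffix (rs123_A); strip it.
  ids <- sub("_[ACGT0-9]+$", "", snp_cols)
  values <- dosage_to_ternary(dos, ids, sample_ids)
  # .raw has no coordinates; synthesise ordered placeholders.
  variants <- data.frame(chrom = "0", bp = seq_along(ids), id = ids,
                         stringsAsFactors = FALSE)
  genotype_matrix(values, variants, sample_ids)
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("reading VCF requires the VariantAnnotation package")
  }
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field: ", path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt)
  if (any(n_alt != 1L)) {
    bad <- which(n_alt != 1L)[1L]
    stop("non-biallelic VCF record: ", rownames(gt)[bad],
         " (", n_alt[bad], " ALT alleles); biallelic records required")
  }
  dos_lookup <- c("0/0" = 0, "0|0" = 0, "0/1" = 1, "1/0" = 1,
                  "0|1" = 1, "1|0" = 1, "1/1" = 2, "1|1" = 2)
  dos <- matrix(dos_lookup[gt], nrow = nrow(gt))
  if (anyNA(dos)) {
    idx <- which(is.na(dos), arr.ind = TRUE)[1L, ]
    stop("missing or unsupported genotype '", gt[idx[1L], idx[2L]],
         "' at variant '", rownames(gt)[idx[1L]], "', sample '",
         colnames(gt)[idx[2L]], "'")
  }
  values <- t(dos) - 1L
  storage.mode(values) <- "integer"
  variants <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    bp = GenomicRanges::start(rr),
    id = names(rr),
    stringsAsFactors = FALSE
  )
  genotype_matrix(values, variants, colnames(gt))
}

#' Write a genotype matrix to disk
#'
#' `traw` writes PLINK's transposed dosage text (variants as rows,
#' alt-allele dosage 0/1/2); `vcf` writes a minimal biallelic VCFv4.2 with
#' GT genotypes. Both round-trip losslessly through [read_genotypes()]
#' (the `.traw` route preserves chromosome and position; placeholder
#' REF/ALT alleles A/B are used since the ternary encoding does not keep
#' nucleotides).
#'
#' @param g A [genotype_matrix].
#' @param path Output file path.
#' @param format `"traw"` or `"vcf"`.
#' @param sidecar If `TRUE` (default), also write `<path>.json` recording
#'   generator parameters (when present) and dimensions.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, format = c("traw", "vcf"),
                            sidecar = TRUE) {
  format <- match.arg(format)
  stopifnot(inherits(g, "genotype_matrix"))
  if (format == "traw") {
    dos <- t(g$values + 1L)
    tab <- data.frame(CHR = g$variants$chrom, SNP = g$variants$id,
                      CM = 0, POS = g$variants$bp,
                      COUNTED = "B", ALT = "A",
                      stringsAsFactors = FALSE)
    names(tab)[3] <- "(C)M"
    tab <- cbind(tab, as.data.frame(dos))
    names(tab)[-(1:6)] <- g$sample_ids
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    gt_codes <- c("0/0", "0/1", "1/1")
    lines <- c(
      "##fileformat=VCFv4.2",
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
              "INFO", "FORMAT", g$sample_ids), collapse = "\t")
    )
    gt <- matrix(gt_codes[t(g$values) + 2L], nrow = ncol(g$values))
    body <- paste(g$variants$chrom, g$variants$bp, g$variants$id,
                  "A", "B", ".", "PASS", ".", "GT",
                  apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
    writeLines(c(lines, body), path)
  }
  if (sidecar) {
    meta <- list(format = format,
                 n_individuals = nrow(g$values),
                 n_positions = ncol(g$values),
                 generator = attr(g, "generator"))
    jsonlite::write_json(meta, paste0(path, ".json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(path)
}

#' Write variant metadata as TSV
#'
#' @param g A [genotype_matrix].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(g, path) {
  utils::write.table(g$variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
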