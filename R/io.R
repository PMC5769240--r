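#' Write a subjects-by-features matrix as TSV
#'
#' First column \code{subject}, one column per feature. The transpose-free
#' convention (subjects in rows) round-trips with
#' \code{\link{read_matrix_tsv}}.
#'
#' @param mat Numeric matrix with subject rownames.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(subject = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a subjects-by-features TSV matrix
#'
#' @param path Path written by \code{\link{write_matrix_tsv}}.
#' @return Numeric matrix with subject rownames.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[-1])
  rownames(m) <- df$subject
  m
}

#' Write genotype dosages as a minimal VCF with a DS FORMAT field
#'
#' Emits a VCFv4.2 file whose only per-sample field is the dosage
#' (\code{DS}), the imputed-dosage convention. REF/ALT are placeholder
#' alleles (A/B): the simulator tracks dosage of the minor allele, not
#' nucleotide identity.
#'
#' @param gt A \code{genotype_matrix}.
#' @param path Output path (plain text).
#' @return \code{path}, invisibly.
#' @export
write_genotype_vcf <- function(gt, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=eqtlens",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage of the minor allele\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(gt$dosage)), collapse = "\t")), con)
  body <- cbind(gt$panel$chrom, gt$panel$pos, gt$panel$rsID, "A", "B", ".",
                ".", ".", "DS", t(format(gt$dosage, trim = TRUE)))
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read genotype dosages from a VCF with a DS field
#'
#' Parses the file with \pkg{vcfR} and extracts the per-sample \code{DS}
#' values. The panel's MAF column is the empirical allele frequency (folded
#' to the minor allele).
#'
#' @param path VCF path (plain or gzipped).
#' @return A \code{genotype_matrix}.
#' @export
read_genotype_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  dos <- t(ds)
  af <- colMeans(dos) / 2
  panel <- data.frame(
    rsID = unname(vcfR::getID(v)),
    chrom = unname(vcfR::getCHROM(v)),
    pos = as.integer(vcfR::getPOS(v)),
    maf = pmin(af, 1 - af),
    stringsAsFactors = FALSE)
  structure(list(dosage = dos, panel = panel), class = "genotype_matrix")
}

#' Write a GWAS summary in the PLINK-assoc-like dialect
#'
#' Whitespace-delimited columns SNP, CHR, BP, P with a header row; the
#' format \code{\link{load_gwas_summary}} reads.
#'
#' @param gwas GWAS summary data frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_gwas_summary <- function(gwas, path) {
  out <- data.frame(SNP = gwas$rsID, CHR = gwas$chrom, BP = gwas$pos,
                    P = gwas$p)
  write.table(out, path, sep = " ", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
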