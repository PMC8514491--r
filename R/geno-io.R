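#' Read genotypes from a VCF file
#'
#' Consumes the GT field of a diploid VCF (v4.x). Multiallelic records
#' (ALT listing more than one allele) are skipped and counted; the count is
#' stored on the returned object as attribute `"n_non_biallelic"` so the QC
#' report can account for them. `./.` (and `.|.` or `.`) become `NA`.
#'
#' @param path path to an (uncompressed or gzipped) VCF
#' @return a [geno_matrix()]
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)   # single-record files come back as a vector
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    warning("VCF contains no variant records; returning an empty matrix")
    smp <- colnames(v@gt)[-1]
    d <- matrix(NA_integer_, length(smp), 0)
    rownames(d) <- smp
    g <- geno_matrix(d, data.frame(id = character(0), chrom = character(0),
                                   pos = integer(0), cM = numeric(0),
                                   ref = character(0), alt = character(0)))
    attr(g, "n_non_biallelic") <- 0L
    return(g)
  }
  biallelic <- !grepl(",", fix$ALT, fixed = TRUE) & fix$ALT != "." & fix$REF != "."
  n_multi <- sum(!biallelic)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  alleles <- gsub("\\|", "/", gt)
  bad_ploidy <- !is.na(alleles) & !grepl("^[0-9.]/[0-9.]$", alleles)
  if (any(bad_ploidy))
    stop("non-diploid GT entry found (e.g. '",
         alleles[which(bad_ploidy)[1]], "'); only diploid VCFs are supported")
  dose <- matrix(NA_integer_, nrow(alleles), ncol(alleles))
  dose[alleles == "0/0"] <- 0L
  dose[alleles %in% c("0/1", "1/0")] <- 1L
  dose[alleles == "1/1"] <- 2L
  dos <- t(dose)
  rownames(dos) <- colnames(gt)
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  vars <- data.frame(id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
                     cM = NA_real_, ref = fix$REF, alt = fix$ALT,
                     stringsAsFactors = FALSE)
  g <- geno_matrix(dos, vars)
  attr(g, "n_non_biallelic") <- n_multi
  g
}

#' Write genotypes to a VCF file
#'
#' Emits a minimal VCF v4.2 with a GT-only FORMAT column; missing calls are
#' written as `./.`.
#'
#' @param g a [geno_matrix()]
#' @param path output path
#' @export
write_vcf <- function(g, path) {
  v <- g$variants
  d <- g$dosages
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=aquagp",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(d)), collapse = "\t")
  ), con)
  if (ncol(d) > 0) {
    code <- c("0/0", "0/1", "1/1")
    gt <- matrix("./.", nrow(d), ncol(d))
    obs <- !is.na(d)
    gt[obs] <- code[d[obs] + 1L]
    lines <- paste(v$chrom, v$pos, v$id, v$ref, v$alt, ".", ".", ".", "GT",
                   sep = "\t")
    body <- apply(gt, 2, paste, collapse = "\t")
    writeLines(paste(lines, body, sep = "\t"), con)
  }
  invisible(path)
}

#' Read / write the 012 dosage TSV format
#'
#' Tab-separated: a header row of variant ids (first cell `id`), then one
#' row per sample with the sample id followed by dosages 0/1/2 (`NA` for
#' missing).
#'
#' @param g a [geno_matrix()]
#' @param path file path
#' @param variants optional variant table to attach on read (otherwise
#'   minimal metadata is reconstructed from the ids)
#' @export
write_012 <- function(g, path) {
  dt <- data.table::as.data.table(g$dosages)
  dt <- cbind(data.table::data.table(id = rownames(g$dosages)), dt)
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_012
#' @export
read_012 <- function(path, variants = NULL) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = "NA", data.table = FALSE)
  ids <- as.character(dt[[1]])
  d <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(d) <- "integer"
  rownames(d) <- ids
  if (!is.null(variants)) {
    geno_matrix(d, variants)
  } else {
    vars <- data.frame(id = colnames(d), chrom = "1",
                       pos = seq_len(ncol(d)), cM = NA_real_,
                       ref = "N", alt = "N", stringsAsFactors = FALSE)
    geno_matrix(d, vars)
  }
}

#' Write phenotypes as TSV
#'
#' One row per individual, `id` first, one column per trait, empty cell for
#' unrecorded values.
#' @param phenotypes data.frame as produced by [simulate_traits()]
#' @param path file path
#' @export
write_phenotypes <- function(phenotypes, path) {
  data.table::fwrite(phenotypes, path, sep = "\t", na = "", quote = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  data.table::fread(path, sep = "\t", header = TRUE, na.strings = "",
                    data.table = FALSE)
}
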