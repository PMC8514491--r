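#' Construct a genotype matrix object
#'
#' A `geno_matrix` holds biallelic SNP genotypes as allele dosages (count of
#' the alternate allele: 0, 1 or 2, with `NA` for missing calls) together
#' with variant metadata. Rows are individuals, columns are variants. This is
#' the container every other module of the package consumes and produces.
#'
#' @param dosages integer matrix, individuals x variants, values in
#'   `{0, 1, 2, NA}`. Row names are sample ids, column names variant ids.
#' @param variants data.frame with one row per variant and columns
#'   `id`, `chrom`, `pos` (physical position, bp), `cM` (genetic position),
#'   `ref`, `alt`. Missing columns are filled with defaults.
#'
#' @return An object of class `geno_matrix`: a list with elements `dosages`
#'   and `variants`.
#' @export
geno_matrix <- function(dosages, variants = NULL) {
  if (!is.matrix(dosages)) stop("`dosages` must be a matrix")
  storage.mode(dosages) <- "integer"
  bad <- !(dosages %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  if (is.null(rownames(dosages)))
    rownames(dosages) <- sprintf("S%04d", seq_len(nrow(dosages)))
  m <- ncol(dosages)
  if (is.null(variants)) {
    variants <- data.frame(
      id = if (is.null(colnames(dosages))) sprintf("snp%05d", seq_len(m))
           else colnames(dosages),
      chrom = rep("1", m), pos = seq_len(m), cM = as.numeric(seq_len(m)),
      ref = rep("A", m), alt = rep("G", m),
      stringsAsFactors = FALSE
    )
  }
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  if (nrow(variants) != m) stop("variants table does not match dosage columns")
  if (is.null(variants$id))
    variants$id <- sprintf("snp%05d", seq_len(m))
  for (col in c("chrom", "ref", "alt"))
    if (is.null(variants[[col]])) variants[[col]] <- if (col == "chrom") "1" else "N"
  if (is.null(variants$pos)) variants$pos <- seq_len(m)
  if (is.null(variants$cM)) variants$cM <- as.numeric(variants$pos)
  colnames(dosages) <- variants$id
  # positions strictly increasing within each chromosome
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (length(p) > 1 && any(diff(p) <= 0))
      stop("variant positions must be strictly increasing within chromosome ", ch)
  }
  structure(list(dosages = dosages, variants = variants),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  d <- x$dosages
  nmiss <- sum(is.na(d))
  cat(sprintf("geno_matrix: %d individuals x %d SNPs (%d chromosomes), %.2f%% missing\n",
              nrow(d), ncol(d), length(unique(x$variants$chrom)),
              100 * nmiss / length(d)))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosages)

#' Sample ids of a genotype matrix
#' @param g a `geno_matrix`
#' @return character vector of sample ids
#' @export
sample_ids <- function(g) rownames(g$dosages)

#' Subset a genotype matrix
#'
#' @param g a `geno_matrix`
#' @param samples optional sample ids or indices to keep
#' @param variants optional variant indices (positions into the variant
#'   table) or variant ids to keep
#' @return a `geno_matrix`
#' @export
subset_geno <- function(g, samples = NULL, variants = NULL) {
  d <- g$dosages
  v <- g$variants
  if (!is.null(samples)) d <- d[samples, , drop = FALSE]
  if (!is.null(variants)) {
    if (is.character(variants)) variants <- match(variants, v$id)
    d <- d[, variants, drop = FALSE]
    v <- v[variants, , drop = FALSE]
    rownames(v) <- NULL
  }
  structure(list(dosages = d, variants = v), class = "geno_matrix")
}

#' Construct a pedigree table
#'
#' A pedigree is a data.frame with columns `id`, `sire`, `dam`, `sex`
#' (`"M"`/`"F"`), and `generation`. Unknown parents are `NA`. The
#' constructor validates acyclicity (no individual is its own ancestor),
#' sex-consistency of parents, and that every named parent exists or is
#' unknown.
#'
#' @param id,sire,dam,sex,generation vectors of equal length (`sire`/`dam`
#'   may contain `NA` or `"0"` for unknown)
#' @return data.frame of class `pedigree`
#' @export
pedigree <- function(id, sire, dam, sex, generation) {
  id <- as.character(id)
  norm <- function(x) {
    x <- as.character(x)
    x[x %in% c("0", "", "NA")] <- NA_character_
    x
  }
  sire <- norm(sire); dam <- norm(dam)
  sex <- as.character(sex)
  if (anyDuplicated(id)) stop("duplicate ids in pedigree")
  if (!all(sex %in% c("M", "F") | is.na(sex)))
    stop("sex must be 'M', 'F' or NA")
  ped <- data.frame(id = id, sire = sire, dam = dam, sex = sex,
                    generation = as.character(generation),
                    stringsAsFactors = FALSE)
  known <- c(ped$sire, ped$dam)
  known <- known[!is.na(known)]
  if (!all(known %in% id)) stop("pedigree references unknown parent id(s): ",
                                paste(setdiff(known, id), collapse = ", "))
  sx <- stats::setNames(ped$sex, ped$id)
  s_sex <- sx[ped$sire[!is.na(ped$sire)]]
  d_sex <- sx[ped$dam[!is.na(ped$dam)]]
  if (any(s_sex != "M", na.rm = TRUE)) stop("a sire is not male")
  if (any(d_sex != "F", na.rm = TRUE)) stop("a dam is not female")
  ped_topological_order(ped)  # errors on cycles
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' Topological order of a pedigree
#'
#' Returns row indices such that every parent precedes its offspring;
#' errors (naming an offending id) if the pedigree contains a cycle.
#'
#' @param ped a pedigree data.frame
#' @return integer vector of row indices
#' @export
ped_topological_order <- function(ped) {
  n <- nrow(ped)
  pos <- stats::setNames(seq_len(n), ped$id)
  placed <- rep(FALSE, n)
  order_out <- integer(0)
  remaining <- seq_len(n)
  while (length(remaining) > 0) {
    ready <- vapply(remaining, function(i) {
      s <- ped$sire[i]; d <- ped$dam[i]
      (is.na(s) || placed[pos[[s]]]) && (is.na(d) || placed[pos[[d]]])
    }, logical(1))
    if (!any(ready))
      stop("pedigree contains a cycle involving id(s): ",
           paste(ped$id[remaining], collapse = ", "))
    order_out <- c(order_out, remaining[ready])
    placed[remaining[ready]] <- TRUE
    remaining <- remaining[!ready]
  }
  order_out
}

#' Write / read a pedigree as CSV
#'
#' Unknown parents are written as `"0"`.
#' @param ped a pedigree
#' @param path file path
#' @export
write_pedigree <- function(ped, path) {
  out <- as.data.frame(ped)
  out$sire[is.na(out$sire)] <- "0"
  out$dam[is.na(out$dam)] <- "0"
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  pedigree(x$id, x$sire, x$dam, x$sex, x$generation)
}

#' Derive a reproducible sub-seed for a named stage
#'
#' All randomness in the package flows from one root seed via named
#' substreams, so each stage (founders, meiosis, traits, noise, subsets,
#' cross-validation, ...) is independently reproducible.
#'
#' @param seed integer root seed
#' @param name character stage label
#' @return an integer seed in `[0, 2^31 - 1)`
#' @export
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 48271 + h * 2654435761) %% 2147483647)
}
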