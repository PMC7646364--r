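# PLINK binary I/O (.bed/.bim/.fam), parental dosage files, pair and
# phenotype tables. The .bed codec implements the variant-major 2-bit
# encoding: per-SNP bytes pack 4 samples, low bits first; 00 = hom A1,
# 01 = missing, 10 = het, 11 = hom A2. Genotypes are A1-allele counts.

.bed_magic <- as.raw(c(0x6c, 0x1b, 0x01))
# 2-bit code -> A1 count (NA for the missing sentinel 01)
.bed_decode <- c(2L, NA_integer_, 1L, 0L)

#' Construct a genotype dataset
#'
#' The in-memory equivalent of a PLINK fileset: a sample table, a variant
#' table, and an individuals x variants matrix of A1-allele counts (NA =
#' missing).
#'
#' @param fam Data frame with columns `fid`, `iid`, `pat`, `mat`, `sex`
#'   (1 = male, 2 = female, 0 = unknown), `pheno`.
#' @param bim Data frame with columns `chr`, `snp`, `cm`, `bp`, `a1`, `a2`.
#' @param geno Integer matrix, `nrow(fam)` x `nrow(bim)`.
#' @return Object of class `genotype_dataset`.
#' @export
as_genotype_dataset <- function(fam, bim, geno) {
  geno <- as.matrix(geno)
  if (nrow(geno) != nrow(fam) || ncol(geno) != nrow(bim)) {
    stop("dimension mismatch: geno is ", nrow(geno), " x ", ncol(geno),
         " but fam has ", nrow(fam), " samples and bim ", nrow(bim), " variants")
  }
  if (!all(geno %in% c(0L, 1L, 2L, NA))) stop("genotypes must be 0/1/2/NA A1 counts")
  structure(list(fam = fam, bim = bim, geno = geno),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("<genotype_dataset> %d samples x %d variants\n",
              nrow(x$fam), nrow(x$bim)))
  invisible(x)
}

#' Write a genotype dataset as PLINK binary files
#'
#' @param dataset A `genotype_dataset`.
#' @param prefix Path prefix; writes `prefix.bed`, `prefix.bim`,
#'   `prefix.fam`.
#' @return The prefix, invisibly.
#' @export
write_plink <- function(dataset, prefix) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  utils::write.table(dataset$fam[, c("fid", "iid", "pat", "mat", "sex", "pheno")],
                     paste0(prefix, ".fam"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(dataset$bim[, c("chr", "snp", "cm", "bp", "a1", "a2")],
                     paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  n <- nrow(dataset$fam)
  npad <- 4L * ceiling(n / 4L)
  # A1 count -> 2-bit code
  code_of <- function(g) {
    out <- integer(length(g))
    out[is.na(g)] <- 1L
    out[!is.na(g) & g == 2L] <- 0L
    out[!is.na(g) & g == 1L] <- 2L
    out[!is.na(g) & g == 0L] <- 3L
    out
  }
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(.bed_magic, con)
  mult <- c(1L, 4L, 16L, 64L)
  for (j in seq_len(ncol(dataset$geno))) {
    codes <- c(code_of(dataset$geno[, j]), rep(0L, npad - n))
    bytes <- colSums(matrix(codes * mult, nrow = 4L))
    writeBin(as.raw(bytes), con)
  }
  invisible(prefix)
}

#' Read PLINK binary files
#'
#' Losslessly loads a `.bed`/`.bim`/`.fam` fileset. The `.bed` must be in
#' variant-major orientation (the third magic byte); missing genotypes are
#' preserved as NA. At X-linked variants, heterozygous calls in males are
#' invalid hemizygotes: they are set missing with a logged count.
#'
#' @param prefix Path prefix of the fileset.
#' @return A `genotype_dataset`.
#' @export
read_plink <- function(prefix) {
  bed_path <- paste0(prefix, ".bed")
  fam <- utils::read.table(paste0(prefix, ".fam"),
                           col.names = c("fid", "iid", "pat", "mat", "sex", "pheno"),
                           colClasses = c("character", "character", "character",
                                          "character", "integer", "numeric"))
  bim <- utils::read.table(paste0(prefix, ".bim"),
                           col.names = c("chr", "snp", "cm", "bp", "a1", "a2"),
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  if (nrow(bim) == 0) stop("empty variant file: ", prefix, ".bim has no rows")
  if (nrow(fam) == 0) stop("empty sample file: ", prefix, ".fam has no rows")
  n <- nrow(fam); m <- nrow(bim)
  bpv <- ceiling(n / 4L)  # bytes per variant
  expected <- 3L + as.numeric(bpv) * m
  actual <- file.size(bed_path)
  raw <- readBin(bed_path, "raw", n = expected)
  if (!identical(raw[1:3], .bed_magic)) {
    stop("bad magic bytes in ", bed_path,
         ": not a variant-major PLINK .bed file (offset 0)")
  }
  if (length(raw) < expected || (!is.na(actual) && actual != expected)) {
    stop("truncated or mis-sized .bed: ", bed_path, " has ", actual,
         " bytes, expected ", expected, " for ", n, " samples x ", m,
         " variants (offset ", length(raw), ")")
  }
  body <- as.integer(raw[-(1:3)])
  codes <- matrix(0L, 4L * bpv, m)
  shift <- body
  for (k in 1:4) {
    codes[seq(k, by = 4L, length.out = bpv), ] <- shift %% 4L
    shift <- shift %/% 4L
  }
  geno <- matrix(.bed_decode[codes[seq_len(n), , drop = FALSE] + 1L], n, m)
  # invalid male hemizygotes on X
  xcols <- which(bim$chr %in% c("X", "23"))
  if (length(xcols)) {
    males <- fam$sex == 1L
    bad <- 0L
    for (j in xcols) {
      hit <- males & !is.na(geno[, j]) & geno[, j] == 1L
      bad <- bad + sum(hit)
      geno[hit, j] <- NA_integer_
    }
    if (bad > 0) message(bad, " male heterozygous X call(s) set to missing")
  }
  as_genotype_dataset(fam, bim, geno)
}

#' Write imputed parental dosages
#'
#' Plain-text dosage table: one row per variant with columns `SNP`, `A1`,
#' `A2`, then one raw-scale (0--2) expected dosage column per virtual
#' parent, headed `<fid>_<role>` where role is `P` (combined parent), `M`
#' (mother) or `F`/`F1`/`F2` (father(s)).
#'
#' @param bim Variant table (`snp`, `a1`, `a2`).
#' @param dosages Named list of matrices (families x variants) keyed by the
#'   imputation role names from [impute_parents()].
#' @param fids Family identifiers, one per family.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_parental_dosages <- function(bim, dosages, fids, path) {
  role_code <- c(parent = "P", mother = "M", father = "F",
                 father1 = "F1", father2 = "F2", mother1 = "M1", mother2 = "M2")
  cols <- list(SNP = bim$snp, A1 = bim$a1, A2 = bim$a2)
  for (nm in names(dosages)) {
    d <- t(dosages[[nm]])  # variants x families
    colnames(d) <- paste0(fids, "_", role_code[[nm]])
    cols <- c(cols, as.data.frame(d, check.names = FALSE))
  }
  df <- do.call(data.frame, c(cols, check.names = FALSE))
  utils::write.table(format(df, digits = 10, trim = TRUE), path,
                     quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' Read a parental dosage file written by [write_parental_dosages()]
#'
#' @param path File path.
#' @return List with `bim` (snp/a1/a2) and `dosages`, a variants x parents
#'   numeric matrix with the parent column names.
#' @export
read_parental_dosages <- function(path) {
  df <- utils::read.table(path, header = TRUE, check.names = FALSE)
  list(bim = df[, c("SNP", "A1", "A2")],
       dosages = as.matrix(df[, -(1:3), drop = FALSE]))
}

#' Read a whitespace-delimited phenotype/covariate table
#'
#' PLINK convention: first two columns are family and individual IDs; a
#' header row naming them (e.g. `FID IID pheno`) is detected and used.
#'
#' @param path File path.
#' @param value_names Names for the value columns when no header is present.
#' @return Data frame with `fid`, `iid` and value columns.
#' @export
read_pheno_table <- function(path, value_names = "pheno") {
  first <- readLines(path, n = 1)
  has_header <- grepl("^\\s*#?\\s*FID\\b", first, ignore.case = TRUE)
  df <- utils::read.table(path, header = has_header,
                          comment.char = if (has_header) "" else "#")
  names(df)[1:2] <- c("fid", "iid")
  if (!has_header) {
    names(df)[-(1:2)] <- value_names[seq_len(ncol(df) - 2)]
  } else {
    names(df) <- tolower(names(df))
    names(df) <- sub("^#", "", names(df))
  }
  df$fid <- as.character(df$fid); df$iid <- as.character(df$iid)
  df
}

#' Read a pair-definition table
#'
#' Columns: `FID IID1 IID2 pair_type` with pair_type in `sib`, `msib`
#' (maternal half sibs), `psib` (paternal half sibs).
#'
#' @param path File path.
#' @return Data frame with `fid`, `iid1`, `iid2`, `pair_type`.
#' @export
read_pairs <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("^\\s*#?\\s*FID\\b", first, ignore.case = TRUE)
  df <- utils::read.table(path, header = has_header,
                          col.names = c("fid", "iid1", "iid2", "pair_type"),
                          colClasses = "character")
  bad <- !df$pair_type %in% c("sib", "msib", "psib")
  if (any(bad)) stop("unknown pair_type value(s): ",
                     paste(unique(df$pair_type[bad]), collapse = ", "))
  df
}

#' Export a simulated cohort as a genotype dataset plus phenotype tables
#'
#' Converts a `family_table` into the sibling-only PLINK-style cohort a
#' genotypes-first pipeline would see: two genotyped siblings per family
#' (parents absent), plus pair definitions and a phenotype table.
#'
#' @param fam A `family_table`.
#' @param chr Chromosome label for the variants (`"X"` for X-linked tables).
#' @return List with `dataset` (a `genotype_dataset`), `pairs`, `pheno`.
#' @export
family_table_to_dataset <- function(fam, chr = NULL) {
  stopifnot(inherits(fam, "family_table"))
  if (is.null(chr)) chr <- if (fam$chrom_type == "X") "X" else "1"
  n <- fam$n; L <- length(fam$p)
  fids <- sprintf("F%05d", seq_len(n))
  sex_code <- function(i) {
    if (fam$chrom_type == "X") ifelse(fam$sexes[i] == "male", 1L, 2L)
    else rep(0L, 1)
  }
  famdf <- data.frame(
    fid = rep(fids, each = 2),
    iid = paste0(rep(fids, each = 2), c("_1", "_2")),
    pat = "0", mat = "0",
    sex = rep(c(sex_code(1), sex_code(2)), n),
    pheno = as.vector(t(ifelse(is.na(fam$pheno), -9, fam$pheno))),
    stringsAsFactors = FALSE)
  bim <- data.frame(chr = chr, snp = sprintf("snp%04d", seq_len(L)),
                    cm = 0, bp = seq_len(L) * 1000L,
                    a1 = "A", a2 = "G", stringsAsFactors = FALSE)
  geno <- matrix(NA_integer_, 2 * n, L)
  geno[seq(1, 2 * n, 2), ] <- as.integer(fam$geno$sib1)
  geno[seq(2, 2 * n, 2), ] <- as.integer(fam$geno$sib2)
  pair_type <- switch(fam$design, full_sib = "sib",
                      maternal_half_sib = "msib", paternal_half_sib = "psib")
  pairs <- data.frame(fid = fids, iid1 = paste0(fids, "_1"),
                      iid2 = paste0(fids, "_2"), pair_type = pair_type,
                      stringsAsFactors = FALSE)
  pheno <- data.frame(fid = famdf$fid, iid = famdf$iid,
                      pheno = as.vector(t(fam$pheno)),
                      stringsAsFactors = FALSE)
  list(dataset = as_genotype_dataset(famdf, bim, geno),
       pairs = pairs, pheno = pheno)
}
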