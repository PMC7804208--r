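# Genotype/phenotype data model, file readers/writers and preprocessing.

#' Construct a genotype matrix
#'
#' Container for a case/control SNP study: a samples-by-SNPs matrix of
#' categorical genotype calls plus a binary phenotype. Missing calls (`NA`)
#' are converted to the reserved missing-genotype category
#' ([missing_label()]) on construction, so every value of every column is a
#' bona fide category.
#'
#' @param geno Character matrix, samples in rows, SNPs in columns. `NA`
#'   entries are mapped to the missing sentinel.
#' @param status Phenotype vector of length `nrow(geno)` with exactly two
#'   states.
#' @param positive The phenotype state regarded as "positive" (case).
#' @param sample_ids,snp_ids Optional identifiers; default to the dimnames
#'   of `geno` or generated `S1..Sn` / `snp1..snpP`.
#' @return An object of class `genotype_matrix` with elements `geno`
#'   (character matrix), `status` (factor with levels control/case),
#'   `sample_ids` and `snp_ids`.
#' @export
genotype_matrix <- function(geno, status, positive = "case",
                            sample_ids = NULL, snp_ids = NULL) {
  if (!is.matrix(geno)) geno <- as.matrix(geno)
  storage.mode(geno) <- "character"
  if (is.null(sample_ids)) sample_ids <- rownames(geno)
  if (is.null(snp_ids)) snp_ids <- colnames(geno)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(geno)))
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(geno)))
  snp_ids <- as.character(snp_ids)
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(snp_ids))
    stop("duplicate snp_ids: ",
         paste(unique(snp_ids[duplicated(snp_ids)]), collapse = ", "),
         call. = FALSE)
  if (length(status) != nrow(geno))
    stop("phenotype length (", length(status), ") does not match number of ",
         "samples (", nrow(geno), ")", call. = FALSE)
  geno[is.na(geno)] <- .MISSING
  dimnames(geno) <- list(sample_ids, snp_ids)
  out <- list(geno = geno,
              status = as_status(status, positive = positive),
              sample_ids = sample_ids,
              snp_ids = snp_ids)
  class(out) <- "genotype_matrix"
  out
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

#' @export
print.genotype_matrix <- function(x, ...) {
  n <- nrow(x$geno); p <- ncol(x$geno)
  cat("Genotype matrix:", n, "samples x", p, "SNPs\n")
  tab <- table(x$status)
  cat("  phenotype:", tab[["case"]], "cases /", tab[["control"]], "controls\n")
  miss <- mean(x$geno == .MISSING)
  cat(sprintf("  missing-call rate: %.3f\n", miss))
  if (isTRUE(attr(x, "preprocessed")))
    cat("  preprocessed;", sum(attr(x, "constant")), "constant SNP(s) flagged\n")
  invisible(x)
}

# Ordered category set of one genotype column: observed labels sorted, with
# the missing sentinel (if present) placed last.
snp_categories <- function(values) {
  u <- unique(values)
  has_miss <- .MISSING %in% u
  u <- sort(u[u != .MISSING])
  if (has_miss) c(u, .MISSING) else u
}

#' Preprocess a genotype matrix
#'
#' Missing calls are retained as the imaginary genotype category (they are
#' never imputed or dropped), and SNPs with a single observed category --
#' which admit no nontrivial binary recoding -- are flagged for exclusion
#' downstream. The number of samples and SNPs never changes.
#'
#' @param x A [genotype_matrix()].
#' @return The same object with attributes `preprocessed = TRUE` and
#'   `constant`, a logical vector flagging single-category SNPs.
#' @export
preprocess <- function(x) {
  stopifnot(inherits(x, "genotype_matrix"))
  ncat <- apply(x$geno, 2L, function(v) length(unique(v)))
  attr(x, "constant") <- ncat <= 1L
  attr(x, "preprocessed") <- TRUE
  x
}

# ---------------------------------------------------------------------------
# File formats
# ---------------------------------------------------------------------------

# Markers accepted as a missing genotype in any text input.
.MISSING_MARKERS <- c("NA", "", ".", "./.", ".|.", "0 0", "00")

normalize_missing <- function(v) {
  v[v %in% .MISSING_MARKERS] <- .MISSING
  v
}

#' Read genotype data from file
#'
#' Supported formats:
#' \describe{
#'   \item{`tsv`}{Self-describing flat file: header row `snp_id` plus sample
#'     ids, a `#target` row with the case/control labels, then one row per
#'     SNP. Missing genotypes written as `NA`.}
#'   \item{`vcf`}{VCF 4.x; only the GT subfield is used. Genotypes are
#'     collapsed to unphased unordered calls (`1|0` and `0/1` both become
#'     `0/1`). The phenotype comes from a sidecar TSV (`phenotype=` path)
#'     with columns `sample_id` and `status`.}
#'   \item{`plink_text`}{PLINK text pair `.ped`/`.map`; pass the `.ped` path
#'     (the `.map` is looked up next to it). Column 6 of the `.ped` is the
#'     phenotype, coded 2 = case, 1 = control. Allele pairs are sorted, so
#'     `A G` and `G A` are the same genotype; `0 0` is missing.}
#' }
#'
#' @param path Input file path.
#' @param format One of `"tsv"`, `"vcf"`, `"plink_text"`.
#' @param phenotype For `format = "vcf"`: path to the phenotype sidecar TSV.
#' @param positive Phenotype state mapped to "case" (tsv/vcf inputs).
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf", "plink_text"),
                           phenotype = NULL, positive = "case") {
  format <- match.arg(format)
  switch(format,
         tsv = read_genotypes_tsv(path, positive = positive),
         vcf = read_genotypes_vcf(path, phenotype = phenotype,
                                  positive = positive),
         plink_text = read_genotypes_ped(path))
}

read_genotypes_tsv <- function(path, positive = "case") {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("malformed genotype TSV: ", path, call. = FALSE)
  split_row <- function(s) strsplit(s, "\t", fixed = TRUE)[[1L]]
  header <- split_row(lines[[1L]])
  if (header[[1L]] != "snp_id")
    stop("genotype TSV must start with a 'snp_id' header row", call. = FALSE)
  sample_ids <- header[-1L]
  trow <- split_row(lines[[2L]])
  if (trow[[1L]] != "#target")
    stop("genotype TSV must carry a '#target' row after the header",
         call. = FALSE)
  status <- trow[-1L]
  body <- lapply(lines[-(1:2)], split_row)
  bad <- vapply(body, length, 1L) != length(header)
  if (any(bad)) stop("ragged rows in genotype TSV", call. = FALSE)
  snp_ids <- vapply(body, `[[`, "", 1L)
  geno <- t(vapply(body, function(r) normalize_missing(r[-1L]),
                   character(length(sample_ids))))
  geno <- t(geno)  # samples x SNPs
  dimnames(geno) <- list(sample_ids, snp_ids)
  genotype_matrix(geno, status, positive = positive)
}

#' Write a genotype matrix as TSV
#'
#' Inverse of `read_genotypes(..., format = "tsv")`: SNPs as rows, samples as
#' columns, a `#target` row with the case/control labels. Missing genotypes
#' are written as `NA`. Reading the file back yields an identical object.
#'
#' @param x A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(x, path) {
  stopifnot(inherits(x, "genotype_matrix"))
  geno <- x$geno
  geno[geno == .MISSING] <- "NA"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("snp_id", x$sample_ids), collapse = "\t"), con)
  writeLines(paste(c("#target", as.character(x$status)), collapse = "\t"), con)
  rows <- vapply(seq_along(x$snp_ids), function(j)
    paste(c(x$snp_ids[[j]], geno[, j]), collapse = "\t"), "")
  writeLines(rows, con)
  invisible(path)
}

read_genotypes_vcf <- function(path, phenotype, positive = "case") {
  if (is.null(phenotype))
    stop("VCF input needs a phenotype sidecar TSV (phenotype=)", call. = FALSE)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt) || nrow(gt) == 0L)
    stop("no GT field found in VCF: ", path, call. = FALSE)
  ids <- vcfR::getID(vcf)
  fallback <- paste0(vcfR::getCHROM(vcf), "_", vcfR::getPOS(vcf))
  ids[is.na(ids) | ids == "."] <- fallback[is.na(ids) | ids == "."]
  # Collapse to unordered, unphased calls: 1|0 == 0/1 == 1/0.
  canon <- function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(.MISSING)
    al <- strsplit(g, "[/|]")[[1L]]
    if (any(al == ".")) return(.MISSING)
    paste(sort(al), collapse = "/")
  }
  geno <- apply(gt, c(1L, 2L), canon)
  geno <- t(geno)  # samples x SNPs
  colnames(geno) <- ids
  ph <- utils::read.table(phenotype, header = TRUE, sep = "\t",
                          colClasses = "character")
  if (!all(c("sample_id", "status") %in% names(ph)))
    stop("phenotype sidecar needs columns sample_id and status", call. = FALSE)
  m <- match(rownames(geno), ph$sample_id)
  if (anyNA(m))
    stop("phenotype sidecar is missing samples: ",
         paste(utils::head(rownames(geno)[is.na(m)], 5L), collapse = ", "),
         call. = FALSE)
  genotype_matrix(geno, ph$status[m], positive = positive)
}

read_genotypes_ped <- function(path) {
  ped_path <- path
  if (!grepl("\\.ped$", ped_path)) ped_path <- paste0(path, ".ped")
  map_path <- sub("\\.ped$", ".map", ped_path)
  if (!file.exists(ped_path) || !file.exists(map_path))
    stop("PLINK text input needs both ", ped_path, " and ", map_path,
         call. = FALSE)
  map <- utils::read.table(map_path, header = FALSE, colClasses = "character")
  snp_ids <- map[[2L]]
  ped <- utils::read.table(ped_path, header = FALSE, colClasses = "character")
  if (ncol(ped) != 6L + 2L * length(snp_ids))
    stop(".ped column count does not match .map (expected ",
         6L + 2L * length(snp_ids), ", got ", ncol(ped), ")", call. = FALSE)
  sample_ids <- ped[[2L]]
  pheno <- ped[[6L]]
  if (!all(pheno %in% c("1", "2")))
    stop("phenotype (.ped column 6) must be coded 1=control/2=case",
         call. = FALSE)
  n <- nrow(ped); p <- length(snp_ids)
  geno <- matrix(.MISSING, n, p, dimnames = list(sample_ids, snp_ids))
  for (j in seq_len(p)) {
    a1 <- ped[[6L + 2L * j - 1L]]
    a2 <- ped[[6L + 2L * j]]
    miss <- a1 == "0" | a2 == "0"
    g <- paste(pmin(a1, a2), pmax(a1, a2))
    g[miss] <- .MISSING
    geno[, j] <- g
  }
  genotype_matrix(geno, ifelse(pheno == "2", "case", "control"))
}
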