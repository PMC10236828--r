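#' Genotype dosage container
#'
#' Samples-by-SNPs additive dosage matrix (values in `[0, 2]`, effect-allele
#' counts) plus per-SNP metadata. Coordinates are 1-based inclusive
#' throughout the package (VCF convention).
#'
#' @param dosages numeric matrix, samples in rows (rownames = sample ids),
#'   SNPs in columns (colnames = SNP ids).
#' @param snp_meta tibble with one row per SNP: `snp_id`, `chrom`, `pos`,
#'   `ref_allele`, `effect_allele` and optionally `maf`. If `maf` is missing
#'   it is computed from the dosages.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, snp_meta) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  snp_meta <- tibble::as_tibble(snp_meta)
  stopifnot(ncol(dosages) == nrow(snp_meta))
  if (is.null(colnames(dosages))) colnames(dosages) <- snp_meta$snp_id
  if (anyDuplicated(snp_meta$snp_id)) abort("duplicate snp_id in metadata")
  if (!identical(colnames(dosages), snp_meta$snp_id)) {
    abort("dosage column names must equal snp_meta$snp_id, in order")
  }
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < -1e-9 || rng[2] > 2 + 1e-9) {
    abort("dosages outside [0, 2]")
  }
  if (any(snp_meta$pos <= 0)) abort("SNP positions must be strictly positive")
  if (!"maf" %in% names(snp_meta) || all(is.na(snp_meta$maf))) {
    af <- colMeans(dosages, na.rm = TRUE) / 2
    snp_meta$maf <- pmin(af, 1 - af)
  }
  structure(list(dosages = dosages, snp_meta = snp_meta),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d SNPs\n",
              nrow(x$dosages), ncol(x$dosages)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Tidy a genotype matrix into long form
#' @param x a `genotype_matrix`.
#' @param ... unused.
#' @return tibble with columns `sample_id`, `snp_id`, `dosage`.
#' @export
tidy.genotype_matrix <- function(x, ...) {
  tibble::as_tibble(x$dosages, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "snp_id",
                        values_to = "dosage")
}

#' Methylation beta-value container
#'
#' Samples-by-CpGs beta matrix in `[0, 1]` plus per-CpG metadata (chromosome,
#' 1-based position, gene symbol, genomic context, CpG-island relation).
#'
#' @param betas numeric matrix, samples in rows, CpGs in columns.
#' @param cpg_meta tibble with `cpg_id`, `chrom`, `pos` and optionally
#'   `gene`, `context` (TSS1500, TSS200, 5'UTR, 1stExon, Body, 3'UTR,
#'   Intergenic) and `island` (Island, Shore, Shelf, OpenSea).
#' @return an object of class `methylation_matrix`.
#' @export
methylation_matrix <- function(betas, cpg_meta) {
  betas <- as.matrix(betas)
  storage.mode(betas) <- "double"
  cpg_meta <- tibble::as_tibble(cpg_meta)
  stopifnot(ncol(betas) == nrow(cpg_meta))
  if (is.null(colnames(betas))) colnames(betas) <- cpg_meta$cpg_id
  if (anyDuplicated(cpg_meta$cpg_id)) abort("duplicate cpg_id in metadata")
  rng <- range(betas, na.rm = TRUE)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9) abort("betas outside [0, 1]")
  structure(list(betas = betas, cpg_meta = cpg_meta),
            class = "methylation_matrix")
}

#' @export
print.methylation_matrix <- function(x, ...) {
  cat(sprintf("<methylation_matrix> %d samples x %d CpGs\n",
              nrow(x$betas), ncol(x$betas)))
  invisible(x)
}

#' @export
dim.methylation_matrix <- function(x) dim(x$betas)

#' M-value matrix of a methylation container
#' @param x a `methylation_matrix`.
#' @param eps clipping constant, see [beta_to_m()].
#' @return numeric matrix of M-values, samples in rows.
#' @export
m_values <- function(x, eps = 1e-6) beta_to_m(x$betas, eps)

#' @rdname methylation_matrix
#' @param ... unused.
#' @export
tidy.methylation_matrix <- function(x, ...) {
  tibble::as_tibble(x$betas, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "cpg_id",
                        values_to = "beta")
}

#' Validate a GWAS summary-statistics table
#'
#' @param x data frame with columns `snp_id`, `effect_allele`, `other_allele`,
#'   `beta`, `se`, `p`, and optionally `freq` and `n`.
#' @return a validated `summary_stats` tibble; rows with `se <= 0` or `p`
#'   outside `(0, 1]` are removed with a message giving the count.
#' @export
summary_stats <- function(x) {
  x <- tibble::as_tibble(x)
  req <- c("snp_id", "effect_allele", "other_allele", "beta", "se", "p")
  miss <- setdiff(req, names(x))
  if (length(miss)) abort(paste0("missing required column(s): ",
                                 paste(miss, collapse = ", ")))
  if (anyDuplicated(x$snp_id)) abort("duplicated snp_id in summary statistics")
  x$effect_allele <- toupper(x$effect_allele)
  x$other_allele <- toupper(x$other_allele)
  bad <- !(x$se > 0) | !(x$p > 0 & x$p <= 1)
  bad[is.na(bad)] <- TRUE
  if (any(bad)) {
    inform(sprintf("summary_stats: rejected %d row(s) with invalid se or p",
                   sum(bad)))
    x <- x[!bad, , drop = FALSE]
  }
  class(x) <- c("summary_stats", class(x))
  x
}

#' Read genotypes from VCF or dosage TSV
#'
#' VCF 4.x files are read through vcfR; the `DS` FORMAT field is used when
#' present, otherwise dosages are counted from `GT`. Non-biallelic records
#' are skipped with a warning. Missing dosages are mean-imputed per SNP
#' (`missing = "impute"`, the default) or the affected samples dropped
#' (`missing = "drop"`); the count of imputed entries is reported.
#'
#' @param path VCF (`.vcf`) or dosage TSV written by [write_genotypes()].
#' @param format `"auto"` (by extension), `"vcf"` or `"dosage"`.
#' @param missing how to handle missing dosages.
#' @return a [genotype_matrix()].
#' @export
load_genotypes <- function(path, format = c("auto", "vcf", "dosage"),
                           missing = c("impute", "drop")) {
  format <- match.arg(format)
  missing <- match.arg(missing)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "dosage"
  }
  if (format == "vcf") {
    gm <- read_genotypes_vcf(path)
  } else {
    gm <- read_genotypes_dosage(path)
  }
  d <- gm$dosages
  if (anyNA(d)) {
    n_na <- sum(is.na(d))
    if (missing == "impute") {
      inform(sprintf("load_genotypes: mean-imputed %d missing dosage(s)", n_na))
      mu <- colMeans(d, na.rm = TRUE)
      idx <- which(is.na(d), arr.ind = TRUE)
      d[idx] <- mu[idx[, 2]]
    } else {
      keep <- complete.cases(d)
      inform(sprintf("load_genotypes: dropped %d sample(s) with missing dosages",
                     sum(!keep)))
      d <- d[keep, , drop = FALSE]
    }
  }
  genotype_matrix(d, gm$snp_meta)
}

read_genotypes_vcf <- function(path) {
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(v),
                                         stringsAsFactors = FALSE))
  multi <- grepl(",", fix$ALT %||% "")
  if (any(multi)) {
    warn(sprintf("skipping %d non-biallelic VCF record(s)", sum(multi)))
  }
  keep <- !multi
  fmt <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  if (is.null(fmt) || all(is.na(fmt))) {
    gt <- vcfR::extract.gt(v, element = "GT")
    fmt <- apply(gt, 2, function(col) {
      vapply(col, function(g) {
        if (is.na(g)) return(NA_real_)
        sum(as.integer(strsplit(gsub("\\|", "/", g), "/")[[1]]))
      }, numeric(1))
    })
    if (is.null(dim(fmt))) fmt <- matrix(fmt, nrow = nrow(gt),
                                         dimnames = dimnames(gt))
  }
  fmt <- fmt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  ids <- fix$ID
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0(fix$CHROM[no_id], ":", fix$POS[no_id])
  snp_meta <- tibble::tibble(
    snp_id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref_allele = fix$REF, effect_allele = fix$ALT
  )
  dos <- t(fmt)                      # samples x snps
  colnames(dos) <- ids
  list(dosages = dos, snp_meta = snp_meta)
}

# Dosage TSV dialect: leading '#'-prefixed metadata rows (one per SNP field),
# then a header row (sample_id + SNP ids) and one row per sample.
read_genotypes_dosage <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines)
  if (length(meta_lines) < 4) {
    abort(paste0("malformed dosage header: expected '#'-prefixed metadata rows",
                 " at top of ", path))
  }
  meta <- lapply(lines[meta_lines], function(l) strsplit(sub("^#", "", l), "\t")[[1]])
  keys <- vapply(meta, `[`, character(1), 1)
  vals <- lapply(meta, function(x) x[-1])
  need <- c("snp_id", "chrom", "pos", "ref_allele", "effect_allele")
  miss <- setdiff(need, keys)
  if (length(miss)) {
    abort(sprintf("malformed dosage header: missing metadata row(s) %s (line %d)",
                  paste(miss, collapse = ", "), max(meta_lines) + 1L))
  }
  meta_tbl <- tibble::tibble(
    snp_id = vals[[which(keys == "snp_id")]],
    chrom = vals[[which(keys == "chrom")]],
    pos = as.integer(vals[[which(keys == "pos")]]),
    ref_allele = vals[[which(keys == "ref_allele")]],
    effect_allele = vals[[which(keys == "effect_allele")]]
  )
  body <- utils::read.delim(text = lines[-meta_lines], sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
  dos <- as.matrix(body[, -1, drop = FALSE])
  rownames(dos) <- body[[1]]
  storage.mode(dos) <- "double"
  list(dosages = dos, snp_meta = meta_tbl)
}

#' @rdname load_genotypes
#' @param x a `genotype_matrix`.
#' @export
write_genotypes <- function(x, path) {
  m <- x$snp_meta
  hdr <- c(
    paste(c("#snp_id", m$snp_id), collapse = "\t"),
    paste(c("#chrom", m$chrom), collapse = "\t"),
    paste(c("#pos", m$pos), collapse = "\t"),
    paste(c("#ref_allele", m$ref_allele), collapse = "\t"),
    paste(c("#effect_allele", m$effect_allele), collapse = "\t")
  )
  body <- cbind(sample_id = rownames(x$dosages),
                as.data.frame(x$dosages, check.names = FALSE))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(body, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a methylation beta table
#'
#' TSV with CpGs in rows: metadata columns (`cpg_id`, `chrom`, `pos`, `gene`,
#' `context`, `island`) followed by one column per sample. Betas are clipped
#' to `[0, 1]`; values outside `[-0.01, 1.01]` before clipping raise a
#' validation error (corrupt file). CpGs missing in more than `max_missing`
#' of samples are dropped with a message.
#'
#' @param path TSV path.
#' @param max_missing maximum tolerated missing fraction per CpG.
#' @return a [methylation_matrix()].
#' @export
load_methylation <- function(path, max_missing = 0.05) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  meta_cols <- intersect(c("cpg_id", "chrom", "pos", "gene", "context",
                           "island"), names(df))
  meta <- tibble::as_tibble(df[meta_cols])
  b <- as.matrix(df[setdiff(names(df), meta_cols)])
  storage.mode(b) <- "double"
  if (any(b < -0.01 | b > 1.01, na.rm = TRUE)) {
    abort("corrupt methylation file: beta values outside [-0.01, 1.01]")
  }
  b <- pmin(pmax(b, 0), 1)
  frac_na <- rowMeans(is.na(b))
  drop <- frac_na > max_missing
  if (any(drop)) {
    inform(sprintf("load_methylation: dropped %d CpG(s) exceeding %.0f%% missing",
                   sum(drop), 100 * max_missing))
    b <- b[!drop, , drop = FALSE]
    meta <- meta[!drop, , drop = FALSE]
  }
  if (anyNA(b)) {                     # remaining sporadic missingness
    mu <- rowMeans(b, na.rm = TRUE)
    idx <- which(is.na(b), arr.ind = TRUE)
    b[idx] <- mu[idx[, 1]]
  }
  bm <- t(b)
  colnames(bm) <- meta$cpg_id
  methylation_matrix(bm, meta)
}

#' @rdname load_methylation
#' @param x a `methylation_matrix`.
#' @export
write_methylation <- function(x, path) {
  out <- dplyr::bind_cols(x$cpg_meta,
                          tibble::as_tibble(t(x$betas)))
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read GWAS summary statistics
#'
#' TSV with columns `snp_id`, `effect_allele`, `other_allele`, `beta`, `se`,
#' `p` and optionally `freq`, `n`. Allele columns are upper-cased; rows with
#' non-positive `se` or `p` outside `(0, 1]` are rejected with a reported
#' count; a missing required column is an error naming the column.
#'
#' @param path TSV path.
#' @return a [summary_stats()] tibble.
#' @export
load_summary_stats <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  summary_stats(df)
}

#' @rdname load_summary_stats
#' @param x a `summary_stats` tibble.
#' @export
write_summary_stats <- function(x, path) {
  write_table(x, path)
}

#' Write a result table deterministically
#'
#' UTF-8 TSV with a fixed column order (as supplied), floats rendered at six
#' significant digits. Writing the same records twice yields byte-identical
#' files; an empty record list yields a header-only file.
#'
#' @param records data frame of results (DMRs, meQTLs, colocalization,
#'   metrics, ...).
#' @param path output path.
#' @export
write_table <- function(records, path) {
  df <- as.data.frame(records, check.names = FALSE)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- signif(df[[j]], 6)
  }
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", eol = "\n")
  invisible(path)
}

#' @rdname write_table
#' @return for `read_table_tsv`, a tibble.
#' @export
read_table_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
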