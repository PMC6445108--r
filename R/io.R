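## File formats.  All formats are plain text:
##  - dosage TSV: two '##' metadata lines (positions, mafs), then a header
##    row (sample_id + SNP ids) and one row per individual;
##  - phenotype TSV: sample_id, value;
##  - summary TSV: snp, z, se, maf, pos;
##  - LD matrix: whitespace-delimited square matrix, either with a header
##    row of SNP ids or plink-style headerless ('.ld' square format);
##  - minimal VCF: unphased GT genotypes only.

#' Write a genotype panel as dosage TSV
#'
#' @param panel a \code{\link{genotype_panel}}.
#' @param file output path.
#' @export
write_dosage_tsv <- function(panel, file) {
  stopifnot(inherits(panel, "genotype_panel"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("##positions=", paste(format(panel$positions, scientific = FALSE,
                                        trim = TRUE), collapse = ",")),
    paste0("##mafs=", paste(format(panel$mafs, digits = 17),
                            collapse = ","))), con)
  df <- data.frame(sample_id = panel$sample_ids, panel$dosages,
                   check.names = FALSE)
  colnames(df) <- c("sample_id", panel$snp_ids)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a genotype panel from dosage TSV
#'
#' @param file path written by \code{\link{write_dosage_tsv}}.
#' @return A \code{\link{genotype_panel}}.
#' @export
read_dosage_tsv <- function(file) {
  lines <- readLines(file)
  meta <- grep("^##", lines, value = TRUE)
  get_meta <- function(key) {
    hit <- grep(paste0("^##", key, "="), meta, value = TRUE)
    if (!length(hit)) return(NULL)
    as.numeric(strsplit(sub(paste0("^##", key, "="), "", hit[1]), ",")[[1]])
  }
  body <- lines[!grepl("^##", lines)]
  df <- utils::read.table(text = body, header = TRUE, sep = "\t",
                          check.names = FALSE)
  dosages <- as.matrix(df[, -1, drop = FALSE])
  genotype_panel(dosages, snp_ids = colnames(df)[-1],
                 positions = get_meta("positions"),
                 sample_ids = df$sample_id,
                 mafs = get_meta("mafs"))
}

#' Write / read a phenotype vector (two-column TSV)
#'
#' @param pheno a \code{phenotype_vector} or numeric vector.
#' @param sample_ids sample labels (taken from the object if absent).
#' @param file path.
#' @export
write_phenotype_tsv <- function(pheno, file, sample_ids = NULL) {
  v <- pheno_values(pheno)
  sample_ids <- sample_ids %||% paste0("ind_", seq_along(v))
  utils::write.table(
    data.frame(sample_id = sample_ids, value = format(v, digits = 17)),
    file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_phenotype_tsv
#' @export
read_phenotype_tsv <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t")
  structure(list(values = as.numeric(df$value),
                 trait_id = "trait", sample_ids = df$sample_id),
            class = "phenotype_vector")
}

#' Write / read a summary dataset (summary TSV + LD matrix)
#'
#' @param sumdat a \code{\link{summary_dataset}}.
#' @param summary_file path for the per-SNP table (columns snp, z, se,
#'   maf, pos).
#' @param ld_file path for the square LD matrix (header row of SNP ids).
#' @export
write_summary_tsv <- function(sumdat, summary_file, ld_file) {
  stopifnot(inherits(sumdat, "summary_dataset"))
  df <- data.frame(snp = sumdat$snp_ids,
                   z = format(sumdat$z, digits = 17),
                   se = format(sumdat$beta_se %||% rep(NA_real_, sumdat$m),
                               digits = 17),
                   maf = format(sumdat$mafs %||% rep(NA_real_, sumdat$m),
                                digits = 17),
                   pos = format(sumdat$positions, scientific = FALSE,
                                trim = TRUE))
  utils::write.table(df, summary_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ld <- format(sumdat$ld, digits = 17)
  utils::write.table(rbind(sumdat$snp_ids, ld), ld_file, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(summary_file)
}

#' @rdname write_summary_tsv
#' @param n sample size behind the Z scores (required: it is not stored in
#'   GWAS summary files and must be supplied by the analyst).
#' @export
read_summary_tsv <- function(summary_file, ld_file, n) {
  df <- utils::read.table(summary_file, header = TRUE, sep = "\t")
  stopifnot(all(c("snp", "z") %in% colnames(df)))
  ld <- read_ld_matrix(ld_file)
  ids <- attr(ld, "snp_ids")
  if (!is.null(ids)) {
    common <- intersect(df$snp, ids)
    if (!setequal(df$snp, ids)) {
      warning("SNP sets in summary and LD files differ; using their ",
              "intersection (", length(common), " SNPs)")
    }
    df <- df[match(common, df$snp), , drop = FALSE]
    ld <- ld[match(common, ids), match(common, ids), drop = FALSE]
  } else if (nrow(ld) != nrow(df)) {
    stop("headerless LD matrix dimension does not match the summary table")
  }
  se <- if ("se" %in% colnames(df) && !all(is.na(df$se)))
    as.numeric(df$se) else NULL
  mafs <- if ("maf" %in% colnames(df) && !all(is.na(df$maf)))
    as.numeric(df$maf) else NULL
  pos <- if ("pos" %in% colnames(df)) as.numeric(df$pos) else NULL
  summary_dataset(z = as.numeric(df$z), ld = unname(as.matrix(ld)), n = n,
                  beta_se = se, snp_ids = df$snp, mafs = mafs,
                  positions = pos)
}

#' Read a square LD matrix
#'
#' Accepts either a matrix with a header row of SNP ids or a plink-style
#' headerless square matrix (\code{--r square} output).
#'
#' @param file path.
#' @return Numeric matrix, with attribute \code{snp_ids} when a header was
#'   present.
#' @export
read_ld_matrix <- function(file) {
  first <- strsplit(trimws(readLines(file, n = 1L)), "[\t ]+")[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(first))))
  m <- as.matrix(utils::read.table(file, header = has_header,
                                   check.names = FALSE))
  m <- unname(m)
  if (has_header) attr(m, "snp_ids") <- first
  m
}

#' Write a test result as a one-row TSV
#'
#' @param result a \code{\link{raa_result}}.
#' @param file path or connection (\code{""} prints to stdout).
#' @export
write_result_tsv <- function(result, file = "") {
  stopifnot(inherits(result, "raa_result"))
  df <- data.frame(
    method = result$method,
    stat_kind = result$stat_kind,
    statistic = format(result$statistic, digits = 17),
    df_or_eigencount = if (!is.null(result$df))
      paste(result$df, collapse = ",") else
        as.character(length(result$eigenvalues)),
    p_value = format(result$p_value, digits = 17))
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(df)
}

#' Write a genotype panel as a minimal VCF
#'
#' Emits unphased GT-only records (0/0, 0/1, 1/1) on a single contig, the
#' smallest VCF that round-trips dosages and positions.
#'
#' @param panel a \code{\link{genotype_panel}}.
#' @param file path.
#' @param chrom contig name.
#' @export
write_minimal_vcf <- function(panel, file, chrom = "1") {
  stopifnot(inherits(panel, "genotype_panel"))
  gt_map <- c("0/0", "0/1", "1/1")
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##contig=<ID=", chrom, ">"),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", panel$sample_ids),
                     collapse = "\t")), con)
  for (j in seq_along(panel$snp_ids)) {
    writeLines(paste(c(chrom,
                       format(panel$positions[j], scientific = FALSE),
                       panel$snp_ids[j], "A", "G", ".", "PASS", ".",
                       "GT", gt_map[panel$dosages[, j] + 1L]),
                     collapse = "\t"), con)
  }
  invisible(file)
}

#' Read genotypes from a VCF file
#'
#' Thin wrapper over \pkg{vcfR}: converts unphased/phased GT fields to
#' alternate-allele dosages.
#'
#' @param file VCF path.
#' @return A \code{\link{genotype_panel}}.
#' @export
read_vcf_genotypes <- function(file) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  gt <- vcfR::extract.gt(v)
  dos <- apply(gt, c(1, 2), function(g) {
    if (is.na(g)) return(NA_real_)
    sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0)
  })
  genotype_panel(t(dos),
                 snp_ids = rownames(gt) %||%
                   paste0("snp_", seq_len(nrow(gt))),
                 positions = as.numeric(v@fix[, "POS"]),
                 sample_ids = colnames(gt))
}
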