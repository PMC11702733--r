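#' Read a variant weight (scoring) file
#'
#' Reads the variant weights that define a PRS. Two dialects are supported:
#' the PGS-Catalog scoring-file dialect (tab-separated, `#`-prefixed metadata
#' header, columns `rsID`, `effect_allele`, `other_allele`, `effect_weight`,
#' optionally `chr_name`/`chr_position`) and a plain TSV with columns
#' `variant_id`, `effect_allele`, optionally `other_allele`/`chrom`/`pos`,
#' and `weight`.
#'
#' @param path Path to the scoring file.
#' @param dialect `"pgs_catalog"` or `"plain_tsv"`.
#' @return A tibble with columns `variant_id`, `effect_allele`,
#'   `other_allele` (possibly `NA`), `weight`, and `chrom`/`pos` when present.
#' @export
read_weight_file <- function(path, dialect = c("plain_tsv", "pgs_catalog")) {
  dialect <- match.arg(dialect)
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  if (dialect == "pgs_catalog") {
    require_columns(df, c("rsID", "effect_allele", "effect_weight"),
                    "PGS-Catalog scoring file")
    df <- dplyr::rename(df, variant_id = "rsID", weight = "effect_weight")
    if ("chr_name" %in% names(df)) df <- dplyr::rename(df, chrom = "chr_name")
    if ("chr_position" %in% names(df)) df <- dplyr::rename(df, pos = "chr_position")
  } else {
    require_columns(df, c("variant_id", "effect_allele", "weight"),
                    "weight file")
  }
  df <- dplyr::mutate(
    df,
    variant_id = as.character(.data$variant_id),
    weight = as.numeric(.data$weight)
  )
  keep <- intersect(c("variant_id", "chrom", "pos", "effect_allele",
                      "other_allele", "weight"), names(df))
  ws <- tibble::as_tibble(df[keep])
  validate_weight_set(ws)
  ws
}

#' Write a variant weight file
#'
#' @param weights A weight set tibble (see [read_weight_file()]).
#' @param path Output path.
#' @param dialect Output dialect; `"pgs_catalog"` prepends a `#` metadata
#'   header and uses PGS-Catalog column names.
#' @return `path`, invisibly.
#' @export
write_weight_file <- function(weights, path,
                              dialect = c("plain_tsv", "pgs_catalog")) {
  dialect <- match.arg(dialect)
  validate_weight_set(weights)
  if (dialect == "pgs_catalog") {
    out <- dplyr::rename(weights, rsID = "variant_id", effect_weight = "weight")
    if ("chrom" %in% names(out)) out <- dplyr::rename(out, chr_name = "chrom")
    if ("pos" %in% names(out)) out <- dplyr::rename(out, chr_position = "pos")
    header <- c("### PGS scoring file", "#format_version=2.0",
                sprintf("#variants_number=%d", nrow(weights)))
    writeLines(header, path)
    readr::write_tsv(out, path, append = TRUE, col_names = TRUE,
                     progress = FALSE)
  } else {
    readr::write_tsv(weights, path, progress = FALSE)
  }
  invisible(path)
}

#' Read / write an ancestry-specific allele frequency panel
#'
#' A frequency panel is a tab-separated table with one row per variant:
#' `variant_id`, `counted_allele`, and one column of allele frequencies per
#' ancestry (the ancestry names are taken from the header, in file order).
#' Frequencies are those of the counted allele within each ancestral
#' population, e.g. as estimated by frequency-deconvolution methods such as
#' GAFA, or taken from gnomAD ancestry groups.
#'
#' @param path Path to the panel file.
#' @return A tibble; ancestry names are recoverable with [panel_ancestries()].
#' @export
read_frequency_panel <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  require_columns(df, id_cols_panel, "frequency panel")
  df <- dplyr::mutate(df, variant_id = as.character(.data$variant_id))
  validate_frequency_panel(df)
  tibble::as_tibble(df)
}

#' @rdname read_frequency_panel
#' @param panel A frequency panel tibble.
#' @export
write_frequency_panel <- function(panel, path) {
  validate_frequency_panel(panel)
  readr::write_tsv(panel, path, progress = FALSE)
  invisible(path)
}

#' Read a global ancestry proportion (Q) table
#'
#' Reads an ADMIXTURE/RFMix-style table of global ancestry proportions: one
#' row per individual, one column per ancestry, plus `individual_id`. Rows
#' whose proportions sum to 1 within `renormalize_tol` are rescaled to sum to
#' exactly 1 (ancestry inference output is often rounded); larger deviations
#' raise an error.
#'
#' @param path Path to the table.
#' @param renormalize_tol Maximum tolerated deviation of a row sum from 1.
#' @return A tibble with `individual_id` and one column per ancestry.
#' @export
read_global_ancestry <- function(path, renormalize_tol = 1e-3) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  require_columns(df, "individual_id", "global ancestry table")
  df <- dplyr::mutate(df, individual_id = as.character(.data$individual_id))
  m <- as.matrix(df[setdiff(names(df), "individual_id")])
  if (any(m < 0)) {
    abort("negative global ancestry proportion", class = "eprs_validation_error")
  }
  rs <- rowSums(m)
  off <- abs(rs - 1) > renormalize_tol
  if (any(off)) {
    abort(sprintf(
      "row %d: ancestry proportions sum to %.6f (beyond renormalize_tol = %g)",
      which(off)[1], rs[which(off)[1]], renormalize_tol),
      class = "eprs_validation_error")
  }
  m <- m / rs
  out <- tibble::as_tibble(cbind(df["individual_id"], as.data.frame(m)))
  validate_global_ancestry(out)
  out
}

#' @rdname read_global_ancestry
#' @param gam A global ancestry tibble.
#' @export
write_global_ancestry <- function(gam, path) {
  validate_global_ancestry(gam)
  readr::write_tsv(gam, path, progress = FALSE)
  invisible(path)
}

#' Drop one ancestry and rescale the remaining proportions
#'
#' Removes one ancestry column from a global ancestry table and divides the
#' remaining proportions, row-wise, by their retained sum so that rows again
#' sum to 1. This is the standard treatment of a trace ancestry (e.g.
#' dropping a near-zero Oceania component before downstream analysis).
#'
#' @param gam Global ancestry tibble.
#' @param drop Name of the ancestry to drop.
#' @return A global ancestry tibble with one fewer ancestry.
#' @export
rescale_dropping_ancestry <- function(gam, drop) {
  validate_global_ancestry(gam)
  anc <- gam_ancestries(gam)
  if (!drop %in% anc) {
    abort(sprintf("'%s' is not a declared ancestry (have: %s)",
                  drop, paste(anc, collapse = ", ")))
  }
  keep <- setdiff(anc, drop)
  if (length(keep) == 0) abort("cannot drop the only ancestry")
  m <- as.matrix(gam[keep])
  rs <- rowSums(m)
  if (any(rs == 0)) {
    abort(sprintf(
      "row %d has zero total proportion in the retained ancestries; rescale undefined",
      which(rs == 0)[1]), class = "eprs_validation_error")
  }
  out <- tibble::as_tibble(cbind(gam["individual_id"], as.data.frame(m / rs)))
  validate_global_ancestry(out)
  out
}

#' Read RFMix msp-style local ancestry calls
#'
#' Parses an RFMix `msp.tsv`-style file: a first comment line declaring the
#' subpopulation code legend (`#Subpopulation order/codes: EUR=0 AFR=1 ...`),
#' a column header line (`#chm spos epos ... ind1.0 ind1.1 ...`), and one row
#' per ancestry-switch interval. Intervals are treated as 0-based half-open
#' (`spos <= pos < epos`). Each requested variant position is mapped to the
#' label of its covering interval, per haplotype.
#'
#' @param path Path to the msp file.
#' @param variant_positions Numeric vector of variant positions (same
#'   coordinate system as the file's `spos`/`epos`).
#' @param variant_ids Optional ids for the returned variant dimension.
#' @return A local ancestry tensor: an integer `n x p x 2` array with an
#'   `ancestries` attribute naming the label set (in code order).
#' @export
read_local_ancestry_msp <- function(path, variant_positions, variant_ids = NULL) {
  lines <- readLines(path)
  if (length(lines) < 3) abort("msp file too short", class = "eprs_format_error")
  legend_line <- lines[1]
  if (!grepl("codes", legend_line, ignore.case = TRUE)) {
    abort("msp file must start with a '#Subpopulation order/codes:' line",
          class = "eprs_format_error")
  }
  legend <- sub(".*:", "", legend_line)
  pairs <- strsplit(trimws(legend), "[[:space:],]+")[[1]]
  pairs <- pairs[nzchar(pairs)]
  codes <- as.integer(sub(".*=", "", pairs))
  anc_names <- sub("=.*", "", pairs)
  anc_names <- anc_names[order(codes)]

  header <- strsplit(sub("^#", "", lines[2]), "\t")[[1]]
  body <- utils::read.table(text = lines[-(1:2)], sep = "\t",
                            col.names = header, check.names = FALSE)
  fixed_cols <- 6L  # chm spos epos sgpos egpos n-snps
  hap_cols <- names(body)[-(1:fixed_cols)]
  ind_ids <- unique(sub("\\.[01]$", "", hap_cols))
  n <- length(ind_ids)
  p <- length(variant_positions)
  spos <- body[[2]]
  epos <- body[[3]]

  row_of <- vapply(variant_positions, function(pos) {
    hit <- which(spos <= pos & pos < epos)
    if (length(hit) == 0) {
      abort(sprintf("variant position %s not covered by any msp interval",
                    format(pos)), class = "eprs_validation_error")
    }
    hit[1]
  }, integer(1))

  lab <- array(NA_integer_, dim = c(n, p, 2))
  for (m in 1:2) {
    cols <- paste0(ind_ids, ".", m - 1L)
    block <- as.matrix(body[row_of, cols, drop = FALSE])  # p x n of codes
    lab[, , m] <- t(block) + 1L  # codes are 0-based
  }
  if (any(lab < 1L | lab > length(anc_names))) {
    abort("msp file contains an ancestry code outside the declared legend",
          class = "eprs_validation_error")
  }
  new_lat(lab, anc_names, ind_ids, variant_ids)
}

#' Read genotype allele counts
#'
#' Reads either a VCF (biallelic records only; counts of the ALT allele from
#' the GT field, or DS dosages when GT is absent) or a plain dosage TSV with
#' individuals in rows, variants in columns, and an `individual_id` first
#' column. Dosage files may declare counted alleles with a comment line
#' `#counted_allele<TAB>id=A<TAB>id2=G...`. Missing genotypes become `NA`.
#' Multiallelic VCF records are skipped with a warning.
#'
#' @param path Path to the genotype file.
#' @param format `"dosage_tsv"` or `"vcf"`.
#' @return A numeric individuals-by-variants matrix of allele counts in
#'   `[0, 2]`, with a `counted_allele` attribute (named character vector)
#'   when the source declares one.
#' @export
read_genotypes <- function(path, format = c("dosage_tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "dosage_tsv") {
    lines <- readLines(path, n = 5L)
    counted <- NULL
    ca_line <- grep("^#counted_allele", lines, value = TRUE)
    if (length(ca_line) == 1) {
      pairs <- strsplit(sub("^#counted_allele\\s+", "", ca_line), "[\t ]+")[[1]]
      counted <- sub(".*=", "", pairs)
      names(counted) <- sub("=.*", "", pairs)
    }
    df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                          progress = FALSE)
    require_columns(df, "individual_id", "dosage matrix")
    g <- as.matrix(df[setdiff(names(df), "individual_id")])
    rownames(g) <- as.character(df$individual_id)
    validate_genotypes(g)
    if (!is.null(counted)) attr(g, "counted_allele") <- counted
    return(g)
  }
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    abort("reading VCF requires the VariantAnnotation package")
  }
  vcf <- VariantAnnotation::readVcf(path)
  alt <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt)
  multi <- n_alt > 1
  if (any(multi)) {
    warn(sprintf("skipping %d multiallelic VCF record(s)", sum(multi)))
    vcf <- vcf[!multi]
    alt <- alt[!multi]
  }
  geno <- VariantAnnotation::geno(vcf)
  if ("GT" %in% names(geno)) {
    gt <- geno$GT  # variants x samples, strings like "0/1", "1|1", "./."
    count1 <- function(s) {
      a <- strsplit(s, "[/|]")[[1]]
      if (any(a == "." | a == "")) return(NA_real_)
      sum(a != "0")
    }
    g <- apply(gt, c(1, 2), count1)
  } else if ("DS" %in% names(geno)) {
    g <- geno$DS
  } else {
    abort("VCF has neither GT nor DS genotype fields",
          class = "eprs_format_error")
  }
  g <- t(g)  # individuals x variants
  validate_genotypes(g)
  attr(g, "counted_allele") <-
    stats::setNames(as.character(unlist(alt)), colnames(g))
  g
}

#' @rdname read_genotypes
#' @param genotypes Individuals-by-variants dosage matrix.
#' @export
write_dosage_tsv <- function(genotypes, path) {
  validate_genotypes(genotypes)
  counted <- attr(genotypes, "counted_allele")
  df <- tibble::as_tibble(genotypes, .name_repair = "minimal")
  df <- dplyr::bind_cols(tibble::tibble(individual_id = rownames(genotypes)), df)
  if (!is.null(counted)) {
    writeLines(paste0("#counted_allele\t",
                      paste0(names(counted), "=", counted, collapse = "\t")),
               path)
    readr::write_tsv(df, path, append = TRUE, col_names = TRUE, progress = FALSE)
  } else {
    readr::write_tsv(df, path, progress = FALSE)
  }
  invisible(path)
}
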