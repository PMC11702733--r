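#' @importFrom rlang abort warn inform %||%
#' @importFrom stats pnorm rnorm runif rbinom sd var coef lm glm quantile
#' @importFrom utils head
NULL

VALID_ALLELES <- c("A", "C", "G", "T")

id_cols_panel <- c("variant_id", "counted_allele")

#' Ancestry labels declared by a frequency panel
#'
#' The panel's ancestry set is defined by its frequency columns, in file
#' column order (every column other than `variant_id` and `counted_allele`).
#'
#' @param panel An ancestry frequency panel, as returned by
#'   [read_frequency_panel()] or [synthesize_frequency_panel()].
#' @return Character vector of ancestry names.
#' @export
panel_ancestries <- function(panel) {
  setdiff(names(panel), id_cols_panel)
}

#' @rdname panel_ancestries
#' @param gam A global ancestry proportion table (one row per individual,
#'   one column per ancestry plus `individual_id`).
#' @export
gam_ancestries <- function(gam) {
  setdiff(names(gam), "individual_id")
}

# p x K frequency matrix, rows ordered as `panel`, columns named by ancestry
freq_matrix <- function(panel) {
  anc <- panel_ancestries(panel)
  m <- as.matrix(panel[anc])
  rownames(m) <- panel$variant_id
  m
}

gam_matrix <- function(gam) {
  m <- as.matrix(gam[gam_ancestries(gam)])
  rownames(m) <- gam$individual_id
  m
}

# Lehmer-style substream seed derivation. Keeps everything below 2^31 - 1 so
# set.seed() receives a valid 32-bit integer; exact in double precision
# because all intermediates stay below 2^53.
derive_seed <- function(seed, index) {
  m <- 2147483647
  s <- (abs(as.numeric(seed)) %% m)
  s <- (s * 48271 + as.numeric(index) * 16807 + 1) %% m
  as.integer(s)
}

stop_not_df <- function(x, what, arg) {
  if (!is.data.frame(x)) {
    abort(sprintf("`%s` must be a data frame (%s).", arg, what))
  }
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column%s: %s",
      what, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
    ), class = "eprs_format_error")
  }
}

validate_weight_set <- function(weights, arg = "weights") {
  stop_not_df(weights, "weight set", arg)
  require_columns(weights, c("variant_id", "effect_allele", "weight"), "weight set")
  if (anyDuplicated(weights$variant_id)) {
    dups <- unique(weights$variant_id[duplicated(weights$variant_id)])
    abort(sprintf("duplicated variant_id in weight set: %s",
                  paste(head(dups, 5), collapse = ", ")),
          class = "eprs_validation_error")
  }
  if (!all(is.finite(weights$weight))) {
    abort("weight set contains non-finite weights", class = "eprs_validation_error")
  }
  bad <- !weights$effect_allele %in% VALID_ALLELES
  if (any(bad)) {
    abort(sprintf("effect_allele must be one of A/C/G/T (offending: %s)",
                  paste(head(unique(weights$effect_allele[bad]), 5), collapse = ", ")),
          class = "eprs_validation_error")
  }
  if ("other_allele" %in% names(weights)) {
    both <- !is.na(weights$other_allele)
    if (any(weights$effect_allele[both] == weights$other_allele[both])) {
      abort("effect_allele must differ from other_allele",
            class = "eprs_validation_error")
    }
  }
  invisible(weights)
}

validate_frequency_panel <- function(panel, arg = "panel") {
  stop_not_df(panel, "frequency panel", arg)
  require_columns(panel, id_cols_panel, "frequency panel")
  anc <- panel_ancestries(panel)
  if (length(anc) < 1) {
    abort("frequency panel declares no ancestry columns",
          class = "eprs_validation_error")
  }
  if (anyDuplicated(anc)) {
    abort("ancestry names must be unique", class = "eprs_validation_error")
  }
  if (anyDuplicated(panel$variant_id)) {
    abort("duplicated variant_id in frequency panel",
          class = "eprs_validation_error")
  }
  for (a in anc) {
    f <- panel[[a]]
    bad <- which(!is.finite(f) | f < 0 | f > 1)
    if (length(bad) > 0) {
      abort(sprintf("frequency outside [0, 1] in ancestry '%s' at row %d",
                    a, bad[1]),
            class = "eprs_validation_error")
    }
  }
  invisible(panel)
}

validate_global_ancestry <- function(gam, tol = 1e-6, arg = "gam") {
  stop_not_df(gam, "global ancestry table", arg)
  require_columns(gam, "individual_id", "global ancestry table")
  m <- gam_matrix(gam)
  if (ncol(m) < 1) abort("no ancestry columns", class = "eprs_validation_error")
  if (any(m < 0)) {
    abort("negative global ancestry proportion", class = "eprs_validation_error")
  }
  rs <- rowSums(m)
  if (any(abs(rs - 1) > tol)) {
    abort(sprintf("global ancestry proportions of row %d sum to %.6f, not 1",
                  which.max(abs(rs - 1)), rs[which.max(abs(rs - 1))]),
          class = "eprs_validation_error")
  }
  invisible(gam)
}

# Local ancestry tensors are integer arrays n x p x 2 whose entries index the
# ancestry set stored in attr(, "ancestries"); dimnames hold individual and
# variant ids.
validate_lat <- function(lat, arg = "lat") {
  if (!is.array(lat) || length(dim(lat)) != 3 || dim(lat)[3] != 2) {
    abort(sprintf("`%s` must be an n x p x 2 local-ancestry array", arg))
  }
  anc <- attr(lat, "ancestries")
  if (is.null(anc)) abort("local-ancestry array lacks an 'ancestries' attribute")
  if (any(lat < 1L | lat > length(anc))) {
    abort("local-ancestry labels outside the declared ancestry set",
          class = "eprs_validation_error")
  }
  invisible(lat)
}

lat_ancestries <- function(lat) attr(lat, "ancestries")

new_lat <- function(labels, ancestries, individual_ids = NULL, variant_ids = NULL) {
  storage.mode(labels) <- "integer"
  dimnames(labels) <- list(individual_ids, variant_ids, c("hap1", "hap2"))
  structure(labels, ancestries = ancestries, class = c("eprs_lat", "array"))
}

#' @export
print.eprs_lat <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<local ancestry tensor: %d individuals x %d variants x 2 haplotypes>\n",
    d[1], d[2]))
  cat("ancestries:", paste(attr(x, "ancestries"), collapse = ", "), "\n")
  invisible(x)
}

validate_genotypes <- function(g, arg = "genotypes") {
  if (!is.matrix(g) || !is.numeric(g)) {
    abort(sprintf("`%s` must be a numeric individuals x variants matrix", arg))
  }
  vals <- g[!is.na(g)]
  if (length(vals) && (min(vals) < 0 || max(vals) > 2)) {
    abort("genotype allele counts must lie in [0, 2]",
          class = "eprs_validation_error")
  }
  invisible(g)
}
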