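#' Harmonize a weight set, a frequency panel, and (optionally) genotypes
#'
#' Aligns all inputs to a shared, identically ordered set of variants and a
#' common counted allele, so that the PRS and its expectation count the same
#' allele. Variants are matched by `variant_id`. When the panel's counted
#' allele equals the weight set's *other* allele, the panel frequencies are
#' flipped (`f -> 1 - f`); when a genotype matrix declares counted alleles
#' and one mismatches the effect allele, its counts are flipped
#' (`g -> 2 - g`). Variants whose alleles cannot be reconciled with the
#' effect/other pair are dropped. Strand-ambiguous (A/T, C/G) variants are
#' kept, matched by id only, with a warning; no strand inference is
#' attempted (the intended use is frequencies and genotypes from the same
#' build and panel). Multiallelic handling happens upstream in
#' [read_genotypes()].
#'
#' Harmonization is idempotent: applying it to its own output is a no-op.
#'
#' @param weights Weight set tibble (see [read_weight_file()]).
#' @param panel Frequency panel tibble (see [read_frequency_panel()]).
#' @param genotypes Optional individuals-by-variants dosage matrix.
#' @return A list of class `eprs_harmonized` with elements `weights`,
#'   `panel`, `genotypes` (or `NULL`), and `report`, a one-row tibble with
#'   counts `n_kept`, `n_flipped_freq`, `n_flipped_geno`, `n_dropped` and a
#'   list-column `dropped_ids`.
#' @export
harmonize <- function(weights, panel, genotypes = NULL) {
  validate_weight_set(weights)
  validate_frequency_panel(panel)
  if (!is.null(genotypes)) validate_genotypes(genotypes)

  ids <- intersect(weights$variant_id, panel$variant_id)
  if (!is.null(genotypes)) ids <- intersect(ids, colnames(genotypes))
  if (length(ids) == 0) {
    abort("no variants shared between the weight set and the frequency panel",
          class = "eprs_validation_error")
  }
  ids <- weights$variant_id[weights$variant_id %in% ids]  # keep weight order

  w <- weights[match(ids, weights$variant_id), ]
  p <- panel[match(ids, panel$variant_id), ]

  other0 <- if ("other_allele" %in% names(w)) w$other_allele else rep(NA_character_, nrow(w))
  ambiguous <- !is.na(other0) &
    paste0(w$effect_allele, other0) %in% c("AT", "TA", "CG", "GC")
  if (any(ambiguous)) {
    warn(sprintf(
      "%d strand-ambiguous (A/T or C/G) variant(s) kept and matched by id only",
      sum(ambiguous)))
  }

  other <- other0
  match_effect <- p$counted_allele == w$effect_allele
  match_other <- !is.na(other) & p$counted_allele == other
  drop <- !(match_effect | match_other)
  flip_freq <- match_other & !match_effect

  anc <- panel_ancestries(p)
  if (any(flip_freq)) {
    p[flip_freq, anc] <- 1 - p[flip_freq, anc]
    p$counted_allele[flip_freq] <- w$effect_allele[flip_freq]
  }

  n_flipped_geno <- 0L
  g <- NULL
  if (!is.null(genotypes)) {
    g <- genotypes[, ids, drop = FALSE]
    counted_g <- attr(genotypes, "counted_allele")
    if (!is.null(counted_g)) {
      cg <- counted_g[ids]
      g_match_eff <- !is.na(cg) & cg == w$effect_allele
      g_match_oth <- !is.na(cg) & !is.na(other) & cg == other
      drop <- drop | (!is.na(cg) & !(g_match_eff | g_match_oth))
      flip_g <- g_match_oth & !g_match_eff
      if (any(flip_g)) {
        g[, flip_g] <- 2 - g[, flip_g]
        cg[flip_g] <- w$effect_allele[flip_g]
        n_flipped_geno <- sum(flip_g & !drop)
      }
      attr(g, "counted_allele") <- cg
    }
  }

  keep <- !drop
  if (!any(keep)) {
    abort("all shared variants dropped during allele harmonization",
          class = "eprs_validation_error")
  }
  dropped_ids <- ids[drop]
  w <- w[keep, ]
  p <- p[keep, ]
  if (!is.null(g)) {
    ca <- attr(g, "counted_allele")
    g <- g[, keep, drop = FALSE]
    if (!is.null(ca)) attr(g, "counted_allele") <- ca[keep]
  }

  report <- tibble::tibble(
    n_input = length(ids),
    n_kept = sum(keep),
    n_flipped_freq = sum(flip_freq & keep),
    n_flipped_geno = n_flipped_geno,
    n_dropped = sum(drop),
    dropped_ids = list(dropped_ids)
  )
  structure(list(weights = w, panel = p, genotypes = g, report = report),
            class = "eprs_harmonized")
}

#' @export
print.eprs_harmonized <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "<harmonized PRS inputs: %d variants kept (%d freq-flipped, %d geno-flipped, %d dropped)>\n",
    r$n_kept, r$n_flipped_freq, r$n_flipped_geno, r$n_dropped))
  invisible(x)
}
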