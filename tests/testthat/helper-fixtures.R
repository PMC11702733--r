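# Small in-code fixtures shared across tests. Everything is generated
# programmatically; tests that need randomness set their own seed first.

make_weights <- function(p = 3, w = NULL, prefix = "v") {
  tibble::tibble(
    variant_id = sprintf("%s%d", prefix, seq_len(p)),
    effect_allele = rep(c("A", "C"), length.out = p),
    other_allele = rep(c("G", "T"), length.out = p),
    weight = w %||% seq(0.1, by = 0.1, length.out = p)
  )
}

make_panel <- function(p = 3, K = 3, f = NULL, ancestries = paste0("a", seq_len(K)),
                       prefix = "v", counted = NULL) {
  fm <- if (is.null(f)) matrix(runif(p * K, 0.1, 0.9), p, K) else f
  colnames(fm) <- ancestries
  tibble::tibble(
    variant_id = sprintf("%s%d", prefix, seq_len(p)),
    counted_allele = counted %||% rep(c("A", "C"), length.out = p)
  ) |>
    dplyr::bind_cols(tibble::as_tibble(as.data.frame(fm)))
}

make_gam <- function(m, ancestries = paste0("a", seq_len(ncol(m)))) {
  colnames(m) <- ancestries
  tibble::as_tibble(as.data.frame(m)) |>
    dplyr::mutate(individual_id = sprintf("i%d", seq_len(nrow(m))), .before = 1)
}

# lat tensor from explicit per-haplotype label matrices
make_lat <- function(lab1, lab2, ancestries) {
  arr <- array(0L, dim = c(nrow(lab1), ncol(lab1), 2))
  arr[, , 1] <- lab1
  arr[, , 2] <- lab2
  eprs:::new_lat(arr, ancestries,
                 sprintf("i%d", seq_len(nrow(lab1))),
                 sprintf("v%d", seq_len(ncol(lab1))))
}

`%||%` <- rlang::`%||%`
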