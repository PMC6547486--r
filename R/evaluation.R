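# Decoy-set evaluation: native recognition, Z-score of the native energy,
# Pearson correlation between energy and model quality, and 20% enrichment.
# Natives are excluded from the correlation and enrichment statistics.

#' Z-score of the native structure within a decoy set
#'
#' `z = (<E_decoy> - E_native) / sd(E_decoy)` with the population standard
#' deviation (divide by n); higher is better. Undefined (NA) when the decoy
#' energies have zero spread.
#'
#' @param native_energy Energy of the native structure.
#' @param decoy_energies Energies of the decoys (length >= 2).
#' @return Numeric z, or `NA` when undefined.
#' @export
#' @examples
#' native_zscore(-100, c(-60, -50, -40)) # positive: native well separated
native_zscore <- function(native_energy, decoy_energies) {
  stopifnot(length(decoy_energies) >= 2)
  delta <- sqrt(mean((decoy_energies - mean(decoy_energies))^2))
  if (delta == 0) return(NA_real_)
  (mean(decoy_energies) - native_energy) / delta
}

#' Is the native structure recognized?
#'
#' TRUE iff the native has strictly the lowest energy in the set; ties with
#' the best decoy count as failure.
#'
#' @inheritParams native_zscore
#' @return Logical.
#' @export
recognize_native <- function(native_energy, decoy_energies) {
  native_energy < min(decoy_energies)
}

#' Pearson correlation between energies and quality scores
#'
#' For a useful potential the correlation with TM-score/GDT_TS-like quality
#' scores is negative (low energy, high quality). Undefined (NA) when either
#' vector has zero variance.
#'
#' @param energies Decoy energies (native excluded).
#' @param quality_scores Matching model quality scores.
#' @return Correlation in `[-1, 1]` or `NA`.
#' @export
pcc_energy_quality <- function(energies, quality_scores) {
  stopifnot(length(energies) == length(quality_scores),
            length(energies) >= 3)
  if (stats::sd(energies) == 0 || stats::sd(quality_scores) == 0)
    return(NA_real_)
  stats::cor(energies, quality_scores)
}

#' 20% enrichment of a decoy ranking
#'
#' Relative occurrence of the most accurate 20% of models (by quality score)
#' among the 20% best-scoring models (by energy), normalised so that a random
#' ranking gives 1 and a perfect one 5. With `N` decoys and
#' `k = max(1, floor(N/5))`: `|top_k(quality) intersect top_k(energy)| * N / k^2`.
#' Ties are broken by stable input order.
#'
#' @inheritParams pcc_energy_quality
#' @return Value in `[0, 5]`.
#' @export
enrichment20 <- function(energies, quality_scores) {
  n <- length(energies)
  stopifnot(n == length(quality_scores), n >= 5)
  k <- max(1L, as.integer(floor(0.2 * n)))
  top_quality <- order(-quality_scores)[seq_len(k)]
  top_energy <- order(energies)[seq_len(k)]
  length(intersect(top_quality, top_energy)) * n / k^2
}

#' Evaluate one decoy set
#'
#' @param native_energy Energy of the native.
#' @param decoy_energies Decoy energies.
#' @param quality_scores Optional quality scores matching the decoys.
#' @param set_id Identifier carried into the result row.
#' @return One-row data frame with `set_id`, `native_energy`, `n_decoys`,
#'   `recognized`, `z_score`, `pcc`, `enrichment20`.
#' @export
evaluate_decoy_set <- function(native_energy, decoy_energies,
                               quality_scores = NULL, set_id = "set") {
  pcc <- NA_real_
  enr <- NA_real_
  if (!is.null(quality_scores)) {
    pcc <- pcc_energy_quality(decoy_energies, quality_scores)
    enr <- enrichment20(decoy_energies, quality_scores)
  }
  data.frame(set_id = set_id,
             native_energy = native_energy,
             n_decoys = length(decoy_energies),
             recognized = recognize_native(native_energy, decoy_energies),
             z_score = native_zscore(native_energy, decoy_energies),
             pcc = pcc,
             enrichment20 = enr,
             stringsAsFactors = FALSE)
}

read_quality_scores <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (is.character(tab[[2]][1]) && is.na(suppressWarnings(as.numeric(tab[[2]][1]))))
    tab <- tab[-1, , drop = FALSE]  # optional header line
  stats::setNames(as.numeric(tab[[2]]), tab[[1]])
}

#' Benchmark a directory of decoy sets
#'
#' Expects one sub-directory per decoy set containing `native.pdb`, any
#' number of decoy `*.pdb` files, and optionally a two-column TSV of quality
#' scores (`model-id<TAB>score`, model-id = decoy file name without `.pdb`).
#' Sets without scores contribute to native recognition and Z-score only.
#'
#' @param dir Benchmark directory.
#' @param potential An `andis_potential`.
#' @param r_cut Distance cutoff used for scoring.
#' @param scores_name File name of the per-set quality table.
#' @return Data frame with one row per set (columns of
#'   [evaluate_decoy_set()]); summary means in attribute `"summary"`.
#' @export
benchmark_decoy_sets <- function(dir, potential, r_cut = 15,
                                 scores_name = "scores.tsv") {
  sets <- list.dirs(dir, recursive = FALSE)
  if (length(sets) == 0L) {
    warning("no decoy sets found in ", dir)
    return(data.frame())
  }
  rows <- lapply(sets, function(sd) {
    native_path <- file.path(sd, "native.pdb")
    decoy_paths <- setdiff(list.files(sd, pattern = "\\.pdb$",
                                      full.names = TRUE), native_path)
    native_e <- score_structure(read_pdb(native_path), potential, r_cut)$energy
    decoy_e <- vapply(decoy_paths, function(p)
      score_structure(read_pdb(p), potential, r_cut)$energy, numeric(1))
    ids <- sub("\\.pdb$", "", basename(decoy_paths))
    quality <- NULL
    score_path <- file.path(sd, scores_name)
    if (file.exists(score_path)) {
      q <- read_quality_scores(score_path)
      if (all(ids %in% names(q))) quality <- unname(q[ids])
      else message("score table incomplete for set ", basename(sd),
                   "; skipping pcc/enrichment")
    }
    evaluate_decoy_set(native_e, unname(decoy_e), quality, basename(sd))
  })
  out <- do.call(rbind, rows)
  attr(out, "summary") <- list(
    n_sets = nrow(out),
    n_recognized = sum(out$recognized),
    mean_z = mean(out$z_score, na.rm = TRUE),
    mean_pcc = mean(out$pcc, na.rm = TRUE),
    mean_enrichment = mean(out$enrichment20, na.rm = TRUE),
    n_undefined_pcc = sum(is.na(out$pcc)))
  out
}
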