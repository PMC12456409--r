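#' Percent specific migration
#'
#' Percentage of input cells that migrated across the transwell filter:
#' `100 * n_migrated / n_input`.
#'
#' @param n_migrated,n_input cell counts (vectorized).
#' @return percentage(s) in `[0, 100]`.
#' @export
percent_migrated <- function(n_migrated, n_input) {
  if (any(!is.finite(n_input)) || any(!is.finite(n_migrated)))
    abort_data("counts must be finite")
  if (any(n_input <= 0)) abort_data("`n_input` must be positive")
  if (any(n_migrated < 0)) abort_data("`n_migrated` must be non-negative")
  if (any(n_migrated > n_input))
    abort_data("n_migrated exceeds n_input (inconsistent counts)")
  100 * n_migrated / n_input
}

#' Migration relative to a per-donor reference
#'
#' Normalizes each treatment's migration percentage to its own donor's
#' reference condition, `100 * treatment / reference` — computed within
#' donor before any averaging across donors.
#'
#' @param treatment_pct,reference_pct migration percentages (vectorized;
#'   elements are matched within donor).
#' @return percentage(s) of the reference.
#' @export
relative_migration <- function(treatment_pct, reference_pct) {
  if (any(!is.finite(treatment_pct)) || any(!is.finite(reference_pct)))
    abort_data("percentages must be finite")
  if (any(reference_pct <= 0))
    abort_data("reference migration must be positive")
  if (any(treatment_pct < 0))
    abort_data("treatment migration must be non-negative")
  100 * treatment_pct / reference_pct
}

#' In vivo homing index of two co-injected dye-labelled populations
#'
#' `HI = (pct_fr_tissue / pct_v_tissue) / (pct_fr_input / pct_v_input)`:
#' the far-red population's representation in the tissue relative to the
#' injected mixture, against the violet population. `HI = 1` means both
#' populations homed equally; swapping the dye labels maps `HI` to
#' `1 / HI`; rescaling the tissue (or input) percentages by a common
#' factor leaves `HI` unchanged.
#'
#' @param pct_fr_tissue,pct_v_tissue percent far-red / violet signal in
#'   the tissue.
#' @param pct_fr_input,pct_v_input percent far-red / violet signal in the
#'   injected input.
#' @return homing index (vectorized, dimensionless).
#' @examples
#' homing_index(60, 40, 50, 50)  # 1.5
#' @export
homing_index <- function(pct_fr_tissue, pct_v_tissue, pct_fr_input,
                         pct_v_input) {
  vals <- cbind(pct_fr_tissue, pct_v_tissue, pct_fr_input, pct_v_input)
  if (any(!is.finite(vals))) abort_data("percentages must be finite")
  if (any(vals <= 0))
    abort_data("all four percentages must be positive (zero denominator)")
  (pct_fr_tissue / pct_v_tissue) / (pct_fr_input / pct_v_input)
}

#' Simulate transwell migration counts
#'
#' Binomial stand-in for a transwell experiment: each replicate draws
#' `Binomial(n_input, p_migrate)` migrated cells.
#'
#' @param n_input cells seeded per replicate.
#' @param p_migrate true migration probability in `[0, 1]`.
#' @param n_replicates number of replicates.
#' @param seed integer seed.
#' @param label row label (default `"synthetic"`).
#' @return data.frame with columns `label`, `replicate`, `n_input`,
#'   `n_migrated`; the true fraction is attached as
#'   `attr(, "ground_truth")`.
#' @export
generate_migration_counts <- function(n_input, p_migrate, n_replicates = 3,
                                      seed = 1L, label = "synthetic") {
  n_input <- check_count(n_input, "n_input", lower = 1L)
  check_scalar(p_migrate, "p_migrate", lower = 0, upper = 1)
  n_replicates <- check_count(n_replicates, "n_replicates", lower = 1L)
  seed <- check_count(seed, "seed", lower = 0L)
  with_seed(seed, {
    out <- data.frame(label = label, replicate = seq_len(n_replicates),
                      n_input = n_input,
                      n_migrated = stats::rbinom(n_replicates, n_input,
                                                 p_migrate))
    attr(out, "ground_truth") <- p_migrate
    out
  })
}
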