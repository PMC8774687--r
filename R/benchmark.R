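#' Simulated trisomy benchmark at the published operating point
#'
#' Runs the whole pipeline on one synthetic cohort at the stated conditions:
#' `n_controls` event-free reference samples plus one whole-chromosome gain
#' case at fetal fraction `ff` (cohort average 7.5% by default),
#' 0.25x-equivalent bin coverage on 750 kb bins over a 22-pseudo-chromosome
#' genome, reference with `K = 300` neighbors and 5 PCs per datatype, then
#' mode-I calling on the Fisher-combined track. The planted chromosome is the
#' grid's last one (the chromosome-21 analogue, 45 Mb).
#'
#' @param seed master seed for the cohort and segmentation.
#' @param ff case fetal fraction (default 0.075).
#' @param n_controls reference panel size (default 50).
#' @param grid pseudo-genome (default [sim_grid()]).
#' @param combine per-bin combination method (default `"fisher"`).
#' @param n_perm CBS permutations (default 1000).
#' @return list: `events` (mode-I event table), `z_segment` (segment Z of the
#'   call on the planted chromosome, NA if absent), `target_chrom`,
#'   `result` (full [predict_sample()] output), `truth`.
#' @export
t21_benchmark <- function(seed = 1L, ff = 0.075, n_controls = 50L,
                          grid = sim_grid(), combine = "fisher",
                          n_perm = 1000L) {
  params <- sim_params(grid = grid, n_controls = n_controls, n_cases = 1L,
                       ff = ff, seed = seed)
  co <- simulate_cohort(params)
  ref <- build_reference_set(co$panel, K = 300L, n_comp = 5L)
  res <- predict_sample(co$cases[[1L]], ref, mode = "I", combine = combine,
                        n_perm = n_perm, seed = seed)
  target <- params$cnv$chrom
  hit <- res$events[res$events$chrom == target, , drop = FALSE]
  list(events = res$events,
       z_segment = if (nrow(hit)) max(hit$z_segment) else NA_real_,
       target_chrom = target,
       result = res,
       truth = co$truth)
}
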