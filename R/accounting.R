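#' Partition a count by fixed ratios
#'
#' Integer partition of `n` items by the given ratios using the
#' largest-remainder rule, e.g. the 8:1:1 train/validation/test split of
#' an image corpus. The parts always sum to `n`.
#'
#' @param n Total count.
#' @param ratios Positive weights (need not sum to 1).
#' @return Integer vector, same length (and names) as `ratios`.
#' @export
partition_counts <- function(n, ratios) {
  abort_if(n < 0 || any(ratios < 0) || sum(ratios) == 0,
           "need n >= 0 and non-negative ratios with a positive sum")
  exact <- n * ratios / sum(ratios)
  base <- floor(exact)
  short <- n - sum(base)
  if (short > 0) {
    give <- order(exact - base, decreasing = TRUE)[seq_len(short)]
    base[give] <- base[give] + 1
  }
  stats::setNames(as.integer(base), names(ratios))
}

#' Labor bookkeeping for manual versus automated weighing
#'
#' Totals the staff time of daily manual weighing against the automated
#' camera-based routine over a monitoring campaign and reports the
#' saving.
#'
#' @param manual_h_per_day Hours/day of manual weighing (default 2).
#' @param auto_h_per_day Hours/day of the automated routine (default
#'   0.25, i.e. 15 minutes).
#' @param days Campaign length, days (default 150).
#' @return List: `manual_total_h`, `auto_total_h`, `saving_h`,
#'   `saving_pct`.
#' @export
labor_accounting <- function(manual_h_per_day = 2, auto_h_per_day = 0.25,
                             days = 150) {
  abort_if(manual_h_per_day <= 0 || auto_h_per_day < 0 || days <= 0,
           "times and days must be positive")
  manual <- manual_h_per_day * days
  auto <- auto_h_per_day * days
  list(manual_total_h = manual, auto_total_h = auto,
       saving_h = manual - auto,
       saving_pct = (manual - auto) / manual * 100)
}
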