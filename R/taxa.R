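# Conditioning on a number of extant species: first-passage stopping, or the
# general sampling approach (GSA), which simulates up to m >> n coexisting
# lineages and cuts the realization at a time drawn uniformly over all
# periods during which exactly n lineages coexist -- avoiding the bias of
# first-passage stopping towards young trees.

#' Simulate trees conditioned on a number of extant species
#'
#' With `gsa = FALSE`, the process is stopped the first time `n` lineages
#' coexist, and the tree is cut exactly at that speciation event (the two
#' newest tips then have zero-length pendant edges). With `gsa = TRUE`, the
#' process is first run until `m` (`m > n`, ideally `m >> n`; a common
#' heuristic is `m >= 10 n`) lineages coexist; the cut time is then drawn
#' uniformly over the union of all time intervals during which exactly `n`
#' lineages coexisted, which yields an unbiased sample of trees with `n`
#' extant species.
#'
#' Realizations that die out (or stall) before reaching the target count are
#' discarded and redrawn, up to `config$retry_cap` attempts; the number of
#' attempts consumed is reported in the result.
#'
#' @param n Number of extant species required (>= 2).
#' @param config A [sim_config()].
#' @param gsa Logical; use the general sampling approach.
#' @param m Number of coexisting species to simulate to under GSA (required
#'   when `gsa = TRUE`; must exceed `n`).
#' @param seed Optional integer seed.
#' @return A `bh_sim` result (see [sim_age()]); its tree always has exactly
#'   `n` extant tips (before any incomplete sampling).
#' @examples
#' res <- sim_taxa(20, sim_config("rexp(0.5)"), seed = 1)
#' tree_stats(res$tree)$extant_tips # 20
#' @export
sim_taxa <- function(n, config, gsa = FALSE, m = NULL, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- as.integer(n)
  if (is.na(n) || n < 2L) {
    bh_stop("bhtree_bad_n", "n must be an integer >= 2")
  }
  if (gsa) {
    if (is.null(m)) bh_stop("bhtree_bad_m", "gsa = TRUE requires m")
    m <- as.integer(m)
    if (is.na(m) || m <= n) bh_stop("bhtree_bad_m", "m must exceed n")
  }
  if (!is.null(seed)) set.seed(seed)
  target <- if (gsa) m else n
  for (attempt in seq_len(config$retry_cap)) {
    eng <- run_engine(config, target = target)
    if (!eng$reached) next
    if (gsa) {
      lin_full <- finalize_lineages(eng, eng$horizon)
      tl <- lineage_count_timeline(lin_full)
      iv <- n_count_intervals(tl, n, eng$horizon)
      if (nrow(iv) == 0L) next # count skipped over n without positive dwell time
      tcut <- sample_cut_time(iv)
      lin <- cut_at_time(lin_full, tcut)
      horizon <- tcut
    } else {
      lin <- finalize_lineages(eng, eng$horizon)
      horizon <- eng$horizon
    }
    return(bh_result(lin, horizon, config, attempts = attempt))
  }
  bh_stop("bhtree_retry_exhausted",
          sprintf("target of %d coexisting species not reached in %d attempts (extinction-dominated or stalling configuration)",
                  target, config$retry_cap))
}

#' Intervals on which the lineage count equals n
#'
#' Decomposes a lineages-through-time step function into the maximal
#' disjoint intervals on which exactly `n` lineages coexist, clipped to
#' `[0, horizon)`. Zero-duration states (transient counts inside an instant
#' of simultaneous point-mass events) never occur in the aggregated
#' timeline, so every returned interval has positive length.
#'
#' @param timeline A step function as returned by
#'   [lineage_count_timeline()].
#' @param n Target lineage count.
#' @param horizon Right end of the observation window.
#' @return Data frame with columns `start`, `end`, `count`.
#' @export
n_count_intervals <- function(timeline, n, horizon) {
  stopifnot(is.data.frame(timeline), nrow(timeline) >= 1L, horizon >= 0)
  starts <- timeline$time
  ends <- c(timeline$time[-1L], Inf)
  ends <- pmin(ends, horizon)
  keep <- timeline$count == n & starts < ends
  out <- data.frame(start = starts[keep], end = ends[keep],
                    count = timeline$count[keep])
  rownames(out) <- NULL
  out
}

#' Draw a cut time uniformly over a union of intervals
#'
#' Selects one interval with probability proportional to its length, then a
#' time uniformly within it -- i.e. a uniform draw over the union. This is
#' the GSA cut-time rule.
#'
#' @param intervals Data frame with `start` and `end` columns (disjoint,
#'   positive length).
#' @return A single time point.
#' @export
sample_cut_time <- function(intervals) {
  stopifnot(is.data.frame(intervals), nrow(intervals) >= 1L)
  len <- intervals$end - intervals$start
  stopifnot(all(len > 0))
  i <- if (nrow(intervals) == 1L) 1L else sample.int(nrow(intervals), 1L, prob = len)
  stats::runif(1L, intervals$start[i], intervals$end[i])
}

#' Truncate a simulated lineage set at a time point
#'
#' Removes every event after time `t`: lineages born after `t` are dropped,
#' and lineages still alive at `t` (including mothers whose terminating
#' speciation lay beyond `t`) become extant tips with end time `t`.
#' Lineages already extinct by `t` are retained, so the result is a
#' complete-tree record. Events at exactly `t` are kept (a cut at a
#' speciation instant keeps the zero-length daughters).
#'
#' @param lineages A lineage table (or `bh_sim` result, whose `$lineages`
#'   is used).
#' @param t Cut time in `[0, horizon]`.
#' @return A truncated lineage table with `horizon` attribute `t`.
#' @export
cut_at_time <- function(lineages, t) {
  if (inherits(lineages, "bh_sim")) lineages <- lineages$lineages
  horizon <- attr(lineages, "horizon")
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0) {
    bh_stop("bhtree_bad_cut", "cut time must be a single non-negative number")
  }
  if (!is.null(horizon) && t > horizon) {
    bh_stop("bhtree_bad_cut", sprintf("cut time %g lies beyond the simulated horizon %g", t, horizon))
  }
  keep <- lineages$origin <= t
  lin <- lineages[keep, , drop = FALSE]
  open <- is.na(lin$end) | lin$end > t
  lin$end[open] <- t
  lin$fate[open] <- "extant"
  rownames(lin) <- NULL
  attr(lin, "horizon") <- t
  lin
}
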