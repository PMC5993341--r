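# Batch execution with reproducible per-replicate substreams, Figure-4-style
# summary statistics, and the constant-rate event estimators used for
# cross-validation.

#' Deterministic per-replicate seed
#'
#' Derives the seed of replicate `k` from a master seed by a Lehmer-style
#' integer hash modulo 2^31 - 1, so that any single replicate can be
#' reproduced in isolation without replaying the whole batch.
#'
#' @param master_seed Integer master seed.
#' @param k Replicate index (vectorized).
#' @return Integer seed(s) in `[1, 2^31 - 2]`.
#' @export
substream_seed <- function(master_seed, k) {
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  s <- (abs(as.numeric(master_seed)) %% m) + 1
  as.integer(((s * 48271 + as.numeric(k) * 1103515245) %% m) + 1)
}

#' Run a batch of independent simulations
#'
#' Runs `numbsim` independent replicates of [sim_age()] or [sim_taxa()]
#' under one configuration. Replicate `k` is seeded with
#' `substream_seed(seed, k)`. Exactly one of `age` or `n` must be given.
#'
#' @param numbsim Number of replicates (>= 1).
#' @param config A [sim_config()].
#' @param age Stem age for age-stopped simulation.
#' @param n Number of extant species for taxon-stopped simulation.
#' @param gsa,m General-sampling-approach settings, passed to [sim_taxa()].
#' @param seed Master seed (default 1).
#' @return A list of `bh_sim` results of length `numbsim`.
#' @examples
#' yule <- run_batch(10, sim_config("rexp(0.5)"), n = 20, seed = 1)
#' table(vapply(yule, `[[`, "", "status"))
#' @export
run_batch <- function(numbsim, config, age = NULL, n = NULL,
                      gsa = FALSE, m = NULL, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  numbsim <- as.integer(numbsim)
  if (is.na(numbsim) || numbsim < 1L) {
    bh_stop("bhtree_bad_config", "numbsim must be a positive integer")
  }
  if (is.null(age) == is.null(n)) {
    bh_stop("bhtree_bad_config", "exactly one of age or n must be given")
  }
  seeds <- substream_seed(seed, seq_len(numbsim))
  lapply(seq_len(numbsim), function(k) {
    set.seed(seeds[k])
    tryCatch(
      if (!is.null(age)) sim_age(age, config) else sim_taxa(n, config, gsa = gsa, m = m),
      bhtree_error = function(e) {
        bh_stop(class(e)[1L], sprintf("replicate %d: %s", k, conditionMessage(e)))
      }
    )
  })
}

#' Summarize a batch of simulations
#'
#' Per-replicate tree statistics plus aggregates in the style used for
#' simulator cross-validation: median and central 95% interval (2.5% and
#' 97.5% percentiles) of the number of extant tips and of the oldest
#' branching time. Replicates that went extinct (and single-survivor
#' replicates, which return no tree) are excluded from the tree-shape
#' aggregates but counted in the status tallies.
#'
#' @param results A list of `bh_sim` results.
#' @return A `batch_summary`: list with `per_tree` (data frame: replicate,
#'   status, attempts, extant_tips, total_tips, oldest_branching_time,
#'   stem_age, total_branch_length), `statuses` (named counts),
#'   `extant_tips` and `oldest_branching` (each median/q2.5/q97.5), and
#'   `attempts` (total).
#' @export
summarize_batch <- function(results) {
  stopifnot(is.list(results), length(results) >= 1L)
  rows <- lapply(seq_along(results), function(k) {
    r <- results[[k]]
    st <- if (!is.null(r$tree)) tree_stats(r$tree) else NULL
    data.frame(replicate = k, status = r$status, attempts = r$attempts,
               extant_tips = if (is.null(st)) NA_integer_ else st$extant_tips,
               total_tips = if (is.null(st)) NA_integer_ else st$total_tips,
               oldest_branching_time = if (is.null(st)) NA_real_ else st$oldest_branching_time,
               stem_age = if (is.null(st)) NA_real_ else st$stem_age,
               total_branch_length = if (is.null(st)) NA_real_ else st$total_branch_length)
  })
  per_tree <- do.call(rbind, rows)
  statuses <- table(factor(per_tree$status,
                           levels = c("completed", "extinct", "single_survivor")))
  if (statuses[["completed"]] == 0L) {
    if (statuses[["extinct"]] == length(results)) {
      bh_stop("bhtree_all_extinct", "every replicate went extinct; no trees to summarize")
    }
    bh_stop("bhtree_all_extinct", "no completed replicate; no trees to summarize")
  }
  agg <- function(x) {
    x <- x[!is.na(x)]
    c(median = stats::median(x),
      q2.5 = unname(stats::quantile(x, 0.025)),
      q97.5 = unname(stats::quantile(x, 0.975)))
  }
  structure(list(per_tree = per_tree, statuses = c(statuses),
                 extant_tips = agg(per_tree$extant_tips),
                 oldest_branching = agg(per_tree$oldest_branching_time),
                 attempts = sum(per_tree$attempts)),
            class = "batch_summary")
}

#' @export
print.batch_summary <- function(x, ...) {
  cat("<batch_summary>", nrow(x$per_tree), "replicates |",
      paste(names(x$statuses), x$statuses, collapse = ", "), "\n")
  cat(sprintf("  extant tips: median %.4g [%.4g, %.4g]\n",
              x$extant_tips["median"], x$extant_tips["q2.5"], x$extant_tips["q97.5"]))
  cat(sprintf("  oldest branching: median %.4g [%.4g, %.4g]\n",
              x$oldest_branching["median"], x$oldest_branching["q2.5"],
              x$oldest_branching["q97.5"]))
  invisible(x)
}

#' Constant-rate event estimators
#'
#' Pools speciation events, extinction events and alive lineage-time over
#' the complete lineage records of a batch (all replicates, including those
#' whose trees went fully extinct -- the records are always retained) and
#' returns the counting-process rate estimators: events divided by total
#' lineage-time. Under exponential clocks these recover the speciation and
#' extinction rates. Intended for complete (unpruned) simulations without
#' shifts.
#'
#' @param results A list of `bh_sim` results.
#' @return A list with `sp_rate`, `ext_rate`, `sp_events`, `ext_events` and
#'   `lineage_time`.
#' @export
estimate_event_rates <- function(results) {
  stopifnot(is.list(results), length(results) >= 1L)
  sp_ev <- 0; ext_ev <- 0; ltime <- 0
  for (r in results) {
    lin <- r$lineages
    # one speciation event per distinct (parent, birth-time) pair among
    # non-origin lineages (a symmetric event spawns two daughters at once)
    ch <- lin[lin$parent != 0L, , drop = FALSE]
    if (nrow(ch)) {
      sp_ev <- sp_ev + sum(!duplicated(ch[, c("parent", "origin")]))
    }
    ext_ev <- ext_ev + sum(lin$fate == "extinct")
    ltime <- ltime + sum(lin$end - lin$origin)
  }
  if (ltime <= 0) bh_stop("bhtree_zero_time", "total alive lineage-time is zero")
  list(sp_rate = sp_ev / ltime, ext_rate = ext_ev / ltime,
       sp_events = sp_ev, ext_events = ext_ev, lineage_time = ltime)
}

#' Write batch output files
#'
#' Writes the completed trees of a batch as Newick (one per line), the
#' per-tip shift annotations as one TSV (with a `tree` column holding the
#' replicate index), and the per-replicate summary as another TSV.
#'
#' @param results A list of `bh_sim` results.
#' @param trees_file,annotations_file,summary_file Output paths (`NULL`
#'   skips the corresponding file).
#' @return The [summarize_batch()] object, invisibly.
#' @export
write_batch <- function(results, trees_file = NULL, annotations_file = NULL,
                        summary_file = NULL) {
  if (!is.null(trees_file)) {
    nwk <- vapply(results, function(r) {
      if (is.null(r$tree)) "" else write_newick(r$tree)
    }, character(1))
    writeLines(nwk[nzchar(nwk)], trees_file)
  }
  if (!is.null(annotations_file)) {
    ann <- do.call(rbind, lapply(seq_along(results), function(k) {
      if (is.null(results[[k]]$tree)) return(NULL)
      write_annotations(results[[k]]$tree, tree_index = k)
    }))
    utils::write.table(ann, annotations_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  smry <- summarize_batch(results)
  if (!is.null(summary_file)) {
    utils::write.table(smry$per_tree, summary_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(smry)
}
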