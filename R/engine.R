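# Lineage-level event loop for the generalized birth-death process.
#
# Every lineage carries two competing clocks: a waiting time to speciation
# and a waiting time to extinction, both drawn at birth from arbitrary
# distributions (and, under the asymmetric mode, the speciation clock of a
# mother is renewed after each budding event). The process starts from a
# single origin lineage at time 0 (the stem age) and runs until a stopping
# condition: a fixed clade age, or a number of coexisting lineages.

#' Simulation configuration
#'
#' Bundles every model setting of the generalized branching process.
#'
#' @param waitsp Waiting-time spec (string, function or [wt_spec()]) for the
#'   time to speciation. Required.
#' @param waitext Waiting-time spec for the time to extinction, or `NULL`
#'   (the default) for no extinction (an infinite waiting time).
#' @param symmetric Logical; `TRUE` (default) for symmetric speciation (both
#'   daughters are new species of age 0 and the mother terminates), `FALSE`
#'   for asymmetric (budding) speciation (one daughter is new; the mother
#'   keeps her age and scheduled extinction time and draws successive
#'   speciation waiting times until one exceeds her extinction time).
#' @param shiftsp,shiftext Lineage-specific shift settings for the
#'   speciation / extinction process: a list `list(prob =, strength =)`.
#'   With probability `prob`, a newly formed species draws a scaling factor
#'   f from the `strength` spec; its waiting times are then drawn from the
#'   base distribution and multiplied by f. The factor is inherited by all
#'   descendants until another shift occurs. Defaults to no shifts
#'   (`prob = 0`).
#' @param complete Logical; `TRUE` (default) returns the complete tree with
#'   extinct lineages, `FALSE` prunes extinct lineages (yielding an
#'   ultrametric reconstructed tree, or the extinct / single-survivor
#'   statuses when fewer than two species survive).
#' @param frac Sampling fraction in (0, 1]; with `frac < 1`, `round(N*frac)`
#'   of the N extant species are retained (incomplete sampling). Requires
#'   `complete = FALSE`.
#' @param sampling `"uniform"` (each extant tip equally likely) or
#'   `"proportional"` (tips sampled without replacement with probability
#'   proportional to their pendant branch lengths).
#' @param compound_shifts Logical; if `TRUE`, a new shift factor multiplies
#'   the inherited factor instead of replacing it. Off by default: a shift
#'   is defined relative to the base distribution.
#' @param retry_cap Maximum number of attempts for taxon-conditioned
#'   simulation before giving up (default 10000).
#' @return An object of class `sim_config`.
#' @examples
#' sim_config("rexp(0.5)") # Yule, speciation rate 0.5
#' sim_config("rexp(0.9)", "rexp(0.1)") # constant-rate birth-death
#' sim_config("rweibull(0.4,3)", symmetric = FALSE) # age-dependent, budding
#' sim_config("rexp(0.8)", shiftsp = list(prob = 0.09, strength = "runif(0.5,1.5)"))
#' @export
sim_config <- function(waitsp, waitext = NULL, symmetric = TRUE,
                       shiftsp = list(prob = 0, strength = NULL),
                       shiftext = list(prob = 0, strength = NULL),
                       complete = TRUE, frac = 1, sampling = c("uniform", "proportional"),
                       compound_shifts = FALSE, retry_cap = 10000L) {
  waitsp <- wt_spec(waitsp)
  if (!is.null(waitext)) waitext <- wt_spec(waitext)
  sampling <- match.arg(sampling)
  shiftsp <- check_shift(shiftsp, "shiftsp")
  shiftext <- check_shift(shiftext, "shiftext")
  stopifnot(is.logical(symmetric), length(symmetric) == 1L,
            is.logical(complete), length(complete) == 1L)
  if (!is.numeric(frac) || length(frac) != 1L || frac <= 0 || frac > 1) {
    bh_stop("bhtree_bad_config", "frac must lie in (0, 1]")
  }
  if (frac < 1 && complete) {
    bh_stop("bhtree_bad_config",
            "incomplete sampling (frac < 1) requires complete = FALSE (sampling acts on the pruned extant tree)")
  }
  retry_cap <- as.integer(retry_cap)
  if (is.na(retry_cap) || retry_cap < 1L) {
    bh_stop("bhtree_bad_config", "retry_cap must be a positive integer")
  }
  structure(list(waitsp = waitsp, waitext = waitext, symmetric = symmetric,
                 shiftsp = shiftsp, shiftext = shiftext, complete = complete,
                 frac = frac, sampling = sampling,
                 compound_shifts = isTRUE(compound_shifts), retry_cap = retry_cap),
            class = "sim_config")
}

#' @noRd
check_shift <- function(s, what) {
  if (is.null(s)) s <- list(prob = 0, strength = NULL)
  if (!is.list(s) || is.null(s$prob)) {
    bh_stop("bhtree_bad_config", sprintf("%s must be list(prob =, strength =)", what))
  }
  p <- s$prob
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    bh_stop("bhtree_bad_config", sprintf("%s$prob must lie in [0, 1]", what))
  }
  strength <- s$strength
  if (p > 0) {
    if (is.null(strength)) {
      bh_stop("bhtree_bad_config",
              sprintf("%s$strength must be given when %s$prob > 0", what, what))
    }
    strength <- wt_spec(strength)
  } else if (!is.null(strength)) {
    strength <- wt_spec(strength)
  }
  list(prob = p, strength = strength)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  waitsp:   ", format(x$waitsp), "\n")
  cat("  waitext:  ", if (is.null(x$waitext)) "none (no extinction)" else format(x$waitext), "\n")
  cat("  mode:     ", if (x$symmetric) "symmetric" else "asymmetric", "\n")
  if (x$shiftsp$prob > 0)
    cat("  shiftsp:  p =", x$shiftsp$prob, ", strength", format(x$shiftsp$strength), "\n")
  if (x$shiftext$prob > 0)
    cat("  shiftext: p =", x$shiftext$prob, ", strength", format(x$shiftext$strength), "\n")
  cat("  complete: ", x$complete, if (x$frac < 1) sprintf("  frac: %g (%s)", x$frac, x$sampling), "\n")
  invisible(x)
}

#' Resolve the fate of a lineage from its two competing clocks
#'
#' A lineage goes extinct when its remaining waiting time to extinction is
#' shorter than its waiting time to speciation, and speciates otherwise.
#' Ties (possible only with point-mass waiting times) are resolved in favour
#' of speciation.
#'
#' @param wait_sp Waiting time to speciation (>= 0).
#' @param wait_ext Remaining waiting time to extinction (>= 0, possibly
#'   `Inf`).
#' @return `"speciation"` or `"extinction"`.
#' @examples
#' resolve_fate(2, 2.5) # speciation
#' resolve_fate(3, 1) # extinction
#' resolve_fate(2, 2) # tie -> speciation
#' @export
resolve_fate <- function(wait_sp, wait_ext) {
  stopifnot(is.numeric(wait_sp), is.numeric(wait_ext),
            length(wait_sp) == 1L, length(wait_ext) == 1L,
            wait_sp >= 0, wait_ext >= 0)
  if (is.infinite(wait_sp) && is.infinite(wait_ext)) {
    bh_stop("bhtree_bad_clocks", "both waiting times are infinite: no event can be resolved")
  }
  if (wait_ext < wait_sp) "extinction" else "speciation"
}

# Core event loop. Runs from a single origin lineage at time 0 until either
# time exceeds `age` or the number of coexisting lineages first reaches
# `target`. Simultaneous events (point-mass clocks) are processed in
# ascending lineage-id order; within a lineage, speciation beats extinction
# on a tie. Returns raw lineage vectors plus stopping bookkeeping.
# fate codes: 0 alive, 1 extinct, 2 terminated by (symmetric) speciation.
#' @noRd
run_engine <- function(cfg, age = Inf, target = Inf) {
  waitsp <- cfg$waitsp
  waitext <- cfg$waitext
  p_sp <- cfg$shiftsp$prob
  p_ext <- cfg$shiftext$prob
  st_sp <- cfg$shiftsp$strength
  st_ext <- cfg$shiftext$strength
  compound <- cfg$compound_shifts
  sym <- cfg$symmetric

  cap <- 256L
  origin <- numeric(cap); sched_ext <- numeric(cap); end_t <- numeric(cap)
  nxt <- numeric(cap); nxt_sp <- numeric(cap)
  parent <- integer(cap); fate <- integer(cap)
  spf <- numeric(cap); extf <- numeric(cap)
  spsh <- logical(cap); extsh <- logical(cap)
  n <- 0L

  spawn <- function(par, t0) {
    if (n == length(origin)) {
      origin <<- c(origin, numeric(n)); sched_ext <<- c(sched_ext, numeric(n))
      end_t <<- c(end_t, numeric(n)); nxt <<- c(nxt, numeric(n))
      nxt_sp <<- c(nxt_sp, numeric(n)); parent <<- c(parent, integer(n))
      fate <<- c(fate, integer(n)); spf <<- c(spf, numeric(n))
      extf <<- c(extf, numeric(n)); spsh <<- c(spsh, logical(n))
      extsh <<- c(extsh, logical(n))
    }
    n <<- n + 1L
    i <- n
    if (par == 0L) {
      # the origin lineage carries factor 1 and is never shift-tested:
      # shifts apply to new species formed at speciation events
      fsp <- 1; fex <- 1; ssh <- FALSE; esh <- FALSE
    } else {
      ssh <- p_sp > 0 && stats::runif(1L) < p_sp
      fsp <- if (ssh) {
        d <- wt_draw(st_sp, 1L)
        if (compound) spf[par] * d else d
      } else spf[par]
      esh <- p_ext > 0 && stats::runif(1L) < p_ext
      fex <- if (esh) {
        d <- wt_draw(st_ext, 1L)
        if (compound) extf[par] * d else d
      } else extf[par]
    }
    se <- if (is.null(waitext)) Inf else t0 + wt_draw(waitext, 1L, fex)
    cand <- t0 + wt_draw(waitsp, 1L, fsp)
    origin[i] <<- t0; parent[i] <<- par; fate[i] <<- 0L
    sched_ext[i] <<- se; end_t[i] <<- NA_real_
    spf[i] <<- fsp; extf[i] <<- fex; spsh[i] <<- ssh; extsh[i] <<- esh
    nxt_sp[i] <<- cand
    nxt[i] <<- min(cand, se)
    i
  }

  alive <- spawn(0L, 0)
  n_alive <- 1L
  reached <- n_alive >= target
  horizon <- if (reached) 0 else NA_real_

  while (!reached && n_alive > 0L) {
    k <- which.min(nxt[alive]) # first minimum = lowest lineage id on ties
    j <- alive[k]
    t <- nxt[j]
    if (t > age || is.infinite(t)) break
    if (nxt_sp[j] <= sched_ext[j]) { # speciation (ties favour speciation)
      if (sym) {
        fate[j] <- 2L
        end_t[j] <- t
        alive <- alive[-k]
        c1 <- spawn(j, t)
        c2 <- spawn(j, t)
        alive <- c(alive, c1, c2)
      } else {
        c1 <- spawn(j, t)
        nxt_sp[j] <- t + wt_draw(waitsp, 1L, spf[j])
        nxt[j] <- min(nxt_sp[j], sched_ext[j])
        alive <- c(alive, c1)
      }
      n_alive <- n_alive + 1L
      if (n_alive >= target) {
        reached <- TRUE
        horizon <- t
      }
    } else { # extinction
      fate[j] <- 1L
      end_t[j] <- t
      alive <- alive[-k]
      n_alive <- n_alive - 1L
    }
  }

  idx <- seq_len(n)
  list(origin = origin[idx], parent = parent[idx], sched_ext = sched_ext[idx],
       end = end_t[idx], fate = fate[idx], sp_factor = spf[idx],
       ext_factor = extf[idx], sp_shifted = spsh[idx], ext_shifted = extsh[idx],
       n = n, n_alive = n_alive, reached = reached, horizon = horizon)
}

# Turn raw engine state into the canonical lineage table, truncated at
# `horizon`: lineages still alive become extant tips at `horizon`.
#' @noRd
finalize_lineages <- function(eng, horizon) {
  fate <- c("extant", "extinct", "speciated")[eng$fate + 1L]
  end <- eng$end
  end[eng$fate == 0L] <- horizon
  lin <- data.frame(
    id = seq_len(eng$n), parent = eng$parent, origin = eng$origin,
    sched_ext = eng$sched_ext, end = end, fate = fate,
    sp_factor = eng$sp_factor, ext_factor = eng$ext_factor,
    sp_shifted = eng$sp_shifted, ext_shifted = eng$ext_shifted
  )
  attr(lin, "horizon") <- horizon
  lin
}

#' Simulate a tree of fixed stem age
#'
#' Runs the branching process from a single origin lineage at time 0 (the
#' stem age) until time `age`. Lineages alive at `age` become extant tips;
#' all events beyond `age` are discarded.
#'
#' @param age Positive stem age of the clade, in the time units of the
#'   waiting-time specs (Myr by convention).
#' @param config A [sim_config()].
#' @param seed Optional integer seed (calls `set.seed()`).
#' @return A `bh_sim` result: a list with `status` (`"completed"`,
#'   `"extinct"` -- no lineage survived to `age` -- or `"single_survivor"` --
#'   exactly one survivor under `complete = FALSE`), `tree` (a [bh_tree]
#'   when status is `"completed"`, otherwise `NULL`), `lineages` (the full
#'   per-lineage record table, always present), `horizon` and `attempts`.
#' @examples
#' res <- sim_age(5, sim_config("const(2)", "const(2.5)"))
#' res$status # "completed"
#' tree_stats(res$tree)$extant_tips # 4: lineages double at t = 2 and 4
#' @export
sim_age <- function(age, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.numeric(age) || length(age) != 1L || !is.finite(age) || age <= 0) {
    bh_stop("bhtree_bad_age", "age must be a single positive finite number")
  }
  if (!is.null(seed)) set.seed(seed)
  eng <- run_engine(config, age = age)
  lin <- finalize_lineages(eng, age)
  bh_result(lin, age, config, attempts = 1L)
}

# Common postprocessing: lineage table -> tree, pruning, sampling, status.
#' @noRd
bh_result <- function(lineages, horizon, config, attempts) {
  n_extant <- sum(lineages$fate == "extant")
  status <- "completed"
  tree <- NULL
  if (n_extant == 0L) {
    status <- "extinct"
  } else {
    tree <- assemble_tree(lineages, horizon)
    if (!config$complete) {
      pr <- prune_extinct(tree)
      status <- pr$status
      tree <- pr$tree
      if (status == "completed" && config$frac < 1) {
        tree <- sample_tips(tree, config$frac, config$sampling)
      }
    }
  }
  structure(list(status = status, tree = tree, lineages = lineages,
                 horizon = horizon, attempts = attempts, config = config),
            class = "bh_sim")
}

#' @export
print.bh_sim <- function(x, ...) {
  cat("<bh_sim> status:", x$status)
  if (!is.null(x$tree)) {
    st <- tree_stats(x$tree)
    cat(sprintf(" | %d extant / %d total tips | stem age %.4g",
                st$extant_tips, st$total_tips, st$stem_age))
  }
  cat(" | attempts:", x$attempts, "\n")
  invisible(x)
}

#' Lineages-through-time step function
#'
#' The piecewise-constant count of coexisting (alive) lineages through time:
#' +1 at each birth, -1 at each extinction; a symmetric speciation event
#' (mother terminates, two daughters born) is a net +1. Simultaneous events
#' at one instant are aggregated, so transient mid-instant counts never
#' appear.
#'
#' @param lineages A lineage table (from `$lineages` of a simulation result)
#'   or a `bh_sim` result.
#' @return A data frame with columns `time` and `count`: the count holds on
#'   each interval `[time[i], time[i+1])` (right-continuous).
#' @examples
#' res <- sim_age(5, sim_config("const(2)", "const(2.5)"))
#' lineage_count_timeline(res) # counts 1, 2, 4 from times 0, 2, 4
#' @export
lineage_count_timeline <- function(lineages) {
  if (inherits(lineages, "bh_sim")) lineages <- lineages$lineages
  births <- lineages$origin
  dead <- lineages$fate %in% c("extinct", "speciated")
  deaths <- lineages$end[dead & !is.na(lineages$end)]
  ev <- c(births, deaths)
  dl <- c(rep.int(1L, length(births)), rep.int(-1L, length(deaths)))
  o <- order(ev)
  ev <- ev[o]
  dl <- dl[o]
  grp <- cumsum(c(TRUE, diff(ev) > 0)) # exact-equality grouping of instants
  net <- unname(rowsum(dl, group = grp)[, 1]) # rows ordered by integer group
  times <- ev[!duplicated(grp)]
  keep <- net != 0L
  data.frame(time = times[keep], count = cumsum(net)[keep])
}
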