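# Operations on assembled trees: pruning extinct lineages, incomplete
# species sampling, and summary statistics.

# Restrict a bh_tree to the given tip ids: drop all other tips, drop
# internal nodes left without kept descendants, and suppress the resulting
# degree-2 nodes, summing edge lengths exactly. The stem absorbs any basal
# history removed at the root.
#' @noRd
keep_tips <- function(tree, tip_ids) {
  nd <- tree$nodes
  keep <- logical(max(nd$id))
  keep[tip_ids] <- TRUE
  # node ids are assigned in preorder, so reverse id order visits children first
  for (i in rev(seq_len(nrow(nd)))) {
    if (keep[nd$id[i]] && !is.na(nd$parent[i])) keep[nd$parent[i]] <- TRUE
  }
  nd <- nd[keep[nd$id], , drop = FALSE]
  # count children of each kept node; splice out single-child internals
  repeat {
    nkid <- table(factor(nd$parent, levels = nd$id))
    single <- nd$id[!nd$is_tip & nkid == 1L]
    if (length(single) == 0L) break
    v <- single[1L]
    vi <- match(v, nd$id)
    ci <- which(!is.na(nd$parent) & nd$parent == v)
    nd$length[ci] <- nd$length[ci] + nd$length[vi]
    nd$parent[ci] <- nd$parent[vi]
    nd <- nd[-vi, , drop = FALSE]
  }
  rownames(nd) <- NULL
  new_bh_tree(nd, tree$horizon)
}

#' Prune extinct lineages from a tree
#'
#' Removes every lineage without extant descendants and suppresses the
#' resulting degree-2 nodes (summing edge lengths); the stem edge absorbs
#' any removed basal history. The pruned tree of a (non-subsampled)
#' simulation is ultrametric. Mirroring the status codes of age-stopped
#' simulation, no tree is returned when fewer than two species survive.
#'
#' @param tree A `bh_tree` with extant/extinct tip marks.
#' @return A list with `status` (`"completed"`, `"extinct"` if no extant
#'   tip, `"single_survivor"` if exactly one) and `tree` (the pruned
#'   `bh_tree`, or `NULL` unless status is `"completed"`).
#' @examples
#' res <- sim_age(5, sim_config("const(2)", "const(2.5)", symmetric = FALSE))
#' prune_extinct(res$tree)$status # "single_survivor"
#' @export
prune_extinct <- function(tree) {
  stopifnot(inherits(tree, "bh_tree"))
  nd <- tree$nodes
  extant <- nd$id[nd$is_tip & nd$extant]
  if (length(extant) == 0L) return(list(status = "extinct", tree = NULL))
  if (length(extant) == 1L) return(list(status = "single_survivor", tree = NULL))
  list(status = "completed", tree = keep_tips(tree, extant))
}

#' Incomplete species sampling
#'
#' Retains `n = round(N * frac)` of the `N` extant tips (round half up,
#' minimum 2), chosen either uniformly at random or by successive draws
#' without replacement with probability proportional to pendant branch
#' lengths (longer pendant branches are more likely to be sampled).
#' Unsampled tips are removed and degree-2 nodes suppressed. `frac = 1` is
#' the identity.
#'
#' @param tree A pruned `bh_tree` whose tips are all extant.
#' @param frac Sampling fraction in (0, 1].
#' @param method `"uniform"` or `"proportional"`.
#' @return The subsampled `bh_tree`.
#' @export
sample_tips <- function(tree, frac, method = c("uniform", "proportional")) {
  stopifnot(inherits(tree, "bh_tree"))
  method <- match.arg(method)
  if (!is.numeric(frac) || length(frac) != 1L || frac <= 0 || frac > 1) {
    bh_stop("bhtree_bad_config", "frac must lie in (0, 1]")
  }
  if (frac == 1) return(tree)
  nd <- tree$nodes
  tips <- nd$id[nd$is_tip]
  if (any(!nd$extant[nd$is_tip])) {
    bh_stop("bhtree_bad_sampling", "sample_tips requires a pruned tree (all tips extant)")
  }
  N <- length(tips)
  nkeep <- floor(N * frac + 0.5) # round half up
  if (nkeep < 2L) {
    bh_stop("bhtree_bad_sampling",
            sprintf("round(N * frac) = %d: at least 2 sampled tips are required", nkeep))
  }
  if (method == "uniform") {
    sel <- sample(tips, nkeep)
  } else {
    w <- nd$length[match(tips, nd$id)]
    if (sum(w) <= 0) {
      bh_stop("bhtree_bad_sampling", "all pendant branch lengths are zero; proportional sampling undefined")
    }
    sel <- sample(tips, nkeep, prob = w) # successive weighted draws w/o replacement
  }
  keep_tips(tree, sel)
}

#' Tree summary statistics
#'
#' @param tree A `bh_tree`.
#' @return A list with `extant_tips`, `total_tips`, `stem_age` (the tree
#'   horizon, time from origin to present), `oldest_branching_time` (time of
#'   the earliest internal node measured from the origin; `NA` for a
#'   one-tip tree), `total_branch_length` (sum of all edge lengths including
#'   the stem; equivalently the total alive lineage-time represented in the
#'   tree), and `ltt` (the lineages-through-time step function implied by
#'   the tree: +1 per branching node, -1 per extinct tip).
#' @examples
#' res <- sim_age(5, sim_config("const(2)", "const(2.5)"))
#' tree_stats(res$tree)[c("extant_tips", "oldest_branching_time")]
#' @export
tree_stats <- function(tree) {
  stopifnot(inherits(tree, "bh_tree"))
  nd <- tree$nodes
  internal <- nd$time[!nd$is_tip]
  ev <- c(0, internal, nd$time[nd$is_tip & !nd$extant])
  dl <- c(1L, rep.int(1L, length(internal)), rep.int(-1L, sum(nd$is_tip & !nd$extant)))
  o <- order(ev)
  ev <- ev[o]; dl <- dl[o]
  grp <- cumsum(c(TRUE, diff(ev) > 0))
  net <- unname(rowsum(dl, grp)[, 1])
  keep <- net != 0L
  ltt <- data.frame(time = ev[!duplicated(grp)][keep], count = cumsum(net)[keep])
  list(extant_tips = sum(nd$is_tip & nd$extant),
       total_tips = sum(nd$is_tip),
       stem_age = tree$horizon,
       oldest_branching_time = if (length(internal)) min(internal) else NA_real_,
       total_branch_length = sum(nd$length),
       ltt = ltt)
}

#' Per-node shift annotation report
#'
#' Tabulates the lineage-specific scaling factors and shift flags carried by
#' every node, plus the four conventional 0/1 tip vectors marking tips whose
#' originating lineage underwent a shift: `shifted.sp.living`,
#' `shifted.sp.extinct` (shifts of the speciation clock among extant /
#' extinct tips) and `shifted.ext.living`, `shifted.ext.extinct` (same for
#' the extinction clock), each named by tip label.
#'
#' @param tree An annotated `bh_tree`.
#' @return A list with `nodes` (data frame: `id`, `label`, `is_tip`,
#'   `extant`, `sp_factor`, `ext_factor`, `sp_shifted`, `ext_shifted`) and
#'   the four named 0/1 vectors.
#' @export
shift_report <- function(tree) {
  stopifnot(inherits(tree, "bh_tree"))
  nd <- tree$nodes
  nodes <- nd[, c("id", "label", "is_tip", "extant",
                  "sp_factor", "ext_factor", "sp_shifted", "ext_shifted")]
  tip <- nd[nd$is_tip, , drop = FALSE]
  liv <- tip[tip$extant, , drop = FALSE]
  ext <- tip[!tip$extant, , drop = FALSE]
  as01 <- function(x, labels) stats::setNames(as.integer(x), labels)
  list(nodes = nodes,
       shifted.sp.living = as01(liv$sp_shifted, liv$label),
       shifted.sp.extinct = as01(ext$sp_shifted, ext$label),
       shifted.ext.living = as01(liv$ext_shifted, liv$label),
       shifted.ext.extinct = as01(ext$ext_shifted, ext$label))
}
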