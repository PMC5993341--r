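# Shared fixtures: point-mass configurations reproducing the deterministic
# doubling / budding traces, and small hand-built trees.

fig_sym_cfg <- function(...) sim_config("const(2)", "const(2.5)", symmetric = TRUE, ...)
fig_asym_cfg <- function(...) sim_config("const(2)", "const(2.5)", symmetric = FALSE, ...)

yule_cfg <- function(rate = 0.5, ...) sim_config(sprintf("rexp(%g)", rate), ...)
crbd_cfg <- function(l = 0.9, mu = 0.1, ...) {
  sim_config(sprintf("rexp(%g)", l), sprintf("rexp(%g)", mu), ...)
}

# Hand-built lineage table: symmetric 3-tip ultrametric tree at horizon 3
# with pendant lengths (2, 1, 1). L1 splits at t=1 into L2 (tip, pendant 2)
# and L3, which splits at t=2 into tips L4, L5 (pendants 1).
lin_3tip <- function() {
  lin <- data.frame(
    id = 1:5, parent = c(0L, 1L, 1L, 3L, 3L),
    origin = c(0, 1, 1, 2, 2), sched_ext = Inf,
    end = c(1, 3, 2, 3, 3),
    fate = c("speciated", "extant", "speciated", "extant", "extant"),
    sp_factor = 1, ext_factor = 1, sp_shifted = FALSE, ext_shifted = FALSE
  )
  attr(lin, "horizon") <- 3
  lin
}

tree_3tip <- function() assemble_tree(lin_3tip())

# 4-tip ultrametric tree with equal pendants: point-mass doubling to t=2.5
tree_4tip <- function() {
  res <- sim_age(2.5, sim_config("const(1)"))
  res$tree
}

# Extant tip count of a result (0 when no tree)
n_tips <- function(res) {
  if (is.null(res$tree)) 0L else tree_stats(res$tree)$extant_tips
}

# Depth (origin -> node) recomputed by summing edge lengths up the tree,
# independent of the stored node times.
node_depths <- function(tree) {
  nd <- tree$nodes
  depth <- numeric(nrow(nd))
  for (i in seq_len(nrow(nd))) { # parents precede children in id order
    p <- nd$parent[i]
    depth[i] <- nd$length[i] + if (is.na(p)) 0 else depth[match(p, nd$id)]
  }
  depth
}
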