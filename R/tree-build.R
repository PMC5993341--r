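# Assembling per-lineage life records into a rooted binary tree with a stem
# (root) edge. A bh_tree stores a flat node table: each node is the endpoint
# of the edge coming from its parent, and carries the shift annotations of
# the lineage that edge belongs to. Node times are absolute (measured from
# the origin at time 0), so edge lengths are differences of event times.

#' Assemble a phylogenetic tree from lineage records
#'
#' Maps a truncated lineage set onto a rooted binary tree. Under symmetric
#' speciation each speciation event becomes an internal node whose two
#' children are the two daughter lineages; under asymmetric speciation each
#' budding event of a mother becomes an internal node with the new daughter
#' on one child edge and the mother's continuation on the other. Edge
#' lengths are inter-event times; the stem edge runs from the origin (time
#' 0) to the first event.
#'
#' @param lineages Lineage table (or `bh_sim` result).
#' @param horizon Tree horizon (defaults to the table's `horizon`
#'   attribute).
#' @return A `bh_tree`: a list with `nodes` (data frame: `id`, `parent`
#'   (`NA` for the root), `time`, `length`, `label`, `is_tip`, `extant`,
#'   `lineage`, `sp_factor`, `ext_factor`, `sp_shifted`, `ext_shifted`),
#'   `stem_length` and `horizon`. Extant tips are labelled `t1, t2, ...`
#'   and extinct tips `x1, x2, ...` in node-id order.
#' @examples
#' res <- sim_age(5, sim_config("const(2)", "const(2.5)"))
#' tr <- assemble_tree(res$lineages)
#' tr$stem_length # 2
#' @export
assemble_tree <- function(lineages, horizon = attr(lineages, "horizon")) {
  if (inherits(lineages, "bh_sim")) {
    if (is.null(horizon)) horizon <- lineages$horizon
    lineages <- lineages$lineages
  }
  stopifnot(is.data.frame(lineages), nrow(lineages) >= 1L, !is.null(horizon))
  lin <- lineages
  if (any(lin$parent != 0L & !(lin$parent %in% lin$id))) {
    bh_stop("bhtree_bad_lineages", "inconsistent parent references in lineage table")
  }
  kid_of <- split(lin$id, factor(lin$parent, levels = lin$id))
  row_of <- function(id) match(id, lin$id)
  ok <- lin$parent == 0L | lin$origin >= lin$origin[row_of(lin$parent)]
  if (any(!ok, na.rm = TRUE)) {
    bh_stop("bhtree_bad_lineages", "child born before its parent")
  }

  nn <- 0L
  cap <- 2L * nrow(lin) + 2L
  nd_parent <- integer(cap); nd_time <- numeric(cap)
  nd_tip <- logical(cap); nd_extant <- logical(cap); nd_lin <- integer(cap)

  add_node <- function(pnode, time, tip, extant, lineage_id) {
    nn <<- nn + 1L
    nd_parent[nn] <<- pnode; nd_time[nn] <<- time
    nd_tip[nn] <<- tip; nd_extant[nn] <<- extant; nd_lin[nn] <<- lineage_id
    nn
  }

  # build the subtree of lineage `li` starting at time `s`; attach to pnode
  build <- function(li, s, pnode) {
    r <- row_of(li)
    kids <- kid_of[[as.character(li)]]
    ktimes <- if (length(kids)) lin$origin[row_of(kids)] else numeric(0)
    sel <- ktimes > s
    kids <- kids[sel]; ktimes <- ktimes[sel]
    if (length(kids) == 0L) {
      add_node(pnode, lin$end[r], TRUE, lin$fate[r] == "extant", li)
      return(invisible(NULL))
    }
    o <- order(ktimes, kids)
    kids <- kids[o]; ktimes <- ktimes[o]
    t1 <- ktimes[1L]
    here <- kids[ktimes == t1]
    nd <- add_node(pnode, t1, FALSE, FALSE, li)
    if (length(here) == 2L) { # symmetric event: mother terminates here
      build(here[1L], t1, nd)
      build(here[2L], t1, nd)
    } else if (length(here) == 1L) {
      if (lin$fate[r] == "speciated" && lin$end[r] == t1) {
        bh_stop("bhtree_bad_lineages", "symmetric speciation with a single daughter")
      }
      # asymmetric: mother (lower id) continues on one edge, daughter on the other
      build(li, t1, nd)
      build(here[1L], t1, nd)
    } else {
      bh_stop("bhtree_bad_lineages", "more than two daughters at one instant")
    }
    invisible(NULL)
  }

  root_lin <- lin$id[lin$parent == 0L]
  if (length(root_lin) != 1L) {
    bh_stop("bhtree_bad_lineages", "lineage table must contain exactly one origin lineage")
  }
  build(root_lin, 0, 0L)

  idx <- seq_len(nn)
  nodes <- data.frame(
    id = idx, parent = ifelse(nd_parent[idx] == 0L, NA_integer_, nd_parent[idx]),
    time = nd_time[idx], length = NA_real_, label = NA_character_,
    is_tip = nd_tip[idx], extant = nd_extant[idx], lineage = nd_lin[idx]
  )
  nodes$length <- nodes$time - ifelse(is.na(nodes$parent), 0, nodes$time[nodes$parent])
  lr <- row_of(nodes$lineage)
  nodes$sp_factor <- lin$sp_factor[lr]
  nodes$ext_factor <- lin$ext_factor[lr]
  nodes$sp_shifted <- lin$sp_shifted[lr]
  nodes$ext_shifted <- lin$ext_shifted[lr]
  nodes$label[nodes$is_tip & nodes$extant] <-
    paste0("t", seq_len(sum(nodes$is_tip & nodes$extant)))
  nodes$label[nodes$is_tip & !nodes$extant] <-
    paste0("x", seq_len(sum(nodes$is_tip & !nodes$extant)))
  new_bh_tree(nodes, horizon)
}

#' @noRd
new_bh_tree <- function(nodes, horizon) {
  root <- nodes$id[is.na(nodes$parent)]
  stopifnot(length(root) == 1L)
  structure(list(nodes = nodes, stem_length = nodes$length[nodes$id == root],
                 root = root, horizon = horizon),
            class = "bh_tree")
}

#' @export
print.bh_tree <- function(x, ...) {
  nd <- x$nodes
  cat(sprintf("<bh_tree> %d tips (%d extant, %d extinct), %d internal nodes, stem %.4g, horizon %.4g\n",
              sum(nd$is_tip), sum(nd$is_tip & nd$extant), sum(nd$is_tip & !nd$extant),
              sum(!nd$is_tip), x$stem_length, x$horizon))
  invisible(x)
}

#' Convert a bh_tree to an ape "phylo" object
#'
#' Tips are numbered in node-id order; the stem edge is exported as
#' `root.edge`. Single-tip trees (one lineage, no branching) cannot be
#' represented as a conventional `phylo` edge matrix and raise an error.
#'
#' @param x A `bh_tree`.
#' @param ... Ignored.
#' @return An object of class `phylo`.
#' @method as.phylo bh_tree
#' @export
as.phylo.bh_tree <- function(x, ...) {
  nd <- x$nodes
  ntip <- sum(nd$is_tip)
  if (ntip < 2L) {
    bh_stop("bhtree_one_tip", "single-tip trees cannot be converted to phylo")
  }
  tip_ids <- nd$id[nd$is_tip]
  int_ids <- c(x$root, setdiff(nd$id[!nd$is_tip], x$root))
  ape_num <- integer(max(nd$id))
  ape_num[tip_ids] <- seq_len(ntip)
  ape_num[int_ids] <- ntip + seq_along(int_ids)
  nonroot <- nd$id[!is.na(nd$parent)]
  edge <- cbind(ape_num[nd$parent[match(nonroot, nd$id)]], ape_num[nonroot])
  phy <- list(edge = edge,
              edge.length = nd$length[match(nonroot, nd$id)],
              tip.label = nd$label[match(tip_ids, nd$id)],
              Nnode = length(int_ids),
              root.edge = x$stem_length)
  class(phy) <- "phylo"
  attr(phy, "order") <- NULL
  ape::reorder.phylo(phy, "cladewise")
}
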