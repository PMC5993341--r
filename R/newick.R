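# Newick serialization. Writing is implemented here (exact control over the
# root-edge form and one-tip trees); reading is delegated to ape's parser
# and the result converted back into the node-table representation, which
# also gives the round-trip tests an independent route. Shift annotations
# travel in a sidecar TSV (see write_annotations) so the Newick stays
# consumable by any standard parser.

#' Write a tree as a Newick string
#'
#' Standard Newick with branch lengths; the stem is emitted as a trailing
#' root-edge length (`(...):stem;`). A one-tip tree is written as
#' `(label:0):stem;`. Children of a node are written in node-id order, so
#' output is deterministic.
#'
#' @param tree A `bh_tree`.
#' @param file Optional path; when given the string is written there
#'   (one tree per line appended by [write_batch()]).
#' @param digits Significant digits for branch lengths (default 12, ample
#'   for the 1e-9 round-trip tolerance).
#' @return The Newick string, invisibly when `file` is given.
#' @examples
#' res <- sim_age(5, sim_config("const(2)", "const(2.5)"))
#' write_newick(res$tree)
#' @export
write_newick <- function(tree, file = NULL, digits = 12L) {
  stopifnot(inherits(tree, "bh_tree"))
  nd <- tree$nodes
  fmt <- function(x) sprintf(paste0("%.", digits, "g"), x)
  if (nrow(nd) == 1L) {
    s <- sprintf("(%s:0):%s;", nd$label[1L], fmt(tree$stem_length))
  } else {
    kids <- split(nd$id, factor(nd$parent, levels = nd$id))
    lab <- nd$label
    len <- nd$length
    tip <- nd$is_tip
    rec <- function(id) {
      i <- match(id, nd$id)
      if (tip[i]) {
        paste0(lab[i], ":", fmt(len[i]))
      } else {
        ch <- sort(kids[[as.character(id)]])
        paste0("(", paste(vapply(ch, rec, character(1)), collapse = ","),
               "):", fmt(len[i]))
      }
    }
    s <- paste0(rec(tree$root), ";")
  }
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

#' Read a Newick string into a bh_tree
#'
#' Parses standard Newick (via ape) and rebuilds the node-table
#' representation. Node times are recovered by accumulating edge lengths
#' from the origin (root edge included; a missing root edge is taken as 0).
#' Tips are marked extant when their time equals the maximum tip time
#' within a relative tolerance of 1e-9 (the convention for trees cut at a
#' common horizon); labels are preserved. Duplicate tip labels are an
#' error.
#'
#' @param text A Newick string (or a path via `file`).
#' @param file Optional path to read from instead of `text`.
#' @return A `bh_tree` (without shift annotations: factors 1, flags FALSE).
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) && is.null(file)) {
    bh_stop("bhtree_parse", "either text or file must be given")
  }
  if (is.null(text)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  phy <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(phy) || !inherits(phy, "phylo")) {
    bh_stop("bhtree_parse", sprintf("malformed Newick: cannot parse '%s'",
                                    substr(text, 1L, 60L)))
  }
  if (anyDuplicated(phy$tip.label)) {
    bh_stop("bhtree_parse", "duplicate tip labels in Newick input")
  }
  if (is.null(phy$edge.length)) {
    bh_stop("bhtree_parse", "Newick input lacks branch lengths")
  }
  stem <- if (is.null(phy$root.edge)) 0 else phy$root.edge
  ntip <- length(phy$tip.label)
  nap <- ntip + phy$Nnode
  root_ape <- ntip + 1L
  # preorder traversal assigning sequential node ids and absolute times
  kids <- split(seq_len(nrow(phy$edge)), factor(phy$edge[, 1L], levels = seq_len(nap)))
  nid <- integer(nap)
  parent <- integer(0); time <- numeric(0); is_tip <- logical(0); label <- character(0)
  ape_of <- integer(0)
  walk <- function(a, t0, pnode) {
    id <- length(parent) + 1L
    parent[id] <<- pnode
    time[id] <<- t0
    is_tip[id] <<- a <= ntip
    label[id] <<- if (a <= ntip) phy$tip.label[a] else NA_character_
    ape_of[id] <<- a
    for (ei in kids[[a]]) {
      walk(phy$edge[ei, 2L], t0 + phy$edge.length[ei], id)
    }
  }
  walk(root_ape, stem, 0L)
  nnode <- length(parent)
  nodes <- data.frame(
    id = seq_len(nnode),
    parent = ifelse(parent == 0L, NA_integer_, parent),
    time = time, length = NA_real_, label = label,
    is_tip = is_tip, extant = FALSE, lineage = NA_integer_,
    sp_factor = 1, ext_factor = 1, sp_shifted = FALSE, ext_shifted = FALSE
  )
  nodes$length <- nodes$time - ifelse(is.na(nodes$parent), 0, nodes$time[nodes$parent])
  horizon <- max(nodes$time[nodes$is_tip])
  tol <- 1e-9 * max(1, abs(horizon))
  nodes$extant <- nodes$is_tip & (horizon - nodes$time) <= tol
  new_bh_tree(nodes, horizon)
}

#' Write per-node shift annotations as a sidecar TSV
#'
#' One row per labelled node (tips; internal nodes have no stable label in
#' plain Newick and are omitted), with columns `node_label`, `sp_factor`,
#' `ext_factor`, `sp_shifted`, `ext_shifted`, `extant` (0/1 flags).
#'
#' @param tree An annotated `bh_tree`.
#' @param file Path of the TSV to write, or `NULL` to return the data
#'   frame only.
#' @param tree_index Optional integer prepended as a `tree` column (used by
#'   batch output).
#' @return The annotation data frame, invisibly when written to file.
#' @export
write_annotations <- function(tree, file = NULL, tree_index = NULL) {
  stopifnot(inherits(tree, "bh_tree"))
  nd <- tree$nodes[tree$nodes$is_tip, , drop = FALSE]
  out <- data.frame(node_label = nd$label,
                    sp_factor = nd$sp_factor, ext_factor = nd$ext_factor,
                    sp_shifted = as.integer(nd$sp_shifted),
                    ext_shifted = as.integer(nd$ext_shifted),
                    extant = as.integer(nd$extant))
  if (!is.null(tree_index)) out <- cbind(tree = tree_index, out)
  if (!is.null(file)) {
    utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
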