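#' Read and validate a rooted phylogeny from a Newick string
#'
#' Thin validating wrapper around [ape::read.tree()]. The returned tree is an
#' ape `phylo` object; polytomies are preserved as-is. Every non-root edge must
#' carry a branch length, tip labels must be unique, and branch lengths must be
#' non-negative. Ultrametricity is *not* required here (only the OU machinery
#' insists on it); use [is_ultrametric_tree()] to check.
#'
#' @param text A Newick string (must end in `;`). Ignored if `file` is given.
#' @param file Optionally, path to a file containing a single Newick tree.
#' @return A `phylo` object.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' tree_depth(tr)
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (!is.null(file)) {
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  if (is.null(text) || !nzchar(trimws(text))) {
    stop("no Newick text supplied")
  }
  .check_newick_syntax(text)
  tr <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e), call. = FALSE)
  )
  if (is.null(tr)) stop("Newick parse error: unparseable string")
  validate_phylo(tr)
  tr
}

# Cheap structural scan so malformed strings fail with a character offset,
# which ape's parser does not report.
.check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop(sprintf("Newick parse error: unbalanced ')' at character offset %d", i),
             call. = FALSE)
      }
    }
  }
  if (depth != 0L) {
    stop(sprintf("Newick parse error: %d unclosed '(' at end of string", depth),
         call. = FALSE)
  }
  if (!grepl(";", text, fixed = TRUE)) {
    stop(sprintf("Newick parse error: missing ';' terminator at character offset %d",
                 nchar(text)), call. = FALSE)
  }
  invisible(TRUE)
}

#' Validate a `phylo` object against the package's structural invariants
#'
#' @param tree A `phylo` object.
#' @param require_lengths Require branch lengths on all edges (default TRUE).
#' @return The tree, invisibly, if valid; otherwise an error.
#' @export
validate_phylo <- function(tree, require_lengths = TRUE) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  if (anyDuplicated(tree$tip.label)) {
    dups <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop("duplicate tip labels: ", paste(dups, collapse = ", "))
  }
  if (require_lengths) {
    if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
      stop("missing branch lengths")
    }
    if (any(tree$edge.length < 0)) stop("negative branch lengths")
  }
  invisible(tree)
}

#' Write a tree to a Newick string
#' @param tree A `phylo` object.
#' @return A Newick string.
#' @export
write_newick <- function(tree) ape::write.tree(tree)

#' Root-to-tip depths of all tips
#' @param tree A `phylo` object with branch lengths.
#' @return Named numeric vector of tip depths, in `tree$tip.label` order.
#' @export
tip_depths <- function(tree) {
  d <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  names(d) <- tree$tip.label
  d
}

#' Tree depth (maximum root-to-tip path length)
#' @inheritParams tip_depths
#' @return A single number.
#' @export
tree_depth <- function(tree) max(tip_depths(tree))

#' Test whether a tree is ultrametric
#'
#' All root-to-tip path lengths must agree within a *relative* tolerance on
#' the tree depth.
#'
#' @inheritParams tip_depths
#' @param tol Relative tolerance (default 1e-6).
#' @return Logical.
#' @export
is_ultrametric_tree <- function(tree, tol = 1e-6) {
  d <- tip_depths(tree)
  mx <- max(d)
  if (mx <= 0) return(FALSE)
  (mx - min(d)) / mx <= tol
}

.assert_ultrametric <- function(tree, tol = 1e-6, what = "this operation") {
  if (!is_ultrametric_tree(tree, tol)) {
    stop(what, " requires an ultrametric tree (tip depths differ by more than ",
         "relative tolerance ", tol, ")")
  }
  invisible(TRUE)
}

#' Rescale a tree to a target depth
#'
#' Multiplies every branch length by `target / tree_depth(tree)`, so the
#' returned tree has depth exactly `target`. Topology is unchanged. Unit depth
#' (`target = 1`) is the convention used throughout the model-fitting code.
#'
#' @inheritParams tip_depths
#' @param target Positive target depth (default 1).
#' @return The rescaled `phylo` object.
#' @export
rescale_depth <- function(tree, target = 1) {
  stopifnot(is.numeric(target), length(target) == 1L, target > 0)
  d <- tree_depth(tree)
  if (d <= 0) stop("zero-depth tree cannot be rescaled")
  tree$edge.length <- tree$edge.length * (target / d)
  tree
}

#' Phylogenetic (Brownian-motion) covariance matrix of a tree
#'
#' Entry (i, j) is the shared root-to-tip path length of tips i and j, i.e.
#' the depth of their most recent common ancestor; the diagonal holds tip
#' depths. Row/column order follows `tree$tip.label`.
#'
#' @inheritParams tip_depths
#' @return An n x n symmetric matrix with tip-label dimnames.
#' @export
phylo_vcv <- function(tree) {
  validate_phylo(tree)
  ape::vcv(tree)
}

#' Read a grafting placement table
#'
#' CSV with columns `new_tip` and `anchor_tips`, the latter a
#' semicolon-separated list of congeneric anchor tip labels.
#'
#' @param file Path to the CSV file.
#' @return A data.frame with columns `new_tip` (character) and `anchor_tips`
#'   (list of character vectors).
#' @export
read_placements <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("new_tip", "anchor_tips") %in% names(df))) {
    stop("placement table must have columns 'new_tip' and 'anchor_tips'")
  }
  df$anchor_tips <- lapply(strsplit(as.character(df$anchor_tips), ";", fixed = TRUE),
                           trimws)
  df[c("new_tip", "anchor_tips")]
}

#' Graft missing taxa onto an ultrametric tree as random sisters
#'
#' Emulates "scenario 2" placement of taxa absent from a backbone tree: each
#' new tip is bound as sister to a uniformly chosen anchor tip from its genus,
#' with the attachment point drawn uniformly along that anchor's pendant edge.
#' The new pendant length is set so the new tip reaches the tree depth, so
#' ultrametricity is preserved exactly. Placements are applied in row order and
#' a previously grafted tip may serve as an anchor if listed. Deterministic
#' given `seed`.
#'
#' @param tree An ultrametric `phylo` object.
#' @param placements A data.frame as returned by [read_placements()], or with
#'   `anchor_tips` as a semicolon-separated character column.
#' @param seed Integer seed for the random anchor/position draws.
#' @return The enlarged `phylo` object. Zero-length edges that can arise when
#'   the split point lands on an existing node are nudged to 1e-9 to keep
#'   covariance matrices non-singular.
#' @export
graft_missing_taxa <- function(tree, placements, seed = 1L) {
  validate_phylo(tree)
  if (is.null(placements) || nrow(placements) == 0L) return(tree)
  .assert_ultrametric(tree, what = "graft_missing_taxa")
  if (is.character(placements$anchor_tips)) {
    placements$anchor_tips <- lapply(
      strsplit(placements$anchor_tips, ";", fixed = TRUE), trimws)
  }
  all_anchors <- unique(unlist(placements$anchor_tips))
  missing <- setdiff(all_anchors, c(tree$tip.label, placements$new_tip))
  if (length(missing)) {
    stop("anchor tips absent from tree: ", paste(missing, collapse = ", "))
  }
  set.seed(seed)
  for (r in seq_len(nrow(placements))) {
    new_tip <- placements$new_tip[r]
    anchors <- intersect(placements$anchor_tips[[r]], tree$tip.label)
    if (!length(anchors)) {
      stop("no anchor tip present in tree for new tip '", new_tip, "'")
    }
    anchor <- anchors[sample.int(length(anchors), 1L)]
    ai <- match(anchor, tree$tip.label)
    pend <- which(tree$edge[, 2] == ai)
    len <- tree$edge.length[pend]
    pos <- stats::runif(1, 0, len)  # distance above the anchor tip
    sub <- ape::read.tree(text = sprintf("(%s:%.17g);", new_tip, pos))
    tree <- ape::bind.tree(tree, sub, where = match(anchor, tree$tip.label),
                           position = pos)
  }
  tree$edge.length[tree$edge.length <= 0] <- 1e-9
  validate_phylo(tree)
  tree
}

# children[[v]] = integer vector of child nodes of v
.children_list <- function(tree) {
  nn <- ape::Ntip(tree) + tree$Nnode
  ch <- vector("list", nn)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]
    ch[[p]] <- c(ch[[p]], tree$edge[e, 2])
  }
  ch
}

# per-edge descendant tip indices (list along rows of tree$edge)
.edge_descendants <- function(tree) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  tipsets <- vector("list", nn)
  for (i in seq_len(ntip)) tipsets[[i]] <- i
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; v <- po$edge[e, 2]
    tipsets[[p]] <- c(tipsets[[p]], tipsets[[v]])
  }
  lapply(seq_len(nrow(tree$edge)), function(e) sort(tipsets[[tree$edge[e, 2]]]))
}

#' Paint branch regimes from tip states by Fitch parsimony
#'
#' Internal node states are reconstructed by the Fitch pass (bottom-up
#' intersection where non-empty, else union; top-down resolution keeps the
#' parent's state when it is in a node's state set). Root ambiguity is resolved
#' to the candidate state carried by the most tips (ties broken by
#' lexicographic order). Each edge is painted with its *child* node's state, so
#' pendant edges always match their tip's observed state — which is what the
#' two-rate BM and two-optimum OU fits require.
#'
#' @param tree A `phylo` object.
#' @param tip_states Named character vector (or factor) mapping every tip label
#'   to a regime label.
#' @return An object of class `regime_painting`: a list with `edge_states`
#'   (character, along `tree$edge` rows), `node_states`, `root_state`,
#'   `tip_states`, `levels`, `n_changes` (the Fitch parsimony score), and the
#'   `tree`.
#' @export
paint_regimes <- function(tree, tip_states) {
  validate_phylo(tree, require_lengths = FALSE)
  tip_states <- stats::setNames(as.character(tip_states), names(tip_states))
  missing <- setdiff(tree$tip.label, names(tip_states))
  if (length(missing)) {
    stop("missing tip states for: ", paste(missing, collapse = ", "))
  }
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  root <- ntip + 1L
  states <- tip_states[tree$tip.label]

  # bottom-up state sets
  sets <- vector("list", nn)
  for (i in seq_len(ntip)) sets[[i]] <- states[i]
  po <- ape::reorder.phylo(tree, "postorder")
  ch <- .children_list(tree)
  internal_po <- unique(po$edge[, 1])  # parents appear after their children
  for (v in internal_po) {
    kid_sets <- lapply(ch[[v]], function(k) sets[[k]])
    inter <- Reduce(intersect, kid_sets)
    sets[[v]] <- if (length(inter)) sort(inter) else sort(unique(unlist(kid_sets)))
  }

  # top-down resolution
  node_state <- character(nn)
  node_state[seq_len(ntip)] <- states
  root_set <- sets[[root]]
  if (length(root_set) == 1L) {
    node_state[root] <- root_set
  } else {
    counts <- table(factor(states, levels = sort(root_set)))
    node_state[root] <- names(counts)[order(-counts, names(counts))][1L]
  }
  pre <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  for (e in seq_len(nrow(pre$edge))) {
    p <- pre$edge[e, 1]; v <- pre$edge[e, 2]
    if (v <= ntip) next
    node_state[v] <- if (node_state[p] %in% sets[[v]]) node_state[p] else sets[[v]][1L]
  }

  edge_states <- node_state[tree$edge[, 2]]
  n_changes <- sum(node_state[tree$edge[, 1]] != node_state[tree$edge[, 2]])
  structure(
    list(edge_states = edge_states,
         node_states = node_state,
         root_state = node_state[root],
         tip_states = states,
         levels = sort(unique(states)),
         n_changes = n_changes,
         tree = tree),
    class = "regime_painting")
}

#' @export
print.regime_painting <- function(x, ...) {
  cat("Regime painting:", length(x$levels), "regime(s) on",
      nrow(x$tree$edge), "edges\n")
  cat("  levels:", paste(x$levels, collapse = ", "), "\n")
  cat("  root regime:", x$root_state, "\n")
  cat("  state changes (Fitch score):", x$n_changes, "\n")
  invisible(x)
}

# Per-regime shared-path matrices: C_r(i,j) = shared root-to-MRCA path length
# spent on edges painted r. Sums over regimes to phylo_vcv(tree).
.regime_vcv <- function(tree, painting) {
  n <- ape::Ntip(tree)
  desc <- .edge_descendants(tree)
  out <- lapply(painting$levels, function(r) {
    M <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
    for (e in which(painting$edge_states == r)) {
      idx <- desc[[e]]
      M[idx, idx] <- M[idx, idx] + tree$edge.length[e]
    }
    M
  })
  names(out) <- painting$levels
  out
}
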