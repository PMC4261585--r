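#' @importFrom stats nlminb pchisq pgamma qgamma runif setNames reorder
#' @importFrom utils read.table write.table modifyList
#' @importFrom ape read.tree
NULL

## Trees are ape "phylo" objects carrying one extra component,
## `edge.category`: an integer vector aligned with the rows of $edge that
## assigns every branch to a rate category (multiplier mu_1..mu_C).
## Class c("rate_tree", "phylo") so all of ape keeps working.

#' Wrap an ape `phylo` object as a rate tree
#'
#' Attaches the per-branch rate-category vector (all 1 by default) that the
#' likelihood machinery expects.
#'
#' @param phy an [ape] `phylo` object with branch lengths.
#' @param edge_category integer vector aligned with the rows of
#'   `phy$edge`; defaults to all 1.
#' @return a `rate_tree`.
#' @export
as_rate_tree <- function(phy, edge_category = NULL) {
  if (is.null(edge_category)) edge_category <- rep(1L, nrow(phy$edge))
  stopifnot(length(edge_category) == nrow(phy$edge))
  phy$edge.category <- as.integer(edge_category)
  class(phy) <- unique(c("rate_tree", class(phy)))
  phy
}

root_node <- function(phy) length(phy$tip.label) + 1L

#' Number of rate categories on a tree's branches
#'
#' @param tree a `rate_tree` (or plain `phylo`, which has one category).
#' @return integer, the number of distinct branch rate categories.
#' @export
n_branch_categories <- function(tree) {
  if (is.null(tree$edge.category)) return(1L)
  length(unique(tree$edge.category))
}

#' Is the tree rooted?
#'
#' A tree is treated as rooted when the root node has exactly two children;
#' a basal polytomy marks an unrooted tree.
#'
#' @param tree a `rate_tree` or `phylo`.
#' @return logical.
#' @export
is_rooted_tree <- function(tree) {
  sum(tree$edge[, 1] == root_node(tree)) == 2L
}

validate_newick_text <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(text))
    stop("newick text must be a single non-empty string", call. = FALSE)
  # labels with embedded whitespace are unsupported; strip all whitespace
  text <- gsub("[[:space:]]+", "", text)
  semi <- regexpr(";", text, fixed = TRUE)
  if (semi < 0L)
    stop("newick parse error: no terminating ';'", call. = FALSE)
  if (semi < nchar(text))
    stop("newick parse error: text after ';' at position ", semi + 1L,
         call. = FALSE)
  depth <- 0L
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("newick parse error: unmatched ')' at position ", i,
             call. = FALSE)
    }
  }
  if (depth != 0L)
    stop("newick parse error: ", depth, " unclosed '(' at end of text",
         call. = FALSE)
  text
}

check_tree_valid <- function(phy) {
  if (is.null(phy$edge.length) || anyNA(phy$edge.length))
    stop("branch lengths required on every branch", call. = FALSE)
  if (any(!is.finite(phy$edge.length)) || any(phy$edge.length < 0))
    stop("branch lengths must be finite and nonnegative", call. = FALSE)
  if (anyDuplicated(phy$tip.label) || any(!nzchar(phy$tip.label)))
    stop("leaf labels must be unique and nonempty", call. = FALSE)
  invisible(phy)
}

#' Parse a standard Newick tree
#'
#' All branches must carry lengths; these are the relative time scale of the
#' analysis. Every branch is placed in rate category 1.
#'
#' @param text a single Newick statement ending in `;`.
#' @return a `rate_tree`.
#' @export
#' @examples
#' tr <- parse_newick("((A:1.0,B:1.0):0.5,C:1.5);")
#' is_rooted_tree(tr)
parse_newick <- function(text) {
  text <- validate_newick_text(text)
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy))
    stop("newick parse error: unreadable tree text", call. = FALSE)
  check_tree_valid(phy)
  as_rate_tree(phy)
}

strip_cat <- function(labels) sub("\\$[^$]*$", "", labels)

cat_suffix <- function(labels) {
  has <- grepl("$", labels, fixed = TRUE)
  suf <- rep(NA_character_, length(labels))
  suf[has] <- sub("^.*\\$", "", labels[has])
  suf
}

#' Parse the `$`-labelled rate-category Newick dialect
#'
#' Node labels may carry a suffix `$k` (k a positive integer) assigning the
#' branch *above* the labelled node to rate category k. Categories are
#' relabelled to contiguous 1..C preserving their numeric order; branches
#' without a label fall in category 1 (with a warning when labels are mixed
#' with unlabelled branches). A `$` on the root is ignored with a warning:
#' the root has no branch.
#'
#' @param text a single Newick statement, possibly with `$k` labels.
#' @return a `rate_tree` with `edge.category` filled in.
#' @export
#' @examples
#' tr <- parse_rate_newick(
#'   "(((t1$1:0.01,t2$1:0.01)$3:0.01,t3$2:0.02)$3:0.01,t4$2:0.03);")
#' n_branch_categories(tr)
parse_rate_newick <- function(text) {
  text <- validate_newick_text(text)
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy))
    stop("newick parse error: unreadable tree text", call. = FALSE)
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  labels <- c(phy$tip.label,
              if (is.null(phy$node.label)) rep("", nnode) else phy$node.label)
  suf <- cat_suffix(labels)
  bad <- !is.na(suf) & !grepl("^[0-9]+$", suf)
  if (any(bad))
    stop("invalid rate-category label '$", suf[which(bad)[1L]],
         "': expected a positive integer after '$'", call. = FALSE)
  cats <- suppressWarnings(as.integer(suf))
  if (any(!is.na(cats) & cats < 1L))
    stop("rate categories must be positive integers", call. = FALSE)
  rt <- root_node(phy)
  if (!is.na(cats[rt])) {
    warning("'$' label on the root node ignored (the root has no branch)")
    cats[rt] <- NA_integer_
  }
  phy$tip.label <- strip_cat(phy$tip.label)
  if (!is.null(phy$node.label)) {
    nl <- strip_cat(phy$node.label)
    phy$node.label <- if (all(!nzchar(nl))) NULL else nl
  }
  check_tree_valid(phy)
  edge_cat <- cats[phy$edge[, 2]]
  n_lab <- sum(!is.na(edge_cat))
  if (n_lab > 0L && n_lab < length(edge_cat))
    warning("tree mixes '$'-labelled and unlabelled branches; ",
            "unlabelled branches assigned rate category 1")
  edge_cat[is.na(edge_cat)] <- 1L
  # relabel to contiguous 1..C preserving numeric order
  edge_cat <- match(edge_cat, sort(unique(edge_cat)))
  as_rate_tree(phy, edge_cat)
}

#' Write a tree as Newick text
#'
#' @param tree a `rate_tree`.
#' @param categories emit `$k` branch-category labels? Default: only when
#'   some branch is outside category 1 (plain trees stay plain Newick).
#' @return a single Newick string.
#' @export
write_newick <- function(tree, categories = NULL) {
  edge_cat <- tree$edge.category
  if (is.null(edge_cat)) edge_cat <- rep(1L, nrow(tree$edge))
  if (is.null(categories)) categories <- any(edge_cat != 1L)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  fmt <- function(x) sprintf("%.17g", x)
  rec <- function(node) {
    kids <- children[[as.character(node)]]
    if (is.null(kids)) return(tree$tip.label[node])
    parts <- vapply(kids, function(e) {
      child <- tree$edge[e, 2]
      lab <- rec(child)
      if (categories) lab <- paste0(lab, "$", edge_cat[e])
      paste0(lab, ":", fmt(tree$edge.length[e]))
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(rec(root_node(tree)), ";")
}

## adjacency list view of the (undirected) tree: per node, the incident
## edges as (neighbour, length, category)
tree_adjacency <- function(tree) {
  nn <- length(tree$tip.label) + tree$Nnode
  adj <- vector("list", nn)
  edge_cat <- tree$edge.category
  if (is.null(edge_cat)) edge_cat <- rep(1L, nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
    len <- tree$edge.length[e]; ct <- edge_cat[e]
    adj[[a]] <- rbind(adj[[a]], c(b, len, ct))
    adj[[b]] <- rbind(adj[[b]], c(a, len, ct))
  }
  adj
}

## rebuild a rate_tree from an adjacency list, rooted at `start`,
## optionally with an extra root splitting edge (n1, n2)
rebuild_from <- function(tree, adj, start) {
  fmt <- function(x) sprintf("%.17g", x)
  rec <- function(node, parent) {
    nb <- adj[[node]]
    kids <- nb[nb[, 1] != parent, , drop = FALSE]
    if (nrow(kids) == 0L) return(tree$tip.label[node])
    parts <- vapply(seq_len(nrow(kids)), function(i) {
      paste0(rec(kids[i, 1], node), "$", kids[i, 3], ":", fmt(kids[i, 2]))
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  suppressWarnings(parse_rate_newick(paste0(rec(start, 0L), ";")))
}

#' Midpoint-root an unrooted tree
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path. A tree
#' that is already rooted (binary root) is returned unchanged. Ties among
#' equally longest paths are broken by the lexicographically smallest pair
#' of leaf labels; a midpoint falling exactly on an internal node makes that
#' node the root (no zero-length branch is inserted). Branch rate categories
#' travel with their branches; the split branch's two halves inherit its
#' category. All leaf-to-leaf path lengths are preserved.
#'
#' @param tree a `rate_tree`.
#' @return a rooted `rate_tree`.
#' @export
midpoint_root <- function(tree) {
  if (length(tree$tip.label) < 2L)
    stop("midpoint rooting needs at least 2 leaves", call. = FALSE)
  if (is_rooted_tree(tree)) return(tree)
  if (all(tree$edge.length == 0))
    stop("midpoint undefined: all branch lengths are zero", call. = FALSE)
  ntip <- length(tree$tip.label)
  d <- ape::dist.nodes(tree)[seq_len(ntip), seq_len(ntip), drop = FALSE]
  dmax <- max(d)
  idx <- which(d >= dmax - 1e-12 * max(1, dmax), arr.ind = TRUE)
  idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  pairs <- data.frame(
    lo = pmin(tree$tip.label[idx[, 1]], tree$tip.label[idx[, 2]]),
    hi = pmax(tree$tip.label[idx[, 1]], tree$tip.label[idx[, 2]]),
    i = idx[, 1], j = idx[, 2], stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$lo, pairs$hi), , drop = FALSE]
  u <- pairs$i[1L]; v <- pairs$j[1L]
  if (tree$tip.label[u] > tree$tip.label[v]) { tmp <- u; u <- v; v <- tmp }
  path <- ape::nodepath(tree, u, v)
  adj <- tree_adjacency(tree)
  target <- d[pairs$i[1L], pairs$j[1L]] / 2
  tol <- 1e-12 * max(1, dmax)
  cum <- 0
  for (i in seq_len(length(path) - 1L)) {
    a <- path[i]; b <- path[i + 1L]
    nb <- adj[[a]]
    row <- nb[nb[, 1] == b, , drop = FALSE][1L, ]
    len <- row[2]; ct <- row[3]
    if (abs(cum - target) <= tol)           # midpoint exactly on node a
      return(rebuild_from(tree, adj, a))
    if (cum + len > target + tol) {
      # split edge (a, b): new root at distance (target - cum) from a
      x <- target - cum
      nn <- length(adj) + 1L
      adj[[a]][adj[[a]][, 1] == b, ] <- c(nn, x, ct)
      adj[[b]][adj[[b]][, 1] == a, ] <- c(nn, len - x, ct)
      adj[[nn]] <- rbind(c(a, x, ct), c(b, len - x, ct))
      return(rebuild_from(tree, adj, nn))
    }
    cum <- cum + len
  }
  rebuild_from(tree, adj, v)  # midpoint on the far endpoint (degenerate)
}

#' Read a tree file (plain or `$`-labelled Newick)
#'
#' @param path path to a Newick file.
#' @return a `rate_tree`.
#' @export
read_tree_file <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  parse_rate_newick(txt)
}
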