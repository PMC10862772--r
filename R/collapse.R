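flip_orient <- function(o) ifelse(o == "+", "-", "+")

## A link equals its reverse-complement twin: from (a,oa) to (b,ob) is the
## same adjacency as from (b,!ob) to (a,!oa). Canonical key = the
## lexicographically smaller of the two spellings.
link_canonical_key <- function(from, from_orient, to, to_orient) {
  k1 <- paste(from, from_orient, to, to_orient, sep = "\t")
  k2 <- paste(to, flip_orient(to_orient), from, flip_orient(from_orient),
              sep = "\t")
  ifelse(k1 <= k2, k1, k2)
}

edge_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\t")
}

#' Collapse an assembly graph into the undirected analysis graph
#'
#' Builds the undirected, weighted graph the SV caller works on: one node
#' per segment (or per complementary segment pair when a pairing map is
#' supplied, matching Bandage's "single" view), and one undirected edge per
#' adjacent node pair with weight equal to the number of distinct links
#' between them. A link and its reverse-complement twin count as one link;
#' remaining parallel links increment the weight. Links from a segment to
#' itself become self-loop edges.
#'
#' @param graph An `assembly_graph` from [parse_gfa()].
#' @param pairing Optional complementary-pair map: a two-column data.frame
#'   (or matrix) of segment names; each row merges two segments into one
#'   node. A segment may appear in at most one pair.
#' @return An object of class `collapsed_graph`: list with
#'   `nodes` (data.frame `id`, `length`), `members` (named character vector
#'   mapping every segment to its node id) and `edges` (data.frame `from`,
#'   `to`, `weight`, with `from <= to`; `from == to` marks a self-loop).
#' @export
collapse_graph <- function(graph, pairing = NULL) {
  stopifnot(inherits(graph, "assembly_graph"))
  segs <- graph$segments
  members <- stats::setNames(segs$name, segs$name)
  if (!is.null(pairing)) {
    pairing <- as.data.frame(pairing, stringsAsFactors = FALSE)
    if (ncol(pairing) != 2) stop("pairing must have two columns")
    all_named <- c(pairing[[1]], pairing[[2]])
    if (anyDuplicated(all_named)) {
      stop("pairing maps segment(s) to more than one partner: ",
           paste(unique(all_named[duplicated(all_named)]), collapse = ", "))
    }
    unknown <- setdiff(all_named, segs$name)
    if (length(unknown) > 0) {
      stop("pairing references unknown segment(s): ",
           paste(unknown, collapse = ", "))
    }
    for (r in seq_len(nrow(pairing))) {
      a <- pairing[r, 1]; b <- pairing[r, 2]
      la <- segs$length[segs$name == a]
      lb <- segs$length[segs$name == b]
      if (la != lb) {
        stop("complementary pair (", a, ", ", b, ") has unequal lengths")
      }
      id <- min(a, b)
      members[[a]] <- id
      members[[b]] <- id
    }
  }
  node_ids <- sort(unique(unname(members)))
  node_len <- segs$length[match(node_ids, segs$name)]
  nodes <- data.frame(id = node_ids, length = node_len,
                      stringsAsFactors = FALSE)

  lk <- graph$links
  if (nrow(lk) > 0) {
    keys <- link_canonical_key(lk$from, lk$from_orient, lk$to, lk$to_orient)
    uniq <- lk[!duplicated(keys), , drop = FALSE]
    u <- unname(members[uniq$from])
    v <- unname(members[uniq$to])
    ek <- edge_key(u, v)
    tab <- table(ek)
    parts <- strsplit(names(tab), "\t", fixed = TRUE)
    edges <- data.frame(
      from = vapply(parts, `[[`, "", 1L),
      to = vapply(parts, `[[`, "", 2L),
      weight = as.integer(tab),
      stringsAsFactors = FALSE
    )
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(from = character(), to = character(),
                        weight = integer(), stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, members = members, edges = edges),
            class = "collapsed_graph")
}

#' @export
print.collapsed_graph <- function(x, ...) {
  cat("collapsed_graph:", nrow(x$nodes), "nodes,", nrow(x$edges),
      "edges (weight sum", sum(x$edges$weight), "),",
      sum(x$edges$from == x$edges$to), "self-loop(s)\n")
  invisible(x)
}

## simple (loop-free, weight-ignored) igraph view used for motif search
simple_igraph <- function(graph) {
  e <- graph$edges
  e <- e[e$from != e$to, c("from", "to"), drop = FALSE]
  igraph::graph_from_data_frame(
    e, directed = FALSE,
    vertices = data.frame(name = graph$nodes$id, stringsAsFactors = FALSE)
  )
}

#' Enumerate all triangles of the collapsed graph
#'
#' Triangles (three mutually adjacent nodes) are the motif scanned for
#' insertions and deletions. Self-loops are ignored for adjacency; edge
#' weights do not matter.
#'
#' @param graph A `collapsed_graph`.
#' @return Character matrix with 3 columns; each row one triangle, node ids
#'   sorted within the row, rows in lexicographic order. Zero rows if none.
#' @export
enumerate_triangles <- function(graph) {
  stopifnot(inherits(graph, "collapsed_graph"))
  g <- simple_igraph(graph)
  tri <- igraph::triangles(g)
  if (length(tri) == 0) {
    return(matrix(character(), ncol = 3,
                  dimnames = list(NULL, c("a", "b", "c"))))
  }
  m <- matrix(igraph::V(g)$name[tri], ncol = 3, byrow = TRUE)
  m <- t(apply(m, 1, sort))
  m <- m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
  colnames(m) <- c("a", "b", "c")
  m
}

#' Enumerate all 4-cycles (squares) of the collapsed graph
#'
#' Squares (simple cycles over 4 distinct nodes) are the motif scanned for
#' complex indels. Chords are permitted: a 4-cycle embedded in a denser
#' subgraph still counts. Each square is reported once, in canonical cycle
#' order (lexicographically smallest rotation/reflection), together with
#' its two opposite (non-adjacent-in-cycle) node pairs.
#'
#' @param graph A `collapsed_graph`.
#' @return List of squares; each element a list with `cycle` (character
#'   vector of the 4 nodes in cycle order) and `pairs` (list of the two
#'   opposite pairs, `cycle[c(1,3)]` and `cycle[c(2,4)]`).
#' @export
enumerate_squares <- function(graph) {
  stopifnot(inherits(graph, "collapsed_graph"))
  e <- graph$edges
  e <- e[e$from != e$to, , drop = FALSE]
  nodes <- graph$nodes$id
  adj <- lapply(stats::setNames(nodes, nodes), function(n) character())
  for (r in seq_len(nrow(e))) {
    adj[[e$from[r]]] <- c(adj[[e$from[r]]], e$to[r])
    adj[[e$to[r]]] <- c(adj[[e$to[r]]], e$from[r])
  }
  out <- list()
  seen <- character()
  n_nodes <- length(nodes)
  if (n_nodes >= 4) {
    for (pi in seq_len(n_nodes - 1L)) {
      p <- nodes[pi]
      for (qi in (pi + 1L):n_nodes) {
        q <- nodes[qi]
        common <- intersect(adj[[p]], adj[[q]])
        common <- setdiff(common, c(p, q))
        if (length(common) < 2) next
        common <- sort(common)
        cm <- utils::combn(common, 2)
        for (k in seq_len(ncol(cm))) {
          r <- cm[1, k]; s <- cm[2, k]
          d1 <- paste(sort(c(p, q)), collapse = "\t")
          d2 <- paste(sort(c(r, s)), collapse = "\t")
          key <- paste(sort(c(d1, d2)), collapse = "\n")
          if (key %in% seen) next
          seen <- c(seen, key)
          out[[length(out) + 1L]] <- canonical_square(c(p, q), c(r, s))
        }
      }
    }
  }
  out
}

## cycle order is diag1[1], diag2[1], diag1[2], diag2[2]; canonicalize to
## the lexicographically smallest rotation/reflection
canonical_square <- function(diag1, diag2) {
  all4 <- c(diag1, diag2)
  a <- min(all4)
  if (a %in% diag1) {
    first <- diag1; second <- diag2
  } else {
    first <- diag2; second <- diag1
  }
  c_node <- setdiff(first, a)
  b <- min(second)
  d <- setdiff(second, b)
  cyc <- c(a, b, c_node, d)
  list(cycle = cyc, pairs = list(cyc[c(1, 3)], cyc[c(2, 4)]))
}

#' List self-loop edges
#'
#' Self-loops (an edge from a node to itself) carry the self-duplication
#' signal: an edge log-fold-change above 1 on a loop calls a tandem
#' duplication on the loop node.
#'
#' @param graph A `collapsed_graph`.
#' @return data.frame with columns `node` and `weight`, one row per
#'   self-loop edge.
#' @export
self_loops <- function(graph) {
  stopifnot(inherits(graph, "collapsed_graph"))
  e <- graph$edges[graph$edges$from == graph$edges$to, , drop = FALSE]
  data.frame(node = e$from, weight = e$weight, stringsAsFactors = FALSE)
}
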