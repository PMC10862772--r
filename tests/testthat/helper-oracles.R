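# Independent brute-force oracles and tiny file builders. These stay
# deliberately naive: direct scans, per-base arrays, and re-derived
# arithmetic, so they cannot share a defect with the implementation.

tmp_file <- function(lines, ext = ".txt") {
  p <- tempfile(fileext = ext)
  writeLines(lines, p)
  p
}

gfa_file <- function(...) tmp_file(c(...), ext = ".gfa")
gaf_file <- function(...) tmp_file(c(...), ext = ".gaf")

# a minimal GAF line: read of length rl aligned to `path` at [ps, pe)
gaf_line <- function(id, path, pl, ps, pe, rl = pe - ps, mapq = 60) {
  paste(id, rl, 0, rl, "+", path, pl, ps, pe, pe - ps, pe - ps, mapq,
        sep = "\t")
}

# --- motif enumeration oracles (direct scans over all tuples) -------------

adjacency_set <- function(graph) {
  e <- graph$edges[graph$edges$from != graph$edges$to, , drop = FALSE]
  paste(pmin(e$from, e$to), pmax(e$from, e$to))
}

brute_triangles <- function(graph) {
  nodes <- sort(graph$nodes$id)
  adj <- adjacency_set(graph)
  has <- function(a, b) paste(min(a, b), max(a, b)) %in% adj
  out <- character()
  if (length(nodes) >= 3) {
    cm <- combn(nodes, 3)
    for (k in seq_len(ncol(cm))) {
      a <- cm[1, k]; b <- cm[2, k]; c <- cm[3, k]
      if (has(a, b) && has(a, c) && has(b, c)) {
        out <- c(out, paste(a, b, c))
      }
    }
  }
  sort(out)
}

# each 4-cycle as "sorted nodes | sorted diagonal pairs"
brute_squares <- function(graph) {
  nodes <- sort(graph$nodes$id)
  adj <- adjacency_set(graph)
  has <- function(a, b) paste(min(a, b), max(a, b)) %in% adj
  out <- character()
  if (length(nodes) >= 4) {
    cm <- combn(nodes, 4)
    for (k in seq_len(ncol(cm))) {
      q <- cm[, k]
      # the 3 ways to split 4 nodes into two diagonal pairs
      pairings <- list(list(c(q[1], q[2]), c(q[3], q[4])),
                       list(c(q[1], q[3]), c(q[2], q[4])),
                       list(c(q[1], q[4]), c(q[2], q[3])))
      for (pr in pairings) {
        d1 <- pr[[1]]; d2 <- pr[[2]]
        # cycle d1[1]-d2[1]-d1[2]-d2[2]: all four rim edges must exist
        if (has(d1[1], d2[1]) && has(d2[1], d1[2]) &&
              has(d1[2], d2[2]) && has(d2[2], d1[1])) {
          out <- c(out, paste(paste(sort(q), collapse = " "), "|",
                              paste(sort(c(paste(sort(d1), collapse = "-"),
                                           paste(sort(d2), collapse = "-"))),
                                    collapse = " ")))
        }
      }
    }
  }
  sort(out)
}

square_key <- function(sq) {
  d1 <- sort(sq$pairs[[1]]); d2 <- sort(sq$pairs[[2]])
  paste(paste(sort(sq$cycle), collapse = " "), "|",
        paste(sort(c(paste(d1, collapse = "-"), paste(d2, collapse = "-"))),
              collapse = " "))
}

# --- link canonicalization oracle -----------------------------------------

brute_canonical_links <- function(links) {
  fl <- function(o) if (o == "+") "-" else "+"
  keys <- character(nrow(links))
  for (r in seq_len(nrow(links))) {
    a <- paste(links$from[r], links$from_orient[r], links$to[r],
               links$to_orient[r])
    b <- paste(links$to[r], fl(links$to_orient[r]), links$from[r],
               fl(links$from_orient[r]))
    keys[r] <- min(a, b)
  }
  unique(keys)
}

# --- per-base depth oracle -------------------------------------------------

# depth profile of one segment given alignment paths and [ps, pe) offsets
brute_depth_profile <- function(seg, seg_lens, paths, starts, ends) {
  prof <- rep(0, seg_lens[[seg]])
  for (i in seq_along(paths)) {
    p <- paths[[i]]
    offs <- cumsum(c(0, seg_lens[p]))[seq_along(p)]
    for (k in seq_along(p)) {
      if (p[k] != seg) next
      lo <- max(starts[i], offs[k]) - offs[k]
      hi <- min(ends[i], offs[k] + seg_lens[[p[k]]]) - offs[k]
      if (hi > lo) prof[(lo + 1):hi] <- prof[(lo + 1):hi] + 1
    }
  }
  prof
}

# --- caller oracle: direct scan of all triples/quadruples/edges ------------

brute_outliers <- function(v) {
  med <- median(v)
  s <- sqrt(sum((v - mean(v))^2) / length(v))
  list(idx = which(abs(v - med) > s), med = med)
}

# returns sorted "type|step|node-set" keys for one lfc table
brute_call_keys <- function(graph, node_lfc, edge_lfc) {
  nodes <- sort(graph$nodes$id)
  adj <- adjacency_set(graph)
  has <- function(a, b) paste(min(a, b), max(a, b)) %in% adj
  e <- graph$edges
  keys <- character()
  for (p in seq_len(nrow(node_lfc))) {
    v <- node_lfc[p, ]
    step_called <- character()
    if (length(nodes) >= 3) {
      cm <- combn(nodes, 3)
      for (k in seq_len(ncol(cm))) {
        tr <- cm[, k]
        if (!(has(tr[1], tr[2]) && has(tr[1], tr[3]) && has(tr[2], tr[3])))
          next
        o <- brute_outliers(v[tr])
        if (length(o$idx) != 1) next
        ty <- if (v[tr][o$idx] > o$med) "insertion" else "deletion"
        keys <- c(keys, paste(ty, p, tr[o$idx], sep = "|"))
        step_called <- c(step_called, tr[o$idx])
      }
    }
    if (length(nodes) >= 4) {
      cm <- combn(nodes, 4)
      for (k in seq_len(ncol(cm))) {
        q <- cm[, k]
        pairings <- list(list(c(q[1], q[2]), c(q[3], q[4])),
                         list(c(q[1], q[3]), c(q[2], q[4])),
                         list(c(q[1], q[4]), c(q[2], q[3])))
        for (pr in pairings) {
          d1 <- pr[[1]]; d2 <- pr[[2]]
          cyc <- c(d1[1], d2[1], d1[2], d2[2])
          if (!(has(cyc[1], cyc[2]) && has(cyc[2], cyc[3]) &&
                  has(cyc[3], cyc[4]) && has(cyc[4], cyc[1]))) next
          o <- brute_outliers(v[cyc])
          if (length(o$idx) == 1) {
            keys <- c(keys, paste("complex_indel", p, cyc[o$idx], sep = "|"))
            step_called <- c(step_called, cyc[o$idx])
          } else if (length(o$idx) == 2 && abs(diff(o$idx)) == 2) {
            vals <- v[cyc][o$idx]
            if ((vals[1] - o$med) * (vals[2] - o$med) < 0) {
              ns <- sort(cyc[o$idx])
              keys <- c(keys,
                        paste("complex_indel", p,
                              paste(ns, collapse = ","), sep = "|"))
              step_called <- c(step_called, cyc[o$idx])
            }
          }
        }
      }
    }
    for (r in seq_len(nrow(e))) {
      if (edge_lfc[p, r] <= 1) next
      if (e$from[r] == e$to[r]) {
        keys <- c(keys, paste("tandem_duplication", p, e$from[r], sep = "|"))
      } else if (e$weight[r] >= 2) {
        lu <- v[[e$from[r]]]; lv <- v[[e$to[r]]]
        n <- if (lu > lv) e$from[r] else if (lv > lu) e$to[r]
        else min(e$from[r], e$to[r])
        if (!(n %in% step_called)) {
          keys <- c(keys, paste("tandem_duplication", p, n, sep = "|"))
        }
      }
    }
  }
  sort(unique(keys))
}

call_keys <- function(calls) {
  sort(unique(paste(calls$sv_type, calls$step_pair, calls$called_node,
                    sep = "|")))
}

# random assembly graph: n segments, each link drawn with random
# orientations; duplicates and loops allowed
random_assembly_graph <- function(n, p_edge = 0.15, p_loop = 0.1,
                                  p_dup = 0.15) {
  names <- sprintf("n%02d", seq_len(n))
  segs <- data.frame(name = names, length = sample(100:999, n, replace = TRUE),
                     sequence = NA_character_, stringsAsFactors = FALSE)
  links <- data.frame(from = character(), from_orient = character(),
                      to = character(), to_orient = character(),
                      stringsAsFactors = FALSE)
  ori <- c("+", "-")
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (i == j) {
        if (runif(1) > p_loop) next
      } else if (runif(1) > p_edge) next
      reps <- 1 + stats::rbinom(1, 2, p_dup)
      for (k in seq_len(reps)) {
        links <- rbind(links, data.frame(
          from = names[i], from_orient = sample(ori, 1),
          to = names[j], to_orient = sample(ori, 1),
          stringsAsFactors = FALSE))
      }
    }
  }
  structure(list(segments = segs, links = links), class = "assembly_graph")
}

# lfc_table built directly from matrices (for caller tests without files)
make_lfc <- function(graph, node_lfc, edge_lfc, sd_mode = "population") {
  n_steps <- nrow(node_lfc)
  cfg <- series_config(sprintf("s%d", seq_len(n_steps + 1)),
                       sd_mode = sd_mode)
  structure(list(node_lfc = node_lfc, edge_lfc = edge_lfc, config = cfg,
                 graph = graph), class = "lfc_table")
}

# chain of nodes s1-s2-...-sn with given lengths
chain_graph <- function(lens) {
  n <- length(lens)
  nm <- sprintf("s%d", seq_len(n))
  structure(list(
    nodes = data.frame(id = nm, length = as.integer(lens),
                       stringsAsFactors = FALSE),
    members = stats::setNames(nm, nm),
    edges = if (n > 1) {
      data.frame(from = nm[-n], to = nm[-1], weight = 1L,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(from = character(), to = character(), weight = integer())
    }
  ), class = "collapsed_graph")
}

# collapsed graph built directly from an edge list (from, to, weight)
make_graph <- function(edges, lengths = NULL) {
  nodes <- sort(unique(c(edges$from, edges$to)))
  if (is.null(lengths)) lengths <- rep(1000L, length(nodes))
  structure(list(
    nodes = data.frame(id = nodes, length = lengths,
                       stringsAsFactors = FALSE),
    members = stats::setNames(nodes, nodes),
    edges = edges[order(edges$from, edges$to), , drop = FALSE]
  ), class = "collapsed_graph")
}
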