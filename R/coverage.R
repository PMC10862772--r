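#' Series configuration
#'
#' Bundles the options that govern coverage normalization and fold-change
#' computation across the sample series.
#'
#' @param sample_ids Ordered sample identifiers (series order; N+1 samples
#'   give N consecutive step pairs).
#' @param bp_totals Total aligned-read base pairs per sample, same order.
#'   Computed from GAF files by [coverage_table()] when not supplied there.
#' @param log_base Base of the log used for fold changes (default 2, so a
#'   fold change "greater than 1" means more than doubling).
#' @param floor_value Coverage floor (default 1): node coverage below this
#'   is raised to it so log ratios stay defined.
#' @param normalization_mode One of `"median_ratio"` (default; multiply
#'   sample n by m / bp_n where m is the median of `bp_totals`, equalizing
#'   sequencing depth), `"bp_ratio"` (multiply by bp_n / m) or
#'   `"none"`.
#' @param sd_mode `"population"` (divide by n; default) or `"sample"`
#'   (divide by n-1) for the outlier rule's standard deviation.
#' @return An object of class `series_config`.
#' @export
series_config <- function(sample_ids, bp_totals = NULL, log_base = 2,
                          floor_value = 1,
                          normalization_mode = c("median_ratio",
                                                 "bp_ratio", "none"),
                          sd_mode = c("population", "sample")) {
  normalization_mode <- match.arg(normalization_mode)
  sd_mode <- match.arg(sd_mode)
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) < 2) stop("a series needs at least 2 samples")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (!is.null(bp_totals)) {
    if (length(bp_totals) != length(sample_ids)) {
      stop("bp_totals must match sample_ids in length")
    }
    if (any(bp_totals <= 0)) stop("bp_totals must all be > 0")
  }
  if (log_base <= 1) stop("log_base must be > 1")
  structure(
    list(sample_ids = sample_ids, bp_totals = bp_totals,
         log_base = log_base, floor_value = floor_value,
         normalization_mode = normalization_mode, sd_mode = sd_mode),
    class = "series_config"
  )
}

## long table (aln, seg, node, covered bp) from alignment paths, with
## terminal segments clipped by path_start/path_end
alignment_base_table <- function(alignments, graph, seg_lengths) {
  n_aln <- nrow(alignments)
  if (n_aln == 0) {
    return(data.table::data.table(aln = integer(), seg = character(),
                                  node = character(), covered = numeric()))
  }
  lens <- lengths(alignments$path_segs)
  segv <- unlist(alignments$path_segs, use.names = FALSE)
  unknown <- setdiff(unique(segv), names(seg_lengths))
  if (length(unknown) > 0) {
    first_bad <- which(vapply(alignments$path_segs,
                              function(p) any(p %in% unknown), logical(1)))[1]
    stop("read '", alignments$read_id[first_bad],
         "' references segment(s) absent from graph: ",
         paste(unknown, collapse = ", "))
  }
  dt <- data.table::data.table(
    aln = rep.int(seq_len(n_aln), lens),
    seg = segv,
    seg_len = as.numeric(seg_lengths[segv])
  )
  ## segment offsets along the concatenated path
  dt[, off := cumsum(seg_len) - seg_len, by = aln]
  dt[, ps := rep.int(as.numeric(alignments$path_start), lens)]
  dt[, pe := rep.int(as.numeric(alignments$path_end), lens)]
  dt[, covered := pmax(0, pmin(pe, off + seg_len) - pmax(ps, off))]
  dt[, node := unname(graph$members[seg])]
  dt[, c("aln", "seg", "node", "covered")]
}

#' Raw per-node mean depth from alignments
#'
#' Computes, for every node of the collapsed graph, the average per-base
#' depth contributed by the alignment paths: each alignment covers its
#' interior path segments fully and its terminal segments clipped by
#' `path_start` / `path_end`; a node's raw coverage is total covered bases
#' divided by node length. No floor or normalization is applied here.
#'
#' @param alignments A `gaf_alignments` data.frame from [parse_gaf()].
#' @param graph A `collapsed_graph`.
#' @param seg_lengths Named numeric vector of segment lengths (defaults to
#'   the collapsed nodes' lengths keyed by member segment).
#' @return Named numeric vector of raw mean depth, one entry per node, in
#'   `graph$nodes$id` order.
#' @export
node_coverage <- function(alignments, graph, seg_lengths = NULL) {
  stopifnot(inherits(graph, "collapsed_graph"))
  if (is.null(seg_lengths)) {
    seg_lengths <- stats::setNames(
      graph$nodes$length[match(unname(graph$members), graph$nodes$id)],
      names(graph$members)
    )
  }
  bt <- alignment_base_table(alignments, graph, seg_lengths)
  cov <- stats::setNames(rep(0, nrow(graph$nodes)), graph$nodes$id)
  if (nrow(bt) > 0) {
    agg <- bt[, .(bases = sum(covered)), by = node]
    cov[agg$node] <- agg$bases
  }
  cov / graph$nodes$length
}

#' Apply the coverage floor
#'
#' Nodes with coverage below the floor are raised to the floor (default 1)
#' so absent or error-depressed nodes do not produce unbounded negative
#' log ratios.
#'
#' @param raw Numeric vector/matrix of coverages (>= 0).
#' @param floor_value The floor (default 1).
#' @return `pmax(raw, floor_value)`, same shape as `raw`.
#' @export
floor_coverage <- function(raw, floor_value = 1) {
  if (any(raw < 0, na.rm = TRUE)) stop("raw coverage must be non-negative")
  pmax(raw, floor_value)
}

#' Normalize coverage across the series
#'
#' Rescales each sample's node coverages for sequencing depth using the
#' median per-sample base-pair total m. In `median_ratio` mode (default)
#' sample n is multiplied by m / bp_n, equalizing depth across the series;
#' `bp_ratio` mode applies bp_n / m instead; `none` leaves coverage
#' unchanged. The floor is re-applied after scaling.
#'
#' @param cov Matrix `[sample x node]` of floored coverages.
#' @param config A `series_config` with `bp_totals` set.
#' @return Matrix of the same shape, normalized and re-floored.
#' @export
normalize_series <- function(cov, config) {
  stopifnot(inherits(config, "series_config"))
  if (config$normalization_mode == "none") return(cov)
  bp <- config$bp_totals
  if (is.null(bp)) stop("bp_totals not set in series_config")
  if (any(bp <= 0)) stop("bp_totals must all be > 0")
  m <- stats::median(bp)
  mult <- switch(config$normalization_mode,
                 median_ratio = m / bp,
                 bp_ratio = bp / m)
  floor_coverage(cov * mult, config$floor_value)
}

#' Per-edge traversal counts from alignments
#'
#' For every consecutive pair of segments in every alignment path, the
#' corresponding undirected edge count is incremented once; traversals in
#' either direction pool into the same count, and a path step from a
#' segment to itself increments that node's self-loop. Consecutive pairs
#' with no edge in the graph are tallied as off-graph adjacencies (attached
#' as attribute `off_graph`), not errors.
#'
#' @param alignments A `gaf_alignments` data.frame.
#' @param graph A `collapsed_graph`.
#' @return Integer vector of counts, one per row of `graph$edges`, with
#'   attribute `off_graph` (count of path adjacencies absent from the
#'   graph).
#' @export
edge_traversals <- function(alignments, graph) {
  stopifnot(inherits(graph, "collapsed_graph"))
  counts <- rep(0L, nrow(graph$edges))
  off_graph <- 0L
  if (nrow(alignments) > 0) {
    lens <- lengths(alignments$path_segs)
    multi <- which(lens >= 2)
    if (length(multi) > 0) {
      froms <- character(); tos <- character()
      segv <- unlist(alignments$path_segs[multi], use.names = FALSE)
      l <- lens[multi]
      ## indices of consecutive pairs within each path
      idx_end <- cumsum(l)
      idx_start <- idx_end - l + 1L
      keep_from <- unlist(mapply(function(s, e) s:(e - 1L), idx_start,
                                 idx_end, SIMPLIFY = FALSE))
      froms <- segv[keep_from]
      tos <- segv[keep_from + 1L]
      u <- unname(graph$members[froms])
      v <- unname(graph$members[tos])
      if (anyNA(u) || anyNA(v)) {
        bad <- unique(c(froms[is.na(u)], tos[is.na(v)]))
        stop("alignment path references segment(s) absent from graph: ",
             paste(bad, collapse = ", "))
      }
      ek <- edge_key(u, v)
      tab <- table(ek)
      graph_keys <- edge_key(graph$edges$from, graph$edges$to)
      hit <- match(names(tab), graph_keys)
      off_graph <- sum(as.integer(tab)[is.na(hit)])
      if (off_graph > 0) {
        message(off_graph, " off-graph path adjacenc(ies) ignored")
      }
      ok <- !is.na(hit)
      counts[hit[ok]] <- counts[hit[ok]] + as.integer(tab)[ok]
    }
  }
  attr(counts, "off_graph") <- as.integer(off_graph)
  counts
}

#' Build the per-sample coverage table for a series
#'
#' Runs [node_coverage()] and [edge_traversals()] for each sample's GAF,
#' floors node coverage, fills in `bp_totals` (sum of mapped read lengths
#' per sample) when the config does not carry them, and normalizes node
#' coverage across the series.
#'
#' @param gaf_paths One GAF path per sample, in series order.
#' @param graph A `collapsed_graph`.
#' @param config A `series_config` whose `sample_ids` match `gaf_paths`.
#' @param min_mapq,min_length Optional alignment filters passed to
#'   [parse_gaf()].
#' @return An object of class `coverage_table`: list with `node_cov`
#'   (matrix sample x node, floored and normalized), `edge_cov` (integer
#'   matrix sample x edge, raw traversal counts), `config` (with
#'   `bp_totals` filled in) and `graph`.
#' @export
coverage_table <- function(gaf_paths, graph, config, min_mapq = 0,
                           min_length = 0) {
  stopifnot(inherits(graph, "collapsed_graph"),
            inherits(config, "series_config"))
  if (length(gaf_paths) != length(config$sample_ids)) {
    stop("need one GAF per sample: got ", length(gaf_paths), " GAF(s) for ",
         length(config$sample_ids), " sample(s)")
  }
  n_s <- length(gaf_paths)
  node_cov <- matrix(0, nrow = n_s, ncol = nrow(graph$nodes),
                     dimnames = list(config$sample_ids, graph$nodes$id))
  edge_cov <- matrix(0L, nrow = n_s, ncol = nrow(graph$edges),
                     dimnames = list(config$sample_ids,
                                     edge_key(graph$edges$from,
                                              graph$edges$to)))
  bp <- numeric(n_s)
  for (i in seq_len(n_s)) {
    aln <- parse_gaf(gaf_paths[[i]], min_mapq = min_mapq,
                     min_length = min_length)
    bp[i] <- sum(as.numeric(aln$read_length))
    node_cov[i, ] <- floor_coverage(node_coverage(aln, graph),
                                    config$floor_value)
    edge_cov[i, ] <- edge_traversals(aln, graph)
  }
  if (is.null(config$bp_totals)) {
    if (any(bp <= 0)) {
      stop("sample(s) with zero mapped bases: ",
           paste(config$sample_ids[bp <= 0], collapse = ", "))
    }
    config$bp_totals <- bp
  }
  node_cov <- normalize_series(node_cov, config)
  structure(list(node_cov = node_cov, edge_cov = edge_cov,
                 config = config, graph = graph),
            class = "coverage_table")
}
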