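#' Median/sd outlier rule for a motif's fold-change values
#'
#' The unit statistic of the caller: given the 3 (triangle) or 4 (square)
#' log-fold-change values of a motif, a value is an outlier when it lies
#' strictly more than one standard deviation from the median. The median of
#' 4 values is the mean of the middle two; the standard deviation is the
#' population sd (divide by n) by default.
#'
#' @param values Numeric vector (finite) of motif lfc values.
#' @param sd_mode `"population"` (default) or `"sample"`.
#' @return List with `outliers` (integer indices into `values`), `median`
#'   and `sd`.
#' @export
outliers_of <- function(values, sd_mode = c("population", "sample")) {
  sd_mode <- match.arg(sd_mode)
  if (any(!is.finite(values))) stop("motif lfc values must be finite")
  med <- stats::median(values)
  s <- if (sd_mode == "population") {
    sqrt(mean((values - mean(values))^2))
  } else {
    stats::sd(values)
  }
  list(outliers = which(abs(values - med) > s), median = med, sd = s)
}

new_sv_call <- function(sv_type, called_nodes, motif, motif_nodes,
                        lfc_values, median, sd, outlier_dev) {
  list(sv_type = sv_type, called_nodes = sort(called_nodes), motif = motif,
       motif_nodes = motif_nodes, lfc_values = lfc_values, median = median,
       sd = sd, outlier_dev = outlier_dev)
}

#' Evaluate one triangle for an insertion/deletion
#'
#' A triangle with exactly one outlier node calls an insertion when the
#' outlier lies above the median (the variant branch is gaining coverage)
#' or a deletion when below. Any other outlier count declines to call.
#'
#' @param nodes Character vector of the 3 triangle node ids.
#' @param values Their lfc values for one step pair, same order.
#' @param sd_mode See [outliers_of()].
#' @return An SV call (list) or `NULL`.
#' @export
call_triangle <- function(nodes, values, sd_mode = "population") {
  o <- outliers_of(values, sd_mode)
  if (length(o$outliers) != 1) return(NULL)
  i <- o$outliers
  sv_type <- if (values[i] > o$median) "insertion" else "deletion"
  new_sv_call(sv_type, nodes[i], "triangle", nodes, values, o$median, o$sd,
              abs(values[i] - o$median))
}

#' Evaluate one square (4-cycle) for a complex indel
#'
#' A square calls a complex indel when it has exactly one outlier, or
#' exactly two outliers sitting on opposite corners of the cycle (no cycle
#' edge between them) with one above and one below the median — the
#' signature of a deletion and an insertion at the same locus.
#'
#' @param square One element of [enumerate_squares()]: list with `cycle`
#'   (4 node ids in cycle order).
#' @param values Their lfc values, in cycle order.
#' @param sd_mode See [outliers_of()].
#' @return An SV call (list) or `NULL`.
#' @export
call_square <- function(square, values, sd_mode = "population") {
  cyc <- square$cycle
  o <- outliers_of(values, sd_mode)
  k <- length(o$outliers)
  if (k == 1) {
    i <- o$outliers
    return(new_sv_call("complex_indel", cyc[i], "square", cyc, values,
                       o$median, o$sd, abs(values[i] - o$median)))
  }
  if (k == 2) {
    i <- o$outliers[1]; j <- o$outliers[2]
    opposite <- abs(i - j) == 2
    opposing <- (values[i] > o$median && values[j] < o$median) ||
      (values[i] < o$median && values[j] > o$median)
    if (opposite && opposing) {
      return(new_sv_call("complex_indel", cyc[c(i, j)], "square", cyc,
                         values, o$median, o$sd,
                         max(abs(values[c(i, j)] - o$median))))
    }
  }
  NULL
}

#' Call tandem duplications for one step pair
#'
#' Two scenarios: (1) any self-loop edge whose lfc exceeds 1 calls a tandem
#' duplication on the loop node; (2) any non-loop edge of weight >= 2 whose
#' lfc exceeds 1 calls a tandem duplication on whichever endpoint has the
#' greater node lfc (ties broken toward the lexicographically smaller id),
#' unless that node already carries another SV call at this step. Both
#' thresholds are strict.
#'
#' @param graph A `collapsed_graph`.
#' @param node_lfc_row Named numeric vector: node lfc at this step pair.
#' @param edge_lfc_row Numeric vector aligned with `graph$edges` rows.
#' @param called_nodes Character vector of nodes already called at this
#'   step (indels and complex indels take precedence).
#' @return List of SV calls (possibly empty).
#' @export
call_tandem_duplications <- function(graph, node_lfc_row, edge_lfc_row,
                                     called_nodes = character()) {
  e <- graph$edges
  calls <- list()
  is_loop <- e$from == e$to
  for (r in which(is_loop & edge_lfc_row > 1)) {
    n <- e$from[r]
    calls[[length(calls) + 1L]] <- new_sv_call(
      "tandem_duplication", n, "self_loop", n,
      edge_lfc_row[r], NA_real_, NA_real_, edge_lfc_row[r]
    )
  }
  for (r in which(!is_loop & e$weight >= 2 & edge_lfc_row > 1)) {
    u <- e$from[r]; v <- e$to[r]
    lu <- node_lfc_row[[u]]; lv <- node_lfc_row[[v]]
    n <- if (lu > lv) u else if (lv > lu) v else min(u, v)
    if (n %in% called_nodes) next
    calls[[length(calls) + 1L]] <- new_sv_call(
      "tandem_duplication", n, "parallel_edge", c(u, v),
      edge_lfc_row[r], NA_real_, NA_real_, edge_lfc_row[r]
    )
  }
  calls
}

empty_calls_df <- function() {
  data.frame(
    sv_type = character(), step_pair = integer(), step_from = character(),
    step_to = character(), called_node = character(),
    motif = character(), motif_nodes = character(), lfc_values = character(),
    median = numeric(), sd = numeric(), outlier_dev = numeric(),
    n_motifs = integer(), stringsAsFactors = FALSE
  )
}

calls_to_df <- function(calls, step_pair, step_from, step_to) {
  if (length(calls) == 0) return(empty_calls_df())
  data.frame(
    sv_type = vapply(calls, `[[`, "", "sv_type"),
    step_pair = step_pair,
    step_from = step_from,
    step_to = step_to,
    called_node = vapply(calls, function(c)
      paste(c$called_nodes, collapse = ","), ""),
    motif = vapply(calls, `[[`, "", "motif"),
    motif_nodes = vapply(calls, function(c)
      paste(c$motif_nodes, collapse = ","), ""),
    lfc_values = vapply(calls, function(c)
      paste(formatC(c$lfc_values, digits = 6, format = "g"),
            collapse = ","), ""),
    median = vapply(calls, `[[`, 0, "median"),
    sd = vapply(calls, `[[`, 0, "sd"),
    outlier_dev = vapply(calls, `[[`, 0, "outlier_dev"),
    n_motifs = 1L,
    stringsAsFactors = FALSE
  )
}

## one row per (called_node, sv_type), keeping the motif with the largest
## |outlier - median| and counting supporting motif instances
dedup_calls <- function(df) {
  if (nrow(df) == 0) return(df)
  key <- paste(df$called_node, df$sv_type, sep = "\t")
  ord <- order(key, -df$outlier_dev)
  df <- df[ord, , drop = FALSE]
  key <- key[ord]
  n_by_key <- table(key)
  keep <- !duplicated(key)
  out <- df[keep, , drop = FALSE]
  out$n_motifs <- as.integer(n_by_key[key[keep]])
  out
}

#' Call all SVs across the series
#'
#' For each consecutive step pair, scans every triangle (insertions /
#' deletions), every square (complex indels), then self-loops and
#' weight >= 2 edges (tandem duplications, which yield to any SV already
#' called on the same node at the same step). Calls supported by several
#' motif instances are collapsed to one row per (node, type, step), keeping
#' the motif with the largest outlier deviation; the pre-deduplication
#' motif-instance counts are kept in the `n_motifs` column and summarized
#' in the `motif_instances` attribute.
#'
#' @param graph A `collapsed_graph`.
#' @param lfc An `lfc_table`.
#' @return data.frame of calls with columns `sv_type`, `step_pair`,
#'   `step_from`, `step_to`, `called_node` (comma-joined when a complex
#'   indel implicates two nodes), `motif`, `motif_nodes`, `lfc_values`,
#'   `median`, `sd`, `outlier_dev`, `n_motifs`; rows ordered by step, node,
#'   type. Attribute `motif_instances` counts calls per (step, type, motif)
#'   before deduplication.
#' @export
call_all <- function(graph, lfc) {
  stopifnot(inherits(graph, "collapsed_graph"), inherits(lfc, "lfc_table"))
  sd_mode <- lfc$config$sd_mode
  samples <- lfc$config$sample_ids
  tri <- enumerate_triangles(graph)
  sq <- enumerate_squares(graph)
  all_steps <- list()
  inst <- list()
  for (p in seq_len(nrow(lfc$node_lfc))) {
    nrow_lfc <- lfc$node_lfc[p, ]
    erow <- lfc$edge_lfc[p, ]
    calls <- list()
    if (nrow(tri) > 0) {
      for (t in seq_len(nrow(tri))) {
        nodes <- tri[t, ]
        c1 <- call_triangle(nodes, unname(nrow_lfc[nodes]), sd_mode)
        if (!is.null(c1)) calls[[length(calls) + 1L]] <- c1
      }
    }
    for (s in sq) {
      c1 <- call_square(s, unname(nrow_lfc[s$cycle]), sd_mode)
      if (!is.null(c1)) calls[[length(calls) + 1L]] <- c1
    }
    df <- calls_to_df(calls, p, samples[p], samples[p + 1])
    raw_df <- df
    df <- dedup_calls(df)
    called <- unique(unlist(strsplit(df$called_node, ",", fixed = TRUE)))
    dups <- call_tandem_duplications(graph, nrow_lfc, erow, called)
    ddf <- calls_to_df(dups, p, samples[p], samples[p + 1])
    raw_df <- rbind(raw_df, ddf)
    ddf <- dedup_calls(ddf)
    step_df <- rbind(df, ddf)
    all_steps[[p]] <- step_df
    if (nrow(raw_df) > 0) {
      inst[[p]] <- stats::aggregate(
        list(n_instances = rep(1L, nrow(raw_df))),
        by = list(step_pair = raw_df$step_pair, sv_type = raw_df$sv_type,
                  motif = raw_df$motif),
        FUN = sum
      )
    }
  }
  out <- do.call(rbind, c(list(empty_calls_df()), all_steps))
  out <- out[order(out$step_pair, out$called_node, out$sv_type), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "motif_instances") <- if (length(inst)) {
    do.call(rbind, inst)
  } else {
    data.frame(step_pair = integer(), sv_type = character(),
               motif = character(), n_instances = integer())
  }
  out
}

#' Compare calls against a truth table
#'
#' Matches calls to implanted events on (sv_type, step_pair, called node
#' set) and reports recall and precision per SV type and overall.
#'
#' @param calls data.frame from [call_all()].
#' @param truth data.frame with columns `sv_type`, `step_pair`, `node`
#'   (comma-joined, sorted, for two-node events), as written by
#'   [build_fixture()].
#' @return data.frame with one row per SV type present in `truth` or
#'   `calls` plus an `"overall"` row; columns `sv_type`, `n_truth`,
#'   `n_called`, `n_matched`, `recall`, `precision`.
#' @export
evaluate_calls <- function(calls, truth) {
  ckey <- paste(calls$sv_type, calls$step_pair, calls$called_node, sep = "\t")
  tkey <- paste(truth$sv_type, truth$step_pair, truth$node, sep = "\t")
  types <- sort(unique(c(calls$sv_type, truth$sv_type)))
  rows <- lapply(c(types, "overall"), function(ty) {
    if (ty == "overall") {
      ck <- ckey; tk <- tkey
    } else {
      ck <- ckey[calls$sv_type == ty]
      tk <- tkey[truth$sv_type == ty]
    }
    matched <- sum(tk %in% ck)
    data.frame(
      sv_type = ty, n_truth = length(tk), n_called = length(ck),
      n_matched = matched,
      recall = if (length(tk)) matched / length(tk) else NA_real_,
      precision = if (length(ck)) sum(ck %in% tk) / length(ck) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
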