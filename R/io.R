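#' Write the SV call table
#'
#' Tab-separated, one row per call, header
#' `sv_type step_from step_to called_node motif_nodes lfc_values evidence`;
#' rows sorted by step, then called node, then type, so identical call sets
#' always produce byte-identical files.
#'
#' @param calls data.frame from [call_all()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sv_table <- function(calls, path) {
  cols <- c("sv_type", "step_from", "step_to", "called_node",
            "motif_nodes", "lfc_values")
  stopifnot(all(cols %in% names(calls)))
  ord <- order(calls$step_pair, calls$called_node, calls$sv_type)
  df <- calls[ord, , drop = FALSE]
  out <- df[, cols, drop = FALSE]
  out$evidence <- df$motif
  con <- file(path, open = "wt")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Diverging color for a log-fold-change value
#'
#' Maps lfc values onto a blue-white-red diverging scale with 0 exactly at
#' the white midpoint; values are clamped to `[-cap, cap]`.
#'
#' @param lfc Numeric vector.
#' @param cap Positive scale endpoint; defaults to `max(abs(lfc))` (an
#'   all-zero input uses the midpoint for every value).
#' @return Character vector of hex colors.
#' @export
lfc_colour <- function(lfc, cap = NULL) {
  ends <- c("#0571B0", "#FFFFFF", "#CA0020")  # blue - white - red
  if (is.null(cap)) cap <- max(abs(lfc))
  if (!is.finite(cap) || cap <= 0) {
    return(rep(ends[2], length(lfc)))
  }
  x <- pmin(pmax(lfc, -cap), cap)
  ramp <- grDevices::colorRamp(ends, space = "rgb")
  rgb <- ramp((x + cap) / (2 * cap))
  grDevices::rgb(rgb[, 1], rgb[, 2], rgb[, 3], maxColorValue = 255)
}

#' Write a Bandage color overlay CSV
#'
#' One row per node with its diverging-scale color for the chosen step
#' pair; loading the CSV in Bandage colors the assembly graph by coverage
#' log-fold-change. The header is exactly `Name,Colour` as Bandage
#' requires; paired segments get one row per member segment so Bandage can
#' match either name.
#'
#' @param graph A `collapsed_graph`.
#' @param lfc An `lfc_table`.
#' @param step_pair Step-pair index (1 = first consecutive sample pair).
#' @param path Output path.
#' @param cap Optional fixed scale endpoint (see [lfc_colour()]).
#' @return `path`, invisibly.
#' @export
write_bandage_csv <- function(graph, lfc, step_pair, path, cap = NULL) {
  stopifnot(inherits(graph, "collapsed_graph"), inherits(lfc, "lfc_table"))
  if (step_pair < 1 || step_pair > nrow(lfc$node_lfc)) {
    stop("step_pair out of range: ", step_pair)
  }
  vals <- lfc$node_lfc[step_pair, graph$nodes$id]
  cols <- lfc_colour(vals, cap)
  names(cols) <- graph$nodes$id
  segs <- names(graph$members)
  lines <- c("Name,Colour",
             paste(segs, cols[unname(graph$members[segs])], sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Dump a coverage or lfc matrix as TSV
#'
#' Writes a `[row-label x item]` matrix (node coverage, edge counts, or
#' lfc) as item-per-row TSV with one column per sample / step pair.
#'
#' @param mat Matrix with dimnames.
#' @param path Output path.
#' @param id_col Name of the first column (default `"node"`).
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path, id_col = "node") {
  df <- data.frame(id = colnames(mat), t(mat), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
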