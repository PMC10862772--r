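#' Log-fold-change tables between consecutive samples
#'
#' For each consecutive step pair (sample n-1 -> n) computes the per-node
#' log ratio of normalized coverage and the per-edge log ratio of traversal
#' counts. Edge counts are floored at the configured floor before the
#' ratio so the log is always defined (node coverage is already floored by
#' [coverage_table()]).
#'
#' @param cov A `coverage_table`.
#' @return An object of class `lfc_table`: list with `node_lfc` (matrix
#'   step-pair x node), `edge_lfc` (matrix step-pair x edge), `config` and
#'   `graph`. Step pair p is the change from sample p to sample p+1; row
#'   names are `"<from>-><to>"`.
#' @export
lfc_table <- function(cov) {
  stopifnot(inherits(cov, "coverage_table"))
  structure(
    list(node_lfc = node_lfc(cov), edge_lfc = edge_lfc(cov),
         config = cov$config, graph = cov$graph),
    class = "lfc_table"
  )
}

step_ratio_log <- function(mat, log_base) {
  n_s <- nrow(mat)
  out <- log(mat[-1, , drop = FALSE] / mat[-n_s, , drop = FALSE],
             base = log_base)
  rownames(out) <- paste0(rownames(mat)[-n_s], "->", rownames(mat)[-1])
  out
}

#' Per-node log-fold-change matrix
#'
#' @param cov A `coverage_table` (node coverage floored and normalized).
#' @return Matrix `[step-pair x node]` of log(cov_n / cov_(n-1)) in the
#'   configured base.
#' @export
node_lfc <- function(cov) {
  stopifnot(inherits(cov, "coverage_table"))
  if (any(cov$node_cov <= 0)) {
    stop("non-positive node coverage: floor contract violated")
  }
  step_ratio_log(cov$node_cov, cov$config$log_base)
}

#' Per-edge log-fold-change matrix
#'
#' Traversal counts are floored (default 1) before the ratio, mirroring the
#' node coverage floor, so edges absent in a sample contribute a defined
#' (not infinite) fold change.
#'
#' @param cov A `coverage_table`.
#' @return Matrix `[step-pair x edge]`.
#' @export
edge_lfc <- function(cov) {
  stopifnot(inherits(cov, "coverage_table"))
  ec <- floor_coverage(cov$edge_cov, cov$config$floor_value)
  step_ratio_log(ec, cov$config$log_base)
}
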