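#' Parse a GAF read-to-graph alignment file
#'
#' Reads tab-separated GAF records (as produced by minigraph when reads are
#' aligned back to the coassembly graph). The column-6 path uses the
#' `>seg` / `<seg` orientation syntax. Records whose path is `*`
#' (unmapped) are skipped; the skipped count is attached as an attribute
#' and reported via a message.
#'
#' @param path Path to a GAF file.
#' @param min_mapq Drop records with mapping quality below this (default 0,
#'   i.e. keep everything).
#' @param min_length Drop records with read length below this (default 0).
#' @return A data.frame of class `gaf_alignments` with columns `read_id`,
#'   `read_length`, `path_length`, `path_start`, `path_end` (0-based
#'   half-open offsets on the concatenated path), `residue_matches`,
#'   `mapq`, and list-columns `path_segs` / `path_orients` (orientation is
#'   `"+"` or `"-"`). Attribute `n_skipped` counts unmapped records;
#'   attribute `n_filtered` counts records removed by the quality/length
#'   filters.
#' @export
parse_gaf <- function(path, min_mapq = 0, min_length = 0) {
  if (!file.exists(path)) stop("GAF file not found: ", path)
  dt <- tryCatch(
    data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                      colClasses = "character"),
    error = function(e) stop("failed to read GAF ", path, ": ",
                             conditionMessage(e))
  )
  if (nrow(dt) == 0) {
    out <- empty_gaf()
    attr(out, "n_skipped") <- 0L
    attr(out, "n_filtered") <- 0L
    return(out)
  }
  if (ncol(dt) < 12) stop("GAF ", path, " has fewer than 12 columns")
  paths <- dt[[6]]
  unmapped <- paths == "*" | paths == ""
  n_skipped <- sum(unmapped)
  if (n_skipped > 0) {
    message(n_skipped, " unmapped GAF record(s) skipped in ", basename(path))
    dt <- dt[!unmapped]
    paths <- dt[[6]]
  }
  bad <- !grepl("^[><]", paths)
  if (any(bad)) {
    stop("GAF path without '>'/'<' orientation syntax at record ",
         which(bad)[1], " of ", path, ": ", paths[which(bad)[1]])
  }
  toks <- regmatches(paths, gregexpr("[><][^><]+", paths))
  path_orients <- lapply(toks, function(x)
    ifelse(substring(x, 1, 1) == ">", "+", "-"))
  path_segs <- lapply(toks, function(x) substring(x, 2))
  out <- data.frame(
    read_id = dt[[1]],
    read_length = as.integer(dt[[2]]),
    path_length = as.integer(dt[[7]]),
    path_start = as.integer(dt[[8]]),
    path_end = as.integer(dt[[9]]),
    residue_matches = as.integer(dt[[10]]),
    mapq = as.integer(dt[[12]]),
    stringsAsFactors = FALSE
  )
  out$path_segs <- path_segs
  out$path_orients <- path_orients
  ok <- with(out, path_start >= 0 & path_start < path_end &
               path_end <= path_length)
  if (!all(ok)) {
    stop("GAF record ", which(!ok)[1], " of ", path,
         " violates 0 <= path_start < path_end <= path_length")
  }
  keep <- out$mapq >= min_mapq & out$read_length >= min_length
  n_filtered <- sum(!keep)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gaf_alignments", "data.frame")
  attr(out, "n_skipped") <- as.integer(n_skipped)
  attr(out, "n_filtered") <- as.integer(n_filtered)
  out
}

empty_gaf <- function() {
  out <- data.frame(
    read_id = character(), read_length = integer(), path_length = integer(),
    path_start = integer(), path_end = integer(),
    residue_matches = integer(), mapq = integer(), stringsAsFactors = FALSE
  )
  out$path_segs <- list()
  out$path_orients <- list()
  class(out) <- c("gaf_alignments", "data.frame")
  out
}
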