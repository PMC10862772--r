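#' Parse a GFA 1.0 assembly graph
#'
#' Reads the S (segment) and L (link) records of a GFA 1.0 file, as emitted
#' by long-read metagenome assemblers. Segments may omit their sequence
#' (`*`) provided they carry an `LN:i:` length tag. Record types other than
#' H/S/L are ignored with a warning.
#'
#' @param path Path to a GFA 1.0 file.
#' @return An object of class `assembly_graph`: a list with
#'   `segments` (data.frame: `name`, `length`, `sequence` — `NA` when the
#'   record carried `*`) and `links` (data.frame: `from`, `from_orient`,
#'   `to`, `to_orient`).
#' @seealso [write_gfa()], [collapse_graph()]
#' @export
parse_gfa <- function(path) {
  if (!file.exists(path)) stop("GFA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  seg_name <- character()
  seg_len <- integer()
  seg_seq <- character()
  lk <- list()
  ignored <- 0L
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(line)) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    rec <- f[[1]]
    if (rec == "H") next
    if (rec == "S") {
      if (length(f) < 3) {
        stop("malformed S record at line ", i, " of ", path)
      }
      name <- f[[2]]
      seqn <- f[[3]]
      if (seqn == "*") {
        ln <- grep("^LN:i:", f[-(1:3)], value = TRUE)
        if (length(ln) == 0) {
          stop("segment '", name, "' at line ", i,
               " has no sequence and no LN:i: tag")
        }
        len <- as.integer(sub("^LN:i:", "", ln[[1]]))
        seqn <- NA_character_
      } else {
        len <- nchar(seqn)
      }
      if (is.na(len) || len < 1L) {
        stop("segment '", name, "' at line ", i, " has invalid length")
      }
      seg_name <- c(seg_name, name)
      seg_len <- c(seg_len, len)
      seg_seq <- c(seg_seq, seqn)
    } else if (rec == "L") {
      if (length(f) < 5 || !f[[3]] %in% c("+", "-") || !f[[5]] %in% c("+", "-")) {
        stop("malformed L record at line ", i, " of ", path)
      }
      lk[[length(lk) + 1L]] <- c(f[[2]], f[[3]], f[[4]], f[[5]])
    } else {
      ignored <- ignored + 1L
    }
  }
  if (ignored > 0L) {
    warning(ignored, " non-H/S/L GFA record(s) ignored in ", basename(path))
  }
  if (anyDuplicated(seg_name)) {
    stop("duplicate segment name(s) in ", path, ": ",
         paste(unique(seg_name[duplicated(seg_name)]), collapse = ", "))
  }
  segments <- data.frame(
    name = seg_name, length = seg_len, sequence = seg_seq,
    stringsAsFactors = FALSE
  )
  if (length(lk) > 0) {
    m <- do.call(rbind, lk)
    links <- data.frame(
      from = m[, 1], from_orient = m[, 2], to = m[, 3], to_orient = m[, 4],
      stringsAsFactors = FALSE
    )
  } else {
    links <- data.frame(
      from = character(), from_orient = character(),
      to = character(), to_orient = character(), stringsAsFactors = FALSE
    )
  }
  bad <- setdiff(unique(c(links$from, links$to)), segments$name)
  if (length(bad) > 0) {
    stop("L record(s) reference unknown segment(s): ",
         paste(bad, collapse = ", "))
  }
  structure(list(segments = segments, links = links),
            class = "assembly_graph")
}

#' Write an assembly graph back to GFA 1.0
#'
#' Inverse of [parse_gfa()] up to record order and tags: segments without a
#' stored sequence are written as `*` with an `LN:i:` tag; all links get a
#' `0M` overlap.
#'
#' @param graph An `assembly_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gfa <- function(graph, path) {
  stopifnot(inherits(graph, "assembly_graph"))
  s <- graph$segments
  s_lines <- ifelse(
    is.na(s$sequence),
    sprintf("S\t%s\t*\tLN:i:%d", s$name, s$length),
    sprintf("S\t%s\t%s", s$name, s$sequence)
  )
  l <- graph$links
  l_lines <- if (nrow(l)) {
    sprintf("L\t%s\t%s\t%s\t%s\t0M", l$from, l$from_orient, l$to, l$to_orient)
  } else character()
  writeLines(c("H\tVN:Z:1.0", s_lines, l_lines), path)
  invisible(path)
}

#' @export
print.assembly_graph <- function(x, ...) {
  cat("assembly_graph:", nrow(x$segments), "segments,",
      nrow(x$links), "links\n")
  invisible(x)
}
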