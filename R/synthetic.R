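#' Configuration for a synthetic graph fixture
#'
#' Describes a desk-scale synthetic dataset: a collapsed-style assembly
#' graph of per-genome backbone chains with implanted SV motifs, per-sample
#' genome abundances, and GAF read paths realizing the requested node
#' depths and edge traversal counts. Fixtures are graph-level: no
#' sequences, no base-calling error model, no assembler in the loop —
#' exactly the inputs the caller consumes.
#'
#' @param seed Integer seed fixing all randomness.
#' @param n_samples Number of samples in the series (>= 2).
#' @param events data.frame with columns `sv_type` (one of `insertion`,
#'   `deletion`, `complex_indel`, `tandem_duplication`), `step_pair`
#'   (1-based index of the consecutive pair the event falls between),
#'   `fold` (> 1; the abundance fold change of the variant), and optional
#'   `genome` (default 1) and `motif` (for tandem duplications:
#'   `"self_loop"` or `"parallel_edge"`, default self-loop).
#' @param n_genomes Number of independent genome backbones.
#' @param abundances Matrix `[n_samples x n_genomes]` of relative genome
#'   abundances (default all 1). Each sample row is internally rescaled to
#'   mean 1 so depths stay on the `depth_base` scale.
#' @param depth_base Mean read depth of a genome at relative abundance 1.
#' @param node_len_range Length range (bp) for every node, drawn uniformly.
#' @param backbone_nodes Backbone chain length per genome; default sizes to
#'   the events (each event consumes one flank pair). An explicit value too
#'   small for the events is an error.
#' @param read_length Nominal read length (bp); caps the span of the
#'   junction-crossing reads that realize edge traversals.
#' @param noise_sd Multiplicative lognormal depth noise (sd on the log
#'   scale; 0 = noiseless).
#' @param label Free-text label recorded with the fixture.
#' @return An object of class `fixture_config`.
#' @export
fixture_config <- function(seed = 0, n_samples = 2, events = NULL,
                           n_genomes = 1, abundances = NULL,
                           depth_base = 20, node_len_range = c(500, 2000),
                           backbone_nodes = NULL, read_length = 1000,
                           noise_sd = 0, label = "custom") {
  if (n_samples < 2) stop("n_samples must be >= 2")
  if (is.null(events)) {
    events <- data.frame(sv_type = character(), step_pair = integer(),
                         fold = numeric(), genome = integer(),
                         motif = character(), stringsAsFactors = FALSE)
  }
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  if (nrow(events) > 0) {
    if (is.null(events$genome)) events$genome <- 1L
    if (is.null(events$motif)) events$motif <- NA_character_
    ok_types <- c("insertion", "deletion", "complex_indel",
                  "tandem_duplication")
    if (!all(events$sv_type %in% ok_types)) {
      stop("unknown sv_type in events")
    }
    if (any(events$fold <= 1)) stop("event fold changes must be > 1")
    if (any(events$step_pair < 1 | events$step_pair > n_samples - 1)) {
      stop("event step_pair out of range for ", n_samples, " samples")
    }
    if (any(events$genome < 1 | events$genome > n_genomes)) {
      stop("event genome out of range")
    }
    is_td <- events$sv_type == "tandem_duplication"
    events$motif[is_td & is.na(events$motif)] <- "self_loop"
    events$motif[!is_td] <- NA_character_
    if (!all(events$motif[is_td] %in% c("self_loop", "parallel_edge"))) {
      stop("tandem_duplication motif must be self_loop or parallel_edge")
    }
  } else {
    events$genome <- integer()
    events$motif <- character()
  }
  if (is.null(abundances)) {
    abundances <- matrix(1, nrow = n_samples, ncol = n_genomes)
  }
  abundances <- as.matrix(abundances)
  if (!all(dim(abundances) == c(n_samples, n_genomes))) {
    stop("abundances must be a [n_samples x n_genomes] matrix")
  }
  if (any(abundances <= 0)) stop("abundances must be positive")
  structure(
    list(seed = as.integer(seed), n_samples = as.integer(n_samples),
         events = events, n_genomes = as.integer(n_genomes),
         abundances = abundances, depth_base = depth_base,
         node_len_range = as.integer(node_len_range),
         backbone_nodes = backbone_nodes,
         read_length = as.integer(read_length),
         noise_sd = noise_sd, label = label),
    class = "fixture_config"
  )
}

## depth multiplier schedule of a variant node: `fold`-fold rise or drop at
## step p (samples are 1-based; step p separates samples p and p+1)
event_mult <- function(direction, fold, step, n_samples) {
  n <- seq_len(n_samples)
  if (direction == "up") ifelse(n <= step, 1 / fold, 1)
  else ifelse(n <= step, 1, 1 / fold)
}

#' Build a synthetic fixture on disk
#'
#' Writes a sequence-free GFA 1.0 graph, one GAF per sample, and a truth
#' table. Each insertion/deletion implants a triangle (a bubble: two flank
#' nodes joined directly and through a variant node whose depth changes by
#' the configured fold while the flanks follow genome abundance); each
#' complex indel implants a square (two parallel one-node paths between
#' flanks, one rising and one falling); each tandem duplication implants a
#' self-loop or a weight-2 parallel edge whose traversal count changes by
#' the fold. Reads are emitted as graph paths realizing the requested node
#' depths (within one read) and edge counts (exactly). All randomness is
#' fixed by `config$seed`; identical configs give byte-identical files.
#'
#' @param config A `fixture_config`.
#' @param dir Output directory (created; default a fresh tempdir).
#' @return List with `gfa` (path), `gafs` (paths in series order),
#'   `truth` (data.frame `sv_type`, `step_pair`, `node`, `motif`,
#'   `genome`; also written to `truth.tsv`), `sample_ids`, and `config`.
#' @export
build_fixture <- function(config, dir = tempfile("gsv_fixture_")) {
  stopifnot(inherits(config, "fixture_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  n_s <- config$n_samples
  ev <- config$events
  abund <- config$abundances
  ## per-sample rescale to mean 1 keeps depths on the depth_base scale;
  ## the caller's series normalization absorbs the resulting bp shifts
  abund_rel <- abund / rowMeans(abund)

  node_name <- character(); node_len <- integer(); node_genome <- integer()
  links <- list()
  ## depth multiplier schedules, filled per node below (default: genome)
  mults <- list()
  truth <- list()
  ## per-edge traversal schedules overriding the default depth-driven count
  dup_edges <- list()

  add_node <- function(name, genome, mult = rep(1, n_s)) {
    node_name <<- c(node_name, name)
    node_len <<- c(node_len, sample(config$node_len_range[1]:
                                      config$node_len_range[2], 1))
    node_genome <<- c(node_genome, genome)
    mults[[name]] <<- mult
  }
  add_link <- function(a, ao, b, bo) {
    links[[length(links) + 1L]] <<- c(a, ao, b, bo)
  }

  for (g in seq_len(config$n_genomes)) {
    gname <- sprintf("g%02d", g)
    ev_g <- ev[ev$genome == g, , drop = FALSE]
    e_g <- nrow(ev_g)
    k_g <- config$backbone_nodes
    if (is.null(k_g)) k_g <- max(2L * e_g + 1L, 4L)
    if (2L * e_g > k_g) {
      stop("genome ", g, ": ", e_g, " events exceed backbone capacity of ",
           k_g, " nodes")
    }
    bb <- sprintf("%sb%03d", gname, seq_len(k_g))
    for (b in bb) add_node(b, g)
    chain_cut <- logical(k_g - 1L)  # links removed for square events
    for (j in seq_len(e_g)) {
      bl <- bb[2L * j - 1L]; br <- bb[2L * j]
      ty <- ev_g$sv_type[j]; p <- ev_g$step_pair[j]; f <- ev_g$fold[j]
      if (ty %in% c("insertion", "deletion")) {
        v <- sprintf("%se%02dv", gname, j)
        add_node(v, g, event_mult(if (ty == "insertion") "up" else "down",
                                  f, p, n_s))
        add_link(bl, "+", v, "+")
        add_link(v, "+", br, "+")
        truth[[length(truth) + 1L]] <-
          data.frame(sv_type = ty, step_pair = p, node = v,
                     motif = "triangle", genome = g, stringsAsFactors = FALSE)
      } else if (ty == "complex_indel") {
        pn <- sprintf("%se%02dp", gname, j)
        qn <- sprintf("%se%02dq", gname, j)
        add_node(pn, g, event_mult("up", f, p, n_s))
        add_node(qn, g, event_mult("down", f, p, n_s))
        add_link(bl, "+", pn, "+"); add_link(pn, "+", br, "+")
        add_link(bl, "+", qn, "+"); add_link(qn, "+", br, "+")
        chain_cut[2L * j - 1L] <- TRUE  # the direct flank link is replaced
        truth[[length(truth) + 1L]] <-
          data.frame(sv_type = ty, step_pair = p,
                     node = paste(sort(c(pn, qn)), collapse = ","),
                     motif = "square", genome = g, stringsAsFactors = FALSE)
      } else {  # tandem_duplication
        motif <- ev_g$motif[j]
        c0 <- max(2, round(config$depth_base * abund_rel[p, g] / 4))
        sched <- ifelse(seq_len(n_s) <= p, c0, round(c0 * f))
        if (motif == "self_loop") {
          add_link(bl, "+", bl, "+")
          dup_edges[[length(dup_edges) + 1L]] <-
            list(from = bl, to = bl, counts = sched)
          truth[[length(truth) + 1L]] <-
            data.frame(sv_type = ty, step_pair = p, node = bl,
                       motif = "self_loop", genome = g,
                       stringsAsFactors = FALSE)
        } else {
          ## second, non-equivalent link makes the chain edge weight 2;
          ## the duplicated flank's own coverage doubles so it carries the
          ## greater node lfc and is the called endpoint
          add_link(bl, "-", br, "+")
          mults[[bl]] <- ifelse(seq_len(n_s) <= p, 1, 2)
          dup_edges[[length(dup_edges) + 1L]] <-
            list(from = bl, to = br, counts = sched)
          truth[[length(truth) + 1L]] <-
            data.frame(sv_type = ty, step_pair = p, node = bl,
                       motif = "parallel_edge", genome = g,
                       stringsAsFactors = FALSE)
        }
      }
    }
    for (i in seq_len(k_g - 1L)) {
      if (!chain_cut[i]) add_link(bb[i], "+", bb[i + 1L], "+")
    }
  }

  names(node_len) <- node_name
  n_nodes <- length(node_name)

  ## node depth matrix [sample x node]
  depth <- matrix(0, nrow = n_s, ncol = n_nodes,
                  dimnames = list(NULL, node_name))
  for (k in seq_len(n_nodes)) {
    depth[, k] <- config$depth_base * abund_rel[, node_genome[k]] *
      mults[[node_name[k]]]
  }
  if (config$noise_sd > 0) {
    depth <- depth * exp(matrix(stats::rnorm(n_s * n_nodes, 0,
                                             config$noise_sd),
                                nrow = n_s))
  }

  ## undirected edge pairs (collapsed view) with traversal-count schedules
  lm <- do.call(rbind, links)
  ek <- edge_key(lm[, 1], lm[, 3])
  pairs <- unique(data.frame(from = pmin(lm[, 1], lm[, 3]),
                             to = pmax(lm[, 1], lm[, 3]),
                             stringsAsFactors = FALSE))
  pairs <- pairs[order(pairs$from, pairs$to), , drop = FALSE]
  ec <- matrix(0L, nrow = n_s, ncol = nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    x <- pairs$from[r]; y <- pairs$to[r]
    ec[, r] <- pmax(1L, as.integer(round(pmin(depth[, x], depth[, y]) / 4)))
  }
  for (d in dup_edges) {
    r <- which(pairs$from == min(d$from, d$to) &
                 pairs$to == max(d$from, d$to))
    ec[, r] <- as.integer(d$counts)
  }

  ## write GFA (sequence-free, LN tags)
  ag <- structure(list(
    segments = data.frame(name = node_name, length = unname(node_len),
                          sequence = NA_character_, stringsAsFactors = FALSE),
    links = data.frame(from = lm[, 1], from_orient = lm[, 2], to = lm[, 3],
                       to_orient = lm[, 4], stringsAsFactors = FALSE)
  ), class = "assembly_graph")
  gfa_path <- file.path(dir, "graph.gfa")
  write_gfa(ag, gfa_path)

  ## emit GAF per sample
  sample_ids <- sprintf("s%d", seq_len(n_s))
  gaf_paths <- file.path(dir, sprintf("sample_%02d.gaf", seq_len(n_s)))
  for (n in seq_len(n_s)) {
    lines <- character()
    edge_bases <- stats::setNames(numeric(n_nodes), node_name)
    for (r in seq_len(nrow(pairs))) {
      x <- pairs$from[r]; y <- pairs$to[r]
      c_n <- ec[n, r]
      if (c_n < 1) next
      olap <- min(config$read_length %/% 2, 50L, node_len[[x]],
                  node_len[[y]])
      span <- 2L * olap
      pl <- node_len[[x]] + node_len[[y]]
      ps <- node_len[[x]] - olap
      ids <- sprintf("s%d_e%04d_%04d", n, r, seq_len(c_n))
      lines <- c(lines, sprintf(
        "%s\t%d\t0\t%d\t+\t>%s>%s\t%d\t%d\t%d\t%d\t%d\t60",
        ids, span, span, x, y, pl, ps, ps + span, span, span))
      edge_bases[[x]] <- edge_bases[[x]] + c_n * olap
      edge_bases[[y]] <- edge_bases[[y]] + c_n * olap
    }
    for (k in seq_len(n_nodes)) {
      nd <- node_name[k]; len <- node_len[[k]]
      target <- depth[n, k] * len - edge_bases[[nd]]
      if (target <= 0) next
      n_full <- floor(target / len)
      partial <- round(target - n_full * len)
      if (n_full > 0) {
        ids <- sprintf("s%d_n%05d_%04d", n, k, seq_len(n_full))
        lines <- c(lines, sprintf(
          "%s\t%d\t0\t%d\t+\t>%s\t%d\t0\t%d\t%d\t%d\t60",
          ids, len, len, nd, len, len, len, len))
      }
      if (partial >= 1) {
        lines <- c(lines, sprintf(
          "s%d_n%05d_part\t%d\t0\t%d\t+\t>%s\t%d\t0\t%d\t%d\t%d\t60",
          n, k, partial, partial, nd, len, partial, partial, partial))
      }
    }
    writeLines(lines, gaf_paths[n])
  }

  truth_df <- if (length(truth)) {
    do.call(rbind, truth)
  } else {
    data.frame(sv_type = character(), step_pair = integer(),
               node = character(), motif = character(), genome = integer(),
               stringsAsFactors = FALSE)
  }
  utils::write.table(truth_df, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  list(gfa = gfa_path, gafs = gaf_paths, truth = truth_df,
       sample_ids = sample_ids, config = config, dir = dir)
}

#' Fixture design emulating the HGT simulation benchmark
#'
#' Two-sample community of 20 genomes: 10 donors and 10 recipients. One
#' gene from each donor is inserted into every recipient, giving
#' 10 x 10 = 100 insertion events between the pre-transfer sample (equal
#' abundances) and the post-transfer sample (relative abundances drawn
#' uniformly from 1..5 per genome). The mutation-rate label only changes
#' inserted-sequence divergence, which a graph-level fixture does not
#' model, so it is recorded but does not alter event counts.
#'
#' @param mutation_rate_label `"m0"` or `"m30"`.
#' @param seed Integer seed.
#' @param depth_base Mean depth at relative abundance 1.
#' @return A `fixture_config` with 100 implanted insertions. The insertion
#'   fold equals `depth_base`, so each inserted gene sits at the coverage
#'   floor before the transfer — novel sequence, then rising.
#' @export
hgtsim_design <- function(mutation_rate_label = c("m0", "m30"), seed = 0,
                          depth_base = 20) {
  mutation_rate_label <- match.arg(mutation_rate_label)
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  n_genomes <- 20L  # 1..10 donors, 11..20 recipients
  abund <- rbind(rep(1, n_genomes),
                 sample(1:5, n_genomes, replace = TRUE))
  events <- data.frame(
    sv_type = "insertion",
    step_pair = 1L,
    fold = depth_base,
    genome = rep(11:20, each = 10L),
    motif = NA_character_,
    stringsAsFactors = FALSE
  )
  fixture_config(seed = seed, n_samples = 2, events = events,
                 n_genomes = n_genomes, abundances = abund,
                 depth_base = depth_base,
                 label = paste0("hgtsim-", mutation_rate_label))
}

#' Fixture design emulating the mock-community SV benchmark
#'
#' Ten genome backbones at the nominal ZymoBIOMICS composition (eight
#' bacteria at 12 relative units, two fungi at 2). Each genome receives 20
#' indels (insertion or deletion, equal odds), 10 tandem duplications (half
#' self-loop, half parallel-edge motif) and 10 complex indels — 40 events
#' per genome, 400 in total, all between the two samples. Half the genomes
#' are variant-dominated in the second sample (full fold), half carry a
#' 50/50 mix of variant and original (half fold). Event node lengths are
#' drawn from 500–2000 bp.
#'
#' @param seed Integer seed.
#' @param depth_base Mean depth at relative abundance 1.
#' @param fold_dominant Fold realized when the variant dominates at T1
#'   (default 8; mixed genomes realize half of it).
#' @return A `fixture_config` with 400 implanted events.
#' @export
zymo_design <- function(seed = 0, depth_base = 20, fold_dominant = 8) {
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  n_genomes <- 10L
  rel <- c(rep(12, 8), 2, 2)
  abund <- rbind(rel, rel)
  dominant <- seq_len(5L)  # genomes 1-5 variant-only at T1, 6-10 mixed
  ev <- list()
  for (g in seq_len(n_genomes)) {
    f <- if (g %in% dominant) fold_dominant else fold_dominant / 2
    indel_types <- sample(c("insertion", "deletion"), 20, replace = TRUE)
    td_motifs <- rep(c("self_loop", "parallel_edge"), 5)
    ev[[g]] <- data.frame(
      sv_type = c(indel_types, rep("tandem_duplication", 10),
                  rep("complex_indel", 10)),
      step_pair = 1L,
      fold = f,
      genome = g,
      motif = c(rep(NA_character_, 20), td_motifs, rep(NA_character_, 10)),
      stringsAsFactors = FALSE
    )
  }
  fixture_config(seed = seed, n_samples = 2, events = do.call(rbind, ev),
                 n_genomes = n_genomes, abundances = abund,
                 depth_base = depth_base, node_len_range = c(500L, 2000L),
                 label = "zymo")
}
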