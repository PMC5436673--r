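#' Construct a labeled directed graph
#'
#' A `hierord_graph` is a dense nonnegative weight matrix `W` together with an
#' ordered vector of unique node labels. `W[i, j] > 0` means information flows
#' from node `i` to node `j` (row = source, column = target). Connectivity
#' matrices from tract-tracing studies are binary 0/1; nonbinary positive
#' weights are accepted with a warning, since the downstream random-walk
#' transition matrix normalizes rows anyway.
#'
#' @param W square numeric matrix of nonnegative edge weights.
#' @param labels character vector of unique node labels; defaults to
#'   `rownames(W)` (or `n1 ... nN` when the matrix is unnamed).
#' @return An object of class `hierord_graph` with fields `labels` and `W`.
#' @examples
#' W <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' W["A", "B"] <- 1
#' W["B", "C"] <- 1
#' g <- directed_graph(W)
#' g
#' @export
directed_graph <- function(W, labels = NULL) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) {
    abort(
      sprintf("graph matrix must be square, got %d x %d", nrow(W), ncol(W)),
      class = "hierord_error_nonsquare"
    )
  }
  n <- nrow(W)
  if (n < 2L) {
    abort("a graph needs at least 2 nodes", class = "hierord_error_too_small")
  }
  if (is.null(labels)) {
    labels <- rownames(W) %||% sprintf("n%d", seq_len(n))
  }
  labels <- as.character(labels)
  if (length(labels) != n) {
    abort("number of labels must match matrix dimension",
      class = "hierord_error_labels"
    )
  }
  if (anyDuplicated(labels)) {
    abort(
      paste0("duplicate node labels: ",
        paste(unique(labels[duplicated(labels)]), collapse = ", ")),
      class = "hierord_error_duplicate_labels"
    )
  }
  storage.mode(W) <- "double"
  if (anyNA(W)) {
    abort("graph matrix contains missing values", class = "hierord_error_parse")
  }
  if (any(W < 0)) {
    abort("negative edge weight in graph matrix",
      class = "hierord_error_negative_weight"
    )
  }
  if (any(W > 0 & W != 1)) {
    warn("graph has nonbinary positive weights; they are used as-is")
  }
  dimnames(W) <- list(labels, labels)
  structure(list(labels = labels, W = W), class = "hierord_graph")
}

#' @export
print.hierord_graph <- function(x, ...) {
  cnt <- graph_counts(x)
  cat(sprintf(
    "<hierord_graph> %d nodes, %d directed connections (%d connected pairs)\n",
    length(x$labels), cnt$n_directed, cnt$n_pairs
  ))
  cat("labels:", paste(head(x$labels, 8L), collapse = ", "),
      if (length(x$labels) > 8L) "..." else "", "\n")
  invisible(x)
}

#' Count connections in a directed graph
#'
#' Reports both conventions for counting "connections": the number of nonzero
#' off-diagonal entries of `W` (directed), and the number of unordered node
#' pairs joined by at least one edge in either direction.
#'
#' @param g a [directed_graph()].
#' @return A one-row tibble with columns `n_nodes`, `n_directed`, `n_pairs`.
#' @export
graph_counts <- function(g) {
  stopifnot(inherits(g, "hierord_graph"))
  W <- g$W
  diag(W) <- 0
  conn <- W > 0
  tibble::tibble(
    n_nodes = length(g$labels),
    n_directed = sum(conn),
    n_pairs = sum((conn | t(conn))[upper.tri(conn)])
  )
}

#' Edge-list view of a graph
#'
#' @param x a [directed_graph()].
#' @param ... unused.
#' @return A tibble with columns `from`, `to`, `weight`, one row per directed
#'   edge, in row-major matrix order.
#' @method as_tibble hierord_graph
#' @export
as_tibble.hierord_graph <- function(x, ...) {
  idx <- which(t(x$W) > 0, arr.ind = TRUE) # transpose for row-major order
  tibble::tibble(
    from = x$labels[idx[, "col"]],
    to = x$labels[idx[, "row"]],
    weight = x$W[cbind(idx[, "col"], idx[, "row"])]
  )
}

guess_delim <- function(line) if (grepl("\t", line)) "\t" else ","

#' Read a directed graph from delimited text
#'
#' Two dialects are supported. `"matrix"`: a comma- or tab-delimited square
#' matrix whose first row and first column hold node labels; the row label is
#' the source and the column label the target. `"edgelist"`: two or three
#' whitespace/comma/tab-separated columns per line (`source target [weight]`);
#' nodes are created in first-appearance order and missing weights default
#' to 1.
#'
#' @param path path to the file.
#' @param format `"matrix"` or `"edgelist"`.
#' @param delim field delimiter for the matrix dialect; guessed from the
#'   header line (tab if present, else comma) when `NULL`.
#' @return A [directed_graph()].
#' @export
read_graph <- function(path, format = c("matrix", "edgelist"), delim = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(sprintf("graph file not found: %s", path),
      class = "hierord_error_io"
    )
  }
  if (format == "matrix") {
    first <- readLines(path, n = 1L)
    delim <- delim %||% guess_delim(first)
    df <- utils::read.table(path,
      sep = delim, header = TRUE, row.names = 1L,
      check.names = FALSE, stringsAsFactors = FALSE, comment.char = ""
    )
    M <- as.matrix(df)
    if (!is.numeric(M)) {
      abort("matrix dialect: non-numeric entries", class = "hierord_error_parse")
    }
    if (nrow(M) != ncol(M)) {
      abort(
        sprintf("matrix dialect: %d rows but %d columns", nrow(M), ncol(M)),
        class = "hierord_error_nonsquare"
      )
    }
    if (!identical(rownames(M), colnames(M))) {
      abort("matrix dialect: row labels differ from column labels",
        class = "hierord_error_parse"
      )
    }
    directed_graph(M)
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) {
      abort("edge list is empty", class = "hierord_error_parse")
    }
    parts <- strsplit(trimws(lines), "[,\t ]+")
    nfield <- lengths(parts)
    bad <- which(nfield < 2L | nfield > 3L)
    if (length(bad) > 0L) {
      abort(
        sprintf("edge list line %d: expected 2 or 3 fields, got %d",
          bad[1L], nfield[bad[1L]]),
        class = "hierord_error_parse"
      )
    }
    from <- vapply(parts, `[[`, "", 1L)
    to <- vapply(parts, `[[`, "", 2L)
    w <- vapply(seq_along(parts), function(i) {
      if (nfield[i] == 3L) {
        v <- suppressWarnings(as.numeric(parts[[i]][3L]))
        if (is.na(v)) {
          abort(sprintf("edge list line %d: unparseable weight '%s'",
            i, parts[[i]][3L]), class = "hierord_error_parse")
        }
        v
      } else 1
    }, numeric(1))
    labels <- unique(as.vector(rbind(from, to)))
    n <- length(labels)
    W <- matrix(0, n, n, dimnames = list(labels, labels))
    W[cbind(from, to)] <- w
    directed_graph(W)
  }
}

#' Write a graph as a labeled matrix
#'
#' Inverse of the matrix dialect of [read_graph()].
#'
#' @param g a [directed_graph()].
#' @param path output path.
#' @param delim field delimiter (default tab).
#' @export
write_graph <- function(g, path, delim = "\t") {
  stopifnot(inherits(g, "hierord_graph"))
  df <- as.data.frame(g$W, check.names = FALSE)
  utils::write.table(df, path,
    sep = delim, quote = FALSE,
    col.names = NA, row.names = TRUE
  )
  invisible(path)
}

#' Extract an induced subgraph
#'
#' Returns the principal submatrix on `keep`, preserving the order of `keep`.
#' This is how a subsystem (e.g. the 16 somatosensory-motor areas of a
#' 47-area cortical matrix) is carved out of a larger connectivity matrix.
#'
#' @param g a [directed_graph()].
#' @param keep character vector of labels to retain, all present in `g`.
#' @return A [directed_graph()] on `keep`.
#' @export
induced_subgraph <- function(g, keep) {
  stopifnot(inherits(g, "hierord_graph"))
  keep <- as.character(keep)
  missing <- setdiff(keep, g$labels)
  if (length(missing) > 0L) {
    abort(
      paste0("labels not in graph: ", paste(missing, collapse = ", ")),
      class = "hierord_error_unknown_label"
    )
  }
  directed_graph(g$W[keep, keep, drop = FALSE], labels = keep)
}

#' Read a node-level table
#'
#' Two-column delimited text mapping node labels to hierarchy levels, with a
#' header row. Used for reference hierarchies and for anchor files.
#'
#' @param path path to a 2-column TSV/CSV (`label`, `level`).
#' @return A tibble with character `label` and numeric `level`.
#' @export
read_levels <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("level file not found: %s", path), class = "hierord_error_io")
  }
  first <- readLines(path, n = 1L)
  delim <- guess_delim(first)
  tb <- readr::read_delim(path,
    delim = delim, show_col_types = FALSE,
    col_types = readr::cols(
      readr::col_character(), readr::col_double(),
      .default = readr::col_skip()
    )
  )
  names(tb)[1:2] <- c("label", "level")
  if (anyDuplicated(tb$label)) {
    abort("duplicate labels in level table",
      class = "hierord_error_duplicate_labels"
    )
  }
  tb
}

#' Write a node-level table
#'
#' Writes a two-column tab-delimited file (`label`, `level`) with a header
#' row, one row per node in the order given; [read_levels()] on the result
#' reproduces the table.
#'
#' @param levels a data frame with columns `label` and `level`.
#' @param path output path.
#' @export
write_levels <- function(levels, path) {
  levels <- as_level_table(levels, allow_empty = TRUE)
  readr::write_tsv(levels[, c("label", "level")], path)
  invisible(path)
}

# Coerce data frames / named vectors to the canonical (label, level) tibble.
as_level_table <- function(x, allow_empty = FALSE) {
  if (is.numeric(x) && !is.null(names(x))) {
    x <- tibble::tibble(label = names(x), level = as.numeric(x))
  }
  if (!is.data.frame(x)) {
    abort("expected a data frame with columns label and level",
      class = "hierord_error_levels"
    )
  }
  x <- tibble::as_tibble(x)
  if (!all(c("label", "level") %in% names(x))) {
    if (ncol(x) >= 2L) names(x)[1:2] <- c("label", "level")
    else abort("level table needs columns label and level",
      class = "hierord_error_levels")
  }
  if (!allow_empty && nrow(x) == 0L) {
    abort("level table is empty", class = "hierord_error_levels")
  }
  x$label <- as.character(x$label)
  x$level <- as.numeric(x$level)
  if (anyDuplicated(x$label)) {
    abort("duplicate labels in level table",
      class = "hierord_error_duplicate_labels"
    )
  }
  x
}

#' Validate an anchor set against a graph
#'
#' Anchors are nodes whose hierarchy level is fixed before optimization
#' (e.g. the primary visual area at level 0). Every anchored label must exist
#' in the graph and every fixed level must lie in `[0, K]`.
#'
#' @param anchors data frame (`label`, `level`), named numeric vector, or a
#'   string `"LABEL=LEVEL,LABEL=LEVEL"`.
#' @param g a [directed_graph()].
#' @param K maximum hierarchy level.
#' @return A validated tibble with columns `label` and `level`.
#' @export
validate_anchors <- function(anchors, g, K) {
  if (is.character(anchors) && length(anchors) == 1L && grepl("=", anchors)) {
    kv <- strsplit(strsplit(anchors, ",")[[1L]], "=")
    anchors <- tibble::tibble(
      label = trimws(vapply(kv, `[[`, "", 1L)),
      level = as.numeric(vapply(kv, `[[`, "", 2L))
    )
  }
  anchors <- as_level_table(anchors)
  missing <- setdiff(anchors$label, g$labels)
  if (length(missing) > 0L) {
    abort(
      paste0("anchored labels not in graph: ", paste(missing, collapse = ", ")),
      class = "hierord_error_unknown_label"
    )
  }
  out_of_range <- anchors$level < 0 | anchors$level > K
  if (any(out_of_range)) {
    abort(
      sprintf("anchor level outside [0, %g] for: %s", K,
        paste(anchors$label[out_of_range], collapse = ", ")),
      class = "hierord_error_anchor_range"
    )
  }
  anchors
}

#' Fraction of pairwise relationships covered by a set of anchors
#'
#' When a node's level is fixed, the pairwise hierarchical relationships it
#' participates in (one per connected neighbour) become known. This reports
#' how much of the total pairwise information the anchors account for, under
#' both connection-counting conventions (directed entries and connected
#' pairs).
#'
#' @param g a [directed_graph()].
#' @param anchor_labels character vector of anchored node labels.
#' @return One-row tibble with counts and percentage fractions.
#' @export
anchor_fraction <- function(g, anchor_labels) {
  stopifnot(inherits(g, "hierord_graph"))
  anchor_labels <- as.character(anchor_labels)
  missing <- setdiff(anchor_labels, g$labels)
  if (length(missing) > 0L) {
    abort(
      paste0("labels not in graph: ", paste(missing, collapse = ", ")),
      class = "hierord_error_unknown_label"
    )
  }
  W <- g$W
  diag(W) <- 0
  conn <- W > 0
  idx <- g$labels %in% anchor_labels
  touch <- outer(idx, idx, `|`)
  pairs <- conn | t(conn)
  tibble::tibble(
    n_directed = sum(conn),
    n_directed_anchored = sum(conn & touch),
    frac_directed = 100 * sum(conn & touch) / sum(conn),
    n_pairs = sum(pairs[upper.tri(pairs)]),
    n_pairs_anchored = sum((pairs & touch)[upper.tri(pairs)]),
    frac_pairs = 100 * sum((pairs & touch)[upper.tri(pairs)]) /
      sum(pairs[upper.tri(pairs)])
  )
}
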