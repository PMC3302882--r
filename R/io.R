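#' Read a numeric matrix from delimited text
#'
#' Accepts CSV or TSV (delimiter guessed from the extension or the first
#' line), with optional header row and optional row-name column.
#'
#' @param path File path.
#' @param header Does the first line name the columns? `NA` (default) treats
#'   a non-numeric first line as a header.
#' @return A numeric matrix with any row names attached.
#' @export
read_matrix <- function(path, header = NA) {
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else " "
  if (is.na(header)) {
    fields <- strsplit(first, delim, fixed = TRUE)[[1L]]
    header <- anyNA(suppressWarnings(as.numeric(fields[-1L])))
  }
  df <- as.data.frame(suppressMessages(readr::read_delim(
    path,
    delim = delim, col_names = header,
    show_col_types = FALSE, progress = FALSE
  )))
  rn <- NULL
  if (ncol(df) > 1L && !is.numeric(df[[1L]])) {
    rn <- as.character(df[[1L]])
    df <- df[, -1L, drop = FALSE]
  }
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("matrix entries must be numeric", call. = FALSE)
  rownames(m) <- rn
  m
}

#' Write the artifacts of a DBHT fit to a directory
#'
#' Emits the standard run outputs: cluster labels (TSV), the dendrogram in
#' Newick form with branch lengths from merge heights, the merge table, the
#' PMFG edge list, the directed bubble tree, and a JSON run report with the
#' input hash, level offsets and package version, sufficient to re-execute
#' the run bit-exactly.
#'
#' @param fit A `dbht` object.
#' @param dir Output directory (created if needed).
#' @param graphml Also write the PMFG as GraphML.
#' @return Invisibly, the paths written.
#' @export
write_dbht <- function(fit, dir, graphml = FALSE) {
  stopifnot(inherits(fit, "dbht"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    labels = file.path(dir, "labels.tsv"),
    newick = file.path(dir, "dendrogram.nwk"),
    merges = file.path(dir, "merges.tsv"),
    edges = file.path(dir, "pmfg_edges.tsv"),
    bubbles = file.path(dir, "bubble_tree.tsv"),
    report = file.path(dir, "report.json")
  )
  readr::write_tsv(tidy(fit)[, c("element", "cluster")], paths[["labels"]])

  hc <- fit$hierarchy
  ape::write.tree(ape::as.phylo(hc), file = paths[["newick"]])

  merges <- tibble::tibble(
    left = hc$merge[, 1L], right = hc$merge[, 2L],
    height = hc$height,
    size = merge_sizes(hc$merge),
    level = attr(hc, "merge_level")
  )
  readr::write_tsv(merges, paths[["merges"]])

  edges <- fit$pmfg$edges
  edges$from <- fit$labels[edges$i]
  edges$to <- fit$labels[edges$j]
  readr::write_tsv(edges[, c("from", "to", "w", "d")], paths[["edges"]])

  dt <- fit$directed_tree
  bt_tbl <- dt$links
  if (nrow(bt_tbl)) {
    bt_tbl$clique <- vapply(
      bt_tbl$clique,
      function(k) paste(fit$labels[k], collapse = ","), character(1)
    )
    bt_tbl$kind_a <- dt$kind[bt_tbl$a]
    bt_tbl$kind_b <- dt$kind[bt_tbl$b]
  }
  readr::write_tsv(bt_tbl, paths[["bubbles"]])

  report <- list(
    package_version = as.character(utils::packageVersion("dbht")),
    n = fit$n,
    recipe = fit$recipe,
    dissimilarity = "sqrt(2 (1 - w)) for the pearson recipe; euclidean otherwise",
    n_clusters = max(fit$clusters$labels),
    level_offsets = as.list(attr(hc, "level_offsets")),
    tie_merges = dt$merged,
    input_hash = input_hash(fit)
  )
  jsonlite::write_json(report, paths[["report"]],
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )

  if (graphml) {
    p <- file.path(dir, "pmfg.graphml")
    igraph::write_graph(pmfg_igraph(fit$pmfg), p, format = "graphml")
    paths <- c(paths, graphml = p)
  }
  invisible(paths)
}

#' @noRd
merge_sizes <- function(merge) {
  sz <- integer(nrow(merge))
  for (r in seq_len(nrow(merge))) {
    sz[r] <- sum(vapply(merge[r, ], function(id) {
      if (id < 0L) 1L else sz[id]
    }, integer(1)))
  }
  sz
}

#' @noRd
input_hash <- function(fit) {
  # dependency-free content hash (djb2 over the serialized edge table)
  bytes <- as.integer(serialize(fit$pmfg$edges, NULL))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Write cluster labels as a two-column TSV
#'
#' @param labels Named vector of cluster memberships (names = elements).
#' @param path Output file.
#' @export
write_labels <- function(labels, path) {
  readr::write_tsv(
    tibble::tibble(
      element = names(labels) %||% as.character(seq_along(labels)),
      cluster = as.vector(labels)
    ),
    path
  )
}

#' @importFrom rlang %||%
NULL
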