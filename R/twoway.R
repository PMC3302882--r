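#' Two-way DBHT clustering of samples and genes
#'
#' Applies DBHT independently to the rows and to the columns of an
#' expression matrix (both with the Pearson recipe, which is invariant to
#' per-row standardization) and cross-tabulates the two partitions by mean
#' expression. Because the method is deterministic and parameter-free, the
#' two ways need no separate tuning.
#'
#' @param x Numeric matrix; rows are one way (e.g. genes), columns the
#'   other (e.g. samples).
#' @return An object of class `dbht_two_way`: `rows` and `cols` (two `dbht`
#'   fits), and `cross_tab`, a tibble of mean expression per row-cluster x
#'   column-cluster cell.
#' @examples
#' x <- nested_benchmark(1, sizes = list(c(8, 8)), rho = 0.8, t_len = 64)$data
#' tw <- dbht_two_way(x)
#' dim(tw$cross_tab)
#' @export
dbht_two_way <- function(x) {
  x <- as.matrix(x)
  rows <- dbht(x, similarity = "pearson")
  cols <- dbht(t(x), similarity = "pearson")
  rl <- rows$clusters$labels
  cl <- cols$clusters$labels
  cells <- expand.grid(
    row_cluster = sort(unique(rl)),
    col_cluster = sort(unique(cl))
  )
  cells$mean_expression <- vapply(seq_len(nrow(cells)), function(r) {
    mean(x[rl == cells$row_cluster[r], cl == cells$col_cluster[r], drop = FALSE])
  }, numeric(1))
  structure(
    list(
      rows = rows, cols = cols,
      cross_tab = tibble::as_tibble(cells)
    ),
    class = "dbht_two_way"
  )
}

#' @export
print.dbht_two_way <- function(x, ...) {
  cat(
    "Two-way DBHT:", max(x$rows$clusters$labels), "row-clusters x",
    max(x$cols$clusters$labels), "column-clusters\n"
  )
  invisible(x)
}
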