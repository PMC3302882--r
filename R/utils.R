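#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the RNG seeded at `seed` and restores the caller's RNG
#' state afterwards, so generators are reproducible without clobbering the
#' session stream. A `NULL` seed leaves the RNG untouched.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Default element labels for an n-element problem
#' @noRd
default_labels <- function(n, labels = NULL) {
  if (!is.null(labels)) {
    if (length(labels) != n) stop("labels must have length ", n, call. = FALSE)
    return(as.character(labels))
  }
  sprintf("v%d", seq_len(n))
}

#' Validate a square symmetric matrix; symmetrize by averaging within tolerance
#'
#' Symmetry tolerance is 1e-8 * max(|x|); beyond that the input is rejected.
#' @noRd
check_symmetric <- function(x, what = "matrix") {
  x <- as.matrix(x)
  if (nrow(x) != ncol(x)) {
    stop(what, " must be square", call. = FALSE)
  }
  if (!is.numeric(x) || anyNA(x)) {
    stop(what, " must be numeric without missing values", call. = FALSE)
  }
  tol <- 1e-8 * max(abs(x), 1e-300)
  if (max(abs(x - t(x))) > tol) {
    stop(what, " is not symmetric within tolerance", call. = FALSE)
  }
  (x + t(x)) / 2
}

#' Adjacency list (neighbours per vertex) from an edge table
#' @noRd
adjacency_list <- function(n, edges) {
  adj <- vector("list", n)
  for (v in seq_len(n)) adj[[v]] <- integer(0)
  for (r in seq_len(nrow(edges))) {
    i <- edges$i[r]
    j <- edges$j[r]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  lapply(adj, sort)
}

#' Connected components of the subgraph induced on `keep`
#'
#' Returns a list of integer vectors (vertex ids in the original numbering).
#' @noRd
induced_components <- function(adj, keep) {
  keep <- sort(keep)
  inset <- logical(length(adj))
  inset[keep] <- TRUE
  seen <- logical(length(adj))
  comps <- list()
  for (s in keep) {
    if (seen[s]) next
    queue <- s
    seen[s] <- TRUE
    comp <- integer(0)
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      comp <- c(comp, v)
      nb <- adj[[v]]
      nb <- nb[inset[nb] & !seen[nb]]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}
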