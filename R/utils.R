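# Internal helpers shared across modules.

# Topological order of `nodes` under `parents`, or NULL if cyclic.
topoSortOrNull <- function(nodes, parents) {
  indeg <- vapply(nodes, function(v) length(parents[[v]]), integer(1))
  children <- setNames(vector("list", length(nodes)), nodes)
  for (v in nodes) for (p in parents[[v]]) children[[p]] <- c(children[[p]], v)
  queue <- sort(nodes[indeg == 0L])
  out <- character(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    out <- c(out, v)
    for (ch in children[[v]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- sort(c(queue, ch))
    }
  }
  if (length(out) == length(nodes)) out else NULL
}

#' Canonical key for a parent set
#'
#' Sorted, semicolon-joined gene symbols; the empty set maps to `"{}"`
#' (an empty string cannot name a vector element in R). Used as the
#' lookup key inside a [LocalScoreTable-class].
#'
#' @param parents character vector of gene symbols.
#' @return length-1 character key.
#' @export
parentSetKey <- function(parents) {
  if (length(parents) == 0L) return("{}")
  paste(sort(parents), collapse = ";")
}

# Row index vector (1-based) of the parent configurations realized in
# `mat` for the given parent columns; parents[1] is the least-significant
# bit. Zero parents -> all ones.
encodeConfigs <- function(mat, parents) {
  if (length(parents) == 0L) return(rep.int(1L, nrow(mat)))
  w <- 2^(seq_along(parents) - 1L)
  as.integer(mat[, parents, drop = FALSE] %*% w) + 1L
}

# All subsets of `x` with size <= k, as a list of character vectors.
subsetsUpTo <- function(x, k) {
  out <- list(character(0))
  for (size in seq_len(min(k, length(x)))) {
    cmb <- utils::combn(x, size, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

# TRUE if `to` is reachable from `from` by directed edges (parents map).
hasPath <- function(from, to, parents, children = NULL) {
  if (is.null(children)) {
    children <- setNames(vector("list", length(parents)), names(parents))
    for (v in names(parents)) for (p in parents[[v]])
      children[[p]] <- c(children[[p]], v)
  }
  seen <- from
  frontier <- from
  while (length(frontier)) {
    nxt <- unique(unlist(children[frontier], use.names = FALSE))
    if (to %in% nxt) return(TRUE)
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  FALSE
}

# Stage-tagged log line on stderr.
stageLog <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}
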