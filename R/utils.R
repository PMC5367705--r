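#' @keywords internal
"_PACKAGE"

# Delimiter auto-detection: tab wins if present in the header line, else comma.
detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("empty file: ", path, call. = FALSE)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

# Connected components of an undirected graph given as a 2-column edge matrix
# over the vertex set `vertices`. Returns integer component labels, 1-based,
# in order of first appearance. Degree-0 vertices form singleton components.
graph_components <- function(vertices, edges) {
  n <- length(vertices)
  idx <- seq_len(n)
  names(idx) <- vertices
  adj <- vector("list", n)
  if (nrow(edges) > 0L) {
    a <- idx[edges[, 1L]]
    b <- idx[edges[, 2L]]
    for (e in seq_along(a)) {
      adj[[a[e]]] <- c(adj[[a[e]]], b[e])
      adj[[b[e]]] <- c(adj[[b[e]]], a[e])
    }
  }
  comp <- integer(n)
  cur <- 0L
  for (v in seq_len(n)) {
    if (comp[v] > 0L) next
    cur <- cur + 1L
    queue <- v
    comp[v] <- cur
    while (length(queue)) {
      u <- queue[[1L]]
      queue <- queue[-1L]
      nb <- adj[[u]]
      new <- nb[comp[nb] == 0L]
      comp[new] <- cur
      queue <- c(queue, new)
    }
  }
  comp
}

# Numerically stable log(1 + exp(x)).
log1pexp <- function(x) {
  out <- pmax(x, 0)
  out + log1p(exp(-abs(x)))
}

# Derive a reproducible child seed below 2^31 from a base seed and an index.
child_seed <- function(seed, k) {
  s <- (as.numeric(seed) %% 97777) * 7919 + as.numeric(k) * 104729
  as.integer(s %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
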