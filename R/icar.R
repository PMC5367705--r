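#' Build the intrinsic CAR (Besag) precision structure for a county graph
#'
#' The ICAR precision is the graph Laplacian of the county adjacency:
#' \eqn{Q_{jj} = n_j} (number of neighbors) and \eqn{Q_{jk} = -1} for
#' adjacent counties. Rows sum to zero, so Q is rank-deficient with null
#' space spanned by the connected-component indicators; the prior is made
#' proper downstream by a sum-to-zero constraint per component. Isolated
#' counties (degree 0) form singleton components whose spatial effect is
#' pinned to zero.
#'
#' @param geo A `geography` object.
#' @return An object of class `icar_structure`: `counties` (order of Q),
#'   `Q` (dense matrix), `n_neighbors`, `component` (integer labels),
#'   `n_components`, `edges` (integer index 2-column matrix),
#'   `neighbors` (list of integer neighbor indices per county).
#' @export
build_icar <- function(geo) {
  stopifnot(inherits(geo, "geography"))
  counties <- geo$counties
  J <- length(counties)
  Q <- matrix(0, J, J, dimnames = list(counties, counties))
  eidx <- cbind(match(geo$edges[, 1L], counties),
                match(geo$edges[, 2L], counties))
  if (nrow(eidx)) {
    Q[eidx] <- Q[eidx] - 1
    Q[eidx[, c(2L, 1L), drop = FALSE]] <- Q[eidx[, c(2L, 1L), drop = FALSE]] - 1
  }
  diag(Q) <- unname(geo$n_neighbors[counties])
  comp <- graph_components(counties, geo$edges)
  nb <- vector("list", J)
  for (e in seq_len(nrow(eidx))) {
    a <- eidx[e, 1L]; b <- eidx[e, 2L]
    nb[[a]] <- c(nb[[a]], b)
    nb[[b]] <- c(nb[[b]], a)
  }
  structure(list(counties = counties, Q = Q,
                 n_neighbors = stats::setNames(unname(geo$n_neighbors[counties]),
                                               counties),
                 component = comp, n_components = max(comp),
                 edges = eidx, neighbors = nb),
            class = "icar_structure")
}

#' @export
print.icar_structure <- function(x, ...) {
  cat(sprintf("ICAR structure: %d counties, %d edges, %d connected component(s)\n",
              length(x$counties), nrow(x$edges), x$n_components))
  invisible(x)
}

# Draw one sample of an ICAR field over the county graph, standardized so the
# empirical SD over non-isolated counties is `scale`; isolated counties get 0.
# Uses the spectral representation of the Laplacian pseudo-inverse.
ricar <- function(icar, scale = 1) {
  J <- length(icar$counties)
  u <- numeric(J)
  if (scale <= 0) return(u)
  eg <- eigen(icar$Q, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  if (!any(pos)) return(u)
  z <- stats::rnorm(sum(pos))
  u <- drop(eg$vectors[, pos, drop = FALSE] %*% (z / sqrt(eg$values[pos])))
  # center per component, pin islands
  deg <- icar$n_neighbors
  for (cc in seq_len(icar$n_components)) {
    members <- which(icar$component == cc)
    if (length(members) == 1L && deg[members] == 0L) {
      u[members] <- 0
    } else {
      u[members] <- u[members] - mean(u[members])
    }
  }
  s <- stats::sd(u[deg > 0])
  if (is.finite(s) && s > 0) u <- u * (scale / s)
  u
}
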