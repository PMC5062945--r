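#' Solve Poiseuille hemodynamics on a vessel network
#'
#' Assigns each segment the conductance \eqn{g = \pi r^4 / (8 \mu L)} and
#' solves the nodal pressure system (flow conservation at interior nodes,
#' prescribed pressures at boundary nodes). Segment flows are stored signed
#' from -> to. Blood viscosity is constant; no radius-dependent
#' (Fahraeus-Lindqvist) correction is applied because the networks here act
#' as fixtures, not as rheology models.
#'
#' @param net A [vessel_network()].
#' @param viscosity Blood viscosity (mPa·s). Internally converted to
#'   mmHg·s (1 mPa·s = 7.5006e-6 mmHg·s).
#' @param inlet_pressure,outlet_pressure Pressures (mmHg) applied to inlet /
#'   outlet nodes whose `pressure` column is `NA`.
#' @param target_inflow Optional total inflow (µm³/s). When given, the
#'   pressure drop (relative to `outlet_pressure`) is rescaled so that the
#'   summed inlet flow matches it exactly (flow is linear in the drop).
#' @return The network with `flow_um3_s` filled and node `pressure` set.
#' @export
solve_hemodynamics <- function(net, viscosity = 4,
                               inlet_pressure = 60, outlet_pressure = 20,
                               target_inflow = NULL) {
  nodes <- net$nodes
  segs <- net$segments
  if (!any(nodes$role == "inlet") || !any(nodes$role == "outlet")) {
    stop("solve_hemodynamics: need at least one inlet and one outlet.",
         call. = FALSE)
  }
  mu <- viscosity * 7.5006e-6 # mmHg s
  len <- segment_lengths(net)
  g <- pi * segs$radius_um^4 / (8 * mu * len)
  n <- nrow(nodes)
  idx <- stats::setNames(seq_len(n), nodes$id)
  i_from <- idx[as.character(segs$from)]
  i_to <- idx[as.character(segs$to)]
  # check connectivity of the undirected graph
  comp <- .graph_components(n, i_from, i_to)
  if (length(unique(comp)) > 1) {
    has_bnd <- vapply(split(nodes$role, comp), function(r)
      any(r != "interior"), logical(1))
    if (!all(has_bnd)) {
      stop("solve_hemodynamics: disconnected components without boundary ",
           "nodes: ", paste(which(!has_bnd), collapse = ", "), call. = FALSE)
    }
  }
  p_bnd <- nodes$pressure
  is_in <- nodes$role == "inlet"
  is_out <- nodes$role == "outlet"
  p_bnd[is_in & is.na(p_bnd)] <- inlet_pressure
  p_bnd[is_out & is.na(p_bnd)] <- outlet_pressure
  fixed <- !is.na(p_bnd)
  L <- Matrix::sparseMatrix(
    i = c(i_from, i_to, i_from, i_to),
    j = c(i_from, i_to, i_to, i_from),
    x = c(g, g, -g, -g), dims = c(n, n)
  )
  free <- which(!fixed)
  P <- p_bnd
  if (length(free)) {
    rhs <- -L[free, fixed, drop = FALSE] %*% p_bnd[fixed]
    A <- L[free, free, drop = FALSE]
    sol <- tryCatch(Matrix::solve(A, rhs), error = function(e)
      stop("solve_hemodynamics: singular pressure system (check ",
           "connectivity).", call. = FALSE))
    P[free] <- as.numeric(sol)
  }
  Q <- g * (P[i_from] - P[i_to])
  if (!is.null(target_inflow)) {
    inflow <- sum(vapply(which(is_in), function(k) {
      sum(Q[i_from == k]) - sum(Q[i_to == k])
    }, numeric(1)))
    if (inflow <= 0) stop("solve_hemodynamics: nonpositive inflow; cannot ",
                          "rescale.", call. = FALSE)
    s <- target_inflow / inflow
    P <- outlet_pressure + (P - outlet_pressure) * s
    Q <- Q * s
  }
  net$nodes$pressure <- P
  net$segments$flow_um3_s <- Q
  net
}

.graph_components <- function(n, i, j) {
  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  for (k in seq_along(i)) {
    ra <- find(i[k]); rb <- find(j[k])
    if (ra != rb) parent[ra] <- rb
  }
  vapply(seq_len(n), find, integer(1))
}

#' Flow conservation residuals at interior nodes
#'
#' @param net A solved [vessel_network()].
#' @return Tibble with node `id`, net signed flow `residual` (µm³/s) and
#'   `relative` residual (net flow / total throughflow).
#' @export
flow_conservation <- function(net) {
  nodes <- net$nodes
  segs <- net$segments
  interior <- nodes$id[nodes$role == "interior"]
  res <- vapply(interior, function(k) {
    sum(segs$flow_um3_s[segs$to == k]) - sum(segs$flow_um3_s[segs$from == k])
  }, numeric(1))
  thru <- vapply(interior, function(k) {
    sum(abs(segs$flow_um3_s[segs$to == k | segs$from == k]))
  }, numeric(1))
  tibble::tibble(id = interior, residual = res,
                 relative = ifelse(thru > 0, abs(res) / thru, 0))
}
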