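#' Cell-contact graph with per-cell environment
#'
#' An undirected graph of cells in physical contact, used to couple the
#' per-cell models through juxtacrine Delta-Notch signalling, together with
#' the piecewise-constant environment of each cell: its extracellular Wnt
#' stimulus `W`, its destruction-complex multiplier `rho_APC`, and its Hes1
#' promoter balance `theta2`.
#'
#' @param cells Character vector of unique cell identifiers.
#' @param edges A two-column matrix or data.frame of cell identifiers giving
#'   the undirected contact edges (no self-loops). May have zero rows.
#' @param W,rho_APC,theta2 Per-cell environment values, recycled to the
#'   number of cells.  `NA` in `theta2` or `rho_APC` means "use the value in
#'   the parameter set".
#' @return An object of class `cell_graph` with fields `cells`,
#'   `neighbours` (named list of neighbour identifiers) and `env` (a
#'   data.frame with one row per cell).
#' @examples
#' g <- cell_graph(c("c1", "c2"), cbind("c1", "c2"), W = 1)
#' mean_neighbour_delta(g, c(c1 = 0.3, c2 = 0.7), "c1")
#' @export
cell_graph <- function(cells, edges = NULL, W = 1, rho_APC = NA_real_,
                       theta2 = NA_real_) {
  cells <- as.character(cells)
  if (anyDuplicated(cells)) stop("cell identifiers must be unique",
                                 call. = FALSE)
  nb <- stats::setNames(rep(list(character(0)), length(cells)), cells)
  if (!is.null(edges) && NROW(edges) > 0) {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2L) stop("'edges' must have two columns",
                                call. = FALSE)
    bad <- !(edges %in% cells)
    if (any(bad)) stop("edge endpoints must be declared cells",
                       call. = FALSE)
    if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed",
                                            call. = FALSE)
    for (i in seq_len(nrow(edges))) {
      a <- edges[i, 1]; b <- edges[i, 2]
      nb[[a]] <- union(nb[[a]], b)
      nb[[b]] <- union(nb[[b]], a)
    }
  }
  env <- data.frame(
    cell = cells,
    W = rep_len(as.numeric(W), length(cells)),
    rho_APC = rep_len(as.numeric(rho_APC), length(cells)),
    theta2 = rep_len(as.numeric(theta2), length(cells)),
    stringsAsFactors = FALSE
  )
  if (any(env$W < 0, na.rm = TRUE)) stop("'W' must be non-negative",
                                         call. = FALSE)
  structure(list(cells = cells, neighbours = nb, env = env),
            class = "cell_graph")
}

#' @export
print.cell_graph <- function(x, ...) {
  ne <- sum(lengths(x$neighbours)) / 2
  cat("cell_graph:", length(x$cells), "cells,", ne, "contact edges\n")
  print(x$env, row.names = FALSE)
  invisible(x)
}

#' Mean neighbouring Delta
#'
#' The juxtacrine input to a cell's Notch receptor production: the
#' arithmetic mean of the Delta ligand concentration over the cell's graph
#' neighbours.  An isolated cell receives zero (no contact signal).
#'
#' @param graph A [cell_graph()].
#' @param delta Named numeric vector of per-cell Delta concentrations (nM).
#' @param cell Cell identifier.
#' @return Mean neighbour Delta (nM).
#' @export
mean_neighbour_delta <- function(graph, delta, cell) {
  stopifnot(inherits(graph, "cell_graph"))
  if (!cell %in% graph$cells) {
    stop("unknown cell '", cell, "'", call. = FALSE)
  }
  nb <- graph$neighbours[[cell]]
  if (length(nb) == 0L) return(0)
  mean(delta[nb])
}

# Per-cell environment resolved against a parameter set: NA overrides fall
# back to the values in `params`.
resolve_env <- function(graph, params) {
  env <- graph$env
  env$rho_APC <- ifelse(is.na(env$rho_APC), params$rho_APC, env$rho_APC)
  env$theta2 <- ifelse(is.na(env$theta2), params$theta2, env$theta2)
  env
}

#' Stacked derivatives for all cells on a contact graph
#'
#' Evaluates [full_rhs()] for every cell, coupling cells through
#' [mean_neighbour_delta()].  With `homogeneous = TRUE` each cell sees its
#' own Delta (`Dbar = D`), which reduces the coupled system to independent
#' copies of the homogeneous single-cell model used in the steady-state and
#' network analyses.
#'
#' @param states A cells x 12 matrix of species concentrations with row
#'   names equal to `graph$cells`, or a named list of state vectors.
#' @param graph A [cell_graph()].
#' @param params A [crypt_params()] object.
#' @param homogeneous Logical; see above.
#' @return A cells x 12 matrix of derivatives.
#' @export
coupled_rhs <- function(states, graph, params, homogeneous = FALSE) {
  stopifnot(inherits(graph, "cell_graph"))
  states <- as_state_matrix(states, graph$cells)
  env <- resolve_env(graph, params)
  delta <- stats::setNames(states[, "D"], graph$cells)
  dbar <- if (homogeneous) {
    unname(delta)
  } else {
    vapply(graph$cells, function(cl) mean_neighbour_delta(graph, delta, cl),
           numeric(1))
  }
  rhs_matrix(states, Dbar = dbar, W = env$W, params = params,
             theta2 = env$theta2, rho_APC = env$rho_APC)
}

as_state_matrix <- function(states, cells) {
  if (is.list(states)) {
    states <- do.call(rbind, states[cells])
  }
  if (!is.matrix(states) || ncol(states) != 12L ||
      nrow(states) != length(cells)) {
    stop("'states' must be a ", length(cells), " x 12 matrix",
         call. = FALSE)
  }
  if (!is.null(rownames(states))) {
    if (!setequal(rownames(states), cells)) {
      stop("state row names must match graph cells", call. = FALSE)
    }
    states <- states[cells, , drop = FALSE]
  } else {
    rownames(states) <- cells
  }
  colnames(states) <- crypt_species()
  states
}

#' Read or write a cell graph as plain-text tables
#'
#' The graph is stored as an edge-list CSV (columns `from`, `to`; possibly
#' zero rows) plus a per-cell environment CSV (columns `cell`, `W`,
#' `rho_APC`, `theta2`).
#'
#' @param edge_path,env_path File paths for the two tables.
#' @param graph A [cell_graph()] (for writing).
#' @return `read_cell_graph()` returns a `cell_graph`.
#' @export
read_cell_graph <- function(edge_path, env_path) {
  env <- utils::read.csv(env_path, stringsAsFactors = FALSE)
  edges <- utils::read.csv(edge_path, stringsAsFactors = FALSE)
  cell_graph(env$cell,
             edges = if (nrow(edges)) as.matrix(edges[, c("from", "to")]),
             W = env$W, rho_APC = env$rho_APC, theta2 = env$theta2)
}

#' @rdname read_cell_graph
#' @export
write_cell_graph <- function(graph, edge_path, env_path) {
  stopifnot(inherits(graph, "cell_graph"))
  seen <- character(0)
  from <- character(0); to <- character(0)
  for (cl in graph$cells) {
    for (nb in graph$neighbours[[cl]]) {
      key <- paste(sort(c(cl, nb)), collapse = "|")
      if (!key %in% seen) {
        seen <- c(seen, key)
        from <- c(from, cl); to <- c(to, nb)
      }
    }
  }
  utils::write.csv(data.frame(from = from, to = to), edge_path,
                   row.names = FALSE)
  utils::write.csv(graph$env, env_path, row.names = FALSE)
  invisible(c(edge_path, env_path))
}
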