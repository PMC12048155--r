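# kNN residue graph with geometric edge attributes ----------------------

#' Graph construction configuration
#'
#' @param k Number of nearest neighbours per residue (default 20; the model
#'   grid uses 10, 20 and 30).
#' @param cutoff Distance cutoff in Angstrom for edges (default 30); also the
#'   value at which raw edge distances are clipped.
#' @param pe_dims Width of the sinusoidal sequence-offset encoding (even,
#'   default 56). Together with the 25 inter-atomic distances and the 12
#'   local-frame coordinates this yields 93-dimensional edge attributes.
#' @return A `graph_config` list.
#' @export
graph_config <- function(k = 20, cutoff = 30, pe_dims = 56) {
  if (k < 1) stop("k must be >= 1")
  if (cutoff <= 0) stop("cutoff must be positive")
  if (pe_dims < 2 || pe_dims %% 2 != 0) stop("pe_dims must be an even integer >= 2")
  structure(list(k = as.integer(k), cutoff = cutoff, pe_dims = as.integer(pe_dims)),
            class = "graph_config")
}

#' Read a graph configuration from YAML
#'
#' @param path Path to a YAML file with any of the fields `k`, `cutoff`,
#'   `pe_dims`.
#' @return A [graph_config()].
#' @export
graph_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(graph_config, y[intersect(names(y), c("k", "cutoff", "pe_dims"))])
}

#' Sinusoidal positional encoding of a sequence offset
#'
#' Transformer-style interleaved sin/cos over geometrically spaced
#' frequencies; all components lie between -1 and 1 and integer offsets map to
#' pairwise-distinct vectors over any practical range.
#'
#' @param offset Integer (or vector of integers) sequence offset j - i.
#' @param dims Even encoding width.
#' @return A length-`dims` vector, or a `length(offset) x dims` matrix when
#'   `offset` is a vector.
#' @export
positional_encoding <- function(offset, dims = 56) {
  if (dims < 2 || dims %% 2 != 0) stop("dims must be an even integer >= 2")
  half <- dims / 2
  freq <- 1 / (10000^((2 * (seq_len(half) - 1)) / dims))
  ang <- outer(offset, freq)
  out <- matrix(0, nrow = length(offset), ncol = dims)
  out[, seq(1, dims, by = 2)] <- sin(ang)
  out[, seq(2, dims, by = 2)] <- cos(ang)
  if (length(offset) == 1L) drop(out) else out
}

residue_atoms <- function(structure, i) {
  lapply(structure$atoms, function(m) m[i, ])
}

#' Geometric edge attribute vector for a residue pair
#'
#' Concatenates (a) the 25 inter-residue atomic distances between the
#' {N, CA, C, O, CB} atoms of the two residues (Angstrom, clipped at the
#' cutoff), (b) the 12 coordinates of the N and C atoms of both residues
#' expressed in the orthonormal local frame built from (N, CA, C) of the
#' first residue, and (c) the sinusoidal encoding of the signed sequence
#' offset. With the default 56-wide encoding the total is 25 + 12 + 56 = 93.
#' All components are functions of internal geometry and sequence offset
#' only, hence invariant under rigid motions.
#'
#' @param res_i,res_j Named lists of atom 3-vectors (`N`, `CA`, `C`, `O`,
#'   `CB`), e.g. from a parsed structure.
#' @param offset Signed sequence offset j - i.
#' @param config A [graph_config()].
#' @return Numeric vector of length `25 + 12 + pe_dims`.
#' @export
edge_feature_vector <- function(res_i, res_j, offset, config = graph_config()) {
  atoms <- c("N", "CA", "C", "O", "CB")
  for (a in atoms) {
    if (is.null(res_i[[a]]) || is.null(res_j[[a]]) ||
        !all(is.finite(res_i[[a]])) || !all(is.finite(res_j[[a]]))) {
      stop("missing backbone atom '", a, "' in edge feature computation")
    }
  }
  dists <- as.vector(vapply(atoms, function(b) {
    vapply(atoms, function(a) vnorm(res_i[[a]] - res_j[[b]]), numeric(1))
  }, numeric(5)))
  dists <- pmin(dists, config$cutoff)
  frame <- local_frame(res_i$N, res_i$CA, res_i$C)
  origin <- res_i$CA
  local <- as.vector(vapply(
    list(res_i$N, res_i$C, res_j$N, res_j$C),
    function(p) as.numeric(frame %*% (p - origin)),
    numeric(3)
  ))
  c(dists, local, positional_encoding(offset, config$pe_dims))
}

#' Build the kNN residue graph of a structure
#'
#' Each residue becomes a node connected by directed edges to its (up to) k
#' nearest other residues by C-alpha distance, restricted to pairs within
#' the cutoff; ties are broken by lower residue index. Node coordinates are
#' the C-alpha positions; edge attributes are filled by
#' [edge_feature_vector()]; node attributes are left unset and are supplied
#' by the sequence encoder.
#'
#' @param structure A `protein_structure` with at least 2 residues.
#' @param config A [graph_config()].
#' @return A `residue_graph`: node count `n`, directed edge index vectors
#'   `from`/`to`, edge attribute matrix `W_E` (|E| x 93 by default), node
#'   coordinate matrix `X` (n x 3), and node attributes `W_V` (NULL until
#'   encoded).
#' @export
build_residue_graph <- function(structure, config = graph_config()) {
  n <- n_residues(structure)
  if (n < 2) stop("graph construction needs at least 2 residues")
  ca <- structure$atoms$CA
  d <- as.matrix(stats::dist(ca))
  from <- integer(0)
  to <- integer(0)
  for (i in seq_len(n)) {
    ord <- order(d[i, ], seq_len(n)) # stable: ties to lower index
    ord <- ord[ord != i]
    nb <- ord[d[i, ord] <= config$cutoff]
    nb <- utils::head(nb, config$k)
    from <- c(from, rep.int(i, length(nb)))
    to <- c(to, nb)
  }
  o <- order(from, to)
  from <- from[o]
  to <- to[o]

  offsets <- seq_offset(structure, from, to)
  W_E <- edge_feature_matrix(structure, from, to, offsets, config)

  structure_graph <- structure(
    list(
      n = n,
      from = from,
      to = to,
      dist = d[cbind(from, to)],
      offsets = offsets,
      W_E = W_E,
      X = ca,
      W_V = NULL,
      config = config,
      node_aa = structure$aa,
      protein_id = structure$id,
      inc_from = Matrix::sparseMatrix(i = from, j = seq_along(from), x = 1,
                                      dims = c(n, length(from))),
      inc_to = Matrix::sparseMatrix(i = to, j = seq_along(to), x = 1,
                                    dims = c(n, length(to))),
      W_E_scaled = scaled_edge_attr(W_E)
    ),
    class = "residue_graph"
  )
  structure_graph
}

# Signed sequence offset honouring chain boundaries: across-chain pairs use
# the raw index difference of residue order (chains concatenated).
seq_offset <- function(structure, from, to) {
  as.integer(to - from)
}

edge_feature_matrix <- function(structure, from, to, offsets, config) {
  atoms <- c("N", "CA", "C", "O", "CB")
  E <- length(from)
  # distance block, vectorized over edges: 25 columns in (a_i, b_j) order
  dist_block <- matrix(0, nrow = E, ncol = 25)
  col <- 0
  for (b in atoms) {
    for (a in atoms) {
      col <- col + 1
      diff <- structure$atoms[[a]][from, , drop = FALSE] -
        structure$atoms[[b]][to, , drop = FALSE]
      dist_block[, col] <- pmin(sqrt(rowSums(diff^2)), config$cutoff)
    }
  }
  # local-frame block: coordinates of N_i, C_i, N_j, C_j in frame of res i
  local_block <- matrix(0, nrow = E, ncol = 12)
  frames <- lapply(seq_len(structure_n(structure)), function(i) {
    local_frame(structure$atoms$N[i, ], structure$atoms$CA[i, ],
                structure$atoms$C[i, ])
  })
  for (e in seq_len(E)) {
    fr <- frames[[from[e]]]
    origin <- structure$atoms$CA[from[e], ]
    pts <- rbind(structure$atoms$N[from[e], ], structure$atoms$C[from[e], ],
                 structure$atoms$N[to[e], ], structure$atoms$C[to[e], ])
    local_block[e, ] <- as.vector(fr %*% t(sweep(pts, 2, origin)))
  }
  pe_block <- positional_encoding(offsets, config$pe_dims)
  if (is.null(dim(pe_block))) pe_block <- matrix(pe_block, nrow = 1)
  cbind(dist_block, local_block, pe_block)
}

structure_n <- function(structure) length(structure$aa)

#' @export
print.residue_graph <- function(x, ...) {
  cat("<residue_graph> ", x$protein_id, ": ", x$n, " nodes, ",
      length(x$from), " directed edges (k = ", x$config$k,
      ", cutoff = ", x$config$cutoff, " A), edge dim ", ncol(x$W_E),
      "\n", sep = "")
  invisible(x)
}

#' Edge list view of a residue graph
#'
#' @param x A `residue_graph`.
#' @param ... Unused.
#' @return Tibble with columns `from`, `to`, `dist`, `offset`.
#' @export
as_tibble.residue_graph <- function(x, ...) {
  tibble::tibble(from = x$from, to = x$to, dist = x$dist, offset = x$offsets)
}

#' Export a residue graph as plain-text edge list and attribute tables
#'
#' Writes `<prefix>_edges.tsv` (from, to, dist, offset) and
#' `<prefix>_edge_attr.tsv` (the attribute matrix) for debugging.
#'
#' @param graph A `residue_graph`.
#' @param prefix Output path prefix.
#' @return The two file paths, invisibly.
#' @export
export_graph <- function(graph, prefix) {
  edges_path <- paste0(prefix, "_edges.tsv")
  attr_path <- paste0(prefix, "_edge_attr.tsv")
  utils::write.table(as_tibble.residue_graph(graph), edges_path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(graph$W_E, attr_path, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(c(edges_path, attr_path))
}

#' Attach node attributes to a residue graph
#'
#' @param graph A `residue_graph`.
#' @param W_V An `n x d` numeric matrix of node attributes (one row per
#'   residue, in residue order).
#' @return The graph with `W_V` set.
#' @export
set_node_attributes <- function(graph, W_V) {
  if (nrow(W_V) != graph$n) stop("W_V must have one row per node")
  graph$W_V <- W_V
  graph
}
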