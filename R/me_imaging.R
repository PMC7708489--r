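# Imaging beyond the memory-effect range: pairwise displacement estimation
# by FFT cross-correlation of eigen-patterns, displacement-graph stitching
# by least squares, image assembly, and the MDS alternative.

#' Displacement between two eigen-patterns by cross-correlation
#'
#' Mean-subtracted, norm-normalized FFT cross-correlation of two same-shape
#' eigen-patterns. If the two emitters sit within one memory-effect patch
#' their patterns are translated copies and a sharp peak appears at the
#' relative displacement u_ij = x_j - x_i (the shift that maps pattern i
#' onto pattern j). The score is the peak height divided by the robust
#' standard deviation of the correlation plane away from the peak.
#'
#' @param pattern_i,pattern_j numeric matrices (rows x cols), or pixel
#'   vectors with `grid` supplied. High-pass the patterns first.
#' @param grid c(rows, cols) when vectors are passed.
#' @param max_shift optional cap on |u| per axis, in pixels.
#' @return list: `u` (integer c(du_row, du_col)), `score`, `peak`
#'   (normalized correlation at the peak).
#' @export
cross_correlate <- function(pattern_i, pattern_j, grid = NULL,
                            max_shift = NULL) {
  as_img <- function(x) {
    if (is.matrix(x)) return(x)
    if (is.null(grid)) stop("grid required for vector patterns")
    matrix(x, grid[1], grid[2])
  }
  A <- as_img(pattern_i); B <- as_img(pattern_j)
  if (!all(dim(A) == dim(B))) stop("patterns must have the same shape")
  A <- A - mean(A); B <- B - mean(B)
  na <- sqrt(sum(A^2)); nb <- sqrt(sum(B^2))
  if (na == 0 || nb == 0) stop("flat pattern has no correlation structure")
  r <- nrow(A); c <- ncol(A)
  Ap <- matrix(0, 2 * r, 2 * c); Bp <- Ap
  Ap[1:r, 1:c] <- A / na; Bp[1:r, 1:c] <- B / nb
  # C(v) = sum_y A(y) B(y + v): peak at v = u with B(y) = A(y - u)
  C <- Re(stats::fft(Conj(stats::fft(Ap)) * stats::fft(Bp), inverse = TRUE)) /
    length(Ap)
  sr <- fft_freq(2 * r) * 2 * r   # shift values per row index
  sc <- fft_freq(2 * c) * 2 * c
  keep_r <- abs(sr) < r; keep_c <- abs(sc) < c
  if (!is.null(max_shift)) {
    keep_r <- keep_r & abs(sr) <= max_shift
    keep_c <- keep_c & abs(sc) <= max_shift
  }
  Cs <- C[keep_r, keep_c, drop = FALSE]
  vr <- sr[keep_r]; vc <- sc[keep_c]
  ix <- arrayInd(which.max(Cs), dim(Cs))
  u <- c(vr[ix[1]], vc[ix[2]])
  peak <- Cs[ix[1], ix[2]]
  # robust background: exclude a window around the peak
  excl_r <- abs(vr - u[1]) <= 4; excl_c <- abs(vc - u[2]) <= 4
  bgv <- Cs[!outer(excl_r, excl_c, "&")]
  s <- stats::mad(bgv)
  if (s == 0) s <- stats::sd(bgv)
  list(u = as.integer(round(u)), score = (peak - stats::median(bgv)) / s,
       peak = peak)
}

# reverse a shift measurement: u_ji = -u_ij (exact antisymmetry)

# Enforce triangle closure on an edge list: while some triangle violates
# ||u_ij + u_jk - u_ik|| > tol, drop the weakest (lowest-score) edge among
# the violating triangles. Spurious correlations (shared background, grain
# coincidences) rarely close cycles, so this removes them while keeping
# genuine memory-effect displacements, which are consistent by construction.
prune_inconsistent_edges <- function(edges, tol = 2) {
  repeat {
    m <- nrow(edges)
    if (m < 3) return(edges)
    key <- paste(edges$i, edges$j)
    lookup <- stats::setNames(seq_len(m), key)
    get_e <- function(a, b) {
      if (a < b) k <- lookup[paste(a, b)] else k <- lookup[paste(b, a)]
      if (is.na(k)) return(NULL)
      s <- if (a < b) 1 else -1
      list(k = unname(k), u = s * c(edges$du_row[k], edges$du_col[k]))
    }
    nodes <- sort(unique(c(edges$i, edges$j)))
    bad <- NULL; bad_viol <- 0
    for (a in nodes) for (b in nodes[nodes > a]) {
      e_ab <- get_e(a, b); if (is.null(e_ab)) next
      for (cC in nodes[nodes > b]) {
        e_bc <- get_e(b, cC); if (is.null(e_bc)) next
        e_ac <- get_e(a, cC); if (is.null(e_ac)) next
        viol <- sqrt(sum((e_ab$u + e_bc$u - e_ac$u)^2))
        if (viol > tol) {
          ks <- c(e_ab$k, e_bc$k, e_ac$k)
          weakest <- ks[which.min(edges$score[ks])]
          if (viol > bad_viol) { bad <- weakest; bad_viol <- viol }
        }
      }
    }
    if (is.null(bad)) return(edges)
    edges <- edges[-bad, , drop = FALSE]
  }
}

#' Build the displacement graph over eigen-patterns
#'
#' Evaluates the pairwise cross-correlation of every unordered pair of kept
#' eigen-patterns; pairs whose correlation score exceeds `theta_edge` become
#' edges carrying the displacement u_ij. Antisymmetry u_ij = -u_ji holds
#' exactly because each unordered pair is computed once. Connected
#' components delimit groups of emitters whose memory-effect patches chain
#' together; emitters in singleton components cannot be located.
#'
#' @param patterns D x K matrix of (high-passed) eigen-patterns, an
#'   `intensity_tm`, or a list of matrices.
#' @param grid c(rows, cols) for matrix input.
#' @param theta_edge edge threshold on the correlation score (robust
#'   z-units above the correlation-plane background).
#' @param theta_peak additional absolute threshold on the normalized
#'   correlation peak. The plane argmax between two *independent* speckle
#'   patterns already reaches ~0.1 (extreme-value statistics over the
#'   plane) with a large z-score, so a z criterion alone over-connects;
#'   genuine within-patch pairs have peaks at the intensity correlation
#'   c(d) (>= ~0.3 for spacings up to 1.5 me_range).
#' @param max_shift optional cap forwarded to [cross_correlate()].
#' @param prune_triangles optionally pre-enforce cycle consistency: while
#'   any triangle of edges has ||u_ij + u_jk - u_ik|| > `cycle_tol`, drop
#'   the lowest-score edge among the violating triangles. Off by default:
#'   [stitch_positions()] removes inconsistent edges more reliably from the
#'   full least-squares residuals.
#' @param cycle_tol triangle closure tolerance in pixels.
#' @return object of class `displacement_graph`: `edges` data.frame
#'   (i, j, du_row, du_col, score), `n_nodes`, `membership` (connected
#'   component label per node).
#' @export
build_displacement_graph <- function(patterns, grid = NULL, theta_edge = 5,
                                     theta_peak = 0.2, max_shift = NULL,
                                     prune_triangles = FALSE, cycle_tol = 2) {
  if (inherits(patterns, "intensity_tm")) {
    grid <- patterns$grid
    patterns <- patterns$matrix
  }
  if (is.list(patterns)) {
    mats <- patterns
  } else {
    if (is.null(grid)) stop("grid required for matrix input")
    mats <- lapply(seq_len(ncol(patterns)), function(k)
      matrix(patterns[, k], grid[1], grid[2]))
  }
  K <- length(mats)
  if (K < 2) stop("need at least 2 eigen-patterns")
  rows <- list(); nr <- 0
  for (i in seq_len(K - 1)) for (j in (i + 1):K) {
    cc <- cross_correlate(mats[[i]], mats[[j]], max_shift = max_shift)
    if (cc$score > theta_edge && cc$peak > theta_peak) {
      nr <- nr + 1
      rows[[nr]] <- data.frame(i = i, j = j, du_row = cc$u[1],
                               du_col = cc$u[2], score = cc$score,
                               peak = cc$peak)
    }
  }
  edges <- if (nr > 0) do.call(rbind, rows) else
    data.frame(i = integer(), j = integer(), du_row = integer(),
               du_col = integer(), score = numeric(), peak = numeric())
  if (prune_triangles && nrow(edges) >= 3)
    edges <- prune_inconsistent_edges(edges, cycle_tol)
  g <- igraph::graph_from_data_frame(
    edges[, c("i", "j")], directed = FALSE,
    vertices = data.frame(name = seq_len(K)))
  membership <- igraph::components(g)$membership[as.character(seq_len(K))]
  structure(list(edges = edges, n_nodes = K,
                 membership = as.integer(membership)),
            class = "displacement_graph")
}

#' @export
print.displacement_graph <- function(x, ...) {
  cat(sprintf("<displacement_graph> %d nodes | %d edges | %d components\n",
              x$n_nodes, nrow(x$edges), length(unique(x$membership))))
  invisible(x)
}

#' Stitch emitter positions from a displacement graph
#'
#' Solves, independently in each connected component and for each axis, the
#' least-squares problem over all edge constraints x_j - x_i = u_ij, with
#' the reference node of the component pinned at the origin. Using all
#' edges at once (rather than accumulating shifts along a path) avoids
#' drift along chains; positions are defined up to one global translation
#' per component. Spurious displacements (shared-background or
#' cross-excitation correlations that are not memory-effect shifts) are
#' rejected robustly: while the worst edge residual
#' ||(x_j - x_i) - u_ij|| exceeds `resid_tol`, that edge is removed and the
#' system re-solved. Only edges lying on cycles can carry a nonzero
#' residual, so removal never disconnects a component. Singleton nodes are
#' reported unlocated.
#'
#' @param graph a `displacement_graph`.
#' @param reference optional node pinned at the origin of its component
#'   (default: lowest-index node of each component).
#' @param resid_tol outlier-rejection threshold on edge residuals, px;
#'   `Inf` disables rejection.
#' @return object of class `object_map`: data.frame `positions` (node,
#'   component, row, col, located), the input graph, `edges_used` (edges
#'   surviving outlier rejection), and `n_rejected`.
#' @export
stitch_positions <- function(graph, reference = NULL, resid_tol = 2) {
  if (nrow(graph$edges) == 0) stop("graph has no edges; nothing to stitch")
  K <- graph$n_nodes
  edges <- graph$edges
  n_rejected <- 0L
  repeat {
    g <- igraph::graph_from_data_frame(
      edges[, c("i", "j")], directed = FALSE,
      vertices = data.frame(name = seq_len(K)))
    membership <- as.integer(igraph::components(g)$membership[
      as.character(seq_len(K))])
    pos <- data.frame(node = seq_len(K), component = membership,
                      row = NA_real_, col = NA_real_, located = FALSE)
    resid <- rep(0, nrow(edges))
    for (comp in unique(membership)) {
      nodes <- which(membership == comp)
      if (length(nodes) == 1) next
      ref <- if (!is.null(reference) && reference %in% nodes) reference
             else min(nodes)
      ek <- which(edges$i %in% nodes)
      e <- edges[ek, , drop = FALSE]
      idx <- stats::setNames(seq_along(nodes), nodes)
      A <- matrix(0, nrow(e), length(nodes))
      for (k in seq_len(nrow(e))) {
        A[k, idx[as.character(e$j[k])]] <- 1
        A[k, idx[as.character(e$i[k])]] <- -1
      }
      free <- nodes != ref
      Af <- A[, free, drop = FALSE]
      fr <- stats::lm.fit(Af, e$du_row)
      fc <- stats::lm.fit(Af, e$du_col)
      sol_r <- ifelse(is.na(fr$coefficients), 0, fr$coefficients)
      sol_c <- ifelse(is.na(fc$coefficients), 0, fc$coefficients)
      pos$row[nodes[free]] <- sol_r
      pos$col[nodes[free]] <- sol_c
      pos$row[ref] <- 0; pos$col[ref] <- 0
      pos$located[nodes] <- TRUE
      resid[ek] <- sqrt(fr$residuals^2 + fc$residuals^2)
    }
    worst <- which.max(resid)
    if (!is.finite(resid_tol) || length(worst) == 0 ||
        resid[worst] <= resid_tol) break
    edges <- edges[-worst, , drop = FALSE]
    n_rejected <- n_rejected + 1L
    if (nrow(edges) == 0) stop("all edges rejected as inconsistent")
  }
  structure(list(positions = pos, graph = graph, edges_used = edges,
                 n_rejected = n_rejected), class = "object_map")
}

#' @export
print.object_map <- function(x, ...) {
  cat(sprintf("<object_map> %d/%d nodes located in %d component(s)\n",
              sum(x$positions$located), nrow(x$positions),
              length(unique(x$positions$component))))
  invisible(x)
}

#' Align recovered positions to ground truth by a global translation
#'
#' The stitched object is only defined up to one translation per connected
#' component; this removes the mean offset (per component) and reports the
#' residual per-node error.
#'
#' @param object_map an `object_map` (or data.frame with row/col/located).
#' @param truth N x 2 matrix of true (row, col) positions, indexed by node.
#' @return data.frame: node, err (Euclidean residual after translation
#'   alignment; NA for unlocated nodes).
#' @export
align_positions <- function(object_map, truth) {
  pos <- if (inherits(object_map, "object_map")) object_map$positions
         else object_map
  err <- rep(NA_real_, nrow(pos))
  for (comp in unique(pos$component)) {
    k <- which(pos$component == comp & pos$located)
    if (length(k) == 0) next
    dr <- mean(truth[k, 1] - pos$row[k])
    dc <- mean(truth[k, 2] - pos$col[k])
    err[k] <- sqrt((pos$row[k] + dr - truth[k, 1])^2 +
                   (pos$col[k] + dc - truth[k, 2])^2)
  }
  data.frame(node = pos$node, err = err)
}

#' Render the reconstructed object
#'
#' Draws brightness-weighted Gaussian spots at the located positions on the
#' camera grid (positions re-centred on the grid). For continuous objects
#' factorized at a heavily overestimated rank, feed only the high-variance
#' (non-spurious) components.
#'
#' @param object_map an `object_map`.
#' @param weights per-node brightness (recycled; default 1).
#' @param grid c(rows, cols) of the output image.
#' @param spot_sigma Gaussian spot width in pixels.
#' @return rows x cols image matrix.
#' @export
assemble_image <- function(object_map, weights = 1, grid = c(64, 64),
                           spot_sigma = 1.5) {
  pos <- object_map$positions
  k <- which(pos$located)
  img <- matrix(0, grid[1], grid[2])
  if (length(k) == 0) return(img)
  w <- rep_len(weights, nrow(pos))
  r0 <- pos$row[k] - mean(range(pos$row[k])) + (grid[1] - 1) / 2
  c0 <- pos$col[k] - mean(range(pos$col[k])) + (grid[2] - 1) / 2
  rr <- matrix(0:(grid[1] - 1), grid[1], grid[2])
  cc <- matrix(0:(grid[2] - 1), grid[1], grid[2], byrow = TRUE)
  for (s in seq_along(k))
    img <- img + w[k[s]] *
      exp(-((rr - r0[s])^2 + (cc - c0[s])^2) / (2 * spot_sigma^2))
  img
}

#' Localize emitters by classical multidimensional scaling
#'
#' Alternative to least-squares stitching: embeds the emitters in the plane
#' from the matrix of pairwise distances ||u_ij|| (double-centering + top
#' eigenvectors, via [stats::cmdscale()]). Distances missing because the
#' pair exceeds the memory-effect range are completed by shortest-path
#' distance through the displacement graph. The configuration is recovered
#' up to a rigid transform and reflection; use [procrustes_align()] to
#' compare with ground truth.
#'
#' @param distance_matrix symmetric non-negative matrix; NA for missing
#'   entries (completed by shortest path).
#' @param dim embedding dimension (2 for planar objects).
#' @return N x dim matrix of positions.
#' @export
mds_localize <- function(distance_matrix, dim = 2) {
  Dm <- as.matrix(distance_matrix)
  if (!isSymmetric(unname(ifelse(is.na(Dm), -1, Dm))))
    stop("distance matrix must be symmetric")
  if (any(Dm < 0, na.rm = TRUE)) stop("distances must be non-negative")
  if (anyNA(Dm)) {
    # explicit edge list: zero-length displacements are real edges too
    K <- nrow(Dm)
    idx <- which(!is.na(Dm) & upper.tri(Dm), arr.ind = TRUE)
    g <- igraph::graph_from_data_frame(
      data.frame(from = idx[, 1], to = idx[, 2]), directed = FALSE,
      vertices = data.frame(name = seq_len(K)))
    Dm <- igraph::distances(g, weights = Dm[idx])
    if (any(!is.finite(Dm)))
      stop("distance matrix cannot be completed: graph is disconnected")
    Dm <- Dm[order(as.integer(rownames(Dm))), order(as.integer(colnames(Dm)))]
  }
  stats::cmdscale(Dm, k = dim)
}

#' Procrustes alignment of two planar configurations
#'
#' Rigidly aligns an estimated configuration to a reference (rotation,
#' reflection, translation, optional scale) and reports the residual.
#' Thin wrapper over [vegan::procrustes()].
#'
#' @param est estimated N x 2 configuration.
#' @param truth reference N x 2 configuration.
#' @param scale allow a global scale (default FALSE: rigid).
#' @return list: `aligned` (est after alignment), `rmse`.
#' @export
procrustes_align <- function(est, truth, scale = FALSE) {
  pr <- vegan::procrustes(as.matrix(truth), as.matrix(est), scale = scale,
                          symmetric = FALSE)
  list(aligned = pr$Yrot + matrix(pr$translation, nrow(est), 2, byrow = TRUE),
       rmse = sqrt(mean(stats::residuals(pr)^2)))
}

#' Graph distance matrix from a displacement graph
#'
#' Pairwise Euclidean lengths ||u_ij|| on edges, NA elsewhere; input for
#' [mds_localize()].
#'
#' @param graph a `displacement_graph`.
#' @return K x K symmetric matrix with NA for non-edges and 0 diagonal.
#' @export
graph_distance_matrix <- function(graph) {
  K <- graph$n_nodes
  Dm <- matrix(NA_real_, K, K)
  diag(Dm) <- 0
  e <- graph$edges
  if (nrow(e)) {
    len <- sqrt(e$du_row^2 + e$du_col^2)
    for (k in seq_len(nrow(e))) {
      Dm[e$i[k], e$j[k]] <- len[k]
      Dm[e$j[k], e$i[k]] <- len[k]
    }
  }
  Dm
}
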