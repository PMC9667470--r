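#' Particle configuration in an orthorhombic box
#'
#' @param positions n x 3 matrix, nm; wrapped into the box when periodic.
#' @param box scalar or length-3 edge lengths, nm (> 0).
#' @param periodic apply minimum-image distances.
#' @export
particle_config <- function(positions, box, periodic = TRUE) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3L, all(is.finite(positions)))
  box <- rep(as.numeric(box), length.out = 3L)
  stopifnot(all(box > 0))
  if (periodic) positions <- positions %% matrix(box, nrow(positions), 3L, byrow = TRUE)
  structure(list(positions = positions, box = box, periodic = periodic),
            class = "particle_config")
}

# n x n matrix of (minimum-image) distances
pairwise_distances <- function(config) {
  p <- config$positions
  d2 <- matrix(0, nrow(p), nrow(p))
  for (d in 1:3) {
    dx <- outer(p[, d], p[, d], "-")
    if (config$periodic) dx <- dx - config$box[d] * round(dx / config$box[d])
    d2 <- d2 + dx^2
  }
  sqrt(d2)
}

#' Contact-cutoff cluster partition
#'
#' Partitions particles into single-linkage connected components of the
#' contact graph: two particles are in contact when their minimum-image
#' distance is at most `cutoff`. Cluster labels are deterministic (the
#' smallest member index). Under periodic boundaries the cutoff must stay
#' below half the smallest box edge, otherwise the minimum-image convention
#' is ambiguous.
#'
#' @param config a [particle_config()].
#' @param cutoff contact distance, nm (default 0.6, the bead-contact
#'   criterion used for drug aggregation analysis).
#' @return A `cluster_partition`: list with `labels` (per-particle id),
#'   `sizes` (decreasing), `n_clusters`.
#' @export
find_clusters <- function(config, cutoff = 0.6) {
  stopifnot(inherits(config, "particle_config"), cutoff > 0)
  if (config$periodic && cutoff >= min(config$box) / 2) {
    stop("cutoff (", cutoff, " nm) must be below half the smallest box edge (",
         min(config$box) / 2, " nm) under periodic boundaries")
  }
  n <- nrow(config$positions)
  D <- pairwise_distances(config)
  adj <- D <= cutoff
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
  comp <- igraph::components(g)$membership
  labels <- stats::ave(seq_len(n), comp, FUN = min)
  sizes <- sort(as.integer(table(labels)), decreasing = TRUE)
  structure(list(labels = as.integer(labels), sizes = sizes,
                 n_clusters = length(sizes)),
            class = "cluster_partition")
}

#' @export
print.cluster_partition <- function(x, ...) {
  cat("<cluster_partition> ", length(x$labels), " particles in ", x$n_clusters,
      " clusters; sizes: ", paste(x$sizes, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Average cluster size along a trajectory
#'
#' Per frame, reports both conventions of the mean aggregate size:
#' the number average N / (number of clusters, monomers included) and the
#' mass (weight) average sum(s^2) / sum(s).
#'
#' @param frames list of [particle_config()] with a consistent particle
#'   count.
#' @param cutoff contact distance, nm.
#' @param times optional frame times, ps (defaults to 0, 1, 2, ...).
#' @return A data.frame (`cluster_trace`) with columns `time_ps`,
#'   `number_avg`, `mass_avg`, `n_clusters`.
#' @export
cluster_trace <- function(frames, cutoff = 0.6, times = NULL) {
  if (length(frames) == 0L) stop("frames must be non-empty")
  counts <- vapply(frames, function(f) nrow(f$positions), integer(1))
  if (length(unique(counts)) != 1L) stop("all frames must have the same particle count")
  if (is.null(times)) times <- seq_along(frames) - 1
  stopifnot(length(times) == length(frames))
  rows <- lapply(seq_along(frames), function(i) {
    part <- find_clusters(frames[[i]], cutoff)
    s <- part$sizes
    data.frame(time_ps = times[i],
               number_avg = sum(s) / length(s),
               mass_avg = sum(s^2) / sum(s),
               n_clusters = length(s))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cluster_trace", class(out))
  out
}
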