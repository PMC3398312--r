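#' Angular distance between two dihedral segments
#'
#' Root-mean-square of the wrapped (phi, psi) differences over the L window
#' positions:
#' \deqn{D(a,b) = \sqrt{\frac{1}{2L} \sum_{k=1}^{L}
#'   \Delta(\phi_{ak},\phi_{bk})^2 + \Delta(\psi_{ak},\psi_{bk})^2}}
#' where \eqn{\Delta} is the angular difference wrapped into \[-180, 180\]
#' degrees. Symmetric, ranges from 0 to 180 degrees.
#'
#' @param phi_a,psi_a,phi_b,psi_b Numeric angle vectors of equal length L, in
#'   degrees, fully defined.
#' @return Distance in degrees.
#' @export
dihedral_distance <- function(phi_a, psi_a, phi_b, psi_b) {
  if (length(phi_a) != length(phi_b) || length(psi_a) != length(psi_b) ||
      length(phi_a) != length(psi_a)) {
    abort("length mismatch between segments")
  }
  ang_a <- c(phi_a, psi_a); ang_b <- c(phi_b, psi_b)
  if (anyNA(ang_a) || anyNA(ang_b)) abort("undefined angle in segment")
  sqrt(mean(wrap_angle(ang_a - ang_b)^2))
}

# n x 2L angle matrix from a segment tibble (phi columns then psi columns)
segment_angle_matrix <- function(segments) {
  cbind(do.call(rbind, segments$phi), do.call(rbind, segments$psi))
}

# distances from one 2L angle vector to the rows of a 2L-column matrix,
# same metric as dihedral_distance()
angles_dist_to <- function(mat, v) {
  d <- wrap_angle(sweep(mat, 2, v))
  sqrt(rowMeans(d^2))
}

#' Single-pass (leader) clustering of dihedral segments
#'
#' Processes segments in input order. The first segment founds a cluster of
#' size one; each subsequent segment is compared to the centroids of all
#' existing clusters and joins the nearest one if that distance is at most
#' `d_th`, otherwise it founds a new cluster. Centroids are circular running
#' means per angle coordinate, updated after every join. The procedure is
#' deterministic given the input order (which is therefore part of any run's
#' provenance); nearest-centroid ties go to the lowest cluster id.
#'
#' @param segments Segment tibble from [extract_segments()] or
#'   [generate_segment_population()].
#' @param d_th Angular threshold in degrees (default 30).
#' @param min_members Cluster-size floor used downstream when building
#'   profiles (default 80). Clustering itself keeps all clusters; the floor
#'   is recorded in the result and applied by [run_cross_profile_analysis()].
#' @return An object of class `segment_clustering`: list with `assignment`
#'   (integer vector, cluster id per segment in creation order), `clusters`
#'   (list of per-cluster member index vectors, centroid angle vectors and
#'   medoid indices), `d_th`, `min_members`, `L`, and the input `segments`.
#' @export
single_pass_cluster <- function(segments, d_th = 30, min_members = 80) {
  stopifnot(d_th > 0, min_members >= 1)
  n <- nrow(segments)
  if (n == 0L) {
    return(structure(list(assignment = integer(), clusters = list(),
                          d_th = d_th, min_members = min_members,
                          L = NA_integer_, segments = segments),
                     class = "segment_clustering"))
  }
  ang <- segment_angle_matrix(segments) * pi / 180
  L <- ncol(ang) / 2L
  # running circular means: per-cluster sums of unit vectors per coordinate
  sin_s <- list(); cos_s <- list(); sizes <- integer()
  cent <- NULL  # k x 2L matrix of centroid angles (radians)
  assignment <- integer(n)
  for (i in seq_len(n)) {
    v <- ang[i, ]
    k <- length(sizes)
    if (k > 0L) {
      d <- wrap_angle(sweep(cent, 2, v) * 180 / pi)
      dist <- sqrt(rowMeans(d^2))
      j <- which.min(dist)           # lowest index on ties
      if (dist[j] <= d_th) {
        assignment[i] <- j
        sin_s[[j]] <- sin_s[[j]] + sin(v)
        cos_s[[j]] <- cos_s[[j]] + cos(v)
        sizes[j] <- sizes[j] + 1L
        cent[j, ] <- atan2(sin_s[[j]], cos_s[[j]])
        next
      }
    }
    # found a new cluster
    sin_s[[k + 1L]] <- sin(v); cos_s[[k + 1L]] <- cos(v)
    sizes[k + 1L] <- 1L
    cent <- rbind(cent, v)
    assignment[i] <- k + 1L
  }
  clusters <- lapply(seq_along(sizes), function(j) {
    members <- which(assignment == j)
    centroid <- wrap_angle(cent[j, ] * 180 / pi)
    med <- members[medoid_of(ang[members, , drop = FALSE] * 180 / pi)]
    list(cluster_id = j, members = members,
         centroid_phi = centroid[seq_len(L)],
         centroid_psi = centroid[L + seq_len(L)],
         medoid = med)
  })
  structure(list(assignment = assignment, clusters = clusters, d_th = d_th,
                 min_members = min_members, L = L, segments = segments),
            class = "segment_clustering")
}

# index (within the rows of `ang`, degrees) of the medoid: argmin of summed
# pairwise distance, lowest index on ties
medoid_of <- function(ang) {
  m <- nrow(ang)
  if (m == 1L) return(1L)
  tot <- numeric(m)
  for (i in seq_len(m)) {
    tot[i] <- sum(angles_dist_to(ang, ang[i, ]))
  }
  which.min(tot)
}

#' Medoid member of a cluster
#'
#' The member whose summed [dihedral_distance()] to all co-members is
#' minimal; ties go to the lowest member index.
#'
#' @param clustering A [single_pass_cluster()] result.
#' @param cluster_id Cluster to query.
#' @return Index into the clustering's segment table.
#' @export
select_medoid <- function(clustering, cluster_id) {
  cl <- clustering$clusters[[cluster_id]]
  if (is.null(cl)) abort("no such cluster")
  cl$medoid
}

#' @export
print.segment_clustering <- function(x, ...) {
  cat(sprintf("<segment_clustering> %d segments, %d clusters (D_th = %g deg)\n",
              length(x$assignment), length(x$clusters), x$d_th))
  invisible(x)
}

#' Tidy a segment clustering into per-segment assignments
#'
#' @param x A [single_pass_cluster()] result.
#' @param ... Unused.
#' @return A tibble with `segment_id`, `cluster_id`, `is_medoid`,
#'   `distance_to_centroid` (degrees).
#' @export
tidy.segment_clustering <- function(x, ...) {
  n <- length(x$assignment)
  if (n == 0L) {
    return(tibble(segment_id = integer(), cluster_id = integer(),
                  is_medoid = logical(), distance_to_centroid = double()))
  }
  ang <- segment_angle_matrix(x$segments)
  medoids <- vapply(x$clusters, `[[`, integer(1), "medoid")
  d2c <- vapply(seq_len(n), function(i) {
    cl <- x$clusters[[x$assignment[i]]]
    dihedral_distance(ang[i, seq_len(x$L)], ang[i, x$L + seq_len(x$L)],
                      cl$centroid_phi, cl$centroid_psi)
  }, double(1))
  tibble(segment_id = seq_len(n), cluster_id = x$assignment,
         is_medoid = seq_len(n) %in% medoids,
         distance_to_centroid = d2c)
}

#' Per-cluster summary
#'
#' @param x A [single_pass_cluster()] result.
#' @param ... Unused.
#' @return A tibble with `cluster_id`, `n_members`, `medoid_segment_id`.
#' @export
glance.segment_clustering <- function(x, ...) {
  tibble(
    cluster_id = vapply(x$clusters, `[[`, integer(1), "cluster_id"),
    n_members = vapply(x$clusters, function(c) length(c$members), integer(1)),
    medoid_segment_id = vapply(x$clusters, `[[`, integer(1), "medoid")
  )
}
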