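#' Hamming dissimilarity matrix of equal-length (gapped) sequences
#'
#' Counts positions at which two sequences differ. A gap against a residue
#' counts as a difference; gap against gap counts as equal (`'.'` and `'-'`
#' are the same gap symbol).
#'
#' @param seqs Character vector (>= 2) of equal-length, possibly gapped
#'   sequences; names become row/column names.
#' @return Symmetric integer matrix with zero diagonal.
#' @export
hamming_matrix <- function(seqs) {
  if (length(seqs) < 2L) abort("need at least 2 sequences")
  seqs <- toupper(gsub(".", "-", seqs, fixed = TRUE))
  if (length(unique(nchar(seqs))) != 1L) {
    abort("ragged input: sequences must have equal length")
  }
  ids <- names(seqs) %||% paste0("seq_", seq_along(seqs))
  m <- do.call(rbind, strsplit(seqs, ""))
  n <- length(seqs)
  D <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- sum(m[i, ] != m[j, ])
      D[i, j] <- d; D[j, i] <- d
    }
  }
  D
}

#' Embed a dissimilarity matrix into two dimensions by classical scaling
#'
#' Classical (Torgerson) multidimensional scaling: the squared
#' dissimilarities are double-centred into a Gram matrix
#' \eqn{B = -\frac{1}{2} J D^{\circ 2} J}, whose top-2 eigenpairs (descending
#' eigenvalue) give the principal coordinates, each axis scaled by the square
#' root of its eigenvalue. When the dissimilarities are Hamming distances
#' this equals PCA of the implied one-hot sequence encoding up to scaling.
#' Sign convention: on each axis the first coordinate of magnitude above
#' 1e-8 is made positive. The embedding is centred by construction.
#'
#' @param D Symmetric dissimilarity matrix with zero diagonal (e.g.
#'   [hamming_matrix()]).
#' @return An object of class `landscape_embedding`: tibble with `id`, `PC1`,
#'   `PC2`; attributes `eigenvalues` (all n) and `degenerate` (TRUE when all
#'   dissimilarities are zero and every point sits at the origin).
#' @export
pca_embed <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 2L || ncol(D) != n) abort("D must be a square matrix, n >= 2")
  if (max(abs(D - t(D))) > 1e-8) abort("D must be symmetric")
  if (max(abs(diag(D))) > 1e-8) abort("D must have a zero diagonal")
  ids <- rownames(D) %||% paste0("seq_", seq_len(n))
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  eg <- eigen((B + t(B)) / 2, symmetric = TRUE)
  ev <- eg$values
  coords <- sapply(1:2, function(k) {
    lam <- ev[k]
    if (lam <= 1e-12) return(rep(0, n))
    v <- eg$vectors[, k] * sqrt(lam)
    f <- v[abs(v) > 1e-8]
    if (length(f) > 0L && f[1] < 0) v <- -v
    v
  })
  degenerate <- all(abs(D) < 1e-12)
  if (degenerate) warn("all dissimilarities are zero; embedding collapses to the origin")
  out <- tibble(id = ids, PC1 = coords[, 1], PC2 = coords[, 2])
  attr(out, "eigenvalues") <- ev
  attr(out, "degenerate") <- degenerate
  class(out) <- c("landscape_embedding", class(out))
  out
}

#' Interpolate compatibility scores into a 2-D landscape surface
#'
#' Builds a regular grid over the bounding box of the embedded points and
#' interpolates S onto it. The default method is piecewise-linear
#' interpolation on the Delaunay triangulation of the points, with
#' inverse-distance-weighted (power `idw_power`) extrapolation outside the
#' convex hull; `method = "idw"` uses inverse-distance weighting everywhere
#' (and accepts as few as two points). Grid nodes that coincide with a data
#' point reproduce its S exactly.
#'
#' @param points Data frame with columns `PC1`, `PC2` (or `x`, `y`) and `S`.
#' @param n_grid Grid nodes per axis (default 100).
#' @param method `"linear"` (Delaunay; needs >= 3 non-collinear points) or
#'   `"idw"`.
#' @param idw_power Power of the inverse-distance weights (default 2).
#' @return An object of class `landscape_surface`: tibble `[x, y, S_interp]`
#'   with attributes `method` and `n_grid`.
#' @export
surface_interpolate <- function(points, n_grid = 100,
                                method = c("linear", "idw"), idw_power = 2) {
  method <- match.arg(method)
  points <- as.data.frame(points)
  if (all(c("x", "y") %in% names(points)) && !"PC1" %in% names(points)) {
    names(points)[match(c("x", "y"), names(points))] <- c("PC1", "PC2")
  }
  stopifnot(all(c("PC1", "PC2", "S") %in% names(points)))
  px <- points$PC1; py <- points$PC2; ps <- points$S
  n <- length(px)
  if (method == "linear") {
    if (n < 3L) abort("linear interpolation needs at least 3 points")
    cc <- cbind(px - mean(px), py - mean(py))
    if (qr(cc)$rank < 2L) {
      abort("points are collinear; use method = 'idw'")
    }
  } else if (n < 1L) {
    abort("no points to interpolate")
  }
  rx <- range(px); ry <- range(py)
  pad <- function(r) if (diff(r) == 0) r + c(-0.5, 0.5) else r
  rx <- pad(rx); ry <- pad(ry)
  xo <- seq(rx[1], rx[2], length.out = n_grid)
  yo <- seq(ry[1], ry[2], length.out = n_grid)
  grid <- expand.grid(x = xo, y = yo, KEEP.OUT.ATTRS = FALSE)
  z <- rep(NA_real_, nrow(grid))
  if (method == "linear") {
    li <- interp::interp(x = px, y = py, z = ps, xo = xo, yo = yo,
                         method = "linear", duplicate = "mean")
    # interp returns z[xo, yo]; expand.grid varies x fastest
    z <- as.vector(li$z)
  }
  idw <- function(gx, gy) {
    d2 <- (px - gx)^2 + (py - gy)^2
    if (any(d2 < 1e-18)) return(ps[which.min(d2)])
    w <- 1 / d2^(idw_power / 2)
    sum(w * ps) / sum(w)
  }
  need <- which(is.na(z))
  for (k in need) z[k] <- idw(grid$x[k], grid$y[k])
  # exactness at data nodes
  for (p in seq_len(n)) {
    hit <- which(abs(grid$x - px[p]) < 1e-9 & abs(grid$y - py[p]) < 1e-9)
    if (length(hit) > 0L) z[hit] <- ps[p]
  }
  out <- tibble(x = grid$x, y = grid$y, S_interp = z)
  attr(out, "method") <- method
  attr(out, "n_grid") <- n_grid
  class(out) <- c("landscape_surface", class(out))
  out
}

#' Plot an evolutionary landscape
#'
#' Filled-contour surface of interpolated compatibility with the embedded
#' sequences overlaid (coloured by family when a `family` column is
#' present).
#'
#' @param surface A [surface_interpolate()] result.
#' @param points Optional data frame with `PC1`, `PC2` and optionally
#'   `family`.
#' @return A ggplot object.
#' @export
plot_landscape <- function(surface, points = NULL) {
  p <- ggplot2::ggplot(surface, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$S_interp)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$S_interp),
                          colour = "white", alpha = 0.4) +
    ggplot2::scale_fill_viridis_c(name = "S") +
    ggplot2::labs(x = "PC1", y = "PC2") +
    ggplot2::theme_minimal()
  if (!is.null(points)) {
    points <- as.data.frame(points)
    if ("family" %in% names(points)) {
      p <- p + ggplot2::geom_point(
        data = points,
        ggplot2::aes(x = .data$PC1, y = .data$PC2, shape = .data$family),
        colour = "black")
    } else {
      p <- p + ggplot2::geom_point(
        data = points, ggplot2::aes(x = .data$PC1, y = .data$PC2),
        colour = "black")
    }
  }
  p
}

#' @export
autoplot.landscape_surface <- function(object, points = NULL, ...) {
  plot_landscape(object, points = points)
}

#' Virtual sequences densifying a landscape
#'
#' Seeded single- and double-point mutants of the input sequences, used to
#' densify the sequence space before interpolation. Gap columns are left
#' untouched; mutated positions get a uniformly drawn different residue.
#'
#' @param seqs Character vector of (gapped) sequences.
#' @param n Number of virtual sequences.
#' @param seed Integer seed.
#' @return Character vector of `n` mutated sequences named `virtual_k`.
#' @export
virtual_sequences <- function(seqs, n = 100, seed = 1) {
  set.seed(seed)
  out <- character(n)
  for (k in seq_len(n)) {
    s <- strsplit(sample(seqs, 1), "")[[1]]
    aa_pos <- which(s %in% AA_ALPHABET)
    n_mut <- min(sample(1:2, 1), length(aa_pos))
    for (p in sample(aa_pos, n_mut)) {
      s[p] <- sample(setdiff(AA_ALPHABET, s[p]), 1)
    }
    out[k] <- paste(s, collapse = "")
  }
  setNames(out, paste0("virtual_", seq_len(n)))
}
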