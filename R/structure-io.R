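#' Read backbone coordinates of one chain from a PDB file
#'
#' Parses the ATOM records of a PDB entry (via [bio3d::read.pdb()]) and
#' returns the N/CA/C backbone trace of one chain, one row per residue in
#' file order. Residues missing any of the three backbone atoms are kept but
#' flagged `complete = FALSE`; they never contribute dihedral angles.
#' HETATM records are skipped. Alternate locations are resolved by keeping
#' the highest-occupancy atom (first on ties). Nonstandard residues are
#' mapped to `'X'`.
#'
#' @param pdb Path to a PDB file, or a character scalar holding PDB-format
#'   text (detected by an embedded newline).
#' @param chain_id Chain identifier to extract (single character).
#' @param structure_id Identifier recorded as the segment source; defaults to
#'   the file name without extension (or `"struct"` for literal text input).
#'
#' @return A tibble of class `backbone_chain` with columns `resnum` (author
#'   numbering), `ins` (insertion code), `aa` (one-letter code or `'X'`),
#'   `complete`, and the nine coordinate columns `n_x..c_z` in Angstrom.
#'   Attributes `structure_id` and `chain_id` carry provenance.
#' @export
read_backbone <- function(pdb, chain_id, structure_id = NULL) {
  stopifnot(is.character(pdb), length(pdb) == 1L)
  if (grepl("\n", pdb, fixed = TRUE)) {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(pdb, path)
    structure_id <- structure_id %||% "struct"
  } else {
    path <- pdb
    structure_id <- structure_id %||% sub("\\.(pdb|ent)$", "",
                                          basename(path), ignore.case = TRUE)
  }
  p <- suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE,
                                        verbose = FALSE))
  at <- p$atom[p$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) abort("empty structure: no ATOM records")
  if (!chain_id %in% at$chain) {
    abort(sprintf("chain not found: '%s'", chain_id))
  }
  at <- at[at$chain == chain_id & at$elety %in% c("N", "CA", "C"), ,
           drop = FALSE]
  at$ins[is.na(at$ins)] <- ""
  at$o[is.na(at$o)] <- 1
  rkey <- paste(at$resno, at$ins, sep = "|")
  res_order <- unique(rkey)

  rows <- lapply(res_order, function(k) {
    ra <- at[rkey == k, , drop = FALSE]
    coords <- list(N = NULL, CA = NULL, C = NULL)
    for (ety in names(coords)) {
      sel <- ra[ra$elety == ety, , drop = FALSE]
      if (nrow(sel) > 0L) {
        # altloc rule: highest occupancy, first wins on a tie
        sel <- sel[which.max(sel$o), , drop = FALSE]
        coords[[ety]] <- c(sel$x, sel$y, sel$z)
      }
    }
    complete <- !any(vapply(coords, is.null, logical(1)))
    coords <- lapply(coords, function(v) v %||% rep(NA_real_, 3))
    aa <- suppressWarnings(bio3d::aa321(ra$resid[1]))
    if (is.na(aa) || !aa %in% AA_ALPHABET) aa <- "X"
    tibble(
      resnum = ra$resno[1], ins = ra$ins[1], aa = aa, complete = complete,
      n_x = coords$N[1], n_y = coords$N[2], n_z = coords$N[3],
      ca_x = coords$CA[1], ca_y = coords$CA[2], ca_z = coords$CA[3],
      c_x = coords$C[1], c_y = coords$C[2], c_z = coords$C[3]
    )
  })
  out <- bind_rows(rows)
  new_backbone_chain(out, structure_id = structure_id, chain_id = chain_id)
}

new_backbone_chain <- function(df, structure_id, chain_id) {
  out <- as_tibble(df)
  attr(out, "structure_id") <- structure_id
  attr(out, "chain_id") <- chain_id
  class(out) <- c("backbone_chain", class(out))
  out
}

#' @export
print.backbone_chain <- function(x, ...) {
  cat(sprintf("<backbone_chain> %s chain %s: %d residues (%d complete)\n",
              attr(x, "structure_id"), attr(x, "chain_id"), nrow(x),
              sum(x$complete)))
  NextMethod()
}

chain_coords <- function(chain, what = c("n", "ca", "c")) {
  what <- match.arg(what)
  as.matrix(chain[, paste0(what, c("_x", "_y", "_z"))])
}

#' Torsion angle of four points
#'
#' Signed dihedral angle about the b-c axis of points a-b-c-d, IUPAC sign
#' convention, in degrees in the interval (-180, 180].
#'
#' @param a,b,c,d Numeric length-3 coordinate vectors.
#' @return Angle in degrees.
#' @export
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  y <- sqrt(sum(b2^2)) * sum(b1 * n2)
  x <- sum(n1 * n2)
  wrap_angle(atan2(y, x) * 180 / pi)
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Backbone phi/psi dihedral angles of a chain
#'
#' phi of residue k uses C(k-1)-N(k)-CA(k)-C(k); psi of residue k uses
#' N(k)-CA(k)-C(k)-N(k+1). An angle is undefined (`NA` with its flag `FALSE`)
#' when any participating residue is incomplete, at the chain termini, or
#' across a chain break (consecutive CA-CA distance > `break_dist`).
#'
#' @param chain A [read_backbone()] result.
#' @param break_dist Chain-break threshold on consecutive CA-CA distance in
#'   Angstrom (default 4.5).
#' @return A tibble with `resnum`, `aa`, `phi`, `psi`, `phi_def`, `psi_def`.
#' @export
compute_dihedrals <- function(chain, break_dist = 4.5) {
  n <- nrow(chain)
  stopifnot(n >= 1L)
  Nc <- chain_coords(chain, "n")
  CAc <- chain_coords(chain, "ca")
  Cc <- chain_coords(chain, "c")
  ok <- chain$complete
  # contiguity between residue k and k+1
  contig <- rep(FALSE, max(n - 1L, 0L))
  if (n >= 2L) {
    for (k in seq_len(n - 1L)) {
      if (ok[k] && ok[k + 1L]) {
        contig[k] <- sqrt(sum((CAc[k, ] - CAc[k + 1L, ])^2)) <= break_dist
      }
    }
  }
  phi <- rep(NA_real_, n); psi <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    if (k > 1L && ok[k] && ok[k - 1L] && contig[k - 1L]) {
      phi[k] <- dihedral_angle(Cc[k - 1L, ], Nc[k, ], CAc[k, ], Cc[k, ])
    }
    if (k < n && ok[k] && ok[k + 1L] && contig[k]) {
      psi[k] <- dihedral_angle(Nc[k, ], CAc[k, ], Cc[k, ], Nc[k + 1L, ])
    }
  }
  tibble(resnum = chain$resnum, aa = chain$aa,
         phi = phi, psi = psi,
         phi_def = !is.na(phi), psi_def = !is.na(psi))
}

#' Harvest sliding-window dihedral segments from a chain
#'
#' Slides an L-residue window along the chain with step one and keeps every
#' window whose 2L dihedral angles (phi and psi at all L positions, the
#' terminal phi/psi taken from the flanking residues) are all defined.
#' Windows touching incomplete residues, chain breaks, or the chain termini
#' are dropped. Overlapping windows are intentional: consecutive starts
#' share L-1 residues.
#'
#' @param chain A [read_backbone()] (or [backbone_from_dihedrals()]) result.
#' @param L Window length in residues (9 and 15 are the conventional
#'   choices).
#' @param break_dist Passed to [compute_dihedrals()].
#' @return A tibble, one row per segment, with columns `source`, `chain`,
#'   `start` (1-based index into the chain), `start_resnum`, `end_resnum`,
#'   `range` (rendered residue range), `sequence`, and list-columns `phi`,
#'   `psi` of length L.
#' @export
extract_segments <- function(chain, L = 15, break_dist = 4.5) {
  stopifnot(L >= 2)
  n <- nrow(chain)
  src <- attr(chain, "structure_id") %||% "struct"
  cid <- attr(chain, "chain_id") %||% "A"
  empty <- tibble(source = character(), chain = character(),
                  start = integer(), start_resnum = integer(),
                  end_resnum = integer(), range = character(),
                  sequence = character(), phi = list(), psi = list())
  if (n < L) return(empty)
  dh <- compute_dihedrals(chain, break_dist = break_dist)
  rows <- list()
  resnum <- chain$resnum
  aa <- chain$aa
  for (s in seq_len(n - L + 1L)) {
    idx <- s:(s + L - 1L)
    if (all(dh$phi_def[idx]) && all(dh$psi_def[idx])) {
      rows[[length(rows) + 1L]] <- tibble(
        source = src, chain = cid, start = s,
        start_resnum = resnum[s], end_resnum = resnum[s + L - 1L],
        range = render_residue_range(src, cid, resnum[s], resnum[s + L - 1L]),
        sequence = paste(aa[idx], collapse = ""),
        phi = list(dh$phi[idx]), psi = list(dh$psi[idx])
      )
    }
  }
  if (length(rows) == 0L) return(empty)
  bind_rows(rows)
}

#' Residue-range notation
#'
#' Renders and parses the `"1jnrA:614-629"` style notation: structure id,
#' chain id, colon, start-end in author numbering (1-based, inclusive).
#'
#' @param structure_id,chain_id,start,end Range components.
#' @return `render_residue_range()`: a string. `parse_residue_range()`: a
#'   list with fields `structure_id`, `chain_id`, `start`, `end`.
#' @export
render_residue_range <- function(structure_id, chain_id, start, end) {
  stopifnot(end >= start)
  sprintf("%s%s:%d-%d", structure_id, chain_id, as.integer(start),
          as.integer(end))
}

#' @rdname render_residue_range
#' @param x A rendered range string.
#' @export
parse_residue_range <- function(x) {
  m <- regmatches(x, regexec("^(.+)(.):(-?[0-9]+)-(-?[0-9]+)$", x))[[1]]
  if (length(m) != 5L) abort(sprintf("cannot parse residue range '%s'", x))
  out <- list(structure_id = m[2], chain_id = m[3],
              start = as.integer(m[4]), end = as.integer(m[5]))
  if (out$end < out$start) abort("residue range has end < start")
  out
}

#' Optimal-superposition C-alpha RMSD (Kabsch)
#'
#' Least-squares superposition of two equal-size point sets by the Kabsch
#' algorithm (SVD with the determinant correction, so only proper rotations
#' are used) followed by the root-mean-square deviation.
#'
#' @param coords_a,coords_b Numeric n x 3 matrices of coordinates in
#'   Angstrom, n >= 3, matched row by row.
#' @return RMSD in Angstrom (non-negative scalar).
#' @export
kabsch_rmsd <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  if (!all(dim(coords_a) == dim(coords_b)) || ncol(coords_a) != 3L) {
    abort("length mismatch: coordinate sets must both be n x 3")
  }
  if (nrow(coords_a) < 3L) abort("need at least 3 points")
  if (!all(is.finite(coords_a)) || !all(is.finite(coords_b))) {
    abort("coordinates must be finite")
  }
  A <- sweep(coords_a, 2, colMeans(coords_a))
  B <- sweep(coords_b, 2, colMeans(coords_b))
  s <- svd(crossprod(B, A))           # 3x3
  d <- sign(det(s$u %*% t(s$v)))
  if (d == 0) d <- 1
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- A %*% t(R)
  sqrt(mean(rowSums((fitted - B)^2)))
}

#' Write a segment table as TSV
#'
#' Wide layout: `source`, `chain`, `start`, `end`, `sequence`,
#' `phi_1..phi_L`, `psi_1..psi_L`.
#'
#' @param segments Output of [extract_segments()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_segments_tsv <- function(segments, path) {
  L <- length(segments$phi[[1]])
  ang <- cbind(
    do.call(rbind, segments$phi),
    do.call(rbind, segments$psi)
  )
  colnames(ang) <- c(paste0("phi_", seq_len(L)), paste0("psi_", seq_len(L)))
  flat <- cbind(
    data.frame(source = segments$source, chain = segments$chain,
               start = segments$start_resnum, end = segments$end_resnum,
               sequence = segments$sequence, stringsAsFactors = FALSE),
    as.data.frame(signif(ang, 7))
  )
  write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_segments_tsv
#' @return `read_segments_tsv()`: the segment tibble.
#' @export
read_segments_tsv <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  phi_cols <- grep("^phi_", names(tab))
  psi_cols <- grep("^psi_", names(tab))
  L <- length(phi_cols)
  stopifnot(L >= 1L, length(psi_cols) == L)
  n <- nrow(tab)
  tibble(
    source = as.character(tab$source), chain = as.character(tab$chain),
    start = tab$start, start_resnum = tab$start, end_resnum = tab$end,
    range = vapply(seq_len(n), function(i) {
      render_residue_range(tab$source[i], tab$chain[i], tab$start[i],
                           tab$end[i])
    }, character(1)),
    sequence = tab$sequence,
    phi = lapply(seq_len(n), function(i) as.numeric(tab[i, phi_cols])),
    psi = lapply(seq_len(n), function(i) as.numeric(tab[i, psi_cols]))
  )
}
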