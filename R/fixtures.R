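# ideal trans peptide geometry (Angstrom / degrees) used by the backbone
# builder: bonds N-CA 1.458, CA-C 1.525, C-N 1.329; angles N-CA-C 111.2,
# CA-C-N 116.2, C-N-CA 121.7; omega fixed at 180.
IDEAL_GEOM <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7, omega = 180
)

# natural-extension-of-reference-frame placement: position of D given
# A, B, C, the bond length r = |C-D|, the bond angle theta = B-C-D and the
# torsion tau = dihedral A-B-C-D (degrees)
nerf_place <- function(a, b, c, r, theta, tau) {
  th <- theta * pi / 180; ta <- tau * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a; ab <- ab / sqrt(sum(ab^2))
  n <- cross3(ab, bc); n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d2 <- c(-r * cos(th), r * sin(th) * cos(ta), r * sin(th) * sin(ta))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Build an ideal-geometry backbone from phi/psi angles
#'
#' Sequential internal-coordinate construction of an N/CA/C backbone with
#' ideal bond lengths and angles and trans peptide bonds (omega = 180), so
#' that [compute_dihedrals()] of the result recovers the inputs (phi of the
#' first and psi of the last residue are structurally undefined and ignored;
#' they may be `NA`).
#'
#' @param phi,psi Equal-length angle vectors in degrees, each in
#'   (-180, 180].
#' @param sequence Optional one-letter sequence of the same length (default
#'   all-alanine).
#' @param structure_id,chain_id Provenance labels.
#' @return A `backbone_chain` tibble (see [read_backbone()]).
#' @export
backbone_from_dihedrals <- function(phi, psi, sequence = NULL,
                                    structure_id = "synthetic",
                                    chain_id = "A") {
  n <- length(phi)
  if (length(psi) != n) abort("phi and psi must have equal length")
  stopifnot(n >= 2)
  used <- c(phi[-1], psi[-n])
  if (anyNA(used) || any(used <= -180 | used > 180)) {
    abort("angles must be in (-180, 180]")
  }
  sequence <- sequence %||% strrep("A", n)
  if (nchar(sequence) != n) abort("sequence length mismatch")
  g <- IDEAL_GEOM
  N <- matrix(NA_real_, n, 3); CA <- matrix(NA_real_, n, 3)
  C <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_n_ca, 0, 0)
  ang <- (180 - g$a_n_ca_c) * pi / 180
  C[1, ] <- CA[1, ] + g$b_ca_c * c(cos(ang), sin(ang), 0)
  for (k in seq_len(n - 1L)) {
    N[k + 1L, ] <- nerf_place(N[k, ], CA[k, ], C[k, ],
                              g$b_c_n, g$a_ca_c_n, psi[k])
    CA[k + 1L, ] <- nerf_place(CA[k, ], C[k, ], N[k + 1L, ],
                               g$b_n_ca, g$a_c_n_ca, g$omega)
    C[k + 1L, ] <- nerf_place(C[k, ], N[k + 1L, ], CA[k + 1L, ],
                              g$b_ca_c, g$a_n_ca_c, phi[k + 1L])
  }
  aa <- strsplit(sequence, "")[[1]]
  df <- tibble(
    resnum = seq_len(n), ins = "", aa = aa, complete = TRUE,
    n_x = N[, 1], n_y = N[, 2], n_z = N[, 3],
    ca_x = CA[, 1], ca_y = CA[, 2], ca_z = CA[, 3],
    c_x = C[, 1], c_y = C[, 2], c_z = C[, 3]
  )
  new_backbone_chain(df, structure_id = structure_id, chain_id = chain_id)
}

#' Write a backbone chain as a minimal PDB file
#'
#' @param chain A `backbone_chain`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_backbone_pdb <- function(chain, path) {
  ok <- chain$complete
  xyz <- c()
  elety <- c(); resno <- c(); resid <- c()
  aa3 <- vapply(chain$aa, function(a) {
    r <- suppressWarnings(bio3d::aa123(a))
    if (is.na(r) || a == "X") "UNK" else r
  }, character(1))
  for (k in which(ok)) {
    xyz <- c(xyz, as.numeric(chain[k, c("n_x", "n_y", "n_z",
                                        "ca_x", "ca_y", "ca_z",
                                        "c_x", "c_y", "c_z")]))
    elety <- c(elety, c("N", "CA", "C"))
    resno <- c(resno, rep(chain$resnum[k], 3))
    resid <- c(resid, rep(aa3[k], 3))
  }
  bio3d::write.pdb(file = path, xyz = xyz, resno = resno, resid = resid,
                   elety = elety, chain = rep(attr(chain, "chain_id") %||% "A",
                                              length(elety)))
  invisible(path)
}

#' Generate a seeded population of segments around planted cluster centroids
#'
#' Draws `k_clusters` centroid angle vectors in (phi, psi)-space with
#' guaranteed pairwise separation, then scatters `members_per_cluster`
#' members around each with wrapped Gaussian angular noise. Member sequences
#' follow a per-cluster positional residue bias (the preferred residue with
#' probability `bias`, otherwise uniform over the rest) so cluster profiles
#' are informative. The member order is shuffled. Centroids are constructed
#' per angle coordinate as equally spaced values (spacing 360/k) with a
#' random rotation and a random cluster-to-offset assignment, which yields
#' exact pairwise separation 360/k degrees in the wrapped-RMS metric;
#' proposals are redrawn until `min_separation` is met (error after 10,000
#' failures).
#'
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments.
#' @param L Segment length (default 15).
#' @param k_clusters Number of planted clusters (default 3).
#' @param members_per_cluster Members per cluster (default 50).
#' @param angular_noise_deg Noise s.d. per angle in degrees (default 3).
#' @param min_separation Required pairwise centroid distance in degrees
#'   (default `min(4 * 30, 360 / k_clusters)`).
#' @param bias Probability of the preferred residue per position (default
#'   0.7).
#' @return List with `segments` (segment tibble as from
#'   [extract_segments()]), `labels` (true cluster of each segment),
#'   `centroids` (k x 2L angle matrix).
#' @export
generate_segment_population <- function(seed, L = 15, k_clusters = 3,
                                        members_per_cluster = 50,
                                        angular_noise_deg = 3,
                                        min_separation = NULL,
                                        bias = 0.7) {
  stopifnot(k_clusters >= 1, members_per_cluster >= 1,
            angular_noise_deg >= 0)
  min_separation <- min_separation %||% min(120, 360 / k_clusters)
  set.seed(seed)
  k <- k_clusters
  draw_centroids <- function() {
    base <- runif(2 * L, -180, 180)
    cent <- matrix(NA_real_, k, 2 * L)
    for (c_ in seq_len(2 * L)) {
      offs <- (sample(k) - 1L) * (360 / k)
      cent[, c_] <- wrap_angle(base[c_] + offs)
    }
    cent
  }
  cent <- NULL
  if (k == 1L) {
    cent <- matrix(runif(2 * L, -180, 180), 1)
  } else {
    for (try in seq_len(10000L)) {
      cand <- draw_centroids()
      dmin <- Inf
      for (a in seq_len(k - 1L)) {
        for (b in (a + 1L):k) {
          dmin <- min(dmin, sqrt(mean(wrap_angle(cand[a, ] - cand[b, ])^2)))
        }
      }
      if (dmin >= min_separation) { cent <- cand; break }
    }
    if (is.null(cent)) abort("cannot satisfy centroid separation in 10,000 draws")
  }
  labels <- rep(seq_len(k), each = members_per_cluster)
  n <- length(labels)
  ang <- cent[labels, , drop = FALSE] +
    matrix(rnorm(n * 2 * L, 0, angular_noise_deg), n)
  ang <- wrap_angle(ang)
  ang[ang == -180] <- 180
  pref <- matrix(sample(AA_ALPHABET, k * L, replace = TRUE), k, L)
  seqs <- vapply(seq_len(n), function(i) {
    picks <- vapply(seq_len(L), function(p) {
      if (runif(1) < bias) pref[labels[i], p]
      else sample(setdiff(AA_ALPHABET, pref[labels[i], p]), 1)
    }, character(1))
    paste(picks, collapse = "")
  }, character(1))
  ord <- sample(n)
  ang <- ang[ord, , drop = FALSE]
  labels <- labels[ord]
  seqs <- seqs[ord]
  segments <- tibble(
    source = "sim", chain = "A", start = seq_len(n),
    start_resnum = seq_len(n), end_resnum = seq_len(n) + L - 1L,
    range = vapply(seq_len(n), function(i) {
      render_residue_range("sim", "A", i, i + L - 1L)
    }, character(1)),
    sequence = seqs,
    phi = lapply(seq_len(n), function(i) ang[i, seq_len(L)]),
    psi = lapply(seq_len(n), function(i) ang[i, L + seq_len(L)])
  )
  list(segments = segments, labels = labels, centroids = cent)
}

# symmetric-Dirichlet(alpha) composition vector over the 20 residues
rdirichlet20 <- function(alpha = 0.5) {
  g <- stats::rgamma(20, shape = alpha)
  g <- pmax(g, 1e-12)
  g / sum(g)
}

#' Generate a mutated sequence family, its PSSM, decoys and a planted target
#'
#' Emulates the inputs of a library search with known ground truth. The
#' family is `family_size` copies of `consensus`, each site mutated to a
#' uniformly drawn different residue with probability
#' `per_site_mutation_rate`. The family PSSM holds log-odds
#' `ln(f_i(j) / b(j))` with a uniform background and one pseudo-count (the
#' pseudo-count stands in for the machinery of iterative profile builders
#' and is never used in structure-profile propensities). The planted target
#' embeds the family PSSM between decoy columns at a recorded offset; decoys
#' are i.i.d. symmetric-Dirichlet(0.5) composition columns converted to
#' log-odds, at lengths drawn from `decoy_length_range`. Fully seeded and
#' deterministic.
#'
#' @param consensus Consensus sequence over the canonical alphabet.
#' @param seed Integer seed.
#' @param family_size Number of family sequences (default 50).
#' @param per_site_mutation_rate Per-site mutation probability in \[0, 1\]
#'   (default 0.1).
#' @param n_decoys Number of decoy profiles (default 200).
#' @param decoy_length_range Inclusive length range of decoys and of the
#'   planted target (default c(30, 120)).
#' @param family_sequences Optional explicit family (equal-length sequences
#'   over the canonical alphabet); when given, the mutation step is skipped
#'   and these sequences define the planted PSSM (e.g. the member sequences
#'   of a structural cluster).
#' @return List with `library` (named list of `sequence_profile`s including
#'   the planted target), `planted_id`, `offset` (first target column of the
#'   embedded family PSSM), `family` (character vector), `family_pssm` (the
#'   unembedded family profile).
#' @export
generate_family_library <- function(consensus, seed, family_size = 50,
                                    per_site_mutation_rate = 0.1,
                                    n_decoys = 200,
                                    decoy_length_range = c(30, 120),
                                    family_sequences = NULL) {
  chars <- strsplit(toupper(consensus), "")[[1]]
  if (!all(chars %in% AA_ALPHABET)) abort("consensus must use the canonical alphabet")
  stopifnot(family_size >= 1, n_decoys >= 0,
            per_site_mutation_rate >= 0, per_site_mutation_rate <= 1)
  set.seed(seed)
  L <- length(chars)
  if (is.null(family_sequences)) {
    family <- vapply(seq_len(family_size), function(i) {
      s <- chars
      mut <- runif(L) < per_site_mutation_rate
      for (p in which(mut)) s[p] <- sample(setdiff(AA_ALPHABET, s[p]), 1)
      paste(s, collapse = "")
    }, character(1))
  } else {
    family <- toupper(family_sequences)
    if (any(nchar(family) != L)) abort("family sequence length mismatch")
    family_size <- length(family)
  }

  fm <- do.call(rbind, strsplit(family, ""))
  counts <- t(vapply(seq_len(L), function(i) {
    as.integer(table(factor(fm[, i], levels = AA_ALPHABET)))
  }, integer(20)))
  f <- (counts + 1) / (family_size + 20)          # one pseudo-count
  fam_scores <- log(f / 0.05)
  argmax_seq <- function(scores) {
    paste(AA_ALPHABET[apply(scores, 1, which.max)], collapse = "")
  }
  family_pssm <- new_sequence_profile("family", argmax_seq(fam_scores),
                                      fam_scores)

  decoy_scores <- function(len) {
    t(vapply(seq_len(len), function(i) log(rdirichlet20(0.5) / 0.05),
             double(20)))
  }
  lens <- sample(seq(decoy_length_range[1], decoy_length_range[2]),
                 n_decoys + 1L, replace = TRUE)
  target_len <- max(lens[1], L + 2L)
  offset <- sample.int(target_len - L + 1L, 1)
  planted_scores <- decoy_scores(target_len)
  planted_scores[offset:(offset + L - 1L), ] <- fam_scores
  planted <- new_sequence_profile("planted", argmax_seq(planted_scores),
                                  planted_scores)
  library <- vector("list", n_decoys + 1L)
  ids <- character(n_decoys + 1L)
  library[[1]] <- planted; ids[1] <- "planted"
  for (d in seq_len(n_decoys)) {
    sc <- decoy_scores(lens[d + 1L])
    library[[d + 1L]] <- new_sequence_profile(sprintf("decoy_%03d", d),
                                              argmax_seq(sc), sc)
    ids[d + 1L] <- sprintf("decoy_%03d", d)
  }
  names(library) <- ids
  list(library = library, planted_id = "planted", offset = offset,
       family = family, family_pssm = family_pssm)
}
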