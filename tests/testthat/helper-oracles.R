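# Independent oracles and tiny fixture builders shared across test files.

# Exhaustive alignment enumeration: best score over all non-empty monotone
# aligned-pair sets, charging internal gap runs open + k*extend and leaving
# all terminal runs free. Independent of the package's DP.
oracle_align_score <- function(sim, open, extend) {
  n <- nrow(sim); m <- ncol(sim)
  best <- -Inf
  rec <- function(li, lj, score, first) {
    if (li >= n || lj >= m) return(invisible())
    for (a in (li + 1L):n) {
      for (b in (lj + 1L):m) {
        cost <- 0
        if (!first) {
          gq <- a - li - 1L; gt <- b - lj - 1L
          if (gq > 0L) cost <- cost + open + gq * extend
          if (gt > 0L) cost <- cost + open + gt * extend
        }
        s2 <- score + sim[a, b] - cost
        if (s2 > best) best <<- s2
        rec(a, b, s2, FALSE)
      }
    }
  }
  rec(0L, 0L, 0, TRUE)
  best
}

# Pearson column kernel computed independently of the package
oracle_similarity <- function(Q, T_) {
  outer(seq_len(nrow(Q)), seq_len(nrow(T_)),
        Vectorize(function(i, j) {
          if (sd(Q[i, ]) == 0 || sd(T_[j, ]) == 0) 0 else cor(Q[i, ], T_[j, ])
        }))
}

# Step-by-step hand simulation of the single-pass clustering recipe:
# (i) first segment founds a cluster; (ii) compute distances to all cluster
# centroids; (iii) join the nearest if within the threshold, else found a new
# cluster; (iv) repeat. Centroids are naive circular means recomputed from
# scratch after every join.
oracle_leader_cluster <- function(phi_list, psi_list, d_th) {
  n <- length(phi_list)
  members <- list()
  assignment <- integer(n)
  centroid_of <- function(idx) {
    ph <- do.call(rbind, phi_list[idx]) * pi / 180
    ps <- do.call(rbind, psi_list[idx]) * pi / 180
    cphi <- atan2(colSums(sin(ph)), colSums(cos(ph))) * 180 / pi
    cpsi <- atan2(colSums(sin(ps)), colSums(cos(ps))) * 180 / pi
    list(phi = cphi, psi = cpsi)
  }
  for (i in seq_len(n)) {
    if (length(members) == 0L) {
      members[[1]] <- i; assignment[i] <- 1L
      next
    }
    d <- vapply(members, function(idx) {
      cen <- centroid_of(idx)
      dihedral_distance(phi_list[[i]], psi_list[[i]], cen$phi, cen$psi)
    }, double(1))
    j <- which.min(d)
    if (d[j] <= d_th) {
      members[[j]] <- c(members[[j]], i)
      assignment[i] <- j
    } else {
      members[[length(members) + 1L]] <- i
      assignment[i] <- length(members)
    }
  }
  assignment
}

# Segment tibble from explicit angle vectors (one row per segment)
make_segments <- function(phi_list, psi_list, sequences = NULL) {
  n <- length(phi_list)
  L <- length(phi_list[[1]])
  sequences <- sequences %||% rep(strrep("A", L), n)
  tibble::tibble(
    source = "toy", chain = "A", start = seq_len(n),
    start_resnum = seq_len(n), end_resnum = seq_len(n) + L - 1L,
    range = paste0("toyA:", seq_len(n), "-", seq_len(n) + L - 1L),
    sequence = sequences,
    phi = phi_list, psi = psi_list
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# structure profile with propensities set directly (for algebraic toys)
toy_profile <- function(pro_list) {
  L <- length(pro_list)
  members <- rep(strrep("A", L), 2)
  bg <- stats::setNames(rep(0.05, 20), AA_ALPHABET)
  prof <- build_structure_profile(members, bg, cluster_id = "toy")
  prof$pro[, ] <- 0
  for (i in seq_len(L)) {
    for (res in names(pro_list[[i]])) {
      prof$pro[i, res] <- pro_list[[i]][[res]]
    }
  }
  prof
}

# hand-rolled fixed-width PDB ATOM/HETATM line
pdb_line <- function(serial, name, resid, chain, resno, x, y, z,
                     occ = 1, alt = " ", record = "ATOM  ") {
  name_f <- if (nchar(name) < 4L) sprintf(" %-3s", name) else name
  sprintf("%s%5d %4s%s%3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          record, serial, name_f, alt, resid, chain, resno, x, y, z, occ, 0)
}

# minimal well-formed PDB text: n residues of backbone-only glycine laid on a
# line, optionally dropping atoms / adding altlocs
simple_pdb_text <- function(n = 3, chain = "A", drop = NULL) {
  lines <- character(0)
  serial <- 1L
  for (k in seq_len(n)) {
    for (atom in c("N", "CA", "C")) {
      if (!is.null(drop) && any(drop$res == k & drop$atom == atom)) next
      base <- (k - 1) * 3.5
      off <- match(atom, c("N", "CA", "C")) * 0.9
      lines <- c(lines, pdb_line(serial, atom, "GLY", chain, k,
                                 base + off, 0.5 * off, 0.1 * serial))
      serial <- serial + 1L
    }
  }
  paste(c(lines, "END"), collapse = "\n")
}

# score of an explicit aligned-pair set under the free-terminal-gap model
path_score <- function(pairs, sim, open, extend) {
  s <- sum(sim[cbind(pairs$query_pos, pairs$target_pos)])
  if (nrow(pairs) > 1L) {
    for (k in 2:nrow(pairs)) {
      gq <- pairs$query_pos[k] - pairs$query_pos[k - 1L] - 1L
      gt <- pairs$target_pos[k] - pairs$target_pos[k - 1L] - 1L
      if (gq > 0L) s <- s - open - gq * extend
      if (gt > 0L) s <- s - open - gt * extend
    }
  }
  s
}

R_z <- function(th) {
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
}

expect_wrapped_equal <- function(a, b, tol = 1e-6) {
  d <- (a - b + 180) %% 360 - 180
  expect_lt(max(abs(d), na.rm = TRUE), tol)
}
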