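#' Background amino-acid composition of a segment set
#'
#' Frequency of each canonical amino acid over all residues of all input
#' segments; `'X'` and other non-canonical symbols are not counted.
#'
#' @param segments Segment tibble (needs a `sequence` column), or a character
#'   vector of sequences.
#' @return Named numeric vector of length 20 summing to 1, in canonical
#'   alphabet order.
#' @export
compute_background <- function(segments) {
  seqs <- if (is.character(segments)) segments else segments$sequence
  chars <- unlist(strsplit(seqs, ""))
  chars <- chars[chars %in% AA_ALPHABET]
  if (length(chars) == 0L) abort("no countable residues")
  counts <- table(factor(chars, levels = AA_ALPHABET))
  setNames(as.numeric(counts) / sum(counts), AA_ALPHABET)
}

#' Build a structure-based propensity profile from cluster member sequences
#'
#' Per window position i and amino acid j the propensity is
#' \deqn{pro_i(j) = p_i(j) / p(j)} where \eqn{p_i(j)} is the observed
#' frequency of j at position i over the cluster members and \eqn{p(j)} the
#' background composition. Raw counts only: no sequence weights and no
#' pseudo-counts. `'X'` residues are excluded from both the numerator and
#' the per-position denominator. Amino acids with zero background get
#' propensity 0 by convention.
#'
#' @param members Character vector of member sequences, all of length L.
#' @param background Named 20-vector summing to 1 (see
#'   [compute_background()]).
#' @param cluster_id Identifier stored in the profile.
#' @return An object of class `structure_profile`: list with `cluster_id`,
#'   `L`, `alphabet`, `counts` (L x 20 integer), `p` (L x 20 frequencies),
#'   `background`, `pro` (L x 20 propensities).
#' @export
build_structure_profile <- function(members, background,
                                    cluster_id = "cluster_1") {
  stopifnot(length(members) >= 1L)
  lens <- nchar(members)
  L <- lens[1]
  if (any(lens != L)) abort("member length mismatch")
  if (abs(sum(background) - 1) > 1e-6) abort("background must sum to 1")
  background <- background[AA_ALPHABET]
  mat <- do.call(rbind, strsplit(members, ""))
  counts <- matrix(0L, nrow = L, ncol = 20,
                   dimnames = list(NULL, AA_ALPHABET))
  for (i in seq_len(L)) {
    tab <- table(factor(mat[, i], levels = AA_ALPHABET))
    counts[i, ] <- as.integer(tab)
  }
  tot <- rowSums(counts)
  p <- counts / ifelse(tot > 0, tot, 1)
  pro <- sweep(p, 2, background, "/")
  pro[, background == 0] <- 0
  pro[p == 0] <- 0
  structure(list(cluster_id = cluster_id, L = L, alphabet = AA_ALPHABET,
                 counts = counts, p = p, background = background, pro = pro),
            class = "structure_profile")
}

#' @export
print.structure_profile <- function(x, ...) {
  cat(sprintf("<structure_profile> %s: L = %d, %d members at position 1\n",
              x$cluster_id, x$L, sum(x$counts[1, ])))
  invisible(x)
}

#' @export
print.sequence_profile <- function(x, ...) {
  cat(sprintf("<sequence_profile> %s: %d positions\n", x$id, nrow(x$scores)))
  invisible(x)
}

new_sequence_profile <- function(id, sequence, scores, frequencies = NULL) {
  scores <- as.matrix(scores)
  colnames(scores) <- AA_ALPHABET
  if (nrow(scores) != nchar(sequence)) abort("row count != sequence length")
  if (!all(is.finite(scores))) abort("non-finite profile scores")
  structure(list(id = id, sequence = sequence, scores = scores,
                 frequencies = frequencies),
            class = "sequence_profile")
}

#' Construct a sequence profile (PSSM) object
#'
#' @param id Identifier.
#' @param sequence Underlying one-letter sequence (may contain `'X'`).
#' @param scores Position x 20 log-odds matrix in canonical alphabet order.
#' @param frequencies Optional position x 20 frequency matrix.
#' @return A `sequence_profile` object.
#' @export
sequence_profile <- function(id, sequence, scores, frequencies = NULL) {
  new_sequence_profile(id, sequence, scores, frequencies)
}

#' Read a PSI-BLAST ASCII PSSM
#'
#' Parses the `-Q`/makemat-style ASCII matrix: a header row with 20 (or 40)
#' amino-acid letters, then one row per position holding the position index,
#' the query residue, 20 integer log-odds and optionally 20 percentage
#' frequencies. Columns are re-mapped from the file's letter order
#' (PSI-BLAST uses A R N D C Q E G H I L K M F P S T W Y V) to the canonical
#' alphabet order.
#'
#' @param text Path to the PSSM file, or its content as a character scalar
#'   with embedded newlines (or a character vector of lines).
#' @param id Identifier for the profile; defaults to the file name.
#' @return A `sequence_profile`.
#' @export
read_pssm <- function(text, id = NULL) {
  if (length(text) == 1L && !grepl("\n", text, fixed = TRUE) &&
      file.exists(text)) {
    id <- id %||% sub("\\.[^.]*$", "", basename(text))
    lines <- readLines(text)
  } else {
    lines <- if (length(text) > 1L) text else strsplit(text, "\n")[[1]]
    id <- id %||% "pssm"
  }
  lines <- trimws(lines, which = "right")
  toks <- lapply(lines, function(l) strsplit(trimws(l), "[[:space:]]+")[[1]])
  # header: the first line made only of single amino-acid letters
  is_header <- vapply(toks, function(t) {
    length(t) >= 20L && all(t %in% AA_ALPHABET)
  }, logical(1))
  if (!any(is_header)) abort("malformed PSSM: no alphabet header row")
  h <- which(is_header)[1]
  file_order <- toks[[h]][1:20]
  body <- toks[(h + 1):length(toks)]
  body <- body[vapply(body, function(t) {
    length(t) >= 2L && grepl("^[0-9]+$", t[1]) && t[2] %in% c(AA_ALPHABET, "X")
  }, logical(1))]
  if (length(body) == 0L) abort("malformed PSSM: empty body")
  n <- length(body)
  scores <- matrix(NA_real_, n, 20)
  freqs <- matrix(NA_real_, n, 20)
  seq_chars <- character(n)
  has_freq <- TRUE
  for (k in seq_len(n)) {
    t <- body[[k]]
    vals <- suppressWarnings(as.numeric(t[-(1:2)]))
    vals <- vals[!is.na(vals)]
    if (length(vals) < 20L) abort(sprintf("malformed PSSM row %d", k))
    seq_chars[k] <- t[2]
    scores[k, ] <- vals[1:20]
    if (length(vals) >= 40L) freqs[k, ] <- vals[21:40] / 100 else has_freq <- FALSE
  }
  perm <- match(AA_ALPHABET, file_order)
  new_sequence_profile(id, paste(seq_chars, collapse = ""),
                       scores[, perm, drop = FALSE],
                       if (has_freq) {
                         f <- freqs[, perm, drop = FALSE]
                         colnames(f) <- AA_ALPHABET
                         f
                       })
}

#' Write a sequence profile in PSI-BLAST ASCII layout
#'
#' Counterpart of [read_pssm()]; used for synthetic libraries and round-trip
#' tests. Scores are written with 6 significant digits in PSI-BLAST column
#' order.
#'
#' @param profile A `sequence_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(profile, path) {
  perm <- match(PSIBLAST_ORDER, AA_ALPHABET)
  sc <- profile$scores[, perm, drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("", sprintf("Last position-specific scoring matrix computed (%s)",
                           profile$id),
               paste(" ", paste(PSIBLAST_ORDER, collapse = "  "))), con)
  seq_chars <- strsplit(profile$sequence, "")[[1]]
  for (k in seq_len(nrow(sc))) {
    writeLines(paste(k, seq_chars[k],
                     paste(format(signif(sc[k, ], 6), trim = TRUE),
                           collapse = " ")), con)
  }
  invisible(path)
}

#' Profile TSV round-trip
#'
#' The package's own plain-text profile format. A commented header records
#' the profile type, id, length and alphabet; for structure profiles the
#' body holds per-position integer counts plus the background composition
#' (frequencies and propensities are recomputed on read, so a zero propensity
#' survives as exactly 0); for sequence profiles the body holds the residue
#' and 20 log-odds values at 6 significant digits. Files with a permuted
#' alphabet header are re-mapped on read.
#'
#' @param profile A `structure_profile` or `sequence_profile`.
#' @param path File path.
#' @return `write_profile_tsv()`: `path` invisibly; `read_profile_tsv()`: the
#'   profile object.
#' @export
write_profile_tsv <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(profile, "structure_profile")) {
    writeLines(c("# crossprofiler profile v1",
                 "# type: structure",
                 paste0("# id: ", profile$cluster_id),
                 paste0("# L: ", profile$L),
                 paste0("# alphabet: ", paste(profile$alphabet, collapse = "")),
                 paste0("# background: ",
                        paste(format(signif(profile$background, 6),
                                     trim = TRUE), collapse = "\t")),
                 paste(c("pos", profile$alphabet), collapse = "\t")), con)
    for (i in seq_len(profile$L)) {
      writeLines(paste(c(i, profile$counts[i, ]), collapse = "\t"), con)
    }
  } else if (inherits(profile, "sequence_profile")) {
    writeLines(c("# crossprofiler profile v1",
                 "# type: sequence",
                 paste0("# id: ", profile$id),
                 paste0("# L: ", nrow(profile$scores)),
                 paste0("# alphabet: ", paste(AA_ALPHABET, collapse = "")),
                 paste(c("pos", "res", AA_ALPHABET), collapse = "\t")), con)
    seq_chars <- strsplit(profile$sequence, "")[[1]]
    for (i in seq_len(nrow(profile$scores))) {
      writeLines(paste(c(i, seq_chars[i],
                         format(signif(profile$scores[i, ], 6), trim = TRUE)),
                       collapse = "\t"), con)
    }
  } else {
    abort("not a profile object")
  }
  invisible(path)
}

#' @rdname write_profile_tsv
#' @export
read_profile_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "# ")]
  field <- function(key) {
    l <- hdr[startsWith(hdr, paste0("# ", key, ":"))]
    if (length(l) == 0L) abort(sprintf("profile file lacks '%s' header", key))
    trimws(sub(paste0("# ", key, ":"), "", l[1], fixed = TRUE))
  }
  if (!any(grepl("^# crossprofiler profile v1$", lines))) {
    abort("version mismatch: not a crossprofiler profile v1 file")
  }
  type <- field("type")
  id <- field("id")
  alpha <- strsplit(field("alphabet"), "")[[1]]
  if (length(alpha) != 20L || !setequal(alpha, AA_ALPHABET)) {
    abort("alphabet mismatch in profile file")
  }
  perm <- match(AA_ALPHABET, alpha)
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)][-1]      # drop the column-name row
  toks <- strsplit(body, "\t", fixed = TRUE)
  if (type == "structure") {
    bg <- as.numeric(strsplit(field("background"), "\t", fixed = TRUE)[[1]])
    counts <- do.call(rbind, lapply(toks, function(t) as.integer(t[-1])))
    counts <- counts[, perm, drop = FALSE]
    bg <- setNames(bg[perm], AA_ALPHABET)
    rebuild_structure_profile(counts, bg, id)
  } else if (type == "sequence") {
    seq <- paste(vapply(toks, `[`, character(1), 2), collapse = "")
    scores <- do.call(rbind, lapply(toks, function(t) as.numeric(t[-(1:2)])))
    new_sequence_profile(id, seq, scores[, perm, drop = FALSE])
  } else {
    abort(sprintf("unknown profile type '%s'", type))
  }
}

# rebuild p/pro from counts + background (shared by TSV reader)
rebuild_structure_profile <- function(counts, background, cluster_id) {
  colnames(counts) <- AA_ALPHABET
  tot <- rowSums(counts)
  p <- counts / ifelse(tot > 0, tot, 1)
  pro <- sweep(p, 2, background, "/")
  pro[, background == 0] <- 0
  pro[p == 0] <- 0
  structure(list(cluster_id = cluster_id, L = nrow(counts),
                 alphabet = AA_ALPHABET, counts = counts, p = p,
                 background = background, pro = pro),
            class = "structure_profile")
}

#' Long-format view of a profile matrix
#'
#' @param x A `structure_profile` or `sequence_profile`.
#' @param ... Unused.
#' @return A tibble with one row per (position, residue) cell: frequencies
#'   and propensities for structure profiles, log-odds scores for sequence
#'   profiles.
#' @export
tidy.structure_profile <- function(x, ...) {
  tibble(
    position = rep(seq_len(x$L), each = 20L),
    residue = rep(x$alphabet, times = x$L),
    count = as.integer(t(x$counts)),
    frequency = as.numeric(t(x$p)),
    propensity = as.numeric(t(x$pro))
  )
}

#' @rdname tidy.structure_profile
#' @export
tidy.sequence_profile <- function(x, ...) {
  n <- nrow(x$scores)
  tibble(
    position = rep(seq_len(n), each = 20L),
    residue = rep(AA_ALPHABET, times = n),
    score = as.numeric(t(x$scores))
  )
}

#' Sequence-logo data for a structure profile
#'
#' Per-position Shannon information content over the observed frequencies,
#' with a log2(20) maximum, and per-letter heights frequency x information.
#' Only the numbers are produced; rendering is left to the caller.
#'
#' @param profile A `structure_profile`.
#' @return A tibble `[position, residue, frequency, information_bits]`.
#' @export
logo_data <- function(profile) {
  stopifnot(inherits(profile, "structure_profile"))
  ic <- apply(profile$p, 1, function(p) {
    p <- p[p > 0]
    log2(20) + sum(p * log2(p))
  })
  tibble(
    position = rep(seq_len(profile$L), each = 20L),
    residue = rep(profile$alphabet, times = profile$L),
    frequency = as.numeric(t(profile$p)),
    information_bits = rep(ic, each = 20L)
  )
}
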