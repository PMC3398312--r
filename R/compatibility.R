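#' Compatibility score S of a sequence region against a structure profile
#'
#' Threads an L-symbol region (one-letter codes, `'-'` for gaps) onto a
#' structure-based propensity profile and sums the per-position
#' log-propensity terms:
#' \deqn{S = \sum_{i=1}^{L} \ln pro_i(j_i)}
#' A gap, an `'X'`, or a residue never observed at its position
#' (propensity 0) contributes exactly `ln(0.0001)` (-9.21), the conventional
#' floor that keeps the logarithm defined. Consequently
#' `S >= L * ln(0.0001)`, with equality iff every position is a gap/zero.
#'
#' @param profile A `structure_profile`.
#' @param region Character scalar of length-L symbols from the alphabet plus
#'   `'-'` (alignment gap) and `'X'`.
#' @param id Identifier recorded in the result.
#' @return An object of class `compatibility_result`: list with `id`, `S`,
#'   `terms` (L values), `n_gap_positions`.
#' @export
score_sequence <- function(profile, region, id = NULL) {
  stopifnot(inherits(profile, "structure_profile"))
  region <- toupper(gsub(".", "-", region, fixed = TRUE))
  chars <- strsplit(region, "")[[1]]
  if (length(chars) != profile$L) {
    abort(sprintf("length mismatch: region has %d symbols, profile L = %d",
                  length(chars), profile$L))
  }
  bad <- setdiff(chars, c(AA_ALPHABET, "-", "X"))
  if (length(bad) > 0L) {
    abort(sprintf("unknown symbols in region: %s",
                  paste(unique(bad), collapse = "")))
  }
  terms <- vapply(seq_len(profile$L), function(i) {
    ch <- chars[i]
    if (ch %in% c("-", "X")) return(LOG_FLOOR)
    pro <- profile$pro[i, ch]
    if (pro == 0) LOG_FLOOR else max(log(pro), LOG_FLOOR)
  }, double(1))
  structure(list(id = id %||% "seq", S = sum(terms), terms = terms,
                 n_gap_positions = sum(chars == "-")),
            class = "compatibility_result")
}

#' @export
print.compatibility_result <- function(x, ...) {
  cat(sprintf("<compatibility_result> %s: S = %.3f (%d gap positions)\n",
              x$id, x$S, x$n_gap_positions))
  invisible(x)
}

#' @export
tidy.compatibility_result <- function(x, ...) {
  tibble(position = seq_along(x$terms), term = x$terms)
}

#' Consensus (deduced) sequence of a structure profile
#'
#' Per position, the residue with the maximal propensity; ties go to the
#' alphabetically first residue. Because the per-position terms of the
#' compatibility score are independent, the consensus attains the global
#' maximum of S over all gapless sequences.
#'
#' @param profile A `structure_profile`.
#' @return Character scalar of length L.
#' @export
consensus_sequence <- function(profile) {
  stopifnot(inherits(profile, "structure_profile"))
  picks <- vapply(seq_len(profile$L), function(i) {
    row <- profile$pro[i, ]
    if (all(row == 0)) abort(sprintf("all-zero propensities at position %d", i))
    AA_ALPHABET[which.max(row)]
  }, character(1))
  paste(picks, collapse = "")
}

#' Family-wide compatibility scores and the shift from an ancestral sequence
#'
#' Scores every member of a gapped family alignment against a structure
#' profile over a designated L-column window, scores a designated ancestral
#' sequence the same way, and reports per-member
#' \deqn{\Delta S = S_{member} - S_{ancestral}.}
#' Negative values mean the existing sequence is less compatible with the
#' structural motif than its ancestor. Members whose window contains no
#' amino acids at all are excluded with reason `"empty region"` rather than
#' scored; an ancestral sequence empty in the window is an error (supply an
#' alternative ancestor, e.g. the next root of the tree, via `ancestral`).
#'
#' @param profile A `structure_profile` of length L.
#' @param family_alignment Named character vector of gapped sequences, all
#'   the same alignment length (e.g. from [read_alignment_fasta()]).
#' @param window Alignment-column window, either `c(start, end)` (1-based,
#'   inclusive, end - start + 1 must equal L) or a `"start-end"` string.
#' @param ancestral Name of the ancestral record in `family_alignment`, or a
#'   gapped sequence of the full alignment length.
#' @return An object of class `family_delta`: list with `scores` (tibble
#'   `[id, S, n_gaps, excluded, reason, delta_S]`), `ancestral_id`, `S_r`.
#' @export
family_delta_scores <- function(profile, family_alignment, window,
                                ancestral) {
  stopifnot(inherits(profile, "structure_profile"))
  if (is.character(window) && length(window) == 1L && grepl("-", window)) {
    w <- as.integer(strsplit(window, "-", fixed = TRUE)[[1]])
  } else {
    w <- as.integer(window)
  }
  if (length(w) != 2L || anyNA(w) || w[2] < w[1]) {
    abort("window must be 'start-end' or c(start, end)")
  }
  if (w[2] - w[1] + 1L != profile$L) {
    abort(sprintf("window spans %d columns but profile L = %d",
                  w[2] - w[1] + 1L, profile$L))
  }
  aln <- toupper(gsub(".", "-", family_alignment, fixed = TRUE))
  if (length(unique(nchar(aln))) != 1L) {
    abort("family alignment rows have unequal lengths")
  }
  if (is.null(names(aln))) names(aln) <- paste0("seq_", seq_along(aln))
  if (w[2] > nchar(aln[1])) abort("window exceeds alignment length")

  if (ancestral %in% names(aln)) {
    anc_id <- ancestral
    anc_seq <- aln[[ancestral]]
  } else {
    anc_id <- "ancestral"
    anc_seq <- toupper(gsub(".", "-", ancestral, fixed = TRUE))
    if (nchar(anc_seq) != nchar(aln[1])) {
      abort("ancestral sequence length differs from the alignment")
    }
  }
  win <- function(s) substr(s, w[1], w[2])
  has_aa <- function(s) any(strsplit(s, "")[[1]] %in% AA_ALPHABET)
  anc_region <- win(anc_seq)
  if (!has_aa(anc_region)) {
    abort("ancestral lacks region: no amino acids in the window")
  }
  s_r <- score_sequence(profile, anc_region, id = anc_id)$S

  rows <- lapply(names(aln), function(id) {
    region <- win(aln[[id]])
    if (!has_aa(region)) {
      tibble(id = id, S = NA_real_, n_gaps = NA_integer_, excluded = TRUE,
             reason = "empty region", delta_S = NA_real_)
    } else {
      r <- score_sequence(profile, region, id = id)
      tibble(id = id, S = r$S, n_gaps = r$n_gap_positions, excluded = FALSE,
             reason = NA_character_, delta_S = r$S - s_r)
    }
  })
  structure(list(scores = bind_rows(rows), ancestral_id = anc_id, S_r = s_r,
                 window = w),
            class = "family_delta")
}

#' @export
print.family_delta <- function(x, ...) {
  sc <- x$scores
  cat(sprintf(
    "<family_delta> %d members (%d excluded); ancestral %s: S_r = %.3f\n",
    nrow(sc), sum(sc$excluded), x$ancestral_id, x$S_r))
  invisible(x)
}

#' @export
tidy.family_delta <- function(x, ...) x$scores

#' @export
glance.family_delta <- function(x, ...) {
  sc <- x$scores[!x$scores$excluded, ]
  tibble(n_scored = nrow(sc), n_excluded = sum(x$scores$excluded),
         S_r = x$S_r, mean_delta_S = mean(sc$delta_S),
         frac_positive_delta = mean(sc$delta_S > 0))
}

#' Histogram data of family ΔS values
#'
#' @param fd A [family_delta_scores()] result.
#' @param binwidth Bin width on the ΔS axis.
#' @return A tibble `[bin_mid, count]`.
#' @export
delta_histogram <- function(fd, binwidth = 2) {
  d <- fd$scores$delta_S
  d <- d[!is.na(d)]
  lo <- floor(min(d) / binwidth) * binwidth
  br <- seq(lo, max(d) + binwidth, by = binwidth)
  h <- hist(d, breaks = br, plot = FALSE)
  tibble(bin_mid = h$mids, count = h$counts)
}

#' @export
autoplot.family_delta <- function(object, binwidth = 2, ...) {
  df <- object$scores[!object$scores$excluded, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta_S)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey40") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = expression(Delta * S), y = "sequences") +
    ggplot2::theme_minimal()
}

#' Read a (gapped) FASTA alignment as a named character vector
#'
#' @param path FASTA file path.
#' @return Named character vector of (possibly gapped) sequences.
#' @export
read_alignment_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::readBStringSet(path)
    setNames(as.character(ss), names(ss))
  } else {
    lines <- readLines(path)
    idx <- grep("^>", lines)
    if (length(idx) == 0L) abort("no FASTA records")
    ids <- sub("^>\\s*", "", lines[idx])
    ids <- vapply(strsplit(ids, "\\s+"), `[`, character(1), 1)
    ends <- c(idx[-1] - 1L, length(lines))
    seqs <- vapply(seq_along(idx), function(k) {
      paste(lines[(idx[k] + 1L):ends[k]], collapse = "")
    }, character(1))
    setNames(gsub("\\s", "", seqs), ids)
  }
}
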