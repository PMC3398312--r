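#' Search configuration
#'
#' Bundles the tunables of the cross-profile search. Gap penalties are in
#' correlation units: an internal gap of length k costs
#' `gap_open + k * gap_extend`. The defaults (0.6 / 0.06) price a single
#' internal gap above the best possible column gain (a perfect correlation
#' of 1.0) minus a typical decoy column (about 0). `column_transform`
#' controls how structure-profile propensities enter the correlation:
#' `"log"` (default) takes `ln(pro)` floored at `ln(1e-4)` so both column
#' types are log-odds-like; `"raw"` uses propensities as-is. `z_threshold`
#' is the significance working point on the library Z-score.
#'
#' @param gap_open,gap_extend Non-negative gap penalties.
#' @param column_transform `"log"` or `"raw"`.
#' @param z_threshold Positive significance threshold (default 8).
#' @return A list of class `search_config`.
#' @export
search_config <- function(gap_open = 0.6, gap_extend = 0.06,
                          column_transform = c("log", "raw"),
                          z_threshold = 8) {
  column_transform <- match.arg(column_transform)
  stopifnot(gap_open >= 0, gap_extend >= 0, z_threshold > 0)
  structure(list(gap_open = gap_open, gap_extend = gap_extend,
                 column_transform = column_transform,
                 z_threshold = z_threshold, log_floor = LOG_FLOOR),
            class = "search_config")
}

#' Transform a profile into comparison space
#'
#' Structure profiles become `ln(pro)` floored at `ln(1e-4)` under the
#' `"log"` transform (or raw propensities under `"raw"`); sequence-profile
#' log-odds are used as-is. Plain matrices pass through unchanged.
#'
#' @param profile A `structure_profile`, `sequence_profile`, or a numeric
#'   position x 20 matrix.
#' @param transform `"log"` or `"raw"` (applies to structure profiles only).
#' @return A position x 20 numeric matrix.
#' @export
profile_columns <- function(profile, transform = "log") {
  if (inherits(profile, "structure_profile")) {
    if (identical(transform, "log")) {
      pmax(suppressWarnings(log(profile$pro)), LOG_FLOOR)
    } else {
      profile$pro
    }
  } else if (inherits(profile, "sequence_profile")) {
    profile$scores
  } else {
    as.matrix(profile)
  }
}

#' Pearson similarity of two profile columns
#'
#' Standard Pearson correlation of two 20-vectors; if either column has zero
#' variance the similarity is defined as 0.
#'
#' @param col_a,col_b Numeric vectors of length 20 (finite).
#' @return Correlation in \[-1, 1\].
#' @export
column_similarity <- function(col_a, col_b) {
  sa <- sd(col_a); sb <- sd(col_b)
  if (sa == 0 || sb == 0) return(0)
  cor(col_a, col_b)
}

# all-pairs column similarity: rows of A vs rows of B, zero-variance rows -> 0
similarity_matrix <- function(A, B) {
  zs <- function(M) {
    mu <- rowMeans(M)
    s <- sqrt(rowSums((M - mu)^2) / (ncol(M) - 1))
    Z <- (M - mu) / ifelse(s > 0, s, 1)
    Z[s == 0, ] <- 0
    Z
  }
  tcrossprod(zs(A), zs(B)) / (ncol(A) - 1)
}

#' Global-local profile-profile alignment
#'
#' Affine-gap dynamic programming over [column_similarity()] scores with no
#' penalty for terminal gaps in either profile: unaligned runs at either end
#' of either profile are free, internal gaps of length k cost
#' `gap_open + k * gap_extend`. Traceback ties prefer the diagonal, then a
#' gap in the query, then a gap in the target.
#'
#' @param query,target Profile objects or position x 20 matrices.
#' @param config A [search_config()].
#' @return A list of class `alignment_result` with `pairs` (tibble of
#'   `query_pos`, `target_pos`, `similarity`, strictly increasing in both),
#'   `raw_score`, and `cigar` (M = aligned pair, D = query position skipped
#'   internally, I = target position skipped internally).
#' @export
align_global_local <- function(query, target, config = search_config()) {
  Q <- profile_columns(query, config$column_transform)
  T_ <- profile_columns(target, config$column_transform)
  if (nrow(Q) < 1L || nrow(T_) < 1L) abort("empty profile")
  sim <- similarity_matrix(Q, T_)
  dp <- glocal_dp(sim, config$gap_open, config$gap_extend)
  pairs <- glocal_traceback(sim, dp, config$gap_open, config$gap_extend)
  structure(list(pairs = pairs, raw_score = dp$score,
                 cigar = pairs_to_cigar(pairs)),
            class = "alignment_result")
}

#' Alignment score only (no traceback)
#'
#' @inheritParams align_global_local
#' @return The optimal raw score.
#' @export
align_score <- function(query, target, config = search_config()) {
  Q <- profile_columns(query, config$column_transform)
  T_ <- profile_columns(target, config$column_transform)
  if (nrow(Q) < 1L || nrow(T_) < 1L) abort("empty profile")
  glocal_dp(similarity_matrix(Q, T_), config$gap_open, config$gap_extend,
            keep = FALSE)$score
}

# Gotoh DP with all terminal gaps free (aligned-pair formulation). M[i,j]:
# best alignment whose last column aligns query i with target j (leading
# unaligned runs are terminal, hence free: the recursion may start from 0 at
# any cell). X: internal gap run in the target (query positions consumed);
# Y: internal gap run in the query (target positions consumed). Y may open
# after an X run so that both profiles can have an internal gap between two
# consecutive aligned pairs. Row-vectorized: the within-row Y recursion
# collapses to a running maximum of max(M, X) + j*extend.
glocal_dp <- function(sim, open, extend, keep = TRUE) {
  n <- nrow(sim); m <- ncol(sim)
  oe <- open + extend
  if (keep) {
    M <- matrix(-Inf, n, m); X <- matrix(-Inf, n, m); Y <- matrix(-Inf, n, m)
  }
  Mprev <- Xprev <- Yprev <- rep(-Inf, m)
  best <- -Inf
  for (i in seq_len(n)) {
    diag_best <- if (i == 1L) {
      rep(0, m)
    } else {
      pmax(0, c(0, head(pmax(Mprev, pmax(Xprev, Yprev)), -1)))
    }
    Mi <- sim[i, ] + diag_best
    Xi <- pmax(Mprev - oe, Xprev - extend)
    base <- pmax(Mi, Xi)
    run <- cummax(base + seq_len(m) * extend)
    # Yi[j] = max_{k<j} base[k] - oe - (j-1-k)*extend
    Yi <- c(-Inf, head(run, -1)) - oe - (seq_len(m) - 1) * extend
    if (keep) { M[i, ] <- Mi; X[i, ] <- Xi; Y[i, ] <- Yi }
    Mprev <- Mi; Xprev <- Xi; Yprev <- Yi
    best <- max(best, max(Mi))
  }
  if (!keep) M <- X <- Y <- NULL
  list(score = best, M = M, X = X, Y = Y)
}

glocal_traceback <- function(sim, dp, open, extend, tol = 1e-9) {
  M <- dp$M; X <- dp$X; Y <- dp$Y
  n <- nrow(M); m <- ncol(M)
  oe <- open + extend
  # best cell: scan row-major, strict improvements only (lowest i, then j)
  best <- -Inf; bi <- 1L; bj <- 1L
  for (i in seq_len(n)) for (j in seq_len(m)) {
    if (M[i, j] > best + tol) { best <- M[i, j]; bi <- i; bj <- j }
  }
  pairs_q <- integer(); pairs_t <- integer()
  i <- bi; j <- bj; state <- "M"
  repeat {
    if (state == "M") {
      pairs_q <- c(i, pairs_q); pairs_t <- c(j, pairs_t)
      val <- M[i, j] - sim[i, j]
      moved <- FALSE
      if (i > 1L && j > 1L) {
        # tie preference: diagonal, then query-gap (Y), then target-gap (X)
        if (abs(M[i - 1L, j - 1L] - val) <= tol) {
          state <- "M"; moved <- TRUE
        } else if (abs(Y[i - 1L, j - 1L] - val) <= tol) {
          state <- "Y"; moved <- TRUE
        } else if (abs(X[i - 1L, j - 1L] - val) <= tol) {
          state <- "X"; moved <- TRUE
        }
      }
      if (!moved) break  # alignment started here; leading gaps are free
      i <- i - 1L; j <- j - 1L
    } else if (state == "Y") {
      # internal gap in the query: target position j-1.. unaligned
      val <- Y[i, j]
      if (abs(M[i, j - 1L] - oe - val) <= tol) {
        state <- "M"
      } else if (abs(X[i, j - 1L] - oe - val) <= tol) {
        state <- "X"
      } else {
        state <- "Y"
      }
      j <- j - 1L
    } else {
      # internal gap in the target: query position i-1.. unaligned
      val <- X[i, j]
      if (abs(M[i - 1L, j] - oe - val) <= tol) {
        state <- "M"
      } else {
        state <- "X"
      }
      i <- i - 1L
    }
  }
  tibble(query_pos = pairs_q, target_pos = pairs_t,
         similarity = sim[cbind(pairs_q, pairs_t)])
}

pairs_to_cigar <- function(pairs) {
  if (nrow(pairs) == 0L) return("")
  ops <- character(0)
  for (k in seq_len(nrow(pairs))) {
    if (k > 1L) {
      dq <- pairs$query_pos[k] - pairs$query_pos[k - 1L] - 1L
      dt <- pairs$target_pos[k] - pairs$target_pos[k - 1L] - 1L
      if (dq > 0L) ops <- c(ops, paste0(dq, "D"))
      if (dt > 0L) ops <- c(ops, paste0(dt, "I"))
    }
    ops <- c(ops, "1M")
  }
  # merge adjacent M runs
  runs <- rle(gsub("^[0-9]+", "", ops))
  counts <- as.integer(gsub("[A-Z]$", "", ops))
  out <- character(0); pos <- 1L
  for (r in seq_along(runs$lengths)) {
    span <- pos:(pos + runs$lengths[r] - 1L)
    out <- c(out, paste0(sum(counts[span]), runs$values[r]))
    pos <- pos + runs$lengths[r]
  }
  paste(out, collapse = "")
}

#' Search a profile library and rank hits by Z-score
#'
#' Aligns the query (typically a structure-based propensity profile) against
#' every sequence profile in the library, corrects the raw scores for target
#' length by a least-squares fit of score on log(length), and standardizes
#' the residuals into library Z-scores. Hits with Z at or above the
#' configured threshold are marked significant (the conventional working
#' point is Z >= 8). With fewer than 10 targets no Z-scores are assigned
#' (raw scores only, flagged with a warning).
#'
#' @param query A `structure_profile` (or any profile/matrix).
#' @param library A list of `sequence_profile` objects (or profile-like
#'   matrices), preferably named.
#' @param config A [search_config()].
#' @param keep_alignments Attach the full alignment of each hit (slower).
#' @return An object of class `profile_search` whose `hits` tibble holds
#'   `rank`, `target_id`, `target_length`, `raw`, `corrected` (residual after
#'   the log-length fit), `z`, `significant`, and (optionally) an
#'   `alignment` list-column, sorted by Z descending.
#' @export
zscore_library_search <- function(query, library, config = search_config(),
                                  keep_alignments = FALSE) {
  if (length(library) == 0L) {
    abort("empty library", class = "crossprofiler_empty_library")
  }
  ids <- names(library) %||% paste0("target_", seq_along(library))
  if (is.null(names(library))) names(library) <- ids
  ids[!nzchar(ids)] <- paste0("target_", which(!nzchar(ids)))
  Q <- profile_columns(query, config$column_transform)
  lens <- vapply(library, function(t) nrow(profile_columns(t)), integer(1))
  raw <- vapply(library, function(t) {
    glocal_dp(similarity_matrix(Q, profile_columns(t)),
              config$gap_open, config$gap_extend, keep = FALSE)$score
  }, double(1))
  if (length(library) >= 10L) {
    fit <- lm(raw ~ log(lens))
    res <- residuals(fit)
    s <- sd(res)
    if (s <= 1e-10 * max(1, max(abs(raw)))) {
      warn("all alignment scores equal; Z-scores set to 0")
      z <- rep(0, length(raw))
    } else {
      z <- (res - mean(res)) / s
    }
  } else {
    warn("library smaller than 10 profiles: raw scores only, no Z-scores")
    z <- rep(NA_real_, length(raw))
    fit <- NULL
  }
  hits <- tibble(target_id = ids, target_length = lens, raw = raw,
                 corrected = if (!is.null(fit)) residuals(fit) else raw,
                 z = z,
                 significant = !is.na(z) & z >= config$z_threshold)
  ord <- order(if (all(is.na(z))) -raw else -z)
  hits <- hits[ord, ]
  hits$rank <- seq_len(nrow(hits))
  hits <- hits[, c("rank", setdiff(names(hits), "rank"))]
  if (keep_alignments) {
    hits$alignment <- lapply(hits$target_id, function(id) {
      align_global_local(query, library[[id]], config)
    })
  }
  structure(list(hits = hits,
                 query_id = if (inherits(query, "structure_profile"))
                   query$cluster_id else "query",
                 config = config, length_fit = fit),
            class = "profile_search")
}

#' @export
print.profile_search <- function(x, ...) {
  cat(sprintf("<profile_search> query %s vs %d targets; %d significant (Z >= %g)\n",
              x$query_id, nrow(x$hits), sum(x$hits$significant, na.rm = TRUE),
              x$config$z_threshold))
  print(head(x$hits, 5))
  invisible(x)
}

#' @export
tidy.profile_search <- function(x, ...) {
  x$hits[, setdiff(names(x$hits), "alignment")]
}

#' @export
glance.profile_search <- function(x, ...) {
  co <- if (!is.null(x$length_fit)) stats::coef(x$length_fit) else c(NA, NA)
  tibble(n_targets = nrow(x$hits),
         n_significant = sum(x$hits$significant, na.rm = TRUE),
         z_threshold = x$config$z_threshold,
         length_fit_intercept = unname(co[1]),
         length_fit_slope = unname(co[2]))
}

#' Z-score histogram data for a library search
#'
#' @param search A [zscore_library_search()] result.
#' @param binwidth Bin width on the Z axis.
#' @return A tibble `[bin_mid, count]`.
#' @export
z_histogram <- function(search, binwidth = 0.5) {
  z <- search$hits$z
  z <- z[!is.na(z)]
  if (length(z) == 0L) return(tibble(bin_mid = double(), count = integer()))
  lo <- floor(min(z) / binwidth) * binwidth
  br <- seq(lo, max(z) + binwidth, by = binwidth)
  h <- hist(z, breaks = br, plot = FALSE)
  tibble(bin_mid = h$mids, count = h$counts)
}

#' Plot the library Z-score distribution
#'
#' @param object A `profile_search`.
#' @param binwidth Histogram bin width.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.profile_search <- function(object, binwidth = 0.5, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey40") +
    ggplot2::geom_vline(xintercept = object$config$z_threshold,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "library Z-score", y = "targets",
                  title = paste("Z-score distribution:", object$query_id)) +
    ggplot2::theme_minimal()
}
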