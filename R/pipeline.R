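#' Configuration for an end-to-end cross-profile run
#'
#' Flat list of stage parameters with the conventional defaults: window
#' length 15, clustering threshold 30 degrees, an 80-member floor for
#' profile building, Z significance threshold 8, gap penalties 0.6/0.06.
#' In simulate mode (no PDB inputs) the run generates its own planted
#' segment population and decoy library from `seed`.
#'
#' @param seed Integer seed for all randomness of the run.
#' @param L Segment window length.
#' @param d_th Clustering threshold (degrees).
#' @param min_members Cluster-size floor for profile building and search.
#' @param z_threshold Significance threshold on library Z-scores.
#' @param gap_open,gap_extend Alignment gap penalties.
#' @param pdb_files,chains Optional equal-length vectors of PDB paths and
#'   chain ids to harvest segments from (omit to simulate).
#' @param library_dir Optional directory of `.pssm` / profile `.tsv` files
#'   to search (omit to simulate a decoy library with one planted target).
#' @param k_clusters,members_per_cluster,angular_noise_deg,family_size,
#'   per_site_mutation_rate,n_decoys Simulate-mode generator settings.
#' @param out_dir Output directory for the report bundle (created).
#' @return A named list of class `run_config`.
#' @export
cross_profile_config <- function(seed = 11, L = 15, d_th = 30,
                                 min_members = 80, z_threshold = 8,
                                 gap_open = 0.6, gap_extend = 0.06,
                                 pdb_files = NULL, chains = NULL,
                                 library_dir = NULL,
                                 k_clusters = 3, members_per_cluster = 80,
                                 angular_noise_deg = 3, family_size = 50,
                                 per_site_mutation_rate = 0.1,
                                 n_decoys = 200,
                                 out_dir = tempfile("crossprofiler_run_")) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Read a directory of sequence profiles
#'
#' `.pssm`/`.mtx` files are parsed as PSI-BLAST ASCII PSSMs, `.tsv` files as
#' the package profile format. Files are read in lexicographic order (the
#' order is part of the run manifest).
#'
#' @param dir Directory path.
#' @return Named list of `sequence_profile`s.
#' @export
read_profile_library <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.(pssm|mtx|tsv)$",
                           full.names = TRUE))
  if (length(files) == 0L) {
    abort("empty library", class = "crossprofiler_empty_library")
  }
  lib <- lapply(files, function(f) {
    if (grepl("\\.tsv$", f)) read_profile_tsv(f) else read_pssm(f)
  })
  names(lib) <- vapply(lib, `[[`, character(1), "id")
  lib
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    if (inherits(e, "crossprofiler_empty_library")) stop(e)
    abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
          parent = e)
  })
}

#' Run the full cross-profile workflow
#'
#' Chains segment harvesting (or simulation), single-pass clustering,
#' profile building for clusters that meet the member floor, the library
#' search, and the report files: per-query hits TSV, Z-score histogram TSV,
#' cluster assignment and summary TSVs, and a JSON manifest recording the
#' seed, the configuration hash, the input order and per-stage counts.
#'
#' @param config A [cross_profile_config()].
#' @return Invisibly, a list with `clustering`, `profiles`, `searches`
#'   (one [zscore_library_search()] result per profile), `manifest`, and
#'   `out_dir`.
#' @export
run_cross_profile_analysis <- function(config = cross_profile_config()) {
  stopifnot(inherits(config, "run_config") || is.list(config))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  scfg <- search_config(gap_open = config$gap_open,
                        gap_extend = config$gap_extend,
                        z_threshold = config$z_threshold)

  # --- segments ---------------------------------------------------------
  simulate <- is.null(config$pdb_files)
  truth <- NULL
  segments <- with_stage("extract", {
    if (simulate) {
      pop <- generate_segment_population(
        seed = config$seed, L = config$L, k_clusters = config$k_clusters,
        members_per_cluster = config$members_per_cluster,
        angular_noise_deg = config$angular_noise_deg)
      truth <- pop$labels
      pop$segments
    } else {
      stopifnot(length(config$pdb_files) == length(config$chains))
      segs <- lapply(seq_along(config$pdb_files), function(k) {
        ch <- read_backbone(config$pdb_files[k], config$chains[k])
        extract_segments(ch, L = config$L)
      })
      bind_rows(segs)
    }
  })
  input_order <- segments$range

  # --- clustering -------------------------------------------------------
  clustering <- with_stage("cluster", {
    single_pass_cluster(segments, d_th = config$d_th,
                        min_members = config$min_members)
  })
  write.table(tidy(clustering),
              file.path(config$out_dir, "cluster_assignments.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(glance(clustering),
              file.path(config$out_dir, "cluster_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # --- profiles (member floor applies here, not to clustering) ----------
  profiles <- with_stage("profiles", {
    background <- compute_background(segments)
    sizes <- glance(clustering)
    keep <- sizes$cluster_id[sizes$n_members >= config$min_members]
    lapply(keep, function(cid) {
      members <- segments$sequence[clustering$assignment == cid]
      members <- members[!grepl("X", members, fixed = TRUE)]
      build_structure_profile(members, background,
                              cluster_id = paste0("cluster_", cid))
    })
  })

  # --- library ----------------------------------------------------------
  library_truth <- NULL
  library <- with_stage("library", {
    if (!is.null(config$library_dir)) {
      read_profile_library(config$library_dir)
    } else {
      if (length(profiles) == 0L) {
        abort("empty library", class = "crossprofiler_empty_library")
      }
      # the planted target's family: the sequences of the first profiled
      # cluster's own members, i.e. a sequence family sharing that local
      # structure, lightly mutated
      cid1 <- as.integer(sub("cluster_", "", profiles[[1]]$cluster_id))
      fam_seqs <- segments$sequence[clustering$assignment == cid1]
      gen <- generate_family_library(
        consensus_sequence(profiles[[1]]), seed = config$seed + 1L,
        family_size = config$family_size,
        per_site_mutation_rate = config$per_site_mutation_rate,
        n_decoys = config$n_decoys,
        family_sequences = fam_seqs)
      library_truth <- gen[c("planted_id", "offset")]
      gen$library
    }
  })
  if (length(library) == 0L) {
    abort("empty library", class = "crossprofiler_empty_library")
  }

  # --- search -----------------------------------------------------------
  searches <- with_stage("search", {
    lapply(profiles, function(pr) zscore_library_search(pr, library, scfg))
  })
  hits <- bind_rows(lapply(searches, function(s) {
    mutate(tidy(s), query = s$query_id)
  }))
  if (nrow(hits) == 0L) {
    hits <- tibble(rank = integer(), target_id = character(),
                   target_length = integer(), raw = double(),
                   corrected = double(), z = double(),
                   significant = logical(), query = character())
  }
  write.table(hits, file.path(config$out_dir, "hits.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(searches) > 0L) {
    write.table(z_histogram(searches[[1]]),
                file.path(config$out_dir, "z_histogram.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # --- manifest ---------------------------------------------------------
  cfg_for_hash <- unclass(config)
  cfg_for_hash$out_dir <- NULL
  cfg_for_hash$pdb_files <- if (!is.null(config$pdb_files))
    basename(config$pdb_files)
  cfg_for_hash$library_dir <- if (!is.null(config$library_dir))
    basename(config$library_dir)
  manifest <- list(
    package = "crossprofiler",
    version = as.character(utils::packageVersion("crossprofiler")),
    seed = config$seed,
    config_hash = rlang::hash(cfg_for_hash),
    input_order = input_order,
    n_segments = nrow(segments),
    n_clusters = length(clustering$clusters),
    n_profiles = length(profiles),
    n_library = length(library),
    n_significant = sum(hits$significant, na.rm = TRUE)
  )
  manifest$manifest_hash <- rlang::hash(manifest)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(clustering = clustering, profiles = profiles,
                 searches = searches, hits = hits, manifest = manifest,
                 truth_labels = truth, library_truth = library_truth,
                 out_dir = config$out_dir))
}
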