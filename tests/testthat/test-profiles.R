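test_that("background composition is a hand count", {
  expect_equal(unname(compute_background("GGGG")["G"]), 1)
  expect_equal(sum(compute_background("GGGG")), 1)
  expect_equal(unname(compute_background(paste(AA_ALPHABET, collapse = ""))),
               rep(0.05, 20))
  # 4 A, 6 V over 10 countable residues
  bg2 <- compute_background(c("AAVV", "AAVV", "VV"))
  expect_equal(unname(bg2["A"]), 0.4)
  expect_equal(unname(bg2["V"]), 0.6)
  expect_error(compute_background("X-"), "no countable residues")
})

test_that("propensities follow counts / background with no pseudo-counts", {
  # uniform members at a position -> pro = 1 for every observed residue
  members <- vapply(1:20, function(i) {
    paste(AA_ALPHABET[(i + 0:2) %% 20 + 1], collapse = "")
  }, character(1))
  bg <- compute_background(members)
  pr <- build_structure_profile(members, bg)
  expect_equal(rowSums(pr$p), rep(1, 3), tolerance = 1e-12)

  # 80/80 glycine at a position with p(G) = 0.08 -> pro = 12.5, absent -> 0
  members2 <- rep("G", 80)
  bg2 <- setNames(rep((1 - 0.08) / 19, 20), AA_ALPHABET)
  bg2["G"] <- 0.08
  pr2 <- build_structure_profile(members2, bg2)
  expect_equal(unname(pr2$pro[1, "G"]), 12.5)
  expect_equal(unname(pr2$pro[1, "A"]), 0)
  # counts are raw
  expect_equal(unname(pr2$counts[1, "G"]), 80L)
  expect_error(build_structure_profile(c("AA", "AAA"), bg), "length mismatch")
})

test_that("normalization identities hold on random profiles", {
  set.seed(31)
  for (rep_ in 1:25) {
    L <- sample(3:15, 1)
    n <- sample(5:60, 1)
    members <- vapply(seq_len(n), function(i) {
      paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = "")
    }, character(1))
    bg <- compute_background(members)
    pr <- build_structure_profile(members, bg)
    expect_lt(max(abs(rowSums(pr$p) - 1)), 1e-9)
    expect_lt(max(abs(rowSums(sweep(pr$pro, 2, pr$background, "*")) - 1)),
              1e-9)
    # count conservation
    expect_equal(unname(rowSums(pr$counts)), rep(n, L))
    # determinism under member order
    pr2 <- build_structure_profile(sample(members), bg)
    expect_equal(pr2$counts, pr$counts)
  }
})

test_that("'X' residues shrink the per-position denominator", {
  members <- c("AXA", "AAA", "AVA", "XAA")
  bg <- compute_background(members)
  pr <- build_structure_profile(members, bg)
  expect_equal(unname(pr$counts[2, "A"]), 2L)
  expect_equal(unname(pr$p[2, "A"]), 2 / 3)   # X excluded from denominator
  expect_equal(rowSums(pr$p)[2], 1)
})

test_that("PSI-BLAST PSSMs parse with the column permutation", {
  prof <- sequence_profile("t1", strrep("A", 15),
                           matrix(rnorm(300), 15, 20))
  path <- withr::local_tempfile(fileext = ".pssm")
  write_pssm(prof, path)
  back <- read_pssm(path)
  expect_equal(nrow(back$scores), 15L)
  expect_equal(unname(back$scores), unname(prof$scores), tolerance = 1e-5)
  expect_equal(back$sequence, prof$sequence)

  # a value written under the PSI-BLAST 'R' column lands in the canonical 'R'
  lines <- c(" A R N D C Q E G H I L K M F P S T W Y V",
             paste("1 A", paste(1:20, collapse = " ")))
  sp <- read_pssm(paste(lines, collapse = "\n"))
  expect_equal(unname(sp$scores[1, "R"]), 2)  # 'R' is file column 2
  expect_equal(unname(sp$scores[1, "A"]), 1)
  expect_equal(unname(sp$scores[1, "V"]), 20)
  expect_equal(which(AA_ALPHABET == "R"), 15L)

  expect_error(read_pssm(paste(c(lines[1], "1 A 1 2 3"), collapse = "\n")),
               "malformed PSSM")
})

test_that("profile TSV round-trips byte-identically and keeps exact zeros", {
  set.seed(41)
  members <- vapply(1:30, function(i) {
    paste(sample(AA_ALPHABET[1:6], 8, replace = TRUE), collapse = "")
  }, character(1))
  pr <- build_structure_profile(members, compute_background(members), "c9")
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_profile_tsv(pr, p1)
  back <- read_profile_tsv(p1)
  write_profile_tsv(back, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_equal(back$counts, pr$counts)
  # background travels at 6 significant digits; propensities recompute from it
  expect_equal(back$pro, pr$pro, tolerance = 1e-5)
  expect_true(any(back$pro == 0))
  zero_cells <- pr$pro == 0
  expect_true(all(back$pro[zero_cells] == 0))

  sp <- sequence_profile("s1", strrep("C", 5), matrix(rnorm(100), 5, 20))
  write_profile_tsv(sp, p1)
  back2 <- read_profile_tsv(p1)
  write_profile_tsv(back2, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_equal(unname(back2$scores), unname(sp$scores), tolerance = 1e-5)
})

test_that("a shuffled alphabet header re-maps values on read", {
  members <- c("WWW", "WWA", "WAW")
  pr <- build_structure_profile(members, compute_background(members), "cw")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profile_tsv(pr, path)
  lines <- readLines(path)
  # permute the alphabet header and the body columns consistently
  perm <- c(20:1)
  alpha_line <- which(startsWith(lines, "# alphabet:"))
  bg_line <- which(startsWith(lines, "# background:"))
  lines[alpha_line] <- paste0("# alphabet: ",
                              paste(AA_ALPHABET[perm], collapse = ""))
  bg_vals <- strsplit(sub("# background: ", "", lines[bg_line]), "\t")[[1]]
  lines[bg_line] <- paste0("# background: ",
                           paste(bg_vals[perm], collapse = "\t"))
  body_start <- max(grep("^#", lines)) + 2L
  for (k in body_start:length(lines)) {
    f <- strsplit(lines[k], "\t")[[1]]
    lines[k] <- paste(c(f[1], f[-1][perm]), collapse = "\t")
  }
  writeLines(lines, path)
  back <- read_profile_tsv(path)
  expect_equal(unname(back$pro[, "W"]), unname(pr$pro[, "W"]),
               tolerance = 1e-5)
  expect_equal(back$counts, pr$counts)
})

test_that("logo data carries frequencies and information content", {
  members <- rep("GGG", 10)
  pr <- build_structure_profile(members,
                                setNames(rep(0.05, 20), AA_ALPHABET))
  ld <- logo_data(pr)
  expect_equal(nrow(ld), 60L)
  # a fully conserved column has the maximal information log2(20)
  expect_equal(unique(ld$information_bits), log2(20))
  expect_equal(sum(ld$frequency), 3)
})
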