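test_that("FASTA reading handles case, missing symbols, and errors", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">A", "acd", ">B", "AC-"), f)
  aln <- read_alignment(f)
  expect_equal(aln$n_taxa, 2L)
  expect_equal(aln$n_sites, 3L)
  expect_equal(aln$seq["A", ], c("A", "C", "D"))
  expect_true(is.na(aln$states["B", 3L]))

  writeLines(c(">A", "ACD", ">B", "AC"), f)
  expect_error(read_alignment(f), "ragged")
  writeLines(c(">A", "ACD", ">A", "ACD"), f)
  expect_error(read_alignment(f), "duplicate taxon")
  writeLines(c(">A", "AC*", ">B", "ACD"), f)
  expect_error(read_alignment(f), "unknown symbol '\\*'.*column 3")
  writeLines(c(">A", "A.D", ">B", "ACD"), f)
  expect_error(read_alignment(f), "unknown symbol")
})

test_that("PHYLIP reading supports both dialects and auto-detection", {
  f <- withr::local_tempfile(fileext = ".phy")
  writeLines(c(" 4 10",
               "tax1      ACDEFGHIKL",
               "tax2      ACDEFGHIK-",
               "tax3      ACDEFGHIKX",
               "tax4      ACDEFGHIK?"), f)
  aln <- read_alignment(f)  # auto
  expect_equal(aln$n_taxa, 4L)
  expect_equal(aln$n_sites, 10L)
  # '-', '?' and 'X' all code missing identically
  expect_true(all(is.na(aln$states[c("tax2", "tax3", "tax4"), 10L])))

  fi <- withr::local_tempfile(fileext = ".phy")
  writeLines(c(" 4 20",
               "tax1      ACDEFGHIKL", "tax2      ACDEFGHIKM",
               "tax3      ACDEFGHIKN", "tax4      ACDEFGHIKP",
               "", "MNPQRSTVWY", "MNPQRSTVWY", "MNPQRSTVWY", "MNPQRSTVWY"),
             fi)
  ali <- read_alignment(fi, format = "phylip-interleaved")
  expect_equal(ali$n_sites, 20L)
  expect_equal(paste(ali$seq["tax1", ], collapse = ""),
               "ACDEFGHIKLMNPQRSTVWY")
  ali2 <- read_alignment(fi)  # auto should also succeed
  expect_identical(ali2$seq, ali$seq)

  fd <- withr::local_tempfile()
  writeLines(c(" 2 3", "tax1 ACD", "tax1 ACD"), fd)
  expect_error(read_alignment(fd), "duplicate taxon")
})

test_that("alignment writing round-trips both formats exactly", {
  set.seed(11)
  for (fmt in c("fasta", "phylip-sequential")) {
    aln <- rand_aln(5L, 37L, missing = 0.15)
    f <- withr::local_tempfile()
    write_alignment(aln, f, format = fmt)
    rt <- read_alignment(f)
    expect_identical(rt$seq, aln$seq)
    expect_identical(rt$states, aln$states)
  }
})

test_that("labels with whitespace are sanitized with a warning", {
  m <- matrix(c("A", "C", "A", "C"), 2L, 2L, byrow = TRUE,
              dimnames = list(c("tax one", "tax_two"), NULL))
  aln <- aa_alignment(m)
  f <- withr::local_tempfile()
  expect_warning(write_alignment(aln, f, "fasta"), "whitespace")
  expect_equal(read_alignment(f)$taxa, c("tax_one", "tax_two"))
})

test_that("degenerate alignments are rejected", {
  expect_error(aa_alignment(matrix(character(0), 2L, 0L,
                                   dimnames = list(c("a", "b"), NULL))),
               "at least one column")
  expect_error(aa_alignment(c(a = "ACD", b = "AC")), "ragged")
})

test_that("Newick reading enforces the branch-length contract", {
  tr <- read_tree("((A:0.1,B:0.2):0.05,C:0.3,D:0.4);")
  expect_equal(length(tr$tip.label), 4L)
  expect_equal(nrow(tr$edge), 5L)
  expect_equal(sort(tr$edge.length), sort(c(0.1, 0.2, 0.05, 0.3, 0.4)))

  tr2 <- read_tree("(A:0.1,B:0.1);")
  expect_equal(sum(tr2$edge.length), 0.2)

  expect_warning(tr3 <- read_tree("((A,B),C);"), "defaulting")
  expect_true(all(tr3$edge.length == 0.1))
  expect_error(read_tree("((A:0.1,B:0.2;"))
  expect_error(read_tree("(A:-0.5,B:0.1);"), "negative")
})

test_that("taxon mismatch is a pairing-time validation error", {
  aln <- aa_alignment(c(A = "AC", B = "AC", Z = "AC"))
  tr <- read_tree("((A:0.1,B:0.2):0.05,C:0.3);")
  m <- instantiate_model(model_spec("poisson", "single", gamma = FALSE),
                         2L, seed = 1)
  expect_error(log_likelihood(aln, tr, m), "taxon mismatch")
})

test_that("profile sets read, renormalize, remap and reject bad rows", {
  f <- withr::local_tempfile()
  set.seed(2)
  m <- matrix(rgamma(60 * 20, 2), 60L)
  m <- m / rowSums(m)
  utils::write.table(format(m, digits = 10), f, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  ps <- read_profile_set(f, name = "C60")
  expect_equal(ps$n_components, 60L)
  expect_null(ps$weights)
  expect_true(all(abs(rowSums(ps$components) - 1) < 1e-8))

  writeLines(paste(rep("0.05", 20L), collapse = " "), f)
  ps1 <- read_profile_set(f)
  expect_equal(unname(ps1$components[1L, ]), rep(0.05, 20L))

  writeLines(paste(rep("0.049", 20L), collapse = " "), f)  # sums to 0.98
  expect_message(ps2 <- read_profile_set(f), "renormalized")
  expect_equal(sum(ps2$components), 1)

  writeLines(paste(rep("0.05", 19L), collapse = " "), f)
  expect_error(read_profile_set(f), "19 fields")
  writeLines(paste(c("-0.05", rep("0.05", 19L)), collapse = " "), f)
  expect_error(read_profile_set(f), "negative")
})

test_that("a profile file order directive remaps columns", {
  f <- withr::local_tempfile()
  ord <- rev(aa_alphabet())
  freqs <- seq(0.01, by = 0.001, length.out = 20L)
  freqs <- freqs / sum(freqs)
  writeLines(c(paste("# order:", paste(ord, collapse = "")),
               paste(format(freqs, digits = 12), collapse = " ")), f)
  ps <- read_profile_set(f)
  expect_equal(unname(ps$components[1L, "A"]), freqs[20L], tolerance = 1e-9)
  expect_equal(unname(ps$components[1L, "P"]), freqs[1L], tolerance = 1e-9)
})

test_that("weighted profile files carry their weights", {
  f <- withr::local_tempfile()
  rows <- vapply(c(2, 6), function(w) {
    paste(c(w, rep(0.05, 20L)), collapse = " ")
  }, character(1L))
  writeLines(rows, f)
  ps <- read_profile_set(f)
  expect_equal(ps$weights, c(0.25, 0.75))
})

test_that("traces round-trip at full precision", {
  tr <- data.frame(cycle = 1:3,
                   log_likelihood = c(-12345.6789, -1 / 3, -2e-17),
                   alpha = c(0.5, NA, 1.23456789012345e-5))
  f <- withr::local_tempfile()
  write_trace(tr, f)
  rt <- suppressWarnings(read_trace(f))
  expect_identical(rt$log_likelihood, tr$log_likelihood)
  expect_identical(rt$alpha, tr$alpha)

  write_trace(tr[0L, ], f)
  expect_equal(nrow(read_trace(f)), 0L)

  writeLines(c("cycle\tlog_likelihood", "1\t-2.5", "2\t-2.5\t9"), f)
  expect_error(read_trace(f), "trace format error")
  expect_error(write_trace(data.frame(cycle = c(2L, 1L),
                                      log_likelihood = c(0, 0)), f),
               "strictly increasing")
})

test_that("fold files round-trip with 1-based indices", {
  folds <- split_folds(100L, 5L, seed = 9L)
  f <- withr::local_tempfile()
  write_folds(folds, f)
  rt <- read_folds(f, 100L)
  for (i in seq_along(folds)) {
    expect_identical(rt[[i]]$test_indices, folds[[i]]$test_indices)
    expect_identical(rt[[i]]$learn_indices, folds[[i]]$learn_indices)
  }
  expect_true(all(vapply(readLines(f), function(s) {
    min(as.integer(strsplit(strsplit(s, "\t")[[1L]][3L], ",")[[1L]])) >= 1L
  }, logical(1L))))
})
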