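#' Read an amino acid alignment
#'
#' Reads FASTA (via seqinr) or PHYLIP (sequential or interleaved, via
#' phangorn).  `format = "auto"` inspects the first non-blank line: a
#' `"<n_taxa> <n_sites>"` header selects PHYLIP (sequential first, then
#' interleaved), anything else is read as FASTA.  Lowercase symbols are
#' upcased; `-`, `?` and `X` are kept as (interchangeable) missing-data
#' symbols; any other symbol (including `.` and `*`) is a format error
#' naming the offending symbol and position.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"fasta"`, `"phylip-sequential"`,
#'   `"phylip-interleaved"`.
#' @return An [aa_alignment].
#' @export
read_alignment <- function(path,
                           format = c("auto", "fasta", "phylip-sequential",
                                      "phylip-interleaved")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    ln <- readLines(path, warn = FALSE)
    ln <- ln[nzchar(trimws(ln))]
    if (length(ln) == 0L) stop("alignment format error: empty file")
    format <- if (grepl("^\\s*\\d+\\s+\\d+\\s*$", ln[1L])) {
      "phylip-auto"
    } else "fasta"
  }
  if (format == "fasta") {
    seqs <- seqinr::read.fasta(path, seqtype = "AA", set.attributes = FALSE,
                               forceDNAtolower = FALSE)
    if (length(seqs) == 0L) stop("alignment format error: no sequences")
    nm <- names(seqs)
    if (anyDuplicated(nm)) {
      stop("alignment format error: duplicate taxon label '",
           nm[duplicated(nm)][1L], "'")
    }
    lens <- lengths(seqs)
    if (length(unique(lens)) != 1L) {
      stop("alignment format error: ragged sequence lengths (",
           paste(unique(lens), collapse = ", "), ")")
    }
    m <- do.call(rbind, seqs)
    rownames(m) <- nm
    return(aa_alignment(m))
  }
  phy_formats <- switch(format,
    "phylip-sequential" = "sequential",
    "phylip-interleaved" = "interleaved",
    "phylip-auto" = c("sequential", "interleaved"))
  check_phylip_names(path)
  last_err <- NULL
  for (f in phy_formats) {
    d <- tryCatch(phangorn::read.phyDat(path, format = f, type = "AA"),
                  error = function(e) e)
    if (!inherits(d, "error")) {
      m <- as.character(d)
      return(aa_alignment(m))
    }
    last_err <- d
  }
  stop("alignment format error: could not parse PHYLIP file: ",
       conditionMessage(last_err))
}

# phangorn de-duplicates silently in some paths; enforce the duplicate-label
# contract by scanning the name field of the header block ourselves.
check_phylip_names <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- ln[nzchar(trimws(ln))]
  hdr <- strsplit(trimws(ln[1L]), "\\s+")[[1L]]
  n_taxa <- suppressWarnings(as.integer(hdr[1L]))
  if (is.na(n_taxa) || length(ln) < n_taxa + 1L) {
    stop("alignment format error: malformed PHYLIP header")
  }
  nm <- vapply(ln[2L:(n_taxa + 1L)],
               function(s) strsplit(trimws(s), "\\s+")[[1L]][1L],
               character(1L), USE.NAMES = FALSE)
  if (anyDuplicated(nm)) {
    stop("alignment format error: duplicate taxon label '",
         nm[duplicated(nm)][1L], "'")
  }
  invisible(nm)
}

#' Write an amino acid alignment
#'
#' Round-trips exactly through [read_alignment], including the missing
#' symbols `-`, `?`, `X`.  Taxon labels containing whitespace are
#' sanitized (whitespace replaced by `_`) with a warning, since both
#' formats delimit labels by whitespace.
#'
#' @param aln an [aa_alignment].
#' @param path output file path.
#' @param format `"fasta"` or `"phylip-sequential"`.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "phylip-sequential")) {
  format <- match.arg(format)
  stopifnot(inherits(aln, "aa_alignment"))
  taxa <- aln$taxa
  if (any(grepl("\\s", taxa))) {
    warning("taxon labels contain whitespace; replaced by '_'")
    taxa <- gsub("\\s+", "_", taxa)
    if (anyDuplicated(taxa)) stop("label sanitization created duplicates")
  }
  seqs <- vapply(seq_len(aln$n_taxa),
                 function(i) paste(aln$seq[i, ], collapse = ""), character(1L))
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "fasta") {
    for (i in seq_along(taxa)) {
      writeLines(c(paste0(">", taxa[i]),
                   gsub("(.{60})", "\\1\n", seqs[i])), con)
    }
  } else {
    writeLines(sprintf(" %d %d", aln$n_taxa, aln$n_sites), con)
    writeLines(sprintf("%-*s  %s", max(nchar(taxa)), taxa, seqs), con)
  }
  invisible(path)
}

#' Read a phylogenetic tree
#'
#' Thin wrapper around [ape::read.tree] that enforces the package's tree
#' contract: branch lengths are required on every edge; edges missing a
#' length are set to `default_length` with a warning; negative lengths are
#' an error.  Leaf-label agreement with an alignment is checked later,
#' when tree and alignment are paired (see [log_likelihood]).
#'
#' @param x a file path or a Newick string.
#' @param default_length branch length substituted (with a warning) for
#'   edges without one.
#' @return An [ape::phylo] tree.
#' @export
read_tree <- function(x, default_length = 0.1) {
  tr <- if (file.exists(x)) ape::read.tree(file = x) else ape::read.tree(text = x)
  if (is.null(tr)) stop("tree parse error: invalid Newick")
  if (is.null(tr$edge.length)) {
    warning("tree has no branch lengths; defaulting all to ", default_length)
    tr$edge.length <- rep(default_length, nrow(tr$edge))
  } else if (anyNA(tr$edge.length)) {
    warning("tree has edges without branch lengths; defaulting to ",
            default_length)
    tr$edge.length[is.na(tr$edge.length)] <- default_length
  }
  if (any(tr$edge.length < 0)) stop("tree has negative branch lengths")
  tr
}

# check a tree/alignment pair share a taxon set (validation error at
# pairing time per the IO contract)
check_tree_taxa <- function(tree, taxa) {
  if (!setequal(tree$tip.label, taxa)) {
    miss <- setdiff(taxa, tree$tip.label)
    extra <- setdiff(tree$tip.label, taxa)
    stop("tree/alignment taxon mismatch",
         if (length(miss)) paste0("; absent from tree: ",
                                  paste(miss, collapse = ", ")),
         if (length(extra)) paste0("; absent from alignment: ",
                                   paste(extra, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Read a profile set
#'
#' Reads a whitespace-delimited table of amino acid frequency profiles,
#' one component per row: either 20 frequencies, or a weight followed by
#' 20 frequencies (detected from the field count, which must be constant).
#' Columns follow the canonical order `ARNDCQEGHILKMFWYVSTP` unless the
#' file starts with a directive line `# order: <20 letters>`, in which
#' case columns are remapped.  Frequencies are floored at `floor` and
#' renormalized to sum to one (a message is emitted when a row needed
#' renormalization beyond `1e-6`); weights are renormalized likewise.
#'
#' @param path file path.
#' @param name identifier for the set (defaults to the file base name).
#' @param floor frequency floor applied before renormalization.
#' @return A [profile_set].
#' @export
read_profile_set <- function(path, name = NULL, floor = 1e-8) {
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  ln <- readLines(path, warn = FALSE)
  order <- AA_ORDER
  dir <- grep("^#\\s*order\\s*:", ln, ignore.case = TRUE, value = TRUE)
  if (length(dir)) {
    ord <- toupper(gsub(".*:\\s*", "", dir[1L]))
    ord <- strsplit(gsub("\\s", "", ord), "")[[1L]]
    if (!setequal(ord, AA_ORDER) || length(ord) != 20L) {
      stop("profile format error: bad order directive")
    }
    order <- ord
  }
  ln <- ln[!grepl("^\\s*#", ln) & nzchar(trimws(ln))]
  if (!length(ln)) stop("profile format error: no rows")
  fields <- strsplit(trimws(ln), "\\s+")
  nf <- lengths(fields)
  if (!all(nf %in% c(20L, 21L)) || length(unique(nf)) != 1L) {
    stop("profile format error: row with ", nf[which(!nf %in% c(20L, 21L))[1L]],
         " fields (expected 20, or 21 with a leading weight)")
  }
  m <- suppressWarnings(matrix(as.numeric(unlist(fields)), length(ln),
                               nf[1L], byrow = TRUE))
  if (anyNA(m)) stop("profile format error: non-numeric field")
  weights <- NULL
  if (nf[1L] == 21L) {
    weights <- m[, 1L]
    m <- m[, -1L, drop = FALSE]
  }
  if (any(m < 0)) stop("profile format error: negative frequency")
  m <- m[, match(AA_ORDER, order), drop = FALSE]
  profile_set(m, weights = weights, name = name, floor = floor)
}

#' Construct a profile set
#'
#' @param components numeric matrix, one row per mixture component, 20
#'   columns of amino acid frequencies in canonical order.
#' @param weights optional prior weights, one per component.
#' @param name identifier (e.g. `"C60"`, `"UDM256"`).
#' @param floor frequency floor applied before renormalization.
#' @return An object of class `profile_set`.
#' @export
profile_set <- function(components, weights = NULL, name = "profiles",
                        floor = 1e-8) {
  components <- as.matrix(components)
  if (ncol(components) != 20L) stop("profiles must have 20 columns")
  if (any(components < 0)) stop("negative frequency in profile")
  raw_sums <- rowSums(components)
  components <- pmax(components, floor)
  components <- components / rowSums(components)
  if (any(abs(raw_sums - 1) > 1e-6)) {
    message(sum(abs(raw_sums - 1) > 1e-6),
            " profile row(s) renormalized to sum to 1")
  }
  if (!is.null(weights)) {
    if (length(weights) != nrow(components)) {
      stop("one weight per component required")
    }
    if (any(weights < 0)) stop("negative weight")
    weights <- weights / sum(weights)
  }
  colnames(components) <- AA_ORDER
  structure(list(name = name, components = components, weights = weights,
                 n_components = nrow(components)),
            class = "profile_set")
}

#' @export
print.profile_set <- function(x, ...) {
  cat("Profile set '", x$name, "': ", x$n_components, " components",
      if (!is.null(x$weights)) " (with weights)", "\n", sep = "")
  invisible(x)
}

#' Write a profile set
#'
#' @param ps a [profile_set].
#' @param path output path.
#' @export
write_profile_set <- function(ps, path) {
  stopifnot(inherits(ps, "profile_set"))
  m <- ps$components
  if (!is.null(ps$weights)) m <- cbind(ps$weights, m)
  utils::write.table(format(m, digits = 17, scientific = TRUE, trim = TRUE),
                     path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write an MCMC trace
#'
#' Tab-separated with a header row; numeric values printed with 17
#' significant digits so that a read/write cycle preserves them exactly.
#'
#' @param trace data frame with columns `cycle`, `log_likelihood`, then
#'   one column per scalar parameter summary.
#' @param path output path.
#' @export
write_trace <- function(trace, path) {
  stopifnot(is.data.frame(trace), all(c("cycle", "log_likelihood") %in%
                                        names(trace)))
  if (nrow(trace) && is.unsorted(trace$cycle, strictly = TRUE)) {
    stop("trace cycles must be strictly increasing")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(trace), collapse = "\t"), con)
  if (nrow(trace)) {
    cols <- lapply(trace, function(v) {
      if (is.double(v)) sprintf("%.17g", v) else as.character(v)
    })
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}

#' Read an MCMC trace written by [write_trace]
#'
#' @param path trace file path.
#' @return Data frame; an empty (header-only) file yields zero rows.
#' @export
read_trace <- function(path) {
  ln <- readLines(path, warn = FALSE)
  if (!length(ln)) stop("trace format error: empty file")
  hdr <- strsplit(ln[1L], "\t", fixed = TRUE)[[1L]]
  body <- ln[-1L]
  if (!length(body)) {
    df <- as.data.frame(matrix(numeric(0), 0L, length(hdr)))
    names(df) <- hdr
    return(df)
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(fields) != length(hdr))) {
    stop("trace format error: row with ",
         lengths(fields)[lengths(fields) != length(hdr)][1L],
         " fields, header has ", length(hdr))
  }
  df <- as.data.frame(lapply(seq_along(hdr), function(j) {
    as.numeric(vapply(fields, `[[`, character(1L), j))
  }))
  names(df) <- hdr
  if (is.unsorted(df$cycle, strictly = TRUE)) {
    stop("trace format error: cycles not strictly increasing")
  }
  df
}

#' Write fold splits
#'
#' One line per replicate: `replicate<TAB>test<TAB>i1,i2,...` with
#' 1-based, sorted column indices.
#'
#' @param folds list of fold splits from [split_folds].
#' @param path output path.
#' @export
write_folds <- function(folds, path) {
  ln <- vapply(folds, function(f) {
    sprintf("%d\ttest\t%s", f$replicate_id,
            paste(sort(f$test_indices), collapse = ","))
  }, character(1L))
  writeLines(ln, path)
  invisible(path)
}

#' Read fold splits written by [write_folds]
#'
#' @param path fold file path.
#' @param n_sites total number of alignment columns (to reconstruct the
#'   learning sets).
#' @return List of fold splits (see [split_folds]).
#' @export
read_folds <- function(path, n_sites) {
  ln <- readLines(path, warn = FALSE)
  ln <- ln[nzchar(ln)]
  lapply(ln, function(s) {
    f <- strsplit(s, "\t", fixed = TRUE)[[1L]]
    if (length(f) != 3L || f[2L] != "test") stop("fold file format error")
    test <- as.integer(strsplit(f[3L], ",", fixed = TRUE)[[1L]])
    if (anyNA(test) || any(test < 1L) || any(test > n_sites)) {
      stop("fold file format error: test index out of range")
    }
    new_fold(as.integer(f[1L]), test, n_sites)
  })
}
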