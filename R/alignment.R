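# Canonical amino acid order used for every profile, rate matrix and
# transition matrix in the package.  Profile files may declare a different
# column order via a header directive and are remapped on read.
AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "W", "Y", "V", "S", "T", "P")

# '-', '?' and 'X' are treated identically: the site contributes a partial
# likelihood vector of ones for that taxon (missing data are marginalized).
MISSING_SYMBOLS <- c("-", "?", "X")

#' Amino acid alphabet
#'
#' The 20 amino acid one-letter codes in the package's canonical order,
#' optionally followed by the missing-data symbols `-`, `?` and `X`, which
#' the package treats interchangeably.
#'
#' @param missing logical; append the missing-data symbols?
#' @return Character vector of symbols.
#' @export
aa_alphabet <- function(missing = FALSE) {
  if (missing) c(AA_ORDER, MISSING_SYMBOLS) else AA_ORDER
}

#' Construct an amino acid alignment
#'
#' An `aa_alignment` stores a taxa-by-sites character matrix over the
#' 20-letter amino acid alphabet plus the missing symbols `-`, `?`, `X`
#' (all treated as missing data), together with an integer coding used by
#' the likelihood machinery (1..20, `NA` for missing).
#'
#' @param x character matrix (taxa in rows, sites in columns) with unique
#'   row names, or a named character vector of equal-length sequence
#'   strings.
#' @return An object of class `aa_alignment` with elements `seq`
#'   (character matrix), `states` (integer matrix, `NA` = missing),
#'   `taxa`, `n_taxa`, `n_sites`.
#' @examples
#' aln <- aa_alignment(c(t1 = "ACDE", t2 = "AC-E"))
#' aln$n_sites
#' @export
aa_alignment <- function(x) {
  if (is.character(x) && !is.matrix(x)) {
    if (is.null(names(x))) stop("sequences must be named by taxon")
    nc <- nchar(x)
    if (length(unique(nc)) != 1L) {
      stop("alignment format error: ragged sequence lengths (",
           paste(unique(nc), collapse = ", "), ")")
    }
    x <- do.call(rbind, strsplit(x, "", fixed = TRUE))
    rownames(x) <- names(nc)
  }
  if (!is.matrix(x) || !is.character(x)) stop("x must be a character matrix")
  if (is.null(rownames(x))) stop("alignment rows must be named by taxon")
  x[] <- toupper(x)
  taxa <- rownames(x)
  if (anyDuplicated(taxa)) {
    stop("alignment format error: duplicate taxon label '",
         taxa[duplicated(taxa)][1L], "'")
  }
  if (ncol(x) < 1L) stop("alignment must have at least one column (n_sites >= 1)")
  ok <- x %in% c(AA_ORDER, MISSING_SYMBOLS)
  if (!all(ok)) {
    bad <- which(!ok)[1L]
    pos <- arrayInd(bad, dim(x))
    stop("alignment format error: unknown symbol '", x[bad], "' at taxon '",
         taxa[pos[1L]], "', column ", pos[2L])
  }
  states <- matrix(match(x, AA_ORDER), nrow(x), ncol(x))
  rownames(states) <- taxa
  structure(
    list(seq = x, states = states, taxa = taxa,
         n_taxa = nrow(x), n_sites = ncol(x)),
    class = "aa_alignment")
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat("Amino acid alignment: ", x$n_taxa, " taxa x ", x$n_sites, " sites\n",
      sep = "")
  frac <- mean(is.na(x$states))
  cat(sprintf("missing/gap fraction: %.3f\n", frac))
  invisible(x)
}

#' Extract alignment columns
#'
#' @param x an `aa_alignment`.
#' @param i column (site) indices, 1-based.
#' @param ... ignored.
#' @return An `aa_alignment` restricted to the selected columns.
#' @export
`[.aa_alignment` <- function(x, i, ...) {
  aa_alignment(x$seq[, i, drop = FALSE])
}

# sequences as strings, named by taxon
aln_strings <- function(aln) {
  vapply(seq_len(aln$n_taxa),
         function(i) paste(aln$seq[i, ], collapse = ""), character(1L)) |>
    stats::setNames(aln$taxa)
}
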