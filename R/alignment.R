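# Alignment container and readers/writers for FASTA and relaxed PHYLIP.

.alphabets <- list(
  AA20 = list(
    states  = c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
    missing = c("-", "?", "X")
  ),
  NT4 = list(
    states  = c("A", "C", "G", "T"),
    missing = c("-", "?", "N")
  )
)

#' Multiple sequence alignment container
#'
#' An alignment is a character matrix of uppercase residues with one row per
#' taxon (unique rownames) over a fixed alphabet: `"AA20"` (20 amino acids,
#' missing symbols `-`, `?`, `X`) or `"NT4"` (4 nucleotides, missing symbols
#' `-`, `?`, `N`). Residues outside the alphabet are mapped to `?` with a
#' warning giving the replacement count.
#'
#' @param x Character matrix (rows = taxa, columns = sites) with rownames,
#'   or a named character vector of equal-length sequence strings.
#' @param alphabet `"AA20"` or `"NT4"`.
#' @return An object of class `teleo_alignment`: the normalized character
#'   matrix with attribute `alphabet`.
#' @examples
#' a <- teleo_alignment(c(t1 = "ARND", t2 = "ARNE"), "AA20")
#' n_sites(a)
#' @export
teleo_alignment <- function(x, alphabet = c("AA20", "NT4")) {
  alphabet <- match.arg(alphabet)
  if (is.character(x) && !is.matrix(x)) {
    if (is.null(names(x))) stop("sequences must be named", call. = FALSE)
    lens <- nchar(x)
    if (length(unique(lens)) > 1L) {
      bad <- names(x)[which(lens != lens[1L])[1L]]
      stop("ragged alignment: taxon '", bad, "' has a different length",
           call. = FALSE)
    }
    x <- do.call(rbind, strsplit(x, "", fixed = TRUE))
  }
  stopifnot(is.matrix(x), is.character(x))
  if (is.null(rownames(x))) stop("alignment matrix must have rownames",
                                 call. = FALSE)
  if (anyDuplicated(rownames(x)))
    stop("duplicate taxon name: '",
         rownames(x)[duplicated(rownames(x))][1L], "'", call. = FALSE)
  ab <- .alphabets[[alphabet]]
  x[] <- toupper(x)
  if (alphabet == "NT4") x[x == "U"] <- "T"
  legal <- c(ab$states, ab$missing)
  bad <- !(x %in% legal)
  if (any(bad)) {
    warning(sum(bad), " residue(s) outside the ", alphabet,
            " alphabet mapped to missing", call. = FALSE)
    x[bad] <- "?"
  }
  structure(x, alphabet = alphabet, class = c("teleo_alignment", "matrix"))
}

#' @export
print.teleo_alignment <- function(x, ...) {
  cat("<teleo_alignment> ", nrow(x), " taxa x ", ncol(x), " sites (",
      attr(x, "alphabet"), ")\n", sep = "")
  invisible(x)
}

#' @rdname teleo_alignment
#' @param a A `teleo_alignment`.
#' @export
alignment_taxa <- function(a) rownames(a)

#' @rdname teleo_alignment
#' @export
n_sites <- function(a) ncol(a)

.is_missing <- function(a) {
  ab <- .alphabets[[attr(a, "alphabet")]]
  matrix(unclass(a) %in% ab$missing, nrow(a), ncol(a),
         dimnames = dimnames(a))
}

#' Read an alignment from FASTA or relaxed PHYLIP
#'
#' FASTA is parsed with [Biostrings::readBStringSet()]; sequence names are
#' truncated at the first whitespace. The PHYLIP dialect is relaxed
#' (whitespace-delimited names of any length, sequences may continue over
#' several lines). Residues are uppercased; residues outside the alphabet are
#' mapped to missing with a warning.
#'
#' @param path File path.
#' @param format `"fasta"` or `"phylip"`.
#' @param alphabet `"AA20"` or `"NT4"`.
#' @return A [teleo_alignment].
#' @export
parse_alignment <- function(path, format = c("fasta", "phylip"),
                            alphabet = c("AA20", "NT4")) {
  format <- match.arg(format)
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "fasta") {
    ss <- Biostrings::readBStringSet(path)
    seqs <- as.character(ss)
    names(seqs) <- sub("\\s.*$", "", names(ss))
  } else {
    seqs <- .read_relaxed_phylip(path)
  }
  teleo_alignment(seqs, alphabet)
}

.read_relaxed_phylip <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- scan(text = lines[1L], what = numeric(), quiet = TRUE)
  if (length(hdr) != 2L)
    stop("malformed PHYLIP header: '", lines[1L], "'", call. = FALSE)
  ntax <- hdr[1L]; nsite <- hdr[2L]
  toks <- scan(text = paste(lines[-1L], collapse = "\n"),
               what = character(), quiet = TRUE)
  seqs <- character(0)
  i <- 1L
  for (s in seq_len(ntax)) {
    if (i > length(toks)) stop("PHYLIP truncated: expected ", ntax,
                               " taxa, found ", s - 1L, call. = FALSE)
    nm <- toks[i]; i <- i + 1L
    acc <- ""
    while (nchar(acc) < nsite) {
      if (i > length(toks))
        stop("ragged PHYLIP row: taxon '", nm, "' has ", nchar(acc),
             " residues, expected ", nsite, call. = FALSE)
      acc <- paste0(acc, toks[i]); i <- i + 1L
    }
    if (nchar(acc) != nsite)
      stop("ragged PHYLIP row: taxon '", nm, "' has ", nchar(acc),
           " residues, expected ", nsite, call. = FALSE)
    seqs[nm] <- acc
  }
  if (i <= length(toks))
    stop("trailing content after ", ntax, " taxa in PHYLIP file",
         call. = FALSE)
  seqs
}

#' Write an alignment to FASTA or relaxed PHYLIP
#'
#' @inheritParams parse_alignment
#' @param a A [teleo_alignment].
#' @param line_width Residues per line for FASTA (canonical width 60).
#' @return `path`, invisibly.
#' @export
write_alignment <- function(a, path, format = c("fasta", "phylip"),
                            line_width = 60L) {
  format <- match.arg(format)
  seqs <- apply(unclass(a), 1L, paste, collapse = "")
  if (format == "fasta") {
    chunks <- lapply(seqs, function(s) {
      starts <- seq(1L, nchar(s), by = line_width)
      substring(s, starts, pmin(starts + line_width - 1L, nchar(s)))
    })
    out <- unlist(mapply(function(nm, ch) c(paste0(">", nm), ch),
                         names(seqs), chunks, SIMPLIFY = FALSE))
  } else {
    out <- c(paste(nrow(a), ncol(a)), paste(names(seqs), seqs))
  }
  writeLines(out, path)
  invisible(path)
}

#' Empirical residue frequencies of an alignment
#'
#' Counts are pooled over all taxa with gaps/missing excluded. Zero counts
#' are floored at a small positive value and the vector renormalized, so +F
#' models never assign probability zero to a residue absent from the data.
#'
#' @param a A [teleo_alignment].
#' @param floor Lower bound applied to zero frequencies before renormalizing.
#' @return Named numeric vector summing to 1, in alphabet state order.
#' @export
empirical_frequencies <- function(a, floor = 1e-10) {
  ab <- .alphabets[[attr(a, "alphabet")]]
  cnt <- table(factor(unclass(a), levels = ab$states))
  f <- as.numeric(cnt)
  if (sum(f) == 0) stop("alignment has no non-missing residues",
                        call. = FALSE)
  f <- f / sum(f)
  f[f < floor] <- floor
  f <- f / sum(f)
  names(f) <- ab$states
  f
}

#' Restrict an alignment to a subset of taxa
#'
#' Rows are restricted to `keep` preserving the original row order; column
#' content is unchanged.
#'
#' @param a A [teleo_alignment].
#' @param keep Character vector of taxon names to retain.
#' @return A [teleo_alignment] with `length(keep)` rows.
#' @export
extract_taxon_subset <- function(a, keep) {
  unknown <- setdiff(keep, rownames(a))
  if (length(unknown))
    stop("unknown taxon: '", unknown[1L], "'", call. = FALSE)
  idx <- which(rownames(a) %in% keep)
  structure(unclass(a)[idx, , drop = FALSE],
            alphabet = attr(a, "alphabet"),
            class = c("teleo_alignment", "matrix"))
}

#' Number of shared sites
#'
#' A site is shared when every taxon in the alignment has a non-missing
#' residue in that column.
#'
#' @param a A [teleo_alignment].
#' @return Integer count of shared columns.
#' @export
shared_site_count <- function(a) {
  miss <- .is_missing(a)
  sum(colSums(miss) == 0L)
}

#' Compress alignment columns into site patterns
#'
#' Identical columns are collapsed into unique patterns with integer weights;
#' all likelihood computations run over patterns so the result is identical
#' to computing over raw sites.
#'
#' @param a A [teleo_alignment].
#' @return An object of class `teleo_patterns`: list with `states` (integer
#'   matrix, taxa x patterns; 1-based state index, 0 = missing), `weights`
#'   (pattern multiplicities summing to the site count), `index` (map from
#'   site to pattern column), `taxa` and `alphabet`.
#' @export
compress_patterns <- function(a) {
  if (ncol(a) == 0L) stop("empty alignment", call. = FALSE)
  ab <- .alphabets[[attr(a, "alphabet")]]
  im <- matrix(match(unclass(a), ab$states, nomatch = 0L), nrow(a), ncol(a))
  keys <- do.call(paste, c(lapply(seq_len(nrow(im)), function(i) im[i, ]),
                           sep = ","))
  uk <- unique(keys)
  index <- match(keys, uk)
  first <- match(uk, keys)
  structure(list(
    states = im[, first, drop = FALSE],
    weights = as.numeric(tabulate(index, nbins = length(uk))),
    index = index,
    taxa = rownames(a),
    alphabet = attr(a, "alphabet")
  ), class = "teleo_patterns")
}

#' @export
print.teleo_patterns <- function(x, ...) {
  cat("<teleo_patterns> ", length(x$taxa), " taxa, ",
      length(x$weights), " patterns over ", sum(x$weights), " sites\n",
      sep = "")
  invisible(x)
}
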