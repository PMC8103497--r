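# Newick parsing/writing (thin wrappers over ape) and branch-length sums.

#' Parse a Newick string
#'
#' Wraps [ape::read.tree()] with an explicit parenthesis-balance check so a
#' malformed string fails with the character position of the imbalance.
#' Internal node labels (e.g. support values) are preserved but never
#' interpreted; absent branch lengths default to 0.
#'
#' @param text A single Newick string (terminated by `;`).
#' @return An [ape::phylo] tree.
#' @examples
#' tr <- parse_newick("(A:0.1,B:0.2);")
#' total_branch_length(tr)
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(text, "")[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L)
      stop("unbalanced ')' at position ", i, call. = FALSE)
  }
  if (depth != 0L)
    stop("unbalanced '(' : ", depth, " unclosed at end of string",
         call. = FALSE)
  semi <- regexpr(";", text, fixed = TRUE)
  if (semi > 0L && semi < nchar(trimws(text)))
    stop("trailing content after ';' at position ", semi + 1L,
         call. = FALSE)
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("Newick parse error: ",
                                          conditionMessage(e), call. = FALSE))
  if (is.null(tr)) stop("Newick parse error", call. = FALSE)
  if (is.null(tr$edge.length)) tr$edge.length <- rep(0, nrow(tr$edge))
  tr$edge.length[is.na(tr$edge.length)] <- 0
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip label: '",
         tr$tip.label[duplicated(tr$tip.label)][1L], "'", call. = FALSE)
  if (any(tr$edge.length < 0))
    stop("negative branch length", call. = FALSE)
  tr
}

#' Write a tree as a Newick string
#'
#' @param tree An [ape::phylo] tree.
#' @param file Optional path; when `NULL` the string is returned.
#' @return The Newick string (invisibly when written to file).
#' @export
write_newick <- function(tree, file = NULL) {
  s <- ape::write.tree(tree)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' Total branch length (TBL) of a tree
#'
#' The sum of all edge lengths, the gene-divergence measure used to rank
#' loci (slowly evolving loci have short TBLs).
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @return Numeric scalar.
#' @export
total_branch_length <- function(tree) {
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  sum(tree$edge.length)
}

# sum of edge lengths along the unique path between two nodes
.path_length <- function(tree, from, to) {
  if (from == to) return(0)
  np <- ape::nodepath(tree, from, to)
  len <- 0
  for (i in seq_len(length(np) - 1L)) {
    e <- which((tree$edge[, 1L] == np[i] & tree$edge[, 2L] == np[i + 1L]) |
               (tree$edge[, 1L] == np[i + 1L] & tree$edge[, 2L] == np[i]))
    len <- len + tree$edge.length[e[1L]]
  }
  len
}
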