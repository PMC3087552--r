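#' Read a Newick tree
#'
#' Thin validating wrapper around [ape::read.tree()]: rejects unparseable
#' strings and negative branch lengths.
#'
#' @param text Newick string (mutually exclusive with `path`).
#' @param path Path to a Newick file.
#' @return An [ape::phylo] tree.
#' @export
read_tree <- function(text = NULL, path = NULL) {
  if (is.null(text) == is.null(path)) {
    abort("supply exactly one of `text` or `path`")
  }
  if (!is.null(path)) text <- paste(readLines(path), collapse = "")
  if (!grepl(";\\s*$", text)) abort("Newick string must end with ';'")
  tr <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(tr) || !inherits(tr, "phylo")) {
    abort(paste0("malformed Newick: ", substr(text, 1, 60)))
  }
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0)) {
    abort("negative branch length in Newick tree")
  }
  if (anyDuplicated(tr$tip.label)) abort("duplicated leaf labels")
  tr
}

#' Write a tree as a Newick string
#'
#' Branch lengths are written with 12 significant digits so that
#' `read_tree(write_tree(x))` round-trips within 1e-9.
#'
#' @param tree An [ape::phylo] tree.
#' @param path Optional output file; if `NULL` the string is returned.
#' @return The Newick string (invisibly when `path` is given).
#' @export
write_tree <- function(tree, path = NULL) {
  nwk <- newick_string(tree)
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}

# Newick serializer with fixed %.12g branch-length formatting (ape's default
# digits are not guaranteed to round-trip at 1e-9).
newick_string <- function(tree) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  rec <- function(node, elen) {
    lab <- if (node <= n_tip) tree$tip.label[node] else ""
    kid_rows <- children[[as.character(node)]]
    body <- if (is.null(kid_rows)) lab else {
      paste0("(", paste(vapply(kid_rows, function(r) {
        rec(tree$edge[r, 2], tree$edge.length[r])
      }, character(1)), collapse = ","), ")", lab)
    }
    if (is.na(elen)) body else paste0(body, ":", sprintf("%.12g", elen))
  }
  if (is.null(tree$edge.length)) {
    return(ape::write.tree(tree))
  }
  paste0(rec(root, NA_real_), ";")
}
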