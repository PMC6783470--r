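#' Construct a protein alignment from sequence strings
#'
#' Validates and normalises a set of aligned protein sequences: residues are
#' upper-cased, '.' gap characters become '-', and the alphabet is restricted
#' to the 20 canonical residues plus '-', 'X', 'B', 'Z'. Selenocysteine 'U'
#' and pyrrolysine 'O' are rejected because they cannot be classified by the
#' CvP statistic.
#'
#' @param seqs named character vector of aligned sequences (equal lengths).
#' @return A [ProteinAlignment-class].
#' @examples
#' proteinAlignment(c(a = "RKDE", b = "QNST"))
#' @export
proteinAlignment <- function(seqs) {
  ids <- trimws(names(seqs))
  if (is.null(ids) || any(!nzchar(ids)))
    stop("every sequence must carry a non-empty identifier")
  if (anyDuplicated(ids))
    stop("duplicate sequence id: ", ids[duplicated(ids)][1L])
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("alignment rows have unequal lengths (", paste(unique(lens), collapse = ", "),
         "): not a rectangular alignment")
  chars <- matrix(toupper(unlist(strsplit(unname(seqs), "", fixed = TRUE))),
                  nrow = length(seqs), byrow = TRUE)
  chars[chars == "."] <- "-"
  rownames(chars) <- ids
  methods::new("ProteinAlignment", ids = ids, chars = chars)
}

#' Read a gapped protein alignment from FASTA
#'
#' @param path FASTA file with at least two records.
#' @return A [ProteinAlignment-class].
#' @seealso [writeFastaAlignment()]
#' @export
readFastaAlignment <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) < 2L)
    stop("alignment FASTA must contain at least 2 records: ", path)
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))  # FASTA id = first token
  proteinAlignment(seqs)
}

#' Write a protein alignment to FASTA
#'
#' @param alignment a [ProteinAlignment-class].
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
writeFastaAlignment <- function(alignment, path) {
  stopifnot(methods::is(alignment, "ProteinAlignment"))
  set <- Biostrings::BStringSet(sequenceStrings(alignment))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Validate a phylogeny for use in this package
#'
#' Checks unique leaf labels, presence and non-negativity of all branch
#' lengths, and (optionally) rootedness. Rootedness follows the Newick
#' convention: a bifurcating top-level split is rooted, a basal
#' multifurcation is unrooted.
#'
#' @param tree an \code{ape::phylo}.
#' @param requireRooted error if the tree is not rooted.
#' @return Invisibly, \code{tree}.
#' @export
validatePhyloTree <- function(tree, requireRooted = FALSE) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf label: ", tree$tip.label[duplicated(tree$tip.label)][1L])
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("every branch must carry a length")
  if (length(tree$edge.length) != nrow(tree$edge))
    stop("branch length count does not match edge count")
  if (any(tree$edge.length < 0))
    stop("negative branch length (", min(tree$edge.length), ") not allowed")
  if (requireRooted && !ape::is.rooted(tree))
    stop("a rooted tree is required here")
  invisible(tree)
}

#' Read a phylogeny from a Newick file
#'
#' One Newick statement; branch lengths are mandatory and must be
#' non-negative. A top-level trifurcation is reported as unrooted
#' (\code{ape::is.rooted}), a bifurcation as rooted.
#'
#' @param path Newick file.
#' @param text optional literal Newick string instead of a file.
#' @return An \code{ape::phylo}.
#' @seealso [writeNewick()], [madRoot()]
#' @export
readNewick <- function(path, text = NULL) {
  tree <- if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
  if (is.null(tree)) stop("could not parse Newick input")
  if (inherits(tree, "multiPhylo")) {
    if (length(tree) != 1L) stop("expected exactly one Newick statement")
    tree <- tree[[1L]]
  }
  validatePhyloTree(tree)
}

#' Write a phylogeny to Newick
#'
#' Branch lengths are emitted to 10 significant digits so that a
#' write-then-read round trip preserves them.
#'
#' @param tree an \code{ape::phylo}.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
writeNewick <- function(tree, path) {
  validatePhyloTree(tree)
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}

#' Read a table of extant-taxon optimal growth temperatures
#'
#' Tab-separated with a header; required columns \code{taxon} and
#' \code{ogt_celsius}, optional \code{copy_id} (distinguishing multiple gene
#' copies of one species; defaults to "1") and \code{psychrophile} (logical;
#' defaults to FALSE).
#'
#' @param path TSV file.
#' @return data.frame with columns taxon, ogt_celsius, copy_id, psychrophile.
#' @seealso [buildCalibrationPoints()]
#' @export
readOgtTable <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  validateOgtRecords(df)
}

#' Validate OGT records
#'
#' Applies the [readOgtTable()] contract to an in-memory data.frame.
#'
#' @param df data.frame with at least columns taxon and ogt_celsius.
#' @return The normalised data.frame.
#' @export
validateOgtRecords <- function(df) {
  if (!all(c("taxon", "ogt_celsius") %in% names(df)))
    stop("OGT table requires columns 'taxon' and 'ogt_celsius'")
  df$taxon <- trimws(as.character(df$taxon))
  ogt <- suppressWarnings(as.numeric(df$ogt_celsius))
  if (anyNA(ogt))
    stop("non-numeric OGT for taxon: ",
         df$taxon[which(is.na(ogt))[1L]])
  if (any(ogt < -5 | ogt > 130))
    stop("OGT outside [-5, 130] degC for taxon: ",
         df$taxon[which(ogt < -5 | ogt > 130)[1L]])
  df$ogt_celsius <- ogt
  df$copy_id <- if ("copy_id" %in% names(df))
    trimws(as.character(df$copy_id)) else "1"
  df$copy_id[!nzchar(df$copy_id) | is.na(df$copy_id)] <- "1"
  df$psychrophile <- if ("psychrophile" %in% names(df))
    .asLogical(df$psychrophile) else FALSE
  key <- paste(df$taxon, df$copy_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (taxon, copy_id): ",
         sub("\r", "/", key[duplicated(key)][1L]))
  df[, c("taxon", "ogt_celsius", "copy_id", "psychrophile")]
}

.asLogical <- function(x) {
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  x <- tolower(trimws(as.character(x)))
  out <- x %in% c("true", "t", "1", "yes")
  bad <- !(x %in% c("true", "t", "1", "yes", "false", "f", "0", "no", "", "na"))
  if (any(bad)) stop("unparseable logical value: ", x[bad][1L])
  out
}

#' Write an OGT table
#'
#' @param df data.frame as returned by [readOgtTable()].
#' @param path output TSV.
#' @return Invisibly, \code{path}.
#' @export
writeOgtTable <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Stable node identifiers for a tree
#'
#' Leaves are identified by their labels; internal nodes by their Newick
#' label when present, otherwise "Node<k>" with k the ape node number.
#'
#' @param tree an \code{ape::phylo}.
#' @return character vector indexed by ape node number (1..Ntip+Nnode).
#' @export
treeNodeIds <- function(tree) {
  n <- ape::Ntip(tree); m <- tree$Nnode
  inner <- paste0("Node", (n + 1L):(n + m))
  if (!is.null(tree$node.label)) {
    lab <- trimws(tree$node.label)
    inner[nzchar(lab) & !is.na(lab)] <- lab[nzchar(lab) & !is.na(lab)]
  }
  c(tree$tip.label, inner)
}

#' Preorder node numbers of a rooted tree
#' @noRd
.preorderNodes <- function(tree) {
  tw <- ape::reorder.phylo(tree, "cladewise")
  c(ape::Ntip(tree) + 1L, tw$edge[, 2L])
}

#' Write per-node annotations as TSV and annotated Newick
#'
#' Emits (a) a TSV with one row per annotated node in preorder and (b),
#' optionally, a Newick file whose internal-node labels carry bracketed
#' \code{[&ogt=<value>]} comments.
#'
#' @param tree rooted \code{ape::phylo}.
#' @param table data.frame with a \code{node} column naming tree nodes (see
#'   [treeNodeIds()]) plus arbitrary annotation columns; an \code{ogt_map}
#'   column feeds the Newick comments.
#' @param tsvPath output TSV path.
#' @param newickPath optional output Newick path.
#' @param header optional comment lines (each written prefixed with "# ").
#' @return Invisibly, \code{tsvPath}.
#' @export
writeNodeAnnotations <- function(tree, table, tsvPath, newickPath = NULL,
                                 header = character()) {
  validatePhyloTree(tree, requireRooted = TRUE)
  ids <- treeNodeIds(tree)
  if (nrow(table) > 0) {
    unknown <- setdiff(table$node, ids)
    if (length(unknown))
      stop("annotation for unknown node id: ", unknown[1L])
    ord <- ids[.preorderNodes(tree)]
    table <- table[order(match(table$node, ord)), , drop = FALSE]
  }
  con <- file(tsvPath, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  utils::write.table(table, con, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(newickPath)) {
    ogt <- NULL
    if (nrow(table) > 0 && "ogt_map" %in% names(table))
      ogt <- stats::setNames(table$ogt_map, table$node)
    writeLines(.annotatedNewick(tree, ogt), newickPath)
  }
  invisible(tsvPath)
}

## Newick writer with [&ogt=...] comments on internal nodes; ape::write.tree
## cannot emit comments, so this small recursive writer handles output only.
.annotatedNewick <- function(tree, ogt = NULL) {
  ids <- treeNodeIds(tree)
  n <- ape::Ntip(tree)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  fmt <- function(x) sprintf("%.10g", x)
  build <- function(node, len) {
    tail <- if (is.na(len)) "" else paste0(":", fmt(len))
    if (node <= n) return(paste0(ids[node], tail))
    es <- kids[[as.character(node)]]
    inner <- vapply(es, function(e)
      build(tree$edge[e, 2L], tree$edge.length[e]), character(1L))
    com <- if (!is.null(ogt) && ids[node] %in% names(ogt)) {
      v <- ogt[[ids[node]]]
      sprintf("[&ogt=%s]", if (is.numeric(v)) sprintf("%.4f", v) else v)
    } else ""
    lab <- if (!is.null(tree$node.label)) {
      l <- tree$node.label[node - n]; if (is.na(l)) "" else l
    } else ""
    paste0("(", paste(inner, collapse = ","), ")", lab, com, tail)
  }
  paste0(build(n + 1L, NA_real_), ";")
}
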