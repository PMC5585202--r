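#' Read an anatomical network from an adjacency matrix CSV
#'
#' The expected dialect is the one used for musculoskeletal networks coded by
#' hand: a square, comma-delimited matrix whose first row and first column
#' carry identical node labels, with cell `(i, j) = 1` when structures `i` and
#' `j` are in physical contact and `0` otherwise. The diagonal must be all 0
#' (a structure is never coded in contact with itself) and the matrix must be
#' symmetric.
#'
#' Tissue classes can be supplied three ways: a `"bone:"` / `"muscle:"` prefix
#' on the labels themselves, the `tissue_map` argument, or neither (tissue is
#' then `"unknown"`). Labels are matched permissively: surrounding whitespace
#' is trimmed, and `tissue_map` matching is case-insensitive.
#'
#' @param path path to the CSV file.
#' @param tissue_map optional named character vector (`id -> tissue`), a
#'   two-column data frame `(id, tissue)`, or the path of a two-column CSV.
#' @param name taxon label; defaults to the file name without extension.
#' @return an [anatomical_network()].
#' @seealso [write_adjacency_csv()], [read_edge_list()]
#' @export
read_adjacency_csv <- function(path, tissue_map = NULL, name = NULL) {
  raw <- utils::read.csv(path, header = TRUE, row.names = NULL,
                         check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("adjacency CSV must have a label column plus data")
  labels <- trimws(as.character(raw[[1]]))
  header <- trimws(colnames(raw)[-1])
  M <- as.matrix(raw[, -1, drop = FALSE])
  if (nrow(M) != ncol(M))
    stop(sprintf("non-square matrix: %d rows x %d columns", nrow(M), ncol(M)))
  if (!identical(labels, header)) {
    bad <- which(labels != header)[1]
    stop(sprintf("row/column labels disagree at position %d: '%s' vs '%s'",
                 bad, labels[bad], header[bad]))
  }
  dup <- unique(labels[duplicated(labels)])
  if (length(dup))
    stop("duplicate label(s): ", paste(dup, collapse = ", "))

  suppressWarnings(num <- matrix(as.numeric(M), nrow(M)))
  nonbin <- which(is.na(num) | !(num %in% c(0, 1)), arr.ind = TRUE)
  if (nrow(nonbin)) {
    i <- nonbin[1, 1]; j <- nonbin[1, 2]
    stop(sprintf("non-binary cell at (%s, %s): '%s'",
                 labels[i], labels[j], M[i, j]))
  }
  asym <- which(num != t(num), arr.ind = TRUE)
  if (nrow(asym)) {
    i <- asym[1, 1]; j <- asym[1, 2]
    stop(sprintf("asymmetric matrix: cell (%s, %s) = %s but (%s, %s) = %s",
                 labels[i], labels[j], num[i, j],
                 labels[j], labels[i], num[j, i]))
  }
  diag_bad <- which(diag(num) != 0)
  if (length(diag_bad))
    stop(sprintf("nonzero diagonal at (%s, %s): self-contact is not coded",
                 labels[diag_bad[1]], labels[diag_bad[1]]))

  ids <- labels
  tissue <- rep("unknown", length(ids))
  pref <- regmatches(ids, regexpr("^(bone|muscle):", ids))
  has_pref <- lengths(regmatches(ids, gregexpr("^(bone|muscle):", ids))) > 0
  if (any(has_pref)) {
    tissue[has_pref] <- sub(":$", "", pref)
    ids[has_pref] <- trimws(sub("^(bone|muscle):", "", ids[has_pref]))
  }
  if (!is.null(tissue_map))
    tissue <- resolve_tissue_map(ids, tissue_map, tissue)

  idx <- which(upper.tri(num) & num == 1, arr.ind = TRUE)
  edges <- if (nrow(idx)) cbind(ids[idx[, 1]], ids[idx[, 2]]) else NULL
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  anatomical_network(ids, edges, tissue = tissue, name = name)
}

resolve_tissue_map <- function(ids, tissue_map, tissue) {
  if (is.character(tissue_map) && length(tissue_map) == 1 &&
      file.exists(tissue_map))
    tissue_map <- utils::read.csv(tissue_map, header = TRUE,
                                  stringsAsFactors = FALSE)
  if (is.data.frame(tissue_map)) {
    tm <- as.character(tissue_map[[2]])
    names(tm) <- as.character(tissue_map[[1]])
    tissue_map <- tm
  }
  hit <- match(tolower(trimws(ids)), tolower(trimws(names(tissue_map))))
  tissue[!is.na(hit)] <- unname(tissue_map[hit[!is.na(hit)]])
  tissue
}

#' Write an anatomical network as an adjacency matrix CSV
#'
#' Writes the dialect read by [read_adjacency_csv()], preserving node order,
#' so `read_adjacency_csv(write_adjacency_csv(net))` reproduces `net`. Output
#' is deterministic (byte-stable across repeated writes).
#'
#' @param net an [anatomical_network()].
#' @param path output file path.
#' @param tissue_prefix if `TRUE` (default), known tissue classes are encoded
#'   as `"bone:"` / `"muscle:"` label prefixes so they round-trip.
#' @return `path`, invisibly.
#' @export
write_adjacency_csv <- function(net, path, tissue_prefix = TRUE) {
  stopifnot(inherits(net, "anatomical_network"))
  A <- adjacency_matrix(net)
  lab <- net$nodes$id
  if (tissue_prefix) {
    known <- net$nodes$tissue != "unknown"
    lab[known] <- paste0(net$nodes$tissue[known], ":", lab[known])
  }
  dimnames(A) <- list(lab, lab)
  out <- data.frame(id = lab, A, check.names = FALSE,
                    stringsAsFactors = FALSE)
  colnames(out)[1] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read an anatomical network from a two-column edge list
#'
#' @param path delimited text file with two (optionally more; extra columns
#'   are ignored) columns of node ids. Lines starting with `#` are skipped.
#' @param sep field separator; default tab, with comma auto-detected.
#' @param tissue_map as in [read_adjacency_csv()].
#' @param name taxon label; defaults to the file name.
#' @return an [anatomical_network()]. Duplicate and reversed pairs collapse to
#'   one undirected link; node order follows first appearance.
#' @export
read_edge_list <- function(path, sep = NULL, tissue_map = NULL, name = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  if (!length(lines)) stop("empty edge list: ", path)
  if (is.null(sep))
    sep <- if (grepl(",", lines[1])) "," else "\t"
  parts <- strsplit(lines, sep, fixed = TRUE)
  if (any(lengths(parts) < 2))
    stop("edge list rows must have at least two columns")
  a <- trimws(vapply(parts, `[[`, "", 1))
  b <- trimws(vapply(parts, `[[`, "", 2))
  blank <- !nzchar(a) | !nzchar(b)
  if (any(blank))
    stop("blank node id on row ", which(blank)[1])
  loops <- a == b
  if (any(loops))
    stop("self-loop row: (", a[which(loops)[1]], ", ", b[which(loops)[1]], ")")
  ids <- unique(c(rbind(a, b)))
  tissue <- rep("unknown", length(ids))
  if (!is.null(tissue_map))
    tissue <- resolve_tissue_map(ids, tissue_map, tissue)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  anatomical_network(ids, cbind(a, b), tissue = tissue, name = name)
}

#' Write an anatomical network as a two-column TSV edge list
#'
#' @param net an [anatomical_network()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "anatomical_network"))
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export a network to GraphML for external visualization tools
#'
#' @param net an [anatomical_network()].
#' @param path output file path (`.graphml`).
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}
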