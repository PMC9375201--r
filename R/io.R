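# Readers and writers for the plain-text formats the package touches:
# Matrix Market bundles in the 10x convention (genes as rows), TSV
# sidecars, CSV tables and JSON provenance sidecars.

readTsvColumn <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE, quote = "",
                         comment.char = "")
  as.character(x[[1]])
}

#' Read an expression matrix
#'
#' Accepts a 10x-style Matrix Market bundle (a directory containing
#' \code{matrix.mtx}, \code{features.tsv}, \code{barcodes.tsv}, or an
#' explicit \code{.mtx} path with sidecars next to it) or a dense
#' CSV/TSV with gene rows, a header of cell ids and gene ids in the first
#' column. Genes are rows, cells are columns. Duplicate gene ids are
#' disambiguated with \code{make.unique} (with a message).
#'
#' @param path directory, \code{.mtx} file, or \code{.csv}/\code{.tsv}
#'   file.
#' @return genes x cells \code{dgCMatrix} with dimnames.
#' @export
readExpressionMatrix <- function(path) {
  if (dir.exists(path)) {
    mtx <- file.path(path, "matrix.mtx")
    feat <- file.path(path, "features.tsv")
    bc <- file.path(path, "barcodes.tsv")
  } else if (grepl("\\.mtx$", path)) {
    mtx <- path
    feat <- file.path(dirname(path), "features.tsv")
    bc <- file.path(dirname(path), "barcodes.tsv")
  } else {
    sep <- if (grepl("\\.csv$", path)) "," else "\t"
    df <- utils::read.table(path, sep = sep, header = TRUE,
                            row.names = 1, check.names = FALSE)
    m <- methods::as(as.matrix(df), "CsparseMatrix")
    if (anyDuplicated(rownames(m))) {
      message("duplicate gene ids disambiguated with make.unique")
      rownames(m) <- make.unique(rownames(m))
    }
    return(m)
  }
  for (f in c(mtx, feat, bc))
    if (!file.exists(f)) stop("missing file: ", f)
  m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  genes <- readTsvColumn(feat)
  cells <- readTsvColumn(bc)
  if (length(genes) != nrow(m))
    stop("features.tsv has ", length(genes), " entries but the matrix ",
         "has ", nrow(m), " rows")
  if (length(cells) != ncol(m))
    stop("barcodes.tsv has ", length(cells), " entries but the matrix ",
         "has ", ncol(m), " columns")
  if (anyDuplicated(genes)) {
    message("duplicate gene ids disambiguated with make.unique")
    genes <- make.unique(genes)
  }
  dimnames(m) <- list(genes, cells)
  m
}

#' Write an expression matrix as a 10x-style Matrix Market bundle
#'
#' @param x genes x cells matrix with dimnames.
#' @param dir output directory (created if needed); writes
#'   \code{matrix.mtx}, \code{features.tsv}, \code{barcodes.tsv}.
#' @return the directory path, invisibly.
#' @export
writeExpressionMatrix <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(methods::as(x, "CsparseMatrix"),
                              "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(x), file.path(dir, "features.tsv"))
  writeLines(colnames(x), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Write a metacell partition as TSV with a JSON provenance sidecar
#'
#' The TSV has columns \code{cell_id} and \code{metacell_id}; metacell ids
#' are written 0-based (the on-disk convention). The sidecar
#' \code{<path>.json} records n_cells, n_metacells, gamma, algorithm and
#' all stored parameters.
#'
#' @param partition a \code{\linkS4class{MetacellPartition}}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writePartition <- function(partition, path) {
  memb <- membership(partition)
  ids <- if (length(partition@cellIds)) partition@cellIds
         else sprintf("cell%05d", seq_along(memb))
  utils::write.table(
    data.frame(cell_id = ids, metacell_id = memb - 1L),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- c(list(n_cells = length(memb),
                 n_metacells = nMetacells(partition),
                 gamma = gammaLevel(partition),
                 algorithm = partition@algorithm),
            partition@parameters)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a metacell partition written by \code{\link{writePartition}}
#'
#' @param path the TSV path (the \code{.json} sidecar is read when
#'   present).
#' @return a \code{\linkS4class{MetacellPartition}}.
#' @export
readPartition <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  algo <- "manual"; params <- list()
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    js <- jsonlite::read_json(side, simplifyVector = TRUE)
    algo <- js$algorithm %||% "manual"
    params <- js[setdiff(names(js),
                         c("n_cells", "n_metacells", "gamma", "algorithm"))]
  }
  MetacellPartition(df$metacell_id + 1L, cellIds = df$cell_id,
                    algorithm = algo, parameters = params)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a metacell network as a weighted edge-list TSV
#'
#' Columns \code{from}, \code{to} (0-based metacell ids) and
#' \code{weight}.
#'
#' @param graph weighted \pkg{igraph} graph from
#'   \code{\link{metacellNetwork}}.
#' @param path output TSV path.
#' @export
writeMetacellGraph <- function(graph, path) {
  el <- igraph::as_edgelist(graph, names = FALSE)
  w <- igraph::E(graph)$weight
  utils::write.table(
    data.frame(from = el[, 1] - 1L, to = el[, 2] - 1L,
               weight = if (is.null(w)) rep(1L, nrow(el)) else w),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a metacell profile
#'
#' Either a directory (Matrix Market \code{matrix.mtx} of the mean assay
#' with \code{features.tsv}, \code{metacell_ids.tsv} and
#' \code{sizes.tsv}; extra assays as \code{<name>.mtx}) or a single CSV
#' (genes x metacells, sizes in the first row as \code{#size}).
#'
#' @param profile a \code{\linkS4class{MetacellProfile}}.
#' @param path output directory, or a path ending in \code{.csv}.
#' @export
writeProfile <- function(profile, path) {
  mean <- SummarizedExperiment::assay(profile, "mean")
  if (grepl("\\.csv$", path)) {
    m <- as.matrix(mean)
    out <- rbind(`#size` = mcSizes(profile), m)
    utils::write.csv(as.data.frame(out), path, quote = FALSE)
    return(invisible(path))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  nm <- names(SummarizedExperiment::assays(profile))
  for (a in nm) {
    f <- file.path(path, if (a == "mean") "matrix.mtx"
                         else paste0(a, ".mtx"))
    Matrix::writeMM(methods::as(methods::as(
      SummarizedExperiment::assay(profile, a), "CsparseMatrix"),
      "generalMatrix"), f)
  }
  writeLines(rownames(profile), file.path(path, "features.tsv"))
  writeLines(colnames(profile), file.path(path, "metacell_ids.tsv"))
  writeLines(as.character(mcSizes(profile)),
             file.path(path, "sizes.tsv"))
  invisible(path)
}

#' Read a metacell profile written by \code{\link{writeProfile}}
#'
#' @param path the directory or CSV path.
#' @return a \code{\linkS4class{MetacellProfile}}.
#' @export
readProfile <- function(path) {
  if (grepl("\\.csv$", path)) {
    df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
    sizes <- as.numeric(df["#size", ])
    m <- as.matrix(df[setdiff(rownames(df), "#size"), , drop = FALSE])
    return(MetacellProfile(m, sizes = sizes))
  }
  m <- methods::as(Matrix::readMM(file.path(path, "matrix.mtx")),
                   "CsparseMatrix")
  dimnames(m) <- list(readTsvColumn(file.path(path, "features.tsv")),
                      readTsvColumn(file.path(path, "metacell_ids.tsv")))
  sizes <- as.numeric(readTsvColumn(file.path(path, "sizes.tsv")))
  extra <- setdiff(list.files(path, pattern = "\\.mtx$"), "matrix.mtx")
  layers <- lapply(stats::setNames(extra, sub("\\.mtx$", "", extra)),
    function(f) {
      l <- methods::as(Matrix::readMM(file.path(path, f)),
                       "CsparseMatrix")
      dimnames(l) <- dimnames(m)
      l
    })
  MetacellProfile(m, sizes = sizes, layers = layers)
}

#' Read per-cell labels from a two-column TSV (cell_id, label)
#'
#' @param path TSV path (header optional, auto-detected).
#' @return named character vector of labels.
#' @export
readLabels <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (identical(tolower(df[1, 1]), "cell_id")) df <- df[-1, , drop = FALSE]
  stats::setNames(as.character(df[[2]]), df[[1]])
}

#' Write per-cell labels as TSV
#' @param labels vector of labels, named by cell id (or unnamed).
#' @param path output path.
#' @param cellIds cell ids to use when \code{labels} is unnamed.
#' @export
writeLabels <- function(labels, path, cellIds = names(labels)) {
  if (is.null(cellIds)) cellIds <- sprintf("cell%05d", seq_along(labels))
  utils::write.table(data.frame(cell_id = cellIds,
                                label = as.character(labels)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a gene-to-GO annotation from a two-column TSV (gene_id, go_id)
#'
#' @param path TSV path; one row per (gene, term) pair.
#' @return named list: gene id -> character vector of GO ids.
#' @export
readGO <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  split(as.character(df[[2]]), df[[1]])
}

#' Write a gene-to-GO annotation as a two-column TSV
#' @param go named list mapping gene id to GO ids.
#' @param path output path.
#' @export
writeGO <- function(go, path) {
  df <- data.frame(gene_id = rep(names(go), lengths(go)),
                   go_id = unlist(go, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a per-cell velocity field from TSV (cell_id, v1, v2, ...)
#' @param path TSV path with a header.
#' @return cells x d numeric matrix with cell ids as row names.
#' @export
readVelocity <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a per-cell velocity field (or any embedding) as TSV
#' @param v rows x d numeric matrix.
#' @param path output path.
#' @param ids row identifiers (default: row names).
#' @export
writeVelocity <- function(v, path, ids = rownames(v)) {
  if (is.null(ids)) ids <- sprintf("cell%05d", seq_len(nrow(v)))
  df <- data.frame(cell_id = ids, as.data.frame(as.matrix(v)))
  colnames(df) <- c("cell_id", paste0("v", seq_len(ncol(v))))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a cell embedding as TSV (cell_id + one column per component)
#' @param embedding a \code{\linkS4class{CellEmbedding}} or matrix.
#' @param path output path.
#' @export
writeEmbedding <- function(embedding, path) {
  m <- if (is(embedding, "CellEmbedding")) embedding@coords
       else as.matrix(embedding)
  ids <- rownames(m)
  if (is.null(ids)) ids <- sprintf("cell%05d", seq_len(nrow(m)))
  df <- data.frame(cell_id = ids, as.data.frame(m))
  colnames(df) <- c("cell_id", paste0("PC", seq_len(ncol(m))))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
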