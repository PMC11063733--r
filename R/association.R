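#' Construct a binary miRNA-disease association matrix
#'
#' The association matrix `MD` is the central input of the pipeline: a binary
#' `nm x nd` matrix with miRNAs on the rows and diseases on the columns,
#' `MD[i, j] = 1` when the association between miRNA `i` and disease `j` is
#' experimentally supported and `0` otherwise. Labels are sorted so that the
#' same input always yields the same matrix, whatever the row order of the
#' source file.
#'
#' @param x Either a numeric matrix with miRNA row names and disease column
#'   names, or a data frame edge list whose first two columns are miRNA and
#'   disease names and whose optional third column holds binary values
#'   (absent pairs default to 0).
#' @param mirna_names,disease_names Optional label vectors overriding the
#'   dimnames when `x` is a matrix.
#'
#' @return An `assoc_matrix`: a binary base matrix with sorted, unique
#'   dimnames and class `c("assoc_matrix", "matrix", "array")`.
#' @export
#' @examples
#' edges <- tibble::tibble(mirna = c("m1", "m2"), disease = c("d1", "d2"))
#' association_matrix(edges)
association_matrix <- function(x, mirna_names = NULL, disease_names = NULL) {
  if (is.data.frame(x)) {
    return(assoc_from_edges(x))
  }
  x <- as.matrix(x)
  if (!is.null(mirna_names)) rownames(x) <- mirna_names
  if (!is.null(disease_names)) colnames(x) <- disease_names
  if (is.null(rownames(x))) rownames(x) <- sprintf("m%d", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- sprintf("d%d", seq_len(ncol(x)))
  new_assoc_matrix(x)
}

new_assoc_matrix <- function(x) {
  storage.mode(x) <- "double"
  if (nrow(x) < 1 || ncol(x) < 1) {
    rlang::abort("association matrix must have at least one miRNA and one disease")
  }
  if (anyNA(x) || !all(x %in% c(0, 1))) {
    rlang::abort("association matrix entries must all be 0 or 1")
  }
  if (anyDuplicated(rownames(x)) || anyDuplicated(colnames(x))) {
    rlang::abort("miRNA and disease names must be unique")
  }
  x <- x[order(rownames(x)), order(colnames(x)), drop = FALSE]
  structure(x, class = c("assoc_matrix", "matrix", "array"))
}

assoc_from_edges <- function(df) {
  if (nrow(df) == 0) rlang::abort("edge list is empty")
  if (ncol(df) < 2) rlang::abort("edge list needs (miRNA, disease[, value]) columns")
  mir <- as.character(df[[1]])
  dis <- as.character(df[[2]])
  val <- if (ncol(df) >= 3) as.numeric(df[[3]]) else rep(1, nrow(df))
  if (anyNA(val) || !all(val %in% c(0, 1))) {
    bad <- unique(val[!val %in% c(0, 1)])
    rlang::abort(paste0(
      "association values must be 0 or 1; found: ",
      paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  mn <- sort(unique(mir))
  dn <- sort(unique(dis))
  m <- matrix(0, length(mn), length(dn), dimnames = list(mn, dn))
  keep <- !duplicated(data.frame(mir, dis, val))
  m[cbind(mir[keep], dis[keep])] <- val[keep]
  new_assoc_matrix(m)
}

#' Read a miRNA-disease association table from delimited text
#'
#' Two on-disk layouts are supported: an *edge list* with columns
#' `(miRNA, disease[, value])`, and a *dense* matrix whose header row holds
#' disease names and whose first column holds miRNA names. Tabs and commas
#' are both accepted as delimiters.
#'
#' @param path Path to a delimited text file.
#' @param format `"auto"` (default; files with at most three columns are read
#'   as edge lists), `"edge_list"`, or `"dense"`.
#' @return An [association_matrix()].
#' @export
read_association_table <- function(path, format = c("auto", "edge_list", "dense")) {
  format <- rlang::arg_match(format)
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  if (file.size(path) == 0) rlang::abort(paste0("empty association file: ", path))
  df <- read_delim_auto(path)
  if (nrow(df) == 0) rlang::abort(paste0("empty association file: ", path))
  if (format == "auto") {
    format <- if (ncol(df) <= 3) "edge_list" else "dense"
  }
  if (format == "edge_list") {
    assoc_from_edges(df)
  } else {
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
    new_assoc_matrix(m)
  }
}

read_delim_auto <- function(path) {
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  readr::read_delim(
    path,
    delim = delim, show_col_types = FALSE, progress = FALSE,
    trim_ws = TRUE
  )
}

#' Write an association matrix to delimited text
#'
#' The edge-list writer emits one `(miRNA, disease, value)` row per known
#' association plus a zero-valued padding row for every miRNA or disease with
#' no links, so that the read/write round trip preserves the full label
#' universes. The dense writer emits the whole matrix.
#'
#' @param assoc An [association_matrix()].
#' @param path Output path; `.csv` extensions get commas, everything else tabs.
#' @param format `"edge_list"` (default) or `"dense"`.
#' @return `path`, invisibly.
#' @export
write_association_table <- function(assoc, path, format = c("edge_list", "dense")) {
  format <- rlang::arg_match(format)
  delim <- if (grepl("\\.csv$", path)) "," else "\t"
  m <- unclass(assoc)
  if (format == "dense") {
    df <- tibble::as_tibble(m, rownames = "mirna")
    readr::write_delim(df, path, delim = delim)
    return(invisible(path))
  }
  edges <- tidy.assoc_matrix(assoc)
  pos <- edges[edges$known == 1, ]
  pad_m <- setdiff(rownames(m), pos$mirna)
  pad_d <- setdiff(colnames(m), pos$disease)
  pad <- tibble::tibble(
    mirna = c(pad_m, rep(rownames(m)[1], length(pad_d))),
    disease = c(rep(colnames(m)[1], length(pad_m)), pad_d),
    known = 0
  )
  out <- rbind(
    tibble::tibble(mirna = pos$mirna, disease = pos$disease, known = pos$known),
    pad
  )
  names(out) <- c("mirna", "disease", "value")
  readr::write_delim(out[order(out$mirna, out$disease), ], path, delim = delim)
  invisible(path)
}

#' @export
print.assoc_matrix <- function(x, ...) {
  cat(sprintf(
    "<assoc_matrix> %d miRNAs x %d diseases, %d known associations (density %.3f)\n",
    nrow(x), ncol(x), sum(x), mean(x)
  ))
  invisible(x)
}

#' Tidy an association matrix into a long tibble
#'
#' @param x An [association_matrix()].
#' @param ... Unused.
#' @return A tibble with columns `mirna`, `disease`, `known`.
#' @export
tidy.assoc_matrix <- function(x, ...) {
  m <- unclass(x)
  tibble::tibble(
    mirna = rep(rownames(m), times = ncol(m)),
    disease = rep(colnames(m), each = nrow(m)),
    known = as.vector(m)
  )
}

#' Rank prediction scores into a candidate table
#'
#' Flattens a score matrix into the ranked candidate list users actually act
#' on: one row per miRNA-disease pair, sorted by descending score, ties broken
#' lexically by miRNA then disease name so output is reproducible.
#'
#' @param scores A numeric `nm x nd` matrix (e.g. `md_star` from
#'   [run_scplpa()]), or a `scplpa_result`.
#' @param known Optional binary matrix of the same shape flagging already
#'   known pairs; defaults to all-zero.
#' @param path Optional output path; when given, the table is also written as
#'   delimited text.
#' @return A tibble with columns `rank`, `mirna`, `disease`, `score`,
#'   `known`.
#' @export
write_predictions <- function(scores, known = NULL, path = NULL) {
  if (inherits(scores, "scplpa_result")) scores <- scores$md_star
  scores <- as.matrix(scores)
  if (!all(is.finite(scores))) rlang::abort("scores must all be finite")
  if (is.null(known)) known <- matrix(0, nrow(scores), ncol(scores))
  known <- as.matrix(known)
  if (!identical(dim(known), dim(scores))) {
    rlang::abort("known mask shape does not match the score matrix")
  }
  out <- tibble::tibble(
    mirna = rep(rownames(scores), times = ncol(scores)),
    disease = rep(colnames(scores), each = nrow(scores)),
    score = as.vector(scores),
    known = as.integer(as.vector(known) != 0)
  )
  out <- out[order(-out$score, out$mirna, out$disease), ]
  out <- tibble::add_column(out, rank = seq_len(nrow(out)), .before = 1)
  if (!is.null(path)) {
    delim <- if (grepl("\\.csv$", path)) "," else "\t"
    readr::write_delim(out, path, delim = delim)
  }
  out
}
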