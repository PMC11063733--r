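#' Disease DAG sets
#'
#' Each disease in a MeSH-style hierarchy is described by the directed acyclic
#' graph of its ancestor terms: `N(d)` is the set of ancestors of `d`
#' *including `d` itself*, reached by following child-to-parent edges. The
#' collection of these per-disease DAGs, plus the size of the disease universe
#' used as the information-content denominator, is what the semantic
#' similarity stage consumes.
#'
#' @param edges A data frame whose first two columns are `(child, parent)`
#'   term names.
#' @param diseases Character vector of the diseases of interest. Defaults to
#'   every node appearing in `edges`; terms not listed here still contribute
#'   as ancestors but get no DAG of their own.
#' @param universe_size Denominator of the ancestor information content;
#'   defaults to `length(diseases)`.
#'
#' @return A `disease_dag_set`: list with elements `ancestors` (named list of
#'   character vectors, self included), `edges` (tibble), `diseases`, and
#'   `universe_size`.
#' @export
#' @examples
#' dags <- disease_dag_set(
#'   tibble::tibble(child = c("A", "B"), parent = c("R", "R"))
#' )
#' dags$ancestors$A
disease_dag_set <- function(edges, diseases = NULL, universe_size = NULL) {
  edges <- tibble::tibble(
    child = as.character(edges[[1]]),
    parent = as.character(edges[[2]])
  )
  edges <- edges[!duplicated(edges), ]
  nodes <- unique(c(edges$child, edges$parent, diseases))
  if (length(nodes) == 0) rlang::abort("DAG set has no nodes")
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = data.frame(name = nodes))
  if (!igraph::is_dag(g)) {
    self <- edges$child[edges$child == edges$parent]
    if (length(self) > 0) {
      cyc <- self[1]
    } else {
      comp <- igraph::components(g, mode = "strong")
      cyc <- names(comp$membership)[comp$membership == which(comp$csize > 1)[1]]
    }
    rlang::abort(paste0(
      "disease hierarchy contains a cycle: ",
      paste(sort(cyc), collapse = " -> ")
    ))
  }
  if (is.null(diseases)) diseases <- sort(nodes)
  if (!all(diseases %in% nodes)) {
    # diseases absent from the edge file are singleton DAGs
    nodes <- unique(c(nodes, diseases))
    g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                       vertices = data.frame(name = nodes))
  }
  anc <- lapply(diseases, function(d) {
    sort(names(igraph::subcomponent(g, d, mode = "out")))
  })
  names(anc) <- diseases
  if (is.null(universe_size)) universe_size <- length(diseases)
  if (universe_size < 1) rlang::abort("universe_size must be at least 1")
  structure(
    list(
      ancestors = anc,
      edges = edges,
      diseases = diseases,
      universe_size = as.integer(universe_size)
    ),
    class = "disease_dag_set"
  )
}

#' Read disease DAG edges from a delimited file
#'
#' @param path Path to a two-column `(child, parent)` delimited text file.
#' @inheritParams disease_dag_set
#' @return A [disease_dag_set()].
#' @export
read_dag_edges <- function(path, diseases = NULL, universe_size = NULL) {
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  df <- read_delim_auto(path)
  if (nrow(df) == 0) rlang::abort(paste0("empty DAG edge file: ", path))
  disease_dag_set(df, diseases = diseases, universe_size = universe_size)
}

#' Write disease DAG edges to a tab-delimited file
#'
#' @param dags A [disease_dag_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dag_edges <- function(dags, path) {
  readr::write_delim(dags$edges, path, delim = "\t")
  invisible(path)
}

#' @export
print.disease_dag_set <- function(x, ...) {
  cat(sprintf(
    "<disease_dag_set> %d diseases, %d edges, universe size %d\n",
    length(x$diseases), nrow(x$edges), x$universe_size
  ))
  invisible(x)
}
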