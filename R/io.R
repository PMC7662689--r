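#' Convert a context network to an igraph object
#'
#' Nodes carry a `type` attribute in `{lncRNA, miRNA, mRNA}`.
#' @param net An `lcenet_context`.
#' @return An undirected `igraph` graph.
#' @export
as_igraph <- function(net) {
  edges <- net$edges
  vertices <- net$nodes %>% select(name = "id", type = "class")
  igraph::graph_from_data_frame(
    d = tibble(from = edges$mirna_id, to = edges$target_id),
    directed = FALSE, vertices = vertices
  )
}

#' Export a context network in SIF format
#'
#' One line per miRNA-target edge: `miRNA regulates target`.
#' @param net An `lcenet_context`.
#' @param path Output path.
#' @export
export_sif <- function(net, path) {
  lines <- sprintf("%s\tregulates\t%s", net$edges$mirna_id,
                   net$edges$target_id)
  writeLines(lines, path)
  invisible(path)
}

#' Export a context network in GraphML format
#'
#' @param net An `lcenet_context`.
#' @param path Output path.
#' @export
export_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}

#' Read and write GMT gene-set files
#'
#' GMT is the standard tab-delimited gene-set format: set name, description,
#' then member genes.
#' @param path File path.
#' @return `read_gmt`: named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[`, "", 1)
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
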