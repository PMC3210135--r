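#' @keywords internal
#' @import methods
#' @importFrom stats setNames aggregate
#' @importFrom utils read.delim write.table
#' @importFrom jsonlite write_json
#' @importFrom igraph make_empty_graph set_vertex_attr add_edges components
#' @importFrom Biostrings readAAStringSet width
"_PACKAGE"

# Canonical residue identity: the full (chain, seq, icode, res_name) 4-tuple.
# Residues differing only in insertion code are distinct.
residueKey <- function(chain, seqNum, insCode, resName) {
  paste(chain, seqNum, insCode, resName, sep = "|")
}

atomResidueKeys <- function(atoms) {
  residueKey(atoms$chain, atoms$seqNum, atoms$insCode, atoms$resName)
}

# Split key strings back into a residue table (inverse of residueKey()).
residueTableFromKeys <- function(keys) {
  if (length(keys) == 0L) {
    return(data.frame(chain = character(), seqNum = integer(),
                      insCode = character(), resName = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(keys, "|", fixed = TRUE)
  data.frame(
    chain = vapply(parts, `[`, "", 1L),
    seqNum = as.integer(vapply(parts, `[`, "", 2L)),
    insCode = vapply(parts, function(p) if (length(p) >= 3L) p[3L] else "", ""),
    resName = vapply(parts, function(p) if (length(p) >= 4L) p[4L] else "", ""),
    stringsAsFactors = FALSE
  )
}

# Connected components of an undirected graph given as an edge list over
# `nodes`; wraps igraph so every merge/cluster step in the package shares one
# implementation. Returns an integer component label per node, components
# numbered by their smallest node (by sort order) for determinism.
edgeListComponents <- function(nodes, edges_a, edges_b) {
  stopifnot(length(edges_a) == length(edges_b))
  nodes <- as.character(nodes)
  if (length(nodes) == 0L) return(integer(0))
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes)
  if (length(edges_a) > 0L) {
    g <- igraph::add_edges(g, rbind(match(as.character(edges_a), nodes),
                                    match(as.character(edges_b), nodes)))
  }
  memb <- igraph::components(g)$membership
  # renumber components in order of their lexicographically smallest node
  as.integer(match(memb, unique(memb[order(nodes)])))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

irWarn <- function(...) warning(..., call. = FALSE)
irStop <- function(...) stop(..., call. = FALSE)
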