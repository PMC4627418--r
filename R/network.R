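#' Weighted undirected gene interaction networks
#'
#' A `gene_network` is a simple undirected graph over gene identifiers with a
#' positive confidence weight on every edge — the connectivity matrix of the
#' neighbor-scoring model. Edges are stored canonically (endpoints sorted,
#' one row per unordered pair); isolated nodes are allowed.
#'
#' @param edges A data frame with columns `from`, `to`, `weight`. Parallel
#'   listings of the same unordered pair are collapsed by keeping the
#'   maximum weight.
#' @param nodes Optional character vector of node identifiers; defaults to
#'   the genes appearing in `edges`. Extra entries become isolated nodes.
#' @return An object of class `gene_network` with components `nodes`
#'   (character) and `edges` (data frame `from`, `to`, `weight`).
#' @examples
#' net <- gene_network(data.frame(from = c("A", "A", "B"),
#'                                to   = c("B", "C", "C"),
#'                                weight = c(0.5, 1, 0.2)))
#' network_degree(net)
#' @export
gene_network <- function(edges = data.frame(from = character(),
                                            to = character(),
                                            weight = numeric()),
                         nodes = NULL) {
  if (!is.data.frame(edges) || !all(c("from", "to") %in% names(edges))) {
    stop_validation("edges must be a data frame with columns from, to[, weight]")
  }
  from <- as.character(edges$from)
  to <- as.character(edges$to)
  weight <- if ("weight" %in% names(edges)) as.numeric(edges$weight) else
    rep(1, nrow(edges))
  if (any(from == "" | to == "") || anyNA(from) || anyNA(to)) {
    stop_validation("gene identifiers must be non-empty strings")
  }
  if (anyNA(weight) || any(!is.finite(weight)) || any(weight <= 0)) {
    stop_validation("all edge weights must be strictly positive and finite")
  }
  if (any(from == to)) {
    stop_validation("self-loops are not allowed in a gene_network")
  }
  # canonical orientation + collapse duplicates by maximum weight
  swap <- from > to
  tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
  key <- paste0(from, "\r", to)
  if (anyDuplicated(key)) {
    weight <- as.numeric(tapply(weight, key, max)[unique(key)])
    keep <- !duplicated(key)
    from <- from[keep]; to <- to[keep]
  }
  ord <- order(from, to)
  edges <- data.frame(from = from[ord], to = to[ord], weight = weight[ord],
                      stringsAsFactors = FALSE)
  nodes <- sort(unique(c(as.character(nodes %||% character()), from, to)))
  if (any(nodes == "") || anyNA(nodes)) {
    stop_validation("gene identifiers must be non-empty strings")
  }
  structure(list(nodes = nodes, edges = edges), class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges)) {
    cat(sprintf("  weights in [%g, %g]\n",
                min(x$edges$weight), max(x$edges$weight)))
  }
  invisible(x)
}

#' Number of edges in a network
#' @param net A `gene_network`.
#' @return Integer edge count.
#' @export
edge_count <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  nrow(net$edges)
}

#' Read a weighted edge list
#'
#' Parses a STRING-style whitespace- or tab-separated edge list
#' (`geneA geneB weight`). Weights are divided by `weight_scale`, so the
#' default 1000 maps STRING's integer combined scores (0-1000) onto
#' confidences in (0, 1]. Duplicate listings of a pair keep the maximum
#' weight; self-loops are dropped with a warning.
#'
#' @param path Path to the edge-list file.
#' @param weight_scale Positive divisor applied to the third column.
#' @param allow_unweighted If `TRUE`, a two-column file is accepted and all
#'   weights are set to 1.
#' @param header If `TRUE`, skip one header line.
#' @return A [gene_network].
#' @export
read_edge_list <- function(path, weight_scale = 1000, allow_unweighted = FALSE,
                           header = FALSE) {
  assert_scalar_number(weight_scale, "weight_scale", lower = 0, strict_lower = TRUE)
  assert_flag(allow_unweighted, "allow_unweighted")
  if (!file.exists(path)) stop_io("edge-list file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  line_no <- seq_along(lines)
  if (header && length(lines)) {
    lines <- lines[-1L]; line_no <- line_no[-1L]
  }
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]; line_no <- line_no[keep]
  if (!length(lines)) stop_validation("edge-list file is empty: ", path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  bad <- which(nf < 2L | (nf < 3L & !allow_unweighted))
  if (length(bad)) {
    stop_io(sprintf("malformed edge-list line %d in %s: expected %s columns",
                    line_no[bad[1L]], path,
                    if (allow_unweighted) ">=2" else ">=3"))
  }
  from <- vapply(fields, `[[`, character(1L), 1L)
  to <- vapply(fields, `[[`, character(1L), 2L)
  raw_w <- vapply(fields, function(f) if (length(f) >= 3L) f[[3L]] else NA_character_,
                  character(1L))
  weight <- rep(1, length(fields))
  has_w <- !is.na(raw_w)
  if (any(has_w)) {
    w <- suppressWarnings(as.numeric(raw_w[has_w]))
    if (anyNA(w)) {
      stop_io(sprintf("malformed edge-list line %d in %s: non-numeric weight",
                      line_no[has_w][which(is.na(w))[1L]], path))
    }
    weight[has_w] <- w / weight_scale
  }
  if (any(weight <= 0)) {
    stop_validation(sprintf(
      "non-positive weight after scaling on line %d of %s",
      line_no[which(weight <= 0)[1L]], path))
  }
  if (any(weight > 1)) {
    warning(sum(weight > 1), " edge weight(s) exceed 1 after scaling by ",
            weight_scale, call. = FALSE)
  }
  loops <- from == to
  if (any(loops)) {
    warning("dropped ", sum(loops), " self-loop(s) while reading ", path,
            call. = FALSE)
  }
  nodes <- unique(c(from, to))
  gene_network(data.frame(from = from[!loops], to = to[!loops],
                          weight = weight[!loops], stringsAsFactors = FALSE),
               nodes = nodes)
}

#' Write a network as an edge-list TSV
#'
#' Writes `geneA<TAB>geneB<TAB>weight` rows in canonical order. Reading the
#' file back with `weight_scale = 1` recovers the network (isolated nodes
#' excepted).
#'
#' @param net A [gene_network].
#' @param path Output path.
#' @param header If `TRUE`, write a `from to weight` header line.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path, header = FALSE) {
  stopifnot(inherits(net, "gene_network"))
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = header)
  invisible(path)
}

#' Read a two-column identifier map
#'
#' @param path TSV with `source<TAB>target` rows, no header.
#' @return A named character vector (names = source, values = target).
#' @export
read_identifier_map <- function(path) {
  if (!file.exists(path)) stop_io("identifier map not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "")
  if (ncol(tab) < 2L) stop_io("identifier map needs two tab-separated columns")
  map <- stats::setNames(tab[[2L]], tab[[1L]])
  if (any(names(map) == "" | map == "")) {
    stop_validation("identifier map contains empty identifiers")
  }
  map
}

#' Rename network nodes through an identifier map
#'
#' Applies a many-to-one source-to-symbol map (e.g. STRING protein IDs to
#' gene symbols). Edges whose endpoints merge become self-loops and are
#' dropped; edges that become parallel are collapsed by maximum weight.
#'
#' @param net A [gene_network].
#' @param map Named character vector (source identifier -> target symbol),
#'   e.g. from [read_identifier_map()].
#' @param keep_unmapped If `TRUE`, nodes absent from the map keep their
#'   original identifier; if `FALSE` (default) they are dropped and a count
#'   is reported.
#' @return The renamed [gene_network].
#' @export
map_identifiers <- function(net, map, keep_unmapped = FALSE) {
  stopifnot(inherits(net, "gene_network"))
  assert_flag(keep_unmapped, "keep_unmapped")
  if (is.null(names(map)) || any(names(map) == "" | map == "")) {
    stop_validation("map must be a named character vector without empty entries")
  }
  mapped <- net$nodes %in% names(map)
  new_id <- ifelse(mapped, unname(map[net$nodes]), net$nodes)
  keep_node <- mapped | keep_unmapped
  if (!keep_unmapped && any(!mapped)) {
    message(sum(!mapped), " unmapped node(s) dropped")
  }
  lut <- stats::setNames(new_id, net$nodes)
  ok <- stats::setNames(keep_node, net$nodes)
  e <- net$edges
  keep_edge <- ok[e$from] & ok[e$to]
  e <- e[keep_edge, , drop = FALSE]
  e$from <- unname(lut[e$from])
  e$to <- unname(lut[e$to])
  loops <- e$from == e$to
  if (any(loops)) {
    warning("dropped ", sum(loops), " edge(s) that became self-loops after mapping",
            call. = FALSE)
    e <- e[!loops, , drop = FALSE]
  }
  nodes <- unique(new_id[keep_node])
  if (!length(nodes)) stop_validation("identifier mapping produced an empty network")
  gene_network(e, nodes = nodes)
}

#' Unweighted node degree
#'
#' Counts incident edges per node (isolated nodes score 0). Degree is the
#' classical essentiality covariate the neighbor score is contrasted with.
#'
#' @param net A [gene_network].
#' @return Named integer vector over all nodes.
#' @export
network_degree <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  deg <- stats::setNames(integer(length(net$nodes)), net$nodes)
  if (nrow(net$edges)) {
    tab <- table(c(net$edges$from, net$edges$to))
    deg[names(tab)] <- as.integer(tab)
  }
  deg
}

#' Sparse symmetric connectivity matrix
#'
#' @param net A [gene_network].
#' @param weighted If `FALSE`, every edge contributes 1 instead of its weight.
#' @return A symmetric `dgCMatrix` with genes as dimnames.
#' @export
as_adjacency <- function(net, weighted = TRUE) {
  stopifnot(inherits(net, "gene_network"))
  n <- length(net$nodes)
  i <- match(net$edges$from, net$nodes)
  j <- match(net$edges$to, net$nodes)
  w <- if (weighted) net$edges$weight else rep(1, length(i))
  Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(w, w),
                       dims = c(n, n), dimnames = list(net$nodes, net$nodes))
}
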