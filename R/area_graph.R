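#' Area adjacency graphs
#'
#' An `area_graph` is the adjacency structure on which all intrinsic CAR
#' (ICAR) computations operate: an ordered set of area labels, a symmetric
#' neighbour list without self-loops, the per-area neighbour counts
#' \eqn{n_i} that appear in the ICAR conditional variance
#' \eqn{\sigma^2/n_i}, and the undirected edge list.
#'
#' Areas with no neighbours ("islands") are rejected: the ICAR conditional
#' mean (the neighbour average) is undefined for them, so the user must
#' merge or connect such areas rather than have the model silently altered.
#'
#' @param area_ids character vector of unique area labels; their order fixes
#'   the index used by every per-area vector in the package.
#' @param edges two-column matrix (or data.frame) of area indices or labels,
#'   one undirected edge per row.
#' @return An object of class `area_graph`: a list with elements
#'   `area_ids`, `neighbors` (list of sorted integer vectors),
#'   `n_neighbors`, `edges` (two-column integer matrix with
#'   `edges[,1] < edges[,2]`), and `n_areas`.
#' @examples
#' g <- area_graph(c("A", "B", "C"), cbind(c(1, 2), c(2, 3)))
#' g$n_neighbors  # path graph: 1, 2, 1
#' @export
area_graph <- function(area_ids, edges) {
  area_ids <- as.character(area_ids)
  n <- length(area_ids)
  if (n < 2L) stop("an area graph needs at least 2 areas")
  if (anyDuplicated(area_ids)) stop("duplicate area ids: ",
    paste(unique(area_ids[duplicated(area_ids)]), collapse = ", "))
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L) stop("edges must have two columns")
  if (is.character(edges)) {
    idx <- match(edges, area_ids)
    bad <- is.na(idx)
    if (any(bad)) stop("unknown area id in edge list: ",
      paste(unique(edges[bad]), collapse = ", "))
    edges <- matrix(idx, ncol = 2L)
  }
  storage.mode(edges) <- "integer"
  if (any(edges < 1L | edges > n)) stop("edge index out of range")
  if (any(edges[, 1L] == edges[, 2L])) {
    loops <- unique(area_ids[edges[edges[, 1L] == edges[, 2L], 1L]])
    stop("self-loop edge(s) on area(s): ", paste(loops, collapse = ", "))
  }
  # canonical undirected form, duplicates dropped
  edges <- cbind(pmin(edges[, 1L], edges[, 2L]),
                 pmax(edges[, 1L], edges[, 2L]))
  edges <- unique(edges)
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]

  neighbors <- vector("list", n)
  for (i in seq_len(n)) neighbors[[i]] <- integer(0)
  if (nrow(edges) > 0L) {
    nb <- split(c(edges[, 2L], edges[, 1L]), c(edges[, 1L], edges[, 2L]))
    for (k in names(nb)) neighbors[[as.integer(k)]] <- sort(unique(nb[[k]]))
  }
  n_neighbors <- lengths(neighbors)
  if (any(n_neighbors == 0L)) {
    stop("island area(s) with no neighbours: ",
         paste(area_ids[n_neighbors == 0L], collapse = ", "),
         " (merge or connect them; the ICAR conditional is undefined)")
  }
  structure(list(area_ids = area_ids, neighbors = neighbors,
                 n_neighbors = as.integer(n_neighbors),
                 edges = edges, n_areas = n),
            class = "area_graph")
}

#' @export
print.area_graph <- function(x, ...) {
  cat(sprintf("area_graph: %d areas, %d edges, %d component(s)\n",
              x$n_areas, nrow(x$edges), length(connected_components(x))))
  invisible(x)
}

#' Regular lattice graph
#'
#' Builds a rows-by-cols grid with rook (4-neighbour) or queen (8-neighbour)
#' contiguity, the standard synthetic stand-in for a real areal map such as
#' a set of census block groups. Areas are ordered row-major and labelled
#' `"r<row>c<col>"`.
#'
#' @param rows,cols positive integers; `rows * cols >= 2`.
#' @param contiguity `"rook"` (edge-sharing) or `"queen"` (edge- or
#'   corner-sharing).
#' @return An [area_graph()].
#' @examples
#' g <- build_lattice(3, 3, "rook")
#' g$n_neighbors[5]  # interior cell has 4 rook neighbours
#' @export
build_lattice <- function(rows, cols, contiguity = c("rook", "queen")) {
  contiguity <- match.arg(contiguity)
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (is.na(rows) || is.na(cols) || rows < 1L || cols < 1L || rows * cols < 2L)
    stop("rows * cols must be at least 2")
  idx <- function(r, c) (r - 1L) * cols + c
  r <- rep(seq_len(rows), each = cols)
  c <- rep(seq_len(cols), times = rows)
  steps <- list(c(0L, 1L), c(1L, 0L))
  if (contiguity == "queen") steps <- c(steps, list(c(1L, 1L), c(1L, -1L)))
  from <- integer(0); to <- integer(0)
  for (s in steps) {
    r2 <- r + s[1L]; c2 <- c + s[2L]
    ok <- r2 >= 1L & r2 <= rows & c2 >= 1L & c2 <= cols
    from <- c(from, idx(r, c)[ok])
    to <- c(to, idx(r2, c2)[ok])
  }
  ids <- sprintf("r%dc%d", r, c)
  area_graph(ids, cbind(from, to))
}

#' Read an adjacency structure from disk
#'
#' Two plain-text dialects are supported. `edge_list_csv` is a CSV with
#' header `src,dst` and one undirected edge per row. `gal` is the GAL-style
#' neighbour list: a first line with the number of areas, then for each area
#' a header line `id n_i` followed by a line of whitespace-separated
#' neighbour ids.
#'
#' Directed/asymmetric input is symmetrized (union of both directions) with
#' a warning, since contiguity is inherently symmetric.
#'
#' @param path file path.
#' @param dialect `"edge_list_csv"` or `"gal"`.
#' @return An [area_graph()].
#' @seealso [write_adjacency()]
#' @export
read_adjacency <- function(path, dialect = c("edge_list_csv", "gal")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "edge_list_csv") {
    df <- utils::read.csv(path, colClasses = "character")
    if (!all(c("src", "dst") %in% names(df)))
      stop("edge-list CSV must have columns 'src' and 'dst'")
    loops <- df$src == df$dst
    if (any(loops))
      stop("self-loop edge(s) on area(s): ",
           paste(unique(df$src[loops]), collapse = ", "))
    ids <- sort(unique(c(df$src, df$dst)))
    e <- cbind(match(df$src, ids), match(df$dst, ids))
    area_graph(ids, e)
  } else {
    lines <- trimws(readLines(path))
    lines <- lines[nzchar(lines)]
    n <- as.integer(strsplit(lines[1L], "\\s+")[[1L]][1L])
    if (is.na(n)) stop("GAL file: first line must give the number of areas")
    ids <- character(n); nbr_ids <- vector("list", n)
    pos <- 2L
    for (k in seq_len(n)) {
      hdr <- strsplit(lines[pos], "\\s+")[[1L]]
      if (length(hdr) != 2L) stop("GAL file: bad area header at line ", pos)
      ids[k] <- hdr[1L]
      cnt <- as.integer(hdr[2L])
      if (cnt > 0L) {
        nbr_ids[[k]] <- strsplit(lines[pos + 1L], "\\s+")[[1L]]
        if (length(nbr_ids[[k]]) != cnt)
          stop("GAL file: area ", ids[k], " declares ", cnt,
               " neighbours but lists ", length(nbr_ids[[k]]))
        pos <- pos + 2L
      } else {
        nbr_ids[[k]] <- character(0)
        pos <- pos + 1L
      }
    }
    unknown <- setdiff(unique(unlist(nbr_ids)), ids)
    if (length(unknown))
      stop("GAL file: unknown neighbour id(s): ",
           paste(unknown, collapse = ", "))
    from <- rep(seq_len(n), lengths(nbr_ids))
    to <- match(unlist(nbr_ids), ids)
    e <- cbind(from, to)
    # check symmetry before the union silently repairs it
    key <- paste(pmin(from, to), pmax(from, to))
    tab <- table(key)
    if (any(tab != 2L))
      warning("asymmetric adjacency input symmetrized (union of directions)")
    area_graph(ids, e)
  }
}

#' Write an adjacency structure to disk
#'
#' Inverse of [read_adjacency()]; round-trips exactly in either dialect.
#'
#' @param graph an [area_graph()].
#' @param path output file path.
#' @param dialect `"edge_list_csv"` or `"gal"`.
#' @export
write_adjacency <- function(graph, path,
                            dialect = c("edge_list_csv", "gal")) {
  dialect <- match.arg(dialect)
  if (dialect == "edge_list_csv") {
    df <- data.frame(src = graph$area_ids[graph$edges[, 1L]],
                     dst = graph$area_ids[graph$edges[, 2L]])
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    out <- character(1L + 2L * graph$n_areas)
    out[1L] <- as.character(graph$n_areas)
    p <- 2L
    for (i in seq_len(graph$n_areas)) {
      out[p] <- paste(graph$area_ids[i], graph$n_neighbors[i])
      out[p + 1L] <- paste(graph$area_ids[graph$neighbors[[i]]],
                           collapse = " ")
      p <- p + 2L
    }
    writeLines(out, path)
  }
  invisible(path)
}

#' Connected components of an area graph
#'
#' Each component gets its own sum-to-zero constraint in the ICAR prior
#' (the prior is improper along one flat direction per component).
#'
#' @param graph an [area_graph()].
#' @return List of integer vectors partitioning `1:n_areas`.
#' @export
connected_components <- function(graph) {
  n <- graph$n_areas
  comp <- integer(n)
  ncomp <- 0L
  for (start in seq_len(n)) {
    if (comp[start] > 0L) next
    ncomp <- ncomp + 1L
    queue <- start
    comp[start] <- ncomp
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- graph$neighbors[[v]]
      new <- nb[comp[nb] == 0L]
      comp[new] <- ncomp
      queue <- c(queue, new)
    }
  }
  split(seq_len(n), comp)
}

#' Sparse binary adjacency matrix of an area graph
#' @param graph an [area_graph()].
#' @return A symmetric sparse [Matrix::sparseMatrix()] W with W_ij = 1 for
#'   neighbours.
#' @keywords internal
adjacency_matrix <- function(graph) {
  e <- graph$edges
  Matrix::sparseMatrix(i = c(e[, 1L], e[, 2L]), j = c(e[, 2L], e[, 1L]),
                       x = 1, dims = c(graph$n_areas, graph$n_areas))
}

#' Greedy proper colouring of an area graph
#'
#' Used to vectorize single-site Metropolis updates of ICAR fields: areas of
#' one colour share no edge, so their full conditionals do not involve each
#' other and can be updated simultaneously.
#'
#' @param graph an [area_graph()].
#' @return List of integer vectors (colour classes) partitioning the areas.
#' @keywords internal
graph_coloring <- function(graph) {
  n <- graph$n_areas
  ord <- order(graph$n_neighbors, decreasing = TRUE)
  color <- integer(n)
  for (v in ord) {
    used <- color[graph$neighbors[[v]]]
    k <- 1L
    while (k %in% used) k <- k + 1L
    color[v] <- k
  }
  split(seq_len(n), color)
}
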