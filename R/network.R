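#' Road network
#'
#' An undirected road network: nodes with lon/lat, edges with polyline
#' geometry and geodesic length. Derived structures (igraph graph, all-pairs
#' node distances, the spatial edge index used for map-matching candidates)
#' are computed lazily and cached inside the object.
#'
#' @param nodes data.frame with columns `id` (integer), `lon`, `lat`.
#' @param edges data.frame with columns `edge_id` (integer), `from`, `to`
#'   (node ids) and optionally `length_m`.
#' @param geoms list of 2-column (lon, lat) matrices, one polyline per edge;
#'   `NULL` means straight lines between the end nodes.
#' @return an object of class `road_network`.
#' @export
road_network <- function(nodes, edges, geoms = NULL) {
  stopifnot(all(c("id", "lon", "lat") %in% names(nodes)),
            all(c("edge_id", "from", "to") %in% names(edges)))
  if (!all(edges$from %in% nodes$id) || !all(edges$to %in% nodes$id))
    stop("edge references a non-existent node", call. = FALSE)
  if (is.null(geoms)) {
    fi <- match(edges$from, nodes$id); ti <- match(edges$to, nodes$id)
    geoms <- lapply(seq_len(nrow(edges)), function(k)
      cbind(lon = c(nodes$lon[fi[k]], nodes$lon[ti[k]]),
            lat = c(nodes$lat[fi[k]], nodes$lat[ti[k]])))
  }
  len <- vapply(geoms, function(g) {
    cd <- polyline_cumdist_m(g); cd[length(cd)]
  }, numeric(1))
  if (!is.null(edges$length_m)) {
    rel <- abs(edges$length_m - len) / pmax(len, 1e-9)
    if (any(rel > 0.001))
      stop("edge length_m disagrees with geodesic polyline length by > 0.1%",
           call. = FALSE)
  }
  edges$length_m <- len
  structure(
    list(nodes = nodes, edges = edges, geoms = geoms, cache = new.env(parent = emptyenv())),
    class = "road_network"
  )
}

#' @export
print.road_network <- function(x, ...) {
  cat(sprintf("road_network: %d nodes, %d edges, total %.1f km\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$length_m) / 1000))
  invisible(x)
}

# igraph representation: vertices named by node id (as character),
# edges weighted by length_m, edge attribute edge_id.
network_graph <- function(net) {
  if (is.null(net$cache$graph)) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(net$edges$from),
                 to = as.character(net$edges$to),
                 weight = net$edges$length_m,
                 edge_id = net$edges$edge_id),
      directed = FALSE,
      vertices = data.frame(name = as.character(net$nodes$id)))
    net$cache$graph <- g
  }
  net$cache$graph
}

network_is_connected <- function(net) {
  igraph::is_connected(network_graph(net))
}

# All-pairs shortest-path node distance matrix (metres), row/col names are
# node ids. Cached; intended for desk-scale networks (<= a few thousand nodes).
node_distances <- function(net) {
  if (is.null(net$cache$dist)) {
    net$cache$dist <- igraph::distances(network_graph(net))
  }
  net$cache$dist
}

# Edge ids and node id sequence of the shortest path between two node ids.
shortest_node_path <- function(net, from, to) {
  key <- paste0(from, "|", to)
  if (is.null(net$cache$paths)) net$cache$paths <- new.env(parent = emptyenv())
  hit <- net$cache$paths[[key]]
  if (!is.null(hit)) return(hit)
  g <- network_graph(net)
  sp <- igraph::shortest_paths(g, from = as.character(from), to = as.character(to),
                               output = "both")
  res <- list(
    nodes = as.integer(igraph::V(g)$name[as.integer(sp$vpath[[1]])]),
    edge_ids = igraph::E(g)$edge_id[as.integer(sp$epath[[1]])]
  )
  net$cache$paths[[key]] <- res
  res
}

# Spatial hash of edge segments for candidate lookup. Buckets of
# `bucket_deg` degrees; each segment is registered in every bucket its
# bounding box (padded by pad_deg) touches.
edge_index <- function(net, bucket_deg = 0.005, pad_deg = 0.001) {
  key <- sprintf("idx_%g_%g", bucket_deg, pad_deg)
  if (!is.null(net$cache[[key]])) return(net$cache[[key]])
  cum <- lapply(net$geoms, polyline_cumdist_m)
  segs <- do.call(rbind, lapply(seq_along(net$geoms), function(k) {
    g <- net$geoms[[k]]
    n <- nrow(g)
    if (n < 2L) return(NULL)
    cd <- cum[[k]]
    cbind(edge_row = k, ax = g[-n, 1], ay = g[-n, 2], bx = g[-1, 1],
          by = g[-1, 2], seg = seq_len(n - 1L),
          cum0_m = cd[-n], len_m = diff(cd))
  }))
  bucket_of <- function(x, y) paste(floor(x / bucket_deg), floor(y / bucket_deg))
  keys <- list(); rows <- list(); n <- 0L
  for (i in seq_len(nrow(segs))) {
    xs <- range(segs[i, c("ax", "bx")]) + c(-pad_deg, pad_deg)
    ys <- range(segs[i, c("ay", "by")]) + c(-pad_deg, pad_deg)
    bx <- seq(floor(xs[1] / bucket_deg), floor(xs[2] / bucket_deg))
    by <- seq(floor(ys[1] / bucket_deg), floor(ys[2] / bucket_deg))
    for (kx in bx) for (ky in by) {
      n <- n + 1L; keys[[n]] <- paste(kx, ky); rows[[n]] <- i
    }
  }
  tab <- split(unlist(rows), unlist(keys))
  idx <- list(segs = segs, buckets = tab, bucket_deg = bucket_deg, cum = cum)
  net$cache[[key]] <- idx
  idx
}

#' Write a road network as GeoJSON
#'
#' One LineString feature per edge with properties `edge_id`, `from`, `to`,
#' `length_m`; node ids/coordinates are recoverable from edge endpoints.
#'
#' @param net a [road_network()].
#' @param path output path.
#' @export
write_road_network_geojson <- function(net, path) {
  feats <- lapply(seq_len(nrow(net$edges)), function(k) {
    list(type = "Feature",
         properties = list(edge_id = net$edges$edge_id[k],
                           from = net$edges$from[k], to = net$edges$to[k],
                           length_m = net$edges$length_m[k]),
         geometry = list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(net$geoms[[k]])),
                                              function(i) as.numeric(net$geoms[[k]][i, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a road network from GeoJSON
#'
#' Inverse of [write_road_network_geojson()].
#'
#' @param path GeoJSON path.
#' @return a [road_network()].
#' @export
read_road_network_geojson <- function(path) {
  js <- jsonlite::read_json(path)
  if (is.null(js$type) || js$type != "FeatureCollection")
    stop("road network GeoJSON must be a FeatureCollection", call. = FALSE)
  feats <- js$features
  geoms <- lapply(feats, function(f) {
    co <- f$geometry$coordinates
    m <- do.call(rbind, lapply(co, function(p) as.numeric(unlist(p))))
    colnames(m) <- c("lon", "lat")
    m
  })
  edges <- do.call(rbind, lapply(feats, function(f)
    data.frame(edge_id = as.integer(f$properties$edge_id),
               from = as.integer(f$properties$from),
               to = as.integer(f$properties$to),
               length_m = as.numeric(f$properties$length_m))))
  first <- do.call(rbind, lapply(geoms, function(g) g[1, , drop = FALSE]))
  last <- do.call(rbind, lapply(geoms, function(g) g[nrow(g), , drop = FALSE]))
  node_df <- unique(data.frame(id = c(edges$from, edges$to),
                               lon = c(first[, 1], last[, 1]),
                               lat = c(first[, 2], last[, 2])))
  node_df <- node_df[!duplicated(node_df$id), , drop = FALSE]
  node_df <- node_df[order(node_df$id), , drop = FALSE]
  road_network(node_df, edges, geoms)
}
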