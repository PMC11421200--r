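# Hidden-Markov-model map matching (Viterbi decoding).
#
# States at each fix are candidate road positions: for every edge whose
# nearest point lies within candidate_radius_m of the fix, the nearest point
# on that edge. Emission log-probability is -d^2 / (2 sigma^2) with d the
# ground distance from fix to candidate. Transition log-probability between
# consecutive candidates is -|route - geodesic| / beta, where route is the
# shortest along-network distance between the two candidate points and
# geodesic the direct haversine distance; pairs with no network route are
# disallowed. Ties are broken deterministically: same edge as the previous
# state first, then lowest edge id.
#
# Internals are matrix-based: a candidate set is a matrix with columns
# edge_row, dist_m, offset_m, lon, lat, ordered by edge id.

# Plain haversine without input marshalling, for the hot loop.
fast_hav_m <- function(lon1, lat1, lon2, lat2) {
  k <- pi / 180
  dlat <- (lat2 - lat1) * k / 2; dlon <- (lon2 - lon1) * k / 2
  a <- sin(dlat)^2 + cos(lat1 * k) * cos(lat2 * k) * sin(dlon)^2
  2 * EARTH_RADIUS_M * asin(pmin(1, sqrt(a)))
}

# Candidate matrices for all fixes of a trip at once. The edge index is
# built with bucket padding that covers the search radius, so each fix needs
# only its own bucket; the point-to-segment projection is vectorised over
# all (fix, segment) pairs. Returns a list (one candidate matrix or NULL per
# fix); each matrix has one row per distinct edge, ordered by edge id.
candidates_for_fixes <- function(net, idx, lon, lat, radius_m) {
  n <- length(lon)
  bd <- idx$bucket_deg
  keys <- paste(floor(lon / bd), floor(lat / bd))
  per_fix <- idx$buckets[keys]
  n_seg <- lengths(per_fix)
  out <- vector("list", n)
  if (sum(n_seg) == 0L) return(out)
  fi <- rep.int(seq_len(n), n_seg)
  sr <- unlist(per_fix, use.names = FALSE)
  s <- idx$segs[sr, , drop = FALSE]
  plon <- lon[fi]; plat <- lat[fi]
  mlat <- m_per_deg_lat(); mlon <- mlat * cos(plat * pi / 180)
  axm <- (s[, "ax"] - plon) * mlon; aym <- (s[, "ay"] - plat) * mlat
  bxm <- (s[, "bx"] - plon) * mlon; bym <- (s[, "by"] - plat) * mlat
  dx <- bxm - axm; dy <- bym - aym
  len2 <- pmax(dx * dx + dy * dy, 1e-12)
  frac <- pmin(1, pmax(0, -(axm * dx + aym * dy) / len2))
  px <- axm + frac * dx; py <- aym + frac * dy
  d <- sqrt(px * px + py * py)
  keep <- d <= radius_m
  if (!any(keep)) return(out)
  fi <- fi[keep]; s <- s[keep, , drop = FALSE]; d <- d[keep]; frac <- frac[keep]
  er <- as.integer(s[, "edge_row"])
  eid <- net$edges$edge_id[er]
  # within each fix keep the nearest point per edge, then order by edge id
  o <- order(fi, eid, d)
  first <- o[!duplicated(cbind(fi, eid)[o, , drop = FALSE])]
  fi <- fi[first]; er <- er[first]; d <- d[first]; frac <- frac[first]
  s <- s[first, , drop = FALSE]
  cand <- cbind(edge_row = er, dist_m = d,
                offset_m = s[, "cum0_m"] + frac * s[, "len_m"],
                lon = s[, "ax"] + frac * (s[, "bx"] - s[, "ax"]),
                lat = s[, "ay"] + frac * (s[, "by"] - s[, "ay"]))
  grp <- split(seq_along(fi), fi)
  for (g in names(grp)) out[[as.integer(g)]] <- cand[grp[[g]], , drop = FALSE]
  out
}

# Sub-polyline of edge `edge_row` between along-edge offsets a and b (metres,
# either order). Returns a 2-column coords matrix including both endpoints.
edge_subpolyline <- function(net, idx, edge_row, a, b) {
  g <- net$geoms[[edge_row]]
  cum <- idx$cum[[edge_row]]
  lo <- min(a, b); hi <- max(a, b)
  inner <- which(cum > lo & cum < hi)
  pts <- rbind(polyline_point_at(g, cum, lo),
               if (length(inner)) g[inner, , drop = FALSE],
               polyline_point_at(g, cum, hi))
  if (a > b) pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
  pts
}

# Shortest along-network distance between candidate (e1, o1) and (e2, o2),
# given pre-extracted edge endpoint/length vectors and the node distance
# matrix. Returns c(dist, u, w); u/w are NA when both candidates share an
# edge.
route_dist <- function(e1, o1, e2, o2, ed_from, ed_to, ed_len, D, node_row) {
  if (e1 == e2) return(c(abs(o2 - o1), NA_integer_, NA_integer_))
  u_nodes <- c(ed_from[e1], ed_to[e1]); u_d <- c(o1, ed_len[e1] - o1)
  w_nodes <- c(ed_from[e2], ed_to[e2]); w_d <- c(o2, ed_len[e2] - o2)
  mid <- D[node_row[u_nodes], node_row[w_nodes]]
  tot <- mid + u_d + rep(w_d, each = 2)  # column-major: (u1w1,u2w1,u1w2,u2w2)
  i <- which.min(tot)
  if (!is.finite(tot[i])) return(c(Inf, NA_integer_, NA_integer_))
  c(tot[i], u_nodes[(i - 1) %% 2 + 1], w_nodes[(i - 1) %/% 2 + 1])
}

#' Map-match a trip to the road network
#'
#' Viterbi-optimal assignment of each fix to a candidate road position
#' (HMM map matching). The matched path is the concatenation of shortest
#' network paths through the chosen candidates; `distance_km` is its
#' along-path length. A fix with no candidate within
#' `candidate_radius_m` splits the trip into independently matched
#' sub-trips, each of which must still pass the trip filters; sub-trips whose
#' matched distance falls below `min_distance_m` are dropped.
#'
#' @param trip an unmatched `taxi_trip` from [extract_trips()].
#' @param network a [road_network()].
#' @param sigma_m GPS noise scale of the emission model, metres.
#' @param beta_m route/geodesic discrepancy scale of the transition model,
#'   metres.
#' @param candidate_radius_m candidate search radius, metres.
#' @param min_fixes,min_duration_s,min_distance_m trip filters re-applied to
#'   sub-trips.
#' @return list of matched `taxi_trip` objects (possibly empty). Each gains
#'   `matched` (list with `edge_ids`, `fix_edge_ids`, `fix_dist_m`,
#'   `path_coords`, `path_cum_m`) and `distance_km`.
#' @export
map_match <- function(trip, network, sigma_m = 10, beta_m = 200,
                      candidate_radius_m = 50, min_fixes = 2L,
                      min_duration_s = 60, min_distance_m = 200) {
  # bucket padding must cover the search radius so one bucket per fix suffices
  cos_min <- max(0.2, min(cos(network$nodes$lat * pi / 180)))
  idx <- edge_index(network,
                    pad_deg = candidate_radius_m / (m_per_deg_lat() * cos_min) + 1e-4)
  fx <- trip$fixes
  cands <- candidates_for_fixes(network, idx, fx$lon, fx$lat, candidate_radius_m)
  has <- !vapply(cands, is.null, logical(1))
  if (!all(has))
    message(sprintf("map_match: %d fixes without candidates; trip split",
                    sum(!has)))
  out <- list()
  r <- rle(has)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    rows <- starts[k]:ends[k]
    sub_fx <- fx[rows, , drop = FALSE]
    dur <- as.numeric(sub_fx$time[nrow(sub_fx)]) - as.numeric(sub_fx$time[1])
    if (nrow(sub_fx) < min_fixes || dur < min_duration_s) next
    m <- viterbi_match(trip$taxi_id, sub_fx, cands[rows], network, idx,
                       sigma_m, beta_m)
    if (is.null(m)) next
    if (m$distance_km * 1000 < min_distance_m) next
    out[[length(out) + 1L]] <- m
  }
  out
}

viterbi_match <- function(taxi_id, fx, cands, net, idx, sigma_m, beta_m) {
  D <- node_distances(net)
  nid <- as.integer(rownames(D))
  node_row <- integer(max(nid)); node_row[nid] <- seq_along(nid)
  ed_from <- net$edges$from; ed_to <- net$edges$to
  ed_len <- net$edges$length_m; ed_id <- net$edges$edge_id
  sig2 <- max(sigma_m, 1e-6)^2
  n <- length(cands)
  score <- vector("list", n); back <- vector("list", n)
  score[[1]] <- -cands[[1]][, "dist_m"]^2 / (2 * sig2)
  if (n >= 2) for (t in 2:n) {
    prev <- cands[[t - 1L]]; cur <- cands[[t]]
    np <- nrow(prev); nc <- nrow(cur)
    psc <- score[[t - 1L]]
    sc <- numeric(nc); bk <- integer(nc)
    for (j in seq_len(nc)) {
      gd <- fast_hav_m(prev[, "lon"], prev[, "lat"], cur[j, "lon"], cur[j, "lat"])
      tot <- rep(-Inf, np)
      for (i in seq_len(np)) {
        if (!is.finite(psc[i])) next
        rd <- route_dist(prev[i, "edge_row"], prev[i, "offset_m"],
                         cur[j, "edge_row"], cur[j, "offset_m"],
                         ed_from, ed_to, ed_len, D, node_row)[1]
        if (!is.finite(rd)) next
        tot[i] <- psc[i] - abs(rd - gd[i]) / beta_m
      }
      best <- max(tot)
      if (!is.finite(best)) { sc[j] <- -Inf; bk[j] <- 1L; next }
      ties <- which(tot == best)
      if (length(ties) > 1L) {
        same <- ties[prev[ties, "edge_row"] == cur[j, "edge_row"]]
        ties <- if (length(same)) same else
          ties[order(ed_id[prev[ties, "edge_row"]])]
      }
      bk[j] <- ties[1]
      sc[j] <- best - cur[j, "dist_m"]^2 / (2 * sig2)
    }
    score[[t]] <- sc; back[[t]] <- bk
    if (all(!is.finite(sc))) return(NULL)  # no consistent route
  }
  fin <- score[[n]]
  best <- max(fin)
  ties <- which(fin == best)
  if (length(ties) > 1L)
    ties <- ties[order(ed_id[cands[[n]][ties, "edge_row"]])]
  chosen <- integer(n); chosen[n] <- ties[1]
  if (n >= 2) for (t in n:2) chosen[t - 1L] <- back[[t]][chosen[t]]
  picked <- do.call(rbind, lapply(seq_len(n), function(t)
    cands[[t]][chosen[t], , drop = FALSE]))
  build_matched_trip(taxi_id, fx, picked, net, idx, D, node_row)
}

# Assemble the matched trip: concatenated path polyline, traversed edge ids,
# per-fix along-path distances and total length.
build_matched_trip <- function(taxi_id, fx, picked, net, idx, D, node_row) {
  n <- nrow(picked)
  ed_from <- net$edges$from; ed_to <- net$edges$to
  ed_len <- net$edges$length_m; ed_id <- net$edges$edge_id
  co_parts <- list(cbind(lon = picked[1, "lon"], lat = picked[1, "lat"]))
  eid_parts <- list(ed_id[picked[1, "edge_row"]])
  fix_dist <- numeric(n)
  sub <- function(e, a, b) {  # interior of edge e between offsets a, b
    g <- net$geoms[[e]]
    if (nrow(g) == 2L) {  # straight edge: direct interpolation
      f <- b / ed_len[e]
      return(cbind(lon = g[1, 1] + f * (g[2, 1] - g[1, 1]),
                   lat = g[1, 2] + f * (g[2, 2] - g[1, 2])))
    }
    edge_subpolyline(net, idx, e, a, b)[-1, , drop = FALSE]
  }
  if (n >= 2) for (t in 2:n) {
    e1 <- picked[t - 1L, "edge_row"]; o1 <- picked[t - 1L, "offset_m"]
    e2 <- picked[t, "edge_row"]; o2 <- picked[t, "offset_m"]
    rd <- route_dist(e1, o1, e2, o2, ed_from, ed_to, ed_len, D, node_row)
    fix_dist[t] <- fix_dist[t - 1L] + rd[1]
    if (e1 == e2) {
      if (abs(o2 - o1) > 0) {
        co_parts[[length(co_parts) + 1L]] <- sub(e1, o1, o2)
        eid_parts[[length(eid_parts) + 1L]] <- ed_id[e1]
      }
    } else {
      u <- rd[2]; w <- rd[3]
      o_u <- if (u == ed_from[e1]) 0 else ed_len[e1]
      if (abs(o_u - o1) > 1e-9) {
        co_parts[[length(co_parts) + 1L]] <- sub(e1, o1, o_u)
        eid_parts[[length(eid_parts) + 1L]] <- ed_id[e1]
      }
      if (u != w) {
        sp <- shortest_node_path(net, u, w)
        if (length(sp$edge_ids)) {
          nodes <- sp$nodes
          for (q in seq_along(sp$edge_ids)) {
            er <- match(sp$edge_ids[q], ed_id)
            g <- net$geoms[[er]]
            if (ed_from[er] != nodes[q])
              g <- g[rev(seq_len(nrow(g))), , drop = FALSE]
            co_parts[[length(co_parts) + 1L]] <- g[-1, , drop = FALSE]
          }
          eid_parts[[length(eid_parts) + 1L]] <- sp$edge_ids
        }
      }
      o_w <- if (w == ed_from[e2]) 0 else ed_len[e2]
      if (abs(o2 - o_w) > 1e-9) {
        co_parts[[length(co_parts) + 1L]] <- sub(e2, o_w, o2)
        eid_parts[[length(eid_parts) + 1L]] <- ed_id[e2]
      }
    }
  }
  coords <- do.call(rbind, co_parts)
  dimnames(coords) <- list(NULL, c("lon", "lat"))
  edge_ids <- unlist(eid_parts, use.names = FALSE)
  edge_ids <- edge_ids[c(TRUE, diff(edge_ids) != 0)]
  tr <- new_trip(taxi_id, fx)
  tr$matched <- list(
    edge_ids = edge_ids,
    fix_edge_ids = ed_id[picked[, "edge_row"]],
    fix_dist_m = fix_dist,
    path_coords = coords,
    path_cum_m = polyline_cumdist_m(coords))
  tr$distance_km <- fix_dist[n] / 1000
  tr
}
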