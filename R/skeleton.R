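# Morphological skeletonization and skeleton-graph utilities.
#
# EBImage provides no thinning operation, so Zhang-Suen thinning is
# implemented here directly, vectorized over shifted copies of the mask.

shift_mat <- function(m, dr, dc) {
  out <- matrix(0L, nrow(m), ncol(m))
  rs <- seq_len(nrow(m)) - dr
  cs <- seq_len(ncol(m)) - dc
  ok_r <- rs >= 1 & rs <= nrow(m)
  ok_c <- cs >= 1 & cs <= ncol(m)
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

# 8-neighbourhood in Zhang-Suen order P2..P9 (N, NE, E, SE, S, SW, W, NW),
# with image rows growing downward.
zs_offsets <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                   c(1, 0), c(1, -1), c(0, -1), c(-1, -1))

#' Skeletonize a binary mask (Zhang-Suen thinning)
#'
#' Iteratively peels border pixels until a single-pixel-wide, 8-connected
#' skeleton remains.
#'
#' @param mask logical or 0/1 matrix.
#' @return logical matrix of the same shape.
#' @export
thin_mask <- function(mask) {
  img <- matrix(as.integer(as.matrix(mask) != 0), nrow(as.matrix(mask)))
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      nb <- lapply(zs_offsets, function(o) shift_mat(img, o[1], o[2]))
      b <- Reduce(`+`, nb)
      ring <- c(nb, nb[1])
      a <- Reduce(`+`, lapply(seq_len(8), function(i) {
        (ring[[i]] == 0L) * (ring[[i + 1]] == 1L)
      }))
      if (sub == 1) {
        cond <- nb[[1]] * nb[[3]] * nb[[5]] == 0L &
          nb[[3]] * nb[[5]] * nb[[7]] == 0L
      } else {
        cond <- nb[[1]] * nb[[3]] * nb[[7]] == 0L &
          nb[[1]] * nb[[5]] * nb[[7]] == 0L
      }
      del <- img == 1L & b >= 2 & b <= 6 & a == 1L & cond
      if (any(del)) {
        img[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img == 1L
}

# Build an igraph over skeleton pixels: vertices are pixels, edges connect
# 8-neighbours with weight 1 (orthogonal) or sqrt(2) (diagonal).
skeleton_graph <- function(skel) {
  px <- which(skel, arr.ind = TRUE)
  n <- nrow(px)
  if (n == 0) {
    return(list(g = igraph::make_empty_graph(0, directed = FALSE),
                px = px, id = matrix(0L, nrow(skel), ncol(skel))))
  }
  id <- matrix(0L, nrow(skel), ncol(skel))
  id[px] <- seq_len(n)
  edges <- NULL
  weights <- NULL
  # half the neighbourhood suffices for an undirected graph
  for (o in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
    r2 <- px[, 1] + o[1]
    c2 <- px[, 2] + o[2]
    ok <- r2 >= 1 & r2 <= nrow(skel) & c2 >= 1 & c2 <= ncol(skel)
    tgt <- integer(n)
    tgt[ok] <- id[cbind(r2[ok], c2[ok])]
    has <- tgt > 0L
    if (any(has)) {
      edges <- rbind(edges, cbind(which(has), tgt[has]))
      weights <- c(weights, rep(sqrt(sum(o^2)), sum(has)))
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (!is.null(edges)) {
    g <- igraph::add_edges(g, t(edges))
    igraph::E(g)$weight <- weights
  }
  list(g = g, px = px, id = id)
}

# Resolve crossings by angular continuity: where two neurites cross, the
# skeleton forms a junction cluster with four arms; opposite (collinear)
# arms are re-connected directly and the cluster is cut, so each neurite
# runs straight through instead of merging into one component. Junctions
# with three arms (true branch points) are left untouched; clusters whose
# arms cannot all be paired are left untouched too.
resolve_crossings <- function(sg, walk_steps = 5, min_pair_angle = 135,
                              merge_px = 4, region_hops = 2) {
  g <- sg$g
  deg <- igraph::degree(g)
  junc <- which(deg >= 3)
  if (length(junc) < 2) return(sg)
  # a crossing usually thins into two nearby Y-junctions: cluster junction
  # pixels within a small geodesic radius of each other
  dj <- igraph::distances(g, v = junc, to = junc)
  jg <- igraph::graph_from_adjacency_matrix(dj <= merge_px,
                                            mode = "undirected",
                                            diag = FALSE)
  jcl <- igraph::components(jg)
  for (k in seq_len(jcl$no)) {
    Jj <- junc[jcl$membership == k]
    J <- unique(unlist(lapply(
      igraph::ego(g, order = region_hops, nodes = Jj), as.integer)))
    arms <- setdiff(unique(unlist(lapply(J, function(v)
      as.integer(igraph::neighbors(g, v))))), J)
    if (length(arms) < 4) next
    centroid <- colMeans(sg$px[Jj, , drop = FALSE])
    dirs <- t(vapply(arms, function(a) {
      cur <- a; prev_set <- J
      for (s in seq_len(walk_steps)) {
        nb <- setdiff(as.integer(igraph::neighbors(g, cur)),
                      c(prev_set, J, arms))
        if (length(nb) != 1 || deg[nb] > 2) break
        prev_set <- c(prev_set, cur)
        cur <- nb
      }
      v <- sg$px[cur, ] - centroid
      v / max(sqrt(sum(v^2)), 1e-9)
    }, numeric(2)))
    # pair arms whose directions are closest to opposite (angle near 180)
    n_a <- length(arms)
    pairs <- utils::combn(n_a, 2)
    cosv <- vapply(seq_len(ncol(pairs)), function(i)
      sum(dirs[pairs[1, i], ] * dirs[pairs[2, i], ]), numeric(1))
    angv <- acos(pmin(pmax(cosv, -1), 1)) * 180 / pi
    ord <- order(-angv)
    used <- logical(n_a)
    chosen <- list()
    for (i in ord) {
      a1 <- pairs[1, i]; a2 <- pairs[2, i]
      if (used[a1] || used[a2]) next
      if (angv[i] < min_pair_angle) next
      used[a1] <- used[a2] <- TRUE
      chosen[[length(chosen) + 1]] <- c(arms[a1], arms[a2])
    }
    if (!all(used)) next        # only cut cleanly resolvable crossings
    eids <- unique(unlist(igraph::incident_edges(g, J)))
    g <- igraph::delete_edges(g, eids)
    for (p in chosen) {
      w <- sqrt(sum((sg$px[p[1], ] - sg$px[p[2], ])^2))
      g <- igraph::add_edges(g, p, weight = w)
    }
  }
  sg$g <- g
  sg
}

# Remove leaf branches shorter than min_len_px (geodesic). Keeps the
# skeleton one pixel wide; iterates until stable.
prune_skeleton <- function(skel, min_len_px) {
  if (min_len_px <= 0 || !any(skel)) return(skel)
  repeat {
    sg <- skeleton_graph(skel)
    deg <- igraph::degree(sg$g)
    tips <- which(deg == 1)
    junctions <- which(deg >= 3)
    if (!length(tips) || !length(junctions)) return(skel)
    removed_any <- FALSE
    for (tip in tips) {
      # walk from the tip to the first junction, measuring path length
      path <- tip
      len <- 0
      cur <- tip
      prev <- 0L
      repeat {
        nbrs <- as.integer(igraph::neighbors(sg$g, cur))
        nxt <- setdiff(nbrs, prev)
        if (!length(nxt)) break        # isolated segment: keep
        nxt <- nxt[1]
        len <- len + sqrt(sum((sg$px[cur, ] - sg$px[nxt, ])^2))
        if (deg[nxt] >= 3) {
          if (len < min_len_px) {
            skel[sg$px[path, , drop = FALSE]] <- FALSE
            removed_any <- TRUE
          }
          break
        }
        prev <- cur
        cur <- nxt
        path <- c(path, cur)
        if (len >= min_len_px) break
      }
    }
    if (!removed_any) return(skel)
  }
}
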