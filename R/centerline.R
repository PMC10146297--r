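# Coronary mask post-processing and centerline extraction: gap bridging
# between interrupted segments, removal of mislabeled components (veins,
# heart tissue), curve skeletonisation by 3D topological thinning, ordered
# cross-section sampling along the centerlines, and LCA/RCA labelling.

# ---- 3D simple-point machinery -------------------------------------------
# A border voxel may be deleted without changing topology iff (a) the
# foreground within its 26-neighbourhood is one 26-connected component and
# (b) the background within its 18-neighbourhood is one 6-connected
# component adjacent to the voxel (Bertrand's characterisation). The 27-cell
# cube adjacency is precomputed once at load time.

.cube <- local({
  pos <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  center <- which(rowSums(abs(pos)) == 0L)
  cheb <- function(i, j) max(abs(pos[i, ] - pos[j, ]))
  manh <- function(i, j) sum(abs(pos[i, ] - pos[j, ]))
  n <- nrow(pos)
  adj26 <- lapply(seq_len(n), function(i) {
    js <- setdiff(seq_len(n), c(i, center))
    js[vapply(js, function(j) cheb(i, j) == 1L, logical(1))]
  })
  adj6 <- lapply(seq_len(n), function(i) {
    js <- setdiff(seq_len(n), c(i, center))
    js[vapply(js, function(j) manh(i, j) == 1L, logical(1))]
  })
  in18 <- which(rowSums(abs(pos)) <= 2L & seq_len(n) != center)
  face <- which(rowSums(abs(pos)) == 1L)
  list(pos = pos, center = center, adj26 = adj26, adj6 = adj6,
       in18 = in18, face = face)
})

# Count connected components of `nodes` (indices into the 27-cube) under the
# given adjacency list, optionally only components touching `must_touch`.
cube_cc <- function(nodes, adj, must_touch = NULL) {
  if (!length(nodes)) return(0L)
  seen <- logical(27L)
  comp <- 0L
  inset <- logical(27L); inset[nodes] <- TRUE
  for (s in nodes) {
    if (seen[s]) next
    frontier <- s
    seen[s] <- TRUE
    members <- s
    while (length(frontier)) {
      nxt <- unique(unlist(adj[frontier], use.names = FALSE))
      nxt <- nxt[inset[nxt] & !seen[nxt]]
      seen[nxt] <- TRUE
      members <- c(members, nxt)
      frontier <- nxt
    }
    if (is.null(must_touch) || any(members %in% must_touch)) comp <- comp + 1L
  }
  comp
}

# Simple-point test on a padded logical array at linear index `i`.
is_simple_point <- function(padded, i, cube_offs) {
  nb <- padded[i + cube_offs]          # 27 cells, cube order
  nb[.cube$center] <- FALSE
  fg <- which(nb)
  if (!length(fg)) return(FALSE)
  if (cube_cc(fg, .cube$adj26) != 1L) return(FALSE)
  bg18 <- .cube$in18[!nb[.cube$in18]]
  if (!length(bg18)) return(FALSE)
  cube_cc(bg18, .cube$adj6, must_touch = .cube$face) == 1L
}

# Curve thinning: iteratively delete simple border points, cycling over the
# six border directions until stable. Voxels with two or fewer foreground
# neighbours are never deleted: a curve voxel whose two neighbours are not
# mutually adjacent is non-simple anyway, and one whose neighbours ARE
# adjacent is locally indistinguishable from the end of a staircase arc -
# deleting those lets a sequential sweep eat a thin digital rod end to end
# (each deletion is topologically simple but shortens the curve). The
# redundant elbow voxels this protection leaves behind are removed later on
# the skeleton graph, where endpoints are globally identifiable.
thin_mask <- function(mask) {
  d <- dim(mask)
  dp <- d + 2L
  padded <- array(FALSE, dp)
  padded[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask
  steps26 <- neighbor_steps(26L)
  offs26 <- steps26[, 1] + steps26[, 2] * dp[1] + steps26[, 3] * dp[1] * dp[2]
  cube_offs <- .cube$pos[, 1] + .cube$pos[, 2] * dp[1] + .cube$pos[, 3] * dp[1] * dp[2]
  dir_steps <- neighbor_steps(6L)
  dir_offs <- dir_steps[, 1] + dir_steps[, 2] * dp[1] + dir_steps[, 3] * dp[1] * dp[2]
  repeat {
    deleted_any <- FALSE
    for (dirk in seq_along(dir_offs)) {
      fg <- which(padded)
      if (!length(fg)) break
      # border in this direction, with > 2 foreground neighbours
      nn <- integer(length(fg))
      for (o in offs26) nn <- nn + padded[fg + o]
      cand <- fg[!padded[fg + dir_offs[dirk]] & nn > 2L]
      for (i in cand) {
        # degree may have dropped during this subiteration
        deg <- sum(padded[i + offs26])
        if (deg <= 2L) next
        if (is_simple_point(padded, i, cube_offs)) {
          padded[i] <- FALSE
          deleted_any <- TRUE
        }
      }
    }
    if (!deleted_any) break
  }
  padded[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L), drop = FALSE]
}

# ---- component geometry helpers ------------------------------------------

component_info <- function(idx_mm) {
  ctr <- colMeans(idx_mm)
  if (nrow(idx_mm) < 2L) {
    return(list(center = ctr, dir = c(0, 0, 1), ends = rbind(ctr, ctr), len = 0))
  }
  pc <- stats::prcomp(idx_mm, center = TRUE)
  dir <- pc$rotation[, 1]
  proj <- as.numeric(sweep(idx_mm, 2, ctr) %*% dir)
  lo <- idx_mm[which.min(proj), ]; hi <- idx_mm[which.max(proj), ]
  list(center = ctr, dir = dir, ends = rbind(lo, hi),
       len = max(proj) - min(proj))
}

angle_deg <- function(u, v) {
  cu <- sqrt(sum(u^2)); cv <- sqrt(sum(v^2))
  if (cu < 1e-9 || cv < 1e-9) return(0)
  acos(clamp(sum(u * v) / (cu * cv), -1, 1)) * 180 / pi
}

#' Bridge discontinuous vessel segments
#'
#' Pairs of component endpoints closer than `max_gap_mm` whose outward
#' directions disagree with the bridge direction by less than `max_angle_deg`
#' are connected by a straight tube of the mean local radius. Idempotent on
#' already-connected masks.
#'
#' @param mask coronary [label_mask()] (labels preserved; bridges take the
#'   label of the first endpoint's component).
#' @param vol the parent [voxel_volume()].
#' @param max_gap_mm maximum bridgeable gap.
#' @param max_angle_deg maximum direction mismatch.
#' @return the gap-connected [label_mask()].
#' @export
connect_gaps <- function(mask, vol, max_gap_mm = 5, max_angle_deg = 45) {
  data <- mask$data
  lab <- label_components(data > 0L, 26L)
  ncomp <- max(lab)
  if (ncomp < 2L) return(mask)
  info <- lapply(seq_len(ncomp), function(ci) {
    idx <- which(lab == ci, arr.ind = TRUE)
    mm <- index_to_mm(vol, idx)
    inf <- component_info(mm)
    inf$n <- nrow(idx)
    inf$radius <- if (inf$len > 1e-6) {
      sqrt(inf$n * voxel_mm3(vol) / (pi * inf$len))
    } else mean(vol$spacing[1:2])
    inf$label <- max(data[lab == ci])
    inf
  })
  changed <- FALSE
  for (a in seq_len(ncomp - 1L)) {
    for (b in (a + 1L):ncomp) {
      for (ea in 1:2) for (eb in 1:2) {
        pa <- info[[a]]$ends[ea, ]; pb <- info[[b]]$ends[eb, ]
        u <- pb - pa
        gap <- sqrt(sum(u^2))
        if (gap > max_gap_mm || gap < 1e-9) next
        # outward direction at each endpoint
        da <- info[[a]]$dir * (if (ea == 1) -1 else 1)
        db <- info[[b]]$dir * (if (eb == 1) -1 else 1)
        if (angle_deg(da, u) >= max_angle_deg) next
        if (angle_deg(db, -u) >= max_angle_deg) next
        r <- mean(c(info[[a]]$radius, info[[b]]$radius))
        grid <- list(dims = dim(data), spacing = vol$spacing, origin = vol$origin)
        alpha <- tube_occupancy(grid, rbind(pa, pb), r)
        data[alpha >= 0.5 & data == 0L] <- info[[a]]$label
        changed <- TRUE
      }
    }
  }
  out <- label_mask(data, vol, semantics = mask$semantics)
  if (changed) connect_gaps(out, vol, max_gap_mm, max_angle_deg) else out
}

#' Remove mislabeled coronary components
#'
#' Applies the three elimination cues in turn: components not reachable from
#' an aortic ostium (within 1.5 mm of the aorta surface) are removed;
#' reachable components whose median attenuation falls below half the
#' calibration factor (heart tissue) are removed; components whose
#' ostium-oriented principal direction runs anti-parallel (> 135 deg) to the
#' nearest retained coronary component are removed (vein surrogate rule).
#'
#' @param mask gap-connected coronary [label_mask()].
#' @param aorta aorta [label_mask()].
#' @param vol the parent [voxel_volume()] (original HU).
#' @param calib a [calibration_factor()].
#' @return cleaned [label_mask()] with all retained voxels labelled
#'   `coronary = 1`.
#' @export
remove_mislabeled <- function(mask, aorta, vol, calib) {
  data <- mask$data
  lab <- label_components(data > 0L, 26L)
  ncomp <- max(lab)
  if (ncomp == 0L) return(label_mask(array(0L, dim(data)), vol, c(coronary = 1L)))
  shell <- dilate_mask(aorta$data > 0L, iter = 3L)
  aorta_mm <- index_to_mm(vol, which(aorta$data > 0L, arr.ind = TRUE))
  keep <- logical(ncomp)
  info <- vector("list", ncomp)
  for (ci in seq_len(ncomp)) {
    sel <- lab == ci
    reachable <- any(shell[sel])
    med_hu <- stats::median(vol$data[sel])
    idx_mm <- index_to_mm(vol, which(sel, arr.ind = TRUE))
    inf <- component_info(idx_mm)
    # orient the principal direction away from the aorta
    d_ends <- apply(inf$ends, 1, function(p) {
      min(sqrt(rowSums(sweep(aorta_mm, 2, p)^2)))
    })
    inf$ostium_dir <- if (d_ends[1] <= d_ends[2]) inf$dir else -inf$dir
    inf$near <- inf$ends[which.min(d_ends), ]
    info[[ci]] <- inf
    keep[ci] <- reachable && med_hu >= 0.5 * calib$value
  }
  # anti-parallel rule against the nearest retained component
  primary <- which(keep)
  for (ci in primary) {
    others <- setdiff(primary, ci)
    if (!length(others)) next
    dmin <- vapply(others, function(cj) {
      sqrt(sum((info[[ci]]$center - info[[cj]]$center)^2))
    }, numeric(1))
    cj <- others[which.min(dmin)]
    if (angle_deg(info[[ci]]$ostium_dir, info[[cj]]$ostium_dir) > 135) {
      keep[ci] <- FALSE
    }
  }
  out <- array(0L, dim(data))
  out[lab %in% which(keep)] <- 1L
  label_mask(out, vol, semantics = c(coronary = 1L))
}

#' Extract centerlines by 3D thinning
#'
#' Thins the post-processed coronary mask to a one-voxel-wide curve
#' skeleton, prunes short spurs, splits the skeleton into segments at branch
#' points, orders each segment from the ostium (skeleton point nearest the
#' aorta) outward and applies a window-3 moving-average smoothing for
#' sub-voxel regularity.
#'
#' @param mask post-processed coronary [label_mask()].
#' @param vol the parent [voxel_volume()].
#' @param aorta optional aorta [label_mask()] used to root the tree at the
#'   ostia; without it each skeleton component is rooted at an arbitrary
#'   voxel.
#' @param spur_mm leaf branches of the skeleton shorter than this are
#'   pruned (thinning artefacts, not vessels).
#' @return object of class `coronary_tree`: list of segments, each with
#'   `points` (n x 3 mm), `label`, `component`; plus `ostia` (matrix of
#'   root points).
#' @export
skeletonize <- function(mask, vol, aorta = NULL, spur_mm = 2) {
  m <- mask$data > 0L
  if (!any(m)) {
    return(structure(list(segments = list(), ostia = matrix(numeric(0), 0, 3)),
                     class = "coronary_tree"))
  }
  mm_mask <- index_to_mm(vol, which(m, arr.ind = TRUE))
  skel <- thin_mask(m)
  idx <- which(skel, arr.ind = TRUE)
  n <- nrow(idx)
  mm <- index_to_mm(vol, idx)
  # adjacency among skeleton voxels (26-connectivity)
  key <- function(ix) ix[, 1] + (ix[, 2] - 1) * 1e4 + (ix[, 3] - 1) * 1e8
  lookup <- new.env(hash = TRUE)
  kk <- key(idx)
  for (i in seq_len(n)) assign(as.character(kk[i]), i, envir = lookup)
  steps <- neighbor_steps(26L)
  adj <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- sweep(steps, 2, as.numeric(idx[i, ]), `+`)
    ok <- nb[, 1] >= 1 & nb[, 2] >= 1 & nb[, 3] >= 1
    nb <- nb[ok, , drop = FALSE]
    hit <- vapply(key(nb), function(k) {
      v <- mget(as.character(k), envir = lookup, ifnotfound = list(NA_integer_))[[1]]
      v
    }, integer(1))
    adj[[i]] <- hit[!is.na(hit)]
  }
  comp <- integer(n)
  cc <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cc <- cc + 1L
    frontier <- s; comp[s] <- cc
    while (length(frontier)) {
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[comp[nxt] == 0L]
      comp[nxt] <- cc
      frontier <- nxt
    }
  }
  aorta_mm <- if (!is.null(aorta) && any(aorta$data > 0L)) {
    index_to_mm(vol, which(aorta$data > 0L, arr.ind = TRUE))
  } else NULL
  segments <- list()
  ostia <- NULL
  for (c_i in seq_len(cc)) {
    nodes <- which(comp == c_i)
    if (length(nodes) == 1L) next
    root <- if (!is.null(aorta_mm)) {
      dmin <- vapply(nodes, function(i) {
        min(sqrt(rowSums(sweep(aorta_mm, 2, mm[i, ])^2)))
      }, numeric(1))
      nodes[which.min(dmin)]
    } else nodes[1]
    ostia <- rbind(ostia, mm[root, ])
    # BFS spanning tree rooted at the ostium: triangle chords left by the
    # elbow-protected thinning drop out of the tree automatically, and the
    # redundant elbows become short leaf twigs that the spur pruning removes
    parent <- rep(NA_integer_, n)
    parent[root] <- 0L
    frontier <- root
    while (length(frontier)) {
      nxt <- integer(0)
      for (u in frontier) {
        vs <- adj[[u]][is.na(parent[adj[[u]]])]
        parent[vs] <- u
        nxt <- c(nxt, vs)
      }
      frontier <- nxt
    }
    in_tree <- rep(FALSE, n)
    in_tree[nodes] <- TRUE
    repeat {
      nchild <- tabulate(parent[in_tree & parent > 0L], nbins = n)
      pruned <- FALSE
      leaves <- which(in_tree & nchild == 0L)
      for (leaf in leaves) {
        if (leaf == root) next
        # walk up to the nearest junction (>= 2 children) or the root
        path <- leaf
        u <- leaf
        while (parent[u] > 0L && nchild[parent[u]] == 1L && parent[u] != root) {
          u <- parent[u]
          path <- c(path, u)
        }
        len <- if (length(path) > 1L) {
          sum(sqrt(rowSums(diff(mm[path, , drop = FALSE])^2)))
        } else 0
        if (len < spur_mm) {
          in_tree[path] <- FALSE
          pruned <- TRUE
        }
      }
      if (!pruned) break
    }
    if (sum(in_tree[nodes]) < 2L) next
    # decompose the pruned tree into maximal chains between critical nodes
    nchild <- tabulate(parent[in_tree & parent > 0L], nbins = n)
    is_crit <- function(u) u == root || nchild[u] >= 2L
    kids <- vector("list", n)
    for (u in which(in_tree)) {
      p <- parent[u]
      if (p > 0L && in_tree[p]) kids[[p]] <- c(kids[[p]], u)
    }
    queue <- root
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (child in kids[[u]]) {
        path <- c(u, child)
        v <- child
        while (!is_crit(v) && length(kids[[v]]) == 1L) {
          v <- kids[[v]]
          path <- c(path, v)
        }
        pts <- mm[path, , drop = FALSE]
        if (nrow(pts) >= 2L) {
          pts <- smooth_polyline(recenter_polyline(smooth_polyline(pts), mm_mask))
          segments[[length(segments) + 1L]] <- list(
            points = pts, label = "unassigned",
            component = c_i, ostium = mm[root, ]
          )
        }
        if (length(kids[[v]])) queue <- c(queue, v)
      }
    }
  }
  structure(list(segments = segments,
                 ostia = if (is.null(ostia)) matrix(numeric(0), 0, 3) else ostia),
            class = "coronary_tree")
}

# Re-centre skeleton points on the local mask cross-section: the sequential
# direction sweep of the thinning can leave the digital skeleton up to a
# voxel off the true axis (an even-width tube has no centre voxel); moving
# each point to the centroid of the nearby mask voxels, in the plane
# perpendicular to the local tangent, restores sub-voxel accuracy.
recenter_polyline <- function(pts, mask_mm, radius = 3, axial = 1) {
  n <- nrow(pts)
  if (n < 2L || !nrow(mask_mm)) return(pts)
  out <- pts
  for (i in seq_len(n)) {
    a <- if (i == 1L) pts[2, ] - pts[1, ]
         else if (i == n) pts[n, ] - pts[n - 1, ]
         else pts[i + 1, ] - pts[i - 1, ]
    nl <- sqrt(sum(a^2))
    if (nl < 1e-9) next
    a <- a / nl
    d <- sweep(mask_mm, 2, pts[i, ])
    along <- as.numeric(d %*% a)
    perp <- d - outer(along, a)
    sel <- abs(along) <= axial & rowSums(perp^2) <= radius^2
    if (sum(sel) >= 3L) out[i, ] <- pts[i, ] + colMeans(perp[sel, , drop = FALSE])
  }
  out
}

# Window-3 moving average, endpoints kept.
smooth_polyline <- function(pts) {
  n <- nrow(pts)
  if (n < 3L) return(pts)
  sm <- pts
  sm[2:(n - 1), ] <- (pts[1:(n - 2), ] + pts[2:(n - 1), ] + pts[3:n, ]) / 3
  sm
}

#' @export
print.coronary_tree <- function(x, ...) {
  len <- sum(vapply(x$segments, function(s) {
    sum(sqrt(rowSums(diff(s$points)^2)))
  }, numeric(1)))
  cat(sprintf("<coronary_tree> %d segments, %d ostia, total length %.1f mm\n",
              length(x$segments), nrow(x$ostia), len))
  invisible(x)
}

# Total centerline length in mm.
tree_length <- function(tree) {
  sum(vapply(tree$segments, function(s) sum(sqrt(rowSums(diff(s$points)^2))),
             numeric(1)))
}

#' Label tree segments as LCA or RCA
#'
#' Each connected component is labelled by the azimuth of its ostium around
#' the aorta centre: the left/posterior sector (135..225 deg) maps to LCA,
#' the right/anterior sector (225..315 deg) to RCA. An ostium within 10 deg
#' of a sector boundary is labelled from supplied metadata when available
#' and flagged `unassigned` otherwise.
#'
#' @param tree a [coronary_tree()] from [skeletonize()].
#' @param aorta aorta [label_mask()] (supplies the aorta centre).
#' @param metadata optional named character vector mapping component index
#'   to a vessel label, used for boundary-ambiguous ostia.
#' @return the tree with segment labels filled in.
#' @export
assign_vessel_labels <- function(tree, aorta, metadata = NULL) {
  if (!length(tree$segments)) return(tree)
  ctr <- attr(aorta, "center_mm")
  if (is.null(ctr)) {
    idx <- which(aorta$data > 0L, arr.ind = TRUE)
    mm <- sweep(sweep(idx[, 1:2, drop = FALSE] - 1, 2, aorta$spacing[1:2], `*`),
                2, aorta$origin[1:2], `+`)
    ctr <- colMeans(mm)
  }
  comp_label <- list()
  for (i in seq_along(tree$segments)) {
    s <- tree$segments[[i]]
    ci <- as.character(s$component)
    if (is.null(comp_label[[ci]])) {
      az <- (atan2(s$ostium[2] - ctr[2], s$ostium[1] - ctr[1]) * 180 / pi) %% 360
      near_boundary <- any(abs(((az - c(135, 225, 315)) + 180) %% 360 - 180) <= 10)
      lab <- if (near_boundary) {
        if (!is.null(metadata) && !is.null(metadata[[ci]])) metadata[[ci]] else "unassigned"
      } else if (az > 135 && az < 225) "LCA"
        else if (az > 225 && az < 315) "RCA"
        else "unassigned"
      comp_label[[ci]] <- lab
    }
    tree$segments[[i]]$label <- comp_label[[ci]]
  }
  tree
}

#' Sample cross-sections along the centerlines
#'
#' One cross-section every `step_mm` along every segment: the local tangent
#' (central differences on the smoothed centerline) defines the sampling
#' plane, in-plane HU values are sampled on a disc by trilinear
#' interpolation, and the centerline attenuation is the trilinear value at
#' the centre point. A section is flagged unreliable when the centerline
#' attenuation exceeds 1.3 x the calibration factor (calcium suspected on
#' the centerline) or the tangent is degenerate.
#'
#' @param tree a labelled [coronary_tree()].
#' @param vol the original (unremapped) [voxel_volume()].
#' @param calib a [calibration_factor()].
#' @param step_mm spacing of sections along the centerline.
#' @param disc_radius_mm radius of the sampled disc.
#' @param sample_spacing_mm in-plane sample spacing on the disc.
#' @param reliability_multiplier centerline attenuation above this multiple
#'   of the calibration factor flags the section unreliable.
#' @param reliability_floor_frac centerline attenuation below this fraction
#'   of the calibration factor also flags the section unreliable (the
#'   centerline has strayed out of the contrast-filled lumen, so its
#'   attenuation is not an accurate lumen estimate either).
#' @return list of `cross_section` objects with fields `center`, `normal`,
#'   `offsets`, `hu`, `center_hu`, `reliable`, `label`.
#' @export
cross_sections <- function(tree, vol, calib, step_mm = 0.5,
                           disc_radius_mm = 3.5, sample_spacing_mm = 0.3,
                           reliability_multiplier = 1.3,
                           reliability_floor_frac = 0.85) {
  if (!length(tree$segments)) return(list())
  g <- seq(-disc_radius_mm, disc_radius_mm, by = sample_spacing_mm)
  disc <- as.matrix(expand.grid(a = g, b = g))
  disc <- disc[rowSums(disc^2) <= disc_radius_mm^2, , drop = FALSE]
  out <- list()
  for (seg in tree$segments) {
    P <- seg$points
    arc <- c(0, cumsum(sqrt(rowSums(diff(P)^2))))
    L <- arc[length(arc)]
    if (L < 1e-6) next
    t_s <- seq(0, L, by = step_mm)
    if (t_s[length(t_s)] < L - 1e-9) t_s <- c(t_s, L)
    C <- sapply(1:3, function(j) stats::approx(arc, P[, j], xout = t_s)$y)
    if (is.null(dim(C))) C <- matrix(C, nrow = 1)
    nT <- nrow(C)
    tang <- matrix(0, nT, 3)
    if (nT >= 2L) {
      tang[1, ] <- C[2, ] - C[1, ]
      tang[nT, ] <- C[nT, ] - C[nT - 1, ]
      if (nT > 2L) tang[2:(nT - 1), ] <- C[3:nT, ] - C[1:(nT - 2), ]
    }
    center_hu <- trilinear_sample(vol, C, outside = NA_real_)
    for (i in seq_len(nT)) {
      tv <- tang[i, ]
      nrm <- sqrt(sum(tv^2))
      degenerate <- nrm < 1e-9
      tv <- if (degenerate) c(0, 0, 1) else tv / nrm
      # orthonormal in-plane basis
      ref <- if (abs(tv[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      u <- ref - sum(ref * tv) * tv
      u <- u / sqrt(sum(u^2))
      w <- c(tv[2] * u[3] - tv[3] * u[2],
             tv[3] * u[1] - tv[1] * u[3],
             tv[1] * u[2] - tv[2] * u[1])
      pts <- cbind(C[i, 1] + disc[, 1] * u[1] + disc[, 2] * w[1],
                   C[i, 2] + disc[, 1] * u[2] + disc[, 2] * w[2],
                   C[i, 3] + disc[, 1] * u[3] + disc[, 2] * w[3])
      hu <- trilinear_sample(vol, pts, outside = NA_real_)
      chu <- center_hu[i]
      reliable <- !degenerate && is.finite(chu) &&
        chu <= reliability_multiplier * calib$value &&
        chu >= reliability_floor_frac * calib$value
      out[[length(out) + 1L]] <- structure(list(
        center = C[i, ], normal = tv, offsets = disc, hu = hu,
        center_hu = chu, reliable = reliable, label = seg$label
      ), class = "cross_section")
    }
  }
  out
}
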