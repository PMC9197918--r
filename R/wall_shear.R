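#' Unit inward vertex normals of a lumen surface
#'
#' Per-vertex normals are the area-weighted average of incident face
#' normals, normalised to unit length.  Face windings are first made
#' consistent by propagating orientation across shared edges (so the input
#' winding, which iso-surfacing does not guarantee, is irrelevant); each
#' connected component is then flipped, if needed, so that the normal at
#' its vertex nearest `interior_point` points toward that point — the
#' inward convention WSS evaluation expects.
#'
#' @param surface a [tri_surface]; each edge may be shared by at most two
#'   faces ("manifold-like").
#' @param interior_point length-3 numeric, a point inside the lumen, m.
#' @return the [tri_surface] with `normals` set and
#'   `orientation = "inward"`.
#' @export
compute_vertex_normals <- function(surface, interior_point) {
  v <- surface$vertices
  f <- surface$faces
  nf <- nrow(f)
  if (nf == 0) stop("surface has no faces")
  interior_point <- as.numeric(interior_point)

  # --- consistent winding via BFS over the edge-face graph ---
  ea <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])  # directed edges, face-major
  lo <- pmin(ea[, 1], ea[, 2])
  hi <- pmax(ea[, 1], ea[, 2])
  key <- (as.numeric(lo) - 1) * nrow(v) + hi
  eid <- match(key, unique(key))
  fid <- rep(seq_len(nf), times = 3)
  fwd <- ea[, 1] == lo  # edge traversed lo -> hi in this face?
  ord <- order(eid)
  cnt <- tabulate(eid)
  if (any(cnt > 2))
    stop("surface is not manifold-like: an edge is shared by > 2 faces")
  # pair up faces across shared edges
  shared <- which(cnt == 2)
  pos <- ord[cumsum(cnt)[shared]]       # second occurrence
  pos1 <- ord[cumsum(cnt)[shared] - 1]  # first occurrence
  fa <- fid[pos1]; fb <- fid[pos]
  consistent <- fwd[pos1] != fwd[pos]   # opposite traversal = same winding
  adj <- vector("list", nf)
  for (i in seq_along(fa)) {
    adj[[fa[i]]] <- c(adj[[fa[i]]], if (consistent[i]) fb[i] else -fb[i])
    adj[[fb[i]]] <- c(adj[[fb[i]]], if (consistent[i]) fa[i] else -fa[i])
  }
  flip <- rep(NA, nf)       # TRUE = reverse this face's winding
  comp <- rep(NA_integer_, nf)
  ncomp <- 0L
  for (start in seq_len(nf)) {
    if (!is.na(flip[start])) next
    ncomp <- ncomp + 1L
    flip[start] <- FALSE
    comp[start] <- ncomp
    queue <- start
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      for (nb in adj[[cur]]) {
        tgt <- abs(nb)
        want <- if (nb > 0) flip[cur] else !flip[cur]
        if (is.na(flip[tgt])) {
          flip[tgt] <- want
          comp[tgt] <- ncomp
          queue <- c(queue, tgt)
        } else if (flip[tgt] != want) {
          stop("surface is not orientable: winding conflict at face ", tgt)
        }
      }
    }
  }
  fn <- face_normals_raw(surface)  # |fn| = 2 * area, so area weighting is free
  fn[flip, ] <- -fn[flip, , drop = FALSE]

  # --- accumulate to vertices ---
  vid <- as.vector(f)
  acc <- rowsum(fn[rep(seq_len(nf), times = 3), , drop = FALSE], vid)
  normals <- matrix(0, nrow(v), 3)
  normals[as.integer(rownames(acc)), ] <- acc
  len <- sqrt(rowSums(normals^2))
  used <- tabulate(vid, nbins = nrow(v)) > 0
  degen <- used & len < 1e-300
  if (any(degen))
    stop("degenerate (zero-area) vertex star at vertex ids: ",
         paste(which(degen), collapse = ", "))
  normals[used, ] <- normals[used, , drop = FALSE] / len[used]

  # --- per-component inward flip driven by interior_point ---
  for (cmp in seq_len(ncomp)) {
    vids <- unique(as.vector(f[comp == cmp, , drop = FALSE]))
    d2 <- rowSums(sweep(v[vids, , drop = FALSE], 2, interior_point, "-")^2)
    near <- vids[which.min(d2)]
    toward <- interior_point - v[near, ]
    if (sum(normals[near, ] * toward) < 0)
      normals[vids, ] <- -normals[vids, , drop = FALSE]
  }
  tri_surface(v, f, normals = normals, orientation = "inward")
}

#' Map voxel gradient tensors onto surface vertices by IDW
#'
#' For every vertex, the `n_neighbors` nearest *valid* voxel centres within
#' `radius` contribute with weights \eqn{w_k = 1/d_k^{power}}; the mapped
#' tensor is the weighted componentwise average.  A voxel centre closer
#' than 1e-12 m short-circuits to that voxel's tensor.  Vertices with no
#' valid voxel in reach are flagged unmapped and excluded from all
#' downstream summaries.
#'
#' @param G a `gradient_field` from [gradient_tensor()].
#' @param surface a [tri_surface].
#' @param power IDW exponent, > 0 (default 2).
#' @param n_neighbors neighbourhood size, >= 1 (default 8).
#' @param radius search radius, m; default 3x the largest voxel pitch.
#' @return list with `tensors` (array `n_vertices` x 3 x 3, 1/s, `NA` rows
#'   where unmapped), `mapped` (logical), `n_unmapped`.
#' @export
map_gradients_to_surface <- function(G, surface, power = 2, n_neighbors = 8,
                                     radius = 3 * max(G$spacing)) {
  if (power <= 0) stop("power must be > 0")
  if (n_neighbors < 1) stop("n_neighbors must be >= 1")
  vv <- which(G$valid)
  if (!length(vv)) stop("gradient field has no valid voxel")
  d <- G$dims
  ijk <- arrayInd(vv, d)
  centers <- sweep(sweep(ijk - 1, 2, G$spacing, "*"), 2, G$origin, "+")
  tens <- matrix(NA_real_, length(vv), 9)
  cidx <- 0L
  for (b in 1:3) for (a in 1:3) {
    cidx <- cidx + 1L
    tens[, cidx] <- G$g[, , , a, b][vv]  # column-major (a,b) pairs
  }
  verts <- surface$vertices
  nvert <- nrow(verts)
  out <- matrix(NA_real_, nvert, 9)
  mapped <- rep(FALSE, nvert)
  c2 <- rowSums(centers^2)
  chunk <- max(1L, as.integer(2e6 / max(1, length(vv))))
  for (s in seq(1, nvert, by = chunk)) {
    e <- min(nvert, s + chunk - 1L)
    X <- verts[s:e, , drop = FALSE]
    # prefilter voxels near this chunk's bounding box
    bb_lo <- apply(X, 2, min) - radius
    bb_hi <- apply(X, 2, max) + radius
    cand <- which(centers[, 1] >= bb_lo[1] & centers[, 1] <= bb_hi[1] &
                  centers[, 2] >= bb_lo[2] & centers[, 2] <= bb_hi[2] &
                  centers[, 3] >= bb_lo[3] & centers[, 3] <= bb_hi[3])
    if (!length(cand)) next
    D2 <- outer(rowSums(X^2), rep(1, length(cand))) +
      outer(rep(1, nrow(X)), c2[cand]) - 2 * X %*% t(centers[cand, , drop = FALSE])
    D2[D2 < 0] <- 0
    for (r in seq_len(nrow(X))) {
      dr <- sqrt(D2[r, ])
      within <- which(dr <= radius)
      if (!length(within)) next
      k <- min(n_neighbors, length(within))
      sel <- within[order(dr[within])[seq_len(k)]]
      dk <- dr[sel]
      gi <- s + r - 1L
      if (dk[1] < 1e-12) {
        out[gi, ] <- tens[cand[sel[1]], ]
      } else {
        w <- 1 / dk^power
        out[gi, ] <- colSums(tens[cand[sel], , drop = FALSE] * w) / sum(w)
      }
      mapped[gi] <- TRUE
    }
  }
  tensors <- array(out, c(nvert, 3, 3))
  list(tensors = tensors, mapped = mapped, n_unmapped = sum(!mapped))
}

#' Wall shear stress vectors on the lumen surface
#'
#' Evaluates the full viscous traction \eqn{\tau = 2 \mu \dot\varepsilon
#' \cdot n} per vertex, with \eqn{\dot\varepsilon} the symmetric part of
#' the mapped velocity-gradient tensor and \eqn{n} the unit inward normal
#' — componentwise exactly the standard Newtonian expansion (no projection
#' onto the tangent plane).  Set `tangential = TRUE` to additionally get
#' the surface-parallel magnitude \eqn{\|\tau - (\tau\cdot n)n\|}.
#'
#' @param surface_gradients result of [map_gradients_to_surface()].
#' @param surface a [tri_surface] with inward normals.
#' @param mu dynamic viscosity, Pa s, > 0.
#' @param tangential also compute the tangential-component magnitude?
#' @return object of class `"surface_vector_field"`: list with `surface`,
#'   `tau` (n x 3, Pa), `magnitude` (Pa), `mapped`, and optionally
#'   `tangential`.
#' @export
wss_vectors <- function(surface_gradients, surface, mu, tangential = FALSE) {
  if (is.null(surface$normals))
    stop("surface has no normals; call compute_vertex_normals() first")
  if (!is.finite(mu) || mu <= 0) stop("mu must be > 0")
  tn <- surface_gradients$tensors
  n <- surface$normals
  S <- array(0, dim(tn))
  for (a in 1:3) for (b in 1:3)
    S[, a, b] <- (tn[, a, b] + tn[, b, a]) / 2
  tau <- matrix(NA_real_, nrow(n), 3)
  for (a in 1:3)
    tau[, a] <- 2 * mu * (S[, a, 1] * n[, 1] + S[, a, 2] * n[, 2] +
                          S[, a, 3] * n[, 3])
  mag <- sqrt(rowSums(tau^2))
  out <- list(surface = surface, tau = tau, magnitude = mag,
              mapped = surface_gradients$mapped)
  if (tangential) {
    tdotn <- rowSums(tau * n)
    tt <- tau - tdotn * n
    out$tangential <- sqrt(rowSums(tt^2))
  }
  structure(out, class = "surface_vector_field")
}

#' @export
print.surface_vector_field <- function(x, ...) {
  m <- x$magnitude[x$mapped]
  cat("surface_vector_field:", length(x$mapped), "vertices,",
      sum(x$mapped), "mapped\n")
  if (length(m))
    cat("  WSS magnitude [Pa]: mean", signif(mean(m), 4),
        " median", signif(stats::median(m), 4),
        " peak", signif(max(m), 4), "\n")
  invisible(x)
}

#' Normalize WSS by a parent-vessel reference
#'
#' Divides every vertex magnitude by the mean magnitude over a
#' parent-vessel vertex patch, the modality-independent way to compare WSS
#' maps whose absolute levels differ.
#'
#' @param field a `surface_vector_field`.
#' @param parent_patch integer vertex ids forming the parent-vessel patch.
#' @return list with `values` (per-vertex dimensionless WSS, `NA` where
#'   unmapped) and `reference` (the parent-vessel mean, Pa).
#' @export
normalize_wss <- function(field, parent_patch) {
  parent_patch <- as.integer(parent_patch)
  if (!length(parent_patch)) stop("parent_patch must be nonempty")
  pm <- field$magnitude[parent_patch]
  pm <- pm[field$mapped[parent_patch] & is.finite(pm)]
  if (!length(pm)) stop("no mapped vertex in parent_patch")
  reference <- mean(pm)
  if (reference <= 0) stop("degenerate parent-vessel reference (zero WSS)")
  list(values = field$magnitude / reference, reference = reference)
}

#' Scale WSS between in-vitro and in-vivo conditions
#'
#' Multiplies the stress by `mu_ratio * u_ratio * d_ratio` — the
#' dynamic-similarity conversion that maps phantom-measured WSS to the
#' vessel-scale equivalent.
#'
#' @param tau a numeric vector/array of stresses (Pa) or a
#'   `surface_vector_field`.
#' @param sim a [similarity_spec].
#' @return the input scaled; a `surface_vector_field` comes back with
#'   `tau`, `magnitude` (and `tangential`) scaled.
#' @export
scale_wss <- function(tau, sim) {
  stopifnot(inherits(sim, "similarity_spec"))
  fac <- sim$mu_ratio * sim$u_ratio * sim$d_ratio
  if (inherits(tau, "surface_vector_field")) {
    tau$tau <- tau$tau * fac
    tau$magnitude <- tau$magnitude * fac
    if (!is.null(tau$tangential)) tau$tangential <- tau$tangential * fac
    tau
  } else {
    tau * fac
  }
}

#' Summary statistics of a surface WSS field
#'
#' @param field a `surface_vector_field`.
#' @param area_weighted weight the mean by vertex Voronoi-ish area (one
#'   third of incident face areas)?  Default `FALSE`: plain unweighted
#'   vertex average.
#' @return object of class `"wss_summary"`: list with `mean`, `peak`,
#'   `median` (Pa), `n_vertices` (mapped count).
#' @export
summarize_wss <- function(field, area_weighted = FALSE) {
  ok <- field$mapped & is.finite(field$magnitude)
  if (!any(ok)) stop("no mapped vertices to summarise")
  m <- field$magnitude[ok]
  if (area_weighted) {
    fn <- face_normals_raw(field$surface)
    fa <- sqrt(rowSums(fn^2)) / 2
    w <- numeric(length(field$mapped))
    acc <- rowsum(rep(fa / 3, 3), as.vector(field$surface$faces))
    w[as.integer(rownames(acc))] <- acc
    wm <- sum(w[ok] * m) / sum(w[ok])
  } else {
    wm <- mean(m)
  }
  structure(list(mean = wm, peak = max(m), median = stats::median(m),
                 n_vertices = sum(ok)),
            class = "wss_summary")
}

#' @export
print.wss_summary <- function(x, ...) {
  cat(sprintf("WSS summary over %d vertices: mean %.4g Pa, median %.4g Pa, peak %.4g Pa\n",
              x$n_vertices, x$mean, x$median, x$peak))
  invisible(x)
}
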