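#' Segment candidate marker components
#'
#' Thresholds the volume at a fixed Hounsfield value and labels
#' 26-connected components of supra-threshold voxels, keeping those
#' whose voxel count lies in `[min_voxels, max_voxels]`.  The size gate
#' is the default defence against cortical bone, which also exceeds any
#' threshold that captures the markers but forms far larger components.
#'
#' @param volume a [voxel_volume()].
#' @param threshold segmentation threshold (HU).  Barium-loaded suture
#'   knots are bright (default 800 HU separates them from soft tissue
#'   and trabecular bone) but dimmer than metal.
#' @param min_voxels,max_voxels inclusive component-size gate.
#' @return A list of components, each an n x 3 matrix of 0-based voxel
#'   indices; empty list when nothing passes.
#' @export
segment_markers <- function(volume, threshold = 800, min_voxels = 3L,
                            max_voxels = 500L) {
  if (!is.finite(threshold))
    mm_validation_error("'threshold' must be finite")
  if (min_voxels < 1L || min_voxels > max_voxels)
    mm_validation_error("need 0 < min_voxels <= max_voxels")
  idx <- which(volume$data >= threshold)
  if (length(idx) == 0L) return(list())
  d <- vol_dims(volume)
  coords <- arrayInd(idx, d)
  n <- length(idx)

  # 13 of the 26 neighbour offsets (half-neighbourhood; the graph is
  # undirected so each pair is found once)
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & offs[, 2] > 0) |
               (offs[, 3] == 0 & offs[, 2] == 0 & offs[, 1] > 0), ,
               drop = FALSE]

  pos_of <- function(cm) {
    ok <- cm[, 1] >= 1 & cm[, 1] <= d[1] & cm[, 2] >= 1 & cm[, 2] <= d[2] &
          cm[, 3] >= 1 & cm[, 3] <= d[3]
    lin <- rep(NA_real_, nrow(cm))
    lin[ok] <- (cm[ok, 3] - 1) * (d[1] * d[2]) + (cm[ok, 2] - 1) * d[1] + cm[ok, 1]
    match(lin, idx)
  }
  edges <- vector("list", nrow(offs))
  for (o in seq_len(nrow(offs))) {
    nb <- pos_of(sweep(coords, 2, -offs[o, ]))
    hit <- which(!is.na(nb))
    if (length(hit)) edges[[o]] <- cbind(hit, nb[hit])
  }
  edges <- do.call(rbind, edges)
  memb <- if (is.null(edges)) {
    seq_len(n)
  } else {
    g <- igraph::make_undirected_graph(as.vector(t(edges)), n = n)
    igraph::components(g)$membership
  }
  comps <- split(seq_len(n), memb)
  sizes <- lengths(comps)
  comps <- comps[sizes >= min_voxels & sizes <= max_voxels]
  lapply(unname(comps), function(i) {
    m <- coords[i, , drop = FALSE] - 1L    # 0-based, matching the affine
    colnames(m) <- c("i", "j", "k")
    m
  })
}

#' Volumetric centroid of a marker component
#'
#' The marker position is the centroid of its member voxel centres in
#' world millimetres.  The default is the unweighted (volumetric)
#' centroid; intensity weighting is available as an option.
#'
#' @param volume a [voxel_volume()].
#' @param component n x 3 matrix of 0-based voxel indices (as returned
#'   by [segment_markers()]).
#' @param weighting `"uniform"` or `"intensity"`.
#' @return Length-3 world point (mm).
#' @export
fit_centroid <- function(volume, component,
                         weighting = c("uniform", "intensity")) {
  weighting <- match.arg(weighting)
  if (is.null(dim(component))) component <- matrix(component, nrow = 1L)
  if (nrow(component) == 0L)
    mm_validation_error("component is empty")
  w <- voxel_to_world(volume, component)
  if (weighting == "uniform") {
    colMeans(w)
  } else {
    ints <- volume$data[component + 1L]
    if (sum(ints) <= 0)
      mm_validation_error("non-positive total intensity; cannot intensity-weight")
    colSums(w * ints) / sum(ints)
  }
}

component_stats <- function(volume, component, weighting = "uniform") {
  ctr <- fit_centroid(volume, component, weighting)
  w <- voxel_to_world(volume, component)
  list(centroid = ctr,
       voxel_count = nrow(component),
       mean_intensity = mean(volume$data[component + 1L]),
       bounding_radius = sqrt(max(rowSums(sweep(w, 2, ctr)^2))))
}

#' Assign marker labels to segmented components
#'
#' Each analyst-provided seed is matched to the component whose centroid
#' is nearest, greedily by ascending distance (ties broken
#' lexicographically by marker label), one component per label.  Matches
#' beyond `distance_cap` are rejected; seeds left unmatched while a
#' competing seed claimed their only candidate raise an ambiguity error,
#' otherwise they are reported with a warning.
#'
#' @param volume a [voxel_volume()].
#' @param components list of components from [segment_markers()].
#' @param seeds named n x 3 matrix (or data frame with `label`, `x`,
#'   `y`, `z`) of approximate marker world positions (mm).
#' @param distance_cap maximum seed-to-centroid distance (mm).  Marker
#'   knots are ~1 mm; the default 10 mm tolerates seed imprecision while
#'   preventing cross-marker capture.
#' @param weighting centroid weighting, see [fit_centroid()].
#' @return A data frame of marker observations: `label`, `x`, `y`, `z`
#'   (centroid, mm), `voxel_count`, `mean_intensity`, `bounding_radius`;
#'   attribute `unmatched` lists labels without a component.
#' @export
assign_labels <- function(volume, components, seeds, distance_cap = 10,
                          weighting = c("uniform", "intensity")) {
  weighting <- match.arg(weighting)
  if (is.data.frame(seeds)) {
    sm <- as.matrix(seeds[, c("x", "y", "z")])
    rownames(sm) <- seeds$label
    seeds <- sm
  }
  seeds <- as_point_matrix(seeds, "seeds")
  if (is.null(rownames(seeds)))
    mm_validation_error("'seeds' must carry marker labels as row names")
  labels <- rownames(seeds)
  stats <- lapply(components, component_stats, volume = volume,
                  weighting = weighting)
  obs_empty <- data.frame(label = character(0), x = numeric(0), y = numeric(0),
                          z = numeric(0), voxel_count = integer(0),
                          mean_intensity = numeric(0),
                          bounding_radius = numeric(0))
  if (length(stats) == 0L) {
    if (length(labels))
      warning(sprintf("no components to match seed(s) %s",
                      paste(labels, collapse = ", ")))
    attr(obs_empty, "unmatched") <- labels
    return(obs_empty)
  }
  cent <- do.call(rbind, lapply(stats, `[[`, "centroid"))
  dmat <- outer(seq_along(labels), seq_along(stats),
                Vectorize(function(s, k) marker_length(seeds[s, ], cent[k, ])))
  cand <- which(dmat <= distance_cap, arr.ind = TRUE)
  ord <- order(dmat[cand], labels[cand[, 1]])
  cand <- cand[ord, , drop = FALSE]
  seed_taken <- rep(FALSE, length(labels))
  comp_taken <- rep(NA_integer_, length(stats))   # which seed took it
  assignment <- rep(NA_integer_, length(labels))
  for (r in seq_len(nrow(cand))) {
    s <- cand[r, 1]; k <- cand[r, 2]
    if (seed_taken[s] || !is.na(comp_taken[k])) next
    assignment[s] <- k
    seed_taken[s] <- TRUE
    comp_taken[k] <- s
  }
  unmatched <- which(is.na(assignment))
  for (s in unmatched) {
    in_cap <- which(dmat[s, ] <= distance_cap)
    if (length(in_cap) > 0L && all(!is.na(comp_taken[in_cap]))) {
      rivals <- unique(labels[comp_taken[in_cap]])
      mm_ambiguity_error(sprintf(
        "markers %s and %s claim the same component(s); refine the seeds",
        paste(rivals, collapse = ", "), labels[s]))
    }
  }
  if (length(unmatched) > 0L)
    warning(sprintf("no component within %g mm of seed(s) %s",
                    distance_cap, paste(labels[unmatched], collapse = ", ")))
  keep <- which(!is.na(assignment))
  obs <- do.call(rbind, lapply(keep, function(s) {
    st <- stats[[assignment[s]]]
    data.frame(label = labels[s], x = st$centroid[1], y = st$centroid[2],
               z = st$centroid[3], voxel_count = st$voxel_count,
               mean_intensity = st$mean_intensity,
               bounding_radius = st$bounding_radius)
  }))
  if (is.null(obs)) obs <- obs_empty
  rownames(obs) <- NULL
  attr(obs, "unmatched") <- labels[unmatched]
  obs
}

#' Localize labelled markers in one volume
#'
#' Convenience wrapper: [segment_markers()] then [assign_labels()].
#'
#' @inheritParams segment_markers
#' @inheritParams assign_labels
#' @return See [assign_labels()].
#' @export
localize_markers <- function(volume, seeds, threshold = 800,
                             min_voxels = 3L, max_voxels = 500L,
                             distance_cap = 10,
                             weighting = c("uniform", "intensity")) {
  comps <- segment_markers(volume, threshold, min_voxels, max_voxels)
  assign_labels(volume, comps, seeds, distance_cap, match.arg(weighting))
}

# named position matrix from an observation data frame
observation_matrix <- function(obs) {
  m <- as.matrix(obs[, c("x", "y", "z")])
  rownames(m) <- obs$label
  m
}
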