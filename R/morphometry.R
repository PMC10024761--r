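# Dendritic morphometry: rooted 3D tree container, Sholl intersection
# profiles, tree metrics, density normalisations and SWC input/output.

#' Construct a neuron morphology
#'
#' A rooted tree of 3D points: exactly one soma root (parent `-1`),
#' parents preceding children, each node tagged `soma`, `apical` or
#' `basal` (dendrites exiting the top of the soma are conventionally
#' apical, the rest basal; the tag is an input property, not inferred
#' from geometry). Optional spines are positions along segments.
#'
#' @param nodes Data frame with columns `id`, `parent` (`-1` for the
#'   root), `x`, `y`, `z` (um), `compartment`.
#' @param spines Optional data frame with columns `node` (child node id
#'   of the bearing segment) and `pos` (fractional position along it).
#' @return An object of class `"neuron_morphology"`.
#' @export
neuron_morphology <- function(nodes, spines = NULL) {
  req <- c("id", "parent", "x", "y", "z", "compartment")
  if (!all(req %in% names(nodes))) {
    stop_config("nodes", paste("must have columns", paste(req, collapse = ", ")))
  }
  roots <- which(nodes$parent == -1)
  if (length(roots) != 1L) {
    stop("structure error: tree must have exactly one soma root",
         call. = FALSE)
  }
  idx <- match(nodes$parent, nodes$id)
  nonroot <- nodes$parent != -1
  if (any(is.na(idx[nonroot]))) {
    stop("structure error: parent ids must exist", call. = FALSE)
  }
  if (any(idx[nonroot] >= seq_len(nrow(nodes))[nonroot])) {
    stop("structure error: parents must precede children (no cycles)",
         call. = FALSE)
  }
  structure(list(nodes = nodes, spines = spines),
            class = "neuron_morphology")
}

#' Parameters for the random morphology generator
#'
#' @param n_branches Number of dendritic segments to grow (> 0).
#' @param branch_length_um Mean segment length (um).
#' @param branch_angle_spread Angular spread (radians) of daughter
#'   directions around the parent direction.
#' @param apical_fraction Fraction of segments grown on the apical
#'   subtree (exiting the top of the soma); the rest are basal.
#' @param spine_density_per_um Linear spine density (spines/um).
#' @param seed Integer seed.
#' @return An object of class `"morph_sim_params"`.
#' @export
morph_sim_params <- function(n_branches = 40,
                             branch_length_um = 30,
                             branch_angle_spread = 0.6,
                             apical_fraction = 0.6,
                             spine_density_per_um = 1.2,
                             seed = 1L) {
  if (n_branches < 1) {
    stop("empty-tree error: n_branches must be at least 1", call. = FALSE)
  }
  check_positive(branch_length_um, "branch_length_um")
  if (apical_fraction < 0 || apical_fraction > 1) {
    stop_config("apical_fraction", "must lie in [0, 1]")
  }
  if (spine_density_per_um < 0) {
    stop_config("spine_density_per_um", "must be non-negative")
  }
  structure(list(n_branches = n_branches,
                 branch_length_um = branch_length_um,
                 branch_angle_spread = branch_angle_spread,
                 apical_fraction = apical_fraction,
                 spine_density_per_um = spine_density_per_um,
                 seed = seed), class = "morph_sim_params")
}

# random unit vector within `spread` radians of direction v
perturb_direction <- function(v, spread) {
  u <- v + stats::rnorm(3, 0, spread)
  u / sqrt(sum(u^2))
}

#' Generate a random dendritic tree
#'
#' Grows a rooted 3D tree from a point soma at the origin: an apical
#' subtree starting upward (+z) and a basal subtree starting downward,
#' extended by randomly choosing a tip to elongate or bifurcate. Spines
#' are placed uniformly along segments at the configured linear density
#' (count = `round(density x total length)` per compartment).
#'
#' @param params A [morph_sim_params()] object.
#' @return A `neuron_morphology`.
#' @export
generate_morphology <- function(params) {
  stopifnot(inherits(params, "morph_sim_params"))
  p <- params
  local_seed(p$seed, {
    n_apical <- round(p$n_branches * p$apical_fraction)
    n_basal <- p$n_branches - n_apical
    nodes <- data.frame(id = 1L, parent = -1L, x = 0, y = 0, z = 0,
                        compartment = "soma", stringsAsFactors = FALSE)
    grow <- function(nodes, n_seg, compartment, first_dir) {
      if (n_seg < 1L) return(nodes)
      tips <- list()  # each: list(node_id, dir)
      root_id <- 1L
      for (k in seq_len(n_seg)) {
        if (length(tips) == 0L) {
          from <- root_id
          dir <- first_dir
        } else if (stats::runif(1) < 0.35 && length(tips) >= 1L) {
          # bifurcate: branch off a random existing tip's parent node
          t_ <- tips[[sample.int(length(tips), 1L)]]
          from <- t_$node
          dir <- perturb_direction(t_$dir, p$branch_angle_spread * 1.5)
        } else {
          ti <- sample.int(length(tips), 1L)
          t_ <- tips[[ti]]
          from <- t_$node
          dir <- perturb_direction(t_$dir, p$branch_angle_spread)
          tips[[ti]] <- NULL
        }
        len <- p$branch_length_um * stats::runif(1, 0.8, 1.2)
        origin <- as.numeric(nodes[match(from, nodes$id), c("x", "y", "z")])
        xyz <- origin + dir * len
        new_id <- max(nodes$id) + 1L
        nodes <- rbind(nodes, data.frame(
          id = new_id, parent = from, x = xyz[1], y = xyz[2], z = xyz[3],
          compartment = compartment, stringsAsFactors = FALSE))
        tips[[length(tips) + 1L]] <- list(node = new_id, dir = dir)
      }
      nodes
    }
    nodes <- grow(nodes, n_apical, "apical", c(0, 0, 1))
    nodes <- grow(nodes, n_basal, "basal", c(0, 0, -1))
    m <- neuron_morphology(nodes)
    total_len <- tree_metrics(m, "all")$total_length_um
    n_spines <- round(p$spine_density_per_um * total_len)
    spines <- NULL
    if (n_spines > 0) {
      seg_child <- nodes$id[nodes$parent != -1]
      seg_len <- segment_lengths(m)$length
      pick <- sample(seq_along(seg_child), n_spines, replace = TRUE,
                     prob = seg_len)
      spines <- data.frame(node = seg_child[pick],
                           pos = stats::runif(n_spines))
    }
    neuron_morphology(nodes, spines)
  })
}

# per-segment endpoints and Euclidean lengths (one row per non-root node)
segment_lengths <- function(m) {
  nodes <- m$nodes
  child <- nodes[nodes$parent != -1, , drop = FALSE]
  par <- nodes[match(child$parent, nodes$id), , drop = FALSE]
  data.frame(
    node = child$id,
    compartment = child$compartment,
    x0 = par$x, y0 = par$y, z0 = par$z,
    x1 = child$x, y1 = child$y, z1 = child$z,
    length = sqrt((child$x - par$x)^2 + (child$y - par$y)^2 +
                    (child$z - par$z)^2)
  )
}

filter_compartment <- function(segs, compartment) {
  if (identical(compartment, "all")) {
    segs[segs$compartment != "soma", , drop = FALSE]
  } else {
    segs[segs$compartment %in% compartment, , drop = FALSE]
  }
}

# number of intersections of one straight segment with the sphere of
# radius r centred at the origin: roots of |p0 + t (p1 - p0)|^2 = r^2
# within t in [0, 1]; a tangent (double root) counts once
segment_sphere_crossings <- function(p0, p1, r) {
  dvec <- p1 - p0
  a <- sum(dvec^2)
  b <- 2 * sum(p0 * dvec)
  cc <- sum(p0^2) - r^2
  if (a == 0) return(0L)
  disc <- b^2 - 4 * a * cc
  if (disc < 0) return(0L)
  sq <- sqrt(disc)
  roots <- unique(c((-b - sq) / (2 * a), (-b + sq) / (2 * a)))
  # half-open in t: a chain crossing exactly at a node is counted once
  # (by the downstream segment), and a terminal tip exactly at radius r
  # touches without crossing
  sum(roots >= 0 & roots < 1)
}

#' Sholl intersection profile
#'
#' Counts, for each radius (multiples of `step_um` from the soma), the
#' intersections of the tree's straight segments with the sphere of that
#' radius centred at the soma, restricted to a compartment class. A
#' segment tangent to a sphere counts once; a segment dipping through a
#' sphere twice counts twice.
#'
#' @param m A `neuron_morphology`.
#' @param step_um Radius step (default 10 um).
#' @param compartment `"apical"`, `"basal"`, or `"all"` (dendrites only).
#' @return A `sholl_profile` data frame: `radius_um`, `intersections`.
#' @export
sholl_profile <- function(m, step_um = 10, compartment = "all") {
  stopifnot(inherits(m, "neuron_morphology"))
  check_positive(step_um, "step_um")
  segs <- filter_compartment(segment_lengths(m), compartment)
  soma <- as.numeric(m$nodes[m$nodes$parent == -1, c("x", "y", "z")])
  max_r <- if (nrow(segs) == 0) 0 else
    max(sqrt((segs$x1 - soma[1])^2 + (segs$y1 - soma[2])^2 +
               (segs$z1 - soma[3])^2),
        sqrt((segs$x0 - soma[1])^2 + (segs$y0 - soma[2])^2 +
               (segs$z0 - soma[3])^2))
  radii <- seq(step_um, max(step_um, ceiling(max_r / step_um) * step_um),
               by = step_um)
  counts <- vapply(radii, function(r) {
    if (nrow(segs) == 0) return(0L)
    sum(vapply(seq_len(nrow(segs)), function(i) {
      segment_sphere_crossings(
        c(segs$x0[i], segs$y0[i], segs$z0[i]) - soma,
        c(segs$x1[i], segs$y1[i], segs$z1[i]) - soma, r)
    }, integer(1)))
  }, integer(1))
  out <- data.frame(radius_um = radii, intersections = counts)
  class(out) <- c("sholl_profile", "data.frame")
  out
}

#' Tree metrics: total length, branch points, terminals
#'
#' @param m A `neuron_morphology`.
#' @param compartment `"apical"`, `"basal"`, or `"all"`.
#' @return List with `total_length_um`, `n_branch_points` (non-root nodes
#'   with two or more children in the filtered tree), `n_terminals`
#'   (leaves), and `n_segments`.
#' @export
tree_metrics <- function(m, compartment = "all") {
  stopifnot(inherits(m, "neuron_morphology"))
  segs <- filter_compartment(segment_lengths(m), compartment)
  if (nrow(segs) == 0L) {
    return(list(total_length_um = 0, n_branch_points = 0L,
                n_terminals = 0L, n_segments = 0L))
  }
  child_ids <- segs$node
  parent_of <- m$nodes$parent[match(child_ids, m$nodes$id)]
  kids_per_node <- table(parent_of)
  root_id <- m$nodes$id[m$nodes$parent == -1]
  internal <- setdiff(names(kids_per_node), as.character(root_id))
  n_branch <- sum(kids_per_node[internal] >= 2)
  n_term <- sum(!child_ids %in% parent_of)
  list(total_length_um = sum(segs$length),
       n_branch_points = as.integer(n_branch),
       n_terminals = as.integer(n_term),
       n_segments = nrow(segs))
}

#' Linear, areal or segment density
#'
#' @param count Number of cells or spines (>= 0).
#' @param extent Positive extent: mm (linear), mm^2 (areal) or um
#'   (dendritic segment).
#' @param units Units string recorded on the result (e.g. `"cells/mm"`,
#'   `"spines/um"`).
#' @return A `density_record` list: `count`, `extent`, `density`, `units`.
#' @export
linear_density <- function(count, extent, units = "cells/mm") {
  if (count < 0) stop_config("count", "must be non-negative")
  if (!is.numeric(extent) || extent <= 0) {
    stop_config("extent", "must be positive")
  }
  structure(list(count = count, extent = extent,
                 density = count / extent, units = units),
            class = "density_record")
}

#' Mean of left/right hemisphere densities
#'
#' The left and right hippocampus are counted separately and their mean
#' density is used as a single observation.
#'
#' @param left,right `density_record`s with matching units.
#' @return A `density_record` with the mean density.
#' @export
bilateral_mean <- function(left, right) {
  stopifnot(inherits(left, "density_record"),
            inherits(right, "density_record"))
  if (!identical(left$units, right$units)) {
    stop("unit mismatch between left and right records", call. = FALSE)
  }
  structure(list(count = (left$count + right$count) / 2,
                 extent = (left$extent + right$extent) / 2,
                 density = (left$density + right$density) / 2,
                 units = left$units),
            class = "density_record")
}

#' Read a morphology from SWC
#'
#' Standard SWC columns (`id type x y z radius parent`); type 1 is soma,
#' 3 basal dendrite, 4 apical dendrite.
#'
#' @param path SWC file path.
#' @return A `neuron_morphology`.
#' @export
read_swc <- function(path) {
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("id", "type", "x", "y", "z",
                                         "radius", "parent"))
  comp <- c("1" = "soma", "3" = "basal", "4" = "apical")
  compartment <- comp[as.character(tab$type)]
  compartment[is.na(compartment)] <- "basal"
  neuron_morphology(data.frame(
    id = tab$id, parent = tab$parent, x = tab$x, y = tab$y, z = tab$z,
    compartment = compartment, stringsAsFactors = FALSE))
}

#' Write a morphology to SWC
#'
#' @param m A `neuron_morphology`.
#' @param path Output file path.
#' @param radius Radius written for every node (um).
#' @return `path`, invisibly.
#' @export
write_swc <- function(m, path, radius = 0.5) {
  type <- c(soma = 1L, basal = 3L, apical = 4L)[m$nodes$compartment]
  tab <- data.frame(id = m$nodes$id, type = type, x = m$nodes$x,
                    y = m$nodes$y, z = m$nodes$z, radius = radius,
                    parent = m$nodes$parent)
  utils::write.table(tab, path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
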