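# SPArc control-point restructuring: iteratively halve the angular sampling
# of a coarse arc, interleaving the energy layers of each parent control
# point between its children, then drop low-weight layers. This is the
# structural part of arc-plan generation; spot weights are taken as given
# (no dose re-optimization is performed between iterations).

#' Interleave a parent's energy layers between two child control points
#'
#' Layers are ranked by descending energy; odd ranks go to the first child
#' in rotation order, even ranks to the second. With a single child (the
#' terminal endpoint of a partial arc) all layers stay together.
#'
#' @param parent_layers List of `energy_layer` objects.
#' @param n_children 1 or 2.
#' @return A list of `n_children` layer lists.
#' @export
redistribute_layers <- function(parent_layers, n_children = 2L) {
  en <- vapply(parent_layers, function(l) l$energy_mev, numeric(1))
  ord <- order(-en)
  sorted <- parent_layers[ord]
  if (n_children == 1L) return(list(sorted))
  idx <- seq_along(sorted)
  list(sorted[idx %% 2L == 1L], sorted[idx %% 2L == 0L])
}

# internal representation: list of list(angle, layers)
arc_nodes <- function(plan) {
  lapply(plan$arc$control_points,
         function(cp) list(angle = cp$angle_deg, layers = cp$layers))
}

nodes_to_plan <- function(plan, nodes, drop_empty = TRUE) {
  if (drop_empty)
    nodes <- Filter(function(nd) length(nd$layers) > 0L, nodes)
  plan$arc$control_points <- lapply(nodes, function(nd)
    control_point(nd$angle, nd$layers))
  plan
}

is_full_arc <- function(plan, tol = 1e-6) {
  abs(abs(plan$arc$stop_deg - plan$arc$start_deg) - 360) < tol
}

# one halving: spacing s -> s/2. Full (cyclic) arcs double every node;
# partial arcs keep the terminal endpoint as a single-child chain so the
# refined grid retains both endpoints (n -> 2n - 1).
halve_nodes <- function(nodes, spacing, dir, full) {
  out <- list()
  n <- length(nodes)
  for (k in seq_len(n)) {
    nd <- nodes[[k]]
    last_partial <- !full && k == n
    kids <- redistribute_layers(nd$layers, if (last_partial) 1L else 2L)
    out[[length(out) + 1L]] <- list(angle = nd$angle, layers = kids[[1]])
    if (!last_partial)
      out[[length(out) + 1L]] <- list(angle = nd$angle + dir * spacing / 2,
                                      layers = kids[[2]])
  }
  out
}

# move surplus layers (slots holding > 1 layer, or any layer sitting in an
# excluded sector) into the nearest allowed empty grid slot.
cleanup_nodes <- function(nodes, allowed) {
  angles <- vapply(nodes, `[[`, numeric(1), "angle")
  free <- allowed & vapply(nodes, function(nd) length(nd$layers) == 0L, logical(1))
  for (k in seq_along(nodes)) {
    nl <- length(nodes[[k]]$layers)
    surplus <- if (!allowed[k]) seq_len(nl) else if (nl > 1L) 2:nl else integer(0)
    if (!length(surplus)) next
    moved <- logical(nl)
    for (j in surplus) {
      cand <- which(free)
      if (!length(cand)) break
      tgt <- cand[which.min(abs(angles[cand] - angles[k]))]
      nodes[[tgt]]$layers <- nodes[[k]]$layers[j]
      free[tgt] <- FALSE
      moved[j] <- TRUE
    }
    nodes[[k]]$layers <- nodes[[k]]$layers[!moved]
  }
  nodes
}

#' Refine a coarse arc to a target control-point spacing
#'
#' Starting from control points equally spaced at the coarse sampling
#' (20 degrees by default upstream), each halving inserts the sector
#' midpoints: a full arc of n points becomes 2n (the duplicate 360-degree
#' endpoint stays excluded), a partial arc of n points becomes 2n - 1
#' (both endpoints retained). [redistribute_layers()] is applied at every
#' halving; after the final halving, any control point still holding more
#' than one layer sheds the surplus to the nearest empty grid slot, layers
#' inside excluded sectors are relocated the same way, and empty control
#' points are deleted.
#'
#' @param plan A SPArc `proton_plan` with equally spaced control points.
#' @param target_spacing Target spacing in degrees; the ratio between the
#'   current and target spacing must be a power of two.
#' @return The refined `proton_plan`.
#' @export
split_control_points <- function(plan, target_spacing) {
  if (plan$modality != "sparc") stop_sparc("split requires a sparc plan")
  nodes <- arc_nodes(plan)
  dir <- plan$arc$direction
  full <- is_full_arc(plan)
  span <- abs(plan$arc$stop_deg - plan$arc$start_deg)
  n <- length(nodes)
  spacing <- span / if (full) n else (n - 1L)
  ratio <- spacing / target_spacing
  k <- round(log2(ratio))
  if (k < 0 || abs(ratio - 2^k) > 1e-9)
    stop_sparc("spacing ratio %.4g is not a power of two", ratio)
  for (i in seq_len(k)) {
    nodes <- halve_nodes(nodes, spacing, dir, full)
    spacing <- spacing / 2
  }
  allowed <- !vapply(nodes, function(nd) {
    any(vapply(plan$arc$excluded_sectors, function(sec)
      angle_in_sector(nd$angle, sec[1], sec[2]), logical(1)))
  }, logical(1))
  if (k > 0 || any(!allowed)) nodes <- cleanup_nodes(nodes, allowed)
  nodes_to_plan(plan, nodes, drop_empty = (k > 0 || any(!allowed)))
}

#' Remove low-weight energy layers, conserving total plan MU
#'
#' Drops every layer whose total MU falls below `theta` times the mean
#' layer MU, never removing the heaviest layer, then rescales all surviving
#' spot weights by a single global factor so the plan total MU is exactly
#' conserved. Control points (or fields) left empty are deleted.
#'
#' @param plan A `proton_plan` with at least one layer.
#' @param theta Threshold as a fraction of the mean layer MU (default 0.1).
#' @return The filtered `proton_plan`.
#' @export
filter_low_weight <- function(plan, theta = 0.1) {
  entries <- plan_layers(plan)
  if (!length(entries)) stop_sparc("plan has no layers")
  mus <- vapply(entries, function(e) layer_mu(e$layer), numeric(1))
  total <- sum(mus)
  cutoff <- theta * total / length(mus)
  keep <- mus >= cutoff
  keep[which.max(mus)] <- TRUE
  factor <- total / sum(mus[keep])

  keep_map <- split(keep, vapply(entries, `[[`, numeric(1), "unit"))
  prune <- function(layers, kept) {
    out <- list()
    for (j in seq_along(layers)) {
      if (!kept[j]) next
      l <- layers[[j]]
      l$spots[, "mu"] <- l$spots[, "mu"] * factor
      out[[length(out) + 1L]] <- l
    }
    out
  }
  if (plan$modality == "impt") {
    for (i in seq_along(plan$fields))
      plan$fields[[i]]$layers <-
        prune(plan$fields[[i]]$layers, keep_map[[as.character(i)]])
    plan$fields <- Filter(function(f) length(f$layers) > 0L, plan$fields)
  } else {
    cps <- plan$arc$control_points
    for (i in seq_along(cps))
      cps[[i]]$layers <- prune(cps[[i]]$layers, keep_map[[as.character(i)]])
    plan$arc$control_points <- Filter(function(cp) length(cp$layers) > 0L, cps)
  }
  plan
}

#' Restructure a coarse arc plan into a deliverable SPArc sequence
#'
#' Runs [split_control_points()] down to the target sampling and then
#' [filter_low_weight()] once, yielding a one-energy-per-control-point arc
#' with total MU conserved.
#'
#' @param plan A coarse SPArc `proton_plan` (default 20-degree sampling).
#' @param target_spacing Final control-point spacing, degrees (default 2.5).
#' @param filter_theta Low-weight threshold fraction (default 0.1).
#' @return A refined, filtered SPArc `proton_plan`.
#' @export
sparc_restructure <- function(plan, target_spacing = 2.5, filter_theta = 0.1) {
  filter_low_weight(split_control_points(plan, target_spacing), filter_theta)
}
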