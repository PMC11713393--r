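# Plan file I/O: a bespoke JSON schema with a canonical serialization
# (alphabetically sorted keys, fixed 6-decimal float format) so that
# parse/write round-trips are byte-stable and fixtures are diffable.

json_escape <- function(s) {
  s <- gsub("\\\\", "\\\\\\\\", s)
  s <- gsub('"', '\\\\"', s)
  s
}

canon_spots <- function(spots) {
  rows <- apply(spots, 1L, function(r)
    paste0("[", paste(canonical_num(r), collapse = ","), "]"))
  paste0("[", paste(rows, collapse = ","), "]")
}

canon_layer <- function(layer) {
  paste0('{"energy_mev":', canonical_num(layer$energy_mev),
         ',"spots":', canon_spots(layer$spots), "}")
}

#' Write a plan to its canonical JSON form
#'
#' Keys are emitted in a fixed alphabetical order and every physical
#' quantity is formatted with exactly six decimals, so
#' `write_plan(parse_plan(f))` is byte-identical to a canonical `f` and
#' repeated round-trips are the identity.
#'
#' @param plan A valid `proton_plan`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_plan <- function(plan, path) {
  viol <- validate_plan(plan)
  if (length(viol)) stop_sparc("cannot write invalid plan: %s", viol[1])
  parts <- character(0)
  if (plan$modality == "sparc") {
    arc <- plan$arc
    cps <- vapply(arc$control_points, function(cp)
      paste0('{"angle_deg":', canonical_num(cp$angle_deg),
             ',"layer":', canon_layer(cp$layers[[1]]), "}"), character(1))
    sec <- vapply(arc$excluded_sectors, function(s)
      paste0("[", canonical_num(s[1]), ",", canonical_num(s[2]), "]"),
      character(1))
    start <- arc$start_deg %||% arc$control_points[[1]]$angle_deg
    stop_ <- arc$stop_deg %||%
      arc$control_points[[length(arc$control_points)]]$angle_deg
    parts <- c(parts, paste0(
      '"arc":{"control_points":[', paste(cps, collapse = ","),
      '],"direction":', as.integer(arc$direction),
      ',"excluded_sectors":[', paste(sec, collapse = ","),
      '],"start_deg":', canonical_num(start),
      ',"stop_deg":', canonical_num(stop_), "}"))
  } else {
    fls <- vapply(plan$fields, function(fl)
      paste0('{"couch_deg":', canonical_num(fl$couch_deg),
             ',"gantry_deg":', canonical_num(fl$gantry_deg),
             ',"layers":[',
             paste(vapply(fl$layers, canon_layer, character(1)), collapse = ","),
             "]}"), character(1))
    parts <- c(parts, paste0('"fields":[', paste(fls, collapse = ","), "]"))
  }
  txt <- paste0("{", paste(c(parts,
    paste0('"fractions":', as.integer(plan$fractions)),
    paste0('"modality":"', json_escape(plan$modality), '"'),
    paste0('"prescription_gy":', canonical_num(plan$prescription_gy))),
    collapse = ","), "}")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(txt, "\n")), con)
  invisible(path)
}

need <- function(node, key, where) {
  if (is.null(node[[key]]))
    stop_sparc("plan schema error at %s: missing \"%s\"", where, key)
  node[[key]]
}

parse_layer <- function(node, where) {
  en <- need(node, "energy_mev", where)
  sp <- need(node, "spots", where)
  if (!length(sp)) stop_sparc("plan schema error at %s.spots: empty", where)
  mat <- do.call(rbind, lapply(seq_along(sp), function(j) {
    row <- unlist(sp[[j]])
    if (length(row) != 3L || !is.numeric(row))
      stop_sparc("plan schema error at %s.spots[%d]: expected [x, y, mu]",
                 where, j)
    row
  }))
  energy_layer(en, mat)
}

#' Parse a plan file
#'
#' Reads the JSON plan schema, preserving spot and layer order exactly, and
#' checks the structural invariants. Malformed input raises an error naming
#' the offending schema path.
#'
#' @param path Plan file path.
#' @return A `proton_plan` passing [validate_plan()].
#' @export
parse_plan <- function(path) {
  if (!file.exists(path)) stop_sparc("plan file not found: %s", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  modality <- need(doc, "modality", "$")
  if (!modality %in% c("impt", "sparc"))
    stop_sparc("unknown modality \"%s\"", modality)
  rx <- need(doc, "prescription_gy", "$")
  fx <- need(doc, "fractions", "$")

  if (modality == "impt") {
    fields <- lapply(seq_along(need(doc, "fields", "$")), function(i) {
      node <- doc$fields[[i]]
      where <- sprintf("$.fields[%d]", i)
      layers <- lapply(seq_along(need(node, "layers", where)), function(j)
        parse_layer(node$layers[[j]], sprintf("%s.layers[%d]", where, j)))
      beam_field(need(node, "gantry_deg", where),
                 node$couch_deg %||% 0, layers)
    })
    plan <- proton_plan("impt", rx, fx, fields = fields)
  } else {
    arcn <- need(doc, "arc", "$")
    cps <- lapply(seq_along(need(arcn, "control_points", "$.arc")), function(i) {
      node <- arcn$control_points[[i]]
      where <- sprintf("$.arc.control_points[%d]", i)
      control_point(need(node, "angle_deg", where),
                    parse_layer(need(node, "layer", where),
                                paste0(where, ".layer")))
    })
    sectors <- lapply(arcn$excluded_sectors %||% list(),
                      function(s) as.numeric(unlist(s)))
    plan <- proton_plan("sparc", rx, fx, arc = list(
      direction = need(arcn, "direction", "$.arc"),
      start_deg = arcn$start_deg %||% cps[[1]]$angle_deg,
      stop_deg = arcn$stop_deg %||% cps[[length(cps)]]$angle_deg,
      control_points = cps,
      excluded_sectors = sectors))
  }
  viol <- validate_plan(plan)
  if (length(viol))
    stop_sparc("plan file violates invariants: %s", paste(viol, collapse = "; "))
  plan
}
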