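#' Manual delineation record for one capillary
#'
#' Holds the polygons and point marks produced by manual (or synthetic)
#' delineation of a single capillary cross-section: the outer vessel boundary,
#' the lumen, zero or more nuclei, caveola marks (centre + diameter) and
#' cell-cell junction marks.
#'
#' @param capillary_id identifier string.
#' @param vessel_outer,lumen [polygon_roi()] objects (or vertex matrices).
#' @param nuclei list of polygons (possibly empty).
#' @param caveolae data.frame with columns `x`, `y`, `diameter_nm` (0 rows ok).
#' @param junctions data.frame with columns `x`, `y` (0 rows ok).
#' @param validate check containment/disjointness invariants (lumen strictly
#'   inside the vessel boundary; every nucleus inside the vessel boundary and
#'   disjoint from the lumen interior).
#' @return object of class `CapillaryAnnotation`.
#' @export
capillary_annotation <- function(capillary_id, vessel_outer, lumen,
                                 nuclei = list(),
                                 caveolae = empty_caveolae(),
                                 junctions = empty_junctions(),
                                 validate = TRUE) {
  vessel_outer <- ensure_polygon(vessel_outer, capillary_id, "vessel_outer")
  lumen <- ensure_polygon(lumen, capillary_id, "lumen")
  nuclei <- lapply(seq_along(nuclei), function(i)
    ensure_polygon(nuclei[[i]], capillary_id, paste0("nucleus[", i, "]")))
  caveolae <- as.data.frame(caveolae)
  junctions <- as.data.frame(junctions)
  if (nrow(caveolae) > 0 &&
      !all(c("x", "y", "diameter_nm") %in% names(caveolae)))
    stop_capmorph("capillary '%s': caveolae need columns x, y, diameter_nm",
                  capillary_id)
  if (nrow(junctions) > 0 && !all(c("x", "y") %in% names(junctions)))
    stop_capmorph("capillary '%s': junctions need columns x, y", capillary_id)
  a <- structure(
    list(capillary_id = as.character(capillary_id), vessel_outer = vessel_outer,
         lumen = lumen, nuclei = nuclei, caveolae = caveolae,
         junctions = junctions),
    class = "CapillaryAnnotation")
  if (validate) validate_annotation(a)
  a
}

empty_caveolae <- function()
  data.frame(x = numeric(0), y = numeric(0), diameter_nm = numeric(0))
empty_junctions <- function() data.frame(x = numeric(0), y = numeric(0))

ensure_polygon <- function(p, id, what) {
  tryCatch(
    if (inherits(p, "capillary_polygon")) p else polygon_roi(p),
    error = function(e) stop_capmorph("capillary '%s', %s: %s", id, what,
                                      conditionMessage(e)))
}

validate_annotation <- function(a) {
  id <- a$capillary_id
  if (!polygon_inside(a$lumen, a$vessel_outer))
    stop_capmorph("capillary '%s': lumen polygon is not inside vessel_outer", id)
  for (i in seq_along(a$nuclei)) {
    if (!polygon_inside(a$nuclei[[i]], a$vessel_outer))
      stop_capmorph("capillary '%s': nucleus %d is not inside vessel_outer", id, i)
    if (!polygon_disjoint(a$nuclei[[i]], a$lumen))
      stop_capmorph("capillary '%s': nucleus %d overlaps the lumen interior", id, i)
  }
  invisible(a)
}

#' @export
print.CapillaryAnnotation <- function(x, ...) {
  cat(sprintf("CapillaryAnnotation '%s': %d nuclei, %d caveolae, %d junctions\n",
              x$capillary_id, length(x$nuclei), nrow(x$caveolae),
              nrow(x$junctions)))
  invisible(x)
}

#' Read capillary annotations from JSON
#'
#' Parses the sidecar annotation document. Schema (all coordinates 0-based
#' pixel centres):
#' \preformatted{
#' {"nm_per_px": 10.0,
#'  "capillaries": [
#'    {"id": "cap-1",
#'     "vessel_outer": [[x, y], ...],
#'     "lumen": [[x, y], ...],
#'     "nuclei": [[[x, y], ...], ...],
#'     "caveolae": [{"x":, "y":, "diameter_nm":}, ...],
#'     "junctions": [{"x":, "y":}, ...]}]}
#' }
#' Every polygon is validated on load; violations are reported with the
#' offending capillary id.
#'
#' @param path JSON file.
#' @return list with elements `nm_per_px` and `annotations` (list of
#'   [capillary_annotation()]).
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop_capmorph("annotation file not found: %s", path)
  doc <- jsonlite::read_json(path)
  nm <- doc$nm_per_px
  if (is.null(nm) || !is.numeric(nm) || nm <= 0)
    stop_capmorph("annotation file %s: missing or invalid nm_per_px", path)
  caps <- doc$capillaries %||% list()
  anns <- lapply(caps, function(cp) {
    id <- cp$id %||% "<unnamed>"
    to_mat <- function(lst) do.call(rbind, lapply(lst, function(v)
      c(as.numeric(v[[1]]), as.numeric(v[[2]]))))
    to_marks <- function(lst, cols) {
      if (length(lst) == 0) {
        if ("diameter_nm" %in% cols) return(empty_caveolae())
        return(empty_junctions())
      }
      as.data.frame(do.call(rbind, lapply(lst, function(m)
        vapply(cols, function(cl) as.numeric(m[[cl]]), numeric(1)))))
    }
    capillary_annotation(
      capillary_id = id,
      vessel_outer = to_mat(cp$vessel_outer),
      lumen = to_mat(cp$lumen),
      nuclei = lapply(cp$nuclei %||% list(), to_mat),
      caveolae = to_marks(cp$caveolae %||% list(), c("x", "y", "diameter_nm")),
      junctions = to_marks(cp$junctions %||% list(), c("x", "y")))
  })
  list(nm_per_px = as.numeric(nm), annotations = anns)
}

#' Write capillary annotations to JSON
#'
#' Inverse of [read_annotations()].
#'
#' @param annotations list of [capillary_annotation()].
#' @param nm_per_px calibration recorded in the sidecar.
#' @param path destination file.
#' @export
write_annotations <- function(annotations, nm_per_px, path) {
  poly_list <- function(p) {
    v <- as_polygon(p)
    lapply(seq_len(nrow(v)), function(i) c(v[i, 1], v[i, 2]))
  }
  doc <- list(
    nm_per_px = nm_per_px,
    capillaries = lapply(annotations, function(a) list(
      id = a$capillary_id,
      vessel_outer = poly_list(a$vessel_outer),
      lumen = poly_list(a$lumen),
      nuclei = lapply(a$nuclei, poly_list),
      caveolae = if (nrow(a$caveolae)) apply(a$caveolae, 1, as.list,
                                             simplify = FALSE) else list(),
      junctions = if (nrow(a$junctions)) apply(a$junctions, 1, as.list,
                                               simplify = FALSE) else list())))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Zone mask set for leakage analysis
#'
#' Boolean rasters, congruent with the image they annotate, for the infarct
#' core, infarct border and remote control zones. Zones must be pairwise
#' disjoint.
#'
#' @param infarct_core,infarct_border,control logical matrices of equal
#'   dimension.
#' @return object of class `ZoneMaskSet`.
#' @export
zone_mask_set <- function(infarct_core, infarct_border, control) {
  ms <- list(infarct_core = infarct_core, infarct_border = infarct_border,
             control = control)
  for (nm in names(ms)) {
    if (!is.matrix(ms[[nm]]) || !is.logical(ms[[nm]]))
      stop_capmorph("zone '%s' must be a logical matrix", nm)
  }
  d <- dim(ms[[1]])
  if (!all(vapply(ms, function(m) identical(dim(m), d), logical(1))))
    stop_capmorph("zone masks must share dimensions")
  if (any(infarct_core & infarct_border) || any(infarct_core & control) ||
      any(infarct_border & control))
    stop_capmorph("zone masks must be pairwise disjoint")
  structure(ms, class = "ZoneMaskSet")
}

#' Counting-frame record
#'
#' One fixed counting frame with its capillary count, as used for
#' immunohistochemistry-based density estimation.
#'
#' @param count non-negative integer capillary count.
#' @param frame_width_um,frame_height_um frame dimensions in micrometres.
#' @param zone_label one of `"infarct"`, `"border"`, `"control"`.
#' @return object of class `FrameCount`.
#' @export
frame_count <- function(count, frame_width_um = 200, frame_height_um = 200,
                        zone_label = "infarct") {
  if (frame_width_um <= 0 || frame_height_um <= 0)
    stop_capmorph("frame dimensions must be positive")
  if (count < 0 || count != round(count))
    stop_capmorph("count must be a non-negative integer")
  structure(list(count = as.integer(count),
                 frame_width_um = frame_width_um,
                 frame_height_um = frame_height_um,
                 zone_label = match.arg(zone_label,
                                        c("infarct", "border", "control"))),
            class = "FrameCount")
}

#' Write a metrics table to CSV
#'
#' One row per capillary (or zone), stable column order, header row, UTF-8.
#'
#' @param records data.frame or list of row-lists sharing a schema.
#' @param path destination CSV.
#' @export
write_metrics_table <- function(records, path) {
  df <- if (is.data.frame(records)) records
  else if (length(records) == 0) data.frame()
  else do.call(rbind, lapply(records, function(r)
    as.data.frame(lapply(r, function(v) if (is.null(v)) NA else v))))
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8",
                     na = "")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_capmorph("cannot write metrics table to %s", path)
  invisible(path)
}

#' Read frame counts from CSV
#'
#' Expects columns `sample_id`, `zone`, `frame_index`, `count` (extra columns
#' are kept).
#'
#' @param path CSV file.
#' @param frame_um frame edge length in micrometres (square frames).
#' @return data.frame with an attached list-column free representation plus
#'   attribute `frame_um`.
#' @export
read_frame_counts <- function(path, frame_um = 200) {
  if (!file.exists(path)) stop_capmorph("counts file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "zone", "count")
  if (!all(need %in% names(df)))
    stop_capmorph("counts file %s must have columns %s", path,
                  paste(need, collapse = ", "))
  attr(df, "frame_um") <- frame_um
  df
}
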