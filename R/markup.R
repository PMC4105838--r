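#' Read and write the vector root markup
#'
#' The toolkit exchanges vectorized root systems in a minimal RSML-like XML
#' schema, compatible with the node lists produced by interactive tracing
#' tools: a `rootsystem` element holding a `scene` (with `width`/`height` in
#' mm) whose `root` children (attributes `id`, `order`, optional `parent`)
#' contain ordered `point` elements with `x`, `y` and `diameter` attributes in
#' mm. Coordinates use a top-left origin with y increasing downward.
#' `write_root_markup()` followed by `parse_root_markup()` is the identity on
#' the data model at six decimal places.
#'
#' @param document XML text, or a file path to an XML document.
#' @param system a [root_system].
#' @param path optional output file; if `NULL` the XML text is returned.
#' @return `parse_root_markup()` a [root_system]; `write_root_markup()` the
#'   XML text (invisibly when written to `path`).
#' @examples
#' rs <- generate_root_system(n_axile = 1, laterals_per_cm = 0, seed = 1)
#' txt <- write_root_markup(rs)
#' identical(write_root_markup(parse_root_markup(txt)), txt)
#' @export
parse_root_markup <- function(document) {
  doc <- tryCatch(
    if (length(document) == 1L && !grepl("<", document, fixed = TRUE) &&
        file.exists(document)) xml2::read_xml(document)
    else xml2::read_xml(paste(document, collapse = "\n")),
    error = function(e) stop_param("malformed XML: ", conditionMessage(e)))
  if (xml2::xml_name(doc) != "rootsystem")
    stop_param("schema error: document element must be <rootsystem>")
  scene <- xml2::xml_find_first(doc, "./scene")
  if (inherits(scene, "xml_missing"))
    stop_param("schema error: <rootsystem> must contain a <scene>")
  extent <- c(as.numeric(xml2::xml_attr(scene, "width")),
              as.numeric(xml2::xml_attr(scene, "height")))
  if (any(is.na(extent)))
    stop_param("schema error: <scene> must carry numeric width and height")
  seed <- xml2::xml_attr(doc, "seed")
  seed <- if (is.na(seed)) NULL else as.integer(seed)
  roots <- lapply(xml2::xml_find_all(scene, "./root"), function(rn) {
    id <- xml2::xml_attr(rn, "id")
    if (is.na(id)) stop_param("schema error: <root> without id attribute")
    ord <- as.integer(xml2::xml_attr(rn, "order"))
    if (is.na(ord)) stop_param("schema error: root '", id, "' without integer order")
    parent <- xml2::xml_attr(rn, "parent")
    pts <- xml2::xml_find_all(rn, "./point")
    get_attr <- function(field) {
      v <- as.numeric(xml2::xml_attr(pts, field))
      miss <- which(is.na(xml2::xml_attr(pts, field)))
      if (length(miss))
        stop_param("schema error: point ", miss[1], " of root '", id,
                   "' is missing the ", field, " attribute")
      v
    }
    nodes <- data.frame(x = get_attr("x"), y = get_attr("y"),
                        diameter = get_attr("diameter"))
    if (any(!is.finite(as.matrix(nodes))) || any(nodes$diameter <= 0))
      stop_param("schema error: root '", id, "' has an invalid node ",
                 "(diameters must be > 0 and coordinates finite)")
    root(id, ord, nodes, parent_id = if (is.na(parent)) NULL else parent)
  })
  root_system(roots, extent, seed)
}

#' @rdname parse_root_markup
#' @export
write_root_markup <- function(system, path = NULL) {
  stopifnot(inherits(system, "root_system"))
  num <- function(v) sprintf("%.6f", v)
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    if (is.null(system$seed)) "<rootsystem>"
    else sprintf("<rootsystem seed=\"%d\">", system$seed),
    sprintf("  <scene width=\"%s\" height=\"%s\">", num(system$extent[1]),
            num(system$extent[2])))
  for (r in system$roots) {
    lines <- c(lines, sprintf("    <root id=\"%s\" order=\"%d\"%s>", r$id, r$order,
                              if (is.null(r$parent_id)) ""
                              else sprintf(" parent=\"%s\"", r$parent_id)))
    lines <- c(lines, sprintf("      <point x=\"%s\" y=\"%s\" diameter=\"%s\"/>",
                              num(r$nodes$x), num(r$nodes$y), num(r$nodes$diameter)))
    lines <- c(lines, "    </root>")
  }
  lines <- c(lines, "  </scene>", "</rootsystem>")
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "")
    return(invisible(txt))
  }
  txt
}

#' Write ground truth lengths as CSV
#'
#' @param system a [root_system].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(system, path) {
  tl <- true_length(system)
  write.csv(tl$per_root, path, row.names = FALSE)
  invisible(path)
}
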