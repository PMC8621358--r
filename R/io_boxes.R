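#' Construct a table of box annotations
#'
#' Bounding boxes use the package-internal convention: 0-based, half-open
#' pixel coordinates, so `width = xmax - xmin` and a box covers the pixel
#' columns `xmin .. xmax - 1`. Ground-truth boxes carry `NA` confidence;
#' detector output carries a confidence in `[0, 1]`.
#'
#' @param xmin,ymin,xmax,ymax numeric vectors of box edges (0-based,
#'   half-open).
#' @param label object class labels (default `"spike"`).
#' @param confidence detection confidences in `[0, 1]`, or `NA` for ground
#'   truth.
#' @param category optional spike category tag (`"top"`, `"inner"`,
#'   `"occluded_emergent"`) used by stratified evaluation.
#' @param image_size optional `c(height, width)`; when given, boxes are
#'   validated against the image bounds.
#' @return a `data.frame` with class `box_annotations`.
#' @export
box_annotations <- function(xmin = numeric(), ymin = numeric(),
                            xmax = numeric(), ymax = numeric(),
                            label = "spike", confidence = NA_real_,
                            category = NA_character_, image_size = NULL) {
  n <- length(xmin)
  stopifnot(length(ymin) == n, length(xmax) == n, length(ymax) == n)
  df <- data.frame(
    xmin = as.numeric(xmin), ymin = as.numeric(ymin),
    xmax = as.numeric(xmax), ymax = as.numeric(ymax),
    label = rep_len(as.character(label), n),
    confidence = rep_len(as.numeric(confidence), n),
    category = rep_len(as.character(category), n),
    stringsAsFactors = FALSE
  )
  if (n > 0) {
    if (any(df$xmin >= df$xmax) || any(df$ymin >= df$ymax)) {
      stop("degenerate box: xmin < xmax and ymin < ymax required")
    }
    if (any(df$xmin < 0) || any(df$ymin < 0)) {
      stop("box coordinates must be non-negative")
    }
    if (!is.null(image_size)) {
      if (any(df$xmax > image_size[2]) || any(df$ymax > image_size[1])) {
        stop("box exceeds image bounds")
      }
    }
    ok <- is.na(df$confidence) | (df$confidence >= 0 & df$confidence <= 1)
    if (!all(ok)) stop("confidence must be in [0, 1] or NA")
  }
  class(df) <- c("box_annotations", "data.frame")
  df
}

clamp_boxes <- function(df, image_size) {
  if (nrow(df) == 0 || is.null(image_size)) return(df)
  H <- image_size[1]; W <- image_size[2]
  out_of_bounds <- df$xmin < 0 | df$ymin < 0 | df$xmax > W | df$ymax > H
  if (any(out_of_bounds)) {
    warning(sum(out_of_bounds), " box(es) exceeded image bounds; clamped")
    df$xmin <- pmax(df$xmin, 0)
    df$ymin <- pmax(df$ymin, 0)
    df$xmax <- pmin(df$xmax, W)
    df$ymax <- pmin(df$ymax, H)
  }
  df
}

#' Read box annotations
#'
#' Supported dialects:
#' * `voc_xml` -- the PASCAL-VOC XML dialect written by LabelImg
#'   (`<object><name/><bndbox/></object>`). On disk VOC coordinates are
#'   1-based and inclusive; they are converted to the internal 0-based
#'   half-open convention as `[xmin - 1, xmax)`.
#' * `yolo_txt` -- one `class cx cy w h [confidence]` line per box, with
#'   centre and size normalised by the image dimensions. Requires
#'   `image_size`.
#' * `yolo_json` -- a JSON array of objects with the same normalised
#'   fields (`class`, `cx`, `cy`, `w`, `h`, optional `confidence`).
#'   Requires `image_size`.
#'
#' Boxes that exceed the image bounds are clamped with a warning.
#'
#' @param path annotation file.
#' @param dialect one of `"voc_xml"`, `"yolo_txt"`, `"yolo_json"`.
#' @param image_size `c(height, width)` of the annotated image; required
#'   for the YOLO dialects because their coordinates are normalised.
#' @return a [box_annotations()] table.
#' @export
read_boxes <- function(path, dialect = c("voc_xml", "yolo_txt", "yolo_json"),
                       image_size = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (dialect == "voc_xml") {
    doc <- tryCatch(xml2::read_xml(path),
                    error = function(e) stop("malformed VOC XML '", path,
                                             "': ", conditionMessage(e)))
    if (is.null(image_size)) {
      sz <- xml2::xml_find_first(doc, ".//size")
      if (!inherits(sz, "xml_missing")) {
        image_size <- c(
          as.numeric(xml2::xml_text(xml2::xml_find_first(sz, "./height"))),
          as.numeric(xml2::xml_text(xml2::xml_find_first(sz, "./width")))
        )
      }
    }
    objs <- xml2::xml_find_all(doc, ".//object")
    if (length(objs) == 0) return(box_annotations())
    num <- function(node, tag) {
      as.numeric(xml2::xml_text(xml2::xml_find_first(node, paste0(".//", tag))))
    }
    df <- box_annotations(
      xmin = vapply(objs, num, numeric(1), "xmin") - 1,
      ymin = vapply(objs, num, numeric(1), "ymin") - 1,
      xmax = vapply(objs, num, numeric(1), "xmax"),
      ymax = vapply(objs, num, numeric(1), "ymax"),
      label = vapply(objs, function(o) {
        xml2::xml_text(xml2::xml_find_first(o, "./name"))
      }, character(1))
    )
    return(clamp_boxes(df, image_size))
  }
  if (is.null(image_size)) {
    stop("image_size = c(height, width) is required for YOLO dialects")
  }
  H <- image_size[1]; W <- image_size[2]
  if (dialect == "yolo_txt") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) return(box_annotations())
    fields <- lapply(strsplit(trimws(lines), "[[:space:]]+"), as.numeric)
    nf <- lengths(fields)
    if (any(nf < 5) || any(vapply(fields, anyNA, logical(1)))) {
      stop("malformed YOLO text file: ", path)
    }
    rec <- do.call(rbind, lapply(fields, function(f) f[1:5]))
    conf <- vapply(fields, function(f) if (length(f) >= 6) f[6] else NA_real_,
                   numeric(1))
  } else {
    objs <- tryCatch(
      jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
      error = function(e) stop("malformed YOLO JSON '", path, "': ",
                               conditionMessage(e))
    )
    if (length(objs) == 0 || (is.data.frame(objs) && nrow(objs) == 0)) {
      return(box_annotations())
    }
    rec <- cbind(objs$class, objs$cx, objs$cy, objs$w, objs$h)
    conf <- if (!is.null(objs$confidence)) objs$confidence else
      rep(NA_real_, nrow(rec))
  }
  df <- box_annotations(
    xmin = round((rec[, 2] - rec[, 4] / 2) * W),
    ymin = round((rec[, 3] - rec[, 5] / 2) * H),
    xmax = round((rec[, 2] + rec[, 4] / 2) * W),
    ymax = round((rec[, 3] + rec[, 5] / 2) * H),
    label = ifelse(rec[, 1] == 0, "spike", as.character(rec[, 1])),
    confidence = conf
  )
  clamp_boxes(df, image_size)
}

#' Write box annotations
#'
#' Inverse of [read_boxes()]: VOC XML is written 1-based inclusive (the
#' LabelImg convention), YOLO dialects are written centre/size normalised
#' by `image_size`. A VOC/YOLO round trip reproduces the input exactly for
#' `voc_xml` and to within one pixel for the YOLO dialects (normalisation
#' rounding).
#'
#' @param boxes a [box_annotations()] table.
#' @inheritParams read_boxes
#' @param image_size `c(height, width)`; required for YOLO dialects and
#'   embedded in the `<size>` element for VOC.
#' @export
write_boxes <- function(boxes, path,
                        dialect = c("voc_xml", "yolo_txt", "yolo_json"),
                        image_size = NULL) {
  dialect <- match.arg(dialect)
  stopifnot(is.data.frame(boxes))
  if (dialect == "voc_xml") {
    doc <- xml2::xml_new_root("annotation")
    xml2::xml_add_child(doc, "folder", "images")
    xml2::xml_add_child(doc, "filename", basename(path))
    if (!is.null(image_size)) {
      sz <- xml2::xml_add_child(doc, "size")
      xml2::xml_add_child(sz, "width", as.character(image_size[2]))
      xml2::xml_add_child(sz, "height", as.character(image_size[1]))
      xml2::xml_add_child(sz, "depth", "3")
    }
    for (i in seq_len(nrow(boxes))) {
      ob <- xml2::xml_add_child(doc, "object")
      xml2::xml_add_child(ob, "name", boxes$label[i])
      xml2::xml_add_child(ob, "pose", "Unspecified")
      xml2::xml_add_child(ob, "truncated", "0")
      xml2::xml_add_child(ob, "difficult", "0")
      bb <- xml2::xml_add_child(ob, "bndbox")
      xml2::xml_add_child(bb, "xmin", format(boxes$xmin[i] + 1, scientific = FALSE))
      xml2::xml_add_child(bb, "ymin", format(boxes$ymin[i] + 1, scientific = FALSE))
      xml2::xml_add_child(bb, "xmax", format(boxes$xmax[i], scientific = FALSE))
      xml2::xml_add_child(bb, "ymax", format(boxes$ymax[i], scientific = FALSE))
    }
    xml2::write_xml(doc, path)
    return(invisible(path))
  }
  if (is.null(image_size)) {
    stop("image_size = c(height, width) is required for YOLO dialects")
  }
  H <- image_size[1]; W <- image_size[2]
  cx <- (boxes$xmin + boxes$xmax) / 2 / W
  cy <- (boxes$ymin + boxes$ymax) / 2 / H
  w <- (boxes$xmax - boxes$xmin) / W
  h <- (boxes$ymax - boxes$ymin) / H
  cls <- ifelse(boxes$label == "spike", 0L, boxes$label)
  if (dialect == "yolo_txt") {
    lines <- vapply(seq_len(nrow(boxes)), function(i) {
      base <- sprintf("%s %.6f %.6f %.6f %.6f", cls[i], cx[i], cy[i], w[i], h[i])
      if (!is.na(boxes$confidence[i])) {
        base <- sprintf("%s %.6f", base, boxes$confidence[i])
      }
      base
    }, character(1))
    writeLines(lines, path)
  } else {
    objs <- lapply(seq_len(nrow(boxes)), function(i) {
      o <- list(class = cls[i], cx = cx[i], cy = cy[i], w = w[i], h = h[i])
      if (!is.na(boxes$confidence[i])) o$confidence <- boxes$confidence[i]
      o
    })
    jsonlite::write_json(objs, path, auto_unbox = TRUE, digits = 10)
  }
  invisible(path)
}
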