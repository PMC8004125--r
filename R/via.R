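#' Read polygon annotations from a VIA-style JSON file
#'
#' Parses a VGG Image Annotator (VIA 3) style project file: polygon regions
#' are stored under `metadata` as flat `xy` arrays `[7, x1, y1, x2, y2, ...]`
#' (shape code 7 = polygon), each pointing into the `file` table through its
#' `vid`. Vertex coordinates are 0-based pixel coordinates with x = column
#' and y = row, and are preserved exactly.
#'
#' @param path path to the JSON file.
#' @return a list of annotations, each a list with `frame_id` (file name) and
#'   `vertices` (an `n x 2` numeric matrix with columns `x`, `y`). A file with
#'   zero regions yields an empty list.
#' @export
read_via_annotations <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stopf("not a parseable VIA JSON file: %s",
                                            conditionMessage(e)))
  files <- doc$file
  fnames <- vapply(files, function(f) as.character(f$fname), "")
  names(fnames) <- vapply(files, function(f) as.character(f$fid), "")
  out <- list()
  for (md in doc$metadata) {
    xy <- as.numeric(unlist(md$xy))
    if (length(xy) < 1 || xy[1] != 7)
      stopf("region is not a polygon (VIA shape code %s)",
            if (length(xy)) xy[1] else "missing")
    coords <- xy[-1]
    if (length(coords) < 6 || length(coords) %% 2 != 0)
      stopf("polygon region must have >= 3 (x, y) vertex pairs")
    v <- matrix(coords, ncol = 2, byrow = TRUE,
                dimnames = list(NULL, c("x", "y")))
    fid <- as.character(md$vid)
    out[[length(out) + 1L]] <- list(
      frame_id = if (fid %in% names(fnames)) fnames[[fid]] else fid,
      vertices = v)
  }
  out
}

#' Write polygon annotations as a VIA-style JSON file
#'
#' Inverse of [read_via_annotations()]: the writer/reader pair round-trips
#' vertex lists exactly.
#'
#' @param annotations list of annotations (`frame_id` + `vertices` matrix).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_via_annotations <- function(annotations, path) {
  files <- list(); metadata <- list()
  fids <- character(0)
  for (i in seq_along(annotations)) {
    a <- annotations[[i]]
    v <- a$vertices
    if (is.null(dim(v)) || nrow(v) < 3) stopf("each polygon needs >= 3 vertices")
    fid <- match(a$frame_id, fids)
    if (is.na(fid)) {
      fids <- c(fids, a$frame_id)
      fid <- length(fids)
      files[[as.character(fid)]] <- list(fid = as.character(fid),
                                         fname = a$frame_id, type = 2, loc = 1,
                                         src = a$frame_id)
    }
    metadata[[sprintf("%d_%d", fid, i)]] <- list(
      vid = as.character(fid), flg = 0, z = list(),
      xy = c(7, as.numeric(t(v))), av = list("1" = "HCC"))
  }
  doc <- list(project = list(pid = "ceusfuse", pname = "ceusfuse annotations",
                             creator = "ceusfuse", vid_list = as.list(as.character(seq_along(fids)))),
              config = list(), attribute = list(),
              file = files, metadata = metadata, view = list())
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
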