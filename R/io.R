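#' Write frames to a multi-page TIFF
#'
#' Frames are stored as 32-bit float TIFF pages. Values must lie in
#' [0, 1]: normalized frames already do; raw camera frames are stored as
#' a fraction of the sensor saturation (recorded in the sidecar written
#' by [write_stack()]).
#'
#' @param frames A matrix or list of matrices.
#' @param path Output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_frames_tiff <- function(frames, path) {
  if (is.matrix(frames)) frames <- list(frames)
  frames <- lapply(frames, function(f) {
    f <- unclass_frame(f)
    if (any(f < 0) || any(f > 1)) {
      stop("frame values must be in [0, 1] for TIFF storage; ",
           "divide camera counts by the sensor saturation first")
    }
    f
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Read frames from a multi-page TIFF
#' @param path `.tif` path.
#' @return List of numeric matrices (grayscale; color channels are
#'   averaged if present).
#' @export
read_frames_tiff <- function(path) {
  if (!file.exists(path)) stop("no such TIFF file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (is.matrix(pages)) pages <- list(pages)
  lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- apply(p, c(1, 2), mean)
    p
  })
}

#' Crop a region of interest from a frame
#'
#' 1-based, inclusive, row-major with the origin at the top-left pixel.
#'
#' @param x Frame or matrix.
#' @param row,col Top-left corner (1-based).
#' @param height,width ROI size in pixels.
#' @return Cropped matrix.
#' @export
crop_roi <- function(x, row, col, height, width) {
  p <- unclass_frame(x)
  if (row < 1 || col < 1 || row + height - 1 > nrow(p) ||
      col + width - 1 > ncol(p)) {
    stop("ROI [", row, ":", row + height - 1, ", ", col, ":",
         col + width - 1, "] outside frame of ", nrow(p), " x ", ncol(p))
  }
  p[row:(row + height - 1), col:(col + width - 1), drop = FALSE]
}

#' Write a reference stack to disk
#'
#' Lateral stacks are written as multi-page float TIFF (one page per
#' plane); the z stack, whose entries are sorted 1D profiles, is written
#' as a single 2D TIFF image (rows = planes, columns = sorted index).
#' Either way a JSON sidecar `<name>.json` records axis, positions,
#' step, center index and entry kind.
#'
#' @param stack A `reference_stack`.
#' @param dir Output directory (created if needed).
#' @param name Base name; defaults to `stack_<axis>`.
#' @return The TIFF path, invisibly.
#' @export
write_stack <- function(stack, dir, name = paste0("stack_", stack$axis)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tif <- file.path(dir, paste0(name, ".tif"))
  if (stack$axis == "z") {
    # sorted profiles of normalized frames lie in [0, 1] already
    m <- do.call(rbind, lapply(stack$entries, as.numeric))
    write_frames_tiff(m, tif)
  } else {
    write_frames_tiff(stack$entries, tif)
  }
  scale <- 1
  meta <- list(axis = stack$axis,
               kind = if (stack$axis == "z") "sorted_profile" else "frame",
               positions_nm = stack$positions_nm,
               step_nm = stack$step_nm,
               center_index = stack$center_index,
               value_scale = scale,
               index_base = 1L)
  jsonlite::write_json(meta, file.path(dir, paste0(name, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(tif)
}

#' Read a reference stack written by [write_stack()]
#' @param dir Directory holding the TIFF and sidecar.
#' @param name Base name (e.g. `stack_x`).
#' @return A `reference_stack`.
#' @export
read_stack <- function(dir, name) {
  tif <- file.path(dir, paste0(name, ".tif"))
  sidecar <- file.path(dir, paste0(name, ".json"))
  if (!file.exists(sidecar)) {
    stop("missing sidecar metadata ", sidecar, ": a reference stack ",
         "needs its JSON sidecar (axis, positions_nm, step_nm, ",
         "center_index); re-export the stack with write_stack()")
  }
  if (!file.exists(tif)) stop("missing stack TIFF: ", tif)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pages <- read_frames_tiff(tif)
  if (identical(meta$kind, "sorted_profile")) {
    m <- pages[[1L]] * meta$value_scale
    entries <- lapply(seq_len(nrow(m)), function(i) {
      structure(as.numeric(m[i, ]), class = "sorted_profile")
    })
  } else {
    entries <- lapply(pages, function(p) {
      attr(p, "normalized") <- TRUE
      p
    })
  }
  reference_stack(meta$axis, entries, as.numeric(meta$positions_nm))
}

#' Stream loop records to a JSONL log
#'
#' Line 1 is a header object embedding the fully resolved configuration
#' and seeds, so any log can be reproduced from its own header; then one
#' JSON object per loop record, flushed per line.
#'
#' @param records Loop record data frame.
#' @param path Output `.jsonl` path.
#' @param header Named list written as the header (should contain the
#'   resolved config and seed).
#' @return `path`, invisibly.
#' @export
write_loop_log <- function(records, path, header = list()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  header$type <- "header"
  ev <- attr(records, "disturbance_events")
  if (!is.null(ev)) header$disturbance_events <- ev
  writeLines(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA,
                              dataframe = "columns"), con)
  for (i in seq_len(nrow(records))) {
    rec <- as.list(records[i, , drop = FALSE])
    rec <- lapply(rec, function(v) v[[1L]])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
    flush(con)
  }
  invisible(path)
}

#' Read a JSONL loop log
#'
#' A truncated final line (interrupted write) is skipped with a warning;
#' everything else must parse.
#'
#' @param path `.jsonl` path from [write_loop_log()].
#' @return Loop record data frame; the parsed header is attached as
#'   attribute `header`, disturbance events (if logged) as
#'   `disturbance_events`.
#' @export
read_loop_log <- function(path) {
  if (!file.exists(path)) stop("no such log file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty loop log: ", path)
  parsed <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    parsed[[i]] <- tryCatch(
      jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
      error = function(e) {
        if (i == length(lines)) {
          warning("skipping truncated final log line in ", path)
          NULL
        } else {
          stop("corrupt log line ", i, " in ", path)
        }
      })
  }
  parsed <- parsed[!vapply(parsed, is.null, logical(1))]
  header <- NULL
  if (identical(parsed[[1L]]$type, "header")) {
    header <- parsed[[1L]]
    parsed <- parsed[-1L]
  }
  if (length(parsed) == 0L) stop("loop log has a header but no records")
  records <- do.call(rbind, lapply(parsed, function(p) {
    as.data.frame(p[setdiff(names(p), "type")])
  }))
  if (!is.null(header$disturbance_events)) {
    attr(records, "disturbance_events") <-
      as.data.frame(header$disturbance_events)
  }
  attr(records, "header") <- header
  records
}

#' Write a bead/feature position track as CSV
#' @param track Data frame with columns `t`, `x_nm`, `y_nm`, `z_nm`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_track_csv <- function(track, path) {
  stopifnot(all(c("t", "x_nm", "y_nm", "z_nm") %in% names(track)))
  utils::write.csv(track, path, row.names = FALSE)
  invisible(path)
}

#' Read a position track CSV
#' @param path CSV with columns `t`, `x_nm`, `y_nm`, `z_nm`.
#' @return Data frame.
#' @export
read_track_csv <- function(path) {
  if (!file.exists(path)) stop("no such track file: ", path)
  tr <- utils::read.csv(path)
  miss <- setdiff(c("t", "x_nm", "y_nm", "z_nm"), names(tr))
  if (length(miss)) {
    stop("track file ", path, " is missing columns: ",
         paste(miss, collapse = ", "))
  }
  tr
}
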