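# Plain-text serialization. Frame streams are JSON-Lines (one frame
# object per line), gold logs and viewing logs are CSV, galleries and
# angular-limit maps are human-readable text. Writers emit full double
# precision so that read(write(x)) reproduces the values exactly.

#' Write a frame stream as JSON-Lines
#'
#' One frame per line: `frame_index`, `t` and a `faces` array whose
#' elements carry `box` \[x, y, w, h\], `score`, `embedding`, `gaze`
#' \[x, y, z\] and, when present, the simulator ground-truth fields.
#'
#' @param faces Candidate-face tibble (as in a `gw_session`).
#' @param path Output file.
#' @param n_frames Total frames (frames with no faces are written with an
#'   empty array); defaults to max frame index + 1.
#' @param fps Frames per second (stored per line via `t`).
#' @return `path`, invisibly.
#' @export
write_frames_jsonl <- function(faces, path, n_frames = NULL, fps = NULL) {
  if (is.null(n_frames)) n_frames <- max(c(faces$frame_index, -1)) + 1
  if (is.null(fps)) {
    fps <- if (n_frames > 1 && nrow(faces) > 0 && any(faces$t > 0)) {
      faces$frame_index[faces$t > 0][1] / faces$t[faces$t > 0][1]
    } else 15
  }
  has_truth <- "true_identity" %in% names(faces)
  has_decision <- "is_target" %in% names(faces) &&
    !all(is.na(faces$is_target))
  split_faces <- split(faces, factor(faces$frame_index, levels = 0:(n_frames - 1)))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(n_frames)) {
    f <- split_faces[[k]]
    face_list <- lapply(seq_len(nrow(f)), function(i) {
      o <- list(box = c(f$x[i], f$y[i], f$w[i], f$h[i]),
                score = f$score[i],
                embedding = as.numeric(f$embedding[[i]]),
                gaze = c(f$gx[i], f$gy[i], f$gz[i]))
      if (has_truth) {
        o$true_identity <- f$true_identity[i]
        o$true_gaze_on_tv <- f$true_gaze_on_tv[i]
      }
      if (has_decision) o$is_target <- f$is_target[i]
      o
    })
    line <- jsonlite::toJSON(
      list(frame_index = k - 1L, t = (k - 1) / fps, faces = face_list),
      auto_unbox = TRUE, digits = I(17), null = "null")
    writeLines(line, con)
  }
  invisible(path)
}

#' Read a JSON-Lines frame stream
#'
#' @param path File written by [write_frames_jsonl()].
#' @return Candidate-face tibble (one row per face, embedding as a
#'   list-column), with attribute `n_frames`.
#' @export
read_frames_jsonl <- function(path) {
  lines <- readLines(path)
  frames <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE,
                   simplifyDataFrame = FALSE)
  rows <- purrr::map_dfr(frames, function(fr) {
    if (length(fr$faces) == 0) return(NULL)
    purrr::map_dfr(seq_along(fr$faces), function(i) {
      fc <- fr$faces[[i]]
      tibble::tibble(
        frame_index = as.integer(fr$frame_index), t = fr$t,
        face = i,
        x = fc$box[1], y = fc$box[2], w = fc$box[3], h = fc$box[4],
        score = fc$score,
        embedding = list(as.numeric(fc$embedding)),
        gx = fc$gaze[1], gy = fc$gaze[2], gz = fc$gaze[3],
        true_identity = fc$true_identity %||% NA_character_,
        true_gaze_on_tv = fc$true_gaze_on_tv %||% NA,
        is_target = fc$is_target %||% NA
      )
    })
  })
  attr(rows, "n_frames") <- length(lines)
  rows
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a duration-coded gold log as CSV
#'
#' Columns `code,start_frame,end_frame`; half-open intervals.
#'
#' @param gold Gold-log tibble.
#' @param path File path.
#' @return `path` (writer, invisibly) / gold-log tibble (reader).
#' @export
write_gold_csv <- function(gold, path) {
  readr::write_csv(gold[, c("code", "start_frame", "end_frame")], path)
  invisible(path)
}

#' @rdname write_gold_csv
#' @export
read_gold_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    code = readr::col_character(),
    start_frame = readr::col_integer(),
    end_frame = readr::col_integer()))
}

#' Write / read an enrollment gallery as a plain text matrix
#'
#' One embedding per row, space-separated, full double precision
#' (`%.17g`), so values round-trip exactly.
#'
#' @param gallery Numeric matrix.
#' @param path File path.
#' @return `path` (writer, invisibly) / matrix (reader).
#' @export
write_gallery <- function(gallery, path) {
  lines <- apply(gallery, 1, function(r) paste(sprintf("%.17g", r),
                                               collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gallery
#' @export
read_gallery <- function(path) {
  rows <- strsplit(readLines(path), " ", fixed = TRUE)
  do.call(rbind, lapply(rows, as.numeric))
}

#' Write / read an angular-limit map
#'
#' A human-readable calibration artifact: comment headers record the
#' television position, grid, frame size, coverage quantile and the global
#' fallback windows; the body is CSV with one row per fitted cell
#' (`cell,yaw_lo,yaw_hi,pitch_lo,pitch_hi,n`).
#'
#' @param limits A `gw_limits` object.
#' @param path File path.
#' @return `path` (writer, invisibly) / `gw_limits` (reader).
#' @export
write_limits <- function(limits, path) {
  g <- attr(limits, "grid"); fsz <- attr(limits, "frame_size")
  fb <- attr(limits, "fallback")
  hdr <- c(
    sprintf("# tv_position: %s", attr(limits, "tv_position")),
    sprintf("# grid: %d %d", g[1], g[2]),
    sprintf("# frame_size: %d %d", fsz[1], fsz[2]),
    sprintf("# coverage_quantile: %.17g", attr(limits, "coverage_quantile")),
    sprintf("# yaw_only: %s", isTRUE(attr(limits, "yaw_only"))),
    sprintf("# fallback: %.17g %.17g %.17g %.17g",
            fb["yaw_lo"], fb["yaw_hi"], fb["pitch_lo"], fb["pitch_hi"]),
    "cell,yaw_lo,yaw_hi,pitch_lo,pitch_hi,n")
  body <- sprintf("%d,%.17g,%.17g,%.17g,%.17g,%d",
                  limits$cell, limits$yaw_lo, limits$yaw_hi,
                  limits$pitch_lo, limits$pitch_hi, limits$n)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_limits
#' @export
read_limits <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  val <- function(key) sub(sprintf("^# %s: ", key), "",
                           grep(sprintf("^# %s:", key), hdr, value = TRUE))
  g <- as.integer(strsplit(val("grid"), " ")[[1]])
  fsz <- as.integer(strsplit(val("frame_size"), " ")[[1]])
  fb <- as.numeric(strsplit(val("fallback"), " ")[[1]])
  names(fb) <- c("yaw_lo", "yaw_hi", "pitch_lo", "pitch_hi")
  body <- lines[!grepl("^#", lines)]
  tab <- utils::read.csv(text = body)
  out <- tibble::as_tibble(tab)
  out$cell <- as.integer(out$cell); out$n <- as.integer(out$n)
  structure(out, class = c("gw_limits", class(out)),
            grid = g, frame_size = fsz, tv_position = val("tv_position"),
            fallback = fb,
            coverage_quantile = as.numeric(val("coverage_quantile")),
            yaw_only = identical(val("yaw_only"), "TRUE"))
}

#' Write a viewing log as CSV plus a JSON summary
#'
#' The CSV has columns `frame_index,viewing`; the JSON summary (written
#' alongside with extension `.json`) records fps, frame counts and the
#' total viewing time in seconds and "m:ss".
#'
#' @param log A `gw_viewing_log`.
#' @param path CSV path; the summary goes to `sub("\\\\.csv$", ".json",
#'   path)`.
#' @return `path`, invisibly.
#' @export
write_viewing_log <- function(log, path) {
  readr::write_csv(tibble::tibble(frame_index = log$frame_index,
                                  viewing = log$viewing), path)
  tv <- total_viewing_time(log)
  summary_path <- sub("\\.csv$", ".json", path)
  if (identical(summary_path, path)) summary_path <- paste0(path, ".json")
  jsonlite::write_json(
    list(fps = attr(log, "fps"), n_frames = nrow(log),
         n_viewing_frames = sum(log$viewing),
         total_viewing_s = tv$seconds, total_viewing = tv$formatted),
    summary_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_viewing_log
#' @param fps Frame rate to attach when reading.
#' @export
read_viewing_log <- function(path, fps) {
  tab <- readr::read_csv(path, col_types = readr::cols(
    frame_index = readr::col_integer(), viewing = readr::col_logical()))
  new_viewing_log(tab$frame_index, tab$viewing, fps)
}
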