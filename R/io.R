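# core io: image stacks (multi-page TIFF), trace tables (CSV), run
# configuration (YAML/JSON)

#' Construct an image stack
#'
#' A time-ordered stack of single-channel 2-D frames with acquisition
#' metadata. Frames are stored as a 3-D array indexed (row, col, time).
#'
#' @param frames 3-D numeric array (row x col x time) or a list of matrices
#'   sharing dimensions.
#' @param channel channel label (single string).
#' @param pixel_size physical pixel size, um/px.
#' @param frame_interval time between frames, s.
#' @param time_origin acquisition start time, s.
#' @return object of class \code{image_stack}.
#' @export
image_stack <- function(frames, channel = "ch1", pixel_size = 1,
                        frame_interval = 1, time_origin = 0) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1L) stop_coac("all frames must share dimensions")
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(dims[[1]], length(frames)))
  }
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stop_coac("`frames` must be a 3-D array (row, col, time)")
  }
  if (dim(frames)[3] < 1L) stop_coac("an image stack needs at least one frame")
  check_pos(pixel_size, "pixel_size")
  check_pos(frame_interval, "frame_interval")
  structure(
    list(frames = frames, channel = as.character(channel)[1],
         pixel_size = pixel_size, frame_interval = frame_interval,
         time_origin = time_origin),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<image_stack> %d frame(s) of %dx%d px, channel '%s'\n  pixel size %g um/px, frame interval %g s\n",
    d[3], d[1], d[2], x$channel, x$pixel_size, x$frame_interval))
  invisible(x)
}

#' Number of frames and frame times of an image stack
#' @param stack an \code{image_stack}.
#' @return \code{n_frames}: integer count. \code{frame_times}: numeric vector
#'   of acquisition times (s) relative to \code{time_origin}.
#' @export
n_frames <- function(stack) dim(stack$frames)[3]

#' @rdname n_frames
#' @export
frame_times <- function(stack) {
  stack$time_origin + (seq_len(n_frames(stack)) - 1L) * stack$frame_interval
}

#' Write an image stack to a multi-page TIFF
#'
#' Intensities are quantized to the requested integer bit depth on the
#' \code{[0, 1]} scale; values already on that grid round-trip bit-exactly.
#' A named list of stacks is written channel-interleaved, frame-major.
#'
#' @param stack an \code{image_stack}, or named list of them (equal frame
#'   counts) for interleaved multi-channel files.
#' @param path output file.
#' @param bits 8 or 16 bits per sample.
#' @return \code{path}, invisibly.
#' @export
write_image_stack <- function(stack, path, bits = 16L) {
  stacks <- if (inherits(stack, "image_stack")) list(stack) else stack
  if (!all(vapply(stacks, inherits, logical(1), "image_stack"))) {
    stop_coac("`stack` must be an image_stack or a list of them")
  }
  nf <- unique(vapply(stacks, n_frames, integer(1)))
  if (length(nf) != 1L) stop_coac("channels must have equal frame counts")
  pages <- list()
  for (t in seq_len(nf)) {
    for (s in stacks) {
      fr <- s$frames[, , t]
      if (any(fr < 0 | fr > 1)) {
        stop_coac("intensities must lie in [0, 1] for TIFF export")
      }
      pages[[length(pages) + 1L]] <- fr
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits),
                  compression = "none", reduce = TRUE)
  invisible(path)
}

#' Read a multi-page TIFF as an image stack
#'
#' @param path TIFF file, single- or channel-interleaved multi-channel as
#'   declared by \code{channels}.
#' @param channel channel to extract; must be one of \code{channels}. With
#'   \code{NULL} and several channels, a named list of stacks is returned.
#' @param channels channel labels in interleave order (default single "ch1").
#' @param pixel_size,frame_interval,time_origin acquisition metadata to attach
#'   (from the run configuration; TIFF itself carries none).
#' @return an \code{image_stack} (or named list of them).
#' @export
read_image_stack <- function(path, channel = NULL, channels = "ch1",
                             pixel_size = 1, frame_interval = 1,
                             time_origin = 0) {
  if (!file.exists(path)) stop_coac("file not found: %s", path)
  # escalate libtiff read warnings (truncation, bad directories) to errors:
  # a partial stack must never be returned silently
  pages <- tryCatch(
    withCallingHandlers(
      tiff::readTIFF(path, all = TRUE),
      warning = function(w) stop_coac("corrupt TIFF %s: %s", path,
                                      conditionMessage(w))),
    error = function(e) stop_coac("cannot read TIFF %s: %s", path,
                                  conditionMessage(e)))
  if (length(pages) == 0L) stop_coac("no frames in %s", path)
  dims <- unique(lapply(pages, dim))
  if (length(dims) != 1L) stop_coac("frame-size mismatch in %s", path)
  k <- length(channels)
  if (length(pages) %% k != 0L) {
    stop_coac("page count %d not a multiple of %d declared channels",
              length(pages), k)
  }
  make_stack <- function(idx, ch) {
    image_stack(pages[idx], channel = ch, pixel_size = pixel_size,
                frame_interval = frame_interval, time_origin = time_origin)
  }
  if (k == 1L && is.null(channel)) return(make_stack(seq_along(pages), channels))
  if (!is.null(channel)) {
    j <- match(channel, channels)
    if (is.na(j)) stop_coac("unknown channel label '%s'", channel)
    return(make_stack(seq(j, length(pages), by = k), channel))
  }
  out <- lapply(seq_len(k), function(j) {
    make_stack(seq(j, length(pages), by = k), channels[j])
  })
  names(out) <- channels
  out
}

#' Trace tables: timed measurement columns
#'
#' A \code{trace_table} is a plain data frame whose first column is
#' \code{time_s} (monotone non-decreasing), with named numeric value columns
#' and an optional \code{units} attribute (named character vector).
#'
#' @param time_s time points, s.
#' @param ... named numeric columns of equal length.
#' @param units optional named character vector of units per value column.
#' @return a \code{data.frame} with class \code{c("trace_table", "data.frame")}.
#' @export
trace_table <- function(time_s, ..., units = NULL) {
  vals <- list(...)
  if (length(vals) && is.null(names(vals))) stop_coac("value columns must be named")
  if (is.unsorted(time_s, na.rm = TRUE)) {
    stop_coac("`time_s` must be monotone non-decreasing")
  }
  lens <- vapply(vals, length, integer(1))
  if (any(lens != length(time_s))) stop_coac("all columns must share length")
  df <- data.frame(time_s = time_s, vals, check.names = FALSE)
  attr(df, "units") <- units
  class(df) <- c("trace_table", "data.frame")
  df
}

#' Write / read a trace table as CSV
#'
#' Numerics are written with 17 significant digits so finite doubles (and NA
#' gaps) survive a round trip exactly.
#'
#' @param x a \code{trace_table} (or plain data frame with a time_s column).
#' @param path CSV path.
#' @return \code{write_trace}: \code{path} invisibly; \code{read_trace}: a
#'   \code{trace_table}.
#' @export
write_trace <- function(x, path) {
  if (nrow(x) == 0L) stop_coac("no rows to write")
  if (anyDuplicated(names(x))) stop_coac("duplicate column names")
  fmt <- vapply(x, function(col) {
    out <- sprintf("%.17g", as.numeric(col))
    out[is.na(col)] <- "NA"
    out
  }, character(nrow(x)))
  fmt <- matrix(fmt, nrow = nrow(x))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(x), collapse = ","), con)
  writeLines(apply(fmt, 1L, paste, collapse = ","), con)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop_coac("file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) == 0L) stop_coac("no rows in %s", path)
  if (anyDuplicated(names(df))) stop_coac("duplicate column names in %s", path)
  bad <- !vapply(df, is.numeric, logical(1)) &
    !vapply(df, function(col) all(is.na(col)), logical(1))
  if (any(bad)) {
    stop_coac("non-numeric cells in column(s): %s",
              paste(names(df)[bad], collapse = ", "))
  }
  df[] <- lapply(df, as.numeric)
  do.call(trace_table, c(list(time_s = df$time_s),
                         df[setdiff(names(df), "time_s")]))
}

#' Run configuration
#'
#' Acquisition and analysis parameters shared by the pipeline stages. The
#' species table drives stoichiometry; fit tolerances and the random seed make
#' runs reproducible. A stable FNV-1a hash of the configuration is attached so
#' downstream results can record their provenance.
#'
#' @param pixel_size um/px. @param frame_interval s.
#' @param pre_bleach_frames number of pre-bleach frames used for FRAP
#'   normalization (default 20).
#' @param bleach_frame_policy "auto" (argmin detection) or a fixed frame index.
#' @param species data.frame with columns name, conc_uM, length, charged
#'   (charged monomers per chain).
#' @param fit_tol relative convergence tolerance passed to the least-squares
#'   fitters.
#' @param seed integer random seed.
#' @return object of class \code{run_config} with a \code{hash} field.
#' @export
run_config <- function(pixel_size = 0.2, frame_interval = 0.2,
                       pre_bleach_frames = 20L, bleach_frame_policy = "auto",
                       species = NULL, fit_tol = 1e-8, seed = 1L) {
  check_pos(pixel_size, "pixel_size")
  check_pos(frame_interval, "frame_interval")
  if (pre_bleach_frames < 1L) stop_coac("pre_bleach_frames must be >= 1")
  if (!is.null(species)) {
    need <- c("name", "conc_uM", "length", "charged")
    if (!all(need %in% names(species))) {
      stop_coac("species table needs columns: %s", paste(need, collapse = ", "))
    }
    if (any(species$conc_uM < 0)) stop_coac("concentrations must be >= 0")
    if (any(species$length < 1)) stop_coac("lengths must be >= 1")
    if (any(species$charged > species$length)) {
      stop_coac("charged monomers cannot exceed chain length")
    }
  }
  cfg <- list(pixel_size = pixel_size, frame_interval = frame_interval,
              pre_bleach_frames = as.integer(pre_bleach_frames),
              bleach_frame_policy = bleach_frame_policy,
              species = species, fit_tol = fit_tol, seed = as.integer(seed))
  cfg$hash <- fnv1a32(cfg)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML or JSON
#' @param path file ending in .yaml/.yml or .json.
#' @return a \code{run_config}.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_coac("file not found: %s", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  }
  if (!is.null(raw$species)) raw$species <- as.data.frame(raw$species)
  do.call(run_config, raw[intersect(names(raw), names(formals(run_config)))])
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf(
    "<run_config %s> pixel %g um/px, interval %g s, %d pre-bleach frames, seed %d\n",
    x$hash, x$pixel_size, x$frame_interval, x$pre_bleach_frames, x$seed))
  if (!is.null(x$species)) cat(sprintf("  %d species\n", nrow(x$species)))
  invisible(x)
}
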