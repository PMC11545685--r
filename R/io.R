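# Image and clip-layout I/O.
#
# On-disk layout for a dataset:
#   <root>/<patient_id>/<vessel>/<clip_id>/frame_%05d.png
# with parallel mask_%05d.png (0/255) and optional wmap_%05d.png.

#' Read a grayscale image file as an 8-bit intensity matrix
#'
#' PNG and TIFF are supported; color images are reduced to their first
#' channel.  Values are returned on the 0--255 scale.
#'
#' @param path path to a PNG or TIFF file.
#' @return numeric matrix with values in \[0, 255\].
#' @export
read_frame_image <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("reading TIFF requires the 'tiff' package", call. = FALSE)
      }
      tiff::readTIFF(path)
    },
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  if (length(dim(x)) == 3) x <- x[, , 1]
  round(255 * x)
}

#' @rdname read_frame_image
#' @param x numeric matrix on the 0--255 scale.
#' @export
write_frame_image <- function(x, path) {
  png::writePNG(clamp01(x / 255), path)
  invisible(path)
}

read_mask_image <- function(path) {
  m <- read_frame_image(path)
  (m >= 128) * 1
}

write_mask_image <- function(mask, path) {
  png::writePNG(mask, path)
  invisible(path)
}

write_wmap_image <- function(w, path) {
  png::writePNG(clamp01(w), path)
  invisible(path)
}

#' Construct a clip record
#'
#' A clip is an ordered run of frames from one vessel of one patient, with
#' aligned binary masks and (optionally) weight maps and per-frame defect
#' labels.
#'
#' @param frames list of 8-bit frame matrices.
#' @param masks list of \{0,1\} mask matrices aligned with `frames`.
#' @param patient_id,vessel_label,clip_id identifiers; `vessel_label` must be
#'   one of the hepatic vessel vocabulary (IVC, RHV, MHV, LHV, MPV/PV, LPV,
#'   RPV, ARPV/RAPV, PRPV/RPPV).
#' @param wmaps optional list of weight-map matrices in \[0, 1\].
#' @param labels optional per-frame defect labels
#'   (`ok`, `blackness`, `no_target`, `blurry`).
#' @return an object of class `wunet_clip`.
#' @export
clip_record <- function(frames, masks, patient_id, vessel_label, clip_id,
                        wmaps = NULL, labels = NULL) {
  if (length(frames) != length(masks)) {
    stop("frames and masks must have equal length", call. = FALSE)
  }
  if (!vessel_label %in% vessel_vocabulary()) {
    stop("unknown vessel label: ", vessel_label, call. = FALSE)
  }
  for (i in seq_along(frames)) {
    check_binary_mask(masks[[i]])
    if (!identical(dim(frames[[i]]), dim(masks[[i]]))) {
      stop("mask ", i, " is not on the same grid as its frame", call. = FALSE)
    }
  }
  structure(
    list(frames = frames, masks = masks, wmaps = wmaps, labels = labels,
         patient_id = patient_id, vessel_label = vessel_label,
         clip_id = clip_id),
    class = "wunet_clip"
  )
}

#' @export
print.wunet_clip <- function(x, ...) {
  cat(sprintf("<wunet_clip> %s / %s / %s: %d frames (%d x %d)\n",
              x$patient_id, x$vessel_label, x$clip_id, length(x$frames),
              nrow(x$frames[[1]]), ncol(x$frames[[1]])))
  invisible(x)
}

#' List clips under a dataset root directory
#'
#' @param root dataset root using the
#'   `<root>/<patient>/<vessel>/<clip>/frame_%05d.png` layout.
#' @return data.frame with columns patient_id, vessel_label, clip_id, path.
#' @export
list_clips <- function(root) {
  if (!dir.exists(root)) stop("no such directory: ", root, call. = FALSE)
  rows <- list()
  for (p in sort(list.dirs(root, recursive = FALSE))) {
    for (v in sort(list.dirs(p, recursive = FALSE))) {
      for (cl in sort(list.dirs(v, recursive = FALSE))) {
        rows[[length(rows) + 1]] <- data.frame(
          patient_id = basename(p), vessel_label = basename(v),
          clip_id = basename(cl), path = cl, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(patient_id = character(), vessel_label = character(),
                      clip_id = character(), path = character()))
  }
  do.call(rbind, rows)
}

#' Read one clip directory into a clip record
#'
#' @param path a clip directory (see [list_clips()]).
#' @param with_wmaps read `wmap_%05d.png` files when present.
#' @return a `wunet_clip`.
#' @export
read_clip <- function(path, with_wmaps = TRUE) {
  ff <- sort(list.files(path, pattern = "^frame_\\d+\\.(png|tiff?)$",
                        full.names = TRUE))
  if (!length(ff)) stop("no frames in clip directory: ", path, call. = FALSE)
  frames <- lapply(ff, read_frame_image)
  mf <- file.path(path, sub("^frame_", "mask_", basename(ff)))
  if (!all(file.exists(mf))) {
    stop("missing mask files in clip directory: ", path, call. = FALSE)
  }
  masks <- lapply(mf, read_mask_image)
  wf <- file.path(path, sub("^frame_", "wmap_", basename(ff)))
  wmaps <- if (with_wmaps && all(file.exists(wf))) {
    lapply(wf, function(f) read_frame_image(f) / 255)
  }
  clip_record(frames, masks,
              patient_id = basename(dirname(dirname(path))),
              vessel_label = basename(dirname(path)),
              clip_id = basename(path), wmaps = wmaps)
}

write_clip <- function(clip, root) {
  dir <- file.path(root, clip$patient_id, clip$vessel_label, clip$clip_id)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(clip$frames)) {
    write_frame_image(clip$frames[[i]],
                      file.path(dir, sprintf("frame_%05d.png", i - 1)))
    write_mask_image(clip$masks[[i]],
                     file.path(dir, sprintf("mask_%05d.png", i - 1)))
    if (!is.null(clip$wmaps)) {
      write_wmap_image(clip$wmaps[[i]],
                       file.path(dir, sprintf("wmap_%05d.png", i - 1)))
    }
  }
  invisible(dir)
}
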