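# Streamline container plus hand-written TCK (MRtrix) and TRK (TrackVis)
# readers/writers. Points are always held in world mm (RAS+) in memory; the
# on-disk coordinate conventions of each format are applied at the boundary.

#' Ordered streamline polylines in world mm
#'
#' @param streamlines List of n_i x 3 numeric matrices, each row a point in
#'   world mm; every streamline must have at least 2 points.
#' @param scores Optional list with per-streamline `rfbc` numeric vector and
#'   `lfbc` list of per-point profiles (see [fbc_scores()]).
#' @param meta List of generation parameters (seed, acceptance statistics, ...).
#' @return An object of class `streamline_set`.
#' @export
streamline_set <- function(streamlines, scores = NULL, meta = list()) {
  if (!is.list(streamlines)) stop("streamlines must be a list", call. = FALSE)
  for (s in streamlines) {
    if (!is.matrix(s) || ncol(s) != 3L || nrow(s) < 2L)
      stop("each streamline must be an n x 3 matrix with n >= 2", call. = FALSE)
  }
  structure(list(streamlines = streamlines, scores = scores, meta = meta),
            class = "streamline_set")
}

#' @export
print.streamline_set <- function(x, ...) {
  npts <- vapply(x$streamlines, nrow, integer(1))
  cat(sprintf("<streamline_set n=%d points/streamline %s scored=%s>\n",
              length(x$streamlines),
              if (length(npts)) sprintf("%d-%d", min(npts), max(npts)) else "-",
              !is.null(x$scores)))
  invisible(x)
}

#' @export
length.streamline_set <- function(x) length(x$streamlines)

# subset a streamline set, carrying scores along
subset_streamlines <- function(set, keep) {
  scores <- set$scores
  if (!is.null(scores)) {
    scores$rfbc <- scores$rfbc[keep]
    scores$lfbc <- scores$lfbc[keep]
  }
  meta <- set$meta
  if (!is.null(meta$ground_truth)) meta$ground_truth <- meta$ground_truth[keep]
  streamline_set(set$streamlines[keep], scores, meta)
}

#' Read streamlines from TCK or TRK
#'
#' The format is chosen by file magic, not extension. Points are returned in
#' world mm regardless of the on-disk convention (TCK stores world mm
#' directly; TRK stores corner-origin voxel-mm which are mapped through the
#' header's `vox_to_ras` after shifting by half a voxel).
#'
#' @param path File path.
#' @return A [streamline_set].
#' @export
read_streamlines <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 6L)
  close(con); on.exit()
  if (rawToChar(magic) == "mrtrix") return(read_tck(path))
  if (rawToChar(magic[1:5]) == "TRACK") return(read_trk(path))
  stop("unknown streamline file magic in ", path, call. = FALSE)
}

#' Write streamlines to TCK or TRK
#' @param set A [streamline_set].
#' @param path Output path; format chosen by extension (`.tck` or `.trk`).
#' @param affine Voxel-to-world matrix, required for TRK output (defines the
#'   voxel grid the TRK header describes).
#' @return `path`, invisibly.
#' @export
write_streamlines <- function(set, path, affine = NULL) {
  if (grepl("\\.tck$", path, ignore.case = TRUE)) write_tck(set, path)
  else if (grepl("\\.trk$", path, ignore.case = TRUE)) write_trk(set, path, affine)
  else stop("unsupported streamline extension for ", path, call. = FALSE)
  invisible(path)
}

# ---- TCK ----------------------------------------------------------------
# Text header terminated by "END\n", then little-endian float32 triplets;
# (NaN,NaN,NaN) separates streamlines, (Inf,Inf,Inf) terminates the file.

read_tck <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    line <- readBin(con, "raw", n = 1L)
    buf <- raw()
    while (length(line) && line != as.raw(10L)) {
      buf <- c(buf, line)
      line <- readBin(con, "raw", n = 1L)
    }
    txt <- rawToChar(buf)
    if (identical(txt, "END")) break
    header <- c(header, txt)
  }
  if (!length(header) || !grepl("^mrtrix tracks", header[1]))
    stop("not a TCK file: ", path, call. = FALSE)
  kv <- header[grepl(":", header, fixed = TRUE)]
  keys <- sub(":.*$", "", kv)
  vals <- trimws(sub("^[^:]*:", "", kv))
  offset <- as.integer(sub("^.*?([0-9]+)$", "\\1", vals[match("file", keys)]))
  dt <- vals[match("datatype", keys)]
  if (!is.na(dt) && !dt %in% c("Float32LE", "Float32"))
    stop("unsupported TCK datatype ", dt, call. = FALSE)
  seek(con, offset)
  raw_data <- readBin(con, "numeric", size = 4L, endian = "little", n = 3e8)
  pts <- matrix(raw_data, ncol = 3L, byrow = TRUE)
  split_tck_points(pts)
}

split_tck_points <- function(pts) {
  streamlines <- list()
  start <- 1L
  for (i in seq_len(nrow(pts))) {
    if (any(is.nan(pts[i, ])) || any(is.infinite(pts[i, ]))) {
      if (i > start) streamlines[[length(streamlines) + 1L]] <-
          pts[start:(i - 1L), , drop = FALSE]
      start <- i + 1L
      if (any(is.infinite(pts[i, ]))) break
    }
  }
  if (length(streamlines))
    streamlines <- lapply(streamlines, function(m) { dimnames(m) <- NULL; m })
  structure(list(streamlines = streamlines, scores = NULL, meta = list()),
            class = "streamline_set")
}

write_tck <- function(set, path) {
  header <- c("mrtrix tracks",
              "datatype: Float32LE",
              sprintf("count: %d", length(set$streamlines)))
  # 'file: . <offset>' must state its own byte offset; fixed-width pad keeps
  # the offset independent of the number it prints
  fixed <- paste0(paste(header, collapse = "\n"), "\n")
  off <- nchar(paste0(fixed, sprintf("file: . %-6d\nEND\n", 0L)), type = "bytes")
  hdr <- paste0(fixed, sprintf("file: . %-6d\nEND\n", off))
  stopifnot(nchar(hdr, type = "bytes") == off)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(hdr), con)
  for (s in set$streamlines) {
    writeBin(as.vector(t(s)), con, size = 4L, endian = "little")
    writeBin(rep(NaN, 3L), con, size = 4L, endian = "little")
  }
  writeBin(rep(Inf, 3L), con, size = 4L, endian = "little")
  invisible(path)
}

# ---- TRK ----------------------------------------------------------------
# 1000-byte binary header. Points are stored in corner-origin voxel-mm:
# world = vox_to_ras %*% (p / voxel_size - 0.5) for voxel-centre indexing.

read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 1000L)
  if (rawToChar(hdr[1:5]) != "TRACK") stop("not a TRK file: ", path, call. = FALSE)
  rd <- function(what, off, n, size) {
    readBin(hdr[(off + 1L):(off + n * size)], what, n = n, size = size,
            endian = "little")
  }
  voxel_size <- rd("numeric", 12L, 3L, 4L)
  n_scalars <- rd("integer", 36L, 1L, 2L)
  n_props <- rd("integer", 236L, 1L, 2L)
  vox_to_ras <- matrix(rd("numeric", 440L, 16L, 4L), 4L, 4L, byrow = TRUE)
  n_count <- rd("integer", 988L, 1L, 4L)
  if (all(vox_to_ras == 0)) {
    vox_to_ras <- diag(4)
    diag(vox_to_ras)[1:3] <- voxel_size
  }
  streamlines <- vector("list", n_count)
  for (i in seq_len(n_count)) {
    m <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    vals <- readBin(con, "numeric", n = m * (3L + n_scalars), size = 4L,
                    endian = "little")
    if (n_props > 0L) readBin(con, "numeric", n = n_props, size = 4L,
                              endian = "little")
    pm <- matrix(vals, ncol = 3L + n_scalars, byrow = TRUE)[, 1:3, drop = FALSE]
    idx <- sweep(pm, 2L, voxel_size, "/") - 0.5
    streamlines[[i]] <- voxel_to_world(idx, vox_to_ras)
  }
  structure(list(streamlines = streamlines, scores = NULL, meta = list()),
            class = "streamline_set")
}

write_trk <- function(set, path, affine = NULL) {
  if (is.null(affine)) affine <- diag(4)
  voxel_size <- voxel_dims_mm(affine)
  hdr <- raw(1000L)
  put <- function(hdr, bytes, off) { hdr[(off + 1L):(off + length(bytes))] <- bytes; hdr }
  hdr <- put(hdr, charToRaw("TRACK"), 0L)
  hdr <- put(hdr, writeBin(c(1L, 1L, 1L), raw(), size = 2L, endian = "little"), 6L)
  hdr <- put(hdr, writeBin(voxel_size, raw(), size = 4L, endian = "little"), 12L)
  hdr <- put(hdr, writeBin(0L, raw(), size = 2L, endian = "little"), 36L)   # n_scalars
  hdr <- put(hdr, writeBin(0L, raw(), size = 2L, endian = "little"), 236L)  # n_properties
  hdr <- put(hdr, writeBin(as.vector(t(affine)), raw(), size = 4L,
                           endian = "little"), 440L)
  hdr <- put(hdr, charToRaw("RAS"), 948L)
  hdr <- put(hdr, writeBin(length(set$streamlines), raw(), size = 4L,
                           endian = "little"), 988L)
  hdr <- put(hdr, writeBin(2L, raw(), size = 4L, endian = "little"), 992L)  # version
  hdr <- put(hdr, writeBin(1000L, raw(), size = 4L, endian = "little"), 996L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  for (s in set$streamlines) {
    idx <- world_to_voxel(s, affine)
    pm <- sweep(idx + 0.5, 2L, voxel_size, "*")
    writeBin(nrow(pm), con, size = 4L, endian = "little")
    writeBin(as.vector(t(pm)), con, size = 4L, endian = "little")
  }
  invisible(path)
}
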