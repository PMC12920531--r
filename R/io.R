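#' Read a labeled point cloud
#'
#' Supported formats:
#' \describe{
#'   \item{`xyz_table`}{whitespace-separated ASCII, `#` comment lines
#'     skipped; columns dispatched by count: 3 = `x y z`, 4 = `x y z label`,
#'     6 = `x y z r g b`, 7 = `x y z r g b label`.}
#'   \item{`ply`}{PLY, `ascii` or `binary_little_endian`; per-vertex float
#'     properties `x`, `y`, `z`, optional uchar `red`, `green`, `blue` and an
#'     optional integer scalar property `label`.}
#'   \item{`fixture`}{a plain-text dataset directory written by
#'     [write_fixture_dir()]; `sample` selects the entry (default: first).}
#' }
#'
#' @param path file (or fixture directory) to read.
#' @param format one of `"auto"`, `"xyz_table"`, `"ply"`, `"fixture"`.
#'   `"auto"` dispatches on the extension (`.ply` vs anything else) and on
#'   `path` being a directory.
#' @param sample for fixtures, the sample id to load.
#' @return a [point_cloud()].
#' @export
read_point_cloud <- function(path, format = c("auto", "xyz_table", "ply",
                                              "fixture"),
                             sample = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "fixture"
    else if (grepl("\\.ply$", path, ignore.case = TRUE)) "ply"
    else "xyz_table"
  }
  if (format != "fixture" && !file.exists(path))
    abort(sprintf("file not found: %s", path))
  switch(format,
         xyz_table = read_xyz_table(path),
         ply = read_ply(path),
         fixture = {
           clouds <- read_fixture_dir(path)
           if (is.null(sample)) clouds[[1]]
           else {
             ids <- vapply(clouds, attr, "", "sample_id")
             if (!sample %in% ids)
               abort(sprintf("sample '%s' not in fixture", sample))
             clouds[[match(sample, ids)]]
           }
         })
}

#' Write a point cloud
#'
#' Inverse of [read_point_cloud()]; `write_point_cloud() |> read_point_cloud()`
#' is the identity on coordinates (to float32 precision for binary PLY),
#' labels, and colors (to 8-bit precision in PLY, where colors are stored as
#' uchar).  Predicted labels are exported exactly like ground-truth labels.
#'
#' @param cloud a [point_cloud()].
#' @param path output file.
#' @param format `"auto"` (from extension), `"xyz_table"`, `"ply"`.
#' @param binary for PLY, write `binary_little_endian` (default) or `ascii`.
#' @param attention optional numeric vector of per-point scalars in (0, 1)
#'   (e.g. spatial-attention gates) written as an extra float property
#'   `attention` in PLY for heatmap rendering.
#' @return `path`, invisibly.
#' @export
write_point_cloud <- function(cloud, path,
                              format = c("auto", "xyz_table", "ply"),
                              binary = TRUE, attention = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.ply$", path, ignore.case = TRUE)) "ply"
              else "xyz_table"
  switch(format,
         xyz_table = write_xyz_table(cloud, path),
         ply = write_ply(cloud, path, binary = binary, attention = attention))
  invisible(path)
}

read_xyz_table <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- strsplit(trimws(lines[keep]), "\\s+")
  lineno <- which(keep)
  if (length(rows) == 0) abort(sprintf("empty point cloud in %s", path))
  nc <- lengths(rows)
  if (!all(nc == nc[1]) || !nc[1] %in% c(3, 4, 6, 7)) {
    bad <- which(!nc %in% c(3, 4, 6, 7) | nc != nc[1])[1]
    abort(sprintf("parse error at line %d of %s: %d columns (expected %s)",
                  lineno[bad], path, nc[bad], "3, 4, 6 or 7"))
  }
  vals <- suppressWarnings(as.numeric(unlist(rows)))
  if (anyNA(vals)) {
    bad <- lineno[ceiling(which(is.na(vals))[1] / nc[1])]
    abort(sprintf("parse error at line %d of %s: non-numeric field",
                  bad, path))
  }
  m <- matrix(vals, ncol = nc[1], byrow = TRUE)
  point_cloud(m[, 1:3, drop = FALSE],
              colors = if (nc[1] >= 6) m[, 4:6, drop = FALSE],
              labels = switch(as.character(nc[1]), "4" = m[, 4], "7" = m[, 7]),
              sample_id = sub("\\.[^.]*$", "", basename(path)))
}

write_xyz_table <- function(cloud, path) {
  cols <- list(cloud$x, cloud$y, cloud$z)
  if ("r" %in% names(cloud)) cols <- c(cols, list(cloud$r, cloud$g, cloud$b))
  if ("label" %in% names(cloud)) cols <- c(cols, list(cloud$label))
  txt <- do.call(paste, c(lapply(cols, function(v)
    if (is.integer(v)) as.character(v) else sprintf("%.9g", v))))
  ok <- tryCatch({ writeLines(txt, path); TRUE }, error = function(e) FALSE)
  if (!ok) abort(sprintf("cannot write %s", path))
  invisible(path)
}

ply_header <- function(n, has_color, has_label, has_att, binary) {
  c("ply",
    sprintf("format %s 1.0",
            if (binary) "binary_little_endian" else "ascii"),
    sprintf("element vertex %d", n),
    "property float x", "property float y", "property float z",
    if (has_color) c("property uchar red", "property uchar green",
                     "property uchar blue"),
    if (has_label) "property int label",
    if (has_att) "property float attention",
    "end_header")
}

write_ply <- function(cloud, path, binary = TRUE, attention = NULL) {
  n <- nrow(cloud)
  has_color <- "r" %in% names(cloud)
  has_label <- "label" %in% names(cloud)
  hdr <- ply_header(n, has_color, has_label, !is.null(attention), binary)
  con <- tryCatch(file(path, "wb"), error = function(e)
    abort(sprintf("cannot write %s", path)))
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  col255 <- if (has_color)
    matrix(pmin(255L, pmax(0L, as.integer(round(255 * cbind(cloud$r, cloud$g,
                                                            cloud$b))))),
           ncol = 3)
  if (binary) {
    xyzraw <- matrix(writeBin(as.numeric(t(pc_coords(cloud))), raw(),
                              size = 4, endian = "little"), nrow = 12)
    rec <- xyzraw
    if (has_color)
      rec <- rbind(rec, matrix(as.raw(t(col255)), nrow = 3))
    if (has_label)
      rec <- rbind(rec, matrix(writeBin(as.integer(cloud$label), raw(),
                                        size = 4, endian = "little"),
                               nrow = 4))
    if (!is.null(attention))
      rec <- rbind(rec, matrix(writeBin(as.numeric(attention), raw(),
                                        size = 4, endian = "little"),
                               nrow = 4))
    writeBin(as.vector(rec), con)
  } else {
    parts <- list(sprintf("%.9g", cloud$x), sprintf("%.9g", cloud$y),
                  sprintf("%.9g", cloud$z))
    if (has_color)
      parts <- c(parts, lapply(1:3, function(j) as.character(col255[, j])))
    if (has_label) parts <- c(parts, list(as.character(cloud$label)))
    if (!is.null(attention))
      parts <- c(parts, list(sprintf("%.9g", attention)))
    writeLines(do.call(paste, parts), con)
  }
  invisible(path)
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    ln <- readLines(con, n = 1)
    if (length(ln) == 0) abort(sprintf("truncated PLY header in %s", path))
    hdr <- c(hdr, ln)
    if (ln == "end_header") break
  }
  fmt <- sub("^format ", "", grep("^format ", hdr, value = TRUE))
  binary <- grepl("binary_little_endian", fmt)
  if (!binary && !grepl("ascii", fmt))
    abort(sprintf("unsupported PLY format '%s'", fmt))
  n <- as.integer(sub("^element vertex ", "",
                      grep("^element vertex ", hdr, value = TRUE)[1]))
  if (is.na(n) || n < 1) abort(sprintf("empty or invalid PLY %s", path))
  props <- strsplit(grep("^property ", hdr, value = TRUE), "\\s+")
  ptype <- vapply(props, `[`, "", 2)
  pname <- vapply(props, `[`, "", 3)
  sizes <- c(float = 4L, float32 = 4L, int = 4L, int32 = 4L,
             uchar = 1L, uint8 = 1L)
  if (!all(ptype %in% names(sizes)))
    abort(sprintf("unsupported PLY property type in %s", path))
  psize <- sizes[ptype]
  vals <- if (binary) {
    rec <- sum(psize)
    buf <- readBin(con, raw(), n = rec * n)
    if (length(buf) < rec * n) abort(sprintf("truncated PLY data in %s", path))
    bufm <- matrix(buf, nrow = rec)
    off <- cumsum(c(0L, psize))
    lapply(seq_along(pname), function(j) {
      bytes <- as.vector(bufm[off[j] + seq_len(psize[j]), , drop = FALSE])
      if (psize[j] == 1) as.integer(bytes)
      else readBin(bytes, if (ptype[j] %in% c("int", "int32")) "integer"
                   else "numeric", n = n, size = 4, endian = "little")
    })
  } else {
    txt <- readLines(con)
    txt <- txt[nzchar(trimws(txt))][seq_len(n)]
    m <- matrix(as.numeric(unlist(strsplit(trimws(txt), "\\s+"))),
                ncol = length(pname), byrow = TRUE)
    lapply(seq_along(pname), function(j) m[, j])
  }
  names(vals) <- pname
  point_cloud(cbind(vals$x, vals$y, vals$z),
              colors = if (all(c("red", "green", "blue") %in% pname))
                cbind(vals$red, vals$green, vals$blue) / 255,
              labels = vals$label,
              sample_id = sub("\\.[^.]*$", "", basename(path)))
}

#' Write a multi-sample fixture directory
#'
#' The dataset container used by the synthetic generator and the training
#' commands: a directory holding one ASCII `x y z label` table per sample
#' plus a `manifest.tsv` (sample_id, file, n_points) and an optional
#' `classes.txt` sidecar with one organ name per line (line `i` names label
#' `i - 1`).
#'
#' @param clouds list of [point_cloud()]s.
#' @param dir output directory (created if needed).
#' @param class_names optional character vector of class names.
#' @return `dir`, invisibly.
#' @export
write_fixture_dir <- function(clouds, dir, class_names = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) abort(sprintf("cannot create %s", dir))
  ids <- vapply(clouds, attr, "", "sample_id")
  files <- paste0(ids, ".xyz")
  for (i in seq_along(clouds))
    write_xyz_table(clouds[[i]], file.path(dir, files[i]))
  man <- data.frame(sample_id = ids, file = files,
                    n_points = vapply(clouds, nrow, 0L))
  if (all(vapply(clouds, function(p) "label" %in% names(p), TRUE))) {
    M <- max(vapply(clouds, function(p) max(p$label), 0L)) + 1L
    hist <- t(vapply(clouds, function(p)
      as.integer(table(factor(p$label, levels = 0:(M - 1)))), integer(M)))
    colnames(hist) <- paste0("n_class", 0:(M - 1))
    man <- cbind(man, hist)
  }
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (is.null(class_names))
    class_names <- attr(clouds[[1]], "class_names")
  if (!is.null(class_names))
    writeLines(class_names, file.path(dir, "classes.txt"))
  invisible(dir)
}

#' Read a fixture directory
#'
#' @param dir a directory written by [write_fixture_dir()].
#' @return list of [point_cloud()]s, named by sample id.
#' @export
read_fixture_dir <- function(dir) {
  manifest <- file.path(dir, "manifest.tsv")
  if (!file.exists(manifest))
    abort(sprintf("no manifest.tsv under %s", dir))
  man <- utils::read.table(manifest, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  cls <- file.path(dir, "classes.txt")
  class_names <- if (file.exists(cls)) readLines(cls)
  clouds <- lapply(seq_len(nrow(man)), function(i) {
    pc <- read_xyz_table(file.path(dir, man$file[i]))
    attr(pc, "sample_id") <- man$sample_id[i]
    attr(pc, "class_names") <- class_names
    pc
  })
  names(clouds) <- man$sample_id
  clouds
}
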