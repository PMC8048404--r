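## PLY and OBJ readers/writers for metrology meshes.
## PLY: ascii 1.0 and binary_little_endian 1.0, vertex x/y/z (float or
## double) plus a uchar-counted integer face list; other per-element
## properties are skipped. OBJ: v and f records; texture/normal slots in
## f (a/b/c syntax) are ignored, polygons are fan-triangulated.

#' Read a triangle mesh
#'
#' Dispatches on the file extension: `.ply` (ASCII or binary little-endian)
#' or `.obj`.
#'
#' @param path mesh file path.
#' @return a [tri_mesh()].
#' @export
read_mesh <- function(path) {
  switch(tolower(tools::file_ext(path)),
         ply = read_ply(path),
         obj = read_obj(path),
         stop("unsupported mesh format: ", path))
}

#' @rdname read_mesh
#' @export
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character(0)
  repeat {
    line <- readLines(con, n = 1L)
    header <- c(header, line)
    if (identical(trimws(line), "end_header")) break
    if (length(header) > 500L) stop("read_ply: header not terminated")
  }
  if (!identical(trimws(header[1L]), "ply")) stop("read_ply: not a PLY file")
  fmt_line <- grep("^format ", header, value = TRUE)[1L]
  fmt <- strsplit(trimws(fmt_line), "\\s+")[[1L]][2L]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop("read_ply: unsupported format ", fmt)

  ## parse element/property declarations in order
  elements <- list()
  cur <- NULL
  for (line in header) {
    tok <- strsplit(trimws(line), "\\s+")[[1L]]
    if (tok[1L] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2L], count = as.integer(tok[3L]), props = list())
    } else if (tok[1L] == "property" && !is.null(cur)) {
      cur$props[[length(cur$props) + 1L]] <-
        if (tok[2L] == "list") list(list = TRUE, count_type = tok[3L],
                                    type = tok[4L], name = tok[5L])
        else list(list = FALSE, type = tok[2L], name = tok[3L])
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur

  type_info <- function(t) switch(t,
    char = , int8 = list(what = "integer", size = 1L, signed = TRUE),
    uchar = , uint8 = list(what = "integer", size = 1L, signed = FALSE),
    short = , int16 = list(what = "integer", size = 2L, signed = TRUE),
    ushort = , uint16 = list(what = "integer", size = 2L, signed = FALSE),
    int = , int32 = list(what = "integer", size = 4L, signed = TRUE),
    uint = , uint32 = list(what = "integer", size = 4L, signed = TRUE),
    float = , float32 = list(what = "numeric", size = 4L, signed = TRUE),
    double = , float64 = list(what = "numeric", size = 8L, signed = TRUE),
    stop("read_ply: unknown type ", t))

  verts <- NULL; faces <- list()
  if (fmt == "ascii") {
    body <- readLines(con)
    body <- body[nzchar(trimws(body))]
    pos <- 0L
    for (el in elements) {
      rows <- body[pos + seq_len(el$count)]
      pos <- pos + el$count
      toks <- strsplit(trimws(rows), "\\s+")
      if (el$name == "vertex") {
        nm <- vapply(el$props, `[[`, character(1L), "name")
        xi <- match(c("x", "y", "z"), nm)
        verts <- t(vapply(toks, function(tk)
          as.numeric(tk[xi]), numeric(3L)))
      } else if (el$name == "face") {
        faces <- lapply(toks, function(tk) {
          k <- as.integer(tk[1L])
          as.integer(tk[1L + seq_len(k)])
        })
      }
    }
  } else {
    for (el in elements) {
      is_list <- vapply(el$props, `[[`, logical(1L), "list")
      if (el$name == "vertex" && !any(is_list)) {
        infos <- lapply(el$props, function(p) type_info(p$type))
        nm <- vapply(el$props, `[[`, character(1L), "name")
        rec <- matrix(NA_real_, el$count, length(infos))
        for (i in seq_len(el$count))
          for (j in seq_along(infos)) {
            ti <- infos[[j]]
            rec[i, j] <- readBin(con, ti$what, 1L, size = ti$size,
                                 signed = ti$signed, endian = "little")
          }
        verts <- rec[, match(c("x", "y", "z"), nm), drop = FALSE]
      } else {
        for (i in seq_len(el$count)) {
          for (p in el$props) {
            if (p$list) {
              ci <- type_info(p$count_type); vi <- type_info(p$type)
              k <- readBin(con, ci$what, 1L, size = ci$size,
                           signed = ci$signed, endian = "little")
              vals <- readBin(con, vi$what, k, size = vi$size,
                              signed = vi$signed, endian = "little")
              if (el$name == "face")
                faces[[length(faces) + 1L]] <- c(k, as.integer(vals))
            } else {
              ti <- type_info(p$type)
              readBin(con, ti$what, 1L, size = ti$size, signed = ti$signed,
                      endian = "little")
            }
          }
        }
      }
    }
    faces <- lapply(faces, function(f) f[1L + seq_len(f[1L])])
  }
  tri_mesh(verts, triangulate_fans(faces) + 1L)  # PLY indices are 0-based
}

## fan-triangulate polygon index lists (0-based in, 0-based out)
triangulate_fans <- function(faces) {
  tris <- lapply(faces, function(f) {
    if (length(f) < 3L) return(NULL)
    cbind(f[1L], f[2:(length(f) - 1L)], f[3:length(f)])
  })
  out <- do.call(rbind, tris)
  if (is.null(out)) matrix(integer(0), 0L, 3L) else out
}

#' @rdname read_mesh
#' @export
read_obj <- function(path) {
  lines <- readLines(path)
  vt <- grep("^v\\s", lines, value = TRUE)
  ft <- grep("^f\\s", lines, value = TRUE)
  verts <- t(vapply(strsplit(trimws(vt), "\\s+"), function(tk)
    as.numeric(tk[2:4]), numeric(3L)))
  faces <- lapply(strsplit(trimws(ft), "\\s+"), function(tk) {
    idx <- vapply(tk[-1L], function(s)
      as.integer(strsplit(s, "/", fixed = TRUE)[[1L]][1L]), integer(1L))
    idx - 1L  # to 0-based for the shared triangulator
  })
  tri_mesh(verts, triangulate_fans(faces) + 1L)
}

#' Write a triangle mesh
#'
#' `write_ply()` emits ASCII PLY; `write_obj()` emits v/f records. Dispatch
#' by extension with `write_mesh()`.
#'
#' @param mesh a [tri_mesh()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  switch(tolower(tools::file_ext(path)),
         ply = write_ply(mesh, path),
         obj = write_obj(mesh, path),
         stop("unsupported mesh format: ", path))
}

#' @rdname write_mesh
#' @export
write_ply <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]), con)
  if (nrow(f) > 0L)
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  invisible(path)
}

#' @rdname write_mesh
#' @export
write_obj <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  lines <- c(sprintf("v %.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]),
             if (nrow(f) > 0L) sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]))
  writeLines(lines, path)
  invisible(path)
}
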