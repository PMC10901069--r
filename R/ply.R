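#' Read a colored scan from a PLY file
#'
#' Reads a Stanford PLY surface triangulation with per-vertex `x,y,z`
#' coordinates and `red,green,blue` colors, the format emitted by phone
#' depth-scanner apps. ASCII and binary-little-endian dialects are
#' supported; big-endian files are rejected. If the bounding-box diagonal
#' is below 10 (i.e. the file is plausibly in metres rather than
#' millimetres) coordinates are scaled by 1000, with a message.
#'
#' @param path path to a `.ply` file.
#' @param require_color error (class `scan2fem_no_color`) when the file has
#'   no red/green/blue vertex properties.
#' @return a [colored_surface()] in mm.
#' @export
read_scan <- function(path, require_color = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- ply_read_header(con)
  if (hdr$format == "binary_big_endian")
    stop("big-endian PLY is not supported (scanner output is little-endian)")
  velem <- hdr$elements[["vertex"]]
  felem <- hdr$elements[["face"]]
  if (is.null(velem) || is.null(felem))
    stop(ply_err("parse", "PLY lacks vertex or face element"))
  pn <- velem$props$name
  if (!all(c("x", "y", "z") %in% pn))
    stop(ply_err("parse", "PLY lacks x,y,z vertex properties"))
  has_color <- all(c("red", "green", "blue") %in% pn)
  if (require_color && !has_color)
    stop(ply_err("no_color", "PLY has no red/green/blue vertex properties"))

  if (hdr$format == "ascii") {
    dat <- ply_read_ascii(con, hdr)
  } else {
    dat <- ply_read_binary(con, hdr)
  }
  vertices <- cbind(dat$vertex[["x"]], dat$vertex[["y"]], dat$vertex[["z"]])
  if (anyNA(vertices)) stop(ply_err("parse", "truncated or corrupt PLY vertex data"))
  colors <- NULL
  if (has_color)
    colors <- cbind(dat$vertex[["red"]], dat$vertex[["green"]], dat$vertex[["blue"]])
  faces <- dat$faces + 1L  # PLY is 0-based
  s <- colored_surface(vertices, faces, colors)
  diag_len <- sqrt(sum((apply(s$vertices, 2, max) - apply(s$vertices, 2, min))^2))
  if (diag_len < 10) {
    message("read_scan: bounding-box diagonal ", signif(diag_len, 3),
            " < 10; interpreting coordinates as metres, scaling by 1000")
    s$vertices <- s$vertices * 1000
  }
  clean_surface(s)
}

ply_err <- function(kind, msg) {
  structure(class = c(paste0("scan2fem_", kind), "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)
ply_is_float <- function(t) t %in% c("float", "float32", "double", "float64")

ply_read_header <- function(con) {
  magic <- readLines(con, n = 1L)
  if (!identical(trimws(magic), "ply")) stop(ply_err("parse", "not a PLY file"))
  format <- NULL
  elements <- list()
  cur <- NULL
  order <- character()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop(ply_err("parse", "PLY header truncated"))
    tok <- strsplit(trimws(line), "\\s+")[[1L]]
    if (length(tok) == 0L || tok[1L] == "comment" || tok[1L] == "obj_info") next
    if (tok[1L] == "format") {
      format <- tok[2L]
    } else if (tok[1L] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2L], count = as.integer(tok[3L]),
                  props = data.frame(name = character(), type = character(),
                                     list_count_type = character(),
                                     stringsAsFactors = FALSE))
      order <- c(order, tok[2L])
    } else if (tok[1L] == "property") {
      if (is.null(cur)) stop(ply_err("parse", "property before element"))
      if (tok[2L] == "list") {
        cur$props <- rbind(cur$props,
                           data.frame(name = tok[5L], type = tok[4L],
                                      list_count_type = tok[3L],
                                      stringsAsFactors = FALSE))
      } else {
        cur$props <- rbind(cur$props,
                           data.frame(name = tok[3L], type = tok[2L],
                                      list_count_type = NA_character_,
                                      stringsAsFactors = FALSE))
      }
    } else if (tok[1L] == "end_header") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      break
    }
  }
  list(format = format, elements = elements, order = order)
}

ply_read_ascii <- function(con, hdr) {
  txt <- readLines(con)
  txt <- txt[nzchar(trimws(txt))]
  pos <- 0L
  out <- list()
  for (nm in hdr$order) {
    el <- hdr$elements[[nm]]
    lines <- txt[pos + seq_len(el$count)]
    if (anyNA(lines)) stop(ply_err("parse", "truncated ASCII PLY"))
    pos <- pos + el$count
    if (nm == "vertex") {
      m <- matrix(as.numeric(unlist(strsplit(trimws(lines), "\\s+"),
                                    use.names = FALSE)),
                  nrow = el$count, byrow = TRUE)
      if (ncol(m) != nrow(el$props)) stop(ply_err("parse", "vertex column mismatch"))
      cols <- list()
      for (j in seq_len(ncol(m))) cols[[el$props$name[j]]] <- m[, j]
      out$vertex <- cols
    } else if (nm == "face") {
      toks <- strsplit(trimws(lines), "\\s+")
      cnt <- vapply(toks, function(t) as.integer(t[1L]), 1L)
      if (any(cnt != 3L)) stop(ply_err("parse", "non-triangular PLY faces"))
      out$faces <- matrix(as.integer(unlist(lapply(toks, function(t) t[2:4]),
                                            use.names = FALSE)),
                          ncol = 3L, byrow = TRUE)
    }
  }
  out
}

ply_read_binary <- function(con, hdr) {
  out <- list()
  for (nm in hdr$order) {
    el <- hdr$elements[[nm]]
    if (nm == "vertex") {
      sizes <- ply_type_size[el$props$type]
      if (anyNA(sizes)) stop(ply_err("parse", "unknown vertex property type"))
      rec <- sum(sizes)
      raw <- readBin(con, "raw", n = rec * el$count)
      if (length(raw) < rec * el$count) stop(ply_err("parse", "truncated binary PLY"))
      m <- matrix(raw, nrow = rec)
      cols <- list()
      off <- 0L
      for (j in seq_len(nrow(el$props))) {
        sz <- sizes[j]
        bytes <- as.vector(m[off + seq_len(sz), , drop = FALSE])
        ty <- el$props$type[j]
        val <- if (ply_is_float(ty)) {
          readBin(bytes, "double", n = el$count, size = sz, endian = "little")
        } else {
          readBin(bytes, "integer", n = el$count, size = sz, endian = "little",
                  signed = !(sz < 4L && grepl("^u", ty)))
        }
        cols[[el$props$name[j]]] <- val
        off <- off + sz
      }
      out$vertex <- cols
    } else if (nm == "face") {
      p <- el$props[el$props$name %in% c("vertex_indices", "vertex_index"), ]
      if (nrow(p) != 1L) stop(ply_err("parse", "face element lacks index list"))
      csz <- ply_type_size[p$list_count_type]
      isz <- ply_type_size[p$type]
      rec <- csz + 3L * isz
      raw <- readBin(con, "raw", n = rec * el$count)
      if (length(raw) < rec * el$count) stop(ply_err("parse", "truncated binary PLY"))
      m <- matrix(raw, nrow = rec)
      cnt <- readBin(as.vector(m[seq_len(csz), , drop = FALSE]), "integer",
                     n = el$count, size = csz, endian = "little", signed = csz >= 4L)
      if (any(cnt != 3L)) stop(ply_err("parse", "non-triangular PLY faces"))
      idx <- matrix(0L, el$count, 3L)
      for (j in 1:3) {
        bytes <- as.vector(m[csz + (j - 1L) * isz + seq_len(isz), , drop = FALSE])
        idx[, j] <- readBin(bytes, "integer", n = el$count, size = isz,
                            endian = "little")
      }
      out$faces <- idx
    }
  }
  out
}

#' Write a colored surface to a PLY file
#'
#' Round-trips with [read_scan()]: coordinates are stored as 32-bit floats
#' (lossless to well under 1e-4 mm at thorax scale) and colors as bytes
#' (lossless).
#'
#' @param surface a [colored_surface()]. Uncolored surfaces are written
#'   white.
#' @param path output path.
#' @param format `"binary_little_endian"` (default) or `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_scan <- function(surface, path, format = c("binary_little_endian", "ascii")) {
  format <- match.arg(format)
  v <- surface$vertices
  f <- surface$faces - 1L
  cols <- surface$colors
  if (is.null(cols)) cols <- matrix(255L, nrow(v), 3L)
  hdr <- c("ply",
           paste("format", format, "1.0"),
           paste("element vertex", nrow(v)),
           "property float x", "property float y", "property float z",
           "property uchar red", "property uchar green", "property uchar blue",
           paste("element face", nrow(f)),
           "property list uchar int vertex_indices",
           "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  if (format == "ascii") {
    vl <- paste(format(v[, 1], trim = TRUE), format(v[, 2], trim = TRUE),
                format(v[, 3], trim = TRUE), cols[, 1], cols[, 2], cols[, 3])
    writeLines(vl, con)
    writeLines(paste(3L, f[, 1], f[, 2], f[, 3]), con)
  } else {
    # interleave per-vertex records: 3 float32 + 3 uint8
    fraw <- writeBin(as.numeric(t(v)), raw(), size = 4L, endian = "little")
    fm <- matrix(fraw, nrow = 12L)
    craw <- as.raw(t(cols))
    cm <- matrix(craw, nrow = 3L)
    writeBin(as.vector(rbind(fm, cm)), con)
    fr <- writeBin(as.integer(t(f)), raw(), size = 4L, endian = "little")
    frm <- matrix(fr, nrow = 12L)
    cnt <- matrix(as.raw(3L), nrow = 1L, ncol = ncol(frm))
    writeBin(as.vector(rbind(cnt, frm)), con)
  }
  invisible(path)
}
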