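#' Read an ASCII triangle mesh (OFF or PLY)
#'
#' Minimal line-based readers for the two common ASCII mesh formats. Faces
#' with more than three vertices are fan-triangulated. Vertex indices in the
#' files are 0-based (the formats' convention) and converted to 1-based.
#'
#' @param path Path to an `.off` or `.ply` file (format sniffed from the
#'   header, not the extension).
#' @return A list with `vertices` (V x 3 matrix) and `faces` (F x 3 integer
#'   matrix, 1-based).
#' @export
read_mesh <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (toupper(lines[[1]]) == "OFF") {
    read_mesh_off(lines)
  } else if (toupper(lines[[1]]) == "PLY") {
    read_mesh_ply(lines)
  } else {
    abort("Unrecognized mesh header; expected ASCII OFF or PLY.")
  }
}

split_nums <- function(line) as.numeric(strsplit(line, "\\s+")[[1]])

read_mesh_off <- function(lines) {
  counts <- split_nums(lines[[2]])
  nv <- counts[1]; nf <- counts[2]
  vs <- t(vapply(lines[3:(2 + nv)], split_nums, numeric(3), USE.NAMES = FALSE))
  fl <- lines[(3 + nv):(2 + nv + nf)]
  faces <- do.call(rbind, lapply(fl, function(l) {
    x <- split_nums(l)
    fan_triangulate(x[-1] + 1)
  }))
  list(vertices = vs, faces = faces)
}

read_mesh_ply <- function(lines) {
  hdr_end <- which(lines == "end_header")[1]
  hdr <- lines[seq_len(hdr_end)]
  if (!any(grepl("^format\\s+ascii", hdr))) abort("Only ASCII PLY is supported.")
  nv <- as.integer(sub(".*vertex\\s+", "", grep("^element vertex", hdr, value = TRUE)[1]))
  nf <- as.integer(sub(".*face\\s+", "", grep("^element face", hdr, value = TRUE)[1]))
  body <- lines[(hdr_end + 1):length(lines)]
  vs <- t(vapply(body[seq_len(nv)], function(l) split_nums(l)[1:3], numeric(3),
                 USE.NAMES = FALSE))
  fl <- body[(nv + 1):(nv + nf)]
  faces <- do.call(rbind, lapply(fl, function(l) {
    x <- split_nums(l)
    fan_triangulate(x[2:(1 + x[1])] + 1)
  }))
  list(vertices = vs, faces = faces)
}

fan_triangulate <- function(idx) {
  if (length(idx) < 3) abort("Face with fewer than 3 vertices.")
  cbind(idx[1], idx[seq(2, length(idx) - 1)], idx[seq(3, length(idx))])
}
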