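#' Particle annotation lists
#'
#' Particle annotations are kept as a tibble with one row per particle and
#' columns `tomogram` (id), `x`, `y`, `z` (0-based voxel coordinates),
#' `phi`, `theta`, `psi` (degrees, ZXZ anticlockwise, template-to-particle
#' rotation) and `score` (LCCmax in `[-1, 1]`). The voxel size (Å) and
#' tomogram dimensions ride along as attributes.
#'
#' @param tomogram character id(s) of the source tomogram.
#' @param x,y,z 0-based voxel coordinates.
#' @param phi,theta,psi Euler angles in degrees (ZXZ anticlockwise).
#' @param score LCCmax values.
#' @param voxel_size voxel size in angstrom (optional but needed for
#'   angstrom output and spatial analyses).
#' @param tomogram_dims integer dimensions of the source tomogram
#'   (optional; positions are checked against them when present).
#' @return A tibble of class `particle_list`.
#' @export
particle_list <- function(tomogram = "tomogram", x = numeric(), y = numeric(),
                          z = numeric(), phi = 0, theta = 0, psi = 0,
                          score = NA_real_, voxel_size = NULL,
                          tomogram_dims = NULL) {
  df <- tibble::tibble(tomogram = tomogram, x = x, y = y, z = z,
                       phi = phi, theta = theta, psi = psi, score = score)
  as_particle_list(df, voxel_size = voxel_size, tomogram_dims = tomogram_dims)
}

#' @rdname particle_list
#' @param df data frame with the particle-list columns.
#' @export
as_particle_list <- function(df, voxel_size = NULL, tomogram_dims = NULL) {
  need <- c("tomogram", "x", "y", "z", "phi", "theta", "psi", "score")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing particle columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  df <- tibble::as_tibble(df)[need]
  if (nrow(df) && any(abs(df$score) > 1 + 1e-6, na.rm = TRUE))
    stop("scores must lie in [-1, 1]", call. = FALSE)
  if (!is.null(tomogram_dims) && nrow(df)) {
    ok <- df$x >= 0 & df$x < tomogram_dims[1] &
      df$y >= 0 & df$y < tomogram_dims[2] &
      df$z >= 0 & df$z < tomogram_dims[3]
    if (!all(ok)) stop("particle positions outside tomogram bounds", call. = FALSE)
  }
  structure(df, class = c("particle_list", class(tibble::tibble())),
            voxel_size = voxel_size, tomogram_dims = tomogram_dims)
}

particle_voxel_size <- function(particles, voxel_size = NULL) {
  vs <- if (!is.null(voxel_size)) voxel_size else attr(particles, "voxel_size")
  if (is.null(vs) || !is.finite(vs) || vs <= 0)
    stop("voxel size missing: supply `voxel_size` or set it on the particle list",
         call. = FALSE)
  vs
}

#' Read and write the native XML particle list
#'
#' The native schema is a `<ParticleList>` root carrying the voxel size
#' and tomogram dimensions as attributes, with one `<Particle>` element
#' per annotation holding `Tomogram`, `X`, `Y`, `Z` (0-based voxels),
#' `Phi`, `Theta`, `Psi` (degrees, ZXZ anticlockwise) and `Score`.
#'
#' @param particles a [particle_list] tibble.
#' @param path file path.
#' @return `read_particle_xml` returns a `particle_list`;
#'   `write_particle_xml` returns `path` invisibly.
#' @export
write_particle_xml <- function(particles, path) {
  doc <- xml2::xml_new_root("ParticleList")
  vs <- attr(particles, "voxel_size")
  dims <- attr(particles, "tomogram_dims")
  if (!is.null(vs)) xml2::xml_set_attr(doc, "VoxelSize", format(vs, digits = 15))
  if (!is.null(dims))
    xml2::xml_set_attr(doc, "TomogramDims", paste(dims, collapse = " "))
  if (nrow(particles)) {
    for (i in seq_len(nrow(particles))) {
      p <- particles[i, ]
      xml2::xml_add_child(
        doc, "Particle",
        Tomogram = p$tomogram,
        X = format(p$x, digits = 15), Y = format(p$y, digits = 15),
        Z = format(p$z, digits = 15),
        Phi = format(p$phi, digits = 15), Theta = format(p$theta, digits = 15),
        Psi = format(p$psi, digits = 15),
        Score = format(p$score, digits = 15))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @rdname write_particle_xml
#' @export
read_particle_xml <- function(path) {
  doc <- xml2::read_xml(path)
  if (xml2::xml_name(doc) != "ParticleList")
    stop("not a particle-list XML document", call. = FALSE)
  vs <- xml2::xml_attr(doc, "VoxelSize")
  vs <- if (is.na(vs)) NULL else as.numeric(vs)
  dims <- xml2::xml_attr(doc, "TomogramDims")
  dims <- if (is.na(dims)) NULL else as.integer(strsplit(dims, "\\s+")[[1]])
  nodes <- xml2::xml_find_all(doc, "./Particle")
  g <- function(a) xml2::xml_attr(nodes, a)
  df <- tibble::tibble(
    tomogram = g("Tomogram"),
    x = as.numeric(g("X")), y = as.numeric(g("Y")), z = as.numeric(g("Z")),
    phi = as.numeric(g("Phi")), theta = as.numeric(g("Theta")),
    psi = as.numeric(g("Psi")),
    score = suppressWarnings(as.numeric(g("Score"))))  # "NA" for unscored
  as_particle_list(df, voxel_size = vs, tomogram_dims = dims)
}

star_columns <- c("rlnMicrographName", "rlnCoordinateX", "rlnCoordinateY",
                  "rlnCoordinateZ", "rlnAngleRot", "rlnAngleTilt",
                  "rlnAnglePsi", "rlnAutopickFigureOfMerit")

#' Read and write RELION 3.1 STAR particle files
#'
#' A single `data_` block with a `loop_` over `rlnMicrographName`,
#' `rlnCoordinateX/Y/Z`, `rlnAngleRot/AngleTilt/AnglePsi` and
#' `rlnAutopickFigureOfMerit`. Euler angles are converted between the
#' native ZXZ-anticlockwise and RELION's ZYZ-clockwise conventions on the
#' way through; coordinates can be written in voxels or angstrom
#' (`angstrom = voxel * voxel_size`).
#'
#' @inheritParams write_particle_xml
#' @param coordinate_unit `"voxel"` or `"angstrom"`.
#' @param voxel_size voxel size in angstrom; required for angstrom
#'   coordinates (defaults to the particle list's own).
#' @return `read_particle_star` returns a `particle_list` (coordinates in
#'   voxels); `write_particle_star` returns `path` invisibly.
#' @export
write_particle_star <- function(particles, path,
                                coordinate_unit = c("voxel", "angstrom"),
                                voxel_size = NULL) {
  coordinate_unit <- match.arg(coordinate_unit)
  xyz <- as.matrix(particles[, c("x", "y", "z")])
  if (coordinate_unit == "angstrom") {
    vs <- particle_voxel_size(particles, voxel_size)
    xyz <- xyz * vs
  }
  if (nrow(particles)) {
    ang <- pytom_to_relion_euler(particles[, c("phi", "theta", "psi")])
  } else {
    ang <- tibble::tibble(rot = numeric(), tilt = numeric(), psi = numeric())
  }
  fmt <- function(x) formatC(x, format = "f", digits = 8)
  rows <- if (nrow(particles)) {
    paste(particles$tomogram, fmt(xyz[, 1]), fmt(xyz[, 2]), fmt(xyz[, 3]),
          fmt(ang$rot), fmt(ang$tilt), fmt(ang$psi), fmt(particles$score),
          sep = "\t")
  } else character()
  header <- c("", "data_", "", "loop_",
              sprintf("_%s #%d", star_columns, seq_along(star_columns)))
  writeLines(c(header, rows, ""), path)
  invisible(path)
}

#' @rdname write_particle_star
#' @export
read_particle_star <- function(path, coordinate_unit = c("voxel", "angstrom"),
                               voxel_size = NULL) {
  coordinate_unit <- match.arg(coordinate_unit)
  lines <- readLines(path)
  lines <- trimws(lines)
  loop_at <- which(lines == "loop_")
  if (!length(loop_at)) stop("no loop_ block in STAR file", call. = FALSE)
  i <- loop_at[1] + 1
  cols <- character()
  while (i <= length(lines) && startsWith(lines[i], "_")) {
    cols <- c(cols, sub("^_([A-Za-z0-9]+).*$", "\\1", lines[i]))
    i <- i + 1
  }
  missing_cols <- setdiff(star_columns, cols)
  if (length(missing_cols))
    stop("STAR file lacks required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  body <- lines[i:length(lines)]
  body <- body[nzchar(body) & !startsWith(body, "data_")]
  if (length(body)) {
    tab <- utils::read.table(text = body, col.names = cols,
                             stringsAsFactors = FALSE)
  } else {
    tab <- stats::setNames(as.data.frame(matrix(nrow = 0, ncol = length(cols))),
                           cols)
  }
  xyz <- as.matrix(tab[, c("rlnCoordinateX", "rlnCoordinateY", "rlnCoordinateZ"),
                       drop = FALSE])
  if (coordinate_unit == "angstrom") {
    if (is.null(voxel_size))
      stop("`voxel_size` required to read angstrom coordinates", call. = FALSE)
    xyz <- xyz / voxel_size
  }
  ang <- if (nrow(tab)) {
    relion_to_pytom_euler(tibble::tibble(rot = tab$rlnAngleRot,
                                         tilt = tab$rlnAngleTilt,
                                         psi = tab$rlnAnglePsi))
  } else {
    tibble::tibble(phi = numeric(), theta = numeric(), psi = numeric())
  }
  df <- tibble::tibble(
    tomogram = as.character(tab$rlnMicrographName),
    x = as.numeric(xyz[, 1]), y = as.numeric(xyz[, 2]), z = as.numeric(xyz[, 3]),
    phi = ang$phi, theta = ang$theta, psi = ang$psi,
    score = as.numeric(tab$rlnAutopickFigureOfMerit))
  as_particle_list(df, voxel_size = voxel_size)
}

#' Convert particle annotations between XML and STAR
#'
#' File-level convenience wrapper over the readers/writers: reads the
#' input document, converts coordinates and Euler conventions, and writes
#' the other format. Lossless up to the Euler-convention round trip.
#'
#' @param input,output file paths.
#' @param direction `"xml_to_star"` or `"star_to_xml"`.
#' @param coordinate_unit unit for STAR coordinates.
#' @param voxel_size voxel size in angstrom (needed for angstrom
#'   coordinates when the XML carries none).
#' @return The particle list, invisibly.
#' @export
convert_particles <- function(input, output,
                              direction = c("xml_to_star", "star_to_xml"),
                              coordinate_unit = c("voxel", "angstrom"),
                              voxel_size = NULL) {
  direction <- match.arg(direction)
  coordinate_unit <- match.arg(coordinate_unit)
  if (direction == "xml_to_star") {
    p <- read_particle_xml(input)
    write_particle_star(p, output, coordinate_unit = coordinate_unit,
                        voxel_size = voxel_size)
  } else {
    p <- read_particle_star(input, coordinate_unit = coordinate_unit,
                            voxel_size = voxel_size)
    write_particle_xml(p, output)
  }
  invisible(p)
}
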