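# File interfaces use millimetres (the field's convention for vascular
# geometry); everything internal is SI.

MM <- 1e-3

#' Read a triangle mesh (OBJ or STL)
#'
#' Wavefront OBJ (`v`/`f` records, polygonal faces fan-triangulated) and
#' STL, both ASCII and binary (auto-detected). File coordinates are
#' millimetres; the returned mesh is in metres. For STL, identical
#' vertices are merged.
#'
#' @param path File path; format from the extension (`.obj`, `.stl`).
#' @return A [triangle_mesh()].
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         obj = read_obj(path),
         stl = read_stl(path),
         stop("unsupported mesh format: .", ext))
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^v\\s", lines, value = TRUE)
  flines <- grep("^f\\s", lines, value = TRUE)
  if (!length(vlines) || !length(flines))
    stop("malformed OBJ (no vertices or faces): ", path)
  V <- do.call(rbind, lapply(seq_along(vlines), function(i) {
    x <- suppressWarnings(as.numeric(strsplit(trimws(vlines[i]), "\\s+")[[1]][2:4]))
    if (any(is.na(x))) stop("malformed OBJ vertex record ", i, " in ", path)
    x
  }))
  F_ <- do.call(rbind, lapply(flines, function(l) {
    tok <- strsplit(trimws(l), "\\s+")[[1]][-1]
    idx <- as.integer(vapply(strsplit(tok, "/"), `[[`, character(1), 1))
    if (length(idx) < 3) stop("OBJ face with fewer than 3 vertices in ", path)
    cbind(idx[1], idx[2:(length(idx) - 1)], idx[3:length(idx)])
  }))
  triangle_mesh(V * MM, F_)
}

#' Write a triangle mesh (OBJ or STL)
#'
#' @param mesh A [triangle_mesh()] (metres; written in millimetres).
#' @param path Output path (`.obj` or `.stl`).
#' @param format For STL: `"ascii"` or `"binary"`.
#' @export
write_mesh <- function(mesh, path, format = c("ascii", "binary")) {
  format <- match.arg(format)
  ext <- tolower(tools::file_ext(path))
  if (ext == "obj") {
    V <- mesh$vertices / MM
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("# endorod mesh (mm)", con)
    writeLines(sprintf("v %.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]), con)
    writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                       mesh$faces[, 3]), con)
  } else if (ext == "stl") {
    if (format == "ascii") write_stl_ascii(mesh, path) else write_stl_binary(mesh, path)
  } else stop("unsupported mesh format: .", ext)
  invisible(path)
}

stl_triangle_soup <- function(mesh) {
  V <- mesh$vertices / MM
  list(a = V[mesh$faces[, 1], , drop = FALSE],
       b = V[mesh$faces[, 2], , drop = FALSE],
       c = V[mesh$faces[, 3], , drop = FALSE],
       n = mesh$normals)
}

write_stl_ascii <- function(mesh, path) {
  s <- stl_triangle_soup(mesh)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid endorod", con)
  for (t in seq_len(nrow(s$a))) {
    writeLines(c(sprintf("  facet normal %.9g %.9g %.9g",
                         s$n[t, 1], s$n[t, 2], s$n[t, 3]),
                 "    outer loop",
                 sprintf("      vertex %.9g %.9g %.9g",
                         c(s$a[t, 1], s$b[t, 1], s$c[t, 1]),
                         c(s$a[t, 2], s$b[t, 2], s$c[t, 2]),
                         c(s$a[t, 3], s$b[t, 3], s$c[t, 3])),
                 "    endloop", "  endfacet"), con)
  }
  writeLines("endsolid endorod", con)
}

write_stl_binary <- function(mesh, path) {
  s <- stl_triangle_soup(mesh)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(rep(0, 80)), con)
  writeBin(as.integer(nrow(s$a)), con, size = 4, endian = "little")
  for (t in seq_len(nrow(s$a))) {
    writeBin(as.numeric(c(s$n[t, ], s$a[t, ], s$b[t, ], s$c[t, ])), con,
             size = 4, endian = "little")
    writeBin(as.raw(c(0, 0)), con)
  }
}

read_stl <- function(path) {
  head <- readBin(path, "raw", n = 5)
  if (identical(rawToChar(head), "solid")) {
    # could still be binary with a "solid" header; check for 'facet'
    txt <- readLines(path, warn = FALSE, n = 50)
    if (any(grepl("facet", txt))) return(read_stl_ascii(path))
  }
  read_stl_binary(path)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) %% 3 != 0) stop("malformed ASCII STL: ", path)
  V <- do.call(rbind, lapply(vl, function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]][2:4])))
  soup_to_mesh(V)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80)
  ntri <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  V <- matrix(0, 3 * ntri, 3)
  for (t in seq_len(ntri)) {
    vals <- readBin(con, "numeric", n = 12, size = 4, endian = "little")
    readBin(con, "raw", n = 2)
    V[3 * t - 2, ] <- vals[4:6]
    V[3 * t - 1, ] <- vals[7:9]
    V[3 * t, ] <- vals[10:12]
  }
  soup_to_mesh(V)
}

# merge identical vertices of a triangle soup (mm in, m out)
soup_to_mesh <- function(V) {
  key <- paste(sprintf("%.7g", V[, 1]), sprintf("%.7g", V[, 2]),
               sprintf("%.7g", V[, 3]))
  uk <- !duplicated(key)
  idx <- match(key, key[uk])
  triangle_mesh(V[uk, , drop = FALSE] * MM,
                matrix(idx, ncol = 3, byrow = TRUE))
}

#' Read / write a centreline polyline
#'
#' CSV files carry columns `x_mm`, `y_mm`, `z_mm`; JSON files a list of
#' `[x, y, z]` millimetre triples.
#'
#' @param path `.csv` or `.json` file.
#' @return A [reference_centreline()] (metres).
#' @export
read_centreline <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    df <- utils::read.csv(path)
    need <- c("x_mm", "y_mm", "z_mm")
    if (!all(need %in% names(df)))
      stop("centreline CSV must have columns x_mm, y_mm, z_mm: ", path)
    for (cn in need) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(df[[cn]]))))
      if (length(bad))
        stop(sprintf("non-numeric value in column %s, row %d of %s",
                     cn, bad[1], path))
    }
    m <- unname(as.matrix(df[, need]))
  } else if (ext == "json") {
    m <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.list(m)) m <- do.call(rbind, m)
    m <- matrix(as.numeric(m), ncol = 3)
  } else stop("unsupported centreline format: .", ext)
  reference_centreline(m * MM)
}

#' @rdname read_centreline
#' @param centreline A [reference_centreline()].
#' @export
write_centreline <- function(centreline, path) {
  P <- centreline$points / MM
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.csv(data.frame(x_mm = P[, 1], y_mm = P[, 2], z_mm = P[, 3]),
                     path, row.names = FALSE)
  } else if (ext == "json") {
    jsonlite::write_json(unname(P), path, digits = NA)
  } else stop("unsupported centreline format: .", ext)
  invisible(path)
}

#' Read / write an insertion drive schedule
#'
#' CSV columns: `time_s`, `push_speed_mm_s`, `twist_speed_deg_s`.
#'
#' @param path CSV file path.
#' @return An [insertion_drive()] (SI units).
#' @export
read_drive <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_s", "push_speed_mm_s", "twist_speed_deg_s")
  if (!all(need %in% names(df)))
    stop("drive CSV must have columns ", paste(need, collapse = ", "))
  insertion_drive(df$time_s, df$push_speed_mm_s * MM,
                  df$twist_speed_deg_s * pi / 180)
}

#' @rdname read_drive
#' @param drive An [insertion_drive()].
#' @export
write_drive <- function(drive, path) {
  utils::write.csv(data.frame(time_s = drive[, 1],
                              push_speed_mm_s = drive[, 2] / MM,
                              twist_speed_deg_s = drive[, 3] * 180 / pi),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a scenario configuration (YAML or JSON)
#'
#' Scenario files describe an instrument (`instrument:` with
#' `total_length_mm`, `n_points`, `E_b_Pa`, `radius_mm`, `density_kg_m3`,
#' `K_p`, `alpha`, `tip_points`, `mu`), solver settings (`solver:`), the
#' time step/duration, and optional geometry and drive file references.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A named list with `params` ([material_params()]), `config`
#'   ([sim_config()]), `n_points`, `total_length`, `dt`, `duration`,
#'   `seed`, and any `geometry`/`drive` paths.
#' @export
read_scenario <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else stop("unsupported scenario format: .", ext)
  inst <- raw$instrument
  num <- function(x) as.numeric(x) # YAML may read 5.0e6 as a string
  params <- material_params(
    young_modulus_shaft = num(inst$E_b_Pa),
    radius = num(inst$radius_mm) * MM,
    density = num(inst$density_kg_m3),
    parallel_spring_constant = num(inst$K_p),
    tip_modulus_ratio = num(inst$alpha),
    tip_point_count = inst$tip_points,
    friction_coefficient = num(inst$mu))
  sv <- raw$solver
  config <- do.call(sim_config, c(list(dt = raw$dt %||% 1e-3), sv))
  list(params = params, config = config,
       n_points = inst$n_points, total_length = inst$total_length_mm * MM,
       dt = raw$dt %||% 1e-3, duration = raw$duration %||% NA_real_,
       seed = raw$seed %||% 1L,
       geometry = raw$geometry, drive = raw$drive, name = inst$name)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a recorded rod trajectory
#'
#' One record per (recorded step, point): CSV columns or JSON-lines fields
#' `step`, `point`, `x_mm`, `y_mm`, `z_mm`.
#'
#' @param sim A [simulate_insertion()] result recorded with
#'   `record_stride > 0`.
#' @param path `.csv` or `.jsonl` output path.
#' @export
write_trajectory <- function(sim, path) {
  tr <- sim$trace
  if (!length(tr$points)) stop("simulation was not recorded (record_stride = 0)")
  ext <- tolower(tools::file_ext(path))
  rows <- do.call(rbind, lapply(seq_along(tr$points), function(k) {
    P <- tr$points[[k]] / MM
    data.frame(record = k, time_s = tr$time[k],
               point = seq_len(nrow(P)),
               x_mm = P[, 1], y_mm = P[, 2], z_mm = P[, 3])
  }))
  if (ext == "csv") {
    utils::write.csv(rows, path, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(rows)))
      writeLines(jsonlite::toJSON(as.list(rows[i, ]), auto_unbox = TRUE), con)
  }
  invisible(path)
}
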