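#' Read a plain-text key-value run configuration
#'
#' The configuration grammar is `key = value` lines (`#` comments and blank
#' lines ignored). Unknown keys are rejected; omitted keys take the package
#' defaults (plasma viscosity 1.5 cP, blood 7.35 cP, density 1.025 kg/L,
#' 25 frames per 0.25 s cycle, and the measured groove-dimension
#' distributions).
#'
#' @param path Path to the configuration file.
#' @return A `tf_run_config`: list with `params` ([geometry_params()]),
#'   `motion` ([motion_model()]), `fluid` ([fluid_properties()]),
#'   `resolution`, `seed` and `outdir`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) stop("malformed config line: `", ln, "`", call. = FALSE)
    kv[[m[2]]] <- trimws(m[3])
  }
  config_from_list(kv)
}

config_keys <- function() {
  c("inner_diameter", "n_grooves",
    "groove_long_mean", "groove_long_sd",
    "groove_radial_mean", "groove_radial_sd",
    "groove_circ_mean", "groove_circ_sd",
    "endocardial_thickness", "cell_diameter",
    "inlet_width", "outlet_width", "curvature_ratio", "node_spacing",
    "cycle_duration", "n_frames", "ejection_fraction", "phase_split",
    "translation_amplitude_x", "translation_amplitude_y",
    "squeeze_amplitude", "groove_width_gain",
    "viscosity", "density", "resolution", "seed", "outdir")
}

config_from_list <- function(kv) {
  unknown <- setdiff(names(kv), config_keys())
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  num <- function(key, default) {
    if (is.null(kv[[key]])) return(default)
    v <- suppressWarnings(as.numeric(kv[[key]]))
    if (is.na(v)) stop("config key `", key, "` is not numeric", call. = FALSE)
    v
  }
  chr <- function(key, default) kv[[key]] %||% default
  params <- geometry_params(
    inner_diameter = num("inner_diameter", 40),
    groove_long = c(num("groove_long_mean", 12.5), num("groove_long_sd", 3.1)),
    groove_radial = c(num("groove_radial_mean", 8.7),
                      num("groove_radial_sd", 0.8)),
    groove_circ = c(num("groove_circ_mean", 21.7), num("groove_circ_sd", 10.7)),
    n_grooves = num("n_grooves", 2),
    endocardial_thickness = num("endocardial_thickness", 5),
    cell_diameter = num("cell_diameter", 6.5),
    inlet_width = num("inlet_width", 10),
    outlet_width = num("outlet_width", 10),
    curvature_ratio = num("curvature_ratio", 0.5),
    node_spacing = num("node_spacing", 0.9)
  )
  motion <- motion_model(
    cycle_duration = num("cycle_duration", 0.25),
    n_frames = num("n_frames", 25),
    ejection_fraction = num("ejection_fraction", 0.4),
    phase_split = num("phase_split", 0.6),
    translation_amplitude = c(num("translation_amplitude_x", 3),
                              num("translation_amplitude_y", 1.5)),
    squeeze_amplitude = num("squeeze_amplitude", 0.5),
    groove_width_gain = num("groove_width_gain", 0.25)
  )
  visc <- chr("viscosity", "plasma")
  if (!visc %in% c("plasma", "blood")) {
    v <- suppressWarnings(as.numeric(visc))
    if (is.na(v) || v <= 0) {
      stop("config key `viscosity` must be `plasma`, `blood` or a positive ",
           "number (Pa s)", call. = FALSE)
    }
    visc <- v
  }
  structure(list(
    params = params, motion = motion,
    fluid = fluid_properties(visc, num("density", 1025)),
    resolution = num("resolution", 1),
    seed = as.integer(num("seed", 1)),
    outdir = chr("outdir", ".")
  ), class = "tf_run_config")
}

#' Write a run configuration
#'
#' Serializes a `tf_run_config` to the key-value grammar of [read_config()];
#' the round trip is lossless.
#'
#' @param config A `tf_run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  p <- config$params; m <- config$motion
  mu <- if (config$fluid$preset %in% c("plasma", "blood")) {
    config$fluid$preset
  } else {
    format(config$fluid$viscosity, digits = 17)
  }
  f17 <- function(x) format(x, digits = 17)
  lines <- c(
    "# trabflow run configuration",
    paste0("inner_diameter = ", f17(p$inner_diameter)),
    paste0("n_grooves = ", p$n_grooves),
    paste0("groove_long_mean = ", f17(p$groove_long[["mean"]])),
    paste0("groove_long_sd = ", f17(p$groove_long[["sd"]])),
    paste0("groove_radial_mean = ", f17(p$groove_radial[["mean"]])),
    paste0("groove_radial_sd = ", f17(p$groove_radial[["sd"]])),
    paste0("groove_circ_mean = ", f17(p$groove_circ[["mean"]])),
    paste0("groove_circ_sd = ", f17(p$groove_circ[["sd"]])),
    paste0("endocardial_thickness = ", f17(p$endocardial_thickness)),
    paste0("cell_diameter = ", f17(p$cell_diameter)),
    paste0("inlet_width = ", f17(p$inlet_width)),
    paste0("outlet_width = ", f17(p$outlet_width)),
    paste0("curvature_ratio = ", f17(p$curvature_ratio)),
    paste0("node_spacing = ", f17(p$node_spacing)),
    paste0("cycle_duration = ", f17(m$cycle_duration)),
    paste0("n_frames = ", m$n_frames),
    paste0("ejection_fraction = ", f17(m$ejection_fraction)),
    paste0("phase_split = ", f17(m$phase_split)),
    paste0("translation_amplitude_x = ", f17(m$translation_amplitude[1])),
    paste0("translation_amplitude_y = ", f17(m$translation_amplitude[2])),
    paste0("squeeze_amplitude = ", f17(m$squeeze_amplitude)),
    paste0("groove_width_gain = ", f17(m$groove_width_gain)),
    paste0("viscosity = ", mu),
    paste0("density = ", f17(config$fluid$density)),
    paste0("resolution = ", f17(config$resolution)),
    paste0("seed = ", config$seed),
    paste0("outdir = ", config$outdir)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write a moving boundary as a file series
#'
#' One file per frame with zero-padded indices. `vtk-legacy` writes ASCII
#' VTK polydata (points + closed polylines per ring, with the persistent
#' `node_id` as point data); `stl` writes the extruded endocardial sheet as
#' an STL surface. A sidecar CSV (`<prefix>_labels.csv`) stores the
#' frame-invariant node labels.
#'
#' @param mb A [tf_moving_boundary].
#' @param dir Output directory (created if missing).
#' @param format `"vtk-legacy"` or `"stl"`.
#' @param prefix File name prefix.
#' @param binary For STL: write binary instead of ASCII.
#' @return Character vector of the files written, invisibly.
#' @export
write_mesh_series <- function(mb, dir, format = c("vtk-legacy", "stl"),
                              prefix = "boundary", binary = FALSE) {
  stopifnot(inherits(mb, "tf_moving_boundary"))
  format <- match.arg(format)
  if (n_frames(mb) == 0) stop("no frames to write", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pad <- max(2L, nchar(as.character(n_frames(mb))))
  files <- character(0)
  for (f in seq_len(n_frames(mb))) {
    stem <- sprintf("%s_%0*d", prefix, pad, f)
    if (format == "vtk-legacy") {
      path <- file.path(dir, paste0(stem, ".vtk"))
      write_vtk_boundary(mb, f, path)
    } else {
      path <- file.path(dir, paste0(stem, ".stl"))
      write_stl(extrude_boundary(mb, f), path, binary = binary)
    }
    files <- c(files, path)
  }
  lab_path <- file.path(dir, paste0(prefix, "_labels.csv"))
  utils::write.csv(
    data.frame(node_id = seq_len(n_nodes(mb)), label = mb$labels),
    lab_path, row.names = FALSE)
  invisible(c(files, lab_path))
}

write_vtk_boundary <- function(mb, frame, path) {
  xy <- mb$frames[[frame]]
  n <- nrow(xy)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("trabflow boundary frame %d", frame),
               "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d float", n)), con)
  utils::write.table(cbind(format(xy, digits = 9), 0), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  sizes <- vapply(mb$rings, length, 0L)
  writeLines(sprintf("LINES %d %d", length(mb$rings),
                     sum(sizes + 2L)), con)
  for (r in mb$rings) {
    writeLines(paste(c(length(r) + 1L, r - 1L, r[1] - 1L), collapse = " "), con)
  }
  writeLines(c(sprintf("POINT_DATA %d", n),
               "SCALARS node_id int 1", "LOOKUP_TABLE default"), con)
  writeLines(paste(seq_len(n) - 1L), con)
  invisible(path)
}

#' Write a solved flow frame as legacy ASCII VTK
#'
#' Unstructured triangle mesh with point-data velocity vectors and pressure.
#'
#' @param ff A [tf_flow_frame].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_flow_vtk <- function(ff, path) {
  xy <- ff$mesh$xy
  tri <- ff$mesh$tri
  n <- nrow(xy)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "trabflow flow frame",
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d float", n)), con)
  utils::write.table(cbind(format(xy, digits = 9), 0), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELLS %d %d", nrow(tri), 4L * nrow(tri)), con)
  utils::write.table(cbind(3L, tri - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", nrow(tri)), con)
  writeLines(as.character(rep(5L, nrow(tri))), con)
  writeLines(c(sprintf("POINT_DATA %d", n),
               "VECTORS velocity float"), con)
  utils::write.table(cbind(format(ff$u, digits = 9), 0), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(c("SCALARS pressure float 1", "LOOKUP_TABLE default"), con)
  writeLines(format(ff$p, digits = 9), con)
  invisible(path)
}

#' Write a triangulated surface as STL
#'
#' @param surface A `tf_surface` (e.g. from [extrude_boundary()]).
#' @param path Output path.
#' @param binary Write binary STL (default ASCII).
#' @return `path`, invisibly.
#' @export
write_stl <- function(surface, path, binary = FALSE) {
  v <- surface$vertices
  f <- surface$faces
  v1 <- v[f[, 1], , drop = FALSE]
  v2 <- v[f[, 2], , drop = FALSE]
  v3 <- v[f[, 3], , drop = FALSE]
  e1 <- v2 - v1; e2 <- v3 - v1
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrm^2))
  nrm <- nrm / pmax(len, 1e-300)
  nf <- nrow(f)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(nf), con, size = 4, endian = "little")
    dat <- t(cbind(nrm, v1, v2, v3))
    for (i in seq_len(nf)) {
      writeBin(as.numeric(dat[, i]), con, size = 4, endian = "little")
      writeBin(as.integer(0), con, size = 2, endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid trabflow", con)
    for (i in seq_len(nf)) {
      writeLines(c(
        sprintf("  facet normal %.9e %.9e %.9e", nrm[i, 1], nrm[i, 2], nrm[i, 3]),
        "    outer loop",
        sprintf("      vertex %.9e %.9e %.9e", v1[i, 1], v1[i, 2], v1[i, 3]),
        sprintf("      vertex %.9e %.9e %.9e", v2[i, 1], v2[i, 2], v2[i, 3]),
        sprintf("      vertex %.9e %.9e %.9e", v3[i, 1], v3[i, 2], v3[i, 3]),
        "    endloop",
        "  endfacet"), con)
    }
    writeLines("endsolid trabflow", con)
  }
  invisible(path)
}

#' Read an STL surface
#'
#' Reads ASCII or binary STL (auto-detected) back into a `tf_surface` with
#' one vertex row per facet corner (no welding).
#'
#' @param path STL file path.
#' @return A `tf_surface`.
#' @export
read_stl <- function(path) {
  head5 <- readBin(path, "raw", n = 5)
  if (identical(rawToChar(head5), "solid") && is_ascii_stl(path)) {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    parts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x)
      as.numeric(x[2:4])))
    verts <- parts
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", n = 80)
    nf <- readBin(con, "integer", n = 1, size = 4, endian = "little")
    verts <- matrix(0, 3 * nf, 3)
    for (i in seq_len(nf)) {
      vals <- readBin(con, "numeric", n = 12, size = 4, endian = "little")
      readBin(con, "integer", n = 1, size = 2, endian = "little")
      verts[3 * (i - 1) + 1:3, ] <- matrix(vals[4:12], 3, 3, byrow = TRUE)
    }
  }
  nf <- nrow(verts) / 3
  structure(list(vertices = verts,
                 faces = matrix(seq_len(3 * nf), nf, 3, byrow = TRUE)),
            class = "tf_surface")
}

is_ascii_stl <- function(path) {
  txt <- suppressWarnings(readLines(path, n = 50, warn = FALSE))
  any(grepl("facet normal", txt))
}

#' Write a wall shear series as CSV
#'
#' Long format: frame, time, node_id, label, shear rate (and WSS when a
#' viscosity is given).
#'
#' @param series A `tf_wss_series`.
#' @param path Output path.
#' @param mu Optional viscosity (Pa s) to add a `tau` column.
#' @return `path`, invisibly.
#' @export
write_wss_csv <- function(series, path, mu = NULL) {
  df <- tidy.tf_wss_series(series)
  names(df)[names(df) == "node"] <- "node_id"
  if (!is.null(mu)) df$tau <- df$gamma * mu
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Summarize completed runs into report tables
#'
#' Collects scenario results and comparison tables into machine-readable
#' summary tables (CSV + JSON) plus strain histograms when present. Every
#' row carries the configuration hash of the run that produced it.
#'
#' @param bundle A named list of `tf_scenario_result` and/or
#'   `tf_comparison` objects.
#' @param dir Output directory; `NULL` writes nothing and only returns the
#'   tables.
#' @param config Optional `tf_run_config` whose hash is attached to rows.
#' @return A named list of tibbles, invisibly when `dir` is given.
#' @export
report <- function(bundle, dir = NULL, config = NULL) {
  if (!length(bundle)) stop("no completed runs to report", call. = FALSE)
  if (is.null(names(bundle)) || any(!nzchar(names(bundle)))) {
    names(bundle) <- paste0("run", seq_along(bundle))
  }
  hash <- if (is.null(config)) NA_character_ else config_hash(config)
  tables <- list()
  for (nm in names(bundle)) {
    x <- bundle[[nm]]
    tab <- if (inherits(x, "tf_scenario_result")) {
      dplyr::mutate(glance.tf_scenario_result(x), run = nm)
    } else if (inherits(x, "tf_comparison")) {
      dplyr::mutate(tibble::as_tibble(x), run = nm)
    } else {
      stop("cannot report object of class ", class(x)[1], " (run `", nm, "`)",
           call. = FALSE)
    }
    tab$config_hash <- hash
    tables[[nm]] <- tab
  }
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(tables)) {
      utils::write.csv(tables[[nm]], file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
    jsonlite::write_json(tables, file.path(dir, "report.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    return(invisible(tables))
  }
  tables
}

#' Hash of a run configuration
#'
#' @param config A `tf_run_config`.
#' @return Character hash, stable across sessions for identical settings.
#' @export
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  write_config(config, tmp)
  rlang::hash(paste(readLines(tmp), collapse = "\n"))
}
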