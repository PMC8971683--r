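# Readers and writers.
#
# Networks travel as versioned JSON; tables as plain CSV with units suffixed
# in column names; image stacks as a plain-text format (a JSON header line
# followed by one line of space-separated integers per image row), since the
# toolchain targets text-only artifacts. A JSON sidecar carries the imaging
# metadata (pixel size, frame rate, seed) a movie cannot represent itself.

NETWORK_SCHEMA <- "zebraflow-network/1"
STACK_SCHEMA <- "zebraflow-stack/1"

#' Write a trunk network to JSON
#'
#' @param net a `trunk_network`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_network_json <- function(net, path) {
  validate_network(net)
  obj <- list(
    schema = NETWORK_SCHEMA,
    nodes = net$nodes,
    edges = net$edges,
    boundary = net$boundary
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Read a trunk network from JSON
#'
#' @param path file written by [write_network_json()].
#' @return a `trunk_network`.
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema) || obj$schema != NETWORK_SCHEMA) {
    stop("not a ", NETWORK_SCHEMA, " file: ", path, call. = FALSE)
  }
  net <- structure(list(nodes = obj$nodes, edges = obj$edges,
                        boundary = obj$boundary), class = "trunk_network")
  validate_network(net)
  net
}

#' Write an image stack as plain text
#'
#' @param stack numeric array (rows x cols x frames) or a matrix (one frame).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(dim(stack), 1L))
  d <- dim(stack)
  con <- file(path, "w")
  on.exit(close(con))
  header <- jsonlite::toJSON(list(schema = STACK_SCHEMA, rows = d[1],
                                  cols = d[2], frames = d[3]),
                             auto_unbox = TRUE)
  writeLines(as.character(header), con)
  for (f in seq_len(d[3])) {
    writeLines(apply(stack[, , f, drop = FALSE], 1,
                     function(r) paste(r, collapse = " ")), con)
  }
  invisible(path)
}

#' Read a plain-text image stack
#'
#' @param path file written by [write_image_stack()].
#' @return numeric array (rows x cols x frames).
#' @export
read_image_stack <- function(path) {
  lines <- readLines(path)
  header <- jsonlite::fromJSON(lines[1])
  if (is.null(header$schema) || header$schema != STACK_SCHEMA) {
    stop("not a ", STACK_SCHEMA, " file: ", path, call. = FALSE)
  }
  nr <- header$rows
  nc <- header$cols
  nf <- header$frames
  body <- lines[-1]
  if (length(body) != nr * nf) stop("truncated stack file", call. = FALSE)
  vals <- scan(text = body, quiet = TRUE)
  # rows were written in row order per frame
  stack <- array(0, dim = c(nr, nc, nf))
  for (f in seq_len(nf)) {
    block <- vals[((f - 1) * nr * nc + 1):(f * nr * nc)]
    stack[, , f] <- matrix(block, nr, nc, byrow = TRUE)
  }
  stack
}

#' Write a movie sidecar (imaging metadata)
#'
#' @param config an [imaging_config()].
#' @param seed the render seed.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_sidecar <- function(config, seed, path) {
  obj <- list(schema = "zebraflow-sidecar/1",
              pixel_size_um = config$pixel_size,
              frame_rate_fps = config$frame_rate,
              psf_sigma_um = config$psf_sigma,
              bit_depth = config$bit_depth,
              noise = unclass(config$noise),
              seed = seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a movie sidecar
#' @param path JSON sidecar file.
#' @return named list of metadata.
#' @export
read_sidecar <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (key in c("pixel_size_um", "frame_rate_fps")) {
    if (is.null(obj[[key]])) {
      stop("sidecar missing required key: ", key, call. = FALSE)
    }
  }
  obj
}

#' Write centerlines as a polyline CSV
#'
#' Columns: vessel_id, vertex_index, x_um, y_um.
#'
#' @param centerlines named list of [vessel_trace()] objects.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_centerlines_csv <- function(centerlines, path) {
  rows <- lapply(centerlines, function(tr) {
    data.frame(vessel_id = tr$vessel_id,
               vertex_index = seq_along(tr$x) - 1L,
               x_um = tr$x, y_um = tr$y)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read centerlines from a polyline CSV
#' @param path CSV written by [write_centerlines_csv()].
#' @return named list of [vessel_trace()] objects.
#' @export
read_centerlines_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("vessel_id", "vertex_index", "x_um", "y_um")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("centerline CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(split(df, df$vessel_id), function(g) {
    g <- g[order(g$vertex_index), ]
    vessel_trace(g$vessel_id[1], g$x_um, g$y_um)
  })
  out[order(names(out))]
}

#' Write a run manifest
#'
#' Records the configuration echo, seed, package version and md5 checksums of
#' the run's outputs.
#'
#' @param config list echoed verbatim.
#' @param seed integer seed.
#' @param files character vector of output paths to checksum.
#' @param path output JSON.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, seed, files, path) {
  sums <- tools::md5sum(files)
  obj <- list(schema = "zebraflow-manifest/1",
              version = as.character(utils::packageVersion("zebraflow")),
              seed = seed,
              config = config,
              outputs = data.frame(file = basename(names(sums)),
                                   md5 = unname(sums)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
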