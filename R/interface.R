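# Image I/O, flat key-value run configuration, and the experiment
# dispatcher behind the command-line interface.

#' Read a grayscale image
#'
#' Reads an 8- or 16-bit single-channel PNG or TIFF as an
#' \code{\link{intensity_image}}. The bit depth is taken from the file
#' metadata unless overridden (e.g. 13 effective bits stored in a 16-bit
#' container).
#'
#' @param path Path to a \code{.png}, \code{.tif}, or \code{.tiff} file.
#' @param bit_depth Optional effective bit depth override; values are
#'   validated against it.
#' @return An \code{\link{intensity_image}}.
#' @export
read_image <- function(path, bit_depth = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    x <- png::readPNG(path, info = TRUE)
    if (length(dim(x)) == 3L) {
      stop("multi-channel PNG not supported; convert to single-channel ",
           "grayscale first", call. = FALSE)
    }
    stored <- attr(x, "info")$bit.depth
    px <- round(unclass(x) * (2^stored - 1))
  } else if (ext %in% c("tif", "tiff")) {
    x <- tiff::readTIFF(path, info = TRUE, as.is = TRUE)
    if (length(dim(x)) == 3L) {
      stop("multi-channel TIFF not supported; convert to single-channel ",
           "grayscale first", call. = FALSE)
    }
    stored <- attr(x, "bits.per.sample")
    if (is.null(stored)) stored <- 16L
    px <- unclass(x)
    if (any(px != floor(px))) {
      stop("floating-point TIFF is not an intensity image; use ",
           "read_descriptor() for descriptor files", call. = FALSE)
    }
  } else {
    stop("unsupported image format '", ext, "'; use PNG or TIFF",
         call. = FALSE)
  }
  n <- if (is.null(bit_depth)) as.integer(stored) else as.integer(bit_depth)
  if (any(px > 2^n - 1)) {
    stop(sprintf("image contains values above %d, inconsistent with bit depth %d",
                 2^n - 1, n), call. = FALSE)
  }
  intensity_image(matrix(px, nrow(px), ncol(px)), n)
}

#' Write a grayscale image
#'
#' Writes an \code{\link{intensity_image}} losslessly: 16-bit TIFF for any
#' bit depth, or 8-bit PNG when the depth is at most 8.
#'
#' @param image An \code{\link{intensity_image}}.
#' @param path Output path ending in \code{.png}, \code{.tif}, or
#'   \code{.tiff}.
#' @return \code{path}, invisibly.
#' @export
write_image <- function(image, path) {
  px <- .img_pixels(image)
  n <- .img_depth(image)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (n > 8) {
      stop("PNG output supports bit depth <= 8 here; write a TIFF instead",
           call. = FALSE)
    }
    png::writePNG(px / 255, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(px / 65535, path, bits.per.sample = 16)
  } else {
    stop("unsupported output format '", ext, "'", call. = FALSE)
  }
  invisible(path)
}

#' Write a descriptor image with sidecar metadata and preview
#'
#' Stores the descriptor values as a 32-bit float TIFF (scaled into
#' \eqn{[0, 1]} by the recorded scale factor), a JSON sidecar
#' (\code{<path>.json}) with the core function kind, patch parameters,
#' variety degree, and scale, and an 8-bit min-max PNG preview
#' (\code{<path base>_preview.png}). A round trip through
#' \code{\link{read_descriptor}} reproduces the values to about \code{1e-6}
#' relative accuracy.
#'
#' @param desc A \code{descriptor_image}.
#' @param path Output TIFF path.
#' @return \code{path}, invisibly.
#' @export
write_descriptor <- function(desc, path) {
  if (!inherits(desc, "descriptor_image")) {
    stop("`desc` must be a descriptor_image", call. = FALSE)
  }
  v <- desc$values
  lo <- min(v)
  scale <- max(abs(v))
  stored <- if (scale > 0) (v - min(0, lo)) / (scale - min(0, lo)) else v * 0
  offset <- min(0, lo)
  tiff::writeTIFF(stored, path, bits.per.sample = 32, reduce = FALSE)
  meta <- list(kind = desc$kind, l = desc$spec$l, bins = desc$spec$bins,
               r = desc$r, bit_depth = desc$bit_depth,
               weighting = desc$spec$weighting,
               estimator = desc$spec$estimator,
               normalized = desc$normalized,
               scale = scale - offset, offset = offset,
               min = min(v), max = max(v))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  rng <- range(v)
  prev <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else v * 0
  png::writePNG(prev,
                paste0(tools::file_path_sans_ext(path), "_preview.png"))
  invisible(path)
}

#' Read a descriptor image written by \code{\link{write_descriptor}}
#'
#' @param path Path to the descriptor TIFF (its \code{.json} sidecar must
#'   sit next to it).
#' @return A \code{descriptor_image}.
#' @export
read_descriptor <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(side)) {
    stop("descriptor TIFF or its .json sidecar missing at ", path,
         call. = FALSE)
  }
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  stored <- tiff::readTIFF(path)
  v <- stored * meta$scale + meta$offset
  spec <- patch_spec(l = meta$l, bins = meta$bins,
                     weighting = meta$weighting, estimator = meta$estimator)
  structure(list(values = unclass(v), kind = meta$kind, spec = spec,
                 r = meta$r, bit_depth = meta$bit_depth,
                 normalized = meta$normalized),
            class = "descriptor_image")
}

#' Read a flat key-value run configuration
#'
#' One \code{key = value} pair per line; blank lines and \code{#} comments
#' are ignored. Values that parse as numbers are returned numeric.
#'
#' @param path Config file path.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^=]+)=(.*)$", ln))[[1]]
    if (length(m) != 3L) stop("malformed config line: ", ln, call. = FALSE)
    key <- trimws(m[2])
    val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Write a flat key-value run configuration
#'
#' @param config Named list of scalar values.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_run_config <- function(config, path) {
  writeLines(sprintf("%s = %s", names(config),
                     vapply(config, function(v) format(v, digits = 15), "")),
             path)
  invisible(path)
}

.cfg <- function(config, key, default = NULL) {
  if (!is.null(config[[key]])) config[[key]] else default
}

#' Run a named experiment from a configuration
#'
#' Dispatches on \code{config$experiment}:
#' \describe{
#'   \item{\code{"bounds"}}{upper-bound table over a range of variety
#'     degrees (\code{r_min}, \code{r_max}) to \code{bounds.csv}.}
#'   \item{\code{"descriptor"}}{descriptor image of an input image (or the
#'     standard pair's first modality) to \code{descriptor.tif}.}
#'   \item{\code{"curve"}}{rotation/translation similarity curves on the
#'     standard pair (or given images) to one CSV per method.}
#'   \item{\code{"match"}}{slice matching on the standard stack to
#'     \code{match.csv} in the deflection-summary schema.}
#'   \item{\code{"warp_select"}}{discrete deformation selection to
#'     \code{warp_select.csv}.}
#'   \item{\code{"synth"}}{writes the standard pair as TIFFs plus a JSON
#'     sidecar recording the generator settings.}
#' }
#' Every output is a pure function of the configuration and its seed, and a
#' resolved copy of the configuration is written next to the results.
#'
#' @param config Named list (see \code{\link{read_run_config}}) with at
#'   least \code{experiment} and \code{out} (output directory).
#' @return The experiment's main result object, invisibly.
#' @export
run_experiment <- function(config) {
  kind <- .cfg(config, "experiment")
  out_dir <- .cfg(config, "out", ".")
  if (is.null(kind)) stop("config needs an `experiment` entry", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- .cfg(config, "seed", 1)
  t0 <- proc.time()[["elapsed"]]
  method <- as.character(.cfg(config, "method", "m2"))
  spec <- patch_spec(
    l = .cfg(config, "l", 7),
    bins = .cfg(config, "bins"),
    weighting = as.character(.cfg(config, "weighting", "uniform")),
    estimator = as.character(.cfg(config, "estimator", "histogram")),
    bandwidth = .cfg(config, "bandwidth", 1)
  )
  size <- .cfg(config, "size", 128)
  n_bits <- .cfg(config, "n", 13)
  result <- switch(as.character(kind),
    bounds = {
      tb <- bounds_table(.cfg(config, "r_min", 2), .cfg(config, "r_max", 256))
      utils::write.csv(tb, file.path(out_dir, "bounds.csv"),
                       row.names = FALSE)
      tb
    },
    descriptor = {
      img <- if (!is.null(config$input)) {
        read_image(config$input, bit_depth = .cfg(config, "bit_depth"))
      } else {
        standard_pair(seed, size = size, n = n_bits)$a
      }
      d <- compute_descriptor_image(img, spec, method)
      write_descriptor(d, file.path(out_dir, "descriptor.tif"))
      d
    },
    curve = {
      pair <- if (!is.null(config$fixed) && !is.null(config$moving)) {
        list(a = read_image(config$fixed,
                            bit_depth = .cfg(config, "bit_depth")),
             b = read_image(config$moving,
                            bit_depth = .cfg(config, "bit_depth")))
      } else {
        standard_pair(seed, size = size, n = n_bits)
      }
      params <- seq(.cfg(config, "from", -25), .cfg(config, "to", 25),
                    by = .cfg(config, "step", 1))
      methods <- strsplit(method, ",", fixed = TRUE)[[1]]
      curves <- similarity_curves(pair$a, pair$b, methods = methods,
                                  spec = spec, parameters = params,
                                  mode = as.character(
                                    .cfg(config, "mode", "rotate")))
      for (m in names(curves)) {
        utils::write.csv(as.data.frame(curves[[m]]),
                         file.path(out_dir, paste0("curve_", m, ".csv")),
                         row.names = FALSE)
      }
      curves
    },
    match = {
      st <- standard_stack(seed, n_slices = .cfg(config, "n_slices", 30),
                           size = .cfg(config, "size", 64), n = n_bits)
      methods <- strsplit(method, ",", fixed = TRUE)[[1]]
      tb <- do.call(rbind, lapply(methods, function(m) {
        as.data.frame(match_slices(st$a, st$b, method = m, spec = spec))
      }))
      utils::write.csv(tb, file.path(out_dir, "match.csv"),
                       row.names = FALSE)
      tb
    },
    warp_select = {
      pair <- standard_pair(seed, size = .cfg(config, "size", 64),
                            n = n_bits)
      n_cand <- .cfg(config, "n_candidates", 50)
      amp <- .cfg(config, "amplitude", 3)
      scl <- .cfg(config, "scale", 32)
      truth <- random_smooth_deformation(seed + 1, nrow(pair$b),
                                         ncol(pair$b), amp, scl)
      cands <- c(list(list(image = warp_image(pair$b, truth),
                           field = truth)),
                 lapply(seq_len(n_cand), function(i) {
                   f <- random_smooth_deformation(seed + 1 + i,
                                                  nrow(pair$b),
                                                  ncol(pair$b), amp, scl)
                   list(image = warp_image(pair$b, f), field = f)
                 }))
      sel <- select_best_deformation(pair$a, cands, truth, method = method,
                                     spec = spec)
      tb <- data.frame(method = method, selected = sel$index, tau = sel$tau)
      utils::write.csv(tb, file.path(out_dir, "warp_select.csv"),
                       row.names = FALSE)
      sel
    },
    synth = {
      pair <- standard_pair(seed, size = size, n = n_bits)
      write_image(pair$a, file.path(out_dir, "modality_a.tif"))
      write_image(pair$b, file.path(out_dir, "modality_b.tif"))
      jsonlite::write_json(
        list(seed = seed, size = size, bit_depth = n_bits,
             lut_a = pair$lut_a, lut_b = pair$lut_b,
             noise_pct = 3, inu_pct = 20),
        file.path(out_dir, "synth.json"), auto_unbox = TRUE, digits = NA)
      pair
    },
    stop("unknown experiment kind: ", kind, call. = FALSE)
  )
  config$elapsed_s <- round(proc.time()[["elapsed"]] - t0, 3)
  write_run_config(config[vapply(config, length, 0L) == 1L],
                   file.path(out_dir, "run_config.txt"))
  invisible(result)
}
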