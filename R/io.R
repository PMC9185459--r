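# Portable text serialization: grids and maps as CSV (full double
# precision via %.17g), metadata as JSON sidecars, configuration as
# YAML/JSON. Round trips are lossless at full floating precision.

fmt_full <- function(x) sprintf("%.17g", x)

#' Write a pixel map as CSV
#'
#' One row per grid row (row-major pixel enumeration: x across columns),
#' with a header comment recording the domain extent and pixel count.
#'
#' @param values Numeric vector of length N or `M x M` matrix.
#' @param path Output file.
#' @param grid The map's grid (used for the header; optional for matrices).
#' @export
write_map_csv <- function(values, path, grid = NULL) {
  m <- if (is.matrix(values)) values else {
    if (is.null(grid)) abort_argument("`grid` needed for vector input")
    grid_matrix(values, grid)
  }
  extent <- if (!is.null(grid)) grid$extent else NA
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# extent=%s M=%d", fmt_full(extent)[1], nrow(m)), con)
  utils::write.table(matrix(fmt_full(m), nrow(m)), con, sep = ",",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
}

#' Read a pixel map written by [write_map_csv()]
#' @param path CSV file path.
#' @return Matrix with attribute `extent`.
#' @export
read_map_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  m <- as.matrix(utils::read.table(path, sep = ",", skip = 1,
                                   colClasses = "numeric"))
  dimnames(m) <- NULL
  ext <- sub(".*extent=([^ ]+).*", "\\1", hdr)
  attr(m, "extent") <- suppressWarnings(as.numeric(ext))
  m
}

#' Write a phantom to a directory
#'
#' Permittivity, conductivity and label maps as CSV plus a JSON metadata
#' sidecar (extent, pixels, background, generator parameters).
#'
#' @param phantom An `mwi_phantom`.
#' @param dir Output directory (created if missing).
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- phantom$grid
  write_map_csv(phantom$eps_r, file.path(dir, "eps_r.csv"), g)
  write_map_csv(phantom$sigma, file.path(dir, "sigma.csv"), g)
  writeLines(phantom$labels, file.path(dir, "labels.txt"))
  pm <- phantom$meta
  if (!is.null(pm$tumor)) pm$tumor <- unclass(pm$tumor)
  meta <- list(extent = g$extent, M = g$M, eps_bg = phantom$eps_bg,
               sigma_bg = phantom$sigma_bg, meta = pm)
  jsonlite::write_json(meta, file.path(dir, "phantom.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a phantom written by [write_phantom()]
#' @param dir Directory path.
#' @return An `mwi_phantom`.
#' @export
read_phantom <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "phantom.json"),
                              simplifyVector = TRUE)
  g <- build_grid(meta$extent, meta$M)
  pm <- meta$meta
  if (!is.null(pm$tumor))
    pm$tumor <- tumor_spec(pm$tumor$diameter, unlist(pm$tumor$center))
  new_phantom(g, as.vector(read_map_csv(file.path(dir, "eps_r.csv"))),
              as.vector(read_map_csv(file.path(dir, "sigma.csv"))),
              readLines(file.path(dir, "labels.txt")),
              eps_bg = meta$eps_bg, sigma_bg = meta$sigma_bg,
              meta = pm)
}

#' Write a scattering dataset
#'
#' Flat CSV of samples (columns `freq_hz, source_idx, receiver_idx, re,
#' im`) plus a JSON sidecar with the array geometry, medium, grid and
#' noise record, sufficient to rebuild the inversion operators.
#'
#' @param dataset An `mwi_dataset`.
#' @param path CSV path; the sidecar gets extension `.json`.
#' @export
write_dataset <- function(dataset, path) {
  d <- dim(dataset$E_s)
  idx <- expand.grid(f = seq_len(d[1]), l = seq_len(d[2]), q = seq_len(d[3]))
  v <- dataset$E_s[cbind(idx$f, idx$l, idx$q)]
  df <- data.frame(freq_hz = fmt_full(dataset$medium$frequencies[idx$f]),
                   source_idx = idx$l, receiver_idx = idx$q,
                   re = fmt_full(Re(v)), im = fmt_full(Im(v)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(F = d[1], L = d[2], Nr = d[3],
               frequencies = dataset$medium$frequencies,
               eps_rb = dataset$medium$eps_rb,
               sigma_b = dataset$medium$sigma_b,
               n_sources = dataset$array$n_sources,
               n_receivers = dataset$array$n_receivers,
               radius = dataset$array$radius,
               fine_M = dataset$fine_M, extent = dataset$extent,
               noise = dataset$noise, born = isTRUE(dataset$born))
  jsonlite::write_json(meta, paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a dataset written by [write_dataset()]
#' @param path CSV path (expects the JSON sidecar alongside).
#' @return An `mwi_dataset`.
#' @export
read_dataset <- function(path) {
  meta <- jsonlite::read_json(paste0(tools::file_path_sans_ext(path), ".json"),
                              simplifyVector = TRUE)
  df <- utils::read.csv(path, colClasses = c("numeric", "integer", "integer",
                                             "numeric", "numeric"))
  Es <- base::array(0i, c(meta$F, meta$L, meta$Nr))
  Es[cbind(match(df$freq_hz, meta$frequencies), df$source_idx,
           df$receiver_idx)] <- complex(real = df$re, imaginary = df$im)
  med <- background_medium(meta$eps_rb, meta$sigma_b, meta$frequencies)
  arr <- antenna_array(meta$n_sources, meta$n_receivers, meta$radius)
  structure(list(E_s = Es, array = arr, medium = med, fine_M = meta$fine_M,
                 extent = meta$extent, noise = as.list(meta$noise),
                 born = isTRUE(meta$born)),
            class = "mwi_dataset")
}

#' Write a reconstruction result
#'
#' Final permittivity/conductivity maps and per-iteration contrasts as CSV,
#' residuals and configuration in a JSON sidecar.
#'
#' @param result An `mwi_recon`.
#' @param dir Output directory.
#' @export
write_recon <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- result$grid
  write_map_csv(result$eps_r, file.path(dir, "eps_r.csv"), g)
  write_map_csv(result$sigma, file.path(dir, "sigma.csv"), g)
  write_map_csv(Re(result$chi), file.path(dir, "chi_re.csv"), g)
  write_map_csv(Im(result$chi), file.path(dir, "chi_im.csv"), g)
  meta <- list(M = g$M, extent = g$extent, residuals = result$residuals,
               iterations = length(result$residuals),
               config = unclass(result$config))
  jsonlite::write_json(meta, file.path(dir, "reconstruction.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Save and load refiner checkpoints
#'
#' The model (configuration, layer plan and all parameters, including
#' batch-normalization running statistics) is serialized as JSON at full
#' floating precision.
#'
#' @param model An `mwi_refiner`.
#' @param path JSON file path.
#' @export
save_refiner <- function(model, path) {
  # parameters are serialized as %.17g strings: bit-exact double round trip
  ser <- list(config = unclass(model$config),
              params = lapply(model$params, function(p)
                lapply(p, function(v)
                  list(dim = dim(v) %||% length(v),
                       data = fmt_full(as.vector(v))))))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_refiner
#' @export
load_refiner <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(refiner_config, ser$config[names(ser$config) %in%
    names(formals(refiner_config))])
  model <- build_refiner(cfg)
  for (nm in names(ser$params)) {
    for (fld in names(ser$params[[nm]])) {
      v <- ser$params[[nm]][[fld]]
      vals <- as.numeric(v$data)
      model$params[[nm]][[fld]] <-
        if (length(v$dim) == 2) matrix(vals, v$dim[1], v$dim[2])
        else vals
    }
  }
  model
}

#' Read a configuration file (YAML or JSON)
#' @param path File path; format chosen by extension.
#' @return Nested configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort_argument("config file '%s' not found", path)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

#' Hash of a configuration
#'
#' MD5 of the canonical JSON serialization; recorded in every pipeline
#' output so runs can be matched to their settings.
#'
#' @param config Configuration list.
#' @return Hex digest string.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  unname(tools::md5sum(tf))
}
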