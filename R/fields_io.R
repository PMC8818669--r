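#' Write a field series to disk
#'
#' Two plain-text layouts are supported: a single long-format CSV
#' (`path` ending in `.csv`; columns `t, x, y, z, vx, vy, vz[, w]`) or a
#' directory holding a `manifest.json` (times, period, kind) plus one CSV
#' per timestep. Both round-trip through [read_field_series()].
#'
#' @param series a `wall_series` or `volume_series`.
#' @param path `.csv` file path or directory path.
#' @return `path`, invisibly.
#' @export
write_field_series <- function(series, path) {
  is_wall <- inherits(series, "wall_series")
  pts <- if (is_wall) series$centers else series$points
  arr <- if (is_wall) series$tau else series$v
  w <- if (is_wall) series$areas else series$weights
  nt <- dim(arr)[3L]
  if (grepl("\\.csv$", path)) {
    dt <- data.table::rbindlist(lapply(seq_len(nt), function(k) {
      d <- data.table::data.table(
        t = series$times[k], x = pts[, 1], y = pts[, 2], z = pts[, 3],
        vx = arr[, 1, k], vy = arr[, 2, k], vz = arr[, 3, k])
      if (!is.null(w)) d$w <- w
      d
    }))
    attr_line <- sprintf("# fusiflow_field kind=%s T=%.17g rho=%.17g",
                         if (is_wall) "wall" else "volume",
                         series$T, if (is_wall) NA else series$rho)
    writeLines(attr_line, path)
    data.table::fwrite(dt, path, append = TRUE, col.names = TRUE)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    files <- sprintf("step_%04d.csv", seq_len(nt))
    for (k in seq_len(nt)) {
      d <- data.table::data.table(
        x = pts[, 1], y = pts[, 2], z = pts[, 3],
        vx = arr[, 1, k], vy = arr[, 2, k], vz = arr[, 3, k])
      if (!is.null(w)) d$w <- w
      data.table::fwrite(d, file.path(path, files[k]))
    }
    jsonlite::write_json(
      list(kind = if (is_wall) "wall" else "volume",
           times = series$times, T = series$T,
           rho = if (is_wall) NULL else series$rho, files = files),
      file.path(path, "manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a field series written by [write_field_series()]
#' @param path `.csv` file or manifest directory.
#' @return a `wall_series` or `volume_series` (per the stored kind).
#' @export
read_field_series <- function(path) {
  if (grepl("\\.csv$", path)) {
    hdr <- readLines(path, n = 1L)
    m <- regmatches(hdr, regexec(
      "kind=(\\w+) T=([0-9eE.+-]+) rho=([0-9eE.+-]+|NA)", hdr))[[1L]]
    if (length(m) == 0L) stop("not a fusiflow field CSV")
    kind <- m[2L]; T <- as.numeric(m[3L])
    rho <- suppressWarnings(as.numeric(m[4L]))
    dt <- data.table::fread(path, skip = 1L)
    times <- sort(unique(dt$t))
    dt <- dt[order(dt$t), ]
    n <- nrow(dt) / length(times)
    first <- dt[seq_len(n), ]
    pts <- as.matrix(first[, c("x", "y", "z")])
    arr <- array(0, dim = c(n, 3L, length(times)))
    for (k in seq_along(times)) {
      rows <- ((k - 1L) * n + 1L):(k * n)
      arr[, 1L, k] <- dt$vx[rows]
      arr[, 2L, k] <- dt$vy[rows]
      arr[, 3L, k] <- dt$vz[rows]
    }
    w <- if ("w" %in% names(dt)) first$w else NULL
  } else {
    man <- jsonlite::read_json(file.path(path, "manifest.json"),
                               simplifyVector = TRUE)
    kind <- man$kind; T <- man$T; times <- man$times
    rho <- man$rho %||% NA_real_
    steps <- lapply(file.path(path, man$files), data.table::fread)
    n <- nrow(steps[[1L]])
    pts <- as.matrix(steps[[1L]][, c("x", "y", "z")])
    arr <- array(0, dim = c(n, 3L, length(times)))
    for (k in seq_along(times)) {
      arr[, 1L, k] <- steps[[k]]$vx
      arr[, 2L, k] <- steps[[k]]$vy
      arr[, 3L, k] <- steps[[k]]$vz
    }
    w <- if ("w" %in% names(steps[[1L]])) steps[[1L]]$w else NULL
  }
  if (identical(kind, "wall"))
    wall_series(pts, arr, times, T, areas = w)
  else
    volume_series(pts, arr, times, T,
                  rho = if (is.na(rho)) 1055 else rho, weights = w)
}
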