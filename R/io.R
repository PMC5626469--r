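# Plain-text dataset exchange.  All tables are comma-separated with a
# header row, UTF-8, '.' decimal; coordinates in km.  Occasions are
# 1-based in files.  The covariate raster is either a CSV of
# x,y,value rows on the grid or an ESRI ASCII grid.

#' Write an integrated SCR dataset to a directory
#'
#' Writes `covariate.csv`, `traps.csv`, `operation.csv`, `time.csv`,
#' `detections.csv`, `sexes.csv`, `aux.csv` and, when the dataset carries
#' a `truth` attribute (synthetic data), a `truth.json` sidecar of the
#' generating parameters.
#'
#' @param data an [scr_data] object.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scr_data <- function(data, dir) {
  stopifnot(inherits(data, "scr_data"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(df, file) utils::write.csv(df, file.path(dir, file),
                                           row.names = FALSE, quote = FALSE)
  sp <- data$space
  w(data.frame(x = sp$centroids[, 1], y = sp$centroids[, 2],
               value = sp$covariate), "covariate.csv")
  tr <- data$traps
  w(data.frame(trap_id = tr$ids, x_km = tr$coords[, 1], y_km = tr$coords[, 2],
               type = tr$type_label), "traps.csv")
  occ_cols <- paste0("occ_", seq_len(tr$K))
  op <- data.frame(trap_id = tr$ids, tr$operation)
  names(op) <- c("trap_id", occ_cols)
  w(op, "operation.csv")
  tm <- data.frame(trap_id = tr$ids, tr$time_raw)
  names(tm) <- c("trap_id", occ_cols)
  w(tm, "time.csv")
  det <- which(data$y == 1L, arr.ind = TRUE)
  w(data.frame(individual_id = data$ids[det[, 1]],
               trap_id = tr$ids[det[, 2]], occasion = det[, 3]),
    "detections.csv")
  n_idx <- seq_len(data$n)
  w(data.frame(individual_id = data$ids[n_idx],
               sex = ifelse(data$sex[n_idx] == 1L, "M", "F")), "sexes.csv")
  if (!is.null(data$aux)) {
    w(data.frame(individual_id = data$ids[data$aux$individual],
                 x_km = data$aux$x, y_km = data$aux$y,
                 occasion = data$aux$occasion, source = data$aux$source),
      "aux.csv")
  }
  truth <- attr(data, "truth")
  if (!is.null(truth) && requireNamespace("jsonlite", quietly = TRUE)) {
    keep <- truth[vapply(truth, function(v) length(v) <= 8, logical(1))]
    jsonlite::write_json(keep, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read an integrated SCR dataset from a directory
#'
#' Reads the files written by [write_scr_data()] (or hand-prepared in the
#' same layout), rebuilds the state space from the covariate raster, and
#' validates referential integrity: every detection's trap must exist and
#' be operational in that occasion, every auxiliary record's individual
#' must be identified, occasions must lie in `1..K`.
#'
#' @param dir directory containing the files.
#' @param M augmented size (default 300).
#' @param covariate_file optional override; either a `x,y,value` CSV or an
#'   ESRI ASCII grid (`.asc`).
#' @param quiet suppress the dimension summary message.
#' @return an [scr_data] object.
#' @export
read_scr_data <- function(dir, M = 300L, covariate_file = NULL, quiet = FALSE) {
  fp <- function(f) file.path(dir, f)
  need <- c("traps.csv", "operation.csv", "time.csv", "detections.csv",
            "sexes.csv")
  miss <- need[!file.exists(fp(need))]
  if (length(miss)) stop(sprintf("missing dataset file(s): %s",
                                 paste(miss, collapse = ", ")))
  cov_path <- if (!is.null(covariate_file)) covariate_file else fp("covariate.csv")
  if (!file.exists(cov_path)) stop(sprintf("covariate raster not found: %s", cov_path))
  space <- if (grepl("\\.asc$", cov_path, ignore.case = TRUE))
    read_ascii_grid(cov_path) else read_covariate_csv(cov_path)

  traps_df <- utils::read.csv(fp("traps.csv"), stringsAsFactors = FALSE)
  op <- utils::read.csv(fp("operation.csv"), stringsAsFactors = FALSE)
  tm <- utils::read.csv(fp("time.csv"), stringsAsFactors = FALSE)
  ord <- match(traps_df$trap_id, op$trap_id)
  if (anyNA(ord)) stop(sprintf("operation.csv: trap '%s' missing",
                               traps_df$trap_id[is.na(ord)][1]))
  ord_t <- match(traps_df$trap_id, tm$trap_id)
  if (anyNA(ord_t)) stop(sprintf("time.csv: trap '%s' missing",
                                 traps_df$trap_id[is.na(ord_t)][1]))
  traps <- scr_traps(cbind(traps_df$x_km, traps_df$y_km), traps_df$type,
                     as.matrix(op[ord, -1, drop = FALSE]),
                     as.matrix(tm[ord_t, -1, drop = FALSE]),
                     ids = traps_df$trap_id)
  detections <- utils::read.csv(fp("detections.csv"), stringsAsFactors = FALSE)
  sexes <- utils::read.csv(fp("sexes.csv"), stringsAsFactors = FALSE)
  aux <- if (file.exists(fp("aux.csv")))
    utils::read.csv(fp("aux.csv"), stringsAsFactors = FALSE) else NULL
  if (!is.null(aux) && nrow(aux) == 0L) aux <- NULL
  data <- scr_data(space, traps, detections, sexes, aux, M = M)
  if (!quiet)
    message(sprintf(
      "read dataset: n = %d, J = %d, K = %d, R_tel = %d, R_opp = %d, nG = %d",
      data$n, traps$J, traps$K, data$R_tel, data$R_opp, space$n_pixels))
  data
}

# rebuild a state space from x,y,value rows on a regular grid
read_covariate_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("x", "y", "value") %in% names(df)))
    stop(sprintf("%s: expected columns x, y, value", path))
  grid_from_points(df$x, df$y, df$value, src = path)
}

grid_from_points <- function(x, y, value, src) {
  ux <- sort(unique(x)); uy <- sort(unique(y))
  res <- if (length(ux) > 1) min(diff(ux)) else if (length(uy) > 1) min(diff(uy)) else 1
  if (length(ux) > 1 && any(abs(diff(ux) / res - round(diff(ux) / res)) > 1e-6))
    stop(sprintf("%s: x coordinates are not on a regular grid", src))
  if (length(uy) > 1 && any(abs(diff(uy) / res - round(diff(uy) / res)) > 1e-6))
    stop(sprintf("%s: y coordinates are not on a regular grid", src))
  ord <- order(y, x)
  structure(
    list(centroids = cbind(x = x[ord], y = y[ord]), resolution = res,
         covariate = value[ord], n_pixels = length(x),
         nx = length(ux), ny = length(uy),
         x0 = ux[1] - res / 2, y0 = uy[1] - res / 2),
    class = "scr_state_space"
  )
}

# minimal ESRI ASCII grid reader (header + rows north-to-south)
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  for (k in c("ncols", "nrows", "cellsize"))
    if (is.null(hdr[[k]])) stop(sprintf("%s: missing '%s' in header", path, k))
  vals <- as.numeric(unlist(strsplit(trimws(lines[i:length(lines)]), "\\s+")))
  nc <- hdr$ncols; nr <- hdr$nrows; res <- hdr$cellsize
  if (length(vals) != nc * nr)
    stop(sprintf("%s: expected %d values, found %d", path, nc * nr, length(vals)))
  if (!is.null(hdr$nodata_value) && any(vals == hdr$nodata_value))
    stop(sprintf("%s: NODATA cells are not supported (mask-free grids only)", path))
  x0 <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else hdr$xllcenter - res / 2
  y0 <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else hdr$yllcenter - res / 2
  # file rows run north to south; flip into y-ascending order
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)[nr:1, , drop = FALSE]
  cx <- x0 + res * (seq_len(nc) - 0.5)
  cy <- y0 + res * (seq_len(nr) - 0.5)
  structure(
    list(centroids = cbind(x = rep(cx, times = nr), y = rep(cy, each = nc)),
         resolution = res, covariate = as.numeric(t(m)),
         n_pixels = nc * nr, nx = nc, ny = nr, x0 = x0, y0 = y0),
    class = "scr_state_space"
  )
}
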