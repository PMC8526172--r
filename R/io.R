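#' Read and write landscapes and fields
#'
#' Landscapes serialize to JSON (template, centres, density, seed,
#' domain); speed and arrival-time fields to a CSV grid with a JSON
#' sidecar header (`<path>.json`) recording `h`, `nx`, `ny`, `v1`, `v2`
#' and the domain.
#'
#' @param fs a [feature_set()].
#' @param path file path.
#' @name frontscape-io
NULL

#' @rdname frontscape-io
#' @export
write_feature_set <- function(fs, path) {
  stopifnot(inherits(fs, "feature_set"))
  obj <- list(domain = fs$domain[c("Lx", "Ly", "periodic_y")],
              template = fs$template[c("kind", "shape", "a", "b")],
              rho = fs$rho, seed = fs$seed,
              centers = unname(fs$centers))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname frontscape-io
#' @export
read_feature_set <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  template <- structure(list(kind = obj$template$kind,
                             shape = obj$template$shape,
                             a = obj$template$a, b = obj$template$b),
                        class = "fs_feature")
  dom <- fs_domain(obj$domain$Lx, obj$domain$Ly, obj$domain$periodic_y)
  centers <- if (length(obj$centers)) matrix(obj$centers, ncol = 2)
             else matrix(numeric(0), 0, 2)
  feature_set(dom, template, centers,
              rho = if (is.null(obj$rho)) NA_real_ else obj$rho,
              seed = obj$seed)
}

write_grid <- function(values, meta, path) {
  utils::write.table(values, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname frontscape-io
#' @param field a `speed_field`.
#' @export
write_speed_field <- function(field, path) {
  stopifnot(inherits(field, "speed_field"))
  write_grid(field$v,
             list(h = field$h, nx = field$nx, ny = field$ny,
                  v1 = field$v1, v2 = field$v2,
                  domain = field$domain[c("Lx", "Ly", "periodic_y")]),
             path)
}

#' @rdname frontscape-io
#' @param af an `arrival_field`. Unreachable cells are stored as `inf`.
#' @export
write_arrival_field <- function(af, path) {
  stopifnot(inherits(af, "arrival_field"))
  write_grid(af$T,
             list(h = af$h, nx = af$nx, ny = af$ny, v1 = af$v1,
                  domain = af$domain[c("Lx", "Ly", "periodic_y")]),
             path)
}

#' @rdname frontscape-io
#' @param pop a `population` snapshot; written as a two-column CSV.
#' @export
write_population <- function(pop, path) {
  utils::write.csv(data.frame(x = pop$x, y = pop$y), path, row.names = FALSE)
  invisible(path)
}

#' @rdname frontscape-io
#' @param series a `front_series` from [ibm_run()]; written as CSV with
#'   `time` and `mean_front` columns (per-row profiles, when recorded, go
#'   to `<path>.profiles.csv`).
#' @export
write_front_series <- function(series, path) {
  utils::write.csv(data.frame(time = series$times,
                              mean_front = series$mean_front_positions),
                   path, row.names = FALSE)
  if (!is.null(series$profiles)) {
    utils::write.csv(series$profiles, paste0(path, ".profiles.csv"),
                     row.names = FALSE)
  }
  invisible(path)
}

#' @rdname frontscape-io
#' @param contours list of polylines from [front_contour()].
#' @param t contour level time recorded alongside each piece.
#' @export
write_contours <- function(contours, t, path) {
  pieces <- lapply(seq_along(contours), function(i) {
    cbind(t = t, piece = i, contours[[i]])
  })
  df <- if (length(pieces)) do.call(rbind, pieces) else
    data.frame(t = numeric(0), piece = integer(0), x = numeric(0),
               y = numeric(0))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
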