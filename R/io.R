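#' Read and write steady flow curves as CSV
#'
#' The interchange format is a plain CSV with header
#' `shear_rate,sigma_xy,N1` (SI units: 1/s, Pa, Pa), UTF-8, `'.'`
#' decimal separator; comment lines starting with `'#'` are tolerated on
#' reading. Round trips are lossless to full double precision.
#'
#' @param curve A `steady_shear_curve` data frame.
#' @param path File path.
#' @return `read_curve_csv` returns a validated `steady_shear_curve`.
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(all(c("shear_rate", "sigma_xy", "N1") %in% names(curve)))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("shear_rate,sigma_xy,N1", con)
  writeLines(sprintf("%.17g,%.17g,%.17g",
                     curve$shear_rate, curve$sigma_xy, curve$N1), con)
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
read_curve_csv <- function(path) {
  out <- tryCatch(
    read.csv(path, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse curve file '", path, "': ",
                             conditionMessage(e)))
  need <- c("shear_rate", "sigma_xy", "N1")
  miss <- setdiff(need, names(out))
  if (length(miss))
    stop("curve file '", path, "' is missing columns: ",
         paste(miss, collapse = ", "))
  bad <- which(!vapply(out[need], is.numeric, logical(1)))
  if (length(bad))
    stop("curve file '", path, "': non-numeric column '", need[bad[1]], "'")
  if (any(out$shear_rate < 0)) {
    row <- which(out$shear_rate < 0)[1]
    stop("curve file '", path, "', data row ", row,
         ": negative shear rate ", out$shear_rate[row])
  }
  if (is.unsorted(out$shear_rate, strictly = TRUE))
    stop("curve file '", path, "': shear rates must be strictly increasing")
  out <- out[, need]
  class(out) <- c("steady_shear_curve", "data.frame")
  out
}

#' Write/read an inverse-solver result as JSON
#'
#' Serialises per-restart parameters, errors, iteration counts and
#' convergence flags plus the aggregate mean/SD and a config echo, with
#' a format-version field.
#'
#' @param result An `inverse_result` from [solve_inverse()].
#' @param path File path.
#' @return `read_result_json` returns a list mirroring the JSON.
#' @export
write_result_json <- function(result, path) {
  stopifnot(inherits(result, "inverse_result"))
  restarts <- lapply(result$restarts, function(r) {
    list(params = r$theta[.RP_FREE_PARAMS],
         error = r$error, iterations = r$iterations,
         converged = r$converged,
         unidentified = as.list(setNames(as.logical(r$unidentified),
                                         .RP_FREE_PARAMS)))
  })
  obj <- list(format_version = 1L,
              backend = result$backend,
              n_converged = result$n_converged,
              all_failed = result$all_failed,
              summary = result$summary,
              restarts = restarts,
              config = unclass(result$config))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "rows", null = "null")
  invisible(path)
}

#' @rdname write_result_json
#' @export
read_result_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}
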