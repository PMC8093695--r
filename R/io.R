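# CSV ingest for GPS fixes and immersion (wet/dry) events, table writers,
# and the run manifest. CSV is the canonical interchange format so that
# fixtures stay diff-able.

parse_timestamp <- function(x) {
  fmts <- c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
            "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d")
  res <- rep(NA_real_, length(x))
  for (f in fmts) {
    idx <- which(is.na(res))
    if (!length(idx)) break
    t <- as.POSIXct(strptime(x[idx], f, tz = "UTC"), tz = "UTC")
    res[idx[!is.na(t)]] <- as.numeric(t[!is.na(t)])
  }
  if (anyNA(res)) {
    stop("unparseable timestamp(s) at row(s): ",
         paste(utils::head(which(is.na(res)), 5), collapse = ", "))
  }
  as.POSIXct(res, origin = "1970-01-01", tz = "UTC")
}

#' Read GPS fixes from CSV
#'
#' Expects header columns `bird_id`, `timestamp` (ISO-8601, UTC), `lat`,
#' `lon`. Rows are sorted by (bird, time); exact duplicate rows are dropped
#' with a message.
#'
#' @param path CSV path.
#' @return Data frame of fixes sorted by `bird_id`, `timestamp`.
#' @export
read_fixes <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("bird_id", "timestamp", "lat", "lon")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("fixes file missing column(s): ",
                         paste(miss, collapse = ", "))
  bad_lat <- which(d$lat < -90 | d$lat > 90)
  if (length(bad_lat)) stop("latitude out of [-90, 90] at row(s): ",
                            paste(utils::head(bad_lat, 5), collapse = ", "))
  bad_lon <- which(d$lon <= -180 | d$lon > 180)
  if (length(bad_lon)) stop("longitude out of (-180, 180] at row(s): ",
                            paste(utils::head(bad_lon, 5), collapse = ", "))
  d$timestamp <- parse_timestamp(d$timestamp)
  ndup <- sum(duplicated(d))
  if (ndup > 0) {
    message(ndup, " duplicate fix row(s) dropped")
    d <- d[!duplicated(d), , drop = FALSE]
  }
  d <- d[order(d$bird_id, d$timestamp), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Read wet/dry immersion events from CSV
#'
#' Expects columns `bird_id`, `timestamp`, `event` with event tokens
#' `wet_in` / `wet_out`. Within a bird, two consecutive `wet_in` (or
#' `wet_out`) events are repaired by dropping the earlier one, with a
#' message.
#'
#' @param path CSV path.
#' @return Data frame of alternating events per bird.
#' @export
read_dives <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(d) == 0) {
    warning("empty dive file: ", path)
    return(data.frame(bird_id = character(), timestamp = parse_timestamp(character(0)),
                      event = character(), stringsAsFactors = FALSE))
  }
  need <- c("bird_id", "timestamp", "event")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("dive file missing column(s): ",
                         paste(miss, collapse = ", "))
  bad <- which(!d$event %in% c("wet_in", "wet_out"))
  if (length(bad)) stop("unknown event token at row(s): ",
                        paste(utils::head(bad, 5), collapse = ", "))
  d$timestamp <- parse_timestamp(d$timestamp)
  d <- d[order(d$bird_id, d$timestamp), , drop = FALSE]
  keep <- rep(TRUE, nrow(d))
  dropped <- 0L
  for (b in unique(d$bird_id)) {
    idx <- which(d$bird_id == b)
    ev <- d$event[idx]
    for (k in seq_along(idx)[-1]) {
      prev <- k - 1L
      while (prev >= 1 && !keep[idx[prev]]) prev <- prev - 1L
      if (prev >= 1 && ev[k] == ev[prev]) {
        keep[idx[prev]] <- FALSE   # drop the earlier orphan
        dropped <- dropped + 1L
      }
    }
  }
  if (dropped > 0) message(dropped, " orphaned wet/dry event(s) repaired")
  d <- d[keep, , drop = FALSE]
  rownames(d) <- NULL
  d
}

write_table_csv <- function(d, path) {
  d2 <- d
  for (nm in names(d2)) {
    if (inherits(d2[[nm]], "POSIXct")) {
      d2[[nm]] <- format(d2[[nm]], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    }
  }
  utils::write.csv(d2, path, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records inputs, seed, package version and row counts so a run can be
#' reproduced bit-exactly from the same config and seed.
#'
#' @param path Output JSON path.
#' @param inputs Named list/character of input files or parameters.
#' @param seed Integer seed used.
#' @param counts Named list of row counts.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, inputs, seed, counts = list()) {
  manifest <- list(
    package = "petrelwind",
    version = as.character(utils::packageVersion("petrelwind")),
    seed = as.integer(seed),
    inputs = inputs,
    counts = counts
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
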