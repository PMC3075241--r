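# Bout-log text format
#
# One header line:
#   #ethotracer-bout <TAB> fly_id cage_id start_iso start_s rate_hz duration_s
#                     food(x,y,z) water(x,y,z) cage(w,d,h,topfrac)
# then one tab-separated data line per frame:
#   frame_index  t_offset_s  x  y  z  code
# with positions in mm at 3 decimals, times at 1 decimal, and code one of
# R/M/W/F/E/D or "-" for an unclassified frame.

#' Write a bout to a bout-log text file
#'
#' Serializes a [bout()] into the package's line-per-frame TSV format, the
#' compact text representation the monitor keeps instead of raw video.
#'
#' @param b A valid [bout()].
#' @param path File path or connection to write to.
#' @param expStart Experiment start datetime used to render the bout's
#'   absolute ISO-8601 start timestamp in the header.
#' @return Invisibly, the number of data lines written.
#' @seealso [readBoutLog()]
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeBoutLog(makeStationaryBout(10), f)
#' readBoutLog(f)
#' @export
writeBoutLog <- function(b, path,
                         expStart = as.POSIXct("2024-01-01 00:00:00", tz = "UTC")) {
  validObject(b)
  g <- b@geometry
  iso <- format(expStart + b@startTime, "%Y-%m-%dT%H:%M:%S")
  header <- paste(
    "#ethotracer-bout", b@flyId, b@cageId, iso,
    sprintf("%.1f", b@startTime), format(b@rateHz), format(b@durationS),
    paste(sprintf("%.3f", g@foodCenter), collapse = ","),
    paste(sprintf("%.3f", g@waterCenter), collapse = ","),
    paste(sprintf("%.4f", c(g@width, g@depth, g@height, g@topFraction)),
          collapse = ","),
    sep = "\t")
  fr <- b@frames
  code <- behaviorCodes()[fr$label]
  code[is.na(code)] <- "-"
  lines <- sprintf("%d\t%.1f\t%.3f\t%.3f\t%.3f\t%s",
                   seq_len(nrow(fr)) - 1L, fr$t, fr$x, fr$y, fr$z, code)
  con <- if (inherits(path, "connection")) path else file(path, "w")
  if (!inherits(path, "connection")) on.exit(close(con))
  writeLines(c(header, lines), con)
  invisible(length(lines))
}

#' Read a bout-log text file
#'
#' Reconstructs a [bout()] from a file produced by [writeBoutLog()], at the
#' serialized precision (mm to 3 decimals, seconds to 1 decimal).
#'
#' @param path File path or connection.
#' @return A `Bout`.
#' @export
readBoutLog <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1L || !startsWith(lines[1], "#ethotracer-bout"))
    stop("parse error at line 1: missing bout-log header")
  h <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(h) != 10L)
    stop("parse error at line 1: header must have 10 tab-separated fields")
  num3 <- function(s, what) {
    v <- suppressWarnings(as.numeric(strsplit(s, ",", fixed = TRUE)[[1]]))
    if (anyNA(v)) stop(sprintf("parse error at line 1: bad %s", what))
    v
  }
  food <- num3(h[8], "food coordinates")
  water <- num3(h[9], "water coordinates")
  cage <- num3(h[10], "cage dimensions")
  geom <- cageGeometry(cage[1], cage[2], cage[3], food, water, cage[4])
  rate <- as.numeric(h[6]); dur <- as.numeric(h[7])
  dataLines <- lines[-1]
  nExp <- round(rate * dur)
  if (length(dataLines) != nExp)
    stop(sprintf("validation error: %d data lines but header implies %d",
                 length(dataLines), nExp))
  parts <- strsplit(dataLines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 6L))
    stop(sprintf("parse error at line %d: expected 6 tab-separated fields, got %d",
                 which(nf != 6L)[1] + 1L, nf[nf != 6L][1]))
  m <- matrix(unlist(parts), ncol = 6L, byrow = TRUE)
  num <- suppressWarnings(apply(m[, 2:5, drop = FALSE], 2, as.numeric))
  num <- matrix(num, ncol = 4L)
  if (anyNA(num))
    stop(sprintf("parse error at line %d: non-numeric field",
                 which(rowSums(is.na(num)) > 0)[1] + 1L))
  badCode <- !(m[, 6] %in% c(behaviorCodes(), "-"))
  if (any(badCode))
    stop(sprintf("parse error at line %d: unknown behavior code '%s'",
                 which(badCode)[1] + 1L, m[badCode, 6][1]))
  frames <- data.frame(t = num[, 1], x = num[, 2], y = num[, 3], z = num[, 4],
                       label = .labelFromCode(m[, 6]))
  bout(h[2], h[3], as.numeric(h[5]), rate, dur, frames, geom)
}

# --- minimal section/key=value config reader --------------------------------

.parseIni <- function(path) {
  lines <- readLines(path)
  lines <- sub("[#;].*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list(); section <- "global"
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^\\[.+\\]$", ln)) {
      section <- sub("^\\[(.+)\\]$", "\\1", ln)
      if (is.null(out[[section]])) out[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1])
      val <- trimws(paste(kv[-1], collapse = "="))
      val <- gsub('^"|"$', "", val)
      num <- suppressWarnings(as.numeric(strsplit(val, ",", fixed = TRUE)[[1]]))
      out[[section]][[key]] <- if (anyNA(num)) val else num
    } else {
      stop(sprintf("config parse error: cannot interpret '%s'", ln))
    }
  }
  out
}

.applyKeys <- function(args, given, map) {
  for (key in names(given)) {
    if (!key %in% names(map)) stop(sprintf("unknown config key '%s'", key))
    args[[map[[key]]]] <- given[[key]]
  }
  args
}

#' Load experiment, classifier, cage and stereo configuration from a file
#'
#' Reads a flat sectioned key/value file with sections `[experiment]`,
#' `[classifier]`, `[cage]` and `[stereo]` (keys in snake_case matching the
#' constructor arguments, e.g. `delta_rest = 1`). Unspecified fields take
#' the documented defaults; invariant violations raise a validation error
#' naming the field.
#'
#' @param path Path to the config file.
#' @return A named list with elements `experiment`
#'   ([experimentConfig()]), `classifier` ([classifierConfig()]), `cage`
#'   ([cageGeometry()]) and `stereo` ([stereoRig()]).
#' @examples
#' f <- tempfile(fileext = ".cfg")
#' writeLines(c("[classifier]", "delta_rest = 0.5"), f)
#' loadConfig(f)$classifier
#' @export
loadConfig <- function(path) {
  ini <- if (is.null(path)) list() else .parseIni(path)
  expMap <- c(cages = "cages", rate_hz = "rateHz", bout_duration_s = "boutDurationS",
              process_s = "processS", lights_on_hour = "lightsOnHour",
              lights_off_hour = "lightsOffHour", start = "start")
  clsMap <- c(delta_rest = "deltaRest", delta_walk = "deltaWalk",
              delta_fly = "deltaFly", window_n = "windowN",
              feed_min_points = "feedMinPoints", feed_radius = "feedRadius",
              drink_radius = "drinkRadius", death_hours = "deathHours")
  cageMap <- c(width = "width", depth = "depth", height = "height",
               food_center = "foodCenter", water_center = "waterCenter",
               top_fraction = "topFraction")
  rigMap <- c(focal_px = "focalPx", baseline_mm = "baselineMm",
              principal_point = "principalPoint", image_size = "imageSize",
              standoff_mm = "standoffMm")
  expArgs <- .applyKeys(list(), ini$experiment, expMap)
  if (!is.null(expArgs$start))
    expArgs$start <- as.POSIXct(expArgs$start, tz = "UTC")
  clsArgs <- .applyKeys(list(), ini$classifier, clsMap)
  cageArgs <- .applyKeys(list(), ini$cage, cageMap)
  rigArgs <- .applyKeys(list(), ini$stereo, rigMap)
  res <- list(experiment = do.call(experimentConfig, expArgs),
              classifier = do.call(classifierConfig, clsArgs),
              cage = do.call(cageGeometry, cageArgs),
              stereo = do.call(stereoRig, rigArgs))
  # disjoint station disks are a config-level invariant of the feeding rule
  cl <- res$classifier; g <- res$cage
  if (sqrt(sum((g@foodCenter - g@waterCenter)^2)) <= cl@feedRadius + cl@drinkRadius)
    stop("validation error: feed_radius/drink_radius disks overlap between stations")
  res
}
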