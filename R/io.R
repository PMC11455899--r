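# Reading the standard tables, receiver clock-drift correction, and
# joining detections to fish metadata.

#' Read a detection CSV
#'
#' Expects header `timestamp,station_id,tag_id,sensor,value` with ISO-8601
#' UTC timestamps. Malformed rows (unparseable timestamp, missing value,
#' negative depth) are rejected individually and counted; a missing column
#' is a schema error.
#'
#' @param path CSV path.
#' @return A data frame of typed detections sorted as read, with attribute
#'   `n_rejected` (count) and `rejected_lines` (1-based data-row numbers).
#' @export
read_detections <- function(path) {
  .check(file.exists(path), paste("file not found:", path))
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  need <- c("timestamp", "station_id", "tag_id", "sensor", "value")
  miss <- setdiff(need, names(d))
  .check(length(miss) == 0L,
         paste("detection CSV missing column(s):", paste(miss, collapse = ", ")))
  ts <- suppressWarnings(.parse_utc(d$timestamp))
  val <- suppressWarnings(as.numeric(d$value))
  bad <- is.na(ts) | is.na(val) | (d$sensor == "depth" & val < 0)
  out <- data.frame(timestamp = ts[!bad], station_id = d$station_id[!bad],
                    tag_id = d$tag_id[!bad], sensor = d$sensor[!bad],
                    value = val[!bad], stringsAsFactors = FALSE)
  attr(out, "n_rejected") <- sum(bad)
  attr(out, "rejected_lines") <- which(bad)
  if (any(bad))
    warning(sprintf("rejected %d malformed detection row(s) (data rows: %s)",
                    sum(bad), paste(utils::head(which(bad), 10), collapse = ", ")),
            call. = FALSE)
  out
}

#' Read a fish metadata CSV
#'
#' Expects header `tag_id,fish_id,sex,length_cm,tagging_date,ground,region`.
#' Only sexed fish with positive length are valid rows.
#'
#' @param path CSV path.
#' @return Data frame of fish records with attribute `n_rejected`.
#' @export
read_fish <- function(path) {
  .check(file.exists(path), paste("file not found:", path))
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  need <- c("tag_id", "fish_id", "sex", "length_cm", "tagging_date",
            "ground", "region")
  miss <- setdiff(need, names(d))
  .check(length(miss) == 0L,
         paste("fish CSV missing column(s):", paste(miss, collapse = ", ")))
  len <- suppressWarnings(as.numeric(d$length_cm))
  tdate <- suppressWarnings(as.Date(d$tagging_date))
  bad <- is.na(len) | len <= 0 | !(d$sex %in% c("F", "M")) | is.na(tdate)
  out <- data.frame(tag_id = d$tag_id[!bad], fish_id = d$fish_id[!bad],
                    sex = d$sex[!bad], length_cm = len[!bad],
                    tagging_date = tdate[!bad], ground = d$ground[!bad],
                    region = d$region[!bad], stringsAsFactors = FALSE)
  attr(out, "n_rejected") <- sum(bad)
  out
}

#' Read a receiver clock table CSV
#'
#' Expects header
#' `station_id,deploy_time,download_time,offset_deploy_s,offset_download_s`.
#' Offsets are receiver clock minus satellite clock, seconds, at
#' initiation and at download.
#'
#' @param path CSV path.
#' @return Data frame of receiver clock records.
#' @export
read_clocks <- function(path) {
  .check(file.exists(path), paste("file not found:", path))
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("station_id", "deploy_time", "download_time",
            "offset_deploy_s", "offset_download_s")
  miss <- setdiff(need, names(d))
  .check(length(miss) == 0L,
         paste("clock CSV missing column(s):", paste(miss, collapse = ", ")))
  out <- data.frame(station_id = as.character(d$station_id),
                    deploy_time = .parse_utc(d$deploy_time),
                    download_time = .parse_utc(d$download_time),
                    offset_deploy_s = as.numeric(d$offset_deploy_s),
                    offset_download_s = as.numeric(d$offset_download_s),
                    stringsAsFactors = FALSE)
  .check(all(out$deploy_time < out$download_time),
         "deploy_time must precede download_time")
  out
}

#' Correct detections for receiver clock drift
#'
#' Applies the linear correction anchored at the satellite clock offsets
#' observed at receiver initiation and download: with elapsed fraction
#' `f = (recorded - deploy) / (download - deploy)`, the corrected time is
#' `recorded - (offset_deploy + (offset_download - offset_deploy) * f)`.
#' Positive offsets mean the receiver clock ran ahead of satellite time.
#' Detections outside a receiver's deployment window are flagged and get
#' the correction clamped to the nearest endpoint, with a warning.
#'
#' @param detections detection data frame (needs `timestamp`, `station_id`).
#' @param clocks receiver clock table as from [read_clocks()].
#' @return The detections with corrected `timestamp`, sorted by corrected
#'   time (ties broken by `station_id`, then input order); the original
#'   times are kept in `timestamp_raw` and out-of-window rows are marked
#'   in the logical column `clamped`.
#' @export
correct_clock_drift <- function(detections, clocks) {
  i <- match(detections$station_id, clocks$station_id)
  .check(!anyNA(i), "detections reference stations absent from clock table")
  dep <- as.numeric(clocks$deploy_time)[i]
  dwn <- as.numeric(clocks$download_time)[i]
  rec <- as.numeric(detections$timestamp)
  f <- (rec - dep) / (dwn - dep)
  clamped <- f < 0 | f > 1
  if (any(clamped))
    warning(sprintf("%d detection(s) outside deployment window; correction clamped",
                    sum(clamped)), call. = FALSE)
  f <- pmin(1, pmax(0, f))
  off <- clocks$offset_deploy_s[i] +
    (clocks$offset_download_s[i] - clocks$offset_deploy_s[i]) * f
  out <- detections
  out$timestamp_raw <- detections$timestamp
  out$timestamp <- .as_utc(rec - off)
  out$clamped <- clamped
  o <- order(out$timestamp, out$station_id, seq_len(nrow(out)))
  out[o, , drop = FALSE]
}

#' Join detections to fish metadata
#'
#' Maps `tag_id` to `fish_id` and attaches sex, length, ground and region
#' to every detection. Detections whose tag is absent from the metadata go
#' to an `unmatched` bucket; a duplicated `tag_id` in the metadata is an
#' error (ambiguous identity).
#'
#' @param detections detection data frame.
#' @param fish fish metadata as from [read_fish()].
#' @return A list: `matched` (detections with fish columns attached) and
#'   `unmatched` (the remainder), plus `n_unmatched`.
#' @export
join_metadata <- function(detections, fish) {
  .check(!anyDuplicated(fish$tag_id),
         "duplicate tag_id in fish metadata; fish identity ambiguous")
  i <- match(detections$tag_id, fish$tag_id)
  known <- !is.na(i)
  matched <- detections[known, , drop = FALSE]
  j <- i[known]
  matched$fish_id <- fish$fish_id[j]
  matched$sex <- fish$sex[j]
  matched$length_cm <- fish$length_cm[j]
  matched$tagging_date <- fish$tagging_date[j]
  matched$ground <- fish$ground[j]
  matched$region <- fish$region[j]
  list(matched = matched,
       unmatched = detections[!known, , drop = FALSE],
       n_unmatched = sum(!known))
}
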