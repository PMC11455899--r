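# internal helpers shared across the pipeline

#' @keywords internal
.as_utc <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  if (inherits(x, "Date")) {
    return(as.POSIXct(format(x), tz = "UTC"))
  }
  as.POSIXct(x, tz = "UTC")
}

#' @keywords internal
.utc_date <- function(t) as.Date(t, tz = "UTC")

#' @keywords internal
.fmt_utc <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

# per-element parsing: unparseable strings become NA, never an error
#' @keywords internal
.parse_utc <- function(x) {
  out <- as.POSIXct(strptime(x, "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC"))
  for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d")) {
    miss <- is.na(out)
    if (!any(miss)) break
    out[miss] <- as.POSIXct(strptime(x[miss], fmt, tz = "UTC"))
  }
  out
}

# stopifnot with a friendlier message
#' @keywords internal
.check <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

# sliding-window range (max - min) over [t_i, t_i + window_s] per element,
# via a doubling (sparse-table) scheme: O(n log n), fully vectorised.
# Returns list(lo, hi, n_in_window) where lo/hi are min/max of x over the
# window starting at each index and n_in_window the number of points in it.
#' @keywords internal
.window_range <- function(t, x, window_s) {
  n <- length(t)
  if (n == 0L) return(list(lo = numeric(0), hi = numeric(0), n = integer(0)))
  # last index whose time is <= t_i + window_s
  e <- findInterval(as.numeric(t) + window_s, as.numeric(t))
  # sparse tables: level k holds min/max over blocks of length 2^k
  K <- max(1L, ceiling(log2(max(1L, max(e - seq_len(n) + 1L)))))
  mn <- mx <- vector("list", K + 1L)
  mn[[1L]] <- x; mx[[1L]] <- x
  len <- 1L
  for (k in seq_len(K)) {
    prev_mn <- mn[[k]]; prev_mx <- mx[[k]]
    m <- length(prev_mn) - len
    if (m <= 0L) { mn[[k + 1L]] <- prev_mn; mx[[k + 1L]] <- prev_mx; next }
    idx <- seq_len(m)
    mn[[k + 1L]] <- pmin(prev_mn[idx], prev_mn[idx + len])
    mx[[k + 1L]] <- pmax(prev_mx[idx], prev_mx[idx + len])
    len <- len * 2L
  }
  w <- e - seq_len(n) + 1L            # window lengths in points
  k <- pmax(0L, floor(log2(pmax(1L, w))))
  half <- bitwShiftL(1L, k)
  i1 <- seq_len(n)
  i2 <- e - half + 1L
  lo <- hi <- numeric(n)
  for (kk in sort(unique(k))) {
    sel <- which(k == kk)
    tab_mn <- mn[[kk + 1L]]; tab_mx <- mx[[kk + 1L]]
    lo[sel] <- pmin(tab_mn[i1[sel]], tab_mn[i2[sel]])
    hi[sel] <- pmax(tab_mx[i1[sel]], tab_mx[i2[sel]])
  }
  list(lo = lo, hi = hi, n = w)
}

#' @keywords internal
.se <- function(x) {
  n <- sum(!is.na(x))
  if (n < 2L) return(NA_real_)
  stats::sd(x, na.rm = TRUE) / sqrt(n)
}
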