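#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_normkit <- function(msg, class) {
  stop(structure(class = c(class, "normkit_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

assert_that <- function(ok, msg, class = "normkit_invalid") {
  if (!isTRUE(ok)) abort_normkit(msg, class)
  invisible(TRUE)
}

## ---- seeded RNG ------------------------------------------------------------

# Run code under a temporary RNG seed, restoring global RNG state afterwards.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# Deterministic 31-bit sub-stream seed from a base seed plus arbitrary tags.
# Plain modular hash; keeps every derived seed in [1, 2^31 - 2].
derive_seed <- function(seed, ...) {
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (tag in list(...)) {
    bytes <- utf8ToInt(paste0("|", paste(format(tag, scientific = FALSE,
                                                trim = TRUE), collapse = ",")))
    for (b in bytes) h <- (h * 69069 + b) %% m
  }
  as.integer(max(1, h))
}

## ---- hashing & JSON --------------------------------------------------------

# md5 of a character string (base R only: via a temp file and tools::md5sum)
md5_string <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  tf <- tempfile(fileext = ".md5")
  on.exit(unlink(tf))
  con <- file(tf, open = "wb")
  writeBin(charToRaw(x), con)
  close(con)
  unname(tools::md5sum(tf))
}

# Canonical JSON: sorted object keys, unboxed scalars, full precision.
canonical_json <- function(x) {
  as.character(jsonlite::toJSON(sort_names(x), auto_unbox = TRUE,
                                digits = NA, null = "null"))
}

sort_names <- function(x) {
  if (is.list(x) && !is.null(names(x)) && length(x)) {
    x <- x[order(names(x))]
    lapply(x, sort_names)
  } else if (is.list(x)) lapply(x, sort_names) else x
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

read_json_file <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
}

## ---- time ------------------------------------------------------------------

# All datetimes are handled timezone-naive in UTC at second precision.
format_datetime <- function(t) format(t, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

parse_datetime <- function(s) as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%S",
                                         tz = "UTC")

## ---- interval algebra ------------------------------------------------------

# Intervals are half-open [start, end) in seconds, kept as a data.frame with
# columns start, end (plus optional payload columns), sorted and disjoint.

intervals <- function(start = numeric(), end = numeric(), ...) {
  df <- data.frame(start = as.numeric(start), end = as.numeric(end), ...)
  df <- df[df$end > df$start, , drop = FALSE]
  if (nrow(df)) df <- df[order(df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

interval_total <- function(iv) if (nrow(iv)) sum(iv$end - iv$start) else 0

# Merge touching/overlapping intervals (payload columns dropped).
interval_union <- function(iv) {
  if (nrow(iv) < 2L) return(intervals(iv$start, iv$end))
  iv <- iv[order(iv$start, iv$end), , drop = FALSE]
  out_s <- iv$start[1]; out_e <- iv$end[1]
  starts <- numeric(); ends <- numeric()
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv$start[i] <= out_e) out_e <- max(out_e, iv$end[i])
    else { starts <- c(starts, out_s); ends <- c(ends, out_e)
           out_s <- iv$start[i]; out_e <- iv$end[i] }
  }
  intervals(c(starts, out_s), c(ends, out_e))
}

# Intersection of one interval set with another; payload columns of `a` kept.
interval_intersect <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(a[0, , drop = FALSE])
  out <- list()
  for (i in seq_len(nrow(a))) {
    s <- pmax(a$start[i], b$start); e <- pmin(a$end[i], b$end)
    keep <- e > s
    if (any(keep)) {
      row <- a[rep(i, sum(keep)), , drop = FALSE]
      row$start <- s[keep]; row$end <- e[keep]
      out[[length(out) + 1L]] <- row
    }
  }
  if (!length(out)) return(a[0, , drop = FALSE])
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Subtract interval set `b` from `a`; payload columns of `a` kept.
interval_subtract <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(a)
  b <- interval_union(b)
  out <- list()
  for (i in seq_len(nrow(a))) {
    pieces <- data.frame(start = a$start[i], end = a$end[i])
    for (j in seq_len(nrow(b))) {
      nxt <- list()
      for (k in seq_len(nrow(pieces))) {
        s <- pieces$start[k]; e <- pieces$end[k]
        bs <- b$start[j]; be <- b$end[j]
        if (be <= s || bs >= e) { nxt[[length(nxt) + 1L]] <- c(s, e); next }
        if (bs > s) nxt[[length(nxt) + 1L]] <- c(s, bs)
        if (be < e) nxt[[length(nxt) + 1L]] <- c(be, e)
      }
      pieces <- if (length(nxt)) {
        m <- do.call(rbind, nxt)
        data.frame(start = m[, 1], end = m[, 2])
      } else data.frame(start = numeric(), end = numeric())
      if (!nrow(pieces)) break
    }
    if (nrow(pieces)) {
      row <- a[rep(i, nrow(pieces)), , drop = FALSE]
      row$start <- pieces$start; row$end <- pieces$end
      out[[length(out) + 1L]] <- row
    }
  }
  if (!length(out)) return(a[0, , drop = FALSE])
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

## ---- robust statistics -----------------------------------------------------

#' Robust z-scores across a vector
#'
#' Centre and scale by median and scaled MAD (consistency constant 1.4826).
#' When the MAD is zero (degenerate spread) values equal to the median get
#' z = 0 and any other value gets +/- Inf, so a single deviant among
#' identical values is still flagged.
#'
#' @param x numeric vector.
#' @return numeric vector of robust z-scores.
#' @export
robust_z <- function(x) {
  med <- stats::median(x)
  s <- stats::mad(x, center = med)
  if (s == 0 || !is.finite(s)) {
    z <- ifelse(x == med, 0, Inf * sign(x - med))
  } else {
    z <- (x - med) / s
  }
  z
}
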