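#' @keywords internal
"_PACKAGE"

# Canonical subtype order; which.max over this order implements the
# documented tie-break priority H3K27M > IDH > DW.
SUBTYPES <- c("H3K27M", "IDH", "DW")

MARKER_CLASSES <- c("H3_specific", "IDH_specific")

H3_DRIVER_GENES <- c("H3F3A", "HIST1H3B", "HIST1H3C")
IDH_DRIVER_GENES <- c("IDH1", "IDH2")

# DNA-mass threshold (ng) below which CSF samples get methylation testing only
BLOD_THRESHOLD_NG <- 5

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_unit_interval <- function(x, field, allow_na = FALSE) {
  if (!is.numeric(x)) stop_field(field, "must be numeric")
  bad <- if (allow_na) {
    !is.na(x) & (!is.finite(x) | x < 0 | x > 1)
  } else {
    !is.finite(x) | x < 0 | x > 1
  }
  if (any(bad)) stop_field(field, "all values must be finite and in [0, 1]")
  invisible(x)
}

check_count <- function(x, field) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x != floor(x))) {
    stop_field(field, "must be a non-negative integer")
  }
  invisible(x)
}

# Write through a temp file in the destination directory, then rename:
# readers never observe a partially written file.
atomic_write <- function(writer, path) {
  tmp <- tempfile(pattern = ".tmp_", tmpdir = dirname(path))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not move temp file onto ", path)
  invisible(path)
}
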