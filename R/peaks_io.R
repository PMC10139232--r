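#  Reading and writing fragment-analysis peak tables. Peaks arrive pre-sized
#  against a size standard; no trace (FSA/ABIF) parsing happens here.

#' Construct a sample run from peak vectors
#'
#' @param sample_id non-empty sample identifier.
#' @param channel channel codes or dye labels (normalized via
#'   [normalize_dye()]).
#' @param size fragment sizes in nt (positive).
#' @param height peak heights in RFU (non-negative).
#' @return a `sample_run`: list with `sample_id` and a `peaks` data.frame
#'   (`channel`, `size`, `height`).
#' @export
sample_run <- function(sample_id, channel = character(0),
                       size = numeric(0), height = numeric(0)) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L,
            nzchar(sample_id))
  if (length(channel)) channel <- normalize_dye(channel)
  size <- as.numeric(size)
  height <- as.numeric(height)
  if (any(!is.finite(size)) || any(size <= 0)) {
    stop("peak sizes must be positive numbers", call. = FALSE)
  }
  if (any(!is.finite(height)) || any(height < 0)) {
    stop("peak heights must be non-negative numbers", call. = FALSE)
  }
  structure(list(
    sample_id = sample_id,
    peaks = data.frame(channel = as.character(channel), size = size,
                       height = height, stringsAsFactors = FALSE)
  ), class = "sample_run")
}

#' @export
print.sample_run <- function(x, ...) {
  cat(sprintf("<sample_run> %s: %d peaks\n", x$sample_id, nrow(x$peaks)))
  if (nrow(x$peaks)) print(x$peaks, row.names = FALSE)
  invisible(x)
}

.sniff_delim <- function(header) {
  counts <- c("\t" = lengths(regmatches(header, gregexpr("\t", header))),
              "," = lengths(regmatches(header, gregexpr(",", header))),
              ";" = lengths(regmatches(header, gregexpr(";", header))))
  if (all(counts == 0)) {
    stop("could not detect a delimiter in the header row", call. = FALSE)
  }
  names(which.max(counts))
}

.match_col <- function(cols, name) {
  hit <- which(tolower(trimws(cols)) == name)
  if (length(hit) == 0L) {
    stop(sprintf("missing required column '%s'", name), call. = FALSE)
  }
  hit[1L]
}

.parse_num <- function(x, what, lines) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out))
  if (length(bad)) {
    stop(sprintf("unparseable %s value '%s' on line %d", what, x[bad[1L]],
                 lines[bad[1L]]), call. = FALSE)
  }
  out
}

#' Read a peak table
#'
#' Two delimited-text dialects are supported. `simple` has one peak per row
#' with columns `sample`, `dye`, `size`, `height`; the delimiter (tab, comma
#' or semicolon) is sniffed from the header row. `genemapper_export` is the
#' tab-delimited genotypes-table export of common fragment-analysis software:
#' one row per sample (columns `Sample File`/`Sample Name` and `Dye`), with
#' repeated `Size N` / `Height N` column pairs (or `Dye N`/`Size N`/`Height N`
#' triplets when dyes vary within a row).
#'
#' Dye strings are normalized with [normalize_dye()], so `"6-FAM"`, `"FAM"`,
#' `"B"` and `"blue"` are equivalent.
#'
#' @param source path to a file, or a character vector of lines.
#' @param dialect `"simple"` (default) or `"genemapper_export"`.
#' @return list of [sample_run()] objects, one per distinct sample id, peaks
#'   in input order.
#' @export
read_peak_table <- function(source, dialect = c("simple", "genemapper_export")) {
  dialect <- match.arg(dialect)
  lines <- if (length(source) == 1L && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else {
    unlist(strsplit(source, "\n", fixed = TRUE))
  }
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty input: no header row", call. = FALSE)
  if (dialect == "simple") .read_simple(lines) else .read_genemapper(lines)
}

.read_simple <- function(lines) {
  delim <- .sniff_delim(lines[1L])
  tab <- utils::read.table(text = lines, sep = delim, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "")
  cols <- names(tab)
  i_s <- .match_col(cols, "sample")
  i_d <- .match_col(cols, "dye")
  i_z <- .match_col(cols, "size")
  i_h <- .match_col(cols, "height")
  if (nrow(tab) == 0L) return(list())
  line_no <- seq_len(nrow(tab)) + 1L
  size <- .parse_num(tab[[i_z]], "size", line_no)
  height <- .parse_num(tab[[i_h]], "height", line_no)
  channel <- normalize_dye(tab[[i_d]])
  ids <- trimws(tab[[i_s]])
  lapply(unique(ids), function(id) {
    keep <- ids == id
    sample_run(id, channel[keep], size[keep], height[keep])
  })
}

.read_genemapper <- function(lines) {
  tab <- utils::read.table(text = lines, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "", fill = TRUE)
  cols <- trimws(names(tab))
  low <- tolower(cols)
  i_s <- which(low %in% c("sample file", "sample name", "sample"))[1L]
  if (is.na(i_s)) {
    stop("missing required column 'Sample File'/'Sample Name'", call. = FALSE)
  }
  size_cols <- grep("^size( [0-9]+)?$", low)
  height_cols <- grep("^height( [0-9]+)?$", low)
  dye_cols <- grep("^dye( [0-9]+)?$", low)
  if (!length(size_cols) || !length(height_cols)) {
    stop("missing required column 'Size'/'Height'", call. = FALSE)
  }
  if (length(size_cols) != length(height_cols)) {
    stop("Size and Height columns are not paired", call. = FALSE)
  }
  ids <- trimws(tab[[i_s]])
  runs <- list()
  for (r in seq_len(nrow(tab))) {
    ch <- sz <- ht <- c()
    for (k in seq_along(size_cols)) {
      sv <- trimws(tab[r, size_cols[k]])
      hv <- trimws(tab[r, height_cols[k]])
      if (!nzchar(sv) && !nzchar(hv)) next
      dye <- if (length(dye_cols) >= k) tab[r, dye_cols[k]] else
        tab[r, dye_cols[1L]]
      ch <- c(ch, dye)
      sz <- c(sz, .parse_num(sv, "size", r + 1L))
      ht <- c(ht, .parse_num(hv, "height", r + 1L))
    }
    id <- ids[r]
    if (is.null(runs[[id]])) {
      runs[[id]] <- list(ch = ch, sz = sz, ht = ht)
    } else {
      runs[[id]] <- list(ch = c(runs[[id]]$ch, ch),
                         sz = c(runs[[id]]$sz, sz),
                         ht = c(runs[[id]]$ht, ht))
    }
  }
  lapply(names(runs), function(id) {
    sample_run(id, runs[[id]]$ch, runs[[id]]$sz, runs[[id]]$ht)
  })
}

#' Write sample runs as a simple peak table
#'
#' Sizes are written with two decimals (fragment-analysis size calling is
#' sub-nucleotide); heights are rounded to integers. `read_peak_table()` on
#' the output reproduces the runs up to this rounding.
#'
#' @param runs a list of [sample_run()] objects (a single run is accepted).
#' @param path optional file path; when `NULL` the lines are returned.
#' @param delim field delimiter (default comma).
#' @return character vector of lines (invisibly when `path` is given).
#' @export
write_peak_table <- function(runs, path = NULL, delim = ",") {
  if (inherits(runs, "sample_run")) runs <- list(runs)
  header <- paste(c("sample", "dye", "size", "height"), collapse = delim)
  body <- unlist(lapply(runs, function(run) {
    if (nrow(run$peaks) == 0L) return(character(0))
    paste(run$sample_id, run$peaks$channel, sprintf("%.2f", run$peaks$size),
          round(run$peaks$height), sep = delim)
  }))
  lines <- c(header, body)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
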