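#' Write a BNp to a plain-text network file
#'
#' Format: a header line `n=<int> p=<float>`, then one line per gene,
#' `gene=<i> regs=<j1,j2,...> out=<bitstring of length 2^k>`.
#'
#' @param net a [bnp()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bnp <- function(net, path) {
  lines <- c(sprintf("n=%d p=%s", net$n, format(net$p, digits = 17)),
             vapply(net$tables, function(tt) {
               sprintf("gene=%d regs=%s out=%s", tt$gene,
                       paste0(tt$regulators, collapse = ","),
                       paste0(tt$outputs, collapse = ""))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a BNp from a plain-text network file
#'
#' @param path file written by [write_bnp()] (or by hand in the same format).
#' @return a [bnp()].
#' @export
read_bnp <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  hdr <- regmatches(lines[1],
                    regexec("^n=([0-9]+) p=([0-9.eE+-]+)$", lines[1]))[[1]]
  if (length(hdr) != 3) stop("malformed header line: ", lines[1])
  n <- as.integer(hdr[2])
  p <- as.numeric(hdr[3])
  body <- lines[-1]
  if (length(body) != n) {
    stop("header declares n=", n, " genes but file has ", length(body),
         " gene lines")
  }
  tables <- lapply(body, function(ln) {
    m <- regmatches(ln, regexec(
      "^gene=([0-9]+) regs=([0-9,]+) out=([01]+)$", ln))[[1]]
    if (length(m) != 4) stop("malformed gene line: ", ln)
    gene <- as.integer(m[2])
    regs <- as.integer(strsplit(m[3], ",")[[1]])
    out <- as.integer(strsplit(m[4], "")[[1]])
    if (length(out) != 2^length(regs)) {
      stop("gene ", gene, ": output bitstring length ", length(out),
           " does not match 2^k = ", 2^length(regs))
    }
    truth_table(gene, regs, out)
  })
  bnp(tables, p)
}

#' Write time series to a TSV file
#'
#' One row per time point, tab-separated 0/1 columns (gene 1 first); a blank
#' line separates consecutive series.
#'
#' @param series list of time-series matrices (or one matrix).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(series, path) {
  if (is.matrix(series)) series <- list(series)
  chunks <- lapply(series, function(m) apply(m, 1, paste0, collapse = "\t"))
  writeLines(unlist(lapply(seq_along(chunks), function(i) {
    if (i == 1) chunks[[i]] else c("", chunks[[i]])
  })), path)
  invisible(path)
}

#' Read time series from a TSV file
#'
#' @param path file in the format of [write_timeseries()].
#' @return list of integer 0/1 matrices, one per blank-line-separated series.
#' @export
read_timeseries <- function(path) {
  lines <- readLines(path)
  breaks <- cumsum(!nzchar(trimws(lines)))
  groups <- split(lines, breaks)
  series <- lapply(groups, function(g) {
    g <- g[nzchar(trimws(g))]
    if (length(g) == 0L) return(NULL)
    rows <- lapply(seq_along(g), function(i) {
      vals <- strsplit(trimws(g[i]), "[\t ]+")[[1]]
      if (!all(vals %in% c("0", "1"))) {
        stop("non-binary token in time-series row: '", g[i], "'")
      }
      as.integer(vals)
    })
    if (length(unique(lengths(rows))) != 1L) {
      stop("inconsistent column counts within one series")
    }
    do.call(rbind, rows)
  })
  series <- series[!vapply(series, is.null, logical(1))]
  names(series) <- NULL
  series
}
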