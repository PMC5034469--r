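#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx as.formula chisq.test coef complete.cases fisher.test
#'   ks.test lm logLik model.matrix pchisq phyper qnorm quantile resid rbinom
#'   rgamma rlnorm rnorm rpois runif sd setNames t.test var vcov
#' @importFrom utils read.delim write.table packageVersion
NULL

# 31-bit polynomial rolling hash; used for config provenance hashes.
hash31 <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "|"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

provenance_header <- function(seed = NA, params = list()) {
  pstr <- paste(names(params), unname(vapply(params, function(p)
    paste(format(p, digits = 10), collapse = ","), "")), sep = "=", collapse = ";")
  sprintf("# admrscan %s; seed=%s; params_hash=%s; %s",
          as.character(utils::packageVersion("admrscan")),
          as.character(seed), hash31(pstr), pstr)
}

#' Write a data frame as TSV with a provenance comment header
#'
#' All pipeline outputs are tab-separated with a single leading `#` comment
#' line recording the package version, seed and parameter hash.
#'
#' @param x data frame.
#' @param path output path.
#' @param seed integer seed recorded in the header.
#' @param params named list of parameters recorded in the header.
#' @return `path`, invisibly.
#' @export
write_tsv_hdr <- function(x, path, seed = NA, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(seed, params), con)
  suppressWarnings(write.table(x, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, col.names = TRUE))
  invisible(path)
}

#' Read a TSV written by [write_tsv_hdr()]
#' @param path file path.
#' @return data frame (comment lines skipped).
#' @export
read_tsv_hdr <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write intervals as BED (0-based, half-open, sorted)
#'
#' @param x data frame with columns `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand`.
#' @param path output path.
#' @param seed,params provenance header fields, see [write_tsv_hdr()].
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, seed = NA, params = list()) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  x <- x[order(x$chrom, x$start, x$end), , drop = FALSE]
  keep <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(x))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(seed, params), con)
  write.table(x[keep], con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED3+ file (0-based, half-open)
#' @param path file path.
#' @return data frame with `chrom`, `start`, `end` and, if present,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  x <- read.delim(path, header = FALSE, comment.char = "#",
                  stringsAsFactors = FALSE)
  names(x) <- c("chrom", "start", "end", "name", "score",
                "strand")[seq_len(ncol(x))]
  x
}

check_intervals <- function(x, what = "intervals") {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) && any(x$end <= x$start))
    stop("malformed ", what, ": end <= start")
  invisible(x)
}
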